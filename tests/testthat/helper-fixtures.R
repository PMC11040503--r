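# Shared fixtures and independent oracles, all built in code.

# Noise-free fully labeled model: one localization exactly on each corner.
perfectModel <- function(...) {
  args <- utils::modifyList(
    list(labelingEfficiency = 1, copiesPerCorner = 1L, blinksMean = 1,
         locPrecisionXY = 0, locPrecisionZ = 0, backgroundDensity = 0,
         globalRotation = 0, seed = 1L),
    list(...))
  do.call(NPCModel, args)
}

# Lay a simulated cohort out on a grid and return the pooled table with the
# known pick centers (emulating one imaged cell with picked NPCs).
cohortToTable <- function(cohort, spacing = 1000) {
  n <- length(cohort)
  ncol <- ceiling(sqrt(n))
  centers <- cbind(((seq_len(n) - 1) %% ncol) * spacing,
                   ((seq_len(n) - 1) %/% ncol) * spacing)
  evs <- do.call(rbind, lapply(seq_len(n), function(i) {
    ev <- eventData(cohort[[i]]$table)
    if (!nrow(ev)) return(NULL)
    ev$x <- ev$x + centers[i, 1]
    ev$y <- ev$y + centers[i, 2]
    ev
  }))
  tab <- if (is.null(evs)) LocalizationTable()
         else LocalizationTable(x = evs$x, y = evs$y,
                                z = if ("z" %in% names(evs)) evs$z else NULL)
  list(table = tab, centers = centers)
}

# Circular standard deviation (degrees) of angles with the given period.
circSdDeg <- function(anglesDeg, period = 45) {
  z <- exp(1i * anglesDeg * 2 * pi / period)
  R <- Mod(mean(z))
  sqrt(-2 * log(R)) * period / (2 * pi)
}

# Simultaneous (Bonferroni) binomial envelope check for a multinomial sample.
withinMultinomialEnvelope <- function(obsCounts, probs, n, alpha = 0.01) {
  a <- alpha / 2 / length(probs)
  lo <- stats::qbinom(a, n, probs)
  hi <- stats::qbinom(1 - a, n, probs)
  all(obsCounts >= lo & obsCounts <= hi)
}

# Independent brute-force minimizer of the fixed-period sine RSS: dense grid
# over the phase, closed-form (A, B) per phase by simple linear regression.
bruteForceSineRss <- function(hist, fold = 8, nGrid = 7200) {
  y <- hist@counts
  centers <- (hist@breaks[-length(hist@breaks)] + hist@breaks[-1]) / 2
  phis <- seq(0, 2 * pi, length.out = nGrid + 1)[-(nGrid + 1)]
  S <- sin(outer(fold * centers, phis, "+"))
  m <- length(y)
  sbar <- colMeans(S)
  ybar <- mean(y)
  cov_ys <- (crossprod(y, S) / m) - ybar * sbar
  var_s <- colMeans(S^2) - sbar^2
  B <- as.vector(cov_ys) / var_s
  A <- ybar - B * sbar
  rss <- vapply(seq_along(phis), function(k) {
    sum((y - (A[k] + B[k] * S[, k]))^2)
  }, numeric(1))
  min(rss)
}

# Boundary-inclusive point-in-polygon, via the package's internal routine.
pointInPolygonTest <- function(centers, roi) {
  if (!nrow(centers)) return(logical(0))
  npcfold:::pointInPolygon(centers[, 1], centers[, 2], roi@vertices)
}

# A random angular histogram (for sine-fit oracle comparisons).
randomHistogram <- function(nBins = 180, lambda = 20) {
  new("AngularHistogram",
      breaks = seq(0, 2 * pi, length.out = nBins + 1),
      counts = as.numeric(stats::rpois(nBins, lambda)))
}

# Exact histogram of a sine-valued intensity at the bin centers.
sineHistogram <- function(A, B, phi, nBins = 180, fold = 8) {
  breaks <- seq(0, 2 * pi, length.out = nBins + 1)
  centers <- (breaks[-length(breaks)] + breaks[-1]) / 2
  new("AngularHistogram", breaks = breaks,
      counts = A + B * sin(fold * centers + phi))
}
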