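# Radial profiles of aligned particles, axial side-view profiles with
# two-Gaussian ring fitting and midpoint alignment, and NPC surface density.

#' Radial distribution of events about the NPC center
#'
#' Histograms event radii and normalizes each bin by its annulus area
#' `pi * (r_out^2 - r_in^2)`, so a uniform disc gives a flat density. Raw
#' counts are always retained alongside.
#'
#' @param x a centered [LocalizationTable-class], [Particle-class] or
#'   [PolarEvents-class].
#' @param binWidth radial bin width in nm (default 5).
#' @param rMax outer radius in nm (default 130, the picking radius).
#' @return a [RadialProfile-class].
#' @export
radialProfile <- function(x, binWidth = 5, rMax = 130) {
  stopifnot(binWidth > 0, rMax > binWidth)
  r <- if (is(x, "PolarEvents")) x@r else toPolar(x)@r
  breaks <- seq(0, rMax, by = binWidth)
  if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
  idx <- findInterval(r, breaks, rightmost.closed = TRUE, left.open = FALSE)
  keep <- idx >= 1 & idx <= length(breaks) - 1
  counts <- tabulate(idx[keep], nbins = length(breaks) - 1L)
  area <- pi * (breaks[-1]^2 - breaks[-length(breaks)]^2)
  new("RadialProfile", breaks = breaks, counts = as.numeric(counts),
      density = counts / area)
}

#' Axial profile of a side-view particle
#'
#' 1D histogram of the axial coordinate using all events of the particle
#' (no lateral gating: the profile averages through the whole thickness of
#' the NPC).
#'
#' @param x a [Particle-class] with a `dz` column or a
#'   [LocalizationTable-class] with a `z` column.
#' @param binWidth axial bin width in nm (default 2).
#' @param range axial range c(lo, hi) nm; default snaps the data range
#'   outward to whole bins aligned on 0.
#' @return an [AxialProfile-class].
#' @export
axialProfile <- function(x, binWidth = 2, range = NULL) {
  stopifnot(binWidth > 0)
  if (is(x, "Particle")) {
    if (!"dz" %in% names(x@events))
      stop("axial profile requires an axial coordinate column 'dz'")
    z <- x@events$dz
    idx <- x@pickIndex
  } else if (is(x, "LocalizationTable")) {
    if (!"z" %in% names(x@events))
      stop("axial profile requires an axial coordinate column 'z'")
    z <- x@events$z
    idx <- NA_integer_
  } else stop("axialProfile expects a Particle or LocalizationTable")
  if (is.null(range)) {
    if (!length(z)) stop("cannot infer an axial range from an empty particle")
    range <- c(floor(min(z) / binWidth) * binWidth,
               ceiling((max(z) + 1e-9) / binWidth) * binWidth)
  }
  breaks <- seq(range[1], range[2], by = binWidth)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  b <- findInterval(z, breaks, rightmost.closed = TRUE, left.open = FALSE)
  keep <- b >= 1 & b <= length(breaks) - 1
  counts <- tabulate(b[keep], nbins = length(breaks) - 1L)
  new("AxialProfile", breaks = breaks, counts = as.numeric(counts),
      particleIndex = as.integer(idx))
}

# Strict local maxima of a numeric vector (indices), endpoints excluded.
localMaxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Fit a sum of two Gaussians to an axial profile
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `a1*exp(-(x-mu1)^2/(2*s1^2)) + a2*exp(-(x-mu2)^2/(2*s2^2)) + c` to the bin
#' centers, initialized from the two most separated local maxima. Means are
#' ordered on output; fits whose means collapse to within one bin width are
#' flagged as effectively single-mode.
#'
#' @param profile an [AxialProfile-class] with at least 7 populated bins
#'   (the model has 7 free parameters).
#' @return a [TwoGaussianFit-class].
#' @export
fitTwoGaussians <- function(profile) {
  stopifnot(is(profile, "AxialProfile"))
  y <- profile@counts
  xc <- (profile@breaks[-length(profile@breaks)] + profile@breaks[-1]) / 2
  bw <- diff(profile@breaks[1:2])
  if (sum(y > 0) < 7L)
    stop("two-Gaussian fit needs at least 7 populated bins")
  peaks <- localMaxima(y)
  peaks <- peaks[y[peaks] >= 0.2 * max(y)]
  if (length(peaks) >= 2L) {
    pick <- c(peaks[1], peaks[length(peaks)])
  } else {
    pick <- order(y, decreasing = TRUE)[1:2]
  }
  pick <- sort(pick)
  init <- list(mu1 = xc[pick[1]], mu2 = xc[pick[2]],
               s1 = max(2 * bw, diff(xc[pick]) / 6),
               s2 = max(2 * bw, diff(xc[pick]) / 6),
               a1 = max(y[pick[1]], 1), a2 = max(y[pick[2]], 1),
               c = max(min(y), 0))
  # fallback initializer: split the mass at its center and use one-sided
  # weighted moments (robust when the peak pair is degenerate)
  ctr <- sum(xc * y) / sum(y)
  side <- xc <= ctr
  wmean <- function(v, w) sum(v * w) / max(sum(w), 1e-12)
  wsd <- function(v, w, m) sqrt(max(sum((v - m)^2 * w) / max(sum(w), 1e-12),
                                    (bw / 2)^2))
  muL <- wmean(xc[side], y[side]); muR <- wmean(xc[!side], y[!side])
  init2 <- list(mu1 = muL, mu2 = muR,
                s1 = wsd(xc[side], y[side], muL),
                s2 = wsd(xc[!side], y[!side], muR),
                a1 = max(y[side], 1), a2 = max(y[!side], 1), c = 0)
  tryFit <- function(ini) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-(xc - mu1)^2 / (2 * s1^2)) +
            a2 * exp(-(xc - mu2)^2 / (2 * s2^2)) + c,
        start = ini,
        lower = c(mu1 = min(xc), mu2 = min(xc), s1 = bw / 10, s2 = bw / 10,
                  a1 = 0, a2 = 0, c = 0),
        upper = c(mu1 = max(xc), mu2 = max(xc), s1 = diff(range(xc)),
                  s2 = diff(range(xc)), a1 = Inf, a2 = Inf, c = max(y)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
  }
  fit <- tryFit(init)
  if (inherits(fit, "error")) fit <- tryFit(init2)
  if (inherits(fit, "error"))
    stop("two-Gaussian fit did not converge (init: mu = ",
         signif(init$mu1, 4), ", ", signif(init$mu2, 4), "): ",
         conditionMessage(fit))
  cf <- stats::coef(fit)
  ord <- order(c(cf["mu1"], cf["mu2"]))
  mu <- unname(c(cf["mu1"], cf["mu2"])[ord])
  sg <- unname(c(cf["s1"], cf["s2"])[ord])
  am <- unname(c(cf["a1"], cf["a2"])[ord])
  new("TwoGaussianFit", mu = mu, sigma = sg, amplitude = am,
      baseline = unname(cf["c"]),
      rss = sum(stats::residuals(fit)^2),
      flagged = (mu[2] - mu[1]) < bw)
}

# Shift a profile's counts by a continuous offset onto a common grid,
# splitting each count linearly between the two overlapped destination bins
# (conserves total counts). Optionally mirror the axis first.
shiftCountsOntoGrid <- function(profile, shift, breaks, flip = FALSE) {
  bw <- diff(breaks[1:2])
  xc <- (profile@breaks[-length(profile@breaks)] + profile@breaks[-1]) / 2
  if (flip) xc <- -xc
  xc <- xc + shift
  out <- numeric(length(breaks) - 1L)
  pos <- (xc - breaks[1]) / bw - 0.5  # fractional destination bin index - 1
  lo <- floor(pos)
  frac <- pos - lo
  for (k in seq_along(xc)) {
    cnt <- profile@counts[k]
    if (cnt == 0) next
    i1 <- lo[k] + 1L
    i2 <- i1 + 1L
    if (i1 >= 1 && i1 <= length(out)) out[i1] <- out[i1] + cnt * (1 - frac[k])
    if (i2 >= 1 && i2 <= length(out)) out[i2] <- out[i2] + cnt * frac[k]
  }
  out
}

#' Align and average axial profiles by their two-Gaussian midpoints
#'
#' Shifts every particle's axial profile so the midpoint of its
#' reference-channel two-Gaussian fit sits at 0, applies the same shift (and
#' any flip) to the matched coimaged-channel profile, and sums the shifted
#' profiles on a common grid. Flips make the cytoplasmic ring positive; with
#' synthetic data the orientation is symmetric, so the default flips nothing
#' — supply `flipFun` (fit, profile) -> logical to drive flips from a
#' reference-channel asymmetry score.
#'
#' @param fits list of [TwoGaussianFit-class], index-matched to `profiles`.
#' @param profiles list of [AxialProfile-class] (reference channel).
#' @param coimaged optional matched list of [AxialProfile-class] for a second
#'   channel.
#' @param flipFun optional function deciding per-particle axis flips.
#' @return a list: `reference` averaged [AxialProfile-class], `coimaged`
#'   (averaged or NULL), `shifts`, `flips`.
#' @export
alignAxial <- function(fits, profiles, coimaged = NULL, flipFun = NULL) {
  n <- length(profiles)
  if (length(fits) != n) stop("fits and profiles must be index-matched")
  if (!is.null(coimaged) && length(coimaged) != n)
    stop("coimaged profiles must be index-matched to the reference")
  shifts <- -vapply(fits, midpoint, numeric(1))
  flips <- if (is.null(flipFun)) rep(FALSE, n)
           else mapply(flipFun, fits, profiles)
  bw <- diff(profiles[[1]]@breaks[1:2])
  span <- max(vapply(seq_len(n), function(i) {
    max(abs(profiles[[i]]@breaks + shifts[i]))
  }, numeric(1)))
  lim <- ceiling(span / bw) * bw
  breaks <- seq(-lim, lim, by = bw)
  sumShift <- function(plist) {
    acc <- numeric(length(breaks) - 1L)
    for (i in seq_len(n))
      acc <- acc + shiftCountsOntoGrid(plist[[i]], shifts[i], breaks,
                                       flip = flips[i])
    new("AxialProfile", breaks = breaks, counts = acc,
        particleIndex = NA_integer_)
  }
  list(reference = sumShift(profiles),
       coimaged = if (is.null(coimaged)) NULL else sumShift(coimaged),
       shifts = shifts, flips = flips)
}

#' NPC surface density within a polygonal ROI
#'
#' Counts centers inside the polygon (boundary-inclusive) and divides by the
#' shoelace area in square microns.
#'
#' @param centers n x 2 matrix (or data.frame) of NPC centers (nm).
#' @param roi an [RoiPolygon-class].
#' @return a list: `density` (per square micron), `count`, `areaUm2`.
#' @examples
#' roi <- RoiPolygon(cbind(c(0, 1e4, 1e4, 0), c(0, 0, 1e3, 1e3)))  # 10 um^2
#' @export
npcDensity <- function(centers, roi) {
  stopifnot(is(roi, "RoiPolygon"))
  area <- roiArea(roi, "um2")
  if (area <= 0) stop("zero-area ROI")
  centers <- matrix(as.numeric(as.matrix(centers)), ncol = 2)
  cnt <- if (nrow(centers))
    sum(pointInPolygon(centers[, 1], centers[, 2], roi@vertices)) else 0L
  list(density = cnt / area, count = as.integer(cnt), areaUm2 = area)
}
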