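# The rotational-symmetry statistic: polar conversion, 50--70 nm annulus
# gating, pooled angular histogram, period-pi/4 sine fit, sector segmentation
# at the sine minima, per-NPC occupancy, and the cohort subunit distribution.

#' Convert centered events to polar coordinates
#'
#' @param x a [LocalizationTable-class] in the common (centered) frame — a
#'   fused superparticle with a `particle` column keeps per-event
#'   provenance — or a single [Particle-class].
#' @return a [PolarEvents-class] with `r = sqrt(x^2 + y^2)` and
#'   `theta = atan2(y, x)` mapped to `[0, 2*pi)`.
#' @export
toPolar <- function(x) {
  if (is(x, "Particle")) {
    ev <- x@events
    px <- ev$dx; py <- ev$dy
    idx <- rep(x@pickIndex, nrow(ev))
  } else if (is(x, "LocalizationTable")) {
    ev <- x@events
    px <- ev$x; py <- ev$y
    idx <- if ("particle" %in% names(ev)) ev$particle else rep(1L, nrow(ev))
  } else {
    stop("toPolar expects a LocalizationTable or Particle")
  }
  new("PolarEvents", r = sqrt(px^2 + py^2),
      theta = wrapRad(atan2(py, px)), particleIndex = as.integer(idx))
}

#' Gate polar events to the analysis annulus
#'
#' Keeps events with `rMin <= r <= rMax` (closed interval). The 50--70 nm
#' default brackets the Nup ring radius and rejects central-channel and
#' far-field background.
#'
#' @param polar a [PolarEvents-class].
#' @param rMin,rMax annulus bounds in nm (defaults 50 and 70).
#' @return the gated [PolarEvents-class]; idempotent.
#' @export
gateAnnulus <- function(polar, rMin = 50, rMax = 70) {
  stopifnot(is(polar, "PolarEvents"), rMin < rMax)
  keep <- polar@r >= rMin & polar@r <= rMax
  new("PolarEvents", r = polar@r[keep], theta = polar@theta[keep],
      particleIndex = polar@particleIndex[keep])
}

#' Pooled angular histogram of gated events
#'
#' @param polar a [PolarEvents-class] (all particles pooled).
#' @param binWidth bin width in degrees; must divide 360 evenly so uniform
#'   bins cover the circle (default 2). Sector counts are taken from raw
#'   event angles, so bins never need to tile the eight sectors.
#' @return an [AngularHistogram-class].
#' @export
angularHistogram <- function(polar, binWidth = 2) {
  stopifnot(is(polar, "PolarEvents"))
  if (binWidth <= 0 || abs(360 / binWidth - round(360 / binWidth)) > 1e-9)
    stop("config error: binWidth (degrees) must divide 360 evenly")
  nb <- as.integer(round(360 / binWidth))
  w <- 2 * pi / nb
  idx <- pmin(floor(polar@theta / w), nb - 1L) + 1L
  new("AngularHistogram", breaks = seq(0, 2 * pi, length.out = nb + 1L),
      counts = as.numeric(tabulate(idx, nbins = nb)))
}

#' Fit a period-pi/4 sine to an angular histogram
#'
#' Least squares of `I(theta) = A + B*sin(fold*theta + phi)` on the bin
#' centers with the frequency fixed at the symmetry fold (8). The problem is
#' solved in closed form through the linearization
#' `A + C*sin(fold*theta) + D*cos(fold*theta)` with `B = sqrt(C^2 + D^2)`,
#' `phi = atan2(D, C)`, which makes `B >= 0` a phase convention rather than a
#' constraint.
#'
#' @param hist an [AngularHistogram-class].
#' @param fold angular frequency (default 8).
#' @return a [SineFit-class].
#' @export
fitSine8 <- function(hist, fold = 8L) {
  stopifnot(is(hist, "AngularHistogram"))
  y <- hist@counts
  if (all(y == 0)) stop("degenerate fit: all-zero histogram")
  centers <- (hist@breaks[-length(hist@breaks)] + hist@breaks[-1]) / 2
  if (length(unique(centers)) < 3L)
    stop("need at least 3 bins to fit offset, amplitude and phase")
  X <- cbind(1, sin(fold * centers), cos(fold * centers))
  beta <- qr.solve(X, y)
  A <- beta[1]; C <- beta[2]; D <- beta[3]
  B <- sqrt(C^2 + D^2)
  phi <- if (B > 0) wrapRad(atan2(D, C)) else 0
  rss <- sum((y - (A + B * sin(fold * centers + phi)))^2)
  new("SineFit", offset = A, amplitude = B, phase = phi,
      fold = as.integer(fold), rss = rss)
}

#' Sector edges at the minima of the fitted sine
#'
#' Minima of `A + B*sin(8*theta + phi)` sit where `8*theta + phi =
#' 3*pi/2 + 2*pi*k`, giving edges `theta_k = (3*pi/2 - phi)/8 + k*pi/4`,
#' k = 0..7, mapped to `[0, 2*pi)` and sorted. Spacing is exactly pi/4 by
#' construction. A zero-amplitude fit has no defined minima; edges fall back
#' to `k*pi/4` with a warning.
#'
#' @param fit a [SineFit-class].
#' @return numeric vector of 8 sector boundary angles (radians).
#' @export
sectorEdges <- function(fit) {
  stopifnot(is(fit, "SineFit"))
  f <- fit@fold
  if (fit@amplitude <= 0) {
    warning("zero-amplitude sine has no minima; using edges at k*pi/4")
    return(seq(0, 2 * pi - pi / f, by = 2 * pi / f))
  }
  k <- 0:(f - 1L)
  sort(wrapRad((3 * pi / 2 - fit@phase) / f + k * 2 * pi / f))
}

#' Per-sector localization counts of one NPC
#'
#' Sector i spans `[edges[i], edges[i+1])` circularly (half-open; the
#' wraparound sector closes the circle), so every event lands in exactly one
#' sector and counts sum to the particle's gated event count.
#'
#' @param polar gated [PolarEvents-class].
#' @param edges the 8 sector edges from [sectorEdges()].
#' @param particleIndex which particle to count; NULL pools all events.
#' @return integer vector of 8 counts.
#' @export
sectorCounts <- function(polar, edges, particleIndex = NULL) {
  stopifnot(is(polar, "PolarEvents"), length(edges) == 8L)
  th <- polar@theta
  if (!is.null(particleIndex)) th <- th[polar@particleIndex == particleIndex]
  width <- pi / 4
  sec <- (floor(wrapRad(th - edges[1]) / width) %% 8) + 1L
  tabulate(sec, nbins = 8L)
}

#' Occupancy scoring of one NPC's sector counts
#'
#' A sector is occupied when its count strictly exceeds half the mean count
#' per sector for this NPC; ties at the threshold are unoccupied. The
#' subunit count is the number of occupied sectors. An all-zero particle
#' scores 0 subunits (threshold 0, strict comparison fails).
#'
#' @param counts integer vector of 8 sector counts.
#' @param edges optional sector edges stored alongside (NA when unknown).
#' @param particleIndex provenance index stored on the result.
#' @return a [SectorOccupancy-class].
#' @examples
#' nSubunits(occupancy(c(10, 10, 10, 10, 10, 10, 10, 0)))  # 7
#' @export
occupancy <- function(counts, edges = rep(NA_real_, 8), particleIndex = NA_integer_) {
  stopifnot(length(counts) == 8L, all(counts >= 0))
  threshold <- mean(counts) / 2
  occ <- counts > threshold
  new("SectorOccupancy", edges = as.numeric(edges),
      counts = as.numeric(counts), threshold = threshold, occupied = occ,
      nSubunits = as.integer(sum(occ)),
      particleIndex = as.integer(particleIndex))
}

#' Cohort subunit-count distribution
#'
#' Applies the pooled-cohort sector edges to every NPC, scores occupancy per
#' NPC, and tabulates the subunit counts. The sine is fitted once on the
#' pooled histogram and its edges shared across the cohort; particles whose
#' total gated count falls below `minTotal` are excluded and reported.
#'
#' @param polar gated [PolarEvents-class] of the whole cohort.
#' @param edges the 8 pooled-cohort sector edges.
#' @param particleIds particle indices making up the cohort; defaults to the
#'   indices present in `polar`. Pass the full cohort list so particles with
#'   zero gated events are still scored (as 0 subunits).
#' @param minTotal exclude NPCs with fewer gated events than this (default 0:
#'   no exclusion).
#' @return a list: `perNPC` data.frame (particle, total, counts s1..s8,
#'   threshold, nSubunits), `distribution` (named probabilities over 0..8),
#'   `fractionEightfold`, `nIncluded`, `nExcluded`.
#' @export
symmetryDistribution <- function(polar, edges, particleIds = NULL,
                                 minTotal = 0L) {
  stopifnot(is(polar, "PolarEvents"))
  if (is.null(particleIds)) particleIds <- sort(unique(polar@particleIndex))
  if (!length(particleIds)) stop("empty cohort")
  rows <- lapply(particleIds, function(i) {
    cnt <- sectorCounts(polar, edges, particleIndex = i)
    occ <- occupancy(cnt, edges = edges, particleIndex = i)
    data.frame(particle = i, total = sum(cnt),
               t(stats::setNames(cnt, paste0("s", 1:8))),
               threshold = occ@threshold, nSubunits = occ@nSubunits)
  })
  perNPC <- do.call(rbind, rows)
  keep <- perNPC$total >= minTotal
  included <- perNPC[keep, , drop = FALSE]
  if (!nrow(included)) stop("no NPCs pass the minTotal filter")
  dist <- tabulate(included$nSubunits + 1L, nbins = 9L) / nrow(included)
  names(dist) <- 0:8
  list(perNPC = perNPC, distribution = dist,
       fractionEightfold = unname(dist["8"]),
       nIncluded = nrow(included), nExcluded = sum(!keep))
}
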