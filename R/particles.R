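# Particle extraction around picked NPC centers, recentering, and
# density-based auto-detection of candidate centers on synthetic data.

#' Extract per-NPC particles around picked centers
#'
#' For each center, keeps the events whose Euclidean distance from the center
#' is at most `pickRadius` (closed disc) and re-expresses them relative to
#' the center. Overlapping picks duplicate events, matching manual-picking
#' semantics; duplication is reported via the `nShared` attribute.
#'
#' @param table a [LocalizationTable-class].
#' @param centers n x 2 matrix (or data.frame) of pick centers (nm).
#' @param pickRadius picking radius in nm (default 130).
#' @param sourceId provenance string stored on each particle.
#' @return list of [Particle-class], one per center (possibly with 0 events).
#' @export
pickParticles <- function(table, centers, pickRadius = 130,
                          sourceId = "table") {
  stopifnot(is(table, "LocalizationTable"), pickRadius > 0)
  centers <- matrix(as.numeric(as.matrix(centers)), ncol = 2)
  ev <- table@events
  hasZ <- "z" %in% names(ev)
  used <- integer(nrow(ev))
  out <- lapply(seq_len(nrow(centers)), function(i) {
    dx <- ev$x - centers[i, 1]
    dy <- ev$y - centers[i, 2]
    keep <- which(sqrt(dx^2 + dy^2) <= pickRadius)
    used[keep] <<- used[keep] + 1L
    df <- data.frame(dx = dx[keep], dy = dy[keep])
    if (hasZ) df$dz <- ev$z[keep]
    Particle(df, center = centers[i, ], pickRadius = pickRadius,
             sourceId = sourceId, pickIndex = i)
  })
  attr(out, "nShared") <- sum(used > 1L)
  out
}

#' Refine a particle's center
#'
#' `circle_fit` (default) shifts the center to the algebraic least-squares
#' (Kasa) circle fit of the events — appropriate for ring-like NPC particles
#' because the downstream 50--70 nm annulus gate is center-sensitive.
#' `centroid` shifts to the event centroid. After shifting, events that fall
#' outside the pick radius are dropped; the dropped count is reported via the
#' `nDropped` attribute. Degenerate geometry (fewer than 3 events, collinear
#' events, or a non-finite fit) falls back to the centroid with a warning.
#'
#' @param particle a [Particle-class].
#' @param method "circle_fit" or "centroid".
#' @return the recentered [Particle-class]; the applied shift (nm, in table
#'   coordinates) is available as attribute `shift`.
#' @export
recenter <- function(particle, method = c("circle_fit", "centroid")) {
  stopifnot(is(particle, "Particle"))
  method <- match.arg(method)
  ev <- particle@events
  if (nrow(ev) == 0L) {
    out <- particle
    attr(out, "shift") <- c(0, 0)
    attr(out, "nDropped") <- 0L
    return(out)
  }
  shift <- NULL
  if (method == "circle_fit") {
    if (nrow(ev) < 3L) {
      warning("circle_fit needs >= 3 events; falling back to centroid")
    } else {
      fit <- kasaCircleFit(ev$dx, ev$dy)
      if (is.null(fit)) {
        warning("degenerate circle fit (collinear events?); falling back to centroid")
      } else {
        shift <- fit[1:2]
      }
    }
  }
  if (is.null(shift)) shift <- c(mean(ev$dx), mean(ev$dy))
  ev$dx <- ev$dx - shift[1]
  ev$dy <- ev$dy - shift[2]
  keep <- sqrt(ev$dx^2 + ev$dy^2) <= particle@pickRadius
  out <- particle
  out@events <- ev[keep, , drop = FALSE]
  rownames(out@events) <- NULL
  out@center <- particle@center + shift
  attr(out, "shift") <- shift
  attr(out, "nDropped") <- as.integer(sum(!keep))
  out
}

#' Auto-detect candidate NPC centers by density-based clustering
#'
#' DBSCAN semantics: events with at least `minPoints` neighbors within `eps`
#' (the event itself included) are core points; clusters are the connected
#' components of core points plus their border points; noise is ignored.
#' Returns the centroid of each cluster. Intended for synthetic cohorts;
#' picked centers on real data remain the primary route.
#'
#' @param table a [LocalizationTable-class].
#' @param eps neighborhood radius (nm).
#' @param minPoints minimum neighborhood size for a core point.
#' @return n x 2 matrix of detected centers (nm); zero rows when nothing
#'   clusters.
#' @export
autoDetectCenters <- function(table, eps = 50, minPoints = 5L) {
  stopifnot(is(table, "LocalizationTable"), eps > 0, minPoints >= 1)
  ev <- table@events
  n <- nrow(ev)
  if (n == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  d <- as.matrix(stats::dist(cbind(ev$x, ev$y)))
  nbr <- d <= eps
  core <- rowSums(nbr) >= minPoints
  labels <- integer(n)            # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      if (!core[j]) next
      reach <- which(nbr[j, ])
      newcl <- reach[labels[reach] == 0L]
      labels[newcl] <- cl
      queue <- c(queue, newcl[core[newcl]])
    }
  }
  if (cl == 0L) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  centers <- t(vapply(seq_len(cl), function(k) {
    idx <- labels == k
    c(mean(ev$x[idx]), mean(ev$y[idx]))
  }, numeric(2)))
  colnames(centers) <- c("x", "y")
  centers
}
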