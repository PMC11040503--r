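# Internal helpers shared across modules: angle wrapping, seed derivation,
# polygon geometry, scoped RNG.

DEG2RAD <- pi / 180

#' Derive a child seed from a master seed and a stream label
#'
#' Each stochastic stage of the pipeline draws from its own RNG stream whose
#' seed is a deterministic function of the master seed and a fixed label, so
#' adding a stage never perturbs the draws of another.
#'
#' @param master integer master seed.
#' @param label character (or coercible) stream label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, label) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((abs(master) %% 2147483647 + h * 7919) %% 2147483647)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Wrap angles (degrees) into [0, period).
wrapDeg <- function(x, period = 360) {
  out <- x %% period
  out[out < 0] <- out[out < 0] + period
  # guard against period itself from floating point
  out[out >= period] <- out[out >= period] - period
  out
}

# Wrap degrees into (-period/2, period/2].
wrapDegSym <- function(x, period = 360) {
  out <- wrapDeg(x, period)
  out[out > period / 2] <- out[out > period / 2] - period
  out
}

# Wrap radians into [0, 2*pi).
wrapRad <- function(x) {
  out <- x %% (2 * pi)
  out[out < 0] <- out[out < 0] + 2 * pi
  out[out >= 2 * pi] <- out[out >= 2 * pi] - 2 * pi
  out
}

# Signed shoelace area (nm^2) of a closed polygon given an n x 2 vertex matrix.
shoelaceArea <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1L)
  sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2]) / 2
}

# Ray-casting point-in-polygon, boundary-inclusive.
pointInPolygon <- function(px, py, v, tol = 1e-9) {
  n <- nrow(v)
  m <- length(px)
  inside <- logical(m)
  i2 <- c(2:n, 1L)
  for (k in seq_len(m)) {
    x <- px[k]; y <- py[k]
    onb <- FALSE
    cross <- FALSE
    for (e in seq_len(n)) {
      x1 <- v[e, 1]; y1 <- v[e, 2]; x2 <- v[i2[e], 1]; y2 <- v[i2[e], 2]
      # on-segment test
      d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
      seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
      if (d * d <= tol * tol * max(seglen2, 1) &&
          x >= min(x1, x2) - tol && x <= max(x1, x2) + tol &&
          y >= min(y1, y2) - tol && y <= max(y1, y2) + tol) {
        onb <- TRUE
        break
      }
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) cross <- !cross
      }
    }
    inside[k] <- onb || cross
  }
  inside
}

# TRUE when two closed segments properly intersect (shared endpoints of
# adjacent polygon edges are excluded by the caller).
segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygonSelfIntersects <- function(v) {
  n <- nrow(v)
  if (n < 4) return(FALSE)
  i2 <- c(2:n, 1L)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (b == a || i2[a] == b || i2[b] == a) next
      if (segmentsIntersect(v[a, ], v[i2[a], ], v[b, ], v[i2[b], ])) return(TRUE)
    }
  }
  FALSE
}

# Algebraic least-squares circle fit (Kasa). Returns c(cx, cy, r).
kasaCircleFit <- function(x, y) {
  stopifnot(length(x) >= 3L)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 < 0) return(NULL)
  c(sol[1], sol[2], sqrt(r2))
}

# Geometric blink counts on {1, 2, ...} with the given mean (>= 1).
rblinks <- function(n, mean) {
  stopifnot(mean >= 1)
  if (mean == 1) return(rep(1L, n))
  1L + stats::rgeom(n, prob = 1 / mean)
}

# Draw n points uniformly inside a polygon by bounding-box rejection.
runifPolygon <- function(n, v) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(v[, 1]); yr <- range(v[, 2])
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cx <- stats::runif(m, xr[1], xr[2])
    cy <- stats::runif(m, yr[1], yr[2])
    keep <- pointInPolygon(cx, cy, v)
    out <- rbind(out, cbind(cx[keep], cy[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# Structured JSON-lines logging used by the pipeline commands.
logEvent <- function(logfile, stage, ...) {
  if (is.null(logfile)) return(invisible(NULL))
  rec <- c(list(stage = stage), list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE)
  cat(line, "\n", file = logfile, append = TRUE, sep = "")
  invisible(NULL)
}
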