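# Base-graphics exports of the two standard figures: the radial distribution
# of an aligned superparticle and a side-view axial profile with its fitted
# two-Gaussian model.

#' Plot a radial profile
#'
#' @param profile a [RadialProfile-class].
#' @param file optional PNG/SVG path; NULL draws on the current device.
#' @param what "density" (area-normalized) or "counts".
#' @return the file path (or NULL), invisibly.
#' @export
plotRadialProfile <- function(profile, file = NULL,
                              what = c("density", "counts")) {
  what <- match.arg(what)
  openDev(file)
  mid <- (profile@breaks[-length(profile@breaks)] + profile@breaks[-1]) / 2
  y <- slot(profile, what)
  plot(mid, y, type = "l", lwd = 2, xlab = "radius (nm)",
       ylab = if (what == "density") "localizations / nm^2" else "localizations",
       main = "Radial distribution")
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

#' Plot an axial profile with an optional two-Gaussian fit
#'
#' @param profile an [AxialProfile-class].
#' @param fit optional [TwoGaussianFit-class] overlaid as a curve.
#' @param file optional PNG/SVG path; NULL draws on the current device.
#' @return the file path (or NULL), invisibly.
#' @export
plotAxialProfile <- function(profile, fit = NULL, file = NULL) {
  openDev(file)
  mid <- (profile@breaks[-length(profile@breaks)] + profile@breaks[-1]) / 2
  plot(mid, profile@counts, type = "h", lwd = 3, col = "grey60",
       xlab = "axial position (nm)", ylab = "localizations",
       main = "Side-view axial profile")
  if (!is.null(fit)) {
    xx <- seq(min(mid), max(mid), length.out = 400)
    yy <- fit@amplitude[1] * exp(-(xx - fit@mu[1])^2 / (2 * fit@sigma[1]^2)) +
      fit@amplitude[2] * exp(-(xx - fit@mu[2])^2 / (2 * fit@sigma[2]^2)) +
      fit@baseline
    graphics::lines(xx, yy, lwd = 2, col = "firebrick")
  }
  if (!is.null(file)) grDevices::dev.off()
  invisible(file)
}

openDev <- function(file) {
  if (is.null(file)) return(invisible(NULL))
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = 900, height = 600, res = 120),
         svg = grDevices::svg(file, width = 7, height = 5),
         stop("unsupported plot format: ", ext))
  invisible(NULL)
}
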