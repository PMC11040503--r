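# Generics and accessors. Slot access from user code goes through these.

#' Number of localization events in an object
#'
#' @param x a [LocalizationTable-class], [Particle-class] or
#'   [PolarEvents-class] object.
#' @return integer event count.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname nEvents
#' @export
setMethod("nEvents", "LocalizationTable", function(x) nrow(x@events))

#' @rdname nEvents
#' @export
setMethod("nEvents", "Particle", function(x) nrow(x@events))

#' @rdname nEvents
#' @export
setMethod("nEvents", "PolarEvents", function(x) length(x@r))

#' Event table of an object
#'
#' @param x a [LocalizationTable-class] or [Particle-class] object.
#' @return the underlying data.frame of events.
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

#' @rdname eventData
#' @export
setMethod("eventData", "LocalizationTable", function(x) x@events)

#' @rdname eventData
#' @export
setMethod("eventData", "Particle", function(x) x@events)

#' Accessors for particles and alignment results
#'
#' `particleCenter` returns the pick center (nm); `pickRadius` the picking
#' radius (nm); `rotations` the per-particle rotations modulo 360/fold;
#' `superparticle` the fused pooled table; `nSubunits` the per-NPC subunit
#' count; `separation` and `midpoint` the ring distance and center of a
#' two-Gaussian axial fit.
#'
#' @param x the object to access.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("particleCenter", function(x) standardGeneric("particleCenter"))

#' @rdname accessors
#' @export
setMethod("particleCenter", "Particle", function(x) x@center)

#' @rdname accessors
#' @export
setGeneric("pickRadius", function(x) standardGeneric("pickRadius"))

#' @rdname accessors
#' @export
setMethod("pickRadius", "Particle", function(x) x@pickRadius)

#' @rdname accessors
#' @export
setGeneric("rotations", function(x) standardGeneric("rotations"))

#' @rdname accessors
#' @export
setMethod("rotations", "AlignmentResult", function(x) x@rotations)

#' @rdname accessors
#' @export
setGeneric("superparticle", function(x) standardGeneric("superparticle"))

#' @rdname accessors
#' @export
setMethod("superparticle", "AlignmentResult", function(x) x@superparticle)

#' @rdname accessors
#' @export
setGeneric("nSubunits", function(x) standardGeneric("nSubunits"))

#' @rdname accessors
#' @export
setMethod("nSubunits", "SectorOccupancy", function(x) x@nSubunits)

#' @rdname accessors
#' @export
setGeneric("separation", function(x) standardGeneric("separation"))

#' @rdname accessors
#' @export
setMethod("separation", "TwoGaussianFit", function(x) x@mu[2] - x@mu[1])

#' @rdname accessors
#' @export
setGeneric("midpoint", function(x) standardGeneric("midpoint"))

#' @rdname accessors
#' @export
setMethod("midpoint", "TwoGaussianFit", function(x) mean(x@mu))

#' Area of a region of interest
#'
#' @param x an [RoiPolygon-class].
#' @param units "nm2" or "um2".
#' @return polygon area by the shoelace formula.
#' @export
setGeneric("roiArea", function(x, units = c("nm2", "um2")) standardGeneric("roiArea"))

#' @rdname roiArea
#' @export
setMethod("roiArea", "RoiPolygon", function(x, units = c("nm2", "um2")) {
  units <- match.arg(units)
  a <- abs(shoelaceArea(x@vertices))
  if (units == "um2") a / 1e6 else a
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "LocalizationTable", function(object) {
  ev <- object@events
  opt <- intersect(c("z", "frame", "channel", "particle"), names(ev))
  cat(sprintf("LocalizationTable with %d events", nrow(ev)))
  if (length(opt)) cat(" [", paste(opt, collapse = ", "), "]", sep = "")
  cat("\n")
  if (nrow(ev)) {
    cat(sprintf("  x: [%.1f, %.1f] nm;  y: [%.1f, %.1f] nm\n",
                min(ev$x), max(ev$x), min(ev$y), max(ev$y)))
  }
})

setMethod("show", "Particle", function(object) {
  cat(sprintf("Particle #%d (%s): %d events within %.0f nm of (%.1f, %.1f)\n",
              object@pickIndex, object@sourceId, nrow(object@events),
              object@pickRadius, object@center[1], object@center[2]))
})

setMethod("show", "NPCModel", function(object) {
  rot <- if (is.na(object@globalRotation)) "random" else
    sprintf("%.1f deg", object@globalRotation)
  cat(sprintf(paste0(
    "NPCModel: %d corners x %d copies on a %.0f nm ring\n",
    "  labeling %.2f, blinks mean %.1f, sigma_xy %.1f nm, sigma_z %.1f nm\n",
    "  ring separation %.0f nm, background %.1f /um^2, phase %s, seed %d\n"),
    object@nCorners, object@copiesPerCorner, object@ringRadius,
    object@labelingEfficiency, object@blinksMean, object@locPrecisionXY,
    object@locPrecisionZ, object@ringSeparation, object@backgroundDensity,
    rot, object@seed))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(paste0(
    "AlignmentResult: %d particles, %d events fused\n",
    "  %d iteration(s), converged: %s; %d particle(s) flagged\n"),
    length(object@rotations), nEvents(object@superparticle),
    object@iterationsRun, object@converged, length(object@flagged)))
})

setMethod("show", "SineFit", function(object) {
  cat(sprintf(
    "SineFit (period pi/%d): I(theta) = %.3f + %.3f * sin(%d*theta + %.4f), rss %.4g\n",
    object@fold / 2, object@offset, object@amplitude, object@fold,
    object@phase, object@rss))
})

setMethod("show", "SectorOccupancy", function(object) {
  cat(sprintf("SectorOccupancy (NPC %d): counts [%s], threshold %.2f -> %d subunits\n",
              object@particleIndex, paste(object@counts, collapse = ", "),
              object@threshold, object@nSubunits))
})

setMethod("show", "TwoGaussianFit", function(object) {
  cat(sprintf(paste0(
    "TwoGaussianFit: mu = (%.2f, %.2f) nm, sigma = (%.2f, %.2f) nm\n",
    "  separation %.2f nm, midpoint %.2f nm%s\n"),
    object@mu[1], object@mu[2], object@sigma[1], object@sigma[2],
    separation(object), midpoint(object),
    if (object@flagged) " [flagged: single-mode]" else ""))
})

setMethod("show", "RoiPolygon", function(object) {
  cat(sprintf("RoiPolygon: %d vertices, area %.3f um^2\n",
              nrow(object@vertices), roiArea(object, "um2")))
})

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %d x %d pixels of %.0f nm, %d events (%d dropped)\n",
              ncol(object@counts), nrow(object@counts), object@pixelSize,
              sum(object@counts), object@nDropped))
})
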