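#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core containers. All coordinates are nanometers throughout the package.
# ---------------------------------------------------------------------------

#' LocalizationTable: single-molecule localization events
#'
#' A flat table of single-molecule localization events, the universal currency
#' between pipeline stages. Mandatory columns are `x` and `y` (nm); optional
#' columns are `z` (axial, nm), `frame` (acquisition frame index), `channel`
#' (label) and `particle` (provenance index used by fused superparticles).
#'
#' @slot events data.frame of events with at least numeric columns x and y.
#' @export
setClass("LocalizationTable", slots = c(events = "data.frame"))

setValidity("LocalizationTable", function(object) {
  ev <- object@events
  msg <- character(0)
  for (col in c("x", "y")) {
    if (!col %in% names(ev)) msg <- c(msg, sprintf("missing column '%s'", col))
    else if (!is.numeric(ev[[col]])) msg <- c(msg, sprintf("column '%s' must be numeric", col))
    else if (any(!is.finite(ev[[col]]))) msg <- c(msg, sprintf("non-finite values in '%s'", col))
  }
  if ("z" %in% names(ev) && any(!is.finite(ev$z)))
    msg <- c(msg, "non-finite values in 'z'")
  if ("frame" %in% names(ev) && any(ev$frame < 0, na.rm = TRUE))
    msg <- c(msg, "'frame' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a LocalizationTable
#'
#' @param x,y numeric lateral coordinates (nm).
#' @param z optional numeric axial coordinates (nm).
#' @param frame optional integer acquisition frame indices.
#' @param channel optional character channel labels.
#' @param particle optional integer provenance (source particle) indices.
#' @return a [LocalizationTable-class] object.
#' @examples
#' tab <- LocalizationTable(x = c(0, 10), y = c(0, 20))
#' nEvents(tab)
#' @export
LocalizationTable <- function(x = numeric(0), y = numeric(0), z = NULL,
                              frame = NULL, channel = NULL, particle = NULL) {
  ev <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(z)) ev$z <- as.numeric(z)
  if (!is.null(frame)) ev$frame <- as.integer(frame)
  if (!is.null(channel)) ev$channel <- as.character(channel)
  if (!is.null(particle)) ev$particle <- as.integer(particle)
  new("LocalizationTable", events = ev)
}

#' RoiPolygon: polygonal region of interest
#'
#' An ordered, non-self-intersecting polygon in nm used for region gating and
#' NPC surface-density estimation. Area is computed with the shoelace formula.
#'
#' @slot vertices numeric matrix (n >= 3 rows) of x, y vertex coordinates (nm).
#' @export
setClass("RoiPolygon", slots = c(vertices = "matrix"))

setValidity("RoiPolygon", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2) return("vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 3) return("a polygon needs at least 3 vertices")
  if (any(!is.finite(v))) return("vertices must be finite")
  if (abs(shoelaceArea(v)) <= 0) return("polygon area must be > 0")
  if (polygonSelfIntersects(v)) return("polygon must not self-intersect")
  TRUE
})

#' Construct an RoiPolygon
#'
#' @param vertices n x 2 numeric matrix (or data.frame) of vertex coordinates (nm).
#' @return an [RoiPolygon-class] object.
#' @export
RoiPolygon <- function(vertices) {
  v <- as.matrix(vertices)
  colnames(v) <- c("x", "y")
  new("RoiPolygon", vertices = v)
}

#' ImageGrid: 2D histogram rendering of localizations
#'
#' @slot pixelSize nm per pixel.
#' @slot origin x, y (nm) of the lower-left corner of pixel (1, 1).
#' @slot counts integer matrix of event counts; rows index y (bottom row
#'   first), columns index x.
#' @slot nDropped number of events outside the grid extent.
#' @export
setClass("ImageGrid", slots = c(pixelSize = "numeric", origin = "numeric",
                                counts = "matrix", nDropped = "integer"))

setValidity("ImageGrid", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (length(object@origin) != 2) return("origin must be length 2")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

# ---------------------------------------------------------------------------
# Synthetic generator model and ground truth
# ---------------------------------------------------------------------------

#' NPCModel: parameterization of the synthetic NPC localization generator
#'
#' Describes the generative model for one synthetic NPC: `nCorners` corner
#' sites on a ring of radius `ringRadius`, each carrying `copiesPerCorner`
#' fluorophore sites labeled independently with probability
#' `labelingEfficiency`; every labeled site emits a geometric number of
#' localizations (mean `blinksMean`, support 1, 2, ...) blurred by isotropic
#' Gaussian localization error `locPrecisionXY`; uniform Poisson background at
#' `backgroundDensity` events per square micron on the 130-nm picking disc.
#' Side views place the ring at axial positions +/- `ringSeparation`/2 with
#' axial error `locPrecisionZ`.
#'
#' @slot ringRadius ring radius in nm (default 60, the midpoint of the
#'   50--70 nm analysis annulus).
#' @slot nCorners number of corners (default 8).
#' @slot copiesPerCorner fluorophore sites per corner (default 4).
#' @slot labelingEfficiency per-site labeling probability in `[0, 1]`.
#' @slot blinksMean mean localizations per labeled site (>= 1).
#' @slot locPrecisionXY lateral localization error sigma (nm).
#' @slot locPrecisionZ axial localization error sigma (nm, side view).
#' @slot ringSeparation axial distance between the two rings (nm, default 50).
#' @slot backgroundDensity uniform background (events per square micron).
#' @slot globalRotation ring phase in degrees, or NA for a random phase.
#' @slot seed RNG seed.
#' @export
setClass("NPCModel",
  slots = c(ringRadius = "numeric", nCorners = "integer",
            copiesPerCorner = "integer", labelingEfficiency = "numeric",
            blinksMean = "numeric", locPrecisionXY = "numeric",
            locPrecisionZ = "numeric", ringSeparation = "numeric",
            backgroundDensity = "numeric", globalRotation = "numeric",
            seed = "integer"))

setValidity("NPCModel", function(object) {
  msg <- character(0)
  if (object@ringRadius <= 0) msg <- c(msg, "ringRadius must be > 0")
  if (object@nCorners < 1) msg <- c(msg, "nCorners must be >= 1")
  if (object@copiesPerCorner < 1) msg <- c(msg, "copiesPerCorner must be >= 1")
  if (object@labelingEfficiency < 0 || object@labelingEfficiency > 1)
    msg <- c(msg, "labelingEfficiency must be in [0, 1]")
  if (object@blinksMean < 1) msg <- c(msg, "blinksMean must be >= 1")
  if (object@locPrecisionXY < 0 || object@locPrecisionZ < 0)
    msg <- c(msg, "localization precisions must be >= 0")
  if (object@ringSeparation < 0) msg <- c(msg, "ringSeparation must be >= 0")
  if (object@backgroundDensity < 0) msg <- c(msg, "backgroundDensity must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an NPCModel
#'
#' Defaults describe a well-behaved Nup-like reference structure: an 8-corner
#' ring of radius 60 nm (centered in the 50--70 nm analysis annulus), 4
#' fluorophore sites per corner, 60% labeling, mean 3 blinks per labeled site,
#' 5 nm lateral / 10 nm axial precision, rings 50 nm apart, and a modest
#' uniform background.
#'
#' @param ringRadius,nCorners,copiesPerCorner,labelingEfficiency,blinksMean
#'   see slot documentation in [NPCModel-class].
#' @param locPrecisionXY,locPrecisionZ,ringSeparation,backgroundDensity,seed
#'   see slot documentation in [NPCModel-class].
#' @param globalRotation numeric phase in degrees or the string "random"
#'   (stored as NA) for an independent uniform phase per particle.
#' @return an [NPCModel-class] object.
#' @examples
#' model <- NPCModel(labelingEfficiency = 1, locPrecisionXY = 0,
#'                   backgroundDensity = 0)
#' @export
NPCModel <- function(ringRadius = 60, nCorners = 8L, copiesPerCorner = 4L,
                     labelingEfficiency = 0.6, blinksMean = 3,
                     locPrecisionXY = 5, locPrecisionZ = 10,
                     ringSeparation = 50, backgroundDensity = 10,
                     globalRotation = "random", seed = 1L) {
  rot <- if (identical(globalRotation, "random")) NA_real_ else as.numeric(globalRotation)
  new("NPCModel", ringRadius = ringRadius, nCorners = as.integer(nCorners),
      copiesPerCorner = as.integer(copiesPerCorner),
      labelingEfficiency = labelingEfficiency, blinksMean = blinksMean,
      locPrecisionXY = locPrecisionXY, locPrecisionZ = locPrecisionZ,
      ringSeparation = ringSeparation, backgroundDensity = backgroundDensity,
      globalRotation = rot, seed = as.integer(seed))
}

#' GroundTruth: generative provenance of a simulated particle
#'
#' @slot cornerAngles corner phases in degrees, `globalRotation + k * 360 / nCorners`.
#' @slot labeledSites logical matrix (nCorners x copiesPerCorner).
#' @slot parentSite integer per event: linear site index
#'   `(corner - 1) * copies + copy`, or -1 for background.
#' @slot trueCenter x, y (nm) of the true particle center.
#' @slot ringAssignment integer per event: 1 nuclear ring, 2 cytoplasmic ring,
#'   NA for top views and background.
#' @export
setClass("GroundTruth",
  slots = c(cornerAngles = "numeric", labeledSites = "matrix",
            parentSite = "integer", trueCenter = "numeric",
            ringAssignment = "integer"))

setValidity("GroundTruth", function(object) {
  lab <- as.vector(t(object@labeledSites))
  ps <- object@parentSite[object@parentSite > 0]
  if (length(ps) && any(!lab[ps])) return("events point to unlabeled parent sites")
  TRUE
})

# ---------------------------------------------------------------------------
# Particles and alignment
# ---------------------------------------------------------------------------

#' Particle: localizations of one picked NPC
#'
#' Events are expressed relative to the particle center; every event lies
#' within `pickRadius` of the origin.
#'
#' @slot events data.frame with numeric columns dx, dy and optionally dz (nm).
#' @slot center x, y (nm) of the pick center in table coordinates.
#' @slot pickRadius picking radius in nm (default pipeline value 130).
#' @slot sourceId provenance string (source cell / file).
#' @slot pickIndex index of the pick within its source.
#' @export
setClass("Particle",
  slots = c(events = "data.frame", center = "numeric", pickRadius = "numeric",
            sourceId = "character", pickIndex = "integer"))

setValidity("Particle", function(object) {
  ev <- object@events
  if (!all(c("dx", "dy") %in% names(ev))) return("events need columns dx, dy")
  if (object@pickRadius <= 0) return("pickRadius must be > 0")
  if (any(!is.finite(object@center))) return("center must be finite")
  if (nrow(ev) &&
      any(sqrt(ev$dx^2 + ev$dy^2) > object@pickRadius + 1e-9))
    return("events must lie within pickRadius of the center")
  TRUE
})

#' Construct a Particle
#'
#' @param events data.frame with columns dx, dy (and optionally dz), nm,
#'   relative to `center`.
#' @param center numeric length-2 pick center (nm).
#' @param pickRadius picking radius (nm).
#' @param sourceId provenance string.
#' @param pickIndex integer pick index.
#' @return a [Particle-class] object.
#' @export
Particle <- function(events, center = c(0, 0), pickRadius = 130,
                     sourceId = "synthetic", pickIndex = 1L) {
  new("Particle", events = as.data.frame(events), center = as.numeric(center),
      pickRadius = pickRadius, sourceId = sourceId,
      pickIndex = as.integer(pickIndex))
}

#' AlignmentConfig: parameters of the eightfold rotational alignment
#'
#' @slot rotationGrid rotation search step (degrees, default 1).
#' @slot symmetryFold rotational symmetry order (default 8).
#' @slot maxIterations iteration cap (default 20).
#' @slot convergenceTol stop when the mean absolute non-symmetry rotation
#'   update falls below this (degrees, default 0.5).
#' @slot annulus radial band (nm) providing the alignment signal (default 50--70).
#' @slot angularBin angular histogram bin width (degrees, default 2).
#' @slot randomize apply the per-iteration random k * (360/fold) degree
#'   rotation to every particle (default TRUE; FALSE only for ablation).
#' @slot seed RNG seed of the dedicated symmetry-randomization stream.
#' @export
setClass("AlignmentConfig",
  slots = c(rotationGrid = "numeric", symmetryFold = "integer",
            maxIterations = "integer", convergenceTol = "numeric",
            annulus = "numeric", angularBin = "numeric",
            randomize = "logical", seed = "integer"))

setValidity("AlignmentConfig", function(object) {
  msg <- character(0)
  if (object@rotationGrid <= 0 || object@rotationGrid > 360 / object@symmetryFold)
    msg <- c(msg, "rotationGrid must be in (0, 360/symmetryFold]")
  if (object@annulus[1] >= object@annulus[2])
    msg <- c(msg, "annulus must satisfy r_min < r_max")
  if (object@angularBin <= 0) msg <- c(msg, "angularBin must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AlignmentConfig
#'
#' @param rotationGrid,symmetryFold,maxIterations,convergenceTol,annulus
#'   see slot documentation in [AlignmentConfig-class].
#' @param angularBin,randomize,seed see slot documentation.
#' @return an [AlignmentConfig-class] object.
#' @export
AlignmentConfig <- function(rotationGrid = 1, symmetryFold = 8L,
                            maxIterations = 20L, convergenceTol = 0.5,
                            annulus = c(50, 70), angularBin = 2,
                            randomize = TRUE, seed = 1L) {
  new("AlignmentConfig", rotationGrid = rotationGrid,
      symmetryFold = as.integer(symmetryFold),
      maxIterations = as.integer(maxIterations),
      convergenceTol = convergenceTol, annulus = as.numeric(annulus),
      angularBin = angularBin, randomize = randomize, seed = as.integer(seed))
}

#' AlignmentResult: per-particle rotations and the fused superparticle
#'
#' @slot rotations per-particle applied rotation, reported modulo
#'   360/symmetryFold (degrees).
#' @slot shifts n x 2 matrix of recentering shifts applied before alignment (nm).
#' @slot superparticle [LocalizationTable-class] pooling all aligned events,
#'   with a `particle` provenance column.
#' @slot iterationsRun number of iterations executed.
#' @slot converged TRUE when the convergence tolerance was reached.
#' @slot trace data.frame (iteration, meanAbsUpdate) convergence trace.
#' @slot config the [AlignmentConfig-class] used.
#' @slot flagged indices of particles with an empty alignment annulus.
#' @export
setClass("AlignmentResult",
  slots = c(rotations = "numeric", shifts = "matrix",
            superparticle = "LocalizationTable", iterationsRun = "integer",
            converged = "logical", trace = "data.frame",
            config = "AlignmentConfig", flagged = "integer"))

setValidity("AlignmentResult", function(object) {
  period <- 360 / object@config@symmetryFold
  if (length(object@rotations) &&
      (any(object@rotations < 0) || any(object@rotations >= period)))
    return("rotations must be reported in [0, 360/symmetryFold)")
  TRUE
})

# ---------------------------------------------------------------------------
# Symmetry statistics
# ---------------------------------------------------------------------------

#' PolarEvents: events in polar coordinates about the NPC center
#'
#' @slot r radii (nm), >= 0.
#' @slot theta angles in radians in `[0, 2*pi)`.
#' @slot particleIndex integer provenance per event.
#' @export
setClass("PolarEvents",
  slots = c(r = "numeric", theta = "numeric", particleIndex = "integer"))

setValidity("PolarEvents", function(object) {
  if (length(object@r) != length(object@theta) ||
      length(object@r) != length(object@particleIndex))
    return("r, theta and particleIndex must have equal length")
  if (any(object@r < 0)) return("radii must be >= 0")
  if (length(object@theta) &&
      (min(object@theta) < 0 || max(object@theta) >= 2 * pi))
    return("theta must lie in [0, 2*pi)")
  TRUE
})

#' AngularHistogram: binned polar angle distribution
#'
#' @slot breaks uniform bin edges in radians covering `[0, 2*pi]`.
#' @slot counts per-bin event counts.
#' @export
setClass("AngularHistogram", slots = c(breaks = "numeric", counts = "numeric"))

setValidity("AngularHistogram", function(object) {
  if (length(object@breaks) != length(object@counts) + 1L)
    return("breaks must have length(counts) + 1")
  w <- diff(object@breaks)
  if (any(abs(w - w[1]) > 1e-9)) return("bins must be uniform")
  TRUE
})

#' SineFit: period-pi/4 sine fitted to an angular histogram
#'
#' The fitted model is `I(theta) = offset + amplitude * sin(fold * theta + phase)`
#' with the frequency fixed at the symmetry fold (period `2*pi/fold`, i.e.
#' pi/4 for the eightfold NPC); amplitude >= 0 by phase convention.
#'
#' @slot offset baseline counts (A).
#' @slot amplitude modulation amplitude (B, >= 0).
#' @slot phase phase in radians in `[0, 2*pi)`.
#' @slot fold fixed angular frequency (default 8).
#' @slot rss residual sum of squares of the fit.
#' @export
setClass("SineFit",
  slots = c(offset = "numeric", amplitude = "numeric", phase = "numeric",
            fold = "integer", rss = "numeric"))

setValidity("SineFit", function(object) {
  if (object@amplitude < 0) return("amplitude must be >= 0")
  TRUE
})

#' SectorOccupancy: per-NPC eight-sector counts and subunit score
#'
#' A sector is occupied when its localization count strictly exceeds half the
#' mean count per sector for that NPC; the subunit count is the number of
#' occupied sectors.
#'
#' @slot edges the 8 sector boundary angles (radians, spaced pi/4).
#' @slot counts the 8 per-sector event counts.
#' @slot threshold half the mean count per sector.
#' @slot occupied logical occupancy flags.
#' @slot nSubunits number of occupied sectors (0--8).
#' @slot particleIndex provenance index of the scored NPC.
#' @export
setClass("SectorOccupancy",
  slots = c(edges = "numeric", counts = "numeric", threshold = "numeric",
            occupied = "logical", nSubunits = "integer",
            particleIndex = "integer"))

setValidity("SectorOccupancy", function(object) {
  if (length(object@counts) != 8L) return("counts must have length 8")
  if (object@nSubunits != sum(object@occupied))
    return("nSubunits must equal the number of occupied sectors")
  if (!identical(object@occupied, object@counts > object@threshold))
    return("occupied flags must follow the strict threshold rule")
  TRUE
})

# ---------------------------------------------------------------------------
# Profiles
# ---------------------------------------------------------------------------

#' RadialProfile: averaged radial distribution of aligned events
#'
#' @slot breaks radial bin edges (nm).
#' @slot counts raw per-bin counts.
#' @slot density counts divided by the annular bin area (events per nm^2), so
#'   a uniform disc gives a flat density.
#' @export
setClass("RadialProfile",
  slots = c(breaks = "numeric", counts = "numeric", density = "numeric"))

#' AxialProfile: 1D histogram along the axial (side-view) coordinate
#'
#' @slot breaks axial bin edges (nm).
#' @slot counts per-bin counts.
#' @slot particleIndex provenance index (NA for averaged profiles).
#' @export
setClass("AxialProfile",
  slots = c(breaks = "numeric", counts = "numeric", particleIndex = "integer"))

#' TwoGaussianFit: double-Gaussian model of an axial side-view profile
#'
#' Model: `a1 * exp(-(x - mu1)^2 / (2 s1^2)) + a2 * exp(-(x - mu2)^2 / (2 s2^2)) + c`,
#' means ordered so mu1 < mu2. The separation mu2 - mu1 estimates the
#' nuclear-to-cytoplasmic ring distance; the midpoint anchors axial alignment.
#'
#' @slot mu ordered means (nm).
#' @slot sigma standard deviations (nm).
#' @slot amplitude peak amplitudes (counts).
#' @slot baseline additive constant (counts).
#' @slot rss residual sum of squares.
#' @slot flagged TRUE when the two means collapsed to within one bin width.
#' @export
setClass("TwoGaussianFit",
  slots = c(mu = "numeric", sigma = "numeric", amplitude = "numeric",
            baseline = "numeric", rss = "numeric", flagged = "logical"))

setValidity("TwoGaussianFit", function(object) {
  if (length(object@mu) != 2 || object@mu[1] > object@mu[2])
    return("means must be ordered mu1 <= mu2")
  if (any(object@sigma <= 0)) return("sigmas must be > 0")
  if (any(object@amplitude < 0) || object@baseline < 0)
    return("amplitudes and baseline must be >= 0")
  TRUE
})
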