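# Config-driven orchestration of the full pipeline: one YAML-serializable
# config, one master seed with per-stage derived streams, JSON-lines logging,
# and file-based command wrappers mirroring the in-memory functions.

#' Default pipeline configuration
#'
#' The analysis defaults are the method's canonical parameters: 130 nm pick
#' radius, 50--70 nm analysis annulus, eightfold symmetry (period-pi/4 sine),
#' and 2D histogram renderings at 15 nm (single-color) and 5 nm (multicolor)
#' pixels. Simulation defaults describe the reference synthetic NPC (see
#' [NPCModel()]).
#'
#' @return a nested list of defaults; serialize with [yaml::write_yaml()].
#' @export
pipelineDefaults <- function() {
  list(
    pick_radius = 130,
    annulus = c(50, 70),
    symmetry_fold = 8,
    pixel_size_single = 15,
    pixel_size_multi = 5,
    rotation_grid = 1,
    angular_bin = 2,
    max_iterations = 20,
    convergence_tol = 0.5,
    min_total = 0,
    recenter_method = "circle_fit",
    seed = 1,
    n_particles = 83,
    model = list(
      ring_radius = 60,
      n_corners = 8,
      copies_per_corner = 4,
      labeling_efficiency = 0.6,
      blinks_mean = 3,
      loc_precision_xy = 5,
      loc_precision_z = 10,
      ring_separation = 50,
      background_density = 10,
      global_rotation = "random"
    )
  )
}

#' Read a pipeline configuration
#'
#' Loads a YAML file and merges it over [pipelineDefaults()]; keys absent
#' from the file keep their defaults, so a config echoed into an output
#' directory always carries every resolved value.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list merged over the file values.
#' @return the resolved configuration list.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- pipelineDefaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Build model and alignment objects from a configuration
#'
#' @param config a configuration list from [readPipelineConfig()].
#' @return `configModel`: an [NPCModel-class]; `configAlignment`: an
#'   [AlignmentConfig-class].
#' @export
configModel <- function(config) {
  m <- config$model
  NPCModel(ringRadius = m$ring_radius, nCorners = m$n_corners,
           copiesPerCorner = m$copies_per_corner,
           labelingEfficiency = m$labeling_efficiency,
           blinksMean = m$blinks_mean, locPrecisionXY = m$loc_precision_xy,
           locPrecisionZ = m$loc_precision_z,
           ringSeparation = m$ring_separation,
           backgroundDensity = m$background_density,
           globalRotation = m$global_rotation,
           seed = deriveSeed(config$seed, "simulate"))
}

#' @rdname configModel
#' @export
configAlignment <- function(config) {
  AlignmentConfig(rotationGrid = config$rotation_grid,
                  symmetryFold = config$symmetry_fold,
                  maxIterations = config$max_iterations,
                  convergenceTol = config$convergence_tol,
                  annulus = config$annulus, angularBin = config$angular_bin,
                  seed = deriveSeed(config$seed, "align"))
}

#' Run the full symmetry analysis in memory
#'
#' pick -> recenter -> eightfold alignment -> polar conversion -> annulus
#' gate -> pooled angular histogram -> period-pi/4 sine fit -> sector
#' segmentation -> per-NPC occupancy -> cohort distribution. Event
#' conservation is checked at each stage and logged.
#'
#' @param table a [LocalizationTable-class].
#' @param centers n x 2 matrix of picked NPC centers (nm).
#' @param config configuration list (see [readPipelineConfig()]).
#' @param logfile optional path receiving JSON-lines stage logs.
#' @return a list: `particles`, `shifts`, `alignment`
#'   ([AlignmentResult-class]), `polarGated`, `histogram`, `sineFit`,
#'   `edges`, `summary` (see [symmetryDistribution()]).
#' @export
runSymmetryAnalysis <- function(table, centers, config = pipelineDefaults(),
                                logfile = NULL) {
  particles <- pickParticles(table, centers, pickRadius = config$pick_radius)
  logEvent(logfile, "pick", n_particles = length(particles),
           n_events = sum(vapply(particles, nEvents, integer(1))),
           n_shared = attr(particles, "nShared"))
  shifts <- matrix(0, length(particles), 2)
  dropped <- 0L
  for (i in seq_along(particles)) {
    rp <- recenter(particles[[i]], method = config$recenter_method)
    shifts[i, ] <- attr(rp, "shift")
    dropped <- dropped + attr(rp, "nDropped")
    particles[[i]] <- rp
  }
  logEvent(logfile, "recenter", n_dropped = dropped)
  alignment <- alignCohort(particles, configAlignment(config), shifts = shifts)
  logEvent(logfile, "align", iterations = alignment@iterationsRun,
           converged = alignment@converged,
           n_flagged = length(alignment@flagged),
           n_events = nEvents(alignment@superparticle))
  polar <- toPolar(fuse(alignment))
  gated <- gateAnnulus(polar, config$annulus[1], config$annulus[2])
  logEvent(logfile, "gate", n_gated = nEvents(gated))
  hist <- angularHistogram(gated, binWidth = config$angular_bin)
  fit <- fitSine8(hist, fold = config$symmetry_fold)
  edges <- sectorEdges(fit)
  summary <- symmetryDistribution(gated, edges,
                                  particleIds = seq_along(particles),
                                  minTotal = config$min_total)
  stopifnot(sum(summary$perNPC$total) == nEvents(gated))  # conservation
  logEvent(logfile, "symmetry", n_included = summary$nIncluded,
           n_excluded = summary$nExcluded,
           fraction_eightfold = summary$fractionEightfold)
  list(particles = particles, shifts = shifts, alignment = alignment,
       polarGated = gated, histogram = hist, sineFit = fit, edges = edges,
       summary = summary)
}

# Echo the resolved config into an output directory (reproducibility).
echoConfig <- function(config, outDir) {
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
}

#' Command: simulate a synthetic cohort to files
#'
#' Writes one localization CSV and one ground-truth JSON sidecar per
#' particle, a cohort manifest, and the resolved configuration.
#'
#' @param config configuration list.
#' @param outDir output directory (created if missing).
#' @param logfile optional JSON-lines log path.
#' @return the manifest data.frame, invisibly.
#' @export
cmdSimulate <- function(config = pipelineDefaults(), outDir,
                        logfile = NULL) {
  if (config$n_particles < 1) stop("config error: n_particles must be >= 1")
  model <- configModel(config)
  validObject(model)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulateCohort(model, config$n_particles,
                           phasePolicy = "random", seed = config$seed)
  manifest <- data.frame(particle = seq_along(cohort),
                         file = sprintf("particle_%04d.csv", seq_along(cohort)),
                         n_events = vapply(cohort, function(p) nEvents(p$table),
                                           integer(1)))
  for (i in seq_along(cohort)) {
    writeLocalizations(cohort[[i]]$table, file.path(outDir, manifest$file[i]))
    tr <- cohort[[i]]$truth
    jsonlite::write_json(
      list(corner_angles = tr@cornerAngles,
           labeled_sites = tr@labeledSites,
           parent_site = tr@parentSite,
           true_center = tr@trueCenter),
      file.path(outDir, sub("\\.csv$", "_truth.json", manifest$file[i])),
      digits = NA)
  }
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  echoConfig(config, outDir)
  logEvent(logfile, "simulate", n_particles = nrow(manifest),
           n_events = sum(manifest$n_events))
  invisible(manifest)
}

#' Command: symmetry analysis from files
#'
#' @param config configuration list.
#' @param locPath localization CSV path.
#' @param centersPath CSV with columns x, y (nm) of picked centers.
#' @param outDir output directory.
#' @param dialect a [locDialect()] for the localization file.
#' @return the in-memory result of [runSymmetryAnalysis()], invisibly.
#' @export
cmdSymmetry <- function(config = pipelineDefaults(), locPath, centersPath,
                        outDir, dialect = locDialect()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outDir, "log.jsonl")
  table <- readLocalizations(locPath, dialect)
  centers <- utils::read.csv(centersPath)
  if (!all(c("x", "y") %in% names(centers)))
    stop("stage centers: file must have columns x and y")
  res <- runSymmetryAnalysis(table, as.matrix(centers[, c("x", "y")]),
                             config, logfile = logfile)
  utils::write.csv(res$summary$perNPC, file.path(outDir, "per_npc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(sine = list(offset = res$sineFit@offset,
                     amplitude = res$sineFit@amplitude,
                     phase = res$sineFit@phase),
         edges = res$edges,
         distribution = as.list(res$summary$distribution),
         fraction_eightfold = res$summary$fractionEightfold,
         n_included = res$summary$nIncluded,
         n_excluded = res$summary$nExcluded),
    file.path(outDir, "cohort_summary.json"), auto_unbox = TRUE, digits = NA)
  echoConfig(config, outDir)
  invisible(res)
}

#' Command: radial profile of a localization table
#'
#' @param config configuration list.
#' @param locPath localization CSV (centered common-frame coordinates).
#' @param outDir output directory.
#' @param dialect a [locDialect()].
#' @return the [RadialProfile-class], invisibly.
#' @export
cmdProfile <- function(config = pipelineDefaults(), locPath, outDir,
                       dialect = locDialect()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  table <- readLocalizations(locPath, dialect)
  prof <- radialProfile(table, rMax = config$pick_radius)
  stopifnot(sum(prof@counts) ==
              sum(toPolar(table)@r <= config$pick_radius))
  utils::write.csv(
    data.frame(r_in = prof@breaks[-length(prof@breaks)],
               r_out = prof@breaks[-1], count = prof@counts,
               density = prof@density),
    file.path(outDir, "radial_profile.csv"), row.names = FALSE)
  echoConfig(config, outDir)
  invisible(prof)
}

#' Command: NPC density from a centers file and ROI
#'
#' @param config configuration list.
#' @param centersPath CSV with columns x, y (nm).
#' @param roiPath ROI JSON (vertex list, nm).
#' @param outDir output directory.
#' @return the density report list, invisibly.
#' @export
cmdDensity <- function(config = pipelineDefaults(), centersPath, roiPath,
                       outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  centers <- utils::read.csv(centersPath)
  if (!all(c("x", "y") %in% names(centers)))
    stop("stage density: centers file must have columns x and y")
  roi <- readRoi(roiPath)
  rep <- npcDensity(as.matrix(centers[, c("x", "y")]), roi)
  jsonlite::write_json(rep, file.path(outDir, "density.json"),
                       auto_unbox = TRUE, digits = NA)
  echoConfig(config, outDir)
  invisible(rep)
}
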