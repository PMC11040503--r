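# Synthetic SMLM generator for NPC-like particles, with ground truth.
#
# Generative model per particle: nCorners corner sites on a ring, each with
# copiesPerCorner fluorophore sites labeled Bernoulli(labelingEfficiency);
# each labeled site emits Geometric({1,2,...}, mean blinksMean) localizations
# blurred by isotropic Gaussian error; plus a uniform Poisson background on
# the 130-nm picking disc so simulation and particle extraction compose.

PICK_DISC_RADIUS <- 130  # nm, matches the default particle picking radius

#' Simulate one NPC particle
#'
#' Draws one synthetic NPC localization cloud centered at `center`, with full
#' generative ground truth. Reproducible for a fixed seed.
#'
#' @param model an [NPCModel-class].
#' @param seed RNG seed; defaults to the model's seed.
#' @param center x, y (nm) of the true particle center.
#' @param sideView when TRUE, events carry an axial coordinate: each site is
#'   assigned to the nuclear or cytoplasmic ring (axial positions
#'   -/+ ringSeparation/2) and axial Gaussian error locPrecisionZ is added.
#' @return a list with elements `table` ([LocalizationTable-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' model <- NPCModel(labelingEfficiency = 1, copiesPerCorner = 1,
#'                   blinksMean = 1, locPrecisionXY = 0,
#'                   backgroundDensity = 0, globalRotation = 0)
#' p <- simulateParticle(model)
#' nEvents(p$table)  # exactly 8
#' @export
simulateParticle <- function(model, seed = model@seed, center = c(0, 0),
                             sideView = FALSE) {
  stopifnot(is(model, "NPCModel"))
  validObject(model)
  withSeed(seed, {
    phase <- if (is.na(model@globalRotation)) stats::runif(1, 0, 360)
             else model@globalRotation
    nC <- model@nCorners
    nK <- model@copiesPerCorner
    cornerAngles <- wrapDeg(phase + (seq_len(nC) - 1) * 360 / nC)
    labeled <- matrix(stats::runif(nC * nK) < model@labelingEfficiency,
                      nrow = nC, ncol = nK)
    siteCorner <- rep(seq_len(nC), each = nK)     # linear site order:
    siteIdx <- which(as.vector(t(labeled)))       # (corner-1)*nK + copy
    nSites <- length(siteIdx)

    xs <- ys <- zs <- numeric(0)
    parent <- integer(0)
    ring <- integer(0)
    if (nSites) {
      blinks <- rblinks(nSites, model@blinksMean)
      parent <- rep(siteIdx, blinks)
      corner <- siteCorner[parent]
      ang <- cornerAngles[corner] * DEG2RAD
      xs <- model@ringRadius * cos(ang)
      ys <- model@ringRadius * sin(ang)
      n <- length(xs)
      if (model@locPrecisionXY > 0) {
        xs <- xs + stats::rnorm(n, 0, model@locPrecisionXY)
        ys <- ys + stats::rnorm(n, 0, model@locPrecisionXY)
      }
      if (sideView) {
        siteRing <- sample(c(1L, 2L), nC * nK, replace = TRUE)
        ring <- siteRing[parent]
        zs <- ifelse(ring == 2L, model@ringSeparation / 2,
                     -model@ringSeparation / 2)
        if (model@locPrecisionZ > 0)
          zs <- zs + stats::rnorm(n, 0, model@locPrecisionZ)
      }
    }

    discAreaUm2 <- pi * (PICK_DISC_RADIUS / 1000)^2
    nBg <- stats::rpois(1, model@backgroundDensity * discAreaUm2)
    if (nBg > 0) {
      rb <- PICK_DISC_RADIUS * sqrt(stats::runif(nBg))
      tb <- stats::runif(nBg, 0, 2 * pi)
      xs <- c(xs, rb * cos(tb))
      ys <- c(ys, rb * sin(tb))
      parent <- c(parent, rep(-1L, nBg))
      if (sideView) {
        zspan <- model@ringSeparation / 2 + 3 * model@locPrecisionZ + 10
        zs <- c(zs, stats::runif(nBg, -zspan, zspan))
        ring <- c(ring, rep(NA_integer_, nBg))
      }
    }

    tab <- if (sideView)
      LocalizationTable(x = xs + center[1], y = ys + center[2], z = zs)
    else
      LocalizationTable(x = xs + center[1], y = ys + center[2])
    truth <- new("GroundTruth", cornerAngles = cornerAngles,
                 labeledSites = labeled, parentSite = as.integer(parent),
                 trueCenter = as.numeric(center),
                 ringAssignment = if (sideView) as.integer(ring)
                                  else rep(NA_integer_, length(parent)))
    list(table = tab, truth = truth)
  })
}

#' Simulate a cohort of independent NPC particles
#'
#' Per-particle seeds are derived deterministically from the master seed, so
#' cohorts are reproducible and individual particles re-simulable.
#'
#' @param model an [NPCModel-class].
#' @param nParticles number of particles (>= 1).
#' @param phasePolicy "random" gives every particle an independent uniform
#'   ring phase (emulating unaligned picked NPCs); "fixed" uses the model's
#'   `globalRotation` (0 if the model's phase is random).
#' @param seed master seed; defaults to the model's seed.
#' @param sideView passed to [simulateParticle()].
#' @return a list of `nParticles` lists with elements `table` and `truth`.
#' @export
simulateCohort <- function(model, nParticles,
                           phasePolicy = c("random", "fixed"),
                           seed = model@seed, sideView = FALSE) {
  stopifnot(nParticles >= 1)
  phasePolicy <- match.arg(phasePolicy)
  m <- model
  if (phasePolicy == "random") {
    m@globalRotation <- NA_real_
  } else if (is.na(m@globalRotation)) {
    m@globalRotation <- 0
  }
  lapply(seq_len(nParticles), function(i) {
    simulateParticle(m, seed = deriveSeed(seed, paste0("particle", i)),
                     sideView = sideView)
  })
}

#' Simulate side-view NPC particles
#'
#' Convenience wrapper: a cohort whose events carry an axial coordinate, with
#' the nuclear and cytoplasmic rings at -/+ `ringSeparation`/2 and per-event
#' ring assignment recorded in the ground truth.
#'
#' @inheritParams simulateCohort
#' @return as [simulateCohort()].
#' @export
simulateSideView <- function(model, nParticles, seed = model@seed) {
  simulateCohort(model, nParticles, phasePolicy = "random", seed = seed,
                 sideView = TRUE)
}

#' Simulate a nuclear-envelope patch of NPCs
#'
#' NPC centers are drawn as a homogeneous Poisson point process of intensity
#' `npcDensity` on the ROI; each center carries one simulated particle.
#'
#' @param model an [NPCModel-class].
#' @param npcDensity NPC surface density (per square micron, >= 0).
#' @param roi an [RoiPolygon-class].
#' @param seed master seed; defaults to the model's seed.
#' @return a list with `table` (pooled [LocalizationTable-class] with a
#'   `particle` provenance column), `centers` (n x 2 matrix of true centers,
#'   nm) and `truths` (list of [GroundTruth-class]).
#' @export
simulateNePatch <- function(model, npcDensity, roi, seed = model@seed) {
  stopifnot(npcDensity >= 0, is(roi, "RoiPolygon"))
  areaUm2 <- roiArea(roi, "um2")
  centers <- withSeed(deriveSeed(seed, "ne-centers"), {
    n <- stats::rpois(1, npcDensity * areaUm2)
    runifPolygon(n, roi@vertices)
  })
  n <- nrow(centers)
  parts <- lapply(seq_len(n), function(i) {
    simulateParticle(model, seed = deriveSeed(seed, paste0("ne-particle", i)),
                     center = centers[i, ])
  })
  if (n) {
    evs <- lapply(seq_len(n), function(i) {
      ev <- parts[[i]]$table@events
      if (nrow(ev)) cbind(ev, particle = i) else NULL
    })
    pooled <- do.call(rbind, evs)
    tab <- if (is.null(pooled)) LocalizationTable()
           else LocalizationTable(x = pooled$x, y = pooled$y,
                                  particle = pooled$particle)
  } else {
    tab <- LocalizationTable()
  }
  list(table = tab, centers = centers,
       truths = lapply(parts, `[[`, "truth"))
}

#' Theoretical subunit-count distribution under the generative model
#'
#' With background-free, low-noise data the number of corners carrying at
#' least one labeled fluorophore site is Binomial(nCorners, q) with
#' q = 1 - (1 - labelingEfficiency)^copiesPerCorner, and the sector-occupancy
#' statistic recovers exactly that count. This closed form is the oracle for
#' the package's parameter-recovery tests.
#'
#' @param model an [NPCModel-class].
#' @return named numeric vector of probabilities over 0..nCorners subunits.
#' @examples
#' m <- NPCModel(labelingEfficiency = 0.5, copiesPerCorner = 1)
#' theoreticalSubunitDistribution(m)["8"]  # 1/256
#' @export
theoreticalSubunitDistribution <- function(model) {
  stopifnot(is(model, "NPCModel"))
  q <- 1 - (1 - model@labelingEfficiency)^model@copiesPerCorner
  k <- 0:model@nCorners
  stats::setNames(stats::dbinom(k, model@nCorners, q), k)
}
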