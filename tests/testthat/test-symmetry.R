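# Polar conversion, annulus gating, sine fitting, sector segmentation and
# the occupancy statistic.

test_that("polar conversion matches closed forms and round-trips", {
  pol <- toPolar(LocalizationTable(x = c(0, -1, 3), y = c(60, 0, -4)))
  expect_equal(pol@r, c(60, 1, 5))
  expect_equal(pol@theta[1:2], c(pi / 2, pi))

  set.seed(4)
  x <- rnorm(200, 0, 50); y <- rnorm(200, 0, 50)
  pol2 <- toPolar(LocalizationTable(x = x, y = y))
  expect_lt(max(abs(pol2@r * cos(pol2@theta) - x)), 1e-9)
  expect_lt(max(abs(pol2@r * sin(pol2@theta) - y)), 1e-9)
  expect_true(all(pol2@theta >= 0 & pol2@theta < 2 * pi))
})

test_that("annulus gating is closed on both ends and idempotent", {
  r <- c(49.9, 50.0, 60, 70.0, 70.1)
  pol <- new("PolarEvents", r = r, theta = rep(1, 5),
             particleIndex = rep(1L, 5))
  g <- gateAnnulus(pol)
  expect_equal(g@r, c(50.0, 60, 70.0))
  expect_equal(nEvents(gateAnnulus(g)), nEvents(g))
  expect_equal(nEvents(gateAnnulus(new("PolarEvents", r = numeric(0),
                                       theta = numeric(0),
                                       particleIndex = integer(0)))), 0L)
})

test_that("the pooled angular histogram conserves counts and sees corners", {
  ang <- seq(0, 315, by = 45) * pi / 180 + 1e-6
  pol <- new("PolarEvents", r = rep(60, 8), theta = ang,
             particleIndex = rep(1L, 8))
  h <- angularHistogram(pol, binWidth = 2)
  expect_equal(length(h@counts), 180L)
  expect_equal(sum(h@counts), 8)
  expect_equal(sum(h@counts > 0), 8L)
  expect_true(all(h@counts[h@counts > 0] == 1))

  expect_error(angularHistogram(pol, binWidth = 7), "divide 360")

  # flatness of uniform angles is not rejected at alpha = 0.001
  for (s in 1:4) {
    set.seed(s)
    polu <- new("PolarEvents", r = rep(60, 4000),
                theta = runif(4000, 0, 2 * pi),
                particleIndex = rep(1L, 4000))
    hu <- angularHistogram(polu, binWidth = 5)
    pval <- chisq.test(hu@counts)$p.value
    expect_gt(pval, 0.001)
  }
})

test_that("the closed-form sine fit recovers exact generative parameters", {
  h <- sineHistogram(A = 100, B = 50, phi = 0)
  fit <- fitSine8(h)
  expect_equal(fit@offset, 100, tolerance = 1e-6)
  expect_equal(fit@amplitude, 50, tolerance = 1e-6)
  expect_equal(fit@phase, 0, tolerance = 1e-6)
  expect_lt(fit@rss, 1e-12)

  fit3 <- fitSine8(sineHistogram(A = 100, B = 50, phi = 0.3))
  expect_equal(fit3@phase, 0.3, tolerance = 1e-6)

  flat <- fitSine8(sineHistogram(A = 7, B = 0, phi = 0))
  expect_equal(flat@offset, 7, tolerance = 1e-9)
  expect_equal(flat@amplitude, 0, tolerance = 1e-9)

  allzero <- sineHistogram(A = 0, B = 0, phi = 0)
  expect_error(fitSine8(allzero), "all-zero")
})

test_that("the sine fit matches an independent brute-force minimizer", {
  set.seed(17)
  for (i in 1:20) {
    h <- randomHistogram(nBins = 90)
    fit <- fitSine8(h)
    brute <- bruteForceSineRss(h, nGrid = 3600)
    denom <- max(brute, 1e-12)
    expect_lt((fit@rss - brute) / denom, 1e-4)
    expect_gte(fit@rss, brute - denom * 1e-4)  # closed form is the global min
  }
})

test_that("sector edges sit at the sine minima with exact pi/4 spacing", {
  e0 <- sectorEdges(new("SineFit", offset = 10, amplitude = 5, phase = 0,
                        fold = 8L, rss = 0))
  expect_equal(e0[1], 3 * pi / 16, tolerance = 1e-12)
  expect_equal(diff(e0), rep(pi / 4, 7), tolerance = 1e-12)

  e3 <- sectorEdges(new("SineFit", offset = 10, amplitude = 5, phase = 0.3,
                        fold = 8L, rss = 0))
  v <- ((e3 + 0.3 / 8) - e0[1]) %% (pi / 4)
  expect_true(all(pmin(v, pi / 4 - v) < 1e-9))

  expect_warning(
    ez <- sectorEdges(new("SineFit", offset = 10, amplitude = 0, phase = 0,
                          fold = 8L, rss = 0)), "no minima")
  expect_equal(ez, seq(0, 2 * pi - pi / 8, by = pi / 4))
})

test_that("sector counting is exhaustive, half-open and convention-stable", {
  edges <- seq(0, 2 * pi - pi / 8, by = pi / 4) + 0.1
  set.seed(8)
  th <- runif(24, 0, 2 * pi)
  pol <- new("PolarEvents", r = rep(60, 24), theta = th,
             particleIndex = rep(3L, 24))
  cnt <- sectorCounts(pol, edges, particleIndex = 3L)
  expect_equal(sum(cnt), 24)

  # an event exactly on an edge opens that sector
  onEdge <- new("PolarEvents", r = 60, theta = edges[4],
                particleIndex = 1L)
  expect_equal(sectorCounts(onEdge, edges)[4], 1L)

  # noiseless corners at sector centers spread evenly
  centers <- edges[1] + pi / 8 + (0:7) * pi / 4
  polc <- new("PolarEvents", r = rep(60, 8), theta = npcfold:::wrapRad(centers),
              particleIndex = rep(1L, 8))
  expect_equal(sectorCounts(polc, edges), rep(1L, 8))
})

test_that("occupancy arithmetic follows the strict half-mean rule", {
  o1 <- occupancy(c(10, 10, 10, 10, 10, 10, 10, 0))
  expect_equal(o1@threshold, 4.375)
  expect_equal(nSubunits(o1), 7L)

  expect_equal(nSubunits(occupancy(rep(3, 8))), 8L)
  expect_equal(nSubunits(occupancy(rep(0, 8))), 0L)

  # a count exactly at the threshold is unoccupied
  tie <- occupancy(c(2, 4, 4, 4, 4, 4, 4, 6))  # mean 4, threshold 2
  expect_false(tie@occupied[1])
  expect_equal(nSubunits(tie), 7L)
})

test_that("cohort distributions are normalized and perfect cohorts score 8", {
  cohort <- simulateCohort(perfectModel(), 30, phasePolicy = "fixed", seed = 1)
  evs <- do.call(rbind, lapply(seq_along(cohort), function(i)
    cbind(eventData(cohort[[i]]$table), particle = i)))
  pol <- gateAnnulus(toPolar(LocalizationTable(x = evs$x, y = evs$y,
                                               particle = evs$particle)))
  fit <- fitSine8(angularHistogram(pol))
  edges <- sectorEdges(fit)
  res <- symmetryDistribution(pol, edges, particleIds = 1:30)
  expect_equal(sum(res$distribution), 1)
  expect_equal(res$fractionEightfold, 1)
  expect_equal(res$nIncluded, 30L)

  # minTotal excludes sparse NPCs and reports them
  res2 <- symmetryDistribution(pol, edges, particleIds = 1:31, minTotal = 3)
  expect_equal(res2$nExcluded, 1L)  # particle 31 has no events
})

test_that("subunit counts are invariant under a global cohort rotation", {
  m <- NPCModel(labelingEfficiency = 0.6, copiesPerCorner = 1, blinksMean = 1,
                locPrecisionXY = 2, backgroundDensity = 0,
                globalRotation = 0)
  cohort <- simulateCohort(m, 80, phasePolicy = "fixed", seed = 5)
  build <- function(rot) {
    evs <- do.call(rbind, lapply(seq_along(cohort), function(i) {
      ev <- eventData(cohort[[i]]$table)
      if (!nrow(ev)) return(NULL)
      cbind(npcfold:::rotateEvents(data.frame(dx = ev$x, dy = ev$y), rot),
            particle = i)
    }))
    gateAnnulus(toPolar(LocalizationTable(x = evs$dx, y = evs$dy,
                                          particle = evs$particle)))
  }
  score <- function(pol) {
    edges <- sectorEdges(fitSine8(angularHistogram(pol)))
    symmetryDistribution(pol, edges, particleIds = seq_along(cohort))
  }
  s0 <- score(build(0))
  s1 <- score(build(13.7))
  expect_equal(s1$perNPC$nSubunits, s0$perNPC$nSubunits)
})

test_that("mean subunit count rises with labeling efficiency (matched seeds)", {
  means <- vapply(c(0.3, 0.5, 0.7, 0.9), function(p) {
    m <- NPCModel(labelingEfficiency = p, copiesPerCorner = 1, blinksMean = 1,
                  locPrecisionXY = 2, backgroundDensity = 0,
                  globalRotation = 0)
    cohort <- simulateCohort(m, 150, phasePolicy = "fixed", seed = 31)
    evs <- do.call(rbind, lapply(seq_along(cohort), function(i) {
      ev <- eventData(cohort[[i]]$table)
      if (!nrow(ev)) return(NULL)
      cbind(ev, particle = i)
    }))
    pol <- gateAnnulus(toPolar(LocalizationTable(x = evs$x, y = evs$y,
                                                 particle = evs$particle)))
    edges <- sectorEdges(fitSine8(angularHistogram(pol)))
    res <- symmetryDistribution(pol, edges, particleIds = seq_along(cohort))
    mean(res$perNPC$nSubunits)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
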