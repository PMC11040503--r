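# Radial profiles, axial two-Gaussian fitting and NPC density.

test_that("radial profiles conserve counts and flatten uniform discs", {
  ring <- toPolar(simulateParticle(perfectModel())$table)
  prof <- radialProfile(ring, binWidth = 5, rMax = 130)
  expect_equal(sum(prof@counts), 8)
  # radius-60 events land in the [55,60) or [60,65) bin (floating point
  # decides which side of the shared edge)
  expect_true(all(which(prof@counts > 0) %in% c(12L, 13L)))

  # uniform disc: area-normalized density is flat across radii
  set.seed(6)
  n <- 60000
  r <- 100 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  disc <- LocalizationTable(x = r * cos(th), y = r * sin(th))
  dp <- radialProfile(disc, binWidth = 10, rMax = 100)
  expect_equal(sum(dp@counts), n)
  dens <- dp@density / mean(dp@density)
  # innermost bins hold few events; allow ~4 relative standard errors there
  expect_lt(max(abs(dens - 1)), 0.16)
})

test_that("axial profiles require z, conserve counts and resolve two rings", {
  sv <- simulateSideView(perfectModel(ringSeparation = 50), 1, seed = 2)[[1]]
  ap <- axialProfile(sv$table, binWidth = 2, range = c(-60, 60))
  expect_equal(sum(ap@counts), nEvents(sv$table))
  expect_equal(sum(ap@counts > 0), 2L)
  mids <- (ap@breaks[-length(ap@breaks)] + ap@breaks[-1]) / 2
  expect_equal(sort(unique(abs(mids[ap@counts > 0]))), 25)

  flat <- LocalizationTable(x = 1:5, y = 1:5)
  expect_error(axialProfile(flat), "'z'")

  m <- NPCModel(ringSeparation = 50, locPrecisionZ = 5, blinksMean = 4,
                labelingEfficiency = 1, backgroundDensity = 0)
  svs <- simulateSideView(m, 50, seed = 7)
  z <- unlist(lapply(svs, function(p) eventData(p$table)$z))
  pooled <- axialProfile(LocalizationTable(x = z * 0, y = z * 0, z = z),
                         binWidth = 2, range = c(-80, 80))
  pk <- npcfold:::localMaxima(pooled@counts)
  pk <- pk[order(pooled@counts[pk], decreasing = TRUE)][1:2]
  midz <- (pooled@breaks[-length(pooled@breaks)] + pooled@breaks[-1]) / 2
  expect_lt(abs(abs(diff(midz[pk])) - 50), 6)
})

test_that("two-Gaussian fits recover exact generative parameters", {
  breaks <- seq(-60, 60, by = 2)
  xc <- (breaks[-length(breaks)] + breaks[-1]) / 2
  y <- 100 * exp(-(xc + 25)^2 / (2 * 25)) + 100 * exp(-(xc - 25)^2 / (2 * 25))
  prof <- new("AxialProfile", breaks = breaks, counts = y,
              particleIndex = 1L)
  fit <- fitTwoGaussians(prof)
  expect_equal(separation(fit), 50, tolerance = 0.1 / 50)
  expect_lt(abs(midpoint(fit)), 0.1)
  expect_equal(fit@sigma, c(5, 5), tolerance = 0.01)
  expect_false(fit@flagged)

  # Poisson-noise recovery: separation unbiased within Monte-Carlo error
  seps <- vapply(1:8, function(s) {
    set.seed(s)
    yn <- rpois(length(xc), y)
    separation(fitTwoGaussians(new("AxialProfile", breaks = breaks,
                                   counts = as.numeric(yn),
                                   particleIndex = 1L)))
  }, numeric(1))
  expect_lt(abs(mean(seps) - 50), 3 * sd(seps) / sqrt(length(seps)))

  sparse <- new("AxialProfile", breaks = seq(0, 10, 2),
                counts = c(1, 2, 1, 0, 0), particleIndex = 1L)
  expect_error(fitTwoGaussians(sparse), "7")
})

test_that("axial alignment removes known per-particle offsets", {
  breaks <- seq(-80, 80, by = 2)
  xc <- (breaks[-length(breaks)] + breaks[-1]) / 2
  shape <- function(off) 80 * exp(-(xc - off + 25)^2 / 50) +
    80 * exp(-(xc - off - 25)^2 / 50)
  offsets <- c(-14, -5, 0, 7, 18)
  profs <- lapply(offsets, function(o)
    new("AxialProfile", breaks = breaks, counts = shape(o),
        particleIndex = 1L))
  fits <- lapply(profs, fitTwoGaussians)
  expect_equal(vapply(fits, midpoint, numeric(1)), offsets, tolerance = 1e-3)

  av <- alignAxial(fits, profs)
  expect_equal(av$shifts, -offsets, tolerance = 1e-3)
  f <- fitTwoGaussians(av$reference)
  expect_lt(abs(midpoint(f)), 1)
  expect_equal(separation(f), 50, tolerance = 2 / 50)

  # a single particle is simply recentered
  one <- alignAxial(fits[3], profs[3])
  expect_equal(sum(one$reference@counts), sum(profs[[3]]@counts),
               tolerance = 1e-9)

  # end-to-end on simulated side views: average fit within one bin of truth
  m <- NPCModel(ringSeparation = 50, locPrecisionZ = 5, blinksMean = 4,
                labelingEfficiency = 0.8, backgroundDensity = 0)
  svs <- simulateSideView(m, 40, seed = 19)
  sprofs <- lapply(svs, function(p)
    axialProfile(p$table, binWidth = 2, range = c(-80, 80)))
  sfits <- lapply(sprofs, fitTwoGaussians)
  sav <- alignAxial(sfits, sprofs)
  send <- fitTwoGaussians(sav$reference)
  expect_lt(abs(separation(send) - 50), 2)

  expect_error(alignAxial(sfits[-1], sprofs), "index-matched")
})

test_that("NPC density arithmetic is exact and boundary-inclusive", {
  roi <- RoiPolygon(cbind(c(0, 4000, 4000, 0), c(0, 0, 2500, 2500)))  # 10 um2
  set.seed(10)
  centers <- cbind(runif(100, 1, 3999), runif(100, 1, 2499))
  d <- npcDensity(centers, roi)
  expect_identical(d$density, 10)
  expect_equal(d$areaUm2, 10)

  # points outside are excluded; a boundary point counts
  mixed <- rbind(centers, c(-50, 100), c(9000, 100), c(0, 1250))
  d2 <- npcDensity(mixed, roi)
  expect_equal(d2$count, 101L)

  # invariance under a rigid transform of centers and ROI together
  a <- 0.6
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  t0 <- c(1500, -700)
  cen2 <- sweep(centers %*% t(R), 2, t0, "+")
  roi2 <- RoiPolygon(sweep(roi@vertices %*% t(R), 2, t0, "+"))
  d3 <- npcDensity(cen2, roi2)
  expect_equal(d3$count, d$count)
  expect_equal(d3$density, d$density, tolerance = 1e-9)
})

test_that("patch simulation and density estimation close the loop", {
  roi <- RoiPolygon(cbind(c(0, 4000, 4000, 0), c(0, 0, 2500, 2500)))
  cheap <- NPCModel(labelingEfficiency = 0, backgroundDensity = 0)
  est <- vapply(1:40, function(s) {
    npcDensity(simulateNePatch(cheap, 10, roi, seed = 100 + s)$centers,
               roi)$density
  }, numeric(1))
  se <- sqrt(10 / 10 / 40)  # Var(count)/area^2 summed over replicates
  expect_lt(abs(mean(est) - 10), 3 * se)
})
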