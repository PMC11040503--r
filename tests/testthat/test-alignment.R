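# Rotational registration, iterative cohort alignment and fusion.

noiselessParticle <- function(phaseDeg = 0) {
  ang <- (phaseDeg + seq(0, 315, by = 45)) * pi / 180
  Particle(data.frame(dx = 60 * cos(ang), dy = 60 * sin(ang)))
}

templateOf <- function(particle, config = AlignmentConfig()) {
  npcfold:::cicCounts(
    npcfold:::annulusAngles(particle, config@annulus), config@angularBin)
}

test_that("rotational offsets are recovered on the grid, modulo 45 degrees", {
  cfg <- AlignmentConfig()
  base <- noiselessParticle(10)  # avoid bin-edge degeneracy at 0
  tmpl <- templateOf(base, cfg)
  expect_equal(rotationalOffset(base, tmpl, cfg), 0)

  for (rot in c(10, 21, 33)) {
    rotated <- noiselessParticle(10 + rot)
    off <- rotationalOffset(rotated, tmpl, cfg)
    expect_lte(min(abs(off - rot), 45 - abs(off - rot)), cfg@rotationGrid / 2)
  }
  # rotations differing by the symmetry fold are equivalent
  off55 <- rotationalOffset(noiselessParticle(10 + 55), tmpl, cfg)
  expect_lte(min(abs(off55 - 10), 45 - abs(off55 - 10)), cfg@rotationGrid / 2)

  # empty annulus: flagged, rotation 0
  tiny <- Particle(data.frame(dx = 1, dy = 1))
  off <- rotationalOffset(tiny, tmpl, cfg)
  expect_equal(as.numeric(off), 0)
  expect_true(attr(off, "flagged"))
})

test_that("a cohort of random-phase copies aligns to a common phase", {
  set.seed(11)
  phases <- runif(60, 0, 360)
  particles <- lapply(phases, noiselessParticle)
  res <- alignCohort(particles, AlignmentConfig(seed = 4))
  expect_s4_class(res, "AlignmentResult")
  expect_true(all(rotations(res) >= 0 & rotations(res) < 45))

  aligned <- (rotations(res) + phases) %% 45
  expect_lt(circSdDeg(aligned, 45), 2)

  # pairwise lag-0 circular cross-correlation of angular histograms is the
  # maximal lag for aligned copies
  cfg <- res@config
  rotp <- lapply(seq_along(particles), function(i) {
    p <- particles[[i]]
    Particle(npcfold:::rotateEvents(eventData(p), rotations(res)[i]))
  })
  h <- lapply(rotp, templateOf, config = cfg)
  nb <- length(h[[1]])
  lagCor <- function(a, b, lag) sum(a * b[((seq_len(nb) - 1 + lag) %% nb) + 1])
  for (i in c(2, 17, 41)) {
    cors <- vapply(0:(nb - 1), function(l) lagCor(h[[1]], h[[i]], l), numeric(1))
    best <- (which.max(cors) - 1) * cfg@angularBin
    offBest <- min(best %% 45, 45 - best %% 45)
    expect_lte(offBest, cfg@angularBin)
  }
})

test_that("alignment is deterministic and idempotent at the fixed point", {
  set.seed(2)
  particles <- lapply(runif(20, 0, 360), noiselessParticle)
  cfg <- AlignmentConfig(seed = 9)
  r1 <- alignCohort(particles, cfg)
  r2 <- alignCohort(particles, cfg)
  expect_identical(rotations(r1), rotations(r2))
  expect_identical(eventData(superparticle(r1)), eventData(superparticle(r2)))

  # an already-aligned cohort converges immediately with tiny updates
  aligned <- lapply(seq_along(particles), function(i) {
    Particle(npcfold:::rotateEvents(eventData(particles[[i]]),
                                              rotations(r1)[i]))
  })
  r3 <- alignCohort(aligned, cfg)
  expect_true(r3@converged)
  expect_lte(r3@iterationsRun, 2L)
  expect_lt(r3@trace$meanAbsUpdate[1], cfg@convergenceTol)
})

test_that("events are conserved through alignment and fusion", {
  m <- NPCModel(labelingEfficiency = 0.7, backgroundDensity = 15)
  cohort <- simulateCohort(m, 25, seed = 6)
  particles <- lapply(seq_along(cohort), function(i) {
    ev <- eventData(cohort[[i]]$table)
    Particle(data.frame(dx = ev$x, dy = ev$y), pickIndex = i)
  })
  res <- alignCohort(particles, AlignmentConfig(seed = 1))
  expect_equal(nEvents(superparticle(res)),
               sum(vapply(particles, nEvents, integer(1))))
  expect_identical(fuse(res), superparticle(res))

  # zero rotations fuse to a plain concatenation
  cat0 <- npcfold:::fuseParticles(particles, rep(0, length(particles)))
  expect_equal(eventData(cat0)$x,
               unlist(lapply(particles, function(p) eventData(p)$dx)),
               ignore_attr = TRUE)
})

test_that("alignment is equivariant under a global pre-rotation", {
  set.seed(5)
  particles <- lapply(runif(15, 0, 360), noiselessParticle)
  cfg <- AlignmentConfig(seed = 3)
  delta <- 10  # a multiple of the angular bin, so binning shifts exactly
  pre <- lapply(particles, function(p)
    Particle(npcfold:::rotateEvents(eventData(p), delta)))
  r0 <- alignCohort(particles, cfg)
  r1 <- alignCohort(pre, cfg)
  expect_equal(rotations(r1), rotations(r0), tolerance = 1e-9)
  # the fused cloud is the original fused cloud rotated by delta
  e0 <- npcfold:::rotateEvents(
    data.frame(dx = eventData(superparticle(r0))$x,
               dy = eventData(superparticle(r0))$y), delta)
  expect_equal(eventData(superparticle(r1))$x, e0$dx, tolerance = 1e-9)
  expect_equal(eventData(superparticle(r1))$y, e0$dy, tolerance = 1e-9)
})

test_that("the random k*45 step preserves lag-45 circular autocorrelation", {
  set.seed(13)
  cfg <- AlignmentConfig(angularBin = 2.5)  # 45 deg = 18 whole bins
  shiftBins <- as.integer(45 / cfg@angularBin)
  for (rep in 1:10) {
    p <- Particle(data.frame(dx = rnorm(40, 0, 45), dy = rnorm(40, 0, 45)),
                  pickRadius = 500)
    h0 <- templateOf(p, cfg)
    k <- sample(0:7, 1)
    pr <- Particle(npcfold:::rotateEvents(eventData(p), k * 45),
                   pickRadius = 500)
    h1 <- templateOf(pr, cfg)
    nb <- length(h0)
    lagCor <- function(h) sum(h * h[((seq_len(nb) - 1 + shiftBins) %% nb) + 1])
    expect_equal(lagCor(h1), lagCor(h0))
  }
})

test_that("coimaged channels inherit the reference alignment", {
  set.seed(21)
  phases <- runif(30, 0, 360)
  particles <- lapply(phases, noiselessParticle)
  res <- alignCohort(particles, AlignmentConfig(seed = 2))

  # identical channel reproduces the fused reference exactly
  co <- transformCoimaged(particles, res)
  expect_equal(eventData(co), eventData(fuse(res)))

  # events at the particle center are fixed points of the rotation
  centers <- lapply(particles, function(p) Particle(data.frame(dx = 0, dy = 0)))
  cc <- transformCoimaged(centers, res)
  expect_equal(max(abs(eventData(cc)$x)), 0)

  # a coimaged channel on a smaller ring peaks at its own radius
  small <- lapply(phases, function(ph) {
    ang <- (ph + seq(0, 315, by = 45)) * pi / 180
    Particle(data.frame(dx = 30 * cos(ang), dy = 30 * sin(ang)))
  })
  cs <- transformCoimaged(small, res)
  prof <- radialProfile(cs, binWidth = 5, rMax = 130)
  expect_equal(which.max(prof@counts), 7L)  # the [30, 35) bin

  expect_error(transformCoimaged(small[-1], res), "particles")
})
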