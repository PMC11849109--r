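# Kinetic forward model and voxel-wise CBF/ATT estimation.

ks42 <- kineticConstants(t1b = t1BloodFromHct(0.42))

test_that("blood T1 follows the haematocrit relaxivity relation", {
  expect_equal(t1BloodFromHct(0.42), 1000 / (0.52 * 0.42 + 0.38))
  expect_equal(t1BloodFromHct(0.42), 1671, tolerance = 1e-3)
  expect_equal(t1BloodFromHct(0.35), 1779, tolerance = 1e-3)
  # higher haematocrit relaxes faster
  expect_true(t1BloodFromHct(0.35) > t1BloodFromHct(0.45))
  expect_error(t1BloodFromHct(0), "hct")
  expect_error(t1BloodFromHct(1), "hct")
})

test_that("pCASL signal is piecewise correct and continuous", {
  # pre-arrival: t = 573 + 700 = 1273 < att
  expect_identical(pcaslSignal(50, 1500, 573, 700, ks42), 0)
  # zero flow gives zero everywhere
  expect_equal(pcaslSignalSchedule(0, 1200, defaultSchedule(), ks42),
               rep(0, 6))
  # continuity at t = att and t = att + tau (vary pld across the boundary)
  att <- 1400; tau <- 573
  eps <- 1e-6
  for (tEdge in c(att, att + tau)) {
    lo <- pcaslSignal(50, att, tau, tEdge - tau - eps, ks42)
    hi <- pcaslSignal(50, att, tau, tEdge - tau + eps, ks42)
    expect_equal(lo, hi, tolerance = 1e-6)
  }
  # decays to zero at long delays, always non-negative
  expect_lt(pcaslSignal(50, 1400, 573, 50000, ks42), 1e-10)
  sig <- pcaslSignalSchedule(50, 1400, defaultSchedule(), ks42)
  expect_true(all(sig >= 0))
})

test_that("late-regime signal matches the single-PLD quantification form", {
  # For t >= att + tau the model must reduce to the standard white-paper
  # single-PLD expression, which is independent of ATT:
  # dM = 2 alpha (m0/lambda) f T1b (1 - exp(-tau/T1b)) exp(-pld/T1b)
  t1 <- bloodT1(ks42)
  for (tau in c(573, 885, 2024)) for (pld in c(2500, 3000)) {
    att <- 900   # att + tau <= tau + pld guaranteed here
    got <- pcaslSignal(50, att, tau, pld, ks42, m0 = 1000)
    want <- 2 * 0.85 * (1000 / 0.9) * (50 / 6000) * (t1 / 1000) *
      (1 - exp(-tau / t1)) * exp(-pld / t1)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("signal is linear in CBF and in M0", {
  sch <- defaultSchedule()
  base <- pcaslSignalSchedule(25, 1300, sch, ks42, m0 = 500)
  expect_equal(pcaslSignalSchedule(50, 1300, sch, ks42, m0 = 500), 2 * base)
  expect_equal(pcaslSignalSchedule(25, 1300, sch, ks42, m0 = 1000), 2 * base)
})

test_that("forward model matches 1-ms numerical integration of the bolus", {
  sch <- defaultSchedule()
  tau <- labelDurations(sch); pld <- postLabelDelays(sch)
  for (cbfV in c(20, 60)) for (attV in c(800, 1400, 2200)) {
    for (k in seq_along(tau)) {
      got <- pcaslSignal(cbfV, attV, tau[k], pld[k], ks42, m0 = 1)
      want <- oracleSignal(cbfV, attV, tau[k], pld[k],
                           t1b = bloodT1(ks42), m0 = 1)
      if (want > 0) expect_equal(got, want, tolerance = 1e-4)
      else expect_equal(got, 0)
    }
  }
})

test_that("noiseless voxel fit recovers the generating parameters", {
  sch <- defaultSchedule()
  y <- pcaslSignalSchedule(50, 1400, sch, ks42, m0 = 1000)
  fit <- fitVoxel(y, 1000, sch, ks42)
  expect_equal(cbf(fit), 50, tolerance = 1e-3)
  expect_equal(att(fit), 1400, tolerance = 1e-3)
  expect_true(converged(fit))
})

test_that("all-zero signals give zero CBF with ATT at the lower bound", {
  fit <- fitVoxel(rep(0, 6), 1000, defaultSchedule(), ks42)
  expect_equal(cbf(fit), 0)
  expect_equal(att(fit), 100)
  expect_false(converged(fit))
})

test_that("optimizer matches an exhaustive grid search", {
  sch <- defaultSchedule()
  set.seed(42)
  # truths drawn inside the bounds and within the identifiable ATT domain
  # (ATT above the minimum PLD; below it the late-time model is flat in ATT)
  for (r in 1:5) {
    cbfT <- round(runif(1, 10, 150))
    attT <- round(runif(1, 80, 260)) * 10
    y <- pcaslSignalSchedule(cbfT, attT, sch, ks42, m0 = 800)
    fit <- fitVoxel(y, 800, sch, ks42)
    gs <- gridSearchFit(y, 800, sch, ks42)
    expect_lte(abs(cbf(fit) - gs$cbf), 1)
    expect_lte(abs(att(fit) - gs$att), 10)
  }
})

test_that("fit input validation catches bad m0 and shape", {
  expect_error(fitVoxel(rep(1, 6), 0, defaultSchedule(), ks42), "m0")
  expect_error(fitVoxel(rep(1, 5), 1, defaultSchedule(), ks42), "schedule")
})

test_that("volume fitting fills masked voxels and NAs the rest", {
  co <- makeCohort(1, effectSlope = 0, seed = 3)
  sim <- simulateAslVolume(co, "S001", defaultSchedule(),
                           phantomSpec(dim = c(12L, 8L, 6L)))
  hct <- cohortSubjects(co)$hct[1]
  maps <- fitVolume(sim$asl, sim$m0, sim$mask, defaultSchedule(), hct)
  expect_true(all(is.na(maps$cbf[!sim$mask])))
  expect_true(all(!is.na(maps$cbf[sim$mask])))
  truth <- cohortTruth(co)
  for (terr in territoryNames()) {
    sel <- sim$parcellation == sim$labels[terr]
    tr <- truth[truth$territory == terr, ]
    expect_equal(unname(territoryMedian(maps$cbf, sel)), tr$cbf,
                 tolerance = 1e-4)
    if (tr$att > 750)    # below the minimum PLD, ATT is not identifiable
      expect_equal(unname(territoryMedian(maps$att, sel)), tr$att,
                   tolerance = 1e-3)
  }
  expect_error(fitVolume(sim$asl, sim$m0[-1, , ], sim$mask,
                         defaultSchedule(), hct), "shape")
})

test_that("territory median follows order-statistics conventions", {
  m <- array(c(42, 1, 2, 3, 4, 5, 10, 20, 30, 40, NA, 7), c(12, 1, 1))
  one <- array(FALSE, dim(m)); one[1, 1, 1] <- TRUE
  expect_equal(territoryMedian(m, one), 42)
  odd <- array(FALSE, dim(m)); odd[2:6, 1, 1] <- TRUE
  expect_equal(territoryMedian(m, odd), 3)
  even <- array(FALSE, dim(m)); even[7:10, 1, 1] <- TRUE
  expect_equal(territoryMedian(m, even), 25)   # mean of central pair
  nas <- array(FALSE, dim(m)); nas[11, 1, 1] <- TRUE
  expect_error(territoryMedian(m, nas), "empty")
})
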