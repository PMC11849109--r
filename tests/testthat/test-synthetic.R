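# Generators: cohorts, ASL volumes, susceptibility phantoms, traces.

test_that("cohort generation is a pure function of its seed", {
  a <- makeCohort(24, effectSlope = 13.2, seed = 7)
  b <- makeCohort(24, effectSlope = 13.2, seed = 7)
  expect_identical(cohortSubjects(a), cohortSubjects(b))
  expect_identical(cohortTruth(a), cohortTruth(b))
  expect_equal(nrow(cohortSubjects(a)), 24)
  expect_error(makeCohort(0), "n must be")
})

test_that("cohort invariants hold", {
  co <- makeCohort(50, seed = 2)
  subj <- cohortSubjects(co)
  truth <- cohortTruth(co)
  expect_true(all(subj$hct > 0 & subj$hct < 1))
  expect_true(all(subj$qrisk >= 5.1 & subj$qrisk <= 45.4))
  sa <- subj$sao2[match(truth$subject, subj$subject)]
  expect_true(all(truth$svo2 >= 0 & truth$svo2 < sa))
  expect_true(all(sa <= 1))
  expect_true(all(subj$moca >= 17 & subj$moca <= 30))
})

test_that("zero slope reduces truth ATT to baseline plus subject offset", {
  co <- makeCohort(1, effectSlope = 0, seed = 1)
  truth <- cohortTruth(co)
  base <- generatorParams(co)$attBaseline
  offs <- truth$att - base[match(truth$territory,
                                 territoryNames())]
  expect_lt(diff(range(offs)), 1e-9)   # one shared offset per subject
})

test_that("regression on generated truth recovers the ATT-QRisk slope", {
  co <- makeCohort(200, effectSlope = 13.2, seed = 3)
  d <- merge(cohortTruth(co), cohortSubjects(co)[, c("subject", "qrisk")])
  fit <- lm(att ~ qrisk + territory, data = d)
  slope <- coef(fit)[["qrisk"]]
  se <- summary(fit)$coefficients["qrisk", "Std. Error"]
  expect_lt(abs(slope - 13.2), 4 * max(se, 1))
})

test_that("noiseless ASL simulation equals the forward model voxel-wise", {
  co <- makeCohort(1, seed = 5)
  sch <- defaultSchedule()
  sim <- simulateAslVolume(co, "S001", sch, phantomSpec(dim = c(12L, 8L, 6L)))
  hct <- cohortSubjects(co)$hct[1]
  ks <- kineticConstants(t1b = t1BloodFromHct(hct))
  truth <- cohortTruth(co)
  for (terr in territoryNames()) {
    sel <- sim$parcellation == sim$labels[terr]
    tr <- truth[truth$territory == terr, ]
    want <- pcaslSignalSchedule(tr$cbf, tr$att, sch, ks, m0 = 1000)
    for (k in seq_len(length(sch))) {
      vol <- sim$asl[, , , k]
      expect_equal(unname(unique(vol[sel])), want[k], tolerance = 1e-12)
    }
  }
  expect_true(all(sim$m0[sim$mask] > 0))
})

test_that("ASL noise has the requested standard deviation", {
  co <- makeCohort(1, seed = 5)
  spec <- phantomSpec(dim = c(14L, 14L, 8L), noiseSd = 0.01, seed = 11L)
  sim <- simulateAslVolume(co, "S001", defaultSchedule(), spec)
  resid <- (sim$asl - sim$noiseless)[array(rep(sim$mask, 6), dim(sim$asl))]
  expect_gt(length(resid), 2000)
  expect_lt(abs(sd(resid) - 0.01 * 1000) / (0.01 * 1000), 0.05)
  # identical spec reproduces identical arrays
  sim2 <- simulateAslVolume(co, "S001", defaultSchedule(), spec)
  expect_identical(sim$asl, sim2$asl)
  expect_error(
    simulateAslVolume(co, "S001", defaultSchedule(), spec,
                      parcellation = array(9L, c(3, 3, 3))),
    "unknown territory label")
})

test_that("susceptibility phantom carries the forward core value", {
  spec <- phantomSpec(dim = c(15L, 15L, 8L), veinRadiusVox = 3)
  ph <- simulateSusceptibilityPhantom(0.60, 0.42, spec)
  expect_equal(ph$coreValue, susceptibilityFromSvo2(0.60, 0.42))
  expect_equal(ph$coreValue, 0.4117, tolerance = 1e-4)
  core <- ph$volumeFraction == 1
  expect_true(all(abs(ph$chi[core] - ph$coreValue) < 1e-12))
  # background is zero without noise
  expect_true(all(ph$chi[ph$volumeFraction == 0] == 0))
  # fully oxygenated vein is diamagnetic relative to CSF
  ph1 <- simulateSusceptibilityPhantom(1.0, 0.42, spec)
  expect_equal(ph1$coreValue, dchiHb(oximetryConstants("SI")) * 0.42)
  expect_lt(ph1$coreValue, 0)
  # determinism with noise
  specN <- phantomSpec(dim = c(15L, 15L, 8L), noiseSd = 0.01, seed = 3L)
  a <- simulateSusceptibilityPhantom(0.6, 0.42, specN)
  b <- simulateSusceptibilityPhantom(0.6, 0.42, specN)
  expect_identical(a$chi, b$chi)
  expect_error(simulateSusceptibilityPhantom(0.6, 0.42,
                                             phantomSpec(veinRadiusVox = -1)),
               "radius")
})

test_that("respiratory trace has exact plateaus and seeded jitter", {
  a <- simulateRespTrace(15.2, breaths = 8, seed = 1)
  b <- simulateRespTrace(15.2, breaths = 8, seed = 1)
  c <- simulateRespTrace(15.2, breaths = 8, seed = 2)
  expect_identical(o2Samples(a), o2Samples(b))
  # plateau samples exact under any seed; ramps differ between seeds
  expect_true(any(o2Samples(a) == 15.2))
  expect_identical(o2Samples(a) == 15.2, o2Samples(c) == 15.2)
  ramp <- o2Samples(a) != 15.2 & o2Samples(a) != 20.9
  expect_true(any(o2Samples(a)[ramp] != o2Samples(c)[ramp]))
  expect_error(simulateRespTrace(15.2, breaths = 2), "breaths")
  expect_error(simulateRespTrace(22, breaths = 5), "etPercent")
})

test_that("session tables carry noise at the reference CoV scale", {
  co <- makeCohort(40, seed = 6)
  tab <- simulateSessionTable(co, sessions = 2, seed = 8)
  expect_equal(nrow(tab), 40 * 2 * 5)
  # noiseless tables reproduce the truth exactly
  tab0 <- simulateSessionTable(co, sessions = 1, seed = 8, noiseScale = 0)
  truth <- cohortTruth(co)
  expect_equal(tab0$att, truth$att, tolerance = 1e-12)
  expect_equal(tab0$cbf, truth$cbf, tolerance = 1e-12)
  # test-retest CoV of ATT lands near its generating level per territory
  rep <- repeatabilityTable(tab, parameters = "att")
  ref <- generatorParams(co)$reference
  for (i in seq_len(nrow(rep))) {
    want <- ref$attCov[match(rep$territory[i], ref$territories)]
    expect_lt(abs(rep$cov[i] - want), 0.6 * want)
  }
})
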