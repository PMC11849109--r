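# Arterial oxygenation: end-tidal extraction, Severinghaus, OEF, CMRO2.

test_that("end-tidal extraction finds expiratory plateaus", {
  tr <- simulateRespTrace(15.2, breaths = 20, seed = 4)
  et <- endTidalValues(tr)
  expect_equal(et$median, 15.2)
  expect_equal(length(et$values), 20)
  # exactly three plateaus for three breaths
  tr3 <- simulateRespTrace(15.2, breaths = 3, seed = 1)
  expect_equal(length(endTidalValues(tr3)$values), 3)
  # constant trace has no extrema
  flat <- respiratoryTrace(rep(16, 200), samplingHz = 10)
  expect_error(endTidalValues(flat), "insufficient breaths")
  # varying plateau levels: odd-count median
  tr5 <- manualTrace(c(14.8, 15.2, 15.6))
  et5 <- endTidalValues(tr5)
  expect_equal(sort(et5$values), c(14.8, 15.2, 15.6))
  expect_equal(et5$median, 15.2)
})

test_that("raw-peak mode picks inspiratory maxima instead", {
  tr <- simulateRespTrace(15.0, breaths = 6, seed = 2, jitterSd = 0)
  pk <- endTidalValues(tr, mode = "peaks")
  expect_true(all(pk$values > 20))
})

test_that("percent to partial-pressure bridge is linear dry-gas scaling", {
  expect_equal(etPercentToPo2(15.2), 108.376)
  expect_equal(etPercentToPo2(0.1), 0.713)
  expect_equal(etPercentToPo2(10), 2 * etPercentToPo2(5))
  expect_error(etPercentToPo2(15, barometric = 40, waterVapour = 47),
               "exceed")
  expect_error(etPercentToPo2(0), "etO2")
})

test_that("Severinghaus curve is correct, increasing and bounded", {
  expect_equal(severinghausSao2(100), 1 / (1 + 23400 / (1e6 + 15000)))
  expect_equal(severinghausSao2(100), 0.9775, tolerance = 1e-4)
  expect_equal(severinghausSao2(108.4), 0.9822, tolerance = 1e-4)
  po2 <- seq(1, 600, by = 0.5)
  s <- severinghausSao2(po2)
  expect_true(all(diff(s) > 0))
  expect_true(all(s < 1))
  expect_gt(severinghausSao2(1e5), 0.999999)
  expect_error(severinghausSao2(0), "po2")
})

test_that("arterial oxygen content follows Hb = Hct/3 and 55.6 umol/g", {
  c42 <- arterialO2Content(0.42)
  expect_equal(c42$hb, 14.0)
  expect_equal(c42$o2a, 778.4)
  c36 <- arterialO2Content(0.36)
  expect_equal(c36$hb, 12.0)
  expect_equal(c36$o2a, 667.2)
  expect_lt(arterialO2Content(1e-6)$o2a, 0.01)
  expect_error(arterialO2Content(1.2), "hct")
})

test_that("OEF arithmetic, bounds and negative flag", {
  expect_equal(as.numeric(computeOef(0.9, 0.9)), 0)
  expect_equal(as.numeric(computeOef(0.977, 0.601)), 0.385, tolerance = 1e-3)
  expect_equal(as.numeric(computeOef(0.95, 0)), 1)
  expect_warning(neg <- computeOef(0.6, 0.7), "negative")
  expect_lt(as.numeric(neg), 0)
  expect_true(attr(neg, "negative"))
  expect_error(computeOef(0, 0.5), "sao2")
})

test_that("OEF and SvO2 are mutual inverses", {
  sa <- 0.98
  for (sv in c(0.2, 0.55, 0.9)) {
    oef <- as.numeric(computeOef(sa, sv))
    expect_equal(sa * (1 - oef), sv, tolerance = 1e-12)
  }
})

test_that("CMRO2 units and linearity", {
  expect_equal(computeCmro2(43.0, 778.4, 0.427), 142.9, tolerance = 1e-3)
  expect_equal(computeCmro2(43.0, 778.4, 0), 0)
  expect_equal(computeCmro2(86.0, 778.4, 0.427),
               2 * computeCmro2(43.0, 778.4, 0.427))
  expect_error(computeCmro2(-1, 778.4, 0.4), ">= 0")
})

test_that("arterialOxygen chains trace to content consistently", {
  tr <- simulateRespTrace(15.2, breaths = 10, seed = 3)
  ao <- arterialOxygen(tr, hct = 0.42)
  expect_equal(ao@etO2, 15.2)
  expect_equal(ao@petO2, etPercentToPo2(15.2))
  expect_equal(sao2(ao), severinghausSao2(etPercentToPo2(15.2)))
  expect_equal(o2Content(ao), 778.4)
})
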