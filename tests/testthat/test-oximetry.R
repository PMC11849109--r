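# QSM venous oximetry: mask erosion, ROI refinement, percentile
# extraction, susceptibility-to-SvO2 inversion.

test_that("one erosion pass matches brute-force 6-connected morphology", {
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  got <- erodeBrainMask(cube)
  expect_identical(got, bruteErode(cube))
  expect_equal(sum(got), 1)        # 3x3x3 solid cube -> single centre voxel
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_equal(sum(erodeBrainMask(single)), 0)
  # two passes strictly shrink a 5^3 cube to its centre voxel
  big <- array(TRUE, c(7, 7, 7))
  inner5 <- array(FALSE, c(7, 7, 7)); inner5[2:6, 2:6, 2:6] <- TRUE
  twice <- erodeBrainMask(erodeBrainMask(inner5))
  expect_identical(twice, bruteErode(bruteErode(inner5)))
  expect_equal(sum(twice), 1)
  # random masks agree with the oracle
  set.seed(9)
  for (r in 1:3) {
    m <- array(runif(6 * 6 * 6) > 0.4, c(6, 6, 6))
    if (!any(m)) next
    expect_identical(erodeBrainMask(m), bruteErode(m))
  }
  expect_error(erodeBrainMask(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("ROI refinement keeps values inside [130, 1000] ppb inclusive", {
  vals <- c(0, 50, 140, 200, 500, 999, 1000, 1200) / 1000   # ppm
  chi <- array(vals, c(8, 1, 1))
  seed <- array(TRUE, c(8, 1, 1))
  kept <- refineVeinRoi(seed, chi)
  expect_equal(sum(kept), 5)
  expect_equal(sort(chi[kept] * 1000), c(140, 200, 500, 999, 1000))
  expect_error(refineVeinRoi(seed, array(0.05, c(8, 1, 1))), "empty")
  allIn <- refineVeinRoi(seed, array(0.5, c(8, 1, 1)))
  expect_equal(sum(allIn), 8)
})

test_that("vein susceptibility is the interpolated 90th percentile", {
  chi <- array(c(140, 200, 500, 999, 1000) / 1000, c(5, 1, 1))
  roi <- array(TRUE, c(5, 1, 1))
  expect_equal(veinSusceptibility(roi, chi), 0.9996)   # rank 3.6 interp
  expect_equal(veinSusceptibility(roi, array(0.5, c(5, 1, 1))), 0.5)
  one <- array(FALSE, c(5, 1, 1)); one[1, 1, 1] <- TRUE
  expect_equal(veinSusceptibility(one, array(0.410, c(5, 1, 1))), 0.410)
  # zeros are excluded before the percentile
  chi0 <- array(c(0, 0, 0, 0, 0.4), c(5, 1, 1))
  expect_equal(veinSusceptibility(roi, chi0), 0.4)
  expect_error(veinSusceptibility(roi, array(0, c(5, 1, 1))), "empty")
})

test_that("SvO2 inversion matches the susceptibility relation", {
  oc <- oximetryConstants("SI")
  # fully oxygenated boundary: dchi = dchiHb * hct  =>  svo2 = 1
  expect_equal(as.numeric(svo2FromSusceptibility(dchiHb(oc) * 0.42, 0.42, oc)),
               1)
  # spec-level worked value
  s <- svo2FromSusceptibility(0.410, 0.42, oc)
  expect_equal(as.numeric(s), 0.601, tolerance = 1e-3)
  expect_false(any(attr(s, "clamped")))
  # round trip at machine precision
  fwd <- susceptibilityFromSvo2(0.35, 0.42, oc)
  expect_equal(as.numeric(svo2FromSusceptibility(fwd, 0.42, oc)), 0.35,
               tolerance = 1e-12)
  # strictly decreasing in dchi
  dchis <- seq(0.1, 1.2, by = 0.05)
  ss <- as.numeric(svo2FromSusceptibility(dchis, 0.42, oc))
  expect_true(all(diff(ss[ss > 0 & ss < 1]) < 0))
  # clamping is flagged
  cl <- svo2FromSusceptibility(5, 0.42, oc)
  expect_equal(as.numeric(cl), 0)
  expect_true(any(attr(cl, "clamped")))
  expect_error(svo2FromSusceptibility(0.4, 0, oc), "hct")
})

test_that("cgs and SI conventions agree when map units match", {
  si <- oximetryConstants("SI")
  cgs <- oximetryConstants("cgs")
  expect_equal(dchi0(si), 4 * pi * dchi0(cgs), tolerance = 1e-12)
  chiSi <- susceptibilityFromSvo2(0.62, 0.40, si)
  chiCgs <- susceptibilityFromSvo2(0.62, 0.40, cgs)
  expect_equal(chiSi, 4 * pi * chiCgs, tolerance = 1e-12)
  expect_equal(as.numeric(svo2FromSusceptibility(chiSi, 0.40, si)),
               as.numeric(svo2FromSusceptibility(chiCgs, 0.40, cgs)),
               tolerance = 1e-12)
})

test_that("phantom chain recovers the generating SvO2", {
  spec <- phantomSpec(dim = c(15L, 15L, 10L), veinRadiusVox = 3)
  ph <- simulateSusceptibilityPhantom(0.60, 0.42, spec)
  # core-only seed: exact recovery
  core <- ph$volumeFraction == 1
  vm <- measureVein("SS", core, ph$chi, 0.42)
  expect_equal(svo2(vm), 0.60, tolerance = 1e-10)
  # dilated seed with partial-volume edges: within the stated tolerance
  vm2 <- measureVein("SS", ph$seedRoi, ph$chi, 0.42)
  expect_lt(abs(svo2(vm2) - 0.60), 0.02)
  expect_true(nVoxels(vm2) >= nVoxels(vm))
})
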