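# Synthetic cohorts, phantoms and traces with the statistical structure the
# analysis assumes, so every stage is testable without acquired data.

# Regional reference values used to seed the generators: per-territory means,
# standard errors (n = 24) and test-retest CoVs for OEF (%), CBF
# (ml/100 ml/min) and ATT (ms), ordered as territoryNames().
.regionalReference <- function() {
  list(
    territories = territoryNames(),
    oefMean = c(42.7, 44.5, 46.5, 34.9, 37.7),
    cbfMean = c(43.0, 44.2, 34.4, 39.6, 36.2),
    attMean = c(1592, 1497, 1399, 1102, 1183),
    oefSe = c(0.7, 0.9, 0.8, 0.8, 0.8),
    cbfSe = c(1.9, 2.0, 1.4, 1.8, 1.7),
    attSe = c(50.1, 50.5, 48.6, 46.0, 47.6),
    oefCov = c(3.6, 4.9, 6.3, 5.8, 8.1),
    cbfCov = c(13.0, 14.1, 7.9, 10.6, 10.3),
    attCov = c(5.1, 7.1, 7.1, 6.7, 6.4),
    nRef = 24,
    qriskRange = c(5.1, 45.4))
}

#' @rdname PhantomSpec
#' @export
setClass("PhantomSpec",
         representation(dim = "integer", voxelSizeMm = "numeric",
                        veinRadiusVox = "numeric", veinAxis = "numeric",
                        noiseSd = "numeric", seed = "integer"),
         validity = function(object) {
           if (length(object@dim) != 3 || any(object@dim < 3))
             return("dim must be three voxel counts >= 3")
           if (object@veinRadiusVox <= 0)
             return("vein radius must be > 0 voxels")
           if (length(object@veinAxis) != 3 ||
               abs(sqrt(sum(object@veinAxis^2)) - 1) > 1e-8)
             return("veinAxis must be a 3-D unit vector")
           if (object@noiseSd < 0) return("noiseSd must be >= 0")
           TRUE
         })

#' Phantom geometry and noise specification
#'
#' Grid shape, voxel size, vein cylinder radius and axis, noise level and
#' seed.  The seed fully determines the generated arrays: identical specs
#' give identical phantoms.
#'
#' @param dim Integer voxel counts (x, y, z).
#' @param voxelSizeMm Isotropic voxel size in mm.
#' @param veinRadiusVox Cylinder radius in voxels (> 0).
#' @param veinAxis Unit vector of the cylinder axis.
#' @param noiseSd Noise standard deviation, in the units of the field it
#'   perturbs (fraction of M0 for ASL, ppm for susceptibility).
#' @param seed Integer seed.
#' @return A \code{PhantomSpec}.
#' @export
phantomSpec <- function(dim = c(12L, 12L, 10L), voxelSizeMm = 1,
                        veinRadiusVox = 3, veinAxis = c(0, 0, 1),
                        noiseSd = 0, seed = 1L) {
  new("PhantomSpec", dim = as.integer(dim), voxelSizeMm = voxelSizeMm,
      veinRadiusVox = veinRadiusVox,
      veinAxis = veinAxis / sqrt(sum(veinAxis^2)),
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' @rdname PhantomSpec
#' @param object A \code{PhantomSpec}.
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %g mm, vein r=%g vox, noiseSd=%g, seed=%d\n",
              paste(object@dim, collapse = "x"), object@voxelSizeMm,
              object@veinRadiusVox, object@noiseSd, object@seed))
})

#' Generate a synthetic cohort with ground truth
#'
#' Draws \code{n} subjects with QRisk scores uniform on the observed range
#' [5.1, 45.4], haematocrit, MoCA, amyloid status and an end-tidal O2
#' level, plus per-territory ground-truth CBF, ATT and SvO2.  Territory
#' means are seeded from the regional reference table; a shared Gaussian
#' subject offset per parameter (sd = reference standard error x sqrt(24),
#' for ATT reduced by the variance the QRisk term itself contributes)
#' creates between-subject spread, and truth ATT follows
#' \code{baseline + effectSlope * qrisk + offset}, with baselines centred
#' so the expected territory means match the reference values.
#'
#' @param n Number of subjects (>= 1).
#' @param effectSlope ATT increase per QRisk point, ms (default 13.2).
#' @param seed Integer seed; fully determines the cohort.
#' @param offsetScale Multiplier on the subject-offset standard deviations
#'   (default 1); 0 gives a deterministic cohort whose only
#'   between-subject variation is the QRisk effect itself.
#' @return A \code{\link{CohortTruth}}.
#' @examples
#' makeCohort(5, seed = 7)
#' @export
makeCohort <- function(n, effectSlope = 13.2, seed = 1L, offsetScale = 1) {
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("n must be >= 1")
  n <- as.integer(n)
  ref <- .regionalReference()
  set.seed(seed)
  qr <- ref$qriskRange
  qrisk <- stats::runif(n, qr[1], qr[2])
  hct <- pmin(pmax(stats::rnorm(n, 0.42, 0.034), 0.30), 0.55)
  moca <- sample(17:30, n, replace = TRUE)
  amyloid <- stats::rbinom(n, 1, 7 / 24) == 1
  etO2 <- stats::runif(n, 14, 17)
  sao2Truth <- severinghausSao2(etPercentToPo2(etO2))

  sdScale <- sqrt(ref$nRef)
  qVar <- diff(qr)^2 / 12
  sdAttOff <- offsetScale * sqrt(max(0, (mean(ref$attSe) * sdScale)^2 -
                                       effectSlope^2 * qVar))
  sdCbfOff <- offsetScale * mean(ref$cbfSe) * sdScale
  sdOefOff <- offsetScale * mean(ref$oefSe) * sdScale
  offAtt <- stats::rnorm(n, 0, sdAttOff)
  offCbf <- stats::rnorm(n, 0, sdCbfOff)
  offOef <- stats::rnorm(n, 0, sdOefOff)

  qCentre <- mean(qr)
  terr <- ref$territories
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    attTruth <- ref$attMean - effectSlope * qCentre +
      effectSlope * qrisk[i] + offAtt[i]
    cbfTruth <- pmax(ref$cbfMean + offCbf[i], 5)
    oefTruth <- pmin(pmax(ref$oefMean + offOef[i], 10), 70) / 100
    data.frame(subject = sprintf("S%03d", i), territory = terr,
               cbf = cbfTruth, att = pmin(pmax(attTruth, 300), 3400),
               svo2 = pmin(pmax(sao2Truth[i] * (1 - oefTruth), 0.2),
                           sao2Truth[i] - 0.01),
               stringsAsFactors = FALSE)
  }))
  subjects <- data.frame(subject = sprintf("S%03d", seq_len(n)),
                         hct = hct, qrisk = qrisk, moca = moca,
                         amyloid = amyloid, etO2 = etO2, sao2 = sao2Truth,
                         stringsAsFactors = FALSE)
  new("CohortTruth", subjects = subjects, truth = truth,
      params = list(effectSlope = effectSlope, seed = seed,
                    attBaseline = ref$attMean - effectSlope * qCentre,
                    sdAttOff = sdAttOff, sdCbfOff = sdCbfOff,
                    sdOefOff = sdOefOff, reference = ref))
}

# Slab parcellation of a phantom grid: territories stacked along x, one
# integer label per territory in atlas order; a one-voxel border is
# background (label 0).
.slabParcellation <- function(dim, nTerr = 5L) {
  parc <- array(0L, dim)
  inner <- (dim[1] - 2L)
  cut <- floor(seq(1, inner + 1, length.out = nTerr + 1))
  for (j in seq_len(nTerr)) {
    xs <- (1L + cut[j]):(cut[j + 1])
    parc[xs, 2:(dim[2] - 1), 2:(dim[3] - 1)] <- j
  }
  parc
}

#' Simulate a multi-delay ASL acquisition for one subject
#'
#' Builds a slab parcellation phantom (one slab per territory, label i for
#' the i-th entry of \code{territoryNames()}, background 0), evaluates the
#' kinetic forward model at each voxel's territory truth and adds
#' independent Gaussian noise of sd \code{noiseSd x M0} to the difference
#' signals.  M0 is constant and positive inside the brain.
#'
#' @param cohort A \code{\link{CohortTruth}}.
#' @param subject Subject identifier present in the cohort.
#' @param schedule An \code{\link{acquisitionSchedule}}.
#' @param spec A \code{\link{phantomSpec}}; \code{noiseSd} is interpreted
#'   as a fraction of M0.
#' @param parcellation Optional integer label volume to use instead of the
#'   built-in slabs; labels must index \code{territoryNames()}.
#' @param m0Value M0 inside the brain (signal units), default 1000.
#' @return List with \code{asl} (4-D array), \code{m0}, \code{mask},
#'   \code{parcellation}, \code{labels} (named territory -> label) and
#'   \code{noiseless} (the noise-free 4-D signals).
#' @export
simulateAslVolume <- function(cohort, subject, schedule,
                              spec = phantomSpec(), parcellation = NULL,
                              m0Value = 1000) {
  truth <- cohortTruth(cohort)
  truth <- truth[truth$subject == subject, ]
  if (nrow(truth) == 0) stop("unknown subject: ", subject)
  hct <- cohortSubjects(cohort)$hct[cohortSubjects(cohort)$subject == subject]
  terr <- territoryNames()
  if (is.null(parcellation))
    parcellation <- .slabParcellation(spec@dim, length(terr))
  labs <- sort(unique(parcellation[parcellation != 0]))
  if (any(!labs %in% seq_along(terr)))
    stop("unknown territory label in parcellation: ",
         paste(setdiff(labs, seq_along(terr)), collapse = ", "))
  constants <- kineticConstants(t1b = t1BloodFromHct(hct))
  d <- dim(parcellation)
  nd <- length(schedule)
  mask <- parcellation > 0
  m0 <- array(0, d); m0[mask] <- m0Value
  noiseless <- array(0, c(d, nd))
  for (lab in labs) {
    row <- truth[match(terr[lab], truth$territory), ]
    sig <- pcaslSignalSchedule(row$cbf, row$att, schedule, constants,
                               m0 = m0Value)
    sel <- parcellation == lab
    for (k in seq_len(nd)) {
      vol <- noiseless[, , , k]
      vol[sel] <- sig[k]
      noiseless[, , , k] <- vol
    }
  }
  asl <- noiseless
  if (spec@noiseSd > 0) {
    set.seed(spec@seed)
    noise <- array(stats::rnorm(length(asl), 0, spec@noiseSd * m0Value),
                   dim(asl))
    maskRep <- array(rep(mask, nd), dim(asl))
    asl <- asl + noise * maskRep
  }
  list(asl = asl, m0 = m0, mask = mask, parcellation = parcellation,
       labels = stats::setNames(seq_along(terr), terr),
       noiseless = noiseless)
}

# Perpendicular distance of each voxel centre from a line through `centre`
# along unit vector `axis`.
.cylinderDistance <- function(dim, centre, axis) {
  g <- expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                   z = seq_len(dim[3]))
  p <- sweep(as.matrix(g), 2, centre)
  proj <- as.numeric(p %*% axis)
  perp <- p - outer(proj, axis)
  array(sqrt(rowSums(perp^2)), dim)
}

#' Simulate a cylindrical vein susceptibility phantom
#'
#' A cylinder along \code{spec@veinAxis} through the grid centre carries
#' the forward susceptibility of the given SvO2 and haematocrit
#' (CSF-referenced, in the unit system of \code{constants}); edge voxels
#' are blended linearly by occupied volume fraction to mimic partial
#' volume, the background is 0, and optional Gaussian noise of sd
#' \code{spec@noiseSd} ppm is added everywhere.
#'
#' @param svo2 Generating venous saturation in [0, 1].
#' @param hct Haematocrit fraction.
#' @param spec A \code{\link{phantomSpec}} (noiseSd in ppm).
#' @param constants An \code{\link{oximetryConstants}}.
#' @param centreOffset Optional (x, y) offset of the cylinder centre in
#'   voxels, for multi-vein volumes.
#' @return List with \code{chi} (ppm), \code{brainMask}, \code{seedRoi}
#'   (cylinder dilated by 1.5 voxels), \code{coreValue} (ppm) and
#'   \code{volumeFraction} (the per-voxel blend fraction).
#' @export
simulateSusceptibilityPhantom <- function(svo2, hct, spec = phantomSpec(),
                                          constants = oximetryConstants("SI"),
                                          centreOffset = c(0, 0)) {
  if (svo2 < 0 || svo2 > 1) stop("svo2 must lie in [0, 1]")
  d <- spec@dim
  core <- susceptibilityFromSvo2(svo2, hct, constants)
  centre <- (d + 1) / 2
  centre[1:2] <- centre[1:2] + centreOffset
  dist <- .cylinderDistance(d, centre, spec@veinAxis)
  r <- spec@veinRadiusVox
  frac <- pmin(pmax(r + 0.5 - dist, 0), 1)
  chi <- frac * core
  if (spec@noiseSd > 0) {
    set.seed(spec@seed)
    chi <- chi + array(stats::rnorm(length(chi), 0, spec@noiseSd), d)
  }
  brainMask <- array(FALSE, d)
  brainMask[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE
  list(chi = chi, brainMask = brainMask, seedRoi = dist <= r + 1.5,
       coreValue = core, volumeFraction = frac)
}

#' Simulate an exhaled-oxygen trace
#'
#' Trapezoidal breaths: an inspiratory plateau at the inspired fraction
#' (~20.9%), a linear expiratory down-ramp, an end-expiratory plateau at
#' exactly \code{etPercent}, and an inspiratory up-ramp.  Seeded Gaussian
#' jitter perturbs the ramps only, so the plateau sample values equal
#' \code{etPercent} exactly and the seed changes jitter but never plateau
#' values.
#'
#' @param etPercent End-tidal O2 plateau value, percent in (0, 21).
#' @param breaths Number of breaths (>= 3; end-tidal extraction needs
#'   multiple cycles).
#' @param samplingHz Sampling rate (default 10 Hz).
#' @param seed Integer seed for the ramp jitter.
#' @param inspiredPercent Inspiratory plateau (default 20.9, room air).
#' @param breathPeriodS Breath period in seconds (default 4).
#' @param jitterSd Ramp jitter sd in percent O2 (default 0.05).
#' @return A \code{\link{respiratoryTrace}}.
#' @export
simulateRespTrace <- function(etPercent, breaths, samplingHz = 10,
                              seed = 1L, inspiredPercent = 20.9,
                              breathPeriodS = 4, jitterSd = 0.05) {
  if (etPercent <= 0 || etPercent >= 21)
    stop("etPercent must lie strictly between 0 and 21")
  if (breaths < 3)
    stop("breaths must be >= 3: end-tidal extraction needs multiple cycles")
  nPer <- round(breathPeriodS * samplingHz)
  nIn <- max(2L, round(0.25 * nPer))
  nDown <- max(2L, round(0.20 * nPer))
  nEt <- max(2L, round(0.30 * nPer))
  nUp <- max(2L, nPer - nIn - nDown - nEt)
  down <- seq(inspiredPercent, etPercent,
              length.out = nDown + 2)[2:(nDown + 1)]
  up <- seq(etPercent, inspiredPercent,
            length.out = nUp + 2)[2:(nUp + 1)]
  breath <- c(rep(inspiredPercent, nIn), down, rep(etPercent, nEt), up)
  samples <- c(rep(breath, breaths), rep(inspiredPercent, nIn))
  rampIdx <- which(samples != inspiredPercent & samples != etPercent)
  set.seed(seed)
  samples[rampIdx] <- pmin(pmax(
    samples[rampIdx] + stats::rnorm(length(rampIdx), 0, jitterSd), 0), 25)
  respiratoryTrace(samples, samplingHz)
}

#' Toy atlas matching the phantom slab parcellation
#'
#' Each vein maps to one slab label (1-5 in \code{territoryNames()}
#' order), with the standard composition rules (SS pools ICVs and BVs;
#' SSS V pools SSS H).
#'
#' @return A \code{\link{veinTerritoryAtlas}}.
#' @export
phantomAtlas <- function() {
  terr <- territoryNames()
  veinTerritoryAtlas(stats::setNames(as.list(seq_along(terr)), terr))
}

#' Simulate the full set of per-subject pipeline inputs
#'
#' One ASL phantom (with its slab parcellation), a single susceptibility
#' volume holding five parallel vein cylinders (one per territory, each at
#' the subject's territory SvO2 truth) with named seed ROIs, the
#' respiratory trace at the subject's end-tidal truth, and the
#' haematocrit.  This is the complete input of \code{\link{runSubject}}.
#'
#' @param cohort A \code{\link{CohortTruth}}.
#' @param subject Subject identifier.
#' @param schedule An \code{\link{acquisitionSchedule}}.
#' @param aslSpec \code{\link{phantomSpec}} for the ASL phantom.
#' @param veinRadiusVox Vein cylinder radius in voxels.
#' @param constants \code{\link{oximetryConstants}} for the map.
#' @param session Session label stored with the inputs (default 1).
#' @param seed Seed for trace jitter and ASL noise.
#' @return Named list of pipeline inputs.
#' @export
simulateSubjectInputs <- function(cohort, subject,
                                  schedule = defaultSchedule(),
                                  aslSpec = phantomSpec(dim = c(17L, 8L, 8L)),
                                  veinRadiusVox = 3,
                                  constants = oximetryConstants("SI"),
                                  session = 1L, seed = 1L) {
  subjects <- cohortSubjects(cohort)
  i <- match(subject, subjects$subject)
  if (is.na(i)) stop("unknown subject: ", subject)
  truth <- cohortTruth(cohort)
  truth <- truth[truth$subject == subject, ]
  aslSpec@seed <- as.integer(seed)
  aslSim <- simulateAslVolume(cohort, subject, schedule, aslSpec)

  terr <- territoryNames()
  spacing <- ceiling(2 * (veinRadiusVox + 1.5)) + 1
  d <- c(spacing * length(terr) + 2L, 2L * ceiling(veinRadiusVox + 3.5),
         10L)
  chi <- array(0, d)
  seeds <- list()
  vSpec <- phantomSpec(dim = d, veinRadiusVox = veinRadiusVox)
  for (j in seq_along(terr)) {
    off <- (j - 0.5) * spacing + 1 - (d[1] + 1) / 2
    ph <- simulateSusceptibilityPhantom(truth$svo2[match(terr[j],
                                                         truth$territory)],
                                        subjects$hct[i], vSpec, constants,
                                        centreOffset = c(off, 0))
    chi <- chi + ph$chi
    seeds[[terr[j]]] <- ph$seedRoi
  }
  brainMask <- array(FALSE, d)
  brainMask[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- TRUE

  trace <- simulateRespTrace(subjects$etO2[i], breaths = 12, seed = seed)
  list(subject = subject, session = session, hct = subjects$hct[i],
       asl = aslSim$asl, m0 = aslSim$m0, aslMask = aslSim$mask,
       parcellation = aslSim$parcellation,
       chi = chi, brainMask = brainMask, veinSeeds = seeds,
       respTrace = trace)
}

#' Simulate session measurement tables from cohort truth
#'
#' Adds per-session measurement noise to the ground truth at the scale of
#' the reference test-retest CoVs (per territory: CBF and ATT noise sd =
#' CoV/100 x reference mean; SvO2 noise sd = OEF CoV/100 x (SaO2 - SvO2))
#' and assembles the regional table rows (one per subject, session and
#' territory) with OEF and CMRO2 recomputed from the noisy components.
#' OEF is not clamped, preserving noise structure.
#'
#' @param cohort A \code{\link{CohortTruth}}.
#' @param sessions Number of sessions (default 2).
#' @param seed Integer seed.
#' @param noiseScale Multiplier on all noise sds (0 = noiseless truth).
#' @return Data frame with columns subject, session, territory, oef, cbf,
#'   att, cmro2, qrisk, hct.
#' @export
simulateSessionTable <- function(cohort, sessions = 2L, seed = 1L,
                                 noiseScale = 1) {
  ref <- generatorParams(cohort)$reference
  subjects <- cohortSubjects(cohort)
  truth <- cohortTruth(cohort)
  j <- match(truth$territory, ref$territories)
  i <- match(truth$subject, subjects$subject)
  sdCbf <- ref$cbfCov[j] / 100 * ref$cbfMean[j] * noiseScale
  sdAtt <- ref$attCov[j] / 100 * ref$attMean[j] * noiseScale
  sdSvo2 <- ref$oefCov[j] / 100 * (subjects$sao2[i] - truth$svo2) * noiseScale
  o2a <- arterialO2Content(subjects$hct)$o2a
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(sessions), function(s) {
    cbfM <- truth$cbf + stats::rnorm(nrow(truth), 0, sdCbf)
    attM <- truth$att + stats::rnorm(nrow(truth), 0, sdAtt)
    svo2M <- truth$svo2 + stats::rnorm(nrow(truth), 0, sdSvo2)
    oefM <- (subjects$sao2[i] - svo2M) / subjects$sao2[i]
    data.frame(subject = truth$subject, session = s,
               territory = truth$territory, oef = oefM, cbf = cbfM,
               att = attM, cmro2 = cbfM * (o2a[i] / 100) * oefM,
               qrisk = subjects$qrisk[i], hct = subjects$hct[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
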