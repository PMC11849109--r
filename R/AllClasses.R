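#' @import methods
NULL

#' Names of the venous drainage territories
#'
#' The five large cerebral veins whose drainage territories carry the
#' regional analysis: the vertical (SSS V) and horizontal (SSS H) segments
#' of the superior sagittal sinus, the straight sinus (SS), the basal veins
#' (BVs) and the internal cerebral veins (ICVs).  Sylvian and tentorial
#' territories are excluded because of susceptibility artefacts and
#' variable anatomy.
#'
#' @return Character vector of length 5.
#' @export
territoryNames <- function() c("SSS V", "SSS H", "SS", "BVs", "ICVs")

# ---------------------------------------------------------------------------
# AcquisitionSchedule

#' @rdname AcquisitionSchedule
#' @export
setClass("AcquisitionSchedule",
         representation(tau = "numeric", pld = "numeric"),
         validity = function(object) {
           if (length(object@tau) != length(object@pld))
             return("tau and pld must have equal length")
           if (length(object@tau) == 0)
             return("schedule must contain at least one (tau, pld) pair")
           if (any(!is.finite(object@tau)) || any(!is.finite(object@pld)))
             return("tau and pld must be finite")
           if (any(object@tau <= 0) || any(object@pld <= 0))
             return("all label durations and post-label delays must be > 0")
           t <- object@tau + object@pld
           if (anyDuplicated(t))
             return("measurement times tau + pld must be distinct")
           TRUE
         })

#' Multi-delay pCASL acquisition schedule
#'
#' A paired grid of label durations (tau) and post-label delays (PLD), both
#' in milliseconds.  The kinetic model is sampled at measurement times
#' \eqn{t = \tau + w} from label onset.
#'
#' @param tau Numeric vector of label durations in ms (> 0).
#' @param pld Numeric vector of post-label delays in ms (> 0), same length.
#' @return An \code{AcquisitionSchedule} object.
#' @examples
#' acquisitionSchedule(tau = c(573, 885, 2024), pld = c(700, 1297, 2158))
#' @export
acquisitionSchedule <- function(tau, pld) {
  new("AcquisitionSchedule", tau = as.numeric(tau), pld = as.numeric(pld))
}

#' Default six-point schedule
#'
#' Union of the two three-delay acquisitions fitted jointly: PLDs
#' (700, 1297, 2158) ms and (1000, 1573, 2024) ms, each with label
#' durations (573, 885, 2024) ms paired index-wise ascending (longer PLDs
#' get longer label durations, approximately equalising signal per delay).
#'
#' @return An \code{AcquisitionSchedule} with six (tau, pld) pairs.
#' @export
defaultSchedule <- function() {
  acquisitionSchedule(tau = c(573, 885, 2024, 573, 885, 2024),
                      pld = c(700, 1297, 2158, 1000, 1573, 2024))
}

#' @describeIn AcquisitionSchedule label durations (ms)
#' @export
setGeneric("labelDurations", function(x) standardGeneric("labelDurations"))
#' @describeIn AcquisitionSchedule post-label delays (ms)
#' @export
setGeneric("postLabelDelays", function(x) standardGeneric("postLabelDelays"))
#' @describeIn AcquisitionSchedule measurement times tau + pld (ms)
#' @export
setGeneric("measurementTimes", function(x) standardGeneric("measurementTimes"))

#' @rdname AcquisitionSchedule
setMethod("labelDurations", "AcquisitionSchedule", function(x) x@tau)
#' @rdname AcquisitionSchedule
setMethod("postLabelDelays", "AcquisitionSchedule", function(x) x@pld)
#' @rdname AcquisitionSchedule
setMethod("measurementTimes", "AcquisitionSchedule", function(x) x@tau + x@pld)
#' @rdname AcquisitionSchedule
#' @param object An \code{AcquisitionSchedule}.
setMethod("show", "AcquisitionSchedule", function(object) {
  cat("AcquisitionSchedule with", length(object@tau), "delays\n")
  print(data.frame(tau_ms = object@tau, pld_ms = object@pld,
                   t_ms = object@tau + object@pld))
})

#' @rdname AcquisitionSchedule
#' @param x An \code{AcquisitionSchedule}.
#' @export
setMethod("length", "AcquisitionSchedule", function(x) length(x@tau))

# ---------------------------------------------------------------------------
# KineticConstants

#' @rdname KineticConstants
#' @export
setClass("KineticConstants",
         representation(alpha = "numeric", lambda = "numeric", t1b = "numeric"),
         validity = function(object) {
           if (length(object@alpha) != 1 || !is.finite(object@alpha) ||
               object@alpha <= 0 || object@alpha > 1)
             return("alpha must be a single value in (0, 1]")
           if (length(object@lambda) != 1 || !is.finite(object@lambda) ||
               object@lambda <= 0)
             return("lambda must be a single positive value")
           if (length(object@t1b) != 1 || !is.finite(object@t1b) ||
               object@t1b <= 0)
             return("t1b must be a single positive value (ms)")
           TRUE
         })

#' Fixed constants of the ASL kinetic model
#'
#' @param alpha Labelling efficiency (fraction inverted), default 0.85.
#' @param lambda Blood-brain partition coefficient (ml/ml), default 0.9;
#'   scales the voxel-wise M0 to blood M0 as \code{m0/lambda}.
#' @param t1b Longitudinal relaxation time of arterial blood in ms,
#'   typically from \code{\link{t1BloodFromHct}}.
#' @return A \code{KineticConstants} object.
#' @examples
#' kineticConstants(t1b = t1BloodFromHct(0.42))
#' @export
kineticConstants <- function(alpha = 0.85, lambda = 0.9, t1b = 1650) {
  new("KineticConstants", alpha = alpha, lambda = lambda, t1b = t1b)
}

#' @describeIn KineticConstants labelling efficiency
#' @export
setGeneric("labellingEfficiency", function(x) standardGeneric("labellingEfficiency"))
#' @describeIn KineticConstants partition coefficient
#' @export
setGeneric("partitionCoefficient", function(x) standardGeneric("partitionCoefficient"))
#' @describeIn KineticConstants blood T1 (ms)
#' @export
setGeneric("bloodT1", function(x) standardGeneric("bloodT1"))

#' @rdname KineticConstants
setMethod("labellingEfficiency", "KineticConstants", function(x) x@alpha)
#' @rdname KineticConstants
setMethod("partitionCoefficient", "KineticConstants", function(x) x@lambda)
#' @rdname KineticConstants
setMethod("bloodT1", "KineticConstants", function(x) x@t1b)
#' @rdname KineticConstants
#' @param object,x A \code{KineticConstants}.
setMethod("show", "KineticConstants", function(object) {
  cat(sprintf("KineticConstants: alpha=%.3g lambda=%.3g T1b=%.1f ms\n",
              object@alpha, object@lambda, object@t1b))
})

# ---------------------------------------------------------------------------
# PerfusionFit

#' @rdname PerfusionFit
#' @export
setClass("PerfusionFit",
         representation(cbf = "numeric", att = "numeric",
                        residualNorm = "numeric", converged = "logical",
                        nPoints = "integer"),
         validity = function(object) {
           if (object@residualNorm < 0) return("residualNorm must be >= 0")
           if (object@cbf < 0 || object@cbf > 200)
             return("cbf outside fit bounds [0, 200]")
           if (object@att < 100 || object@att > 3500)
             return("att outside fit bounds [100, 3500] ms")
           TRUE
         })

#' Per-voxel perfusion fit result
#'
#' Holds the CBF (ml/100 ml/min) and ATT (ms) estimated by
#' \code{\link{fitVoxel}}, the residual norm in signal units, a convergence
#' flag and the number of delays used.
#'
#' @name PerfusionFit
#' @aliases cbf att
NULL

#' @describeIn PerfusionFit CBF estimate (ml/100 ml/min)
#' @export
setGeneric("cbf", function(x) standardGeneric("cbf"))
#' @describeIn PerfusionFit ATT estimate (ms)
#' @export
setGeneric("att", function(x) standardGeneric("att"))
#' @describeIn PerfusionFit residual norm (signal units)
#' @export
setGeneric("residualNorm", function(x) standardGeneric("residualNorm"))
#' @describeIn PerfusionFit did the optimiser converge?
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname PerfusionFit
setMethod("cbf", "PerfusionFit", function(x) x@cbf)
#' @rdname PerfusionFit
setMethod("att", "PerfusionFit", function(x) x@att)
#' @rdname PerfusionFit
setMethod("residualNorm", "PerfusionFit", function(x) x@residualNorm)
#' @rdname PerfusionFit
setMethod("converged", "PerfusionFit", function(x) x@converged)
#' @rdname PerfusionFit
#' @param object,x A \code{PerfusionFit}.
setMethod("show", "PerfusionFit", function(object) {
  cat(sprintf("PerfusionFit: CBF=%.2f ml/100ml/min ATT=%.0f ms (resid %.3g, %s, %d delays)\n",
              object@cbf, object@att, object@residualNorm,
              if (object@converged) "converged" else "NOT converged",
              object@nPoints))
})

# ---------------------------------------------------------------------------
# OximetryConstants

#' @rdname OximetryConstants
#' @export
setClass("OximetryConstants",
         representation(dchi0Cgs = "numeric", dchiHbCgs = "numeric",
                        unitSystem = "character"),
         validity = function(object) {
           if (!object@unitSystem %in% c("SI", "cgs"))
             return("unitSystem must be 'SI' or 'cgs'")
           if (!is.finite(object@dchi0Cgs) || object@dchi0Cgs <= 0)
             return("dchi0Cgs must be positive")
           TRUE
         })

#' Susceptibility-oximetry constants
#'
#' Stores the susceptibility difference per unit haematocrit between fully
#' deoxygenated and fully oxygenated red cells (0.27 ppm in cgs units) and
#' the susceptibility difference between fully oxygenated red cells and
#' water (-0.03 ppm cgs).  SI values are the cgs values multiplied by
#' \eqn{4\pi}; the accessors return the constants in the active unit
#' system, so a susceptibility map in SI ppm must be paired with
#' \code{unitSystem = "SI"}.
#'
#' @param unitSystem "SI" (default) or "cgs".
#' @param dchi0Cgs,dchiHbCgs The cgs values; defaults 0.27 and -0.03 ppm.
#' @return An \code{OximetryConstants} object.
#' @examples
#' oc <- oximetryConstants("SI")
#' dchi0(oc)   # 4*pi*0.27
#' @export
oximetryConstants <- function(unitSystem = c("SI", "cgs"),
                              dchi0Cgs = 0.27, dchiHbCgs = -0.03) {
  unitSystem <- match.arg(unitSystem)
  new("OximetryConstants", dchi0Cgs = dchi0Cgs, dchiHbCgs = dchiHbCgs,
      unitSystem = unitSystem)
}

#' @describeIn OximetryConstants deoxy-oxy susceptibility per unit Hct (ppm,
#'   active unit system)
#' @export
setGeneric("dchi0", function(x) standardGeneric("dchi0"))
#' @describeIn OximetryConstants oxygenated-cell minus water susceptibility
#'   (ppm, active unit system)
#' @export
setGeneric("dchiHb", function(x) standardGeneric("dchiHb"))
#' @describeIn OximetryConstants active unit system
#' @export
setGeneric("unitSystem", function(x) standardGeneric("unitSystem"))

.unitFactor <- function(x) if (x@unitSystem == "SI") 4 * pi else 1

#' @rdname OximetryConstants
setMethod("dchi0", "OximetryConstants", function(x) x@dchi0Cgs * .unitFactor(x))
#' @rdname OximetryConstants
setMethod("dchiHb", "OximetryConstants", function(x) x@dchiHbCgs * .unitFactor(x))
#' @rdname OximetryConstants
setMethod("unitSystem", "OximetryConstants", function(x) x@unitSystem)
#' @rdname OximetryConstants
#' @param object,x An \code{OximetryConstants}.
setMethod("show", "OximetryConstants", function(object) {
  cat(sprintf("OximetryConstants [%s]: dchi0=%.5g ppm/Hct, dchiHb-H2O=%.5g ppm\n",
              object@unitSystem, dchi0(object), dchiHb(object)))
})

# ---------------------------------------------------------------------------
# VeinMeasurement

#' @rdname VeinMeasurement
#' @export
setClass("VeinMeasurement",
         representation(vein = "character", roi = "array",
                        dchi = "numeric", svo2 = "numeric",
                        nVoxels = "integer", clamped = "logical"),
         validity = function(object) {
           if (object@nVoxels < 1L) return("nVoxels must be >= 1")
           if (object@svo2 < 0 || object@svo2 > 1)
             return("svo2 must lie in [0, 1]")
           TRUE
         })

#' Venous oximetry result for one vein
#'
#' The refined ROI (logical array), the extracted vein-CSF susceptibility
#' difference in ppm, the derived venous oxygen saturation, voxel count
#' and whether the saturation was clamped into [0, 1].
#'
#' @name VeinMeasurement
NULL

#' @describeIn VeinMeasurement venous oxygen saturation (fraction)
#' @export
setGeneric("svo2", function(x) standardGeneric("svo2"))
#' @describeIn VeinMeasurement vein-CSF susceptibility difference (ppm)
#' @export
setGeneric("veinDchi", function(x) standardGeneric("veinDchi"))
#' @describeIn VeinMeasurement number of ROI voxels
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname VeinMeasurement
setMethod("svo2", "VeinMeasurement", function(x) x@svo2)
#' @rdname VeinMeasurement
setMethod("veinDchi", "VeinMeasurement", function(x) x@dchi)
#' @rdname VeinMeasurement
setMethod("nVoxels", "VeinMeasurement", function(x) x@nVoxels)
#' @rdname VeinMeasurement
#' @param object,x A \code{VeinMeasurement}.
setMethod("show", "VeinMeasurement", function(object) {
  cat(sprintf("VeinMeasurement %s: dchi=%.4f ppm, SvO2=%.3f (%d voxels%s)\n",
              object@vein, object@dchi, object@svo2, object@nVoxels,
              if (object@clamped) ", clamped" else ""))
})

# ---------------------------------------------------------------------------
# RespiratoryTrace

#' @rdname RespiratoryTrace
#' @export
setClass("RespiratoryTrace",
         representation(samples = "numeric", samplingHz = "numeric",
                        window = "integer"),
         validity = function(object) {
           if (length(object@samples) < 2) return("trace needs >= 2 samples")
           if (any(object@samples < 0 | object@samples > 25))
             return("O2 percentages must lie in [0, 25]")
           if (object@samplingHz <= 0) return("samplingHz must be positive")
           if (length(object@window) != 2 ||
               object@window[1] < 1L ||
               object@window[2] > length(object@samples) ||
               object@window[1] > object@window[2])
             return("window must be a non-empty index range inside the trace")
           TRUE
         })

#' Exhaled-oxygen trace
#'
#' @param samples Numeric vector of exhaled O2 percentages over time.
#' @param samplingHz Sampling rate in Hz.
#' @param window Optional integer range (first, last sample index) marking
#'   the acquisition window; defaults to the whole trace.
#' @return A \code{RespiratoryTrace} object.
#' @export
respiratoryTrace <- function(samples, samplingHz, window = NULL) {
  if (is.null(window)) window <- c(1L, length(samples))
  new("RespiratoryTrace", samples = as.numeric(samples),
      samplingHz = samplingHz, window = as.integer(window))
}

#' @describeIn RespiratoryTrace the O2 samples (percent)
#' @export
setGeneric("o2Samples", function(x) standardGeneric("o2Samples"))
#' @describeIn RespiratoryTrace sampling rate (Hz)
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname RespiratoryTrace
setMethod("o2Samples", "RespiratoryTrace", function(x) x@samples)
#' @rdname RespiratoryTrace
setMethod("samplingRate", "RespiratoryTrace", function(x) x@samplingHz)
#' @rdname RespiratoryTrace
#' @param object,x A \code{RespiratoryTrace}.
setMethod("show", "RespiratoryTrace", function(object) {
  cat(sprintf("RespiratoryTrace: %d samples @ %g Hz (%.1f s), O2 %.1f-%.1f%%\n",
              length(object@samples), object@samplingHz,
              length(object@samples) / object@samplingHz,
              min(object@samples), max(object@samples)))
})

# ---------------------------------------------------------------------------
# ArterialOxygen

#' @rdname ArterialOxygen
#' @export
setClass("ArterialOxygen",
         representation(etO2 = "numeric", petO2 = "numeric", sao2 = "numeric",
                        hb = "numeric", o2a = "numeric"),
         validity = function(object) {
           if (object@sao2 <= 0 || object@sao2 > 1)
             return("sao2 must lie in (0, 1]")
           if (abs(object@o2a - object@hb * 55.6) > 1e-9 * max(1, object@o2a))
             return("o2a must equal hb * 55.6 umol O2/g")
           TRUE
         })

#' Arterial oxygenation summary for one subject
#'
#' End-tidal O2 (percent), the equivalent partial pressure (mmHg), SaO2
#' from the Severinghaus relation, haemoglobin concentration (g/100 ml,
#' HCT/3) and arterial oxygen content (umol O2/100 ml blood).
#'
#' @name ArterialOxygen
NULL

#' @describeIn ArterialOxygen arterial oxygen saturation (fraction)
#' @export
setGeneric("sao2", function(x) standardGeneric("sao2"))
#' @describeIn ArterialOxygen arterial O2 content (umol/100 ml blood)
#' @export
setGeneric("o2Content", function(x) standardGeneric("o2Content"))

#' @rdname ArterialOxygen
setMethod("sao2", "ArterialOxygen", function(x) x@sao2)
#' @rdname ArterialOxygen
setMethod("o2Content", "ArterialOxygen", function(x) x@o2a)
#' @rdname ArterialOxygen
#' @param object,x An \code{ArterialOxygen}.
setMethod("show", "ArterialOxygen", function(object) {
  cat(sprintf(
    "ArterialOxygen: EtO2=%.2f%% PetO2=%.1f mmHg SaO2=%.4f Hb=%.2f g/100ml [O2]a=%.1f umol/100ml\n",
    object@etO2, object@petO2, object@sao2, object@hb, object@o2a))
})

# ---------------------------------------------------------------------------
# VeinTerritoryAtlas

#' @rdname VeinTerritoryAtlas
#' @export
setClass("VeinTerritoryAtlas",
         representation(mapping = "list", upstream = "list"),
         validity = function(object) {
           if (is.null(names(object@mapping)) || any(names(object@mapping) == ""))
             return("mapping must be a named list of label vectors")
           labs <- unlist(object@mapping)
           if (anyDuplicated(labs))
             return("exclusive territories must be pairwise disjoint")
           up <- unlist(object@upstream)
           if (length(up) && !all(up %in% names(object@mapping)))
             return("upstream veins must be keys of mapping")
           if (length(object@upstream) &&
               !all(names(object@upstream) %in% names(object@mapping)))
             return("upstream rule keys must be keys of mapping")
           TRUE
         })

#' Vein-to-territory atlas
#'
#' Maps each vein to the set of integer parcellation labels of its
#' exclusive drainage territory, plus composition rules naming the
#' upstream veins whose territories are pooled into the composed ("total")
#' territory: SS_total = SS + ICVs + BVs, SSS V_total = SSS V + SSS H.
#'
#' @param mapping Named list, vein name -> integer label vector.
#' @param upstream Named list, vein name -> character vector of upstream
#'   vein names (default: the two rules above, restricted to veins present).
#' @return A \code{VeinTerritoryAtlas} object.
#' @examples
#' veinTerritoryAtlas(list(`SSS V` = 1L, `SSS H` = 2L, SS = 3L,
#'                         BVs = 4L, ICVs = 5L))
#' @export
veinTerritoryAtlas <- function(mapping,
                               upstream = list("SS" = c("ICVs", "BVs"),
                                               "SSS V" = "SSS H")) {
  mapping <- lapply(mapping, as.integer)
  upstream <- upstream[names(upstream) %in% names(mapping)]
  upstream <- lapply(upstream, function(v) v[v %in% names(mapping)])
  upstream <- upstream[lengths(upstream) > 0]
  new("VeinTerritoryAtlas", mapping = mapping, upstream = upstream)
}

#' @describeIn VeinTerritoryAtlas vein names in the atlas
#' @export
setGeneric("veins", function(x) standardGeneric("veins"))
#' @rdname VeinTerritoryAtlas
setMethod("veins", "VeinTerritoryAtlas", function(x) names(x@mapping))
#' @rdname VeinTerritoryAtlas
#' @param object,x A \code{VeinTerritoryAtlas}.
setMethod("show", "VeinTerritoryAtlas", function(object) {
  cat("VeinTerritoryAtlas:", length(object@mapping), "veins\n")
  for (v in names(object@mapping))
    cat(sprintf("  %-6s %d labels%s\n", v, length(object@mapping[[v]]),
                if (v %in% names(object@upstream))
                  paste0(" (+ upstream ",
                         paste(object@upstream[[v]], collapse = ", "), ")")
                else ""))
})

# ---------------------------------------------------------------------------
# CohortTruth

#' @rdname CohortTruth
#' @export
setClass("CohortTruth",
         representation(subjects = "data.frame", truth = "data.frame",
                        params = "list"),
         validity = function(object) {
           need <- c("subject", "hct", "qrisk", "moca", "amyloid",
                     "etO2", "sao2")
           if (!all(need %in% names(object@subjects)))
             return(paste("subjects must contain columns:",
                          paste(need, collapse = ", ")))
           needT <- c("subject", "territory", "cbf", "att", "svo2")
           if (!all(needT %in% names(object@truth)))
             return(paste("truth must contain columns:",
                          paste(needT, collapse = ", ")))
           if (any(object@subjects$hct <= 0 | object@subjects$hct >= 1))
             return("hct must lie in (0, 1)")
           sa <- object@subjects$sao2[match(object@truth$subject,
                                            object@subjects$subject)]
           if (any(object@truth$svo2 < 0 | object@truth$svo2 >= sa))
             return("each svo2 must satisfy 0 <= svo2 < sao2")
           TRUE
         })

#' Synthetic cohort with ground truth
#'
#' Subject-level covariates plus per-(subject, territory) ground-truth CBF,
#' ATT and SvO2, with the generator parameters recorded in \code{params}.
#'
#' @name CohortTruth
NULL

#' @describeIn CohortTruth subject-level covariate table
#' @export
setGeneric("cohortSubjects", function(x) standardGeneric("cohortSubjects"))
#' @describeIn CohortTruth long per-territory truth table
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @describeIn CohortTruth generator parameters
#' @export
setGeneric("generatorParams", function(x) standardGeneric("generatorParams"))

#' @rdname CohortTruth
setMethod("cohortSubjects", "CohortTruth", function(x) x@subjects)
#' @rdname CohortTruth
setMethod("cohortTruth", "CohortTruth", function(x) x@truth)
#' @rdname CohortTruth
setMethod("generatorParams", "CohortTruth", function(x) x@params)
#' @rdname CohortTruth
#' @param object,x A \code{CohortTruth}.
setMethod("show", "CohortTruth", function(object) {
  cat(sprintf("CohortTruth: %d subjects x %d territories (ATT-QRisk slope %.3g ms/point, seed %s)\n",
              nrow(object@subjects),
              length(unique(object@truth$territory)),
              object@params$effectSlope, object@params$seed))
})

# ---------------------------------------------------------------------------
# GroupModelResult

#' @rdname GroupModelResult
#' @export
setClass("GroupModelResult",
         representation(outcome = "character", predictor = "character",
                        coefficients = "data.frame", method = "character",
                        singular = "logical", model = "ANY"),
         validity = function(object) {
           if (!all(c("term", "estimate", "stdError") %in%
                    names(object@coefficients)))
             return("coefficients must have columns term, estimate, stdError")
           if (!object@predictor %in% object@coefficients$term)
             return("coefficient table must include the predictor slope term")
           TRUE
         })

#' Group-level mixed-model result
#'
#' Fixed-effect coefficient table from the linear mixed model
#' \code{outcome ~ predictor * territory + (1 | subject)}, with a
#' singularity flag and the fitting method ("lmer", or "ols" when a random
#' intercept is unidentifiable, e.g. one observation per subject).
#'
#' @name GroupModelResult
NULL

#' @describeIn GroupModelResult fixed-effect coefficient table
#' @export
setGeneric("coefficientTable", function(x) standardGeneric("coefficientTable"))
#' @describeIn GroupModelResult estimated slope of the predictor term
#' @export
setGeneric("slopeEstimate", function(x) standardGeneric("slopeEstimate"))

#' @rdname GroupModelResult
setMethod("coefficientTable", "GroupModelResult", function(x) x@coefficients)
#' @rdname GroupModelResult
setMethod("slopeEstimate", "GroupModelResult", function(x) {
  x@coefficients$estimate[x@coefficients$term == x@predictor][1]
})
#' @rdname GroupModelResult
#' @param object,x A \code{GroupModelResult}.
setMethod("show", "GroupModelResult", function(object) {
  cat(sprintf("GroupModelResult [%s%s]: %s ~ %s * territory + (1|subject)\n",
              object@method, if (object@singular) ", singular" else "",
              object@outcome, object@predictor))
  print(object@coefficients, row.names = FALSE)
})
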