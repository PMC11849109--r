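# Per-subject orchestration and the thin group-model stage.

#' Pipeline configuration
#'
#' Bundles every tunable of the per-subject pipeline so that a run is a
#' pure function of (config, inputs).  Fully serialisable to YAML/JSON via
#' the plain-list representation.
#'
#' @param schedule An \code{\link{acquisitionSchedule}}.
#' @param alpha,lambda Kinetic constants (labelling efficiency, partition
#'   coefficient).
#' @param unitSystem Susceptibility unit convention, "SI" or "cgs".
#' @param lowerPpb,upperPpb Vein ROI refinement thresholds (ppb).
#' @param percentile Vein susceptibility extraction percentile.
#' @param barometric,waterVapour Pressures (mmHg) for the end-tidal
#'   percent-to-mmHg bridge.
#' @param minProminence,minSpacingS End-tidal detection parameters.
#' @param atlas A \code{\link{veinTerritoryAtlas}} (default: the phantom
#'   slab atlas).
#' @param combiner Territory combiner, "pooled" or "weighted".
#' @return A named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(schedule = defaultSchedule(),
                           alpha = 0.85, lambda = 0.9,
                           unitSystem = "SI",
                           lowerPpb = 130, upperPpb = 1000,
                           percentile = 0.9,
                           barometric = 760, waterVapour = 47,
                           minProminence = 1, minSpacingS = 1.5,
                           atlas = phantomAtlas(),
                           combiner = "pooled") {
  structure(list(schedule = schedule, alpha = alpha, lambda = lambda,
                 unitSystem = unitSystem, lowerPpb = lowerPpb,
                 upperPpb = upperPpb, percentile = percentile,
                 barometric = barometric, waterVapour = waterVapour,
                 minProminence = minProminence, minSpacingS = minSpacingS,
                 atlas = atlas, combiner = combiner),
            class = "pipelineConfig")
}

#' Run the full per-subject pipeline
#'
#' Executes, in order: voxel-wise CBF/ATT fitting over the masked ASL
#' volume; arterial oxygenation from the respiratory trace and
#' haematocrit; brain-mask erosion; and per vein: territory composition,
#' pooled-median CBF/ATT aggregation, ROI refinement, percentile
#' susceptibility extraction, SvO2 inversion, OEF and CMRO2.  A failing
#' territory produces an \code{NA} row and a logged reason; the run
#' continues for the remaining territories.  Deterministic given its
#' inputs.
#'
#' @param inputs Named list as produced by
#'   \code{\link{simulateSubjectInputs}}: subject, session, hct, asl, m0,
#'   aslMask, parcellation, chi, brainMask, veinSeeds, respTrace.
#' @param config A \code{\link{pipelineConfig}}.
#' @return Data frame with one row per vein (subject, session, territory,
#'   oef, cbf, att, cmro2, svo2, nVoxels), with attributes \code{log}
#'   (character vector of per-stage messages), \code{sao2} and \code{o2a}.
#' @export
runSubject <- function(inputs, config = pipelineConfig()) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  maps <- fitVolume(inputs$asl, inputs$m0, inputs$aslMask, config$schedule,
                    inputs$hct, alpha = config$alpha, lambda = config$lambda)
  note("fit %d voxels", sum(inputs$aslMask))

  ao <- arterialOxygen(inputs$respTrace, inputs$hct,
                       barometric = config$barometric,
                       waterVapour = config$waterVapour,
                       minProminence = config$minProminence,
                       minSpacingS = config$minSpacingS)
  note("SaO2 %.4f from EtO2 %.2f%%", sao2(ao), ao@etO2)

  oc <- oximetryConstants(config$unitSystem)
  eroded <- erodeBrainMask(inputs$brainMask)
  atlas <- config$atlas

  rows <- lapply(veins(atlas), function(vein) {
    res <- tryCatch({
      labels <- composeTerritories(atlas, vein)
      cbfV <- aggregateTerritory(maps$cbf, inputs$parcellation, labels,
                                 combiner = config$combiner)
      attV <- aggregateTerritory(maps$att, inputs$parcellation, labels,
                                 combiner = config$combiner)
      seed <- inputs$veinSeeds[[vein]]
      if (is.null(seed) || !any(seed)) stop("empty seed ROI")
      vm <- measureVein(vein, seed & eroded, inputs$chi, inputs$hct, oc,
                        lowerPpb = config$lowerPpb,
                        upperPpb = config$upperPpb,
                        percentile = config$percentile)
      oefV <- as.numeric(computeOef(sao2(ao), svo2(vm)))
      data.frame(subject = inputs$subject, session = inputs$session,
                 territory = vein, oef = oefV, cbf = cbfV, att = attV,
                 cmro2 = cbfV * (o2Content(ao) / 100) * oefV,
                 svo2 = svo2(vm), nVoxels = nVoxels(vm),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      note("%s: %s", vein, conditionMessage(e))
      data.frame(subject = inputs$subject, session = inputs$session,
                 territory = vein, oef = NA_real_, cbf = NA_real_,
                 att = NA_real_, cmro2 = NA_real_, svo2 = NA_real_,
                 nVoxels = NA_integer_, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "log") <- log
  attr(out, "sao2") <- sao2(ao)
  attr(out, "o2a") <- o2Content(ao)
  out
}

#' Fit the group-level linear mixed model
#'
#' Thin glue over \code{lme4::lmer}:
#' \code{outcome ~ predictor * territory + (1 | subject)} (random
#' intercept per subject).  When the random intercept is unidentifiable —
#' one observation per subject, or a single territory — the model falls
#' back to ordinary least squares and is flagged with
#' \code{method = "ols"}; a singular mixed fit is reported, not an error.
#'
#' @param table Data frame with columns subject, territory, the outcome
#'   and the predictor.
#' @param outcome Outcome column name (e.g. "att").
#' @param predictor Predictor column name (e.g. "qrisk").
#' @param interaction Include the predictor x territory interaction
#'   (default TRUE, matching the study design).
#' @return A \code{\link{GroupModelResult}}.
#' @export
fitGroupModel <- function(table, outcome, predictor, interaction = TRUE) {
  stopifnot(all(c("subject", "territory", outcome, predictor) %in%
                names(table)))
  table <- table[is.finite(table[[outcome]]) & is.finite(table[[predictor]]), ]
  if (length(unique(table$subject)) < 2) stop("need >= 2 subjects")
  multiTerr <- length(unique(table$territory)) > 1
  fixed <- if (multiTerr)
    paste(outcome, "~", predictor, if (interaction) "*" else "+",
          "territory")
  else paste(outcome, "~", predictor)

  # If the fixed effects alone fit the data exactly (noiseless input), the
  # variance components are on the boundary and the mixed-model deviance is
  # degenerate; the exact least-squares solution is the answer.
  ols0 <- stats::lm(stats::as.formula(fixed), data = table)
  if (stats::sigma(ols0) <= 1e-8 * max(stats::sd(table[[outcome]]), 1e-12)) {
    # a perfect fit is the detected condition, not a defect to warn about
    cf <- suppressWarnings(summary(ols0))$coefficients
    coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        stdError = cf[, "Std. Error"],
                        stringsAsFactors = FALSE)
    rownames(coefs) <- NULL
    return(new("GroupModelResult", outcome = outcome, predictor = predictor,
               coefficients = coefs, method = "ols", singular = FALSE,
               model = ols0))
  }

  fit <- tryCatch(
    lme4::lmer(stats::as.formula(paste(fixed, "+ (1 | subject)")),
               data = table, REML = TRUE),
    error = function(e) e)
  if (inherits(fit, "error")) {
    fit <- stats::lm(stats::as.formula(fixed), data = table)
    method <- "ols"
    singular <- FALSE
    cf <- summary(fit)$coefficients
  } else {
    method <- "lmer"
    singular <- lme4::isSingular(fit)
    cf <- stats::coef(summary(fit))
  }
  coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      stdError = cf[, "Std. Error"],
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  new("GroupModelResult", outcome = outcome, predictor = predictor,
      coefficients = coefs, method = method, singular = singular,
      model = fit)
}

#' Predicted change from a regression coefficient
#'
#' \code{coefficient * delta}: e.g. a slope of 13.2 ms per QRisk point
#' predicts a 132 ms ATT increase per 10-point QRisk increase.
#'
#' @param coefficient Slope in outcome units per predictor point.
#' @param delta Change in the predictor, in predictor points.
#' @return Predicted change in outcome units.
#' @examples
#' predictedChange(13.2, 10)  # 132
#' @export
predictedChange <- function(coefficient, delta) {
  if (!is.finite(coefficient) || !is.finite(delta))
    stop("inputs must be finite")
  coefficient * delta
}
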