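# Arterial oxygenation from the exhaled-O2 trace, OEF and CMRO2.

#' End-tidal oxygen values from a respiratory trace
#'
#' Detects the end-expiratory extrema of the exhaled-O2 trace.  Expiration
#' carries alveolar gas, so end-tidal O2 values are local minima of the
#' trace; they are found as peaks of the negated trace (flat plateaus
#' allowed), separated by at least \code{minSpacingS} seconds and with a
#' prominence of at least \code{minProminence} percentage points relative
#' to the neighbouring inspiratory excursions.  \code{mode = "peaks"}
#' instead detects raw maxima of the trace, for auditing against
#' pipelines that ran a generic peak finder on the unnegated signal.
#'
#' @param trace A \code{\link{respiratoryTrace}}.
#' @param minProminence Minimum extremum prominence in percent O2.
#' @param minSpacingS Minimum spacing between breaths in seconds.
#' @param mode "minima" (physiological end-tidal, default) or "peaks".
#' @return List with \code{values} (percent, in time order), \code{median}
#'   and \code{indices} (sample indices within the window).
#' @export
endTidalValues <- function(trace, minProminence = 1, minSpacingS = 1.5,
                           mode = c("minima", "peaks")) {
  mode <- match.arg(mode)
  x <- o2Samples(trace)[trace@window[1]:trace@window[2]]
  y <- if (mode == "minima") -x else x
  minDist <- max(1L, round(minSpacingS * samplingRate(trace)))
  pk <- pracma::findpeaks(y, minpeakdistance = minDist,
                          peakpat = "[+]{1,}[0]*[-]{1,}")
  if (is.null(pk) || nrow(pk) < 1)
    stop("insufficient breaths: fewer than 3 end-tidal extrema detected")
  idx <- sort(pk[, 2])
  # prominence against the deepest excursion between neighbouring extrema
  keep <- vapply(seq_along(idx), function(k) {
    left <- if (k == 1) 1L else idx[k - 1]
    right <- if (k == length(idx)) length(y) else idx[k + 1]
    promL <- y[idx[k]] - min(y[left:idx[k]])
    promR <- y[idx[k]] - min(y[idx[k]:right])
    min(promL, promR) >= minProminence
  }, logical(1))
  idx <- idx[keep]
  if (length(idx) < 3)
    stop("insufficient breaths: fewer than 3 end-tidal extrema detected")
  values <- x[idx]
  list(values = values, median = stats::median(values),
       indices = idx + trace@window[1] - 1L)
}

#' Convert an end-tidal O2 percentage to a partial pressure
#'
#' \eqn{P_{ET}O_2 = (EtO_2/100)(P_B - P_{H_2O})}: the dry-gas fraction
#' times barometric pressure corrected for water vapour at body
#' temperature.
#'
#' @param etO2 End-tidal O2 in percent, in (0, 100).
#' @param barometric Barometric pressure in mmHg (default 760).
#' @param waterVapour Water vapour pressure in mmHg (default 47).
#' @return Partial pressure in mmHg.
#' @examples
#' etPercentToPo2(15.2)  # 108.4 mmHg
#' @export
etPercentToPo2 <- function(etO2, barometric = 760, waterVapour = 47) {
  if (any(etO2 <= 0) || any(etO2 >= 100))
    stop("etO2 must lie strictly between 0 and 100 percent")
  if (barometric <= waterVapour)
    stop("barometric pressure must exceed water vapour pressure")
  etO2 / 100 * (barometric - waterVapour)
}

#' Severinghaus haemoglobin dissociation curve
#'
#' \deqn{SaO_2 = \left(1 + \frac{23400}{P O_2^3 + 150\,P O_2}\right)^{-1}}
#' Strictly increasing on (0, Inf) and bounded by 1.
#'
#' @param po2 Oxygen partial pressure in mmHg (> 0).
#' @return Arterial oxygen saturation as a fraction.
#' @examples
#' severinghausSao2(100)  # 0.9775
#' @export
severinghausSao2 <- function(po2) {
  if (any(!is.finite(po2)) || any(po2 <= 0)) stop("po2 must be > 0")
  1 / (1 + 23400 / (po2^3 + 150 * po2))
}

#' Arterial oxygen content from haematocrit
#'
#' Haemoglobin concentration is estimated as Hct/3 (g/100 ml with Hct in
#' percent), and each gram of haemoglobin carries 55.6 umol O2, so
#' \eqn{[O_2]_a = \mathrm{Hb} \times 55.6} umol O2/100 ml blood.
#' Dissolved oxygen is neglected.
#'
#' @param hct Haematocrit fraction in (0, 1).
#' @return Named list with \code{hb} (g/100 ml) and \code{o2a}
#'   (umol O2/100 ml blood).
#' @examples
#' arterialO2Content(0.42)  # hb 14.0, o2a 778.4
#' @export
arterialO2Content <- function(hct) {
  if (any(!is.finite(hct)) || any(hct <= 0) || any(hct >= 1))
    stop("hct must lie strictly in (0, 1)")
  hb <- hct * 100 / 3
  list(hb = hb, o2a = hb * 55.6)
}

#' Oxygen extraction fraction
#'
#' \eqn{OEF = (SaO_2 - SvO_2)/SaO_2}.  Negative results (venous saturation
#' above arterial, possible under noise) are returned unclamped with a
#' warning and a \code{"negative"} attribute, preserving the noise
#' structure for repeatability statistics.
#'
#' @param sao2 Arterial saturation fraction in (0, 1].
#' @param svo2 Venous saturation fraction in [0, 1].
#' @return OEF fraction with attribute \code{negative}.
#' @export
computeOef <- function(sao2, svo2) {
  if (any(sao2 <= 0) || any(sao2 > 1)) stop("sao2 must lie in (0, 1]")
  if (any(svo2 < 0) || any(svo2 > 1)) stop("svo2 must lie in [0, 1]")
  oef <- (sao2 - svo2) / sao2
  neg <- oef < 0
  if (any(neg)) warning("negative OEF: svo2 exceeds sao2")
  attr(oef, "negative") <- neg
  oef
}

#' Cerebral metabolic rate of oxygen
#'
#' \eqn{CMRO_2 = CBF \times [O_2]_a \times OEF}, with \eqn{[O_2]_a}
#' supplied per 100 ml blood and CBF in ml/100 ml/min, so the content is
#' divided by 100 (umol per ml blood) to land on umol O2/100 ml
#' tissue/min.
#'
#' @param cbf Cerebral blood flow, ml/100 ml/min (>= 0).
#' @param o2a Arterial oxygen content, umol O2/100 ml blood (>= 0).
#' @param oef Oxygen extraction fraction (>= 0).
#' @return CMRO2 in umol O2/100 ml tissue/min.
#' @examples
#' computeCmro2(43.0, 778.4, 0.427)  # ~142.9
#' @export
computeCmro2 <- function(cbf, o2a, oef) {
  if (any(cbf < 0) || any(o2a < 0) || any(oef < 0))
    stop("cbf, o2a and oef must all be >= 0")
  cbf * (o2a / 100) * oef
}

#' Full arterial oxygenation summary
#'
#' Chains end-tidal extraction, the percent-to-mmHg bridge, the
#' Severinghaus relation and the haematocrit-based oxygen content into an
#' \code{\link{ArterialOxygen}} object.
#'
#' @param trace A \code{\link{respiratoryTrace}}, or a single end-tidal
#'   percentage.
#' @param hct Haematocrit fraction.
#' @param barometric,waterVapour Pressures in mmHg for the bridge.
#' @param ... Further arguments to \code{\link{endTidalValues}}.
#' @return An \code{\link{ArterialOxygen}}.
#' @export
arterialOxygen <- function(trace, hct, barometric = 760, waterVapour = 47,
                           ...) {
  etO2 <- if (is(trace, "RespiratoryTrace"))
    endTidalValues(trace, ...)$median else as.numeric(trace)
  petO2 <- etPercentToPo2(etO2, barometric, waterVapour)
  sa <- severinghausSao2(petO2)
  content <- arterialO2Content(hct)
  new("ArterialOxygen", etO2 = etO2, petO2 = petO2, sao2 = sa,
      hb = content$hb, o2a = content$o2a)
}
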