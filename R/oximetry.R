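# Venous oximetry from quantitative susceptibility maps.

#' Erode a brain mask by one 6-connected pass
#'
#' Removes the outermost voxel layer of a binary mask: a voxel survives
#' only if all six face neighbours (and itself) are inside the mask.
#' Voxels on the array border are removed (outside counts as background),
#' which is the intent of the step — trimming tissue-air boundary voxels
#' where background-field removal is unreliable.
#'
#' @param mask Logical 3-D array, non-empty.
#' @return Logical array of the same shape, a subset of \code{mask}.
#' @export
erodeBrainMask <- function(mask) {
  if (length(dim(mask)) != 3) stop("mask must be a 3-D array")
  if (!any(mask)) stop("mask is empty")
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  shift <- function(dx, dy, dz)
    padded[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz]
  out <- mask &
    shift(-1, 0, 0) & shift(1, 0, 0) &
    shift(0, -1, 0) & shift(0, 1, 0) &
    shift(0, 0, -1) & shift(0, 0, 1)
  out
}

#' Refine a vein seed ROI by susceptibility thresholding
#'
#' Keeps the seed voxels whose susceptibility lies within
#' [\code{lowerPpb}, \code{upperPpb}] (inclusive), so that only venous
#' voxels remain; the defaults of 130 and 1000 ppb exclude surrounding
#' tissue below and artefactual values above.  1 ppm = 1000 ppb.
#'
#' @param seedRoi Logical array marking the hand-drawn (or simulated) seed.
#' @param chi Numeric array of susceptibilities in ppm, same shape.
#' @param lowerPpb,upperPpb Thresholds in parts per billion.
#' @return Logical array: the surviving voxels.
#' @export
refineVeinRoi <- function(seedRoi, chi, lowerPpb = 130, upperPpb = 1000) {
  if (!identical(dim(seedRoi), dim(chi)))
    stop("seedRoi and chi shapes do not agree")
  if (!any(seedRoi)) stop("seed ROI is empty")
  ppb <- chi * 1000
  out <- seedRoi & !is.na(chi) & ppb >= lowerPpb & ppb <= upperPpb
  if (!any(out))
    stop("empty region: no seed voxels within [", lowerPpb, ", ", upperPpb,
         "] ppb")
  out
}

#' Extract the vein susceptibility from a refined ROI
#'
#' The 90th percentile (by default) of the non-zero in-ROI values, using
#' linear interpolation between order statistics (rank
#' \eqn{p\,(n-1)+1}).  Taking a high percentile counters partial-volume
#' dilution at the vessel edge.
#'
#' @param roi Logical array: the refined ROI.
#' @param chi Susceptibility array in ppm, same shape.
#' @param percentile Probability in (0, 1]; default 0.9.
#' @return Vein-minus-CSF susceptibility difference in ppm (the map is
#'   referenced to CSF).
#' @export
veinSusceptibility <- function(roi, chi, percentile = 0.9) {
  if (!identical(dim(roi), dim(chi)))
    stop("roi and chi shapes do not agree")
  v <- chi[roi]
  v <- v[!is.na(v) & v != 0]
  if (length(v) == 0) stop("empty region: no non-zero voxels in ROI")
  as.numeric(stats::quantile(v, percentile, type = 7, names = FALSE))
}

#' Venous oxygen saturation from a susceptibility difference
#'
#' Inverts the vein-CSF susceptibility relation
#' \deqn{\Delta\chi_{vein-CSF} = (1 - SvO_2)\,\Delta\chi_0\,\mathrm{Hct}
#'       + \Delta\chi_{Hb-H_2O}\,\mathrm{Hct}}
#' for \eqn{SvO_2}.  Results are clamped to [0, 1]; the \code{"clamped"}
#' attribute records whether clamping occurred.  Strictly decreasing in
#' \code{dchi} for fixed \code{hct}.
#'
#' @param dchi Susceptibility difference in ppm, in the unit system of
#'   \code{constants}.
#' @param hct Haematocrit fraction in (0, 1).
#' @param constants An \code{\link{oximetryConstants}} object matching the
#'   map's unit convention.
#' @return SvO2 fraction with attribute \code{clamped}.
#' @examples
#' svo2FromSusceptibility(0.41, 0.42, oximetryConstants("SI"))
#' @export
svo2FromSusceptibility <- function(dchi, hct,
                                   constants = oximetryConstants("SI")) {
  if (any(!is.finite(hct)) || any(hct <= 0) || any(hct >= 1))
    stop("hct must lie strictly in (0, 1)")
  s <- 1 - (dchi / hct - dchiHb(constants)) / dchi0(constants)
  clamped <- s < 0 | s > 1
  s <- pmin(pmax(s, 0), 1)
  attr(s, "clamped") <- clamped
  s
}

#' @describeIn svo2FromSusceptibility forward relation: susceptibility
#'   difference (ppm) generated by a given SvO2 and haematocrit.
#' @param svo2 Venous oxygen saturation fraction in [0, 1].
#' @export
susceptibilityFromSvo2 <- function(svo2, hct,
                                   constants = oximetryConstants("SI")) {
  if (any(svo2 < 0) || any(svo2 > 1)) stop("svo2 must lie in [0, 1]")
  if (any(hct <= 0) || any(hct >= 1)) stop("hct must lie strictly in (0, 1)")
  (1 - svo2) * dchi0(constants) * hct + dchiHb(constants) * hct
}

#' Measure one vein end to end
#'
#' Refine the seed ROI by thresholding, extract the percentile
#' susceptibility and invert to SvO2.
#'
#' @param vein Vein name (e.g. "SS").
#' @param seedRoi Logical seed array.
#' @param chi Susceptibility map (ppm).
#' @param hct Haematocrit fraction.
#' @param constants \code{\link{oximetryConstants}} for the map's units.
#' @param lowerPpb,upperPpb Refinement thresholds (ppb).
#' @param percentile Extraction percentile, default 0.9.
#' @return A \code{\link{VeinMeasurement}}.
#' @export
measureVein <- function(vein, seedRoi, chi, hct,
                        constants = oximetryConstants("SI"),
                        lowerPpb = 130, upperPpb = 1000, percentile = 0.9) {
  roi <- refineVeinRoi(seedRoi, chi, lowerPpb, upperPpb)
  dchi <- veinSusceptibility(roi, chi, percentile)
  s <- svo2FromSusceptibility(dchi, hct, constants)
  new("VeinMeasurement", vein = vein, roi = roi, dchi = dchi,
      svo2 = as.numeric(s), nVoxels = sum(roi),
      clamped = isTRUE(any(attr(s, "clamped"))))
}
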