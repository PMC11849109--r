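# Single-blood-compartment pCASL kinetic model and voxel-wise estimation.

#' Blood T1 from haematocrit
#'
#' Longitudinal relaxation time of arterial blood from the individual
#' haematocrit via the linear relaxivity relation
#' \eqn{1/T_1 \,[s^{-1}] = 0.52\,\mathrm{Hct} + 0.38}.
#'
#' @param hct Haematocrit as a volume fraction in (0, 1).
#' @return Blood T1 in milliseconds.
#' @examples
#' t1BloodFromHct(0.42)  # ~1671 ms
#' @export
t1BloodFromHct <- function(hct) {
  if (any(!is.finite(hct)) || any(hct <= 0) || any(hct >= 1))
    stop("hct must lie strictly in (0, 1)")
  1000 / (0.52 * hct + 0.38)
}

#' pCASL difference signal under the single-blood-compartment model
#'
#' Forward model of the label-control difference signal \eqn{\Delta M} at
#' measurement time \eqn{t = \tau + w} (label onset origin).  Labelled
#' blood arrives between \code{att} and \code{att + tau}, decays at the T1
#' of blood throughout (no exchange into tissue), and the voxel-wise M0 is
#' converted to blood M0 through the partition coefficient
#' (\code{m0 / lambda}).  Piecewise in \eqn{t}:
#' \itemize{
#'   \item \eqn{t < \mathrm{ATT}}: 0 (label not yet arrived);
#'   \item \eqn{\mathrm{ATT} \le t < \mathrm{ATT}+\tau}: inflow phase,
#'     \eqn{2\alpha m_{0b} f T_{1b} e^{-\mathrm{ATT}/T_{1b}}
#'          (1 - e^{-(t-\mathrm{ATT})/T_{1b}})};
#'   \item \eqn{t \ge \mathrm{ATT}+\tau}: decay of the full bolus,
#'     \eqn{2\alpha m_{0b} f T_{1b} e^{-\mathrm{ATT}/T_{1b}}
#'          (1 - e^{-\tau/T_{1b}}) e^{-(t-\mathrm{ATT}-\tau)/T_{1b}}}
#' }
#' with \eqn{f = \mathrm{CBF}/6000} in ml/ml/s and \eqn{T_{1b}} in seconds
#' inside the prefactor.  Continuous in \eqn{t} across both boundaries and
#' linear in both \code{cbf} and \code{m0}.
#'
#' @param cbf Cerebral blood flow, ml/100 ml/min (>= 0).
#' @param att Arterial transit time, ms (> 0).
#' @param tau Label duration(s), ms (> 0); vectorised.
#' @param pld Post-label delay(s), ms (> 0); vectorised with \code{tau}.
#' @param constants A \code{\link{kineticConstants}} object.
#' @param m0 Equilibrium magnetisation of the voxel (signal units).
#' @return \eqn{\Delta M} in signal units, one value per (tau, pld) pair.
#' @examples
#' ks <- kineticConstants(t1b = 1650)
#' pcaslSignal(50, 1200, tau = 2024, pld = 2024, constants = ks)
#' @export
pcaslSignal <- function(cbf, att, tau, pld, constants = kineticConstants(),
                        m0 = 1) {
  if (any(!is.finite(c(cbf, att, tau, pld, m0))))
    stop("all inputs must be finite")
  if (any(cbf < 0)) stop("cbf must be >= 0")
  if (any(att <= 0) || any(tau <= 0) || any(pld <= 0))
    stop("att, tau and pld must be > 0")
  t1 <- bloodT1(constants)                      # ms
  f <- cbf / 6000                               # ml/ml/s
  m0b <- m0 / partitionCoefficient(constants)
  amp <- 2 * labellingEfficiency(constants) * m0b * f * (t1 / 1000)
  t <- tau + pld
  inflow <- amp * exp(-att / t1) * (1 - exp(-(t - att) / t1))
  decay  <- amp * exp(-att / t1) * (1 - exp(-tau / t1)) *
    exp(-(t - att - tau) / t1)
  out <- ifelse(t < att, 0, ifelse(t < att + tau, inflow, decay))
  as.numeric(out)
}

#' @describeIn pcaslSignal forward signals over a whole schedule
#' @param schedule An \code{\link{acquisitionSchedule}}.
#' @export
pcaslSignalSchedule <- function(cbf, att, schedule,
                                constants = kineticConstants(), m0 = 1) {
  pcaslSignal(cbf, att, labelDurations(schedule), postLabelDelays(schedule),
              constants, m0)
}

#' Fit CBF and ATT for one voxel
#'
#' Bounded nonlinear least squares of the six-delay difference signals
#' (normalised by M0) against \code{\link{pcaslSignal}}, with a fixed
#' multi-start over ATT to avoid local minima of the piecewise model.
#' The candidate with the smallest residual sum of squares wins; ties go
#' to the smallest ATT.  Deterministic given its inputs.
#'
#' @param signals Numeric vector of difference signals, one per schedule
#'   pair (negative values are kept: unbiased under zero-mean noise).
#' @param m0 Voxel M0 (> 0).
#' @param schedule An \code{\link{acquisitionSchedule}} (>= 3 pairs).
#' @param constants A \code{\link{kineticConstants}} object.
#' @param lower,upper Fit bounds c(cbf, att): defaults [0, 200] ml/100
#'   ml/min and [100, 3500] ms.
#' @param cbfStart CBF starting value (default 50).
#' @param attStarts ATT multi-start grid, default c(800, 1200, 1600, 2000).
#' @return A \code{\link{PerfusionFit}}.  All-zero input returns cbf = 0
#'   with ATT pinned at its lower bound and \code{converged = FALSE}
#'   (ATT unidentifiable).
#' @examples
#' sch <- defaultSchedule()
#' ks <- kineticConstants(t1b = t1BloodFromHct(0.42))
#' y <- pcaslSignalSchedule(50, 1400, sch, ks, m0 = 1000)
#' fitVoxel(y, 1000, sch, ks)
#' @export
fitVoxel <- function(signals, m0, schedule, constants = kineticConstants(),
                     lower = c(0, 100), upper = c(200, 3500),
                     cbfStart = 50, attStarts = c(800, 1200, 1600, 2000)) {
  if (length(m0) != 1 || !is.finite(m0) || m0 <= 0)
    stop("m0 must be a single positive value")
  n <- length(schedule)
  if (length(signals) != n)
    stop("signals must have one value per schedule pair")
  if (n < 3) stop("need at least 3 signal points")
  if (all(signals == 0))
    return(new("PerfusionFit", cbf = 0, att = lower[2], residualNorm = 0,
               converged = FALSE, nPoints = as.integer(n)))
  tau <- labelDurations(schedule)
  pld <- postLabelDelays(schedule)
  y <- signals / m0
  resFn <- function(p) y - pcaslSignal(p[1], p[2], tau, pld, constants, 1)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14, gtol = 0)
  cand <- lapply(attStarts, function(a0) {
    fit <- minpack.lm::nls.lm(par = c(cbfStart, a0), lower = lower,
                              upper = upper, fn = resFn, control = ctrl)
    list(par = fit$par, ssq = sum(fit$fvec^2), ok = fit$info %in% 1:4)
  })
  ssqs <- vapply(cand, `[[`, numeric(1), "ssq")
  best <- min(ssqs)
  tied <- which(ssqs <= best * (1 + 1e-9) + 1e-300)
  pick <- tied[which.min(vapply(cand[tied], function(cc) cc$par[2],
                                numeric(1)))]
  ch <- cand[[pick]]
  new("PerfusionFit", cbf = ch$par[1], att = ch$par[2],
      residualNorm = sqrt(ch$ssq) * m0, converged = ch$ok,
      nPoints = as.integer(n))
}

#' Fit CBF and ATT maps over a masked volume
#'
#' Runs \code{\link{fitVoxel}} at every in-mask voxel of a 4-D ASL
#' difference-signal array, with blood T1 derived from the subject's
#' haematocrit.  Voxels outside the mask are \code{NA} in both maps.
#'
#' @param asl 4-D array (x, y, z, delay) of difference signals; the 4th
#'   dimension matches the schedule length.
#' @param m0 3-D array of voxel-wise M0 (positive inside the mask).
#' @param mask Logical 3-D array (non-empty).
#' @param schedule An \code{\link{acquisitionSchedule}}.
#' @param hct Subject haematocrit (fraction), used for blood T1.
#' @param alpha,lambda Labelling efficiency and partition coefficient.
#' @param ... Further arguments to \code{\link{fitVoxel}}.
#' @return List with 3-D arrays \code{cbf}, \code{att} and logical
#'   \code{converged}.
#' @export
fitVolume <- function(asl, m0, mask, schedule, hct,
                      alpha = 0.85, lambda = 0.9, ...) {
  d <- dim(asl)
  if (length(d) != 4) stop("asl must be a 4-D array")
  if (!identical(d[1:3], dim(m0)) || !identical(d[1:3], dim(mask)))
    stop("asl, m0 and mask shapes do not agree")
  if (d[4] != length(schedule))
    stop("4th dimension of asl must match the schedule length")
  if (!any(mask)) stop("mask is empty")
  constants <- kineticConstants(alpha = alpha, lambda = lambda,
                                t1b = t1BloodFromHct(hct))
  cbfMap <- array(NA_real_, d[1:3])
  attMap <- array(NA_real_, d[1:3])
  convMap <- array(NA, d[1:3])
  sig <- matrix(asl, nrow = prod(d[1:3]), ncol = d[4])
  idx <- which(mask)
  for (i in idx) {
    fit <- fitVoxel(sig[i, ], m0[i], schedule, constants, ...)
    cbfMap[i] <- cbf(fit)
    attMap[i] <- att(fit)
    convMap[i] <- converged(fit)
  }
  list(cbf = cbfMap, att = attMap, converged = convMap)
}

#' Median of a parameter map over a territory
#'
#' Median of the in-territory, non-missing voxel values; even counts take
#' the mean of the central pair.
#'
#' @param map Numeric array of voxel values (may contain \code{NA}).
#' @param territory Logical array (same shape) selecting the territory.
#' @return Scalar median.
#' @export
territoryMedian <- function(map, territory) {
  if (!identical(dim(map), dim(territory)))
    stop("map and territory shapes do not agree")
  v <- map[territory]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop("empty territory: no non-missing voxels after masking")
  stats::median(v)
}
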