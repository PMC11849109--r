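# Independent oracles used across the suite.  These deliberately avoid the
# package's closed-form code paths.

# Numerical integration of the labelled-bolus delivery-and-decay integral:
# blood labelled at the labelling plane during [0, tau] arrives at the voxel
# between att and att + tau, decayed by exp(-att/T1b) in transit, and keeps
# decaying at T1b until readout at t = tau + pld.  Trapezoidal rule, 1 ms.
oracleSignal <- function(cbf, att, tau, pld, alpha = 0.85, lambda = 0.9,
                         t1b = 1650, m0 = 1, dt = 1) {
  t <- tau + pld
  lo <- att
  hi <- min(t, att + tau)
  if (hi <= lo) return(0)
  u <- seq(lo, hi, by = dt)
  if (u[length(u)] < hi) u <- c(u, hi)
  integrand <- exp(-att / t1b) * exp(-(t - u) / t1b)
  # trapezoid with possibly uneven last panel
  w <- diff(u)
  integral <- sum(w * (integrand[-length(u)] + integrand[-1]) / 2)
  2 * alpha * (m0 / lambda) * (cbf / 6000) / 1000 * integral
}

# Exhaustive grid-search least squares for (CBF, ATT).  The model is linear
# in CBF, so the sum of squares decomposes as
# ssq = |y|^2 - 2 cbf <g, y> + cbf^2 |g|^2 with g the unit-CBF signal.
gridSearchFit <- function(signals, m0, schedule, constants,
                          cbfGrid = seq(0, 200, by = 1),
                          attGrid = seq(100, 3500, by = 10)) {
  y <- signals / m0
  g <- vapply(attGrid, function(a)
    pcaslSignal(1, a, labelDurations(schedule), postLabelDelays(schedule),
                constants, 1), numeric(length(schedule)))
  gy <- as.numeric(crossprod(g, y))       # per att
  gg <- colSums(g^2)
  ssq <- outer(cbfGrid^2, gg) - 2 * outer(cbfGrid, gy) + sum(y^2)
  ix <- arrayInd(which.min(ssq), dim(ssq))
  list(cbf = cbfGrid[ix[1]], att = attGrid[ix[2]],
       ssq = ssq[ix[1], ix[2]])
}

# Brute-force 6-connected erosion by explicit neighbour loops.
bruteErode <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- TRUE
    for (off in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                     c(0, 0, -1), c(0, 0, 1))) {
      p <- c(i, j, k) + off
      if (any(p < 1) || any(p > d)) { nb <- FALSE; break }
      if (!mask[p[1], p[2], p[3]]) { nb <- FALSE; break }
    }
    out[i, j, k] <- nb
  }
  out
}

# Direct re-implementation of the Bland-Altman statistics from the raw
# paired table, written independently of the package functions.
bruteRepeatability <- function(x1, x2) {
  n <- length(x1)
  s <- 0
  for (i in seq_len(n)) s <- s + (x1[i] - x2[i])^2
  sigma <- sqrt(s / (2 * n))
  gm <- sum(x1 + x2) / (2 * n)
  list(sigma = sigma, cov = 100 * sigma / gm)
}

# A respiratory trace with explicit, possibly different plateau levels per
# breath, assembled directly (independent of simulateRespTrace).
manualTrace <- function(plateaus, inspired = 20.9, hz = 10) {
  breath <- function(low) c(rep(inspired, 10),
                            seq(inspired, low, length.out = 8)[2:7],
                            rep(low, 12),
                            seq(low, inspired, length.out = 8)[2:7])
  respiratoryTrace(c(unlist(lapply(plateaus, breath)), rep(inspired, 10)),
                   samplingHz = hz)
}
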