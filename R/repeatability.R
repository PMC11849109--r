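# Test-retest repeatability: Bland-Altman within-subject SD and CoV.

#' Bland-Altman within-subject standard deviation
#'
#' \deqn{\sigma_{inter} = \sqrt{\sum_i (x_{1i} - x_{2i})^2 / 2n}}
#' over \eqn{n} paired test-retest measurements.
#'
#' @param x1,x2 Paired numeric vectors (session 1 and 2), length n >= 2.
#' @return \eqn{\sigma_{inter}} in the units of the measurements.
#' @examples
#' withinSubjectSD(c(40, 50, 60), c(44, 48, 60))  # sqrt(20/6)
#' @export
withinSubjectSD <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("x1 and x2 must be paired")
  if (length(x1) < 2) stop("need at least 2 subjects")
  if (any(!is.finite(x1)) || any(!is.finite(x2)))
    stop("values must be finite")
  sqrt(sum((x1 - x2)^2) / (2 * length(x1)))
}

#' Inter-session within-subject coefficient of variation
#'
#' \code{100 * withinSubjectSD(x1, x2) / mean(c(x1, x2))}: the
#' within-subject SD as a percentage of the grand mean of both sessions'
#' values (per-subject means average to the same number).
#'
#' @inheritParams withinSubjectSD
#' @return CoV in percent.
#' @export
covInterSession <- function(x1, x2) {
  m <- mean(c(x1, x2))
  if (m == 0) stop("mean value is zero; CoV undefined")
  100 * withinSubjectSD(x1, x2) / m
}

#' Regional repeatability table
#'
#' From a regional table with exactly two sessions per subject, computes
#' per (territory, parameter): the mean, the standard error of the
#' between-subject mean (from session-averaged values) and the
#' inter-session CoV.
#'
#' @param table Data frame with columns subject, session, territory and
#'   the parameter columns.
#' @param parameters Character vector of parameter column names.
#' @return Data frame (territory x parameter) with mean, stdError, sigmaInter
#'   and cov columns.
#' @export
repeatabilityTable <- function(table,
                               parameters = c("oef", "cbf", "att", "cmro2")) {
  stopifnot(all(c("subject", "session", "territory") %in% names(table)))
  sess <- sort(unique(table$session))
  if (length(sess) != 2)
    stop("repeatability needs exactly 2 sessions; found ", length(sess))
  out <- list()
  for (terr in unique(table$territory)) {
    t1 <- table[table$territory == terr & table$session == sess[1], ]
    t2 <- table[table$territory == terr & table$session == sess[2], ]
    t2 <- t2[match(t1$subject, t2$subject), ]
    for (p in parameters) {
      x1 <- t1[[p]]; x2 <- t2[[p]]
      ok <- is.finite(x1) & is.finite(x2)
      x1 <- x1[ok]; x2 <- x2[ok]
      if (length(x1) < 2) next
      subjMean <- (x1 + x2) / 2
      out[[length(out) + 1]] <- data.frame(
        territory = terr, parameter = p, n = length(x1),
        mean = mean(c(x1, x2)),
        stdError = stats::sd(subjMean) / sqrt(length(subjMean)),
        sigmaInter = withinSubjectSD(x1, x2),
        cov = covInterSession(x1, x2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
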