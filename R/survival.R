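# Survival endpoints: Kaplan-Meier product-limit estimation, the Mantel-Cox
# (log-rank) two-group test with the O/E hazard-ratio pair, and the
# maximally-selected expression cutpoint. The estimators are computed from
# first principles (they are small, and their conventions -- tie handling,
# median definition, reciprocal hazard-ratio reporting -- are part of the
# interface); the survival package serves as an independent cross-check in
# the test suite.

checkSurvivalRecords <- function(time, event) {
  if (!length(time)) stop("need at least one record")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' Censored records tied with an event time are considered at risk for the
#' events at that time (standard convention). The median is the smallest
#' time at which the survival estimate drops to 0.5 or below; when the
#' curve never reaches 0.5 the median is `NA` (flagged undefined).
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return list with `table` (data.frame `time`, `nRisk`, `nEvent`,
#'   `nCensor`, `survival` at each distinct event time), `median`, `n`.
#' @export
kmEstimate <- function(time, event) {
  checkSurvivalRecords(time, event)
  n <- length(time)
  tt <- sort(unique(time[event == 1]))
  surv <- 1
  rows <- lapply(tt, function(t0) {
    atRisk <- sum(time >= t0)
    d <- sum(time == t0 & event == 1)
    cens <- sum(time == t0 & event == 0)
    data.frame(time = t0, nRisk = atRisk, nEvent = d, nCensor = cens)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(), nRisk = numeric(), nEvent = numeric(),
               nCensor = numeric())
  tab$survival <- cumprod(1 - tab$nEvent / tab$nRisk)
  # tolerance so that a product-limit step landing exactly on 1/2 counts
  reached <- tab$survival <= 0.5 + 1e-12
  med <- if (any(reached)) min(tab$time[reached]) else NA_real_
  list(table = tab, median = med, n = n)
}

#' Mantel-Cox log-rank test with O/E hazard-ratio pair
#'
#' Pools the distinct event times of both groups; at each, the observed
#' events in group B are compared with their hypergeometric expectation,
#' giving the Mantel-Cox chi-square statistic (1 df). The hazard ratio is
#' the observed/expected ratio `HR(B/A) = (O_B/E_B) / (O_A/E_A)`; the
#' reciprocal pair `HR(A/B) * HR(B/A) = 1` holds exactly. A group with zero
#' events gives an `NA` (flagged) hazard ratio while the test is still
#' computed.
#'
#' @param timeA,eventA records of group A.
#' @param timeB,eventB records of group B.
#' @return list with `chisq`, `p`, `hrBA`, `hrAB`, `observed`, `expected`.
#' @export
logrankHazardRatio <- function(timeA, eventA, timeB, eventB) {
  checkSurvivalRecords(timeA, eventA)
  checkSurvivalRecords(timeB, eventB)
  time <- c(timeA, timeB); event <- c(eventA, eventB)
  grp <- rep(c(0L, 1L), c(length(timeA), length(timeB)))  # 1 = B
  tt <- sort(unique(time[event == 1]))
  O <- c(A = 0, B = 0); E <- c(A = 0, B = 0); V <- 0
  for (t0 in tt) {
    at <- time >= t0
    n1 <- sum(at & grp == 1L); n0 <- sum(at & grp == 0L)
    nn <- n0 + n1
    d1 <- sum(time == t0 & event == 1 & grp == 1L)
    d0 <- sum(time == t0 & event == 1 & grp == 0L)
    dd <- d0 + d1
    O <- O + c(d0, d1)
    E <- E + c(n0, n1) * dd / nn
    if (nn > 1) V <- V + dd * (n1 / nn) * (n0 / nn) * (nn - dd) / (nn - 1)
  }
  chisq <- if (V > 0) (O[["B"]] - E[["B"]])^2 / V else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  hrBA <- if (O[["A"]] > 0 && O[["B"]] > 0)
    (O[["B"]] / E[["B"]]) / (O[["A"]] / E[["A"]]) else NA_real_
  list(chisq = unname(chisq), p = unname(p),
       hrBA = hrBA, hrAB = if (is.na(hrBA)) NA_real_ else 1 / hrBA,
       observed = O, expected = E)
}

#' Maximally-selected survival cutpoint for a continuous marker
#'
#' Splits the cohort at every observed marker value inside the percentile
#' bounds and returns the threshold that maximizes the log-rank statistic
#' between the resulting low (marker <= threshold) and high groups --
#' the procedure used to dichotomize expression scores against survival.
#' Ties are resolved to the smallest threshold. The maximally-selected
#' statistic is biased: the naive p-value attached to it is NOT corrected
#' for the search, and a warning says so.
#'
#' @param time,event survival records (>= 4).
#' @param marker continuous marker values (not all equal).
#' @param bounds percentile search bounds (default 10th to 90th).
#' @return list with `threshold`, `statistic`, `pNaive`, `nLow`, `nHigh`
#'   and `candidates` (the searched thresholds with their statistics).
#' @export
survivalCutpoint <- function(time, event, marker, bounds = c(0.1, 0.9)) {
  checkSurvivalRecords(time, event)
  if (length(time) < 4) stop("need at least 4 records")
  if (length(unique(marker)) < 2) stop("marker values are all equal")
  qb <- stats::quantile(marker, bounds, names = FALSE)
  cand <- sort(unique(marker[marker >= qb[1] & marker <= qb[2]]))
  # a threshold must leave both sides non-empty
  cand <- cand[vapply(cand, function(cc)
    any(marker <= cc) && any(marker > cc), TRUE)]
  if (!length(cand)) stop("no candidate threshold inside the bounds")
  stat <- vapply(cand, function(cc) {
    lo <- marker <= cc
    logrankHazardRatio(time[lo], event[lo], time[!lo], event[!lo])$chisq
  }, 0)
  best <- which.max(stat)  # which.max takes the first (smallest) on ties
  thr <- cand[best]
  warning("maximally selected statistic: the naive p-value is not ",
          "corrected for the threshold search")
  list(threshold = thr, statistic = stat[best],
       pNaive = stats::pchisq(stat[best], 1, lower.tail = FALSE),
       nLow = sum(marker <= thr), nHigh = sum(marker > thr),
       candidates = data.frame(threshold = cand, statistic = stat))
}
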