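# Synthetic survival cohorts: exponential or Weibull event times per group
# with administrative censoring, and an optional continuous marker with a
# planted cutpoint above which the hazard is multiplied by a stated ratio.

#' Specification of a synthetic survival cohort
#'
#' Each element of `groups` is a list with `label`, `dist` ("exponential"
#' or "weibull"), `rate` (exponential) or `shape`/`scale` (Weibull), and
#' `n`. An optional `marker` plants a continuous marker: uniform on (0, 1),
#' with the hazard multiplied by `hrAbove` for records whose marker exceeds
#' `cutpoint` (single-group cohorts are typical for the cutpoint search).
#'
#' @param groups list of group specifications (see Details).
#' @param censorTime administrative censoring time (same units as the event
#'   times); events after it are censored at it.
#' @param marker optional list(cutpoint, hrAbove).
#' @param seed RNG seed.
#' @return validated list of class `survivalCohortSpec`.
#' @export
survivalCohortSpec <- function(groups = list(
                                 list(label = "A", dist = "exponential",
                                      rate = 0.1, n = 30),
                                 list(label = "B", dist = "exponential",
                                      rate = 0.27, n = 30)),
                               censorTime = Inf, marker = NULL,
                               seed = 1L) {
  for (g in groups) {
    stopifnot(!is.null(g$label), g$n >= 1,
              g$dist %in% c("exponential", "weibull"))
    if (g$dist == "exponential") stopifnot(g$rate > 0)
    else stopifnot(g$shape > 0, g$scale > 0)
  }
  stopifnot(censorTime >= 0)
  if (!is.null(marker))
    stopifnot(marker$cutpoint > 0, marker$cutpoint < 1, marker$hrAbove > 0)
  spec <- list(groups = groups, censorTime = censorTime, marker = marker,
               seed = as.integer(seed))
  class(spec) <- "survivalCohortSpec"
  spec
}

#' Generate a synthetic survival cohort
#'
#' @param spec a [survivalCohortSpec()].
#' @return list with `data` (data.frame `id`, `time`, `event`, `group`, and
#'   `marker` when planted) and `truth` (the spec's hazards, censoring time
#'   and marker plant).
#' @export
generateSurvivalCohort <- function(spec) {
  stopifnot(inherits(spec, "survivalCohortSpec"))
  withSeed(spec$seed, {
    rows <- list()
    for (g in spec$groups) {
      mk <- if (!is.null(spec$marker)) stats::runif(g$n) else
        rep(NA_real_, g$n)
      hrMult <- if (!is.null(spec$marker))
        ifelse(mk > spec$marker$cutpoint, spec$marker$hrAbove, 1) else
        rep(1, g$n)
      t <- if (g$dist == "exponential")
        stats::rexp(g$n, rate = g$rate * hrMult)
      else
        # proportional-hazards Weibull: multiply hazard by hrMult
        stats::rweibull(g$n, shape = g$shape,
                        scale = g$scale / hrMult^(1 / g$shape))
      event <- as.integer(t <= spec$censorTime)
      time <- pmin(t, spec$censorTime)
      # time > 0 invariant: censoring at 0 yields zero-time censored records
      time <- pmax(time, .Machine$double.eps)
      rows[[g$label]] <- data.frame(
        id = sprintf("%s_%03d", g$label, seq_len(g$n)),
        time = time, event = event, group = g$label, marker = mk,
        stringsAsFactors = FALSE)
    }
    dat <- do.call(rbind, c(rows, make.row.names = FALSE))
    if (is.null(spec$marker)) dat$marker <- NULL
    list(data = dat,
         truth = list(groups = spec$groups, censorTime = spec$censorTime,
                      marker = spec$marker))
  })
}

#' Simulate a morphometric profile cohort with planted classes
#'
#' Draws per-sample 12-variable profiles as multivariate normal around
#' class-specific means -- a lightweight stand-in for running the full
#' phantom-morphometry chain when only the staging statistics are under
#' test (Z-scores, PCA, clustering).
#'
#' @param classMeans numeric matrix, classes x 12 variables (rownames are
#'   class labels; colnames default to `profileVariableNames()`).
#' @param nPerClass samples per class (recycled).
#' @param sd within-class sd, one value or per-variable vector.
#' @param seed RNG seed.
#' @return data.frame in the layout of [morphometricProfile()] output.
#' @export
simulateProfileCohort <- function(classMeans, nPerClass = 7, sd = 1,
                                  seed = 1L) {
  stopifnot(is.matrix(classMeans), ncol(classMeans) == 12,
            !is.null(rownames(classMeans)))
  if (is.null(colnames(classMeans)))
    colnames(classMeans) <- profileVariableNames()
  nPerClass <- rep(nPerClass, length.out = nrow(classMeans))
  sd <- rep(sd, length.out = 12)
  withSeed(seed, {
    rows <- list()
    for (ci in seq_len(nrow(classMeans))) {
      cl <- rownames(classMeans)[ci]
      for (i in seq_len(nPerClass[ci])) {
        x <- stats::rnorm(12, classMeans[ci, ], sd)
        rows[[paste0(cl, i)]] <- data.frame(
          sample_id = sprintf("%s_%02d", cl, i), class = cl,
          t(stats::setNames(x, colnames(classMeans))),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}
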