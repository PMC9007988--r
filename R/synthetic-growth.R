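# Synthetic longitudinal log-bioluminescence cohorts from the generative
# Gompertz model: for mouse i of group g at day t,
#   log y_i(t) = log b_i + exp(-a_i t) (z0_i - log b_i) + eps,
# with log b_i = mean_logb[g] + eta_b (normal) and a_i = mean_a[g] + eta_a
# (normal truncated to a_i > 0, so every simulated curve saturates), and an
# independent normal z0_i. The same mean function and truncation are used by
# the fitter, so generator and model share one likelihood.

#' Specification of a two-group synthetic growth cohort
#'
#' @param groups character(2) group labels (control first); defaults to
#'   vehicle (`"AA"`) versus chemical sympathectomy (`"6-OHDA"`).
#' @param meanLogB numeric(2) group means of the asymptotic log level.
#' @param meanA numeric(2) group means of the rate (1/day, > 0).
#' @param sdEtaB,sdEtaA sd of the mouse effects on log b and a (shared
#'   across groups).
#' @param meanZ0,sdZ0 mean and sd of the log level at t = 0.
#' @param sdEps residual sd of the observation noise.
#' @param nMice mice per group (recycled to length 2).
#' @param days observation days, strictly increasing.
#' @param seed RNG seed.
#' @return validated list of class `growthCohortSpec`.
#' @export
growthCohortSpec <- function(groups = c("AA", "6-OHDA"),
                             meanLogB = c(6, 7), meanA = c(0.4, 0.3),
                             sdEtaB = 0.3, sdEtaA = 0.1,
                             meanZ0 = 2, sdZ0 = 0.5, sdEps = 0.3,
                             nMice = 10, days = seq(0, 21, by = 3),
                             seed = 1L) {
  nMice <- rep(as.integer(nMice), length.out = 2)
  spec <- list(groups = as.character(groups), meanLogB = meanLogB,
               meanA = meanA, sdEtaB = sdEtaB, sdEtaA = sdEtaA,
               meanZ0 = meanZ0, sdZ0 = sdZ0, sdEps = sdEps,
               nMice = nMice, days = days, seed = as.integer(seed))
  stopifnot(length(spec$groups) == 2, length(meanLogB) == 2,
            length(meanA) == 2, all(meanA > 0), sdEtaB >= 0, sdEtaA >= 0,
            sdZ0 >= 0, sdEps >= 0, all(nMice >= 1),
            length(days) >= 1, !is.unsorted(days, strictly = TRUE))
  class(spec) <- "growthCohortSpec"
  spec
}

rtruncnormPos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- stats::rnorm(sum(bad), mean, sd)
  out
}

#' Generate a synthetic growth cohort with planted parameters
#'
#' @param spec a [growthCohortSpec()].
#' @return list with `data` (data.frame `mouse_id`, `group`, `day`,
#'   `log_biolum`) and `truth` (`mouse`: per-mouse `log_b`, `a`, `z0`;
#'   `group`: the planted group means; `sds`: the variance components).
#' @export
generateGrowthCohort <- function(spec) {
  stopifnot(inherits(spec, "growthCohortSpec"))
  withSeed(spec$seed, {
    rows <- list(); mrows <- list()
    for (g in 1:2) {
      for (m in seq_len(spec$nMice[g])) {
        id <- sprintf("%s_%02d", spec$groups[g], m)
        logb <- spec$meanLogB[g] + stats::rnorm(1, 0, spec$sdEtaB)
        a <- rtruncnormPos(1, spec$meanA[g], spec$sdEtaA)
        z0 <- stats::rnorm(1, spec$meanZ0, spec$sdZ0)
        mu <- gompertzLogMean(spec$days, logb, a, z0)
        y <- mu + stats::rnorm(length(spec$days), 0, spec$sdEps)
        rows[[id]] <- data.frame(mouse_id = id, group = spec$groups[g],
                                 day = spec$days, log_biolum = y,
                                 stringsAsFactors = FALSE)
        mrows[[id]] <- data.frame(mouse_id = id, group = spec$groups[g],
                                  log_b = logb, a = a, z0 = z0,
                                  stringsAsFactors = FALSE)
      }
    }
    list(data = do.call(rbind, c(rows, make.row.names = FALSE)),
         truth = list(
           mouse = do.call(rbind, c(mrows, make.row.names = FALSE)),
           group = data.frame(group = spec$groups,
                              mean_log_b = spec$meanLogB,
                              mean_a = spec$meanA,
                              stringsAsFactors = FALSE),
           sds = c(sdEtaB = spec$sdEtaB, sdEtaA = spec$sdEtaA,
                   sdZ0 = spec$sdZ0, sdEps = spec$sdEps)))
  })
}
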