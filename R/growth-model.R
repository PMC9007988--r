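# Hierarchical Bayesian Gompertz growth model for longitudinal
# log-bioluminescence data.
#
# Observation model, mouse i at day t:
#   log y_i(t) = log b_i + exp(-a_i t) (z0_i - log b_i) + eps,
#   eps ~ N(0, sigma_eps^2)
# Hierarchy:
#   log b_i = mean_log_b[g(i)] + eta_b,  eta_b ~ N(0, sigma_b^2)
#   a_i     = mean_a[g(i)]     + eta_a,  eta_a ~ N(0, sigma_a^2), a_i > 0
#   z0_i ~ N(z0_mean, z0_sd^2)   (nuisance level at t = 0)
# Priors (weakly informative, scale-aware; recorded in the fit object):
#   mean_log_b ~ N(max log y, 5^2); mean_a ~ half-N(1);
#   all sds ~ half-N(1).
# The posterior is sampled by MCMC through JAGS; convergence is summarized
# by split-Rhat and effective sample size, and the fit fails loudly
# (configurably) when split-Rhat exceeds its threshold.

#' Gompertz mean of the log signal
#'
#' `log_b + exp(-a t) (z0 - log_b)`: the log level saturates at `log_b`
#' (the asymptotic plateau) at exponential rate `a` from the initial value
#' `z0` at t = 0.
#'
#' @param t time in days (vectorized).
#' @param logB asymptotic log level.
#' @param a rate, 1/day; must be > 0.
#' @param z0 log level at t = 0.
#' @return numeric vector of log levels.
#' @examples
#' gompertzLogMean(0, logB = 5, a = 0.3, z0 = 1)   # z0
#' gompertzLogMean(log(2), logB = 2, a = 1, z0 = 0) # exactly 1
#' @export
gompertzLogMean <- function(t, logB, a, z0) {
  if (any(a <= 0)) stop("rate a must be > 0")
  # algebraically logB + exp(-a t) (z0 - logB); written so that t = 0
  # returns z0 exactly in floating point
  z0 + (1 - exp(-a * t)) * (logB - z0)
}

gompertzModelString <- "
model {
  for (n in 1:N) {
    mu[n] <- logb[mouse[n]] + exp(-a[mouse[n]] * t[n]) *
             (z0[mouse[n]] - logb[mouse[n]])
    y[n] ~ dnorm(mu[n], tau_eps)
  }
  for (i in 1:M) {
    logb[i] ~ dnorm(mu_b[g[i]], tau_b)
    a[i] ~ dnorm(mu_a[g[i]], tau_a) T(0,)
    z0[i] ~ dnorm(z0_mean, z0_tau)
  }
  for (k in 1:G) {
    mu_b[k] ~ dnorm(b_mean, b_tau)
    mu_a[k] ~ dnorm(0, a_tau) T(0,)
  }
  sigma_eps ~ dnorm(0, sd_tau) T(0,)
  sigma_b ~ dnorm(0, sd_tau) T(0,)
  sigma_a ~ dnorm(0, sd_tau) T(0,)
  tau_eps <- 1 / (sigma_eps * sigma_eps)
  tau_b <- 1 / (sigma_b * sigma_b)
  tau_a <- 1 / (sigma_a * sigma_a)
}"

# split-Rhat: each chain halved, potential scale reduction over the halves
splitRhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- length(ch) %/% 2
    halves <- c(halves, list(ch[seq_len(n)], ch[n + seq_len(n)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical Gompertz model by MCMC
#'
#' @param data data.frame with columns `mouse_id`, `group`, `day` and
#'   either `log_biolum` or `raw_biolum` (raw values are floored at
#'   `detectionLimit` before the log transform, with a message).
#' @param priors optional overrides: `bMean`, `bSd`, `aSd`, `z0Mean`,
#'   `z0Sd`, `sdScale`.
#' @param chains,warmup,draws MCMC layout (default 4 chains, 2000 warmup,
#'   2000 kept draws per chain).
#' @param thin thinning interval.
#' @param seed integer seed (mandatory); drives every chain's RNG.
#' @param rhatThreshold split-Rhat threshold for the convergence check.
#' @param onBadFit `"error"` (default), `"warning"` or `"none"` when the
#'   threshold is exceeded.
#' @param detectionLimit floor for raw bioluminescence below detection.
#' @return a [GompertzFit-class].
#' @export
fitGompertzHierarchy <- function(data, priors = list(), chains = 4,
                                 warmup = 2000, draws = 2000, thin = 1,
                                 seed, rhatThreshold = 1.01,
                                 onBadFit = c("error", "warning", "none"),
                                 detectionLimit = 1) {
  onBadFit <- match.arg(onBadFit)
  if (missing(seed)) stop("a seed is mandatory")
  seed <- as.integer(seed)
  if (!nrow(data)) stop("empty cohort")
  if (!"log_biolum" %in% names(data)) {
    if (!"raw_biolum" %in% names(data))
      stop("data needs a log_biolum or raw_biolum column")
    nlow <- sum(data$raw_biolum <= detectionLimit)
    if (nlow) message(nlow, " raw value(s) at or below the detection limit ",
                      detectionLimit, " floored before log transform")
    data$log_biolum <- log(pmax(data$raw_biolum, detectionLimit))
  }
  need <- c("mouse_id", "group", "day", "log_biolum")
  stopifnot(all(need %in% names(data)))
  if (any(!is.finite(data$log_biolum)) || any(!is.finite(data$day)))
    stop("non-finite values in cohort data")

  mice <- unique(data[, c("mouse_id", "group")])
  if (anyDuplicated(mice$mouse_id))
    stop("a mouse_id appears in more than one group")
  groups <- unique(as.character(mice$group))
  mice$index <- seq_len(nrow(mice))
  nobs <- table(data$mouse_id)
  if (any(nobs < 2))
    warning(sum(nobs < 2), " mouse/mice with fewer than 2 observations; ",
            "their parameters are informed by partial pooling only")

  firstObs <- vapply(split(data, data$mouse_id), function(d)
    d$log_biolum[which.min(d$day)], 0)
  p <- utils::modifyList(
    list(bMean = max(data$log_biolum), bSd = 5, aSd = 1,
         z0Mean = mean(firstObs), z0Sd = 5, sdScale = 1),
    priors)

  jdata <- list(
    N = nrow(data), M = nrow(mice), G = length(groups),
    y = data$log_biolum, t = data$day,
    mouse = mice$index[match(data$mouse_id, mice$mouse_id)],
    g = match(mice$group, groups),
    b_mean = p$bMean, b_tau = 1 / p$bSd^2, a_tau = 1 / p$aSd^2,
    z0_mean = p$z0Mean, z0_tau = 1 / p$z0Sd^2,
    sd_tau = 1 / p$sdScale^2)

  inits <- lapply(seq_len(chains), function(ch) {
    list(mu_b = rep(p$bMean, length(groups)),
         mu_a = rep(0.3, length(groups)),
         logb = vapply(split(data, data$mouse_id)[mice$mouse_id],
                       function(d) max(d$log_biolum), 0) + 0.1,
         a = rep(0.3, nrow(mice)),
         z0 = unname(firstObs[mice$mouse_id]),
         sigma_eps = 0.5, sigma_b = 0.5, sigma_a = 0.2,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1009L + ch) %% 2147483647L)
  })

  model <- rjags::jags.model(textConnection(gompertzModelString),
                             data = jdata, inits = inits, n.chains = chains,
                             n.adapt = max(200, warmup %/% 2), quiet = TRUE)
  stats::update(model, n.iter = warmup, progress.bar = "none")
  monitor <- c("mu_b", "mu_a", "sigma_eps", "sigma_b", "sigma_a",
               "logb", "a", "z0")
  samp <- rjags::coda.samples(model, monitor, n.iter = draws * thin,
                              thin = thin, progress.bar = "none")

  # readable parameter names (JAGS drops the [1] index on singletons)
  rename <- function(nm) {
    out <- nm
    if (length(groups) == 1) {
      out[out == "mu_b"] <- "mu_b[1]"
      out[out == "mu_a"] <- "mu_a[1]"
    }
    if (nrow(mice) == 1) {
      out[out == "logb"] <- "logb[1]"
      out[out == "a"] <- "a[1]"
      out[out == "z0"] <- "z0[1]"
    }
    for (k in seq_along(groups)) {
      out[out == sprintf("mu_b[%d]", k)] <-
        sprintf("mean_log_b[%s]", groups[k])
      out[out == sprintf("mu_a[%d]", k)] <- sprintf("mean_a[%s]", groups[k])
    }
    for (i in seq_len(nrow(mice))) {
      out[out == sprintf("logb[%d]", i)] <-
        sprintf("log_b[%s]", mice$mouse_id[i])
      out[out == sprintf("a[%d]", i)] <- sprintf("a[%s]", mice$mouse_id[i])
      out[out == sprintf("z0[%d]", i)] <- sprintf("z0[%s]", mice$mouse_id[i])
    }
    out
  }
  for (ch in seq_along(samp))
    colnames(samp[[ch]]) <- rename(colnames(samp[[ch]]))

  pars <- colnames(samp[[1]])
  rhat <- vapply(pars, function(pp)
    splitRhat(lapply(samp, function(ch) as.numeric(ch[, pp]))), 0)
  ess <- vapply(pars, function(pp)
    sum(vapply(samp, function(ch)
      as.numeric(coda::effectiveSize(as.numeric(ch[, pp]))), 0)), 0)
  diag <- data.frame(parameter = pars, rhat = unname(rhat),
                     ess = unname(ess), stringsAsFactors = FALSE)
  bad <- diag$parameter[diag$rhat > rhatThreshold]
  if (length(bad)) {
    msg <- sprintf("split-Rhat above %.3f for %d parameter(s): %s",
                   rhatThreshold, length(bad),
                   paste(utils::head(bad, 5), collapse = ", "))
    if (onBadFit == "error") stop(msg)
    if (onBadFit == "warning") warning(msg)
  }
  new("GompertzFit", draws = samp, diagnostics = diag, groups = groups,
      mice = mice, data = data, priors = p, seed = seed)
}

drawMatrix <- function(fit) {
  do.call(rbind, lapply(fit@draws, unclass))
}

#' Posterior probability that one group's parameter exceeds the other's
#'
#' Draw-wise (chains pooled, iterations matched) probability that the
#' second group's group-level parameter exceeds the first group's; exact
#' ties contribute one half. With the default group order this is the
#' posterior probability that the sympathectomized group exceeds the
#' control group.
#'
#' @param fit a [GompertzFit-class].
#' @param parameter `"log_b"` (asymptotic log level) or `"a"` (rate).
#' @param groups character(2); defaults to the fit's group order.
#' @return probability in `[0, 1]`.
#' @export
groupDifferenceProbability <- function(fit, parameter = c("log_b", "a"),
                                       groups = NULL) {
  parameter <- match.arg(parameter)
  if (is.null(groups)) groups <- fit@groups
  if (length(groups) != 2 || !all(groups %in% fit@groups))
    stop("need two groups present in the fit")
  base <- if (parameter == "log_b") "mean_log_b" else "mean_a"
  dm <- drawMatrix(fit)
  x1 <- dm[, sprintf("%s[%s]", base, groups[1])]
  x2 <- dm[, sprintf("%s[%s]", base, groups[2])]
  mean((x2 > x1) + 0.5 * (x2 == x1))
}

#' Bivariate HPD credible regions of the group-level parameters
#'
#' Kernel-density highest-posterior-density regions of
#' (mean log b, mean a) per group at the requested probabilities, nested by
#' construction, plus boxplot-convention marginal summaries (median,
#' quartiles, 1.5 IQR whiskers shortened to the most extreme draw inside
#' them).
#'
#' @param fit a [GompertzFit-class] with >= 500 pooled draws.
#' @param probs region probabilities.
#' @param gridN kernel-density grid resolution per axis.
#' @return named list per group: `levels` (density thresholds), `areas`
#'   (region areas in parameter units), `contours`
#'   ([grDevices::contourLines] output per probability), `marginals`
#'   (five-number summaries for both parameters), `draws`.
#' @export
credibleRegions2d <- function(fit, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                              gridN = 101) {
  dm <- drawMatrix(fit)
  if (nrow(dm) < 500) stop("need at least 500 draws for HPD regions")
  probs <- sort(probs)
  out <- list()
  for (g in fit@groups) {
    x <- dm[, sprintf("mean_log_b[%s]", g)]
    y <- dm[, sprintf("mean_a[%s]", g)]
    padx <- 0.3 * (max(x) - min(x)) + 1e-9
    pady <- 0.3 * (max(y) - min(y)) + 1e-9
    kd <- MASS::kde2d(x, y, n = gridN,
                      lims = c(min(x) - padx, max(x) + padx,
                               min(y) - pady, max(y) + pady))
    cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
    dens <- sort(as.numeric(kd$z), decreasing = TRUE)
    cum <- cumsum(dens * cell) / sum(dens * cell)
    levels <- vapply(probs, function(pp) dens[which(cum >= pp)[1]], 0)
    areas <- vapply(levels, function(lv) sum(kd$z >= lv) * cell, 0)
    contours <- lapply(levels, function(lv)
      grDevices::contourLines(kd$x, kd$y, kd$z, levels = lv))
    marg <- function(v) {
      st <- grDevices::boxplot.stats(v, coef = 1.5, do.out = TRUE)$stats
      c(whiskerLow = st[1], q1 = st[2], median = st[3], q3 = st[4],
        whiskerHigh = st[5])
    }
    out[[g]] <- list(probs = probs, levels = levels, areas = areas,
                     contours = contours,
                     marginals = list(mean_log_b = marg(x), mean_a = marg(y)),
                     draws = cbind(mean_log_b = x, mean_a = y))
  }
  out
}

#' Posterior predictive growth-curve bands
#'
#' Central 0.5 and 0.95 intervals of the mouse-level (or group-level) mean
#' growth curve at the requested times; optionally observation-level bands
#' that add the residual noise.
#'
#' @param fit a [GompertzFit-class].
#' @param mouse a mouse id present in the fit, or `NULL`.
#' @param group a group label (used when `mouse` is `NULL`): the band of
#'   the group-mean curve, with z0 taken as the per-draw mean of the
#'   group's mouse-level z0.
#' @param times numeric vector of days.
#' @param includeNoise also return observation-level bands (flagged in the
#'   `type` column).
#' @return data.frame: `time`, `type` (`"mean"`/`"observation"`),
#'   `median`, `lo50`, `hi50`, `lo95`, `hi95`.
#' @export
posteriorPredictive <- function(fit, mouse = NULL, group = NULL, times,
                                includeNoise = FALSE) {
  stopifnot(all(is.finite(times)))
  dm <- drawMatrix(fit)
  if (!is.null(mouse)) {
    if (!mouse %in% fit@mice$mouse_id) stop("unknown mouse id: ", mouse)
    logb <- dm[, sprintf("log_b[%s]", mouse)]
    a <- dm[, sprintf("a[%s]", mouse)]
    z0 <- dm[, sprintf("z0[%s]", mouse)]
  } else {
    if (is.null(group) || !group %in% fit@groups)
      stop("give a mouse id or a group label present in the fit")
    logb <- dm[, sprintf("mean_log_b[%s]", group)]
    a <- dm[, sprintf("mean_a[%s]", group)]
    ids <- fit@mice$mouse_id[fit@mice$group == group]
    z0 <- rowMeans(dm[, sprintf("z0[%s]", ids), drop = FALSE])
  }
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  band <- function(curveMat, type) {
    qq <- apply(curveMat, 2, stats::quantile, probs = qs)
    data.frame(time = times, type = type, median = qq[3, ],
               lo50 = qq[2, ], hi50 = qq[4, ], lo95 = qq[1, ],
               hi95 = qq[5, ], row.names = NULL)
  }
  mcurve <- vapply(times, function(tt)
    logb + exp(-a * tt) * (z0 - logb), numeric(length(logb)))
  out <- band(mcurve, "mean")
  if (includeNoise) {
    eps <- withSeed(fit@seed + 1L,
                    matrix(stats::rnorm(length(logb) * length(times), 0,
                                        dm[, "sigma_eps"]),
                           nrow = length(logb)))
    out <- rbind(out, band(mcurve + eps, "observation"))
  }
  out
}
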