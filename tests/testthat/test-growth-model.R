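test_that("the Gompertz log-mean obeys its closed-form identities", {
  expect_equal(gompertzLogMean(0, logB = 5, a = 0.7, z0 = 1.3), 1.3)
  expect_equal(gompertzLogMean(log(2), logB = 2, a = 1, z0 = 0), 1.0)
  expect_lt(abs(gompertzLogMean(100, logB = 4.2, a = 0.3, z0 = 1) - 4.2),
            1e-12)
  expect_error(gompertzLogMean(1, logB = 5, a = 0, z0 = 1))
  expect_error(gompertzLogMean(1, logB = 5, a = -0.2, z0 = 1))
})

test_that("a noiseless mouse concentrates the posterior at the NLS fit", {
  skip_if_not_installed("minpack.lm")
  days <- seq(0, 21, 3)
  set.seed(2)
  y <- gompertzLogMean(days, logB = 6.2, a = 0.4, z0 = 1.5) +
    rnorm(length(days), 0, 0.001)
  dat <- data.frame(mouse_id = "m1", group = "G", day = days,
                    log_biolum = y)
  nls <- minpack.lm::nlsLM(
    log_biolum ~ lb + exp(-a * day) * (z0 - lb), data = dat,
    start = list(lb = 5, a = 0.3, z0 = 1))
  co <- coef(nls)
  fit <- fitGompertzHierarchy(dat, chains = 2, warmup = 1500, draws = 1500,
                              seed = 5, onBadFit = "none")
  dm <- pdacnerve:::drawMatrix(fit)
  expect_lt(abs(median(dm[, "log_b[m1]"]) - co[["lb"]]), 0.02)
  expect_lt(abs(median(dm[, "a[m1]"]) - co[["a"]]), 0.02)
  expect_lt(abs(median(dm[, "z0[m1]"]) - co[["z0"]]), 0.02)
})

test_that("the fit validates its inputs and reports diagnostics", {
  expect_error(fitGompertzHierarchy(data.frame(), seed = 1), "empty")
  dat <- data.frame(mouse_id = "m", group = "G", day = c(0, 3),
                    log_biolum = c(1, NA))
  expect_error(fitGompertzHierarchy(dat, seed = 1), "non-finite")
  expect_error(fitGompertzHierarchy(
    data.frame(mouse_id = "m", group = "G", day = 0, log_biolum = 1)),
    "seed")
  # raw bioluminescence is floored then logged
  raw <- data.frame(mouse_id = rep(c("m1", "m2"), each = 4),
                    group = "G", day = rep(c(0, 3, 6, 9), 2),
                    raw_biolum = c(0.5, 10, 100, 1000, 2, 20, 200, 2000))
  expect_message(
    fit <- fitGompertzHierarchy(raw, chains = 2, warmup = 300, draws = 300,
                                seed = 3, onBadFit = "none"),
    "detection limit")
  expect_s4_class(fit, "GompertzFit")
  d <- fitDiagnostics(fit)
  expect_true(all(c("parameter", "rhat", "ess") %in% names(d)))
  expect_true(all(is.finite(d$rhat)))
})

test_that("group means are recovered within posterior uncertainty", {
  spec <- growthCohortSpec(meanLogB = c(6, 7), meanA = c(0.35, 0.35),
                           sdEtaB = 0.3, sdEtaA = 0.1, sdEps = 0.3,
                           nMice = 6, days = seq(0, 21, 3), seed = 21)
  co <- generateGrowthCohort(spec)
  fit <- fitGompertzHierarchy(co$data, chains = 2, warmup = 1000,
                              draws = 1000, seed = 9, onBadFit = "none")
  dm <- pdacnerve:::drawMatrix(fit)
  for (g in 1:2) {
    x <- dm[, sprintf("mean_log_b[%s]", spec$groups[g])]
    expect_lt(abs(median(x) - spec$meanLogB[g]), 3 * sd(x))
    xa <- dm[, sprintf("mean_a[%s]", spec$groups[g])]
    expect_lt(abs(median(xa) - spec$meanA[g]), 3 * sd(xa))
  }
})

test_that("group difference probability follows the tie-aware definition", {
  mk <- function(a, b) {
    m <- cbind(a, b)
    colnames(m) <- c("mean_log_b[A]", "mean_log_b[B]")
    makeTestFit(m, groups = c("A", "B"))
  }
  # paired enumeration: every B draw exceeds its A draw
  f <- mk(c(1, 2, 3, 1, 2, 3), c(2, 3, 4, 2, 3, 4))
  expect_equal(groupDifferenceProbability(f, "log_b"), 1)
  # identical draws tie out at one half
  f2 <- mk(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(groupDifferenceProbability(f2, "log_b"), 0.5)
  expect_error(groupDifferenceProbability(f, "log_b", groups = c("A", "C")))
})

test_that("HPD credible regions match the analytic normal ellipse", {
  set.seed(31)
  n <- 4000
  sx <- 1.3; sy <- 0.6; rho <- 0.4
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  m <- cbind(5 + sx * x, 2 + sy * y)
  colnames(m) <- c("mean_log_b[A]", "mean_a[A]")
  fit <- makeTestFit(m, groups = "A")
  cr <- credibleRegions2d(fit, probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  detSigma <- (sx * sy)^2 * (1 - rho^2)
  analytic <- pi * qchisq(0.95, 2) * sqrt(detSigma)
  expect_lt(abs(cr$A$areas[5] - analytic) / analytic, 0.15)
  # nesting by construction
  expect_true(all(diff(cr$A$areas) > 0))
  expect_true(all(diff(cr$A$levels) < 0))
  # whiskers never exceed the draw range
  mg <- cr$A$marginals$mean_log_b
  expect_gte(mg[["whiskerLow"]], min(m[, 1]))
  expect_lte(mg[["whiskerHigh"]], max(m[, 1]))
  expect_error(credibleRegions2d(makeTestFit(m[1:100, ], groups = "A")),
               "500")
})

test_that("posterior predictive bands nest and honor degenerate draws", {
  n <- 600
  m <- cbind(rep(6, n), rep(0.4, n), rep(1.5, n), rep(0.3, n),
             rep(6, n), rep(0.4, n))
  colnames(m) <- c("log_b[m1]", "a[m1]", "z0[m1]", "sigma_eps",
                   "mean_log_b[G]", "mean_a[G]")
  fit <- makeTestFit(m, groups = "G", miceIds = "m1", miceGroups = "G")
  pp <- posteriorPredictive(fit, mouse = "m1", times = c(0, 5, 15))
  expect_equal(pp$lo95, pp$hi95)
  expect_equal(pp$median, gompertzLogMean(c(0, 5, 15), 6, 0.4, 1.5))
  expect_error(posteriorPredictive(fit, mouse = "nope", times = 0),
               "unknown")
  # with spread: 0.95 interval contains the 0.5 interval everywhere
  set.seed(2)
  m2 <- m
  m2[, "log_b[m1]"] <- rnorm(n, 6, 0.3)
  m2[, "a[m1]"] <- abs(rnorm(n, 0.4, 0.05))
  fit2 <- makeTestFit(m2, groups = "G", miceIds = "m1", miceGroups = "G")
  pp2 <- posteriorPredictive(fit2, mouse = "m1", times = seq(0, 20, 4))
  expect_true(all(pp2$lo95 <= pp2$lo50 + 1e-12))
  expect_true(all(pp2$hi95 >= pp2$hi50 - 1e-12))
  # group-level curve works too
  ppg <- posteriorPredictive(fit2, group = "G", times = c(0, 10))
  expect_equal(nrow(ppg), 2)
})

test_that("rescaling time leaves the plateau posterior unchanged", {
  spec <- growthCohortSpec(meanLogB = c(6, 6.8), meanA = c(0.4, 0.3),
                           sdEtaB = 0.2, sdEtaA = 0.05, sdEps = 0.2,
                           nMice = 4, days = seq(0, 21, 3), seed = 13)
  co <- generateGrowthCohort(spec)
  fit1 <- fitGompertzHierarchy(co$data, chains = 2, warmup = 800,
                               draws = 800, seed = 4, onBadFit = "none")
  co2 <- co$data
  co2$day <- co2$day / 7   # days -> weeks; rates scale by 7
  fit2 <- fitGompertzHierarchy(co2, chains = 2, warmup = 800, draws = 800,
                               seed = 4, onBadFit = "none",
                               priors = list(aSd = 7))
  d1 <- pdacnerve:::drawMatrix(fit1); d2 <- pdacnerve:::drawMatrix(fit2)
  for (g in spec$groups) {
    nm <- sprintf("mean_log_b[%s]", g)
    expect_lt(abs(median(d1[, nm]) - median(d2[, nm])),
              3 * (sd(d1[, nm]) + sd(d2[, nm])))
  }
})
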