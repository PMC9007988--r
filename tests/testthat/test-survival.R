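test_that("the product-limit estimator matches a hand-computed worked set", {
  # records: 1 (event), 2+ (censored), 3, 4, 4+, 6
  time <- c(1, 2, 3, 4, 4, 6)
  event <- c(1, 0, 1, 1, 0, 1)
  km <- kmEstimate(time, event)
  # hand product-limit: 5/6, 5/6*3/4, 5/6*3/4*2/3, 0
  expect_equal(km$table$time, c(1, 3, 4, 6))
  expect_equal(km$table$nRisk, c(6, 4, 3, 1))
  expect_equal(km$table$survival,
               c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0))
  expect_equal(km$median, 4)  # first time survival <= 0.5
  # censored records tied with an event stay at risk for it
  expect_equal(km$table$nCensor[km$table$time == 4], 1)
})

test_that("KM degenerate cases and invariants hold", {
  km <- kmEstimate(rep(5, 4), rep(1, 4))
  expect_equal(km$table$survival, 0)
  expect_equal(km$median, 5)
  kmC <- kmEstimate(c(2, 4, 8), c(0, 0, 0))
  expect_equal(nrow(kmC$table), 0)
  expect_true(is.na(kmC$median))
  expect_error(kmEstimate(c(0, 1), c(1, 1)), "positive")
  # survival is non-increasing and within [0, 1] on random data
  set.seed(12)
  for (i in 1:5) {
    tt <- rexp(25, 0.2); ev <- rbinom(25, 1, 0.7)
    s <- kmEstimate(tt, ev)$table$survival
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
  # agreement with the survival package estimator
  tt <- rexp(40, 0.1); ev <- rbinom(40, 1, 0.8)
  km2 <- kmEstimate(tt, ev)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  expect_equal(km2$table$survival, sf$surv[sf$n.event > 0])
})

test_that("the Mantel-Cox test matches a hand O/E table", {
  # A: 1, 3 (events); B: 2 (event), 4+ (censored), 5 (event)
  lr <- logrankHazardRatio(c(1, 3), c(1, 1), c(2, 4, 5), c(1, 0, 1))
  EA <- 2 / 5 + 1 / 4 + 1 / 3
  EB <- 3 / 5 + 3 / 4 + 2 / 3 + 1
  V <- 1 * (2 / 5) * (3 / 5) +
    1 * (1 / 4) * (3 / 4) +
    1 * (1 / 3) * (2 / 3)
  expect_equal(unname(lr$observed), c(2, 2))
  expect_equal(unname(lr$expected), c(EA, EB))
  expect_equal(lr$chisq, (2 - EB)^2 / V)
  expect_equal(lr$hrBA, (2 / EB) / (2 / EA))
  expect_equal(lr$hrAB * lr$hrBA, 1)
})

test_that("log-rank edge cases and symmetries behave", {
  # identical groups: no signal, unit hazard ratio
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 0, 1)
  lr <- logrankHazardRatio(tt, ev, tt, ev)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$hrBA, 1)
  # relabeling swaps the reciprocal pair, statistic unchanged
  set.seed(6)
  tA <- rexp(15, 0.1); tB <- rexp(15, 0.3)
  l1 <- logrankHazardRatio(tA, rep(1, 15), tB, rep(1, 15))
  l2 <- logrankHazardRatio(tB, rep(1, 15), tA, rep(1, 15))
  expect_equal(l1$chisq, l2$chisq)
  expect_equal(l1$hrBA, l2$hrAB)
  # independent reference implementation
  sd <- survival::survdiff(
    survival::Surv(c(tA, tB), rep(1, 30)) ~ rep(c("A", "B"), each = 15))
  expect_equal(l1$chisq, sd$chisq)
  # zero events in one group: HR flagged, test still computed
  l0 <- logrankHazardRatio(c(2, 3), c(1, 1), c(5, 6), c(0, 0))
  expect_true(is.na(l0$hrBA))
  expect_true(is.finite(l0$chisq))
})

test_that("simulated hazard ratios are recovered across replicates", {
  # the O/E estimator shrinks large ratios toward unity, so recovery is
  # checked at the band the estimator actually supports at this n
  hits <- 0; n <- 20; hrs <- numeric(n)
  for (r in seq_len(n)) {
    spec <- survivalCohortSpec(groups = list(
      list(label = "A", dist = "exponential", rate = 0.1, n = 30),
      list(label = "B", dist = "exponential", rate = 0.27, n = 30)),
      censorTime = 40, seed = 300 + r)
    co <- generateSurvivalCohort(spec)
    A <- co$data[co$data$group == "A", ]; B <- co$data[co$data$group == "B", ]
    hrs[r] <- logrankHazardRatio(A$time, A$event, B$time, B$event)$hrBA
    hits <- hits + (abs(hrs[r] - 2.7) / 2.7 <= 0.30)
  }
  expect_gte(hits / n, 0.8)
  expect_gt(median(hrs), 1.8)   # clearly away from the null
  expect_lt(median(hrs), 2.7 * 1.15)
})

test_that("the cutpoint search maximizes the split and flags its bias", {
  # a single candidate inside tight bounds is returned as-is
  tt <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ev <- rep(1, 8)
  mk <- c(1, 1, 1, 2, 2, 3, 3, 3)
  expect_warning(cp <- survivalCutpoint(tt, ev, mk, bounds = c(0.45, 0.55)),
                 "not\\s+corrected")
  expect_equal(cp$threshold, 2)
  expect_equal(cp$nLow, 5)
  expect_error(suppressWarnings(
    survivalCutpoint(tt, ev, rep(1, 8))), "equal")
  expect_error(suppressWarnings(
    survivalCutpoint(tt[1:3], ev[1:3], mk[1:3])), "4 records")
})

test_that("a planted expression threshold is recovered across replicates", {
  hits <- 0; n <- 20
  for (r in seq_len(n)) {
    spec <- survivalCohortSpec(groups = list(
      list(label = "all", dist = "exponential", rate = 0.05, n = 60)),
      censorTime = 40, marker = list(cutpoint = 0.65, hrAbove = 3),
      seed = 400 + r)
    co <- generateSurvivalCohort(spec)
    cp <- suppressWarnings(
      survivalCutpoint(co$data$time, co$data$event, co$data$marker))
    hits <- hits + (abs(cp$threshold - 0.65) <= 0.15)
  }
  expect_gte(hits / n, 0.8)
})

test_that("an uninformative marker rarely reaches extreme statistics", {
  ok <- 0; n <- 20
  set.seed(77)
  for (r in seq_len(n)) {
    tt <- rexp(40, 0.1); mk <- runif(40)
    cp <- suppressWarnings(survivalCutpoint(tt, rep(1, 40), mk))
    ok <- ok + (cp$statistic < qchisq(0.999, 1))
  }
  expect_gte(ok / n, 0.9)
})
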