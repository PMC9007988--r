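mkProfiles <- function(n, classes, means, sd = 1, seed = 1) {
  mns <- matrix(rep(means, each = length(classes)), length(classes), 12,
                dimnames = list(classes, profileVariableNames()))
  simulateProfileCohort(mns, nPerClass = n, sd = sd, seed = seed)
}

test_that("Z-scores follow the control-referenced definition cell by cell", {
  set.seed(4)
  prof <- simulateProfileCohort(
    matrix(rnorm(24, 5, 2), 2, 12,
           dimnames = list(c("control", "PanIN"), profileVariableNames())),
    nPerClass = 6, sd = 1, seed = 7)
  z <- zscoreMatrix(prof, "control")
  # scalar oracle: recompute every cell by hand
  m <- as.matrix(prof[, profileVariableNames()])
  ctrl <- m[prof$class == "control", ]
  for (j in seq_len(12)) {
    zc <- (mean(m[prof$class == "PanIN", j]) - mean(ctrl[, j])) /
      sd(ctrl[, j])
    expect_equal(unname(z["PanIN", j]), zc)
  }
  expect_equal(unname(z["control", ]), rep(0, 12))
})

test_that("Z-score edge cases: exact offsets, zero sd, few controls", {
  # a class sitting exactly at xbar_c + 2 sigma_c scores z = 2
  prof <- mkProfiles(4, c("control", "les"), rep(0, 12), sd = 1, seed = 3)
  m <- as.matrix(prof[, profileVariableNames()])
  ctrl <- prof$class == "control"
  target <- colMeans(m[ctrl, ]) + 2 * apply(m[ctrl, ], 2, sd)
  prof[!ctrl, profileVariableNames()] <-
    matrix(rep(target, each = sum(!ctrl)), sum(!ctrl), 12)
  z <- zscoreMatrix(prof, "control")
  expect_equal(unname(z["les", ]), rep(2, 12))
  # zero control sd flags the variable
  prof2 <- prof
  prof2[ctrl, "vessel_mean_radius_um"] <- 4
  z2 <- zscoreMatrix(prof2, "control")
  expect_true(is.na(z2["les", "vessel_mean_radius_um"]))
  expect_error(zscoreMatrix(prof[c(1, 5:8), ], "control"), "2 control")
})

test_that("Z-scores are invariant to rescaling a variable's units", {
  prof <- mkProfiles(5, c("control", "les"), rnorm(12, 3), seed = 9)
  z1 <- zscoreMatrix(prof, "control")
  prof2 <- prof
  prof2$axon_mean_branch_length_um <- prof2$axon_mean_branch_length_um * 1000
  z2 <- zscoreMatrix(prof2, "control")
  expect_equal(z1["les", "axon_mean_branch_length_um"],
               z2["les", "axon_mean_branch_length_um"])
})

test_that("PCA embedding is complete, ordered and sign-fixed", {
  prof <- mkProfiles(8, c("control", "les"), rnorm(12, 10, 3), seed = 2)
  pc <- pcaEmbed(prof, standardize = TRUE)
  expect_equal(sum(pc$explainedVariance), 1)
  expect_true(all(diff(pc$explainedVariance) <= 1e-12))
  # sign convention: largest-|loading| positive
  for (j in seq_len(ncol(pc$loadings)))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  # reconstruction reproduces the standardized data
  m <- scale(as.matrix(prof[, profileVariableNames()]))
  rec <- pc$scores %*% t(pc$loadings)
  expect_equal(unname(rec), unname(m[, rownames(pc$loadings)]),
               tolerance = 1e-8)
  # eigen-decomposition oracle (up to sign, handled by the convention)
  ev <- eigen(stats::cov(m))
  expect_equal(unname(pc$explainedVariance),
               ev$values / sum(ev$values), tolerance = 1e-8)
})

test_that("collinear data load entirely on the first component", {
  prof <- mkProfiles(6, "only", rep(0, 12), sd = 0, seed = 1)
  v <- rnorm(6)
  prof$axon_volume_density_pct <- v
  prof$vessel_volume_density_pct <- 2 * v
  expect_warning(pc <- pcaEmbed(prof, standardize = TRUE), "constant")
  expect_equal(pc$explainedVariance[1], 1, tolerance = 1e-12)
})

test_that("Ward clustering recovers well-separated planted classes", {
  mns <- matrix(0, 3, 12,
                dimnames = list(c("control", "lesion", "tumor"),
                                profileVariableNames()))
  mns[2, ] <- 8; mns[3, 1:6] <- -8   # >= 6 pooled sds of separation
  prof <- simulateProfileCohort(mns, nPerClass = 10, sd = 1, seed = 5)
  hc <- hierarchicalCluster(prof, k = 3, referenceLabels = prof$class)
  expect_equal(hc$ari, 1)
  expect_equal(sort(unique(hc$labels)), 1:3)
  # permutation invariance of the partition
  perm <- sample(nrow(prof))
  hc2 <- hierarchicalCluster(prof[perm, ], k = 3,
                             referenceLabels = prof$class[perm])
  expect_equal(hc2$ari, 1)
  # k = 1 puts everything together; bad k errors
  expect_equal(unname(unique(hierarchicalCluster(prof, k = 1)$labels)), 1L)
  expect_error(hierarchicalCluster(prof, k = 0))
  expect_error(hierarchicalCluster(prof, k = nrow(prof) + 1))
})

test_that("a cohort mimicking the staging design orders its groups", {
  # group 1: control-like; group 2: sprouting lesions (more, smaller
  # branches, less contact); group 3: invasive (intermediate density,
  # lesion-like contacts) -- the planted three-group structure
  base <- c(0.5, 10, 30, 4, 1.5, 4, 25, 12, 1, 150, 800, 3)
  lesion <- base + c(0.6, 25, -15, 10, 0, 1, -15, 0, 2, -80, -300, 4)
  tumor <- base + c(0.2, 20, -12, 8, 0, 1, -13, -1, 1.5, -70, -250, 6)
  mns <- rbind(control = base, asympt = base, lesion = lesion,
               tumor = tumor)
  colnames(mns) <- profileVariableNames()
  prof <- simulateProfileCohort(mns, nPerClass = c(6, 4, 8, 7),
                                sd = pmax(abs(base) * 0.08, 0.05), seed = 8)
  ref <- c(control = 1, asympt = 1, lesion = 2, tumor = 3)[prof$class]
  hc <- hierarchicalCluster(prof, k = 3, referenceLabels = ref)
  expect_gt(hc$ari, 0.9)
  # control and asymptomatic cluster together
  expect_equal(length(unique(hc$labels[prof$class %in%
                                         c("control", "asympt")])), 1)
})
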