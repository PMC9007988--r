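test_that("phantom generation is deterministic and validated", {
  spec <- tissueClassSpec("PanIN", seed = 4)
  p1 <- generateTissuePhantom(spec)
  p2 <- generateTissuePhantom(spec)
  expect_identical(maskArray(p1$axon), maskArray(p2$axon))
  expect_identical(maskArray(p1$vessel), maskArray(p2$vessel))
  expect_identical(p1$truth, p2$truth)
  expect_error(tissuePhantomSpec(alignmentFraction = 1.5))
  expect_error(tissuePhantomSpec(vesselRadius = -1))
  expect_error(tissuePhantomSpec(gridDim = c(4, 4, 4), vesselRadius = 10),
               "too small")
})

test_that("a spec with zero axons gives an empty axon mask and zero truth", {
  ph <- generateTissuePhantom(tissuePhantomSpec(axonCount = 0, seed = 1))
  expect_equal(sum(maskArray(ph$axon)), 0)
  tr <- ph$truth
  expect_equal(tr$value[tr$variable == "axon_volume_density_pct"], 0)
  expect_equal(tr$value[tr$variable == "axon_branch_count_per_mm3"], 0)
})

test_that("a rasterized straight cylinder has near-analytic volume", {
  # 100 um x radius 2 um cylinder at 1 um voxels
  tube <- rasterizeTubes(rbind(c(10, 15, 15), c(110, 15, 15)), radius = 2,
                         gridDim = c(120L, 30L, 30L), voxelSize = 1)
  analytic <- pi * 2^2 * 100
  expect_lt(abs(maskVolume(tube) - analytic) / analytic, 0.15)
})

test_that("sprouting and alignment knobs move the planted truth monotonely", {
  base <- generateTissuePhantom(tissueClassSpec("control", seed = 9))
  hot <- generateTissuePhantom(tissueClassSpec("control", seed = 9,
                                               hotspot = TRUE,
                                               hotspotMultiplier = 3))
  val <- function(ph, v) ph$truth$value[ph$truth$variable == v]
  expect_gt(val(hot, "axon_branch_count_per_mm3"),
            val(base, "axon_branch_count_per_mm3"))
  lo <- generateTissuePhantom(tissuePhantomSpec(alignmentFraction = 0.2,
                                                seed = 5))
  hi <- generateTissuePhantom(tissuePhantomSpec(alignmentFraction = 1,
                                                seed = 5))
  expect_gte(val(hi, "contact_axon_bv_pct"), val(lo, "contact_axon_bv_pct"))
})

test_that("organ phantom volumes are self-consistent voxel counts", {
  org <- generateOrganVolume(seed = 2)
  vox <- prod(voxelSize(org$nerve))
  expect_equal(org$truth$V_TH_TOTAL, sum(maskArray(org$nerve)) * vox)
  expect_equal(org$truth$V_Panc, sum(maskArray(org$organ)) * vox)
  expect_equal(org$truth$V_PDAC, sum(maskArray(org$tumor)) * vox)
  expect_equal(org$truth$V_TH_INTRA,
               sum(maskArray(org$nerve) & maskArray(org$tumor)) * vox)
  # tumor contained in organ; nerve restricted to organ
  expect_true(all(!(maskArray(org$tumor) & !maskArray(org$organ))))
  expect_true(all(!(maskArray(org$nerve) & !maskArray(org$organ))))
  # partition estimator reproduces the truth exactly
  part <- nerveVolumePartition(org$nerve, org$organ, org$tumor)
  expect_equal(part$V_TH_INTRA, org$truth$V_TH_INTRA)
  # no tumor -> no intratumoral nerve
  org0 <- generateOrganVolume(tumorFraction = 0, seed = 3)
  expect_equal(org0$truth$V_PDAC, 0)
  expect_equal(org0$truth$V_TH_INTRA, 0)
})

test_that("growth cohorts follow the generative Gompertz model", {
  # zero noise: every series lies exactly on the group-mean curve
  spec <- growthCohortSpec(meanLogB = c(6, 7), meanA = c(0.4, 0.3),
                           sdEtaB = 0, sdEtaA = 0, sdZ0 = 0, sdEps = 0,
                           meanZ0 = 2, nMice = 2, days = seq(0, 30, 5),
                           seed = 1)
  co <- generateGrowthCohort(spec)
  for (g in 1:2) {
    sub <- co$data[co$data$group == spec$groups[g], ]
    expect_equal(sub$log_biolum,
                 gompertzLogMean(sub$day, spec$meanLogB[g], spec$meanA[g], 2))
  }
  # t = 0 observation equals z0; day 30 at a = 0.4 is within e^-12 of log b
  d0 <- co$data[co$data$day == 0 & co$data$group == "AA", ]
  expect_equal(d0$log_biolum, rep(2, nrow(d0)))
  d30 <- co$data[co$data$day == 30 & co$data$group == "AA", ]
  expect_equal(d30$log_biolum, rep(6 + exp(-12) * (2 - 6), nrow(d30)))
  expect_lt(abs(d30$log_biolum[1] - 6), 1e-4)
  # planted rates always positive, determinism, invariants
  spec2 <- growthCohortSpec(meanA = c(0.3, 0.25), sdEtaA = 0.3, seed = 8)
  co2 <- generateGrowthCohort(spec2)
  expect_true(all(co2$truth$mouse$a > 0))
  expect_identical(generateGrowthCohort(spec2)$data, co2$data)
  expect_error(growthCohortSpec(days = c(3, 1)))
  expect_error(growthCohortSpec(meanA = c(-0.1, 0.2)))
})

test_that("survival cohorts honor the planted hazards and censoring", {
  # exponential mean with effectively no censoring
  spec <- survivalCohortSpec(groups = list(
    list(label = "A", dist = "exponential", rate = 0.2, n = 4000)),
    censorTime = Inf, seed = 5)
  co <- generateSurvivalCohort(spec)
  expect_true(all(co$data$event == 1))
  # CLT bound: |mean - 1/rate| < 4 * sd / sqrt(n)
  expect_lt(abs(mean(co$data$time) - 5), 4 * 5 / sqrt(4000))
  # censoring at (effectively) zero censors every record
  spec0 <- survivalCohortSpec(groups = list(
    list(label = "A", dist = "exponential", rate = 0.2, n = 20)),
    censorTime = 0, seed = 5)
  co0 <- generateSurvivalCohort(spec0)
  expect_true(all(co0$data$event == 0))
  expect_true(all(co0$data$time > 0))  # record invariant
  # weibull branch + marker plant
  spec2 <- survivalCohortSpec(groups = list(
    list(label = "B", dist = "weibull", shape = 1.5, scale = 12, n = 50)),
    censorTime = 30, marker = list(cutpoint = 0.5, hrAbove = 4), seed = 6)
  co2 <- generateSurvivalCohort(spec2)
  expect_true(all(co2$data$marker >= 0 & co2$data$marker <= 1))
  hi <- co2$data$marker > 0.5
  # higher hazard above the cutpoint -> shorter event times on average
  expect_lt(mean(co2$data$time[hi]), mean(co2$data$time[!hi]))
})

test_that("simulated profile cohorts carry the planted class structure", {
  mns <- matrix(0, 3, 12,
                dimnames = list(c("g1", "g2", "g3"),
                                profileVariableNames()))
  mns[2, ] <- 8; mns[3, ] <- -8
  prof <- simulateProfileCohort(mns, nPerClass = 5, sd = 1, seed = 2)
  expect_equal(nrow(prof), 15)
  expect_identical(prof, simulateProfileCohort(mns, nPerClass = 5, sd = 1,
                                               seed = 2))
  agg <- aggregate(prof$axon_volume_density_pct, list(prof$class), mean)
  expect_gt(agg$x[agg$Group.1 == "g2"], 5)
  expect_lt(agg$x[agg$Group.1 == "g3"], -5)
})
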