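test_that("VolumeMask validates its geometry and counts volume exactly", {
  m <- VolumeMask(array(TRUE, c(10, 10, 10)), voxelSize = 2)
  expect_equal(maskVolume(m), 1000 * 8)
  expect_equal(maskVolume(VolumeMask(array(FALSE, c(4, 4, 4)), 1)), 0)
  expect_error(VolumeMask(array(TRUE, c(4, 4, 4)), voxelSize = -1))
  expect_error(new("VolumeMask", mask = array(TRUE, c(2, 2)),
                   voxelSize = c(1, 1, 1), anatomicalAxis = NA_integer_))
})

test_that("nerve partition matches a brute-force per-voxel oracle", {
  set.seed(42)
  d <- c(16L, 16L, 16L)
  organArr <- array(runif(prod(d)) < 0.7, d)
  tumorArr <- organArr & array(runif(prod(d)) < 0.3, d)
  nerveArr <- organArr & array(runif(prod(d)) < 0.2, d)
  organ <- VolumeMask(organArr, 3); tumor <- VolumeMask(tumorArr, 3)
  nerve <- VolumeMask(nerveArr, 3)
  part <- nerveVolumePartition(nerve, organ, tumor)
  ref <- bruteVolumes(nerve, organ, tumor)
  expect_equal(part$V_TH_TOTAL, ref$V_TH_TOTAL)
  expect_equal(part$V_TH_INTRA, ref$V_TH_INTRA)
  expect_equal(part$V_Panc, ref$V_Panc)
  expect_equal(part$V_PDAC, ref$V_PDAC)
  expect_equal(part$intratumoralDensity, ref$V_TH_INTRA / ref$V_PDAC)
  expect_equal(part$extratumoralDensity,
               (ref$V_TH_TOTAL - ref$V_TH_INTRA) /
                 (ref$V_Panc - ref$V_PDAC))
  # additivity: intra + extra volumes = total, exactly
  extraVol <- part$extratumoralDensity * (part$V_Panc - part$V_PDAC)
  expect_equal(part$V_TH_INTRA + extraVol, part$V_TH_TOTAL)
})

test_that("degenerate partitions are flagged, never crash", {
  d <- c(8L, 8L, 8L)
  organ <- VolumeMask(array(TRUE, d), 2)
  empty <- VolumeMask(array(FALSE, d), 2)
  nerve <- VolumeMask(array(c(TRUE, rep(FALSE, prod(d) - 1)), d), 2)
  p <- nerveVolumePartition(nerve, organ, empty)
  expect_equal(p$V_TH_INTRA, 0)
  expect_true(is.na(p$intratumoralDensity))
  expect_equal(p$extratumoralDensity, p$V_TH_TOTAL / p$V_Panc)
  # nerve wholly inside tumor
  tumorArr <- array(FALSE, d); tumorArr[1:4, , ] <- TRUE
  nerveArr <- array(FALSE, d); nerveArr[2, 2, 2] <- TRUE
  p2 <- nerveVolumePartition(VolumeMask(nerveArr, 2), organ,
                             VolumeMask(tumorArr, 2))
  expect_equal(p2$percentIntratumoral, 100)
  # violations error with offending voxel count
  out <- VolumeMask(array(TRUE, d), 2)
  orgSmall <- VolumeMask(array(FALSE, d), 2)
  expect_error(nerveVolumePartition(nerve, orgSmall, out), "voxels outside")
  expect_error(nerveVolumePartition(nerve, organ,
                                    VolumeMask(array(FALSE, c(4, 4, 4)), 2)),
               "shape")
})

test_that("volumes scale as voxel^3 while ratios are invariant", {
  set.seed(7)
  d <- c(12L, 12L, 12L)
  organArr <- array(runif(prod(d)) < 0.8, d)
  tumorArr <- organArr & array(runif(prod(d)) < 0.4, d)
  nerveArr <- organArr & array(runif(prod(d)) < 0.3, d)
  p1 <- nerveVolumePartition(VolumeMask(nerveArr, 1),
                             VolumeMask(organArr, 1),
                             VolumeMask(tumorArr, 1))
  p2 <- nerveVolumePartition(VolumeMask(nerveArr, 2),
                             VolumeMask(organArr, 2),
                             VolumeMask(tumorArr, 2))
  expect_equal(p2$V_TH_TOTAL, 8 * p1$V_TH_TOTAL)
  expect_equal(p2$V_PDAC, 8 * p1$V_PDAC)
  expect_equal(p2$intratumoralDensity, p1$intratumoralDensity)
  expect_equal(p2$percentIntratumoral, p1$percentIntratumoral)
})

test_that("sectional nerve fraction partitions the organ exactly", {
  # uniform 10%: nerve fills a fixed 10% slab pattern of every section
  d <- c(10L, 10L, 40L)
  organArr <- array(TRUE, d)
  nerveArr <- array(FALSE, d)
  nerveArr[1, 1:10, ] <- TRUE  # 10 of 100 voxels in every z-plane
  sec <- sectionalNerveFraction(VolumeMask(nerveArr, 2),
                                VolumeMask(organArr, 2), nLevels = 10,
                                axis = 3)
  expect_equal(sec$percent, rep(10, 10))
  expect_equal(sum(sec$organVoxels), sum(organArr))
  # empty nerve -> all zero
  sec0 <- sectionalNerveFraction(VolumeMask(array(FALSE, d), 2),
                                 VolumeMask(organArr, 2), axis = 3)
  expect_equal(sec0$percent, rep(0, 10))
  expect_error(sectionalNerveFraction(VolumeMask(nerveArr, 2),
                                      VolumeMask(organArr, 2), nLevels = 0))
})

test_that("a head-to-tail density gradient gives a decreasing profile", {
  d <- c(10L, 10L, 40L)
  organArr <- array(TRUE, d)
  nerveArr <- array(FALSE, d)
  # nerve fraction decreases linearly with z: plane z gets 41 - z voxels
  for (z in seq_len(d[3])) {
    k <- d[3] + 1 - z
    nerveArr[cbind(rep(1:10, length.out = k),
                   rep(1:10, each = 10)[seq_len(k)], z)] <- TRUE
  }
  nerve <- VolumeMask(nerveArr, 2); organ <- VolumeMask(organArr, 2)
  sec <- sectionalNerveFraction(nerve, organ, nLevels = 10, axis = 3)
  expect_true(all(diff(sec$percent) < 0))
  # brute-force slab counts
  for (lev in seq_len(10)) {
    zs <- ((lev - 1) * 4 + 1):(lev * 4)
    expect_equal(sec$nerveVoxels[lev], sum(nerveArr[, , zs]))
    expect_equal(sec$organVoxels[lev], sum(organArr[, , zs]))
  }
})

test_that("mask TIFF round trip preserves voxels and metadata", {
  set.seed(5)
  arr <- array(runif(8 * 8 * 6) < 0.4, c(8L, 8L, 6L))
  m <- VolumeMask(arr, c(2, 2, 2), anatomicalAxis = 3L)
  path <- file.path(withr::local_tempdir(), "mask.tiff")
  writeMaskTIFF(m, path)
  back <- readMaskTIFF(path)
  expect_identical(maskArray(back), arr)
  expect_equal(voxelSize(back), c(2, 2, 2))
  expect_equal(back@anatomicalAxis, 3L)
})
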