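# Whole-organ nerve volumetrics.
#
# Quantities follow the standard light-sheet workflow for cleared pancreata:
# the segmented nerve volume is partitioned against the tumor surface, and
# nerve density profiles are taken on equidistant sections along the organ
# axis. All volumes use voxel-centre membership: a voxel is inside a
# structure iff its mask value is set.

checkSameGeometry <- function(..., what = "masks") {
  masks <- list(...)
  d1 <- dim(maskArray(masks[[1]]))
  v1 <- voxelSize(masks[[1]])
  for (m in masks[-1]) {
    if (!identical(dim(maskArray(m)), d1))
      stop(what, " must share one grid shape (", paste(d1, collapse = "x"),
           " vs ", paste(dim(maskArray(m)), collapse = "x"), ")")
    if (!isTRUE(all.equal(voxelSize(m), v1)))
      stop(what, " must share one voxel size")
  }
  invisible(TRUE)
}

#' Partition nerve volume relative to a tumor inside an organ
#'
#' Splits the total segmented nerve volume (`V_TH_TOTAL`) into its
#' intratumoral part (`V_TH_INTRA`, nerve voxels inside the tumor mask) and
#' the extratumoral remainder, and derives the two nerve densities used for
#' staging whole-organ innervation: intratumoral density
#' `V_TH_INTRA / V_PDAC` and extratumoral density
#' `(V_TH_TOTAL - V_TH_INTRA) / (V_Panc - V_PDAC)`.
#'
#' Ratios with a zero denominator are returned as `NA` (flagged undefined),
#' never as an error. The nerve mask is assumed to be already restricted to
#' the organ (extra-organ nerve trunks removed upstream).
#'
#' @param nerve,organ,tumor [VolumeMask-class] objects on one grid; the
#'   tumor mask must be a subset of the organ mask.
#' @return A list of class `nervePartition` with elements `V_TH_TOTAL`,
#'   `V_TH_INTRA`, `V_Panc`, `V_PDAC` (um^3), `intratumoralDensity`,
#'   `extratumoralDensity`, `percentIntratumoral`.
#' @examples
#' organ <- VolumeMask(array(TRUE, c(8, 8, 8)), 2)
#' tumor <- VolumeMask(array(FALSE, c(8, 8, 8)), 2)
#' nerve <- organ
#' nerveVolumePartition(nerve, organ, tumor)
#' @export
nerveVolumePartition <- function(nerve, organ, tumor) {
  checkSameGeometry(nerve, organ, tumor)
  vox <- prod(voxelSize(nerve))
  nm <- maskArray(nerve); om <- maskArray(organ); tm <- maskArray(tumor)
  outside <- sum(tm & !om)
  if (outside > 0)
    stop("tumor mask is not contained in the organ mask (", outside,
         " voxels outside)")
  vTotal <- sum(nm) * vox
  vIntra <- sum(nm & tm) * vox
  vPanc <- sum(om) * vox
  vPdac <- sum(tm) * vox
  safeRatio <- function(a, b) if (b > 0) a / b else NA_real_
  out <- list(
    V_TH_TOTAL = vTotal,
    V_TH_INTRA = vIntra,
    V_Panc = vPanc,
    V_PDAC = vPdac,
    intratumoralDensity = safeRatio(vIntra, vPdac),
    extratumoralDensity = safeRatio(vTotal - vIntra, vPanc - vPdac),
    percentIntratumoral = if (vTotal > 0) 100 * vIntra / vTotal else NA_real_
  )
  class(out) <- "nervePartition"
  out
}

#' @export
print.nervePartition <- function(x, ...) {
  cat("Nerve volume partition (um^3):\n")
  cat(sprintf("  V_TH_TOTAL %.6g  V_TH_INTRA %.6g  V_Panc %.6g  V_PDAC %.6g\n",
              x$V_TH_TOTAL, x$V_TH_INTRA, x$V_Panc, x$V_PDAC))
  cat(sprintf("  intratumoral density %.4g, extratumoral density %.4g, %%intratumoral %.4g\n",
              x$intratumoralDensity, x$extratumoralDensity,
              x$percentIntratumoral))
  invisible(x)
}

#' Sectional nerve fraction along the organ axis
#'
#' Splits the organ extent along one axis into `nLevels` equal slabs
#' (half-open index intervals, last slab closed) and reports, per slab, the
#' nerve signal as a percentage of the organ cross-section:
#' `100 * (nerve & organ voxels) / organ voxels`. Mirrors the density
#' profiles measured on equidistant optical sections from the nerve entrance
#' at the pancreatic head towards the tail.
#'
#' @param nerve,organ [VolumeMask-class] objects on one grid.
#' @param nLevels number of slabs (default 10).
#' @param axis axis index along which to section; defaults to the organ's
#'   `anatomicalAxis` annotation, else 3.
#' @return data.frame with `level`, `organVoxels`, `nerveVoxels`,
#'   `percent` (`NA` where a slab holds no organ voxels).
#' @export
sectionalNerveFraction <- function(nerve, organ, nLevels = 10, axis = NULL) {
  checkSameGeometry(nerve, organ)
  if (is.null(axis)) {
    axis <- organ@anatomicalAxis
    if (is.na(axis)) axis <- 3L
  }
  nLevels <- as.integer(nLevels)
  if (is.na(nLevels) || nLevels < 1L) stop("nLevels must be >= 1")
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  om <- maskArray(organ)
  nm <- maskArray(nerve) & om
  planeOrgan <- apply(om, axis, sum)
  planeNerve <- apply(nm, axis, sum)
  occ <- which(planeOrgan > 0)
  if (!length(occ)) stop("organ mask is empty along the chosen axis")
  lo <- min(occ); hi <- max(occ)
  # half-open equal slabs over the occupied extent; last slab closed
  breaks <- lo + (hi - lo + 1) * (0:nLevels) / nLevels
  slab <- findInterval(occ, breaks, rightmost.closed = TRUE)
  slab[slab > nLevels] <- nLevels
  orgCount <- vapply(seq_len(nLevels),
                     function(l) sum(planeOrgan[occ[slab == l]]), 0)
  nrvCount <- vapply(seq_len(nLevels),
                     function(l) sum(planeNerve[occ[slab == l]]), 0)
  data.frame(level = seq_len(nLevels),
             organVoxels = orgCount,
             nerveVoxels = nrvCount,
             percent = ifelse(orgCount > 0, 100 * nrvCount / orgCount,
                              NA_real_))
}
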