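# The 12-variable morphometric profile of one tissue sample.
#
# Variables (units):
#  1 axon_volume_density_pct        axon voxels / grid voxels x 100
#  2 axon_branch_count_per_mm3      skeleton edges per mm^3
#  3 axon_mean_branch_length_um     mean skeleton edge length
#  4 axon_branchpoint_count_per_mm3 degree>=3 skeleton nodes per mm^3
#  5 vessel_volume_density_pct
#  6 vessel_mean_radius_um          distance transform at vessel centreline
#  7 contact_axon_bv_pct            % axon surface in contact with vessels
#  8 contact_bv_axon_pct            % vessel surface in contact with axons
#  9 contact_zone_count_per_mm2     zones per mm^2 of axon surface
# 10 contact_zone_mean_area_um2
# 11 contact_area_per_mm3           um^2 of interface per mm^3 of tissue
# 12 axon_vessel_median_distance_um median axon-centreline to vessel-surface
#                                   distance

#' Names of the 12 morphometric profile variables
#'
#' The canonical column order of the axon/vessel/contact descriptors
#' produced by [morphometricProfile()] (units in the file-level comments
#' and the methods vignette).
#'
#' @return character(12).
#' @export
profileVariableNames <- function() {
  c("axon_volume_density_pct", "axon_branch_count_per_mm3",
    "axon_mean_branch_length_um", "axon_branchpoint_count_per_mm3",
    "vessel_volume_density_pct", "vessel_mean_radius_um",
    "contact_axon_bv_pct", "contact_bv_axon_pct",
    "contact_zone_count_per_mm2", "contact_zone_mean_area_um2",
    "contact_area_per_mm3", "axon_vessel_median_distance_um")
}

# mean inscribed radius at centreline voxels. The EDT to the nearest
# background voxel centre overshoots the continuous radius by ~s/2, while
# the thinned centreline sits off the continuous axis by ~s/2 (an
# even-diameter tube has no centre voxel), undershooting by the same
# amount; the two half-voxel biases cancel, so the raw EDT is reported.
vesselRadiusEstimate <- function(arr, dm, s) {
  if (!any(arr)) return(NA_real_)
  thin <- cpp_thin(as.logical(arr), dm)
  if (!any(thin)) return(NA_real_)
  distBg <- cpp_edt(!as.logical(arr), dm, rep(s, 3))
  mean(pmax(distBg[thin], s / 2))
}

#' Compute the 12-variable axon/vessel morphometric profile
#'
#' Assembles, for one tissue sample, the dozen descriptors of sympathetic
#' axon architecture and axon-blood-vessel interaction used for Z-score
#' staging: axon density and branching (via [skeletonize()] and
#' [branchStatistics()]), vessel density and calibre, and the surface
#' contact statistics of [contactStatistics()]. An empty axon mask yields
#' zero densities and `NA` (undefined) for all surface-relative variables.
#'
#' @param axon,vessel [VolumeMask-class] objects on one isotropic grid.
#' @param sampleId sample identifier carried into the output row.
#' @param class tissue-class label (e.g. control, NF, ADM, PanIN, PDAC).
#' @param d contact distance in um (see [contactStatistics()]).
#' @param pruneLength skeleton spur-pruning length in um (default 3 voxels).
#' @return one-row data.frame: `sample_id`, `class`, then the 12 variables
#'   named as in `profileVariableNames()`.
#' @export
morphometricProfile <- function(axon, vessel, sampleId = "sample",
                                class = NA_character_, d = 2,
                                pruneLength = NULL) {
  checkSameGeometry(axon, vessel)
  vs <- voxelSize(axon)
  if (max(vs) - min(vs) > 1e-9)
    stop("morphometric profiling requires isotropic voxels")
  s <- vs[1]
  dm <- dim(maskArray(axon))
  gridMm3 <- prod(dm) * s^3 / 1e9
  arrA <- maskArray(axon); arrV <- maskArray(vessel)

  v <- stats::setNames(rep(NA_real_, 12), profileVariableNames())
  v["axon_volume_density_pct"] <- 100 * sum(arrA) / prod(dm)
  v["vessel_volume_density_pct"] <- 100 * sum(arrV) / prod(dm)

  if (any(arrA)) {
    skel <- skeletonize(axon, pruneLength = pruneLength)
    bs <- branchStatistics(skel, gridMm3)
    v["axon_branch_count_per_mm3"] <- bs$branchCountPerMm3
    v["axon_mean_branch_length_um"] <-
      if (is.na(bs$meanBranchLength)) 0 else bs$meanBranchLength
    v["axon_branchpoint_count_per_mm3"] <- bs$branchPointCountPerMm3
  } else {
    v["axon_branch_count_per_mm3"] <- 0
    v["axon_mean_branch_length_um"] <- 0
    v["axon_branchpoint_count_per_mm3"] <- 0
  }

  v["vessel_mean_radius_um"] <- vesselRadiusEstimate(arrV, dm, s)

  cs <- contactStatistics(axon, vessel, d = d)
  v["contact_axon_bv_pct"] <- cs$pctContactAxonBV
  v["contact_bv_axon_pct"] <- cs$pctContactBVAxon
  v["contact_zone_count_per_mm2"] <- cs$zoneCountPerMm2
  v["contact_zone_mean_area_um2"] <- cs$meanZoneArea
  v["contact_area_per_mm3"] <- cs$contactAreaPerMm3

  if (any(arrA) && any(arrV)) {
    facesV <- cpp_exposed_faces(as.logical(arrV), dm)
    if (any(facesV > 0)) {
      distVS <- cpp_edt(facesV > 0L, dm, rep(s, 3))
      thinA <- cpp_thin(as.logical(arrA), dm)
      if (any(thinA))
        v["axon_vessel_median_distance_um"] <- stats::median(distVS[thinA])
    }
  }

  out <- data.frame(sample_id = sampleId, class = class, t(v),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Batch morphometric profiling over a sample manifest
#'
#' @param manifest data.frame with columns `sample_id`, `class`,
#'   `axon_path`, `vessel_path` (multi-page TIFFs readable by
#'   [readMaskTIFF()]).
#' @param voxelSize voxel size in um passed to the reader when no sidecar
#'   is present.
#' @param ... passed to [morphometricProfile()].
#' @return data.frame, one profile row per manifest row.
#' @export
batchMorphometry <- function(manifest, voxelSize = NULL, ...) {
  need <- c("sample_id", "class", "axon_path", "vessel_path")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    a <- readMaskTIFF(manifest$axon_path[i], voxelSize = voxelSize)
    b <- readMaskTIFF(manifest$vessel_path[i], voxelSize = voxelSize)
    morphometricProfile(a, b, sampleId = manifest$sample_id[i],
                        class = manifest$class[i], ...)
  })
  do.call(rbind, rows)
}
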