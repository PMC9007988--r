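# Mask I/O: multi-page 8-bit TIFF (0/255), one page per z-plane, with the
# voxel size carried in a small JSON sidecar (<file>.json) because baseline
# TIFF tags do not hold a z spacing.

#' Write a VolumeMask to a multi-page TIFF
#'
#' Pages are z-planes; foreground is written as 255, background as 0. The
#' voxel size (um) and anatomical axis are stored in a JSON sidecar at
#' `paste0(path, ".json")`.
#'
#' @param mask a [VolumeMask-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeMaskTIFF <- function(mask, path) {
  arr <- maskArray(mask)
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(z) matrix(as.numeric(arr[, , z]),
                                     nrow = dim(arr)[1]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "LZW")
  meta <- list(voxel_size_um = voxelSize(mask),
               anatomical_axis = mask@anatomicalAxis,
               dim = dim(arr))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a VolumeMask from a multi-page TIFF
#'
#' Accepts any grey-level multi-page TIFF; values above `threshold` (on the
#' 0-1 scale used by [tiff::readTIFF()]) are foreground. The voxel size is
#' taken from the JSON sidecar written by [writeMaskTIFF()] unless supplied.
#' Anisotropic voxel sizes are accepted.
#'
#' @param path TIFF path.
#' @param voxelSize voxel edge length(s) in um; overrides the sidecar.
#' @param threshold foreground threshold on the 0-1 intensity scale.
#' @return A [VolumeMask-class].
#' @export
readMaskTIFF <- function(path, voxelSize = NULL, threshold = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  axisAnn <- NA_integer_
  if (is.null(voxelSize)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("no voxelSize given and no sidecar found at ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    voxelSize <- meta$voxel_size_um
    if (!is.null(meta$anatomical_axis) && !is.na(meta$anatomical_axis))
      axisAnn <- as.integer(meta$anatomical_axis)
  }
  d <- c(dim(pages[[1]]), length(pages))
  arr <- array(FALSE, d)
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]] > threshold
  VolumeMask(arr, voxelSize, anatomicalAxis = axisAnn)
}
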