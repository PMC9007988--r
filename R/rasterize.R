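#' Rasterize tube centrelines into a VolumeMask
#'
#' Marks every voxel whose centre lies within `radius` of any piecewise-
#' linear centreline (capsule tubes). Voxel (i, j, k) has centre
#' `(i - 0.5, j - 0.5, k - 0.5) * voxelSize` micrometres.
#'
#' @param polylines a single n x 3 matrix of points (um) or a list of them.
#' @param radius tube radius, um.
#' @param gridDim integer(3) grid shape in voxels.
#' @param voxelSize isotropic voxel edge length, um.
#' @return A [VolumeMask-class].
#' @examples
#' tube <- rasterizeTubes(rbind(c(5, 10, 10), c(35, 10, 10)),
#'                        radius = 2, gridDim = c(20, 10, 10), voxelSize = 2)
#' maskVolume(tube)
#' @export
rasterizeTubes <- function(polylines, radius, gridDim, voxelSize) {
  if (is.matrix(polylines)) polylines <- list(polylines)
  d <- as.integer(gridDim)
  cur <- as.logical(array(FALSE, d))
  for (pl in polylines) {
    stopifnot(is.matrix(pl), ncol(pl) == 3, nrow(pl) >= 2)
    sg <- polylineSegs(pl)
    cur <- cpp_paint_capsules(cur, d, rep(voxelSize, 3), sg$A, sg$B, radius)
  }
  VolumeMask(array(cur, d), voxelSize)
}
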