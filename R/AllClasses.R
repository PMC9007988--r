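#' @useDynLib pdacnerve, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' VolumeMask: a 3D binary segmentation mask with physical voxel size
#'
#' The carrier for every segmented structure handled by the package (axons,
#' vessels, whole organ, tumor nodules). Wraps a 3D logical array together
#' with the voxel edge lengths in micrometres and an optional annotation of
#' the anatomical head-to-tail axis (1 = x, 2 = y, 3 = z).
#'
#' @slot mask 3D `logical` array; `TRUE` marks voxels inside the structure.
#' @slot voxelSize numeric(3), voxel edge length per axis in micrometres.
#' @slot anatomicalAxis integer(1), index of the head-to-tail axis, or `NA`.
#'
#' @seealso [VolumeMask()] for construction, [maskVolume()],
#'   [nerveVolumePartition()], [sectionalNerveFraction()].
#' @export
setClass("VolumeMask",
  representation(mask = "array", voxelSize = "numeric",
                 anatomicalAxis = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L)
      msg <- c(msg, "mask must be a 3D array")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
        any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive finite numbers (um)")
    if (length(object@anatomicalAxis) != 1L ||
        (!is.na(object@anatomicalAxis) &&
         !object@anatomicalAxis %in% 1:3))
      msg <- c(msg, "anatomicalAxis must be NA or 1, 2, 3")
    if (length(msg)) msg else TRUE
  })

#' Construct a VolumeMask
#'
#' @param mask 3D array coercible to logical (numeric arrays are read as
#'   nonzero = foreground).
#' @param voxelSize voxel edge length(s) in micrometres; a single value is
#'   used for all three axes (isotropic voxels).
#' @param anatomicalAxis optional head-to-tail axis index (1, 2 or 3).
#' @return A [VolumeMask-class] object.
#' @examples
#' m <- VolumeMask(array(FALSE, c(8, 8, 8)), voxelSize = 2)
#' maskVolume(m)
#' @export
VolumeMask <- function(mask, voxelSize, anatomicalAxis = NA_integer_) {
  if (is.numeric(mask)) {
    d <- dim(mask)
    mask <- array(mask != 0, d)
  }
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("VolumeMask", mask = mask, voxelSize = as.numeric(voxelSize),
      anatomicalAxis = as.integer(anatomicalAxis)[1L])
}

setMethod("show", "VolumeMask", function(object) {
  d <- dim(object@mask)
  cat("VolumeMask:", paste(d, collapse = " x "), "voxels,",
      paste(signif(object@voxelSize, 4), collapse = " x "), "um/voxel\n")
  cat("  foreground:", sum(object@mask), "voxels (",
      signif(maskVolume(object), 6), "um^3 )\n")
  if (!is.na(object@anatomicalAxis))
    cat("  anatomical axis:", object@anatomicalAxis, "\n")
})

#' NetworkSkeleton: centreline graph of a tubular network
#'
#' Produced by [skeletonize()]. Nodes are endpoints, branch points (junction
#' voxel clusters are collapsed to one node) or loop anchors; edges are the
#' centreline paths between them, with physical lengths in micrometres.
#'
#' @slot nodes data.frame with columns `node`, `x`, `y`, `z` (voxel indices,
#'   1-based), `degree`.
#' @slot edges data.frame with columns `edge`, `from`, `to`, `length` (um),
#'   `nvox`.
#' @slot paths list of integer matrices (one per edge) holding the ordered
#'   voxel coordinates of each centreline path.
#' @slot voxelSize numeric(3), micrometres.
#' @seealso [skeletonize()], [branchStatistics()].
#' @export
setClass("NetworkSkeleton",
  representation(nodes = "data.frame", edges = "data.frame",
                 paths = "list", voxelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@edges) != length(object@paths))
      msg <- c(msg, "one path per edge required")
    if (nrow(object@edges) > 0 &&
        !all(c(object@edges$from, object@edges$to) %in% object@nodes$node))
      msg <- c(msg, "edge endpoints must be node ids")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "NetworkSkeleton", function(object) {
  cat("NetworkSkeleton:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges)) {
    cat("  total length:", signif(sum(object@edges$length), 6), "um;",
        "branch points (degree >= 3):",
        sum(object@nodes$degree >= 3), "\n")
  }
})

#' GompertzFit: posterior draws from the hierarchical Gompertz growth model
#'
#' Returned by [fitGompertzHierarchy()]. Holds the MCMC draws for all mouse-
#' and group-level parameters and variance components, plus convergence
#' diagnostics (split-Rhat, effective sample size).
#'
#' @slot draws a [coda::mcmc.list] with one chain per element; columns are
#'   the monitored parameters.
#' @slot diagnostics data.frame with `parameter`, `rhat` (split-Rhat), `ess`.
#' @slot groups character vector of group labels in model order.
#' @slot mice data.frame mapping `mouse_id` to model index and group.
#' @slot data the input cohort data.frame.
#' @slot priors list of resolved prior hyperparameters.
#' @slot seed integer seed used for the sampler.
#' @seealso [groupDifferenceProbability()], [credibleRegions2d()],
#'   [posteriorPredictive()].
#' @export
setClass("GompertzFit",
  representation(draws = "ANY", diagnostics = "data.frame",
                 groups = "character", mice = "data.frame",
                 data = "data.frame", priors = "list", seed = "integer"))

setMethod("show", "GompertzFit", function(object) {
  nd <- sum(vapply(object@draws, nrow, 1L))
  cat("GompertzFit:", length(object@draws), "chains,", nd,
      "total draws,", length(object@groups), "groups (",
      paste(object@groups, collapse = ", "), ")\n")
  bad <- object@diagnostics$rhat > 1.01
  cat("  split-Rhat max:", signif(max(object@diagnostics$rhat), 4),
      if (any(bad)) sprintf("(%d parameters above 1.01)", sum(bad)) else "",
      "\n")
})
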