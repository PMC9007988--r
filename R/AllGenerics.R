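#' @describeIn VolumeMask-class the logical voxel array.
#' @param object,x a `VolumeMask`.
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname VolumeMask-class
#' @export
setMethod("maskArray", "VolumeMask", function(x) x@mask)

#' @describeIn VolumeMask-class voxel edge lengths in micrometres.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname VolumeMask-class
#' @export
setMethod("voxelSize", "VolumeMask", function(x) x@voxelSize)

#' Physical volume of a mask
#'
#' Volume of the foreground in cubic micrometres: voxel count times voxel
#' volume (voxel-centre membership, no partial-volume weighting).
#'
#' @param x a [VolumeMask-class].
#' @return numeric(1), micrometres cubed.
#' @examples
#' m <- VolumeMask(array(TRUE, c(10, 10, 10)), voxelSize = 2)
#' maskVolume(m)  # 1000 voxels x 8 um^3
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @rdname maskVolume
#' @export
setMethod("maskVolume", "VolumeMask", function(x) {
  sum(x@mask) * prod(x@voxelSize)
})

#' @describeIn NetworkSkeleton-class node table.
#' @param x a `NetworkSkeleton`.
#' @export
setGeneric("skeletonNodes", function(x) standardGeneric("skeletonNodes"))

#' @rdname NetworkSkeleton-class
#' @export
setMethod("skeletonNodes", "NetworkSkeleton", function(x) x@nodes)

#' @describeIn NetworkSkeleton-class edge table.
#' @export
setGeneric("skeletonEdges", function(x) standardGeneric("skeletonEdges"))

#' @rdname NetworkSkeleton-class
#' @export
setMethod("skeletonEdges", "NetworkSkeleton", function(x) x@edges)

#' @describeIn GompertzFit-class the `coda::mcmc.list` of posterior draws.
#' @param x a `GompertzFit`.
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @rdname GompertzFit-class
#' @export
setMethod("posteriorDraws", "GompertzFit", function(x) x@draws)

#' @describeIn GompertzFit-class convergence diagnostics table.
#' @export
setGeneric("fitDiagnostics", function(x) standardGeneric("fitDiagnostics"))

#' @rdname GompertzFit-class
#' @export
setMethod("fitDiagnostics", "GompertzFit", function(x) x@diagnostics)
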