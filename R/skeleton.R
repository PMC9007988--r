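# Centreline extraction for tubular networks (axons, vessels).
#
# Thinning is done in C++ (topology-preserving removal of simple points,
# 6-direction sub-iterations); the graph is assembled here: 26-adjacent
# skeleton voxels, junction-voxel clusters collapsed to single nodes, spur
# edges shorter than the pruning length removed, and degree-2 pass-through
# nodes merged away so that one edge equals one anatomical branch.

NB26 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
NB26 <- NB26[rowSums(abs(NB26)) > 0, , drop = FALSE]

emptySkeleton <- function(voxelSize) {
  new("NetworkSkeleton",
      nodes = data.frame(node = integer(), x = integer(), y = integer(),
                         z = integer(), degree = integer()),
      edges = data.frame(edge = integer(), from = integer(), to = integer(),
                         length = numeric(), nvox = integer()),
      paths = list(), voxelSize = voxelSize)
}

pathLength <- function(coords, voxelSize) {
  if (nrow(coords) < 2) return(0)
  st <- diff(coords) * rep(voxelSize, each = nrow(coords) - 1)
  sum(sqrt(rowSums(st^2)))
}

#' Skeletonize a tubular mask into a centreline network
#'
#' Reduces a binary tube network to a one-voxel-wide, topology-preserving
#' centreline (simple-point thinning), then assembles the centreline graph:
#' endpoints and branch points become nodes (26-connected clusters of
#' junction voxels collapse to one node), the paths between them become
#' edges with physical lengths (sum of inter-voxel Euclidean steps times the
#' voxel size). Terminal spurs shorter than `pruneLength` -- thinning
#' artifacts on rasterized tubes -- are removed, and pass-through nodes left
#' behind by pruning are merged.
#'
#' @param mask a [VolumeMask-class].
#' @param pruneLength spur-pruning threshold in micrometres; the default is
#'   3 voxel edge lengths.
#' @return A [NetworkSkeleton-class]; empty mask gives an empty skeleton.
#' @export
skeletonize <- function(mask, pruneLength = NULL) {
  vs <- voxelSize(mask)
  arr <- maskArray(mask)
  if (is.null(pruneLength)) pruneLength <- 3 * max(vs)
  if (!sum(arr)) return(emptySkeleton(vs))
  d <- dim(arr)
  thin <- array(cpp_thin(as.logical(arr), d), d)

  lin <- which(thin)
  coords <- arrayInd(lin, d)
  nv <- length(lin)
  idmap <- integer(prod(d))
  idmap[lin] <- seq_len(nv)

  # adjacency (26-connectivity), vectorized per offset
  fromAll <- integer(0); toAll <- integer(0)
  for (o in seq_len(nrow(NB26))) {
    nb <- coords + rep(NB26[o, ], each = nv)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nlin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    hit <- idmap[nlin] > 0
    fromAll <- c(fromAll, which(ok)[hit])
    toAll <- c(toAll, idmap[nlin[hit]])
  }
  deg <- tabulate(fromAll, nbins = nv)
  adj <- vector("list", nv)
  if (length(fromAll)) {
    sp <- split(toAll, fromAll)
    adj[as.integer(names(sp))] <- sp
  }

  # node voxels: endpoints/isolated (deg <= 1), junctions (deg >= 3),
  # plus one anchor per all-degree-2 loop component
  isNode <- deg != 2L
  comp <- array(cpp_label26(as.logical(thin), d), d)[lin]
  for (cc in setdiff(unique(comp), comp[isNode]))
    isNode[which(comp == cc)[1]] <- TRUE

  # collapse 26-connected junction clusters to single graph nodes
  clusterOf <- integer(nv)
  nodeCount <- 0L
  junc <- which(deg >= 3L)
  if (length(junc)) {
    jm <- array(FALSE, d)
    jm[lin[junc]] <- TRUE
    jl <- array(cpp_label26(as.logical(jm), d), d)[lin[junc]]
    clusterOf[junc] <- jl
    nodeCount <- max(jl)
  }
  others <- which(isNode & deg < 3L)
  clusterOf[others] <- nodeCount + seq_along(others)
  nodeCount <- nodeCount + length(others)

  # trace edges between node voxels through degree-2 chains
  usedStep <- new.env(hash = TRUE)
  stepKey <- function(a, b) paste0(a, "_", b)
  edgeFrom <- integer(0); edgeTo <- integer(0)
  paths <- list()
  nodeVox <- which(isNode)
  for (v in nodeVox) {
    for (n in adj[[v]]) {
      if (isNode[n] && clusterOf[n] == clusterOf[v]) next  # intra-cluster
      if (exists(stepKey(v, n), envir = usedStep)) next
      assign(stepKey(v, n), TRUE, envir = usedStep)
      path <- c(v, n)
      prev <- v; cur <- n
      while (!isNode[cur]) {
        nxt <- adj[[cur]][adj[[cur]] != prev]
        prev <- cur; cur <- nxt[1]
        path <- c(path, cur)
      }
      assign(stepKey(cur, prev), TRUE, envir = usedStep)
      edgeFrom <- c(edgeFrom, clusterOf[v])
      edgeTo <- c(edgeTo, clusterOf[cur])
      paths[[length(paths) + 1L]] <- coords[path, , drop = FALSE]
    }
  }

  # node table: representative voxel per cluster (first member)
  repVox <- vapply(seq_len(nodeCount),
                   function(k) which(clusterOf == k)[1], 1L)
  nodes <- data.frame(node = seq_len(nodeCount),
                      x = coords[repVox, 1], y = coords[repVox, 2],
                      z = coords[repVox, 3], degree = 0L)
  edges <- data.frame(edge = seq_along(paths), from = edgeFrom, to = edgeTo,
                      length = vapply(paths, pathLength, 0, voxelSize = vs),
                      nvox = vapply(paths, nrow, 1L))
  skel <- prunedSkeleton(nodes, edges, paths, vs, pruneLength)
  skel
}

# spur removal + degree-2 merge + degree bookkeeping
prunedSkeleton <- function(nodes, edges, paths, vs, pruneLength) {
  degOf <- function() {
    tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
  }
  initiallyIsolated <- nodes$node[degOf() == 0L]
  # junction consolidation: thinning can leave two junction voxels of one
  # anatomical branch point separated by a voxel or two; contract short
  # edges joining two branch-point nodes
  repeat {
    dg <- degOf()
    short <- which(edges$from != edges$to &
                     dg[edges$from] >= 3L & dg[edges$to] >= 3L &
                     edges$length < pruneLength)
    if (!length(short)) break
    e <- short[which.min(edges$length[short])]
    a <- edges$from[e]; b <- edges$to[e]
    edges <- edges[-e, , drop = FALSE]
    paths <- paths[-e]
    edges$from[edges$from == b] <- a
    edges$to[edges$to == b] <- a
  }
  repeat {
    dg <- degOf()
    leaf <- (dg[edges$from] == 1L & dg[edges$to] >= 2L) |
      (dg[edges$to] == 1L & dg[edges$from] >= 2L)
    drop <- which(leaf & edges$length < pruneLength)
    if (!length(drop)) break
    # remove the shortest spur first, then re-evaluate
    drop <- drop[which.min(edges$length[drop])]
    edges <- edges[-drop, , drop = FALSE]
    paths <- paths[-drop]
  }
  # merge pass-through nodes (exactly two incident edges, not a self-loop)
  repeat {
    dg <- degOf()
    selfloop <- edges$from == edges$to
    cand <- which(dg == 2L)
    merged <- FALSE
    for (nd in cand) {
      inc <- which((edges$from == nd | edges$to == nd) & !selfloop)
      if (length(inc) != 2L) next
      e1 <- inc[1]; e2 <- inc[2]
      p1 <- paths[[e1]]; p2 <- paths[[e2]]
      if (edges$from[e1] == nd) { p1 <- p1[nrow(p1):1, , drop = FALSE]
        a <- edges$to[e1] } else a <- edges$from[e1]
      if (edges$to[e2] == nd) { p2 <- p2[nrow(p2):1, , drop = FALSE]
        b <- edges$from[e2] } else b <- edges$to[e2]
      pj <- rbind(p1, p2[-1, , drop = FALSE])
      edges$from[e1] <- a; edges$to[e1] <- b
      edges$length[e1] <- pathLength(pj, vs)
      edges$nvox[e1] <- nrow(pj)
      paths[[e1]] <- pj
      edges <- edges[-e2, , drop = FALSE]
      paths <- paths[-e2]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  # drop nodes orphaned by pruning; single-voxel components are retained
  keep <- sort(unique(c(edges$from, edges$to, initiallyIsolated)))
  remap <- integer(nrow(nodes))
  remap[keep] <- seq_along(keep)
  nodes <- nodes[keep, , drop = FALSE]
  nodes$node <- seq_len(nrow(nodes))
  if (nrow(edges)) {
    edges$from <- remap[edges$from]
    edges$to <- remap[edges$to]
    edges$edge <- seq_len(nrow(edges))
  }
  nodes$degree <- tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("NetworkSkeleton", nodes = nodes, edges = edges, paths = paths,
      voxelSize = vs)
}

#' Branch statistics of a skeletonized network
#'
#' A branch is one skeleton edge; a branch point is a node of degree >= 3.
#' Densities are normalized by the analysed tissue volume.
#'
#' @param skel a [NetworkSkeleton-class].
#' @param tissueVolume analysed volume in mm^3 (must be > 0).
#' @return list with `branchCountPerMm3`, `meanBranchLength` (um, `NA` when
#'   there are no branches), `branchPointCountPerMm3`.
#' @export
branchStatistics <- function(skel, tissueVolume) {
  if (!is.numeric(tissueVolume) || tissueVolume <= 0)
    stop("tissueVolume must be positive (mm^3)")
  ed <- skeletonEdges(skel)
  nd <- skeletonNodes(skel)
  list(branchCountPerMm3 = nrow(ed) / tissueVolume,
       meanBranchLength = if (nrow(ed)) mean(ed$length) else NA_real_,
       branchPointCountPerMm3 = sum(nd$degree >= 3L) / tissueVolume)
}
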