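# Fixture builders and independent brute-force oracles. Everything here is
# deliberately written in plain R (shifts, loops, BFS) so that it shares no
# code path with the package's C++ kernels.

straightTubeMask <- function(length_um = 100, radius = 4, voxel = 2,
                             pad = 10) {
  d <- c(as.integer((length_um + 2 * pad) / voxel), 20L, 20L)
  ctr <- c(10, 10) * voxel
  rasterizeTubes(rbind(c(pad, ctr[1], ctr[2]),
                       c(pad + length_um, ctr[1], ctr[2])),
                 radius = radius, gridDim = d, voxelSize = voxel)
}

yTubeMask <- function(radius = 4, voxel = 2) {
  d <- c(60L, 60L, 20L)
  arms <- list(rbind(c(10, 60, 20), c(60, 60, 20)),
               rbind(c(60, 60, 20), c(100, 90, 20)),
               rbind(c(60, 60, 20), c(100, 30, 20)))
  rasterizeTubes(arms, radius = radius, gridDim = d, voxelSize = voxel)
}

# blobby random mask from a few spheres (controlled surface size)
randomBlobMask <- function(dim = c(32L, 32L, 32L), voxel = 1,
                           nSpheres = 3, rRange = c(3, 6)) {
  arr <- array(FALSE, dim)
  co <- arrayInd(seq_len(prod(dim)), dim)
  for (i in seq_len(nSpheres)) {
    c0 <- runif(3, 6, dim - 6)
    r <- runif(1, rRange[1], rRange[2])
    arr[rowSums(sweep(co, 2, c0)^2) <= r^2] <- TRUE
  }
  VolumeMask(arr, voxel)
}

# ---- brute-force voxel oracles (plain R) ----

bruteVolumes <- function(nerve, organ, tumor) {
  nm <- maskArray(nerve); om <- maskArray(organ); tm <- maskArray(tumor)
  vox <- prod(voxelSize(nerve))
  tot <- 0; intra <- 0; panc <- 0; pdac <- 0
  d <- dim(nm)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (nm[x, y, z]) tot <- tot + 1
    if (nm[x, y, z] && tm[x, y, z]) intra <- intra + 1
    if (om[x, y, z]) panc <- panc + 1
    if (tm[x, y, z]) pdac <- pdac + 1
  }
  list(V_TH_TOTAL = tot * vox, V_TH_INTRA = intra * vox,
       V_Panc = panc * vox, V_PDAC = pdac * vox)
}

# exposed faces by array shifts (R route, no C++)
bruteExposedFaces <- function(arr) {
  d <- dim(arr)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  faces <- array(0L, d)
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb <- pad[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2],
              2:(d[3] + 1) + sh[3]]
    faces <- faces + (arr & !nb)
  }
  faces
}

# 26-connected components of a logical array by BFS over a voxel list
bruteLabel26 <- function(arr) {
  d <- dim(arr)
  idx <- which(arr)
  lab <- integer(length(idx))
  names(lab) <- idx
  co <- arrayInd(idx, d)
  key <- function(p) (p[1] - 1) + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
  lookup <- stats::setNames(seq_along(idx), apply(co, 1, key))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cur <- 0L
  for (i in seq_along(idx)) {
    if (lab[i]) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        p <- co[v, ] + offs[o, ]
        if (any(p < 1) || any(p > d)) next
        j <- lookup[as.character(key(p))]
        if (!is.na(j) && !lab[j]) { lab[j] <- cur; queue <- c(queue, j) }
      }
    }
  }
  list(labels = lab, n = cur, coords = co)
}

# exhaustive all-pairs surface-distance contact oracle
bruteContactStats <- function(axon, vessel, dcut) {
  s <- voxelSize(axon)[1]
  arrA <- maskArray(axon); arrV <- maskArray(vessel)
  d <- dim(arrA)
  fA <- bruteExposedFaces(arrA); fV <- bruteExposedFaces(arrV)
  surfA <- which(fA > 0); surfV <- which(fV > 0)
  areaA <- sum(fA) * s^2; areaV <- sum(fV) * s^2
  coA <- arrayInd(surfA, d); coV <- arrayInd(surfV, d)
  minDistTo <- function(from, to) {
    if (!nrow(to)) return(rep(Inf, nrow(from)))
    # all-pairs squared distances via the expansion |a-b|^2
    d2 <- outer(rowSums(from^2), rep(1, nrow(to))) +
      outer(rep(1, nrow(from)), rowSums(to^2)) -
      2 * from %*% t(to)
    sqrt(pmax(apply(d2, 1, min), 0)) * s
  }
  contA <- if (length(surfA)) minDistTo(coA, coV) <= dcut + 1e-9 else logical(0)
  contV <- if (length(surfV)) minDistTo(coV, coA) <= dcut + 1e-9 else logical(0)
  caA <- sum(fA[surfA[contA]]) * s^2
  caV <- sum(fV[surfV[contV]]) * s^2
  zm <- array(FALSE, d); zm[surfA[contA]] <- TRUE
  nz <- bruteLabel26(zm)$n
  gridMm3 <- prod(d) * s^3 / 1e9
  list(pctContactAxonBV = if (areaA > 0) 100 * caA / areaA else NA_real_,
       pctContactBVAxon = if (areaV > 0) 100 * caV / areaV else NA_real_,
       zoneCountPerMm2 = if (areaA > 0) nz / (areaA / 1e6) else NA_real_,
       meanZoneArea = if (nz > 0) caA / nz else NA_real_,
       contactAreaPerMm3 = (caA + caV) / 2 / gridMm3,
       nZones = nz)
}

# minimal GompertzFit for unit tests of the posterior summaries
makeTestFit <- function(drawsMatrix, groups, miceIds = character(0),
                        miceGroups = character(0), nchains = 2) {
  n <- nrow(drawsMatrix)
  half <- n %/% 2
  ch <- list(coda::mcmc(drawsMatrix[seq_len(half), , drop = FALSE]),
             coda::mcmc(drawsMatrix[half + seq_len(half), , drop = FALSE]))
  mice <- data.frame(mouse_id = miceIds, group = miceGroups,
                     index = seq_along(miceIds),
                     stringsAsFactors = FALSE)
  new("GompertzFit", draws = ch,
      diagnostics = data.frame(parameter = colnames(drawsMatrix),
                               rhat = 1, ess = n),
      groups = groups, mice = mice,
      data = data.frame(), priors = list(), seed = 1L)
}
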