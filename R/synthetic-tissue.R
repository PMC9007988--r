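# Synthetic tissue phantoms: tubular axon and vessel networks with planted
# ground truth, emulating the innervation patterns of pancreatic tissue
# classes (control/asymptomatic acinar tissue, noninvasive neoplastic
# lesions, invasive tumor regions): class-dependent axon density, sprouting
# (branch rate), branch length, periacinar axon-vessel alignment and vessel
# calibre.
#
# Geometry is continuous (piecewise-linear centrelines, capsule tubes) and
# is rasterized by voxel-centre membership; the truth record is computed
# from the continuous geometry BEFORE voxelization, with per-variable
# tolerances that absorb the discretization error.

# evaluate expr under a fixed seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

unitv <- function(v) v / sqrt(sum(v^2))

# orthonormal pair perpendicular to t
perpBasis <- function(t) {
  a <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitv(pracmaCross(t, a))
  v <- pracmaCross(t, u)
  list(u = u, v = v)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# resample a polyline (n x 3, um) to points every `delta` um of arc length
resamplePolyline <- function(pts, delta) {
  if (nrow(pts) < 2) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  tot <- arc[length(arc)]
  if (tot <= delta) return(pts[c(1, nrow(pts)), , drop = FALSE])
  s <- seq(0, tot, by = delta)
  cbind(stats::approx(arc, pts[, 1], xout = s)$y,
        stats::approx(arc, pts[, 2], xout = s)$y,
        stats::approx(arc, pts[, 3], xout = s)$y)
}

polylineLength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

polylineSegs <- function(pts) {
  list(A = pts[-nrow(pts), , drop = FALSE], B = pts[-1, , drop = FALSE])
}

#' Specification of a synthetic axon/vessel tissue phantom
#'
#' Parameterizes the generator of [generateTissuePhantom()]. Defaults
#' describe a healthy acinar region: a few straight-ish vessels, moderately
#' branched axons mostly aligned along vessels. See [tissueClassSpec()] for
#' presets matching the tissue classes used in staging.
#'
#' @param gridDim integer(3), grid shape in voxels.
#' @param voxelSize isotropic voxel edge length, um.
#' @param vesselCount,vesselRadius number of vessels and their radius (um).
#' @param axonCount number of axons.
#' @param axonRadius axon tube radius (um).
#' @param trunkLength target axon trunk length (um).
#' @param branchRate expected branch points per 100 um of trunk.
#' @param branchLengthMean,branchLengthSd branch length distribution (um),
#'   truncated at 10 um.
#' @param alignmentFraction fraction of axons whose trunk is constrained to
#'   run within contact distance of a vessel surface.
#' @param alignmentGap surface-to-surface gap of aligned trunks (um).
#' @param hotspot logical; localized sprouting hotspot present.
#' @param hotspotMultiplier multiplier on `branchRate` when `hotspot`.
#' @param contactDistance contact distance d used for the planted contact
#'   truth (um).
#' @param seed integer RNG seed; identical spec + seed gives identical
#'   volumes.
#' @return validated list of class `tissuePhantomSpec`.
#' @export
tissuePhantomSpec <- function(gridDim = c(96L, 96L, 96L), voxelSize = 1,
                              vesselCount = 5, vesselRadius = 4,
                              axonCount = 6, axonRadius = 2,
                              trunkLength = 70, branchRate = 1.5,
                              branchLengthMean = 30, branchLengthSd = 8,
                              alignmentFraction = 0.8, alignmentGap = 0,
                              hotspot = FALSE, hotspotMultiplier = 3,
                              contactDistance = 2, seed = 1L) {
  spec <- list(gridDim = as.integer(gridDim), voxelSize = voxelSize,
               vesselCount = as.integer(vesselCount),
               vesselRadius = vesselRadius,
               axonCount = as.integer(axonCount), axonRadius = axonRadius,
               trunkLength = trunkLength, branchRate = branchRate,
               branchLengthMean = branchLengthMean,
               branchLengthSd = branchLengthSd,
               alignmentFraction = alignmentFraction,
               alignmentGap = alignmentGap, hotspot = isTRUE(hotspot),
               hotspotMultiplier = hotspotMultiplier,
               contactDistance = contactDistance, seed = as.integer(seed))
  with(spec, {
    stopifnot(length(gridDim) == 3, all(gridDim >= 1), voxelSize > 0,
              vesselCount >= 0, axonCount >= 0, vesselRadius > 0,
              axonRadius > 0, branchRate >= 0, branchLengthMean > 0,
              branchLengthSd >= 0, alignmentFraction >= 0,
              alignmentFraction <= 1, hotspotMultiplier >= 0,
              contactDistance >= 0, trunkLength > 0)
  })
  maxR <- max(spec$vesselRadius * (spec$vesselCount > 0),
              spec$axonRadius * (spec$axonCount > 0))
  if ((spec$vesselCount > 0 || spec$axonCount > 0) &&
      min(spec$gridDim * spec$voxelSize) < 2 * maxR + 2 * spec$voxelSize)
    stop("grid too small to contain any tube at the requested radius")
  class(spec) <- "tissuePhantomSpec"
  spec
}

# correlated random walk inside the margin box, step um, start uniform
walkPolyline <- function(lo, hi, step, targetLen, wobble = 0.15) {
  p <- stats::runif(3, lo, hi)
  dir <- unitv(stats::rnorm(3))
  pts <- matrix(p, 1, 3)
  len <- 0
  while (len < targetLen) {
    dir <- unitv(dir + stats::rnorm(3, 0, wobble))
    q <- p + step * dir
    if (any(q < lo) || any(q > hi)) break
    pts <- rbind(pts, q)
    len <- len + step
    p <- q
  }
  pts
}

# trunk polyline following a vessel at fixed surface gap
alignedPolyline <- function(vesselPts, offsetDist, targetLen, lo, hi) {
  res <- resamplePolyline(vesselPts, 4)
  n <- nrow(res)
  if (n < 3) return(NULL)
  need <- ceiling(targetLen / 4) + 1
  i0 <- if (n > need) sample.int(n - need, 1) else 1L
  idx <- i0:min(n, i0 + need - 1)
  a <- unitv(stats::rnorm(3))
  out <- matrix(NA_real_, length(idx), 3)
  kept <- 0
  for (j in seq_along(idx)) {
    i <- idx[j]
    tv <- if (i < n) res[i + 1, ] - res[i, ] else res[i, ] - res[i - 1, ]
    tv <- unitv(tv)
    u <- a - sum(a * tv) * tv
    if (sqrt(sum(u^2)) < 1e-6) next
    p <- res[i, ] + offsetDist * unitv(u)
    if (any(p < lo) || any(p > hi)) break
    kept <- kept + 1
    out[kept, ] <- p
  }
  if (kept < 2) return(NULL)
  out[seq_len(kept), , drop = FALSE]
}

# branch-point arc positions kept clear of the trunk ends and of each other
# (margin/minSep um), so the planted topology survives spur pruning and
# junction consolidation; k is reduced when the trunk cannot host it
drawSeparatedArcs <- function(k, tl, margin = 6, minSep = 6) {
  if (tl <= 2 * margin) return(numeric(0))
  while (k > 0) {
    for (try in 1:100) {
      x <- sort(stats::runif(k, margin, tl - margin))
      if (k == 1 || min(diff(x)) >= minSep) return(x)
    }
    k <- k - 1
  }
  numeric(0)
}

# split trunk at branch arc positions -> piece lengths
trunkPieceLengths <- function(trunkLen, branchArcs) {
  cuts <- sort(branchArcs)
  diff(c(0, cuts, trunkLen))
}

#' Generate a synthetic axon/vessel tissue phantom with planted truth
#'
#' Draws vessel and axon centrelines per the spec (correlated random walks;
#' aligned axon trunks resampled along a vessel at a fixed surface gap;
#' Poisson branching with class-dependent sprouting), rasterizes them as
#' capsule tubes (voxel centres within the radius), and computes the
#' morphometric ground truth from the continuous geometry: analytic tube
#' volumes and branch bookkeeping, and surface-sampled contact statistics.
#' The truth contact rule adds one voxel edge to the contact distance to
#' emulate the voxel-centre distance measurement of the estimator (surface
#' voxel centres sit about half a voxel inside the continuous surface on
#' each side).
#'
#' @param spec a [tissuePhantomSpec()].
#' @return list with `axon` and `vessel` ([VolumeMask-class]) and `truth`,
#'   a data.frame with columns `variable` (the 12 profile variables),
#'   `value`, `tolerance`, `type` (`"relative"`/`"absolute"`).
#' @export
generateTissuePhantom <- function(spec) {
  stopifnot(inherits(spec, "tissuePhantomSpec"))
  withSeed(spec$seed, {
    d <- spec$gridDim; s <- spec$voxelSize
    ext <- d * s
    gridMm3 <- prod(ext) / 1e9
    margin <- max(spec$vesselRadius, spec$axonRadius) + s
    lo <- rep(margin, 3); hi <- ext - margin

    # ---- vessels ----
    # redrawn when two vessels would fuse (analytic tube volumes assume
    # disjoint tubes)
    vesselPls <- list()
    if (spec$vesselCount > 0) {
      vSegA <- NULL; vSegB <- NULL
      vClear <- 2 * spec$vesselRadius + s
      for (v in seq_len(spec$vesselCount)) {
        pl <- NULL
        for (try in 1:20) {
          cand <- walkPolyline(lo, hi, step = 4,
                               targetLen = 0.9 * max(ext), wobble = 0.08)
          # a capillary shorter than ~40 um is a blob, not a vessel
          if (nrow(cand) < 2 || polylineLength(cand) < 40) next
          pl <- cand
          if (is.null(vSegA)) break
          dmin <- min(cpp_min_dist_segments(resamplePolyline(cand, 4),
                                            vSegA, vSegB))
          if (dmin >= vClear) break
        }
        if (is.null(pl)) next
        sg <- polylineSegs(pl)
        vSegA <- rbind(vSegA, sg$A); vSegB <- rbind(vSegB, sg$B)
        vesselPls[[length(vesselPls) + 1]] <- pl
      }
    }

    # ---- axons ----
    nAligned <- round(spec$alignmentFraction * spec$axonCount)
    # one aligned axon per vessel: two touching axons on one vessel would
    # fuse in the rasterized mask and shred the skeleton topology
    nAligned <- min(nAligned, length(vesselPls))
    rate <- spec$branchRate *
      (if (spec$hotspot) spec$hotspotMultiplier else 1)
    axons <- list()   # each: list(trunk = pts, branches = list(pts), arcs)
    # collision avoidance: axon tubes fusing in the rasterized mask would
    # create junctions the truth record knows nothing about, so candidate
    # trunks and branches keeping less than one tube diameter (plus one
    # voxel) of clearance from already-placed axons are redrawn
    axSegA <- NULL; axSegB <- NULL
    clearance <- 2 * spec$axonRadius + s
    tooClose <- function(pts, skip = 0) {
      if (is.null(axSegA) || is.null(pts)) return(FALSE)
      if (skip > 0 && nrow(pts) > skip) pts <- pts[-seq_len(skip), ,
                                                   drop = FALSE]
      any(cpp_min_dist_segments(pts, axSegA, axSegB) < clearance)
    }
    addSegs <- function(pl) {
      sg <- polylineSegs(pl)
      axSegA <<- rbind(axSegA, sg$A); axSegB <<- rbind(axSegB, sg$B)
    }
    if (spec$axonCount > 0) {
      for (ax in seq_len(spec$axonCount)) {
        aligned <- ax <= nAligned
        trunk <- NULL
        if (aligned) {
          vp <- vesselPls[[1 + (ax - 1) %% length(vesselPls)]]
          for (try in 1:10) {
            cand <- alignedPolyline(
              vp, spec$vesselRadius + spec$axonRadius + spec$alignmentGap,
              spec$trunkLength, lo, hi)
            if (!is.null(cand) && !tooClose(resamplePolyline(cand, 3))) {
              trunk <- cand; break
            }
            if (is.null(trunk)) trunk <- cand  # keep a fallback
          }
        }
        if (is.null(trunk)) {
          for (try in 1:20) {
            cand <- walkPolyline(lo, hi, step = 4,
                                 targetLen = spec$trunkLength)
            trunk <- cand
            if (nrow(cand) >= 2 &&
                !tooClose(resamplePolyline(cand, 3))) break
          }
        }
        if (is.null(trunk) || nrow(trunk) < 2) next
        addSegs(trunk)
        tl <- polylineLength(trunk)
        k <- stats::rpois(1, rate * tl / 100)
        arcs <- drawSeparatedArcs(k, tl, margin = 6, minSep = 6)
        res <- resamplePolyline(trunk, 1)
        arcAt <- function(a) res[min(nrow(res), max(1, round(a) + 1)), ]
        branches <- list(); keptArcs <- numeric(0)
        for (b in seq_along(arcs)) {
          p0 <- arcAt(arcs[b])
          i <- min(nrow(res) - 1, max(1, round(arcs[b]) + 1))
          tv <- res[i + 1, ] - res[i, ]
          tv <- if (sum(tv^2) < 1e-12) unitv(stats::rnorm(3)) else unitv(tv)
          placed <- NULL
          for (try in 1:10) {
            # direction well away from the trunk tangent
            repeat {
              dir <- unitv(stats::rnorm(3))
              if (abs(sum(dir * tv)) < 0.6) break
            }
            blen <- max(10, stats::rnorm(1, spec$branchLengthMean,
                                         spec$branchLengthSd))
            # clip to margin box
            tmax <- blen
            for (axis in 1:3) {
              if (dir[axis] > 1e-12)
                tmax <- min(tmax, (hi[axis] - p0[axis]) / dir[axis])
              if (dir[axis] < -1e-12)
                tmax <- min(tmax, (lo[axis] - p0[axis]) / dir[axis])
            }
            if (tmax < 10) next
            blen <- min(blen, tmax)
            cand <- rbind(p0, p0 + blen * dir)
            # clearance check skipping the first ~9 um near the own trunk
            chk <- resamplePolyline(cand, 3)
            if (!tooClose(chk, skip = 3)) { placed <- cand; break }
          }
          if (is.null(placed)) next
          branches[[length(branches) + 1]] <- placed
          keptArcs <- c(keptArcs, arcs[b])
          addSegs(placed)
        }
        axons[[length(axons) + 1]] <-
          list(trunk = trunk, branches = branches, arcs = keptArcs,
               trunkLen = tl)
      }
    }

    # ---- rasterize ----
    axonMask <- array(FALSE, d); vesselMask <- array(FALSE, d)
    paintAll <- function(mask, pls, r) {
      cur <- as.logical(mask)
      for (pl in pls) {
        sg <- polylineSegs(pl)
        cur <- cpp_paint_capsules(cur, d, rep(s, 3), sg$A, sg$B, r)
      }
      array(cur, d)
    }
    vesselMask <- paintAll(vesselMask, vesselPls, spec$vesselRadius)
    axonPls <- unlist(lapply(axons, function(a) c(list(a$trunk), a$branches)),
                      recursive = FALSE)
    if (length(axonPls))
      axonMask <- paintAll(axonMask, axonPls, spec$axonRadius)

    truth <- phantomTruth(spec, axons, vesselPls, gridMm3)
    list(axon = VolumeMask(axonMask, s),
         vessel = VolumeMask(vesselMask, s),
         truth = truth)
  })
}

# continuous-geometry ground truth for the 12 profile variables
phantomTruth <- function(spec, axons, vesselPls, gridMm3) {
  s <- spec$voxelSize
  ra <- spec$axonRadius; rv <- spec$vesselRadius
  # Voxel-measurement emulation. (1) Surface-voxel centres sit inside the
  # continuous surface by roughly U(0, s) along the normal, so the
  # centre-to-centre contact rule (<= d) seen from the continuous geometry
  # is a soft threshold: P(contact | gap g) = P(S <= d - g) with
  # S = insetA + insetV ~ triangular(0, 2s, mode s). (2) Exposed-face
  # counting measures the area of an isotropically oriented smooth surface
  # with the lattice factor 3/2, so absolute truth areas are stated in that
  # metric.
  contactWeight <- function(g) {
    x <- spec$contactDistance - g
    ifelse(x <= 0, 0,
           ifelse(x <= s, x^2 / (2 * s^2),
                  ifelse(x <= 2 * s, 1 - (2 * s - x)^2 / (2 * s^2), 1)))
  }
  latticeFactor <- 1.5
  gridUm3 <- gridMm3 * 1e9

  axonLens <- vapply(axons, function(a)
    a$trunkLen + sum(vapply(a$branches, polylineLength, 0)), 0)
  totalAxonLen <- sum(axonLens)
  edgeLens <- unlist(lapply(axons, function(a) {
    c(trunkPieceLengths(a$trunkLen, a$arcs),
      vapply(a$branches, polylineLength, 0))
  }))
  nBranchPts <- sum(vapply(axons, function(a) length(a$arcs), 0))
  vesselLen <- sum(vapply(vesselPls, polylineLength, 0))

  segsOf <- function(pls) {
    A <- do.call(rbind, lapply(pls, function(p) polylineSegs(p)$A))
    B <- do.call(rbind, lapply(pls, function(p) polylineSegs(p)$B))
    list(A = A, B = B)
  }
  axonPls <- unlist(lapply(axons, function(a) c(list(a$trunk), a$branches)),
                    recursive = FALSE)

  # surface-sampled contact truth
  nAng <- 12; delta <- 2
  ringPoints <- function(pl, r) {
    res <- resamplePolyline(pl, delta)
    n <- nrow(res)
    if (n < 2) return(NULL)
    pts <- matrix(NA_real_, n * nAng, 3)
    ring <- 0
    for (i in seq_len(n)) {
      tv <- if (i < n) res[i + 1, ] - res[i, ] else res[i, ] - res[i - 1, ]
      nb <- perpBasis(unitv(tv))
      th <- 2 * pi * (seq_len(nAng) - 1) / nAng
      pts[ring * nAng + seq_len(nAng), ] <-
        t(res[i, ] + r * (outer(nb$u, cos(th)) + outer(nb$v, sin(th))))
      ring <- ring + 1
    }
    pts[seq_len(ring * nAng), , drop = FALSE]
  }

  v7 <- v8 <- v9 <- v10 <- v11 <- v12 <- NA_real_
  contactAreaAx <- contactAreaVes <- 0; nZones <- 0
  if (length(axonPls) && length(vesselPls)) {
    vs <- segsOf(vesselPls)
    as_ <- segsOf(axonPls)
    # axon side
    axContactFrac <- 0; totPts <- 0
    contactPts <- NULL
    for (pl in axonPls) {
      rp <- ringPoints(pl, ra)
      if (is.null(rp)) next
      w <- contactWeight(cpp_min_dist_segments(rp, vs$A, vs$B) - rv)
      axContactFrac <- axContactFrac + sum(w)
      totPts <- totPts + length(w)
      if (any(w >= 0.5))
        contactPts <- rbind(contactPts, rp[w >= 0.5, , drop = FALSE])
    }
    # zones: connected components of the 3D contact point cloud, merged at
    # a 2-voxel cell size -- 26-connected voxel zones join contact patches
    # that meet anywhere in space (e.g. branch roots on an aligned trunk),
    # which per-polyline bookkeeping would count separately
    zoneCount <- 0
    if (!is.null(contactPts) && nrow(contactPts) > 0) {
      cell <- 2 * s
      ci <- floor(sweep(contactPts, 2, cell, "/")) + 1
      storage.mode(ci) <- "integer"
      cd <- as.integer(apply(ci, 2, max) + 1L)
      cm <- array(FALSE, cd)
      cm[ci] <- TRUE
      zoneCount <- max(cpp_label26(as.logical(cm), cd))
    }
    v7 <- if (totPts > 0) 100 * axContactFrac / totPts else NA_real_
    patchA <- delta * 2 * pi * ra / nAng
    contactAreaAx <- axContactFrac * patchA * latticeFactor
    nZones <- zoneCount
    axSurf <- 2 * pi * ra * totalAxonLen          # um^2
    v9 <- if (axSurf > 0) zoneCount / (axSurf / 1e6) else NA_real_
    v10 <- if (zoneCount > 0) contactAreaAx / zoneCount else NA_real_
    # vessel side
    vesContact <- 0; vesPts <- 0
    for (pl in vesselPls) {
      rp <- ringPoints(pl, rv)
      if (is.null(rp)) next
      w <- contactWeight(cpp_min_dist_segments(rp, as_$A, as_$B) - ra)
      vesContact <- vesContact + sum(w)
      vesPts <- vesPts + nrow(rp)
    }
    v8 <- if (vesPts > 0) 100 * vesContact / vesPts else NA_real_
    contactAreaVes <- vesContact * delta * 2 * pi * rv / nAng * latticeFactor
    v11 <- (contactAreaAx + contactAreaVes) / 2 / gridMm3
    # median centreline-to-vessel-surface distance
    allCl <- do.call(rbind, lapply(axonPls, resamplePolyline, delta = 2))
    v12 <- stats::median(cpp_min_dist_segments(allCl, vs$A, vs$B) - rv)
  }

  # capsule rasterization adds hemispherical end caps: a full cap pair per
  # trunk/vessel, one far-end hemisphere per branch (the root is embedded
  # in the trunk)
  nTrunks <- length(axons)
  nBranches <- sum(vapply(axons, function(a) length(a$branches), 0))
  axonVol <- pi * ra^2 * totalAxonLen +
    nTrunks * 4 / 3 * pi * ra^3 + nBranches * 2 / 3 * pi * ra^3
  vesselVol <- pi * rv^2 * vesselLen +
    length(vesselPls) * 4 / 3 * pi * rv^3
  vals <- c(
    axon_volume_density_pct = 100 * axonVol / gridUm3,
    axon_branch_count_per_mm3 = length(edgeLens) / gridMm3,
    axon_mean_branch_length_um = if (length(edgeLens)) mean(edgeLens) else 0,
    axon_branchpoint_count_per_mm3 = nBranchPts / gridMm3,
    vessel_volume_density_pct = 100 * vesselVol / gridUm3,
    vessel_mean_radius_um = if (length(vesselPls)) rv else NA_real_,
    contact_axon_bv_pct = v7,
    contact_bv_axon_pct = v8,
    contact_zone_count_per_mm2 = v9,
    contact_zone_mean_area_um2 = v10,
    contact_area_per_mm3 = v11,
    axon_vessel_median_distance_um = v12)
  # the median skeleton-to-vessel distance is a median of a bimodal
  # (aligned vs free axon) distribution, so its tolerance is hybrid:
  # 3 um or 35%, whichever is larger
  tol <- c(0.25, 0.30, 0.30, 0.40, 0.25, 0.25,
           15, 15, 0.75, 0.75, 0.75,
           max(3, 0.35 * abs(if (is.na(v12)) 0 else v12)))
  type <- c(rep("relative", 6), "absolute", "absolute",
            "relative", "relative", "relative", "absolute")
  data.frame(variable = profileVariableNames(), value = unname(vals),
             tolerance = tol, type = type, stringsAsFactors = FALSE)
}

#' Tissue-class presets for the phantom generator
#'
#' Preset [tissuePhantomSpec()] parameterizations reproducing the
#' qualitative innervation patterns of the staging classes: control and
#' asymptomatic acinar tissue (dense vessel-aligned axons, few branches),
#' noninvasive neoplastic lesions (NF/ADM/PanIN: sprouting hotspots with
#' more, shorter branches, reduced axon-vessel alignment, enlarged vessels)
#' and well-differentiated invasive tumor regions (similar contact changes,
#' moderate density).
#'
#' @param class one of `"control"`, `"asympt"`, `"NF"`, `"ADM"`, `"PanIN"`,
#'   `"PDAC"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [tissuePhantomSpec()].
#' @return a `tissuePhantomSpec`.
#' @export
tissueClassSpec <- function(class = c("control", "asympt", "NF", "ADM",
                                      "PanIN", "PDAC"),
                            seed = 1L, ...) {
  class <- match.arg(class)
  base <- switch(class,
    control = ,
    asympt = list(axonCount = 6, branchRate = 1.5, branchLengthMean = 30,
                  alignmentFraction = 0.8, vesselRadius = 4,
                  hotspot = FALSE),
    NF = ,
    ADM = ,
    PanIN = list(axonCount = 10, branchRate = 2, branchLengthMean = 15,
                 alignmentFraction = 0.4, vesselRadius = 5,
                 hotspot = TRUE, hotspotMultiplier = 2.5),
    PDAC = list(axonCount = 7, branchRate = 2, branchLengthMean = 15,
                alignmentFraction = 0.35, vesselRadius = 5,
                hotspot = TRUE, hotspotMultiplier = 2))
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(tissuePhantomSpec, args)
}
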