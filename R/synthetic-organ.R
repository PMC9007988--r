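# Whole-organ phantom: ellipsoidal organ, tumor nodule inside it, nerve
# tubes partly routed through the tumor. Returned "true" volumes are the
# voxel counts times the voxel volume of the returned masks, so they are
# self-consistent with the volumetric estimators by construction.

#' Generate an organ/tumor/nerve phantom with known volume partition
#'
#' Builds an ellipsoidal organ mask, an ellipsoidal tumor nodule contained
#' in it (`tumorFraction` of the organ semi-axes; 0 gives no tumor) and a
#' set of nerve tubes whose trunks run along the organ's long axis, a
#' fraction of which is routed through the tumor centre.
#'
#' @param gridDim integer(3) grid shape in voxels.
#' @param voxelSize isotropic voxel size, um.
#' @param tumorFraction tumor semi-axes as a fraction of the organ's
#'   (0 to 0.9).
#' @param nerveCount number of nerve tubes.
#' @param nerveRadius nerve tube radius, um.
#' @param intratumoralFraction fraction of nerves routed through the tumor
#'   centre.
#' @param seed RNG seed.
#' @return list with `nerve`, `organ`, `tumor` ([VolumeMask-class], the
#'   nerve mask restricted to the organ) and `truth`: `V_TH_TOTAL`,
#'   `V_TH_INTRA`, `V_Panc`, `V_PDAC` in um^3.
#' @export
generateOrganVolume <- function(gridDim = c(96L, 48L, 48L), voxelSize = 4,
                                tumorFraction = 0.35, nerveCount = 8,
                                nerveRadius = 6,
                                intratumoralFraction = 0.3, seed = 1L) {
  stopifnot(length(gridDim) == 3, all(gridDim >= 8), voxelSize > 0,
            tumorFraction >= 0, tumorFraction <= 0.9, nerveCount >= 0,
            nerveRadius > 0, intratumoralFraction >= 0,
            intratumoralFraction <= 1)
  withSeed(seed, {
    d <- as.integer(gridDim); s <- voxelSize
    ext <- d * s
    ctr <- ext / 2
    semi <- 0.45 * ext
    co <- arrayInd(seq_len(prod(d)), d)
    cx <- sweep(sweep(co, 2, 0.5), 2, s, "*")  # voxel centres, um
    ell <- function(centre, ax) {
      rowSums(sweep(sweep(cx, 2, centre), 2, ax, "/")^2) <= 1
    }
    organ <- array(ell(ctr, semi), d)
    tumor <- array(FALSE, d)
    tctr <- ctr + c(0.15, 0, 0) * ext
    if (tumorFraction > 0) {
      tumor <- array(ell(tctr, tumorFraction * semi), d)
      tumor <- tumor & organ  # containment guaranteed; enforce anyway
    }
    nerve <- array(FALSE, d)
    if (nerveCount > 0) {
      nIntra <- round(intratumoralFraction * nerveCount)
      for (i in seq_len(nerveCount)) {
        through <- if (tumorFraction > 0) tctr else ctr
        target <- if (i <= nIntra) through
                  else ctr + stats::runif(3, -0.25, 0.25) * ext
        y0 <- target[2] + stats::rnorm(1, 0, 0.05 * ext[2])
        z0 <- target[3] + stats::rnorm(1, 0, 0.05 * ext[3])
        A <- matrix(c(0.05 * ext[1], y0, z0), 1)
        B <- matrix(c(0.95 * ext[1], target[2], target[3]), 1)
        mid <- matrix(c(target[1], target[2], target[3]), 1)
        nerve <- array(cpp_paint_capsules(as.logical(nerve), d, rep(s, 3),
                                          rbind(A, mid), rbind(mid, B),
                                          nerveRadius), d)
      }
      nerve <- nerve & organ  # nerve mask restricted to the organ
    }
    vox <- s^3
    truth <- list(V_TH_TOTAL = sum(nerve) * vox,
                  V_TH_INTRA = sum(nerve & tumor) * vox,
                  V_Panc = sum(organ) * vox,
                  V_PDAC = sum(tumor) * vox)
    list(nerve = VolumeMask(nerve, s, anatomicalAxis = 1L),
         organ = VolumeMask(organ, s, anatomicalAxis = 1L),
         tumor = VolumeMask(tumor, s, anatomicalAxis = 1L),
         truth = truth)
  })
}
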