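# Axon/vessel contact quantification on voxel surfaces.
#
# A surface voxel is a mask voxel with at least one face-adjacent background
# voxel (the image border counts as background); its surface area is its
# exposed-face count times the voxel face area. A surface voxel of one
# structure is "in contact" when its centre lies within the contact distance
# d of some surface-voxel centre of the other structure. Contact zones are
# 26-connected components of the axon-side contact voxels.

surfaceInfo <- function(arr, d, s) {
  faces <- cpp_exposed_faces(as.logical(arr), d)
  list(faces = faces, surf = faces > 0L, area = sum(faces) * s^2)
}

#' Axon-vessel contact statistics
#'
#' Computes the five contact descriptors of the morphometric profile:
#' percentage of axon surface area in contact with the vessel surface
#' (`pctContactAxonBV`), the reciprocal vessel-side percentage
#' (`pctContactBVAxon`), the number of contact zones per mm^2 of axon
#' surface, the mean contact-zone area (um^2), and the total contact area
#' per mm^3 of analysed tissue (um^2/mm^3, averaged over the two sides of
#' the interface so that swapping the masks leaves it unchanged).
#'
#' Distances between surface-voxel centres come from an exact Euclidean
#' distance transform. Undefined ratios (empty surfaces, no zones) are
#' returned as `NA`.
#'
#' @param axon,vessel [VolumeMask-class] objects on one grid; isotropic
#'   voxels are required for area bookkeeping.
#' @param d contact distance in micrometres (>= 0); default 2 um, about one
#'   voxel at the generator resolution.
#' @return list with the five descriptors plus `nZones`,
#'   `contactAreaAxon`, `contactAreaVessel` (um^2).
#' @export
contactStatistics <- function(axon, vessel, d = 2) {
  checkSameGeometry(axon, vessel)
  vs <- voxelSize(axon)
  if (max(vs) - min(vs) > 1e-9)
    stop("contact statistics require isotropic voxels")
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0)
    stop("contact distance d must be a single number >= 0")
  s <- vs[1]
  dm <- dim(maskArray(axon))
  A <- surfaceInfo(maskArray(axon), dm, s)
  V <- surfaceInfo(maskArray(vessel), dm, s)

  contactOf <- function(me, other) {
    # me surface voxels within d of other's surface-voxel centres
    if (!any(other$surf)) return(rep(FALSE, length(me$surf)))
    dist <- cpp_edt(other$surf, dm, rep(s, 3))
    me$surf & dist <= d + 1e-9
  }
  cA <- contactOf(A, V)
  cV <- contactOf(V, A)
  contactAreaA <- sum(A$faces[cA]) * s^2
  contactAreaV <- sum(V$faces[cV]) * s^2

  # zones: 26-connected components of axon contact voxels
  zoneMask <- array(FALSE, dm); zoneMask[cA] <- TRUE
  lab <- cpp_label26(as.logical(zoneMask), dm)
  nZones <- if (any(cA)) max(lab) else 0L
  meanZoneArea <- if (nZones > 0) contactAreaA / nZones else NA_real_

  gridMm3 <- prod(dm) * s^3 / 1e9
  list(
    pctContactAxonBV = if (A$area > 0) 100 * contactAreaA / A$area
                       else NA_real_,
    pctContactBVAxon = if (V$area > 0) 100 * contactAreaV / V$area
                       else NA_real_,
    zoneCountPerMm2 = if (A$area > 0) nZones / (A$area / 1e6) else NA_real_,
    meanZoneArea = meanZoneArea,
    contactAreaPerMm3 = (contactAreaA + contactAreaV) / 2 / gridMm3,
    nZones = as.integer(nZones),
    contactAreaAxon = contactAreaA,
    contactAreaVessel = contactAreaV
  )
}
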