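#' @include AllClasses.R volume.R
NULL

#' Default striatal anatomy
#'
#' Ellipsoidal stand-ins for the four striatal nuclei at anatomically
#' plausible head-centered coordinates (putamen about 4.8 ml, caudate about
#' 2.9 ml per side).  The x axis runs left (-) to right (+), y posterior to
#' anterior, z inferior to superior.
#'
#' @param putamenSBR numeric(2), true SBR of (left, right) putamen.
#' @param caudateSBR numeric(2), true SBR of (left, right) caudate.
#' @return list of four \code{StriatalStructure}s.
#' @export
defaultStructures <- function(putamenSBR = c(2, 2), caudateSBR = putamenSBR) {
  list(
    StriatalStructure("putamen", "left",  c(-27, -2, 0), c(8, 16, 9), putamenSBR[1]),
    StriatalStructure("putamen", "right", c( 27, -2, 0), c(8, 16, 9), putamenSBR[2]),
    StriatalStructure("caudate", "left",  c(-13, 14, 8), c(6, 13, 9), caudateSBR[1]),
    StriatalStructure("caudate", "right", c( 13, 14, 8), c(6, 13, 9), caudateSBR[2]))
}

structureMask <- function(spec, s, dilate = 0) {
  ellipsoidMask(spec@gridShape, spec@voxelSize, s@center, s@semiAxes + dilate)
}

brainMask <- function(spec) {
  ellipsoidMask(spec@gridShape, spec@voxelSize, c(0, 0, 0), spec@brainSemiAxes)
}

#' Piecewise-constant activity map of a phantom
#'
#' Builds the noiseless ground-truth activity distribution: 0 outside the
#' brain ellipsoid, \code{backgroundActivity} inside it, and
#' \code{backgroundActivity * (1 + trueSBR)} inside each striatal structure.
#' Deterministic; no RNG involved.
#'
#' @param spec a valid \code{PhantomSpec}.
#' @return a \code{SpectVolume}.
#' @export
buildActivityMap <- function(spec) {
  validObject(spec)
  brain <- brainMask(spec)
  a <- array(0, spec@gridShape)
  a[brain] <- spec@backgroundActivity
  for (s in spec@structures) {
    m <- structureMask(spec, s)
    if (any(m & !brain))
      stop(sprintf("structure %s %s extends outside the brain", s@side, s@kind))
    a[m] <- spec@backgroundActivity * (1 + s@trueSBR)
  }
  SpectVolume(a, spec@voxelSize)
}

#' Region masks of a phantom
#'
#' \code{makePutamenMasks} builds generously oversized unilateral putamen
#' masks (the putamen ellipsoid dilated by \code{dilation} mm) for the
#' hottest-voxel analysis; voxels within \code{caudateExclusion} mm of a
#' caudate are removed so the masks capture putaminal signal only.
#' \code{makeReferenceMask} builds the nonspecific reference region: the
#' brain minus all striatal structures dilated by \code{margin} mm.
#'
#' @param spec a \code{PhantomSpec} whose structures include both putamina.
#' @param dilation mm added to the putamen semi-axes (default 6).
#' @param caudateExclusion mm added to the caudate semi-axes for the
#'   exclusion zone (default 2).
#' @return \code{makePutamenMasks}: named list with logical arrays
#'   \code{left} and \code{right}.
#' @export
makePutamenMasks <- function(spec, dilation = 6, caudateExclusion = 2) {
  validObject(spec)
  kinds <- vapply(spec@structures, function(s) s@kind, "")
  sides <- vapply(spec@structures, function(s) s@side, "")
  excl <- array(FALSE, spec@gridShape)
  for (s in spec@structures[kinds == "caudate"])
    excl <- excl | structureMask(spec, s, dilate = caudateExclusion)
  brain <- brainMask(spec)
  out <- list()
  for (side in c("left", "right")) {
    i <- which(kinds == "putamen" & sides == side)
    if (length(i) != 1L) stop("phantom must contain exactly one ", side, " putamen")
    m <- structureMask(spec, spec@structures[[i]], dilate = dilation)
    out[[side]] <- m & brain & !excl
  }
  out
}

#' @param margin mm by which each structure is dilated before subtraction
#'   from the brain (default 4).
#' @return \code{makeReferenceMask}: logical 3-D array.
#' @rdname makePutamenMasks
#' @export
makeReferenceMask <- function(spec, margin = 4) {
  validObject(spec)
  ref <- brainMask(spec)
  for (s in spec@structures) ref <- ref & !structureMask(spec, s, dilate = margin)
  if (!any(ref)) stop("reference mask is empty")
  ref
}
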