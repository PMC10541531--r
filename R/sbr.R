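#' @include AllClasses.R volume.R
NULL

#' Hottest-voxel specific binding ratio
#'
#' Computes the specific binding ratio of a region from a DVR image by the
#' hottest-voxels method: the \code{n} highest in-mask DVR values are
#' averaged, where \code{n} corresponds to a fixed total volume (default
#' 10 ml, i.e. 1250 voxels on a 2 mm isotropic grid), and the SBR is that
#' mean minus 1.  Because the mask is much larger than the structure itself,
#' the measure is robust against mask placement.  Selection is deterministic
#' under ties (ordered by value, then by linear voxel index).
#'
#' @param dvr \code{SpectVolume} in DVR units.
#' @param mask logical array, same grid; its volume must be at least
#'   \code{targetVolumeMl}.
#' @param targetVolumeMl total hottest-voxel volume in ml (default 10).
#' @return the SBR (a single number).
#' @export
hottestVoxelSBR <- function(dvr, mask, targetVolumeMl = 10) {
  stopifnot(is(dvr, "SpectVolume"))
  if (!identical(dim(mask), dim(dvr@data)))
    stop("mask must share the volume grid")
  vml <- voxelVolumeMl(dvr)
  n <- round(targetVolumeMl / vml)
  maskMl <- sum(mask) * vml
  if (maskMl < targetVolumeMl)
    stop(sprintf("mask volume %.2f ml is smaller than the target %.2f ml",
                 maskMl, targetVolumeMl))
  vals <- dvr@data[mask]
  ord <- order(vals, seq_along(vals), decreasing = c(TRUE, FALSE),
               method = "radix")
  mean(vals[ord[seq_len(n)]]) - 1
}

#' Bilateral putamen SBR of one scan
#'
#' Applies \code{\link{hottestVoxelSBR}} to the left and right putamen masks
#' and summarizes the scan by the minimum SBR over hemispheres (the more
#' affected side).
#'
#' @param dvr \code{SpectVolume} in DVR units.
#' @param maskLeft,maskRight logical putamen masks.
#' @param targetVolumeMl hottest-voxel volume per side in ml (default 10).
#' @param scanID identifier stored in the result.
#' @return an \code{\linkS4class{SBRResult}}.
#' @export
putamenSBRBilateral <- function(dvr, maskLeft, maskRight, targetVolumeMl = 10,
                                scanID = "scan") {
  l <- hottestVoxelSBR(dvr, maskLeft, targetVolumeMl)
  r <- hottestVoxelSBR(dvr, maskRight, targetVolumeMl)
  n <- round(targetVolumeMl / voxelVolumeMl(dvr))
  new("SBRResult", scanID = as.character(scanID), sbrLeft = l, sbrRight = r,
      sbrMin = min(l, r), nVoxelsUsed = as.integer(n))
}
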