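#' @include AllClasses.R volume.R
NULL

#' Scale a volume to distribution-volume-ratio (DVR) units
#'
#' Divides every voxel by the 75th percentile of the voxel intensities in a
#' nonspecific reference region, so the scaled image is a semi-quantitative
#' DVR image in which the reference region sits at 1.  The percentile uses
#' the linear-interpolation convention between order statistics
#' (\code{stats::quantile} type 7), pinned by the test suite.
#'
#' @param v a \code{SpectVolume}.
#' @param refMask logical array of the reference region, same grid as
#'   \code{v}, nonempty.
#' @return list with \code{volume} (the scaled \code{SpectVolume}) and
#'   \code{factor} (the 75th-percentile divisor).
#' @export
scaleToDVR <- function(v, refMask) {
  stopifnot(is(v, "SpectVolume"))
  if (!identical(dim(refMask), dim(v@data)))
    stop("reference mask must share the volume grid")
  if (!any(refMask)) stop("reference mask is empty")
  q75 <- stats::quantile(v@data[refMask], 0.75, names = FALSE, type = 7)
  if (q75 <= 0)
    stop("degenerate scan: reference-region 75th percentile is not positive")
  list(volume = SpectVolume(v@data / q75, v@voxelSize, v@origin), factor = q75)
}
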