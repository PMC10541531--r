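#' @include AllClasses.R
NULL

#' Accessors for SpectVolume and BodyContour
#'
#' \code{imgData} returns the raw 3-D array, \code{voxelSize} the voxel edge
#' lengths in mm, \code{voxelVolumeMl} the volume of one voxel in ml,
#' \code{contourMask} the filled-ellipse mask of a \code{BodyContour} and
#' \code{contourEllipses} its per-slice ellipse table.
#'
#' @param x a \code{SpectVolume} or \code{BodyContour}.
#' @return see description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setMethod("imgData", "SpectVolume", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "SpectVolume", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "BodyContour", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("voxelVolumeMl", function(x) standardGeneric("voxelVolumeMl"))
#' @rdname accessors
#' @export
setMethod("voxelVolumeMl", "SpectVolume", function(x) prod(x@voxelSize) / 1000)

#' @rdname accessors
#' @export
setGeneric("contourMask", function(x) standardGeneric("contourMask"))
#' @rdname accessors
#' @export
setMethod("contourMask", "BodyContour", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("contourEllipses", function(x) standardGeneric("contourEllipses"))
#' @rdname accessors
#' @export
setMethod("contourEllipses", "BodyContour", function(x) x@ellipses)

#' Effect size and cutoff of a two-Gaussian fit
#'
#' \code{effectSize} returns the distance between the two fitted Gaussians
#' scaled to the pooled standard deviation,
#' \deqn{d = (M_2 - M_1) / \sqrt{(SD_1^2 + SD_2^2)/2},}
#' and \code{cutoff} the decision threshold halfway between the component
#' means in units of standard deviations,
#' \deqn{c = (SD_2 M_1 + SD_1 M_2) / (SD_1 + SD_2).}
#'
#' @param fit a \code{TwoGaussianFit} (or anything with M1/SD1/M2/SD2 slots).
#' @return a single number.
#' @examples
#' f <- new("TwoGaussianFit", A1 = 1, M1 = 0, SD1 = 1, A2 = 1, M2 = 1,
#'          SD2 = 1, sse = 0, d = 1, c = 0.5, nValues = 0L, binWidth = 0.1)
#' effectSize(f)  # 1
#' cutoff(f)      # 0.5
#' @name mixture-derived
NULL

#' @rdname mixture-derived
#' @export
setGeneric("effectSize", function(fit) standardGeneric("effectSize"))
#' @rdname mixture-derived
#' @export
setMethod("effectSize", "TwoGaussianFit", function(fit)
  (fit@M2 - fit@M1) / sqrt((fit@SD1^2 + fit@SD2^2) / 2))

#' @rdname mixture-derived
#' @export
setGeneric("cutoff", function(fit) standardGeneric("cutoff"))
#' @rdname mixture-derived
#' @export
setMethod("cutoff", "TwoGaussianFit", function(fit)
  (fit@SD2 * fit@M1 + fit@SD1 * fit@M2) / (fit@SD1 + fit@SD2))

setMethod("show", "SpectVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectVolume %d x %d x %d, voxel %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(format(object@voxelSize, digits = 3), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: grid %s @ %g mm, brain semi-axes %s mm,\n",
                     "  %d structure(s), background %g, scatter %g (FWHM %g mm),",
                     " PSF %g mm, countScale %g\n"),
              paste(object@gridShape, collapse = "x"), object@voxelSize,
              paste(object@brainSemiAxes, collapse = "/"),
              length(object@structures), object@backgroundActivity,
              object@scatterFraction, object@scatterFWHM, object@psfFWHM,
              object@countScale))
})

setMethod("show", "BodyContour", function(object) {
  cat(sprintf("BodyContour: %d slice ellipse(s), mask %s (%d voxels)\n",
              nrow(object@ellipses), paste(dim(object@mask), collapse = "x"),
              sum(object@mask)))
})

setMethod("show", "ScanPair", function(object) {
  cat(sprintf("ScanPair (%s): true min putamen SBR %.3f\n",
              object@truthClass, object@trueMinPutamenSBR))
  cat("  no-ASC arm: "); show(object@volumeNoASC)
  cat("  ASC arm:    "); show(object@volumeASC)
})

setMethod("show", "TwoGaussianFit", function(object) {
  cat("Two-Gaussian histogram fit\n")
  cat(sprintf("  reduced: A1 = %.3f, M1 = %.3f, SD1 = %.3f\n",
              object@A1, object@M1, object@SD1))
  cat(sprintf("  normal:  A2 = %.3f, M2 = %.3f, SD2 = %.3f\n",
              object@A2, object@M2, object@SD2))
  cat(sprintf("  effect size d = %.3f, cutoff c = %.3f, SSE = %.4g (n = %d)\n",
              object@d, object@c, object@sse, object@nValues))
})

setMethod("show", "SBRResult", function(object) {
  cat(sprintf("SBR [%s]: left %.3f, right %.3f, min %.3f (n = %d voxels/side)\n",
              object@scanID, object@sbrLeft, object@sbrRight, object@sbrMin,
              object@nVoxelsUsed))
})
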