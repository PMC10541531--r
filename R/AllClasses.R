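#' @import methods
NULL

#' SpectVolume: a 3-D image volume
#'
#' The universal image container of the package: a 3-D grid of finite,
#' typically nonnegative intensities together with its (isotropic or
#' anisotropic) voxel size in mm and the mm position of the first voxel.
#' Emission images, DVR images, attenuation-factor maps and binary masks are
#' all carried as \code{SpectVolume}s.
#'
#' @slot data 3-D numeric array of finite values.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (all > 0).
#' @slot origin numeric(3), mm coordinate of the center of voxel (1,1,1).
#'   The default constructor centers the grid on (0,0,0).
#'
#' @exportClass SpectVolume
setClass("SpectVolume",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"))

setValidity("SpectVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3-D array")
  if (!all(is.finite(d))) return("all voxel values must be finite")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive reals (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite reals (mm)")
  TRUE
})

#' @param data 3-D numeric array.
#' @param voxelSize voxel size in mm; scalar (isotropic) or length 3.
#' @param origin mm coordinate of voxel (1,1,1); defaults to a grid centered
#'   on the origin.
#' @rdname SpectVolume-class
#' @export
SpectVolume <- function(data, voxelSize = 2, origin = NULL) {
  data <- as.array(data)
  storage.mode(data) <- "double"
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  if (is.null(origin)) origin <- -(dim(data) - 1) / 2 * voxelSize
  new("SpectVolume", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' StriatalStructure: one ellipsoidal striatal nucleus
#'
#' Geometric and intensity recipe for one striatal structure of the digital
#' phantom (caudate or putamen, left or right).  Activity inside the
#' structure is \code{background * (1 + trueSBR)}.
#'
#' @slot kind "caudate" or "putamen".
#' @slot side "left" or "right".
#' @slot center numeric(3), mm center in the head-centered frame.
#' @slot semiAxes numeric(3), positive mm semi-axes.
#' @slot trueSBR nonnegative true specific binding ratio.
#' @exportClass StriatalStructure
setClass("StriatalStructure",
  representation(kind = "character", side = "character", center = "numeric",
                 semiAxes = "numeric", trueSBR = "numeric"))

setValidity("StriatalStructure", function(object) {
  if (!object@kind %in% c("caudate", "putamen")) return("kind must be caudate/putamen")
  if (!object@side %in% c("left", "right")) return("side must be left/right")
  if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
    return("semiAxes must be 3 positive mm values")
  if (object@trueSBR < 0) return("trueSBR must be >= 0")
  TRUE
})

#' @rdname StriatalStructure-class
#' @param kind,side,center,semiAxes,trueSBR see slots.
#' @export
StriatalStructure <- function(kind, side, center, semiAxes, trueSBR = 0) {
  new("StriatalStructure", kind = kind, side = side,
      center = as.numeric(center), semiAxes = as.numeric(semiAxes),
      trueSBR = as.numeric(trueSBR))
}

#' PhantomSpec: recipe for one synthetic subject
#'
#' Describes an ellipsoidal "brain" of uniform nonspecific background
#' activity with embedded striatal structures, and the forward-model
#' parameters that turn the activity map into a SPECT-like emission image:
#' a broad scatter contamination term, the reconstructed-image resolution
#' (7 mm FWHM Gaussian), and the count scale that controls Poisson noise.
#'
#' @slot gridShape integer(3) grid dimensions (voxels).
#' @slot voxelSize positive voxel edge length in mm (isotropic).
#' @slot brainSemiAxes numeric(3) mm semi-axes of the brain ellipsoid.
#' @slot structures list of \code{StriatalStructure}.
#' @slot backgroundActivity positive background (nonspecific) activity.
#' @slot scatterFraction scatter-to-primary fraction in [0,1).
#' @slot scatterFWHM FWHM (mm) of the broad scatter kernel.
#' @slot psfFWHM FWHM (mm) of the resolution/post-filter kernel.
#' @slot countScale expected counts per unit activity per voxel; \code{Inf}
#'   switches Poisson noise off (expected-value images are returned).
#' @slot seed integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 brainSemiAxes = "numeric", structures = "list",
                 backgroundActivity = "numeric", scatterFraction = "numeric",
                 scatterFWHM = "numeric", psfFWHM = "numeric",
                 countScale = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    return("gridShape must be 3 positive integers")
  if (object@voxelSize <= 0) return("voxelSize must be > 0")
  if (length(object@brainSemiAxes) != 3L || any(object@brainSemiAxes <= 0))
    return("brainSemiAxes must be positive")
  # brain must fit with >= 2 voxels margin on every side
  halfExtent <- (object@gridShape - 1) / 2 * object@voxelSize
  if (any(object@brainSemiAxes > halfExtent - 2 * object@voxelSize))
    return("grid too small: need >= 2 voxels margin around the brain")
  if (!all(vapply(object@structures, inherits, TRUE, "StriatalStructure")))
    return("structures must be StriatalStructure objects")
  for (s in object@structures) {
    # structure surface must lie inside the brain ellipsoid
    if (structureProtrudes(s, object@brainSemiAxes))
      return(sprintf("structure %s %s extends outside the brain ellipsoid",
                     s@side, s@kind))
  }
  if (object@backgroundActivity <= 0) return("backgroundActivity must be > 0")
  if (object@scatterFraction < 0 || object@scatterFraction >= 1)
    return("scatterFraction must be in [0,1)")
  if (object@scatterFWHM <= 0 || object@psfFWHM <= 0)
    return("scatterFWHM and psfFWHM must be > 0")
  if (object@countScale <= 0) return("countScale must be > 0")
  TRUE
})

# conservative containment check: bounding box corners of the structure
# ellipsoid must satisfy the brain ellipsoid inequality
structureProtrudes <- function(s, brainSemiAxes) {
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  corners <- sweep(sweep(sgn, 2, s@semiAxes, `*`), 2, s@center, `+`)
  any(rowSums(sweep(corners, 2, brainSemiAxes, `/`)^2) > 1)
}

#' @rdname PhantomSpec-class
#' @param gridShape,voxelSize,brainSemiAxes,structures,backgroundActivity
#'   see slots.
#' @param scatterFraction,scatterFWHM,psfFWHM,countScale,seed see slots.
#' @export
PhantomSpec <- function(gridShape = c(70L, 86L, 60L), voxelSize = 2,
                        brainSemiAxes = c(65, 80, 55),
                        structures = list(), backgroundActivity = 1,
                        scatterFraction = 0.3, scatterFWHM = 80,
                        psfFWHM = 7, countScale = 20, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize),
      brainSemiAxes = as.numeric(brainSemiAxes), structures = structures,
      backgroundActivity = as.numeric(backgroundActivity),
      scatterFraction = as.numeric(scatterFraction),
      scatterFWHM = as.numeric(scatterFWHM), psfFWHM = as.numeric(psfFWHM),
      countScale = as.numeric(countScale), seed = as.integer(seed))
}

#' AttenuationModel: uniform Chang attenuation parameters
#'
#' Parameters of the uniform (Chang) attenuation model: the narrow-beam
#' linear attenuation coefficient and the number of equally spaced
#' transaxial ray directions over which the survival factor is averaged.
#'
#' @slot muPerCm narrow-beam attenuation coefficient (1/cm), default 0.146
#'   as appropriate for 159 keV photons of 123-I in soft tissue.
#' @slot nAngles number of transaxial ray directions (>= 4).
#' @slot rayStep step length (mm) of the sampled-ray fallback tracer.
#' @exportClass AttenuationModel
setClass("AttenuationModel",
  representation(muPerCm = "numeric", nAngles = "integer", rayStep = "numeric"))

setValidity("AttenuationModel", function(object) {
  if (object@muPerCm <= 0) return("muPerCm must be > 0")
  if (object@nAngles < 4L) return("nAngles must be >= 4")
  if (object@rayStep <= 0) return("rayStep must be > 0")
  TRUE
})

#' @rdname AttenuationModel-class
#' @param muPerCm,nAngles,rayStep see slots.
#' @export
AttenuationModel <- function(muPerCm = 0.146, nAngles = 64L, rayStep = 1) {
  new("AttenuationModel", muPerCm = as.numeric(muPerCm),
      nAngles = as.integer(nAngles), rayStep = as.numeric(rayStep))
}

#' BodyContour: per-slice elliptical head contour
#'
#' The outer contour of the head as fitted separately in each transaxial
#' plane: an ellipse per slice (center, semi-axes, rotation) plus the filled
#' binary mask volume derived from the ellipses.  Slices without
#' supra-threshold signal carry no ellipse and an empty mask plane.
#'
#' @slot ellipses data.frame with columns slice, cx, cy (mm), a, b (mm
#'   semi-axes), phi (radians).
#' @slot mask logical 3-D array, the filled ellipses.
#' @slot voxelSize numeric(3) mm.
#' @slot origin numeric(3) mm.
#' @exportClass BodyContour
setClass("BodyContour",
  representation(ellipses = "data.frame", mask = "array",
                 voxelSize = "numeric", origin = "numeric"))

setValidity("BodyContour", function(object) {
  e <- object@ellipses
  need <- c("slice", "cx", "cy", "a", "b", "phi")
  if (!all(need %in% names(e))) return("ellipses must have slice,cx,cy,a,b,phi")
  if (nrow(e) > 0 && any(e$a <= 0 | e$b <= 0))
    return("ellipse semi-axes must be positive")
  for (k in e$slice) if (!any(object@mask[, , k]))
    return(sprintf("mask empty on slice %d that has an ellipse", k))
  TRUE
})

#' ScanPair: matched without-ASC / with-ASC volumes for one subject
#'
#' One simulated subject: the emission image reconstructed without
#' attenuation/scatter correction, the matched image with the Chang-corrected
#' (ASC analogue) treatment, the ground-truth class and minimum putamen SBR,
#' and the region masks used downstream.
#'
#' @slot volumeNoASC,volumeASC \code{SpectVolume}s on the same grid.
#' @slot truthClass "normal" or "reduced".
#' @slot trueMinPutamenSBR true minimum putamen SBR over hemispheres.
#' @slot masks named list of logical arrays: putamen_left, putamen_right,
#'   reference, brain.
#' @exportClass ScanPair
setClass("ScanPair",
  representation(volumeNoASC = "SpectVolume", volumeASC = "SpectVolume",
                 truthClass = "character", trueMinPutamenSBR = "numeric",
                 masks = "list"))

setValidity("ScanPair", function(object) {
  if (!identical(dim(object@volumeNoASC@data), dim(object@volumeASC@data)))
    return("the two arms must share the grid")
  if (!isTRUE(all.equal(object@volumeNoASC@voxelSize, object@volumeASC@voxelSize)))
    return("the two arms must share the voxel size")
  if (!object@truthClass %in% c("normal", "reduced"))
    return("truthClass must be normal/reduced")
  if (any(object@volumeNoASC@data < 0) || any(object@volumeASC@data < 0))
    return("voxel values must be >= 0")
  need <- c("putamen_left", "putamen_right", "reference", "brain")
  if (!all(need %in% names(object@masks)))
    return("masks must include putamen_left, putamen_right, reference, brain")
  for (m in object@masks[need])
    if (!identical(dim(m), dim(object@volumeNoASC@data)))
      return("all masks must share the volume grid")
  TRUE
})

#' ReaderModel: simulated human reader
#'
#' A surrogate for a human reader of DAT-SPECT displays: the reader calls a
#' scan "reduced" when the (noisily perceived, possibly biased) minimum
#' putamen SBR falls below a personal threshold, and "normal" at or above it.
#'
#' @slot threshold decision threshold on the SBR scale.
#' @slot noiseSD nonnegative SD of the perceptual noise.
#' @slot bias additive perceptual bias.
#' @slot seed integer RNG seed.
#' @exportClass ReaderModel
setClass("ReaderModel",
  representation(threshold = "numeric", noiseSD = "numeric", bias = "numeric",
                 seed = "integer"))

setValidity("ReaderModel", function(object) {
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  TRUE
})

#' @rdname ReaderModel-class
#' @param threshold,noiseSD,bias,seed see slots.
#' @export
ReaderModel <- function(threshold, noiseSD = 0, bias = 0, seed = 1L) {
  new("ReaderModel", threshold = as.numeric(threshold),
      noiseSD = as.numeric(noiseSD), bias = as.numeric(bias),
      seed = as.integer(seed))
}

#' CohortSpec: recipe for a simulated two-class cohort
#'
#' A cohort is a two-class mixture of subjects: "normal" scans and scans
#' with a Parkinson-typical "reduced" striatal signal.  Each subject's target
#' minimum putamen SBR is drawn from its class Gaussian (truncated at 0); the
#' worse hemisphere receives the drawn value and the better hemisphere the
#' drawn value times \code{asymmetry}.  Class distribution defaults follow
#' the two-Gaussian decomposition of a large clinical DAT-SPECT sample
#' (reduced: mean 0.579, SD 0.157; normal: mean 1.577, SD 0.320; 47.8%
#' reduced).
#'
#' @slot nScans positive number of scans.
#' @slot prevalenceReduced probability of the reduced class, in [0,1].
#' @slot sbrNormalMean,sbrNormalSd normal-class SBR Gaussian.
#' @slot sbrReducedMean,sbrReducedSd reduced-class SBR Gaussian.
#' @slot asymmetry better-to-worse hemisphere SBR ratio (>= 1).
#' @slot caudateRatioReduced caudate-to-putamen SBR ratio in reduced scans
#'   (relative caudate preservation); caudate tracks putamen 1:1 in normals.
#' @slot phantom \code{PhantomSpec} providing grid/forward-model defaults
#'   (its structures slot is ignored; anatomy is the package default).
#' @slot seed integer RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nScans = "integer", prevalenceReduced = "numeric",
                 sbrNormalMean = "numeric", sbrNormalSd = "numeric",
                 sbrReducedMean = "numeric", sbrReducedSd = "numeric",
                 asymmetry = "numeric", caudateRatioReduced = "numeric",
                 phantom = "PhantomSpec", seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@nScans < 1L) return("nScans must be >= 1")
  if (object@prevalenceReduced < 0 || object@prevalenceReduced > 1)
    return("prevalenceReduced must be in [0,1]")
  if (object@sbrNormalSd <= 0 || object@sbrReducedSd <= 0)
    return("class SDs must be > 0")
  if (object@asymmetry < 1) return("asymmetry must be >= 1")
  TRUE
})

#' @rdname CohortSpec-class
#' @param nScans,prevalenceReduced,sbrNormalMean,sbrNormalSd see slots.
#' @param sbrReducedMean,sbrReducedSd,asymmetry,caudateRatioReduced see slots.
#' @param phantom,seed see slots.
#' @export
CohortSpec <- function(nScans, prevalenceReduced = 0.478,
                       sbrNormalMean = 1.577, sbrNormalSd = 0.320,
                       sbrReducedMean = 0.579, sbrReducedSd = 0.157,
                       asymmetry = 1.3, caudateRatioReduced = 1.5,
                       phantom = PhantomSpec(), seed = 1L) {
  new("CohortSpec", nScans = as.integer(nScans),
      prevalenceReduced = as.numeric(prevalenceReduced),
      sbrNormalMean = as.numeric(sbrNormalMean),
      sbrNormalSd = as.numeric(sbrNormalSd),
      sbrReducedMean = as.numeric(sbrReducedMean),
      sbrReducedSd = as.numeric(sbrReducedSd),
      asymmetry = as.numeric(asymmetry),
      caudateRatioReduced = as.numeric(caudateRatioReduced),
      phantom = phantom, seed = as.integer(seed))
}

#' HistogramData: fixed-width histogram of SBR values
#'
#' @slot binWidth positive bin width (default 0.1 on the SBR scale).
#' @slot centers ordered, equally spaced bin centers.
#' @slot counts nonnegative counts, one per center (integers when built
#'   from data; exact model evaluations are admitted for testing fits).
#' @exportClass HistogramData
setClass("HistogramData",
  representation(binWidth = "numeric", centers = "numeric", counts = "numeric"))

setValidity("HistogramData", function(object) {
  if (object@binWidth <= 0) return("binWidth must be > 0")
  if (length(object@centers) != length(object@counts))
    return("centers and counts must have equal length")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (length(object@centers) > 1) {
    gaps <- diff(object@centers)
    if (any(abs(gaps - object@binWidth) > 1e-9 * object@binWidth))
      return("centers must be equally spaced by binWidth")
  }
  TRUE
})

#' TwoGaussianFit: two-Gaussian decomposition of an SBR histogram
#'
#' Result of fitting the sum of two Gaussians
#' \deqn{A_1 e^{-(x-M_1)^2/2SD_1^2} + A_2 e^{-(x-M_2)^2/2SD_2^2}}
#' to histogram counts, with component 1 (the lower mean, M1 < M2) the
#' "reduced" population and component 2 the "normal" population.  Carries the
#' derived effect size \code{d} and the normal/reduced cutoff \code{c}.
#'
#' @slot A1,M1,SD1 amplitude, mean, SD of the reduced component.
#' @slot A2,M2,SD2 amplitude, mean, SD of the normal component.
#' @slot sse sum of squared residuals of the fit.
#' @slot d effect size (M2-M1 scaled to the pooled SD).
#' @slot c cutoff halfway between M1 and M2 in units of SD.
#' @slot nValues number of values entering the histogram.
#' @slot binWidth histogram bin width.
#' @exportClass TwoGaussianFit
setClass("TwoGaussianFit",
  representation(A1 = "numeric", M1 = "numeric", SD1 = "numeric",
                 A2 = "numeric", M2 = "numeric", SD2 = "numeric",
                 sse = "numeric", d = "numeric", c = "numeric",
                 nValues = "integer", binWidth = "numeric"))

setValidity("TwoGaussianFit", function(object) {
  if (object@A1 <= 0 || object@A2 <= 0) return("amplitudes must be > 0")
  if (object@SD1 <= 0 || object@SD2 <= 0) return("SDs must be > 0")
  if (object@M1 >= object@M2) return("components must be ordered M1 < M2")
  if (object@sse < 0) return("sse must be >= 0")
  # derived fields must be consistent with the parameters
  dd <- (object@M2 - object@M1) / sqrt((object@SD1^2 + object@SD2^2) / 2)
  cc <- (object@SD2 * object@M1 + object@SD1 * object@M2) /
        (object@SD1 + object@SD2)
  if (abs(dd - object@d) > 1e-8 * max(1, abs(dd)))
    return("slot d inconsistent with M/SD slots")
  if (abs(cc - object@c) > 1e-8 * max(1, abs(cc)))
    return("slot c inconsistent with M/SD slots")
  TRUE
})

#' SBRResult: putamen SBR summary for one scan
#'
#' @slot scanID scan identifier.
#' @slot sbrLeft,sbrRight per-hemisphere hottest-voxel putamen SBR.
#' @slot sbrMin minimum of the two (the scan's summary value).
#' @slot nVoxelsUsed number of hottest voxels averaged per side.
#' @exportClass SBRResult
setClass("SBRResult",
  representation(scanID = "character", sbrLeft = "numeric", sbrRight = "numeric",
                 sbrMin = "numeric", nVoxelsUsed = "integer"))

setValidity("SBRResult", function(object) {
  if (!isTRUE(all.equal(object@sbrMin, min(object@sbrLeft, object@sbrRight))))
    return("sbrMin must equal min(sbrLeft, sbrRight)")
  if (object@sbrMin <= -1) return("SBR must be > -1 (DVR >= 0)")
  TRUE
})
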