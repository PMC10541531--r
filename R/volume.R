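#' @include AllClasses.R
NULL

# mm coordinates of voxel centers along one axis
axisCoords <- function(n, voxelSize, origin) origin + (seq_len(n) - 1) * voxelSize

# coordinate vectors for all three axes of a volume-like object
gridCoords <- function(dims, voxelSize, origin) {
  lapply(1:3, function(a) axisCoords(dims[a], voxelSize[a], origin[a]))
}

sameGrid <- function(v1, v2) {
  identical(dim(v1@data), dim(v2@data)) &&
    isTRUE(all.equal(v1@voxelSize, v2@voxelSize)) &&
    isTRUE(all.equal(v1@origin, v2@origin))
}

stopIfGridMismatch <- function(v1, v2) {
  if (!sameGrid(v1, v2))
    stop("volumes must share grid dimensions, voxel size and origin")
}

#' Ellipsoid voxel mask
#'
#' Logical mask of voxels whose centers lie inside the axis-aligned ellipsoid
#' \code{sum(((x - center)/semiAxes)^2) <= 1}, on a centered grid.
#'
#' @param gridShape integer(3) grid dimensions.
#' @param voxelSize voxel size (mm), scalar or length 3.
#' @param center ellipsoid center (mm).
#' @param semiAxes ellipsoid semi-axes (mm).
#' @return logical 3-D array.
#' @export
ellipsoidMask <- function(gridShape, voxelSize, center, semiAxes) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  origin <- -(gridShape - 1) / 2 * voxelSize
  co <- gridCoords(gridShape, voxelSize, origin)
  ux <- ((co[[1]] - center[1]) / semiAxes[1])^2
  uy <- ((co[[2]] - center[2]) / semiAxes[2])^2
  uz <- ((co[[3]] - center[3]) / semiAxes[3])^2
  q <- outer(outer(ux, uy, `+`), uz, `+`)
  q <= 1
}

# FWHM (mm) -> Gaussian sigma (mm)
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# normalized 1-D Gaussian kernel at a given voxel pitch, truncated at 4 sigma
gaussKernel1d <- function(fwhm, pitch) {
  sigma <- fwhmToSigma(fwhm) / pitch
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution of every column of a matrix with a centered kernel,
# zero-padded at the edges
convColumns <- function(m, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  pad <- matrix(0, r, ncol(m))
  mp <- rbind(pad, m, pad)
  out <- stats::filter(mp, kernel, method = "convolution", sides = 2)
  out <- out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  out[is.na(out)] <- 0
  out
}

# separable 3-D Gaussian blur of an array (zero-padded boundaries);
# the kernel is normalized per axis, so total mass is conserved for
# signal away from the grid boundary
blurArray <- function(a, fwhm, voxelSize) {
  d <- dim(a)
  for (axis in 1:3) {
    k <- gaussKernel1d(fwhm, voxelSize[axis])
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- convColumns(matrix(ap, nrow = dp[1]), k)
    a <- aperm(array(m, dp), order(perm))
  }
  a
}

#' Gaussian blur of a volume
#'
#' Separable 3-D Gaussian convolution specified by its full width at half
#' maximum.  The kernel is normalized, so total activity away from the grid
#' boundary is conserved.
#'
#' @param v a \code{SpectVolume}.
#' @param fwhm full width at half maximum of the kernel, in mm.
#' @return a \code{SpectVolume} on the same grid.
#' @export
gaussianBlur <- function(v, fwhm) {
  stopifnot(is(v, "SpectVolume"), fwhm > 0)
  SpectVolume(blurArray(v@data, fwhm, v@voxelSize), v@voxelSize, v@origin)
}

#' Read/write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti} keeping the \code{SpectVolume} voxel
#' geometry in the NIfTI header.
#'
#' @param v a \code{SpectVolume}.
#' @param path file path (".nii" or ".nii.gz").
#' @return \code{readVolume} returns a \code{SpectVolume};
#'   \code{writeVolume} returns \code{path} invisibly.
#' @export
writeVolume <- function(v, path) {
  img <- RNifti::asNifti(v@data, internal = FALSE)
  RNifti::pixdim(img) <- v@voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  SpectVolume(array(as.vector(img), dim = dim(img)), RNifti::pixdim(img)[1:3])
}
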