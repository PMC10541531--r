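#' @include AllClasses.R volume.R phantom.R attenuation.R
NULL

# forward-model ingredients shared by scan-pair and cohort simulation:
# primary = A(x) * activity, scatter = broad-blurred copy, resolution blur,
# and the Chang factors from the delineated contour
forwardExpected <- function(primArr, spec, C = NULL) {
  withScatter <- primArr
  if (spec@scatterFraction > 0)
    withScatter <- primArr + spec@scatterFraction *
      blurArray(primArr, spec@scatterFWHM, rep(spec@voxelSize, 3))
  e0 <- blurArray(withScatter, spec@psfFWHM, rep(spec@voxelSize, 3))
  e1 <- if (is.null(C)) NULL else
    blurArray(C * primArr, spec@psfFWHM, rep(spec@voxelSize, 3))
  list(noASC = e0, asc = e1)
}

poissonArm <- function(expected, countScale, seed) {
  if (is.infinite(countScale)) return(expected)
  set.seed(seed)
  array(stats::rpois(length(expected), countScale * expected), dim(expected))
}

#' Simulate one matched without-ASC / with-ASC scan pair
#'
#' Generates the two arms of the experiment for a single phantom.  The
#' without-ASC arm is
#' \code{Poisson(countScale * blurPSF(A * activity + sf * broadblur(A * activity)))}
#' with \code{A} the Chang survival factors of the true brain contour; the
#' with-ASC arm applies the first-order Chang correction factors \code{C}
#' (from the automatically delineated contour, unless \code{contour} is
#' supplied) to the attenuated primary signal, with no scatter term:
#' \code{Poisson(countScale * blurPSF(C * A * activity))}.  With
#' \code{countScale = Inf} the noise-free expected images are returned.
#' The arms draw independent noise with derived sub-seeds (\code{seed} for
#' the without-ASC arm, \code{seed + 1} for the with-ASC arm).
#'
#' @param spec a valid \code{PhantomSpec}.
#' @param atten an \code{AttenuationModel}, or \code{NULL} for identity
#'   attenuation (A = C = 1; forward model disabled).
#' @param contour optional \code{BodyContour} used for the Chang correction
#'   instead of automatic delineation (e.g. the true contour).
#' @param truthClass "normal" or "reduced", stored as ground truth.
#' @param cap maximum Chang correction factor.
#' @return a \code{\linkS4class{ScanPair}}.
#' @export
simulateScanPair <- function(spec, atten = AttenuationModel(), contour = NULL,
                             truthClass = "normal", cap = 10) {
  validObject(spec)
  act <- buildActivityMap(spec)
  brain <- brainMask(spec)
  vox <- rep(spec@voxelSize, 3)
  if (is.null(atten)) {
    primArr <- act@data
    C <- array(1, spec@gridShape)
  } else {
    trueContour <- bodyContourFromMask(brain, spec@voxelSize)
    A <- attenuationFactors(trueContour, atten)
    primArr <- A@data * act@data
    if (is.null(contour)) {
      # delineate from the noise-free without-ASC image, as the clinical
      # contour tool operates on the non-corrected reconstruction
      e0pre <- forwardExpected(primArr, spec)$noASC
      contour <- delineateBodyContour(SpectVolume(e0pre, spec@voxelSize))
    }
    Ad <- attenuationFactors(contour, atten)
    C <- pmin(1 / Ad@data, cap)
  }
  ee <- forwardExpected(primArr, spec, C)
  d0 <- poissonArm(ee$noASC, spec@countScale, spec@seed)
  d1 <- poissonArm(ee$asc, spec@countScale, spec@seed + 1L)
  pm <- makePutamenMasks(spec)
  putSBR <- vapply(spec@structures,
                   function(s) if (s@kind == "putamen") s@trueSBR else Inf, 1.0)
  new("ScanPair",
      volumeNoASC = SpectVolume(d0, spec@voxelSize),
      volumeASC = SpectVolume(d1, spec@voxelSize),
      truthClass = truthClass,
      trueMinPutamenSBR = min(putSBR),
      masks = list(putamen_left = pm$left, putamen_right = pm$right,
                   reference = makeReferenceMask(spec), brain = brain))
}

#' Simulated reader of an SBR value
#'
#' Applies the \code{\linkS4class{ReaderModel}}: the scan is called
#' "reduced" when \code{sbrMin + bias + N(0, noiseSD)} falls below the
#' reader's threshold, "normal" at or above it (ties are normal).
#'
#' @param sbrMin numeric vector of minimum putamen SBR values.
#' @param model a \code{ReaderModel}.
#' @return character vector of labels.
#' @export
simulateReader <- function(sbrMin, model) {
  validObject(model)
  set.seed(model@seed)
  noise <- if (model@noiseSD > 0)
    stats::rnorm(length(sbrMin), 0, model@noiseSD) else 0
  ifelse(sbrMin + model@bias + noise < model@threshold, "reduced", "normal")
}

# draw the ground-truth table of a cohort (classes and per-side true SBR);
# consumes the RNG stream seeded with cohort@seed
drawTruthTable <- function(cohort) {
  n <- cohort@nScans
  set.seed(cohort@seed)
  cls <- ifelse(stats::runif(n) < cohort@prevalenceReduced, "reduced", "normal")
  mu <- ifelse(cls == "reduced", cohort@sbrReducedMean, cohort@sbrNormalMean)
  sd <- ifelse(cls == "reduced", cohort@sbrReducedSd, cohort@sbrNormalSd)
  target <- stats::rnorm(n, mu, sd)
  while (any(bad <- target < 0))
    target[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
  worseLeft <- stats::runif(n) < 0.5
  worse <- target
  better <- target * cohort@asymmetry
  data.frame(
    scan_id = sprintf("scan%04d", seq_len(n)),
    truth_class = cls,
    true_sbr_left = ifelse(worseLeft, worse, better),
    true_sbr_right = ifelse(worseLeft, better, worse),
    stringsAsFactors = FALSE)
}

caudateSBR <- function(cohort, cls, putSBR) {
  if (cls == "reduced") cohort@caudateRatioReduced * putSBR else putSBR
}

# per-cohort precomputation: all subjects share the phantom geometry, so the
# attenuation factors, delineated contour, Chang factors and the blurred
# per-structure basis images are computed once; a scan's expected image is a
# linear combination of the basis images
cohortBasis <- function(cohort, atten = AttenuationModel(), cap = 10) {
  ph <- cohort@phantom
  structures <- defaultStructures(putamenSBR = c(1, 1))
  spec <- PhantomSpec(gridShape = ph@gridShape, voxelSize = ph@voxelSize,
                      brainSemiAxes = ph@brainSemiAxes,
                      structures = structures,
                      backgroundActivity = ph@backgroundActivity,
                      scatterFraction = ph@scatterFraction,
                      scatterFWHM = ph@scatterFWHM, psfFWHM = ph@psfFWHM,
                      countScale = ph@countScale, seed = ph@seed)
  brain <- brainMask(spec)
  vox <- rep(spec@voxelSize, 3)
  bg <- spec@backgroundActivity
  if (is.null(atten)) {
    A <- array(1, spec@gridShape)
    C <- array(1, spec@gridShape)
  } else {
    trueContour <- bodyContourFromMask(brain, spec@voxelSize)
    A <- attenuationFactors(trueContour, atten)@data
    # delineate once from a representative normal-class scan
    refStruct <- defaultStructures(putamenSBR = rep(cohort@sbrNormalMean, 2))
    refSpec <- spec; refSpec@structures <- refStruct
    actRef <- buildActivityMap(refSpec)
    e0ref <- forwardExpected(A * actRef@data, refSpec)$noASC
    delin <- delineateBodyContour(SpectVolume(e0ref, spec@voxelSize))
    C <- pmin(1 / attenuationFactors(delin, atten)@data, cap)
  }
  comp <- list(bg * brain)
  for (s in structures) comp <- c(comp, list(bg * structureMask(spec, s)))
  basisNoASC <- lapply(comp, function(a) forwardExpected(A * a, spec)$noASC)
  basisASC <- lapply(comp, function(a)
    blurArray(C * A * a, spec@psfFWHM, vox))
  structKey <- vapply(structures, function(s) paste(s@kind, s@side, sep = "_"), "")
  pm <- makePutamenMasks(spec)
  basis <- list(spec = spec, structures = structures, structKey = structKey,
                basisNoASC = basisNoASC, basisASC = basisASC,
                masks = list(putamen_left = pm$left, putamen_right = pm$right,
                             reference = makeReferenceMask(spec), brain = brain))
  basis$calibration <- calibrateTargetSBR(basis)
  basis
}

# The drawn class distributions describe the MEASURED putamen SBR (they
# parameterize clinical semi-quantitative results), whereas the phantom's
# structure SBR is the underlying activity contrast, which the measurement
# chain (resolution blur, scatter, hottest-voxel averaging over an oversized
# mask) compresses substantially.  Calibrate the affine response of the
# noise-free with-ASC measurement once per cohort geometry, so that a scan
# built for target t measures t in the with-ASC arm; the without-ASC arm
# then lands wherever attenuation and scatter put it, as in real data.
calibrateTargetSBR <- function(basis, probes = c(1, 3, 6)) {
  ref <- basis$masks$reference
  pl <- basis$masks$putamen_left
  vml <- prod(rep(basis$spec@voxelSize, 3)) / 1000
  nHot <- round(10 / vml)
  measured <- vapply(probes, function(t) {
    e1 <- scanExpected(basis, rep(t, length(basis$structures)), "asc")
    q75 <- stats::quantile(e1[ref], 0.75, names = FALSE, type = 7)
    mean(sort(e1[pl] / q75, decreasing = TRUE)[seq_len(nHot)]) - 1
  }, 1.0)
  co <- stats::coef(stats::lm(measured ~ probes))
  list(alpha = unname(co[1]), beta = unname(co[2]))
}

# invert the measurement response: phantom structure SBR for a target
# measured SBR (floored at 0)
targetToTrueSBR <- function(cal, target) {
  pmax((target - cal$alpha) / cal$beta, 0)
}

# per-structure phantom SBR multipliers for one truth-table row, in basis
# order; the per-side targets go through the inverse measurement response
scanStructSBR <- function(cohort, basis, row) {
  sideSBR <- c(left = targetToTrueSBR(basis$calibration, row$true_sbr_left),
               right = targetToTrueSBR(basis$calibration, row$true_sbr_right))
  vapply(basis$structures, function(s) {
    p <- sideSBR[[s@side]]
    if (s@kind == "putamen") p else caudateSBR(cohort, row$truth_class, p)
  }, 1.0)
}

scanExpected <- function(basis, sbrs, arm = c("noASC", "asc")) {
  arm <- match.arg(arm)
  b <- if (arm == "noASC") basis$basisNoASC else basis$basisASC
  e <- b[[1]]
  for (j in seq_along(sbrs)) e <- e + sbrs[j] * b[[j + 1]]
  e
}

#' Simulate a whole two-class cohort
#'
#' Draws the ground-truth table (class and per-hemisphere true putamen SBR
#' for every scan) and, unless \code{volumes = FALSE}, the matched
#' without-ASC / with-ASC volumes for every scan.  All subjects share the
#' phantom geometry (the anatomy is fixed by the cohort's
#' \code{PhantomSpec}); only the striatal binding varies, so the attenuation
#' and correction maps are computed once for the cohort.  Scan i draws its
#' arm noise with sub-seeds \code{seed + 2i} and \code{seed + 2i + 1}.
#'
#' @param cohort a \code{CohortSpec}.
#' @param atten an \code{AttenuationModel}, or \code{NULL} for identity
#'   attenuation.
#' @param volumes logical; \code{FALSE} returns the truth table only.
#' @param cap maximum Chang correction factor.
#' @return list with \code{truth} (data.frame) and \code{scans} (list of
#'   \code{ScanPair}, or \code{NULL} when \code{volumes = FALSE}).
#' @export
simulateCohort <- function(cohort, atten = AttenuationModel(), volumes = TRUE,
                           cap = 10) {
  validObject(cohort)
  truth <- drawTruthTable(cohort)
  if (!volumes) return(list(truth = truth, scans = NULL))
  basis <- cohortBasis(cohort, atten, cap)
  cs <- cohort@phantom@countScale
  scans <- vector("list", cohort@nScans)
  for (i in seq_len(cohort@nScans)) {
    row <- truth[i, ]
    sbrs <- scanStructSBR(cohort, basis, row)
    e0 <- scanExpected(basis, sbrs, "noASC")
    e1 <- scanExpected(basis, sbrs, "asc")
    d0 <- poissonArm(e0, cs, cohort@seed + 2L * i)
    d1 <- poissonArm(e1, cs, cohort@seed + 2L * i + 1L)
    scans[[i]] <- new("ScanPair",
      volumeNoASC = SpectVolume(d0, basis$spec@voxelSize),
      volumeASC = SpectVolume(d1, basis$spec@voxelSize),
      truthClass = row$truth_class,
      trueMinPutamenSBR = min(row$true_sbr_left, row$true_sbr_right),
      masks = basis$masks)
  }
  list(truth = truth, scans = scans)
}
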