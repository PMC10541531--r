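# shared fixtures, built lazily and cached for the whole run

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

# cylinder ("disc stack") phantom: activity 1 inside a disc of radius R on
# slices kRange, plus its exact contour and the forward-attenuated image
discPhantom <- function(R = 50, gs = c(64L, 64L, 64L), kRange = 17:48) {
  co <- seq(-(gs[1] - 1), gs[1] - 1, by = 2)
  disc <- outer(co^2, co^2, `+`) <= R^2
  mask <- array(FALSE, gs)
  for (k in kRange) mask[, , k] <- disc
  act <- array(0, gs); act[mask] <- 1
  list(mask = mask, act = act, co = co, disc = disc, R = R, kRange = kRange)
}

cachedDisc <- function() cached("disc", function() {
  d <- discPhantom()
  d$contour <- bodyContourFromMask(d$mask, 2)
  d$A <- attenuationFactors(d$contour, AttenuationModel())
  d$fwd <- SpectVolume(imgData(d$A) * d$act, 2)
  d
})

# noise-free full-size scan pair with the default forward model
cachedDefaultPair <- function() cached("defaultPair", function() {
  # putamen-only anatomy: the mask-robustness property assumes enlargement
  # away from any other hot structure
  spec <- PhantomSpec(structures = defaultStructures(putamenSBR = c(2, 2.6))[1:2],
                      countScale = Inf)
  simulateScanPair(spec)
})

# noise-free mini scan pair (24^3) for fast SBR checks
miniPair <- function(putamenSBR = c(2, 2), scatterFraction = 0.3) {
  spec <- miniPhantomSpec(putamenSBR = putamenSBR)
  spec@scatterFraction <- scatterFraction
  simulateScanPair(spec)
}

# DVR-scaled minimum putamen SBR of one arm of a ScanPair
pairSBR <- function(pair, arm = c("no_asc", "asc"), targetVolumeMl = 10) {
  arm <- match.arg(arm)
  v <- if (arm == "no_asc") pair@volumeNoASC else pair@volumeASC
  dvr <- scaleToDVR(v, pair@masks$reference)$volume
  putamenSBRBilateral(dvr, pair@masks$putamen_left, pair@masks$putamen_right,
                      targetVolumeMl = targetVolumeMl)
}
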