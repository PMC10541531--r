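#' @include AllClasses.R simulate.R preprocess.R sbr.R mixture.R agreement.R
NULL

# per-scan measurement on one arm restricted to the needed voxels:
# DVR scaling by the reference-region 75th percentile, then hottest-voxel
# SBR per putamen
measureArm <- function(counts, need) {
  q75 <- stats::quantile(counts[need$refIdx], 0.75, names = FALSE, type = 7)
  if (q75 <= 0) stop("degenerate scan: reference 75th percentile <= 0")
  sbrSide <- function(idx) {
    v <- counts[idx] / q75
    ord <- order(v, seq_along(v), decreasing = c(TRUE, FALSE), method = "radix")
    mean(v[ord[seq_len(need$nHot)]]) - 1
  }
  l <- sbrSide(need$leftIdx); r <- sbrSide(need$rightIdx)
  c(left = l, right = r, min = min(l, r), factor = q75)
}

#' Run the end-to-end without-ASC versus with-ASC experiment
#'
#' Simulates a cohort, measures the putamen SBR of every scan in both arms
#' (DVR scaling by the reference-region 75th percentile, hottest-voxel
#' analysis, minimum over hemispheres), calibrates each arm independently by
#' the two-Gaussian histogram fit and its cutoff, categorizes every scan in
#' each arm, and summarizes between-arm agreement (cross table, Cohen's
#' kappa, percentage of discrepant cases) plus a chi-square homogeneity test
#' of the discrepancy proportion across \code{nSubgroups} round-robin scan
#' subgroups (emulating acquisition-hardware strata).
#'
#' Scans are processed in a stream: only the voxels needed for measurement
#' (reference region and putamen masks) are simulated per scan, so large
#' cohorts run in bounded memory.  Deterministic given \code{cohort@seed}.
#'
#' @param cohort a \code{CohortSpec}.
#' @param atten an \code{AttenuationModel}, or \code{NULL} to disable the
#'   attenuation/scatter forward model (identity arms).
#' @param binWidth histogram bin width for the calibration (default 0.1).
#' @param targetVolumeMl hottest-voxel volume per putamen (default 10 ml).
#' @param nSubgroups number of round-robin subgroups for the homogeneity
#'   test (default 4; set to 0 to skip).
#' @param cap maximum Chang correction factor.
#' @param calibrate logical; \code{FALSE} skips the histogram calibration,
#'   categorization and agreement stages and returns the SBR records only
#'   (useful for cohorts too small to support a 6-parameter fit).
#' @param outDir optional directory; when given, writes
#'   \code{sbr.csv}, \code{truth.csv}, \code{fit_no_asc.json},
#'   \code{fit_asc.json} and \code{agreement.json}.
#' @return list with elements \code{records} (per-scan data.frame),
#'   \code{fits}, \code{cutoffs}, \code{crossTable}, \code{kappa},
#'   \code{discrepancyPct}, \code{subgroupTest}.
#' @export
runExperiment <- function(cohort, atten = AttenuationModel(), binWidth = 0.1,
                          targetVolumeMl = 10, nSubgroups = 4L, cap = 10,
                          calibrate = TRUE, outDir = NULL) {
  validObject(cohort)
  truth <- drawTruthTable(cohort)
  basis <- cohortBasis(cohort, atten, cap)
  vml <- prod(rep(basis$spec@voxelSize, 3)) / 1000
  nHot <- round(targetVolumeMl / vml)
  leftIdx <- which(basis$masks$putamen_left)
  rightIdx <- which(basis$masks$putamen_right)
  if (length(leftIdx) < nHot || length(rightIdx) < nHot)
    stop("putamen masks smaller than the hottest-voxel target volume")
  refIdx <- which(basis$masks$reference)
  needIdx <- c(refIdx, leftIdx, rightIdx)
  need <- list(refIdx = seq_along(refIdx),
               leftIdx = length(refIdx) + seq_along(leftIdx),
               rightIdx = length(refIdx) + length(leftIdx) + seq_along(rightIdx),
               nHot = nHot)
  # basis restricted to the needed voxels
  b0 <- lapply(basis$basisNoASC, function(a) a[needIdx])
  b1 <- lapply(basis$basisASC, function(a) a[needIdx])
  cs <- cohort@phantom@countScale
  n <- cohort@nScans
  out <- matrix(NA_real_, n, 8)
  for (i in seq_len(n)) {
    sbrs <- scanStructSBR(cohort, basis, truth[i, ])
    e0 <- b0[[1]]; e1 <- b1[[1]]
    for (j in seq_along(sbrs)) {
      e0 <- e0 + sbrs[j] * b0[[j + 1]]
      e1 <- e1 + sbrs[j] * b1[[j + 1]]
    }
    d0 <- if (is.infinite(cs)) e0 else {
      set.seed(cohort@seed + 2L * i); stats::rpois(length(e0), cs * e0)
    }
    d1 <- if (is.infinite(cs)) e1 else {
      set.seed(cohort@seed + 2L * i + 1L); stats::rpois(length(e1), cs * e1)
    }
    out[i, 1:4] <- measureArm(d0, need)
    out[i, 5:8] <- measureArm(d1, need)
  }
  records <- cbind(truth, data.frame(
    sbr_left_no_asc = out[, 1], sbr_right_no_asc = out[, 2],
    sbr_min_no_asc = out[, 3],
    sbr_left_asc = out[, 5], sbr_right_asc = out[, 6],
    sbr_min_asc = out[, 7]))
  if (!calibrate) return(list(records = records))
  fits <- list(
    no_asc = fitTwoGaussians(buildHistogram(records$sbr_min_no_asc, binWidth)),
    asc = fitTwoGaussians(buildHistogram(records$sbr_min_asc, binWidth)))
  cuts <- c(no_asc = cutoff(fits$no_asc), asc = cutoff(fits$asc))
  records$category_no_asc <- categorize(records$sbr_min_no_asc, cuts["no_asc"])
  records$category_asc <- categorize(records$sbr_min_asc, cuts["asc"])
  ct <- crossTable(records$category_no_asc, records$category_asc)
  kap <- cohenKappa(ct)
  disc <- discrepancyProportion(ct)
  subgroupTest <- NULL
  if (nSubgroups >= 2L && n >= 2L * nSubgroups) {
    grp <- rep_len(seq_len(nSubgroups), n)
    discr <- records$category_no_asc != records$category_asc
    tab <- cbind(discordant = tapply(discr, grp, sum),
                 concordant = tapply(!discr, grp, sum))
    subgroupTest <- tryCatch(chiSquareHomogeneity(tab), error = function(e) NULL)
  }
  res <- list(records = records, fits = fits, cutoffs = cuts, crossTable = ct,
              kappa = kap, discrepancyPct = disc, subgroupTest = subgroupTest)
  if (!is.null(outDir)) writeExperiment(res, outDir)
  res
}

fitAsList <- function(fit, arm) {
  list(arm = arm, A1 = fit@A1, M1 = fit@M1, SD1 = fit@SD1, A2 = fit@A2,
       M2 = fit@M2, SD2 = fit@SD2, sse = fit@sse, d = fit@d, c = fit@c,
       n = fit@nValues, bin_width = fit@binWidth)
}

writeExperiment <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  r <- res$records
  long <- rbind(
    data.frame(scan_id = r$scan_id, arm = "no_asc", sbr_left = r$sbr_left_no_asc,
               sbr_right = r$sbr_right_no_asc, sbr_min = r$sbr_min_no_asc),
    data.frame(scan_id = r$scan_id, arm = "asc", sbr_left = r$sbr_left_asc,
               sbr_right = r$sbr_right_asc, sbr_min = r$sbr_min_asc))
  utils::write.csv(long, file.path(outDir, "sbr.csv"), row.names = FALSE)
  utils::write.csv(r[, c("scan_id", "truth_class", "true_sbr_left",
                         "true_sbr_right")],
                   file.path(outDir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(fitAsList(res$fits$no_asc, "no_asc"),
                       file.path(outDir, "fit_no_asc.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(fitAsList(res$fits$asc, "asc"),
                       file.path(outDir, "fit_asc.json"), auto_unbox = TRUE,
                       digits = NA)
  ag <- list(cross_table = unclass(res$crossTable), kappa = res$kappa$kappa,
             kappa_se = res$kappa$se, discrepancy_pct = res$discrepancyPct,
             subgroup_test = res$subgroupTest)
  jsonlite::write_json(ag, file.path(outDir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Read an experiment configuration from YAML
#'
#' Builds a \code{CohortSpec} and \code{AttenuationModel} from a YAML file
#' with top-level blocks \code{cohort}, \code{phantom} and
#' \code{attenuation}; fields not given keep the package defaults.
#'
#' @param path YAML file path.
#' @return list with \code{cohort} and \code{atten}.
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  phArgs <- cfg$phantom %||% list()
  ph <- do.call(PhantomSpec, phArgs)
  coArgs <- cfg$cohort %||% list()
  coArgs$phantom <- ph
  cohort <- do.call(CohortSpec, coArgs)
  atArgs <- cfg$attenuation %||% list()
  atten <- if (isTRUE(atArgs$identity)) NULL else {
    atArgs$identity <- NULL
    do.call(AttenuationModel, atArgs)
  }
  list(cohort = cohort, atten = atten)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published reference tables
#'
#' Loads the published reference values shipped with the package from a
#' large (n = 1740) clinical evaluation of attenuation and scatter
#' correction in DAT-SPECT: the per-reader agreement summary, the
#' with-versus-without-ASC categorization cross tables (visual and
#' automatic), the two-Gaussian SBR histogram decomposition per arm, and
#' the per-hardware-setting discrepancy counts.
#'
#' @param which one of "reader_agreement", "crosstables",
#'   "mixture_parameters", "hardware_discrepancy".
#' @return a data.frame.
#' @export
referenceTable <- function(which = c("reader_agreement", "crosstables",
                                     "mixture_parameters",
                                     "hardware_discrepancy")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("published_", which, ".csv"),
                      package = "SpectASC", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write small deterministic fixtures
#'
#' Writes, under \code{outDir}: one normal and one reduced miniature
#' \code{ScanPair} (24^3 grid) as NIfTI volumes with integer-label region
#' masks, a truth CSV, copies of the published reference tables, and a JSON
#' with the effect size / cutoff recomputed from the published mixture
#' parameters.  Regeneration is byte-identical (fixed seeds throughout).
#'
#' @param outDir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
generateFixtures <- function(outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  specs <- list(
    normal = miniPhantomSpec(putamenSBR = c(1.6, 1.7), seed = 101L),
    reduced = miniPhantomSpec(putamenSBR = c(0.5, 0.65), seed = 201L))
  for (nm in names(specs)) {
    pair <- simulateScanPair(specs[[nm]], truthClass = nm)
    base <- file.path(outDir, nm)
    writeVolume(pair@volumeNoASC, paste0(base, "_no_asc.nii.gz"))
    writeVolume(pair@volumeASC, paste0(base, "_asc.nii.gz"))
    lab <- array(0L, dim(pair@volumeNoASC@data))
    lab[pair@masks$brain] <- 1L
    lab[pair@masks$reference] <- 2L
    lab[pair@masks$putamen_left] <- 3L
    lab[pair@masks$putamen_right] <- 4L
    writeVolume(SpectVolume(lab, specs[[nm]]@voxelSize),
                paste0(base, "_labels.nii.gz"))
    paths <- c(paths, paste0(base, c("_no_asc.nii.gz", "_asc.nii.gz",
                                     "_labels.nii.gz")))
  }
  truth <- data.frame(
    scan_id = names(specs), truth_class = names(specs),
    true_sbr_left = vapply(specs, function(s) s@structures[[1]]@trueSBR, 1.0),
    true_sbr_right = vapply(specs, function(s) s@structures[[2]]@trueSBR, 1.0))
  tp <- file.path(outDir, "truth.csv")
  utils::write.csv(truth, tp, row.names = FALSE)
  paths <- c(paths, tp)
  for (w in c("reader_agreement", "crosstables", "mixture_parameters",
              "hardware_discrepancy")) {
    p <- file.path(outDir, paste0(w, ".csv"))
    utils::write.csv(referenceTable(w), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  mix <- referenceTable("mixture_parameters")
  derived <- lapply(seq_len(nrow(mix)), function(i) {
    with(mix[i, ], list(
      arm = arm, M1 = M1, SD1 = SD1, M2 = M2, SD2 = SD2,
      d = (M2 - M1) / sqrt((SD1^2 + SD2^2) / 2),
      c = (SD2 * M1 + SD1 * M2) / (SD1 + SD2)))
  })
  jp <- file.path(outDir, "mixture_derived.json")
  jsonlite::write_json(derived, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}

#' Miniature phantom for fixtures and fast tests
#'
#' A 24^3, 2 mm phantom with a scaled-down brain and putamen-only anatomy;
#' noise-free by default.
#'
#' @param putamenSBR numeric(2) (left, right) true putamen SBR.
#' @param seed integer seed.
#' @param countScale Poisson count scale (default \code{Inf}: noise-free).
#' @return a \code{PhantomSpec}.
#' @export
miniPhantomSpec <- function(putamenSBR = c(2, 2), seed = 1L,
                            countScale = Inf) {
  structures <- list(
    StriatalStructure("putamen", "left", c(-7, -1, 0), c(3.5, 5.5, 3.5),
                      putamenSBR[1]),
    StriatalStructure("putamen", "right", c(7, -1, 0), c(3.5, 5.5, 3.5),
                      putamenSBR[2]),
    StriatalStructure("caudate", "left", c(-4, 6, 4), c(2.5, 4, 3), putamenSBR[1]),
    StriatalStructure("caudate", "right", c(4, 6, 4), c(2.5, 4, 3), putamenSBR[2]))
  PhantomSpec(gridShape = c(24L, 24L, 24L), voxelSize = 2,
              brainSemiAxes = c(17, 18, 15), structures = structures,
              scatterFraction = 0.3, scatterFWHM = 40, psfFWHM = 7,
              countScale = countScale, seed = seed)
}
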