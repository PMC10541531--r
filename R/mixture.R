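#' @include AllClasses.R
NULL

#' Fixed-width histogram of SBR values
#'
#' Bins values into half-open bins \code{[edge, edge + binWidth)} whose edges
#' are anchored at integer multiples of \code{binWidth} starting at 0.
#' Negative values (possible for SBR in pathological scans) are clamped into
#' the first bin.  Empty bins between occupied bins are retained with count
#' zero, so the centers form an unbroken equally spaced grid.
#'
#' @param values numeric vector, at least one value.
#' @param binWidth positive bin width (default 0.1).
#' @return a \code{\linkS4class{HistogramData}}.
#' @export
buildHistogram <- function(values, binWidth = 0.1) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("need at least one finite value")
  idx <- pmax(floor(values / binWidth), 0)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  new("HistogramData", binWidth = binWidth,
      centers = (seq_along(counts) - 0.5) * binWidth,
      counts = as.numeric(counts))
}

twoGaussModel <- function(x, p) {
  p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) +
    p[4] * exp(-(x - p[5])^2 / (2 * p[6]^2))
}

# weighted moments of a histogram fragment -> one-Gaussian start values
fragmentStart <- function(centers, counts, binWidth) {
  w <- sum(counts)
  if (w <= 0) return(NULL)
  m <- sum(centers * counts) / w
  s <- sqrt(sum((centers - m)^2 * counts) / w + binWidth^2 / 12)
  s <- max(s, binWidth / 2)
  list(A = max(counts), M = m, SD = s)
}

#' Fit the sum of two Gaussians to a histogram
#'
#' Minimizes the sum of squared differences between the bin counts and
#' \deqn{A_1 e^{-(x-M_1)^2/2SD_1^2} + A_2 e^{-(x-M_2)^2/2SD_2^2}}
#' evaluated at the bin centers, using the Nelder-Mead simplex (derivative
#' free) with deterministic multi-start initialization: the histogram is
#' split at its empirical 40th/50th/60th percentile bins and the moments of
#' each half provide the start values.  Amplitudes and SDs are
#' log-parameterized so positivity is structural.  The best-SSE solution is
#' returned with the components relabeled so that M1 < M2 (component 1 =
#' reduced population).
#'
#' @param hist a \code{\linkS4class{HistogramData}} with at least 6 occupied
#'   bins (the model has 6 free parameters).
#' @param nRestarts number of simplex polishing restarts per start point
#'   (restarting the simplex from its own solution escapes premature
#'   collapse; default 3).
#' @param maxit maximum function evaluations per simplex run (default 5000).
#' @return a \code{\linkS4class{TwoGaussianFit}}.
#' @export
fitTwoGaussians <- function(hist, nRestarts = 3L, maxit = 5000L) {
  stopifnot(is(hist, "HistogramData"))
  x <- hist@centers; y <- as.numeric(hist@counts)
  if (sum(y > 0) < 6L)
    stop("need at least 6 occupied bins to fit 6 parameters")
  obj <- function(th) {
    p <- c(exp(th[1]), th[2], exp(th[3]), exp(th[4]), th[5], exp(th[6]))
    r <- y - twoGaussModel(x, p)
    s <- sum(r * r)
    if (!is.finite(s)) return(1e300)
    s
  }
  total <- sum(y)
  cum <- cumsum(y)
  best <- NULL
  for (q in c(0.4, 0.5, 0.6)) {
    split <- which(cum >= q * total)[1]
    lo <- fragmentStart(x[1:split], y[1:split], hist@binWidth)
    hi <- if (split < length(x))
      fragmentStart(x[(split + 1):length(x)], y[(split + 1):length(x)],
                    hist@binWidth) else NULL
    if (is.null(lo) || is.null(hi)) next
    th <- c(log(lo$A), lo$M, log(lo$SD), log(hi$A), hi$M, log(hi$SD))
    ok <- FALSE
    for (r in seq_len(nRestarts)) {
      fit <- try(stats::optim(th, obj, method = "Nelder-Mead",
                              control = list(maxit = maxit, reltol = 1e-12)),
                 silent = TRUE)
      if (inherits(fit, "try-error") || !is.finite(fit$value)) break
      th <- fit$par
      ok <- TRUE
    }
    if (ok && (is.null(best) || fit$value < best$value))
      best <- list(par = th, value = fit$value)
  }
  if (is.null(best)) stop("two-Gaussian fit failed from every start")
  p <- c(exp(best$par[1]), best$par[2], exp(best$par[3]),
         exp(best$par[4]), best$par[5], exp(best$par[6]))
  if (p[2] > p[5]) p <- p[c(4, 5, 6, 1, 2, 3)]   # enforce M1 < M2
  d <- (p[5] - p[2]) / sqrt((p[3]^2 + p[6]^2) / 2)
  cc <- (p[6] * p[2] + p[3] * p[5]) / (p[3] + p[6])
  new("TwoGaussianFit", A1 = p[1], M1 = p[2], SD1 = p[3],
      A2 = p[4], M2 = p[5], SD2 = p[6], sse = best$value,
      d = d, c = cc, nValues = as.integer(round(total)), binWidth = hist@binWidth)
}

#' Binary categorization of an SBR value
#'
#' A scan is "reduced" when its minimum putamen SBR is smaller than the
#' cutoff \code{c}, and "normal" when it is equal to or larger than the
#' cutoff (ties are normal).
#'
#' @param sbrMin numeric vector of minimum putamen SBR values.
#' @param c cutoff, typically \code{cutoff(fit)} of a two-Gaussian fit.
#' @return character vector of "normal"/"reduced".
#' @export
categorize <- function(sbrMin, c) {
  ifelse(sbrMin < c, "reduced", "normal")
}

#' Draw SBR values from a two-class Gaussian mixture
#'
#' Utility used in simulations and tests: class membership is Bernoulli
#' (\code{prevalenceReduced}), values come from the class Gaussian truncated
#' at 0 (negative draws are redrawn).
#'
#' @param n number of values.
#' @param prevalenceReduced probability of the reduced class.
#' @param meanReduced,sdReduced,meanNormal,sdNormal class Gaussians.
#' @return list with \code{sbr} (numeric) and \code{class}
#'   ("normal"/"reduced").
#' @export
sampleMixtureSBR <- function(n, prevalenceReduced = 0.478,
                             meanReduced = 0.579, sdReduced = 0.157,
                             meanNormal = 1.577, sdNormal = 0.320) {
  cls <- ifelse(stats::runif(n) < prevalenceReduced, "reduced", "normal")
  mu <- ifelse(cls == "reduced", meanReduced, meanNormal)
  sd <- ifelse(cls == "reduced", sdReduced, sdNormal)
  v <- stats::rnorm(n, mu, sd)
  while (any(bad <- v < 0)) v[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
  list(sbr = v, class = cls)
}
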