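#' @include AllClasses.R
NULL

sbrLabels <- c("normal", "reduced")

checkLabels <- function(x, what) {
  if (!all(x %in% sbrLabels))
    stop(sprintf("%s must contain only 'normal'/'reduced' labels", what))
}

#' 2x2 cross table of paired categorizations
#'
#' Tabulates paired binary labels, rows = condition A, columns = condition B,
#' in the fixed order normal, reduced.
#'
#' @param labelsA,labelsB equal-length character vectors of
#'   "normal"/"reduced".
#' @return 2x2 integer matrix with dimnames.
#' @export
crossTable <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  checkLabels(labelsA, "labelsA"); checkLabels(labelsB, "labelsB")
  table(factor(labelsA, sbrLabels), factor(labelsB, sbrLabels))
}

# coerce any 2x2 count input to a plain numeric matrix
as2x2 <- function(t) {
  m <- as.matrix(unclass(t))
  if (!identical(dim(m), c(2L, 2L))) stop("need a 2x2 count table")
  if (any(m < 0)) stop("counts must be >= 0")
  if (sum(m) < 1) stop("table total must be >= 1")
  m
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with the
#' large-sample (Fleiss-Cohen-Everitt) asymptotic standard error.
#'
#' @param t 2x2 count table (matrix or \code{table}).
#' @return list with \code{kappa}, \code{se}, \code{pObserved},
#'   \code{pExpected}.
#' @examples
#' cohenKappa(matrix(c(893, 10, 15, 822), 2, 2))  # kappa 0.971, se 0.006
#' @export
cohenKappa <- function(t) {
  m <- as2x2(t)
  n <- sum(m)
  p <- m / n
  po <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  if (pe >= 1) stop("degenerate marginals: expected agreement is 1")
  k <- (po - pe) / (1 - pe)
  term1 <- sum(diag(p) * (1 - (pr + pc) * (1 - k))^2)
  term2 <- (1 - k)^2 * (p[1, 2] * (pc[1] + pr[2])^2 +
                        p[2, 1] * (pc[2] + pr[1])^2)
  term3 <- (k - pe * (1 - k))^2
  se <- sqrt(max(term1 + term2 - term3, 0) / (n * (1 - pe)^2))
  list(kappa = k, se = se, pObserved = po, pExpected = pe)
}

#' Percentage of discrepant cases
#'
#' The off-diagonal proportion of a paired 2x2 table, as a percentage.
#'
#' @param t 2x2 count table.
#' @return percentage in [0, 100].
#' @export
discrepancyProportion <- function(t) {
  m <- as2x2(t)
  100 * (m[1, 2] + m[2, 1]) / sum(m)
}

#' Majority vote of three readers
#'
#' @param l1,l2,l3 equal-length "normal"/"reduced" vectors.
#' @return the label held by at least two of the three readers (binary
#'   labels cannot tie among three).
#' @export
majorityVote <- function(l1, l2, l3) {
  checkLabels(l1, "l1"); checkLabels(l2, "l2"); checkLabels(l3, "l3")
  nReduced <- (l1 == "reduced") + (l2 == "reduced") + (l3 == "reduced")
  ifelse(nReduced >= 2, "reduced", "normal")
}

#' Intra-reader consensus over two sessions and a tie-break read
#'
#' If the two reading sessions agree, the agreed label is the consensus;
#' discrepant cases are decided by the third (tie-break) read.
#'
#' @param session1,session2,tiebreak "normal"/"reduced" vectors.
#' @return consensus labels.
#' @export
intraReaderConsensus <- function(session1, session2, tiebreak) {
  checkLabels(session1, "session1"); checkLabels(session2, "session2")
  checkLabels(tiebreak, "tiebreak")
  ifelse(session1 == session2, session1, tiebreak)
}

#' Chi-square test of homogeneity for a k x 2 table
#'
#' Pearson chi-square test that the binomial proportion is the same in all k
#' rows (df = k - 1), e.g. the proportion of discrepant cases across
#' hardware settings.
#'
#' @param t k x 2 count matrix.
#' @return list with \code{chi2}, \code{df}, \code{p}.
#' @export
chiSquareHomogeneity <- function(t) {
  m <- as.matrix(t)
  if (ncol(m) != 2L || nrow(m) < 2L) stop("need a k x 2 table with k >= 2")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

# smallest k with P(X >= k | Binomial(d, 1/2)) <= alpha
binomCritical <- function(d, alpha) {
  k <- stats::qbinom(alpha, d, 0.5, lower.tail = FALSE) + 1
  while (k > 0 && stats::pbinom(k - 2, d, 0.5, lower.tail = FALSE) <= alpha)
    k <- k - 1
  k
}

#' Power of the McNemar test (post hoc)
#'
#' Unconditional exact power of the McNemar test for paired binary data:
#' the number of discordant pairs is \eqn{D \sim Binomial(n, p_d)}, and
#' given \eqn{D} the exact one-sided binomial test (null p = 1/2, level
#' \code{alpha}) is applied to the larger discordant cell, whose probability
#' under the alternative is \eqn{OR/(OR+1)}.  The reported power is the
#' average of the conditional exact power over the distribution of \eqn{D}.
#' An asymptotic (normal-approximation) variant is available for sensitivity
#' analysis.
#'
#' @param n number of pairs.
#' @param pDiscordant probability of a discordant pair, in (0, 1).
#' @param oddsRatio ratio of the two discordant-cell probabilities (> 0).
#' @param alpha significance level (default 0.05).
#' @param sided "one" (default) or "two".
#' @param method "exact" (default) or "asymptotic".
#' @return power as a percentage.
#' @examples
#' mcnemarPower(1740, 0.05, 2)  # about 91.9
#' @export
mcnemarPower <- function(n, pDiscordant, oddsRatio, alpha = 0.05,
                         sided = c("one", "two"),
                         method = c("exact", "asymptotic")) {
  sided <- match.arg(sided); method <- match.arg(method)
  stopifnot(n >= 1, pDiscordant > 0, pDiscordant < 1, oddsRatio > 0,
            alpha > 0, alpha < 1)
  if (n * pDiscordant < 1)
    warning("expected discordant count below 1; power estimate is fragile")
  p1 <- oddsRatio / (1 + oddsRatio)   # upper discordant cell under H1
  D <- 0:n
  wD <- stats::dbinom(D, n, pDiscordant)
  aSide <- if (sided == "one") alpha else alpha / 2
  condPower <- vapply(D, function(d) {
    if (d == 0) return(0)
    if (method == "exact") {
      kHi <- binomCritical(d, aSide)
      pow <- stats::pbinom(kHi - 1, d, p1, lower.tail = FALSE)
      if (sided == "two") {
        # symmetric lower rejection region
        kLo <- d - kHi
        pow <- pow + stats::pbinom(kLo, d, p1)
      }
      pow
    } else {
      z <- stats::qnorm(1 - aSide)
      s0 <- sqrt(d) / 2
      s1 <- sqrt(d * p1 * (1 - p1))
      pow <- stats::pnorm((d * p1 - d / 2 - z * s0) / s1)
      if (sided == "two")
        pow <- pow + stats::pnorm((d / 2 - z * s0 - d * p1) / s1)
      pow
    }
  }, 1.0)
  100 * sum(wD * condPower)
}
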