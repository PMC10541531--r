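test_that("histogram binning follows the anchored half-open convention", {
  h <- buildHistogram(c(0.05, 0.149, 0.151), 0.1)
  expect_equal(h@counts, c(1, 2))
  expect_equal(h@centers, c(0.05, 0.15))
  # empty bins between occupied bins are retained
  h2 <- buildHistogram(c(0.05, 0.55), 0.1)
  expect_equal(h2@counts, c(1, 0, 0, 0, 0, 1))
  # negative values clamp into the first bin
  h3 <- buildHistogram(c(-0.2, 0.01), 0.1)
  expect_equal(h3@counts, 2)
  expect_error(buildHistogram(1, 0), "binWidth")
})

test_that("histogram counts account for every value", {
  set.seed(9)
  v <- rexp(1e4, 0.8)
  h <- buildHistogram(v)
  expect_equal(sum(h@counts), 1e4)
  # independent counting oracle on a coarse partition
  expect_equal(sum(h@counts[h@centers < 1]), sum(v < 1))
})

test_that("a noiseless two-Gaussian histogram is recovered to machine precision", {
  p <- c(50, 0.39, 0.14, 30, 1.26, 0.30)
  centers <- seq(0.05, 2.55, by = 0.1)
  counts <- p[1] * exp(-(centers - p[2])^2 / (2 * p[3]^2)) +
    p[4] * exp(-(centers - p[5])^2 / (2 * p[6]^2))
  fit <- fitTwoGaussians(new("HistogramData", binWidth = 0.1,
                             centers = centers, counts = counts))
  expect_lt(max(abs(c(fit@A1, fit@M1, fit@SD1, fit@A2, fit@M2, fit@SD2) - p)),
            1e-4)
  expect_lt(fit@sse, 1e-8)
  # the returned solution is at least as good as the moment start values
  expect_lte(fit@sse, sum((counts - counts)^2) + 1e-8)
})

test_that("component order is canonical and d, c are exchange invariant", {
  p <- c(50, 0.39, 0.14, 30, 1.26, 0.30)
  centers <- seq(0.05, 2.55, by = 0.1)
  counts <- p[1] * exp(-(centers - p[2])^2 / (2 * p[3]^2)) +
    p[4] * exp(-(centers - p[5])^2 / (2 * p[6]^2))
  fit <- fitTwoGaussians(new("HistogramData", binWidth = 0.1,
                             centers = centers, counts = counts))
  expect_lt(fit@M1, fit@M2)
  # exchanging the component labels and reordering leaves d and c unchanged
  dSwap <- (fit@M1 - fit@M2) / sqrt((fit@SD2^2 + fit@SD1^2) / 2)
  expect_equal(effectSize(fit), -dSwap)
  cSwap <- (fit@SD1 * fit@M2 + fit@SD2 * fit@M1) / (fit@SD2 + fit@SD1)
  expect_equal(cutoff(fit), cSwap)
})

test_that("fits require at least as many occupied bins as parameters", {
  expect_error(fitTwoGaussians(buildHistogram(c(0.1, 0.2, 0.3, 1.1, 1.2))),
               "6 occupied bins")
})

test_that("effect size and cutoff have their closed forms", {
  f <- new("TwoGaussianFit", A1 = 1, M1 = 0, SD1 = 1, A2 = 1, M2 = 1, SD2 = 1,
           sse = 0, d = 1, c = 0.5, nValues = 0L, binWidth = 0.1)
  expect_equal(effectSize(f), 1)         # unit case: SD1 = SD2 = 1, M2 - M1 = 1
  expect_equal(cutoff(f), 0.5)           # symmetric SDs: midpoint
  f2 <- new("TwoGaussianFit", A1 = 1, M1 = 0.3, SD1 = 0.1, A2 = 1, M2 = 1.5,
            SD2 = 0.3, sse = 0, d = (1.5 - 0.3) / sqrt((0.01 + 0.09) / 2),
            c = (0.3 * 0.3 + 0.1 * 1.5) / 0.4, nValues = 0L, binWidth = 0.1)
  expect_equal(effectSize(f2), 1.2 / sqrt(0.05))
  expect_equal(cutoff(f2), 0.24 / 0.4)
})

test_that("categorization uses a strict < cutoff with ties normal", {
  expect_equal(categorize(0.661, 0.661), "normal")
  expect_equal(categorize(0.661 - 1e-12, 0.661), "reduced")
  set.seed(2)
  v <- runif(100, 0, 2)
  once <- categorize(v, 0.9)
  expect_identical(categorize(v, 0.9), once)   # idempotent
})

test_that("the calibrated cutoff misclassifies < 5% of a well-separated mixture", {
  set.seed(31)
  s <- sampleMixtureSBR(5000)
  fit <- fitTwoGaussians(buildHistogram(s$sbr))
  expect_gt(fit@d, 3)
  lab <- categorize(s$sbr, cutoff(fit))
  expect_lt(mean(lab != s$class), 0.05)
})
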