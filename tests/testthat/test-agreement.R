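visualCells <- matrix(c(893, 10, 15, 822), 2, 2)      # rows: without ASC
automaticCells <- matrix(c(944, 6, 25, 765), 2, 2)

test_that("cross tables count pairs and preserve marginals", {
  a <- c("normal", "normal", "reduced", "reduced", "normal")
  b <- c("normal", "reduced", "reduced", "reduced", "normal")
  t <- crossTable(a, b)
  expect_equal(as.vector(t), c(2, 0, 1, 2))
  expect_equal(rowSums(t), c(normal = 3, reduced = 2))
  expect_equal(colSums(t), c(normal = 2, reduced = 3))
  # identical lists: off-diagonal zero
  t2 <- crossTable(a, a)
  expect_equal(t2[1, 2] + t2[2, 1], 0)
  expect_error(crossTable(a, b[-1]), "equal length")
  expect_error(crossTable(c("normal", "maybe"), c("normal", "normal")),
               "labels")
})

test_that("Cohen's kappa reproduces published categorization agreement", {
  kv <- cohenKappa(visualCells)
  expect_equal(round(kv$kappa, 3), 0.971)
  expect_equal(round(kv$se, 3), 0.006)
  ka <- cohenKappa(automaticCells)
  expect_equal(round(ka$kappa, 3), 0.964)
  expect_equal(round(ka$se, 3), 0.006)
})

test_that("kappa has its boundary and invariance properties", {
  expect_equal(cohenKappa(matrix(c(40, 0, 0, 60), 2, 2))$kappa, 1)
  expect_equal(cohenKappa(matrix(c(25, 25, 25, 25), 2, 2))$kappa, 0)
  k1 <- cohenKappa(visualCells)$kappa
  k2 <- cohenKappa(t(visualCells))$kappa   # transposing rows and columns
  expect_equal(k1, k2)
  expect_true(k1 >= -1 && k1 <= 1)
  expect_error(cohenKappa(matrix(c(10, 0, 0, 0), 2, 2)), "degenerate")
})

test_that("discrepancy percentages match the published tables", {
  expect_equal(round(discrepancyProportion(automaticCells), 2), 1.78)
  expect_equal(round(discrepancyProportion(visualCells), 2), 1.44)
  expect_equal(discrepancyProportion(matrix(c(10, 0, 0, 20), 2, 2)), 0)
  # zero discrepancy is equivalent to kappa 1 for nondegenerate marginals
  t <- matrix(c(30, 0, 0, 12), 2, 2)
  expect_equal(discrepancyProportion(t) == 0, cohenKappa(t)$kappa == 1)
})

test_that("majority vote is exhaustively permutation invariant", {
  labs <- c("normal", "reduced")
  for (i in labs) for (j in labs) for (k in labs) {
    v <- majorityVote(i, j, k)
    expect_equal(v, names(which.max(table(factor(c(i, j, k), labs)))))
    expect_equal(majorityVote(k, i, j), v)
    expect_equal(majorityVote(j, k, i), v)
  }
})

test_that("intra-reader consensus uses the third read only on discrepancies", {
  expect_equal(intraReaderConsensus("normal", "normal", "reduced"), "normal")
  expect_equal(intraReaderConsensus("normal", "reduced", "reduced"), "reduced")
  expect_equal(intraReaderConsensus("reduced", "normal", "normal"), "normal")
})

test_that("chi-square homogeneity reproduces the published hardware tests", {
  hw <- referenceTable("hardware_discrepancy")
  vis <- cbind(hw$visual_discrepant, hw$n - hw$visual_discrepant)
  expect_equal(round(chiSquareHomogeneity(vis)$p, 3), 0.423)
  aut <- cbind(hw$automatic_discrepant, hw$n - hw$automatic_discrepant)
  expect_equal(round(chiSquareHomogeneity(aut)$p, 3), 0.940)
  # identical proportions across rows
  same <- matrix(c(5, 10, 15, 95, 190, 285), ncol = 2)
  res <- chiSquareHomogeneity(same)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 2)
  expect_error(chiSquareHomogeneity(matrix(c(0, 5, 0, 10), 2, 2)), "zero")
})

test_that("the exact McNemar test controls its size at the null", {
  # conditional size of the critical region for every discordant count
  for (d in 1:200) {
    k <- SpectASC:::binomCritical(d, 0.05)
    expect_lte(pbinom(k - 1, d, 0.5, lower.tail = FALSE), 0.05)
    if (k >= 2)
      expect_gt(pbinom(k - 2, d, 0.5, lower.tail = FALSE), 0.05)
  }
  # unconditional power at OR = 1 never exceeds the level; the smallest
  # configuration legitimately warns about its tiny expected discordant count
  for (n in c(10, 50, 200)) for (pd in c(0.05, 0.2)) {
    pw <- if (n * pd < 1) suppressWarnings(mcnemarPower(n, pd, 1)) else
      mcnemarPower(n, pd, 1)
    expect_lte(pw, 5)
  }
  expect_warning(mcnemarPower(10, 0.05, 1), "fragile")
})

test_that("McNemar power grows with n and matches the asymptotic variant", {
  pw <- vapply(c(73, 200, 500, 1740), function(n) mcnemarPower(n, 0.05, 2), 1.0)
  expect_true(all(diff(pw) > 0))
  # agreement of exact and normal-approximation power at large n * pd
  ex <- mcnemarPower(2000, 0.05, 2)
  as <- mcnemarPower(2000, 0.05, 2, method = "asymptotic")
  expect_lt(abs(ex - as), 2)
})
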