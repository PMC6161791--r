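test_that("detection filter keeps exactly the genes detected in every cell", {
  x <- matrix(1, 3, 4, dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  p <- matrix(0.005, 3, 4, dimnames = dimnames(x))
  p["b", 2] <- 0.02
  out <- detectionFilter(x, p, alpha = 0.01)
  expect_identical(rownames(out), c("a", "c"))

  # brute-force row scan oracle on a dropout dataset
  se <- simulateCycleData(29, 100, 100, dropoutRate = 0.1, seed = 4)
  filt <- detectionFilter(se, alpha = 0.01)
  keepOracle <- character(0)
  pv <- assay(se, "detection")
  for (g in rownames(se)) {
    ok <- TRUE
    for (c0 in colnames(se)) if (pv[g, c0] >= 0.01) { ok <- FALSE; break }
    if (ok) keepOracle <- c(keepOracle, g)
  }
  expect_identical(rownames(filt), keepOracle)
  # idempotent
  expect_identical(rownames(detectionFilter(filt, alpha = 0.01)),
                   rownames(filt))
  # all genes failing yields an empty matrix with a warning, not an error
  expect_warning(res <- detectionFilter(x, p, alpha = 1e-6), "no genes")
  expect_identical(nrow(res), 0L)
})

test_that("log2 + quantile normalization equalizes column distributions", {
  x <- cbind(s1 = c(1, 2, 4), s2 = c(2, 4, 8))
  rownames(x) <- c("g1", "g2", "g3")
  out <- log2QuantileNormalize(x)
  # log2 columns are (0,1,2) and (1,2,3); the mean quantile vector is
  # (0.5, 1.5, 2.5) and both columns are monotone, so both get it exactly
  expect_equal(unname(out[, 1]), c(0.5, 1.5, 2.5))
  expect_equal(unname(out[, 2]), c(0.5, 1.5, 2.5))

  set.seed(1)
  y <- matrix(rexp(300, 0.2) + 0.5, 60, 5)
  qn <- log2QuantileNormalize(y)
  sorted <- apply(qn, 2, sort)
  for (j in 2:5) expect_identical(sorted[, j], sorted[, 1])
  # ranks preserved within each column
  for (j in 1:5) expect_identical(order(qn[, j]), order(y[, j]))
  # single cell: identity up to the log transform
  expect_equal(log2QuantileNormalize(y[, 1, drop = FALSE]),
               log2(y[, 1, drop = FALSE]))
  expect_error(log2QuantileNormalize(cbind(c(0, 1), c(1, 2))), "non-positive")
  expect_silent(log2QuantileNormalize(cbind(c(0, 1), c(1, 2)), pseudoCount = 1))
})

test_that("columns already equal up to permutation stay one multiset", {
  x <- cbind(s1 = c(8, 2, 4), s2 = c(2, 4, 8))
  out <- log2QuantileNormalize(x)
  expect_equal(sort(out[, 1]), sort(out[, 2]))
  expect_identical(order(out[, 1]), order(x[, 1]))
})

test_that("vst + robust spline normalization is monotone and centres cells", {
  set.seed(2)
  # odd gene count keeps the median an exact order statistic (a spline knot)
  x <- matrix(2^rnorm(606, 8, 2), 101, 6,
              dimnames = list(paste0("g", 1:101), paste0("s", 1:6)))
  x <- sweep(x, 2, c(1, 2, 0.5, 1.5, 0.8, 1.2), "*")  # cell-specific scale
  out <- vstRsnNormalize(x)
  # monotone within each cell
  for (j in 1:6) {
    o <- order(x[, j])
    expect_true(all(diff(out[o, j]) >= -1e-12))
  }
  # per-cell medians agree across cells
  meds <- apply(out, 2, median)
  expect_lt(max(meds) - min(meds), 1e-6)
  # identical cells come out identical
  same <- x[, c(1, 1, 1)]
  colnames(same) <- paste0("r", 1:3)
  outSame <- vstRsnNormalize(same)
  expect_equal(outSame[, 1], outSame[, 2], ignore_attr = TRUE)
  expect_equal(outSame[, 2], outSame[, 3], ignore_attr = TRUE)
  # too few genes falls back to quantile normalization with a warning
  expect_warning(vstRsnNormalize(x[1:3, ]), "falling back")
})

test_that("3-IQR masking applies the type-7 quartile fence per gene", {
  x <- rbind(spiky = c(1, 1, 1, 1, 1, 100), flat = rep(5, 6))
  colnames(x) <- paste0("s", 1:6)
  out <- maskOutliers(x, kIqr = 3)
  expect_identical(unname(is.na(out["spiky", ])), c(rep(FALSE, 5), TRUE))
  expect_true(all(!is.na(out["flat", ])))  # IQR 0: fences collapse, no mask
  expect_identical(attr(out, "nMasked"), 1L)

  # hand-computed fence on a crafted row
  row <- c(2, 4, 6, 8, 10, 40)
  q <- quantile(row, c(0.25, 0.75), type = 7)
  hi <- q[2] + 3 * (q[2] - q[1])
  out2 <- maskOutliers(rbind(r = row), kIqr = 3)
  expect_identical(unname(is.na(out2["r", ])), unname(row > hi))

  # one injected spike per gene -> exactly one mask per gene
  set.seed(6)
  m <- matrix(rnorm(50 * 29, 8, 0.2), 50, 29)
  for (g in 1:50) m[g, sample(29, 1)] <- 50
  masked <- maskOutliers(m, kIqr = 3)
  expect_identical(unname(rowSums(is.na(masked))), rep(1, 50))

  # masked count is non-increasing in k
  counts <- vapply(c(1, 2, 3, 5), function(k)
    attr(maskOutliers(m, kIqr = k), "nMasked"), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("kNN imputation recovers twins and matches the exhaustive oracle", {
  # perfect twin: gene A missing at cell 3, gene B identical elsewhere
  x <- rbind(A = c(1, 2, NA, 4), B = c(1, 2, 9, 4), C = c(5, 5, 5, 5))
  colnames(x) <- paste0("s", 1:4)
  out <- imputeMissing(x, nNeighbors = 1)
  expect_identical(out["A", 3], x["B", 3])
  # observed entries bit-identical; complete input untouched
  expect_identical(out[!is.na(x)], x[!is.na(x)])
  expect_identical(imputeMissing(out), out)

  # brute-force oracle on a 200 x 29 noiseless matrix with 5% masking
  se <- simulateCycleData(29, 150, 50, noiseSd = 0, seed = 10)
  m <- assay(se, "exprs")
  set.seed(20)
  holes <- sample(length(m), round(0.05 * length(m)))
  m[holes] <- NA
  filled <- imputeMissing(m, nNeighbors = 10)
  expect_equal(filled, bfKnnImpute(m, 10))

  # failure and fallback modes
  allNA <- rbind(g1 = c(NA, NA), g2 = c(1, 2))
  expect_error(imputeMissing(allNA), "g1")
  lonely <- rbind(g1 = c(1, NA), g2 = c(2, NA))
  expect_warning(res <- imputeMissing(lonely), "own-mean")
  expect_identical(unname(res["g1", 2]), 1)
})
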