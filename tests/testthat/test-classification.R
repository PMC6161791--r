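test_that("SOM training is deterministic and reduces quantization error", {
  se <- simulateCycleData(20, 40, 20, noiseSd = 0.2, seed = 21)
  out <- mapFromDataset(se)
  a <- trainSOM(out$map, gridRows = 4, gridCols = 4, epochs = 30, seed = 5)
  b <- trainSOM(out$map, gridRows = 4, gridCols = 4, epochs = 30, seed = 5)
  expect_identical(codebook(a), codebook(b))
  expect_identical(bmuAssignments(a), bmuAssignments(b))
  for (s in 1:5) {
    m <- trainSOM(out$map, gridRows = 4, gridCols = 4, epochs = 25, seed = s)
    qe <- quantizationErrors(m)
    expect_length(qe, 26)
    expect_lte(qe[length(qe)], qe[1])
  }
  expect_error(trainSOM(out$map, lr = c(0, 0.1)), "positive")
  expect_warning(trainSOM(out$map, gridRows = 9, gridCols = 9, epochs = 2,
                          seed = 1), "fewer genes")
})

test_that("a 1x1 grid prototype converges to the lone training vector", {
  x <- matrix(c(0, 0.4, 1, 0.2), 1, 4,
              dimnames = list("g", paste0("p", 1:4)))
  som <- trainSOM(x, gridRows = 1, gridCols = 1, epochs = 100,
                  lr = c(0.5, 0.001), seed = 1)
  expect_lt(max(abs(codebook(som) - x[1, ])), 1e-3)
})

test_that("a 1x2 grid splits two separated groups like 2-means", {
  set.seed(30)
  g1 <- matrix(rep(c(1, 0, 0, 0), each = 15), 15, 4) + rnorm(60, 0, 0.05)
  g2 <- matrix(rep(c(0, 0, 1, 1), each = 15), 15, 4) + rnorm(60, 0, 0.05)
  x <- rbind(g1, g2)
  rownames(x) <- paste0("g", 1:30)
  colnames(x) <- paste0("p", 1:4)
  som <- trainSOM(x, gridRows = 1, gridCols = 2, epochs = 50,
                  radius = c(1, 0.05), seed = 2)
  somGroup <- bmuAssignments(som)[, "col"]
  km <- kmeans(x, centers = 2, nstart = 10)$cluster
  # same partition up to label swap
  agree <- max(mean((somGroup == 1) == (km == 1)),
               mean((somGroup == 1) == (km == 2)))
  expect_equal(agree, 1)
  # prototypes land near the group means
  proto <- codebook(som)
  mu <- rbind(colMeans(g1), colMeans(g2))
  err <- min(max(abs(proto - mu)), max(abs(proto - mu[2:1, ])))
  expect_lt(err, 0.1)
})

test_that("known genes pass through and isolated genes stay non-cyclic", {
  se <- simulateCycleData(29, 60, 40, noiseSd = 0, seed = 23)
  out <- mapFromDataset(se, known = rownames(se)[rowData(se)$cyclic][1:40])
  som <- trainSOM(out$map, seed = 3)
  calls <- classifyCandidates(som, out$map, out$known)
  rownames(calls) <- calls$gene
  # every known (non-constant) gene is called cyclic with its map phase
  kn <- calls[out$known, ]
  expect_true(all(kn$isKnownCycleGene))
  expect_true(all(kn$call != "non-cyclic"))
  expect_true(all(!kn$isNovelCandidate))
  # flat genes are constant at zero noise: never cyclic regardless of BMU
  flat <- calls[rownames(se)[!rowData(se)$cyclic], ]
  expect_true(all(flat$call == "non-cyclic"))
  expect_true(all(!flat$isNovelCandidate))
  # novel candidates are exactly the cyclic calls that are not known
  expect_identical(calls$isNovelCandidate,
                   calls$call != "non-cyclic" & !calls$isKnownCycleGene)
  expect_error(classifyCandidates(som, out$map, c("absent1", "absent2")),
               "no known")
})

test_that("the cyclic set grows monotonically with neighborhood radius", {
  se <- simulateCycleData(29, 60, 40, noiseSd = 0.3, seed = 24)
  out <- mapFromDataset(se, known = rownames(se)[rowData(se)$cyclic][1:30])
  som <- trainSOM(out$map, seed = 4)
  prev <- character(0)
  for (r in c(0, 1, 2, 4)) {
    calls <- classifyCandidates(som, out$map, out$known,
                                neighborhoodRadius = r)
    cycSet <- calls$gene[calls$call != "non-cyclic"]
    expect_true(all(prev %in% cycSet))
    prev <- cycSet
  }
})

test_that("noiseless unknown cyclers with interior peaks are recovered", {
  se <- simulateCycleData(29, 100, 50, noiseSd = 0, seed = 25)
  cyc <- rownames(se)[rowData(se)$cyclic]
  known <- cyc[1:60]
  unknown <- setdiff(cyc, known)
  out <- mapFromDataset(se, known = known)
  som <- trainSOM(out$map, seed = 5)
  calls <- classifyCandidates(som, out$map, known)
  rownames(calls) <- calls$gene
  cut <- metadata(se)$phaseCutpoints
  margin <- 2 / (ncol(se) + 1)
  phi <- rowData(se)[unknown, "phi"]
  interior <- abs(phi - cut[1]) > margin & abs(phi - cut[2]) > margin &
    phi > margin & phi < 1 - margin
  int <- unknown[interior]
  expect_identical(unname(calls[int, "call"]),
                   unname(rowData(se)[int, "truePhase"]))
})

test_that("panel index conserves counts and reports absences", {
  calls <- data.frame(
    gene = paste0("g", 1:10),
    call = c("G1", "G1", "S", "G2M", rep("non-cyclic", 6)),
    isKnownCycleGene = FALSE, isNovelCandidate = FALSE,
    stringsAsFactors = FALSE)
  rep1 <- panelIndex(calls, paste0("g", 1:10))
  expect_identical(nCyclic(rep1), 4L)
  expect_identical(sum(perPhaseCounts(rep1)), nCyclic(rep1))
  expect_equal(fractionCyclic(rep1), 0.4)
  # zero cyclic calls
  rep0 <- panelIndex(calls[5:10, ], paste0("g", 5:10))
  expect_identical(nCyclic(rep0), 0L)
  expect_true(all(perPhaseCounts(rep0) == 0))
  # absent genes are reported, and still count in the denominator
  rep2 <- panelIndex(calls, c("g1", "g3", "gX", "gY"))
  expect_identical(rep2@absentGenes, c("gX", "gY"))
  expect_identical(panelSize(rep2), 4L)
  expect_equal(fractionCyclic(rep2), 0.5)
  expect_error(panelIndex(calls, character(0)), "empty")
})

test_that("a 38-cycler panel of 70 recovers 38 cyclic (54%) at zero noise", {
  se <- simulateCycleData(29, 100, 100, noiseSd = 0, seed = 26)
  panel <- makePanel(se, 38, 32, seed = 27)
  known <- setdiff(rownames(se)[rowData(se)$cyclic], panel)
  out <- mapFromDataset(se, known = known)
  som <- trainSOM(out$map, seed = 6)
  report <- panelIndex(classifyCandidates(som, out$map, known), panel)
  expect_identical(panelSize(report), 70L)
  expect_identical(nCyclic(report), 38L)
  expect_identical(round(100 * fractionCyclic(report)), 54)
  expect_identical(sum(perPhaseCounts(report)), 38L)
})
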