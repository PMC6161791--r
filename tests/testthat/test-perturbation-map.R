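test_that("min-max scaling is linear, flags constants, and is affine-invariant", {
  expect_equal(unname(minmaxScaleProfile(c(2, 4, 6))), c(0, 0.5, 1),
               ignore_attr = TRUE)
  const <- minmaxScaleProfile(c(5, 5, 5))
  expect_equal(unname(const), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(const, "constant"))
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(15)
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    expect_equal(as.numeric(minmaxScaleProfile(a * x + b)),
                 as.numeric(minmaxScaleProfile(x)))
  }
  # idempotent on already-scaled profiles
  s <- minmaxScaleProfile(runif(10))
  expect_equal(as.numeric(minmaxScaleProfile(as.numeric(s))), as.numeric(s))
})

test_that("the map reorders cells and scales rows, keeping constants", {
  x <- rbind(up = c(1, 2, 3, 4), down = c(8, 6, 4, 2), flat = c(3, 3, 3, 3))
  colnames(x) <- paste0("c", 1:4)
  ordId <- identityOrdering(colnames(x))
  mp <- buildPerturbationMap(x, ordId)
  expect_equal(unname(scaledMap(mp)["up", ]), c(0, 1/3, 2/3, 1))
  expect_identical(constantGenes(mp), "flat")
  expect_true(all(scaledMap(mp)["flat", ] == 0))
  # reversing the ordering reverses every row
  mpRev <- buildPerturbationMap(x, identityOrdering(rev(colnames(x))))
  expect_equal(unname(scaledMap(mpRev)["up", ]),
               rev(unname(scaledMap(mp)["up", ])))
  # cell mismatch is rejected with the symmetric difference
  expect_error(buildPerturbationMap(x[, 1:3], ordId), "c4")
})

test_that("noiseless map peaks land at the cell nearest each gene's phase", {
  se <- simulateCycleData(29, 60, 0, noiseSd = 0, seed = 8)
  out <- mapFromDataset(se)
  m <- scaledMap(out$map)
  th <- colData(se)$theta
  phi <- setNames(rowData(se)$phi, rownames(se))
  pos <- match(colnames(se), positionCells(out$map))
  for (g in rownames(se)) {
    circd <- pmin(abs(th - phi[g]), 1 - abs(th - phi[g]))
    expect_identical(unname(which.max(m[g, ])),
                     unname(pos[which.min(circd)]))
  }
})

test_that("segment cutpoints maximize vote agreement (paper-style blocks)", {
  # perfect marker profiles with true boundaries (15, 22) on 29 positions
  n <- 29
  prof <- function(idx) { v <- rep(0.05, n); v[idx] <- 1; minmaxScaleProfile(v) }
  x <- rbind(mg1 = prof(1:15), mS = prof(16:22), mG2 = prof(23:29))
  colnames(x) <- sprintf("p%02d", 1:n)
  mp <- buildPerturbationMap(x, identityOrdering(colnames(x)))
  markers <- list(G1 = "mg1", S = "mS", G2M = "mG2")
  seg <- assignPhaseSegments(mp, markers)
  expect_identical(segmentBoundaries(seg), c(15L, 22L))
  expect_identical(as.character(positionPhases(seg)),
                   rep(c("G1", "S", "G2M"), c(15, 7, 7)))

  # minimal case: one position per phase
  x3 <- rbind(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
  colnames(x3) <- c("p1", "p2", "p3")
  mp3 <- buildPerturbationMap(x3, identityOrdering(colnames(x3)))
  seg3 <- assignPhaseSegments(mp3, list(G1 = "a", S = "b", G2M = "c"))
  expect_identical(segmentBoundaries(seg3), c(1L, 2L))

  expect_error(assignPhaseSegments(mp3, list(G1 = "a", S = "b", G2M = "zz")),
               "G2M")
})

test_that("noisy-vote segmentation equals the O(n^2) cutpoint oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 29
    noisy <- function(idx) {
      v <- runif(n, 0, 0.45); v[idx] <- v[idx] + runif(length(idx), 0.2, 0.8)
      minmaxScaleProfile(v)
    }
    x <- rbind(mg1 = noisy(1:15), mS = noisy(16:22), mG2 = noisy(23:29))
    colnames(x) <- sprintf("p%02d", 1:n)
    mp <- buildPerturbationMap(x, identityOrdering(colnames(x)))
    markers <- list(G1 = "mg1", S = "mS", G2M = "mG2")
    seg <- assignPhaseSegments(mp, markers)
    # recompute the votes independently, then search all cutpoint pairs
    m <- scaledMap(mp)
    votes <- sapply(1:n, function(p) {
      mu <- c(G1 = mean(m["mg1", p]), S = mean(m["mS", p]),
              G2M = mean(m["mG2", p]))
      names(mu)[which.max(mu)]
    })
    expect_identical(segmentBoundaries(seg), as.integer(bfBestCutpoints(votes)))
  }
})

test_that("segmentation ignores positive rescaling of marker inputs", {
  se <- simulateCycleData(29, 40, 0, noiseSd = 0, seed = 16)
  out <- mapFromDataset(se)
  x <- assay(se, "exprs")
  x["CYC0001", ] <- 10 * x["CYC0001", ] + 2
  mp2 <- buildPerturbationMap(x, out$ordering)
  expect_identical(segmentBoundaries(assignPhaseSegments(mp2, out$markers)),
                   segmentBoundaries(phaseSegments(out$map)))
})

test_that("peak phase reads the segment under the circular window maximum", {
  n <- 29
  spike <- rep(0, n); spike[18] <- 1
  x <- rbind(g = spike,
             mg1 = c(rep(1, 15), rep(0, 14)),
             mS = c(rep(0, 15), rep(1, 7), rep(0, 7)),
             mG2 = c(rep(0, 22), rep(1, 7)),
             k = rep(4, n))
  colnames(x) <- sprintf("p%02d", 1:n)
  mp <- buildPerturbationMap(x, identityOrdering(colnames(x)))
  phaseSegments(mp) <- assignPhaseSegments(mp, list(G1 = "mg1", S = "mS",
                                                    G2M = "mG2"))
  pk <- peakPhase(mp, "g")
  expect_identical(pk$phase, "S")
  # window-3 smoothing ties positions 17..19; any of them is inside S
  expect_true(pk$peakPosition %in% 17:19)
  const <- peakPhase(mp, "k")
  expect_identical(const$phase, "non-cyclic")
  expect_identical(const$score, 0)
  # window width 1: the window mean is the raw scaled value
  expect_identical(peakPhase(mp, "g", window = 1)$peakPosition, 18L)
  expect_equal(peakPhase(mp, "g", window = 1)$score, 1 - mean(scaledMap(mp)["g", ]))
})

test_that("noiseless interior-peak genes are phased 100% correctly", {
  se <- simulateCycleData(29, 80, 0, noiseSd = 0, seed = 18)
  out <- mapFromDataset(se)
  cut <- metadata(se)$phaseCutpoints
  th <- sort(colData(se)$theta)
  # interior = peak phase not within one cell spacing of a segment boundary
  margin <- 2 / (ncol(se) + 1)
  phi <- rowData(se)$phi
  interior <- abs(phi - cut[1]) > margin & abs(phi - cut[2]) > margin &
    phi > margin & phi < 1 - margin
  for (g in rownames(se)[interior]) {
    expect_identical(peakPhase(out$map, g)$phase,
                     rowData(se)[g, "truePhase"])
  }
})
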