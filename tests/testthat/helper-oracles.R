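suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent brute-force oracles, deliberately coded differently from the
# package internals (plain double loops and full enumerations).

bfPairwiseCellDist <- function(x) {
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt(sum((x[, i] - x[, j])^2))
  d
}

# all n! permutations of 1..n, one per row
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, ifelse(p >= i, p + 1L, p))))
}

permPathLengths <- function(d, perms) {
  n <- ncol(perms)
  len <- numeric(nrow(perms))
  for (i in seq_len(n - 1L))
    len <- len + d[cbind(perms[, i], perms[, i + 1L])]
  len
}

bfShortestPathLength <- function(d) {
  min(permPathLengths(d, allPerms(nrow(d))))
}

# plain nearest-neighbour construction (no refinement), lowest-index ties
bfNearestNeighbourLength <- function(d, start) {
  n <- nrow(d)
  used <- rep(FALSE, n)
  cur <- start; used[cur] <- TRUE
  len <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!used)
    nxt <- cand[which.min(d[cur, cand])]
    len <- len + d[cur, nxt]
    used[nxt] <- TRUE
    cur <- nxt
  }
  len
}

# exhaustive kNN imputation re-coding the pinned neighbour rule (RMS
# difference over cells observed in both genes)
bfKnnImpute <- function(x, k) {
  out <- x
  ng <- nrow(x)
  for (g in seq_len(ng)) {
    for (c0 in which(is.na(x[g, ]))) {
      ds <- rep(Inf, ng)
      for (h in seq_len(ng)) {
        if (h == g || is.na(x[h, c0])) next
        shared <- !is.na(x[g, ]) & !is.na(x[h, ])
        if (!any(shared)) next
        ds[h] <- sqrt(mean((x[g, shared] - x[h, shared])^2))
      }
      elig <- which(is.finite(ds))
      if (!length(elig)) { out[g, c0] <- mean(x[g, ], na.rm = TRUE); next }
      nb <- elig[order(ds[elig], elig)][seq_len(min(k, length(elig)))]
      out[g, c0] <- mean(x[nb, c0])
    }
  }
  out
}

# O(n^2) cutpoint scoring loop over all (b1, b2) pairs
bfBestCutpoints <- function(votes) {
  n <- length(votes)
  best <- NULL; bestScore <- -1
  for (b1 in 1:(n - 2)) for (b2 in (b1 + 1):(n - 1)) {
    sc <- sum(votes[1:b1] == "G1") + sum(votes[(b1 + 1):b2] == "S") +
      sum(votes[(b2 + 1):n] == "G2M")
    if (sc > bestScore) { bestScore <- sc; best <- c(b1, b2) }
  }
  best
}

# shared fixtures -------------------------------------------------------

markersFromTruth <- function(se, genes = NULL) {
  rd <- rowData(se)
  if (is.null(genes)) genes <- rownames(se)[rd$cyclic]
  split(genes, rd[genes, "truePhase"])[c("G1", "S", "G2M")]
}

identityOrdering <- function(cells) {
  new("CellOrdering", order = cells, pathLength = 0,
      orientationAnchor = "unoriented", solverTag = "exact-dp")
}

# a random symmetric distance matrix with zero diagonal
randomDistMatrix <- function(n, seed) {
  set.seed(seed)
  d <- matrix(runif(n * n, 0.1, 1), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("c", seq_len(n)), paste0("c", seq_len(n)))
  d
}

# run order -> orient -> map -> segments on a simulated dataset
mapFromDataset <- function(se, known = NULL, seed = 1) {
  rd <- rowData(se)
  cyc <- rownames(se)[rd$cyclic]
  if (is.null(known)) known <- cyc
  markers <- markersFromTruth(se, known)
  dm <- cellDistanceMatrix(se, cyc)
  ord <- orientOrdering(shortestHamiltonianPath(dm, seed = seed), se, markers)
  mp <- buildPerturbationMap(se, ord)
  phaseSegments(mp) <- assignPhaseSegments(mp, markers)
  list(map = mp, ordering = ord, markers = markers, known = known)
}
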