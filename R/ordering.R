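#' Euclidean cell-cell distances restricted to cell-cycle genes
#'
#' Pairwise Euclidean distance between cells computed on the intersection
#' of a known cell-cycle gene set (e.g. the GO "cell cycle process"
#' members) with the genes present in the matrix. Similarity between cells
#' on these genes is taken to reflect similarity in cell-cycle stage.
#'
#' @param x genes x cells matrix or SummarizedExperiment (assay
#'   \code{exprs}), complete (impute first).
#' @param cycleGenes character vector of cell-cycle gene ids; the genes
#'   actually used (the intersection) are recorded in the result.
#' @return a \linkS4class{CellDistanceMatrix}, metric \code{"euclidean"}.
#' @export
setGeneric("cellDistanceMatrix",
           function(x, cycleGenes) standardGeneric("cellDistanceMatrix"))

#' @rdname cellDistanceMatrix
setMethod("cellDistanceMatrix", "matrix", function(x, cycleGenes) {
  if (anyNA(x)) stop("missing entries: impute before computing distances")
  used <- intersect(rownames(x), cycleGenes)
  if (!length(used))
    stop("no overlap between the cycle gene set (",
         length(cycleGenes), " genes) and the matrix")
  d <- as.matrix(dist(t(x[used, , drop = FALSE]), method = "euclidean"))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  new("CellDistanceMatrix", d = d, geneSubsetUsed = used,
      metricTag = "euclidean")
})

#' @rdname cellDistanceMatrix
setMethod("cellDistanceMatrix", "SummarizedExperiment",
  function(x, cycleGenes) cellDistanceMatrix(assay(x, "exprs"), cycleGenes))

#' Network-based cell adjacency as a distance
#'
#' The soft-threshold co-expression adjacency applied across cells rather
#' than genes: similarity s = (1 + pearson)/2 between cell profiles,
#' adjacency a = s^beta element-wise, returned as distance d = 1 - a with a
#' zero diagonal. A zero-variance cell has its correlations defined as 0
#' (s = 1/2) with a warning.
#'
#' @param x genes x cells matrix or SummarizedExperiment, >= 3 cells,
#'   complete.
#' @param beta positive integer soft-threshold power, default 6.
#' @return a \linkS4class{CellDistanceMatrix}, metric
#'   \code{"network-adjacency"}.
#' @export
setGeneric("networkAdjacency",
           function(x, beta = 6L) standardGeneric("networkAdjacency"))

#' @rdname networkAdjacency
setMethod("networkAdjacency", "matrix", function(x, beta = 6L) {
  stopifnot(beta >= 1)
  if (ncol(x) < 3L) stop("need >= 3 cells")
  if (anyNA(x)) stop("missing entries: impute before computing adjacency")
  zv <- apply(x, 2, sd) == 0
  if (any(zv))
    warning("zero-variance cell(s), correlations set to 0: ",
            paste(colnames(x)[zv], collapse = ", "))
  r <- suppressWarnings(cor(x))
  r[!is.finite(r)] <- 0
  s <- (1 + r) / 2
  a <- s^beta
  d <- 1 - a
  d <- (d + t(d)) / 2
  d[d < 0] <- 0
  diag(d) <- 0
  new("CellDistanceMatrix", d = d, geneSubsetUsed = rownames(x),
      metricTag = "network-adjacency")
})

#' @rdname networkAdjacency
setMethod("networkAdjacency", "SummarizedExperiment",
  function(x, beta = 6L) networkAdjacency(assay(x, "exprs"), beta = beta))

#' Shortest Hamiltonian path through the cells
#'
#' Estimates the minimum-total-distance open path visiting every cell
#' exactly once — the open-path variant of the travelling salesman problem,
#' obtained by closing the tour through a dummy node with zero-cost edges.
#' At or below \code{exactThreshold} cells the provably minimal path is
#' found by Held-Karp dynamic programming over vertex subsets; above it,
#' the best of \code{restarts} nearest-neighbour constructions (each from a
#' distinct start cell, ties broken by lowest cell index) refined by 2-opt
#' to a local optimum.
#'
#' @param dist a \linkS4class{CellDistanceMatrix} or a symmetric numeric
#'   matrix with cell-id dimnames.
#' @param exactThreshold largest n solved exactly (default 15, hard cap 20).
#' @param restarts nearest-neighbour starts for the heuristic; default one
#'   per cell.
#' @param seed seed used only to sample starts when \code{restarts} is
#'   smaller than the number of cells.
#' @return a \linkS4class{CellOrdering} (unoriented); its
#'   \code{pathLength} equals the sum of consecutive distances.
#' @examples
#' d <- abs(outer(1:5, 1:5, "-"))
#' dimnames(d) <- list(letters[1:5], letters[1:5])
#' cellOrder(shortestHamiltonianPath(d))
#' @export
shortestHamiltonianPath <- function(dist, exactThreshold = 15, restarts = NULL,
                                    seed = 1) {
  d <- if (is(dist, "CellDistanceMatrix")) distMatrix(dist) else dist
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("need a square distance matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L)
    return(new("CellOrdering", order = ids, pathLength = 0,
               orientationAnchor = "unoriented", solverTag = "exact-dp"))
  if (n <= min(exactThreshold, 20)) {
    res <- .held_karp_path(unname(d))
    tag <- "exact-dp"
  } else {
    if (is.null(restarts)) restarts <- n
    starts <- if (restarts >= n) seq_len(n) else {
      set.seed(as.integer(seed))
      sort(sample.int(n, restarts))
    }
    res <- .nn_two_opt(unname(d), as.integer(starts))
    tag <- "nn-2opt"
  }
  new("CellOrdering", order = ids[res$order], pathLength = res$length,
      orientationAnchor = "unoriented", solverTag = tag)
}

# Mean peak position of each marker class along an ordered matrix.
.markerCentroids <- function(ord, x, markers) {
  vapply(CYCLE_PHASES, function(ph) {
    g <- intersect(markers[[ph]], rownames(x))
    peaks <- apply(x[g, ord, drop = FALSE], 1, which.max)
    mean(peaks)
  }, numeric(1))
}

#' Orient a cell ordering by phase-marker anchors
#'
#' The Hamiltonian path fixes the sequence of cells but not its direction.
#' Direction is chosen so that the mean peak position of G1 markers
#' precedes that of S markers, which precedes G2/M: the order with more of
#' the three pairwise precedences satisfied wins; ties keep the input. By
#' default only reversal is considered (an open path has a fixed cut);
#' \code{closed = TRUE} additionally rotates the start, for orderings that
#' were closed into a tour. With no usable markers the input is returned
#' unchanged and flagged as arbitrarily oriented.
#'
#' @param ordering a \linkS4class{CellOrdering}.
#' @param x genes x cells matrix or SummarizedExperiment.
#' @param markers named list with elements \code{G1}, \code{S}, \code{G2M}
#'   of marker gene ids.
#' @param closed treat the path as a closed tour and allow rotation.
#' @return the oriented \linkS4class{CellOrdering} (idempotent).
#' @export
orientOrdering <- function(ordering, x, markers, closed = FALSE) {
  if (is(x, "SummarizedExperiment")) x <- assay(x, "exprs")
  have <- vapply(CYCLE_PHASES, function(ph)
    length(intersect(markers[[ph]], rownames(x))) > 0, logical(1))
  if (!all(have)) {
    warning("marker class(es) absent, orientation is arbitrary: ",
            paste(CYCLE_PHASES[!have], collapse = ", "))
    ordering@orientationAnchor <- "arbitrary"
    return(ordering)
  }
  score <- function(ord) {
    ctr <- .markerCentroids(ord, x, markers)
    sum(ctr["G1"] < ctr["S"], ctr["S"] < ctr["G2M"], ctr["G1"] < ctr["G2M"])
  }
  ord <- cellOrder(ordering)
  n <- length(ord)
  candidates <- if (closed) {
    rot <- lapply(seq_len(n) - 1L, function(k)
      ord[((seq_len(n) - 1L + k) %% n) + 1L])
    c(rot, lapply(rot, rev))
  } else {
    list(ord, rev(ord))
  }
  scores <- vapply(candidates, score, numeric(1))
  best <- candidates[[which.max(scores)]]  # ties keep the earliest (input first)
  ordering@order <- best
  ordering@orientationAnchor <- "G1-S-G2M-markers"
  validObject(ordering)
  ordering
}

#' Agreement of a recovered cell order with a circular ground truth
#'
#' Kendall rank correlation between a recovered linear order and the true
#' circular order, maximized over all rotations of the truth and both
#' directions — the natural score for an open path cut anywhere along a
#' cycle.
#'
#' @param recovered character vector of cell ids in recovered order.
#' @param truth character vector of cell ids in true circular order.
#' @return the best-aligned Kendall tau in [-1, 1].
#' @export
circularOrderAgreement <- function(recovered, truth) {
  stopifnot(setequal(recovered, truth))
  n <- length(truth)
  best <- -1
  pos <- seq_len(n)
  for (k in seq_len(n) - 1L) {
    rot <- truth[((seq_len(n) - 1L + k) %% n) + 1L]
    for (cand in list(rot, rev(rot))) {
      tau <- cor(pos, match(recovered, cand), method = "kendall")
      if (tau > best) best <- tau
    }
  }
  best
}
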