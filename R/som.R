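#' Train a Self-Organizing Map on perturbation profiles
#'
#' Online Kohonen training on the per-gene scaled profiles of a
#' perturbation map: for each presented gene the best-matching unit (BMU)
#' is the prototype nearest in Euclidean distance, and all prototypes move
#' toward the sample by lr * exp(-latticeDist^2 / (2 radius^2)). Learning
#' rate and neighborhood radius decay (linearly by default) across epochs;
#' presentation order is reshuffled each epoch under the seed, so training
#' is bit-for-bit reproducible. The mean gene-to-BMU distance
#' (quantization error) is recorded before training and after every epoch.
#'
#' Prototypes are initialized uniformly at random within the per-position
#' data range (seeded), so the quantization error starts from an
#' uninformed lattice and decreases as the map organizes.
#'
#' @param x a \linkS4class{PerturbationMap} or a genes x positions matrix.
#' @param gridRows,gridCols lattice size, default 6 x 6 (sized for
#'   hundreds to thousands of genes; a warning fires when genes are fewer
#'   than nodes).
#' @param epochs full passes over the genes, default 200.
#' @param lr learning-rate schedule (start, end), default c(0.5, 0.01).
#' @param radius neighborhood-radius schedule (start, end); default starts
#'   at half the larger lattice dimension and ends at 0.5.
#' @param decay \code{"linear"} (default) or \code{"exponential"}.
#' @param seed integer seed (mandatory determinism).
#' @return a \linkS4class{SOMModel}.
#' @export
trainSOM <- function(x, gridRows = 6L, gridCols = 6L, epochs = 200L,
                     lr = c(0.5, 0.01),
                     radius = c(max(gridRows, gridCols) / 2, 0.5),
                     decay = c("linear", "exponential"), seed = 1) {
  if (is(x, "PerturbationMap")) x <- scaledMap(x)
  decay <- match.arg(decay)
  stopifnot(is.matrix(x), gridRows >= 1, gridCols >= 1, epochs >= 1)
  if (nrow(x) == 0L) stop("empty map: no genes to train on")
  if (any(lr <= 0) || any(radius <= 0))
    stop("learning-rate and radius schedules must be positive")
  nGenes <- nrow(x)
  nNodes <- as.integer(gridRows * gridCols)
  if (nGenes < nNodes)
    warning(sprintf("fewer genes (%d) than lattice nodes (%d)", nGenes, nNodes))

  set.seed(as.integer(seed))
  nodeRow <- ((seq_len(nNodes) - 1L) %% gridRows) + 1L
  nodeCol <- ((seq_len(nNodes) - 1L) %/% gridRows) + 1L
  gridD2 <- outer(nodeRow, nodeRow, "-")^2 + outer(nodeCol, nodeCol, "-")^2

  rng <- apply(x, 2, range)
  codes <- vapply(seq_len(ncol(x)), function(j)
    runif(nNodes, rng[1, j], rng[2, j]), numeric(nNodes))
  codes <- matrix(codes, nrow = nNodes,
                  dimnames = list(sprintf("node%02d", seq_len(nNodes)),
                                  colnames(x)))

  qe <- numeric(epochs + 1L)
  bmuOf <- function(codes) {
    # genes x nodes squared cross-distances, BMU = per-gene argmin
    cross <- outer(rowSums(x^2), rep(1, nNodes)) +
      outer(rep(1, nGenes), rowSums(codes^2)) - 2 * x %*% t(codes)
    list(bmu = max.col(-cross, ties.method = "first"),
         dist = sqrt(pmax(apply(cross, 1, min), 0)))
  }
  qe[1] <- mean(bmuOf(codes)$dist)

  sched <- function(s, e) {
    if (epochs == 1L) return(s[1])
    if (decay == "linear") {
      s[1] + (s[2] - s[1]) * (e - 1) / (epochs - 1)
    } else {
      s[1] * (s[2] / s[1])^((e - 1) / (epochs - 1))
    }
  }

  for (e in seq_len(epochs)) {
    lrE <- sched(lr, e)
    radE <- sched(radius, e)
    gauss <- exp(-gridD2 / (2 * radE^2))
    for (i in sample.int(nGenes)) {
      xi <- x[i, ]
      d2 <- rowSums(codes^2) - 2 * (codes %*% xi) + sum(xi^2)
      bmu <- which.min(d2)
      h <- lrE * gauss[, bmu]
      codes <- codes + h * (matrix(xi, nNodes, ncol(x), byrow = TRUE) - codes)
    }
    qe[e + 1L] <- mean(bmuOf(codes)$dist)
  }

  fin <- bmuOf(codes)
  assignments <- cbind(row = nodeRow[fin$bmu], col = nodeCol[fin$bmu])
  rownames(assignments) <- rownames(x)
  new("SOMModel", codebook = codes, gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), assignments = assignments,
      trainingParams = list(epochs = as.integer(epochs), lr = lr,
                            radius = radius, decay = decay,
                            seed = as.integer(seed)),
      qeTrace = qe)
}

#' Call cyclic genes by SOM co-location with known cell-cycle genes
#'
#' A gene is called cyclic iff it is itself a known cell-cycle gene, or its
#' BMU lattice neighborhood (Euclidean lattice distance <=
#' \code{neighborhoodRadius}) contains at least \code{minKnown} known cycle
#' genes — genes with perturbation patterns similar to known cycle genes
#' are inferred to be new candidates. The phase label comes from the
#' perturbation map's peak segment (\code{\link{peakPhase}}), with the SOM
#' gating cyclic vs non-cyclic; constant genes are always non-cyclic.
#'
#' @param som a trained \linkS4class{SOMModel} over the same genes.
#' @param map the \linkS4class{PerturbationMap} with segments assigned.
#' @param knownCycleGenes character vector of known cycle gene ids, or a
#'   named list of such vectors (e.g. per-phase GMT sets); the union is
#'   used.
#' @param neighborhoodRadius lattice radius, default 1 (BMU node plus its
#'   4-neighbors).
#' @param minKnown known genes required inside the neighborhood, default 1.
#' @param window peak-detection window passed to \code{\link{peakPhase}}.
#' @return data.frame of per-gene calls: \code{gene}, \code{call} (G1, S,
#'   G2M or non-cyclic), BMU coordinates, known-gene count in the
#'   neighborhood, peak score / position / wrap flag, and the
#'   \code{isKnownCycleGene} / \code{isNovelCandidate} flags.
#' @export
classifyCandidates <- function(som, map, knownCycleGenes,
                               neighborhoodRadius = 1, minKnown = 1,
                               window = 3) {
  if (is.list(knownCycleGenes))
    knownCycleGenes <- unique(unlist(knownCycleGenes, use.names = FALSE))
  genes <- rownames(scaledMap(map))
  known <- intersect(knownCycleGenes, genes)
  if (!length(known)) stop("no known cell-cycle genes present in the map")
  a <- bmuAssignments(som)
  if (!all(genes %in% rownames(a)))
    stop("SOM was not trained on the map's genes")
  a <- a[genes, , drop = FALSE]
  isKnown <- genes %in% known
  ka <- a[isKnown, , drop = FALSE]

  nKnownNear <- vapply(seq_along(genes), function(i) {
    d <- sqrt((ka[, 1] - a[i, 1])^2 + (ka[, 2] - a[i, 2])^2)
    self <- isKnown[i]  # a known gene does not count itself
    sum(d <= neighborhoodRadius) - as.integer(self)
  }, numeric(1))

  peaks <- lapply(genes, function(g) peakPhase(map, g, window = window))
  peakPh <- vapply(peaks, `[[`, character(1), "phase")
  gate <- isKnown | nKnownNear >= minKnown
  call <- ifelse(gate & peakPh != "non-cyclic", peakPh, "non-cyclic")

  data.frame(
    gene = genes,
    call = call,
    bmuRow = unname(a[, 1]),
    bmuCol = unname(a[, 2]),
    nKnownNeighborhood = as.integer(nKnownNear),
    peakScore = vapply(peaks, `[[`, numeric(1), "score"),
    peakPosition = vapply(peaks, function(p) as.integer(p$peakPosition),
                          integer(1)),
    wrapsAround = vapply(peaks, `[[`, logical(1), "wrapsAround"),
    isKnownCycleGene = isKnown,
    isNovelCandidate = call != "non-cyclic" & !isKnown,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-phase cell-cycle index of a gene panel
#'
#' Counts how many genes of a query panel are called cyclic overall and per
#' phase — the panel's cell-cycle index. Panel genes absent from the calls
#' (not measured in the dataset) are reported as uncalled, not fatal; the
#' cyclic fraction is computed over the full panel size.
#'
#' @param calls per-gene call data.frame from
#'   \code{\link{classifyCandidates}}.
#' @param panel character vector of panel gene ids (nonempty).
#' @return a \linkS4class{PanelIndexReport}.
#' @export
panelIndex <- function(calls, panel) {
  if (!length(panel)) stop("empty panel")
  panel <- unique(panel)
  present <- calls[calls$gene %in% panel, , drop = FALSE]
  absent <- setdiff(panel, calls$gene)
  cyc <- present$call %in% CYCLE_PHASES
  perPhase <- vapply(CYCLE_PHASES, function(ph) sum(present$call == ph),
                     integer(1))
  new("PanelIndexReport",
      panelSize = length(panel),
      nCyclic = as.integer(sum(cyc)),
      fractionCyclic = sum(cyc) / length(panel),
      perPhaseCounts = perPhase,
      calls = present,
      absentGenes = absent)
}
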