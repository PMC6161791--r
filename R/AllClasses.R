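#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor dist median quantile rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib cycleMap, .registration = TRUE
NULL

#' Cell-cycle phase labels used throughout the package
#'
#' The three phases resolved by the map, in cycle order. G0 and G1 are not
#' distinguished; S precedes G2/M.
#' @export
CYCLE_PHASES <- c("G1", "S", "G2M")

#' Pairwise cell distances on a gene subset
#'
#' Symmetric cell-by-cell distance matrix with provenance: which genes were
#' used and which metric (plain Euclidean on cycle genes, or the
#' soft-threshold correlation-network adjacency turned into a distance).
#'
#' @slot d symmetric numeric matrix, zero diagonal, nonnegative, with cell
#'   ids as dimnames.
#' @slot geneSubsetUsed character vector of the genes the metric actually
#'   used (after intersection with the expression matrix).
#' @slot metricTag one of \code{"euclidean"}, \code{"network-adjacency"}.
#' @exportClass CellDistanceMatrix
setClass("CellDistanceMatrix",
  slots = c(d = "matrix", geneSubsetUsed = "character", metricTag = "character"))

setValidity("CellDistanceMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("distance matrix needs matching cell-id dimnames")
  if (any(!is.finite(d))) return("non-finite distances")
  if (max(abs(d - t(d))) > 1e-12) return("distance matrix not symmetric (tol 1e-12)")
  if (any(diag(d) != 0)) return("diagonal must be exactly zero")
  if (any(d < 0)) return("negative distances")
  if (!object@metricTag %in% c("euclidean", "network-adjacency"))
    return("unknown metricTag")
  TRUE
})

#' A one-dimensional ordering of cells along the cell cycle
#'
#' A permutation of cell ids defining the virtual cell-cycle time axis,
#' produced by the shortest-Hamiltonian-path solver and (optionally)
#' oriented by phase-marker anchors.
#'
#' @slot order character vector: cell ids in path order.
#' @slot pathLength total distance along consecutive path edges.
#' @slot orientationAnchor how direction was fixed (\code{"unoriented"},
#'   \code{"G1-S-G2M-markers"}, or \code{"arbitrary"} when markers were
#'   unavailable).
#' @slot solverTag \code{"exact-dp"} (Held-Karp) or \code{"nn-2opt"}.
#' @exportClass CellOrdering
setClass("CellOrdering",
  slots = c(order = "character", pathLength = "numeric",
            orientationAnchor = "character", solverTag = "character"))

setValidity("CellOrdering", function(object) {
  if (anyDuplicated(object@order)) return("order contains duplicate cells")
  if (length(object@pathLength) != 1L || object@pathLength < 0)
    return("pathLength must be a single nonnegative number")
  TRUE
})

#' Contiguous G1 / S / G2M segments over ordered cells
#'
#' Two cutpoints splitting path positions 1..n into three nonempty
#' contiguous blocks labelled G1, S, G2M in cycle order: G1 = 1..b1,
#' S = (b1+1)..b2, G2M = (b2+1)..n.
#'
#' @slot boundaries integer of length 2, the cutpoints (b1, b2).
#' @slot nPositions number of ordered positions covered.
#' @exportClass PhaseSegments
setClass("PhaseSegments",
  slots = c(boundaries = "integer", nPositions = "integer"))

setValidity("PhaseSegments", function(object) {
  b <- object@boundaries; n <- object@nPositions
  if (length(b) != 2L || length(n) != 1L) return("need 2 boundaries, 1 size")
  if (n < 3L) return("need at least 3 positions for 3 phases")
  if (!(b[1] >= 1L && b[1] < b[2] && b[2] < n))
    return("boundaries must satisfy 1 <= b1 < b2 < n (nonempty blocks)")
  TRUE
})

#' Cell-cycle perturbation map
#'
#' Per-gene expression profiles over cells ordered along the cell cycle,
#' min-max scaled to [0, 1] per gene (0 = undetectable, 1 = maximum
#' expression). Constant genes scale to all-zero and are flagged, not
#' dropped. Optionally carries the G1/S/G2M segmentation.
#'
#' @slot scaled genes x ordered-positions numeric matrix in [0, 1];
#'   column names are the ordered cell ids.
#' @slot positionCell cell id at each path position 1..n.
#' @slot segments a \linkS4class{PhaseSegments} or NULL.
#' @slot constantGenes gene ids whose profile was constant before scaling.
#' @exportClass PerturbationMap
setClass("PerturbationMap",
  slots = c(scaled = "matrix", positionCell = "character",
            segments = "ANY", constantGenes = "character"))

setValidity("PerturbationMap", function(object) {
  m <- object@scaled
  if (!identical(colnames(m), object@positionCell))
    return("scaled column names must equal positionCell")
  if (is.null(rownames(m))) return("scaled needs gene-id rownames")
  if (any(m < 0 | m > 1)) return("scaled values must lie in [0, 1]")
  nc <- setdiff(rownames(m), object@constantGenes)
  if (length(nc)) {
    sub <- m[nc, , drop = FALSE]
    if (any(abs(apply(sub, 1, max) - 1) > 1e-12) ||
        any(abs(apply(sub, 1, min)) > 1e-12))
      return("non-constant rows must attain both 0 and 1")
  }
  if (!is.null(object@segments)) {
    if (!is(object@segments, "PhaseSegments")) return("segments must be PhaseSegments")
    if (object@segments@nPositions != ncol(m))
      return("segments cover a different number of positions")
  }
  TRUE
})

#' Self-Organizing Map trained on perturbation profiles
#'
#' A rows x cols Kohonen lattice of prototype vectors over the map's
#' ordered positions, with each gene assigned to its best-matching unit
#' (BMU) and the per-epoch quantization-error trace kept as a convergence
#' diagnostic.
#'
#' @slot codebook (rows*cols) x nPositions prototype matrix; node k sits at
#'   lattice coordinates (row, col) = (((k-1) %% rows) + 1, ((k-1) %/% rows) + 1).
#' @slot gridRows,gridCols lattice dimensions.
#' @slot assignments genes x 2 integer matrix (row, col) of BMU coordinates,
#'   gene ids as rownames.
#' @slot trainingParams list echoing epochs, learning-rate and radius
#'   schedules, decay mode and seed.
#' @slot qeTrace numeric of length epochs + 1: mean gene-to-BMU Euclidean
#'   distance before training (element 1) and after each epoch.
#' @exportClass SOMModel
setClass("SOMModel",
  slots = c(codebook = "matrix", gridRows = "integer", gridCols = "integer",
            assignments = "matrix", trainingParams = "list",
            qeTrace = "numeric"))

setValidity("SOMModel", function(object) {
  if (nrow(object@codebook) != object@gridRows * object@gridCols)
    return("codebook rows must equal gridRows * gridCols")
  a <- object@assignments
  if (ncol(a) != 2L || is.null(rownames(a))) return("assignments must be genes x 2 with gene ids")
  if (any(a[, 1] < 1L | a[, 1] > object@gridRows) ||
      any(a[, 2] < 1L | a[, 2] > object@gridCols))
    return("BMU coordinates outside the lattice")
  TRUE
})

#' Per-phase cell-cycle index of a gene panel
#'
#' Summary of how many genes of a query panel are perturbed to a specific
#' cell-cycle phase: total cyclic count, fraction of the panel, per-phase
#' counts, and the per-gene calls behind them.
#'
#' @slot panelSize number of genes queried.
#' @slot nCyclic panel genes called cyclic (any phase).
#' @slot fractionCyclic nCyclic / panelSize (raw ratio; reports round to
#'   whole percent).
#' @slot perPhaseCounts named integer counts for G1, S, G2M.
#' @slot calls data.frame of per-gene \code{PhaseCall} records for panel
#'   genes present in the dataset.
#' @slot absentGenes panel genes not present in the dataset (uncalled).
#' @exportClass PanelIndexReport
setClass("PanelIndexReport",
  slots = c(panelSize = "integer", nCyclic = "integer",
            fractionCyclic = "numeric", perPhaseCounts = "integer",
            calls = "data.frame", absentGenes = "character"))

setValidity("PanelIndexReport", function(object) {
  if (!identical(names(object@perPhaseCounts), CYCLE_PHASES))
    return("perPhaseCounts must be named G1, S, G2M")
  if (sum(object@perPhaseCounts) != object@nCyclic)
    return("per-phase counts must sum to nCyclic")
  if (object@nCyclic > object@panelSize) return("nCyclic exceeds panelSize")
  TRUE
})
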