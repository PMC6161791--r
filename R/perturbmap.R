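#' Min-max scale one gene's profile to [0, 1]
#'
#' (x - min)/(max - min): 0 marks the lowest (undetectable) level and 1 the
#' maximum expression. A constant profile returns all zeros and carries the
#' attribute \code{constant = TRUE}.
#'
#' @param profile numeric vector of per-cell values, no NAs.
#' @return scaled numeric vector with attribute \code{constant}.
#' @examples
#' minmaxScaleProfile(c(2, 4, 6))
#' @export
minmaxScaleProfile <- function(profile) {
  if (anyNA(profile)) stop("profile contains missing values")
  rng <- range(profile)
  if (rng[1] == rng[2]) {
    out <- rep(0, length(profile))
    names(out) <- names(profile)
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (profile - rng[1]) / (rng[2] - rng[1])
  attr(out, "constant") <- FALSE
  out
}

#' Build the cell-cycle perturbation map
#'
#' Reorders cells by the given ordering and min-max scales each gene's
#' profile, yielding a diagram of how every gene's expression is perturbed
#' as a cell passes through the cell cycle. Constant genes are flagged and
#' kept (all-zero rows), not dropped.
#'
#' @param x genes x cells matrix or SummarizedExperiment (assay
#'   \code{exprs}), complete.
#' @param ordering a \linkS4class{CellOrdering} covering exactly the
#'   matrix's cells.
#' @return a \linkS4class{PerturbationMap} (segments unset).
#' @export
setGeneric("buildPerturbationMap",
           function(x, ordering) standardGeneric("buildPerturbationMap"))

#' @rdname buildPerturbationMap
setMethod("buildPerturbationMap", "matrix", function(x, ordering) {
  if (anyNA(x)) stop("missing entries: impute before mapping")
  ord <- cellOrder(ordering)
  extra <- setdiff(ord, colnames(x))
  missing <- setdiff(colnames(x), ord)
  if (length(extra) || length(missing))
    stop("ordering/matrix cell mismatch; in ordering only: {",
         paste(extra, collapse = ", "), "}, in matrix only: {",
         paste(missing, collapse = ", "), "}")
  m <- x[, ord, drop = FALSE]
  rng <- cbind(apply(m, 1, min), apply(m, 1, max))
  const <- rng[, 1] == rng[, 2]
  scaled <- (m - rng[, 1]) / ifelse(const, 1, rng[, 2] - rng[, 1])
  scaled[const, ] <- 0
  new("PerturbationMap", scaled = scaled, positionCell = ord,
      segments = NULL, constantGenes = rownames(m)[const])
})

#' @rdname buildPerturbationMap
setMethod("buildPerturbationMap", "SummarizedExperiment",
  function(x, ordering) buildPerturbationMap(assay(x, "exprs"), ordering))

# Per-position phase votes: each position votes for the phase whose
# markers have the highest mean scaled expression there (ties to the
# earlier phase in cycle order, deterministically).
.phaseVotes <- function(map, markers) {
  m <- scaledMap(map)
  votes <- vapply(seq_len(ncol(m)), function(p) {
    means <- vapply(CYCLE_PHASES, function(ph)
      mean(m[intersect(markers[[ph]], rownames(m)), p]), numeric(1))
    CYCLE_PHASES[which.max(means)]
  }, character(1))
  factor(votes, levels = CYCLE_PHASES)
}

# Exhaustive contiguity-constrained cutpoint search over (b1, b2):
# maximize the number of positions whose vote matches their block label.
.bestCutpoints <- function(votes) {
  n <- length(votes)
  cumG1 <- cumsum(votes == "G1")
  cumS <- cumsum(votes == "S")
  cumG2 <- cumsum(votes == "G2M")
  best <- c(NA_integer_, NA_integer_)
  bestScore <- -1L
  for (b1 in seq_len(n - 2L)) {
    for (b2 in seq(b1 + 1L, n - 1L)) {
      sc <- cumG1[b1] + (cumS[b2] - cumS[b1]) + (cumG2[n] - cumG2[b2])
      if (sc > bestScore) {  # ties keep smallest (b1, b2)
        bestScore <- sc
        best <- c(b1, b2)
      }
    }
  }
  list(boundaries = as.integer(best), score = bestScore)
}

#' Assign contiguous G1/S/G2M segments to map positions
#'
#' Each ordered position votes for the phase whose markers have the
#' highest mean scaled expression there; the two cutpoints are then chosen
#' to maximize total vote agreement under the constraint that the three
#' phase blocks are contiguous and in cycle order (exhaustive search over
#' all cutpoint pairs, O(n^2)).
#'
#' @param map a \linkS4class{PerturbationMap}.
#' @param markers named list with elements \code{G1}, \code{S}, \code{G2M};
#'   each class must have at least one gene present in the map.
#' @return a \linkS4class{PhaseSegments}; assign it into the map with
#'   \code{phaseSegments(map) <- segments}.
#' @export
assignPhaseSegments <- function(map, markers) {
  m <- scaledMap(map)
  for (ph in CYCLE_PHASES)
    if (!length(intersect(markers[[ph]], rownames(m))))
      stop("marker class absent from the map: ", ph)
  votes <- .phaseVotes(map, markers)
  cut <- .bestCutpoints(votes)
  new("PhaseSegments", boundaries = cut$boundaries,
      nPositions = ncol(m))
}

# Circular moving average over positions with the given window width.
.circularWindowMean <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  idx <- outer(seq_len(n), seq(-half, half), function(i, o) ((i + o - 1L) %% n) + 1L)
  rowMeans(matrix(x[idx], nrow = n))
}

#' Phase of peak expression for one gene
#'
#' Finds the gene's maximum-mean window (circular moving average, default
#' width 3) over ordered positions and returns the phase segment containing
#' the window centre, together with a peak score (max window mean minus
#' overall mean). A constant-flagged gene returns \code{"non-cyclic"} with
#' score 0. \code{wrapsAround} marks peaks whose window spans the G2M-to-G1
#' wrap, where the circular argmax decides between the two phases.
#'
#' @param map a \linkS4class{PerturbationMap} with segments assigned.
#' @param gene gene id present in the map.
#' @param window circular window width (odd), default 3; width 1 uses the
#'   raw scaled values.
#' @return list with \code{phase}, \code{score}, \code{peakPosition},
#'   \code{wrapsAround}.
#' @export
peakPhase <- function(map, gene, window = 3) {
  m <- scaledMap(map)
  if (!gene %in% rownames(m)) stop("gene not in map: ", gene)
  if (gene %in% constantGenes(map))
    return(list(phase = "non-cyclic", score = 0, peakPosition = NA_integer_,
                wrapsAround = FALSE))
  if (is.null(phaseSegments(map)))
    stop("map carries no phase segments; run assignPhaseSegments first")
  stopifnot(window >= 1, window %% 2 == 1)
  x <- m[gene, ]
  sm <- .circularWindowMean(x, window)
  peak <- which.max(sm)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  wraps <- (peak - half) < 1L || (peak + half) > n
  phases <- positionPhases(map)
  list(phase = as.character(phases[peak]),
       score = max(sm) - mean(x),
       peakPosition = as.integer(peak),
       wrapsAround = wraps)
}
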