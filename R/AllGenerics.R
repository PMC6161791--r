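#' Accessors for cycleMap S4 objects
#'
#' Small read-only accessors so downstream code never touches slots.
#'
#' @param x a cycleMap S4 object.
#' @param value replacement value (setters only).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellOrder", function(x) standardGeneric("cellOrder"))
#' @rdname accessors
#' @export
setGeneric("pathLength", function(x) standardGeneric("pathLength"))
#' @rdname accessors
#' @export
setGeneric("solverTag", function(x) standardGeneric("solverTag"))
#' @rdname accessors
#' @export
setGeneric("orientationAnchor", function(x) standardGeneric("orientationAnchor"))
#' @rdname accessors
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))
#' @rdname accessors
#' @export
setGeneric("metricTag", function(x) standardGeneric("metricTag"))
#' @rdname accessors
#' @export
setGeneric("geneSubsetUsed", function(x) standardGeneric("geneSubsetUsed"))
#' @rdname accessors
#' @export
setGeneric("scaledMap", function(x) standardGeneric("scaledMap"))
#' @rdname accessors
#' @export
setGeneric("positionCells", function(x) standardGeneric("positionCells"))
#' @rdname accessors
#' @export
setGeneric("constantGenes", function(x) standardGeneric("constantGenes"))
#' @rdname accessors
#' @export
setGeneric("phaseSegments", function(x) standardGeneric("phaseSegments"))
#' @rdname accessors
#' @export
setGeneric("phaseSegments<-", function(x, value) standardGeneric("phaseSegments<-"))
#' @rdname accessors
#' @export
setGeneric("segmentBoundaries", function(x) standardGeneric("segmentBoundaries"))
#' @rdname accessors
#' @export
setGeneric("positionPhases", function(x) standardGeneric("positionPhases"))
#' @rdname accessors
#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))
#' @rdname accessors
#' @export
setGeneric("bmuAssignments", function(x) standardGeneric("bmuAssignments"))
#' @rdname accessors
#' @export
setGeneric("quantizationErrors", function(x) standardGeneric("quantizationErrors"))
#' @rdname accessors
#' @export
setGeneric("panelSize", function(x) standardGeneric("panelSize"))
#' @rdname accessors
#' @export
setGeneric("nCyclic", function(x) standardGeneric("nCyclic"))
#' @rdname accessors
#' @export
setGeneric("fractionCyclic", function(x) standardGeneric("fractionCyclic"))
#' @rdname accessors
#' @export
setGeneric("perPhaseCounts", function(x) standardGeneric("perPhaseCounts"))
#' @rdname accessors
#' @export
setGeneric("phaseCalls", function(x) standardGeneric("phaseCalls"))

setMethod("cellOrder", "CellOrdering", function(x) x@order)
setMethod("pathLength", "CellOrdering", function(x) x@pathLength)
setMethod("solverTag", "CellOrdering", function(x) x@solverTag)
setMethod("orientationAnchor", "CellOrdering", function(x) x@orientationAnchor)

setMethod("distMatrix", "CellDistanceMatrix", function(x) x@d)
setMethod("metricTag", "CellDistanceMatrix", function(x) x@metricTag)
setMethod("geneSubsetUsed", "CellDistanceMatrix", function(x) x@geneSubsetUsed)

setMethod("scaledMap", "PerturbationMap", function(x) x@scaled)
setMethod("positionCells", "PerturbationMap", function(x) x@positionCell)
setMethod("constantGenes", "PerturbationMap", function(x) x@constantGenes)
setMethod("phaseSegments", "PerturbationMap", function(x) x@segments)
setMethod("phaseSegments<-", "PerturbationMap", function(x, value) {
  x@segments <- value
  validObject(x)
  x
})

setMethod("segmentBoundaries", "PhaseSegments", function(x) x@boundaries)
setMethod("positionPhases", "PhaseSegments", function(x) {
  b <- x@boundaries
  n <- x@nPositions
  factor(rep(CYCLE_PHASES, times = c(b[1], b[2] - b[1], n - b[2])),
         levels = CYCLE_PHASES)
})
setMethod("positionPhases", "PerturbationMap", function(x) {
  if (is.null(x@segments)) stop("map carries no phase segments yet")
  positionPhases(x@segments)
})

setMethod("codebook", "SOMModel", function(x) x@codebook)
setMethod("bmuAssignments", "SOMModel", function(x) x@assignments)
setMethod("quantizationErrors", "SOMModel", function(x) x@qeTrace)

setMethod("panelSize", "PanelIndexReport", function(x) x@panelSize)
setMethod("nCyclic", "PanelIndexReport", function(x) x@nCyclic)
setMethod("fractionCyclic", "PanelIndexReport", function(x) x@fractionCyclic)
setMethod("perPhaseCounts", "PanelIndexReport", function(x) x@perPhaseCounts)
setMethod("phaseCalls", "PanelIndexReport", function(x) x@calls)

setMethod("show", "CellDistanceMatrix", function(object) {
  cat(sprintf("CellDistanceMatrix: %d cells, metric '%s', %d genes used\n",
              nrow(object@d), object@metricTag, length(object@geneSubsetUsed)))
})

setMethod("show", "CellOrdering", function(object) {
  n <- length(object@order)
  cat(sprintf("CellOrdering: %d cells, path length %.4g [%s, %s]\n",
              n, object@pathLength, object@solverTag, object@orientationAnchor))
  cat("  ", paste(head(object@order, 6), collapse = " -> "),
      if (n > 6) "-> ..." else "", "\n")
})

setMethod("show", "PhaseSegments", function(object) {
  b <- object@boundaries
  cat(sprintf("PhaseSegments over %d positions: G1 #1-#%d | S #%d-#%d | G2M #%d-#%d\n",
              object@nPositions, b[1], b[1] + 1L, b[2], b[2] + 1L,
              object@nPositions))
})

setMethod("show", "PerturbationMap", function(object) {
  cat(sprintf("PerturbationMap: %d genes x %d ordered cells (scaled 0-1), %d constant\n",
              nrow(object@scaled), ncol(object@scaled),
              length(object@constantGenes)))
  if (!is.null(object@segments)) show(object@segments)
})

setMethod("show", "SOMModel", function(object) {
  qe <- object@qeTrace
  cat(sprintf("SOMModel: %dx%d lattice, %d genes, %d epochs; QE %.4g -> %.4g\n",
              object@gridRows, object@gridCols, nrow(object@assignments),
              length(qe) - 1L, qe[1], qe[length(qe)]))
})

setMethod("show", "PanelIndexReport", function(object) {
  pc <- object@perPhaseCounts
  cat(sprintf("PanelIndexReport: %d of %d panel genes cyclic (%d%%)\n",
              object@nCyclic, object@panelSize,
              round(100 * object@fractionCyclic)))
  cat(sprintf("  G1: %d  S: %d  G2M: %d", pc["G1"], pc["S"], pc["G2M"]))
  if (length(object@absentGenes))
    cat(sprintf("  (%d panel genes absent from dataset)",
                length(object@absentGenes)))
  cat("\n")
})
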