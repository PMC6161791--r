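#' Read and write expression matrices and gene sets
#'
#' TSV matrices are genes-as-rows with the gene id in the first column and
#' cell ids in the header; masked (missing) entries are empty fields. MTX
#' output is Matrix Market triplet format with sidecar \code{.rownames} /
#' \code{.colnames} files, omitting missing entries. GMT is the standard
#' tab-separated gene-set format (set name, description, members).
#'
#' @param x matrix or SummarizedExperiment to write.
#' @param path file path.
#' @param assayName which assay to write for a SummarizedExperiment.
#' @name cycleMapIO
NULL

#' @rdname cycleMapIO
#' @export
writeExpressionTSV <- function(x, path, assayName = "exprs") {
  m <- if (is(x, "SummarizedExperiment")) assay(x, assayName) else x
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname cycleMapIO
#' @export
readExpressionTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @rdname cycleMapIO
#' @export
writeExpressionMTX <- function(x, path, assayName = "exprs") {
  m <- if (is(x, "SummarizedExperiment")) assay(x, assayName) else x
  idx <- which(!is.na(m), arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(idx))), con)
  writeLines(sprintf("%d %d %.17g", idx[, 1], idx[, 2], m[idx]), con)
  writeLines(rownames(m), paste0(path, ".rownames"))
  writeLines(colnames(m), paste0(path, ".colnames"))
  invisible(path)
}

#' @rdname cycleMapIO
#' @export
readExpressionMTX <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "%")]
  hdr <- scan(text = lines[1], quiet = TRUE)
  trip <- read.table(text = lines[-1], col.names = c("i", "j", "x"))
  m <- matrix(NA_real_, hdr[1], hdr[2])
  m[cbind(trip$i, trip$j)] <- trip$x
  rownames(m) <- readLines(paste0(path, ".rownames"))
  colnames(m) <- readLines(paste0(path, ".colnames"))
  m
}

#' @rdname cycleMapIO
#' @param sets named list of character vectors (gene sets).
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname cycleMapIO
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}

#' Write a cell ordering as TSV plus JSON sidecar
#'
#' Two-column TSV (rank, cell_id) and a \code{.json} sidecar carrying
#' path length, solver and orientation anchor.
#'
#' @param ordering a \linkS4class{CellOrdering}.
#' @param path TSV path; the sidecar gets \code{.json} appended.
#' @importFrom jsonlite write_json read_json
#' @export
writeOrderingTSV <- function(ordering, path) {
  ord <- cellOrder(ordering)
  write.table(data.frame(rank = seq_along(ord), cell_id = ord), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_json(list(path_length = pathLength(ordering),
                  solver_tag = solverTag(ordering),
                  orientation_anchor = orientationAnchor(ordering)),
             paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOrderingTSV
#' @export
readOrderingTSV <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  meta <- read_json(paste0(path, ".json"))
  new("CellOrdering", order = as.character(df$cell_id[order(df$rank)]),
      pathLength = as.numeric(meta$path_length),
      orientationAnchor = meta$orientation_anchor,
      solverTag = meta$solver_tag)
}

#' Write a distance matrix as TSV with cell-id header row and column
#' @param dist a \linkS4class{CellDistanceMatrix}.
#' @param path file path.
#' @export
writeDistanceTSV <- function(dist, path) {
  d <- distMatrix(dist)
  df <- data.frame(cell_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a perturbation map as TSV plus JSON sidecar
#'
#' The TSV holds the scaled genes x ordered-cells matrix; the sidecar
#' records segment boundaries and constant genes.
#'
#' @param map a \linkS4class{PerturbationMap}.
#' @param path TSV path; sidecar gets \code{.json} appended.
#' @export
writeMapTSV <- function(map, path) {
  writeExpressionTSV(scaledMap(map), path)
  seg <- phaseSegments(map)
  write_json(list(boundaries = if (is.null(seg)) NULL else segmentBoundaries(seg),
                  n_positions = length(positionCells(map)),
                  constant_genes = constantGenes(map)),
             paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname writeMapTSV
#' @export
readMapTSV <- function(path) {
  m <- readExpressionTSV(path)
  meta <- read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mp <- new("PerturbationMap", scaled = m, positionCell = colnames(m),
            segments = NULL,
            constantGenes = as.character(meta$constant_genes))
  if (length(meta$boundaries))
    phaseSegments(mp) <- new("PhaseSegments",
                             boundaries = as.integer(meta$boundaries),
                             nPositions = as.integer(meta$n_positions))
  mp
}

#' Long-format export of map values for circular (radial) plotting
#'
#' One row per gene and ordered position, carrying the position's phase
#' label and the scaled value — the data behind a radial cell-cycle plot
#' where the angle is the cell position and the radius the 0-1 expression
#' level.
#'
#' @param map a \linkS4class{PerturbationMap} with segments assigned.
#' @param genes gene ids to export (all must be present).
#' @return data.frame with columns \code{gene}, \code{position},
#'   \code{cell}, \code{phase}, \code{scaled_value}.
#' @export
exportRadialPlotData <- function(map, genes) {
  m <- scaledMap(map)
  bad <- setdiff(genes, rownames(m))
  if (length(bad)) stop("genes not in map: ", paste(bad, collapse = ", "))
  phases <- as.character(positionPhases(map))
  n <- ncol(m)
  do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g, position = seq_len(n), cell = positionCells(map),
               phase = phases, scaled_value = unname(m[g, ]),
               stringsAsFactors = FALSE)))
}
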