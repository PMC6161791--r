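#' Detection filter: keep genes significantly detected in every cell
#'
#' Retains exactly the genes whose detection p-value is below \code{alpha}
#' in every cell, the standard "present in all samples" filter for
#' bead-array data. Gene order is preserved. If no gene survives, an empty
#' matrix is returned with a warning rather than an error.
#'
#' @param x genes x cells expression matrix, or a SummarizedExperiment with
#'   assays \code{exprs} and \code{detection}.
#' @param detect matched genes x cells detection p-value matrix (matrix
#'   method only; the SummarizedExperiment method takes it from the
#'   \code{detection} assay).
#' @param alpha nominal detection significance level, default 0.01.
#' @return the filtered object, same class as \code{x}.
#' @export
setGeneric("detectionFilter",
           function(x, detect, alpha = 0.01) standardGeneric("detectionFilter"))

#' @rdname detectionFilter
setMethod("detectionFilter", "matrix", function(x, detect, alpha = 0.01) {
  stopifnot(is.matrix(detect), alpha > 0, alpha < 1)
  if (!identical(dim(x), dim(detect)))
    stop("expression and detection matrices have different dimensions")
  if (any(detect < 0 | detect > 1)) stop("detection p-values outside [0, 1]")
  keep <- rowSums(detect < alpha) == ncol(detect)
  if (!any(keep)) warning("no genes pass the detection filter")
  x[keep, , drop = FALSE]
})

#' @rdname detectionFilter
setMethod("detectionFilter", "SummarizedExperiment",
  function(x, detect, alpha = 0.01) {
    if (missing(detect)) {
      if (!"detection" %in% names(assays(x)))
        stop("no 'detection' assay in the SummarizedExperiment")
      detect <- assay(x, "detection")
    }
    stopifnot(alpha > 0, alpha < 1)
    if (!identical(dim(assay(x, "exprs")), dim(detect)))
      stop("expression and detection matrices have different dimensions")
    keep <- rowSums(detect < alpha) == ncol(x)
    if (!any(keep)) warning("no genes pass the detection filter")
    x[keep, ]
  })

#' Log2 transformation followed by quantile normalization
#'
#' Applies log2 (with an optional pseudo-count for zeros) and then forces
#' every cell (column) to share the same empirical distribution: each
#' column's sorted values become the across-cell mean of order statistics,
#' ranks within each cell preserved. Ties receive the mean of the tied
#' reference quantiles. Quantile normalization is delegated to
#' \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param x genes x cells matrix or SummarizedExperiment (assay
#'   \code{exprs}).
#' @param pseudoCount added before log2; 0 disables it, in which case
#'   non-positive values are an error.
#' @param isLog set TRUE when values are already on the log scale (the
#'   SummarizedExperiment method reads \code{metadata(x)$isLogTransformed}).
#' @return normalized object of the same class; values on the log2 scale.
#' @importFrom limma normalizeQuantiles
#' @export
setGeneric("log2QuantileNormalize",
  function(x, pseudoCount = 0, isLog = FALSE)
    standardGeneric("log2QuantileNormalize"))

#' @rdname log2QuantileNormalize
setMethod("log2QuantileNormalize", "matrix",
  function(x, pseudoCount = 0, isLog = FALSE) {
    if (anyNA(x)) stop("missing values: impute before quantile normalization")
    if (!isLog) {
      if (any(x + pseudoCount <= 0))
        stop("non-positive values; set a pseudoCount or pre-transform")
      x <- log2(x + pseudoCount)
    }
    if (ncol(x) == 1L) return(x)
    out <- normalizeQuantiles(x, ties = TRUE)
    dimnames(out) <- dimnames(x)
    out
  })

#' @rdname log2QuantileNormalize
setMethod("log2QuantileNormalize", "SummarizedExperiment",
  function(x, pseudoCount = 0, isLog = FALSE) {
    if (missing(isLog))
      isLog <- isTRUE(metadata(x)$isLogTransformed)
    assay(x, "exprs") <- log2QuantileNormalize(assay(x, "exprs"),
                                               pseudoCount = pseudoCount,
                                               isLog = isLog)
    metadata(x)$isLogTransformed <- TRUE
    x
  })

# Fit the arcsinh variance-stabilizing coefficients from the matrix's own
# mean-sd trend: gene means binned, per-bin sd regressed on mean. Returns
# c(a, b) for asinh(a + b*x); b <= 0 means no trend (identity transform).
.fitVstCoefs <- function(x, nBins = 20) {
  m <- rowMeans(x)
  s <- apply(x, 1, sd)
  ok <- is.finite(m) & is.finite(s)
  m <- m[ok]; s <- s[ok]
  if (length(m) < 4) return(c(a = 0, b = 0))
  bins <- cut(rank(m, ties.method = "first"),
              breaks = min(nBins, max(2, length(m) %/% 2)))
  bm <- tapply(m, bins, mean)
  bs <- tapply(s, bins, mean)
  ok <- is.finite(bm) & is.finite(bs)
  if (sum(ok) < 2) return(c(a = 0, b = 0))
  fit <- stats::lm(bs[ok] ~ bm[ok])
  c(a = unname(stats::coef(fit)[1]), b = unname(stats::coef(fit)[2]))
}

#' Variance-stabilizing transform followed by robust spline normalization
#'
#' Two-step normalization for fine mapping: (1) a variance-stabilizing
#' transform \code{asinh(a + b*x)} whose coefficients are fit from the
#' matrix's own binned mean-sd trend (when the trend is flat or decreasing
#' the transform is the identity; \code{vst = "log2"} selects a plain
#' log2(x + pseudoCount) instead); (2) robust spline normalization, mapping
#' each cell's quantiles onto a reference cell's quantiles with a monotone
#' Hermite spline, so output is monotone in input within each cell. The
#' reference defaults to the pseudo-cell of per-rank means across cells.
#'
#' With fewer genes than spline knots the function falls back to quantile
#' normalization and warns.
#'
#' @param x genes x cells matrix or SummarizedExperiment (assay
#'   \code{exprs}), no missing values, >= 2 cells.
#' @param vst \code{"arcsinh"} (default) or \code{"log2"}.
#' @param reference optional cell id to normalize against instead of the
#'   per-rank mean pseudo-cell.
#' @param nKnots spline knots over quantile probabilities (odd keeps the
#'   median an exact knot), default 21.
#' @param pseudoCount used by the \code{"log2"} mode.
#' @return normalized object of the same class.
#' @importFrom stats splinefun
#' @export
setGeneric("vstRsnNormalize",
  function(x, vst = c("arcsinh", "log2"), reference = NULL, nKnots = 21,
           pseudoCount = 1) standardGeneric("vstRsnNormalize"))

#' @rdname vstRsnNormalize
setMethod("vstRsnNormalize", "matrix",
  function(x, vst = c("arcsinh", "log2"), reference = NULL, nKnots = 21,
           pseudoCount = 1) {
    vst <- match.arg(vst)
    if (ncol(x) < 2L) stop("need at least 2 cells")
    if (anyNA(x)) stop("missing values: impute before normalization")
    if (vst == "arcsinh") {
      co <- .fitVstCoefs(x)
      y <- if (co["b"] > 0) asinh(co["a"] + co["b"] * x) else x
    } else {
      if (any(x + pseudoCount <= 0)) stop("non-positive values under log2 mode")
      y <- log2(x + pseudoCount)
    }
    if (nrow(y) < 4L) {
      warning("fewer genes than spline knots; falling back to quantile normalization")
      return(log2QuantileNormalize(y, isLog = TRUE))
    }
    ref <- if (is.null(reference)) {
      rowMeans(apply(y, 2, sort))
    } else {
      if (!reference %in% colnames(y)) stop("reference cell not found: ", reference)
      sort(y[, reference])
    }
    p <- seq(0, 1, length.out = nKnots)
    out <- y
    for (j in seq_len(ncol(y))) {
      xq <- quantile(y[, j], p, type = 7, names = FALSE)
      yq <- quantile(ref, p, type = 7, names = FALSE)
      keep <- !duplicated(xq)
      if (any(!keep))  # collapse tied knots: mean reference quantile per knot
        yq <- tapply(yq, match(xq, xq[keep]), mean)
      xq <- xq[keep]
      if (length(xq) < 4L) {
        warning("too few distinct quantile knots; falling back to quantile normalization")
        return(log2QuantileNormalize(y, isLog = TRUE))
      }
      f <- splinefun(xq, as.numeric(yq), method = "monoH.FC")
      out[, j] <- f(y[, j])
    }
    out
  })

#' @rdname vstRsnNormalize
setMethod("vstRsnNormalize", "SummarizedExperiment",
  function(x, vst = c("arcsinh", "log2"), reference = NULL, nKnots = 21,
           pseudoCount = 1) {
    assay(x, "exprs") <- vstRsnNormalize(assay(x, "exprs"), vst = vst,
                                         reference = reference,
                                         nKnots = nKnots,
                                         pseudoCount = pseudoCount)
    metadata(x)$isLogTransformed <- TRUE
    x
  })

#' Mask extreme outliers per gene by the k-IQR fence
#'
#' Per gene (row, across cells) values more extreme than \code{kIqr}
#' interquartile ranges away from the first or third quartile are set to
#' missing; everything else is untouched. Quartiles use linear
#' interpolation of order statistics (quantile type 7). A constant row has
#' IQR 0 and nothing masked. The number of masked entries is attached as
#' attribute \code{nMasked} (matrix) or \code{metadata(x)$nMaskedOutliers}.
#'
#' @param x genes x cells matrix or SummarizedExperiment, >= 4 cells.
#' @param kIqr fence multiplier, default 3.
#' @return the object with outliers set to NA.
#' @export
setGeneric("maskOutliers",
           function(x, kIqr = 3) standardGeneric("maskOutliers"))

#' @rdname maskOutliers
setMethod("maskOutliers", "matrix", function(x, kIqr = 3) {
  stopifnot(kIqr > 0)
  if (ncol(x) < 4L) stop("need >= 4 cells per gene for quartile estimation")
  q <- t(apply(x, 1, quantile, probs = c(0.25, 0.75), type = 7, na.rm = TRUE))
  iqr <- q[, 2] - q[, 1]
  lo <- q[, 1] - kIqr * iqr
  hi <- q[, 2] + kIqr * iqr
  bad <- (x < lo | x > hi)  # strict: "more extreme than" the fence
  bad[is.na(bad)] <- FALSE
  x[bad] <- NA
  attr(x, "nMasked") <- sum(bad)
  x
})

#' @rdname maskOutliers
setMethod("maskOutliers", "SummarizedExperiment", function(x, kIqr = 3) {
  m <- maskOutliers(assay(x, "exprs"), kIqr = kIqr)
  n <- attr(m, "nMasked")
  attr(m, "nMasked") <- NULL
  assay(x, "exprs") <- m
  metadata(x)$nMaskedOutliers <- n
  x
})

# Pairwise gene distances tolerating missing entries: root-mean-square
# difference over cells observed in both genes; NaN when no cell is shared.
.rmsGeneDistance <- function(x) {
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  o <- obs * 1
  shared <- o %*% t(o)
  ss <- (x0^2) %*% t(o) + o %*% t(x0^2) - 2 * (x0 %*% t(x0))
  d <- sqrt(pmax(ss, 0) / shared)
  diag(d) <- 0
  d
}

#' Nearest-neighbor averaging imputation of missing entries
#'
#' For each missing entry (g, c): the \code{nNeighbors} genes closest to g
#' (root-mean-square difference over cells observed in both genes, ties by
#' gene order), restricted to genes observed at cell c, are averaged at c.
#' Observed entries are never modified. A gene with no eligible neighbor at
#' c falls back to its own observed mean, with a warning. A gene missing in
#' every cell is an error.
#'
#' @param x genes x cells matrix or SummarizedExperiment with NAs.
#' @param nNeighbors neighbors averaged per missing entry, default 10.
#' @return the completed object; no NAs remain.
#' @export
setGeneric("imputeMissing",
           function(x, nNeighbors = 10) standardGeneric("imputeMissing"))

#' @rdname imputeMissing
setMethod("imputeMissing", "matrix", function(x, nNeighbors = 10) {
  stopifnot(nNeighbors >= 1)
  obs <- !is.na(x)
  gid <- if (is.null(rownames(x))) as.character(seq_len(nrow(x))) else rownames(x)
  allMiss <- gid[rowSums(obs) == 0]
  if (length(allMiss))
    stop("gene(s) missing in every cell: ", paste(allMiss, collapse = ", "))
  if (all(obs)) return(x)
  d <- .rmsGeneDistance(x)
  out <- x
  fellBack <- character(0)
  for (g in which(rowSums(!obs) > 0)) {
    for (c0 in which(!obs[g, ])) {
      elig <- which(obs[, c0])
      elig <- elig[elig != g & is.finite(d[g, elig])]
      if (!length(elig)) {
        out[g, c0] <- mean(x[g, obs[g, ]])
        fellBack <- c(fellBack, gid[g])
        next
      }
      nb <- elig[order(d[g, elig], elig)][seq_len(min(nNeighbors, length(elig)))]
      out[g, c0] <- mean(x[nb, c0])
    }
  }
  if (length(fellBack))
    warning("no eligible neighbor; used own-mean fallback for: ",
            paste(unique(fellBack), collapse = ", "))
  out
})

#' @rdname imputeMissing
setMethod("imputeMissing", "SummarizedExperiment", function(x, nNeighbors = 10) {
  assay(x, "exprs") <- imputeMissing(assay(x, "exprs"), nNeighbors = nNeighbors)
  x
})
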