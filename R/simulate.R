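#' Simulate a single-cell expression matrix spanning one cell cycle
#'
#' Generates a gene x cell log-scale expression matrix with known circular
#' ground truth, emulating a panel of cells captured across one cell cycle
#' (as in a Fucci-staged experiment): each cell sits at a latent position
#' theta on the unit circle, cyclic genes follow a von-Mises-style bump
#' peaking at a gene-specific phase, flat genes are constant, and optional
#' Gaussian noise and dropout are layered on top. A matched detection
#' p-value matrix is simulated alongside: detected values draw p from
#' Uniform(0, 0.005), dropped-out values from Uniform(0.05, 1).
#'
#' Cells are placed at theta_i = i/(nCells+1): evenly spaced through the
#' cycle but leaving a double-width gap across the origin. The origin
#' models the division boundary, where no interphase cell is captured, so
#' the widest gap on the circle marks where an open-path ordering should be
#' cut. An optional jitter perturbs cells within their slots.
#'
#' The cyclic mean for gene g at cell i is
#' \code{baseline + amplitude * exp(kappa * (cos(2*pi*(theta_i - phi_g)) - 1))},
#' a smooth circular single-peak profile whose sharpness is set by kappa.
#'
#' @param nCells number of cells (>= 4); 29 matches the map size the
#'   package's defaults are tuned for.
#' @param nCyclicGenes,nFlatGenes numbers of cycle-regulated and constant
#'   genes.
#' @param phaseFractions three positive fractions (G1, S, G2M) summing to 1
#'   that partition the circle into contiguous phase arcs. Default
#'   (15, 7, 7)/29: fifteen G1 cells, seven S, seven G2/M at 29 cells.
#' @param noiseSd Gaussian noise sd on the log scale (0 = noiseless).
#' @param dropoutRate probability an entry is dropped to the baseline floor.
#' @param kappa concentration (peak sharpness) of cyclic profiles, > 0.
#' @param amplitude peak height above baseline, log2 units, > 0.
#' @param baseline baseline log2 expression floor.
#' @param jitter within-slot positional jitter as a fraction of the cell
#'   spacing, in [0, 0.5); 0 keeps cells exactly evenly spaced.
#' @param seed integer seed; regeneration with identical arguments is
#'   bit-for-bit reproducible.
#'
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assays
#'   \code{exprs} (log-scale values) and \code{detection} (p-values),
#'   per-gene truth in \code{rowData} (cyclic flag, peak phase phi, kappa,
#'   amplitude, baseline, true phase, panel flag) and per-cell truth in
#'   \code{colData} (theta, true phase). \code{metadata} records the seed,
#'   parameters and phase cutpoints.
#'
#' @examples
#' se <- simulateCycleData(nCells = 29, nCyclicGenes = 50, nFlatGenes = 50,
#'                         seed = 1)
#' table(SummarizedExperiment::colData(se)$truePhase)
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @export
simulateCycleData <- function(nCells = 29, nCyclicGenes = 100,
                              nFlatGenes = 100,
                              phaseFractions = c(G1 = 15, S = 7, G2M = 7) / 29,
                              noiseSd = 0, dropoutRate = 0, kappa = 5,
                              amplitude = 3, baseline = 6, jitter = 0,
                              seed = 1) {
  stopifnot(nCells >= 4, nCyclicGenes >= 0, nFlatGenes >= 0,
            nCyclicGenes + nFlatGenes >= 1, kappa > 0, amplitude > 0,
            dropoutRate >= 0, dropoutRate <= 1, jitter >= 0, jitter < 0.5)
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  if (length(phaseFractions) != 3L || any(phaseFractions <= 0))
    stop("phaseFractions must be three positive fractions")
  if (abs(sum(phaseFractions) - 1) > 1e-9)
    stop("phaseFractions must sum to 1 (tolerance 1e-9)")

  set.seed(as.integer(seed))
  i <- seq_len(nCells)
  off <- if (jitter > 0) runif(nCells, -jitter, jitter) else numeric(nCells)
  theta <- (i + off) / (nCells + 1)
  theta <- pmin(pmax(theta, 0), 1 - 1e-12)
  cut1 <- phaseFractions[[1]]
  cut2 <- phaseFractions[[1]] + phaseFractions[[2]]
  cellPhase <- ifelse(theta < cut1, "G1", ifelse(theta < cut2, "S", "G2M"))

  cellIds <- sprintf("cell%02d", i)
  geneIds <- c(if (nCyclicGenes) sprintf("CYC%04d", seq_len(nCyclicGenes)),
               if (nFlatGenes) sprintf("FLAT%04d", seq_len(nFlatGenes)))
  cyclic <- rep(c(TRUE, FALSE), c(nCyclicGenes, nFlatGenes))

  phi <- rep(NA_real_, length(geneIds))
  phi[cyclic] <- runif(nCyclicGenes)
  flatLevel <- rep(NA_real_, length(geneIds))
  flatLevel[!cyclic] <- baseline + runif(nFlatGenes, 0, amplitude)

  mu <- matrix(0, length(geneIds), nCells, dimnames = list(geneIds, cellIds))
  if (nCyclicGenes) {
    ph <- outer(phi[cyclic], theta, function(p, t) cos(2 * pi * (t - p)))
    mu[cyclic, ] <- baseline + amplitude * exp(kappa * (ph - 1))
  }
  if (nFlatGenes) mu[!cyclic, ] <- flatLevel[!cyclic]

  vals <- mu
  if (noiseSd > 0)
    vals <- vals + matrix(rnorm(length(mu), sd = noiseSd), nrow(mu), ncol(mu))

  drop <- matrix(runif(length(mu)) < dropoutRate, nrow(mu), ncol(mu))
  vals[drop] <- baseline
  pv <- matrix(runif(length(mu), 0, 0.005), nrow(mu), ncol(mu),
               dimnames = dimnames(mu))
  pv[drop] <- runif(sum(drop), 0.05, 1)

  genePhase <- rep(NA_character_, length(geneIds))
  genePhase[cyclic] <- ifelse(phi[cyclic] < cut1, "G1",
                              ifelse(phi[cyclic] < cut2, "S", "G2M"))

  SummarizedExperiment(
    assays = list(exprs = vals, detection = pv),
    rowData = DataFrame(cyclic = cyclic, phi = phi, kappa = ifelse(cyclic, kappa, NA_real_),
                        amplitude = ifelse(cyclic, amplitude, NA_real_),
                        baseline = baseline, flatLevel = flatLevel,
                        truePhase = genePhase, inPanel = FALSE,
                        row.names = geneIds),
    colData = DataFrame(theta = theta, truePhase = cellPhase,
                        row.names = cellIds),
    metadata = list(seed = as.integer(seed),
                    phaseFractions = phaseFractions,
                    phaseCutpoints = c(cut1, cut2),
                    isLogTransformed = TRUE,
                    params = list(nCells = nCells,
                                  nCyclicGenes = nCyclicGenes,
                                  nFlatGenes = nFlatGenes, noiseSd = noiseSd,
                                  dropoutRate = dropoutRate, kappa = kappa,
                                  amplitude = amplitude, baseline = baseline,
                                  jitter = jitter)))
}

#' Sample a query gene panel from a synthetic dataset
#'
#' Draws a reproducible panel mixing true cyclers and flat genes, mirroring
#' a prognostic signature whose members may or may not be cycle-regulated
#' (e.g. a 70-gene panel with 38 cyclers).
#'
#' @param se a dataset from \code{\link{simulateCycleData}}.
#' @param nCyclicInPanel,nFlatInPanel how many genes of each class to draw.
#' @param seed integer seed for the draw.
#' @return character vector of panel gene ids (cyclers first).
#' @seealso \code{\link{markPanel}} to set the \code{inPanel} truth flags.
#' @export
makePanel <- function(se, nCyclicInPanel, nFlatInPanel, seed = 1) {
  rd <- rowData(se)
  cyc <- rownames(se)[rd$cyclic]
  flat <- rownames(se)[!rd$cyclic]
  if (nCyclicInPanel > length(cyc))
    stop(sprintf("panel needs %d cyclic genes but only %d available (short by %d)",
                 nCyclicInPanel, length(cyc), nCyclicInPanel - length(cyc)))
  if (nFlatInPanel > length(flat))
    stop(sprintf("panel needs %d flat genes but only %d available (short by %d)",
                 nFlatInPanel, length(flat), nFlatInPanel - length(flat)))
  set.seed(as.integer(seed))
  c(sample(cyc, nCyclicInPanel), sample(flat, nFlatInPanel))
}

#' Record panel membership in a dataset's truth table
#'
#' @param se a dataset from \code{\link{simulateCycleData}}.
#' @param panel character vector of gene ids.
#' @return the dataset with \code{rowData(se)$inPanel} set.
#' @export
markPanel <- function(se, panel) {
  bad <- setdiff(panel, rownames(se))
  if (length(bad))
    stop("panel genes not in dataset: ", paste(bad, collapse = ", "))
  rowData(se)$inPanel <- rownames(se) %in% panel
  se
}
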