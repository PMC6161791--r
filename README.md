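# cycleMap

Cell-cycle mapping of single-cell transcriptomes: order cells along the
cycle with a shortest-Hamiltonian-path solver, build a 0–1 scaled
perturbation map with G1/S/G2-M segments, classify genes into cycle
phases with a Self-Organizing Map anchored by known cycle genes, and
compute a per-phase **cell-cycle index** for arbitrary gene panels.

## The problem and the method

An asynchronous cell population samples every stage of the cell cycle; a
bulk profile averages those stages away. Given expression profiles of
individual cells, cycleMap reconstructs the cycle as a *virtual time
axis*:

1. **Order.** Compute Euclidean distances between cells on a known
   cell-cycle gene set (or the soft-threshold network adjacency
   `d = 1 − ((1 + r)/2)^β`), then solve the shortest Hamiltonian path —
   the open-path variant of the TSP — exactly (Held–Karp, `n ≤ 15`) or by
   nearest-neighbor + 2-opt, and orient the path so G1 markers precede S
   precede G2/M.
2. **Map.** Reorder cells, min–max scale each gene to [0, 1]
   (0 = undetectable, 1 = maximum expression), and split positions into
   contiguous G1 / S / G2M segments by exhaustive vote-maximizing
   cutpoint search.
3. **Classify.** Train a Kohonen SOM on the scaled profiles; a gene whose
   best-matching unit neighborhood contains known cycle genes is called
   cyclic, with its phase read from the segment of its (circularly
   smoothed) peak.
4. **Index.** Summarize a query panel as per-phase counts and the cyclic
   fraction — how much of the panel reads out cell-cycle activity.

A normalization stack for bead-array-style input (detection-p filter,
log2 + quantile normalization, arcsinh VST + robust spline normalization,
3-IQR outlier masking, nearest-neighbor imputation) and a synthetic
generator with known circular ground truth (`simulateCycleData()`) are
included; every stage is validated against that truth. See the vignette
`vignettes/cell-cycle-mapping.Rmd` for the model, parameter meanings and
design notes.

## Worked example

Simulate a 29-cell map (15 G1, 7 S, 7 G2/M cells) with 100 cyclic and 100
flat genes, hide 38 cyclers inside a 70-gene query panel, and ask how
much of the panel is cycle-regulated:

```r
library(cycleMap)
library(SummarizedExperiment)

se <- simulateCycleData(nCells = 29, nCyclicGenes = 100, nFlatGenes = 100,
                        noiseSd = 0, seed = 1)
rd <- rowData(se)
panel  <- makePanel(se, nCyclicInPanel = 38, nFlatInPanel = 32, seed = 2)
known  <- setdiff(rownames(se)[rd$cyclic], panel)   # known cycle genes
markers <- split(known, rd[known, "truePhase"])[c("G1", "S", "G2M")]

dm  <- cellDistanceMatrix(se, rownames(se)[rd$cyclic])
ord <- orientOrdering(shortestHamiltonianPath(dm, seed = 1), se, markers)
mp  <- buildPerturbationMap(se, ord)
phaseSegments(mp) <- assignPhaseSegments(mp, markers)
som <- trainSOM(mp, seed = 1)
report <- panelIndex(classifyCandidates(som, mp, known), panel)
report
```

Printed output:

```
CellOrdering: 29 cells, path length 95.82 [nn-2opt, G1-S-G2M-markers]
   cell01 -> cell02 -> cell03 -> cell04 -> cell05 -> cell06 -> ...
PhaseSegments over 29 positions: G1 #1-#14 | S #15-#22 | G2M #23-#29
PanelIndexReport: 38 of 70 panel genes cyclic (54%)
  G1: 18  S: 11  G2M: 9
```

The solver recovers the true circular cell order (the path is cut at the
division-boundary gap), the marker vote places the phase boundaries
within one position of the simulated (15, 22) truth, and the panel index
recovers exactly the 38 hidden cyclers — 54% of the panel — split across
the three phases. `exportRadialPlotData()` emits the long-format table
behind the circular map plots, and `runPipeline()` runs all stages from a
single seeded config with a hash manifest.

A thin CLI over the same functions lives at `inst/scripts/cyclemap.R`
(subcommands `simulate`, `normalize`, `order`, `map`, `classify`,
`index-panel`, `run-all`).

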