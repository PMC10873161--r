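# commfactor

Infer directed, weighted cell-cell communication networks from a
single-cell gene expression matrix alone — no ligand-receptor database
required for the inference itself.

## Who this is for

Single-cell analysts who want a communication network between individual
cells (not only cell types), or who study systems where curated
ligand-receptor resources are thin, and methodologists who want a
transparent, fully testable implementation of decomposition-based
communication inference with planted-truth simulations built in.

## The model

The expression matrix *A* (*m* genes × *n* cells) is factorized as

    A = R Σ W

* **R** (*m* × *m*) — a gene regulatory network adjacency matrix:
  `R[i, j]` is the regulatory strength of gene *i* on gene *j*. Inferred
  internally by lasso projection + monotone pseudotime + lag-1 regression
  (`inferGRN()`), or supplied by any external tool (`loadUserGRN()`).
* **Σ** (*m* × *n*) — the singular-value matrix of *A* (`computeSigma()`).
* **W** (*n* × *n*) — the cell-cell communication matrix, solved with the
  Moore–Penrose pseudoinverse: `W = pinv(R Σ) A` (`computeW()`; the
  minimum-norm least-squares solution). `W[i, j] ≥ 0` is a signal from
  cell *i* to cell *j*, `W[i, j] < 0` one from *j* to *i*, `|W[i, j]|`
  its strength, `W[i, i]` autoregulation. With more cells than genes,
  `computeWSampled()` averages the solve over random cell subsets.

Downstream, `resolveDirections()` turns the signed *W* into a directed
cell network, `aggregateToTypes()` averages it into a *k* × *k* cell-type
matrix with mean-threshold significance calls, `identifyLRPairs()`
nominates ligand-receptor pairs behind a chosen type-pair communication
(sorted-expression Pearson correlation with Bonferroni control), and
`rocAuc()` / `spatialTruth()` benchmark networks against literature or
spatial ground truth. `makePlantedDataset()` simulates expression data
with planted communication so every claim can be tested against known
truth.

## Worked example

```r
library(commfactor)

sim <- makePlantedDataset(seed = 42, m = 60, n = 72, k = 3,
                          n_comm = 2, noise_sd = 0.3)
plantedTypeComm(sim$truth)
#>   source_type target_type
#> 1          T2          T1
#> 2          T1          T3

grn <- inferGRN(sim$expr)
grn
#> GRNMatrix over 60 genes; 123 directed edges

w <- computeWSampled(sim$expr, grn, seed = 42)   # n = 72 > m = 60
w
#> CommunicationMatrix over 72 cells (signed; 62.2% non-negative entries)

types <- aggregateToTypes(resolveDirections(w), sim$labels)
types
#> TypeCommMatrix over 3 cell types
#>   mean-threshold 0.02082; 5 of 9 ordered pairs significant

topKEdges(types, 3)
#>   source target   strength
#> 7     T1     T3 0.02519210
#> 4     T1     T2 0.02468172
#> 6     T3     T2 0.02415600
```

The strongest edge, T1 → T3, is one of the two planted communications;
the aggregated strengths are means of per-cell-pair evidence, and the
mean-threshold rule flags every ordered pair whose strength strictly
exceeds the average of all nine entries. Sender attribution in this
factorization is weaker than receiver attribution (see the methods
vignette's limitations section), which is why the annotation layer below
is checked independently.

```r
lr <- plantedLRPairs(sim$truth)
db <- makeLRDatabase(data.frame(ligand = lr$ligand, receptor = lr$receptor))
identifyLRPairs(sim$expr, sim$labels, db,
                lr$source_type[1], lr$target_type[1])[,
  c("ligand", "receptor", "r", "p_adj", "significant")]
#>   ligand receptor         r        p_adj significant
#> 1   g001     g002 0.9730992 1.624392e-15        TRUE
```

The planted ligand-receptor pair is recovered with a sorted-profile
correlation of 0.97 and a Bonferroni-adjusted p-value far below the 0.01
significance level.

See `vignettes/commfactor-methods.Rmd` for the model's assumptions,
every tunable parameter with its default and rationale, and the method's
known limitations.

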