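---
title: "Inferring cell-cell communication by matrix factorization: model, choices, limits"
author: "commfactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-cell communication by matrix factorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commfactor)
```

## The model

A single-cell expression matrix $A$ ($m$ genes $\times$ $n$ cells) mixes two
layers of regulation: genes regulate genes within a cell, and cells influence
cells within a tissue. `commfactor` separates the two by factorizing

$$A = R\,\Sigma\,W,$$

where

* $R$ ($m \times m$) is a gene regulatory network (GRN) adjacency matrix,
  $R_{ij}$ the strength with which gene $i$ regulates gene $j$;
* $\Sigma$ ($m \times n$) is the singular-value matrix of $A$ (from
  $A = U \Sigma V^\top$), a gene-by-cell "hub" that carries the joint
  spectral structure of the data;
* $W$ ($n \times n$) is the unknown cell-cell communication matrix.

Because $R\Sigma$ is rectangular and generally rank-deficient, $W$ is solved
with the Moore–Penrose pseudoinverse,

$$W = (R\Sigma)^{+} A,$$

which is the unique minimum-Frobenius-norm least-squares solution of
$(R\Sigma)W \approx A$. Entries of $W$ are signed: $W_{ij} \ge 0$ is read as a
signal sent from cell $i$ to cell $j$, $W_{ij} < 0$ as a signal from $j$ to
$i$, $|W_{ij}|$ as its strength, and $W_{ii}$ as autoregulation of cell $i$.
No ligand-receptor prior enters the inference; L-R annotation is a separate,
downstream validation step.

## Stages and the parameters that matter

### GRN inference (`inferGRN`)

Any external GRN can be supplied through `loadUserGRN()`; the built-in
inference scores every ordered gene pair $(u, v)$ in three steps:

1. **Projection** (`lassoProject`): an L1-penalized regression of $u$ on all
   other genes gives a denoised per-cell profile of $u$. The `penalty` is
   glmnet's $\lambda$ on standardized predictors (default: per-gene 3-fold
   cross-validation over the grid 0.01–1).
2. **Monotone pseudotime** (`monotoneOrder`): cells are sorted ascending
   (stable ties by cell index), giving a linear, monotone series along which
   temporal language ("lag") is meaningful.
3. **Lag-1 regression** (`laggedRegressionEdge`): fit
   $v_t = \alpha v_{t-1} + \beta u_{t-1} + c$ over the ordered cells; the
   edge strength is $|t(\beta)|$, kept when its two-sided p-value clears
   `edge_alpha` (default 0.01). For each unordered pair only the stronger
   direction survives (ties resolved toward the earlier gene, so the result
   is deterministic).

**Ordering key.** The pseudotime can be keyed on the lasso projection of the
regulator (`pseudotime = "projected"`) or on its raw expression
(`pseudotime = "raw"`, the default). The projected key has a failure mode we
consider disqualifying as a default: when one gene $v$ dominates the
projection of $u$ (the common case for a genuinely co-regulated pair), the
cells get ordered by $v$ itself, the autoregressive $v_{t-1}$ term then
absorbs the entire association, and precisely the strongest true pairs are
scored near zero. The raw key avoids this and detects planted regulator–
target pairs reliably; both keys are exposed.

`max_genes` (default 2000) caps the $O(m^2)$ pair loop by variance ranking.

### Decomposition (`computeSigma`, `computeW`, `computeWSampled`)

$\Sigma$ is held as singular values plus shape; $R\Sigma$ is formed by
scaling the first $\min(m,n)$ columns of $R$, which is numerically identical
to the dense product without the $m \times n$ temporary. The pseudoinverse
truncates singular values of $R\Sigma$ below
`rcond` $\times \sigma_{max}$, with `rcond` defaulting to
$\max(m,n)\cdot\varepsilon$ — the standard cutoff. $A$ is not centered
before the SVD. When $\mathrm{rank}(R\Sigma) < n$ the cell side of the
system is underdetermined; the solve proceeds (minimum-norm) and a warning
reports the rank.

With more cells than genes the deficiency is structural, and
`computeWSampled` averages over random cell subsets: each round draws
`batch_size` cells (default $m$), solves the decomposition on the column
subset, and each $W_{ij}$ is finally the mean over rounds containing both
cells. The round count defaults to an expected pair coverage of 3 and is
extended until every pair is covered at least once, so the estimate is
well-defined everywhere and reproducible under `seed`. The estimator is
self-consistent: type-level networks from independent sampling seeds agree
(median Spearman $\approx 0.9$ in the test suite's planted datasets).

### Directed networks and type aggregation (`resolveDirections`, `aggregateToTypes`)

Both $W_{ij} > 0$ and $W_{ji} < 0$ encode an $i \to j$ signal under the sign
rule, so the default combination is additive,
$D_{ij} = \max(W_{ij}, 0) + \max(-W_{ji}, 0)$, which preserves total
evidence ($D_{ij} + D_{ji} = |W_{ij}| + |W_{ji}|$); `combine = "mean"`
halves it. Autocrine loops $D_{ii} = \max(W_{ii}, 0)$ are kept because the
diagonal is interpreted as self-regulation.

Type-level strength is the **mean** of $D$ over ordered cell pairs (not the
sum), so types of different sizes are comparable; within-type aggregation
includes the self-loops. Significance uses the mean-threshold rule: a pair
is significant iff its strength strictly exceeds the mean of all $k^2$
entries — ties at the mean are not significant, and a constant matrix has no
significant pairs.

### Ligand-receptor identification (`identifyLRPairs`)

For an ordered type pair (source $\to$ target): intersect expression genes
with database genes; drop genes "expressed" (nonzero fraction $\ge$
`expressed_frac`, default 0.3) in strictly more than half the types
(no type specificity); drop ligand genes with more than 70% zeros in the
source type and receptor genes likewise in the target type; collapse
multi-subunit complexes by the per-cell minimum (the limiting subunit);
sort the ligand profile of the source cells and the receptor profile of the
target cells each in descending order, truncate to the shorter length, and
compute Pearson's correlation with its exact t-transform p-value; finally
Bonferroni-correct within the family of pairs tested **for this ordered
type pair** and flag adjusted $p <$ `alpha` (default 0.01). The 0.3
expressed-fraction default mirrors the 70%-zero rule from the opposite
side; both are configurable. Database records with subunits absent from the
matrix are skipped with a warning; duplicates are tested once.

Note the sorted-profile correlation compares expression *rank patterns*
across the two populations — it does not match individual sender cells to
receiver cells.

### Evaluation (`binarizeMean`, `rocAuc`, `spatialTruth`, `lrGlobalCorrelation`)

ROC curves sweep the continuous type-level strengths over all distinct
values (a single binarization cannot produce a curve); the trapezoidal AUC
is cross-checked internally against the Mann–Whitney rank-sum form with
midranks and the two must agree to $10^{-9}$. The mean-threshold
binarization is reported alongside as the single-point confusion rule.
Spatial ground truth declares two spots neighbors when their distance is at
most `neighbor_factor` (default 1.5) times the median nearest-neighbor
distance — a declared stand-in for platform-specific adjacency, and
configurable. `lrGlobalCorrelation` correlates type-level strengths with a
database-wide ligand-mean $\times$ receptor-mean coexpression score.

## The synthetic generator

`makePlantedDataset` emulates the features this method consumes: cell types
with type-specific markers, a sender type expressing a ligand-like gene, a
receiver type expressing a five-gene response module driven by the ligand's
latent activity (coupling coefficient 1.0 before noise), multiplicative
lognormal noise, and 90% dropout on background entries (realistic sparsity
for non-marker genes). Cross-type coupling is planted through matched latent
ranks, so the descending-sorted sender and receiver profiles are identical
before noise — exactly the statistic the L-R test measures. It does **not**
emulate counts, batch effects, doublets, or droplet chemistry; passing tests
therefore speak to the method's behavior under its own assumptions, not to
robustness against those artifacts.

`makeLaggedPair` generates the elementary regulatory signal (an AR(1)
driver $x$ and $y_t = \beta x_{t-1} + \epsilon$) for the lagged-regression
stage; `embedLaggedPair` pads it with independent noise genes.

Test problem sizes are desk-scale by choice: $m = 100$, $n = 120$, $k = 3$
with two planted pairs for end-to-end experiments, 50 noise genes for GRN
experiments, 10–20 seeds per experiment.

## Known limitations

These are properties of the factorization itself; the package's tests
measure all three on planted data rather than hiding them.

* **Sender attribution is positional.** The rows of
  $W = (R\Sigma)^{+}A$ correspond to columns of $R\Sigma$, and column $j$
  of $\Sigma$ associates with gene $j$, not cell $j$ — only the shapes
  identify the two index sets. Receiver-side structure in $W$'s columns is
  genuine (the test suite shows column mass localizing the cells that
  express the planted regulator), but which *cell* a row's signal is
  attributed to rides on the gene/cell index identification. On simulations
  whose gene order carries no information about cell identity, ordered
  (sender $\to$ receiver) type-pair recovery is at chance level, and the
  acceptance suite reports exactly that.
* **Direction of a linear-Gaussian regulatory pair is unidentifiable from
  unordered cells.** Once cells are exchangeable, a pair with
  $y = \beta x_{lag} +$ Gaussian noise presents as a bivariate Gaussian
  sample, which is symmetric in $x \leftrightarrow y$; no value-sorting
  pseudotime can recover the true lag. The lag-1 machinery detects the
  *association* reliably (the planted pair attains the top strength), but
  which direction survives resolution is a coin flip. Direction claims are
  meaningful only when coupling is nonlinear, noise is non-Gaussian, or a
  real trajectory orders the cells.
* **Gene subsampling shifts the index identification**, so type-level
  networks computed on gene subsets correlate only moderately with the
  full-gene network. This is the same root cause as the first point and is
  measured, not assumed, by the stability experiment.

Practical consequences: treat type-pair calls as *undirected association
plus receiver localization*; prefer a user-supplied GRN when one is
available; and read the L-R identification — which operates on expression
directly and recovers planted pairs essentially always in our experiments —
as the most robust layer of the stack.
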