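# Ligand-receptor identification: given an inferred communication from
# one cell type to another, nominate the L-R pairs behind it. The
# procedure intersects the expressed genes with the L-R database,
# removes universally expressed genes, removes genes silent in the
# relevant type, collapses subunit complexes by their minimum, and tests
# each surviving pair by Pearson correlation of the descending-sorted
# sender-ligand and receiver-receptor profiles with Bonferroni control.

#' Collapse a subunit complex to per-cell values
#'
#' Multi-subunit ligand or receptor complexes are summarized by the
#' minimum expression across subunits in each cell (the limiting
#' subunit); single genes pass through unchanged.
#'
#' @param expr genes x cells expression matrix (or SummarizedExperiment).
#' @param subunits non-empty character vector of gene identifiers, all
#'   present in `expr`.
#' @return named numeric vector, one value per cell.
#' @export
collapseComplex <- function(expr, subunits) {
  expr <- as_expr_matrix(expr)
  if (!length(subunits)) stop("empty subunit list")
  missing <- setdiff(subunits, rownames(expr))
  if (length(missing))
    stop("subunit(s) absent from expression: ",
         paste(missing, collapse = ", "))
  sub <- expr[subunits, , drop = FALSE]
  setNames(apply(sub, 2L, min), colnames(expr))
}

#' Remove universally expressed genes
#'
#' A gene counts as expressed in a cell type when its nonzero fraction
#' among that type's cells is at least `expressed_frac`; a gene expressed
#' in strictly more than half of the types is considered universal (no
#' cell-type specificity) and removed.
#'
#' @param expr genes x cells expression matrix.
#' @param labels named factor of cell-type labels.
#' @param genes candidate gene set (subset of rownames of `expr`).
#' @param expressed_frac nonzero-fraction defining "expressed in a type"
#'   (default 0.3).
#' @return the surviving gene subset, in input order.
#' @export
specificityFilter <- function(expr, labels, genes, expressed_frac = 0.3) {
  expr <- as_expr_matrix(expr)
  lab <- labels[colnames(expr)]
  lv <- levels(droplevels(lab))
  if (length(lv) < 2L) stop("need at least 2 cell types")
  genes <- intersect(genes, rownames(expr))
  n_types <- vapply(genes, function(g) {
    sum(vapply(lv, function(t) {
      cells <- which(lab == t)
      mean(expr[g, cells] > 0) >= expressed_frac
    }, TRUE))
  }, 1L)
  genes[n_types <= length(lv) / 2]
}

#' Remove genes silent within one cell type
#'
#' A gene survives for a given type iff its zero-expression fraction
#' among that type's cells is at most 0.70 (genes with zeros in more
#' than 70% of the type's cells are removed).
#'
#' @param expr genes x cells expression matrix.
#' @param labels named factor of cell-type labels.
#' @param type the type label to screen against.
#' @param genes candidate gene set.
#' @param zero_frac maximum tolerated zero fraction (default 0.70).
#' @return the surviving gene subset, in input order.
#' @export
zeroFractionFilter <- function(expr, labels, type, genes,
                               zero_frac = 0.70) {
  expr <- as_expr_matrix(expr)
  lab <- labels[colnames(expr)]
  cells <- which(lab == type)
  if (!length(cells)) stop("type has no cells: ", type)
  genes <- intersect(genes, rownames(expr))
  keep <- vapply(genes, function(g)
    mean(expr[g, cells] == 0) <= zero_frac, TRUE)
  genes[keep]
}

#' Correlation of sorted ligand and receptor profiles
#'
#' Both value vectors are sorted in descending order (ties stable by
#' original cell index) and truncated to the shorter length; the Pearson
#' correlation and its two-sided p-value (t-transform with
#' `min(m1, m2) - 2` degrees of freedom) are returned. If either
#' truncated vector is constant the correlation is undefined and
#' `(r = 0, p = 1)` is returned with `degenerate = TRUE`.
#'
#' @param ligand_vals per-cell ligand values in the sender type.
#' @param receptor_vals per-cell receptor values in the receiver type.
#' @return list with `r`, `p`, `n` (length used), `degenerate`.
#' @export
sortedPearsonTest <- function(ligand_vals, receptor_vals) {
  n <- min(length(ligand_vals), length(receptor_vals))
  if (n < 3L) stop("need at least 3 cells on each side")
  l <- ligand_vals[order(ligand_vals, decreasing = TRUE)][seq_len(n)]
  r <- receptor_vals[order(receptor_vals, decreasing = TRUE)][seq_len(n)]
  if (sd(l) == 0 || sd(r) == 0)
    return(list(r = 0, p = 1, n = n, degenerate = TRUE))
  ct <- cor.test(l, r, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * M)` with M the number of L-R pairs tested for the
#' ordered type pair at hand.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param m family size; defaults to `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroniAdjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = FALSE) ||
      any(!is.finite(p_values)))
    stop("p-values must lie in [0, 1]")
  pmin(1, p_values * m)
}

#' Identify ligand-receptor pairs behind a type-level communication
#'
#' Full pipeline for one ordered type pair (source -> target): intersect
#' the expression genes with the database genes, apply the specificity
#' filter ([specificityFilter()]), screen ligand genes against the
#' source type and receptor genes against the target type with the
#' 70%-zero rule ([zeroFractionFilter()]), collapse complexes
#' ([collapseComplex()]), test every surviving pair with
#' [sortedPearsonTest()], and Bonferroni-adjust over the pairs tested.
#' Pairs with adjusted p below `alpha` are flagged significant. Database
#' records with subunits absent from the expression matrix are skipped
#' with a warning; duplicate records are tested once.
#'
#' @param expr genes x cells expression matrix (or SummarizedExperiment).
#' @param labels named factor of cell-type labels.
#' @param lrdb an `LRDatabase` (see [readLRDatabase()], [makeLRDatabase()]).
#' @param source_type,target_type ordered type pair (>= 3 cells each).
#' @param alpha significance level on the adjusted p-value (default 0.01).
#' @param expressed_frac passed to [specificityFilter()].
#' @param zero_frac passed to [zeroFractionFilter()].
#' @return data.frame with one row per tested pair (ligand, receptor,
#'   m1, m2, r, p, p_adj, significant, degenerate), sorted by ascending
#'   adjusted p. Zero rows when no pair survives the filters.
#' @export
identifyLRPairs <- function(expr, labels, lrdb, source_type, target_type,
                            alpha = 0.01, expressed_frac = 0.3,
                            zero_frac = 0.70) {
  expr <- as_expr_matrix(expr)
  lab <- labels[colnames(expr)]
  src_cells <- which(lab == source_type)
  tgt_cells <- which(lab == target_type)
  if (length(src_cells) < 3L || length(tgt_cells) < 3L)
    stop("both types need at least 3 cells")

  empty <- data.frame(ligand = character(0), receptor = character(0),
                      m1 = integer(0), m2 = integer(0), r = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), degenerate = logical(0),
                      stringsAsFactors = FALSE)

  # G3 = expression genes  ∩  database genes; then specificity -> G4
  g1 <- rownames(expr)
  g2 <- unique(unlist(c(lrdb$ligand_subunits, lrdb$receptor_subunits)))
  g3 <- intersect(g1, g2)
  if (!length(g3)) return(empty)
  g4 <- specificityFilter(expr, labels, g3, expressed_frac)
  lig_ok <- zeroFractionFilter(expr, labels, source_type, g4, zero_frac)
  rec_ok <- zeroFractionFilter(expr, labels, target_type, g4, zero_frac)

  key <- paste(lrdb$ligand, lrdb$receptor, sep = "|")
  lrdb <- lrdb[!duplicated(key), , drop = FALSE]

  skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(lrdb))) {
    ls <- lrdb$ligand_subunits[[i]]
    rs <- lrdb$receptor_subunits[[i]]
    if (!all(c(ls, rs) %in% g1)) { skipped <- skipped + 1L; next }
    if (!all(ls %in% lig_ok) || !all(rs %in% rec_ok)) next
    lvals <- collapseComplex(expr, ls)[src_cells]
    rvals <- collapseComplex(expr, rs)[tgt_cells]
    tst <- sortedPearsonTest(lvals, rvals)
    rows[[length(rows) + 1L]] <- data.frame(
      ligand = lrdb$ligand[i], receptor = lrdb$receptor[i],
      m1 = length(src_cells), m2 = length(tgt_cells),
      r = tst$r, p = tst$p, p_adj = NA_real_,
      significant = NA, degenerate = tst$degenerate,
      stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(skipped, " database record(s) skipped: subunit(s) absent ",
            "from the expression matrix")
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroniAdjust(out$p, nrow(out))
  out$significant <- out$p_adj < alpha
  out[order(out$p_adj, out$p, out$ligand, out$receptor), , drop = FALSE]
}
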