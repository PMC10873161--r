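# Benchmarking utilities: mean-threshold binarization, ROC/AUC against a
# ground-truth table (with an internal rank-sum cross-check), spatial
# neighbor ground truth from spot coordinates, and the global
# L-R-coexpression correlation diagnostic.

#' Binarize a type-level network at the mean threshold
#'
#' Entry 1 iff the aggregated strength strictly exceeds the mean of all
#' k^2 entries; this is the same rule as the `significant` flags of a
#' [TypeCommMatrix-class].
#'
#' @param t a [TypeCommMatrix-class].
#' @return integer k x k 0/1 matrix.
#' @export
binarizeMean <- function(t) {
  stopifnot(is(t, "TypeCommMatrix"))
  s <- commStrengths(t)
  b <- (s > mean(s)) + 0L
  dimnames(b) <- dimnames(s)
  b
}

# Flatten a score input (TypeCommMatrix, matrix, or data.frame) to a
# data.frame (source, target, score).
as_score_frame <- function(scores) {
  if (is(scores, "TypeCommMatrix")) scores <- commStrengths(scores)
  if (is.matrix(scores)) {
    idx <- expand.grid(source = rownames(scores), target = colnames(scores),
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    idx$score <- scores[cbind(idx$source, idx$target)]
    return(idx)
  }
  scores <- as.data.frame(scores)
  names(scores)[1:3] <- c("source", "target", "score")
  scores
}

#' ROC curve and AUC of communication scores against ground truth
#'
#' Sweeps the score threshold over all distinct score values to build the
#' ROC curve; the trapezoidal AUC is verified internally against the
#' rank-sum (Mann-Whitney with midranks) formulation, and the two must
#' agree to 1e-9.
#'
#' @param scores a [TypeCommMatrix-class], a scored matrix, or a
#'   data.frame (source, target, score).
#' @param truth data.frame (source_type/source, target_type/target,
#'   supported) covering every scored pair, with at least one positive
#'   and one negative.
#' @return list of class `ROCResult` with `thresholds` (descending),
#'   `tpr`, `fpr` (each starting at 0 and ending at 1) and `auc`.
#' @export
rocAuc <- function(scores, truth) {
  sc <- as_score_frame(scores)
  truth <- as.data.frame(truth)
  names(truth)[1:3] <- c("source", "target", "supported")
  key_s <- paste(sc$source, sc$target, sep = "\r")
  key_t <- paste(truth$source, truth$target, sep = "\r")
  hit <- match(key_s, key_t)
  if (any(is.na(hit)))
    stop("ground truth does not cover every scored pair")
  y <- as.logical(truth$supported[hit])
  x <- sc$score
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: need at least one positive and one negative")
  thr <- sort(unique(x), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(x >= t & y) / n1, 1)
  fpr <- vapply(thr, function(t) sum(x >= t & !y) / n0, 1)
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  if (tpr[length(tpr)] != 1 || fpr[length(fpr)] != 1) {
    tpr <- c(tpr, 1); fpr <- c(fpr, 1)
    thr <- c(thr, -Inf)
  }
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  # rank-sum cross-check (midranks handle ties)
  rk <- rank(x)
  auc_mw <- (sum(rk[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (abs(auc - auc_mw) > 1e-9)
    stop("internal AUC cross-check failed: trapezoid ", auc,
         " vs rank-sum ", auc_mw)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat("ROCResult:", length(x$thresholds), "thresholds, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Spatial neighbor ground truth from spot coordinates
#'
#' Two spots are neighbors when their Euclidean distance is at most
#' `neighbor_factor` times the median nearest-neighbor distance. An
#' ordered type pair (a, b) is marked supported iff some neighboring
#' spot pair carries labels (a, b) in either orientation.
#'
#' @param spots data.frame (spot_id, x, y, type); see [readSpots()].
#' @param neighbor_factor multiple of the median nearest-neighbor
#'   distance defining adjacency (default 1.5).
#' @return ground-truth data.frame (source_type, target_type, supported)
#'   over all ordered label pairs.
#' @export
spatialTruth <- function(spots, neighbor_factor = 1.5) {
  spots <- as.data.frame(spots)
  if (nrow(spots) < 2L) stop("need at least 2 spots")
  lv <- unique(as.character(spots$type))
  if (length(lv) < 2L) stop("need at least 2 distinct labels")
  d <- as.matrix(dist(spots[, c("x", "y")]))
  diag(d) <- Inf
  med_nn <- median(apply(d, 1L, min))
  adj <- d <= neighbor_factor * med_nn
  grid <- expand.grid(source_type = lv, target_type = lv,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lab <- as.character(spots$type)
  supported <- vapply(seq_len(nrow(grid)), function(i) {
    a <- grid$source_type[i]; b <- grid$target_type[i]
    any(adj[lab == a, lab == b, drop = FALSE])
  }, TRUE)
  grid$supported <- supported
  grid
}

#' Correlation between communication strengths and L-R coexpression
#'
#' For every ordered type pair, a coexpression score is the mean over
#' database pairs of (mean ligand expression in the source type) x
#' (mean receptor expression in the target type), complexes collapsed by
#' the subunit minimum; the function returns the Pearson correlation and
#' p-value between the flattened type-level strengths and these scores.
#'
#' @param t a [TypeCommMatrix-class].
#' @param expr genes x cells expression matrix.
#' @param labels named factor of cell-type labels.
#' @param lrdb an `LRDatabase`.
#' @return list with `r`, `p`, `scores` (the per-pair coexpression
#'   scores), `degenerate` (TRUE when either vector is constant, in
#'   which case r = 0, p = 1).
#' @export
lrGlobalCorrelation <- function(t, expr, labels, lrdb) {
  stopifnot(is(t, "TypeCommMatrix"))
  expr <- as_expr_matrix(expr)
  lab <- labels[colnames(expr)]
  lv <- typeLabels(t)
  if (length(lv)^2 < 3L) stop("need at least 3 ordered type pairs")
  usable <- vapply(seq_len(nrow(lrdb)), function(i)
    all(c(lrdb$ligand_subunits[[i]], lrdb$receptor_subunits[[i]]) %in%
          rownames(expr)), TRUE)
  lrdb <- lrdb[usable, , drop = FALSE]
  if (!nrow(lrdb)) stop("no database pair with all subunits in expression")
  lvals <- lapply(lrdb$ligand_subunits, collapseComplex, expr = expr)
  rvals <- lapply(lrdb$receptor_subunits, collapseComplex, expr = expr)
  type_mean <- function(vals, type) mean(vals[lab == type])
  s <- commStrengths(t)
  scores <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in lv) for (b in lv) {
    scores[a, b] <- mean(vapply(seq_len(nrow(lrdb)), function(i)
      type_mean(lvals[[i]], a) * type_mean(rvals[[i]], b), 1))
  }
  xs <- as.vector(s); ys <- as.vector(scores)
  if (sd(xs) == 0 || sd(ys) == 0)
    return(list(r = 0, p = 1, scores = scores, degenerate = TRUE))
  ct <- cor.test(xs, ys, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, scores = scores,
       degenerate = FALSE)
}
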