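# From the signed cell-cell matrix W to directed networks: sign
# resolution at the cell level, aggregation to cell-type level with the
# mean-threshold significance rule, top-k summaries and cross-condition
# comparison.

#' Resolve the signed W into a directed cell network
#'
#' Under the sign rule, W[i, j] >= 0 is an i -> j signal and W[j, i] < 0
#' is also an i -> j signal; the final communication between two cells is
#' determined jointly by both entries. The default additive combination
#' is `D[i, j] = max(W[i, j], 0) + max(-W[j, i], 0)` for i != j;
#' `combine = "mean"` halves it. Diagonal (autocrine) strengths are
#' `D[i, i] = max(W[i, i], 0)`.
#'
#' @param w a [CommunicationMatrix-class] (or bare square matrix with
#'   cell dimnames).
#' @param combine `"add"` (default) or `"mean"`.
#' @return a [CellCommNetwork-class].
#' @export
resolveDirections <- function(w, combine = c("add", "mean")) {
  combine <- match.arg(combine)
  wm <- if (is(w, "CommunicationMatrix")) wValues(w) else as.matrix(w)
  d <- pmax(wm, 0) + pmax(-t(wm), 0)
  if (combine == "mean") d <- d / 2
  diag(d) <- pmax(diag(wm), 0)
  new("CellCommNetwork", strengths = d)
}

#' Edge list of a directed cell network
#'
#' @param net a [CellCommNetwork-class].
#' @return data.frame (source, target, strength) of the edges with
#'   positive strength, in descending strength order (ties by source
#'   then target).
#' @export
networkEdges <- function(net) {
  stopifnot(is(net, "CellCommNetwork"))
  d <- commStrengths(net)
  idx <- which(d > 0, arr.ind = TRUE)
  out <- data.frame(source = rownames(d)[idx[, 1L]],
                    target = colnames(d)[idx[, 2L]],
                    strength = d[idx], stringsAsFactors = FALSE)
  out[order(-out$strength, out$source, out$target), , drop = FALSE]
}

#' Aggregate a cell network to the cell-type level
#'
#' The strength of the ordered type pair (a, b) is the mean of D[i, j]
#' over all ordered cell pairs with i in a and j in b (for a = b this
#' includes the autocrine i = j terms). The significance threshold is the
#' mean of all k^2 aggregated strengths; a pair is significant when its
#' strength strictly exceeds the threshold.
#'
#' @param net a [CellCommNetwork-class].
#' @param labels named factor of cell-type labels covering every cell
#'   (see [makeLabels()]).
#' @return a [TypeCommMatrix-class].
#' @export
aggregateToTypes <- function(net, labels) {
  stopifnot(is(net, "CellCommNetwork"))
  d <- commStrengths(net)
  cells <- rownames(d)
  if (!all(cells %in% names(labels)))
    stop("unlabeled cells in the network")
  lab <- labels[cells]
  lv <- levels(droplevels(lab))
  if (any(table(factor(lab, levels = lv)) == 0L))
    stop("empty cell type")
  k <- length(lv)
  s <- matrix(0, k, k, dimnames = list(lv, lv))
  idx <- split(seq_along(cells), factor(lab, levels = lv))
  for (a in lv) for (b in lv)
    s[a, b] <- mean(d[idx[[a]], idx[[b]], drop = FALSE])
  thr <- mean(s)
  new("TypeCommMatrix", strengths = s, threshold = thr,
      significant = s > thr)
}

#' Strongest type-level communications
#'
#' @param t a [TypeCommMatrix-class].
#' @param k number of edges to keep (>= 1).
#' @return data.frame (source, target, strength) of the k ordered type
#'   pairs with the largest strength, zero-strength pairs excluded, ties
#'   broken by source then target label.
#' @export
topKEdges <- function(t, k) {
  stopifnot(is(t, "TypeCommMatrix"), k >= 1)
  s <- commStrengths(t)
  idx <- which(s > 0, arr.ind = TRUE)
  out <- data.frame(source = rownames(s)[idx[, 1L]],
                    target = colnames(s)[idx[, 2L]],
                    strength = s[idx], stringsAsFactors = FALSE)
  out <- out[order(-out$strength, out$source, out$target), , drop = FALSE]
  head(out, k)
}

#' Compare significant communications across two conditions
#'
#' Classifies every ordered type pair by its significance flags in two
#' type-level networks over the same label set (order may differ).
#'
#' @param t1,t2 [TypeCommMatrix-class] objects with identical label sets.
#' @return data.frame (source, target, category) with category one of
#'   `both`, `condition1_only`, `condition2_only`, `neither`.
#' @export
compareConditions <- function(t1, t2) {
  stopifnot(is(t1, "TypeCommMatrix"), is(t2, "TypeCommMatrix"))
  lv <- typeLabels(t1)
  if (!setequal(lv, typeLabels(t2)))
    stop("type label sets differ between the two conditions")
  s1 <- isSignificant(t1)
  s2 <- isSignificant(t2)[lv, lv]
  grid <- expand.grid(source = lv, target = lv,
                      stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  cat_of <- function(a, b) {
    if (s1[a, b] && s2[a, b]) "both"
    else if (s1[a, b]) "condition1_only"
    else if (s2[a, b]) "condition2_only"
    else "neither"
  }
  grid$category <- factor(
    mapply(cat_of, grid$source, grid$target),
    levels = c("both", "condition1_only", "condition2_only", "neither"))
  grid
}
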