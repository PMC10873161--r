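# Gene regulatory network inference: the left factor R of A = R Sigma W.
# The built-in inference follows the projection-plus-lagged-regression
# scheme: each candidate regulator is denoised by an L1-penalized
# projection onto the remaining genes, cells are reordered along the
# resulting monotone pseudotime, and a lag-1 regression scores the
# directed effect on every candidate target. Any externally inferred GRN
# can replace this step via loadUserGRN().

#' L1-penalized projection of one gene onto the others
#'
#' Returns the lasso-predicted (denoised) per-cell expression of `gene`
#' from all other genes, the first stage of the built-in GRN inference.
#' With `penalty = 0` this is the least-squares projection; with a large
#' enough penalty every coefficient is zeroed and the gene's mean is
#' returned for every cell.
#'
#' @param expr genes x cells expression matrix (or SummarizedExperiment).
#' @param gene gene identifier to project.
#' @param penalty non-negative lasso penalty (glmnet's lambda, objective
#'   `1/(2n) * RSS + penalty * ||beta||_1` on standardized predictors).
#' @return numeric vector of projected values, one per cell, named.
#' @export
lassoProject <- function(expr, gene, penalty) {
  expr <- as_expr_matrix(expr)
  if (!gene %in% rownames(expr)) stop("unknown gene: ", gene)
  if (nrow(expr) < 2L) stop("need at least 2 genes to project")
  if (penalty < 0) stop("penalty must be non-negative")
  y <- expr[gene, ]
  x <- t(expr[setdiff(rownames(expr), gene), , drop = FALSE])
  proj <- if (ncol(x) == 1L) {
    lasso_univariate(x[, 1L], y, penalty)
  } else {
    fit <- glmnet::glmnet(x, y, alpha = 1, lambda = penalty,
                          standardize = TRUE, thresh = 1e-12,
                          maxit = 1e6)
    drop(predict(fit, newx = x, s = penalty))
  }
  setNames(as.numeric(proj), colnames(expr))
}

# Closed-form univariate lasso on the standardized predictor (population
# sd, matching glmnet's internal standardization).
lasso_univariate <- function(x, y, penalty) {
  n <- length(y)
  xc <- x - mean(x)
  sx <- sqrt(mean(xc^2))
  if (sx == 0) return(rep(mean(y), n))
  z <- xc / sx
  rho <- mean(z * (y - mean(y)))
  b <- sign(rho) * max(abs(rho) - penalty, 0)
  mean(y) + b * z
}

#' Order cells along a monotone pseudotime
#'
#' Sorts cells by their projected values ascending, ties broken stably by
#' original cell index, yielding the linear, monotone pseudotime series
#' that the lagged regression runs along.
#'
#' @param projected numeric per-cell values (e.g. from [lassoProject()]).
#' @return list with `order` (integer permutation of cell indices) and
#'   `values` (the projected values in that order, non-decreasing).
#' @export
monotoneOrder <- function(projected) {
  if (length(projected) < 3L) stop("need at least 3 cells")
  ord <- order(projected)                # radix sort: stable on ties
  list(order = ord, values = unname(projected[ord]))
}

#' Score a directed edge by lag-1 regression
#'
#' Fits `v[t] = alpha * v[t-1] + beta * u[t-1] + intercept` by least
#' squares over t = 2..n and reports the absolute t-statistic of beta as
#' the directed regulatory strength of u on v, with its two-sided
#' p-value. Degenerate designs (constant lagged u, or constant v) return
#' strength 0 and p = 1.
#'
#' @param u_series regulator values in pseudotime order.
#' @param v_series target values in the same cell order.
#' @return named numeric vector `c(strength = , p = )`.
#' @export
laggedRegressionEdge <- function(u_series, v_series) {
  n <- length(u_series)
  if (length(v_series) != n) stop("series must have equal length")
  if (n < 10L) stop("series too short (need >= 10)")
  y <- v_series[2:n]
  vlag <- v_series[1:(n - 1L)]
  ulag <- u_series[1:(n - 1L)]
  if (sd(y) == 0 || sd(ulag) == 0)
    return(c(strength = 0, p = 1))
  drop_vlag <- sd(vlag) == 0
  X <- if (drop_vlag) cbind(1, ulag) else cbind(1, vlag, ulag)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(c(strength = 0, p = 1))   # collinear design
  beta <- backsolve(R, backsolve(R, crossprod(X, y), transpose = TRUE))
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  if (df < 1L) return(c(strength = 0, p = 1))
  s2 <- sum(resid^2) / df
  XtXinv <- chol2inv(R)
  j <- ncol(X)                                      # ulag coefficient
  se <- sqrt(s2 * XtXinv[j, j])
  if (!is.finite(se) || se == 0) {
    # perfect fit: infinite evidence unless beta itself is zero
    if (abs(beta[j]) < 1e-12) return(c(strength = 0, p = 1))
    return(c(strength = Inf, p = 0))
  }
  tstat <- beta[j] / se
  c(strength = abs(tstat),
    p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

# Pick one lasso penalty per regulator by 3-fold cross-validation over a
# small grid (deterministic interleaved folds).
cv_penalty <- function(x, y, grid = c(0.01, 0.03, 0.1, 0.3, 1)) {
  foldid <- rep_len(1:3, length(y))
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, lambda = rev(sort(grid)),
                          foldid = foldid, standardize = TRUE)
  cv$lambda.min
}

#' Infer a gene regulatory network from expression
#'
#' For every ordered gene pair (u, v): project u onto the other genes
#' with the lasso ([lassoProject()]), reorder cells along u's monotone
#' pseudotime ([monotoneOrder()]), and score the directed effect with a
#' lag-1 regression ([laggedRegressionEdge()]); the edge weight is the
#' absolute t-statistic when its p-value clears `edge_alpha`, else 0.
#' Between the two directions of each gene pair only the stronger is
#' kept. When `m > max_genes`, inference is restricted to the
#' `max_genes` most variable genes.
#'
#' @param expr genes x cells expression matrix (or SummarizedExperiment).
#' @param penalty lasso penalty; `NULL` selects one per regulator by
#'   3-fold cross-validation over a small grid.
#' @param edge_alpha p-value threshold below which an edge weight is
#'   retained (default 0.01).
#' @param max_genes cap on the number of genes entering the O(m^2) pair
#'   loop (default 2000, by variance ranking).
#' @param pseudotime ordering key for the monotone pseudotime of each
#'   regulator: `"raw"` (default) sorts cells by the regulator's own
#'   expression; `"projected"` sorts by its lasso projection onto the
#'   other genes. The projected key degenerates when a single strong
#'   correlate dominates the projection (the ordering then follows that
#'   correlate and the autoregressive term absorbs the association), so
#'   the raw key is the default; see the methods vignette.
#' @return a [GRNMatrix-class] over the (possibly restricted) gene set.
#' @export
inferGRN <- function(expr, penalty = NULL, edge_alpha = 0.01,
                     max_genes = 2000L,
                     pseudotime = c("raw", "projected")) {
  pseudotime <- match.arg(pseudotime)
  expr <- as_expr_matrix(expr)
  m <- nrow(expr)
  if (m < 2L) stop("need at least 2 genes")
  if (m > max_genes) {
    vars <- apply(expr, 1L, var)
    keep <- order(vars, decreasing = TRUE)[seq_len(max_genes)]
    expr <- expr[sort(keep), , drop = FALSE]
    m <- nrow(expr)
  }
  genes <- rownames(expr)
  strength <- pmat <- matrix(0, m, m, dimnames = list(genes, genes))
  pmat[] <- 1
  for (ui in seq_len(m)) {
    u <- genes[ui]
    if (pseudotime == "projected") {
      pen_u <- penalty
      if (is.null(pen_u)) {
        x <- t(expr[-ui, , drop = FALSE])
        pen_u <- if (ncol(x) >= 2L) cv_penalty(x, expr[ui, ]) else 0.1
      }
      key <- lassoProject(expr, u, pen_u)
    } else {
      key <- expr[ui, ]
    }
    mo <- monotoneOrder(key)
    u_series <- expr[ui, mo$order]   # raw regulator values along pseudotime
    for (vi in seq_len(m)) {
      if (vi == ui) next
      res <- laggedRegressionEdge(u_series, expr[vi, mo$order])
      strength[ui, vi] <- res[["strength"]]
      pmat[ui, vi] <- res[["p"]]
    }
  }
  r <- ifelse(pmat < edge_alpha, strength, 0)
  # direction resolution: keep the stronger of (u,v) and (v,u)
  lower <- which(lower.tri(r), arr.ind = TRUE)
  for (e in seq_len(nrow(lower))) {
    i <- lower[e, 1L]; j <- lower[e, 2L]
    if (r[i, j] == 0 && r[j, i] == 0) next
    if (r[i, j] > r[j, i]) r[j, i] <- 0
    else if (r[j, i] > r[i, j]) r[i, j] <- 0
    else r[max(i, j), min(i, j)] <- 0    # tie: keep the earlier-gene row
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  new("GRNMatrix", weights = r)
}

#' Load a user-supplied gene regulatory network
#'
#' Accepts either a dense square matrix file (header + rowname table) or
#' a 3-column edge list (regulator, target, weight), over any subset of
#' the expression genes. The result is aligned to the expression gene
#' order; genes absent from the GRN get zero rows and columns, with a
#' warning listing them. Genes in the GRN but absent from the expression
#' matrix are an error.
#'
#' @param path GRN file path (TSV/CSV).
#' @param expr the paired expression matrix (or SummarizedExperiment).
#' @return a [GRNMatrix-class] aligned to the expression gene order.
#' @export
loadUserGRN <- function(path, expr) {
  expr <- as_expr_matrix(expr)
  genes <- rownames(expr)
  sep <- detect_delim(path)
  tab <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  r <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  is_edge_list <- ncol(tab) == 3L && is.character(tab[[2L]]) &&
    is.numeric(tab[[3L]])
  if (is_edge_list) {
    # edge list: regulator, target, weight
    names(tab) <- c("source", "target", "strength")
    covered <- union(tab$source, tab$target)
    unknown <- setdiff(covered, genes)
    if (length(unknown))
      stop("GRN gene(s) not present in expression: ",
           paste(head(unknown, 5L), collapse = ", "))
    r[cbind(tab$source, tab$target)] <- tab$strength
  } else {
    # dense: first column gene ids, header gene ids
    ids <- as.character(tab[[1L]])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(mat) <- ids
    covered <- ids
    unknown <- setdiff(union(ids, colnames(mat)), genes)
    if (length(unknown))
      stop("GRN gene(s) not present in expression: ",
           paste(head(unknown, 5L), collapse = ", "))
    if (!identical(sort(ids), sort(colnames(mat))))
      stop("dense GRN must be square over one gene set")
    r[ids, colnames(mat)] <- mat
  }
  absent <- setdiff(genes, covered)
  if (length(absent))
    warning(length(absent), " expression gene(s) absent from the GRN get ",
            "zero rows/columns: ", paste(head(absent, 5L), collapse = ", "))
  diag(r) <- 0
  new("GRNMatrix", weights = r)
}
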