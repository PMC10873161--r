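# The algebraic core: A = R Sigma W. Sigma comes from the SVD of A; the
# cell-cell communication matrix W is the minimum-norm least-squares
# solution W = pinv(R Sigma) A, computed through an explicit SVD-based
# pseudoinverse with an rcond cutoff. When there are more cells than
# genes the factorization is rank-deficient on the cell side; a
# cell-sampling scheme averages W over random cell subsets.

#' Compute the singular spectrum of an expression matrix
#'
#' Singular value decomposition A = U diag(d) t(V); the middle factor
#' Sigma of the A = R Sigma W model is the m x n diagonal matrix of
#' singular values.
#'
#' @param expr genes x cells expression matrix (or SummarizedExperiment).
#' @return a [SingularSpectrum-class].
#' @export
computeSigma <- function(expr) {
  expr <- as_expr_matrix(expr)
  s <- svd(expr)
  new("SingularSpectrum", d = s$d, u = s$u, v = s$v,
      dim = dim(expr))
}

# pinv(M) %*% B via SVD with relative cutoff rcond * sigma_max.
pinv_solve <- function(M, B, rcond) {
  s <- svd(M)
  tol <- rcond * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(M), ncol(B)))
  dinv <- 1 / s$d[keep]
  s$v[, keep, drop = FALSE] %*%
    (dinv * (t(s$u[, keep, drop = FALSE]) %*% B))
}

default_rcond <- function(m, n) max(m, n) * .Machine$double.eps

# R Sigma without materializing Sigma: scale R's first min(m, n) columns
# by the singular values, remaining columns (n > m case) are zero.
r_sigma <- function(r, sigma) {
  m <- sigma@dim[1L]; n <- sigma@dim[2L]
  k <- min(m, n)
  rs <- matrix(0, m, n)
  rs[, seq_len(k)] <- sweep(r[, seq_len(k), drop = FALSE], 2L,
                            sigma@d, "*")
  rs
}

#' Solve the cell-cell communication matrix W
#'
#' Solves `W = pinv(R Sigma) A`: the minimum-Frobenius-norm least-squares
#' solution of `(R Sigma) W ~ A`, where R is the GRN adjacency matrix and
#' Sigma the singular-value matrix of A. Singular values of `R Sigma`
#' below `rcond * sigma_max` are treated as zero. When rank(R Sigma) < n
#' the cell side of the factorization cannot be fully determined and a
#' warning reports the deficiency.
#'
#' @param expr genes x cells expression matrix (or SummarizedExperiment).
#' @param grn a [GRNMatrix-class] in the same gene order.
#' @param sigma optional precomputed [SingularSpectrum-class] of `expr`.
#' @param rcond relative rank-truncation tolerance; default
#'   `max(m, n) * .Machine$double.eps`.
#' @return a [CommunicationMatrix-class] (n x n, signed).
#' @export
computeW <- function(expr, grn, sigma = NULL, rcond = NULL) {
  expr <- as_expr_matrix(expr)
  stopifnot(is(grn, "GRNMatrix"))
  if (!identical(geneIds(grn), rownames(expr)))
    stop("GRN gene order must match the expression gene order")
  if (is.null(sigma)) sigma <- computeSigma(expr)
  if (!identical(sigma@dim, dim(expr)))
    stop("sigma was not computed from this expression matrix")
  if (is.null(rcond)) rcond <- default_rcond(nrow(expr), ncol(expr))
  if (all(grnWeights(grn) == 0))
    stop("R Sigma is identically zero: no communication inferable ",
         "from an empty regulatory network")
  rs <- r_sigma(grnWeights(grn), sigma)
  n <- ncol(expr)
  w <- pinv_solve(rs, expr, rcond)
  sv <- svd(rs, nu = 0, nv = 0)$d
  rk <- sum(sv > rcond * max(sv, 0))
  if (rk < n)
    warning("rank(R Sigma) = ", rk, " < ", n, " cells: the communication ",
            "matrix is determined only up to this rank")
  dimnames(w) <- list(colnames(expr), colnames(expr))
  new("CommunicationMatrix", w = w)
}

#' Reconstruct the expression matrix from its three factors
#'
#' Returns `R Sigma W`. When W came from [computeW()] this is the
#' orthogonal projection of A onto the column space of `R Sigma`.
#'
#' @param grn a [GRNMatrix-class].
#' @param sigma a [SingularSpectrum-class].
#' @param w a [CommunicationMatrix-class].
#' @return numeric m x n matrix.
#' @export
reconstructExpression <- function(grn, sigma, w) {
  stopifnot(is(grn, "GRNMatrix"), is(sigma, "SingularSpectrum"),
            is(w, "CommunicationMatrix"))
  r <- grnWeights(grn)
  if (nrow(r) != sigma@dim[1L] || ncol(wValues(w)) != sigma@dim[2L])
    stop("non-conformable factor shapes")
  out <- r_sigma(r, sigma) %*% wValues(w)
  dimnames(out) <- list(geneIds(grn), cellIds(w))
  out
}

#' Mean squared reconstruction error
#'
#' Mean over all m*n entries of the squared difference between the
#' original expression matrix and its reconstruction.
#'
#' @param expr genes x cells expression matrix.
#' @param recon reconstruction of the same shape.
#' @return non-negative scalar.
#' @export
reconstructionMSE <- function(expr, recon) {
  expr <- as.matrix(expr); recon <- as.matrix(recon)
  if (!identical(dim(expr), dim(recon)))
    stop("expression and reconstruction shapes differ")
  mean((expr - recon)^2)
}

#' Solve W by cell sampling when cells outnumber genes
#'
#' With n > m the factorization is rank-deficient on the cell side. This
#' routine repeatedly samples a random cell subset of size `batch_size`
#' (<= m), solves the decomposition on the column subset, and averages
#' each W entry over the rounds in which both of its cells were drawn.
#' Rounds are extended until every ordered cell pair has been covered at
#' least once. With n <= m it delegates to [computeW()] unchanged.
#'
#' @param expr genes x cells expression matrix (or SummarizedExperiment).
#' @param grn a [GRNMatrix-class] in the same gene order.
#' @param batch_size cells per round (2 <= batch_size <= m); default
#'   `min(m, n)`.
#' @param n_rounds minimum number of rounds; default gives every cell
#'   pair an expected coverage of at least 3.
#' @param seed integer seed for the subset draws.
#' @param rcond passed to [computeW()].
#' @return a [CommunicationMatrix-class].
#' @export
computeWSampled <- function(expr, grn, batch_size = NULL, n_rounds = NULL,
                            seed = 1L, rcond = NULL) {
  expr <- as_expr_matrix(expr)
  m <- nrow(expr); n <- ncol(expr)
  if (n <= m) return(computeW(expr, grn, rcond = rcond))
  if (is.null(batch_size)) batch_size <- m
  if (batch_size > m) stop("batch_size must not exceed the gene count")
  if (batch_size < 2L) stop("batch_size must be at least 2")
  if (is.null(n_rounds))
    n_rounds <- ceiling(3 / (batch_size / n)^2)
  acc <- cnt <- matrix(0, n, n)
  withr::with_seed(as.integer(seed), {
    done <- 0L
    repeat {
      done <- done + 1L
      cells <- sort(sample(n, batch_size))
      sub <- expr[, cells, drop = FALSE]
      wsub <- suppressWarnings(
        wValues(computeW(sub, grn, rcond = rcond)))
      acc[cells, cells] <- acc[cells, cells] + wsub
      cnt[cells, cells] <- cnt[cells, cells] + 1
      if (done >= n_rounds && all(cnt > 0)) break
      if (done > n_rounds + 50L * n)
        stop("cell-pair coverage not reached; increase batch_size")
    }
  })
  w <- acc / pmax(cnt, 1)
  dimnames(w) <- list(colnames(expr), colnames(expr))
  new("CommunicationMatrix", w = w)
}
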