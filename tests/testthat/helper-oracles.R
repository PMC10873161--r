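# Independent oracles used to freeze expected values. Each deliberately
# avoids the code path it checks: the lasso oracle is plain coordinate
# descent, the lagged-regression oracle is the closed-form normal
# equations, the AUC oracle counts concordant pairs exhaustively, and
# the singular-value oracle goes through the symmetric eigenproblem.

# Coordinate-descent lasso matching glmnet's objective
# (1/(2n)) * RSS + lambda * ||b||_1 on predictors standardized with the
# population (1/n) variance. Returns fitted values.
oracle_lasso_fit <- function(X, y, lambda, tol = 1e-10, maxit = 1e5) {
  mx <- colMeans(X)
  sx <- sqrt(colMeans(sweep(X, 2, mx)^2))
  ok <- sx > 0
  Z <- sweep(sweep(X[, ok, drop = FALSE], 2, mx[ok]), 2, sx[ok], "/")
  my <- mean(y)
  b <- rep(0, ncol(Z))
  r <- y - my
  for (it in seq_len(maxit)) {
    delta <- 0
    for (j in seq_len(ncol(Z))) {
      bj <- b[j]
      rho <- mean(Z[, j] * r) + bj          # mean(Z_j^2) = 1
      bn <- sign(rho) * max(abs(rho) - lambda, 0)
      if (bn != bj) {
        r <- r - (bn - bj) * Z[, j]
        delta <- max(delta, abs(bn - bj))
      }
      b[j] <- bn
    }
    if (delta < tol) break
  }
  drop(my + Z %*% b)
}

# Closed-form least squares for v[t] ~ 1 + v[t-1] + u[t-1]; returns the
# coefficient on u[t-1].
oracle_lagged_beta <- function(u, v) {
  n <- length(u)
  X <- cbind(1, v[1:(n - 1)], u[1:(n - 1)])
  y <- v[2:n]
  beta <- solve(crossprod(X), crossprod(X, y))
  beta[3]
}

# Exhaustive concordant-pair AUC with the 1/2 tie convention.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Singular values via the symmetric eigenproblem of t(A) %*% A.
oracle_singular_values <- function(A) {
  ev <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}
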