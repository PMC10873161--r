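# Shared fixtures. Everything is generated in code at test time; the
# expensive planted-data recovery experiment is memoised so the
# property tests and the acceptance tests share one computation.

rand_expr <- function(seed, m, n) {
  withr::with_seed(seed, {
    e <- matrix(abs(rnorm(m * n)), m, n,
                dimnames = list(sprintf("g%02d", seq_len(m)),
                                sprintf("c%02d", seq_len(n))))
  })
  e
}

rand_grn <- function(seed, genes) {
  m <- length(genes)
  withr::with_seed(seed, {
    r <- matrix(rnorm(m * m), m, m, dimnames = list(genes, genes))
  })
  diag(r) <- 0
  new("GRNMatrix", weights = r)
}

# Orthogonal completion of the left singular vectors of A, signs fixed
# so the leading columns equal U exactly.
completed_u_grn <- function(A) {
  s <- svd(A)
  q <- qr.Q(qr(s$u), complete = TRUE)
  sgn <- sign(diag(qr.R(qr(s$u))))
  k <- ncol(s$u)
  q[, seq_len(k)] <- sweep(q[, seq_len(k), drop = FALSE], 2, sgn, "*")
  dimnames(q) <- list(rownames(A), rownames(A))
  new("GRNMatrix", weights = q)
}

# Planted-data pipeline: GRN inference, sampled decomposition, direction
# resolution, type aggregation. Returns the TypeCommMatrix plus truth.
planted_type_network <- function(seed, m = 100L, n = 120L, k = 3L,
                                 n_comm = 2L, noise_sd = 0.3) {
  sim <- makePlantedDataset(seed = seed, m = m, n = n, k = k,
                            n_comm = n_comm, noise_sd = noise_sd)
  grn <- inferGRN(sim$expr)
  w <- if (ncol(sim$expr) > nrow(sim$expr))
    computeWSampled(sim$expr, grn, seed = seed)
  else suppressWarnings(computeW(sim$expr, grn))
  types <- aggregateToTypes(resolveDirections(w), sim$labels)
  list(types = types, truth = sim$truth, labels = sim$labels,
       expr = sim$expr, grn = grn, w = w)
}

# Memoised 20-seed end-to-end recovery experiment (shared between the
# module-level property tests and the end-to-end recovery checks).
.recovery_cache <- new.env(parent = emptyenv())
recovery_experiment <- function(seeds = 1:20) {
  key <- paste0("s", paste(range(seeds), collapse = "_"))
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  runs <- lapply(seeds, function(s) {
    run <- planted_type_network(s)
    sig <- isSignificant(run$types)
    strengths <- commStrengths(run$types)
    tc <- plantedTypeComm(run$truth)
    planted <- matrix(FALSE, nrow(sig), ncol(sig), dimnames = dimnames(sig))
    planted[cbind(tc$source_type, tc$target_type)] <- TRUE
    list(sig = sig, strengths = strengths, planted = planted,
         truth = run$truth)
  })
  .recovery_cache[[key]] <- runs
  runs
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
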