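test_that("lasso projection matches its closed forms and the oracle", {
  # gene that is an exact linear combination of two others: zero penalty
  # reproduces it exactly
  withr::with_seed(21, {
    g2 <- abs(rnorm(40)); g3 <- abs(rnorm(40))
  })
  e <- rbind(g1 = 2 * g2 + 3 * g3, g2 = g2, g3 = g3)
  colnames(e) <- sprintf("c%02d", 1:40)
  proj <- lassoProject(e, "g1", penalty = 0)
  expect_lt(max(abs(proj - e["g1", ])), 1e-6)

  # penalty large enough to zero every coefficient: constant at the mean
  proj_inf <- lassoProject(e, "g1", penalty = 1e6)
  expect_equal(unname(proj_inf), rep(mean(e["g1", ]), 40), tolerance = 1e-8)

  # random matrix against the independent coordinate-descent oracle
  em <- rand_expr(5, 20, 50)
  p_pkg <- lassoProject(em, "g01", penalty = 0.1)
  p_ora <- oracle_lasso_fit(t(em[-1, , drop = FALSE]), em["g01", ], 0.1)
  expect_lt(max(abs(p_pkg - p_ora)), 1e-6)

  expect_error(lassoProject(em, "nope", 0.1), "unknown gene")
})

test_that("univariate projection (2-gene case) uses the soft threshold", {
  e <- rand_expr(8, 2, 30)
  # penalty 0 reduces to simple regression fitted values
  proj <- lassoProject(e, "g01", penalty = 0)
  fit <- fitted(lm(e["g01", ] ~ e["g02", ]))
  expect_equal(unname(proj), unname(fit), tolerance = 1e-8)
  # huge penalty gives the mean
  expect_equal(unname(lassoProject(e, "g01", penalty = 100)),
               rep(mean(e["g01", ]), 30))
})

test_that("monotone ordering is ascending and stable on ties", {
  mo <- monotoneOrder(c(3, 1, 2))
  expect_identical(mo$order, c(2L, 3L, 1L))
  expect_identical(mo$values, c(1, 2, 3))

  tied <- monotoneOrder(rep(5, 4))
  expect_identical(tied$order, 1:4)          # stable tie rule

  withr::with_seed(2, v <- sample(rep(1:5, 3)))
  expect_true(!is.unsorted(monotoneOrder(v)$values))
  expect_error(monotoneOrder(c(1, 2)), "at least 3")
})

test_that("lagged regression scores directed dependence", {
  # constant regressor is degenerate
  res <- laggedRegressionEdge(rep(1, 50), rnorm(50))
  expect_identical(unname(res), c(0, 1))
  # constant target too
  res2 <- laggedRegressionEdge(rnorm(50), rep(2, 50))
  expect_identical(unname(res2), c(0, 1))

  # planted coefficient recovered along true time (oracle-checked)
  p <- makeLaggedPair(seed = 7, n = 200, beta = 0.8, lag_noise_sd = 0.1)
  expect_lt(abs(oracle_lagged_beta(p$x, p$y) - 0.8), 0.1)
  res3 <- laggedRegressionEdge(p$x, p$y)
  expect_lt(res3[["p"]], 1e-10)
  # and the reverse direction carries far less evidence in true time
  res4 <- laggedRegressionEdge(p$y, p$x)
  expect_gt(res3[["strength"]], res4[["strength"]])

  # v identically u lagged by one: essentially perfect dependence
  withr::with_seed(4, u <- cumsum(rnorm(60)))
  v <- c(u[1], u[-60])
  res5 <- laggedRegressionEdge(u, v)
  expect_lt(res5[["p"]], 1e-10)

  expect_error(laggedRegressionEdge(1:5, 1:5), "too short")
  expect_error(laggedRegressionEdge(1:20, 1:10), "equal length")
})

test_that("two-gene lag structure yields a single directed edge", {
  # construct g2 = lag-1 of g1 along g1's monotone order
  withr::with_seed(99, {
    n <- 60
    g1 <- sort(abs(rnorm(n, 5, 2)))
    perm <- sample(n)
    noise <- abs(rnorm(n, 0, 0.05))
  })
  g1u <- g1[perm]
  o <- order(g1u)
  g2u <- numeric(n)
  s <- g1u[o]
  g2u[o] <- c(s[1], s[1:(n - 1)]) + noise
  e <- rbind(g1 = g1u, g2 = g2u)
  colnames(e) <- sprintf("c%02d", seq_len(n))
  r <- grnWeights(inferGRN(e))
  expect_identical(which(r != 0), which(matrix(c(FALSE, FALSE, TRUE, FALSE), 2)))
  expect_gt(r["g1", "g2"], 2)
})

test_that("independent noise genes produce an empty network", {
  zero_rate <- mean(vapply(1:20, function(s) {
    e <- rand_expr(s + 300, 10, 60)
    all(grnWeights(inferGRN(e, edge_alpha = 1e-6)) == 0)
  }, TRUE))
  expect_gte(zero_rate, 0.95)
})

test_that("GRN inference is equivariant to gene order and direction-exclusive", {
  sim <- makePlantedDataset(seed = 5, m = 24, n = 45, k = 3,
                            n_comm = 1, noise_sd = 0.3)
  e <- sim$expr
  r1 <- grnWeights(inferGRN(e))
  withr::with_seed(6, perm <- sample(nrow(e)))
  r2 <- grnWeights(inferGRN(e[perm, , drop = FALSE]))
  expect_equal(r2[rownames(r1), colnames(r1)], r1, tolerance = 1e-10)

  # mutual exclusivity and clean diagonal
  expect_true(all(diag(r1) == 0))
  expect_true(all(r1 == 0 | t(r1) == 0))
  expect_true(all(is.finite(r1)))
})

test_that("gene cap restricts inference to the most variable genes", {
  sim <- makePlantedDataset(seed = 8, m = 30, n = 40, k = 2,
                            n_comm = 1, noise_sd = 0.3)
  grn <- inferGRN(sim$expr, max_genes = 10L)
  expect_length(geneIds(grn), 10L)
  vars <- apply(sim$expr, 1, var)
  expect_setequal(geneIds(grn),
                  names(sort(vars, decreasing = TRUE))[1:10])
})

test_that("user GRNs load from edge lists and shuffled dense files", {
  e <- rand_expr(10, 3, 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(source = "g01", target = "g02", weight = 0.5), f)
  suppressWarnings(grn <- loadUserGRN(f, e))
  r <- grnWeights(grn)
  expect_identical(dim(r), c(3L, 3L))
  expect_equal(r["g01", "g02"], 0.5)
  expect_equal(sum(r != 0), 1L)

  write_tsv(data.frame(source = "g01", target = "gX", weight = 1), f)
  expect_error(loadUserGRN(f, e), "not present")

  # dense file in shuffled gene order is realigned
  dm <- matrix(1:9, 3, 3,
               dimnames = list(c("g03", "g01", "g02"),
                               c("g03", "g01", "g02")))
  diag(dm) <- 0
  ft <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(dm), dm, check.names = FALSE),
              ft, sep = "\t", quote = FALSE, row.names = FALSE)
  grn2 <- loadUserGRN(ft, e)
  expect_identical(geneIds(grn2), rownames(e))
  expect_equal(grnWeights(grn2)["g03", "g01"], dm["g03", "g01"])

  # genes missing from the GRN get zero rows/columns with a warning
  write_tsv(data.frame(source = "g01", target = "g02", weight = 2), f)
  expect_warning(grn3 <- loadUserGRN(f, e), "zero rows")
  expect_true(all(grnWeights(grn3)["g03", ] == 0))
})
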