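lr_fixture <- function() {
  # 4 genes x 8 cells, two types of 4 cells, hand-set patterns
  e <- rbind(
    lig  = c(5, 4, 3, 2, 0, 0, 0, 0),   # sender-specific ligand
    rec  = c(0, 0, 0, 0, 4, 3, 2, 1),   # receiver-specific receptor
    univ = c(1, 2, 1, 2, 1, 2, 1, 2),   # expressed everywhere
    rare = c(0, 0, 0, 1, 0, 0, 0, 0))   # nearly silent
  colnames(e) <- paste0("c", 1:8)
  labels <- factor(rep(c("A", "B"), each = 4), levels = c("A", "B"))
  names(labels) <- colnames(e)
  list(expr = e, labels = labels)
}

test_that("complexes collapse to the limiting subunit", {
  fx <- lr_fixture()
  expect_identical(collapseComplex(fx$expr, "lig"), fx$expr["lig", ])
  two <- collapseComplex(fx$expr, c("lig", "univ"))
  expect_equal(unname(two),
               unname(pmin(fx$expr["lig", ], fx$expr["univ", ])))
  expect_equal(unname(two[5]), 0)       # zero subunit zeroes the cell
  expect_error(collapseComplex(fx$expr, character(0)), "empty")
  expect_error(collapseComplex(fx$expr, "absent"), "absent")
})

test_that("specificity filter removes universally expressed genes", {
  # 4 types, gene nonzero in all cells of all types -> removed
  e <- rbind(g_all = rep(1, 8), g_two = c(1, 1, 1, 1, 0, 0, 0, 0),
             g_none = rep(0, 8))
  colnames(e) <- paste0("c", 1:8)
  labels <- factor(rep(c("t1", "t2", "t3", "t4"), each = 2))
  names(labels) <- colnames(e)
  out <- specificityFilter(e, labels, rownames(e))
  expect_false("g_all" %in% out)        # expressed in 4 of 4 types
  expect_true("g_two" %in% out)         # 2 of 4 is not > k/2
  expect_true("g_none" %in% out)        # kept here; zero filter removes later
})

test_that("zero-fraction filter applies the strict 70% boundary", {
  mk <- function(nz) c(rep(1, 10 - nz), rep(0, nz))
  e <- rbind(g80 = mk(8), g70 = mk(7), g0 = mk(0))
  colnames(e) <- paste0("c", 1:10)
  labels <- factor(rep("A", 10)); names(labels) <- colnames(e)
  out <- zeroFractionFilter(e, labels, "A", rownames(e))
  expect_false("g80" %in% out)          # 0.8 > 0.7 removed
  expect_true("g70" %in% out)           # exactly 0.7 kept
  expect_true("g0" %in% out)
})

test_that("sorted Pearson test matches its contract", {
  # affinely related strictly decreasing vectors: r = 1
  a <- c(9, 7, 5, 3, 1); b <- 2 * a + 3
  res <- sortedPearsonTest(a, b)
  expect_equal(res$r, 1)
  expect_false(res$degenerate)

  # truncation to the shorter side
  res2 <- sortedPearsonTest(c(5, 4, 3, 2, 1), c(3, 2, 1))
  expect_identical(res2$n, 3L)

  # constant side is degenerate
  res3 <- sortedPearsonTest(rep(2, 5), 1:5)
  expect_identical(res3[c("r", "p")], list(r = 0, p = 1))
  expect_true(res3$degenerate)

  expect_error(sortedPearsonTest(1:2, 1:2), "at least 3")

  # planted noiseless coupling: perfect correlation, tiny p at n >= 30
  sim <- makePlantedDataset(seed = 2, m = 40, n = 90, k = 3,
                            n_comm = 1, noise_sd = 0)
  lr <- plantedLRPairs(sim$truth)
  send <- sim$expr[lr$ligand[1], sim$labels == lr$source_type[1]]
  recv <- sim$expr[lr$receptor[1], sim$labels == lr$target_type[1]]
  res4 <- sortedPearsonTest(send, recv)
  expect_equal(res4$r, 1, tolerance = 1e-12)
  expect_lt(res4$p, 1e-6)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(0.0005, 10), 0.005)
  expect_equal(bonferroniAdjust(0.5, 10), 1)
  expect_equal(bonferroniAdjust(c(0.2, 0.8), 1), c(0.2, 0.8))
  expect_error(bonferroniAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # agreement with the standard implementation
  p <- c(0.001, 0.02, 0.3)
  expect_equal(bonferroniAdjust(p), p.adjust(p, "bonferroni"))
})

test_that("the L-R pipeline filters, tests and ranks pairs", {
  fx <- lr_fixture()
  db <- makeLRDatabase(data.frame(ligand = c("lig", "rare"),
                                  receptor = c("rec", "rec")))
  out <- identifyLRPairs(fx$expr, fx$labels, db, "A", "B",
                         expressed_frac = 0.5)
  # 'rare' fails the 70%-zero rule in type A, so one pair is tested
  expect_identical(nrow(out), 1L)
  expect_identical(out$ligand, "lig")
  expect_identical(out$m1, 4L)
  expect_identical(out$p_adj, out$p)    # M = 1

  # a ligand failing the source-type zero filter empties the result
  db2 <- makeLRDatabase(data.frame(ligand = "rare", receptor = "rec"))
  expect_identical(nrow(identifyLRPairs(fx$expr, fx$labels, db2, "A", "B",
                                        expressed_frac = 0.5)), 0L)

  # duplicate records are tested once (M counts unique pairs)
  db3 <- makeLRDatabase(data.frame(ligand = c("lig", "lig"),
                                   receptor = c("rec", "rec")))
  out3 <- identifyLRPairs(fx$expr, fx$labels, db3, "A", "B",
                          expressed_frac = 0.5)
  expect_identical(nrow(out3), 1L)
  expect_identical(out3$p_adj, out3$p)

  # records with absent subunits are skipped with a warning
  db4 <- makeLRDatabase(data.frame(ligand = c("lig", "ghost"),
                                   receptor = c("rec", "rec")))
  expect_warning(out4 <- identifyLRPairs(fx$expr, fx$labels, db4, "A", "B",
                                         expressed_frac = 0.5), "skipped")
  expect_identical(nrow(out4), 1L)
})

test_that("swapping source and target swaps the tested populations", {
  sim <- makePlantedDataset(seed = 31, m = 40, n = 40, k = 2,
                            n_comm = 1, noise_sd = 0.2)
  lr <- plantedLRPairs(sim$truth)
  db <- makeLRDatabase(data.frame(ligand = lr$ligand, receptor = lr$receptor))
  fwd <- suppressWarnings(identifyLRPairs(sim$expr, sim$labels, db,
                                          lr$source_type[1], lr$target_type[1]))
  rev <- suppressWarnings(identifyLRPairs(sim$expr, sim$labels, db,
                                          lr$target_type[1], lr$source_type[1]))
  # the ligand is silent in the reversed source type, so the reversed
  # direction tests nothing
  expect_identical(nrow(fwd), 1L)
  expect_identical(nrow(rev), 0L)
})

test_that("planted ligand-receptor pairs are recovered and ranked first", {
  ok <- vapply(1:10, function(s) {
    sim <- makePlantedDataset(seed = s, m = 100, n = 120, k = 3,
                              n_comm = 2, noise_sd = 0.3)
    lr <- plantedLRPairs(sim$truth)
    bg <- setdiff(rownames(sim$expr), unique(c(lr$ligand, lr$receptor)))[1:20]
    db <- makeLRDatabase(data.frame(
      ligand = c(lr$ligand, bg[1:10]),
      receptor = c(lr$receptor, bg[11:20])))
    all(vapply(seq_len(nrow(lr)), function(i) {
      out <- suppressWarnings(identifyLRPairs(
        sim$expr, sim$labels, db, lr$source_type[i], lr$target_type[i]))
      nrow(out) > 0 &&
        out$ligand[1] == lr$ligand[i] && out$receptor[1] == lr$receptor[i] &&
        out$significant[1]
    }, TRUE))
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
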