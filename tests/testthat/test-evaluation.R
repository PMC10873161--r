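mk_type_matrix <- function(vals, labels = NULL) {
  k <- sqrt(length(vals))
  if (is.null(labels)) labels <- paste0("T", seq_len(k))
  s <- matrix(vals, k, k, dimnames = list(labels, labels))
  new("TypeCommMatrix", strengths = s, threshold = mean(s),
      significant = s > mean(s))
}

test_that("mean binarization matches the significance flags", {
  t <- mk_type_matrix(c(1, 2, 3, 4))
  b <- binarizeMean(t)
  expect_identical(unname(b), rbind(c(0L, 1L), c(0L, 1L)))
  expect_identical(b == 1L, unname(isSignificant(t)) | FALSE,
                   ignore_attr = TRUE)

  # worked example: {1,2,3,4,6} plus padding -> mean 3.2, ones at {4,6}
  vals <- c(1, 2, 3, 4, 6, 3.2, 3.2, 3.2, 3.2)
  t2 <- mk_type_matrix(vals)
  expect_identical(sum(binarizeMean(t2)), 2L)
  expect_identical(which(binarizeMean(t2) == 1L), which(vals > mean(vals)))

  # constant matrix: nothing exceeds the mean strictly
  expect_true(all(binarizeMean(mk_type_matrix(rep(2, 4))) == 0L))
})

test_that("ROC/AUC agrees with exhaustive pair counting", {
  truth6 <- data.frame(source = paste0("s", 1:6), target = "t",
                       supported = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  scores6 <- data.frame(source = paste0("s", 1:6), target = "t",
                        score = c(5, 4, 3, 2, 1, 0))
  r <- rocAuc(scores6, truth6)
  expect_equal(r$auc, oracle_auc(scores6$score, truth6$supported))

  # perfect separation
  tr <- data.frame(source = c("a", "b"), target = c("b", "a"),
                   supported = c(TRUE, FALSE))
  sc <- data.frame(source = c("a", "b"), target = c("b", "a"),
                   score = c(0.9, 0.1))
  expect_equal(rocAuc(sc, tr)$auc, 1.0)

  # all scores tied: chance
  sc$score <- c(0.5, 0.5)
  expect_equal(rocAuc(sc, tr)$auc, 0.5)

  # degenerate truth is an error
  tr$supported <- c(TRUE, TRUE)
  expect_error(rocAuc(sc, tr), "positive and one negative")
  expect_error(rocAuc(sc[1, ], tr[2, ]), "cover")
})

test_that("ROC curves are monotone with valid endpoints", {
  withr::with_seed(55, {
    n <- 40
    truth <- data.frame(source = paste0("p", 1:n), target = "q",
                        supported = runif(n) < 0.4)
    truth$supported[1:2] <- c(TRUE, FALSE)
    scores <- data.frame(source = truth$source, target = "q",
                         score = round(runif(n), 2))
  })
  r <- rocAuc(scores, truth)
  expect_true(!is.unsorted(r$tpr))
  expect_true(!is.unsorted(r$fpr))
  expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
  expect_equal(c(r$tpr[length(r$tpr)], r$fpr[length(r$fpr)]), c(1, 1))
  # trapezoid equals the curve integral by construction; cross-check
  # against the exhaustive oracle once more
  expect_equal(r$auc, oracle_auc(scores$score, truth$supported),
               tolerance = 1e-12)
})

test_that("AUC is invariant under monotone transforms and flips on negation", {
  withr::with_seed(56, {
    scores <- data.frame(source = paste0("p", 1:20), target = "q",
                         score = rnorm(20))
    truth <- data.frame(source = paste0("p", 1:20), target = "q",
                        supported = c(rep(TRUE, 8), rep(FALSE, 12)))
  })
  a1 <- rocAuc(scores, truth)$auc
  scores2 <- scores; scores2$score <- exp(scores$score)
  expect_equal(rocAuc(scores2, truth)$auc, a1, tolerance = 1e-12)
  scores3 <- scores; scores3$score <- -scores$score
  expect_equal(rocAuc(scores3, truth)$auc + a1, 1, tolerance = 1e-12)
})

test_that("AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(57, {
    scores <- data.frame(source = paste0("p", 1:30), target = "q",
                         score = sample(seq(0, 1, 0.05), 30, replace = TRUE))
    truth <- data.frame(source = scores$source, target = "q",
                        supported = runif(30) < 0.5)
    truth$supported[1:2] <- c(TRUE, FALSE)
  })
  a <- rocAuc(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth$supported, scores$score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(a, ref, tolerance = 1e-9)
})

test_that("spatial neighbor rule builds the expected ground truth", {
  spots <- data.frame(spot_id = c("s1", "s2"), x = c(0, 1), y = c(0, 0),
                      type = c("a", "b"))
  gt <- spatialTruth(spots)
  expect_true(gt$supported[gt$source_type == "a" & gt$target_type == "b"])
  expect_true(gt$supported[gt$source_type == "b" & gt$target_type == "a"])

  # far-away singleton label is unsupported everywhere
  spots3 <- rbind(spots, data.frame(spot_id = "s3", x = 50, y = 50,
                                    type = "c"))
  gt3 <- spatialTruth(spots3)
  with_c <- gt3[gt3$source_type == "c" | gt3$target_type == "c", ]
  expect_false(any(with_c$supported[with_c$source_type !=
                                      with_c$target_type]))

  # hexagonal 7-spot grid: the interior spot has exactly 6 neighbors
  ang <- (0:5) * pi / 3
  hex <- data.frame(spot_id = paste0("h", 0:6),
                    x = c(0, cos(ang)), y = c(0, sin(ang)),
                    type = c("ctr", rep(c("rim1", "rim2"), 3)))
  d <- as.matrix(dist(hex[, c("x", "y")])); diag(d) <- Inf
  expect_identical(sum(d[1, ] <= 1.5 * median(apply(d, 1, min))), 6L)
  gt_hex <- spatialTruth(hex)
  expect_true(all(gt_hex$supported[gt_hex$source_type == "ctr" &
                                     gt_hex$target_type != "ctr"]))

  expect_error(spatialTruth(spots[1, ]), "at least 2")
  spots$type <- "a"
  expect_error(spatialTruth(spots), "distinct labels")
})

test_that("global L-R coexpression correlation is computed per type pair", {
  fx_expr <- rbind(
    ligA = c(4, 4, 0, 0, 0, 0), recB = c(0, 0, 3, 3, 0, 0),
    ligC = c(0, 0, 0, 0, 2, 2), other = c(1, 1, 1, 1, 1, 1))
  colnames(fx_expr) <- paste0("c", 1:6)
  labels <- factor(rep(c("A", "B", "C"), each = 2))
  names(labels) <- colnames(fx_expr)
  db <- makeLRDatabase(data.frame(ligand = c("ligA", "ligC"),
                                  receptor = c("recB", "recB")))
  # strengths proportional to the coexpression scores give r = 1
  probe <- lrGlobalCorrelation(mk_type_matrix(rep(1, 9), c("A", "B", "C")),
                               fx_expr, labels, db)
  t1 <- mk_type_matrix(as.vector(2 * probe$scores + 0), c("A", "B", "C"))
  res <- lrGlobalCorrelation(t1, fx_expr, labels, db)
  expect_equal(res$r, 1, tolerance = 1e-12)

  # constant strengths are degenerate
  resc <- lrGlobalCorrelation(mk_type_matrix(rep(1, 9), c("A", "B", "C")),
                              fx_expr, labels, db)
  expect_true(resc$degenerate || abs(resc$r) < 1)

  # empty usable database is an error
  db_ghost <- makeLRDatabase(data.frame(ligand = "nope", receptor = "recB"))
  expect_error(lrGlobalCorrelation(t1, fx_expr, labels, db_ghost),
               "no database pair")
})

test_that("communication strengths correlate with planted coexpression", {
  pos <- vapply(1:10, function(s) {
    run <- planted_type_network(s, m = 60, n = 72, k = 3, n_comm = 2,
                                noise_sd = 0.3)
    lr <- plantedLRPairs(run$truth)
    db <- makeLRDatabase(data.frame(ligand = lr$ligand,
                                    receptor = lr$receptor))
    res <- lrGlobalCorrelation(run$types, run$expr, run$labels, db)
    res$r
  }, 1)
  expect_gte(mean(pos > 0), 0.7)
})
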