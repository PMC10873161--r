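# Seeded simulators with planted regulatory and communication structure.
# These define the validation conditions for the whole package: every
# recovery experiment in the test suite runs against datasets produced
# here, with the planted truth recorded alongside.

#' Simulate an expression matrix with planted cell-cell communication
#'
#' Cells are partitioned near-evenly into `k` types. For each planted
#' ordered type pair (a, b), one "ligand-like" gene is highly expressed
#' only in type a, and its per-cell latent activity drives a five-gene
#' response module (the first module gene playing the receptor role)
#' expressed only in type b, with coupling coefficient 1.0 before noise.
#' The coupling is realized through matched latent ranks: the sender cell
#' of rank r and the receiver cell of rank r carry the same latent level,
#' so the sorted sender ligand profile and sorted receiver response
#' profile are identical before noise. Noise is multiplicative lognormal
#' with log-sd `noise_sd` on planted entries; background entries are
#' lognormal draws thinned by dropout (90% zeros), emulating the sparsity
#' of non-marker genes in scRNA-seq data.
#'
#' @param seed integer; the same seed reproduces the dataset bitwise.
#' @param m number of genes (>= 20, and >= 6 per planted pair).
#' @param n number of cells (>= 2k).
#' @param k number of cell types.
#' @param n_comm number of planted ordered type pairs (<= k(k-1)).
#' @param noise_sd non-negative log-sd of the lognormal noise.
#' @return list with elements `expr` (genes x cells matrix), `labels`
#'   (named factor), `truth` (a [PlantedTruth-class]).
#' @examples
#' sim <- makePlantedDataset(seed = 1, m = 40, n = 30, k = 3,
#'                           n_comm = 2, noise_sd = 0.3)
#' dim(sim$expr)
#' plantedTypeComm(sim$truth)
#' @export
makePlantedDataset <- function(seed, m = 100L, n = 120L, k = 3L,
                               n_comm = 2L, noise_sd = 0.3) {
  seed <- as.integer(seed)
  if (m < 20L) stop("m must be at least 20")
  if (n < 2L * k) stop("n must be at least 2k")
  if (k < 1L) stop("k must be at least 1")
  if (n_comm > k * (k - 1L))
    stop("n_comm exceeds the number of ordered type pairs k(k-1)")
  if (6L * n_comm > m)
    stop("m too small: each planted pair reserves 6 genes")
  if (noise_sd < 0) stop("noise_sd must be non-negative")

  genes <- sprintf("g%03d", seq_len(m))
  cells <- sprintf("c%03d", seq_len(n))
  types <- paste0("T", seq_len(k))
  type_of <- factor(rep(types, length.out = n), levels = types)
  names(type_of) <- cells

  withr::with_seed(seed, {
    # background: lognormal around 1 with 90% dropout
    expr <- matrix(rlnorm(m * n, meanlog = 0, sdlog = max(noise_sd, 0)),
                   m, n, dimnames = list(genes, cells))
    expr[matrix(runif(m * n) < 0.90, m, n)] <- 0

    # choose planted ordered type pairs
    all_pairs <- expand.grid(source = seq_len(k), target = seq_len(k))
    all_pairs <- all_pairs[all_pairs$source != all_pairs$target, , drop = FALSE]
    pick <- sample(nrow(all_pairs), n_comm)
    planted <- all_pairs[pick, , drop = FALSE]

    grn_edges <- list(); lr_pairs <- list(); type_comm <- list()
    for (p in seq_len(nrow(planted))) {
      a <- planted$source[p]; b <- planted$target[p]
      idx <- (p - 1L) * 6L
      ligand <- genes[idx + 1L]
      module <- genes[idx + 2:6]
      send <- which(type_of == types[a])
      recv <- which(type_of == types[b])
      nmax <- max(length(send), length(recv))
      # shared decreasing latent levels, rank r -> level lat[r]
      lat <- 2 + 4 * (nmax - seq_len(nmax)) / (nmax - 1)
      send_rank <- sample(length(send))
      recv_rank <- sample(length(recv))
      noisy <- function(v) v * rlnorm(length(v), 0, noise_sd)
      expr[ligand, send] <- noisy(lat[send_rank])
      for (g in module)
        expr[g, recv] <- noisy(lat[recv_rank])   # coupling coefficient 1.0
      grn_edges[[p]] <- data.frame(regulator = ligand, target = module,
                                   stringsAsFactors = FALSE)
      lr_pairs[[p]] <- data.frame(ligand = ligand, receptor = module[1L],
                                  source_type = types[a],
                                  target_type = types[b],
                                  stringsAsFactors = FALSE)
      type_comm[[p]] <- data.frame(source_type = types[a],
                                   target_type = types[b],
                                   stringsAsFactors = FALSE)
    }
  })

  truth <- new("PlantedTruth",
    grnEdges = if (n_comm) do.call(rbind, grn_edges) else
      data.frame(regulator = character(0), target = character(0)),
    typeComm = if (n_comm) do.call(rbind, type_comm) else
      data.frame(source_type = character(0), target_type = character(0)),
    lrPairs = if (n_comm) do.call(rbind, lr_pairs) else
      data.frame(ligand = character(0), receptor = character(0),
                 source_type = character(0), target_type = character(0)),
    seed = seed)
  validateExpression(expr)
  list(expr = expr, labels = type_of, truth = truth)
}

#' Simulate a lagged regulator-target gene pair
#'
#' Generates an AR(1) driver series x and a target series with
#' `y[t] = beta * x[t-1] + noise`, the elementary structure the lagged
#' regression step of GRN inference is designed to detect. Series are on
#' an arbitrary (possibly negative) scale; shift before embedding them in
#' an expression matrix.
#'
#' @param seed integer seed.
#' @param n series length (>= 30).
#' @param beta coupling coefficient; 0 plants no direction.
#' @param lag_noise_sd non-negative sd of the Gaussian innovation noise.
#' @return list with numeric vectors `x`, `y` and `direction`, one of
#'   `"x->y"` or `"none"`.
#' @export
makeLaggedPair <- function(seed, n, beta, lag_noise_sd = 0.1) {
  if (n < 30L) stop("n must be at least 30")
  if (lag_noise_sd < 0) stop("lag_noise_sd must be non-negative")
  withr::with_seed(as.integer(seed), {
    x <- numeric(n)
    x[1L] <- rnorm(1L)
    for (t in 2:n) x[t] <- 0.7 * x[t - 1L] + rnorm(1L, sd = 0.5)
    y <- numeric(n)
    y[1L] <- rnorm(1L, sd = lag_noise_sd)
    y[2:n] <- beta * x[1:(n - 1L)] + rnorm(n - 1L, sd = lag_noise_sd)
  })
  list(x = x, y = y, direction = if (beta == 0) "none" else "x->y")
}

#' Embed a lagged pair among independent noise genes
#'
#' Builds a small expression matrix whose first two genes are the shifted
#' (non-negative) x and y series of [makeLaggedPair()], in true time
#' order, padded with `n_noise` independent lognormal noise genes. Used
#' to probe direction recovery by [inferGRN()].
#'
#' @param seed integer seed (also seeds the noise genes).
#' @param n cells (>= 30).
#' @param beta,lag_noise_sd passed to [makeLaggedPair()].
#' @param n_noise number of noise genes.
#' @return list with `expr`, `regulator`, `target`, `direction`.
#' @export
embedLaggedPair <- function(seed, n = 200L, beta = 0.8,
                            lag_noise_sd = 0.1, n_noise = 50L) {
  pair <- makeLaggedPair(seed, n, beta, lag_noise_sd)
  shift <- function(v) v - min(v) + 0.1
  noise <- withr::with_seed(as.integer(seed) + 10000L,
    matrix(rlnorm(n_noise * n, 0, 0.5), n_noise, n))
  expr <- rbind(shift(pair$x), shift(pair$y), noise)
  rownames(expr) <- c("gx", "gy", sprintf("noise%03d", seq_len(n_noise)))
  colnames(expr) <- sprintf("c%03d", seq_len(n))
  list(expr = expr, regulator = "gx", target = "gy",
       direction = pair$direction)
}

#' Write a planted dataset to disk in the package's exchange formats
#'
#' Writes the expression matrix (dense TSV), the label table, and the
#' planted truth (JSON) into a directory; the companion of the
#' `simulate` command of the command-line interface.
#'
#' @param sim result of [makePlantedDataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writePlantedDataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expr = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.json"))
  writeExpression(sim$expr, paths[["expr"]])
  write.table(data.frame(cell_id = names(sim$labels),
                         type = as.character(sim$labels)),
              paths[["labels"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(seed = truth@seed, grn_edges = truth@grnEdges,
         type_comm = truth@typeComm, lr_pairs = truth@lrPairs),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
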