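# One-call orchestration: expression + labels -> GRN -> Sigma -> W ->
# type-level network (-> optional L-R identification and evaluation),
# with a plain-text key-value config, deterministic seeding, and a run
# manifest. Stage outputs on disk are sufficient to resume downstream
# stages without recomputation.

pipeline_defaults <- function() {
  list(expr = NULL, labels = NULL, outdir = NULL,
       grn.mode = "infer", grn.path = NULL, grn.penalty = NULL,
       grn.edge_alpha = 0.01, grn.max_genes = 2000,
       decomposition.rcond = NULL, decomposition.sampling = "auto",
       network.combine = "add", network.top_k = 10,
       lr.db = NULL, lr.alpha = 0.01, lr.expressed_frac = 0.3,
       lr.zero_frac = 0.70,
       normalize = FALSE, seed = 1, resume = FALSE)
}

#' Read a plain-text key-value pipeline config
#'
#' One `key = value` pair per line, `#` comments allowed; the accepted
#' keys are those of [validatePipelineConfig()]. Unknown keys are an
#' error naming the offender.
#'
#' @param path config file path.
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  cfg <- setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, 1L, FUN.VALUE = ""))
  num_keys <- c("grn.penalty", "grn.edge_alpha", "grn.max_genes",
                "decomposition.rcond", "network.top_k", "lr.alpha",
                "lr.expressed_frac", "lr.zero_frac", "seed")
  for (k in intersect(names(cfg), num_keys))
    cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in intersect(names(cfg), c("normalize", "resume")))
    cfg[[k]] <- as.logical(cfg[[k]])
  validatePipelineConfig(cfg)
}

#' Validate and complete a pipeline config
#'
#' @param config named list of overrides of the defaults (expr, labels
#'   and outdir are required; grn.mode is "infer" or "load").
#' @return the completed config list.
#' @export
validatePipelineConfig <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; known keys: ", paste(names(defaults), collapse = ", "))
  cfg <- defaults
  cfg[names(config)] <- config
  for (k in c("expr", "labels", "outdir"))
    if (is.null(cfg[[k]])) stop("config key '", k, "' is required")
  for (k in c("expr", "labels"))
    if (!file.exists(cfg[[k]])) stop("missing input file: ", cfg[[k]])
  if (!cfg$grn.mode %in% c("infer", "load"))
    stop("grn.mode must be 'infer' or 'load'")
  if (cfg$grn.mode == "load") {
    if (is.null(cfg$grn.path)) stop("grn.mode = load requires grn.path")
    if (!file.exists(cfg$grn.path)) stop("missing GRN file: ", cfg$grn.path)
  }
  if (!cfg$decomposition.sampling %in% c("auto", "on", "off"))
    stop("decomposition.sampling must be 'auto', 'on' or 'off'")
  if (!is.null(cfg$lr.db) && !file.exists(cfg$lr.db))
    stop("missing L-R database file: ", cfg$lr.db)
  cfg
}

log_stage <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[%s] done in %.2fs", stage,
                    as.numeric(Sys.time()) - t0))
}

#' Run the full communication-inference pipeline
#'
#' Stages: read inputs, infer or load the GRN, compute the singular
#' spectrum, solve W (cell-sampled when cells outnumber genes and
#' sampling is "auto" or "on"), resolve directions, aggregate to the
#' type level, and optionally identify L-R pairs for every significant
#' ordered type pair. All stage outputs are written under
#' `config$outdir`; the returned manifest records the paths, the
#' reconstruction MSE, rank(R Sigma), the type count, the significant
#' pair count, the seed, and the package version. Identical config and
#' seed reproduce identical outputs. With `resume = TRUE`, stages whose
#' output files already exist are read back instead of recomputed.
#'
#' @param config config list (see [validatePipelineConfig()]) or path to
#'   a key-value config file (see [readPipelineConfig()]).
#' @param verbose log stage timings to stderr.
#' @return the manifest, invisibly also written to
#'   `outdir/manifest.json`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  cfg <- if (is.character(config)) readPipelineConfig(config)
         else validatePipelineConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(grn = file.path(cfg$outdir, "grn.tsv"),
                w = file.path(cfg$outdir, "w.tsv"),
                types = file.path(cfg$outdir, "type_strengths.tsv"),
                edges = file.path(cfg$outdir, "type_edges.tsv"),
                lr = file.path(cfg$outdir, "lr_results.tsv"),
                manifest = file.path(cfg$outdir, "manifest.json"))

  t0 <- as.numeric(Sys.time())
  expr <- readExpression(cfg$expr, normalize = cfg$normalize)
  labels <- readLabels(cfg$labels, expr)
  log_stage(verbose, "read", t0)

  t0 <- as.numeric(Sys.time())
  if (cfg$resume && file.exists(paths$grn)) {
    grn <- suppressWarnings(loadUserGRN(paths$grn, expr))
  } else if (cfg$grn.mode == "load") {
    grn <- loadUserGRN(cfg$grn.path, expr)
  } else {
    grn <- inferGRN(expr, penalty = cfg$grn.penalty,
                    edge_alpha = cfg$grn.edge_alpha,
                    max_genes = cfg$grn.max_genes)
    if (!identical(geneIds(grn), rownames(expr)))
      expr <- expr[geneIds(grn), , drop = FALSE]   # max_genes restriction
    write_square(grnWeights(grn), "gene", paths$grn)
  }
  log_stage(verbose, "grn", t0)

  t0 <- as.numeric(Sys.time())
  sigma <- computeSigma(expr)
  sampled <- switch(cfg$decomposition.sampling,
                    auto = ncol(expr) > nrow(expr), on = TRUE, off = FALSE)
  if (cfg$resume && file.exists(paths$w)) {
    wtab <- read.delim(paths$w, check.names = FALSE)
    wm <- as.matrix(wtab[, -1L, drop = FALSE])
    rownames(wm) <- as.character(wtab[[1L]])
    w <- new("CommunicationMatrix", w = wm)
  } else {
    w <- if (sampled)
      computeWSampled(expr, grn, seed = cfg$seed,
                      rcond = cfg$decomposition.rcond)
    else suppressWarnings(
      computeW(expr, grn, sigma, rcond = cfg$decomposition.rcond))
    write_square(wValues(w), "cell", paths$w)
  }
  recon <- reconstructExpression(grn, sigma, w)
  mse <- reconstructionMSE(expr, recon)
  sv <- svd(r_sigma(grnWeights(grn), sigma), nu = 0, nv = 0)$d
  rc <- if (is.null(cfg$decomposition.rcond))
    default_rcond(nrow(expr), ncol(expr)) else cfg$decomposition.rcond
  rank_rs <- sum(sv > rc * max(sv))
  log_stage(verbose, "decompose", t0)

  t0 <- as.numeric(Sys.time())
  net <- resolveDirections(w, combine = cfg$network.combine)
  types <- aggregateToTypes(net, labels)
  write_square(commStrengths(types), "type", paths$types)
  writeNetwork(topKEdges(types, cfg$network.top_k), paths$edges)
  log_stage(verbose, "network", t0)

  lr_n <- NA_integer_
  if (!is.null(cfg$lr.db)) {
    t0 <- as.numeric(Sys.time())
    lrdb <- readLRDatabase(cfg$lr.db)
    sig <- which(isSignificant(types), arr.ind = TRUE)
    res <- list()
    for (e in seq_len(nrow(sig))) {
      a <- typeLabels(types)[sig[e, 1L]]
      b <- typeLabels(types)[sig[e, 2L]]
      one <- suppressWarnings(
        identifyLRPairs(expr, labels, lrdb, a, b, alpha = cfg$lr.alpha,
                        expressed_frac = cfg$lr.expressed_frac,
                        zero_frac = cfg$lr.zero_frac))
      if (nrow(one)) {
        one$source_type <- a; one$target_type <- b
        res[[length(res) + 1L]] <- one
      }
    }
    lr_all <- if (length(res)) do.call(rbind, res) else
      data.frame(ligand = character(0))
    write.table(lr_all, paths$lr, sep = "\t", quote = FALSE,
                row.names = FALSE)
    lr_n <- if (length(res)) sum(lr_all$significant) else 0L
    log_stage(verbose, "lr", t0)
  }

  manifest <- list(
    config = cfg[!vapply(cfg, is.null, TRUE)],
    paths = paths[!vapply(paths, is.null, TRUE)],
    n_genes = nrow(expr), n_cells = ncol(expr),
    k_types = nlevels(labels),
    reconstruction_mse = mse,
    rank_r_sigma = rank_rs,
    sampled = sampled,
    n_significant_pairs = sum(isSignificant(types)),
    n_significant_lr = lr_n,
    seed = cfg$seed,
    version = as.character(packageVersion("commfactor")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_square <- function(mat, id_name, path) {
  tab <- data.frame(rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1L] <- id_name
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
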