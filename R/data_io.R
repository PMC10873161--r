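# Readers and writers for the external artifacts: expression matrices
# (dense TSV/CSV or Matrix Market), cell labels, L-R databases, ground
# truth tables, spatial spot tables and network edge lists. All readers
# validate identifiers strictly and preserve file order end-to-end.

# Coerce user input (matrix or SummarizedExperiment) to a validated
# genes x cells expression matrix. Row/column names are mandatory: every
# downstream factor indexes against them.
as_expr_matrix <- function(expr, assay = 1L) {
  if (is(expr, "SummarizedExperiment")) {
    expr <- as.matrix(SummarizedExperiment::assay(expr, assay))
  }
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  validateExpression(expr)
  expr
}

#' Validate a genes x cells expression matrix
#'
#' Checks the contract every downstream step relies on: unique gene and
#' cell identifiers as dimnames, and finite non-negative values.
#'
#' @param expr numeric matrix, genes in rows, cells in columns.
#' @return the matrix, invisibly, if valid; otherwise an error.
#' @export
validateExpression <- function(expr) {
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry gene and cell identifiers as dimnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate cell identifiers in expression matrix")
  if (!is.numeric(expr) || any(!is.finite(expr)))
    stop("expression values must be finite numbers")
  if (any(expr < 0))
    stop("expression values must be non-negative")
  invisible(expr)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix from disk
#'
#' Dense input is a delimited table (tab or comma, auto-detected) with
#' gene identifiers in the first column and cell identifiers in the
#' header. Sparse input is a Matrix Market coordinate file plus gene and
#' barcode sidecar files (one identifier per line, order defining row and
#' column order).
#'
#' @param path path to the dense table or .mtx file.
#' @param format one of "auto", "dense", "mtx". "auto" picks "mtx" for a
#'   `.mtx` extension.
#' @param genes,barcodes sidecar paths for mtx input; default to
#'   `genes.tsv` / `barcodes.tsv` next to the .mtx file.
#' @param normalize if TRUE, apply library-size scaling to 1e4 counts per
#'   cell followed by log1p. Default FALSE: values are used as provided.
#' @return a validated genes x cells numeric matrix.
#' @export
readExpression <- function(path, format = c("auto", "dense", "mtx"),
                           genes = NULL, barcodes = NULL,
                           normalize = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  if (format == "mtx") {
    if (is.null(genes)) genes <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes)) barcodes <- file.path(dirname(path), "barcodes.tsv")
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes)
    cell_ids <- readLines(barcodes)
    # sidecars may be multi-column (id \t symbol); the first field is the id
    gene_ids <- vapply(strsplit(gene_ids, "\t"), `[`, "", 1L)
    cell_ids <- vapply(strsplit(cell_ids, "\t"), `[`, "", 1L)
    if (length(gene_ids) != nrow(m))
      stop("gene sidecar lists ", length(gene_ids), " genes but matrix has ",
           nrow(m), " rows")
    if (length(cell_ids) != ncol(m))
      stop("barcode sidecar lists ", length(cell_ids),
           " cells but matrix has ", ncol(m), " columns")
    dimnames(m) <- list(gene_ids, cell_ids)
  } else {
    sep <- detect_delim(path)
    tab <- read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                      check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m))
      stop("non-numeric expression entries in ", path)
    rownames(m) <- gene_ids
  }
  storage.mode(m) <- "double"
  validateExpression(m)
  if (normalize) {
    libs <- colSums(m)
    if (any(libs == 0)) stop("cannot normalize: cell with zero library size")
    m <- log1p(sweep(m, 2L, libs / 1e4, "/"))
  }
  m
}

#' Write an expression matrix as a dense TSV table
#'
#' Inverse of the dense branch of [readExpression()]: gene identifiers in
#' the first column (`gene`), cell identifiers as the header.
#'
#' @param expr genes x cells matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(expr, path) {
  expr <- as_expr_matrix(expr)
  tab <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cell-type labels and align them to an expression matrix
#'
#' Expects a two-column table (cell identifier, type label) with a
#' header. Every cell of the expression matrix must be labeled; label
#' rows for unknown cells are dropped with a warning. The level order of
#' the returned factor is the first-appearance order in the file.
#'
#' @param path label table path (TSV/CSV, delimiter auto-detected).
#' @param expr the paired expression matrix (or SummarizedExperiment).
#' @return named factor of length ncol(expr), names = cell identifiers in
#'   expression column order.
#' @export
readLabels <- function(path, expr) {
  expr <- as_expr_matrix(expr)
  sep <- detect_delim(path)
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label table needs cell_id and type columns")
  ids <- as.character(tab[[1L]])
  types <- as.character(tab[[2L]])
  makeLabels(setNames(types, ids), expr)
}

#' Build a validated cell-type label factor
#'
#' @param labels named character (or factor) vector mapping cell id to
#'   type label.
#' @param expr the paired expression matrix.
#' @return named factor aligned to the expression column order, levels in
#'   first-appearance order.
#' @export
makeLabels <- function(labels, expr) {
  expr <- as_expr_matrix(expr)
  cells <- colnames(expr)
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by cell identifier")
  extra <- setdiff(ids, cells)
  if (length(extra)) {
    warning("dropping ", length(extra), " label row(s) for cells absent ",
            "from the expression matrix: ",
            paste(head(extra, 5L), collapse = ", "))
    labels <- labels[ids %in% cells]
    ids <- names(labels)
  }
  if (anyDuplicated(ids)) stop("duplicate cell identifiers in labels")
  missing <- setdiff(cells, ids)
  if (length(missing))
    stop("unlabeled cells: ", paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "")
  vals <- as.character(labels)
  lv <- unique(vals)                      # first-appearance order
  out <- factor(vals[match(cells, ids)], levels = lv)
  names(out) <- cells
  out
}

# Split a ligand/receptor field into subunits: "(ITGAM+ITGB2)" or
# "ITGAM+ITGB2" -> c("ITGAM", "ITGB2").
split_subunits <- function(x) {
  x <- gsub("^\\(|\\)$", "", trimws(x))
  parts <- strsplit(x, "\\+|&")[[1L]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Read a ligand-receptor database table
#'
#' Accepts two dialects: (a) `ligand` and `receptor` columns whose fields
#' may encode multi-subunit complexes as `"(SUB1+SUB2)"` or
#' `"SUB1+SUB2"`; (b) explicit subunit columns named `ligand`,
#' `ligand2`, ..., `receptor`, `receptor2`, ... An optional `pathway`
#' column is carried through.
#'
#' @param path table path (TSV/CSV with header).
#' @return a data.frame of class `LRDatabase` with list-columns
#'   `ligand_subunits`, `receptor_subunits` and character columns
#'   `ligand`, `receptor` (subunits joined by "+"), `pathway`.
#' @export
readLRDatabase <- function(path) {
  sep <- detect_delim(path)
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
  makeLRDatabase(tab)
}

#' Construct a ligand-receptor database from a data.frame
#'
#' @param tab data.frame in either dialect accepted by [readLRDatabase()].
#' @return an `LRDatabase` data.frame; see [readLRDatabase()].
#' @export
makeLRDatabase <- function(tab) {
  nm <- tolower(names(tab))
  lig_cols <- which(grepl("^ligand", nm))
  rec_cols <- which(grepl("^receptor", nm))
  if (!length(lig_cols) || !length(rec_cols))
    stop("L-R table needs ligand and receptor columns")
  collect <- function(row, cols) {
    vals <- unlist(lapply(cols, function(j) {
      v <- row[[j]]
      if (is.na(v) || !nzchar(trimws(as.character(v)))) character(0)
      else split_subunits(as.character(v))
    }))
    unname(vals)
  }
  lig <- lapply(seq_len(nrow(tab)), function(i) collect(tab[i, ], lig_cols))
  rec <- lapply(seq_len(nrow(tab)), function(i) collect(tab[i, ], rec_cols))
  bad <- !vapply(lig, length, 1L) | !vapply(rec, length, 1L)
  if (any(bad))
    stop("L-R record(s) with empty subunit list at row(s): ",
         paste(head(which(bad), 5L), collapse = ", "))
  pathway <- if ("pathway" %in% nm)
    as.character(tab[[which(nm == "pathway")[1L]]]) else NA_character_
  out <- data.frame(
    ligand = vapply(lig, paste, "", collapse = "+"),
    receptor = vapply(rec, paste, "", collapse = "+"),
    pathway = pathway, stringsAsFactors = FALSE)
  out$ligand_subunits <- lig
  out$receptor_subunits <- rec
  class(out) <- c("LRDatabase", "data.frame")
  out
}

#' Read a literature ground-truth table of type pairs
#'
#' @param path TSV/CSV with header columns source_type, target_type,
#'   supported (logical or 0/1).
#' @return data.frame with those columns, `supported` logical.
#' @export
readGroundTruth <- function(path) {
  sep <- detect_delim(path)
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("source_type", "target_type", "supported")
  tab$supported <- as.logical(tab$supported)
  if (anyDuplicated(tab[, c("source_type", "target_type")]))
    stop("duplicate (source, target) pairs in ground truth")
  tab
}

#' Read a spatial spot table
#'
#' @param path TSV/CSV with header columns spot_id, x, y, type.
#' @return data.frame with columns spot_id, x, y, type.
#' @export
readSpots <- function(path) {
  sep <- detect_delim(path)
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE)
  names(tab)[1:4] <- c("spot_id", "x", "y", "type")
  if (anyDuplicated(tab$spot_id)) stop("duplicate spot identifiers")
  if (any(!is.finite(tab$x)) || any(!is.finite(tab$y)))
    stop("non-finite spot coordinates")
  tab
}

#' Write a directed network edge list
#'
#' Three-column TSV (source, target, strength) in deterministic order:
#' descending strength, ties broken by source then target label.
#'
#' @param edges data.frame with columns source, target, strength.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetwork <- function(edges, path) {
  edges <- as.data.frame(edges)[, 1:3]
  names(edges) <- c("source", "target", "strength")
  if (nrow(edges) && any(!is.finite(edges$strength)))
    stop("non-finite edge strength")
  o <- order(-edges$strength, edges$source, edges$target)
  write.table(edges[o, , drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a network edge list written by [writeNetwork()]
#'
#' @param path edge-list TSV path.
#' @return data.frame with columns source, target, strength.
#' @export
readNetwork <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("source", "target", "strength")
  tab
}
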