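#' @import methods
#' @importFrom stats cor cor.test dist median p.adjust predict pt rlnorm
#'   rnorm runif sd var setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

#' SingularSpectrum: the SVD of a gene expression matrix
#'
#' Holds the singular value decomposition A = U diag(d) t(V) of an
#' m x n expression matrix, retained so that the middle factor of the
#' A = R Sigma W decomposition can be materialized and checked. Sigma is
#' represented logically by the singular values plus the matrix shape; the
#' dense m x n diagonal matrix is available via [sigmaMatrix()].
#'
#' @slot d numeric, singular values sorted non-increasing (length min(m, n)).
#' @slot u numeric matrix, m x min(m, n) left singular vectors.
#' @slot v numeric matrix, n x min(m, n) right singular vectors.
#' @slot dim integer of length 2, the shape (m, n) of the decomposed matrix.
#'
#' @seealso [computeSigma()], [sigmaMatrix()]
#' @exportClass SingularSpectrum
setClass("SingularSpectrum",
  representation(d = "numeric", u = "matrix", v = "matrix", dim = "integer"))

setValidity("SingularSpectrum", function(object) {
  k <- min(object@dim)
  if (length(object@dim) != 2L || any(object@dim < 1L))
    return("dim must be two positive integers")
  if (length(object@d) != k)
    return("number of singular values must equal min(m, n)")
  if (any(!is.finite(object@d)) || any(object@d < 0))
    return("singular values must be finite and non-negative")
  if (is.unsorted(rev(object@d)))
    return("singular values must be sorted non-increasing")
  if (!identical(dim(object@u), c(object@dim[1L], k)))
    return("u must be m x min(m, n)")
  if (!identical(dim(object@v), c(object@dim[2L], k)))
    return("v must be n x min(m, n)")
  TRUE
})

#' GRNMatrix: a weighted directed gene regulatory network
#'
#' Square adjacency matrix over the genes of a paired expression matrix;
#' entry (i, j) is the regulatory strength of gene i acting on gene j.
#' This is the left factor R of the A = R Sigma W decomposition.
#' Networks produced by [inferGRN()] and [loadUserGRN()] additionally
#' have a zero diagonal, and [inferGRN()] keeps at most one direction
#' per unordered gene pair (direction resolution); neither is a class
#' invariant, so externally constructed operators (e.g. orthogonal
#' matrices used as diagnostics) are representable too.
#'
#' @slot weights numeric matrix, m x m, finite; dimnames are the gene
#'   identifiers in expression-matrix order.
#'
#' @seealso [inferGRN()], [loadUserGRN()], [grnWeights()]
#' @exportClass GRNMatrix
setClass("GRNMatrix", representation(weights = "matrix"))

setValidity("GRNMatrix", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (is.null(rownames(w)) || is.null(colnames(w)))
    return("weights must carry gene identifiers as dimnames")
  if (!identical(rownames(w), colnames(w)))
    return("row and column gene identifiers must match")
  if (anyDuplicated(rownames(w))) return("duplicate gene identifiers")
  if (any(!is.finite(w))) return("weights must be finite")
  TRUE
})

#' CommunicationMatrix: the solved cell-cell communication factor W
#'
#' The n x n right factor of A = R Sigma W, solved as W = pinv(R Sigma) A.
#' Entries are signed: W[i, j] >= 0 means the communication signal is sent
#' from cell i to cell j, W[i, j] < 0 means it is sent from cell j to
#' cell i, and |W[i, j]| is the strength. W[i, i] is the autoregulation of
#' cell i. Use [resolveDirections()] to turn the signed matrix into a
#' directed network.
#'
#' @slot w numeric matrix, n x n, finite; dimnames are the cell
#'   identifiers in expression-matrix column order.
#'
#' @seealso [computeW()], [computeWSampled()], [resolveDirections()]
#' @exportClass CommunicationMatrix
setClass("CommunicationMatrix", representation(w = "matrix"))

setValidity("CommunicationMatrix", function(object) {
  w <- object@w
  if (nrow(w) != ncol(w)) return("w must be square")
  if (is.null(rownames(w)) || is.null(colnames(w)))
    return("w must carry cell identifiers as dimnames")
  if (!identical(rownames(w), colnames(w)))
    return("row and column cell identifiers must match")
  if (anyDuplicated(rownames(w))) return("duplicate cell identifiers")
  if (any(!is.finite(w))) return("w must be finite")
  TRUE
})

#' CellCommNetwork: a directed cell-level communication network
#'
#' Non-negative directed strengths D between individual cells, derived
#' from a signed [CommunicationMatrix-class] by the sign rule: both W[i, j]
#' (when positive) and W[j, i] (when negative) carry evidence of an i -> j
#' signal, combined additively by default. Diagonal entries are autocrine
#' self-loops, D[i, i] = max(W[i, i], 0).
#'
#' @slot strengths numeric matrix, n x n, finite and non-negative;
#'   dimnames are cell identifiers.
#'
#' @seealso [resolveDirections()], [aggregateToTypes()], [networkEdges()]
#' @exportClass CellCommNetwork
setClass("CellCommNetwork", representation(strengths = "matrix"))

setValidity("CellCommNetwork", function(object) {
  d <- object@strengths
  if (nrow(d) != ncol(d)) return("strengths must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("strengths must carry matching cell identifiers as dimnames")
  if (any(!is.finite(d)) || any(d < 0))
    return("strengths must be finite and non-negative")
  TRUE
})

#' TypeCommMatrix: aggregated cell-type communication with significance
#'
#' k x k matrix of mean cell-pair communication strengths between ordered
#' cell-type pairs, with the mean-threshold significance rule applied: a
#' type pair is significant when its strength strictly exceeds the mean of
#' all k^2 entries.
#'
#' @slot strengths numeric k x k matrix of non-negative mean strengths;
#'   dimnames are the type labels in first-appearance order.
#' @slot threshold numeric scalar, the mean of all k^2 strengths.
#' @slot significant logical k x k matrix, strengths > threshold.
#'
#' @seealso [aggregateToTypes()], [topKEdges()], [compareConditions()],
#'   [binarizeMean()]
#' @exportClass TypeCommMatrix
setClass("TypeCommMatrix",
  representation(strengths = "matrix", threshold = "numeric",
                 significant = "matrix"))

setValidity("TypeCommMatrix", function(object) {
  s <- object@strengths
  if (nrow(s) != ncol(s)) return("strengths must be square")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    return("strengths must carry matching type labels as dimnames")
  if (any(!is.finite(s))) return("strengths must be finite")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    return("threshold must be a finite scalar")
  if (!identical(dim(object@significant), dim(s)))
    return("significant must have the shape of strengths")
  if (!identical(object@significant, s > object@threshold))
    return("significant flags must equal strengths > threshold")
  TRUE
})

#' PlantedTruth: ground truth of a simulated dataset
#'
#' Records the structure planted by [makePlantedDataset()]: the true
#' regulatory edges (each planted ligand drives a response module), the
#' true ordered cell-type communication pairs, and the planted
#' ligand-receptor pairs with their sender and receiver types.
#'
#' @slot grnEdges data.frame with columns regulator, target.
#' @slot typeComm data.frame with columns source_type, target_type.
#' @slot lrPairs data.frame with columns ligand, receptor, source_type,
#'   target_type.
#' @slot seed integer seed the dataset was generated under.
#'
#' @seealso [makePlantedDataset()]
#' @exportClass PlantedTruth
setClass("PlantedTruth",
  representation(grnEdges = "data.frame", typeComm = "data.frame",
                 lrPairs = "data.frame", seed = "integer"))

setValidity("PlantedTruth", function(object) {
  if (!all(c("regulator", "target") %in% names(object@grnEdges)))
    return("grnEdges needs regulator and target columns")
  if (!all(c("source_type", "target_type") %in% names(object@typeComm)))
    return("typeComm needs source_type and target_type columns")
  if (!all(c("ligand", "receptor", "source_type", "target_type") %in%
           names(object@lrPairs)))
    return("lrPairs needs ligand, receptor, source_type, target_type")
  TRUE
})
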