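# Accessor generics and show methods for the core classes.

#' @rdname SingularSpectrum-class
#' @param object,x an object of the documented class
#' @export
setGeneric("singularValues", function(object) standardGeneric("singularValues"))

#' @rdname SingularSpectrum-class
#' @export
setMethod("singularValues", "SingularSpectrum", function(object) object@d)

#' @rdname SingularSpectrum-class
#' @export
setGeneric("leftVectors", function(object) standardGeneric("leftVectors"))

#' @rdname SingularSpectrum-class
#' @export
setMethod("leftVectors", "SingularSpectrum", function(object) object@u)

#' @rdname SingularSpectrum-class
#' @export
setGeneric("rightVectors", function(object) standardGeneric("rightVectors"))

#' @rdname SingularSpectrum-class
#' @export
setMethod("rightVectors", "SingularSpectrum", function(object) object@v)

#' Materialize the middle factor Sigma as a dense matrix
#'
#' Returns the m x n matrix with the singular values on the leading
#' diagonal and zeros elsewhere, i.e. the middle factor of A = R Sigma W.
#'
#' @param object a [SingularSpectrum-class]
#' @return numeric m x n matrix
#' @export
sigmaMatrix <- function(object) {
  stopifnot(is(object, "SingularSpectrum"))
  m <- object@dim[1L]; n <- object@dim[2L]
  s <- matrix(0, m, n)
  k <- min(m, n)
  s[cbind(seq_len(k), seq_len(k))] <- object@d
  s
}

#' @rdname GRNMatrix-class
#' @param object,x an object of the documented class
#' @export
setGeneric("grnWeights", function(object) standardGeneric("grnWeights"))

#' @rdname GRNMatrix-class
#' @export
setMethod("grnWeights", "GRNMatrix", function(object) object@weights)

#' @rdname GRNMatrix-class
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname GRNMatrix-class
#' @export
setMethod("geneIds", "GRNMatrix", function(object) rownames(object@weights))

#' @rdname CommunicationMatrix-class
#' @param object,x an object of the documented class
#' @export
setGeneric("wValues", function(object) standardGeneric("wValues"))

#' @rdname CommunicationMatrix-class
#' @export
setMethod("wValues", "CommunicationMatrix", function(object) object@w)

#' @rdname CommunicationMatrix-class
#' @export
setGeneric("cellIds", function(object) standardGeneric("cellIds"))

#' @rdname CommunicationMatrix-class
#' @export
setMethod("cellIds", "CommunicationMatrix",
          function(object) rownames(object@w))

#' @rdname CellCommNetwork-class
#' @export
setMethod("cellIds", "CellCommNetwork",
          function(object) rownames(object@strengths))

#' @rdname CellCommNetwork-class
#' @param object,x an object of the documented class
#' @export
setGeneric("commStrengths", function(object) standardGeneric("commStrengths"))

#' @rdname CellCommNetwork-class
#' @export
setMethod("commStrengths", "CellCommNetwork",
          function(object) object@strengths)

#' @rdname TypeCommMatrix-class
#' @export
setMethod("commStrengths", "TypeCommMatrix", function(object) object@strengths)

#' @rdname TypeCommMatrix-class
#' @param object,x an object of the documented class
#' @export
setGeneric("typeLabels", function(object) standardGeneric("typeLabels"))

#' @rdname TypeCommMatrix-class
#' @export
setMethod("typeLabels", "TypeCommMatrix",
          function(object) rownames(object@strengths))

#' @rdname TypeCommMatrix-class
#' @export
setGeneric("commThreshold", function(object) standardGeneric("commThreshold"))

#' @rdname TypeCommMatrix-class
#' @export
setMethod("commThreshold", "TypeCommMatrix", function(object) object@threshold)

#' @rdname TypeCommMatrix-class
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

#' @rdname TypeCommMatrix-class
#' @export
setMethod("isSignificant", "TypeCommMatrix",
          function(object) object@significant)

#' @rdname PlantedTruth-class
#' @param object,x an object of the documented class
#' @export
setGeneric("plantedTypeComm", function(object) standardGeneric("plantedTypeComm"))

#' @rdname PlantedTruth-class
#' @export
setMethod("plantedTypeComm", "PlantedTruth", function(object) object@typeComm)

#' @rdname PlantedTruth-class
#' @export
setGeneric("plantedLRPairs", function(object) standardGeneric("plantedLRPairs"))

#' @rdname PlantedTruth-class
#' @export
setMethod("plantedLRPairs", "PlantedTruth", function(object) object@lrPairs)

#' @rdname PlantedTruth-class
#' @export
setGeneric("plantedGRNEdges", function(object) standardGeneric("plantedGRNEdges"))

#' @rdname PlantedTruth-class
#' @export
setMethod("plantedGRNEdges", "PlantedTruth", function(object) object@grnEdges)

setMethod("show", "SingularSpectrum", function(object) {
  cat("SingularSpectrum of a", object@dim[1L], "x", object@dim[2L],
      "expression matrix\n")
  cat("  singular values:", length(object@d),
      sprintf("(max %.4g, min %.4g)\n", max(object@d), min(object@d)))
})

setMethod("show", "GRNMatrix", function(object) {
  w <- object@weights
  cat("GRNMatrix over", nrow(w), "genes;", sum(w != 0), "directed edges\n")
})

setMethod("show", "CommunicationMatrix", function(object) {
  cat("CommunicationMatrix over", nrow(object@w), "cells",
      sprintf("(signed; %.1f%% non-negative entries)\n",
              100 * mean(object@w >= 0)))
})

setMethod("show", "CellCommNetwork", function(object) {
  d <- object@strengths
  cat("CellCommNetwork over", nrow(d), "cells;",
      sum(d > 0), "directed edges (incl.", sum(diag(d) > 0),
      "autocrine loops)\n")
})

setMethod("show", "TypeCommMatrix", function(object) {
  cat("TypeCommMatrix over", nrow(object@strengths), "cell types\n")
  cat(sprintf("  mean-threshold %.4g; %d of %d ordered pairs significant\n",
              object@threshold, sum(object@significant),
              length(object@significant)))
})

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth (seed", object@seed, "):",
      nrow(object@typeComm), "planted type pairs,",
      nrow(object@lrPairs), "L-R pairs,",
      nrow(object@grnEdges), "regulatory edges\n")
})
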