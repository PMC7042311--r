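# Accessor generics and show methods for the core containers.

#' @describeIn ModelParams-class genome-wide mutation rate per division.
#' @param object,x an object of the documented class.
#' @export
setGeneric("muL", function(object) standardGeneric("muL"))

#' @rdname ModelParams-class
#' @export
setMethod("muL", "ModelParams", function(object) object@mu * object@L)

#' @describeIn ModelParams-class per-cell survival rate.
#' @export
setGeneric("survivalRate", function(object) standardGeneric("survivalRate"))

#' @rdname ModelParams-class
#' @export
setMethod("survivalRate", "ModelParams", function(object) object@beta)

#' @describeIn ModelParams-class genome length in base pairs.
#' @export
setGeneric("genomeLength", function(object) standardGeneric("genomeLength"))

#' @rdname ModelParams-class
#' @export
setMethod("genomeLength", "ModelParams", function(object) object@L)

setMethod("show", "ModelParams", function(object) {
  cat("ModelParams: mu =", format(object@mu, digits = 4),
      "/bp/division, L =", format(object@L, digits = 4),
      "bp, muL =", format(muL(object), digits = 4),
      "/genome/division, beta =", format(object@beta, digits = 4), "\n")
})

#' @describeIn DistanceHistogram-class distinct observed distances.
#' @export
setGeneric("distanceSupport", function(object) standardGeneric("distanceSupport"))

#' @rdname DistanceHistogram-class
#' @export
setMethod("distanceSupport", "DistanceHistogram", function(object) object@y)

#' @describeIn DistanceHistogram-class observation counts per distance.
#' @export
setGeneric("distanceCounts", function(object) standardGeneric("distanceCounts"))

#' @rdname DistanceHistogram-class
#' @export
setMethod("distanceCounts", "DistanceHistogram", function(object) object@count)

#' @describeIn DistanceHistogram-class total number of recorded distances
#'   (twice the number of unordered pairs).
#' @export
setGeneric("nDistances", function(object) standardGeneric("nDistances"))

#' @rdname DistanceHistogram-class
#' @export
setMethod("nDistances", "DistanceHistogram", function(object) sum(object@count))

#' @describeIn DistanceHistogram-class expand back to a raw vector of
#'   distances.
#' @export
setGeneric("expandDistances", function(object) standardGeneric("expandDistances"))

#' @rdname DistanceHistogram-class
#' @export
setMethod("expandDistances", "DistanceHistogram",
          function(object) rep(object@y, times = object@count))

setMethod("show", "DistanceHistogram", function(object) {
  cat("DistanceHistogram:", nDistances(object), "distances,",
      length(object@y), "distinct values")
  if (length(object@y))
    cat(", range [", min(object@y), ", ", max(object@y), "]", sep = "")
  cat("\n")
})

setMethod("show", "DistancePMF", function(object) {
  cat("DistancePMF on 0..", max(object@support), " (total mass ",
      format(sum(object@prob), digits = 6), ")\n", sep = "")
  cat("  muL =", format(muL(object@params), digits = 4),
      " beta =", format(object@params@beta, digits = 4), "\n")
})

#' @describeIn PosteriorChain-class data.frame of draws.
#' @export
setGeneric("chainDraws", function(object) standardGeneric("chainDraws"))

#' @rdname PosteriorChain-class
#' @export
setMethod("chainDraws", "PosteriorChain", function(object) object@draws)

#' @describeIn PosteriorChain-class fraction of accepted proposals.
#' @export
setGeneric("acceptanceRate", function(object) standardGeneric("acceptanceRate"))

#' @rdname PosteriorChain-class
#' @export
setMethod("acceptanceRate", "PosteriorChain",
          function(object) mean(object@draws$accepted))

setMethod("show", "PosteriorChain", function(object) {
  cat("PosteriorChain:", nrow(object@draws), "steps, acceptance rate",
      format(acceptanceRate(object), digits = 3), "\n")
})

#' @describeIn Tissue-class number of alive cells.
#' @export
setGeneric("nCells", function(object) standardGeneric("nCells"))

#' @rdname Tissue-class
#' @export
setMethod("nCells", "Tissue", function(object) length(object@alive))

#' @describeIn Tissue-class node ids of alive cells.
#' @export
setGeneric("aliveCells", function(object) standardGeneric("aliveCells"))

#' @rdname Tissue-class
#' @export
setMethod("aliveCells", "Tissue", function(object) object@alive)

#' @describeIn Tissue-class total division events executed.
#' @export
setGeneric("nDivisions", function(object) standardGeneric("nDivisions"))

#' @rdname Tissue-class
#' @export
setMethod("nDivisions", "Tissue", function(object) object@divisions)

setMethod("show", "Tissue", function(object) {
  cat("Tissue (", object@config@mode, "): ", nCells(object), " cells, ",
      object@divisions, " divisions (", object@branchings, " branching), ",
      "muL = ", object@config@muL, ", beta = ", object@config@beta, "\n",
      sep = "")
})

setMethod("show", "BulkSample", function(object) {
  cat("BulkSample:", length(object@cells), "cells")
  if (length(object@center))
    cat(" centred at (", paste(round(object@center, 1), collapse = ", "), ")",
        sep = "")
  cat("\n")
})

#' @describeIn SignatureMatrix-class matrix of channel probabilities.
#' @export
setGeneric("signatureProbs", function(object) standardGeneric("signatureProbs"))

#' @rdname SignatureMatrix-class
#' @export
setMethod("signatureProbs", "SignatureMatrix", function(object) object@probs)

#' @describeIn SignatureMatrix-class signature names.
#' @export
setGeneric("signatureNames", function(object) standardGeneric("signatureNames"))

#' @rdname SignatureMatrix-class
#' @export
setMethod("signatureNames", "SignatureMatrix",
          function(object) colnames(object@probs))

setMethod("show", "SignatureMatrix", function(object) {
  cat("SignatureMatrix: 96 channels x", ncol(object@probs), "signatures (",
      paste(colnames(object@probs), collapse = ", "), ")\n")
})
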