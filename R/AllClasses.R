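#' @import methods
#' @importFrom stats dpois dnbinom rpois rbinom rnbinom runif quantile
#'   median cor integrate pchisq setNames
NULL

#' Evolutionary parameters of a growing tissue
#'
#' Container for the three quantities every model expression consumes: the
#' per-base-pair mutation rate per cell division `mu`, the sequenced genome
#' length `L` (bp), and the per-cell survival rate `beta`, i.e. the
#' probability that both daughter lineages of a division survive,
#' conditioned on non-extinction of the observed lineage.  The genome-wide
#' rate `muL = mu * L` (mutations per genome per division) is derived and is
#' the scale on which inference operates.
#'
#' @slot mu numeric(1), mutations per base pair per division, `>= 0`.
#' @slot L numeric(1), genome length in base pairs, `>= 1`.
#' @slot beta numeric(1), survival rate in `(0, 1]`.
#' @seealso [modelParams()], [muL()], [betaFromAlpha()]
#' @export
setClass("ModelParams",
  slots = c(mu = "numeric", L = "numeric", beta = "numeric"))

setValidity("ModelParams", function(object) {
  msg <- character()
  if (length(object@mu) != 1L || is.na(object@mu) || object@mu < 0)
    msg <- c(msg, "'mu' must be a single non-negative number")
  if (length(object@L) != 1L || is.na(object@L) || object@L < 1)
    msg <- c(msg, "'L' must be a single number >= 1")
  if (length(object@beta) != 1L || is.na(object@beta) ||
      object@beta <= 0 || object@beta > 1)
    msg <- c(msg, "'beta' must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' Either `mu` (per bp) or `muL` (per genome) must be given; the other is
#' derived through `L`.  Populations with `beta <= 1/3` cannot grow (the
#' per-daughter death probability would exceed 1/2), so a warning is issued;
#' all model expressions still evaluate.
#'
#' @param mu mutation rate per base pair per division.
#' @param L sequenced genome length in base pairs (default 3e9).
#' @param beta per-cell survival rate in `(0, 1]`.
#' @param muL genome-wide mutation rate per division; alternative to `mu`.
#' @return A [ModelParams-class] object.
#' @examples
#' p <- modelParams(muL = 1.14, beta = 0.96)
#' muL(p)
#' @export
modelParams <- function(mu = NULL, L = 3e9, beta, muL = NULL) {
  if (is.null(mu) && is.null(muL))
    stop("one of 'mu' or 'muL' must be supplied")
  if (!is.null(mu) && !is.null(muL) && abs(mu * L - muL) > 1e-8 * max(1, muL))
    stop("'mu', 'L' and 'muL' are inconsistent")
  if (is.null(mu)) mu <- muL / L
  obj <- new("ModelParams", mu = as.numeric(mu), L = as.numeric(L),
             beta = as.numeric(beta))
  if (obj@beta <= 1/3)
    warning("beta <= 1/3: the population is not growing ",
            "(homeostatic or shrinking); estimates remain valid as ",
            "effective rates but the exponential-growth coalescent is ",
            "a poor description", call. = FALSE)
  obj
}

#' Truncation limits for the infinite model sums
#'
#' The distance distribution involves infinite sums over branching divisions
#' `r` and total divisions `i`; real data have a finite maximum distance and
#' a conservative cut-off of 30 for both indices leaves the distribution
#' unchanged on the observed support (larger indices feed only far larger
#' distances).
#'
#' @slot rMax integer(1), maximum number of branching divisions, `>= 1`.
#' @slot iMax integer(1), maximum number of total divisions, `>= rMax`.
#' @export
setClass("TruncationLimits", slots = c(rMax = "integer", iMax = "integer"))

setValidity("TruncationLimits", function(object) {
  if (length(object@rMax) != 1L || object@rMax < 1L)
    return("'rMax' must be a single integer >= 1")
  if (length(object@iMax) != 1L || object@iMax < object@rMax)
    return("'iMax' must be a single integer >= rMax")
  TRUE
})

#' @param rMax maximum branching divisions (default 30).
#' @param iMax maximum total divisions (default `max(rMax, 30)`).
#' @return A [TruncationLimits-class] object.
#' @rdname TruncationLimits-class
#' @export
truncationLimits <- function(rMax = 30L, iMax = max(rMax, 30L)) {
  new("TruncationLimits", rMax = as.integer(rMax), iMax = as.integer(iMax))
}

#' Probability mass function of mutational distances
#'
#' The model-predicted distribution of the mutational distance `y` on an
#' integer support `0..yMax`.  Because the generating sums are truncated the
#' probabilities can total slightly less than 1; the constructor records the
#' truncation used.
#'
#' @slot support integer vector, distances `0..yMax`.
#' @slot prob numeric vector of probabilities, same length as support.
#' @slot params the [ModelParams-class] used.
#' @slot trunc the [TruncationLimits-class] used.
#' @seealso [distanceDistribution()]
#' @export
setClass("DistancePMF",
  slots = c(support = "integer", prob = "numeric",
            params = "ModelParams", trunc = "TruncationLimits"))

setValidity("DistancePMF", function(object) {
  if (length(object@support) != length(object@prob))
    return("support and prob must have equal length")
  if (any(object@prob < -1e-12) || any(object@prob > 1 + 1e-12))
    return("probabilities must lie in [0, 1]")
  if (sum(object@prob) > 1 + 1e-8)
    return("probabilities must sum to at most 1")
  TRUE
})

#' Observed histogram of mutational distances
#'
#' Sufficient statistic for inference: counts of mutational distances `y`
#' (non-negative integers).  Every unordered pair of ancestral cells
#' contributes two distances, one per lineage, so the total count is twice
#' the number of pairs considered.
#'
#' @slot y integer vector of distinct observed distances (sorted).
#' @slot count numeric vector of positive observation counts; non-integer
#'   weights arise when a pooled histogram is rescaled to an effective
#'   sample size.
#' @seealso [distanceHistogram()], [buildHistogram()], [treeDistances()]
#' @export
setClass("DistanceHistogram", slots = c(y = "integer", count = "numeric"))

setValidity("DistanceHistogram", function(object) {
  if (length(object@y) != length(object@count))
    return("y and count must have equal length")
  if (length(object@y) && (any(object@y < 0L) || anyDuplicated(object@y)))
    return("y must be distinct non-negative integers")
  if (length(object@count) && any(object@count <= 0))
    return("counts must be positive")
  if (is.unsorted(object@y)) return("y must be sorted increasingly")
  TRUE
})

#' Build a distance histogram
#'
#' @param distances integer vector of raw observed distances, or the
#'   distinct support if `count` is given.
#' @param count optional counts matching `distances`.
#' @return A [DistanceHistogram-class].
#' @examples
#' distanceHistogram(c(0, 2, 2, 5))
#' @export
distanceHistogram <- function(distances, count = NULL) {
  if (is.null(count)) {
    if (length(distances) == 0L)
      return(new("DistanceHistogram", y = integer(), count = numeric()))
    tab <- table(as.integer(distances))
    y <- as.integer(names(tab))
    count <- as.numeric(tab)
  } else {
    o <- order(distances)
    y <- as.integer(distances)[o]
    count <- as.numeric(count)[o]
    keep <- count > 0
    y <- y[keep]; count <- count[keep]
  }
  new("DistanceHistogram", y = y, count = count)
}

#' Metropolis-Hastings sampler configuration
#'
#' Defaults follow the reference analysis: burn-in of 200 steps, uniform
#' random-walk proposal half-widths of 0.15 for `muL` (per-genome scale) and
#' 0.06 for `beta`, flat priors on `muL` in `[0.01, 100]` and `beta` in
#' `[0.05, 1]`, and sum truncation at 30.
#'
#' @slot nSteps integer, total chain length.
#' @slot burnIn integer, discarded initial steps.
#' @slot hwMuL numeric, proposal half-width for `muL`.
#' @slot hwBeta numeric, proposal half-width for `beta`.
#' @slot priorMuL numeric(2), uniform prior bounds for `muL`.
#' @slot priorBeta numeric(2), uniform prior bounds for `beta` within (0, 1].
#' @slot trunc [TruncationLimits-class].
#' @slot seed integer or NA; when set, the chain is fully reproducible.
#' @export
setClass("MCMCConfig",
  slots = c(nSteps = "integer", burnIn = "integer",
            hwMuL = "numeric", hwBeta = "numeric",
            priorMuL = "numeric", priorBeta = "numeric",
            trunc = "TruncationLimits", seed = "integer"))

setValidity("MCMCConfig", function(object) {
  msg <- character()
  if (object@nSteps <= object@burnIn)
    msg <- c(msg, "'nSteps' must exceed 'burnIn'")
  if (object@hwMuL <= 0 || object@hwBeta <= 0)
    msg <- c(msg, "proposal half-widths must be positive")
  if (length(object@priorMuL) != 2L || diff(object@priorMuL) <= 0)
    msg <- c(msg, "'priorMuL' must be an increasing length-2 interval")
  if (length(object@priorBeta) != 2L || diff(object@priorBeta) <= 0 ||
      object@priorBeta[1] <= 0 || object@priorBeta[2] > 1)
    msg <- c(msg, "'priorBeta' must be an increasing interval within (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @param nSteps chain length (default 5000).
#' @param burnIn burn-in steps (default 200).
#' @param hwMuL proposal half-width for muL (default 0.15).
#' @param hwBeta proposal half-width for beta (default 0.06).
#' @param priorMuL flat prior bounds for muL (default `c(0.01, 100)`).
#' @param priorBeta flat prior bounds for beta (default `c(0.05, 1)`).
#' @param trunc a [TruncationLimits-class] (default cut-off 30).
#' @param seed integer seed, or NA to use the current RNG state.
#' @return An [MCMCConfig-class] object.
#' @rdname MCMCConfig-class
#' @export
mcmcConfig <- function(nSteps = 5000L, burnIn = 200L,
                       hwMuL = 0.15, hwBeta = 0.06,
                       priorMuL = c(0.01, 100), priorBeta = c(0.05, 1),
                       trunc = truncationLimits(), seed = NA_integer_) {
  new("MCMCConfig", nSteps = as.integer(nSteps), burnIn = as.integer(burnIn),
      hwMuL = hwMuL, hwBeta = hwBeta,
      priorMuL = as.numeric(priorMuL), priorBeta = as.numeric(priorBeta),
      trunc = trunc, seed = as.integer(seed))
}

#' Posterior sample from the Metropolis-Hastings chain
#'
#' @slot draws data.frame with columns `step`, `muL`, `beta`, `logLik`,
#'   `accepted`, one row per MCMC step.
#' @slot config the [MCMCConfig-class] used.
#' @seealso [runMCMC()], [summarizePosterior()]
#' @export
setClass("PosteriorChain",
  slots = c(draws = "data.frame", config = "MCMCConfig"))

setValidity("PosteriorChain", function(object) {
  need <- c("step", "muL", "beta", "logLik", "accepted")
  if (!all(need %in% names(object@draws)))
    return(paste("draws must contain columns", paste(need, collapse = ", ")))
  if (nrow(object@draws) != object@config@nSteps)
    return("chain length must equal the configured number of steps")
  TRUE
})

#' Simulator configuration
#'
#' @slot mode one of `"well-mixed"`, `"spatial-2D"`, `"spatial-3D"`.
#' @slot targetCells integer, final population size.
#' @slot muL numeric, mutations per genome per division.
#' @slot beta numeric, survival rate in (0, 1].
#' @slot gridSide integer, lattice side length (spatial modes).
#' @slot seed integer or NA.
#' @export
setClass("SimConfig",
  slots = c(mode = "character", targetCells = "integer", muL = "numeric",
            beta = "numeric", gridSide = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  if (!object@mode %in% c("well-mixed", "spatial-2D", "spatial-3D"))
    return("mode must be 'well-mixed', 'spatial-2D' or 'spatial-3D'")
  if (object@targetCells < 2L) return("'targetCells' must be >= 2")
  if (object@beta <= 0 || object@beta > 1) return("'beta' must be in (0, 1]")
  if (object@muL < 0) return("'muL' must be non-negative")
  TRUE
})

#' @param mode growth mode (default `"well-mixed"`).
#' @param targetCells population size at which the simulation stops
#'   (default 1e4; the validation analyses in the sources use up to 1e6).
#' @param muL mutations per genome per division.
#' @param beta per-cell survival rate.
#' @param gridSide lattice side (default: generous for `targetCells`).
#' @param seed integer seed or NA.
#' @return A [SimConfig-class] object.
#' @rdname SimConfig-class
#' @export
simConfig <- function(mode = "well-mixed", targetCells = 1e4, muL, beta,
                      gridSide = NULL, seed = NA_integer_) {
  if (is.null(gridSide)) {
    gridSide <- if (mode == "spatial-2D") ceiling(2.5 * sqrt(targetCells))
                else if (mode == "spatial-3D") ceiling(2.5 * targetCells^(1/3))
                else 0L
  }
  new("SimConfig", mode = mode, targetCells = as.integer(targetCells),
      muL = as.numeric(muL), beta = as.numeric(beta),
      gridSide = as.integer(gridSide), seed = as.integer(seed))
}

#' Simulated tissue with full lineage record
#'
#' Cells are nodes of a lineage tree rooted at node 1; every surviving
#' daughter created by a division is a new node carrying `nMut` novel
#' mutations.  Mutation identifiers are the integers
#' `mutOffset[n] + 1 .. mutOffset[n] + nMut[n]` for node `n`, so per-cell
#' mutation sets are reconstructed lazily from root paths.
#'
#' @slot parent integer, parent node of each node (0 for the root).
#' @slot nMut integer, novel mutations acquired by each node at birth.
#' @slot mutOffset numeric, cumulative mutation-id offset per node.
#' @slot alive integer, node ids of currently alive cells.
#' @slot pos matrix of lattice coordinates (0-row for well-mixed mode).
#' @slot divisions integer, total division events executed.
#' @slot branchings integer, divisions with two surviving daughters.
#' @slot divisionLog integer vector, surviving daughters (1 or 2) per
#'   division event, in event order.
#' @slot config the [SimConfig-class] used.
#' @seealso [simulateTissue()], [takeSamples()], [groundTruthDistances()]
#' @export
setClass("Tissue",
  slots = c(parent = "integer", nMut = "integer", mutOffset = "numeric",
            alive = "integer", pos = "matrix",
            divisions = "integer", branchings = "integer",
            divisionLog = "integer", config = "SimConfig"))

#' A sampled biopsy
#'
#' @slot cells integer, node ids of the sampled cells.
#' @slot center numeric, lattice coordinates of the patch centre
#'   (length 0 for well-mixed tissues).
#' @export
setClass("BulkSample", slots = c(cells = "integer", center = "numeric"))

#' Sequencing-noise configuration
#'
#' @slot meanDepth numeric, mean coverage `Z` (reads; default 100).
#' @slot vafThreshold numeric in (0, 1): minimum cell fraction for a
#'   mutation to be called clonal to the sample (default 0.3).
#' @slot diploid logical; when TRUE read fractions are halved (heterozygous
#'   variants in a diploid genome).
#' @export
setClass("SeqConfig",
  slots = c(meanDepth = "numeric", vafThreshold = "numeric",
            diploid = "logical"))

setValidity("SeqConfig", function(object) {
  if (object@meanDepth < 1) return("'meanDepth' must be >= 1")
  if (object@vafThreshold <= 0 || object@vafThreshold >= 1)
    return("'vafThreshold' must be in (0, 1)")
  TRUE
})

#' @param meanDepth mean sequencing depth (default 100).
#' @param vafThreshold clonality threshold on the cell-fraction scale
#'   (default 0.3).
#' @param diploid halve read fractions for heterozygous diploid variants
#'   (default FALSE, matching the simulator's haploid bookkeeping).
#' @return A [SeqConfig-class] object.
#' @rdname SeqConfig-class
#' @export
seqConfig <- function(meanDepth = 100, vafThreshold = 0.3, diploid = FALSE) {
  new("SeqConfig", meanDepth = as.numeric(meanDepth),
      vafThreshold = as.numeric(vafThreshold), diploid = diploid)
}

#' Trinucleotide mutational-signature matrix
#'
#' 96 substitution classes (pyrimidine-centred trinucleotide contexts) by
#' named signatures; each column is a probability distribution over
#' channels.
#'
#' @slot probs numeric matrix, 96 rows (channel names) x signatures.
#' @seealso [readSignatureMatrix()], [fitExposures()]
#' @export
setClass("SignatureMatrix", slots = c(probs = "matrix"))

setValidity("SignatureMatrix", function(object) {
  p <- object@probs
  if (nrow(p) != 96L) return("signature matrix must have 96 channel rows")
  if (is.null(rownames(p)) || is.null(colnames(p)))
    return("channel row names and signature column names are required")
  if (any(p < -1e-12)) return("signature probabilities must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-6))
    return("each signature column must sum to 1")
  TRUE
})

#' @param probs 96 x k matrix of channel probabilities with row and column
#'   names.
#' @return A [SignatureMatrix-class] object.
#' @rdname SignatureMatrix-class
#' @export
signatureMatrix <- function(probs) new("SignatureMatrix", probs = probs)
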