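# Trinucleotide mutational-signature decomposition and per-mutation
# assignment, supporting signature-stratified rate inference.

#' The 96 trinucleotide substitution channels
#'
#' Pyrimidine-centred single-base substitutions in their trinucleotide
#' context, in the conventional `"A[C>A]A"` notation and ordering
#' (substitution-major, then 5' and 3' flank alphabetically).
#'
#' @return character vector of length 96.
#' @export
trinucleotideChannels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(p, q)
      paste0(p, "[", s, "]", q))))))
}

#' Read a signature matrix from TSV
#'
#' Expects 96 rows (channel names in the first column or as row names) and
#' one column per signature; columns are renormalised to sum to exactly 1
#' to absorb rounding in the file.
#'
#' @param path tab-delimited file.
#' @return A [SignatureMatrix-class].
#' @export
readSignatureMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!is.numeric(df[[1L]])) {
    rn <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
    rownames(df) <- rn
  }
  m <- as.matrix(df)
  chan <- trinucleotideChannels()
  if (!setequal(rownames(m), chan))
    stop("signature file does not cover the 96 trinucleotide channels")
  m <- m[chan, , drop = FALSE]
  m <- sweep(m, 2L, colSums(m), "/")
  signatureMatrix(m)
}

#' Non-negative signature exposures for a channel-count vector
#'
#' Non-negative least-squares regression of the sample's 96 channel counts
#' against the signature dictionary.  Signatures with exposure above
#' `tol` form the sample's candidate set for per-mutation assignment.
#'
#' @param channelCounts numeric vector of 96 channel counts (named or in
#'   channel order).
#' @param sigs a [SignatureMatrix-class].
#' @param tol threshold below which an exposure counts as zero
#'   (default 1e-8).
#' @return named numeric vector of exposures with attribute `candidates`,
#'   the names of signatures with non-zero exposure.
#' @export
fitExposures <- function(channelCounts, sigs, tol = 1e-8) {
  stopifnot(is(sigs, "SignatureMatrix"))
  chan <- trinucleotideChannels()
  if (length(channelCounts) != 96L)
    stop("'channelCounts' must have length 96")
  if (any(channelCounts < 0)) stop("channel counts must be non-negative")
  if (!is.null(names(channelCounts))) {
    if (!setequal(names(channelCounts), chan))
      stop("channel names do not match the 96 trinucleotide channels")
    channelCounts <- channelCounts[chan]
  }
  A <- signatureProbs(sigs)
  if (all(channelCounts == 0)) {
    expo <- setNames(numeric(ncol(A)), colnames(A))
  } else {
    fit <- pracma::lsqnonneg(A, as.numeric(channelCounts))
    expo <- setNames(fit$x, colnames(A))
  }
  structure(expo, candidates = names(expo)[expo > tol])
}

#' Assign one mutation to a candidate signature
#'
#' The likelihood of a mutation under a signature is the signature's
#' probability for the mutation's channel.  The top candidate is assigned
#' only when its likelihood is at least `ratio` times that of every other
#' candidate; otherwise the mutation goes to `"Other"`.
#'
#' @param channel the mutation's trinucleotide channel, e.g. `"A[C>T]G"`.
#' @param sigs a [SignatureMatrix-class] restricted to (or indexed by) the
#'   candidate signatures.
#' @param candidates candidate signature names (default: all columns).
#' @param ratio dominance factor required for assignment (default 2).
#' @return list with `signature` (name or `"Other"`) and `likelihoods`.
#' @export
assignMutation <- function(channel, sigs, candidates = signatureNames(sigs),
                           ratio = 2) {
  stopifnot(is(sigs, "SignatureMatrix"), length(candidates) >= 1L)
  A <- signatureProbs(sigs)
  if (!channel %in% rownames(A)) stop("unknown channel: ", channel)
  lik <- setNames(A[channel, candidates], candidates)
  top <- which.max(lik)
  assigned <- if (length(lik) == 1L ||
                  all(lik[top] >= ratio * lik[-top])) names(lik)[top]
              else "Other"
  list(signature = assigned, likelihoods = lik)
}

#' Assign a vector of mutations to signatures
#'
#' Vectorised convenience wrapper around [assignMutation()]: fits the
#' candidate set with [fitExposures()] from the channel tally, then
#' assigns every mutation.
#'
#' @param channels character vector, one trinucleotide channel per
#'   mutation (named by mutation identifier when available).
#' @param sigs a [SignatureMatrix-class].
#' @param ratio dominance factor (default 2).
#' @return character vector of signature names (or `"Other"`), named like
#'   `channels`.
#' @export
assignMutations <- function(channels, sigs, ratio = 2) {
  chan <- trinucleotideChannels()
  counts <- setNames(numeric(96), chan)
  tab <- table(channels)
  counts[names(tab)] <- as.numeric(tab)
  expo <- fitExposures(counts, sigs)
  cand <- attr(expo, "candidates")
  if (!length(cand)) cand <- signatureNames(sigs)
  A <- signatureProbs(sigs)[, cand, drop = FALSE]
  byChannel <- apply(A, 1L, function(lik) {
    top <- which.max(lik)
    if (length(lik) == 1L || all(lik[top] >= ratio * lik[-top]))
      colnames(A)[top] else "Other"
  })
  setNames(byChannel[channels], names(channels))
}

#' Signature-stratified mutational-distance histograms
#'
#' Splits every pairwise distance by the signature stratum of the
#' differing mutations: for each unordered pair of profiles and each
#' stratum, the distance contribution is the number of stratum mutations
#' in the set difference.  Strata partition the unstratified distances
#' exactly, so per-stratum rate inference decomposes the overall rate.
#'
#' @param profiles named list (>= 2) of mutation-identifier vectors.
#' @param assignments named character vector mapping every mutation
#'   identifier occurring in `profiles` to a signature (or `"Other"`).
#' @return named list of [DistanceHistogram-class], one per stratum.
#' @export
stratifiedHistograms <- function(profiles, assignments) {
  if (length(profiles) < 2L) stop("at least 2 profiles are required")
  profiles <- lapply(profiles, function(p) unique(as.character(p)))
  allMut <- unique(unlist(profiles, use.names = FALSE))
  if (!all(allMut %in% names(assignments)))
    stop("every mutation in the profiles needs a signature assignment")
  strata <- sort(unique(assignments[allMut]))
  dists <- lapply(strata, function(s) integer(0))
  names(dists) <- strata
  n <- length(profiles)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- profiles[[i]]; b <- profiles[[j]]
    d1 <- setdiff(a, b); d2 <- setdiff(b, a)
    for (s in strata) {
      dists[[s]] <- c(dists[[s]],
                      sum(assignments[d1] == s), sum(assignments[d2] == s))
    }
  }
  lapply(dists, distanceHistogram)
}
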