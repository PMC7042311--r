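# Independent oracles used across the suite.  These deliberately avoid
# the package's own evaluation paths.

# Poisson pmf via an explicit factorial series: lambda^x / x! times a
# truncated exponential series, all in plain arithmetic.
oraclePoisson <- function(x, lambda, terms = 200L) {
  fact <- if (x == 0L) 1 else prod(seq_len(x))
  expSeries <- sum(vapply(0:terms, function(k) {
    (-lambda)^k / if (k == 0L) 1 else prod(seq_len(k))
  }, numeric(1)))
  lambda^x / fact * expSeries
}

# Probability of m single-survivor divisions among r branching divisions
# by exhaustive enumeration of division-outcome sequences: sequences of
# length r + m over {branching, non-branching} that end with a branching
# division and contain exactly r branchings.
oracleNonBranching <- function(m, r, beta) {
  len <- r + m
  total <- 0
  for (code in 0:(2^(len - 1L) - 1L)) {
    bits <- as.integer(intToBits(code))[seq_len(len - 1L)]
    seqc <- c(bits, 1L)  # last division must branch
    if (sum(seqc) == r)
      total <- total + beta^r * (1 - beta)^m
  }
  total
}

# Finite-population coalescent-interval density (the exact expression the
# large-population form approximates).
oracleCoalescentFiniteN <- function(dt, beta, N0) {
  exp(-beta * dt) * exp((1 - N0 * exp(-beta * dt)) / (beta * N0))
}

# Forward sampler for the distance of a single lineage given r branching
# divisions (geometric/negative-binomial non-branching count plus Poisson
# mutations), bypassing all package pmf code.
oracleSampleDistanceGivenR <- function(n, r, beta, muL) {
  m <- stats::rnbinom(n, size = r, prob = beta)
  stats::rpois(n, (r + m) * muL)
}

# Brute-force set distances by element-wise membership checks.
oracleSetDistances <- function(a, b) {
  a <- unique(a); b <- unique(b)
  y1 <- 0L
  for (x in a) if (!any(x == b)) y1 <- y1 + 1L
  y2 <- 0L
  for (x in b) if (!any(x == a)) y2 <- y2 + 1L
  c(y1, y2)
}

# Total-variation distance between an empirical sample of non-negative
# integers and a model pmf given on 0..yMax (missing model mass counts
# fully towards the distance).
tvToPMF <- function(draws, support, prob) {
  tab <- tabulate(draws + 1L, nbins = max(max(draws) + 1L, length(support)))
  emp <- tab / length(draws)
  full <- numeric(length(emp))
  full[support + 1L] <- prob
  0.5 * (sum(abs(emp - full)) + max(0, 1 - sum(prob)))
}

# Same comparison on a coarsened support partition (bin width chosen by
# the caller); coarsening bounds the pure-sampling contribution to the
# total-variation distance on wide supports.
tvToPMFBinned <- function(draws, support, prob, width) {
  top <- max(max(draws), max(support))
  breaks <- seq(0L, top + width, by = width)
  empBin <- tabulate(findInterval(draws, breaks), nbins = length(breaks)) /
    length(draws)
  supBin <- findInterval(support, breaks)
  modBin <- vapply(seq_along(breaks), function(b)
    sum(prob[supBin == b]), numeric(1))
  0.5 * (sum(abs(empBin - modBin)) + max(0, 1 - sum(prob)))
}

# Small deterministic tissue for cross-module tests.
makeTestTissue <- function(muL = 3, beta = 0.9, n = 300, seed = 7,
                           mode = "well-mixed") {
  simulateTissue(simConfig(mode, n, muL = muL, beta = beta, seed = seed))
}

toySignaturePath <- function() {
  system.file("extdata", "toy_signatures_synthetic.tsv", package = "mutdist")
}
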