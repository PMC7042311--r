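# Closed-form probability model for mutational distances in an
# exponentially growing cell population.
#
# Along a single cell lineage, each division adds a Poisson(muL) number of
# novel mutations.  A division leaves two surviving lineages with
# probability beta ("branching") or one with probability 1 - beta
# ("non-branching"), so the number m of non-branching divisions
# interleaved with r branching divisions is NegBin(r, beta).  The number
# of branching divisions separating two ancestral cells follows from the
# pair coalescent of a deterministically growing population, discretised
# to integer division counts.  Compounding the three gives the predicted
# distribution of mutational distances P(y).

#' Poisson probability of acquiring x mutations in one division
#'
#' @param x non-negative integer count(s) of novel mutations.
#' @param params a [ModelParams-class].
#' @return probability of each `x` under Poisson(muL).
#' @examples
#' probMutationsPerDivision(0, modelParams(muL = 1.14, beta = 0.96))
#' @export
probMutationsPerDivision <- function(x, params) {
  stopifnot(is(params, "ModelParams"))
  if (any(x < 0) || any(x != floor(x)))
    stop("'x' must be non-negative integers")
  dpois(x, muL(params))
}

#' Negative-binomial probability of m non-branching divisions
#'
#' Probability that `m` single-survivor divisions occur alongside `r`
#' branching (two-survivor) divisions:
#' `choose(r + m - 1, r - 1) * beta^r * (1 - beta)^m`.
#'
#' @param m non-negative integer count(s) of non-branching divisions.
#' @param r positive integer, number of branching divisions.
#' @param beta survival rate in (0, 1].
#' @return probability of each `m`.
#' @examples
#' probNonBranching(0, 1, 0.96)  # reduces to beta
#' @export
probNonBranching <- function(m, r, beta) {
  if (any(r < 1) || any(r != floor(r))) stop("'r' must be a positive integer")
  if (any(m < 0) || any(m != floor(m)))
    stop("'m' must be non-negative integers")
  if (beta <= 0 || beta > 1) stop("'beta' must be in (0, 1]")
  dnbinom(m, size = r, prob = beta)
}

#' Density of the scaled time between coalescence events
#'
#' Large-population approximation to the pair-coalescent interval density
#' in a population growing as `exp(beta * t)`:
#' `f(dt) = exp(-beta * dt) * exp(-exp(-beta * dt) / beta)`.
#' Time is measured in cell divisions.  Integrating over `[r, r + 1]` gives
#' the un-normalised probability of `r` branching divisions.
#'
#' @param dt non-negative time(s) between coalescence events, divisions.
#' @param beta survival rate in (0, 1].
#' @return density value(s).
#' @seealso [probBranchingDivisions()]
#' @export
coalescentIntervalDensity <- function(dt, beta) {
  if (any(dt < 0)) stop("'dt' must be non-negative")
  if (beta <= 0 || beta > 1) stop("'beta' must be in (0, 1]")
  exp(-beta * dt) * exp(-exp(-beta * dt) / beta)
}

#' Distribution of branching divisions between two ancestral cells
#'
#' Discretised, normalised pair-coalescent interval distribution for an
#' exponentially expanding population:
#' `P(r) = [F(r + 1) - F(r)] / [1 - F(1)]` with
#' `F(r) = exp(-exp(-beta * r) / beta)`, supported on r = 1, 2, ....
#'
#' @param r positive integer(s), number of branching divisions.
#' @param beta survival rate in (0, 1].
#' @return probability of each `r`.
#' @examples
#' sum(probBranchingDivisions(1:200, 0.5))  # ~1 (telescoping sum)
#' @export
probBranchingDivisions <- function(r, beta) {
  if (any(r < 1) || any(r != floor(r)))
    stop("'r' must be positive integers (positive branch lengths only)")
  if (beta <= 0 || beta > 1) stop("'beta' must be in (0, 1]")
  Fr <- function(x) exp(-exp(-beta * x) / beta)
  (Fr(r + 1) - Fr(r)) / (1 - Fr(1))
}

# Collapsed weights over total divisions i = 1..iMax:
# w[i] = sum_{r=1..min(i,rMax)} P(r) * NegBin(i - r; r, beta),
# so that P(y) = sum_i w[i] * Poisson(y; i * muL).  The (r, i) double sum
# collapses because the Poisson factor depends on i only.
totalDivisionWeights <- function(beta, trunc) {
  rMax <- trunc@rMax; iMax <- trunc@iMax
  pr <- probBranchingDivisions(seq_len(rMax), beta)
  w <- numeric(iMax)
  for (r in seq_len(rMax)) {
    i <- r:iMax
    w[i] <- w[i] + pr[r] * dnbinom(i - r, size = r, prob = beta)
  }
  w
}

#' Distribution of the mutational distance given r branching divisions
#'
#' Truncated sum over the total number of divisions `i = r..iMax`:
#' `P(y | r) = sum_i choose(i-1, r-1) beta^r (1-beta)^(i-r)
#'             exp(-i muL) (i muL)^y / y!`.
#' At `beta = 1` only the `i = r` term survives and the expression is the
#' Poisson pmf with mean `r * muL` exactly.
#'
#' @param y non-negative integer distance(s).
#' @param r positive integer, branching divisions separating the two cells.
#' @param params a [ModelParams-class].
#' @param trunc a [TruncationLimits-class].
#' @return probability of each `y`.
#' @export
probDistanceGivenR <- function(y, r, params, trunc = truncationLimits()) {
  stopifnot(is(params, "ModelParams"), is(trunc, "TruncationLimits"))
  if (length(r) != 1L || r < 1 || r != floor(r))
    stop("'r' must be a single positive integer")
  if (r > trunc@rMax) stop("'r' exceeds the truncation limit")
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must be non-negative integers")
  mL <- muL(params); beta <- params@beta
  i <- r:trunc@iMax
  wi <- dnbinom(i - r, size = r, prob = beta)
  vapply(y, function(yy) sum(wi * dpois(yy, i * mL)), numeric(1))
}

#' Predicted distribution of mutational distances
#'
#' The full compound distribution
#' `P(y) = sum_r sum_i P(r) choose(i-1, r-1) beta^r (1-beta)^(i-r)
#'         exp(-i muL) (i muL)^y / y!`,
#' truncated at the configured limits.  For large `muL` the pmf is
#' multimodal with peaks near integer multiples of `muL`; smaller `beta`
#' shifts weight towards larger distances.
#'
#' @param params a [ModelParams-class].
#' @param trunc a [TruncationLimits-class].
#' @param yMax support upper end; when NULL, the smallest y reaching
#'   cumulative mass `1 - massTol`, capped at `10 * iMax * max(1, muL)`.
#' @param massTol tolerance on the missing tail mass used to pick `yMax`
#'   (default 1e-6).
#' @return A [DistancePMF-class] on support `0..yMax`.
#' @examples
#' pmf <- distanceDistribution(modelParams(muL = 1.14, beta = 0.96))
#' sum(pmf@prob)
#' @export
distanceDistribution <- function(params, trunc = truncationLimits(),
                                 yMax = NULL, massTol = 1e-6) {
  stopifnot(is(params, "ModelParams"), is(trunc, "TruncationLimits"))
  if (!is.null(yMax) && yMax < 0) stop("'yMax' must be non-negative")
  mL <- muL(params); beta <- params@beta
  w <- totalDivisionWeights(beta, trunc)
  lam <- seq_along(w) * mL
  cap <- ceiling(10 * trunc@iMax * max(1, mL))
  if (is.null(yMax)) {
    # total truncated mass sum(w) is the best achievable; stop when the
    # remaining deficit relative to it is below massTol
    target <- sum(w) - massTol
    yMax <- 0L
    acc <- sum(w * dpois(0L, lam))
    block <- 256L
    while (acc < target && yMax < cap) {
      ys <- (yMax + 1L):min(yMax + block, cap)
      p <- vapply(ys, function(yy) sum(w * dpois(yy, lam)), numeric(1))
      cs <- acc + cumsum(p)
      hit <- which(cs >= target)
      if (length(hit)) { yMax <- ys[hit[1L]]; acc <- cs[hit[1L]]; break }
      yMax <- ys[length(ys)]; acc <- cs[length(cs)]
    }
  }
  support <- 0:yMax
  prob <- .distancePMFValues(support, mL, w)
  new("DistancePMF", support = as.integer(support), prob = prob,
      params = params, trunc = trunc)
}

# P(y) for given support under collapsed weights w (linear scale).
.distancePMFValues <- function(y, mL, w) {
  lam <- seq_along(w) * mL
  # outer-product evaluation; dpois is vectorised over the long pair
  ny <- length(y); ni <- length(w)
  p <- dpois(rep(y, times = ni), rep(lam, each = ny))
  as.numeric(matrix(p, nrow = ny) %*% w)
}

# log P(y) with log-sum-exp over i, robust for extreme y where every
# linear-scale term underflows.
.distanceLogPMFValues <- function(y, mL, w) {
  lam <- seq_along(w) * mL
  lw <- ifelse(w > 0, log(w), -Inf)
  ny <- length(y); ni <- length(w)
  lp <- dpois(rep(y, times = ni), rep(lam, each = ny), log = TRUE)
  m <- matrix(lp + rep(lw, each = ny), nrow = ny)
  apply(m, 1L, function(row) {
    mx <- max(row)
    if (!is.finite(mx)) return(-Inf)
    mx + log(sum(exp(row - mx)))
  })
}

#' Forward Monte-Carlo sampling of mutational distances
#'
#' Draws distances directly from the generative hierarchy: the number of
#' branching divisions `r` from the coalescent distribution, the
#' non-branching divisions `m` from the negative binomial, and the
#' distance from a Poisson with mean `(r + m) * muL`.  This route never
#' evaluates the assembled pmf, so it doubles as an independent check of
#' [distanceDistribution()].
#'
#' @param params a [ModelParams-class].
#' @param n number of draws.
#' @param rBig support cap for sampling `r` (default 2000; the tail mass
#'   beyond it is far below sampling resolution for `beta >= 0.05`).
#' @return integer vector of `n` distances.
#' @export
sampleDistances <- function(params, n, rBig = 2000L) {
  stopifnot(is(params, "ModelParams"))
  beta <- params@beta; mL <- muL(params)
  pr <- probBranchingDivisions(seq_len(rBig), beta)
  r <- sample.int(rBig, n, replace = TRUE, prob = pr)
  m <- rnbinom(n, size = r, prob = beta)
  rpois(n, (r + m) * mL)
}

#' Convert a per-daughter death probability into a survival rate
#'
#' With microscopic per-daughter death probability `alpha`, conditioning a
#' division on non-extinction of the observed lineage gives the effective
#' survival rate `beta = (1 - alpha) / (1 + alpha)`.
#'
#' @param alpha death probability per daughter cell, in `[0, 1)`.
#' @return survival rate `beta`.
#' @examples
#' betaFromAlpha(0.5)  # 1/3: the homeostatic boundary
#' @export
betaFromAlpha <- function(alpha) {
  if (any(alpha < 0) || any(alpha >= 1)) stop("'alpha' must be in [0, 1)")
  (1 - alpha) / (1 + alpha)
}

#' Convert a survival rate into a per-daughter death probability
#'
#' Inverse of [betaFromAlpha()]: `alpha = (1 - beta) / (1 + beta)`.
#' Growing populations require `alpha < 1/2`, i.e. `beta > 1/3`.
#'
#' @param beta survival rate in (0, 1].
#' @return death probability per daughter.
#' @export
alphaFromBeta <- function(beta) {
  if (any(beta <= 0) || any(beta > 1)) stop("'beta' must be in (0, 1]")
  (1 - beta) / (1 + beta)
}

#' Write a distance pmf to CSV
#'
#' Two columns `y, probability`.
#'
#' @param pmf a [DistancePMF-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeDistancePMF <- function(pmf, path) {
  stopifnot(is(pmf, "DistancePMF"))
  utils::write.csv(data.frame(y = pmf@support, probability = pmf@prob),
                   path, row.names = FALSE)
  invisible(path)
}
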