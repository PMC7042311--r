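# Metropolis-Hastings inference of (muL, beta) from a distance histogram.
#
# The likelihood treats the pooled distances as independent draws from the
# model pmf P(y); correlation between pairs sharing ancestry is ignored,
# matching the derivation of the model itself.  Priors are flat on both
# parameters, so the acceptance probability reduces to the likelihood
# ratio.

# fast log-likelihood on pre-extracted support/counts
.logLikValue <- function(yv, cv, mL, beta, trunc) {
  w <- totalDivisionWeights(beta, trunc)
  lp <- .distanceLogPMFValues(yv, mL, w)
  if (any(!is.finite(lp))) return(-Inf)
  sum(cv * lp)
}

#' Log-likelihood of model parameters given a distance histogram
#'
#' `sum_y count[y] * log P(y | muL, beta)` with the truncated model pmf.
#' Returns `-Inf` (a rejectable value) when any observed distance has zero
#' probability under the truncated model.
#'
#' @param hist a [DistanceHistogram-class] (non-empty).
#' @param params a [ModelParams-class].
#' @param trunc a [TruncationLimits-class].
#' @return scalar log-likelihood.
#' @examples
#' h <- distanceHistogram(c(1, 1, 2, 3))
#' logLikelihood(h, modelParams(muL = 1.5, beta = 0.9))
#' @export
logLikelihood <- function(hist, params, trunc = truncationLimits()) {
  stopifnot(is(hist, "DistanceHistogram"), is(params, "ModelParams"))
  if (length(hist@y) == 0L) stop("the histogram is empty")
  .logLikValue(hist@y, hist@count, muL(params), params@beta, trunc)
}

#' Goodness of fit of a distance histogram to a model pmf
#'
#' Chi-square test of the observed distance counts against the model
#' probabilities, with support bins merged from the tail until every
#' expected count reaches `minExpected`.  Distances pooled over sample
#' pairs are positively correlated (pairs share ancestors), so the test
#' statistic is rescaled by the ratio of the effective to the nominal
#' sample size (a design-effect correction); pass the number of distinct
#' ancestral cells as `nEff` when the histogram comes from
#' [ancestralDistanceHistogram()] or [ancestorAgeHistogram()].
#'
#' @param hist a [DistanceHistogram-class].
#' @param pmf a [DistancePMF-class] covering the observed support.
#' @param nEff effective number of independent observations (default: the
#'   nominal total count).
#' @param minExpected minimum expected effective count per bin
#'   (default 5); bins are contiguous support segments of approximately
#'   equal model probability.
#' @return list with `statistic`, `df`, `pValue`, `nBins`.
#' @export
distanceGOF <- function(hist, pmf, nEff = nDistances(hist),
                        minExpected = 5) {
  stopifnot(is(hist, "DistanceHistogram"), is(pmf, "DistancePMF"))
  n <- nDistances(hist)
  yMax <- max(max(hist@y), max(pmf@support))
  p <- numeric(yMax + 2L)
  p[pmf@support + 1L] <- pmf@prob
  p[yMax + 2L] <- max(0, 1 - sum(pmf@prob))  # truncated tail mass
  p <- p / sum(p)
  obs <- numeric(yMax + 2L)
  obs[hist@y + 1L] <- hist@count
  nBins <- max(2L, min(floor(nEff / minExpected), 20L))
  # contiguous equal-probability bins from the model cdf
  edges <- unique(c(0, findInterval(seq_len(nBins - 1L) / nBins,
                                    cumsum(p)) + 1L, length(p)))
  nBins <- length(edges) - 1L
  if (nBins < 2L)
    stop("too few adequately filled bins for a goodness-of-fit test")
  binP <- numeric(nBins); binO <- numeric(nBins)
  for (b in seq_len(nBins)) {
    idx <- (edges[b] + 1L):edges[b + 1L]
    binP[b] <- sum(p[idx]); binO[b] <- sum(obs[idx])
  }
  E <- nEff * binP
  O <- nEff * binO / n
  stat <- sum((O - E)^2 / E)
  df <- nBins - 1L
  list(statistic = stat, df = df,
       pValue = pchisq(stat, df, lower.tail = FALSE),
       nBins = nBins)
}

# coarse maximum-likelihood scan used for chain initialisation: log-spaced
# muL grid crossed with a beta grid, confined to the prior box
.gridScanStart <- function(yv, cv, config) {
  lo <- max(config@priorMuL[1], 1e-3)
  muls <- exp(seq(log(lo), log(config@priorMuL[2]), length.out = 80L))
  betas <- seq(max(config@priorBeta[1], 0.1), config@priorBeta[2],
               length.out = 15L)
  best <- c(mean(c(config@priorMuL)), mean(c(config@priorBeta)))
  bestLL <- -Inf
  for (m in muls) for (b in betas) {
    ll <- .logLikValue(yv, cv, m, b, config@trunc)
    if (ll > bestLL) { bestLL <- ll; best <- c(m, b) }
  }
  best
}

#' Run the Metropolis-Hastings sampler
#'
#' Standard random-walk Metropolis: both parameters receive additive
#' uniform proposals with the configured half-widths; a proposal falling
#' outside the flat prior bounds is rejected outright; otherwise it is
#' accepted with probability `min(1, likelihood ratio)`.  The chain is
#' fully reproducible when a seed is configured.
#'
#' By default the chain starts from a uniform draw within the prior
#' bounds.  Because the distance likelihood is multimodal in `muL` (a
#' sub-multiple of the true rate aligns every observed peak with a peak
#' of the model), `init = "grid"` starts the chain at the best point of a
#' coarse likelihood scan instead, which keeps the random walk in the
#' dominant mode; use it whenever `muL` may exceed a few units.
#'
#' @param hist a [DistanceHistogram-class].
#' @param config an [MCMCConfig-class].
#' @param init `"random"` (uniform draw from the priors, default) or
#'   `"grid"` (coarse maximum-likelihood scan).
#' @return A [PosteriorChain-class].
#' @examples
#' h <- distanceHistogram(rpois(100, 2))
#' ch <- runMCMC(h, mcmcConfig(nSteps = 500, seed = 1))
#' acceptanceRate(ch)
#' @export
runMCMC <- function(hist, config = mcmcConfig(),
                    init = c("random", "grid")) {
  stopifnot(is(hist, "DistanceHistogram"), is(config, "MCMCConfig"))
  init <- match.arg(init)
  if (length(hist@y) == 0L) stop("the histogram is empty")
  if (!is.na(config@seed)) set.seed(config@seed)
  yv <- hist@y; cv <- hist@count
  trunc <- config@trunc
  n <- config@nSteps
  muLs <- numeric(n); betas <- numeric(n)
  lls <- numeric(n); acc <- logical(n)
  cur <- if (init == "grid") .gridScanStart(yv, cv, config)
         else c(runif(1, config@priorMuL[1], config@priorMuL[2]),
                runif(1, config@priorBeta[1], config@priorBeta[2]))
  curLL <- .logLikValue(yv, cv, cur[1], cur[2], trunc)
  consecRej <- 0L
  maxRej <- 10L * max(config@burnIn, 1L)
  for (s in seq_len(n)) {
    prop <- cur + c(runif(1, -config@hwMuL, config@hwMuL),
                    runif(1, -config@hwBeta, config@hwBeta))
    inBounds <- prop[1] >= config@priorMuL[1] &&
      prop[1] <= config@priorMuL[2] &&
      prop[2] >= config@priorBeta[1] && prop[2] <= config@priorBeta[2]
    accepted <- FALSE
    if (inBounds) {
      propLL <- .logLikValue(yv, cv, prop[1], prop[2], trunc)
      if (is.infinite(curLL) && is.infinite(propLL)) {
        accepted <- TRUE  # flat -Inf region: keep moving
      } else {
        accepted <- log(runif(1)) < (propLL - curLL)
      }
      if (accepted) { cur <- prop; curLL <- propLL }
    }
    muLs[s] <- cur[1]; betas[s] <- cur[2]; lls[s] <- curLL; acc[s] <- accepted
    consecRej <- if (accepted) 0L else consecRej + 1L
    if (consecRej > maxRej)
      stop("MCMC diagnostics: more than ", maxRej,
           " consecutive rejections; check proposal half-widths and priors")
  }
  new("PosteriorChain",
      draws = data.frame(step = seq_len(n), muL = muLs, beta = betas,
                         logLik = lls, accepted = acc),
      config = config)
}

#' Posterior medians and 95% credibility intervals
#'
#' Point estimates are post-burn-in sample medians; intervals are the
#' central 95% quantile ranges.
#'
#' @param chain a [PosteriorChain-class].
#' @param burnIn steps to discard (default: the configured burn-in).
#' @param L genome length in bp, used to convert `muL` to a per-bp rate
#'   (default 3e9).
#' @return list with `muLMedian`, `muLCI`, `betaMedian`, `betaCI`,
#'   `muPerBp`, `acceptanceRate`.
#' @export
summarizePosterior <- function(chain, burnIn = NULL, L = 3e9) {
  stopifnot(is(chain, "PosteriorChain"))
  if (is.null(burnIn)) burnIn <- chain@config@burnIn
  d <- chain@draws
  if (burnIn >= nrow(d)) stop("burn-in leaves no posterior draws")
  d <- d[(burnIn + 1L):nrow(d), ]
  qs <- c(0.025, 0.975)
  list(muLMedian = median(d$muL),
       muLCI = unname(quantile(d$muL, qs)),
       betaMedian = median(d$beta),
       betaCI = unname(quantile(d$beta, qs)),
       muPerBp = median(d$muL) / L,
       acceptanceRate = mean(d$accepted))
}

#' Parameter-recovery experiment on simulated tissues
#'
#' For every `(muL, beta)` pair of the grid: grow `nTissues` replicate
#' tissues, sample each, pool the ancestor-age mutational-distance
#' histograms built from the recorded lineages
#' ([ancestralDistanceHistogram()]), and run the grid-initialised MCMC on
#' the pooled histogram.  Replicates average over the large
#' tissue-to-tissue randomness of the earliest clade splits, which a
#' single stochastic genealogy cannot.  Reports per-point truth,
#' posterior medians and credibility intervals, plus Spearman rank
#' correlations between truth and estimate and relative errors
#' `eta = mean(|estimate - truth| / truth)` across the grid.
#'
#' @param grid data.frame with columns `muL` and `beta`.
#' @param targetCells tissue size per simulation (default 1e4).
#' @param nSamples biopsies per tissue (default 200).
#' @param cellsPerSample cells per biopsy (default 1: single-cell
#'   sampling, which keeps every sample MRCA distinct).
#' @param mode simulator growth mode (default `"well-mixed"`).
#' @param nTissues replicate tissues pooled per grid point (default 5).
#' @param maxAncestors earliest distinct ancestors kept per tissue
#'   (default 20).
#' @param config an [MCMCConfig-class]; its seed slot is overridden
#'   per grid point for reproducibility.
#' @param seed base integer seed.
#' @param errorSummary `"mean"` (default) or `"median"` aggregation of the
#'   relative errors.
#' @return list with `results` (data.frame, one row per grid point) and
#'   `summary` (list `rhoMu`, `rhoBeta`, `etaMu`, `etaBeta`).
#' @export
recoveryExperiment <- function(grid, targetCells = 1e4, nSamples = 200,
                               cellsPerSample = 1, mode = "well-mixed",
                               nTissues = 5L, maxAncestors = 20,
                               config = mcmcConfig(nSteps = 4000L),
                               seed = 1L, errorSummary = c("mean", "median")) {
  stopifnot(is.data.frame(grid), all(c("muL", "beta") %in% names(grid)),
            nrow(grid) >= 1L)
  errorSummary <- match.arg(errorSummary)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    truth <- grid[g, ]
    row <- data.frame(muL = truth$muL, beta = truth$beta,
                      muLHat = NA_real_, muLLo = NA_real_, muLHi = NA_real_,
                      betaHat = NA_real_, betaLo = NA_real_,
                      betaHi = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    ptSeed <- (seed + 7919L * g) %% .Machine$integer.max
    out <- tryCatch({
      ys <- integer(0); nEff <- 0L
      for (t in seq_len(nTissues)) {
        sc <- simConfig(mode = mode, targetCells = targetCells,
                        muL = truth$muL, beta = truth$beta,
                        seed = (ptSeed + 131L * t) %% .Machine$integer.max)
        tissue <- simulateTissue(sc)
        samples <- takeSamples(tissue, nSamples = nSamples,
                               cellsPerSample = cellsPerSample,
                               strategy = "maximal-distance")
        anc <- ancestralCells(tissue, samples, maxAncestors)
        ys <- c(ys, rep(as.integer(anc$age), times = anc$nPairs))
        nEff <- nEff + nrow(anc)
      }
      # composite-likelihood adjustment: pooled pair distances are highly
      # correlated (they share ancestors), so the histogram is rescaled
      # to the number of distinct ancestral cells actually observed
      hist <- distanceHistogram(ys)
      hist <- distanceHistogram(hist@y,
                                hist@count * nEff / sum(hist@count))
      cfg <- config
      cfg@seed <- as.integer((ptSeed + 1L) %% .Machine$integer.max)
      chain <- runMCMC(hist, cfg, init = "grid")
      summarizePosterior(chain)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      row$error <- conditionMessage(out)
    } else {
      row$muLHat <- out$muLMedian; row$muLLo <- out$muLCI[1]
      row$muLHi <- out$muLCI[2]
      row$betaHat <- out$betaMedian; row$betaLo <- out$betaCI[1]
      row$betaHi <- out$betaCI[2]
    }
    res[[g]] <- row
  }
  results <- do.call(rbind, res)
  ok <- !is.na(results$muLHat)
  agg <- if (errorSummary == "mean") mean else median
  summary <- list(
    rhoMu = cor(results$muL[ok], results$muLHat[ok], method = "spearman"),
    rhoBeta = cor(results$beta[ok], results$betaHat[ok],
                  method = "spearman"),
    etaMu = agg(abs(results$muLHat[ok] - results$muL[ok]) /
                  results$muL[ok]),
    etaBeta = agg(abs(results$betaHat[ok] - results$beta[ok]) /
                    results$beta[ok]),
    nFailed = sum(!ok))
  list(results = results, summary = summary)
}
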