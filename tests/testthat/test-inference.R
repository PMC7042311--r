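# Likelihood, Metropolis-Hastings sampler and posterior summaries.

test_that("log-likelihood matches closed forms and the assembled pmf", {
  p <- modelParams(muL = 1.5, beta = 1)
  n <- 40
  h0 <- distanceHistogram(rep(0, n))
  closed <- n * log(sum(probBranchingDivisions(1:30, 1) * exp(-(1:30) * 1.5)))
  expect_equal(logLikelihood(h0, p), closed, tolerance = 1e-10)
  # single observation equals the log pmf value
  p2 <- modelParams(muL = 4, beta = 0.8)
  pmf <- distanceDistribution(p2, yMax = 60)
  h1 <- distanceHistogram(7)
  expect_equal(logLikelihood(h1, p2), log(pmf@prob[pmf@support == 7]),
               tolerance = 1e-10)
  # doubling the data doubles the log-likelihood
  h2 <- distanceHistogram(c(1, 1, 3, 5))
  h2d <- distanceHistogram(rep(c(1, 1, 3, 5), 2))
  expect_equal(logLikelihood(h2d, p2), 2 * logLikelihood(h2, p2))
  # raw-list and counted representations agree
  h3 <- distanceHistogram(c(2L, 3L), count = c(2, 1))
  h3r <- distanceHistogram(c(2, 2, 3))
  expect_equal(logLikelihood(h3, p2), logLikelihood(h3r, p2))
})

test_that("likelihood surface peaks near the generating parameters", {
  set.seed(5)
  p <- modelParams(muL = 5, beta = 0.7)
  h <- distanceHistogram(sampleDistances(p, 500))
  muls <- seq(2, 10, by = 0.25)
  betas <- seq(0.3, 1, by = 0.05)
  # the scan dips below the growth threshold beta = 1/3, whose warning is
  # exercised elsewhere
  ll <- suppressWarnings(outer(muls, betas, Vectorize(function(m, b)
    logLikelihood(h, modelParams(muL = m, beta = b)))))
  best <- which(ll == max(ll), arr.ind = TRUE)
  expect_lt(abs(muls[best[1]] - 5) / 5, 0.15)
  expect_lt(abs(betas[best[2]] - 0.7), 0.2)
})

test_that("the sampler is reproducible and respects its contracts", {
  set.seed(2)
  h <- distanceHistogram(sampleDistances(modelParams(muL = 2, beta = 0.9), 150))
  cfg <- mcmcConfig(nSteps = 600, seed = 99)
  ch1 <- runMCMC(h, cfg)
  ch2 <- runMCMC(h, cfg)
  expect_identical(chainDraws(ch1), chainDraws(ch2))
  expect_equal(nrow(chainDraws(ch1)), 600)
  ar <- acceptanceRate(ch1)
  expect_gt(ar, 0); expect_lt(ar, 1)
  # every accepted move stays inside the prior box
  d <- chainDraws(ch1)
  expect_true(all(d$muL >= cfg@priorMuL[1] & d$muL <= cfg@priorMuL[2]))
  expect_true(all(d$beta >= cfg@priorBeta[1] & d$beta <= cfg@priorBeta[2]))
})

test_that("degenerate all-zero data drive the chain to the smallest mutation rate", {
  h <- distanceHistogram(rep(0, 200))
  cfg <- mcmcConfig(nSteps = 1500, burnIn = 200, priorMuL = c(0.01, 2),
                    seed = 4)
  ch <- runMCMC(h, cfg)
  sm <- summarizePosterior(ch)
  expect_lt(sm$muLMedian, 0.25)
})

test_that("posterior summaries match a sort-based quantile oracle", {
  draws <- data.frame(step = 1:100, muL = rep(2, 100), beta = rep(0.5, 100),
                      logLik = 0, accepted = TRUE)
  ch <- new("PosteriorChain", draws = draws,
            config = mcmcConfig(nSteps = 100L, burnIn = 10L))
  sm <- summarizePosterior(ch)
  expect_equal(sm$muLMedian, 2)
  expect_equal(sm$betaMedian, 0.5)
  expect_equal(diff(sm$muLCI), 0)
  set.seed(8)
  vals <- rlnorm(400)
  draws2 <- data.frame(step = 1:400, muL = vals, beta = runif(400),
                       logLik = 0, accepted = TRUE)
  ch2 <- new("PosteriorChain", draws = draws2,
             config = mcmcConfig(nSteps = 400L, burnIn = 0L))
  sm2 <- summarizePosterior(ch2, burnIn = 0)
  sorted <- sort(vals)
  expect_equal(sm2$muLMedian, median(sorted))
  expect_equal(sm2$muLCI, unname(quantile(sorted, c(0.025, 0.975))))
  # per-bp conversion on the genome scale
  draws3 <- draws; draws3$muL <- 1.37
  ch3 <- new("PosteriorChain", draws = draws3,
             config = mcmcConfig(nSteps = 100L, burnIn = 10L))
  expect_equal(signif(summarizePosterior(ch3, L = 3e9)$muPerBp, 2), 4.6e-10)
  expect_error(summarizePosterior(ch, burnIn = 100), "no posterior")
})

test_that("inference on model-generated distances recovers the truth", {
  set.seed(12)
  p <- modelParams(muL = 5, beta = 0.7)
  h <- distanceHistogram(sampleDistances(p, 2000))
  ch <- runMCMC(h, mcmcConfig(nSteps = 2500, seed = 13), init = "grid")
  sm <- summarizePosterior(ch)
  expect_lt(abs(sm$muLMedian - 5) / 5, 0.15)
  expect_gt(sm$betaCI[2], 0.55)
  expect_lt(sm$betaCI[1], 0.9)
})

test_that("recovery experiment runs end to end on a tiny grid", {
  grid <- data.frame(muL = c(3, 8), beta = c(0.9, 0.7))
  rec <- recoveryExperiment(grid, targetCells = 600, nSamples = 40,
                            nTissues = 2,
                            config = mcmcConfig(nSteps = 800L), seed = 21)
  expect_equal(nrow(rec$results), 2)
  expect_true(all(!is.na(rec$results$muLHat)))
  expect_true(all(rec$results$muLHat >= rec$results$muLLo &
                  rec$results$muLHat <= rec$results$muLHi))
  expect_named(rec$summary,
               c("rhoMu", "rhoBeta", "etaMu", "etaBeta", "nFailed"))
  expect_equal(rec$summary$nFailed, 0)
})

test_that("goodness-of-fit accepts matching data and rejects gross mismatch", {
  set.seed(31)
  p <- modelParams(muL = 4, beta = 0.8)
  pmf <- distanceDistribution(p, yMax = 150)
  good <- distanceHistogram(sampleDistances(p, 3000))
  expect_gt(distanceGOF(good, pmf)$pValue, 0.01)
  bad <- distanceHistogram(sampleDistances(modelParams(muL = 9, beta = 0.5),
                                           3000))
  expect_lt(distanceGOF(bad, pmf)$pValue, 1e-6)
})
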