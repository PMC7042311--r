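# Closed-form model components: per-division mutations, non-branching
# divisions, coalescent branching distribution, and the assembled
# distance distribution.

test_that("per-division mutation pmf matches closed forms and a series oracle", {
  expect_identical(probMutationsPerDivision(0, modelParams(muL = 0, beta = 1)), 1)
  p <- modelParams(muL = 1.14, beta = 0.96)
  expect_equal(probMutationsPerDivision(0, p), exp(-1.14))
  p2 <- modelParams(muL = 2.5, beta = 0.9)
  expect_equal(probMutationsPerDivision(3, p2), oraclePoisson(3L, 2.5),
               tolerance = 1e-12)
  # normalisation over a generous support
  expect_equal(sum(probMutationsPerDivision(0:200, p2)), 1, tolerance = 1e-12)
  expect_error(probMutationsPerDivision(-1, p), "non-negative")
})

test_that("non-branching-division pmf matches enumeration and sums to one", {
  expect_equal(probNonBranching(0, 1, 0.96), 0.96)
  expect_identical(probNonBranching(3, 2, 1), 0)
  expect_equal(probNonBranching(2, 3, 0.5), oracleNonBranching(2L, 3L, 0.5),
               tolerance = 1e-12)
  for (r in c(1, 4)) for (beta in c(0.3, 0.8))
    expect_equal(sum(probNonBranching(0:400, r, beta)), 1, tolerance = 1e-12)
  expect_error(probNonBranching(1, 0, 0.5), "positive")
})

test_that("coalescent interval density matches its finite-population form and quadrature", {
  expect_equal(coalescentIntervalDensity(0, 1), exp(-1))
  # large-population approximation against the exact finite-N expression
  dt <- seq(0, 20, by = 0.25)
  for (beta in c(0.5, 0.96)) {
    expect_lt(max(abs(coalescentIntervalDensity(dt, beta) -
                      oracleCoalescentFiniteN(dt, beta, 1e6))), 1e-4)
  }
  # integral over [r, r+1] equals the closed-form bracket before
  # normalisation
  for (beta in c(0.4, 0.7, 0.95)) for (r in c(1, 2, 5)) {
    quad <- integrate(coalescentIntervalDensity, r, r + 1, beta = beta,
                      rel.tol = 1e-12)$value
    Fr <- function(x) exp(-exp(-beta * x) / beta)
    expect_lt(abs(quad - (Fr(r + 1) - Fr(r))), 1e-8)
  }
  expect_error(coalescentIntervalDensity(-1, 0.5), "non-negative")
})

test_that("branching-division distribution is normalised and matches substitution", {
  for (beta in seq(0.05, 1, by = 0.05))
    expect_equal(sum(probBranchingDivisions(1:2000, beta)), 1,
                 tolerance = 1e-10)
  expect_equal(probBranchingDivisions(1, 1),
               (exp(-exp(-2)) - exp(-exp(-1))) / (1 - exp(-exp(-1))))
  expect_error(probBranchingDivisions(0, 0.5), "positive")
})

test_that("distance distribution given r collapses to Poisson at beta = 1", {
  p <- modelParams(muL = 1, beta = 1)
  expect_identical(probDistanceGivenR(0, 2, p), dpois(0, 2))
  ys <- 0:15
  p3 <- modelParams(muL = 2.2, beta = 1)
  expect_identical(probDistanceGivenR(ys, 3, p3), dpois(ys, 3 * 2.2))
})

test_that("distance distribution given r matches Monte-Carlo draws and is truncation-stable", {
  set.seed(42)
  draws <- oracleSampleDistanceGivenR(1e6, 1, 0.5, 1)
  p <- modelParams(muL = 1, beta = 0.5)
  expect_equal(probDistanceGivenR(1, 1, p), mean(draws == 1), tolerance = 2e-3)
  tr1 <- truncationLimits(30, 30)
  tr2 <- truncationLimits(30, 60)
  for (y in c(0, 3, 10))
    expect_equal(probDistanceGivenR(y, 2, p, tr1),
                 probDistanceGivenR(y, 2, p, tr2), tolerance = 1e-6)
})

test_that("assembled distance pmf collapses at beta = 1 and carries its mass", {
  p <- modelParams(muL = 2, beta = 1)
  pmf <- distanceDistribution(p, yMax = 80)
  direct <- sapply(pmf@support, function(y)
    sum(probBranchingDivisions(1:30, 1) * dpois(y, (1:30) * 2)))
  expect_equal(pmf@prob, direct, tolerance = 1e-12)
  # automatic support captures at least 1 - 1e-6 of the truncated mass
  p2 <- modelParams(muL = 1.14, beta = 0.96)
  pmf2 <- distanceDistribution(p2)
  expect_gte(sum(pmf2@prob), 0.999)
  # doubling the truncation changes nothing appreciably at moderate beta
  pmfA <- distanceDistribution(p2, truncationLimits(30, 30), yMax = 60)
  pmfB <- distanceDistribution(p2, truncationLimits(60, 60), yMax = 60)
  expect_lt(max(abs(pmfA@prob - pmfB@prob)), 1e-8)
})

test_that("forward sampler reproduces the assembled pmf", {
  set.seed(7)
  p <- modelParams(muL = 5, beta = 0.7)
  pmf <- distanceDistribution(p, yMax = 400)
  draws <- sampleDistances(p, 2e5)
  expect_lt(tvToPMF(draws, pmf@support, pmf@prob), 0.01)
})

test_that("death-probability and survival-rate conversions are exact inverses", {
  expect_identical(betaFromAlpha(0), 1)
  expect_identical(betaFromAlpha(0.5), 1/3)
  expect_identical(alphaFromBeta(1), 0)
  expect_equal(alphaFromBeta(1/3), 1/2)
  a <- seq(0, 0.95, by = 0.05)
  expect_equal(alphaFromBeta(betaFromAlpha(a)), a, tolerance = 1e-12)
  b <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(betaFromAlpha(a)) < 0))
  expect_true(all(diff(alphaFromBeta(b)) < 0))
  expect_error(betaFromAlpha(1), "alpha")
  expect_error(alphaFromBeta(0), "beta")
})

test_that("parameter container validates and warns for non-growing populations", {
  p <- modelParams(mu = 1e-9, L = 3e9, beta = 0.9)
  expect_equal(muL(p), 3)
  expect_error(modelParams(muL = -1, beta = 0.5))
  expect_error(modelParams(muL = 1, beta = 0))
  expect_warning(modelParams(muL = 1, beta = 0.3), "not growing")
})
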