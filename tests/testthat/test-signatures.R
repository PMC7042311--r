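# Trinucleotide-signature decomposition and stratified histograms.

sigs <- readSignatureMatrix(toySignaturePath())

test_that("the shipped toy matrix is a valid signature dictionary", {
  A <- signatureProbs(sigs)
  expect_equal(dim(A), c(96L, 6L))
  expect_equal(unname(colSums(A)), rep(1, 6), tolerance = 1e-9)
  expect_setequal(rownames(A), trinucleotideChannels())
})

test_that("exposures recover pure and mixed compositions", {
  A <- signatureProbs(sigs)
  pure <- 500 * A[, "TS2"]
  e1 <- fitExposures(pure, sigs)
  expect_equal(unname(e1["TS2"]), 500, tolerance = 1e-6)
  expect_lt(sum(e1[-2]), 1e-6)
  mix <- 0.6 * A[, "TS1"] + 0.4 * A[, "TS4"]
  e2 <- fitExposures(1000 * mix, sigs)
  expect_equal(unname(e2["TS1"]), 600, tolerance = 1e-4)
  expect_equal(unname(e2["TS4"]), 400, tolerance = 1e-4)
  expect_setequal(attr(e2, "candidates"), c("TS1", "TS4"))
  e0 <- fitExposures(numeric(96), sigs)
  expect_true(all(e0 == 0))
})

test_that("orthogonal signatures separate into per-channel sums", {
  chan <- trinucleotideChannels()
  A <- matrix(0, 96, 2, dimnames = list(chan, c("L", "R")))
  A[1:48, 1] <- 1 / 48
  A[49:96, 2] <- 1 / 48
  orth <- signatureMatrix(A)
  counts <- setNames(rpois(96, 5), chan)
  e <- fitExposures(counts, orth)
  expect_equal(unname(e["L"]), sum(counts[1:48]), tolerance = 1e-6)
  expect_equal(unname(e["R"]), sum(counts[49:96]), tolerance = 1e-6)
})

test_that("adding a signature never worsens the least-squares residual", {
  A <- signatureProbs(sigs)
  set.seed(17)
  counts <- as.numeric(200 * (0.5 * A[, 1] + 0.3 * A[, 3] + 0.2 * A[, 5])) +
    rpois(96, 1)
  resid <- function(cols) {
    fit <- pracma::lsqnonneg(A[, cols, drop = FALSE], counts)
    sqrt(sum((counts - A[, cols, drop = FALSE] %*% fit$x)^2))
  }
  r2 <- resid(c(1, 3))
  r3 <- resid(c(1, 3, 5))
  expect_lte(r3, r2 + 1e-9)
})

test_that("the dominance rule assigns mutations or falls back to Other", {
  one <- assignMutation("A[C>A]A", sigs, candidates = "TS1")
  expect_equal(one$signature, "TS1")
  chan <- trinucleotideChannels()
  A <- matrix(1 / 96, 96, 2, dimnames = list(chan, c("X", "Y")))
  tied <- signatureMatrix(A)
  expect_equal(assignMutation("A[C>A]A", tied)$signature, "Other")
  expect_error(assignMutation("bogus", sigs), "unknown channel")
})

test_that("channel draws from one signature are predominantly assigned to it", {
  set.seed(23)
  # two candidates with a strong (40x) per-channel contrast
  chan <- trinucleotideChannels()
  w <- ifelse(seq_len(96) <= 48, 40, 1)
  A2 <- cbind(sigA = w / sum(w), sigB = rev(w) / sum(w))
  rownames(A2) <- chan
  two <- signatureMatrix(A2)
  draws <- sample(chan, 600, replace = TRUE, prob = A2[, "sigA"])
  asg <- vapply(draws, function(ch)
    assignMutation(ch, two)$signature, character(1))
  expect_gte(mean(asg == "sigA"), 0.95)
  # with the full toy dictionary the candidate set comes from the
  # regression and the generating signature dominates
  A <- signatureProbs(sigs)
  draws2 <- sample(rownames(A), 600, replace = TRUE, prob = A[, "TS3"])
  names(draws2) <- sprintf("m%03d", seq_along(draws2))
  asgAll <- assignMutations(draws2, sigs)
  expect_equal(names(which.max(table(asgAll))), "TS3")
  expect_gte(mean(asgAll == "TS3"), 0.85)
})

test_that("stratified histograms partition the pairwise distances", {
  profs <- list(s1 = c("m1", "m2", "m3"), s2 = c("m2", "m3", "m4", "m5"),
                s3 = c("m2", "m6"))
  asgOne <- setNames(rep("TS1", 6), paste0("m", 1:6))
  hs <- stratifiedHistograms(profs, asgOne)
  expect_named(hs, "TS1")
  flat <- buildHistogram(profs)
  expect_identical(distanceSupport(hs$TS1), distanceSupport(flat))
  expect_identical(distanceCounts(hs$TS1), distanceCounts(flat))
  # two strata are additive per pair
  asgTwo <- setNames(c("A", "A", "B", "B", "A", "B"), paste0("m", 1:6))
  hs2 <- stratifiedHistograms(profs, asgTwo)
  totalStrata <- sum(sapply(hs2, function(h)
    sum(distanceSupport(h) * distanceCounts(h))))
  totalFlat <- sum(distanceSupport(flat) * distanceCounts(flat))
  expect_equal(totalStrata, totalFlat)
  expect_error(stratifiedHistograms(profs, asgTwo[-1]), "assignment")
})

test_that("a two-signature tissue yields separable per-stratum rates", {
  # two mutational processes with rates 4 and 1 write into disjoint strata;
  # per-stratum ancestor-age histograms then carry the same division
  # structure scaled by each rate
  tis <- makeTestTissue(muL = 5, beta = 0.9, n = 400, seed = 19)
  sa <- takeSamples(tis, nSamples = 30, cellsPerSample = 3)
  prof <- sampleProfiles(tis, sa)
  muts <- unique(unlist(prof))
  set.seed(20)
  asg <- setNames(sample(c("fast", "slow"), length(muts), TRUE,
                         prob = c(0.8, 0.2)), muts)
  hs <- stratifiedHistograms(prof, asg)
  mean_of <- function(h) sum(distanceSupport(h) * distanceCounts(h)) /
    nDistances(h)
  expect_gt(mean_of(hs$fast), 2 * mean_of(hs$slow))
})
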