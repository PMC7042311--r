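# Gillespie tissue growth, sampling, sequencing noise and lineage
# bookkeeping.

test_that("perfect survival yields exactly N - 1 divisions", {
  tis <- simulateTissue(simConfig(targetCells = 8, muL = 1, beta = 1,
                                  seed = 1))
  expect_equal(nDivisions(tis), 7L)
  expect_true(all(tis@divisionLog == 2L))
  expect_equal(nCells(tis), 8L)
})

test_that("a zero mutation rate leaves all cells with the founder genotype", {
  tis <- simulateTissue(simConfig(targetCells = 50, muL = 0, beta = 0.8,
                                  seed = 2))
  for (cell in aliveCells(tis)[1:5])
    expect_length(cellMutations(tis, cell), 0)
})

test_that("mutation burden grows like rate times divisions", {
  tis <- makeTestTissue(muL = 3, beta = 0.9, n = 400, seed = 3)
  depths <- mutdist:::.nodeDepths(tis)
  burdens <- mutdist:::.cumMutations(tis)
  cells <- aliveCells(tis)
  ratio <- sum(burdens[cells]) / (3 * sum(depths[cells]))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("simulation is reproducible under a fixed seed", {
  c1 <- simConfig(targetCells = 200, muL = 2, beta = 0.85, seed = 11)
  t1 <- simulateTissue(c1)
  t2 <- simulateTissue(c1)
  expect_identical(t1@parent, t2@parent)
  expect_identical(t1@nMut, t2@nMut)
  expect_identical(t1@alive, t2@alive)
})

test_that("spatial growth stays on the lattice and fails loudly when full", {
  tis <- simulateTissue(simConfig("spatial-2D", 150, muL = 1, beta = 0.9,
                                  seed = 5))
  pos <- tis@pos[aliveCells(tis), ]
  expect_true(all(pos >= 1 & pos <= tis@config@gridSide))
  expect_false(anyDuplicated(paste(pos[, 1], pos[, 2])) > 0)
  cfgFull <- simConfig("spatial-2D", 150, muL = 1, beta = 1, gridSide = 9,
                       seed = 6)
  expect_error(simulateTissue(cfgFull), "fewer sites")
})

test_that("biopsies are disjoint and spatially coherent", {
  tis <- simulateTissue(simConfig("spatial-2D", 500, muL = 2, beta = 0.9,
                                  seed = 7))
  sa <- takeSamples(tis, nSamples = 8, cellsPerSample = 12)
  cells <- unlist(lapply(sa, function(s) s@cells))
  expect_equal(anyDuplicated(cells), 0L)
  for (s in sa) {
    pos <- tis@pos[s@cells, , drop = FALSE]
    spread <- max(dist(pos))
    expect_lt(spread, 14)  # compact patch, not scattered over the tissue
  }
  expect_error(takeSamples(tis, 100, 100), "more cells")
  # single-cell sampling returns true single-cell profiles
  sc <- takeSamples(tis, 5, 1)
  prof <- sampleProfiles(tis, sc)
  for (i in seq_along(sc))
    expect_equal(prof[[i]], cellMutations(tis, sc[[i]]@cells))
})

test_that("the whole tissue collapses to the founder lineage profile", {
  tis <- makeTestTissue(muL = 2, beta = 0.9, n = 120, seed = 9)
  all <- new("BulkSample", cells = aliveCells(tis), center = numeric(0))
  prof <- sampleProfiles(tis, list(all))[[1]]
  depths <- mutdist:::.nodeDepths(tis)
  # the sample MRCA of everything is the global root chain
  fr <- mutationFractions(tis, all)
  expect_setequal(prof, fr$mutation[fr$fraction == 1])
})

test_that("sequencing noise has the documented moments and edge cases", {
  fr <- data.frame(mutation = 1:20000, fraction = 1)
  nt <- sequencingNoise(fr, seqConfig(meanDepth = 100), seed = 10)
  expect_equal(mean(nt$depth), 100, tolerance = 0.01)
  expect_equal(mean(nt$vaf, na.rm = TRUE), 1, tolerance = 1e-6)
  ntD <- sequencingNoise(fr, seqConfig(meanDepth = 100, diploid = TRUE),
                         seed = 10)
  expect_equal(mean(ntD$vaf, na.rm = TRUE), 0.5, tolerance = 0.01)
  fr0 <- data.frame(mutation = 1:500, fraction = 0)
  nt0 <- sequencingNoise(fr0, seqConfig(), seed = 11)
  expect_true(all(nt0$altReads == 0))
  expect_true(all(is.na(nt0$vaf[nt0$depth == 0])))
})

test_that("variant read counts follow the Poisson-binomial mixture", {
  set.seed(12)
  f <- 0.3; Z <- 20
  fr <- data.frame(mutation = seq_len(3e4), fraction = f)
  nt <- sequencingNoise(fr, seqConfig(meanDepth = Z))
  emp <- tabulate(nt$altReads + 1L, nbins = 40) / nrow(nt)
  mix <- sapply(0:39, function(a)
    sum(dpois(0:120, Z) * dbinom(a, 0:120, f)))
  # expected TV for 3e4 draws over ~15 occupied bins is ~0.012
  expect_lt(0.5 * sum(abs(emp - mix)), 0.025)
})

test_that("clonal profiles apply the cell-fraction threshold", {
  tab <- data.frame(mutation = 1:2, depth = c(100, 100),
                    altReads = c(100, 2), vaf = c(1.0, 0.02))
  expect_equal(clonalProfile(tab, threshold = 0.3), 1L)
  expect_equal(clonalProfile(tab, threshold = 0), c(1L, 2L))
  tabD <- data.frame(mutation = 1, depth = 100, altReads = 50, vaf = 0.5)
  expect_equal(clonalProfile(tabD, threshold = 0.9, diploid = TRUE), 1L)
})

test_that("noisy clonal profiles converge to the lineage-derived truth", {
  tis <- makeTestTissue(muL = 4, beta = 0.9, n = 500, seed = 13)
  sa <- takeSamples(tis, nSamples = 4, cellsPerSample = 20)
  truthProf <- sampleProfiles(tis, sa)
  for (i in seq_along(sa)) {
    fr <- mutationFractions(tis, sa[[i]])
    # noiseless read-out: VAF equals the true cell fraction
    tab <- data.frame(mutation = fr$mutation, depth = 1000,
                      altReads = round(1000 * fr$fraction),
                      vaf = fr$fraction)
    expect_setequal(clonalProfile(tab, threshold = 0.999), truthProf[[i]])
  }
})

test_that("lineage-derived distances agree with the set-based module", {
  tis <- makeTestTissue(muL = 5, beta = 0.85, n = 400, seed = 14)
  sa <- takeSamples(tis, nSamples = 12, cellsPerSample = 5)
  prof <- sampleProfiles(tis, sa)
  hTruth <- groundTruthDistances(tis, sa)
  hSet <- buildHistogram(prof)
  expect_identical(distanceSupport(hTruth), distanceSupport(hSet))
  expect_identical(distanceCounts(hTruth), distanceCounts(hSet))
  # ancestor-age paths agree likewise
  hA <- ancestralDistanceHistogram(tis, sa, maxAncestors = Inf)
  hB <- ancestorAgeHistogram(prof, maxAncestors = Inf)
  expect_identical(distanceSupport(hA), distanceSupport(hB))
  expect_identical(distanceCounts(hA), distanceCounts(hB))
})

test_that("sample genealogies reproduce pairwise lineage distances", {
  tis <- makeTestTissue(muL = 3, beta = 0.95, n = 600, seed = 15)
  sa <- takeSamples(tis, nSamples = 10, cellsPerSample = 1)
  tr <- sampleGenealogy(tis, sa)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 10)
  # patristic root-to-tip spans match the recorded mutation burdens
  cm <- mutdist:::.cumMutations(tis)
  depths <- mutdist:::.nodeDepths(tis)
  rootNode <- Reduce(function(a, b) mutdist:::.lca(a, b, tis@parent, depths),
                     vapply(sa, function(s) s@cells[1], numeric(1)))
  tipSpan <- ape::node.depth.edgelength(tr)[seq_len(10)]
  truthSpan <- cm[vapply(sa, function(s) s@cells[1], numeric(1))] - cm[rootNode]
  expect_equal(tipSpan[order(tr$tip.label)],
               truthSpan[order(names(sa))])
})

test_that("pair-ancestor branching depths approximate the coalescent law", {
  # the exact stochastic genealogy is Yule-like; the deterministic-growth
  # coalescent is only an approximation, so agreement is bulk-level
  rs <- integer(0)
  for (seed in c(31, 32)) {
    tis <- simulateTissue(simConfig("well-mixed", 4000, muL = 0,
                                    beta = 0.96, seed = seed))
    par <- tis@parent
    nkids <- tabulate(par[par > 0], nbins = length(par))
    bb <- par > 0L & nkids[pmax(par, 1L)] == 2L
    dB <- integer(length(par))
    for (i in seq_along(par)) {
      p <- par[i]
      dB[i] <- (if (p > 0) dB[p] else 0L) + (if (bb[i]) 1L else 0L)
    }
    depth <- mutdist:::.nodeDepths(tis)
    cells <- vapply(takeSamples(tis, 120, 1), function(s) s@cells,
                    numeric(1))
    for (i in 1:119) for (j in (i + 1):120) {
      r <- dB[mutdist:::.lca(cells[i], cells[j], par, depth)]
      if (r >= 1L) rs <- c(rs, r)
    }
  }
  emp <- tabulate(pmin(rs, 15L), nbins = 15L) / length(rs)
  theo <- probBranchingDivisions(1:15, 0.96)
  theo[15] <- theo[15] + (1 - sum(theo))
  expect_lt(0.5 * sum(abs(emp - theo)), 0.35)
  expect_equal(which.max(emp), 1L)  # mode at a single branching division
})
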