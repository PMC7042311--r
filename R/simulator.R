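# Stochastic tissue growth with per-division Poisson mutation accrual.
#
# Gillespie event loop: since all eligible cells share the same division
# rate, the next dividing cell is drawn uniformly among them.  A division
# produces two surviving daughters with probability beta, one with
# probability 1 - beta; every surviving daughter inherits its parent's
# mutations and gains a Poisson(muL) number of novel ones.  In the spatial
# modes growth is boundary-driven: only cells with a free lattice
# neighbour (von Neumann neighbourhood) are eligible, and a two-survivor
# division places the second daughter on a random free neighbour site.  A
# one-survivor division replaces the cell in place, so death leaves no
# lattice vacancy, consistent with the effective survival rate being
# conditioned on non-extinction of the observed lineage.

.neighbourOffsets <- function(dim) {
  if (dim == 2L) matrix(c(1, 0, -1, 0, 0, 1, 0, -1), ncol = 2, byrow = TRUE)
  else rbind(diag(3), -diag(3))
}

#' Simulate a growing tissue
#'
#' Grows a cell population from a single founder to `targetCells` alive
#' cells, recording the full lineage (every surviving daughter is a node
#' of the lineage tree) and the novel mutations acquired at each birth.
#' Fully reproducible when the config carries a seed.
#'
#' @param config a [SimConfig-class].
#' @return A [Tissue-class].
#' @examples
#' tis <- simulateTissue(simConfig(targetCells = 50, muL = 2, beta = 0.9,
#'                                 seed = 1))
#' nCells(tis)
#' @export
simulateTissue <- function(config) {
  stopifnot(is(config, "SimConfig"))
  if (!is.na(config@seed)) set.seed(config@seed)
  spatial <- config@mode != "well-mixed"
  dim <- if (config@mode == "spatial-3D") 3L else 2L
  target <- config@targetCells
  muL <- config@muL
  beta <- config@beta

  cap <- as.integer(ceiling(4 * target / beta) + 16L)
  parent <- integer(cap); nMut <- integer(cap)
  nNodes <- 1L  # founder, no mutations of its own
  grow <- function(need) {
    while (nNodes + need > length(parent)) {
      parent <<- c(parent, integer(length(parent)))
      nMut <<- c(nMut, integer(length(nMut)))
    }
  }

  divisions <- 0L; branchings <- 0L
  logCap <- as.integer(ceiling(2 * target / beta) + 16L)
  divLog <- integer(logCap)

  if (!spatial) {
    alive <- integer(target); alive[1L] <- 1L; nAlive <- 1L
    while (nAlive < target) {
      idx <- sample.int(nAlive, 1L)
      cell <- alive[idx]
      divisions <- divisions + 1L
      if (divisions > length(divLog)) divLog <- c(divLog, integer(logCap))
      if (runif(1) < beta) {
        branchings <- branchings + 1L
        divLog[divisions] <- 2L
        grow(2L)
        k <- rpois(2L, muL)
        d1 <- nNodes + 1L; d2 <- nNodes + 2L
        parent[d1] <- cell; parent[d2] <- cell
        nMut[d1] <- k[1L]; nMut[d2] <- k[2L]
        nNodes <- nNodes + 2L
        alive[idx] <- d1
        nAlive <- nAlive + 1L
        alive[nAlive] <- d2
      } else {
        divLog[divisions] <- 1L
        grow(1L)
        d <- nNodes + 1L
        parent[d] <- cell
        nMut[d] <- rpois(1L, muL)
        nNodes <- nNodes + 1L
        alive[idx] <- d
      }
    }
    pos <- matrix(numeric(0), nrow = 0, ncol = dim)
    aliveIds <- alive[seq_len(nAlive)]
  } else {
    side <- config@gridSide
    nSites <- side^dim
    if (nSites < target)
      stop("the lattice has fewer sites than 'targetCells'")
    occ <- integer(nSites)           # site -> node id (0 = empty)
    coord <- matrix(0L, nrow = cap, ncol = dim)
    off <- .neighbourOffsets(dim)
    mid <- rep(as.integer(ceiling(side / 2)), dim)
    siteOf <- function(xy) {
      s <- xy[1L]
      if (dim >= 2L) s <- s + (xy[2L] - 1L) * side
      if (dim == 3L) s <- s + (xy[3L] - 1L) * side^2
      s
    }
    emptyNeighbours <- function(xy) {
      res <- integer(0); resXY <- matrix(0L, nrow = 0, ncol = dim)
      for (j in seq_len(nrow(off))) {
        nb <- xy + off[j, ]
        if (any(nb < 1L) || any(nb > side)) next
        s <- siteOf(nb)
        if (occ[s] == 0L) { res <- c(res, s); resXY <- rbind(resXY, nb) }
      }
      list(sites = res, xy = resXY)
    }
    coord[1L, ] <- mid
    occ[siteOf(mid)] <- 1L
    nAlive <- 1L
    frontier <- integer(target); frontier[1L] <- 1L  # node ids
    fCount <- 1L
    inFrontier <- logical(cap); inFrontier[1L] <- TRUE
    while (nAlive < target) {
      # pick an eligible cell (lazy frontier maintenance)
      cell <- NA_integer_
      en <- NULL
      while (fCount > 0L) {
        pick <- sample.int(fCount, 1L)
        cand <- frontier[pick]
        en <- emptyNeighbours(coord[cand, ])
        if (length(en$sites)) { cell <- cand; break }
        inFrontier[cand] <- FALSE
        frontier[pick] <- frontier[fCount]
        fCount <- fCount - 1L
      }
      if (is.na(cell)) {
        partial <- .makeTissue(parent, nMut, nNodes,
                               .aliveFromOcc(occ), coord, dim,
                               divisions, branchings, divLog, config)
        cond <- structure(
          class = c("mutdistGridFull", "error", "condition"),
          list(message = "lattice full before reaching targetCells",
               call = sys.call(-1), tissue = partial))
        stop(cond)
      }
      divisions <- divisions + 1L
      if (divisions > length(divLog)) divLog <- c(divLog, integer(logCap))
      if (runif(1) < beta) {
        branchings <- branchings + 1L
        divLog[divisions] <- 2L
        grow(2L)
        if (length(inFrontier) < length(parent))
          inFrontier <- c(inFrontier,
                          logical(length(parent) - length(inFrontier)))
        k <- rpois(2L, muL)
        d1 <- nNodes + 1L; d2 <- nNodes + 2L
        parent[d1] <- cell; parent[d2] <- cell
        nMut[d1] <- k[1L]; nMut[d2] <- k[2L]
        nNodes <- nNodes + 2L
        # d1 replaces the parent in place, d2 takes a free neighbour
        coord[d1, ] <- coord[cell, ]
        occ[siteOf(coord[cell, ])] <- d1
        j <- if (length(en$sites) == 1L) 1L else sample.int(length(en$sites), 1L)
        coord[d2, ] <- en$xy[j, ]
        occ[en$sites[j]] <- d2
        nAlive <- nAlive + 1L
        inFrontier[cell] <- FALSE
        for (d in c(d1, d2)) {
          fCount <- fCount + 1L
          if (fCount > length(frontier)) frontier <- c(frontier, integer(target))
          frontier[fCount] <- d
          inFrontier[d] <- TRUE
        }
      } else {
        divLog[divisions] <- 1L
        grow(1L)
        if (length(inFrontier) < length(parent))
          inFrontier <- c(inFrontier,
                          logical(length(parent) - length(inFrontier)))
        d <- nNodes + 1L
        parent[d] <- cell
        nMut[d] <- rpois(1L, muL)
        nNodes <- nNodes + 1L
        coord[d, ] <- coord[cell, ]
        occ[siteOf(coord[cell, ])] <- d
        inFrontier[cell] <- FALSE
        fCount <- fCount + 1L
        if (fCount > length(frontier)) frontier <- c(frontier, integer(target))
        frontier[fCount] <- d
        inFrontier[d] <- TRUE
      }
    }
    aliveIds <- .aliveFromOcc(occ)
    pos <- coord
  }
  .makeTissue(parent, nMut, nNodes, aliveIds, pos, dim,
              divisions, branchings, divLog, config)
}

.aliveFromOcc <- function(occ) sort(occ[occ != 0L])

.makeTissue <- function(parent, nMut, nNodes, aliveIds, pos, dim,
                        divisions, branchings, divLog, config) {
  parent <- parent[seq_len(nNodes)]
  nMut <- nMut[seq_len(nNodes)]
  if (nrow(pos)) pos <- pos[seq_len(nNodes), , drop = FALSE]
  new("Tissue", parent = parent, nMut = nMut,
      mutOffset = cumsum(c(0, nMut))[seq_len(nNodes)],
      alive = as.integer(aliveIds), pos = pos,
      divisions = divisions, branchings = branchings,
      divisionLog = divLog[seq_len(divisions)], config = config)
}

# cumulative mutations from root to each node (root path sum)
.cumMutations <- function(tissue) {
  n <- length(tissue@parent)
  cm <- numeric(n)
  for (i in seq_len(n)) {
    p <- tissue@parent[i]
    cm[i] <- tissue@nMut[i] + if (p > 0L) cm[p] else 0
  }
  cm
}

# divisions from root to each node
.nodeDepths <- function(tissue) {
  n <- length(tissue@parent)
  d <- integer(n)
  for (i in seq_len(n)) {
    p <- tissue@parent[i]
    d[i] <- if (p > 0L) d[p] + 1L else 0L
  }
  d
}

# lowest common ancestor of two nodes via depth-aligned walking
.lca <- function(a, b, parent, depth) {
  while (depth[a] > depth[b]) a <- parent[a]
  while (depth[b] > depth[a]) b <- parent[b]
  while (a != b) { a <- parent[a]; b <- parent[b] }
  a
}

#' Mutation identifiers carried by a single cell
#'
#' The union of the novel mutations of every node on the cell's root path.
#' Identifiers are the integers assigned at birth.
#'
#' @param tissue a [Tissue-class].
#' @param node node id.
#' @return integer vector of mutation identifiers.
#' @export
cellMutations <- function(tissue, node) {
  stopifnot(is(tissue, "Tissue"))
  if (node < 1L || node > length(tissue@parent)) stop("unknown node id")
  ids <- integer(0)
  while (node > 0L) {
    k <- tissue@nMut[node]
    if (k > 0L) ids <- c(ids, tissue@mutOffset[node] + seq_len(k))
    node <- tissue@parent[node]
  }
  sort(as.integer(ids))
}

#' Take biopsy samples from a simulated tissue
#'
#' In the spatial modes each sample is a contiguous patch of cells grown
#' outwards from a seed cell; seed cells are chosen by greedy
#' farthest-point ("maximal-distance") placement, which maximises the
#' pairwise spatial separation of the biopsies, or at random.  In
#' well-mixed mode cells are drawn uniformly without replacement.  Samples
#' are disjoint.
#'
#' @param tissue a [Tissue-class].
#' @param nSamples number of biopsies.
#' @param cellsPerSample cells per biopsy (1 gives single-cell samples).
#' @param strategy `"maximal-distance"` (default) or `"random"`; ignored in
#'   well-mixed mode.
#' @return list of [BulkSample-class] objects.
#' @export
takeSamples <- function(tissue, nSamples, cellsPerSample = 1L,
                        strategy = c("maximal-distance", "random")) {
  stopifnot(is(tissue, "Tissue"))
  strategy <- match.arg(strategy)
  alive <- tissue@alive
  if (nSamples * cellsPerSample > length(alive))
    stop("requested more cells than are alive in the tissue")
  spatial <- tissue@config@mode != "well-mixed"
  if (!spatial) {
    picked <- sample(alive, nSamples * cellsPerSample)
    idx <- split(picked, rep(seq_len(nSamples), each = cellsPerSample))
    return(lapply(idx, function(cells)
      new("BulkSample", cells = as.integer(sort(cells)), center = numeric(0))))
  }
  P <- tissue@pos[alive, , drop = FALSE]
  nA <- nrow(P)
  centers <- integer(nSamples)  # indices into `alive`
  if (strategy == "random") {
    centers <- sample.int(nA, nSamples)
  } else {
    centers[1L] <- sample.int(nA, 1L)
    minD <- rowSums((P - matrix(P[centers[1L], ], nA, ncol(P),
                                byrow = TRUE))^2)
    if (nSamples > 1L) for (s in 2:nSamples) {
      centers[s] <- which.max(minD)
      minD <- pmin(minD, rowSums((P - matrix(P[centers[s], ], nA, ncol(P),
                                             byrow = TRUE))^2))
    }
  }
  taken <- logical(nA)
  out <- vector("list", nSamples)
  for (s in seq_len(nSamples)) {
    c0 <- P[centers[s], ]
    d2 <- rowSums((P - matrix(c0, nA, ncol(P), byrow = TRUE))^2)
    d2[taken] <- Inf
    sel <- order(d2)[seq_len(cellsPerSample)]
    if (any(!is.finite(d2[sel])))
      stop("not enough unsampled cells near sample centre")
    taken[sel] <- TRUE
    out[[s]] <- new("BulkSample", cells = as.integer(sort(alive[sel])),
                    center = as.numeric(c0))
  }
  names(out) <- sprintf("S%03d", seq_len(nSamples))
  out
}

#' Per-mutation cell fractions within a biopsy
#'
#' For every mutation carried by at least one sampled cell, the fraction
#' of the biopsy's cells that carry it, computed from the lineage record.
#'
#' @param tissue a [Tissue-class].
#' @param sample a [BulkSample-class] drawn from `tissue`.
#' @return data.frame with columns `mutation` (integer id) and `fraction`.
#' @export
mutationFractions <- function(tissue, sample) {
  stopifnot(is(tissue, "Tissue"), is(sample, "BulkSample"))
  cells <- sample@cells
  if (!all(cells %in% tissue@alive))
    stop("the sample does not originate from this tissue")
  cnt <- integer(length(tissue@parent))
  for (cell in cells) {
    n <- cell
    while (n > 0L) { cnt[n] <- cnt[n] + 1L; n <- tissue@parent[n] }
  }
  carriers <- which(cnt > 0L & tissue@nMut > 0L)
  if (!length(carriers))
    return(data.frame(mutation = integer(0), fraction = numeric(0)))
  muts <- unlist(lapply(carriers, function(n)
    tissue@mutOffset[n] + seq_len(tissue@nMut[n])), use.names = FALSE)
  frac <- rep(cnt[carriers] / length(cells), times = tissue@nMut[carriers])
  data.frame(mutation = as.integer(muts), fraction = frac)
}

#' Simulate sequencing noise for a biopsy
#'
#' Per mutation, the sequencing depth is Poisson with the configured mean
#' and the variant read count is binomial in the depth with success
#' probability equal to the mutation's cell fraction (halved for
#' heterozygous variants when the diploid flag is set).  Rows with zero
#' sampled depth are emitted with missing VAF.
#'
#' @param fractions data.frame with columns `mutation` and `fraction`
#'   (from [mutationFractions()]).
#' @param seq a [SeqConfig-class].
#' @param seed optional integer seed.
#' @return data.frame with columns `mutation`, `depth`, `altReads`, `vaf`.
#' @export
sequencingNoise <- function(fractions, seq = seqConfig(), seed = NULL) {
  stopifnot(is(seq, "SeqConfig"),
            all(c("mutation", "fraction") %in% names(fractions)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fractions)
  f <- fractions$fraction
  if (seq@diploid) f <- f / 2
  depth <- rpois(n, seq@meanDepth)
  alt <- rbinom(n, depth, f)
  vaf <- ifelse(depth > 0L, alt / depth, NA_real_)
  data.frame(mutation = fractions$mutation, depth = depth,
             altReads = alt, vaf = vaf)
}

#' Clonal mutation profile of a sequenced biopsy
#'
#' Mutations whose observed cell fraction (VAF, doubled when the data are
#' diploid/heterozygous) reaches the clonality threshold form the sample's
#' MRCA genotype.  A threshold of 0 keeps every detected mutation (at
#' least one variant read).
#'
#' @param noisyTable data.frame from [sequencingNoise()].
#' @param threshold clonality cut-off on the cell-fraction scale
#'   (default 0.3).
#' @param diploid whether VAFs are on the half-fraction scale.
#' @return integer vector of mutation identifiers (the sample profile).
#' @export
clonalProfile <- function(noisyTable, threshold = 0.3, diploid = FALSE) {
  stopifnot(all(c("mutation", "altReads", "vaf") %in% names(noisyTable)))
  frac <- noisyTable$vaf * if (diploid) 2 else 1
  keep <- !is.na(frac) & noisyTable$altReads > 0L & frac >= threshold
  sort(noisyTable$mutation[keep])
}

#' Exact MRCA profiles of a set of biopsies
#'
#' Uses the recorded lineage tree: each sample's MRCA node is the lowest
#' common ancestor of its cells, and its genotype is the mutation set of
#' that node's root path.  This is the no-noise reference the sequencing
#' path should reproduce.
#'
#' @param tissue a [Tissue-class].
#' @param samples list of [BulkSample-class] objects.
#' @return named list of integer mutation-identifier vectors.
#' @export
sampleProfiles <- function(tissue, samples) {
  stopifnot(is(tissue, "Tissue"))
  depth <- .nodeDepths(tissue)
  nodes <- vapply(samples, function(s) {
    if (!all(s@cells %in% tissue@alive))
      stop("a sample does not originate from this tissue")
    Reduce(function(a, b) .lca(a, b, tissue@parent, depth), s@cells)
  }, numeric(1))
  prof <- lapply(nodes, function(n) cellMutations(tissue, n))
  if (is.null(names(prof)))
    names(prof) <- sprintf("S%03d", seq_along(prof))
  prof
}

#' Ground-truth mutational-distance histogram
#'
#' All pairwise mutational distances among the sample MRCA cells, read
#' directly off the recorded lineage tree (no reconstruction noise): for
#' each pair of MRCA nodes the two distances are the mutation counts on
#' the paths from the pair's common ancestor to either node.
#'
#' @param tissue a [Tissue-class].
#' @param samples list of [BulkSample-class] objects from `tissue`.
#' @return A [DistanceHistogram-class].
#' @export
groundTruthDistances <- function(tissue, samples) {
  stopifnot(is(tissue, "Tissue"), length(samples) >= 2L)
  depth <- .nodeDepths(tissue)
  cm <- .cumMutations(tissue)
  mrca <- vapply(samples, function(s) {
    if (!all(s@cells %in% tissue@alive))
      stop("a sample does not originate from this tissue")
    Reduce(function(a, b) .lca(a, b, tissue@parent, depth), s@cells)
  }, numeric(1))
  n <- length(mrca)
  dists <- numeric(n * (n - 1L))
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    l <- .lca(mrca[i], mrca[j], tissue@parent, depth)
    dists[k + 1L] <- cm[mrca[i]] - cm[l]
    dists[k + 2L] <- cm[mrca[j]] - cm[l]
    k <- k + 2L
  }
  distanceHistogram(as.integer(dists[seq_len(k)]))
}

#' Reconstructable ancestral cells and their mutational ages
#'
#' For every unordered pair of samples, the pair's common-ancestor cell is
#' located on the recorded lineage tree; its mutational age is the number
#' of mutations separating it from the global MRCA of all samples.  Pairs
#' coalescing at the global MRCA itself carry no ancestral information
#' (the coalescent model is normalised over ancestors at least one
#' branching division after founding) and are dropped.  Following the
#' treatment of real single-cell phylogenies, only the `maxAncestors`
#' earliest distinct ancestral cells (smallest mutational age, the
#' molecular-clock proxy for time) are retained.
#'
#' @param tissue a [Tissue-class].
#' @param samples list of [BulkSample-class] objects from `tissue`.
#' @param maxAncestors number of earliest distinct ancestral cells kept
#'   (default 20, matching the early-development analyses; `Inf` keeps
#'   all).
#' @return data.frame with one row per distinct ancestral cell: `node`
#'   (lineage node id), `age` (mutations since the global MRCA) and
#'   `nPairs` (number of sample pairs coalescing there).
#' @export
ancestralCells <- function(tissue, samples, maxAncestors = 20) {
  stopifnot(is(tissue, "Tissue"), length(samples) >= 2L)
  if (maxAncestors < 1) stop("'maxAncestors' must be >= 1")
  depth <- .nodeDepths(tissue)
  cm <- .cumMutations(tissue)
  mrca <- vapply(samples, function(s) {
    if (!all(s@cells %in% tissue@alive))
      stop("a sample does not originate from this tissue")
    Reduce(function(a, b) .lca(a, b, tissue@parent, depth), s@cells)
  }, numeric(1))
  g <- Reduce(function(a, b) .lca(a, b, tissue@parent, depth), mrca)
  n <- length(mrca)
  ls <- numeric(n * (n - 1L) / 2); k <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    l <- .lca(mrca[i], mrca[j], tissue@parent, depth)
    if (l != g) { k <- k + 1L; ls[k] <- l }
  }
  if (k == 0L)
    stop("all sample pairs coalesce at the global MRCA; take more or ",
         "finer samples")
  ls <- ls[seq_len(k)]
  tab <- table(ls)
  nodes <- as.numeric(names(tab))
  df <- data.frame(node = nodes, age = cm[nodes] - cm[g],
                   nPairs = as.numeric(tab))
  df <- df[order(df$age, depth[df$node]), ]
  df <- df[seq_len(min(maxAncestors, nrow(df))), ]
  rownames(df) <- NULL
  df
}

#' Ancestor-age distance histogram from the lineage record
#'
#' Exact counterpart of [ancestorAgeHistogram()] computed from the
#' recorded lineage tree: the mutational ages of the earliest
#' reconstructable ancestral cells (see [ancestralCells()]), each counted
#' once per sample pair coalescing there.  The pair multiplicity carries
#' the coalescent weighting of the pair model; distances from pairs
#' sharing an ancestor are correlated, so goodness-of-fit tests should use
#' the number of distinct ancestors as the effective sample size (see
#' [distanceGOF()]).  This is the histogram consumed by the
#' parameter-recovery validation.
#'
#' @param tissue a [Tissue-class].
#' @param samples list of [BulkSample-class] objects from `tissue`.
#' @param maxAncestors earliest distinct ancestors kept (default 20).
#' @return A [DistanceHistogram-class].
#' @export
ancestralDistanceHistogram <- function(tissue, samples, maxAncestors = 20) {
  anc <- ancestralCells(tissue, samples, maxAncestors)
  distanceHistogram(rep(as.integer(anc$age), times = anc$nPairs))
}

#' Genealogy of a set of samples as a phylogenetic tree
#'
#' The lineage tree induced by the sample MRCA cells, with branch lengths
#' in mutations: internal nodes are the ancestral cells detectable from
#' the samples, i.e. the common ancestors at which sampled lineages
#' coalesce.  Requires that no sample MRCA is an ancestor of another
#' (guaranteed for single-cell samples).
#'
#' @param tissue a [Tissue-class].
#' @param samples list of [BulkSample-class] objects.
#' @return an [ape::phylo] tree whose tips are the samples.
#' @export
sampleGenealogy <- function(tissue, samples) {
  stopifnot(is(tissue, "Tissue"), length(samples) >= 2L)
  depth <- .nodeDepths(tissue)
  cm <- .cumMutations(tissue)
  parent <- tissue@parent
  tipNodes <- vapply(samples, function(s) {
    Reduce(function(a, b) .lca(a, b, parent, depth), s@cells)
  }, numeric(1))
  if (anyDuplicated(tipNodes))
    stop("two samples share the same MRCA cell; genealogy tips must be distinct")
  # count sampled lineages passing through each node
  cnt <- integer(length(parent))
  for (tn in tipNodes) {
    n <- tn
    while (n > 0L) { cnt[n] <- cnt[n] + 1L; n <- parent[n] }
  }
  isTip <- logical(length(parent)); isTip[tipNodes] <- TRUE
  if (any(cnt[tipNodes] > 1L))
    stop("a sample MRCA is ancestral to another sample; use finer samples")
  kids <- split(seq_along(parent)[parent > 0L], parent[parent > 0L])
  nTips <- length(tipNodes)
  edges <- matrix(0L, nrow = 0, ncol = 2)
  lens <- numeric(0)
  nextInternal <- nTips + 1L
  tipIndex <- setNames(seq_len(nTips), as.character(tipNodes))
  # iterative reduction from the global root
  # returns the phylo node id assigned to the reduced subtree root
  reduce <- function(node) {
    repeat {
      if (isTip[node]) return(tipIndex[[as.character(node)]])
      ch <- kids[[as.character(node)]]
      ch <- ch[cnt[ch] > 0L]
      if (length(ch) >= 2L) break
      node <- ch  # unary chain: skip through
    }
    id <- nextInternal; nextInternal <<- nextInternal + 1L
    ch <- kids[[as.character(node)]]
    ch <- ch[cnt[ch] > 0L]
    for (c0 in ch) {
      # descend to the next kept node to compute the branch length
      sub <- c0
      repeat {
        if (isTip[sub]) break
        sch <- kids[[as.character(sub)]]
        sch <- sch[cnt[sch] > 0L]
        if (length(sch) >= 2L) break
        sub <- sch
      }
      childId <- reduce(sub)
      edges <<- rbind(edges, c(id, childId))
      lens <<- c(lens, cm[sub] - cm[node])
    }
    id
  }
  if (cnt[1L] < nTips) stop("internal error: root not ancestral to all tips")
  # skip down to the MRCA of all tips
  start <- 1L
  repeat {
    if (isTip[start]) break
    ch <- kids[[as.character(start)]]
    ch <- ch[cnt[ch] > 0L]
    if (length(ch) >= 2L) break
    start <- ch
  }
  reduce(start)
  labels <- names(samples)
  if (is.null(labels)) labels <- sprintf("S%03d", seq_len(nTips))
  tr <- list(edge = edges, edge.length = lens, tip.label = labels,
             Nnode = nextInternal - (nTips + 1L))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}
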