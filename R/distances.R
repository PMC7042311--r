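# Reconstruction of ancestral mutational profiles and observed
# mutational-distance histograms.
#
# A sample profile is the set of mutations clonal to a bulk sample, i.e.
# the genotype of the sample's most recent common ancestor cell.  The
# intersection of two profiles is the genotype of a yet more ancestral
# cell, and the two set differences are the mutational distances of the
# pair to that ancestor.

#' Mutational distances between two sample profiles
#'
#' For profiles `A` and `B` (sets of mutation identifiers) the two
#' distances to their common ancestor `A` intersect `B` are
#' `y1 = |A \\ (A n B)|` and `y2 = |B \\ (A n B)|`.
#'
#' @param a,b character (or integer) vectors of mutation identifiers;
#'   duplicates are ignored (set semantics).
#' @return integer vector `c(y1, y2)`.
#' @examples
#' pairwiseDistances(c("a", "b", "c"), c("b", "c", "d", "e"))  # 1, 2
#' @export
pairwiseDistances <- function(a, b) {
  a <- unique(a); b <- unique(b)
  common <- sum(a %in% b)
  c(length(a) - common, length(b) - common)
}

#' Genotype of the common ancestor of a set of samples
#'
#' The intersection of all profiles: mutations present in every sample's
#' MRCA were present in their joint ancestor.
#'
#' @param profiles non-empty list of mutation-identifier vectors.
#' @return vector of mutation identifiers (possibly empty).
#' @export
ancestralProfile <- function(profiles) {
  if (length(profiles) == 0L) stop("'profiles' must be non-empty")
  Reduce(intersect, lapply(profiles, unique))
}

#' Histogram of pairwise mutational distances among sample profiles
#'
#' Records both distances of every unordered pair of ancestral profiles.
#' With `combinationDepth = 2` (default) the ancestral profiles are the
#' sample MRCAs themselves and all sample pairs are compared.  Larger
#' depths add intersections of all k-subsets (k < depth) to the pool of
#' ancestral profiles before pairing, iterating the reconstruction of ever
#' deeper ancestors.  Distances are pooled over all pairs; pairs sharing
#' ancestry are correlated, an approximation inherited from the model's
#' pair-coalescent derivation.
#'
#' @param profiles named list (>= 2) of mutation-identifier vectors.
#' @param combinationDepth maximum subset size whose intersections enter
#'   the ancestral pool (default 2: sample profiles only).
#' @return A [DistanceHistogram-class].
#' @examples
#' buildHistogram(list(s1 = c("a", "b", "c"), s2 = c("b", "c", "d", "e")))
#' @export
buildHistogram <- function(profiles, combinationDepth = 2L) {
  if (length(profiles) < 2L) stop("at least 2 profiles are required")
  if (combinationDepth < 2L) stop("'combinationDepth' must be >= 2")
  profiles <- lapply(profiles, unique)
  pool <- profiles
  if (combinationDepth > 2L) {
    for (k in 2:(combinationDepth - 1L)) {
      if (k > length(profiles)) break
      idx <- utils::combn(length(profiles), k, simplify = FALSE)
      anc <- lapply(idx, function(j) ancestralProfile(profiles[j]))
      pool <- c(pool, anc)
    }
    # deduplicate identical ancestral genotypes
    key <- vapply(pool, function(s) paste(sort(s), collapse = "\r"),
                  character(1))
    pool <- pool[!duplicated(key)]
  }
  n <- length(pool)
  dists <- integer(n * (n - 1L))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- pairwiseDistances(pool[[i]], pool[[j]])
      dists[k + 1:2] <- d
      k <- k + 2L
    }
  }
  distanceHistogram(dists[seq_len(k)])
}

#' Mutational ages of reconstructed ancestral cells
#'
#' The inference-facing summary of a multi-sample dataset.  The
#' intersection of all profiles is the genotype `G` of the global MRCA;
#' for each unordered pair of samples the intersection `A` n `B` is the
#' genotype of the pair's own common ancestor, and its mutational age
#' `y = |(A n B) \\ G|` counts the mutations separating that ancestor
#' from the global MRCA.  Pairs whose common ancestor coincides with the
#' global MRCA are excluded: the coalescent model is normalised over
#' ancestors at least one branching division after the founding cell.
#' Ancestors shared by several pairs are counted once per pair, which is
#' the coalescent weighting of the pair model; distances from pairs
#' sharing ancestry are therefore correlated (a pooling approximation
#' inherited from the model).
#'
#' Only the `maxAncestors` earliest distinct ancestral genotypes (smallest
#' age — the molecular-clock proxy for time) are retained, following the
#' restriction to the earliest branching events used for real
#' developmental phylogenies.
#'
#' @param profiles named list (>= 2) of mutation-identifier vectors.
#' @param maxAncestors earliest distinct ancestral genotypes kept
#'   (default 20; `Inf` keeps all).
#' @return A [DistanceHistogram-class].
#' @seealso [ancestralDistanceHistogram()] for the lineage-record
#'   equivalent on simulated tissues.
#' @export
ancestorAgeHistogram <- function(profiles, maxAncestors = 20) {
  if (length(profiles) < 2L) stop("at least 2 profiles are required")
  if (maxAncestors < 1) stop("'maxAncestors' must be >= 1")
  profiles <- lapply(profiles, unique)
  g <- ancestralProfile(profiles)
  n <- length(profiles)
  key <- character(0); age <- integer(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    anc <- intersect(profiles[[i]], profiles[[j]])
    y <- length(anc) - length(g)
    if (y > 0L) {  # G is a subset of every pair intersection
      key <- c(key, paste(sort(anc), collapse = "\r"))
      age <- c(age, y)
    }
  }
  if (!length(age))
    stop("all sample pairs coalesce at the global MRCA; no ancestral ",
         "ages to histogram")
  first <- !duplicated(key)
  keep <- key[first][order(age[first])]
  keep <- keep[seq_len(min(maxAncestors, length(keep)))]
  distanceHistogram(age[key %in% keep])
}

#' Sibling mutational distances from a lineage tree
#'
#' For single-cell data the phylogeny itself records the ancestral cells:
#' every internal node is an ancestor and its two child branch lengths (in
#' mutations) are the distances of the two daughter lineages to it.  The
#' histogram is restricted to the `maxBranchings` earliest branching
#' events, ranked by cumulative mutations from the root (a molecular-clock
#' proxy for time, since calendar times are unavailable).  Polytomies are
#' resolved into ladders of zero-length branches (with a message), which
#' contributes one zero distance per extra child, consistent with
#' unresolved simultaneous-looking divisions.
#'
#' @param tree an [ape::phylo] tree whose branch lengths are integer
#'   mutation counts (non-integer lengths are rounded with a warning).
#' @param maxBranchings number of earliest branching events to use
#'   (default all).
#' @return A [DistanceHistogram-class].
#' @examples
#' tr <- ape::read.tree(text = "(a:3,b:5);")
#' treeDistances(tr)
#' @export
treeDistances <- function(tree, maxBranchings = Inf) {
  stopifnot(inherits(tree, "phylo"))
  if (maxBranchings < 1) stop("'maxBranchings' must be >= 1")
  if (is.null(tree$edge.length))
    stop("the tree must carry branch lengths (mutation counts)")
  if (any(abs(tree$edge.length - round(tree$edge.length)) > 1e-8)) {
    warning("non-integer branch lengths rounded to mutation counts",
            call. = FALSE)
  }
  tree$edge.length <- round(tree$edge.length)
  if (!ape::is.binary(tree) || !ape::is.rooted(tree) ||
      any(tabulate(tree$edge[, 1L]) > 2L)) {
    message("resolving polytomies as zero-length ladder expansions")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  nTips <- length(tree$tip.label)
  rootDist <- ape::node.depth.edgelength(tree)  # mutations from root
  internal <- (nTips + 1L):(nTips + tree$Nnode)
  internal <- internal[order(rootDist[internal])]
  use <- internal[seq_len(min(maxBranchings, length(internal)))]
  childLens <- tree$edge.length[tree$edge[, 1L] %in% use]
  distanceHistogram(as.integer(childLens))
}
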