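# Readers, writers and the pipeline driver tying the modules together.

# polynomial rolling hash of a deparsed object; embedded in output
# headers so that a result file identifies the configuration that
# produced it.
.configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.outputHeader <- function(config, seed) {
  c(sprintf("# mutdist %s", as.character(utils::packageVersion("mutdist"))),
    sprintf("# seed: %s", if (is.null(seed) || is.na(seed)) "NA" else seed),
    sprintf("# config: %s", .configHash(config)))
}

#' Read sample mutation profiles
#'
#' Two formats are supported.  `"tsv"`: a presence matrix with mutation
#' identifiers in the first column (or as row names) and one 0/1 column
#' per sample.  `"vcf"`: a multi-sample VCF; a variant belongs to a
#' sample's profile when its genotype contains a non-reference allele;
#' variants with missing genotypes are excluded from that sample with a
#' warning.  VCF mutation identifiers are `chrom:pos:ref:alt` (1-based).
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"` (default: by file extension).
#' @return named list of mutation-identifier vectors.
#' @export
readProfiles <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  format <- match.arg(format, c("tsv", "vcf"))
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
    if (!is.numeric(df[[1L]])) {
      ids <- as.character(df[[1L]])
      df <- df[, -1L, drop = FALSE]
    } else ids <- rownames(df)
    if (anyDuplicated(ids)) stop("duplicate mutation identifiers in ", path)
    lapply(as.list(df), function(col) ids[col != 0])
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
                 sep = ":")
    gt <- vcfR::extract.gt(v, element = "GT")
    if (anyNA(gt))
      warning(sum(is.na(gt)), " missing genotype call(s) excluded",
              call. = FALSE)
    out <- lapply(seq_len(ncol(gt)), function(j) {
      g <- gt[, j]
      present <- !is.na(g) & grepl("[1-9]", g)
      ids[present]
    })
    names(out) <- colnames(gt)
    out
  }
}

#' Write sample profiles as a presence matrix
#'
#' @param profiles named list of mutation-identifier vectors.
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
writeProfiles <- function(profiles, path) {
  ids <- sort(unique(unlist(profiles, use.names = FALSE)))
  m <- vapply(profiles, function(p) as.integer(ids %in% p),
              integer(length(ids)))
  df <- data.frame(mutation = ids, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a distance histogram as two-column CSV
#'
#' Columns `y, count`; comment lines starting with `#` are ignored.
#'
#' @param path CSV file.
#' @return A [DistanceHistogram-class].
#' @export
readHistogram <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  distanceHistogram(df$y, df$count)
}

#' @param hist a [DistanceHistogram-class].
#' @param header optional character vector of comment lines.
#' @rdname readHistogram
#' @export
writeHistogram <- function(hist, path, header = NULL) {
  stopifnot(is(hist, "DistanceHistogram"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.csv(data.frame(y = hist@y, count = hist@count), con,
                   row.names = FALSE)
  invisible(path)
}

#' Read a lineage tree from newick
#'
#' Branch lengths are interpreted as integer mutation counts; non-integer
#' lengths are rounded with a warning.
#'
#' @param path newick file.
#' @return an [ape::phylo] tree.
#' @export
readLineageTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length))
    stop("the tree in ", path, " has no branch lengths")
  if (any(abs(tr$edge.length - round(tr$edge.length)) > 1e-8))
    warning("non-integer branch lengths rounded to mutation counts",
            call. = FALSE)
  tr$edge.length <- round(tr$edge.length)
  tr
}

#' Write noisy variant tables for a set of biopsies
#'
#' One row per mutation per sample: `mutation, depth, alt_reads, vaf,
#' sample`.
#'
#' @param tissue a [Tissue-class].
#' @param samples list of [BulkSample-class].
#' @param seq a [SeqConfig-class].
#' @param path output TSV.
#' @param seed optional integer seed for the noise draws.
#' @return invisibly, the combined data.frame.
#' @export
writeVariantTable <- function(tissue, samples, seq = seqConfig(), path,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tabs <- lapply(seq_along(samples), function(i) {
    fr <- mutationFractions(tissue, samples[[i]])
    nt <- sequencingNoise(fr, seq)
    nt$sample <- if (!is.null(names(samples))) names(samples)[i]
                 else sprintf("S%03d", i)
    nt
  })
  out <- do.call(rbind, tabs)
  names(out) <- c("mutation", "depth", "alt_reads", "vaf", "sample")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.outputHeader(seq, seed), con)
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Run a pipeline stage
#'
#' Dispatches the named subcommand on a configuration list and writes its
#' artifacts (CSV/TSV/JSON with seed and config-hash headers).  This is
#' the programmatic core behind the `exec/mutdist` command-line script.
#'
#' Subcommands and their settings:
#' \describe{
#'   \item{simulate}{`muL`, `beta`, `targetCells`, `mode`, `nSamples`,
#'     `cellsPerSample`, `meanDepth`, `out` (variant TSV),
#'     `treeOut` (optional newick of the sample genealogy).}
#'   \item{distances}{`profiles` (TSV/VCF path), `combinationDepth`,
#'     `out` (histogram CSV).}
#'   \item{infer}{`histogram` (CSV path), `L`, `effectiveL` (scaling for
#'     callable genome / copy number; multiplies `L`), MCMC settings
#'     (`nSteps`, `burnIn`, `hwMuL`, `hwBeta`, `priorMuL`, `priorBeta`,
#'     `rMax`, `iMax`), `out` (summary JSON), `chainOut` (optional CSV).}
#'   \item{recover}{`grid` (data.frame or CSV path with muL, beta),
#'     `targetCells`, `nSamples`, `cellsPerSample`, `mode`, MCMC settings,
#'     `out` (report CSV).}
#'   \item{signatures}{`profiles`, `channels` (TSV path mapping mutation
#'     to channel), `signatures` (TSV matrix path), `outPrefix`.}
#' }
#'
#' @param config named list with at least `subcommand` and `seed`.
#' @return invisibly, the subcommand's main result object.
#' @export
runPipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$subcommand))
  seed <- if (is.null(config$seed)) NA_integer_ else as.integer(config$seed)
  hdr <- .outputHeader(config, seed)
  cfg <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  mcfgFrom <- function(chainSeed) {
    mcmcConfig(
      nSteps = cfg("nSteps", 5000L), burnIn = cfg("burnIn", 200L),
      hwMuL = cfg("hwMuL", 0.15), hwBeta = cfg("hwBeta", 0.06),
      priorMuL = cfg("priorMuL", c(0.01, 100)),
      priorBeta = cfg("priorBeta", c(0.05, 1)),
      trunc = truncationLimits(cfg("rMax", 30L), cfg("iMax", 30L)),
      seed = chainSeed)
  }
  switch(config$subcommand,
    simulate = {
      sc <- simConfig(mode = cfg("mode", "well-mixed"),
                      targetCells = cfg("targetCells", 1e4),
                      muL = config$muL, beta = config$beta, seed = seed)
      tissue <- simulateTissue(sc)
      samples <- takeSamples(tissue, cfg("nSamples", 10L),
                             cfg("cellsPerSample", 10L))
      if (!is.null(config$out))
        writeVariantTable(tissue, samples,
                          seqConfig(meanDepth = cfg("meanDepth", 100)),
                          config$out,
                          seed = if (is.na(seed)) NULL else seed + 1L)
      if (!is.null(config$treeOut)) {
        tr <- sampleGenealogy(tissue, samples)
        ape::write.tree(tr, config$treeOut)
      }
      invisible(tissue)
    },
    distances = {
      profiles <- readProfiles(config$profiles)
      hist <- buildHistogram(profiles, cfg("combinationDepth", 2L))
      if (!is.null(config$out)) writeHistogram(hist, config$out, header = hdr)
      invisible(hist)
    },
    infer = {
      hist <- if (is(config$histogram, "DistanceHistogram")) config$histogram
              else readHistogram(config$histogram)
      L <- cfg("L", 3e9) * cfg("effectiveL", 1)
      chain <- runMCMC(hist, mcfgFrom(seed), init = cfg("init", "grid"))
      sm <- summarizePosterior(chain, L = L)
      if (!is.null(config$chainOut)) {
        con <- file(config$chainOut, "w"); writeLines(hdr, con)
        utils::write.csv(chainDraws(chain), con, row.names = FALSE)
        close(con)
      }
      if (!is.null(config$out)) {
        out <- c(sm, list(seed = seed, configHash = .configHash(config),
                          version = as.character(
                            utils::packageVersion("mutdist"))))
        jsonlite::write_json(out, config$out, auto_unbox = TRUE, digits = NA)
      }
      invisible(sm)
    },
    recover = {
      grid <- if (is.data.frame(config$grid)) config$grid
              else utils::read.csv(config$grid, comment.char = "#")
      rec <- recoveryExperiment(
        grid, targetCells = cfg("targetCells", 1e4),
        nSamples = cfg("nSamples", 200L),
        cellsPerSample = cfg("cellsPerSample", 1L),
        mode = cfg("mode", "well-mixed"),
        nTissues = cfg("nTissues", 5L),
        maxAncestors = cfg("maxAncestors", 20),
        config = mcfgFrom(NA_integer_),
        seed = if (is.na(seed)) 1L else seed)
      if (!is.null(config$out)) {
        con <- file(config$out, "w"); writeLines(hdr, con)
        utils::write.csv(rec$results, con, row.names = FALSE)
        close(con)
      }
      invisible(rec)
    },
    signatures = {
      profiles <- readProfiles(config$profiles)
      chanMap <- utils::read.delim(config$channels, comment.char = "#")
      channels <- setNames(as.character(chanMap[[2L]]),
                           as.character(chanMap[[1L]]))
      sigs <- readSignatureMatrix(config$signatures)
      assignments <- assignMutations(channels, sigs)
      hists <- stratifiedHistograms(profiles, assignments)
      if (!is.null(config$outPrefix)) {
        for (s in names(hists))
          writeHistogram(hists[[s]],
                         paste0(config$outPrefix, "_", gsub("\\W", "_", s),
                                ".csv"), header = hdr)
      }
      invisible(hists)
    },
    stop("unknown subcommand: ", config$subcommand))
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Command-line flags override file values; the file supplies defaults.
#'
#' @param path YAML or JSON file.
#' @param overrides named list merged over the file contents.
#' @return named list suitable for [runPipeline()].
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  base <- if (is.null(path)) list()
          else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                simplifyVector = TRUE)
          else yaml::read_yaml(path)
  utils::modifyList(base, overrides[!vapply(overrides, is.null, logical(1))])
}
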