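## Composition-based binning: oligonucleotide frequency profiles, Pearson
## correlation, average-linkage clustering, marker-seeded cluster
## extraction, size/read filters, and the duplication-driven subdivision
## loop.

#' Oligonucleotide frequency profile of a sequence
#'
#' Computes strand-merged (canonical) k-mer frequencies for each k in
#' \code{kSet}, normalises each per-k block to sum to one, and concatenates
#' the blocks. Windows containing letters outside A/C/G/T (e.g. N) are
#' skipped. The profile is invariant under reverse complement of the input.
#'
#' @param sequence a character string, [Biostrings::DNAString] or
#'   length-one [Biostrings::DNAStringSet].
#' @param kSet integer vector of word sizes; default 3:6, i.e. tri- through
#'   hexanucleotides.
#' @return named numeric vector; names are \code{"k<k>_<word>"}.
#' @export
kmerProfile <- function(sequence, kSet = 3:6) {
  if (is(sequence, "DNAStringSet")) sequence <- sequence[[1L]]
  s <- Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(s) <= max(kSet))
    stop("sequence shorter than the largest word size")
  rc <- Biostrings::reverseComplement(s)
  blocks <- lapply(kSet, function(k) {
    cnt <- Biostrings::oligonucleotideFrequency(s, width = k) +
      Biostrings::oligonucleotideFrequency(rc, width = k)
    tot <- sum(cnt)
    v <- if (tot > 0) cnt / tot else cnt * 0
    names(v) <- paste0("k", k, "_", names(v))
    v
  })
  unlist(blocks)
}

#' Oligonucleotide profiles for a set of scaffolds
#'
#' @param seqs a [Biostrings::DNAStringSet].
#' @param kSet word sizes as in [kmerProfile()].
#' @return numeric matrix, one row per scaffold.
#' @export
kmerProfiles <- function(seqs, kSet = 3:6) {
  stopifnot(is(seqs, "DNAStringSet"))
  rc <- Biostrings::reverseComplement(seqs)
  blocks <- lapply(kSet, function(k) {
    cnt <- Biostrings::oligonucleotideFrequency(seqs, width = k) +
      Biostrings::oligonucleotideFrequency(rc, width = k)
    tot <- rowSums(cnt)
    v <- cnt / ifelse(tot > 0, tot, 1)
    colnames(v) <- paste0("k", k, "_", colnames(v))
    v
  })
  m <- do.call(cbind, blocks)
  rownames(m) <- names(seqs)
  m
}

#' Pearson correlation between two composition profiles
#'
#' @param p,q equal-length numeric profile vectors.
#' @return the Pearson product-moment correlation, in \eqn{[-1, 1]}.
#' @export
profileCorrelation <- function(p, q) {
  if (length(p) != length(q)) stop("profiles must have equal length")
  if (var(p) == 0 || var(q) == 0)
    stop("profile with zero variance: correlation undefined")
  unname(cor(p, q))
}

#' Hierarchically cluster scaffolds by composition
#'
#' Agglomerative clustering (average linkage) on the distance
#' \eqn{d = 1 - r}, where r is the Pearson correlation between
#' oligonucleotide profiles. Scaffolds at or below \code{minScaffoldBp}
#' are excluded before clustering.
#'
#' @param profiles profile matrix from [kmerProfiles()] (rows = scaffolds).
#' @param lengths named integer vector of scaffold lengths (bp).
#' @param minScaffoldBp length cutoff; scaffolds must be strictly longer.
#' @return an [stats::hclust] tree over the retained scaffolds; a single
#'   retained scaffold yields a degenerate single-leaf tree object that
#'   [extractSeedClusters()] handles as one cluster.
#' @export
clusterScaffolds <- function(profiles, lengths, minScaffoldBp = 3000) {
  keep <- rownames(profiles)[lengths[rownames(profiles)] > minScaffoldBp]
  if (length(keep) == 0L) stop("no scaffolds pass the length filter")
  profiles <- profiles[keep, , drop = FALSE]
  if (length(keep) == 1L) {
    out <- list(labels = keep, singleton = TRUE)
    class(out) <- "flavbin_singleton"
    return(out)
  }
  d <- as.dist(1 - cor(t(profiles)))
  hclust(d, method = "average")
}

## flat clusters at merge height <= 1 - rMin
cutClusters <- function(tree, rMin) {
  if (inherits(tree, "flavbin_singleton"))
    return(setNames(1L, tree$labels))
  cutree(tree, h = 1 - rMin)
}

#' Extract marker-seeded clusters from a composition dendrogram
#'
#' Cuts the dendrogram into flat clusters at merge height
#' \eqn{d \le 1 - r_{min}} and keeps only clusters containing at least one
#' marker-bearing scaffold (scaffolds carrying a single-copy phylogenetic
#' marker identify the clusters worth pursuing).
#'
#' @param tree tree from [clusterScaffolds()].
#' @param markers character vector of marker-bearing scaffold ids.
#' @param lengths,reads named integer vectors over all scaffolds.
#' @param rMin minimum within-cluster Pearson correlation (default 0.90).
#' @return a [BinSet-class]; empty (with a message) when no cluster holds a
#'   marker.
#' @export
extractSeedClusters <- function(tree, markers, lengths, reads, rMin = 0.90) {
  cl <- cutClusters(tree, rMin)
  ids <- split(names(cl), cl)
  seeded <- ids[vapply(ids, function(v) any(v %in% markers), logical(1))]
  if (length(seeded) == 0L) {
    message("no marker-bearing clusters found")
    seeded <- list()
  }
  names(seeded) <- if (length(seeded))
    sprintf("bin%02d", seq_along(seeded)) else character(0)
  newBinSet(seeded, lengths, reads, markers)
}

#' Construct a bin set from explicit membership
#'
#' @param bins named list of character vectors of scaffold ids.
#' @param lengths,reads named integer vectors over all scaffolds.
#' @param markers character vector of marker-bearing scaffold ids.
#' @param unconverged bin ids flagged unconverged by subdivision.
#' @return a [BinSet-class].
#' @export
binSet <- function(bins, lengths, reads, markers = character(0),
                   unconverged = character(0)) {
  newBinSet(bins, lengths, reads, markers, unconverged)
}

newBinSet <- function(bins, lengths, reads, markers = character(0),
                      unconverged = character(0)) {
  new("BinSet", bins = bins,
      scaffoldLength = setNames(as.integer(lengths), names(lengths)),
      scaffoldReads = setNames(as.integer(reads), names(reads)),
      seedMarkers = lapply(bins, function(v) intersect(v, markers)),
      unconverged = unconverged)
}

#' Apply the cumulative-size or read-count bin filters
#'
#' First-pass candidates must exceed the cumulative length of previously
#' sequenced genomes of the group (> 1.9 Mbp, strict). Second-pass
#' candidates are first restricted to scaffolds strictly longer than
#' 5,000 bp and must then contain strictly more than 10,000 reads.
#'
#' @param binSet a [BinSet-class].
#' @param stage \code{"size"} (first pass) or \code{"reads"} (second pass).
#' @param minBp,minReads,minScaffoldBp filter thresholds.
#' @return the filtered [BinSet-class].
#' @export
filterCandidates <- function(binSet, stage = c("size", "reads"),
                             minBp = 1.9e6, minReads = 10000,
                             minScaffoldBp = 5000) {
  stage <- match.arg(stage)
  bins <- binSet@bins
  if (stage == "size") {
    keep <- vapply(bins, function(v)
      sum(binSet@scaffoldLength[v]) > minBp, logical(1))
    bins <- bins[keep]
  } else {
    bins <- lapply(bins, function(v)
      v[binSet@scaffoldLength[v] > minScaffoldBp])
    keep <- vapply(bins, function(v)
      length(v) > 0L && sum(binSet@scaffoldReads[v]) > minReads, logical(1))
    bins <- bins[keep]
  }
  newBinSet(bins, binSet@scaffoldLength, binSet@scaffoldReads,
            unlist(binSet@seedMarkers, use.names = FALSE),
            binSet@unconverged)
}

#' Subdivide a bin until its duplication estimate drops below a cap
#'
#' While the bin's estimated single-copy-gene duplication is at or above
#' \code{dupMax} percent, the bin is split at the root of its internal
#' composition dendrogram (two subtrees) and each part is recursed on.
#' Singleton bins cannot be split and are returned as-is; if the iteration
#' cap is exceeded the current part is returned flagged unconverged.
#'
#' @param members character vector of scaffold ids in the bin.
#' @param profiles profile matrix covering the members.
#' @param qualityFn function(character ids) -> percent duplication.
#' @param dupMax duplication cap in percent (default 10).
#' @param maxIter recursion cap.
#' @return list with \code{bins} (list of character vectors) and
#'   \code{unconverged} (logical per bin).
#' @export
subdivideUntilClean <- function(members, profiles, qualityFn,
                                dupMax = 10.0, maxIter = 32L) {
  recurse <- function(ids, depth) {
    dup <- qualityFn(ids)
    if (dup < dupMax || length(ids) == 1L)
      return(list(list(ids = ids, unconverged = FALSE)))
    if (depth >= maxIter)
      return(list(list(ids = ids, unconverged = TRUE)))
    pr <- profiles[ids, , drop = FALSE]
    tree <- hclust(as.dist(1 - cor(t(pr))), method = "average")
    part <- cutree(tree, k = 2L)
    if (length(unique(part)) < 2L)
      return(list(list(ids = ids, unconverged = TRUE)))
    c(recurse(ids[part == 1L], depth + 1L),
      recurse(ids[part == 2L], depth + 1L))
  }
  out <- recurse(members, 0L)
  list(bins = lapply(out, `[[`, "ids"),
       unconverged = vapply(out, `[[`, logical(1), "unconverged"))
}

#' Purity of a bin assignment against known genome membership
#'
#' Fraction of binned scaffolds whose bin's majority genome matches their
#' own true genome.
#'
#' @param binSet a [BinSet-class].
#' @param scaffoldGenome named character vector: scaffold id -> genome id.
#' @return numeric purity in \eqn{[0, 1]}.
#' @export
binPurity <- function(binSet, scaffoldGenome) {
  tot <- 0L; ok <- 0L
  for (v in binSet@bins) {
    g <- scaffoldGenome[v]
    tab <- table(g)
    ok <- ok + max(tab)
    tot <- tot + length(g)
  }
  if (tot == 0L) return(NA_real_)
  ok / tot
}
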