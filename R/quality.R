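## Bin refinement and quality: taxonomy-vote filtering, duplicate-scaffold
## removal, pangenome core-genome construction, and completeness /
## duplication / genome-size estimation.

#' Remove scaffolds whose CDS taxonomy vote falls below a threshold
#'
#' For each scaffold, the fraction of CDS with a top hit (among CDS that
#' have any hit) assigned to \code{targetPhylum} is computed; scaffolds
#' strictly below \code{minFrac} are removed. Scaffolds with no annotated
#' CDS carry no evidence either way and are retained, flagged
#' \code{"no-evidence"}.
#'
#' @param members character vector of scaffold ids.
#' @param annotations CDS annotation data.frame (needs \code{scaffold_id},
#'   \code{top_hit_phylum}; \code{NA} = no hit).
#' @param targetPhylum phylum the vote is counted for (default
#'   \code{"Bacteroidetes"}).
#' @param minFrac vote threshold, strict \code{<} removal (default 0.60).
#' @return list with \code{kept}, \code{removed} and \code{flagged}
#'   character vectors.
#' @export
taxonomyFilter <- function(members, annotations,
                           targetPhylum = "Bacteroidetes", minFrac = 0.60) {
  ann <- annotations[annotations$scaffold_id %in% members, , drop = FALSE]
  frac <- vapply(members, function(s) {
    hits <- ann$top_hit_phylum[ann$scaffold_id == s]
    hits <- hits[!is.na(hits)]
    if (length(hits) == 0L) return(NA_real_)
    mean(hits == targetPhylum)
  }, numeric(1))
  flagged <- members[is.na(frac)]
  removed <- members[!is.na(frac) & frac < minFrac]
  kept <- setdiff(members, removed)
  list(kept = kept, removed = removed, flagged = flagged)
}

#' Remove duplicated scaffolds by shared gene content
#'
#' Works over an injected homology relation between CDS (pairs of
#' homologous CDS ids, e.g. from a reciprocal protein search). For every
#' pair of scaffolds, if the fraction of the shorter scaffold's genes with
#' a homolog on the longer one is at least \code{minShared}, the shorter
#' scaffold is dropped. Scaffolds are processed longest-first, so the
#' longer member of a pair is always the keeper; length ties are broken
#' lexicographically by id.
#'
#' @param members character vector of scaffold ids.
#' @param lengths named integer vector of scaffold lengths.
#' @param cdsScaffold named character: cds_id -> scaffold_id.
#' @param homologyPairs data.frame with columns \code{cds_a}, \code{cds_b}
#'   (symmetric relation; either orientation accepted).
#' @param minShared shared-gene fraction at which the shorter scaffold is
#'   removed (\code{>=}, default 0.85).
#' @return list with \code{kept} and \code{removed} character vectors.
#' @export
dedupScaffolds <- function(members, lengths, cdsScaffold, homologyPairs,
                           minShared = 0.85) {
  ord <- members[order(-lengths[members], members)]
  pairs <- rbind(
    data.frame(a = homologyPairs$cds_a, b = homologyPairs$cds_b),
    data.frame(a = homologyPairs$cds_b, b = homologyPairs$cds_a)
  )
  genesOf <- split(names(cdsScaffold), unname(cdsScaffold))
  removed <- character(0)
  for (i in seq_along(ord)) {
    keeper <- ord[i]
    if (keeper %in% removed) next
    for (j in seq_along(ord)) {
      if (j <= i) next
      shorter <- ord[j]
      if (shorter %in% removed) next
      genes <- genesOf[[shorter]]
      if (is.null(genes) || length(genes) == 0L) next
      sharedOnKeeper <- genes[genes %in% pairs$a[pairs$b %in% genesOf[[keeper]]]]
      frac <- length(unique(sharedOnKeeper)) / length(unique(genes))
      if (frac >= minShared) removed <- c(removed, shorter)
    }
  }
  list(kept = setdiff(members, removed), removed = removed)
}

#' Build the core genome from a pangenome gene-family count table
#'
#' A gene family enters the core when it occurs (count >= 1) in every
#' member genome; its expected per-genome multiplicity is the minimum count
#' across members. Families at exactly one copy in every member are the
#' conserved single-copy genes (CSCGs).
#'
#' @param counts integer matrix or data.frame, genomes x families.
#' @return a [CoreGenome-class].
#' @export
buildCoreGenome <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("need at least two genomes for a pangenome")
  if (ncol(counts) == 0L || is.null(colnames(counts)))
    stop("counts must have named family columns")
  mins <- apply(counts, 2L, min)
  maxs <- apply(counts, 2L, max)
  core <- mins[mins >= 1L]
  cscg <- colnames(counts)[mins == 1L & maxs == 1L]
  new("CoreGenome", coreCounts = setNames(as.integer(core), names(core)),
      cscg = cscg)
}

#' Count core-gene occurrences identified in a bin
#'
#' Counts, over the bin's CDS annotations, occurrences of each core family
#' capped at the family's expected multiplicity (extra copies are
#' duplication, not completeness), along with the number of CSCG families
#' found more than once.
#'
#' @param members scaffold ids of the bin.
#' @param annotations CDS annotation table with \code{family_ids}.
#' @param core a [CoreGenome-class].
#' @param capped cap per-family counts at the expected multiplicity
#'   (default TRUE).
#' @return list with \code{identified_core} and \code{duplicate_cscgs}
#'   integers.
#' @export
countCoreFamilies <- function(members, annotations, core, capped = TRUE) {
  ann <- annotations[annotations$scaffold_id %in% members, , drop = FALSE]
  fams <- unlist(splitFamilyIds(ann$family_ids), use.names = FALSE)
  tab <- table(fams)
  expd <- coreFamilies(core)
  found <- setNames(rep(0L, length(expd)), names(expd))
  common <- intersect(names(tab), names(expd))
  found[common] <- as.integer(tab[common])
  identified <- if (capped) sum(pmin(found, expd)) else sum(found)
  dupes <- sum(found[cscgFamilies(core)] > 1L)
  list(identified_core = as.integer(identified),
       duplicate_cscgs = as.integer(dupes))
}

#' Estimate percent completeness of a bin
#'
#' Identified core-gene occurrences over the expected total for the
#' pangenome core, as a percentage to two decimals.
#'
#' @param identifiedCore integer, identified core occurrences (capped at
#'   expected multiplicities).
#' @param core a [CoreGenome-class].
#' @return percent complete, rounded to 2 decimals.
#' @export
estimateCompleteness <- function(identifiedCore, core) {
  expd <- expectedCoreTotal(core)
  if (expd == 0L) stop("core genome has no expected occurrences")
  if (identifiedCore < 0) stop("identifiedCore must be non-negative")
  round(100 * identifiedCore / expd, 2L)
}

#' Estimate percent duplication of a bin
#'
#' Number of conserved single-copy genes found more than once, over the
#' number of CSCGs in the core, as a percentage to two decimals.
#'
#' @param duplicateCscgs integer count of CSCG families with > 1 copy.
#' @param core a [CoreGenome-class].
#' @return percent duplication, rounded to 2 decimals.
#' @export
estimateDuplication <- function(duplicateCscgs, core) {
  n <- length(cscgFamilies(core))
  if (n == 0L) stop("core genome has no single-copy families")
  if (duplicateCscgs < 0) stop("duplicateCscgs must be non-negative")
  round(100 * duplicateCscgs / n, 2L)
}

#' Extrapolate the full genome size of a partial bin
#'
#' Scales the bin's assembled size up by its estimated completeness and
#' down by its estimated duplication:
#' \deqn{size_{genome} = \frac{total_{bp}}{complete/100} \times
#'   (1 - duplication/100)}
#' rounded to the nearest integer.
#'
#' @param totalBp assembled bin size in bp.
#' @param pctComplete percent completeness, in (0, 100].
#' @param pctDuplication percent duplication, in [0, 100).
#' @return approximate genome size in bp (integer-valued numeric).
#' @export
extrapolateGenomeSize <- function(totalBp, pctComplete, pctDuplication = 0) {
  if (pctComplete <= 0) stop("pctComplete must be positive")
  if (pctDuplication < 0 || pctDuplication >= 100)
    stop("pctDuplication must be in [0, 100)")
  round(totalBp / (pctComplete / 100) * (1 - pctDuplication / 100))
}

#' Full quality report for a set of bins
#'
#' @param binSet a [BinSet-class].
#' @param annotations CDS annotation table.
#' @param core a [CoreGenome-class].
#' @return data.frame with one row per bin: identified core genes, percent
#'   complete, duplicate CSCGs, percent duplication, total bp and
#'   extrapolated genome size.
#' @export
binQualityReport <- function(binSet, annotations, core) {
  rows <- lapply(names(binSet@bins), function(b) {
    v <- binSet@bins[[b]]
    cc <- countCoreFamilies(v, annotations, core)
    pc <- estimateCompleteness(cc$identified_core, core)
    pd <- estimateDuplication(cc$duplicate_cscgs, core)
    data.frame(
      bin_id = b,
      total_bp = sum(binSet@scaffoldLength[v]),
      n_scaffolds = length(v),
      identified_core = cc$identified_core,
      pct_complete = pc,
      duplicate_cscgs = cc$duplicate_cscgs,
      pct_duplication = pd,
      approx_genome_bp = if (pc > 0)
        extrapolateGenomeSize(sum(binSet@scaffoldLength[v]), pc, pd)
      else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
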