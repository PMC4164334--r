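## Read-level population analysis: pileups, quality-based correction, SNP
## calling, variant-track reconstruction and seasonal classification.

#' Build a read pileup over a scaffold region
#'
#' @param alignTab alignment data.frame (see
#'   [SyntheticCommunity-class] for the schema); \code{sequence} holds the
#'   read bases in scaffold orientation, \code{quality} the Phred+33
#'   string.
#' @param scaffoldId scaffold to pile up.
#' @param start,end 0-based half-open region.
#' @return a \code{"flavbin_pileup"} list: \code{positions} (0-based),
#'   \code{bases} and \code{quals} matrices (reads x positions, \code{NA}
#'   outside each read), \code{read_ids}, \code{scaffold_id}.
#' @export
buildPileup <- function(alignTab, scaffoldId, start, end) {
  sel <- alignTab[alignTab$scaffold_id == scaffoldId &
                    alignTab$end > start & alignTab$start < end, ,
                  drop = FALSE]
  width <- end - start
  nb <- nrow(sel)
  bases <- matrix(NA_character_, nb, width)
  quals <- matrix(NA_integer_, nb, width)
  for (i in seq_len(nb)) {
    rs <- sel$start[i]; re <- sel$end[i]
    from <- max(rs, start); to <- min(re, end)
    idx <- (from - start + 1L):(to - start)
    seqChars <- strsplit(sel$sequence[i], "", fixed = TRUE)[[1L]]
    qInts <- utf8ToInt(sel$quality[i]) - 33L
    bases[i, idx] <- seqChars[(from - rs + 1L):(to - rs)]
    quals[i, idx] <- qInts[(from - rs + 1L):(to - rs)]
  }
  structure(list(positions = seq.int(start, end - 1L),
                 bases = bases, quals = quals,
                 read_ids = sel$read_id, scaffold_id = scaffoldId),
            class = "flavbin_pileup")
}

## majority base of a column; ties broken by summed quality, then
## lexicographically
consensusBase <- function(b, q) {
  ok <- !is.na(b)
  b <- b[ok]; q <- q[ok]
  if (length(b) == 0L) return(NA_character_)
  tab <- sort(table(b), decreasing = TRUE)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  qs <- vapply(top, function(x) sum(q[b == x]), numeric(1))
  top <- top[qs == max(qs)]
  sort(top)[1L]
}

#' Correct unsupported low-quality base calls to the column consensus
#'
#' A call with Phred quality below \code{qMin} whose base is seen in no
#' other read at that site is replaced by the column consensus base.
#' Calls at or above \code{qMin}, and low-quality calls supported by at
#' least one other read, are left untouched.
#'
#' @param pileup a pileup from [buildPileup()].
#' @param qMin Phred cutoff (default 30).
#' @return the corrected pileup.
#' @export
correctLowQuality <- function(pileup, qMin = 30L) {
  b <- pileup$bases; q <- pileup$quals
  for (j in seq_len(ncol(b))) {
    col <- b[, j]
    low <- which(!is.na(col) & q[, j] < qMin)
    if (length(low) == 0L) next
    cons <- consensusBase(col, q[, j])
    for (i in low) {
      supported <- any(col[-i] == col[i], na.rm = TRUE)
      if (!supported) b[i, j] <- cons
    }
  }
  pileup$bases <- b
  pileup
}

#' Call SNPs from a pileup
#'
#' A site is a SNP when read coverage is at least \code{minCov} and at
#' least \code{minAlt} reads carry the same non-consensus base. The
#' consensus is the majority base; ties are broken by summed quality, then
#' lexicographically.
#'
#' @param pileup a (quality-corrected) pileup.
#' @param minCov minimum coverage (default 4).
#' @param minAlt minimum reads supporting an alternative allele (default 2).
#' @return data.frame: \code{position} (0-based), \code{consensus},
#'   \code{alt} (comma-separated alleles), \code{coverage},
#'   \code{alt_count} (reads on the best-supported alt).
#' @export
callSnps <- function(pileup, minCov = 4L, minAlt = 2L) {
  out <- list()
  b <- pileup$bases; q <- pileup$quals
  for (j in seq_len(ncol(b))) {
    col <- b[, j]
    ok <- !is.na(col)
    cov <- sum(ok)
    if (cov < minCov) next
    cons <- consensusBase(col, q[, j])
    tab <- table(col[ok])
    alt <- names(tab)[names(tab) != cons & tab >= minAlt]
    if (length(alt) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      position = pileup$positions[j], consensus = cons,
      alt = paste(alt, collapse = ","), coverage = cov,
      alt_count = max(tab[alt]), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(position = integer(), consensus = character(),
                      alt = character(), coverage = integer(),
                      alt_count = integer()))
  do.call(rbind, out)
}

#' Select CDS with draft-genome-like coverage
#'
#' Mean read depth over the CDS span must be strictly greater than
#' \code{minCov} (the draft-genome convention is 8x; 7x admits more CDS
#' while still excluding poorly covered ones).
#'
#' @param cdsTab annotation data.frame with \code{cds_id},
#'   \code{scaffold_id}, \code{start}, \code{end}.
#' @param alignTab alignment data.frame.
#' @param minCov coverage cutoff (default 7).
#' @return \code{cdsTab} rows passing the cutoff, with a
#'   \code{mean_coverage} column appended.
#' @export
selectCds <- function(cdsTab, alignTab, minCov = 7) {
  cov <- vapply(seq_len(nrow(cdsTab)), function(i) {
    s <- cdsTab$scaffold_id[i]; a <- cdsTab$start[i]; b <- cdsTab$end[i]
    sel <- alignTab[alignTab$scaffold_id == s & alignTab$end > a &
                      alignTab$start < b, , drop = FALSE]
    if (nrow(sel) == 0L) return(0)
    sum(pmin(sel$end, b) - pmax(sel$start, a)) / (b - a)
  }, numeric(1))
  out <- cdsTab[cov > minCov, , drop = FALSE]
  out$mean_coverage <- cov[cov > minCov]
  out
}

#' Reconstruct variant tracks over a CDS from SNP patterns
#'
#' Reads covering at least one SNP site are grouped by single-link
#' compatibility: two reads link when they overlap at one or more SNP
#' sites and agree at every shared SNP site; connected components are the
#' candidate tracks. When the transitive closure forces two disagreeing
#' reads into one component the CDS is classified \code{"undetermined"}
#' (the variants cannot be separated), as is a CDS whose SNPs collapse
#' into a single component. A CDS without SNPs yields one track of all its
#' reads, classified \code{"no_snps"}.
#'
#' @param pileup pileup over the CDS span (quality-corrected).
#' @param snps SNP table from [callSnps()].
#' @param readSeasons named character vector: read_id -> season (used for
#'   each track's seasonal composition; optional).
#' @return list with \code{classification} (\code{"no_snps"},
#'   \code{"undetermined"} or \code{"multi_variant"}) and \code{tracks}, a
#'   list of lists (\code{read_ids}, \code{alleles}, \code{consensus},
#'   \code{span}, \code{season}).
#' @export
reconstructTracks <- function(pileup, snps, readSeasons = NULL) {
  nReads <- length(pileup$read_ids)
  if (nrow(snps) == 0L) {
    tr <- list(makeTrack(pileup, seq_len(nReads), integer(0), readSeasons))
    return(list(classification = "no_snps", tracks = tr))
  }
  snpCols <- match(snps$position, pileup$positions)
  A <- pileup$bases[, snpCols, drop = FALSE]
  covers <- which(rowSums(!is.na(A)) > 0L)
  if (length(covers) == 0L)
    return(list(classification = "undetermined", tracks = list()))
  ## single-link components over compatible informative overlaps
  comp <- seq_along(covers)
  for (ii in seq_along(covers)) {
    for (jj in seq_along(covers)) {
      if (jj <= ii) next
      a <- A[covers[ii], ]; b <- A[covers[jj], ]
      shared <- !is.na(a) & !is.na(b)
      if (!any(shared)) next
      if (all(a[shared] == b[shared])) {
        old <- comp[jj]; new <- comp[ii]
        comp[comp == old] <- new
      }
    }
  }
  groups <- split(covers, comp)
  ## a component containing two reads that disagree at a shared SNP site
  ## cannot be resolved into clean variants
  conflict <- any(vapply(groups, function(g) {
    if (length(g) < 2L) return(FALSE)
    for (x in seq_along(g)) for (y in seq_along(g)) {
      if (y <= x) next
      a <- A[g[x], ]; b <- A[g[y], ]
      sh <- !is.na(a) & !is.na(b)
      if (any(sh) && any(a[sh] != b[sh])) return(TRUE)
    }
    FALSE
  }, logical(1)))
  tracks <- lapply(groups, function(g) makeTrack(pileup, g, snpCols, readSeasons))
  names(tracks) <- NULL
  classification <- if (conflict || length(tracks) < 2L) "undetermined"
  else "multi_variant"
  list(classification = classification, tracks = tracks)
}

makeTrack <- function(pileup, rows, snpCols, readSeasons) {
  b <- pileup$bases[rows, , drop = FALSE]
  q <- pileup$quals[rows, , drop = FALSE]
  covered <- which(colSums(!is.na(b)) > 0L)
  cons <- vapply(seq_len(ncol(b)), function(j)
    consensusBase(b[, j], q[, j]), character(1))
  alleles <- if (length(snpCols)) cons[snpCols] else character(0)
  seasons <- if (!is.null(readSeasons))
    unname(readSeasons[pileup$read_ids[rows]]) else NULL
  list(read_ids = pileup$read_ids[rows],
       alleles = alleles,
       consensus = paste(ifelse(is.na(cons), "N", cons), collapse = ""),
       span = if (length(covered)) max(covered) - min(covered) + 1L else 0L,
       season = if (!is.null(seasons)) classifySeason(seasons) else NA_character_)
}

#' Pick the reference track for pairwise comparisons
#'
#' The reference is the track with the most supporting reads; ties are
#' broken by highest nucleotide identity to the CDS consensus, then by
#' lexicographic order of the first member read id.
#'
#' @param tracks list of tracks from [reconstructTracks()].
#' @param cdsConsensus character(1) consensus nucleotide sequence of the
#'   CDS span (same length as each track consensus).
#' @return the index of the reference track.
#' @export
pickReference <- function(tracks, cdsConsensus) {
  if (length(tracks) == 0L) stop("no tracks")
  if (length(tracks) == 1L) return(1L)
  nReads <- vapply(tracks, function(t) length(t$read_ids), integer(1))
  cand <- which(nReads == max(nReads))
  if (length(cand) > 1L) {
    ident <- vapply(cand, function(i)
      sequenceIdentity(tracks[[i]]$consensus, cdsConsensus), numeric(1))
    cand <- cand[ident == max(ident)]
  }
  if (length(cand) > 1L) {
    first <- vapply(cand, function(i) sort(tracks[[i]]$read_ids)[1L],
                    character(1))
    cand <- cand[order(first)][1L]
  }
  cand[1L]
}

## identity over positions where both strings have a determined base
sequenceIdentity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  ok <- x != "N" & y != "N"
  if (!any(ok)) return(0)
  mean(x[ok] == y[ok])
}

#' Classify the seasonal composition of a read set
#'
#' @param seasons character vector of per-read season labels
#'   (\code{"summer"} / \code{"winter"}).
#' @return \code{"summer_only"}, \code{"winter_only"} or \code{"both"}.
#' @export
classifySeason <- function(seasons) {
  if (length(seasons) == 0L || anyNA(seasons))
    stop("every member read must carry a season label")
  if (!all(seasons %in% c("summer", "winter")))
    stop("season labels must be 'summer' or 'winter'")
  hasS <- any(seasons == "summer"); hasW <- any(seasons == "winter")
  if (hasS && hasW) "both" else if (hasS) "summer_only" else "winter_only"
}

#' Summarise a per-bin variant census table
#'
#' Takes a census with one row per bin (CDS above the coverage cutoff,
#' CDS without SNPs, CDS with multiple variants, and winter-only /
#' summer-only / both-season variant counts) and sums the columns,
#' returning totals including the overall number of variants.
#'
#' @param census data.frame with columns \code{bin}, \code{cds_gt7x},
#'   \code{cds_no_snp}, \code{cds_multi_variant}, \code{winter_only},
#'   \code{summer_only}, \code{both_seasons}.
#' @return named numeric vector of column totals plus
#'   \code{total_variants}.
#' @export
summarizeVariantCensus <- function(census) {
  num <- census[, setdiff(names(census), "bin"), drop = FALSE]
  tot <- colSums(num)
  c(tot, total_variants = sum(tot[c("winter_only", "summer_only",
                                    "both_seasons")]))
}
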