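## Readers and writers for the pipeline's plain-text formats.

#' Read scaffolds from a FASTA file
#'
#' Lowercase bases are uppercased with a warning; letters outside
#' A/C/G/T/N are rejected.
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] (empty for an empty file).
#' @export
readScaffoldFasta <- function(path) {
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  x <- Biostrings::readBStringSet(path)
  chars <- as.character(x)
  if (any(grepl("[acgtn]", chars))) {
    warning("lowercase bases found; uppercasing")
    chars <- toupper(chars)
  }
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stop("invalid characters in record(s): ",
         paste(names(x)[bad], collapse = ", "))
  Biostrings::DNAStringSet(setNames(chars, names(x)))
}

#' Write scaffolds to FASTA (60-column wrapping)
#'
#' @param seqs a [Biostrings::DNAStringSet] or named character vector.
#' @param path output file.
#' @export
writeScaffoldFasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

ALIGNMENT_COLUMNS <- c("read_id", "scaffold_id", "start", "end", "strand",
                       "sample_id", "season", "sequence", "quality")

#' Read and validate a read-alignment table
#'
#' Tab-separated with the columns \code{read_id}, \code{scaffold_id},
#' \code{start}, \code{end} (0-based half-open), \code{strand},
#' \code{sample_id}, \code{season}, \code{sequence}, \code{quality}.
#' Errors name the offending row: duplicate read ids, negative or inverted
#' coordinates, seasons other than summer/winter, and (when
#' \code{scaffolds} is given) dangling scaffold ids or reads running past
#' their scaffold end.
#'
#' @param path TSV file.
#' @param scaffolds optional [Biostrings::DNAStringSet] to validate
#'   against.
#' @return the validated data.frame.
#' @export
readAlignmentTable <- function(path, scaffolds = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(start = "integer", end = "integer"))
  missing <- setdiff(ALIGNMENT_COLUMNS, names(df))
  if (length(missing))
    stop("alignment table lacks columns: ", paste(missing, collapse = ", "))
  dup <- which(duplicated(df$read_id))
  if (length(dup))
    stop("duplicate read_id at row ", dup[1L], ": ", df$read_id[dup[1L]])
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad)) stop("bad coordinates at row ", bad[1L])
  bad <- which(!df$season %in% c("summer", "winter"))
  if (length(bad))
    stop("bad season token at row ", bad[1L], ": ", df$season[bad[1L]])
  if (!is.null(scaffolds)) {
    lens <- setNames(Biostrings::width(scaffolds), names(scaffolds))
    bad <- which(!df$scaffold_id %in% names(lens))
    if (length(bad))
      stop("unknown scaffold_id at row ", bad[1L], ": ",
           df$scaffold_id[bad[1L]])
    bad <- which(df$end > lens[df$scaffold_id])
    if (length(bad))
      stop("read extends beyond scaffold at row ", bad[1L], ": ",
           df$read_id[bad[1L]])
  }
  df
}

#' Write a read-alignment table
#' @param df alignment data.frame.
#' @param path output TSV.
#' @export
writeAlignmentTable <- function(df, path) {
  write.table(df[, ALIGNMENT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a CDS annotation table
#'
#' Tab-separated: \code{cds_id}, \code{scaffold_id}, \code{start},
#' \code{end} (0-based half-open), \code{strand}, \code{product},
#' \code{top_hit_phylum}, \code{family_ids} (comma-separated, may be
#' empty), \code{is_marker}.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readAnnotationTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cds_id", "scaffold_id", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad)) stop("bad CDS coordinates at row ", bad[1L])
  df
}

#' Read a pangenome gene-family count table
#'
#' Tab-separated, first column \code{genome_id}, remaining columns one per
#' gene family, integer occurrence counts.
#'
#' @param path TSV file.
#' @return integer matrix, genomes x families.
#' @export
readPangenomeCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("pangenome counts must be non-negative")
  m
}

#' Read a per-bin variant census table
#'
#' @param path TSV with columns \code{bin}, \code{cds_gt7x},
#'   \code{cds_no_snp}, \code{cds_multi_variant}, \code{winter_only},
#'   \code{summer_only}, \code{both_seasons}.
#' @return data.frame, suitable for [summarizeVariantCensus()].
#' @export
readVariantCensus <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
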