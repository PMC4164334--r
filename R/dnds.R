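## Nei-Gojobori (1986)-style dN/dS estimation with Jukes-Cantor correction,
## under the bacterial genetic code (table 11). Used to screen gene variant
## pairs for purifying selection and for synonymous saturation (dS > 2.0).

#' Estimate dN and dS for a pair of aligned coding sequences
#'
#' Counts synonymous and nonsynonymous sites and differences by pathway
#' enumeration (for codons differing at more than one position, all
#' mutational pathways are averaged; pathways passing through a stop codon
#' are excluded when a stop-free pathway exists), applies the Jukes-Cantor
#' multiple-hit correction, and classifies the pair. Aligned codons
#' containing a gap, and codon columns containing an in-frame stop in
#' either sequence, are removed before counting. Translation uses genetic
#' code table 11 (bacterial). Single-site changes to a stop codon are
#' counted as nonsynonymous in the site tally.
#'
#' dS above \code{dsSaturation} flags the pair as saturated in synonymous
#' substitutions (the dS estimate is unreliable, and a disparate gene
#' history such as recombination may be suspected); dS also serves as a
#' relative proxy for time since divergence.
#'
#' @param seqA,seqB aligned coding sequences (equal length, multiple of 3
#'   after removing gapped/stop codon columns; \code{"-"} marks gaps).
#' @param dsSaturation dS cutoff above which the estimate is flagged
#'   saturated (default 2.0).
#' @return an object of class \code{"flavbin_dnds"}: list with \code{dN},
#'   \code{dS}, \code{ratio} (\code{NA} when dS = 0), \code{saturated},
#'   \code{classification} (\code{"purifying"}, \code{"neutral"},
#'   \code{"positive"} or \code{"undefined"}), raw counts \code{N},
#'   \code{S}, \code{Nd}, \code{Sd}, \code{pN}, \code{pS},
#'   \code{codons_used}, and \code{correction_undefined} (TRUE when pN or
#'   pS >= 3/4: the correction has no finite solution there and the
#'   distance is reported as \code{Inf}).
#' @export
computeDnDs <- function(seqA, seqB, dsSaturation = 2.0) {
  code <- Biostrings::getGeneticCode("11")
  a <- toupper(as.character(seqA)); b <- toupper(as.character(seqB))
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  if (nchar(a) %% 3L != 0L) stop("aligned length must be a multiple of 3")
  n <- nchar(a)
  ca <- substring(a, seq(1L, n, 3L), seq(3L, n, 3L))
  cb <- substring(b, seq(1L, n, 3L), seq(3L, n, 3L))
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE) &
    !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS) &
    grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("no usable codon columns after trimming")

  uniq <- unique(c(ca, cb))
  siteTab <- vapply(uniq, synSites, numeric(1), code = code)
  sa <- siteTab[ca]
  sb <- siteTab[cb]
  S <- (sum(sa) + sum(sb)) / 2
  N <- 3 * length(ca) - S

  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    d <- codonDifferences(ca[i], cb[i], code)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }

  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  corrUndef <- (pS >= 3 / 4) || (pN >= 3 / 4)
  ## at p >= 3/4 the multiple-hit correction has no finite solution: the
  ## divergence is beyond the correctable range and reported as Inf
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 3 / 4) return(Inf)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS); dN <- jc(pN)

  ratio <- if (dS > 0) dN / dS else NA_real_
  if (is.nan(ratio)) ratio <- NA_real_
  classification <- if (is.na(ratio)) "undefined"
  else if (ratio < 1) "purifying"
  else if (ratio > 1) "positive"
  else "neutral"
  structure(list(
    dN = dN, dS = dS, ratio = ratio,
    saturated = isTRUE(!is.na(dS) && dS > dsSaturation),
    classification = classification,
    N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
    codons_used = length(ca),
    correction_undefined = corrUndef
  ), class = "flavbin_dnds")
}

#' @export
print.flavbin_dnds <- function(x, ...) {
  cat(sprintf("dN = %.4f, dS = %.4f, dN/dS = %s (%s)%s\n",
              x$dN, x$dS,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio),
              x$classification,
              if (x$saturated) " [dS saturated]" else ""))
  invisible(x)
}

## number of synonymous sites of a codon: per position, the fraction of
## the three possible point changes that preserve the amino acid (changes
## to stop codons count as nonsynonymous)
synSites <- function(codon, code) {
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (bb in setdiff(bases, substr(codon, pos, pos))) {
      new <- codon
      substr(new, pos, pos) <- bb
      if (code[[new]] == aa && code[[new]] != "*") s <- s + 1 / 3
    }
  }
  s
}

## average synonymous/nonsynonymous differences between two codons over
## all mutational pathways; pathways through stops dropped when avoidable
codonDifferences <- function(x, y, code) {
  pos <- which(strsplit(x, "")[[1L]] != strsplit(y, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else
    lapply(asplit(permutations(pos), 1L), as.integer)
  walk <- function(order) {
    cur <- x; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(y, p, p)
      if (code[[nxt]] == "*") return(NULL)   # pathway hits a stop
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) {
    ## every pathway passes a stop: count all steps, stops as nonsynonymous
    res <- lapply(perms, function(order) {
      cur <- x; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(y, p, p)
        if (code[[nxt]] == "*" || code[[nxt]] != code[[cur]]) nd <- nd + 1
        else sd <- sd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
    ok <- rep(TRUE, length(res))
  }
  m <- do.call(rbind, res[ok])
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

## all permutations of a small vector (k <= 3 here)
permutations <- function(v) {
  k <- length(v)
  if (k == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_len(k)) {
    rest <- permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}
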