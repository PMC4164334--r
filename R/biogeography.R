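## Spatio-temporal abundance of bins: percent-of-reads abundance tables,
## seasonal-composition outlier scaffolds, and permutation t-tests.

#' Bin abundance as percent of reads per sample and season
#'
#' Treats each read as one individual (rare taxa in a deep Sanger
#' metagenome are sampled far below their population size), so a bin's
#' abundance in a sample is 100 x (reads mapping to the bin's scaffolds) /
#' (all reads in the sample). Seasonal columns pool all samples of each
#' season. An \code{unbinned} row carries reads outside any bin and a
#' \code{TOTAL} row sums the bin rows.
#'
#' @param binSet a [BinSet-class].
#' @param alignTab alignment data.frame with \code{read_id},
#'   \code{scaffold_id}, \code{sample_id}, \code{season}.
#' @return data.frame with a \code{bin} column, one column per season and
#'   per sample, in percent.
#' @export
abundanceMatrix <- function(binSet, alignTab) {
  samples <- unique(alignTab$sample_id)
  totals <- table(alignTab$sample_id)[samples]
  if (any(totals == 0) || length(samples) == 0L)
    stop("every sample must contain at least one read")
  seasonOf <- tapply(alignTab$season, alignTab$sample_id, function(s) s[1L])
  seasons <- unique(alignTab$season)
  seasonTotals <- vapply(seasons, function(ss)
    sum(totals[seasonOf[samples] == ss]), numeric(1))

  scaffold2bin <- rep(names(binSet@bins),
                      vapply(binSet@bins, length, integer(1)))
  names(scaffold2bin) <- unlist(binSet@bins, use.names = FALSE)
  readBin <- scaffold2bin[alignTab$scaffold_id]
  readBin[is.na(readBin)] <- "unbinned"

  rows <- c(names(binSet@bins), "unbinned")
  m <- matrix(0, length(rows), length(samples),
              dimnames = list(rows, samples))
  tab <- table(factor(readBin, levels = rows), alignTab$sample_id)
  m[, samples] <- tab[, samples]
  pctSample <- sweep(m, 2L, as.numeric(totals), "/") * 100
  pctSeason <- vapply(seasons, function(ss) {
    inSeason <- samples[seasonOf[samples] == ss]
    100 * rowSums(m[, inSeason, drop = FALSE]) /
      sum(totals[inSeason])
  }, numeric(length(rows)))
  out <- data.frame(bin = rows, pctSeason, pctSample,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("bin", seasons, samples)
  total <- c(bin = "TOTAL",
             as.list(colSums(out[out$bin != "unbinned", -1L, drop = FALSE])))
  rbind(out, as.data.frame(total, check.names = FALSE))
}

#' Flag scaffolds whose seasonal composition is an outlier within a bin
#'
#' Computes each scaffold's summer-read fraction and flags scaffolds
#' outside the Tukey fences \eqn{[Q1 - k \cdot IQR, Q3 + k \cdot IQR]} of
#' the bin's distribution. Flagged scaffolds should be excluded from
#' biogeographical summaries but retained for gene-content analyses. Bins
#' with fewer than four scaffolds carrying reads give no calls
#' (insufficient data).
#'
#' @param members scaffold ids of one bin.
#' @param alignTab alignment data.frame.
#' @param k fence multiplier (default 1.5).
#' @return data.frame: \code{scaffold_id}, \code{summer_fraction},
#'   \code{flag} (\code{"ok"}, \code{"outlier"} or \code{"insufficient"}).
#' @export
seasonalOutliers <- function(members, alignTab, k = 1.5) {
  sel <- alignTab[alignTab$scaffold_id %in% members, , drop = FALSE]
  frac <- tapply(sel$season == "summer", sel$scaffold_id, mean)
  ids <- names(frac)
  if (length(ids) < 4L)
    return(data.frame(scaffold_id = ids,
                      summer_fraction = as.numeric(frac),
                      flag = "insufficient", stringsAsFactors = FALSE))
  qs <- quantile(frac, c(0.25, 0.75), names = FALSE)
  iqr <- qs[2L] - qs[1L]
  lo <- qs[1L] - k * iqr; hi <- qs[2L] + k * iqr
  data.frame(scaffold_id = ids,
             summer_fraction = as.numeric(frac),
             flag = ifelse(frac < lo | frac > hi, "outlier", "ok"),
             stringsAsFactors = FALSE)
}

## pooled-variance two-sample t statistic; 0 for two identical constant
## groups, +/-Inf for separated constant groups
tStatistic <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (dm == 0) return(0)
    return(sign(dm) * Inf)
  }
  dm / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Two-sided permutation t-test
#'
#' Recomputes the pooled-variance t statistic under \code{B} random
#' relabelings of group membership; the two-sided p-value uses the add-one
#' convention \eqn{p = (1 + \#\{|t^*| \ge |t_{obs}|\}) / (B + 1)}, so p is
#' never zero and always at least \eqn{1/(B+1)}.
#'
#' @param a,b numeric observation vectors for the two groups (e.g.
#'   per-scaffold read fractions).
#' @param B number of permutations (default 10,000).
#' @param seed optional RNG seed for reproducibility.
#' @return list with \code{t_obs}, \code{B}, \code{p_value}.
#' @export
permutationTTest <- function(a, b, B = 10000L, seed = NULL) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  tObs <- tStatistic(a, b)
  pool <- c(a, b)
  n1 <- length(a); n <- length(pool)
  hits <- 0L
  eps <- 1e-12
  for (i in seq_len(B)) {
    idx <- sample.int(n, n1)
    tP <- tStatistic(pool[idx], pool[-idx])
    if (abs(tP) >= abs(tObs) - eps) hits <- hits + 1L
  }
  list(t_obs = tObs, B = as.integer(B),
       p_value = (1 + hits) / (B + 1))
}
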