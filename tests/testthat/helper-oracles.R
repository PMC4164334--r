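## Independent brute-force oracles used across the suite. These stay
## deliberately naive (window loops, per-column scans, per-codon
## translation) so they are independent of the implementation paths they
## check.

## sliding-window canonical k-mer frequencies by explicit string walking
bruteKmerFreq <- function(seq, k) {
  seq <- toupper(seq)
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  counts <- new.env()
  n <- nchar(seq)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("[^ACGT]", w)) next
    for (word in c(w, rc(w))) {
      counts[[word]] <- (if (is.null(counts[[word]])) 0 else counts[[word]]) + 1
    }
  }
  v <- unlist(as.list(counts))
  v / sum(v)
}

## brute-force SNP scan over a base matrix (reads x positions)
bruteSnpScan <- function(bases, positions, minCov = 4, minAlt = 2) {
  hits <- integer(0)
  for (j in seq_len(ncol(bases))) {
    col <- bases[, j]
    col <- col[!is.na(col)]
    if (length(col) < minCov) next
    tab <- table(col)
    cons <- names(tab)[which.max(tab)]  # ties irrelevant for is-SNP
    if (any(tab[names(tab) != cons] >= minAlt)) hits <- c(hits, positions[j])
  }
  hits
}

## per-codon translate-and-compare classification of point differences
## between two equal-length in-frame sequences (table 11)
bruteSnpClasses <- function(a, b) {
  code <- Biostrings::getGeneticCode("11")
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3 == 0)
  n <- nchar(a)
  ca <- substring(a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(b, seq(1, n, 3), seq(3, n, 3))
  syn <- 0; nonsyn <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    ## single-site diffs only (planted haplotypes never stack in a codon
    ## across one pair beyond what the planner placed)
    diffs <- which(strsplit(ca[i], "")[[1]] != strsplit(cb[i], "")[[1]])
    for (p in diffs) {
      tmp <- ca[i]
      substr(tmp, p, p) <- substr(cb[i], p, p)
      if (code[[tmp]] == code[[ca[i]]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      ca[i] <- tmp
    }
  }
  c(syn = syn, nonsyn = nonsyn)
}

## evolve a codon sequence under a Markov substitution process with
## relative nonsynonymous acceptance omega; returns the mutated sequence
evolveCodons <- function(seq, nSubs, omega) {
  code <- Biostrings::getGeneticCode("11")
  bases <- c("A", "C", "G", "T")
  n <- nchar(seq)
  done <- 0
  while (done < nSubs) {
    p <- sample.int(n, 1)
    ci <- (p - 1) %/% 3
    codon <- substr(seq, ci * 3 + 1, ci * 3 + 3)
    b <- sample(setdiff(bases, substr(seq, p, p)), 1)
    new <- codon
    substr(new, (p - 1) %% 3 + 1, (p - 1) %% 3 + 1) <- b
    if (code[[new]] == "*") next
    syn <- code[[new]] == code[[codon]]
    if (!syn && runif(1) > omega) next
    substr(seq, p, p) <- b
    done <- done + 1
  }
  seq
}

randomStopFreeCds <- function(nCodons) {
  codons <- apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                              c("T","C","A","G")), 1, paste, collapse = "")
  code <- Biostrings::getGeneticCode("11")
  ok <- codons[code[codons] != "*"]
  paste(sample(ok, nCodons, replace = TRUE), collapse = "")
}

## small community shared by several tests (cached per session)
smallCommunity <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- communitySpec(numGenomes = 2, genomeLength = 150000L,
                            scaffoldLengthRange = c(5000L, 10000L),
                            readsPerSample = 150L, plantedCscgCount = 12L,
                            seed = 11L)
      cache <<- generateCommunity(spec)
    }
    cache
  }
})

## random pileup object for caller tests
randomPileup <- function(nReads, width, alphabet = c("A", "C", "G", "T"),
                         naFrac = 0.2) {
  bases <- matrix(sample(alphabet, nReads * width, replace = TRUE),
                  nReads, width)
  bases[matrix(runif(nReads * width) < naFrac, nReads, width)] <- NA
  quals <- matrix(sample(30:40, nReads * width, replace = TRUE),
                  nReads, width)
  quals[is.na(bases)] <- NA
  structure(list(positions = seq_len(width) - 1L, bases = bases,
                 quals = quals,
                 read_ids = sprintf("r%03d", seq_len(nReads)),
                 scaffold_id = "s1"),
            class = "flavbin_pileup")
}
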