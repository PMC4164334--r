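## Synthetic metagenomic communities with known ground truth.
##
## Genomes are simulated as independent Markov chains over {A,C,G,T} so that
## genomes differ in oligonucleotide composition the way distinct taxa do,
## scaffolds are contiguous genome slices, and Sanger-like reads (~1 kb) are
## drawn per sample according to a genome-by-sample abundance matrix.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a variant-planting plan
#'
#' @param cdsId identifier of the CDS the haplotypes are planted on.
#' @param numHaplotypes number of haplotypes (>= 1); haplotype 1 is the
#'   unmodified reference.
#' @param synSnps,nonsynSnps synonymous / nonsynonymous point differences of
#'   each non-reference haplotype relative to haplotype 1, classified under
#'   genetic code table 11.
#' @param readsPerHaplotype reads emitted per haplotype.
#' @param seasonBias fraction of each haplotype's reads labelled summer
#'   (length 1 or \code{numHaplotypes}).
#' @return a [VariantPlan-class] object.
#' @export
variantPlan <- function(cdsId, numHaplotypes = 2L, synSnps = 1L,
                        nonsynSnps = 0L, readsPerHaplotype = 10L,
                        seasonBias = 0.5) {
  new("VariantPlan", cdsId = as.character(cdsId),
      numHaplotypes = as.integer(numHaplotypes),
      synSnps = as.integer(synSnps), nonsynSnps = as.integer(nonsynSnps),
      readsPerHaplotype = as.integer(readsPerHaplotype),
      seasonBias = as.numeric(seasonBias))
}

#' Construct a synthetic community specification
#'
#' Defaults describe the package's reference community: four rare
#' planktonic genomes of 2 Mbp with distinguishable order-2 Markov
#' composition, scaffolds of 5-20 kb, Sanger-like reads of 1,008 +/- 150 bp
#' drawn from six samples (three winter sites, three summer sites) with
#' genome-specific seasonal abundance profiles, and 199 planted single-copy
#' core families per genome.
#'
#' @param numGenomes,genomeLength,markovOrder,scaffoldLengthRange see
#'   [CommunitySpec-class].
#' @param readLengthMean,readLengthSd read length model (bp).
#' @param abundance genomes x samples matrix of expected read fractions;
#'   default gives each genome a distinct seasonal profile.
#' @param samples data.frame (\code{sample_id}, \code{site_id},
#'   \code{season}); default three winter and three summer sites.
#' @param readsPerSample reads drawn per sample.
#' @param plantedCscgCount single-copy core families planted per genome.
#' @param plantedVariants list of [VariantPlan-class].
#' @param errorRate per-base substitution error rate.
#' @param qualityHighFraction fraction of base qualities at or above Q30.
#' @param seed RNG seed.
#' @return a validated [CommunitySpec-class] object.
#' @export
communitySpec <- function(numGenomes = 4L,
                          genomeLength = 2000000L,
                          markovOrder = 2L,
                          scaffoldLengthRange = c(5000L, 20000L),
                          readLengthMean = 1008,
                          readLengthSd = 150,
                          abundance = NULL,
                          samples = NULL,
                          readsPerSample = 800L,
                          plantedCscgCount = 199L,
                          plantedVariants = list(),
                          errorRate = 1e-3,
                          qualityHighFraction = 0.97,
                          seed = 42L) {
  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = c("W03", "W04", "W06", "S12", "S13", "S14"),
      site_id = c("GoMA03", "GoMA04", "GoMA06", "GoMA12", "GoMA13", "GoMA14"),
      season = c("winter", "winter", "winter", "summer", "summer", "summer"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(abundance)) {
    ## seasonal profiles: genome 1 summer-skewed ... genome n winter-skewed
    n <- numGenomes
    w <- seq(0.9, 0.1, length.out = n)       # winter share of each genome
    base <- rep(1 / n, n)
    abundance <- sapply(seq_len(nrow(samples)), function(j) {
      if (samples$season[j] == "winter") base * w * 2 else base * (1 - w) * 2
    })
    abundance <- sweep(abundance, 2, pmax(colSums(abundance), 1), "/") *
      pmin(colSums(abundance), 1)
    rownames(abundance) <- paste0("G", seq_len(n))
    colnames(abundance) <- samples$sample_id
  }
  new("CommunitySpec",
      numGenomes = as.integer(numGenomes),
      genomeLength = as.integer(genomeLength),
      markovOrder = as.integer(markovOrder),
      scaffoldLengthRange = as.integer(scaffoldLengthRange),
      readLengthMean = as.numeric(readLengthMean),
      readLengthSd = as.numeric(readLengthSd),
      abundance = abundance,
      samples = samples,
      readsPerSample = as.integer(readsPerSample),
      plantedCscgCount = as.integer(plantedCscgCount),
      plantedVariants = plantedVariants,
      errorRate = as.numeric(errorRate),
      qualityHighFraction = as.numeric(qualityHighFraction),
      seed = as.integer(seed))
}

## Sample one sequence of length L from an order-`order` Markov chain with
## the given per-state cumulative transition rows (4^order x 4).
markovChainSeq <- function(L, cumTrans, order) {
  nstate <- nrow(cumTrans)
  mod <- as.integer(nstate / 4L)
  c1 <- cumTrans[, 1L]; c2 <- cumTrans[, 2L]; c3 <- cumTrans[, 3L]
  u <- runif(L)
  out <- integer(L)
  s <- sample.int(nstate, 1L)
  for (i in seq_len(L)) {
    b <- 1L + (u[i] > c1[s]) + (u[i] > c2[s]) + (u[i] > c3[s])
    out[i] <- b
    s <- ((s - 1L) %% mod) * 4L + b
  }
  intToUtf8(c(65L, 67L, 71L, 84L)[out])
}

randomTransitions <- function(order, concentration = 1) {
  nstate <- 4L^order
  ## Dirichlet rows via normalized gammas; sharper rows -> stronger signal
  g <- matrix(stats::rgamma(nstate * 4L, shape = concentration), nstate, 4L)
  p <- g / rowSums(g)
  t(apply(p, 1L, cumsum))
}

## random stop-free coding sequence of nCodons codons (ends without a stop;
## a terminal stop codon is irrelevant for the analyses here)
randomCds <- function(nCodons) {
  codons <- apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                              c("T","C","A","G")), 1L, paste, collapse = "")
  ok <- setdiff(codons, STOP_CODONS)
  paste(sample(ok, nCodons, replace = TRUE), collapse = "")
}

## classify the point change codon[pos] -> base under code:
## "syn", "nonsyn" or "stop"
classifyChange <- function(codon, pos, base, code) {
  new <- codon
  substr(new, pos, pos) <- base
  if (code[[new]] == "*") return("stop")
  if (code[[new]] == code[[codon]]) "syn" else "nonsyn"
}

#' Plant haplotypes with controlled synonymous/nonsynonymous divergence
#'
#' Generates \code{numHaplotypes} haplotype sequences over a coding
#' sequence. Haplotype 1 is the input; every other haplotype carries exactly
#' \code{synSnps} synonymous and \code{nonsynSnps} nonsynonymous point
#' differences from haplotype 1 (genetic code table 11), at positions
#' distinct across all haplotypes, never creating an in-frame stop. Labelled
#' reads covering the full CDS are emitted for each haplotype with the
#' plan's seasonal bias.
#'
#' Uses the session RNG; call \code{set.seed()} for reproducibility.
#'
#' @param cdsSeq character(1) coding sequence (length divisible by 3, no
#'   internal stop codons).
#' @param plan a [VariantPlan-class].
#' @return list with \code{haplotypes} (character vector) and \code{reads}
#'   (data.frame: \code{read_id}, \code{haplotype}, \code{season},
#'   \code{sequence}).
#' @export
plantVariants <- function(cdsSeq, plan) {
  cdsSeq <- toupper(as.character(cdsSeq))
  n <- nchar(cdsSeq)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  code <- Biostrings::getGeneticCode("11")
  codons0 <- substring(cdsSeq, seq(1L, n, 3L), seq(3L, n, 3L))
  if (any(codons0 %in% STOP_CODONS)) stop("CDS contains internal stop codons")

  nHap <- plan@numHaplotypes
  perHap <- plan@synSnps + plan@nonsynSnps
  usedPos <- integer(0)
  haplotypes <- character(nHap)
  haplotypes[1L] <- cdsSeq
  bases <- c("A", "C", "G", "T")

  for (h in seq_len(nHap)[-1L]) {
    seqh <- cdsSeq
    need <- c(rep("syn", plan@synSnps), rep("nonsyn", plan@nonsynSnps))
    placed <- 0L
    attempts <- 0L
    maxAttempts <- 200L * max(1L, perHap) + 2000L
    while (placed < length(need)) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop("cannot place requested SNPs without creating a stop codon; ",
             "CDS too short or constrained for the plan")
      ci <- sample.int(length(codons0), 1L)
      pos <- sample.int(3L, 1L)
      gpos <- (ci - 1L) * 3L + pos
      if (gpos %in% usedPos) next
      codon <- codons0[ci]
      alt <- sample(setdiff(bases, substr(codon, pos, pos)))
      hit <- FALSE
      for (b in alt) {
        if (classifyChange(codon, pos, b, code) == need[placed + 1L]) {
          substr(seqh, gpos, gpos) <- b
          usedPos <- c(usedPos, gpos)
          placed <- placed + 1L
          hit <- TRUE
          break
        }
      }
      if (!hit) next
    }
    haplotypes[h] <- seqh
  }

  bias <- rep(plan@seasonBias, length.out = nHap)
  reads <- do.call(rbind, lapply(seq_len(nHap), function(h) {
    m <- plan@readsPerHaplotype
    if (m == 0L) return(NULL)
    nSummer <- round(bias[h] * m)
    data.frame(
      read_id = sprintf("%s_H%d_r%02d", plan@cdsId, h, seq_len(m)),
      haplotype = h,
      season = c(rep("summer", nSummer), rep("winter", m - nSummer)),
      sequence = haplotypes[h],
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(reads))
    reads <- data.frame(read_id = character(), haplotype = integer(),
                        season = character(), sequence = character())
  list(haplotypes = haplotypes, reads = reads)
}

#' Generate a synthetic metagenomic community
#'
#' Builds \code{numGenomes} genomes from independently parameterised Markov
#' chains, slices them into scaffolds, plants single-copy core gene (CSCG)
#' and marker annotations plus any requested gene variants, and draws
#' Sanger-like labelled reads per sample according to the abundance matrix.
#' Output is byte-identical for a fixed \code{seed}.
#'
#' @param spec a [CommunitySpec-class].
#' @return a [SyntheticCommunity-class].
#' @export
generateCommunity <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  nG <- spec@numGenomes

  ## --- genomes and scaffolds -------------------------------------------
  scafSeq <- character(0)
  scafGenome <- character(0)
  scafId <- character(0)
  for (g in seq_len(nG)) {
    ct <- randomTransitions(spec@markovOrder)
    genome <- markovChainSeq(spec@genomeLength, ct, spec@markovOrder)
    pos <- 1L
    i <- 0L
    lens <- integer(0)
    while (pos <= spec@genomeLength) {
      len <- sample(spec@scaffoldLengthRange[1L]:spec@scaffoldLengthRange[2L], 1L)
      rem <- spec@genomeLength - pos + 1L
      if (rem < spec@scaffoldLengthRange[1L]) break  # trailing sliver dropped
      len <- min(len, rem)
      i <- i + 1L
      lens <- c(lens, len)
      scafSeq <- c(scafSeq, substr(genome, pos, pos + len - 1L))
      scafGenome <- c(scafGenome, paste0("G", g))
      scafId <- c(scafId, sprintf("G%d_S%03d", g, i))
      pos <- pos + len
    }
  }
  names(scafSeq) <- scafId
  scafLen <- nchar(scafSeq)
  names(scafGenome) <- scafId

  ## --- planted annotations ---------------------------------------------
  geneLen <- 900L
  ann <- list()
  corePlacements <- list()
  cursor <- setNames(rep(50L, length(scafId)), scafId)
  placeGene <- function(genomeId, family, product, isMarker) {
    cand <- scafId[scafGenome == genomeId &
                     cursor[scafId] + geneLen + 50L < scafLen[scafId]]
    if (!length(cand)) stop("no room left to place planted genes; ",
                            "increase genome or scaffold size")
    s <- sample(cand, 1L)
    st <- cursor[[s]]
    cursor[[s]] <<- st + geneLen + sample(50:500, 1L)
    id <- sprintf("%s_%s", s, family)
    ann[[length(ann) + 1L]] <<- data.frame(
      cds_id = id, scaffold_id = s, start = st, end = st + geneLen,
      strand = "+", product = product,
      top_hit_phylum = "Bacteroidetes",
      family_ids = family, is_marker = isMarker,
      stringsAsFactors = FALSE)
    corePlacements[[length(corePlacements) + 1L]] <<- data.frame(
      genome = genomeId, family = family, cds_id = id, scaffold_id = s,
      stringsAsFactors = FALSE)
    id
  }
  for (g in seq_len(nG)) {
    gid <- paste0("G", g)
    placeGene(gid, "MARKER_DNAG", "DNA primase (DnaG)", TRUE)
    for (k in seq_len(spec@plantedCscgCount))
      placeGene(gid, sprintf("CSCG_%03d", k), "conserved single-copy gene", FALSE)
  }

  ## --- planted variant CDS (stop-free sequence spliced into a scaffold) --
  variantReadRows <- list()
  readHaplotype <- character(0)
  summerSamples <- spec@samples$sample_id[spec@samples$season == "summer"]
  winterSamples <- spec@samples$sample_id[spec@samples$season == "winter"]
  for (pl in spec@plantedVariants) {
    nCodons <- 405L   # 1,215 bp, comfortably holds typical SNP plans
    s <- sample(scafId[scafLen > 3L * nCodons + 200L], 1L)
    st <- as.integer(scafLen[[s]] - 3L * nCodons - 100L)
    cds <- randomCds(nCodons)
    substr(scafSeq[[s]], st + 1L, st + 3L * nCodons) <- cds
    ann[[length(ann) + 1L]] <- data.frame(
      cds_id = pl@cdsId, scaffold_id = s, start = st, end = st + 3L * nCodons,
      strand = "+", product = "planted variant CDS",
      top_hit_phylum = "Bacteroidetes", family_ids = NA_character_,
      is_marker = FALSE, stringsAsFactors = FALSE)
    pv <- plantVariants(cds, pl)
    if (nrow(pv$reads)) {
      nr <- nrow(pv$reads)
      smp <- ifelse(pv$reads$season == "summer",
                    summerSamples[(seq_len(nr) %% max(1L, length(summerSamples))) + 1L][seq_len(nr)],
                    winterSamples[(seq_len(nr) %% max(1L, length(winterSamples))) + 1L][seq_len(nr)])
      qual <- vapply(nchar(pv$reads$sequence), function(L)
        encodeQuality(drawQualities(L, spec@qualityHighFraction)), character(1))
      variantReadRows[[length(variantReadRows) + 1L]] <- data.frame(
        read_id = pv$reads$read_id, scaffold_id = s,
        start = st, end = st + 3L * nCodons, strand = "+",
        sample_id = smp, season = pv$reads$season,
        sequence = pv$reads$sequence, quality = qual,
        stringsAsFactors = FALSE)
      readHaplotype <- c(readHaplotype,
                         setNames(paste0(pl@cdsId, "_H", pv$reads$haplotype),
                                  pv$reads$read_id))
    }
  }
  annotations <- do.call(rbind, ann)

  ## --- background reads -------------------------------------------------
  readRows <- list()
  ridx <- 0L
  for (j in seq_len(nrow(spec@samples))) {
    fr <- spec@abundance[, j]
    probs <- c(fr, max(0, 1 - sum(fr)))
    counts <- stats::rmultinom(1L, spec@readsPerSample, probs)[, 1L]
    for (g in seq_len(nG)) {
      m <- counts[g]
      if (m == 0L) next
      gScafs <- scafId[scafGenome == paste0("G", g)]
      pick <- sample(gScafs, m, replace = TRUE, prob = scafLen[gScafs])
      lens <- pmax(100L, as.integer(round(rnorm(m, spec@readLengthMean,
                                                spec@readLengthSd))))
      lens <- pmin(lens, scafLen[pick])
      starts <- vapply(seq_len(m), function(i)
        sample.int(scafLen[[pick[i]]] - lens[i] + 1L, 1L) - 1L, integer(1))
      seqs <- substring(scafSeq[pick], starts + 1L, starts + lens)
      nerr <- rbinom(m, lens, spec@errorRate)
      for (i in which(nerr > 0L)) {
        p <- sample.int(lens[i], nerr[i])
        for (pp in p) {
          old <- substr(seqs[i], pp, pp)
          substr(seqs[i], pp, pp) <- sample(setdiff(c("A","C","G","T"), old), 1L)
        }
      }
      quals <- vapply(lens, function(L)
        encodeQuality(drawQualities(L, spec@qualityHighFraction)), character(1))
      ids <- sprintf("R%07d", ridx + seq_len(m))
      ridx <- ridx + m
      readRows[[length(readRows) + 1L]] <- data.frame(
        read_id = ids, scaffold_id = pick, start = starts,
        end = starts + lens, strand = sample(c("+", "-"), m, replace = TRUE),
        sample_id = spec@samples$sample_id[j],
        season = spec@samples$season[j],
        sequence = unname(seqs), quality = quals,
        stringsAsFactors = FALSE)
    }
  }
  alignments <- do.call(rbind, c(readRows, variantReadRows))
  if (is.null(alignments))
    alignments <- data.frame(read_id = character(), scaffold_id = character(),
                             start = integer(), end = integer(),
                             strand = character(), sample_id = character(),
                             season = character(), sequence = character(),
                             quality = character())
  rownames(alignments) <- NULL

  truth <- list(
    scaffold_genome = scafGenome,
    read_haplotype = readHaplotype,
    core_placements = do.call(rbind, corePlacements)
  )
  new("SyntheticCommunity",
      scaffolds = Biostrings::DNAStringSet(scafSeq),
      alignments = alignments,
      annotations = annotations,
      truth = truth,
      spec = spec)
}

## Phred-like qualities: `highFrac` of bases uniform on 30..45, the rest
## uniform on 10..29
drawQualities <- function(L, highFrac) {
  hi <- runif(L) < highFrac
  q <- integer(L)
  q[hi] <- sample(30:45, sum(hi), replace = TRUE)
  q[!hi] <- sample(10:29, sum(!hi), replace = TRUE)
  q
}
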