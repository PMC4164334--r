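## hand-build a pileup from explicit per-read strings ("." = not covered)
pileupFromStrings <- function(reads, quals = NULL) {
  width <- nchar(reads[1])
  bases <- do.call(rbind, lapply(reads, function(r) {
    v <- strsplit(r, "")[[1]]
    v[v == "."] <- NA
    v
  }))
  q <- if (is.null(quals)) matrix(40L, length(reads), width) else
    do.call(rbind, lapply(quals, function(x) as.integer(x)))
  q[is.na(bases)] <- NA
  structure(list(positions = seq_len(width) - 1L, bases = bases, quals = q,
                 read_ids = sprintf("r%02d", seq_along(reads)),
                 scaffold_id = "s"),
            class = "flavbin_pileup")
}

test_that("unsupported low-quality calls are corrected to the consensus", {
  pu <- pileupFromStrings(c("T", "A", "A", "A", "A"),
                          list(29L, 40L, 40L, 40L, 40L))
  out <- correctLowQuality(pu)
  expect_equal(out$bases[1, 1], "A")        # lone Q29 T -> consensus A

  ## two mutually supporting low-quality Ts survive
  pu2 <- pileupFromStrings(c("T", "T", "A", "A", "A"),
                           list(29L, 29L, 40L, 40L, 40L))
  out2 <- correctLowQuality(pu2)
  expect_equal(out2$bases[1:2, 1], c("T", "T"))

  ## Q30 singleton is at the cutoff and kept
  pu3 <- pileupFromStrings(c("T", "A", "A", "A", "A"),
                           list(30L, 40L, 40L, 40L, 40L))
  expect_equal(correctLowQuality(pu3)$bases[1, 1], "T")
})

test_that("SNP calls require >= 4x coverage and >= 2 mutated reads", {
  expect_equal(nrow(callSnps(pileupFromStrings(c("A", "A", "G", "G")))), 1L)
  expect_equal(nrow(callSnps(pileupFromStrings(c("A", "A", "A", "G")))), 0L)
  expect_equal(nrow(callSnps(pileupFromStrings(c("A", "G", "G")))), 0L)
  snp <- callSnps(pileupFromStrings(c("AA", "AA", "GA", "GA", "CA")))
  expect_equal(snp$position, 0L)
  expect_equal(snp$alt, "G")   # C is a singleton, not reported
})

test_that("the caller matches a brute-force column scan on random pileups", {
  set.seed(101)
  for (i in 1:300) {
    pu <- randomPileup(nReads = sample(2:8, 1), width = sample(3:12, 1),
                       naFrac = runif(1, 0, 0.5))
    got <- callSnps(pu)$position
    want <- bruteSnpScan(pu$bases, pu$positions)
    expect_identical(got, as.integer(want),
                     info = sprintf("random pileup %d", i))
  }
})

test_that("CDS selection uses mean depth with a strict 7x cutoff", {
  ## 8 reads of 70 bp over a 80 bp CDS -> depth 7.0 exactly -> excluded
  mk <- function(n, len, cdsLen = 80L) {
    data.frame(read_id = sprintf("r%d", 1:n), scaffold_id = "s",
               start = 0L, end = len, strand = "+", sample_id = "x",
               season = "summer",
               sequence = strrep("A", len), quality = strrep("I", len))
  }
  cds <- data.frame(cds_id = "c1", scaffold_id = "s", start = 0L, end = 80L)
  expect_equal(nrow(selectCds(cds, mk(8, 70L))), 0L)     # exactly 7.0
  sel <- selectCds(cds, mk(8, 75L))                       # 7.5
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$mean_coverage, 7.5)
  expect_equal(nrow(selectCds(cds, mk(0, 10L)[0, ])), 0L)
})

test_that("two planted haplotypes are recovered as exactly two tracks", {
  set.seed(55)
  cds <- randomStopFreeCds(100)
  plan <- variantPlan("c", 2, synSnps = 3, nonsynSnps = 2,
                      readsPerHaplotype = 10, seasonBias = c(1, 0))
  pv <- plantVariants(cds, plan)
  aln <- data.frame(read_id = pv$reads$read_id, scaffold_id = "s",
                    start = 0L, end = nchar(cds), strand = "+",
                    sample_id = "x", season = pv$reads$season,
                    sequence = pv$reads$sequence,
                    quality = strrep("I", nchar(cds)))
  pu <- buildPileup(aln, "s", 0L, nchar(cds))
  snps <- callSnps(pu)
  expect_equal(nrow(snps), 5L)
  seasons <- setNames(aln$season, aln$read_id)
  tr <- reconstructTracks(pu, snps, seasons)
  expect_equal(tr$classification, "multi_variant")
  expect_length(tr$tracks, 2L)
  memberships <- lapply(tr$tracks, function(t)
    sort(unique(pv$reads$haplotype[match(t$read_ids, pv$reads$read_id)])))
  expect_setequal(memberships, list(1L, 2L))      # exact recovery
  expect_setequal(unlist(lapply(tr$tracks, `[[`, "read_ids")),
                  aln$read_id)                    # partition of all reads
  expect_setequal(vapply(tr$tracks, `[[`, character(1), "season"),
                  c("summer_only", "winter_only"))
})

test_that("three haplotypes with seasonal structure are recovered", {
  set.seed(56)
  cds <- randomStopFreeCds(150)  # 450 bp region, three variants
  plan <- variantPlan("c", 3, synSnps = 4, nonsynSnps = 1,
                      readsPerHaplotype = 4, seasonBias = c(1, 0.5, 0))
  pv <- plantVariants(cds, plan)
  aln <- data.frame(read_id = pv$reads$read_id, scaffold_id = "s",
                    start = 0L, end = nchar(cds), strand = "+",
                    sample_id = "x", season = pv$reads$season,
                    sequence = pv$reads$sequence,
                    quality = strrep("I", nchar(cds)))
  pu <- buildPileup(aln, "s", 0L, nchar(cds))
  tr <- reconstructTracks(pu, callSnps(pu), setNames(aln$season, aln$read_id))
  expect_equal(tr$classification, "multi_variant")
  expect_length(tr$tracks, 3L)
  seas <- vapply(tr$tracks, `[[`, character(1), "season")
  expect_setequal(seas, c("summer_only", "both", "winter_only"))
})

test_that("no SNPs yields one track; disjoint SNP reads degrade to undetermined", {
  pu <- pileupFromStrings(c("AAAA", "AAAA", "AAAA", "AAAA"))
  tr <- reconstructTracks(pu, callSnps(pu))
  expect_equal(tr$classification, "no_snps")
  expect_length(tr$tracks, 1L)
  expect_length(tr$tracks[[1]]$read_ids, 4L)

  ## two reads disagreeing at their only shared SNP -> two tracks
  pu2 <- pileupFromStrings(c("A", "A", "G", "G"))
  tr2 <- reconstructTracks(pu2, callSnps(pu2))
  expect_length(tr2$tracks, 2L)

  ## transitive single-link conflict: x~y at site 0, y~z at site 1, but x
  ## and z disagree at site 2 -> the merged component cannot be resolved
  pu3 <- pileupFromStrings(c("A.G.", "A.G.",   # x
                             "AC..", "AC..",   # y
                             ".CT.", ".CT.",   # z
                             "G...", "G...",   # alt allele at site 0
                             ".T..", ".T.."))  # alt allele at site 1
  snps3 <- callSnps(pu3)
  expect_setequal(snps3$position, 0:2)
  tr3 <- reconstructTracks(pu3, snps3)
  expect_equal(tr3$classification, "undetermined")
})

test_that("reference track choice: reads, then identity, then id", {
  t1 <- list(read_ids = c("b1", "b2"), alleles = "A", consensus = "AAAA",
             span = 4L, season = "both")
  t2 <- list(read_ids = c("a1", "a2", "a3"), alleles = "G",
             consensus = "GAAA", span = 4L, season = "both")
  expect_equal(pickReference(list(t1, t2), "AAAA"), 2L)   # most reads
  t3 <- list(read_ids = c("c1", "c2", "c3"), alleles = "T",
             consensus = "TTTA", span = 4L, season = "both")
  expect_equal(pickReference(list(t3, t2), "GAAA"), 2L)   # identity tiebreak
  expect_equal(pickReference(list(t2), "AAAA"), 1L)       # single track
})

test_that("season classification is strict about labels", {
  expect_equal(classifySeason(c("summer", "summer")), "summer_only")
  expect_equal(classifySeason(c("winter")), "winter_only")
  expect_equal(classifySeason(c("summer", "winter")), "both")
  expect_error(classifySeason(c("summer", NA)), "season label")
  expect_error(classifySeason(character(0)), "season label")
})

test_that("the variant census summary reproduces the expected totals", {
  census <- readVariantCensus(system.file("extdata", "variant_census.tsv",
                                          package = "flavbin"))
  tot <- summarizeVariantCensus(census)
  expect_equal(unname(tot["winter_only"]), 23)
  expect_equal(unname(tot["summer_only"]), 36)
  expect_equal(unname(tot["both_seasons"]), 42)
  expect_equal(unname(tot["total_variants"]), 101)
})
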