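test_that("degenerate specs: single scaffold without reads, infeasible specs", {
  spec <- communitySpec(numGenomes = 1, genomeLength = 10000L,
                        scaffoldLengthRange = c(10000L, 10000L),
                        readsPerSample = 0L, plantedCscgCount = 2L,
                        abundance = matrix(1, 1, 6), seed = 3L)
  cm <- generateCommunity(spec)
  expect_length(scaffolds(cm), 1L)
  expect_equal(nrow(alignments(cm)), 0L)

  expect_error(communitySpec(genomeLength = 10000L,
                             scaffoldLengthRange = c(20000L, 30000L)),
               "longer than the genome")
  expect_error(communitySpec(readLengthMean = 0), "readLengthMean")
  bad <- matrix(0.6, 4, 6)  # columns sum to 2.4
  expect_error(communitySpec(abundance = bad), "sum to <= 1")
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- communitySpec(numGenomes = 2, genomeLength = 60000L,
                        scaffoldLengthRange = c(5000L, 8000L),
                        readsPerSample = 60L, plantedCscgCount = 5L,
                        seed = 99L)
  a <- generateCommunity(spec)
  b <- generateCommunity(spec)
  expect_identical(as.character(scaffolds(a)), as.character(scaffolds(b)))
  expect_identical(alignments(a), alignments(b))
  expect_identical(annotations(a), annotations(b))
})

test_that("genomes have distinguishable composition (within-genome r > between)", {
  cm <- smallCommunity()
  pr <- kmerProfiles(scaffolds(cm))
  g <- groundTruth(cm)$scaffold_genome[rownames(pr)]
  cc <- cor(t(pr))
  same <- cc[outer(g, g, "==") & upper.tri(cc)]
  diff <- cc[outer(g, g, "!=") & upper.tri(cc)]
  expect_gt(mean(same), mean(diff))
  expect_gt(min(same), max(diff))  # cleanly separable at these sizes
})

test_that("brute-force window tally agrees with the profile computation", {
  cm <- smallCommunity()
  s <- as.character(scaffolds(cm)[[1]])
  s <- substr(s, 1, 2000)
  for (k in c(3, 4)) {
    oracle <- bruteKmerFreq(s, k)
    p <- kmerProfile(s, kSet = k)
    names(p) <- sub(sprintf("^k%d_", k), "", names(p))
    p <- p[p > 0]
    expect_equal(sort(names(p)), sort(names(oracle)))
    expect_equal(p[sort(names(p))], oracle[sort(names(p))], tolerance = 1e-12)
  }
})

test_that("every emitted read maps within its scaffold and appears once", {
  cm <- smallCommunity()
  aln <- alignments(cm)
  lens <- setNames(Biostrings::width(scaffolds(cm)), names(scaffolds(cm)))
  expect_false(anyDuplicated(aln$read_id) > 0)
  expect_true(all(aln$start >= 0))
  expect_true(all(aln$end <= lens[aln$scaffold_id]))
  expect_true(all(nchar(aln$sequence) == aln$end - aln$start))
  expect_true(all(nchar(aln$quality) == aln$end - aln$start))
})

test_that("realized per-sample genome fractions track the abundance matrix", {
  spec <- communitySpec(numGenomes = 3, genomeLength = 100000L,
                        scaffoldLengthRange = c(5000L, 10000L),
                        readsPerSample = 2000L, plantedCscgCount = 3L,
                        seed = 21L)
  cm <- generateCommunity(spec)
  aln <- alignments(cm)
  g <- groundTruth(cm)$scaffold_genome
  readGenome <- g[aln$scaffold_id]
  for (j in seq_len(nrow(spec@samples))) {
    sid <- spec@samples$sample_id[j]
    sel <- readGenome[aln$sample_id == sid]
    realized <- table(factor(sel, levels = rownames(spec@abundance))) /
      spec@readsPerSample
    expected <- spec@abundance[, j]
    ## binomial sampling error: 4 sd at n = 2000
    tol <- 4 * sqrt(expected * (1 - expected) / spec@readsPerSample) + 1e-9
    expect_true(all(abs(as.numeric(realized) - expected) < tol))
  }
})

test_that("base qualities follow the quality model", {
  cm <- smallCommunity()
  q <- unlist(lapply(alignments(cm)$quality, function(s) utf8ToInt(s) - 33L))
  expect_gt(mean(q >= 30), 0.93)
  expect_lt(mean(q >= 30), 0.995)
})

test_that("plantVariants realises exact synonymous/nonsynonymous counts", {
  set.seed(5)
  cds <- randomStopFreeCds(405)  # 1,215 bp
  plan <- variantPlan("cdsX", numHaplotypes = 2, synSnps = 47,
                      nonsynSnps = 13, readsPerHaplotype = 4)
  pv <- plantVariants(cds, plan)
  h1 <- pv$haplotypes[1]; h2 <- pv$haplotypes[2]
  nd <- sum(strsplit(h1, "")[[1]] != strsplit(h2, "")[[1]])
  expect_equal(nd, 60)
  cls <- bruteSnpClasses(h1, h2)
  expect_equal(unname(cls["syn"]), 47)
  expect_equal(unname(cls["nonsyn"]), 13)
  ## no stops introduced
  aa <- Biostrings::translate(Biostrings::DNAString(h2),
                              genetic.code = Biostrings::getGeneticCode("11"))
  expect_false(grepl("\\*", as.character(aa)))
})

test_that("plantVariants degenerate plans and errors", {
  set.seed(6)
  cds <- randomStopFreeCds(30)
  one <- plantVariants(cds, variantPlan("c", numHaplotypes = 1,
                                        readsPerHaplotype = 2))
  expect_identical(one$haplotypes, cds)

  ## a single Phe codon admits one synonymous change and no second one
  expect_error(
    plantVariants("TTTTGG", variantPlan("c", 2, synSnps = 3, nonsynSnps = 0,
                                        readsPerHaplotype = 1)),
    "cannot place")
  expect_error(plantVariants("TTTA", variantPlan("c")), "divisible by 3")
  expect_error(plantVariants("TTTTAATTT", variantPlan("c")), "stop codons")

  pv <- plantVariants("TTTAAA", variantPlan("c", 2, synSnps = 1,
                                            nonsynSnps = 0,
                                            readsPerHaplotype = 1))
  cls <- bruteSnpClasses(pv$haplotypes[1], pv$haplotypes[2])
  expect_equal(unname(cls["syn"]), 1)
  expect_equal(unname(cls["nonsyn"]), 0)
})

test_that("planted haplotype reads carry the planned season split", {
  set.seed(7)
  cds <- randomStopFreeCds(60)
  pv <- plantVariants(cds, variantPlan("c", 3, synSnps = 2, nonsynSnps = 1,
                                       readsPerHaplotype = 10,
                                       seasonBias = c(1, 0.5, 0)))
  sp <- split(pv$reads$season, pv$reads$haplotype)
  expect_true(all(sp[["1"]] == "summer"))
  expect_equal(sum(sp[["2"]] == "summer"), 5)
  expect_true(all(sp[["3"]] == "winter"))
})
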