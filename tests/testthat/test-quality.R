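ann3 <- function(scaffold, phyla) {
  data.frame(cds_id = sprintf("%s_c%d", scaffold, seq_along(phyla)),
             scaffold_id = scaffold, start = 0L, end = 10L, strand = "+",
             product = "x", top_hit_phylum = phyla,
             family_ids = NA_character_, is_marker = FALSE,
             stringsAsFactors = FALSE)
}

test_that("taxonomy vote removes scaffolds strictly below 60%", {
  ann <- rbind(
    ann3("s50", c(rep("Bacteroidetes", 5), rep("Proteobacteria", 5))),
    ann3("s60", c(rep("Bacteroidetes", 6), rep("Proteobacteria", 4))),
    ann3("sNA", rep(NA_character_, 3))
  )
  out <- taxonomyFilter(c("s50", "s60", "sNA", "sEmpty"), ann)
  expect_setequal(out$removed, "s50")           # 50% < 60% -> removed
  expect_true("s60" %in% out$kept)              # exactly 60% retained
  expect_setequal(out$flagged, c("sNA", "sEmpty"))  # no evidence, retained
  expect_true(all(out$flagged %in% out$kept))

  ## idempotent
  again <- taxonomyFilter(out$kept, ann)
  expect_setequal(again$kept, out$kept)
})

test_that("duplicate-scaffold removal drops the shorter at >= 85% shared genes", {
  lens <- c(L = 10000L, Mid = 6000L, S = 4000L)
  cdsScaffold <- c(setNames(rep("L", 10), paste0("L", 1:10)),
                   setNames(rep("S", 10), paste0("S", 1:10)),
                   setNames(rep("Mid", 4), paste0("M", 1:4)))
  ## 9/10 of S's genes homologous on L -> 90% -> S removed
  pairs <- data.frame(cds_a = paste0("S", 1:9), cds_b = paste0("L", 1:9))
  out <- dedupScaffolds(c("L", "Mid", "S"), lens, cdsScaffold, pairs)
  expect_setequal(out$removed, "S")

  ## exactly 85%: 17/20 genes
  cds2 <- c(setNames(rep("L", 20), paste0("l", 1:20)),
            setNames(rep("S", 20), paste0("s", 1:20)))
  p85 <- data.frame(cds_a = paste0("s", 1:17), cds_b = paste0("l", 1:17))
  out85 <- dedupScaffolds(c("L", "S"), lens[c("L", "S")], cds2, p85)
  expect_setequal(out85$removed, "S")

  ## disjoint content: both kept; and idempotence
  none <- data.frame(cds_a = character(), cds_b = character())
  outN <- dedupScaffolds(c("L", "S"), lens[c("L", "S")], cds2, none)
  expect_length(outN$removed, 0L)
  again <- dedupScaffolds(out$kept, lens, cdsScaffold, pairs)
  expect_length(again$removed, 0L)
})

test_that("core genome is the per-family minimum over genomes with CSCGs at one", {
  counts <- rbind(G1 = c(M1 = 2L, M2 = 1L, M3 = 1L),
                  G2 = c(M1 = 3L, M2 = 1L, M3 = 0L),
                  G3 = c(M1 = 2L, M2 = 1L, M3 = 5L))
  core <- buildCoreGenome(counts)
  expect_equal(coreFamilies(core), c(M1 = 2L, M2 = 1L))
  expect_equal(expectedCoreTotal(core), 3L)
  expect_equal(cscgFamilies(core), "M2")

  ## all singletons -> all CSCG
  ones <- matrix(1L, 3, 4, dimnames = list(NULL, paste0("F", 1:4)))
  expect_setequal(cscgFamilies(buildCoreGenome(ones)), paste0("F", 1:4))
  ## a zero row empties the core
  zero <- rbind(ones, 0L)
  expect_length(coreFamilies(buildCoreGenome(zero)), 0L)
  expect_error(buildCoreGenome(counts[1, , drop = FALSE]), "two genomes")
})

test_that("core minimum matches an exhaustive scan on random tables", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rpois(5 * 8, 1.2), 5, 8,
                dimnames = list(NULL, paste0("F", 1:8)))
    core <- buildCoreGenome(m)
    for (f in colnames(m)) {
      inAll <- all(m[, f] >= 1)
      expect_equal(f %in% names(coreFamilies(core)), inAll)
      if (inAll)
        expect_equal(unname(coreFamilies(core)[f]), min(m[, f]))
      expect_equal(f %in% cscgFamilies(core), all(m[, f] == 1))
    }
  }
})

test_that("completeness and duplication follow the estimator arithmetic", {
  counts <- matrix(1L, 2, 199, dimnames = list(NULL, sprintf("C%03d", 1:199)))
  ## pad the core to 665 families / 799 occurrences with multi-copy families
  extra <- matrix(2L, 2, 134, dimnames = list(NULL, sprintf("X%03d", 1:134)))
  core <- buildCoreGenome(cbind(counts, extra))
  expect_equal(length(coreFamilies(core)), 333L)
  core799 <- new("CoreGenome",
                 coreCounts = setNames(c(rep(1L, 199), rep(600L, 1)),
                                       c(sprintf("C%03d", 1:199), "BULK")),
                 cscg = sprintf("C%03d", 1:199))
  expect_equal(expectedCoreTotal(core799), 799L)
  expect_equal(estimateCompleteness(668, core799), 83.60)
  expect_equal(estimateCompleteness(457, core799), 57.20)
  expect_equal(estimateCompleteness(0, core799), 0)
  expect_equal(estimateCompleteness(799, core799), 100)
  expect_equal(estimateDuplication(14, core799), 7.04)
  expect_equal(estimateDuplication(4, core799), 2.01)
  expect_equal(estimateDuplication(0, core799), 0)
  expect_error(estimateDuplication(1, new("CoreGenome",
                                          coreCounts = c(A = 2L),
                                          cscg = character(0))),
               "single-copy")
})

test_that("genome-size extrapolation matches the reference bin table within 2 bp", {
  expect_equal(extrapolateGenomeSize(2220739, 83.60, 0.00), 2656386,
               tolerance = 2.1 / 2656386)
  expect_equal(extrapolateGenomeSize(703361, 36.80, 2.01), 1872889,
               tolerance = 2.1 / 1872889)
  expect_equal(extrapolateGenomeSize(1453303, 57.20, 7.04), 2361871,
               tolerance = 2.1 / 2361871)
  expect_equal(extrapolateGenomeSize(799420, 37.92, 0.00), 2108175,
               tolerance = 2.1 / 2108175)
  expect_identical(extrapolateGenomeSize(12345, 100, 0), 12345)
  expect_error(extrapolateGenomeSize(1000, 0, 0), "positive")
})

test_that("planted core genes are recovered as completeness on synthetic bins", {
  cm <- smallCommunity()
  ann <- annotations(cm)
  cp <- groundTruth(cm)$core_placements
  pang <- table(cp$genome, cp$family)
  pang <- matrix(as.integer(pang), nrow(pang), dimnames = dimnames(pang))
  core <- buildCoreGenome(pang)

  g1 <- names(groundTruth(cm)$scaffold_genome)[
    groundTruth(cm)$scaffold_genome == "G1"]
  cc <- countCoreFamilies(g1, ann, core)
  ## the whole genome holds every planted family exactly once
  expect_equal(cc$identified_core, expectedCoreTotal(core))
  expect_equal(cc$duplicate_cscgs, 0L)
  expect_equal(estimateCompleteness(cc$identified_core, core), 100)

  ## dropping scaffolds drops identified core genes accordingly (+-1)
  drop <- unique(cp$scaffold_id[cp$genome == "G1"])[1]
  kept <- setdiff(g1, drop)
  lost <- sum(cp$genome == "G1" & cp$scaffold_id == drop)
  cc2 <- countCoreFamilies(kept, ann, core)
  expect_equal(cc2$identified_core, cc$identified_core - lost)

  ## merging two genomes doubles single-copy genes -> 100% duplication
  g2 <- names(groundTruth(cm)$scaffold_genome)[
    groundTruth(cm)$scaffold_genome == "G2"]
  ccM <- countCoreFamilies(c(g1, g2), ann, core)
  expect_equal(estimateDuplication(ccM$duplicate_cscgs, core), 100)
})
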