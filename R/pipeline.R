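## The pipeline driver: configuration defaults for every stage threshold,
## and the staged run from scaffolds to bins, quality,
## variants and biogeography.

#' Pipeline configuration with the default stage thresholds
#'
#' @param rMin minimum within-cluster profile correlation (0.90).
#' @param minScaffoldBpPass1 length filter before clustering (3,000 bp,
#'   strict >).
#' @param minScaffoldBpPass2 length filter in the read-count pass
#'   (5,000 bp, strict >).
#' @param minBinBp first-pass cumulative size filter (1.9 Mbp, strict >).
#' @param minBinReads second-pass read filter (10,000 reads, strict >).
#' @param dupMaxPct subdivision cap on percent duplication (10).
#' @param taxonVoteMin taxonomy vote below which a scaffold is removed
#'   (0.60, strict <).
#' @param dedupMinShared shared-gene fraction at which the shorter of two
#'   scaffolds is dropped (0.85, >=).
#' @param snpMinCov minimum coverage for SNP calling (4).
#' @param snpMinAlt minimum reads on an alternative allele (2).
#' @param cdsMinCov CDS mean-coverage cutoff (7, strict >).
#' @param qMin Phred cutoff for the low-quality correction (30).
#' @param dsSaturation dS saturation cutoff (2.0).
#' @param permutations permutation count for abundance tests (10,000).
#' @param seed RNG seed for the permutation stage.
#' @return a list of class \code{"flavbin_config"}.
#' @export
pipelineConfig <- function(rMin = 0.90,
                           minScaffoldBpPass1 = 3000,
                           minScaffoldBpPass2 = 5000,
                           minBinBp = 1.9e6,
                           minBinReads = 10000,
                           dupMaxPct = 10.0,
                           taxonVoteMin = 0.60,
                           dedupMinShared = 0.85,
                           snpMinCov = 4L,
                           snpMinAlt = 2L,
                           cdsMinCov = 7,
                           qMin = 30L,
                           dsSaturation = 2.0,
                           permutations = 10000L,
                           seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[setdiff(names(cfg), "seed")],
                       function(v) is.numeric(v) && v > 0 || identical(v, 0),
                       logical(1))))
  structure(cfg, class = "flavbin_config")
}

#' Run the full pipeline on a synthetic (or loaded) community
#'
#' Stages, in order: composition profiles and clustering; marker-seeded
#' cluster extraction with the size filter; the read-count pass; taxonomy
#' and duplicate-scaffold refinement; completeness/duplication quality
#' reporting with the subdivision loop; variant tracks and dN/dS over
#' sufficiently covered CDS; and bin abundance with seasonal outliers.
#' A stage failure halts the run with prior outputs intact in the
#' returned manifest.
#'
#' @param community a [SyntheticCommunity-class] (or an object with the
#'   same accessors).
#' @param pangenome genomes x families count matrix for the core genome;
#'   by default derived from the community's planted core placements.
#' @param config a [pipelineConfig()] list.
#' @param outDir optional directory; when given, stage outputs are written
#'   as TSV/FASTA.
#' @return a manifest list: \code{config}, per-stage outputs, and
#'   \code{timings} (seconds per stage).
#' @export
runPipeline <- function(community, pangenome = NULL,
                        config = pipelineConfig(), outDir = NULL) {
  manifest <- list(config = config, timings = c())
  tic <- function() proc.time()[["elapsed"]]
  stamp <- function(stage, t0)
    manifest$timings[[stage]] <<- round(tic() - t0, 3L)

  seqs <- scaffolds(community)
  aln <- alignments(community)
  ann <- annotations(community)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  reads <- table(factor(aln$scaffold_id, levels = names(seqs)))
  reads <- setNames(as.integer(reads), names(seqs))

  ## stage 1: composition binning
  t0 <- tic()
  profiles <- kmerProfiles(seqs)
  tree <- clusterScaffolds(profiles, lens, config$minScaffoldBpPass1)
  markers <- unique(ann$scaffold_id[ann$is_marker %in% TRUE])
  binSet <- extractSeedClusters(tree, markers, lens, reads, config$rMin)
  binSet <- filterCandidates(binSet, "size", minBp = config$minBinBp)
  binSet <- filterCandidates(binSet, "reads", minReads = config$minBinReads,
                             minScaffoldBp = config$minScaffoldBpPass2)
  manifest$bins <- binSet
  stamp("binning", t0)
  if (length(binSet@bins) == 0L) {
    warning("no bins pass the filters; stopping after binning")
    return(manifest)
  }

  ## stage 2: refinement
  t0 <- tic()
  cdsScaffold <- setNames(ann$scaffold_id, ann$cds_id)
  fams <- splitFamilyIds(ann$family_ids)
  famKey <- vapply(fams, function(v)
    if (length(v)) v[1L] else NA_character_, character(1))
  shared <- split(ann$cds_id, famKey)
  homologyPairs <- do.call(rbind, lapply(shared, function(ids) {
    if (length(ids) < 2L) return(NULL)
    t(combn(ids, 2L))
  }))
  homologyPairs <- if (is.null(homologyPairs))
    data.frame(cds_a = character(), cds_b = character())
  else data.frame(cds_a = homologyPairs[, 1L], cds_b = homologyPairs[, 2L])
  refined <- lapply(binSet@bins, function(v) {
    tf <- taxonomyFilter(v, ann, minFrac = config$taxonVoteMin)
    dd <- dedupScaffolds(tf$kept, lens, cdsScaffold, homologyPairs,
                         minShared = config$dedupMinShared)
    dd$kept
  })
  binSet <- newBinSet(refined, lens, reads, markers, binSet@unconverged)
  manifest$refined <- binSet
  stamp("refinement", t0)

  ## stage 3: quality with subdivision
  t0 <- tic()
  if (is.null(pangenome)) {
    cp <- groundTruth(community)$core_placements
    if (is.null(cp)) stop("quality stage needs a pangenome count table")
    pangenome <- with(cp, table(genome, family))
    pangenome <- matrix(as.integer(pangenome), nrow(pangenome),
                        dimnames = dimnames(pangenome))
  }
  core <- buildCoreGenome(pangenome)
  dupOf <- function(ids) {
    cc <- countCoreFamilies(ids, ann, core)
    estimateDuplication(cc$duplicate_cscgs, core)
  }
  cleaned <- list()
  unconv <- character(0)
  for (b in names(binSet@bins)) {
    sub <- subdivideUntilClean(binSet@bins[[b]], profiles, dupOf,
                               dupMax = config$dupMaxPct)
    nm <- if (length(sub$bins) == 1L) b else
      paste0(b, letters[seq_along(sub$bins)])
    names(sub$bins) <- nm
    cleaned <- c(cleaned, sub$bins)
    unconv <- c(unconv, nm[sub$unconverged])
  }
  binSet <- newBinSet(cleaned, lens, reads, markers, unconv)
  manifest$quality <- binQualityReport(binSet, ann, core)
  manifest$finalBins <- binSet
  stamp("quality", t0)

  ## stage 4: variants
  t0 <- tic()
  readSeason <- setNames(aln$season, aln$read_id)
  eligible <- selectCds(ann, aln, minCov = config$cdsMinCov)
  variantRows <- list()
  for (i in seq_len(nrow(eligible))) {
    cds <- eligible[i, ]
    pu <- buildPileup(aln, cds$scaffold_id, cds$start, cds$end)
    pu <- correctLowQuality(pu, qMin = config$qMin)
    snps <- callSnps(pu, minCov = config$snpMinCov,
                     minAlt = config$snpMinAlt)
    tr <- reconstructTracks(pu, snps, readSeason)
    variantRows[[cds$cds_id]] <- list(
      cds_id = cds$cds_id, n_snps = nrow(snps),
      classification = tr$classification, tracks = tr$tracks)
  }
  manifest$variants <- variantRows
  stamp("variants", t0)

  ## stage 5: biogeography
  t0 <- tic()
  manifest$abundance <- abundanceMatrix(binSet, aln)
  manifest$outliers <- lapply(binSet@bins, seasonalOutliers, alignTab = aln)
  stamp("biogeography", t0)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    memb <- data.frame(
      bin_id = rep(names(binSet@bins),
                   vapply(binSet@bins, length, integer(1))),
      scaffold_id = unlist(binSet@bins, use.names = FALSE))
    write.table(memb, file.path(outDir, "bins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(manifest$quality, file.path(outDir, "quality.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(manifest$abundance, file.path(outDir, "abundance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <- file.path(outDir,
                                  c("bins.tsv", "quality.tsv", "abundance.tsv"))
  }
  manifest
}
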