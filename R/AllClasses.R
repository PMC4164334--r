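#' @import methods
#' @importFrom stats cor cutree hclust as.dist quantile rbinom rnorm runif
#'   setNames var ks.test
#' @importFrom utils read.delim write.table head combn
NULL

#' Plan for planting gene variants into a synthetic CDS
#'
#' Describes a set of haplotypes to plant over one coding sequence: how many
#' haplotypes, how many synonymous and nonsynonymous point differences each
#' non-reference haplotype carries relative to haplotype 1 (classified under
#' the bacterial genetic code, table 11), how many reads support each
#' haplotype, and what fraction of those reads are labelled summer.
#'
#' @slot cdsId character(1) identifier of the target CDS.
#' @slot numHaplotypes integer(1), at least 1.
#' @slot synSnps integer(1) synonymous changes per non-reference haplotype.
#' @slot nonsynSnps integer(1) nonsynonymous changes per non-reference
#'   haplotype.
#' @slot readsPerHaplotype integer(1) reads emitted per haplotype.
#' @slot seasonBias numeric, fraction of each haplotype's reads labelled
#'   summer; length 1 (recycled) or \code{numHaplotypes}.
#'
#' @exportClass VariantPlan
setClass("VariantPlan",
  representation(
    cdsId = "character",
    numHaplotypes = "integer",
    synSnps = "integer",
    nonsynSnps = "integer",
    readsPerHaplotype = "integer",
    seasonBias = "numeric"
  )
)

setValidity("VariantPlan", function(object) {
  msg <- character()
  if (length(object@numHaplotypes) != 1L || object@numHaplotypes < 1L)
    msg <- c(msg, "numHaplotypes must be a single integer >= 1")
  if (object@synSnps < 0L || object@nonsynSnps < 0L)
    msg <- c(msg, "SNP counts must be non-negative")
  if (object@readsPerHaplotype < 0L)
    msg <- c(msg, "readsPerHaplotype must be non-negative")
  if (any(object@seasonBias < 0) || any(object@seasonBias > 1))
    msg <- c(msg, "seasonBias must lie in [0, 1]")
  if (!length(object@seasonBias) %in% c(1L, object@numHaplotypes))
    msg <- c(msg, "seasonBias must have length 1 or numHaplotypes")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic metagenomic community
#'
#' Parameters for [generateCommunity()]: the number and length of genomes,
#' the order of the per-genome Markov composition model, scaffold and read
#' length distributions, the genome-by-sample expected read fractions, the
#' sample design (site and season per sample), planted conserved single-copy
#' gene (CSCG) families, planted gene variants, and the sequencing error /
#' base quality model.
#'
#' @slot numGenomes integer(1) number of source genomes.
#' @slot genomeLength integer(1) length of each genome in bp.
#' @slot markovOrder integer(1) order of the composition Markov chain.
#' @slot scaffoldLengthRange integer(2) min and max scaffold length (bp).
#' @slot readLengthMean numeric(1) mean read length in bp.
#' @slot readLengthSd numeric(1) read length standard deviation in bp.
#' @slot abundance numeric matrix, genomes x samples, expected read
#'   fractions; each column sums to at most 1 (any remainder is unassigned).
#' @slot samples data.frame with columns \code{sample_id}, \code{site_id},
#'   \code{season} (\code{"summer"} or \code{"winter"}).
#' @slot readsPerSample integer(1) reads drawn per sample.
#' @slot plantedCscgCount integer(1) single-copy core families planted in
#'   every genome.
#' @slot plantedVariants list of [VariantPlan-class] objects.
#' @slot errorRate numeric(1) per-base substitution error rate.
#' @slot qualityHighFraction numeric(1) fraction of bases with Phred >= 30.
#' @slot seed integer(1) RNG seed; a fixed seed gives byte-identical output.
#'
#' @exportClass CommunitySpec
setClass("CommunitySpec",
  representation(
    numGenomes = "integer",
    genomeLength = "integer",
    markovOrder = "integer",
    scaffoldLengthRange = "integer",
    readLengthMean = "numeric",
    readLengthSd = "numeric",
    abundance = "matrix",
    samples = "data.frame",
    readsPerSample = "integer",
    plantedCscgCount = "integer",
    plantedVariants = "list",
    errorRate = "numeric",
    qualityHighFraction = "numeric",
    seed = "integer"
  )
)

setValidity("CommunitySpec", function(object) {
  msg <- character()
  if (object@numGenomes < 1L) msg <- c(msg, "need at least one genome")
  if (object@genomeLength < 1L) msg <- c(msg, "genomeLength must be positive")
  if (object@readLengthMean <= 0) msg <- c(msg, "readLengthMean must be > 0")
  if (length(object@scaffoldLengthRange) != 2L ||
      any(object@scaffoldLengthRange < 1L) ||
      diff(object@scaffoldLengthRange) < 0L)
    msg <- c(msg, "scaffoldLengthRange must be increasing positive (min, max)")
  if (object@scaffoldLengthRange[2L] > object@genomeLength)
    msg <- c(msg, "scaffolds cannot be longer than the genome")
  if (any(object@abundance < 0))
    msg <- c(msg, "abundance fractions must be non-negative")
  if (nrow(object@abundance) != object@numGenomes)
    msg <- c(msg, "abundance must have one row per genome")
  if (ncol(object@abundance) != nrow(object@samples))
    msg <- c(msg, "abundance must have one column per sample")
  if (any(colSums(object@abundance) > 1 + 1e-9))
    msg <- c(msg, "each sample's genome fractions must sum to <= 1")
  if (!all(object@samples$season %in% c("summer", "winter")))
    msg <- c(msg, "season must be 'summer' or 'winter'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec:", object@numGenomes, "genomes x",
      object@genomeLength, "bp (order-", object@markovOrder,
      " Markov composition)\n", sep = " ")
  cat("  scaffolds", object@scaffoldLengthRange[1L], "-",
      object@scaffoldLengthRange[2L], "bp; reads ~N(",
      object@readLengthMean, ",", object@readLengthSd, ") bp\n")
  cat("  samples:", nrow(object@samples), "(",
      sum(object@samples$season == "winter"), "winter,",
      sum(object@samples$season == "summer"), "summer ) x",
      object@readsPerSample, "reads\n")
  cat("  planted CSCG families:", object@plantedCscgCount,
      "; planted variant plans:", length(object@plantedVariants), "\n")
})

#' A generated synthetic community with ground truth
#'
#' Result of [generateCommunity()]: assembled scaffolds, a read alignment
#' table, CDS annotations, and the ground truth maps (scaffold to genome,
#' read to haplotype) against which every downstream stage can be scored.
#'
#' @slot scaffolds a [Biostrings::DNAStringSet] of scaffold sequences.
#' @slot alignments data.frame of reads: \code{read_id}, \code{scaffold_id},
#'   \code{start} (0-based), \code{end} (half-open), \code{strand},
#'   \code{sample_id}, \code{season}, \code{sequence} (scaffold
#'   orientation), \code{quality} (Phred+33 string).
#' @slot annotations data.frame of CDS: \code{cds_id}, \code{scaffold_id},
#'   \code{start}, \code{end} (0-based half-open), \code{strand},
#'   \code{product}, \code{top_hit_phylum}, \code{family_ids}
#'   (comma-separated), \code{is_marker}.
#' @slot truth list with \code{scaffold_genome} (named character),
#'   \code{read_haplotype} (named character, planted reads only), and
#'   \code{core_placements} (data.frame of planted core genes).
#' @slot spec the [CommunitySpec-class] used.
#'
#' @exportClass SyntheticCommunity
setClass("SyntheticCommunity",
  representation(
    scaffolds = "DNAStringSet",
    alignments = "data.frame",
    annotations = "data.frame",
    truth = "list",
    spec = "CommunitySpec"
  )
)

setMethod("show", "SyntheticCommunity", function(object) {
  cat("SyntheticCommunity:", length(object@scaffolds), "scaffolds (",
      sum(Biostrings::width(object@scaffolds)), "bp ) from",
      object@spec@numGenomes, "genomes\n")
  cat("  reads:", nrow(object@alignments), "; CDS annotations:",
      nrow(object@annotations), "\n")
})

#' A set of phylogenetic bins over scaffolds
#'
#' Container for the binning stage: each bin is a set of scaffold ids, with
#' per-scaffold lengths and read counts carried along so cumulative size and
#' read filters can be applied, plus the marker flags that seeded the bins.
#'
#' @slot bins named list of character vectors of scaffold ids.
#' @slot scaffoldLength named integer, bp per scaffold.
#' @slot scaffoldReads named integer, reads per scaffold.
#' @slot seedMarkers named list of character vectors: marker-bearing
#'   scaffolds per bin.
#' @slot unconverged character vector of bin ids whose subdivision hit the
#'   iteration cap.
#'
#' @exportClass BinSet
setClass("BinSet",
  representation(
    bins = "list",
    scaffoldLength = "integer",
    scaffoldReads = "integer",
    seedMarkers = "list",
    unconverged = "character"
  ),
  prototype(unconverged = character())
)

setValidity("BinSet", function(object) {
  all_ids <- unlist(object@bins, use.names = FALSE)
  if (anyDuplicated(all_ids))
    return("a scaffold may belong to at most one bin")
  if (!all(all_ids %in% names(object@scaffoldLength)))
    return("every binned scaffold needs a recorded length")
  TRUE
})

setMethod("show", "BinSet", function(object) {
  cat("BinSet of", length(object@bins), "bins\n")
  if (length(object@bins)) {
    s <- binSummary(object)
    print(head(s, 10L))
    if (nrow(s) > 10L) cat("  ...", nrow(s) - 10L, "more bins\n")
  }
})

#' Core genome derived from a pangenome count table
#'
#' The core genome of a reference pangenome: for every gene family present
#' in all member genomes, the expected per-genome multiplicity is the
#' minimum count observed across members. Families at exactly one copy in
#' every member are the conserved single-copy genes (CSCGs) used for
#' duplication screening.
#'
#' @slot coreCounts named integer: family id to expected count.
#' @slot cscg character vector of single-copy core family ids.
#'
#' @exportClass CoreGenome
setClass("CoreGenome",
  representation(coreCounts = "integer", cscg = "character")
)

setValidity("CoreGenome", function(object) {
  msg <- character()
  if (any(object@coreCounts < 1L))
    msg <- c(msg, "core family expected counts must be >= 1")
  if (!all(object@cscg %in% names(object@coreCounts)))
    msg <- c(msg, "cscg must be a subset of the core families")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoreGenome", function(object) {
  cat("CoreGenome:", length(object@coreCounts), "core families,",
      sum(object@coreCounts), "expected occurrences,",
      length(object@cscg), "single-copy (CSCG)\n")
})
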