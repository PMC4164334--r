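#' Accessors for synthetic communities and bin sets
#'
#' @param x a [SyntheticCommunity-class], [BinSet-class] or
#'   [CoreGenome-class] object as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))

#' @rdname accessors
#' @export
setGeneric("alignments", function(x) standardGeneric("alignments"))

#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("binMembers", function(x) standardGeneric("binMembers"))

#' @rdname accessors
#' @export
setGeneric("binSummary", function(x) standardGeneric("binSummary"))

#' @rdname accessors
#' @export
setGeneric("coreFamilies", function(x) standardGeneric("coreFamilies"))

#' @rdname accessors
#' @export
setGeneric("cscgFamilies", function(x) standardGeneric("cscgFamilies"))

#' @rdname accessors
#' @export
setGeneric("expectedCoreTotal", function(x) standardGeneric("expectedCoreTotal"))

#' @rdname accessors
setMethod("scaffolds", "SyntheticCommunity", function(x) x@scaffolds)

#' @rdname accessors
setMethod("alignments", "SyntheticCommunity", function(x) x@alignments)

#' @rdname accessors
setMethod("annotations", "SyntheticCommunity", function(x) x@annotations)

#' @rdname accessors
setMethod("groundTruth", "SyntheticCommunity", function(x) x@truth)

#' @rdname accessors
setMethod("binMembers", "BinSet", function(x) x@bins)

#' @rdname accessors
setMethod("binSummary", "BinSet", function(x) {
  data.frame(
    bin_id = names(x@bins),
    n_scaffolds = vapply(x@bins, length, integer(1)),
    cumulative_bp = vapply(x@bins, function(ids)
      sum(x@scaffoldLength[ids]), integer(1)),
    total_reads = vapply(x@bins, function(ids)
      sum(x@scaffoldReads[ids]), integer(1)),
    n_markers = vapply(names(x@bins), function(b)
      length(x@seedMarkers[[b]]), integer(1)),
    row.names = NULL
  )
})

#' @rdname accessors
setMethod("coreFamilies", "CoreGenome", function(x) x@coreCounts)

#' @rdname accessors
setMethod("cscgFamilies", "CoreGenome", function(x) x@cscg)

#' @rdname accessors
setMethod("expectedCoreTotal", "CoreGenome", function(x)
  sum(x@coreCounts))
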