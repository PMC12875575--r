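#' Accessors for TEforge objects
#'
#' `variants()` returns the `GRanges` of a catalog; `referenceId()` its
#' reference identifier; `nVariants()` the variant count. `alleles()` and
#' `alleleFreqs()` access a [GenotypeMatrix-class]; `sampleIds()` its sample
#' names. `matchedPairs()`, `unmatchedTruth()` and `unmatchedPred()` access a
#' [MatchSet-class].
#'
#' @param x a TEforge object.
#' @return the slot contents (see Details of each class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setMethod("variants", "TECatalog", function(x) x@variants)

#' @rdname accessors
#' @export
setGeneric("referenceId", function(x) standardGeneric("referenceId"))
#' @rdname accessors
#' @export
setMethod("referenceId", "TECatalog", function(x) x@referenceId)

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setMethod("nVariants", "TECatalog", function(x) length(x@variants))

#' @rdname accessors
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))
#' @rdname accessors
#' @export
setMethod("alleles", "GenotypeMatrix", function(x) x@alleles)

#' @rdname accessors
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))
#' @rdname accessors
#' @export
setMethod("alleleFreqs", "GenotypeMatrix", function(x) x@freqs)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))
#' @rdname accessors
#' @export
setMethod("ploidy", "GenotypeMatrix", function(x) x@ploidy)

#' @rdname accessors
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))
#' @rdname accessors
#' @export
setMethod("matchedPairs", "MatchSet", function(x) x@matches)

#' @rdname accessors
#' @export
setGeneric("unmatchedTruth", function(x) standardGeneric("unmatchedTruth"))
#' @rdname accessors
#' @export
setMethod("unmatchedTruth", "MatchSet", function(x) x@unmatchedTruth)

#' @rdname accessors
#' @export
setGeneric("unmatchedPred", function(x) standardGeneric("unmatchedPred"))
#' @rdname accessors
#' @export
setMethod("unmatchedPred", "MatchSet", function(x) x@unmatchedPred)
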