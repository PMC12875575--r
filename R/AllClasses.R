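#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
NULL

DNA_BASES_STRICT <- c("A", "C", "G", "T")

#' Mutation-model parameters for TE consensus sequences
#'
#' Holds the per-base rates and per-sequence fractions of the sequence
#' variation model applied to TE insertion sequences: SNPs, INDELs with
#' geometric lengths, 5' truncation and a 3' polyA tail.
#'
#' @slot snpRate per-base SNP probability.
#' @slot indelRate per-base probability of seeding an INDEL event.
#' @slot indelGeomP success parameter of the geometric INDEL length
#'   distribution on \{1, 2, ...\}.
#' @slot truncateSeqFraction fraction of sequences subjected to 5' truncation.
#' @slot maxTruncateLenFraction maximum fraction of a sequence's length that a
#'   truncation may remove.
#' @slot polyaMinLen,polyaMaxLen integer bounds on the appended polyA tail.
#' @slot polyaFraction fraction of sequences receiving a polyA tail.
#' @export
setClass("VariationProfile",
  representation(
    snpRate = "numeric",
    indelRate = "numeric",
    indelGeomP = "numeric",
    truncateSeqFraction = "numeric",
    maxTruncateLenFraction = "numeric",
    polyaMinLen = "integer",
    polyaMaxLen = "integer",
    polyaFraction = "numeric"
  )
)

setValidity("VariationProfile", function(object) {
  msg <- character()
  fr <- c(
    snpRate = object@snpRate, indelRate = object@indelRate,
    truncateSeqFraction = object@truncateSeqFraction,
    maxTruncateLenFraction = object@maxTruncateLenFraction,
    polyaFraction = object@polyaFraction
  )
  bad <- names(fr)[!is.finite(fr) | fr < 0 | fr > 1]
  if (length(bad))
    msg <- c(msg, paste0("rates/fractions must lie in [0,1]: ",
                         paste(bad, collapse = ", ")))
  p <- object@indelGeomP
  if (!is.finite(p) || p <= 0 || p > 1)
    msg <- c(msg, "indelGeomP must lie in (0,1]")
  if (object@polyaMinLen < 0L || object@polyaMinLen > object@polyaMaxLen)
    msg <- c(msg, "need 0 <= polyaMinLen <= polyaMaxLen")
  if (length(msg)) msg else TRUE
})

#' Construct a VariationProfile
#'
#' Defaults follow the simulator's standard parameter set: SNP rate 0.02,
#' INDEL rate 0.005, geometric parameter 0.7 for INDEL lengths, 30% of
#' sequences truncated at the 5' end by at most half their length. PolyA
#' tails are appended to every sequence with a uniform length in \[5, 50\] bp.
#'
#' @param snpRate,indelRate per-base event probabilities.
#' @param indelGeomP geometric success parameter in (0,1].
#' @param truncateSeqFraction probability that a sequence is 5'-truncated.
#' @param maxTruncateLenFraction maximum fraction of length removed.
#' @param polyaMinLen,polyaMaxLen polyA tail length bounds (bp).
#' @param polyaFraction probability that a sequence receives a polyA tail.
#' @return A \linkS4class{VariationProfile}.
#' @examples
#' VariationProfile()
#' VariationProfile(snpRate = 0.05, polyaFraction = 0)
#' @export
VariationProfile <- function(snpRate = 0.02, indelRate = 0.005,
                             indelGeomP = 0.7, truncateSeqFraction = 0.3,
                             maxTruncateLenFraction = 0.5,
                             polyaMinLen = 5L, polyaMaxLen = 50L,
                             polyaFraction = 1.0) {
  new("VariationProfile",
      snpRate = snpRate, indelRate = indelRate, indelGeomP = indelGeomP,
      truncateSeqFraction = truncateSeqFraction,
      maxTruncateLenFraction = maxTruncateLenFraction,
      polyaMinLen = as.integer(polyaMinLen),
      polyaMaxLen = as.integer(polyaMaxLen),
      polyaFraction = polyaFraction)
}

setMethod("show", "VariationProfile", function(object) {
  cat("VariationProfile\n",
      "  snpRate=", object@snpRate,
      " indelRate=", object@indelRate,
      " indelGeomP=", object@indelGeomP, "\n",
      "  truncateSeqFraction=", object@truncateSeqFraction,
      " maxTruncateLenFraction=", object@maxTruncateLenFraction, "\n",
      "  polyA: [", object@polyaMinLen, ",", object@polyaMaxLen,
      "] bp, fraction=", object@polyaFraction, "\n", sep = "")
})

#' A mutated sequence together with its edit record
#'
#' The result of [mutateSequence()]: the output sequence, the ordered list of
#' applied edits, and a FASTA-identifier-safe string encoding of those edits.
#' Replaying `edits` against the source sequence with [replayEdits()]
#' reproduces `sequence` exactly, and
#' `decodeEditAnnotation(annotation)` equals `edits`.
#'
#' @slot sequence character(1), the mutated nucleotide sequence.
#' @slot edits data.frame with columns `kind`, `pos`, `payload`.
#' @slot annotation character(1) encoding of the edits.
#' @export
setClass("MutatedSequence",
  representation(sequence = "character", edits = "data.frame",
                 annotation = "character")
)

setMethod("show", "MutatedSequence", function(object) {
  cat("MutatedSequence of length", nchar(object@sequence), "with",
      nrow(object@edits), "edits\n  annotation:",
      substr(object@annotation, 1, 70), "\n")
})

#' Catalog of TE insertion and deletion variants
#'
#' An overlap-free, coordinate-sorted set of TE variants against one
#' reference. Variants live in a `GRanges`: insertions are zero-width ranges
#' marking the insertion point (inserted between the two flanking reference
#' bases), deletions span the deleted reference interval. Metadata columns:
#' `id`, `kind` (INS/DEL), `sequence` (inserted sequence for INS, empty for
#' DEL), `family`, `superfamily`, `source` (random/real/pangenome/file), and
#' `annotation` (the mutator edit string, possibly empty).
#'
#' @slot variants a `GRanges` as described above.
#' @slot referenceId character(1) identifier of the reference assembly.
#' @seealso [mergeCatalog()], [writeCatalog()], [readCatalog()]
#' @export
setClass("TECatalog",
  representation(variants = "GRanges", referenceId = "character")
)

.validTEVariants <- function(gr) {
  if (length(gr) == 0L) return(TRUE)
  msg <- character()
  need <- c("id", "kind", "sequence", "family", "superfamily", "source",
            "annotation")
  miss <- setdiff(need, colnames(mcols(gr)))
  if (length(miss))
    return(paste0("missing metadata columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(mcols(gr)$id))
    msg <- c(msg, "variant ids must be unique")
  kind <- mcols(gr)$kind
  if (!all(kind %in% c("INS", "DEL")))
    msg <- c(msg, "kind must be INS or DEL")
  ins <- kind == "INS"
  if (any(ins & width(gr) != 0L))
    msg <- c(msg, "INS variants must be zero-width (insertion points)")
  if (any(ins & !nzchar(mcols(gr)$sequence)))
    msg <- c(msg, "INS variants must carry a non-empty sequence")
  if (any(!ins & width(gr) <= 0L))
    msg <- c(msg, "DEL variants must have positive width")
  if (any(!ins & nzchar(mcols(gr)$sequence)))
    msg <- c(msg, "DEL variants must have empty sequence (read from reference)")
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(!is.na(sl))) {
    lens <- sl[as.character(seqnames(gr))]
    ok <- is.na(lens) | (bedStart(gr) >= 0 & bedEnd(gr) <= lens)
    if (!all(ok))
      msg <- c(msg, "variant coordinates exceed chromosome bounds")
  }
  if (length(msg)) msg else TRUE
}

setValidity("TECatalog", function(object) {
  gr <- object@variants
  msg <- .validTEVariants(gr)
  msg <- if (isTRUE(msg)) character() else msg
  if (length(gr) > 1L) {
    o <- order(as.character(seqnames(gr)), bedStart(gr), bedEnd(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "variants must be sorted by (chrom, start, end)")
    if (.countCatalogConflicts(gr) > 0L)
      msg <- c(msg, "variants overlap (or an INS lies inside a DEL)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TECatalog", function(object) {
  gr <- object@variants
  cat("TECatalog with", length(gr), "variants (",
      sum(mcols(gr)$kind == "INS"), "INS,",
      sum(mcols(gr)$kind == "DEL"), "DEL ) on reference '",
      object@referenceId, "'\n")
})

#' Per-sample, per-haplotype allele states for a catalog
#'
#' @slot samples ordered sample identifiers.
#' @slot ploidy 1 or 2.
#' @slot alleles integer matrix (variants x haplotypes) of 0/1 allele states;
#'   rows named by variant id, columns `<sample>_h<k>`.
#' @slot freqs per-variant simulated allele frequency, named by variant id.
#' @export
setClass("GenotypeMatrix",
  representation(samples = "character", ploidy = "integer",
                 alleles = "matrix", freqs = "numeric")
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!object@ploidy %in% c(1L, 2L))
    msg <- c(msg, "ploidy must be 1 or 2")
  if (ncol(object@alleles) != length(object@samples) * object@ploidy)
    msg <- c(msg, "allele matrix columns must equal samples x ploidy")
  if (nrow(object@alleles) != length(object@freqs))
    msg <- c(msg, "one frequency per variant required")
  if (any(!object@alleles %in% c(0L, 1L)))
    msg <- c(msg, "allele states must be 0 or 1")
  if (any(object@freqs < 0 | object@freqs > 1))
    msg <- c(msg, "allele frequencies must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@alleles), "variants x",
      length(object@samples), "samples (ploidy", object@ploidy, ")\n")
})

#' Block decomposition of a reference at TE-variant breakpoints
#'
#' The reference is split once, per chromosome, into invariable blocks
#' (unchanged reference sequence) and variable blocks owned by exactly one
#' catalog variant: deletion blocks span the deletable interval, insertion
#' blocks are zero-width at the insertion point. Invariable and deletion
#' blocks tile each chromosome exactly. All haplotypes are then assembled by
#' concatenating blocks, which is what makes multi-genome simulation
#' O(m*(n+c)) instead of O(m*n*c) for m genomes, n variants, genome length c.
#'
#' @slot blocks named list (one element per chromosome) of data.frames with
#'   columns `start`, `end` (0-based half-open), `type`
#'   (invariable/ins/del) and `variantId` (NA for invariable blocks).
#' @slot seqlengths named numeric vector of chromosome lengths.
#' @export
setClass("BlockPartition",
  representation(blocks = "list", seqlengths = "numeric")
)

setValidity("BlockPartition", function(object) {
  for (chrom in names(object@blocks)) {
    b <- object@blocks[[chrom]]
    tile <- b[b$type != "ins", , drop = FALSE]
    len <- object@seqlengths[[chrom]]
    if (nrow(tile)) {
      if (tile$start[1L] != 0 || tile$end[nrow(tile)] != len ||
          (nrow(tile) > 1L &&
           !all(tile$start[-1L] == tile$end[-nrow(tile)])))
        return(paste0("blocks do not tile chromosome ", chrom))
    } else if (len != 0) {
      return(paste0("blocks do not tile chromosome ", chrom))
    }
  }
  TRUE
})

setMethod("show", "BlockPartition", function(object) {
  nb <- sum(vapply(object@blocks, nrow, 0L))
  cat("BlockPartition:", nb, "blocks over", length(object@blocks),
      "chromosome(s)\n")
})

#' Pairing of truth and predicted variants under a positional tolerance
#'
#' @slot matches data.frame of matched pairs (one row per pair) with columns
#'   `chrom`, `truthId`, `truthPos`, `predId`, `predPos`, `distance`,
#'   `truthGT`, `predGT`, `superfamily`.
#' @slot unmatchedTruth,unmatchedPred data.frames of unmatched records.
#' @slot tolerance positional tolerance in bp.
#' @export
setClass("MatchSet",
  representation(matches = "data.frame", unmatchedTruth = "data.frame",
                 unmatchedPred = "data.frame", tolerance = "numeric")
)

setValidity("MatchSet", function(object) {
  m <- object@matches
  msg <- character()
  if (nrow(m)) {
    if (anyDuplicated(m$truthId) || anyDuplicated(m$predId))
      msg <- c(msg, "each variant may appear in at most one match")
    if (any(m$distance > object@tolerance))
      msg <- c(msg, "matched distance exceeds tolerance")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MatchSet", function(object) {
  cat("MatchSet: ", nrow(object@matches), " matched, ",
      nrow(object@unmatchedTruth), " unmatched truth, ",
      nrow(object@unmatchedPred), " unmatched predicted (tolerance ",
      object@tolerance, " bp)\n", sep = "")
})

#' Detection and genotyping metrics derived from a MatchSet
#'
#' @slot tp,fp,fn counts.
#' @slot sensitivity,precision,f1,genotypeAccuracy fractions in \[0,1\];
#'   `NA` when the defining denominator is zero.
#' @export
setClass("TEMetrics",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 sensitivity = "numeric", precision = "numeric",
                 f1 = "numeric", genotypeAccuracy = "numeric")
)

setMethod("show", "TEMetrics", function(object) {
  cat("TEMetrics: tp=", object@tp, " fp=", object@fp, " fn=", object@fn,
      "\n  sensitivity=", round(object@sensitivity, 2),
      " precision=", round(object@precision, 2),
      " F1=", round(object@f1, 2),
      " genotypeAccuracy=", round(object@genotypeAccuracy, 2), "\n",
      sep = "")
})

#' Short-read (paired-end) simulation parameters
#'
#' @slot depth fold coverage per individual.
#' @slot readLength read length in bp.
#' @slot fragmentMean,fragmentSd fragment-length Normal parameters (bp).
#' @slot subErrorRate per-base substitution error probability.
#' @slot baseQuality constant Phred quality assigned to every base.
#' @export
setClass("ShortReadConfig",
  representation(depth = "numeric", readLength = "integer",
                 fragmentMean = "numeric", fragmentSd = "numeric",
                 subErrorRate = "numeric", baseQuality = "integer")
)

setValidity("ShortReadConfig", function(object) {
  msg <- character()
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be >= 1")
  if (object@subErrorRate < 0 || object@subErrorRate >= 1)
    msg <- c(msg, "subErrorRate must lie in [0,1)")
  if (object@fragmentMean < object@readLength && object@fragmentSd == 0)
    msg <- c(msg, "fragmentMean < readLength with fragmentSd = 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ShortReadConfig-class
#' @param depth,readLength,fragmentMean,fragmentSd,subErrorRate,baseQuality
#'   see the class slots.
#' @export
ShortReadConfig <- function(depth = 30, readLength = 150L,
                            fragmentMean = 400, fragmentSd = 50,
                            subErrorRate = 0.001, baseQuality = 35L) {
  new("ShortReadConfig", depth = depth, readLength = as.integer(readLength),
      fragmentMean = fragmentMean, fragmentSd = fragmentSd,
      subErrorRate = subErrorRate, baseQuality = as.integer(baseQuality))
}

#' Long-read simulation parameters
#'
#' @slot depth fold coverage per individual.
#' @slot errorRate per-base total error probability.
#' @slot lengthMean,lengthSd read-length Normal parameters (bp), truncated
#'   below at 100 bp.
#' @slot errorSplit fractions of (substitution, insertion, deletion) errors,
#'   summing to 1.
#' @export
setClass("LongReadConfig",
  representation(depth = "numeric", errorRate = "numeric",
                 lengthMean = "numeric", lengthSd = "numeric",
                 errorSplit = "numeric")
)

setValidity("LongReadConfig", function(object) {
  msg <- character()
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msg <- c(msg, "errorRate must lie in [0,1)")
  if (object@lengthMean <= 0) msg <- c(msg, "lengthMean must be positive")
  if (length(object@errorSplit) != 3L ||
      abs(sum(object@errorSplit) - 1) > 1e-8 || any(object@errorSplit < 0))
    msg <- c(msg, "errorSplit must be 3 non-negative fractions summing to 1")
  if (length(msg)) msg else TRUE
})

#' @rdname LongReadConfig-class
#' @param depth,errorRate,lengthMean,lengthSd,errorSplit see the class slots.
#' @export
LongReadConfig <- function(depth = 30, errorRate = 0.05,
                           lengthMean = 15000, lengthSd = 5000,
                           errorSplit = c(0.4, 0.3, 0.3)) {
  new("LongReadConfig", depth = depth, errorRate = errorRate,
      lengthMean = lengthMean, lengthSd = lengthSd, errorSplit = errorSplit)
}

#' Specification for a synthetic toy reference genome
#'
#' @slot refLength total length in bp (>= 1000).
#' @slot nChroms number of chromosomes (length split evenly).
#' @slot gc GC content in \[0,1\].
#' @slot nRunCount,nRunLength number and length of embedded N runs.
#' @slot seed integer seed making the fixture deterministic.
#' @export
setClass("FixtureSpec",
  representation(refLength = "numeric", nChroms = "integer", gc = "numeric",
                 nRunCount = "integer", nRunLength = "integer",
                 seed = "integer")
)

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (object@refLength < 1000) msg <- c(msg, "refLength must be >= 1000")
  if (object@gc < 0 || object@gc > 1) msg <- c(msg, "gc must lie in [0,1]")
  if (object@nChroms < 1L) msg <- c(msg, "nChroms must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname FixtureSpec-class
#' @param refLength,nChroms,gc,nRunCount,nRunLength,seed see the class slots.
#' @export
FixtureSpec <- function(refLength = 100000, nChroms = 1L, gc = 0.41,
                        nRunCount = 0L, nRunLength = 0L, seed = 1L) {
  new("FixtureSpec", refLength = refLength, nChroms = as.integer(nChroms),
      gc = gc, nRunCount = as.integer(nRunCount),
      nRunLength = as.integer(nRunLength), seed = as.integer(seed))
}
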