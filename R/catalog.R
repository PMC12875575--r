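#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

# Build the catalog GRanges from parallel vectors. start/end are 0-based
# half-open (BED frame); INS have start == end (the insertion point).
newVariantGRanges <- function(chrom, start0, end0, id, kind, sequence,
                              family, superfamily, source, annotation,
                              seqlen = NULL) {
  gr <- GRanges(chrom, IRanges(start = start0 + 1L, end = end0))
  n <- length(gr)
  mcols(gr) <- DataFrame(
    id = rep_len(as.character(id), n),
    kind = rep_len(as.character(kind), n),
    sequence = rep_len(as.character(sequence), n),
    family = rep_len(as.character(family), n),
    superfamily = rep_len(as.character(superfamily), n),
    source = rep_len(as.character(source), n),
    annotation = rep_len(as.character(annotation), n))
  if (!is.null(seqlen)) {
    lv <- union(seqlevels(gr), names(seqlen))
    GenomeInfoDb::seqlevels(gr) <- lv
    seqlengths(gr)[names(seqlen)] <- seqlen
  }
  gr
}

# Count overlap conflicts in a sorted variant GRanges (DEL/DEL overlap,
# INS strictly inside a DEL, or duplicated INS points).
.countCatalogConflicts <- function(gr) {
  n <- 0L
  for (chrom in unique(as.character(seqnames(gr)))) {
    g <- gr[as.character(seqnames(gr)) == chrom]
    s <- bedStart(g); e <- bedEnd(g); kind <- mcols(g)$kind
    maxEnd <- -1L; curS <- -1L; insPts <- integer()
    for (i in order(s, e)) {
      if (kind[i] == "INS") {
        if (s[i] %in% insPts || (s[i] > curS && s[i] < maxEnd)) n <- n + 1L
        else insPts <- c(insPts, s[i])
      } else {
        if (s[i] < maxEnd) n <- n + 1L
        else { curS <- s[i]; maxEnd <- e[i] }
      }
    }
  }
  n
}

#' Construct a TECatalog from a variant GRanges
#'
#' Sorts the variants by (chrom, start, end) and validates the catalog
#' invariants (unique ids, INS/DEL shape constraints, no overlaps).
#'
#' @param variants a `GRanges` with the catalog metadata columns (see
#'   [TECatalog-class]).
#' @param referenceId identifier of the reference the coordinates refer to.
#' @return a [TECatalog-class].
#' @export
TECatalog <- function(variants = GRanges(), referenceId = "") {
  if (length(variants)) {
    o <- order(as.character(seqnames(variants)), bedStart(variants),
               bedEnd(variants))
    variants <- variants[o]
  }
  new("TECatalog", variants = variants, referenceId = referenceId)
}

.parseFamilyId <- function(x) {
  # "family#superfamily" -> c(family, superfamily); no '#' -> superfamily ""
  hash <- regexpr("#", x, fixed = TRUE)
  fam <- ifelse(hash > 0L, substr(x, 1L, hash - 1L), x)
  sf <- ifelse(hash > 0L, substring(x, hash + 1L), "")
  cbind(family = fam, superfamily = sf)
}

# N-runs longer than `threshold` per chromosome, as 0-based half-open
# intervals.
.longNRuns <- function(seqs, threshold) {
  lapply(seqs, function(s) {
    m <- gregexpr("N+", s)[[1L]]
    if (m[1L] == -1L) return(cbind(start = integer(), end = integer()))
    len <- attr(m, "match.length")
    keep <- len > threshold
    cbind(start = as.integer(m[keep]) - 1L,
          end = as.integer(m[keep]) - 1L + len[keep])
  })
}

#' Generate random TE insertions across a reference
#'
#' Each insertion draws a consensus sequence uniformly from the library,
#' passes it through [mutateSequence()] under its own RNG sub-stream, and is
#' assigned a uniform random insertion point on the reference (chromosome
#' chosen proportionally to length). Points falling inside N runs longer
#' than `nRunThreshold`, or colliding with an already placed insertion, are
#' rejected and redrawn up to `maxRetries` times.
#'
#' @param reference a `DNAStringSet`, named character vector, or FASTA path.
#' @param library TE consensus sequences with identifiers
#'   `family#superfamily`.
#' @param nIns number of insertions to place.
#' @param profile a [VariationProfile-class] for consensus mutation.
#' @param nRunThreshold N runs longer than this are not insertion targets.
#' @param maxRetries total placement retries before giving up.
#' @param excludeRegions optional `GRanges` of intervals (e.g. sites already
#'   reserved for deletions) whose interior is not an insertion target.
#' @param seed optional master seed; by default one is drawn from the
#'   caller's RNG stream.
#' @return a `GRanges` of INS variants (zero-width insertion points).
#' @export
generateRandomInsertions <- function(reference, library, nIns,
                                     profile = VariationProfile(),
                                     nRunThreshold = 10L,
                                     maxRetries = 10L * nIns + 100L,
                                     excludeRegions = NULL,
                                     seed = NULL) {
  if (nIns < 0L) stop("nIns must be >= 0")
  ref <- asSeqSet(reference)
  lib <- asSeqSet(library)
  if (!length(lib)) stop("consensus library is empty")
  if (is.null(seed)) seed <- drawSeed()
  if (nIns == 0L)
    return(newVariantGRanges(character(), integer(), integer(), character(),
                             character(), character(), character(),
                             character(), character(), character(),
                             seqlen = nchar(ref)))
  lens <- nchar(ref)
  nruns <- .longNRuns(ref, nRunThreshold)
  fam <- .parseFamilyId(names(lib))

  set.seed(substreamSeed(seed, "placement"))
  placed <- data.frame(chrom = character(), pos = integer())
  consensusIdx <- integer()
  tries <- 0L
  while (nrow(placed) < nIns) {
    if (tries >= maxRetries)
      stop("could not place ", nIns, " non-overlapping insertions (placed ",
           nrow(placed), " after ", tries, " retries)")
    tries <- tries + 1L
    ci <- sample.int(length(ref), 1L, prob = lens)
    chrom <- names(ref)[ci]
    if (lens[ci] < 2L) next
    pos <- sample.int(lens[ci] - 1L, 1L)  # 0-based point in [1, len-1]
    nr <- nruns[[ci]]
    if (nrow(nr) && any(pos > nr[, "start"] & pos < nr[, "end"])) next
    if (!is.null(excludeRegions)) {
      ex <- excludeRegions[as.character(seqnames(excludeRegions)) == chrom]
      if (length(ex) && any(pos > bedStart(ex) & pos < bedEnd(ex))) next
    }
    if (any(placed$chrom == chrom & placed$pos == pos)) next
    placed <- rbind(placed, data.frame(chrom = chrom, pos = pos))
    consensusIdx <- c(consensusIdx, sample.int(length(lib), 1L))
  }

  muts <- lapply(seq_len(nIns), function(i) {
    withSubstream(seed, paste0("rins", i),
                  mutateSequence(lib[[consensusIdx[i]]], profile))
  })
  newVariantGRanges(
    chrom = placed$chrom, start0 = placed$pos, end0 = placed$pos,
    id = sprintf("rins%04d", seq_len(nIns)), kind = "INS",
    sequence = vapply(muts, function(m) m@sequence, character(1L)),
    family = fam[consensusIdx, "family"],
    superfamily = fam[consensusIdx, "superfamily"],
    source = "random",
    annotation = vapply(muts, function(m) m@annotation, character(1L)),
    seqlen = lens)
}

#' Sample TE deletions from known variant sites
#'
#' Deletion variants are not invented: they are drawn without replacement
#' from a catalog of known TE intervals on the reference (a BED file or a
#' `GRanges`), whose coordinates are copied verbatim.
#'
#' @param knownSites BED path (0-based half-open; optional 4th column
#'   `family#superfamily`) or a `GRanges` (optionally with `family`,
#'   `superfamily` metadata).
#' @param nDel number of deletions to sample.
#' @param seed optional seed (drawn from the caller's stream by default).
#' @return a `GRanges` of DEL variants.
#' @export
selectDeletions <- function(knownSites, nDel, seed = NULL) {
  if (nDel < 0L) stop("nDel must be >= 0")
  if (is.character(knownSites)) {
    bed <- utils::read.table(knownSites, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    gr <- GRanges(bed[[1L]], IRanges(start = bed[[2L]] + 1L, end = bed[[3L]]))
    if (ncol(bed) >= 4L) {
      fam <- .parseFamilyId(as.character(bed[[4L]]))
      mcols(gr)$family <- fam[, "family"]
      mcols(gr)$superfamily <- fam[, "superfamily"]
    }
  } else {
    gr <- knownSites
  }
  if (length(gr) < nDel)
    stop("only ", length(gr), " known sites available, cannot sample ",
         nDel, " deletions")
  if (is.null(seed)) seed <- drawSeed()
  if (nDel == 0L) gr <- gr[integer()]
  else {
    set.seed(substreamSeed(seed, "deletions"))
    gr <- gr[sample.int(length(gr), nDel)]
  }
  fam <- if (!is.null(mcols(gr)$family)) mcols(gr)$family else
    rep("", length(gr))
  sf <- if (!is.null(mcols(gr)$superfamily)) mcols(gr)$superfamily else
    rep("", length(gr))
  newVariantGRanges(
    chrom = as.character(seqnames(gr)), start0 = bedStart(gr),
    end0 = bedEnd(gr),
    id = sprintf("del%04d", seq_len(length(gr))), kind = "DEL",
    sequence = "", family = fam, superfamily = sf, source = "random",
    annotation = "")
}

#' Load real TE insertions from a RepeatMasker-style FASTA
#'
#' Identifiers must follow `chrom-position-family#superfamily`
#' (e.g. `chr1-683234-AluSp#SINE/Alu`). The position is interpreted as
#' 1-based and converted to the internal 0-based insertion point, so
#' position 683234 becomes insertion point 683233 (inserted between
#' reference bases 683233 and 683234 in 0-based numbering).
#'
#' @param realFasta FASTA path (or `DNAStringSet`) of insertion sequences.
#' @return a `GRanges` of INS variants with `source = "real"`.
#' @export
loadRealInsertions <- function(realFasta) {
  seqs <- asSeqSet(realFasta)
  pat <- "^([^-]+)-([0-9]+)-([^#]+)#(.+)$"
  bad <- !grepl(pat, names(seqs))
  if (any(bad))
    stop("identifier does not match 'chrom-position-family#superfamily': '",
         names(seqs)[which(bad)[1L]], "'")
  chrom <- sub(pat, "\\1", names(seqs))
  pos1 <- as.integer(sub(pat, "\\2", names(seqs)))
  newVariantGRanges(
    chrom = chrom, start0 = pos1 - 1L, end0 = pos1 - 1L,
    id = names(seqs), kind = "INS", sequence = unname(seqs),
    family = sub(pat, "\\3", names(seqs)),
    superfamily = sub(pat, "\\4", names(seqs)),
    source = "real", annotation = "")
}

#' Merge insertions and deletions into an overlap-free catalog
#'
#' Variants are pooled and sorted by (chrom, start, end). Conflicts —
#' overlapping deletions, an insertion point strictly inside a deletion
#' interval, or two insertions at the same point — are resolved by dropping
#' the later-sorted variant with a warning, so a catalog is always produced.
#'
#' @param insertions,deletions `GRanges` of variants (either may be empty or
#'   contain a mix of kinds).
#' @param referenceId reference identifier stored on the catalog.
#' @return a [TECatalog-class].
#' @export
mergeCatalog <- function(insertions = GRanges(), deletions = GRanges(),
                         referenceId = "") {
  gr <- suppressWarnings(c(insertions, deletions))
  if (!length(gr)) return(TECatalog(gr, referenceId))
  gr <- gr[order(as.character(seqnames(gr)), bedStart(gr), bedEnd(gr))]
  keep <- rep(TRUE, length(gr))
  for (chrom in unique(as.character(seqnames(gr)))) {
    idx <- which(as.character(seqnames(gr)) == chrom)
    s <- bedStart(gr[idx]); e <- bedEnd(gr[idx]); kind <- mcols(gr[idx])$kind
    maxEnd <- -1L; curS <- -1L; insPts <- integer()
    for (j in seq_along(idx)) {
      if (kind[j] == "INS") {
        if (s[j] %in% insPts || (s[j] > curS && s[j] < maxEnd))
          keep[idx[j]] <- FALSE
        else insPts <- c(insPts, s[j])
      } else {
        if (s[j] < maxEnd) keep[idx[j]] <- FALSE
        else { curS <- s[j]; maxEnd <- e[j] }
      }
    }
  }
  if (any(!keep))
    warning("dropped ", sum(!keep),
            " conflicting variant(s) during catalog merge: ",
            paste(utils::head(mcols(gr)$id[!keep], 5L), collapse = ", "))
  TECatalog(gr[keep], referenceId)
}

CATALOG_BED_COLS <- c("chrom", "start", "end", "id", "kind", "family",
                      "superfamily")

#' Serialize / load a catalog as BED + FASTA
#'
#' The BED file has seven tab-separated columns — chrom, start, end, id,
#' kind, family, superfamily — with 0-based half-open coordinates
#' (insertions have start == end). The FASTA file holds the insertion
#' sequences keyed by variant id, with the mutator annotation carried in the
#' FASTA description. `readCatalog(writeCatalog(x))` reproduces the catalog
#' (the `source` column of loaded variants is `"file"`). The BED file may be
#' freely edited between writing and re-reading, e.g. to enrich or exclude
#' variants in specific regions before genome simulation.
#'
#' @param catalog a [TECatalog-class].
#' @param bedPath,fastaPath output/input paths. For a DEL-only catalog the
#'   FASTA is written empty and may be absent on read.
#' @return `readCatalog` returns a [TECatalog-class]; `writeCatalog` returns
#'   the BED path invisibly.
#' @export
writeCatalog <- function(catalog, bedPath, fastaPath) {
  gr <- variants(catalog)
  df <- data.frame(
    chrom = as.character(seqnames(gr)), start = bedStart(gr),
    end = bedEnd(gr), id = mcols(gr)$id, kind = mcols(gr)$kind,
    family = mcols(gr)$family, superfamily = mcols(gr)$superfamily,
    stringsAsFactors = FALSE)
  utils::write.table(df, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ins <- gr[mcols(gr)$kind == "INS"]
  seqs <- DNAStringSet(mcols(ins)$sequence)
  ann <- mcols(ins)$annotation
  names(seqs) <- paste0(mcols(ins)$id,
                        ifelse(nzchar(ann), paste0(" ", ann), ""))
  writeXStringSet(seqs, fastaPath)
  invisible(bedPath)
}

#' @rdname writeCatalog
#' @param referenceId reference identifier stored on the loaded catalog.
#' @export
readCatalog <- function(bedPath, fastaPath = NULL, referenceId = "") {
  if (file.size(bedPath) == 0L)
    return(TECatalog(GRanges(), referenceId))
  bed <- utils::read.table(bedPath, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = CATALOG_BED_COLS)
  seqs <- character(); ann <- character()
  if (!is.null(fastaPath) && file.exists(fastaPath) &&
      file.size(fastaPath) > 0L) {
    fa <- readDNAStringSet(fastaPath)
    ids <- sub("\\s.*$", "", names(fa))
    desc <- ifelse(grepl("\\s", names(fa)),
                   sub("^\\S+\\s+", "", names(fa)), "")
    seqs <- stats::setNames(as.character(fa), ids)
    ann <- stats::setNames(desc, ids)
  }
  isIns <- bed$kind == "INS"
  missing <- setdiff(bed$id[isIns], names(seqs))
  if (length(missing))
    stop("INS variant(s) in BED have no FASTA sequence: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sequence <- ifelse(isIns, unname(seqs[bed$id]), "")
  annotation <- ifelse(isIns & bed$id %in% names(ann),
                       unname(ann[bed$id]), "")
  annotation[is.na(annotation)] <- ""
  gr <- newVariantGRanges(
    chrom = bed$chrom, start0 = bed$start, end0 = bed$end, id = bed$id,
    kind = bed$kind, sequence = sequence, family = bed$family,
    superfamily = bed$superfamily, source = "file",
    annotation = annotation)
  TECatalog(gr, referenceId)
}
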