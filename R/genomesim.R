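#' Assign per-haplotype allele states under simulated allele frequencies
#'
#' Each variant draws an allele frequency `f ~ Uniform(freqLow, freqHigh)`;
#' each haplotype then carries the alternate allele independently with
#' probability `f`. The defaults (0.1, 0.9) span common and rare
#' polymorphisms without fixing or losing variants.
#'
#' @param catalog a [TECatalog-class].
#' @param nSamples number of samples (>= 1).
#' @param ploidy 1 or 2.
#' @param freqLow,freqHigh allele-frequency bounds, `0 <= low <= high <= 1`.
#' @param seed optional seed (drawn from the caller's stream by default).
#' @return a [GenotypeMatrix-class].
#' @export
assignGenotypes <- function(catalog, nSamples, ploidy = 2L,
                            freqLow = 0.1, freqHigh = 0.9, seed = NULL) {
  if (nSamples < 1L) stop("nSamples must be >= 1")
  if (!(freqLow >= 0 && freqLow <= freqHigh && freqHigh <= 1))
    stop("need 0 <= freqLow <= freqHigh <= 1")
  ploidy <- as.integer(ploidy)
  if (is.null(seed)) seed <- drawSeed()
  set.seed(substreamSeed(seed, "genotypes"))
  ids <- mcols(variants(catalog))$id
  nvar <- length(ids)
  samples <- sprintf("sample%03d", seq_len(nSamples))
  hapNames <- as.vector(t(outer(samples, seq_len(ploidy),
                                function(s, k) paste0(s, "_h", k))))
  freqs <- runif(nvar, freqLow, freqHigh)
  alleles <- matrix(rbinom(nvar * nSamples * ploidy, 1L,
                           rep(freqs, times = nSamples * ploidy)),
                    nrow = nvar, ncol = nSamples * ploidy,
                    dimnames = list(ids, hapNames))
  new("GenotypeMatrix", samples = samples, ploidy = ploidy,
      alleles = alleles, freqs = stats::setNames(freqs, ids))
}

#' Partition a reference into blocks at TE-variant breakpoints
#'
#' Computes, once per cohort, the block decomposition that every haplotype
#' assembly reuses: per chromosome the breakpoints are all variant starts
#' and ends, yielding at most `2n + 1` blocks. Invariable and deletion
#' blocks tile the chromosome exactly; insertion blocks are zero-width.
#'
#' @param reference `DNAStringSet`, named character vector, or FASTA path.
#' @param catalog a [TECatalog-class] valid against the reference lengths.
#' @return a [BlockPartition-class].
#' @export
partitionBlocks <- function(reference, catalog) {
  ref <- asSeqSet(reference)
  gr <- variants(catalog)
  chroms <- setdiff(unique(as.character(seqnames(gr))), names(ref))
  if (length(chroms))
    stop("catalog chromosome(s) absent from reference: ",
         paste(chroms, collapse = ", "))
  blocks <- list()
  for (chrom in names(ref)) {
    len <- nchar(ref[[chrom]])
    g <- gr[as.character(seqnames(gr)) == chrom]
    if (length(g) && any(bedEnd(g) > len))
      stop("variant beyond end of ", chrom)
    b <- data.frame(start = numeric(), end = numeric(), type = character(),
                    variantId = character(), stringsAsFactors = FALSE)
    cur <- 0
    for (i in seq_along(g)) {
      s <- bedStart(g)[i]; e <- bedEnd(g)[i]
      if (s > cur)
        b <- rbind(b, data.frame(start = cur, end = s, type = "invariable",
                                 variantId = NA_character_))
      if (mcols(g)$kind[i] == "INS") {
        b <- rbind(b, data.frame(start = s, end = s, type = "ins",
                                 variantId = mcols(g)$id[i]))
        cur <- max(cur, s)
      } else {
        b <- rbind(b, data.frame(start = s, end = e, type = "del",
                                 variantId = mcols(g)$id[i]))
        cur <- e
      }
    }
    if (cur < len || nrow(b) == 0L)
      b <- rbind(b, data.frame(start = cur, end = len, type = "invariable",
                               variantId = NA_character_))
    rownames(b) <- NULL
    blocks[[chrom]] <- b
  }
  new("BlockPartition", blocks = blocks,
      seqlengths = vapply(ref, nchar, 0))
}

#' Assemble one haplotype by block concatenation
#'
#' Invariable blocks are copied verbatim; a deletion block is omitted iff
#' the haplotype carries the deletion allele; an insertion sequence is
#' spliced at its zero-width block iff the allele is carried. With
#' `perGenomeProfile` set, every spliced insertion is first passed through
#' [mutateSequence()] under a haplotype-specific RNG sub-stream (truncation
#' and polyA disabled for this within-cohort pass), so the same TE differs
#' slightly between genomes, as it does across real individuals.
#'
#' @param partition a [BlockPartition-class] from [partitionBlocks()].
#' @param reference the reference sequences.
#' @param catalog the [TECatalog-class] used to build `partition`.
#' @param hapAlleles named integer vector (variant id -> 0/1) covering every
#'   catalog variant.
#' @param perGenomeProfile `NULL`, or a [VariationProfile-class] for
#'   within-cohort TE sequence diversity.
#' @param hapId label of this haplotype (used for the RNG sub-stream).
#' @param seed master seed for per-genome variation sub-streams.
#' @return a named character vector, one assembled sequence per chromosome.
#' @export
assembleHaplotype <- function(partition, reference, catalog, hapAlleles,
                              perGenomeProfile = NULL, hapId = "h",
                              seed = NULL) {
  ref <- asSeqSet(reference)
  gr <- variants(catalog)
  ids <- mcols(gr)$id
  if (!all(ids %in% names(hapAlleles)))
    stop("hapAlleles does not cover all catalog variants")
  insSeq <- stats::setNames(mcols(gr)$sequence, ids)
  if (!is.null(perGenomeProfile)) {
    if (is.null(seed)) seed <- drawSeed()
    innerProfile <- perGenomeProfile
    innerProfile@truncateSeqFraction <- 0
    innerProfile@polyaFraction <- 0
  }
  out <- character()
  for (chrom in names(partition@blocks)) {
    b <- partition@blocks[[chrom]]
    pieces <- character(nrow(b))
    for (j in seq_len(nrow(b))) {
      if (b$type[j] == "invariable") {
        pieces[j] <- substr(ref[[chrom]], b$start[j] + 1L, b$end[j])
      } else if (b$type[j] == "del") {
        if (hapAlleles[[b$variantId[j]]] == 0L)
          pieces[j] <- substr(ref[[chrom]], b$start[j] + 1L, b$end[j])
      } else {  # ins
        if (hapAlleles[[b$variantId[j]]] == 1L) {
          s <- insSeq[[b$variantId[j]]]
          if (!is.null(perGenomeProfile))
            s <- withSubstream(seed, paste0(hapId, "|", b$variantId[j]),
                               mutateSequence(s, innerProfile))@sequence
          pieces[j] <- s
        }
      }
    }
    out[[chrom]] <- paste(pieces, collapse = "")
  }
  out
}

#' Naive cut-and-splice haplotype construction (correctness oracle)
#'
#' Applies the carried variants one at a time, right to left, by string
#' cut-and-splice — the O(m*n*c) baseline the block assembler replaces.
#' Kept as an independent oracle: its output must be byte-identical to
#' [assembleHaplotype()] whenever per-genome variation is off.
#'
#' @inheritParams assembleHaplotype
#' @return a named character vector of assembled sequences.
#' @export
naiveApply <- function(reference, catalog, hapAlleles) {
  ref <- asSeqSet(reference)
  gr <- variants(catalog)
  ids <- mcols(gr)$id
  if (!all(ids %in% names(hapAlleles)))
    stop("hapAlleles does not cover all catalog variants")
  out <- ref
  for (chrom in names(ref)) {
    g <- gr[as.character(seqnames(gr)) == chrom]
    # right-to-left; at a shared coordinate (INS point on a DEL start) the
    # DEL must be excised before the INS is spliced in front of it
    g <- g[order(bedStart(g), mcols(g)$kind == "DEL", decreasing = TRUE)]
    s <- out[[chrom]]
    for (i in seq_along(g)) {
      if (hapAlleles[[mcols(g)$id[i]]] != 1L) next
      p <- bedStart(g)[i]; e <- bedEnd(g)[i]
      if (mcols(g)$kind[i] == "INS") {
        s <- paste0(substr(s, 1L, p), mcols(g)$sequence[i],
                    substring(s, p + 1L))
      } else {
        s <- paste0(substr(s, 1L, p), substring(s, e + 1L))
      }
    }
    out[[chrom]] <- s
  }
  out
}

# One VCF data line per catalog variant. Anchors follow VCF convention:
# POS is the 1-based base preceding the event; events at the chromosome
# start anchor on the following base instead.
.vcfRecords <- function(catalog, reference, freqs) {
  ref <- asSeqSet(reference)
  gr <- variants(catalog)
  n <- length(gr)
  rec <- data.frame(chrom = as.character(seqnames(gr)), pos = integer(n),
                    id = mcols(gr)$id, ref = character(n),
                    alt = character(n), info = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    chrom <- rec$chrom[i]
    s <- bedStart(gr)[i]; e <- bedEnd(gr)[i]
    kind <- mcols(gr)$kind[i]
    if (s > nchar(ref[[chrom]]))
      stop("variant ", rec$id[i], " beyond end of ", chrom)
    if (kind == "INS") {
      seq <- mcols(gr)$sequence[i]
      if (s >= 1L) {
        anchor <- substr(ref[[chrom]], s, s)
        rec$pos[i] <- s; rec$ref[i] <- anchor
        rec$alt[i] <- paste0(anchor, seq)
      } else {
        anchor <- substr(ref[[chrom]], 1L, 1L)
        rec$pos[i] <- 1L; rec$ref[i] <- anchor
        rec$alt[i] <- paste0(seq, anchor)
      }
      svlen <- nchar(seq)
    } else {
      delseq <- substr(ref[[chrom]], s + 1L, e)
      if (s >= 1L) {
        anchor <- substr(ref[[chrom]], s, s)
        rec$pos[i] <- s; rec$ref[i] <- paste0(anchor, delseq)
        rec$alt[i] <- anchor
      } else {
        anchor <- substr(ref[[chrom]], e + 1L, e + 1L)
        rec$pos[i] <- 1L; rec$ref[i] <- paste0(delseq, anchor)
        rec$alt[i] <- anchor
      }
      svlen <- -(e - s)
    }
    rec$info[i] <- paste0(
      "SVTYPE=", kind, ";SVLEN=", svlen,
      ";TEFAM=", .infoSafe(mcols(gr)$family[i]),
      ";TESF=", .infoSafe(mcols(gr)$superfamily[i]),
      ";AF=", signif(freqs[[rec$id[i]]], 6))
  }
  rec
}

.infoSafe <- function(x) {
  x <- gsub("[;=[:space:]]", "_", x)
  ifelse(nzchar(x), x, ".")
}

VCF_INFO_HEADER <- c(
  '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Variant kind (INS or DEL)">',
  '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed TE length">',
  '##INFO=<ID=TEFAM,Number=1,Type=String,Description="TE family">',
  '##INFO=<ID=TESF,Number=1,Type=String,Description="TE superfamily">',
  '##INFO=<ID=AF,Number=1,Type=Float,Description="Simulated allele frequency">',
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')

.writeVcfFile <- function(rec, contigs, gtMatrix, samples, path,
                          phased = FALSE) {
  sep <- if (phased) "|" else "/"
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    VCF_INFO_HEADER,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    gts <- gtMatrix[i, , drop = TRUE]
    body[i] <- paste(c(rec$chrom[i], rec$pos[i], rec$id[i], rec$ref[i],
                       rec$alt[i], ".", "PASS", rec$info[i], "GT",
                       gsub("/", sep, gts, fixed = TRUE)),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the simulated truth VCF
#'
#' Emits a VCF 4.2 with one record per catalog variant and one GT column per
#' sample. Insertions anchor on the base preceding the insertion point
#' (`REF` = anchor, `ALT` = anchor + inserted sequence); deletions anchor on
#' the base preceding the deleted interval (`REF` = anchor + deleted bases,
#' `ALT` = anchor); events at a chromosome start anchor on the following
#' base. ALT sequences are explicit (not symbolic), so applying the VCF back
#' onto the reference reproduces every haplotype exactly
#' ([applyVcfToReference()]). INFO carries SVTYPE, SVLEN (signed), TEFAM,
#' TESF and the simulated allele frequency AF.
#'
#' @param catalog a [TECatalog-class].
#' @param genotypes a [GenotypeMatrix-class] for the catalog.
#' @param reference the reference sequences (for anchor bases and contig
#'   headers).
#' @param vcfPath output path.
#' @param phased emit `|`-separated genotypes instead of unphased `/`.
#' @return the path, invisibly.
#' @export
writeSimVcf <- function(catalog, genotypes, reference, vcfPath,
                        phased = FALSE) {
  ref <- asSeqSet(reference)
  rec <- .vcfRecords(catalog, ref, alleleFreqs(genotypes))
  al <- alleles(genotypes)
  pl <- ploidy(genotypes)
  gt <- matrix("", nrow = nrow(rec), ncol = length(sampleIds(genotypes)))
  for (sI in seq_along(sampleIds(genotypes))) {
    cols <- (sI - 1L) * pl + seq_len(pl)
    gt[, sI] <- apply(al[rec$id, cols, drop = FALSE], 1L, paste,
                      collapse = "/")
  }
  .writeVcfFile(rec, vapply(ref, nchar, 0), gt, sampleIds(genotypes),
                vcfPath, phased)
}

#' Apply a simulated VCF back onto the reference
#'
#' Reconstructs every haplotype of every sample by splicing the VCF records
#' (right to left per chromosome) into the reference: the round-trip check
#' that the emitted VCF and the emitted genomes describe the same sequences.
#'
#' @param vcfPath a VCF written by [writeSimVcf()].
#' @param reference the reference sequences.
#' @return a named list: for each sample, a list of per-haplotype named
#'   character vectors of chromosome sequences.
#' @export
applyVcfToReference <- function(vcfPath, reference) {
  ref <- asSeqSet(reference)
  v <- VariantAnnotation::readVcf(vcfPath, genome = "sim")
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refAll <- as.character(VariantAnnotation::ref(v))
  altAll <- as.character(unlist(VariantAnnotation::alt(v)))
  gtm <- VariantAnnotation::geno(v)$GT
  samples <- colnames(gtm)
  o <- order(chrom, -pos)
  out <- list()
  for (s in samples) {
    gts <- strsplit(gtm[, s], "[/|]")
    pl <- length(gts[[1L]])
    haps <- list()
    for (k in seq_len(pl)) {
      hap <- ref
      for (i in o) {
        if (gts[[i]][k] != "1") next
        ch <- chrom[i]
        stopifnot(substr(hap[[ch]], pos[i],
                         pos[i] + nchar(refAll[i]) - 1L) == refAll[i])
        hap[[ch]] <- paste0(substr(hap[[ch]], 1L, pos[i] - 1L), altAll[i],
                            substring(hap[[ch]], pos[i] + nchar(refAll[i])))
      }
      haps[[paste0("h", k)]] <- hap
    }
    out[[s]] <- haps
  }
  out
}

#' Simulate a cohort of TE-variant-containing genomes
#'
#' Composes [assignGenotypes()], [partitionBlocks()] (computed once and
#' reused across all genomes — the chunk-merge speedup),
#' [assembleHaplotype()] per haplotype, and [writeSimVcf()]. Writes one
#' FASTA per haplotype (`<sample>_h<k>.fa`), one multi-sample VCF
#' (`truth.vcf`), and a JSON manifest recording the seed, parameters and
#' per-haplotype expected lengths.
#'
#' @inheritParams assignGenotypes
#' @param reference the reference sequences.
#' @param perGenomeProfile `NULL`, or a [VariationProfile-class] applied to
#'   each spliced insertion per haplotype (within-cohort TE diversity; not
#'   recorded in the VCF, which describes TE presence/absence).
#' @param outdir output directory (created if needed).
#' @param phased emit phased genotypes.
#' @return invisibly, a list with `genotypes`, `vcf`, `fastas` (named by
#'   haplotype), and `manifest` (the manifest path).
#' @export
simulateCohort <- function(reference, catalog, nSamples, ploidy = 2L,
                           freqLow = 0.1, freqHigh = 0.9,
                           perGenomeProfile = NULL, outdir, seed = NULL,
                           phased = FALSE) {
  if (is.null(seed)) seed <- drawSeed()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- asSeqSet(reference)
  geno <- assignGenotypes(catalog, nSamples, ploidy, freqLow, freqHigh,
                          seed = seed)
  part <- partitionBlocks(ref, catalog)
  gr <- variants(catalog)
  insLen <- ifelse(mcols(gr)$kind == "INS", nchar(mcols(gr)$sequence),
                   -width(gr))
  al <- alleles(geno)
  fastas <- character(); expLen <- numeric()
  for (hap in colnames(al)) {
    hapAll <- stats::setNames(al[, hap], rownames(al))
    seqs <- assembleHaplotype(part, ref, catalog, hapAll,
                              perGenomeProfile = perGenomeProfile,
                              hapId = hap, seed = seed)
    fp <- file.path(outdir, paste0(hap, ".fa"))
    writeXStringSet(DNAStringSet(seqs), fp)
    fastas[[hap]] <- fp
    expLen[[hap]] <- sum(nchar(ref)) + sum(insLen * hapAll[mcols(gr)$id])
  }
  vcf <- file.path(outdir, "truth.vcf")
  writeSimVcf(catalog, geno, ref, vcf, phased = phased)
  manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(list(
    seed = seed, nSamples = nSamples, ploidy = ploidy,
    freqLow = freqLow, freqHigh = freqHigh,
    perGenomeVariation = !is.null(perGenomeProfile),
    nVariants = nVariants(catalog),
    referenceLength = sum(nchar(ref)),
    haplotypes = as.list(stats::setNames(basename(fastas), names(fastas))),
    expectedHaplotypeLengths = as.list(expLen),
    vcf = basename(vcf)), manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(genotypes = geno, vcf = vcf, fastas = fastas,
                 manifest = manifest))
}
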