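#' Generate a synthetic toy reference genome
#'
#' Draws i.i.d. bases at the requested GC content, splits the total length
#' evenly over `nChroms` chromosomes (`chr1`, `chr2`, ...), and plants the
#' requested number of N runs at recorded positions away from chromosome
#' edges. Deterministic per `spec@seed`.
#'
#' @param spec a [FixtureSpec-class].
#' @param fastaPath optional path; if given the FASTA is written there.
#' @return a list: `seqs` (named character vector) and `nRuns` (data.frame
#'   `chrom`, `start`, `end`, 0-based half-open).
#' @export
makeReference <- function(spec, fastaPath = NULL) {
  validObject(spec)
  set.seed(substreamSeed(spec@seed, "reference"))
  perChrom <- floor(spec@refLength / spec@nChroms)
  seqs <- character(); nRuns <- NULL
  for (i in seq_len(spec@nChroms)) {
    chrom <- paste0("chr", i)
    s <- randomDNA(perChrom, spec@gc)
    if (spec@nRunCount > 0L && spec@nRunLength > 0L) {
      lo <- floor(perChrom * 0.1); hi <- floor(perChrom * 0.9)
      starts <- sort(sample(seq(lo, hi - spec@nRunLength,
                                length.out = max(spec@nRunCount * 3L, 10L)),
                            spec@nRunCount))
      for (st in starts) {
        substr(s, st + 1L, st + spec@nRunLength) <-
          strrep("N", spec@nRunLength)
        nRuns <- rbind(nRuns, data.frame(chrom = chrom, start = st,
                                         end = st + spec@nRunLength))
      }
    }
    seqs[[chrom]] <- s
  }
  if (is.null(nRuns))
    nRuns <- data.frame(chrom = character(), start = integer(),
                        end = integer())
  if (!is.null(fastaPath))
    writeXStringSet(DNAStringSet(seqs), fastaPath)
  list(seqs = seqs, nRuns = nRuns)
}

#' Generate a synthetic TE consensus library
#'
#' One random sequence per family, with identifiers `family#superfamily`
#' parseable by the catalog loaders. The default family mix approximates
#' real TE length scales (an Alu-like SINE of 300 bp, an L1-like LINE of
#' 6 kb, an SVA-like element of 1.5 kb, an ERV-like element of 8 kb) but
#' every sequence is synthetic — no real consensus sequences are shipped.
#'
#' @param families data.frame with columns `name`, `superfamily`, `length`.
#' @param seed integer seed.
#' @return a named character vector of consensus sequences.
#' @export
makeConsensusLibrary <- function(families = data.frame(
                                   name = c("AluSyn", "L1Syn", "SVASyn",
                                            "ERVSyn"),
                                   superfamily = c("SINE/Alu", "LINE/L1",
                                                   "Retroposon/SVA",
                                                   "LTR/ERVK"),
                                   length = c(300L, 6000L, 1500L, 8000L)),
                                 seed = 1L) {
  if (anyDuplicated(families$name))
    stop("duplicate family names in library specification")
  set.seed(substreamSeed(seed, "library"))
  seqs <- vapply(families$length, randomDNA, "", gc = 0.45)
  stats::setNames(seqs, paste0(families$name, "#", families$superfamily))
}

#' Build a toy pangenome GFA with known bubbles
#'
#' Constructs a linear reference path of random backbone segments with
#' `nBubbles` simple bubbles whose variable sequences are drawn from a TE
#' consensus library, alternating insertion bubbles (the TE lies on the
#' off-reference path) and deletion bubbles (the TE lies on the reference
#' path with a direct source-to-sink link skipping it). Returns the
#' expected variants as a manifest, so pangenome extraction can be checked
#' against the construction.
#'
#' @param nBubbles number of bubbles (>= 0).
#' @param library consensus library (named character vector, `DNAStringSet`
#'   or FASTA path).
#' @param seed integer seed.
#' @param gfaPath output GFA path.
#' @param refName name of the reference P record (also the manifest
#'   chromosome).
#' @param backboneLen length of each backbone segment.
#' @return a list: `gfaPath` and `manifest` (data.frame `chrom`, `start`,
#'   `end`, `kind`, `family`, `superfamily`, `sequence`; coordinates
#'   0-based half-open on the reference path).
#' @export
makeToyGFA <- function(nBubbles, library, seed = 1L, gfaPath,
                       refName = "ref", backboneLen = 500L) {
  if (nBubbles < 0L) stop("nBubbles must be >= 0")
  lib <- asSeqSet(library)
  fam <- .parseFamilyId(names(lib))
  set.seed(substreamSeed(seed, "toygfa"))
  segs <- character(); links <- character()
  manifest <- NULL
  for (i in seq_len(nBubbles + 1L))
    segs[[paste0("b", i)]] <- randomDNA(backboneLen, 0.5)
  ## reference path: b1 [bubble1] b2 [bubble2] ... b(n+1)
  refSteps <- "b1"; cum <- backboneLen
  for (i in seq_len(nBubbles)) {
    li <- ((i - 1L) %% length(lib)) + 1L
    te <- paste0("t", i)
    segs[[te]] <- lib[[li]]
    nxt <- paste0("b", i + 1L)
    if (i %% 2L == 1L) {
      ## insertion bubble: ref = b_i -> b_{i+1}; alt = b_i -> t_i -> b_{i+1}
      prev <- refSteps[length(refSteps)]
      links <- c(links,
                 sprintf("L\t%s\t+\t%s\t+\t0M", prev, nxt),
                 sprintf("L\t%s\t+\t%s\t+\t0M", prev, te),
                 sprintf("L\t%s\t+\t%s\t+\t0M", te, nxt))
      manifest <- rbind(manifest, data.frame(
        chrom = refName, start = cum, end = cum, kind = "INS",
        family = fam[li, "family"], superfamily = fam[li, "superfamily"],
        sequence = lib[[li]], stringsAsFactors = FALSE))
    } else {
      ## deletion bubble: ref = b_i -> t_i -> b_{i+1}; alt = direct link
      prev <- refSteps[length(refSteps)]
      links <- c(links,
                 sprintf("L\t%s\t+\t%s\t+\t0M", prev, te),
                 sprintf("L\t%s\t+\t%s\t+\t0M", te, nxt),
                 sprintf("L\t%s\t+\t%s\t+\t0M", prev, nxt))
      refSteps <- c(refSteps, te)
      manifest <- rbind(manifest, data.frame(
        chrom = refName, start = cum, end = cum + nchar(lib[[li]]),
        kind = "DEL", family = fam[li, "family"],
        superfamily = fam[li, "superfamily"], sequence = "",
        stringsAsFactors = FALSE))
      cum <- cum + nchar(lib[[li]])
    }
    refSteps <- c(refSteps, nxt)
    cum <- cum + backboneLen
  }
  if (is.null(manifest))
    manifest <- data.frame(chrom = character(), start = integer(),
                           end = integer(), kind = character(),
                           family = character(), superfamily = character(),
                           sequence = character(), stringsAsFactors = FALSE)
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\t%s\t%s", names(segs), unname(segs)),
             links,
             sprintf("P\t%s\t%s\t*", refName,
                     paste0(refSteps, "+", collapse = ",")))
  writeLines(lines, gfaPath)
  list(gfaPath = gfaPath, manifest = manifest)
}

#' Degrade a truth VCF into a synthetic prediction set
#'
#' Emulates an imperfect TE detector so the comparison module can be tested
#' without running a real one: truth positions are jittered by a rounded
#' Normal(0, `jitterSd`); a `dropRate` fraction of calls is deleted
#' (missed); spurious calls are added at `spuriousRate` x the truth count,
#' at random positions; and genotypes are flipped to a different random
#' genotype at `gtFlipRate`.
#'
#' @param truthVcf path to a truth VCF (e.g. from [simulateCohort()]).
#' @param jitterSd positional jitter standard deviation in bp.
#' @param dropRate,spuriousRate,gtFlipRate rates in \[0,1\] (spuriousRate may
#'   exceed 1).
#' @param seed integer seed.
#' @param outVcf output path for the degraded single-sample VCF.
#' @param sample truth sample column whose genotypes are carried over.
#' @return the output path, invisibly.
#' @export
degradePredictions <- function(truthVcf, jitterSd = 0, dropRate = 0,
                               spuriousRate = 0, gtFlipRate = 0, seed = 1L,
                               outVcf, sample = 1L) {
  stopifnot(dropRate >= 0, dropRate <= 1, gtFlipRate >= 0, gtFlipRate <= 1,
            spuriousRate >= 0)
  set.seed(substreamSeed(seed, "degrade"))
  v <- VariantAnnotation::readVcf(truthVcf, genome = "sim")
  rr <- SummarizedExperiment::rowRanges(v)
  hdr <- VariantAnnotation::header(v)
  contigs <- GenomeInfoDb::seqlengths(rr)
  df <- data.frame(
    chrom = as.character(seqnames(rr)),
    pos = GenomicRanges::start(rr),
    kind = as.character(VariantAnnotation::info(v)$SVTYPE),
    gt = VariantAnnotation::geno(v)$GT[, sample],
    stringsAsFactors = FALSE)
  keep <- runif(nrow(df)) >= dropRate
  df <- df[keep, , drop = FALSE]
  if (jitterSd > 0 && nrow(df))
    df$pos <- pmax(1L, df$pos + as.integer(round(rnorm(nrow(df), 0,
                                                       jitterSd))))
  if (gtFlipRate > 0 && nrow(df)) {
    flip <- which(runif(nrow(df)) < gtFlipRate)
    gtSpace <- c("0/0", "0/1", "1/1")
    for (i in flip)
      df$gt[i] <- sample(setdiff(gtSpace, .normGT(df$gt[i])), 1L)
  }
  nSpur <- round(spuriousRate * nrow(v))
  if (nSpur > 0L) {
    sc <- sample(names(contigs), nSpur, replace = TRUE, prob = contigs)
    df <- rbind(df, data.frame(
      chrom = sc,
      pos = vapply(sc, function(ch)
        sample.int(max(contigs[[ch]] - 1L, 1L), 1L), 0L),
      kind = "INS",
      gt = sample(c("0/1", "1/1"), nSpur, replace = TRUE),
      stringsAsFactors = FALSE))
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rec <- data.frame(
    chrom = df$chrom, pos = df$pos,
    id = sprintf("dpred%05d", seq_len(nrow(df))),
    ref = ifelse(df$kind == "DEL", "NN", "N"),
    alt = ifelse(df$kind == "DEL", "N", "NN"),
    info = paste0("SVTYPE=", df$kind), stringsAsFactors = FALSE)
  gt <- matrix(df$gt, ncol = 1L)
  .writeVcfFile(rec, contigs, gt, "degraded", outVcf)
  invisible(outVcf)
}
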