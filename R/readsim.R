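# Substitute bases at the given 1-based positions of one read with a
# uniformly chosen different base.
.substituteAt <- function(chars, at) {
  for (i in at)
    chars[i] <- sample(setdiff(DNA_BASES_STRICT, chars[i]), 1L)
  chars
}

#' Simulate paired-end short reads
#'
#' Cuts the genome into `N = round(depth * totalLength / (2 * readLength *
#' nHaplotypes))` fragments (so realized coverage matches the requested
#' per-individual depth), with fragment start uniform on each chromosome
#' (chromosomes chosen proportionally to length) and fragment length drawn
#' from Normal(fragmentMean, fragmentSd) truncated to \[readLength,
#' chromosome length\]. R1 is the 5' `readLength` bases of the fragment and
#' R2 the reverse complement of its 3' end; substitution errors are i.i.d.
#' at `subErrorRate`; all bases receive the constant `baseQuality`.
#'
#' @param genome `DNAStringSet`, named character vector, or FASTA path(s)
#'   (several haplotype FASTAs may be concatenated by the caller).
#' @param config a [ShortReadConfig-class].
#' @param r1Path,r2Path output FASTQ paths for the two mates.
#' @param nHaplotypes haplotypes represented in `genome` for one
#'   individual; depth is per individual, split evenly across haplotypes.
#' @param seed optional seed.
#' @return invisibly, a list with `nPairs` and `realizedDepth`.
#' @export
simulateShortReads <- function(genome, config = ShortReadConfig(),
                               r1Path, r2Path, nHaplotypes = 1L,
                               seed = NULL) {
  validObject(config)
  seqs <- asSeqSet(genome)
  lens <- nchar(seqs)
  if (!length(seqs) || sum(lens) == 0) stop("genome is empty")
  r <- config@readLength
  if (any(lens < r)) stop("chromosome shorter than the read length")
  if (!is.null(seed)) set.seed(seed)
  N <- round(config@depth * sum(lens) / (2 * r * nHaplotypes))
  chromIdx <- sample.int(length(seqs), N, replace = TRUE, prob = lens)
  fragLen <- pmin(pmax(round(rnorm(N, config@fragmentMean,
                                   config@fragmentSd)), r),
                  lens[chromIdx])
  start <- vapply(seq_len(N), function(i)
    sample.int(lens[chromIdx[i]] - fragLen[i] + 1L, 1L), 0L)
  chromSeq <- unname(seqs[chromIdx])
  r1 <- substr(chromSeq, start, start + r - 1L)
  r2 <- revComp(substr(chromSeq, start + fragLen - r, start + fragLen - 1L))
  if (config@subErrorRate > 0) {
    for (mate in 1:2) {
      reads <- if (mate == 1L) r1 else r2
      nerr <- rbinom(N, r, config@subErrorRate)
      for (i in which(nerr > 0L)) {
        chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        at <- sample.int(r, nerr[i])
        reads[i] <- paste(.substituteAt(chars, at), collapse = "")
      }
      if (mate == 1L) r1 <- reads else r2 <- reads
    }
  }
  ids <- sprintf("frag%07d", seq_len(N))
  qual <- rep(strrep(phredChar(config@baseQuality), r), N)
  writeFastq(stats::setNames(r1, paste0(ids, "/1")), qual, r1Path)
  writeFastq(stats::setNames(r2, paste0(ids, "/2")), qual, r2Path)
  invisible(list(nPairs = N,
                 realizedDepth = 2 * r * N * nHaplotypes / sum(lens)))
}

#' Simulate long single-end reads
#'
#' Draws reads until the total emitted bases reach `depth * totalLength /
#' nHaplotypes`. Read lengths follow Normal(lengthMean, lengthSd) truncated
#' to \[100, chromosome length\]; the strand is chosen uniformly. Errors are
#' applied base-wise: with probability `errorRate` a base suffers an event,
#' typed substitution / 1-bp insertion / 1-bp deletion according to
#' `errorSplit`.
#'
#' @param genome as in [simulateShortReads()].
#' @param config a [LongReadConfig-class].
#' @param outPath output FASTQ path.
#' @param nHaplotypes haplotypes per individual represented in `genome`.
#' @param seed optional seed.
#' @return invisibly, a list with `nReads`, `realizedDepth` (source bases
#'   drawn over genome length; >= the requested depth by the stopping rule)
#'   and `meta`, a per-read data.frame of source chromosome, start, length
#'   and strand.
#' @export
simulateLongReads <- function(genome, config = LongReadConfig(), outPath,
                              nHaplotypes = 1L, seed = NULL) {
  validObject(config)
  seqs <- asSeqSet(genome)
  lens <- nchar(seqs)
  if (!length(seqs) || sum(lens) == 0) stop("genome is empty")
  if (!is.null(seed)) set.seed(seed)
  target <- config@depth * sum(lens) / nHaplotypes
  total <- 0
  reads <- character()
  meta <- list()
  while (total < target) {
    ci <- sample.int(length(seqs), 1L, prob = lens)
    len <- min(max(round(rnorm(1L, config@lengthMean, config@lengthSd)),
                   100L), lens[ci])
    s <- sample.int(lens[ci] - len + 1L, 1L)
    read <- substr(seqs[[ci]], s, s + len - 1L)
    strand <- if (runif(1L) < 0.5) "-" else "+"
    if (strand == "-") read <- revComp(read)
    total <- total + len
    meta[[length(meta) + 1L]] <- data.frame(
      chrom = names(seqs)[ci], start = s, len = len, strand = strand,
      stringsAsFactors = FALSE)
    if (config@errorRate > 0) {
      nev <- rbinom(1L, len, config@errorRate)
      if (nev > 0L) {
        chars <- strsplit(read, "", fixed = TRUE)[[1L]]
        at <- sort(sample.int(len, nev), decreasing = TRUE)
        type <- sample.int(3L, nev, replace = TRUE,
                           prob = config@errorSplit)
        for (j in seq_len(nev)) {
          p <- at[j]
          if (type[j] == 1L) {
            chars[p] <- sample(setdiff(DNA_BASES_STRICT, chars[p]), 1L)
          } else if (type[j] == 2L) {
            chars <- append(chars, sample(DNA_BASES_STRICT, 1L), after = p)
          } else {
            chars <- chars[-p]
          }
        }
        read <- paste(chars, collapse = "")
      }
    }
    reads <- c(reads, read)
  }
  ids <- sprintf("lread%06d", seq_along(reads))
  quals <- vapply(nchar(reads), function(n) strrep(phredChar(20L), n), "")
  writeFastq(stats::setNames(reads, ids), quals, outPath)
  invisible(list(nReads = length(reads),
                 realizedDepth = total * nHaplotypes / sum(lens),
                 meta = do.call(rbind, meta)))
}

#' Print equivalent external read-simulator invocations
#'
#' For users who prefer the established external engines, prints the
#' Mason2 (short-read) or PBSIM3 (long-read) command line corresponding to
#' a configuration, without running anything.
#'
#' @param mode `"short"`, `"pacbio"` or `"ont"`.
#' @param config a [ShortReadConfig-class] or [LongReadConfig-class].
#' @param genomePath genome FASTA path to appear in the command.
#' @param outPrefix output prefix to appear in the command.
#' @return the command string, invisibly (also printed).
#' @export
emitReadsimCommands <- function(mode = c("short", "pacbio", "ont"), config,
                                genomePath = "genome.fa",
                                outPrefix = "reads") {
  mode <- match.arg(mode)
  cmd <- if (mode == "short") {
    sprintf(paste("mason_simulator -ir %s -n %s --illumina-read-length %d",
                  "--fragment-mean-size %d --fragment-size-std-dev %d",
                  "-o %s_1.fq -or %s_2.fq"),
            genomePath, "<computed-from-depth>", config@readLength,
            round(config@fragmentMean), round(config@fragmentSd),
            outPrefix, outPrefix)
  } else {
    sprintf(paste("pbsim --strategy wgs --method qshmm --depth %g",
                  "--length-mean %d --length-sd %d --accuracy-mean %g",
                  "--genome %s --prefix %s"),
            config@depth, round(config@lengthMean), round(config@lengthSd),
            1 - config@errorRate, genomePath, outPrefix)
  }
  cat(cmd, "\n")
  invisible(cmd)
}
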