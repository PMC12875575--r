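#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement BStringSet
#' @importFrom stats runif rnorm rbinom rgeom
NULL

# BED-frame coordinates (0-based half-open) of a GRanges; zero-width
# insertion points map to start == end.
bedStart <- function(gr) GenomicRanges::start(gr) - 1L
bedEnd <- function(gr) GenomicRanges::end(gr)

#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Sequences (and haplotypes) get their own RNG sub-streams so that the
#' output for one sequence does not depend on the order in which the others
#' are processed. The sub-seed is a stable polynomial hash of the label,
#' folded with the master seed modulo 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param id character label of the stream (e.g. a sequence id).
#' @return an integer seed in \[0, 2^31 - 2\].
#' @examples
#' substreamSeed(42L, "chr1")
#' @export
substreamSeed <- function(seed, id) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(as.character(id))) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded by substreamSeed(),
# restoring the caller's RNG state afterwards.
withSubstream <- function(seed, id, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substreamSeed(seed, id))
  expr
}

# Draw an integer seed for a sub-task from the current RNG stream, so that
# determinism flows from whatever seed the caller set.
drawSeed <- function() sample.int(2147483646L, 1L)

randomDNA <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# Coerce a FASTA path or XStringSet-like object to a named character vector.
asSeqSet <- function(x) {
  if (length(x) == 0L) stop("empty sequence set")
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[ACGTN]+$", x)) {
    x <- readDNAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  stop("cannot interpret sequences of class ", class(x)[1L])
}

#' Count canonical-orientation k-mers of a sequence set
#'
#' A small exact k-mer counter used to verify that two genome assemblies are
#' identical as k-mer multisets (the block-concatenation assembler against
#' the naive cut-and-splice applier).
#'
#' @param seqs a `DNAStringSet`, named character vector, or FASTA path.
#' @param k k-mer size (default 21).
#' @return a named integer vector of k-mer counts (forward orientation).
#' @examples
#' countKmers(c(chr = "ACGTACGT"), k = 4)
#' @export
countKmers <- function(seqs, k = 21L) {
  seqs <- asSeqSet(seqs)
  all <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }), use.names = FALSE)
  c(table(all))
}

kmerSet <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

phredChar <- function(q) rawToChar(as.raw(q + 33L))

writeFastq <- function(seqs, quals, path) {
  x <- DNAStringSet(seqs)
  writeXStringSet(x, path, format = "fastq", qualities = BStringSet(quals))
}
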