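#' Draw INDEL lengths from a geometric distribution
#'
#' INDEL lengths follow a geometric distribution on the positive integers,
#' `P(L = k) = p (1 - p)^(k - 1)`, so the mean length is `1/p`. With the
#' default `p = 0.7` most INDELs are 1-2 bp, as in real TE copies.
#'
#' @param p success parameter in (0, 1].
#' @param n number of draws.
#' @return integer vector of `n` lengths, each >= 1.
#' @examples
#' set.seed(1); mean(sampleIndelLength(0.7, 1e4))  # ~ 1/0.7
#' @export
sampleIndelLength <- function(p, n = 1L) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1)
    stop("geometric parameter p must lie in (0, 1]")
  rgeom(n, p) + 1L
}

.emptyEdits <- function() {
  data.frame(kind = character(), pos = integer(), payload = character(),
             stringsAsFactors = FALSE)
}

.edit <- function(kind, pos, payload) {
  data.frame(kind = kind, pos = as.integer(pos),
             payload = as.character(payload), stringsAsFactors = FALSE)
}

#' Introduce sequence variation into a TE consensus sequence
#'
#' Applies, in a fixed order, the four classes of variation observed in real
#' TE copies: 5' truncation, SNPs, INDELs, and a 3' polyA tail. The fixed
#' order gives every recorded edit a well-defined coordinate frame:
#' truncation length refers to the source sequence; SNP positions refer to
#' the truncated sequence; INDEL positions refer to the post-SNP sequence
#' (INDELs are applied right-to-left so their positions stay valid); the
#' polyA tail is appended last.
#'
#' Per base, a non-N base turns into one of the three other bases with
#' probability `snpRate`; each position independently seeds an INDEL with
#' probability `indelRate` (insertion or deletion with equal probability, the
#' length drawn by [sampleIndelLength()]; inserted bases are uniform on
#' A/C/G/T; deletions remove bases rightward, clipped at the sequence end).
#' The whole sequence is 5'-truncated with probability
#' `truncateSeqFraction`, removing a prefix of length uniform on
#' `[1, floor(maxTruncateLenFraction * length)]`, and receives a polyA tail
#' of uniform length in `[polyaMinLen, polyaMaxLen]` with probability
#' `polyaFraction`.
#'
#' @param source a nucleotide string (alphabet A/C/G/T/N).
#' @param profile a [VariationProfile-class].
#' @return a [MutatedSequence-class]; its `edits` replay to `sequence` via
#'   [replayEdits()] and round-trip through
#'   [encodeEditAnnotation()]/[decodeEditAnnotation()].
#' @examples
#' set.seed(7)
#' m <- mutateSequence(strrep("ACGT", 100), VariationProfile())
#' identical(replayEdits(strrep("ACGT", 100), m@edits), m@sequence)
#' @export
mutateSequence <- function(source, profile = VariationProfile()) {
  if (!is.character(source) || length(source) != 1L || !nzchar(source))
    stop("source must be a single non-empty nucleotide string")
  validObject(profile)
  source <- toupper(source)
  chars <- strsplit(source, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c(DNA_BASES_STRICT, "N")))
    stop("source contains characters outside {A,C,G,T,N}")

  edits <- list()

  ## 5' truncation (length recorded against the source frame)
  if (runif(1L) < profile@truncateSeqFraction) {
    maxlen <- floor(profile@maxTruncateLenFraction * length(chars))
    if (maxlen >= 1L) {
      tlen <- sample.int(maxlen, 1L)
      chars <- chars[-seq_len(tlen)]
      edits[[length(edits) + 1L]] <- .edit("trunc", NA_integer_, tlen)
    }
  }

  ## SNPs (positions in the truncated frame)
  if (length(chars) && profile@snpRate > 0) {
    hits <- which(chars != "N" & runif(length(chars)) < profile@snpRate)
    for (i in hits) {
      alt <- sample(setdiff(DNA_BASES_STRICT, chars[i]), 1L)
      edits[[length(edits) + 1L]] <-
        .edit("snp", i, paste0(chars[i], alt))
      chars[i] <- alt
    }
  }

  ## INDELs (positions in the post-SNP frame; applied right-to-left)
  if (length(chars) && profile@indelRate > 0) {
    seeds <- which(runif(length(chars)) < profile@indelRate)
    indels <- list()
    for (i in seeds) {
      len <- sampleIndelLength(profile@indelGeomP, 1L)
      if (runif(1L) < 0.5) {
        ins <- paste(sample(DNA_BASES_STRICT, len, replace = TRUE),
                     collapse = "")
        indels[[length(indels) + 1L]] <- .edit("ins", i, ins)
      } else {
        indels[[length(indels) + 1L]] <- .edit("del", i, len)
      }
    }
    if (length(indels)) {
      edits <- c(edits, indels)
      chars <- .applyIndels(chars, do.call(rbind, indels))
    }
  }

  ## 3' polyA tail
  if (runif(1L) < profile@polyaFraction && profile@polyaMaxLen >= 1L) {
    span <- profile@polyaMaxLen - profile@polyaMinLen + 1L
    plen <- profile@polyaMinLen + sample.int(span, 1L) - 1L
    if (plen >= 1L) {
      chars <- c(chars, rep("A", plen))
      edits[[length(edits) + 1L]] <- .edit("polya", NA_integer_, plen)
    }
  }

  edits <- if (length(edits)) do.call(rbind, edits) else .emptyEdits()
  rownames(edits) <- NULL
  new("MutatedSequence",
      sequence = paste(chars, collapse = ""),
      edits = edits,
      annotation = encodeEditAnnotation(edits))
}

# Apply ins/del edits (positions in the current frame) right-to-left.
.applyIndels <- function(chars, indels) {
  indels <- indels[order(indels$pos, decreasing = TRUE), , drop = FALSE]
  for (j in seq_len(nrow(indels))) {
    pos <- indels$pos[j]
    if (indels$kind[j] == "ins") {
      ins <- strsplit(indels$payload[j], "", fixed = TRUE)[[1L]]
      chars <- append(chars, ins, after = pos - 1L)
    } else {
      len <- as.integer(indels$payload[j])
      drop <- pos:min(pos + len - 1L, length(chars))
      chars <- chars[-drop]
    }
  }
  chars
}

#' Replay a recorded edit list against a source sequence
#'
#' Deterministically re-applies the edits produced by [mutateSequence()]
#' (truncation, then SNPs, then INDELs right-to-left, then polyA), verifying
#' SNP reference bases along the way.
#'
#' @param source the original nucleotide string.
#' @param edits an edit data.frame (`kind`, `pos`, `payload`).
#' @return the reconstructed mutated sequence.
#' @export
replayEdits <- function(source, edits) {
  chars <- strsplit(toupper(source), "", fixed = TRUE)[[1L]]
  tr <- edits[edits$kind == "trunc", , drop = FALSE]
  if (nrow(tr)) chars <- chars[-seq_len(as.integer(tr$payload[1L]))]
  snps <- edits[edits$kind == "snp", , drop = FALSE]
  for (j in seq_len(nrow(snps))) {
    pos <- snps$pos[j]
    refalt <- strsplit(snps$payload[j], "", fixed = TRUE)[[1L]]
    if (chars[pos] != refalt[1L])
      stop("SNP reference mismatch at position ", pos)
    chars[pos] <- refalt[2L]
  }
  indels <- edits[edits$kind %in% c("ins", "del"), , drop = FALSE]
  if (nrow(indels)) chars <- .applyIndels(chars, indels)
  pa <- edits[edits$kind == "polya", , drop = FALSE]
  if (nrow(pa)) chars <- c(chars, rep("A", as.integer(pa$payload[1L])))
  paste(chars, collapse = "")
}

#' Encode / decode an edit list as a FASTA-identifier-safe string
#'
#' The annotation grammar is `VAR=` followed by comma-separated tokens, or
#' `VAR=none` for an empty edit list: `T5:<len>` (5' truncation),
#' `S:<pos>:<ref><alt>` (SNP), `I:<pos>:<seq>` (insertion), `D:<pos>:<len>`
#' (deletion), `PA:<len>` (polyA tail). The encoding is whitespace-free and
#' lossless: `decodeEditAnnotation(encodeEditAnnotation(e))` equals `e`.
#'
#' @param edits an edit data.frame as produced by [mutateSequence()].
#' @return `encodeEditAnnotation`: a single string.
#' @examples
#' encodeEditAnnotation(mutateSequence(strrep("ACGT", 50))@edits)
#' @export
encodeEditAnnotation <- function(edits) {
  if (is.null(edits) || nrow(edits) == 0L) return("VAR=none")
  tok <- vapply(seq_len(nrow(edits)), function(j) {
    switch(edits$kind[j],
      trunc = paste0("T5:", edits$payload[j]),
      snp   = paste0("S:", edits$pos[j], ":", edits$payload[j]),
      ins   = paste0("I:", edits$pos[j], ":", edits$payload[j]),
      del   = paste0("D:", edits$pos[j], ":", edits$payload[j]),
      polya = paste0("PA:", edits$payload[j]),
      stop("unknown edit kind: ", edits$kind[j]))
  }, character(1L))
  paste0("VAR=", paste(tok, collapse = ","))
}

#' @rdname encodeEditAnnotation
#' @param annotation an annotation string produced by `encodeEditAnnotation`.
#' @return `decodeEditAnnotation`: the edit data.frame.
#' @export
decodeEditAnnotation <- function(annotation) {
  if (!is.character(annotation) || length(annotation) != 1L ||
      !startsWith(annotation, "VAR="))
    stop("annotation must be a single string starting with 'VAR='")
  body <- substring(annotation, 5L)
  if (body == "none") return(.emptyEdits())
  toks <- strsplit(body, ",", fixed = TRUE)[[1L]]
  rows <- lapply(toks, function(t) {
    f <- strsplit(t, ":", fixed = TRUE)[[1L]]
    bad <- function() stop("malformed annotation token: '", t, "'")
    if (f[1L] == "T5") {
      if (length(f) != 2L || !grepl("^[0-9]+$", f[2L])) bad()
      .edit("trunc", NA_integer_, f[2L])
    } else if (f[1L] == "S") {
      if (length(f) != 3L || !grepl("^[0-9]+$", f[2L]) ||
          !grepl("^[ACGT]{2}$", f[3L])) bad()
      .edit("snp", as.integer(f[2L]), f[3L])
    } else if (f[1L] == "I") {
      if (length(f) != 3L || !grepl("^[0-9]+$", f[2L]) ||
          !grepl("^[ACGT]+$", f[3L])) bad()
      .edit("ins", as.integer(f[2L]), f[3L])
    } else if (f[1L] == "D") {
      if (length(f) != 3L || !grepl("^[0-9]+$", f[2L]) ||
          !grepl("^[0-9]+$", f[3L])) bad()
      .edit("del", as.integer(f[2L]), f[3L])
    } else if (f[1L] == "PA") {
      if (length(f) != 2L || !grepl("^[0-9]+$", f[2L])) bad()
      .edit("polya", NA_integer_, f[2L])
    } else bad()
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
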