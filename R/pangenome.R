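#' Read a GFA 1.x sequence graph
#'
#' Parses S (segment), L (link) and P (path) records of a Graphical
#' Fragment Assembly file. Segments must carry explicit sequences. Paths are
#' kept as ordered, oriented segment lists; one of them is later designated
#' as the reference path for bubble anchoring.
#'
#' @param path GFA file path.
#' @return a list with elements `segments` (named character vector of
#'   sequences), `links` (data.frame `from`, `fromOrient`, `to`,
#'   `toOrient`) and `paths` (named list of data.frames `seg`, `orient`).
#' @export
readGFA <- function(path) {
  lines <- readLines(path)
  segs <- character(); links <- list(); paths <- list()
  for (ln in lines) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (f[1L] == "S") {
      if (length(f) < 3L || f[3L] == "*")
        stop("segment without explicit sequence: ", f[2L])
      segs[[f[2L]]] <- toupper(f[3L])
    } else if (f[1L] == "L") {
      if (length(f) < 5L) stop("malformed L record")
      links[[length(links) + 1L]] <- data.frame(
        from = f[2L], fromOrient = f[3L], to = f[4L], toOrient = f[5L],
        stringsAsFactors = FALSE)
    } else if (f[1L] == "P") {
      if (length(f) < 3L) stop("malformed P record")
      steps <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
      paths[[f[2L]]] <- data.frame(
        seg = sub("[+-]$", "", steps),
        orient = sub("^.*([+-])$", "\\1", steps),
        stringsAsFactors = FALSE)
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(from = character(), fromOrient = character(),
               to = character(), toOrient = character(),
               stringsAsFactors = FALSE)
  list(segments = segs, links = links, paths = paths)
}

.orientedSeq <- function(segments, seg, orient) {
  s <- segments[[seg]]
  if (orient == "-") revComp(s) else s
}

# Directed adjacency over oriented nodes "seg+" / "seg-". Each GFA link
# A a B b induces A^a -> B^b and the reverse-complement edge B^!b -> A^!a.
.orientedAdjacency <- function(gfa) {
  flip <- function(o) ifelse(o == "+", "-", "+")
  l <- gfa$links
  from <- c(paste0(l$from, l$fromOrient),
            paste0(l$to, flip(l$toOrient)))
  to <- c(paste0(l$to, l$toOrient),
          paste0(l$from, flip(l$fromOrient)))
  keep <- !duplicated(paste(from, to))
  split(to[keep], factor(from[keep], levels = unique(from[keep])))
}

#' Detect simple bubbles along the reference path of a pangenome graph
#'
#' A simple bubble is a pair of nodes (source, sink) on the reference path
#' joined by exactly two internally vertex-disjoint directed walks: one
#' along the reference path, one deviating through non-reference segments
#' (or a direct source-to-sink link, for a deletion bubble whose alternate
#' sequence is empty). Reference coordinates are computed from cumulative
#' segment lengths along the reference path, in the 0-based half-open frame:
#' the bubble interval starts at the end of the source segment. Cyclic or
#' branching off-reference regions are skipped with a warning.
#'
#' @param gfa a graph from [readGFA()] (or a GFA path).
#' @param refPath name of the reference P record; defaults to the only path
#'   in the graph, and errors if several paths exist and none is named.
#' @return a data.frame with one row per bubble: `sourceNode`, `sinkNode`,
#'   `refSeq`, `altSeq`, `chrom` (the reference path name), `start`, `end`.
#' @export
detectBubbles <- function(gfa, refPath = NULL) {
  if (is.character(gfa)) gfa <- readGFA(gfa)
  if (is.null(refPath)) {
    if (length(gfa$paths) == 1L) refPath <- names(gfa$paths)
    else stop("no reference path designated (graph has ",
              length(gfa$paths), " paths)")
  }
  if (!refPath %in% names(gfa$paths))
    stop("reference path '", refPath, "' not found in graph")
  rp <- gfa$paths[[refPath]]
  refNodes <- paste0(rp$seg, rp$orient)
  refIndex <- stats::setNames(seq_along(refNodes), refNodes)
  segLen <- nchar(gfa$segments)[rp$seg]
  cumEnd <- cumsum(segLen)  # 0-based end of each ref segment
  adj <- .orientedAdjacency(gfa)

  out <- list()
  for (i in seq_len(length(refNodes) - 1L)) {
    s <- refNodes[i]
    nexts <- adj[[s]]
    if (is.null(nexts)) next
    for (v in setdiff(nexts, refNodes[i + 1L])) {
      if (!is.na(refIndex[v])) {
        ## direct link to a downstream ref node: deletion bubble
        j <- refIndex[[v]]
        if (j <= i + 1L) next
        interior <- seq(i + 1L, j - 1L)
        refSeq <- paste(vapply(interior, function(kk)
          .orientedSeq(gfa$segments, rp$seg[kk], rp$orient[kk]),
          character(1L)), collapse = "")
        out[[length(out) + 1L]] <- data.frame(
          sourceNode = s, sinkNode = v, refSeq = refSeq, altSeq = "",
          chrom = refPath, start = cumEnd[i], end = cumEnd[j - 1L],
          stringsAsFactors = FALSE)
      } else {
        ## walk off-reference until a ref node is reached
        walk <- character(); node <- v; ok <- TRUE
        for (step in seq_len(length(gfa$segments) + 1L)) {
          if (node %in% walk) { ok <- FALSE; break }  # cycle
          walk <- c(walk, node)
          nx <- adj[[node]]
          if (is.null(nx) || length(nx) != 1L) { ok <- FALSE; break }
          if (!is.na(refIndex[nx])) { node <- nx; break }
          node <- nx
          if (step > length(gfa$segments)) { ok <- FALSE; break }
        }
        if (!ok || is.na(refIndex[node])) {
          warning("skipping cyclic or branching region after node ", s)
          next
        }
        j <- refIndex[[node]]
        if (j <= i) { warning("skipping backward bubble at node ", s); next }
        interior <- if (j > i + 1L) seq(i + 1L, j - 1L) else integer()
        refSeq <- paste(vapply(interior, function(kk)
          .orientedSeq(gfa$segments, rp$seg[kk], rp$orient[kk]),
          character(1L)), collapse = "")
        altSeq <- paste(vapply(walk, function(w)
          .orientedSeq(gfa$segments, sub("[+-]$", "", w),
                       sub("^.*([+-])$", "\\1", w)), character(1L)),
          collapse = "")
        if (identical(refSeq, altSeq)) next
        out[[length(out) + 1L]] <- data.frame(
          sourceNode = s, sinkNode = node, refSeq = refSeq, altSeq = altSeq,
          chrom = refPath, start = cumEnd[i],
          end = if (j > i + 1L) cumEnd[j - 1L] else cumEnd[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sourceNode = character(), sinkNode = character(),
                      refSeq = character(), altSeq = character(),
                      chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Classify a sequence against a TE consensus library by k-mer containment
#'
#' Computes, for each library entry, the fraction of the query's k-mers
#' present in that entry's k-mer set, strand-aware (the reverse complement
#' of the query is also scored and the better orientation kept). The best
#' entry is reported if its containment reaches `minKmerContainment`.
#' Because containment is measured on the query, truncated copies of a
#' consensus still classify to it.
#'
#' @param sequence query nucleotide string (length >= k).
#' @param library consensus library (FASTA path, `DNAStringSet`, or named
#'   character vector) with identifiers `family#superfamily`.
#' @param minKmerContainment minimum containment fraction (default 0.5).
#' @param k k-mer size (default 15).
#' @return a list `(family, superfamily, containment)` or `NULL` if no entry
#'   reaches the threshold.
#' @export
classifyTE <- function(sequence, library, minKmerContainment = 0.5,
                       k = 15L) {
  lib <- asSeqSet(library)
  if (!length(lib)) stop("consensus library is empty")
  if (nchar(sequence) < k) return(NULL)
  qf <- kmerSet(toupper(sequence), k)
  qr <- kmerSet(revComp(sequence), k)
  best <- 0; bestIdx <- NA_integer_
  for (i in seq_along(lib)) {
    ls <- kmerSet(lib[[i]], k)
    cont <- max(mean(qf %in% ls), mean(qr %in% ls))
    if (cont > best) { best <- cont; bestIdx <- i }
  }
  if (is.na(bestIdx) || best < minKmerContainment) return(NULL)
  fam <- .parseFamilyId(names(lib)[bestIdx])
  list(family = unname(fam[1L, "family"]),
       superfamily = unname(fam[1L, "superfamily"]),
       containment = best)
}

#' Extract TE variants from a pangenome graph
#'
#' Runs [detectBubbles()] and classifies each bubble's sequence with
#' [classifyTE()]: a bubble whose alternate (non-reference) path is a TE and
#' whose reference side is empty becomes an insertion; a bubble whose
#' reference-only side is a TE and whose alternate is empty becomes a
#' deletion. Bubbles failing classification (or balanced substitution
#' bubbles) are dropped.
#'
#' @inheritParams detectBubbles
#' @inheritParams classifyTE
#' @return a `GRanges` of variants with `source = "pangenome"`; coordinates
#'   are on the reference path, chromosome named after it.
#' @export
extractPangenomeVariants <- function(gfa, library, refPath = NULL,
                                     minKmerContainment = 0.5, k = 15L) {
  bubbles <- detectBubbles(gfa, refPath)
  rows <- list()
  for (i in seq_len(nrow(bubbles))) {
    b <- bubbles[i, ]
    if (nzchar(b$altSeq) && !nzchar(b$refSeq)) {
      cls <- classifyTE(b$altSeq, library, minKmerContainment, k)
      if (is.null(cls)) next
      rows[[length(rows) + 1L]] <- list(
        chrom = b$chrom, start0 = b$start, end0 = b$start, kind = "INS",
        sequence = b$altSeq, family = cls$family,
        superfamily = cls$superfamily)
    } else if (nzchar(b$refSeq) && !nzchar(b$altSeq)) {
      cls <- classifyTE(b$refSeq, library, minKmerContainment, k)
      if (is.null(cls)) next
      rows[[length(rows) + 1L]] <- list(
        chrom = b$chrom, start0 = b$start, end0 = b$end, kind = "DEL",
        sequence = "", family = cls$family, superfamily = cls$superfamily)
    }
  }
  if (!length(rows))
    return(newVariantGRanges(character(), integer(), integer(), character(),
                             character(), character(), character(),
                             character(), character(), character()))
  newVariantGRanges(
    chrom = vapply(rows, `[[`, "", "chrom"),
    start0 = vapply(rows, `[[`, 0, "start0"),
    end0 = vapply(rows, `[[`, 0, "end0"),
    id = sprintf("pan%04d", seq_along(rows)),
    kind = vapply(rows, `[[`, "", "kind"),
    sequence = vapply(rows, `[[`, "", "sequence"),
    family = vapply(rows, `[[`, "", "family"),
    superfamily = vapply(rows, `[[`, "", "superfamily"),
    source = "pangenome", annotation = "")
}
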