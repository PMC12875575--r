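.normGT <- function(gt) {
  # unordered genotype: "1/0" == "0/1"; "./." and missing -> NA
  out <- vapply(gt, function(g) {
    if (is.na(g) || !nzchar(g)) return(NA_character_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_character_)
    paste(sort(al), collapse = "/")
  }, character(1L), USE.NAMES = FALSE)
  out
}

.emptyCallFrame <- function() {
  data.frame(id = character(), chrom = character(), pos = numeric(),
             kind = character(), gt = character(), superfamily = character(),
             stringsAsFactors = FALSE)
}

#' Load truth or predicted TE calls from VCF or BED
#'
#' Normalizes calls to a common frame: `chrom`, `pos` (0-based internal
#' representative position), `kind` (INS/DEL, `NA` if unknown), `gt`
#' (unordered genotype string, `NA` if absent) and `superfamily` (`NA`
#' unless a TESF INFO field is present). For a VCF, POS is taken as the
#' left-anchor base preceding the event, so the internal position equals
#' POS numerically; kind comes from SVTYPE when present, else from REF/ALT
#' lengths; the genotype of one `sample` column is captured. For BED, the
#' position is the interval start (already 0-based) and genotypes come from
#' an optional `genotypeColumn`.
#'
#' @param path input file.
#' @param format `"vcf"`, `"bed"`, or `"auto"` (by file extension).
#' @param sample VCF sample column to take genotypes from (index or name).
#' @param genotypeColumn optional 1-based BED column holding genotypes.
#' @return a data.frame of normalized calls.
#' @export
loadPredictions <- function(path, format = c("auto", "vcf", "bed"),
                            sample = 1L, genotypeColumn = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
      else if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
      else stop("cannot infer format of '", path,
                "'; pass format = 'vcf' or 'bed'")
  }
  if (format == "vcf") {
    v <- VariantAnnotation::readVcf(path, genome = "pred")
    if (nrow(v) == 0L) return(.emptyCallFrame())
    rr <- SummarizedExperiment::rowRanges(v)
    refLen <- nchar(as.character(VariantAnnotation::ref(v)))
    altLen <- vapply(VariantAnnotation::alt(v), function(a)
      if (length(a)) nchar(as.character(a[[1L]])) else 0L, 0L)
    kind <- rep(NA_character_, nrow(v))
    inf <- VariantAnnotation::info(v)
    if ("SVTYPE" %in% colnames(inf)) {
      kind <- as.character(inf$SVTYPE)
      kind[!kind %in% c("INS", "DEL")] <- NA_character_
    }
    kind[is.na(kind) & altLen > refLen] <- "INS"
    kind[is.na(kind) & altLen < refLen] <- "DEL"
    gt <- rep(NA_character_, nrow(v))
    gm <- VariantAnnotation::geno(v)
    if ("GT" %in% names(gm) && ncol(gm$GT) >= 1L)
      gt <- .normGT(gm$GT[, sample])
    sf <- if ("TESF" %in% colnames(inf)) as.character(inf$TESF)
      else rep(NA_character_, nrow(v))
    ids <- rownames(v)
    if (is.null(ids)) ids <- sprintf("pred%05d", seq_len(nrow(v)))
    data.frame(id = ids, chrom = as.character(seqnames(rr)),
               pos = GenomicRanges::start(rr), kind = kind, gt = gt,
               superfamily = sf, stringsAsFactors = FALSE)
  } else {
    if (file.size(path) == 0L) return(.emptyCallFrame())
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, comment.char = "#")
    gt <- if (!is.null(genotypeColumn) && ncol(bed) >= genotypeColumn)
      .normGT(as.character(bed[[genotypeColumn]]))
      else rep(NA_character_, nrow(bed))
    data.frame(id = sprintf("pred%05d", seq_len(nrow(bed))),
               chrom = as.character(bed[[1L]]), pos = bed[[2L]],
               kind = NA_character_, gt = gt,
               superfamily = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Match truth against predicted calls under a positional tolerance
#'
#' Per chromosome, all truth/predicted pairs within `tolerance` bp (and of
#' the same kind, if `typeAware` and both kinds are known) are candidate
#' matches; they are accepted greedily by ascending distance, ties broken by
#' ascending truth position then ascending predicted position, each variant
#' used at most once. Greedy matching with deterministic tie-breaking is
#' reproducible; on crossing configurations it can fall one short of the
#' maximum-cardinality matching (see the package vignette).
#'
#' @param truth,predicted normalized call data.frames (from
#'   [loadPredictions()], or with at least `chrom` and `pos`; optional
#'   `id`, `kind`, `gt`, `superfamily`).
#' @param tolerance maximum |truth pos - predicted pos| in bp (default 50).
#' @param typeAware if `TRUE`, INS may only match INS and DEL only DEL.
#' @return a [MatchSet-class].
#' @export
matchVariants <- function(truth, predicted, tolerance = 50,
                          typeAware = FALSE) {
  if (tolerance < 0) stop("tolerance must be >= 0")
  truth <- .fillCallFrame(truth, "truth")
  predicted <- .fillCallFrame(predicted, "pred")
  cand <- NULL
  for (chrom in intersect(unique(truth$chrom), unique(predicted$chrom))) {
    ti <- which(truth$chrom == chrom)
    pi <- which(predicted$chrom == chrom)
    d <- abs(outer(truth$pos[ti], predicted$pos[pi], `-`))
    ok <- d <= tolerance
    if (typeAware) {
      kt <- truth$kind[ti]; kp <- predicted$kind[pi]
      known <- outer(!is.na(kt), !is.na(kp), `&`)
      same <- outer(kt, kp, `==`); same[is.na(same)] <- TRUE
      ok <- ok & (!known | same)
    }
    idx <- which(ok, arr.ind = TRUE)
    if (nrow(idx))
      cand <- rbind(cand, data.frame(
        t = ti[idx[, 1L]], p = pi[idx[, 2L]],
        d = d[idx], tpos = truth$pos[ti[idx[, 1L]]],
        ppos = predicted$pos[pi[idx[, 2L]]]))
  }
  usedT <- logical(nrow(truth)); usedP <- logical(nrow(predicted))
  pairs <- list()
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$d, cand$tpos, cand$ppos), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      ti <- cand$t[r]; pi <- cand$p[r]
      if (usedT[ti] || usedP[pi]) next
      usedT[ti] <- TRUE; usedP[pi] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        chrom = truth$chrom[ti], truthId = truth$id[ti],
        truthPos = truth$pos[ti], predId = predicted$id[pi],
        predPos = predicted$pos[pi], distance = cand$d[r],
        truthGT = truth$gt[ti], predGT = predicted$gt[pi],
        superfamily = truth$superfamily[ti], stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(chrom = character(), truthId = character(),
               truthPos = numeric(), predId = character(),
               predPos = numeric(), distance = numeric(),
               truthGT = character(), predGT = character(),
               superfamily = character(), stringsAsFactors = FALSE)
  new("MatchSet", matches = matches,
      unmatchedTruth = truth[!usedT, , drop = FALSE],
      unmatchedPred = predicted[!usedP, , drop = FALSE],
      tolerance = tolerance)
}

.fillCallFrame <- function(df, prefix) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    stop("call frame needs 'chrom' and 'pos' columns")
  n <- nrow(df)
  if (is.null(df$id)) df$id <- sprintf("%s%05d", prefix, seq_len(n))
  if (is.null(df$kind)) df$kind <- rep(NA_character_, n)
  if (is.null(df$gt)) df$gt <- rep(NA_character_, n)
  else df$gt <- .normGT(df$gt)
  if (is.null(df$superfamily)) df$superfamily <- rep(NA_character_, n)
  df[c("id", "chrom", "pos", "kind", "gt", "superfamily")]
}

#' Detection metrics from a match set
#'
#' `tp` is the number of matched pairs, `fn` the unmatched truth count, and
#' `fp` the unmatched predicted count; sensitivity = tp/(tp+fn), precision
#' = tp/(tp+fp), F1 their harmonic mean. A metric whose denominator is zero
#' is reported as `NA`. Fractions are kept at full precision (display
#' rounds to 2 decimals). Genotype accuracy is filled in from
#' [genotypeConcordance()].
#'
#' @param matchset a [MatchSet-class].
#' @return a [TEMetrics-class].
#' @export
computeMetrics <- function(matchset) {
  tp <- nrow(matchset@matches)
  fn <- nrow(matchset@unmatchedTruth)
  fp <- nrow(matchset@unmatchedPred)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  new("TEMetrics", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), sensitivity = sens, precision = prec, f1 = f1,
      genotypeAccuracy = genotypeConcordance(matchset))
}

#' Genotype concordance over positionally matched variants
#'
#' The fraction of matched pairs whose truth and predicted genotypes are
#' exactly identical, compared as unordered allele multisets, among all
#' matched pairs carrying a genotype on both sides. Matches lacking a
#' predicted genotype (presence-only detectors) are excluded from the
#' denominator; `NA` if no pair has genotypes on both sides.
#'
#' @param matchset a [MatchSet-class].
#' @return a fraction in \[0,1\], or `NA`.
#' @export
genotypeConcordance <- function(matchset) {
  m <- matchset@matches
  both <- !is.na(m$truthGT) & !is.na(m$predGT)
  if (!any(both)) return(NA_real_)
  mean(m$truthGT[both] == m$predGT[both])
}

.metricsRow <- function(stratum, ms) {
  met <- computeMetrics(ms)
  data.frame(stratum = stratum, tp = met@tp, fp = met@fp, fn = met@fn,
             sensitivity = met@sensitivity, precision = met@precision,
             f1 = met@f1, genotype_accuracy = met@genotypeAccuracy,
             stringsAsFactors = FALSE)
}

#' Write a comparison report
#'
#' Writes a TSV with two sections: the matched pairs (truth id, positions,
#' distance, both genotypes, concordant flag) and a metrics block with an
#' overall row plus, if requested, one row per truth superfamily. Section
#' headers start with `#`.
#'
#' @param matchset a [MatchSet-class].
#' @param outPath output file.
#' @param stratifyBySuperfamily add per-superfamily metric rows (computed by
#'   restricting truth, matches and matched predictions to the stratum;
#'   unmatched predictions of unknown superfamily count only in the overall
#'   row).
#' @return invisibly, the metrics data.frame written in the metrics block.
#' @export
compareReport <- function(matchset, outPath,
                          stratifyBySuperfamily = FALSE) {
  m <- matchset@matches
  pairs <- data.frame(
    truth_id = m$truthId, chrom = m$chrom, truth_pos = m$truthPos,
    pred_id = m$predId, pred_pos = m$predPos, distance = m$distance,
    truth_gt = m$truthGT, pred_gt = m$predGT,
    concordant = !is.na(m$truthGT) & !is.na(m$predGT) &
      m$truthGT == m$predGT,
    stringsAsFactors = FALSE)
  metrics <- .metricsRow("overall", matchset)
  if (stratifyBySuperfamily) {
    sfs <- sort(unique(stats::na.omit(c(m$superfamily,
                                        matchset@unmatchedTruth$superfamily))))
    for (sf in sfs) {
      sub <- new("MatchSet",
                 matches = m[!is.na(m$superfamily) & m$superfamily == sf, ,
                             drop = FALSE],
                 unmatchedTruth = matchset@unmatchedTruth[
                   !is.na(matchset@unmatchedTruth$superfamily) &
                     matchset@unmatchedTruth$superfamily == sf, ,
                   drop = FALSE],
                 unmatchedPred = matchset@unmatchedPred[
                   !is.na(matchset@unmatchedPred$superfamily) &
                     matchset@unmatchedPred$superfamily == sf, ,
                   drop = FALSE],
                 tolerance = matchset@tolerance)
      metrics <- rbind(metrics, .metricsRow(sf, sub))
    }
  }
  con <- file(outPath, "w")
  on.exit(close(con))
  writeLines("# matched_pairs", con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("# metrics", con)
  utils::write.table(metrics, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(metrics)
}
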