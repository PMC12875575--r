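library(GenomicRanges)
library(S4Vectors)

test_that("random insertions are valid, non-overlapping and in bounds", {
  ref <- toyReference(100000, nChroms = 2L)
  lib <- toyLibrary()
  expect_length(generateRandomInsertions(ref, lib, 0L, seed = 1L), 0L)
  ins <- generateRandomInsertions(ref, lib, 10L,
                                  VariationProfile(polyaMaxLen = 10L),
                                  seed = 5L)
  expect_length(ins, 10L)
  expect_true(all(width(ins) == 0L))
  expect_true(all(mcols(ins)$kind == "INS"))
  expect_false(any(duplicated(paste(seqnames(ins), start(ins)))))
  lens <- setNames(nchar(ref), names(ref))
  expect_true(all(TEforge:::bedStart(ins) <
                    lens[as.character(seqnames(ins))]))
  expect_true(all(nzchar(mcols(ins)$sequence)))
  expect_true(all(mcols(ins)$family %in% c("AluSyn", "L1Syn")))
})

test_that("2200 insertions spread over many chromosomes stay in bounds", {
  ref <- toyReference(220000, nChroms = 22L, seed = 8L)
  lib <- toyLibrary()
  ins <- generateRandomInsertions(ref, lib, 2200L,
                                  VariationProfile(snpRate = 0,
                                                   indelRate = 0,
                                                   truncateSeqFraction = 0,
                                                   polyaFraction = 0),
                                  seed = 9L)
  expect_length(ins, 2200L)
  expect_setequal(as.character(unique(seqnames(ins))), names(ref))
  lens <- setNames(nchar(ref), names(ref))
  expect_true(all(TEforge:::bedStart(ins) <
                    lens[as.character(seqnames(ins))]))
})

test_that("insertion points avoid long N runs", {
  fx <- makeReference(FixtureSpec(refLength = 20000, nChroms = 1L,
                                  nRunCount = 4L, nRunLength = 500L,
                                  seed = 4L))
  ins <- generateRandomInsertions(fx$seqs, toyLibrary(), 50L,
                                  VariationProfile(polyaMaxLen = 10L),
                                  nRunThreshold = 10L, seed = 6L)
  pos <- TEforge:::bedStart(ins)
  for (r in seq_len(nrow(fx$nRuns)))
    expect_false(any(pos > fx$nRuns$start[r] & pos < fx$nRuns$end[r]))
})

test_that("placement failure reports the achieved count", {
  ref <- c(chr1 = strrep("ACGT", 5))  # 20 bp: at most 19 distinct points
  expect_error(
    generateRandomInsertions(ref, toyLibrary(), 100L,
                             VariationProfile(snpRate = 0, indelRate = 0,
                                              truncateSeqFraction = 0,
                                              polyaFraction = 0),
                             maxRetries = 200L, seed = 2L),
    "placed")
})

test_that("deletions are sampled without replacement from known sites", {
  ref <- toyReference()
  sites <- toyKnownSites(ref, n = 100L)
  expect_length(selectDeletions(sites, 0L, seed = 1L), 0L)
  del <- selectDeletions(sites, 50L, seed = 1L)
  expect_length(del, 50L)
  expect_true(all(mcols(del)$kind == "DEL"))
  key <- paste(seqnames(del), start(del), end(del))
  siteKey <- paste(seqnames(sites), start(sites), end(sites))
  expect_true(all(key %in% siteKey))
  expect_false(any(duplicated(key)))
  expect_error(selectDeletions(sites, 101L, seed = 1L), "known sites")
})

test_that("real insertion identifiers parse with 1-based positions", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "real.fa")
  writeLines(c(">chr1-683234-AluSp#SINE/Alu",
               strrep("ACGT", 75)), fa)
  v <- loadRealInsertions(fa)
  expect_identical(as.character(seqnames(v)), "chr1")
  expect_identical(TEforge:::bedStart(v), 683233L)
  expect_identical(width(v), 0L)
  expect_identical(mcols(v)$kind, "INS")
  expect_identical(mcols(v)$family, "AluSp")
  expect_identical(mcols(v)$superfamily, "SINE/Alu")
  expect_identical(nchar(mcols(v)$sequence), 300L)

  writeLines(c(">chr1_683234_AluSp", "ACGT"), fa)
  expect_error(loadRealInsertions(fa), "chr1_683234_AluSp")
})

test_that("well-formed real FASTA yields one unique variant per record", {
  set.seed(44)
  dir <- withr::local_tempdir()
  for (rep in 1:5) {
    k <- sample(2:20, 1L)
    ids <- sprintf("chr%d-%d-Fam%d#SINE/Alu", sample.int(5L, k, TRUE),
                   sample.int(1e6, k), seq_len(k))
    fa <- file.path(dir, "r.fa")
    writeLines(as.vector(rbind(paste0(">", ids),
                               replicate(k, TEforge:::randomDNA(60, .5)))),
               fa)
    v <- loadRealInsertions(fa)
    expect_length(v, k)
    expect_false(anyDuplicated(mcols(v)$id) > 0)
  }
})

test_that("merge produces a sorted, overlap-free catalog and warns on drops", {
  ref <- toyReference()
  ins <- generateRandomInsertions(ref, toyLibrary(), 50L,
                                  VariationProfile(polyaMaxLen = 10L),
                                  seed = 7L)
  del <- selectDeletions(toyKnownSites(ref, 100L), 50L, seed = 8L)
  cat100 <- suppressWarnings(mergeCatalog(ins, del, "toy"))
  expect_s4_class(cat100, "TECatalog")
  expect_true(validObject(cat100))

  # INS strictly inside a DEL is dropped with a warning
  delGr <- TEforge:::newVariantGRanges("chr1", 100L, 400L, "d1", "DEL", "",
                                       "F", "S", "random", "")
  insGr <- TEforge:::newVariantGRanges("chr1", 200L, 200L, "i1", "INS",
                                       "ACGT", "F", "S", "random", "")
  expect_warning(merged <- mergeCatalog(insGr, delGr), "dropped")
  expect_identical(mcols(variants(merged))$id, "d1")

  # boundary insertion points are allowed
  edgeIns <- TEforge:::newVariantGRanges("chr1", 100L, 100L, "i2", "INS",
                                         "ACGT", "F", "S", "random", "")
  both <- mergeCatalog(edgeIns, delGr)
  expect_identical(nVariants(both), 2L)

  expect_identical(nVariants(mergeCatalog()), 0L)
})

test_that("catalog merge invariants hold across many random seeds", {
  ref <- toyReference(30000)
  lib <- toyLibrary()
  for (s in 1:100) {
    set.seed(s)
    n <- sample.int(15L, 1L)
    pos <- sample.int(29000L, n)
    ins <- TEforge:::newVariantGRanges(
      "chr1", pos, pos, sprintf("i%02d", 1:n), "INS", strrep("A", 30L),
      "F", "S", "random", "")
    m <- sample.int(8L, 1L)
    ds <- sample.int(28000L, m)
    del <- TEforge:::newVariantGRanges(
      "chr1", ds, ds + sample(50:500, m, replace = TRUE),
      sprintf("d%02d", 1:m), "DEL", "", "F", "S", "random", "")
    catalog <- suppressWarnings(mergeCatalog(ins, del))
    expect_true(validObject(catalog))
    gr <- variants(catalog)
    o <- order(as.character(seqnames(gr)), TEforge:::bedStart(gr),
               TEforge:::bedEnd(gr))
    expect_identical(o, seq_along(gr))
    expect_identical(TEforge:::.countCatalogConflicts(gr), 0L)
  }
})

test_that("catalog BED+FASTA round trip is the identity", {
  dir <- withr::local_tempdir()
  ref <- toyReference()
  ins <- generateRandomInsertions(ref, toyLibrary(), 60L,
                                  VariationProfile(polyaMaxLen = 10L),
                                  seed = 10L)
  del <- selectDeletions(toyKnownSites(ref, 100L), 40L, seed = 11L)
  catalog <- suppressWarnings(mergeCatalog(ins, del, "toy"))
  bed <- file.path(dir, "cat.bed"); fa <- file.path(dir, "cat.fa")
  writeCatalog(catalog, bed, fa)
  back <- readCatalog(bed, fa, "toy")
  g1 <- variants(catalog); g2 <- variants(back)
  expect_identical(as.character(seqnames(g1)), as.character(seqnames(g2)))
  expect_identical(start(g1), start(g2))
  expect_identical(end(g1), end(g2))
  for (col in c("id", "kind", "sequence", "family", "superfamily",
                "annotation"))
    expect_identical(mcols(g1)[[col]], mcols(g2)[[col]], label = col)

  # byte-level: write(read(write(x))) == write(x), modulo trailing newline
  bed2 <- file.path(dir, "cat2.bed"); fa2 <- file.path(dir, "cat2.fa")
  writeCatalog(back, bed2, fa2)
  expect_identical(readLines(bed), readLines(bed2))
  expect_identical(readLines(fa), readLines(fa2))
})

test_that("DEL-only catalogs and hand-edited BEDs are readable", {
  dir <- withr::local_tempdir()
  ref <- toyReference()
  del <- selectDeletions(toyKnownSites(ref, 30L), 10L, seed = 3L)
  catalog <- mergeCatalog(deletions = del, referenceId = "toy")
  bed <- file.path(dir, "d.bed"); fa <- file.path(dir, "d.fa")
  writeCatalog(catalog, bed, fa)
  expect_identical(nVariants(readCatalog(bed, fa)), 10L)
  expect_identical(nVariants(readCatalog(bed)), 10L)  # FASTA optional

  # user edits the BED (drops rows, keeps the dialect) and re-reads
  lines <- readLines(bed)
  writeLines(lines[1:5], bed)
  expect_identical(nVariants(readCatalog(bed)), 5L)

  # an INS row whose sequence is missing from the FASTA errors
  writeLines("chr1\t10\t10\tghost\tINS\tF\tS", bed)
  expect_error(readCatalog(bed, fa), "ghost")
})
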