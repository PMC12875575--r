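library(GenomicRanges)
library(S4Vectors)

test_that("genotype assignment honours frequency bounds exactly at 0 and 1", {
  ref <- toyReference()
  ins <- generateRandomInsertions(ref, toyLibrary(), 10L,
                                  VariationProfile(polyaMaxLen = 10L),
                                  seed = 1L)
  catalog <- mergeCatalog(ins, referenceId = "toy")
  gAll <- assignGenotypes(catalog, 5L, 2L, 1, 1, seed = 2L)
  expect_true(all(alleles(gAll) == 1L))
  gNone <- assignGenotypes(catalog, 5L, 2L, 0, 0, seed = 2L)
  expect_true(all(alleles(gNone) == 0L))
  expect_error(assignGenotypes(catalog, 5L, 2L, 0.9, 0.1), "freqLow")
  expect_error(assignGenotypes(catalog, 0L), "nSamples")
})

test_that("empirical carrier fraction recovers f = 0.3 over 2000 haplotypes", {
  ref <- toyReference()
  ins <- generateRandomInsertions(ref, toyLibrary(), 5L,
                                  VariationProfile(polyaMaxLen = 10L),
                                  seed = 3L)
  catalog <- mergeCatalog(ins, referenceId = "toy")
  g <- assignGenotypes(catalog, 1000L, 2L, 0.3, 0.3, seed = 4L)
  se <- sqrt(0.3 * 0.7 / 2000)
  carrier <- rowMeans(alleles(g))
  expect_true(all(abs(carrier - 0.3) < 3 * se))
  expect_true(all(alleleFreqs(g) == 0.3))
})

test_that("block partition tiles the reference and is bounded by 2n+1", {
  ref <- toyReference(10000)
  emptyPart <- partitionBlocks(ref, TECatalog(referenceId = "toy"))
  b <- emptyPart@blocks$chr1
  expect_identical(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(0, 10000))

  delGr <- TEforge:::newVariantGRanges("chr1", 100L, 400L, "d1", "DEL", "",
                                       "F", "S", "random", "")
  part <- partitionBlocks(c(chr1 = substr(ref[[1]], 1, 1000)),
                          TECatalog(delGr))
  b <- part@blocks$chr1
  expect_equal(b$start, c(0, 100, 400))
  expect_equal(b$end, c(100, 400, 1000))
  expect_identical(b$type, c("invariable", "del", "invariable"))

  inst <- randomInstance(99L)
  part <- partitionBlocks(inst$ref, inst$catalog)
  n <- nVariants(inst$catalog)
  expect_lte(nrow(part@blocks$chrA), 2L * n + 1L)
  # concatenating non-insertion blocks reproduces the reference
  bl <- part@blocks$chrA
  tiles <- bl[bl$type != "ins", , drop = FALSE]
  glued <- paste(substring(inst$ref[["chrA"]], tiles$start + 1L, tiles$end),
                 collapse = "")
  expect_identical(glued, inst$ref[["chrA"]])

  far <- TEforge:::newVariantGRanges("chrA", 10L, 999999L, "dX", "DEL", "",
                                     "F", "S", "random", "")
  expect_error(partitionBlocks(inst$ref, TECatalog(far)), "beyond")
})

test_that("all-reference and single-insertion haplotypes behave exactly", {
  inst <- randomInstance(5L)
  part <- partitionBlocks(inst$ref, inst$catalog)
  zero <- setNames(rep(0L, length(inst$alleles)), names(inst$alleles))
  out <- assembleHaplotype(part, inst$ref, inst$catalog, zero)
  expect_identical(out[["chrA"]], inst$ref[["chrA"]])

  ins <- TEforge:::newVariantGRanges("chrA", 50L, 50L, "i1", "INS",
                                     strrep("ACG", 100L), "F", "S",
                                     "random", "")
  catalog <- TECatalog(ins)
  part1 <- partitionBlocks(inst$ref, catalog)
  one <- assembleHaplotype(part1, inst$ref, catalog, c(i1 = 1L))
  expect_identical(nchar(one[["chrA"]]), nchar(inst$ref[["chrA"]]) + 300L)
  expect_error(assembleHaplotype(part1, inst$ref, catalog, c(zz = 1L)),
               "cover")
})

test_that("chunk-merge assembly equals the naive applier on random instances", {
  for (s in 1:40) {
    inst <- randomInstance(s)
    part <- partitionBlocks(inst$ref, inst$catalog)
    a <- assembleHaplotype(part, inst$ref, inst$catalog, inst$alleles)
    b <- naiveApply(inst$ref, inst$catalog, inst$alleles)
    expect_identical(a, b)
  }
})

test_that("chunk-merge and naive outputs share the same 21-mer multiset", {
  inst <- randomInstance(77L)
  part <- partitionBlocks(inst$ref, inst$catalog)
  a <- assembleHaplotype(part, inst$ref, inst$catalog, inst$alleles)
  b <- naiveApply(inst$ref, inst$catalog, inst$alleles)
  ka <- countKmers(a, 21L); kb <- countKmers(b, 21L)
  expect_identical(ka[order(names(ka))], kb[order(names(kb))])
})

test_that("per-genome variation diversifies the same insertion across genomes", {
  ref <- c(chrA = TEforge:::randomDNA(2000, 0.5))
  ins <- TEforge:::newVariantGRanges("chrA", 500L, 500L, "i1", "INS",
                                     TEforge:::randomDNA(400, 0.5),
                                     "F", "S", "random", "")
  catalog <- TECatalog(ins)
  part <- partitionBlocks(ref, catalog)
  pg <- VariationProfile(snpRate = 0.05, indelRate = 0)
  h1 <- assembleHaplotype(part, ref, catalog, c(i1 = 1L),
                          perGenomeProfile = pg, hapId = "s1_h1", seed = 9L)
  h2 <- assembleHaplotype(part, ref, catalog, c(i1 = 1L),
                          perGenomeProfile = pg, hapId = "s2_h1", seed = 9L)
  expect_false(identical(h1, h2))
  # truncation/polyA are disabled in the within-cohort pass: flanks intact
  expect_identical(substr(h1[["chrA"]], 1, 500), substr(ref[["chrA"]], 1, 500))
  h1again <- assembleHaplotype(part, ref, catalog, c(i1 = 1L),
                               perGenomeProfile = pg, hapId = "s1_h1",
                               seed = 9L)
  expect_identical(h1, h1again)  # sub-stream determinism
})

test_that("VCF records anchor correctly and round-trip onto the reference", {
  dir <- withr::local_tempdir()
  set.seed(12)
  ref <- c(chrA = TEforge:::randomDNA(5000, 0.5))
  ins <- TEforge:::newVariantGRanges("chrA", c(0L, 1200L), c(0L, 1200L),
                                     c("i0", "i1"), "INS",
                                     c("ACGTT", strrep("TG", 50L)),
                                     "F", "S", "random", "")
  del <- TEforge:::newVariantGRanges("chrA", 3000L, 3120L, "d1", "DEL", "",
                                     "F", "S", "random", "")
  catalog <- mergeCatalog(ins, del)
  g <- assignGenotypes(catalog, 2L, 2L, 1, 1, seed = 5L)
  vcf <- file.path(dir, "t.vcf")
  writeSimVcf(catalog, g, ref, vcf)
  lines <- grep("^[^#]", readLines(vcf), value = TRUE)
  f <- strsplit(lines, "\t")
  # REF equals the reference substring at (POS, POS + len(REF))
  for (x in f) {
    pos <- as.integer(x[2])
    expect_identical(substr(ref[["chrA"]], pos, pos + nchar(x[4]) - 1L),
                     x[4])
  }
  # DEL of width w has len(REF) = w + 1 and SVLEN = -w
  delLine <- f[[which(vapply(f, function(x) x[3] == "d1", TRUE))]]
  expect_identical(nchar(delLine[4]), 121L)
  expect_match(delLine[8], "SVLEN=-120;")
  # insertion at the chromosome start anchors on the following base
  i0 <- f[[which(vapply(f, function(x) x[3] == "i0", TRUE))]]
  expect_identical(as.integer(i0[2]), 1L)
  expect_identical(i0[5], paste0("ACGTT", i0[4]))

  back <- applyVcfToReference(vcf, ref)
  want <- naiveApply(ref, catalog,
                     setNames(rep(1L, 3L), mcols(variants(catalog))$id))
  expect_identical(back$sample001$h1[["chrA"]], want[["chrA"]])
})

test_that("phased emission writes | separators", {
  dir <- withr::local_tempdir()
  inst <- randomInstance(3L)
  g <- assignGenotypes(inst$catalog, 2L, 2L, 0.5, 0.5, seed = 6L)
  vcf <- file.path(dir, "p.vcf")
  writeSimVcf(inst$catalog, g, inst$ref, vcf, phased = TRUE)
  gtcols <- grep("^[^#]", readLines(vcf), value = TRUE)
  expect_true(all(grepl("\\d\\|\\d", vapply(strsplit(gtcols, "\t"),
                                            `[`, "", 10L))))
})

test_that("cohort simulation writes consistent FASTA, VCF and manifest", {
  dir <- withr::local_tempdir()
  ref <- toyReference(40000)
  ins <- generateRandomInsertions(ref, toyLibrary(), 12L,
                                  VariationProfile(polyaMaxLen = 10L),
                                  seed = 21L)
  del <- selectDeletions(toyKnownSites(ref, 30L), 8L, seed = 22L)
  catalog <- suppressWarnings(mergeCatalog(ins, del, "toy"))
  res <- simulateCohort(ref, catalog, nSamples = 4L, ploidy = 2L,
                        outdir = file.path(dir, "cohort"), seed = 33L)
  expect_length(res$fastas, 8L)
  vcfLines <- readLines(res$vcf)
  expect_identical(sum(!startsWith(vcfLines, "#")), nVariants(catalog))
  header <- strsplit(grep("^#CHROM", vcfLines, value = TRUE), "\t")[[1L]]
  expect_length(header, 9L + 4L)

  manifest <- jsonlite::read_json(res$manifest)
  al <- alleles(res$genotypes)
  gr <- variants(catalog)
  insLen <- ifelse(mcols(gr)$kind == "INS", nchar(mcols(gr)$sequence),
                   -width(gr))
  for (hap in names(res$fastas)) {
    fa <- Biostrings::readDNAStringSet(res$fastas[[hap]])
    got <- sum(Biostrings::width(fa))
    want <- sum(nchar(ref)) +
      sum(insLen * al[mcols(gr)$id, hap])
    expect_identical(got, as.integer(want))
    expect_equal(manifest$expectedHaplotypeLengths[[hap]], got,
                 ignore_attr = TRUE)
  }

  # empty catalog: output equals the reference
  res0 <- simulateCohort(ref, TECatalog(referenceId = "toy"), nSamples = 1L,
                         ploidy = 1L, outdir = file.path(dir, "c0"),
                         seed = 34L)
  fa0 <- Biostrings::readDNAStringSet(res0$fastas[[1L]])
  expect_identical(as.character(fa0[["chr1"]]), unname(ref[["chr1"]]))
})

test_that("haplotype length conservation holds across seeds", {
  dir <- withr::local_tempdir()
  ref <- toyReference(20000)
  for (s in c(101L, 202L, 303L)) {
    ins <- generateRandomInsertions(ref, toyLibrary(), 6L,
                                    VariationProfile(polyaMaxLen = 10L),
                                    seed = s)
    del <- selectDeletions(toyKnownSites(ref, 20L), 4L, seed = s + 1L)
    catalog <- suppressWarnings(mergeCatalog(ins, del, "toy"))
    res <- simulateCohort(ref, catalog, nSamples = 2L,
                          outdir = file.path(dir, paste0("c", s)), seed = s)
    gr <- variants(catalog)
    insLen <- ifelse(mcols(gr)$kind == "INS", nchar(mcols(gr)$sequence),
                     -width(gr))
    al <- alleles(res$genotypes)
    for (hap in colnames(al)) {
      fa <- Biostrings::readDNAStringSet(res$fastas[[hap]])
      expect_identical(sum(Biostrings::width(fa)),
                       as.integer(sum(nchar(ref)) +
                                    sum(insLen * al[mcols(gr)$id, hap])))
    }
  }
})
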