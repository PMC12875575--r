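# Shared in-code fixtures: everything is generated at test time.

toyLibrary <- function(seed = 2L) {
  makeConsensusLibrary(
    data.frame(name = c("AluSyn", "L1Syn"),
               superfamily = c("SINE/Alu", "LINE/L1"),
               length = c(300L, 2000L)),
    seed = seed)
}

toyReference <- function(len = 50000, nChroms = 1L, seed = 3L, ...) {
  makeReference(FixtureSpec(refLength = len, nChroms = nChroms,
                            seed = seed, ...))$seqs
}

# Disjoint known TE sites for deletion sampling.
toyKnownSites <- function(seqs, n = 30L, width = 150L) {
  chroms <- rep(names(seqs), length.out = n)
  starts <- unlist(lapply(names(seqs), function(ch) {
    k <- sum(chroms == ch)
    round(seq(500, nchar(seqs[[ch]]) - 1000, length.out = k))
  }))
  GenomicRanges::GRanges(sort(chroms),
                         IRanges::IRanges(start = starts + 1L,
                                          width = width))
}

# A random (reference, catalog, alleles) instance for assembler oracles.
randomInstance <- function(seed, refLen = 3000L, maxVar = 8L) {
  set.seed(seed)
  ref <- c(chrA = TEforge:::randomDNA(refLen, 0.5))
  lib <- toyLibrary(seed)
  nIns <- sample.int(maxVar, 1L)
  ins <- generateRandomInsertions(ref, lib, nIns,
                                  VariationProfile(polyaMaxLen = 10L),
                                  seed = seed + 1L)
  sites <- toyKnownSites(ref, n = 10L, width = 80L)
  del <- selectDeletions(sites, sample.int(5L, 1L), seed = seed + 2L)
  catalog <- suppressWarnings(mergeCatalog(ins, del, "toy"))
  ids <- S4Vectors::mcols(variants(catalog))$id
  alleles <- stats::setNames(rbinom(length(ids), 1L, 0.6), ids)
  list(ref = ref, catalog = catalog, alleles = alleles)
}

# Brute-force maximum-cardinality matching between truth and predicted
# positions under a tolerance: independent oracle for the greedy matcher.
bruteMaxMatching <- function(tpos, ppos, tol) {
  best <- 0L
  recurse <- function(ti, usedP) {
    if (ti > length(tpos)) return(0L)
    skip <- recurse(ti + 1L, usedP)
    take <- 0L
    for (pj in seq_along(ppos)) {
      if (usedP[pj] || abs(tpos[ti] - ppos[pj]) > tol) next
      usedP[pj] <- TRUE
      take <- max(take, 1L + recurse(ti + 1L, usedP))
      usedP[pj] <- FALSE
    }
    max(skip, take)
  }
  recurse(1L, logical(length(ppos)))
}

# Enumerate all simple directed s->t paths over an oriented adjacency list.
enumeratePaths <- function(adj, s, t, cap = 32L) {
  paths <- list()
  walk <- function(node, seen) {
    if (length(paths) > cap) return()
    if (node == t) {
      paths[[length(paths) + 1L]] <<- seen
      return()
    }
    for (nx in adj[[node]]) {
      if (nx %in% seen) next
      walk(nx, c(seen, nx))
    }
  }
  walk(s, s)
  paths
}

# Brute-force simple-bubble finder on a parsed GFA: for every ordered pair
# of reference anchors, a bubble exists iff exactly two internally
# vertex-disjoint paths join them, one being the reference subpath.
bruteBubbles <- function(gfa, refPath) {
  rp <- gfa$paths[[refPath]]
  refNodes <- paste0(rp$seg, rp$orient)
  adj <- TEforge:::.orientedAdjacency(gfa)
  out <- NULL
  for (i in seq_len(length(refNodes) - 1L)) {
    for (j in seq(i + 1L, length(refNodes))) {
      paths <- enumeratePaths(adj, refNodes[i], refNodes[j])
      if (length(paths) != 2L) next
      interiors <- lapply(paths, function(p) p[-c(1L, length(p))])
      if (length(intersect(interiors[[1L]], interiors[[2L]])) > 0L) next
      refSub <- refNodes[i:j]
      isRef <- vapply(paths, function(p) identical(p, refSub), TRUE)
      if (sum(isRef) != 1L) next
      ## interior of the non-ref path must avoid other ref anchors
      altInt <- interiors[[which(!isRef)]]
      if (any(altInt %in% refNodes)) next
      out <- rbind(out, data.frame(sourceNode = refNodes[i],
                                   sinkNode = refNodes[j],
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
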