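test_that("barcode assignment matches membership and unique rescue", {
  wl <- buildWhitelist(tinyMetadata())
  entries <- whitelistEntries(wl)

  exact <- assignBarcodes(entries[1L], wl)
  expect_identical(exact$well_id, wellIds(wl)[1L])
  expect_identical(exact$distance, 0L)
  expect_false(exact$corrected)

  # one substitution away from exactly one entry: rescued when maxDist = 1
  mutated <- paste0("T", substr(entries[1L], 2L, 11L))
  # oracle: brute-force Hamming scan confirms uniqueness of the neighbor
  expect_identical(
    bruteAssign(mutated, entries, wellIds(wl), 1L), wellIds(wl)[1L]
  )
  strict <- assignBarcodes(mutated, wl, maxDist = 0L)
  expect_true(is.na(strict$well_id))
  rescued <- assignBarcodes(mutated, wl, maxDist = 1L)
  expect_identical(rescued$well_id, wellIds(wl)[1L])
  expect_true(rescued$corrected)
  expect_identical(rescued$distance, 1L)

  # equidistant between two entries: the brute-force scan shows the tie
  # and the assignment stays unassigned
  md <- tinyMetadata()
  ab <- ampBatches(md)
  ab$pool_barcode <- c("AAAA", "AAAT")
  wl2 <- buildWhitelist(experimentMetadata(seqBatches(md), ab, wellsCells(md)))
  tie <- paste0("AAAG", substr(whitelistEntries(wl2)[1L], 5L, 11L))
  d <- rowSums(charMat(whitelistEntries(wl2)) != matrix(
    strsplit(tie, "")[[1L]], length(wl2), 11L, byrow = TRUE
  ))
  expect_identical(sum(d == 1L), 2L)
  expect_true(is.na(assignBarcodes(tie, wl2, maxDist = 1L)$well_id))

  expect_error(assignBarcodes("ACGT", wl), "length")
  # N never matches exactly but can be rescued as a single mismatch
  withN <- paste0("N", substr(entries[1L], 2L, 11L))
  expect_true(is.na(assignBarcodes(withN, wl, maxDist = 0L)$well_id))
  expect_identical(
    assignBarcodes(withN, wl, maxDist = 1L)$well_id, wellIds(wl)[1L]
  )
})

test_that("assignment agrees with a brute-force Hamming scan", {
  set.seed(31L)
  entries <- unique(randomDna(1500L, 11L))[seq_len(1024L)]
  wells <- sprintf("W%04d", seq_along(entries))
  wl <- new("Whitelist",
    entries = entries, ampBatchIds = rep("AB1", length(entries)),
    wellIds = wells
  )
  observed <- c(
    sample(entries, 120L, replace = TRUE), # members
    vapply(sample(entries, 60L), function(e) {
      i <- sample(11L, 1L)
      substr(e, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
        substr(e, i, i)), 1L)
      e
    }, character(1L), USE.NAMES = FALSE), # singly mutated
    randomDna(60L, 11L) # random
  )
  for (maxDist in c(0L, 1L)) {
    got <- assignBarcodes(observed, wl, maxDist = maxDist)$well_id
    want <- bruteAssign(observed, entries, wells, maxDist)
    expect_identical(got, want)
  }
})

test_that("UMI collapse follows the exact and directional rules", {
  expect_identical(collapseUmis(character(), "exact"), 0L)
  expect_identical(collapseUmis(character(), "directional"), 0L)

  # four UMIs at pairwise distance >= 2 stay four in both modes
  umis <- c("AAAAAAAA", "CCCCAAAA", "AAAATTTT", "GGGGAAAA")
  dists <- outer(seq_along(umis), seq_along(umis), Vectorize(function(i, j) {
    sum(charMat(umis)[i, ] != charMat(umis)[j, ])
  }))
  expect_true(all(dists[upper.tri(dists)] >= 2L))
  expect_identical(collapseUmis(umis, "exact"), 4L)
  expect_identical(collapseUmis(umis, "directional"), 4L)

  # a dominant UMI absorbs its distance-1 satellite: 9 >= 2*1 - 1
  skewed <- c(rep("AAAAAAAA", 9L), "AAAAAAAC")
  expect_identical(collapseUmis(skewed, "exact"), 2L)
  expect_identical(collapseUmis(skewed, "directional"), 1L)

  # 5 vs 1 merges too (5 >= 2*1 - 1)
  expect_identical(
    collapseUmis(c(rep("AAAAAAAA", 5L), "AAAAAAAT"), "directional"), 1L
  )

  # two balanced UMIs do NOT merge: 2 >= 2*2 - 1 is false
  expect_identical(
    collapseUmis(rep(c("AAAAAAAA", "AAAAAAAT"), each = 2L), "directional"),
    2L
  )

  # merging is transitive down a count gradient: 4 -> 2 -> 1 chain
  chain <- c(
    rep("AAAAAAAA", 4L), rep("AAAAAAAT", 2L), "AAAAAATT"
  )
  expect_identical(collapseUmis(chain, "directional"), 1L)

  expect_error(collapseUmis(c("AAAA", "AAAAAAAA")), "same length")
})

test_that("directional counts never exceed exact counts", {
  set.seed(32L)
  for (rep in 1:20) {
    umis <- sample(
      c(randomDna(5L, 8L), "AAAAAAAA", "AAAAAAAT", "AAAAAATT"),
      sample(1:40, 1L),
      replace = TRUE
    )
    expect_lte(
      collapseUmis(umis, "directional"), collapseUmis(umis, "exact")
    )
  }
})

.makeAlignments <- function(readIds, mapped = TRUE, feature = "G1",
                            mapq = 255L, ambiguous = FALSE) {
  data.frame(
    read_id = readIds, mapped = mapped, feature_id = feature,
    mapq = mapq, ambiguous = ambiguous, stringsAsFactors = FALSE
  )
}

test_that("counting collapses UMIs per well x feature and excludes by rule", {
  wl <- buildWhitelist(tinyMetadata())
  wellBc <- whitelistEntries(wl)[1L]
  lab <- function(i, umi, bc = wellBc) {
    sprintf("r%d:%s:%s:%s", i, substr(bc, 1L, 4L), substr(bc, 5L, 11L), umi)
  }
  aln <- rbind(
    .makeAlignments(lab(1L, "AAAAAAAA")),
    .makeAlignments(lab(2L, "AAAAAAAA")),
    .makeAlignments(lab(3L, "CCCCCCCC")),
    .makeAlignments(lab(4L, "GGGGGGGG"), ambiguous = TRUE,
      feature = NA_character_),
    .makeAlignments(lab(5L, "GGGGGGGG"), mapped = FALSE,
      feature = NA_character_)
  )
  counts <- countReads(aln, wl, features = c("G1", "G2"))
  m <- SummarizedExperiment::assay(counts, "counts")
  # two distinct UMIs among the three counted same-well reads
  expect_identical(unname(m["G1", wellIds(wl)[1L]]), 2)
  expect_identical(sum(m), 2)
  st <- demuxStats(counts)
  expect_identical(st$ambiguous, 1L)
  expect_identical(st$unmapped, 1L)
  expect_identical(st$counted, 3L)
  # conservation identity over all exclusion classes
  expect_identical(
    st$n_input,
    st$counted + st$unmapped + st$ambiguous + st$no_feature +
      st$unknown_feature + st$unassigned_barcode + st$low_mapq
  )
  # matrix spans every whitelist well and every feature
  expect_identical(dim(m), c(2L, length(wl)))

  expect_error(
    countReads(.makeAlignments("nolabel"), wl, "G1"),
    "cannot parse barcode label.*nolabel"
  )
})

test_that("exact-mode totals equal the brute-force distinct-triple count", {
  set.seed(33L)
  md <- tinyMetadata(nAmp = 2L, wellsPerBatch = 3L)
  wl <- buildWhitelist(md)
  features <- sprintf("G%d", 1:8)
  n <- 800L
  bcIdx <- sample(length(wl), n, replace = TRUE)
  bc <- whitelistEntries(wl)[bcIdx]
  umi <- sample(randomDna(40L, 8L), n, replace = TRUE)
  feat <- sample(features, n, replace = TRUE)
  aln <- .makeAlignments(
    sprintf(
      "x%d:%s:%s:%s", seq_len(n), substr(bc, 1L, 4L),
      substr(bc, 5L, 11L), umi
    ),
    feature = feat
  )
  counts <- countReads(aln, wl, features)
  expect_identical(
    sum(SummarizedExperiment::assay(counts, "counts")),
    as.double(bruteTripleCount(wellIds(wl)[bcIdx], feat, umi))
  )

  # per-cell monotonicity of the directional collapse
  directional <- countReads(aln, wl, features, umiMode = "directional")
  expect_true(all(
    SummarizedExperiment::assay(directional, "counts") <=
      SummarizedExperiment::assay(counts, "counts")
  ))
})

test_that("SAM streams parse with gene tags, flags and MAPQ filtering", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:1000",
    "r1:ACGT:AACCGGT:AAAAAAAA\t0\tchr1\t10\t255\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII\tGX:Z:G1",
    "r2:ACGT:AACCGGT:CCCCCCCC\t0\tchr1\t20\t5\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII\tGX:Z:G1",
    "r3:ACGT:AACCGGT:GGGGGGGG\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r4:ACGT:AACCGGT:TTTTTTTT\t0\tchr1\t30\t255\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII\tGX:Z:G1;G2",
    "r5:ACGT:AACCGGT:AAAATTTT\t256\tchr1\t10\t255\t10M\t*\t0\t0\t*\t*\tGX:Z:G1"
  ), sam)
  aln <- readSamAlignments(sam)
  expect_identical(nrow(aln), 4L) # the secondary record is dropped
  expect_identical(aln$mapped, c(TRUE, TRUE, FALSE, TRUE))
  expect_identical(aln$feature_id[1L], "G1")
  expect_true(aln$ambiguous[4L]) # multi-gene tag
  expect_true(is.na(aln$feature_id[4L]))

  wl <- buildWhitelist(tinyMetadata())
  counts <- countReads(aln, wl, c("G1", "G2"), mapqMin = 10L)
  st <- demuxStats(counts)
  expect_identical(st$low_mapq, 1L)
  expect_identical(st$counted, 1L)
})

test_that("exon-overlap annotation resolves unique, ambiguous and none", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "t", "exon", "1", "100", ".", "+", ".",
      "gene_id \"G1\"; transcript_id \"G1\";", sep = "\t"),
    paste("chr1", "t", "exon", "80", "200", ".", "+", ".",
      "gene_id \"G2\"; transcript_id \"G2\";", sep = "\t")
  ), gtf)
  aln <- data.frame(
    read_id = c("a", "b", "c", "d"),
    mapped = c(TRUE, TRUE, TRUE, TRUE),
    rname = "chr1", pos = c(10L, 85L, 300L, 10L),
    strand = c("+", "+", "+", "-"), cigar = "10M",
    mapq = 255L, feature_id = NA_character_, ambiguous = FALSE,
    stringsAsFactors = FALSE
  )
  ann <- annotateAlignments(aln, gtf)
  expect_identical(ann$feature_id[1L], "G1")
  expect_true(ann$ambiguous[2L]) # overlaps exons of G1 and G2
  expect_true(is.na(ann$feature_id[3L])) # no exon under the read
  expect_true(is.na(ann$feature_id[4L])) # antisense, strand-aware default
  unstranded <- annotateAlignments(aln, gtf, strandAware = FALSE)
  expect_identical(unstranded$feature_id[4L], "G1")
})

test_that("count matrices round-trip through the exchange directory", {
  set.seed(34L)
  wl <- buildWhitelist(tinyMetadata())
  bc <- sample(whitelistEntries(wl), 50L, replace = TRUE)
  aln <- .makeAlignments(
    sprintf(
      "y%d:%s:%s:%s", 1:50, substr(bc, 1L, 4L), substr(bc, 5L, 11L),
      randomDna(50L, 8L)
    ),
    feature = sample(c("G1", "G2", "ERCC-00001"), 50L, replace = TRUE)
  )
  counts <- countReads(aln, wl, c("G1", "G2", "ERCC-00001"))
  dir <- tempfile()
  writeCountMatrix(counts, dir)
  expect_true(all(file.exists(file.path(
    dir, c("matrix.mtx", "features.tsv", "barcodes.tsv", "stats.json",
      "counts.tsv")
  ))))
  back <- readCountMatrix(dir)
  expect_identical(
    as.matrix(SummarizedExperiment::assay(back, "counts")),
    as.matrix(SummarizedExperiment::assay(counts, "counts"))
  )
  expect_identical(demuxStats(back)$counted, demuxStats(counts)$counted)
})
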