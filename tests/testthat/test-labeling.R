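test_that("barcodes are sliced at the declared layout offsets", {
  cdna <- randomDna(1L, 66L)
  r1 <- makeShortReadQ(paste0("TGA", "ACGT", cdna, "TT"), strrep("I", 75L))
  r2 <- makeShortReadQ(paste0("AACCGGT", "ACGTACGT"), strrep("I", 15L))
  labeled <- labelReads(r1, r2)

  expect_identical(labeled$disposition, "kept")
  expect_identical(labeled$pb, "ACGT")
  expect_identical(labeled$cb, "AACCGGT")
  expect_identical(labeled$umi, "ACGTACGT")
  expect_identical(labeled$cdna_seq, cdna) # the 66 nt middle slice
  expect_identical(nchar(labeled$cdna_seq), 66L)
  # barcodes end up in the read name, colon-delimited
  expect_identical(labeled$labeled_id, paste(
    labeled$read_id, "ACGT", "AACCGGT", "ACGTACGT",
    sep = ":"
  ))
})

test_that("short mates and low-quality barcodes are discarded with reasons", {
  cdna <- randomDna(1L, 66L)
  r1 <- makeShortReadQ(
    rep(paste0("TGA", "ACGT", cdna, "TT"), 3L),
    c(
      strrep("I", 75L),
      strrep("I", 75L),
      paste0("III", "##II", strrep("I", 68L)) # two PB bases at Phred 2
    )
  )
  r2 <- makeShortReadQ(
    c(substr("AACCGGTACGTACGT", 1L, 14L), rep("AACCGGTACGTACGT", 2L)),
    c(strrep("I", 14L), strrep("#", 15L), strrep("I", 15L))
  )
  labeled <- labelReads(r1, r2, minBarcodeQual = 20L)
  expect_identical(labeled$disposition, c(
    "discarded:too_short", # R2 of 14 nt cannot hold CB + UMI
    "discarded:low_quality_barcode", # all 15 R2 barcode bases at Phred 2
    "discarded:low_quality_barcode" # 2 low PB bases exceed the tolerance of 1
  ))

  # exactly one low-quality barcode base is tolerated by default
  r1b <- makeShortReadQ(
    paste0("TGA", "ACGT", cdna, "TT"),
    paste0("III", "#III", strrep("I", 68L))
  )
  r2b <- makeShortReadQ("AACCGGTACGTACGT", strrep("I", 15L))
  expect_identical(labelReads(r1b, r2b)$disposition, "kept")

  st <- labelingStats(labeled)
  expect_identical(st$n_input, 3L)
  expect_identical(st$n_kept, 0L)
  expect_identical(
    st$n_input,
    st$n_kept + sum(unlist(st$n_discarded_by_reason))
  )
})

test_that("mismatched mate ids are a pairing error", {
  r1 <- makeShortReadQ(
    paste0("TGA", "ACGT", randomDna(1L, 66L), "TT"), strrep("I", 75L),
    ids = "readA/1"
  )
  r2 <- makeShortReadQ("AACCGGTACGTACGT", strrep("I", 15L), ids = "readB/2")
  expect_error(labelReads(r1, r2), "mate ids disagree")

  # a /1 vs /2 suffix is not a mismatch
  r2ok <- makeShortReadQ("AACCGGTACGTACGT", strrep("I", 15L), ids = "readA/2")
  expect_identical(labelReads(r1, r2ok)$disposition, "kept")
})

test_that("labeling conserves reads and stays reversible", {
  set.seed(7L)
  n <- 400L
  pairs <- randomReadPairs(n, highQual = FALSE)
  labeled <- labelReads(pairs$r1, pairs$r2, minBarcodeQual = 20L)

  st <- labelingStats(labeled)
  expect_identical(
    st$n_input, st$n_kept + sum(unlist(st$n_discarded_by_reason))
  )

  kept <- labeled[labeled$disposition == "kept", ]
  # original R1 (minus the trimmed right adapter) and R2 reconstruct
  idx <- match(kept$read_id, as.character(ShortRead::id(pairs$r1)))
  origR1 <- as.character(ShortRead::sread(pairs$r1))[idx]
  origR2 <- as.character(ShortRead::sread(pairs$r2))[idx]
  expect_identical(
    paste0(kept$la_seq, kept$pb, kept$cdna_seq),
    substr(origR1, 1L, nchar(origR1) - 2L)
  )
  expect_identical(paste0(kept$cb, kept$umi), origR2)
})

test_that("optional poly-A trimming removes only long terminal runs", {
  cdna <- paste0(randomDna(1L, 49L), "C", strrep("A", 16L))
  r1 <- makeShortReadQ(paste0("TGA", "ACGT", cdna, "TT"), strrep("I", 75L))
  r2 <- makeShortReadQ("AACCGGTACGTACGT", strrep("I", 15L))
  trimmed <- labelReads(r1, r2, trimPolyA = TRUE)
  expect_identical(nchar(trimmed$cdna_seq), 50L)
  expect_identical(nchar(trimmed$cdna_qual), 50L)
  # off by default
  expect_identical(nchar(labelReads(r1, r2)$cdna_seq), 66L)
})

test_that("FASTQ splitting yields exact chunk sizes and reconcatenates", {
  recs <- function(n) {
    list(
      ids = sprintf("r%02d", seq_len(n)), seqs = randomDna(n, 20L),
      quals = randomQuals(n, 20L)
    )
  }
  five <- recs(5L)
  fq <- writeFastqLines(
    five$ids, five$seqs, five$quals, tempfile(fileext = ".fastq")
  )
  chunks <- splitFastq(fq, tempfile(), chunkSize = 2L, compress = FALSE)
  expect_length(chunks, 3L)
  sizes <- vapply(chunks, function(p) length(readLines(p)) / 4L, numeric(1L))
  expect_identical(unname(sizes), c(2, 2, 1))
  expect_match(basename(chunks[1L]), "part001\\.fastq$")
  expect_identical(
    unlist(lapply(chunks, readLines), use.names = FALSE), readLines(fq)
  )

  # empty stream: zero chunks
  empty <- writeFastqLines(
    character(), character(), character(), tempfile(fileext = ".fastq")
  )
  expect_length(splitFastq(empty, tempfile(), chunkSize = 2L), 0L)
})

test_that("split/concatenate is the identity for arbitrary chunk sizes", {
  set.seed(11L)
  n <- 237L
  ids <- sprintf("read%04d", seq_len(n))
  seqs <- randomDna(n, 30L)
  quals <- randomQuals(n, 30L)
  fq <- writeFastqLines(ids, seqs, quals, tempfile(fileext = ".fastq.gz"))
  original <- readLines(gzfile(fq))
  for (chunkSize in c(1L, 7L, 64L, 300L)) {
    chunks <- splitFastq(fq, tempfile(), chunkSize = chunkSize)
    expect_identical(
      unlist(lapply(chunks, function(p) readLines(gzfile(p)))),
      original
    )
    nFull <- length(chunks) - 1L
    if (nFull > 0L) {
      fullSizes <- vapply(
        chunks[seq_len(nFull)],
        function(p) length(readLines(gzfile(p))) / 4L, numeric(1L)
      )
      expect_true(all(fullSizes == chunkSize))
    }
  }
})

test_that("a truncated FASTQ record is reported with its byte offset", {
  lines <- c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT")
  path <- tempfile(fileext = ".fastq")
  writeLines(lines, path)
  err <- expect_error(
    splitFastq(path, tempfile(), chunkSize = 10L), "truncated FASTQ record"
  )
  # the partial record starts after the 16 bytes of the first record
  expect_match(conditionMessage(err), "byte offset 16")
})
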