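test_that("conversion concatenates PB, CB and UMI onto read 1", {
  lab <- randomLabeledTable(1L)
  lab$pb <- "ACGT"
  lab$cb <- "AACCGGT"
  lab$umi <- "TTTTAAAA"
  conv <- convertReads(lab)
  expect_identical(conv$r1_seq, "ACGTAACCGGTTTTTAAAA")
  expect_identical(nchar(conv$r1_seq), 19L)
  # cDNA passes through byte-identical
  expect_identical(conv$r2_seq, lab$cdna_seq)
  expect_identical(conv$r2_qual, lab$cdna_qual)
  expect_identical(conv$read_id, lab$read_id)
})

test_that("discarded and malformed labeled reads violate the precondition", {
  lab <- randomLabeledTable(2L)
  lab$disposition[2L] <- "discarded:too_short"
  expect_error(convertReads(lab), "discarded")
  expect_identical(nrow(convertReads(lab, onDiscarded = "drop")), 1L)

  bad <- randomLabeledTable(1L)
  bad$umi <- ""
  expect_error(convertReads(bad), "empty barcode")
})

test_that("per-base (base, quality) pairs survive conversion and inversion", {
  set.seed(21L)
  lab <- randomLabeledTable(500L)
  conv <- convertReads(lab)
  # qualities follow the sequence concatenation order PB, CB, UMI
  expect_identical(
    conv$r1_qual, paste0(lab$pb_qual, lab$cb_qual, lab$umi_qual)
  )
  pairs <- function(seqs, quals) {
    paste(
      unlist(strsplit(seqs, "")), unlist(strsplit(quals, "")),
      sep = "/"
    )
  }
  expect_identical(
    sort(pairs(conv$r1_seq, conv$r1_qual)),
    sort(pairs(
      paste0(lab$pb, lab$cb, lab$umi),
      paste0(lab$pb_qual, lab$cb_qual, lab$umi_qual)
    ))
  )

  # inversion reconstructs the labeled read exactly
  back <- invertConvertedReads(conv)
  for (col in c(
    "pb", "pb_qual", "cb", "cb_qual", "umi", "umi_qual",
    "cdna_seq", "cdna_qual"
  )) {
    expect_identical(back[[col]], lab[[col]])
  }
})

test_that("converted FASTQ files follow the 10X naming and content layout", {
  set.seed(22L)
  lab <- randomLabeledTable(20L)
  out <- writeConvertedFastq(convertReads(lab), tempfile(), sample = "s1")
  expect_match(basename(out["r1"]), "^s1_S1_L001_R1_001\\.fastq\\.gz$")
  fq1 <- ShortRead::readFastq(out["r1"])
  fq2 <- ShortRead::readFastq(out["r2"])
  expect_identical(
    as.character(ShortRead::sread(fq1)), paste0(lab$pb, lab$cb, lab$umi)
  )
  expect_identical(as.character(ShortRead::sread(fq2)), lab$cdna_seq)
})

test_that("the whitelist enumerates pool x well composites within batches", {
  md <- tinyMetadata(nAmp = 2L, wellsPerBatch = 3L)
  wl <- buildWhitelist(md)
  expect_identical(length(wl), 6L) # 2 batches x 3 wells
  expect_true(all(nchar(whitelistEntries(wl)) == 11L))

  # entry = pool barcode || cell barcode, mapped to its well
  ab <- ampBatches(md)
  ws <- wellsCells(md)
  expect_identical(
    whitelistEntries(wl),
    paste0(ab$pool_barcode[match(ws$amp_batch_id, ab$amp_batch_id)],
      ws$cell_barcode
    )
  )
  expect_identical(wellIds(wl), ws$well_id)

  # zero wells: empty whitelist and empty file
  empty <- experimentMetadata(
    seqBatches(md), ampBatches(md), wellsCells(md)[0L, ]
  )
  wl0 <- buildWhitelist(empty)
  expect_identical(length(wl0), 0L)
  f <- writeWhitelist(wl0, tempfile())
  expect_identical(file.size(f), 0)
})

test_that("a composite collision aborts naming both wells", {
  md <- tinyMetadata(nAmp = 2L, wellsPerBatch = 2L)
  ab <- ampBatches(md)
  ws <- wellsCells(md)
  # both batches share a pool barcode and W1/W3 share a cell barcode,
  # so the two wells collapse onto one 11-mer
  ab$pool_barcode <- c("ACGT", "ACGT")
  ws$cell_barcode[ws$well_id %in% c("W1", "W3")] <- "AAACCCG"
  expect_error(
    buildWhitelist(experimentMetadata(seqBatches(md), ab, ws)),
    "W1 and W3"
  )
})

test_that("whitelist size equals the sum of per-batch well counts", {
  set.seed(23L)
  for (rep in 1:5) {
    nAmp <- sample(1:4, 1L)
    pbs <- unique(randomDna(nAmp * 3L, 4L))[seq_len(nAmp)]
    wellsPerBatch <- sample(1:6, nAmp, replace = TRUE)
    wells <- do.call(rbind, lapply(seq_len(nAmp), function(i) {
      cbs <- unique(randomDna(wellsPerBatch[i] * 3L, 7L))[
        seq_len(wellsPerBatch[i])
      ]
      data.frame(
        well_id = sprintf("A%dW%d", i, seq_along(cbs)),
        amp_batch_id = sprintf("AB%d", i), cell_barcode = cbs
      )
    }))
    md <- experimentMetadata(
      data.frame(
        batch_id = "SB1", run_name = "", r1_path = "", r2_path = "",
        notes = ""
      ),
      data.frame(
        amp_batch_id = sprintf("AB%d", seq_len(nAmp)),
        seq_batch_id = "SB1", pool_barcode = pbs
      ),
      wells
    )
    expect_identical(length(buildWhitelist(md)), sum(wellsPerBatch))
  }
})

test_that("whitelist files hold one uppercase entry per line, no header", {
  wl <- buildWhitelist(tinyMetadata())
  path <- writeWhitelist(wl, tempfile())
  lines <- readLines(path)
  expect_identical(lines, whitelistEntries(wl))
  expect_false(any(grepl("[^ACGT]", lines)))
  back <- readWhitelist(path)
  expect_identical(whitelistEntries(back), whitelistEntries(wl))
  # with metadata, the well mapping is restored
  back2 <- readWhitelist(path, md = tinyMetadata())
  expect_identical(wellIds(back2), wellIds(wl))
})

test_that("aligner geometry follows the layout and renders 1-based flags", {
  p <- starsoloParams()
  expect_identical(p@cbLen, 11L) # 4 nt pool + 7 nt cell barcode
  expect_identical(p@umiStart, 12L)
  expect_identical(p@umiLen, 8L)
  expect_identical(p@cbStart + p@cbLen, p@umiStart)
  expect_identical(p@umiStart + p@umiLen - 1L, 19L)

  flags <- renderStarsoloParams(p)
  expect_match(flags, "CB_UMI_Simple", fixed = TRUE)
  expect_match(flags, "--soloCBstart 1 --soloCBlen 11", fixed = TRUE)
  expect_match(flags, "--soloUMIstart 12 --soloUMIlen 8", fixed = TRUE)
  expect_match(flags, "--soloFeatures Gene GeneFull SJ Velocyto",
    fixed = TRUE
  )

  # a longer UMI shifts the flags and re-checks the composite invariant
  p10 <- starsoloParams(marsLayout(umiLen = 10L))
  expect_identical(p10@umiLen, 10L)
  expect_identical(p10@umiStart, 12L)
  expect_match(renderStarsoloParams(p10), "--soloUMIlen 10", fixed = TRUE)
})
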