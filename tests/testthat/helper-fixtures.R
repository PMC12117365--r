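## Shared fixtures and independent oracles. Everything is generated in
## code at test time; no binary fixtures live in the repository.

makeShortReadQ <- function(seqs, quals, ids = sprintf("r%03d", seq_along(seqs))) {
  ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(seqs),
    quality = Biostrings::BStringSet(quals),
    id = Biostrings::BStringSet(ids)
  )
}

writeFastqLines <- function(ids, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(ids)) {
    writeLines(
      as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con, sep = "\n"
    )
  }
  path
}

randomQuals <- function(n, len, lo = 25L, hi = 40L) {
  vapply(seq_len(n), function(i) {
    intToUtf8(33L + sample(lo:hi, len, replace = TRUE))
  }, character(1L))
}

## A synthetic MARS-seq read pair set with known barcodes: R1 = LA + PB +
## cDNA + RA, R2 = CB + UMI (the standard layout).
randomReadPairs <- function(n, la = "TGA", ra = "TT", cdnaLen = 66L,
                            highQual = TRUE) {
  pb <- randomDna(n, 4L)
  cb <- randomDna(n, 7L)
  umi <- randomDna(n, 8L)
  cdna <- randomDna(n, cdnaLen)
  q1 <- if (highQual) strrep("I", nchar(la) + 4L + cdnaLen + nchar(ra)) else
    randomQuals(n, nchar(la) + 4L + cdnaLen + nchar(ra))
  q2 <- if (highQual) strrep("I", 15L) else randomQuals(n, 15L)
  list(
    pb = pb, cb = cb, umi = umi, cdna = cdna,
    r1 = makeShortReadQ(paste0(la, pb, cdna, ra), rep_len(q1, n)),
    r2 = makeShortReadQ(paste0(cb, umi), rep_len(q2, n))
  )
}

## Build a synthetic labeled-read table directly (bypasses FASTQ I/O) for
## conversion round-trip properties.
randomLabeledTable <- function(n, cdnaLen = 66L) {
  S4Vectors::DataFrame(
    read_id = sprintf("r%05d", seq_len(n)),
    labeled_id = NA_character_,
    pb = randomDna(n, 4L), pb_qual = randomQuals(n, 4L),
    cb = randomDna(n, 7L), cb_qual = randomQuals(n, 7L),
    umi = randomDna(n, 8L), umi_qual = randomQuals(n, 8L),
    la_seq = rep("TGA", n), la_qual = rep("III", n),
    cdna_seq = randomDna(n, cdnaLen), cdna_qual = randomQuals(n, cdnaLen),
    disposition = rep("kept", n)
  )
}

charMat <- function(x) do.call(rbind, strsplit(x, "", fixed = TRUE))

## Independent brute-force barcode assignment: full Hamming scan over the
## whitelist, no shared code with assignBarcodes().
bruteAssign <- function(observed, entries, wells, maxDist) {
  entryMat <- charMat(entries)
  vapply(observed, function(bc) {
    d <- rowSums(entryMat != matrix(
      strsplit(bc, "")[[1L]], nrow(entryMat), ncol(entryMat), byrow = TRUE
    ))
    if (any(d == 0L)) return(wells[which(d == 0L)[1L]])
    if (maxDist >= 1L && sum(d == 1L) == 1L) return(wells[which(d == 1L)])
    NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

## Independent distinct-triple oracle for exact-mode counting.
bruteTripleCount <- function(well, feature, umi) {
  nrow(unique(data.frame(well, feature, umi, stringsAsFactors = FALSE)))
}

## Create an XLSX workbook from named data.frames using the system
## python's openpyxl (sheet order follows the list order).
makeWorkbook <- function(path, sheets) {
  tsvs <- vapply(names(sheets), function(nm) {
    f <- tempfile(fileext = ".tsv")
    utils::write.table(sheets[[nm]], f,
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    f
  }, character(1L))
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import openpyxl, sys, csv",
    "wb = openpyxl.Workbook(); wb.remove(wb.active)",
    "for arg in sys.argv[2:]:",
    "    name, p = arg.split('=', 1)",
    "    ws = wb.create_sheet(name)",
    "    with open(p) as fh:",
    "        for row in csv.reader(fh, delimiter='\\t'):",
    "            ws.append(row)",
    "wb.save(sys.argv[1])"
  ), script)
  status <- system2("python", c(
    script, path, paste0(names(sheets), "=", tsvs)
  ), stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  path
}

## A tiny consistent metadata object with distinct barcode geometry.
tinyMetadata <- function(nAmp = 2L, wellsPerBatch = 3L) {
  pbs <- c("ACGT", "TTGG", "CCAA", "GGTC")[seq_len(nAmp)]
  cbs <- c("AACCGGT", "CCAATTG", "GGTTACA", "TTGGCAC")[seq_len(wellsPerBatch)]
  experimentMetadata(
    seqBatches = data.frame(
      batch_id = "SB1", run_name = "t", r1_path = "R1.fq",
      r2_path = "R2.fq", notes = ""
    ),
    ampBatches = data.frame(
      amp_batch_id = sprintf("AB%d", seq_len(nAmp)),
      seq_batch_id = "SB1", pool_barcode = pbs
    ),
    wells = data.frame(
      well_id = sprintf("W%d", seq_len(nAmp * wellsPerBatch)),
      amp_batch_id = rep(sprintf("AB%d", seq_len(nAmp)),
        each = wellsPerBatch
      ),
      cell_barcode = rep(cbs, times = nAmp)
    )
  )
}
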