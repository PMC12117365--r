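#' @importFrom ShortRead readFastq writeFastq ShortReadQ sread
NULL

.asShortReadQ <- function(x, what) {
  if (is(x, "ShortReadQ")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(what, " FASTQ not found: ", x)
    return(ShortRead::readFastq(x))
  }
  stop(what, " must be a ShortReadQ or a FASTQ path")
}

.qualStrings <- function(fq) {
  # quality(ShortReadQ) is a FastqQuality; quality() again unwraps the
  # underlying BStringSet
  as.character(Biostrings::quality(Biostrings::quality(fq)))
}

#' Extract barcode labels from MARS-seq read pairs
#'
#' Slices every read pair according to the layout: the pool barcode sits
#' after the left adapter on read 1, the cDNA follows it, and the final
#' `raLen` bases of read 1 are always trimmed as the right adapter; read 2
#' carries the cell barcode then the UMI. The three barcodes are recorded
#' in the labeled read name as `<orig_id><delim>PB<delim>CB<delim>UMI`, the
#' convention the demultiplexer parses back out of aligned reads.
#'
#' Pairs are discarded (never dropped silently) with a reason:
#' `too_short` when either mate is shorter than the layout demands, or
#' `low_quality_barcode` when more than `maxLowQualBases` of the barcode
#' bases (pool + cell barcode + UMI; 19 under the default layout) fall
#' below `minBarcodeQual`. Barcode integrity is what demultiplexing hinges
#' on; cDNA quality is left to the aligner.
#'
#' @param r1,r2 FASTQ paths (optionally gzipped) or `ShortReadQ` objects;
#'   mates must be in the same order and their ids must agree up to a
#'   `/1`/`/2` suffix or comment.
#' @param layout a [ReadLayout-class].
#' @param minBarcodeQual Phred threshold below which a barcode base counts
#'   as low-quality (default 20).
#' @param maxLowQualBases how many low-quality barcode bases are tolerated
#'   before the pair is discarded (default 1).
#' @param trimPolyA trim a trailing run of >= 10 A's from the cDNA
#'   (default off).
#' @param delim label delimiter in read names (default `":"`; some SAM
#'   consumers tokenize names differently).
#' @return A [S4Vectors::DataFrame] with one row per input pair: `read_id`,
#'   `labeled_id`, `pb`, `cb`, `umi`, their quality strings, `la_seq` /
#'   `la_qual` (the trimmed left adapter, kept so labeling stays
#'   reversible), `cdna_seq`, `cdna_qual` and `disposition`
#'   (`"kept"` or `"discarded:<reason>"`). Labeling statistics are in
#'   `labelingStats()` of the result.
#' @seealso [writeLabeledFastq()], [convertReads()], [labelingStats()]
#' @export
labelReads <- function(r1, r2, layout = marsLayout(),
                       minBarcodeQual = 20L, maxLowQualBases = 1L,
                       trimPolyA = FALSE, delim = ":") {
  fq1 <- .asShortReadQ(r1, "r1")
  fq2 <- .asShortReadQ(r2, "r2")
  if (length(fq1) != length(fq2)) {
    stop(
      "mate files differ in record count: ", length(fq1), " vs ",
      length(fq2)
    )
  }

  ids1 <- as.character(ShortRead::id(fq1))
  ids2 <- as.character(ShortRead::id(fq2))
  key1 <- .pairKey(ids1)
  key2 <- .pairKey(ids2)
  bad <- which(key1 != key2)
  if (length(bad)) {
    stop(
      "malformed FASTQ pairing: mate ids disagree at record ", bad[1L],
      " (\"", ids1[bad[1L]], "\" vs \"", ids2[bad[1L]], "\")"
    )
  }

  s1 <- as.character(ShortRead::sread(fq1))
  s2 <- as.character(ShortRead::sread(fq2))
  q1 <- .qualStrings(fq1)
  q2 <- .qualStrings(fq2)
  w1 <- nchar(s1)
  w2 <- nchar(s2)
  n <- length(s1)

  la <- layout@laLen
  pb <- layout@pbLen
  ra <- layout@raLen
  cb <- layout@cbLen
  umi <- layout@umiLen

  tooShort <- w1 < minRead1Length(layout) | w2 < cb + umi

  laSeq <- ifelse(tooShort, "", substr(s1, 1L, la))
  laQual <- ifelse(tooShort, "", substr(q1, 1L, la))
  pbSeq <- ifelse(tooShort, "", substr(s1, la + 1L, la + pb))
  pbQual <- ifelse(tooShort, "", substr(q1, la + 1L, la + pb))
  cdnaSeq <- ifelse(tooShort, "", substr(s1, la + pb + 1L, w1 - ra))
  cdnaQual <- ifelse(tooShort, "", substr(q1, la + pb + 1L, w1 - ra))
  cbSeq <- ifelse(tooShort, "", substr(s2, 1L, cb))
  cbQual <- ifelse(tooShort, "", substr(q2, 1L, cb))
  umiSeq <- ifelse(tooShort, "", substr(s2, cb + 1L, cb + umi))
  umiQual <- ifelse(tooShort, "", substr(q2, cb + 1L, cb + umi))

  # count barcode bases under the Phred threshold (PB + CB + UMI)
  bcQual <- paste0(pbQual, cbQual, umiQual)
  nLow <- vapply(bcQual, function(qq) {
    if (qq == "") return(0L)
    sum(utf8ToInt(qq) - 33L < minBarcodeQual)
  }, integer(1L), USE.NAMES = FALSE)
  lowQual <- !tooShort & nLow > maxLowQualBases

  if (trimPolyA) {
    hit <- !tooShort & grepl("A{10,}$", cdnaSeq)
    if (any(hit)) {
      keepLen <- nchar(sub("A{10,}$", "", cdnaSeq[hit]))
      cdnaSeq[hit] <- substr(cdnaSeq[hit], 1L, keepLen)
      cdnaQual[hit] <- substr(cdnaQual[hit], 1L, keepLen)
    }
  }

  disposition <- rep("kept", n)
  disposition[lowQual] <- "discarded:low_quality_barcode"
  disposition[tooShort] <- "discarded:too_short"

  kept <- disposition == "kept"
  labeledId <- rep(NA_character_, n)
  labeledId[kept] <- paste(
    key1[kept], pbSeq[kept], cbSeq[kept], umiSeq[kept],
    sep = delim
  )

  out <- S4Vectors::DataFrame(
    read_id = key1, labeled_id = labeledId,
    pb = pbSeq, pb_qual = pbQual,
    cb = cbSeq, cb_qual = cbQual,
    umi = umiSeq, umi_qual = umiQual,
    la_seq = laSeq, la_qual = laQual,
    cdna_seq = cdnaSeq, cdna_qual = cdnaQual,
    disposition = disposition
  )
  reasons <- sub(
    "^discarded:", "", unique(disposition[disposition != "kept"])
  )
  byReason <- vapply(
    reasons,
    function(r) sum(disposition == paste0("discarded:", r)),
    integer(1L)
  )
  S4Vectors::metadata(out)$stats <- list(
    n_input = n, n_kept = sum(kept),
    n_discarded_by_reason = as.list(byReason)
  )
  S4Vectors::metadata(out)$layout <- layout
  S4Vectors::metadata(out)$delim <- delim
  out
}

#' @describeIn labelReads Labeling statistics of a labeled-read table:
#'   a list with `n_input`, `n_kept` and `n_discarded_by_reason`, which
#'   always satisfy `n_input = n_kept + sum(n_discarded_by_reason)`.
#' @param labeled the return value of `labelReads()`.
#' @export
labelingStats <- function(labeled) {
  S4Vectors::metadata(labeled)$stats
}

#' Write labeled cDNA reads as FASTQ
#'
#' Emits the kept reads' cDNA with the barcode-labeled names, the
#' single-end stream a conventional (non-velocity) aligner consumes.
#'
#' @param labeled the return value of [labelReads()].
#' @param path output FASTQ path; gzipped when it ends in `.gz`.
#' @return Invisibly, the number of records written.
#' @export
writeLabeledFastq <- function(labeled, path) {
  kept <- labeled[labeled$disposition == "kept", ]
  fq <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(kept$cdna_seq),
    quality = Biostrings::BStringSet(kept$cdna_qual),
    id = Biostrings::BStringSet(kept$labeled_id)
  )
  ShortRead::writeFastq(
    fq, path, mode = "w", compress = grepl("\\.gz$", path)
  )
  invisible(nrow(kept))
}

#' Split a FASTQ stream into bounded chunks
#'
#' Streams a FASTQ file into chunks of at most `chunkSize` records so that
#' downstream aligners with per-file memory restrictions can work through
#' them; every chunk except possibly the last holds exactly `chunkSize`
#' records and concatenating the chunks reproduces the input record
#' sequence. Records are passed through byte-for-byte, never re-parsed.
#' The default chunk size is 4 000 000 reads per file.
#'
#' @param path input FASTQ, gzipped or plain.
#' @param outPrefix output prefix; chunks are named
#'   `<outPrefix>.partNNN.fastq[.gz]` with a zero-padded index from 001.
#' @param chunkSize records per chunk (default 4e6).
#' @param compress gzip the chunks (default `TRUE`).
#' @return Character vector of chunk paths (empty for an empty input).
#' @export
splitFastq <- function(path, outPrefix, chunkSize = 4000000L,
                       compress = TRUE) {
  chunkSize <- as.integer(chunkSize)
  if (is.na(chunkSize) || chunkSize < 1L) stop("chunkSize must be >= 1")
  con <- if (grepl("\\.gz$", path)) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
  on.exit(close(con), add = TRUE)

  suffix <- if (compress) ".fastq.gz" else ".fastq"
  chunkLines <- 4L * chunkSize
  blockLines <- min(chunkLines, 400000L)
  buffer <- character(0L)
  bytesRead <- 0L
  chunkPaths <- character(0L)

  flush <- function(lines) {
    idx <- length(chunkPaths) + 1L
    out <- sprintf("%s.part%03d%s", outPrefix, idx, suffix)
    ocon <- if (compress) gzfile(out, "wb") else file(out, "wb")
    writeLines(lines, ocon, sep = "\n")
    close(ocon)
    chunkPaths[idx] <<- out
  }

  repeat {
    block <- readLines(con, n = blockLines)
    if (length(block) == 0L) break
    bytesRead <- bytesRead + sum(nchar(block, type = "bytes") + 1L)
    buffer <- c(buffer, block)
    while (length(buffer) >= chunkLines) {
      flush(buffer[seq_len(chunkLines)])
      buffer <- buffer[-seq_len(chunkLines)]
    }
  }
  if (length(buffer) %% 4L != 0L) {
    partial <- length(buffer) %% 4L
    offset <- bytesRead -
      sum(nchar(utils::tail(buffer, partial), type = "bytes") + 1L)
    stop(
      "truncated FASTQ record: ", partial,
      " trailing line(s) at byte offset ", offset
    )
  }
  if (length(buffer)) flush(buffer)
  chunkPaths
}
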