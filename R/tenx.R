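#' Convert labeled MARS-seq reads to the 10X 3' layout
#'
#' Splice-aware CB/UMI counting aligners expect the droplet convention:
#' barcodes on read 1, cDNA on read 2. For each kept labeled pair the
#' converted read 1 is the concatenation pool barcode + cell barcode + UMI
#' (19 nt under the default layout) and read 2 is the adapter-free cDNA,
#' unchanged. Quality strings travel with their bases: the new read-1
#' qualities are the original pool-barcode, cell-barcode and UMI base
#' qualities in that order, so every (base, quality) pair is conserved.
#' The conversion is invertible given the layout — see
#' [invertConvertedReads()].
#'
#' @param labeled the return value of [labelReads()]. Discarded rows are a
#'   precondition violation: filter on `disposition == "kept"` first (or
#'   pass `onDiscarded = "drop"`).
#' @param onDiscarded `"error"` (default) or `"drop"`.
#' @return A [S4Vectors::DataFrame] with `read_id`, `r1_seq`, `r1_qual`,
#'   `r2_seq`, `r2_qual`.
#' @seealso [writeConvertedFastq()], [buildWhitelist()], [starsoloParams()]
#' @export
convertReads <- function(labeled, onDiscarded = c("error", "drop")) {
  onDiscarded <- match.arg(onDiscarded)
  discarded <- labeled$disposition != "kept"
  if (any(discarded)) {
    if (onDiscarded == "error") {
      stop(
        "cannot convert discarded read pair(s), e.g. \"",
        labeled$read_id[which(discarded)[1L]],
        "\"; filter on disposition == \"kept\" first"
      )
    }
    labeled <- labeled[!discarded, ]
  }
  if (nrow(labeled) &&
    any(labeled$pb == "" | labeled$cb == "" | labeled$umi == "")) {
    stop("malformed label: empty barcode segment in a kept read")
  }
  out <- S4Vectors::DataFrame(
    read_id = labeled$read_id,
    r1_seq = paste0(labeled$pb, labeled$cb, labeled$umi),
    r1_qual = paste0(labeled$pb_qual, labeled$cb_qual, labeled$umi_qual),
    r2_seq = labeled$cdna_seq,
    r2_qual = labeled$cdna_qual
  )
  S4Vectors::metadata(out)$layout <- S4Vectors::metadata(labeled)$layout
  out
}

#' Invert a 10X-style conversion
#'
#' Splits the converted read 1 back into pool barcode, cell barcode and
#' UMI at the layout's offsets and returns the segments with their quality
#' strings; together with the cDNA on read 2 this reconstructs the labeled
#' read exactly.
#'
#' @param converted the return value of [convertReads()].
#' @param layout the [ReadLayout-class] used for conversion.
#' @return A [S4Vectors::DataFrame] with `read_id`, `pb`, `cb`, `umi`,
#'   their quality strings, `cdna_seq` and `cdna_qual`.
#' @export
invertConvertedReads <- function(converted, layout = marsLayout()) {
  pb <- layout@pbLen
  cb <- layout@cbLen
  umi <- layout@umiLen
  if (nrow(converted) && any(nchar(converted$r1_seq) != pb + cb + umi)) {
    stop("converted read 1 length does not match the layout composite")
  }
  S4Vectors::DataFrame(
    read_id = converted$read_id,
    pb = substr(converted$r1_seq, 1L, pb),
    pb_qual = substr(converted$r1_qual, 1L, pb),
    cb = substr(converted$r1_seq, pb + 1L, pb + cb),
    cb_qual = substr(converted$r1_qual, pb + 1L, pb + cb),
    umi = substr(converted$r1_seq, pb + cb + 1L, pb + cb + umi),
    umi_qual = substr(converted$r1_qual, pb + cb + 1L, pb + cb + umi),
    cdna_seq = converted$r2_seq,
    cdna_qual = converted$r2_qual
  )
}

#' Write converted reads as a 10X-style FASTQ pair
#'
#' File names follow the droplet convention
#' `<sample>_S1_L001_R1_001.fastq.gz` / `<sample>_S1_L001_R2_001.fastq.gz`
#' for drop-in compatibility with CB/UMI-aware aligners. Writing is
#' streamed in bounded batches, so arbitrarily large tables of converted
#' reads never require a whole-file buffer.
#'
#' @param converted the return value of [convertReads()].
#' @param outDir output directory (created if absent).
#' @param sample sample name used in the file names.
#' @param batchSize records per write batch.
#' @return Named character vector with the `r1` and `r2` paths.
#' @export
writeConvertedFastq <- function(converted, outDir, sample = "converted",
                                batchSize = 1000000L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  r1Path <- file.path(outDir, sprintf("%s_S1_L001_R1_001.fastq.gz", sample))
  r2Path <- file.path(outDir, sprintf("%s_S1_L001_R2_001.fastq.gz", sample))
  n <- nrow(converted)
  starts <- if (n) seq(1L, n, by = batchSize) else integer()
  mode <- "w"
  for (s in starts) {
    idx <- s:min(s + batchSize - 1L, n)
    ids <- Biostrings::BStringSet(converted$read_id[idx])
    ShortRead::writeFastq(
      ShortRead::ShortReadQ(
        sread = Biostrings::DNAStringSet(converted$r1_seq[idx]),
        quality = Biostrings::BStringSet(converted$r1_qual[idx]),
        id = ids
      ),
      r1Path, mode = mode, compress = TRUE
    )
    ShortRead::writeFastq(
      ShortRead::ShortReadQ(
        sread = Biostrings::DNAStringSet(converted$r2_seq[idx]),
        quality = Biostrings::BStringSet(converted$r2_qual[idx]),
        id = ids
      ),
      r2Path, mode = mode, compress = TRUE
    )
    mode <- "a"
  }
  if (length(starts) == 0L) {
    # still create the (empty) pair so downstream tooling sees both files
    for (p in c(r1Path, r2Path)) {
      con <- gzfile(p, "wb")
      close(con)
    }
  }
  c(r1 = r1Path, r2 = r2Path)
}

#' Build the composite-barcode whitelist of an experiment
#'
#' For every amplification batch and every well in it, one entry: the
#' batch's pool barcode concatenated with the well's cell barcode (11 nt
#' under the default layout). The whitelist spans the whole experiment —
#' the union over all batches, matching a single aligner run; subset the
#' metadata first for a per-batch whitelist. Two wells producing the same
#' composite is an unrecoverable plate-design error and aborts with both
#' well identities.
#'
#' @param md a validated [ExperimentMetadata-class].
#' @return A [Whitelist-class].
#' @examples
#' wl <- buildWhitelist(exampleMetadata())
#' length(wl)
#' head(whitelistEntries(wl))
#' @export
setGeneric("buildWhitelist", function(md) standardGeneric("buildWhitelist"))

#' @rdname buildWhitelist
setMethod("buildWhitelist", "ExperimentMetadata", function(md) {
  ab <- md@ampBatches
  ws <- md@wells
  pbOf <- stats::setNames(ab$pool_barcode, ab$amp_batch_id)
  keep <- ws$amp_batch_id %in% names(pbOf)
  ws <- ws[keep, , drop = FALSE]
  entries <- paste0(toupper(pbOf[ws$amp_batch_id]), toupper(ws$cell_barcode))
  if (anyDuplicated(entries)) {
    d <- entries[duplicated(entries)][1L]
    stop(
      "whitelist collision: wells ",
      paste(ws$well_id[entries == d], collapse = " and "),
      " both produce composite barcode ", d
    )
  }
  new("Whitelist",
    entries = unname(entries),
    ampBatchIds = ws$amp_batch_id,
    wellIds = ws$well_id
  )
})

#' Write / read a whitelist file
#'
#' The file format counting aligners consume: one uppercase composite
#' barcode per line, LF-terminated, no header.
#'
#' @param wl a [Whitelist-class].
#' @param path output path (conventionally `whitelist.txt`).
#' @return `writeWhitelist`: invisibly, `path`. `readWhitelist`: a
#'   [Whitelist-class]; the file stores no well identities, so entries
#'   double as well ids unless `md` is supplied to restore the mapping.
#' @param md optional [ExperimentMetadata-class] used to restore the
#'   entry-to-well mapping when reading.
#' @export
writeWhitelist <- function(wl, path) {
  stopifnot(is(wl, "Whitelist"))
  .writeLinesLf(wl@entries, path)
  invisible(path)
}

#' @rdname writeWhitelist
#' @export
readWhitelist <- function(path, md = NULL) {
  if (!is.null(md)) {
    wl <- buildWhitelist(md)
    fileEntries <- toupper(readLines(path))
    fileEntries <- fileEntries[fileEntries != ""]
    if (!setequal(fileEntries, wl@entries)) {
      stop("whitelist file does not match the metadata's composites")
    }
    return(wl)
  }
  entries <- toupper(readLines(path))
  entries <- entries[entries != ""]
  new("Whitelist",
    entries = entries, ampBatchIds = rep("", length(entries)),
    wellIds = entries
  )
}

#' Barcode geometry parameters for a CB/UMI counting aligner
#'
#' Derives the `CB_UMI_Simple` geometry from a read layout: on the
#' converted read 1 the composite cell barcode (pool + cell barcode)
#' starts at position 1 and the UMI follows immediately. For the default
#' MARS-seq layout this is a barcode of length 11 starting at 1 and an
#' 8 nt UMI starting at 12. Requesting the `Velocyto` feature set makes
#' the aligner emit spliced/unspliced/ambiguous matrices for RNA
#' velocity.
#'
#' @param layout a [ReadLayout-class].
#' @param features aligner feature sets to request.
#' @return A [StarsoloParams-class].
#' @examples
#' renderStarsoloParams(starsoloParams())
#' @export
starsoloParams <- function(layout = marsLayout(),
                           features = c(
                             "Gene", "GeneFull", "SJ", "Velocyto"
                           )) {
  stopifnot(is(layout, "ReadLayout"))
  cbLen <- layout@pbLen + layout@cbLen
  new("StarsoloParams",
    soloType = "CB_UMI_Simple",
    cbStart = 1L, cbLen = cbLen,
    umiStart = cbLen + 1L, umiLen = layout@umiLen,
    features = features
  )
}

#' @rdname starsoloParams
#' @param params a [StarsoloParams-class].
#' @return `renderStarsoloParams`: the single-line flag string to splice
#'   into an aligner command.
#' @export
renderStarsoloParams <- function(params) {
  stopifnot(is(params, "StarsoloParams"))
  sprintf(
    paste(
      "--soloType %s --soloCBstart %d --soloCBlen %d",
      "--soloUMIstart %d --soloUMIlen %d --soloFeatures %s"
    ),
    params@soloType, params@cbStart, params@cbLen, params@umiStart,
    params@umiLen, paste(params@features, collapse = " ")
  )
}
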