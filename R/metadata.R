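## Canonical table schemas. The three tables describe one experiment:
## sequencing batches (one pair of FASTQ files each), amplification batches
## (one pool barcode each, nested in a sequencing batch) and wells (one cell
## barcode each, nested in an amplification batch).
.METADATA_SCHEMA <- list(
  seq_batch = list(
    required = "batch_id",
    optional = c("run_name", "r1_path", "r2_path", "notes")
  ),
  amp_batch = list(
    required = c("amp_batch_id", "seq_batch_id", "pool_barcode"),
    optional = character()
  ),
  wells_cells = list(
    required = c("well_id", "amp_batch_id", "cell_barcode"),
    optional = character()
  )
)

## Header aliases: accepts the field's customary capitalized headers in
## addition to the canonical lower-case ones (matching is case-insensitive
## after alias resolution).
.HEADER_ALIASES <- c(
  seq_batch_id = "seq_batch_id",
  sb_id = "batch_id",
  amp_batch_id = "amp_batch_id",
  ab_id = "amp_batch_id",
  pool_barcode = "pool_barcode",
  pool_bc = "pool_barcode",
  pb = "pool_barcode",
  well_id = "well_id",
  cell_barcode = "cell_barcode",
  cell_bc = "cell_barcode",
  cb = "cell_barcode"
)

.normalizeHeaders <- function(x, table) {
  h <- tolower(trimws(x))
  hit <- h %in% names(.HEADER_ALIASES)
  h[hit] <- unname(.HEADER_ALIASES[h[hit]])
  # the seq_batch table's own id column may arrive as "seq_batch_id"
  if (table == "seq_batch") h[h == "seq_batch_id"] <- "batch_id"
  h
}

.trimFrame <- function(df) {
  df[] <- lapply(df, function(col) trimws(as.character(col)))
  df
}

.completeTable <- function(df, table) {
  sch <- .METADATA_SCHEMA[[table]]
  colnames(df) <- .normalizeHeaders(colnames(df), table)
  missing <- setdiff(sch$required, colnames(df))
  if (length(missing)) {
    stop(
      "table '", table, "' is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  for (col in setdiff(sch$optional, colnames(df))) df[[col]] <- ""
  df <- .trimFrame(df[, c(sch$required, sch$optional), drop = FALSE])
  # fixed alphabet for whitelist matching: barcodes are upper-cased on
  # ingest; residual non-ACGT characters become validation errors
  for (col in intersect(c("pool_barcode", "cell_barcode"), colnames(df))) {
    df[[col]] <- toupper(df[[col]])
  }
  rownames(df) <- NULL
  df
}

#' Convert a spreadsheet workbook to canonical metadata files
#'
#' Reads the three experiment-description sheets (`seq_batch`, `amp_batch`,
#' `wells_cells`; matched by name, case-insensitively) from an XLSX workbook
#' and writes them as UTF-8, LF-terminated, tab-separated files with a
#' header line. Cell values are trimmed of surrounding whitespace; no other
#' coercion is applied. Conversion does not validate content — run
#' [validateMetadata()] on the result.
#'
#' @param workbookPath path to an `.xlsx` workbook.
#' @param outDir output directory (created if absent).
#' @return Invisibly, a named character vector of the three file paths.
#' @seealso [readExperimentMetadata()], [validateMetadata()]
#' @export
convertWorkbook <- function(workbookPath, outDir) {
  if (!file.exists(workbookPath)) {
    stop("workbook not found: ", workbookPath)
  }
  sheets <- readxl::excel_sheets(workbookPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  for (table in names(.METADATA_SCHEMA)) {
    hit <- which(tolower(sheets) == table)
    if (length(hit) == 0L) stop("sheet not found: ", table)
    df <- as.data.frame(
      readxl::read_excel(
        workbookPath,
        sheet = sheets[hit[1L]], col_types = "text"
      ),
      stringsAsFactors = FALSE
    )
    df[is.na(df)] <- ""
    colnames(df) <- .normalizeHeaders(colnames(df), table)
    missing <- setdiff(.METADATA_SCHEMA[[table]]$required, colnames(df))
    if (length(missing)) {
      stop(
        "sheet '", table, "' is missing required column(s): ",
        paste(missing, collapse = ", ")
      )
    }
    df <- .trimFrame(df)
    path <- file.path(outDir, paste0(table, ".txt"))
    lines <- c(
      paste(colnames(df), collapse = "\t"),
      if (nrow(df)) {
        apply(df, 1L, paste, collapse = "\t")
      }
    )
    .writeLinesLf(lines, path)
    out[table] <- path
  }
  invisible(out)
}

.readMetadataTable <- function(path, table) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(
    path,
    colClasses = "character", check.names = FALSE,
    blank.lines.skip = TRUE
  )
  .completeTable(df, table)
}

#' Read experiment metadata from tab-separated files
#'
#' Parses `seq_batch.txt`, `amp_batch.txt` and `wells_cells.txt` (or three
#' explicitly named files) into an [ExperimentMetadata-class] object.
#' Barcodes are upper-cased on ingest; header aliases used by existing
#' plate layouts are accepted case-insensitively. Parsing does not
#' validate — call [validateMetadata()] before using the object.
#'
#' @param dir directory containing the three canonical files; ignored when
#'   all three path arguments are given.
#' @param seqBatchPath,ampBatchPath,wellsPath explicit file paths.
#' @return An [ExperimentMetadata-class] object.
#' @examples
#' md <- exampleMetadata()
#' dir <- tempfile()
#' writeMetadata(md, dir)
#' md2 <- readExperimentMetadata(dir)
#' passed(validateMetadata(md2))
#' @export
readExperimentMetadata <- function(dir = NULL, seqBatchPath = NULL,
                                   ampBatchPath = NULL, wellsPath = NULL) {
  if (is.null(seqBatchPath)) seqBatchPath <- file.path(dir, "seq_batch.txt")
  if (is.null(ampBatchPath)) ampBatchPath <- file.path(dir, "amp_batch.txt")
  if (is.null(wellsPath)) wellsPath <- file.path(dir, "wells_cells.txt")
  new("ExperimentMetadata",
    seqBatches = .readMetadataTable(seqBatchPath, "seq_batch"),
    ampBatches = .readMetadataTable(ampBatchPath, "amp_batch"),
    wells = .readMetadataTable(wellsPath, "wells_cells")
  )
}

#' Construct experiment metadata from in-memory tables
#'
#' @param seqBatches,ampBatches,wells data.frames following the canonical
#'   schemas (missing optional columns are filled with empty strings).
#' @return An [ExperimentMetadata-class] object.
#' @export
experimentMetadata <- function(seqBatches, ampBatches, wells) {
  new("ExperimentMetadata",
    seqBatches = .completeTable(seqBatches, "seq_batch"),
    ampBatches = .completeTable(ampBatches, "amp_batch"),
    wells = .completeTable(wells, "wells_cells")
  )
}

#' Write experiment metadata as canonical tab-separated files
#'
#' @param md an [ExperimentMetadata-class].
#' @param outDir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
writeMetadata <- function(md, outDir) {
  stopifnot(is(md, "ExperimentMetadata"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(
    seq_batch = md@seqBatches, amp_batch = md@ampBatches,
    wells_cells = md@wells
  )
  out <- character()
  for (table in names(tabs)) {
    df <- tabs[[table]]
    path <- file.path(outDir, paste0(table, ".txt"))
    lines <- c(
      paste(colnames(df), collapse = "\t"),
      if (nrow(df)) apply(df, 1L, paste, collapse = "\t")
    )
    .writeLinesLf(lines, path)
    out[table] <- path
  }
  invisible(out)
}

#' A small consistent example experiment
#'
#' One sequencing batch, two amplification batches of two wells each;
#' handy for examples and as a template for real experiments.
#'
#' @return An [ExperimentMetadata-class] object that passes validation.
#' @export
exampleMetadata <- function() {
  experimentMetadata(
    seqBatches = data.frame(
      batch_id = "SB1", run_name = "example", r1_path = "R1.fastq.gz",
      r2_path = "R2.fastq.gz", notes = ""
    ),
    ampBatches = data.frame(
      amp_batch_id = c("AB1", "AB2"),
      seq_batch_id = "SB1",
      pool_barcode = c("ACGT", "TTGG")
    ),
    wells = data.frame(
      well_id = c("W1", "W2", "W3", "W4"),
      amp_batch_id = c("AB1", "AB1", "AB2", "AB2"),
      cell_barcode = c("AACCGGT", "CCAATTG", "AACCGGT", "CCAATTG")
    )
  )
}

.err <- function(code, table, row, message) {
  data.frame(
    code = code, table = table, row = as.integer(row),
    message = message, stringsAsFactors = FALSE
  )
}

#' Validate experiment metadata
#'
#' Checks every invariant of the three metadata tables and reports all
#' violations at once (no fail-fast): empty required fields, duplicate
#' identifiers, barcode length and alphabet, dangling foreign keys,
#' amplification batches without wells, and duplicate
#' (amplification batch, cell barcode) pairs. Violations are report
#' content, never exceptions; pipeline entry points convert a failed report
#' into a hard stop.
#'
#' Error codes: `SB_EMPTY`, `SB_DUP`, `AB_EMPTY`, `AB_DUP`, `AB_FK`,
#' `PB_LEN`, `PB_ALPHABET`, `WS_EMPTY`, `WS_DUP`, `WS_FK`, `CB_LEN`,
#' `CB_ALPHABET`, `DUP_CB`, `AB_NO_WELLS`. Warning codes: `PB_SHARED`
#' (one pool barcode reused by several amplification batches).
#'
#' @param md an [ExperimentMetadata-class].
#' @param layout a [ReadLayout-class] giving the expected pool/cell barcode
#'   lengths (defaults to the standard 4/7 nt).
#' @return A [ValidationReport-class]; `passed(report)` is `TRUE` iff no
#'   errors were found.
#' @examples
#' report <- validateMetadata(exampleMetadata())
#' passed(report)
#' @export
setGeneric("validateMetadata", function(md, layout = marsLayout()) {
  standardGeneric("validateMetadata")
})

#' @rdname validateMetadata
setMethod("validateMetadata", "ExperimentMetadata", function(md, layout) {
  sb <- md@seqBatches
  ab <- md@ampBatches
  ws <- md@wells
  errors <- .reportFrame()
  warnings <- .reportFrame()
  add <- function(...) errors <<- rbind(errors, .err(...))

  .checkId <- function(values, table, emptyCode, dupCode, what) {
    for (i in which(values == "")) {
      add(emptyCode, table, i, paste0("empty ", what))
    }
    dup <- values[values != "" & duplicated(values)]
    for (d in unique(dup)) {
      for (i in which(values == d)) {
        add(dupCode, table, i, sprintf("duplicate %s \"%s\"", what, d))
      }
    }
  }
  .checkBarcode <- function(values, table, expectLen, lenCode, alphaCode,
                            what) {
    for (i in seq_along(values)) {
      v <- values[i]
      if (nchar(v) != expectLen) {
        add(lenCode, table, i, sprintf(
          "%s \"%s\" has length %d, expected %d", what, v, nchar(v),
          expectLen
        ))
      } else if (grepl("[^ACGT]", v)) {
        add(alphaCode, table, i, sprintf(
          "%s \"%s\" contains characters outside {A,C,G,T}", what, v
        ))
      }
    }
  }

  .checkId(sb$batch_id, "seq_batch", "SB_EMPTY", "SB_DUP", "batch_id")
  .checkId(
    ab$amp_batch_id, "amp_batch", "AB_EMPTY", "AB_DUP", "amp_batch_id"
  )
  .checkId(ws$well_id, "wells_cells", "WS_EMPTY", "WS_DUP", "well_id")

  for (i in which(!ab$seq_batch_id %in% sb$batch_id)) {
    add("AB_FK", "amp_batch", i, sprintf(
      "seq_batch_id \"%s\" does not match any sequencing batch",
      ab$seq_batch_id[i]
    ))
  }
  for (i in which(!ws$amp_batch_id %in% ab$amp_batch_id)) {
    add("WS_FK", "wells_cells", i, sprintf(
      "amp_batch_id \"%s\" does not match any amplification batch",
      ws$amp_batch_id[i]
    ))
  }

  .checkBarcode(
    ab$pool_barcode, "amp_batch", layout@pbLen, "PB_LEN", "PB_ALPHABET",
    "pool_barcode"
  )
  .checkBarcode(
    ws$cell_barcode, "wells_cells", layout@cbLen, "CB_LEN", "CB_ALPHABET",
    "cell_barcode"
  )

  pair <- paste(ws$amp_batch_id, ws$cell_barcode, sep = "\r")
  for (d in unique(pair[duplicated(pair)])) {
    for (i in which(pair == d)) {
      add("DUP_CB", "wells_cells", i, sprintf(
        "duplicate (amp_batch_id, cell_barcode) pair (\"%s\", \"%s\")",
        ws$amp_batch_id[i], ws$cell_barcode[i]
      ))
    }
  }

  for (i in which(!ab$amp_batch_id %in% ws$amp_batch_id)) {
    add("AB_NO_WELLS", "amp_batch", i, sprintf(
      "amplification batch \"%s\" has no wells", ab$amp_batch_id[i]
    ))
  }

  shared <- unique(ab$pool_barcode[duplicated(ab$pool_barcode) &
    ab$pool_barcode != ""])
  for (s in shared) {
    warnings <- rbind(warnings, .err(
      "PB_SHARED", "amp_batch", NA_integer_,
      sprintf(
        "pool_barcode \"%s\" is shared by %d amplification batches", s,
        sum(ab$pool_barcode == s)
      )
    ))
  }

  new("ValidationReport", errors = errors, warnings = warnings)
})
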