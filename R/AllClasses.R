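#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MARS-seq read layout
#'
#' Declarative byte-offset map of the two mates of a MARS-seq read pair.
#' Read 1 carries a fixed left adapter (`laLen`, default 3 nt), the pool
#' barcode (`pbLen`, default 4 nt), the cDNA insert, and a fixed right
#' adapter (`raLen`, default 2 nt) at the 3' end. Read 2 carries the cell
#' barcode (`cbLen`, default 7 nt) followed by the UMI (`umiLen`, default
#' 8 nt). The cDNA span is derived per read as
#' `width(R1) - laLen - pbLen - raLen`; on a 75 nt read 1 the default layout
#' yields a 66 nt insert.
#'
#' @slot laLen,pbLen,raLen,cbLen,umiLen integer segment lengths in
#'   nucleotides.
#' @seealso [marsLayout()], [labelReads()], [starsoloParams()]
#' @exportClass ReadLayout
setClass("ReadLayout",
  representation(
    laLen = "integer", pbLen = "integer", raLen = "integer",
    cbLen = "integer", umiLen = "integer"
  )
)

setValidity("ReadLayout", function(object) {
  v <- c(
    laLen = object@laLen, pbLen = object@pbLen, raLen = object@raLen,
    cbLen = object@cbLen, umiLen = object@umiLen
  )
  if (any(is.na(v))) return("segment lengths must not be NA")
  if (any(v < 0L)) return("segment lengths must be >= 0")
  if (object@pbLen < 1L || object@cbLen < 1L || object@umiLen < 1L)
    return("pool barcode, cell barcode and UMI must have length >= 1")
  TRUE
})

#' Construct a MARS-seq read layout
#'
#' @param laLen,pbLen,raLen,cbLen,umiLen segment lengths in nucleotides;
#'   defaults describe the standard MARS-seq layout (left adapter 3, pool
#'   barcode 4, right adapter 2 on read 1; cell barcode 7 and UMI 8 on
#'   read 2).
#' @return A [ReadLayout-class] object.
#' @examples
#' layout <- marsLayout()
#' compositeLength(layout) # 4 + 7 + 8 = 19
#' @export
marsLayout <- function(laLen = 3L, pbLen = 4L, raLen = 2L,
                       cbLen = 7L, umiLen = 8L) {
  new("ReadLayout",
    laLen = as.integer(laLen), pbLen = as.integer(pbLen),
    raLen = as.integer(raLen), cbLen = as.integer(cbLen),
    umiLen = as.integer(umiLen)
  )
}

#' @describeIn marsLayout Length of the composite barcode
#'   (pool barcode + cell barcode + UMI) a converted read 1 carries.
#' @param layout a [ReadLayout-class].
#' @export
compositeLength <- function(layout) {
  stopifnot(is(layout, "ReadLayout"))
  layout@pbLen + layout@cbLen + layout@umiLen
}

#' @describeIn marsLayout Minimum read-1 length the layout admits (adapters
#'   and pool barcode plus at least one cDNA base).
#' @export
minRead1Length <- function(layout) {
  stopifnot(is(layout, "ReadLayout"))
  layout@laLen + layout@pbLen + layout@raLen + 1L
}

setMethod("show", "ReadLayout", function(object) {
  cat("ReadLayout: R1 = LA(", object@laLen, ") + PB(", object@pbLen,
    ") + cDNA + RA(", object@raLen, "); R2 = CB(", object@cbLen,
    ") + UMI(", object@umiLen, ")\n",
    sep = ""
  )
})

#' Validated MARS-seq experiment metadata
#'
#' Holds the three experiment description tables: sequencing batches
#' (`seq_batch`), amplification batches (`amp_batch`, each tied to one pool
#' barcode), and wells (`wells_cells`, each tied to one cell barcode within
#' an amplification batch).
#'
#' @slot seqBatches data.frame with columns `batch_id`, `run_name`,
#'   `r1_path`, `r2_path`, `notes`.
#' @slot ampBatches data.frame with columns `amp_batch_id`, `seq_batch_id`,
#'   `pool_barcode`.
#' @slot wells data.frame with columns `well_id`, `amp_batch_id`,
#'   `cell_barcode`.
#' @seealso [readExperimentMetadata()], [validateMetadata()],
#'   [buildWhitelist()]
#' @exportClass ExperimentMetadata
setClass("ExperimentMetadata",
  representation(
    seqBatches = "data.frame",
    ampBatches = "data.frame",
    wells = "data.frame"
  )
)

setValidity("ExperimentMetadata", function(object) {
  need <- list(
    seqBatches = c("batch_id", "run_name", "r1_path", "r2_path", "notes"),
    ampBatches = c("amp_batch_id", "seq_batch_id", "pool_barcode"),
    wells = c("well_id", "amp_batch_id", "cell_barcode")
  )
  for (nm in names(need)) {
    missing <- setdiff(need[[nm]], colnames(slot(object, nm)))
    if (length(missing)) {
      return(sprintf(
        "%s lacks required column(s): %s", nm,
        paste(missing, collapse = ", ")
      ))
    }
  }
  TRUE
})

#' @rdname ExperimentMetadata-class
#' @param object an `ExperimentMetadata`.
#' @export
setGeneric("seqBatches", function(object) standardGeneric("seqBatches"))
#' @rdname ExperimentMetadata-class
#' @export
setGeneric("ampBatches", function(object) standardGeneric("ampBatches"))
#' @rdname ExperimentMetadata-class
#' @export
setGeneric("wellsCells", function(object) standardGeneric("wellsCells"))

#' @rdname ExperimentMetadata-class
setMethod("seqBatches", "ExperimentMetadata", function(object) object@seqBatches)
#' @rdname ExperimentMetadata-class
setMethod("ampBatches", "ExperimentMetadata", function(object) object@ampBatches)
#' @rdname ExperimentMetadata-class
setMethod("wellsCells", "ExperimentMetadata", function(object) object@wells)

setMethod("show", "ExperimentMetadata", function(object) {
  cat("ExperimentMetadata:",
    nrow(object@seqBatches), "sequencing batch(es),",
    nrow(object@ampBatches), "amplification batch(es),",
    nrow(object@wells), "well(s)\n"
  )
})

#' Metadata validation report
#'
#' Exhaustive report produced by [validateMetadata()]. Violations are report
#' content, never exceptions: the report collects every problem found in one
#' pass so that all mistakes can be fixed together, and `passed(report)` is
#' `TRUE` exactly when no errors were recorded. Pipeline entry points turn a
#' failed report into a hard stop before any reads are touched.
#'
#' @slot errors data.frame with columns `code`, `table`, `row`, `message`.
#' @slot warnings data.frame of the same shape.
#' @seealso [validateMetadata()]
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(errors = "data.frame", warnings = "data.frame")
)

.reportFrame <- function() {
  data.frame(
    code = character(), table = character(), row = integer(),
    message = character(), stringsAsFactors = FALSE
  )
}

setValidity("ValidationReport", function(object) {
  need <- c("code", "table", "row", "message")
  if (!all(need %in% colnames(object@errors)) ||
    !all(need %in% colnames(object@warnings))) {
    return("errors/warnings need columns code, table, row, message")
  }
  TRUE
})

#' @rdname ValidationReport-class
#' @param object a `ValidationReport`.
#' @export
setGeneric("passed", function(object) standardGeneric("passed"))
#' @rdname ValidationReport-class
setMethod("passed", "ValidationReport", function(object) {
  nrow(object@errors) == 0L
})

#' @rdname ValidationReport-class
#' @export
setGeneric("validationErrors", function(object) {
  standardGeneric("validationErrors")
})
#' @rdname ValidationReport-class
setMethod("validationErrors", "ValidationReport", function(object) {
  object@errors
})

#' @rdname ValidationReport-class
#' @export
setGeneric("validationWarnings", function(object) {
  standardGeneric("validationWarnings")
})
#' @rdname ValidationReport-class
setMethod("validationWarnings", "ValidationReport", function(object) {
  object@warnings
})

setMethod("show", "ValidationReport", function(object) {
  status <- if (passed(object)) "PASSED" else "FAILED"
  cat("ValidationReport:", status, "-", nrow(object@errors), "error(s),",
    nrow(object@warnings), "warning(s)\n"
  )
  if (nrow(object@errors)) {
    e <- utils::head(object@errors, 10L)
    for (i in seq_len(nrow(e))) {
      cat(sprintf(
        "  [%s] %s row %s: %s\n", e$code[i], e$table[i],
        ifelse(is.na(e$row[i]), "-", e$row[i]), e$message[i]
      ))
    }
    if (nrow(object@errors) > 10L) {
      cat("  ...", nrow(object@errors) - 10L, "more\n")
    }
  }
})

#' Composite-barcode whitelist
#'
#' The enumerated set of valid composite barcodes of an experiment: for
#' every amplification batch and every well in it, the pool barcode
#' concatenated with the well's cell barcode (11 nt under the default
#' layout). Each entry maps back to its amplification batch and well
#' identity; aligners and the demultiplexer match observed barcodes against
#' this set.
#'
#' @slot entries character vector of unique uppercase composite barcodes.
#' @slot ampBatchIds,wellIds character vectors parallel to `entries`.
#' @seealso [buildWhitelist()], [assignBarcodes()], [writeWhitelist()]
#' @exportClass Whitelist
setClass("Whitelist",
  representation(
    entries = "character", ampBatchIds = "character", wellIds = "character"
  )
)

setValidity("Whitelist", function(object) {
  n <- length(object@entries)
  if (length(object@ampBatchIds) != n || length(object@wellIds) != n) {
    return("entries, ampBatchIds and wellIds must be parallel vectors")
  }
  if (anyDuplicated(object@entries)) {
    return("whitelist entries must be unique")
  }
  if (n > 0L && length(unique(nchar(object@entries))) != 1L) {
    return("all whitelist entries must have the same length")
  }
  if (n > 0L && any(grepl("[^ACGT]", object@entries))) {
    return("whitelist entries must be over the alphabet {A,C,G,T}")
  }
  TRUE
})

#' @rdname Whitelist-class
#' @param object a `Whitelist`.
#' @export
setGeneric("whitelistEntries", function(object) {
  standardGeneric("whitelistEntries")
})
#' @rdname Whitelist-class
setMethod("whitelistEntries", "Whitelist", function(object) object@entries)

#' @rdname Whitelist-class
#' @export
setGeneric("wellIds", function(object) standardGeneric("wellIds"))
#' @rdname Whitelist-class
setMethod("wellIds", "Whitelist", function(object) object@wellIds)

#' @rdname Whitelist-class
#' @export
setGeneric("ampBatchIds", function(object) standardGeneric("ampBatchIds"))
#' @rdname Whitelist-class
setMethod("ampBatchIds", "Whitelist", function(object) object@ampBatchIds)

setMethod("length", "Whitelist", function(x) length(x@entries))

setMethod("show", "Whitelist", function(object) {
  cat("Whitelist:", length(object@entries), "composite barcode(s)")
  if (length(object@entries)) {
    cat(" of length", nchar(object@entries[1L]), "nt,",
      length(unique(object@ampBatchIds)), "amplification batch(es)"
    )
  }
  cat("\n")
})

#' Splice-aware aligner barcode geometry
#'
#' CB/UMI geometry for a `CB_UMI_Simple`-style counting aligner run on
#' converted reads: the composite cell barcode (pool barcode + cell barcode)
#' occupies positions `cbStart .. cbStart+cbLen-1` of the converted read 1
#' and the UMI follows immediately. Positions are 1-based, matching the
#' aligner's convention.
#'
#' @slot soloType character, the barcode-handling mode.
#' @slot cbStart,cbLen,umiStart,umiLen integer 1-based geometry.
#' @slot features character, the count-matrix feature sets requested
#'   (spliced/unspliced classification for RNA velocity comes from the
#'   aligner's `Velocyto` feature).
#' @seealso [starsoloParams()], [renderStarsoloParams()]
#' @exportClass StarsoloParams
setClass("StarsoloParams",
  representation(
    soloType = "character", cbStart = "integer", cbLen = "integer",
    umiStart = "integer", umiLen = "integer", features = "character"
  )
)

setValidity("StarsoloParams", function(object) {
  if (object@cbStart + object@cbLen != object@umiStart) {
    return("cbStart + cbLen must equal umiStart (CB and UMI are adjacent)")
  }
  if (object@cbLen < 1L || object@umiLen < 1L) {
    return("cbLen and umiLen must be >= 1")
  }
  TRUE
})

setMethod("show", "StarsoloParams", function(object) {
  cat("StarsoloParams:", renderStarsoloParams(object), "\n")
})

#' Augmented reference bundle
#'
#' Paths and tallies for a genome reference augmented with ERCC spike-in
#' sequences by [buildReference()].
#'
#' @slot fastaPath,gtfPath paths to the augmented FASTA and GTF.
#' @slot nGenomeSeqs,nSpikeins integer record counts.
#' @exportClass ReferenceBundle
setClass("ReferenceBundle",
  representation(
    fastaPath = "character", gtfPath = "character",
    nGenomeSeqs = "integer", nSpikeins = "integer"
  )
)

#' @rdname ReferenceBundle-class
#' @param object a `ReferenceBundle`.
#' @export
setGeneric("nSpikeins", function(object) standardGeneric("nSpikeins"))
#' @rdname ReferenceBundle-class
setMethod("nSpikeins", "ReferenceBundle", function(object) object@nSpikeins)

#' @rdname ReferenceBundle-class
#' @export
setGeneric("nGenomeSeqs", function(object) standardGeneric("nGenomeSeqs"))
#' @rdname ReferenceBundle-class
setMethod("nGenomeSeqs", "ReferenceBundle", function(object) {
  object@nGenomeSeqs
})

#' @rdname ReferenceBundle-class
#' @export
setGeneric("referencePaths", function(object) {
  standardGeneric("referencePaths")
})
#' @rdname ReferenceBundle-class
setMethod("referencePaths", "ReferenceBundle", function(object) {
  c(fasta = object@fastaPath, gtf = object@gtfPath)
})

setMethod("show", "ReferenceBundle", function(object) {
  cat("ReferenceBundle:", object@nGenomeSeqs, "genome sequence(s) +",
    object@nSpikeins, "ERCC spike-in(s)\n",
    " fasta:", object@fastaPath, "\n gtf:  ", object@gtfPath, "\n"
  )
})

#' Well-by-feature UMI count matrix
#'
#' The terminal output of demultiplexing: deduplicated molecule counts for
#' every whitelist well and every reference feature (genes then ERCC
#' spike-ins). Stored as a `SummarizedExperiment` with features as rows and
#' wells as columns (the orientation of the standard single-cell matrix
#' exchange format); the `counts` assay is a sparse integer matrix.
#' Demultiplexing tallies (unmapped, ambiguous, unassigned-barcode, counted
#' reads) live in `metadata(x)$stats` and satisfy the conservation identity
#' with the input read count.
#'
#' @seealso [countReads()], [writeCountMatrix()], [readCountMatrix()],
#'   [demuxStats()]
#' @exportClass WellCountMatrix
setClass("WellCountMatrix", contains = "SummarizedExperiment")

setValidity("WellCountMatrix", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("a 'counts' assay is required")
  }
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m@x < 0)) return("counts must be non-negative")
  TRUE
})

#' @rdname WellCountMatrix-class
#' @param object a `WellCountMatrix`.
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))
#' @rdname WellCountMatrix-class
setMethod("featureIds", "WellCountMatrix", function(object) rownames(object))

#' @rdname WellCountMatrix-class
setMethod("wellIds", "WellCountMatrix", function(object) colnames(object))

#' @rdname WellCountMatrix-class
#' @export
setGeneric("demuxStats", function(object) standardGeneric("demuxStats"))
#' @rdname WellCountMatrix-class
setMethod("demuxStats", "WellCountMatrix", function(object) {
  S4Vectors::metadata(object)$stats
})

setMethod("show", "WellCountMatrix", function(object) {
  m <- SummarizedExperiment::assay(object, "counts")
  cat("WellCountMatrix:", nrow(m), "feature(s) x", ncol(m), "well(s),",
    sum(m), "molecule(s)\n"
  )
  st <- S4Vectors::metadata(object)$stats
  if (!is.null(st)) {
    cat(" reads:", paste(names(st), unlist(st), sep = "=", collapse = ", "),
      "\n"
    )
  }
})

#' Simulation configuration
#'
#' Parameters of a synthetic MARS-seq experiment generated by
#' [simulateExperiment()]. Defaults describe a small two-plate experiment:
#' 2 amplification batches of 8 wells, 20 genes plus 3 ERCC spike-ins,
#' 200 reads per well at a mean duplication of 2 reads per molecule,
#' error-free 75 nt read 1.
#'
#' @slot nAmpBatches,wellsPerBatch,nGenes,nErcc,readsPerWell integer counts.
#' @slot duplicationRate numeric mean reads per planted molecule (>= 1).
#' @slot barcodeErrorRate,umiErrorRate numeric per-base substitution
#'   probabilities in `[0, 1]` applied to barcode and UMI bases.
#' @slot read1Len integer read-1 length (default 75 nt).
#' @slot geneLen integer planted transcript length (cDNA reads are drawn
#'   from these sequences).
#' @slot laSeq,raSeq fixed left/right adapter sequences.
#' @slot seed integer RNG seed; identical seed means byte-identical outputs.
#' @slot compress logical, gzip the FASTQ outputs.
#' @seealso [simConfig()], [simulateExperiment()]
#' @exportClass MarsSimConfig
setClass("MarsSimConfig",
  representation(
    nAmpBatches = "integer", wellsPerBatch = "integer",
    nGenes = "integer", nErcc = "integer", readsPerWell = "integer",
    duplicationRate = "numeric", barcodeErrorRate = "numeric",
    umiErrorRate = "numeric", read1Len = "integer", geneLen = "integer",
    laSeq = "character", raSeq = "character", seed = "integer",
    compress = "logical"
  )
)

setValidity("MarsSimConfig", function(object) {
  counts <- c(
    object@nAmpBatches, object@wellsPerBatch, object@nGenes,
    object@nErcc, object@readsPerWell
  )
  if (any(counts < 0L)) return("counts must be >= 0")
  p <- c(object@barcodeErrorRate, object@umiErrorRate)
  if (any(p < 0) || any(p > 1)) return("error rates must lie in [0, 1]")
  if (object@duplicationRate < 1) return("duplicationRate must be >= 1")
  if (object@read1Len < nchar(object@laSeq) + 4L + nchar(object@raSeq) + 1L) {
    return("read1Len leaves no room for cDNA")
  }
  if (object@geneLen < object@read1Len) {
    return("geneLen must be >= read1Len so inserts fit inside transcripts")
  }
  if (grepl("[^ACGT]", object@laSeq) || grepl("[^ACGT]", object@raSeq)) {
    return("adapters must be over {A,C,G,T}")
  }
  TRUE
})

setMethod("show", "MarsSimConfig", function(object) {
  cat("MarsSimConfig:", object@nAmpBatches, "amp batch(es) x",
    object@wellsPerBatch, "well(s),", object@nGenes, "gene(s) +",
    object@nErcc, "ERCC,", object@readsPerWell, "read(s)/well, seed",
    object@seed, "\n"
  )
})
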