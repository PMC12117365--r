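#' Assemble a pipeline run configuration
#'
#' Collects the paths and thresholds of a full preprocessing run. The
#' `velocity` toggle mirrors the convention of appending a velocity flag
#' to a run: when `TRUE`, the 10X conversion and whitelist stages execute
#' so a splice-aware CB/UMI aligner can produce spliced/unspliced
#' matrices downstream.
#'
#' @param metaDir directory with `seq_batch.txt`, `amp_batch.txt`,
#'   `wells_cells.txt`.
#' @param outDir output directory.
#' @param r1,r2 FASTQ paths; when `NULL`, taken from the first sequencing
#'   batch's `r1_path`/`r2_path` resolved against `metaDir`'s parent.
#' @param velocity run the 10X conversion + whitelist stages.
#' @param samPath optional aligned SAM/BAM to demultiplex into counts.
#' @param gtfPath optional annotation GTF (feature universe; also used to
#'   annotate SAMs lacking gene tags).
#' @param chunkSize optional [splitFastq()] chunk size for the labeled
#'   FASTQ (`NULL` skips splitting; the aligner-facing default is 4e6).
#' @param minBarcodeQual,maxLowQualBases labeling thresholds, see
#'   [labelReads()].
#' @param umiMode,maxBcDist,mapqMin counting parameters, see
#'   [countReads()].
#' @param sample sample name for converted FASTQ files.
#' @param seed seed echoed into the run report.
#' @return A validated configuration list of class `MarsRunConfig`.
#' @seealso [runPipeline()], [readRunConfig()]
#' @export
runConfig <- function(metaDir, outDir, r1 = NULL, r2 = NULL,
                      velocity = FALSE, samPath = NULL, gtfPath = NULL,
                      chunkSize = NULL, minBarcodeQual = 20L,
                      maxLowQualBases = 1L,
                      umiMode = c("exact", "directional"),
                      maxBcDist = 0L, mapqMin = 0L, sample = "sample",
                      seed = 1L) {
  cfg <- list(
    metaDir = metaDir, outDir = outDir, r1 = r1, r2 = r2,
    velocity = isTRUE(velocity), samPath = samPath, gtfPath = gtfPath,
    chunkSize = chunkSize, minBarcodeQual = as.integer(minBarcodeQual),
    maxLowQualBases = as.integer(maxLowQualBases),
    umiMode = match.arg(umiMode), maxBcDist = as.integer(maxBcDist),
    mapqMin = as.integer(mapqMin), sample = sample,
    seed = as.integer(seed)
  )
  class(cfg) <- "MarsRunConfig"
  cfg
}

#' @rdname runConfig
#' @param path a YAML file whose keys are `runConfig()` arguments.
#' @param ... overrides applied on top of the file's values.
#' @export
readRunConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(runConfig, vals)
}

.resolveFastqPaths <- function(cfg, md) {
  if (!is.null(cfg$r1) && !is.null(cfg$r2)) {
    return(c(r1 = cfg$r1, r2 = cfg$r2))
  }
  sb <- seqBatches(md)
  if (nrow(sb) == 0L || sb$r1_path[1L] == "" || sb$r2_path[1L] == "") {
    stop("no FASTQ paths: supply r1/r2 or fill them in seq_batch.txt")
  }
  base <- dirname(cfg$metaDir)
  c(
    r1 = file.path(base, sb$r1_path[1L]),
    r2 = file.path(base, sb$r2_path[1L])
  )
}

#' Run the preprocessing pipeline
#'
#' Executes the stages in dependency order with checkpoint semantics:
#' metadata is validated first and a failed report is a hard stop (a
#' non-zero exit at the command line) before any read is touched. Then
#' reads are labeled and written as a labeled cDNA FASTQ (optionally
#' split into bounded chunks); with `velocity = TRUE` the converted
#' 10X-style pair, the whitelist and the aligner parameter file are
#' produced; when an aligned SAM is supplied the count matrix is
#' demultiplexed. External aligner invocations are rendered into
#' `commands.sh`, never executed. A run report (JSON and text) records
#' per-stage tallies; the conservation identities
#' (`n_input = n_kept + discarded` for labeling, `n_input = counted +
#' excluded` for demultiplexing) hold in the report by construction.
#'
#' @param cfg a configuration from [runConfig()] / [readRunConfig()].
#' @param layout a [ReadLayout-class].
#' @return Invisibly, a list with the report (also written to
#'   `report.json` / `report.txt`), the labeled table, and the produced
#'   paths; plus `counts` (a [WellCountMatrix-class]) when counting ran.
#' @export
runPipeline <- function(cfg, layout = marsLayout()) {
  stopifnot(inherits(cfg, "MarsRunConfig"))

  ## checkpoint: validate before touching any read
  md <- readExperimentMetadata(cfg$metaDir)
  report <- validateMetadata(md, layout)
  if (!passed(report)) {
    show(report)
    stop(
      "stage metadata-validation failed: ",
      nrow(validationErrors(report)),
      " error(s); no reads were processed"
    )
  }

  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stages <- list()

  fq <- .resolveFastqPaths(cfg, md)
  labeled <- labelReads(
    fq["r1"], fq["r2"], layout,
    minBarcodeQual = cfg$minBarcodeQual,
    maxLowQualBases = cfg$maxLowQualBases
  )
  stages$labeling <- labelingStats(labeled)
  paths$labeledFastq <- file.path(cfg$outDir, "labeled.fastq.gz")
  writeLabeledFastq(labeled, paths$labeledFastq)

  if (!is.null(cfg$chunkSize)) {
    paths$chunks <- splitFastq(
      paths$labeledFastq, file.path(cfg$outDir, "labeled"),
      chunkSize = cfg$chunkSize
    )
    stages$split <- list(
      n_chunks = length(paths$chunks), chunk_size = cfg$chunkSize
    )
  }

  wl <- buildWhitelist(md)
  params <- starsoloParams(layout)
  if (cfg$velocity) {
    kept <- labeled[labeled$disposition == "kept", ]
    converted <- convertReads(kept)
    tenxDir <- file.path(cfg$outDir, "tenx")
    conv <- writeConvertedFastq(converted, tenxDir, sample = cfg$sample)
    paths$convertedR1 <- unname(conv["r1"])
    paths$convertedR2 <- unname(conv["r2"])
    paths$whitelist <- file.path(tenxDir, "whitelist.txt")
    writeWhitelist(wl, paths$whitelist)
    paths$alignerParams <- file.path(tenxDir, "starsolo_params.txt")
    .writeLinesLf(renderStarsoloParams(params), paths$alignerParams)
    message("aligner parameters: ", renderStarsoloParams(params))
    stages$velocity <- list(
      n_converted = nrow(converted), whitelist_size = length(wl)
    )
  }

  counts <- NULL
  if (!is.null(cfg$samPath)) {
    aln <- readSamAlignments(cfg$samPath)
    if (all(is.na(aln$feature_id)) && !is.null(cfg$gtfPath)) {
      aln <- annotateAlignments(aln, cfg$gtfPath)
    }
    features <- if (!is.null(cfg$gtfPath)) {
      referenceFeatures(cfg$gtfPath)
    } else {
      sort(unique(stats::na.omit(aln$feature_id)))
    }
    counts <- countReads(
      aln, wl, features,
      umiMode = cfg$umiMode, maxBcDist = cfg$maxBcDist,
      mapqMin = cfg$mapqMin
    )
    paths$countsDir <- file.path(cfg$outDir, "counts")
    writeCountMatrix(counts, paths$countsDir)
    stages$demultiplex <- demuxStats(counts)
  }

  ## external tools are rendered, never executed
  cmds <- c(
    "#!/bin/sh",
    "# external aligner invocations rendered by marstools",
    sprintf(
      "bowtie2 -p 4 -x <index-prefix> -U %s -S aligned.sam",
      paths$labeledFastq
    ),
    if (cfg$velocity) {
      sprintf(
        paste(
          "STAR --soloCBwhitelist %s %s --readFilesIn %s %s",
          "--readFilesCommand zcat"
        ),
        paths$whitelist, renderStarsoloParams(params),
        paths$convertedR2, paths$convertedR1
      )
    }
  )
  paths$commands <- file.path(cfg$outDir, "commands.sh")
  .writeLinesLf(cmds, paths$commands)

  runReport <- list(
    package = "marstools",
    version = as.character(utils::packageVersion("marstools")),
    config = cfg[!vapply(cfg, is.null, logical(1L))],
    stages = stages
  )
  jsonlite::write_json(
    runReport, file.path(cfg$outDir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  txt <- c(
    sprintf("marstools %s run report", runReport$version),
    sprintf("metadata: %d seq batch(es), %d amp batch(es), %d well(s)",
      nrow(seqBatches(md)), nrow(ampBatches(md)), nrow(wellsCells(md))
    ),
    sprintf(
      "labeling: %d read pair(s), %d kept, %d discarded",
      stages$labeling$n_input, stages$labeling$n_kept,
      stages$labeling$n_input - stages$labeling$n_kept
    ),
    if (!is.null(stages$split)) {
      sprintf("split: %d chunk(s) of <= %d reads",
        stages$split$n_chunks, stages$split$chunk_size
      )
    },
    if (!is.null(stages$velocity)) {
      sprintf("velocity: %d converted pair(s), whitelist of %d",
        stages$velocity$n_converted, stages$velocity$whitelist_size
      )
    },
    if (!is.null(stages$demultiplex)) {
      sprintf(
        "demultiplex: %d alignment(s), %d counted, matrix total %d",
        stages$demultiplex$n_input, stages$demultiplex$counted,
        sum(SummarizedExperiment::assay(counts, "counts"))
      )
    }
  )
  .writeLinesLf(txt, file.path(cfg$outDir, "report.txt"))

  invisible(list(
    report = runReport, labeled = labeled, whitelist = wl,
    counts = counts, paths = paths, validation = report
  ))
}
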