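#' Simulation configuration constructor
#'
#' @param nAmpBatches,wellsPerBatch,nGenes,nErcc,readsPerWell experiment
#'   dimensions; defaults are a small two-plate experiment (2 batches of
#'   8 wells, 20 genes + 3 spike-ins, 200 reads per well).
#' @param duplicationRate mean reads per planted molecule (default 2;
#'   duplicate reads are what UMI collapse removes).
#' @param barcodeErrorRate,umiErrorRate per-base substitution rates applied
#'   to the pool/cell barcode bases and to the UMI bases of each read
#'   (default 0).
#' @param read1Len read-1 length in nt (default 75: 3 adapter + 4 pool
#'   barcode + 66 cDNA + 2 adapter).
#' @param geneLen planted transcript length in nt.
#' @param laSeq,raSeq fixed left/right adapter sequences (any fixed value
#'   satisfies the layout; defaults `"TGA"` / `"TT"`).
#' @param seed RNG seed; identical seed yields byte-identical outputs.
#' @param compress gzip FASTQ outputs (default `TRUE`).
#' @return A [MarsSimConfig-class].
#' @seealso [simulateExperiment()]
#' @export
simConfig <- function(nAmpBatches = 2L, wellsPerBatch = 8L, nGenes = 20L,
                      nErcc = 3L, readsPerWell = 200L,
                      duplicationRate = 2, barcodeErrorRate = 0,
                      umiErrorRate = 0, read1Len = 75L, geneLen = 500L,
                      laSeq = "TGA", raSeq = "TT", seed = 42L,
                      compress = TRUE) {
  new("MarsSimConfig",
    nAmpBatches = as.integer(nAmpBatches),
    wellsPerBatch = as.integer(wellsPerBatch),
    nGenes = as.integer(nGenes), nErcc = as.integer(nErcc),
    readsPerWell = as.integer(readsPerWell),
    duplicationRate = as.numeric(duplicationRate),
    barcodeErrorRate = as.numeric(barcodeErrorRate),
    umiErrorRate = as.numeric(umiErrorRate),
    read1Len = as.integer(read1Len), geneLen = as.integer(geneLen),
    laSeq = toupper(laSeq), raSeq = toupper(raSeq),
    seed = as.integer(seed), compress = isTRUE(compress)
  )
}

# Byte-deterministic FASTQ writer (R's gzfile stores no timestamp, so
# identical content means identical bytes, gzipped or not).
.writeFastqFile <- function(ids, seqs, quals, path, compress) {
  con <- if (compress) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (length(ids)) {
    writeLines(
      as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con,
      sep = "\n"
    )
  }
  invisible(path)
}

#' Simulate a complete MARS-seq experiment
#'
#' Generates every artifact the preprocessing stages consume, with a known
#' ground truth: metadata tables, paired FASTQ following the MARS-seq
#' layout (fixed left adapter, pool barcode and cDNA plus right adapter on
#' read 1; cell barcode and UMI on read 2), a toy genome FASTA + GTF
#' augmented with spike-ins via [buildReference()], an oracle SAM of
#' perfectly aligned, barcode-labeled, gene-tagged reads (so
#' demultiplexing is testable without an aligner), and the planted count
#' matrix.
#'
#' Pool and cell barcodes are drawn at pairwise Hamming distance >= 2
#' within each role (an infeasible request errors). Per well, molecules
#' (feature, UMI) are planted and reads are drawn from them with mean
#' multiplicity `duplicationRate`; cDNA is a random window of the
#' feature's planted sequence. Substitution errors (never indels — the
#' layout slices at fixed offsets) are injected into barcode and UMI
#' bases at the configured rates. The ground-truth count of a
#' (well, feature) pair is its number of distinct planted (sequenced)
#' UMIs; with error rates 0 the full pipeline reproduces this matrix
#' exactly.
#'
#' @param cfg a [MarsSimConfig-class].
#' @param outDir output directory (created; sub-directories `meta/`,
#'   `ref/`, `truth/` plus FASTQ/SAM files inside).
#' @return A list: `md` ([ExperimentMetadata-class]), `metaDir`, `r1`,
#'   `r2`, `sam`, `reference` ([ReferenceBundle-class]), `features`,
#'   `truth` ([WellCountMatrix-class], also written under `truth/`),
#'   `whitelist` ([Whitelist-class]) and `provenance` (per-read
#'   data.frame with planted and observed barcodes).
#' @examples
#' sim <- simulateExperiment(simConfig(readsPerWell = 20L), tempfile())
#' sum(SummarizedExperiment::assay(sim$truth, "counts"))
#' @export
simulateExperiment <- function(cfg, outDir) {
  stopifnot(is(cfg, "MarsSimConfig"))
  validObject(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(cfg@seed, .simulateExperimentImpl(cfg, outDir))
}

.simulateExperimentImpl <- function(cfg, outDir) {
  layout <- marsLayout(
    laLen = nchar(cfg@laSeq), raLen = nchar(cfg@raSeq)
  )
  cdnaLen <- cfg@read1Len - layout@laLen - layout@pbLen - layout@raLen

  ## barcodes: pairwise distance >= 2 within each role
  pbs <- .sampleSeparatedBarcodes(cfg@nAmpBatches, layout@pbLen, 2L)
  cbs <- .sampleSeparatedBarcodes(cfg@wellsPerBatch, layout@cbLen, 2L)

  ampIds <- sprintf("AB%02d", seq_len(cfg@nAmpBatches))
  nWells <- cfg@nAmpBatches * cfg@wellsPerBatch
  wellTable <- data.frame(
    well_id = sprintf("W%04d", seq_len(max(nWells, 0L))),
    amp_batch_id = rep(ampIds, each = cfg@wellsPerBatch),
    cell_barcode = rep(cbs, times = cfg@nAmpBatches),
    stringsAsFactors = FALSE
  )
  r1Path <- file.path(
    outDir, if (cfg@compress) "sim_R1.fastq.gz" else "sim_R1.fastq"
  )
  r2Path <- sub("_R1", "_R2", r1Path)
  md <- experimentMetadata(
    seqBatches = data.frame(
      batch_id = "SB1", run_name = "simulated", r1_path = basename(r1Path),
      r2_path = basename(r2Path), notes = ""
    ),
    ampBatches = data.frame(
      amp_batch_id = ampIds, seq_batch_id = "SB1", pool_barcode = pbs
    ),
    wells = wellTable
  )
  metaDir <- file.path(outDir, "meta")
  writeMetadata(md, metaDir)

  ## toy reference: genes tiled on one chromosome, spike-ins appended
  geneIds <- sprintf("G%04d", seq_len(cfg@nGenes))
  geneSeqs <- randomDna(cfg@nGenes, cfg@geneLen)
  spacer <- 50L
  geneStarts <- (seq_len(cfg@nGenes) - 1L) * (cfg@geneLen + spacer) + 1L
  chrParts <- character(2L * cfg@nGenes)
  if (cfg@nGenes > 0L) {
    chrParts[seq(1L, by = 2L, length.out = cfg@nGenes)] <- geneSeqs
    chrParts[seq(2L, by = 2L, length.out = cfg@nGenes)] <-
      randomDna(cfg@nGenes, spacer)
  }
  chr1 <- paste0(chrParts, collapse = "")
  genomePath <- file.path(outDir, "genome.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(
      if (nchar(chr1)) chr1 else "N", "chr1"
    )),
    genomePath, width = 60L
  )
  gtfPath <- file.path(outDir, "genes.gtf")
  gtfLines <- unlist(lapply(seq_len(cfg@nGenes), function(i) {
    attrs <- sprintf(
      "gene_id \"%s\"; transcript_id \"%s\";", geneIds[i], geneIds[i]
    )
    sprintf(
      "chr1\tsimulation\t%s\t%d\t%d\t.\t+\t.\t%s",
      c("gene", "transcript", "exon"), geneStarts[i],
      geneStarts[i] + cfg@geneLen - 1L, attrs
    )
  }))
  .writeLinesLf(
    c("#!genome-build simulated-toy", gtfLines), gtfPath
  )
  erccSeqs <- randomDna(cfg@nErcc, cfg@geneLen)
  ercc <- Biostrings::DNAStringSet(erccSeqs)
  names(ercc) <- sprintf("ERCC-%05d", seq_len(cfg@nErcc))
  reference <- buildReference(
    genomePath, gtfPath, ercc, file.path(outDir, "ref")
  )

  features <- c(geneIds, names(ercc))
  featSeq <- c(geneSeqs, erccSeqs)
  featRname <- c(rep("chr1", cfg@nGenes), names(ercc))
  featOffset <- c(geneStarts, rep(1L, cfg@nErcc))

  ## plant molecules, then reads with mean multiplicity duplicationRate
  nReadsTotal <- nWells * cfg@readsPerWell
  if (nReadsTotal > 0L && length(features) == 0L) {
    stop("cannot simulate reads without any features")
  }
  wellIdx <- rep(seq_len(nWells), each = cfg@readsPerWell)
  featOfRead <- integer(0L)
  umiOfRead <- character(0L)
  if (nReadsTotal > 0L) {
    nMol <- max(1L, as.integer(round(cfg@readsPerWell / cfg@duplicationRate)))
    featOfRead <- integer(nReadsTotal)
    umiOfRead <- character(nReadsTotal)
    for (w in seq_len(nWells)) {
      molFeat <- sample.int(length(features), nMol, replace = TRUE)
      molUmi <- randomDna(nMol, layout@umiLen)
      pick <- sample.int(nMol, cfg@readsPerWell, replace = TRUE)
      rows <- (w - 1L) * cfg@readsPerWell + seq_len(cfg@readsPerWell)
      featOfRead[rows] <- molFeat[pick]
      umiOfRead[rows] <- molUmi[pick]
    }
  }

  insertStart <- if (nReadsTotal > 0L) {
    sample.int(cfg@geneLen - cdnaLen + 1L, nReadsTotal, replace = TRUE)
  } else {
    integer()
  }
  cdna <- substr(
    featSeq[featOfRead], insertStart, insertStart + cdnaLen - 1L
  )

  pbOfRead <- md@ampBatches$pool_barcode[
    match(wellTable$amp_batch_id[wellIdx], md@ampBatches$amp_batch_id)
  ]
  cbOfRead <- wellTable$cell_barcode[wellIdx]
  pbObs <- .mutateBases(pbOfRead, cfg@barcodeErrorRate)
  cbObs <- .mutateBases(cbOfRead, cfg@barcodeErrorRate)
  umiObs <- .mutateBases(umiOfRead, cfg@umiErrorRate)

  readIds <- sprintf("SIM.%07d", seq_len(nReadsTotal))
  r1Seq <- paste0(cfg@laSeq, pbObs, cdna, cfg@raSeq)
  r2Seq <- paste0(cbObs, umiObs)
  q1 <- strrep("I", cfg@read1Len)
  q2 <- strrep("I", layout@cbLen + layout@umiLen)
  .writeFastqFile(
    readIds, r1Seq, rep(q1, nReadsTotal), r1Path, cfg@compress
  )
  .writeFastqFile(
    readIds, r2Seq, rep(q2, nReadsTotal), r2Path, cfg@compress
  )

  ## oracle SAM: perfect alignments of the labeled cDNA, gene-tagged
  samPath <- file.path(outDir, "aligned.sam")
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:chr1\tLN:%d", max(nchar(chr1), 1L)),
    sprintf("@SQ\tSN:%s\tLN:%d", names(ercc), Biostrings::width(ercc)),
    "@PG\tID:marstools-sim\tPN:marstools-sim"
  )
  records <- if (nReadsTotal > 0L) {
    sprintf(
      "%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tGX:Z:%s",
      paste(readIds, pbObs, cbObs, umiObs, sep = ":"),
      featRname[featOfRead], featOffset[featOfRead] + insertStart - 1L,
      cdnaLen, cdna, strrep("I", cdnaLen), features[featOfRead]
    )
  } else {
    character()
  }
  .writeLinesLf(c(header, records), samPath)

  ## ground truth: distinct planted (well, feature, UMI) triples
  wl <- buildWhitelist(md)
  triples <- unique(data.frame(
    well = wellTable$well_id[wellIdx], feat = features[featOfRead],
    umi = umiOfRead, stringsAsFactors = FALSE
  ))
  truthMat <- Matrix::sparseMatrix(
    i = match(triples$feat, features),
    j = match(triples$well, wellTable$well_id),
    x = rep(1L, nrow(triples)),
    dims = c(length(features), nWells),
    dimnames = list(features, wellTable$well_id)
  )
  truth <- new(
    "WellCountMatrix",
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = truthMat),
      colData = S4Vectors::DataFrame(
        well_id = wellTable$well_id,
        amp_batch_id = wellTable$amp_batch_id,
        row.names = wellTable$well_id
      )
    )
  )
  S4Vectors::metadata(truth)$stats <- list(
    n_input = nReadsTotal, counted = nReadsTotal
  )
  writeCountMatrix(truth, file.path(outDir, "truth"))

  provenance <- data.frame(
    read_id = readIds,
    well_id = wellTable$well_id[wellIdx],
    feature_id = features[featOfRead],
    umi = umiOfRead, pb = pbOfRead, cb = cbOfRead,
    pb_obs = pbObs, cb_obs = cbObs, umi_obs = umiObs,
    stringsAsFactors = FALSE
  )
  utils::write.table(
    provenance, file.path(outDir, "provenance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  list(
    md = md, metaDir = metaDir, r1 = r1Path, r2 = r2Path, sam = samPath,
    reference = reference, features = features, truth = truth,
    whitelist = wl, provenance = provenance, layout = layout
  )
}
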