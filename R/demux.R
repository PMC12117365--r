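#' Match observed composite barcodes against a whitelist
#'
#' An observed barcode that is a whitelist member is assigned to its well
#' at distance 0. With `maxDist = 1`, a non-member that sits at Hamming
#' distance 1 from exactly one whitelist entry is rescued as a corrected
#' assignment; a tie (two or more entries at distance 1) or any barcode at
#' distance >= 2 stays unassigned — correcting a tie would fabricate a
#' well identity. The strict default (`maxDist = 0`) counts only exact
#' members.
#'
#' @param observed character vector of composite barcodes, each the
#'   whitelist's entry length, over `{A,C,G,T,N}` (an `N` never matches
#'   exactly and counts as one mismatch).
#' @param wl a [Whitelist-class].
#' @param maxDist 0 (strict) or 1 (one-substitution correction).
#' @return A [S4Vectors::DataFrame] with `observed`, `well_id`
#'   (`NA` when unassigned), `corrected` and `distance` (`NA` when
#'   unassigned).
#' @examples
#' wl <- buildWhitelist(exampleMetadata())
#' assignBarcodes(whitelistEntries(wl)[1], wl)
#' @export
assignBarcodes <- function(observed, wl, maxDist = 0L) {
  stopifnot(is(wl, "Whitelist"), maxDist %in% c(0L, 1L))
  entryLen <- if (length(wl@entries)) nchar(wl@entries[1L]) else 0L
  if (length(observed) && any(nchar(observed) != entryLen)) {
    bad <- observed[nchar(observed) != entryLen][1L]
    stop(
      "malformed composite barcode \"", bad, "\": expected length ",
      entryLen
    )
  }
  if (length(observed) && any(grepl("[^ACGTN]", observed))) {
    stop("composite barcodes must be over {A,C,G,T,N}")
  }

  hit <- match(observed, wl@entries)
  well <- wl@wellIds[hit]
  corrected <- rep(FALSE, length(observed))
  distance <- ifelse(is.na(hit), NA_integer_, 0L)

  if (maxDist == 1L) {
    miss <- unique(observed[is.na(hit)])
    for (bc in miss) {
      neighborHits <- match(.hamming1Variants(bc), wl@entries)
      neighborHits <- neighborHits[!is.na(neighborHits)]
      if (length(neighborHits) == 1L) {
        idx <- observed == bc
        well[idx] <- wl@wellIds[neighborHits]
        corrected[idx] <- TRUE
        distance[idx] <- 1L
      }
    }
  }
  S4Vectors::DataFrame(
    observed = observed, well_id = well, corrected = corrected,
    distance = distance
  )
}

#' Collapse a multiset of UMIs into molecule classes
#'
#' `exact` mode counts distinct UMI strings. `directional` mode treats a
#' low-count UMI one substitution away from a higher-count neighbor as a
#' sequencing-error lineage of that neighbor: a directed merge `u -> v` is
#' allowed when the UMIs are at Hamming distance 1 and
#' `count(u) >= 2 * count(v) - 1`; the count is the number of connected
#' components after following such merges transitively from the
#' highest-count UMIs downward. Directional counts are therefore never
#' larger than exact counts.
#'
#' @param umis character vector (a multiset) of equal-length UMIs.
#' @param mode `"exact"` or `"directional"`.
#' @return Integer molecule count; 0 for an empty multiset.
#' @examples
#' collapseUmis(c(rep("AAAAAAAA", 9), "AAAAAAAC"), "exact") # 2
#' collapseUmis(c(rep("AAAAAAAA", 9), "AAAAAAAC"), "directional") # 1
#' @export
collapseUmis <- function(umis, mode = c("exact", "directional")) {
  mode <- match.arg(mode)
  if (length(umis) == 0L) return(0L)
  if (length(unique(nchar(umis))) != 1L) {
    stop("all UMIs in one multiset must have the same length")
  }
  if (mode == "exact") return(length(unique(umis)))

  tab <- table(umis)
  # deterministic processing order: count descending, sequence as tie-break
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  seqs <- names(tab)[ord]
  counts <- as.integer(tab)[ord]
  n <- length(seqs)
  if (n == 1L) return(1L)

  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  visited <- logical(n)
  components <- 0L
  for (root in seq_len(n)) {
    if (visited[root]) next
    components <- components + 1L
    queue <- root
    visited[root] <- TRUE
    while (length(queue)) {
      u <- queue[1L]
      queue <- queue[-1L]
      cand <- which(!visited)
      if (length(cand) == 0L) break
      d1 <- cand[rowSums(
        mat[cand, , drop = FALSE] !=
          matrix(mat[u, ], length(cand), ncol(mat), byrow = TRUE)
      ) == 1L]
      mergeable <- d1[counts[u] >= 2L * counts[d1] - 1L]
      if (length(mergeable)) {
        visited[mergeable] <- TRUE
        queue <- c(queue, mergeable)
      }
    }
  }
  components
}

# strip secondary/supplementary records so the stream has one record per
# aligned read
.SAM_FLAG_UNMAPPED <- 4L
.SAM_FLAG_SECONDARY <- 256L
.SAM_FLAG_SUPPLEMENTARY <- 2048L

#' Read a SAM/BAM alignment stream for demultiplexing
#'
#' Loads the fields demultiplexing needs: read name (carrying the barcode
#' label), mapped flag, position, MAPQ and the per-read gene tag (`GX` by
#' default; a tag value holding several `;`-separated genes marks the read
#' as ambiguous). Secondary and supplementary records are dropped so each
#' read contributes one record. SAM text is converted through the
#' standard BAM route internally.
#'
#' @param path SAM or BAM file.
#' @param featureTag two-letter tag holding the assigned gene/spike-in id.
#' @return data.frame with `read_id`, `mapped`, `rname`, `pos`, `strand`,
#'   `cigar`, `mapq`, `feature_id` (`NA` when absent or ambiguous) and
#'   `ambiguous`.
#' @seealso [annotateAlignments()] for SAMs lacking gene tags,
#'   [countReads()]
#' @export
readSamAlignments <- function(path, featureTag = "GX") {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest,
      overwrite = TRUE, indexDestination = FALSE
    )
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "strand", "mapq", "cigar"),
      tag = featureTag
    )
  )[[1L]]
  flag <- res$flag
  keep <- bitwAnd(flag, .SAM_FLAG_SECONDARY + .SAM_FLAG_SUPPLEMENTARY) == 0L
  tag <- res$tag[[featureTag]]
  if (is.null(tag)) tag <- rep(NA_character_, length(res$qname))
  mapped <- bitwAnd(flag, .SAM_FLAG_UNMAPPED) == 0L
  ambiguous <- mapped & !is.na(tag) & grepl(";", tag, fixed = TRUE)
  feature <- ifelse(mapped & !ambiguous, tag, NA_character_)
  data.frame(
    read_id = res$qname, mapped = mapped,
    rname = as.character(res$rname), pos = res$pos,
    strand = as.character(res$strand), cigar = res$cigar,
    mapq = res$mapq, feature_id = feature, ambiguous = ambiguous,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
}

#' Annotate alignments by exon overlap
#'
#' For alignment streams without per-read gene tags: assigns each mapped
#' read the gene whose exons it overlaps (GTF coordinates, 1-based
#' inclusive), strand-aware by default. A read overlapping exons of two or
#' more distinct genes is marked ambiguous; a read overlapping none gets
#' no feature.
#'
#' @param aln the data.frame from [readSamAlignments()].
#' @param gtfPath the (ERCC-augmented) annotation GTF.
#' @param strandAware require the read and the gene to be on the same
#'   strand (default `TRUE`).
#' @return `aln` with `feature_id` and `ambiguous` recomputed.
#' @export
annotateAlignments <- function(aln, gtfPath, strandAware = TRUE) {
  gtf <- rtracklayer::import(gtfPath, format = "gtf")
  exons <- gtf[gtf$type == "exon"]
  idx <- which(aln$mapped & !is.na(aln$pos))
  aln$feature_id <- NA_character_
  aln$ambiguous <- FALSE
  if (length(idx) == 0L || length(exons) == 0L) return(aln)
  widths <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    aln$cigar[idx]
  )
  reads <- GenomicRanges::GRanges(
    seqnames = aln$rname[idx],
    ranges = IRanges::IRanges(start = aln$pos[idx], width = widths),
    strand = if (strandAware) aln$strand[idx] else "*"
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    reads, exons, ignore.strand = !strandAware
  ))
  genes <- split(
    exons$gene_id[S4Vectors::subjectHits(hits)],
    S4Vectors::queryHits(hits)
  )
  nGene <- vapply(genes, function(g) length(unique(g)), integer(1L))
  qi <- as.integer(names(genes))
  one <- qi[nGene == 1L]
  aln$feature_id[idx[one]] <- vapply(
    genes[nGene == 1L], function(g) g[[1L]], character(1L)
  )
  aln$ambiguous[idx[qi[nGene > 1L]]] <- TRUE
  aln
}

#' Ordered feature ids of a reference annotation
#'
#' Unique `gene_id`s in GTF order; with an ERCC-augmented reference built
#' by [buildReference()] this yields genes first, spike-ins last — the
#' feature ordering of the count matrix.
#'
#' @param gtfPath annotation GTF.
#' @return character vector of feature ids.
#' @export
referenceFeatures <- function(gtfPath) {
  gtf <- rtracklayer::import(gtfPath, format = "gtf")
  unique(gtf$gene_id[!is.na(gtf$gene_id)])
}

.parseLabels <- function(readIds, compositeLen, delim = ":") {
  parts <- strsplit(readIds, delim, fixed = TRUE)
  np <- lengths(parts)
  bad <- which(np < 4L)
  if (length(bad)) {
    stop(
      "cannot parse barcode label from read id \"", readIds[bad[1L]],
      "\": expected <id>", delim, "PB", delim, "CB", delim, "UMI"
    )
  }
  pb <- mapply(function(p, k) p[k - 2L], parts, np)
  cb <- mapply(function(p, k) p[k - 1L], parts, np)
  umi <- mapply(function(p, k) p[k], parts, np)
  composite <- paste0(pb, cb)
  bad <- which(nchar(composite) != compositeLen | umi == "")
  if (length(bad)) {
    stop(
      "cannot parse barcode label from read id \"", readIds[bad[1L]],
      "\": barcode segments do not match the whitelist geometry"
    )
  }
  list(composite = composite, umi = unname(umi))
}

#' Demultiplex aligned reads into a well-by-feature count matrix
#'
#' Each alignment's read name carries the `PB:CB:UMI` label planted during
#' read labeling. The pool+cell composite is matched against the
#' whitelist ([assignBarcodes()]); unmapped reads, reads below the MAPQ
#' threshold, ambiguous (multi-gene) reads, featureless reads and reads
#' with an unassignable barcode are excluded and tallied. Per
#' (well, feature), the count is the number of UMI classes after
#' [collapseUmis()] in the requested mode. The matrix always spans every
#' whitelist well and every reference feature; the tallies in
#' `demuxStats()` satisfy `n_input = counted + sum(excluded)`.
#'
#' @param alignments data.frame from [readSamAlignments()] (optionally
#'   passed through [annotateAlignments()]).
#' @param wl a [Whitelist-class].
#' @param features ordered feature ids spanning the reference (see
#'   [referenceFeatures()]); observed features outside this set are
#'   tallied as `unknown_feature` and excluded.
#' @param umiMode `"exact"` (default) or `"directional"`.
#' @param maxBcDist barcode-correction radius, 0 (default) or 1.
#' @param mapqMin minimum MAPQ (default 0, no filter).
#' @param delim label delimiter used at labeling time.
#' @return A [WellCountMatrix-class].
#' @seealso [writeCountMatrix()], [demuxStats()]
#' @export
countReads <- function(alignments, wl, features,
                       umiMode = c("exact", "directional"),
                       maxBcDist = 0L, mapqMin = 0L, delim = ":") {
  umiMode <- match.arg(umiMode)
  stopifnot(is(wl, "Whitelist"))
  if (length(wl@entries) == 0L) stop("whitelist is empty")
  wells <- wl@wellIds

  n <- nrow(alignments)
  stats <- list(
    n_input = n, unmapped = 0L, low_mapq = 0L, ambiguous = 0L,
    no_feature = 0L, unknown_feature = 0L, unassigned_barcode = 0L,
    counted = 0L
  )

  active <- rep(TRUE, n)
  drop <- function(which, key) {
    stats[[key]] <<- stats[[key]] + sum(which)
    active[which] <<- FALSE
  }
  drop(active & !alignments$mapped, "unmapped")
  drop(
    active & !is.na(alignments$mapq) & alignments$mapq < mapqMin,
    "low_mapq"
  )
  drop(active & alignments$ambiguous, "ambiguous")
  drop(active & is.na(alignments$feature_id), "no_feature")
  drop(active & !alignments$feature_id %in% features, "unknown_feature")

  compositeLen <- nchar(wl@entries[1L])
  well <- rep(NA_character_, n)
  umi <- rep(NA_character_, n)
  if (any(active)) {
    lab <- .parseLabels(
      alignments$read_id[active], compositeLen, delim
    )
    asg <- assignBarcodes(lab$composite, wl, maxDist = maxBcDist)
    well[active] <- asg$well_id
    umi[active] <- lab$umi
  }
  drop(active & is.na(well), "unassigned_barcode")
  stats$counted <- sum(active)

  feat <- alignments$feature_id
  key <- paste(well[active], feat[active], sep = "\r")
  umiSets <- split(umi[active], key)
  counts <- vapply(
    umiSets, collapseUmis, integer(1L),
    mode = umiMode
  )
  parts <- strsplit(names(umiSets), "\r", fixed = TRUE)
  wIdx <- match(vapply(parts, `[`, character(1L), 1L), wells)
  fIdx <- match(vapply(parts, `[`, character(1L), 2L), features)

  mat <- Matrix::sparseMatrix(
    i = fIdx, j = wIdx, x = counts,
    dims = c(length(features), length(wells)),
    dimnames = list(features, wells)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(
      well_id = wells, amp_batch_id = wl@ampBatchIds,
      row.names = wells
    )
  )
  out <- new("WellCountMatrix", se)
  S4Vectors::metadata(out)$stats <- stats
  S4Vectors::metadata(out)$umi_mode <- umiMode
  out
}

#' Write / read a count matrix directory
#'
#' The ecosystem-standard sparse triplet exchange layout: `matrix.mtx`
#' (MatrixMarket, features x wells), `features.tsv`, `barcodes.tsv` (well
#' ids), plus `stats.json` with the demultiplexing tallies. Matrices with
#' at most `denseLimit` entries are additionally written as a dense
#' `counts.tsv` for eyeballing.
#'
#' @param x a [WellCountMatrix-class].
#' @param outDir output directory (created if absent).
#' @param denseLimit write `counts.tsv` when `nrow * ncol <= denseLimit`.
#' @return `writeCountMatrix`: invisibly, `outDir`. `readCountMatrix`: a
#'   [WellCountMatrix-class].
#' @export
writeCountMatrix <- function(x, outDir, denseLimit = 100000L) {
  stopifnot(is(x, "WellCountMatrix"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  m <- SummarizedExperiment::assay(x, "counts")
  Matrix::writeMM(m, file.path(outDir, "matrix.mtx"))
  .writeLinesLf(rownames(m), file.path(outDir, "features.tsv"))
  .writeLinesLf(colnames(m), file.path(outDir, "barcodes.tsv"))
  st <- S4Vectors::metadata(x)$stats
  if (!is.null(st)) {
    jsonlite::write_json(
      st, file.path(outDir, "stats.json"),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  if (as.double(nrow(m)) * ncol(m) <= denseLimit) {
    dense <- as.matrix(m)
    utils::write.table(
      data.frame(feature = rownames(m), dense, check.names = FALSE),
      file.path(outDir, "counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(outDir)
}

#' @rdname writeCountMatrix
#' @param dir a directory written by `writeCountMatrix`.
#' @export
readCountMatrix <- function(dir) {
  m <- methods::as(
    Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix"
  )
  feats <- readLines(file.path(dir, "features.tsv"))
  wells <- readLines(file.path(dir, "barcodes.tsv"))
  dimnames(m) <- list(feats, wells)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(well_id = wells, row.names = wells)
  )
  out <- new("WellCountMatrix", se)
  statsPath <- file.path(dir, "stats.json")
  if (file.exists(statsPath)) {
    S4Vectors::metadata(out)$stats <- jsonlite::read_json(
      statsPath,
      simplifyVector = TRUE
    )
  }
  out
}
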