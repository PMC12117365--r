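#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   width
NULL

# Run expr with a private RNG stream, leaving the caller's stream intact.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.checkErccSet <- function(ercc) {
  ids <- names(ercc)
  if (is.null(ids) || any(ids == "")) {
    stop("every ERCC record needs a non-empty id")
  }
  if (anyDuplicated(ids)) {
    stop(
      "duplicate ERCC id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  if (any(Biostrings::width(ercc) == 0L)) {
    stop("ERCC sequences must be non-empty")
  }
  bad <- grepl("[^ACGTN]", as.character(ercc))
  if (any(bad)) {
    stop(
      "ERCC sequence(s) outside alphabet {A,C,G,T,N}: ",
      paste(ids[bad], collapse = ", ")
    )
  }
  invisible(ercc)
}

#' Read an ERCC spike-in sequence set
#'
#' Accepts either a FASTA file or the consortium's tab-delimited definition
#' table (a header line naming an `ERCC_ID` column and a `Sequence`
#' column). The standard consortium set contains 92 control sequences.
#'
#' @param path path to the spike-in definition file.
#' @return A named [Biostrings::DNAStringSet] of spike-in sequences.
#' @seealso [buildReference()], [erccSyntheticSet()]
#' @export
readErccSet <- function(path) {
  if (!file.exists(path)) stop("ERCC file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    ercc <- Biostrings::readDNAStringSet(path)
    names(ercc) <- sub("[ \t].*$", "", names(ercc))
  } else {
    df <- utils::read.delim(path, colClasses = "character",
      check.names = FALSE)
    idCol <- grep("ERCC.?ID", colnames(df), ignore.case = TRUE)
    seqCol <- grep("^Sequence$", colnames(df), ignore.case = TRUE)
    if (length(idCol) == 0L || length(seqCol) == 0L) {
      stop(
        "tab-delimited ERCC definition needs an 'ERCC_ID' and a ",
        "'Sequence' column"
      )
    }
    ercc <- Biostrings::DNAStringSet(toupper(trimws(df[[seqCol[1L]]])))
    names(ercc) <- trimws(df[[idCol[1L]]])
  }
  .checkErccSet(ercc)
}

#' Deterministic synthetic spike-in set
#'
#' Generates a reproducible set of synthetic spike-in sequences with
#' consortium-style ids (`ERCC-00001`, ...). This is a synthetic stand-in
#' with the same cardinality and shape as the consortium set (92 records by
#' default), intended for tests, examples and offline runs; real
#' experiments should supply the consortium file via [readErccSet()].
#'
#' @param n number of spike-ins (default 92, the size of the standard set).
#' @param minLen,maxLen sequence length range in nt.
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return A named [Biostrings::DNAStringSet].
#' @export
erccSyntheticSet <- function(n = 92L, minLen = 300L, maxLen = 600L,
                             seed = 1948L) {
  .withSeed(seed, {
    lens <- if (n > 0L) {
      sample(seq.int(minLen, maxLen), n, replace = TRUE)
    } else {
      integer()
    }
    seqs <- vapply(lens, function(L) randomDna(1L, L), character(1L))
    ercc <- Biostrings::DNAStringSet(seqs)
    names(ercc) <- sprintf("ERCC-%05d", seq_len(n))
    ercc
  })
}

# Light structural validation of a GTF: 9 tab-separated fields with
# numeric, ordered coordinates on every non-comment line.
.checkGtfLines <- function(lines) {
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "" || startsWith(line, "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop(
        "cannot parse GTF line ", i, ": expected 9 tab-separated fields, ",
        "found ", length(fields)
      )
    }
    start <- suppressWarnings(as.integer(fields[4L]))
    end <- suppressWarnings(as.integer(fields[5L]))
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      stop("cannot parse GTF line ", i, ": bad coordinates")
    }
  }
  invisible(lines)
}

.erccGtfLines <- function(ercc) {
  if (length(ercc) == 0L) return(character())
  ids <- names(ercc)
  lens <- Biostrings::width(ercc)
  unlist(lapply(seq_along(ids), function(i) {
    attrs <- sprintf(
      "gene_id \"%s\"; transcript_id \"%s\";", ids[i], ids[i]
    )
    sprintf(
      "%s\tERCC\t%s\t1\t%d\t.\t+\t.\t%s",
      ids[i], c("gene", "transcript", "exon"), lens[i], attrs
    )
  }))
}

#' Append ERCC spike-ins to a genome reference
#'
#' Appends one FASTA record per spike-in after the genome records
#' (preserving genome record order and sequence content) and adds, per
#' spike-in, `gene`/`transcript`/`exon` annotation lines spanning the full
#' spike-in length on the `+` strand with `gene_id` = `transcript_id` = the
#' spike-in id. Spike-ins are synthetic unspliced transcripts, so they are
#' annotated as single-exon features; coordinates are 1-based inclusive
#' with start 1 and end the sequence length. The aligner indexes themselves
#' are built externally — see [renderIndexCommands()] for ready-to-run
#' command strings.
#'
#' @param genomeFasta path to the genome FASTA.
#' @param annotationGtf path to the gene annotation GTF.
#' @param ercc a named [Biostrings::DNAStringSet] or a path accepted by
#'   [readErccSet()].
#' @param outDir output directory (created if absent).
#' @param name basename for the augmented `<name>.fa` / `<name>.gtf`.
#' @return A [ReferenceBundle-class] with the output paths and tallies.
#' @examples
#' dir <- tempfile()
#' dir.create(dir)
#' genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 30),
#'   collapse = "")))
#' Biostrings::writeXStringSet(genome, file.path(dir, "g.fa"))
#' writeLines(
#'   paste("chr1", "toy", "exon", "1", "120", ".", "+", ".",
#'     "gene_id \"g1\"; transcript_id \"g1\";", sep = "\t"),
#'   file.path(dir, "g.gtf")
#' )
#' bundle <- buildReference(
#'   file.path(dir, "g.fa"), file.path(dir, "g.gtf"),
#'   erccSyntheticSet(3), dir
#' )
#' nSpikeins(bundle)
#' @export
buildReference <- function(genomeFasta, annotationGtf, ercc, outDir,
                           name = "reference") {
  if (is.character(ercc)) ercc <- readErccSet(ercc)
  stopifnot(is(ercc, "DNAStringSet"))
  if (length(ercc)) .checkErccSet(ercc)

  genome <- Biostrings::readDNAStringSet(genomeFasta)
  genomeIds <- sub("[ \t].*$", "", names(genome))
  clash <- intersect(genomeIds, names(ercc))
  if (length(clash)) {
    stop(
      "genome sequence id(s) collide with ERCC id(s): ",
      paste(clash, collapse = ", ")
    )
  }

  gtfLines <- sub("\r$", "", readLines(annotationGtf))
  .checkGtfLines(gtfLines)

  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fastaPath <- file.path(outDir, paste0(name, ".fa"))
  gtfPath <- file.path(outDir, paste0(name, ".gtf"))

  Biostrings::writeXStringSet(c(genome, ercc), fastaPath, width = 60L)
  .writeLinesLf(
    c(gtfLines[gtfLines != ""], .erccGtfLines(ercc)), gtfPath
  )

  new("ReferenceBundle",
    fastaPath = fastaPath, gtfPath = gtfPath,
    nGenomeSeqs = length(genome), nSpikeins = length(ercc)
  )
}

#' Render aligner index-building command strings
#'
#' The package stops at the augmented FASTA/GTF; index construction belongs
#' to the aligners. This renders the ready-to-run commands for a Bowtie2
#' index (the classic MARS-seq aligner) and a STAR genome (used for the
#' splice-aware RNA-velocity route).
#'
#' @param bundle a [ReferenceBundle-class].
#' @param indexDir directory the commands will write indexes into.
#' @param threads thread count rendered into the commands.
#' @return Named character vector of shell command strings.
#' @export
renderIndexCommands <- function(bundle, indexDir = "index", threads = 4L) {
  stopifnot(is(bundle, "ReferenceBundle"))
  c(
    bowtie2 = sprintf(
      "bowtie2-build --threads %d %s %s/genome", threads,
      bundle@fastaPath, indexDir
    ),
    star = sprintf(
      paste(
        "STAR --runMode genomeGenerate --runThreadN %d",
        "--genomeDir %s/star --genomeFastaFiles %s --sjdbGTFfile %s"
      ),
      threads, indexDir, bundle@fastaPath, bundle@gtfPath
    )
  )
}
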