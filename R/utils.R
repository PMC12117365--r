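DNA_BASES4 <- c("A", "C", "G", "T")

#' Random DNA strings
#'
#' Uniform i.i.d. nucleotide strings over A/C/G/T, used by the simulator and
#' the property-test fixtures.
#'
#' @param n number of strings.
#' @param len length of each string.
#' @return character vector of `n` strings of `len` nt.
#' @export
randomDna <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(DNA_BASES4, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# All Hamming-distance-1 variants of one barcode over {A,C,G,T}; excludes
# the input itself. For a length-L input over ACGT this is 3L strings; a
# non-ACGT base (e.g. N) contributes 4 variants at its position, all at
# distance 1 from the input.
.hamming1Variants <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  out <- character(0L)
  for (i in seq_along(chars)) {
    for (b in DNA_BASES4) {
      if (b != chars[i]) {
        y <- chars
        y[i] <- b
        out <- c(out, paste0(y, collapse = ""))
      }
    }
  }
  unique(out)
}

# Hamming distance between equal-length strings; vectorized over y.
.hammingDist <- function(x, y) {
  xc <- strsplit(x, "", fixed = TRUE)[[1L]]
  vapply(
    strsplit(y, "", fixed = TRUE),
    function(yc) sum(xc != yc), integer(1L)
  )
}

# Greedy sample of n barcodes of length len with pairwise Hamming
# distance >= minDist. Errors when the space cannot accommodate n codes.
.sampleSeparatedBarcodes <- function(n, len, minDist = 2L,
                                     maxTries = 5000L) {
  if (n == 0L) return(character())
  if (n > 4^len) {
    stop("cannot draw ", n, " distinct barcodes of length ", len)
  }
  chosen <- character(0L)
  tries <- 0L
  while (length(chosen) < n) {
    cand <- randomDna(1L, len)
    ok <- if (length(chosen) == 0L) {
      TRUE
    } else {
      all(.hammingDist(cand, chosen) >= minDist)
    }
    if (ok) {
      chosen <- c(chosen, cand)
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > maxTries) {
        stop(
          "barcode space exhausted: cannot place ", n,
          " codes of length ", len, " at pairwise distance >= ", minDist
        )
      }
    }
  }
  chosen
}

# Per-base substitution noise at rate p; substitutions only, never the
# original base, so every hit is a true mismatch.
.mutateBases <- function(seqs, p) {
  if (p <= 0 || length(seqs) == 0L) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- stats::runif(length(flat)) < p
  if (any(hit)) {
    repl <- vapply(
      flat[hit],
      function(b) sample(setdiff(DNA_BASES4, b), 1L),
      character(1L),
      USE.NAMES = FALSE
    )
    flat[hit] <- repl
  }
  vapply(
    split(flat, rep(seq_along(lens), lens)),
    paste0, character(1L),
    collapse = "", USE.NAMES = FALSE
  )
}

# Strip a mate suffix (/1, /2) and any comment after whitespace from a
# FASTQ read id, leaving the pairing key.
.pairKey <- function(ids) {
  sub("/[12]$", "", sub("[ \t].*$", "", ids))
}

.writeLinesLf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
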