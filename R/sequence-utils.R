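# Low-level sequence encoding shared by the hexamer, scanning and GC modules.
# Genomes are handled as named character vectors (one element per contig) with
# 0-based half-open coordinates everywhere, matching BED semantics.

BASES <- c("A", "C", "G", "T")

# ASCII lookup: A/a->1, C/c->2, G/g->3, T/t->4, everything else NA
.base_lut <- local({
  lut <- rep(NA_integer_, 127L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut
})

#' Encode a DNA string as integers 1..4 (A,C,G,T), NA for other letters
#' @param seq single character string.
#' @return integer vector of length `nchar(seq)`.
#' @keywords internal
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  .base_lut[utf8ToInt(seq)]
}

#' Hexamer codes along an encoded sequence
#'
#' Position `i` (1-based) holds the code (1..4096) of the 6-mer starting at
#' `i`; windows containing a non-ACGT base are NA. Codes are
#' `1 + sum (base-1) * 4^(5..0)`, i.e. AAAAAA = 1, TTTTTT = 4096.
#'
#' @param enc integer vector from [encode_seq()].
#' @return integer vector of length `length(enc) - 5` (empty if shorter).
#' @keywords internal
hexamer_codes <- function(enc) {
  n <- length(enc) - 5L
  if (n < 1L) return(integer(0))
  code <- integer(n)
  for (k in 0:5) {
    code <- code + (enc[(1L + k):(n + k)] - 1L) * 4L^(5L - k)
  }
  code + 1L
}

#' Reverse-complement lookup for hexamer codes
#'
#' `hexamer_revcomp_table()[h]` is the code of the reverse complement of the
#' hexamer with code `h`.
#' @return integer vector of length 4096.
#' @keywords internal
hexamer_revcomp_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    h <- 0:4095
    rc <- integer(4096)
    for (k in 0:5) {
      base <- (h %/% 4L^(5L - k)) %% 4L      # base at position k, 0..3
      rc <- rc + (3L - base) * 4L^k          # complement, reversed order
    }
    tab <<- rc + 1L
    tab
  }
})

#' Spell out a hexamer code as a string (for logs and tables)
#' @keywords internal
hexamer_string <- function(code) {
  stopifnot(all(code >= 1L & code <= 4096L))
  vapply(code, function(h) {
    h <- h - 1L
    paste(BASES[(h %/% 4L^(5:0)) %% 4L + 1L], collapse = "")
  }, character(1))
}

#' Reverse complement of a DNA string
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read a genome from FASTA into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector, one element per contig.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- as.character(ss)
  names(g) <- sub("\\s.*$", "", names(ss))
  g
}

#' Write a genome (named character vector) as FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Coerce a single-contig argument: plain unnamed string becomes contig "chr1"
.as_genome <- function(genome) {
  stopifnot(is.character(genome))
  if (is.null(names(genome))) {
    if (length(genome) != 1L)
      stop("multi-contig genomes must be named")
    names(genome) <- "chr1"
  }
  genome
}

# intervals: data.frame with chrom, start, end (0-based half-open)
.as_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop(sprintf("invalid %s at row %d: start=%s end=%s", what, bad[1],
                 df$start[bad[1]], df$end[bad[1]]))
  if (any(!nzchar(df$chrom))) stop("empty chromosome name")
  invisible(df)
}
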