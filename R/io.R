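# Readers and writers for the plain-text formats the pipeline consumes and
# produces. All coordinates on disk follow BED semantics (0-based half-open);
# they are used unshifted internally.

#' Read a narrowPeak file
#'
#' Standard 10-column narrowPeak; the summit is `start + column 10`. A
#' summit offset of -1 (caller did not report one) falls back to the
#' interval midpoint, with a message.
#'
#' @param path file path.
#' @return data.frame chrom, start, end, name, score, strand, summit
#'   (absolute 0-based).
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 10L) stop("narrowPeak needs 10 columns, got ", ncol(df))
  names(df)[1:10] <- c("chrom", "start", "end", "name", "score", "strand",
                       "signal", "pvalue", "qvalue", "peak_offset")
  nosummit <- df$peak_offset < 0
  if (any(nosummit)) {
    message(sum(nosummit), " record(s) without summit; using interval midpoint")
    df$peak_offset[nosummit] <- (df$end - df$start)[nosummit] %/% 2L
  }
  df$summit <- df$start + df$peak_offset
  .validate_intervals(df, "narrowPeak record")
  df[, c("chrom", "start", "end", "name", "score", "strand", "summit")]
}

#' Read a BED3+ file into an interval data.frame
#' @param path file path.
#' @return data.frame chrom, start, end (extra columns kept unnamed).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  .validate_intervals(df, "BED record")
  df
}

#' Read / write a cut-site track
#'
#' BED-like TSV: chrom, 0-based position, position + 1, strand.
#'
#' @param path file path.
#' @return data.frame chrom, pos, strand.
#' @export
read_cuts <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("cut track needs 4 columns (chrom, pos, pos+1, strand)")
  data.frame(chrom = df[[1]], pos = df[[2]], strand = df[[4]])
}

#' @rdname read_cuts
#' @param cuts data.frame chrom/pos/strand.
#' @param header optional provenance comment line (without the leading "#").
#' @export
write_cuts <- function(cuts, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(data.frame(cuts$chrom, cuts$pos, cuts$pos + 1L,
                                cuts$strand),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an interval data.frame as BED3
#' @param intervals data.frame chrom/start/end.
#' @param path output file.
#' @inheritParams write_cuts
#' @export
write_bed <- function(intervals, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(intervals[, c("chrom", "start", "end")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV with an optional provenance header comment
#' @param df data.frame.
#' @param path output file.
#' @inheritParams write_cuts
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (provenance comments skipped)
#' @param path file path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a PeakMatrix counts (and normalized) table
#'
#' Peaks as rows "chrom:start-end", samples as columns.
#' @param pm a [peak_matrix()].
#' @param path output file.
#' @inheritParams write_cuts
#' @export
write_matrix_tsv <- function(pm, path, header = NULL) {
  df <- data.frame(peak = peak_id(pm$peaks), pm$counts, check.names = FALSE)
  write_tsv(df, path, header = header)
}
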