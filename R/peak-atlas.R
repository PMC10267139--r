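# Universal peak atlas: merge fixed-width windows around per-sample peak
# summits, count cut sites per peak, variance-stabilize, percentile-filter.

#' PeakMatrix: peaks x samples counts with sample metadata
#'
#' The central container of the pipeline. `peaks` is a data.frame of 0-based
#' half-open intervals (chrom, start, end, and any extra columns such as
#' `gc`); `counts` is a non-negative integer matrix with one row per peak and
#' one column per sample; `samples` is the sample sheet (must contain
#' `sample`, typically also `source`, `population`, `condition`, `dataset`);
#' `normalized` holds variance-stabilized scores once [vst_normalize()] has
#' run.
#'
#' @param peaks data.frame with chrom/start/end.
#' @param counts integer matrix, rows = peaks, columns = samples.
#' @param samples data.frame; `samples$sample` must match `colnames(counts)`.
#' @param normalized optional numeric matrix, same shape as `counts`.
#' @return object of class `PeakMatrix`.
#' @export
peak_matrix <- function(peaks, counts, samples, normalized = NULL) {
  counts <- as.matrix(counts)
  .validate_intervals(peaks, "peak")
  if (nrow(counts) != nrow(peaks))
    stop("counts rows (", nrow(counts), ") != peaks (", nrow(peaks), ")")
  if (!"sample" %in% names(samples)) stop("sample sheet needs a 'sample' column")
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample
  if (!identical(colnames(counts), as.character(samples$sample)))
    stop("colnames(counts) must match samples$sample")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  rownames(counts) <- peak_id(peaks)
  if (!is.null(normalized)) {
    normalized <- as.matrix(normalized)
    if (!all(dim(normalized) == dim(counts)))
      stop("normalized must have the same shape as counts")
    dimnames(normalized) <- dimnames(counts)
  }
  structure(
    list(peaks = peaks, counts = counts, samples = samples,
         normalized = normalized, size_factors = NULL, dispersion = NULL),
    class = "PeakMatrix"
  )
}

#' @export
print.PeakMatrix <- function(x, ...) {
  cat(sprintf("PeakMatrix: %d peaks x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$normalized)) "" else " (VST normalized)"))
  if ("source" %in% names(x$samples))
    cat("  sources:", paste(names(table(x$samples$source)),
                            table(x$samples$source), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.PeakMatrix <- function(x) dim(x$counts)

#' Peak identifiers "chrom:start-end" (0-based half-open)
#' @param peaks data.frame with chrom/start/end.
#' @export
peak_id <- function(peaks) {
  sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
}

#' Build the universal peak map
#'
#' For each sample, the `top_k` peaks by caller score are reduced to fixed
#' windows of `2 * halfwidth` bases centred on the summit, and the windows of
#' all samples are union-merged (overlapping or abutting windows collapse)
#' into a single sorted, disjoint atlas that provides one coordinate system
#' for counting across samples.
#'
#' @param per_sample_peaks list of data.frames, each with chrom, start, end,
#'   summit (absolute 0-based) and optionally `score` (caller statistic used
#'   for the top-k cut; if absent all peaks are kept).
#' @param top_k number of top peaks retained per sample (ties broken by
#'   genomic order).
#' @param halfwidth half window size in bases; the window is
#'   `[summit - halfwidth, summit + halfwidth)`.
#' @return data.frame chrom/start/end, sorted, pairwise disjoint.
#' @export
build_universal_peaks <- function(per_sample_peaks, top_k = 50000L,
                                  halfwidth = 250L) {
  stopifnot(top_k >= 1L, halfwidth >= 1L)
  if (!length(per_sample_peaks)) stop("no peak sets supplied")
  windows <- lapply(seq_along(per_sample_peaks), function(i) {
    pk <- per_sample_peaks[[i]]
    if (is.null(pk$summit) || anyNA(pk$summit))
      stop("missing summit in peak set ", i,
           if (!is.null(pk$summit)) paste0(" (record ", which(is.na(pk$summit))[1], ")") else "")
    if (!is.null(pk$score) && nrow(pk) > top_k) {
      ord <- order(-pk$score, pk$chrom, pk$start)
      pk <- pk[ord[seq_len(top_k)], , drop = FALSE]
    }
    start <- pk$summit - halfwidth
    if (any(start < 0)) {
      message(sum(start < 0), " window(s) clipped at position 0")
      start <- pmax(start, 0L)
    }
    data.frame(chrom = pk$chrom, start = start, end = pk$summit + halfwidth)
  })
  all_win <- do.call(rbind, windows)
  gr <- GenomicRanges::reduce(.as_granges(all_win))  # merges abutting windows
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' Count cut sites in atlas peaks
#'
#' A cut at 0-based position p is counted in the (unique, since the atlas is
#' disjoint) interval with start <= p < end. Chromosomes present in the cut
#' track but absent from the atlas are ignored with a message.
#'
#' @param cuts data.frame with chrom, pos (0-based), optionally strand.
#' @param atlas data.frame chrom/start/end from [build_universal_peaks()].
#' @return integer vector of counts, one per atlas row.
#' @export
count_cuts_in_peaks <- function(cuts, atlas) {
  .validate_intervals(atlas, "atlas interval")
  if (nrow(cuts) == 0L) return(integer(nrow(atlas)))
  missing_chr <- setdiff(unique(cuts$chrom), unique(atlas$chrom))
  if (length(missing_chr))
    message("ignoring cuts on chromosome(s) absent from atlas: ",
            paste(missing_chr, collapse = ", "))
  cut_gr <- GenomicRanges::GRanges(cuts$chrom,
                                   IRanges::IRanges(cuts$pos + 1L, width = 1L))
  GenomicRanges::countOverlaps(.as_granges(atlas), cut_gr)
}

#' Variance-stabilizing transformation of a peak count matrix
#'
#' Size factors are estimated by median-of-ratios against the per-peak
#' geometric mean (restricted to peaks with all-positive counts; if none
#' exist, zeros are ignored in the reference with a message). A single common
#' negative-binomial dispersion is then fit by maximum likelihood on the
#' size-factor-scaled counts, and the closed-form NB variance-stabilizing
#' transform
#' \deqn{g(n) = \log_2\left(\frac{n}{s} + \frac{1}{2\alpha} +
#'   \sqrt{\frac{n}{s}\left(\frac{n}{s}+\frac{1}{\alpha}\right) +
#'   \frac{1}{4\alpha^2}}\right)}
#' is applied entry-wise. g is strictly monotone in n and asymptotically
#' log2(n/s).
#'
#' @param pm a [peak_matrix()].
#' @return the PeakMatrix with `normalized`, `size_factors` and `dispersion`
#'   filled in.
#' @export
vst_normalize <- function(pm) {
  stopifnot(inherits(pm, "PeakMatrix"))
  counts <- pm$counts
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  sf <- size_factors(counts)
  scaled <- sweep(counts, 2L, sf, "/")
  alpha <- .fit_common_dispersion(counts, scaled, sf)
  norm <- log2(scaled + 1 / (2 * alpha) +
               sqrt(scaled * (scaled + 1 / alpha) + 1 / (4 * alpha^2)))
  pm$normalized <- norm
  pm$size_factors <- sf
  pm$dispersion <- alpha
  pm
}

#' Median-of-ratios size factors
#'
#' @param counts integer matrix peaks x samples.
#' @return numeric vector, one size factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  allpos <- rowSums(counts == 0) == 0L
  if (!any(allpos)) {
    message("no peak with all-positive counts; ignoring zeros in the reference")
    logref <- apply(counts, 1L, function(x) mean(log(x[x > 0])))
    use <- is.finite(logref)
  } else {
    logref <- rowMeans(log(pmax(counts, 1e-300)))
    use <- allpos
  }
  sf <- apply(counts[use, , drop = FALSE], 2L, function(x) {
    exp(stats::median(log(x[x > 0]) - logref[use][x > 0]))
  })
  unname(sf)
}

# common NB dispersion by ML on scaled counts, fitted means = per-peak
# scaled-count means times size factor
.fit_common_dispersion <- function(counts, scaled, sf) {
  mu0 <- rowMeans(scaled)
  keep <- mu0 > 0
  y <- counts[keep, , drop = FALSE]
  mu <- outer(rowMeans(scaled[keep, , drop = FALSE]), sf)
  nll <- function(log_alpha) {
    a <- exp(log_alpha)
    -sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE))
  }
  opt <- stats::optimize(nll, interval = c(log(1e-8), log(10)))
  exp(opt$minimum)
}

#' Filter peaks by the percentile of their maximum score
#'
#' Per peak, the maximum score across samples is taken; peaks whose maximum
#' is at or above the `q` quantile (linear interpolation) of all maxima are
#' retained.
#'
#' @param pm a [peak_matrix()].
#' @param q quantile in \[0, 1); default 0.80.
#' @param channel score channel: "normalized" (default; requires
#'   [vst_normalize()] first) or "counts".
#' @return the filtered PeakMatrix.
#' @export
percentile_filter <- function(pm, q = 0.80,
                              channel = c("normalized", "counts")) {
  stopifnot(inherits(pm, "PeakMatrix"))
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q >= 1)
    stop("q must lie in [0, 1)")
  channel <- match.arg(channel)
  scores <- pm[[channel]]
  if (is.null(scores)) stop("channel '", channel, "' is empty; run vst_normalize()")
  maxima <- apply(scores, 1L, max)
  threshold <- stats::quantile(maxima, q, type = 7, names = FALSE)
  subset_peak_matrix(pm, which(maxima >= threshold))
}

#' Subset a PeakMatrix by peak indices
#' @param pm a [peak_matrix()].
#' @param idx integer vector of peak rows to keep.
#' @export
subset_peak_matrix <- function(pm, idx) {
  pm$peaks <- pm$peaks[idx, , drop = FALSE]
  rownames(pm$peaks) <- NULL
  pm$counts <- pm$counts[idx, , drop = FALSE]
  if (!is.null(pm$normalized))
    pm$normalized <- pm$normalized[idx, , drop = FALSE]
  pm
}
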