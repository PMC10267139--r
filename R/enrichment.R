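# Motif enrichment in differential peaks: GC content, GC-matched background
# sampling, and Fisher's exact test per motif and direction.

#' GC content of peaks
#'
#' `(#G + #C) / (interval length excluding N)` per peak; all-N peaks get NA
#' (callers should drop them, which is reported).
#'
#' @param peaks data.frame chrom/start/end (0-based half-open).
#' @param genome named character vector of contigs.
#' @return numeric vector of GC fractions (NA for all-N peaks).
#' @export
gc_content <- function(peaks, genome) {
  genome <- .as_genome(genome)
  .validate_intervals(peaks, "peak")
  out <- rep(NA_real_, nrow(peaks))
  for (chrom in unique(peaks$chrom)) {
    if (!chrom %in% names(genome)) stop("contig '", chrom, "' not in genome")
    enc <- encode_seq(genome[[chrom]])
    rows <- which(peaks$chrom == chrom)
    if (any(peaks$end[rows] > length(enc) | peaks$start[rows] < 0))
      stop("interval outside contig '", chrom, "'")
    is_gc <- cumsum(c(0L, !is.na(enc) & (enc == 2L | enc == 3L)))
    is_ok <- cumsum(c(0L, !is.na(enc)))
    gc <- is_gc[peaks$end[rows] + 1L] - is_gc[peaks$start[rows] + 1L]
    ok <- is_ok[peaks$end[rows] + 1L] - is_ok[peaks$start[rows] + 1L]
    out[rows] <- ifelse(ok > 0, gc / ok, NA_real_)
  }
  if (anyNA(out)) message(sum(is.na(out)), " all-N peak(s); GC undefined")
  out
}

#' Sample a GC-matched background peak set
#'
#' GC values are binned into `bins` equal-occupancy groups (bin edges are
#' quantiles of the pooled differential + background values); each
#' background peak's inclusion probability is proportional to
#' (differential bin proportion / background bin proportion) for its bin,
#' and `n` peaks are drawn without replacement, so the selected background
#' reproduces the differential set's GC bin proportions. The draw is
#' realized by stratified allocation (largest-remainder bin targets, uniform
#' sampling within each bin), which hits the intended inclusion
#' probabilities exactly; sequential weighted draws without replacement
#' would systematically under-sample the heavy bins as they deplete.
#'
#' @param differential_gc GC fractions of the differential peaks.
#' @param background_pool_gc GC fractions of the candidate background peaks.
#' @param n number of background peaks to select (default 2500); if the pool
#'   is smaller, the whole pool is returned with a warning.
#' @param bins number of GC bins (default 20).
#' @param seed integer seed.
#' @param binning "quantile" (equal occupancy, default) or "width" (equal
#'   width).
#' @return integer indices into `background_pool_gc`.
#' @export
gc_matched_sample <- function(differential_gc, background_pool_gc, n = 2500L,
                              bins = 20L, seed = 1L,
                              binning = c("quantile", "width")) {
  binning <- match.arg(binning)
  stopifnot(n >= 1L, bins >= 2L)
  if (!length(background_pool_gc)) stop("background pool is empty")
  differential_gc <- differential_gc[!is.na(differential_gc)]
  pool_ok <- which(!is.na(background_pool_gc))
  pool_gc <- background_pool_gc[pool_ok]
  if (length(pool_gc) < n) {
    warning("background pool (", length(pool_gc), ") < n (", n,
            "); returning the whole pool")
    return(pool_ok)
  }
  pooled <- c(differential_gc, pool_gc)
  edges <- if (binning == "quantile") {
    unique(stats::quantile(pooled, probs = seq(0, 1, length.out = bins + 1L),
                           type = 7, names = FALSE))
  } else {
    seq(min(pooled), max(pooled), length.out = bins + 1L)
  }
  bin_of <- function(x) {
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(b, length(edges) - 1L)
  }
  diff_bin <- bin_of(differential_gc)
  pool_bin <- bin_of(pool_gc)
  nb <- length(edges) - 1L
  diff_prop <- tabulate(diff_bin, nb) / length(diff_bin)
  pool_prop <- tabulate(pool_bin, nb) / length(pool_bin)
  orphan <- which(diff_prop > 0 & pool_prop == 0)
  if (length(orphan))
    warning("GC bin(s) ", paste(orphan, collapse = ", "),
            " have differential mass but no background members; ",
            "their mass is redistributed proportionally")
  if (all(diff_prop[pool_prop > 0] == 0))
    stop("no overlap between differential and background GC bins")
  capacity <- tabulate(pool_bin, nb)
  # largest-remainder allocation of n over bins, capped at capacity; any
  # shortfall (orphan or full bins) is redistributed proportionally
  want <- diff_prop * n
  want[capacity == 0] <- 0
  target <- pmin(floor(want), capacity)
  repeat {
    short <- n - sum(target)
    if (short <= 0) break
    room <- capacity - target
    frac <- want - floor(want)
    pref <- order(-(frac * (room > 0)), -room)
    takeable <- pref[room[pref] > 0]
    add <- takeable[seq_len(min(short, length(takeable)))]
    if (!length(add)) stop("background pool cannot supply ", n, " peaks")
    target[add] <- target[add] + 1L
    want <- target  # after the first pass, distribute purely by room
  }
  .with_seed(seed, {
    sel <- integer(0)
    for (b in which(target > 0)) {
      members <- which(pool_bin == b)
      sel <- c(sel, members[sample.int(length(members), target[b])])
    }
    pool_ok[sort(sel)]
  })
}

#' Fisher's exact test of motif enrichment in differential peaks
#'
#' For each motif, peaks are scored for presence (>= 1 overlapping motif
#' instance by >= 1 base); the 2x2 table of presence x (differential vs
#' background) is tested one-sided for enrichment (hypergeometric upper
#' tail), the odds ratio is reported as the sample estimate `(a d)/(b c)`
#' (NA when `b c = 0`), and p-values are BH-corrected across the motifs
#' tested.
#'
#' @param differential data.frame chrom/start/end of differential peaks.
#' @param background data.frame chrom/start/end of (GC-matched) background
#'   peaks; must be disjoint from `differential`.
#' @param instances motif instance data.frame from [scan_pwm()] /
#'   [scan_pwms()] (columns motif, chrom, start, end).
#' @return data.frame per motif: a, b, c, d, odds_ratio, p, fdr. An empty
#'   differential set yields a result flagged `untestable = TRUE`.
#' @export
fisher_motif_enrichment <- function(differential, background, instances) {
  motifs <- unique(instances$motif)
  if (nrow(differential) == 0L) {
    out <- data.frame(motif = motifs, a = NA_integer_, b = NA_integer_,
                      c = NA_integer_, d = NA_integer_,
                      odds_ratio = NA_real_, p = NA_real_, fdr = NA_real_)
    attr(out, "untestable") <- TRUE
    return(out)
  }
  diff_gr <- .as_granges(differential)
  bg_gr <- .as_granges(background)
  if (length(GenomicRanges::findOverlaps(diff_gr, bg_gr)) > 0L)
    warning("differential and background sets overlap")
  rows <- lapply(motifs, function(m) {
    inst_gr <- .as_granges(instances[instances$motif == m, , drop = FALSE])
    a <- sum(GenomicRanges::countOverlaps(diff_gr, inst_gr) > 0L)
    b <- nrow(differential) - a
    cc <- sum(GenomicRanges::countOverlaps(bg_gr, inst_gr) > 0L)
    d <- nrow(background) - cc
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE),
                            alternative = "greater")$p.value
    or <- if (b * cc == 0) NA_real_ else (a * d) / (b * cc)
    data.frame(motif = m, a = a, b = b, c = cc, d = d, odds_ratio = or, p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$fdr, out$p), , drop = FALSE]
}

#' One-sided Fisher test of a presence 2x2 table
#'
#' The table is `rbind(c(a, b), c(c, d))` with a = differential peaks with
#' the motif, b = without, c/d the same for the background set. Returns the
#' enrichment (upper-tail hypergeometric) p-value and the sample odds ratio
#' `(a d)/(b c)` (NA when `b c = 0`).
#'
#' @param a,b,c,d non-negative table counts.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_presence_test <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  p <- stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE),
                          alternative = "greater")$p.value
  list(odds_ratio = if (b * c == 0) NA_real_ else (a * d) / (b * c), p = p)
}

#' Motif enrichment for both directions of a labeled differential result
#'
#' Convenience wrapper: for each direction (`differential_up_A`,
#' `differential_up_B`), draws a GC-matched background from the
#' `background`-labeled peaks and runs [fisher_motif_enrichment()].
#'
#' @param labeled data.frame from [label_peaks()] (with peak coordinates).
#' @param instances motif instances from [scan_pwms()].
#' @param genome named character vector (for GC content).
#' @param n_background background sample size per direction (default 2500).
#' @param bins GC bins (default 20).
#' @param seed integer seed.
#' @return data.frame with a `direction` column ("up_A"/"up_B") stacked over
#'   both directions.
#' @export
motif_enrichment_by_direction <- function(labeled, instances, genome,
                                          n_background = 2500L, bins = 20L,
                                          seed = 1L) {
  bg_pool <- labeled[labeled$label == "background", , drop = FALSE]
  bg_gc <- gc_content(bg_pool, genome)
  out <- list()
  for (dir in c("A", "B")) {
    diff_set <- labeled[labeled$label == paste0("differential_up_", dir), ,
                        drop = FALSE]
    if (nrow(diff_set) == 0L) next
    diff_gc <- gc_content(diff_set, genome)
    sel <- gc_matched_sample(diff_gc, bg_gc, n = n_background, bins = bins,
                             seed = seed + match(dir, c("A", "B")))
    enr <- fisher_motif_enrichment(diff_set, bg_pool[sel, , drop = FALSE],
                                   instances)
    enr$direction <- paste0("up_", dir)
    out[[dir]] <- enr
  }
  do.call(rbind, out)
}
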