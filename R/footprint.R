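# Tn5 hexamer bias correction and transcription factor footprinting.
#
# The correction has three ingredients: (1) genomic hexamer frequencies
# (blacklist excluded), (2) per-motif positional hexamer frequencies in a
# +/-250 bp window around motif centers, (3) per-sample cut-site hexamer
# factors (cut share over genomic share, renormalized). The expected cut
# profile around a motif is the positional frequencies weighted by the cut
# factors; the footprint score is log2(observed / expected) after both are
# scaled to mean 1, and is summarized as flanking accessibility (FA) and
# footprint depth (FPD) over fixed regions derived from the motif width.
#
# Hexamer anchor convention (used identically everywhere): the hexamer at a
# genomic position p is the 6-base window [p - 3, p + 3) around the
# insertion bond, read on the plus strand for plus-strand contexts and
# reverse-complemented for minus-strand contexts. Because the window itself
# is the same 6 bases either way, a strand-symmetric model sees one context
# per position.

.FLANK <- 250L

# 0-based genome position of the anchored hexamer's 1-based index in the
# hexamer_codes() vector: window [p-3, p+3) starts at 0-based p-3 = index p-2
.hex_index_at <- function(pos0) pos0 - 2L

#' Genomic hexamer frequencies excluding blacklist regions
#'
#' Sliding-window counts of every 6-mer fully outside the blacklist
#' (windows containing N dropped), converted to proportions. By default the
#' reverse complement of every window is counted too (`double_stranded`),
#' so the frequencies describe the double-stranded genome and are exactly
#' strand-symmetric.
#'
#' @param genome named character vector of contigs.
#' @param blacklist optional data.frame chrom/start/end (0-based half-open)
#'   of regions to exclude.
#' @param double_stranded count both strands (default TRUE).
#' @return numeric vector of 4096 proportions summing to 1.
#' @export
genome_hexamer_freq <- function(genome, blacklist = NULL,
                                double_stranded = TRUE) {
  genome <- .as_genome(genome)
  counts <- numeric(4096)
  for (chrom in names(genome)) {
    enc <- encode_seq(genome[[chrom]])
    hex <- hexamer_codes(enc)
    if (!length(hex)) next
    keep <- !is.na(hex)
    if (!is.null(blacklist)) {
      bl <- blacklist[blacklist$chrom == chrom, , drop = FALSE]
      for (i in seq_len(nrow(bl))) {
        # window starting at 0-based s covers [s, s+6); overlap iff
        # s < bl_end and s + 6 > bl_start
        s0 <- seq_along(hex) - 1L
        keep <- keep & !(s0 < bl$end[i] & s0 + 6L > bl$start[i])
      }
    }
    if (any(keep)) counts <- counts + tabulate(hex[keep], 4096L)
  }
  if (sum(counts) == 0) stop("no usable hexamer windows (everything blacklisted?)")
  if (double_stranded) {
    rc <- hexamer_revcomp_table()
    counts <- (counts + counts[rc]) / 2
  }
  counts / sum(counts)
}

# usable instances: full window +/- flank plus hexamer anchor margin inside
# the contig; returns instances with a precomputed 0-based center column
.usable_instances <- function(instances, contig_lengths, flank = .FLANK) {
  W <- instances$end - instances$start
  center <- instances$start + W %/% 2L
  len <- contig_lengths[instances$chrom]
  ok <- center - flank - 3L >= 0L & center + flank + 3L + 6L <= len
  if (!all(ok))
    message(sum(!ok), " instance(s) without full +/-", flank,
            " bp flank dropped")
  inst <- instances[ok, , drop = FALSE]
  inst$center <- center[ok]
  inst
}

#' Positional hexamer frequencies around motif centers
#'
#' For all instances of one motif, counts at each relative position
#' -flank..+flank (oriented by instance strand) the hexamer anchored at that
#' position, then normalizes each position so the mean over the 4096
#' hexamers is 1 (counts times 4096 / total). Instances without a full
#' flank inside their contig are dropped with a message.
#'
#' @param instances data.frame chrom/start/end/strand for one motif.
#' @param genome named character vector of contigs.
#' @param flank window half-width (default 250).
#' @return numeric matrix (2 flank + 1) x 4096; rownames are relative
#'   positions. Every row has mean 1.
#' @export
positional_hexamer_freq <- function(instances, genome, flank = .FLANK) {
  genome <- .as_genome(genome)
  lens <- vapply(genome, nchar, integer(1))
  inst <- .usable_instances(instances, lens, flank)
  if (nrow(inst) == 0L) stop("no usable motif instance with full flanks")
  rc <- hexamer_revcomp_table()
  npos <- 2L * flank + 1L
  counts <- matrix(0, npos, 4096L)
  for (chrom in unique(inst$chrom)) {
    hex <- hexamer_codes(encode_seq(genome[[chrom]]))
    sub <- inst[inst$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (sub$strand[i] == "+") {
        pos0 <- sub$center[i] + (-flank:flank)
        h <- hex[.hex_index_at(pos0)]
      } else {
        pos0 <- sub$center[i] - (-flank:flank)
        h <- rc[hex[.hex_index_at(pos0)]]
      }
      ok <- !is.na(h)
      if (any(ok))
        counts[cbind(which(ok), h[ok])] <- counts[cbind(which(ok), h[ok])] + 1
    }
  }
  tot <- rowSums(counts)
  if (any(tot == 0)) stop("position(s) with no usable hexamer")
  out <- counts * (4096 / tot)
  rownames(out) <- as.character(-flank:flank)
  out
}

#' Per-sample cut-site hexamer frequency factors
#'
#' The hexamer at each cut site is counted (oriented by cut strand), the
#' per-hexamer cut shares (summing to 1) are divided by the genomic shares,
#' and the ratios are renormalized to sum 1. Hexamers absent from the genome
#' get factor 0; cuts whose hexamer context contains N are skipped.
#'
#' @param cuts data.frame chrom/pos/strand (0-based cut positions).
#' @param genome named character vector of contigs.
#' @param genome_freq 4096 genomic proportions from [genome_hexamer_freq()].
#' @return numeric vector of 4096 factors summing to 1.
#' @export
cut_hexamer_factors <- function(cuts, genome, genome_freq) {
  genome <- .as_genome(genome)
  stopifnot(length(genome_freq) == 4096L)
  if (nrow(cuts) < 1000L)
    warning("fewer than 1000 cuts; hexamer factors will be unstable")
  rc <- hexamer_revcomp_table()
  counts <- numeric(4096)
  skipped <- 0L
  for (chrom in unique(cuts$chrom)) {
    if (!chrom %in% names(genome)) stop("contig '", chrom, "' not in genome")
    hex <- hexamer_codes(encode_seq(genome[[chrom]]))
    sub <- cuts[cuts$chrom == chrom, , drop = FALSE]
    idx <- .hex_index_at(sub$pos)
    ok <- idx >= 1L & idx <= length(hex)
    h <- rep(NA_integer_, nrow(sub))
    h[ok] <- hex[idx[ok]]
    minus <- !is.na(h) & sub$strand == "-"
    h[minus] <- rc[h[minus]]
    skipped <- skipped + sum(is.na(h))
    counts <- counts + tabulate(h[!is.na(h)], 4096L)
  }
  if (skipped) message(skipped, " cut(s) skipped (N or edge context)")
  if (sum(counts) == 0) stop("no usable cuts")
  share <- counts / sum(counts)
  factors <- ifelse(genome_freq > 0, share / genome_freq, 0)
  factors / sum(factors)
}

#' Expected cut profile around a motif
#'
#' `e(pos) = sum_h positional(pos, h) * factors(h)`, normalized to sum 1:
#' the cut rate the Tn5 sequence preference alone predicts at each position
#' around the motif.
#'
#' @param positional matrix from [positional_hexamer_freq()].
#' @param factors 4096 factors from [cut_hexamer_factors()].
#' @return numeric vector (one value per position) summing to 1.
#' @export
expected_cut_profile <- function(positional, factors) {
  stopifnot(ncol(positional) == 4096L, length(factors) == 4096L)
  e <- as.numeric(positional %*% factors)
  if (all(e == 0)) stop("degenerate expected profile (all zero)")
  e / sum(e)
}

#' Observed cut counts around motif centers
#'
#' Aggregates cut-site counts at each relative position -flank..+flank over
#' all instances of one motif, orienting the axis by instance strand and
#' pooling both cut strands.
#'
#' @param cuts data.frame chrom/pos/strand.
#' @param instances data.frame chrom/start/end/strand for one motif.
#' @param genome named character vector of contigs (for bounds).
#' @param flank window half-width (default 250).
#' @return numeric vector of length `2 flank + 1`.
#' @export
observed_cut_profile <- function(cuts, instances, genome, flank = .FLANK) {
  genome <- .as_genome(genome)
  lens <- vapply(genome, nchar, integer(1))
  inst <- .usable_instances(instances, lens, flank)
  if (nrow(inst) == 0L) stop("no usable motif instance with full flanks")
  npos <- 2L * flank + 1L
  obs <- numeric(npos)
  for (chrom in unique(inst$chrom)) {
    sub <- inst[inst$chrom == chrom, , drop = FALSE]
    cc <- tabulate(cuts$pos[cuts$chrom == chrom] + 1L, lens[chrom])
    for (i in seq_len(nrow(sub))) {
      pos0 <- if (sub$strand[i] == "+") sub$center[i] + (-flank:flank)
              else sub$center[i] - (-flank:flank)
      obs <- obs + cc[pos0 + 1L]
    }
  }
  obs
}

#' Footprint score profile
#'
#' Observed and expected are each scaled to mean 1 and the per-position
#' score is `log2(observed / expected)`; positions with expected 0 are
#' masked (NA). Under pure sequence bias the score is 0 everywhere in
#' expectation; protein binding depresses it across the motif (the
#' footprint) and raises it in the flanks.
#'
#' @param observed numeric vector of per-position cut counts.
#' @param expected numeric vector from [expected_cut_profile()].
#' @return list of class `FootprintProfile` with `position`, `observed`,
#'   `expected` (both mean-1 scaled) and `score`; `empty = TRUE` when the
#'   observed window held no cuts.
#' @export
footprint_score <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  n <- length(observed)
  flank <- (n - 1L) %/% 2L
  if (sum(observed) == 0) {
    return(structure(list(position = -flank:flank, observed = observed,
                          expected = expected, score = rep(NA_real_, n),
                          empty = TRUE), class = "FootprintProfile"))
  }
  obs <- observed / mean(observed)
  exp_ <- expected / mean(expected)
  score <- ifelse(exp_ > 0, log2(obs / exp_), NA_real_)
  structure(list(position = -flank:flank, observed = obs, expected = exp_,
                 score = score, empty = FALSE), class = "FootprintProfile")
}

#' @export
print.FootprintProfile <- function(x, ...) {
  cat(sprintf("FootprintProfile: %d positions%s", length(x$position),
              if (isTRUE(x$empty)) " (empty)" else ""), "\n")
  if (!is.null(x$fa)) cat(sprintf("  FA = %.4f, FPD = %.4f\n", x$fa, x$fpd))
  invisible(x)
}

#' Footprint summary regions for a motif width
#'
#' base region: |pos| <= W/2 + 5; flank region: min(18, W/2 + 10) <= |pos|
#' <= 50; background region: 200 <= |pos| <= 250. The literal `min()` in the
#' flank inner edge lets very wide motifs (W > 26) overlap base and flank;
#' `flank_rule = "max"` switches to `max(18, W/2 + 10)`.
#'
#' @param width motif width W (>= 4).
#' @param flank_rule "min" (literal, default) or "max".
#' @return list of integer position vectors `base`, `flank`, `background`
#'   (positions relative to the motif center, both signs).
#' @export
footprint_regions <- function(width, flank_rule = c("min", "max")) {
  flank_rule <- match.arg(flank_rule)
  stopifnot(width >= 4)
  pos <- -.FLANK:.FLANK
  base_r <- width / 2 + 5
  inner <- if (flank_rule == "min") min(18, width / 2 + 10)
           else max(18, width / 2 + 10)
  list(base = pos[abs(pos) <= base_r],
       flank = pos[abs(pos) >= inner & abs(pos) <= 50],
       background = pos[abs(pos) >= 200 & abs(pos) <= 250])
}

#' Flanking accessibility and footprint depth of a score profile
#'
#' `FPD = trimmed_mean(base) - mean(flank)` with the top and bottom 10% of
#' base-region values trimmed (floor(0.1 k) values per tail);
#' `FA = mean(flank) - mean(background)`. Masked positions are excluded
#' from their region's mean; a fully masked region yields NA.
#'
#' @param profile a [footprint_score()] result (or any list with `position`
#'   and `score`).
#' @param width motif width used to derive the regions.
#' @param trim trim fraction per tail for the base region (default 0.10).
#' @param flank_rule passed to [footprint_regions()].
#' @return the profile with `fa`, `fpd`, `width` fields added.
#' @export
compute_fa_fpd <- function(profile, width, trim = 0.10,
                           flank_rule = c("min", "max")) {
  reg <- footprint_regions(width, flank_rule = match.arg(flank_rule))
  sc <- function(posns) {
    v <- profile$score[match(posns, profile$position)]
    v[!is.na(v)]
  }
  region_mean <- function(v) if (length(v)) mean(v) else NA_real_
  base_v <- sc(reg$base)
  tm <- if (length(base_v)) mean(base_v, trim = trim) else NA_real_
  fl <- region_mean(sc(reg$flank))
  bg <- region_mean(sc(reg$background))
  profile$fpd <- tm - fl
  profile$fa <- fl - bg
  profile$width <- width
  profile
}

#' Footprint profiles and FA/FPD for many motifs in one sample
#'
#' Runs the full bias-corrected footprinting stack: genomic hexamer
#' frequencies (blacklist excluded), per-sample cut hexamer factors, then
#' per motif the positional hexamer frequencies, expected and observed
#' profiles, footprint scores, and FA/FPD.
#'
#' @param cuts data.frame chrom/pos/strand for one sample.
#' @param instances motif instances (several motifs) with columns
#'   motif/chrom/start/end/strand.
#' @param genome named character vector of contigs.
#' @param blacklist optional blacklist intervals.
#' @param flank window half-width (default 250).
#' @param genome_freq,factors optionally precomputed model components.
#' @return list with `profiles` (named list of FootprintProfile) and
#'   `summary` (data.frame motif/width/n_instances/fa/fpd).
#' @export
footprint_profiles <- function(cuts, instances, genome, blacklist = NULL,
                               flank = .FLANK, genome_freq = NULL,
                               factors = NULL) {
  genome <- .as_genome(genome)
  if (is.null(genome_freq))
    genome_freq <- genome_hexamer_freq(genome, blacklist)
  if (is.null(factors))
    factors <- cut_hexamer_factors(cuts, genome, genome_freq)
  motifs <- unique(instances$motif)
  profiles <- list()
  rows <- list()
  for (m in motifs) {
    inst <- instances[instances$motif == m, , drop = FALSE]
    W <- inst$end[1] - inst$start[1]
    positional <- positional_hexamer_freq(inst, genome, flank)
    expected <- expected_cut_profile(positional, factors)
    observed <- observed_cut_profile(cuts, inst, genome, flank)
    prof <- footprint_score(observed, expected)
    prof <- compute_fa_fpd(prof, W)
    prof$motif <- m
    profiles[[m]] <- prof
    rows[[m]] <- data.frame(motif = m, width = W, n_instances = nrow(inst),
                            fa = prof$fa, fpd = prof$fpd)
  }
  list(profiles = profiles, summary = do.call(rbind, rows))
}

#' Between-condition footprint differences
#'
#' Joins two per-motif FA/FPD summaries (e.g. condition A = BM, B = CB) and
#' reports `delta_fa = fa_A - fa_B` and `delta_fpd = fpd_A - fpd_B` per
#' motif, with ranks by each delta. Motifs missing from one condition are
#' dropped with a message.
#'
#' @param summary_a,summary_b data.frames from `footprint_profiles()$summary`.
#' @return data.frame motif/width/fa_a/fa_b/fpd_a/fpd_b/delta_fa/delta_fpd
#'   with `rank_delta_fa` and `rank_delta_fpd` (1 = most negative delta_fpd,
#'   i.e. deepest relative footprint in A; 1 = most positive delta_fa).
#' @export
differential_footprint <- function(summary_a, summary_b) {
  common <- intersect(summary_a$motif, summary_b$motif)
  dropped <- length(union(summary_a$motif, summary_b$motif)) - length(common)
  if (dropped) message(dropped, " motif(s) present in only one condition dropped")
  a <- summary_a[match(common, summary_a$motif), , drop = FALSE]
  b <- summary_b[match(common, summary_b$motif), , drop = FALSE]
  out <- data.frame(motif = common, width = a$width,
                    fa_a = a$fa, fa_b = b$fa, fpd_a = a$fpd, fpd_b = b$fpd,
                    delta_fa = a$fa - b$fa, delta_fpd = a$fpd - b$fpd)
  out$rank_delta_fpd <- rank(out$delta_fpd, ties.method = "first")
  out$rank_delta_fa <- rank(-out$delta_fa, ties.method = "first")
  out[order(out$delta_fpd), , drop = FALSE]
}
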