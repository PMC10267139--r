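# Synthetic validation experiments. Each function builds its own inputs with
# the generators, runs the relevant pipeline stages, and returns the summary
# quantities; the test suite and the acceptance script both call these so
# the reported numbers always come from a fresh end-to-end computation.

#' Bias-correction null experiment
#'
#' Cuts are simulated purely from a planted hexamer bias table (no
#' protection) on a genome carrying planted consensus instances of the NFI
#' fixture motifs; instances are then recovered by scanning and
#' footprinted. If the hexamer correction absorbs the planted bias, the
#' mean |footprint score| across the +/-250 window is small for every
#' motif (pure counting noise).
#'
#' @param seed integer seed.
#' @param genome_length genome size in bases (default 2e6).
#' @param depth total cuts (default 1e6).
#' @param n_plant consensus instances planted per motif (default 1500;
#'   keeps per-position counts high enough that counting noise alone sits
#'   well below 0.05 mean |score|).
#' @param scan_p scan p-value cutoff (default 1e-3, the smallest round
#'   cutoff that can retain a width-5 consensus match, since the best
#'   achievable match p-value is 4^-W).
#' @return list: `per_motif` (data.frame motif, n_instances,
#'   mean_abs_score, fa, fpd), `max_mean_abs_score`, `elapsed_sec`.
#' @export
bias_null_experiment <- function(seed = 1L, genome_length = 2000000L,
                                 depth = 1000000L, n_plant = 1500L,
                                 scan_p = 1e-3) {
  t0 <- Sys.time()
  pwms <- nfi_fixture_pwms()
  genome <- make_genome(genome_length, gc_fraction = 0.45, seed = seed)
  planted <- list()
  for (i in seq_along(pwms)) {
    r <- plant_motif_instances(genome, pwms[[i]], n = n_plant,
                               protected_fraction = 0, seed = seed + i,
                               exclude = do.call(rbind, planted))
    genome <- r$genome
    planted[[i]] <- r$instances
  }
  bias <- make_bias_table(seed = seed + 100L)
  cuts <- simulate_cut_sites(genome, bias, depth = depth, seed = seed + 200L)
  instances <- scan_pwms(genome, pwms, p_cutoff = scan_p)
  fp <- footprint_profiles(cuts, instances, genome)
  mas <- vapply(fp$profiles, function(p) mean(abs(p$score), na.rm = TRUE),
                numeric(1))
  per_motif <- data.frame(fp$summary, mean_abs_score = mas[fp$summary$motif])
  list(per_motif = per_motif, max_mean_abs_score = max(mas),
       elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Planted-footprint ranking experiment
#'
#' One genome carries planted instances of the three NFI fixture motifs and
#' `n_decoys` random decoy motifs. Per seed, condition A cuts are simulated
#' with the NFI instances protected (`protection_factor`), condition B cuts
#' with no protection; footprint FA/FPD are computed per motif from the
#' planted instance lists and the NFI motifs' ranks by `delta_fpd` (A - B,
#' most negative first) are recorded.
#'
#' @param seeds integer vector; one replicate per seed.
#' @param genome_length genome size (default 1e6).
#' @param depth cuts per condition (default 5e5).
#' @param n_per_motif planted instances per motif (default 100).
#' @param n_decoys decoy motifs (default 20).
#' @param protection_factor cut-rate multiplier inside protected NFI
#'   instances in condition A (default 0.2).
#' @param base_seed seed for the shared genome, planting and bias table.
#' @return list: `ranks` (data.frame seed x motif rank by delta_fpd for the
#'   NFI motifs), `all_top3_fraction` (fraction of seeds where all three
#'   NFI motifs rank in the top 3), `n_motifs`.
#' @export
footprint_ranking_experiment <- function(seeds = 1:10,
                                         genome_length = 1000000L,
                                         depth = 500000L,
                                         n_per_motif = 100L, n_decoys = 20L,
                                         protection_factor = 0.2,
                                         base_seed = 424242L) {
  pwms <- c(nfi_fixture_pwms(),
            decoy_pwms(n_decoys, width = rep(6:8, length.out = n_decoys),
                       seed = base_seed))
  nfi_ids <- names(nfi_fixture_pwms())
  genome <- make_genome(genome_length, gc_fraction = 0.45, seed = base_seed)
  planted <- list()
  for (i in seq_along(pwms)) {
    r <- plant_motif_instances(genome, pwms[[i]], n = n_per_motif,
                               protected_fraction = 1, seed = base_seed + i,
                               exclude = do.call(rbind, planted))
    genome <- r$genome
    planted[[i]] <- r$instances
  }
  instances <- do.call(rbind, planted)
  nfi_instances <- instances[instances$motif %in% nfi_ids, , drop = FALSE]
  bias <- make_bias_table(seed = base_seed + 999L)
  genome_freq <- genome_hexamer_freq(genome)
  positional <- lapply(split(instances, instances$motif), function(inst)
    positional_hexamer_freq(inst, genome))
  widths <- vapply(split(instances$end - instances$start, instances$motif),
                   function(w) w[1], numeric(1))

  one_condition <- function(cuts) {
    factors <- cut_hexamer_factors(cuts, genome, genome_freq)
    rows <- lapply(names(positional), function(m) {
      inst <- instances[instances$motif == m, , drop = FALSE]
      expected <- expected_cut_profile(positional[[m]], factors)
      observed <- observed_cut_profile(cuts, inst, genome)
      prof <- compute_fa_fpd(footprint_score(observed, expected), widths[m])
      data.frame(motif = m, width = widths[m], n_instances = nrow(inst),
                 fa = prof$fa, fpd = prof$fpd)
    })
    do.call(rbind, rows)
  }

  ranks <- list()
  for (s in seeds) {
    cuts_a <- simulate_cut_sites(genome, bias, depth = depth,
                                 seed = s * 1000L + 1L,
                                 instances = nfi_instances,
                                 protection_factor = protection_factor)
    cuts_b <- simulate_cut_sites(genome, bias, depth = depth,
                                 seed = s * 1000L + 2L)
    dfp <- differential_footprint(one_condition(cuts_a), one_condition(cuts_b))
    r <- dfp$rank_delta_fpd[match(nfi_ids, dfp$motif)]
    ranks[[as.character(s)]] <- data.frame(seed = s, motif = nfi_ids, rank = r)
  }
  ranks <- do.call(rbind, ranks)
  top3 <- tapply(ranks$rank, ranks$seed, function(r) all(r <= 3))
  list(ranks = ranks, all_top3_fraction = mean(top3),
       n_motifs = length(pwms))
}

#' GC de-confounding experiment
#'
#' Repeats of a GC-confounded null ([simulate_gc_confound()]): motif
#' presence depends only on GC, differential peaks are GC-shifted, there is
#' no true association. Each repeat tests enrichment once against a naive
#' random background and once against a GC-matched background
#' ([gc_matched_sample()]), both of size `n_background`.
#'
#' @param n_repeats number of repeats (default 100).
#' @param n_background background sample size (default 2500).
#' @param seed integer base seed.
#' @param alpha significance threshold counted as a (spurious) rejection.
#' @return list with `naive_reject_rate` and `matched_reject_rate`.
#' @export
gc_deconfounding_experiment <- function(n_repeats = 100L,
                                        n_background = 2500L, seed = 1L,
                                        alpha = 0.05) {
  naive <- matched <- logical(n_repeats)
  for (r in seq_len(n_repeats)) {
    s <- simulate_gc_confound(seed = seed + r)
    pv <- function(idx)
      fisher_presence_test(sum(s$diff_present), sum(!s$diff_present),
                           sum(s$pool_present[idx]),
                           sum(!s$pool_present[idx]))$p
    idx_naive <- .with_seed(seed + 10000L + r,
                            sample(length(s$pool_gc), n_background))
    naive[r] <- pv(idx_naive) < alpha
    idx_matched <- gc_matched_sample(s$diff_gc, s$pool_gc, n = n_background,
                                     seed = seed + 20000L + r)
    matched[r] <- pv(idx_matched) < alpha
  }
  list(naive_reject_rate = mean(naive), matched_reject_rate = mean(matched))
}

#' NB test calibration and effect-recovery experiment
#'
#' Calibration: a null count matrix (no planted effects) is tested in the
#' mid population window and the fraction of p < 0.05 recorded. Recovery:
#' log2FC of magnitude `effect` is planted in a subset of peaks with strong
#' baselines (half up, half down, so the median-of-ratios normalization's
#' mostly-balanced-composition assumption holds) and the fraction of
#' high-coverage planted peaks whose estimate falls within +/-0.5 of their
#' planted value is recorded.
#'
#' @param seed integer seed.
#' @param n_null peaks in the null matrix (default 2000).
#' @param n_recovery peaks in the recovery matrix (default 1000), of which
#'   `n_planted` carry the effect.
#' @param n_planted planted differential peaks (default 200).
#' @param effect planted log2 fold-change (default 2).
#' @return list with `type1_fraction`, `recovery_fraction`,
#'   `n_high_coverage`.
#' @export
nb_calibration_experiment <- function(seed = 1L, n_null = 2000L,
                                      n_recovery = 1000L, n_planted = 200L,
                                      effect = 2) {
  sheet <- synthetic_sample_sheet()
  sim0 <- simulate_count_matrix(n_null, sheet, seed = seed)
  res0 <- fit_nb_wald(sim0$matrix, window = 3:5)
  type1 <- mean(res0$p < 0.05, na.rm = TRUE)

  eff <- numeric(n_recovery)
  eff[seq_len(n_planted)] <- rep_len(c(effect, -effect), n_planted)
  sim1 <- simulate_count_matrix(n_recovery, sheet, effects = eff,
                                baseline_meanlog = log(400),
                                baseline_sdlog = 0.5, seed = seed + 1L)
  res1 <- fit_nb_wald(sim1$matrix, window = 3:5)
  hi <- which(eff != 0 & res1$base_mean >= 100)
  recovery <- mean(abs(res1$log2fc[hi] - eff[hi]) <= 0.5)
  list(type1_fraction = type1, recovery_fraction = recovery,
       n_high_coverage = length(hi))
}
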