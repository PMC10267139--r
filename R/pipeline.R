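# Run configuration and the end-to-end pipeline driver chaining
# atlas -> counts -> VST -> filter -> differential -> labels ->
# (motif enrichment, footprinting).

#' Pipeline run configuration
#'
#' Collects every tunable constant with its standard default: top 50k peaks
#' per sample, 500 bp summit windows, 80th-percentile filter, FDR < 0.1 and
#' |log2FC| > log2(1.25) differential thresholds, background p > 0.1, 2500
#' GC-matched background peaks in 20 bins, scan p-value 1e-4 capped at 500k
#' instances, +/-250 bp footprint windows with a 10% trimmed mean. Unknown
#' keys are rejected.
#'
#' @param ... overrides of the defaults listed above, plus input paths
#'   (`genome`, `blacklist`, `cuts`, `peaks`, `pwms`, `sample_sheet`).
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    genome = NULL, blacklist = NULL, cuts = NULL, peaks = NULL,
    pwms = NULL, sample_sheet = NULL,
    top_k = 50000L, halfwidth = 250L, percentile = 0.80,
    filter_channel = "normalized",
    fdr_max = 0.1, lfc_min = log2(1.25), bg_p_min = 0.1,
    n_background = 2500L, gc_bins = 20L,
    scan_p = 1e-4, max_instances = 500000L,
    footprint_flank = 250L, trim = 0.10,
    windows = list(early = 1:2, mid = 3:5, late = 6:7),
    contrast = c("source", "BM", "CB"),
    covariates = NULL,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

# short stable hash of the config for provenance headers
.config_hash <- function(config) {
  raw <- serialize(config[order(names(config))], NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% .Machine$integer.max)
}

.provenance <- function(config) {
  sprintf("footprintr %s config_hash=%s seed=%d",
          as.character(utils::packageVersion("footprintr")),
          .config_hash(config), config$seed)
}

#' Run the pipeline end to end
#'
#' `mode = "simulate"` writes a complete synthetic input set (genome FASTA,
#' per-sample cut tracks and narrowPeak calls, truth tables, PWM file paths)
#' into `out_dir`. `mode = "compare_sources"` consumes such a directory (or
#' the paths in `config`) and runs atlas, counting, VST, percentile filter,
#' the NB Wald test per population window, labeling, GC-matched motif
#' enrichment and footprinting, writing one TSV per stage with a provenance
#' header. `mode = "compare_conditions"` is the same driver with a
#' condition contrast (e.g. knockdown vs control, dataset as covariate).
#'
#' @param config a [run_config()].
#' @param mode "simulate", "compare_sources" or "compare_conditions".
#' @param out_dir result directory (created if missing).
#' @return (invisibly) a list of the main result objects.
#' @export
run_pipeline <- function(config,
                         mode = c("compare_sources", "compare_conditions",
                                  "simulate"),
                         out_dir) {
  stopifnot(inherits(config, "run_config"))
  mode <- match.arg(mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (mode == "simulate") return(.pipeline_simulate(config, out_dir))
  if (mode == "compare_conditions" && identical(config$contrast[1], "source"))
    config$contrast[1] <- "condition"
  .pipeline_compare(config, out_dir)
}

# synthetic input set: two sources x two replicates on one genome, NFI
# instances protected in the first source only
.pipeline_simulate <- function(config, out_dir) {
  seed <- config$seed
  genome_len <- 200000L
  depth <- 200000L
  pwms <- nfi_fixture_pwms()
  genome <- make_genome(genome_len, gc_fraction = 0.45, seed = seed)
  planted <- list()
  for (i in seq_along(pwms)) {
    res <- plant_motif_instances(genome, pwms[[i]], n = 60L,
                                 protected_fraction = 1, seed = seed + i,
                                 exclude = do.call(rbind, planted))
    genome <- res$genome
    planted[[i]] <- res$instances
  }
  instances <- do.call(rbind, planted)
  bias <- make_bias_table(seed = seed + 100L)
  sheet <- synthetic_sample_sheet(n_populations = 3L, n_replicates = 2L)
  src_a <- config$contrast[2]
  cut_paths <- character(0)
  for (j in seq_len(nrow(sheet))) {
    protected_here <- sheet$source[j] == src_a
    cuts <- simulate_cut_sites(genome, bias, depth = depth,
                               seed = seed + 200L + j,
                               instances = if (protected_here) instances else NULL,
                               protection_factor = 0.2)
    path <- file.path(out_dir, paste0("cuts_", sheet$sample[j], ".tsv"))
    write_cuts(cuts, path, header = .provenance(config))
    cut_paths[sheet$sample[j]] <- path
    # peak calls: summit windows at planted instances plus shared decoy
    # positions, jittered a little per sample as a real caller would
    decoys <- .with_seed(seed + 300L,
                         sample(seq(500L, genome_len - 500L, by = 1500L), 90L))
    summits <- sort(c(instances$start,
                      decoys + .with_seed(seed + 300L + j,
                                          sample(-20:20, 90L, replace = TRUE))))
    pk <- data.frame(chrom = "chr1", start = pmax(summits - 200L, 0L),
                     end = summits + 200L, name = ".", score = 100,
                     strand = ".", signal = 0, pvalue = -1, qvalue = -1,
                     peak_offset = pmin(summits, 200L))
    utils::write.table(pk, file.path(out_dir, paste0("peaks_", sheet$sample[j],
                                                     ".narrowPeak")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
  write_tsv(sheet, file.path(out_dir, "samples.tsv"), header = .provenance(config))
  write_tsv(instances, file.path(out_dir, "truth_instances.tsv"),
            header = .provenance(config))
  file.copy(system.file("extdata", "nfi_motifs_synthetic.jaspar",
                        package = "footprintr"),
            file.path(out_dir, "motifs.jaspar"), overwrite = TRUE)
  invisible(list(out_dir = out_dir, sheet = sheet, instances = instances))
}

.pipeline_compare <- function(config, out_dir) {
  hd <- .provenance(config)
  genome <- read_genome_fasta(config$genome)
  sheet <- read_tsv(config$sample_sheet)
  blacklist <- if (!is.null(config$blacklist)) read_bed(config$blacklist)
  pwms <- read_jaspar(config$pwms)
  per_sample_peaks <- lapply(config$peaks, read_narrowpeak)
  cuts <- lapply(config$cuts, read_cuts)
  if (is.null(names(cuts)) || !all(sheet$sample %in% names(cuts)))
    stop("config$cuts must be named by sample id covering the sample sheet")

  atlas <- build_universal_peaks(per_sample_peaks, top_k = config$top_k,
                                 halfwidth = config$halfwidth)
  counts <- matrix(0L, nrow(atlas), nrow(sheet),
                   dimnames = list(NULL, sheet$sample))
  for (s in sheet$sample) counts[, s] <- count_cuts_in_peaks(cuts[[s]], atlas)
  pm <- peak_matrix(atlas, counts, sheet)
  pm <- vst_normalize(pm)
  pm_f <- percentile_filter(pm, q = config$percentile,
                            channel = config$filter_channel)
  write_bed(atlas, file.path(out_dir, "atlas.bed"), header = hd)
  write_matrix_tsv(pm, file.path(out_dir, "matrix.tsv"), header = hd)

  instances <- scan_pwms(genome, pwms, p_cutoff = config$scan_p,
                         max_instances = config$max_instances)
  write_tsv(instances, file.path(out_dir, "instances.tsv"), header = hd)

  use_windows <- "population" %in% names(sheet) &&
    length(unique(sheet$population)) > 1L
  windows <- if (use_windows) config$windows else list(all = NULL)
  results <- list()
  for (wname in names(windows)) {
    if (!is.null(windows[[wname]])) {
      in_w <- sheet$population %in% windows[[wname]]
      lev_n <- table(factor(sheet[[config$contrast[1]]][in_w],
                            levels = config$contrast[2:3]))
      if (any(lev_n < 2L)) {
        message("window '", wname, "' skipped: fewer than 2 samples per level")
        next
      }
    }
    res <- fit_nb_wald(pm_f, window = windows[[wname]],
                       contrast = config$contrast,
                       covariates = config$covariates)
    res <- label_peaks(res, fdr_max = config$fdr_max,
                       lfc_min = config$lfc_min, bg_p_min = config$bg_p_min)
    write_tsv(res, file.path(out_dir, paste0("differential_", wname, ".tsv")),
              header = hd)
    enr <- motif_enrichment_by_direction(res, instances, genome,
                                         n_background = config$n_background,
                                         bins = config$gc_bins,
                                         seed = config$seed)
    if (!is.null(enr))
      write_tsv(enr, file.path(out_dir, paste0("enrichment_", wname, ".tsv")),
                header = hd)
    results[[wname]] <- list(differential = res, enrichment = enr)
  }

  genome_freq <- genome_hexamer_freq(genome, blacklist)
  grp <- factor(sheet[[config$contrast[1]]],
                levels = c(config$contrast[2], config$contrast[3]))
  fp <- list()
  for (lev in levels(grp)) {
    pooled <- do.call(rbind, cuts[sheet$sample[grp == lev]])
    pooled <- pooled[order(pooled$chrom, pooled$pos), ]
    fp[[lev]] <- footprint_profiles(pooled, instances, genome,
                                    blacklist = blacklist,
                                    flank = config$footprint_flank,
                                    genome_freq = genome_freq)
    write_tsv(fp[[lev]]$summary,
              file.path(out_dir, paste0("footprint_", lev, ".tsv")),
              header = hd)
  }
  dfp <- differential_footprint(fp[[levels(grp)[1]]]$summary,
                                fp[[levels(grp)[2]]]$summary)
  write_tsv(dfp, file.path(out_dir, "footprint_diff.tsv"), header = hd)
  invisible(list(atlas = atlas, matrix = pm, filtered = pm_f,
                 instances = instances, windows = results,
                 footprints = fp, footprint_diff = dfp))
}
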