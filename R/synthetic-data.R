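# Synthetic data generators: genomes, planted motif instances, hexamer-biased
# Tn5 cut sites with footprint protection, and NB count matrices with planted
# differential effects. Every downstream stage is testable against the ground
# truth these return.

# run expr with a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random genome with controlled GC content
#'
#' Bases are i.i.d. with P(G) = P(C) = `gc_fraction / 2` and
#' P(A) = P(T) = `(1 - gc_fraction) / 2`, so base composition is
#' strand-symmetric like a real double-stranded genome.
#'
#' @param length genome length in bases (>= 1000).
#' @param gc_fraction target GC fraction, strictly between 0 and 1.
#' @param seed integer seed; the same seed reproduces the same sequence.
#' @return a single character string of A/C/G/T.
#' @export
make_genome <- function(length, gc_fraction = 0.5, seed = 1L) {
  if (length < 1000L) stop("genome length must be >= 1000 bases")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0, 1)")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  .with_seed(seed, paste(sample(BASES, length, replace = TRUE, prob = p),
                         collapse = ""))
}

#' Random strand-symmetric Tn5 hexamer bias table
#'
#' Draws one positive relative cut propensity per hexamer (log-normal),
#' symmetrizes so that a hexamer and its reverse complement share the same
#' propensity (Tn5 acts as a homodimer and a cut has no intrinsic strand),
#' and scales to mean 1.
#'
#' @param seed integer seed.
#' @param sdlog log-scale spread of the propensities.
#' @param symmetric keep the strand symmetry (default TRUE).
#' @return numeric vector of length 4096, all > 0, mean 1.
#' @export
make_bias_table <- function(seed = 1L, sdlog = 0.35, symmetric = TRUE) {
  b <- .with_seed(seed, stats::rlnorm(4096, meanlog = 0, sdlog = sdlog))
  if (symmetric) {
    rc <- hexamer_revcomp_table()
    b <- (b + b[rc]) / 2
  }
  b / mean(b)
}

#' Validate a bias table
#' @param bias_table numeric vector of per-hexamer relative cut propensities.
#' @keywords internal
.check_bias_table <- function(bias_table) {
  if (length(bias_table) != 4096L) stop("bias table must have 4096 entries")
  if (any(bias_table <= 0)) stop("bias table entries must be > 0")
  if (abs(mean(bias_table) - 1) > 1e-9) stop("bias table mean must be 1")
  invisible(bias_table)
}

#' Consensus sequence of a PWM (argmax base per column)
#' @param pwm a [pwm()] object.
#' @return character string of length `pwm_width(pwm)`.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$probs, 2L, which.max)], collapse = "")
}

#' Plant motif consensus instances into a genome
#'
#' Writes the PWM consensus (argmax base per column; on the minus strand its
#' reverse complement) at `n` random non-overlapping positions, keeping at
#' least `margin` bases of flank inside the genome so that full footprint
#' windows exist around every instance. A stated fraction of the instances is
#' flagged protected (bound by a factor that blocks Tn5).
#'
#' @param genome single character string (or named length-1 vector).
#' @param pwm a [pwm()] object.
#' @param n number of instances to place.
#' @param protected_fraction fraction in \[0, 1\]; exactly
#'   `round(n * protected_fraction)` instances are flagged.
#' @param seed integer seed.
#' @param margin minimum flank kept inside the genome (default 250, the
#'   footprint window half-width).
#' @param exclude optional data.frame with start/end columns (e.g. instances
#'   planted by an earlier call); new placements avoid these intervals so
#'   successive plantings never overwrite each other.
#' @return list with `genome` (modified sequence) and `instances`
#'   (data.frame: motif, chrom, start, end, strand, protected).
#' @export
plant_motif_instances <- function(genome, pwm, n, protected_fraction = 0,
                                  seed = 1L, margin = 250L, exclude = NULL) {
  genome <- .as_genome(genome)
  chrom <- names(genome)[1]
  seq <- genome[[1]]
  L <- nchar(seq)
  W <- pwm_width(pwm)
  stopifnot(protected_fraction >= 0, protected_fraction <= 1)
  if (n == 0L) {
    return(list(genome = stats::setNames(seq, chrom),
                instances = data.frame(motif = character(0), chrom = character(0),
                                       start = integer(0), end = integer(0),
                                       strand = character(0), protected = logical(0))))
  }
  lo <- margin                      # 0-based minimum start
  hi <- L - margin - W              # 0-based maximum start
  if (hi < lo) stop("genome too short for the requested flank margin")
  cons <- pwm_consensus(pwm)
  excl_start <- if (!is.null(exclude)) exclude$start else integer(0)
  excl_end <- if (!is.null(exclude)) exclude$end else integer(0)
  .with_seed(seed, {
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n) {
      tries <- tries + 1L
      if (tries > 200L * n)
        stop("could not place ", n, " non-overlapping instances after ",
             tries, " tries")
      cand <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      clash <- (length(starts) && any(abs(cand - starts) < W)) ||
        (length(excl_start) && any(cand < excl_end & cand + W > excl_start))
      if (!clash) starts <- c(starts, cand)
    }
    strands <- sample(c("+", "-"), n, replace = TRUE)
    n_prot <- round(n * protected_fraction)
    protected <- logical(n)
    if (n_prot > 0L) protected[sample.int(n, n_prot)] <- TRUE
    for (i in seq_len(n)) {
      ins <- if (strands[i] == "+") cons else revcomp(cons)
      substr(seq, starts[i] + 1L, starts[i] + W) <- ins
    }
    inst <- data.frame(motif = pwm$id, chrom = chrom, start = starts,
                       end = starts + W, strand = strands,
                       protected = protected)
    inst <- inst[order(inst$start), , drop = FALSE]
    rownames(inst) <- NULL
    list(genome = stats::setNames(seq, chrom), instances = inst)
  })
}

#' Simulate hexamer-biased Tn5 cut sites with optional footprint protection
#'
#' Cut positions are drawn from a multinomial over genome positions whose
#' weight is `bias_table[hexamer anchored at the position]`, multiplied by
#' `protection_factor` inside protected motif instances. The hexamer anchor
#' is the 6-base window `[pos - 3, pos + 3)` around the insertion bond (the
#' same anchor the correction models use). Positions within 5 bases of either
#' genome end are excluded. Cut strands are Bernoulli(0.5), independent of
#' position.
#'
#' @param genome single character string (or named length-1 vector).
#' @param bias_table 4096 relative propensities, mean 1 (see
#'   [make_bias_table()]).
#' @param depth total number of cuts to draw (>= 1).
#' @param seed integer seed.
#' @param instances optional data.frame from [plant_motif_instances()]; rows
#'   with `protected == TRUE` get their cut rate multiplied by
#'   `protection_factor`.
#' @param protection_factor multiplicative rate reduction in \[0, 1\] across
#'   protected instances (0 = fully protected).
#' @return data.frame with chrom, pos (0-based), strand, sorted by position.
#' @export
simulate_cut_sites <- function(genome, bias_table, depth, seed = 1L,
                               instances = NULL, protection_factor = 1) {
  genome <- .as_genome(genome)
  chrom <- names(genome)[1]
  seq <- genome[[1]]
  L <- nchar(seq)
  stopifnot(depth >= 1)
  .check_bias_table(bias_table)
  if (protection_factor < 0 || protection_factor > 1)
    stop("protection_factor must be in [0, 1]")
  enc <- encode_seq(seq)
  hex <- hexamer_codes(enc)              # hex[i] = code of 6-mer at 1-based i
  support <- 5L:(L - 6L)                 # 0-based positions kept
  anchor_idx <- support - 2L             # 1-based start of [pos-3, pos+3)
  w <- bias_table[hex[anchor_idx]]
  w[is.na(w)] <- 0
  if (!is.null(instances)) {
    prot <- instances[instances$protected, , drop = FALSE]
    for (i in seq_len(nrow(prot))) {
      inside <- support >= prot$start[i] & support < prot$end[i]
      w[inside] <- w[inside] * protection_factor
    }
  }
  if (all(w == 0)) stop("all cut weights are zero")
  .with_seed(seed, {
    idx <- sample.int(length(support), depth, replace = TRUE, prob = w)
    pos <- support[idx]
    strand <- sample(c("+", "-"), depth, replace = TRUE)
    ord <- order(pos)
    data.frame(chrom = chrom, pos = pos[ord], strand = strand[ord])
  })
}

#' Simulate a negative-binomial peak count matrix with planted effects
#'
#' Counts are NB with mean `baseline_i * sizefactor_j * 2^(effect_i * x_j)`,
#' where `x_j` indicates membership of sample j in `effect_source`, plus
#' (when the sheet has a `population` column) peak-specific population shifts
#' so the population covariate carries real signal. Per-peak GC fractions are
#' drawn from a beta distribution; with `gc_confound = TRUE` the peaks that
#' carry effects are drawn from a GC-shifted beta instead, creating the
#' confound that GC-matched background sampling must remove.
#'
#' @param n_peaks number of peaks.
#' @param samples sample sheet data.frame with `sample`, `source` (2 levels,
#'   >= 2 samples each) and optionally `population`.
#' @param effects numeric vector of true log2 fold-changes per peak
#'   (default all 0). Positive = higher in `effect_source`.
#' @param effect_source the source level carrying `2^effects`; default the
#'   first sorted level.
#' @param dispersion NB dispersion alpha (> 0); variance = mu + alpha mu^2.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-peak
#'   baseline means.
#' @param pop_sd SD (log2 scale) of peak x population shifts (0 disables).
#' @param gc_confound plant a GC shift in the differential peaks.
#' @param gc_mean,gc_shift mean GC of null peaks and additive shift of
#'   differential peaks under the confound.
#' @param seed integer seed.
#' @return list with `matrix` (a [peak_matrix()]; `peaks$gc` holds GC) and
#'   `truth` (peak, true_log2fc, differential, gc, plus the dispersion and
#'   seed used).
#' @export
simulate_count_matrix <- function(n_peaks, samples, effects = NULL,
                                  effect_source = NULL, dispersion = 0.05,
                                  baseline_meanlog = log(200),
                                  baseline_sdlog = 1, pop_sd = 0.25,
                                  gc_confound = FALSE, gc_mean = 0.45,
                                  gc_shift = 0.10, seed = 1L) {
  stopifnot(n_peaks >= 1, dispersion > 0)
  if (!all(c("sample", "source") %in% names(samples)))
    stop("sample sheet needs 'sample' and 'source' columns")
  src <- factor(samples$source)
  if (nlevels(src) != 2L) stop("exactly two source levels required")
  if (any(table(src) < 2L)) stop("need >= 2 samples per source level")
  if (is.null(effect_source)) effect_source <- levels(src)[1]
  if (!effect_source %in% levels(src)) stop("unknown effect_source")
  has_pop <- "population" %in% names(samples)
  if (has_pop) {
    X <- stats::model.matrix(~ source + factor(population), data = samples)
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
      stop("degenerate design; aliased column(s): ",
           paste(aliased, collapse = ", "))
    }
  }
  if (is.null(effects)) effects <- numeric(n_peaks)
  stopifnot(length(effects) == n_peaks)
  n_s <- nrow(samples)
  .with_seed(seed, {
    baseline <- stats::rlnorm(n_peaks, baseline_meanlog, baseline_sdlog)
    sf <- stats::rlnorm(n_s, 0, 0.15)
    x <- as.numeric(samples$source == effect_source)
    log2mu <- outer(log2(baseline), rep(1, n_s)) + outer(effects, x) +
      matrix(log2(sf), n_peaks, n_s, byrow = TRUE)
    if (has_pop && pop_sd > 0) {
      pops <- factor(samples$population)
      shift <- matrix(stats::rnorm(n_peaks * nlevels(pops), 0, pop_sd),
                      n_peaks, nlevels(pops))
      log2mu <- log2mu + shift[, as.integer(pops), drop = FALSE]
    }
    counts <- matrix(stats::rnbinom(n_peaks * n_s, mu = 2^log2mu,
                                    size = 1 / dispersion),
                     n_peaks, n_s, dimnames = list(NULL, samples$sample))
    conc <- 40
    is_diff <- effects != 0
    gc_mu <- ifelse(gc_confound & is_diff, gc_mean + gc_shift, gc_mean)
    gc <- stats::rbeta(n_peaks, gc_mu * conc, (1 - gc_mu) * conc)
    peaks <- data.frame(chrom = "chr1",
                        start = (seq_len(n_peaks) - 1L) * 1000L,
                        end = (seq_len(n_peaks) - 1L) * 1000L + 500L,
                        gc = gc)
    truth <- data.frame(peak = peak_id(peaks), true_log2fc = effects,
                        differential = is_diff, gc = gc)
    attr(truth, "dispersion") <- dispersion
    attr(truth, "effect_source") <- effect_source
    attr(truth, "seed") <- seed
    list(matrix = peak_matrix(peaks, counts, samples), truth = truth)
  })
}

#' Simulate a GC-confounded null for motif enrichment
#'
#' Generates the situation GC-matched background sampling exists to defuse:
#' differential peaks have a GC distribution shifted upward relative to the
#' background pool, and motif presence in any peak depends only on its GC
#' (logistic in GC), with no true association with differential status.
#' A naive random background then shows spurious Fisher enrichment; a
#' GC-matched background should not.
#'
#' @param n_diff number of differential peaks.
#' @param n_pool number of candidate background peaks.
#' @param gc_mean mean GC of the background pool.
#' @param gc_shift additive GC shift of the differential peaks.
#' @param conc beta concentration of the GC distributions.
#' @param presence_intercept,presence_slope logistic model of motif presence,
#'   `P(present) = plogis(intercept + slope * gc)`.
#' @param seed integer seed.
#' @return list with `diff_gc`, `pool_gc`, `diff_present`, `pool_present`.
#' @export
simulate_gc_confound <- function(n_diff = 500L, n_pool = 20000L,
                                 gc_mean = 0.45, gc_shift = 0.06, conc = 40,
                                 presence_intercept = -4,
                                 presence_slope = 8, seed = 1L) {
  .with_seed(seed, {
    diff_gc <- stats::rbeta(n_diff, (gc_mean + gc_shift) * conc,
                            (1 - gc_mean - gc_shift) * conc)
    pool_gc <- stats::rbeta(n_pool, gc_mean * conc, (1 - gc_mean) * conc)
    pr <- function(gc) stats::plogis(presence_intercept + presence_slope * gc)
    list(diff_gc = diff_gc, pool_gc = pool_gc,
         diff_present = stats::runif(n_diff) < pr(diff_gc),
         pool_present = stats::runif(n_pool) < pr(pool_gc))
  })
}

#' Default two-source sample sheet for simulations
#'
#' Mirrors a sorted-population comparison design: two sources and
#' `n_populations` stages with `n_replicates` samples per (source,
#' population) cell.
#'
#' @param sources two source labels.
#' @param n_populations number of population stages per source.
#' @param n_replicates replicates per source x population.
#' @return sample sheet data.frame (sample, source, population).
#' @export
synthetic_sample_sheet <- function(sources = c("BM", "CB"),
                                   n_populations = 7L, n_replicates = 2L) {
  stopifnot(length(sources) == 2L)
  df <- expand.grid(replicate = seq_len(n_replicates),
                    population = seq_len(n_populations),
                    source = sources, stringsAsFactors = FALSE)
  data.frame(sample = sprintf("%s_p%d_r%d", df$source, df$population,
                              df$replicate),
             source = df$source, population = df$population)
}
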