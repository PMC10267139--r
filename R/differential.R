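# Differential accessibility: per-peak negative-binomial GLM with covariates,
# Wald test on the source contrast, BH correction, and the threshold labels
# that feed motif enrichment.

#' Population windows used to group samples before testing
#'
#' The standard scheme groups seven sorted populations into early (1-2),
#' mid (3-5) and late (6-7) maturation windows.
#'
#' @param name one of "early", "mid", "late", or "custom".
#' @param members population ids when `name = "custom"`.
#' @return integer vector of population ids.
#' @export
population_window <- function(name = c("early", "mid", "late", "custom"),
                              members = NULL) {
  name <- match.arg(name)
  switch(name,
         early = 1:2, mid = 3:5, late = 6:7,
         custom = {
           if (is.null(members)) stop("custom window needs members")
           as.integer(members)
         })
}

# standard errors of glm.fit coefficients (unit-dispersion family)
.glm_coef_se <- function(fit) {
  p <- fit$rank
  Qr <- fit$qr
  covmat <- chol2inv(Qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- rep(NA_real_, length(fit$coefficients))
  se[Qr$pivot[seq_len(p)]] <- sqrt(diag(covmat))
  names(se) <- names(fit$coefficients)
  se
}

# per-peak NB dispersion by Cox-Reid adjusted profile maximum likelihood:
# the -0.5 log det(X' W X) adjustment removes the downward bias the plain
# MLE incurs from the fitted coefficients
.nb_alpha_mle <- function(y, mu, X) {
  if (all(y == 0) || all(mu <= 0)) return(NA_real_)
  nll <- function(la) {
    a <- exp(la)
    w <- mu / (1 + a * mu)
    cr <- 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
    -sum(stats::dnbinom(y, mu = mu, size = 1 / a, log = TRUE)) + cr
  }
  exp(stats::optimize(nll, interval = c(log(1e-8), log(30)))$minimum)
}

#' Negative-binomial Wald test for differential accessibility
#'
#' Per peak, a negative-binomial log-link GLM is fit by iteratively
#' reweighted least squares with `log(size factor)` offsets and the design
#' `~ source + covariates`. Per-peak dispersions are estimated by Cox-Reid
#' adjusted profile maximum likelihood (the adjustment removes the downward
#' bias due to the fitted coefficients) and shrunk toward the across-peak
#' trend mean by a 50/50 blend
#' in log space; the Wald statistic on the source coefficient (converted to
#' the log2 scale) is compared with a standard normal, and p-values are
#' BH-adjusted across tested peaks. Peaks with all-zero counts are excluded
#' from testing and from the BH denominator.
#'
#' @param pm a [peak_matrix()]; `pm$samples` must contain the contrast
#'   column and any covariates.
#' @param window optional population ids (see [population_window()]); only
#'   samples whose `population` is in the window are used.
#' @param contrast length-3 character vector `c(column, levelA, levelB)`;
#'   positive log2fc means higher in `levelA`.
#' @param covariates character vector of sample-sheet columns modeled as
#'   categorical covariates (default "population" when present).
#' @return data.frame with peak coordinates and per-peak `base_mean`,
#'   `log2fc`, `se`, `wald`, `p`, `fdr`. The contrast is stored in
#'   `attr(, "contrast")`.
#' @export
fit_nb_wald <- function(pm, window = NULL,
                        contrast = c("source", "BM", "CB"),
                        covariates = NULL) {
  stopifnot(inherits(pm, "PeakMatrix"), length(contrast) == 3L)
  samples <- pm$samples
  counts <- pm$counts
  if (!is.null(window)) {
    if (!"population" %in% names(samples))
      stop("sample sheet has no 'population' column for windowing")
    keep <- samples$population %in% window
    samples <- samples[keep, , drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }
  ccol <- contrast[1]
  if (!ccol %in% names(samples)) stop("no sample column '", ccol, "'")
  lvls <- c(contrast[3], contrast[2])           # reference = levelB
  if (!all(lvls %in% samples[[ccol]]))
    stop("contrast levels absent from '", ccol, "'")
  grp <- factor(samples[[ccol]], levels = lvls)
  if (any(table(grp) < 2L)) stop("need >= 2 samples per contrast level")
  if (is.null(covariates))
    covariates <- intersect("population", names(samples))
  constant <- vapply(covariates,
                     function(cv) length(unique(samples[[cv]])) < 2L, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    covariates <- covariates[!constant]
  }
  dat <- data.frame(.grp = grp)
  for (cv in covariates) dat[[cv]] <- factor(samples[[cv]])
  form <- stats::as.formula(paste("~", paste(c(".grp", covariates), collapse = " + ")))
  X <- stats::model.matrix(form, data = dat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix rank-deficient; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  coef_name <- paste0(".grp", contrast[2])
  sf <- size_factors(counts)
  offset <- log(sf)
  n_peaks <- nrow(counts)
  scaled_means <- rowMeans(sweep(counts, 2L, sf, "/"))

  fit_one <- function(y, alpha) {
    fam <- if (is.null(alpha)) stats::poisson() else
      MASS::negative.binomial(theta = 1 / alpha)
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                    control = stats::glm.control(maxit = 50)))
  }

  # pass 1: per-peak dispersion MLEs
  alpha_mle <- rep(NA_real_, n_peaks)
  tested <- rowSums(counts) > 0
  for (i in which(tested)) {
    y <- counts[i, ]
    f0 <- fit_one(y, NULL)
    a0 <- .nb_alpha_mle(y, f0$fitted.values, X)
    if (is.na(a0)) next
    f1 <- fit_one(y, max(a0, 1e-8))
    alpha_mle[i] <- .nb_alpha_mle(y, f1$fitted.values, X)
  }
  n_dropped <- sum(!tested)
  if (n_dropped) message(n_dropped, " all-zero peak(s) excluded from testing")
  # trend center = arithmetic mean of the CR-adjusted MLEs (the geometric
  # mean is biased low by Jensen); the blend below stays in log space
  trend_alpha <- mean(alpha_mle[is.finite(alpha_mle)])
  if (!is.finite(trend_alpha) || trend_alpha <= 0) trend_alpha <- 0.05
  trend <- log(trend_alpha)

  # pass 2: final fit at the shrunk dispersion
  out <- data.frame(pm$peaks[, c("chrom", "start", "end"), drop = FALSE],
                    base_mean = scaled_means, log2fc = NA_real_,
                    se = NA_real_, wald = NA_real_, p = NA_real_,
                    fdr = NA_real_)
  out$peak <- peak_id(pm$peaks)
  for (i in which(tested)) {
    la <- if (is.na(alpha_mle[i])) trend else
      0.5 * (log(pmax(alpha_mle[i], trend_alpha / 20)) + trend)
    alpha <- min(max(exp(la), 1e-8), 30)
    fit <- fit_one(counts[i, ], alpha)
    beta <- fit$coefficients[coef_name]
    se <- .glm_coef_se(fit)[coef_name]
    if (!is.finite(beta) || !is.finite(se) || se <= 0) next
    out$log2fc[i] <- beta / log(2)
    out$se[i] <- se / log(2)
    out$wald[i] <- beta / se
    out$p[i] <- 2 * stats::pnorm(-abs(out$wald[i]))
  }
  out$fdr[!is.na(out$p)] <- stats::p.adjust(out$p[!is.na(out$p)], method = "BH")
  attr(out, "contrast") <- contrast
  out
}

#' Label peaks as differential, background, or neither
#'
#' `differential_up_A`: fdr < `fdr_max` and log2fc > `lfc_min`;
#' `differential_up_B`: fdr < `fdr_max` and log2fc < `-lfc_min`;
#' `background`: p > `bg_p_min` and |log2fc| < `lfc_min`; everything else
#' (including untested peaks) is `neither`. A is the first contrast level of
#' [fit_nb_wald()] (e.g. BM), B the second.
#'
#' @param result data.frame from [fit_nb_wald()].
#' @param fdr_max FDR threshold for the differential sets (default 0.1).
#' @param lfc_min log2 fold-change threshold (default `log2(1.25)`).
#' @param bg_p_min minimum raw p for the background set (default 0.1).
#' @return the result with a `label` column added.
#' @export
label_peaks <- function(result, fdr_max = 0.1, lfc_min = log2(1.25),
                        bg_p_min = 0.1) {
  lab <- rep("neither", nrow(result))
  ok <- !is.na(result$p)
  lab[ok & result$fdr < fdr_max & result$log2fc > lfc_min] <- "differential_up_A"
  lab[ok & result$fdr < fdr_max & result$log2fc < -lfc_min] <- "differential_up_B"
  lab[ok & result$p > bg_p_min & abs(result$log2fc) < lfc_min] <- "background"
  result$label <- lab
  result
}

#' Fold change of peaks overlapping a query region
#'
#' @param result data.frame from [fit_nb_wald()] (peak coordinates attached).
#' @param query either a data.frame with chrom/start/end or a string
#'   "chrom:start-end" (0-based half-open).
#' @return the overlapping rows in atlas order, with a `fold_change`
#'   (`2^log2fc`) column; empty when nothing overlaps.
#' @export
region_fold_change <- function(result, query) {
  if (is.character(query)) {
    m <- regmatches(query, regexec("^(.+):(\\d+)-(\\d+)$", query))[[1]]
    if (length(m) != 4L) stop("query must be 'chrom:start-end'")
    query <- data.frame(chrom = m[2], start = as.integer(m[3]),
                        end = as.integer(m[4]))
  }
  hit <- result$chrom == query$chrom[1] &
    result$start < query$end[1] & result$end > query$start[1]
  rows <- result[hit, , drop = FALSE]
  rows$fold_change <- 2^rows$log2fc
  rows
}
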