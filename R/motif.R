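# Position weight matrices: construction, JASPAR / MEME-minimal parsers, and
# genome scanning with exact match p-values obtained by dynamic-programming
# convolution of the integer-discretized column score distributions.

#' Construct a position weight matrix
#'
#' @param probs 4 x W numeric matrix of per-column base probabilities, rows
#'   in A, C, G, T order. Each column must sum to 1 (within 1e-6). Zero
#'   entries are replaced by a 1e-4 pseudo-probability and the column
#'   renormalized, with a message.
#' @param id motif identifier.
#' @param name optional human-readable name.
#' @param background base frequencies of the scanning null model (A, C, G,
#'   T); default uniform.
#' @return object of class `pwm`.
#' @export
pwm <- function(probs, id, name = id, background = rep(0.25, 4)) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) stop("probs must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 4L) stop("PWM width must be >= 4")
  if (any(probs < 0)) stop("negative PWM entries")
  if (any(probs == 0)) {
    message("PWM '", id, "': zero entries replaced by 1e-4 pseudo-probability")
    probs[probs == 0] <- 1e-4
  }
  csum <- colSums(probs)
  if (any(abs(csum - 1) > 1e-6 & abs(csum) < .Machine$double.eps))
    stop("empty PWM column")
  probs <- sweep(probs, 2L, csum, "/")
  stopifnot(length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  rownames(probs) <- BASES
  structure(list(id = id, name = name, probs = probs,
                 background = background), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%s), width %d, consensus %s\n",
              x$id, x$name, ncol(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' Width (number of columns) of a PWM
#' @param x a [pwm()].
#' @export
pwm_width <- function(x) ncol(x$probs)

#' Read PWMs from a JASPAR-format file
#'
#' Accepts the standard JASPAR text layout: a `>ID name` header followed by
#' four lines `A [ 12 3 ... ]` (brackets optional). Counts are converted to
#' probabilities per column.
#'
#' @param path file path.
#' @param background scanning background passed to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no JASPAR records in ", path)
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1L) hdr[2] else id
    rows <- lapply(BASES, function(b) {
      ln <- grep(paste0("^\\s*", b, "[\\s\\[]"), block, perl = TRUE, value = TRUE)
      if (length(ln) != 1L) stop("JASPAR record ", id, ": need one '", b, "' row")
      as.numeric(strsplit(trimws(gsub("[][A-Za-z]", " ", ln)), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("JASPAR record ", id, ": ragged rows")
    m <- do.call(rbind, rows)
    out[[id]] <- pwm(sweep(m, 2L, colSums(m), "/"), id = id, name = name,
                     background = background)
  }
  out
}

#' Read PWMs from a MEME minimal-format file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections; the
#' file-level `Background letter frequencies` line, when present, becomes
#' the scanning background.
#'
#' @param path file path.
#' @return named list of [pwm()] objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl)) {
    tok <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    if (all(BASES %in% names(vals))) bg <- unname(vals[BASES])
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    hdr <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- hdr[2]
    name <- if (length(hdr) > 2L) hdr[3] else id
    mat_line <- grep("letter-probability matrix", lines)
    mat_line <- mat_line[mat_line > s][1]
    if (is.na(mat_line)) stop("MOTIF ", id, ": no letter-probability matrix")
    w <- as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[mat_line]))
    rows <- lines[(mat_line + 1L):(mat_line + w)]
    m <- t(vapply(rows, function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]]),
                  numeric(4)))
    out[[id]] <- pwm(t(m), id = id, name = name, background = bg)
  }
  out
}

# integer-discretized log-likelihood-ratio score matrix (milli-bits) and the
# exact null distribution of the total score under the background model
.pwm_score_model <- function(pwm, granularity = 1000) {
  S <- round(granularity * log2(pwm$probs / pwm$background))
  q <- pwm$background
  # DP convolution over columns; track offset so the array starts at 0
  dist <- 1
  offset <- 0L
  for (j in seq_len(ncol(S))) {
    s <- S[, j]
    mn <- min(s)
    rng <- max(s) - mn
    new <- numeric(length(dist) + rng)
    for (b in 1:4) {
      sh <- s[b] - mn
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * q[b]
    }
    dist <- new
    offset <- offset + mn
  }
  pval <- rev(cumsum(rev(dist)))      # P(score >= offset + k - 1)
  pval <- pmin(pval, 1)
  list(S = S, offset = offset, pval = pval, granularity = granularity)
}

# integer scores of every window of an encoded sequence under score matrix S
.window_scores <- function(enc, S) {
  W <- ncol(S)
  n <- length(enc) - W + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(W)) {
    v <- S[enc[j:(n + j - 1L)], j]
    v[is.na(v)] <- -Inf               # windows with N never match
    sc <- sc + v
  }
  sc
}

#' Scan a genome for PWM matches with exact p-values
#'
#' Both strands are scored with the log2 likelihood ratio
#' `sum_j log2(p(b_j) / q(b_j))`; the match p-value `P(score >= s)` under
#' the background model is computed exactly by dynamic-programming
#' convolution of the integer-discretized column score distributions
#' (granularity 1/1000 bit). Matches with `p <= p_cutoff` are retained; if
#' more than `max_instances` remain, the best by p-value are kept (ties by
#' genomic coordinate).
#'
#' @param genome named character vector of contigs (a bare string is treated
#'   as contig "chr1").
#' @param pwm a [pwm()].
#' @param p_cutoff match p-value cutoff (default 1e-4). Note that a motif of
#'   width W cannot score below `prod(background)^W`, so cutoffs below
#'   `4^-W` (uniform background) return nothing.
#' @param max_instances cap on retained instances per motif (default 5e5).
#' @return data.frame: motif, chrom, start, end (0-based half-open), strand,
#'   score (bits), p; sorted by coordinate.
#' @export
scan_pwm <- function(genome, pwm, p_cutoff = 1e-4, max_instances = 500000L) {
  genome <- .as_genome(genome)
  model <- .pwm_score_model(pwm)
  W <- ncol(model$S)
  # minus strand = scan with the reverse-complemented score matrix
  S_rc <- model$S[4:1, W:1, drop = FALSE]
  hits <- list()
  for (chrom in names(genome)) {
    enc <- encode_seq(genome[[chrom]])
    if (length(enc) < W) next
    for (strand in c("+", "-")) {
      sc <- .window_scores(enc, if (strand == "+") model$S else S_rc)
      k <- sc - model$offset + 1      # index into pval table
      ok <- which(is.finite(sc) & k >= 1)
      if (!length(ok)) next
      p <- rep(1, length(sc))
      p[ok] <- model$pval[pmin(k[ok], length(model$pval))]
      keep <- ok[p[ok] <= p_cutoff]
      if (!length(keep)) next
      hits[[paste(chrom, strand)]] <- data.frame(
        motif = pwm$id, chrom = chrom, start = keep - 1L,
        end = keep - 1L + W, strand = strand,
        score = sc[keep] / model$granularity, p = p[keep])
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      p = numeric(0)))
  }
  res <- do.call(rbind, hits)
  if (nrow(res) > max_instances) {
    ord <- order(res$p, res$chrom, res$start)
    res <- res[ord[seq_len(max_instances)], , drop = FALSE]
  }
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan several PWMs and bind the results
#' @param genome as in [scan_pwm()].
#' @param pwms list of [pwm()] objects.
#' @inheritParams scan_pwm
#' @return combined data.frame of instances.
#' @export
scan_pwms <- function(genome, pwms, p_cutoff = 1e-4, max_instances = 500000L) {
  do.call(rbind, lapply(pwms, function(m)
    scan_pwm(genome, m, p_cutoff = p_cutoff, max_instances = max_instances)))
}

#' Bundled NFI motif fixtures (synthetic stand-ins)
#'
#' Three synthetic PWMs whose consensus sequences are the NFI family sites
#' TGGCANNNTGCCA (full palindromic-spaced site), TGCCAA and GCCAA (the two
#' half-sites). The probability values are constructed (sharp consensus with
#' uniform spacer columns), not taken from any database; they are stand-ins
#' that make planted instances recoverable by the scanner.
#'
#' @param background scanning background passed to [pwm()].
#' @return named list of three [pwm()] objects (`NFI_full`, `NFI_half_T`,
#'   `NFI_half`).
#' @export
nfi_fixture_pwms <- function(background = rep(0.25, 4)) {
  path <- system.file("extdata", "nfi_motifs_synthetic.jaspar",
                      package = "footprintr")
  read_jaspar(path, background = background)
}

#' Random sharp-consensus decoy PWMs
#'
#' Decoys for ranking experiments: each motif has a random consensus of the
#' requested width with probability `sharpness` on the consensus base.
#'
#' @param n number of decoys.
#' @param width motif width (recycled).
#' @param sharpness consensus base probability.
#' @param seed integer seed.
#' @return named list of [pwm()] objects `decoy01`, `decoy02`, ...
#' @export
decoy_pwms <- function(n, width = 6L, sharpness = 0.91, seed = 1L) {
  width <- rep_len(width, n)
  .with_seed(seed, {
    out <- list()
    for (i in seq_len(n)) {
      cons <- sample.int(4L, width[i], replace = TRUE)
      probs <- matrix((1 - sharpness) / 3, 4L, width[i])
      probs[cbind(cons, seq_len(width[i]))] <- sharpness
      id <- sprintf("decoy%02d", i)
      out[[id]] <- pwm(probs, id = id)
    }
    out
  })
}
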