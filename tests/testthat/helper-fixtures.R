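# Shared fixtures, built in code at test time.

# a sharp single-consensus PWM from a string like "TGCCAA"
consensus_pwm <- function(cons, id = cons, sharpness = 0.91) {
  idx <- match(strsplit(cons, "")[[1]], c("A", "C", "G", "T"))
  probs <- matrix((1 - sharpness) / 3, 4, length(idx))
  probs[cbind(idx, seq_along(idx))] <- sharpness
  pwm(probs, id = id)
}

# brute-force interval union on one chromosome (oracle for the atlas merge)
brute_merge <- function(starts, ends, chrom = "chr1") {
  L <- max(ends)
  covered <- logical(L)
  for (i in seq_along(starts)) covered[(starts[i] + 1):ends[i]] <- TRUE
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  keep <- r$values
  data.frame(chrom = chrom, start = begins[keep] - 1L, end = stops[keep])
}

# brute-force BH step-up (oracle for p.adjust)
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# one-sided (enrichment) Fisher p by direct hypergeometric summation with
# choose(); oracle for fisher_presence_test
brute_fisher_greater <- function(a, b, c, d) {
  m <- a + b          # differential peaks
  n <- c + d          # background peaks
  k <- a + c          # peaks with the motif
  hi <- min(m, k)
  x <- a:hi
  sum(choose(m, x) * choose(n, k - x)) / choose(m + n, k)
}

# exhaustive scoring of every window of a sequence on both strands
# (oracle for scan_pwm); llr in milli-bits, integer-discretized like the scan
brute_scan <- function(seq, pwm_obj, p_cutoff) {
  S <- round(1000 * log2(pwm_obj$probs / pwm_obj$background))
  W <- ncol(S)
  q <- pwm_obj$background
  # exact null distribution by enumerating all 4^W words
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  wscore <- vapply(seq_len(nrow(words)),
                   function(i) sum(S[cbind(words[i, ], 1:W)]), numeric(1))
  wprob <- apply(words, 1, function(w) prod(q[w]))
  pval_of <- function(s) sum(wprob[wscore >= s])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  chars <- strsplit(seq, "")[[1]]
  for (i in seq_len(nchar(seq) - W + 1)) {
    win <- chars[i:(i + W - 1)]
    for (strand in c("+", "-")) {
      w <- if (strand == "+") win else rev(unname(comp[win]))
      s <- sum(S[cbind(match(w, c("A", "C", "G", "T")), 1:W)])
      p <- pval_of(s)
      if (p <= p_cutoff)
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, end = i - 1L + W, strand = strand,
          score = s / 1000, p = p)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), ]
}
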