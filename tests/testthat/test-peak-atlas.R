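# Universal peak atlas, counting, VST, percentile filter.

mk_peaks <- function(summits, chrom = "chr1", score = NULL) {
  data.frame(chrom = chrom, start = pmax(summits - 100, 0),
             end = summits + 100, summit = summits,
             score = if (is.null(score)) rev(seq_along(summits)) else score)
}

test_that("summit windows merge according to their spacing", {
  one <- build_universal_peaks(list(mk_peaks(1000)), halfwidth = 250)
  expect_equal(one, data.frame(chrom = "chr1", start = 750, end = 1250))

  near <- build_universal_peaks(list(mk_peaks(c(1000, 1300))), halfwidth = 250)
  expect_equal(nrow(near), 1)
  expect_equal(near$end - near$start, 800)

  far <- build_universal_peaks(list(mk_peaks(c(1000, 1600))), halfwidth = 250)
  expect_equal(nrow(far), 2)
  expect_equal(far$end - far$start, c(500, 500))
})

test_that("atlas construction clips at zero, needs summits, respects top_k", {
  expect_message(clip <- build_universal_peaks(list(mk_peaks(100)),
                                               halfwidth = 250), "clipped")
  expect_equal(clip$start, 0)

  nosum <- mk_peaks(c(500, 700)); nosum$summit[2] <- NA
  expect_error(build_universal_peaks(list(nosum)), "summit")

  pk <- mk_peaks(c(1000, 5000, 9000), score = c(3, 1, 2))
  top2 <- build_universal_peaks(list(pk), top_k = 2, halfwidth = 100)
  expect_equal(top2$start, c(900, 8900))  # scores 3 and 2 kept
})

test_that("the merged atlas equals a brute-force interval union and is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    summits <- sample(500:20000, 40)
    atlas <- build_universal_peaks(list(mk_peaks(summits)), halfwidth = 250)
    oracle <- brute_merge(pmax(summits - 250, 0), summits + 250)
    expect_equal(atlas, oracle)
    # abutting intervals merge
    again <- GenomicRanges::reduce(footprintr:::.as_granges(atlas))
    expect_equal(length(again), nrow(atlas))
    expect_true(all(diff(atlas$start) > 0))
    expect_true(all(atlas$start[-1] >= atlas$end[-nrow(atlas)]))
  }
})

test_that("cut counting matches a naive per-cut linear scan", {
  set.seed(7)
  atlas <- build_universal_peaks(
    list(mk_peaks(sort(sample(seq(500, 60000, by = 900), 50)))),
    halfwidth = 200)
  cuts <- data.frame(chrom = "chr1", pos = sample(0:60500, 5000, replace = TRUE),
                     strand = "+")
  counted <- count_cuts_in_peaks(cuts, atlas)
  naive <- vapply(seq_len(nrow(atlas)), function(i)
    sum(cuts$pos >= atlas$start[i] & cuts$pos < atlas$end[i]), integer(1))
  expect_identical(as.integer(counted), naive)
  expect_lte(sum(counted), nrow(cuts))

  expect_identical(count_cuts_in_peaks(cuts[0, ], atlas), integer(nrow(atlas)))
  inside <- data.frame(chrom = "chr1",
                       pos = seq(atlas$start[1], atlas$start[1] + 9), strand = "+")
  ten <- count_cuts_in_peaks(inside, atlas)
  expect_equal(ten[1], 10)
  expect_equal(sum(ten), 10)
  suppressWarnings(
    expect_message(count_cuts_in_peaks(data.frame(chrom = "chrX", pos = 5,
                                                  strand = "+"), atlas),
                   "absent from atlas"))
})

test_that("size factors recover known scaling and VST evens out the variance", {
  peaks <- data.frame(chrom = "chr1", start = (0:4) * 1000, end = (0:4) * 1000 + 500)
  base <- c(10L, 40L, 100L, 7L, 300L)
  counts <- cbind(s1 = base, s2 = base * 2L)
  samples <- data.frame(sample = c("s1", "s2"))
  sf <- size_factors(counts)
  expect_equal(sf[2] / sf[1], 2.0)

  pm <- vst_normalize(peak_matrix(peaks, cbind(s1 = base, s2 = base), samples))
  expect_equal(pm$size_factors, c(1, 1), tolerance = 1e-12)
  expect_equal(pm$normalized[, 1], pm$normalized[, 2])

  # monotone in counts within a sample
  ord <- order(base)
  expect_true(all(diff(pm$normalized[ord, 1]) > 0))
})

test_that("VST flattens the SD-vs-mean trend on NB data with common dispersion", {
  set.seed(31)
  n <- 600
  mu <- 2^runif(n, 4, 12)
  counts <- sapply(1:8, function(j) rnbinom(n, mu = mu, size = 1 / 0.05))
  colnames(counts) <- paste0("s", 1:8)
  pm <- peak_matrix(data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 600,
                               end = (seq_len(n) - 1) * 600 + 500),
                    counts, data.frame(sample = paste0("s", 1:8)))
  pm <- vst_normalize(pm)
  m <- rowMeans(pm$normalized)
  s <- apply(pm$normalized, 1, sd)
  slope <- coef(lm(s ~ m))[2]
  expect_lt(abs(slope), 0.05)
  # raw log counts, for contrast, have a strongly negative slope
  raw_s <- apply(log2(counts + 1), 1, sd)
  expect_gt(abs(coef(lm(raw_s ~ m))[2]), abs(slope))
})

test_that("percentile filter applies the interpolated quantile threshold", {
  counts <- matrix(1:10, ncol = 1, dimnames = list(NULL, "s1"))
  counts <- cbind(counts, s2 = rep(0L, 10))
  pm <- peak_matrix(data.frame(chrom = "chr1", start = (0:9) * 600,
                               end = (0:9) * 600 + 500),
                    counts, data.frame(sample = c("s1", "s2")))
  kept <- percentile_filter(pm, q = 0.8, channel = "counts")
  expect_equal(nrow(kept$counts), 2)           # maxima 9, 10 >= 8.2
  expect_equal(kept$counts[, "s1"], c(9L, 10L), ignore_attr = TRUE)

  allsame <- peak_matrix(pm$peaks, matrix(5L, 10, 2,
                                          dimnames = list(NULL, c("s1", "s2"))),
                         data.frame(sample = c("s1", "s2")))
  expect_equal(nrow(percentile_filter(allsame, 0.8, "counts")$counts), 10)
  expect_equal(nrow(percentile_filter(pm, 0, "counts")$counts), 10)
  expect_error(percentile_filter(pm, 1, "counts"), "q must")
  expect_error(percentile_filter(pm, -0.1, "counts"), "q must")
})
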