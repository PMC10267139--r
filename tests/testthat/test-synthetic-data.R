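# Generators: genomes, bias tables, planted instances, cut sites, counts.

test_that("make_genome honors length, GC content, and seed", {
  g <- make_genome(4000, 0.5, seed = 1)
  expect_equal(nchar(g), 4000)
  expect_true(all(strsplit(g, "")[[1]] %in% c("A", "C", "G", "T")))

  g2 <- make_genome(1e5, 0.6, seed = 7)
  gc <- mean(strsplit(g2, "")[[1]] %in% c("G", "C"))
  expect_gte(gc, 0.59)
  expect_lte(gc, 0.61)

  expect_identical(make_genome(5000, 0.4, seed = 3),
                   make_genome(5000, 0.4, seed = 3))
  expect_false(identical(make_genome(5000, 0.4, seed = 3),
                         make_genome(5000, 0.4, seed = 4)))
  expect_error(make_genome(500, 0.5), "length")
  expect_error(make_genome(5000, 0), "gc_fraction")
  expect_error(make_genome(5000, 1), "gc_fraction")
})

test_that("bias tables satisfy their invariants and strand symmetry", {
  b <- make_bias_table(seed = 2)
  expect_length(b, 4096)
  expect_true(all(b > 0))
  expect_lt(abs(mean(b) - 1), 1e-9)
  rc <- footprintr:::hexamer_revcomp_table()
  expect_equal(b, b[rc])
  expect_identical(make_bias_table(seed = 2), make_bias_table(seed = 2))
})

test_that("planted consensus instances appear at the recorded coordinates", {
  pw <- consensus_pwm("TGCCAA")
  g <- make_genome(5000, 0.5, seed = 9)
  res <- plant_motif_instances(g, pw, n = 8, seed = 4, margin = 250)
  expect_equal(nrow(res$instances), 8)
  for (i in seq_len(8)) {
    inst <- res$instances[i, ]
    written <- substr(res$genome[[1]], inst$start + 1, inst$end)
    expected <- if (inst$strand == "+") "TGCCAA" else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString("TGCCAA")))
    expect_identical(written, expected)
    expect_gte(inst$start, 250)
    expect_lte(inst$end, 5000 - 250)
  }
})

test_that("planting n = 0 leaves the genome unchanged; protected count is exact", {
  pw <- consensus_pwm("TGCCAA")
  g <- make_genome(5000, 0.5, seed = 9)
  res0 <- plant_motif_instances(g, pw, n = 0, seed = 1)
  expect_identical(unname(res0$genome[[1]]), g)
  expect_equal(nrow(res0$instances), 0)

  res <- plant_motif_instances(make_genome(100000, 0.5, seed = 1), pw,
                               n = 50, protected_fraction = 0.5, seed = 2)
  expect_equal(sum(res$instances$protected), 25)
})

test_that("successive plantings with exclude never overlap earlier instances", {
  g <- make_genome(50000, 0.5, seed = 5)
  p1 <- plant_motif_instances(g, consensus_pwm("TGCCAA"), n = 40, seed = 1)
  p2 <- plant_motif_instances(p1$genome, consensus_pwm("GGGTTTAC", id = "x"),
                              n = 40, seed = 2, exclude = p1$instances)
  for (i in seq_len(nrow(p1$instances))) {
    inst <- p1$instances[i, ]
    expect_identical(substr(p2$genome[[1]], inst$start + 1, inst$end),
                     if (inst$strand == "+") "TGCCAA" else "TTGGCA")
  }
})

test_that("uniform-bias cut sites are multinomially uniform", {
  g <- make_genome(10000, 0.5, seed = 11)
  cuts <- simulate_cut_sites(g, rep(1, 4096), depth = 1e6, seed = 12)
  expect_equal(nrow(cuts), 1e6)
  expect_false(is.unsorted(cuts$pos))
  # support excludes 5 bases at each end
  expect_gte(min(cuts$pos), 5)
  expect_lte(max(cuts$pos), 10000 - 6)
  counts <- tabulate(cuts$pos - 4, 10000 - 10)
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("full protection yields zero cuts inside protected instances", {
  g <- make_genome(20000, 0.5, seed = 13)
  pw <- consensus_pwm("TGCCAA")
  res <- plant_motif_instances(g, pw, n = 20, protected_fraction = 1, seed = 3)
  cuts <- simulate_cut_sites(res$genome, rep(1, 4096), depth = 2e5, seed = 14,
                             instances = res$instances, protection_factor = 0)
  for (i in seq_len(nrow(res$instances))) {
    inst <- res$instances[i, ]
    expect_equal(sum(cuts$pos >= inst$start & cuts$pos < inst$end), 0)
  }
})

test_that("an up-weighted hexamer gains a proportional share of cuts", {
  g <- make_genome(100000, 0.5, seed = 15)
  rc <- footprintr:::hexamer_revcomp_table()
  h <- match("TGACGT", footprintr:::hexamer_string(1:4096))
  bias <- rep(1, 4096)
  bias[c(h, rc[h])] <- 10
  bias <- bias / mean(bias)
  cuts <- simulate_cut_sites(g, bias, depth = 1e6, seed = 16)
  hex <- footprintr:::hexamer_codes(footprintr:::encode_seq(g))
  anchors <- hex[cuts$pos - 2L]
  genome_share <- mean(hex %in% c(h, rc[h]))
  cut_share <- mean(anchors %in% c(h, rc[h]), na.rm = TRUE)
  expect_gt(cut_share / genome_share, 10 * 0.85)
  expect_lt(cut_share / genome_share, 10 * 1.15)
})

test_that("cut-site generation is reproducible under the seed", {
  g <- make_genome(20000, 0.5, seed = 1)
  b <- make_bias_table(seed = 1)
  expect_identical(simulate_cut_sites(g, b, depth = 1e4, seed = 5),
                   simulate_cut_sites(g, b, depth = 1e4, seed = 5))
})

test_that("NB counts approach the Poisson limit as dispersion vanishes", {
  sheet <- data.frame(sample = paste0("s", 1:20),
                      source = rep(c("BM", "CB"), each = 10))
  sim <- simulate_count_matrix(300, sheet, dispersion = 1e-6,
                               baseline_meanlog = log(500),
                               baseline_sdlog = 0, pop_sd = 0, seed = 21)
  # remove the size-factor component by scaling columns
  sc <- sweep(sim$matrix$counts, 2, colMeans(sim$matrix$counts) /
                mean(sim$matrix$counts), "/")
  cv <- apply(sc, 1, sd) / rowMeans(sc)
  expect_lt(abs(median(cv) * sqrt(median(rowMeans(sc))) - 1), 0.2)
})

test_that("confounded designs are rejected with the aliased columns named", {
  sheet <- data.frame(sample = paste0("s", 1:8),
                      source = rep(c("BM", "CB"), each = 4),
                      population = rep(1:2, each = 4))  # source == population
  expect_error(simulate_count_matrix(50, sheet, seed = 1), "aliased")
})

test_that("gc-confounded truth shifts differential peak GC upward", {
  sheet <- synthetic_sample_sheet(n_populations = 2)
  eff <- c(rep(2, 200), rep(0, 800))
  sim <- simulate_count_matrix(1000, sheet, effects = eff, gc_confound = TRUE,
                               seed = 22)
  expect_gt(mean(sim$truth$gc[sim$truth$differential]),
            mean(sim$truth$gc[!sim$truth$differential]) + 0.03)
  expect_identical(sim$truth$differential, eff != 0)
})
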