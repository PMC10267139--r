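# Hexamer models, expected profiles, footprint scores, FA/FPD.

hexstr <- footprintr:::hexamer_string

test_that("hexamer encoding and reverse-complement tables are involutions", {
  rc <- footprintr:::hexamer_revcomp_table()
  expect_equal(rc[rc], 1:4096)
  expect_equal(hexstr(match("TGACGT", hexstr(1:4096))), "TGACGT")
  h <- footprintr:::hexamer_codes(footprintr:::encode_seq("ACGTACGTA"))
  expect_equal(hexstr(h[1]), "ACGTAC")
  expect_equal(hexstr(h[4]), "TACGTA")
})

test_that("genomic hexamer frequencies match hand enumeration", {
  expect_equal(genome_hexamer_freq("AAAAAAAA", double_stranded = FALSE)[1], 1)
  both <- genome_hexamer_freq("AAAAAAAA")  # counts the minus strand too
  expect_equal(both[1], 0.5)
  expect_equal(both[4096], 0.5)

  g <- "ACGTACGTACGTACGTACGTACGTACGTAC"   # 30 bases
  bl <- data.frame(chrom = "chr1", start = 10, end = 14)
  freq <- genome_hexamer_freq(g, blacklist = bl, double_stranded = FALSE)
  # oracle: windows fully outside [10, 14)
  starts0 <- 0:(nchar(g) - 6)
  keep <- !(starts0 < 14 & starts0 + 6 > 10)
  hexes <- substring(g, starts0 + 1, starts0 + 6)[keep]
  oracle <- table(factor(hexes, levels = hexstr(1:4096))) / sum(keep)
  expect_equal(unname(freq), as.numeric(oracle))
  expect_error(genome_hexamer_freq(g, data.frame(chrom = "chr1", start = 0,
                                                 end = 30)), "blacklisted")
})

test_that("a large random genome concentrates hexamer frequencies", {
  freq <- genome_hexamer_freq(make_genome(3e5, 0.5, seed = 23))
  expect_lt(max(freq), 2 / 4096)
})

test_that("positional hexamer frequencies equal hand tabulation for one instance", {
  g <- make_genome(2000, 0.5, seed = 24)
  inst <- data.frame(motif = "m", chrom = "chr1", start = 1000, end = 1006,
                     strand = "+")
  mat <- positional_hexamer_freq(inst, g, flank = 20)
  expect_equal(dim(mat), c(41, 4096))
  expect_equal(rowMeans(mat), rep(1, 41), ignore_attr = TRUE)
  center <- 1000 + 3
  for (q in c(-20, -3, 0, 7, 20)) {
    hex <- substr(g, center + q - 3 + 1, center + q + 3)
    expect_equal(unname(mat[as.character(q), match(hex, hexstr(1:4096))]), 4096)
  }
})

test_that("opposite-strand instances in a palindromic context agree", {
  core <- "ACGCGT"
  pad <- make_genome(1000, 0.5, seed = 25)
  left <- substr(pad, 1, 400)
  arm <- substr(pad, 401, 700)
  rcarm <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(arm)))
  # genome: left | arm core rc(arm) | arm core rc(arm) (palindromic blocks)
  block <- paste0(arm, core, rcarm)
  g <- paste0(left, block, block)
  s1 <- 400 + 300          # 0-based start of first core
  s2 <- 400 + 606 + 300
  inst <- data.frame(motif = "m", chrom = "chr1",
                     start = c(s1, s2), end = c(s1, s2) + 6,
                     strand = c("+", "-"))
  m1 <- positional_hexamer_freq(inst[1, ], g, flank = 100)
  m2 <- positional_hexamer_freq(inst[2, ], g, flank = 100)
  expect_equal(m1, m2)
})

test_that("cut hexamer factors recover the planted bias", {
  g <- make_genome(200000, 0.5, seed = 26)
  gf <- genome_hexamer_freq(g)
  # null bias: factors near uniform
  cuts0 <- simulate_cut_sites(g, rep(1, 4096), depth = 5e5, seed = 27)
  f0 <- cut_hexamer_factors(cuts0, g, gf)
  expect_equal(sum(f0), 1, tolerance = 1e-12)
  expect_lt(mad(f0) / (1 / 4096), 0.25)

  # one hexamer (and its revcomp) up-weighted tenfold
  rc <- footprintr:::hexamer_revcomp_table()
  h <- match("TGACGT", hexstr(1:4096))
  bias <- rep(1, 4096); bias[c(h, rc[h])] <- 10
  bias <- bias / mean(bias)
  cuts1 <- simulate_cut_sites(g, bias, depth = 5e5, seed = 28)
  f1 <- cut_hexamer_factors(cuts1, g, gf)
  expect_gt(f1[h] / (10 / (4094 + 2 * 10)), 0.8)
  expect_lt(f1[h] / (10 / (4094 + 2 * 10)), 1.2)

  expect_identical(cut_hexamer_factors(cuts1, g, gf),
                   cut_hexamer_factors(cuts1, g, gf))
  expect_warning(cut_hexamer_factors(cuts1[1:10, ], g, gf), "1000")
})

test_that("expected profiles follow the two normalization contracts", {
  g <- make_genome(5000, 0.5, seed = 29)
  inst <- data.frame(motif = "m", chrom = "chr1",
                     start = c(1000, 2000, 3500), end = c(1006, 2006, 3506),
                     strand = c("+", "-", "+"))
  pos <- positional_hexamer_freq(inst, g, flank = 50)
  uniform <- rep(1 / 4096, 4096)
  e <- expected_cut_profile(pos, uniform)
  expect_equal(e, rep(1 / 101, 101), tolerance = 1e-12)

  f <- runif(4096); f <- f / sum(f)
  e2 <- expected_cut_profile(pos, f)
  expect_equal(sum(e2), 1, tolerance = 1e-12)
  oracle <- as.numeric(pos %*% f); oracle <- oracle / sum(oracle)
  expect_equal(e2, oracle)
})

test_that("footprint scores are zero under proportionality and depth-invariant", {
  e <- runif(501) + 0.5; e <- e / sum(e)
  prof <- footprint_score(e * 3000, e)
  expect_equal(prof$score, rep(0, 501), tolerance = 1e-12)

  obs <- rpois(501, 200)
  p1 <- footprint_score(obs, e)
  p2 <- footprint_score(obs * 2, e)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)

  empty <- footprint_score(rep(0, 501), e)
  expect_true(empty$empty)
  expect_true(all(is.na(empty$score)))
})

test_that("footprint regions follow the width formulas", {
  r6 <- footprint_regions(6)
  expect_equal(range(abs(r6$base)), c(0, 8))
  expect_equal(length(r6$base), 17)
  expect_equal(range(abs(r6$flank)), c(13, 50))
  expect_equal(range(abs(r6$background)), c(200, 250))
  expect_equal(length(r6$background), 102)

  r13 <- footprint_regions(13)
  expect_equal(max(abs(r13$base)), 11)       # 13/2 + 5 = 11.5
  expect_equal(min(abs(r13$flank)), 17)      # min(18, 16.5) -> 16.5
  r30 <- footprint_regions(30)
  expect_equal(min(abs(r30$flank)), 18)      # min(18, 25) = 18
  expect_equal(min(abs(footprint_regions(30, flank_rule = "max")$flank)), 25)
})

test_that("FA and FPD match direct region arithmetic on a step profile", {
  prof <- list(position = -250:250, score = rep(0, 501))
  expect_equal(compute_fa_fpd(prof, 12)$fa, 0)
  expect_equal(compute_fa_fpd(prof, 12)$fpd, 0)

  reg <- footprint_regions(12)
  step <- rep(0, 501)
  step[match(reg$base, -250:250)] <- -1
  step[match(reg$flank, -250:250)] <- 0.5
  prof2 <- compute_fa_fpd(list(position = -250:250, score = step), 12)
  expect_equal(prof2$fa, 0.5)
  expect_equal(prof2$fpd, -1.5)

  # masked positions are excluded from the region means
  step_na <- step
  step_na[match(reg$background, -250:250)[1:30]] <- NA
  prof3 <- compute_fa_fpd(list(position = -250:250, score = step_na), 12)
  expect_equal(prof3$fa, 0.5)
})

test_that("the trimmed mean drops floor(0.1 k) values from each tail", {
  x <- 1:10
  expect_equal(mean(x, trim = 0.1), mean(sort(x)[2:9]))
  expect_equal(mean(x, trim = 0.1), 5.5)
  y <- c(100, 1:9)  # outlier suppressed by the trim
  expect_equal(mean(y, trim = 0.1), mean(sort(y)[2:9]))
})

test_that("protected instances show a depressed base region vs unprotected", {
  g <- make_genome(300000, 0.45, seed = 31)
  pw <- nfi_fixture_pwms()$NFI_half_T
  decoy <- consensus_pwm("GATCTAGA", id = "decoy")
  p1 <- plant_motif_instances(g, pw, n = 120, protected_fraction = 1, seed = 32)
  p2 <- plant_motif_instances(p1$genome, decoy, n = 120, seed = 33,
                              exclude = p1$instances)
  genome <- p2$genome
  bias <- make_bias_table(seed = 34)
  cuts <- simulate_cut_sites(genome, bias, depth = 3e5, seed = 35,
                             instances = p1$instances, protection_factor = 0.2)
  fp <- footprint_profiles(cuts, rbind(p1$instances, p2$instances), genome)
  base6 <- footprint_regions(6)$base
  prot_base <- mean(fp$profiles$NFI_half_T$score[match(base6, -250:250)],
                    na.rm = TRUE)
  base8 <- footprint_regions(8)$base
  decoy_base <- mean(fp$profiles$decoy$score[match(base8, -250:250)],
                     na.rm = TRUE)
  expect_lt(prot_base, 0)
  expect_lt(prot_base, decoy_base - 0.5)
  expect_lt(fp$summary$fpd[fp$summary$motif == "NFI_half_T"],
            fp$summary$fpd[fp$summary$motif == "decoy"] - 0.5)
})

test_that("differential footprints are antisymmetric and drop unshared motifs", {
  a <- data.frame(motif = c("m1", "m2", "m3"), width = 6,
                  n_instances = 10, fa = c(0.5, 0.2, 0.1),
                  fpd = c(-1, -0.2, 0))
  b <- data.frame(motif = c("m1", "m2", "m4"), width = 6,
                  n_instances = 10, fa = c(0.1, 0.2, 0.3),
                  fpd = c(-0.1, -0.2, -0.3))
  expect_message(d <- differential_footprint(a, b), "dropped")
  expect_equal(sort(d$motif), c("m1", "m2"))
  expect_equal(d$delta_fpd[d$motif == "m1"], -0.9)
  d0 <- suppressMessages(differential_footprint(a, a))
  expect_equal(d0$delta_fa, rep(0, 3))
  expect_equal(d0$delta_fpd, rep(0, 3))
  dr <- suppressMessages(differential_footprint(b, a))
  expect_equal(sort(dr$delta_fpd), sort(-d$delta_fpd))
})
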