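test_that("cgi_contrast arithmetic and not-available sides", {
  calls <- data.table::data.table(
    position = c(5L, 50L), strand = "forward", context = "CpG",
    n_methylated = c(10L, 70L), n_unmethylated = c(90L, 30L))
  iv <- data.frame(start = 0L, end = 10L)
  cc <- cgi_contrast(calls, iv)
  expect_equal(cc$mc_pct_inside, 10.0)
  expect_equal(cc$mc_pct_outside, 70.0)
  expect_equal(cc$difference, 60.0)
  # everything inside -> outside not available
  cc2 <- cgi_contrast(calls[1], iv)
  expect_true(is.na(cc2$mc_pct_outside))
})

test_that("length frequencies normalise and compare across samples", {
  lf <- length_frequency(c(40L, 40L, 60L, 60L))
  expect_equal(lf$frequency[lf$length == 40], 0.5)
  expect_equal(sum(lf$frequency), 1)
  expect_error(length_frequency(integer(0)), "empty")
  set.seed(1)
  lf2 <- length_frequency(sample(30:90, 500, replace = TRUE))
  expect_equal(sum(lf2$frequency), 1)
  cmp <- compare_length_sets(list(a = c(40L, 60L), b = c(40L, 50L)))
  expect_equal(cmp[cmp$length == 40]$mean, 0.5)
  expect_equal(cmp[cmp$length == 50]$mean, 0.25)
})

test_that("expected_unique evaluates the uniform-amplification closed form", {
  expect_equal(expected_unique(5, 0), 0)
  expect_equal(expected_unique(1, 10), 1)
  expect_equal(expected_unique(1000, 1000), 1000 * (1 - (1 - 1 / 1000)^1000))
  expect_equal(round(expected_unique(1000, 1000), 1), 632.3)
  expect_error(expected_unique(0, 10), "M")
})

test_that("complexity curve is monotone, bounded, and matches the closed form", {
  M <- 1000L; n_total <- 16000L
  set.seed(42)
  mol <- sample.int(M, n_total, replace = TRUE)    # uniform amplification
  aln <- data.table::data.table(
    read_id = sprintf("r%05d", seq_len(n_total)),
    position = mol * 10L, end = mol * 10L + 60L,
    strand_view = "OT", mismatches = 0L, mapq = 37L, duplicate = FALSE)
  cc <- complexity_curve(aln, start = 350L)
  expect_true(all(cc$unique_count <= cc$subsample_size))
  expect_true(all(diff(cc$unique_count) >= 0))
  # replicate subsamples give the Monte-Carlo SE at each ladder point
  reps <- replicate(50, complexity_curve(aln, start = 350L)$unique_count)
  se <- apply(reps, 1, stats::sd)
  expected <- expected_unique(M, cc$subsample_size)
  expect_true(all(abs(cc$unique_count - expected) <= 3 * pmax(se, 1)))

  # all-unique library sits on the diagonal
  aln_u <- data.table::data.table(
    read_id = sprintf("r%04d", 1:2000), position = 1:2000 * 3L,
    end = 1:2000 * 3L + 50L, strand_view = "OT",
    mismatches = 0L, mapq = 37L, duplicate = FALSE)
  cc_u <- complexity_curve(aln_u, start = 350L)
  expect_identical(cc_u$unique_count, cc_u$subsample_size)

  # single-molecule library saturates at 1
  aln_1 <- data.table::data.table(
    read_id = sprintf("r%03d", 1:400), position = 7L, end = 60L,
    strand_view = "OT", mismatches = 0L, mapq = 37L, duplicate = FALSE)
  expect_true(all(complexity_curve(aln_1, start = 350L)$unique_count == 1L))

  # library smaller than the ladder start collapses to one point
  cc_s <- complexity_curve(aln_u[1:100], start = 350L)
  expect_equal(nrow(cc_s), 1L)
  expect_equal(cc_s$subsample_size, 100L)
})

test_that("positive-control scoring counts retained and deaminated Cs", {
  full_top <- control_oligo_sequence("control_full")
  none_top <- control_oligo_sequence("control_none")
  cpos <- which(strsplit(full_top, "")[[1]] == "C")
  # ideal bisulfite: full-methyl keeps all Cs, no-methyl converts all
  conv_none <- chartr("C", "T", none_top)
  one_deam <- full_top
  substr(one_deam, cpos[3], cpos[3]) <- "T"
  reads <- c(full_top, full_top, conv_none, one_deam, rand_dna(60), rand_dna(44))
  rpt <- score_positive_controls(reads)
  full <- rpt$strands[["control_full.top"]]
  expect_equal(full$n_reads, 3L)
  expect_equal(sum(full$per_read_deaminated == 0), 2L)
  expect_equal(sum(full$per_read_deaminated == 1), 1L)   # one C deaminated
  expect_equal(full$per_position$retained + full$per_position$deaminated,
               rep(full$n_reads, 15L))
  none <- rpt$strands[["control_none.top"]]
  expect_equal(none$n_reads, 1L)
  expect_true(all(none$per_position$deaminated == 1L))   # all 15 converted
  expect_equal(rpt$control_fraction, 4 / 6)
})

test_that("control templates carry exactly 15 Cs per strand", {
  for (ctl in c("control_full", "control_none")) {
    top <- control_oligo_sequence(ctl)
    bot <- paleometh:::revcomp_string(top)
    expect_equal(nchar(top), 60L)
    expect_equal(sum(strsplit(top, "")[[1]] == "C"), 15L)
    expect_equal(sum(strsplit(bot, "")[[1]] == "C"), 15L)
  }
  expect_error(control_oligo("control_full", top_sequence = strrep("AC", 30)),
               "15 Cs")
})

test_that("exoVII control scoring recovers trimmed length modes", {
  cfg <- sim_config(exo_residual_support = 3L)
  ctl <- control_oligo("control_exovii")
  # untreated: top strand read is the full 60-mer
  untreated <- apply_conversion(ctl, "none", cfg)
  lf_un <- score_exovii_controls(untreated$seq)
  expect_setequal(lf_un$control_exovii$length, c(40L, 60L))  # both strands
  # treated with residual 3 at both ends: 60 - 2*10 + 2*3 = 46
  set.seed(5)
  trimmed <- apply_conversion(apply_exovii(ctl, cfg), "none", cfg)
  lf_tr <- score_exovii_controls(trimmed$seq)
  expect_true(46L %in% lf_tr$control_exovii$length)
  expect_equal(sum(lf_tr$control_exovii$frequency), 1)
})

test_that("damage profiling refuses converted libraries", {
  aln <- data.table::data.table(read_id = "r1", position = 0L, end = 10L,
                                strand_view = "OT", mismatches = 0L,
                                mapq = 37L, duplicate = FALSE)
  expect_error(ct_by_beta_bin(aln, NULL, NULL, NULL,
                              library_conversion = "bisulfite"),
               "non-converted")
})

test_that("rank-sum test matches full enumeration and handles symmetry", {
  rs <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, enumerate_ranksum_p(c(1, 2), c(3, 4)))
  expect_equal(rs$p_value, 1 / 3, tolerance = 1e-9)
  expect_equal(rank_sum_test(c(5, 6, 7), c(5, 6, 7))$p_value, 1.0)
  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
  # large-sample normal approximation close to enumeration at n = m = 8
  set.seed(3)
  x <- rnorm(8); y <- rnorm(8) + 0.5
  p_exact <- enumerate_ranksum_p(x, y)
  p_norm <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))$p.value
  expect_lt(abs(rank_sum_test(x, y)$p_value - p_exact), 0.02)
  expect_lt(abs(p_norm - p_exact), 0.02)
})

test_that("linear fit matches a hand-computed OLS", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  fit <- linear_fit_r2(x, y)
  # closed-form OLS
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx; intercept <- mean(y) - slope * mean(x)
  r2 <- (sxy^2) / (sxx * sum((y - mean(y))^2))
  expect_equal(fit$slope, slope, tolerance = 1e-6)
  expect_equal(fit$intercept, intercept, tolerance = 1e-6)
  expect_equal(fit$r_squared, r2, tolerance = 1e-6)
  expect_equal(suppressWarnings(linear_fit_r2(x, 2 * x + 1)$r_squared), 1.0)
  expect_error(linear_fit_r2(rep(1, 5), y), "constant")
  set.seed(9)
  noise <- linear_fit_r2(rnorm(500), rnorm(500))
  expect_lt(noise$r_squared, 0.05)
})
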