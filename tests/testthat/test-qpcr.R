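test_that("amplification efficiency matches the closed form", {
  # ideal 10-fold series: Ct step log2(10) = 3.3219 cycles per decade
  s <- data.frame(log10_input = 0:-3, ct = 18 + 3.321928 * (0:3))
  e <- amplification_efficiency(s)
  expect_equal(e$efficiency_percent, 100, tolerance = 1e-4)
  expect_equal(e$r_squared, 1, tolerance = 1e-12)
  # slower amplification: 3.6 cycles per decade
  s2 <- data.frame(log10_input = 0:-3, ct = 18 + 3.6 * (0:3))
  expect_equal(amplification_efficiency(s2)$efficiency_percent, 89.6,
               tolerance = 0.05)
  # 2-fold-per-step series at one cycle per step is exactly E = 100%
  s3 <- data.frame(log10_input = log10(2^-(0:7)), ct = 18 + 0:7)
  expect_equal(amplification_efficiency(s3)$efficiency_percent, 100,
               tolerance = 1e-6)
  expect_error(amplification_efficiency(
    data.frame(log10_input = 0:-1, ct = c(18, 21))), "insufficient")
  expect_error(amplification_efficiency(
    data.frame(log10_input = rep(0, 4), ct = rep(18, 4))),
    "span|degenerate")
})

test_that("comparative-CT folds behave like powers of (1+E)", {
  expect_equal(comparative_ct_fold(20, 20), 1.0)
  expect_equal(comparative_ct_fold(20, 21), 2.0)
  expect_equal(comparative_ct_fold(20, 23.154), 2^3.154, tolerance = 1e-9)
  # reciprocity
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 15, 30); b <- runif(1, 15, 30); e <- runif(1, 0.8, 1)
    expect_equal(comparative_ct_fold(a, b, e) *
                   comparative_ct_fold(b, a, e), 1, tolerance = 1e-12)
  }
})

test_that("relative copy number follows 2^-ddCt", {
  expect_equal(relative_copy_number(20, 20, 20, 20), 1.0)
  expect_equal(relative_copy_number(19, 20, 20, 20), 2.0)
  # two-copy vs one-copy recovery under replicate noise
  set.seed(91)
  est <- replicate(1000, {
    relative_copy_number(ct_target = 19 + rnorm(3, 0, 0.2),
                         ct_reference = 20 + rnorm(3, 0, 0.2),
                         ct_target_calibrator = 20 + rnorm(3, 0, 0.2),
                         ct_reference_calibrator = 20 + rnorm(3, 0, 0.2))
  })
  expect_gt(mean(est), 1.7)
  expect_lt(mean(est), 2.3)
})

test_that("fold recovery from simulated experiments is unbiased", {
  for (f in c(1, 2, 6.5, 8.9)) {
    sim <- simulate_ct_data(f, efficiency = 1, sigma = 0.2,
                            n_replicates = 1000, seed = round(f * 10))
    expect_equal(estimate_fold(sim), f, tolerance = 0.035)
  }
  # noiseless: exact
  sim0 <- simulate_ct_data(2, efficiency = 1, sigma = 0, n_replicates = 3)
  expect_equal(diff(tapply(sim0$replicates$ct, sim0$replicates$condition,
                           mean))[[1]], 1)
  expect_equal(estimate_fold(sim0), 2)
  # the simulated dilution series encodes the requested efficiency
  sim9 <- simulate_ct_data(1, efficiency = 0.9, sigma = 0,
                           n_replicates = 3)
  expect_equal(amplification_efficiency(sim9$dilution_series)$
                 efficiency_percent, 90, tolerance = 1e-6)
})

test_that("discriminating primers anchor polymorphisms at their 3' ends", {
  tab <- host_table()
  native <- native_like_cds(seed = 6)
  res <- design(native, tab, seed = 29, max_rounds = 300, restarts = 4)
  pairs <- design_discriminating_primers(native, res$sequence)
  for (side in c("native", "synthetic")) {
    pp <- pairs[[side]]
    expect_equal(pp$amplicon_length,
                 pairs$native$amplicon_length)
    expect_true(0 %in% pp$discriminating_positions$forward ||
                  any(pp$discriminating_positions$forward <= 2))
    expect_true(0 %in% pp$discriminating_positions$reverse ||
                  any(pp$discriminating_positions$reverse <= 2))
  }
  # primers match their own template and mismatch the other at the 3' end
  f_nat <- pairs$native$forward
  f_syn <- pairs$synthetic$forward
  expect_true(grepl(f_nat, native, fixed = TRUE))
  expect_true(grepl(f_syn, res$sequence, fixed = TRUE))
  expect_false(substr(f_nat, nchar(f_nat), nchar(f_nat)) ==
                 substr(f_syn, nchar(f_syn), nchar(f_syn)))
  # reverse primer is the reverse complement of its template slice
  rp <- pairs$native$reverse
  slice <- substr(native, pairs$native$amplicon_end - nchar(rp) + 1,
                  pairs$native$amplicon_end)
  expect_equal(rp, reverse_complement(slice))
  # identical templates: no discriminating site
  expect_error(design_discriminating_primers(native, native),
               "no discriminating site")
  # polymorphisms only in the 5' third fail by default, succeed at 1.0
  a <- random_clean_dna(300, design_constraints(gc_target = 50,
                                                gc_window = 10), seed = 2)
  b <- a
  substr(b, 30, 30) <- if (substr(a, 30, 30) == "A") "G" else "A"
  substr(b, 70, 70) <- if (substr(a, 70, 70) == "C") "T" else "C"
  substr(b, 150, 150) <- if (substr(a, 150, 150) == "C") "G" else "C"
  expect_error(design_discriminating_primers(a, b), "no discriminating")
  expect_silent(design_discriminating_primers(
    a, b, three_prime_region_fraction = 1.0,
    amplicon_len = c(60, 280)))
})
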