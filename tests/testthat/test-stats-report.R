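test_that("interlaminar comparison handles paired and degenerate cases", {
  a <- c(1, 2, 3, 4, 5, 6)
  id <- interlaminar_compare(a, a, paired = TRUE)
  expect_equal(id$p_value, 1)
  expect_match(paste(id$notes, collapse = " "), "differences zero")
  ## uniform shift of 10 with n = 24: all-positive signed ranks, exact
  ## null p = 2 / 2^24 at the extreme statistic -- far below 1e-4
  set.seed(61)
  b <- rnorm(24)
  shifted <- interlaminar_compare(b + 10, b, paired = TRUE)
  expect_lt(shifted$p_value, 1e-4)
  expect_equal(shifted$test, "Wilcoxon signed-rank")
  ## unpaired falls back to the rank-sum test
  un <- interlaminar_compare(rnorm(10) + 3, rnorm(12), paired = FALSE)
  expect_equal(un$test, "Wilcoxon rank-sum")
  ## low-n note attached, test still runs
  low <- interlaminar_compare(c(1, 2, 3), c(4, 5, 6), paired = TRUE)
  expect_match(paste(low$notes, collapse = " "), "low power")
  expect_true(is.finite(low$p_value))
})

test_that("synthetic enhancement cohorts reject in the right direction", {
  set.seed(62)
  dsi_in <- runif(20, 0.15, 0.35)
  dsi_out <- pmin(dsi_in * 1.8 + rnorm(20, sd = 0.03), 1)
  res <- interlaminar_compare(dsi_out, dsi_in, paired = TRUE)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$effect_summary$median_a, res$effect_summary$median_b)
})

test_that("proportion comparison is the 2x2 chi-square without correction", {
  expect_equal(proportion_compare(50, 100, 50, 100)$p_value, 1)
  ## hand-computed chi-square for (98/134 vs 47/109)
  k1 <- 98; n1 <- 134; k2 <- 47; n2 <- 109
  p_pool <- (k1 + k2) / (n1 + n2)
  expected <- c(n1 * p_pool, n1 * (1 - p_pool), n2 * p_pool, n2 * (1 - p_pool))
  observed <- c(k1, n1 - k1, k2, n2 - k2)
  stat_hand <- sum((observed - expected)^2 / expected)
  res <- proportion_compare(k1, n1, k2, n2)
  expect_equal(res$statistic, stat_hand)
  expect_lt(proportion_compare(0, 10, 10, 10)$p_value, 0.001)
  expect_error(proportion_compare(3, 0, 1, 2), class = "validation_error")
})

test_that("Spearman association matches ranks", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  expect_equal(spearman_assoc(x, x)$statistic, 1)
  expect_equal(spearman_assoc(x, -x)$statistic, -1)
  ## 10-point fixture with two swaps: brute-force rank formula
  y <- x
  y[c(1, 2)] <- y[c(2, 1)]
  rho_hand <- 1 - 6 * sum((rank(x) - rank(y))^2) / (10 * (10^2 - 1))
  expect_equal(spearman_assoc(x, y)$statistic, rho_hand)
  expect_error(spearman_assoc(rep(1, 6), 1:6), class = "undefined_correlation")
  expect_error(spearman_assoc(1:4, 1:4), class = "validation_error")
})

test_that("sign test matches exact binomial arithmetic", {
  ## all 24 above the reference
  res <- sign_test(rep(1.2, 24), null_value = 1)
  expect_equal(res$p_value, 2 * 0.5^24, tolerance = 1e-10)
  ## even split
  expect_equal(sign_test(c(rep(2, 12), rep(0, 12)), 1)$p_value, 1)
  ## 20 above / 4 below: two-sided exact binomial tail sum
  vals <- c(rep(2, 20), rep(0, 4))
  p_hand <- 2 * sum(dbinom(20:24, 24, 0.5))
  expect_equal(sign_test(vals, 1)$p_value, p_hand)
  ## ties with the reference are removed first
  expect_equal(sign_test(c(rep(2, 20), rep(0, 4), rep(1, 5)), 1)$n, 24)
  expect_error(sign_test(rep(1, 5), 1), class = "undefined_test")
})

test_that("bonferroni-style corrected p values never decrease, cap at 1", {
  m <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  ct <- contrast_conditions(m + 0.5, m, n_comparisons = 16)
  expect_true(all(ct$p_corrected >= ct$p_raw))
  expect_true(all(ct$p_corrected <= 1))
})

test_that("the pipeline runs end to end and is seed-deterministic", {
  out1 <- file.path(tempdir(), "lg-run1")
  out2 <- file.path(tempdir(), "lg-run2")
  cfg <- list(n_probes = 3, n_input_sites = 4, n_output_sites = 4,
              n_starts = 3)
  rep1 <- run_pipeline(cfg, seed = 21, out_dir = out1)
  rep2 <- run_pipeline(cfg, seed = 21, out_dir = out2)
  expect_null(rep1$failed_stage)
  for (f in c("sites.csv", "layers.csv", "gainfits.json", "gc.json",
              "report.md"))
    expect_true(file.exists(file.path(out1, f)), label = f)
  ## byte-identical outputs for the same seed
  for (f in c("gainfits.json", "gc.json", "report.md"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  ## report numbers are recomputable from the emitted CSV
  sites <- read.csv(file.path(out1, "sites.csv"))
  med_out <- median(with(sites, tapply(dsi[group == "output"],
                                       probe_id[group == "output"], median)))
  expect_equal(med_out, median(rep1$population$dsi_output_medians))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("a degenerate cohort fails its stage gracefully", {
  ## with all noise off the blank PSTH variance is exactly zero, the SNR
  ## is undefined for every site, and the screening stage must fail
  ## without throwing
  cfg <- list(n_probes = 1, n_input_sites = 1, n_output_sites = 1,
              truth = list(psth_noise_sd = 0, gc_coupling = FALSE,
                           noise = list(type = "gaussian_cv", scale = 0)))
  rep <- suppressWarnings(run_pipeline(cfg, seed = 5))
  expect_false(is.null(rep$failed_stage))
})
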