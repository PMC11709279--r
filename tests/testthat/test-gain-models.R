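test_that("threshold-linear nonlinearity matches its closed forms", {
  ## at threshold: A * sigma / sqrt(2 pi)
  expect_equal(threshold_linear(3, A = 2, g0 = 3, sigma = 1.5),
               2 * 1.5 / sqrt(2 * pi))
  ## far above threshold: linear asymptote
  expect_equal(threshold_linear(5 + 10 * 0.2, A = 1.7, g0 = 5, sigma = 0.2),
               1.7 * 10 * 0.2, tolerance = 1e-10)
  expect_error(threshold_linear(1, 1, 0, sigma = 0),
               class = "validation_error")
})

test_that("threshold-linear equals the Gaussian-expectation quadrature", {
  ## f(g) must equal E[A max(g + e - g0, 0)], e ~ N(0, sigma^2)
  set.seed(41)
  for (i in 1:20) {
    A <- runif(1, 0.5, 3); g0 <- runif(1, -2, 5)
    sigma <- runif(1, 0.2, 4); g <- runif(1, -5, 15)
    quad <- stats::integrate(function(e)
      A * pmax(g + e - g0, 0) * dnorm(e, sd = sigma),
      lower = -10 * sigma, upper = 10 * sigma, rel.tol = 1e-12)$value
    expect_equal(threshold_linear(g, A, g0, sigma), quad, tolerance = 1e-8)
  }
})

test_that("sigma -> 0 limit is the rectifier; power law reduces correctly", {
  g <- seq(-5, 20, length.out = 100)
  expect_lt(max(abs(threshold_linear(g, 2, 3, sigma = 1e-4) -
                      2 * pmax(g - 3, 0))), 1e-6)
  expect_equal(power_law(3, A = 2, g0 = 1, n = 2), 8)
  expect_equal(power_law(g, 2, 1, n = 1), 2 * pmax(g - 1, 0))
  expect_equal(power_law(0.5, 2, 1, n = 3), 0)
  expect_error(power_law(1, 1, 0, n = 0), class = "validation_error")
})

test_that("adjusted R2 follows its defining formula", {
  expect_equal(adjusted_r2(c(1, 2, 3, 4), c(1, 2, 3, 4), 2), 1)
  ## constant fit on a 5-point series: direct arithmetic oracle
  obs <- c(2, 4, 6, 3, 5)
  fitted <- rep(mean(obs), 5)
  n_param <- 1
  oracle <- 1 - (5 - 1) / (5 - 1) * 2 * sum((fitted - obs)^2) /
    (0 + sum((obs - mean(obs))^2))
  expect_equal(adjusted_r2(fitted, obs, n_param), oracle)
  expect_equal(oracle, -1)   # constant fit: numerator = denominator
  ## unused parameter strictly lowers the value
  f2 <- c(1.1, 2.2, 2.9, 4.2, 4.8)
  expect_lt(adjusted_r2(f2, obs, 3), adjusted_r2(f2, obs, 2))
  expect_error(adjusted_r2(rep(1, 5), rep(1, 5), 1), class = "undefined_r2")
})

make_paired_rates <- function(gt, seed, n_reps = 20) {
  ## repetition-resolved input rates + exact model II forward pass
  set.seed(seed)
  C <- length(gt$conditions)
  rin <- matrix(rep(gt$input_mean, n_reps), ncol = n_reps) +
    matrix(rnorm(C * n_reps, sd = 2), C, n_reps)
  rin <- pmax(rin, 0)
  rownames(rin) <- gt$conditions
  list(rin = rin,
       rout = gain_model_forward(rin, gt$gain, gt$nonlinearity))
}

test_that("noise-free model II data are refit essentially exactly", {
  gt <- make_ground_truth(seed = 1)
  d <- make_paired_rates(gt, seed = 42)
  fit <- fit_gain_model(d$rin, d$rout, gt$conditions, model = "II",
                        n_starts = 5, seed = 1)
  expect_lt(fit$J, 1e-6)
  expect_gte(fit$adj_r2, 0.999)
  expect_equal(unname(fit$w), unname(gt$gain), tolerance = 1e-4)
  expect_equal(fit$dsi_of_gain, gt$gain_dsi_realized, tolerance = 1e-3)
})

test_that("identity transmission is captured by Model I", {
  set.seed(43)
  rin <- matrix(runif(13 * 10, 5, 40), 13, 10)
  conds <- c(as.character(seq(0, 330, 30)), "blank")
  fit <- fit_gain_model(rin, rin, conds, model = "I", n_starts = 5, seed = 2)
  expect_gte(fit$adj_r2, 0.999)
  expect_equal(unname(fit$fitted), unname(rin), tolerance = 1e-3)
})

test_that("model II always nests model I in residual terms", {
  for (s in 1:4) {
    gt <- make_ground_truth(list(noise = list(type = "gaussian_cv",
                                              scale = 0.15)), seed = s)
    sim <- simulate_probe(gt, 4, 4, seed = s, psth = FALSE)
    rin <- layer_average_rates(sim$table, input_site_ids(sim))
    rout <- layer_average_rates(sim$table, output_site_ids(sim))
    f1 <- fit_gain_model(rin, rout, gt$conditions, "I", n_starts = 4, seed = s)
    f2 <- fit_gain_model(rin, rout, gt$conditions, "II", n_starts = 4, seed = s)
    expect_lte(f2$J, f1$J)
  }
})

test_that("models III and IV honor their gain/suppression structure", {
  gt <- make_ground_truth(seed = 11)
  d <- make_paired_rates(gt, seed = 44)
  f3 <- fit_gain_model(d$rin, d$rout, gt$conditions, model = "III", seed = 1)
  f4 <- fit_gain_model(d$rin, d$rout, gt$conditions, model = "IV", seed = 1)
  expect_length(unique(f4$w), 1)          # shared gain in IV
  expect_length(f3$suppression, 1)        # shared suppression in III
  expect_length(f4$suppression, length(gt$conditions))
  expect_true(all(f3$w >= 0))
  ## III approximates the smoothed-threshold truth well, and its tuned
  ## gain carries the direction signal
  expect_gt(f3$adj_r2, 0.95)
  expect_gt(f3$dsi_of_gain, 0.1)
})

test_that("contribution decomposition is exact arithmetic", {
  expect_equal(contribution_decomposition(0.2, 0.5, 0.2, 0.4)$contrib_nonlin, 0)
  both <- contribution_decomposition(0.2, 0.5, 0.2, 0.5)
  expect_equal(both$contrib_nonlin, 0)
  expect_equal(both$contrib_gain, 1)
  cd <- contribution_decomposition(0.2, 0.5, 0.29, 0.47)
  expect_equal(cd$contrib_nonlin, 0.3)
  expect_equal(cd$contrib_gain, 0.6)
  ## additivity identity
  expect_equal(cd$contrib_nonlin + cd$contrib_gain, (0.47 - 0.2) / (0.5 - 0.2))
  expect_error(contribution_decomposition(0.3, 0.3, 0.3, 0.3),
               class = "undefined_contribution")
})

test_that("response ratios align the preferred direction to 90 degrees", {
  conds <- c(as.character(seq(0, 330, 30)), "blank")
  inp <- setNames(rep(10, 13), conds)
  ## identity: ratio 1 everywhere
  rr <- response_ratio_tuning(inp, inp, theta_pref = 60)
  expect_true(all(rr$ratio == 1))
  expect_equal(rr$ratio_blank, 1)
  ## peaked output at 270: after alignment the peak sits at 90
  outp <- setNames(c(von_mises_direction(seq(0, 330, 30), 270, 2, 2, 20, 5, 2),
                     8), conds)
  rr2 <- response_ratio_tuning(inp, outp, theta_pref = 270)
  expect_equal(rr2$aligned_directions[which.max(rr2$ratio)], 90)
  expect_gt(rr2$ratio_pref, rr2$ratio_null)
  expect_gt(rr2$ratio_pref, rr2$ratio_blank)
  ## non-positive input is masked
  inp2 <- inp; inp2[["30"]] <- 0
  rr3 <- response_ratio_tuning(inp2, outp, 270)
  expect_equal(sum(is.na(rr3$ratio)), 1)
})

test_that("gain fits reject malformed inputs", {
  rin <- matrix(1:12, 3, 4)
  conds <- c("0", "120", "blank")
  expect_error(fit_gain_model(rin, rin[, 1:3], conds),
               class = "validation_error")
  expect_error(fit_gain_model(rin * 0, rin * 0, conds),
               class = "degenerate_input")
  one_rep <- matrix(1, 3, 1)
  expect_error(fit_gain_model(one_rep, one_rep, conds),
               class = "validation_error")
})
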