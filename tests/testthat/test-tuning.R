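test_that("noise-free von Mises data are recovered to high precision", {
  dirs <- seq(0, 345, 15)
  true <- list(theta_pref = 132, sigma1 = 2.4, sigma2 = 1.1,
               alpha = 28, beta = 9, r0 = 3.5)
  y <- von_mises_direction(dirs, true$theta_pref, true$sigma1, true$sigma2,
                           true$alpha, true$beta, true$r0)
  fit <- fit_direction_tuning(y, dirs)
  for (p in names(true))
    expect_equal(fit[[p]], true[[p]], tolerance = 1e-3, label = p)
  expect_lt(fit$residual, 1e-6)
  expect_equal(fit$theta_null, (fit$theta_pref + 180) %% 360)
})

test_that("flat responses yield near-zero amplitudes", {
  dirs <- seq(0, 330, 30)
  fit <- fit_direction_tuning(rep(7, 12), dirs)
  expect_lt(fit$alpha + fit$beta, 1e-3)
  expect_equal(unname(predict_direction_tuning(fit, c(0, 90, 200))),
               rep(7, 3), tolerance = 1e-3)
})

test_that("a 180-degree shift swaps the two lobes", {
  dirs <- seq(0, 330, 30)
  y <- von_mises_direction(dirs, 60, 2, 2, 20, 5, 2)
  f1 <- fit_direction_tuning(y, dirs)
  f2 <- fit_direction_tuning(von_mises_direction(dirs + 180, 60, 2, 2, 20, 5, 2),
                             dirs)
  expect_equal(preferred_direction_difference(f2$theta_pref,
                                              f1$theta_pref + 180), 0,
               tolerance = 1e-2)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-2)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-2)
})

test_that("DSI matches its closed-form anchors", {
  expect_equal(compute_dsi(r_pref = 2, r_null = 1)$dsi, 1 / 3)
  expect_equal(compute_dsi(r_pref = 5, r_null = 5)$dsi, 0)
  expect_equal(compute_dsi(r_pref = 4, r_null = 0)$dsi, 1)
  expect_error(compute_dsi(r_pref = 0, r_null = 0), class = "undefined_dsi")
})

test_that("DSI/OSI are scale-invariant but not shift-invariant", {
  dirs <- seq(0, 330, 30)
  set.seed(21)
  for (i in 1:5) {
    y <- von_mises_direction(dirs, runif(1, 0, 360), runif(1, 1, 3),
                             runif(1, 1, 3), runif(1, 10, 30),
                             runif(1, 2, 9), runif(1, 1, 5))
    d0 <- compute_dsi(fit_direction_tuning(y, dirs))$dsi
    d_scaled <- compute_dsi(fit_direction_tuning(3 * y, dirs))$dsi
    d_shifted <- compute_dsi(fit_direction_tuning(y + 20, dirs))$dsi
    expect_equal(d_scaled, d0, tolerance = 1e-4)
    expect_gt(abs(d_shifted - d0), 1e-3)
  }
})

test_that("optimizer never ends above the initial guess residual", {
  dirs <- seq(0, 330, 30)
  set.seed(22)
  for (i in 1:8) {
    y <- pmax(von_mises_direction(dirs, runif(1, 0, 360), 2, 2,
                                  20, 8, 4) + rnorm(12, sd = 3), 0)
    fit <- fit_direction_tuning(y, dirs)
    expect_lte(fit$residual, fit$initial_residual)
  }
})

test_that("orientation fits recover parameters, OSI and HWHH behave", {
  dirs <- seq(0, 330, 30)
  y <- von_mises_orientation(dirs, 40, 1.8, 22, 4)
  fit <- fit_orientation_tuning(y, dirs)
  expect_equal(fit$theta_pref, 40, tolerance = 1e-2)
  expect_equal(fit$sigma1, 1.8, tolerance = 1e-2)
  expect_equal(fit$theta_ortho, 130, tolerance = 1e-2)
  ## flat responses: no orientation preference
  flat <- fit_orientation_tuning(rep(6, 12), dirs)
  expect_lt(abs(flat$osi), 1e-3)
  expect_equal(flat$op_ratio, 1, tolerance = 1e-3)
  ## narrower tuning -> smaller half width
  broad <- fit_orientation_tuning(von_mises_orientation(dirs, 40, 0.8, 22, 4),
                                  dirs)
  narrow <- fit_orientation_tuning(von_mises_orientation(dirs, 40, 6, 22, 4),
                                   dirs)
  expect_lt(narrow$hwhh, broad$hwhh)
  ## HWHH is where the fitted curve crosses half height above offset
  half_val <- von_mises_orientation(40 + fit$hwhh, 40, 1.8, 22, 4)
  expect_equal(half_val, 4 + 22 / 2, tolerance = 1e-6)
})

test_that("F1/F0 matches Fourier closed forms", {
  tf <- 2
  tt <- seq(0, 1999, 1)        # 2 s at 1 ms
  ## constant PSTH: no modulation
  expect_equal(compute_f1f0(rep(10, length(tt)), tt, tf)$ratio, 0)
  ## pure sinusoid c + a sin: ratio a/c
  y <- 10 + 4 * sin(2 * pi * tf * tt / 1000)
  expect_equal(compute_f1f0(y, tt, tf)$ratio, 0.4, tolerance = 1e-3)
  ## half-wave rectified sinusoid: ratio pi/2, classified simple
  hw <- pmax(sin(2 * pi * tf * tt / 1000), 0)
  res <- compute_f1f0(hw, tt, tf)
  expect_equal(res$ratio, pi / 2, tolerance = 1e-3)
  expect_equal(res$classification, "simple")
  expect_error(compute_f1f0(rep(0, length(tt)), tt, tf),
               class = "undefined_ratio")
  expect_error(compute_f1f0(rep(1, 100), seq(0, 99), 2),
               class = "validation_error")
})

test_that("preferred-direction differences use circular distance", {
  expect_equal(preferred_direction_difference(350, 10), 20)
  expect_equal(preferred_direction_difference(0, 180), 180)
  expect_equal(preferred_direction_difference(90, 250), 160)
  expect_equal(classify_direction_shift(c(20, 160, 90)),
               c("maintained", "reversed", "other"))
  ## symmetry and circular triangle inequality on random triples
  set.seed(23)
  a <- runif(30, 0, 360); b <- runif(30, 0, 360); c <- runif(30, 0, 360)
  expect_equal(preferred_direction_difference(a, b),
               preferred_direction_difference(b, a))
  expect_true(all(preferred_direction_difference(a, c) <=
                    preferred_direction_difference(a, b) +
                    preferred_direction_difference(b, c) + 1e-12))
})

test_that("tuning fit errors on underdetermined input", {
  expect_error(fit_direction_tuning(c(1, 2, 3), c(0, 90, 180)),
               class = "underdetermined_fit")
})
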