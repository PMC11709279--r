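test_that("tables round-trip through both dialects", {
  tab <- tiny_table(n_sites = 3, dirs = seq(0, 300, 60), n_trials = 4)
  for (dialect in c("csv", "hdf5")) {
    path <- tempfile(fileext = if (dialect == "csv") ".csv" else ".h5")
    write_trial_table(tab, path, dialect)
    back <- read_trial_table(path, dialect)
    expect_identical(back$rates, tab$rates, label = dialect)
    expect_identical(back$site_ids, tab$site_ids)
    expect_equal(back$relative_depth, tab$relative_depth)
    expect_identical(back$conditions, tab$conditions)
    expect_identical(back$area_label, tab$area_label)
    unlink(path)
  }
})

test_that("HDF5 round-trip preserves PSTHs from the generator bit-exactly", {
  sim <- simulate_probe(make_ground_truth(seed = 5), 2, 2, seed = 5)
  path <- tempfile(fileext = ".h5")
  write_trial_table(sim$table, path, "hdf5")
  back <- read_trial_table(path, "hdf5")
  expect_identical(back$rates, sim$table$rates)
  expect_identical(back$psth, sim$table$psth)
  expect_equal(back$psth_t0_ms, sim$table$psth_t0_ms)
  unlink(path)
})

test_that("malformed inputs raise the named errors", {
  tab <- tiny_table()
  ## missing blank condition
  expect_error(trial_response_table(
    "p", "s1", 0.5, c("0", "90"), array(1, c(1, 2, 1))),
    class = "integrity_error")
  ## duplicate directions modulo 360
  expect_error(trial_response_table(
    "p", "s1", 0.5, c("0", "360", "blank"), array(1, c(1, 3, 1))),
    class = "integrity_error")
  ## CSV with a duplicated key
  path <- tempfile(fileext = ".csv")
  write_trial_table(tab, path, "csv")
  lines <- readLines(path)
  writeLines(c(lines, lines[3]), path)
  expect_error(read_trial_table(path, "csv"), class = "integrity_error")
  ## CSV missing a required column
  writeLines(c("probe_id,site_id,rate", "p,s1,3"), path)
  expect_error(read_trial_table(path, "csv"), class = "format_error")
  unlink(path)
})

test_that("SNR equals the max condition/blank variance ratio", {
  ## all conditions identical to blank -> snr = 1, fails
  flat <- lapply(1:7, function(k) c(5, 9, 5, 9, 5, 9))
  tab <- psth_table(flat, dirs = seq(0, 300, 60))
  res <- compute_snr(tab, "s1", window_ms = c(0, 10))
  expect_equal(res$snr, 1)
  expect_false(res$passes)

  ## condition variance 20 vs blank variance 2.5 -> snr exactly 8,
  ## which the strict threshold rejects
  cond <- 10 + c(-6, -2, 0, 2, 6)             # var 20
  blank <- c(1, 2, 3, 4, 5)                   # var 2.5
  tab2 <- psth_table(c(lapply(1:6, function(k) cond), list(blank)),
                     dirs = seq(0, 300, 60))
  res2 <- compute_snr(tab2, 1, window_ms = c(0, 8))
  expect_equal(res2$snr, 8)
  expect_false(res2$passes)

  ## random PSTHs match a direct two-pass variance oracle
  set.seed(11)
  ps <- lapply(1:9, function(k) rnorm(50, mean = 10, sd = k))
  tab3 <- psth_table(ps, dirs = seq(0, 315, 45))
  res3 <- compute_snr(tab3, 1, window_ms = c(0, 98))
  two_pass_var <- function(v) sum((v - sum(v) / length(v))^2) / (length(v) - 1)
  oracle <- max(vapply(ps[1:8], two_pass_var, numeric(1))) / two_pass_var(ps[[9]])
  expect_equal(res3$snr, oracle)
})

test_that("SNR is invariant to PSTH shifts and common rate rescaling", {
  set.seed(12)
  ps <- lapply(1:7, function(k) rnorm(40, 10, k))
  dirs <- seq(0, 300, 60)
  snr0 <- compute_snr(psth_table(ps, dirs), 1, c(0, 78))$snr
  shifted <- lapply(ps, function(v) v + 100)
  scaled <- lapply(ps, function(v) v * 3.7)
  expect_equal(compute_snr(psth_table(shifted, dirs), 1, c(0, 78))$snr, snr0)
  expect_equal(compute_snr(psth_table(scaled, dirs), 1, c(0, 78))$snr, snr0)
})

test_that("screening applies a strict threshold and orders by depth", {
  ## three one-site tables with snr 7.9 / 8.0 / 8.1 via variance ratios
  mk <- function(snr) {
    cond <- 10 + c(-6, -2, 0, 2, 6) * sqrt(snr / 8)  # var = 2.5 * snr
    psth_table(c(lapply(1:6, function(k) cond), list(c(1, 2, 3, 4, 5))),
               dirs = seq(0, 300, 60))
  }
  survivors <- suppressWarnings(vapply(c(7.9, 8, 8.1), function(s)
    nrow(screen_sites(mk(s), window_ms = c(0, 8))), integer(1)))
  expect_equal(survivors, c(0L, 0L, 1L))
  expect_warning(screen_sites(mk(7.9), window_ms = c(0, 8)), "no site")

  ## threshold 0: every site with defined SNR survives; planted silent
  ## site is excluded at the default threshold
  sim <- simulate_probe(make_ground_truth(seed = 2), 4, 4, seed = 2,
                        n_silent_sites = 1)
  all_pass <- screen_sites(sim$table, threshold = 0)
  expect_equal(nrow(all_pass), 9)
  surv <- screen_sites(sim$table)
  expect_false(sim$silent_sites %in% surv$site_id)
  expect_true(all(diff(surv$relative_depth) >= 0))

  ## idempotence: re-screening the survivors changes nothing
  keep <- match(surv$site_id, sim$table$site_ids)
  tab2 <- sim$table
  tab2$site_ids <- tab2$site_ids[keep]
  tab2$relative_depth <- tab2$relative_depth[keep]
  tab2$rates <- tab2$rates[keep, , , drop = FALSE]
  tab2$psth <- tab2$psth[keep, , , , drop = FALSE]
  expect_equal(screen_sites(tab2)$site_id, surv$site_id)
})
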