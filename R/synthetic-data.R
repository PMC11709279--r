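# Synthetic laminar probe generator with known ground truth.
#
# Input-layer sites carry von Mises direction tuning; output-layer sites
# are the input-layer mean passed through a direction-tuned linear gain
# and a smoothed threshold-linear nonlinearity. PSTHs rise with a
# logistic time course whose half-maximum sits at the layer's latency,
# and their bin noise can be driven by a condition-dependent VAR process
# across layers so directed-connectivity analysis has a planted truth.

#' Ground truth for a synthetic probe
#'
#' Builds the full parameter set the generator samples from. All defaults
#' are the study conditions emulated by the package: 12 equally spaced
#' directions, 10 repetitions, ~10% blank trials, input-layer tuning with
#' a DSI near 0.25, a direction-tuned transmission gain, and a latency
#' gap between input (38.6 ms) and output (51.8 ms) layers.
#'
#' @param config named list overriding defaults; recognized keys:
#'   \describe{
#'     \item{n_directions}{number of equally spaced directions (6–72),
#'       default 12}
#'     \item{n_reps}{repetitions per grating direction (2–100), default 10}
#'     \item{blank_fraction}{fraction of all trials that are blank,
#'       in (0, 0.5), default 0.10}
#'     \item{theta_pref}{columnar preferred direction (degrees), default 90}
#'     \item{gain_type}{\code{"tuned"} or \code{"untuned"}}
#'     \item{gain_dsi}{target DSI of the gain curve (tuned case),
#'       default 0.3}
#'     \item{gain_sigma}{concentration of the gain tuning, default 1.5}
#'     \item{gain_blank}{blank gain relative to the mean grating gain,
#'       default 0.8 (tuned) / 1 (untuned)}
#'     \item{input_alpha, input_beta, input_r0, input_sigma1,
#'       input_sigma2}{input-layer von Mises parameters (spikes/s,
#'       concentrations); defaults 25, 13, 5, 2, 2}
#'     \item{blank_rate}{input-layer blank response (spikes/s), default 6}
#'     \item{nonlinearity}{list(A, g0, sigma), default (1, 4, 3)}
#'     \item{latency_by_layer}{named ms vector, default L2/3 = L5 = 51.8,
#'       L4 = L6 = 38.6}
#'     \item{noise}{list(type, scale): \code{"gaussian_sqrt"} (sd =
#'       scale*sqrt(mean), default scale 1), \code{"gaussian_cv"}
#'       (sd = scale*mean) or \code{"poisson"}}
#'     \item{psth_noise_sd}{iid PSTH bin noise sd (spikes/s), default 2}
#'     \item{gc_coupling}{logical: drive PSTH noise with the
#'       condition-dependent interlaminar VAR process, default TRUE}
#'   }
#' @param seed integer seed; the truth is deterministic given
#'   (config, seed).
#' @return object of class \code{ground_truth}; notable fields:
#'   \code{directions}, \code{conditions}, \code{gain} (named w(S) vector
#'   including blank), \code{gain_dsi} (realized), \code{input_mean}
#'   (named layer-mean input tuning), \code{output_mean} (noise-free
#'   output-layer mean per condition).
#' @export
make_ground_truth <- function(config = list(), seed = 1L) {
  defaults <- list(
    n_directions = 12L, n_reps = 10L, blank_fraction = 0.10,
    theta_pref = 90, gain_type = "tuned", gain_dsi = 0.3,
    gain_sigma = 1.5, gain_blank = NULL,
    input_alpha = 25, input_beta = 13, input_r0 = 5,
    input_sigma1 = 2, input_sigma2 = 2, blank_rate = 6,
    nonlinearity = list(A = 1, g0 = 4, sigma = 3),
    latency_by_layer = c("L2/3" = 51.8, "L4" = 38.6,
                         "L5" = 51.8, "L6" = 38.6),
    noise = list(type = "gaussian_sqrt", scale = 1),
    psth_noise_sd = 2, gc_coupling = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("validation_error", "unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)

  bad <- character()
  if (cfg$n_directions < 6 || cfg$n_directions > 72) bad <- c(bad, "n_directions")
  if (cfg$n_reps < 2 || cfg$n_reps > 100) bad <- c(bad, "n_reps")
  if (cfg$blank_fraction <= 0 || cfg$blank_fraction >= 0.5)
    bad <- c(bad, "blank_fraction")
  if (!cfg$gain_type %in% c("tuned", "untuned")) bad <- c(bad, "gain_type")
  if (cfg$gain_type == "tuned" &&
      (cfg$gain_dsi < 0 || cfg$gain_dsi >= 1)) bad <- c(bad, "gain_dsi")
  if (cfg$nonlinearity$sigma <= 0) bad <- c(bad, "nonlinearity")
  if (cfg$noise$type %in% c("gaussian_sqrt", "gaussian_cv") &&
      cfg$noise$scale < 0) bad <- c(bad, "noise")
  if (length(bad))
    stopf("validation_error", "config values out of range: %s",
          paste(bad, collapse = ", "))

  dirs <- seq(0, 360 - 360 / cfg$n_directions, by = 360 / cfg$n_directions)
  conds <- c(as.character(dirs), BLANK)

  ## gain curve: w(theta) = w0 * (1 + k * basis), with k solving
  ## (w_pref - w_null)/(w_pref + w_null) = gain_dsi  =>  k = 2d/(1-d)
  if (cfg$gain_type == "tuned") {
    k <- 2 * cfg$gain_dsi / (1 - cfg$gain_dsi)
    shape <- 1 + k * vm_basis(deg2rad(dirs - cfg$theta_pref), cfg$gain_sigma)
    w0 <- 1 / mean(shape)            # mean grating gain = 1
    w_dirs <- w0 * shape
    gb <- if (is.null(cfg$gain_blank)) 0.8 else cfg$gain_blank
  } else {
    w_dirs <- rep(1, length(dirs))
    gb <- if (is.null(cfg$gain_blank)) 1 else cfg$gain_blank
  }
  gain <- stats::setNames(c(w_dirs, gb), conds)

  input_mean <- stats::setNames(c(
    von_mises_direction(dirs, cfg$theta_pref, cfg$input_sigma1,
                        cfg$input_sigma2, cfg$input_alpha, cfg$input_beta,
                        cfg$input_r0),
    cfg$blank_rate), conds)
  nl <- cfg$nonlinearity
  output_mean <- threshold_linear(gain * input_mean, nl$A, nl$g0, nl$sigma)

  realized_gain_dsi <- gain_dsi(gain, conds)

  structure(c(cfg, list(
    directions = dirs, conditions = conds, gain = gain,
    gain_dsi_realized = realized_gain_dsi,
    input_mean = input_mean, output_mean = output_mean,
    seed = as.integer(seed))), class = "ground_truth")
}

## condition-dependent interlaminar VAR(1) coupling for PSTH noise.
## Edges follow the planted connectivity: L4 -> L2/3 and L4 -> L5 grow
## from blank to null to preferred; L2/3 -> L5 switches on near the
## preferred direction only.
gc_coupling_matrix <- function(truth, condition) {
  layers <- c("L2/3", "L4", "L5", "L6")
  A <- diag(0.3, 4)
  dimnames(A) <- list(layers, layers)
  s <- if (condition == BLANK) 0 else
    vm_basis(deg2rad(as.numeric(condition) - truth$theta_pref), 1.5)
  A["L2/3", "L4"] <- 0.15 + 0.35 * s
  A["L5", "L4"] <- 0.12 + 0.3 * s
  A["L5", "L2/3"] <- 0.45 * max(s - 0.5, 0) * 2
  A
}

#' Simulate one laminar probe placement
#'
#' Draws trial-resolved rates and PSTHs for \code{n_input_sites} sites in
#' the input layers (L4, L6) and \code{n_output_sites} sites in the
#' output layers (L2/3, L5). Noise-free output-layer means equal
#' \code{f(w(S) * input-layer mean)} per condition; trial rates add the
#' configured noise; PSTHs rise logistically with half-maximum at the
#' layer latency.
#'
#' @param truth a [make_ground_truth()] object.
#' @param n_input_sites,n_output_sites site counts (>= 1 each).
#' @param seed integer seed for the noise realizations.
#' @param psth generate PSTHs (needed for SNR screening, latency and GC),
#'   default TRUE.
#' @param n_silent_sites number of planted unresponsive sites (flat PSTH,
#'   fails the SNR screen), default 0.
#' @return list of class \code{synthetic_probe}: \code{table} (a
#'   [trial_response_table()]), \code{truth}, \code{layer_labels},
#'   \code{site_role} (\code{"input"}/\code{"output"}/\code{"silent"}),
#'   \code{silent_sites}.
#' @export
simulate_probe <- function(truth, n_input_sites = 6, n_output_sites = 6,
                           seed = 1L, psth = TRUE, n_silent_sites = 0) {
  if (n_input_sites < 1 || n_output_sites < 1)
    stopf("validation_error", "site counts must be >= 1")
  nz <- truth$noise
  if (nz$type %in% c("gaussian_sqrt", "gaussian_cv") && nz$scale < 0)
    stopf("validation_error", "noise sd must be >= 0")

  conds <- truth$conditions
  C <- length(conds)
  n_grating_trials <- truth$n_directions * truth$n_reps
  n_blank <- max(1L, round(truth$blank_fraction /
                             (1 - truth$blank_fraction) * n_grating_trials))
  n_rep_max <- max(truth$n_reps, n_blank)
  reps_per_cond <- c(rep(truth$n_reps, truth$n_directions), n_blank)

  ## site layout: output sites split over L2/3 and L5, input over L4, L6
  half_out <- ceiling(n_output_sites / 2)
  half_in <- ceiling(n_input_sites / 2)
  depth_out <- c(seq(0.05, 0.30, length.out = half_out),
                 seq(0.60, 0.74, length.out = n_output_sites - half_out))
  depth_in <- c(seq(0.37, 0.56, length.out = half_in),
                seq(0.78, 0.95, length.out = n_input_sites - half_in))
  depth_silent <- if (n_silent_sites > 0)
    seq(0.40, 0.50, length.out = n_silent_sites) else numeric()
  depth <- c(depth_out, depth_in, depth_silent)
  role <- c(rep("output", n_output_sites), rep("input", n_input_sites),
            rep("silent", n_silent_sites))
  o <- order(depth)
  depth <- depth[o]; role <- role[o]
  ns <- length(depth)
  site_ids <- sprintf("site%02d", seq_len(ns))
  layer <- as.character(assign_layers(depth)$layer)

  nlp <- truth$nonlinearity
  ## deterministic site-to-site amplitude spread: seeds vary only the
  ## noise realizations, never the noise-free means
  site_factor <- rep(1, ns)
  in_pos <- which(role == "input")
  site_factor[in_pos] <- seq(0.85, 1.15, length.out = length(in_pos))

  dat <- with_local_seed(seed, {

    ## per-site noise-free condition means
    mean_site <- matrix(0, ns, C, dimnames = list(site_ids, conds))
    in_mean_layer <- truth$input_mean * mean(site_factor[role == "input"])
    out_mean <- threshold_linear(truth$gain * in_mean_layer,
                                 nlp$A, nlp$g0, nlp$sigma)
    for (i in seq_len(ns)) {
      mean_site[i, ] <- switch(role[i],
        input = truth$input_mean * site_factor[i],
        output = out_mean,
        silent = rep(truth$blank_rate, C))
    }

    draw_noise <- function(m, n) switch(nz$type,
      gaussian_sqrt = m + stats::rnorm(n, sd = nz$scale * sqrt(max(m, 0))),
      gaussian_cv = m + stats::rnorm(n, sd = nz$scale * max(m, 0)),
      poisson = stats::rpois(n, lambda = max(m, 0)) + 0,
      stopf("validation_error", "unknown noise type '%s'", nz$type))

    ## input and silent sites: mean + trial noise; output sites are
    ## generated causally from the repetition-resolved input-layer
    ## average, output_i = f(w(S) * xbar_i) + noise -- the transmission
    ## model the gain fits estimate
    rates <- array(NA_real_, c(ns, C, n_rep_max))
    in_idx <- which(role == "input")
    for (k in seq_len(C)) {
      nrep <- reps_per_cond[k]
      for (i in which(role != "output"))
        rates[i, k, seq_len(nrep)] <- pmax(draw_noise(mean_site[i, k], nrep), 0)
      xbar <- colMeans(matrix(rates[in_idx, k, seq_len(nrep)],
                              nrow = length(in_idx)))
      drive <- threshold_linear(truth$gain[[k]] * xbar, nlp$A, nlp$g0,
                                nlp$sigma)
      for (i in which(role == "output"))
        rates[i, k, seq_len(nrep)] <- pmax(
          if (nz$type == "poisson") vapply(drive, function(m)
            stats::rpois(1, max(m, 0)) + 0, numeric(1))
          else drive + stats::rnorm(nrep, sd = switch(nz$type,
            gaussian_sqrt = nz$scale * sqrt(pmax(drive, 0)),
            gaussian_cv = nz$scale * pmax(drive, 0))), 0)
    }

    psth_arr <- NULL
    bin_ms <- 2; t0_ms <- -50
    if (psth) {
      tt <- t0_ms + (seq_len(150) - 1) * bin_ms  # -50..248 ms
      nt <- length(tt)
      psth_arr <- array(NA_real_, c(ns, C, n_rep_max, nt))
      tau <- 4
      rise <- vapply(seq_len(ns), function(i)
        1 / (1 + exp(-(tt - truth$latency_by_layer[[layer[i]]]) / tau)),
        numeric(nt))        # [time, site]
      for (k in seq_len(C)) {
        nrep <- reps_per_cond[k]
        ## layer-level VAR noise shared by sites within a layer
        for (r in seq_len(nrep)) {
          layer_noise <- if (isTRUE(truth$gc_coupling)) {
            A <- gc_coupling_matrix(truth, conds[k])
            e <- matrix(stats::rnorm(nt * 4, sd = truth$psth_noise_sd), nt, 4)
            zz <- matrix(0, nt, 4, dimnames = list(NULL, colnames(A)))
            zz[1, ] <- e[1, ]
            for (t in 2:nt) zz[t, ] <- A %*% zz[t - 1, ] + e[t, ]
            zz
          } else NULL
          for (i in seq_len(ns)) {
            flat <- role[i] == "silent" || conds[k] == BLANK
            base <- if (flat) rates[i, k, r] else rates[i, k, r] * rise[, i]
            priv <- stats::rnorm(nt, sd = truth$psth_noise_sd / 2)
            shared <- if (is.null(layer_noise)) 0 else layer_noise[, layer[i]]
            psth_arr[i, k, r, ] <- pmax(base + priv + shared, 0)
          }
        }
      }
    }
    list(site_factor = site_factor, mean_site = mean_site,
         in_mean_layer = in_mean_layer, out_mean = out_mean,
         rates = rates, psth = psth_arr, bin_ms = bin_ms, t0_ms = t0_ms)
  })

  tab <- trial_response_table(
    probe_id = sprintf("synthetic-seed%d", seed),
    site_ids = site_ids, relative_depth = depth, conditions = conds,
    rates = dat$rates, psth = dat$psth,
    psth_bin_ms = dat$bin_ms, psth_t0_ms = dat$t0_ms,
    area_label = "A17",
    stimulus_meta = list(contrast = 0.9, tf_hz = 2, sf_cpd = 0.1,
                         duration_s = 2, synthetic = TRUE))
  structure(list(
    table = tab, truth = truth, layer_labels = stats::setNames(layer, site_ids),
    site_role = stats::setNames(role, site_ids),
    silent_sites = site_ids[role == "silent"],
    site_factor = dat$site_factor,
    input_layer_mean = dat$in_mean_layer,
    output_layer_mean = dat$out_mean), class = "synthetic_probe")
}

#' Simulate a coupled multichannel time series
#'
#' Draws from a stable vector-autoregressive (VAR) process with known
#' directed couplings, the fixture for Granger-causality analysis.
#'
#' @param coupling array \code{[channel, channel, lag]} of VAR
#'   coefficients (\code{coupling[i, j, l]}: effect of channel j at lag l
#'   on channel i); a matrix is treated as a single lag.
#' @param n_samples number of retained time points.
#' @param seed integer seed.
#' @param innovation_sd per-channel innovation standard deviations
#'   (recycled).
#' @param burn_in discarded initial samples, default 200.
#' @return numeric matrix \code{[n_samples, channel]}; channel names from
#'   the coupling dimnames.
#' @export
simulate_coupled_timeseries <- function(coupling, n_samples, seed = 1L,
                                        innovation_sd = 1, burn_in = 200) {
  ch_names <- dimnames(coupling)[[1]]
  if (is.matrix(coupling)) coupling <- array(coupling, c(dim(coupling), 1))
  m <- dim(coupling)[1]
  p <- dim(coupling)[3]
  if (dim(coupling)[2] != m)
    stopf("validation_error", "coupling must be square per lag")
  ## companion-matrix spectral radius
  comp <- matrix(0, m * p, m * p)
  for (l in seq_len(p)) comp[1:m, ((l - 1) * m + 1):(l * m)] <- coupling[, , l]
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1)
    stopf("stability_error", "unstable VAR: spectral radius %.3f", rho)
  sd_vec <- rep_len(innovation_sd, m)
  x <- with_local_seed(seed, {
    n_tot <- n_samples + burn_in
    e <- matrix(stats::rnorm(n_tot * m), n_tot, m) %*% diag(sd_vec, m)
    z <- matrix(0, n_tot, m)
    z[1:p, ] <- e[1:p, ]
    for (t in (p + 1):n_tot) {
      acc <- e[t, ]
      for (l in seq_len(p)) acc <- acc + coupling[, , l] %*% z[t - l, ]
      z[t, ] <- acc
    }
    z[(burn_in + 1):n_tot, , drop = FALSE]
  })
  colnames(x) <- ch_names %||% paste0("ch", seq_len(m))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
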