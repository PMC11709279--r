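# Direction and orientation tuning: von Mises fits and selectivity indices.

## Normalized von Mises basis: 1 at delta = 0, 0 at delta = 180 degrees.
## Written relative to exp(sigma) so large concentrations do not overflow.
vm_basis <- function(delta_rad, sigma) {
  (exp(sigma * (cos(delta_rad) - 1)) - exp(-2 * sigma)) / (1 - exp(-2 * sigma))
}

#' Evaluate a direction tuning curve
#'
#' Double von Mises in direction space: a preferred-direction lobe of
#' amplitude \code{alpha} and concentration \code{sigma1}, a null-direction
#' lobe (always 180 degrees opposite) of amplitude \code{beta} and
#' concentration \code{sigma2}, on an offset \code{r0}. Each lobe is
#' normalized to peak at 1, so the curve evaluates to \code{alpha + r0} at
#' the preferred direction and \code{beta + r0} at the null direction.
#'
#' @param theta directions in degrees.
#' @param theta_pref preferred direction in degrees.
#' @param sigma1,sigma2 concentration (tuning-width) parameters, > 0.
#' @param alpha,beta lobe amplitudes (spikes/s).
#' @param r0 offset (spikes/s).
#' @return rates in spikes/s.
#' @export
von_mises_direction <- function(theta, theta_pref, sigma1, sigma2,
                                alpha, beta, r0) {
  d <- deg2rad(theta - theta_pref)
  alpha * vm_basis(d, sigma1) + beta * vm_basis(d - pi, sigma2) + r0
}

#' Evaluate an orientation tuning curve
#'
#' Single von Mises on the doubled angle (period 180 degrees), peaking at
#' the preferred orientation.
#'
#' @param theta orientations/directions in degrees.
#' @param theta_pref preferred orientation in degrees.
#' @param sigma1 concentration parameter, > 0.
#' @param alpha amplitude (spikes/s).
#' @param r0 offset (spikes/s).
#' @return rates in spikes/s.
#' @export
von_mises_orientation <- function(theta, theta_pref, sigma1, alpha, r0) {
  alpha * vm_basis(2 * deg2rad(theta - theta_pref), sigma1) + r0
}

#' Fit a direction tuning curve
#'
#' Bounded local least squares of the double von Mises curve to per-
#' direction mean rates. Initial guesses: preferred direction at the
#' response argmax (lowest index wins ties), both concentrations 1, both
#' amplitudes max - min, offset at the minimum response. The null
#' direction is constrained to preferred + 180. A second start with the
#' two lobes swapped guards against label switching; the lower-residual
#' solution is kept.
#'
#' @param responses per-direction mean rates (spikes/s).
#' @param directions matching directions in degrees; at least 6 distinct.
#' @return object of class \code{direction_tuning_fit}: fields
#'   \code{theta_pref}, \code{theta_null}, \code{sigma1}, \code{sigma2},
#'   \code{alpha}, \code{beta}, \code{r0}, \code{residual} (sum of
#'   squares), \code{fitted} (at the input directions), \code{converged}.
#' @export
fit_direction_tuning <- function(responses, directions) {
  responses <- as.numeric(responses)
  directions <- as.numeric(directions) %% 360
  if (length(responses) != length(directions))
    stopf("validation_error", "responses and directions differ in length")
  if (length(unique(directions)) < 6)
    stopf("underdetermined_fit", "need >= 6 distinct directions, got %d",
          length(unique(directions)))
  if (!all(is.finite(responses)))
    stopf("validation_error", "non-finite responses")

  rmax <- max(responses); rmin <- min(responses)
  th0 <- directions[which.max(responses)]
  amp0 <- max(rmax - rmin, 1e-6)
  obj <- function(p) {
    sum((von_mises_direction(directions, p[1], p[2], p[3], p[4], p[5], p[6]) -
           responses)^2)
  }
  lower <- c(-Inf, 1e-3, 1e-3, 0, 0, -Inf)
  upper <- c(Inf, 50, 50, Inf, Inf, Inf)
  starts <- list(c(th0, 1, 1, amp0, amp0, rmin),
                 c(th0 + 180, 1, 1, amp0, amp0, rmin))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stopf("fit_error", "direction tuning optimizer failed")
  p <- best$par
  ## ensure the preferred lobe is the larger one
  if (p[5] > p[4]) p <- c(p[1] + 180, p[3], p[2], p[5], p[4], p[6])
  theta_pref <- p[1] %% 360
  structure(list(
    theta_pref = theta_pref, theta_null = (theta_pref + 180) %% 360,
    sigma1 = p[2], sigma2 = p[3], alpha = p[4], beta = p[5], r0 = p[6],
    residual = best$value,
    initial_residual = obj(starts[[1]]),
    fitted = von_mises_direction(directions, p[1], p[2], p[3], p[4], p[5], p[6]),
    directions = directions, responses = responses,
    converged = best$convergence == 0
  ), class = "direction_tuning_fit")
}

#' Evaluate a fitted direction tuning curve
#' @param fit a \code{direction_tuning_fit}.
#' @param theta directions in degrees.
#' @return fitted rates (spikes/s).
#' @export
predict_direction_tuning <- function(fit, theta) {
  von_mises_direction(theta, fit$theta_pref, fit$sigma1, fit$sigma2,
                      fit$alpha, fit$beta, fit$r0)
}

#' Direction selectivity index
#'
#' \code{DSI = (R_pref - R_null) / (R_pref + R_null)} with the preferred-
#' and null-direction responses taken from the fitted tuning curve (the
#' default) or supplied directly. DSI = 1/3 when the preferred response is
#' exactly twice the null response; 1 when the null response is zero.
#'
#' @param fit a \code{direction_tuning_fit}, or \code{NULL} when
#'   \code{r_pref}/\code{r_null} are given.
#' @param r_pref,r_null responses in the preferred and null direction
#'   (spikes/s); default from the fitted curve.
#' @return list with \code{dsi}, \code{r_pref}, \code{r_null}.
#' @export
compute_dsi <- function(fit = NULL, r_pref = NULL, r_null = NULL) {
  if (is.null(r_pref)) r_pref <- predict_direction_tuning(fit, fit$theta_pref)
  if (is.null(r_null)) r_null <- predict_direction_tuning(fit, fit$theta_null)
  if (r_pref + r_null <= 0)
    stopf("undefined_dsi", "R_pref + R_null <= 0")
  list(dsi = (r_pref - r_null) / (r_pref + r_null),
       r_pref = r_pref, r_null = r_null)
}

#' Fit an orientation tuning curve
#'
#' As [fit_direction_tuning()] but on the doubled angle (period 180
#' degrees); also returns the orientation selectivity index
#' \code{OSI = (R_pref - R_ortho)/(R_pref + R_ortho)}, the orthogonal-to-
#' preferred response ratio (OP ratio), and the half-width at half-height
#' (HWHH, degrees) of the fitted curve above its offset.
#'
#' @inheritParams fit_direction_tuning
#' @return object of class \code{orientation_tuning_fit} with fields
#'   \code{theta_pref} (in \code{[0, 180)}), \code{theta_ortho},
#'   \code{sigma1}, \code{alpha}, \code{r0}, \code{residual},
#'   \code{fitted}, \code{osi}, \code{op_ratio}, \code{hwhh}.
#' @export
fit_orientation_tuning <- function(responses, directions) {
  responses <- as.numeric(responses)
  directions <- as.numeric(directions) %% 360
  if (length(unique(directions %% 180)) < 4)
    stopf("underdetermined_fit", "need >= 4 distinct orientations")
  if (!all(is.finite(responses)))
    stopf("validation_error", "non-finite responses")
  rmax <- max(responses); rmin <- min(responses)
  th0 <- directions[which.max(responses)] %% 180
  obj <- function(p) {
    sum((von_mises_orientation(directions, p[1], p[2], p[3], p[4]) -
           responses)^2)
  }
  fit <- stats::optim(c(th0, 1, max(rmax - rmin, 1e-6), rmin), obj,
                      method = "L-BFGS-B",
                      lower = c(-Inf, 1e-3, 0, -Inf),
                      upper = c(Inf, 50, Inf, Inf),
                      control = list(maxit = 500, factr = 1e4))
  p <- fit$par
  theta_pref <- p[1] %% 180
  r_pref <- von_mises_orientation(theta_pref, p[1], p[2], p[3], p[4])
  r_ortho <- von_mises_orientation(theta_pref + 90, p[1], p[2], p[3], p[4])
  osi <- if (r_pref + r_ortho > 0) (r_pref - r_ortho) / (r_pref + r_ortho)
  else NA_real_
  structure(list(
    theta_pref = theta_pref, theta_ortho = (theta_pref + 90) %% 180,
    sigma1 = p[2], alpha = p[3], r0 = p[4],
    residual = fit$value,
    fitted = von_mises_orientation(directions, p[1], p[2], p[3], p[4]),
    osi = osi,
    op_ratio = if (r_pref > 0) r_ortho / r_pref else NA_real_,
    hwhh = orientation_hwhh(p[2]),
    converged = fit$convergence == 0
  ), class = "orientation_tuning_fit")
}

## Half-width at half-height of the normalized orientation lobe, degrees.
## Solve vm_basis(2*delta, sigma) = 1/2 for delta analytically.
orientation_hwhh <- function(sigma) {
  ## vm_basis = (exp(s(c-1)) - exp(-2s)) / (1 - exp(-2s)) = 1/2
  ## => cos(2 delta) = 1 + log((1 + exp(-2s)) / 2) / s
  c2 <- 1 + log((1 + exp(-2 * sigma)) / 2) / sigma
  rad2deg(acos(pmax(-1, pmin(1, c2)))) / 2
}

#' Response modulation ratio F1/F0
#'
#' F1 is the amplitude of the Fourier component of the trial-averaged
#' response at the stimulus drift temporal frequency; F0 is the mean rate.
#' Sites with F1/F0 >= 1 respond as simple cells, < 1 as complex cells.
#'
#' @param psth trial-averaged rate time course (spikes/s) during the
#'   stimulus epoch.
#' @param times_ms bin-center times in ms (uniform spacing).
#' @param tf_hz stimulus temporal frequency (Hz).
#' @return list with \code{f1}, \code{f0}, \code{ratio},
#'   \code{classification} (\code{"simple"} or \code{"complex"}).
#' @export
compute_f1f0 <- function(psth, times_ms, tf_hz) {
  t_s <- times_ms / 1000
  dur <- diff(range(t_s)) + (t_s[2] - t_s[1])
  if (dur * tf_hz < 2)
    stopf("validation_error", "need >= 2 stimulus cycles (have %.2f)",
          dur * tf_hz)
  f0 <- mean(psth)
  if (f0 == 0) stopf("undefined_ratio", "mean rate is zero")
  f1 <- 2 * Mod(mean(psth * exp(-2i * pi * tf_hz * t_s)))
  ratio <- f1 / f0
  list(f1 = f1, f0 = f0, ratio = ratio,
       classification = if (ratio >= 1) "simple" else "complex")
}

#' Tuning summary for one site
#'
#' Convenience wrapper: fits direction and orientation tuning to a site's
#' per-direction mean rates and collects DSI, OSI and the preferred
#' direction.
#'
#' @param tab a [trial_response_table()].
#' @param site site id or index.
#' @return list with \code{direction_fit}, \code{orientation_fit},
#'   \code{dsi}, \code{osi}, \code{theta_pref}.
#' @export
site_tuning_summary <- function(tab, site) {
  m <- site_mean_rates(tab, site)
  dirs <- condition_directions(tab)
  sel <- !is.na(dirs)
  dfit <- fit_direction_tuning(m[sel], dirs[sel])
  ofit <- fit_orientation_tuning(m[sel], dirs[sel])
  d <- tryCatch(compute_dsi(dfit), undefined_dsi = function(e) list(dsi = NA))
  list(direction_fit = dfit, orientation_fit = ofit,
       dsi = d$dsi, osi = ofit$osi, theta_pref = dfit$theta_pref,
       blank_rate = unname(m[BLANK]))
}
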