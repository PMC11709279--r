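# Interlaminar gain-transmission models: a linear gain per stimulus
# condition followed by a static nonlinearity, fitted to layer-averaged
# repetition-resolved rates.
#
# Model I:   output = f(w * input),        one shared gain w
# Model II:  output = f(w(S) * input),     gain varies per condition
# Model III: output = ReLU(w(S)*input - T) tuned gain, shared suppression
# Model IV:  output = ReLU(w*input - T(S)) shared gain, tuned suppression

#' Smoothed threshold-linear nonlinearity
#'
#' The Gaussian-smoothed rectifier
#' \deqn{f(g) = \frac{A(g-g_0)}{2}\left(1 + \mathrm{erf}\frac{g-g_0}
#'   {\sqrt{2}\sigma}\right) + \frac{A\sigma}{\sqrt{2\pi}}
#'   e^{-(g-g_0)^2 / 2\sigma^2},}
#' equal to the expectation of \code{A * max(g + e - g0, 0)} for Gaussian
#' noise \code{e} with standard deviation \code{sigma}. It is smooth,
#' strictly positive, and converges to \code{A * max(g - g0, 0)} as
#' \code{sigma} shrinks. At \code{g = g0} it evaluates to
#' \code{A * sigma / sqrt(2*pi)}.
#'
#' @param g drive (gain times input rate).
#' @param A output gain, >= 0.
#' @param g0 threshold.
#' @param sigma transition smoothness, > 0.
#' @return rates, same shape as \code{g}.
#' @export
threshold_linear <- function(g, A, g0, sigma) {
  if (sigma <= 0) stopf("validation_error", "sigma must be > 0")
  z <- g - g0
  (A * z / 2) * (1 + erf(z / (sqrt(2) * sigma))) +
    (A * sigma / sqrt(2 * pi)) * exp(-z^2 / (2 * sigma^2))
}

#' Power-law nonlinearity
#'
#' \code{f(g) = A * max(g - g0, 0)^n}: half rectification raised to an
#' exponent.
#'
#' @param g drive.
#' @param A output gain, >= 0.
#' @param g0 threshold.
#' @param n exponent, > 0.
#' @return rates, same shape as \code{g}.
#' @export
power_law <- function(g, A, g0, n) {
  if (n <= 0) stopf("validation_error", "exponent must be > 0")
  A * pmax(g - g0, 0)^n
}

#' Adjusted goodness of fit
#'
#' Parameter-penalized agreement between fitted and observed responses:
#' \deqn{adjR^2 = 1 - \frac{N-1}{N-N_{param}} \cdot
#'   \frac{2\sum(\hat R - R)^2}
#'        {\sum(\hat R - \bar{\hat R})^2 + \sum(R - \bar R)^2}.}
#' A perfect fit gives exactly 1; adding unused parameters strictly
#' lowers the value.
#'
#' @param fitted,observed equal-length rate vectors.
#' @param n_param number of free parameters; must be < \code{length(observed)}.
#' @return scalar adjusted R-squared.
#' @export
adjusted_r2 <- function(fitted, observed, n_param) {
  n <- length(observed)
  if (length(fitted) != n)
    stopf("validation_error", "fitted and observed differ in length")
  if (n <= n_param)
    stopf("validation_error", "need more samples than parameters")
  den <- sum((fitted - mean(fitted))^2) + sum((observed - mean(observed))^2)
  if (den == 0) stopf("undefined_r2", "both series are constant")
  1 - (n - 1) / (n - n_param) * 2 * sum((fitted - observed)^2) / den
}

model_ic <- function(J, n_sample, n_param) {
  list(aic = n_sample * log(J / n_sample) + 2 * n_param,
       bic = n_sample * log(J / n_sample) + log(n_sample) * n_param)
}

#' Fit an interlaminar gain model
#'
#' Minimizes the residual \code{J = sum over conditions and repetitions of
#' (predicted - observed)^2} between model output and the observed
#' output-layer rates, where both input and output are layer-averaged
#' rates paired by repetition within each condition. The per-condition
#' gains (Models II/III) and suppressions (Model IV) are profiled out by
#' inner one-dimensional optimization, and the remaining shared
#' parameters are fitted by bounded multi-start least squares.
#'
#' The gain scale in Models I and II trades off against the nonlinearity
#' parameters; after fitting, gains are renormalized so the mean gain
#' over grating conditions is 1 (a prediction-invariant
#' reparameterization), and the parameter count is reduced by one
#' accordingly.
#'
#' @param input_rates,output_rates matrices \code{[condition, repetition]}
#'   of layer-averaged rates (NA-padded where repetition counts differ).
#' @param conditions character vector naming the rows (degrees or
#'   \code{"blank"}).
#' @param model \code{"I"}, \code{"II"}, \code{"III"} or \code{"IV"}.
#' @param family nonlinearity for Models I/II: \code{"threshold_linear"}
#'   or \code{"power_law"} (Models III/IV always use the rectifier).
#' @param n_starts number of seeded multi-start restarts, default 10.
#' @param seed RNG seed for the restarts.
#' @return object of class \code{gain_model_fit}: \code{w} (per-condition
#'   gain), \code{suppression} (Models III/IV), \code{nonlinearity}
#'   (named parameters), \code{J}, \code{adj_r2}, \code{aic}, \code{bic},
#'   \code{n_param}, \code{fitted} matrix, \code{dsi_of_gain},
#'   \code{dsi_of_output}.
#' @export
fit_gain_model <- function(input_rates, output_rates, conditions,
                           model = c("II", "I", "III", "IV"),
                           family = c("threshold_linear", "power_law"),
                           n_starts = 10, seed = 1L) {
  model <- match.arg(model)
  family <- match.arg(family)
  if (!all(dim(input_rates) == dim(output_rates)))
    stopf("validation_error", "input and output shapes differ")
  if (nrow(input_rates) != length(conditions))
    stopf("validation_error", "conditions must name the rows")
  ok <- !is.na(input_rates) & !is.na(output_rates)
  if (any(rowSums(ok) < 2))
    stopf("validation_error", "need >= 2 paired repetitions per condition")
  if (all(input_rates[ok] == 0))
    stopf("degenerate_input", "all-zero input rates")

  C <- length(conditions)
  is_blank <- conditions == BLANK
  rmax <- max(output_rates[ok], input_rates[ok])
  x <- lapply(seq_len(C), function(k) input_rates[k, ok[k, ]])
  y <- lapply(seq_len(C), function(k) output_rates[k, ok[k, ]])
  n_sample <- sum(lengths(y))

  ## family forward function over shared params p
  fwd <- if (model %in% c("I", "II")) {
    if (family == "threshold_linear")
      function(g, p) threshold_linear(g, p[1], p[2], p[3])
    else function(g, p) power_law(g, p[1], p[2], p[3])
  } else NULL

  sse <- function(a, b) sum((a - b)^2)

  if (model == "I") {
    obj <- function(p) sum(vapply(seq_len(C), function(k)
      sse(fwd(x[[k]], p), y[[k]]), numeric(1)))
    best <- multistart_optim(obj, family, rmax, x, y, n_starts, seed)
    p <- best$par
    w <- rep(1, C)
    J <- best$value
    n_param <- 3
  } else if (model == "II") {
    ## profile out w(S): each gain only enters its own condition
    w_for <- function(p) vapply(seq_len(C), function(k) {
      stats::optimize(function(w) sse(fwd(w * x[[k]], p), y[[k]]),
                      c(0, 50), tol = 1e-9)$minimum
    }, numeric(1))
    obj <- function(p) {
      w <- w_for(p)
      sum(vapply(seq_len(C), function(k)
        sse(fwd(w[k] * x[[k]], p), y[[k]]), numeric(1)))
    }
    best <- multistart_optim(obj, family, rmax, x, y, n_starts, seed)
    p <- best$par
    w <- w_for(p)
    J <- best$value
    ## normalize mean grating gain to 1 (prediction-invariant)
    cscale <- mean(w[!is_blank])
    if (cscale > 0) {
      w <- w / cscale
      if (family == "threshold_linear")
        p <- c(p[1] * cscale, p[2] / cscale, p[3] / cscale)
      else p <- c(p[1] * cscale^p[3], p[2] / cscale, p[3])
    }
    n_param <- C + 3 - 1
  } else if (model == "III") {
    ## tuned gain, shared suppression: ReLU(w(S) x - T)
    w_for <- function(T) vapply(seq_len(C), function(k) {
      stats::optimize(function(w) sse(pmax(w * x[[k]] - T, 0), y[[k]]),
                      c(0, 50), tol = 1e-9)$minimum
    }, numeric(1))
    obj <- function(T) {
      w <- w_for(T)
      sum(vapply(seq_len(C), function(k)
        sse(pmax(w[k] * x[[k]] - T, 0), y[[k]]), numeric(1)))
    }
    best <- stats::optimize(obj, c(-rmax, rmax), tol = 1e-7)
    Tpar <- best$minimum
    w <- w_for(Tpar)
    J <- best$objective
    p <- NULL
    n_param <- C + 1
  } else { # Model IV: shared gain, tuned suppression
    T_for <- function(w) vapply(seq_len(C), function(k) {
      stats::optimize(function(T) sse(pmax(w * x[[k]] - T, 0), y[[k]]),
                      c(-50 * rmax, 50 * rmax), tol = 1e-9)$minimum
    }, numeric(1))
    obj <- function(w) {
      T <- T_for(w)
      sum(vapply(seq_len(C), function(k)
        sse(pmax(w * x[[k]] - T[k], 0), y[[k]]), numeric(1)))
    }
    best <- stats::optimize(obj, c(0, 50), tol = 1e-7)
    wshared <- best$minimum
    Tvec <- T_for(wshared)
    w <- rep(wshared, C)
    J <- best$objective
    p <- NULL
    n_param <- C + 1
  }

  predicted <- matrix(NA_real_, C, ncol(input_rates))
  for (k in seq_len(C)) {
    g <- w[k] * x[[k]]
    predicted[k, ok[k, ]] <- if (model %in% c("I", "II")) fwd(g, p)
    else if (model == "III") pmax(g - Tpar, 0)
    else pmax(g - Tvec[k], 0)
  }
  fitted_vec <- predicted[ok]
  obs_vec <- output_rates[ok]
  ic <- model_ic(max(J, .Machine$double.xmin), n_sample, n_param)
  nl <- switch(model,
    I = , II = stats::setNames(as.list(p),
      c("A", "g0", if (family == "threshold_linear") "sigma" else "n")),
    III = list(T = Tpar), IV = list(T = Tvec))

  structure(list(
    model = model, family = if (model %in% c("I", "II")) family else "relu",
    conditions = conditions, w = stats::setNames(w, conditions),
    suppression = if (model == "III") Tpar else if (model == "IV") Tvec
    else NULL,
    nonlinearity = nl,
    J = J, n_param = n_param, n_sample = n_sample,
    adj_r2 = adjusted_r2(fitted_vec, obs_vec, n_param),
    aic = ic$aic, bic = ic$bic,
    fitted = predicted,
    dsi_of_gain = if (model %in% c("II", "III")) gain_dsi(w, conditions)
    else NA_real_,
    dsi_of_output = model_output_dsi(predicted, conditions)
  ), class = "gain_model_fit")
}

multistart_optim <- function(obj, family, rmax, x, y, n_starts, seed) {
  ## heuristic start: linear scaling, threshold at zero, moderate smoothness
  scale0 <- mean(unlist(y)) / max(mean(unlist(x)), 1e-9)
  base <- if (family == "threshold_linear") c(max(scale0, 1e-3), 0, rmax / 10)
  else c(max(scale0, 1e-3), 0, 1)
  lower <- if (family == "threshold_linear") c(1e-6, -rmax, 1e-3)
  else c(1e-6, -rmax, 0.5)
  upper <- if (family == "threshold_linear") c(100, rmax, rmax)
  else c(100, rmax, 5)
  starts <- with_local_seed(seed, {
    c(list(base), lapply(seq_len(max(n_starts - 1, 0)), function(i) {
      s <- base * stats::runif(3, 0.3, 3) +
        c(0, stats::runif(1, -0.3, 0.3) * rmax, 0)
      pmin(pmax(s, lower), upper)
    }))
  })
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e3)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stopf("fit_error", "gain-model optimizer failed")
  best
}

## DSI of the gain curve: gain at the peak grating direction versus the
## diametrically opposite grid direction.
gain_dsi <- function(w, conditions) {
  dirs <- suppressWarnings(as.numeric(conditions))
  sel <- !is.na(dirs)
  wg <- w[sel]; dg <- dirs[sel]
  kp <- which.max(wg)
  kn <- which.min(preferred_direction_difference(dg, (dg[kp] + 180) %% 360))
  if (wg[kp] + wg[kn] <= 0) return(NA_real_)
  unname((wg[kp] - wg[kn]) / (wg[kp] + wg[kn]))
}

## DSI of the model's predicted output: von Mises fit to per-condition
## mean predictions over the grating directions.
model_output_dsi <- function(predicted, conditions) {
  dirs <- suppressWarnings(as.numeric(conditions))
  sel <- !is.na(dirs)
  m <- rowMeans(predicted[sel, , drop = FALSE], na.rm = TRUE)
  out <- tryCatch({
    fit <- fit_direction_tuning(m, dirs[sel])
    compute_dsi(fit)$dsi
  }, error = function(e) NA_real_)
  out
}

#' Forward pass of a gain-transmission model
#'
#' Applies a per-condition linear gain and a static nonlinearity to
#' repetition-resolved input rates: \code{output[k, i] = f(w[k] *
#' input[k, i])}. Used to generate model-consistent data and predictions.
#'
#' @param input_rates matrix \code{[condition, repetition]}.
#' @param gain per-condition gain vector \code{w(S)} (recycled if scalar).
#' @param nonlinearity named list: \code{A}, \code{g0} and \code{sigma}
#'   (threshold-linear) or \code{n} (power law).
#' @return matrix of predicted output rates, same shape as
#'   \code{input_rates}.
#' @export
gain_model_forward <- function(input_rates, gain, nonlinearity) {
  w <- rep_len(gain, nrow(input_rates))
  g <- input_rates * w
  nl <- nonlinearity
  if (!is.null(nl$sigma)) threshold_linear(g, nl$A, nl$g0, nl$sigma)
  else power_law(g, nl$A, nl$g0, nl$n)
}

#' Decompose the sources of selectivity enhancement
#'
#' Splits the DSI gap between the output and input layers into the part
#' reproduced by an untuned gain plus nonlinearity (Model I) and the
#' additional part contributed by gain tuning (Model II):
#' \code{contrib_nonlin = (dsi_modelI - dsi_input) / (dsi_output -
#' dsi_input)} and \code{contrib_gain = (dsi_modelII - dsi_modelI) /
#' (dsi_output - dsi_input)}. The two terms sum to
#' \code{(dsi_modelII - dsi_input)/(dsi_output - dsi_input)} by
#' construction.
#'
#' @param dsi_input,dsi_output,dsi_modelI,dsi_modelII scalar DSIs.
#' @return list with \code{contrib_nonlin} and \code{contrib_gain}.
#' @export
contribution_decomposition <- function(dsi_input, dsi_output,
                                       dsi_modelI, dsi_modelII) {
  den <- dsi_output - dsi_input
  if (den == 0) stopf("undefined_contribution", "output DSI equals input DSI")
  list(contrib_nonlin = (dsi_modelI - dsi_input) / den,
       contrib_gain = (dsi_modelII - dsi_modelI) / den)
}

#' Output/input response-ratio tuning
#'
#' Ratio of output-layer to input-layer response per condition, with the
#' direction axis circularly shifted so the preferred direction maps to
#' 90 degrees. Conditions where the input response is not positive are
#' masked.
#'
#' @param input_tuning,output_tuning named per-condition mean rates
#'   (names: degrees or \code{"blank"}).
#' @param theta_pref preferred direction (degrees) used for the
#'   alignment.
#' @return list of class \code{response_ratio_tuning}:
#'   \code{aligned_directions}, \code{ratio} (same order), and scalars
#'   \code{ratio_blank}, \code{ratio_null}, \code{ratio_pref}.
#' @export
response_ratio_tuning <- function(input_tuning, output_tuning, theta_pref) {
  if (!identical(names(input_tuning), names(output_tuning)))
    stopf("alignment_error", "condition sets differ")
  conds <- names(input_tuning)
  dirs <- suppressWarnings(as.numeric(conds))
  ratio <- ifelse(input_tuning > 0, output_tuning / input_tuning, NA_real_)
  sel <- !is.na(dirs)
  aligned <- (dirs[sel] - theta_pref + 90) %% 360
  rg <- ratio[sel]
  o <- order(aligned)
  kp <- which.min(preferred_direction_difference(aligned, 90))
  kn <- which.min(preferred_direction_difference(aligned, 270))
  structure(list(
    aligned_directions = aligned[o], ratio = rg[o],
    ratio_blank = if (BLANK %in% conds) unname(ratio[conds == BLANK])
    else NA_real_,
    ratio_pref = unname(rg[kp]), ratio_null = unname(rg[kn])
  ), class = "response_ratio_tuning")
}

#' Layer-averaged repetition-resolved rates
#'
#' Averages time-averaged rates across all given sites for each
#' (condition, repetition) slot, the quantity entering the gain models.
#'
#' @param tab a [trial_response_table()].
#' @param sites site ids or indices to average over.
#' @return matrix \code{[condition, repetition]} with NA where no site
#'   has that repetition.
#' @export
layer_average_rates <- function(tab, sites) {
  idx <- vapply(sites, function(s) site_index(tab, s), integer(1))
  r <- tab$rates[idx, , , drop = FALSE]
  out <- apply(r, c(2, 3), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  rownames(out) <- tab$conditions
  out
}
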