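# Latency estimation, layer assignment, CSD and probe-perpendicularity QC.

#' Response latency from a PSTH
#'
#' Latency is the first post-onset time at which the baseline-subtracted
#' response reaches half of its post-onset maximum, with linear
#' interpolation between bins. The baseline is the pre-stimulus mean; the
#' maximum is searched within \code{search_window_ms} after onset to avoid
#' late rebound peaks.
#'
#' @param psth trial-averaged rate time course (spikes/s).
#' @param times_ms bin-center times (ms) relative to stimulus onset; must
#'   cover pre- and post-onset epochs.
#' @param baseline_window interval (ms) over which to estimate the
#'   baseline; default the whole pre-onset epoch.
#' @param search_window_ms post-onset window (ms) in which to take the
#'   response maximum, default \code{c(0, 200)}.
#' @return latency in ms (>= 0).
#' @export
compute_latency <- function(psth, times_ms,
                            baseline_window = NULL,
                            search_window_ms = c(0, 200)) {
  if (length(psth) != length(times_ms))
    stopf("validation_error", "psth and times differ in length")
  if (!any(times_ms < 0) || !any(times_ms >= 0))
    stopf("validation_error", "psth must cover pre- and post-onset epochs")
  if (is.null(baseline_window)) baseline_window <- c(min(times_ms), 0)
  base_sel <- times_ms >= baseline_window[1] & times_ms < baseline_window[2]
  r <- psth - mean(psth[base_sel])
  post <- times_ms >= search_window_ms[1] & times_ms <= search_window_ms[2]
  rmax <- max(r[post])
  if (rmax <= 0)
    stopf("undefined_latency", "post-onset maximum is not positive")
  half <- rmax / 2
  tp <- times_ms[post]; rp <- r[post]
  k <- which(rp >= half)[1]
  if (k == 1) return(max(tp[1], 0))
  ## linear interpolation between the straddling bins
  t0 <- tp[k - 1]; t1 <- tp[k]; r0 <- rp[k - 1]; r1 <- rp[k]
  t0 + (half - r0) / (r1 - r0) * (t1 - t0)
}

#' Layer assignment configuration
#'
#' Relative-depth boundaries separating L2/3, L4, L5 and L6. Defaults are
#' 0.35, 0.58 and 0.76 from the cortical surface (depth 0 = top of L2/3,
#' depth 1 = L6/white-matter border).
#'
#' @param boundaries three strictly increasing depths in (0, 1).
#' @return list of class \code{layer_assignment_config}.
#' @export
layer_assignment_config <- function(boundaries = c(0.35, 0.58, 0.76)) {
  b <- as.numeric(boundaries)
  if (length(b) != 3 || any(b <= 0) || any(b >= 1) || any(diff(b) <= 0))
    stopf("validation_error", "boundaries must satisfy 0 < b1 < b2 < b3 < 1")
  structure(list(boundaries = b), class = "layer_assignment_config")
}

#' Assign cortical layers from relative depth
#'
#' Half-open convention: depth < b1 is L2/3, [b1, b2) is L4, [b2, b3) is
#' L5, >= b3 is L6. L2/3 and L5 form the "output" group, L4 and L6 the
#' "input" group.
#'
#' @param relative_depth numeric vector in \code{[0, 1]}.
#' @param config a [layer_assignment_config()].
#' @return data frame with \code{relative_depth}, \code{layer} (factor
#'   with levels L2/3, L4, L5, L6) and \code{group} ("output"/"input").
#' @export
assign_layers <- function(relative_depth, config = layer_assignment_config()) {
  d <- as.numeric(relative_depth)
  if (any(!is.finite(d)) || any(d < 0 | d > 1))
    stopf("validation_error", "relative depth outside [0,1]")
  b <- config$boundaries
  layer <- cut(d, breaks = c(-Inf, b, Inf), right = FALSE,
               labels = c("L2/3", "L4", "L5", "L6"))
  group <- ifelse(layer %in% c("L2/3", "L5"), "output", "input")
  data.frame(relative_depth = d, layer = layer, group = group,
             stringsAsFactors = FALSE)
}

#' Current source density from laminar LFPs
#'
#' Standard second spatial difference across equally spaced contacts:
#' \code{CSD(d,t) = -(LFP(d-1,t) - 2 LFP(d,t) + LFP(d+1,t)) / spacing^2}.
#' Edge channels are dropped.
#'
#' @param lfp matrix \code{[depth, time]}.
#' @param spacing_um inter-contact spacing in micrometres (uniform).
#' @return matrix \code{[depth - 2, time]}; rownames carry the retained
#'   depth indices.
#' @export
compute_csd <- function(lfp, spacing_um) {
  if (!is.matrix(lfp) || nrow(lfp) < 3)
    stopf("validation_error", "need >= 3 depths")
  if (length(spacing_um) != 1 || spacing_um <= 0)
    stopf("validation_error", "spacing must be a positive scalar")
  n <- nrow(lfp)
  csd <- -(lfp[1:(n - 2), , drop = FALSE] -
             2 * lfp[2:(n - 1), , drop = FALSE] +
             lfp[3:n, , drop = FALSE]) / spacing_um^2
  rownames(csd) <- 2:(n - 1)
  csd
}

#' Probe perpendicularity quality control
#'
#' Two summary statistics over the sites of one probe placement:
#' RF-center dispersion — the mean Euclidean distance of receptive-field
#' centers from their mean center, divided by twice the geometric mean of
#' the RF radii (i.e. relative to the population-averaged RF diameter) —
#' and preferred-orientation consistency — the modulus of the mean unit
#' phasor at the doubled orientation angle, 1 when all sites share one
#' preferred orientation, 0 under complete cancellation.
#'
#' @param rf_list data frame or list with per-site columns/fields
#'   \code{x}, \code{y} (RF center, degrees of visual angle) and
#'   \code{sigma} (RF radius, > 0).
#' @param preferred_orientations per-site preferred orientations
#'   (degrees).
#' @return list of class \code{probe_qc} with
#'   \code{rf_center_dispersion} and \code{orientation_consistency}.
#' @export
probe_qc <- function(rf_list, preferred_orientations) {
  rf <- as.data.frame(rf_list)
  if (nrow(rf) < 2) stopf("validation_error", "need >= 2 sites with RF fits")
  if (any(rf$sigma <= 0)) stopf("validation_error", "RF radius must be > 0")
  dx <- rf$x - mean(rf$x); dy <- rf$y - mean(rf$y)
  dispersion <- mean(sqrt(dx^2 + dy^2)) /
    (2 * exp(mean(log(rf$sigma))))
  th <- deg2rad(preferred_orientations)
  consistency <- Mod(mean(exp(2i * th)))
  structure(list(rf_center_dispersion = dispersion,
                 orientation_consistency = consistency,
                 rf_list = rf,
                 preferred_orientations = preferred_orientations),
            class = "probe_qc")
}

#' Running median across cortical depth
#'
#' Depth profile used for laminar plots: a centered running median over
#' \code{window} neighbouring sites (ordered by depth), with a bootstrap
#' SEM per window.
#'
#' @param depth per-site relative depth.
#' @param value per-site statistic (e.g. DSI or latency).
#' @param window odd window size in sites, default 7.
#' @param n_boot bootstrap resamples for the SEM, default 1000.
#' @param seed RNG seed for the bootstrap.
#' @return data frame with \code{depth}, \code{median}, \code{sem}.
#' @export
laminar_profile <- function(depth, value, window = 7, n_boot = 1000,
                            seed = 1L) {
  o <- order(depth)
  depth <- depth[o]; value <- value[o]
  half <- window %/% 2
  n <- length(depth)
  rows <- lapply(seq_len(n), function(i) {
    sel <- max(1, i - half):min(n, i + half)
    v <- value[sel]
    c(depth = depth[i], median = stats::median(v, na.rm = TRUE),
      sem = boot_sem_median(v, n_boot, seed + i))
  })
  as.data.frame(do.call(rbind, rows))
}
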