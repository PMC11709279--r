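# Pairwise-conditional Granger causality from VAR first principles.
#
# GC(to <- from | rest) = ln( var_reduced / var_full ), where var_full is
# the residual variance of the target channel in a VAR on all channels
# and var_reduced the same with the source channel removed (all other
# channels retained as the conditioning set). Conditioning removes
# spurious dependence induced by common drivers.

## Build the lagged regression design. `series` is one [time x channel]
## matrix or a list of such matrices (trials); lags never cross trial
## boundaries. Channels are demeaned per trial.
var_design <- function(series, order) {
  if (is.matrix(series)) series <- list(series)
  Xs <- list(); Ys <- list()
  for (s in series) {
    s <- scale(s, center = TRUE, scale = FALSE)
    n <- nrow(s)
    if (n <= order + 1) next
    idx <- (order + 1):n
    Ys[[length(Ys) + 1]] <- s[idx, , drop = FALSE]
    Xs[[length(Xs) + 1]] <- do.call(cbind, lapply(seq_len(order), function(l)
      s[idx - l, , drop = FALSE]))
  }
  if (!length(Ys)) stopf("estimation_error", "series shorter than the lag order")
  list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys))
}

var_lstsq <- function(X, Y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    stopf("estimation_error", "rank-deficient lagged regressors")
  B <- qr.coef(qr_x, Y)
  E <- Y - X %*% B
  Sigma <- crossprod(E) / (nrow(X) - ncol(X))
  list(B = B, Sigma = Sigma, n_eff = nrow(X))
}

#' Fit a vector autoregressive model
#'
#' Least-squares VAR on demeaned channels, with the lag order selected by
#' AIC over \code{1..max_order} when not given. Accepts a single
#' \code{[time, channel]} matrix or a list of per-trial matrices (lags
#' are built within trials only).
#'
#' @param series matrix \code{[time, channel]} or list of such matrices;
#'   >= 2 channels.
#' @param max_order largest lag order tried, default 20.
#' @param order fixed lag order (skips selection).
#' @return list of class \code{var_fit}: \code{A} (coefficient array
#'   \code{[to, from, lag]}), \code{Sigma} (residual covariance),
#'   \code{order}, \code{aic} (per candidate order), \code{stable}.
#' @export
fit_var <- function(series, max_order = 20, order = NULL) {
  mat1 <- if (is.matrix(series)) series else series[[1]]
  m <- ncol(mat1)
  if (m < 2) stopf("validation_error", "need >= 2 channels")
  if (is.null(order)) {
    aics <- vapply(seq_len(max_order), function(p) {
      d <- var_design(series, p)
      f <- var_lstsq(d$X, d$Y)
      det_s <- det(f$Sigma)
      if (det_s <= 0) return(Inf)
      nrow(d$X) * log(det_s) + 2 * p * m^2
    }, numeric(1))
    order <- which.min(aics)
  } else aics <- NULL
  d <- var_design(series, order)
  f <- var_lstsq(d$X, d$Y)
  ## reshape coefficients: column block l of t(B) is lag-l matrix
  A <- array(0, c(m, m, order),
             dimnames = list(colnames(mat1), colnames(mat1), NULL))
  for (l in seq_len(order))
    A[, , l] <- t(f$B[((l - 1) * m + 1):(l * m), , drop = FALSE])
  comp <- matrix(0, m * order, m * order)
  for (l in seq_len(order)) comp[1:m, ((l - 1) * m + 1):(l * m)] <- A[, , l]
  if (order > 1)
    comp[(m + 1):(m * order), 1:(m * (order - 1))] <- diag(m * (order - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) warning(sprintf("fitted VAR unstable (radius %.3f)", rho))
  ev <- eigen(f$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) warning("residual covariance not positive definite")
  structure(list(A = A, Sigma = f$Sigma, order = order, aic = aics,
                 n_eff = f$n_eff, stable = rho < 1), class = "var_fit")
}

#' Pairwise-conditional Granger causality
#'
#' For every directed channel pair, the log ratio of the target's
#' residual variance without versus with the source channel in the VAR,
#' all remaining channels kept in both models (the conditioning set).
#' Estimates below zero (possible from finite samples) are clamped to 0
#' and flagged.
#'
#' @param series matrix \code{[time, channel]} or list of per-trial
#'   matrices; >= 2 channels (>= 3 for the conditioning to matter).
#' @param order VAR lag order; selected by AIC up to \code{max_order}
#'   when NULL.
#' @param max_order order-selection bound, default 20.
#' @return list of class \code{gc_result}: \code{gc} matrix
#'   \code{[to, from]} (diagonal \code{NA}), \code{order},
#'   \code{var_fit}, \code{clamped} logical matrix.
#' @export
pairwise_conditional_gc <- function(series, order = NULL, max_order = 20) {
  full <- fit_var(series, max_order = max_order, order = order)
  m <- ncol(full$Sigma)
  nm <- colnames(full$A) %||% paste0("ch", seq_len(m))
  gc <- matrix(NA_real_, m, m, dimnames = list(to = nm, from = nm))
  clamped <- matrix(FALSE, m, m, dimnames = dimnames(gc))
  subset_series <- function(keep) {
    if (is.matrix(series)) series[, keep, drop = FALSE]
    else lapply(series, function(s) s[, keep, drop = FALSE])
  }
  for (j in seq_len(m)) {            # source channel removed
    keep <- setdiff(seq_len(m), j)
    d <- var_design(subset_series(keep), full$order)
    red <- var_lstsq(d$X, d$Y)       # univariate AR allowed here
    for (i in keep) {
      ii <- match(i, keep)
      v_full <- full$Sigma[i, i]
      v_red <- red$Sigma[ii, ii]
      if (v_full <= 0 || v_red <= 0)
        stopf("numerical_error", "singular residual variance (channel %s)",
              nm[i])
      val <- log(v_red / v_full)
      if (val < 0) { clamped[i, j] <- TRUE; val <- 0 }
      gc[i, j] <- val
    }
  }
  structure(list(gc = gc, order = full$order, var_fit = full,
                 clamped = clamped), class = "gc_result")
}

#' Z-score GC values over a normalization set
#'
#' Centers and scales a collection of GC values (all condition and
#' layer-pair entries of one probe placement) to mean 0 and unit
#' variance, ignoring \code{NA} diagonal entries.
#'
#' @param gc_values numeric vector/matrix/array of GC values.
#' @return same shape, z-scored.
#' @export
normalize_gc <- function(gc_values) {
  v <- gc_values[!is.na(gc_values)]
  (gc_values - mean(v)) / stats::sd(v)
}

#' Contrast normalized GC between two conditions
#'
#' Per layer-pair difference of normalized GC across probes, tested with
#' a paired Wilcoxon signed-rank test and Bonferroni-corrected by
#' multiplying each p-value by \code{n_comparisons} (capped at 1).
#'
#' @param gc_a,gc_b matrices \code{[probe, layer_pair]} of normalized GC
#'   under two conditions; column names must match.
#' @param n_comparisons Bonferroni multiplier (e.g. 16 for a 4 x 4
#'   connection grid).
#' @return data frame with \code{pair}, \code{median_diff},
#'   \code{p_raw}, \code{p_corrected}.
#' @export
contrast_conditions <- function(gc_a, gc_b, n_comparisons) {
  gc_a <- as.matrix(gc_a); gc_b <- as.matrix(gc_b)
  if (!identical(dim(gc_a), dim(gc_b)) ||
      !identical(colnames(gc_a), colnames(gc_b)))
    stopf("alignment_error", "layer pairs do not match across conditions")
  rows <- lapply(seq_len(ncol(gc_a)), function(k) {
    d <- gc_a[, k] - gc_b[, k]
    d <- d[is.finite(d)]
    p <- if (all(d == 0)) 1
    else suppressWarnings(stats::wilcox.test(d)$p.value)
    data.frame(pair = colnames(gc_a)[k] %||% as.character(k),
               median_diff = stats::median(d),
               p_raw = p, p_corrected = min(1, p * n_comparisons),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Condition-resolved layer GC for one probe
#'
#' Forms layer signals by averaging PSTH time courses across the sites of
#' each layer, then computes pairwise-conditional GC per stimulus
#' condition from the per-trial series.
#'
#' @param tab a [trial_response_table()] with PSTHs.
#' @param layers named per-site layer labels (from [assign_layers()]).
#' @param conditions conditions to analyze (default all).
#' @param use_layers layers to include as channels, default
#'   \code{c("L2/3", "L4", "L5")}.
#' @param order,max_order VAR order control (default: AIC up to 10).
#' @return list of class \code{layer_gc}: \code{gc} array
#'   \code{[condition, to, from]}, \code{normalized} (z-scored over all
#'   entries), \code{order}.
#' @export
layer_gc <- function(tab, layers, conditions = tab$conditions,
                     use_layers = c("L2/3", "L4", "L5"),
                     order = NULL, max_order = 10) {
  if (is.null(tab$psth)) stopf("format_error", "PSTHs required for GC")
  layers <- layers[tab$site_ids]
  present <- use_layers[use_layers %in% layers]
  if (length(present) < 2)
    stopf("validation_error", "need sites in >= 2 of the requested layers")
  k_sel <- match(conditions, tab$conditions)
  res <- array(NA_real_, c(length(conditions), length(present), length(present)),
               dimnames = list(conditions, present, present))
  ord_used <- NULL
  for (ci in seq_along(k_sel)) {
    k <- k_sel[ci]
    nrep <- sum(apply(!is.na(tab$rates[, k, , drop = FALSE]), 3, any))
    trials <- lapply(seq_len(nrep), function(r) {
      do.call(cbind, stats::setNames(lapply(present, function(L) {
        idx <- which(layers == L)
        colMeans(matrix(tab$psth[idx, k, r, ],
                        nrow = length(idx)), na.rm = TRUE)
      }), present))
    })
    g <- pairwise_conditional_gc(trials, order = order %||% ord_used,
                                 max_order = max_order)
    ord_used <- g$order     # select once, reuse across conditions
    res[ci, , ] <- g$gc
  }
  structure(list(gc = res, normalized = normalize_gc(res), order = ord_used),
            class = "layer_gc")
}
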