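# The interlaminar statistical battery and the end-to-end pipeline.

comparison_result <- function(test, statistic, p_value, n, effect_summary,
                              corrected_p = NULL, notes = character()) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n = n, effect_summary = effect_summary,
                 corrected_p = corrected_p, notes = notes),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, n = %s\n",
              x$test, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Interlaminar comparison of probe-level medians
#'
#' Two-sided Wilcoxon signed-rank test for paired probe-level medians
#' (e.g. output vs input layers of the same probe placements), or the
#' rank-sum test for independent groups. Reports median and a bootstrap
#' SEM per group. With fewer than 5 probes a low-power note is attached
#' and the test still runs. All-zero paired differences are degenerate:
#' p = 1 with a note.
#'
#' @param a,b numeric vectors of probe-level medians.
#' @param paired paired comparison (default TRUE).
#' @param seed seed for the bootstrap SEM.
#' @return a \code{comparison_result}.
#' @export
interlaminar_compare <- function(a, b, paired = TRUE, seed = 1L) {
  notes <- character()
  if (paired && length(a) != length(b))
    stopf("validation_error", "paired comparison needs equal lengths")
  n <- if (paired) length(a) else c(length(a), length(b))
  if (min(n) < 5) notes <- c(notes, "low power: n < 5")
  eff <- list(
    median_a = stats::median(a), sem_a = boot_sem_median(a, seed = seed),
    median_b = stats::median(b), sem_b = boot_sem_median(b, seed = seed + 1))
  if (paired && all(a - b == 0)) {
    return(comparison_result(
      "Wilcoxon signed-rank", NA_real_, 1, n, eff,
      notes = c(notes, "all paired differences zero; test undefined")))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
  comparison_result(
    if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum",
    unname(ht$statistic), ht$p.value, n, eff, notes = notes)
}

#' Compare two proportions
#'
#' Chi-square test (no continuity correction) on the 2 x 2 table of
#' successes and failures, e.g. the per-layer proportions of sites with
#' DSI > 1/3.
#'
#' @param k_a,n_a successes and total in group a.
#' @param k_b,n_b successes and total in group b.
#' @return a \code{comparison_result}.
#' @export
proportion_compare <- function(k_a, n_a, k_b, n_b) {
  if (n_a == 0 || n_b == 0) stopf("validation_error", "empty group")
  if (k_a > n_a || k_b > n_b) stopf("validation_error", "k exceeds n")
  tabm <- matrix(c(k_a, n_a - k_a, k_b, n_b - k_b), 2, byrow = TRUE)
  ht <- suppressWarnings(stats::chisq.test(tabm, correct = FALSE))
  comparison_result("chi-square", unname(ht$statistic), ht$p.value,
                    c(n_a, n_b),
                    list(prop_a = k_a / n_a, prop_b = k_b / n_b))
}

#' Spearman rank correlation
#'
#' @param x,y equal-length numeric vectors, n >= 5, neither constant.
#' @return a \code{comparison_result}; \code{statistic} is rho.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stopf("validation_error", "unequal lengths")
  if (length(x) < 5) stopf("validation_error", "need n >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("undefined_correlation", "constant input vector")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  comparison_result("Spearman", unname(ht$estimate), ht$p.value, length(x),
                    list(rho = unname(ht$estimate)))
}

#' Exact sign test against a reference value
#'
#' Two-sided exact binomial test on the signs of \code{values -
#' null_value}, ties removed (used e.g. to test whether response ratios
#' differ from 1).
#'
#' @param values numeric vector.
#' @param null_value reference, default 0.
#' @return a \code{comparison_result}.
#' @export
sign_test <- function(values, null_value = 0) {
  d <- values - null_value
  d <- d[d != 0]
  if (!length(d)) stopf("undefined_test", "all values tie the reference")
  ht <- stats::binom.test(sum(d > 0), length(d))
  comparison_result("sign test", sum(d > 0), ht$p.value, length(d),
                    list(median = stats::median(values),
                         n_above = sum(d > 0), n_below = sum(d < 0)))
}

# ---------------------------------------------------------------------------
# Pipeline

#' Run the full laminar analysis pipeline on synthetic probes
#'
#' Executes, per probe: generation, SNR screening, tuning fits, layer
#' assignment, gain-model fitting (Models I and II), response-ratio
#' tuning, and condition-resolved layer GC; then the population
#' statistics (interlaminar DSI comparison, response-ratio sign tests,
#' contribution decomposition, GC condition contrasts). Fully seeded.
#'
#' @param config named list: \code{n_probes} (default 6), \code{truth}
#'   (config list passed to [make_ground_truth()]), \code{n_input_sites},
#'   \code{n_output_sites} (default 6 each), \code{family} (nonlinearity
#'   for the gain models), \code{n_starts} (restarts, default 5),
#'   \code{adj_r2_gate} (probe acceptance on Model II fit, default 0.8),
#'   \code{gc} (run the GC stage, default TRUE).
#' @param seed master seed.
#' @param out_dir output directory; created if missing. Writes
#'   \code{sites.csv}, \code{layers.csv}, \code{gainfits.json},
#'   \code{gc.json} and \code{report.md}.
#' @return list of class \code{pipeline_report} (invisibly, also written
#'   to disk): \code{sites}, \code{probes}, \code{population},
#'   \code{failed_stage} (NULL on success).
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  cfg <- utils::modifyList(list(
    n_probes = 6L, truth = list(), n_input_sites = 6L, n_output_sites = 6L,
    family = "threshold_linear", n_starts = 5L, adj_r2_gate = 0.8,
    gc = TRUE), config)
  report <- list(config = cfg, seed = seed, failed_stage = NULL)

  probes <- list(); site_rows <- list()
  for (pi in seq_len(cfg$n_probes)) {
    pseed <- seed * 1000L + pi
    pr <- tryCatch(
      analyze_probe(cfg, pseed),
      error = function(e) e)
    if (inherits(pr, "error")) {
      report$failed_stage <- sprintf("probe %d: %s", pi, conditionMessage(pr))
      break
    }
    probes[[pi]] <- pr
    site_rows[[pi]] <- pr$sites
  }
  report$probes <- probes
  report$sites <- if (length(site_rows)) do.call(rbind, site_rows) else NULL

  if (is.null(report$failed_stage)) {
    report$population <- tryCatch(
      population_summary(probes, cfg, seed),
      error = function(e) { report$failed_stage <<- conditionMessage(e); NULL })
  }
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  invisible(report)
}

analyze_probe <- function(cfg, pseed) {
  truth <- make_ground_truth(cfg$truth, seed = pseed)
  sim <- simulate_probe(truth, cfg$n_input_sites, cfg$n_output_sites,
                        seed = pseed)
  tab <- sim$table
  surv <- screen_sites(tab)
  if (nrow(surv) == 0) stopf("pipeline_error", "screening left no sites")
  lay <- assign_layers(surv$relative_depth)
  tt <- psth_times(tab)

  sites <- do.call(rbind, lapply(seq_len(nrow(surv)), function(i) {
    sid <- surv$site_id[i]
    ts <- site_tuning_summary(tab, sid)
    k_pref <- which.min(preferred_direction_difference(
      condition_directions(tab), ts$theta_pref))
    psm <- colMeans(matrix(tab$psth[site_index(tab, sid), k_pref, , ],
                           ncol = length(tt)), na.rm = TRUE)
    lat <- tryCatch(compute_latency(psm, tt),
                    undefined_latency = function(e) NA_real_)
    data.frame(probe_id = tab$probe_id, site_id = sid,
               relative_depth = surv$relative_depth[i],
               layer = as.character(lay$layer[i]), group = lay$group[i],
               snr = surv$snr[i], theta_pref = ts$theta_pref,
               dsi = ts$dsi, osi = ts$osi, latency_ms = lat,
               stringsAsFactors = FALSE)
  }))

  in_sites <- sites$site_id[sites$group == "input"]
  out_sites <- sites$site_id[sites$group == "output"]
  if (length(in_sites) < 1 || length(out_sites) < 1)
    stopf("pipeline_error", "need surviving sites in both layer groups")
  rin <- layer_average_rates(tab, in_sites)
  rout <- layer_average_rates(tab, out_sites)
  fitI <- fit_gain_model(rin, rout, tab$conditions, model = "I",
                         family = cfg$family, n_starts = cfg$n_starts,
                         seed = pseed)
  fitII <- fit_gain_model(rin, rout, tab$conditions, model = "II",
                          family = cfg$family, n_starts = cfg$n_starts,
                          seed = pseed)

  dirs <- condition_directions(tab)
  mk <- function(m) stats::setNames(rowMeans(m, na.rm = TRUE), tab$conditions)
  min_t <- mk(rin); mout_t <- mk(rout)
  sel <- !is.na(dirs)
  in_fit <- fit_direction_tuning(min_t[sel], dirs[sel])
  out_fit <- fit_direction_tuning(mout_t[sel], dirs[sel])
  dsi_in <- compute_dsi(in_fit)$dsi
  dsi_out <- compute_dsi(out_fit)$dsi
  ratio <- response_ratio_tuning(min_t, mout_t, out_fit$theta_pref)

  gc_res <- if (isTRUE(cfg$gc)) {
    k_pref <- which.min(preferred_direction_difference(dirs, truth$theta_pref))
    k_null <- which.min(preferred_direction_difference(
      dirs, (truth$theta_pref + 180) %% 360))
    layer_gc(tab, stats::setNames(sim$layer_labels, names(sim$layer_labels)),
             conditions = c(BLANK, tab$conditions[k_null],
                            tab$conditions[k_pref]), order = 1)
  } else NULL

  list(truth = truth, table_id = tab$probe_id, sites = sites,
       dsi_input = dsi_in, dsi_output = dsi_out,
       dsi_modelI = fitI$dsi_of_output, dsi_modelII = fitII$dsi_of_output,
       fitI = fitI, fitII = fitII, ratio = ratio, gc = gc_res)
}

population_summary <- function(probes, cfg, seed) {
  gate <- vapply(probes, function(p) p$fitII$adj_r2 > cfg$adj_r2_gate,
                 logical(1))
  med_by_group <- function(p, g)
    stats::median(p$sites$dsi[p$sites$group == g], na.rm = TRUE)
  dsi_out <- vapply(probes, med_by_group, numeric(1), "output")
  dsi_in <- vapply(probes, med_by_group, numeric(1), "input")
  contrib <- lapply(probes[gate], function(p)
    tryCatch(contribution_decomposition(p$dsi_input, p$dsi_output,
                                        p$dsi_modelI, p$dsi_modelII),
             undefined_contribution = function(e) NULL))
  contrib <- contrib[!vapply(contrib, is.null, logical(1))]
  ratios <- list(
    blank = vapply(probes, function(p) p$ratio$ratio_blank, numeric(1)),
    null = vapply(probes, function(p) p$ratio$ratio_null, numeric(1)),
    pref = vapply(probes, function(p) p$ratio$ratio_pref, numeric(1)))

  gc_contrasts <- NULL
  if (all(vapply(probes, function(p) !is.null(p$gc), logical(1)))) {
    flat <- function(p, ci) {
      g <- p$gc$normalized[ci, , ]
      v <- as.vector(g)
      names(v) <- outer(rownames(g), colnames(g),
                        function(a, b) paste(b, "->", a))
      v[!is.na(v)]
    }
    mat_for <- function(ci) do.call(rbind, lapply(probes, flat, ci))
    n_cmp <- length(flat(probes[[1]], 1))
    gc_contrasts <- list(
      null_vs_blank = contrast_conditions(mat_for(2), mat_for(1), n_cmp),
      pref_vs_blank = contrast_conditions(mat_for(3), mat_for(1), n_cmp),
      pref_vs_null = contrast_conditions(mat_for(3), mat_for(2), n_cmp))
  }

  list(
    n_probes = length(probes), n_gated = sum(gate), gate = gate,
    dsi_output_medians = dsi_out, dsi_input_medians = dsi_in,
    dsi_compare = interlaminar_compare(dsi_out, dsi_in, paired = TRUE,
                                       seed = seed),
    dsi_enhancement = stats::median((dsi_out - dsi_in) / dsi_in),
    ratio_pref = ratios$pref, ratio_null = ratios$null,
    ratio_blank = ratios$blank,
    ratio_null_vs_1 = sign_test(ratios$null, 1),
    ratio_pref_gt_null = mean(ratios$pref > ratios$null),
    contrib_nonlin = vapply(contrib, `[[`, numeric(1), "contrib_nonlin"),
    contrib_gain = vapply(contrib, `[[`, numeric(1), "contrib_gain"),
    adj_r2_modelI = vapply(probes, function(p) p$fitI$adj_r2, numeric(1)),
    adj_r2_modelII = vapply(probes, function(p) p$fitII$adj_r2, numeric(1)),
    gc_contrasts = gc_contrasts)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$sites)) {
    utils::write.csv(report$sites, file.path(out_dir, "sites.csv"),
                     row.names = FALSE)
    utils::write.csv(report$sites[c("probe_id", "site_id", "relative_depth",
                                    "layer", "group")],
                     file.path(out_dir, "layers.csv"), row.names = FALSE)
  }
  fits <- lapply(report$probes, function(p) list(
    probe_id = p$table_id,
    modelI = fit_to_list(p$fitI), modelII = fit_to_list(p$fitII),
    dsi_input = p$dsi_input, dsi_output = p$dsi_output))
  jsonlite::write_json(fits, file.path(out_dir, "gainfits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  gc_list <- lapply(report$probes, function(p)
    if (is.null(p$gc)) NULL else list(order = p$gc$order, gc = p$gc$gc))
  jsonlite::write_json(list(per_probe = gc_list,
                            contrasts = report$population$gc_contrasts),
                       file.path(out_dir, "gc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(render_report(report), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

fit_to_list <- function(f) {
  list(model = f$model, family = f$family, w = as.list(f$w),
       nonlinearity = f$nonlinearity, J = f$J, adj_r2 = f$adj_r2,
       aic = f$aic, bic = f$bic, n_param = f$n_param,
       dsi_of_gain = f$dsi_of_gain, dsi_of_output = f$dsi_of_output)
}

render_report <- function(report) {
  p <- report$population
  lines <- c(
    "# Laminar direction-selectivity pipeline report", "",
    sprintf("seed: %d; probes: %d", report$seed, length(report$probes)), "")
  if (!is.null(report$failed_stage)) {
    return(c(lines, sprintf("**FAILED**: %s", report$failed_stage)))
  }
  fmt <- function(x) sprintf("%.4g", x)
  c(lines,
    "## Interlaminar DSI",
    sprintf("- output-layer median DSI: %s (per-probe medians)",
            fmt(stats::median(p$dsi_output_medians))),
    sprintf("- input-layer median DSI: %s", fmt(stats::median(p$dsi_input_medians))),
    sprintf("- paired comparison: p = %s (%s)", fmt(p$dsi_compare$p_value),
            p$dsi_compare$test),
    sprintf("- median DSI enhancement (out-in)/in: %s", fmt(p$dsi_enhancement)),
    "",
    "## Response ratio (output/input)",
    sprintf("- preferred: median %s; null: median %s; blank: median %s",
            fmt(stats::median(p$ratio_pref)), fmt(stats::median(p$ratio_null)),
            fmt(stats::median(p$ratio_blank))),
    sprintf("- ratio(null) vs 1: sign test p = %s", fmt(p$ratio_null_vs_1$p_value)),
    sprintf("- fraction of probes with ratio(pref) > ratio(null): %s",
            fmt(p$ratio_pref_gt_null)),
    "",
    "## Gain models",
    sprintf("- adjR2 Model I (median): %s; Model II (median): %s",
            fmt(stats::median(p$adj_r2_modelI)),
            fmt(stats::median(p$adj_r2_modelII))),
    sprintf("- probes passing the adjR2 > %s gate: %d / %d",
            fmt(report$config$adj_r2_gate), p$n_gated, p$n_probes),
    sprintf("- contribution of nonlinearity (median): %s",
            fmt(stats::median(p$contrib_nonlin))),
    sprintf("- contribution of tuned gain (median): %s",
            fmt(stats::median(p$contrib_gain))),
    "",
    "## GC contrasts",
    if (is.null(p$gc_contrasts)) "- (not run)" else c(
      sprintf("- pref vs blank, largest median difference: %s",
              p$gc_contrasts$pref_vs_blank$pair[
                which.max(p$gc_contrasts$pref_vs_blank$median_diff)]),
      sprintf("- null vs blank, largest median difference: %s",
              p$gc_contrasts$null_vs_blank$pair[
                which.max(p$gc_contrasts$null_vs_blank$median_diff)])))
}
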