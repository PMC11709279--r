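#' Trial-resolved laminar response table
#'
#' The container holding one probe placement: per-site relative depth, the
#' stimulus conditions (drifting-grating directions in degrees plus the
#' reserved \code{"blank"} condition), time-averaged rates per
#' (site, condition, repetition), and optionally the rate time courses
#' (PSTHs) at a fixed bin width.
#'
#' Trial counts may differ between conditions (blank trials are a small
#' fraction of the total); missing repetitions are \code{NA}-padded along
#' the trial dimension.
#'
#' @param probe_id character scalar identifying the probe placement.
#' @param site_ids character vector of site identifiers.
#' @param relative_depth numeric vector in \code{[0, 1]}, one per site
#'   (0 = pial border of L2/3, 1 = L6/white-matter border).
#' @param conditions character vector: directions formatted as degrees in
#'   \code{[0, 360)} (e.g. \code{"30"}) and the token \code{"blank"}.
#' @param rates numeric array \code{[site, condition, trial]} of
#'   time-averaged rates in spikes/s; unused trial slots are \code{NA}.
#' @param psth optional numeric array \code{[site, condition, trial, time]}
#'   of rate time courses (spikes/s).
#' @param psth_bin_ms PSTH bin width in ms (default 2, i.e. 500 Hz).
#' @param psth_t0_ms time of the first PSTH bin relative to stimulus onset
#'   (ms, typically negative so a pre-stimulus baseline is present).
#' @param area_label cortical area, e.g. \code{"A17"} or \code{"A18"}.
#' @param stimulus_meta named list of stimulus parameters kept for record
#'   (contrast, spatial/temporal frequency, duration).
#' @return an object of class \code{trial_response_table}.
#' @export
trial_response_table <- function(probe_id, site_ids, relative_depth,
                                 conditions, rates, psth = NULL,
                                 psth_bin_ms = 2, psth_t0_ms = 0,
                                 area_label = "A17",
                                 stimulus_meta = list()) {
  tab <- structure(list(
    probe_id = as.character(probe_id),
    site_ids = as.character(site_ids),
    relative_depth = as.numeric(relative_depth),
    conditions = as.character(conditions),
    rates = rates,
    psth = psth,
    psth_bin_ms = psth_bin_ms,
    psth_t0_ms = psth_t0_ms,
    area_label = as.character(area_label),
    stimulus_meta = stimulus_meta
  ), class = "trial_response_table")
  validate_trial_table(tab)
}

#' Validate a trial response table
#'
#' Checks the structural invariants: blank condition present, directions
#' distinct modulo 360, every site has at least one trial per condition,
#' consistent array shapes.
#'
#' @param tab a [trial_response_table()].
#' @return the table, invisibly validated (errors on violation).
#' @export
validate_trial_table <- function(tab) {
  if (!inherits(tab, "trial_response_table"))
    stopf("format_error", "not a trial_response_table")
  req <- c("probe_id", "site_ids", "relative_depth", "conditions", "rates")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stopf("format_error", "missing field(s): %s", paste(miss, collapse = ", "))
  ns <- length(tab$site_ids)
  if (length(tab$relative_depth) != ns)
    stopf("format_error", "relative_depth length != number of sites")
  if (any(tab$relative_depth < 0 | tab$relative_depth > 1))
    stopf("validation_error", "relative_depth outside [0,1]")
  if (!(BLANK %in% tab$conditions))
    stopf("integrity_error", "blank condition missing")
  dirs <- condition_directions(tab)
  dd <- dirs[!is.na(dirs)] %% 360
  if (anyDuplicated(dd))
    stopf("integrity_error", "duplicate directions modulo 360")
  if (anyDuplicated(tab$conditions))
    stopf("integrity_error", "duplicate conditions")
  dm <- dim(tab$rates)
  if (length(dm) != 3 || dm[1] != ns || dm[2] != length(tab$conditions))
    stopf("format_error", "rates must be [site x condition x trial]")
  ntr <- apply(!is.na(tab$rates), c(1, 2), sum)
  if (any(ntr < 1))
    stopf("integrity_error", "every site needs >= 1 trial for every condition")
  if (!is.null(tab$psth)) {
    dp <- dim(tab$psth)
    if (length(dp) != 4 || !all(dp[1:3] == dm))
      stopf("format_error", "psth must be [site x condition x trial x time]")
  }
  invisible(tab)
}

#' @export
print.trial_response_table <- function(x, ...) {
  nd <- sum(!is.na(condition_directions(x)))
  cat(sprintf(
    "trial_response_table '%s' (%s): %d sites, %d directions + blank, up to %d trials%s\n",
    x$probe_id, x$area_label, length(x$site_ids), nd, dim(x$rates)[3],
    if (is.null(x$psth)) "" else sprintf(", PSTH %g ms bins", x$psth_bin_ms)))
  invisible(x)
}

#' Numeric directions of a table's conditions
#'
#' @param tab a [trial_response_table()].
#' @return numeric vector of directions in degrees, \code{NA} at the blank
#'   condition.
#' @export
condition_directions <- function(tab) {
  suppressWarnings(ifelse(tab$conditions == BLANK, NA_real_,
                          as.numeric(tab$conditions)))
}

#' PSTH time axis in ms relative to stimulus onset
#' @param tab a [trial_response_table()] with PSTHs.
#' @return numeric vector of bin-center times (ms).
#' @export
psth_times <- function(tab) {
  if (is.null(tab$psth)) stopf("format_error", "table has no PSTHs")
  tab$psth_t0_ms + (seq_len(dim(tab$psth)[4]) - 1) * tab$psth_bin_ms
}

#' Per-condition mean rates for one site
#' @param tab a [trial_response_table()].
#' @param site site id or index.
#' @return named numeric vector, one mean rate per condition.
#' @export
site_mean_rates <- function(tab, site) {
  i <- site_index(tab, site)
  m <- apply(tab$rates[i, , , drop = FALSE], 2, mean, na.rm = TRUE)
  names(m) <- tab$conditions
  m
}

site_index <- function(tab, site) {
  if (is.character(site)) {
    i <- match(site, tab$site_ids)
    if (is.na(i)) stopf("validation_error", "unknown site '%s'", site)
    i
  } else as.integer(site)
}

# ---------------------------------------------------------------------------
# On-disk formats

#' Write a trial response table
#'
#' Two dialects: \code{"csv"} is a long table with header
#' \code{probe_id,site_id,relative_depth,condition,trial,rate} (probe-level
#' metadata in \code{#}-prefixed header comments; PSTHs are not
#' representable); \code{"hdf5"} stores \code{/sites}, \code{/conditions},
#' \code{/rates} and optionally \code{/psth} plus JSON-encoded metadata,
#' and round-trips bit-exactly.
#'
#' @param tab a [trial_response_table()].
#' @param path output file path.
#' @param dialect \code{"hdf5"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
write_trial_table <- function(tab, path, dialect = c("hdf5", "csv")) {
  dialect <- match.arg(dialect)
  validate_trial_table(tab)
  if (dialect == "csv") write_trial_table_csv(tab, path)
  else write_trial_table_h5(tab, path)
  invisible(path)
}

#' Read a trial response table
#'
#' @param path file path written by [write_trial_table()].
#' @param dialect \code{"hdf5"} or \code{"csv"}.
#' @return a validated [trial_response_table()].
#' @export
read_trial_table <- function(path, dialect = c("hdf5", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("format_error", "no such file: %s", path)
  tab <- if (dialect == "csv") read_trial_table_csv(path)
  else read_trial_table_h5(path)
  validate_trial_table(tab)
}

write_trial_table_csv <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(area_label = tab$area_label, stimulus_meta = tab$stimulus_meta)
  writeLines(sprintf("# meta: %s",
                     jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             con)
  dm <- dim(tab$rates)
  idx <- which(!is.na(tab$rates), arr.ind = TRUE)
  df <- data.frame(
    probe_id = tab$probe_id,
    site_id = tab$site_ids[idx[, 1]],
    relative_depth = tab$relative_depth[idx[, 1]],
    condition = tab$conditions[idx[, 2]],
    trial = idx[, 3],
    rate = tab$rates[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(match(df$site_id, tab$site_ids),
                 match(df$condition, tab$conditions), df$trial), ]
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_trial_table_csv <- function(path) {
  first <- readLines(path, n = 1)
  meta <- list(area_label = "A17", stimulus_meta = list())
  if (startsWith(first, "# meta: "))
    meta <- jsonlite::fromJSON(sub("^# meta: ", "", first),
                               simplifyVector = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("probe_id", "site_id", "relative_depth", "condition", "trial", "rate")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("format_error", "CSV missing column(s): %s",
          paste(miss, collapse = ", "))
  for (col in c("relative_depth", "rate")) df[[col]] <- as.numeric(df[[col]])
  df$trial <- as.integer(df$trial)
  if (anyDuplicated(df[c("site_id", "condition", "trial")]))
    stopf("integrity_error", "duplicate (site, condition, trial) keys")
  site_ids <- unique(df$site_id)
  conds <- unique(df$condition)
  dirs <- suppressWarnings(as.numeric(conds[conds != BLANK]))
  conds <- c(as.character(sort(dirs)), if (BLANK %in% conds) BLANK)
  ntr <- max(df$trial)
  rates <- array(NA_real_, c(length(site_ids), length(conds), ntr))
  rates[cbind(match(df$site_id, site_ids),
              match(df$condition, conds), df$trial)] <- df$rate
  depth <- df$relative_depth[match(site_ids, df$site_id)]
  trial_response_table(
    probe_id = df$probe_id[1], site_ids = site_ids, relative_depth = depth,
    conditions = conds, rates = rates,
    area_label = meta$area_label,
    stimulus_meta = as.list(meta$stimulus_meta))
}

write_trial_table_h5 <- function(tab, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll())
  rhdf5::h5createGroup(path, "sites")
  rhdf5::h5write(tab$site_ids, path, "sites/id")
  rhdf5::h5write(tab$relative_depth, path, "sites/relative_depth")
  rhdf5::h5write(tab$conditions, path, "conditions")
  rhdf5::h5write(tab$rates, path, "rates")
  if (!is.null(tab$psth)) rhdf5::h5write(tab$psth, path, "psth")
  meta <- list(probe_id = tab$probe_id, area_label = tab$area_label,
               psth_bin_ms = tab$psth_bin_ms, psth_t0_ms = tab$psth_t0_ms,
               stimulus_meta = tab$stimulus_meta)
  rhdf5::h5write(as.character(
    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)), path, "meta")
}

read_trial_table_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll())
  nm <- rhdf5::h5ls(path)$name
  for (req in c("rates", "conditions", "meta"))
    if (!(req %in% nm)) stopf("format_error", "HDF5 missing '%s'", req)
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, "meta"))
  psth <- if ("psth" %in% nm) rhdf5::h5read(path, "psth") else NULL
  trial_response_table(
    probe_id = meta$probe_id,
    site_ids = as.character(rhdf5::h5read(path, "sites/id")),
    relative_depth = as.numeric(rhdf5::h5read(path, "sites/relative_depth")),
    conditions = as.character(rhdf5::h5read(path, "conditions")),
    rates = rhdf5::h5read(path, "rates"),
    psth = psth,
    psth_bin_ms = meta$psth_bin_ms, psth_t0_ms = meta$psth_t0_ms,
    area_label = meta$area_label,
    stimulus_meta = as.list(meta$stimulus_meta))
}

# ---------------------------------------------------------------------------
# SNR screening

#' Response signal-to-noise ratio of a recording site
#'
#' SNR is the largest across-directions variance of the trial-averaged
#' PSTH over the analysis window, divided by the same variance for the
#' blank condition: \code{SNR = max_theta Var(R(theta, T)) / Var(R(blank, T))},
#' with \code{T} the 0–200 ms post-onset window by default. Sites pass at
#' a strict \code{SNR > 8}.
#'
#' @param tab a [trial_response_table()] with PSTHs.
#' @param site site id or index.
#' @param window_ms analysis window (ms after stimulus onset), default
#'   \code{c(0, 200)}.
#' @param threshold pass threshold (strict inequality), default 8.
#' @return a list of class \code{snr_result} with \code{snr},
#'   \code{var_by_condition}, \code{var_blank} and \code{passes}.
#' @export
compute_snr <- function(tab, site, window_ms = c(0, 200), threshold = 8) {
  if (is.null(tab$psth)) stopf("format_error", "PSTHs required for SNR")
  i <- site_index(tab, site)
  tt <- psth_times(tab)
  if (window_ms[1] < min(tt) - tab$psth_bin_ms / 2 ||
      window_ms[2] > max(tt) + tab$psth_bin_ms / 2)
    stopf("validation_error", "window outside recorded span")
  sel <- tt >= window_ms[1] & tt <= window_ms[2]
  ## trial-average first, then variance over time bins
  cond_var <- vapply(seq_along(tab$conditions), function(k) {
    m <- apply(tab$psth[i, k, , sel, drop = FALSE], 4, mean, na.rm = TRUE)
    stats::var(m)
  }, numeric(1))
  names(cond_var) <- tab$conditions
  vb <- cond_var[[BLANK]]
  if (!is.finite(vb) || vb <= 0)
    stopf("undefined_snr", "blank-condition variance is zero for site %s",
          tab$site_ids[i])
  vdir <- cond_var[tab$conditions != BLANK]
  snr <- max(vdir) / vb
  structure(list(snr = snr, var_by_condition = vdir, var_blank = vb,
                 passes = snr > threshold, threshold = threshold),
            class = "snr_result")
}

#' Screen recording sites by SNR
#'
#' Keeps only sites whose SNR strictly exceeds \code{threshold}; sites
#' with undefined SNR (zero blank variance) are excluded with a recorded
#' reason. Survivors are ordered by relative depth, ascending.
#'
#' @param tab a [trial_response_table()] with PSTHs.
#' @param threshold SNR threshold (strict), default 8.
#' @param window_ms analysis window in ms, default \code{c(0, 200)}.
#' @return data frame with columns \code{site_id}, \code{relative_depth},
#'   \code{snr}; one row per surviving site. Attribute \code{"excluded"}
#'   lists dropped sites and reasons. Empty survivor set raises a warning,
#'   not an error.
#' @export
screen_sites <- function(tab, threshold = 8, window_ms = c(0, 200)) {
  rows <- lapply(seq_along(tab$site_ids), function(i) {
    res <- tryCatch(compute_snr(tab, i, window_ms, threshold),
                    undefined_snr = function(e) e)
    if (inherits(res, "condition"))
      return(list(site_id = tab$site_ids[i], keep = FALSE,
                  reason = conditionMessage(res), snr = NA_real_))
    list(site_id = tab$site_ids[i], keep = res$snr > threshold,
         reason = if (res$snr > threshold) NA_character_ else
           sprintf("snr %.3g <= %g", res$snr, threshold),
         snr = res$snr)
  })
  keep <- vapply(rows, `[[`, logical(1), "keep")
  out <- data.frame(
    site_id = vapply(rows[keep], `[[`, character(1), "site_id"),
    relative_depth = tab$relative_depth[keep],
    snr = vapply(rows[keep], `[[`, numeric(1), "snr"),
    stringsAsFactors = FALSE)
  out <- out[order(out$relative_depth), , drop = FALSE]
  rownames(out) <- NULL
  excl <- data.frame(
    site_id = vapply(rows[!keep], `[[`, character(1), "site_id"),
    reason = vapply(rows[!keep], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  if (nrow(out) == 0) warning("no site passed the SNR screen")
  out
}
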