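# Small fixtures built in code.

## Minimal table: explicit rates, no PSTH.
tiny_table <- function(n_sites = 2, dirs = c(0, 120, 240), n_trials = 2,
                       seed = 99) {
  conds <- c(as.character(dirs), "blank")
  rates <- with_seed(seed, array(round(runif(n_sites * length(conds) *
                                               n_trials, 1, 40), 3),
                                 c(n_sites, length(conds), n_trials)))
  trial_response_table(
    probe_id = "tiny", site_ids = sprintf("s%d", seq_len(n_sites)),
    relative_depth = seq(0.1, 0.9, length.out = n_sites),
    conditions = conds, rates = rates,
    stimulus_meta = list(tf_hz = 2))
}

## Table with hand-built PSTHs so SNR is exactly controllable.
## Each condition's trial-averaged PSTH is given directly (one trial).
psth_table <- function(psth_by_cond, dirs, bin_ms = 2, t0_ms = 0) {
  conds <- c(as.character(dirs), "blank")
  stopifnot(length(psth_by_cond) == length(conds))
  nt <- length(psth_by_cond[[1]])
  psth <- array(NA_real_, c(1, length(conds), 1, nt))
  rates <- array(NA_real_, c(1, length(conds), 1))
  for (k in seq_along(conds)) {
    psth[1, k, 1, ] <- psth_by_cond[[k]]
    rates[1, k, 1] <- mean(psth_by_cond[[k]])
  }
  trial_response_table(
    probe_id = "psth", site_ids = "s1", relative_depth = 0.5,
    conditions = conds, rates = rates, psth = psth,
    psth_bin_ms = bin_ms, psth_t0_ms = t0_ms)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

input_site_ids <- function(sim) names(sim$site_role)[sim$site_role == "input"]
output_site_ids <- function(sim) names(sim$site_role)[sim$site_role == "output"]
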