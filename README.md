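# lamigain

Laminar analysis of direction selectivity in early visual cortex: tuning
curves, selectivity indices, interlaminar gain-transmission models, and
directed connectivity — for electrophysiologists working with
multielectrode linear-probe recordings, and for modelers who need a
tested reference implementation of the analysis chain.

## The problem

In a cortical column of carnivore early visual cortex, the
thalamorecipient **input layers** (L4, L6) drive the **output layers**
(L2/3, L5). Direction selectivity — quantified per recording site by

    DSI = (R_pref − R_null) / (R_pref + R_null)

with responses taken from a fitted double von Mises direction tuning
curve — is stronger in the output layers. `lamigain` asks *why*, by
fitting the interlaminar transmission model

    R_out,i(S) = f( w(S) · R_in,i(S) )

to repetition-resolved, layer-averaged rates, where `w(S)` is a linear
gain per stimulus condition `S` (gratings of varying direction, plus a
blank) and `f` is a static nonlinearity — by default the
Gaussian-smoothed threshold-linear function

    f(g) = (A(g−g₀)/2)(1 + erf((g−g₀)/(√2σ))) + (Aσ/√(2π)) exp(−(g−g₀)²/(2σ²)).

Four nested variants are compared (untuned vs tuned gain; tuned gain vs
tuned subtractive suppression under a hard rectifier) via adjusted R²,
AIC and BIC, and the DSI gap between layers is decomposed into the share
explained by the nonlinearity alone and the share requiring gain
tuning. Pairwise-conditional Granger causality between layer-resolved
signals (VAR least squares, built from first principles) locates the
condition-dependent connections behind the tuned gain.

All estimators are exercised on a synthetic laminar probe generator with
known ground truth (von Mises input tuning, tuned gain, planted
condition-dependent interlaminar coupling, latency gradients, trial
noise), so the whole pipeline is testable offline.

## Worked example

```r
library(lamigain)

truth <- make_ground_truth(seed = 1)            # tuned gain, gain-DSI 0.3
sim   <- simulate_probe(truth, n_input_sites = 6, n_output_sites = 6, seed = 1)

survivors <- screen_sites(sim$table)            # SNR > 8, strict
head(survivors, 3)
#>   site_id relative_depth      snr
#> 1  site01          0.050 754.1086
#> 2  site02          0.175 841.2945
#> 3  site03          0.300 707.3049

site_tuning_summary(sim$table, "site01")$dsi    # an output-layer site
#> [1] 0.6008721

rin  <- layer_average_rates(sim$table, names(sim$site_role)[sim$site_role == "input"])
rout <- layer_average_rates(sim$table, names(sim$site_role)[sim$site_role == "output"])
fit  <- fit_gain_model(rin, rout, sim$table$conditions, model = "II")
fit$adj_r2                                      # 0.9826
round(fit$w, 3)
#>     0    30    60    90   120   150   180   210   240   270   300   330 blank
#> 0.980 1.085 1.218 1.246 1.198 1.065 0.920 0.898 0.834 0.793 0.867 0.896 0.664
```

The fitted gain curve peaks at the columnar preferred direction (90°),
exceeds its null-direction value (270°), and is lowest under the blank —
the direction-tuned gain signature. At single-probe noise levels the
fitted gain-DSI (0.22 here) scatters around the generated value of 0.30;
across 20 seeded probes the median absolute error is about 0.03 (see the
acceptance script below).

The full pipeline — screening, tuning, layer assignment, model fits,
response ratios, GC contrasts, population statistics — runs with

```r
report <- run_pipeline(list(n_probes = 4), seed = 1, out_dir = "results")
```

writing `sites.csv`, `layers.csv`, `gainfits.json`, `gc.json` and a
human-readable `report.md`.

## Layout

- `R/` — data model and IO (`trial_response_table`, HDF5/CSV, SNR
  screening), synthetic generator, tuning fits, laminar tools (latency,
  layers, CSD, probe QC), gain models, Granger causality, statistics and
  pipeline.
- `tests/testthat/` — unit, property and acceptance tests (all fixtures
  generated in code).
- `vignettes/laminar-gain-analysis.Rmd` — the methods vignette: model
  definitions, parameter conventions, generator design, numerical
  choices, limitations.
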