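---
title: "Laminar direction selectivity and interlaminar gain transmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar direction selectivity and interlaminar gain transmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamigain)
```

## The scientific problem

In the early visual cortex of carnivores, signals ascend through the
laminar circuit of a cortical column: the thalamorecipient *input layers*
(L4 and L6) project to the *output layers* (L2/3 and L5), which relay
onward. Direction selectivity — a stronger response to a grating drifting
in one direction than in the opposite direction — is present in all
layers, and the question `lamigain` addresses quantitatively is how that
selectivity is transformed between the two stages: is it merely
inherited, or is it actively sharpened by the interlaminar transmission?

The package implements the full analysis chain for multielectrode
laminar recordings of multi-unit activity (MUA): quality control and
screening, tuning-curve fitting and selectivity indices, layer
assignment, four competing transmission models with model comparison, a
decomposition of where selectivity enhancement comes from, and
directed-connectivity estimates between layer-resolved signals. Every
stage is exercised on a synthetic probe generator with known ground
truth, so each estimator's recovery properties are testable without any
recorded data.

## Data model and screening

A probe placement is held in a `trial_response_table`: per-site relative
cortical depth in $[0, 1]$, stimulus conditions (directions in degrees
plus a reserved blank condition), time-averaged rates per (site,
condition, repetition), and optionally rate time courses (PSTHs) at a
fixed 2 ms bin width. Blank trials are a minority of the total (the
generator default is 10%), so trial counts differ between conditions and
the trial dimension is NA-padded. Two on-disk dialects are supported:
HDF5 (lossless, includes PSTHs) and a long-format CSV (rates only).

Sites are screened by a response signal-to-noise ratio
$$\mathrm{SNR} = \frac{\max_\theta \mathrm{Var}_T\, R(\theta, T)}
{\mathrm{Var}_T\, R(\mathrm{blank}, T)},$$
where the variance is taken over the time bins of the *trial-averaged*
PSTH in the 0–200 ms post-onset window. Only sites with SNR strictly
greater than 8 enter the analysis. Both variances use the same estimator
(denominator $n-1$), which cancels in the ratio; the SNR is invariant to
adding a constant to all PSTHs and to rescaling all rates by a common
factor.

## Tuning curves and selectivity indices

Direction tuning of the time-averaged rate is fitted with a double von
Mises curve,
$$R(\theta) = \alpha\,\frac{e^{\sigma_1 \cos(\theta - \theta_{pref})} - e^{-\sigma_1}}
{e^{\sigma_1} - e^{-\sigma_1}}
+ \beta\,\frac{e^{\sigma_2 \cos(\theta - \theta_{null})} - e^{-\sigma_2}}
{e^{\sigma_2} - e^{-\sigma_2}} + R_0,$$
with the null direction constrained to $\theta_{pref} + 180°$. Each lobe
is normalized to peak at 1, so $R(\theta_{pref}) = \alpha + R_0$ and
$R(\theta_{null}) = \beta + R_0$. Fitting is bounded local least squares
(`optim`, L-BFGS-B) from the standard initial guesses — preferred
direction at the response argmax (lowest index on ties), $\sigma_1 =
\sigma_2 = 1$, amplitudes at max − min, offset at the minimum — plus a
second start with the two lobes swapped to guard against label
switching. Bounds are $\sigma \in (10^{-3}, 50]$, $\alpha, \beta \ge 0$.

The direction selectivity index is computed from the fitted curve,
$$\mathrm{DSI} = \frac{R(\theta_{pref}) - R(\theta_{null})}
{R(\theta_{pref}) + R(\theta_{null})},$$
so DSI $= 1/3$ exactly when the preferred response is twice the null
response. Responses are *not* blank-subtracted before fitting (the blank
rate is kept as a separate reference), a negative offset is permitted,
and the DSI requires $R_{pref} + R_{null} > 0$. A raw-response DSI can
be formed by passing raw rates to `compute_dsi()` directly; the
fitted-curve version is the default because the fit interpolates between
the sampled directions and denoises the two responses consistently.

Orientation tuning uses the single-lobe analogue on the doubled angle
(period 180°), yielding the OSI, the orthogonal-to-preferred response
ratio, and the half-width at half-height, which has the closed form
$\mathrm{HWHH} = \tfrac12 \arccos\!\big(1 + \log((1 + e^{-2\sigma_1})/2)/\sigma_1\big)$
for the normalized lobe. The modulation ratio F1/F0 is the amplitude of
the Fourier component of the trial-averaged response at the stimulus
drift frequency over the mean rate; a half-wave-rectified sinusoid gives
exactly $\pi/2$.

## Layer assignment and latency

Relative depth 0 marks the pial border of L2/3 and 1 the L6/white-matter
border. Layers are assigned by three depth boundaries — 0.35, 0.58, 0.76
— with a lower-closed/upper-open convention (a site exactly at a
boundary belongs to the deeper layer; the convention is a package choice
since depth values rarely tie in practice). Response latency is the
first post-onset time at which the baseline-subtracted PSTH reaches half
of its post-onset maximum, linearly interpolated between bins; the
maximum is searched within 0–200 ms so late rebound peaks cannot shift
it. The CSD helper is the standard negative second spatial difference
across equally spaced contacts, and probe perpendicularity QC summarizes
the dispersion of receptive-field centers (relative to twice the
geometric mean of the RF radii) and the modulus of the mean doubled-angle
orientation phasor.

## The interlaminar gain models

The core of the package is a two-stage transmission model from the
repetition-resolved, layer-averaged input rate $R_{in,i}(S)$ to the
output rate: a linear gain followed by a static nonlinearity,
$$\hat R_{out,i}(S) = f\!\big(w(S)\, R_{in,i}(S)\big).$$

* **Model I** (untuned gain): one shared $w$ for all conditions
  including blank.
* **Model II** (tuned gain): one $w(S)$ per condition.
* **Model III**: tuned gain, shared subtractive suppression, hard
  rectifier: $\hat R = [\,w(S) R_{in} - T\,]_+$.
* **Model IV**: shared gain, tuned suppression: $\hat R = [\,w R_{in} -
  T(S)\,]_+$.

The default nonlinearity for Models I/II is the Gaussian-smoothed
threshold-linear function
$$f(g) = \frac{A (g - g_0)}{2}\Big(1 + \mathrm{erf}\,\frac{g - g_0}{\sqrt 2 \sigma}\Big)
+ \frac{A \sigma}{\sqrt{2\pi}} e^{-(g - g_0)^2 / 2\sigma^2},$$
which equals the expectation of $A\,[g + \varepsilon - g_0]_+$ under
Gaussian noise $\varepsilon$ and converges to $A\,[g - g_0]_+$ as
$\sigma \to 0$; a power law $A [g - g_0]_+^n$ is available as an
alternative.

Fitting minimizes $J = \sum_S \sum_i (\hat R_{out,i}(S) -
R_{out,i}(S))^2$. Because each per-condition gain enters only its own
condition's residual, the gains are *profiled out* by inner
one-dimensional optimization, leaving only the shared nonlinearity
parameters to a bounded multi-start outer search (10 seeded restarts by
default; bounds $A \in (0, 100]$, $g_0 \in [-r_{max}, r_{max}]$,
$\sigma \in (10^{-3}, r_{max}]$, $n \in (0.5, 5]$). This nested scheme
is deterministic given the seed and, on data generated by the model
itself, recovers the gain curve to numerical precision.

Gain scale is not identified in Models I/II — $(w, g_0, \sigma, A)
\mapsto (cw, cg_0, c\sigma, A/c)$ leaves every prediction unchanged — so
after fitting, gains are renormalized to mean 1 over grating conditions
(a prediction-invariant reparameterization) and the free-parameter count
is reduced by one. Model comparison uses the parameter-penalized
agreement
$$adjR^2 = 1 - \frac{N - 1}{N - N_{param}}\,
\frac{2\sum(\hat R - R)^2}{\sum(\hat R - \bar{\hat R})^2 + \sum(R - \bar R)^2},$$
which is exactly 1 for a perfect fit, together with
$\mathrm{AIC} = N \ln(J/N) + 2 N_{param}$ and BIC with a $\ln N$
penalty. Since Model I is a constrained Model II, $J_{II} \le J_{I}$
always; a fit violating this would indicate an optimizer failure and is
asserted in the test suite. Blank and grating samples carry equal weight
in $J$, one term per (condition, repetition).

Population summaries gate probes on $adjR^2(\text{Model II}) > 0.8$.
The enhancement decomposition then splits the output-minus-input DSI gap
into the share reproduced with an untuned gain (nonlinearity alone,
$(\mathrm{DSI}_{I} - \mathrm{DSI}_{in})/(\mathrm{DSI}_{out} -
\mathrm{DSI}_{in})$) and the additional share from gain tuning
($(\mathrm{DSI}_{II} - \mathrm{DSI}_{I})/(\mathrm{DSI}_{out} -
\mathrm{DSI}_{in})$); the two add to $(\mathrm{DSI}_{II} -
\mathrm{DSI}_{in})/(\mathrm{DSI}_{out} - \mathrm{DSI}_{in})$ by
construction.

## Directed connectivity

Pairwise-conditional Granger causality is computed from first
principles: least-squares vector autoregression on demeaned layer
signals (lag order by AIC, default search up to 20; lags never cross
trial boundaries), then for each directed pair
$$GC(\mathrm{to} \leftarrow \mathrm{from} \mid \mathrm{rest}) =
\ln \frac{\sigma^2_{reduced}}{\sigma^2_{full}},$$
the log ratio of the target's residual variance with the source channel
excluded versus included, all remaining channels kept in both models.
Conditioning on the remaining channels removes the spurious dependence a
persistent common driver induces between its targets. Small negative
estimates (possible in finite samples) are clamped to zero and flagged.
GC values are z-scored over all (condition, layer-pair) entries of one
probe placement before condition contrasts, which use paired Wilcoxon
tests with Bonferroni correction by the number of layer pairs compared
(e.g. 16 for a full 4 × 4 grid).

For condition-resolved GC the pipeline averages PSTHs across the sites
of each layer and pools the lagged regressions across trials of one
condition (per-trial demeaning, lags built within trials). Pooled least
squares was preferred over averaging per-trial coefficient estimates
because single trials are short relative to the channel × lag count and
per-trial fits would be noisy or rank-deficient; both approaches
estimate the same stationary model.

## The statistical battery

Probe-level comparisons use the median across sites within each layer
group of a probe placement as the unit of analysis: Wilcoxon signed-rank
for paired groups, rank-sum for independent groups, both two-sided, with
the SEM of a median estimated by a seeded bootstrap (1000 resamples; the
choice of estimator only affects error bars, never p-values). Proportions
are compared with an uncorrected 2 × 2 chi-square, correlations with
Spearman's rank coefficient, and deviations of a ratio from a reference
with an exact two-sided sign test. Bonferroni correction is applied only
where families of comparisons arise (GC contrasts); elsewhere p-values
are reported uncorrected. Under a true null the paired comparison holds
its nominal 5% size (checked at 400 seeded replicates against a 7%
ceiling).

## What the synthetic generator emulates — and what it does not

`make_ground_truth()` fixes the study conditions: 12 equally spaced
directions (6–72 supported), 10 repetitions (2–100), 10% blank trials, a
columnar preferred direction shared by all sites, input-layer von Mises
tuning with DSI 0.25 (α = 25, β = 13, R₀ = 5 spikes/s), a tuned
transmission gain with target gain-DSI 0.3 — the two-point construction
$w(\theta) = w_0 (1 + k\, b(\theta))$ with $k = 2d/(1-d)$ hits the
target exactly — a blank gain of 0.8 relative to the mean grating gain,
nonlinearity $(A, g_0, \sigma) = (1, 4, 3)$, and response latencies of
38.6 ms (input layers) versus 51.8 ms (output layers). Trial noise is
Gaussian with a standard deviation proportional to the square root of the
mean (scale 1), reflecting the Poisson-like variance scaling of rate
estimates; proportional-to-mean and Poisson options exist. PSTHs rise
logistically (time constant 4 ms) with the half-maximum crossing at the
layer latency — the latency estimator defines latency *only* through the
half-max rule, so the rise shape is a free choice.

Output-layer trials are generated causally from the repetition-resolved
input-layer average, $R_{out,i} = f(w(S)\, \bar R_{in,i}) +
\text{noise}$, so the transmission model the gain fits estimate is
literally present in the data, repetition pairing included. PSTH bin
noise is, by default, driven by a condition-dependent VAR(1) process
across layers with planted edges (L4→L2/3 and L4→L5 grow from blank to
null to preferred; L2/3→L5 switches on near the preferred direction), so
directed-connectivity analysis also has a known truth.

Passing tests on this generator demonstrate estimator correctness —
forward-model self-consistency, parameter recovery at realistic noise,
calibrated test size — not fidelity to every property of cortical data.
Real MUA has slow nonstationarities, correlated trial-to-trial
variability within layers, tuning-width diversity, and non-columnar
scatter of preferred directions, none of which the generator emulates;
conclusions about recorded data still require the recorded data.

## Numerical choices and degenerate inputs

Angles are degrees at every interface and radians internally; the von
Mises basis is evaluated relative to $e^{\sigma}$ so concentrations up
to the bound of 50 cannot overflow. Zero blank-condition variance makes
the SNR undefined: such sites are excluded with a recorded reason rather
than propagating NaN. An all-zero input layer is rejected as degenerate
before gain fitting. In `screen_sites()` an empty survivor set is a
warning, not an error, so cohort loops continue. All randomized
procedures (multi-start restarts, bootstrap SEM, the generator) consume
explicit seeds and restore the caller's RNG state.

Problem sizes in the tests and the acceptance script were chosen to
probe each property at the smallest scale where it is informative:
20 seeded probes for recovery-under-noise, 50,000 samples for the VAR
closed-form check, 400 replicates for test-size calibration, and a
4-probe pipeline for the end-to-end qualitative checks.

## Worked example

```{r example, eval = FALSE}
library(lamigain)

truth <- make_ground_truth(seed = 1)
sim <- simulate_probe(truth, n_input_sites = 6, n_output_sites = 6, seed = 1)

survivors <- screen_sites(sim$table)
tuning <- site_tuning_summary(sim$table, survivors$site_id[1])
tuning$dsi

rin <- layer_average_rates(sim$table,
                           names(sim$site_role)[sim$site_role == "input"])
rout <- layer_average_rates(sim$table,
                            names(sim$site_role)[sim$site_role == "output"])
fit <- fit_gain_model(rin, rout, sim$table$conditions, model = "II")
fit$adj_r2
fit$dsi_of_gain          # compare truth$gain_dsi_realized

report <- run_pipeline(list(n_probes = 4), seed = 1, out_dir = "results")
```

## Known limitations

The gain models operate on layer-averaged signals, so heterogeneous
transmission across sites within a layer is averaged away by design.
Layer boundaries are fixed relative depths, not discovered from the CSD.
The GC stage estimates linear time-domain dependence; spectral or
state-space extensions are out of scope. The acquisition-side voltage
thresholding that produces MUA from raw extracellular signals is
upstream of this package, which starts from rates.
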