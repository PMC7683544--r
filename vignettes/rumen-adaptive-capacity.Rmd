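---
title: "Modelling rumen acid-status kinetics and adaptive-capacity scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling rumen acid-status kinetics and adaptive-capacity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumenadapt)
```

## The problem

A high-concentrate diet raises the production of volatile fatty acids in
the rumen and depresses rumen pH; below a threshold around pH 5.5–6.0 the
animal is in sub-acute ruminal acidosis (SARA), with consequences for
intake, fibre digestion and health. Animals on the same diet differ
markedly in how well they buffer this challenge, and `rumenadapt` turns
repeated post-prandial pH curves into a per-animal, quantitative phenotype
of that buffering capacity.

The design the package is built around samples each animal at 0, 1, 2, 4
and 6 h after the morning feed, on 9 days spread over 5 experimental weeks:
two pre-change days (`d1`, `d2 = d1 + 3`), four consecutive days right
after the switch to the high-concentrate diet (`d3`–`d6`), then one day per
week (`d7 = d6 + 4`, `d8 = d7 + 6`, `d9 = d8 + 7`). Weeks are W1 =
{d1, d2}, W2 = {d3–d6}, W3–W5 = {d7}, {d8}, {d9}. The calendar gap between
`d2` and `d3` is not fixed by that structure; the default schedule uses 4
days (configurable via `sampling_schedule(d3_gap = )`), and the choice only
affects the weight of the single d2→d3 scoring step.

All model fitting uses the hydrogen-ion concentration
$[\mathrm{H}^+] = 10^{-\mathrm{pH}}$ (mol/L). The pH scale is a logarithm:
means, variances and test statistics computed on it answer a different
question than the same quantities on the concentration scale, and the two
can disagree. `compare_scales()` runs the whole analysis both ways and
tabulates the discrepancy; the pH mode fits the quadratic to pH directly
and defines the amplitude as the downward deviation `v0 − min`.

## Step 1: a re-parametrised quadratic per curve

Five points per curve leave room for three parameters, so each animal-day
is summarised by $[\mathrm{H}^+](t) = a t^2 + b t + c$, estimated by
ordinary least squares (`fit_quadratic`). The model is linear in its
parameters, so OLS reaches the global optimum directly; the re-parametrised
form below is an exact transformation of that optimum, which is why no
nonlinear optimiser (and no starting-value strategy for 72 curves) is
needed.

`reparametrise()` converts $(a, b, c)$ over the closed window $[0, 6]$ h to

* `v0` — the model value at $t = 0$, the pre-feeding baseline,
* `t_peak` — the within-window argmax (the vertex $-b/2a$ when $a < 0$ and
  interior, otherwise the maximising endpoint),
* `A` — amplitude, the peak value minus `v0` (non-negative by
  construction, because the window contains $t = 0$),
* `v_last` — the model value at 6 h,
* `R` — recovery, $(\max - v_0)/(\max - v_{last}) \times 100$: 100 means
  the curve returns exactly to baseline at 6 h.

`R` has a pole as $v_{last} \to \max$, and the field also uses the bounded
complementary convention $(\max - v_{last})/(\max - v_0) \times 100$; both
are implemented (`recovery_definition = "table1"` (default) or
`"complement"`), and `R` is reported missing, with a warning, when the
curve never deviates (`A = 0`) or ends at its peak.

The inverse map (`inverse_reparametrise`) reconstructs the unique
concave-down quadratic with an interior peak from $(v_0, A, R)$:
$c = v_0$, $a = -b^2/4A$, and $b = 2A(1 + 10/\sqrt{R})/T$ over a window of
length $T$ — the root of the vertex-height/endpoint system whose peak lies
strictly inside the window. The forward–inverse round trip is exact to
machine precision and is tested over thousands of random feasible triples.

Threshold descriptors (`derive_threshold_vars`) take the acidosis threshold
θ in pH units (default 5.5; reported thresholds range to 6.0) and compute
the time above $10^{-\theta}$ analytically from the quadratic's roots, plus
the peak exceedance. Both shrink as θ rises; the Group-1 descriptors
(`v0`, `A`, `R`) are θ-free, which is the main reason they carry the
downstream analysis.

## Step 2: random-intercept mixed models

Each descriptor is strongly right-skewed, so a power transform $v^\lambda$
is selected by the Box-Cox profile likelihood on the grid
$[-2, 2]$ in steps of 0.01 (`boxcox_lambda`, backed by `MASS::boxcox`). The
plain power $v^\lambda$ is used rather than the scaled form
$(v^\lambda - 1)/\lambda$: at fixed λ they differ by a monotone affine map,
which changes no mixed-model test, and the plain power keeps values on the
conventional reporting scale. A Shapiro–Wilk screen of the raw descriptor
(`shapiro_check`) warns — it does not decide — before transformation.

The longitudinal model (`fit_mixed`) is

$$v_{ijk} = \alpha_j + G_i + \beta\,(\mathrm{days}_k \cdot 1_{j=2}) +
\varepsilon_{ijk},\qquad G_i \sim N(0, \sigma_A^2),\;
\varepsilon_{ijk} \sim N(0, \sigma^2),$$

with fixed week means $\alpha_1..\alpha_5$ (long-term response), a day
slope β counting 1–4 across the first post-change week and inert elsewhere
(short-term response), and a per-animal random intercept. Assumptions:
Gaussian intercepts and residuals on the transformed scale, homoscedastic
and serially independent residuals — no autocorrelation, random slopes or
heteroscedasticity are modelled.

Two fits are kept: REML for the reported variance components and
$\rho = \sigma_A^2/(\sigma^2+\sigma_A^2)$ (`icc`), and ML for the nested
likelihood-ratio tests (`lrt_fixed_effects`) — REML likelihoods are not
comparable across fixed-effect structures. The week test constrains the
five means to one (df = 4); the day test drops β (df = 1). χ² is clipped at
zero and is invariant to positive rescaling of the response (so the 10⁷
display scale never changes a test). In a design of 8 animals the ML tests
are mildly anti-conservative (null rejection a little above the nominal
0.05); at this sample size that is inherent to the χ² reference, and the
calibration is quantified by simulation in the test suite and the
acceptance script rather than corrected.

`posthoc_weeks` forms all ten pairwise week contrasts from the REML
fixed-effect covariance with normal-approximation z statistics — the
effective denominator df of a small mixed model is ambiguous, so no t
reference is claimed — adjusts them by Benjamini–Hochberg, and assigns a
compact letter display (insert-and-absorb algorithm; weeks sharing a letter
do not differ at adjusted p < 0.05).

`power_simulation` estimates the power of either test by simulating from
the model at a supplied truth (`simulate_mixed`) and recording the
rejection fraction with its binomial standard error. Power at the null
sits at the nominal level, and rises steeply with cohort size for a
moderate day slope (with β at a quarter of a residual SD per day the
package's own runs give roughly 35%, 70% and 94% at 8, 20 and 40 animals,
500 simulations each).

## Step 3: phase-plane scoring

For each animal the pairs $(v_0, A)$ of consecutive sampling days define a
step in the phase plane. The quadrant of the change gives the score
(`score_step`): both descriptors falling is the adaptive direction (+2),
both rising the opposite (−2); a rising baseline with a falling amplitude
still records an effort of adaptation (+1), the mirror case −1. A zero
change counts as a decrease by default (non-deterioration is credited;
configurable), which only matters when exactly one delta is zero — when
both are zero the step's weight is zero anyway.

The weight (`step_weight`) is the Euclidean displacement divided by the
calendar-day gap, so weekly steps are not over-weighted against
consecutive-day steps. The daily index is $d = s\,\omega$, and the global
index (`global_index`) sums $d$ from the d2→d3 step onward — the first
step compares two pre-change days and is excluded by default
(`include_first_step = TRUE` restores it). GI is homogeneous of degree one
under joint rescaling of the phase plane, so the ×10⁷ display convention
never changes a rank. `unweighted_global_index` sets ω ≡ 1; comparing the
two shows how much of a rank is driven by displacement magnitude rather
than direction. `score_step` and the scoring pipeline accept more than two
coordinates (all-decrease = +2, all-increase = −2, otherwise majority with
ties decided by the non-baseline coordinates), though only the
two-dimensional case is exercised by the shipped analyses.

## The synthetic cohort generator

`generate_cohort` simulates the full design with known ground truth so
every stage is testable without any data download. The generative skeleton
is the Step-2 model applied on the transformed scale of `v0` and `A`:
per-animal Gaussian intercepts, week means, optional day slope and
residuals; values are back-transformed (exponents 0.20 and 0.28 by
default), combined with a recovery percentage drawn from a truncated
normal, converted to quadratic coefficients via `inverse_reparametrise`,
evaluated at the five sampling times, and perturbed with multiplicative
lognormal noise (CV 3% by default — equivalently additive noise on pH,
matching how pH electrodes err).

Default calibration, chosen once: week means follow the qualitative
pattern of a baseline dip after the diet change and a rise in the final
week for both descriptors; variance components put the between-animal
share at 0.56 for transformed `v0` and 0.17 for transformed `A`; the
recovery distribution (mean 85, SD 10) is truncated to the feasible
interval $R > 100A/(A + (1-f)v_0)$ with a floor $f = 0.5$ on the
end-of-window concentration — post-prandial recovery is near-complete
physiologically, and the floor keeps the 6-h value within about 0.3 pH of
baseline. Under these defaults simulated pH stays within roughly 5.0–7.5
and extreme days approach the pH 5.5 acidosis threshold.

What the generator does *not* emulate: serial correlation of residuals
within a week, skewness beyond what the power transform induces,
informative missingness (drop-out is uniform and off by default),
feeding-behaviour covariates, or any feedback of acid status on subsequent
days. Passing tests on simulated cohorts therefore demonstrate that the
pipeline recovers the truth *under the model's own assumptions* — they do
not validate those assumptions against real rumen data.

## Numerical choices and degenerate inputs

* Quadratic fits require ≥3 distinct times; animal-days below the
  configurable minimum (default 4 points) are excluded with a warning.
* Exactly three points give the interpolating parabola (rss = 0); a
  rank-deficient design raises an error rather than a silent pseudo-fit.
* For non-concave fits the window endpoint maximises the curve, keeping
  `A ≥ 0` defined for every fit.
* `dur` uses strict exceedance and the Lebesgue measure of the
  above-threshold set, computed from the discriminant — tangent curves
  contribute zero duration.
* The compact letter display resolves ties deterministically; contrast
  p-values of exactly adjusted 0.05 are non-significant.
* Mixed fits run with `lme4` singular-fit checks silenced: a zero
  between-animal variance is a legitimate boundary estimate (ρ = 0), not a
  failure.
* Problem sizes in the shipped simulations (1,000 null cohorts, 200
  calibration replicates, 300–500 power replicates) were chosen so
  Monte-Carlo error is small against the bands being checked.

## Limitations

* The recovery descriptor's printed-form definition diverges as
  $v_{last} \to \max$; analyses of `R` should prefer the complement
  convention when curves hover near full recovery.
* With 8 animals, variance-component estimates and ρ are noisy (the
  between-animal df is 7), and ML LRTs run slightly hot; conclusions about
  individual variance shares should rest on replication, not one cohort.
* GI has no shipped uncertainty quantification (a residual bootstrap would
  be the natural extension).
* The week structure treats W3–W5 as single-day weeks; the model cannot
  separate week effects from day effects there by design.
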