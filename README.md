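# rumenadapt

Quantifying how well individual ruminants buffer a high-concentrate diet
challenge, from post-prandial rumen pH time series.

High-producing ruminants are fed highly fermentable diets that depress rumen
pH and can push animals into sub-acute ruminal acidosis (SARA). Within a
herd, some animals tolerate the challenge and others do not, so a
per-animal, quantitative phenotype of adaptive capacity is valuable for
precision feeding and for selecting robust animals. The difficulty is that
the data live on two embedded time scales: an hourly post-prandial curve
(samples at 0, 1, 2, 4 and 6 h after the morning feed) nested inside a
multi-week challenge design (9 sampling days: two on the standard diet, four
immediately after the diet change, then one per week). `rumenadapt`
implements a three-step modelling procedure that merges the two scales into
a single per-animal index. All modelling is done on the hydrogen-ion
concentration [H+] = 10^(−pH) (mol/L), because the pH scale is logarithmic
and distorts statistics computed on it; a pH-scale mode is provided for
comparison.

**Step 1 — synthetic variables** (`fit_quadratic`, `reparametrise`,
`fit_all`). Each animal-day curve is fitted with a quadratic
[H+](t) = a·t² + b·t + c and re-parametrised into biologically meaningful
descriptors: the pre-feeding baseline v0 = [H+](0), the post-prandial
amplitude A = max [H+] − v0, and the recovery percentage
R = (max − v0)/(max − v_last) × 100 at t = 6 h. Threshold-dependent
descriptors (time above an acidosis threshold θ, default pH 5.5, and the
peak exceedance) are derived analytically from the quadratic's roots
(`derive_threshold_vars`), and a Spearman screen relates all candidate
descriptors (`spearman_matrix`).

**Step 2 — longitudinal mixed models** (`boxcox_lambda`, `fit_mixed`,
`lrt_fixed_effects`, `posthoc_weeks`, `icc`). Each Box-Cox-transformed
descriptor v^λ is analysed with the random-intercept model

    v_ijk = α_j + G_i + β·(days_k · 1{j=2}) + ε_ijk,
    G_i ~ N(0, σ_A²),  ε_ijk ~ N(0, σ²),

with fixed week means α_1..α_5, a day slope β active only in the first
post-change week, and a per-animal intercept. Week and day effects are
tested by nested ML likelihood-ratio tests; pairwise week contrasts carry
Benjamini–Hochberg adjustment and a compact letter display; the intraclass
correlation ρ = σ_A²/(σ² + σ_A²) measures the between-animal share of the
variance. `power_simulation` estimates test power by Monte Carlo at any
cohort size.

**Step 3 — phase-plane scoring** (`daily_scores`, `global_index`,
`rank_animals`). Each animal traces a trajectory in the (v0, A) plane across
the 9 days. Every step gets a quadrant score s ∈ {−2, −1, 1, 2} (both
descriptors falling = +2, both rising = −2, mixed = ±1) weighted by the
per-day Euclidean displacement ω, and the global index GI = Σ s·ω over the
steps from the last pre-change day onward ranks the animals: the higher
(less negative) the GI, the better the adaptive capacity.

A synthetic-cohort generator (`generate_cohort`) simulates the full design
with known ground truth, and `run_pipeline` / `compare_scales` orchestrate
everything.

## Worked example

Recompute per-animal indices from the bundled reference table of daily
phase-plane scores (eight goats from a high-concentrate diet-challenge
study, values ×10⁷):

```r
library(rumenadapt)
ref <- read.csv(system.file("extdata", "goat_daily_scores.csv",
                            package = "rumenadapt"))
gi <- vapply(seq_len(nrow(ref)),
             function(i) global_index(as.numeric(ref[i, 2:9]))$gi, numeric(1))
data.frame(animal = ref$animal_id, recomputed = round(gi, 2),
           published = ref$index)
#>   animal recomputed published
#> 1  Goat1     -26.43    -26.42
#> 2  Goat2      -6.66     -6.66
#> 3  Goat3      -6.51     -6.51
#> 4  Goat4     -14.02     -4.01
#> 5  Goat5      -4.70     -4.70
#> 6  Goat6      -4.31     -4.31
#> 7  Goat7     -24.53    -24.53
#> 8  Goat8      -3.77     -3.76
```

Six of the eight indices are reproduced to the rounding of the 2-dp inputs
(Goat 4's published row is internally inconsistent — its printed steps do
not sum to its printed index). Ranking the published indices identifies the
best and worst responders:

```r
rank_animals(setNames(ref$index, ref$animal_id))
#>   rank animal_id     gi  tied
#> 1    1     Goat8  -3.76 FALSE
#> ...
#> 8    8     Goat1 -26.42 FALSE
```

A full simulated analysis from scratch:

```r
res <- run_pipeline(pipeline_config(seed = 42))
res
#> Three-step analysis on the h_conc scale: 72 curves, 8 animals
#>
#> Step 2 summary:
#>   variable lambda   rho chi2_week   p_week chi2_days p_days
#> 1       v0  -0.59 0.583     64.29 3.63e-13      0.16  0.685
#> 2        A   0.09 0.234     22.20 1.83e-04      2.50  0.114
#> 3        R   2.00 0.021     13.41 9.42e-03      0.23  0.629
#>
#> Step 3 ranking (gi x 1e7):
#>   rank animal_id    gi  tied
#> 1    1       g01 10.74 FALSE
#> ...
```

The simulated cohort has a built-in week effect and no day slope, and the
tests recover exactly that: strong week effects for v0 and A, no day effect,
and a majority of the v0 variance attributable to stable between-animal
differences (ρ ≈ 0.58).

## Vignette

`vignettes/rumen-adaptive-capacity.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale, what
the synthetic-data generator does and does not emulate, the numerical
choices, and known limitations.
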