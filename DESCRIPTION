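Package: rumenadapt
Title: Quantifying Ruminant Adaptive Capacity from Post-Prandial Rumen
    Acid-Status Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify, at the individual-animal level, the capacity
    of ruminants to adapt to a high-concentrate diet challenge from
    post-prandial rumen pH time series sampled on two embedded time scales
    (hours within day, days and weeks across the challenge). A three-step
    procedure (i) summarises each post-prandial hydrogen-ion concentration
    curve with a re-parametrised quadratic model yielding biologically
    meaningful synthetic variables (baseline v0, amplitude A, recovery R,
    plus threshold-dependent acidosis descriptors), (ii) analyses the
    synthetic variables with Box-Cox power transforms and random-intercept
    linear mixed models (week and within-week day effects, likelihood-ratio
    tests, FDR-adjusted pairwise week contrasts, intraclass correlation),
    and (iii) scores daily displacements in the (v0, A) phase plane to
    produce a per-animal global adaptive-capacity index and ranking. A
    synthetic-cohort generator with known ground truth supports testing and
    power analysis by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
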