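---
title: "Methods: biophoton quality assessment of fresh herbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophoton quality assessment of fresh herbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biophoton)
```

## The measurement and its parameters

A photomultiplier in a darkroom counts single photons from a plant sample in
1-s bins. One session per sample comprises a 10-min instrument background
run, a 10-min spontaneous-emission (SPE) run after 1 h of dark adaptation, a
15-s white-light excitation followed by a 5-min delayed-luminescence (DL)
run (repeated three times), and a second 10-min background run. Fresh mass
(g) and, for leaves, thickness (mm) are recorded for normalization.
`validate_session()` checks these protocol expectations and reports
deviations as advisory findings, never as errors, because real sessions are
occasionally truncated and remain analyzable.

Three quantities summarize a sample:

* **CPS** (counts/s): the SPE mean rate minus the pooled background rate.
  Backgrounds are pooled duration-weighted over the pre- and post-run —
  this uses all dark data and is symmetric to slow drift. A missing
  post-background degrades gracefully to the pre-run alone. Negative CPS is
  possible for very weak emitters and is *retained with a warning*:
  clipping at zero would bias group means upward.
* **I₀** (counts/s): the DL intensity at the end of excitation.
* **T** (s): the DL coherence time, the time for intensity to fall to
  1/m² of I₀, with m = 3 throughout.

## The decay model

DL decay is modelled by the hyperbolic law

$$I(t) = A\,\operatorname{csch}^2\!\left(\frac{t}{B} + C\right),$$

with amplitude A > 0 (counts/s scale, absorbing sample size and detection
geometry), time parameter B > 0 (seconds) and shape parameter C > 0
(dimensionless). This is the unique hyperbolic form under which the two
derived characteristics have closed forms consistent with each other:

$$I_0 = I(0) = A\,\operatorname{csch}^2 C, \qquad
T = B\left[\operatorname{arcsinh}(m \sinh C) - C\right],$$

and the identity $I(T) = I_0/m^2$ holds exactly — the package verifies it
to 1e-9 relative tolerance over random models in its test suite. Note that
a superficially simpler reading of the T formula without the inverse-sinh
square root is dimensionally inconsistent (it would not vanish at m = 1 and
can go negative); the arcsinh form is the one the decay law itself implies,
and `coherence_time()` returns an exact 0 at m = 1.

## Fitting

`fit_dl_curve()` estimates (A, B, C) per DL run by minimizing the Poisson
negative log-likelihood of the bin counts. The per-bin model mean is the
*exact integral* of the rate over the bin, using the antiderivative
$\int \operatorname{csch}^2 = -\coth$, plus the floor:

$$\mu_k = A B\left[\coth\!\left(\tfrac{t_k}{B}+C\right) -
\coth\!\left(\tfrac{t_{k+1}}{B}+C\right)\right] + \text{offset}\cdot\Delta t.$$

A midpoint-rule mean was rejected: at 1-s bins it biases the estimates at
the 1e-4 relative level — invisible under noise, but it would contaminate
noise-free self-consistency checks and couple the estimator to the bin
width. The simulator uses the same exact integral for the same reason, so
generation and inference share no discretization error.

Numerical choices, in order of consequence:

* **Objective**: Poisson likelihood by default — DL counts are small
  integers, and the likelihood weights early high-rate bins correctly
  without an ad-hoc variance model. A variance-weighted least-squares
  option (`loss = "wls"`) exists for cross-checking.
* **Offset**: the steady floor under the decay (instrument background plus
  the sample's own spontaneous emission) is measured independently in every
  session, so it is held *fixed* by default at that measured value; this
  removes one parameter from a fit whose (A, C) directions are already
  strongly correlated. `offset_mode = "fitted"` frees it.
* **Optimization**: L-BFGS-B on log-parameters (enforcing positivity and
  bounds A ∈ (0, 1e9], B ∈ [0.1, 3600] s, C ∈ [1e-3, 20]) with an analytic
  gradient, started from a coarse (B, C) grid on which A is profiled by
  least squares, followed by one restart from the solution. A failed line
  search on the restart merely means the first pass had converged; the
  convergence flag is the OR of the two passes.
* **Degenerate inputs**: a series whose first-decile mean rate does not
  exceed the floor by more than twice its Poisson standard error cannot
  identify a decay and raises a classed `NonDecayingSignal` error rather
  than returning an arbitrary fit. Optimizer failure, by contrast, returns
  a result flagged `converged = FALSE` so that replicate aggregation can
  proceed.
* **First bins**: `discard_initial_bins` (default 0) allows dropping
  possible excitation-source afterglow; the default preserves the full
  curve since the measurement protocol itself applies no discard.

Each of the three DL repeats is fitted separately and the derived I₀ and T
are averaged over converged replicates (`summarize_replicates()`); fitting
repeats separately is robust to inter-repeat drift in the floor, whereas
averaging raw curves would smear it.

Normalization divides by fresh mass × thickness for leaves and by mass
alone for near-spherical flowers (whose emitting surface scales with mass
the same way volume does). The product, rather than two separate reports,
gives one comparable intensity density per sample; the mode is recorded in
the result so the choice stays auditable.

## Statistics

Group comparisons use the classical equal-variance two-tailed Student's
t-test (`var_equal = FALSE` gives Welch), associations the Pearson
correlation with the exact t-transform p-value; both are hand-computed in
closed form and the suite verifies them against `stats::t.test()` /
`stats::cor.test()` to 1e-10 — a deliberate dual-route check rather than a
wrapper. Significance is declared at p ≤ 0.05 and **no multiple-testing
correction** is applied: the report instead records the number of tests
performed, so a reader can apply any correction they prefer.

Correlations are computed at per-sample granularity by default (the
synthetic generator provides per-sample contents); aggregating to
group-stage means first is a documented alternative when contents were
assayed on pooled material — both are honest, they answer slightly
different questions, and the per-sample mode has more power when available.

## The synthetic-data generator

`simulate_cohort()` draws complete studies with known ground truth.
Background and SPE streams are homogeneous Poisson; DL streams are
inhomogeneous Poisson with the exact per-bin integrals above. Defaults are
the package's fixed study conditions:

| parameter | default | meaning |
|---|---|---|
| base A, B, C | 2000 counts/s, 60 s, 0.8 | reference-cell Gu decay |
| SPE rate / background | 50 / 5 counts/s | sample emission over dark rate |
| durations | 600 s background & SPE, 300 s DL ×3, 1-s bins | protocol runs |
| group effects | healthy:poor = 2 on A, 1:1.4 on B | state contrast |
| stage decay | ×0.8 on A and SPE per stage | growth trend |
| noise_sd | 0.25 (log scale) | per-sample lognormal heterogeneity |
| rho_content | 0.9 | target cor(log I₀, log content) |

The decay magnitudes are generator conventions chosen to put per-bin DL
counts in the few-hundreds-to-thousands range typical of leaf measurements;
they are not instrument-calibrated values. Per-sample heterogeneity is one
lognormal multiplier that scales A and the SPE rate jointly; emission
additionally scales with the tissue amount (mass × thickness relative to
mid-range), so size normalization in the pipeline recovers the intrinsic
signal. Content follows $k\,I_0^{\gamma}\varepsilon$ with γ = 1 and
lognormal ε whose spread is calibrated in closed form so the realized
log-scale correlation matches `rho_content` in expectation — an infeasible
target (|ρ| ≥ 1, or no I₀ variation at all) errors at design time. The
per-sample B multiplier is coupled as (multiplier)^(−0.5), making stronger
emitters decay faster, which yields the negative T-versus-content
association characteristic of healthy versus stressed plants. Absorbance
triplets scale with the square root of the intrinsic multiplier so pigment
contents track the same group structure.

Reproducibility: one master seed; each (sample, run) stream gets a seed
from a fixed counter scheme, so enlarging a design never reshuffles the
streams of earlier samples.

What the generator does *not* emulate — detector dead time and
afterpulsing, temperature drift, ambient light leaks, spectral structure,
non-Poisson photon statistics — bounds what green tests mean: they certify
the estimators and statistics under ideal counting noise, not robustness to
instrument pathologies.

## Problem sizes in the test suite

The suite validates decay-law consistency on 1000 random models, parameter
recovery on 200 Poisson replicates of the reference decay (observed
relative RMSE is near 1% for both I₀ and T, far inside the 10%/15% gates),
grid-oracle equivalence on 20 random instances, t-test calibration on 5000
null cohorts, and the qualitative healthy/poor findings on 20 full-pipeline
cohorts of 30 samples per group — sizes at which every check is
informative while the whole suite stays fast enough to run on every change.

## Known limitations

* The Gu law is the only decay family offered; multi-exponential or
  stretched-exponential alternatives and spectral decomposition are out of
  scope.
* The fit assumes a constant floor during the 5-min DL run; slow SPE drift
  within a run is not modelled (between-run drift is absorbed by per-repeat
  fitting).
* Count files are headerless one- or two-column text; vendor binary
  formats are not read.
* Reported CPS/I₀ units after normalization follow the divisor
  (counts/s/g or counts/s/g/mm); comparisons across species with different
  normalization modes are not meaningful and the mode column should be
  checked before pooling.
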