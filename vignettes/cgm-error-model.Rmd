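---
title: "Modelling the error of factory-calibrated CGM sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the error of factory-calibrated CGM sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmerr)
```

## The model

A factory-calibrated CGM sensor converts an electrochemical current into a
glucose reading using a conversion function fixed at manufacture. Over a
10-day wear, three distinct mechanisms separate its output from the
laboratory blood-glucose (BG) reference:

**Kinetics.** Glucose diffuses from plasma into the interstitium; under a
steady-state balance assumption the two-compartment transport collapses to
a first-order linear system, IG = h ⊗ BG with h(t) = (1/τ)·e^(−t/τ). The
time constant τ (minutes) is treated as specific to the subject–sensor
coupling, because the sensing site and the device's own processing both
affect the apparent delay. `tau = 0` is allowed and means no delay — fitted
values close to zero do occur, so the lower bound must be feasible.

**Calibration error.** With no in-vivo recalibration, drifts in sensor
sensitivity accumulate over the full lifetime. The noiseless sensor signal
is modelled as IGs(t) = a(t)·IG(t) + b(t), with a unitless gain a(t) and an
offset b(t) in mg/dL, each drawn from one of five function families:
polynomials of order 0–3 in time-since-insertion, or a three-parameter
exponential. Time enters these functions in *days* (t_min/1440), so a
poly-m coefficient p_k carries units days^−k; the exponential is
parameterised as initial value, final value and time constant in days,
f(t) = p₁ + (p₀ − p₁)·e^(−t/p₂), which reproduces that naming exactly.
5 × 5 = 25 candidate (a, b) pairs are considered.

**Noise.** The residual measurement noise v(t) is autocorrelated; candidate
models are AR(q), q = 1…10, at the CGM sampling period T (5 min by
default), driven by zero-mean white noise of SD σ (mg/dL). Stationarity
requires all roots of A(z) = 1 − α₁z − … − α_q z^q inside the unit circle;
every constructor and estimator in the package enforces this. The driving
noise is taken Gaussian — the least-squares estimators implicitly assume
it, and nothing in the data pipeline can distinguish heavier tails at the
sample sizes involved.

## Discretisation and numerical choices

* The kinetic convolution is discretised per segment by the exact
  zero-order-hold recursion IG[k] = φ·IG[k−1] + (1−φ)·BG[k], φ = e^(−Δ/τ),
  which is unconditionally stable and exact for inputs held constant on
  (t[k−1], t[k]]. A forward-Euler scheme was rejected: it loses accuracy
  and can destabilise at small τ.
* The first sample of each segment starts at steady state, IG = BG. With
  reference data available only inside clinical sessions, this initial
  condition is wrong whenever the true interstitial state carries history
  from before the session; the transient decays like e^(−t/τ). The
  synthetic recovery harness therefore extends each session's reference
  coverage 60 min backwards (`true_bg_pairs(..., warmup_min = 60)`) so the
  filter has settled by the first matched pair — a luxury real data does
  not offer, where the residual transient simply contributes to the first
  few samples of each session as it must have in any study with
  session-restricted references.
* τ is box-bounded in [0, 60] min: zero must be attainable (it is observed)
  and 60 min is a generous physiological ceiling. The exponential
  calibration time constant is bounded in [0.05, 50] days.
* In the single-step optimiser the AR coefficients are represented by their
  reflection (partial autocorrelation) coefficients, box-bounded in
  [−1 + 10⁻³, 1 − 10⁻³]. The Levinson step-up recursion maps this box
  exactly onto the stationarity region (for q = 2, the open triangle
  α₁ + α₂ < 1, α₂ − α₁ < 1, |α₂| < 1) with a 10⁻³ margin that keeps the
  optimum interior. This turns the stationarity constraint into plain box
  bounds, so a bound-constrained quasi-Newton optimiser (L-BFGS-B) meets
  the "gradient-based constrained local optimiser" contract without a
  nonlinear-constraint solver.
* Internal parameter scaling puts every coordinate at order one (τ scaled
  by 10, drift coefficients by their expected magnitude, reflection
  coefficients by 0.2) so finite-difference gradients are balanced.
* An AR fit that lands outside the stationarity region (possible for the
  unconstrained forward–backward estimator on short series) is projected
  inward by clipping its reflection coefficients to magnitude 1 − 10⁻³.
* Unit-circle root tests subtract 10⁻⁶ so numerical root-finding error
  cannot classify an exact unit root as stationary.
* Degenerate inputs: segments shorter than 3 residuals contribute nothing
  to whitening (warning); sessions with fewer than 4 reference samples are
  skipped (warning); an RSS of exactly zero yields a −∞ BIC sentinel
  flagged `degenerate`; all-saturated traces come back empty and flagged.

## Identification

**Two-step.** Step one estimates θ = {τ, calibration coefficients} by
nonlinear least squares on the matched (reference, CGM) pairs, using
Levenberg–Marquardt with the standard initialisation τ = 7 min, a ≡ 1,
b ≡ 0. Step two fits the noise model to the step-one residuals by
forward–backward (modified covariance) least squares, with no lag products
crossing a session boundary — the sessions are days apart, so cross-segment
lags would be meaningless. σ̂ is the SD of the forward one-step prediction
errors. Because the BIC arithmetic assumes independent residuals, the RSS
entering it is computed after whitening the residuals with the inverse of
an AR(2) fitted to them; the whitening order is fixed at 2, the order
consistently found for CGM sensor noise. The first two residuals of each
segment are dropped by the whitening filter, and `n` in the BIC is the
number of whitened residuals actually summed.

**Single-step.** All parameters (θ, α) are estimated simultaneously by
minimising the whitened objective
Σ_j [ r_j(θ) − Σ_k α_k r_{j−k}(θ) ]², lags confined within segments and the
first q pairs of each segment excluded; σ̂ is the sample SD of the whitened
residuals at the optimum. By default θ is initialised at the two-step
solution and α at the two-step AR fit (falling back to (1.30, −0.42) for
q = 2 when that fit is unusable). Starting from the two-step solution makes
the procedure's defining property — its optimised objective can never
exceed the two-step whitened RSS — hold by construction on every sensor;
`init_theta = "defaults"` restores the τ = 7/a ≡ 1/b ≡ 0 start for
sensitivity checks. A per-sensor α initialisation is used rather than a
cohort-average model because the procedure must work on a standalone
sensor.

**Uncertainty.** Approximate standard errors for θ come from the numeric
Jacobian of the whitened residual vector at the optimum (Gauss–Markov);
AR-coefficient standard errors from the AR regression; the per-parameter
coefficient of variation of the estimation error is se/|estimate|. These
are first-order approximations and are reported as such.

## Model selection

For each sensor and each candidate calibration pair, the first
identification step is run and BIC = n·ln(RSS/n) + (N_p + 1)·ln(n) computed
on the whitened residuals, where N_p counts calibration coefficients and
the +1 accounts for τ (for AR-order selection the same formula is used with
n_params = q, the +1 covering σ). Candidates are compared through the
distribution, across sensors, of their BIC difference from the
time-invariant reference (poly₀, poly₀). "Lowest distribution" is
operationalised as the lowest median; among candidates whose medians lie
within an equivalence margin (2 BIC units by default) the simplest one wins
— fewest calibration parameters, ties broken toward the lower polynomial
order in a(t). This margin-then-simplicity rule mirrors how near-ties
between a second-order gain model and its richer neighbours should resolve.

## The synthetic study generator

No public dataset of factory-calibrated traces with dense laboratory
references exists, so the package generates its own study: a 10-day wear
with three 12-h in-clinic sessions (days 2, 4 and 10 by default, starting
at 08:00), reference samples every 15 min within sessions carrying 2% CV
white assay noise, and CGM readings every 5 min throughout, clipped to the
40–400 mg/dL display range.

BG profiles are built as a constant baseline (110–140 mg/dL) plus smooth
meal-excursion kernels — a logistic rise (30–60 min) times an exponential
decay (60–120 min time constant), three meals a day with jittered timing,
amplitudes 60–140 mg/dL — and occasional induced dips to 60–70 mg/dL,
emulating the deliberate glycemic excursions of an in-clinic protocol. The
construction is twice continuously differentiable, as the smoothing model
assumes, and confined to [50, 350] mg/dL so display saturation arises only
through sensor error. It does **not** emulate circadian basal drift,
sensor dropout, compression artefacts, or the ragged high-frequency
structure of real BG; recovery results on these profiles therefore
demonstrate estimator correctness under the model's own assumptions, not
robustness to model violation.

Cohort parameter populations:

* `jitter = FALSE` (default): every sensor at the published single-step
  cohort medians — τ = 3.78 min, a = (0.95, 0.004, 0), b₀ = 6.35 mg/dL,
  α = (1.30, −0.42), σ = 3.19 mg/dL. This is the configuration of the
  parameter-recovery experiments: fixed truth, cohort medians of the
  estimates compared to it.
* `jitter = "iqr"`: between-sensor heterogeneity with spreads derived from
  the published interquartile ranges (normal with sd = IQR/1.349;
  lognormal for τ); noise parameters stay fixed.
* `jitter = "curved"`: the population for model-*identifiability*
  experiments. A gain population centred at a₂ = 0 (the reported median)
  makes half the cohort effectively first-order, so a "second-order
  cohort" drawn that way cannot be recovered by any selection rule — the
  generating model is simply absent from half the sensors. Instead the
  gain is drawn as a bounded trajectory: endpoint gains g(0) ~ U(0.85,
  1.05), g(10 d) − g(0) = ±U(0.10, 0.30), and a midpoint curvature
  deviation ±U(0.10, 0.22), giving |a₂| between 0.004 and 0.0088 days⁻²
  (the beyond-quartile range of the reported population, which spans a
  much wider range than its IQR suggests) while keeping the gain itself
  physical. Unbounded coefficient draws were rejected because extreme
  gains push the late-wear readings into the 400 mg/dL display clip, and
  the saturation-removal rule then deletes exactly the samples carrying
  the curvature signal.

Everything is reproducible: each stochastic operation takes an explicit
seed, a cohort's master seed expands deterministically to per-sensor seeds,
and no global RNG state is touched.

## Reference smoothing

Within each session the sparse, noisy reference samples are projected onto
a 1-min grid by Tikhonov regularisation: minimise
(y − Gu)ᵀΣ⁻¹(y − Gu) + γ·uᵀF₂ᵀF₂u, with Σ diagonal (variances (cv·yᵢ)² —
the measured value stands in for the unknown truth) and F₂ the
second-difference operator. Under the Bayesian reading — second differences
of u are white noise of unknown variance — γ is chosen by maximising the
marginal likelihood, implemented as the generalised maximum-likelihood
criterion (the whitened residual quadratic form divided by the
(n−2)-th root of the product of the nonzero eigenvalues of I − A(γ), A the
influence matrix), searched on a 61-point log grid from 10⁻⁴ to 10⁸.
Reference times are snapped to the nearest grid point, which keeps the
penalised normal equations pentadiagonal and lets sparse Cholesky solves
carry the whole grid search. Linear signals are in the penalty's null
space, so noise-free linear data are reconstructed exactly for any γ, and
the γ → ∞ limit is the weighted least-squares line — both serve as oracles
in the tests. Sessions are smoothed independently (they are days apart),
there is no extrapolation beyond a session's first and last sample, gaps
longer than 20 min between consecutive references are masked, and CGM
samples are matched to the grid only within 30 s (ties resolve to the
earlier grid point — an arbitrary, documented choice).

## Problem sizes used by the test experiments

The recovery experiments run 40 sensors (the size at which cohort medians
are stable to well within the tolerances asserted); model-selection
recovery uses 10 cohorts of 20 sensors against the 9-candidate polynomial
grid; AR-order recovery uses 100 replicates of length 5000. These sizes
were chosen as the smallest at which the Monte-Carlo error of the asserted
statistic is comfortably below the assertion tolerance.

## Known limitations

* Transient sensor disconnections and pressure-induced attenuations are
  not modelled.
* The noise is a single sensor-specific component; separating a common
  (across parallel sensors) component requires multi-sensor wearers, which
  the study design does not include.
* The estimation-error CVs are first-order Gauss–Markov approximations.
* The reference-outlier spike rule (`flag_reference_outliers`) is an
  automated stand-in for manual visual inspection, is off by default, and
  flags the neighbours of very large spikes along with the spike itself.
* Smoothing assumes the 2% CV assay error model; gross reference outliers
  must be handled before smoothing.
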