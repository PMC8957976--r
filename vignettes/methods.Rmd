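---
title: "Methods: generative model, inversion, and synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generative model, inversion, and synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modeling and numerical choices behind
`cmcdcm`: the generative model, the variational inversion, the group
statistics, and — most importantly for interpreting results — what the
synthetic cohorts do and do not emulate.

## The generative model

**Neural dynamics.** Five neural mass points (MC, PFC, BG, MTL, SENS;
indices 1–5, all matrices row = target, column = source) evolve as
`dy/dt = A y + C x + Σ_i y_i D(i) y`. The diagonal of `A` holds strictly
negative self-decay rates; off-diagonal entries exist only where the
network variant allows them: eight shared directed edges (SENS↔MC,
MTL↔PFC, SENS↔PFC, PFC→MC, PFC→BG), plus BG→PFC in the *direct* variant,
or two gating triples (BG, MTL→PFC) and (BG, SENS→PFC) in the
*modulatory* variant. MC→PFC is deliberately absent; the asymmetry is
part of the architecture. The variants differ by exactly one free
parameter (two gating entries versus one fixed edge), which keeps the
model comparison nearly complexity-neutral by construction.

**Drivers.** Since a resting run has no task, deterministic low-frequency
drivers stand in for spontaneous fluctuations: for each frequency in
{0.01, 0.02, 0.04, 0.08} Hz, two boxcars with a 90° lag, obtained by
thresholding sine/cosine at zero. Each micro-time bin takes the sign that
holds over the bin's interior (midpoint evaluation). This convention
matters more than it looks: the default TR/16 grid hits every zero
crossing exactly, where the floating-point sign of `sin` is noise, and a
left-edge threshold would let the realized transition slip by one bin in
a resolution-dependent way — enough to move the integrated response by
~1e-2 and break step-size refinement. With midpoint evaluation the
transition times are pinned to the true crossings at every resolution,
and the duty-cycle and quarter-period-shift identities hold exactly. The
boxcars take values {0, 1} and are not mean-centered: sign conventions of
`C` would otherwise be unidentifiable. Every driver enters every region
(`C` mask all ones). Drivers are generated at micro-time dt = TR/16 and
down-sampled to scan times by nearest-bin lookup when used in the GLM.

**Hemodynamics.** Each region passes its neural trace through a
balloon–Windkessel cascade — vasodilatory signal
`ds/dt = y − κs − γ(f−1)`, inflow `df/dt = s`, volume
`τ dv/dt = f − v^{1/α}`, deoxyhemoglobin
`τ dq/dt = f·(1−(1−ρ)^{1/f})/ρ − v^{1/α} q/v` — with output
`V0 (k1(1−q) + k2(1−q/v) + k3(1−v))`, `k1 = 7ρ`, `k2 = 2`,
`k3 = 2ρ − 0.2`. Constants default to κ = 0.64 s⁻¹, γ = 0.32 s⁻¹,
τ = 2 s, α = 0.32, ρ = 0.4, V0 = 0.04, fixed across regions during
generation; inversion can optionally estimate shared log-scalings of τ
and κ (`dcm_control(fit_hemo = TRUE)`), off by default. The positive
states f, v, q are integrated on the log scale. This is an exact
reparameterization of the same equations with one important numerical
consequence: sustained deactivation drives flow asymptotically toward
zero instead of through it, so physically meaningful inhibitory episodes
do not crash the integrator. Divergence (non-finite states, or neural
magnitudes above `y_bound = 1e3`) raises a structured error naming the
offending parameters — never a silent NaN.

**Integration.** Both simulation and the inversion's forward sweeps use
classical fixed-step RK4 at dt = TR/16 with inputs held constant over
each micro-bin. A fixed-step scheme keeps runs bit-reproducible and fast
at five nodes; RK4 (rather than a first-order scheme) is needed to meet
the package's accuracy contract — endpoint agreement within 1e-3 with an
adaptive high-accuracy reference integrator, which the test suite checks
against `deSolve::lsoda` at rtol 1e-10. A first-order method at this
step size has global error near 1e-2 on these dynamics and cannot meet
that bound.

## Synthetic cohorts: what is emulated, what is chosen, what is not

The published group tables provide the anchors: PD gating means 0.24
(BG|MTL→PFC) and −1.59 (BG|SENS→PFC) versus control means −3.84 and
−2.39; the eight fixed-connection group means for both groups; and the
printed per-group dispersions, which are used as between-subject jitter
SDs (their interpretation as posterior SDs versus population dispersions
is ambiguous in the source; the package adopts the dispersion reading
and flags it here). Cohort sizes default to 70 PD + 41 HC = 111.

Everything else the literature does not pin down is a package default,
chosen once on stability and identifiability grounds and then frozen:

* **Self-decay −1.0 Hz** (jitter 0.1). The control-group gating gains are
  large (−3.84); with weaker self-inhibition the bilinear feedback loop
  BG → (MTL,SENS→PFC gain) → PFC → BG is episodically unstable at any
  driver amplitude strong enough to be informative.
* **Driver weights**: magnitude 0.075 Hz on a fixed zero-mean sign
  pattern with per-region band separation — MTL is driven by the two slow
  oscillations, SENS by the two fast ones, BG by a broadband alternation,
  MC and PFC by complementary mixtures (`driver_weight_pattern()`).
  Zero-mean drive keeps neural excursions fluctuating about rest, the
  regime in which the balloon model is well behaved; band separation
  gives the two gated source states distinct spectral signatures, which
  is what lets inversion attribute bilinear BOLD signal to the correct
  gating parameter. (All-positive weight patterns were found to make the
  two gating effects collinear — their products share a common slow
  envelope — and unidentifiable at any stable amplitude.) Jitter is 10%
  of each weight's magnitude.
* **Observation noise**: i.i.d. Gaussian per sample, scaled per subject
  so that temporal signal SD / noise SD ≈ 3 — mid-range for simulation
  practice in this model class; no noise figure is published.
* **Direct-variant BG→PFC generative mean**: 0.2 (PD) / 0.1 (HC), jitter
  0.1. No value is published; only the sign structure (PD above HC) is
  anchored, so the numbers are arbitrary-but-documented.

The cohorts emulate the *statistical* structure the analysis assumes:
group-specific means, between-subject jitter, additive noise. They do not
emulate scanner drift, motion, physiological noise, spatial structure,
multi-echo acquisition, or hemodynamic variability across regions and
subjects — so passing recovery tests demonstrates correctness of the
estimator under the model's own assumptions, not robustness to real
fMRI artifacts.

## Inversion

`dcm_fit()` maximizes a Laplace free energy
`F = log p(y|θ,h) + log p(θ) + log p(h) + ½log|Σ_θ| + ½log|Σ_h| + const`
with a Gaussian likelihood under a single shared noise precision
`exp(h)`. The loop: finite-difference Jacobian of the predicted
scan-sampled BOLD (forward differences, step 1e-4 on the latent scale);
Gauss–Newton ascent with step-halving (up to 6 halvings) accepting only
free-energy increases; closed-form Newton update of `h` each outer
iteration under its Normal(4, 1) hyperprior; convergence when the
improvement falls below 0.01 nats, or 64 iterations (the convergence
record is then flagged). Initialization is at the prior means; optional
multi-start (`dcm_control(multi_start = list(n, seed))`) exists for hard
cases but is off by default — on the synthetic regimes shipped here the
default basin already contains the optimum (verified by comparing
truth-initialized and default fits). The posterior covariance is the
inverse of the Gauss–Newton precision at the accepted optimum
(eigenvalue floor checked in tests), reported on the generative scale via
the delta method.

**Priors.** Off-diagonal `A` entries: Normal(0, 1/16). Driver weights:
Normal(0, 1). Self-decay is fitted as `a_ii = −exp(ℓ)` with
ℓ ~ Normal(0, 1/64), i.e. centered on −1 Hz — matching the generative
default, so that prior-mean initialization starts from the canonical
resting model. Gating entries: Normal(0, 1), the convention of the
reference DCM implementations for second-order effects; a 1/16 variance
here would declare published-scale gains (magnitude 2–4) a priori
impossible and provably biases recovery — with the tight prior, the
shrunk solution has *higher* free energy than the truth, so no optimizer
could recover planted gains of that size.

**Evidence.** The converged F is the log-evidence plug-in for model
comparison. Strictness at the conventional thresholds is deliberate:
log Bayes factors of exactly 3 or 10 do not clear the "moderate"/"strong"
bars.

## Group statistics

Bayesian parameter averaging is the fixed-effects combination: group
precision `Σ_i P_i − (n−1) P_0`, group mean
`Σ_g (Σ_i P_i μ_i − (n−1) P_0 μ_0)`; the shared prior is counted exactly
once. The combination runs on the generative scale with the prior mapped
through the same delta-method transform as the posteriors. A combined
precision that is not positive definite (possible if per-subject
posteriors are wider than the prior) is an error with diagnostics, not a
silent repair.

Directional tests standardize the group difference,
`z = (μ_PD − μ_HC)/√(σ_PD² + σ_HC²)`, and report `p_less = Φ(z)`,
`p_greater = 1 − Φ(z)`. This is simultaneously the one-sided tail of the
standardized difference and the posterior probability of the opposite
sign under independent Gaussian group posteriors — two readings, one
implementation. The printed dialect (two decimals, "<0.001" floor,
em-dash for the direction not tested under the sequential convention) is
available via `format_directional_table()`. Applying the test to the
published group summaries reproduces every printed p column except the
"greater" column of the SENS→PFC gating row, where the published
difference (0.80) over its combined dispersion (≈0.64) yields p ≈ 0.11,
not <0.001; the package reports the recomputed value and surfaces the
discrepancy rather than matching the printed one. The dispersions in
those tables are treated as standard deviations, the only reading under
which the remaining columns reproduce.

## Regressor-quality check

At ROI level, `omnibus_f()` regresses each region's trace on an intercept
plus the eight boxcars (unconvolved by default, so the GLM sees exactly
the DCM's drivers; below 0.08 Hz a canonical HRF mainly phase-shifts —
optional polynomial drift columns are available) and computes the omnibus
F over all oscillatory coefficients, df = (8, scans − 9). The group test
centers log F at its *exact* null expectation
`ψ(df1/2) − log(df1/2) − ψ(df2/2) + log(df2/2)` (digamma), not at
log of the mean of the null F: the null mean of log F is about −0.13 at
(8, 231) and a test centered at 0 or at `log(df2/(df2−2))` would be
biased by roughly −2.6 t-units at n = 111. The one-sample t across
subjects has df = n − 1 (110 at the full cohort size).

## Problem sizes and determinism

Unit tests run on 80–150 s simulations and 10–20 inversions; the
stochastic recovery experiments use the full protocol (240 scans,
TR 2.5 s, 10 subjects for recovery, 8 × 2 fits for model selection),
each inversion taking a few seconds. All randomness flows through
explicit seeds (per-subject seeds derived from a master seed); fits
themselves are deterministic, so identical inputs give identical
reports.

## Known limitations

* Deterministic-input DCM only: no stochastic resting-state DCM and no
  cross-spectral formulation; a single static fit per run, so dynamic
  (time-varying) connectivity is out of scope.
* One shared noise precision across regions; per-region precisions are a
  straightforward extension but are not what the group statistics here
  assume.
* The inverse problem is solved under the same integrator family as the
  generator (an "inverse crime" in the favorable direction); the adaptive
  oracle bounds integration error but not model misspecification.
* Gating estimates at SNR 3 carry posterior SDs of ~0.3–0.5 per subject;
  single-subject gating values are not interpretable point estimates, and
  all shipped analyses aggregate across subjects.
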