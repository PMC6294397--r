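---
title: "Models and methods behind classim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind classim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

classim simulates a noisy-bar 2AFC psychophysical protocol and the analysis
chain used to characterise perceptual filtering from the trial-by-trial
statistics of the noise: double-pass internal-noise estimation,
classification-image descriptors with analytic noise floors, and a scalar
metric suite over a contrast-by-SNR grid. This vignette records the models,
the parameter choices, the numerical decisions, and the places where the
design was genuinely open.

## Stimuli and protocol

A stimulus is a vector of 13 bar luminances stored in *contrast units*:
one unit is the monitor noise quantum (0.3 cd/m² against the 30 cd/m²
background), so the noise SD equals the contrast multiplier
`c ∈ {1, 2, 4, 8}` numerically. Each trial presents a non-target
`s⁰ = n⁰ + t⁰` and a target `s¹ = n¹ + t¹`; the noise components are iid
zero-mean Gaussian per bar, the signal components are zero except at the
centre bar, whose offset is `ρ = SNR × σ_N` with the sign pattern of the
task (bright, dark, mixed polarity, or polarity discrimination; the mixed
task draws the target sign as an iid fair coin each trial, the simplest
reading of "random assignment"). Condition (contrast level, SNR level) is
constant within a 50-trial block. Double-pass blocks replay the stimuli of
trials 1–25 as trials 26–50 in a uniformly random permutation; `pass_mate`
records the bijection.

Deliberate simplifications: no monitor clipping of extreme luminances
(truncation would distort the Gaussian statistics every estimator assumes);
no rendering, timing, fixation or eccentricity geometry; spatial 2AFC and
temporal 2IFC are computationally identical under the difference rule, so no
protocol distinction is made. Screen side is generated and logged but never
used by the analysis: responses are coded by stimulus identity, which is
also what double-pass agreement must be computed on.

What the generator does *not* emulate about real data: serial dependencies,
learning or vigilance drifts, response bias, and lapses. Passing tests
therefore demonstrate correctness of the estimators for a stationary,
bias-free observer — they do not certify behaviour under the
non-stationarities of human sessions (the first-trial filter exists
precisely to probe such questions on real data).

## Observer models

All observers share three stages.

* **Front end** — a difference-of-Gaussians filter
  `f_i = k·φ(x_i, σ₁) − φ(x_i, σ₂)` sampled every 9 arcmin (the bar width),
  defaults `k = 4`, `σ₁ = 5`, `σ₂ = 20` arcmin, 25 taps (±108 arcmin, where
  the tails are < 10⁻⁴ of the peak), normalised to unit energy and applied
  as a 'same' convolution with zero padding (the background is 0 in contrast
  units, so zero padding is the physically neutral boundary).
* **Branches** — linear `b_lin = s * f`, and nonlinear `b_nlin = b_lin²`
  (elementwise). Divisive gain control, when enabled:
  `b̂_lin = b_lin / (10 + (Σb_lin)²)` (the signed sum, as the formula is
  written; an Open Question flag in the code would allow a magnitude sum)
  and `b̂_nlin = b_nlin / (0.4 + Σb_nlin)`.
* **Read-out** — Gaussian window `w` of SD `σ_w = 40` arcmin centred on the
  target bar, evaluated at the 13 bar positions with peak 1 and *not*
  renormalised (any global factor is absorbed by the intrinsic-noise
  calibration); decision variable `r = ⟨w, branches + e⟩`, intrinsic noise
  `e` iid Gaussian per position, drawn fresh for every stimulus. The MAX
  observer instead takes `r = max(w × b_lin + e)` with `σ_w` set to 40, 80,
  120, 160 arcmin as contrast level drops from 4 to 1. The two-branch
  variants: template (#1) `b_lin` only; energy (#2) `b_nlin` only;
  gain-controlled energy (#3); hybrid (#4) `b_lin + b̂_nlin`; fully
  gain-controlled hybrid (#5), which switches to `k = 6`, `σ₁ = 2.5`,
  `σ₂ = 10`, `σ_w = 10` arcmin. Responses follow the difference rule with
  ties (difference ≤ 0) resolved to the non-target.

Noise placement: `late` adds `e` after the branch nonlinearity (the
default); `early` adds it before squaring, `(s*f + e)²`;
`response_dependent` scales it by the front-end magnitude, `b + |b|·e`.
Along a purely linear branch these distinctions collapse, so they are only
meaningful for the energy branch.

### Front-end input gain

`observer_config(input_gain = 0.1)` converts stored contrast units into the
front end's operating units. This is the one genuinely free constant in the
model family: the divisive-normalisation constants (10 and 0.4) are absolute,
so the stimulus scale decides *where* in the contrast range the energy
branch's pool `Σb_nlin ≈ 13σ²` crosses its semi-saturation constant 0.4. At
`input_gain = 0.1` the crossing sits at contrast level ≈ 2, inside the
experimental range — the regime in which the hybrid model expresses its
signature behaviour: the energy branch contributes at low contrast and is
divisively silenced at high contrast. A gain of 1 (raw contrast units) puts
the pool at 13–830, crushing the energy branch everywhere and degenerating
the hybrid into a template matcher; a gain ≲ 0.01 (Weber fractions) leaves
the pool far below 0.4, removing the normalisation transition instead. The
default was fixed once from this dimensional argument and is exposed as a
config field.

### Intrinsic-noise calibration

`calibrate_noise_sd()` bisects on log noise SD until the mean d′ over the
4×4 grid equals 1 (threshold), with d′ per condition from
`√2·Φ⁻¹(pc)`; stimuli and standard-normal noise draws are frozen across SD
candidates, making the objective deterministic and monotone. Because
intrinsic noise can only reduce d′, architectures whose external-noise-limited
ceiling lies below 1 admit no solution: the broad read-out window dilutes the
central-bar template, capping the pure template matcher near mean d′ ≈ 0.9.
The function then errors by default; the documented fallback
(`target = "ceiling_fraction"`) targets d′ = ceiling/√2, i.e. an intrinsic
source whose decision-stage variance matches the external drive — internal
noise near 1 in external-noise units, the centre of the empirically
plausible range (1/5, 5). The tolerance (±0.05 on mean d′) makes the "∼1"
target testable.

## Double-pass internal noise

The 2-parameter SDT model: decision variable `d_ext + ε_int`,
`d_ext ~ N(d′_in, 1)` fixed across a repeated pass, `ε_int ~ N(0, N_int)`
fresh on every presentation, response = sign. Forward map:
`pc = Φ(d′_in/√(1+N_int²))` and
`pa = E[Φ(d/N_int)² + (1−Φ(d/N_int))²]` over `d ~ N(d′_in, 1)`, evaluated
with 64-node Gauss–Hermite quadrature (`pracma::gaussHermite`); `N_int = 0`
is treated as the deterministic limit `pa = 1`. A Monte-Carlo simulator of
the same observer serves as the test oracle for the quadrature. Estimation
minimises `(pc−p̂c)² + (pa−p̂a)²` by an 81×81 grid (d′_in linear in [0, 10],
N_int log-spaced in [0.01, 100]) followed by Nelder–Mead refinement on
(d′_in, log N_int) at `reltol = 1e-12`; the grid step avoids local minima,
the refinement supplies the self-consistency property (round-tripping the
forward map recovers parameters to ~1e-3). Gaussian noise only; estimates
are flagged `plausible` inside (1/5, 5). Response bias is assumed absent —
the simulated observers are bias-free by construction.

## Descriptors, noise floors, drives

Classified noise `n^[q,z]` feeds the first-order descriptors
`h¹ = μ(n^[1,1]) − μ(n^[1,0])`, `h⁰ = μ(n^[0,0]) − μ(n^[0,1])`,
`h = h¹ + h⁰`, and the second-order descriptor
`H = cov(n^[1,1]) + cov(n^[0,0]) − cov(n^[1,0]) − cov(n^[0,1])` (sample
covariance, n−1 denominator — matched in the decoupled null so the floor
cancels exactly). A Fourier-power variant applies the same combination rule
to the one-sided DFT power of each sample (7 frequencies, DC retained,
frequency axis in cycles/deg from the 9-arcmin sampling).

The drive `λ_d = log(RMS_d/RMS*_d)` (natural log; the base would only
rescale trends) compares descriptor RMS to the decoupled-process
expectation. With `k = √(2/(m·pc·(1−pc)))` the floors are derived from the
sampling variance of the bin statistics: `k·σ_N` for `h`, `k·σ_N/√2` for
`h¹`/`h⁰` alone, `√2·k·σ_N²` for the diagonal of `H` and `k·σ_N²`
off-diagonal. For `λ₂` the off-diagonal region is multiplied by √2 before
pooling so both regions share the diagonal floor. These constants are
validated against a Monte-Carlo decoupled oracle in the test suite (mean
measured/expected RMS within [0.97, 1.03] per region) — the validation is
mandatory because the floor normalisation is what makes drives comparable
across conditions and orders.

Two estimator-level subtleties matter for null tests. First, the log of a
noisy RMS is biased: for n iid Gaussian elements the exact null mean of λ is
`(ψ(n/2) − log(n/2))/2` ≈ −0.039 at n = 13; tests compare mean null drives
against this exact value rather than 0. Second, response conditioning
slightly *reduces* the sampling variance of classified covariances below the
unconditional floor when the observer is strongly stimulus-coupled, so a
calibrated template matcher shows a small negative λ₂ (about −0.02 at
100×6000 trials) — an RMS deficit, not second-order structure. This
decisional-transducer artifact motivates the one-sided rectifier below.

### Eigen-decomposition

`eigendecompose()` takes the symmetric eigen-system of `H` and judges
eigenvalue significance against the pooled SD of eigenvalues from
decoupled surrogates (responses permuted across trials, `H` recomputed;
default 100 shuffles, 3×SD band, positive and negative counts kept
separately). Pooling the null across eigenvalue ranks (rather than
per-rank) matches the single null band used for significance displays; a
per-rank variant would be straightforward but changes nothing tested here.
A caveat discovered with the simulated energy observer: under a broad
read-out window the expected kernel `Fᵀdiag(w)F` is close to
translation-invariant, its leading eigenvalues arrive in near-degenerate
even/odd pairs, and the estimated leading eigenvector's phase is arbitrary —
individual eigenvectors are then Fourier-like and do not reproduce the
front-end profile in space, although their *power spectra* (hence their
sharpness) remain locked to the front-end passband. Conclusions should rest
on spectral properties of the eigenvectors, not on their spatial profiles,
unless the read-out is narrow.

## Metric suite

* **Sharpness** — spectral centroid of the unit-sum one-sided power
  spectrum, in cycles/deg. Degenerate inputs error (all-zero profile);
  a constant profile scores 0 (all power at DC). Noisier descriptors bias
  the centroid upward (flat noise spectrum), which is exactly why the
  eigenvector-sharpness control exists.
* **Linearity / nonlinearity index** — marker 1 is `λ¹ − λ⁰`; marker 2 is
  `(λ₂ − λ₁)·sign(λ₂)`, the orientation that makes "more nonlinear" score
  positive, with `sign(0) = 0` so an exactly linear system scores 0. The
  aggregate is their sum; the linearity index is its negative.
  `nonlinearity_index()` defaults to the literal per-value sign; it also
  accepts a null SD for λ₂ (sign gated to 0 inside 3 null-SD) or an
  externally supplied sign. `run_grid()` uses an *architecture-level,
  one-sided* rectifier: 1 if the grid-pooled λ₂ exceeds 3 pooled-SE, else 0.
  Rationale: the marker is acknowledged to be non-monotone — a per-cell sign
  flips by estimation noise wherever λ₂ ≈ 0 and injects ±λ₁-sized jumps that
  destroy dependence estimates; whether second-order structure exists is a
  property of the observer, not of one condition; and a significant λ₂
  *deficit* (the transducer artifact above) is not evidence of nonlinear
  processing.
* **Dependence** — Pearson correlation of a metric against level indices
  1–4. For contrast this equals correlating against log₂ multiplier (affine
  invariance); `raw_levels = TRUE` correlates against the raw multipliers
  {1, 2, 4, 8} instead. Constant metrics return NA with a warning rather
  than 0, so they drop out of aggregates.
* **Separability** — marginal outer-product prediction `S* = (rΣ·cΣ)/g` and
  the SVD index `v₁²/Σvᵢ²` (squared singular values; 1 iff rank-1,
  lower-bounded by 1/4 for a 4×4 surface).
* **d′ and efficiency** — `d′ = √2·Φ⁻¹(pc)` (the 2AFC difference-rule
  mapping; pc clipped to `[1/(2m), 1−1/(2m)]` when the trial count is
  supplied), efficiency `(d′/SNR)²` since the ideal template observer's d′
  equals the SNR.
* **Trend tests** — thin wrappers over `wilcox.test` (two-tailed signed
  rank; all-zero differences return p = 1) and `friedman.test`.

## Grid experiments and the dipper

`run_grid()` simulates, per grid cell, `n_sims` replicate sessions of
`n_trials_per_condition` trials (drives averaged across replicates; the
replicate SD supplies the λ₂ gate width) plus `n_doublepass_blocks`
double-pass blocks for the internal-noise fit, then assembles metric
surfaces, dependence coefficients and separability indices. The acceptance
checks run 6 replicates of 6000 trials per cell with 30 double-pass blocks —
6000 trials matches the per-simulation mass used for the reference
model-level results, and 6 replicates stabilise the pooled-λ₂ gate; the
vignetted examples use smaller sizes since only signs and structure are at
stake.

`dipper()` measures threshold-versus-pedestal curves on noiseless stimuli:
the non-target carries the pedestal ρ⁰ at the centre bar, the target
ρ⁰ + Δρ. Δρ is swept geometrically (20 probes over ±1.2 decades around a
branch-aware analytic guess, auto-expanded up to 3 times), percent correct
measured by simulation, and the 75% threshold interpolated linearly in
percent correct versus log Δρ — a cumulative-Gaussian fit was considered
and rejected as needless machinery for a monotone, densely sampled sweep.
Pedestals: 0 (detection) plus values spanning two orders of magnitude
anchored on the hybrid model's detection threshold (half a decade below to
1.5 decades above), since the model gives no absolute pedestal unit. A
gain-controlled branch saturates at large pedestals and can cap performance
below 75% for *any* Δρ (a vertical handle); `dipper()` records such points
as NA rather than failing. Acceptance runs use 10 pedestals × 25
simulations × 800 trials — reduced from the reference scale of 50 × 100 ×
1000, which changes threshold SEs but not the shape features under test
(dip below detection threshold for the hybrid, flat linear branch, steeper
energy-branch handle).

## Reproducibility and problem sizes

All randomness flows through R's global RNG; every entry point is
deterministic after `set.seed()`, and `scripts/acceptance.R` derives one
sub-seed per target from its `--seed` argument. The full test suite runs in
under two minutes on one CPU; the acceptance script in well under one.

## Known limitations

- The model observers are stationary and bias-free; nothing here estimates
  or corrects response bias, non-Gaussian internal noise, or higher-order
  Volterra terms.
- Drives carry the small-sample log-RMS bias and the transducer
  variance-suppression artifact quantified above; both are negligible
  against the drive magnitudes of structured observers (λ₁ ≈ 2–3) but
  visible in high-precision null tests.
- Spatial profiles of individual second-order eigenvectors are unreliable
  under broad read-out pooling (degenerate eigen-pairs); use their spectra.
- The dipper's pedestal axis is anchored to the simulated detection
  threshold, not to a physical contrast scale.
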