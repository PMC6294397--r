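# classim

Classification-image analysis of noisy-bar psychophysics, with simulated
model observers.

## The problem

In a classic probe of early spatial vision, an observer views two arrays of
13 vertical bars whose luminances are perturbed by independent Gaussian noise
(SD σ_N), and reports which array carries a luminance offset ρ on its centre
bar (2AFC). Varying the noise contrast (σ_N ∈ {1, 2, 4, 8} monitor units of
0.3 cd/m²) and the signal-to-noise ratio (ρ/σ_N ∈ {1, 2, 3, 4}) yields a
4×4 condition grid over which the *perceptual filter* itself can be
characterised trial by trial:

- **Double-pass internal noise.** Blocks of 50 trials replay trials 1–25 as
  trials 26–50 in permuted order. The fraction correct `pc` and the
  response-agreement fraction `pa` on repeated pairs jointly constrain a
  2-parameter signal detection model — decision variable
  `d_ext + ε_int` with `d_ext ~ N(d′_in, 1)` and `ε_int ~ N(0, N_int)` —
  giving the internal/external noise ratio `N_int`.
- **Classification images.** Sorting the noise samples `n^[q,z]` by interval
  (`q`: target/non-target) and outcome (`z`: correct/error) gives the
  first-order descriptor `h = h^[1] + h^[0]` (difference of bin means) and
  the second-order descriptor
  `H = Σ_{q,z} (2δ_{qz}−1) cov(n^[q,z])`, an operational estimate of the
  second-order Volterra kernel.
- **Drives.** Descriptor amplitude is summarised by
  `λ_d = log(RMS_d / RMS*_d)`, the log-ratio of descriptor RMS to the
  analytic RMS of a response-shuffled (decoupled) process,
  `RMS*_1 = kσ_N`, with `k = sqrt(2/(m·pc·(1−pc)))`.
- **Metrics.** Tuning sharpness (spectral centroid of the descriptor power
  spectrum), an aggregate linearity index built from
  `λ^[1]−λ^[0]` and `(λ_2−λ_1)·sign(λ_2)`, efficiency `(d′/SNR)²` against
  the ideal observer (whose d′ equals the SNR), Pearson contrast/SNR
  dependence of each metric, and two separability estimators for 4×4 metric
  surfaces (marginal outer-product prediction and the SVD index
  `v₁²/Σvᵢ²`).

No human data ship with the package: a family of model observers generates
every dataset. All observers share a difference-of-Gaussians front end
(`f_i = k·φ(x_i, σ₁) − φ(x_i, σ₂)`, unit energy) applied by convolution, a
Gaussian read-out window `w` (SD 40 arcmin) and fixed late Gaussian intrinsic
noise `e`: the template matcher `r = ⟨w, b_lin + e⟩`; the energy model
`r = ⟨w, b_lin² + e⟩` with optional divisive gain control
`b̂_nlin = b_nlin/(0.4 + Σb_nlin)`; the MAX uncertainty rule
`r = max(w·b_lin + e)` with a window that broadens at low contrast; and the
hybrid two-branch model `r = ⟨w, b_lin + b̂_nlin + e⟩`, whose
gain-controlled energy branch dominates at low contrast and is divisively
silenced at high contrast — reproducing the signature contrast-driven
transition from nonlinear to linear behaviour, and the classic dipper
(threshold-versus-pedestal) function.

## Worked example

```r
library(classim)
set.seed(42)

## hybrid two-branch observer, intrinsic noise calibrated to mean d' = 1
cfg <- calibrate_noise_sd(observer_config("hybrid_gc_nlin"),
                          n_trials_per_condition = 1500)
round(cfg$noise_sd, 4)
#> [1] 0.0579

## one low-contrast condition: simulate, classify, summarise
cond <- condition_spec("bright", contrast_level = 1, snr_level = 2)
trials <- make_trials(cond, 6000)
resp <- respond(trials, cfg)
ds <- drive_set(classify_noise(trials, resp))
round(c(pc = mean(resp$correct), lambda1 = ds$lambda1,
        lambda1_tp = ds$lambda1_tp, lambda1_ta = ds$lambda1_ta,
        lambda2 = ds$lambda2, sharpness = sharpness(ds$h)), 3)
#>         pc    lambda1 lambda1_tp lambda1_ta    lambda2  sharpness
#>      0.709      2.670      2.322      2.330      0.185      0.033

## internal noise from 30 double-pass blocks at the same condition
dp <- make_session(list(cond), n_blocks_per_condition = 30, "double_pass")
est <- estimate_internal_noise(summarize_double_pass(respond(dp, cfg), dp))
est
#> <internal_noise_estimate> dprime_in=0.576 N_int=0.475 (mse=2.64e-16, plausible=TRUE)

## full 4x4 grid: contrast dependence of the headline metrics
g <- run_grid(cfg, n_trials_per_condition = 3000, n_sims = 4,
              n_doublepass_blocks = 20)
print(subset(g$dependence, metric %in% c("sharpness", "n_int", "linearity")),
      row.names = FALSE)
#>     metric   contrast         snr
#>  sharpness -0.6928742  0.33655460
#>  linearity  0.4174349 -0.31771016
#>      n_int -0.9528917  0.01049084
```

Reading the output: at low contrast the first-order drive λ₁ ≈ 2.7 (descriptor
RMS e^2.7 ≈ 15× its decoupled floor) with a clearly positive second-order
drive λ₂ ≈ 0.19 — the energy branch is contributing. Across the grid,
sharpness and estimated internal noise fall as contrast rises while the
linearity index rises: the divisive normalisation of the energy branch hands
control to the linear branch at high contrast. `dipper(cfg$noise_sd)`
simulates the matching threshold-versus-pedestal curves (facilitation dip for
the hybrid, flat for the linear branch, steep handle for the energy branch).

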