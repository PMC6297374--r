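# synstab

Stability analysis of muscle-synergy activations in human walking.

## What it does, and for whom

Surface EMG during treadmill walking can be decomposed into a handful of
**muscle synergies** — fixed non-negative weighting vectors over muscles
(`W`) driven by shared time-varying activation coefficients (`C`), via
non-negative matrix factorization:

    M = W C + ε,   W ≥ 0, C ≥ 0

`synstab` is for motor-control and gait researchers who want to quantify
how stable those activation coefficients are from stride to stride, with
two complementary dynamical-systems measures computed on delay-coordinate
reconstructions `S(t) = [q(t), q(t+τ), …, q(t+(d_E−1)τ)]` of each
activation:

* **Local dynamic stability** — the short-term maximum Lyapunov exponent
  λ\*, the OLS slope of the mean log nearest-neighbor divergence curve
  `⟨ln D_j(i)⟩` over the 0–1 stride window (Rosenstein's method), in nats
  per stride. Larger λ\* = faster within-stride divergence.
* **Orbital stability** — the maximum Floquet multiplier, the spectral
  radius of the linearized Poincaré map `S_{k+1} − S* ≈ J(S*)(S_k − S*)`
  fit at each percent of the gait cycle (100 sections per trial);
  magnitudes < 1 mean per-stride perturbations decay.

The full pipeline: zero-lag Butterworth filtering (40 Hz high-pass,
rectify, 10 Hz low-pass) → heel-contact segmentation → 100-point cycle
time-normalization → 30-cycle retention → peak + unit-variance
normalization → NMF with cross-validated VAF model selection (18/12 cycle
splits, 95% CI lower bounds > 90% global / > 75% per muscle) and a
shuffled-data control → cosine-similarity synergy sorting (threshold 0.71)
→ AMI/FNN embedding selection → λ\* and Floquet multipliers per synergy →
speed-band trend slopes.

A first-class synthetic-data module generates EMG with known synergy
structure and tunable stride-to-stride dynamics, plus dynamical oracles
with closed-form stability constants (logistic map, linear stride maps),
so every stage is verifiable without laboratory recordings.

## Worked example

```r
library(synstab)

# 12-muscle, 52-cycle synthetic walking trial with 5 known synergies,
# rendered as raw-EMG-like 1000 Hz signals
sim <- simulate_gait_emg(synth_config(seed = 1), raw = TRUE)

# preprocess to the muscles x 3000 analysis matrix
mat <- preprocess_emg(sim$recording)
mat
#> <emg_matrix> 12 muscles x 3000 time steps (30 cycles x 100 phase points)

# select the number of synergies by cross-validated VAF
vt <- cross_validated_vaf(mat, n_range = 1:6, seed = 1, n_restarts = 2)
n <- select_num_synergies(vt)
n
#> [1] 5

# extract synergies at the selected number
fit <- nmf(mat$values, n, seed = 1)
fit
#> <synergy_set> 5 synergies, 12 muscles x 3000 time steps, global VAF 99.25%

# per-synergy stability: embedding delay from the first AMI minimum,
# unified dimension 6, lambda* over 0-1 stride, Floquet summary over the
# 100 Poincare sections
activation_stability(fit$C, horizon = 200)
#>   synergy tau d    lambda lambda_r2   fm_mean    fm_max lambda_units
#> 1       1  20 6 0.4184843 0.1859741 0.5884863 0.7543755  nats/stride
#> 2       2  16 6 0.9705445 0.7468030 0.5489476 0.6823304  nats/stride
#> 3       3  19 6 0.6517176 0.4980017 0.5739434 0.8744656  nats/stride
#> 4       4  27 6 0.3307675 0.1352576 0.5347591 0.6911335  nats/stride
#> 5       5  21 6 0.4968272 0.2968614 0.5562295 0.7605643  nats/stride
```

Read: every synergy activation is locally unstable within a stride
(λ\* > 0) yet orbitally stable across strides (mean Floquet magnitudes
~0.53–0.59, well below 1) — the characteristic signature of steady gait
dynamics. The delays τ = 16–27% of the gait cycle are where the first AMI
minimum lands for bump-like activation waveforms. The modest fit R²
reflects the additive measurement noise this synthetic trial carries: the
divergence curve rises quickly toward saturation, exactly as in noisy
experimental activations.

The same stages are scriptable from a shell via `inst/scripts/synstab`
(subcommands `simulate`, `preprocess`, `synergies`, `stability`, `trends`,
`run`), and `run_pipeline(pipeline_config(...))` orchestrates everything
end-to-end with a manifest of parameters, seeds and file checksums.

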