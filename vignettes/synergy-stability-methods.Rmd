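---
title: "Methods: local dynamic and orbital stability of muscle-synergy activations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local dynamic and orbital stability of muscle-synergy activations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synstab)
```

## The problem

During steady treadmill walking the central nervous system appears to drive
the leg and trunk muscles through a small number of *muscle synergies*: fixed
non-negative weighting vectors over muscles, each activated by a shared
time-varying coefficient. `synstab` asks how *stable* those activation
coefficients are from stride to stride, using two complementary
dynamical-systems measures:

* **Local dynamic stability** — the short-term maximum Lyapunov exponent
  $\lambda^*$, the average exponential rate at which infinitesimally close
  trajectories of the reconstructed activation dynamics diverge over one
  stride. Positive values mean nearby strides separate; larger values mean
  they separate faster.
* **Orbital stability** — the maximum Floquet multiplier, the dominant
  eigenvalue magnitude of the linearized stride-to-stride (Poincaré) map
  about the mean limit cycle. Magnitudes below 1 mean per-stride
  perturbations decay across subsequent strides.

The two measures answer different questions and can disagree: a gait can be
locally divergent within a stride ($\lambda^* > 0$) yet orbitally stable
(multipliers < 1), because $\lambda^*$ is deliberately fit over a *short*
(0–1 stride) window.

## Pipeline and model

### EMG preprocessing

Raw multi-channel surface EMG is high-pass filtered at 40 Hz (zero-lag
4th-order Butterworth), full-wave rectified, low-pass filtered at 10 Hz
(same filter class) to a linear envelope, segmented at right heel contacts,
and each cycle linearly time-interpolated onto 100 phase points (1 point =
1% of the gait cycle). The first 10 cycles (gait initiation) and everything
after the 30 analyzed cycles — with at least 10 more recorded (gait
termination) — are excluded, giving a muscles × 3000 matrix. Each muscle row
is divided by its own peak and then by its own standard deviation, so all
muscles enter the factorization with unit variance.

Choices the underlying convention leaves open, fixed here:

* *Zero lag* is implemented as a forward–backward pass (the magnitude
  response is squared, effectively 8th order), with odd-reflection end
  padding of three filter lengths per side.
* Interpolation targets phases $k/100$ of the cycle duration, $k = 0..99$,
  endpoint excluded, so consecutive normalized cycles tile without
  duplicating the heel-contact sample; a cycle already on the grid
  round-trips exactly.
* The standard deviation is the population SD (divide by $n$); both the
  peak and SD divisors are retained in a normalization record so either
  convention can be audited or inverted.
* Peak normalization is per muscle by default (`peak_scope = "global"`
  switches to a single global peak).
* The order of operations is exactly: high-pass → rectify → low-pass →
  segment → time-normalize → concatenate → peak-normalize → SD-normalize.

### Synergy extraction and model selection

The matrix $M$ (muscles × 3000) is factorized as $M = WC + \varepsilon$,
$W, C \ge 0$, by multiplicative updates minimizing the squared Euclidean
error (Lee–Seung), run from 20 seeded random restarts (uniform
initialization scaled to the matrix mean) with convergence declared at a
relative residual change below $10^{-6}$ or 1000 iterations; a $10^{-12}$
constant guards the update denominators. Weighting columns are rescaled to
unit norm with the inverse scale absorbed into $C$, leaving $WC$ unchanged.

The number of synergies is selected by cross-validation: each repetition
draws 18 of the 30 cycles (whole cycles, uniformly without replacement) for
training and refits only $C$ on the held-out 12 cycles with $W$ frozen. The
variability accounted for,
$\mathrm{VAF} = \left[1 - \sum (M_o - M_r)^2 / \sum M_o^2\right] \times 100$
(uncentered sums of squares), is scored globally and per muscle on the
held-out data over 10 repetitions; 95% confidence intervals use the
$t$-distribution with 9 df. The selected $N$ is the smallest whose global
CI lower bound strictly exceeds 90% and whose every per-muscle CI lower
bound strictly exceeds 75%. A shuffled-data control (each muscle row
independently permuted, preserving values, range and variance while
destroying inter-muscle structure) provides the chance baseline.

Synergies are sorted across trials by a two-stage cosine-similarity
procedure with threshold 0.71 — the two-tailed critical Pearson correlation
at $\alpha = 0.01$ with $12 - 2 = 10$ df, `critical_similarity_threshold()`
— matching on the weighting vectors *or* the cycle-averaged activation
waveforms, resolving conflicts toward the highest-scoring pair, then
re-matching everything against the group means. Pearson correlation is
available as an alternative score (`method = "pearson"`); cosine is the
default operative score. Synergies clearing no threshold stay unmatched
rather than being forced into a group.

### State-space reconstruction

Each activation row is embedded by delay coordinates
$S(t) = [q(t), q(t+\tau), \ldots, q(t+(d_E-1)\tau)]$. The delay $\tau$ is
the first local minimum of the average mutual information (16 equal-width
bins, lags to 100 samples); the dimension comes from global false nearest
neighbors (Kennel criterion, $R_{tol} = 15$, $A_{tol} = 2$), but the
pipeline default follows the convention of unifying $d_E = 6$ across
subjects and synergies. On the synthetic generator's default output the
selected delays fall at 17–27% of the gait cycle, bracketing the 20–23%
range typical of real synergy activations.

Two estimator details worth knowing:

* The binned AMI of an *exactly periodic deterministic* series (e.g. a pure
  sine) is jagged — exact state recurrences starve the joint histogram —
  and its first local minimum is not a reliable quarter-period detector
  there. On noisy, aperiodic physiological activations (the estimator's
  target domain) the curve is smooth and the first minimum well defined;
  the test suite asserts the quarter-period *decorrelation* property for
  the sine rather than a specific minimum location.
* In the FNN test, neighbor pairs closer than $10^{-8}$ × series SD are
  treated as genuine (recurrences of the same state): the Kennel distance
  ratio is numerically meaningless at such separations.

### Short-term maximum Lyapunov exponent

Following the nearest-neighbor divergence approach, each embedded point is
paired with its Euclidean nearest neighbor at temporal distance greater
than a Theiler window of 100 samples (one stride, the mean-period rule);
pairs with exactly zero initial separation are dropped (no divergence
information; $\ln 0$ undefined). The mean log distance
$\langle \ln D_j(i) \rangle$ is tracked for $i = 0..1000$ samples and
$\lambda^*$ is the OLS slope over $i \in [0, 100]$ — both endpoints
included, no weighting — scaled by 100 samples/stride and reported in
**nats per stride**. The fit window and $R^2$ accompany every result.
$\lambda^*$ is invariant to amplitude rescaling of the series, and the
estimator reproduces the logistic-map ($r = 4$) exponent $\ln 2$ within a
few percent when fit over the pre-saturation steps.

### Maximum Floquet multipliers

A Poincaré section is taken at every percent of the gait cycle — 100
sections per trial. The state of stride $k$ at phase $p$ is the delay
embedding starting at sample $(k-1) \cdot 100 + p$; strides whose embedding
window $(d_E - 1)\tau$ runs past the series end are dropped from the
affected sections only, so all 100 sections always exist. The fixed point
$S^*$ of each section is the mean state (average trajectory), and the
linearized map $S_{k+1} - S^* \approx J(S^*)(S_k - S^*)$ is fit by least
squares over all consecutive-stride pairs via SVD pseudoinverse
(rank-deficient deviation sets fall back to the least-norm solution,
flagged per section). The maximum Floquet multiplier is the spectral radius
of $J$; the trial summary is the mean across the 100 sections (the max is
also reported), with "orbitally stable" meaning the summary statistic is
below 1. For simulated linear stride maps with a known fixed point,
`fit_jacobian(..., fixed_point =)` accepts the true $S^*$ — the transient
sample mean of a decaying trajectory is a biased fixed-point estimate, and
with the true value supplied the noiseless recovery is exact to machine
precision.

### Speed trends

`increasing_rates()` regresses a stability measure on walking speed
separately within a slower and a faster band per subject and synergy and
returns both slopes and their paired difference; hypothesis testing is left
to standard routines. The default bands are 2.0–5.0 and 5.0–8.0 km/h with a
shared 5.0 boundary; the disjoint convention (fast band from 5.5) is a
parameter away, since the source conventions differ between their text and
figure definitions. A synergy observed at fewer than two speeds within a
band (e.g. a mid-swing synergy absent at the slowest speeds) is marked
not-computed rather than zero.

## The synthetic generator

`synth_config()` defaults encode the study conditions the pipeline targets:
12 muscles at 1000 Hz, 52 recorded cycles (protocols record "over 50"; 50
complete heel-contact-to-heel-contact cycles remain, supporting the
10/30/10 retention rule), 5 synergies with one circular-Gaussian activation
bump per cycle centered at 15, 40, 60, 80 and 97% of the cycle (body
support, forward propulsion, swing initiation, mid-swing, late swing), and
additive noise at 5% of signal SD, clipped at zero.

Cycle-to-cycle dynamics enter through the bump *parameters* — each cycle's
center and amplitude follow AR(1) dynamics
$x_c = \rho x_{c-1} + \sigma \epsilon_c$ around the configured means — so
stride-to-stride variability is controllable while the mean cycle stays
fixed. The innovation scale $\sigma$ (`phase_jitter_sd`, in % cycle;
default 1.5) is the operative "instability knob" for stability sweeps:
raising it increases the per-stride perturbation magnitude, which raises
$\lambda^*$, while the fitted stride-map spectral radius — hence the
Floquet summary — is governed by the persistence $\rho$ (default 0.3) and
stays flat. Sweeping $\rho$ itself at fixed stationary variance would
*shrink* the innovations as $\rho \to 1$, which is why the jitter scale,
not $\rho$, is swept. This reproduces, at desk scale, the qualitative
pattern of interest: rising local instability with invariant orbital
stability.

What the generator does *not* emulate: subject-specific EMG morphology,
electromechanical delay, crosstalk, nonstationary fatigue drift, or
speed-dependent changes in bump timing. Passing tests on synthetic data
therefore validate the *estimators and plumbing*, not any claim about real
gait.

Raw mode (`simulate_gait_emg(..., raw = TRUE)`) up-samples each cycle's
envelopes to a duration-jittered 1000 Hz grid and multiplies by zero-mean
wideband carrier noise, so the full filter–rectify–envelope chain can be
exercised from raw-like input; dynamical oracles with closed-form answers
(`logistic_map`, exponent $\ln 2$ at $r = 4$; `linear_stride_system`, known
spectral radius) calibrate the Lyapunov and Floquet estimators.

## Numerical choices and degenerate inputs

* NMF denominators guarded by $10^{-12}$; residual is non-increasing at
  every update (property-tested).
* Constant (zero-variance) muscle rows, zero weighting columns, zero
  vectors in cosine similarity, constant series in AMI, and too-short
  series everywhere raise informative errors rather than propagating NaN.
* First-local-minimum ties resolve to the first index of a plateau; a
  curve with no interior minimum falls back to the global minimum with a
  flag, mirrored by the FNN dimension fallback.
* OLS $R^2$ of a constant response is reported as 0.

## Problem sizes used in tests and the acceptance script

Scaled-down but structurally faithful sizes keep the suites fast while
preserving every contract: candidate synergy numbers run over 1–6 in
selection experiments (the rule returns the *smallest* qualifying $N$, and
the qualifier is 5 by construction, so restricting the contiguous range
above 6 cannot change the answer; the user-facing default remains 1–12);
cross-validation inner fits use 2 restarts at tolerance $10^{-5}$ and at
most 500 iterations; divergence horizons of 150–200 samples cover the
0–100-sample fit window with margin; sweep experiments use 6 jitter levels
(0.25–2.0% cycle) × 10 seeds. The sweep stops at 2% cycle because the
activations are bounded: beyond that the nearest-neighbor divergence
saturates within the 0–1 stride window and $\lambda^*$ plateaus, so larger
jitters probe the saturation, not the response. The pipeline smoke test
runs 3 synthetic conditions with 3 CV repetitions over candidate range
4–6.

## Known limitations

* The Floquet spectral-radius estimate from a noisy 6×6 Jacobian is
  upward-biased (a max over noisy eigenvalues); averaging across seeds or
  sections is recommended, and the per-trial summary does exactly that.
* $\lambda^*$ units (nats/stride) assume the 100-points-per-cycle grid;
  applying the functions to differently sampled series requires adjusting
  `samples_per_stride`, the Theiler window and the horizon together.
* The matcher's greedy conflict resolution is order-independent given
  distinct scores but does not globally optimize the assignment; with ≤ 6
  synergies per trial this is immaterial in practice.
* Hypothesis tests on speed trends (repeated-measures ANOVA, post hoc
  contrasts, normality checks) are intentionally out of scope; the package
  returns the per-subject slopes and paired differences those tests
  consume.
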