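---
title: "Transient brain states from amplitude envelopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient brain states from amplitude envelopes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented by `envhmm`, the choices the
implementation makes where a choice was genuinely open, and what the
synthetic-data tests do and do not establish about real recordings.

## The generative model

The data are band-limited oscillatory amplitude envelopes: the magnitude of
the analytic signal of band-pass-filtered (4–30 Hz by default) source-space
activity, downsampled to 40 Hz, spatially smoothed, demeaned and
variance-normalized per subject, and concatenated over subjects. After
PCA whitening to `M` components (40 by default), the model for the scores
`y_t ∈ R^M` is a K-state hidden Markov model:

* a hidden chain `s_t ∈ {1…K}` with initial distribution `π_0` and a
  row-stochastic transition matrix `π`;
* per state, a multivariate normal observation model
  `y_t | s_t = k ~ N(μ_k, Σ_k)` — states are distinguished by both their
  mean *and* covariance over components, which is what lets them encode
  whole-brain patterns of oscillatory power and covariation.

Mutually exclusive states with sample-by-sample switching are the point of
the method: where sliding-window connectivity is forced to average over
seconds, the HMM can assign every 25 ms sample.

## Variational inference

Priors are conjugate and weakly informative on whitened data:

| hyperparameter | default | meaning |
|---|---|---|
| Dirichlet concentration (transition rows, `π_0`) | 1 per entry | flat over the simplex |
| Gaussian–Wishart prior mean `m_0` | 0 | whitened data are centered |
| mean-precision scale `β_0` | 1e-3 | broad prior on state means |
| Wishart degrees of freedom `ν_0` | M | minimal proper value |
| Wishart inverse scale `W_0⁻¹` | `M · I` | prior expected precision `ν_0 W_0 = I`, matching unit-variance scores |

All of these are arguments of `hmm_prior()`.

The posterior factorizes over the hidden chain and the parameters. The
E-step runs forward–backward recursions (per subject segment, in C++) under
the *expected* log parameters — `E[ln π]` from the Dirichlet posteriors and
the expected Gaussian log density under the Gaussian–Wishart posteriors.
The recursions are normalized per sample, so chains of 10⁶ samples pose no
underflow risk; the accumulated log normalizers give the collapsed bound.
The M-step is the standard conjugate update from responsibility-weighted
sufficient statistics. The free energy is reported as

```
F = − log Z̃  +  KL(q(π_0)‖p) + Σ_rows KL(q(π_row)‖p) + Σ_k KL(q(μ_k, Λ_k)‖p)
```

with lower values better; `−F` approximates the log model evidence. `F` is
non-increasing over E/M iterations on every fixture (asserted in the test
suite), and for K = 1 the converged bound is tight: it equals the
closed-form conjugate log marginal likelihood to ~1e-13, which the tests
verify against an independently coded formula.

**Initialization.** Each restart seeds `stats::kmeans` on the scores and
softens the resulting partition into responsibilities (90% on the assigned
state), followed by an M-step. Near-symmetric random responsibilities were
rejected after measurement: they start the optimizer next to the symmetric
saddle point of the variational objective, where the free energy barely
moves for many iterations (defeating any relative-change stopping rule) and
from which even hundreds of forced iterations frequently fail to escape.
The k-means partition breaks the symmetry decisively; a sparse random
assignment is the fallback if k-means degenerates. Ten restarts are run by
default and the realization with the lowest final free energy is kept.

**Convergence.** Relative free-energy change below `tol = 1e-5` with a
minimum of 5 iterations, capped at `max_iter = 500`.

**Segments.** Concatenated subjects are not one long recording: each
segment restarts the chain from `π_0`, no transitions are counted across
boundaries, and Viterbi decoding runs per segment. This avoids inventing a
spurious cross-subject transition at every boundary.

**Determinism.** Everything downstream of a seed is reproducible
bit-for-bit; ties (Viterbi, argmax of maps and sweeps, PCA component signs)
break deterministically toward the lowest index / largest-magnitude-positive
loading.

## Envelope preparation

The per-subject order is fixed: band-pass → (optional beamformer) → Hilbert
envelope → windowed downsampling → spatial smoothing → demean/normalize →
concatenate.

* Filters are Butterworth (order 5 by default), applied forward and
  backward for zero phase. The forward–backward passes use odd-reflection
  padding and steady-state initial conditions; without them, narrow-band
  filters (0.5 Hz at 40 Hz sampling) leave seconds-long edge transients —
  a constant series should pass a low-pass unchanged, and here it does,
  exactly.
* The Hilbert envelope is computed in the frequency domain (positive
  frequencies doubled); it is exact for the interior of a tone and tracks
  amplitude modulators, both asserted in tests.
* Downsampling averages within 100 ms windows at 75% overlap (200 Hz → 40
  Hz); trailing partial windows are dropped rather than zero-padded, which
  would bias window means low.
* Spatial smoothing is a Gaussian kernel over voxel coordinates,
  `σ = FWHM / (2√(2 ln 2))`, weights renormalized per voxel so a uniform
  field is a fixed point.
* "Normalized by the global variance" is implemented as division by the
  global (pooled over voxels and samples) standard deviation after
  per-voxel demeaning, giving each subject block pooled variance 1;
  dividing by the variance itself would make the result depend on the
  data's units.

## Beamformer

The LCMV scalar beamformer uses the textbook weights
`w' = [h'C⁻¹h]⁻¹ h'C⁻¹` with unit gain `w'h = 1` enforced to 1e-8 in tests.
Two places needed a decision:

* **Orientation.** The dipole orientation maximizes the projected SNR ratio
  `(v'H'C⁻¹Hv)/(v'H'C⁻²Hv)`, solved as a 3 × 3 generalized eigenproblem.
  When the ratio is flat (e.g. `C ∝ I`, where numerator and denominator
  coincide), the tie breaks by maximizing projected power within the
  degenerate eigenspace, which reduces to the leading right-singular
  direction of the whitened lead field. Zero lead-field columns are treated
  as inactive axes (their orientation component is 0); linear dependence
  among active columns is an error. A relative jitter ladder guards the
  factorization when the covariance is nearly singular (rank-one data plus
  a tiny ridge).
* **Noise normalization.** The projected time course is divided by
  `√(w'w)`: `w'w` is the variance of projected uncorrelated unit sensor
  noise, so dividing by its square root gives every location unit noise
  variance — the standard neural-activity-index convention. The tests
  verify that for white sensor noise the normalized variance is 1 and
  independent of the lead-field scale (the depth-bias correction).
* Covariance regularization is a diagonal ridge scaled by the mean sensor
  variance, default 0; the estimate errors out when the (regularized)
  covariance is numerically singular rather than silently pseudo-inverting.

## State statistics

Hard Viterbi indicators, not thresholded marginals, define the state time
courses. Conventions:

* The virtual sample before each segment is "no state", so a run that
  opens a segment counts as an occurrence; without this the occurrence sum
  is undefined at the first sample.
* Mean interval length is implemented exactly as
  `(T − Σ_t(u_t = k)) / occurrences(k)` even though that is not the
  literal mean gap between consecutive visits (it also counts time before
  the first and after the last visit). The literal statistic is provided
  separately as `mean_gap_between_visits()` so nobody has to guess which
  one a number is.
* The identity `mean_life_time × occurrences × sampling_rate = total dwell
  samples` holds exactly and is asserted against an independent run-length
  encoding on 1000 random paths.
* Diagonal masking of the transition matrix (for display) sets `NA` without
  renormalizing rows.
* Both the posterior expected transition matrix and the empirical
  within-segment frequency matrix are available, since either may be
  wanted and they differ in finite samples.

## Partial-correlation maps

The state maps regress each voxel's envelope on the state-indicator design.
This is the one place where the obvious construction is ill-posed, and the
implementation deviates deliberately from it. With mutually exclusive,
exhaustive indicators the columns sum to one, so the design plus an
intercept — equivalently, any internally demeaned design — is exactly
collinear: given the mean and the other states, state k's indicator carries
no information at all, and a voxel's mean offset leaks into every other
state's residual direction (a voxel equal to one state's indicator plus
noise acquires spurious partial correlations near −0.9 for *other* states
under any centered definition; a minimum-norm pseudoinverse solution
spreads a single state's effect across all states). The well-posed
quantity is the partial correlation in the **no-intercept** GLM on the raw
indicators: residualize the voxel and `x_k` on the raw other columns and
take the uncentered correlation of the residuals, which equals
`t/√(t² + df)` for that regressor. Both identities — the residualization
and the t-statistic form — are used as independent oracles in the tests,
agreeing to 1e-10.

Signed maps (state-specific increases *and* decreases) arise because the
pipeline hands this statistic per-voxel-demeaned envelopes, not because the
statistic centers anything itself; it is invariant to rescaling a voxel but
deliberately not to shifting it. The GLM always runs on full-rank envelope
data, never on PCA scores, so maps live in anatomical space. A state absent
from the decoded path is dropped with a warning and reported as `NA`.
Thresholding (e.g. display of the 60–100% range of the per-state maximum)
is presentation-only.

## Timescale analyses

`fo_window_sweep()` asks at which timescale a state's fractional occupancy
best explains an envelope: for each window width the occupancy regressor is
computed at a one-sample step — maximal overlap, so regressor and envelope
share a time base without interpolation, with the regressor aligned to the
envelope sample at the window center — and the correlation recorded. The
default width grid is logarithmic over 0.1–8 s. On synthetic envelopes
whose only fast structure is state switching (mean dwell 6 samples at 40
Hz) the sweep peaks at ≤ 0.5 s; after low-passing the same envelopes below
0.5 Hz it peaks at ≥ 0.8 s. That contrast — fast states, slow control — is
asserted in the acceptance tests, and `add_bandlimited_noise()` provides
the complementary control of injecting spectrally matched noise. The
amplitude of that control noise is a required argument, not a default,
because no principled value exists independent of the data at hand.

## Synthetic data: what it emulates, and what it does not

The generators produce exactly the statistical structure the model assumes:
geometric dwell times induced by self-transition probabilities
(`mean_lifetime_samples` maps to `p = 1 − 1/mean`, the HMM's own dwell
law, so recovery tests are well-posed), Gaussian emissions, non-negative
envelope-like voxel data as baseline + state topography + noise rectified
at zero, independent chain restarts per subject, and dipolar sensor
mixtures. Deliberately **not** emulated: 1/f spectral shape and temporal
autocorrelation of real envelope noise, spatially correlated sensor and
source noise, inter-subject topography variability, head-geometry-realistic
lead fields, and artifacts. Passing tests therefore demonstrate that the
implementation is correct and that the method recovers the truth *when the
model's assumptions hold*; they say nothing about robustness to the many
ways real MEG violates those assumptions.

The canonical recovery fixture (`example_ground_truth()`) fixes K = 4
states, M = 10 dimensions, self-transition 0.9, means at exact unit
pairwise separation, and per-state covariances `σ²(I + u_k u_kᵀ)` with
σ = 0.25 and a seeded random unit vector `u_k`. The covariance scale is the
one genuinely free parameter: it places the means about 4 noise standard
deviations apart, the separation regime a recovery test presumes (with
unit covariances the same means sit 1 σ apart and even the *generating*
parameters cannot decode the chain much above 70–83% accuracy — no
inference algorithm could pass a 90% recovery bar there), and the distinct
rank-one structure makes covariance recovery a non-trivial check. The
envelope fixtures use topography gains of 1.5 against noise σ = 0.4,
strong enough for reliable segmentation, weak enough that the maps stay in
the statistic's linear regime.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make the statistics sharp while keeping a full run in tens
of seconds: exhaustive-oracle grids at K ∈ {2,3}, T ∈ {2…8}; the recovery
fixture at T = 48000 (20 minutes at 40 Hz) with 10 restarts; envelope
fixtures of 15000–24000 samples; 10⁵-sample chains for empirical
transition and dwell statistics. Other numerics: covariances are handled
through Cholesky factors; the Wishart inverse scales are symmetrized each
M-step; a state with numerically zero responsibility keeps its prior;
`fit_hmm` refuses constant (zero-variance) components, band edges at or
above Nyquist are errors, and degenerate sweep regressors (a window
covering the whole series) yield `NA` rather than a spurious correlation.

## Limitations

Observation models are Gaussian only (no autoregressive emissions); there
is no per-subject HMM with post-hoc state matching; model-order selection
is reported (free energy, minimum fractional occupancy, mean life time per
K) but not automated, since the free energy typically keeps improving with
K and the choice is ultimately about the granularity a study needs. NIfTI
export requires voxels on a regular grid. Real-data concerns — artifact
rejection, coregistration, lead-field computation — are upstream of this
package and out of its scope.
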