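---
title: "Predicting treatment outcomes from static and dynamic network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting treatment outcomes from static and dynamic network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Resting-state fMRI studies of brain-stimulation therapies commonly ask
whether changes in functional network connectivity (FNC) between a
baseline visit (v1) and a post-treatment visit (v3) carry enough
information to predict each patient's clinical response. `fncpredict`
implements the full analysis chain for this question, starting from
per-scan intrinsic connectivity network (ICN) time courses (one column
per network, e.g. the 53 networks of a spatially constrained ICA
template, organized into seven functional domains):

1. **Time-course post-processing** — polynomial detrending (up to cubic),
   regression of the six realignment parameters and their temporal
   derivatives, median/MAD despiking with interpolation, and zero-phase
   0.01–0.15 Hz band-pass filtering, in that order.
2. **Static FNC** — Pearson correlation between post-processed time
   courses, per-scan z-scoring, upper-triangle vectorization
   (C(C−1)/2 = 1378 features for C = 53), and v1 − v3 change features.
3. **Dynamic FNC** — 20-TR sliding windows stepped by 1 TR, with a
   graphical-lasso (L1-penalized inverse covariance) estimate of each
   window's correlation matrix.
4. **Meta-state global dynamism** — fuzzy k-means over all windows
   pooled across subjects (k = 5 connectivity patterns), discretization
   of the membership weights into 8 signed bins, and four per-scan
   summaries: number of distinct meta-states, number of switches,
   occupied range (maximal L1 separation), and total travelled distance.
5. **Outcome prediction** — partial least squares regression (PLSR) of
   the percentage score change `100 (v1 − v3) / v1` on the static
   (P = 1378) or combined (P = 1382) change features, inside a repeated
   ten-fold cross-validation harness with per-repetition accuracy r and
   R², permutation nulls, covariate deconfounding, and a Welch t
   comparison of the static-only and combined accuracy distributions.
6. **Weight anatomy** — element-wise mean and SD over all
   repetitions × folds coefficient maps (10,000 maps for 1000 × 10),
   positive/negative sums per 7 × 7 functional-domain pair normalized by
   pair size, ranked strongest connections, and cross-outcome weight-map
   correlations.

Because clinical imaging data of this kind are access-restricted, the
package ships a first-class synthetic cohort generator
(`generate_cohort()`) whose planted ground truth makes every stage
testable end to end.

## The synthetic cohort: what it emulates

Each subject contributes two scans (v1, v3) of T × C time courses
(default T = 400 volumes, the length of a 4:58 acquisition at
TR = 0.745 s; the default cohort is 50 subjects). A scan is generated
as:

* a **semi-Markov latent state sequence** over `n_latent_states`
  covariance states, dwell times `1 + Geometric(1/state_dwell)`; states
  are visited in cyclic order from a random start. The cyclic order
  keeps every state's long-run occupancy at 1/k whatever the dwell time,
  which matters for identifiability: with uniformly random transitions,
  a subject's switching speed leaks into the realized state occupancy
  and hence into the *static* time-averaged correlation, and the static
  and dynamic channels of the planted outcome become confounded. With
  balanced occupancy, switching speed is visible only to the dynamic
  branch — which is exactly the contrast the package needs to test.
* **state covariances** built from a shared sparse diagonally dominant
  precision backbone, with each state adding one strongly connected
  module on its own contiguous block of networks. Sparse precisions make
  the graphical-lasso stage meaningful; the per-state modules keep
  distinct states separable in 20-TR windows of any cohort draw.
* **nuisance structure**: random cubic drift, a linear mixture of six
  random-walk motion parameters (so the motion-regression stage is
  consequential), and sparse high-amplitude spikes (so despiking is
  consequential), all recorded in the ground truth.

The outcome percentage change is a *planted linear combination* of the
subject's **true** v1 − v3 connectivity differences (driven by a
per-scan loading on a chosen edge set, SD `static_delta_sd`) and
**true** v1 − v3 dynamism differences (driven by a log-normal per-scan
dwell multiplier, SD `dwell_log_sd`), plus Gaussian noise. Outcomes are
computed from the generator's own covariances, not from estimated FNC,
so estimation error stays genuine noise in recovery experiments. With
`target_r2` set, the noise SD is calibrated analytically so that the
planted signal explains exactly that share of outcome variance
(`ground_truth$oracle_r2`).

What the generator does **not** emulate: hemodynamics, spatial maps,
scanner drift structure, site effects, non-Gaussian physiological noise,
or outcome nonlinearity. Passing tests therefore demonstrate that the
*pipeline* recovers what it is designed to recover under its own model
class — not that real clinical outcomes are predictable at any
particular accuracy.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `detrend_order` | 3 | polynomial trends removed per column |
| `despike_mad_threshold` | 4 | MAD multiplier for outlier flagging |
| `band_low_hz`, `band_high_hz` | 0.01, 0.15 | Butterworth passband (Hz) |
| `filter_order` | 5 | Butterworth prototype order (applied forward–backward) |
| `window_tr`, `step_tr` | 20, 1 | sliding-window length and step (TRs) |
| `glasso_lambda` | 0.1 | L1 penalty on the per-window precision |
| `k`, `fuzziness` | 5, 2 | connectivity patterns and fuzzy exponent |
| `folds`, `repetitions` | 10, 100–1000 | CV harness geometry |
| `n_components`, `select` | 10, `"cv"` | PLS component budget and selection mode |

## Design choices where the method description is open

* **z-scoring scope.** Connectivity matrices are standardized within
  scan across their own off-diagonal entries (`zscore_fnc()`). This is
  the only scope computable per scan without sharing statistics across
  subjects; a cohort-wide per-feature alternative (`zscore_features()`)
  is provided. The choice changes feature scales, not their rank order
  within a scan.
* **Graphical-lasso conventions.** The penalty applies to the precision
  matrix (diagonal included, the standard covariance-dual formulation,
  so the estimated covariance is `S + lambda I` on the diagonal), and
  the reported per-window matrix is the correlation implied by the
  inverse of the estimated precision — not a partial-correlation map.
  `glasso_lambda` is fixed rather than tuned per subject, for
  determinism; windows are rectangular and untapered. Consecutive
  windows warm-start the block coordinate descent; if a stale warm
  start stalls convergence the solver silently restarts cold, and only
  a cold-start failure is an error.
* **Meta-state discretization.** Membership weights are cut at the
  cohort-pooled octiles into the 8 signed bins −4…−1, +1…+4 (centering
  each pattern on its cohort median, then quartiles of each half). The
  bin map is monotone and deterministic; constant membership columns
  are rejected as uninformative. Distances in meta-state space are L1.
* **Pattern fitting is group-level.** Fuzzy k-means is fitted on
  windows pooled over all subjects and sessions so that meta-states are
  commensurable across the cohort; per-subject patterns would make the
  four dynamism measures incomparable between subjects. Note this means
  pattern centroids and bin edges see all scans — when prediction
  features are derived from them, those statistics are fitted outside
  the CV loop. For the four global dynamism summaries this is a
  scale-setting step shared by all subjects, and the outcome never
  enters it; the accuracy-relevant statistics (feature standardization,
  component count, coefficients) are always fitted inside training
  folds only.
* **Dynamism features entering prediction** are v1 − v3 differences of
  the four measures, mirroring the static change-feature convention.
* **PLS component count** is selected per training fold by inner
  5-fold CV over 1…10 components (minimizing held-out squared error,
  refitting on the full training fold), the default `select = "cv"`. A
  fixed-count mode exists for large bookkeeping runs where accuracy is
  not the question. On low-rank planted signals the inner CV typically
  chooses 1–2 components and is markedly more accurate than any fixed
  larger count.
* **Model comparison** is a two-sample Welch t-test between the two
  1000-length per-repetition accuracy vectors run on identical fold
  partitions (same seed); a paired test is available
  (`compare_models(..., paired = TRUE)`) and is more powerful, but the
  two-sample form is the default reporting convention. The package's own
  shipped directional checks of the static-vs-combined contrast use the
  paired form, since the repetition-level gain on shared partitions is
  exactly the paired quantity; both forms are reported by the
  reproduction script.
* **Permutation tests** recompute the full CV at a reduced repetition
  count per permutation (recorded in the result) and use the
  add-one estimator `p = (1 + #{null ≥ obs}) / (1 + n_perm)`, which is
  valid at any repetition count.

## Numerical choices

* Detrending and nuisance regression are QR-based least-squares
  projections; rank-deficient designs drop collinear columns with a
  warning. Motion derivatives are backward differences with a zero
  first row.
* Despiking interpolates flagged samples linearly between the nearest
  clean neighbours; edge flags take the nearest clean value. A fully
  flagged column is an error, not a silent repair.
* The band-pass removes the column mean before filtering (DC lies
  outside the passband; subtracting it avoids edge transients of the
  forward–backward pass).
* The graphical lasso converges when the mean absolute off-diagonal
  covariance update falls below `tol` times the mean absolute
  off-diagonal of S; the returned matrix is re-symmetrized with an
  exact unit diagonal. The 2 × 2 solution has the closed form
  `soft(s12, lambda) / (1 + lambda)`, used as a test anchor.
* Fuzzy k-means inherits `e1071::cmeans`; degenerate fits (coincident
  centroids or an empty pattern) are refit with an incremented seed and
  a warning.
* PLS extraction stops early if the deflated cross-covariance or score
  norm underflows; coefficient recovery solves the small triangular
  `P'W` system rather than inverting anything of size P.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` exercise the pipeline at
sizes chosen to finish on one CPU while keeping every stage
scientifically meaningful: the weight-map bookkeeping run uses the full
1000 × 10 CV geometry at N = 50, P = 1382 (fixed 5 components); the
planted static-effect recovery cohort uses N = 50, C = 20, T = 400, a
10-edge planted support and oracle R² = 0.4 with 100 CV repetitions;
the static-vs-combined contrast cohorts use N = 50, C = 15, T = 400,
three latent states (dwell 35 TRs, log-SD 1.2) with effects
`c(0, 6, 0, 1.5)` on the true dynamism differences; the permutation
calibration uses 200 null datasets × 99 permutations at reduced CV
settings. Oracle cross-checks (brute-force dynamism, proximal-gradient
graphical lasso, SIMPLS) run at toy sizes.

## Known limitations

* All models are linear; no nonlinear prediction is attempted.
* The graphical-lasso penalty level is a fixed default, not tuned.
* Meta-state patterns come from fuzzy k-means memberships; no ICA
  rotation of centroids is applied.
* The generator's spike, drift and motion models are simple linear
  contaminations; they exercise the cleaning stages but do not imitate
  any scanner's artifact physics.
* Only one scan per visit is simulated and consumed; studies with
  repeated scans per visit need an upstream selection or averaging
  rule.
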