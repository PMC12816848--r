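---
title: "Threshold-weighted overlap mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-weighted overlap mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twomapper)
```

# The consistency model

`twomapper` operates on a cohort of co-registered, *unthresholded*
z-statistic volumes, one per subject. The central quantity is per-voxel:
let `s_1 … s_N` be the subjects' (neighbourhood-sampled, masked) statistics
at a voxel, and

$$O(t) = \frac{1}{N}\,\#\{\,i : s_i \ge t\,\}$$

the fraction of subjects activating at or above threshold `t`. `O` is the
empirical survival function of activation across the cohort: non-increasing,
taking values `k/N`. Sweeping `t` over `n` even steps spanning `(0, t_max]`,
the threshold-weighted consistency is the weighted Riemann sum

$$C = \frac{\sum_i w(t_i)\,O(t_i)}{\sum_i w(t_i)}, \qquad
  w(t) = t \ \text{(linear, default)} \ \text{or} \ w(t) = 1.$$

`C` lies in `[0, 1]`: 1 when every subject reaches the voxel's peak level,
0 when no subject activates. The linear weight encodes that a large
semantic-vs-control signal difference is stronger evidence of genuine
involvement than a marginal one, so higher statistical levels count more.
The uniform weight is the plain AUC of the survival curve; because `O` is
non-increasing, uniform weighting never gives a smaller value than linear
weighting.

For a worked closed form, take three subjects with samples `(2, 1, 0)`.
Then `O(t) = 2/3` on `(0, 1]` and `1/3` on `(1, 2]`, so in the continuous
limit `C_linear = ∫ t·O(t) dt / ∫ t dt = (5/6)/2 = 5/12` and
`C_uniform = 1/2`. The discrete sweep converges to these values with grid
error below `1/n`:

```{r closedform}
weightedConsistency(overlapCurve(c(2, 1, 0), nGridSteps = 1000), "linear")
weightedConsistency(overlapCurve(c(2, 1, 0), nGridSteps = 1000), "uniform")
```

## Assumptions

* All maps share one grid and one affine. A mismatch is an error, never an
  implicit resample: registration to the template is an upstream
  preprocessing responsibility and silent resampling would change the
  statistics being compared.
* Non-activation is `z ≤ 0`. Loaders therefore replace NaN/Inf with 0 (and
  report the count), and all masking writes zeros outside the mask.
* Statistics are z-equivalents of first-level GLM contrasts, so `z = 3.1`
  (`p < 0.001`) is used throughout as the conventional single-subject
  significance level.

# The pipeline and its parameters

`computeTwomMap()` chains four stages; each parameter below is exposed with
its default.

**Relevant-voxel selection** (`relevantVoxelOptions()`). Per subject, a
voxel is eligible when `z > minZ` (default 0, exclusive) and its connected
suprathreshold component has at least `minClusterVoxels` voxels (default
10, 26-connectivity): clusters under 10 voxels (< 0.1 cm³ on a 2 mm grid)
are discounted as spatially unreliable outlier activations. The analysis
mask keeps voxels eligible in at least `minSubjects` subjects (default 1 —
deliberately permissive so single-subject effects, the clinically
interesting outliers, are not erased; the original method's value of 2 is a
flag away). `upperZCap` (default none) *winsorises* values above the cap
instead of excluding them: exclusion would turn the strongest activators
into apparent non-activators and invert the metric's meaning.
`mode = "all_voxels"` drops the cluster criterion for exhaustive searches.

**Neighbourhood sampling** (`radiusMm`, default 2; `aggregate`, default
`"max"`). Each subject's value at a voxel is the aggregate over all voxels
whose centre lies within the radius — on a 2 mm grid, the centre plus its 6
face neighbours. Gyral anatomy varies across individuals even after
nonlinear registration, so exact voxel-to-voxel correspondence is too
strict; the sphere absorbs ±1-voxel misalignment. The maximum is the
default aggregate precisely because the sphere exists to *tolerate jitter*
(a mean would re-dilute a correctly-detected but displaced activation); the
mean is available by flag. One consequence to keep in mind: the max of
several noise voxels is positive more often than a single noise voxel
(empirically ≈ 0.75 per subject for smoothed unit noise at radius 2 mm), so
engagement at `tau = 0+` has a nonzero floor on pure noise. Engagement at
`tau = 0` is therefore a map of "any activation at all", not a specific
detector; specific claims should use `tau = 3.1` or the consistency map
itself, and the radius-0 map is available when an undilated picture is
wanted.

**Threshold grid** (`gridMaxRule`, default `"per_voxel"`; `nGridSteps`,
default 100). The top of the sweep is the peak sampled value at the voxel.
The phrase "the peak detected in the individual subject data" is ambiguous
in scope, so the package makes the rule explicit and selectable:
`"per_voxel"` (self-normalising — a voxel where all subjects agree at
z = 2 is as consistent as one where all agree at z = 8), `"global"` (one
cohort-wide maximum; comparable across voxels but dominated by the single
strongest activation), and `"fixed"` (an explicit cap such as 3.1). With
100 steps the discretisation error is bounded by 1/100, far below the
1/N resolution of `O` for any feasible cohort; the bound is verified
numerically in the tests. Under linear weighting the grid-top factor
cancels from the ratio, so per-voxel grids cost nothing extra.

**Weighting** (`weighting`, default `"linear"`). The original formulation
of the method is described only as allocating "more value" to higher
signals; linear-in-`t` is this package's explicit choice of that weighting,
labelled as such, with uniform as the alternative.

# Engagement, profiles and atypicality

`engagementMap(cohort, tau)` reports, per voxel, the fraction of subjects
whose sampled masked value meets `tau` (`tau = 0` meaning strictly
positive). Values are exact multiples of `1/N`, which makes statements like
"engaged by 3 of 15 subjects (20%)" directly readable off the map.

`voxelProfile()` extracts the per-subject samples at one mm coordinate
through *the same* masking and sampling code path as the map — the profile
is the map's evidence, and
`weightedConsistency(overlapCurve(profile))` reproduces the map value at
that voxel to machine precision (a test asserts agreement within 1e-12).

`flagAtypicalSubjects()` codifies what a reader does with such plots by
eye: a subject is atypical at a voxel when they activate strongly
(`z_sampled ≥ minZ`, default 3.1) at a location where the cohort rarely
reaches significance (engagement at `engagementTau = 3.1` at most
`maxCohortFraction = 0.25`). The gate threshold is deliberately a
*separate* parameter from `minZ`: if the gate were evaluated at `minZ`
itself, raising the flagging threshold could newly open the gate (lower
engagement) and add flagged subjects, breaking the natural monotonicity
"a stricter flag never flags more people". With a fixed gate, raising
`minZ` provably only shrinks the flagged set. There is no quantitative
criterion for "atypical" in the field; this rule is a stated, tunable
operationalisation, not an established norm.

# The synthetic-cohort generator

`makeZmapCohort()` emulates the features of a registered multi-subject
z-map cohort that the method is sensitive to:

* a **common strong network** (amplitude 6, well above `z = 3.1`, in every
  subject) — the shared task network;
* a **consistently weak region** (per-subject amplitude uniform on
  1.5–4.5, straddling 3.1) — the "everyone activates a bit, only half
  reach significance" scenario;
* a **subgroup region** (amplitude 6 in `k` listed subjects, 0 in the
  rest) — atypical organisation in a few individuals;
* smooth background noise: white Gaussian noise smoothed at
  `smoothingFwhmMm` (default 6 mm, a typical effective smoothness of
  preprocessed fMRI) and rescaled so the marginal sd equals `noiseSd`
  (default 1, emulating a null z-map);
* per-subject rigid integer-voxel **jitter** of ROI placement (residual
  anatomical variability), and optional **lesions** (signal-void regions
  forced to 0 in listed subjects).

`simulateBoldCohort()` generates block-design BOLD runs instead: the
default paradigm alternates 7 semantic and 7 line-matching blocks (4 trials
of 4 s each, 3 s inter-block delay) with 4 interleaved 14 s fixation
blocks, 322 s in total; `verio` and `prisma` variants set TR = 3.0 s and
0.933 s. Block positions for the fixation periods are not uniquely
determined by those totals, so the default interleaves them after every 3–4
active blocks and the sequence is fully configurable. Each voxel's series
is baseline + amplitude × (boxcar ∗ HRF) + white noise; the HRF is the
canonical double-gamma (gamma shapes 6 and 16, undershoot ratio 6, scaled
to unit peak so amplitudes are in signal units), chosen because no specific
HRF is canonical to the method and this is the field's default.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: temporal autocorrelation (no prewhitening is
modelled), physiological noise and scanner drift beyond the cosine basis,
realistic anatomy or tissue contrast, registration error beyond rigid
integer jitter, and pathology-induced neurovascular uncoupling. Recovery
results on synthetic cohorts validate the *computation*, not the
acquisition.

All randomness is fixed by the recipe's single seed; identical recipes are
bitwise reproducible.

# First-level GLM

`buildDesignMatrix()` produces HRF-convolved condition boxcars sampled at
the TR, an intercept, and `floor(2T/highpass)` cosine drift columns
(default cutoff 100 s) — the standard discrete-cosine surrogate for
high-pass filtering, applied identically to data and regressors by
inclusion in the model. `fitGlmContrast()` runs voxelwise OLS;
`t = c'β̂ / √(σ̂² c'(X'X)⁻¹c)` at `volumes − rank` degrees of freedom is
mapped to z through the sign-preserving quantile transform computed in
log-p space (accurate far into the tails) and clipped at |z| = 8.2, the
conventional finite ceiling of the normal quantile near single precision.
Cluster "significance" is a fixed extent filter (default 10 voxels,
26-connectivity), an explicit simplification standing in for random-field
cluster inference, which requires smoothness estimation outside this
package's scope.

# Numerical choices and degenerate inputs

* Thresholds are computed as `t_i = t_max · (i/n)` so that `i = n` gives
  exactly `t_max` and the peak subject always counts as activating at the
  top of its own grid (`O` uses `≥` at grid points, so ties count as
  activating).
* Voxels where no subject activates (all samples ≤ 0) yield a degenerate
  empty curve and `C = 0`; the same convention covers voxels outside the
  analysis mask.
* Peak ties in cluster tables break to the lowest linear voxel index;
  surviving clusters are relabelled in decreasing size order, making
  tables deterministic.
* A paired difference with zero mean and zero variance is 0; a nonzero
  constant shift with zero variance is degenerate (infinite t) and clipped
  to ±8.2.
* Dice on two empty masks is undefined and raised as an error rather than
  reported as 0 or 100.
* Voxel indices are 0-based everywhere at the interface; mm coordinates
  follow the volume's affine. `mmToVoxel` rounds to the nearest voxel and
  refuses out-of-grid coordinates.

# Validation strategy and problem sizes

The test suite validates the vectorised map against an independent
triple-loop reference (per voxel, per subject, per threshold; neighbourhood
membership by exhaustive mm-distance scan, components by hand-rolled BFS)
on 12³-grid, 8-subject cohorts, with agreement required at 1e-9. Planted
recovery uses 16³ grids with N = 15–24; GLM null calibration uses one 32³
run (32,768 voxels, 107 volumes), enough to resolve a tail probability of
0.001 against its Monte-Carlo error. These sizes were chosen as the
smallest at which every failure mode the suite probes is expressed;
the computation scales unchanged to template-resolution grids.

# Known limitations

* No null distribution is defined for `C`, so consistency maps support
  description and ranking, not hypothesis tests.
* The fixed-effects group map is the equal-weight (Stouffer) combination;
  without per-subject variance maps a variance-weighted combination is not
  possible, and random-effects inference is out of scope.
* Engagement at `tau = 0+` under max-sampling has the noise floor discussed
  above; compare against the radius-0 map or use a higher `tau` for
  specific claims.
* Surface-based analysis, registration, smoothing of real data and atlas
  labelling are all upstream or out of scope.
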