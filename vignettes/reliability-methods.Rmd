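---
title: "Methods: mapping the reliability of responses to naturalistic movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping the reliability of responses to naturalistic movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natview)
```

This vignette documents the statistical and numerical methods implemented in
`natview`: what each stage computes, the parameter conventions (with units
and defaults), and the deliberate numerical choices. The package targets
studies in which subjects repeatedly view naturalistic movie clips while
BOLD fMRI and eye position are recorded, and the question is *where* and
*why* the evoked responses are reproducible.

## 1. The reliability measurements

### Intra-subject correlation

For a subject who saw the same clip twice, `voxelwise_correlation()`
computes the zero-lag Pearson correlation between the two session time
series at every voxel in the shared brain mask. `fisher_z()` applies the
unscaled transform `z = atanh(r)`; the number of timepoints minus one is
recorded as metadata (`dof`) but *not* used to rescale z — group-level
inference comes from the variability of z across subjects, not from a
per-voxel parametric variance. Voxels with |r| ≥ 1 or zero variance are
flagged `NA` and never rejected.

`intra_subject_group_test()` then runs a voxelwise one-sample t-test of the
per-subject z values against zero (`dof = n_subjects - 1`, two-sided p) and
controls the false discovery rate across masked voxels with the
Benjamini–Hochberg step-up (`bh_fdr()`, a thin wrapper over
`stats::p.adjust(method = "BH")`). The significance mask is the BH-rejected
set at `q_level` (default 0.03); the nominal voxelwise `p_thresh` (default
0.0033) is recorded for reporting only, because the realized p cutoff of a
BH rejection set is data-dependent.

### Inter-subject correlation and the circular-shift null

`inter_subject_correlation()` computes the correlation map for every
unordered subject pair and summarizes them as the mean of the pairwise
Fisher-z maps. Parametric p-values are not trusted here: BOLD series are
strongly autocorrelated, so the effective degrees of freedom are far below
the number of volumes. `circular_shift_null()` instead builds an empirical
null by circularly shifting every subject's series by a random,
subject-distinct offset drawn uniformly from `[T/8, 7T/8]` volumes — large
enough to destroy alignment, far enough from 0 and T to avoid wrap-around
residual alignment — and pooling pairwise correlations at a random voxel
subsample (default 200 voxels per draw) over as many draws as needed to
reach `n_null_samples` pooled values. Two observed quantities are referred
to their pooled nulls, upper tail (the alternative is positive synchrony):

- each pairwise correlation (`p_pair`), and
- the per-voxel mean pairwise z (`p_map`), which is BH-corrected into a
  significance mask.

P-values use the permutation floor `(1 + #{null ≥ obs}) / (1 + n_null)`, so
a p of exactly 0 is impossible. `n_null_samples` counts pooled samples
(draws × pairs × sampled voxels), the convention under which nulls of 10^7
samples are reported for this method.

### Contrasts of reliability

`reproducibility_difference()` tests the voxelwise change in Fisher z
between two states: **paired** (the same subjects with vs without nuisance
regression; paired t, `dof = n - 1`) or **two-sample** (independent groups,
e.g. free viewing vs fixation; pooled-variance t, `dof = n1 + n2 - 2`). The
threshold is an uncorrected voxelwise p (default 0.03), as conventional for
these difference maps. Both t statistics are computed in closed form,
vectorized over voxels, and are cross-checked against `stats::t.test()` in
the unit tests.

## 2. Stimulus processing

### Phase scrambling

`phase_scramble()` replaces the phases of the movie's full 3D (space ×
time) Fourier transform with the phases of a white-noise array's transform,
which is Hermitian by construction, so the inverse transform is exactly
real. The DC phase is forced to 0, preserving the global mean. Because only
unit-modulus factors are substituted, every spectral magnitude is preserved
to machine precision (measured relative error ~1e-16). Output is left
unclipped by default: clipping into the original intensity range would
alter the spectrum.

### Scene-transition detection

`frame_difference()` is the sum of absolute pixel differences between
consecutive frames. `detect_scene_transitions()` flags frames whose
difference exceeds a threshold; with `threshold = "auto"` the threshold is
`mean + k·SD` (default k = 5) of the *background* difference series,
estimated iteratively: exceedances are excluded and the threshold
recomputed until the exceedance set is stable. The iteration matters when
one very large cut would otherwise inflate the SD and mask smaller cuts;
on outlier-free series it reduces to the single-pass rule. This automatic
rule stands in for manual visual confirmation of each cut.

### Block-matching motion weights

Cuts differ in how much image motion they cause, so detected events are
weighted by `block_matching_motion()`: the frame before the cut is
partitioned into `block_size × block_size` tiles (default 9) and each tile
is matched against the cut frame by exhaustive sum-of-absolute-differences
search over integer displacements within `±max_displacement`. Ties break
toward the smallest displacement magnitude, then row-major order. The
scalar weight is the mean Euclidean displacement magnitude over *interior*
tiles — tiles whose full search window lies inside the frame. Border tiles
have a clipped search range that cannot represent the true displacement and
would bias the mean toward zero on small frames; if no tile is interior,
all tiles contribute.

## 3. Gaze processing

Eye-tracking traces (`gaze_trace`, default 30 Hz) pass through
`interpolate_lost()` (linear interpolation over dropout samples) and
`smooth_gaze()` (centered moving average, default 1 s window).
`saccade_amplitude()` converts consecutive-sample displacement in pixels to
degrees of visual angle; the default `"linear"` model scales by
screen-degrees per screen-pixel, and the `"arctan"` model applies the exact
geometry given a viewing distance. The output is demeaned by default, ready
for regressor construction, and is one sample shorter than the trace
(differencing). `intra_subject_gaze_consistency()` correlates two viewings'
coordinate traces after temporal re-alignment by interpolation.

## 4. Hemodynamic regressors

`hrf_model()` is the canonical double-gamma impulse response: a positive
gamma density peaking at 6 s minus an undershoot gamma peaking at 16 s with
ratio 1/6, truncated at 32 s, sampled by `hrf_kernel()` at the source rate.
`build_regressor()` applies the full chain to any explanatory signal
(saccade amplitudes, weighted cut impulses from `events_to_signal()`):

1. demean;
2. causal convolution with the HRF at the source rate (zero-padded start,
   truncated to the signal length, scaled by dt so amplitudes are
   rate-invariant);
3. zero-phase low-pass filtering (4th-order Butterworth applied
   forward–backward via `signal::filtfilt()`, default cutoff 0.25 Hz) —
   zero-phase so that the filter does not shift the regressor relative to
   the data it will be regressed against;
4. sampling at the acquisition times `k · tr_s`;
5. demean again.

The convolution is verified against a brute-force O(n²) oracle to 1e-10 in
the test suite, and a 0.4 Hz oscillation is attenuated more than 10× as
strongly as a 0.05 Hz one through the chain.

`nuisance_regression()` removes any set of regressors from every voxel time
series by OLS on `[intercept | regressors]` via a QR decomposition, erroring
on rank deficiency with the offending columns named. Volume conditioning
(`condition_volume()`) trims the analysis window (default: drop the first
12 s, when onset transients dominate), removes a polynomial trend per voxel
(default cubic, `detrend_poly_rows()`), and optionally smooths spatially
(`smooth_gaussian_3d()`, separable Gaussian with reflecting boundaries,
default FWHM 6 mm on 3 mm voxels).

## 5. The synthetic generator

Because no public ground truth exists for these analyses, `natview` ships a
generator whose truth is exact.

`ground_truth()` lays out up to three unit-SD components on a voxel grid
(default 16 × 16 × 8, 160 volumes at TR 2 s): a *content* component
(HRF-convolved white noise, the stimulus-locked signal proper), a *cuts*
component (HRF-convolved impulse train at the scene-cut times, scaled by
motion weights) and a *gaze* component (likewise for saccade onsets). Each
occupies its own contiguous block by default so recovered maps are visually
checkable. `generate_subject_sessions()` adds the amplitude-scaled
components and fresh Gaussian noise (optionally AR(1)) per session. Key
property: with component amplitude `a` and noise SD `σ`, the expected
between-session correlation in a driven voxel is `a²/(a² + σ²)` — the
handle by which recovery accuracy is asserted quantitatively.

`generate_movie()` synthesizes a grayscale movie as a periodic low-pass
texture drifting at 0.1 px/frame (sub-pixel drift via an FFT phase ramp),
with scene cuts implemented as exact integer circular translations of
specified magnitude. Cut detection on these movies is therefore exactly
scorable, and block matching should recover the translation to the pixel.
`generate_gaze()` produces piecewise-constant fixation with saccades at
given times plus Gaussian jitter at 30 Hz.

**Scope and limits.** The generator validates the *analysis chain*, not the
physiology: noise is Gaussian (optionally AR(1)), components are spatially
homogeneous within their blocks, movies are translating textures without
occlusion, lighting change or independent object motion, and gaze has no
smooth pursuit. These are the regimes in which the estimators' correctness
can be asserted exactly; realism beyond them is out of scope.

## 6. File-based pipeline

`study_manifest()` validates a session table (subject, session, condition,
NIfTI path, optional gaze TSV), `run_reliability_analysis()` runs
conditioning, intra-subject group tests and inter-subject
correlation + permutation null per condition, and `run_confound_analysis()`
builds the chosen confound regressor per session (saccade amplitudes from
gaze TSVs, or motion-weighted cut events detected from movie frames on
disk), maps its correlation with the signal, and contrasts reliability with
vs without nuisance regression. All maps are written as NIfTI with the TR
recorded in the header, plus JSON sidecars/summaries; identical
configuration and seed reproduce the outputs byte for byte.

## 7. Numerical conventions

- Correlations are computed by vectorized closed-form sums; results agree
  with `stats::cor()` to better than 1e-12 and are clamped to [-1, 1] to
  guard 1-ulp excursions from rounding.
- All significance thresholds are parameters with the defaults stated
  above, not constants buried in code.
- Every stochastic step takes an explicit integer seed (< 2^31) and is
  bitwise reproducible; nothing reads the global RNG state implicitly.
- Problem sizes: the defaults (2048 voxels, 160 volumes, 9 subjects) run
  each full analysis in seconds; the circular-shift null costs
  O(draws × pairs × sampled voxels) and is the only stage whose cost grows
  with the requested null size.
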