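# natview

Reliability analysis of fMRI responses to naturalistic movie stimuli.

When different people watch the same movie — or one person watches it twice —
large parts of cortex respond with highly reproducible BOLD time courses.
`natview` implements the full analysis chain for quantifying that
reproducibility and for asking what drives it:

- **Intra-subject correlation maps**: voxelwise Pearson correlation between
  two viewings of the same movie by the same subject, Fisher z-transformed
  and tested across subjects with a one-sample t-test under
  Benjamini–Hochberg false-discovery-rate control.
- **Inter-subject correlation (ISC) maps**: pairwise correlations between
  different subjects watching the same movie, with a nonparametric
  **circular-shift permutation null** that respects the autocorrelation of
  BOLD time series.
- **Control stimuli** by 3D Fourier **phase scrambling** of the movie:
  the scrambled clip has exactly the original's spatiotemporal magnitude
  spectrum but no recognizable content, so any reliability that survives is
  attributable to low-level stimulus statistics.
- **Confound analysis**: scene-transition (shot boundary) detection with
  block-matching motion weighting, saccade-amplitude extraction from
  eye-tracking traces, construction of hemodynamic regressors from either,
  and nuisance variable regression to test how much reproducibility each
  confound accounts for.
- A **synthetic-data generator** with exact ground truth (which voxels carry
  stimulus-locked signal, at what amplitude, with which scene cuts and
  saccades), used to validate every stage end to end: in a voxel driven by a
  unit-variance shared component of amplitude *a* over noise of SD σ, the
  expected between-session correlation is *a*²/(*a*² + σ²).

## Worked example

Simulate a small two-session study with a known stimulus-driven region, then
recover it:

```r
library(natview)

truth <- ground_truth(grid_shape = c(12, 12, 6), n_timepoints = 200, tr_s = 2,
                      effect_amplitudes = c(content = 1.5),
                      noise_sd = 1, seed = 7)
truth
#> <ground_truth> 12x12x6 grid, 200 TRs @ 2 s; amplitudes [content=1.5, cuts=0, gaze=0]; noise sd 1

sessions <- generate_subject_sessions(truth, n_subjects = 6,
                                      n_sessions_per_subject = 2)
sessions[[1]]
#> <volume4d> 12x12x6 grid, 200 volumes, TR 2 s (subject sub01, session ses1)
```

Intra-subject reliability of subject 1 (amplitude 1.5 over unit noise
predicts r = 1.5² / (1.5² + 1) ≈ 0.69 in the active region, 0 elsewhere):

```r
r11 <- voxelwise_correlation(sessions[[1]], sessions[[2]])
mean(r11$values[truth$active_voxel_mask])    #> 0.692
mean(r11$values[!truth$active_voxel_mask])   #> 0.001
```

Group-level map across the six subjects:

```r
zmaps <- lapply(1:6, function(s)
  fisher_z(voxelwise_correlation(sessions[[2 * s - 1]], sessions[[2 * s]]),
           n_timepoints = 200))
grp <- intra_subject_group_test(zmaps, q_level = 0.03)
sum(grp$sig_mask)                                       #> 110 (of 864 voxels)
dice_coefficient(grp$sig_mask, truth$active_voxel_mask) #> 0.991
```

Inter-subject correlation with a permutation null (10,000 pooled
circular-shift samples):

```r
firsts <- sessions[seq(1, 12, by = 2)]
isc <- inter_subject_correlation(firsts)
nul <- circular_shift_null(firsts, n_null_samples = 1e4, seed = 1)
mean(isc$mean_z$values[truth$active_voxel_mask])  #> 0.859
sum(nul$sig_mask)                                 #> 110
```

On the stimulus side, detect and motion-weight the scene cuts of a generated
movie, then turn them into a scanner-resolution hemodynamic regressor:

```r
g <- generate_movie(120, 63, 63, cut_times = c(40, 90),
                    cut_shift_pixels = c(5, -4), seed = 3)
ev <- weight_events(detect_scene_transitions(g$movie), g$movie)
ev$times    #> 40 90
ev$weights  #> 5  4   (pixels of inter-frame motion at each cut)

reg <- build_regressor(events_to_signal(ev, 30, duration_s = 400),
                       source_rate_hz = 30, tr_s = 2, n_volumes = 60,
                       name = "cuts")
reg
#> <regressor:cuts> 60 volumes @ TR 2 s (source 30 Hz)
```

For a file-based study (NIfTI volumes, TSV gaze traces, PGM movie frames on
disk), `study_manifest()` + `run_reliability_analysis()` /
`run_confound_analysis()` run the same chain end to end and write the
resulting maps and a JSON summary. See the vignette
(`vignettes/reliability-methods.Rmd`) for the methods in detail.

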