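test_that("all generators are bitwise deterministic under a fixed seed", {
  m1 <- generate_movie(30, 16, 16, cut_times = 15, cut_shift_pixels = 3,
                       seed = 5)
  m2 <- generate_movie(30, 16, 16, cut_times = 15, cut_shift_pixels = 3,
                       seed = 5)
  expect_identical(m1$movie$frames, m2$movie$frames)
  g1 <- generate_gaze(5, 30, saccade_times = 2, saccade_px = list(c(10, 5)),
                      seed = 3)
  g2 <- generate_gaze(5, 30, saccade_times = 2, saccade_px = list(c(10, 5)),
                      seed = 3)
  expect_identical(g1$trace$x_px, g2$trace$x_px)
  tr <- ground_truth(grid_shape = c(6, 6, 3), n_timepoints = 80, seed = 4)
  v1 <- generate_subject_sessions(tr, 2, 2)
  v2 <- generate_subject_sessions(tr, 2, 2)
  expect_identical(lapply(v1, `[[`, "data"), lapply(v2, `[[`, "data"))
  # different seeds differ
  m3 <- generate_movie(30, 16, 16, seed = 6)
  expect_false(identical(m1$movie$frames, m3$movie$frames))
})

test_that("generator preconditions are enforced", {
  expect_error(generate_movie(-10, 8, 8), "positive")
  expect_error(generate_movie(10, 8, 8, cut_times = 1,
                              cut_shift_pixels = 2), "preceding")
  expect_error(generate_movie(10, 8, 8, cut_times = 5,
                              cut_shift_pixels = integer(0)), "one shift")
  expect_error(generate_gaze(5, rate_hz = 0), "positive")
  expect_error(generate_gaze(5, saccade_times = 6,
                             saccade_px = list(c(1, 1))), "\\[0, duration")
  expect_error(ground_truth(noise_sd = 0), "positive")
  expect_error(ground_truth(ar1 = 1), "\\[0, 1\\)")
  tr <- ground_truth(grid_shape = c(6, 6, 3), n_timepoints = 80)
  expect_error(generate_subject_sessions(tr, 2, 1, n_timepoints = 60),
               "match")
})

test_that("ground truth invariants hold", {
  tr <- ground_truth(grid_shape = c(10, 10, 5), n_timepoints = 100,
                     effect_amplitudes = c(content = 1, cuts = 1),
                     cut_times = c(30, 60), cut_motion_weights = c(2, 3),
                     seed = 7)
  expect_true(all(tr$active_voxel_mask <= tr$brain_mask))
  expect_length(tr$shared_signal, 100)
  expect_true(all(diff(tr$cut_times) > 0))
  expect_equal(stats::sd(tr$shared_signal), 1, tolerance = 1e-12)
  expect_equal(stats::sd(tr$component_signals$cuts), 1, tolerance = 1e-12)
  # zero-amplitude truth has an empty active mask
  tr0 <- ground_truth(effect_amplitudes = c(content = 0))
  expect_false(any(tr0$active_voxel_mask))
})

test_that("intra-subject r concentrates at the shared-variance fraction", {
  # amplitude / noise_sd = 2 -> r -> 2^2 / (2^2 + 1) = 0.8 for long series
  tr <- ground_truth(grid_shape = c(12, 12, 6), n_timepoints = 500,
                     effect_amplitudes = c(content = 2), noise_sd = 1,
                     seed = 5)
  vols <- generate_subject_sessions(tr, 2, 2)
  r <- voxelwise_correlation(vols[[1]], vols[[2]])$values
  expect_equal(mean(r[tr$active_voxel_mask]), 0.8, tolerance = 0.05)
  expect_lt(abs(mean(r[!tr$active_voxel_mask])), 0.05)
  # pure noise: r near 0 everywhere
  tr0 <- ground_truth(grid_shape = c(12, 12, 6), n_timepoints = 500,
                      effect_amplitudes = c(content = 0), seed = 6)
  v0 <- generate_subject_sessions(tr0, 1, 2)
  expect_lt(abs(mean(voxelwise_correlation(v0[[1]], v0[[2]])$values)), 0.02)
})

test_that("two sessions of one subject differ only in their noise", {
  tr <- ground_truth(grid_shape = c(8, 8, 4), n_timepoints = 200,
                     effect_amplitudes = c(content = 2), seed = 9)
  vols <- generate_subject_sessions(tr, 1, 2)
  d <- vols[[1]]$data - vols[[2]]$data
  # the difference carries no trace of the shared signal
  dm <- matrix(d, ncol = 200)
  cors <- abs(as.numeric(dm %*% tr$shared_signal) /
                (sqrt(rowSums(dm^2)) * sqrt(sum(tr$shared_signal^2))))
  expect_lt(mean(cors[as.vector(tr$active_voxel_mask)]), 0.1)
})

test_that("mean active-voxel r increases with effect amplitude", {
  rs <- vapply(c(0.5, 1, 2), function(a) {
    tr <- ground_truth(grid_shape = c(8, 8, 4), n_timepoints = 300,
                       effect_amplitudes = c(content = a), seed = 31)
    vols <- generate_subject_sessions(tr, 1, 2)
    mean(voxelwise_correlation(vols[[1]], vols[[2]])$values[
      tr$component_masks$content])
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
  # closed-form check at each amplitude
  expect_equal(rs, c(0.25, 1, 4) / (c(0.25, 1, 4) + 1), tolerance = 0.08)
})

test_that("AR(1) noise has the requested marginal scale and autocorrelation", {
  tr <- ground_truth(grid_shape = c(6, 6, 2), n_timepoints = 400,
                     effect_amplitudes = c(content = 0), noise_sd = 1.5,
                     ar1 = 0.5, seed = 13)
  v <- generate_subject_sessions(tr, 1, 1)[[1]]
  m <- matrix(v$data, ncol = 400)
  sds <- apply(m, 1, stats::sd)
  expect_equal(mean(sds), 1.5, tolerance = 0.05)
  ac <- mean(apply(m, 1, function(x)
    stats::acf(x, plot = FALSE, lag.max = 1)$acf[2]))
  expect_equal(ac, 0.5, tolerance = 0.05)
  # the circular-shift null stays calibrated under autocorrelated noise
  vols <- generate_subject_sessions(tr, 4, 1)
  cs <- circular_shift_null(vols, n_null_samples = 2e4, seed = 2,
                            n_sample_voxels = 48)
  expect_lt(abs(mean(cs$p_pair <= 0.05) - 0.05), 0.02)
})

test_that("the generated study is recovered by the analysis it feeds", {
  # generator/analysis consistency: FDR-controlled recovery of the active set
  tr <- ground_truth(grid_shape = c(10, 10, 5), n_timepoints = 160,
                     effect_amplitudes = c(content = 2), seed = 17)
  vols <- generate_subject_sessions(tr, 9, 2)
  zm <- intra_z_from_sessions(vols, 9)
  gt <- intra_subject_group_test(zm)
  expect_gte(dice_coefficient(gt$sig_mask, tr$active_voxel_mask), 0.95)
})

test_that("synthetic outputs round-trip through their file formats", {
  td <- withr::local_tempdir()
  # movie frames + sidecar
  mv <- generate_movie(6, 12, 12, seed = 2)$movie
  write_movie_frames(mv, file.path(td, "frames"))
  mv2 <- read_movie_frames(file.path(td, "frames"))
  expect_identical(dim(mv2$frames), dim(mv$frames))
  expect_equal(mv2$frame_rate_hz, mv$frame_rate_hz)
  expect_lt(max(abs(mv2$frames - mv$frames)), 0.5 + 1e-9)  # 8-bit rounding
  # gaze TSV
  g <- generate_gaze(2, 30, seed = 3)$trace
  write_gaze_tsv(g, file.path(td, "g.tsv"))
  g2 <- read_gaze_tsv(file.path(td, "g.tsv"))
  expect_equal(g2$x_px, g$x_px, tolerance = 1e-9)
  # events TSV
  ev <- event_train(c(10, 20), c(1.5, 2.5), 30, 30)
  write_events_tsv(ev, file.path(td, "ev.tsv"))
  ev2 <- read_events_tsv(file.path(td, "ev.tsv"), 30, 30)
  expect_identical(ev2$times, ev$times)
  expect_equal(ev2$weights, ev$weights)
  # NIfTI with TR in the header
  tr <- ground_truth(grid_shape = c(4, 4, 2), n_timepoints = 10, seed = 1)
  v <- generate_subject_sessions(tr, 1, 1)[[1]]
  write_volume4d_nifti(v, file.path(td, "v.nii.gz"))
  v2 <- read_volume4d_nifti(file.path(td, "v.nii.gz"))
  expect_equal(v2$data, v$data, tolerance = 1e-6)
  expect_equal(v2$tr_s, 2)
  # ground truth JSON
  write_ground_truth_json(tr, file.path(td, "truth.json"))
  j <- jsonlite::read_json(file.path(td, "truth.json"),
                           simplifyVector = TRUE)
  expect_equal(j$noise_sd, tr$noise_sd)
  expect_identical(sort(j$active_voxel_index), which(tr$active_voxel_mask))
})
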