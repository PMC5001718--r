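#' Study manifest
#'
#' Table of sessions entering an analysis: one row per scanning session with
#' subject, session and condition labels, the NIfTI path and (optionally)
#' the gaze TSV path, plus the analysis window. The window defaults to
#' starting 12 s after movie onset, discarding the transient response to the
#' movie replacing the blank screen.
#'
#' @param rows data.frame with columns `subject_id`, `session_id`,
#'   `condition` (e.g. `"intact-free"`, `"scrambled-free"`,
#'   `"intact-fixation"`), `nifti_path`, and optionally `gaze_path`.
#' @param start_s analysis window start in seconds (default 12).
#' @param end_s window end; `NULL` = to the end of the series.
#' @param check_paths verify that referenced files exist.
#' @return an object of class `study_manifest`.
#' @export
study_manifest <- function(rows, start_s = 12, end_s = NULL,
                           check_paths = TRUE) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("manifest is empty")
  need <- c("subject_id", "session_id", "condition", "nifti_path")
  miss <- setdiff(need, names(rows))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (check_paths) {
    bad <- which(!file.exists(rows$nifti_path))
    if (length(bad))
      stop("missing NIfTI files at manifest rows: ",
           paste(bad, collapse = ", "))
    if ("gaze_path" %in% names(rows)) {
      gp <- rows$gaze_path
      bad <- which(!is.na(gp) & nzchar(gp) & !file.exists(gp))
      if (length(bad))
        stop("missing gaze files at manifest rows: ",
             paste(bad, collapse = ", "))
    }
  }
  structure(list(rows = rows, start_s = start_s, end_s = end_s),
            class = "study_manifest")
}

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf("<study_manifest> %d sessions, %d subjects, conditions: %s\n",
              nrow(x$rows), length(unique(x$rows$subject_id)),
              paste(unique(x$rows$condition), collapse = ", ")))
  invisible(x)
}

#' Read a study manifest from TSV
#'
#' @param path TSV with the columns of [study_manifest()].
#' @param ... passed to [study_manifest()].
#' @return a `study_manifest`.
#' @export
read_manifest_tsv <- function(path, ...) {
  study_manifest(utils::read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE), ...)
}

#' Trim, detrend and optionally smooth a session
#'
#' The conditioning applied to every session before correlation analysis:
#' drop volumes acquired before `start_s` (and after `end_s` if given),
#' remove a third-order polynomial trend from every voxel, and optionally
#' smooth spatially.
#'
#' @param vol a [volume4d()].
#' @param start_s,end_s analysis window in seconds from series start.
#' @param detrend_order polynomial detrending order (default 3).
#' @param fwhm_mm spatial smoothing FWHM; 0 disables (default 0 — synthetic
#'   grids are small relative to a 6 mm kernel).
#' @param voxel_mm voxel size used by the smoother.
#' @return a conditioned [volume4d()].
#' @export
condition_volume <- function(vol, start_s = 12, end_s = NULL,
                             detrend_order = 3, fwhm_mm = 0,
                             voxel_mm = 3) {
  stopifnot(inherits(vol, "volume4d"))
  nt <- dim(vol$data)[4]
  onset <- (seq_len(nt) - 1L) * vol$tr_s
  keep <- onset >= start_s
  if (!is.null(end_s)) keep <- keep & onset <= end_s
  if (sum(keep) < detrend_order + 2L)
    stop("analysis window too short")
  d <- dim(vol$data)
  m <- matrix(vol$data, nrow = prod(d[1:3]), ncol = nt)[, keep, drop = FALSE]
  m <- detrend_poly_rows(m, detrend_order)
  out <- volume4d(array(m, c(d[1:3], sum(keep))), vol$tr_s, vol$mask,
                  vol$subject_id, vol$session_id)
  if (fwhm_mm > 0) out <- smooth_gaussian_3d(out, fwhm_mm, voxel_mm)
  out
}

default_config <- function(config = list()) {
  utils::modifyList(list(detrend_order = 3, fwhm_mm = 0, voxel_mm = 3,
                         p_thresh = 0.0033, q_level = 0.03,
                         n_null = 1e4, seed = 1, out_dir = NULL,
                         cutoff_hz = 0.25, diff_p_thresh = 0.03,
                         regressor_p_thresh = 0.011),
                    config)
}

load_sessions <- function(manifest) {
  rows <- manifest$rows
  lapply(seq_len(nrow(rows)), function(i)
    read_volume4d_nifti(rows$nifti_path[i],
                        subject_id = rows$subject_id[i],
                        session_id = rows$session_id[i]))
}

intra_pairs_by_subject <- function(rows) {
  split(seq_len(nrow(rows)), rows$subject_id)
}

# intra-subject z maps (first two sessions of each subject), given
# conditioned volumes aligned with manifest rows
intra_z_maps <- function(vols, rows) {
  by_sub <- intra_pairs_by_subject(rows)
  short <- names(by_sub)[vapply(by_sub, length, integer(1)) < 2L]
  if (length(short))
    stop("subjects with fewer than 2 sessions (rows ",
         paste(unlist(by_sub[short]), collapse = ", "),
         "): ", paste(short, collapse = ", "))
  nt <- dim(vols[[1]]$data)[4]
  lapply(by_sub, function(idx)
    fisher_z(voxelwise_correlation(vols[[idx[1]]], vols[[idx[2]]]), nt))
}

write_bundle_maps <- function(bundle, out_dir, prefix) {
  for (nm in c("mean_z", "t_map", "p_map", "q_map"))
    if (!is.null(bundle[[nm]]))
      write_stat_map_nifti(bundle[[nm]],
                           file.path(out_dir,
                                     sprintf("%s_%s.nii.gz", prefix, nm)))
  invisible(NULL)
}

#' Run the reliability analysis over a study manifest
#'
#' For every condition present in the manifest: conditions each session
#' (window trim, polynomial detrend, optional smoothing), computes
#' intra-subject correlation maps (first two sessions per subject) with the
#' parametric group test, and inter-subject correlation maps (first session
#' per subject) with the circular-shift permutation inference. When
#' `config$out_dir` is set, statistic maps and a machine-readable JSON
#' summary (significant voxel counts, thresholds, seeds) are written there.
#'
#' @param manifest a [study_manifest()].
#' @param config named list overriding defaults: `detrend_order` (3),
#'   `fwhm_mm` (0), `p_thresh` (0.0033), `q_level` (0.03), `n_null` (1e4),
#'   `seed` (1), `out_dir` (NULL).
#' @return named list per condition, each with `intra` (the
#'   [intra_subject_group_test()] bundle plus `z_maps`), `inter` (the
#'   [inter_subject_correlation()] and [circular_shift_null()] results) and
#'   `summary`.
#' @export
run_reliability_analysis <- function(manifest, config = list()) {
  stopifnot(inherits(manifest, "study_manifest"))
  cfg <- default_config(config)
  rows <- manifest$rows
  vols <- load_sessions(manifest)
  vols <- lapply(vols, condition_volume, start_s = manifest$start_s,
                 end_s = manifest$end_s, detrend_order = cfg$detrend_order,
                 fwhm_mm = cfg$fwhm_mm, voxel_mm = cfg$voxel_mm)
  out <- list()
  for (cond in unique(rows$condition)) {
    sel <- which(rows$condition == cond)
    crows <- rows[sel, , drop = FALSE]
    cvols <- vols[sel]
    zmaps <- intra_z_maps(cvols, crows)
    intra <- intra_subject_group_test(zmaps, p_thresh = cfg$p_thresh,
                                      q_level = cfg$q_level)
    intra$z_maps <- zmaps
    first_idx <- vapply(intra_pairs_by_subject(crows), `[`, integer(1), 1L)
    inter_vols <- cvols[first_idx]
    inter <- inter_subject_correlation(inter_vols)
    perm <- circular_shift_null(inter_vols, n_null_samples = cfg$n_null,
                                seed = cfg$seed, q_level = cfg$q_level)
    summary <- list(condition = cond,
                    n_subjects = length(zmaps),
                    n_timepoints = dim(cvols[[1]]$data)[4],
                    intra_sig_voxels = sum(intra$sig_mask),
                    inter_sig_voxels = sum(perm$sig_mask),
                    p_thresh = cfg$p_thresh, q_level = cfg$q_level,
                    n_null = cfg$n_null, seed = cfg$seed,
                    start_s = manifest$start_s,
                    detrend_order = cfg$detrend_order,
                    fwhm_mm = cfg$fwhm_mm)
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_bundle_maps(intra, cfg$out_dir, paste0(cond, "_intra"))
      write_stat_map_nifti(inter$mean_z,
                           file.path(cfg$out_dir,
                                     paste0(cond, "_inter_mean_z.nii.gz")))
      write_stat_map_nifti(perm$p_map,
                           file.path(cfg$out_dir,
                                     paste0(cond, "_inter_perm_p.nii.gz")))
      jsonlite::write_json(summary,
                           file.path(cfg$out_dir,
                                     paste0(cond, "_summary.json")),
                           auto_unbox = TRUE)
    }
    out[[cond]] <- list(intra = intra,
                        inter = list(isc = inter, perm = perm),
                        summary = summary)
  }
  out
}

# build the per-session confound regressor
confound_regressor <- function(confound, row, nt, tr_s, cfg, events) {
  if (confound == "gaze") {
    if (!("gaze_path" %in% names(row)) || is.na(row$gaze_path) ||
        !nzchar(row$gaze_path))
      stop("gaze confound requested but session ", row$session_id,
           " of ", row$subject_id, " has no gaze_path")
    trace <- smooth_gaze(read_gaze_tsv(row$gaze_path))
    amp <- saccade_amplitude(trace)
    build_regressor(amp, trace$rate_hz, tr_s = tr_s, n_volumes = nt,
                    cutoff_hz = cfg$cutoff_hz, name = "saccade_amplitude")
  } else {
    if (is.null(events))
      stop("cuts confound requested but no movie frames or event train ",
           "supplied (config$frames_dir or config$events)")
    sig <- events_to_signal(events, events$frame_rate_hz,
                            duration_s = events$n_frames /
                              events$frame_rate_hz)
    build_regressor(sig, events$frame_rate_hz, tr_s = tr_s, n_volumes = nt,
                    cutoff_hz = cfg$cutoff_hz, name = "scene_transitions")
  }
}

# trim a regressor built on the full session to the analysis window
window_regressor <- function(reg, nt_full, tr_s, start_s, end_s, nt_out) {
  onset <- (seq_len(nt_full) - 1L) * tr_s
  keep <- onset >= start_s
  if (!is.null(end_s)) keep <- keep & onset <= end_s
  v <- reg$values[keep][seq_len(nt_out)]
  structure(list(values = v - mean(v), tr_s = tr_s, name = reg$name,
                 source_rate_hz = reg$source_rate_hz),
            class = "regressor")
}

#' Run a confound analysis (gaze behavior or scene transitions)
#'
#' Builds the confound regressor for every session — the saccade-amplitude
#' regressor from each session's gaze trace, or the motion-weighted
#' scene-transition regressor from the movie (shared across sessions) — and
#' produces (i) the group map of voxelwise correlation with the regressor,
#' (ii) intra-subject reproducibility with and without nuisance variable
#' regression of the confound, and (iii) the without-minus-with difference
#' map with a paired t-test at an uncorrected threshold.
#'
#' @param manifest a [study_manifest()]; sessions of a single condition.
#' @param confound `"gaze"` or `"cuts"`.
#' @param config as in [run_reliability_analysis()], plus
#'   `regressor_p_thresh` (0.011), `diff_p_thresh` (0.03) and, for
#'   `"cuts"`, either `frames_dir` (PGM frame directory; transitions are
#'   detected and motion-weighted from it) or `events` (an [event_train()]).
#' @return list with `regressor_map`, `intra_without`, `intra_with`,
#'   `difference`, `regressors`, `summary`.
#' @export
run_confound_analysis <- function(manifest, confound = c("gaze", "cuts"),
                                  config = list()) {
  stopifnot(inherits(manifest, "study_manifest"))
  confound <- match.arg(confound)
  cfg <- default_config(config)
  rows <- manifest$rows
  vols_raw <- load_sessions(manifest)
  nt_full <- dim(vols_raw[[1]]$data)[4]
  tr_s <- vols_raw[[1]]$tr_s

  events <- NULL
  if (confound == "cuts") {
    if (!is.null(cfg$events)) {
      events <- cfg$events
    } else if (!is.null(cfg$frames_dir)) {
      movie <- read_movie_frames(cfg$frames_dir)
      events <- weight_events(detect_scene_transitions(movie), movie)
    }
  }
  regs_full <- lapply(seq_len(nrow(rows)), function(i)
    confound_regressor(confound, rows[i, , drop = FALSE], nt_full, tr_s,
                       cfg, events))

  vols <- lapply(vols_raw, condition_volume, start_s = manifest$start_s,
                 end_s = manifest$end_s, detrend_order = cfg$detrend_order,
                 fwhm_mm = cfg$fwhm_mm, voxel_mm = cfg$voxel_mm)
  nt <- dim(vols[[1]]$data)[4]
  regs <- lapply(regs_full, window_regressor, nt_full = nt_full,
                 tr_s = tr_s, start_s = manifest$start_s,
                 end_s = manifest$end_s, nt_out = nt)

  reg_map <- regressor_correlation_map(vols, regs,
                                       p_thresh = cfg$regressor_p_thresh,
                                       q_level = cfg$q_level)
  z_without <- intra_z_maps(vols, rows)
  vols_nvr <- lapply(seq_along(vols), function(i)
    nuisance_regression(vols[[i]], list(regs[[i]])))
  z_with <- intra_z_maps(vols_nvr, rows)
  diff <- reproducibility_difference(z_without, z_with, test = "paired",
                                     p_thresh = cfg$diff_p_thresh)
  summary <- list(confound = confound,
                  n_sessions = length(vols),
                  n_subjects = length(z_without),
                  regressor_sig_voxels = sum(reg_map$sig_mask),
                  difference_sig_voxels = sum(diff$sig_mask),
                  regressor_p_thresh = cfg$regressor_p_thresh,
                  diff_p_thresh = cfg$diff_p_thresh,
                  q_level = cfg$q_level)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bundle_maps(reg_map, cfg$out_dir, paste0(confound, "_regressor"))
    write_stat_map_nifti(diff$diff_map,
                         file.path(cfg$out_dir,
                                   paste0(confound, "_diff.nii.gz")))
    jsonlite::write_json(summary,
                         file.path(cfg$out_dir,
                                   paste0(confound, "_summary.json")),
                         auto_unbox = TRUE)
  }
  list(regressor_map = reg_map,
       intra_without = z_without, intra_with = z_with,
       difference = diff, regressors = regs, summary = summary)
}
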