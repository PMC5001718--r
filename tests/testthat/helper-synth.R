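# shared fixture builders; everything is generated in code at test time

# intra-subject Fisher-z maps from a subject-major session list
# (n_sessions = 2 per subject)
intra_z_from_sessions <- function(vols, n_subjects) {
  nt <- dim(vols[[1]]$data)[4]
  lapply(seq_len(n_subjects), function(s)
    fisher_z(voxelwise_correlation(vols[[2 * s - 1]], vols[[2 * s]]), nt))
}

# one session per subject (the first of each)
first_sessions <- function(vols, n_subjects) {
  vols[2 * seq_len(n_subjects) - 1L]
}

# write a session bundle to disk and return a manifest data.frame
write_session_rows <- function(vols, dir, condition = "intact-free",
                               gaze_traces = NULL) {
  rows <- lapply(seq_along(vols), function(i) {
    p <- file.path(dir, sprintf("%s_%02d.nii.gz", condition, i))
    write_volume4d_nifti(vols[[i]], p)
    gp <- NA_character_
    if (!is.null(gaze_traces)) {
      gp <- file.path(dir, sprintf("%s_%02d_gaze.tsv", condition, i))
      write_gaze_tsv(gaze_traces[[i]], gp)
    }
    data.frame(subject_id = vols[[i]]$subject_id,
               session_id = vols[[i]]$session_id,
               condition = condition, nifti_path = p, gaze_path = gp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
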