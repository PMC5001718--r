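#' Write a 4D volume as NIfTI-1
#'
#' The repetition time is stored in the 4th pixdim slot; the mask is written
#' alongside as `<stem>_mask.nii.gz` when `write_mask = TRUE`.
#'
#' @param vol a [volume4d()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_mm isotropic voxel size recorded in the header (default 3).
#' @param write_mask also write the brain mask next to the data.
#' @return `path`, invisibly.
#' @export
write_volume4d_nifti <- function(vol, path, voxel_mm = 3,
                                 write_mask = FALSE) {
  stopifnot(inherits(vol, "volume4d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(voxel_mm, voxel_mm, voxel_mm, vol$tr_s)
  RNifti::writeNifti(img, path)
  if (write_mask) {
    mpath <- sub("(\\.nii)(\\.gz)?$", "_mask\\1\\2", path)
    RNifti::writeNifti(RNifti::asNifti(vol$mask * 1L), mpath)
  }
  invisible(path)
}

#' Read a 4D NIfTI volume
#'
#' @param path NIfTI file path.
#' @param tr_s repetition time; taken from the header 4th pixdim if `NULL`.
#' @param mask optional logical 3D array; defaults to all in-brain.
#' @param subject_id,session_id labels to attach.
#' @return a [volume4d()].
#' @export
read_volume4d_nifti <- function(path, tr_s = NULL, mask = NULL,
                                subject_id = NA_character_,
                                session_id = NA_character_) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  if (is.null(tr_s)) {
    pd <- RNifti::pixdim(img)
    tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else
      stop("TR not present in the header; pass `tr_s`")
  }
  volume4d(data, tr_s, mask, subject_id, session_id)
}

#' Write a statistic map as NIfTI-1 with a JSON sidecar
#'
#' The sidecar records `stat_kind`, `dof` and the fraction of flagged
#' voxels; `NA` values are written as 0 with the mask distinguishing them.
#'
#' @param map a [stat_map()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_stat_map_nifti <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  v <- map$values
  v[is.na(v)] <- 0
  RNifti::writeNifti(RNifti::asNifti(v), path)
  side <- sub("(\\.nii)(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(stat_kind = map$stat_kind, dof = map$dof,
                            n_masked = sum(map$mask),
                            n_flagged = sum(is.na(map$values[map$mask]))),
                       side, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Write / read a gaze trace as TSV
#'
#' Columns `time_s`, `x_px`, `y_px`.
#'
#' @param trace a [gaze_trace()].
#' @param path TSV path.
#' @return `path` (write) or a [gaze_trace()] (read).
#' @export
write_gaze_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "gaze_trace"))
  utils::write.table(data.frame(time_s = trace$time_s, x_px = trace$x_px,
                                y_px = trace$y_px),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @param rate_hz,screen_px,screen_deg geometry attached on read (defaults
#'   as in [gaze_trace()]).
#' @export
read_gaze_tsv <- function(path, rate_hz = 30, screen_px = c(800, 600),
                          screen_deg = c(26.9, 20.3)) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  gaze_trace(d$time_s, d$x_px, d$y_px, rate_hz, screen_px, screen_deg)
}

#' Write an event train as TSV
#'
#' Columns `frame_index`, `time_s`, `weight`.
#'
#' @param train an [event_train()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(train, path) {
  stopifnot(inherits(train, "event_train"))
  utils::write.table(data.frame(frame_index = train$times,
                                time_s = event_times_s(train),
                                weight = train$weights),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event train from TSV
#'
#' @param path TSV written by [write_events_tsv()].
#' @param n_frames,frame_rate_hz movie geometry for the train.
#' @return an [event_train()].
#' @export
read_events_tsv <- function(path, n_frames, frame_rate_hz = 30) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  event_train(d$frame_index, d$weight, n_frames, frame_rate_hz)
}

# ASCII PGM (P2) writer/reader for single grayscale frames
write_pgm <- function(mat, path, max_val = 255) {
  v <- round(pmin(pmax(mat, 0), max_val))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(max_val)),
             con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  stopifnot(lines[1] == "P2")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' Write a movie as numbered PGM frames with a JSON sidecar
#'
#' Frames go to `frame_000001.pgm`, ... in `dir`; the sidecar
#' `movie.json` records `frame_rate_hz`, `degrees_width`, `degrees_height`.
#' Pixel values are clipped into \[0, 255\] and rounded (PGM is 8-bit); use
#' `rescale = TRUE` to map the full data range onto \[0, 255\] first (e.g.
#' for phase-scrambled movies whose values leave the original range).
#'
#' @param movie a [movie_tensor()].
#' @param dir output directory (created if missing).
#' @param rescale rescale min..max to 0..255 before writing.
#' @return `dir`, invisibly.
#' @export
write_movie_frames <- function(movie, dir, rescale = FALSE) {
  stopifnot(inherits(movie, "movie_tensor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- movie$frames
  if (rescale) {
    rg <- range(f)
    f <- if (diff(rg) > 0) (f - rg[1]) / diff(rg) * 255 else f * 0
  }
  for (t in seq_len(dim(f)[3]))
    write_pgm(f[, , t], file.path(dir, sprintf("frame_%06d.pgm", t)))
  jsonlite::write_json(list(frame_rate_hz = movie$frame_rate_hz,
                            degrees_width = movie$degrees_width,
                            degrees_height = movie$degrees_height),
                       file.path(dir, "movie.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a movie from a directory of numbered PGM frames
#'
#' @param dir directory written by [write_movie_frames()] (PGM frames plus
#'   `movie.json`).
#' @return a [movie_tensor()].
#' @export
read_movie_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pgm$", full.names = TRUE))
  if (length(files) == 0L) stop("no PGM frames in ", dir)
  frames <- lapply(files, read_pgm)
  meta_path <- file.path(dir, "movie.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
    list(frame_rate_hz = 30, degrees_width = 26.9, degrees_height = 20.3)
  arr <- array(unlist(frames), c(dim(frames[[1]]), length(frames)))
  movie_tensor(arr, meta$frame_rate_hz, meta$degrees_width,
               meta$degrees_height)
}

#' Write ground truth as JSON
#'
#' Serializes the scalar and vector fields plus the voxel indices of the
#' active mask (1-based linear indices), enough to reconstruct the masks on
#' the stated grid.
#'
#' @param truth a [ground_truth()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(grid_shape = truth$grid_shape, n_timepoints = truth$n_timepoints,
         tr_s = truth$tr_s, frame_rate_hz = truth$frame_rate_hz,
         effect_amplitudes = as.list(truth$effect_amplitudes),
         noise_sd = truth$noise_sd, ar1 = truth$ar1, seed = truth$seed,
         cut_times = truth$cut_times,
         cut_motion_weights = truth$cut_motion_weights,
         gaze_event_times = truth$gaze_event_times,
         active_voxel_index = which(truth$active_voxel_mask),
         component_voxel_index = lapply(truth$component_masks, which),
         shared_signal = truth$shared_signal),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
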