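#' Grayscale movie container
#'
#' Bundles an ordered stack of 2D grayscale frames with its frame rate and the
#' visual angle the display spans. This is the stimulus object consumed by
#' [phase_scramble()], [detect_scene_transitions()] and [weight_events()].
#'
#' @param frames numeric 3D array, `height x width x n_frames`; all values
#'   must be finite.
#' @param frame_rate_hz positive frame rate in Hz.
#' @param degrees_width,degrees_height visual angle spanned by the display.
#' @return an object of class `movie_tensor`.
#' @export
movie_tensor <- function(frames, frame_rate_hz = 30,
                         degrees_width = 26.9, degrees_height = 20.3) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3D array (height x width x n_frames)")
  if (any(dim(frames) <= 0L)) stop("frame dimensions must be positive")
  if (!all(is.finite(frames))) stop("pixel values must be finite")
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be positive")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 degrees_width = degrees_width,
                 degrees_height = degrees_height),
            class = "movie_tensor")
}

#' @export
print.movie_tensor <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_tensor> %d frames of %dx%d px @ %g Hz (%.1f x %.1f deg)\n",
              d[3], d[1], d[2], x$frame_rate_hz,
              x$degrees_width, x$degrees_height))
  invisible(x)
}

n_frames <- function(movie) dim(movie$frames)[3]

#' Weighted point-event train
#'
#' Scene transitions (shot boundaries) as a train of frame-indexed events with
#' non-negative weights (block-matching motion magnitude in pixels/frame).
#' Frame indices are 1-based; an event at frame `t` marks an abrupt change
#' between frames `t - 1` and `t`, so valid times lie in `2..n_frames`.
#'
#' @param times integer frame indices, strictly increasing.
#' @param weights non-negative event weights; recycled from 1 if omitted.
#' @param n_frames total number of frames in the source movie.
#' @param frame_rate_hz frame rate used to convert indices to seconds.
#' @return an object of class `event_train`.
#' @export
event_train <- function(times, weights = rep(1, length(times)),
                        n_frames, frame_rate_hz = 30) {
  times <- as.integer(times)
  if (length(times) && any(diff(times) <= 0))
    stop("event times must be strictly increasing")
  if (length(times) && (min(times) < 2L || max(times) > n_frames))
    stop("event times must lie in [2, n_frames] (an event needs a preceding frame)")
  if (length(weights) != length(times))
    stop("`weights` and `times` must have equal length")
  if (length(weights) && any(weights < 0)) stop("weights must be non-negative")
  structure(list(times = times, weights = as.numeric(weights),
                 n_frames = as.integer(n_frames),
                 frame_rate_hz = frame_rate_hz),
            class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events in %d frames @ %g Hz\n",
              length(x$times), x$n_frames, x$frame_rate_hz))
  invisible(x)
}

#' Seconds at which events occur
#' @param train an [event_train()].
#' @return numeric vector of event onset times in seconds.
#' @export
event_times_s <- function(train) (train$times - 1) / train$frame_rate_hz

#' Eye-tracking gaze trace
#'
#' Timestamped horizontal/vertical gaze coordinates in screen pixels, with the
#' screen geometry needed to convert pixel displacements to visual angle.
#' Defaults match a 800 x 600 display spanning 26.9 x 20.3 degrees sampled at
#' 30 Hz.
#'
#' @param time_s strictly increasing timestamps in seconds.
#' @param x_px,y_px gaze coordinates in pixels; `NA` marks lost samples.
#' @param rate_hz nominal sampling rate.
#' @param screen_px numeric length-2, display resolution (width, height).
#' @param screen_deg numeric length-2, visual angle spanned (width, height).
#' @return an object of class `gaze_trace`.
#' @export
gaze_trace <- function(time_s, x_px, y_px, rate_hz = 30,
                       screen_px = c(800, 600), screen_deg = c(26.9, 20.3)) {
  if (length(time_s) == 0L) stop("empty gaze trace")
  if (any(diff(time_s) <= 0)) stop("timestamps must be strictly increasing")
  if (length(x_px) != length(time_s) || length(y_px) != length(time_s))
    stop("time, x and y must have equal length")
  structure(list(time_s = as.numeric(time_s), x_px = as.numeric(x_px),
                 y_px = as.numeric(y_px), rate_hz = rate_hz,
                 screen_px = screen_px, screen_deg = screen_deg),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("<gaze_trace> %d samples @ %g Hz, %.1f s\n",
              length(x$time_s), x$rate_hz, diff(range(x$time_s))))
  invisible(x)
}

#' 4D fMRI volume
#'
#' Voxel-by-time brain data on a 3D grid with repetition time and brain mask;
#' the unit of all correlation analyses.
#'
#' @param data numeric 4D array `nx x ny x nz x n_timepoints`.
#' @param tr_s repetition time in seconds.
#' @param mask logical 3D array of in-brain voxels; defaults to all `TRUE`.
#' @param subject_id,session_id labels carried through the pipeline.
#' @return an object of class `volume4d`.
#' @export
volume4d <- function(data, tr_s, mask = NULL,
                     subject_id = NA_character_, session_id = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, time)")
  if (dim(data)[4] < 2L) stop("need at least 2 timepoints")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("`tr_s` must be positive")
  grid <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (!identical(dim(mask), as.integer(grid)))
    stop("mask dimensions must match the data grid")
  structure(list(data = data, tr_s = tr_s, mask = mask,
                 subject_id = subject_id, session_id = session_id),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %dx%dx%d grid, %d volumes, TR %g s (subject %s, session %s)\n",
              d[1], d[2], d[3], d[4], x$tr_s, x$subject_id, x$session_id))
  invisible(x)
}

# voxels-in-mask x time matrix view of a volume4d
vox_mat <- function(vol) {
  d <- dim(vol$data)
  m <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4])
  m[as.vector(vol$mask), , drop = FALSE]
}

# rebuild a 3D map from per-masked-voxel values (NA outside the mask)
map_from_masked <- function(values, mask) {
  out <- array(NA_real_, dim(mask))
  out[mask] <- values
  out
}

#' Per-voxel statistic map
#'
#' The output surface of every inference step: a per-voxel statistic with its
#' kind (`r`, `z`, `t`, `p`, `q` or `diff`) and degrees-of-freedom metadata.
#'
#' @param values numeric 3D array; `NA` outside the mask or at flagged voxels.
#' @param stat_kind one of `"r"`, `"z"`, `"t"`, `"p"`, `"q"`, `"diff"`.
#' @param mask logical 3D array.
#' @param dof degrees of freedom (required for `t` maps).
#' @return an object of class `stat_map`.
#' @export
stat_map <- function(values, stat_kind, mask, dof = NULL) {
  stat_kind <- match.arg(stat_kind, c("r", "z", "t", "p", "q", "diff"))
  if (!identical(dim(values), dim(mask)))
    stop("values and mask dimensions differ")
  v <- values[mask]
  v <- v[!is.na(v)]
  if (stat_kind == "r" && length(v) && (min(v) < -1 - 1e-12 || max(v) > 1 + 1e-12))
    stop("r map values must lie in [-1, 1]")
  if (stat_kind %in% c("p", "q") && length(v) && (min(v) < 0 || max(v) > 1))
    stop("p/q map values must lie in [0, 1]")
  if (stat_kind == "t" && is.null(dof))
    stop("t maps require `dof`")
  structure(list(values = values, stat_kind = stat_kind, mask = mask,
                 dof = dof),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<stat_map:%s> %d masked voxels (%d flagged), range [%.3g, %.3g]%s\n",
              x$stat_kind, length(v), sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              if (!is.null(x$dof)) sprintf(", dof %g", x$dof) else ""))
  invisible(x)
}

#' Dice overlap coefficient between two logical masks
#'
#' @param a,b logical arrays of identical dimension.
#' @return `2|a&b| / (|a|+|b|)`; `NaN` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
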