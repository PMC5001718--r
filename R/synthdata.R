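# periodic smooth random texture: Gaussian low-pass of white noise in the
# Fourier domain; periodicity makes subpixel circular shifts exact
random_texture <- function(height, width, scale_px = 6, sd = 30, mean = 128) {
  z <- matrix(stats::rnorm(height * width), height, width)
  fy <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
  fx <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
  att <- exp(-2 * pi^2 * scale_px^2 * outer(fy^2, fx^2, `+`))
  tex <- Re(stats::fft(stats::fft(z) * att, inverse = TRUE)) / length(z)
  tex <- (tex - base::mean(tex)) / stats::sd(tex)
  mean + sd * tex
}

# exact circular shift of a periodic image by (possibly fractional) pixels
# via a Fourier phase ramp
subpixel_shift <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  fy <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fx <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  ramp <- exp(-2i * pi * (outer(fy * dy, fx * dx, `+`)))
  Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / length(img)
}

#' Generate a synthetic movie with injected scene transitions
#'
#' Produces a grayscale movie of a smoothly drifting periodic texture. At
#' each cut time the running texture is globally translated by the stated
#' integer pixel offset in one frame, producing an abrupt frame-to-frame
#' change whose block-matching motion magnitude equals the injected shift.
#' Between cuts the texture drifts by a small fraction of a pixel per frame
#' and independent per-pixel noise is added, giving a non-degenerate
#' background frame-difference level.
#'
#' @param n_frames,height,width movie dimensions (all positive).
#' @param cut_times integer frame indices of the transitions, strictly
#'   increasing, in `2..n_frames` (a cut needs a preceding frame).
#' @param cut_shift_pixels integer translation (pixels, along x) applied at
#'   each cut; one per cut. Its absolute value is the ground-truth motion
#'   magnitude.
#' @param seed integer seed; identical seeds give identical tensors.
#' @param frame_rate_hz frame rate recorded on the movie.
#' @param drift_px_per_frame background drift speed (default 0.1 px/frame).
#' @param texture_scale_px correlation length of the texture (default 6 px).
#' @param noise_sd per-pixel frame noise SD in gray levels (default 0.5).
#' @return list with `movie` (a [movie_tensor()]) and `truth` (list with
#'   `cut_times`, `cut_motion_weights` = `abs(cut_shift_pixels)`, `seed`).
#' @export
generate_movie <- function(n_frames, height, width,
                           cut_times = integer(0),
                           cut_shift_pixels = integer(0),
                           seed = 1, frame_rate_hz = 30,
                           drift_px_per_frame = 0.1,
                           texture_scale_px = 6, noise_sd = 0.5) {
  if (n_frames <= 0 || height <= 0 || width <= 0)
    stop("dimensions must be positive")
  cut_times <- as.integer(cut_times)
  if (length(cut_times)) {
    if (any(diff(cut_times) <= 0)) stop("cut_times must be strictly increasing")
    if (min(cut_times) < 2L || max(cut_times) > n_frames)
      stop("cuts must lie in [2, n_frames] (a cut needs a preceding frame)")
  }
  if (length(cut_shift_pixels) != length(cut_times))
    stop("one shift per cut required")
  set.seed(as.integer(seed))
  tex <- random_texture(height, width, texture_scale_px)
  frames <- array(0, c(height, width, n_frames))
  off_x <- 0
  for (t in seq_len(n_frames)) {
    if (t > 1L) off_x <- off_x + drift_px_per_frame
    k <- match(t, cut_times)
    if (!is.na(k)) off_x <- off_x + cut_shift_pixels[k]
    frames[, , t] <- subpixel_shift(tex, 0, off_x) +
      noise_sd * matrix(stats::rnorm(height * width), height, width)
  }
  list(movie = movie_tensor(frames, frame_rate_hz),
       truth = list(cut_times = cut_times,
                    cut_motion_weights = abs(cut_shift_pixels),
                    seed = seed))
}

#' Generate a synthetic gaze trace with known saccades
#'
#' Piecewise-constant fixation positions starting at screen center, with an
#' instantaneous jump of `saccade_px[k, ]` pixels at each `saccade_times[k]`,
#' plus isotropic Gaussian jitter, sampled at `rate_hz` (default 30).
#'
#' @param duration_s trace duration in seconds.
#' @param rate_hz sampling rate (> 0).
#' @param saccade_times onset seconds in `[0, duration_s)`.
#' @param saccade_px matrix (n x 2) or list of length-2 integer offsets
#'   `(dx, dy)` in pixels.
#' @param jitter_sd_px fixational jitter SD in pixels (>= 0).
#' @param seed integer seed.
#' @param screen_px,screen_deg display geometry (defaults 800 x 600 px,
#'   26.9 x 20.3 deg).
#' @return list with `trace` (a [gaze_trace()]) and `truth` (list with
#'   `gaze_event_times`, `saccade_px`, `seed`).
#' @export
generate_gaze <- function(duration_s, rate_hz = 30,
                          saccade_times = numeric(0),
                          saccade_px = matrix(0, 0, 2),
                          jitter_sd_px = 1, seed = 1,
                          screen_px = c(800, 600),
                          screen_deg = c(26.9, 20.3)) {
  if (rate_hz <= 0) stop("`rate_hz` must be positive")
  if (jitter_sd_px < 0) stop("`jitter_sd_px` must be non-negative")
  if (is.list(saccade_px)) saccade_px <- do.call(rbind, saccade_px)
  saccade_px <- matrix(as.numeric(saccade_px), ncol = 2)
  if (nrow(saccade_px) != length(saccade_times))
    stop("one (dx, dy) offset per saccade required")
  if (length(saccade_times) &&
      (min(saccade_times) < 0 || max(saccade_times) >= duration_s))
    stop("saccade times must lie in [0, duration_s)")
  set.seed(as.integer(seed))
  t_s <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  n <- length(t_s)
  x <- rep(screen_px[1] / 2, n); y <- rep(screen_px[2] / 2, n)
  for (k in seq_along(saccade_times)) {
    after <- t_s >= saccade_times[k]
    x[after] <- x[after] + saccade_px[k, 1]
    y[after] <- y[after] + saccade_px[k, 2]
  }
  x <- x + stats::rnorm(n, sd = jitter_sd_px)
  y <- y + stats::rnorm(n, sd = jitter_sd_px)
  list(trace = gaze_trace(t_s, x, y, rate_hz, screen_px, screen_deg),
       truth = list(gaze_event_times = saccade_times,
                    saccade_px = saccade_px, seed = seed))
}

# standardize to zero mean, unit SD (no-op for constant input)
standardize <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

# smooth stimulus-locked feature time course at TR resolution:
# HRF-convolved white noise, standardized
content_component <- function(n_timepoints, tr_s) {
  raw <- stats::rnorm(n_timepoints)
  kern <- hrf_kernel(hrf_model(), tr_s)
  standardize(stats::convolve(raw, rev(kern),
                              type = "open")[seq_len(n_timepoints)])
}

# HRF-convolved weighted impulse train at TR resolution from event seconds
event_component <- function(times_s, weights, n_timepoints, tr_s) {
  x <- numeric(n_timepoints)
  idx <- pmin(round(times_s / tr_s) + 1L, n_timepoints)
  for (k in seq_along(idx)) x[idx[k]] <- x[idx[k]] + weights[k]
  kern <- hrf_kernel(hrf_model(), tr_s)
  standardize(stats::convolve(x, rev(kern),
                              type = "open")[seq_len(n_timepoints)])
}

# a contiguous rectangular block mask inside a grid
block_mask <- function(grid_shape, lo, hi) {
  m <- array(FALSE, grid_shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Ground truth for a synthetic multi-subject experiment
#'
#' Encodes the generative structure the reliability analyses presuppose: a
#' stimulus-locked component shared across sessions and subjects (the
#' HRF-convolved "content" feature time course), optional scene-cut and
#' gaze event components on their own active regions, and independent
#' session noise. Every component signal is standardized to unit SD, so in a
#' voxel driven by a single component with amplitude `a` and noise SD
#' `sigma`, the expected between-session correlation is
#' `a^2 / (a^2 + sigma^2)`.
#'
#' @param grid_shape 3D voxel grid (default `c(16, 16, 8)`).
#' @param n_timepoints volumes per session (default 160).
#' @param tr_s repetition time (default 2 s).
#' @param effect_amplitudes named amplitudes for `content`, `cuts`, `gaze`.
#' @param component_masks named list of logical 3D masks; defaults place each
#'   nonzero-amplitude component in its own contiguous block.
#' @param cut_times integer movie-frame indices of scene cuts.
#' @param cut_motion_weights non-negative per-cut motion magnitudes.
#' @param gaze_event_times saccade onset seconds.
#' @param frame_rate_hz movie frame rate used to place cut impulses.
#' @param noise_sd session noise SD (> 0; default 1).
#' @param ar1 lag-1 autoregressive coefficient of the session noise
#'   (default 0 = white; in `[0, 1)`).
#' @param brain_mask logical 3D array (default: all voxels in-brain).
#' @param seed integer seed fixing the component time courses and the session
#'   noise streams drawn by [generate_subject_sessions()].
#' @return an object of class `ground_truth` with fields
#'   `active_voxel_mask` (union of active component masks), `shared_signal`
#'   (the content component at TR resolution), `component_signals`,
#'   `component_masks`, `cut_times`, `cut_motion_weights`,
#'   `gaze_event_times`, `effect_amplitudes`, `noise_sd`, `ar1`, `seed`,
#'   `grid_shape`, `n_timepoints`, `tr_s`, `frame_rate_hz`, `brain_mask`.
#' @export
ground_truth <- function(grid_shape = c(16, 16, 8), n_timepoints = 160,
                         tr_s = 2,
                         effect_amplitudes = c(content = 1, cuts = 0,
                                               gaze = 0),
                         component_masks = NULL,
                         cut_times = integer(0),
                         cut_motion_weights = rep(1, length(cut_times)),
                         gaze_event_times = numeric(0),
                         frame_rate_hz = 30,
                         noise_sd = 1, ar1 = 0, brain_mask = NULL,
                         seed = 1) {
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (ar1 < 0 || ar1 >= 1) stop("`ar1` must lie in [0, 1)")
  amp <- c(content = 0, cuts = 0, gaze = 0)
  amp[names(effect_amplitudes)] <- effect_amplitudes
  if (is.null(brain_mask)) brain_mask <- array(TRUE, grid_shape)
  cut_times <- as.integer(cut_times)
  if (length(cut_times) && any(diff(cut_times) <= 0))
    stop("cut_times must be strictly increasing")
  duration <- n_timepoints * tr_s
  if (length(cut_times) && max((cut_times - 1) / frame_rate_hz) >= duration)
    stop("cut beyond the session duration")
  if (length(cut_motion_weights) != length(cut_times))
    stop("one motion weight per cut required")

  if (is.null(component_masks)) {
    # contiguous blocks so map recovery is visually checkable
    g <- grid_shape
    component_masks <- list(
      content = block_mask(g, c(2, 2, 2),
                           pmax(c(2, 2, 2), round(g * 0.6))),
      cuts = block_mask(g, c(round(g[1] * 0.7), 2, 2),
                        c(g[1] - 1, round(g[2] * 0.45), g[3] - 1)),
      gaze = block_mask(g, c(round(g[1] * 0.7), round(g[2] * 0.55), 2),
                        c(g[1] - 1, g[2] - 1, g[3] - 1)))
  }
  for (m in component_masks)
    if (!identical(dim(m), as.integer(grid_shape)))
      stop("component mask dimensions must match the grid")

  set.seed(as.integer(seed))
  signals <- list(
    content = content_component(n_timepoints, tr_s),
    cuts = if (length(cut_times))
      event_component((cut_times - 1) / frame_rate_hz, cut_motion_weights,
                      n_timepoints, tr_s) else numeric(n_timepoints),
    gaze = if (length(gaze_event_times))
      event_component(gaze_event_times, rep(1, length(gaze_event_times)),
                      n_timepoints, tr_s) else numeric(n_timepoints))

  active <- array(FALSE, grid_shape)
  for (nm in names(amp))
    if (amp[[nm]] > 0) active <- active | component_masks[[nm]]
  active <- active & brain_mask
  structure(list(active_voxel_mask = active,
                 shared_signal = signals$content,
                 component_signals = signals,
                 component_masks = component_masks,
                 cut_times = cut_times,
                 cut_motion_weights = as.numeric(cut_motion_weights),
                 gaze_event_times = gaze_event_times,
                 effect_amplitudes = amp,
                 noise_sd = noise_sd, ar1 = ar1,
                 grid_shape = as.integer(grid_shape),
                 n_timepoints = as.integer(n_timepoints),
                 tr_s = tr_s, frame_rate_hz = frame_rate_hz,
                 brain_mask = brain_mask, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %s grid, %d TRs @ %g s; amplitudes [%s]; noise sd %g%s\n",
    paste(x$grid_shape, collapse = "x"), x$n_timepoints, x$tr_s,
    paste(sprintf("%s=%g", names(x$effect_amplitudes), x$effect_amplitudes),
          collapse = ", "),
    x$noise_sd, if (x$ar1 > 0) sprintf(" (AR1 %g)", x$ar1) else ""))
  invisible(x)
}

# AR(1) noise with stationary marginal SD `sd`
ar1_noise <- function(n, phi, sd) {
  if (phi == 0) return(stats::rnorm(n, sd = sd))
  innov_sd <- sd * sqrt(1 - phi^2)
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive"))
}

#' Generate multi-subject repeated-session 4D volumes
#'
#' Each voxel time series is the sum, over components the voxel belongs to,
#' of `amplitude_c * signal_c` (the unit-SD HRF-convolved component time
#' course, identical across sessions and subjects), plus independent
#' Gaussian (optionally AR(1)) noise with SD `truth$noise_sd` drawn freshly
#' per session. Two sessions of one subject therefore differ only in their
#' noise realizations. All randomness derives from `truth$seed`, so repeated
#' calls with the same truth are identical.
#'
#' @param truth a [ground_truth()].
#' @param n_subjects,n_sessions_per_subject study size.
#' @param n_timepoints,grid_shape,tr_s taken from `truth` by default; if
#'   supplied they must match it.
#' @return list of [volume4d()] objects with `subject_id` `"sub<i>"` and
#'   `session_id` `"ses<j>"`, ordered subject-major.
#' @export
generate_subject_sessions <- function(truth, n_subjects,
                                      n_sessions_per_subject,
                                      n_timepoints = truth$n_timepoints,
                                      grid_shape = truth$grid_shape,
                                      tr_s = truth$tr_s) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_timepoints != truth$n_timepoints)
    stop("`n_timepoints` does not match truth$shared_signal length")
  if (!identical(as.integer(grid_shape), truth$grid_shape))
    stop("`grid_shape` does not match the truth grid")
  if (length(truth$shared_signal) != n_timepoints)
    stop("truth$shared_signal length must equal n_timepoints")
  nv <- prod(grid_shape)
  base <- matrix(0, nv, n_timepoints)
  for (nm in names(truth$effect_amplitudes)) {
    a <- truth$effect_amplitudes[[nm]]
    if (a > 0) {
      sel <- as.vector(truth$component_masks[[nm]] & truth$brain_mask)
      base[sel, ] <- base[sel, ] +
        a * matrix(truth$component_signals[[nm]], sum(sel), n_timepoints,
                   byrow = TRUE)
    }
  }
  set.seed(truth$seed + 1L)  # distinct stream from the component draws
  out <- vector("list", n_subjects * n_sessions_per_subject)
  k <- 0L
  for (s in seq_len(n_subjects)) {
    for (j in seq_len(n_sessions_per_subject)) {
      noise <- if (truth$ar1 == 0) {
        matrix(stats::rnorm(nv * n_timepoints, sd = truth$noise_sd),
               nv, n_timepoints)
      } else {
        t(vapply(seq_len(nv), function(i)
          ar1_noise(n_timepoints, truth$ar1, truth$noise_sd),
          numeric(n_timepoints)))
      }
      k <- k + 1L
      out[[k]] <- volume4d(array(base + noise, c(grid_shape, n_timepoints)),
                           tr_s, truth$brain_mask,
                           subject_id = sprintf("sub%02d", s),
                           session_id = sprintf("ses%d", j))
    }
  }
  out
}
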