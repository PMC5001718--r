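# linear interpolation over lost (NA / off-screen) samples; a plain moving
# average would otherwise propagate tracker sentinel values
interpolate_lost <- function(t, v, screen_max = NULL) {
  bad <- !is.finite(v)
  if (!is.null(screen_max)) bad <- bad | v < 0 | v > screen_max
  if (all(bad)) stop("gaze trace contains no valid samples")
  if (any(bad)) {
    v[bad] <- stats::approx(t[!bad], v[!bad], xout = t[bad], rule = 2)$y
  }
  v
}

# centered moving average with the window truncated at the edges
running_mean <- function(v, k) {
  n <- length(v)
  if (k <= 1L) return(v)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half_lo, 1L)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-average smoothing and demeaning of a gaze trace
#'
#' Filters the horizontal and vertical gaze coordinates with a centered
#' moving average over `window_s` seconds (default 1 s, which suppresses the
#' extreme excursions caused by eye blinks), then removes the mean from each
#' axis. Samples flagged as lost (non-finite or off-screen) are linearly
#' interpolated before averaging. The window is truncated at the trace edges.
#'
#' @param trace a [gaze_trace()].
#' @param window_s moving-average window in seconds.
#' @return a [gaze_trace()] with smoothed, demeaned coordinates.
#' @export
smooth_gaze <- function(trace, window_s = 1.0) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (window_s <= 0) stop("`window_s` must be positive")
  x <- interpolate_lost(trace$time_s, trace$x_px, trace$screen_px[1])
  y <- interpolate_lost(trace$time_s, trace$y_px, trace$screen_px[2])
  k <- max(1L, round(window_s * trace$rate_hz))
  x <- running_mean(x, k); y <- running_mean(y, k)
  gaze_trace(trace$time_s, x - mean(x), y - mean(y), trace$rate_hz,
             trace$screen_px, trace$screen_deg)
}

#' Instantaneous saccade-amplitude signal from a gaze trace
#'
#' For each pair of consecutive gaze samples, the visual angle spanned by the
#' displacement. Two displacement models are available: the linear
#' (small-angle) model scales each pixel axis by the degrees-per-pixel of the
#' display (`screen_deg / screen_px`), and the exact model computes the angle
#' between the two gaze rays given a viewing distance. The per-axis angles
#' are combined Euclidean-wise and the resulting amplitude series is
#' demeaned. Differencing makes the signal invariant to constant offsets in
#' either coordinate.
#'
#' @param trace a [gaze_trace()], normally the output of [smooth_gaze()].
#' @param model `"linear"` (default; the display geometry alone suffices) or
#'   `"arctan"` (requires `viewing_distance_px`).
#' @param viewing_distance_px viewing distance expressed in screen pixels
#'   (same unit as the coordinates); only used by the exact model.
#' @param demean subtract the mean amplitude (default `TRUE`).
#' @return numeric vector of length `n - 1` (degrees), with attribute
#'   `time_s` giving the timestamp of the second sample of each pair.
#' @export
saccade_amplitude <- function(trace, model = c("linear", "arctan"),
                              viewing_distance_px = NULL, demean = TRUE) {
  stopifnot(inherits(trace, "gaze_trace"))
  model <- match.arg(model)
  n <- length(trace$time_s)
  if (n < 2L) stop("need at least two gaze samples")
  if (model == "linear") {
    dx_deg <- diff(trace$x_px) * trace$screen_deg[1] / trace$screen_px[1]
    dy_deg <- diff(trace$y_px) * trace$screen_deg[2] / trace$screen_px[2]
    amp <- sqrt(dx_deg^2 + dy_deg^2)
  } else {
    if (is.null(viewing_distance_px))
      stop("the exact model needs `viewing_distance_px`")
    # gaze rays from the eye to screen points (offsets from screen center)
    cx <- mean(range(trace$x_px)); cy <- mean(range(trace$y_px))
    vx <- trace$x_px - cx; vy <- trace$y_px - cy
    d <- viewing_distance_px
    dots <- vx[-n] * vx[-1] + vy[-n] * vy[-1] + d^2
    norms <- sqrt((vx^2 + vy^2 + d^2))
    ct <- pmin(pmax(dots / (norms[-n] * norms[-1]), -1), 1)
    amp <- acos(ct) * 180 / pi
  }
  out <- if (demean) amp - mean(amp) else amp
  attr(out, "time_s") <- trace$time_s[-1]
  out
}

#' Intra-subject gaze-trajectory consistency between two sessions
#'
#' Pearson correlation of the horizontal and of the vertical gaze coordinate
#' series across two sessions of the same stimulus. The second trace is
#' linearly resampled onto the first trace's time grid over the overlapping
#' window before correlating.
#'
#' @param trace_a,trace_b [gaze_trace()] objects.
#' @return named numeric `c(r_x =, r_y =)`; `NA` with a warning when a series
#'   has zero variance (undefined correlation).
#' @export
intra_subject_gaze_consistency <- function(trace_a, trace_b) {
  stopifnot(inherits(trace_a, "gaze_trace"), inherits(trace_b, "gaze_trace"))
  keep <- trace_a$time_s >= min(trace_b$time_s) &
          trace_a$time_s <= max(trace_b$time_s)
  if (sum(keep) < 3L) stop("traces do not overlap enough in time")
  t0 <- trace_a$time_s[keep]
  bx <- stats::approx(trace_b$time_s, trace_b$x_px, xout = t0)$y
  by <- stats::approx(trace_b$time_s, trace_b$y_px, xout = t0)$y
  safe_cor <- function(u, v) {
    if (stats::sd(u) == 0 || stats::sd(v) == 0) {
      warning("zero-variance gaze series; correlation undefined")
      return(NA_real_)
    }
    stats::cor(u, v)
  }
  c(r_x = safe_cor(trace_a$x_px[keep], bx),
    r_y = safe_cor(trace_a$y_px[keep], by))
}
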