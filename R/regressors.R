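#' Canonical double-gamma HRF model
#'
#' Parameters of the canonical hemodynamic response function: a positive
#' gamma density peaking near 6 s minus a scaled gamma undershoot peaking
#' near 16 s, both with 1 s dispersion, undershoot ratio 1/6, kernel length
#' 32 s.
#'
#' @param peak_delay_s,undershoot_delay_s gamma delays in seconds.
#' @param peak_disp_s,undershoot_disp_s gamma dispersions in seconds.
#' @param undershoot_ratio weight of the undershoot gamma.
#' @param length_s kernel length in seconds (>= 24).
#' @return an object of class `hrf_model`.
#' @export
hrf_model <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                      peak_disp_s = 1, undershoot_disp_s = 1,
                      undershoot_ratio = 1 / 6, length_s = 32) {
  if (length_s < 24) stop("kernel length must be at least 24 s")
  structure(list(kind = "canonical-double-gamma",
                 peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_disp_s = peak_disp_s,
                 undershoot_disp_s = undershoot_disp_s,
                 undershoot_ratio = undershoot_ratio,
                 length_s = length_s),
            class = "hrf_model")
}

#' Sample the canonical HRF kernel
#'
#' Double-gamma impulse response sampled at `dt_s`:
#' `dgamma(t, delay/disp, scale = disp)` for the peak minus
#' `ratio * dgamma(...)` for the undershoot. With the default parameters the
#' kernel is 0 at t = 0 and peaks at `(delay - disp)` = 5 s.
#'
#' @param model an [hrf_model()].
#' @param dt_s sampling interval in seconds.
#' @return numeric kernel of length `floor(length_s / dt_s) + 1`.
#' @export
hrf_kernel <- function(model = hrf_model(), dt_s) {
  if (!is.numeric(dt_s) || dt_s <= 0) stop("`dt_s` must be positive")
  t <- seq(0, model$length_s, by = dt_s)
  stats::dgamma(t, shape = model$peak_delay_s / model$peak_disp_s,
                scale = model$peak_disp_s) -
    model$undershoot_ratio *
      stats::dgamma(t, shape = model$undershoot_delay_s / model$undershoot_disp_s,
                    scale = model$undershoot_disp_s)
}

#' Convert a weighted event train to a sampled impulse signal
#'
#' A time series of zeros with an impulse of height equal to the event weight
#' at each event time, at the requested sampling rate.
#'
#' @param train an [event_train()].
#' @param rate_hz sampling rate of the output signal.
#' @param duration_s signal duration in seconds.
#' @return numeric vector of length `round(duration_s * rate_hz)`.
#' @export
events_to_signal <- function(train, rate_hz, duration_s) {
  stopifnot(inherits(train, "event_train"))
  if (rate_hz <= 0 || duration_s <= 0) stop("rate and duration must be positive")
  n <- round(duration_s * rate_hz)
  x <- numeric(n)
  if (length(train$times) == 0L) return(x)
  t_s <- event_times_s(train)
  if (any(t_s >= duration_s)) stop("event beyond the signal duration")
  idx <- round(t_s * rate_hz) + 1L
  x[idx] <- x[idx] + train$weights
  x
}

#' Build a hemodynamic regressor from a stimulus or behavior signal
#'
#' The regressor-construction chain applied to every explanatory signal
#' (saccade amplitude, scene-transition events): demean, convolve causally
#' with the canonical HRF at the source rate (zero-padded start, truncated to
#' the signal length), anti-alias low-pass filter (zero-phase 4th-order
#' Butterworth, default cutoff 0.25 Hz), sample at the volume acquisition
#' times `k * tr_s`, demean again.
#'
#' @param signal numeric time series at `source_rate_hz`.
#' @param source_rate_hz sampling rate of `signal` in Hz.
#' @param hrf an [hrf_model()].
#' @param tr_s scanner repetition time in seconds.
#' @param n_volumes number of volumes the regressor must cover.
#' @param cutoff_hz anti-alias cutoff; must be below the source Nyquist.
#' @param name label carried on the regressor.
#' @return an object of class `regressor` with fields `values` (length
#'   `n_volumes`), `tr_s`, `name`, `source_rate_hz`.
#' @export
build_regressor <- function(signal, source_rate_hz, hrf = hrf_model(),
                            tr_s, n_volumes, cutoff_hz = 0.25,
                            name = "regressor") {
  if (source_rate_hz <= 0) stop("`source_rate_hz` must be positive")
  if (cutoff_hz >= source_rate_hz / 2)
    stop("`cutoff_hz` must be below the source Nyquist frequency")
  if (length(signal) < round((n_volumes - 1) * tr_s * source_rate_hz) + 1)
    stop("signal too short to cover the last acquisition time")
  x <- signal - mean(signal)
  dt <- 1 / source_rate_hz
  kern <- hrf_kernel(hrf, dt)
  conv <- stats::convolve(x, rev(kern), type = "open")[seq_along(x)] * dt
  bf <- signal::butter(4, cutoff_hz / (source_rate_hz / 2), type = "low")
  filt <- signal::filtfilt(bf, conv)
  idx <- round((seq_len(n_volumes) - 1L) * tr_s * source_rate_hz) + 1L
  if (max(idx) > length(filt)) stop("signal too short after resampling")
  v <- filt[idx]
  structure(list(values = v - mean(v), tr_s = tr_s, name = name,
                 source_rate_hz = source_rate_hz),
            class = "regressor")
}

#' @export
print.regressor <- function(x, ...) {
  cat(sprintf("<regressor:%s> %d volumes @ TR %g s (source %g Hz)\n",
              x$name, length(x$values), x$tr_s, x$source_rate_hz))
  invisible(x)
}

#' Polynomial detrending of a time series
#'
#' Removes a least-squares polynomial fit of the given order (default 3,
#' modelling slow scanner drift); the residual is orthogonal to the
#' polynomial basis.
#'
#' @param series numeric vector, length > order + 1.
#' @param order polynomial order.
#' @return detrended residual of the same length.
#' @export
detrend_poly <- function(series, order = 3) {
  n <- length(series)
  if (n <= order + 1) stop("series too short for the requested order")
  X <- cbind(1, stats::poly(seq_len(n), degree = order))
  as.numeric(series - X %*% qr.coef(qr(X), series))
}

# detrend every row of a voxels x time matrix (shared basis, one solve)
detrend_poly_rows <- function(m, order = 3) {
  n <- ncol(m)
  if (n <= order + 1) stop("series too short for the requested order")
  X <- cbind(1, stats::poly(seq_len(n), degree = order))
  t(qr.resid(qr(X), t(m)))
}

# 1D symmetric-kernel convolution along dimension `d` of a 3D/4D array with
# half-sample (repeat-edge) mirror boundaries; conserves the total sum
convolve_dim_reflect <- function(arr, kern, d) {
  r <- (length(kern) - 1L) / 2L
  n <- dim(arr)[d]
  out <- array(0, dim(arr))
  idx <- vector("list", length(dim(arr)))
  idx[] <- list(quote(expr = ))
  for (s in -r:r) {
    src <- seq_len(n) + s
    src[src < 1L] <- 1L - src[src < 1L]
    src[src > n] <- 2L * n + 1L - src[src > n]
    idx[[d]] <- src
    out <- out + kern[s + r + 1L] * do.call(`[`, c(list(arr), idx))
  }
  out
}

#' Spatial Gaussian smoothing of a 4D volume
#'
#' Convolves each time frame with an isotropic 3D Gaussian of the given full
#' width at half maximum (`sigma = fwhm / (2 sqrt(2 ln 2))` in mm, converted
#' to voxel units), implemented separably with repeat-edge mirror boundaries
#' so the per-frame sum is conserved.
#'
#' @param vol a [volume4d()].
#' @param fwhm_mm full width at half maximum in mm (default 6).
#' @param voxel_mm isotropic voxel edge in mm (default 3).
#' @return a smoothed [volume4d()] with the same metadata.
#' @export
smooth_gaussian_3d <- function(vol, fwhm_mm = 6.0, voxel_mm = 3.0) {
  stopifnot(inherits(vol, "volume4d"))
  if (fwhm_mm <= 0) stop("`fwhm_mm` must be positive")
  if (fwhm_mm < voxel_mm) stop("FWHM below the voxel size is not supported")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3 * sigma_vox))
  if (any(r > dim(vol$data)[1:3]))
    stop("kernel radius exceeds the grid; grid too small for this FWHM")
  kern <- stats::dnorm(-r:r, sd = sigma_vox)
  kern <- kern / sum(kern)
  out <- vol$data
  for (d in 1:3) out <- convolve_dim_reflect(out, kern, d)
  volume4d(out, vol$tr_s, vol$mask, vol$subject_id, vol$session_id)
}
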