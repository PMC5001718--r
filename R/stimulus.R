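#' Fourier phase scrambling of a grayscale movie
#'
#' Produces a control stimulus matched to the input in its full 3D (space x
#' time) Fourier magnitude spectrum but with randomized phases, destroying all
#' perceptual structure while preserving the second-order statistics
#' (luminance distribution, spatial and temporal frequency content).
#'
#' The random phases are taken from the 3D FFT of a white-noise array, which
#' is Hermitian-symmetric by construction, so the scrambled spectrum is
#' Hermitian and the inverse transform is real. The DC phase is fixed at 0,
#' preserving the global mean intensity exactly; every magnitude is preserved
#' exactly because only unit-modulus phase factors are substituted.
#'
#' @param movie a [movie_tensor()].
#' @param seed integer seed; the same seed reproduces the same scramble.
#' @param clip optional length-2 numeric range to clip the output into; by
#'   default the output is left unclipped (values may leave the input range;
#'   clipping would alter the magnitude spectrum).
#' @return a [movie_tensor()] of the same shape and metadata.
#' @export
phase_scramble <- function(movie, seed, clip = NULL) {
  stopifnot(inherits(movie, "movie_tensor"))
  f <- movie$frames
  if (length(f) == 0L) stop("empty movie")
  spec <- stats::fft(f)
  set.seed(as.integer(seed))
  noise <- array(stats::rnorm(length(f)), dim(f))
  phase <- Arg(stats::fft(noise))
  phase[1, 1, 1] <- 0  # keep DC (global mean) exactly
  out_spec <- Mod(spec) * exp(1i * phase)
  out <- Re(stats::fft(out_spec, inverse = TRUE)) / length(f)
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  movie_tensor(out, movie$frame_rate_hz, movie$degrees_width,
               movie$degrees_height)
}

#' Frame-difference series of a movie
#'
#' Sum of absolute pixel differences between consecutive frames; element `t`
#' is the difference between frames `t` and `t + 1` shifted so that the value
#' for frame index `t` (2..n) describes the change into that frame.
#'
#' @param movie a [movie_tensor()] with at least two frames.
#' @return numeric vector of length `n_frames - 1`, named by target frame.
#' @export
frame_difference <- function(movie) {
  f <- movie$frames
  nf <- dim(f)[3]
  if (nf < 2L) stop("need at least two frames")
  d <- vapply(seq_len(nf - 1L),
              function(t) sum(abs(f[, , t + 1L] - f[, , t])),
              numeric(1))
  names(d) <- as.character(2:nf)
  d
}

#' Detect scene transitions (shot boundaries)
#'
#' Flags frames where the sum of absolute pixel differences against the
#' preceding frame exceeds a threshold. With `threshold = "auto"` the
#' threshold is `mean + k * SD` of the background frame-difference series,
#' estimated iteratively: exceedances are excluded and the threshold
#' re-computed until stable, so that the cuts themselves do not inflate the
#' background spread (one large cut would otherwise mask smaller ones). This
#' outlier rule stands in for manual visual affirmation of each cut.
#'
#' @param movie a [movie_tensor()] with at least two frames.
#' @param threshold positive numeric, or `"auto"`.
#' @param k multiplier for the auto threshold (default 5 SD).
#' @return an [event_train()] of transition frame indices, weights
#'   initialized to 1. Pass to [weight_events()] for motion weighting.
#' @export
detect_scene_transitions <- function(movie, threshold = "auto", k = 5) {
  d <- frame_difference(movie)
  if (identical(threshold, "auto")) {
    keep <- rep(TRUE, length(d))
    for (it in 1:10) {
      threshold <- mean(d[keep]) + k * stats::sd(d[keep])
      if (is.na(threshold)) { threshold <- mean(d[keep]); break }
      new_keep <- d <= threshold
      if (identical(new_keep, keep)) break
      keep <- new_keep
    }
  } else if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive or \"auto\"")
  }
  times <- which(d > threshold) + 1L
  event_train(times, rep(1, length(times)), n_frames = n_frames(movie),
              frame_rate_hz = movie$frame_rate_hz)
}

# candidate displacements ordered by magnitude, then row-major (dy, dx);
# ties in SAD are broken by taking the earliest candidate in this order
displacement_grid <- function(max_displacement) {
  g <- expand.grid(dx = -max_displacement:max_displacement,
                   dy = -max_displacement:max_displacement)
  g <- g[order(g$dx^2 + g$dy^2, g$dy, g$dx), ]
  as.matrix(g[, c("dy", "dx")])
}

#' Block-matching motion estimation between two frames
#'
#' Partitions `frame_a` into `block_size x block_size` tiles (partial tiles at
#' the borders are truncated) and finds, for each tile, the integer
#' displacement within `+/- max_displacement` that minimizes the
#' sum-of-absolute-differences (SAD) against `frame_b`, searching
#' exhaustively. Candidate displacements that would move the tile outside
#' `frame_b` are skipped. Ties are broken toward the smallest displacement
#' magnitude, then row-major order.
#'
#' The scalar motion weight is the mean Euclidean magnitude of the estimated
#' displacements over interior tiles, i.e. tiles whose full search window lies
#' inside the frame; border tiles have a clipped search range that cannot
#' identify the true displacement, and on small frames they would dominate
#' the mean. If no tile is interior, all tiles contribute.
#'
#' @param frame_a,frame_b numeric matrices of identical shape.
#' @param block_size tile edge in pixels (default 9).
#' @param max_displacement search radius in pixels.
#' @return list with `dy`, `dx` (per-tile displacement matrices), `magnitude`
#'   (per-tile Euclidean magnitude), `interior` (logical, full search window
#'   in bounds) and `weight` (scalar mean magnitude over interior tiles).
#' @export
block_matching_motion <- function(frame_a, frame_b, block_size = 9,
                                  max_displacement = 8) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stop("frames must have the same shape")
  h <- nrow(frame_a); w <- ncol(frame_a)
  if (block_size > h || block_size > w)
    stop("block_size larger than the image")
  if (max_displacement < 1) stop("max_displacement must be >= 1")
  cand <- displacement_grid(max_displacement)
  r0 <- seq(1L, h, by = block_size)
  c0 <- seq(1L, w, by = block_size)
  nb_r <- length(r0); nb_c <- length(c0)
  dy <- dx <- matrix(0L, nb_r, nb_c)
  interior <- matrix(FALSE, nb_r, nb_c)
  for (i in seq_len(nb_r)) {
    rows <- r0[i]:min(r0[i] + block_size - 1L, h)
    for (j in seq_len(nb_c)) {
      cols <- c0[j]:min(c0[j] + block_size - 1L, w)
      blk <- frame_a[rows, cols, drop = FALSE]
      interior[i, j] <-
        rows[1] - max_displacement >= 1L &&
        rows[length(rows)] + max_displacement <= h &&
        cols[1] - max_displacement >= 1L &&
        cols[length(cols)] + max_displacement <= w
      best <- Inf; best_d <- c(0L, 0L)
      for (ci in seq_len(nrow(cand))) {
        di <- cand[ci, 1L]; dj <- cand[ci, 2L]
        tr <- rows + di; tc <- cols + dj
        if (tr[1] < 1L || tr[length(tr)] > h ||
            tc[1] < 1L || tc[length(tc)] > w) next
        sad <- sum(abs(blk - frame_b[tr, tc, drop = FALSE]))
        if (sad < best) { best <- sad; best_d <- c(di, dj) }
      }
      dy[i, j] <- best_d[1L]; dx[i, j] <- best_d[2L]
    }
  }
  mag <- sqrt(dy^2 + dx^2)
  use <- if (any(interior)) interior else !is.na(mag)
  list(dy = dy, dx = dx, magnitude = mag, interior = interior,
       weight = mean(mag[use]))
}

#' Weight scene-transition events by block-matching motion
#'
#' Replaces each event's weight by the scalar motion weight between the frame
#' preceding the event and the event frame, estimated with
#' [block_matching_motion()].
#'
#' @param train an [event_train()].
#' @param movie the [movie_tensor()] the events refer to.
#' @param block_size block-matching tile size (default 9).
#' @param max_displacement block-matching search radius in pixels.
#' @return the train with motion-magnitude weights (pixels/frame).
#' @export
weight_events <- function(train, movie, block_size = 9, max_displacement = 8) {
  stopifnot(inherits(train, "event_train"), inherits(movie, "movie_tensor"))
  if (length(train$times) == 0L) return(train)
  if (min(train$times) < 2L) stop("event at the first frame has no predecessor")
  if (max(train$times) > n_frames(movie)) stop("event beyond the movie")
  w <- vapply(train$times, function(t) {
    block_matching_motion(movie$frames[, , t - 1L], movie$frames[, , t],
                          block_size = block_size,
                          max_displacement = max_displacement)$weight
  }, numeric(1))
  event_train(train$times, w, n_frames = train$n_frames,
              frame_rate_hz = train$frame_rate_hz)
}
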