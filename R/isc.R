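# Pearson correlation of corresponding rows of two matrices (voxels x time);
# rows with zero variance give NA
row_correlation <- function(a, b) {
  am <- a - rowMeans(a)
  bm <- b - rowMeans(b)
  sa <- sqrt(rowSums(am^2))
  sb <- sqrt(rowSums(bm^2))
  r <- rowSums(am * bm) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  # guard rounding just past +/-1
  pmin(pmax(r, -1), 1)
}

# correlation of each row of `m` with one vector `v`
row_cor_vec <- function(m, v) {
  vm <- v - mean(v)
  sv <- sqrt(sum(vm^2))
  if (sv == 0) stop("zero-variance regressor")
  mm <- m - rowMeans(m)
  sm <- sqrt(rowSums(mm^2))
  r <- as.numeric(mm %*% vm) / (sm * sv)
  r[sm == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

check_matched <- function(a, b) {
  if (!identical(dim(a$data)[1:3], dim(b$data)[1:3]))
    stop("volume grids do not match")
  if (dim(a$data)[4] != dim(b$data)[4])
    stop("time series lengths do not match")
  if (!any(a$mask & b$mask)) stop("masks are disjoint")
}

#' Voxelwise zero-lag Pearson correlation between two sessions
#'
#' The elementary reliability measurement: for every voxel in the shared
#' mask, the zero-lag Pearson correlation between the two time series.
#' Between two sessions of the same subject this is the intra-subject
#' correlation; between sessions of different subjects, an inter-subject
#' correlation. Voxels with zero variance in either series are flagged `NA`.
#'
#' @param a,b [volume4d()] objects on the same grid with equal lengths.
#' @return a [stat_map()] of kind `"r"` on the intersection mask.
#' @export
voxelwise_correlation <- function(a, b) {
  stopifnot(inherits(a, "volume4d"), inherits(b, "volume4d"))
  check_matched(a, b)
  mask <- a$mask & b$mask
  av <- volume4d(a$data, a$tr_s, mask)
  bv <- volume4d(b$data, b$tr_s, mask)
  r <- row_correlation(vox_mat(av), vox_mat(bv))
  stat_map(map_from_masked(r, mask), "r", mask)
}

#' Fisher r-to-z transform of a correlation map
#'
#' `z = atanh(r)` per voxel. The number of timepoints minus one is recorded
#' as degrees-of-freedom metadata on the map; the transform itself is the
#' unscaled atanh (group-level inference is supplied by the t-test across
#' subjects, not by a per-voxel variance rescaling). Voxels with `|r| >= 1`
#' are flagged `NA` rather than mapped to infinity.
#'
#' @param rmap a [stat_map()] of kind `"r"`.
#' @param n_timepoints number of timepoints the correlations were computed
#'   from.
#' @return a [stat_map()] of kind `"z"` with `dof = n_timepoints - 1`.
#' @export
fisher_z <- function(rmap, n_timepoints) {
  stopifnot(inherits(rmap, "stat_map"), rmap$stat_kind == "r")
  v <- rmap$values
  z <- ifelse(abs(v) < 1, atanh(v), NA_real_)
  stat_map(z, "z", rmap$mask, dof = as.integer(n_timepoints) - 1L)
}

# vectorised one-sample t across columns of a voxels x subjects matrix
one_sample_t_rows <- function(zmat) {
  n <- ncol(zmat)
  m <- rowMeans(zmat)
  s <- sqrt(rowSums((zmat - m)^2) / (n - 1))
  t_stat <- m / (s / sqrt(n))
  t_stat[s == 0] <- NA_real_
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, p = p, mean = m, dof = n - 1L)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with `m` p-values sorted ascending, reject all
#' hypotheses up to the largest `i` with `p(i) <= i * q / m`. Adjusted q
#' values are the monotone `p * m / i` (computed via [stats::p.adjust()]);
#' rejection at level `q_level` is `q <= q_level`.
#'
#' @param pvalues numeric p-values in \[0, 1\] (`NA` allowed, never rejected).
#' @param q_level FDR level.
#' @return list with `reject` (logical) and `q` (adjusted values).
#' @export
bh_fdr <- function(pvalues, q_level = 0.03) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  reject <- !is.na(q) & q <= q_level
  list(reject = reject, q = q)
}

#' Group-level test of intra-subject reproducibility
#'
#' Averages nothing away: takes one Fisher-z map per subject, runs a
#' voxelwise one-sample t-test of the subject z values against zero
#' (`dof = n_subjects - 1`), converts to two-sided p, and controls the false
#' discovery rate across masked voxels with the Benjamini-Hochberg step-up at
#' `q_level`. The significance mask is the BH-rejected set; `p_thresh` is
#' recorded in the output for reporting (the realized p cutoff of a BH
#' rejection set is data-dependent).
#'
#' @param zmaps list of [stat_map()] objects of kind `"z"`, one per subject.
#' @param p_thresh nominal voxelwise p threshold to record (default 0.0033).
#' @param q_level FDR level (default 0.03).
#' @return list with `mean_z`, `t_map`, `p_map`, `q_map` ([stat_map()]s),
#'   `sig_mask` (logical 3D array), `dof`, `p_thresh`, `q_level`.
#' @export
intra_subject_group_test <- function(zmaps, p_thresh = 0.0033,
                                     q_level = 0.03) {
  if (length(zmaps) < 3L) stop("need at least 3 subjects")
  stopifnot(all(vapply(zmaps, function(m)
    inherits(m, "stat_map") && m$stat_kind == "z", logical(1))))
  mask <- Reduce(`&`, lapply(zmaps, `[[`, "mask"))
  zmat <- vapply(zmaps, function(m) m$values[mask], numeric(sum(mask)))
  res <- one_sample_t_rows(zmat)
  q <- bh_fdr(res$p, q_level)
  sig <- array(FALSE, dim(mask))
  sig[mask] <- q$reject
  list(mean_z = stat_map(map_from_masked(res$mean, mask), "z", mask,
                         dof = zmaps[[1]]$dof),
       t_map = stat_map(map_from_masked(res$t, mask), "t", mask,
                        dof = res$dof),
       p_map = stat_map(map_from_masked(res$p, mask), "p", mask),
       q_map = stat_map(map_from_masked(q$q, mask), "q", mask),
       sig_mask = sig, dof = res$dof,
       p_thresh = p_thresh, q_level = q_level)
}

subject_pairs <- function(n) {
  idx <- utils::combn(n, 2)
  lapply(seq_len(ncol(idx)), function(k) idx[, k])
}

#' Pairwise inter-subject correlation maps
#'
#' Computes the voxelwise zero-lag correlation for every unordered pair of
#' subjects watching the same stimulus, and summarizes them as the mean of
#' the Fisher-z pairwise maps.
#'
#' @param sessions list of [volume4d()] objects, one per subject, matched in
#'   grid and length.
#' @return list with `pair_maps` (list of `"r"` [stat_map()]s named
#'   `"i-j"`), `pairs` (list of index pairs), and `mean_z` ([stat_map()]).
#' @export
inter_subject_correlation <- function(sessions) {
  n <- length(sessions)
  if (n < 2L) stop("need at least 2 subjects")
  pairs <- subject_pairs(n)
  nt <- dim(sessions[[1]]$data)[4]
  pair_maps <- lapply(pairs, function(pr)
    voxelwise_correlation(sessions[[pr[1]]], sessions[[pr[2]]]))
  names(pair_maps) <- vapply(pairs, function(pr)
    paste(pr, collapse = "-"), character(1))
  mask <- pair_maps[[1]]$mask
  zsum <- Reduce(`+`, lapply(pair_maps, function(m)
    ifelse(abs(m$values) < 1, atanh(m$values), NA_real_)))
  list(pair_maps = pair_maps, pairs = pairs,
       mean_z = stat_map(zsum / length(pair_maps), "z", mask,
                         dof = nt - 1L))
}

#' Circular-shift permutation null for inter-subject correlation
#'
#' Builds an empirical null distribution of trivial inter-subject
#' correlations by circularly shifting every subject's time series by a
#' random, subject-distinct amount (so the series are no longer aligned in
#' time), then computing pairwise correlations at a random subsample of mask
#' voxels and pooling them into a single null. The procedure respects the
#' autocorrelation of each series, unlike a parametric null. Shifts are drawn
#' uniformly from `[T/8, 7T/8]` volumes, excluding identity shifts and
#' near-zero shifts that would leave residual alignment.
#'
#' `n_null_samples` counts pooled null correlation values (draws x pairs x
#' sampled voxels), matching how large permutation nulls are reported for
#' this method.
#'
#' Two observed quantities are tested against their pooled nulls, upper tail
#' (the alternative is positive synchrony), with the p floor
#' `(1 + #null >= obs) / (1 + n_null)`:
#' the individual pairwise correlations (`p_pair`) and the per-voxel mean
#' pairwise Fisher z (`p_map`).
#'
#' @param sessions list of [volume4d()] objects, one per subject.
#' @param n_null_samples minimum number of pooled null samples (>= 1000).
#' @param seed integer seed for shift and voxel sampling.
#' @param n_sample_voxels voxels sampled per draw for the null (default 200,
#'   capped at the mask size).
#' @param q_level FDR level applied to the per-voxel p map.
#' @return list with `null_pair`, `null_mean_z` (pooled null samples),
#'   `p_pair` (voxels-in-mask x pairs matrix), `p_map`, `q_map`
#'   ([stat_map()]s), `sig_mask`, `pairs`, `n_draws`.
#' @export
circular_shift_null <- function(sessions, n_null_samples, seed,
                                n_sample_voxels = 200, q_level = 0.03) {
  n <- length(sessions)
  if (n < 2L) stop("need at least 2 subjects")
  if (n_null_samples < 1000) stop("need at least 1000 null samples")
  nt <- dim(sessions[[1]]$data)[4]
  lo <- max(1L, ceiling(nt / 8)); hi <- floor(7 * nt / 8)
  if (hi - lo + 1L < n)
    stop("series too short to draw distinct shifts for every subject")
  mask <- Reduce(`&`, lapply(sessions, `[[`, "mask"))
  mats <- lapply(sessions, function(s)
    vox_mat(volume4d(s$data, s$tr_s, mask)))
  nv <- nrow(mats[[1]])
  nvs <- min(n_sample_voxels, nv)
  pairs <- subject_pairs(n)
  np <- length(pairs)
  n_draws <- ceiling(n_null_samples / (np * nvs))

  set.seed(as.integer(seed))
  null_pair <- vector("list", n_draws)
  null_mean <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    shifts <- sample(lo:hi, n, replace = FALSE)
    vsel <- sample.int(nv, nvs)
    shifted <- lapply(seq_len(n), function(i) {
      ord <- c((shifts[i] + 1L):nt, 1L:shifts[i])
      mats[[i]][vsel, ord, drop = FALSE]
    })
    rp <- vapply(pairs, function(pr)
      row_correlation(shifted[[pr[1]]], shifted[[pr[2]]]),
      numeric(nvs))
    null_pair[[d]] <- as.numeric(rp)
    null_mean[[d]] <- rowMeans(atanh(pmin(pmax(rp, -0.999999), 0.999999)))
  }
  null_pair <- sort(unlist(null_pair))
  null_mean <- sort(unlist(null_mean))

  # observed statistics on the full mask
  obs_pair <- vapply(pairs, function(pr)
    row_correlation(mats[[pr[1]]], mats[[pr[2]]]), numeric(nv))
  obs_mean <- rowMeans(atanh(pmin(pmax(obs_pair, -0.999999), 0.999999)))

  upper_p <- function(obs, null_sorted) {
    ge <- length(null_sorted) - findInterval(obs, null_sorted,
                                             left.open = TRUE)
    (1 + ge) / (1 + length(null_sorted))
  }
  p_pair <- apply(obs_pair, 2, upper_p, null_sorted = null_pair)
  p_vox <- upper_p(obs_mean, null_mean)
  q <- bh_fdr(p_vox, q_level)
  sig <- array(FALSE, dim(mask))
  sig[mask] <- q$reject
  list(null_pair = null_pair, null_mean_z = null_mean,
       p_pair = p_pair,
       p_map = stat_map(map_from_masked(p_vox, mask), "p", mask),
       q_map = stat_map(map_from_masked(q$q, mask), "q", mask),
       sig_mask = sig, pairs = pairs, n_draws = n_draws)
}

#' Nuisance variable regression (NVR)
#'
#' Removes confound regressors from every voxel time series by ordinary
#' least squares on `[intercept | regressors]`; returns the residual volume.
#' Residuals are orthogonal to every regressor.
#'
#' @param vol a [volume4d()].
#' @param regressors list of `regressor` objects (or plain numeric vectors)
#'   matching the volume's length.
#' @return a [volume4d()] of residuals with the same metadata.
#' @export
nuisance_regression <- function(vol, regressors) {
  stopifnot(inherits(vol, "volume4d"))
  if (!is.list(regressors) || inherits(regressors, "regressor"))
    regressors <- list(regressors)
  nt <- dim(vol$data)[4]
  cols <- lapply(regressors, function(r)
    if (inherits(r, "regressor")) r$values else as.numeric(r))
  if (any(vapply(cols, length, integer(1)) != nt))
    stop("regressor length does not match the volume")
  X <- cbind(intercept = 1, do.call(cbind, cols))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)])
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  d <- dim(vol$data)
  Y <- t(matrix(vol$data, nrow = prod(d[1:3]), ncol = nt))
  res <- qr.resid(qx, Y)
  out <- array(t(res), dim = d)
  volume4d(out, vol$tr_s, vol$mask, vol$subject_id, vol$session_id)
}

#' Group map of correlation between the fMRI signal and a regressor
#'
#' For every session, correlates each voxel time series with that session's
#' regressor (zero lag); transforms to Fisher z; tests across sessions with a
#' voxelwise one-sample t; controls FDR with Benjamini-Hochberg.
#'
#' @param sessions list of [volume4d()] objects.
#' @param regressors list of `regressor` objects, one per session.
#' @param p_thresh nominal p threshold recorded on the output.
#' @param q_level FDR level.
#' @return as [intra_subject_group_test()], plus `r_maps` (per-session list).
#' @export
regressor_correlation_map <- function(sessions, regressors,
                                      p_thresh = 0.011, q_level = 0.03) {
  if (length(sessions) != length(regressors))
    stop("need exactly one regressor per session")
  nt <- dim(sessions[[1]]$data)[4]
  mask <- Reduce(`&`, lapply(sessions, `[[`, "mask"))
  zmaps <- vector("list", length(sessions))
  r_maps <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    v <- if (inherits(regressors[[i]], "regressor"))
      regressors[[i]]$values else as.numeric(regressors[[i]])
    if (length(v) != nt) stop("regressor length does not match session ", i)
    if (stats::sd(v) == 0) stop("zero-variance regressor for session ", i)
    m <- vox_mat(volume4d(sessions[[i]]$data, sessions[[i]]$tr_s, mask))
    r <- row_cor_vec(m, v)
    r_maps[[i]] <- stat_map(map_from_masked(r, mask), "r", mask)
    zmaps[[i]] <- fisher_z(r_maps[[i]], nt)
  }
  out <- intra_subject_group_test(zmaps, p_thresh = p_thresh,
                                  q_level = q_level)
  out$r_maps <- r_maps
  out
}

#' Contrast of reproducibility with vs without a manipulation
#'
#' Tests the voxelwise difference in Fisher-z reproducibility between two
#' states, either paired (the same subjects with vs without nuisance
#' regression; paired t, `dof = n - 1`) or two-sample (e.g. free viewing
#' vs fixation groups; pooled-variance t, `dof = n1 + n2 - 2`). The
#' threshold is an uncorrected voxelwise p, as is conventional for these
#' difference maps.
#'
#' @param z_without,z_with lists of `"z"` [stat_map()]s. For `"paired"` the
#'   lists are matched by subject; for `"two_sample"` they are the two
#'   groups.
#' @param test `"paired"` or `"two_sample"`.
#' @param p_thresh uncorrected voxelwise p threshold (default 0.03).
#' @return list with `diff_map` (mean without-minus-with difference,
#'   [stat_map()] kind `"diff"`), `t_map`, `p_map`, `sig_mask`, `dof`.
#' @export
reproducibility_difference <- function(z_without, z_with,
                                       test = c("paired", "two_sample"),
                                       p_thresh = 0.03) {
  test <- match.arg(test)
  getz <- function(maps, mask) vapply(maps, function(m) m$values[mask],
                                      numeric(sum(mask)))
  mask <- Reduce(`&`, lapply(c(z_without, z_with), `[[`, "mask"))
  if (test == "paired") {
    if (length(z_without) != length(z_with))
      stop("paired test needs matched subject lists")
    if (length(z_without) < 2L) stop("paired test needs at least 2 pairs")
    dmat <- getz(z_without, mask) - getz(z_with, mask)
    res <- one_sample_t_rows(dmat)
    diff_v <- res$mean; t_v <- res$t; p_v <- res$p; dof <- res$dof
  } else {
    n1 <- length(z_without); n2 <- length(z_with)
    if (n1 < 2L || n2 < 2L) stop("two-sample test needs >= 2 per group")
    a <- getz(z_without, mask); b <- getz(z_with, mask)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    ss1 <- rowSums((a - m1)^2); ss2 <- rowSums((b - m2)^2)
    dof <- n1 + n2 - 2L
    sp <- sqrt((ss1 + ss2) / dof)
    t_v <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    t_v[sp == 0] <- NA_real_
    p_v <- 2 * stats::pt(-abs(t_v), df = dof)
    diff_v <- m1 - m2
  }
  sig <- array(FALSE, dim(mask))
  sig[mask] <- !is.na(p_v) & p_v <= p_thresh
  list(diff_map = stat_map(map_from_masked(diff_v, mask), "diff", mask),
       t_map = stat_map(map_from_masked(t_v, mask), "t", mask, dof = dof),
       p_map = stat_map(map_from_masked(p_v, mask), "p", mask),
       sig_mask = sig, dof = dof, p_thresh = p_thresh)
}
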