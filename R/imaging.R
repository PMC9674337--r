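# Calcium-imaging analysis: motion correction, dF/F, ROI metrics, and the
# center-of-mass retinotopy test with a pixel-shuffle permutation null.

#' Construct a fluorescence movie
#'
#' @param frames T x H x W array of fluorescence counts (>= 0).
#' @param frame_rate Acquisition rate, Hz (default 5).
#' @param pixel_size_um Pixel size, um (default 0.9).
#' @param timeline Named list of stimulus markers, s from movie start:
#'   `stim_start`, `stim_end` (end of expansion), optionally `flash`.
#' @return A `fluor_movie`.
#' @export
fluor_movie <- function(frames, frame_rate = 5, pixel_size_um = 0.9,
                        timeline = list()) {
  stopifnot(length(dim(frames)) == 3, all(frames >= 0, na.rm = TRUE))
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size_um = pixel_size_um, timeline = timeline,
                 times = (seq_len(dim(frames)[1]) - 1) / frame_rate),
            class = "fluor_movie")
}

#' @method print fluor_movie
#' @export
print.fluor_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fluor_movie> %d frames of %d x %d px, %g Hz, %.2f um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$pixel_size_um))
  invisible(x)
}

# Integer-pixel translational offset of frame relative to ref by phase
# correlation (cross-power spectrum peak).
.phase_shift <- function(ref, frame) {
  fa <- fft(ref); fb <- fft(frame)
  cp <- fa * Conj(fb)
  denom <- Mod(cp); denom[denom < 1e-12] <- 1e-12
  r <- Re(fft(cp / denom, inverse = TRUE))
  idx <- arrayInd(which.max(r), dim(r))
  sh <- idx - 1L
  n <- dim(ref)
  sh <- ifelse(sh > n / 2, sh - n, sh) # wrap to signed shifts
  c(row = sh[1], col = sh[2])
}

# Shift a matrix by integer pixels, padding with the frame median.
.shift_frame <- function(m, dr, dc) {
  out <- matrix(median(m), nrow(m), ncol(m))
  sr <- seq_len(nrow(m)); sc <- seq_len(ncol(m))
  src_r <- sr - dr; src_c <- sc - dc
  ok_r <- src_r >= 1 & src_r <= nrow(m)
  ok_c <- src_c >= 1 & src_c <= ncol(m)
  out[sr[ok_r], sc[ok_c]] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register and denoise a fluorescence movie
#'
#' Corrects translational (breathing) motion by phase-correlation
#' registration of each frame to a reference -- the temporal mean of the
#' pre-stimulus baseline window -- returning integer-pixel shifts, then
#' applies a 3 x 3 spatial median filter to every frame. Frames whose
#' estimated shift exceeds 10% of the frame size are flagged and excluded
#' (replaced by the previous valid frame).
#'
#' @param movie A `fluor_movie`.
#' @param baseline_s Baseline used for the reference frame, s.
#' @param max_shift_frac Exclusion threshold as a fraction of frame size.
#' @param median_filter Apply the 3 x 3 median filter?
#' @return The corrected `fluor_movie`, with a `shifts` tibble
#'   (`frame`, `dr`, `dc`, `excluded`) attached.
#' @export
preprocess_movie <- function(movie, baseline_s = 2, max_shift_frac = 0.1,
                             median_filter = TRUE) {
  stopifnot(inherits(movie, "fluor_movie"), dim(movie$frames)[1] >= 2)
  d <- dim(movie$frames)
  t0 <- movie$timeline$stim_start %||% baseline_s
  base_idx <- which(movie$times < t0 & movie$times >= t0 - baseline_s)
  if (!length(base_idx)) base_idx <- 1L
  ref <- apply(movie$frames[base_idx, , , drop = FALSE], c(2, 3), mean)
  shifts <- matrix(0L, d[1], 2)
  out <- movie$frames
  excluded <- logical(d[1])
  for (i in seq_len(d[1])) {
    sh <- .phase_shift(ref, movie$frames[i, , ])
    shifts[i, ] <- sh
    if (any(abs(sh) > max_shift_frac * d[2:3])) {
      excluded[i] <- TRUE
      out[i, , ] <- out[max(i - 1, 1), , ]
    } else if (any(sh != 0)) {
      out[i, , ] <- .shift_frame(movie$frames[i, , ], sh[1], sh[2])
    }
  }
  if (any(excluded)) {
    warn(sprintf("%d frames excluded (shift > %d%% of frame)",
                 sum(excluded), round(100 * max_shift_frac)))
  }
  if (median_filter) {
    for (i in seq_len(d[1])) out[i, , ] <- median3_cpp(out[i, , ])
  }
  res <- movie
  res$frames <- out
  res$shifts <- tibble(frame = seq_len(d[1]), dr = shifts[, 1],
                       dc = shifts[, 2], excluded = excluded)
  res
}

#' Compute dF/F relative to the pre-stimulus baseline
#'
#' Baseline fluorescence F0 is the per-pixel average over the 2 s before
#' stimulus presentation (`detrend = "constant"`), or, when the baseline
#' drifts, the extrapolation of a per-pixel linear fit to the pre-stimulus
#' time course (`detrend = "linear"`). dF/F(t) = (F(t) - F0(t)) / F0bar
#' with F0bar the mean baseline level; pixels with non-positive baseline
#' are masked invalid (NA) and excluded from ROI means.
#'
#' @param movie A (preprocessed) `fluor_movie` whose timeline carries
#'   `stim_start`.
#' @param baseline_s Baseline window length, s.
#' @param detrend `"constant"` or `"linear"`.
#' @return A `dff_stack`: `dff` (T x H x W), `times`, `frame_rate`,
#'   `pixel_size_um`, `timeline`.
#' @export
compute_dff <- function(movie, baseline_s = 2,
                        detrend = c("constant", "linear")) {
  stopifnot(inherits(movie, "fluor_movie"))
  detrend <- match.arg(detrend)
  t0 <- movie$timeline$stim_start %||%
    abort("timeline$stim_start required for dF/F")
  idx <- which(movie$times < t0 & movie$times >= t0 - baseline_s)
  if (length(idx) < 2) abort("baseline window outside recording")
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, nrow = d[1]) # T x (H*W)
  tb <- movie$times[idx]
  if (detrend == "constant") {
    f0 <- matrix(colMeans(flat[idx, , drop = FALSE]),
                 nrow = d[1], ncol = d[2] * d[3], byrow = TRUE)
  } else {
    # per-pixel linear fit on the baseline, extrapolated over the movie
    X <- cbind(1, tb)
    beta <- solve(crossprod(X), crossprod(X, flat[idx, , drop = FALSE]))
    f0 <- cbind(1, movie$times) %*% beta
  }
  f0bar <- colMeans(flat[idx, , drop = FALSE])
  bad <- f0bar <= 0
  dff <- sweep(flat - f0, 2, pmax(f0bar, .Machine$double.eps), "/")
  dff[, bad] <- NA_real_
  structure(list(dff = array(dff, dim = d), times = movie$times,
                 frame_rate = movie$frame_rate,
                 pixel_size_um = movie$pixel_size_um,
                 timeline = movie$timeline),
            class = "dff_stack")
}

# ROI-mean time course, NA pixels excluded.
.roi_trace <- function(stack, mask) {
  stopifnot(any(mask))
  d <- dim(stack$dff)
  flat <- matrix(stack$dff, nrow = d[1])
  rowMeans(flat[, as.vector(mask), drop = FALSE], na.rm = TRUE)
}

#' Loom-window and flash-window peak metrics for an ROI
#'
#' The looming response is the ROI-mean dF/F over the window from
#' stimulus start until 1 s after the end of expansion; `loom_peak` and
#' `loom_peak_time` are its maximum and argmax. The flash response is the
#' maximum dF/F within 1.5 s after the flash minus the minimum dF/F in
#' the 1 s before the flash.
#'
#' @param stack A `dff_stack`.
#' @param mask Logical H x W ROI mask.
#' @param label Optional ROI label carried into the output.
#' @return A one-row tibble: `label`, `loom_peak`, `loom_peak_time_s`,
#'   `flash_peak` (NA if the timeline has no flash marker).
#' @export
roi_peak_metrics <- function(stack, mask, label = "roi") {
  stopifnot(inherits(stack, "dff_stack"))
  tl <- stack$timeline
  if (is.null(tl$stim_start) || is.null(tl$stim_end)) {
    abort("timeline must carry stim_start and stim_end")
  }
  tr <- .roi_trace(stack, mask)
  t <- stack$times
  win <- t >= tl$stim_start & t <= tl$stim_end + 1
  if (!any(win)) abort("looming window outside recording")
  loom_peak <- max(tr[win])
  loom_t <- t[win][which.max(tr[win])]
  flash_peak <- NA_real_
  if (!is.null(tl$flash)) {
    post <- t > tl$flash & t <= tl$flash + 1.5
    pre <- t >= tl$flash - 1 & t <= tl$flash
    if (!any(post) || !any(pre)) abort("flash window outside recording")
    flash_peak <- max(tr[post]) - min(tr[pre])
  }
  tibble(label = label, loom_peak = loom_peak, loom_peak_time_s = loom_t,
         flash_peak = flash_peak)
}

#' Range of loom-response peak times across subregions
#'
#' Computes each subregion's loom peak time and returns the spread
#' (max minus min): near zero for synchronously activated fields (field
#' C) and of order the sweep duration for retinotopically activated ones
#' (field A). Subregions with no positive peak in the loom window are
#' excluded with a warning.
#'
#' @param stack A `dff_stack`.
#' @param masks Named list of >= 2 disjoint logical masks.
#' @return A list: `range_s` and the per-subregion `peaks` tibble.
#' @export
peak_time_range <- function(stack, masks) {
  stopifnot(length(masks) >= 2)
  peaks <- purrr::imap_dfr(masks, function(m, nm) {
    roi_peak_metrics(stack, m, label = nm)
  })
  ok <- peaks$loom_peak > 0
  if (!all(ok)) {
    warn(sprintf("%d subregions without a loom-window peak excluded",
                 sum(!ok)))
  }
  pk <- peaks[ok, , drop = FALSE]
  list(range_s = max(pk$loom_peak_time_s) - min(pk$loom_peak_time_s),
       peaks = peaks)
}

#' Center-of-mass trajectory of dF/F within a dendritic field
#'
#' Per-frame intensity-weighted centroid of the (non-negative part of
#' the) dF/F inside the mask, in um. Negative dF/F values are clipped to
#' zero for weighting; frames with zero total mass are skipped.
#'
#' @param stack A `dff_stack`.
#' @param mask Logical H x W field mask.
#' @param frame_window Optional `c(t_from, t_to)` in s restricting the
#'   frames used.
#' @param shuffled Flag recorded on the output (set by
#'   [shuffle_null_trajectory()]).
#' @return A `com_trajectory` tibble: `frame`, `time_s`, `x_um`, `y_um`
#'   (x = column, y = row direction), `mass`.
#' @export
com_trajectory <- function(stack, mask, frame_window = NULL,
                           shuffled = FALSE) {
  stopifnot(inherits(stack, "dff_stack"), any(mask))
  d <- dim(stack$dff)
  idx <- seq_len(d[1])
  if (!is.null(frame_window)) {
    idx <- which(stack$times >= frame_window[1] &
                   stack$times <= frame_window[2])
  }
  pix <- which(mask)
  rows <- ((pix - 1) %% d[2]) + 1
  cols <- ((pix - 1) %/% d[2]) + 1
  flat <- matrix(stack$dff, nrow = d[1])[idx, pix, drop = FALSE]
  w <- pmax(flat, 0)
  w[is.na(w)] <- 0
  mass <- rowSums(w)
  keep <- mass > 0
  if (!any(keep)) {
    warn("all-zero dF/F window: empty trajectory")
  }
  out <- tibble(
    frame = idx[keep], time_s = stack$times[idx][keep],
    x_um = (w[keep, , drop = FALSE] %*% cols / mass[keep])[, 1] *
      stack$pixel_size_um,
    y_um = (w[keep, , drop = FALSE] %*% rows / mass[keep])[, 1] *
      stack$pixel_size_um,
    mass = mass[keep]
  )
  class(out) <- c("com_trajectory", class(out))
  attr(out, "shuffled") <- shuffled
  attr(out, "pixel_size_um") <- stack$pixel_size_um
  out
}

#' Pixel-shuffle null ensemble of CoM trajectories
#'
#' Randomly redistributes the dF/F pixel values within the mask --
#' independently in every frame, preserving each frame's value multiset
#' -- and recomputes the center-of-mass trajectory, `n_shuffles` times.
#' The ensemble provides the null band against which an observed
#' trajectory's spatial spread is compared.
#'
#' @inheritParams com_trajectory
#' @param n_shuffles Number of shuffled trajectories.
#' @param seed RNG seed.
#' @return A list of `com_trajectory` tibbles (`shuffled = TRUE`).
#' @export
shuffle_null_trajectory <- function(stack, mask, n_shuffles = 100,
                                    frame_window = NULL, seed = 1L) {
  stopifnot(n_shuffles >= 1)
  d <- dim(stack$dff)
  pix <- which(mask)
  .local_seed(seed, {
    purrr::map(seq_len(n_shuffles), function(k) {
      sh <- stack
      flat <- matrix(sh$dff, nrow = d[1])
      for (i in seq_len(d[1])) {
        flat[i, pix] <- flat[i, pix][sample.int(length(pix))]
      }
      sh$dff <- array(flat, dim = d)
      com_trajectory(sh, mask, frame_window = frame_window,
                     shuffled = TRUE)
    })
  })
}

# Spatial spread statistic of a trajectory: net displacement between
# trajectory start and end (mean over the first/last 20% of frames).
.traj_spread <- function(traj) {
  n <- nrow(traj)
  if (n < 2) return(0)
  k <- max(1, floor(n / 5))
  head_xy <- colMeans(traj[seq_len(k), c("x_um", "y_um")])
  tail_xy <- colMeans(traj[(n - k + 1):n, c("x_um", "y_um")])
  sqrt(sum((tail_xy - head_xy)^2))
}

#' Retinotopy test: observed CoM spread against the shuffle null band
#'
#' Compares the net CoM displacement of the observed trajectory with the
#' 95% band of the pixel-shuffle null ensemble: a retinotopically
#' sweeping activation leaves the band; spatially uniform activation
#' stays inside it.
#'
#' The permutation null assumes pixel noise is exchangeable within the
#' mask. Spatial smoothing (e.g. the 3 x 3 median filter of
#' [preprocess_movie()]) correlates neighbouring pixels and makes the
#' test anti-conservative, so compute the dF/F stack for this test from
#' a movie preprocessed with `median_filter = FALSE`.
#'
#' @inheritParams shuffle_null_trajectory
#' @return A one-row tibble: `observed_um`, `null_q95_um`,
#'   `outside_null`.
#' @export
com_null_test <- function(stack, mask, n_shuffles = 100,
                          frame_window = NULL, seed = 1L) {
  obs <- .traj_spread(com_trajectory(stack, mask,
                                     frame_window = frame_window))
  nulls <- shuffle_null_trajectory(stack, mask, n_shuffles,
                                   frame_window = frame_window,
                                   seed = seed)
  q95 <- quantile(vapply(nulls, .traj_spread, numeric(1)), 0.95,
                  names = FALSE)
  tibble(observed_um = obs, null_q95_um = q95,
         outside_null = obs > q95)
}

#' Pearson correlation between CoM trajectory and stimulus position
#'
#' Correlates each CoM coordinate with the stimulus position on the
#' frames the trajectory covers. Degenerate cases (zero variance in
#' either series) are reported as r = 0 with `degenerate = TRUE` rather
#' than erroring mid-pipeline.
#'
#' @param traj A `com_trajectory`.
#' @param stimulus_positions Tibble with `time_s` and a position column
#'   (first non-time column used, e.g. `az_deg`).
#' @return A tibble with one row per spatial axis: `axis`, `r`,
#'   `degenerate`.
#' @export
position_correlation <- function(traj, stimulus_positions) {
  stopifnot(nrow(stimulus_positions) >= 1)
  if (nrow(traj) < 3) abort("need at least 3 frames for correlation")
  pos_col <- setdiff(names(stimulus_positions), "time_s")[1]
  pos <- approx(stimulus_positions$time_s, stimulus_positions[[pos_col]],
                xout = traj$time_s, rule = 2)$y
  one <- function(x, axis) {
    if (sd(x) == 0 || sd(pos) == 0) {
      tibble(axis = axis, r = 0, degenerate = TRUE)
    } else {
      tibble(axis = axis, r = cor(x, pos), degenerate = FALSE)
    }
  }
  dplyr::bind_rows(one(traj$x_um, "x"), one(traj$y_um, "y"))
}
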