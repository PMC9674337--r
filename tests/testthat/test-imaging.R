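# Imaging pipeline: registration, dF/F, ROI metrics, CoM retinotopy test.

# Structured static frame for registration tests.
structured_frame <- function(h = 40, w = 50, seed = 1) {
  set.seed(seed)
  base <- matrix(100, h, w)
  base[10:20, 15:30] <- 180
  base[25:35, 5:15] <- 140
  base + matrix(rnorm(h * w, 0, 1), h, w)
}

test_that("phase correlation recovers injected integer shifts exactly", {
  ref <- structured_frame()
  nt <- 8
  shifts <- cbind(dr = c(0, 1, -2, 2, 0, -1, 2, -2),
                  dc = c(0, -1, 2, 1, 2, 0, -2, 1))
  frames <- array(0, dim = c(nt, nrow(ref), ncol(ref)))
  for (i in seq_len(nt)) {
    frames[i, , ] <- loomlab:::.shift_frame(ref, shifts[i, 1],
                                            shifts[i, 2])
  }
  mv <- fluor_movie(frames, timeline = list(stim_start = 0.4))
  pp <- preprocess_movie(mv, median_filter = FALSE)
  # recovered corrections undo the injected translations
  expect_equal(pp$shifts$dr, -shifts[, "dr"], ignore_attr = TRUE)
  expect_equal(pp$shifts$dc, -shifts[, "dc"], ignore_attr = TRUE)
  # corrected interior matches the reference
  expect_lt(max(abs(pp$frames[4, 10:30, 10:40] - ref[10:30, 10:40])), 1e-9)
})

test_that("median filter removes single-pixel outliers, keeps constants", {
  f <- matrix(7, 20, 20)
  expect_equal(median3_cpp(f), f)
  f[10, 10] <- 1000
  expect_equal(median3_cpp(f)[10, 10], 7)
})

test_that("dF/F definition: zero for constant, exact for a step", {
  nt <- 30; h <- 8; w <- 8
  frames <- array(100, dim = c(nt, h, w))
  mv <- fluor_movie(frames, timeline = list(stim_start = 2, stim_end = 4))
  st <- compute_dff(mv)
  expect_true(all(abs(st$dff) < 1e-12))
  # +50% step after the baseline
  frames[mv$times >= 2, , ] <- 150
  st2 <- compute_dff(fluor_movie(frames,
                                 timeline = list(stim_start = 2,
                                                 stim_end = 4)))
  expect_equal(st2$dff[nt, 1, 1], 0.5, tolerance = 1e-12)
  # gain invariance
  st3 <- compute_dff(fluor_movie(frames * 3.7,
                                 timeline = list(stim_start = 2,
                                                 stim_end = 4)))
  expect_equal(st3$dff, st2$dff, tolerance = 1e-12)
})

test_that("linear detrending recovers a step riding on drift within 1%", {
  nt <- 40; h <- 6; w <- 6; rate <- 5
  times <- (seq_len(nt) - 1) / rate
  drift <- 4 # counts per s
  frames <- array(0, dim = c(nt, h, w))
  for (i in seq_len(nt)) frames[i, , ] <- 100 + drift * times[i]
  step_frames <- times >= 3 & times < 5
  frames[step_frames, , ] <- frames[step_frames, , ] + 50
  mv <- fluor_movie(frames, timeline = list(stim_start = 3,
                                            stim_end = 5))
  st <- compute_dff(mv, detrend = "linear")
  amp <- mean(st$dff[step_frames, , ])
  # dF/F normalizes by the mean baseline level (drift included)
  f0bar <- mean(100 + drift * times[times >= 1 & times < 3])
  expect_equal(amp, 50 / f0bar, tolerance = 0.01)
  # constant-baseline version misattributes the drift
  stc <- compute_dff(mv, detrend = "constant")
  expect_gt(abs(mean(stc$dff[step_frames, , ]) - 0.5),
            abs(amp - 0.5))
})

test_that("ROI metrics find loom and flash peaks by construction", {
  nt <- 60; rate <- 5
  times <- (seq_len(nt) - 1) / rate
  tl <- list(stim_start = 2, stim_end = 6, flash = 8)
  trace <- 100 * (1 + 0.8 * exp(-(times - 5)^2 / 0.5) -
                    0.1 * (times > 7 & times <= 8) +
                    0.4 * (times > 8 & times <= 9))
  frames <- array(rep(trace, 16), dim = c(nt, 4, 4))
  st <- compute_dff(fluor_movie(frames, timeline = tl))
  mask <- matrix(TRUE, 4, 4)
  pm <- roi_peak_metrics(st, mask)
  expect_equal(pm$loom_peak, 0.8, tolerance = 0.01)
  expect_equal(pm$loom_peak_time_s, 5, tolerance = 0.21)
  # flash peak = post-flash bump amplitude plus pre-flash dip depth
  expect_equal(pm$flash_peak, 0.4 + 0.1, tolerance = 0.02)
  # flat trace: zero flash response
  flat <- compute_dff(fluor_movie(array(100, dim = c(nt, 4, 4)),
                                  timeline = tl))
  expect_equal(roi_peak_metrics(flat, mask)$flash_peak, 0)
})

test_that("peak-time range separates sequential from synchronous fields", {
  nt <- 50; rate <- 5
  times <- (seq_len(nt) - 1) / rate
  tl <- list(stim_start = 2, stim_end = 8)
  frames <- array(100, dim = c(nt, 10, 10))
  # five column bands peaking 0.8 s apart (total spread 3.2 s)
  for (k in 1:5) {
    pk <- 3 + 0.8 * (k - 1)
    bump <- 60 * exp(-(times - pk)^2 / 0.18)
    cols <- (2 * k - 1):(2 * k)
    frames[, , cols] <- frames[, , cols] + bump
  }
  st <- compute_dff(fluor_movie(frames, timeline = tl))
  masks <- lapply(1:5, function(k) {
    m <- matrix(FALSE, 10, 10); m[, (2 * k - 1):(2 * k)] <- TRUE; m
  })
  names(masks) <- paste0("sub", 1:5)
  ptr <- peak_time_range(st, masks)
  expect_equal(ptr$range_s, 3.2, tolerance = 1 / rate + 1e-9)
  # identical traces across subregions: range 0
  uni <- array(100, dim = c(nt, 10, 10))
  uni[, , ] <- uni + rep(30 * exp(-(times - 4)^2 / 0.5), 100)
  stu <- compute_dff(fluor_movie(uni, timeline = tl))
  expect_equal(peak_time_range(stu, masks)$range_s, 0)
})

test_that("CoM is the weighted centroid, translation-equivariant", {
  nt <- 5; h <- 12; w <- 12
  tl <- list(stim_start = 0.4, stim_end = 0.8)
  # single bright pixel appearing after the baseline
  frames2 <- array(100, dim = c(nt, h, w))
  frames2[3:5, 4, 7] <- 300
  st <- compute_dff(fluor_movie(frames2, timeline = tl))
  mask <- matrix(TRUE, h, w)
  traj <- com_trajectory(st, mask)
  expect_equal(unique(traj$x_um), 7 * 0.9, tolerance = 1e-9)
  expect_equal(unique(traj$y_um), 4 * 0.9, tolerance = 1e-9)
  # two equal pixels -> midpoint
  frames3 <- array(100, dim = c(nt, h, w))
  frames3[3:5, 4, 5] <- 300
  frames3[3:5, 4, 9] <- 300
  st3 <- compute_dff(fluor_movie(frames3, timeline = tl))
  traj3 <- com_trajectory(st3, mask)
  expect_equal(unique(traj3$x_um), 7 * 0.9, tolerance = 1e-9)
  # translation of pattern and mask translates the CoM
  frames4 <- array(100, dim = c(nt, h, w))
  frames4[3:5, 6, 9] <- 300
  st4 <- compute_dff(fluor_movie(frames4, timeline = tl))
  traj4 <- com_trajectory(st4, mask)
  expect_equal(traj4$x_um - traj$x_um, rep(2 * 0.9, 3), tolerance = 1e-9)
  expect_equal(traj4$y_um - traj$y_um, rep(2 * 0.9, 3), tolerance = 1e-9)
})

test_that("pixel shuffling preserves mass and flattens trajectories", {
  g <- gen_field_movie(synth_movie_spec("retinotopic_sweep",
                                        noise_sigma = 0, seed = 3))
  st <- compute_dff(g$movie)
  mask <- g$masks$A
  nulls <- shuffle_null_trajectory(st, mask, n_shuffles = 5,
                                   frame_window = c(2, 6), seed = 2)
  expect_length(nulls, 5)
  obs <- com_trajectory(st, mask, frame_window = c(2, 6))
  # per-frame total mass unchanged by the permutation
  expect_equal(nulls[[1]]$mass, obs$mass, tolerance = 1e-9)
  # shuffled spread is tiny compared to the observed sweep
  spread <- function(tr) {
    sqrt(sum((colMeans(utils::tail(tr[, c("x_um", "y_um")], 3)) -
                colMeans(utils::head(tr[, c("x_um", "y_um")], 3)))^2))
  }
  expect_gt(spread(obs), 10 * max(vapply(nulls, spread, numeric(1))))
  # determinism
  nulls2 <- shuffle_null_trajectory(st, mask, n_shuffles = 5,
                                    frame_window = c(2, 6), seed = 2)
  expect_equal(nulls[[3]]$x_um, nulls2[[3]]$x_um)
})

test_that("position correlation handles perfect, degenerate and short
           input", {
  traj <- tibble::tibble(frame = 1:10, time_s = seq(0.2, 2, by = 0.2),
                         x_um = seq(1, 10), y_um = rep(2, 10),
                         mass = 1)
  pos <- tibble::tibble(time_s = traj$time_s,
                        az_deg = 3 * traj$x_um - 7)
  pc <- position_correlation(traj, pos)
  expect_equal(pc$r[pc$axis == "x"], 1)
  expect_true(pc$degenerate[pc$axis == "y"])
  expect_equal(pc$r[pc$axis == "y"], 0)
  expect_error(position_correlation(traj[1:2, ], pos), "3 frames")
})
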