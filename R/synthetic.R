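# Synthetic-data generators. Every generator is a pure function of
# (spec, seed) and returns its ground truth alongside the data, so
# analysis-stage recovery tests consume only the data and compare against
# the truth.

#' Specification for a synthetic fluorescence movie
#'
#' Emulates the acquisition geometry of the imaging experiments (5 Hz,
#' 0.9 um/pixel) over two stylized dendritic-field masks: a crescent
#' "A" field and a compact blob "C" field. Activation is either a
#' retinotopically sweeping Gaussian spot (field A-like), a spatially
#' uniform common time course (field C-like), or a polarity-ratio pair
#' (see [gen_polarity_movies()]). Gaussian pixel noise, linear baseline
#' drift and frame-wise integer translation (breathing) are optional.
#'
#' @param mode `"retinotopic_sweep"` or `"uniform"`.
#' @param height,width Frame size, px.
#' @param amplitude Peak dF/F of the activation.
#' @param noise_sigma Gaussian noise SD as a fraction of the peak
#'   fluorescence increase.
#' @param drift_slope Baseline drift, dF/F per s.
#' @param motion_amplitude Breathing translation amplitude, px.
#' @param baseline_s Pre-stimulus baseline, s.
#' @param stim_s Stimulus (sweep) duration, s.
#' @param post_s Post-stimulus tail, s.
#' @param frame_rate Hz. @param pixel_size_um um/px.
#' @param f0 Baseline fluorescence counts.
#' @param spot_sigma_px Sweep-spot Gaussian SD, px.
#' @param seed RNG seed.
#' @return A `synth_movie_spec`.
#' @export
synth_movie_spec <- function(mode = c("retinotopic_sweep", "uniform"),
                             height = 56, width = 72, amplitude = 1,
                             noise_sigma = 0.1, drift_slope = 0,
                             motion_amplitude = 0, baseline_s = 2,
                             stim_s = 4, post_s = 1, frame_rate = 5,
                             pixel_size_um = 0.9, f0 = 100,
                             spot_sigma_px = 5, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(amplitude > 0, noise_sigma >= 0, f0 > 0)
  structure(as.list(environment()), class = "synth_movie_spec")
}

#' Stylized field masks for synthetic movies
#'
#' A crescent-shaped "A" field and a disjoint round "C" blob.
#'
#' @param height,width Frame size, px.
#' @return Named list of logical masks `A` and `C`.
#' @export
synth_field_masks <- function(height = 56, width = 72) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  # crescent: annulus sector around a center below the frame
  cx <- width * 0.38; cy <- height * 1.1
  rad <- sqrt((rr - cy)^2 + (cc - cx)^2)
  A <- rad > height * 0.55 & rad < height * 0.8 & rr < height * 0.75
  # blob: disc in the upper-right corner region
  bx <- width * 0.8; by <- height * 0.22
  C <- sqrt((rr - by)^2 + (cc - bx)^2) < height * 0.16
  C <- C & !A
  stopifnot(any(A), any(C), !any(A & C))
  list(A = A, C = C)
}

# Path of the sweep spot through a mask: order mask pixels by azimuthal
# sweep coordinate (column), take smoothed quantile path.
.sweep_path <- function(mask, n) {
  pix <- which(mask)
  rows <- ((pix - 1) %% nrow(mask)) + 1
  cols <- ((pix - 1) %/% nrow(mask)) + 1
  o <- order(cols, rows)
  qs <- seq(0.02, 0.98, length.out = n)
  idx <- pmax(1, ceiling(qs * length(pix)))
  ord_cols <- cols[o][idx]
  # row path: mean mask row at each column
  row_at <- vapply(ord_cols, function(cl) mean(rows[cols == cl]),
                   numeric(1))
  cbind(row = row_at, col = ord_cols)
}

#' Generate a synthetic fluorescence movie with ground truth
#'
#' In `"retinotopic_sweep"` mode a Gaussian activation spot traverses
#' the field A mask in register with a linear stimulus-position track;
#' in `"uniform"` mode the whole mask rises and falls with one common
#' loom-like time course. Gaussian noise, linear drift and frame-wise
#' integer translation are then added per the spec.
#'
#' @param spec A [synth_movie_spec()].
#' @param field Which mask carries the activation (`"A"` or `"C"`).
#' @return A list: `movie` (a [fluor_movie()]), `truth` (spot path,
#'   stimulus positions, shifts, amplitude), `masks`.
#' @export
gen_field_movie <- function(spec, field = if (spec$mode ==
                                              "retinotopic_sweep") "A" else "C") {
  masks <- synth_field_masks(spec$height, spec$width)
  mask <- masks[[field]]
  nt <- round((spec$baseline_s + spec$stim_s + spec$post_s) *
                spec$frame_rate)
  times <- (seq_len(nt) - 1) / spec$frame_rate
  stim_on <- times >= spec$baseline_s &
    times < spec$baseline_s + spec$stim_s
  n_on <- sum(stim_on)
  rr <- matrix(seq_len(spec$height), spec$height, spec$width)
  cc <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)

  # baseline fluorescence carries the dendritic anatomy (dye-filled
  # fields are visible at rest), giving registration its anchors
  base_img <- spec$f0 * (1 + 0.6 * masks$A + 0.6 * masks$C)
  .local_seed(spec$seed, {
    frames <- array(rep(base_img, each = nt),
                    dim = c(nt, spec$height, spec$width))
    truth <- list(amplitude = spec$amplitude)
    if (spec$mode == "retinotopic_sweep") {
      path <- .sweep_path(mask, n_on)
      truth$spot_path <- tibble(time_s = times[stim_on],
                                row = path[, "row"], col = path[, "col"])
      truth$stimulus_positions <- tibble(
        time_s = times[stim_on],
        az_deg = seq(-40, 40, length.out = n_on))
      cent <- matrix(NA_real_, n_on, 2)
      k <- 1
      for (i in which(stim_on)) {
        spot <- exp(-((rr - path[k, "row"])^2 + (cc - path[k, "col"])^2) /
                      (2 * spec$spot_sigma_px^2)) * mask
        frames[i, , ] <- base_img + spec$f0 * spec$amplitude * spot
        cent[k, ] <- c(sum(rr * spot), sum(cc * spot)) / sum(spot)
        k <- k + 1
      }
      # centroid of the activation actually drawn (spot truncated by the
      # mask), the recoverable ground truth
      truth$activation_centroid <- tibble(
        time_s = times[stim_on], row = cent[, 1], col = cent[, 2])
    } else {
      # loom-like common time course peaking at stimulus end
      amp_t <- rep(0, nt)
      amp_t[stim_on] <- (seq_len(n_on) / n_on)^2
      post <- which(!stim_on & times >= spec$baseline_s)
      if (length(post)) amp_t[post] <- exp(-(seq_along(post)) / 2)
      truth$time_course <- tibble(time_s = times, amp = amp_t)
      for (i in seq_len(nt)) {
        frames[i, , ] <- base_img + spec$f0 * spec$amplitude * amp_t[i] * mask
      }
    }
    if (spec$drift_slope != 0) {
      for (i in seq_len(nt)) {
        frames[i, , ] <- frames[i, , ] +
          spec$f0 * spec$drift_slope * times[i]
      }
    }
    shifts <- tibble(frame = seq_len(nt), dr = 0L, dc = 0L)
    if (spec$motion_amplitude > 0) {
      shifts$dr <- as.integer(round(spec$motion_amplitude *
                                      sin(2 * pi * 0.7 * times)))
      shifts$dc <- as.integer(round(spec$motion_amplitude *
                                      cos(2 * pi * 0.5 * times)))
      for (i in seq_len(nt)) {
        frames[i, , ] <- .shift_frame(frames[i, , ], shifts$dr[i],
                                      shifts$dc[i])
      }
    }
    truth$shifts <- shifts
    if (spec$noise_sigma > 0) {
      frames <- frames + rnorm(length(frames), 0,
                               spec$noise_sigma * spec$amplitude * spec$f0)
      frames[frames < 0] <- 0
    }
    movie <- fluor_movie(frames, spec$frame_rate, spec$pixel_size_um,
                         timeline = list(
                           stim_start = spec$baseline_s,
                           stim_end = spec$baseline_s + spec$stim_s,
                           flash = spec$baseline_s + spec$stim_s))
    list(movie = movie, truth = truth, masks = masks)
  })
}

#' Paired ON- and OFF-stimulus movies with a known response ratio
#'
#' Generates two uniform-activation movies whose ROI loom-peak dF/F
#' ratio (ON over OFF) equals `ratio_true` before noise, for
#' parameter-recovery tests of the peak-ratio pipeline.
#'
#' @param spec A [synth_movie_spec()] (its `amplitude` is the OFF peak).
#' @param ratio_true Target ON/OFF peak ratio (> 0).
#' @param field Field mask carrying the activation.
#' @return A list: `on`, `off` (each a `gen_field_movie()` result),
#'   `ratio_true`.
#' @export
gen_polarity_movies <- function(spec, ratio_true = 2.4, field = "C") {
  stopifnot(ratio_true > 0)
  off_spec <- spec
  off_spec$mode <- "uniform"
  on_spec <- off_spec
  on_spec$amplitude <- spec$amplitude * ratio_true
  on_spec$seed <- spec$seed + 1000L
  list(on = gen_field_movie(on_spec, field = field),
       off = gen_field_movie(off_spec, field = field),
       ratio_true = ratio_true)
}

#' Reference synaptic event train with exact counts
#'
#' Stand-in for encoder output: exactly `n_exc` excitatory and `n_inh`
#' inhibitory events over `[-duration, 0]` s (t = 0 the projected
#' collision). The `"loom_like"` profile draws event times from a
#' density proportional to the angular expansion rate
#' \eqn{\dot\theta(t) \propto a/(t^2 + a^2)} (a = l/|v|), so the rate
#' ramps toward collision; `"uniform"` draws uniformly.
#'
#' @param n_exc,n_inh Event counts.
#' @param duration_s Train duration, s.
#' @param temporal_profile `"loom_like"` or `"uniform"`.
#' @param l_over_v Loom kinematic parameter for the loom-like density,
#'   ms.
#' @param grid Optional [facet_grid_spec()]; if given, excitatory events
#'   receive facet ids drawn uniformly so retinotopic mapping is
#'   exercised; otherwise facet ids are NA.
#' @param seed RNG seed.
#' @return A `SynapticEventTrain` tibble.
#' @export
gen_reference_eventset <- function(n_exc, n_inh, duration_s = 2,
                                   temporal_profile = c("loom_like",
                                                        "uniform"),
                                   l_over_v = 80, grid = NULL,
                                   seed = 1L) {
  temporal_profile <- match.arg(temporal_profile)
  stopifnot(n_exc >= 0, n_inh >= 0, duration_s > 0)
  a <- l_over_v / 1000
  draw_times <- function(n) {
    if (n == 0) return(numeric(0))
    if (temporal_profile == "uniform") {
      sort(runif(n, -duration_s, 0))
    } else {
      # inverse-CDF sampling: cumulative of a/(t^2+a^2) is atan(a/|t|)
      th0 <- atan(a / duration_s)
      th1 <- pi / 2 - 1e-9
      u <- runif(n, th0, th1)
      sort(-a / tan(u))
    }
  }
  .local_seed(seed, {
    exc <- tibble(
      time_s = draw_times(n_exc), polarity = "OFF", class = "excitatory",
      facet_id = if (is.null(grid)) NA_integer_ else
        sample.int(nrow(grid$centers), n_exc, replace = TRUE),
      source = "synthetic")
    inh <- tibble(
      time_s = draw_times(n_inh), polarity = "OFF", class = "inhibitory",
      facet_id = NA_integer_, source = "synthetic")
    out <- dplyr::arrange(dplyr::bind_rows(exc, inh), .data$time_s)
    attr(out, "grid") <- grid
    out
  })
}
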