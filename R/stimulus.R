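# Stimulus synthesis in eye-centered angular coordinates (azimuth/elevation,
# degrees, stimulus-centered at (0,0)). Frames are H x W matrices indexed
# [row = elevation, col = azimuth], luminance in [0, 1].

#' Half-angle subtended by an approaching square
#'
#' An object of half-size l approaching at constant speed v < 0 subtends the
#' half-angle \eqn{\theta(t) = \arctan((l/|v|)/|t|)} at time t before
#' projected collision (t = 0). The approach is fully characterized by the
#' ratio l/|v| in ms; theta grows monotonically and reaches 90 deg (a full
#' angle of 180 deg) at collision.
#'
#' @param t Time relative to projected collision, s; must be negative.
#' @param l_over_v Half-size over approach speed, ms.
#' @return Half-angle in degrees.
#' @examples
#' loom_half_angle(-0.08, 80) # 45 degrees
#' @export
loom_half_angle <- function(t, l_over_v) {
  stopifnot(l_over_v > 0)
  if (any(t >= 0)) abort("t must be < 0: collision reached at t = 0")
  atan((l_over_v / 1000) / abs(t)) * 180 / pi
}

# Half-angle clamped for rendering: 90 deg at and after collision.
.half_angle_clamped <- function(t, l_over_v) {
  ifelse(t >= 0, 90, atan((l_over_v / 1000) / pmax(abs(t), 1e-12)) * 180 / pi)
}

#' Looming-stimulus parameters
#'
#' @param l_over_v Half-size over approach speed, ms.
#' @param polarity One of `"black"`, `"white"`, `"checkered"`,
#'   `"concentric"`. Black squares appear on a light background, white on a
#'   dark one; checkerboards and concentric squares appear on a 50%
#'   luminance background.
#' @param background_luminance Background in \[0, 1\]; default depends on
#'   polarity (1 for black, 0 for white, 0.5 for mixed-polarity stimuli).
#' @param coherence Spatial coherence in percent, \[0, 100\].
#' @param coarse_pixel_deg Coarse-pixelation cell size, degrees (2.5 deg,
#'   the photoreceptor receptive-field scale).
#' @param frame_rate Display refresh rate, Hz.
#' @param t_start,t_end Start/end time relative to projected collision, s.
#' @param hold_s Post-loom hold, s, during which the final frame persists.
#' @param extent_deg Angular extent of the screen per axis, degrees.
#' @param pixel_deg Fine rendering pitch, degrees/pixel.
#' @param coarse Force coarse pixelation even at 100% coherence (the
#'   coherence-series protocol pixelates every stimulus before
#'   scrambling); `NULL` coarsens only when `coherence < 100`.
#' @param n_checkers Checkers per side for the checkered polarity.
#' @param n_rings Alternating rings for the concentric polarity.
#' @param seed RNG seed for the coherence scrambling.
#' @return A `loom_spec` object accepted by [render_stimulus()].
#' @export
loom_spec <- function(l_over_v = 80,
                      polarity = c("black", "white", "checkered", "concentric"),
                      background_luminance = NULL,
                      coherence = 100, coarse_pixel_deg = 2.5,
                      frame_rate = 240, t_start = -2, t_end = 0,
                      hold_s = 0, extent_deg = 80, pixel_deg = 0.5,
                      coarse = NULL, n_checkers = 8, n_rings = 5,
                      seed = 1L) {
  polarity <- match.arg(polarity)
  if (is.null(background_luminance)) {
    background_luminance <- switch(polarity,
      black = 1, white = 0, checkered = 0.5, concentric = 0.5)
  }
  stopifnot(l_over_v > 0, coherence >= 0, coherence <= 100,
            t_start < t_end, frame_rate > 0, pixel_deg > 0,
            background_luminance >= 0, background_luminance <= 1)
  structure(list(l_over_v = l_over_v, polarity = polarity,
                 background_luminance = background_luminance,
                 coherence = coherence, coarse_pixel_deg = coarse_pixel_deg,
                 frame_rate = frame_rate, t_start = t_start, t_end = t_end,
                 hold_s = hold_s, extent_deg = extent_deg,
                 pixel_deg = pixel_deg, coarse = coarse,
                 n_checkers = n_checkers, n_rings = n_rings, seed = seed),
            class = "loom_spec")
}

#' Translating-square stimulus parameters
#'
#' A square of fixed angular size translating at constant angular speed
#' along the azimuth axis.
#'
#' @param size_deg Full angular size of the square, degrees.
#' @param speed_deg_s Angular speed, degrees/s.
#' @param az_start Starting azimuth of the square center, degrees.
#' @param luminance Square luminance in \[0, 1\].
#' @param background_luminance Background luminance.
#' @param duration_s Duration, s.
#' @inheritParams loom_spec
#' @return A `translate_spec` object accepted by [render_stimulus()].
#' @export
translate_spec <- function(size_deg = 10, speed_deg_s = 20, az_start = -30,
                           luminance = 0, background_luminance = 1,
                           duration_s = 3, frame_rate = 240,
                           extent_deg = 80, pixel_deg = 0.5) {
  stopifnot(size_deg > 0, duration_s > 0)
  structure(list(size_deg = size_deg, speed_deg_s = speed_deg_s,
                 az_start = az_start, luminance = luminance,
                 background_luminance = background_luminance,
                 duration_s = duration_s, frame_rate = frame_rate,
                 extent_deg = extent_deg, pixel_deg = pixel_deg),
            class = "translate_spec")
}

#' Post-loom flash parameters
#'
#' After a loom the screen steps abruptly back to its original background
#' luminance; this renders that step in isolation: `pre_luminance` for
#' `pre_s` seconds, then `background_luminance`.
#'
#' @param pre_luminance Full-screen luminance before the flash.
#' @param background_luminance Luminance after the step.
#' @param pre_s,post_s Durations before/after the step, s.
#' @inheritParams loom_spec
#' @return A `flash_spec` object accepted by [render_stimulus()].
#' @export
flash_spec <- function(pre_luminance = 0, background_luminance = 1,
                       pre_s = 1, post_s = 2, frame_rate = 240,
                       extent_deg = 80, pixel_deg = 0.5) {
  structure(list(pre_luminance = pre_luminance,
                 background_luminance = background_luminance,
                 pre_s = pre_s, post_s = post_s, frame_rate = frame_rate,
                 extent_deg = extent_deg, pixel_deg = pixel_deg),
            class = "flash_spec")
}

.new_stimulus_movie <- function(frames, frame_rate, pixel_deg, times,
                                coarse = FALSE) {
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_pitch = pixel_deg,
                 angular_extent = dim(frames)[2] * pixel_deg,
                 times = times, coarse = coarse),
            class = "stimulus_movie")
}

#' @method print stimulus_movie
#' @export
print.stimulus_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<stimulus_movie> %d frames of %d x %d px (%.1f deg at %.2f deg/px), %g Hz%s\n",
    d[1], d[2], d[3], x$angular_extent, x$pixel_pitch, x$frame_rate,
    if (isTRUE(x$coarse)) ", coarse" else ""))
  invisible(x)
}

# Pixel-center coordinate vector for a given extent/pitch.
.pix_centers <- function(extent_deg, pixel_deg) {
  n <- round(extent_deg / pixel_deg)
  (seq_len(n) - (n + 1) / 2) * pixel_deg
}

#' Render a stimulus movie
#'
#' Renders a [loom_spec()], [translate_spec()] or [flash_spec()] into a
#' `stimulus_movie`: a T x H x W luminance array in \[0, 1\] in eye-centered
#' angular coordinates. For looms with `coherence < 100`, the movie is
#' coarse-pixelated at `coarse_pixel_deg` and scrambled via
#' [scramble_coherence()].
#'
#' @param params A stimulus spec object.
#' @return A `stimulus_movie`.
#' @examples
#' m <- render_stimulus(loom_spec(80, "black", t_start = -0.5,
#'                                extent_deg = 40, pixel_deg = 1))
#' range(m$frames)
#' @export
render_stimulus <- function(params) UseMethod("render_stimulus")

#' @export
render_stimulus.loom_spec <- function(params) {
  p <- params
  times <- .frame_times(p$t_start, p$t_end + p$hold_s, p$frame_rate)
  az <- .pix_centers(p$extent_deg, p$pixel_deg)
  el <- az
  if (2 * .half_angle_clamped(p$t_end - 1 / p$frame_rate, p$l_over_v) >
      p$extent_deg) {
    warn("final stimulus exceeds screen extent; clipped")
  }
  frames <- array(p$background_luminance,
                  dim = c(length(times), length(el), length(az)))
  for (i in seq_along(times)) {
    th <- .half_angle_clamped(times[i], p$l_over_v)
    rows <- which(abs(el) <= th)
    cols <- which(abs(az) <= th)
    if (!length(rows) || !length(cols)) next
    patch <- switch(p$polarity,
      black = matrix(0, length(rows), length(cols)),
      white = matrix(1, length(rows), length(cols)),
      checkered = {
        # fixed checker count, size scales with the square
        ci <- floor((el[rows] + th) / (2 * th / p$n_checkers))
        cj <- floor((az[cols] + th) / (2 * th / p$n_checkers))
        ci <- pmin(ci, p$n_checkers - 1); cj <- pmin(cj, p$n_checkers - 1)
        (outer(ci, cj, "+") %% 2)
      },
      concentric = {
        # five alternating square rings, outermost dark
        frac_r <- pmax(abs(outer(el[rows], rep(1, length(cols)))),
                       abs(outer(rep(1, length(rows)), az[cols]))) / th
        ring <- pmin(floor(frac_r * p$n_rings), p$n_rings - 1)
        (p$n_rings - 1 - ring) %% 2
      })
    frames[i, rows, cols] <- patch
  }
  m <- .new_stimulus_movie(frames, p$frame_rate, p$pixel_deg, times)
  if (p$coherence < 100 || isTRUE(p$coarse)) {
    m <- coarsen_pixelate(m, p$coarse_pixel_deg)
    m <- scramble_coherence(m, p$coherence, seed = p$seed)
  }
  m
}

#' @export
render_stimulus.translate_spec <- function(params) {
  p <- params
  times <- seq(0, p$duration_s - 1 / p$frame_rate, by = 1 / p$frame_rate)
  az <- .pix_centers(p$extent_deg, p$pixel_deg)
  el <- az
  frames <- array(p$background_luminance,
                  dim = c(length(times), length(el), length(az)))
  half <- p$size_deg / 2
  centers <- p$az_start + p$speed_deg_s * times
  rows <- which(abs(el) <= half)
  for (i in seq_along(times)) {
    cols <- which(abs(az - centers[i]) <= half)
    if (length(cols)) frames[i, rows, cols] <- p$luminance
  }
  m <- .new_stimulus_movie(frames, p$frame_rate, p$pixel_deg, times)
  m$stimulus_positions <- tibble(time_s = times, az_deg = centers, el_deg = 0)
  m
}

#' @export
render_stimulus.flash_spec <- function(params) {
  p <- params
  times <- seq(-p$pre_s, p$post_s - 1 / p$frame_rate, by = 1 / p$frame_rate)
  n <- round(p$extent_deg / p$pixel_deg)
  lum <- ifelse(times < 0, p$pre_luminance, p$background_luminance)
  frames <- array(rep(lum, n * n), dim = c(length(times), n, n))
  .new_stimulus_movie(frames, p$frame_rate, p$pixel_deg, times)
}

.frame_times <- function(t_start, t_end, frame_rate) {
  n <- round((t_end - t_start) * frame_rate)
  t_start + (seq_len(n) - 1) / frame_rate
}

#' Coarse-pixelate a stimulus movie
#'
#' Replaces local edge motion by an equivalent local luminance change:
#' each `pixel_deg` cell takes the mean luminance of the fine pixels it
#' covers, per frame. Border cells covering fewer fine pixels average over
#' the covered area. The framewise mean luminance is preserved when the
#' grid is commensurate with the extent.
#'
#' @param movie A `stimulus_movie`.
#' @param pixel_deg Coarse cell size, degrees (default 2.5).
#' @return A coarse `stimulus_movie` whose pixel pitch is `pixel_deg`.
#' @export
coarsen_pixelate <- function(movie, pixel_deg = 2.5) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (pixel_deg < movie$pixel_pitch) {
    abort("pixel_deg must be >= the movie's pixel pitch")
  }
  block <- pixel_deg / movie$pixel_pitch
  d <- dim(movie$frames)
  n_coarse <- ceiling(d[2] / block)
  # fine index -> coarse cell index (handles non-integer block sizes by
  # assigning each fine pixel to the cell containing its center)
  idx <- pmin(floor((seq_len(d[2]) - 0.5) / block) + 1, n_coarse)
  out <- array(0, dim = c(d[1], n_coarse, n_coarse))
  counts <- table(factor(idx, levels = seq_len(n_coarse)))
  for (i in seq_len(d[1])) {
    fr <- movie$frames[i, , ]
    rs <- rowsum(fr, idx)                    # sum over rows into cells
    cs <- rowsum(t(rs), idx)                 # then over columns
    out[i, , ] <- t(cs) / outer(as.numeric(counts), as.numeric(counts))
  }
  m <- .new_stimulus_movie(out, movie$frame_rate, pixel_deg, movie$times,
                           coarse = TRUE)
  m
}

#' Scramble the spatial coherence of a coarse movie
#'
#' Applies one fixed (per-seed) random bijection of coarse-cell positions,
#' each cell displaced at most \eqn{r(c) = r_{max} (1 - c/100)} from its
#' true position, with \eqn{r_{max}} half the screen extent. The
#' permutation is constant across frames, so each cell keeps its own
#' luminance time course and the per-frame luminance multiset is preserved
#' exactly. `coherence = 100` is the identity; at 0 the permutation is
#' unrestricted.
#'
#' @param movie A coarse `stimulus_movie` (see [coarsen_pixelate()]).
#' @param coherence Percent coherence in \[0, 100\].
#' @param seed RNG seed fixing the permutation.
#' @return A `stimulus_movie` with scrambled cell positions.
#' @export
scramble_coherence <- function(movie, coherence, seed = 1L) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (!isTRUE(movie$coarse)) {
    abort("movie must be coarse-pixelated before coherence scrambling")
  }
  stopifnot(coherence >= 0, coherence <= 100)
  if (coherence == 100) return(movie)
  d <- dim(movie$frames)
  n <- d[2]
  cc <- .pix_centers(n * movie$pixel_pitch, movie$pixel_pitch)
  pos <- cbind(rep(cc, times = n), rep(cc, each = n)) # (row, col) deg
  ncell <- n * n
  perm <- .local_seed(seed, {
    if (coherence == 0) {
      sample.int(ncell)
    } else {
      r_max <- n * movie$pixel_pitch / 2
      r <- r_max * (1 - coherence / 100)
      perm <- seq_len(ncell)
      # random transposition proposals, accepted only if both cells stay
      # within radius r of their true positions
      for (k in seq_len(20L * ncell)) {
        ij <- sample.int(ncell, 2L)
        cand <- perm; cand[ij] <- perm[rev(ij)]
        da <- sqrt(sum((pos[cand[ij[1]], ] - pos[ij[1], ])^2))
        db <- sqrt(sum((pos[cand[ij[2]], ] - pos[ij[2], ])^2))
        if (da <= r && db <= r) perm <- cand
      }
      perm
    }
  })
  out <- movie
  flat <- matrix(movie$frames, nrow = d[1]) # T x (H*W), column-major cells
  flat_s <- flat
  flat_s[, perm] <- flat                    # cell j's content shown at perm[j]
  out$frames <- array(flat_s, dim = d)
  out
}

#' Hexagonal-ish facet grid at eye resolution
#'
#' Facet (ommatidium) centers on a square lattice with ~2 degree spacing,
#' the locust eye's spatial resolution, each with a Gaussian acceptance
#' profile of half-width at half-maximum equal to the spacing.
#'
#' @param extent_deg Angular extent covered per axis, degrees.
#' @param spacing_deg Nearest-neighbour facet spacing, degrees.
#' @param acceptance_hwhm_deg Gaussian half-width at half-maximum of a
#'   facet's receptive field, degrees.
#' @return A `facet_grid_spec` with a tibble of facet centers.
#' @export
facet_grid_spec <- function(extent_deg = 80, spacing_deg = 2,
                            acceptance_hwhm_deg = 2) {
  cc <- .pix_centers(extent_deg, spacing_deg)
  centers <- tibble(
    facet_id = seq_len(length(cc)^2),
    az_deg = rep(cc, each = length(cc)),
    el_deg = rep(cc, times = length(cc))
  )
  structure(list(centers = centers, spacing_deg = spacing_deg,
                 acceptance_hwhm_deg = acceptance_hwhm_deg,
                 extent_deg = extent_deg),
            class = "facet_grid_spec")
}

#' Sample a stimulus movie at ommatidial resolution
#'
#' Computes, per facet and frame, the Gaussian-weighted spatial average of
#' luminance around the facet center (weights truncated at 3 sigma and
#' renormalized).
#'
#' @param movie A `stimulus_movie`.
#' @param grid A [facet_grid_spec()]; defaults to one matching the movie
#'   extent.
#' @return A `facet_luminance` object: `traces` (n_facets x T matrix in
#'   \[0, 1\]), `frame_rate`, `times`, and the grid.
#' @export
sample_facets <- function(movie, grid = NULL) {
  stopifnot(inherits(movie, "stimulus_movie"))
  if (is.null(grid)) grid <- facet_grid_spec(extent_deg = movie$angular_extent)
  if (nrow(grid$centers) == 0) abort("facet grid is empty")
  d <- dim(movie$frames)
  cc <- .pix_centers(movie$angular_extent, movie$pixel_pitch)
  sigma <- grid$acceptance_hwhm_deg / sqrt(2 * log(2))
  cut <- 3 * sigma
  # sparse facet x pixel weight matrix (pixels column-major: row index fast)
  trip_i <- vector("list", nrow(grid$centers))
  trip_j <- vector("list", nrow(grid$centers))
  trip_x <- vector("list", nrow(grid$centers))
  for (f in seq_len(nrow(grid$centers))) {
    azf <- grid$centers$az_deg[f]; elf <- grid$centers$el_deg[f]
    rows <- which(abs(cc - elf) <= cut)
    cols <- which(abs(cc - azf) <= cut)
    if (!length(rows) || !length(cols)) next
    wr <- exp(-(cc[rows] - elf)^2 / (2 * sigma^2))
    wc <- exp(-(cc[cols] - azf)^2 / (2 * sigma^2))
    w <- outer(wr, wc)
    trip_i[[f]] <- rep(f, length(w))
    trip_j[[f]] <- as.vector(outer(rows, (cols - 1) * d[2], "+"))
    trip_x[[f]] <- as.vector(w / sum(w))
  }
  W <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x),
                            dims = c(nrow(grid$centers), d[2] * d[3]))
  flat <- t(matrix(movie$frames, nrow = d[1]))  # (H*W) x T
  traces <- as.matrix(W %*% flat)
  traces <- pmin(pmax(traces, 0), 1)  # guard rounding at the boundaries
  structure(list(traces = traces, frame_rate = movie$frame_rate,
                 times = movie$times, grid = grid),
            class = "facet_luminance")
}

#' @method print facet_luminance
#' @export
print.facet_luminance <- function(x, ...) {
  cat(sprintf("<facet_luminance> %d facets x %d frames at %g Hz\n",
              nrow(x$traces), ncol(x$traces), x$frame_rate))
  invisible(x)
}

# Evaluate code with a private, restored RNG state.
.local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
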