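# Facet luminance -> ON/OFF synaptic event trains. Event trains are plain
# tibbles (time_s, polarity, class, facet_id, source) so the whole encoding
# stage composes with dplyr verbs.

#' Encoding parameters
#'
#' The photoreceptor/lamina stage is modeled as a difference-of-exponentials
#' band-pass temporal filter on luminance, half-wave rectified into ON
#' (luminance increase) and OFF (decrease) drive channels. A threshold
#' stands in for medullary spiking, and `gain` converts suprathreshold
#' drive into an inhomogeneous-Poisson event intensity.
#'
#' @param tau_fast_ms,tau_slow_ms Band-pass filter time constants, ms.
#' @param threshold Medullary spiking threshold in drive units.
#' @param gain Excitatory events per unit suprathreshold drive-second,
#'   per facet; set by [calibrate_event_gain()].
#' @param inh_gain Inhibitory events per unit pooled drive-second; set by
#'   [calibrate_event_gain()].
#' @param inh_lag_ms Lag of the pooled inhibitory drive behind excitation.
#' @param spont_exc_rate,spont_inh_rate Aggregate spontaneous event rates,
#'   Hz (500 excitatory, 30 inhibitory).
#' @return An `encoding_params` list.
#' @export
encoding_params <- function(tau_fast_ms = 10, tau_slow_ms = 100,
                            threshold = 0.01, gain = 1, inh_gain = 1,
                            inh_lag_ms = 30,
                            spont_exc_rate = 500, spont_inh_rate = 30) {
  if (tau_fast_ms <= 0 || tau_slow_ms <= 0) {
    abort("filter time constants must be positive")
  }
  if (spont_exc_rate < 0 || spont_inh_rate < 0) {
    abort("spontaneous rates must be non-negative")
  }
  stopifnot(threshold >= 0, tau_fast_ms < tau_slow_ms)
  structure(list(tau_fast_ms = tau_fast_ms, tau_slow_ms = tau_slow_ms,
                 threshold = threshold, gain = gain, inh_gain = inh_gain,
                 inh_lag_ms = inh_lag_ms,
                 spont_exc_rate = spont_exc_rate,
                 spont_inh_rate = spont_inh_rate),
            class = "encoding_params")
}

# First-order exponential smoothing along rows of a facets x T matrix,
# initialized at the first sample (no onset transient for constant input).
.ema <- function(x, tau_ms, dt_ms) {
  a <- exp(-dt_ms / tau_ms)
  out <- x
  for (t in 2:ncol(x)) out[, t] <- a * out[, t - 1] + (1 - a) * x[, t]
  out
}

#' Transduce facet luminance into ON and OFF drive signals
#'
#' Band-pass filters each facet's luminance trace (difference of fast and
#' slow exponential averages) and half-wave rectifies the result: the
#' positive lobe is the ON drive, the sign-flipped negative lobe the OFF
#' drive. Both channels are non-negative; constant luminance decays to zero
#' drive.
#'
#' @param lum A `facet_luminance` from [sample_facets()].
#' @param params [encoding_params()].
#' @return A `facet_drive` object with `on` and `off` matrices
#'   (facets x T), `times`, and `frame_rate`.
#' @export
transduce_facets <- function(lum, params = encoding_params()) {
  stopifnot(inherits(lum, "facet_luminance"))
  dt_ms <- 1000 / lum$frame_rate
  bp <- .ema(lum$traces, params$tau_fast_ms, dt_ms) -
    .ema(lum$traces, params$tau_slow_ms, dt_ms)
  structure(list(on = pmax(bp, 0), off = pmax(-bp, 0),
                 times = lum$times, frame_rate = lum$frame_rate,
                 grid = lum$grid),
            class = "facet_drive")
}

# Expected suprathreshold drive integrals (drive-seconds) used both by
# calibration and by event generation.
.drive_integrals <- function(drive, params) {
  dt_s <- 1 / drive$frame_rate
  lag <- round(params$inh_lag_ms / 1000 * drive$frame_rate)
  son <- pmax(drive$on - params$threshold, 0)
  soff <- pmax(drive$off - params$threshold, 0)
  pooled <- colSums(son) + colSums(soff)          # wide-field pooled drive
  pooled <- c(rep(0, lag), pooled)[seq_along(pooled)]
  on_share <- sum(son) / max(sum(son) + sum(soff), .Machine$double.eps)
  list(son = son, soff = soff, pooled = pooled, dt_s = dt_s,
       exc_total = (sum(son) + sum(soff)) * dt_s,
       inh_total = sum(pooled) * dt_s,
       on_share = on_share)
}

#' Calibrate event gains to the reference event budgets
#'
#' Sets the excitatory and inhibitory gains so the *expected* number of
#' visually driven events for this stimulus equals the target budgets:
#' 80,000 excitatory and 7,000 inhibitory events for the reference loom.
#' Because the Poisson expectation is linear in gain, calibration is exact
#' in expectation; realized counts fluctuate by ~sqrt(N) (< 0.5%).
#'
#' @param drive A `facet_drive` from [transduce_facets()], computed on the
#'   reference stimulus.
#' @param params [encoding_params()].
#' @param exc_budget,inh_budget Target event totals.
#' @return `params` with `gain` and `inh_gain` set.
#' @export
calibrate_event_gain <- function(drive, params = encoding_params(),
                                 exc_budget = 80000, inh_budget = 7000) {
  stopifnot(inherits(drive, "facet_drive"))
  s <- .drive_integrals(drive, params)
  if (s$exc_total <= 0) {
    abort(paste("no suprathreshold drive: event budget unattainable;",
                "lower the threshold"))
  }
  params$gain <- exc_budget / s$exc_total
  params$inh_gain <- inh_budget / s$inh_total
  params
}

#' Generate synaptic events from drive signals
#'
#' Draws visually driven events as an inhomogeneous Poisson process with
#' intensity `gain * max(drive - threshold, 0)` per facet and frame bin.
#' ON drive yields ON-excitatory events and OFF drive OFF-excitatory
#' events, each carrying its facet id. Inhibitory events are drawn from the
#' wide-field pooled rectified drive (both channels, lagged by
#' `inh_lag_ms`) scaled by `inh_gain`; their ON/OFF label is drawn in
#' proportion to each channel's share of total drive and they carry no
#' facet id (wide-field origin).
#'
#' @param drive A `facet_drive`.
#' @param params Calibrated [encoding_params()].
#' @param seed RNG seed.
#' @return A `SynapticEventTrain` tibble with columns `time_s`, `polarity`
#'   (`"ON"`/`"OFF"`), `class` (`"excitatory"`/`"inhibitory"`), `facet_id`
#'   (NA for wide-field/spontaneous events) and `source`, sorted by time.
#' @export
generate_events <- function(drive, params, seed = 1L) {
  stopifnot(inherits(drive, "facet_drive"))
  s <- .drive_integrals(drive, params)
  empty <- tibble(time_s = numeric(), polarity = character(),
                  class = character(), facet_id = integer(),
                  source = character())
  .local_seed(seed, {
    exc <- purrr::map2_dfr(
      list(s$son, s$soff), c("ON", "OFF"),
      function(mat, pol) {
        lam <- params$gain * mat * s$dt_s
        nz <- which(lam > 0)
        if (!length(nz)) return(NULL)
        k <- rpois(length(nz), lam[nz])
        keep <- k > 0
        if (!any(keep)) return(NULL)
        nz <- nz[keep]; k <- k[keep]
        fid <- ((nz - 1) %% nrow(mat)) + 1
        bin <- ((nz - 1) %/% nrow(mat)) + 1
        tibble(
          time_s = rep(drive$times[bin], k) + runif(sum(k), 0, s$dt_s),
          polarity = pol, class = "excitatory",
          facet_id = rep(fid, k), source = "visual"
        )
      })
    lam_i <- params$inh_gain * s$pooled * s$dt_s
    ki <- rpois(length(lam_i), lam_i)
    inh <- if (sum(ki) > 0) {
      tibble(
        time_s = rep(drive$times, ki) + runif(sum(ki), 0, s$dt_s),
        polarity = ifelse(runif(sum(ki)) < s$on_share, "ON", "OFF"),
        class = "inhibitory", facet_id = NA_integer_, source = "visual"
      )
    } else NULL
    dplyr::arrange(dplyr::bind_rows(empty, exc, inh), .data$time_s)
  })
}

#' Append spontaneous synaptic events
#'
#' Adds homogeneous Poisson background events at the stated aggregate
#' rates (500 Hz excitatory, 30 Hz inhibitory) over a time window, marked
#' `source = "spontaneous"`, and re-sorts the train. Spontaneous events
#' carry the OFF-pathway label, placing them on the pathways active at
#' rest in the dark-loom configuration (excitation to field A, inhibition
#' to field C).
#'
#' @param train A `SynapticEventTrain` tibble (may be empty).
#' @param t_start,t_end Window over which to draw background events, s.
#' @param params [encoding_params()] carrying the spontaneous rates.
#' @param seed RNG seed.
#' @return The merged, time-sorted event tibble.
#' @export
add_spontaneous <- function(train, t_start, t_end,
                            params = encoding_params(), seed = 1L) {
  if (t_end <= t_start) abort("t_end must exceed t_start")
  dur <- t_end - t_start
  .local_seed(seed, {
    draw <- function(rate, cls) {
      n <- rpois(1, rate * dur)
      if (n == 0) return(NULL)
      tibble(time_s = sort(runif(n, t_start, t_end)),
             polarity = "OFF", class = cls,
             facet_id = NA_integer_, source = "spontaneous")
    }
    spont <- dplyr::bind_rows(draw(params$spont_exc_rate, "excitatory"),
                              draw(params$spont_inh_rate, "inhibitory"))
    dplyr::arrange(dplyr::bind_rows(train, spont), .data$time_s)
  })
}

#' Render, sample, transduce, calibrate and encode a loom in one call
#'
#' Convenience wrapper running the full stimulus-to-events chain for a
#' loom: [render_stimulus()] -> [sample_facets()] -> [transduce_facets()]
#' -> [calibrate_event_gain()] -> [generate_events()] (+ optional
#' spontaneous background).
#'
#' @param spec A [loom_spec()].
#' @param params [encoding_params()].
#' @param calibrate Recalibrate gains on this stimulus' own drive? If
#'   `FALSE`, `params` gains are used as-is (e.g. gains calibrated on a
#'   reference loom applied to a scrambled variant).
#' @param spontaneous Add spontaneous background events?
#' @param exc_budget,inh_budget Calibration targets.
#' @param seed RNG seed for event draws.
#' @return A `SynapticEventTrain` tibble (see [generate_events()]), with
#'   the drive and calibrated params attached as attributes.
#' @examples
#' \donttest{
#' tr <- encode_loom(loom_spec(80, "black", t_start = -1, extent_deg = 40),
#'                   exc_budget = 2000, inh_budget = 200, seed = 2)
#' dplyr::count(tr, class)
#' }
#' @export
encode_loom <- function(spec, params = encoding_params(), calibrate = TRUE,
                        spontaneous = FALSE, exc_budget = 80000,
                        inh_budget = 7000, seed = 1L) {
  movie <- render_stimulus(spec)
  drive <- transduce_facets(sample_facets(movie), params)
  if (calibrate) {
    params <- calibrate_event_gain(drive, params, exc_budget, inh_budget)
  }
  train <- generate_events(drive, params, seed = seed)
  if (spontaneous) {
    train <- add_spontaneous(train, min(drive$times),
                             max(drive$times) + 1 / drive$frame_rate,
                             params, seed = seed + 1L)
  }
  attr(train, "params") <- params
  attr(train, "grid") <- drive$grid
  train
}
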