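# Higher-level simulation experiments: the mapping comparisons behind the
# model analyses (field A vs C efficacy, removal-fraction equivalence,
# split curve, clustering, coherence series). Each returns a tidy tibble.

# Spike count for one mapped train, with a settle margin before the
# events so counts exclude the initial-condition transient.
.loom_spike_count <- function(morph, channels, map, t_start, t_end,
                              settle_s = 0.4, dt_ms = 0.02) {
  res <- simulate_lgmd(morph, channels, map,
                       t_start = t_start - settle_s, t_end = t_end,
                       dt_ms = dt_ms, v_init = -64)
  sum(res$spike_times_s >= t_start)
}

#' Spike-count response for a mapped loom under one mapping scheme
#'
#' Maps an encoded train onto the morphology and simulates it, returning
#' a one-row tibble. The simulation window covers the train with a 0.4 s
#' settle margin; spikes during the margin are not counted.
#'
#' @param train Encoded `SynapticEventTrain` (see [encode_loom()]).
#' @param morph,channels Model (see [build_morphology()],
#'   [default_channelset()]).
#' @param mode,seed,... Passed to [map_events()].
#' @param t_start,t_end Stimulus window, s (defaults from the train).
#' @param dt_ms Integration step.
#' @return Tibble: `mode`, `seed`, `n_events`, `n_spikes`,
#'   `peak_ifr_hz`, `exc_charge_nC`.
#' @export
loom_response <- function(train, morph, channels = default_channelset(),
                          mode = "retinotopic_A", seed = 1L,
                          t_start = min(train$time_s),
                          t_end = max(train$time_s) + 0.05,
                          dt_ms = 0.02, ...) {
  map <- map_events(train, morph, mode = mode, seed = seed, ...)
  res <- simulate_lgmd(morph, channels, map, t_start = t_start - 0.4,
                       t_end = t_end, dt_ms = dt_ms, v_init = -64)
  d <- detect_spikes_ifr(res)
  tibble(
    mode = mode, seed = seed, n_events = nrow(map),
    n_spikes = sum(res$spike_times_s >= t_start),
    peak_ifr_hz = max(d$ifr$rate_hz),
    exc_charge_nC = res$exc_charge_nC
  )
}

#' Largest removal fraction at which field C input still matches field A
#'
#' Reproduces the relocation experiment: all loom-evoked excitation is
#' moved to random field C compartments and progressively removed; the
#' function reports, per mapping seed, the largest removal fraction for
#' which the field C spike count is still at least the all-field-A count,
#' and their average.
#'
#' @param train Encoded reference train.
#' @param morph,channels Model.
#' @param fractions Candidate removal fractions (sorted increasing).
#' @param seeds Mapping seeds to average over.
#' @return A list: `fraction` (mean over seeds, in \[0,1\]), `per_seed`
#'   tibble (`seed`, `fraction`, `n_a`), and the per-fraction counts.
#' @export
find_removal_fraction <- function(train, morph,
                                  channels = default_channelset(),
                                  fractions = seq(0.3, 0.85, by = 0.05),
                                  seeds = 1:5) {
  t0 <- min(train$time_s); t1 <- max(train$time_s) + 0.05
  cnt <- function(map) .loom_spike_count(morph, channels, map, t0, t1)
  rows <- purrr::map_dfr(seeds, function(s) {
    n_a <- cnt(map_events(train, morph, "retinotopic_A", seed = s))
    best <- 0
    counts <- numeric(length(fractions))
    for (i in seq_along(fractions)) {
      counts[i] <- cnt(map_events(train, morph, "random_C",
                                  removal_fraction = fractions[i],
                                  seed = s))
      if (counts[i] >= n_a) best <- fractions[i] else break
    }
    tibble(seed = s, fraction = best, n_a = n_a,
           counts = list(tibble(fraction = fractions,
                                n_c = counts)))
  })
  list(fraction = mean(rows$fraction),
       per_seed = rows[, c("seed", "fraction", "n_a")],
       detail = tidyr::unnest(rows[, c("seed", "counts")],
                              "counts"))
}

#' Spike count as a function of the field A / field C excitation split
#'
#' Varies the fraction of excitatory events relocated from retinotopic
#' field A positions to random field C positions (with 60% of the moved
#' events removed) and simulates each configuration.
#'
#' @param train Encoded reference train.
#' @param morph,channels Model.
#' @param fractions Split fractions to evaluate.
#' @param removal_fraction Removal applied to moved events.
#' @param move_inhibition See [map_events()]; `FALSE` (default here)
#'   keeps inhibition at its natural field C site so the curve's
#'   endpoints coincide with the all-A and all-C reference runs.
#' @param seed Mapping seed.
#' @return Tibble: `split_fraction`, `n_spikes`, `peak_ifr_hz`.
#' @export
split_response_curve <- function(train, morph,
                                 channels = default_channelset(),
                                 fractions = c(0, 0.25, 0.5, 0.75, 1),
                                 removal_fraction = 0.6,
                                 move_inhibition = FALSE, seed = 2L) {
  purrr::map_dfr(fractions, function(f) {
    r <- loom_response(train, morph, channels, mode = "split",
                       split_fraction = f,
                       removal_fraction = removal_fraction,
                       move_inhibition = move_inhibition, seed = seed)
    tibble(split_fraction = f, n_spikes = r$n_spikes,
           peak_ifr_hz = r$peak_ifr_hz)
  })
}

#' Spike count as clustered field C mapping narrows
#'
#' Compares random field C mapping against clustered mappings of
#' decreasing spatial extent (the sigmoid recruitment front and
#' steepness scaled together by `width_scales`).
#'
#' @param train Encoded reference train.
#' @param loom The [loom_spec()] behind the train.
#' @param morph,channels Model.
#' @param width_scales Cluster width scales, decreasing = narrower.
#' @param removal_fraction Removal applied to the field C events.
#' @param seed Mapping seed.
#' @return Tibble: `width_scale` (Inf = random mapping), `n_spikes`.
#' @export
clustering_response_curve <- function(train, loom, morph,
                                      channels = default_channelset(),
                                      width_scales = c(1, 0.5, 0.25),
                                      removal_fraction = 0.6, seed = 3L) {
  rand <- loom_response(train, morph, channels, mode = "random_C",
                        removal_fraction = removal_fraction, seed = seed)
  rows <- purrr::map_dfr(width_scales, function(w) {
    r <- loom_response(train, morph, channels, mode = "clustered_C",
                       removal_fraction = removal_fraction,
                       cluster_width_scale = w, loom = loom, seed = seed)
    tibble(width_scale = w, n_spikes = r$n_spikes)
  })
  dplyr::bind_rows(tibble(width_scale = Inf, n_spikes = rand$n_spikes),
                   rows)
}

#' Peak firing rate versus spatial coherence for checkered looms
#'
#' Runs the coherence-series protocol: checkered looms are
#' coarse-pixelated at 2.5 degrees, scrambled to each coherence level,
#' encoded with gains calibrated once on the reference black loom, mapped
#' by contrast polarity (OFF facets retinotopic to field A, ON facets
#' random to field C), and simulated.
#'
#' @param coherences Coherence levels, percent.
#' @param params Calibrated [encoding_params()] (from the reference
#'   loom).
#' @param morph,channels Model.
#' @param l_over_v,t_start,hold_s Loom kinematics, s.
#' @param removal_fraction Removal applied to the field C share.
#' @param seed Base seed (scramble and event draws derive from it).
#' @return Tibble: `coherence`, `n_events`, `n_spikes`, `peak_ifr_hz`.
#' @export
coherence_response_curve <- function(coherences = c(100, 50, 0), params,
                                     morph,
                                     channels = default_channelset(),
                                     l_over_v = 80, t_start = -2,
                                     hold_s = 0.2,
                                     removal_fraction = 0.6, seed = 4L) {
  purrr::map_dfr(coherences, function(coh) {
    sp <- loom_spec(l_over_v, "checkered", coherence = coh,
                    t_start = t_start, t_end = 0, hold_s = hold_s,
                    coarse = TRUE, seed = seed + 3L)
    trc <- encode_loom(sp, params = params, calibrate = FALSE,
                       spontaneous = TRUE, seed = seed)
    r <- loom_response(trc, morph, channels, mode = "polarity",
                       removal_fraction = removal_fraction, seed = seed)
    tibble(coherence = coh, n_events = r$n_events,
           n_spikes = r$n_spikes, peak_ifr_hz = r$peak_ifr_hz)
  })
}

#' Axial-resistance factor equalizing field C and field A budgets
#'
#' Reproduces the electrotonic-distance manipulation: the axial
#' resistance between field C and the main neurite is increased until the
#' full excitatory budget delivered to random field C compartments
#' elicits the same spike count as the same budget delivered
#' retinotopically to field A -- i.e. until as much excitation is needed
#' in field C as in field A for the same response. (Matching single-EPSP
#' amplitudes instead, [match_epsp_factor()], does not transfer to full
#' budgets in a compact field C: concentrated input loses driving force;
#' see the methods vignette.)
#'
#' @param train Encoded reference train.
#' @param morph,channels Model.
#' @param interval Search interval for the factor (applied on top of the
#'   morphology's tuned link scale).
#' @param seed Mapping seed.
#' @return A list: `factor`, `n_a`, `n_c` (counts at the returned
#'   factor).
#' @export
match_budget_factor <- function(train, morph,
                                channels = default_channelset(),
                                interval = c(1, 32), seed = 1L) {
  t0 <- min(train$time_s); t1 <- max(train$time_s) + 0.05
  cnt <- function(m, mode) {
    .loom_spike_count(m, channels,
                      map_events(train, m, mode, seed = seed), t0, t1)
  }
  diff_at <- function(fac) {
    m <- scale_axial_resistance(morph, fac)
    cnt(m, "random_C") - cnt(m, "retinotopic_A")
  }
  lo <- interval[1]; hi <- interval[2]
  if (diff_at(lo) < 0) {
    warn("field C no stronger than field A at the lower bound")
    fac <- lo
  } else {
    for (i in 1:6) { # bisection on log scale; counts are integer anyway
      mid <- sqrt(lo * hi)
      if (diff_at(mid) >= 0) lo <- mid else hi <- mid
    }
    fac <- lo
  }
  m <- scale_axial_resistance(morph, fac)
  list(factor = fac, n_a = cnt(m, "retinotopic_A"),
       n_c = cnt(m, "random_C"))
}
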