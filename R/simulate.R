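# Simulation front end over the compiled branched-cable solver.

#' Alpha-synapse parameters
#'
#' Excitatory default: 0.15 ms time constant, 14 nS maximal conductance,
#' +10 mV reversal. Inhibitory default: 2 ms, 8 nS, -78 mV. The alpha
#' conductance is \eqn{g(t) = g_{max}(t/\tau)e^{1 - t/\tau}}, peaking at
#' `g_max` at `t = tau`.
#'
#' @param exc,inh Lists with `tau_ms`, `g_max_nS`, `e_rev_mV`.
#' @return A `synapse_params` list.
#' @export
synapse_params <- function(exc = list(tau_ms = 0.15, g_max_nS = 14,
                                      e_rev_mV = 10),
                           inh = list(tau_ms = 2, g_max_nS = 8,
                                      e_rev_mV = -78)) {
  stopifnot(exc$tau_ms > 0, inh$tau_ms > 0,
            exc$g_max_nS >= 0, inh$g_max_nS >= 0)
  structure(list(exc = exc, inh = inh), class = "synapse_params")
}

#' Simulate the reduced compartmental LGMD
#'
#' Integrates the branched cable equation with an implicit
#' (unconditionally stable) scheme at fixed `dt_ms` (default 0.02 ms),
#' delivering mapped synaptic events as alpha conductances, and returns
#' membrane potential traces, detected spikes, and the integrated
#' synaptic charge \eqn{\int \sum_i g_i(t)(E_{rev} - V)\,dt}.
#'
#' @param morph An `lgmd_morphology`.
#' @param channels A `channelset` (see [default_channelset()]).
#' @param events A mapped event tibble from [map_events()] (columns
#'   `time_s`, `class`, `comp_id`, `g_scale`), or `NULL` for an
#'   event-free run. Events outside the simulated window are ignored
#'   with a warning.
#' @param t_start,t_end Simulated window, s.
#' @param dt_ms Time step, ms.
#' @param syn [synapse_params()].
#' @param record Compartment ids whose membrane potential is recorded
#'   (default SIZ and axon).
#' @param record_every Record every k-th step.
#' @param spike_comp Compartment used for spike detection (default axon).
#' @param spike_threshold_mV,refractory_ms Upward-crossing threshold
#'   (-20 mV) and de-duplication refractory period (2 ms).
#' @param inj Optional current step: `list(comp, nA, from_ms, to_ms)`
#'   with times measured from `t_start`.
#' @param clamp_mv If non-`NULL`, hold every compartment at this voltage
#'   (synaptic charge accounting continues; used for charge-conservation
#'   checks).
#' @param v_init Initial potential, mV.
#' @return A `sim_result`: `vm` (recorded traces, mV), `t_ms` (from
#'   `t_start`), `spike_times_s` (absolute), `exc_charge_nC`,
#'   `inh_charge_nC`, `dt_ms`.
#' @examples
#' morph <- build_morphology(morph_config(n_a_cols = 2, n_a_rows = 2,
#'                                        n_c = 4, n_b = 2))
#' res <- simulate_lgmd(morph, default_channelset(), NULL,
#'                      t_start = 0, t_end = 0.2)
#' glance(res)
#' @export
simulate_lgmd <- function(morph, channels = default_channelset(),
                          events = NULL, t_start, t_end, dt_ms = 0.02,
                          syn = synapse_params(),
                          record = c(morph$siz_comp, morph$axon_comp),
                          record_every = 5L,
                          spike_comp = morph$axon_comp,
                          spike_threshold_mV = -20, refractory_ms = 2,
                          inj = NULL, clamp_mv = NULL, v_init = -65) {
  stopifnot(inherits(morph, "lgmd_morphology"), dt_ms > 0,
            t_end > t_start)
  co <- morph$compartments
  ch <- .channels_per_comp(morph, channels)
  nstep <- ceiling((t_end - t_start) * 1000 / dt_ms)

  if (is.null(events) || nrow(events) == 0) {
    ev <- tibble(step = integer(), comp = integer(), w = numeric(),
                 type = integer())
  } else {
    stopifnot(all(c("time_s", "class", "comp_id", "g_scale") %in%
                    names(events)))
    inside <- events$time_s >= t_start &
      events$time_s < t_start + nstep * dt_ms / 1000
    if (any(!inside)) {
      warn(sprintf("%d events outside the simulated window ignored",
                   sum(!inside)))
      events <- events[inside, , drop = FALSE]
    }
    g_max <- ifelse(events$class == "excitatory",
                    syn$exc$g_max_nS, syn$inh$g_max_nS)
    ev <- tibble(
      step = as.integer(floor((events$time_s - t_start) * 1000 / dt_ms)),
      comp = as.integer(events$comp_id) - 1L,
      w = g_max * events$g_scale / 1000, # nS -> uS
      type = ifelse(events$class == "excitatory", 0L, 1L)
    )
    ev <- dplyr::arrange(ev, .data$step)
  }

  inj_comp <- -1L; inj_na <- 0; inj_from <- 0L; inj_to <- 0L
  if (!is.null(inj)) {
    inj_comp <- as.integer(inj$comp) - 1L
    inj_na <- inj$nA
    inj_from <- as.integer(round(inj$from_ms / dt_ms))
    inj_to <- as.integer(round(inj$to_ms / dt_ms))
  }

  res <- cable_sim_cpp(
    parent = as.integer(dplyr::coalesce(co$parent_id, 0L)) - 1L,
    length_um = co$length_um, diam_um = co$diam_um,
    ra_ohm_cm = co$ra_ohm_cm, ra_scale = co$ra_scale,
    cm_uf_cm2 = co$cm_uf_cm2,
    g_pas = ch$g_pas, e_pas = ch$e_pas,
    dens = ch$dens, revs = ch$revs,
    ev_step = ev$step, ev_comp = ev$comp, ev_w_us = ev$w,
    ev_type = ev$type,
    tau_e = syn$exc$tau_ms, e_e = syn$exc$e_rev_mV,
    tau_i = syn$inh$tau_ms, e_i = syn$inh$e_rev_mV,
    nstep = nstep, dt = dt_ms, v_init = v_init,
    record_idx = as.integer(record) - 1L,
    record_every = as.integer(record_every),
    spike_comp = as.integer(spike_comp) - 1L,
    spike_thresh = spike_threshold_mV, refrac_ms = refractory_ms,
    inj_comp = inj_comp, inj_na = inj_na,
    inj_start = inj_from, inj_end = inj_to,
    clamp = !is.null(clamp_mv), clamp_mv = clamp_mv %||% 0,
    kin = ch$kin)

  colnames(res$vm) <- paste0("comp_", record)
  structure(list(
    vm = res$vm, t_ms = res$t_ms,
    spike_times_s = t_start + res$spike_t_ms / 1000,
    exc_charge_nC = res$exc_charge_nC,
    inh_charge_nC = res$inh_charge_nC,
    dt_ms = dt_ms, t_start = t_start, t_end = t_end,
    record = record, n_events = nrow(ev)
  ), class = "sim_result")
}

#' @method print sim_result
#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %.2f-%.2f s at dt = %g ms: %d spikes, %.2f nC excitatory charge\n",
    x$t_start, x$t_end, x$dt_ms, length(x$spike_times_s),
    x$exc_charge_nC))
  invisible(x)
}

#' Detect spikes and estimate the instantaneous firing rate
#'
#' Upward threshold crossings on a recorded membrane-potential trace,
#' de-duplicated with a refractory period, followed by convolution of the
#' spike train with a normalized Gaussian kernel (default SD 20 ms) to
#' give the instantaneous firing rate (IFR, spikes/s). Each spike's
#' kernel integrates to one, so the IFR integral equals the spike count.
#'
#' @param result A `sim_result`.
#' @param comp Which recorded column to use (default the axon if
#'   recorded, else the first).
#' @param threshold_mV Crossing threshold.
#' @param refractory_ms Minimum inter-spike interval.
#' @param kernel_sd_ms Gaussian kernel SD, ms.
#' @return A list with `spike_times_s` and an `ifr` tibble
#'   (`time_s`, `rate_hz`).
#' @export
detect_spikes_ifr <- function(result, comp = NULL, threshold_mV = -20,
                              refractory_ms = 2, kernel_sd_ms = 20) {
  stopifnot(inherits(result, "sim_result"))
  k <- if (is.null(comp)) ncol(result$vm) else {
    match(paste0("comp_", comp), colnames(result$vm))
  }
  v <- result$vm[, k]
  t_s <- result$t_start + result$t_ms / 1000
  up <- which(v[-1] >= threshold_mV & v[-length(v)] < threshold_mV) + 1
  spk <- numeric(0)
  for (ti in t_s[up]) {
    if (!length(spk) || (ti - spk[length(spk)]) * 1000 > refractory_ms) {
      spk <- c(spk, ti)
    }
  }
  sd_s <- kernel_sd_ms / 1000
  rate <- rep(0, length(t_s))
  for (ti in spk) {
    rate <- rate + stats::dnorm(t_s, ti, sd_s)
  }
  list(spike_times_s = spk,
       ifr = tibble(time_s = t_s, rate_hz = rate))
}

#' Tune the field C link so matched EPSPs match at the SIZ
#'
#' Binary-searches the axial-resistance scale factor of the field C
#' connecting segment (see [scale_axial_resistance()]) until a single
#' excitatory EPSP delivered to a field C compartment depolarizes the SIZ
#' by the same amount as the same EPSP delivered to a field A terminal.
#' With that factor applied, equal event budgets in the two fields
#' produce equal responses.
#'
#' @param morph An `lgmd_morphology`.
#' @param channels A `channelset`.
#' @param interval Search interval for the factor.
#' @param tol Relative amplitude tolerance.
#' @return The scale factor.
#' @export
match_epsp_factor <- function(morph, channels = default_channelset(),
                              interval = c(1, 400), tol = 0.01) {
  amp <- function(m, comp) {
    # settle 250 ms to steady state, then deliver one EPSP
    ev <- tibble(time_s = 0.25, class = "excitatory",
                 comp_id = comp, g_scale = 1)
    r <- simulate_lgmd(m, channels, ev, t_start = 0, t_end = 0.32,
                       record = m$siz_comp, record_every = 1L)
    post <- r$t_ms >= 250
    max(r$vm[post, 1]) - r$vm[which(r$t_ms >= 249.5)[1], 1]
  }
  co <- morph$compartments
  # representative terminals: central field A column's tip, mid field C
  ag <- morph$a_grid
  a_term <- ag$comp_id[ag$row == max(ag$row) &
                         ag$col == ceiling(max(ag$col) / 2)][1]
  c_mid <- co$id[co$region == "C"][ceiling(sum(co$region == "C") / 2)]
  target <- amp(morph, a_term)
  f <- function(fac) {
    amp(scale_axial_resistance(morph, fac), c_mid) - target
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo)
  if (flo < 0) return(lo) # C already no stronger than A
  for (i in 1:25) {
    mid <- sqrt(lo * hi)
    fm <- f(mid)
    if (abs(fm) < tol * target) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Spikes from a simulation as a tibble
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return A tibble with `spike` index and `time_s`.
#' @export
tidy.sim_result <- function(x, ...) {
  tibble(spike = seq_along(x$spike_times_s), time_s = x$spike_times_s)
}

#' One-row summary of a simulation
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return A one-row tibble: spike count, peak recorded Vm, synaptic
#'   charge, step size.
#' @export
glance.sim_result <- function(x, ...) {
  tibble(
    n_spikes = length(x$spike_times_s),
    peak_vm_mV = max(x$vm),
    exc_charge_nC = x$exc_charge_nC,
    inh_charge_nC = x$inh_charge_nC,
    dt_ms = x$dt_ms
  )
}
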