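# Compartmental solver: resting stability, reference ODE oracle, charge
# accounting, spike detection / IFR, step-size robustness.

test_that("the tuned model rests quietly near -64 mV", {
  morph <- ref_morph()
  res <- simulate_lgmd(morph, ref_channels(), NULL, t_start = 0,
                       t_end = 1, v_init = -64)
  v <- res$vm[res$t_ms > 300, ] # after the initial-condition transient
  expect_equal(length(res$spike_times_s[res$spike_times_s > 0.3]), 0)
  expect_lt(max(abs(v - v[nrow(v), 1])), 0.5)
  expect_lt(abs(v[nrow(v), 1] + 64), 1.5)
})

test_that("a passive two-compartment EPSP matches a dense ODE oracle", {
  morph <- cable_morph(n = 2, length_um = 40, diam_um = 4)
  ch <- passive_channelset(g_pas = 0.25, e_pas = -65)
  syn <- synapse_params()
  ev <- tibble::tibble(time_s = 0.010, class = "excitatory",
                       comp_id = 2, g_scale = 1)
  res <- simulate_lgmd(morph, ch, ev, t_start = 0, t_end = 0.05,
                       record = c(1, 2), record_every = 1L)

  # independent oracle: dense-output ODE integration of the same
  # two-compartment circuit, synapse conductance in closed form
  area <- pi * 4e-4 * 40e-4                    # cm^2
  cap <- 0.8 * area * 1e3                      # nF
  gm <- 0.25 * area * 1e3                      # uS
  r_half <- 60 * (40e-4 / 2) / (pi * (2e-4)^2) # Ohm
  ga <- 1e6 / (2 * r_half)                     # uS
  gmax <- syn$exc$g_max_nS / 1000; tau <- syn$exc$tau_ms
  t_on <- 10                                   # ms
  gsyn <- function(t) {
    ifelse(t > t_on,
           gmax * ((t - t_on) / tau) * exp(1 - (t - t_on) / tau), 0)
  }
  rhs <- function(t, y, parms) {
    v1 <- y[1]; v2 <- y[2]
    dv1 <- (gm * (-65 - v1) + ga * (v2 - v1)) / cap
    dv2 <- (gm * (-65 - v2) + ga * (v1 - v2) +
              gsyn(t) * (10 - v2)) / cap
    list(c(dv1, dv2))
  }
  t_eval <- res$t_ms
  sol <- deSolve::lsoda(c(-65, -65), t_eval, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10, hmax = 0.002)
  expect_lt(max(abs(res$vm[, 1] - sol[, 2])), 0.1)
  expect_lt(max(abs(res$vm[, 2] - sol[, 3])), 0.1)
  # the EPSP is actually there
  expect_gt(max(res$vm[, 2]) + 65, 1)
})

test_that("clamped-voltage synaptic charge matches the per-event closed
           form", {
  morph <- cable_morph(n = 5)
  ch <- passive_channelset()
  n_ev <- 40
  ev <- tibble::tibble(
    time_s = seq(0.005, 0.08, length.out = n_ev),
    class = "excitatory",
    comp_id = sample(1:5, n_ev, replace = TRUE),
    g_scale = 1)
  res <- simulate_lgmd(morph, ch, ev, t_start = 0, t_end = 0.12,
                       clamp_mv = -60)
  analytic <- n_ev * epsp_charge(14, 0.15, 10, -60) * 1e-3 # nC
  expect_equal(res$exc_charge_nC, analytic, tolerance = 0.01)
})

test_that("spike detection and IFR behave like a normalized kernel
           estimate", {
  morph <- ref_morph()
  quiet <- simulate_lgmd(morph, ref_channels(), NULL, t_start = 0,
                         t_end = 0.3, v_init = -64)
  d0 <- detect_spikes_ifr(quiet)
  # quiescent after settling (any settling spike's kernel has decayed)
  expect_lt(max(d0$ifr$rate_hz[d0$ifr$time_s > 0.25]), 1e-6)

  # synthetic result object: regular 100 Hz spiking trace
  t_ms <- seq(0, 1000, by = 0.1)
  v <- rep(-65, length(t_ms))
  spike_at <- seq(100, 900, by = 10) # ms -> 100 Hz
  for (s in spike_at) v[t_ms >= s & t_ms < s + 0.5] <- 0
  fake <- structure(list(vm = matrix(v, ncol = 1,
                                     dimnames = list(NULL, "comp_1")),
                         t_ms = t_ms, t_start = 0, dt_ms = 0.1),
                    class = "sim_result")
  d <- detect_spikes_ifr(fake, comp = 1)
  expect_equal(length(d$spike_times_s), length(spike_at))
  # kernel integrates to one per spike
  dt_s <- 1e-4
  expect_equal(sum(d$ifr$rate_hz) * dt_s, length(spike_at),
               tolerance = 0.01)
  # plateau near 100 spk/s mid-train
  mid <- d$ifr$time_s > 0.3 & d$ifr$time_s < 0.7
  expect_equal(mean(d$ifr$rate_hz[mid]), 100, tolerance = 0.02)
})

test_that("events outside the window are ignored with a warning", {
  morph <- cable_morph(n = 3)
  ev <- tibble::tibble(time_s = c(0.01, 0.5), class = "excitatory",
                       comp_id = 1, g_scale = 1)
  expect_warning(
    res <- simulate_lgmd(morph, passive_channelset(), ev,
                         t_start = 0, t_end = 0.1),
    "outside")
  expect_equal(res$n_events, 1)
})

test_that("halving the step leaves a small event-driven response
           unchanged", {
  morph <- ref_morph()
  # subthreshold train so the peak-Vm comparison is not dominated by
  # spike-peak timing
  tr <- small_train(600, 60, seed = 12)
  map <- map_events(tr, morph, "random_C", seed = 2)
  r1 <- simulate_lgmd(morph, ref_channels(), map, t_start = -1.4,
                      t_end = 0.05, dt_ms = 0.02, v_init = -64)
  r2 <- simulate_lgmd(morph, ref_channels(), map, t_start = -1.4,
                      t_end = 0.05, dt_ms = 0.01, v_init = -64)
  expect_lte(abs(length(r1$spike_times_s) - length(r2$spike_times_s)), 1)
  expect_lt(abs(max(r1$vm[, 1]) - max(r2$vm[, 1])), 0.5)
})

test_that("conductance scaling and event removal are interchangeable", {
  morph <- ref_morph()
  tr <- ref_train()
  cnt <- function(method) {
    map <- map_events(tr, morph, "random_C", removal_fraction = 0.6,
                      removal_method = method, seed = 5)
    res <- simulate_lgmd(morph, ref_channels(), map, t_start = -2.4,
                         t_end = 0.2, v_init = -64)
    sum(res$spike_times_s > -2)
  }
  expect_lte(abs(cnt("remove") - cnt("scale")), 2)
})

test_that("sim results expose tidy() and glance()", {
  morph <- cable_morph(n = 3)
  res <- simulate_lgmd(morph, passive_channelset(), NULL, t_start = 0,
                       t_end = 0.05)
  expect_equal(nrow(tidy(res)), 0)
  g <- glance(res)
  expect_equal(g$n_spikes, 0)
  expect_s3_class(g, "tbl_df")
})
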