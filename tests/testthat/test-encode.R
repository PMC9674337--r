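# Luminance-to-event encoding: band-pass transduction, Poisson event
# generation, calibration, spontaneous background.

# Minimal facet_luminance built by hand.
toy_lum <- function(traces, frame_rate = 240) {
  structure(list(traces = traces, frame_rate = frame_rate,
                 times = (seq_len(ncol(traces)) - 1) / frame_rate,
                 grid = NULL),
            class = "facet_luminance")
}

test_that("band-pass transduction rejects DC and splits polarity", {
  # constant luminance: both channels decay to ~0
  lum <- toy_lum(matrix(0.6, 1, 480))
  d <- transduce_facets(lum)
  expect_lt(max(d$on[, 400:480]), 1e-6)
  expect_lt(max(d$off[, 400:480]), 1e-6)

  # step down: OFF pulse, no ON
  tr <- matrix(1, 1, 480); tr[1, 241:480] <- 0.2
  d <- transduce_facets(toy_lum(tr))
  expect_gt(max(d$off), 0.1)
  expect_lt(max(d$on), 1e-9)

  # step up then equal step down: ON then OFF pulses of equal integral
  tr <- matrix(0.3, 1, 960)
  tr[1, 241:960] <- 0.8   # up at frame 241
  tr[1, 721:960] <- 0.3   # down at frame 721
  d <- transduce_facets(toy_lum(tr))
  expect_equal(sum(d$on), sum(d$off), tolerance = 0.01)

  expect_error(encoding_params(tau_fast_ms = -1), "positive")
})

test_that("event generation is thresholded Poisson with linear gain", {
  tr <- matrix(1, 4, 480); tr[, 241:480] <- 0
  d <- transduce_facets(toy_lum(tr))

  # drive everywhere below threshold: no events
  p_hi <- encoding_params(threshold = 10, gain = 100)
  expect_equal(nrow(generate_events(d, p_hi, seed = 1)), 0)

  # determinism
  p <- encoding_params(threshold = 0.01, gain = 300, inh_gain = 30)
  e1 <- generate_events(d, p, seed = 3)
  expect_identical(e1, generate_events(d, p, seed = 3))
  expect_true(all(diff(e1$time_s) >= 0))
  expect_true(all(e1$polarity[e1$class == "excitatory"] == "OFF"))
  expect_true(all(!is.na(e1$facet_id[e1$class == "excitatory"])))
  expect_true(all(is.na(e1$facet_id[e1$class == "inhibitory"])))

  # doubling the gain doubles the expected count (Monte-Carlo over
  # 100 seeds, relative error < 5%)
  p2 <- p; p2$gain <- 2 * p$gain
  n1 <- mean(vapply(1:100, function(s) {
    ev <- generate_events(d, p, seed = s)
    sum(ev$class == "excitatory")
  }, numeric(1)))
  n2 <- mean(vapply(1:100, function(s) {
    ev <- generate_events(d, p2, seed = s)
    sum(ev$class == "excitatory")
  }, numeric(1)))
  expect_equal(n2 / n1, 2, tolerance = 0.05)
})

test_that("calibration hits requested budgets in expectation", {
  tr <- matrix(1, 4, 480); tr[, 241:480] <- 0
  d <- transduce_facets(toy_lum(tr))
  p <- calibrate_event_gain(d, exc_budget = 3000, inh_budget = 300)
  counts <- vapply(1:30, function(s) {
    ev <- generate_events(d, p, seed = s)
    c(sum(ev$class == "excitatory"), sum(ev$class == "inhibitory"))
  }, numeric(2))
  expect_equal(mean(counts[1, ]), 3000, tolerance = 0.02)
  expect_equal(mean(counts[2, ]), 300, tolerance = 0.05)

  # unattainable budget: all drive below threshold
  expect_error(
    calibrate_event_gain(d, encoding_params(threshold = 100)),
    "threshold")
})

test_that("spontaneous background is Poisson at the stated rates", {
  p <- encoding_params() # 500 Hz excitatory, 30 Hz inhibitory
  empty <- tibble::tibble(time_s = numeric(), polarity = character(),
                          class = character(), facet_id = integer(),
                          source = character())
  tr <- add_spontaneous(empty, 0, 10, p, seed = 2)
  n_exc <- sum(tr$class == "excitatory")
  n_inh <- sum(tr$class == "inhibitory")
  expect_lt(abs(n_exc - 5000), 3 * sqrt(5000))
  expect_lt(abs(n_inh - 300), 4 * sqrt(300))
  expect_true(all(diff(tr$time_s) >= 0))
  expect_true(all(tr$source == "spontaneous"))

  # rate zero leaves the train unchanged
  p0 <- encoding_params(spont_exc_rate = 0, spont_inh_rate = 0)
  vis <- small_train()
  expect_identical(nrow(add_spontaneous(vis, -1, 0, p0, seed = 1)),
                   nrow(vis))
  expect_error(add_spontaneous(empty, 1, 0), "exceed")
})

test_that("white and black looms yield mirrored ON/OFF event totals", {
  pb <- suppressWarnings(
    encode_loom(small_loom_spec(), exc_budget = 4000, inh_budget = 400,
                seed = 5))
  pw <- suppressWarnings(
    encode_loom(loom_spec(80, "white", t_start = -0.5, t_end = 0,
                          extent_deg = 40, pixel_deg = 1),
                exc_budget = 4000, inh_budget = 400, seed = 5))
  tab_b <- table(pb$polarity[pb$class == "excitatory"])
  tab_w <- table(pw$polarity[pw$class == "excitatory"])
  # black loom drives the OFF channel, white the ON channel
  expect_gt(tab_b[["OFF"]] / sum(tab_b), 0.95)
  expect_gt(tab_w[["ON"]] / sum(tab_w), 0.95)
})

test_that("event trains round-trip through CSV", {
  tr <- small_train()
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(tr, path)
  tr2 <- read_events_csv(path)
  expect_equal(nrow(tr2), nrow(tr))
  expect_equal(tr2$time_s, tr$time_s, tolerance = 1e-12)
  expect_equal(tr2$class, tr$class)
})
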