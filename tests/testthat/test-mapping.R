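# Event -> compartment mapping schemes.

test_that("retinotopic mapping sends neighboring facets to neighboring
           field A compartments", {
  morph <- ref_morph()
  grid <- facet_grid_spec(extent_deg = 80)
  # two horizontally adjacent facets near the center
  ctr <- which(grid$centers$az_deg == 1 & grid$centers$el_deg == 1)
  nbr <- which(grid$centers$az_deg == 3 & grid$centers$el_deg == 1)
  tr <- tibble::tibble(time_s = c(0.1, 0.2), polarity = "OFF",
                       class = "excitatory",
                       facet_id = c(ctr, nbr), source = "visual")
  m <- map_events(tr, morph, "retinotopic_A", grid = grid)
  co <- morph$compartments
  expect_true(all(co$region[m$comp_id] == "A"))
  ag <- morph$a_grid
  pos <- ag[match(m$comp_id, ag$comp_id), ]
  # same or adjacent grid columns, same row
  expect_lte(abs(diff(pos$col)), 1)
  expect_equal(pos$row[1], pos$row[2])
})

test_that("random field C mapping conserves events and is reproducible", {
  morph <- ref_morph()
  tr <- small_train()
  m1 <- map_events(tr, morph, "random_C", seed = 4)
  m2 <- map_events(tr, morph, "random_C", seed = 4)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), nrow(tr))
  co <- morph$compartments
  exc <- m1$class == "excitatory" & m1$source != "spontaneous"
  expect_true(all(co$region[m1$comp_id[exc]] == "C"))
  # inhibition (OFF pathway) goes to field C
  inh <- m1$class == "inhibitory"
  expect_true(all(co$region[m1$comp_id[inh]] == "C"))
})

test_that("removal fraction drops or scales the mapped events", {
  morph <- ref_morph()
  tr <- small_train()
  n_exc <- sum(tr$class == "excitatory")
  mr <- map_events(tr, morph, "random_C", removal_fraction = 0.6,
                   removal_method = "remove", seed = 1)
  expect_equal(sum(mr$class == "excitatory"), round(0.4 * n_exc))
  ms <- map_events(tr, morph, "random_C", removal_fraction = 0.6,
                   removal_method = "scale", seed = 1)
  expect_equal(nrow(ms), nrow(tr))
  expect_true(all(ms$g_scale[ms$class == "excitatory"] == 0.4))
  expect_true(all(ms$g_scale > 0 & ms$g_scale <= 1))
})

test_that("split mapping at f = 0 reduces to the retinotopic mapping", {
  morph <- ref_morph()
  tr <- small_train()
  m0 <- map_events(tr, morph, "split", split_fraction = 0,
                   removal_fraction = 0.6, seed = 7)
  mr <- map_events(tr, morph, "retinotopic_A", seed = 7)
  exc <- m0$class == "excitatory"
  expect_equal(m0$comp_id[exc], mr$comp_id[mr$class == "excitatory"])
  expect_error(map_events(tr, morph, "split", split_fraction = 1.5),
               "split_fraction")
})

test_that("split mapping moves matched shares of events between fields", {
  morph <- ref_morph()
  tr <- small_train(6000, 600)
  co <- morph$compartments
  m <- map_events(tr, morph, "split", split_fraction = 0.5,
                  removal_fraction = 0.6, seed = 8)
  exc_reg <- co$region[m$comp_id[m$class == "excitatory"]]
  inh_reg <- co$region[m$comp_id[m$class == "inhibitory"]]
  # about half the excitation moved to C, 60% of it then removed:
  # C share of surviving excitation ~ 0.2 / 0.7
  expect_equal(mean(exc_reg == "C"), 0.2 / 0.7, tolerance = 0.15)
  # about half the inhibition relocated to field B
  expect_equal(mean(inh_reg == "B"), 0.5, tolerance = 0.15)
  # with move_inhibition = FALSE inhibition stays in field C
  m2 <- map_events(tr, morph, "split", split_fraction = 0.5,
                   removal_fraction = 0.6, move_inhibition = FALSE,
                   seed = 8)
  expect_true(all(co$region[m2$comp_id[m2$class == "inhibitory"]] == "C"))
})

test_that("clustered mapping recruits compartments from the center out", {
  morph <- ref_morph()
  spec <- loom_spec(80, "black", t_start = -1, t_end = 0)
  tr <- gen_reference_eventset(4000, 0, duration_s = 1,
                               temporal_profile = "loom_like", seed = 3)
  m <- map_events(tr, morph, "clustered_C", loom = spec, seed = 3)
  co <- morph$compartments
  expect_true(all(co$region[m$comp_id] == "C"))
  # mean distance from the cluster center grows with time
  c_ids <- co$id[co$region == "C"]
  ctr <- c_ids[which.min((co$x_um[c_ids] - mean(co$x_um[c_ids]))^2 +
                           (co$y_um[c_ids] - mean(co$y_um[c_ids]))^2)]
  d <- sqrt((co$x_um[m$comp_id] - co$x_um[ctr])^2 +
              (co$y_um[m$comp_id] - co$y_um[ctr])^2)
  early <- d[m$time_s < quantile(m$time_s, 0.2)]
  late <- d[m$time_s > quantile(m$time_s, 0.8)]
  expect_lt(mean(early), mean(late))
  expect_error(map_events(tr, morph, "clustered_C", loom = spec,
                          cluster_center = 1), "center")
  expect_error(map_events(tr, morph, "clustered_C"), "loom")
})

test_that("polarity mapping routes OFF to field A and ON to field C", {
  morph <- ref_morph()
  grid <- facet_grid_spec(extent_deg = 80)
  tr <- tibble::tibble(
    time_s = seq(0.01, 0.4, length.out = 400),
    polarity = rep(c("ON", "OFF"), 200),
    class = "excitatory",
    facet_id = sample.int(nrow(grid$centers), 400, replace = TRUE),
    source = "visual")
  attr(tr, "grid") <- grid
  m <- map_events(tr, morph, "polarity", seed = 2)
  co <- morph$compartments
  expect_true(all(co$region[m$comp_id[m$polarity == "OFF"]] == "A"))
  expect_true(all(co$region[m$comp_id[m$polarity == "ON"]] == "C"))
})
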