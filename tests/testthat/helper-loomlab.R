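# Shared fixtures, built in code and cached across test files. The
# reference loom (l/|v| = 80 ms, black, coherent) and the tuned model are
# expensive, so they are constructed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

ref_loom_spec <- function() {
  loom_spec(80, "black", t_start = -2, t_end = 0, hold_s = 0.2)
}

# Encoded reference train (calibrated 80,000 / 7,000 budgets +
# spontaneous background). The loom outgrowing the screen near collision
# is expected; the clipping warning is part of normal rendering.
ref_train <- function() {
  cached("ref_train", suppressWarnings(
    encode_loom(ref_loom_spec(), spontaneous = TRUE, seed = 1)
  ))
}

ref_morph <- function() cached("ref_morph", build_morphology())
ref_channels <- function() cached("ref_channels", default_channelset())

# Calibrated drive of the reference loom (for encoder tests that need
# the drive but not the events).
ref_drive <- function() {
  cached("ref_drive", suppressWarnings({
    movie <- render_stimulus(ref_loom_spec())
    transduce_facets(sample_facets(movie))
  }))
}

ref_params <- function() {
  cached("ref_params", calibrate_event_gain(ref_drive()))
}

# A small, fast stimulus for unit tests (0.5 s, 40 deg screen).
small_loom_spec <- function(...) {
  loom_spec(80, "black", t_start = -0.5, t_end = 0, extent_deg = 40,
            pixel_deg = 1, ...)
}

# A fast synthetic train for mapping/simulation unit tests.
small_train <- function(n_exc = 2000, n_inh = 200, seed = 11) {
  cached(paste0("small_train_", n_exc, "_", seed), {
    gen_reference_eventset(n_exc, n_inh, duration_s = 1,
                           grid = facet_grid_spec(extent_deg = 80),
                           seed = seed)
  })
}

# Purely passive channel set over the standard regions (used by solver
# oracle tests).
passive_channelset <- function(g_pas = 0.25, e_pas = -65) {
  regions <- c("axon", "SIZ", "trunk", "A", "B", "C")
  dens <- matrix(0, length(regions), 7,
                 dimnames = list(regions,
                                 c("na", "kdr", "hcn", "kd", "km",
                                   "cat", "kca")))
  pas <- lapply(regions, function(r) list(g_pas = g_pas, e_pas = e_pas))
  names(pas) <- regions
  structure(list(dens = dens, pas = pas,
                 revs = c(ena = 65, ek = -80, eh = -35, eca = 120),
                 kinetics = c(na_m_vh = -48, na_m_k = 5.5,
                              na_h_vh = -54, kdr_vh = -45)),
            class = "channelset")
}

# Hand-built unbranched passive cable posing as an lgmd_morphology (all
# compartments labelled SIZ so region lookup works); used for analytic
# cable oracles.
cable_morph <- function(n = 25, length_um = 20, diam_um = 5,
                        ra = 60, cm = 0.8) {
  comp <- tibble::tibble(
    id = seq_len(n),
    parent_id = c(NA_integer_, seq_len(n - 1)),
    region = "SIZ",
    length_um = length_um, diam_um = diam_um,
    ra_ohm_cm = ra, ra_scale = 1, cm_uf_cm2 = cm,
    x_um = 0, y_um = (seq_len(n) - 1) * length_um, z_um = 0
  )
  structure(list(compartments = comp,
                 a_grid = tibble::tibble(comp_id = integer(),
                                         row = integer(),
                                         col = integer()),
                 c_root = NA_integer_, siz_comp = 1L, axon_comp = 1L,
                 config = NULL),
            class = "lgmd_morphology")
}
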