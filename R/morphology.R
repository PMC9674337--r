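# Reduced LGMD morphology: a branched compartment tree with region labels
# (A, B, C, trunk, SIZ, axon). The full reconstruction has 2518
# compartments (1352 in field A, 455 in field C); this reduced stand-in
# mirrors the regional architecture and electrotonic ordering -- field C
# proximal to the spike initiation zone, field A distal beyond the trunk --
# at a size tractable for desk-scale simulation sweeps.

#' Reduced-morphology configuration
#'
#' @param n_a_cols,n_a_rows Field A grid (default 12 x 10 = 120
#'   compartments laid out isomorphic to the facet grid).
#' @param n_c Field C compartments (positions on a 30 um-spaced sheet so
#'   inter-compartment distances are defined for clustered mapping).
#' @param n_b,n_trunk,n_siz,n_axon Compartment counts for the remaining
#'   regions.
#' @param dims Named list of `c(length_um, diam_um)` per region.
#' @param ra_ohm_cm Axial resistivity, Ohm cm.
#' @param cm_uf_cm2 Specific membrane capacitance, uF/cm^2.
#' @param c_link_ra_scale Axial-resistance scale of the segment linking
#'   field C to the trunk. The default was tuned (scripted sweep, see the
#'   methods vignette) so that relocating all loom excitation to random
#'   field C compartments and removing 60% of it reproduces the
#'   all-field-A spike count, the calibration the passive-attenuation
#'   account prescribes.
#' @return A `morph_config` list for [build_morphology()].
#' @export
morph_config <- function(n_a_cols = 12, n_a_rows = 10, n_c = 30, n_b = 10,
                         n_trunk = 4, n_siz = 5, n_axon = 5,
                         dims = list(axon = c(60, 8), SIZ = c(40, 15),
                                     trunk = c(75, 20), B = c(60, 6),
                                     C = c(80, 8), C_link = c(80, 10),
                                     A = c(100, 10)),
                         ra_ohm_cm = 60, cm_uf_cm2 = 0.8,
                         c_link_ra_scale = 3.25) {
  stopifnot(n_a_cols >= 1, n_a_rows >= 1, n_c >= 2, n_trunk >= 2,
            n_siz >= 1, n_axon >= 1, c_link_ra_scale > 0)
  structure(as.list(environment()), class = "morph_config")
}

#' Build the reduced LGMD morphology
#'
#' Constructs a connected compartment tree in Hines order (every parent id
#' precedes its children): axon -> SIZ -> trunk, with field B and field C
#' branching off the trunk base (electrotonically close to the SIZ) and
#' field A as a grid of columns beyond the full trunk (electrotonically
#' distal). Field A compartments carry `(col, row)` grid coordinates
#' isomorphic to the facet grid; field C compartments carry positions in
#' um so inter-compartment distances are defined.
#'
#' @param config A [morph_config()].
#' @return An `lgmd_morphology`: a tibble of compartments plus lookup
#'   indices.
#' @examples
#' morph <- build_morphology()
#' dplyr::count(morph$compartments, region)
#' @export
build_morphology <- function(config = morph_config()) {
  cf <- config
  rows <- list()
  add <- function(region, parent, length_um, diam_um, x, y, z,
                  ra_scale = 1) {
    id <- length(rows) + 1L
    rows[[id]] <<- tibble(
      id = id, parent_id = parent, region = region,
      length_um = length_um, diam_um = diam_um,
      ra_ohm_cm = cf$ra_ohm_cm, ra_scale = ra_scale,
      cm_uf_cm2 = cf$cm_uf_cm2, x_um = x, y_um = y, z_um = z)
    id
  }
  dim_of <- function(r) cf$dims[[r]]
  # axon chain (root first)
  prev <- NA_integer_
  for (i in seq_len(cf$n_axon)) {
    d <- dim_of("axon")
    prev <- add("axon", prev, d[1], d[2], 0, -(cf$n_axon - i + 1) * d[1] -
                  cf$n_siz * dim_of("SIZ")[1], 0)
  }
  for (i in seq_len(cf$n_siz)) {
    d <- dim_of("SIZ")
    prev <- add("SIZ", prev, d[1], d[2], 0, -(cf$n_siz - i) * d[1], 0)
  }
  siz_top <- prev
  trunk_ids <- integer(cf$n_trunk)
  for (i in seq_len(cf$n_trunk)) {
    d <- dim_of("trunk")
    prev <- add("trunk", prev, d[1], d[2], 0, i * d[1], 0)
    trunk_ids[i] <- prev
  }
  trunk_top <- prev
  # field B: chain off the trunk base
  prev_b <- trunk_ids[1]
  for (i in seq_len(cf$n_b)) {
    d <- dim_of("B")
    prev_b <- add("B", prev_b, d[1], d[2], -60 - i * d[1],
                  dim_of("trunk")[1], 0)
  }
  # field C: link compartment off the second trunk compartment, then two
  # branch chains across a positioned sheet
  dl <- dim_of("C_link")
  c_root <- add("C", trunk_ids[min(2, cf$n_trunk)], dl[1], dl[2],
                80, 2 * dim_of("trunk")[1], 0,
                ra_scale = cf$c_link_ra_scale)
  n_rest <- cf$n_c - 1L
  n_br1 <- ceiling(n_rest / 2)
  d <- dim_of("C")
  c_pos <- function(k) { # k = 1..n_rest on a 6-wide sheet, 30 um spacing
    c(x = 110 + ((k - 1) %% 6) * 30,
      y = 2 * dim_of("trunk")[1] + ((k - 1) %/% 6) * 30)
  }
  prev_c <- c_root
  for (k in seq_len(n_br1)) {
    p <- c_pos(k)
    prev_c <- add("C", prev_c, d[1], d[2], p["x"], p["y"], 0)
  }
  prev_c <- c_root
  for (k in (n_br1 + 1):n_rest) {
    p <- c_pos(k)
    prev_c <- add("C", prev_c, d[1], d[2], p["x"], p["y"], 30)
  }
  # field A: column bases chained along a backbone from the trunk top,
  # each column a chain of rows
  d <- dim_of("A")
  a_ids <- matrix(NA_integer_, cf$n_a_rows, cf$n_a_cols)
  base_prev <- trunk_top
  y0 <- cf$n_trunk * dim_of("trunk")[1] + 60
  for (cc in seq_len(cf$n_a_cols)) {
    for (rr in seq_len(cf$n_a_rows)) {
      par <- if (rr == 1) base_prev else a_ids[rr - 1, cc]
      a_ids[rr, cc] <- add("A", par, d[1], d[2],
                           (cc - (cf$n_a_cols + 1) / 2) * 40,
                           y0 + (rr - 1) * d[1], 0)
      if (rr == 1) base_prev <- a_ids[1, cc]
    }
  }
  comp <- dplyr::bind_rows(rows)
  if (any(comp$parent_id >= comp$id, na.rm = TRUE)) {
    abort("internal error: morphology not in Hines order")
  }
  structure(list(
    compartments = comp,
    a_grid = tibble(comp_id = as.vector(a_ids),
                    row = rep(seq_len(cf$n_a_rows), cf$n_a_cols),
                    col = rep(seq_len(cf$n_a_cols), each = cf$n_a_rows)),
    c_root = c_root,
    siz_comp = siz_top,
    axon_comp = 1L,
    config = cf
  ), class = "lgmd_morphology")
}

#' @method print lgmd_morphology
#' @export
print.lgmd_morphology <- function(x, ...) {
  tab <- table(x$compartments$region)
  cat("<lgmd_morphology>", nrow(x$compartments), "compartments:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Scale the axial resistance of the field C connecting segment
#'
#' Multiplies the axial resistance of the dendritic segment connecting
#' field C to the main neurite by `factor`, leaving the properties of the
#' branches within field C untouched. Raising the factor electrotonically
#' distances field C from the spike initiation zone.
#'
#' @param morph An `lgmd_morphology`.
#' @param factor Positive scale factor (1 = identity).
#' @param region_link Which link to scale; only `"C"` is defined.
#' @return The modified morphology.
#' @export
scale_axial_resistance <- function(morph, factor, region_link = "C") {
  stopifnot(inherits(morph, "lgmd_morphology"), factor > 0)
  if (!identical(region_link, "C")) abort("unknown region link")
  i <- morph$c_root
  morph$compartments$ra_scale[i] <- morph$compartments$ra_scale[i] * factor
  morph
}

#' Region-specific channel densities and reversal potentials
#'
#' Hodgkin-Huxley-style channel complement of the reduced model: fast Na+
#' and delayed-rectifier K+ at the SIZ/axon, HCN and inactivating K+ (KD)
#' in field A dendrites (HCN is absent from field C), M-type K+ in the
#' axon, and low-threshold Ca2+ plus Ca2+-dependent K+ near the SIZ.
#' Densities are mS/cm^2. Defaults were tuned (scripted sweep) so the
#' resting potential sits near -65 mV and the reference black loom drives
#' a firing profile peaking near projected collision.
#'
#' @param file Optional YAML file overriding the defaults; the package
#'   ships its tuned set in `inst/extdata/channelset-default.yaml`.
#' @return A `channelset` list: `dens` (region x channel densities),
#'   `pas` (leak per region), `revs` (reversal potentials, mV).
#' @export
default_channelset <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "channelset-default.yaml",
                        package = "loomlab")
  }
  raw <- yaml::read_yaml(file)
  dens <- do.call(rbind, lapply(raw$densities, function(r) unlist(r)))
  stopifnot(all(dens >= 0), dens["C", "hcn"] == 0)
  kin_default <- c(na_m_vh = -38, na_m_k = 5.5, na_h_vh = -48,
                   kdr_vh = -37)
  kin <- kin_default
  if (!is.null(raw$kinetics)) kin[names(raw$kinetics)] <- unlist(raw$kinetics)
  structure(list(
    dens = dens,
    pas = raw$passive,
    revs = unlist(raw$reversals),
    kinetics = kin
  ), class = "channelset")
}

# Expand a channelset to per-compartment vectors/matrix for the solver.
.channels_per_comp <- function(morph, channels) {
  reg <- morph$compartments$region
  dens <- channels$dens[reg, c("na", "kdr", "hcn", "kd", "km", "cat",
                               "kca"), drop = FALSE]
  g_pas <- vapply(reg, function(r) channels$pas[[r]]$g_pas, numeric(1))
  e_pas <- vapply(reg, function(r) channels$pas[[r]]$e_pas, numeric(1))
  kin <- channels$kinetics %||%
    c(na_m_vh = -38, na_m_k = 5.5, na_h_vh = -48, kdr_vh = -37)
  list(dens = unname(dens), g_pas = unname(g_pas), e_pas = unname(e_pas),
       revs = channels$revs[c("ena", "ek", "eh", "eca")],
       kin = unname(kin))
}

#' Write / read a morphology as SWC-style text
#'
#' Standard seven-column SWC (`id type x y z radius parent`) with an
#' eighth column carrying the region label. `type` follows SWC
#' conventions loosely (2 = axon, 3 = dendrite, 5 = custom for SIZ/trunk).
#'
#' @param morph An `lgmd_morphology`.
#' @param path File path.
#' @return `write_swc` returns `path` invisibly; `read_swc` returns the
#'   compartment tibble (geometry and topology only -- electrical
#'   parameters and grid metadata are not stored in SWC).
#' @export
write_swc <- function(morph, path) {
  co <- morph$compartments
  type <- dplyr::case_match(co$region, "axon" ~ 2L, "A" ~ 3L, "B" ~ 3L,
                            "C" ~ 3L, .default = 5L)
  lines <- sprintf("%d %d %.2f %.2f %.2f %.3f %d %s",
                   co$id, type, co$x_um, co$y_um, co$z_um, co$diam_um / 2,
                   dplyr::coalesce(co$parent_id, -1L), co$region)
  writeLines(c("# id type x y z radius parent region", lines), path)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x_um", "y_um",
                                         "z_um", "radius", "parent_id",
                                         "region"))
  tibble(
    id = as.integer(raw$id),
    parent_id = ifelse(raw$parent_id < 0, NA_integer_,
                       as.integer(raw$parent_id)),
    region = as.character(raw$region),
    diam_um = 2 * raw$radius,
    x_um = raw$x_um, y_um = raw$y_um, z_um = raw$z_um
  )
}

#' Input resistance at a compartment from a current step
#'
#' Runs a passive (or full) simulation with a small hyperpolarizing
#' current step and reports `abs(dV_ss / I)`.
#'
#' @param morph An `lgmd_morphology`.
#' @param channels A `channelset`; default passive-only measurement uses
#'   the tuned set.
#' @param comp Compartment id at which to inject and measure (default the
#'   SIZ).
#' @param i_na Step amplitude, nA.
#' @param t_step_ms Step duration, ms (long enough to reach steady state).
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(morph, channels = default_channelset(),
                             comp = morph$siz_comp, i_na = -1,
                             t_step_ms = 200) {
  res <- simulate_lgmd(morph, channels, events = NULL,
                       t_start = 0, t_end = (2 * t_step_ms + 50) / 1000,
                       record = comp, inj = list(comp = comp, nA = i_na,
                                                 from_ms = 25,
                                                 to_ms = 25 + 2 * t_step_ms))
  v <- res$vm[, 1]
  t <- res$t_ms
  v0 <- mean(v[t < 20])
  vss <- mean(v[t > 25 + 1.5 * t_step_ms & t < 25 + 2 * t_step_ms])
  abs((vss - v0) / i_na) # mV / nA = MOhm
}
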