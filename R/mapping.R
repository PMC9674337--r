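# Event -> compartment mapping schemes. A SynapseMap is the event train
# tibble augmented with `comp_id` and `g_scale` columns; removed events
# are dropped, so `nrow()` is the number of delivered synaptic events.

#' Map synaptic events onto morphology compartments
#'
#' Assigns every event in a train to a compartment under one of the
#' dendritic mapping schemes:
#'
#' * `"retinotopic_A"` -- each visually driven excitatory event goes to
#'   the field A grid compartment isomorphic to its facet position
#'   (neighbouring facets, neighbouring compartments).
#' * `"random_C"` -- every excitatory event goes to a pseudo-randomly
#'   selected field C compartment; a `removal_fraction` of them can be
#'   removed (or conductance-scaled, see `removal_method`) without
#'   touching inhibition.
#' * `"clustered_C"` -- excitatory events go to field C, but eligibility
#'   spreads from a central compartment as the loom expands: a
#'   compartment at distance d from the center is recruited with weight
#'   \eqn{1/(1 + \exp((d - d_{front}(t))/s))}, the front
#'   \eqn{d_{front}(t)} growing with the stimulus half-angle and
#'   steepness s = 80 um by default. `cluster_width_scale < 1` narrows
#'   the clustering (front and steepness shrink together).
#' * `"split"` -- a pseudo-random fraction `split_fraction` of excitatory
#'   events is moved from the retinotopic field A mapping to random field
#'   C locations, with `removal_fraction` (default 60%) of the moved
#'   events removed or scaled; the same percentage of inhibitory events
#'   is moved from field C to field B.
#' * `"polarity"` -- the checkered-stimulus rule: OFF-facet events map
#'   retinotopically to field A, ON-facet events map randomly to field C
#'   (with `removal_fraction` applied to the field C share).
#'
#' Inhibitory events go to random field C compartments (OFF pathway) or
#' field B (ON pathway); spontaneous excitatory events scatter over field
#' A. Scale factors lie in (0, 1].
#'
#' @param train A `SynapticEventTrain` tibble (see [generate_events()]).
#' @param morph An `lgmd_morphology`.
#' @param mode Mapping scheme, see above.
#' @param grid The [facet_grid_spec()] the train was encoded on; defaults
#'   to the train's `grid` attribute.
#' @param split_fraction Fraction moved to field C for `"split"`.
#' @param removal_fraction Fraction of field C-relocated events removed
#'   (or conductance-scaled).
#' @param removal_method `"remove"` drops events, `"scale"` multiplies
#'   their conductance by `1 - removal_fraction`; both reductions have
#'   the same effect on output firing.
#' @param move_inhibition For `"split"`: move the matching percentage of
#'   inhibitory events from field C to field B (`TRUE`, the stated
#'   protocol)? With `FALSE` inhibition keeps its natural field C
#'   location for every split fraction, anchoring the curve's endpoints
#'   to the all-field-A and all-field-C reference simulations; see the
#'   methods vignette for when each applies in a reduced morphology.
#' @param cluster_center Field C compartment id serving as the loom
#'   response center (defaults to the field C root's central neighbour).
#' @param cluster_r_max Maximal recruitment radius, um.
#' @param cluster_steepness Sigmoid steepness, um.
#' @param cluster_width_scale Common scale on radius and steepness.
#' @param loom The [loom_spec()] behind the train (needed by
#'   `"clustered_C"` for the angular-size time course).
#' @param seed RNG seed.
#' @return The train tibble with `comp_id` and `g_scale` columns.
#' @export
map_events <- function(train, morph,
                       mode = c("retinotopic_A", "random_C", "clustered_C",
                                "split", "polarity"),
                       grid = attr(train, "grid"),
                       split_fraction = 0.5, removal_fraction = 0,
                       removal_method = c("remove", "scale"),
                       move_inhibition = TRUE,
                       cluster_center = NULL, cluster_r_max = 150,
                       cluster_steepness = 80, cluster_width_scale = 1,
                       loom = NULL, seed = 1L) {
  mode <- match.arg(mode)
  removal_method <- match.arg(removal_method)
  stopifnot(inherits(morph, "lgmd_morphology"))
  if (mode == "split" &&
      (split_fraction < 0 || split_fraction > 1)) {
    abort("split_fraction must lie in [0, 1]")
  }
  stopifnot(removal_fraction >= 0, removal_fraction <= 1)
  co <- morph$compartments
  a_ids <- morph$a_grid
  c_ids <- co$id[co$region == "C"]
  b_ids <- co$id[co$region == "B"]

  retino <- function(df) {
    stopifnot(!is.null(grid))
    ext <- grid$extent_deg
    ncol_a <- max(a_ids$col); nrow_a <- max(a_ids$row)
    fc <- grid$centers[df$facet_id, ]
    col <- pmin(pmax(ceiling((fc$az_deg + ext / 2) / ext * ncol_a), 1),
                ncol_a)
    row <- pmin(pmax(ceiling((fc$el_deg + ext / 2) / ext * nrow_a), 1),
                nrow_a)
    lut <- matrix(0L, nrow_a, ncol_a)
    lut[cbind(a_ids$row, a_ids$col)] <- a_ids$comp_id
    lut[cbind(row, col)]
  }

  .local_seed(seed, {
    train$comp_id <- NA_integer_
    train$g_scale <- 1
    exc <- which(train$class == "excitatory" &
                   train$source != "spontaneous")
    inh <- which(train$class == "inhibitory")
    spont_e <- which(train$class == "excitatory" &
                       train$source == "spontaneous")

    # inhibition: OFF pathway -> field C, ON pathway -> field B
    if (length(inh)) {
      off_i <- inh[train$polarity[inh] == "OFF"]
      on_i <- inh[train$polarity[inh] == "ON"]
      train$comp_id[off_i] <- sample(c_ids, length(off_i), replace = TRUE)
      train$comp_id[on_i] <- sample(b_ids, length(on_i), replace = TRUE)
    }
    if (length(spont_e)) {
      train$comp_id[spont_e] <- sample(a_ids$comp_id, length(spont_e),
                                       replace = TRUE)
    }

    apply_removal <- function(train, idx) {
      if (removal_fraction == 0 || !length(idx)) return(train)
      if (removal_method == "scale") {
        train$g_scale[idx] <- train$g_scale[idx] * (1 - removal_fraction)
        train
      } else {
        drop <- sample(idx, round(removal_fraction * length(idx)))
        train$g_scale[drop] <- NA_real_ # marked, dropped below
        train
      }
    }

    if (length(exc)) {
      if (mode == "retinotopic_A") {
        train$comp_id[exc] <- retino(train[exc, ])
      } else if (mode == "random_C") {
        train$comp_id[exc] <- sample(c_ids, length(exc), replace = TRUE)
        train <- apply_removal(train, exc)
      } else if (mode == "clustered_C") {
        if (is.null(loom)) abort("clustered_C mapping needs the loom spec")
        center <- cluster_center %||% c_ids[which.min(
          (co$x_um[c_ids] - mean(co$x_um[c_ids]))^2 +
            (co$y_um[c_ids] - mean(co$y_um[c_ids]))^2)]
        if (!(center %in% c_ids)) abort("cluster center not in field C")
        dists <- sqrt((co$x_um[c_ids] - co$x_um[center])^2 +
                        (co$y_um[c_ids] - co$y_um[center])^2 +
                        (co$z_um[c_ids] - co$z_um[center])^2)
        th0 <- loom_half_angle(loom$t_start, loom$l_over_v)
        prog <- (pmin(.half_angle_clamped(train$time_s[exc],
                                          loom$l_over_v), 90) - th0) /
          (90 - th0)
        front <- cluster_width_scale * cluster_r_max * pmax(prog, 0)
        s <- cluster_width_scale * cluster_steepness
        train$comp_id[exc] <- vapply(front, function(fr) {
          w <- 1 / (1 + exp((dists - fr) / s))
          sample(c_ids, 1L, prob = w)
        }, integer(1))
        train <- apply_removal(train, exc)
      } else if (mode == "split") {
        moved <- exc[runif(length(exc)) < split_fraction]
        stay <- setdiff(exc, moved)
        if (length(stay)) train$comp_id[stay] <- retino(train[stay, ])
        if (length(moved)) {
          train$comp_id[moved] <- sample(c_ids, length(moved),
                                         replace = TRUE)
          train <- apply_removal(train, moved)
        }
        # matching percentage of inhibition moved from field C to field B
        if (move_inhibition) {
          inh_c <- inh[!is.na(train$comp_id[inh]) &
                         train$comp_id[inh] %in% c_ids]
          move_i <- inh_c[runif(length(inh_c)) < split_fraction]
          if (length(move_i)) {
            train$comp_id[move_i] <- sample(b_ids, length(move_i),
                                            replace = TRUE)
          }
        }
      } else if (mode == "polarity") {
        off_e <- exc[train$polarity[exc] == "OFF"]
        on_e <- exc[train$polarity[exc] == "ON"]
        if (length(off_e)) train$comp_id[off_e] <- retino(train[off_e, ])
        if (length(on_e)) {
          train$comp_id[on_e] <- sample(c_ids, length(on_e),
                                        replace = TRUE)
          train <- apply_removal(train, on_e)
        }
      }
    }
    out <- train[!is.na(train$g_scale), , drop = FALSE]
    stopifnot(all(out$g_scale > 0), all(out$g_scale <= 1))
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
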