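#' Charge transferred by a single alpha-synapse EPSP
#'
#' The alpha conductance \eqn{g(t) = g_{max} (t/\tau) e^{1 - t/\tau}} has
#' integral \eqn{\int g\,dt = g_{max}\,\tau\,e}. At a fixed membrane
#' potential the synaptic charge is therefore
#' \eqn{Q = g_{max}\,\tau\,e\,(E_{rev} - V_m)} — the closed form evaluated
#' here. The default membrane potential of −50 mV is a loom-representative
#' depolarized value: the potential at which LGMD dendrites sit, on
#' average, while a looming stimulus drives them.
#'
#' @param g_max Maximal synaptic conductance, nS.
#' @param tau Alpha-function time constant, ms.
#' @param e_rev Synaptic reversal potential, mV.
#' @param v_m Membrane potential at which the charge is evaluated, mV.
#' @return Charge in pC. Values \eqn{\le 0} (when `e_rev <= v_m`) are
#'   returned with a warning since they carry no excitatory charge.
#' @examples
#' epsp_charge() # 0.34 pC for the default excitatory synapse at -50 mV
#' @export
epsp_charge <- function(g_max = 14, tau = 0.15, e_rev = 10, v_m = -50) {
  stopifnot(g_max >= 0, tau > 0)
  if (e_rev <= v_m && g_max > 0) {
    warn("e_rev <= v_m: synapse carries no excitatory charge")
  }
  # nS * ms * mV = 1e-9 S * 1e-3 s * 1e-3 V = 1e-15 C = 1e-3 pC
  g_max * tau * exp(1) * (e_rev - v_m) * 1e-3
}

#' Total charge and ion count for a loom's worth of EPSPs
#'
#' Multiplies the per-EPSP charge by the event count and converts the total
#' charge to an ion count under the monovalent assumption (one elementary
#' charge per ion). Dividing coulombs by the elementary charge is
#' arithmetically identical to multiplying by Avogadro's number and dividing
#' by Faraday's constant.
#'
#' @param n_events Number of excitatory synaptic events.
#' @param q_epsp Charge per event, pC.
#' @return A tibble with `total_charge_nC` and `ion_count`.
#' @examples
#' loom_ion_budget(80000, epsp_charge()) # ~27 nC, ~1.7e11 ions
#' @export
loom_ion_budget <- function(n_events, q_epsp) {
  stopifnot(n_events >= 0, q_epsp >= 0)
  total_pC <- n_events * q_epsp
  tibble(
    total_charge_nC = total_pC * 1e-3,
    ion_count = total_pC * 1e-12 / .E_CHARGE
  )
}

#' ATP cost of pumping synaptic ions back out
#'
#' The Na+/K+ pump expels three Na+ ions per ATP molecule; the Na/Ca
#' exchanger removes one Ca2+ per ATP, and each Ca2+ carries two elementary
#' charges. If a fraction `ca_charge_fraction` (x) of the total synaptic
#' charge Q is carried by Ca2+, the ATP cost is
#' \deqn{ATP = (Q/e)\,[(1-x)/3 + x/2].}
#'
#' @param ion_count Total monovalent-equivalent ion count, i.e. Q divided by
#'   the elementary charge.
#' @param ca_charge_fraction Fraction of charge carried by Ca2+, in
#'   \[0, 1\]. See [calibrate_ca_fraction()] for the package default.
#' @return ATP molecules (numeric scalar).
#' @examples
#' atp_from_ions(1.7e11, 0)    # Na+-only cost
#' @export
atp_from_ions <- function(ion_count, ca_charge_fraction = 0) {
  stopifnot(ion_count >= 0,
            ca_charge_fraction >= 0, ca_charge_fraction <= 1)
  x <- ca_charge_fraction
  ion_count * ((1 - x) / 3 + x / 2)
}

#' Calibrate the Ca2+ charge fraction against the count-based estimate
#'
#' The Ca2+ share of the excitatory synaptic current is not directly
#' measurable here; this helper back-computes the fraction x at which the
#' ion-pump route [atp_from_ions()] reproduces a target total ATP cost
#' (by default the count-based estimate
#' `atp_from_counts(70000, 26200, 32)`). This is a calibration, not a
#' measurement of pump stoichiometry.
#'
#' @param ion_count Total ion count from [loom_ion_budget()].
#' @param target_atp ATP total the pump route should reproduce.
#' @return Calibrated `ca_charge_fraction` in \[0, 1\].
#' @export
calibrate_ca_fraction <- function(ion_count,
                                  target_atp = atp_from_counts(70000, 26200, 32)) {
  stopifnot(ion_count > 0, target_atp > 0)
  # ATP/ion = (1-x)/3 + x/2 = 1/3 + x/6  =>  x = 6 (ATP/ion - 1/3)
  x <- 6 * (target_atp / ion_count - 1 / 3)
  if (x < 0 || x > 1) {
    abort("target ATP outside the range attainable by Na+/Ca2+ stoichiometry")
  }
  x
}

#' Count-based total energy cost of synaptic transmission
#'
#' Independent cross-check on the charge-based ATP estimate:
#' \eqn{E_{tot} = E_{syn} N_{syn} N_{spk}}, the literature cost per synapse
#' per presynaptic spike times the number of synapses times the number of
#' presynaptic spikes per loom.
#'
#' @param e_syn ATP molecules per synapse per spike (literature estimate
#'   70,000 for excitatory transmission).
#' @param n_syn Number of synapses (131,000 field A synapses x the ~20%
#'   of the eye a loom covers gives 26,200).
#' @param n_spk Presynaptic spikes per loom.
#' @return Total ATP molecules.
#' @examples
#' atp_from_counts(70000, 26200, 32) # ~6e10
#' @export
atp_from_counts <- function(e_syn = 70000, n_syn = 26200, n_spk = 32) {
  stopifnot(e_syn >= 0, n_syn >= 0, n_spk >= 0)
  e_syn * n_syn * n_spk
}

#' ATP savings from relocating excitation to field C
#'
#' Relocating a fraction `f` of the excitatory input to field C allows a
#' fraction `r` (default 60%) of the relocated events to be removed at
#' unchanged spike output, because field C sits electrotonically closer to
#' the spike initiation zone. The saved ATP is `baseline_atp * f * r`.
#'
#' @param baseline_atp ATP cost with all excitation in field A.
#' @param fraction_moved_to_c Fraction of excitation relocated, \[0, 1\].
#' @param removal_fraction Fraction of relocated events removable, \[0, 1\].
#' @return ATP molecules saved.
#' @examples
#' energy_savings(6e10, 1)   # 3.6e10: all excitation relocated
#' energy_savings(6e10, 0.5) # half that for an even split
#' @export
energy_savings <- function(baseline_atp, fraction_moved_to_c,
                           removal_fraction = 0.6) {
  stopifnot(baseline_atp >= 0,
            fraction_moved_to_c >= 0, fraction_moved_to_c <= 1,
            removal_fraction >= 0, removal_fraction <= 1)
  baseline_atp * fraction_moved_to_c * removal_fraction
}

#' Mean excitatory current over a loom
#'
#' @param total_charge_nC Integrated excitatory synaptic charge, nC.
#' @param duration_s Loom duration, s.
#' @return Mean current in nA.
#' @export
mean_current <- function(total_charge_nC, duration_s) {
  stopifnot(total_charge_nC >= 0)
  if (duration_s <= 0) abort("duration must be positive")
  total_charge_nC / duration_s
}

#' Full ATP accounting for one loom
#'
#' Runs the whole energy chain: per-EPSP charge, total charge and ion count,
#' ATP by pump stoichiometry (Na+-only and at the calibrated Ca2+ fraction),
#' the independent count-based estimate, the relocation savings, and the
#' mean excitatory current.
#'
#' @param n_events Excitatory event count per loom.
#' @param g_max,tau,e_rev,v_m Alpha-synapse parameters, see [epsp_charge()].
#' @param ca_charge_fraction Ca2+ charge fraction; `NULL` (default)
#'   calibrates it with [calibrate_ca_fraction()].
#' @param e_syn,n_syn,n_spk Count-based estimate factors, see
#'   [atp_from_counts()].
#' @param duration_s Loom duration used for the mean-current figure.
#' @param total_charge_nC Optional measured charge (e.g. from
#'   [simulate_lgmd()]'s integrated synaptic current) overriding the
#'   analytic `n_events * q_epsp` product.
#' @return An object of class `energy_report`; see [tidy.energy_report()].
#' @examples
#' rep <- energy_report(80000)
#' glance(rep)
#' @export
energy_report <- function(n_events = 80000, g_max = 14, tau = 0.15,
                          e_rev = 10, v_m = -50,
                          ca_charge_fraction = NULL,
                          e_syn = 70000, n_syn = 26200, n_spk = 32,
                          duration_s = 5.4, total_charge_nC = NULL) {
  q <- epsp_charge(g_max, tau, e_rev, v_m)
  budget <- loom_ion_budget(n_events, q)
  if (!is.null(total_charge_nC)) {
    budget$total_charge_nC <- total_charge_nC
    budget$ion_count <- total_charge_nC * 1e-9 / .E_CHARGE
  }
  atp_counts <- atp_from_counts(e_syn, n_syn, n_spk)
  if (is.null(ca_charge_fraction)) {
    ca_charge_fraction <- calibrate_ca_fraction(budget$ion_count, atp_counts)
  }
  out <- list(
    q_epsp_pC = q,
    n_events = n_events,
    total_charge_nC = budget$total_charge_nC,
    ion_count = budget$ion_count,
    ca_charge_fraction = ca_charge_fraction,
    atp_na_only = atp_from_ions(budget$ion_count, 0),
    atp_pump = atp_from_ions(budget$ion_count, ca_charge_fraction),
    atp_counts_method = atp_counts,
    savings_all_c = NA_real_,
    savings_split = NA_real_,
    mean_current_nA = mean_current(budget$total_charge_nC, duration_s),
    duration_s = duration_s
  )
  out$savings_all_c <- energy_savings(out$atp_pump, 1)
  out$savings_split <- energy_savings(out$atp_pump, 0.5)
  structure(out, class = "energy_report")
}

#' @method print energy_report
#' @export
print.energy_report <- function(x, ...) {
  cat("<energy_report>\n")
  cat(sprintf("  per-EPSP charge     %.3f pC\n", x$q_epsp_pC))
  cat(sprintf("  events per loom     %s\n", format(x$n_events, big.mark = ",")))
  cat(sprintf("  total charge        %.1f nC (%.3g ions)\n",
              x$total_charge_nC, x$ion_count))
  cat(sprintf("  ATP, Na+-only       %.3g\n", x$atp_na_only))
  cat(sprintf("  ATP, pump route     %.3g (Ca2+ charge fraction %.3f)\n",
              x$atp_pump, x$ca_charge_fraction))
  cat(sprintf("  ATP, count route    %.3g (Esyn x Nsyn x Nspk)\n",
              x$atp_counts_method))
  cat(sprintf("  savings, all-C      %.3g\n", x$savings_all_c))
  cat(sprintf("  savings, even split %.3g\n", x$savings_split))
  cat(sprintf("  mean current        %.2f nA over %.1f s\n",
              x$mean_current_nA, x$duration_s))
  invisible(x)
}

#' Tidy an energy report into one row per quantity
#'
#' @param x An `energy_report`.
#' @param ... Unused.
#' @return A tibble with columns `quantity`, `value`, `unit`.
#' @export
tidy.energy_report <- function(x, ...) {
  tibble(
    quantity = c("q_epsp", "n_events", "total_charge", "ion_count",
                 "ca_charge_fraction", "atp_na_only", "atp_pump",
                 "atp_counts_method", "savings_all_c", "savings_split",
                 "mean_current"),
    value = c(x$q_epsp_pC, x$n_events, x$total_charge_nC, x$ion_count,
              x$ca_charge_fraction, x$atp_na_only, x$atp_pump,
              x$atp_counts_method, x$savings_all_c, x$savings_split,
              x$mean_current_nA),
    unit = c("pC", "events", "nC", "ions", "fraction", "ATP", "ATP",
             "ATP", "ATP", "ATP", "nA")
  )
}

#' One-row summary of an energy report
#'
#' @param x An `energy_report`.
#' @param ... Unused.
#' @return A one-row tibble with the headline quantities.
#' @export
glance.energy_report <- function(x, ...) {
  tibble(
    q_epsp_pC = x$q_epsp_pC,
    total_charge_nC = x$total_charge_nC,
    ion_count = x$ion_count,
    atp_pump = x$atp_pump,
    atp_counts_method = x$atp_counts_method,
    savings_all_c = x$savings_all_c,
    mean_current_nA = x$mean_current_nA
  )
}
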