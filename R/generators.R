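# Synthetic-data generators. These emulate the three kinds of raw data the
# pipeline consumes — calibration titrations, single-cell FRET event streams
# and IC-MS isotopologue tables — with the statistical structure the
# downstream stages assume, so the whole pipeline runs without instrument
# data. With all noise at zero each generator is the exact forward model of
# the corresponding analysis stage.

#' Generate a sensor calibration titration
#'
#' Forward sensor model evaluated at a ladder of ATP concentrations:
#' FRET ratio = offset + occupancy(ATP) + Gaussian noise.
#'
#' @param params A [hill_calibration()] (the generating sensor parameters).
#' @param concentrations ATP concentrations in mM (all > 0); default 12
#'   log-spaced points between 0.1 and 10 mM.
#' @param noise_sd Gaussian noise sd in ratio units (0 = exact forward
#'   model).
#' @param seed Optional seed.
#' @return Data frame with columns `atp_mM`, `fret_ratio`.
#' @export
gen_calibration_titration <- function(params = hill_calibration(),
                                      concentrations =
                                        10^seq(log10(0.1), log10(10),
                                               length.out = 12),
                                      noise_sd = 0, seed = NULL) {
  if (any(!is.finite(concentrations)) || any(concentrations <= 0))
    stopf("all titration concentrations must be > 0")
  ratio <- fret_ratio_from_atp(concentrations, params)
  if (noise_sd > 0)
    ratio <- ratio + with_seed(seed, stats::rnorm(length(ratio), 0, noise_sd))
  data.frame(atp_mM = concentrations, fret_ratio = ratio)
}

#' Generate a single-cell FRET event stream
#'
#' Emulates continuous flow-cytometry acquisition of biosensor-expressing
#' cells: event times are uniform over the acquisition window; EGFP
#' intensities are log-normal with median well above the gating floor; the
#' FRET intensity is EGFP times the sensor ratio at the event's ATP level,
#' times multiplicative log-normal noise. A stated fraction of events are
#' low-intensity autofluorescence contaminants below the MFI floor, which
#' gating is expected to remove.
#'
#' @param scenario A [scenario_spec()] (supplies the ATP trajectory, noise
#'   model and default seed), or a bare `function(t) -> ATP mM`.
#' @param n_events Number of events (>= 1).
#' @param duration Acquisition window length in seconds (> 0).
#' @param params A [hill_calibration()].
#' @param seed Optional seed; defaults to the scenario's.
#' @return Data frame with columns `time_s`, `egfp`, `fret`, ordered by
#'   time, with attributes `acquisition_window` and `gate_label`.
#' @export
gen_event_stream <- function(scenario, n_events = 5000L, duration = 600,
                             params = hill_calibration(), seed = NULL) {
  if (is.function(scenario))
    scenario <- list(atp_trajectory = scenario,
                     noise_model = list(event_cv = 0.05,
                                        autofluorescence_fraction = 0.2),
                     seed = NULL)
  if (n_events < 1L) stopf("'n_events' must be >= 1")
  if (duration <= 0) stopf("'duration' must be > 0")
  nm <- scenario$noise_model
  with_seed(seed %||% scenario$seed, {
    t <- sort(stats::runif(n_events, 0, duration))
    n_auto <- round(nm$autofluorescence_fraction * n_events)
    is_auto <- seq_len(n_events) %in%
      sample.int(n_events, n_auto, replace = FALSE)
    egfp <- numeric(n_events)
    fret <- numeric(n_events)
    # biosensor-positive cells
    nc <- sum(!is_auto)
    egfp[!is_auto] <- stats::rlnorm(nc, log(3000), 0.35)
    ratio_true <- fret_ratio_from_atp(scenario$atp_trajectory(t[!is_auto]),
                                      params)
    noise <- if (nm$event_cv > 0)
      exp(stats::rnorm(nc, 0, nm$event_cv)) else rep(1, nc)
    fret[!is_auto] <- egfp[!is_auto] * ratio_true * noise
    # autofluorescence contaminants, below the MFI floor on both channels
    egfp[is_auto] <- stats::rlnorm(n_auto, log(200), 0.5)
    fret[is_auto] <- stats::rlnorm(n_auto, log(200), 0.5)
  })
  out <- data.frame(time_s = t, egfp = egfp, fret = fret)
  attr(out, "acquisition_window") <- c(0, duration)
  attr(out, "gate_label") <- "ungated"
  out
}

# convolve a true MDV with per-carbon natural 13C abundance: each of the
# still-unlabeled carbons is independently 13C with probability p
convolve_natural <- function(mdv, p) {
  C <- length(mdv) - 1L
  out <- numeric(C + 1L)
  for (i in 0:C) {
    if (mdv[i + 1L] == 0) next
    add <- stats::dbinom(0:(C - i), C - i, p)
    out[(i:C) + 1L] <- out[(i:C) + 1L] + mdv[i + 1L] * add
  }
  out
}

#' Generate an IC-MS isotopologue table from a flux vector
#'
#' Simulates steady-state MDVs with the forward cumomer simulator, convolves
#' them per carbon with natural 13C abundance, perturbs them with truncated
#' Gaussian noise (negative fractions floored at zero, then renormalized so
#' each MDV stays on the simplex), and scales them to amounts by metabolite
#' pool size.
#'
#' @param flux_vector Balanced named net-flux vector.
#' @param network A `flux_model` (default the packaged central-carbon
#'   model).
#' @param tracer `"U13C6"` or `"U12C6"`.
#' @param mdv_sd Sd of the truncated Gaussian MDV noise (fraction units).
#' @param natural_abundance_per_carbon Per-carbon 13C probability (default
#'   0.011).
#' @param seed Optional seed.
#' @param pools Named vector of pool sizes (amount units); default 10 for
#'   every metabolite.
#' @param condition Condition label stored in the table.
#' @return Data frame with columns `metabolite`, `pathway`, `condition`,
#'   `tracer`, `mass_shift`, `amount`.
#' @export
gen_isotopologue_table <- function(flux_vector,
                                   network = central_carbon_model(),
                                   tracer = c("U13C6", "U12C6"),
                                   mdv_sd = 0,
                                   natural_abundance_per_carbon = 0.011,
                                   seed = NULL, pools = NULL,
                                   condition = "sample") {
  tracer <- match.arg(tracer)
  check_balance(network, flux_vector)
  mdvs <- simulate_mdvs(network, flux_vector, tracer = tracer)
  mets <- names(mdvs)
  if (is.null(pools)) pools <- stats::setNames(rep(10, length(mets)), mets)
  pathway <- stats::setNames(network$metabolites$pathway,
                             network$metabolites$name)
  rows <- with_seed(seed, lapply(mets, function(met) {
    mdv <- mdvs[[met]]
    if (natural_abundance_per_carbon > 0)
      mdv <- convolve_natural(mdv, natural_abundance_per_carbon)
    if (mdv_sd > 0) {
      mdv <- pmax(mdv + stats::rnorm(length(mdv), 0, mdv_sd), 0)
      mdv <- mdv / sum(mdv)
    }
    data.frame(metabolite = met, pathway = pathway[[met]],
               condition = condition, tracer = tracer,
               mass_shift = seq_along(mdv) - 1L,
               amount = unname((pools[[met]] %||% 10) * mdv))
  }))
  do.call(rbind, rows)
}

#' Generate the full isotopologue data set for one scenario
#'
#' Convenience wrapper producing the matched pair of tracer tables the
#' natural-isotope correction needs: one acquisition with U-13C6 glucose and
#' one control with U-12C6 glucose, same condition label and noise model.
#'
#' @param scenario A [scenario_spec()].
#' @param network A `flux_model`.
#' @param seed Optional seed; defaults to the scenario's.
#' @return Data frame (both tracers stacked).
#' @export
gen_scenario_tracer_tables <- function(scenario,
                                       network = central_carbon_model(),
                                       seed = NULL) {
  seed <- seed %||% scenario$seed
  rbind(
    gen_isotopologue_table(scenario$flux_vector, network, "U13C6",
                           mdv_sd = scenario$noise_model$mdv_sd,
                           seed = seed, pools = scenario$pools,
                           condition = scenario$name),
    gen_isotopologue_table(scenario$flux_vector, network, "U12C6",
                           mdv_sd = scenario$noise_model$mdv_sd,
                           seed = seed + 1L, pools = scenario$pools,
                           condition = scenario$name))
}
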