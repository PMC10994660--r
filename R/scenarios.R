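# Study conditions: three hematopoietic stem cell states — quiescent
# (PBS-treated), proliferative (5-FU-treated) and OXPHOS-inhibited
# (oligomycin-treated) — each encoded as a balanced net-flux vector on the
# glucose-uptake = 100 scale, its boundary-drain configuration, metabolite
# pool sizes for amount scaling, and an ATP trajectory for the event-stream
# generator. Glucose uptake (100) and the lactate effluxes (65 quiescent,
# 80 OXPHOS-inhibited, 78 = 65 x 1.2 proliferative) are the pinned study
# values; the remaining fluxes are balanced choices documented in the
# methods vignette.

scenario_flux_tables <- function() {
  base <- c(hk = 100, pgi = 80, pfk = 90, ald = 90, tpi = 90, gapdh = 185,
            pk = 185, ldh = 65, pdh = 30, pc = 5, accoa_in = 15, cs = 45,
            idh = 45, akgdh = 45, sdh = 45, fum = 45, mdh = 45, g6pd = 20,
            rpe = 10, rpi = 10, tkt1 = 5, tal = 5, tkt2 = 5, lac_eff = 65,
            pyr_eff = 85, nas_eff = 5, oaa_eff = 5, co2_eff = 135)
  fu <- c(hk = 100, pgi = 72, pfk = 84, ald = 84, tpi = 84, gapdh = 174,
          pk = 174, ldh = 78, pdh = 36, pc = 5, accoa_in = 9, cs = 45,
          idh = 45, akgdh = 45, sdh = 45, fum = 45, mdh = 45, g6pd = 28,
          rpe = 12, rpi = 16, tkt1 = 6, tal = 6, tkt2 = 6, lac_eff = 78,
          pyr_eff = 55, nas_eff = 10, oaa_eff = 5, co2_eff = 149)
  ox <- c(hk = 100, pgi = 86, pfk = 94, ald = 94, tpi = 94, gapdh = 192,
          pk = 192, ldh = 80, pdh = 12, pc = 2, accoa_in = 3, cs = 15,
          idh = 15, akgdh = 15, sdh = 15, fum = 15, mdh = 15, g6pd = 14,
          rpe = 8, rpi = 6, tkt1 = 4, tal = 4, tkt2 = 4, lac_eff = 80,
          pyr_eff = 98, nas_eff = 2, oaa_eff = 2, co2_eff = 54)
  list(quiescent = base, proliferative_5FU = fu, oxphos_inhibited = ox)
}

#' Ground-truth flux vectors for the three study conditions
#'
#' Balanced net-flux vectors (glucose uptake = 100) for quiescent,
#' proliferative (5-FU) and OXPHOS-inhibited cells. Relative to quiescent,
#' the proliferative vector has elevated anaerobic glycolysis (lactate efflux
#' 78 vs 65), higher pyruvate dehydrogenase flux and a doubled
#' nucleotide-synthesis drain; the OXPHOS-inhibited vector has the maximal
#' modelable lactate efflux (80), a collapsed TCA cycle and a reduced
#' nucleotide-synthesis drain.
#'
#' @return Named list of named numeric flux vectors.
#' @export
gen_flux_scenarios <- function() scenario_flux_tables()

scenario_pools <- function() {
  base <- c(G6P = 8, F6P = 10, FBP = 5, DHAP = 6, GAP = 2, PEP = 4,
            PYR = 12, LAC = 30, CIT = 10, AKG = 6, SUC = 8, FUM = 5,
            MAL = 9, CO2 = 1, AcCoA = 2, OAA = 3, Ru5P = 2, X5P = 2,
            R5P = 4, S7P = 3, E4P = 1)
  fu <- base
  fu[c("G6P", "DHAP", "GAP", "PEP", "PYR", "LAC")] <-
    2 * base[c("G6P", "DHAP", "GAP", "PEP", "PYR", "LAC")]
  fu["F6P"] <- 6; fu["FBP"] <- 18
  fu[c("Ru5P", "X5P", "R5P", "S7P", "E4P")] <-
    2 * base[c("Ru5P", "X5P", "R5P", "S7P", "E4P")]
  ox <- base
  ox[c("G6P", "F6P", "DHAP", "GAP", "PEP", "PYR", "LAC")] <-
    1.5 * base[c("G6P", "F6P", "DHAP", "GAP", "PEP", "PYR", "LAC")]
  ox["FBP"] <- 12
  ox["R5P"] <- 2
  list(quiescent = base, proliferative_5FU = fu, oxphos_inhibited = ox)
}

scenario_trajectories <- function() {
  sigmoid_drop <- function(level, drop, t0, tau)
    function(t) level - drop * stats::plogis((t - t0) / tau)
  list(quiescent = sigmoid_drop(0.90, 0.15, 300, 40),
       proliferative_5FU = sigmoid_drop(0.85, 0.40, 300, 30),
       oxphos_inhibited = sigmoid_drop(0.80, 0.50, 300, 20))
}

#' Full specification of a simulated study condition
#'
#' Bundles everything the generators need for one condition: the balanced
#' flux vector, the boundary-drain configuration used when refitting, pool
#' sizes for isotopologue amount scaling, an ATP-vs-time trajectory for the
#' event-stream generator, and the noise model.
#'
#' @param name One of `"quiescent"`, `"proliferative_5FU"`,
#'   `"oxphos_inhibited"`.
#' @param seed Integer seed stored with the scenario.
#' @param noise_model List with `event_cv` (multiplicative CV of event FRET
#'   intensities), `mdv_sd` (sd of MDV fraction noise) and
#'   `autofluorescence_fraction` (fraction of sub-gate contaminant events).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name = c("quiescent", "proliferative_5FU",
                                   "oxphos_inhibited"),
                          seed = 1L,
                          noise_model = list(event_cv = 0.05, mdv_sd = 0.01,
                                             autofluorescence_fraction = 0.2)) {
  name <- match.arg(name)
  stopifnot(noise_model$event_cv >= 0, noise_model$mdv_sd >= 0,
            noise_model$autofluorescence_fraction >= 0,
            noise_model$autofluorescence_fraction < 1)
  fluxes <- scenario_flux_tables()[[name]]
  structure(list(
    name = name,
    flux_vector = fluxes,
    fixed_effluxes = as.list(fluxes[c("pyr_eff", "nas_eff", "oaa_eff")]),
    lactate_efflux = unname(fluxes["lac_eff"]),
    pools = scenario_pools()[[name]],
    atp_trajectory = scenario_trajectories()[[name]],
    noise_model = noise_model,
    seed = seed
  ), class = "scenario_spec")
}
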