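#!/usr/bin/env Rscript
# Generate every input the downstream analyses consume: a sensor calibration
# titration, single-cell FRET event streams for a control and a treated arm,
# and matched U-13C6 / U-12C6 isotopologue tables for the three study
# conditions, all from known ground truth so each later stage can be checked
# against what was put in.

suppressPackageStartupMessages(library(hscflux))
dir.create("results", showWarnings = FALSE)
dir.create("results/simulated", showWarnings = FALSE, recursive = TRUE)

seed <- 20260920L

cat("== 01: simulating raw inputs ==\n")

# calibration titration: forward sensor model + small ratio noise. The
# ladder spans the sensor's dynamic range (occupancy ~0.03-0.98) with three
# replicates per concentration; deeper saturation adds no information and
# only feeds the occupancy-range exclusion rule.
ladder <- rep(10^seq(log10(0.2), log10(3), length.out = 12), each = 3)
titration <- gen_calibration_titration(hill_calibration(),
                                       concentrations = ladder,
                                       noise_sd = 0.005, seed = seed)
write.csv(titration, "results/simulated/titration.csv", row.names = FALSE)
cat(sprintf("titration: %d points, ratio %.3f-%.3f\n", nrow(titration),
            min(titration$fret_ratio), max(titration$fret_ratio)))

# event streams: quiescent control arm vs proliferative (5-FU) arm, each
# with a perturbation-driven ATP drop midway through the acquisition
for (arm in c("quiescent", "proliferative_5FU")) {
  scn <- scenario_spec(arm, seed = seed + match(arm, c("quiescent",
                                                       "proliferative_5FU")))
  ev <- gen_event_stream(scn, n_events = 5000, duration = 600)
  write_event_stream(ev, sprintf("results/simulated/events_%s.csv", arm))
  cat(sprintf("events (%s): %d events over %g s\n", arm, nrow(ev), 600))
}

# isotopologue tables: three conditions, both tracers, with per-carbon
# natural abundance and MDV noise
net <- central_carbon_model()
tables <- lapply(names(gen_flux_scenarios()), function(nm) {
  scn <- scenario_spec(nm, seed = seed + 10 + match(nm,
                         names(gen_flux_scenarios())))
  gen_scenario_tracer_tables(scn, net)
})
tracer_table <- do.call(rbind, tables)
write.csv(tracer_table, "results/simulated/isotopologues.csv",
          row.names = FALSE)
cat(sprintf("isotopologues: %d rows, %d metabolites x %d conditions x 2 tracers\n",
            nrow(tracer_table), length(unique(tracer_table$metabolite)),
            length(unique(tracer_table$condition))))

# ground-truth flux vectors, for later comparison
jsonlite::write_json(lapply(gen_flux_scenarios(), as.list),
                     "results/simulated/true_fluxes.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote ground-truth flux vectors\n")
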