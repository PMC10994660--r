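test_that("generators are bit-identical under a fixed seed", {
  scn <- scenario_spec("quiescent", seed = 77)
  expect_identical(gen_event_stream(scn, 500, 120),
                   gen_event_stream(scn, 500, 120))
  expect_identical(
    gen_calibration_titration(noise_sd = 0.02, seed = 5),
    gen_calibration_titration(noise_sd = 0.02, seed = 5))
  m <- central_carbon_model()
  v <- gen_flux_scenarios()$quiescent
  expect_identical(
    gen_isotopologue_table(v, m, mdv_sd = 0.01, seed = 9),
    gen_isotopologue_table(v, m, mdv_sd = 0.01, seed = 9))
})

test_that("the noiseless titration is the exact forward sensor model", {
  cal <- hill_calibration()
  tit <- gen_calibration_titration(cal)
  expect_equal(tit$fret_ratio, fret_ratio_from_atp(tit$atp_mM, cal))
  # half-saturation point: ratio = offset + 0.5
  at_ka <- gen_calibration_titration(cal, concentrations = cal$K_A)
  expect_equal(at_ka$fret_ratio, 1.96)
  # [L] -> 0: ratio -> offset
  low <- gen_calibration_titration(cal, concentrations = 1e-8)
  expect_equal(low$fret_ratio, 1.46, tolerance = 1e-6)
  expect_error(gen_calibration_titration(cal, concentrations = c(1, -2)),
               "> 0")
})

test_that("a noiseless refit recovers the generating parameters", {
  gen <- hill_calibration(n = 2.2, K_A = 1.3)
  cal <- fit_hill(gen_calibration_titration(gen))
  expect_equal(cal$n, 2.2, tolerance = 1e-8)
  expect_equal(cal$K_A, 1.3, tolerance = 1e-8)
})

test_that("event streams follow the ATP trajectory through the sensor", {
  # constant ATP, zero noise: all biosensor events share one ratio
  scn <- scenario_spec("quiescent", seed = 3,
                       noise_model = list(event_cv = 0, mdv_sd = 0,
                                          autofluorescence_fraction = 0.2))
  scn$atp_trajectory <- function(t) rep(0.9, length(t))
  ev <- gate_events(gen_event_stream(scn, 2000, 300))
  ratios <- fret_value(ev$fret, ev$egfp)
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(ratios[1], fret_ratio_from_atp(0.9))
  # step-down trajectory: gated median ratio drops across the step
  scn$atp_trajectory <- function(t) ifelse(t < 150, 0.9, 0.4)
  ev2 <- gate_events(gen_event_stream(scn, 2000, 300))
  r2 <- fret_value(ev2$fret, ev2$egfp)
  expect_gt(median(r2[ev2$time_s < 150]), median(r2[ev2$time_s >= 150]))
})

test_that("autofluorescence contaminants sit below the gate", {
  scn <- scenario_spec("quiescent", seed = 13)
  ev <- gen_event_stream(scn, 4000, 300)
  g <- gate_events(ev)
  # the configured 20% contaminant fraction is removed by the MFI floor
  expect_lt(nrow(g) / nrow(ev), 0.81)
  expect_true(all(g$egfp > 1000 & g$fret > 1000))
})

test_that("isotopologue tables carry natural abundance per carbon", {
  m <- central_carbon_model()
  v <- gen_flux_scenarios()$quiescent
  # U-12C6 control with natural abundance off: pure M+0
  t0 <- gen_isotopologue_table(v, m, "U12C6", natural_abundance_per_carbon = 0)
  expect_true(all(t0$amount[t0$mass_shift >= 1] == 0))
  # with 1.1% per carbon, a 6-carbon metabolite shows binomial M+1
  t1 <- gen_isotopologue_table(v, m, "U12C6",
                               natural_abundance_per_carbon = 0.011)
  f <- labeling_fractions(t1, "F6P", tracer = "U12C6")
  expect_equal(unname(f["M+1"]), dbinom(1, 6, 0.011), tolerance = 1e-12)
  expect_equal(unname(f["M+2"]), dbinom(2, 6, 0.011), tolerance = 1e-12)
})

test_that("pure glycolytic flux gives fully labeled lactate in the table", {
  toy <- toy_networks()$glycolysis
  tab <- gen_isotopologue_table(toy$fluxes, toy$model, "U13C6",
                                natural_abundance_per_carbon = 0)
  f <- labeling_fractions(tab, "L")
  expect_equal(unname(f["M+3"]), 1)
})

test_that("unbalanced flux vectors are rejected by the generator", {
  m <- central_carbon_model()
  v <- gen_flux_scenarios()$quiescent
  v["pfk"] <- v["pfk"] + 2
  expect_error(gen_isotopologue_table(v, m), "balance")
})

test_that("generated MDVs stay on the simplex under noise", {
  m <- central_carbon_model()
  v <- gen_flux_scenarios()$oxphos_inhibited
  tab <- gen_isotopologue_table(v, m, mdv_sd = 0.05, seed = 1,
                                pools = NULL)
  expect_true(all(tab$amount >= 0))
  totals <- tapply(tab$amount, tab$metabolite, sum)
  expect_true(all(abs(totals - 10) < 1e-9))   # default pool size 10
})

test_that("scenario flux vectors encode the study design", {
  sc <- gen_flux_scenarios()
  for (v in sc) expect_equal(unname(v["hk"]), 100)
  expect_equal(unname(sc$quiescent["lac_eff"]), 65)
  expect_equal(unname(sc$oxphos_inhibited["lac_eff"]), 80)
  # proliferative: elevated anaerobic glycolysis; OXPHOS-inhibited: reduced
  # nucleotide-synthesis drain
  expect_gt(sc$proliferative_5FU["lac_eff"], sc$quiescent["lac_eff"])
  expect_lt(sc$oxphos_inhibited["nas_eff"], sc$quiescent["nas_eff"])
})
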