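# hscflux

Quantitative metabolic analysis of rare hematopoietic cells: single-cell ATP
measurement with a ratiometric FRET biosensor, U-¹³C₆-glucose isotope-tracer
processing, and steady-state ¹³C metabolic flux analysis (¹³C-MFA) of the
glycolysis / pentose-phosphate / TCA network.

Hematopoietic stem cells (HSCs) are too rare for conventional metabolomics to
track their metabolism over time, and their glycolytic reprogramming under
stress (proliferation induced by 5-fluorouracil, or OXPHOS inhibition by
oligomycin) plays out within minutes. This package implements the three
quantitative layers such a study needs, as reusable, tested functions:

1. **Biosensor calibration** — a GO-ATeam2-type sensor reports ATP through
   the FRET/EGFP ratio. Sensor occupancy follows the Hill equation

   θ = [L]ⁿ / (K_Aⁿ + [L]ⁿ),  with θ = FRET ratio − 1.46,

   and the calibration is fitted by ordinary least squares on the
   log-linearized form log(θ/(1−θ)) = n·log[L] − n·log K_A. Conversion is
   bidirectional: ratio → θ → [L] (mM) and back.
2. **ATP time courses** — flow-cytometry event streams (time, EGFP, FRET per
   cell) are gated (MFI floor plus top-fraction quantile gate per channel),
   the per-event ratio is smoothed against time with a penalized-spline GAM
   (`mgcv::gam`, automatic smoothness), converted to ATP, and
   baseline-corrected between arms by the ratio of fitted values at t = 0.
3. **Tracer analysis and ¹³C-MFA** — IC-MS isotopologue tables are
   quantified, normalized to labeling fractions, corrected for natural
   isotope abundance against a U-¹²C₆ control (subtraction with zero floor),
   and summarized per pathway. Steady-state fluxes over a central-carbon
   network (glucose uptake pinned to 100) are estimated by multi-start
   least squares between measured and simulated mass-distribution vectors
   (MDVs). The forward simulator uses a cumomer decomposition (cascaded
   linear systems per labeling weight, with carbon-atom transition maps and
   molecular symmetry); an exhaustive positional-isotopomer simulator is
   included as an independent cross-check. The quiescent lactate efflux is
   selected by scanning candidates 0–100 (low candidates fail with reversed
   glycolysis), and stressed-condition effluxes are scaled by the ratio of
   labeled-glycolytic shares with a feasibility cap.

Because no raw cytometry or metabolomics data are public for this design,
the package ships first-class synthetic generators (`gen_*`) that emulate
calibration titrations, drifting event clouds with autofluorescence
contaminants, and isotopologue tables with ~1.1 %/carbon natural abundance —
all from known ground truth, so every stage is testable end to end.

## Worked example

```r
library(hscflux)

## calibrate the sensor from a (here: noiseless synthetic) titration
cal <- fit_hill(gen_calibration_titration())
print(cal)
#> Hill calibration: n = 3.1234 , K_A = 0.84699 mM, offset = 1.46
#>   fit: R^2 = 1.000000, 12 points used, 0 excluded

## convert a measured FRET ratio to ATP concentration
theta_to_atp(ratio_to_theta(1.80, cal), cal)
#> ratio 1.80 -> 0.685 mM ATP

## fit fluxes to (noiseless synthetic) MDVs of the quiescent condition
m    <- central_carbon_model()
meas <- simulate_mdvs(m, gen_flux_scenarios()$quiescent)[m$measured]
est  <- fit_fluxes(m, meas, fixed_fluxes = list(hk = 100, lac_eff = 65,
                   pyr_eff = 85, nas_eff = 5, oaa_eff = 5),
                   cycles = 10, seed = 1)
est$free
#> residual 1.7e-24; tkt1 = 5.000 (true 5), accoa_in = 15.000 (true 15)
```

The fitted Hill coefficient and half-saturation constant are recovered
exactly from noiseless data; the flux fit recovers the generating
transketolase flux (the oxidative-PPP split) and the unlabeled acetyl-CoA
inflow (fatty-acid-oxidation share of the TCA cycle) on the glucose-uptake
= 100 scale.

## Analysis workflow

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates titration, event streams, isotopologue tables, true fluxes |
| `02_calibration.R` | fits the Hill calibration, writes `calibration.json` |
| `03_atp_timecourse.R` | gates, smooths, converts, baseline-corrects ATP traces |
| `04_tracer.R` | natural-isotope flags/correction, pathway totals, F1,6BP/F6P readout |
| `05_mfa.R` | lactate-efflux scan, efflux scaling, per-condition flux fits |

Run them in order: `for s in analysis/0*.R; do Rscript $s; done`

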