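---
title: "Quantitative metabolic analysis of hematopoietic stem cells: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative metabolic analysis of hematopoietic stem cells: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscflux)
```

This vignette is the package's own account of the models it implements, the
choices behind their defaults, and what the synthetic-data tests do and do
not establish about real data.

## 1. The biosensor calibration model

A GO-ATeam2-type sensor is a genetically encoded ratiometric ATP reporter:
EGFP donor, orange acceptor, and a FRET/EGFP ratio that increases with ATP
binding. The package models the measured ratio as a fixed instrument offset
plus the sensor occupancy,

$$\theta = \frac{[L]^n}{K_A^n + [L]^n}, \qquad
  \mathrm{ratio} = 1.46 + \theta,$$

with $[L]$ the ATP concentration in mM, $K_A$ the half-saturation
concentration and $n$ the Hill coefficient. Fitting uses the log-linearized
form
$$\log\frac{\theta}{1-\theta} = n\log[L] - n\log K_A$$
by ordinary least squares; the slope gives $n$ and the intercept gives
$K_A = \exp(-\mathrm{intercept}/n)$. Natural logarithms are used — the
slope, and hence $n$ and $K_A$, are invariant to the base, so only the
intercept bookkeeping depends on this choice.

Defaults: `n = 3.1234`, `K_A = 0.84699` mM, `offset = 1.46`. The offset is
treated as an instrument constant and never refit; $K_A$ is carried in mM
(Mg-ATP titrations and physiological discussion both live in the millimolar
range).

**Occupancy outside (0, 1).** Noisy single events routinely exceed the
sensor's dynamic range. Two policies are exposed: `flag` (keep boundary
values, `NA` beyond them, mark everything out of $(0,1)$ in an attribute)
and `clip` (clamp to $[10^{-6}, 1-10^{-6}]$). The time-course pipeline uses
`clip`, since a fitted curve brushing the range limits should convert to a
near-0 (or near-saturating) concentration rather than drop out.

**Exclusion rule and its bias.** Titration points whose occupancy falls
outside $(0,1)$ after offset subtraction are excluded from the regression
and counted in the diagnostics. This exclusion is asymmetric at saturated
points: noise can only push an included point's logit downward there, so
titration ladders that reach deep saturation give a small but systematic
downward bias in $K_A$ (about 2.5 % at ratio noise sd 0.01 with points at
10 mM). The Monte-Carlo unbiasedness test therefore uses a ladder spanning
occupancy ~0.02–0.98, which is also the sensible experimental design; with
noiseless data any ladder recovers the parameters exactly.

## 2. ATP time courses from event streams

Events are (time, EGFP, FRET) triples, one cell each, streamed continuously
over an acquisition window (default 600 s, 1 s analysis grid).

* **Gating.** Both channels must exceed an MFI floor (default 1000) and lie
  in the top `top_fraction` (default 0.45, representing a top-40–50 % gate)
  of their channel's post-floor distribution. Quantiles are
  linear-interpolation quantiles, computed channel-wise after the floor.
  The gate's parameters are recorded on the stream; re-applying the
  identical gate is a no-op (a literal re-application of a quantile gate
  would keep shrinking the set, which is never what an analyst means).
* **Smoothing.** The per-event FRET/EGFP ratio is fitted against time with
  `mgcv::gam(ratio ~ s(time))` in default settings: a thin-plate penalized
  regression spline with smoothness chosen by GCV. The penalty null space
  contains constants and straight lines, so those are reproduced exactly;
  the smoother is linear, hence translation-equivariant in the ratio.
* **Conversion and baseline correction.** The fitted curve converts
  pointwise to ATP (clip mode). To compare arms with different baselines,
  the control trace is multiplied by treated(0)/control(0), where "0 s" is
  the fitted value at the grid point nearest zero — the fitted rather than
  a raw value, for noise robustness, since the paper-level procedure does
  not specify which.
* **Endpoints.** Window means over the closed grid window (e.g. the last
  1–2 minutes) summarize each arm. Density (pseudocolor-style) output is a
  plain 2-D kernel density grid (`MASS::kde2d`, normal-reference
  bandwidth), not a plot.

## 3. Tracer tables

Isotopologue tables are long data frames (metabolite, pathway, condition,
tracer, mass shift, amount). Amount units are carried opaquely; every
operation is a ratio or a sum, so semi-quantitative units are fine.

* Calibration-curve quantitation inverts `area = slope·amount + intercept`
  with a zero floor.
* *Labeling rate* is defined as $1 - $ fraction(M+0) — the term is used in
  the field without a formula.
* Natural-isotope correction subtracts the matched U-¹²C₆-control amount
  from each labeled isotopologue, flooring at zero. Isotopologues whose
  control amount exceeds 5 % of the labeled amount are flagged; the
  workflow corrects only the flagged ones (the correction's intended
  selective use), though blanket correction is available. Both corrected
  and raw tables are accepted by the pathway summaries, since the
  upstream convention is not fixed.
* Pathway totals sum all M+i, i ≥ 1 over member metabolites; the heatmap
  transform is labeling rate + 1 (entries in [1, 2]), matching the
  pseudo-count display convention.

## 4. The flux model and simulator

The packaged network (`inst/extdata/central_carbon.yaml`) covers
glycolysis, the oxidative and non-oxidative pentose-phosphate pathway, the
pyruvate branch point (lactate dehydrogenase, pyruvate dehydrogenase,
pyruvate carboxylase) and a single-pool TCA cycle with lumped aconitase +
isocitrate dehydrogenase and succinate dehydrogenase. Cytosol and
mitochondria are one pool. Microbial fermentation chemistry (pyruvate
formate lyase, ethanol fermentation) is rejected by a profile validator.
Atom maps follow standard carbon-transition conventions; succinate and
fumarate symmetry is expressed as equal-weight alternative maps. The map
file is versioned data, not code.

Two deliberate modeling choices deserve emphasis:

* **Unlabeled acetyl-CoA inflow.** With 100 % U-¹³C₆ glucose as the sole
  carbon source, every steady-state MDV would be fully labeled and carry no
  flux information. Real HSC data show persistently incomplete TCA
  labeling, consistent with dilution from non-glucose carbon — in HSCs
  chiefly fatty-acid oxidation. The model therefore includes an unlabeled
  acetyl-CoA inflow (`accoa_in`). This both matches the biology and makes
  the fit identifiable.
* **Fixed drains.** Non-lactate boundary drains (pyruvate, nucleotide
  synthesis, oxaloacetate) are configuration values, fixed during a fit,
  mirroring the practice of taking non-lactate effluxes from a tool's
  defaults rather than fitting them.

**Simulation.** `simulate_mdvs()` solves the steady-state labeling balances
by cumomer decomposition: the fraction of molecules labeled on each carbon
subset obeys, weight by weight, a linear system; solving the cascade and
Möbius-inverting gives every MDV. This is equivalent to an
elementary-metabolite-unit treatment without pruning (the network is small
enough that pruning is unnecessary; one simulation costs ~5 ms).
Reversible reactions are represented as net + exchange unidirectional
pairs; exchange defaults to 0 and is configurable per reaction. A negative
net flux on a reversible reaction simply runs the reverse atom map.
`simulate_mdvs_enum()` is an independent reference: it tracks all $2^C$
positional isotopomers per metabolite and solves the same balances by
fixed-point iteration. The test suite requires the two to agree to $10^{-9}$
on every fixture network, including ones with condensation reactions,
symmetric scrambling and genuine label recycling.

Degenerate inputs are diagnosed, not silently mishandled: unbalanced flux
vectors, negative irreversible fluxes, and dead pools (a metabolite with no
consumption, whose steady-state labeling is undefined) all raise named
errors.

## 5. Flux fitting, efflux scan, efflux scaling

The flux vector is parameterized by a small set of free fluxes (for the
packaged network: the first transketolase flux and the acetyl-CoA inflow);
all dependent fluxes are recovered exactly from steady-state balance with
glucose uptake pinned to 100 and the lactate efflux pinned to its
configured value, so every reported vector is balanced by construction.
The objective is the (optionally variance-weighted; default uniform) sum of
squared differences between simulated and measured MDVs, plus a smooth
penalty on negative irreversible fluxes. Optimization restarts `cycles`
times (default 100) from uniform random starting points, restart seed =
base seed + restart index, each restart capped at 2000 iterations
(`nlminb`). The best converged restart is reported together with the full
restart × reaction flux matrix and its per-reaction standard deviation.

**Lactate-efflux scan.** Candidates 0–100 in steps of 5 are each fitted
and classified: `infeasible` (fit failure — e.g. candidate 0 removes the
lactate pool's only consumption), `reversed_glycolysis` (any net flux on
the hexokinase→pyruvate-kinase chain below $-10^{-6}$), or `ok`; among `ok`
candidates the minimal residual wins. On synthetic quiescent data generated
at efflux 65 with near-100 % glycolytic labeling, candidates below ~40 fail
with reversed glycolysis — with the drains fixed, a small lactate efflux
forces the balance to push hexose backwards — and 65 is selected. The step
size 5 matches the decrement used in the feasibility cap.

**Efflux scaling.** A stressed condition's efflux is
$65 \times \mathrm{share}_{treated}/\mathrm{share}_{control}$, where the
share is the labeled-glycolytic fraction of all labeled metabolites. Values
above the modelable maximum (85) descend in steps of 5 until a feasibility
probe passes; the reading adopted here is that 85 itself is the first value
tried on the way down. With equal shares the quiescent baseline 65 is
returned exactly.

**Identifiability.** The two free fluxes are identified through distinct
channels: the acetyl-CoA inflow through the overall TCA dilution, and the
transketolase (oxidative-PPP) flux through the pyruvate-dehydrogenase flux
forced by balance and, more weakly, through CO₂ relabeling via pyruvate
carboxylase. On noiseless data both recover to well under 1 % with 100
restarts. Under realistic measurement noise the oxidative-PPP split can
drift toward its bounds while lactate, the pyruvate branch and the drains
stay tight; the workflow reports fitted against generating values rather
than hiding this.

## 6. What the synthetic generators emulate — and what they do not

`gen_calibration_titration` is the exact forward sensor model plus Gaussian
ratio noise. `gen_event_stream` draws event times uniformly over the window
(no arrival model is claimed by the acquisition it emulates; uniform is the
simplest defensible choice), log-normal EGFP (median 3000, well above the
MFI floor), FRET = EGFP × ratio × log-normal noise (CV 0.05 default), and a
20 % autofluorescence component (log-normal, median 200) below the floor so
that gating has something to remove. `gen_isotopologue_table` runs the
forward simulator, convolves each MDV per carbon with natural ¹³C abundance
(1.1 %/carbon default, binomial over the unlabeled carbons), adds truncated
Gaussian noise renormalized to the simplex, and scales by pool size.

The three scenario flux vectors pin glucose uptake = 100 and lactate
effluxes 65 / 78 / 80 (quiescent / proliferative / OXPHOS-inhibited); the
remaining values are balanced choices made once: the proliferative vector
has a doubled nucleotide-synthesis drain, higher pyruvate-dehydrogenase
flux and less unlabeled acetyl-CoA (less fatty-acid oxidation); the
OXPHOS-inhibited vector has a collapsed TCA cycle and reduced
nucleotide-synthesis drain. One stoichiometric fact is worth recording:
with uptake pinned at 100, a larger pentose-phosphate diversion necessarily
lowers absolute flux through phosphofructokinase (the non-oxidative branch
returns only a fraction of what the oxidative branch takes), so "elevated
glycolysis" in the proliferative state is expressed where it is observable
— in the lactate efflux and the pyruvate branch — and the elevated
F1,6BP/F6P readout is carried by the metabolite pools, which is also where
the real assay measures it.

Not emulated: spectral overlap/compensation, IC-MS peak shapes, per-cell
tracking (each event is one cell observed once), photobleaching, pH or
temperature dependence of the sensor, isotopically nonstationary labeling
and compartmentation. Passing tests on this synthetic data establish that
the pipeline's inference is correct when its assumptions hold; they cannot
establish that real instruments satisfy those assumptions.

## 7. Numerical choices and problem sizes

* Cumomer systems are solved densely per weight (largest block ≈ 180
  unknowns); MDVs must sum to 1 within $10^{-9}$ and the enumeration
  cross-check agrees to $10^{-9}$.
* The isotopomer reference iterates to a $10^{-13}$ stationarity tolerance
  (cap 50 000 sweeps) — label-recycling networks converge geometrically.
* Fits in the test suite use 100 restarts for the recovery checks and
  2–20 restarts where a scan or a qualitative comparison only needs a
  local refit; event-stream checks use 5000 events over 600 s. These sizes
  were chosen so the whole suite runs comfortably on one CPU.
* Ties and degenerate cases: empty gates warn rather than error; a fit in
  which no restart reaches a feasible simulation raises a fit-failure
  error; zero-candidate or all-failing scans error with the full status
  table attached.

## 8. Known limitations

* The atom-map file encodes one standard convention for carbon transitions;
  alternative lumpings (e.g. splitting the lumped oxidative-PPP step) would
  change individual fluxes but not the balance structure.
* The efflux scan's failure boundary (~40) depends on the fixed-drain
  configuration; it is a property of the study conditions, not a universal
  constant.
* The Hill fit's exclusion rule biases $K_A$ on deeply saturated ladders
  (section 1); design titrations inside the dynamic range.
* No profile-likelihood confidence intervals for fluxes; restart dispersion
  is reported instead.
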