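#!/usr/bin/env Rscript
# Fit the FRET -> ATP Hill calibration from the simulated titration and
# check that the generating sensor parameters are recovered.

suppressPackageStartupMessages(library(hscflux))

cat("== 02: sensor calibration ==\n")
titration <- read.csv("results/simulated/titration.csv")
cal <- fit_hill(titration)
print(cal)

cat(sprintf("generating parameters: n = 3.1234, K_A = 0.84699 mM\n"))
cat(sprintf("recovered:             n = %.4f, K_A = %.5f mM (R^2 = %.5f)\n",
            cal$n, cal$K_A, cal$diagnostics$r_squared))

write_calibration(cal, "results/calibration.json")
cat("wrote results/calibration.json\n")
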