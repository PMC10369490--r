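#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with known ground truth.
#
# Three pHRE frame-table presets (flat control, desolvation-like upward
# pKa shift, inverted deep-arginine-like shift) plus the stopped-flow /
# titration suite. Everything downstream (geometry, census, profiles,
# fits, attribution) consumes these tables.

library(phrex)

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1L

for (preset in c("flat-profile", "desolvation-shift",
                 "salt-bridge-inversion")) {
  fx <- make_fixtures(preset, seed = seed, n_frames = 5000, dir = out)
  cat(sprintf("%-22s %d frames, truth pKa range %.2f..%.2f\n",
              preset, nrow(fx$frames), min(fx$truth$pka_values),
              max(fx$truth$pka_values)))
}

kin <- make_fixtures("kinetics-suite", seed = seed, dir = out)
cat(sprintf("kinetics-suite         %d traces + titration table (%d pH)\n",
            length(kin$traces), nrow(kin$titration)))
cat("written under", out, "\n")
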