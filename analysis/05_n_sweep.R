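#!/usr/bin/env Rscript
# Fertilization-rate sweep 0-200 kg N/ha in steps of 10 (split 50/50 over
# the two application dates) for the normal and hot archetypes: yields,
# N-use efficiencies, leaching and the optimal (plateau-entry) rates.

suppressPackageStartupMessages(library(barleygap))
seed <- 1
dir.create("results", showWarnings = FALSE)
cfg <- site_fixture(dz = 1)

for (lab in c("normal", "hot")) {
  sw <- n_sweep(cfg, lab, rates = seq(0, 200, 10), seed = seed,
                spinup_years = 1)
  out <- sw[, c("rate_kgN_ha", "grain_t_ha", "uptake_kgN_ha", "aen",
                "pfpn", "ren", "wue", "leach_kgN_ha")]
  out[-1] <- round(out[-1], 2)
  write.csv(out, sprintf("results/n_sweep_%s.csv", lab), row.names = FALSE)
  message(sprintf("%-6s optimal N rate: %d kg/ha (max yield %.2f t/ha)",
                  lab, optimal_rate(sw), max(sw$grain_t_ha)))
}
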