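#!/usr/bin/env Rscript
# Build the study inputs: seeded synthetic weather for the three season
# archetypes (normal 2020, hot 2021, wet 2022), the packaged site
# configuration (soil horizons, management calendar), and noisy
# pseudo-observations standing in for the field data streams.

suppressPackageStartupMessages(library(barleygap))
seed <- 1
dir.create("results", showWarnings = FALSE)
cfg <- site_fixture(dz = 1)

for (i in seq_len(nrow(cfg$archetypes))) {
  a <- cfg$archetypes[i, ]
  ws <- generate_weather(a$label, a$year, seed, cfg)
  write_weather(ws, file.path("results", sprintf("weather_%s_%d.csv",
                                                 a$label, a$year)))
  sel <- ws$date >= as.Date(a$sowing) & ws$date <= as.Date(a$harvest)
  message(sprintf(
    "%-6s %d: season mean T %.1f C (target %.1f), precip %.1f mm (target %.1f)",
    a$label, a$year, mean((ws$tmin[sel] + ws$tmax[sel]) / 2),
    a$season_tmean, sum(ws$precip[sel]), a$season_precip))
}

# truth run of the normal season and its noisy observation files
ws <- generate_weather("normal", 2020, seed, cfg)
mgmt <- build_management(cfg, 2020, "normal")
truth <- run_simulation(cfg, ws, mgmt)
obs <- make_observations(truth, noise_model(swc_sd = 0.02), seed = seed)
write.csv(obs, "results/observations_normal_2020.csv", row.names = FALSE)
message("wrote weather series and ", nrow(obs), " pseudo-observations")
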