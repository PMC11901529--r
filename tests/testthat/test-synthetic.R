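test_that("generated seasons hit the archetype climate targets", {
  cfg <- site_fixture()
  for (seed in c(1, 2)) {
    for (lab in c("normal", "hot", "wet")) {
      a <- archetype_info(cfg, lab)
      ws <- generate_weather(lab, a$year, seed, cfg)
      expect_equal(nrow(ws), 365 + (a$year %% 4 == 0))
      sel <- ws$date >= as.Date(a$sowing) & ws$date <= as.Date(a$harvest)
      tmean <- mean((ws$tmin[sel] + ws$tmax[sel]) / 2)
      expect_lt(abs(tmean - a$season_tmean), 0.3)
      expect_lt(abs(sum(ws$precip[sel]) - a$season_precip), 5)
      expect_true(all(ws$tmin <= ws$tmax))
      expect_true(all(ws$precip >= 0 & ws$srad >= 0 & ws$wind >= 0))
      expect_true(all(ws$rh >= 0 & ws$rh <= 100))
    }
  }
})

test_that("the generator is deterministic and hot seasons are hotter", {
  cfg <- site_fixture()
  w1 <- generate_weather("normal", 2020, 9, cfg)
  w2 <- generate_weather("normal", 2020, 9, cfg)
  expect_identical(w1$precip, w2$precip)
  expect_identical(w1$tmax, w2$tmax)
  w3 <- generate_weather("normal", 2020, 10, cfg)
  expect_false(identical(w1$precip, w3$precip))
  # hot season-window mean exceeds normal's for any seed (by construction)
  for (seed in 1:5) {
    sn <- generate_weather("normal", 2020, seed, cfg)
    sh <- generate_weather("hot", 2021, seed, cfg)
    an <- archetype_info(cfg, "normal"); ah <- archetype_info(cfg, "hot")
    mn <- with(sn[sn$date >= as.Date(an$sowing) &
                    sn$date <= as.Date(an$harvest), ],
               mean((tmin + tmax) / 2))
    mh <- with(sh[sh$date >= as.Date(ah$sowing) &
                    sh$date <= as.Date(ah$harvest), ],
               mean((tmin + tmax) / 2))
    expect_gt(mh, mn)
  }
})

test_that("zero noise gives a smooth deterministic series", {
  cfg <- site_fixture()
  ws <- generate_weather("normal", 2020, 1, cfg, noise = 0)
  tmean <- (ws$tmin + ws$tmax) / 2
  # smooth harmonic: small day-to-day steps only
  expect_lt(max(abs(diff(tmean))), 0.6)
  # deterministic schedule: rain on a fixed day-of-year pattern
  expect_identical(ws$precip > 0, (as.integer(format(ws$date, "%j")) %% 3) == 0)
})

test_that("pseudo-observations reproduce the truth at zero noise", {
  cfg <- site_fixture(dz = 2)
  run <- run_season("normal", seed = 3, config = cfg)
  obs <- make_observations(run, noise_model(swc_sd = 0, lai_rel_sd = 0,
                                            biomass_rel_sd = 0,
                                            stage_jitter_days = 0), seed = 1)
  swc15 <- obs[obs$variable == "swc" & obs$depth_cm == 15, ]
  expect_equal(swc15$value, run$daily$theta_15, tolerance = 1e-12)
  lai <- obs[obs$variable == "lai", ]
  expect_true(all(lai$value %in% run$daily$lai))
  # stage dates recorded without jitter
  st <- obs[obs$variable == "stage_flowering", ]
  expect_equal(st$value, run$seasons[[1]]$summary$days_to_flowering)
})

test_that("observation noise has the configured magnitude and seed", {
  cfg <- site_fixture(dz = 2)
  run <- run_season("normal", seed = 3, config = cfg)
  nm <- noise_model(swc_sd = 0.02)
  o1 <- make_observations(run, nm, seed = 5)
  o2 <- make_observations(run, nm, seed = 5)
  expect_identical(o1$value, o2$value)
  swc <- o1[o1$variable == "swc" & o1$depth_cm == 40, ]
  resid <- swc$value - run$daily$theta_40
  # empirical sd within 20% of the nominal 0.02 over >= 300 points
  expect_gte(length(resid), 300)
  expect_lt(abs(sd(resid) - 0.02) / 0.02, 0.2)
})
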