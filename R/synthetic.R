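#' Site configuration for the marginal sandy (Arenosol) barley site
#'
#' Bundles the soil profile (five pedogenetic horizons with measured van
#' Genuchten-Mualem parameters, texture and bulk density), the management
#' calendar of the three experimental seasons (sowing, split ammonium-nitrate
#' fertilization, harvest), site constants and the model parameter defaults.
#' The deepest described horizon (105-120 cm) extends to the 150 cm domain
#' bottom.
#'
#' @param dz Grid cell size (cm), default 1.
#' @param n_rate Season fertilizer rate (kg N ha-1), split 50/50 over the
#'   two application dates.
#' @return List of class `site_config`.
#' @export
site_fixture <- function(dz = 1, n_rate = 100) {
  horizons <- list(
    soil_horizon(0, 30, vg_params(0.0145, 0.419, 0.011, 1.395, 58.87,
                                  pwp_measured = 0.071),
                 bulk_density = 1.47, sand = 45.2, silt = 44.3, clay = 10.5,
                 name = "Ap"),
    soil_horizon(30, 50, vg_params(0.0260, 0.306, 0.033, 1.980, 9.34,
                                   pwp_measured = 0.043),
                 bulk_density = 1.59, sand = 88.0, silt = 7.4, clay = 4.6,
                 name = "B1"),
    soil_horizon(50, 78, vg_params(0.0205, 0.285, 0.040, 3.647, 5.88,
                                   pwp_measured = 0.034),
                 bulk_density = 1.64, sand = 81.9, silt = 11.4, clay = 6.7,
                 name = "B2"),
    soil_horizon(78, 105, vg_params(0.0240, 0.323, 0.088, 2.821, 5.05,
                                    pwp_measured = 0.056),
                 bulk_density = 1.76, sand = 90.9, silt = 5.9, clay = 3.2,
                 name = "2C(k)"),
    soil_horizon(105, 120, vg_params(0.0260, 0.312, 0.047, 4.575, 1.95,
                                     pwp_measured = 0.026),
                 bulk_density = 1.66, sand = 95.4, silt = 2.9, clay = 1.7,
                 name = "2C")
  )
  # mineralizable organic N: total Kjeldahl N of the plough layer
  # (0.103 % of 1.47 g cm-3 x 30 cm = 4410 t ha-1 soil ~ 4540 kg N ha-1)
  org_pool <- 0.103 / 100 * 1.47 * 30 * 1e5  # kg N ha-1
  archetypes <- data.frame(
    label = c("normal", "hot", "wet"),
    year = c(2020L, 2021L, 2022L),
    season_tmean = c(15.9, 18.6, 17.9),   # deg C, sowing -> harvest
    season_precip = c(225.4, 327.8, 346.2),  # mm, sowing -> harvest
    sun_anom = c(0.00, 0.05, -0.02),  # clear-sky fraction anomaly
    sowing = c("2020-04-27", "2021-05-10", "2022-05-04"),
    fert1 = c("2020-04-27", "2021-05-07", "2022-05-03"),
    fert2 = c("2020-06-08", "2021-06-11", "2022-06-06"),
    harvest = c("2020-08-12", "2021-08-13", "2022-08-09"),
    stringsAsFactors = FALSE
  )
  structure(list(
    latitude = 54.588, elevation = 120,
    horizons = horizons, dz = dz, domain_depth = 150,
    sensor_depths = c(15, 40, 60, 90, 110),
    kc = 1.15, k_ext = 0.6, feddes = feddes_default(),
    phen = phenology_params(), crop = crop_params(), npar = n_params(),
    init_h = -200, init_smn = 71.3, init_no3_frac = 0.7,
    init_smn_depth = 30, org_pool = org_pool,
    n_rate = n_rate, archetypes = archetypes,
    spinup_years = 5
  ), class = "site_config")
}

#' Archetype lookup
#' @param config A [site_fixture()] configuration.
#' @param label One of "normal", "hot", "wet".
#' @return One-row data.frame of archetype targets and dates.
#' @export
archetype_info <- function(config, label) {
  a <- config$archetypes[config$archetypes$label == label, ]
  if (nrow(a) != 1) stop("unknown archetype: ", label)
  a
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic full-year daily weather series for one archetype
#'
#' Harmonic annual temperature cycle plus first-order autocorrelated noise;
#' two-state (wet/dry) precipitation occurrence chain with gamma wet-day
#' amounts; solar radiation as a clear-sky envelope damped by cloudiness
#' tied to wet days; bounded autocorrelated relative humidity and wind.
#' After generation, season-window temperatures are shifted and wet-day
#' amounts rescaled so the growing-season means hit the archetype targets
#' (mean temperature within +/- 0.3 deg C by construction, precipitation
#' total within +/- 5 mm).  Full calendar years are produced so that the
#' winter leaching season is simulated.
#'
#' @param archetype "normal", "hot" or "wet".
#' @param year Calendar year the series is labelled with.
#' @param seed Integer seed; identical seeds give identical series.
#' @param config A [site_fixture()] configuration.
#' @param noise Noise amplitude multiplier; 0 gives the smooth harmonic
#'   series with a deterministic precipitation schedule.
#' @return A [weather_series()] covering the full calendar year.
#' @export
generate_weather <- function(archetype, year, seed, config = site_fixture(),
                             noise = 1) {
  a <- archetype_info(config, archetype)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  # season window: archetype management dates transposed to this year
  md <- function(x) as.Date(sprintf("%d-%s", year, substr(x, 6, 10)))
  s0 <- md(a$sowing); s1 <- md(a$harvest)
  in_season <- dates >= s0 & dates <= s1

  with_seed(seed + 1000L * match(archetype, c("normal", "hot", "wet")), {
    harm <- 7.2 + 11.5 * cos(2 * pi * (doy - 201) / 365.25)
    ar1 <- function(n, rho, sd) {
      e <- numeric(n)
      z <- rnorm(n)
      e[1] <- z[1] * sd
      for (i in 2:n) e[i] <- rho * e[i - 1] + sd * sqrt(1 - rho^2) * z[i]
      e
    }
    tmean <- harm + noise * ar1(nd, 0.7, 2.3)

    # precipitation occurrence chain and gamma amounts: infrequent,
    # heavy-tailed summer events (a few large storms drain straight through
    # this sandy profile, which drives the stress regime) but frequent
    # frontal winter precipitation that recharges and leaches the profile
    if (noise > 0) {
      seas <- cos(2 * pi * (doy - 201) / 365.25)  # +1 midsummer, -1 winter
      p01 <- 0.26 - 0.14 * seas
      p11 <- 0.50 - 0.16 * seas
      wet <- logical(nd)
      wet[1] <- runif(1) < 0.3
      for (i in 2:nd)
        wet[i] <- runif(1) < (if (wet[i - 1]) p11[i] else p01[i])
      amt_mean <- 5.5 + 0.9 * seas
      precip <- ifelse(wet, rgamma(nd, shape = 0.7) * amt_mean / 0.7, 0)
    } else {
      wet <- (doy %% 3) == 0
      precip <- ifelse(wet, 5, 0)
    }

    dr <- pmax(5 + 3.5 * cos(2 * pi * (doy - 201) / 365.25), 3) *
      ifelse(wet, 0.65, 1)
    tmin <- tmean - dr / 2
    tmax <- tmean + dr / 2

    ra <- extraterrestrial_radiation(config$latitude, doy)
    tau_dry <- 0.62 + a$sun_anom + noise * 0.10 * ar1(nd, 0.4, 1)
    tau <- ifelse(wet, pmax(0.25, 0.55 * tau_dry), tau_dry)
    srad <- pmax(ra * pmin(pmax(tau, 0.10), 0.78), 0.3)

    rh <- pmin(pmax(76 + ifelse(wet, 10, 0) + noise * ar1(nd, 0.6, 7),
                    40), 98)
    wind <- pmax(3 + noise * ar1(nd, 0.5, 1.1), 0.3)
  })

  # hit the archetype growing-season targets
  tmean_season <- mean((tmin[in_season] + tmax[in_season]) / 2)
  shift <- a$season_tmean - tmean_season
  tmin <- tmin + shift
  tmax <- tmax + shift
  psum <- sum(precip[in_season])
  if (psum <= 0) stop("generate_weather: no season precipitation to scale")
  precip[in_season] <- precip[in_season] * a$season_precip / psum

  weather_series(
    data.frame(date = dates, tmin = tmin, tmax = tmax, rh = rh, wind = wind,
               srad = srad, precip = precip),
    latitude = config$latitude, elevation = config$elevation
  )
}

#' Observation noise model
#' @param swc_sd Absolute SWC noise sd (cm3 cm-3).
#' @param lai_rel_sd Relative LAI noise sd.
#' @param biomass_rel_sd Relative organ-biomass noise sd.
#' @param stage_jitter_days Uniform stage-date jitter half-width (days).
#' @return List of class `noise_model`.
#' @export
noise_model <- function(swc_sd = 0.02, lai_rel_sd = 0.1,
                        biomass_rel_sd = 0.1, stage_jitter_days = 2) {
  stopifnot(swc_sd >= 0, lai_rel_sd >= 0, biomass_rel_sd >= 0,
            stage_jitter_days >= 0)
  structure(list(swc_sd = swc_sd, lai_rel_sd = lai_rel_sd,
                 biomass_rel_sd = biomass_rel_sd,
                 stage_jitter_days = stage_jitter_days),
            class = "noise_model")
}

#' Derive noisy pseudo-observations from a simulation ledger
#'
#' Emulates the study's field data streams: daily soil water content at the
#' five sensor depths, 4-6 in-season LAI and organ biomass samplings, and
#' stage dates (emergence, flowering, maturity), all perturbed per the noise
#' model under the given seed.
#'
#' @param run A [run_simulation()] result (the truth run).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param n_biomass_dates Number of in-season biomass/LAI sampling dates.
#' @return Long data.frame `date,variable,depth_cm,value,sd`.
#' @export
make_observations <- function(run, noise = noise_model(), seed = 1,
                              n_biomass_dates = 5) {
  led <- run$daily
  swc_cols <- grep("^theta_", names(led), value = TRUE)
  depths <- as.numeric(sub("theta_", "", swc_cols))
  with_seed(seed, {
    obs <- do.call(rbind, lapply(seq_along(swc_cols), function(j) {
      v <- led[[swc_cols[j]]]
      data.frame(date = led$date, variable = "swc", depth_cm = depths[j],
                 value = pmax(v + rnorm(length(v), 0, noise$swc_sd), 0.001),
                 sd = noise$swc_sd)
    }))
    seasons <- run$seasons
    for (ss in seasons) {
      win <- led$date >= ss$sowing & led$date <= ss$harvest
      idx <- which(win & led$lai > 0)
      if (length(idx) > 0) {
        pick <- unique(round(seq(min(idx), max(idx),
                                 length.out = n_biomass_dates)))
        for (vv in c("lai", "leaf_t_ha", "stem_t_ha", "grain_t_ha",
                     "tab_t_ha")) {
          rel <- if (vv == "lai") noise$lai_rel_sd else noise$biomass_rel_sd
          val <- led[[vv]][pick]
          obs <- rbind(obs, data.frame(
            date = led$date[pick], variable = vv, depth_cm = NA,
            value = pmax(val * (1 + rnorm(length(pick), 0, rel)), 0),
            sd = rel * pmax(val, 1e-6)))
        }
      }
      for (st in c("emergence", "flowering", "maturity")) {
        d0 <- ss$summary[[paste0("days_to_", st)]]
        if (!is.na(d0)) {
          jit <- if (noise$stage_jitter_days > 0)
            sample(-noise$stage_jitter_days:noise$stage_jitter_days, 1) else 0
          obs <- rbind(obs, data.frame(
            date = ss$sowing + d0 + jit, variable = paste0("stage_", st),
            depth_cm = NA, value = d0 + jit,
            sd = noise$stage_jitter_days))
        }
      }
    }
    obs
  })
}
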