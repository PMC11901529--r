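#' Build a management calendar
#'
#' One row per cropping season with sowing, split fertilization and harvest
#' dates.  For years other than the archetype's own, the archetype's
#' month-day pattern is transposed.
#'
#' @param config A [site_fixture()] configuration.
#' @param years Integer vector of calendar years.
#' @param labels Archetype label per year.
#' @param n_rate Season N rate (kg N ha-1), split 50/50 over the two
#'   application dates.
#' @return Data frame `year,label,sowing,fert1,fert2,harvest,n_rate`.
#' @export
build_management <- function(config, years, labels,
                             n_rate = config$n_rate) {
  stopifnot(length(years) == length(labels))
  rows <- lapply(seq_along(years), function(i) {
    a <- archetype_info(config, labels[i])
    md <- function(x) as.Date(sprintf("%d-%s", years[i], substr(x, 6, 10)))
    data.frame(year = years[i], label = labels[i], sowing = md(a$sowing),
               fert1 = md(a$fert1), fert2 = md(a$fert2),
               harvest = md(a$harvest), n_rate = n_rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the coupled soil-water-crop-nitrogen simulation
#'
#' Daily loop over a contiguous weather series: reference ET and its canopy
#' partition, Richards soil water flow with Feddes root uptake, the soil
#' mineral-N balance with convective nitrate transport, and thermal-time
#' crop growth under switchable water/N stress.  The stress switches
#' disable only the growth reduction; water flow, transpiration and N
#' transport always run, so a potential run still reports drainage and
#' leaching.
#'
#' @param config A [site_fixture()] configuration.
#' @param weather A [weather_series()] (one or more contiguous years).
#' @param management A [build_management()] calendar.
#' @param water_on,n_on Stress switches (both TRUE = actual run).
#' @param init Optional initial state list with elements `h` (per-node
#'   matric head) and `npools` (an `n_pools`), e.g. from [spin_up()].
#' @param control Solver control overrides passed to [richards_step()].
#' @return List of class `run_outputs`: `daily` ledger data.frame, `seasons`
#'   (list with `sowing`, `harvest`, `summary` per season), and
#'   `final_state` for chaining runs.
#' @export
run_simulation <- function(config, weather, management,
                           water_on = TRUE, n_on = TRUE, init = NULL,
                           control = list()) {
  grid <- build_grid(config$horizons, dz = config$dz,
                     domain_depth = config$domain_depth)
  sn <- sensor_nodes(grid, config$sensor_depths)
  nd <- nrow(weather)
  et0 <- et0_series(weather)
  tmean <- (weather$tmin + weather$tmax) / 2

  h <- if (!is.null(init$h)) init$h else rep(config$init_h, grid$n)
  state <- soil_water_state(h, grid)
  npools <- if (!is.null(init$npools)) init$npools else
    n_pools_init(grid, smn = config$init_smn,
                 no3_frac = config$init_no3_frac,
                 smn_depth = config$init_smn_depth,
                 org_pool = config$org_pool)
  n_total0 <- n_total(npools) - npools$cum_fert + npools$cum_uptake +
    npools$cum_leach_bottom + npools$cum_denit
  topsoil <- grid$z <= config$npar$min_depth

  crop <- NULL
  cur_season <- NULL
  seasons <- list()

  # quick lookups for management events
  ev_sow <- setNames(seq_len(nrow(management)), format(management$sowing))
  ev_har <- setNames(seq_len(nrow(management)), format(management$harvest))

  cols <- c("precip", "tmean", "et0", "ep", "tp", "ea", "ta", "alpha",
            "runoff", "drainage", "balance_error",
            paste0("theta_", config$sensor_depths),
            "dvs", "lai", "leaf_t_ha", "stem_t_ha", "grain_t_ha",
            "tab_t_ha", "root_depth",
            "n_demand", "n_uptake_kg_ha", "n_index", "no3_leach_kg_ha",
            "leach_conc_mgN_L", "no3_profile", "nh4_profile", "org_pool",
            "n_balance_error", "n_min_release")
  led <- matrix(NA_real_, nd, length(cols), dimnames = list(NULL, cols))

  for (d in seq_len(nd)) {
    dstr <- format(weather$date[d])

    # --- management: sowing and fertilization
    if (!is.null(ev_sow[dstr]) && !is.na(ev_sow[dstr])) {
      crop <- crop_state_init(config$crop)
      cur_season <- list(row = ev_sow[[dstr]],
                         sowing = weather$date[d], day0 = d)
    }
    mrow <- management[management$fert1 == weather$date[d] |
                         management$fert2 == weather$date[d], ]
    if (nrow(mrow) > 0) {
      npools <- apply_fertilizer(npools, mrow$n_rate[1] / 2, grid,
                                 config$npar)
    }

    # --- crop development
    lai <- 0; root_frac <- numeric(grid$n); tp_on <- FALSE
    if (!is.null(crop)) {
      crop <- dvs_update(crop, tmean[d], config$phen, config$crop)
      crop <- root_advance(crop, tmean[d], config$phen, config$crop)
      if (crop$emerged) {
        lai <- crop$lai
        root_frac <- root_profile(grid, crop$root_depth)
        tp_on <- TRUE
      }
    }

    # --- evapotranspiration demand and soil water
    etp <- partition_et(et0[d], lai, kc = config$kc, k_ext = config$k_ext)
    tp_d <- if (tp_on) etp$tp else 0
    ep_d <- etp$ep + (if (tp_on) 0 else etp$tp)  # bare soil takes it all
    step <- richards_step(state, grid, precip = weather$precip[d],
                          ep = ep_d, tp = tp_d, root_frac = root_frac,
                          feddes = config$feddes, control = control)
    state <- step$state
    alpha_day <- step$alpha_day

    # --- soil nitrogen
    se <- (state$theta - grid$theta_r) / (grid$theta_s - grid$theta_r)
    npools <- mineralize(npools, tmean[d], mean(se[topsoil]), grid,
                         config$npar)
    release <- attr(npools, "release")
    npools <- nitrify(npools, tmean[d], se, config$npar)
    npools <- immobilize(npools, tmean[d], se, grid, config$npar)
    dem <- if (!is.null(crop)) crop_n_demand(crop, config$crop, config$npar)
           else list(demand = 0, deficit = NULL)
    upt <- n_uptake(npools, dem$demand, root_frac, config$npar)
    npools <- upt$pools
    tr <- transport_leach(npools, step$q_int, state$theta, grid, config$npar)
    npools <- tr$pools

    # --- crop growth and N allocation
    n_index_day <- upt$n_index
    if (!is.null(crop) && crop$emerged && crop$alive && crop$dvs < 2) {
      if (upt$uptake > 0 && !is.null(dem$deficit) && sum(dem$deficit) > 0) {
        crop$n_mass <- crop$n_mass +
          upt$uptake * dem$deficit / sum(dem$deficit)
      }
      # post-anthesis grain N not covered by uptake comes from the canopy
      if (crop$dvs >= 1 && !is.null(dem$deficit) && dem$demand > 0) {
        got_grain <- if (sum(dem$deficit) > 0)
          upt$uptake * dem$deficit[["grain"]] / sum(dem$deficit) else 0
        need <- dem$deficit[["grain"]] / config$npar$demand_tau - got_grain
        rem <- n_remobilize(crop, need, config$crop, config$npar)
        crop <- rem$state
        n_index_day <- min(1, (upt$uptake + rem$moved) / dem$demand)
      }
      pot <- potential_growth(0.5 * weather$srad[d], crop$lai, config$crop,
                              tmean = tmean[d])
      act <- apply_stress(pot, alpha_day, n_index_day, water_on, n_on)
      crop <- partition_growth(crop, act, config$crop)
      crop <- lai_update(crop, config$crop)
    }

    # --- ledger
    ntot <- n_total(npools)
    n_err <- ntot - (n_total0 + npools$cum_fert - npools$cum_uptake -
                       npools$cum_leach_bottom - npools$cum_denit)
    led[d, ] <- c(weather$precip[d], tmean[d], et0[d], ep_d, tp_d,
                  step$budget$ea, step$budget$ta, alpha_day,
                  step$budget$runoff, step$budget$drainage,
                  step$budget$balance_error,
                  state$theta[sn],
                  if (!is.null(crop)) crop$dvs else NA_real_,
                  lai,
                  if (!is.null(crop)) crop$biomass[c("leaf", "stem", "grain")]
                  else rep(NA_real_, 3),
                  if (!is.null(crop)) sum(crop$biomass[c("leaf", "stem",
                                                         "grain")])
                  else NA_real_,
                  if (!is.null(crop)) crop$root_depth else NA_real_,
                  dem$demand, upt$uptake, n_index_day,
                  tr$leach$no3_kg_ha, tr$leach$conc_mgN_L,
                  sum(npools$no3), sum(npools$nh4), npools$org,
                  n_err, release)

    # --- harvest
    if (!is.null(ev_har[dstr]) && !is.na(ev_har[dstr]) && !is.null(crop)) {
      win <- cur_season$day0:d
      summ <- harvest(crop, alpha_daily = led[win, "alpha"],
                      n_index_daily = led[win, "n_index"])
      seasons[[length(seasons) + 1]] <- list(
        sowing = cur_season$sowing, harvest = weather$date[d],
        year = management$year[cur_season$row],
        label = management$label[cur_season$row],
        n_rate = management$n_rate[cur_season$row],
        summary = summ)
      # roots and senesced leaves return their N to the organic pool
      npools$org <- npools$org + crop$n_mass[["root"]] + crop$senesced_n
      npools$cum_uptake <- npools$cum_uptake - crop$n_mass[["root"]] -
        crop$senesced_n
      crop <- NULL
      cur_season <- NULL
    }
  }

  daily <- data.frame(date = weather$date, led)
  structure(list(daily = daily, seasons = seasons,
                 final_state = list(h = state$h, npools = npools),
                 config = config),
            class = "run_outputs")
}

#' Spin up the soil water and nitrogen state
#'
#' Runs `years` pre-simulation years looping the three weather archetypes
#' (normal, hot, wet, normal, ...) with the same management and N rate, and
#' returns the end state to initialize the analysis run.
#'
#' @param config A [site_fixture()] configuration.
#' @param start_year First analysis year (spin-up occupies the years
#'   before).
#' @param years Number of spin-up years (>= 0), default 5.
#' @param seed Integer seed for the synthetic weather.
#' @param n_rate Spin-up fertilization rate (kg N ha-1).
#' @param water_on,n_on Stress switches during spin-up.
#' @return List with `h` and `npools` (and the spin-up `run` for
#'   inspection); with `years = 0` the configured initial state.
#' @export
spin_up <- function(config, start_year, years = 5, seed = 1,
                    n_rate = config$n_rate, water_on = TRUE, n_on = TRUE) {
  stopifnot(years >= 0)
  if (years == 0) {
    grid <- build_grid(config$horizons, dz = config$dz,
                       domain_depth = config$domain_depth)
    return(list(h = rep(config$init_h, grid$n),
                npools = n_pools_init(grid, smn = config$init_smn,
                                      no3_frac = config$init_no3_frac,
                                      smn_depth = config$init_smn_depth,
                                      org_pool = config$org_pool),
                run = NULL))
  }
  labels <- rep(c("normal", "hot", "wet"), length.out = years)
  yrs <- seq(start_year - years, start_year - 1)
  ws <- do.call(rbind, lapply(seq_along(yrs), function(i) {
    generate_weather(labels[i], yrs[i], seed, config)
  }))
  ws <- weather_series(ws, config$latitude, config$elevation)
  mgmt <- build_management(config, yrs, labels, n_rate = n_rate)
  run <- run_simulation(config, ws, mgmt, water_on = water_on, n_on = n_on)
  list(h = run$final_state$h, npools = run$final_state$npools, run = run)
}

#' Run one archetype season end to end
#'
#' Convenience wrapper: optional spin-up, then a full calendar year of the
#' archetype's weather with its management, returning the run outputs with
#' the season summary.
#'
#' @param label Archetype label ("normal", "hot", "wet").
#' @param seed Integer seed.
#' @param config A [site_fixture()] configuration.
#' @param n_rate Season N rate (kg N ha-1).
#' @param spinup_years Spin-up length (years), default 0.
#' @param water_on,n_on Stress switches.
#' @param extend_days Days of the following year to append (same archetype
#'   weather), so that the post-season autumn/winter leaching is captured;
#'   0 = calendar year only.
#' @return A `run_outputs` object (one season).
#' @export
run_season <- function(label, seed = 1, config = site_fixture(),
                       n_rate = config$n_rate, spinup_years = 0,
                       water_on = TRUE, n_on = TRUE, extend_days = 0) {
  a <- archetype_info(config, label)
  init <- spin_up(config, a$year, years = spinup_years, seed = seed,
                  n_rate = n_rate, water_on = water_on, n_on = n_on)
  ws <- generate_weather(label, a$year, seed, config)
  if (extend_days > 0) {
    ws2 <- generate_weather(label, a$year + 1, seed, config)
    ws <- weather_series(rbind(ws, ws2[seq_len(min(extend_days, nrow(ws2))), ]),
                         config$latitude, config$elevation)
  }
  mgmt <- build_management(config, a$year, label, n_rate = n_rate)
  run_simulation(config, ws, mgmt, water_on = water_on, n_on = n_on,
                 init = init)
}
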