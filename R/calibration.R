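#' Predicted phenology dates for one season
#'
#' Thermal-time-only simulation of the development stages from a daily mean
#' temperature series starting at sowing.
#'
#' @param phen A [phenology_params()].
#' @param tmean Daily mean temperatures from sowing day onward (deg C).
#' @param crop A [crop_params()].
#' @return Named vector: days after sowing to emergence, flowering,
#'   maturity (NA when not reached within the series).
#' @export
simulate_phenology <- function(phen, tmean, crop = crop_params()) {
  st <- crop_state_init(crop)
  for (t in tmean) {
    st <- dvs_update(st, t, phen, crop)
    if (!is.na(st$maturity_day)) break
  }
  c(emergence = as.numeric(st$emergence_day),
    flowering = as.numeric(st$flowering_day),
    maturity = as.numeric(st$maturity_day))
}

#' Calibrate phenology against observed stage dates
#'
#' Stage 1 of the two-stage protocol: SCE-UA over the thermal sums
#' (emergence, flowering, maturity) minimizing the root-mean-square day
#' error over all stages and seasons.  By default the most
#' climate-contrasting seasons (normal 2020 and wet 2022) are calibrated
#' and the held-out season is reported for validation.
#'
#' @param obs Data frame `year,stage,day` with stage in
#'   `emergence,flowering,maturity` and `day` in days after sowing.
#' @param weather_by_year Named list of [weather_series()] keyed by year.
#' @param config A [site_fixture()] configuration.
#' @param specs Optional list of [param_spec()] over `tt_emerge`,
#'   `tt_flower`, `tt_mature`.
#' @param seed,max_eval SCE-UA controls.
#' @return A `calib_result` with extra fields: `phen` (calibrated
#'   [phenology_params()]), `predicted` (per season), and
#'   `under_determined` flag when only one stage type was observed.
#' @export
calibrate_phenology <- function(obs, weather_by_year, config = site_fixture(),
                                specs = NULL, seed = 1, max_eval = 1500) {
  if (nrow(obs) == 0) stop("calibrate_phenology: no stage observations")
  if (is.null(specs)) {
    specs <- list(param_spec("tt_emerge", 40, 250),
                  param_spec("tt_flower", 400, 1400),
                  param_spec("tt_mature", 250, 1100))
  }
  years <- sort(unique(obs$year))
  seasons <- lapply(years, function(y) {
    a <- config$archetypes[config$archetypes$year == y, ]
    if (nrow(a) != 1) stop("calibrate_phenology: no archetype for year ", y)
    ws <- weather_by_year[[as.character(y)]]
    if (is.null(ws)) stop("calibrate_phenology: no weather for year ", y)
    i0 <- which(ws$date == as.Date(a$sowing))
    if (length(i0) != 1) stop("calibrate_phenology: sowing date not in weather")
    list(year = y, tmean = (ws$tmin + ws$tmax)[i0:nrow(ws)] / 2,
         obs = obs[obs$year == y, ])
  })
  objective <- function(par) {
    phen <- phenology_params(
      tt_emerge = if ("tt_emerge" %in% names(par)) par[["tt_emerge"]]
                  else config$phen$tt_emerge,
      tt_flower = if ("tt_flower" %in% names(par)) par[["tt_flower"]]
                  else config$phen$tt_flower,
      tt_mature = if ("tt_mature" %in% names(par)) par[["tt_mature"]]
                  else config$phen$tt_mature,
      t_base = config$phen$t_base, t_opt = config$phen$t_opt,
      min_emerge_days = config$phen$min_emerge_days)
    err2 <- 0; n <- 0
    for (ss in seasons) {
      pred <- simulate_phenology(phen, ss$tmean, config$crop)
      for (k in seq_len(nrow(ss$obs))) {
        p <- pred[[ss$obs$stage[k]]]
        e <- if (is.na(p)) 150 else p - ss$obs$day[k]
        err2 <- err2 + e^2; n <- n + 1
      }
    }
    sqrt(err2 / n)
  }
  res <- sce_ua(objective, specs, seed = seed, max_eval = max_eval)
  phen <- phenology_params(
    t_base = config$phen$t_base, t_opt = config$phen$t_opt,
    tt_emerge = if ("tt_emerge" %in% names(res$par)) res$par[["tt_emerge"]]
                else config$phen$tt_emerge,
    tt_flower = if ("tt_flower" %in% names(res$par)) res$par[["tt_flower"]]
                else config$phen$tt_flower,
    tt_mature = if ("tt_mature" %in% names(res$par)) res$par[["tt_mature"]]
                else config$phen$tt_mature,
    min_emerge_days = config$phen$min_emerge_days)
  res$phen <- phen
  res$predicted <- lapply(seasons, function(ss)
    c(year = ss$year, simulate_phenology(phen, ss$tmean, config$crop)))
  res$under_determined <- length(unique(obs$stage)) < 2
  res
}

#' Calibrate per-horizon saturated conductivity against soil water content
#'
#' Stage 2 of the protocol: all laboratory hydraulic parameters are held at
#' their measured values and only Ks is inversely estimated, per horizon, in
#' log10 space over \[0.1, 1000\] cm d-1.  The objective is the pooled RMSE
#' of simulated vs observed water content across the sensor depths.  Crop
#' parameters are held fixed: the full model is run once at the reference
#' Ks to record the season's surface forcing (net infiltration demand,
#' potential evaporation and transpiration, root profiles), and each SCE-UA
#' evaluation reruns the soil water column under that forcing.
#'
#' @param obs Long data.frame `date,variable,depth_cm,value` with
#'   `variable == "swc"` rows at the sensor depths.
#' @param config A [site_fixture()] configuration.
#' @param weather A [weather_series()] covering the observation window.
#' @param management A [build_management()] calendar for the same window.
#' @param bounds Ks search bounds (cm d-1).
#' @param seed,max_eval SCE-UA controls.
#' @param horizons Indices of the horizons to calibrate (default: all).
#' @return A `calib_result` with extra fields `ks` (named per horizon,
#'   cm d-1), `fit_by_depth` (d, RMSE, BIAS per sensor depth at the
#'   optimum), and `reference_run`.
#' @export
calibrate_ks <- function(obs, config, weather, management,
                         bounds = c(0.1, 1000), seed = 1, max_eval = 2000,
                         horizons = seq_along(config$horizons)) {
  swc <- obs[obs$variable == "swc", ]
  if (nrow(swc) == 0) stop("calibrate_ks: no soil water content observations")
  grid <- build_grid(config$horizons, dz = config$dz,
                     domain_depth = config$domain_depth)
  depths <- sort(unique(swc$depth_cm))
  nodes <- sensor_nodes(grid, depths)
  if (any(abs(grid$z[nodes] - depths) > grid$dz))
    stop("calibrate_ks: observation depth with no matching grid node")

  ref <- run_simulation(config, weather, management)
  led <- ref$daily
  day_of <- match(as.Date(swc$date), led$date)
  if (anyNA(day_of))
    stop("calibrate_ks: observation dates outside the simulated window")
  di <- match(swc$depth_cm, depths)

  nd_obj <- max(day_of)  # nothing after the last observation matters
  root_mat <- vapply(seq_len(nd_obj), function(d) {
    rd <- led$root_depth[d]
    if (is.na(rd) || rd <= 0) numeric(grid$n) else root_profile(grid, rd)
  }, numeric(grid$n))
  rain_cm <- weather$precip[seq_len(nd_obj)] / 10
  ep_cm <- led$ep[seq_len(nd_obj)] / 10
  tp_cm <- led$tp[seq_len(nd_obj)] / 10
  h0 <- rep(config$init_h, grid$n)

  run_theta <- function(ks_by_horizon, fast = TRUE) {
    ksn <- ks_by_horizon_to_nodes(config, grid, ks_by_horizon, horizons)
    # coarser step floor during the search: poor candidates fail fast
    out <- .richards_run_cpp(h0, grid$theta_r, grid$theta_s, grid$alpha,
                             grid$vg_n, ksn, grid$dz, rain_cm, ep_cm, tp_cm,
                             root_mat, config$feddes, as.integer(nodes),
                             dt_min = if (fast) 1e-3 else 1e-4,
                             max_substeps = if (fast) 1500L else 4000L)
    out$theta
  }
  objective <- function(par) {
    # extreme Ks combinations can defeat the flow solver; score them out
    th <- tryCatch(run_theta(unname(par)), error = function(e) NULL)
    if (is.null(th)) return(1e3)
    sim <- th[cbind(di, day_of)]
    sqrt(mean((sim - swc$value)^2))
  }
  specs <- lapply(horizons, function(i)
    param_spec(paste0("ks_", i), bounds[1], bounds[2], "log10"))
  res <- sce_ua(objective, specs, seed = seed, max_eval = max_eval)
  res$ks <- setNames(unname(res$par),
                     vapply(config$horizons[horizons], `[[`, character(1),
                            "name"))
  th_opt <- run_theta(unname(res$par))
  res$fit_by_depth <- do.call(rbind, lapply(seq_along(depths), function(j) {
    sel <- di == j
    fit_stats(th_opt[cbind(di[sel], day_of[sel])], swc$value[sel],
              variable = sprintf("SWC at %g cm", depths[j]))
  }))
  res$reference_run <- ref
  res
}

ks_by_horizon_to_nodes <- function(config, grid, ks_values, horizons) {
  ks_h <- vapply(config$horizons, function(h) h$vg$ks, numeric(1))
  ks_h[horizons] <- ks_values
  ks_h[grid$horizon]
}

#' Two-stage calibration protocol
#'
#' Enforces the calibration order: phenology first (crop development), then
#' soil hydraulics (per-horizon Ks) with crop parameters held fixed.
#'
#' @param obs_stages Stage-date observations for [calibrate_phenology()].
#' @param obs_swc Soil water content observations for [calibrate_ks()].
#' @param weather_by_year Named list of [weather_series()] keyed by year.
#' @param config A [site_fixture()] configuration.
#' @param seed Integer seed.
#' @param max_eval_phen,max_eval_ks Evaluation budgets.
#' @return List with `phenology` and `ks` calibration results and the
#'   updated `config`.
#' @export
calibrate_site <- function(obs_stages, obs_swc, weather_by_year,
                           config = site_fixture(), seed = 1,
                           max_eval_phen = 1500, max_eval_ks = 2000) {
  phen_res <- calibrate_phenology(obs_stages, weather_by_year, config,
                                  seed = seed, max_eval = max_eval_phen)
  config$phen <- phen_res$phen
  years <- sort(unique(as.integer(format(as.Date(obs_swc$date), "%Y"))))
  ws <- do.call(rbind, weather_by_year[as.character(years)])
  ws <- weather_series(ws, config$latitude, config$elevation)
  labels <- vapply(years, function(y)
    config$archetypes$label[config$archetypes$year == y], character(1))
  mgmt <- build_management(config, years, labels)
  ks_res <- calibrate_ks(obs_swc, config, ws, mgmt, seed = seed,
                         max_eval = max_eval_ks)
  list(phenology = phen_res, ks = ks_res, config = config)
}
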