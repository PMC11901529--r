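#' Default spring-barley phenology parameters
#'
#' Thermal-time development on the DVS scale: 0 at emergence, 1 at flowering,
#' 2 at physiological maturity.  Thermal sums are degree-days above `t_base`.
#' Defaults are standard spring-barley values chosen so that, under the
#' region's season temperatures, emergence takes 7-10 days and flowering /
#' maturity fall 56-68 / 92-104 days after sowing.
#'
#' @param t_base Base temperature (deg C).
#' @param t_opt Optimum temperature (deg C): daily thermal time is
#'   `min(tmean, t_opt) - t_base`, so development does not keep
#'   accelerating in hot spells.
#' @param tt_emerge Thermal sum sowing -> emergence (deg C d).
#' @param tt_flower Thermal sum emergence -> DVS 1 (deg C d).
#' @param tt_mature Thermal sum DVS 1 -> DVS 2 (deg C d).
#' @param min_emerge_days Minimum calendar days sowing -> emergence.
#' @return List of class `phenology_params`.
#' @export
phenology_params <- function(t_base = 0, t_opt = 15, tt_emerge = 100,
                             tt_flower = 760, tt_mature = 500,
                             min_emerge_days = 7) {
  stopifnot(tt_emerge > 0, tt_flower > 0, tt_mature > 0, t_base < 15,
            t_opt > t_base)
  structure(list(t_base = t_base, t_opt = t_opt, tt_emerge = tt_emerge,
                 tt_flower = tt_flower, tt_mature = tt_mature,
                 min_emerge_days = min_emerge_days),
            class = "phenology_params")
}

#' Daily effective thermal time
#' @param tmean Daily mean temperature (deg C).
#' @param phen A [phenology_params()].
#' @return Degree-days (>= 0), capped at `t_opt - t_base`.
#' @export
thermal_time_day <- function(tmean, phen) {
  pmax(pmin(tmean, phen$t_opt) - phen$t_base, 0)
}

#' Default spring-barley crop growth parameters
#'
#' Radiation-use-efficiency growth: gross daily biomass gain is
#' `rue * radiation * (1 - exp(-k_ext * lai))` where the radiation fed in by
#' the simulation engine is intercepted photosynthetically active radiation
#' (0.5 x global solar).  The DVS-indexed partition table routes growth to
#' leaf/stem/grain/root (rows sum to 1; grain receives nothing before
#' DVS 1).  Leaf senescence is first-order from `sen_start_dvs` onward.
#'
#' @param rue Radiation use efficiency (g DM per MJ intercepted PAR).
#' @param tg_base,tg_opt Temperature response of assimilation: the daily
#'   growth factor ramps linearly from 0 at `tg_base` (deg C) to 1 at
#'   `tg_opt`, flat above.
#' @param k_ext Canopy extinction coefficient.
#' @param sla Specific leaf area (ha kg-1; 0.002 ha kg-1 = 20 m2 kg-1).
#' @param partition Data frame with columns `dvs,leaf,stem,grain,root`.
#' @param sen_start_dvs DVS at which leaf senescence starts.
#' @param sen_rate First-order leaf senescence rate (d-1).
#' @param max_root_depth Maximum rooting depth (cm), <= 120.
#' @param root_rate Root deepening rate (cm per deg C d).
#' @param init_root_depth Rooting depth at emergence (cm).
#' @param init_leaf Leaf biomass at emergence (t DM ha-1).
#' @param n_conc Data frame of organ target N concentrations (%) indexed by
#'   DVS, columns `dvs,leaf,stem,grain,root` (linearly interpolated).
#' @return List of class `crop_params`.
#' @export
crop_params <- function(
    rue = 2.7, k_ext = 0.6, sla = 0.002,
    tg_base = 3, tg_opt = 17,
    partition = data.frame(
      dvs   = c(0.0, 0.5, 1.0, 1.3, 2.0),
      leaf  = c(0.60, 0.40, 0.06, 0.00, 0.00),
      stem  = c(0.15, 0.40, 0.44, 0.10, 0.00),
      grain = c(0.00, 0.00, 0.40, 0.90, 1.00),
      root  = c(0.25, 0.20, 0.10, 0.00, 0.00)),
    sen_start_dvs = 1.3, sen_rate = 0.04,
    max_root_depth = 110, root_rate = 0.10, init_root_depth = 5,
    init_leaf = 0.005,
    n_conc = data.frame(
      dvs   = c(0, 1, 2),
      leaf  = c(3.0, 2.2, 1.2),
      stem  = c(1.5, 0.9, 0.4),
      grain = c(2.36, 2.36, 2.36),
      root  = c(1.0, 0.8, 0.7))) {
  rs <- rowSums(partition[, c("leaf", "stem", "grain", "root")])
  if (any(abs(rs - 1) > 1e-9))
    stop("crop_params: partition rows must sum to 1")
  if (any(partition$grain[partition$dvs < 1] > 0))
    stop("crop_params: grain fraction must be 0 before DVS 1")
  if (max_root_depth > 120)
    stop("crop_params: max_root_depth must be <= 120 cm")
  structure(list(rue = rue, tg_base = tg_base, tg_opt = tg_opt,
                 k_ext = k_ext, sla = sla, partition = partition,
                 sen_start_dvs = sen_start_dvs, sen_rate = sen_rate,
                 max_root_depth = max_root_depth, root_rate = root_rate,
                 init_root_depth = init_root_depth, init_leaf = init_leaf,
                 n_conc = n_conc),
            class = "crop_params")
}

#' Initial crop state at sowing
#' @param params A [crop_params()].
#' @return List of class `crop_state`: development stage `dvs`, thermal-time
#'   accumulators, `lai`, organ biomass pools (t DM ha-1), organ N masses
#'   (kg N ha-1), rooting depth (cm) and bookkeeping totals.
#' @export
crop_state_init <- function(params = crop_params()) {
  structure(list(
    sown = TRUE, emerged = FALSE, alive = TRUE,
    days_since_sowing = 0, tt_sowing = 0, dvs = 0,
    lai = 0, root_depth = 0,
    biomass = c(leaf = 0, stem = 0, grain = 0, root = 0),
    n_mass = c(leaf = 0, stem = 0, grain = 0, root = 0),
    cum_growth = 0, cum_senesced = 0, senesced_leaf = 0, senesced_n = 0,
    flowering_day = NA_integer_, maturity_day = NA_integer_,
    emergence_day = NA_integer_
  ), class = "crop_state")
}

#' Advance crop development by one day of thermal time
#'
#' Before emergence, degree-days accumulate toward `tt_emerge` (gated by the
#' minimum emergence duration); afterwards DVS advances by
#' `max(tmean - t_base, 0) / tt_stage` per day, capped at 2.
#'
#' @param state A `crop_state`.
#' @param tmean Daily mean air temperature (deg C).
#' @param phen A [phenology_params()].
#' @param crop A [crop_params()] (for initial leaf/root at emergence).
#' @return Updated state.
#' @export
dvs_update <- function(state, tmean, phen, crop = crop_params()) {
  if (!state$alive) return(state)
  state$days_since_sowing <- state$days_since_sowing + 1
  dd <- thermal_time_day(tmean, phen)
  if (!state$emerged) {
    state$tt_sowing <- state$tt_sowing + dd
    if (state$tt_sowing >= phen$tt_emerge - 1e-9 &&
        state$days_since_sowing >= phen$min_emerge_days) {
      state$emerged <- TRUE
      state$emergence_day <- state$days_since_sowing
      # thermal time beyond the emergence sum already drives development
      state$dvs <- (state$tt_sowing - phen$tt_emerge) / phen$tt_flower
      state$biomass["leaf"] <- crop$init_leaf
      state$cum_growth <- state$cum_growth + crop$init_leaf  # seed reserves
      state$lai <- crop$init_leaf * 1000 * crop$sla
      state$root_depth <- crop$init_root_depth
    }
    return(state)
  }
  if (state$dvs < 1) {
    state$dvs <- state$dvs + dd / phen$tt_flower
    if (state$dvs >= 1 - 1e-9 && is.na(state$flowering_day)) {
      state$dvs <- max(state$dvs, 1)
      # convert the overshoot beyond DVS 1 to the post-anthesis scale
      state$dvs <- 1 + (state$dvs - 1) * phen$tt_flower / phen$tt_mature
      state$flowering_day <- state$days_since_sowing
    }
  } else {
    state$dvs <- state$dvs + dd / phen$tt_mature
  }
  if (state$dvs >= 2 - 1e-9 && is.na(state$maturity_day)) {
    state$dvs <- 2
    state$maturity_day <- state$days_since_sowing
  }
  state$dvs <- min(state$dvs, 2)
  state
}

#' Gross (unstressed) daily biomass increment
#'
#' `rue * rad * (1 - exp(-k_ext * lai))`, converted from g m-2 to t ha-1.
#' `rad` is the radiation the efficiency refers to (the engine passes
#' intercepted-PAR-basis radiation, 0.5 x global).
#'
#' @param rad Radiation (MJ m-2 d-1), >= 0.
#' @param lai Leaf area index, >= 0.
#' @param params A [crop_params()].
#' @param tmean Optional daily mean temperature (deg C) for the assimilation
#'   temperature factor; omitted = no temperature limitation.
#' @return Biomass increment (t DM ha-1 d-1).
#' @export
potential_growth <- function(rad, lai, params = crop_params(), tmean = NULL) {
  stopifnot(rad >= 0, lai >= 0)
  ft <- if (is.null(tmean)) 1 else
    min(max((tmean - params$tg_base) / (params$tg_opt - params$tg_base), 0), 1)
  gain_g_m2 <- params$rue * ft * rad * (1 - exp(-params$k_ext * lai))
  gain_g_m2 / 100  # g m-2 -> t ha-1
}

#' Apply abiotic stress to potential growth
#'
#' Liebig-style minimum of the water and nitrogen availability indices, with
#' independent switches so that potential / water-limited / N-limited /
#' actual runs share one code path.
#'
#' @param growth_pot Potential growth (t DM ha-1 d-1).
#' @param alpha_day Water availability index in \[0, 1\].
#' @param n_index_day N availability index in \[0, 1\].
#' @param water_on,n_on Stress switches.
#' @return Actual growth (t DM ha-1 d-1).
#' @export
apply_stress <- function(growth_pot, alpha_day, n_index_day,
                         water_on = TRUE, n_on = TRUE) {
  stopifnot(alpha_day >= 0, alpha_day <= 1, n_index_day >= 0, n_index_day <= 1)
  f <- min(if (water_on) alpha_day else 1, if (n_on) n_index_day else 1)
  growth_pot * f
}

#' DVS-interpolated organ partition fractions
#'
#' Linear interpolation of the partition table, with the grain fraction
#' forced to 0 before DVS 1 (the pre-anthesis share is reassigned to stem).
#'
#' @param dvs Development stage in \[0, 2\].
#' @param params A [crop_params()].
#' @return Named numeric vector (leaf, stem, grain, root) summing to 1.
#' @export
partition_fractions <- function(dvs, params = crop_params()) {
  if (dvs < 0 || dvs > 2) stop("partition_fractions: dvs outside [0, 2]")
  tab <- params$partition
  f <- vapply(c("leaf", "stem", "grain", "root"), function(org) {
    approx(tab$dvs, tab[[org]], xout = dvs, rule = 2)$y
  }, numeric(1))
  if (dvs < 1 && f["grain"] > 0) {
    f["stem"] <- f["stem"] + f["grain"]
    f["grain"] <- 0
  }
  f / sum(f)
}

#' Partition actual growth to the organ pools
#' @param state A `crop_state`.
#' @param growth_act Actual growth (t DM ha-1 d-1).
#' @param params A [crop_params()].
#' @return Updated state (`cum_growth` includes the increment).
#' @export
partition_growth <- function(state, growth_act, params = crop_params()) {
  f <- partition_fractions(state$dvs, params)
  state$biomass <- state$biomass + growth_act * f
  state$cum_growth <- state$cum_growth + growth_act
  state
}

#' Update LAI from the leaf pool with first-order senescence
#'
#' Senesced leaf mass leaves the green leaf pool (and its area) but is
#' remembered for the carbon balance.
#'
#' @param state A `crop_state`.
#' @param params A [crop_params()].
#' @return Updated state.
#' @export
lai_update <- function(state, params = crop_params()) {
  if (state$dvs >= params$sen_start_dvs && state$biomass["leaf"] > 0) {
    loss <- params$sen_rate * state$biomass["leaf"]
    # senescing leaves keep structural N; only the mass leaves the pool
    n_conc_leaf <- if (state$biomass["leaf"] > 0)
      state$n_mass["leaf"] / (state$biomass["leaf"] * 1000) else 0
    state$biomass["leaf"] <- state$biomass["leaf"] - loss
    state$n_mass["leaf"] <- state$n_mass["leaf"] - n_conc_leaf * loss * 1000
    state$cum_senesced <- state$cum_senesced + loss
    state$senesced_leaf <- state$senesced_leaf + loss
    state$senesced_n <- state$senesced_n + n_conc_leaf * loss * 1000
  }
  state$lai <- max(0, state$biomass[["leaf"]] * 1000 * params$sla)
  state
}

#' Advance rooting depth with thermal time
#' @param state A `crop_state`.
#' @param tmean Daily mean temperature (deg C).
#' @param phen A [phenology_params()].
#' @param params A [crop_params()].
#' @return Updated state; depth capped at `max_root_depth` and frozen after
#'   flowering.
#' @export
root_advance <- function(state, tmean, phen, params = crop_params()) {
  if (!state$emerged || state$dvs >= 1) return(state)
  dd <- thermal_time_day(tmean, phen)
  state$root_depth <- min(state$root_depth + params$root_rate * dd,
                          params$max_root_depth)
  state
}

#' Season summary at harvest
#'
#' @param state A `crop_state` at harvest.
#' @param alpha_daily Daily water availability indices over the season.
#' @param n_index_daily Daily N availability indices over the season.
#' @return List of class `season_summary`: grain yield and total aboveground
#'   biomass (t DM ha-1), phenology dates (days after sowing), season mean
#'   stress indices and organ N masses (kg N ha-1).
#' @export
harvest <- function(state, alpha_daily = 1, n_index_daily = 1) {
  if (!state$emerged) stop("harvest: harvest before emergence")
  tab <- unname(state$biomass["leaf"] + state$biomass["stem"] +
                  state$biomass["grain"])
  structure(list(
    grain_yield = unname(state$biomass["grain"]),
    tab = tab,
    leaf = unname(state$biomass["leaf"]),
    stem = unname(state$biomass["stem"]),
    root = unname(state$biomass["root"]),
    dvs = state$dvs,
    days_to_flowering = state$flowering_day,
    days_to_maturity = state$maturity_day,
    days_to_emergence = state$emergence_day,
    alpha_avg = season_alpha(alpha_daily),
    n_index_avg = season_alpha(n_index_daily),
    n_uptake = state$n_mass,
    n_uptake_total = sum(state$n_mass)
  ), class = "season_summary")
}
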