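#' Soil nitrogen cycle parameters
#'
#' A first-order mineral-N balance standing in for a full soil organic
#' matter model: one mineralizable organic pool feeding NH4, first-order
#' nitrification NH4 -> NO3, demand-driven root-zone extraction, and
#' convective NO3 transport with the Richards water fluxes.  NH4 is treated
#' as sorbed (immobile); denitrification is off by default (sandy, aerobic
#' profile).
#'
#' Rate modifiers: temperature factor Q10^((T - t_ref)/10) and a trapezoidal
#' moisture factor on effective saturation (0 below `se_dry`, rising to 1 at
#' `se_opt_lo`, 1 up to `se_opt_hi`, falling to `f_sat` at saturation).
#'
#' @param k_min First-order mineralization rate of the organic pool at
#'   `t_ref` and optimal moisture (d-1).
#' @param q10 Temperature sensitivity (-).
#' @param t_ref Reference temperature (deg C).
#' @param se_dry,se_opt_lo,se_opt_hi,f_sat Moisture-factor break points.
#' @param k_nit First-order nitrification rate (d-1).
#' @param k_imm First-order microbial immobilization rate of topsoil
#'   mineral N back into the organic pool (d-1); competes with crop uptake
#'   for fertilizer N, which is why apparent recovery stays well below 1.
#' @param k_denit First-order denitrification rate (d-1), default 0.
#' @param fert_depth Fertilizer incorporation depth (cm).
#' @param fert_nh4_frac NH4 share of fertilizer N (ammonium nitrate: 0.5).
#' @param min_depth Depth over which mineralized N enters the profile (cm).
#' @param uptake_frac Maximum fraction of a rooted node's mineral N
#'   extractable per day (d-1).
#' @param demand_tau Time constant for relaxing the crop N deficit (d).
#' @param remob_rate Maximum fraction of the mobilizable vegetative N that
#'   can be retranslocated to the grain per day (d-1).
#' @param leach_depth Reporting depth for nitrate leaching (cm).
#' @return List of class `n_params`.
#' @export
n_params <- function(k_min = 8e-5, q10 = 2, t_ref = 20,
                     se_dry = 0.1, se_opt_lo = 0.5, se_opt_hi = 0.9,
                     f_sat = 0.5, k_nit = 0.05, k_imm = 0.008, k_denit = 0,
                     fert_depth = 10, fert_nh4_frac = 0.5, min_depth = 30,
                     uptake_frac = 0.08, demand_tau = 3, remob_rate = 0.1,
                     leach_depth = 120) {
  structure(as.list(environment()), class = "n_params")
}

#' Temperature modifier for soil N transformations
#' @param tmean Soil/air temperature (deg C).
#' @param params An [n_params()].
#' @return Q10 factor, 1 at the reference temperature.
#' @export
n_f_temp <- function(tmean, params = n_params()) {
  params$q10^((tmean - params$t_ref) / 10)
}

#' Moisture modifier for soil N transformations
#' @param se Effective saturation in \[0, 1\].
#' @param params An [n_params()].
#' @return Trapezoidal factor in \[0, 1\].
#' @export
n_f_moist <- function(se, params = n_params()) {
  p <- params
  ifelse(se <= p$se_dry, 0,
  ifelse(se < p$se_opt_lo, (se - p$se_dry) / (p$se_opt_lo - p$se_dry),
  ifelse(se <= p$se_opt_hi, 1,
         1 - (1 - p$f_sat) * (se - p$se_opt_hi) / (1 - p$se_opt_hi))))
}

#' Initialize the soil mineral and organic N pools
#'
#' @param grid A [build_grid()] grid.
#' @param smn Initial soil mineral N (kg N ha-1) distributed uniformly over
#'   the top `smn_depth` cm.
#' @param no3_frac NO3 share of the initial mineral N.
#' @param smn_depth Depth of the initial mineral N (cm).
#' @param org_pool Mineralizable organic N pool (kg N ha-1).
#' @return List of class `n_pools`: per-node `no3`, `nh4` (kg N ha-1) and
#'   scalar `org`, plus cumulative ledgers used by the mass-balance audit.
#' @export
n_pools_init <- function(grid, smn = 71.3, no3_frac = 0.7, smn_depth = 30,
                         org_pool = 4500) {
  w <- pmin(pmax(smn_depth / grid$dz - (seq_len(grid$n) - 1), 0), 1)
  w <- w / sum(w)
  structure(list(
    no3 = smn * no3_frac * w,
    nh4 = smn * (1 - no3_frac) * w,
    org = org_pool,
    cum_fert = 0, cum_min = 0, cum_uptake = 0, cum_leach_bottom = 0,
    cum_leach_report = 0, cum_denit = 0
  ), class = "n_pools")
}

#' Total profile mineral + organic N (kg N ha-1)
#' @param pools An `n_pools` object.
#' @return Scalar mass.
#' @export
n_total <- function(pools) sum(pools$no3) + sum(pools$nh4) + pools$org

#' Daily mineralization of the organic pool
#'
#' First-order release `k_min * pool * fT * ftheta` into NH4 over the top
#' `min_depth` cm; the organic pool is decremented.
#'
#' @param pools An `n_pools`.
#' @param tmean Daily mean temperature (deg C).
#' @param se_topsoil Mean effective saturation of the topsoil.
#' @param grid A [build_grid()] grid.
#' @param params An [n_params()].
#' @return Updated pools; attribute `release` holds the day's flux
#'   (kg N ha-1 d-1).
#' @export
mineralize <- function(pools, tmean, se_topsoil, grid, params = n_params()) {
  release <- params$k_min * pools$org * n_f_temp(tmean, params) *
    n_f_moist(se_topsoil, params)
  release <- min(release, pools$org)
  w <- pmin(pmax(params$min_depth / grid$dz - (seq_len(grid$n) - 1), 0), 1)
  w <- w / sum(w)
  pools$nh4 <- pools$nh4 + release * w
  pools$org <- pools$org - release
  pools$cum_min <- pools$cum_min + release
  attr(pools, "release") <- release
  pools
}

#' Daily microbial immobilization of topsoil mineral N
#'
#' First-order transfer of NO3 and NH4 in the biologically active topsoil
#' (`min_depth`) into the organic pool, with the same temperature/moisture
#' modifiers as mineralization.  Total profile N is conserved.
#'
#' @param pools An `n_pools`.
#' @param tmean Daily mean temperature (deg C).
#' @param se Per-node effective saturation.
#' @param grid A [build_grid()] grid.
#' @param params An [n_params()].
#' @return Updated pools.
#' @export
immobilize <- function(pools, tmean, se, grid, params = n_params()) {
  if (params$k_imm <= 0) return(pools)
  rate <- params$k_imm * n_f_temp(tmean, params) * n_f_moist(se, params)
  rate <- pmin(rate, 1)
  top <- grid$z <= params$min_depth
  dn <- pools$no3 * rate * top
  da <- pools$nh4 * rate * top
  pools$no3 <- pools$no3 - dn
  pools$nh4 <- pools$nh4 - da
  pools$org <- pools$org + sum(dn) + sum(da)
  pools
}

#' Daily nitrification NH4 -> NO3
#'
#' First-order in NH4 with the same temperature/moisture modifiers;
#' conserves total mineral N exactly.
#'
#' @param pools An `n_pools`.
#' @param tmean Daily mean temperature (deg C).
#' @param se Per-node effective saturation (or a scalar).
#' @param params An [n_params()].
#' @return Updated pools.
#' @export
nitrify <- function(pools, tmean, se, params = n_params()) {
  rate <- params$k_nit * n_f_temp(tmean, params) * n_f_moist(se, params)
  transfer <- pmin(pools$nh4, pools$nh4 * rate)
  pools$nh4 <- pools$nh4 - transfer
  pools$no3 <- pools$no3 + transfer
  pools
}

#' Apply a fertilizer event
#'
#' Ammonium-nitrate stoichiometry: the dose is split `fert_nh4_frac` /
#' `1 - fert_nh4_frac` between NH4 and NO3 and mixed into the top
#' `fert_depth` cm.
#'
#' @param pools An `n_pools`.
#' @param amount Dose (kg N ha-1), >= 0.
#' @param grid A [build_grid()] grid.
#' @param params An [n_params()].
#' @return Updated pools.
#' @export
apply_fertilizer <- function(pools, amount, grid, params = n_params()) {
  if (amount < 0) stop("apply_fertilizer: negative amount")
  if (amount == 0) return(pools)
  w <- pmin(pmax(params$fert_depth / grid$dz - (seq_len(grid$n) - 1), 0), 1)
  w <- w / sum(w)
  pools$nh4 <- pools$nh4 + amount * params$fert_nh4_frac * w
  pools$no3 <- pools$no3 + amount * (1 - params$fert_nh4_frac) * w
  pools$cum_fert <- pools$cum_fert + amount
  pools
}

#' Daily crop nitrogen demand
#'
#' Deficit between DVS-dependent target organ N concentrations and current
#' organ N mass, relaxed over `demand_tau` days; floored at zero per organ
#' and zero at maturity.
#'
#' @param state A `crop_state`.
#' @param crop A [crop_params()].
#' @param params An [n_params()].
#' @return List with `demand` (kg N ha-1 d-1) and per-organ `deficit`
#'   (kg N ha-1).
#' @export
crop_n_demand <- function(state, crop = crop_params(), params = n_params()) {
  organs <- c("leaf", "stem", "grain", "root")
  if (!state$emerged || state$dvs >= 2) {
    z <- setNames(numeric(4), organs)
    return(list(demand = 0, deficit = z))
  }
  tab <- crop$n_conc
  deficit <- vapply(organs, function(org) {
    target_pct <- approx(tab$dvs, tab[[org]], xout = state$dvs, rule = 2)$y
    max(0, target_pct / 100 * state$biomass[[org]] * 1000 - state$n_mass[[org]])
  }, numeric(1))
  list(demand = sum(deficit) / params$demand_tau, deficit = deficit)
}

#' Demand-driven crop N uptake from the rooted profile
#'
#' Supply per rooted node is capped at `uptake_frac` of its mineral N per
#' day; realized uptake is `min(demand, supply)`, removed proportionally to
#' nodal availability (NO3 and NH4 in proportion to their pools).  The N
#' availability index is uptake/demand, defined as 1 when demand is zero.
#'
#' @param pools An `n_pools`.
#' @param demand Crop demand (kg N ha-1 d-1), >= 0.
#' @param root_frac Per-node root density fractions.
#' @param params An [n_params()].
#' @return List with updated `pools`, realized `uptake` (kg N ha-1 d-1) and
#'   `n_index` in \[0, 1\].
#' @export
n_uptake <- function(pools, demand, root_frac, params = n_params()) {
  stopifnot(demand >= 0)
  if (demand == 0) return(list(pools = pools, uptake = 0, n_index = 1))
  rooted <- root_frac > 0
  avail <- numeric(length(root_frac))
  avail[rooted] <- params$uptake_frac *
    (pools$no3[rooted] + pools$nh4[rooted])
  supply <- sum(avail)
  uptake <- min(demand, supply)
  if (uptake > 0) {
    take <- avail / supply * uptake
    tot <- pools$no3 + pools$nh4
    share_no3 <- ifelse(tot > 0, pools$no3 / pmax(tot, 1e-300), 0)
    pools$no3 <- pmax(pools$no3 - take * share_no3, 0)
    pools$nh4 <- pmax(pools$nh4 - take * (1 - share_no3), 0)
    pools$cum_uptake <- pools$cum_uptake + uptake
  }
  list(pools = pools, uptake = uptake, n_index = uptake / demand)
}

#' Convective nitrate transport and leaching
#'
#' Explicit upwind advection of NO3 with the day's mean interface water
#' fluxes, sub-stepped to respect the Courant limit.  Rain carries no N in;
#' leaching is recorded at `leach_depth` (flux and flow-weighted
#' concentration) and the bottom outflow feeds the profile mass balance.
#'
#' @param pools An `n_pools`.
#' @param q_int Mean interface fluxes from [richards_step()] (mm d-1,
#'   positive downward, length n+1).
#' @param theta Per-node water content (cm3 cm-3) used as mobile water.
#' @param grid A [build_grid()] grid.
#' @param params An [n_params()].
#' @param dt_days Step length (days), default 1.
#' @return List with updated `pools` and `leach` record: `water_mm`,
#'   `no3_kg_ha` (flux across `leach_depth` per day) and `conc_mgN_L`
#'   (100 x kg ha-1 / mm; 0 when no downward flow).
#' @export
transport_leach <- function(pools, q_int, theta, grid, params = n_params(),
                            dt_days = 1) {
  n <- grid$n
  dz_mm <- grid$dz * 10
  q <- q_int  # mm d-1
  j_rep <- round(params$leach_depth / grid$dz) + 1  # interface index
  j_rep <- min(j_rep, n + 1)
  # Courant-limited sub-stepping on mobile water volume per cell (mm)
  vol <- pmax(theta, 1e-4) * dz_mm
  courant <- max(abs(q[2:(n + 1)]) * dt_days / vol, 0)
  # factor 2: a cell can lose water through both faces at once
  nsub <- max(1L, ceiling(courant * 2.1))
  dt <- dt_days / nsub
  no3 <- pools$no3
  leach_rep <- 0
  leach_bot <- 0
  qi <- q[2:(n + 1)]
  for (k in seq_len(nsub)) {
    conc <- no3 / vol  # kg ha-1 per mm of water
    # upwind concentration at interfaces below each node (rain carries no N)
    cu <- ifelse(qi >= 0, conc, c(conc[-1], 0))
    f <- qi * cu
    no3 <- no3 + (c(0, f[-n]) - f) * dt
    leach_rep <- leach_rep + f[j_rep - 1] * dt
    leach_bot <- leach_bot + f[n] * dt
  }
  no3 <- pmax(no3, 0)
  pools$no3 <- no3
  pools$cum_leach_bottom <- pools$cum_leach_bottom + leach_bot
  pools$cum_leach_report <- pools$cum_leach_report + leach_rep
  water_mm <- q[j_rep] * dt_days
  conc_rep <- if (water_mm > 1e-12 && leach_rep > 0)
    100 * leach_rep / water_mm else 0
  list(pools = pools,
       leach = list(water_mm = water_mm, no3_kg_ha = leach_rep,
                    conc_mgN_L = conc_rep))
}

#' Convert a nitrate-N concentration to a nitrate concentration
#' @param mg_n_per_l mg NO3-N per litre.
#' @return mg NO3 per litre (x 62/14).
#' @export
no3_n_to_no3 <- function(mg_n_per_l) mg_n_per_l * 62 / 14

#' Retranslocate vegetative nitrogen to the filling grain
#'
#' After anthesis, grain N demand not met by soil uptake is drawn from the
#' mobilizable vegetative N — the organ N above the structural (maturity)
#' concentration of leaf, stem and root — at up to `remob_rate` of that pool
#' per day.  This is how most grain N accrues in cereals; without it, grain
#' filling would require fresh soil N exactly when the profile is driest.
#'
#' @param state A `crop_state` with `dvs >= 1`.
#' @param grain_need Unmet grain N flow for the day (kg N ha-1 d-1).
#' @param crop A [crop_params()].
#' @param params An [n_params()].
#' @return List with updated `state` and the amount `moved` (kg N ha-1).
#' @export
n_remobilize <- function(state, grain_need, crop = crop_params(),
                         params = n_params()) {
  if (state$dvs < 1 || grain_need <= 0)
    return(list(state = state, moved = 0))
  organs <- c("leaf", "stem", "root")
  tab <- crop$n_conc
  structural <- vapply(organs, function(org) {
    tab[[org]][nrow(tab)] / 100 * state$biomass[[org]] * 1000
  }, numeric(1))
  mobilizable <- pmax(unlist(state$n_mass[organs]) - structural, 0)
  avail <- params$remob_rate * sum(mobilizable)
  moved <- min(grain_need, avail)
  if (moved > 0) {
    take <- moved * mobilizable / sum(mobilizable)
    state$n_mass[organs] <- state$n_mass[organs] - take
    state$n_mass["grain"] <- state$n_mass[["grain"]] + moved
  }
  list(state = state, moved = moved)
}
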