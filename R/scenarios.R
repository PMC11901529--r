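#' Four-run stress-switch yield-gap decomposition
#'
#' Runs the potential ({water off, N off}), water-limited ({on, off}),
#' N-limited ({off, on}) and actual ({on, on}) configurations over the
#' three archetype seasons and decomposes the yield gap.  The switches
#' disable only the growth response; soil water flow and N transport still
#' run in every configuration.
#'
#' @param config A [site_fixture()] configuration.
#' @param seed Integer seed for the synthetic weather.
#' @param labels Archetype seasons to simulate.
#' @param n_rate Fertilization of the limited/actual runs (kg N ha-1).
#' @param spinup_years Spin-up length per run (years).
#' @return Data frame of class `yield_gap_report`: per season the four
#'   yields (t DM ha-1) and the absolute (t ha-1) / relative (%) losses for
#'   water-only, N-only and combined stress.
#' @export
yield_gap_decomposition <- function(config = site_fixture(), seed = 1,
                                    labels = c("normal", "hot", "wet"),
                                    n_rate = 100, spinup_years = 0) {
  runs <- list(pot = c(FALSE, FALSE), wlim = c(TRUE, FALSE),
               nlim = c(FALSE, TRUE), act = c(TRUE, TRUE))
  out <- lapply(labels, function(lab) {
    gy <- vapply(runs, function(sw) {
      r <- run_season(lab, seed = seed, config = config, n_rate = n_rate,
                      spinup_years = spinup_years,
                      water_on = sw[1], n_on = sw[2])
      r$seasons[[1]]$summary$grain_yield
    }, numeric(1))
    lw <- yield_loss(gy[["pot"]], gy[["wlim"]])
    ln <- yield_loss(gy[["pot"]], gy[["nlim"]])
    lc <- yield_loss(gy[["pot"]], gy[["act"]])
    data.frame(label = lab,
               y_pot = gy[["pot"]], y_wlim = gy[["wlim"]],
               y_nlim = gy[["nlim"]], y_act = gy[["act"]],
               loss_water_t_ha = lw$absolute, loss_water_pct = lw$relative,
               loss_n_t_ha = ln$absolute, loss_n_pct = ln$relative,
               loss_combined_t_ha = lc$absolute,
               loss_combined_pct = lc$relative,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out), class = c("yield_gap_report", "data.frame"))
}

#' Nitrogen fertilization rate sweep
#'
#' One full-season run per rate (default N0 plus 10-200 by 10, each split
#' 50/50 over the two application dates), with the spin-up repeated at the
#' same rate so the soil N state is consistent with the scenario.  AE_N and
#' RE_N are computed against the N0 row of the same sweep.
#'
#' @param config A [site_fixture()] configuration.
#' @param label Archetype season.
#' @param rates N rates (kg N ha-1); 0 is added if absent (baseline).
#' @param seed Integer seed.
#' @param spinup_years Spin-up length per rate (years).
#' @param water_on,n_on Stress switches (defaults: actual run).
#' @param extend_days Days of the following year appended to each run so
#'   the autumn/winter/spring leaching that follows the season is counted
#'   (default 300, i.e. through the next October).
#' @return Data frame with one row per rate: grain yield (t DM ha-1), grain
#'   and total N uptake (kg N ha-1), leached N below the reporting depth
#'   over the run (kg N ha-1), AE_N, PFP_N, RE_N, WUE (kg ha-1 mm-1), and
#'   the season stress indices.
#' @export
n_sweep <- function(config = site_fixture(), label = "normal",
                    rates = seq(0, 200, by = 10), seed = 1,
                    spinup_years = 0, water_on = TRUE, n_on = TRUE,
                    extend_days = 300) {
  rates <- sort(unique(c(0, rates)))
  rows <- lapply(rates, function(rate) {
    r <- run_season(label, seed = seed, config = config, n_rate = rate,
                    spinup_years = spinup_years,
                    water_on = water_on, n_on = n_on,
                    extend_days = extend_days)
    ss <- r$seasons[[1]]$summary
    d <- r$daily
    win <- d$date >= r$seasons[[1]]$sowing & d$date <= r$seasons[[1]]$harvest
    water_used <- sum(d$ea[win] + d$ta[win])  # season evapotranspiration
    data.frame(rate_kgN_ha = rate,
               grain_t_ha = ss$grain_yield,
               tab_t_ha = ss$tab,
               grain_n_kg_ha = ss$n_uptake[["grain"]],
               uptake_kgN_ha = ss$n_uptake_total,
               leach_kgN_ha = sum(d$no3_leach_kg_ha),
               water_used_mm = water_used,
               alpha_avg = ss$alpha_avg,
               n_index_avg = ss$n_index_avg,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  y0 <- tab$grain_t_ha[tab$rate_kgN_ha == 0] * 1000
  u0 <- tab$grain_n_kg_ha[tab$rate_kgN_ha == 0]
  tab$aen <- NA_real_
  tab$pfpn <- NA_real_
  tab$ren <- NA_real_
  tab$wue <- wue(tab$grain_t_ha * 1000, tab$water_used_mm)
  pos <- tab$rate_kgN_ha > 0
  tab$aen[pos] <- ae_n(tab$grain_t_ha[pos] * 1000, y0, tab$rate_kgN_ha[pos])
  tab$pfpn[pos] <- pfp_n(tab$grain_t_ha[pos] * 1000, tab$rate_kgN_ha[pos])
  tab$ren[pos] <- re_n(tab$grain_n_kg_ha[pos], u0, tab$rate_kgN_ha[pos])
  tab
}

#' Optimal N rate from a sweep table
#'
#' The smallest rate whose grain yield is within `tol` of the sweep
#' maximum (plateau-entry definition).
#'
#' @param sweep A [n_sweep()] table (needs `rate_kgN_ha`, `grain_t_ha`).
#' @param tol Relative tolerance (default 1 %).
#' @return Rate in kg N ha-1 (one of the sweep's rates).
#' @export
optimal_rate <- function(sweep, tol = 0.01) {
  if (nrow(sweep) < 2) stop("optimal_rate: need at least 2 sweep rows")
  ymax <- max(sweep$grain_t_ha)
  ok <- sweep$grain_t_ha >= (1 - tol) * ymax
  min(sweep$rate_kgN_ha[ok])
}
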