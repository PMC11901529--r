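#' Default Feddes root-water-uptake pressure heads
#'
#' Anaerobiosis point h1 = -10 cm, optimal range h2 = -25 to h3 = -300 cm,
#' wilting point h4 = -15000 cm.  Uptake is zero above h1 and below h4, full
#' between h2 and h3, and ramps linearly in between.
#'
#' @return Numeric vector c(h1, h2, h3, h4) in cm.
#' @export
feddes_default <- function() c(-10, -25, -300, -15000)

#' Feddes uptake-reduction factor
#' @param h Matric head (cm), vectorized.
#' @param feddes Pressure-head vector c(h1, h2, h3, h4), see
#'   [feddes_default()].
#' @return Reduction factor in \[0, 1\].
#' @export
feddes_reduction <- function(h, feddes = feddes_default()) {
  h1 <- feddes[1]; h2 <- feddes[2]; h3 <- feddes[3]; h4 <- feddes[4]
  out <- numeric(length(h))
  out[h < h1 & h >= h2] <- (h1 - h[h < h1 & h >= h2]) / (h1 - h2)
  out[h < h2 & h >= h3] <- 1
  sel <- h < h3 & h > h4
  out[sel] <- (h[sel] - h4) / (h3 - h4)
  out
}

#' Construct a soil water state from matric heads
#' @param h Matric head per node (cm).
#' @param grid A [build_grid()] grid.
#' @return List of class `soil_water_state` with `h` and consistent `theta`.
#' @export
soil_water_state <- function(h, grid) {
  if (length(h) != grid$n) stop("soil_water_state: h length != grid nodes")
  theta <- grid$theta_r + (grid$theta_s - grid$theta_r) *
    ifelse(h >= 0, 1, (1 + (grid$alpha * abs(h))^grid$vg_n)^(-(1 - 1 / grid$vg_n)))
  structure(list(h = h, theta = theta), class = "soil_water_state")
}

#' Advance the Richards solution over one (or part of one) day
#'
#' Mixed-form, mass-conservative modified-Picard iteration with adaptive
#' sub-daily stepping (time step halved on non-convergence down to
#' `dt_min`).  Upper boundary: atmospheric flux demand `precip - ep`
#' switching to ponded-head control (excess reported as runoff) or to
#' dry-surface control (evaporation limited by exfiltration capacity).
#' Lower boundary: free drainage, q = K(h) at the bottom node.
#'
#' @param state A [soil_water_state()].
#' @param grid A [build_grid()] grid.
#' @param precip Water reaching the surface (mm d-1).
#' @param ep Potential soil evaporation (mm d-1).
#' @param tp Potential transpiration (mm d-1); ignored when `sink` is given.
#' @param root_frac Per-node root density fraction (sums to 1 over rooted
#'   nodes); ignored when `sink` is given.
#' @param sink Optional fixed extraction per node (mm d-1); bypasses the
#'   Feddes reduction.
#' @param feddes Feddes pressure heads, see [feddes_default()].
#' @param dt_days Length of the step in days (default 1).
#' @param control List of solver controls: `dt_init`, `dt_min`, `dt_max`
#'   (days), `max_iter`, `tol`, `h_dry` (cm).
#' @return List with the new `state`, a one-row `budget` data.frame (mm:
#'   precip, runoff, ea, ta, drainage, storage_change, balance_error),
#'   `alpha_day` = ta/tp (1 when tp = 0), mean interface fluxes `q_int`
#'   (mm d-1, positive downward, length n+1) and per-node mean uptake
#'   `sink` (mm d-1).
#' @export
richards_step <- function(state, grid, precip = 0, ep = 0, tp = 0,
                          root_frac = NULL, sink = NULL,
                          feddes = feddes_default(), dt_days = 1,
                          control = list()) {
  stopifnot(dt_days > 0)
  ctl <- modifyList(list(dt_init = 0.05, dt_min = 1e-4, dt_max = 0.25,
                         max_iter = 40, tol = 2e-4, h_dry = -1e5), control)
  if (is.null(root_frac)) root_frac <- numeric(grid$n)
  sink_cm <- if (is.null(sink)) NULL else sink / 10
  res <- .richards_day_cpp(state$h, grid$theta_r, grid$theta_s, grid$alpha,
                           grid$vg_n, grid$ks, grid$dz,
                           precip / 10, ep / 10, tp / 10, root_frac, feddes,
                           sink_cm, dt_days, ctl$dt_init, ctl$dt_min,
                           ctl$dt_max, ctl$max_iter, ctl$tol, ctl$h_dry)
  ta_mm <- res$ta * 10
  budget <- data.frame(
    precip = precip * dt_days, runoff = res$runoff * 10,
    ea = res$ea * 10, ta = ta_mm, drainage = res$drainage * 10,
    storage_change = res$storage_change * 10,
    balance_error = res$balance_error * 10
  )
  alpha_day <- if (tp * dt_days > 0)
    min(max(ta_mm / (tp * dt_days), 0), 1) else 1
  list(state = structure(list(h = res$h, theta = res$theta),
                         class = "soil_water_state"),
       budget = budget, alpha_day = alpha_day,
       q_int = res$q_int * 10, sink = res$sink * 10,
       n_substeps = res$n_substeps)
}

#' Feddes root water uptake for a given state
#'
#' Distributes the transpiration demand over the rooted nodes in proportion
#' to root density, reduced per node by the Feddes pressure-head factor.
#'
#' @param state A [soil_water_state()].
#' @param grid A [build_grid()] grid.
#' @param root_density Per-node root fraction, summing to 1 over rooted
#'   nodes.
#' @param tp Potential transpiration (mm d-1), >= 0.
#' @param feddes Feddes pressure heads.
#' @return List with `sink` (mm d-1 per node), `ta` (mm d-1) and
#'   `alpha_day` = ta/tp (1 when tp = 0).
#' @export
root_uptake <- function(state, grid, root_density, tp,
                        feddes = feddes_default()) {
  stopifnot(tp >= 0, length(root_density) == grid$n)
  red <- feddes_reduction(state$h, feddes)
  sink <- red * root_density * tp
  ta <- sum(sink)
  list(sink = sink, ta = ta, alpha_day = if (tp > 0) ta / tp else 1)
}

#' Season-mean water availability index
#'
#' Mean of the daily actual-to-potential transpiration ratios over a window
#' (whole season or a sub-stage); ranges from 1 (no water stress) to 0.
#'
#' @param alpha_daily Numeric vector of daily ratios in \[0, 1\].
#' @return Mean value in \[0, 1\].
#' @export
season_alpha <- function(alpha_daily) {
  if (length(alpha_daily) == 0) stop("season_alpha: empty window")
  if (anyNA(alpha_daily)) stop("season_alpha: NA values")
  mean(alpha_daily)
}

#' Triangular root density profile
#'
#' Root density decreasing linearly from the surface to the rooting depth,
#' discretized on the grid and normalized to sum to 1.
#'
#' @param grid A [build_grid()] grid.
#' @param root_depth Rooting depth (cm); 0 gives an all-zero profile.
#' @return Per-node fraction vector.
#' @export
root_profile <- function(grid, root_depth) {
  w <- pmax(0, 1 - grid$z / max(root_depth, 1e-9))
  w[grid$z > root_depth] <- 0
  s <- sum(w)
  if (s > 0) w / s else w
}
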