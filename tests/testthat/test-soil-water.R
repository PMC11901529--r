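test_that("van Genuchten retention reproduces the measured parameter set", {
  ap <- ap_params()
  expect_equal(vg_theta(0, ap), 0.419)
  # the dry limit is theta_r; the approach rate depends on n, so the
  # low-n topsoil is checked loosely and a high-n subsoil tightly
  expect_lt(vg_theta(-1e9, ap) - 0.0145, 2e-3)
  b2 <- vg_params(0.0205, 0.285, 0.040, 3.647, 5.88)
  expect_lt(vg_theta(-1e9, b2) - 0.0205, 1e-6)
  # hand evaluation of the closed form at h = -100 cm (Ap parameters):
  # Se = (1 + (0.011*100)^1.395)^-(1 - 1/1.395) = 0.80595
  expect_equal(vg_theta(-100, ap), 0.340512, tolerance = 1e-5)
})

test_that("Mualem conductivity matches its closed form", {
  ap <- ap_params()
  expect_equal(vg_k(0, ap), 58.87)
  expect_equal(vg_k_se(1, ap), 58.87)
  # hand evaluation at Se = 0.5, m = 1 - 1/1.395:
  # K = Ks * sqrt(0.5) * (1 - (1 - 0.5^(1/m))^m)^2
  expect_equal(vg_k_se(0.5, ap), 0.0266101, tolerance = 1e-4)
})

test_that("retention and conductivity are continuous and monotone in h", {
  set.seed(7)
  h <- -10^seq(-2, 7, length.out = 400)
  for (i in 1:20) {
    p <- vg_params(theta_r = runif(1, 0.01, 0.03),
                   theta_s = runif(1, 0.28, 0.42),
                   alpha = runif(1, 0.011, 0.088),
                   n = runif(1, 1.4, 4.6),
                   ks = runif(1, 1.9, 59))
    th <- vg_theta(h, p)
    kk <- vg_k(h, p)
    expect_true(all(diff(th) <= 1e-12))       # drier -> less water
    expect_true(all(diff(kk) <= 1e-12))
    expect_true(all(th >= p$theta_r - 1e-12 & th <= p$theta_s + 1e-12))
    expect_true(all(kk >= 0 & kk <= p$ks + 1e-12))  # K underflows when dry
    # no jumps an order larger than neighbours (continuity on the grid)
    expect_lt(max(abs(diff(th))), 0.05)
  }
})

test_that("grid construction maps horizons and rejects broken profiles", {
  cfg <- site_fixture()
  g <- build_grid(cfg$horizons, dz = 1, domain_depth = 150)
  expect_equal(g$n, 150)
  # horizon switches at the documented depths, deepest extends to 150
  breaks <- which(diff(g$horizon) != 0)
  expect_equal(g$z[breaks + 1] - 0.5, c(30, 50, 78, 105))
  # the deepest horizon extends from 120 cm to the domain bottom
  expect_equal(g$horizon[150], 5)
  expect_equal(g$horizon[130], 5)
  g1 <- build_grid(list(soil_horizon(0, 150, ap_params())), dz = 5)
  expect_equal(g1$n, 30)
  expect_true(all(g1$horizon == 1))
  expect_error(
    build_grid(list(soil_horizon(0, 30, ap_params()),
                    soil_horizon(40, 120, ap_params()))),
    "profile error")
})

test_that("a hydrostatic profile under zero forcing stays put", {
  g <- uniform_grid(dz = 2)
  s <- soil_water_state(g$z - 1e5, g)  # deep water table
  th0 <- s$theta
  for (d in 1:30) s <- richards_step(s, g)$state
  expect_lt(max(abs(s$theta - th0)), 1e-6)
})

test_that("steady rainfall reproduces the Darcy steady-flux solution", {
  # homogeneous column, q = Ks/10: the steady state is uniform h* with
  # K(h*) = q and bottom drainage q (free drainage, unit gradient)
  for (p in table4_params()) {
    q <- p$ks / 10
    hstar <- uniroot(function(h) vg_k(h, p) - q, c(-5000, -1e-4),
                     tol = 1e-12)$root
    g <- uniform_grid(p, dz = 2)
    s <- soil_water_state(rep(hstar, g$n), g)
    for (d in 1:15) r <- { r <- richards_step(s, g, precip = q * 10); s <- r$state; r }
    expect_equal(r$budget$drainage, q * 10, tolerance = 0.01)
    expect_equal(s$h[40], hstar, tolerance = 0.02)
  }
  # transient approach from a drier profile (fast horizon)
  p <- ap_params()
  q <- p$ks / 10
  hstar <- uniroot(function(h) vg_k(h, p) - q, c(-5000, -1e-4), tol = 1e-12)$root
  g <- uniform_grid(p, dz = 2)
  s <- soil_water_state(rep(-100, g$n), g)
  for (d in 1:30) r <- { r <- richards_step(s, g, precip = q * 10); s <- r$state; r }
  expect_equal(r$budget$drainage, q * 10, tolerance = 0.01 * q * 10)
  expect_equal(s$h[40], hstar, tolerance = 0.5)
})

test_that("with zero forcing the storage change mirrors drainage", {
  g <- uniform_grid(dz = 2)
  s <- soil_water_state(rep(-50, g$n), g)
  r <- richards_step(s, g)  # no rain, no evaporation, no sink
  expect_equal(r$budget$storage_change, -r$budget$drainage,
               tolerance = 1e-3)
  expect_lt(abs(r$budget$balance_error), 0.1)
})

test_that("Feddes uptake reduces transpiration by pressure head", {
  g <- uniform_grid(dz = 2)
  rd <- root_profile(g, 60)
  # all rooted nodes in the optimal range
  s <- soil_water_state(rep(-100, g$n), g)
  u <- root_uptake(s, g, rd, tp = 4)
  expect_equal(u$ta, 4)
  expect_equal(u$alpha_day, 1)
  # all rooted nodes at wilting
  s <- soil_water_state(rep(-2e4, g$n), g)
  u <- root_uptake(s, g, rd, tp = 4)
  expect_equal(u$ta, 0)
  expect_equal(u$alpha_day, 0)
  # uniform roots, half the rooted nodes optimal, half wilted -> 0.5
  h <- rep(-2e4, g$n)
  h[1:15] <- -100
  rd_u <- c(rep(1 / 30, 30), rep(0, g$n - 30))
  u <- root_uptake(soil_water_state(h, g), g, rd_u, tp = 4)
  expect_equal(u$alpha_day, 0.5, tolerance = 1e-12)
  # no demand -> no stress by convention
  expect_equal(root_uptake(s, g, rd, tp = 0)$alpha_day, 1)
})

test_that("season alpha is the mean daily ratio", {
  expect_equal(season_alpha(rep(1, 10)), 1)
  expect_equal(season_alpha(c(1, 0.5, 0)), 0.5)
  expect_equal(season_alpha(rep(3.8 / 5.0, 90)), 0.76)
  expect_error(season_alpha(numeric(0)), "empty")
})

test_that("daily water balance closes through a forced spell", {
  cfg <- site_fixture(dz = 2)
  ws <- generate_weather("normal", 2020, 3, cfg)
  ws <- weather_series(ws[91:180, ], cfg$latitude, cfg$elevation)
  g <- build_grid(cfg$horizons, dz = 2, domain_depth = 150)
  s <- soil_water_state(rep(-150, g$n), g)
  et0 <- et0_series(ws)
  worst <- 0
  for (d in seq_len(nrow(ws))) {
    r <- richards_step(s, g, precip = ws$precip[d], ep = et0[d] * 0.6,
                       tp = et0[d] * 0.4, root_frac = root_profile(g, 80))
    s <- r$state
    worst <- max(worst, abs(r$budget$balance_error))
  }
  expect_lt(worst, 0.1)
})

test_that("halving the grid spacing barely changes seasonal drainage", {
  drain <- vapply(c(2, 1), function(dz) {
    cfg <- site_fixture(dz = dz)
    ws <- generate_weather("normal", 2020, 3, cfg)
    ws <- weather_series(ws[60:240, ], cfg$latitude, cfg$elevation)
    mgmt <- build_management(cfg, 2020, "normal")
    run <- run_simulation(cfg, ws, mgmt)
    sum(run$daily$drainage)
  }, numeric(1))
  expect_lt(abs(drain[2] - drain[1]) / max(drain[1], 1), 0.02)
})
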