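# Table-4 hydraulic parameter sets used across the suite
ap_params <- function() vg_params(0.0145, 0.419, 0.011, 1.395, 58.87)

table4_params <- function() list(
  Ap    = vg_params(0.0145, 0.419, 0.011, 1.395, 58.87),
  B1    = vg_params(0.0260, 0.306, 0.033, 1.980, 9.34),
  B2    = vg_params(0.0205, 0.285, 0.040, 3.647, 5.88),
  `2Ck` = vg_params(0.0240, 0.323, 0.088, 2.821, 5.05),
  `2C`  = vg_params(0.0260, 0.312, 0.047, 4.575, 1.95)
)

uniform_grid <- function(p = ap_params(), dz = 2, depth = 150) {
  build_grid(list(soil_horizon(0, depth, p)), dz = dz, domain_depth = depth)
}

# Independent step-by-step FAO-56 worksheet calculation (scalar), kept
# deliberately separate from the package implementation: every intermediate
# quantity is computed explicitly in worksheet order.
fao56_worksheet <- function(tmin, tmax, rh, wind, srad, lat_deg, elev, doy) {
  t_mean <- (tmax + tmin) / 2
  # saturation vapour pressure (kPa)
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  e_s <- (e0(tmax) + e0(tmin)) / 2
  e_a <- e_s * rh / 100
  slope <- 4098 * (0.6108 * exp(17.27 * t_mean / (t_mean + 237.3))) /
    (t_mean + 237.3)^2
  pressure <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  psy <- 0.665e-3 * pressure
  # extraterrestrial radiation
  phi <- pi / 180 * lat_deg
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  ws <- acos(-tan(phi) * tan(dec))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  rso <- (0.75 + 2e-5 * elev) * ra
  rns <- (1 - 0.23) * srad
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(e_a)) * (1.35 * min(srad / rso, 1) - 0.35)
  rn <- rns - rnl
  num <- 0.408 * slope * rn + psy * 900 / (t_mean + 273) * wind * (e_s - e_a)
  num / (slope + psy * (1 + 0.34 * wind))
}

write_weather_csv <- function(df, path, srad_col = "srad_mj_m2") {
  names(df)[names(df) == "srad"] <- srad_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

mini_weather_df <- function(n = 3, start = "2020-05-01") {
  data.frame(date = format(seq(as.Date(start), by = "day", length.out = n)),
             tmin_c = 8 + seq_len(n), tmax_c = 18 + seq_len(n),
             rh_pct = 70, wind_ms = 2, srad = 18, precip_mm = c(0, 5, 0)[
               ((seq_len(n) - 1) %% 3) + 1])
}
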