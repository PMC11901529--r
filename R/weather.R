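#' Construct and validate a daily weather series
#'
#' A weather series is a data.frame with one row per calendar day and columns
#' `date` (Date), `tmin`, `tmax` (deg C), `rh` (% mean relative humidity),
#' `wind` (m s-1 at 2 m), `srad` (MJ m-2 d-1 global solar radiation) and
#' `precip` (mm d-1), plus attributes `latitude` (decimal degrees) and
#' `elevation` (m).  Dates must be strictly increasing with no gaps.
#'
#' @param df Data frame with the columns above.
#' @param latitude Site latitude in decimal degrees, in \[-90, 90\].
#' @param elevation Site elevation in m.
#' @return The validated data.frame of class `weather_series`.
#' @export
weather_series <- function(df, latitude, elevation) {
  need <- c("date", "tmin", "tmax", "rh", "wind", "srad", "precip")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("weather series: missing columns: ", paste(miss, collapse = ", "))
  if (abs(latitude) > 90) stop("weather series: latitude outside [-90, 90]")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("weather series: unparseable dates")
  d <- diff(as.integer(df$date))
  if (any(d <= 0)) stop("weather series: dates not strictly increasing")
  if (any(d > 1)) {
    gaps <- df$date[which(d > 1)] + 1
    stop("weather series: gap error, missing day(s) starting at: ",
         paste(format(gaps), collapse = ", "))
  }
  bad <- which(df$tmin > df$tmax)
  if (length(bad) > 0)
    stop("weather series: record error, tmin > tmax on ",
         paste(format(df$date[bad]), collapse = ", "))
  if (any(df$rh < 0 | df$rh > 100)) stop("weather series: rh outside [0, 100]")
  if (any(df$wind < 0)) stop("weather series: negative wind")
  if (any(df$srad < 0)) stop("weather series: negative radiation")
  if (any(df$precip < 0)) stop("weather series: negative precipitation")
  attr(df, "latitude") <- latitude
  attr(df, "elevation") <- elevation
  class(df) <- c("weather_series", "data.frame")
  df
}

#' Read a daily weather file
#'
#' Comma-delimited text with header
#' `date,tmin_c,tmax_c,rh_pct,wind_ms,srad_mj_m2,precip_mm` and ISO-8601
#' dates.  If the radiation column is instead headed `srad_j_cm2` the values
#' are converted to MJ m-2 d-1 (x 0.01) at read time; any other radiation
#' header is a format error — unit dialects are never guessed silently.
#'
#' @param path File path.
#' @inheritParams weather_series
#' @return A [weather_series()].
#' @export
read_weather <- function(path, latitude, elevation) {
  if (!file.exists(path)) stop("read_weather: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixed <- c("date", "tmin_c", "tmax_c", "rh_pct", "wind_ms")
  if (!all(fixed %in% names(raw)) || !("precip_mm" %in% names(raw)))
    stop("read_weather: format error, expected header ",
         "date,tmin_c,tmax_c,rh_pct,wind_ms,srad_mj_m2,precip_mm")
  if ("srad_mj_m2" %in% names(raw)) {
    srad <- raw$srad_mj_m2
  } else if ("srad_j_cm2" %in% names(raw)) {
    srad <- raw$srad_j_cm2 * 0.01  # J cm-2 d-1 -> MJ m-2 d-1
  } else {
    stop("read_weather: format error, unknown radiation units header ",
         "(expected srad_mj_m2 or srad_j_cm2)")
  }
  weather_series(
    data.frame(date = as.Date(raw$date), tmin = raw$tmin_c, tmax = raw$tmax_c,
               rh = raw$rh_pct, wind = raw$wind_ms, srad = srad,
               precip = raw$precip_mm),
    latitude = latitude, elevation = elevation
  )
}

#' Write a weather series to the package's delimited format
#' @param ws A [weather_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(ws, path) {
  out <- data.frame(date = format(ws$date), tmin_c = ws$tmin, tmax_c = ws$tmax,
                    rh_pct = ws$rh, wind_ms = ws$wind, srad_mj_m2 = ws$srad,
                    precip_mm = ws$precip)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Daily extraterrestrial radiation
#'
#' @param latitude Decimal degrees.
#' @param doy Day of year (1-366), vectorized.
#' @return Ra in MJ m-2 d-1.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  if (abs(latitude) > 90) stop("latitude outside [-90, 90]")
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(delta)
  ws <- acos(pmin(1, pmax(-1, x)))  # clamp handles polar day/night
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(ra, 0)
}

#' FAO-56 reference Penman-Monteith evapotranspiration, daily time step
#'
#' Reference-crop formulation (grass, albedo 0.23), soil heat flux G = 0 at
#' the daily step.  Actual vapour pressure from mean relative humidity
#' applied to the mean saturation vapour pressure.
#'
#' @param tmin,tmax Daily minimum/maximum air temperature (deg C).
#' @param rh Daily mean relative humidity (%).
#' @param wind Wind speed at 2 m (m s-1).
#' @param srad Global solar radiation (MJ m-2 d-1).
#' @param latitude Decimal degrees, in \[-90, 90\].
#' @param elevation Site elevation (m).
#' @param doy Day of year.
#' @return ET0 in mm d-1 (non-negative).  All arguments vectorized.
#' @export
et0_penman_monteith <- function(tmin, tmax, rh, wind, srad,
                                latitude, elevation, doy) {
  if (abs(latitude) > 90) stop("et0: latitude outside [-90, 90]")
  tmean <- (tmax + tmin) / 2
  svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (svp(tmax) + svp(tmin)) / 2
  ea <- pmin(es, rh / 100 * es)
  delta <- 4098 * svp(tmean) / (tmean + 237.3)^2
  p_kpa <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * p_kpa
  ra <- extraterrestrial_radiation(latitude, doy)
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * srad
  rel_sun <- ifelse(rso > 0, pmin(1, srad / rso), 1)
  sigma <- 4.903e-9
  rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * rel_sun - 0.35)
  rn <- rns - rnl
  g <- 0
  num <- 0.408 * delta * (rn - g) +
    gamma * 900 / (tmean + 273) * wind * (es - ea)
  den <- delta + gamma * (1 + 0.34 * wind)
  pmax(num / den, 0)
}

#' Reference evapotranspiration for a whole weather series
#' @param ws A [weather_series()].
#' @return Numeric vector of daily ET0 (mm d-1) aligned with `ws`.
#' @export
et0_series <- function(ws) {
  et0_penman_monteith(ws$tmin, ws$tmax, ws$rh, ws$wind, ws$srad,
                      latitude = attr(ws, "latitude"),
                      elevation = attr(ws, "elevation"),
                      doy = as.integer(format(ws$date, "%j")))
}

#' Partition potential evapotranspiration into soil evaporation and
#' transpiration demand
#'
#' Beer-law canopy split: tp = kc * et0 * (1 - exp(-k_ext * lai)) and
#' ep = kc * et0 * exp(-k_ext * lai), so ep + tp = kc * et0 exactly.
#'
#' @param et0 Reference evapotranspiration (mm d-1), >= 0.
#' @param lai Leaf area index (m2 m-2), >= 0.
#' @param kc Crop coefficient (default 1).
#' @param k_ext Canopy extinction coefficient (default 0.6 for cereals).
#' @return List with `et0`, `ep`, `tp` (mm d-1).
#' @export
partition_et <- function(et0, lai, kc = 1, k_ext = 0.6) {
  if (any(lai < 0)) stop("partition_et: negative lai")
  if (any(et0 < 0)) stop("partition_et: negative et0")
  f <- exp(-k_ext * lai)
  list(et0 = et0, ep = kc * et0 * f, tp = kc * et0 * (1 - f))
}
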