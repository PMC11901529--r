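test_that("weather files are read, validated and unit-converted", {
  f <- tempfile(fileext = ".csv")
  df <- mini_weather_df(3)
  write_weather_csv(df, f)
  ws <- read_weather(f, latitude = 54.6, elevation = 120)
  expect_s3_class(ws, "weather_series")
  expect_equal(nrow(ws), 3)
  expect_equal(ws$tmin, df$tmin_c)
  expect_equal(ws$srad, rep(18, 3))

  # gap: day 2 missing from a 3-day span, error names the missing date
  df_gap <- mini_weather_df(3)
  df_gap <- df_gap[-2, ]
  write_weather_csv(df_gap, f)
  expect_error(read_weather(f, 54.6, 120), "2020-05-02")

  # record error: tmin > tmax
  df_bad <- mini_weather_df(3)
  df_bad$tmin_c[2] <- 30
  write_weather_csv(df_bad, f)
  expect_error(read_weather(f, 54.6, 120), "tmin > tmax")

  # radiation dialect J cm-2 d-1: 1500 -> 15 MJ m-2 d-1
  df_j <- mini_weather_df(3)
  df_j$srad <- 1500
  write_weather_csv(df_j, f, srad_col = "srad_j_cm2")
  ws_j <- read_weather(f, 54.6, 120)
  expect_equal(ws_j$srad, rep(15, 3))

  # unknown radiation header is a format error, never silently guessed
  df_u <- mini_weather_df(3)
  write_weather_csv(df_u, f, srad_col = "srad_watts")
  expect_error(read_weather(f, 54.6, 120), "format error")

  # round trip through the writer
  ws2 <- read_weather(write_weather(ws, f), 54.6, 120)
  expect_equal(ws2$precip, ws$precip)
})

test_that("reference evapotranspiration matches an independent FAO-56 worksheet", {
  got <- et0_penman_monteith(tmin = 12, tmax = 22, rh = 70, wind = 2,
                             srad = 20, latitude = 54.6, elevation = 120,
                             doy = 180)
  oracle <- fao56_worksheet(12, 22, 70, 2, 20, 54.6, 120, 180)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_gt(got, 2)  # a clear midsummer day at 54 N evaporates a few mm
  expect_lt(got, 8)

  # a few more conditions, same oracle
  for (case in list(c(2, 12, 90, 1, 8, 100), c(-3, 5, 80, 4, 6, 320),
                    c(15, 28, 55, 3, 25, 200))) {
    expect_equal(
      et0_penman_monteith(case[1], case[2], case[3], case[4], case[5],
                          54.6, 120, case[6]),
      max(fao56_worksheet(case[1], case[2], case[3], case[4], case[5],
                          54.6, 120, case[6]), 0),
      tolerance = 1e-10)
  }
})

test_that("et0 is non-negative, increases with wind under vapour deficit", {
  e1 <- et0_penman_monteith(12, 22, 70, 2, 20, 54.6, 120, 180)
  e2 <- et0_penman_monteith(12, 22, 70, 4, 20, 54.6, 120, 180)
  expect_gt(e2, e1)
  expect_error(et0_penman_monteith(12, 22, 70, 2, 20, 95, 120, 180),
               "latitude")
  # over a generated year: non-negative everywhere, summer peak
  ws <- generate_weather("normal", 2020, 11, site_fixture())
  et0 <- et0_series(ws)
  expect_true(all(et0 >= 0))
  mo <- as.integer(format(ws$date, "%m"))
  expect_gt(mean(et0[mo %in% 4:9]), mean(et0[mo %in% c(1:3, 10:12)]))
})

test_that("canopy partition conserves kc*et0 and follows Beer's law", {
  # bare soil
  p <- partition_et(5, 0)
  expect_equal(p$tp, 0)
  expect_equal(p$ep, 5)
  # closed canopy
  p <- partition_et(5, 10, kc = 1, k_ext = 0.6)
  expect_equal(p$ep / 5, exp(-6), tolerance = 1e-12)
  # analytic half split: exp(-0.6 L) = 0.5 at L = log(2)/0.6
  p <- partition_et(4, log(2) / 0.6, kc = 1, k_ext = 0.6)
  expect_equal(p$tp, 2, tolerance = 1e-12)
  expect_equal(p$ep, 2, tolerance = 1e-12)
  # conservation to machine precision on random inputs
  set.seed(42)
  for (i in 1:50) {
    et0 <- runif(1, 0, 8); lai <- runif(1, 0, 8); kc <- runif(1, 0.7, 1.3)
    p <- partition_et(et0, lai, kc = kc)
    expect_equal(p$ep + p$tp, kc * et0, tolerance = 1e-14)
  }
  expect_error(partition_et(4, -1), "negative lai")
})
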