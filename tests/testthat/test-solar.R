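test_that("solar position matches reference geometry", {
  # equator at the March equinox, solar noon: sun at the zenith within 1 deg
  s <- solar_position(as.POSIXct("2022-03-20 12:07", tz = "UTC"), 0, 0, 0)
  expect_lt(s$zenith * 180 / pi, 1)

  # 36.6 N on the June solstice at solar noon: zenith ~ 13.2 deg (NOAA
  # ephemeris: lat - declination = 36.6 - 23.44 with small corrections)
  s2 <- solar_position(as.POSIXct("2022-06-21 12:02", tz = "UTC"),
                       36.6, -119.5, -8)
  expect_equal(s2$zenith * 180 / pi, 13.2, tolerance = 0.5)

  # unit direction for arbitrary inputs
  for (hr in c(3, 9, 15, 21)) {
    sp <- solar_position(as.POSIXct(sprintf("2022-02-11 %02d:00", hr),
                                    tz = "UTC"), -41, 147, 10)
    expect_equal(sum(sp$sun_direction^2), 1, tolerance = 1e-12)
  }
})

test_that("noon elevation follows the declination closed form", {
  for (lat in c(0, 20, 36.6, 55)) {
    best <- Inf; zen <- NA
    for (m in seq(11 * 60, 13 * 60, by = 2)) {
      tt <- as.POSIXct("2022-06-21 00:00", tz = "UTC") + m * 60
      sp <- solar_position(tt, lat, 0, 0)
      if (sp$zenith < best) { best <- sp$zenith; zen <- sp }
    }
    expected_elev <- 90 - abs(lat - zen$declination * 180 / pi)
    expect_equal(zen$elevation * 180 / pi, expected_elev, tolerance = 0.5)
  }
})

test_that("clear-sky shortwave respects limits and magnitude checks", {
  atm <- atmosphere_state(T_a = 298, h = 0.4)
  noon <- solar_position(as.POSIXct("2022-06-21 12:02", tz = "UTC"),
                         36.6, -119.5, -8)
  # transmittances forced to 1: direct normal equals the distance-corrected
  # extraterrestrial flux
  ov <- list(rayleigh = 1, ozone = 1, gas = 1, water = 1, aerosol = 1)
  sw1 <- clearsky_shortwave(noon, atm, doy = 172, override = ov)
  expect_equal(sw1$S_dn, sw1$E0)
  expect_equal(sw1$E0, 1361 * (1 + 0.033 * cos(2 * pi * 172 / 365)),
               tolerance = 1e-9)

  # clean clear atmosphere at 20 deg zenith: direct normal in [850, 1050]
  s20 <- list(zenith = 20 * pi / 180, above_horizon = TRUE)
  sw <- clearsky_shortwave(s20, atmosphere_state(T_a = 295, h = 0.3,
                                                 turbidity = 0.04))
  expect_gt(sw$S_dn, 850); expect_lt(sw$S_dn, 1050)
  expect_gt(sw$S_diff, 0)
  expect_lt(sw$S_dn, sw$E0)   # never exceeds the solar constant
  expect_true(sw$diffuse_fraction > 0 && sw$diffuse_fraction < 1)

  # night: all shortwave zero
  night <- list(zenith = 1.8, above_horizon = FALSE)
  swn <- clearsky_shortwave(night, atm)
  expect_equal(swn$S_dn, 0); expect_equal(swn$S_diff, 0)
})

test_that("downwelling longwave has the blackbody limit and grows with water", {
  atm <- atmosphere_state(T_a = 300, h = 0.5)
  expect_equal(downwelling_longwave(atm, eps_a = 1), 5.67e-8 * 300^4)
  # dry sky emissivity below 0.8
  dry <- atmosphere_state(T_a = 300, h = 0.5, w_cm = 1e-6)
  expect_lt(downwelling_longwave(dry) / (5.67e-8 * 300^4), 0.8)
  # monotone in precipitable water at fixed temperature
  w <- seq(0.3, 5, by = 0.2)
  L <- vapply(w, function(wi) {
    downwelling_longwave(atmosphere_state(T_a = 300, h = 0.5, w_cm = wi))
  }, 0)
  expect_true(all(diff(L) > 0))
  expect_true(all(L < 5.67e-8 * 300^4))
})

test_that("precipitable water is positive, monotone, and plausible", {
  h <- seq(0.1, 0.9, by = 0.1)
  w_h <- precipitable_water(rep(298, length(h)), h)
  expect_true(all(diff(w_h) > 0))
  Ta <- seq(280, 310, by = 5)
  w_T <- precipitable_water(Ta, rep(0.5, length(Ta)))
  expect_true(all(diff(w_T) > 0))
  expect_true(all(w_T > 0))
  # magnitude check at 25 C / 50% RH: between 1 and 4 cm (dewpoint ~ 14 C)
  w <- precipitable_water(298, 0.5)
  expect_gt(w, 1); expect_lt(w, 4)
})

test_that("synthetic weather has the right shape and record count", {
  wx <- synth_weather("2022-06-21", 36.6, -119.5, -8, timestep_min = 15)
  expect_equal(nrow(wx), 97)              # 24 h at 15 min + both endpoints
  expect_equal(max(wx$Ta_C), 36, tolerance = 1e-6)
  expect_equal(min(wx$Ta_C), 16, tolerance = 1e-6)
  # humidity anti-phased with temperature
  expect_equal(which.max(wx$Ta_C), which.min(wx$RH))
  # radiation zero at night, positive at midday
  expect_equal(wx$S_dn[1], 0)
  expect_gt(wx$S_dn[which.min(wx$zenith)], 700)
  expect_true(all(wx$L_dn > 0))

  flat <- synth_weather("2022-06-21", 36.6, -119.5, -8, T_min = 20, T_max = 20,
                        timestep_min = 60)
  expect_equal(nrow(flat), 25)
  expect_true(all(abs(flat$Ta_C - 20) < 1e-9))
  expect_error(synth_weather("2022-06-21", 36.6, -119.5, -8,
                             T_min = 30, T_max = 20), "T_max")
})
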