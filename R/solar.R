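#' Solar position from standard astronomical relationships
#'
#' Computes the solar zenith and azimuth from the solar declination, the
#' equation of time and the local hour angle, and returns the unit vector
#' pointing from the surface toward the sun (z up, x east, y north; azimuth
#' clockwise from north).
#'
#' @param time POSIXct time (interpreted as local standard time with the
#'   given UTC offset).
#' @param latitude,longitude Degrees (north / east positive).
#' @param utc_offset Hours to add to UTC to obtain local standard time
#'   (e.g. -8 for the US Pacific zone).
#' @return A list with `zenith` and `azimuth` (radians), `elevation`
#'   (radians), `sun_direction` (unit length-3 vector), `declination`
#'   (radians) and `above_horizon` (logical).
#' @export
#' @examples
#' s <- solar_position(as.POSIXct("2022-06-21 12:00", tz = "UTC"), 0, 0, 0)
solar_position <- function(time, latitude, longitude, utc_offset = 0) {
  if (abs(latitude) > 90) stop("latitude must be within [-90, 90]")
  lt <- as.POSIXlt(time, tz = attr(time, "tzone") %||% "UTC")
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  # fractional year (radians)
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  # declination (Spencer series)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  # equation of time, minutes
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  # true solar time, minutes
  tst <- hour * 60 + eot + 4 * longitude - 60 * utc_offset
  ha <- (tst / 4 - 180) * pi / 180          # hour angle, radians
  lat <- latitude * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  cosz <- pmin(1, pmax(-1, cosz))
  zen <- acos(cosz)
  # azimuth clockwise from north
  az <- atan2(sin(ha), cos(ha) * sin(lat) - tan(decl) * cos(lat)) + pi
  az <- az %% (2 * pi)
  elev <- pi / 2 - zen
  sd <- c(sin(zen) * sin(az), sin(zen) * cos(az), cos(zen))
  list(zenith = zen, azimuth = az, elevation = elev,
       sun_direction = sd / sqrt(sum(sd^2)),
       declination = decl, above_horizon = zen < pi / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Atmosphere state container
#'
#' @param T_a Air temperature (K).
#' @param h Relative humidity, fraction in `[0, 1]`.
#' @param p_atm Air pressure (Pa).
#' @param turbidity Broadband aerosol optical depth (unitless).
#' @param ozone_cm Total-column ozone (atm-cm).
#' @param C_a Ambient CO2 mole fraction (umol mol-1).
#' @param w_cm Optional precipitable water (cm); estimated from `T_a` and `h`
#'   with [precipitable_water()] if `NULL`.
#' @return A list of class `cf_atmosphere`.
#' @export
atmosphere_state <- function(T_a = 298.15, h = 0.5, p_atm = 101325,
                             turbidity = 0.05, ozone_cm = 0.3, C_a = 390,
                             w_cm = NULL) {
  if (h < 0 || h > 1) stop("relative humidity must be in [0,1]")
  if (p_atm <= 0 || T_a <= 0) stop("T_a and p_atm must be positive")
  if (is.null(w_cm)) w_cm <- precipitable_water(T_a, h)
  structure(list(T_a = T_a, h = h, p_atm = p_atm, turbidity = turbidity,
                 ozone_cm = ozone_cm, C_a = C_a, w_cm = w_cm),
            class = "cf_atmosphere")
}

#' Precipitable water from near-surface temperature and humidity
#'
#' Empirical exponential-in-dewpoint estimate
#' `w = exp(0.07 * T_dp - 0.02)` cm, with the dewpoint obtained by inverting
#' the Tetens saturation curve at the ambient vapor pressure. Increasing in
#' both temperature and humidity.
#'
#' @param T_a Air temperature (K).
#' @param h Relative humidity fraction.
#' @param coef Overridable coefficients `c(a, b)` of `w = exp(a * Tdp + b)`.
#' @return Precipitable water (cm).
#' @export
precipitable_water <- function(T_a, h, coef = c(0.07, -0.02)) {
  if (any(h < 0 | h > 1)) stop("relative humidity must be in [0,1]")
  e <- pmax(h, 1e-6) * saturation_vapor_pressure(T_a)
  lr <- log(e / 611)
  tdp <- 240.97 * lr / (17.502 - lr)   # Tetens inverse, deg C
  exp(coef[1] * tdp + coef[2])
}

# Relative optical air mass (Kasten-Young), pressure-uncorrected.
.air_mass <- function(zenith) {
  zd <- zenith * 180 / pi
  1 / (cos(zenith) + 0.50572 * (96.07995 - zd)^(-1.6364))
}

#' Clear-sky direct and diffuse shortwave fluxes
#'
#' Broadband clear-sky transmittance product: the direct normal flux is the
#' distance-corrected extraterrestrial flux multiplied by transmittances for
#' Rayleigh scattering, ozone, uniformly mixed gases, water vapor and
#' aerosols (published broadband coefficient set); the diffuse horizontal
#' flux comes from the Rayleigh- and aerosol-scattered fractions. Every
#' transmittance can be overridden for auditing through `override`.
#'
#' @param solar A solar position as returned by [solar_position()].
#' @param atm An [atmosphere_state()].
#' @param doy Day of year for the earth-sun distance correction (default 172).
#' @param override Optional named list forcing any of the transmittances
#'   `rayleigh`, `ozone`, `gas`, `water`, `aerosol` to fixed values.
#' @return List with `S_dn` (direct normal, W m-2), `S_diff` (diffuse
#'   horizontal, W m-2), `diffuse_fraction`, and the transmittances used.
#' @export
clearsky_shortwave <- function(solar, atm, doy = 172, override = list()) {
  E0 <- .const$solar * (1 + 0.033 * cos(2 * pi * doy / 365))
  if (!isTRUE(solar$above_horizon)) {
    return(list(S_dn = 0, S_diff = 0, diffuse_fraction = 0,
                transmittances = NULL, E0 = E0))
  }
  z <- solar$zenith
  am  <- .air_mass(z)
  amp <- am * atm$p_atm / 101325
  Tr <- override$rayleigh %||%
    exp(-0.0903 * amp^0.84 * (1 + amp - amp^1.01))
  X <- atm$ozone_cm * am
  To <- override$ozone %||%
    (1 - 0.1611 * X * (1 + 139.48 * X)^(-0.3035) -
       0.002715 * X / (1 + 0.044 * X + 0.0003 * X^2))
  Tg <- override$gas %||% exp(-0.0127 * amp^0.26)
  W <- atm$w_cm * am
  Tw <- override$water %||%
    (1 - 2.4959 * W / ((1 + 79.034 * W)^0.6828 + 6.385 * W))
  ta <- atm$turbidity
  Ta <- override$aerosol %||%
    exp(-ta^0.873 * (1 + ta - ta^0.7088) * am^0.9108)
  tr <- c(rayleigh = Tr, ozone = To, gas = Tg, water = Tw, aerosol = Ta)
  if (any(tr < 0)) stop("negative transmittance; check atmosphere parameters")
  S_dn <- E0 * prod(tr)
  # scattered (diffuse) components: half the Rayleigh-scattered beam plus a
  # forward-scattered aerosol share, referenced to the flux after absorption
  Taa <- 1 - 0.1 * (1 - am + am^1.06) * (1 - Ta)     # aerosol absorption part
  Tas <- Ta / Taa                                    # aerosol scattering part
  base <- E0 * cos(z) * To * Tg * Tw * Taa
  S_diff <- 0.79 * base * (0.5 * (1 - Tr) + 0.84 * (1 - Tas)) /
    (1 - am + am^1.02)
  S_diff <- max(0, S_diff)
  gh <- S_dn * cos(z) + S_diff
  list(S_dn = S_dn, S_diff = S_diff,
       diffuse_fraction = if (gh > 0) S_diff / gh else 0,
       transmittances = tr, E0 = E0)
}

#' Downwelling longwave flux on a horizontal surface
#'
#' Clear-sky effective emissivity as an increasing function of precipitable
#' water, `eps_a = 1 - (1 + w) * exp(-sqrt(1.2 + 3 w))` with `w` in cm,
#' applied to the blackbody flux at air temperature.
#'
#' @param atm An [atmosphere_state()] (uses `T_a` and `w_cm`).
#' @param eps_a Optional forced emissivity (e.g. 1 for the blackbody limit).
#' @return Flux (W m-2).
#' @export
downwelling_longwave <- function(atm, eps_a = NULL) {
  if (atm$T_a <= 0) stop("air temperature must be positive (K)")
  if (is.null(eps_a)) {
    w <- atm$w_cm
    eps_a <- 1 - (1 + w) * exp(-sqrt(1.2 + 3 * w))
  }
  eps_a * .const$sigma * atm$T_a^4
}

#' Generate a synthetic clear-sky diurnal weather series
#'
#' Sinusoidal air temperature peaking mid-afternoon (15:00 local), relative
#' humidity anti-phased with temperature, and clear-sky radiation computed at
#' every step from the solar position. Stands in for measured weather-station
#' forcing.
#'
#' @param date Date (or string) of the simulated day.
#' @param latitude,longitude,utc_offset Site location.
#' @param T_min,T_max Daily air temperature extremes (deg C); the minimum
#'   occurs at 05:00, the maximum at 15:00 local time.
#' @param RH_min,RH_max Relative humidity extremes (fractions), anti-phased
#'   with temperature.
#' @param timestep_min Output resolution (minutes).
#' @param atm Template [atmosphere_state()] supplying pressure, turbidity,
#'   ozone and CO2.
#' @return A data.frame with columns `time`, `Ta_C`, `RH`, `S_dn`, `S_diff`,
#'   `L_dn`, `zenith`.
#' @export
synth_weather <- function(date, latitude, longitude, utc_offset,
                          T_min = 16, T_max = 36, RH_min = 0.20, RH_max = 0.75,
                          timestep_min = 15, atm = atmosphere_state()) {
  if (T_max < T_min) stop("T_max must be >= T_min")
  if (any(c(RH_min, RH_max) < 0) || any(c(RH_min, RH_max) > 1)) {
    stop("RH bounds must be in [0,1]")
  }
  day0 <- as.POSIXct(paste(as.character(as.Date(date)), "00:00:00"), tz = "UTC")
  times <- day0 + seq(0, 24 * 3600, by = timestep_min * 60)
  hh <- as.numeric(times - day0, units = "hours")
  # piecewise sinusoid: minimum at 05:00, maximum at 15:00, 14-h decline
  hh2 <- ifelse(hh < 5, hh + 24, hh)
  phase <- ifelse(hh2 >= 15, cos(pi * (hh2 - 15) / 14), cos(pi * (hh2 - 15) / 10))
  u <- (phase + 1) / 2
  Ta <- T_min + (T_max - T_min) * u
  RH <- RH_max - (RH_max - RH_min) * u
  doy <- as.POSIXlt(day0)$yday + 1
  n <- length(times)
  S_dn <- S_diff <- L_dn <- zen <- numeric(n)
  for (i in seq_len(n)) {
    a <- atmosphere_state(T_a = Ta[i] + 273.15, h = RH[i], p_atm = atm$p_atm,
                          turbidity = atm$turbidity, ozone_cm = atm$ozone_cm,
                          C_a = atm$C_a)
    sp <- solar_position(times[i], latitude, longitude, utc_offset)
    sw <- clearsky_shortwave(sp, a, doy = doy)
    S_dn[i] <- sw$S_dn; S_diff[i] <- sw$S_diff
    L_dn[i] <- downwelling_longwave(a)
    zen[i] <- sp$zenith
  }
  data.frame(time = times, Ta_C = Ta, RH = RH, S_dn = S_dn, S_diff = S_diff,
             L_dn = L_dn, zenith = zen)
}
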