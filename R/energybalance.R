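#' Saturation vapor pressure (Tetens equation)
#'
#' `e_s(T) = 611 * exp(17.502 * T_C / (T_C + 240.97))` Pa with `T_C` in
#' degrees Celsius; strictly increasing in temperature.
#'
#' @param T_K Temperature (K), vectorized.
#' @return Saturation vapor pressure (Pa).
#' @export
#' @examples
#' saturation_vapor_pressure(298.15)
saturation_vapor_pressure <- function(T_K) {
  if (any(T_K <= 0)) stop("temperature must be positive (K)")
  tc <- T_K - 273.15
  611 * exp(17.502 * tc / (tc + 240.97))
}

#' Combine stomatal and boundary-layer conductances to water vapor
#'
#' Series combination `g_M = (1/g_s + 1/g_bw)^-1` with the boundary-layer
#' conductance to water vapor taken as `g_bw = 1.08 * g_H`. Either
#' conductance equal to zero gives `g_M = 0`.
#'
#' @param g_s Stomatal conductance (mol m-2 s-1), vectorized.
#' @param g_H Boundary-layer conductance to heat (mol m-2 s-1).
#' @return Overall conductance to water vapor (mol m-2 s-1).
#' @export
couple_gM <- function(g_s, g_H) {
  if (any(g_s < 0) || any(g_H < 0)) stop("conductances must be >= 0")
  g_bw <- 1.08 * g_H
  out <- rep_len(0, max(length(g_s), length(g_H)))
  g_s <- rep_len(g_s, length(out)); g_bw <- rep_len(g_bw, length(out))
  ok <- g_s > 0 & g_bw > 0
  out[ok] <- 1 / (1 / g_s[ok] + 1 / g_bw[ok])
  out
}

#' Boundary-layer conductance to heat for a flat leaf
#'
#' Laminar flat-plate form `g_H = 0.135 * sqrt(u / d)` (mol m-2 s-1) with
#' wind speed `u` (m s-1) and characteristic leaf dimension `d` (m).
#'
#' @param u Wind speed (m s-1).
#' @param d Characteristic dimension (m).
#' @return Conductance (mol m-2 s-1).
#' @export
boundary_layer_gH <- function(u, d) {
  if (any(u < 0) || any(d <= 0)) stop("need u >= 0 and d > 0")
  0.135 * sqrt(u / d)
}

#' Surface energy balance residual
#'
#' Residual of the surface energy budget at a trial surface temperature:
#' absorbed all-wave radiation minus thermal emission, sensible, latent and
#' other fluxes. Two-sided surfaces (leaves) emit from both faces
#' (`2 eps sigma T_s^4`); one-sided surfaces (ground) from one.
#'
#' @param T_s Trial surface temperature (K), vectorized.
#' @param R Absorbed all-wave radiation flux per one-sided area (W m-2).
#' @param eps Thermal emissivity.
#' @param T_a Air temperature (K).
#' @param h Relative humidity fraction.
#' @param p_atm Air pressure (Pa).
#' @param g_H Boundary-layer conductance to heat (mol m-2 s-1).
#' @param g_M Overall conductance to water vapor (mol m-2 s-1).
#' @param f_s Surface saturation fraction (1 for leaves).
#' @param Q_other Additional flux term (W m-2), e.g. storage.
#' @param twosided Logical; emit from both faces.
#' @return Residual (W m-2); positive when the surface would warm.
#' @export
energy_balance_residual <- function(T_s, R, eps, T_a, h, p_atm = 101325,
                                    g_H = 0.5, g_M = 0, f_s = 1, Q_other = 0,
                                    twosided = TRUE) {
  nf <- ifelse(twosided, 2, 1)
  emis <- nf * eps * .const$sigma * T_s^4
  H <- .const$cp * g_H * (T_s - T_a)
  E <- g_M * (saturation_vapor_pressure(T_s) * f_s -
                saturation_vapor_pressure(T_a) * h) / p_atm
  R - emis - H - .const$lambda * E - Q_other
}

#' Solve the surface energy balance for temperature (secant method)
#'
#' Secant iteration started from the deterministic bracket
#' `(T_a - 20, T_a + 20)` K, run until the residual is below `tol`.
#' All arguments are vectorized over surfaces; every surface is iterated
#' simultaneously.
#'
#' @inheritParams energy_balance_residual
#' @param tol Residual tolerance (W m-2).
#' @param max_iter Maximum secant iterations.
#' @return A list with `T_s` (K), `H`, `lambdaE` (W m-2), `E`
#'   (mol m-2 s-1), `residual`, `iterations` and `dew` (logical, TRUE where
#'   the latent flux is negative, i.e. condensation).
#' @export
solve_surface_temperature <- function(R, eps, T_a, h, p_atm = 101325,
                                      g_H = 0.5, g_M = 0, f_s = 1,
                                      Q_other = 0, twosided = TRUE,
                                      tol = 1e-4, max_iter = 100) {
  if (tol <= 0) stop("tol must be positive")
  n <- max(length(R), length(T_a), length(g_M), length(g_H), length(eps),
           length(h), length(Q_other))
  R <- rep_len(R, n); eps <- rep_len(eps, n); T_a <- rep_len(T_a, n)
  h <- rep_len(h, n); p_atm <- rep_len(p_atm, n); g_H <- rep_len(g_H, n)
  g_M <- rep_len(g_M, n); f_s <- rep_len(f_s, n)
  Q_other <- rep_len(Q_other, n); twosided <- rep_len(twosided, n)
  f <- function(x) energy_balance_residual(x, R, eps, T_a, h, p_atm, g_H,
                                           g_M, f_s, Q_other, twosided)
  x0 <- T_a - 20; x1 <- T_a + 20
  f0 <- f(x0); f1 <- f(x1)
  it <- 0L
  repeat {
    it <- it + 1L
    df <- f1 - f0
    step_ok <- abs(df) > 1e-300
    x2 <- ifelse(step_ok, x1 - f1 * (x1 - x0) / df, x1)
    # keep iterates physical
    x2 <- pmin(pmax(x2, 150), 450)
    f2 <- f(x2)
    conv <- abs(f2) <= tol
    if (all(conv) || it >= max_iter) {
      if (!all(conv)) {
        stop(sprintf(
          "energy balance failed to converge for %d surface(s) within %d iterations (worst residual %.3g W m-2, bracket [%.2f, %.2f] K)",
          sum(!conv), max_iter, max(abs(f2[!conv])), min(x1[!conv], x2[!conv]),
          max(x1[!conv], x2[!conv])))
      }
      T_s <- x2
      break
    }
    x0 <- x1; f0 <- f1; x1 <- x2; f1 <- f2
  }
  E <- g_M * (saturation_vapor_pressure(T_s) * f_s -
                saturation_vapor_pressure(T_a) * h) / p_atm
  H <- .const$cp * g_H * (T_s - T_a)
  list(T_s = T_s, H = H, lambdaE = .const$lambda * E, E = E,
       residual = f(T_s), iterations = it, dew = E < 0)
}
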