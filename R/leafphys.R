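#' Convert PAR energy flux to photon flux density
#'
#' Uses the standard conversion 4.57 umol photons per joule in the PAR band.
#'
#' @param flux_W_m2 PAR energy flux (W m-2).
#' @return Photon flux density Q (umol m-2 s-1).
#' @export
par_energy_to_photons <- function(flux_W_m2) {
  if (any(flux_W_m2 < 0)) stop("PAR flux must be >= 0")
  .const$par_photon * flux_W_m2
}

#' Stomatal conductance model parameters
#'
#' Coefficients of the hyperbolic light/VPD stomatal response. Defaults are
#' the fitted almond values: `E_m` the maximum transpiration rate
#' (mmol m-2 s-1), `i_0` a photon-flux offset for dark transpiration
#' (umol m-2 s-1), and `k` (umol m-2 s-1 mmol mol-1), `b` (mmol mol-1) bulk
#' parameters.
#'
#' @param E_m,i_0,k,b Model coefficients (all positive).
#' @return A list of class `cf_stomatal_params`.
#' @export
stomatal_params <- function(E_m = 20.43, i_0 = 38.48, k = 18383, b = 49.68) {
  if (any(c(E_m, i_0, k, b) <= 0)) stop("stomatal parameters must be positive")
  structure(list(E_m = E_m, i_0 = i_0, k = k, b = b),
            class = "cf_stomatal_params")
}

#' Stomatal conductance as a hyperbolic function of light and VPD
#'
#' `g_s = E_m (Q + i_0) / (k + b Q + (Q + i_0) D)`. With the documented
#' parameter units (`E_m` mmol m-2 s-1, `Q` umol m-2 s-1, `D` mmol mol-1,
#' `k` umol m-2 s-1 mmol mol-1, `b` mmol mol-1) the value is in
#' mol m-2 s-1. Increasing in `Q`, decreasing in `D`; bounded above by
#' `E_m / D` for `D > 0`.
#'
#' @param Q Photosynthetic photon flux density (umol m-2 s-1).
#' @param D Leaf-to-air vapor pressure deficit (mmol mol-1).
#' @param params A [stomatal_params()] object.
#' @return Stomatal conductance to water vapor (mol m-2 s-1).
#' @export
#' @examples
#' stomatal_conductance(2000, 10, stomatal_params())
stomatal_conductance <- function(Q, D, params = stomatal_params()) {
  if (any(Q < 0) || any(D < 0)) stop("Q and D must be >= 0")
  p <- params
  p$E_m * (Q + p$i_0) / (p$k + p$b * Q + (Q + p$i_0) * D)
}

#' Vapor pressure deficit between leaf interior and ambient air
#'
#' Mole-fraction VPD `D = (e_s(T_L) - h e_s(T_a)) / p_atm * 1000`
#' (mmol mol-1), floored at zero.
#'
#' @param T_L Leaf temperature (K).
#' @param T_a Air temperature (K).
#' @param h Ambient relative humidity fraction.
#' @param p_atm Air pressure (Pa).
#' @return VPD (mmol mol-1).
#' @export
vapor_pressure_deficit <- function(T_L, T_a, h, p_atm = 101325) {
  pmax(0, (saturation_vapor_pressure(T_L) -
             h * saturation_vapor_pressure(T_a)) / p_atm * 1000)
}

#' FvCB C3 photosynthesis parameters
#'
#' Rates at 25 C in umol m-2 s-1 (`R_d25`, `V_cmax25`, `J_max25`), the
#' two-parameter temperature response of the maximum electron transport rate
#' (`C_Jmax` unitless, `dHa_Jmax` kJ mol-1; multiplier
#' `exp(C_Jmax - dHa_Jmax/(Rg T))`, which is ~1 at 25 C for the defaults),
#' the initial quantum yield `alpha`, Michaelis constants and the CO2
#' compensation point at 25 C with their Arrhenius activation energies
#' (kJ mol-1), ambient oxygen `O` (mmol mol-1), and the electron-transport
#' curvature `theta_J`.
#'
#' @param R_d25,V_cmax25,J_max25,C_Jmax,dHa_Jmax,alpha Fitted parameters.
#' @param K_c25,Ha_Kc,K_o25,Ha_Ko,Gamma25,Ha_Gamma,Ha_Vcmax,Ha_Rd Kinetic
#'   constants and activation energies (Bernacchi-style defaults).
#' @param O Oxygen mole fraction (mmol mol-1).
#' @param theta_J Curvature of the electron transport light response.
#' @return A list of class `cf_fvcb_params`.
#' @export
fvcb_params <- function(R_d25 = 1.491, V_cmax25 = 99.5, J_max25 = 185.0,
                        C_Jmax = 17.57, dHa_Jmax = 43.54, alpha = 0.41,
                        K_c25 = 404.9, Ha_Kc = 79.43,
                        K_o25 = 278.4, Ha_Ko = 36.38,
                        Gamma25 = 42.75, Ha_Gamma = 37.83,
                        Ha_Vcmax = 65.33, Ha_Rd = 46.39,
                        O = 210, theta_J = 0.7) {
  p <- list(R_d25 = R_d25, V_cmax25 = V_cmax25, J_max25 = J_max25,
            C_Jmax = C_Jmax, dHa_Jmax = dHa_Jmax, alpha = alpha,
            K_c25 = K_c25, Ha_Kc = Ha_Kc, K_o25 = K_o25, Ha_Ko = Ha_Ko,
            Gamma25 = Gamma25, Ha_Gamma = Ha_Gamma, Ha_Vcmax = Ha_Vcmax,
            Ha_Rd = Ha_Rd, O = O, theta_J = theta_J)
  if (any(unlist(p) <= 0)) stop("FvCB parameters must be positive")
  structure(p, class = "cf_fvcb_params")
}

# Arrhenius multiplier normalized to 1 at 25 C; Ha in kJ mol-1.
.arrhenius <- function(Ha, T_K) {
  exp(1000 * Ha / .const$Rgas * (1 / 298.15 - 1 / T_K))
}

#' FvCB net assimilation at given intercellular CO2
#'
#' Rubisco-limited and RuBP-regeneration-limited gross rates with Arrhenius
#' temperature scaling of `V_cmax`, `R_d`, `K_c`, `K_o` and `Gamma*`, the
#' two-parameter exponential response of `J_max`, and a non-rectangular
#' hyperbola light response for the electron transport rate `J`. Net
#' assimilation is `min(A_c, A_j) - R_d`.
#'
#' @param C_i Intercellular CO2 (umol mol-1), > 0.
#' @param Q Photon flux density (umol m-2 s-1).
#' @param T_L Leaf temperature (K).
#' @param params A [fvcb_params()] object.
#' @return A list with `A_c`, `A_j` (gross, umol m-2 s-1), `A_net`, `R_d`,
#'   `J`, `Gamma_star` and `limitation` (`"Rubisco"` or `"RuBP"`).
#' @export
fvcb_assimilation <- function(C_i, Q, T_L, params = fvcb_params()) {
  if (any(C_i <= 0)) stop("C_i must be positive")
  p <- params
  Vc <- p$V_cmax25 * .arrhenius(p$Ha_Vcmax, T_L)
  Rd <- p$R_d25 * .arrhenius(p$Ha_Rd, T_L)
  Kc <- p$K_c25 * .arrhenius(p$Ha_Kc, T_L)
  Ko <- p$K_o25 * .arrhenius(p$Ha_Ko, T_L)
  Gs <- p$Gamma25 * .arrhenius(p$Ha_Gamma, T_L)
  Jm <- p$J_max25 * exp(p$C_Jmax - 1000 * p$dHa_Jmax / (.const$Rgas * T_L))
  aq <- p$alpha * Q
  disc <- pmax(0, (aq + Jm)^2 - 4 * p$theta_J * aq * Jm)
  J <- (aq + Jm - sqrt(disc)) / (2 * p$theta_J)
  A_c <- Vc * (C_i - Gs) / (C_i + Kc * (1 + p$O / Ko))
  A_j <- J * (C_i - Gs) / (4 * C_i + 8 * Gs)
  A_net <- pmin(A_c, A_j) - Rd
  list(A_c = A_c, A_j = A_j, A_net = A_net, R_d = Rd, J = J, Gamma_star = Gs,
       limitation = ifelse(A_c <= A_j, "Rubisco", "RuBP"))
}

#' Solve the coupled assimilation / intercellular CO2 balance
#'
#' Finds the fixed point of `A(C_i) = g_tc (C_a - C_i)` with the CO2
#' transport conductance `g_tc = (1.6/g_s + 1.37/g_bc)^-1` by damped
#' fixed-point iteration. Vectorized over leaves.
#'
#' @param Q Photon flux density (umol m-2 s-1).
#' @param T_L Leaf temperature (K).
#' @param g_s Stomatal conductance to water vapor (mol m-2 s-1), > 0.
#' @param C_a Ambient CO2 (umol mol-1).
#' @param g_bc Boundary-layer conductance to CO2... supplied as the heat
#'   boundary-layer value is customary; pass a large number to remove the
#'   boundary-layer limitation.
#' @param params A [fvcb_params()] object.
#' @param tol Convergence tolerance on `C_i` (umol mol-1).
#' @param max_iter Iteration cap.
#' @return A list with `A` (net, umol m-2 s-1), `C_i`, `g_s`, `limitation`
#'   and `iterations`.
#' @export
solve_coupled_A_Ci <- function(Q, T_L, g_s, C_a = 390, g_bc = 1,
                               params = fvcb_params(), tol = 0.01,
                               max_iter = 200) {
  if (any(g_s <= 0)) stop("g_s must be positive")
  n <- max(length(Q), length(T_L), length(g_s))
  Q <- rep_len(Q, n); T_L <- rep_len(T_L, n); g_s <- rep_len(g_s, n)
  g_tc <- 1 / (1.6 / g_s + 1.37 / rep_len(g_bc, n))
  # analytic per-branch solution of A(C_i) = g_tc (C_a - C_i) as initializer;
  # each limitation branch gives a quadratic in C_i with one positive root
  p <- params
  Vc <- p$V_cmax25 * .arrhenius(p$Ha_Vcmax, T_L)
  Rd <- p$R_d25 * .arrhenius(p$Ha_Rd, T_L)
  Kc <- p$K_c25 * .arrhenius(p$Ha_Kc, T_L)
  Ko <- p$K_o25 * .arrhenius(p$Ha_Ko, T_L)
  Gs <- p$Gamma25 * .arrhenius(p$Ha_Gamma, T_L)
  Jm <- p$J_max25 * exp(p$C_Jmax - 1000 * p$dHa_Jmax / (.const$Rgas * T_L))
  aq <- p$alpha * Q
  J <- (aq + Jm - sqrt(pmax(0, (aq + Jm)^2 - 4 * p$theta_J * aq * Jm))) /
    (2 * p$theta_J)
  K <- Kc * (1 + p$O / Ko)
  qpos <- function(a, b, cc) (-b + sqrt(pmax(0, b^2 - 4 * a * cc))) / (2 * a)
  Ci_c <- qpos(g_tc, Vc - Rd + g_tc * (K - C_a),
               -(Vc * Gs + Rd * K + g_tc * C_a * K))
  Ci_j <- qpos(4 * g_tc, J - 4 * Rd + g_tc * (8 * Gs - 4 * C_a),
               -(J * Gs + 8 * Rd * Gs + 8 * g_tc * C_a * Gs))
  Ci <- pmax(pmax(Ci_c, Ci_j), 1e-3)
  it <- 0L
  repeat {
    it <- it + 1L
    f <- fvcb_assimilation(pmax(Ci, 1e-6), Q, T_L, params)
    Ci_new <- C_a - f$A_net / g_tc
    Ci_new <- pmax(Ci_new, 1e-3)
    d <- Ci_new - Ci
    Ci <- Ci + 0.5 * d
    if (max(abs(d)) < tol) break
    if (it >= max_iter) {
      stop(sprintf(
        "A-Ci coupling failed to converge: %d leaves, worst |dCi| = %.4g after %d iterations",
        sum(abs(d) >= tol), max(abs(d)), it))
    }
  }
  f <- fvcb_assimilation(pmax(Ci, 1e-6), Q, T_L, params)
  list(A = f$A_net, C_i = Ci, g_s = g_s, limitation = f$limitation,
       iterations = it)
}

#' Reference gas-exchange measurement design
#'
#' Ten light/temperature/humidity combinations emulating a standard
#' chamber protocol: a seven-point light response at 25 C and 60% RH plus
#' three high-light points at elevated temperature and varied humidity.
#'
#' @return A data.frame with columns `Q` (umol m-2 s-1), `T_L` (K), `RH`.
#' @export
gas_exchange_design <- function() {
  data.frame(
    Q = c(0, 50, 200, 400, 800, 1200, 2000, 2000, 2000, 2000),
    T_L = 273.15 + c(25, 25, 25, 25, 25, 25, 25, 30, 35, 35),
    RH = c(rep(0.6, 7), 0.45, 0.30, 0.60)
  )
}

#' Simulate gas-exchange observations from known parameters
#'
#' Forward model used by the parameter-recovery machinery: stomatal
#' conductance from the hyperbolic model and net assimilation from the
#' coupled FvCB solution at that conductance. Optional multiplicative
#' Gaussian noise.
#'
#' @param design Data.frame with `Q`, `T_L` (K), `RH` columns.
#' @param sp,fp True parameter objects.
#' @param C_a Ambient CO2 (umol mol-1).
#' @param p_atm Pressure (Pa).
#' @param g_bc Boundary-layer conductance (mol m-2 s-1).
#' @param noise_sd Multiplicative noise s.d. (0 = noiseless).
#' @return `design` with added `A_obs`, `gs_obs` columns.
#' @export
simulate_gas_exchange <- function(design = gas_exchange_design(),
                                  sp = stomatal_params(), fp = fvcb_params(),
                                  C_a = 390, p_atm = 101325, g_bc = 2,
                                  noise_sd = 0) {
  D <- vapor_pressure_deficit(design$T_L, design$T_L, design$RH, p_atm)
  gs <- stomatal_conductance(design$Q, D, sp)
  A <- solve_coupled_A_Ci(design$Q, design$T_L, gs, C_a, g_bc, fp)$A
  if (noise_sd > 0) {
    gs <- gs * (1 + rnorm(length(gs), 0, noise_sd))
    A <- A * (1 + rnorm(length(A), 0, noise_sd))
  }
  cbind(design, data.frame(A_obs = A, gs_obs = pmax(gs, 1e-4)))
}

#' Fit stomatal and photosynthesis parameters to gas-exchange data
#'
#' Least-squares fits: the stomatal coefficients by Levenberg-Marquardt on
#' the hyperbolic conductance model, then the FvCB parameters (`R_d25`,
#' `V_cmax25`, `J_max25`, `dHa_Jmax`, `alpha`) on the coupled net-assimilation
#' prediction evaluated at the observed conductances. `C_Jmax` is tied to
#' `dHa_Jmax` by `C_Jmax = dHa_Jmax / (Rg * 298.15)` (unit multiplier at
#' 25 C), which removes its redundancy with `J_max25`.
#'
#' @param data Data.frame with columns `Q`, `T_L` (K), `RH`, `A_obs`,
#'   `gs_obs`. Chamber air temperature is taken equal to leaf temperature.
#' @param C_a Ambient CO2 (umol mol-1).
#' @param p_atm Pressure (Pa).
#' @param g_bc Chamber boundary-layer conductance (mol m-2 s-1).
#' @return A list with elements `stomatal` ([stomatal_params()]) and `fvcb`
#'   ([fvcb_params()]).
#' @export
fit_gas_exchange <- function(data, C_a = 390, p_atm = 101325, g_bc = 2) {
  need <- c("Q", "T_L", "RH", "A_obs", "gs_obs")
  if (!all(need %in% names(data))) {
    stop("gas-exchange table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(data) < 5) {
    stop("need at least as many observations (", nrow(data),
         ") as free parameters (5 for the photosynthesis fit)")
  }
  D <- vapor_pressure_deficit(data$T_L, data$T_L, data$RH, p_atm)
  sfit <- minpack.lm::nlsLM(
    gs_obs ~ E_m * (Q + i_0) / (k + b * Q + (Q + i_0) * D),
    data = cbind(data, D = D),
    start = list(E_m = 10, i_0 = 20, k = 8000, b = 20),
    lower = c(1e-3, 1e-3, 1, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  sp <- do.call(stomatal_params, as.list(coef(sfit)))

  predA <- function(R_d25, V_cmax25, J_max25, dHa_Jmax, alpha) {
    fp <- fvcb_params(R_d25 = R_d25, V_cmax25 = V_cmax25, J_max25 = J_max25,
                      C_Jmax = 1000 * dHa_Jmax / (.const$Rgas * 298.15),
                      dHa_Jmax = dHa_Jmax, alpha = alpha)
    # tight tolerance: the least-squares jacobian is computed by finite
    # differences, so the prediction must be smooth well below the step size
    solve_coupled_A_Ci(data$Q, data$T_L, data$gs_obs, C_a, g_bc, fp,
                       tol = 1e-7)$A
  }
  # Stage 1: the four parameters that are always identifiable from a light
  # curve plus high-light temperature points (the Jmax activation energy only
  # influences observations that are RuBP-limited away from 25 C, which this
  # classic design need not contain).
  dHa0 <- 50
  f1 <- minpack.lm::nlsLM(
    A_obs ~ predA(R_d25, V_cmax25, J_max25, dHa0, alpha),
    data = data,
    start = list(R_d25 = 1, V_cmax25 = 60, J_max25 = 120, alpha = 0.3),
    lower = c(0.01, 5, 5, 0.01), upper = c(20, 500, 800, 1),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  c1 <- coef(f1)
  # Stage 2: refine all five when the activation energy is identifiable;
  # otherwise keep the stage-1 fit with the prior value.
  cf <- tryCatch({
    f2 <- minpack.lm::nlsLM(
      A_obs ~ predA(R_d25, V_cmax25, J_max25, dHa_Jmax, alpha),
      data = data,
      start = list(R_d25 = c1[["R_d25"]], V_cmax25 = c1[["V_cmax25"]],
                   J_max25 = c1[["J_max25"]], dHa_Jmax = dHa0,
                   alpha = c1[["alpha"]]),
      lower = c(0.01, 5, 5, 5, 0.01), upper = c(20, 500, 800, 200, 1),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    coef(f2)
  }, error = function(e) c(c1, dHa_Jmax = dHa0))
  fp <- fvcb_params(R_d25 = cf[["R_d25"]], V_cmax25 = cf[["V_cmax25"]],
                    J_max25 = cf[["J_max25"]],
                    C_Jmax = 1000 * cf[["dHa_Jmax"]] / (.const$Rgas * 298.15),
                    dHa_Jmax = cf[["dHa_Jmax"]], alpha = cf[["alpha"]])
  list(stomatal = sp, fvcb = fp)
}
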