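test_that("PAR energy to photon conversion uses the standard factor", {
  expect_equal(par_energy_to_photons(0), 0)
  expect_equal(par_energy_to_photons(100), 457)
  expect_equal(par_energy_to_photons(2000 / 4.57), 2000, tolerance = 1e-3)
  expect_error(par_energy_to_photons(-1), ">= 0")
})

test_that("stomatal conductance reproduces hand arithmetic exactly", {
  sp <- stomatal_params()
  # Q = 0, D = 0: g_s = E_m * i_0 / k
  expect_equal(stomatal_conductance(0, 0, sp), 20.43 * 38.48 / 18383,
               tolerance = 1e-9)
  # Q = 2000, D = 10
  expect_equal(stomatal_conductance(2000, 10, sp),
               20.43 * (2000 + 38.48) /
                 (18383 + 49.68 * 2000 + (2000 + 38.48) * 10),
               tolerance = 1e-9)
  # increasing in Q, decreasing in D
  Q <- seq(0, 2500, by = 50)
  expect_true(all(diff(stomatal_conductance(Q, 15, sp)) > 0))
  D <- seq(0, 60, by = 2)
  expect_true(all(diff(stomatal_conductance(1000, D, sp)) < 0))
  # bounded above by E_m / D (mmol over mmol/mol -> mol m-2 s-1)
  expect_lt(stomatal_conductance(1e7, 20, sp), 20.43 / 20)
})

test_that("FvCB limits are correct at the compensation point and in the dark", {
  fp <- fvcb_params()
  TL <- 298.15
  f0 <- fvcb_assimilation(300, 1000, TL, fp)
  gs_star <- f0$Gamma_star
  fc <- fvcb_assimilation(gs_star, 1000, TL, fp)
  expect_equal(fc$A_net, -fc$R_d, tolerance = 1e-9)
  fd <- fvcb_assimilation(300, 0, TL, fp)
  expect_equal(fd$J, 0, tolerance = 1e-9)
  expect_equal(fd$A_net, -fd$R_d, tolerance = 1e-9)
  expect_equal(fd$R_d, 1.491, tolerance = 1e-9)   # 25 C reference value
})

test_that("light response is saturating and bounded by the RuBP ceiling", {
  fp <- fvcb_params()
  Q <- seq(0, 2500, by = 25)
  A <- fvcb_assimilation(280, Q, 298.15, fp)$A_net
  expect_true(all(diff(A) > -1e-12))       # non-decreasing
  expect_lt(A[length(A)] - A[length(A) - 10], 0.05)  # saturated at high Q
  # A_net + R_d <= J / 4 everywhere (electron-transport ceiling)
  f <- fvcb_assimilation(280, Q, 298.15, fp)
  expect_true(all(f$A_net + f$R_d <= f$J / 4 + 1e-9))
  # a frozen mid-curve value from the closed-form expressions evaluated
  # independently (Rubisco-limited branch at 25 C, Ci = 280)
  Kc <- 404.9; Ko <- 278.4; Gs <- 42.75
  Ac_oracle <- 99.5 * (280 - Gs) / (280 + Kc * (1 + 210 / Ko))
  expect_equal(fvcb_assimilation(280, 2000, 298.15, fp)$A_c, Ac_oracle,
               tolerance = 1e-9)
})

test_that("coupled A-Ci solution has the right limits and matches a grid scan", {
  fp <- fvcb_params()
  # large g_s: no diffusive limitation
  big <- solve_coupled_A_Ci(1500, 298.15, 50, 390, g_bc = 100, fp)
  expect_equal(big$C_i, 390, tolerance = 1)
  # dark: respiration drives C_i above ambient
  dark <- solve_coupled_A_Ci(0, 298.15, 0.05, 390, 1, fp)
  expect_equal(dark$A, -fvcb_assimilation(dark$C_i, 0, 298.15, fp)$R_d,
               tolerance = 1e-6)
  expect_gt(dark$C_i, 390)
  # brute-force scan oracle over C_i
  for (Q in c(100, 600, 1800)) {
    for (gs in c(0.05, 0.15, 0.4)) {
      sol <- solve_coupled_A_Ci(Q, 303.15, gs, 390, 1, fp)
      ci_grid <- seq(0.01, 780, by = 0.01)
      g_tc <- 1 / (1.6 / gs + 1.37 / 1)
      gap <- abs(fvcb_assimilation(ci_grid, Q, 303.15, fp)$A_net -
                   g_tc * (390 - ci_grid))
      ci_star <- ci_grid[which.min(gap)]
      expect_equal(sol$C_i, ci_star, tolerance = 0.05)
    }
  }
  # continuity in Q across the Rubisco/RuBP crossover: no jump exceeds the
  # smooth light-response slope near the origin (~alpha/4 per photon)
  Q <- seq(0, 2400, by = 4)
  A <- solve_coupled_A_Ci(Q, 298.15, 0.25, 390, 1, fp)$A
  expect_lt(max(abs(diff(A))), 0.41 * 4 / 2)
})

test_that("parameter fitting recovers the truth from noiseless data", {
  dat <- simulate_gas_exchange(noise_sd = 0)
  fit <- fit_gas_exchange(dat)
  for (p in c("E_m", "i_0", "k", "b")) {
    expect_equal(fit$stomatal[[p]], stomatal_params()[[p]],
                 tolerance = 1e-3)
  }
  truth <- fvcb_params()
  for (p in c("R_d25", "V_cmax25", "alpha")) {
    expect_equal(fit$fvcb[[p]], truth[[p]], tolerance = 2e-3)
  }
  # Jmax is compared as the effective 25 C value: the two-parameter
  # temperature multiplier exp(C - Ha/(Rg T)) is ~1.006 (not exactly 1) at
  # 25 C for the reference coefficient pair, and the fit normalizes it to 1
  jm_eff <- function(p) p$J_max25 * exp(p$C_Jmax - 1000 * p$dHa_Jmax /
                                          (8.314 * 298.15))
  expect_equal(jm_eff(fit$fvcb), jm_eff(truth), tolerance = 2e-3)
  # the fitted model reproduces the observations regardless of the weakly
  # identified Jmax activation energy
  pred <- solve_coupled_A_Ci(dat$Q, dat$T_L, dat$gs_obs, 390, 2,
                             fit$fvcb, tol = 1e-7)$A
  expect_equal(pred, dat$A_obs, tolerance = 1e-3)
  expect_error(fit_gas_exchange(simulate_gas_exchange()[1:3, ]),
               "at least as many")
})
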