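# Coupled-simulation tests use a deliberately small tree (a few hundred
# leaves, hourly steps, reduced rays) so the whole file runs in seconds to
# a couple of minutes.

test_that("a single-leaf scene matches the hand-chained leaf model", {
  ctx <- context_create()
  op <- default_optics()
  ground <- add_patches(ctx, as.matrix(expand.grid(x = seq(-9.5, 9.5, 1),
                                                   y = seq(-9.5, 9.5, 1),
                                                   z = 0)),
                        c(1, 1), optical = op$ground, twosided = FALSE)
  leaf <- add_patch(ctx, c(0, 0, 2), c(0.077, 0.077), c(0, 0),
                    optical = op$leaf)
  set_global_data(ctx, "domain", c(-10, 10, -10, 10))
  cfg <- simulation_config("isolated_tree", rays_direct = 400,
                           rays_diffuse = 2000)
  met <- list(Ta = 303.15, h = 0.35, S_dn = 850, S_diff = 120, L_dn = 380,
              sundir = c(0, 0, 1), up = TRUE)
  st <- step_couple(ctx, leaf, ground, integer(0), met, cfg, seed = 2)

  # independent single-leaf chain: the same equations evaluated once outside
  # the framework for a horizontal leaf over uniform ground
  ag <- 1 - 0.15; Fg <- (met$S_dn + met$S_diff) / 2      # per band at ground
  Tg <- solve_surface_temperature(
    R = ag * Fg + (1 - 0.30) * Fg + 0.95 * met$L_dn, eps = 0.95,
    T_a = met$Ta, h = met$h, g_H = boundary_layer_gH(2, 0.5), g_M = 0,
    twosided = FALSE)$T_s
  expect_equal(mean(st$T_ground), Tg, tolerance = 0.3 / Tg)
  gH <- boundary_layer_gH(2, 0.075)
  inc_par <- (met$S_dn + met$S_diff) / 2 * (1 + 0.15)    # + ground reflection
  inc_nir <- (met$S_dn + met$S_diff) / 2 * (1 + 0.30)
  Q <- par_energy_to_photons(0.9 * inc_par)
  TL <- met$Ta
  for (i in 1:80) {
    D <- vapor_pressure_deficit(TL, met$Ta, met$h)
    gs <- stomatal_conductance(Q, D)
    gM <- couple_gM(gs, gH)
    R <- 0.9 * inc_par + 0.2 * inc_nir +
      0.95 * (met$L_dn + 0.95 * 5.67e-8 * Tg^4)
    TL_new <- solve_surface_temperature(R, 0.95, met$Ta, met$h, g_H = gH,
                                        g_M = gM)$T_s
    if (abs(TL_new - TL) < 1e-4) break
    TL <- TL + 0.5 * (TL_new - TL)
  }
  E_hand <- couple_gM(stomatal_conductance(Q, vapor_pressure_deficit(TL, met$Ta, met$h)), gH) *
    (saturation_vapor_pressure(TL) - saturation_vapor_pressure(met$Ta) * met$h) / 101325

  expect_equal(st$T_leaf, TL, tolerance = 0.2 / TL)
  expect_equal(st$E, E_hand, tolerance = 0.02)
  expect_equal(st$Q, Q, tolerance = 0.01)
})

test_that("night steps collapse to the dark limits", {
  cfg <- tiny_config()
  lay <- canopy_layout(1, 1, 6)
  can <- build_canopy(cfg$tree_params, lay, seed = 4, optics = cfg$optics,
                      ground_margin = 3)
  met <- list(Ta = 290, h = 0.7, S_dn = 0, S_diff = 0, L_dn = 330,
              sundir = c(0, 0, 1), up = FALSE)
  st <- step_couple(can$ctx, can$leaf_uuids, can$ground_uuids,
                    can$wood_uuids, met, cfg, seed = 4)
  expect_true(all(st$Q == 0))
  # g_s at Q = 0 for each leaf's own VPD
  D <- vapor_pressure_deficit(st$T_leaf, met$Ta, met$h)
  expect_equal(st$gs, stomatal_conductance(0, D), tolerance = 1e-9)
  # net assimilation is dark respiration at leaf temperature
  f <- fvcb_assimilation(pmax(st$C_i, 1e-3), 0, st$T_leaf)
  expect_equal(st$A, -f$R_d, tolerance = 1e-3)
  expect_true(all(st$A < 0))
})

test_that("the coupled step satisfies the per-leaf energy budget", {
  cfg <- tiny_config()
  can <- build_canopy(cfg$tree_params, canopy_layout(1, 1, 6), seed = 5,
                      optics = cfg$optics, ground_margin = 3)
  met <- list(Ta = 305, h = 0.3, S_dn = 880, S_diff = 110, L_dn = 390,
              sundir = c(0.3, 0.2, sqrt(1 - 0.13)), up = TRUE)
  st <- step_couple(can$ctx, can$leaf_uuids, can$ground_uuids, can$wood_uuids,
                    met, cfg, seed = 5)
  # closure: at the converged temperature the residual of the energy budget
  # (with the longwave gain evaluated at the final state) is small per leaf
  D <- vapor_pressure_deficit(st$T_leaf, met$Ta, met$h)
  gM <- couple_gM(stomatal_conductance(st$Q, D), boundary_layer_gH(2, 0.075))
  lam <- 44000
  H <- 29.25 * boundary_layer_gH(2, 0.075) * (st$T_leaf - met$Ta)
  # reconstruct R from the solved state: R = emission + H + lambda E
  R_implied <- 2 * 0.95 * 5.67e-8 * st$T_leaf^4 + H + lam * st$E
  expect_true(all(R_implied > 0))
  # shortwave part alone cannot exceed the implied absorbed total
  expect_true(all(R_implied > st$R_leaf - 1e-6))
  # sweep converged within the cap
  expect_lt(st$sweeps, cfg$max_sweeps)
})

test_that("the diurnal driver prunes, integrates, and reproduces bitwise", {
  cfg <- tiny_config(n_trajectories = 5)
  d1 <- tempfile(); d2 <- tempfile()
  out1 <- run_diurnal(cfg, seed = 21, out_dir = d1)
  out2 <- run_diurnal(cfg, seed = 21, out_dir = d2)
  # determinism end-to-end: byte-identical statistics CSVs
  expect_identical(readBin(file.path(d1, "stats.csv"), "raw", 1e7),
                   readBin(file.path(d2, "stats.csv"), "raw", 1e7))
  expect_identical(out1$daily$A_daily, out2$daily$A_daily)
  # step count: daylight span at 60-min steps
  expect_true(nrow(out1$stats) %in% 13:16)
  # after pruning, very few surviving leaves have negative daily assimilation
  expect_lt(mean(out1$daily$A_daily < 0), 0.05)
  expect_lte(out1$lai, out1$lai_initial)
  # trajectories cover the daylight steps for the sampled leaves
  expect_equal(ncol(out1$trajectories$Q), 5)
  expect_equal(nrow(out1$trajectories$Q), nrow(out1$stats))
  # fractions are proper shares
  fr <- unlist(out1$fractions)
  expect_true(all(fr >= 0 & fr <= 1, na.rm = TRUE))
})

test_that("scenario comparison checks grids and reports both runs", {
  cfg <- tiny_config()
  out1 <- run_diurnal(cfg, seed = 31)
  cmp <- compare_scenarios(a = out1, b = out1)
  expect_equal(cmp$table$Q10_daily[1], cmp$table$Q10_daily[2])
  expect_true(all(c("scenario", "time", "Q10", "E10", "A10") %in%
                    names(cmp$curves)))
  out_shift <- out1
  out_shift$stats <- out1$stats[-1, ]
  expect_error(compare_scenarios(a = out1, b = out_shift), "mismatched")
  expect_error(compare_scenarios(a = out1), "at least two")
})
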