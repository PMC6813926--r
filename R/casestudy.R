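# Coupled diurnal simulation: radiation -> energy balance -> stomatal
# conductance -> photosynthesis, per leaf, over a day.

#' Configuration for the diurnal canopy case study
#'
#' Defaults reproduce the study conditions: a 3x3 block of almond-like trees
#' at 1 tree per 36 m^2 with periodic lateral boundaries (`dense_canopy`) or
#' a single tree with open surroundings (`isolated_tree`); 60 cm^2 leaves;
#' leaf reflectivity = transmissivity = 0.05 (PAR) and 0.4 (NIR); ambient
#' CO2 390 umol mol-1; a clear midsummer day at 36.6 N with 15-min steps;
#' 200 direct and 500 diffuse rays per primitive.
#'
#' @param scenario `"dense_canopy"` or `"isolated_tree"`.
#' @param ... Overrides for any configuration field.
#' @return A list of class `cf_config`.
#' @export
simulation_config <- function(scenario = c("dense_canopy", "isolated_tree"),
                              ...) {
  scenario <- match.arg(scenario)
  cfg <- list(
    scenario = scenario,
    date = "2022-06-21", latitude = 36.6, longitude = -119.5, utc_offset = -8,
    timestep_min = 15,
    T_min = 16, T_max = 36, RH_min = 0.20, RH_max = 0.75,
    p_atm = 101325, turbidity = 0.12, C_a = 390,
    nx = if (scenario == "dense_canopy") 3 else 1,
    ny = if (scenario == "dense_canopy") 3 else 1,
    spacing = 6,
    periodic = scenario == "dense_canopy",
    ground_margin = if (scenario == "dense_canopy") 0 else 6,
    tree_params = tree_params_almond(),
    optics = default_optics(),
    rays_direct = 200, rays_diffuse = 500,
    scattering_iterations = 3,
    max_sweeps = 30, dT_tol = 0.05, damping = 0.5,
    wind = 2, leaf_dim = 0.075,
    stomatal = stomatal_params(), fvcb = fvcb_params(),
    n_trajectories = 10
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "cf_config")
}

# Precompute everything reusable across time steps for a fixed geometry.
.engine_build <- function(ctx, leaf_uuids, ground_uuids, wood_uuids, cfg,
                          seed, domain) {
  periodic <- if (cfg$periodic) domain else NULL
  scene <- scene_build(ctx, periodic = periodic)
  recv <- c(leaf_uuids, ground_uuids)
  cache <- hemisphere_cache(scene, cfg$rays_diffuse, seed, receivers = recv)
  nl <- length(leaf_uuids); ng <- length(ground_uuids)
  op <- lapply(c(PAR = "PAR", NIR = "NIR", LW = "LW"), function(b) {
    .band_optics(ctx, scene$uuids, b)
  })
  pk_recv <- match(recv, scene$uuids)
  list(ctx = ctx, scene = scene, cache = cache, cfg = cfg,
       leaf_uuids = leaf_uuids, ground_uuids = ground_uuids,
       wood_uuids = wood_uuids,
       nl = nl, ng = ng,
       i_leaf = seq_len(nl), i_ground = nl + seq_len(ng),
       pk_recv = pk_recv,
       pk_wood = match(wood_uuids, scene$uuids),
       nf_recv = ifelse(ctx$twosided[recv], 2, 1),
       op = op,
       gH_leaf = boundary_layer_gH(cfg$wind, cfg$leaf_dim),
       gH_ground = boundary_layer_gH(max(cfg$wind, 0.5), 0.5),
       normal = ctx$normal[recv, , drop = FALSE],
       seed = seed)
}

# One coupled time step. met: list(Ta, h, S_dn, S_diff, L_dn, sundir, up).
# Tprev: list(leaf, ground) previous-step temperatures (K) for warm starts.
.engine_step <- function(eng, met, Tprev) {
  cfg <- eng$cfg
  nl <- eng$nl; ng <- eng$ng
  il <- eng$i_leaf; ig <- eng$i_ground
  nrecv <- nl + ng
  # --- shortwave: one geometric trace, two bands ---------------------------
  inc_dir <- numeric(nrecv)
  if (met$up && met$S_dn > 1) {   # skip the trace when the beam is negligible
    ridx0 <- eng$pk_recv - 1L
    nrep <- 0L
    if (!is.null(eng$scene$periodic)) {
      zen <- acos(min(1, max(-1, met$sundir[3])))
      travel <- diff(eng$scene$zrange) * tan(min(zen, 1.48))
      perx <- eng$scene$periodic[2] - eng$scene$periodic[1]
      nrep <- max(1L, min(3L, as.integer(ceiling(travel / perx))))
    }
    fhat <- cpp_trace_collimated(eng$scene$ptr, met$sundir, ridx0,
                                 as.integer(cfg$rays_direct),
                                 as.double(eng$seed), -1, nrep)
    cosi <- drop(eng$normal %*% met$sundir)
    cosi <- ifelse(eng$nf_recv == 2, abs(cosi), pmax(0, cosi))
    inc_dir <- cosi * fhat      # per unit collimated flux
  }
  skyfrac <- eng$nf_recv * eng$cache$sky / eng$cache$nrays
  # both shortwave bands share the sampled geometry; their scattering passes
  # run through one fused matrix-vector product
  Sb <- met$S_dn / 2; Db <- met$S_diff / 2     # equal PAR/NIR partition
  opP <- eng$op$PAR[eng$pk_recv, , drop = FALSE]
  opN <- eng$op$NIR[eng$pk_recv, , drop = FALSE]
  aP <- 1 - opP[, 1] - opP[, 2]; aN <- 1 - opN[, 1] - opN[, 2]
  incP <- Sb * inc_dir + Db * skyfrac
  absP <- aP * incP; absN <- aN * incP
  if (cfg$scattering_iterations > 0 && (Sb > 0 || Db > 0)) {
    SP <- (opP[, 1] + opP[, 2]) * incP
    SN <- (opN[, 1] + opN[, 2]) * incP
    s1 <- numeric(eng$scene$n); s2 <- numeric(eng$scene$n)
    for (k in seq_len(cfg$scattering_iterations)) {
      if (all(SP <= 0) && all(SN <= 0)) break
      s1[eng$pk_recv] <- SP / eng$nf_recv
      s2[eng$pk_recv] <- SN / eng$nf_recv
      mv <- cpp_cache_matvec2(eng$cache$ptr, eng$cache$tgt, eng$cache$cnt,
                              s1, s2)
      IinP <- (eng$nf_recv / eng$cache$nrays) * mv$a
      IinN <- (eng$nf_recv / eng$cache$nrays) * mv$b
      absP <- absP + aP * IinP
      absN <- absN + aN * IinN
      SP <- (opP[, 1] + opP[, 2]) * IinP
      SN <- (opN[, 1] + opN[, 2]) * IinN
    }
  }
  abs_band <- list(PAR = absP, NIR = absN)
  # --- longwave + energy balance sweeps ------------------------------------
  opLW <- eng$op$LW
  eps_recv <- opLW[eng$pk_recv, 3]
  T_leaf <- Tprev$leaf; T_ground <- Tprev$ground
  sp <- cfg$stomatal
  svec <- numeric(eng$scene$n)
  svec[eng$pk_wood] <- opLW[eng$pk_wood, 3] * .const$sigma * met$Ta^4
  Q <- par_energy_to_photons(pmax(abs_band$PAR[il], 0))
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    svec[eng$pk_recv[il]] <- eps_recv[il] * .const$sigma * T_leaf^4
    svec[eng$pk_recv[ig]] <- eps_recv[ig] * .const$sigma * T_ground^4
    # rays escaping downward past the modeled ground see unmodeled
    # surroundings at the mean ground exitance (open scenes only; with
    # periodic boundaries the count is ~0)
    L_ground <- mean(eps_recv[ig]) * .const$sigma * mean(T_ground)^4
    I_LW <- (eng$nf_recv / eng$cache$nrays) *
      (cpp_cache_matvec(eng$cache$ptr, eng$cache$tgt, eng$cache$cnt, svec) +
         eng$cache$sky * met$L_dn + eng$cache$down * L_ground)
    R_tot <- abs_band$PAR + abs_band$NIR + eps_recv * I_LW
    D <- vapor_pressure_deficit(T_leaf, met$Ta, met$h, cfg$p_atm)
    gs <- stomatal_conductance(Q, D, sp)
    gM <- couple_gM(gs, eng$gH_leaf)
    sol_l <- solve_surface_temperature(
      R = R_tot[il], eps = eps_recv[il], T_a = met$Ta, h = met$h,
      p_atm = cfg$p_atm, g_H = eng$gH_leaf, g_M = gM, f_s = 1,
      twosided = TRUE)
    sol_g <- solve_surface_temperature(
      R = R_tot[ig], eps = eps_recv[ig], T_a = met$Ta, h = met$h,
      p_atm = cfg$p_atm, g_H = eng$gH_ground, g_M = 0, f_s = 1,
      twosided = FALSE)
    d_max <- max(abs(sol_l$T_s - T_leaf), abs(sol_g$T_s - T_ground))
    T_leaf <- T_leaf + cfg$damping * (sol_l$T_s - T_leaf)
    T_ground <- T_ground + cfg$damping * (sol_g$T_s - T_ground)
    if (d_max < cfg$dT_tol) break
    if (sweeps >= cfg$max_sweeps) {
      worst <- which.max(abs(sol_l$T_s - T_leaf))
      stop(sprintf(
        "coupling sweep did not converge (max |dT| = %.3f K after %d sweeps; worst leaf uuid %d)",
        d_max, sweeps, eng$leaf_uuids[worst]))
    }
  }
  D <- vapor_pressure_deficit(T_leaf, met$Ta, met$h, cfg$p_atm)
  gs <- stomatal_conductance(Q, D, sp)
  gM <- couple_gM(gs, eng$gH_leaf)
  E <- gM * (saturation_vapor_pressure(T_leaf) -
               saturation_vapor_pressure(met$Ta) * met$h) / cfg$p_atm
  ph <- solve_coupled_A_Ci(Q, T_leaf, pmax(gs, 1e-6), cfg$C_a,
                           g_bc = 1.08 * eng$gH_leaf, params = cfg$fvcb)
  list(Q = Q, T_leaf = T_leaf, T_ground = T_ground, gs = gs, E = E,
       A = ph$A, C_i = ph$C_i, abs_PAR = abs_band$PAR[il],
       abs_NIR = abs_band$NIR[il], sweeps = sweeps,
       R_leaf = (abs_band$PAR + abs_band$NIR)[il])
}

#' One coupled radiation / energy-balance / gas-exchange step
#'
#' Runs the fixed-point sweep for a single instant: shortwave tracing,
#' longwave exchange at the current temperatures, stomatal conductance,
#' secant energy-balance solve, damped temperature update until the largest
#' per-leaf change is below tolerance, then the coupled A-Ci solution.
#'
#' @param ctx A `cf_context` holding the scene.
#' @param leaf_uuids,ground_uuids,wood_uuids Primitive roles. Wood surfaces
#'   occlude and emit at air temperature but are not solved.
#' @param met List with `Ta` (K), `h`, `S_dn`, `S_diff`, `L_dn` (W m-2),
#'   `sundir` (unit vector), `up` (sun above horizon).
#' @param config A [simulation_config()].
#' @param seed Master seed.
#' @return Per-leaf state: `Q`, `T_leaf`, `gs`, `E`, `A`, `C_i`, plus ground
#'   temperatures and the sweep count.
#' @export
step_couple <- function(ctx, leaf_uuids, ground_uuids, wood_uuids = integer(0),
                        met, config = simulation_config(), seed = 1) {
  dom <- tryCatch(get_global_data(ctx, "domain"), error = function(e) NULL)
  eng <- .engine_build(ctx, leaf_uuids, ground_uuids, wood_uuids, config,
                       seed, dom)
  .engine_step(eng, met, list(leaf = rep(met$Ta, length(leaf_uuids)),
                              ground = rep(met$Ta, length(ground_uuids))))
}

# simulate all daylight steps; collect = FALSE -> only daily A (precursor)
.simulate_day <- function(eng, wx, cfg, collect = TRUE, traj_uuids = NULL) {
  steps <- which(wx$zenith < pi / 2)
  if (length(steps) < 2) stop("no daylight in the weather series")
  nl <- eng$nl
  dt <- cfg$timestep_min * 60
  acc <- list(Q = numeric(nl), E = numeric(nl), A = numeric(nl),
              PAR = numeric(nl))
  prev <- NULL
  Tprev <- list(leaf = rep(wx$Ta_C[steps[1]] + 273.15, nl),
                ground = rep(wx$Ta_C[steps[1]] + 273.15, eng$ng))
  stats <- if (collect) vector("list", length(steps))
  traj <- if (collect && length(traj_uuids)) {
    ti <- match(traj_uuids, eng$leaf_uuids)
    list(idx = ti, Q = NULL, T_L = NULL, gs = NULL, E = NULL, A = NULL)
  }
  frac_below <- numeric(length(steps))
  for (si in seq_along(steps)) {
    k <- steps[si]
    sp <- solar_position(wx$time[k], cfg$latitude, cfg$longitude,
                         cfg$utc_offset)
    met <- list(Ta = wx$Ta_C[k] + 273.15, h = wx$RH[k], S_dn = wx$S_dn[k],
                S_diff = wx$S_diff[k], L_dn = wx$L_dn[k],
                sundir = sp$sun_direction, up = sp$above_horizon)
    st <- .engine_step(eng, met, Tprev)
    Tprev <- list(leaf = st$T_leaf, ground = st$T_ground)
    cur <- list(Q = st$Q, E = st$E, A = st$A, PAR = st$abs_PAR)
    if (!is.null(prev)) {
      for (v in names(acc)) acc[[v]] <- acc[[v]] + (prev[[v]] + cur[[v]]) / 2 * dt
    }
    prev <- cur
    if (collect) {
      sel <- eng$stat_idx
      stats[[si]] <- data.frame(
        time = wx$time[k], zenith = sp$zenith, Ta = met$Ta,
        Q10 = top_fraction(pmax(st$abs_PAR[sel], 0)),
        E10 = top_fraction(pmax(st$E[sel], 0)),
        A10 = if (any(st$A[sel] > 0)) top_fraction(pmax(st$A[sel], 0)) else NA_real_,
        mean_Q = mean(st$Q[sel]), mean_TL = mean(st$T_leaf[sel]),
        mean_gs = mean(st$gs[sel]), mean_E = mean(st$E[sel]),
        mean_A = mean(st$A[sel]), sweeps = st$sweeps)
      frac_below[si] <- mean(st$T_leaf[sel] < met$Ta)
      if (!is.null(traj)) {
        for (v in c("Q", "gs", "E", "A")) {
          traj[[v]] <- rbind(traj[[v]], st[[v]][traj$idx])
        }
        traj$T_L <- rbind(traj$T_L, st$T_leaf[traj$idx])
      }
    }
  }
  out <- list(daily = acc, times = wx$time[steps],
              frac_below_Ta = frac_below)
  if (collect) {
    out$stats <- do.call(rbind, stats)
    out$traj <- traj
  }
  out
}

#' Run the full diurnal case study
#'
#' Builds the canopy, generates the synthetic clear-sky weather, runs a
#' precursor diurnal simulation, removes the leaves with negative daily net
#' CO2 assimilation, reruns the pruned canopy, and returns per-step
#' population statistics, per-leaf daily integrals, top-decile flux
#' fractions and 10 random leaf trajectories. Bitwise reproducible for a
#' fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed Master seed.
#' @param out_dir Optional directory for CSV outputs (`stats.csv`,
#'   `daily.csv`, `trajectories.csv`).
#' @return A list of class `cf_diurnal` (see Details in the vignette):
#'   `stats` per time step, `daily` per-leaf integrals (mol m-2 day-1 for Q,
#'   E, A), `fractions` (daily and midday top-decile shares), `lai`,
#'   `trajectories`, `config`.
#' @export
run_diurnal <- function(config = simulation_config(), seed = 1,
                        out_dir = NULL) {
  cfg <- config
  lay <- canopy_layout(cfg$nx, cfg$ny, cfg$spacing)
  can <- build_canopy(cfg$tree_params, lay, seed = seed, optics = cfg$optics,
                      ground_margin = cfg$ground_margin)
  ctx <- can$ctx
  atm <- atmosphere_state(p_atm = cfg$p_atm, turbidity = cfg$turbidity,
                          C_a = cfg$C_a)
  wx <- synth_weather(cfg$date, cfg$latitude, cfg$longitude, cfg$utc_offset,
                      cfg$T_min, cfg$T_max, cfg$RH_min, cfg$RH_max,
                      cfg$timestep_min, atm)
  add_timeseries(ctx, wx)
  ground_area <- get_global_data(ctx, "ground_area")

  # statistics population: central tree in the canopy, the tree itself when
  # isolated
  central <- which.min(rowSums(lay$positions^2))

  eng <- .engine_build(ctx, can$leaf_uuids, can$ground_uuids, can$wood_uuids,
                       cfg, seed, can$domain)
  eng$stat_idx <- seq_along(can$leaf_uuids)
  pre <- .simulate_day(eng, wx, cfg, collect = FALSE)
  pruned <- prune_negative_leaves(ctx, pre$daily$A, can$leaf_uuids,
                                  ground_area)
  keep <- match(pruned$kept, can$leaf_uuids)
  leaf_uuids <- pruned$kept
  tree_id <- can$tree_id[keep]

  eng <- .engine_build(ctx, leaf_uuids, can$ground_uuids, can$wood_uuids,
                       cfg, seed, can$domain)
  eng$stat_idx <- which(tree_id == central)
  traj_uuids <- .with_seed(seed + 7,
                           sample(leaf_uuids, min(cfg$n_trajectories,
                                                  length(leaf_uuids))))
  main <- .simulate_day(eng, wx, cfg, collect = TRUE, traj_uuids = traj_uuids)

  sel <- eng$stat_idx
  daily <- data.frame(
    uuid = leaf_uuids,
    tree_id = tree_id,
    Q_daily = main$daily$Q * 1e-6,   # mol photons m-2 d-1
    E_daily = main$daily$E,          # mol H2O m-2 d-1
    A_daily = main$daily$A * 1e-6,   # mol CO2 m-2 d-1
    PAR_daily = main$daily$PAR * 1e-6)  # MJ m-2 d-1
  stats <- main$stats
  noon <- which.min(stats$zenith)
  midday <- which(abs(as.numeric(stats$time - stats$time[noon],
                                 units = "hours")) <= 2)
  fractions <- list(
    Q10_daily = top_fraction(pmax(daily$Q_daily[sel], 0)),
    E10_daily = top_fraction(pmax(daily$E_daily[sel], 0)),
    A10_daily = top_fraction(pmax(daily$A_daily[sel], 0)),
    Q10_noon = stats$Q10[noon],
    E10_noon = stats$E10[noon],
    A10_noon = stats$A10[noon],
    E10_midday_mean = mean(stats$E10[midday], na.rm = TRUE),
    Q10_midday_mean = mean(stats$Q10[midday], na.rm = TRUE),
    A10_midday_mean = mean(stats$A10[midday], na.rm = TRUE))
  out <- structure(list(
    stats = stats, daily = daily, fractions = fractions,
    lai = pruned$lai, lai_initial = can$lai,
    n_pruned = length(pruned$removed),
    frac_below_Ta = main$frac_below_Ta,
    noon_index = noon,
    trajectories = main$traj, traj_uuids = traj_uuids,
    stat_leaf_uuids = leaf_uuids[sel],
    config = cfg, seed = seed), class = "cf_diurnal")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(stats, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    utils::write.csv(daily, file.path(out_dir, "daily.csv"),
                     row.names = FALSE)
    tj <- out$trajectories
    if (!is.null(tj)) {
      tl <- data.frame(time = rep(main$times, times = length(tj$idx)),
                       uuid = rep(traj_uuids, each = length(main$times)),
                       Q = as.vector(tj$Q), T_L = as.vector(tj$T_L),
                       gs = as.vector(tj$gs), E = as.vector(tj$E),
                       A = as.vector(tj$A))
      utils::write.csv(tl, file.path(out_dir, "trajectories.csv"),
                       row.names = FALSE)
    }
  }
  out
}

#' Compare diurnal scenario outputs
#'
#' Checks that the runs share a time grid and assembles the daily and
#' midday top-decile fraction table (one row per scenario) plus the per-step
#' fraction curves for plotting.
#'
#' @param ... Named `cf_diurnal` outputs (e.g. `canopy = , tree = `).
#' @return List with `table` (top-decile fractions by scenario) and `curves`
#'   (long data.frame of per-step Q10/E10/A10).
#' @export
compare_scenarios <- function(...) {
  runs <- list(...)
  if (length(runs) < 2) stop("need at least two outputs to compare")
  t0 <- runs[[1]]$stats$time
  for (r in runs) {
    if (!isTRUE(all.equal(as.numeric(r$stats$time), as.numeric(t0)))) {
      stop("scenario outputs have mismatched time grids")
    }
  }
  tab <- do.call(rbind, lapply(names(runs), function(nm) {
    f <- runs[[nm]]$fractions
    data.frame(scenario = nm, Q10_daily = f$Q10_daily, E10_daily = f$E10_daily,
               A10_daily = f$A10_daily, Q10_noon = f$Q10_noon,
               E10_noon = f$E10_noon, A10_noon = f$A10_noon)
  }))
  curves <- do.call(rbind, lapply(names(runs), function(nm) {
    s <- runs[[nm]]$stats
    data.frame(scenario = nm, time = s$time, Q10 = s$Q10, E10 = s$E10,
               A10 = s$A10)
  }))
  list(table = tab, curves = curves)
}
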