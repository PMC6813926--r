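# Shared scene builders for the test suite. All fixtures are constructed in
# code; nothing is read from disk except the cube mesh in inst/extdata.

# lone black horizontal patch at height z
lone_patch_ctx <- function(z = 1, size = c(1, 1), rotation = c(0, 0),
                           optical = list(PAR = c(0, 0, 1))) {
  ctx <- context_create()
  uuid <- add_patch(ctx, c(0, 0, z), size, rotation, optical)
  list(ctx = ctx, uuid = uuid)
}

# closed isothermal box of one-sided patches facing inward, edge s
enclosure_ctx <- function(s = 2, eps = 1, T = 300) {
  ctx <- context_create()
  op <- list(LW = c(0, 0, eps))
  h <- s / 2
  add_patch(ctx, c(0, 0, 0), c(s, s), c(0, 0), op, twosided = FALSE)
  add_patch(ctx, c(0, 0, s), c(s, s), c(pi, 0), op, twosided = FALSE)
  add_patch(ctx, c(-h, 0, h), c(s, s), c(pi / 2, pi / 2), op, twosided = FALSE)
  add_patch(ctx, c(h, 0, h), c(s, s), c(pi / 2, 3 * pi / 2), op, twosided = FALSE)
  add_patch(ctx, c(0, -h, h), c(s, s), c(pi / 2, 0), op, twosided = FALSE)
  add_patch(ctx, c(0, h, h), c(s, s), c(pi / 2, pi), op, twosided = FALSE)
  set_primitive_data(ctx, context_uuids(ctx), "temperature", T)
  ctx
}

# two horizontal plates (lower faces up, upper faces down) with periodic
# lateral boundaries, emulating infinite parallel plates
parallel_plates_ctx <- function(s = 4, gap = 1, eps = c(1, 1), T = c(320, 280),
                                rho = c(0, 0)) {
  ctx <- context_create()
  low <- add_patch(ctx, c(0, 0, 0), c(s, s), c(0, 0),
                   list(LW = c(rho[1], 0, eps[1]), PAR = c(rho[1], 0, eps[1])),
                   twosided = FALSE)
  up <- add_patch(ctx, c(0, 0, gap), c(s, s), c(pi, 0),
                  list(LW = c(rho[2], 0, eps[2]), PAR = c(rho[2], 0, eps[2])),
                  twosided = FALSE)
  set_primitive_data(ctx, low, "temperature", T[1])
  set_primitive_data(ctx, up, "temperature", T[2])
  list(ctx = ctx, low = low, up = up,
       domain = c(-s / 2, s / 2, -s / 2, s / 2))
}

# brute-force nearest-hit oracle (double precision Moller-Trumbore in R)
brute_ray_nearest <- function(ctx, origin, dir, skip = NA) {
  dir <- dir / sqrt(sum(dir^2))
  best <- -1L; bt <- Inf
  for (u in context_uuids(ctx)) {
    if (!is.na(skip) && u == skip) next
    v <- primitive_vertices(ctx, u)
    tris <- if (ctx$kind[u] == 2L) list(v[c(1, 2, 3), ], v[c(1, 3, 4), ])
            else list(v)
    for (tv in tris) {
      e1 <- tv[2, ] - tv[1, ]; e2 <- tv[3, ] - tv[1, ]
      pv <- c(dir[2] * e2[3] - dir[3] * e2[2], dir[3] * e2[1] - dir[1] * e2[3],
              dir[1] * e2[2] - dir[2] * e2[1])
      det <- sum(e1 * pv)
      if (abs(det) < 1e-14) next
      s <- origin - tv[1, ]
      uu <- sum(s * pv) / det
      if (uu < -1e-9 || uu > 1 + 1e-9) next
      qv <- c(s[2] * e1[3] - s[3] * e1[2], s[3] * e1[1] - s[1] * e1[3],
              s[1] * e1[2] - s[2] * e1[1])
      vv <- sum(dir * qv) / det
      if (vv < -1e-9 || uu + vv > 1 + 1e-9) next
      tt <- sum(e2 * qv) / det
      if (tt > 1e-6 && tt < bt) { bt <- tt; best <- u }
    }
  }
  list(uuid = best, t = bt)
}

# tiny tree configuration for fast coupled-simulation tests
tiny_config <- function(scenario = "isolated_tree", ...) {
  tp <- tree_params_almond(leaves_per_segment = 4)
  tp$levels[[1]]$children <- 3
  tp$levels[[2]]$children <- 3
  tp$levels[[3]]$children <- 4
  simulation_config(scenario, tree_params = tp, timestep_min = 60,
                    rays_direct = 60, rays_diffuse = 120, ground_margin = 3,
                    ...)
}
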