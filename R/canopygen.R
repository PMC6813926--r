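# Procedural tree and canopy generation.

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Spherical (uniform-orientation) leaf inclination distribution
#'
#' Tabulated density of the spherical leaf angle distribution,
#' `f(theta) = sin(theta)` on `[0, 90]` degrees (per-degree density).
#'
#' @param n Number of table points.
#' @return Data.frame with `angle` (degrees) and `density` (per degree).
#' @export
spherical_leaf_pdf <- function(n = 91) {
  a <- seq(0, 90, length.out = n)
  data.frame(angle = a, density = sin(a * pi / 180) * pi / 180)
}

#' Plagiophile (orchard-tree) leaf inclination distribution
#'
#' Tabulated beta-shaped inclination density with mean near 32 degrees,
#' representative of measured almond/orchard canopies whose leaves are
#' predominantly sub-horizontal. Used as the case-study default.
#'
#' @param n Number of table points.
#' @param a,b Beta shape parameters on inclination/90.
#' @return Data.frame with `angle` (degrees) and `density` (per degree).
#' @export
plagiophile_leaf_pdf <- function(n = 91, a = 2.2, b = 4) {
  x <- seq(0, 90, length.out = n)
  d <- stats::dbeta(x / 90, a, b) / 90
  data.frame(angle = x, density = d)
}

#' Sample leaf inclination angles from a tabulated p.d.f.
#'
#' Inverse-CDF sampling of a piecewise-linear density tabulated on
#' `[0, 90]` degrees. The table must integrate to 1 (trapezoidal rule,
#' relative tolerance 1e-3).
#'
#' @param pdf_table Data.frame with columns `angle` (degrees, increasing)
#'   and `density` (per degree, nonnegative).
#' @param n Number of samples.
#' @param seed Seed for the private sampling stream.
#' @return Numeric vector of inclination angles (degrees).
#' @export
sample_leaf_inclination <- function(pdf_table, n, seed = 1) {
  a <- pdf_table$angle; f <- pdf_table$density
  if (any(f < 0)) stop("leaf inclination densities must be nonnegative")
  if (is.unsorted(a, strictly = TRUE)) stop("angles must be strictly increasing")
  w <- diff(a) * (utils::head(f, -1) + utils::tail(f, -1)) / 2
  tot <- sum(w)
  if (abs(tot - 1) > 1e-3) {
    stop(sprintf("leaf inclination p.d.f. integrates to %.4f, not 1", tot))
  }
  cdf <- c(0, cumsum(w)) / tot
  u <- .with_seed(seed, runif(n))
  # invert the piecewise-linear CDF segment by segment
  i <- findInterval(u, cdf, rightmost.closed = TRUE)
  i[i >= length(a)] <- length(a) - 1L
  a0 <- a[i]; a1 <- a[i + 1L]; f0 <- f[i]; f1 <- f[i + 1L]
  p <- (u - cdf[i]) * tot                # probability mass into the segment
  da <- a1 - a0
  slope <- (f1 - f0) / da
  out <- numeric(n)
  lin <- abs(slope) < 1e-12
  out[lin] <- a0[lin] + ifelse(f0[lin] > 0, p[lin] / f0[lin], da[lin] / 2)
  q <- !lin
  disc <- pmax(0, f0[q]^2 + 2 * slope[q] * p[q])
  out[q] <- a0[q] + (sqrt(disc) - f0[q]) / slope[q]
  pmin(pmax(out, 0), 90)
}

#' Branching-architecture parameters of the default almond-like tree
#'
#' Recursive branching levels (child count, branch angle with perturbation,
#' segment length with jitter, radius taper, upward curvature) plus the leaf
#' parameters. Defaults give a roughly 7 m tall orchard tree; any field can
#' be overridden.
#'
#' @param leaves_per_segment Leaves attached to each terminal twig.
#' @param leaf_area One-sided area of every leaf (m^2).
#' @param inclination_pdf Tabulated leaf inclination density
#'   (see [sample_leaf_inclination()]).
#' @return A list of class `cf_tree_params` with elements `trunk`, `levels`
#'   and `leaf`.
#' @export
tree_params_almond <- function(leaves_per_segment = 46, leaf_area = 0.006,
                               inclination_pdf = spherical_leaf_pdf()) {
  structure(list(
    trunk = list(length = 1.6, radius = 0.10),
    levels = list(
      list(children = 5, angle = 14, angle_sd = 6, length = 3.4,
           length_jitter = 0.15, radius_ratio = 0.45, curvature = 0.05),
      list(children = 7, angle = 20, angle_sd = 10, length = 1.1,
           length_jitter = 0.20, radius_ratio = 0.35, curvature = 0),
      list(children = 12, angle = 26, angle_sd = 13, length = 0.8,
           length_jitter = 0.20, radius_ratio = 0.30, curvature = -0.05)
    ),
    leaf = list(per_segment = leaves_per_segment, area = leaf_area,
                inclination_pdf = inclination_pdf, scatter = 0.06)
  ), class = "cf_tree_params")
}

# triangulated tapered tube around an axis segment; returns list(v0,v1,v2).
# Thin twigs become area-equivalent flat ribbons (width pi*r, whose
# azimuth-averaged projected width equals the cylinder diameter); thicker
# members are 6-sided tubes.
.tube_tris <- function(p0, p1, r0, r1, nrad = 6, phi = 0) {
  ax <- p1 - p0
  L <- sqrt(sum(ax^2)); ax <- ax / L
  ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(ax[2] * ref[3] - ax[3] * ref[2], ax[3] * ref[1] - ax[1] * ref[3],
         ax[1] * ref[2] - ax[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(ax[2] * u[3] - ax[3] * u[2], ax[3] * u[1] - ax[1] * u[3],
         ax[1] * u[2] - ax[2] * u[1])
  if (r0 < 0.02) {
    w <- (cos(phi) * u + sin(phi) * v)
    a0 <- p0 - w * (pi * r0 / 2); a1 <- p0 + w * (pi * r0 / 2)
    b0 <- p1 - w * (pi * r1 / 2); b1 <- p1 + w * (pi * r1 / 2)
    return(list(v0 = rbind(a0, a0), v1 = rbind(a1, b1), v2 = rbind(b1, b0)))
  }
  th <- seq(0, 2 * pi, length.out = nrad + 1)[-(nrad + 1)]
  ring <- cbind(cos(th), sin(th)) %*% rbind(u, v)
  b0 <- sweep(ring * r0, 2L, p0, "+")
  b1 <- sweep(ring * r1, 2L, p1, "+")
  nx <- c(2:nrad, 1)
  list(v0 = rbind(b0, b0[nx, , drop = FALSE]),
       v1 = rbind(b1, b1),
       v2 = rbind(b0[nx, , drop = FALSE], b1[nx, , drop = FALSE]))
}

# rotate unit vector `dir` away from itself by `ang` toward azimuthal
# direction `phi` measured in the plane normal to dir
.branch_dir <- function(dir, ang, phi) {
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(dir[2] * ref[3] - dir[3] * ref[2], dir[3] * ref[1] - dir[1] * ref[3],
         dir[1] * ref[2] - dir[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2], dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  w <- cos(phi) * u + sin(phi) * v
  cos(ang) * dir + sin(ang) * w
}

#' Generate one procedural tree
#'
#' Recursive branching: each level spawns `children` branches per parent
#' segment at the configured mean angle with random perturbations of the
#' stated magnitude; terminal segments carry the leaves, whose inclinations
#' are drawn from the supplied tabulated p.d.f. and azimuths uniformly.
#' Deterministic for a fixed seed.
#'
#' @param ctx A `cf_context` to add the primitives to.
#' @param params A [tree_params_almond()]-style parameter list.
#' @param seed Integer seed.
#' @param origin Length-3 base position of the trunk.
#' @param leaf_optical,wood_optical Named per-band optical property lists
#'   passed to the primitive constructors.
#' @return A list with `leaf_uuids`, `wood_uuids`, `leaf_count`,
#'   `leaf_area` (m^2), `height` (m).
#' @export
generate_tree <- function(ctx, params, seed = 1, origin = c(0, 0, 0),
                          leaf_optical = NULL, wood_optical = NULL) {
  if (length(params$levels) < 1) stop("need at least one branching level")
  pdf <- params$leaf$inclination_pdf
  w <- diff(pdf$angle) * (utils::head(pdf$density, -1) + utils::tail(pdf$density, -1)) / 2
  if (abs(sum(w) - 1) > 1e-3) stop("leaf inclination p.d.f. is not normalized")
  res <- .with_seed(seed, {
    segs <- list(list(p0 = origin, p1 = origin + c(0, 0, params$trunk$length),
                      dir = c(0, 0, 1), r = params$trunk$radius))
    all_tris <- list(.tube_tris(segs[[1]]$p0, segs[[1]]$p1,
                                params$trunk$radius, params$trunk$radius * 0.8))
    first <- TRUE
    for (lev in params$levels) {
      nxt <- vector("list", length(segs) * lev$children)
      m <- 0L
      for (s in segs) {
        phi0 <- runif(1, 0, 2 * pi)
        for (ci in seq_len(lev$children)) {
          ang <- (lev$angle + rnorm(1, 0, lev$angle_sd)) * pi / 180
          ang <- min(max(ang, 0.05), pi / 2)
          phi <- phi0 + 2.399963 * (ci - 1) + rnorm(1, 0, 0.3)  # golden angle
          len <- lev$length * (1 + runif(1, -lev$length_jitter, lev$length_jitter))
          # attach point on the parent: scaffolds keep off the lower trunk,
          # higher-order laterals are distributed along the full parent
          frac <- if (first) 0.4 + 0.6 * ci / lev$children
                  else 0.1 + 0.9 * ci / lev$children
          base <- s$p0 + (s$p1 - s$p0) * frac
          d <- .branch_dir(s$dir, ang, phi)
          d <- d + c(0, 0, lev$curvature)           # upward tendency
          d <- d / sqrt(sum(d^2))
          r0 <- s$r * lev$radius_ratio
          m <- m + 1L
          nxt[[m]] <- list(p0 = base, p1 = base + d * len, dir = d, r = r0)
          all_tris[[length(all_tris) + 1L]] <-
            .tube_tris(base, base + d * len, r0, r0 * 0.6,
                       phi = runif(1, 0, 2 * pi))
        }
      }
      segs <- nxt[seq_len(m)]
      first <- FALSE
    }
    # leaves on terminal segments
    nseg <- length(segs)
    npl <- params$leaf$per_segment
    nl <- nseg * npl
    t_along <- rep(seq(0.1, 1, length.out = npl), nseg)
    p0m <- do.call(rbind, lapply(segs, `[[`, "p0"))
    p1m <- do.call(rbind, lapply(segs, `[[`, "p1"))
    i <- rep(seq_len(nseg), each = npl)
    centers <- p0m[i, ] + (p1m[i, ] - p0m[i, ]) * t_along
    sct <- if (is.null(params$leaf$scatter)) 0.06 else params$leaf$scatter
    centers <- centers + matrix(runif(3 * nl, -sct, sct), nl, 3L)
    incl <- sample_leaf_inclination(pdf, nl, seed = floor(runif(1, 1, 2^30)))
    azi <- runif(nl, 0, 2 * pi)
    list(tris = all_tris, centers = centers, incl = incl, azi = azi,
         nl = nl, top = max(p1m[, 3]))
  })
  v0 <- do.call(rbind, lapply(res$tris, `[[`, "v0"))
  v1 <- do.call(rbind, lapply(res$tris, `[[`, "v1"))
  v2 <- do.call(rbind, lapply(res$tris, `[[`, "v2"))
  wood <- add_triangles(ctx, v0, v1, v2, optical = wood_optical,
                        twosided = FALSE)
  side <- sqrt(params$leaf$area)
  leaves <- add_patches(ctx, res$centers, c(side, side),
                        zeniths = res$incl * pi / 180, azimuths = res$azi,
                        optical = leaf_optical, twosided = TRUE)
  list(leaf_uuids = leaves, wood_uuids = wood, leaf_count = res$nl,
       leaf_area = res$nl * params$leaf$area, height = res$top)
}

#' Regular canopy layout
#'
#' @param nx,ny Rows and columns of trees.
#' @param spacing Length-2 (or scalar) tree spacing (m).
#' @return List of class `cf_layout` with positions centered on the origin,
#'   the plant density (trees per m^2) and the domain extent.
#' @export
canopy_layout <- function(nx = 3, ny = 3, spacing = 6) {
  spacing <- rep_len(spacing, 2L)
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing[2]
  g <- expand.grid(x = xs, y = ys)
  ext <- c(nx * spacing[1], ny * spacing[2])
  structure(list(positions = as.matrix(g), spacing = spacing,
                 density = 1 / prod(spacing),
                 extent = ext,
                 domain = c(-ext[1] / 2, ext[1] / 2, -ext[2] / 2, ext[2] / 2)),
            class = "cf_layout")
}

#' Build a canopy of procedurally generated trees over tiled ground
#'
#' Trees share the same architecture parameters and differ only through
#' their per-tree random streams derived from the master seed. The ground is
#' tiled with opaque one-sided patches. Per-primitive data `is_leaf` and
#' `tree_id` are set; the reported LAI is total leaf area over the domain
#' ground area.
#'
#' @param tree_params A [tree_params_almond()]-style list.
#' @param layout A [canopy_layout()].
#' @param seed Master seed.
#' @param optics Named list of per-band optical properties for `leaf`,
#'   `wood` and `ground` surfaces.
#' @param ground_tile Edge length of the ground patches (m).
#' @param ground_margin Extra ground extent beyond the tree domain (m),
#'   useful for isolated-tree scenes.
#' @return List with `ctx`, `leaf_uuids`, `wood_uuids`, `ground_uuids`,
#'   `tree_id` (per leaf), `lai`, `domain`.
#' @export
build_canopy <- function(tree_params, layout = canopy_layout(), seed = 1,
                         optics = default_optics(), ground_tile = 1,
                         ground_margin = 0) {
  ctx <- context_create()
  dom <- layout$domain + c(-1, 1, -1, 1) * ground_margin
  gx <- seq(dom[1] + ground_tile / 2, dom[2] - ground_tile / 2, by = ground_tile)
  gy <- seq(dom[3] + ground_tile / 2, dom[4] - ground_tile / 2, by = ground_tile)
  gg <- expand.grid(x = gx, y = gy)
  ground <- add_patches(ctx, cbind(gg$x, gg$y, 0), c(ground_tile, ground_tile),
                        optical = optics$ground, twosided = FALSE)
  ntree <- nrow(layout$positions)
  leaf_uuids <- integer(0); wood_uuids <- integer(0); tree_id <- integer(0)
  la <- 0
  for (ti in seq_len(ntree)) {
    tr <- generate_tree(ctx, tree_params, seed = seed * 1000L + ti,
                        origin = c(layout$positions[ti, 1],
                                   layout$positions[ti, 2], 0),
                        leaf_optical = optics$leaf, wood_optical = optics$wood)
    leaf_uuids <- c(leaf_uuids, tr$leaf_uuids)
    wood_uuids <- c(wood_uuids, tr$wood_uuids)
    tree_id <- c(tree_id, rep(ti, length(tr$leaf_uuids)))
    la <- la + tr$leaf_area
  }
  set_primitive_data(ctx, leaf_uuids, "is_leaf", 1)
  set_primitive_data(ctx, c(wood_uuids, ground), "is_leaf", 0)
  set_primitive_data(ctx, leaf_uuids, "tree_id", tree_id)
  ground_area <- prod(layout$extent)
  set_global_data(ctx, "domain", layout$domain)
  set_global_data(ctx, "ground_area", ground_area)
  list(ctx = ctx, leaf_uuids = leaf_uuids, wood_uuids = wood_uuids,
       ground_uuids = ground, tree_id = tree_id,
       lai = la / ground_area, domain = layout$domain)
}

#' Default optical property sets for the PAR, NIR and LW bands
#'
#' Leaves: reflectivity = transmissivity = 0.05 (PAR) and 0.4 (NIR),
#' longwave emissivity 0.95. Ground: PAR albedo 0.15, NIR 0.30,
#' emissivity 0.95. Wood intermediate.
#'
#' @return Nested list `surface -> band -> c(rho, tau, eps)`.
#' @export
default_optics <- function() {
  list(
    leaf = list(PAR = c(0.05, 0.05, 0), NIR = c(0.40, 0.40, 0),
                LW = c(0, 0, 0.95)),
    wood = list(PAR = c(0.15, 0, 0), NIR = c(0.35, 0, 0),
                LW = c(0, 0, 0.95)),
    ground = list(PAR = c(0.15, 0, 0), NIR = c(0.30, 0, 0),
                  LW = c(0, 0, 0.95))
  )
}

#' Build a horizontally homogeneous leaf slab (turbid-medium fixture)
#'
#' Leaves with the given orientation distribution are placed uniformly at
#' random in a box above tiled ground; used with periodic lateral boundaries
#' this emulates an infinite homogeneous canopy whose direct-beam
#' transmission has the closed-form exponential solution.
#'
#' @param L Leaf area index of the slab (m^2 m^-2).
#' @param leaf_area Per-leaf one-sided area (m^2).
#' @param depth Slab thickness (m).
#' @param extent Lateral edge length of the (square) domain (m).
#' @param orientation_pdf Leaf inclination p.d.f. table.
#' @param seed Seed.
#' @param optics As in [build_canopy()]; default black leaves in PAR.
#' @param ground_tile Ground patch edge (m).
#' @param z0 Height of the slab base above the ground (m).
#' @return List with `ctx`, `leaf_uuids`, `ground_uuids`, `domain`,
#'   `leaf_count`.
#' @export
build_homogeneous_slab <- function(L, leaf_area = 0.006, depth = 2,
                                   extent = 6,
                                   orientation_pdf = spherical_leaf_pdf(),
                                   seed = 1,
                                   optics = list(leaf = list(PAR = c(0, 0, 1)),
                                                 ground = list(PAR = c(0, 0, 1))),
                                   ground_tile = 0.5, z0 = 0.5) {
  if (L <= 0) stop("leaf area index must be positive")
  ctx <- context_create()
  dom <- c(-extent / 2, extent / 2, -extent / 2, extent / 2)
  gx <- seq(dom[1] + ground_tile / 2, dom[2] - ground_tile / 2, by = ground_tile)
  gg <- expand.grid(x = gx, y = gx)
  ground <- add_patches(ctx, cbind(gg$x, gg$y, 0), c(ground_tile, ground_tile),
                        optical = optics$ground, twosided = FALSE)
  n <- round(L * extent^2 / leaf_area)
  dat <- .with_seed(seed, {
    list(centers = cbind(runif(n, dom[1], dom[2]), runif(n, dom[3], dom[4]),
                         runif(n, z0, z0 + depth)),
         incl = sample_leaf_inclination(orientation_pdf, n,
                                        seed = floor(runif(1, 1, 2^30))),
         azi = runif(n, 0, 2 * pi))
  })
  side <- sqrt(leaf_area)
  leaves <- add_patches(ctx, dat$centers, c(side, side),
                        zeniths = dat$incl * pi / 180, azimuths = dat$azi,
                        optical = optics$leaf, twosided = TRUE)
  set_global_data(ctx, "domain", dom)
  list(ctx = ctx, leaf_uuids = leaves, ground_uuids = ground, domain = dom,
       leaf_count = n)
}
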