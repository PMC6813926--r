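#' Define a radiation waveband
#'
#' @param name Band name, e.g. `"PAR"`, `"NIR"`, `"LW"`.
#' @param collimated_flux Source flux on a surface normal to the beam
#'   (W m-2), e.g. direct-normal solar flux.
#' @param diffuse_flux Diffuse ambient flux on a horizontal surface (W m-2).
#' @param emission Logical; include thermal emission exchange (longwave).
#' @param scattering_iterations Number of reflect/transmit redistribution
#'   passes (0 disables scattering).
#' @return A list of class `cf_band`.
#' @export
radiation_band <- function(name, collimated_flux = 0, diffuse_flux = 0,
                           emission = FALSE, scattering_iterations = 3) {
  if (collimated_flux < 0 || diffuse_flux < 0) stop("source fluxes must be >= 0")
  if (scattering_iterations < 0) stop("scattering_iterations must be >= 0")
  structure(list(name = name, collimated_flux = collimated_flux,
                 diffuse_flux = diffuse_flux, emission = emission,
                 scattering_iterations = as.integer(scattering_iterations)),
            class = "cf_band")
}

# Pack the live planar primitives of a context into a C++ scene.
# periodic: NULL or c(xmin, xmax, ymin, ymax) for laterally wrapped domains.
#' Build the ray-tracing acceleration structure for a context
#'
#' Packs all live planar primitives (triangles and patches) into a uniform
#' spatial grid held in C++. The returned handle is reused by all tracing
#' calls while the geometry is unchanged.
#'
#' @param ctx A `cf_context`.
#' @param periodic Optional `c(xmin, xmax, ymin, ymax)` lateral periodic
#'   domain; rays leaving a side re-enter on the opposite side.
#' @param cell_size Grid cell edge (m); chosen automatically if `NULL`. With
#'   a periodic domain the cell must divide both periods, which is enforced
#'   by adjusting the automatic choice (an explicit incompatible value is an
#'   error).
#' @return A list of class `cf_scene` with the external pointer and the
#'   uuid packing order.
#' @export
scene_build <- function(ctx, periodic = NULL, cell_size = NULL) {
  .ctx_check(ctx)
  uuids <- context_uuids(ctx)
  uuids <- uuids[ctx$kind[uuids] %in% c(1L, 2L)]
  if (length(uuids) == 0L) stop("no planar primitives in context")
  np <- length(uuids)
  kind <- ctx$kind[uuids]
  pverts <- ctx$verts[uuids, 1:12, drop = FALSE]
  ntri_per <- ifelse(kind == 2L, 2L, 1L)
  ntri <- sum(ntri_per)
  tv <- matrix(0, ntri, 9L)
  t2p <- integer(ntri)
  is_tri <- kind == 1L
  rows_tri <- cumsum(ntri_per) - ntri_per + 1L   # first tri row of each prim
  # triangles: as stored
  tv[rows_tri[is_tri], ] <- pverts[is_tri, 1:9, drop = FALSE]
  t2p[rows_tri[is_tri]] <- which(is_tri) - 1L
  # patches: split (v1,v2,v3) + (v1,v3,v4)
  ip <- which(!is_tri)
  if (length(ip)) {
    r1 <- rows_tri[ip]
    tv[r1, 1:3] <- pverts[ip, 1:3]; tv[r1, 4:6] <- pverts[ip, 4:6]
    tv[r1, 7:9] <- pverts[ip, 7:9]
    tv[r1 + 1L, 1:3] <- pverts[ip, 1:3]; tv[r1 + 1L, 4:6] <- pverts[ip, 7:9]
    tv[r1 + 1L, 7:9] <- pverts[ip, 10:12]
    t2p[r1] <- ip - 1L
    t2p[r1 + 1L] <- ip - 1L
  }
  # masks
  mask_nu <- mask_nv <- integer(np)
  mask_off <- integer(np)
  mdat <- integer(0)
  for (k in seq_len(np)) {
    mk <- ctx$masks[[uuids[k]]]
    if (!is.null(mk)) {
      mask_nu[k] <- nrow(mk); mask_nv[k] <- ncol(mk)
      mask_off[k] <- length(mdat)
      mdat <- c(mdat, as.integer(mk))
    }
  }
  per <- !is.null(periodic)
  dom <- if (per) as.numeric(periodic) else numeric(4)
  cs <- if (is.null(cell_size)) -1 else cell_size
  if (per) {
    perx <- dom[2] - dom[1]; pery <- dom[4] - dom[3]
    if (is.null(cell_size)) {
      # median first-edge length of the packed triangles, grid-aligned to the
      # periodic domain
      e1 <- tv[, 4:6] - tv[, 1:3]
      med <- stats::median(sqrt(rowSums(e1^2)))
      cs <- min(max(0.9 * med, 0.02), perx / 4)
      cs <- perx / max(1, round(perx / cs))
    }
    if (abs(pery / cs - round(pery / cs)) > 1e-9) {
      stop("periodic cell size must divide both lateral periods")
    }
  }
  ptr <- cpp_scene_build(tv, t2p, np, kind, pverts,
                         ctx$twosided[uuids], mask_nu, mask_nv, mask_off,
                         if (length(mdat)) mdat else integer(1),
                         per, dom, cs)
  structure(list(ptr = ptr, uuids = uuids, n = np,
                 periodic = if (per) dom else NULL,
                 zrange = range(ctx$verts[uuids, c(3, 6, 9, 12)], na.rm = TRUE)),
            class = "cf_scene")
}

#' Sample the hemispherical exchange operator
#'
#' Launches cosine-weighted rays from every receiving primitive (both faces
#' for two-sided surfaces) and records which primitive, or the sky, each
#' incoming direction sees. The aggregated hit counts act as a sampled
#' radiative exchange operator reused for diffuse sky light, scattered flux
#' redistribution and longwave emission exchange, so the expensive geometry
#' sampling is done once per static scene.
#'
#' @param scene A `cf_scene` from [scene_build()].
#' @param rays Rays per receiving primitive.
#' @param seed Master seed (each primitive derives its own stream).
#' @param receivers Optional subset of uuids to act as receivers (defaults to
#'   all packed primitives).
#' @return A list of class `cf_raycache`.
#' @export
hemisphere_cache <- function(scene, rays = 500, seed = 1, receivers = NULL) {
  stopifnot(inherits(scene, "cf_scene"))
  ridx <- if (is.null(receivers)) seq_len(scene$n) - 1L
          else match(receivers, scene$uuids) - 1L
  if (anyNA(ridx)) stop("receivers must be packed planar primitives of the scene")
  out <- cpp_sample_hemisphere(scene$ptr, as.integer(ridx), as.integer(rays),
                               as.double(seed))
  out$receivers <- scene$uuids[ridx + 1L]
  out$scene <- scene
  class(out) <- "cf_raycache"
  out
}

# Incident flux (per one-sided area) from per-face source exitance vector
# s_face (indexed by packed prim) plus a sky radiance term.
# cache$nrays, cache$sky per receiver; nfaces from the context.
.cache_incident <- function(ctx, cache, s_face, sky_exitance) {
  nf <- ifelse(ctx$twosided[cache$receivers], 2, 1)
  ex <- cpp_cache_matvec(cache$ptr, cache$tgt, cache$cnt, s_face)
  (nf / cache$nrays) * (ex + cache$sky * sky_exitance)
}

.band_optics <- function(ctx, uuids, band) {
  m <- ctx$optical[[band]]
  if (is.null(m)) stop("no optical properties defined for band '", band, "'")
  if (anyNA(m[uuids, ])) {
    bad <- uuids[which(rowSums(is.na(m[uuids, , drop = FALSE])) > 0)]
    stop("primitive(s) lack optical properties for band '", band, "': uuid ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  m[uuids, , drop = FALSE]
}

#' Trace the collimated (direct solar) source
#'
#' Reverse Monte-Carlo estimate of the unoccluded fraction of every
#' receiving primitive for a shared beam direction; the absorbed direct flux
#' per one-sided area is `(1 - rho - tau) * S * |cos(theta_inc)| * fhat`.
#'
#' @param ctx A `cf_context`.
#' @param band A [radiation_band()] (uses `collimated_flux`).
#' @param sun_direction Unit vector pointing toward the source.
#' @param rays_per_primitive Stratified launch points per primitive.
#' @param seed Master seed.
#' @param scene Optional prebuilt [scene_build()] handle.
#' @param receivers Optional uuid subset to trace (defaults to all).
#' @return A list with `uuids`, `fhat`, `incident` and `absorbed` (W m-2 of
#'   one-sided area).
#' @export
trace_direct <- function(ctx, band, sun_direction, rays_per_primitive = 200,
                         seed = 1, scene = NULL, receivers = NULL) {
  if (rays_per_primitive < 1) stop("rays_per_primitive must be >= 1")
  if (sun_direction[3] <= 0) stop("sun must be above the horizon for a direct trace")
  if (is.null(scene)) scene <- scene_build(ctx)
  ridx <- if (is.null(receivers)) seq_len(scene$n) - 1L
          else match(receivers, scene$uuids) - 1L
  uu <- scene$uuids[ridx + 1L]
  op <- .band_optics(ctx, uu, band$name)
  d <- sun_direction / sqrt(sum(sun_direction^2))
  nrep <- 0L
  if (!is.null(scene$periodic)) {
    zen <- acos(min(1, max(-1, d[3])))
    travel <- diff(scene$zrange) * tan(min(zen, 1.48))  # cap near-horizon
    perx <- scene$periodic[2] - scene$periodic[1]
    nrep <- max(1L, min(3L, as.integer(ceiling(travel / perx))))
  }
  fhat <- cpp_trace_collimated(scene$ptr, d, as.integer(ridx),
                               as.integer(rays_per_primitive),
                               as.double(seed), -1, nrep)
  cosi <- drop(ctx$normal[uu, , drop = FALSE] %*% d)
  cosi <- ifelse(ctx$twosided[uu], abs(cosi), pmax(0, cosi))
  incident <- band$collimated_flux * cosi * fhat
  list(uuids = uu, fhat = fhat, incident = incident,
       absorbed = as.numeric((1 - op[, 1] - op[, 2]) * incident))
}

#' Trace the isotropic diffuse (sky) source
#'
#' Cosine-weighted hemisphere sampling per face: the fraction of rays
#' escaping upward to the sky times the diffuse horizontal flux gives the
#' incident diffuse flux on each surface.
#'
#' @inheritParams trace_direct
#' @param rays_per_primitive Hemisphere samples per primitive.
#' @param cache Optional [hemisphere_cache()] to reuse.
#' @return A list with `uuids`, `incident`, `absorbed`.
#' @export
trace_diffuse <- function(ctx, band, rays_per_primitive = 500, seed = 1,
                          scene = NULL, cache = NULL) {
  if (rays_per_primitive < 1) stop("rays_per_primitive must be >= 1")
  if (is.null(cache)) {
    if (is.null(scene)) scene <- scene_build(ctx)
    cache <- hemisphere_cache(scene, rays_per_primitive, seed)
  }
  uu <- cache$receivers
  op <- .band_optics(ctx, uu, band$name)
  nf <- ifelse(ctx$twosided[uu], 2, 1)
  incident <- band$diffuse_flux * nf * cache$sky / cache$nrays
  list(uuids = uu, incident = incident,
       absorbed = as.numeric((1 - op[, 1] - op[, 2]) * incident))
}

#' Trace thermal emission exchange
#'
#' Reverse formulation: each receiving primitive samples its incoming
#' longwave radiance; a ray hitting surface j contributes `eps_j sigma T_j^4`
#' and a ray escaping to the sky contributes the downwelling longwave flux.
#' Absorbed is `eps_i` times the sampled irradiance; emission is
#' `n_faces eps_i sigma T_i^4`. In an isothermal enclosure every sampled ray
#' carries exactly the enclosure radiance, so the net flux is zero for any
#' ray count.
#'
#' @inheritParams trace_diffuse
#' @param L_dn Downwelling sky longwave flux on a horizontal surface (W m-2).
#' @param temperature Optional named numeric vector of surface temperatures
#'   (K) indexed by uuid; defaults to primitive data `"temperature"`.
#' @return List with `uuids`, `incident`, `absorbed`, `emitted`, `net`
#'   (W m-2 one-sided area).
#' @export
trace_emission <- function(ctx, band, rays_per_primitive = 500, seed = 1,
                           L_dn = 0, scene = NULL, cache = NULL,
                           temperature = NULL) {
  if (is.null(cache)) {
    if (is.null(scene)) scene <- scene_build(ctx)
    cache <- hemisphere_cache(scene, rays_per_primitive, seed)
  }
  sc <- cache$scene
  uu <- cache$receivers
  op_all <- .band_optics(ctx, sc$uuids, band$name)
  Tall <- if (is.null(temperature)) {
    get_primitive_data(ctx, sc$uuids, "temperature")
  } else temperature[as.character(sc$uuids)]
  if (anyNA(Tall)) {
    stop("missing temperature for uuid(s): ",
         paste(utils::head(sc$uuids[is.na(Tall)], 5), collapse = ", "))
  }
  s_face <- op_all[, 3] * .const$sigma * Tall^4   # per-face exitance of sources
  incident <- .cache_incident(ctx, cache, s_face, L_dn)
  op <- .band_optics(ctx, uu, band$name)
  nf <- ifelse(ctx$twosided[uu], 2, 1)
  Ti <- Tall[match(uu, sc$uuids)]
  emitted <- as.numeric(nf * op[, 3] * .const$sigma * Ti^4)
  absorbed <- as.numeric(op[, 3] * incident)
  list(uuids = uu, incident = incident, absorbed = absorbed,
       emitted = emitted, net = absorbed - emitted)
}

#' Redistribute scattered (reflected + transmitted) flux
#'
#' Iteratively re-emits each primitive's outstanding scattered share
#' `(rho + tau)` of its incident flux through the sampled exchange operator,
#' accumulating the absorbed fraction at every pass. The outstanding
#' unscattered energy decreases geometrically with the iteration count and
#' is reported so the truncation error is measurable.
#'
#' @inheritParams trace_diffuse
#' @param incident Named or positional numeric vector of first-pass incident
#'   flux (W m-2 one-sided) aligned with the cache receivers.
#' @param iterations Number of redistribution passes.
#' @return List with `uuids`, `absorbed` (additional absorbed flux),
#'   `escaped_power` (W), `residual_power` (W, outstanding after the last
#'   pass).
#' @export
scatter_iterate <- function(ctx, band, incident, iterations = 3,
                            rays_per_primitive = 500, seed = 1,
                            scene = NULL, cache = NULL) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (is.null(cache)) {
    if (is.null(scene)) scene <- scene_build(ctx)
    cache <- hemisphere_cache(scene, rays_per_primitive, seed)
  }
  sc <- cache$scene
  if (!identical(cache$receivers, sc$uuids)) {
    stop("scatter_iterate needs a cache sampled for all primitives")
  }
  uu <- sc$uuids
  op <- .band_optics(ctx, uu, band$name)
  area <- ctx$area[uu]
  nf <- ifelse(ctx$twosided[uu], 2, 1)
  srel <- (op[, 1] + op[, 2])          # scattered share of incident
  a <- 1 - srel
  S <- srel * incident                 # outstanding scattered flux, per 1-sided area
  absorbed <- numeric(length(uu))
  escaped <- 0
  k <- 0L
  while (k < iterations && any(S > 0)) {
    k <- k + 1L
    escaped <- escaped + sum(S * area * cache$sky / cache$nrays)
    Iin <- .cache_incident(ctx, cache, S / nf, 0)
    absorbed <- absorbed + a * Iin
    S <- srel * Iin
  }
  list(uuids = uu, absorbed = as.numeric(absorbed), escaped_power = escaped,
       residual_power = sum(S * area))
}

#' Run a full waveband and store per-primitive absorbed flux
#'
#' Sums the direct, diffuse, scattered and (if enabled) thermal emission
#' components for one band and writes the result to primitive data
#' `radiation_flux_<band>`. Deterministic for a fixed seed.
#'
#' @param ctx A `cf_context`.
#' @param band A [radiation_band()].
#' @param sun_direction Unit vector toward the sun (needed when
#'   `collimated_flux > 0`).
#' @param L_dn Sky longwave flux for emission bands.
#' @param rays Named list with `direct`, `diffuse`, `emission` ray counts.
#' @param seed Master seed.
#' @param scene,cache Optional prebuilt acceleration structures.
#' @return Invisibly, a list with `uuids`, `absorbed`, plus the component
#'   results.
#' @export
run_band <- function(ctx, band, sun_direction = c(0, 0, 1), L_dn = 0,
                     rays = list(direct = 200, diffuse = 500, emission = 500),
                     seed = 1, scene = NULL, cache = NULL) {
  if (is.null(scene)) scene <- scene_build(ctx)
  need_hemi <- band$diffuse_flux > 0 || band$emission ||
    band$scattering_iterations > 0
  if (is.null(cache) && need_hemi) {
    cache <- hemisphere_cache(scene, rays$diffuse, seed)
  }
  uu <- scene$uuids
  total <- numeric(length(uu))
  incident_sw <- numeric(length(uu))
  parts <- list()
  if (band$collimated_flux > 0 && sun_direction[3] > 0) {
    dr <- trace_direct(ctx, band, sun_direction, rays$direct, seed, scene)
    total <- total + dr$absorbed
    incident_sw <- incident_sw + dr$incident
    parts$direct <- dr
  }
  if (band$diffuse_flux > 0) {
    df <- trace_diffuse(ctx, band, rays$diffuse, seed, scene, cache)
    total <- total + df$absorbed
    incident_sw <- incident_sw + df$incident
    parts$diffuse <- df
  }
  if (band$scattering_iterations > 0 && any(incident_sw > 0)) {
    scx <- scatter_iterate(ctx, band, incident_sw, band$scattering_iterations,
                           rays$diffuse, seed, scene, cache)
    total <- total + scx$absorbed
    parts$scatter <- scx
  }
  if (band$emission) {
    em <- trace_emission(ctx, band, rays$emission, seed, L_dn, scene, cache)
    total <- total + em$net   # net longwave contribution to the budget
    parts$emission <- em
  }
  total <- as.numeric(total)
  set_primitive_data(ctx, uu, paste0("radiation_flux_", band$name), total)
  invisible(c(list(uuids = uu, absorbed = total), parts))
}
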