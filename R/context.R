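#' Create an empty simulation context
#'
#' The context is the central registry of geometric primitives (triangles,
#' patches, voxels), their per-band optical properties, named per-primitive
#' and global data, and date/time-indexed weather series. It has reference
#' semantics: all `add_*`/`set_*` functions modify it in place.
#'
#' Coordinate system: right-handed Cartesian, z up, x east, y north.
#' Azimuth angles are measured clockwise from north.
#'
#' @return An object of class `cf_context`.
#' @export
#' @examples
#' ctx <- context_create()
#' add_patch(ctx, center = c(0, 0, 1), size = c(1, 1))
#' primitive_area(ctx, 1L)
context_create <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$n     <- 0L
  ctx$cap   <- 0L
  ctx$kind  <- integer()              # 1 triangle, 2 patch, 3 voxel
  ctx$alive <- logical()
  ctx$verts <- matrix(NA_real_, 0L, 24L)  # up to 8 vertices, xyz packed
  ctx$nvert <- integer()
  ctx$normal <- matrix(NA_real_, 0L, 3L)
  ctx$area  <- numeric()
  ctx$solid <- numeric()
  ctx$twosided <- logical()
  ctx$masks <- list()
  ctx$optical <- new.env(parent = emptyenv())   # band -> cap x 3 matrix (rho, tau, eps)
  ctx$pdata <- new.env(parent = emptyenv())     # name -> list(values, set)
  ctx$gdata <- new.env(parent = emptyenv())
  ctx$ts    <- NULL                             # data.frame: time + numeric columns
  class(ctx) <- "cf_context"
  ctx
}

#' @export
print.cf_context <- function(x, ...) {
  cat(sprintf("<cf_context> %d primitives (%d alive), %d band(s), %d data field(s)\n",
              x$n, sum(x$alive[seq_len(x$n)]), length(ls(x$optical)), length(ls(x$pdata))))
  invisible(x)
}

.ctx_check <- function(ctx) {
  if (!inherits(ctx, "cf_context")) stop("not a cf_context")
  invisible(ctx)
}

.ctx_grow <- function(ctx, add) {
  need <- ctx$n + add
  if (need <= ctx$cap) return(invisible(ctx))
  newcap <- max(need, 2L * ctx$cap, 64L)
  pad <- newcap - ctx$cap
  ctx$kind  <- c(ctx$kind, integer(pad))
  ctx$alive <- c(ctx$alive, logical(pad))
  ctx$verts <- rbind(ctx$verts, matrix(NA_real_, pad, 24L))
  ctx$nvert <- c(ctx$nvert, integer(pad))
  ctx$normal <- rbind(ctx$normal, matrix(NA_real_, pad, 3L))
  ctx$area  <- c(ctx$area, numeric(pad))
  ctx$solid <- c(ctx$solid, numeric(pad))
  ctx$twosided <- c(ctx$twosided, logical(pad))
  length(ctx$masks) <- newcap
  for (b in ls(ctx$optical)) {
    ctx$optical[[b]] <- rbind(ctx$optical[[b]], matrix(NA_real_, pad, 3L))
  }
  for (nm in ls(ctx$pdata)) {
    d <- ctx$pdata[[nm]]
    d$values <- c(d$values, rep(d$values[NA_integer_], pad))
    d$set <- c(d$set, logical(pad))
    ctx$pdata[[nm]] <- d
  }
  ctx$cap <- newcap
  invisible(ctx)
}

# Register rows in bulk; returns the new uuids (row indices, never recycled).
.ctx_add_rows <- function(ctx, kind, verts, nvert, normal, area, solid,
                          twosided, optical = NULL, masks = NULL) {
  m <- length(kind)
  .ctx_grow(ctx, m)
  idx <- ctx$n + seq_len(m)
  ctx$kind[idx]  <- kind
  ctx$alive[idx] <- TRUE
  ctx$verts[idx, seq_len(ncol(verts))] <- verts
  ctx$nvert[idx] <- nvert
  ctx$normal[idx, ] <- normal
  ctx$area[idx]  <- area
  ctx$solid[idx] <- solid
  ctx$twosided[idx] <- twosided
  if (!is.null(masks)) ctx$masks[idx] <- masks
  ctx$n <- ctx$n + m
  if (!is.null(optical)) {
    for (b in names(optical)) {
      v <- optical[[b]]
      if (is.null(dim(v))) v <- matrix(v, m, 3L, byrow = TRUE)
      .ctx_set_optical_rows(ctx, idx, b, v)
    }
  }
  idx
}

.ctx_band_matrix <- function(ctx, band) {
  if (is.null(ctx$optical[[band]])) {
    ctx$optical[[band]] <- matrix(NA_real_, ctx$cap, 3L,
                                  dimnames = list(NULL, c("rho", "tau", "eps")))
  }
  ctx$optical[[band]]
}

.ctx_set_optical_rows <- function(ctx, idx, band, v) {
  m <- .ctx_band_matrix(ctx, band)
  m[idx, ] <- v
  ctx$optical[[band]] <- m
  invisible(ctx)
}

.ctx_rows <- function(ctx, uuids, allow_dead = FALSE) {
  uuids <- as.integer(uuids)
  bad <- uuids < 1L | uuids > ctx$n | is.na(uuids)
  if (any(bad)) stop("unknown uuid: ", paste(uuids[bad], collapse = ", "))
  if (!allow_dead && any(!ctx$alive[uuids])) {
    stop("unknown uuid (deleted): ",
         paste(uuids[!ctx$alive[uuids]], collapse = ", "))
  }
  uuids
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

# Local orthonormal frame for a patch whose normal has spherical angles
# (zenith from +z, azimuth clockwise from north = +y).
.patch_frame <- function(zenith, azimuth) {
  n  <- c(sin(zenith) * sin(azimuth), sin(zenith) * cos(azimuth), cos(zenith))
  e1 <- c(cos(azimuth), -sin(azimuth), 0)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(n = n, e1 = e1, e2 = e2)
}

#' Add a rectangular patch primitive
#'
#' @param ctx A `cf_context`.
#' @param center Numeric length-3 center position (m).
#' @param size Numeric length-2 edge lengths (m), along the patch's local x
#'   and y axes.
#' @param rotation Numeric length-2 spherical angles (radians) of the patch
#'   normal: `c(zenith, azimuth)` with zenith measured from vertical and
#'   azimuth clockwise from north. Default is a horizontal, upward-facing
#'   patch.
#' @param optical Named list of per-band optical properties; each element is
#'   `c(rho, tau, eps)` (reflectivity, transmissivity, emissivity).
#' @param mask Optional logical matrix; `FALSE` cells are holes. The stored
#'   area is the full rectangle area times the solid fraction, and rays
#'   passing through masked-out cells do not intersect the patch.
#' @param twosided Logical; whether the surface exchanges radiation on both
#'   faces (leaves) or only on the `+normal` face (ground, walls).
#' @return The integer uuid of the new primitive.
#' @export
add_patch <- function(ctx, center, size, rotation = c(0, 0), optical = NULL,
                      mask = NULL, twosided = TRUE) {
  .ctx_check(ctx)
  if (length(size) != 2L || any(!is.finite(size)) || any(size <= 0)) {
    stop("patch size components must be positive finite numbers")
  }
  if (!is.null(mask)) {
    if (!is.matrix(mask) || !is.logical(mask)) {
      stop("mask must be a logical matrix")
    }
  }
  fr <- .patch_frame(rotation[1], rotation[2])
  h1 <- fr$e1 * size[1] / 2
  h2 <- fr$e2 * size[2] / 2
  v <- rbind(center - h1 - h2, center + h1 - h2, center + h1 + h2, center - h1 + h2)
  solid <- if (is.null(mask)) 1 else mean(mask)
  if (solid <= 0) stop("mask has no solid cells; patch would have zero area")
  verts <- matrix(NA_real_, 1L, 24L)
  verts[1, 1:12] <- as.numeric(t(v))
  .ctx_add_rows(ctx, 2L, verts, 4L, matrix(fr$n, 1L), prod(size) * solid, solid,
                twosided,
                optical = .optical_rows(optical, 1L),
                masks = list(mask))
}

.optical_rows <- function(optical, m) {
  if (is.null(optical)) return(NULL)
  out <- list()
  for (b in names(optical)) {
    v <- optical[[b]]
    if (is.null(dim(v))) {
      if (length(v) != 3L) stop("optical entries must be c(rho, tau, eps)")
      if (v[1] + v[2] > 1 + 1e-12) stop("rho + tau must be <= 1 for band ", b)
      if (v[3] < 0 || v[3] > 1) stop("emissivity must be in [0,1] for band ", b)
      out[[b]] <- matrix(v, m, 3L, byrow = TRUE)
    } else {
      if (any(v[, 1] + v[, 2] > 1 + 1e-12)) stop("rho + tau must be <= 1 for band ", b)
      out[[b]] <- v
    }
  }
  out
}

#' Add many patches at once (vectorized)
#'
#' Bulk equivalent of [add_patch()] used by the canopy generators. All patch
#' geometry arguments are per-row.
#'
#' @param ctx A `cf_context`.
#' @param centers n x 3 matrix of centers.
#' @param sizes n x 2 matrix (or length-2 vector recycled) of edge lengths.
#' @param zeniths,azimuths Normal direction angles (radians), recycled.
#' @param optical Named list: band -> `c(rho, tau, eps)` applied to all rows.
#' @param twosided Logical scalar or vector.
#' @return Integer vector of uuids.
#' @export
add_patches <- function(ctx, centers, sizes, zeniths = 0, azimuths = 0,
                        optical = NULL, twosided = TRUE) {
  .ctx_check(ctx)
  centers <- as.matrix(centers)
  m <- nrow(centers)
  if (is.null(dim(sizes))) sizes <- matrix(sizes, m, 2L, byrow = TRUE)
  if (any(sizes <= 0)) stop("patch size components must be positive")
  zeniths <- rep_len(zeniths, m); azimuths <- rep_len(azimuths, m)
  twosided <- rep_len(twosided, m)
  st <- sin(zeniths); ct <- cos(zeniths); sa <- sin(azimuths); ca <- cos(azimuths)
  n  <- cbind(st * sa, st * ca, ct)
  e1 <- cbind(ca, -sa, 0)
  e2 <- cbind(n[, 2] * e1[, 3] - n[, 3] * e1[, 2],
              n[, 3] * e1[, 1] - n[, 1] * e1[, 3],
              n[, 1] * e1[, 2] - n[, 2] * e1[, 1])
  h1 <- e1 * (sizes[, 1] / 2); h2 <- e2 * (sizes[, 2] / 2)
  verts <- matrix(NA_real_, m, 24L)
  v1 <- centers - h1 - h2; v2 <- centers + h1 - h2
  v3 <- centers + h1 + h2; v4 <- centers - h1 + h2
  verts[, 1:3] <- v1; verts[, 4:6] <- v2; verts[, 7:9] <- v3; verts[, 10:12] <- v4
  .ctx_add_rows(ctx, rep(2L, m), verts, rep(4L, m), n,
                sizes[, 1] * sizes[, 2], rep(1, m), twosided,
                optical = .optical_rows(optical, m))
}

#' Add a triangle primitive
#'
#' @inheritParams add_patch
#' @param v0,v1,v2 Numeric length-3 vertex coordinates (m). The normal follows
#'   the right-hand rule on the winding order `v0 -> v1 -> v2`.
#' @return The integer uuid of the new primitive.
#' @export
add_triangle <- function(ctx, v0, v1, v2, optical = NULL, twosided = TRUE) {
  .ctx_check(ctx)
  e1 <- v1 - v0; e2 <- v2 - v0
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  a2 <- sqrt(sum(cr^2))
  if (a2 <= 1e-14 * max(sum(e1^2), sum(e2^2), 1e-300)) {
    stop("degenerate triangle: vertices are collinear")
  }
  verts <- matrix(NA_real_, 1L, 24L)
  verts[1, 1:9] <- c(v0, v1, v2)
  .ctx_add_rows(ctx, 1L, verts, 3L, matrix(cr / a2, 1L), a2 / 2, 1, twosided,
                optical = .optical_rows(optical, 1L))
}

#' Add many triangles at once (vectorized)
#'
#' @param ctx A `cf_context`.
#' @param v0,v1,v2 n x 3 matrices of vertex coordinates.
#' @inheritParams add_patches
#' @return Integer vector of uuids.
#' @export
add_triangles <- function(ctx, v0, v1, v2, optical = NULL, twosided = TRUE) {
  .ctx_check(ctx)
  m <- nrow(v0)
  e1 <- v1 - v0; e2 <- v2 - v0
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  a2 <- sqrt(rowSums(cr^2))
  if (any(a2 <= 0)) stop("degenerate triangle: vertices are collinear")
  verts <- matrix(NA_real_, m, 24L)
  verts[, 1:3] <- v0; verts[, 4:6] <- v1; verts[, 7:9] <- v2
  .ctx_add_rows(ctx, rep(1L, m), verts, rep(3L, m), cr / a2, a2 / 2,
                rep(1, m), rep_len(twosided, m),
                optical = .optical_rows(optical, m))
}

#' Add an axis-aligned voxel primitive
#'
#' Voxels carry data and can serve as binning volumes; they do not
#' participate in ray tracing.
#'
#' @param ctx A `cf_context`.
#' @param center Numeric length-3 center (m).
#' @param size Numeric length-3 edge lengths (m).
#' @return The integer uuid of the new primitive.
#' @export
add_voxel <- function(ctx, center, size) {
  .ctx_check(ctx)
  if (any(size <= 0)) stop("voxel size components must be positive")
  h <- size / 2
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  v <- sweep(s %*% diag(h), 2L, center, "+")
  verts <- matrix(NA_real_, 1L, 24L)
  verts[1, ] <- as.numeric(t(v))
  area <- 2 * (size[1] * size[2] + size[2] * size[3] + size[1] * size[3])
  .ctx_add_rows(ctx, 3L, verts, 8L, matrix(c(0, 0, 1), 1L), area, 1, FALSE)
}

#' Delete primitives and all their attached data
#'
#' UUIDs are never reused; deletion leaves holes in the uuid sequence.
#'
#' @param ctx A `cf_context`.
#' @param uuids Integer uuids to remove.
#' @export
delete_primitives <- function(ctx, uuids) {
  .ctx_check(ctx)
  idx <- .ctx_rows(ctx, uuids)
  ctx$alive[idx] <- FALSE
  ctx$masks[idx] <- list(NULL)
  for (nm in ls(ctx$pdata)) {
    d <- ctx$pdata[[nm]]
    d$values[idx] <- d$values[NA_integer_]
    d$set[idx] <- FALSE
    ctx$pdata[[nm]] <- d
  }
  invisible(ctx)
}

#' Rigid-body / similarity transform of primitives
#'
#' Applies scale, then rotation (both about each primitive's own centroid),
#' then translation. Areas scale by `scale^2`; normals are re-derived from the
#' transformed vertices.
#'
#' @param ctx A `cf_context`.
#' @param uuids Integer uuids.
#' @param translation Length-3 displacement (m).
#' @param rotation Optional `list(axis = , angle = )`, axis a length-3 vector,
#'   angle in radians (right-hand rule).
#' @param scale Positive scalar.
#' @export
transform_primitive <- function(ctx, uuids, translation = c(0, 0, 0),
                                rotation = NULL, scale = 1) {
  .ctx_check(ctx)
  idx <- .ctx_rows(ctx, uuids)
  if (scale <= 0) stop("scale must be positive")
  R <- diag(3)
  if (!is.null(rotation)) {
    ax <- .unit(rotation$axis); th <- rotation$angle
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3L, 3L)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  for (i in idx) {
    nv <- ctx$nvert[i]
    v <- matrix(ctx$verts[i, seq_len(3L * nv)], nv, 3L, byrow = TRUE)
    p <- colMeans(v)
    v <- sweep(sweep(v, 2L, p) %*% t(R) * scale, 2L, p + translation, "+")
    ctx$verts[i, seq_len(3L * nv)] <- as.numeric(t(v))
    if (ctx$kind[i] == 1L) {
      e1 <- v[2, ] - v[1, ]; e2 <- v[3, ] - v[1, ]
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      ctx$area[i] <- sqrt(sum(cr^2)) / 2
      ctx$normal[i, ] <- cr / sqrt(sum(cr^2))
    } else if (ctx$kind[i] == 2L) {
      e1 <- v[2, ] - v[1, ]; e2 <- v[4, ] - v[1, ]
      cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      full <- sqrt(sum(cr^2))
      ctx$area[i] <- full * ctx$solid[i]
      ctx$normal[i, ] <- cr / full
    } else {
      e <- list(v[2, ] - v[1, ], v[4, ] - v[1, ], v[5, ] - v[1, ])
      a <- sapply(e, function(x) sqrt(sum(x^2)))
      ctx$area[i] <- 2 * (a[1] * a[2] + a[2] * a[3] + a[1] * a[3])
    }
  }
  invisible(ctx)
}

#' @rdname context_accessors
#' @export
primitive_count <- function(ctx) { .ctx_check(ctx); sum(ctx$alive[seq_len(ctx$n)]) }

#' @rdname context_accessors
#' @export
context_uuids <- function(ctx) { .ctx_check(ctx); which(ctx$alive[seq_len(ctx$n)]) }

#' Context geometry accessors
#'
#' @param ctx A `cf_context`.
#' @param uuids Integer uuids.
#' @param uuid A single integer uuid.
#' @name context_accessors
#' @return `primitive_area` and `primitive_solid_fraction` return numeric
#'   vectors; `primitive_normal` an n x 3 matrix; `primitive_vertices` a
#'   matrix of vertex coordinates for one primitive; `primitive_kind` a
#'   character vector; `primitive_count` the number of live primitives;
#'   `context_uuids` all live uuids; `total_area` the summed area.
#' @export
primitive_area <- function(ctx, uuids) { ctx$area[.ctx_rows(ctx, uuids)] }

#' @rdname context_accessors
#' @export
primitive_normal <- function(ctx, uuids) { ctx$normal[.ctx_rows(ctx, uuids), , drop = FALSE] }

#' @rdname context_accessors
#' @export
primitive_solid_fraction <- function(ctx, uuids) { ctx$solid[.ctx_rows(ctx, uuids)] }

#' @rdname context_accessors
#' @export
primitive_kind <- function(ctx, uuids) {
  c("triangle", "patch", "voxel")[ctx$kind[.ctx_rows(ctx, uuids)]]
}

#' @rdname context_accessors
#' @export
primitive_vertices <- function(ctx, uuid) {
  i <- .ctx_rows(ctx, uuid)[1]
  nv <- ctx$nvert[i]
  matrix(ctx$verts[i, seq_len(3L * nv)], nv, 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' @rdname context_accessors
#' @export
primitive_centroid <- function(ctx, uuids) {
  idx <- .ctx_rows(ctx, uuids)
  out <- matrix(0, length(idx), 3L)
  for (k in seq_along(idx)) {
    i <- idx[k]; nv <- ctx$nvert[i]
    out[k, ] <- colMeans(matrix(ctx$verts[i, seq_len(3L * nv)], nv, 3L, byrow = TRUE))
  }
  out
}

#' @rdname context_accessors
#' @export
total_area <- function(ctx) { .ctx_check(ctx); sum(ctx$area[context_uuids(ctx)]) }

#' Set or get per-primitive optical properties for a waveband
#'
#' @param ctx A `cf_context`.
#' @param uuids Integer uuids.
#' @param band Band name (e.g. `"PAR"`, `"NIR"`, `"LW"`).
#' @param rho,tau,eps Reflectivity, transmissivity, emissivity in `[0, 1]`,
#'   with `rho + tau <= 1`. Recycled across `uuids`.
#' @export
set_primitive_optical <- function(ctx, uuids, band, rho = 0, tau = 0, eps = 1) {
  .ctx_check(ctx)
  idx <- .ctx_rows(ctx, uuids)
  m <- length(idx)
  v <- cbind(rep_len(rho, m), rep_len(tau, m), rep_len(eps, m))
  if (any(v < 0) || any(v[, 3] > 1) || any(v[, 1] + v[, 2] > 1 + 1e-12)) {
    stop("optical properties must satisfy rho,tau,eps in [0,1] and rho+tau <= 1")
  }
  .ctx_set_optical_rows(ctx, idx, band, v)
}

#' @rdname set_primitive_optical
#' @export
get_primitive_optical <- function(ctx, uuids, band) {
  .ctx_check(ctx)
  idx <- .ctx_rows(ctx, uuids)
  m <- ctx$optical[[band]]
  if (is.null(m)) stop("no optical properties defined for band '", band, "'")
  out <- m[idx, , drop = FALSE]
  colnames(out) <- c("rho", "tau", "eps")
  out
}

#' Set or get named per-primitive data
#'
#' Values round-trip exactly and keep their storage type. Reading a name that
#' was never set for a given primitive is an error distinct from an unknown
#' uuid.
#'
#' @param ctx A `cf_context`.
#' @param uuids Integer uuids (vectorized).
#' @param name Data field name.
#' @param value Scalar or vector recycled across `uuids`.
#' @export
set_primitive_data <- function(ctx, uuids, name, value) {
  .ctx_check(ctx)
  idx <- .ctx_rows(ctx, uuids)
  d <- ctx$pdata[[name]]
  if (is.null(d)) {
    proto <- value[NA_integer_]
    d <- list(values = rep(proto, ctx$cap), set = logical(ctx$cap))
  } else if (typeof(d$values) != typeof(value)) {
    stop("primitive data '", name, "' already holds type ", typeof(d$values),
         ", refusing to overwrite with type ", typeof(value))
  }
  d$values[idx] <- rep_len(value, length(idx))
  d$set[idx] <- TRUE
  ctx$pdata[[name]] <- d
  invisible(ctx)
}

#' @rdname set_primitive_data
#' @export
get_primitive_data <- function(ctx, uuids, name) {
  .ctx_check(ctx)
  idx <- .ctx_rows(ctx, uuids)
  d <- ctx$pdata[[name]]
  if (is.null(d)) stop("unknown primitive data name: '", name, "'")
  if (any(!d$set[idx])) {
    stop("primitive data '", name, "' not set for uuid(s): ",
         paste(idx[!d$set[idx]], collapse = ", "))
  }
  d$values[idx]
}

#' @rdname set_primitive_data
#' @export
has_primitive_data <- function(ctx, uuids, name) {
  .ctx_check(ctx)
  idx <- .ctx_rows(ctx, uuids)
  d <- ctx$pdata[[name]]
  if (is.null(d)) return(rep(FALSE, length(idx)))
  d$set[idx]
}

#' Set or get global (context-wide) data
#'
#' @param ctx A `cf_context`.
#' @param name Field name.
#' @param value Any R object.
#' @export
set_global_data <- function(ctx, name, value) {
  .ctx_check(ctx)
  ctx$gdata[[name]] <- value
  invisible(ctx)
}

#' @rdname set_global_data
#' @export
get_global_data <- function(ctx, name) {
  .ctx_check(ctx)
  if (!exists(name, envir = ctx$gdata, inherits = FALSE)) {
    stop("unknown global data name: '", name, "'")
  }
  ctx$gdata[[name]]
}

#' Attach a weather time series to the context
#'
#' @param ctx A `cf_context`.
#' @param data A data.frame with a POSIXct `time` column (strictly
#'   increasing) and numeric variable columns.
#' @param time_col Name of the timestamp column.
#' @export
add_timeseries <- function(ctx, data, time_col = "time") {
  .ctx_check(ctx)
  if (!time_col %in% names(data)) stop("no '", time_col, "' column in time series")
  tt <- data[[time_col]]
  if (is.character(tt)) tt <- as.POSIXct(tt, tz = "UTC")
  if (any(diff(as.numeric(tt)) <= 0)) stop("time series must be strictly increasing in time")
  df <- data[setdiff(names(data), time_col)]
  df <- cbind(data.frame(time = tt), df)
  ctx$ts <- df
  invisible(ctx)
}

#' Query a weather variable at an instant (linear interpolation)
#'
#' Queries outside the record span are errors; no extrapolation is performed.
#'
#' @param ctx A `cf_context`.
#' @param name Variable (column) name.
#' @param t POSIXct time(s).
#' @return Numeric value(s).
#' @export
query_timeseries <- function(ctx, name, t) {
  .ctx_check(ctx)
  if (is.null(ctx$ts)) stop("no time series attached to this context")
  if (!name %in% names(ctx$ts)) stop("unknown time-series variable: '", name, "'")
  x <- as.numeric(ctx$ts$time); xo <- as.numeric(t)
  if (any(xo < x[1] - 1e-9 | xo > x[length(x)] + 1e-9)) {
    stop("query time outside the record span (", format(ctx$ts$time[1]), " to ",
         format(ctx$ts$time[length(x)]), "); no extrapolation")
  }
  stats::approx(x, ctx$ts[[name]], xout = xo, rule = 2)$y
}
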