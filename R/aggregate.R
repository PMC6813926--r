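# Voxel binning, leaf-population statistics, daily integration, pruning.

#' Bin planar primitives into a voxel grid
#'
#' Membership is decided by the primitive centroid; a centroid exactly on a
#' cell boundary is assigned to the lower-index cell. Leaf area density is
#' member area over cell volume.
#'
#' @param ctx A `cf_context`.
#' @param origin Length-3 grid origin (m).
#' @param cell Length-3 cell edge lengths (m), all positive.
#' @param dims Length-3 integer cell counts.
#' @param uuids Optional subset of primitives to bin (default: all planar).
#' @return A list of class `cf_voxelgrid` with `members` (list of uuid
#'   vectors per cell, in x-fastest order), `area`, `lad` (m^2 m^-3),
#'   `origin`, `cell`, `dims`.
#' @export
bin_primitives <- function(ctx, origin, cell, dims, uuids = NULL) {
  .ctx_check(ctx)
  if (any(cell <= 0)) stop("voxel cells must have positive volume")
  dims <- as.integer(dims)
  if (is.null(uuids)) {
    uuids <- context_uuids(ctx)
    uuids <- uuids[ctx$kind[uuids] %in% c(1L, 2L)]
  }
  cen <- primitive_centroid(ctx, uuids)
  u <- sweep(cen, 2L, origin) / matrix(cell, nrow(cen), 3L, byrow = TRUE)
  idx <- floor(u)
  # boundary tie rule: integer coordinates belong to the lower cell
  on_b <- u == idx & idx > 0
  idx[on_b] <- idx[on_b] - 1
  inside <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
    idx[, 2] >= 0 & idx[, 2] < dims[2] &
    idx[, 3] >= 0 & idx[, 3] < dims[3]
  lin <- (idx[, 3] * dims[2] + idx[, 2]) * dims[1] + idx[, 1] + 1
  ncell <- prod(dims)
  members <- vector("list", ncell)
  sp <- split(uuids[inside], lin[inside])
  members[as.integer(names(sp))] <- sp
  area <- numeric(ncell)
  ar <- vapply(split(ctx$area[uuids[inside]], lin[inside]), sum, 0)
  area[as.integer(names(ar))] <- ar
  structure(list(members = members, area = area,
                 lad = area / prod(cell), origin = origin, cell = cell,
                 dims = dims),
            class = "cf_voxelgrid")
}

#' Top-decile (or top-q) flux fraction of a leaf population
#'
#' Share of the total (area-weighted) flux carried by the leaves above the
#' q-th area-weighted quantile: with `q = 0.9`, the fraction of the whole-
#' canopy flux contributed by the top 10% of leaves. The boundary leaf is
#' included fractionally so the top group holds exactly `1 - q` of the total
#' leaf area; with equal leaf areas this is the top 10% by count.
#'
#' @param values Per-leaf nonnegative flux values.
#' @param weights Leaf areas (default equal).
#' @param q Quantile (default 0.9 for the top decile).
#' @return The flux fraction in `[0, 1]`.
#' @export
#' @examples
#' top_fraction(rep(1, 10))           # uniform population: 0.1
top_fraction <- function(values, weights = NULL, q = 0.9) {
  if (length(values) == 0) stop("empty population")
  if (any(values < 0)) stop("top_fraction requires nonnegative values")
  if (all(values == 0)) stop("all-zero values: flux fraction undefined")
  if (is.null(weights)) weights <- rep(1, length(values))
  o <- order(values, decreasing = TRUE)
  v <- values[o]; w <- weights[o]
  target <- (1 - q) * sum(w)
  cw <- cumsum(w)
  k <- which(cw >= target)[1]
  full <- if (k > 1) sum(v[seq_len(k - 1)] * w[seq_len(k - 1)]) else 0
  partial <- v[k] * (target - if (k > 1) cw[k - 1] else 0)
  (full + partial) / sum(v * w)
}

#' Empirical probability density of a leaf population
#'
#' Density-normalized histogram (integrates to 1). Bin selection follows the
#' Freedman-Diaconis rule unless a bin count is given.
#'
#' @param values Per-leaf values (at least 2 distinct).
#' @param bins `"FD"` or an integer bin count.
#' @return A list of class `cf_pdf` with `mids`, `breaks`, `density`,
#'   `counts`.
#' @export
population_pdf <- function(values, bins = "FD") {
  if (length(unique(values)) < 2) {
    h <- list(mids = mean(values), breaks = range(values) + c(-0.5, 0.5),
              density = 1, counts = length(values))
    return(structure(h, class = "cf_pdf"))
  }
  br <- if (identical(bins, "FD")) "FD" else as.integer(bins)
  h <- graphics::hist(values, breaks = br, plot = FALSE)
  structure(list(mids = h$mids, breaks = h$breaks, density = h$density,
                 counts = h$counts), class = "cf_pdf")
}

#' Integrate per-leaf flux trajectories over daylight hours
#'
#' Trapezoidal integration of each leaf's time series restricted to the
#' daylight steps (exact for piecewise-linear trajectories). Units are flux
#' times seconds.
#'
#' @param trajectories Matrix, time steps in rows, leaves in columns.
#' @param times POSIXct or numeric (seconds) time stamps, uniform step.
#' @param daylight Logical mask per time step (default all TRUE).
#' @return Numeric vector of per-leaf integrals.
#' @export
daily_integrate <- function(trajectories, times, daylight = NULL) {
  trajectories <- as.matrix(trajectories)
  n <- nrow(trajectories)
  if (length(times) != n) stop("mismatched trajectory and time lengths")
  if (is.null(daylight)) daylight <- rep(TRUE, n)
  if (length(daylight) != n) stop("mismatched daylight mask length")
  tt <- as.numeric(times)
  keep <- which(daylight)
  if (length(keep) < 2) return(numeric(ncol(trajectories)))
  tt <- tt[keep]; y <- trajectories[keep, , drop = FALSE]
  dt <- diff(tt)
  colSums((y[-1, , drop = FALSE] + y[-length(tt), , drop = FALSE]) / 2 * dt)
}

#' Remove leaves whose daily net CO2 assimilation is negative
#'
#' Canopy-refinement rule: leaves whose daily respiration exceeds daily
#' assimilation are deleted from the context, and the leaf area index is
#' recomputed over the domain ground area. Applying the rule twice removes
#' nothing the second time.
#'
#' @param ctx A `cf_context`.
#' @param daily_A Numeric vector of per-leaf daily net assimilation, named
#'   by uuid or aligned with `leaf_uuids`.
#' @param leaf_uuids Integer uuids of the leaf population.
#' @param ground_area Domain ground area (m^2) for the LAI.
#' @return List with `removed` (uuids), `kept` (uuids), `lai`.
#' @export
prune_negative_leaves <- function(ctx, daily_A, leaf_uuids, ground_area) {
  if (length(daily_A) != length(leaf_uuids)) {
    stop("daily_A must cover every leaf primitive (uuid mismatch)")
  }
  bad <- leaf_uuids[daily_A < 0]
  if (length(bad)) delete_primitives(ctx, bad)
  kept <- setdiff(leaf_uuids, bad)
  list(removed = bad, kept = kept,
       lai = sum(ctx$area[kept]) / ground_area)
}
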