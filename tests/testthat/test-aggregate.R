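test_that("voxel binning assigns by centroid with the lower-cell tie rule", {
  ctx <- context_create()
  u1 <- add_patch(ctx, c(0.5, 0.5, 0.5), c(1, 1))   # inside cell (1,1,1)
  vg <- bin_primitives(ctx, c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_equal(vg$lad[1], 1.0)
  expect_equal(vg$members[[1]], u1)
  expect_equal(sum(vg$area), total_area(ctx))
  # centroid exactly on the x = 1 boundary goes to the lower-index cell
  ctx2 <- context_create()
  u2 <- add_patch(ctx2, c(1, 0.5, 0.5), c(0.5, 0.5))
  vg2 <- bin_primitives(ctx2, c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_equal(vg2$members[[1]], u2)
  expect_error(bin_primitives(ctx2, c(0, 0, 0), c(0, 1, 1), c(2, 2, 2)),
               "positive volume")
})

test_that("slab binning recovers the construction LAI and conserves area", {
  sl <- build_homogeneous_slab(2, extent = 6, depth = 2, seed = 3, z0 = 0.5)
  vg <- bin_primitives(sl$ctx, c(-3, -3, 0.25), c(6, 6, 2.5), c(1, 1, 1),
                       uuids = sl$leaf_uuids)
  expect_equal(sum(vg$area), sum(primitive_area(sl$ctx, sl$leaf_uuids)))
  expect_equal(sum(vg$area) / 36, 2, tolerance = 0.01)  # column LAI
})

test_that("top-decile fraction has exact degenerate and closed-form limits", {
  expect_equal(top_fraction(rep(3.7, 10)), 0.10)
  one_hot <- c(rep(0, 9), 5)
  expect_equal(top_fraction(one_hot), 1.0)
  # scale invariance
  set.seed(8)
  v <- rexp(500)
  expect_equal(top_fraction(v), top_fraction(17.3 * v), tolerance = 1e-12)
  # exponential population: X_0.9 -> 0.1 * (1 + ln 10)
  set.seed(9)
  v2 <- rexp(20000)
  expect_equal(top_fraction(v2), 0.1 * (1 + log(10)), tolerance = 0.03)
  # heavier-tailed lognormal populations concentrate more flux at the top
  set.seed(10)
  z <- rnorm(20000)
  xq <- vapply(c(0.5, 1, 1.5, 2), function(s) top_fraction(exp(s * z)), 0)
  expect_true(all(diff(xq) > 0))
  expect_error(top_fraction(numeric(0)), "empty")
  expect_error(top_fraction(c(-1, 2)), "nonnegative")
  expect_error(top_fraction(c(0, 0)), "all-zero")
  # area weighting: a big leaf counts by its area share
  expect_equal(top_fraction(c(1, 1), weights = c(9, 1), q = 0.9),
               0.1, tolerance = 1e-12)
})

test_that("population densities integrate to one", {
  set.seed(11)
  v <- rnorm(5000)
  p <- population_pdf(v)
  expect_equal(sum(p$density * diff(p$breaks)), 1, tolerance = 1e-12)
  # exponential samples: log-density slope approximates -1/mean
  e <- rexp(50000, rate = 2)
  pe <- population_pdf(e, bins = 40)
  keep <- pe$density > 0 & pe$mids < quantile(e, 0.95)
  fit <- lm(log(pe$density[keep]) ~ pe$mids[keep])
  expect_equal(unname(coef(fit)[2]), -2, tolerance = 0.1)
  pc <- population_pdf(rep(1, 10))
  expect_equal(sum(pc$counts > 0), 1)
})

test_that("daylight integration is exact for piecewise-linear trajectories", {
  tt <- seq(0, 3600 * 10, by = 900)
  n <- length(tt)
  # constant flux over the full span
  const <- matrix(2, n, 1)
  expect_equal(daily_integrate(const, tt)[1], 2 * 3600 * 10)
  # triangular profile: closed-form area
  tri <- matrix(pmax(0, 1 - abs(tt - 18000) / 18000), n, 1)
  expect_equal(daily_integrate(tri, tt)[1], 18000, tolerance = 1e-12)
  # masked (night) steps contribute nothing
  mask <- tt >= 3600 & tt <= 3600 * 9
  expect_equal(daily_integrate(const, tt, mask)[1], 2 * 8 * 3600)
  expect_error(daily_integrate(const, tt[-1]), "mismatched")
})

test_that("negative-assimilation pruning removes the right leaves once", {
  ctx <- context_create()
  uu <- add_patches(ctx, cbind(0, 0, 1:3), c(0.1, 0.1))
  res <- prune_negative_leaves(ctx, c(-1, 0.5, 2), uu, ground_area = 1)
  expect_equal(res$removed, uu[1])
  expect_equal(res$lai, 2 * 0.01)
  # idempotent: a second application removes nothing
  res2 <- prune_negative_leaves(ctx, c(0.5, 2), res$kept, ground_area = 1)
  expect_length(res2$removed, 0)
  expect_equal(res2$lai, res$lai)
  # all positive: nothing removed; all negative: empty canopy
  ctx2 <- context_create()
  uu2 <- add_patches(ctx2, cbind(0, 0, 1:3), c(0.1, 0.1))
  expect_length(prune_negative_leaves(ctx2, c(1, 2, 3), uu2, 1)$removed, 0)
  res3 <- prune_negative_leaves(ctx2, c(-1, -2, -3), uu2, 1)
  expect_equal(res3$lai, 0)
  expect_error(prune_negative_leaves(ctx2, c(1, 2), uu2, 1), "uuid mismatch")
})
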