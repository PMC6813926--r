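test_that("leaf inclination sampling recovers the tabulated distribution", {
  # uniform density on [0, 90]: mean angle -> 45 degrees
  unif <- data.frame(angle = c(0, 90), density = c(1 / 90, 1 / 90))
  s <- sample_leaf_inclination(unif, 20000, seed = 4)
  expect_equal(mean(s), 45, tolerance = 3 * 26 / sqrt(20000) / 45)
  # spherical density: mean -> 1 radian = 57.3 degrees
  s2 <- sample_leaf_inclination(spherical_leaf_pdf(), 20000, seed = 5)
  expect_equal(mean(s2), 180 / pi, tolerance = 0.01)
  # Kolmogorov-Smirnov distance to the target CDF below 0.02 at n = 1e4
  cdf_sph <- function(a) 1 - cos(a * pi / 180)
  ks <- suppressWarnings(ks.test(s2[1:10000], cdf_sph))
  expect_lt(unname(ks$statistic), 0.02)
  # delta-like density stays in its bin
  delta <- data.frame(angle = c(0, 29, 30, 31, 90),
                      density = c(0, 0, 1 / 1, 0, 0))
  sd3 <- sample_leaf_inclination(delta, 500, seed = 6)
  expect_true(all(sd3 >= 29 & sd3 <= 31))
  expect_error(sample_leaf_inclination(
    data.frame(angle = c(0, 90), density = c(-1, 1)), 10), "nonnegative")
  expect_error(sample_leaf_inclination(
    data.frame(angle = c(0, 90), density = c(1, 1)), 10), "integrates")
})

test_that("tree generation is deterministic and respects leaf parameters", {
  ctx1 <- context_create(); ctx2 <- context_create()
  tp <- tree_params_almond(leaves_per_segment = 3, leaf_area = 0.006)
  tp$levels[[1]]$children <- 2; tp$levels[[2]]$children <- 2
  tp$levels[[3]]$children <- 3
  t1 <- generate_tree(ctx1, tp, seed = 11)
  t2 <- generate_tree(ctx2, tp, seed = 11)
  expect_identical(ctx1$verts[seq_len(ctx1$n), ], ctx2$verts[seq_len(ctx2$n), ])
  t3 <- generate_tree(ctx2, tp, seed = 12)
  expect_false(identical(primitive_vertices(ctx1, t1$leaf_uuids[1]),
                         primitive_vertices(ctx2, t3$leaf_uuids[1])))
  # every leaf is a 60 cm^2 patch; totals are exact
  expect_equal(t1$leaf_count, 2 * 2 * 3 * 3)
  areas <- primitive_area(ctx1, t1$leaf_uuids)
  expect_true(all(abs(areas - 0.006) < 1e-12))
  expect_equal(t1$leaf_area, t1$leaf_count * 0.006)
  expect_error(generate_tree(ctx1, list(levels = list())), "at least one")
})

test_that("generated leaf inclinations match the requested p.d.f.", {
  ctx <- context_create()
  tp <- tree_params_almond(leaves_per_segment = 30)
  t1 <- generate_tree(ctx, tp, seed = 2)
  nrm <- primitive_normal(ctx, t1$leaf_uuids)
  incl <- acos(pmin(1, abs(nrm[, 3]))) * 180 / pi
  cdf_sph <- function(a) 1 - cos(a * pi / 180)
  ks <- suppressWarnings(ks.test(incl, cdf_sph))
  expect_lt(unname(ks$statistic), 0.02)
  # spherical orientations: G-function (mean projection) ~ 0.5 for any view
  for (d in list(c(0, 0, 1), c(1, 0, 0), c(0.5, 0.5, sqrt(0.5)))) {
    G <- mean(abs(nrm %*% d))
    expect_equal(G, 0.5, tolerance = 0.02)
  }
})

test_that("canopy layout and construction give the stated density and LAI", {
  lay <- canopy_layout(3, 3, 6)
  expect_equal(lay$density, 1 / 36)
  expect_equal(nrow(lay$positions), 9)
  expect_equal(lay$domain, c(-9, 9, -9, 9))
  tp <- tree_params_almond(leaves_per_segment = 2)
  tp$levels[[1]]$children <- 2; tp$levels[[2]]$children <- 2
  tp$levels[[3]]$children <- 2
  can <- build_canopy(tp, canopy_layout(2, 2, 6), seed = 9)
  expect_equal(length(can$leaf_uuids), 4 * 2^3 * 2)
  expect_equal(can$lai, sum(primitive_area(can$ctx, can$leaf_uuids)) / 144)
  # same master seed: bitwise identical canopy
  can2 <- build_canopy(tp, canopy_layout(2, 2, 6), seed = 9)
  expect_identical(can$ctx$verts[seq_len(can$ctx$n), ],
                   can2$ctx$verts[seq_len(can2$ctx$n), ])
})

test_that("homogeneous slab fixture has the right counts and first-order optics", {
  sl <- build_homogeneous_slab(2, leaf_area = 0.006, extent = 10, seed = 1)
  expect_equal(sl$leaf_count, round(2 * 100 / 0.006))
  # thin slab: direct transmission ~ 1 - G L at normal incidence
  sl2 <- build_homogeneous_slab(0.05, extent = 4, seed = 2)
  sc <- scene_build(sl2$ctx, periodic = sl2$domain)
  b <- radiation_band("PAR", collimated_flux = 1000)
  dr <- trace_direct(sl2$ctx, b, c(0, 0, 1), 10000, 3, scene = sc,
                     receivers = sl2$ground_uuids)
  expect_equal(mean(dr$fhat), 1 - 0.5 * 0.05, tolerance = 0.004)
  expect_error(build_homogeneous_slab(-1), "positive")
})
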