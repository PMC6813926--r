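test_that("patch construction handles size, masks and solid fractions", {
  ctx <- context_create()
  u1 <- add_patch(ctx, c(0, 0, 1), c(1, 1))
  expect_equal(primitive_area(ctx, u1), 1.0)
  expect_equal(primitive_solid_fraction(ctx, u1), 1.0)

  mask <- matrix(rep(c(TRUE, FALSE), 8), 4, 4)   # half solid
  u2 <- add_patch(ctx, c(0, 0, 2), c(1, 1), mask = mask)
  expect_equal(primitive_area(ctx, u2), 0.5)

  mask3 <- matrix(TRUE, 4, 4); mask3[1, 1:4] <- FALSE  # 12/16 solid
  u3 <- add_patch(ctx, c(0, 0, 3), c(2, 3), mask = mask3)
  expect_equal(primitive_area(ctx, u3), 6 * 0.75)

  expect_error(add_patch(ctx, c(0, 0, 0), c(-1, 1)), "positive")
  expect_error(add_patch(ctx, c(0, 0, 0), c(1, 1),
                         mask = matrix(FALSE, 2, 2)), "zero area")
})

test_that("triangle construction computes area and winding-order normal", {
  ctx <- context_create()
  u <- add_triangle(ctx, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(primitive_area(ctx, u), 0.5)
  expect_equal(drop(primitive_normal(ctx, u)), c(0, 0, 1))
  u2 <- add_triangle(ctx, c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  expect_equal(primitive_area(ctx, u2), 2.0)
  # reversed winding flips the normal
  u3 <- add_triangle(ctx, c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))
  expect_equal(drop(primitive_normal(ctx, u3)), c(0, 0, -1))
  expect_error(add_triangle(ctx, c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
})

test_that("transforms scale areas correctly and preserve them when rigid", {
  ctx <- context_create()
  u <- add_triangle(ctx, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  v_before <- primitive_vertices(ctx, u)
  transform_primitive(ctx, u)                    # identity
  expect_identical(primitive_vertices(ctx, u), v_before)

  transform_primitive(ctx, u, scale = 2)
  expect_equal(primitive_area(ctx, u), 2.0)

  p <- add_patch(ctx, c(1, 2, 3), c(1, 2))
  n0 <- drop(primitive_normal(ctx, p))
  transform_primitive(ctx, p, rotation = list(axis = c(0, 0, 1), angle = pi / 2))
  expect_equal(primitive_area(ctx, p), 2.0)
  expect_equal(drop(primitive_normal(ctx, p)), n0, tolerance = 1e-12)

  # rigid motion leaves the summed area invariant to 1e-9 relative
  tot0 <- total_area(ctx)
  transform_primitive(ctx, context_uuids(ctx), translation = c(3, -2, 5),
                      rotation = list(axis = c(1, 2, 3), angle = 0.7))
  expect_equal(total_area(ctx), tot0, tolerance = 1e-9)
})

test_that("uuids are never reused and deletion removes attached data", {
  ctx <- context_create()
  u1 <- add_patch(ctx, c(0, 0, 0), c(1, 1))
  u2 <- add_patch(ctx, c(0, 0, 1), c(1, 1))
  set_primitive_data(ctx, c(u1, u2), "temperature", c(300, 301))
  delete_primitives(ctx, u1)
  u3 <- add_patch(ctx, c(0, 0, 2), c(1, 1))
  expect_true(u3 > u2)                     # the hole is never refilled
  expect_false(u3 == u1)
  expect_error(get_primitive_data(ctx, u1, "temperature"), "uuid")
  expect_equal(get_primitive_data(ctx, u2, "temperature"), 301)
})

test_that("primitive data round-trips, is typed, and errors are specific", {
  ctx <- context_create()
  uu <- add_patches(ctx, matrix(c(0, 0, 0, 0, 0, 1, 0, 0, 2), 3, byrow = TRUE),
                    c(1, 1))
  set_primitive_data(ctx, uu[1], "temperature", 300.0)
  expect_identical(get_primitive_data(ctx, uu[1], "temperature"), 300.0)
  set_primitive_data(ctx, uu, "gs", 0.1)
  expect_equal(get_primitive_data(ctx, uu, "gs"), rep(0.1, 3))
  # unknown name vs unknown uuid are distinguishable
  expect_error(get_primitive_data(ctx, uu[1], "nope"), "unknown primitive data name")
  expect_error(get_primitive_data(ctx, 999L, "gs"), "unknown uuid")
  # unset for this uuid
  set_primitive_data(ctx, uu[1], "partial", 1)
  expect_error(get_primitive_data(ctx, uu[2], "partial"), "not set")
  # declared type is sticky
  expect_error(set_primitive_data(ctx, uu[1], "gs", "a string"), "type")
  set_global_data(ctx, "lai", 2.9)
  expect_equal(get_global_data(ctx, "lai"), 2.9)
  expect_error(get_global_data(ctx, "missing"), "unknown global")
})

test_that("time series interpolate linearly and refuse extrapolation", {
  ctx <- context_create()
  t0 <- as.POSIXct("2022-06-21 10:00", tz = "UTC")
  add_timeseries(ctx, data.frame(time = c(t0, t0 + 3600),
                                 Ta_C = c(20, 22)))
  expect_equal(query_timeseries(ctx, "Ta_C", t0 + 1800), 21)
  expect_equal(query_timeseries(ctx, "Ta_C", t0), 20)
  expect_error(query_timeseries(ctx, "Ta_C", t0 - 3600), "span")
  expect_error(query_timeseries(ctx, "RH", t0), "unknown time-series")
  expect_error(add_timeseries(ctx, data.frame(time = c(t0, t0), x = 1:2)),
               "strictly increasing")
})

test_that("mesh files round-trip and the cube fixture has the closed-form area", {
  ctx <- context_create()
  add_triangle(ctx, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  add_triangle(ctx, c(0, 0, 1), c(1, 0, 1), c(0, 1, 1))
  ply <- tempfile(fileext = ".ply")
  write_mesh(ctx, ply)
  ctx2 <- context_create()
  uu <- read_mesh(ctx2, ply)
  expect_length(uu, 2)
  expect_equal(primitive_vertices(ctx2, uu[1]),
               primitive_vertices(ctx, 1L), tolerance = 1e-6,
               ignore_attr = TRUE)

  cube <- system.file("extdata", "cube.obj", package = "canopyflux")
  ctx3 <- context_create()
  tris <- read_mesh(ctx3, cube)
  expect_length(tris, 12)
  expect_equal(total_area(ctx3), 6 * 2^2)

  # PLY <-> OBJ cross-format round trip preserves area to 1e-6 relative
  obj <- tempfile(fileext = ".obj")
  write_mesh(ctx3, obj)
  ctx4 <- context_create()
  read_mesh(ctx4, obj)
  ply2 <- tempfile(fileext = ".ply")
  write_mesh(ctx4, ply2)
  ctx5 <- context_create()
  read_mesh(ctx5, ply2)
  expect_equal(total_area(ctx5), total_area(ctx3), tolerance = 1e-6)

  expect_error(read_mesh(ctx3, "mesh.stl"), "extension")
  bad <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2"), bad)
  expect_error(read_mesh(ctx3, bad), "end_header")
})

test_that("XML configuration round-trips and schema errors are specific", {
  ctx <- context_create()
  add_patch(ctx, c(0, 0, 1), c(1, 2), c(pi / 6, pi / 4),
            optical = list(PAR = c(0.05, 0.05, 0)))
  f <- tempfile(fileext = ".xml")
  write_xml_state(f, ctx, stomatal = stomatal_params(), fvcb = fvcb_params())
  cfg <- read_xml_config(f)
  expect_equal(primitive_count(cfg$ctx), 1)
  expect_equal(primitive_area(cfg$ctx, 1L), 2, tolerance = 1e-9)
  expect_equal(drop(primitive_normal(cfg$ctx, 1L)),
               drop(primitive_normal(ctx, 1L)), tolerance = 1e-9)
  expect_equal(get_primitive_optical(cfg$ctx, 1L, "PAR")[1, ],
               c(rho = 0.05, tau = 0.05, eps = 0))
  # fitted physiology block is readable
  expect_equal(cfg$stomatal$E_m, 20.43)
  expect_equal(cfg$fvcb$V_cmax25, 99.5)
  expect_equal(cfg$fvcb$J_max25, 185.0)

  bad <- tempfile(fileext = ".xml")
  writeLines('<canopyflux><patch size="1 1"/></canopyflux>', bad)
  expect_error(read_xml_config(bad), "missing required attribute 'center'")
})
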