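test_that("an empty scene renders to pure shaded soil", {
  f <- field_config(sowing_density = 100, plot_width = 20, plot_depth = 20,
                    thermal_time = 100, seed = 1)
  sc <- suppressWarnings(build_canopy(f, plant_params()))
  cam <- nadir_camera(gsd = 1, px = 64, look_at = c(10, 10, 0))
  tx <- texture_set("procedural", "procedural", seed = 4)
  fr <- render_scene(sc, cam, flat_light(), tx, aa_factor = 1)
  expect_true(all(fr$owner == 0))
  # fully diffuse light: rgb equals the soil albedo looked up at the pixel's
  # ground point
  ras <- wheattips:::rasterize_pass(matrix(0, 0, 3), matrix(0L, 0, 3),
                                    integer(0), matrix(0, 0, 2), cam)
  alb <- wheattips:::texture_lookup(tx$soil, tx$texture_scale,
                                    as.vector(ras$tu), as.vector(ras$tv))
  expect_equal(as.vector(fr$rgb), as.vector(array(alb, dim(fr$rgb))),
               tolerance = 1e-12)
})

test_that("triangle pixel coverage matches a brute-force scan", {
  cam <- nadir_camera(gsd = 1, px = 48, look_at = c(0, 0, 0))
  # a single triangle on the soil plane, axis-aligned in world space
  V <- rbind(c(-10, -8, 20), c(12, -8, 20), c(-10, 14, 20))
  ras <- wheattips:::rasterize_pass(V, matrix(c(1L, 2L, 3L), 1, 3), 1L,
                                    matrix(0, 3, 2), cam)
  pj <- project_point(V, cam)
  want <- oracle_triangle_coverage(pj$u, pj$v, 48, 48)
  expect_identical(ras$owner == 1L, want)
})

test_that("the z-buffer keeps the nearer of two overlapping triangles", {
  cam <- nadir_camera(gsd = 4, px = 32, look_at = c(0, 0, 0))
  V <- rbind(c(-12, -12, 60), c(12, -12, 60), c(0, 12, 60),    # nearer
             c(-12, -12, 20), c(12, -12, 20), c(0, 12, 20))    # farther
  F_ <- rbind(c(1L, 2L, 3L), c(4L, 5L, 6L))
  ras <- wheattips:::rasterize_pass(V, F_, c(1L, 2L), matrix(0, 6, 2), cam)
  overlap <- ras$owner %in% c(1L, 2L)
  expect_true(any(overlap))
  expect_true(all(ras$owner[overlap] == 1L))
  # depth along the (oblique) view rays: at least the vertical drop, and
  # bounded by it over the cosine of the worst ray angle
  d_min <- cam$height - 60
  got <- ras$depth[ras$owner == 1L]
  expect_true(all(got >= d_min - 1e-9))
  expect_true(all(got <= d_min / cos(cam$horizontal_fov * pi / 360 * sqrt(2))))
})

test_that("rendering is invariant to triangle order after canonicalization", {
  sc <- single_plant_scene(21, 240)
  m <- wheattips:::scene_mesh(sc)
  cam <- nadir_camera(gsd = 1.5, px = 96)
  ord <- wheattips:::canonical_face_order(m$V, m$F, m$owner)
  set.seed(1)
  perm <- sample(nrow(m$F))
  ord2 <- wheattips:::canonical_face_order(m$V, m$F[perm, ], m$owner[perm])
  a <- wheattips:::rasterize_pass(m$V, m$F[ord, ], m$owner[ord], m$UV, cam)
  b <- wheattips:::rasterize_pass(m$V, m$F[perm, ][ord2, ],
                                  m$owner[perm][ord2], m$UV, cam)
  expect_identical(a$depth, b$depth)
  expect_identical(a$owner, b$owner)
})

test_that("fully diffuse light makes shadow casting a no-op, bit for bit", {
  sc <- single_plant_scene(31, 260)
  cam <- nadir_camera(gsd = 1.5, px = 96)
  tx <- texture_set("procedural", "procedural", seed = 9)
  a <- render_scene(sc, cam, light_config(diffuse_fraction = 1,
                                          cast_shadows = TRUE), tx)
  b <- render_scene(sc, cam, light_config(diffuse_fraction = 1,
                                          cast_shadows = FALSE), tx)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$depth, b$depth)
  expect_identical(a$owner, b$owner)
})

test_that("soil ownership coincides with the analytic ray-plane distance", {
  for (s in 1:5) {
    set.seed(s)
    f <- field_config(thermal_time = runif(1, 100, 350), seed = s,
                      plot_width = 200, plot_depth = 200,
                      sowing_density = 150)
    sc <- build_canopy(f, plant_params())
    cam <- camera_for_gsd(1.5, view_zenith = runif(1, 0, 40), fov = 40,
                          sensor_width_px = 64, look_at = c(100, 100, 0))
    fr <- render_scene(sc, cam, flat_light(), texture_set(), aa_factor = 1)
    soil_ras <- wheattips:::rasterize_pass(matrix(0, 0, 3), matrix(0L, 0, 3),
                                           integer(0), matrix(0, 0, 2), cam)
    is_soil <- fr$owner == 0
    matches_analytic <- abs(fr$depth - soil_ras$depth) < 1e-6
    expect_identical(is_soil, matches_analytic & soil_ras$owner == 0)
  }
})

test_that("cast shadows darken sunlit soil behind a panel", {
  # oblique sun: the panel's shadow falls on soil visible beside it
  panel <- panel_leaf(-40, 40, -40, 40, 80)
  sc <- scene_from_leaves(list(panel))
  cam <- nadir_camera(gsd = 2, px = 96)
  li <- light_config(sun_zenith = 45, sun_azimuth = 0,
                     diffuse_fraction = 0.3, cast_shadows = TRUE)
  li_off <- light_config(sun_zenith = 45, sun_azimuth = 0,
                         diffuse_fraction = 0.3, cast_shadows = FALSE)
  a <- render_scene(sc, cam, li, texture_set())
  b <- render_scene(sc, cam, li_off, texture_set())
  expect_true(mean(a$rgb[, , 2][a$owner == 0]) <
                mean(b$rgb[, , 2][b$owner == 0]))
})

test_that("degenerate triangles are skipped with a warning", {
  bad <- panel_leaf(-10, 10, -10, 10, 50)
  bad$vertices[4, ] <- bad$vertices[3, ]  # second face collapses
  sc <- scene_from_leaves(list(bad))
  cam <- nadir_camera(gsd = 2, px = 48)
  expect_warning(render_scene(sc, cam, flat_light(), texture_set()),
                 class = "wheattips_degenerate_triangles")
})

test_that("PNG write/read round-trips through the gamma encoding", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_frame_png(img, path)
  back <- read_image_png(path)
  expect_equal(back, img, tolerance = 0.02)  # 8-bit quantization
})
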