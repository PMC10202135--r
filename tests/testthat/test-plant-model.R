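test_that("Haun stage is thermal time over phyllochron", {
  expect_equal(haun_stage(0, 100), 0)
  expect_equal(haun_stage(250, 100), 2.5)
  expect_equal(haun_stage(400, 100), 4)
  expect_error(haun_stage(100, 0), class = "wheattips_invalid_parameter")
  expect_error(haun_stage(-5, 100), class = "wheattips_invalid_parameter")
})

test_that("parameter containers validate their invariants", {
  expect_error(plant_params(phyllochron = -1),
               class = "wheattips_invalid_parameter")
  expect_error(plant_params(inclination_angle = 120),
               class = "wheattips_invalid_parameter")
  expect_error(plant_params(leaf_length_by_rank = c(10, -5),
                            leaf_max_width_by_rank = c(1, 1)),
               class = "wheattips_invalid_parameter")
  expect_error(field_config(sowing_density = 0),
               class = "wheattips_invalid_parameter")
})

test_that("midrib arc length equals expansion times nominal length", {
  p <- plant_params()
  for (rank in 1:4) {
    for (f in c(0.25, 0.5, 0.8, 1)) {
      leaf <- build_leaf(rank, f, p, azimuth = 37)
      arc <- sum(sqrt(rowSums(diff(leaf$midrib)^2)))
      nominal <- f * p$leaf_length_by_rank[rank]
      expect_lt(abs(arc - nominal) / nominal, 1e-3)
      expect_equal(leaf$tip_point, leaf$midrib[nrow(leaf$midrib), ])
    }
  }
})

test_that("a straight vertical leaf ends directly above its insertion", {
  p <- plant_params(inclination_angle = 0, curvature = 0)
  leaf <- build_leaf(1, 1, p, azimuth = 0, base = c(10, 20, 0))
  L <- p$leaf_length_by_rank[1]
  expect_equal(leaf$tip_point, c(10, 20, L), tolerance = 1e-6)
})

test_that("half-expanded leaf has half arc length and a zero-width tip", {
  p <- plant_params(leaf_length_by_rank = c(100, 120),
                    leaf_max_width_by_rank = c(5, 6))
  leaf <- build_leaf(1, 0.5, p)
  arc <- sum(sqrt(rowSums(diff(leaf$midrib)^2)))
  expect_equal(arc, 50, tolerance = 1e-6)
  # the final mesh vertex is the tip point itself (width collapses to 0)
  expect_equal(leaf$vertices[nrow(leaf$vertices), ], leaf$tip_point)
  expect_error(build_leaf(7, 1, plant_params()),
               class = "wheattips_invalid_rank")
})

test_that("leaf census follows the Haun stage rule", {
  p <- plant_params()
  for (tt in seq(10, 600, by = 37)) {
    set.seed(1)
    pl <- build_plant(tt, p)
    H <- tt / p$phyllochron
    expect_equal(length(pl$leaves), ceiling(H))
  }
  set.seed(2)
  pl <- build_plant(250, p)  # H = 2.5
  exp_frac <- vapply(pl$leaves, function(l) l$expansion_fraction, 0)
  expect_equal(exp_frac, c(1, 1, 0.5))
})

test_that("no tillers before the tillering onset stage", {
  p <- plant_params(tiller_onset_haun = 3.5, tiller_number = 2)
  set.seed(3)
  pl <- build_plant(200, p)  # H = 2 < 3.5
  expect_equal(length(pl$leaves), 2)
  expect_true(all(vapply(pl$leaves, function(l) l$tiller, 0L) == 0L))
  set.seed(3)
  pl2 <- build_plant(400, p)  # H = 4 >= 3.5: tillers present
  expect_true(any(vapply(pl2$leaves, function(l) l$tiller, 0L) > 0L))
})

test_that("canopy assembly respects density, rows, jitter and seed", {
  # 200 plants/m^2 on a 0.5 m x 0.1 m plot -> 10 plants
  f <- field_config(sowing_density = 200, row_spacing = 100,
                    plot_width = 500, plot_depth = 100,
                    position_jitter_sd = 5, thermal_time = 150, seed = 11)
  sc <- build_canopy(f, plant_params())
  expect_length(sc$plants, 10)

  sc2 <- build_canopy(f, plant_params())
  for (i in seq_along(sc$plants))
    expect_identical(sc$plants[[i]]$base_position,
                     sc2$plants[[i]]$base_position)

  f0 <- field_config(sowing_density = 200, row_spacing = 100,
                     plot_width = 500, plot_depth = 100,
                     position_jitter_sd = 0, thermal_time = 150, seed = 11)
  sc0 <- build_canopy(f0, plant_params())
  xs <- sort(vapply(sc0$plants, function(p) p$base_position[1], 0))
  expect_equal(xs, (seq_len(10) - 0.5) * 50, tolerance = 1e-9)
  expect_true(all(vapply(sc0$plants, function(p) p$base_position[2], 0) == 50))

  tiny <- field_config(sowing_density = 100, plot_width = 20, plot_depth = 20,
                       thermal_time = 100, seed = 1)
  expect_warning(empty <- build_canopy(tiny, plant_params()),
                 class = "wheattips_empty_scene")
  expect_length(empty$plants, 0)
})

test_that("scenes are reproducible bit-for-bit under a fixed seed", {
  f <- field_config(thermal_time = 230, seed = 99)
  a <- build_canopy(f, plant_params())
  b <- build_canopy(f, plant_params())
  expect_identical(a, b)
})

test_that("OBJ export writes the full triangle census", {
  sc <- single_plant_scene(5, 180)
  path <- withr::local_tempfile(fileext = ".obj")
  write_scene_obj(sc, path)
  lines <- readLines(path)
  n_faces <- sum(vapply(sc$plants[[1]]$leaves,
                        function(l) nrow(l$faces), 0L))
  expect_equal(sum(grepl("^f ", lines)), n_faces + 2)  # + 2 soil triangles
})
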