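test_that("the all-defaults condition is at zero distance from itself", {
  tab <- run_realism_ablation(n_images = 3, combos = list(character(0)),
                              seed = 2)
  expect_equal(tab$condition, "none")
  expect_equal(tab$distance, 0, tolerance = 1e-9)
})

test_that("lighting variation leaves the tip geometry untouched", {
  scenes <- wheattips:::make_scenes(3, seed = 6)
  cam <- camera_for_gsd(0.8, view_zenith = 45, fov = 40,
                        sensor_width_px = 192, look_at = c(150, 150, 0))
  base <- wheattips:::render_condition(scenes, cam, lt = FALSE, sb = FALSE,
                                       lc = FALSE, seed = 10)
  lit <- wheattips:::render_condition(scenes, cam, lt = FALSE, sb = FALSE,
                                      lc = TRUE, seed = 10)
  for (i in 1:3) {
    expect_equal(base$annotations[[i]]$center_u, lit$annotations[[i]]$center_u)
    expect_equal(nrow(base$annotations[[i]]), nrow(lit$annotations[[i]]))
  }
  # but the imagery itself differs
  expect_false(identical(base$frames[[1]]$rgb, lit$frames[[1]]$rgb))
})

test_that("the full 7-row factor ladder completes with unique labels", {
  tab <- run_realism_ablation(n_images = 4, seed = 3)
  expect_equal(nrow(tab), 7)
  expect_setequal(tab$condition, c("LT", "SB", "LC", "LT+SB", "LC+SB",
                                   "LC+LT", "LC+LT+SB"))
  expect_false(anyDuplicated(tab$condition) > 0)
  expect_equal(tab$distance[tab$condition == "LC+LT+SB"], 0,
               tolerance = 1e-9)
  expect_true(all(is.finite(tab$rmse)))
  expect_error(run_realism_ablation(n_images = 2,
                                    combos = list("LT", "XX")),
               class = "wheattips_invalid_parameter")
})

test_that("a single-GSD sweep equals a plain evaluation of that dataset", {
  scenes <- wheattips:::make_scenes(3, seed = 12, plot_width = 220,
                                    plot_depth = 220)
  tab <- run_resolution_sweep(scenes, gsd_values = 0.8, seed = 12,
                              sensor_width_px = 256,
                              look_at = c(110, 110, 0))
  # manual stage-by-stage invocation with the same scenes and camera
  cam <- camera_for_gsd(0.8, view_zenith = 45, fov = 40,
                        sensor_width_px = 256, look_at = c(110, 110, 0))
  gts <- list(); dets <- list()
  for (i in seq_along(scenes)) {
    fr <- render_scene(scenes[[i]], cam, flat_light(), texture_set(),
                       aa_factor = 1)
    gts[[i]] <- suppressWarnings(annotate_tips(scenes[[i]], fr))
    dets[[i]] <- detect_tips(fr)
  }
  per_image <- eval_image_table(gts, dets)
  want <- count_metrics(per_image$y, per_image$y_hat)
  expect_equal(tab$mae, want$mae)
  expect_equal(tab$rmse, want$rmse)
  expect_error(run_resolution_sweep(scenes, gsd_values = c(0.5, -1)),
               class = "wheattips_invalid_parameter")
})

test_that("annotation counts are stable across GSDs at nadir", {
  # sparse scenes: tip visibility is then unambiguous and purely geometric
  # (in dense canopies the pixel-level z-test is resolution dependent)
  rng <- default_parameter_ranges()
  rng$sowing_density <- c(30, 60)
  rng$thermal_time <- c(80, 250)
  scenes <- wheattips:::make_scenes(3, ranges = rng, seed = 17,
                                    plot_width = 150, plot_depth = 150)
  counts <- list()
  for (g in c(0.8, 1.6)) {
    cam <- camera_for_gsd(g, view_zenith = 0, fov = 40,
                          sensor_width_px = 256, look_at = c(75, 75, 0))
    counts[[as.character(g)]] <- vapply(scenes, function(sc) {
      fr <- render_scene(sc, cam, flat_light(), texture_set(), aa_factor = 1)
      nrow(suppressWarnings(annotate_tips(sc, fr)))
    }, 0L)
  }
  expect_identical(counts[[1]], counts[[2]])
})

test_that("experiment drivers are deterministic given their seeds", {
  a <- run_realism_ablation(n_images = 2, combos = list("LC"), seed = 9)
  b <- run_realism_ablation(n_images = 2, combos = list("LC"), seed = 9)
  expect_equal(a, b)
})

test_that("autoplot methods return ggplot objects for each result type", {
  sc <- single_plant_scene(2, 150)
  fr <- render_scene(sc, nadir_camera(1.5, 96), flat_light(), texture_set(),
                     aa_factor = 1)
  expect_s3_class(ggplot2::autoplot(fr), "ggplot")

  per_image <- tibble::tibble(image = 1:4, stage = c(1.2, 2.2, 3.2, 2.8),
                              y = c(2, 4, 6, 5), y_hat = c(2, 3, 5, 5),
                              tp = c(2, 3, 4, 5), fp = c(0, 0, 1, 0),
                              fn = c(0, 1, 2, 0))
  expect_s3_class(ggplot2::autoplot(per_stage_report(per_image)), "ggplot")

  sweep_tab <- structure(tibble::tibble(gsd = c(0.5, 1), n_images = 2,
                                        mae = c(1, 2), rmse = c(1.5, 2.5),
                                        r2 = c(0.9, 0.5)),
                         class = c("experiment_table", class(tibble::tibble())))
  expect_s3_class(ggplot2::autoplot(sweep_tab), "ggplot")

  set.seed(1)
  emb <- tibble::tibble(dim1 = rnorm(10), dim2 = rnorm(10))
  expect_s3_class(plot_gap_embedding(emb, rep(c("A", "B"), 5)), "ggplot")
})
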