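test_that("excess-green mask isolates a green blob with a bimodal split", {
  img <- array(0, c(24, 24, 3))
  img[, , 1] <- 120 / 255; img[, , 2] <- 100 / 255; img[, , 3] <- 80 / 255
  blob <- 8:17
  img[blob, blob, 1] <- 50 / 255
  img[blob, blob, 2] <- 200 / 255
  img[blob, blob, 3] <- 50 / 255
  # ExG: 300/255 on the blob vs 0 on the background
  mask <- vegetation_mask(img)
  want <- matrix(FALSE, 24, 24); want[blob, blob] <- TRUE
  expect_identical(unclass(mask)[, ], want)
})

test_that("a constant or grey image yields an empty mask with a warning", {
  grey <- array(0.4, c(16, 16, 3))
  expect_warning(m <- vegetation_mask(grey),
                 class = "wheattips_degenerate_image")
  expect_false(any(m))
})

test_that("channel scaling preserves the Otsu split of the mask", {
  set.seed(5)
  img <- array(runif(32 * 32 * 3, 0.1, 0.4), c(32, 32, 3))
  img[10:20, 10:20, 2] <- img[10:20, 10:20, 2] + 0.4
  m1 <- vegetation_mask(img)
  m2 <- vegetation_mask(img * 2)
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])
})

test_that("skeleton endpoints count line ends, rings and T-junctions", {
  line <- matrix(FALSE, 20, 20); line[10, 5:14] <- TRUE
  se <- skeleton_endpoints(line)
  expect_equal(nrow(se$endpoints), 2)
  expect_setequal(se$endpoints$u, c(4, 13))

  ring <- matrix(FALSE, 20, 20)
  ring[5, 5:15] <- TRUE; ring[15, 5:15] <- TRUE
  ring[5:15, 5] <- TRUE; ring[5:15, 15] <- TRUE
  expect_equal(nrow(skeleton_endpoints(ring)$endpoints), 0)

  tee <- matrix(FALSE, 21, 21)
  tee[5, 3:18] <- TRUE; tee[5:18, 10] <- TRUE
  expect_equal(nrow(skeleton_endpoints(tee)$endpoints), 3)

  expect_equal(nrow(skeleton_endpoints(matrix(FALSE, 5, 5))$endpoints), 0)
})

test_that("taper classification keeps the wedge apex and drops blunt ends", {
  # blade-like mask: rounded blunt butt, straight shaft, wedge-tapered apex
  # (a bare triangle would also taper into its base corners, which are
  # legitimately sharp; the rounded end is the blunt case of interest)
  pencil <- matrix(FALSE, 40, 60)
  for (r in 1:40) for (cc in 1:60)
    if ((r - 20)^2 + (cc - 10)^2 <= 36) pencil[r, cc] <- TRUE
  pencil[14:26, 10:36] <- TRUE
  for (cc in 37:56) {
    half <- 6 * (56 - cc) / 20
    pencil[(20 - floor(half)):(20 + floor(half)), cc] <- TRUE
  }
  se <- skeleton_endpoints(pencil)
  expect_equal(nrow(se$endpoints), 2)
  det <- classify_tips(se, pencil, border_margin = 0)
  expect_equal(nrow(det), 1)
  expect_gt(det$center_u, 45)  # the tapered apex, not the rounded butt

  rect <- matrix(FALSE, 40, 60); rect[14:26, 5:55] <- TRUE
  se_r <- skeleton_endpoints(rect)
  det_r <- classify_tips(se_r, rect, border_margin = 0)
  expect_equal(nrow(det_r), 0)

  lone <- matrix(FALSE, 20, 20); lone[10, 10] <- TRUE
  det_l <- classify_tips(skeleton_endpoints(lone), lone, border_margin = 0)
  expect_equal(nrow(det_l), 0)
})

test_that("detection count never exceeds the endpoint count", {
  for (s in 1:4) {
    set.seed(s)
    f <- field_config(thermal_time = runif(1, 120, 300), seed = s,
                      plot_width = 200, plot_depth = 200,
                      sowing_density = 150)
    sc <- build_canopy(f, plant_params())
    cam <- nadir_camera(gsd = 0.8, px = 256, look_at = c(100, 100, 0))
    fr <- render_scene(sc, cam, flat_light(), texture_set(), aa_factor = 1)
    det <- detect_tips(fr)
    ep <- skeleton_endpoints(vegetation_mask(fr$rgb), prune = 2L)
    expect_lte(nrow(det), nrow(ep$endpoints))
  }
})

test_that("a soil-only render yields no detections and detect is idempotent", {
  f <- field_config(sowing_density = 100, plot_width = 20, plot_depth = 20,
                    thermal_time = 100, seed = 1)
  sc <- suppressWarnings(build_canopy(f, plant_params()))
  cam <- nadir_camera(gsd = 1, px = 96, look_at = c(10, 10, 0))
  fr <- render_scene(sc, cam, flat_light(),
                     texture_set("procedural", "procedural"), aa_factor = 1)
  expect_equal(nrow(suppressWarnings(detect_tips(fr))), 0)

  sc2 <- single_plant_scene(3, 180)
  fr2 <- render_scene(sc2, nadir_camera(gsd = 1, px = 256), flat_light(),
                      texture_set(), aa_factor = 1)
  d1 <- detect_tips(fr2)
  d2 <- detect_tips(fr2)
  expect_identical(d1, d2)
})

test_that("clean single-plant renders are detected near the true tips", {
  sc <- single_plant_scene(1004, 180)  # H = 1.8: two leaves
  cam <- camera_for_gsd(0.3, view_zenith = 0, fov = 40,
                        sensor_width_px = 768, look_at = c(0, 0, 0))
  fr <- render_scene(sc, cam, flat_light(), texture_set(), aa_factor = 2)
  ann <- annotate_tips(sc, fr)
  det <- detect_tips(fr)
  expect_gte(nrow(det), 1)
  for (j in seq_len(nrow(det))) {
    dmin <- min(sqrt((det$center_u[j] - ann$center_u)^2 +
                       (det$center_v[j] - ann$center_v)^2))
    expect_lt(dmin, 6)
  }
})

test_that("detections serialize through both interchange dialects", {
  det <- tibble::tibble(center_u = c(10.5, 20), center_v = c(30, 40.25),
                        box_x = c(4.5, 14), box_y = c(24, 34.25),
                        box_w = 12, box_h = 12, score = c(0.9, 0.4))
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, pj)
  write_detections(det, pc)
  bj <- read_detections(pj)
  bc <- read_detections(pc)
  expect_equal(bj$center_u, det$center_u)
  expect_equal(bj$score, det$score)
  expect_equal(bc$center_v, det$center_v)
})
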