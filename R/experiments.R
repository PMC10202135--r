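# Experiment drivers: realism-factor ablation and spatial-resolution sweep.

# Build n canopy scenes from a Latin-hypercube sample of the ranges.
make_scenes <- function(n, ranges = default_parameter_ranges(), seed = 1L,
                        plot_width = 300, plot_depth = 300) {
  samples <- sample_parameter_sets(n, ranges, seed = seed)
  map(seq_len(n), function(i) {
    cfg <- params_from_sample(samples[i, ], seed = derive_seed(seed, 100 + i),
                              plot_width = plot_width, plot_depth = plot_depth)
    build_canopy(cfg$field, cfg$params)
  })
}

# Per-scene light/texture draws for the three realism factors. When a factor
# is not varied it is pinned to its default: the standard (flat) soil
# background, the standard leaf texture, and constant fully diffuse
# illumination.
experiment_light <- function(varied, seed) {
  if (!varied) return(light_config(diffuse_fraction = 1, cast_shadows = FALSE))
  set.seed(seed)
  light_config(sun_zenith = runif(1, 15, 60),
               sun_azimuth = runif(1, 0, 360),
               diffuse_fraction = runif(1, 0.2, 1),
               cast_shadows = TRUE)
}

experiment_textures <- function(leaf_varied, soil_varied, seed) {
  texture_set(leaf_texture = if (leaf_varied) "procedural" else "standard",
              soil_texture = if (soil_varied) "procedural" else "standard",
              seed = seed)
}

# Render one experiment condition: returns frames, annotations, stages.
render_condition <- function(scenes, camera, lt, sb, lc, seed,
                             aa_factor = 1L) {
  frames <- vector("list", length(scenes))
  anns <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    li <- experiment_light(lc, derive_seed(seed, 10 + i))
    tx <- experiment_textures(lt, sb, derive_seed(seed, 50 + i))
    frames[[i]] <- render_scene(scenes[[i]], camera, li, tx,
                                aa_factor = aa_factor)
    anns[[i]] <- suppressWarnings(annotate_tips(scenes[[i]], frames[[i]]))
  }
  list(frames = frames, annotations = anns,
       stages = map_dbl(scenes, "mean_haun"))
}

parse_flags <- function(flags) {
  flags <- toupper(flags)
  bad <- setdiff(flags, c("LT", "SB", "LC"))
  if (length(bad) > 0)
    abort(sprintf("Unknown realism flags: %s.", paste(bad, collapse = ", ")),
          class = "wheattips_invalid_parameter")
  flags
}

#' Realism-factor ablation experiment
#'
#' Generates one image set per requested combination of the three realism
#' factors -- leaf texture (LT), soil background (SB), light condition (LC) --
#' varying only the flagged factors and pinning the others to their defaults
#' (standard soil, standard leaf texture, constant fully diffuse light). For
#' each condition the detector is run against the automatic annotations, and
#' the feature-space [dataset_distance()] to a designated reference set is
#' recorded. The default grid is the 7-row factor ladder LT, SB, LC, LT+SB,
#' LC+SB, LC+LT, LC+LT+SB; the reference defaults to the full-realism
#' (LC+LT+SB) set itself, the most realistic set the simulator can produce.
#'
#' @param n_images Images per condition.
#' @param combos List of character vectors, each a subset of
#'   `c("LT", "SB", "LC")` (an empty vector is the all-defaults condition).
#' @param detector Detector plug-in `function(frame, ...)` returning a
#'   detection tibble; default [detect_tips()].
#' @param seed Master seed.
#' @param reference Optional list of reference images (arrays or frames) for
#'   the distance; defaults to the full-realism condition's images.
#' @param ranges Parameter ranges for the scene sample.
#' @param camera A [camera_config()]; default desk-scale 45-degree view.
#' @param extractor Feature extractor for [dataset_distance()].
#' @return An `ExperimentTable` tibble: `condition`, `n_images`, `rmse`,
#'   `r2`, `distance`.
#' @export
run_realism_ablation <- function(n_images = 20,
                                 combos = list("LT", "SB", "LC",
                                               c("LT", "SB"), c("LC", "SB"),
                                               c("LC", "LT"),
                                               c("LC", "LT", "SB")),
                                 detector = detect_tips, seed = 1L,
                                 reference = NULL,
                                 ranges = default_parameter_ranges(),
                                 camera = NULL,
                                 extractor = "handcrafted") {
  combos <- map(combos, parse_flags)
  labels <- map_chr(combos, function(f)
    if (length(f) == 0) "none" else paste(f, collapse = "+"))
  if (anyDuplicated(labels) > 0)
    abort("Condition labels must be unique.",
          class = "wheattips_invalid_parameter")
  if (is.null(camera))
    camera <- camera_for_gsd(0.8, view_zenith = 45, fov = 40,
                             sensor_width_px = 256,
                             look_at = c(150, 150, 0))
  scenes <- make_scenes(n_images, ranges, seed = derive_seed(seed, 1))

  ref_feats <- NULL
  if (!is.null(reference)) ref_feats <- extract_features(reference, extractor)

  rows <- list()
  cond_sets <- list()
  for (ci in seq_along(combos)) {
    f <- combos[[ci]]
    cond <- render_condition(scenes, camera,
                             lt = "LT" %in% f, sb = "SB" %in% f,
                             lc = "LC" %in% f,
                             seed = derive_seed(seed, 1000 + ci))
    cond_sets[[labels[ci]]] <- cond
  }
  if (is.null(ref_feats)) {
    ref_label <- if ("LC+LT+SB" %in% labels) "LC+LT+SB"
                 else labels[length(labels)]
    ref_feats <- extract_features(cond_sets[[ref_label]]$frames, extractor)
  }
  for (ci in seq_along(combos)) {
    cond <- cond_sets[[labels[ci]]]
    dets <- map(cond$frames, function(fr) detector(fr))
    per_image <- eval_image_table(cond$annotations, dets, cond$stages)
    cm <- count_metrics(per_image$y, per_image$y_hat)
    feats <- extract_features(cond$frames, extractor)
    rows[[ci]] <- tibble(condition = labels[ci], n_images = n_images,
                         rmse = cm$rmse, r2 = cm$r2,
                         distance = dataset_distance(ref_feats, feats))
  }
  out <- bind_rows(rows)
  class(out) <- c("experiment_table", class(out))
  out
}

#' Spatial-resolution sweep
#'
#' Re-renders the same scenes at a grid of ground sampling distances by
#' adjusting the camera height ([camera_for_gsd()]), annotates, runs the
#' detector, and records the per-GSD counting metrics. The default grid is
#' 0.1 to 2.0 mm per pixel in 0.1 mm steps.
#'
#' @param scenes List of `canopy_scene`s (e.g. from the internal sampler via
#'   [generate_dataset()] components), or an integer: how many scenes to
#'   sample with `seed`.
#' @param gsd_values GSD grid (mm per pixel, all > 0).
#' @param detector Detector plug-in; default [detect_tips()].
#' @param seed Seed used when `scenes` is a count.
#' @param sensor_width_px Sensor size used for all GSDs.
#' @param view_zenith,fov Viewing geometry (degrees).
#' @param ranges Parameter ranges when sampling scenes.
#' @param look_at Ground point the camera aims at.
#' @return An `experiment_table` tibble: `gsd`, `n_images`, `mae`, `rmse`,
#'   `r2`.
#' @export
run_resolution_sweep <- function(scenes = 20,
                                 gsd_values = seq(0.1, 2.0, by = 0.1),
                                 detector = detect_tips, seed = 1L,
                                 sensor_width_px = 384,
                                 view_zenith = 45, fov = 40,
                                 ranges = default_parameter_ranges(),
                                 look_at = NULL) {
  if (any(gsd_values <= 0))
    abort("GSD values must be positive.",
          class = "wheattips_invalid_parameter")
  if (is.numeric(scenes) && length(scenes) == 1) {
    rng <- ranges
    rng$thermal_time <- c(80, 280)  # early stages: tips resolvable at fine GSD
    scenes <- make_scenes(scenes, rng, seed = seed,
                          plot_width = 220, plot_depth = 220)
  }
  if (is.null(look_at)) look_at <- c(110, 110, 0)
  rows <- list()
  for (g in gsd_values) {
    camera <- camera_for_gsd(g, view_zenith = view_zenith, fov = fov,
                             sensor_width_px = sensor_width_px,
                             look_at = look_at)
    gts <- list(); dets <- list()
    for (i in seq_along(scenes)) {
      frame <- render_scene(scenes[[i]], camera,
                            light_config(diffuse_fraction = 1,
                                         cast_shadows = FALSE),
                            texture_set(), aa_factor = 1L)
      gts[[i]] <- suppressWarnings(annotate_tips(scenes[[i]], frame))
      dets[[i]] <- detector(frame)
    }
    per_image <- eval_image_table(gts, dets, map_dbl(scenes, "mean_haun"))
    cm <- count_metrics(per_image$y, per_image$y_hat)
    rows[[length(rows) + 1]] <- tibble(gsd = g, n_images = length(scenes),
                                       mae = cm$mae, rmse = cm$rmse,
                                       r2 = cm$r2)
  }
  out <- bind_rows(rows)
  class(out) <- c("experiment_table", class(out))
  out
}
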