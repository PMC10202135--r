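# Dataset assembly and interchange: manifest JSON, COCO boxes, flat CSV.

MANIFEST_VERSION <- "1.0"

#' Build a dataset manifest
#'
#' @param records List of [image_record()]s (unique image paths).
#' @param config Named list: generation configuration snapshot.
#' @param master_seed Integer master seed of the generation run.
#' @return A `tip_manifest` object.
#' @export
tip_manifest <- function(records = list(), config = list(), master_seed = NA) {
  paths <- map(records, "image")
  if (anyDuplicated(unlist(paths)) > 0)
    abort("Image paths in a manifest must be unique.",
          class = "wheattips_invalid_parameter")
  structure(list(version = MANIFEST_VERSION, master_seed = master_seed,
                 config = config, records = records),
            class = "tip_manifest")
}

#' @export
print.tip_manifest <- function(x, ...) {
  n_ann <- sum(map_int(x$records, function(r) nrow(r$annotations)))
  cat(sprintf("<tip_manifest> %d images, %d leaf-tip annotations, seed %s\n",
              length(x$records), n_ann, format(x$master_seed)))
  invisible(x)
}

annotation_cols <- function(df) {
  num <- c("center_u", "center_v", "box_x", "box_y", "box_w", "box_h", "depth")
  int <- c("plant_id", "leaf_rank", "leaf_id")
  out <- tibble(center_u = double(0))
  if (is.null(df) || length(df) == 0 || (is.data.frame(df) && nrow(df) == 0)) {
    df <- as.data.frame(setNames(
      c(lapply(num, function(x) double(0)), lapply(int, function(x) integer(0))),
      c(num, int)))
  }
  df <- as_tibble(df)
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in int) df[[cn]] <- as.integer(df[[cn]])
  df[, c(num[1:6], int, num[7])]
}

record_to_list <- function(r) {
  list(image = r$image, width = r$width, height = r$height, gsd = r$gsd,
       haun_stage = r$haun_stage, provenance = r$provenance,
       annotations = annotation_cols(r$annotations))
}

record_from_list <- function(l) {
  image_record(image = l$image, width = l$width, height = l$height,
               gsd = l$gsd, haun_stage = l$haun_stage,
               annotations = annotation_cols(l$annotations),
               provenance = lapply(l$provenance, function(x) x))
}

#' Write a dataset to disk
#'
#' Writes tile images as PNG (`images/`), the manifest as JSON, annotations
#' in COCO-format JSON (bbox `[x, y, w, h]`, boxes clipped to the image
#' bounds) and as a flat CSV (`image, center_u, center_v, plant_id,
#' leaf_rank`).
#'
#' @param manifest A [tip_manifest()]; records carrying in-memory pixels are
#'   written out and stripped.
#' @param out_dir Output directory (created if needed).
#' @return The on-disk manifest (no in-memory pixels), invisibly.
#' @export
write_dataset <- function(manifest, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  recs <- map(manifest$records, function(r) {
    rel <- if (grepl("^images/", r$image %||% "")) r$image
           else file.path("images", basename(r$image))
    if (!is.null(r$rgb)) write_frame_png(r$rgb, file.path(out_dir, rel))
    r$image <- rel
    r$rgb <- NULL
    r
  })
  out <- tip_manifest(recs, manifest$config, manifest$master_seed)
  jsonlite::write_json(
    list(version = out$version, master_seed = out$master_seed,
         config = out$config, records = map(out$records, record_to_list)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_coco(out, file.path(out_dir, "annotations_coco.json"))
  write_annotations_csv(out, file.path(out_dir, "annotations.csv"))
  invisible(out)
}

write_coco <- function(manifest, path) {
  images <- list(); anns <- list(); aid <- 0L
  for (i in seq_along(manifest$records)) {
    r <- manifest$records[[i]]
    images[[i]] <- list(id = i, file_name = r$image,
                        width = r$width, height = r$height)
    a <- r$annotations
    if (nrow(a) > 0) {
      for (j in seq_len(nrow(a))) {
        aid <- aid + 1L
        x0 <- max(0, a$box_x[j]); y0 <- max(0, a$box_y[j])
        x1 <- min(r$width, a$box_x[j] + a$box_w[j])
        y1 <- min(r$height, a$box_y[j] + a$box_h[j])
        anns[[aid]] <- list(id = aid, image_id = i, category_id = 1L,
                            bbox = c(x0, y0, x1 - x0, y1 - y0),
                            area = (x1 - x0) * (y1 - y0), iscrowd = 0L,
                            plant_id = a$plant_id[j],
                            leaf_rank = a$leaf_rank[j])
      }
    }
  }
  jsonlite::write_json(
    list(images = images, annotations = anns,
         categories = list(list(id = 1L, name = "leaf_tip"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

write_annotations_csv <- function(manifest, path) {
  rows <- map(manifest$records, function(r) {
    a <- r$annotations
    if (nrow(a) == 0) return(NULL)
    tibble(image = r$image, center_u = a$center_u, center_v = a$center_v,
           plant_id = a$plant_id, leaf_rank = a$leaf_rank)
  })
  df <- bind_rows(rows)
  if (nrow(df) == 0)
    df <- tibble(image = character(), center_u = double(),
                 center_v = double(), plant_id = integer(),
                 leaf_rank = integer())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest from disk
#'
#' Inverse of [write_dataset()]: `read_dataset(write_dataset(x, d))` equals
#' `x` field for field.
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @param check_images Verify that every referenced image file exists.
#' @return A `tip_manifest`.
#' @export
read_dataset <- function(dir, check_images = TRUE) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    abort(sprintf("No manifest.json under '%s'.", dir),
          class = "wheattips_parse_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  recs <- raw$records
  n <- if (is.data.frame(recs)) nrow(recs) else length(recs)
  records <- vector("list", n %||% 0)
  for (i in seq_len(length(records))) {
    l <- if (is.data.frame(recs)) {
      row <- recs[i, ]
      list(image = row$image, width = row$width, height = row$height,
           gsd = row$gsd, haun_stage = row$haun_stage,
           provenance = as.list(row$provenance),
           annotations = row$annotations[[1]])
    } else recs[[i]]
    rec <- tryCatch(record_from_list(l), error = function(e)
      abort(sprintf("Malformed record %d in '%s': %s", i, path,
                    conditionMessage(e)),
            class = "wheattips_parse_error"))
    if (check_images && !file.exists(file.path(dir, rec$image)))
      abort(sprintf("Record %d: image file '%s' is missing under '%s'.",
                    i, rec$image, dir),
            class = "wheattips_parse_error")
    records[[i]] <- rec
  }
  cfg <- if (length(raw$config) == 0) list() else as.list(raw$config)
  tip_manifest(records, cfg, raw$master_seed)
}

#' Re-attach annotations to externally translated images
#'
#' For datasets translated image-by-image (e.g. by an appearance-transfer
#' network that preserves leaf boundaries and hence tip positions), the
#' original annotations remain valid. This pairs each manifest record with
#' its translated counterpart by filename, verifies identical pixel
#' dimensions, and returns a manifest pointing at the translated images with
#' the annotations unchanged. Annotations are never rescaled: a
#' dimension-changed image is rejected.
#'
#' @param manifest A `tip_manifest`.
#' @param translated_dir Directory holding one identically named, identically
#'   sized image per record.
#' @param source_dir Directory the manifest image paths are relative to
#'   (used only to compare dimensions when records lack width/height).
#' @return A `tip_manifest` whose records point into `translated_dir`.
#' @export
attach_annotations_to_translated <- function(manifest, translated_dir,
                                             source_dir = NULL) {
  problems <- character()
  recs <- map(manifest$records, function(r) {
    cand <- file.path(translated_dir, basename(r$image))
    if (!file.exists(cand)) {
      problems <<- c(problems,
                     sprintf("missing counterpart for '%s'", r$image))
      return(r)
    }
    dims <- dim(png::readPNG(cand))
    if (dims[1] != r$height || dims[2] != r$width) {
      problems <<- c(problems,
                     sprintf("dimension mismatch for '%s' (%dx%d vs %dx%d)",
                             r$image, dims[2], dims[1], r$width, r$height))
      return(r)
    }
    r$image <- cand
    r
  })
  if (length(problems) > 0)
    abort(paste0("Translated dataset does not match the manifest:\n",
                 paste0("  - ", problems, collapse = "\n")),
          class = "wheattips_translation_mismatch")
  tip_manifest(recs, manifest$config, manifest$master_seed)
}

#' Generate a complete annotated dataset
#'
#' End-to-end pipeline: Latin-hypercube sample `n_scenes` parameter sets,
#' build one canopy per set, render it, place leaf-tip annotations, tile the
#' frame into training-size subimages, and write everything to `out_dir`.
#' Fully deterministic given `seed`.
#'
#' @param n_scenes Number of scenes (parameter sets).
#' @param out_dir Output directory.
#' @param ranges Parameter ranges for [sample_parameter_sets()].
#' @param seed Master seed.
#' @param camera A [camera_config()], or `NULL` for a default 45-degree view
#'   aimed at the plot centre at 0.5 mm/px.
#' @param light A [light_config()], or a `function(i, seed)` returning one
#'   per scene (used by the realism experiments).
#' @param textures A [texture_set()], or a `function(i, seed)` returning one
#'   per scene.
#' @param tile_size,stride Tiling geometry (px); see
#'   [tile_with_annotations()].
#' @param aa_factor Supersampling factor passed to [render_scene()].
#' @param plot_width,plot_depth Plot extent (mm).
#' @return The on-disk `tip_manifest` (also written as `manifest.json`).
#' @export
generate_dataset <- function(n_scenes, out_dir,
                             ranges = default_parameter_ranges(),
                             seed = 1L, camera = NULL,
                             light = light_config(),
                             textures = texture_set(),
                             tile_size = 256, stride = 224,
                             aa_factor = 1L,
                             plot_width = 400, plot_depth = 300) {
  config <- list(n_scenes = n_scenes, tile_size = tile_size, stride = stride,
                 aa_factor = aa_factor, plot_width = plot_width,
                 plot_depth = plot_depth)
  if (n_scenes == 0)
    return(write_dataset(tip_manifest(list(), config, seed), out_dir))
  samples <- sample_parameter_sets(n_scenes, ranges, seed = seed)
  if (is.null(camera))
    camera <- camera_for_gsd(0.5, view_zenith = 45, fov = 40,
                             sensor_width_px = 768, sensor_height_px = 768,
                             look_at = c(plot_width / 2, plot_depth / 2, 0))
  records <- list()
  for (i in seq_len(n_scenes)) {
    scene_seed <- derive_seed(seed, 100 + i)
    cfg <- params_from_sample(samples[i, ], seed = scene_seed,
                              plot_width = plot_width,
                              plot_depth = plot_depth)
    scene <- build_canopy(cfg$field, cfg$params)
    li <- if (is.function(light)) light(i, derive_seed(seed, 200 + i)) else light
    tx <- if (is.function(textures)) textures(i, derive_seed(seed, 300 + i))
          else textures
    frame <- render_scene(scene, camera, li, tx, aa_factor = aa_factor)
    ann <- suppressWarnings(annotate_tips(scene, frame))
    parent <- image_record(
      image = sprintf("scene%03d.png", i),
      width = camera$sensor_width_px, height = camera$sensor_height_px,
      gsd = frame$gsd, haun_stage = scene$mean_haun,
      annotations = ann,
      provenance = list(scene_seed = scene_seed, set_id = samples$set_id[i]),
      rgb = frame$rgb)
    records <- c(records, tile_with_annotations(parent, tile_size, stride))
  }
  write_dataset(tip_manifest(records, config, seed), out_dir)
}
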