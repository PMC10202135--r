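# Automatic leaf-tip labelling and sliding-window tiling.

#' Place leaf-tip annotations on a rendered frame
#'
#' Projects every leaf tip of the scene into the frame and tests its
#' visibility against the z-buffer: a tip is visible iff some pixel's owner
#' within a `(2 window + 1)^2` pixel window around its projection is that
#' leaf, or the buffer depth at the projection pixel exceeds the tip depth
#' minus `depth_eps` (i.e. the tip is front-most where it lands). Tips are
#' sub-pixel-thin, so a pure single-pixel owner test would drop visible
#' tips; the owner clause therefore uses the window (default 3 x 3), while
#' the depth clause is evaluated at the projection pixel itself so that a
#' thin occluder just in front of the tip is not seen past. Only visible
#' tips whose centre lies inside the image are emitted, each with a
#' 12 x 12 px box.
#'
#' @param scene The `canopy_scene` the frame was rendered from.
#' @param frame The matching `rendered_frame`.
#' @param box_size Side of the emitted square boxes (px).
#' @param depth_eps Depth tolerance (mm).
#' @param window Half-width of the pixel window (1 gives 3 x 3).
#' @return A tibble of annotations: `center_u`, `center_v`, `box_x`, `box_y`,
#'   `box_w`, `box_h`, `plant_id`, `leaf_rank`, `leaf_id`, `depth`.
#' @export
annotate_tips <- function(scene, frame, box_size = 12, depth_eps = 2,
                          window = 1L) {
  camera <- frame$camera
  m <- scene_mesh(scene)
  empty <- tibble(center_u = double(), center_v = double(),
                  box_x = double(), box_y = double(),
                  box_w = double(), box_h = double(),
                  plant_id = integer(), leaf_rank = integer(),
                  leaf_id = integer(), depth = double())
  if (nrow(m$tips) == 0) {
    warn("Scene has no leaves; returning an empty annotation table.",
         class = "wheattips_no_tips")
    return(empty)
  }
  cb <- camera_basis(camera)
  K <- camera_intrinsics(camera)
  P <- as.matrix(m$tips[, c("x", "y", "z")])
  rel <- sweep(P, 2, cb$pos, "-")
  camc <- rel %*% t(cb$R)
  ok <- camc[, 3] > 1e-6
  u <- K$cx + K$fx * camc[, 1] / camc[, 3]
  v <- K$cy + K$fy * camc[, 2] / camc[, 3]
  d <- sqrt(rowSums(rel^2))
  in_frame <- ok & u >= 0 & u < K$W & v >= 0 & v < K$H
  if (!any(in_frame)) {
    warn("No leaf tip projects into the frame.", class = "wheattips_no_tips")
    return(empty)
  }
  H <- nrow(frame$depth); W <- ncol(frame$depth)
  visible <- logical(nrow(m$tips))
  for (i in which(in_frame)) {
    ui <- round(u[i]); vi <- round(v[i])
    us <- max(0, ui - window):min(W - 1, ui + window)
    vs <- max(0, vi - window):min(H - 1, vi + window)
    own <- frame$owner[vs + 1, us + 1, drop = FALSE]
    dep_at <- frame$depth[min(max(vi, 0), H - 1) + 1, min(max(ui, 0), W - 1) + 1]
    visible[i] <- any(own == m$tips$leaf_id[i]) || dep_at > d[i] - depth_eps
  }
  keep <- which(in_frame & visible)
  tibble(center_u = u[keep], center_v = v[keep],
         box_x = u[keep] - box_size / 2, box_y = v[keep] - box_size / 2,
         box_w = box_size, box_h = box_size,
         plant_id = m$tips$plant_id[keep],
         leaf_rank = m$tips$leaf_rank[keep],
         leaf_id = m$tips$leaf_id[keep],
         depth = d[keep])
}

# Window start offsets: stride steps, with the last window clamped so it
# abuts the image border; every pixel is covered by at least one window.
tile_starts <- function(n, tile, stride) {
  if (tile >= n) return(0L)
  s <- seq(0L, n - tile, by = stride)
  if (s[length(s)] != n - tile) s <- c(s, n - tile)
  as.integer(s)
}

#' An image record (one image plus its annotations)
#'
#' @param image Image path (possibly not yet on disk), or `NA`.
#' @param width,height Image size (px).
#' @param gsd Ground sampling distance (mm/px).
#' @param haun_stage Mean Haun stage of the pictured scene.
#' @param annotations Annotation tibble as from [annotate_tips()].
#' @param provenance Named list (scene seed, parameter-set id, tile origin).
#' @param rgb Optional in-memory H x W x 3 array.
#' @return An `image_record` object.
#' @export
image_record <- function(image, width, height, gsd, haun_stage,
                         annotations, provenance = list(), rgb = NULL) {
  structure(
    list(image = image, width = as.integer(width), height = as.integer(height),
         gsd = gsd, haun_stage = haun_stage,
         annotations = annotation_cols(annotations), provenance = provenance,
         rgb = rgb),
    class = "image_record")
}

#' Tile an image record into training-size subimages
#'
#' Sliding windows of `tile_size` px at `stride` px steps, with the last
#' row/column clamped to abut the border so every pixel is covered. An
#' annotation is assigned to a tile iff its centre lies inside the tile
#' (half-open `[u0, u0 + tile)`), with coordinates translated by the tile
#' origin; annotations falling in window overlaps are duplicated per tile.
#'
#' @param record An [image_record()] (with or without in-memory pixels).
#' @param tile_size Window side (px).
#' @param stride Step between windows (px, `0 < stride <= tile_size`).
#' @return A list of `image_record` tiles; each has `provenance$tile_u0/v0`.
#' @export
tile_with_annotations <- function(record, tile_size = 1024, stride = 896) {
  if (stride <= 0 || stride > tile_size)
    abort("`stride` must satisfy 0 < stride <= tile_size.",
          class = "wheattips_invalid_parameter")
  if (tile_size > record$width || tile_size > record$height) {
    warn("Tile larger than the image; emitting a single clamped tile.",
         class = "wheattips_tile_clamped")
    tile_w <- min(tile_size, record$width)
    tile_h <- min(tile_size, record$height)
  } else {
    tile_w <- tile_h <- tile_size
  }
  us <- tile_starts(record$width, tile_w, stride)
  vs <- tile_starts(record$height, tile_h, stride)
  ann <- record$annotations
  tiles <- list()
  for (v0 in vs) {
    for (u0 in us) {
      inside <- ann$center_u >= u0 & ann$center_u < u0 + tile_w &
        ann$center_v >= v0 & ann$center_v < v0 + tile_h
      sub <- ann[inside, , drop = FALSE]
      sub$center_u <- sub$center_u - u0
      sub$center_v <- sub$center_v - v0
      sub$box_x <- sub$box_x - u0
      sub$box_y <- sub$box_y - v0
      rgb <- NULL
      if (!is.null(record$rgb))
        rgb <- record$rgb[(v0 + 1):(v0 + tile_h), (u0 + 1):(u0 + tile_w), ,
                          drop = FALSE]
      prov <- record$provenance
      prov$tile_u0 <- u0
      prov$tile_v0 <- v0
      base <- if (is.na(record$image)) "tile" else
        sub("\\.png$", "", basename(record$image))
      tiles[[length(tiles) + 1]] <- image_record(
        image = sprintf("%s_u%d_v%d.png", base, u0, v0),
        width = tile_w, height = tile_h, gsd = record$gsd,
        haun_stage = record$haun_stage, annotations = sub,
        provenance = prov, rgb = rgb)
    }
  }
  tiles
}
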