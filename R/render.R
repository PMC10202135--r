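# Z-buffer rendering of canopy scenes.
#
# Rasterization replaces physically based ray tracing: a z-buffer over the
# textured soil plane with Lambertian shading, an isotropic diffuse term, and
# hard shadows by any-hit ray tests against the triangle set. This retains
# the three realism factors manipulated downstream (leaf texture, soil
# background, illumination) at desk-scale rendering cost.

#' Lambertian shading with a diffuse sky term
#'
#' color = albedo * (f_d + (1 - f_d) * max(0, n . s) * lit), clamped to
#' \[0, 1\], where `f_d` is the diffuse fraction, `s` the unit vector toward
#' the sun and `lit` is 0 for shadowed points. With `f_d = 1` (fully diffuse,
#' overcast) the result is the albedo itself, independent of shadows.
#'
#' @param normal Unit surface normal: 3-vector or n x 3 matrix.
#' @param albedo Surface colour: 3-vector or n x 3 matrix in \[0, 1\].
#' @param light A [light_config()].
#' @param in_shadow Logical (scalar or length n): blocked from direct sun?
#' @return An n x 3 matrix of colours in \[0, 1\].
#' @export
shade <- function(normal, albedo, light, in_shadow = FALSE) {
  if (is.null(dim(normal))) normal <- matrix(normal, 1, 3)
  if (is.null(dim(albedo))) albedo <- matrix(albedo, 1, 3)
  s <- sun_vector(light)
  ndots <- pmax(0, as.vector(normal %*% s))
  direct <- (1 - light$diffuse_fraction) * ndots * ifelse(in_shadow, 0, 1)
  fac <- light$diffuse_fraction + direct
  pmin(pmax(albedo * fac, 0), 1)
}

# Canonical face order: by owner, then by face centroid, so rendering does
# not depend on the order in which triangles were assembled.
canonical_face_order <- function(V, F_, owner) {
  cx <- (V[F_[, 1], 1] + V[F_[, 2], 1] + V[F_[, 3], 1]) / 3
  cy <- (V[F_[, 1], 2] + V[F_[, 2], 2] + V[F_[, 3], 2]) / 3
  cz <- (V[F_[, 1], 3] + V[F_[, 2], 3] + V[F_[, 3], 3]) / 3
  order(owner, cx, cy, cz)
}

rasterize_pass <- function(V, F_, owner, UV, camera, aa = 1L) {
  cb <- camera_basis(camera)
  K <- camera_intrinsics(camera)
  cpp_rasterize(V, F_ - 1L, as.integer(owner), UV, cb$pos, cb$R,
                aa * K$fx, aa * K$fy,
                aa * K$cx + (aa - 1) / 2, aa * K$cy + (aa - 1) / 2,
                as.integer(aa * K$W), as.integer(aa * K$H))
}

shade_pass <- function(ras, scene, camera, light, textures, V, F_) {
  H <- nrow(ras$depth); W <- ncol(ras$depth)
  owner <- as.vector(ras$owner)
  rgb <- matrix(0, H * W, 3)

  soil_idx <- which(owner == 0L)
  leaf_idx <- which(owner > 0L)
  albedo <- matrix(0, H * W, 3)
  if (length(soil_idx) > 0) {
    albedo[soil_idx, ] <- texture_lookup(
      textures$soil, textures$texture_scale,
      as.vector(ras$tu)[soil_idx], as.vector(ras$tv)[soil_idx])
  }
  if (length(leaf_idx) > 0) {
    albedo[leaf_idx, ] <- texture_lookup(
      textures$leaf, textures$texture_scale,
      as.vector(ras$tu)[leaf_idx], as.vector(ras$tv)[leaf_idx])
  }

  vis <- which(owner >= 0L)
  if (length(vis) == 0) return(array(0, c(H, W, 3)))
  N <- cbind(as.vector(ras$nx)[vis], as.vector(ras$ny)[vis],
             as.vector(ras$nz)[vis])
  P <- cbind(as.vector(ras$px)[vis], as.vector(ras$py)[vis],
             as.vector(ras$pz)[vis])
  # two-sided leaf material: orient normals toward the camera
  cb <- camera_basis(camera)
  to_cam <- sweep(-P, 2, cb$pos, "+")
  flip <- rowSums(N * to_cam) < 0
  N[flip, ] <- -N[flip, ]

  in_shadow <- rep(FALSE, length(vis))
  if (light$cast_shadows && light$diffuse_fraction < 1 && nrow(F_) > 0) {
    s <- sun_vector(light)
    lit_cand <- which(as.vector(N %*% s) > 0)
    if (length(lit_cand) > 0) {
      hit <- cpp_any_hit(P[lit_cand, , drop = FALSE], matrix(s, 1, 3),
                         V, F_ - 1L, 0.5)
      in_shadow[lit_cand] <- hit
    }
    # below-horizon facets receive no direct light anyway
  }
  rgb[vis, ] <- shade(N, albedo[vis, , drop = FALSE], light, in_shadow)
  array(rgb, c(H, W, 3))
}

downsample_rgb <- function(rgb_hi, aa) {
  if (aa == 1L) return(rgb_hi)
  Hh <- dim(rgb_hi)[1]; Wh <- dim(rgb_hi)[2]
  H <- Hh / aa; W <- Wh / aa
  out <- array(0, c(H, W, 3))
  for (k in 1:3) {
    m <- rgb_hi[, , k]
    dim(m) <- c(aa, H, aa, W)
    out[, , k] <- apply(m, c(2, 4), mean)
  }
  out
}

#' Render a canopy scene
#'
#' Z-buffer rasterization of all leaf triangles over the textured soil plane,
#' with per-pixel depth and primitive-owner buffers, Lambertian + diffuse
#' shading, optional hard cast shadows, and `aa_factor^2` supersampling of
#' the colour channels. The depth and owner buffers are computed at the final
#' resolution (one sample at each pixel centre).
#'
#' @param scene A `canopy_scene` from [build_canopy()].
#' @param camera A [camera_config()].
#' @param light A [light_config()].
#' @param textures A [texture_set()].
#' @param aa_factor Supersampling factor for the colour image (integer >= 1).
#' @return A `rendered_frame`: list with `rgb` (H x W x 3, linear \[0, 1\]),
#'   `depth` (mm, `Inf` where no surface), `owner` (0 = soil, k >= 1 = global
#'   leaf id, -1 = none), `camera`, `light`, `gsd` (mm/px).
#' @export
render_scene <- function(scene, camera, light = light_config(),
                         textures = texture_set(), aa_factor = 2L) {
  m <- scene_mesh(scene)
  if (nrow(m$F) > 0) {
    ord <- canonical_face_order(m$V, m$F, m$owner)
    m$F <- m$F[ord, , drop = FALSE]
    m$owner <- m$owner[ord]
  }
  ras1 <- rasterize_pass(m$V, m$F, m$owner, m$UV, camera, aa = 1L)
  if (ras1$degenerate > 0)
    warn(sprintf("Skipped %d degenerate (zero-area) triangles.",
                 ras1$degenerate),
         class = "wheattips_degenerate_triangles")
  aa <- max(1L, as.integer(aa_factor))
  ras_hi <- if (aa == 1L) ras1 else
    rasterize_pass(m$V, m$F, m$owner, m$UV, camera, aa = aa)
  rgb_hi <- shade_pass(ras_hi, scene, camera, light, textures, m$V, m$F)
  structure(
    list(rgb = downsample_rgb(rgb_hi, aa),
         depth = ras1$depth, owner = ras1$owner,
         camera = camera, light = light, gsd = camera_gsd(camera)),
    class = "rendered_frame")
}

#' @export
print.rendered_frame <- function(x, ...) {
  cat(sprintf("<rendered_frame> %d x %d px, GSD %.3f mm/px, %d leaf-owned pixels\n",
              ncol(x$depth), nrow(x$depth), x$gsd, sum(x$owner > 0)))
  invisible(x)
}

#' Write a rendered frame (or plain RGB array) as PNG
#'
#' Colours are kept linear in memory; gamma 2.2 encoding is applied only
#' here, at file write, and the image is quantized to 8 bits.
#'
#' @param frame A `rendered_frame` or an H x W x 3 array in \[0, 1\].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  rgb <- if (inherits(frame, "rendered_frame")) frame$rgb else frame
  enc <- round(pmin(pmax(rgb, 0), 1)^(1 / 2.2) * 255) / 255
  png::writePNG(enc, path)
  invisible(path)
}

#' Read a PNG image as a linear RGB array
#'
#' Inverse of the encoding applied by [write_frame_png()].
#'
#' @param path PNG path.
#' @param linearize Undo the gamma 2.2 encoding (default TRUE).
#' @return An H x W x 3 array in \[0, 1\].
#' @export
read_image_png <- function(path, linearize = TRUE) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  if (linearize) img^2.2 else img
}
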