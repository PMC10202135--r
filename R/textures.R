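# Procedural fallback textures. User-supplied PNG/JPEG images override them;
# the procedural generators keep the package fully self-contained.

# Multi-octave value noise in [0, 1]: coarse uniform grids, bilinearly
# upsampled and summed with halving amplitudes.
value_noise <- function(h, w, cell = 16, octaves = 3, seed = 1L) {
  set.seed(seed)
  out <- matrix(0, h, w)
  amp <- 1; total <- 0
  for (o in seq_len(octaves)) {
    gh <- max(2, ceiling(h / cell) + 1)
    gw <- max(2, ceiling(w / cell) + 1)
    g <- matrix(runif(gh * gw), gh, gw)
    ys <- (seq_len(h) - 1) / cell + 1
    xs <- (seq_len(w) - 1) / cell + 1
    y0 <- pmin(floor(ys), gh - 1); x0 <- pmin(floor(xs), gw - 1)
    fy <- ys - y0; fx <- xs - x0
    a <- g[cbind(rep(y0, w), rep(x0, each = h))]
    b <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
    cc <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
    d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
    fy_m <- matrix(rep(fy, w), h, w)
    fx_m <- matrix(rep(fx, each = h), h, w)
    layer <- matrix(a, h, w) * (1 - fy_m) * (1 - fx_m) +
      matrix(b, h, w) * (1 - fy_m) * fx_m +
      matrix(cc, h, w) * fy_m * (1 - fx_m) +
      matrix(d, h, w) * fy_m * fx_m
    out <- out + amp * layer
    total <- total + amp
    amp <- amp / 2
    cell <- max(2, cell / 2)
  }
  out / total
}

#' Procedural soil texture
#'
#' A Perlin-like brown field: multi-octave value noise modulating a soil
#' colour, with fine speckle emulating aggregates.
#'
#' @param size Texture side length (px).
#' @param seed Integer seed.
#' @param base Base soil colour (RGB in \[0, 1\]).
#' @return A `size x size x 3` array in \[0, 1\].
#' @export
procedural_soil_texture <- function(size = 256, seed = 1L,
                                    base = c(0.42, 0.31, 0.21)) {
  n1 <- value_noise(size, size, cell = 32, octaves = 4, seed = seed)
  set.seed(derive_seed(seed, 2))
  speck <- matrix(runif(size * size, -0.5, 0.5), size, size)
  shade <- 0.55 + 0.7 * n1 + 0.12 * speck
  out <- array(0, c(size, size, 3))
  for (k in 1:3) out[, , k] <- pmin(pmax(base[k] * shade, 0), 1)
  out
}

#' Procedural leaf texture
#'
#' Band-noise green: longitudinal brightness stripes (parallel veins) plus
#' low-frequency noise over a green base colour. The texture x axis maps to
#' the along-blade direction.
#'
#' @param size Texture side length (px).
#' @param seed Integer seed.
#' @param base Base leaf colour (RGB in \[0, 1\]).
#' @return A `size x size x 3` array in \[0, 1\].
#' @export
procedural_leaf_texture <- function(size = 256, seed = 1L,
                                    base = c(0.20, 0.45, 0.12)) {
  n1 <- value_noise(size, size, cell = 24, octaves = 3, seed = seed)
  vein <- matrix(rep(0.5 + 0.5 * sin(seq_len(size) * 2 * pi / 9), each = size),
                 size, size)
  shade <- 0.72 + 0.32 * n1 + 0.16 * (vein - 0.5)
  out <- array(0, c(size, size, 3))
  for (k in 1:3) out[, , k] <- pmin(pmax(base[k] * shade, 0), 1)
  out
}

flat_texture <- function(color, size = 8) {
  out <- array(0, c(size, size, 3))
  for (k in 1:3) out[, , k] <- color[k]
  out
}

#' Texture set for rendering
#'
#' Bundles the leaf and soil albedo textures and their ground scale. Each
#' texture may be a numeric `H x W x 3` array in \[0, 1\], the path of a PNG
#' image, or one of the procedural generator ids `"procedural"` (noisy,
#' seed-dependent) and `"standard"` (the fixed flat reference colour used as
#' the default when a realism factor is not varied).
#'
#' @param leaf_texture,soil_texture Texture specification (see above).
#' @param texture_scale Ground size of one texture pixel (mm, > 0).
#' @param seed Seed for the procedural generators.
#' @return A `texture_set` object.
#' @export
texture_set <- function(leaf_texture = "standard", soil_texture = "standard",
                        texture_scale = 1, seed = 1L) {
  if (texture_scale <= 0)
    abort("`texture_scale` must be positive.",
          class = "wheattips_invalid_parameter")
  resolve <- function(spec, kind, seed) {
    if (is.character(spec) && length(spec) == 1) {
      if (spec == "standard") {
        return(flat_texture(if (kind == "leaf") c(0.20, 0.45, 0.12)
                            else c(0.42, 0.31, 0.21)))
      }
      if (spec == "procedural") {
        return(if (kind == "leaf") procedural_leaf_texture(seed = seed)
               else procedural_soil_texture(seed = seed))
      }
      img <- png::readPNG(spec)
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      return(img[, , 1:3, drop = FALSE])
    }
    stopifnot(is.numeric(spec), length(dim(spec)) == 3)
    spec
  }
  structure(
    list(leaf = resolve(leaf_texture, "leaf", derive_seed(seed, 11)),
         soil = resolve(soil_texture, "soil", derive_seed(seed, 13)),
         texture_scale = texture_scale),
    class = "texture_set")
}

# Sample a texture at ground coordinates (mm), wrapping periodically.
texture_lookup <- function(tex, scale, x_mm, y_mm) {
  h <- dim(tex)[1]; w <- dim(tex)[2]
  i <- (floor(y_mm / scale) %% h) + 1
  j <- (floor(x_mm / scale) %% w) + 1
  cbind(tex[cbind(i, j, 1)], tex[cbind(i, j, 2)], tex[cbind(i, j, 3)])
}
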