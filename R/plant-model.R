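# Procedural wheat seedling geometry.
#
# A leaf blade is a quadratic Bezier midrib in the vertical plane of the leaf
# azimuth (insertion angle + droop control), swept with a tapering width
# profile: the blade is widest at 30% of the midrib length and tapers linearly
# to zero at the tip, which is the detected feature.

# Evaluate a quadratic Bezier at parameters t (vector) for 3D control points.
bezier3 <- function(t, p0, p1, p2) {
  b0 <- (1 - t)^2; b1 <- 2 * t * (1 - t); b2 <- t^2
  cbind(b0 * p0[1] + b1 * p1[1] + b2 * p2[1],
        b0 * p0[2] + b1 * p1[2] + b2 * p2[2],
        b0 * p0[3] + b1 * p1[3] + b2 * p2[3])
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Relative half-width profile along the blade: 0.5 at the insertion, maximum
# (1) at 30% of the midrib length, linear taper to 0 at the tip.
blade_width_profile <- function(x) {
  ifelse(x <= 0.3, 0.5 + 0.5 * x / 0.3, (1 - x) / 0.7)
}

#' Build a single leaf blade mesh
#'
#' Constructs the triangle mesh of one leaf: a quadratic Bezier midrib leaving
#' the insertion point at `inclination_angle` from the vertical and drooping
#' according to `curvature`, swept by a width profile that reaches its maximum
#' at 30% of the midrib length and tapers to zero at the tip. The midrib
#' polyline length equals `expansion_fraction` times the rank's nominal blade
#' length (exactly, by a final rescale), and the tip point is the last midrib
#' vertex.
#'
#' @param rank Leaf rank (1-based index into the per-rank dimension tables).
#' @param expansion_fraction Fraction of final blade length already expanded,
#'   in (0, 1].
#' @param params A [plant_params()] object.
#' @param azimuth Azimuth of the vertical midrib plane, degrees.
#' @param base Insertion point, 3D (mm).
#' @param n_segments Number of midrib segments of the returned polyline.
#' @return A `leaf_mesh` list with elements `vertices` (n x 3, mm), `faces`
#'   (m x 3, 1-based), `uv` (n x 2 texture coordinates, mm along / across the
#'   blade), `midrib`, `tip_point`, `rank`, `expansion_fraction`, `azimuth`.
#' @export
build_leaf <- function(rank, expansion_fraction, params,
                       azimuth = 0, base = c(0, 0, 0), n_segments = 16) {
  if (rank < 1 || rank > length(params$leaf_length_by_rank))
    abort(sprintf("Rank %d is outside the parameter tables (1..%d).",
                  rank, length(params$leaf_length_by_rank)),
          class = "wheattips_invalid_rank")
  if (expansion_fraction <= 0 || expansion_fraction > 1)
    abort("`expansion_fraction` must lie in (0, 1].",
          class = "wheattips_invalid_parameter")

  L <- params$leaf_length_by_rank[rank]
  wmax <- params$leaf_max_width_by_rank[rank] * expansion_fraction
  phi <- azimuth * pi / 180
  incl <- params$inclination_angle * pi / 180
  droop <- min(incl + params$curvature * pi / 2, 160 * pi / 180)

  dir_at <- function(beta) c(sin(beta) * cos(phi), sin(beta) * sin(phi), cos(beta))
  p0 <- base
  p1 <- base + dir_at(incl) * (L / 2)
  p2 <- p1 + dir_at(droop) * (L / 2)

  # dense sampling, rescale so the full curve has arc length L, truncate at
  # the expanded fraction, then resample at equal arc increments
  tt <- seq(0, 1, length.out = 600)
  dense <- bezier3(tt, p0, p1, p2)
  seglen <- sqrt(rowSums(diff(dense)^2))
  cum <- c(0, cumsum(seglen))
  dense <- sweep(sweep(dense, 2, base, "-") * (L / cum[length(cum)]), 2, base, "+")
  cum <- cum * (L / cum[length(cum)])
  cum[length(cum)] <- L  # guard against one-ulp rounding below L

  s_target <- expansion_fraction * L
  s_grid <- seq(0, s_target, length.out = n_segments + 1)
  midrib <- apply(dense, 2, function(col)
    stats::approx(cum, col, xout = s_grid, rule = 2)$y)
  midrib <- matrix(midrib, ncol = 3)
  # exact midrib polyline length == expansion_fraction * L
  plen <- polyline_length(midrib)
  midrib <- sweep(sweep(midrib, 2, base, "-") * (s_target / plen), 2, base, "+")

  s_arc <- c(0, cumsum(sqrt(rowSums(diff(midrib)^2))))
  S <- s_arc[length(s_arc)]
  half_w <- wmax * blade_width_profile(s_arc / S) / 2
  cross_dir <- c(-sin(phi), cos(phi), 0)

  n_sta <- nrow(midrib) - 1L  # stations with nonzero width; last point is the tip
  V <- matrix(0, 2 * n_sta + 1L, 3)
  UV <- matrix(0, 2 * n_sta + 1L, 2)
  for (i in seq_len(n_sta)) {
    V[2 * i - 1L, ] <- midrib[i, ] - half_w[i] * cross_dir
    V[2 * i, ]      <- midrib[i, ] + half_w[i] * cross_dir
    UV[2 * i - 1L, ] <- c(s_arc[i], 0)
    UV[2 * i, ]      <- c(s_arc[i], 2 * half_w[i])
  }
  V[2 * n_sta + 1L, ] <- midrib[n_sta + 1L, ]
  UV[2 * n_sta + 1L, ] <- c(S, half_w[n_sta])

  F_ <- matrix(0L, 2 * (n_sta - 1L) + 1L, 3)
  for (i in seq_len(n_sta - 1L)) {
    l0 <- 2L * i - 1L; r0 <- 2L * i; l1 <- 2L * i + 1L; r1 <- 2L * i + 2L
    F_[2 * i - 1L, ] <- c(l0, r0, r1)
    F_[2 * i, ]      <- c(l0, r1, l1)
  }
  F_[nrow(F_), ] <- c(2L * n_sta - 1L, 2L * n_sta, 2L * n_sta + 1L)

  structure(
    list(vertices = V, faces = F_, uv = UV, midrib = midrib,
         tip_point = midrib[nrow(midrib), ], rank = as.integer(rank),
         expansion_fraction = expansion_fraction, azimuth = azimuth),
    class = "leaf_mesh")
}

#' Build a wheat seedling at a given thermal time
#'
#' The Haun stage H = thermal_time / phyllochron sets the leaf census:
#' `floor(H)` fully expanded leaves plus one leaf at expansion `H - floor(H)`
#' when H is fractional (so `ceiling(H)` leaves in total). Successive leaf
#' azimuths alternate by 180 degrees plus Gaussian phyllotactic jitter.
#' Tillers (smaller secondary shoots sharing the plant base) are added only
#' when H has reached `tiller_onset_haun` and `tiller_number > 0`.
#'
#' Uses the current R random number stream for the azimuth jitter; seed the
#' stream (or call via [build_canopy()]) for reproducibility.
#'
#' @param thermal_time Cumulative thermal time (degree-days, >= 0).
#' @param params A [plant_params()] object.
#' @param base_position 3D insertion point of the plant base (mm, on the soil
#'   plane so `base_position[3] == 0`).
#' @param plant_id Integer identifier carried into annotations.
#' @param base_azimuth First-leaf azimuth (degrees); drawn uniformly when `NA`.
#' @return A `wheat_plant` list with elements `leaves` (list of `leaf_mesh`,
#'   main stem then tillers), `base_position`, `haun_stage`, `plant_id`.
#'   Main-stem leaves have `tiller = 0L`; tiller leaves `tiller >= 1L`.
#' @export
build_plant <- function(thermal_time, params, base_position = c(0, 0, 0),
                        plant_id = 1L, base_azimuth = NA) {
  H <- haun_stage(thermal_time, params$phyllochron)
  if (is.na(base_azimuth)) base_azimuth <- runif(1, 0, 360)
  n_leaves <- ceiling(H)
  max_rank <- length(params$leaf_length_by_rank)

  grow_shoot <- function(H_shoot, shoot_params, az0, tiller_idx) {
    n <- ceiling(H_shoot)
    out <- vector("list", n)
    for (k in seq_len(n)) {
      expansion <- if (k <= floor(H_shoot)) 1 else H_shoot - floor(H_shoot)
      az <- az0 + (k - 1) * 180 + rnorm(1, 0, shoot_params$phyllotaxy_jitter)
      ins <- base_position + c(0, 0, 1.5 * (k - 1))
      leaf <- build_leaf(min(k, max_rank), expansion, shoot_params,
                         azimuth = az, base = ins)
      leaf$tiller <- as.integer(tiller_idx)
      out[[k]] <- leaf
    }
    out
  }

  leaves <- grow_shoot(H, params, base_azimuth, 0L)

  if (H >= params$tiller_onset_haun && params$tiller_number > 0) {
    tp <- params
    tp$leaf_length_by_rank <- params$leaf_length_by_rank * 0.6
    tp$leaf_max_width_by_rank <- params$leaf_max_width_by_rank * 0.6
    H_t <- max(H - params$tiller_onset_haun + 1, 0.5)
    for (j in seq_len(params$tiller_number)) {
      az_t <- base_azimuth + 90 + runif(1, -30, 30) + (j - 1) * 180
      leaves <- c(leaves, grow_shoot(H_t, tp, az_t, j))
    }
  }

  structure(
    list(leaves = leaves, base_position = base_position,
         haun_stage = H, plant_id = as.integer(plant_id)),
    class = "wheat_plant")
}

#' Assemble a canopy scene from a field configuration
#'
#' Places `round(sowing_density * plot area)` plants on rows spaced
#' `row_spacing` apart, with Gaussian positional jitter, all at the thermal
#' time of the field configuration. Fully deterministic given the field seed.
#'
#' @param field A [field_config()] object.
#' @param params A [plant_params()] object shared by all plants.
#' @return A `canopy_scene` list: `plants`, `plot` (width, depth in mm),
#'   `thermal_time`, `mean_haun`, `seed`, `params`.
#' @examples
#' sc <- build_canopy(field_config(seed = 7), plant_params())
#' length(sc$plants)
#' @export
build_canopy <- function(field, params) {
  set.seed(field$seed)
  area_m2 <- field$plot_width * field$plot_depth / 1e6
  n <- round(field$sowing_density * area_m2)
  if (n < 1) {
    warn("Plot too small for one plant at this density; returning an empty scene.",
         class = "wheattips_empty_scene")
    plants <- list()
  } else {
    n_rows <- max(1L, floor(field$plot_depth / field$row_spacing))
    row_of <- (seq_len(n) - 1L) %% n_rows + 1L
    plants <- vector("list", n)
    for (i in seq_len(n)) {
      r <- row_of[i]
      in_row <- which(row_of == r)
      k <- match(i, in_row)
      x0 <- (k - 0.5) * field$plot_width / length(in_row)
      y0 <- (r - 0.5) * field$plot_depth / n_rows
      if (field$position_jitter_sd > 0) {
        x0 <- x0 + rnorm(1, 0, field$position_jitter_sd)
        y0 <- y0 + rnorm(1, 0, field$position_jitter_sd)
      }
      x0 <- min(max(x0, 0), field$plot_width)
      y0 <- min(max(y0, 0), field$plot_depth)
      plants[[i]] <- build_plant(field$thermal_time, params,
                                 base_position = c(x0, y0, 0), plant_id = i)
    }
  }
  structure(
    list(plants = plants, plot = c(field$plot_width, field$plot_depth),
         thermal_time = field$thermal_time,
         mean_haun = if (n >= 1) mean(map_dbl(plants, "haun_stage")) else NA_real_,
         seed = field$seed, params = params),
    class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene> %d plants on a %.0f x %.0f mm plot, mean Haun %.2f\n",
              length(x$plants), x$plot[1], x$plot[2], x$mean_haun))
  invisible(x)
}

# Flatten a scene into a single triangle soup with global leaf ids.
# Returns vertices V, faces F (1-based), per-face owner (global leaf id),
# per-vertex UV, and the tip table.
scene_mesh <- function(scene) {
  Vs <- list(); Fs <- list(); owners <- list(); UVs <- list()
  tips <- list()
  offset <- 0L
  leaf_id <- 0L
  for (p in scene$plants) {
    for (leaf in p$leaves) {
      leaf_id <- leaf_id + 1L
      Vs[[leaf_id]] <- leaf$vertices
      UVs[[leaf_id]] <- leaf$uv
      Fs[[leaf_id]] <- leaf$faces + offset
      owners[[leaf_id]] <- rep(leaf_id, nrow(leaf$faces))
      tips[[leaf_id]] <- tibble(
        leaf_id = leaf_id, plant_id = p$plant_id, leaf_rank = leaf$rank,
        tiller = leaf$tiller %||% 0L,
        x = leaf$tip_point[1], y = leaf$tip_point[2], z = leaf$tip_point[3])
      offset <- offset + nrow(leaf$vertices)
    }
  }
  if (leaf_id == 0L) {
    return(list(V = matrix(0, 0, 3), F = matrix(0L, 0, 3),
                owner = integer(0), UV = matrix(0, 0, 2),
                tips = tibble(leaf_id = integer(), plant_id = integer(),
                              leaf_rank = integer(), tiller = integer(),
                              x = double(), y = double(), z = double())))
  }
  list(V = do.call(rbind, Vs), F = do.call(rbind, Fs),
       owner = unlist(owners), UV = do.call(rbind, UVs),
       tips = bind_rows(tips))
}

#' Count the leaves of every plant in a scene
#'
#' @param scene A `canopy_scene`.
#' @return A tibble with one row per plant: `plant_id`, `haun_stage`,
#'   `n_leaves`.
#' @export
scene_leaf_census <- function(scene) {
  bind_rows(map(scene$plants, function(p)
    tibble(plant_id = p$plant_id, haun_stage = p$haun_stage,
           n_leaves = length(p$leaves))))
}

#' Export a canopy scene as a Wavefront OBJ mesh
#'
#' Writes all leaf triangles (grouped per leaf) plus the soil rectangle for
#' inspection in any mesh viewer.
#'
#' @param scene A `canopy_scene`.
#' @param path Output `.obj` path.
#' @return `path`, invisibly.
#' @export
write_scene_obj <- function(scene, path) {
  m <- scene_mesh(scene)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wheattips canopy scene", con)
  w <- scene$plot[1]; d <- scene$plot[2]
  soil <- rbind(c(0, 0, 0), c(w, 0, 0), c(w, d, 0), c(0, d, 0))
  for (i in seq_len(nrow(soil)))
    writeLines(sprintf("v %.4f %.4f %.4f", soil[i, 1], soil[i, 2], soil[i, 3]), con)
  if (nrow(m$V) > 0)
    writeLines(sprintf("v %.4f %.4f %.4f", m$V[, 1], m$V[, 2], m$V[, 3]), con)
  writeLines("g soil", con)
  writeLines(c("f 1 2 3", "f 1 3 4"), con)
  if (nrow(m$F) > 0) {
    writeLines("g leaves", con)
    Fo <- m$F + 4L
    writeLines(sprintf("f %d %d %d", Fo[, 1], Fo[, 2], Fo[, 3]), con)
  }
  invisible(path)
}
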