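# Independent oracles and fixture builders shared across tests. These are
# deliberately written without using the package's rendering/matching code
# paths they check.

# --- vectorized Moller-Trumbore any-hit oracle -------------------------------
# Is the ray origin + t*dir blocked by any triangle with t in (tmin, tmax)?
oracle_ray_blocked <- function(orig, dir, V, F_, tmax, tmin = 0.5,
                               tmax_margin = 0.5) {
  if (nrow(F_) == 0) return(FALSE)
  A <- V[F_[, 1], , drop = FALSE]
  E1 <- V[F_[, 2], , drop = FALSE] - A
  E2 <- V[F_[, 3], , drop = FALSE] - A
  hx <- dir[2] * E2[, 3] - dir[3] * E2[, 2]
  hy <- dir[3] * E2[, 1] - dir[1] * E2[, 3]
  hz <- dir[1] * E2[, 2] - dir[2] * E2[, 1]
  det <- E1[, 1] * hx + E1[, 2] * hy + E1[, 3] * hz
  ok <- abs(det) > 1e-12
  sx <- orig[1] - A[, 1]; sy <- orig[2] - A[, 2]; sz <- orig[3] - A[, 3]
  u <- (sx * hx + sy * hy + sz * hz) / det
  qx <- sy * E1[, 3] - sz * E1[, 2]
  qy <- sz * E1[, 1] - sx * E1[, 3]
  qz <- sx * E1[, 2] - sy * E1[, 1]
  v <- (dir[1] * qx + dir[2] * qy + dir[3] * qz) / det
  t <- (E2[, 1] * qx + E2[, 2] * qy + E2[, 3] * qz) / det
  any(ok & u >= 0 & u <= 1 & v >= 0 & u + v <= 1 &
        t > tmin & t < tmax - tmax_margin)
}

# --- homogeneous-matrix pinhole projection oracle ----------------------------
oracle_project <- function(p, camera) {
  zen <- camera$view_zenith * pi / 180
  az <- camera$view_azimuth * pi / 180
  horiz <- camera$height * tan(zen)
  pos <- c(camera$look_at[1] - horiz * cos(az),
           camera$look_at[2] - horiz * sin(az), camera$height)
  fwd <- c(camera$look_at[1], camera$look_at[2], 0) - pos
  fwd <- fwd / sqrt(sum(fwd^2))
  up <- if (abs(fwd[3]) > 0.999) c(0, 1, 0) else c(0, 0, 1)
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  right <- right / sqrt(sum(right^2))
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  fx <- (camera$sensor_width_px / 2) / tan(camera$horizontal_fov * pi / 360)
  # 4x4 homogeneous world -> clip pipeline, assembled independently
  Rt <- rbind(cbind(rbind(right, down, fwd), -rbind(right, down, fwd) %*% pos),
              c(0, 0, 0, 1))
  K <- rbind(c(fx, 0, camera$sensor_width_px / 2, 0),
             c(0, fx, camera$sensor_height_px / 2, 0),
             c(0, 0, 1, 0))
  q <- K %*% Rt %*% c(p, 1)
  c(u = q[1] / q[3], v = q[2] / q[3])
}

# --- brute-force maximum bipartite matching (augmenting paths) ---------------
# adj: logical matrix (detections x ground truths), TRUE where IoU > thr.
oracle_max_matching <- function(adj) {
  nd <- nrow(adj); ng <- ncol(adj)
  match_gt <- rep(0L, ng)
  try_det <- function(i, seen) {
    for (j in seq_len(ng)) {
      if (adj[i, j] && !seen[j]) {
        seen[j] <- TRUE
        if (match_gt[j] == 0L || Recall(match_gt[j], seen)) {
          match_gt[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_len(nd)) if (try_det(i, rep(FALSE, ng))) n <- n + 1L
  n
}

# --- brute-force point-in-triangle coverage scan -----------------------------
oracle_triangle_coverage <- function(su, sv, W, H) {
  covered <- matrix(FALSE, H, W)
  D <- (sv[2] - sv[3]) * (su[1] - su[3]) + (su[3] - su[2]) * (sv[1] - sv[3])
  for (v in 0:(H - 1)) for (u in 0:(W - 1)) {
    l1 <- ((sv[2] - sv[3]) * (u - su[3]) + (su[3] - su[2]) * (v - sv[3])) / D
    l2 <- ((sv[3] - sv[1]) * (u - su[3]) + (su[1] - su[3]) * (v - sv[3])) / D
    l3 <- 1 - l1 - l2
    covered[v + 1, u + 1] <- l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9
  }
  covered
}

# --- fixture builders --------------------------------------------------------
single_plant_scene <- function(seed, thermal_time,
                               params = plant_params(phyllotaxy_jitter = 12)) {
  set.seed(seed)
  pl <- build_plant(thermal_time, params, base_position = c(0, 0, 0),
                    plant_id = 1L)
  structure(list(plants = list(pl), plot = c(400, 400),
                 thermal_time = thermal_time, mean_haun = pl$haun_stage,
                 seed = seed, params = params),
            class = "canopy_scene")
}

# A custom scene from hand-built leaf meshes (e.g. occluding panels).
scene_from_leaves <- function(leaves, plot = c(400, 400)) {
  plants <- lapply(seq_along(leaves), function(i) {
    structure(list(leaves = leaves[i], base_position = c(0, 0, 0),
                   haun_stage = 1, plant_id = i), class = "wheat_plant")
  })
  structure(list(plants = plants, plot = plot, thermal_time = 100,
                 mean_haun = 1, seed = 0, params = plant_params()),
            class = "canopy_scene")
}

# A rectangular horizontal "leaf" panel at height z spanning [x0,x1]x[y0,y1],
# shaped like the package's leaf meshes.
panel_leaf <- function(x0, x1, y0, y1, z, rank = 1L) {
  V <- rbind(c(x0, y0, z), c(x1, y0, z), c(x1, y1, z), c(x0, y1, z))
  F_ <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  structure(list(vertices = V, faces = F_,
                 uv = cbind(c(0, x1 - x0, x1 - x0, 0), c(0, 0, y1 - y0, y1 - y0)),
                 midrib = rbind(c(x0, (y0 + y1) / 2, z), c(x1, (y0 + y1) / 2, z)),
                 tip_point = c(x1, (y0 + y1) / 2, z),
                 rank = rank, expansion_fraction = 1, azimuth = 0,
                 tiller = 0L),
            class = "leaf_mesh")
}

nadir_camera <- function(gsd = 1.5, px = 256, look_at = c(0, 0, 0)) {
  camera_for_gsd(gsd, view_zenith = 0, fov = 40, sensor_width_px = px,
                 look_at = look_at)
}

flat_light <- function() light_config(diffuse_fraction = 1, cast_shadows = FALSE)

# Render a small image set for gap experiments (geometry varies with seed;
# lighting varies only when vary_light).
gap_image_set <- function(seed, n = 20, vary_light = FALSE, px = 160) {
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seed + i)
    f <- field_config(thermal_time = runif(1, 100, 350), seed = seed + i,
                      plot_width = 250, plot_depth = 250,
                      sowing_density = runif(1, 100, 300))
    sc <- build_canopy(f, plant_params())
    cam <- camera_for_gsd(1.2, view_zenith = 45, fov = 40,
                          sensor_width_px = px, look_at = c(125, 125, 0))
    li <- if (vary_light) {
      set.seed(seed + 1000 + i)
      light_config(sun_zenith = runif(1, 15, 60),
                   sun_azimuth = runif(1, 0, 360),
                   diffuse_fraction = runif(1, 0.2, 0.7),
                   cast_shadows = TRUE)
    } else flat_light()
    frames[[i]] <- render_scene(sc, cam, li, texture_set(), aa_factor = 1)$rgb
  }
  frames
}
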