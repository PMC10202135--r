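# Pinhole viewing geometry and illumination configuration.

#' Camera configuration
#'
#' A pinhole camera above the soil plane. The default preset mimics a
#' field-phenotyping rig: 45 degree view zenith at 1.8 m height with a
#' 5472 x 3648 px sensor.
#'
#' @param height Camera height above the soil plane (mm, > 0).
#' @param view_zenith Tilt from the vertical in degrees, within \[0, 60\];
#'   0 is nadir.
#' @param view_azimuth Azimuth of the viewing direction (degrees).
#' @param horizontal_fov Horizontal field of view (degrees, in (1, 120)).
#' @param sensor_width_px,sensor_height_px Sensor size in pixels (>= 16).
#' @param look_at Point on the soil plane the camera looks at (mm, z = 0).
#' @return A `camera_config` object.
#' @export
camera_config <- function(height = 1800, view_zenith = 45, view_azimuth = 0,
                          horizontal_fov = 40,
                          sensor_width_px = 5472, sensor_height_px = 3648,
                          look_at = c(0, 0, 0)) {
  if (height <= 0)
    abort("`height` must be positive.", class = "wheattips_invalid_parameter")
  if (view_zenith < 0 || view_zenith > 60)
    abort("`view_zenith` must lie in [0, 60] degrees.",
          class = "wheattips_invalid_parameter")
  if (horizontal_fov <= 1 || horizontal_fov >= 120)
    abort("`horizontal_fov` must lie in (1, 120) degrees.",
          class = "wheattips_invalid_parameter")
  if (sensor_width_px < 16 || sensor_height_px < 16)
    abort("Sensor must be at least 16 px in each dimension.",
          class = "wheattips_invalid_parameter")
  structure(
    list(height = height, view_zenith = view_zenith,
         view_azimuth = view_azimuth, horizontal_fov = horizontal_fov,
         sensor_width_px = as.integer(sensor_width_px),
         sensor_height_px = as.integer(sensor_height_px),
         look_at = c(look_at[1], look_at[2], 0)),
    class = "camera_config")
}

#' Illumination configuration
#'
#' Direct sunlight plus an isotropic diffuse sky term. `diffuse_fraction = 1`
#' is the fully diffuse (overcast) limit in which shadows vanish.
#'
#' @param sun_zenith,sun_azimuth Sun direction in degrees.
#' @param diffuse_fraction Share of irradiance arriving isotropically, in
#'   \[0, 1\].
#' @param cast_shadows Should direct light be blocked by leaf geometry?
#' @return A `light_config` object.
#' @export
light_config <- function(sun_zenith = 35, sun_azimuth = 120,
                         diffuse_fraction = 1, cast_shadows = TRUE) {
  if (diffuse_fraction < 0 || diffuse_fraction > 1)
    abort("`diffuse_fraction` must lie in [0, 1].",
          class = "wheattips_invalid_parameter")
  structure(
    list(sun_zenith = sun_zenith, sun_azimuth = sun_azimuth,
         diffuse_fraction = diffuse_fraction,
         cast_shadows = isTRUE(cast_shadows)),
    class = "light_config")
}

# Camera centre and world->camera rotation (rows: right, down, forward).
# Image u grows rightward, v downward; pixel centres at integer coordinates.
camera_basis <- function(camera) {
  zen <- camera$view_zenith * pi / 180
  az <- camera$view_azimuth * pi / 180
  horiz <- camera$height * tan(zen)
  pos <- c(camera$look_at[1] - horiz * cos(az),
           camera$look_at[2] - horiz * sin(az),
           camera$height)
  fwd <- camera$look_at + c(0, 0, 0) - pos
  fwd <- fwd / sqrt(sum(fwd^2))
  up_hint <- if (abs(fwd[3]) > 0.999) c(0, 1, 0) else c(0, 0, 1)
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  right <- cx(fwd, up_hint)
  right <- right / sqrt(sum(right^2))
  down <- cx(fwd, right)
  R <- rbind(right, down, fwd)
  dimnames(R) <- NULL
  list(pos = pos, R = R)
}

camera_intrinsics <- function(camera) {
  W <- camera$sensor_width_px; H <- camera$sensor_height_px
  fx <- (W / 2) / tan(camera$horizontal_fov * pi / 360)
  list(fx = fx, fy = fx, cx = W / 2, cy = H / 2, W = W, H = H)
}

#' Nominal centre ground sampling distance of a camera
#'
#' GSD = 2 (height / cos(zenith)) tan(fov / 2) / sensor_width_px, i.e. the
#' ground footprint of one pixel at the image centre along the horizontal
#' sensor axis (mm per pixel).
#'
#' @param camera A [camera_config()].
#' @return GSD in mm per pixel.
#' @export
camera_gsd <- function(camera) {
  2 * (camera$height / cos(camera$view_zenith * pi / 180)) *
    tan(camera$horizontal_fov * pi / 360) / camera$sensor_width_px
}

#' Camera achieving a target ground sampling distance
#'
#' Solves the centre-GSD relation for the camera height, the mechanism used to
#' sweep spatial resolution: GSD = 2 (h / cos(zenith)) tan(fov/2) / width_px.
#'
#' @param target_gsd Desired centre GSD (mm per pixel, > 0).
#' @param view_zenith View zenith angle (degrees).
#' @param fov Horizontal field of view (degrees).
#' @param sensor_width_px,sensor_height_px Sensor size (px).
#' @param look_at Ground point the camera looks at.
#' @param view_azimuth Viewing azimuth (degrees).
#' @return A [camera_config()] whose [camera_gsd()] equals `target_gsd`.
#' @examples
#' camera_for_gsd(0.3, view_zenith = 45, fov = 40, sensor_width_px = 1024)
#' @export
camera_for_gsd <- function(target_gsd, view_zenith = 0, fov = 40,
                           sensor_width_px = 1024,
                           sensor_height_px = sensor_width_px,
                           look_at = c(0, 0, 0), view_azimuth = 0) {
  if (target_gsd <= 0)
    abort("`target_gsd` must be positive.",
          class = "wheattips_invalid_parameter")
  height <- target_gsd * sensor_width_px * cos(view_zenith * pi / 180) /
    (2 * tan(fov * pi / 360))
  if (height <= 0)
    abort("Unreachable GSD: solved camera height is not positive.",
          class = "wheattips_invalid_parameter")
  camera_config(height = height, view_zenith = view_zenith,
                view_azimuth = view_azimuth, horizontal_fov = fov,
                sensor_width_px = sensor_width_px,
                sensor_height_px = sensor_height_px, look_at = look_at)
}

#' Project world points into the image
#'
#' Standard pinhole projection. Returned coordinates are sub-pixel reals in
#' the convention: origin top-left, pixel centres at integer coordinates,
#' u rightward, v downward. Depth is the Euclidean distance from the camera
#' centre (the distance along the view ray).
#'
#' @param p A 3-vector or an n x 3 matrix of world points (mm).
#' @param camera A [camera_config()].
#' @return A tibble with columns `u`, `v` (px) and `d` (mm).
#' @export
project_point <- function(p, camera) {
  if (is.null(dim(p))) p <- matrix(p, 1, 3)
  cb <- camera_basis(camera)
  K <- camera_intrinsics(camera)
  rel <- sweep(p, 2, cb$pos, "-")
  camc <- rel %*% t(cb$R)
  if (any(camc[, 3] <= 1e-9))
    abort("Point at or behind the camera plane.",
          class = "wheattips_behind_camera")
  tibble(u = K$cx + K$fx * camc[, 1] / camc[, 3],
         v = K$cy + K$fy * camc[, 2] / camc[, 3],
         d = sqrt(rowSums(rel^2)))
}

# Unit vector pointing from the scene toward the sun.
sun_vector <- function(light) {
  zen <- light$sun_zenith * pi / 180
  az <- light$sun_azimuth * pi / 180
  c(sin(zen) * cos(az), sin(zen) * sin(az), cos(zen))
}
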