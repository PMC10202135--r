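#' Architectural parameters of a wheat seedling
#'
#' Bundles the plant-level parameters that drive the procedural seedling
#' generator: the phyllochron (thermal time between the appearance of two
#' consecutive leaves), per-rank blade dimensions, insertion inclination,
#' midrib droop, phyllotactic jitter, and tillering controls.
#'
#' @param phyllochron Thermal time per leaf appearance (degree-days per leaf);
#'   must be positive. Default 100.
#' @param leaf_length_by_rank Numeric vector of final blade lengths (mm) for
#'   ranks 1, 2, ...; all positive.
#' @param leaf_max_width_by_rank Numeric vector of maximum blade widths (mm),
#'   same length as `leaf_length_by_rank`; all positive.
#' @param inclination_angle Angle of the midrib at insertion, measured from the
#'   vertical, in degrees within \[0, 90\].
#' @param curvature Dimensionless droop coefficient (>= 0) controlling how far
#'   the midrib bends away from its insertion direction toward the horizontal
#'   and beyond; 0 gives a straight blade.
#' @param phyllotaxy_jitter Standard deviation (degrees) of the azimuth
#'   deviation from strict 180 degree alternation between successive leaves.
#' @param tiller_onset_haun Haun stage from which tillers may appear.
#' @param tiller_number Number of tillers once tillering has started (>= 0).
#'   Default 0: the seedling stages targeted here are before tillering.
#'
#' @return An object of class `plant_params` (a validated list).
#' @examples
#' p <- plant_params()
#' p$phyllochron
#' @export
plant_params <- function(phyllochron = 100,
                         leaf_length_by_rank = c(70, 100, 130, 155, 175, 190),
                         leaf_max_width_by_rank = c(4, 5, 6, 7, 8, 9),
                         inclination_angle = 40,
                         curvature = 0.4,
                         phyllotaxy_jitter = 12,
                         tiller_onset_haun = 4,
                         tiller_number = 0) {
  if (!is.numeric(phyllochron) || length(phyllochron) != 1 || phyllochron <= 0)
    abort("`phyllochron` must be a single positive number.",
          class = "wheattips_invalid_parameter")
  if (any(leaf_length_by_rank <= 0) || any(leaf_max_width_by_rank <= 0))
    abort("Leaf lengths and widths must all be positive.",
          class = "wheattips_invalid_parameter")
  if (length(leaf_length_by_rank) != length(leaf_max_width_by_rank))
    abort("Length and width tables must cover the same ranks.",
          class = "wheattips_invalid_parameter")
  if (inclination_angle < 0 || inclination_angle > 90)
    abort("`inclination_angle` must lie in [0, 90] degrees.",
          class = "wheattips_invalid_parameter")
  if (curvature < 0)
    abort("`curvature` must be >= 0.", class = "wheattips_invalid_parameter")
  if (tiller_number < 0)
    abort("`tiller_number` must be >= 0.", class = "wheattips_invalid_parameter")
  structure(
    list(phyllochron = phyllochron,
         leaf_length_by_rank = as.numeric(leaf_length_by_rank),
         leaf_max_width_by_rank = as.numeric(leaf_max_width_by_rank),
         inclination_angle = inclination_angle,
         curvature = curvature,
         phyllotaxy_jitter = phyllotaxy_jitter,
         tiller_onset_haun = tiller_onset_haun,
         tiller_number = tiller_number),
    class = "plant_params")
}

#' Field and sowing configuration for canopy assembly
#'
#' @param sowing_density Plants per square metre (> 0).
#' @param row_spacing Distance between sowing rows (mm, > 0).
#' @param plot_width,plot_depth Extent of the simulated plot (mm, > 0);
#'   width runs along rows (x), depth across rows (y).
#' @param position_jitter_sd Standard deviation of the Gaussian positional
#'   jitter of each plant around its grid position (mm, >= 0).
#' @param thermal_time Cumulative thermal time since emergence (degree-days,
#'   >= 0); together with the phyllochron it sets the Haun stage.
#' @param seed Integer seed making the canopy draw reproducible.
#'
#' @return An object of class `field_config`.
#' @export
field_config <- function(sowing_density = 250,
                         row_spacing = 100,
                         plot_width = 400,
                         plot_depth = 300,
                         position_jitter_sd = 5,
                         thermal_time = 250,
                         seed = 1L) {
  spatial <- c(sowing_density, row_spacing, plot_width, plot_depth)
  if (any(spatial <= 0))
    abort("Density, spacing and plot dimensions must be positive.",
          class = "wheattips_invalid_parameter")
  if (position_jitter_sd < 0 || thermal_time < 0)
    abort("`position_jitter_sd` and `thermal_time` must be >= 0.",
          class = "wheattips_invalid_parameter")
  structure(
    list(sowing_density = sowing_density, row_spacing = row_spacing,
         plot_width = plot_width, plot_depth = plot_depth,
         position_jitter_sd = position_jitter_sd,
         thermal_time = thermal_time, seed = as.integer(seed)),
    class = "field_config")
}

#' Haun stage from thermal time
#'
#' The Haun stage counts the fully expanded leaves on the main stem, with
#' fractional values for a partially expanded youngest leaf. Under a constant
#' phyllochron it is simply the ratio of cumulative thermal time to the
#' phyllochron.
#'
#' @param thermal_time Cumulative thermal time since emergence (degree-days,
#'   >= 0).
#' @param phyllochron Thermal time per leaf (degree-days, > 0).
#' @return The Haun stage (real, >= 0). Vectorised over `thermal_time`.
#' @examples
#' haun_stage(250, 100) # 2.5
#' @export
haun_stage <- function(thermal_time, phyllochron) {
  if (!is.numeric(phyllochron) || any(phyllochron <= 0))
    abort("`phyllochron` must be positive.",
          class = "wheattips_invalid_parameter")
  if (any(thermal_time < 0))
    abort("`thermal_time` must be >= 0.",
          class = "wheattips_invalid_parameter")
  thermal_time / phyllochron
}
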