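# Latin hypercube sampling of the simulator parameter space.

#' Default parameter ranges for the canopy simulator
#'
#' Reads the editable range table shipped with the package
#' (`inst/extdata/default_ranges.yaml`). Each entry maps a parameter name to
#' a `[lo, hi]` interval: first-rank blade length (mm), a per-rank length
#' growth factor, maximum blade width (mm), insertion inclination (degrees),
#' midrib curvature, sowing density (plants per square metre), phyllochron
#' (degree-days) and thermal time (degree-days, i.e. the development stage).
#'
#' @param path Optional path to a user YAML file with the same layout.
#' @return A named list of two-element numeric ranges.
#' @export
default_parameter_ranges <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_ranges.yaml", package = "wheattips")
  rng <- yaml::read_yaml(path)
  lapply(rng, as.numeric)
}

#' Latin hypercube sample of a parameter space
#'
#' Draws `n` parameter sets such that, for every parameter, the `n` sampled
#' values occupy `n` distinct equal-width strata of its range (the Latin
#' hypercube property). Deterministic given `seed`.
#'
#' @param n Number of parameter sets (>= 1).
#' @param ranges Named list of `c(lo, hi)` ranges with `lo < hi`, e.g.
#'   [default_parameter_ranges()].
#' @param seed Integer seed.
#' @return A tibble with `n` rows, one column per parameter, plus `set_id`.
#' @examples
#' sample_parameter_sets(4, list(inclination = c(20, 70)), seed = 1)
#' @export
sample_parameter_sets <- function(n, ranges = default_parameter_ranges(),
                                  seed = 1L) {
  if (length(ranges) == 0)
    abort("`ranges` must contain at least one parameter.",
          class = "wheattips_invalid_parameter")
  if (n < 1) abort("`n` must be >= 1.", class = "wheattips_invalid_parameter")
  bad <- names(ranges)[map_dbl(ranges, function(r) r[2] - r[1]) <= 0]
  if (length(bad) > 0)
    abort(sprintf("Ranges must satisfy lo < hi (violated by: %s).",
                  paste(bad, collapse = ", ")),
          class = "wheattips_invalid_parameter")
  set.seed(seed)
  U <- lhs::randomLHS(n, length(ranges))
  out <- as_tibble(setNames(
    lapply(seq_along(ranges), function(j) {
      r <- ranges[[j]]
      r[1] + U[, j] * (r[2] - r[1])
    }),
    names(ranges)))
  mutate(out, set_id = seq_len(n), .before = 1)
}

#' Turn one sampled parameter row into simulator configurations
#'
#' Maps a row of [sample_parameter_sets()] onto a [plant_params()] /
#' [field_config()] pair. Per-rank blade lengths follow a geometric
#' progression from `leaf_length_rank1` with ratio `leaf_length_growth`,
#' capped at 200 mm; widths scale with length.
#'
#' @param row A one-row data frame (or named list) of sampled parameters.
#' @param n_ranks Number of leaf ranks to tabulate.
#' @param seed Seed stored in the field configuration.
#' @param plot_width,plot_depth Plot extent (mm).
#' @return A list with elements `params` and `field`.
#' @export
params_from_sample <- function(row, n_ranks = 6, seed = 1L,
                               plot_width = 400, plot_depth = 300) {
  g <- function(name, default) {
    v <- row[[name]]
    if (is.null(v) || is.na(v)) default else as.numeric(v)
  }
  len1 <- g("leaf_length_rank1", 70)
  growth <- g("leaf_length_growth", 1.3)
  lengths <- pmin(len1 * growth^(seq_len(n_ranks) - 1), 200)
  widths <- pmax(g("leaf_width_max", 6) * lengths / max(lengths), 2)
  params <- plant_params(
    phyllochron = g("phyllochron", 100),
    leaf_length_by_rank = lengths,
    leaf_max_width_by_rank = widths,
    inclination_angle = g("inclination", 40),
    curvature = g("curvature", 0.4),
    phyllotaxy_jitter = g("phyllotaxy_jitter", 12))
  field <- field_config(
    sowing_density = g("sowing_density", 250),
    row_spacing = g("row_spacing", 100),
    plot_width = plot_width, plot_depth = plot_depth,
    position_jitter_sd = g("position_jitter_sd", 5),
    thermal_time = g("thermal_time", 250),
    seed = seed)
  list(params = params, field = field)
}
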