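#' Read a full analysis configuration from YAML
#'
#' Parses the optional YAML configuration shared by the command-line entry
#' points. Recognised sections (all optional, all keys defaulted):
#' `field` (`length_m`, `width_m`, `arc_radius_m`), `clustering` (`eps`,
#' `min_additional`), `features` (`immediate`, `extended`, `quadrant`,
#' `available_space` radii) and `rf` (`n_trees`, `max_depth`, `min_split`,
#' `min_leaf`, `train_fraction`, `seed`).
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return List with components `field`, `clustering`, `radii`, `rf`.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  f <- cfg$field %||% list()
  cl <- cfg$clustering %||% list()
  fe <- cfg$features %||% list()
  rf <- cfg$rf %||% list()
  list(
    field = field_spec(
      length_m = f$length_m %||% 159.5,
      width_m = f$width_m %||% 128.8,
      arc_radius_m = f$arc_radius_m %||% 50
    ),
    clustering = clustering_params(
      eps = cl$eps %||% 7.5,
      min_additional = cl$min_additional %||% 3L
    ),
    radii = feature_radii(
      immediate = fe$immediate %||% 5,
      extended = fe$extended %||% 10,
      quadrant = fe$quadrant %||% 10,
      available_space = fe$available_space %||% 10
    ),
    rf = rf_config(
      n_trees = rf$n_trees %||% 500L,
      max_depth = rf$max_depth %||% 10L,
      min_split = rf$min_split %||% 50L,
      min_leaf = rf$min_leaf %||% 5L,
      train_fraction = rf$train_fraction %||% 0.8,
      seed = rf$seed %||% 1L
    )
  )
}
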