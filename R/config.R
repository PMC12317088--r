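# YAML/JSON run configuration for the command-line interface. Precedence:
# command-line flags override config-file values override package
# defaults; the effective values are echoed into the transform JSON.

#' Default run configuration
#'
#' @return A named list of all pipeline options with their defaults.
#' @export
default_run_config <- function() {
  list(
    window = 32L, layers = 4L, min_distance = 16, max_features = 500L,
    ratio = 0.75, threshold = 3, iterations = 2000L, seed = 0L,
    preprocess = TRUE, clip_quantile = 0.99, rotate_moving = 0L,
    polarity = "auto", embedding = "mean", bins = 32L, pixel_size = 1.0
  )
}

#' Read a YAML or JSON run configuration
#'
#' Unknown keys raise a configuration error; missing keys fall back to
#' [default_run_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   pure defaults.
#' @param overrides Named list applied on top of the file values (e.g.
#'   parsed command-line flags).
#' @return The merged configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
    ext <- tolower(tools::file_ext(path))
    vals <- switch(ext,
      yaml = ,
      yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop_config(sprintf("config must be YAML or JSON, got '.%s'", ext))
    )
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown) > 0L) {
      stop_config(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
    }
    cfg[names(vals)] <- vals
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1L))]
  cfg[names(overrides)] <- overrides
  cfg
}

#' Pyramid config from a run configuration
#'
#' @param cfg A list from [read_run_config()].
#' @return A [pyramid_config()].
#' @export
run_config_pyramid <- function(cfg) {
  pyramid_config(window = cfg$window, layers = cfg$layers,
                 min_distance = cfg$min_distance,
                 max_features = cfg$max_features)
}
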