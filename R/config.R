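#' Read a pipeline configuration file
#'
#' The whole analysis is driven by one YAML file with top-level keys
#' `dataset`, `variables`, `distance`, `reduction`, `clustering`,
#' `archetypes`, `seed`, `palette` and `output_dir`. Relative paths are
#' resolved against the directory containing the config file, so a config
#' can ship next to its data.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list with a validated spec table in
#'   `$specs`.
#' @export
#' @examples
#' cfg <- read_pipeline_config(
#'   system.file("extdata", "demo_config.yaml", package = "phenodist"))
#' cfg$distance
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || is.na(p) || !nzchar(p)) return(p)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }

  if (is.null(raw$dataset)) abort("config must name a `dataset` file")
  if (is.null(raw$variables) || !length(raw$variables)) {
    abort("config must declare at least one variable under `variables`")
  }
  specs <- purrr::map_dfr(raw$variables, function(v) {
    variable_spec(name = v$name,
                  kind = v$kind %||% "qualitative",
                  source = v$source %||% if (identical(v$kind, "quantitative")) "numeric" else "ontology_file",
                  source_path = if (identical(v$source %||% "", "numeric") ||
                                    identical(v$kind, "quantitative")) NA_character_
                                else resolve(v$source_path),
                  weight = v$weight %||% 1)
  })
  validate_specs(specs)

  distance <- raw$distance %||% "semantic"
  if (!distance %in% c("semantic", "gower", "both")) {
    abort("`distance` must be one of: semantic, gower, both")
  }
  reduction <- modifyList(list(method = "pcoa", n_dims = 4,
                               undefined_policy = "error",
                               n_init = 4, max_iter = 300, tol = 1e-6),
                          as.list(raw$reduction %||% list()))
  if (!reduction$method %in% c("pcoa", "mmds", "laplacian")) {
    abort("`reduction$method` must be one of: pcoa, mmds, laplacian")
  }
  if (reduction$n_dims < 1) abort("`reduction$n_dims` must be >= 1")

  clustering <- modifyList(list(algorithms = "kmeans", k = 3),
                           as.list(raw$clustering %||% list()))
  bad_alg <- setdiff(clustering$algorithms, clustering_algorithms())
  if (length(bad_alg)) {
    abort(sprintf("unknown clustering algorithm(s): %s", paste(bad_alg, collapse = ", ")))
  }
  archetypes <- modifyList(list(mode = "single", fraction = 0.05),
                           as.list(raw$archetypes %||% list()))
  if (!archetypes$mode %in% c("single", "multiple")) {
    abort("`archetypes$mode` must be 'single' or 'multiple'")
  }
  if (archetypes$fraction <= 0 || archetypes$fraction > 1) {
    abort("`archetypes$fraction` must be in (0, 1]")
  }
  seed <- as.integer(raw$seed %||% 1L)

  structure(list(
    dataset = resolve(raw$dataset),
    specs = specs,
    distance = distance,
    reduction = reduction,
    clustering = clustering,
    archetypes = archetypes,
    seed = seed,
    palette = unlist(raw$palette) %||% default_palette(),
    output_dir = resolve(raw$output_dir %||% "phenodist_run")
  ), class = "pipeline_config")
}

#' Colour-vision-deficiency-safe default palette
#'
#' Eight colours chosen for legibility under the common colour vision
#' deficiencies (the Okabe-Ito set); override per run through the config
#' `palette` key.
#'
#' @return Character vector of 8 hex colours.
#' @export
default_palette <- function() {
  c("#E69F00", "#56B4E9", "#009E73", "#F0E442",
    "#0072B2", "#D55E00", "#CC79A7", "#999999")
}
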