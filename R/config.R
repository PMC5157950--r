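#' Default run configuration
#'
#' The full configuration tree with model defaults: the life-history
#' parameters, the genotype-grid sampling, the environment list, the assay
#' settings (initial densities, pulse, mode) and the reproducibility
#' fields. The \code{"reduced"} preset uses a 9 x 5 genotype grid and
#' desk-scale horizons; the \code{"paper"} preset records the full-scale
#' configuration (44k-genotype stochastic grid, 1e8-hour horizon) but such
#' runs are long and must be launched explicitly.
#'
#' @param preset "reduced" or "paper".
#' @return a named list of class \code{run_config}.
#' @export
default_config <- function(preset = c("reduced", "paper")) {
  preset <- match.arg(preset)
  p <- unclass(life_history_params())
  grid <- if (preset == "reduced") {
    list(mechanism = "discrete",
         trait_segments = list(c(0, 1, 0.125)),
         c_range = c(0.05, 0.45, 0.1))
  } else {
    list(mechanism = "discrete",
         trait_segments = list(c(0, 1, 0.01)),
         c_range = c(0.05, 0.45, 0.01))
  }
  horizon <- if (preset == "reduced") 1e6 else 1e8
  cfg <- list(
    preset = preset,
    params = p,
    grid = grid,
    environments = list(
      list(kind = "deterministic", T = 199, R0 = 1e8, horizon = horizon,
           n_runs = 1L)),
    init_total = 1e8,
    assay = list(X0 = c(1e3, 1e7, 1e10), R0 = 1e8, mode = "GS",
                 tie_tol = 1e-9),
    seed = 1L,
    out_dir = "results")
  class(cfg) <- "run_config"
  cfg
}

merge_defaults <- function(user, defaults) {
  if (!is.list(user)) return(user)
  out <- defaults
  for (nm in names(user)) {
    if (nm %in% names(defaults) && is.list(defaults[[nm]]) &&
        is.list(user[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_defaults(user[[nm]], defaults[[nm]])
    } else {
      out[[nm]] <- user[[nm]]
    }
  }
  out
}

#' Load a run configuration from a JSON or YAML file
#'
#' Reads a key-value document (JSON for \code{.json}, YAML otherwise --
#' YAML being a JSON superset either syntax works there), fills every
#' missing field from [default_config()], validates the result (including
#' the \eqn{\beta > 1} and \eqn{0 \le \nu \le 1} constraints over the
#' admissible division-rate range) and attaches the parameter provenance
#' tags. An empty file yields the full default configuration.
#'
#' @param path file path.
#' @return a validated \code{run_config} list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list()
    else jsonlite::fromJSON(txt, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  } else {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  preset <- if (!is.null(raw$preset)) raw$preset else "reduced"
  cfg <- merge_defaults(raw, default_config(preset))
  # yaml/json may read segment lists as plain lists of vectors
  if (is.list(cfg$grid$trait_segments) &&
      !is.list(cfg$grid$trait_segments[[1]]) &&
      !is.numeric(cfg$grid$trait_segments[[1]]))
    cfg$grid$trait_segments <- list(unlist(cfg$grid$trait_segments))
  cfg$grid$trait_segments <- lapply(cfg$grid$trait_segments, unlist)
  cfg$grid$c_range <- unlist(cfg$grid$c_range)
  class(cfg) <- "run_config"
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a \code{run_config} list.
#' @return \code{cfg} with validated parameters, or an error naming the
#'   offending key/constraint.
#' @export
validate_config <- function(cfg) {
  p <- cfg$params
  class(p) <- "life_history_params"
  validate_life_history_params(p)
  cfg$params <- unclass(p)
  spec <- genotype_grid_spec(cfg$grid$mechanism, cfg$grid$trait_segments,
                             cfg$grid$c_range)
  config_environments(cfg)   # errors on malformed environment entries
  if (cfg$init_total <= 0)
    stop("config: init_total must be > 0", call. = FALSE)
  if (!cfg$assay$mode %in% c("S", "GS"))
    stop("config: assay$mode must be 'S' or 'GS'", call. = FALSE)
  attr(cfg, "sources") <- param_sources()
  invisible(cfg)
}

#' Save a run configuration (with provenance tags) as JSON
#'
#' @param cfg a \code{run_config} list.
#' @param path output file; conventionally \code{config_echo.json} in the
#'   run's output directory.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  echo <- unclass(cfg)
  echo$param_sources <- as.list(param_sources())
  jsonlite::write_json(echo, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_params <- function(cfg) {
  p <- cfg$params
  class(p) <- "life_history_params"
  p
}

config_grid <- function(cfg) {
  build_genotype_grid(
    genotype_grid_spec(cfg$grid$mechanism, cfg$grid$trait_segments,
                       cfg$grid$c_range),
    params = config_params(cfg))
}

config_environments <- function(cfg) {
  lapply(cfg$environments, function(e)
    environment_spec(kind = e$kind,
                     T = e$T, lambda_T = e$lambda_T,
                     R0 = if (is.null(e$R0)) 1e8 else e$R0,
                     horizon = if (is.null(e$horizon)) 1e6 else e$horizon,
                     n_runs = if (is.null(e$n_runs)) 1L else e$n_runs))
}
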