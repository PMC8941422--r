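# Run configuration: YAML/JSON round-trip with strict validation. Unknown
# keys are rejected so typos fail fast instead of silently using defaults.

CONFIG_KEYS <- list(
  params = c("n", "beta", "gamma", "rho", "b", "c", "mu", "l_min", "l_max"),
  integrator = c("dt", "t_end", "record_every"),
  steady = c("t_min", "delta_i_tol", "delta_t"),
  experiment = c("sweep_name", "sweep_values", "sweep_name_y",
                 "sweep_values_y", "oracle_M", "oracle_seed",
                 "oracle_replicates", "adopter_prob"),
  output = "output_dir"
)

#' Build a run configuration
#'
#' @param params A [model_params()] object.
#' @param dt,t_end,record_every Integrator settings.
#' @param criterion A [steady_state_criterion()].
#' @param experiment Named list of experiment settings (sweep axes/values,
#'   oracle `M`/seed/replicates, `adopter_prob`).
#' @param output_dir Directory for outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(params = model_params(), dt = 0.01, t_end = 10000,
                       record_every = 1,
                       criterion = steady_state_criterion(),
                       experiment = list(), output_dir = ".") {
  stopifnot(inherits(params, "model_params"),
            inherits(criterion, "steady_state_criterion"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (!is.numeric(t_end) || t_end <= 0)
    stop("'t_end' must be positive", call. = FALSE)
  bad <- setdiff(names(experiment), CONFIG_KEYS$experiment)
  if (length(bad))
    stop("unknown experiment key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(params = params, dt = dt, t_end = t_end,
                 record_every = record_every, criterion = criterion,
                 experiment = experiment, output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys fall back to the standard defaults (`n = 20`, `gamma = 1`,
#' `b = 0.18`, `mu = 1e-4`, levels 0 to 5, and the package's reference
#' `beta`, `rho`, `c`); unknown keys are rejected with their key path.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # keep YAML-1.1 boolean-like scalars (notably the key "n") as strings
    yaml::yaml.load(paste(readLines(path, warn = FALSE), collapse = "\n"),
                    handlers = list("bool#yes" = identity,
                                    "bool#no" = identity))
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config root must be a mapping", call. = FALSE)
  bad <- setdiff(names(raw), names(CONFIG_KEYS))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in intersect(names(raw), c("params", "integrator", "steady"))) {
    bad <- setdiff(names(raw[[sec]]), CONFIG_KEYS[[sec]])
    if (length(bad))
      stop("unknown config key(s): ",
           paste(paste0(sec, ".", bad), collapse = ", "), call. = FALSE)
  }
  params <- tryCatch(
    do.call(model_params, as.list(raw$params)),
    error = function(e) stop("invalid 'params': ", conditionMessage(e),
                             call. = FALSE))
  integ <- as.list(raw$integrator)
  steady <- tryCatch(
    do.call(steady_state_criterion, as.list(raw$steady)),
    error = function(e) stop("invalid 'steady': ", conditionMessage(e),
                             call. = FALSE))
  run_config(params = params,
             dt = integ$dt %||% 0.01,
             t_end = integ$t_end %||% 10000,
             record_every = integ$record_every %||% 1,
             criterion = steady,
             experiment = as.list(raw$experiment),
             output_dir = if (is.null(raw$output)) "."
                          else as.character(raw$output))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(
    params = unclass(config$params),
    integrator = list(dt = config$dt, t_end = config$t_end,
                      record_every = config$record_every),
    steady = unclass(config$criterion),
    experiment = config$experiment,
    output = config$output_dir
  )
  if (!length(out$experiment)) out$experiment <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the fully resolved
#' configuration, the seed and the package version, as JSON.
#'
#' @param config A `run_config`.
#' @param path Output path (`.json`).
#' @param seed Seed used for any randomness (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(
    package = "instdyn",
    version = as.character(utils::packageVersion("instdyn")),
    seed = seed,
    params = unclass(config$params),
    integrator = list(dt = config$dt, t_end = config$t_end,
                      record_every = config$record_every),
    steady = unclass(config$criterion),
    experiment = config$experiment,
    output_dir = config$output_dir
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
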