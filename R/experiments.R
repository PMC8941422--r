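# Experiment drivers: parameter sweeps to steady state and detectors for the
# model's qualitative phenomena — collapse thresholds, source-sink and
# institutional free-riding, localization, bistability.
#
# Every steady-state run inside a sweep starts from the standard initial
# condition (not continuation from the previous grid point), so hysteresis
# is probed only by detect_bistability().

SWEEPABLE <- c("beta", "gamma", "rho", "b", "c", "mu")

steady_row <- function(params, criterion, dt, extra = NULL) {
  res <- run_to_steady_state(params, criterion = criterion, dt = dt)
  s <- res$summary
  occ <- as.data.frame(as.list(stats::setNames(
    s$level_occupancy, paste0("occupancy_", names(s$level_occupancy)))))
  freq <- as.data.frame(as.list(stats::setNames(
    s$level_frequency, paste0("frequency_", names(s$level_frequency)))))
  cbind(as.data.frame(extra),
        data.frame(global_frequency = s$global_frequency,
                   mean_i = s$mean_i, t_final = res$t,
                   converged = res$converged),
        occ, freq)
}

#' One-dimensional parameter sweep to steady state
#'
#' For each value of the named parameter, runs the system to steady state
#' from the standard initial condition and records the summary statistics.
#'
#' @param params Baseline [model_params()]; the swept field is replaced per
#'   grid point.
#' @param name One of `"beta"`, `"gamma"`, `"rho"`, `"b"`, `"c"`, `"mu"`.
#' @param values Numeric vector of parameter values.
#' @param criterion A [steady_state_criterion()].
#' @param dt Integrator step size.
#' @return An object of class `sweep_result`: a data frame with one row per
#'   grid point (the swept value, `global_frequency`, `mean_i`, `t_final`,
#'   `converged`, per-level `occupancy_*` and `frequency_*` columns), with
#'   attributes `axis` and `params`.
#' @export
sweep_parameter <- function(params, name, values,
                            criterion = steady_state_criterion(),
                            dt = 0.01) {
  stopifnot(inherits(params, "model_params"))
  if (!is.character(name) || length(name) != 1L || !(name %in% SWEEPABLE))
    stop("'name' must be one of: ", paste(SWEEPABLE, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(values))) stop("'values' must be finite", call. = FALSE)
  rows <- lapply(values, function(v) {
    p <- do.call(update_params,
                 c(list(params), stats::setNames(list(v), name)))
    steady_row(p, criterion, dt, stats::setNames(list(v), name))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(value = numeric(0))
  structure(out, axis = name, params = params, class = c("sweep_result",
                                                         "data.frame"))
}

#' Two-dimensional parameter sweep
#'
#' Runs [sweep_parameter()] logic over the Cartesian grid of two parameters.
#'
#' @inheritParams sweep_parameter
#' @param name_x,name_y Swept parameter names.
#' @param values_x,values_y Grid values.
#' @return A `sweep_result` data frame with both axis columns; attribute
#'   `axis` holds `c(name_x, name_y)`.
#' @export
sweep_grid <- function(params, name_x, values_x, name_y, values_y,
                       criterion = steady_state_criterion(), dt = 0.01) {
  stopifnot(inherits(params, "model_params"))
  for (nm in c(name_x, name_y))
    if (!(nm %in% SWEEPABLE))
      stop("'", nm, "' is not a sweepable parameter", call. = FALSE)
  if (name_x == name_y) stop("axes must differ", call. = FALSE)
  grid <- expand.grid(x = values_x, y = values_y, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    repl <- stats::setNames(list(grid$x[k], grid$y[k]), c(name_x, name_y))
    p <- do.call(update_params, c(list(params), repl))
    steady_row(p, criterion, dt, repl)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(value = numeric(0))
  structure(out, axis = c(name_x, name_y), params = params,
            class = c("sweep_result", "data.frame"))
}

#' Locate the sharpest jump along a sweep
#'
#' Finds the largest jump of a metric between adjacent grid points of a 1-d
#' sweep and classifies it as a discontinuous transition when the jump
#' exceeds `jump_tol`. Optionally refines the bracketing interval by
#' bisection, re-running steady states inside the bracket.
#'
#' @param sweep A 1-d `sweep_result`, sorted along its axis.
#' @param metric Column to monitor (default `"global_frequency"`).
#' @param jump_tol Jump size above which the transition is classified
#'   discontinuous (default 0.2).
#' @param refine_to Target axis resolution for bisection refinement; `NULL`
#'   (default) skips refinement. At most 12 bisection steps.
#' @param criterion,dt Passed to the refinement runs.
#' @return An object of class `threshold_estimate`: list with `parameter`,
#'   `bracket` (`c(low, high)`), `jump`, `classification`
#'   (`"continuous"` or `"discontinuous"`) and `jump_tol`.
#' @export
locate_discontinuity <- function(sweep, metric = "global_frequency",
                                 jump_tol = 0.2, refine_to = NULL,
                                 criterion = steady_state_criterion(),
                                 dt = 0.01) {
  stopifnot(inherits(sweep, "sweep_result"))
  axis <- attr(sweep, "axis")
  if (length(axis) != 1L)
    stop("discontinuity location needs a 1-d sweep", call. = FALSE)
  if (!metric %in% names(sweep))
    stop("metric '", metric, "' not present in sweep", call. = FALSE)
  x <- sweep[[axis]]
  if (length(x) < 2L) stop("need at least 2 grid points", call. = FALSE)
  if (is.unsorted(x)) stop("sweep must be sorted along its axis",
                           call. = FALSE)
  y <- sweep[[metric]]

  jumps <- abs(diff(y))
  k <- which.max(jumps)
  low <- x[k]; high <- x[k + 1L]
  y_low <- y[k]; y_high <- y[k + 1L]

  if (!is.null(refine_to) && refine_to > 0) {
    base <- attr(sweep, "params")
    for (step in seq_len(12L)) {
      if ((high - low) <= refine_to) break
      mid <- (low + high) / 2
      p <- do.call(update_params,
                   c(list(base), stats::setNames(list(mid), axis)))
      res <- run_to_steady_state(p, criterion = criterion, dt = dt)
      y_mid <- if (metric == "global_frequency") res$summary$global_frequency
               else if (metric == "mean_i") res$summary$mean_i
               else stop("refinement supports global_frequency or mean_i",
                         call. = FALSE)
      # keep the half containing the larger change
      if (abs(y_mid - y_low) >= abs(y_high - y_mid)) {
        high <- mid; y_high <- y_mid
      } else {
        low <- mid; y_low <- y_mid
      }
    }
  }
  jump <- abs(y_high - y_low)
  structure(list(parameter = axis, bracket = c(low = low, high = high),
                 jump = jump,
                 classification = if (jump > jump_tol) "discontinuous"
                                  else "continuous",
                 jump_tol = jump_tol),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("Threshold in '%s': bracket [%g, %g], jump %.4g (%s)\n",
              x$parameter, x$bracket[1], x$bracket[2], x$jump,
              x$classification))
  invisible(x)
}

#' Probe for bistability at a parameter point
#'
#' Runs the system to steady state from a low-adoption and a high-adoption
#' binomial initial condition (both uniform over levels) and compares the
#' steady global adoption frequencies. Coexistence of an extinct and an
#' active attractor shows up as a gap between the two.
#'
#' @param params A [model_params()] object (already at the point of
#'   interest, or modified via `...`).
#' @param ... Named parameter overrides for the probed point.
#' @param low_p,high_p Adoption probabilities of the two initial conditions.
#' @param gap_tol Gap in `global_frequency` above which the point is flagged
#'   bistable (default 0.05).
#' @param criterion,dt Steady-state settings.
#' @return An object of class `bistability_result`: list with `params`,
#'   `low` and `high` (each the result of [run_to_steady_state()]),
#'   `distance`, `bistable`, and `both_converged`.
#' @export
detect_bistability <- function(params, ..., low_p = 0.01, high_p = 0.9,
                               gap_tol = 0.05,
                               criterion = steady_state_criterion(),
                               dt = 0.01) {
  stopifnot(inherits(params, "model_params"))
  if (length(list(...))) params <- update_params(params, ...)
  for (p in c(low_p, high_p))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("initial adoption probabilities must lie in [0, 1]",
           call. = FALSE)
  lo <- run_to_steady_state(params, initial_condition(params, low_p),
                            criterion = criterion, dt = dt)
  hi <- run_to_steady_state(params, initial_condition(params, high_p),
                            criterion = criterion, dt = dt)
  both <- lo$converged && hi$converged
  if (!both)
    warning("at least one steady-state run did not converge; ",
            "comparison may be unreliable", call. = FALSE)
  dist <- abs(hi$summary$global_frequency - lo$summary$global_frequency)
  structure(list(params = params, low = lo, high = hi, distance = dist,
                 bistable = both && dist > gap_tol,
                 both_converged = both, gap_tol = gap_tol),
            class = "bistability_result")
}

#' @export
print.bistability_result <- function(x, ...) {
  cat(sprintf(paste0("Bistability probe: low-start %.4g, high-start %.4g, ",
                     "gap %.4g -> %s\n"),
              x$low$summary$global_frequency,
              x$high$summary$global_frequency, x$distance,
              if (x$bistable) "bistable" else "monostable"))
  invisible(x)
}

#' Institutional free-riding curve
#'
#' Sweeps the global diffusion rate and reports the quantities that expose
#' source-sink dynamics: the occupancy of the no-institution level, the
#' adopter frequency inside those groups (who cannot generate the behaviour
#' internally), and the global adoption frequency.
#'
#' @param params A [model_params()] object.
#' @param rho_values Sorted, non-negative global diffusion rates.
#' @inheritParams sweep_parameter
#' @return A `sweep_result` over `rho` (see [sweep_parameter()]); the
#'   columns `occupancy_<l_min>` and `frequency_<l_min>` carry the
#'   free-riding signal.
#' @export
free_riding_curve <- function(params, rho_values,
                              criterion = steady_state_criterion(),
                              dt = 0.01) {
  if (any(rho_values < 0) || is.unsorted(rho_values))
    stop("'rho_values' must be sorted and non-negative", call. = FALSE)
  sweep_parameter(params, "rho", rho_values, criterion = criterion, dt = dt)
}

#' Write a sweep as tidy CSV
#'
#' One row per grid point per metric: axis column(s), `metric`, `value`.
#'
#' @param sweep A `sweep_result`.
#' @param path Output file path.
#' @return The tidy data frame, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  axis <- attr(sweep, "axis")
  metrics <- setdiff(names(sweep), axis)
  tidy <- do.call(rbind, lapply(metrics, function(m) {
    cbind(sweep[, axis, drop = FALSE],
          data.frame(metric = m, value = as.numeric(sweep[[m]])))
  }))
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(tidy)
}
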