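# Initial conditions, time integration, steady-state detection, summaries.

#' Standard initial condition
#'
#' Groups are spread uniformly over institutional levels, and within each
#' level the number of adopters is binomially distributed,
#' \eqn{G_{i,\ell} = \mathrm{Binom}(i; n, p) / L}. The default
#' `adopter_prob = 0.01` gives an average of 1% adopters.
#'
#' @param params A [model_params()] object.
#' @param adopter_prob Per-individual adoption probability in `[0, 1]`.
#' @return A normalized group-distribution matrix.
#' @export
initial_condition <- function(params, adopter_prob = 0.01) {
  if (!is.numeric(adopter_prob) || length(adopter_prob) != 1L ||
      is.na(adopter_prob) || adopter_prob < 0 || adopter_prob > 1)
    stop("'adopter_prob' must be a probability in [0, 1]", call. = FALSE)
  L <- n_levels(params)
  pmf <- stats::dbinom(0:params$n, params$n, adopter_prob)
  G <- matrix(rep(pmf / L, L), ncol = L)
  group_distribution(G / sum(G), params)
}

#' Steady-state criterion
#'
#' A state counts as stationary once `t >= t_min` and the mean number of
#' adopters per group has changed by less than `delta_i_tol` over a window
#' `delta_t`. Defaults: record stable long-run values when `t >= 10000` and
#' the change in mean adopters over `delta_t = 1` is below `1e-10`.
#'
#' @param t_min Minimum time before convergence may be declared.
#' @param delta_i_tol Tolerance on the change in mean adopters per group.
#' @param delta_t Width of the comparison window.
#' @return An object of class `steady_state_criterion`.
#' @export
steady_state_criterion <- function(t_min = 10000, delta_i_tol = 1e-10,
                                   delta_t = 1) {
  for (nm in c("t_min", "delta_i_tol", "delta_t")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm),
           call. = FALSE)
  }
  structure(list(t_min = t_min, delta_i_tol = delta_i_tol,
                 delta_t = delta_t),
            class = "steady_state_criterion")
}

integration_failure <- function(t_fail, dt) {
  stop(sprintf(paste0("integration produced a state entry below -1e-9 ",
                      "at t = %g; the step size dt = %g is too large, ",
                      "retry with a smaller dt"), t_fail, dt),
       call. = FALSE)
}

#' Integrate the master equations
#'
#' Advances the coupled system with a fixed-step classical 4th-order
#' Runge-Kutta scheme. Entries driven slightly negative by integration noise
#' are clipped to zero; an entry below `-1e-9` aborts with an error naming
#' the failure time (the step size is too large for the rates present).
#' Recorded states stay normalized within `1e-9`.
#'
#' @param G0 Initial group-distribution matrix.
#' @param params A [model_params()] object.
#' @param t_end Final time.
#' @param dt Step size (default 0.01).
#' @param record_every Interval between recorded states (default 1).
#' @return An object of class `trajectory`: a list with `times`, `states`
#'   (a 3-d array, state x time), `summaries` (data frame of per-time
#'   summary statistics) and the clip/renormalization counters.
#' @export
integrate_trajectory <- function(G0, params, t_end, dt = 0.01,
                                 record_every = 1) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (!is.numeric(t_end) || t_end <= 0)
    stop("'t_end' must be positive", call. = FALSE)
  G0 <- group_distribution(G0, params)
  res <- cpp_integrate(G0, params$n, params$l_min, params$beta, params$gamma,
                       params$rho, params$b, params$c, params$mu,
                       t_end, dt, record_every)
  if (!isTRUE(res$ok)) integration_failure(res$t_fail, dt)
  states <- res$states
  dimnames(states) <- c(dimnames(G0), list(NULL))
  summaries <- do.call(rbind, lapply(seq_along(res$times), function(k) {
    s <- summarize_state(states[, , k], params)
    data.frame(time = res$times[k], global_frequency = s$global_frequency,
               mean_i = s$mean_i)
  }))
  structure(list(times = res$times, states = states, summaries = summaries,
                 params = params, dt = dt,
                 n_clipped = res$n_clipped, n_renorm = res$n_renorm),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d recorded states, t in [%g, %g]\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  cat(sprintf("  final global frequency: %.6g\n",
              x$summaries$global_frequency[nrow(x$summaries)]))
  invisible(x)
}

#' Run the system to steady state
#'
#' Integrates until the steady-state criterion is met, or until a hard time
#' cap (default `10 * t_min`) at which the run is reported as not converged.
#'
#' @param params A [model_params()] object.
#' @param G0 Initial state (default: [initial_condition()]).
#' @param criterion A [steady_state_criterion()].
#' @param dt Step size.
#' @param t_cap Hard time cap; default `10 * criterion$t_min`.
#' @return A list with `G` (final state), `t` (final time), `converged`
#'   (logical) and `summary` ([summarize_state()] of the final state).
#' @export
run_to_steady_state <- function(params, G0 = initial_condition(params),
                                criterion = steady_state_criterion(),
                                dt = 0.01, t_cap = 10 * criterion$t_min) {
  stopifnot(inherits(params, "model_params"),
            inherits(criterion, "steady_state_criterion"))
  G0 <- group_distribution(G0, params)
  res <- cpp_run_steady(G0, params$n, params$l_min, params$beta,
                        params$gamma, params$rho, params$b, params$c,
                        params$mu, dt, criterion$t_min,
                        criterion$delta_i_tol, criterion$delta_t, t_cap)
  if (!isTRUE(res$ok)) integration_failure(res$t_fail, dt)
  G <- res$G
  dimnames(G) <- list(i = 0:params$n, l = levels_of(params))
  list(G = G, t = res$t, converged = res$converged,
       summary = summarize_state(G, params))
}

#' Summary statistics of a state
#'
#' @param G Group-distribution matrix.
#' @param params A [model_params()] object.
#' @return A list with `global_frequency` (mean adopter fraction across all
#'   groups), `mean_i` (mean adopters per group), `level_occupancy` (fraction
#'   of groups at each level) and `level_frequency` (adopter fraction within
#'   each level; `NA` for unoccupied levels).
#' @export
summarize_state <- function(G, params) {
  i <- 0:params$n
  occ <- colSums(G)
  mean_i_level <- colSums(i * G)
  occupied <- occ > OCCUPANCY_TOL
  level_freq <- ifelse(occupied,
                       mean_i_level / (params$n * ifelse(occupied, occ, 1)),
                       NA_real_)
  names(occ) <- names(level_freq) <- levels_of(params)
  mean_i <- sum(mean_i_level)
  list(global_frequency = mean_i / params$n, mean_i = mean_i,
       level_occupancy = occ, level_frequency = level_freq)
}

#' Export a trajectory as tidy data frames
#'
#' @param x A `trajectory`.
#' @return A list of two data frames: `states` (time, i, level, mass) and
#'   `metrics` (time, metric, value).
#' @export
trajectory_long <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  d <- dim(x$states)
  states <- data.frame(
    time = rep(x$times, each = d[1] * d[2]),
    i = rep.int(rep(as.integer(dimnames(x$states)[[1]]), d[2]), d[3]),
    level = rep.int(rep(as.integer(dimnames(x$states)[[2]]),
                        each = d[1]), d[3]),
    mass = as.vector(x$states)
  )
  metrics <- data.frame(
    time = rep(x$summaries$time, 2L),
    metric = rep(c("global_frequency", "mean_i"),
                 each = nrow(x$summaries)),
    value = c(x$summaries$global_frequency, x$summaries$mean_i)
  )
  list(states = states, metrics = metrics)
}
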