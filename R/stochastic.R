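# Event-driven stochastic simulation of a finite ensemble of groups: the
# brute-force counterpart of the mean-field master equations. M explicit
# groups each hold an adopter count i and an institutional level l; events
# (adoption, abandonment, level up/down) occur with exponential waiting
# times, with the global field and the fitness profile recomputed from the
# instantaneous empirical state after every event.

#' Construct an ensemble state
#'
#' @param i Integer vector of adopter counts, one per group (in `[0, n]`).
#' @param l Integer vector of institutional levels, one per group.
#' @param params A [model_params()] object.
#' @return An object of class `ensemble_state`.
#' @export
ensemble_state <- function(i, l, params) {
  stopifnot(inherits(params, "model_params"))
  i <- as.integer(i)
  l <- as.integer(l)
  if (length(i) != length(l) || length(i) < 1L)
    stop("'i' and 'l' must be equal-length vectors with at least one group",
         call. = FALSE)
  if (any(is.na(i)) || any(i < 0L) || any(i > params$n))
    stop("adopter counts must lie in [0, n]", call. = FALSE)
  if (any(is.na(l)) || any(l < params$l_min) || any(l > params$l_max))
    stop("levels must lie in [l_min, l_max]", call. = FALSE)
  structure(list(i = i, l = l, params = params), class = "ensemble_state")
}

#' Sample the standard ensemble initial condition
#'
#' Levels uniform over the level range, adopter counts binomial — the
#' finite-M counterpart of [initial_condition()].
#'
#' @param params A [model_params()] object.
#' @param M Number of groups.
#' @param adopter_prob Per-individual adoption probability.
#' @return An `ensemble_state`.
#' @export
sample_ensemble <- function(params, M, adopter_prob = 0.01) {
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("'M' must be >= 1", call. = FALSE)
  ensemble_state(stats::rbinom(M, params$n, adopter_prob),
                 sample(levels_of(params), M, replace = TRUE), params)
}

#' Empirical group distribution of an ensemble
#'
#' @param state An [ensemble_state()].
#' @return A group-distribution matrix (fractions of groups per (i, level)).
#' @export
empirical_distribution <- function(state) {
  p <- state$params
  C <- table(factor(state$i, levels = 0:p$n),
             factor(state$l, levels = levels_of(p)))
  group_distribution(unclass(C) / length(state$i), p)
}

#' Per-group event rates
#'
#' For each group: adoption at rate \eqn{\ell \beta (i + \hat R)(n - i)}
#' with \eqn{\hat R = \rho \bar i} the empirical global field, abandonment
#' at rate \eqn{\gamma i}, and level up/down at rate
#' \eqn{\rho[\max(\hat Z_{\ell\pm1}/\hat Z_\ell - 1, 0) + \mu]} with
#' \eqn{\hat Z} the fitness profile of the empirical distribution; boundary
#' and empty-level rules as in the mean-field equations.
#'
#' @param state An [ensemble_state()].
#' @return A data frame with one row per group: `i`, `l`, `adopt`, `abandon`,
#'   `level_up`, `level_down`.
#' @export
event_rates <- function(state) {
  p <- state$params
  G <- empirical_distribution(state)
  Rhat <- global_field(G, p)
  fit <- perceived_fitness(G, p)
  Z <- fit$Z
  occ <- fit$occupied
  lv <- levels_of(p)
  L <- length(lv)

  pair_rate <- function(src, tgt) {
    # per-group rate of moving from level index src to adjacent index tgt
    if (occ[src] && occ[tgt]) {
      p$rho * (max(Z[tgt] / Z[src] - 1, 0) + p$mu)
    } else {
      p$rho * p$mu
    }
  }
  up_rate <- c(vapply(seq_len(L - 1L), function(j) pair_rate(j, j + 1L),
                      numeric(1)), 0)
  down_rate <- c(0, vapply(seq_len(L - 1L), function(j) pair_rate(j + 1L, j),
                           numeric(1)))

  j <- match(state$l, lv)
  data.frame(
    i = state$i, l = state$l,
    adopt = state$l * p$beta * (state$i + Rhat) * (p$n - state$i),
    abandon = p$gamma * state$i,
    level_up = up_rate[j],
    level_down = down_rate[j]
  )
}

#' Simulate the ensemble with an exact stochastic algorithm
#'
#' Gillespie simulation over the event rates of [event_rates()]:
#' exponentially distributed waiting times and categorical event choice,
#' reproducible given the seed. The empirical distribution is recorded at
#' each requested time.
#'
#' @param params A [model_params()] object.
#' @param M Number of groups (ignored when `init` is given).
#' @param t_end Final time; `record_times` defaults to `0:t_end`.
#' @param seed Integer seed.
#' @param record_times Increasing vector of times at which to record.
#' @param init Optional [ensemble_state()] to start from; default
#'   [sample_ensemble()] with 1% adopters.
#' @param adopter_prob Adoption probability for the default `init`.
#' @return An object of class `ensemble_run`: list with `times`, `states`
#'   (3-d array of empirical distributions), `summaries` (data frame),
#'   `params`, `M`, `seed`.
#' @export
simulate_ensemble <- function(params, M, t_end, seed,
                              record_times = seq(0, t_end),
                              init = NULL, adopter_prob = 0.01) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(t_end) || t_end <= 0)
    stop("'t_end' must be positive", call. = FALSE)
  record_times <- sort(unique(as.numeric(record_times)))
  if (any(record_times < 0) || length(record_times) < 1L)
    stop("'record_times' must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  if (is.null(init)) init <- sample_ensemble(params, M, adopter_prob)
  stopifnot(inherits(init, "ensemble_state"))
  M <- length(init$i)

  C0 <- table(factor(init$i, levels = 0:params$n),
              factor(init$l, levels = levels_of(params)))
  C0 <- matrix(as.integer(C0), nrow = params$n + 1L)
  res <- cpp_gillespie(C0, params$n, params$l_min, params$beta,
                       params$gamma, params$rho, params$b, params$c,
                       params$mu, record_times)
  states <- res$states
  dimnames(states) <- list(i = 0:params$n, l = levels_of(params), NULL)
  summaries <- do.call(rbind, lapply(seq_along(record_times), function(k) {
    s <- summarize_state(states[, , k], params)
    cbind(data.frame(time = record_times[k],
                     global_frequency = s$global_frequency,
                     mean_i = s$mean_i),
          as.data.frame(as.list(stats::setNames(
            s$level_occupancy,
            paste0("occupancy_", names(s$level_occupancy))))))
  }))
  structure(list(times = record_times, states = states,
                 summaries = summaries, params = params, M = M,
                 seed = as.integer(seed)),
            class = "ensemble_run")
}

#' Average replicate ensemble runs
#'
#' Pointwise means and Monte-Carlo standard errors of the summary statistics
#' across replicate runs recorded at identical times.
#'
#' @param runs A list of `ensemble_run` objects (at least 2) with identical
#'   `times`.
#' @return A data frame with one row per (time, metric): `time`, `metric`,
#'   `mean`, `se`, `n_runs`.
#' @export
ensemble_average <- function(runs) {
  if (!is.list(runs) || length(runs) < 2L)
    stop("need at least 2 runs", call. = FALSE)
  if (!all(vapply(runs, inherits, logical(1), "ensemble_run")))
    stop("all elements must be ensemble runs", call. = FALSE)
  t0 <- runs[[1]]$times
  same <- vapply(runs, function(r) {
    length(r$times) == length(t0) && all(r$times == t0)
  }, logical(1))
  if (!all(same)) stop("runs have mismatched record times", call. = FALSE)

  metrics <- setdiff(names(runs[[1]]$summaries), "time")
  out <- lapply(metrics, function(m) {
    vals <- vapply(runs, function(r) r$summaries[[m]],
                   numeric(length(t0)))  # times x runs
    data.frame(time = t0, metric = m,
               mean = rowMeans(vals),
               se = apply(vals, 1L, stats::sd) / sqrt(length(runs)),
               n_runs = length(runs))
  })
  do.call(rbind, out)
}
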