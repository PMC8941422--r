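#' Model parameters
#'
#' Bundle of all rate, benefit and cost constants of the coupled
#' behaviour-institution model, plus the institutional level range.
#'
#' The population consists of many groups of `n` individuals. Within a group
#' at institutional level \eqn{\ell}, the behaviour spreads from adopters to
#' non-adopters at rate \eqn{\ell\beta} per (adopter, non-adopter) pair, so at
#' \eqn{\ell = 0} it cannot spread internally at all; adopters abandon it at
#' rate \eqn{\gamma}. The global diffusion rate \eqn{\rho} couples groups
#' through a shared field of adopters and also sets the timescale of
#' institutional change. Groups gain log-fitness `b` per adopter and pay
#' log-fitness `c` per institutional level; `mu` is a small
#' fitness-independent rate of switching to an adjacent level, which lets
#' unoccupied levels be discovered.
#'
#' Defaults `n = 20`, `gamma = 1`, `b = 0.18`, `mu = 1e-4` and levels
#' \eqn{\ell \in [0, 5]} are the model's standard study conditions. `beta`,
#' `rho` and `c` have no single canonical value; the shipped defaults
#' (`beta = 0.1`, `rho = 0.05`, `c = 1`) are a documented reference point in
#' the active regime: `beta * n = 2` makes level-1 groups modestly
#' supercritical, and `rho` is small relative to `gamma`.
#'
#' @param n Group size (integer, >= 1).
#' @param beta Within-group transmission rate per (adopter, non-adopter) pair.
#' @param gamma Behaviour abandonment rate per adopter.
#' @param rho Global diffusion rate; also scales institutional-change rates.
#' @param b Collective benefit per adopter (log-fitness units).
#' @param c Cost per institutional level (log-fitness units).
#' @param mu Fitness-independent institutional transition ("invention") rate.
#' @param l_min,l_max Integer bounds of institutional strength.
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$beta
#' @export
model_params <- function(n = 20, beta = 0.1, gamma = 1.0, rho = 0.05,
                         b = 0.18, c = 1.0, mu = 1e-4,
                         l_min = 0L, l_max = 5L) {
  n <- as.integer(n)
  l_min <- as.integer(l_min)
  l_max <- as.integer(l_max)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1", call. = FALSE)
  for (nm in c("beta", "gamma", "rho", "b", "c", "mu")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
  }
  if (is.na(l_min) || is.na(l_max) || l_min > l_max)
    stop("'l_min' must be <= 'l_max'", call. = FALSE)
  structure(
    list(n = n, beta = beta, gamma = gamma, rho = rho, b = b, c = c,
         mu = mu, l_min = l_min, l_max = l_max),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters:\n")
  cat(sprintf("  n = %d, levels = [%d, %d]\n", x$n, x$l_min, x$l_max))
  cat(sprintf("  beta = %g, gamma = %g, rho = %g\n", x$beta, x$gamma, x$rho))
  cat(sprintf("  b = %g, c = %g, mu = %g\n", x$b, x$c, x$mu))
  invisible(x)
}

levels_of <- function(params) seq.int(params$l_min, params$l_max)

n_levels <- function(params) params$l_max - params$l_min + 1L

#' Modify one or more model parameters
#'
#' Returns a new `model_params` with the given fields replaced, re-running
#' validation.
#'
#' @param params A [model_params()] object.
#' @param ... Named fields to replace.
#' @return A `model_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  nm <- names(repl)
  if (is.null(nm) || any(nm == "") || !all(nm %in% names(params)))
    stop("unknown parameter name(s): ",
         paste(setdiff(nm, names(params)), collapse = ", "), call. = FALSE)
  args <- unclass(params)
  args[nm] <- repl
  do.call(model_params, args)
}
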