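# Mean-field state and master-equation right-hand sides.
#
# The state G is an (n+1) x L matrix: G[i+1, j] is the fraction of groups
# with i adopters (i = 0..n) at institutional level l_min + j - 1. All
# right-hand-side terms are written as paired in/out flows, so each returned
# rate array sums to zero exactly (probability conservation).

# Occupancy threshold below which a level is treated as empty (its fitness is
# a 0/0); must match the C++ core.
OCCUPANCY_TOL <- 1e-12

#' Build a group-distribution matrix
#'
#' Validates and labels a matrix as a distribution of groups over
#' (adopters, institutional level) states.
#'
#' @param G Numeric matrix with `n + 1` rows (adopter counts `0:n`) and one
#'   column per institutional level.
#' @param params A [model_params()] object.
#' @return The matrix with dimnames `i` (adopters) and `l` (levels).
#' @export
group_distribution <- function(G, params) {
  stopifnot(inherits(params, "model_params"))
  G <- as.matrix(G)
  if (nrow(G) != params$n + 1L || ncol(G) != n_levels(params))
    stop(sprintf("G must be %d x %d for these parameters",
                 params$n + 1L, n_levels(params)), call. = FALSE)
  if (any(G < -1e-12))
    stop("G has negative entries beyond tolerance", call. = FALSE)
  G[G < 0] <- 0
  if (abs(sum(G) - 1) > 1e-9)
    stop("G must sum to 1 within 1e-9", call. = FALSE)
  dimnames(G) <- list(i = 0:params$n, l = levels_of(params))
  G
}

#' Global diffusion field
#'
#' The field \eqn{R = \rho \sum_{i,\ell} i \, G_{i,\ell}}: the global
#' diffusion rate times the mean number of adopters per group. It enters the
#' within-group contagion as extra adopters that any non-adopter is exposed
#' to, regardless of group membership.
#'
#' @param G Group-distribution matrix (see [group_distribution()]).
#' @param params A [model_params()] object.
#' @return A single non-negative number.
#' @export
global_field <- function(G, params) {
  i <- 0:params$n
  params$rho * sum(i * rowSums(G))
}

#' Perceived fitness per institutional level
#'
#' For each occupied level \eqn{\ell}, the occupancy-weighted mean of
#' \eqn{\exp(b i - c \ell)} over the groups at that level:
#' \deqn{Z_\ell = \frac{\sum_i e^{b i - c \ell} G_{i,\ell}}{\sum_i G_{i,\ell}}.}
#' Only the fitness of a level is observed, not the behaviour of individual
#' groups, so institutional imitation is driven by these level averages.
#' Unoccupied levels (total mass below an internal tolerance) are flagged and
#' given the sentinel value \eqn{e^{-c\ell}} (an empty group's fitness); the
#' sentinel is reported but never used in fitness-ratio flows.
#'
#' @inheritParams global_field
#' @return A list with `Z` (numeric, one entry per level, named by level) and
#'   `occupied` (logical of the same length).
#' @export
perceived_fitness <- function(G, params) {
  i <- 0:params$n
  lv <- levels_of(params)
  occ <- colSums(G)
  num <- colSums(exp(params$b * i) * G) * exp(-params$c * lv)
  occupied <- occ > OCCUPANCY_TOL
  Z <- ifelse(occupied, num / ifelse(occupied, occ, 1), exp(-params$c * lv))
  names(Z) <- names(occupied) <- lv
  list(Z = Z, occupied = occupied)
}

#' Behavioural-diffusion terms of the master equation
#'
#' Rate of change of each \eqn{G_{i,\ell}} from within-group contagion and
#' relaxation alone: adoption moves a group from \eqn{(i, \ell)} to
#' \eqn{(i+1, \ell)} at rate \eqn{\ell\beta (i + R)(n - i)} and relaxation
#' moves it to \eqn{(i-1, \ell)} at rate \eqn{\gamma i}, with `R` the global
#' field computed from the same state.
#'
#' @inheritParams global_field
#' @return A matrix of the same shape as `G`, summing to zero.
#' @export
diffusion_rhs <- function(G, params) {
  n <- params$n
  i <- 0:n
  R <- global_field(G, params)
  lv <- levels_of(params)
  # per-state outflow rates (per unit mass)
  adopt <- outer(i, lv, function(i, l) l * params$beta * (i + R) * (n - i))
  relax <- params$gamma * i
  fa <- adopt * G       # adoption flux out of (i, l), into (i+1, l)
  fr <- relax * G       # relaxation flux out of (i, l), into (i-1, l)
  dG <- -fa - fr
  dG[-1, ] <- dG[-1, ] + fa[-(n + 1), ]
  dG[-(n + 1), ] <- dG[-(n + 1), ] + fr[-1, ]
  dimnames(dG) <- dimnames(G)
  dG
}

#' Institutional-selection terms of the master equation
#'
#' Rate of change of each \eqn{G_{i,\ell}} from fitness-biased switching
#' between adjacent institutional levels. A group at level \eqn{\ell} moves
#' to a neighbouring level \eqn{\ell'} at per-group rate
#' \deqn{\rho \left[\max(Z_{\ell'} / Z_\ell - 1,\, 0) + \mu\right],}
#' i.e. proportionally to the fitness advantage of the target level, plus the
#' fitness-independent innovation rate \eqn{\mu}. The adopter count `i` is
#' carried unchanged across a level switch. Flows into unoccupied target
#' levels use the \eqn{\rho\mu} term only, and flows beyond the boundary
#' levels do not exist, so the returned array conserves mass exactly.
#'
#' @inheritParams global_field
#' @param fitness Optionally, the result of [perceived_fitness()] on the same
#'   `G` (recomputed when `NULL`).
#' @return A matrix of the same shape as `G`, summing to zero.
#' @export
selection_rhs <- function(G, params, fitness = NULL) {
  if (is.null(fitness)) fitness <- perceived_fitness(G, params)
  Z <- fitness$Z
  occ <- fitness$occupied
  L <- n_levels(params)
  dG <- matrix(0, nrow(G), ncol(G), dimnames = dimnames(G))
  if (L < 2L) return(dG)
  for (j in seq_len(L - 1L)) {
    if (occ[j] && occ[j + 1L]) {
      up <- params$rho * (max(Z[j + 1L] / Z[j] - 1, 0) + params$mu)
      down <- params$rho * (max(Z[j] / Z[j + 1L] - 1, 0) + params$mu)
    } else {
      up <- down <- params$rho * params$mu
    }
    flux <- up * G[, j] - down * G[, j + 1L]   # net flow j -> j+1, per i
    dG[, j] <- dG[, j] - flux
    dG[, j + 1L] <- dG[, j + 1L] + flux
  }
  dG
}

#' Full master-equation right-hand side
#'
#' Sum of the behavioural-diffusion and institutional-selection terms, with
#' the global field `R` and the fitness profile `Z` both evaluated once on
#' the input state.
#'
#' @inheritParams global_field
#' @return A matrix of the same shape as `G`, summing to zero.
#' @export
total_rhs <- function(G, params) {
  diffusion_rhs(G, params) + selection_rhs(G, params)
}
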