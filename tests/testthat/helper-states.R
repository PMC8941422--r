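# Shared fixtures: small parameter sets and random normalized states.

# reference parameter point used across tests (the package defaults)
ref_params <- function(...) update_params(model_params(), ...)

# a tiny system: n = 2, two levels, for hand-checkable cases
tiny_params <- function(...) {
  update_params(model_params(n = 2, beta = 0.5, gamma = 1, rho = 0,
                             b = 0.18, c = 1, mu = 1e-4,
                             l_min = 0, l_max = 1), ...)
}

# random normalized group distribution for property tests
random_state <- function(params) {
  G <- matrix(stats::runif((params$n + 1) * (params$l_max - params$l_min + 1)),
              nrow = params$n + 1)
  group_distribution(G / sum(G), params)
}

# point-mass state: all groups at (i0, l0)
point_state <- function(params, i0, l0) {
  G <- matrix(0, params$n + 1, params$l_max - params$l_min + 1)
  G[i0 + 1, l0 - params$l_min + 1] <- 1
  group_distribution(G, params)
}

# short steady-state settings for unit tests (the full protocol is exercised
# in the acceptance tests)
quick_criterion <- function() {
  steady_state_criterion(t_min = 50, delta_i_tol = 1e-9, delta_t = 1)
}
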