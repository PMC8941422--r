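# Right-hand-side terms of the master equations, against hand-computed
# oracles on systems small enough to evaluate by inspection.

test_that("global field is rho times the mean adopters per group", {
  p <- ref_params(rho = 0.1)
  expect_equal(global_field(point_state(p, 0, 3), p), 0)
  expect_equal(global_field(point_state(p, 5, 2), p), 0.5)
  p1 <- ref_params(rho = 1)
  G <- 0.5 * point_state(p1, 2, 0) + 0.5 * point_state(p1, 4, 5)
  expect_equal(global_field(group_distribution(G, p1), p1), 3.0)
})

test_that("perceived fitness is the occupancy-weighted mean of exp(bi - cl)", {
  p <- ref_params(b = 0.18, c = 1)
  # delta distribution collapses the weighted mean
  fit <- perceived_fitness(point_state(p, 10, 1), p)
  expect_equal(fit$Z[["1"]], exp(0.18 * 10 - 1))
  expect_equal(fit$Z[["1"]], 2.225541, tolerance = 1e-6)
  expect_true(fit$occupied[["1"]])
  # unoccupied levels are flagged and get the empty-group sentinel
  expect_false(fit$occupied[["3"]])
  expect_equal(fit$Z[["3"]], exp(-3))
  # b = 0 removes the i-dependence entirely
  p0 <- ref_params(b = 0)
  set.seed(42)
  fit0 <- perceived_fitness(random_state(p0), p0)
  expect_equal(unname(fit0$Z), exp(-p0$c * (0:5)))
  # mixed occupancy: weighted mean over two adopter counts
  pm <- ref_params()
  G <- 0.25 * point_state(pm, 2, 1) + 0.75 * point_state(pm, 8, 1)
  fit <- perceived_fitness(group_distribution(G, pm), pm)
  expect_equal(fit$Z[["1"]],
               (0.25 * exp(0.18 * 2) + 0.75 * exp(0.18 * 8)) * exp(-1))
})

test_that("diffusion terms match the hand-evaluated 3-state chain", {
  # n = 2, single level l = 1, beta = 0.5, gamma = 1, rho = 0, mass at i = 1:
  # adoption flux 1*0.5*(1+0)*(2-1) = 0.5, relaxation flux 1*1 = 1
  p <- model_params(n = 2, beta = 0.5, gamma = 1, rho = 0,
                    l_min = 1, l_max = 1)
  G <- group_distribution(matrix(c(0, 1, 0), ncol = 1), p)
  dG <- diffusion_rhs(G, p)
  expect_equal(as.numeric(dG), c(1.0, -1.5, 0.5), tolerance = 1e-12)
})

test_that("level-0 groups are inert under diffusion", {
  p <- ref_params(rho = 0)
  G <- point_state(p, 4, 0)
  dG <- diffusion_rhs(G, p)
  # relaxation still drains adopters, but no adoption flow exists at l = 0
  expect_equal(dG[5, 1], -p$gamma * 4)
  expect_equal(dG[6, 1], 0)       # no inflow to i = 5
  # and with no adopters at all, the l = 0 column is completely static
  dG0 <- diffusion_rhs(point_state(p, 0, 0), p)
  expect_equal(max(abs(dG0)), 0)
})

test_that("selection terms match the hand-evaluated two-level flow", {
  # levels {0, 1}, all mass at i = 0 split 0.5/0.5, c = 1, rho = 1,
  # mu = 1e-4: Z0 = 1, Z1 = exp(-1); up-rate = mu (clamped),
  # down-rate = (e - 1) + mu
  p <- model_params(n = 2, beta = 0, gamma = 0, rho = 1, b = 0.3, c = 1,
                    mu = 1e-4, l_min = 0, l_max = 1)
  G <- group_distribution(matrix(c(0.5, 0, 0, 0.5, 0, 0), 3, 2), p)
  dG <- selection_rhs(G, p)
  expect_equal(dG[1, 1], 0.5 * (exp(1) - 1 + 1e-4) - 0.5 * 1e-4,
               tolerance = 1e-12)
  expect_equal(dG[1, 1], 0.859141, tolerance = 1e-6)
  expect_equal(dG[1, 2], -dG[1, 1], tolerance = 1e-15)
})

test_that("selection vanishes without global diffusion or fitness gaps", {
  p <- ref_params(rho = 0)
  set.seed(7)
  expect_equal(max(abs(selection_rhs(random_state(p), p))), 0)
  # identical Z on all occupied levels and mu = 0: ratios are 1, clamp(0) = 0
  p2 <- ref_params(b = 0, c = 0, mu = 0)
  set.seed(8)
  expect_equal(max(abs(selection_rhs(random_state(p2), p2))), 0)
})

test_that("flows into unoccupied levels carry only the innovation rate", {
  p <- ref_params(rho = 1, mu = 1e-3)
  G <- point_state(p, 10, 2)      # only level 2 occupied
  dG <- selection_rhs(G, p)
  expect_equal(dG[11, 2], p$rho * p$mu)            # into empty level 1
  expect_equal(dG[11, 4], p$rho * p$mu)            # into empty level 3
  expect_equal(dG[11, 3], -2 * p$rho * p$mu)
  expect_equal(sum(dG[, c(1, 5, 6)]), 0)           # nothing beyond neighbours
})

test_that("total rhs is the sum of its parts and conserves mass", {
  p <- ref_params()
  set.seed(11)
  for (rep in 1:5) {
    G <- random_state(p)
    dG <- total_rhs(G, p)
    expect_equal(dG, diffusion_rhs(G, p) + selection_rhs(G, p))
    expect_lt(abs(sum(dG)), 1e-12)
    expect_lt(abs(sum(diffusion_rhs(G, p))), 1e-12)
    expect_lt(abs(sum(selection_rhs(G, p))), 1e-12)
  }
  # rho = 0 with all mass at i = 0 is an absorbing configuration
  p0 <- ref_params(rho = 0)
  G0 <- 1 / 6 * Reduce(`+`, lapply(0:5, function(l) point_state(p0, 0, l)))
  expect_equal(max(abs(total_rhs(group_distribution(G0, p0), p0))), 0)
})

test_that("R and C++ right-hand sides agree on random states", {
  set.seed(21)
  for (rep in 1:10) {
    p <- model_params(n = sample(3:20, 1), beta = runif(1, 0, 0.3),
                      gamma = runif(1, 0.5, 2), rho = runif(1, 0, 0.5),
                      b = runif(1, 0, 0.3), c = runif(1, 0, 2),
                      mu = 10^runif(1, -5, -2),
                      l_min = 0, l_max = sample(1:5, 1))
    G <- random_state(p)
    a <- total_rhs(G, p)
    b_ <- instdyn:::cpp_total_rhs(G, p$n, p$l_min, p$beta, p$gamma, p$rho,
                                  p$b, p$c, p$mu)
    expect_lt(max(abs(a - b_)), 1e-13)
  }
})

test_that("rescaling beta, gamma and time leaves diffusion unchanged", {
  # (beta, gamma) -> (k beta, k gamma) with t -> t / k is a pure change of
  # time units for the diffusion dynamics (rho = 0 removes selection)
  p1 <- ref_params(rho = 0, beta = 0.08, gamma = 1)
  p2 <- ref_params(rho = 0, beta = 0.16, gamma = 2)
  G0 <- initial_condition(p1)
  tr1 <- integrate_trajectory(G0, p1, t_end = 10, dt = 0.01,
                              record_every = 10)
  tr2 <- integrate_trajectory(G0, p2, t_end = 5, dt = 0.005,
                              record_every = 5)
  G1 <- tr1$states[, , dim(tr1$states)[3]]
  G2 <- tr2$states[, , dim(tr2$states)[3]]
  expect_lt(max(abs(G1 - G2)), 1e-10)
})
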