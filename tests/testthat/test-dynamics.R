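test_that("population rate formulas evaluate exactly", {
  expect_equal(pop_rate("pop_climate", list(rN = 0.1, k = 1, alpha = 0.2),
                        N_prev = 0.5, C_prev = 0.3),
               0.1 * (1 - 0.5 + 0.06))
  # logistic equilibrium: N = k with no climate effect
  expect_equal(pop_rate("pop_climate", list(rN = 0.4, k = 2, alpha = 0.5),
                        N_prev = 2, C_prev = 0), 0)
  # beta = 0 collapses the warfare variant onto the plain logistic
  for (N in c(0.1, 1, 3)) {
    expect_equal(
      pop_rate("pop_warfare", list(rN = 0.3, k = 2, beta = 0),
               N_prev = N, W_prev = 5),
      pop_rate("pop_climate", list(rN = 0.3, k = 2, alpha = 0),
               N_prev = N, C_prev = 1))
  }
})

test_that("warfare rate formulas evaluate exactly", {
  expect_equal(war_rate("war_additive_climate",
                        list(lambda = 0.02, psi = 0.5, mu = 0.3),
                        W_prev = 1, N_prev = 10, C_prev = 0.4), 0.1)
  # conflict equilibrium lambda * N = mu
  expect_equal(war_rate("war_basic", list(lambda = 0.2, mu = 0.1),
                        W_prev = 3, N_prev = 0.5), 0)
  # pressure variant at C = 1 equals the basic variant
  for (N in c(0.2, 1, 4)) {
    expect_equal(
      war_rate("war_pressure", list(lambda = 0.3, mu = 0.1),
               W_prev = 1, N_prev = N, C_prev = 1),
      war_rate("war_basic", list(lambda = 0.3, mu = 0.1),
               W_prev = 1, N_prev = N))
  }
})

test_that("model nesting identities hold across random states", {
  states <- withr::with_seed(3, data.frame(N = runif(20, 0.05, 3),
                                           W = runif(20, 0, 6),
                                           C = runif(20, 10, 50)))
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    # full productivity model with gamma = 0 reduces to the climate model
    expect_equal(
      pop_rate("pop_climate_warfare",
               list(rN = 0.3, k = 1, alpha = 0.02, gamma = 0),
               N_prev = s$N, C_prev = s$C, W_prev = s$W),
      pop_rate("pop_climate", list(rN = 0.3, k = 1, alpha = 0.02),
               N_prev = s$N, C_prev = s$C))
    # with alpha = 0 it matches the warfare variant at beta = -rN * gamma
    gamma <- -0.12
    expect_equal(
      pop_rate("pop_climate_warfare",
               list(rN = 0.3, k = 1, alpha = 0, gamma = gamma),
               N_prev = s$N, C_prev = s$C, W_prev = s$W),
      pop_rate("pop_warfare", list(rN = 0.3, k = 1, beta = -0.3 * gamma),
               N_prev = s$N, W_prev = s$W))
    # additive-climate warfare model with psi = 0 reduces to the basic one
    expect_equal(
      war_rate("war_additive_climate",
               list(lambda = 0.2, psi = 0, mu = 0.1),
               W_prev = s$W + 0.1, N_prev = s$N, C_prev = s$C),
      war_rate("war_basic", list(lambda = 0.2, mu = 0.1),
               W_prev = s$W + 0.1, N_prev = s$N))
  }
})

test_that("rate functions are monotone in population where theory says so", {
  Ns <- seq(0.1, 3, length.out = 30)
  r_pop <- pop_rate("pop_climate", list(rN = 0.3, k = 1, alpha = 0.01),
                    N_prev = Ns, C_prev = 35)
  expect_true(all(diff(r_pop) < 0))
  r_war <- war_rate("war_basic", list(lambda = 0.2, mu = 0.1),
                    W_prev = 1, N_prev = Ns)
  expect_true(all(diff(r_war) > 0))
})

test_that("foreign parameters, missing forcings and bad states error", {
  expect_error(pop_rate("pop_climate",
                        list(rN = 0.3, k = 1, alpha = 0, beta = 1),
                        N_prev = 1, C_prev = 1), "foreign")
  expect_error(pop_rate("pop_climate", list(rN = 0.3, k = 1),
                        N_prev = 1, C_prev = 1), "missing")
  expect_error(pop_rate("pop_climate", list(rN = 0.3, k = 1, alpha = 0.1),
                        N_prev = 1), "requires `C`")
  expect_error(pop_rate("pop_climate", list(rN = -0.3, k = 1, alpha = 0),
                        N_prev = 1, C_prev = 1), "positive")
  expect_error(pop_rate("war_basic", list(lambda = 1, mu = 1),
                        N_prev = 1), "not a population variant")
  expect_error(war_rate("war_pressure", list(lambda = 1, mu = 1),
                        W_prev = 1, N_prev = 1, C_prev = 0),
               "pressure ratio undefined")
})

test_that("one step multiplies by exp(rate) and preserves positivity", {
  p <- list(rN = 0.1, k = 1, alpha = 0.2)
  expect_equal(step_state("pop_climate", p, 0.5, list(C = 0.3)),
               0.5 * exp(0.056))
  # equilibrium: zero rate leaves the state unchanged
  expect_equal(step_state("pop_climate", p, 1, list(C = 0)), 1)
  expect_equal(step_state("war_basic", list(lambda = 0.2, mu = 0.1),
                          2, list(N = 0.5)), 2)
  # extreme rates are clipped with a warning but the state stays positive
  expect_warning(
    out <- step_state("war_basic", list(lambda = 100, mu = 0.1),
                      1, list(N = 10)), "clipped")
  expect_true(out > 0 && is.finite(out))
})

test_that("the subtractive warfare-mortality reading is available", {
  p <- list(rN = 0.3, k = 1, beta = 0.1)
  manual <- 0.5 * exp(0.3 * (1 - 0.5)) - 0.1 * 2
  expect_equal(step_state("pop_warfare", p, 0.5, list(W = 2),
                          warfare_term = "subtract"), manual)
  expect_error(step_state("pop_warfare", p, 0.01, list(W = 5),
                          warfare_term = "subtract"), "non-positive")
})

test_that("trajectory simulation equals manual iteration of the map", {
  C <- proxy_series(seq(50, by = 25, length.out = 10),
                    withr::with_seed(9, runif(10, 20, 50)))
  p <- list(rN = 0.3, k = 1, alpha = 0.01)
  traj <- simulate_trajectory("pop_climate", p, initial = 0.1,
                              forcings = list(C = C))
  manual <- numeric(10)
  manual[1] <- 0.1
  for (i in 2:10) {
    manual[i] <- manual[i - 1] *
      exp(0.3 * (1 - manual[i - 1] / 1 + 0.01 * C$values[i - 1]))
  }
  expect_equal(traj$values, manual)
  expect_identical(traj$times, C$times)
  expect_identical(traj$step, C$step)
})

test_that("constant forcing at equilibrium yields a constant trajectory", {
  C <- proxy_series(seq(0, 225, by = 25), rep(10, 10))
  # N = k * (1 + alpha * C) is the lateral-perturbation equilibrium
  p <- list(rN = 0.4, k = 1, alpha = 0.02)
  traj <- simulate_trajectory("pop_climate", p, initial = 1.2,
                              forcings = list(C = C))
  expect_equal(traj$values, rep(1.2, 10))
})

test_that("divergence is reported with the offending step", {
  C <- proxy_series(seq(0, 225, by = 25), rep(30, 10))
  expect_error(
    suppressWarnings(simulate_trajectory(
      "pop_climate", list(rN = 1, k = 1, alpha = 1), initial = 1,
      forcings = list(C = C), cap = 1e6)),
    "diverged at step")
  expect_error(simulate_trajectory("pop_climate",
                                   list(rN = 0.3, k = 1, alpha = 0.1),
                                   initial = 1, forcings = list()),
               "missing forcing")
})

test_that("the logistic map converges to k across the stable regime", {
  C <- proxy_series(seq_len(600), rep(1, 600), step = 1)
  for (rN in c(0.1, 0.5, 1, 1.5, 1.9)) {
    for (N0 in c(0.05, 0.5, 2.5)) {
      traj <- simulate_trajectory("pop_climate",
                                  list(rN = rN, k = 1, alpha = 0),
                                  initial = N0, forcings = list(C = C))
      expect_equal(traj$values[600], 1, tolerance = 1e-6)
    }
  }
})

test_that("coupled simulation equals the manual two-variable loop", {
  C <- proxy_series(seq(50, by = 25, length.out = 12),
                    withr::with_seed(4, runif(12, 25, 45)))
  params <- list(rN = 0.3, k = 1, alpha = 0.01, gamma = -0.1,
                 lambda = 0.3, mu = 0.1)
  out <- simulate_coupled("pop_climate_warfare", "war_basic", params,
                          N0 = 0.1, W0 = 0.5, climate = C)
  N <- W <- numeric(12)
  N[1] <- 0.1; W[1] <- 0.5
  for (i in 2:12) {
    N[i] <- N[i - 1] * exp(0.3 * (1 - N[i - 1] + 0.01 * C$values[i - 1] -
                                    0.1 * W[i - 1]))
    W[i] <- W[i - 1] * exp(0.3 * N[i - 1] - 0.1)
  }
  expect_equal(out$N$values, N)
  expect_equal(out$W$values, W)
  expect_true(all(out$N$values > 0 & out$W$values > 0))
})
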