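test_that("the BIC formula and its elementary properties hold", {
  expect_equal(bic_rss(1, 10, 2), 10 * log(0.1) + 2 * log(10))
  # one extra parameter at equal RSS costs exactly ln(n)
  expect_equal(bic_rss(0.5, 36, 3) - bic_rss(0.5, 36, 2), log(36))
  rss_grid <- c(0.1, 0.5, 1, 4)
  bics <- vapply(rss_grid, bic_rss, numeric(1), n = 36, p = 2)
  expect_true(all(diff(bics) > 0))
  expect_warning(out <- bic_rss(0, 10, 2), "perfect fit")
  expect_identical(out, -Inf)
})

test_that("the coefficient of prediction anchors and hand value are exact", {
  obs <- c(0.2, 0.5, 1.1, 0.8)
  expect_identical(coefficient_of_prediction(obs, obs), 1)
  expect_identical(coefficient_of_prediction(obs, rep(mean(obs), 4)), 0)
  expect_equal(coefficient_of_prediction(c(1, 2, 3), c(3, 2, 1)), -3)
})

test_that("the coefficient of prediction is shift- and scale-invariant", {
  obs <- withr::with_seed(11, rnorm(20))
  pred <- withr::with_seed(12, obs + rnorm(20, sd = 0.5))
  base <- coefficient_of_prediction(obs, pred)
  for (a in c(-3, 10)) {
    expect_equal(coefficient_of_prediction(obs + a, pred + a), base)
  }
  for (c in c(-2, 0.1, 40)) {
    expect_equal(coefficient_of_prediction(c * obs, c * pred), base)
  }
})

test_that("the coefficient of prediction rejects ill-posed input", {
  expect_error(coefficient_of_prediction(1:3, 1:4), "equal length")
  expect_error(coefficient_of_prediction(1, 1), "at least 2")
  expect_error(coefficient_of_prediction(rep(2, 5), 1:5), "constant")
})

test_that("noise-free data returns the generating parameters exactly", {
  presets <- list(scenario_northern_like(seed = 3, obs_noise_sd = 0),
                  scenario_southern_like(seed = 3, obs_noise_sd = 0),
                  scenario_boom_bust(seed = 3, obs_noise_sd = 0))
  for (sc in presets) {
    synth <- generate_coupled(sc)
    covs <- list(N = synth$N, W = synth$W, C = synth$C)
    for (variant in c(sc$pop_variant, sc$war_variant)) {
      spec <- model_spec(variant)
      response <- if (spec$target == "population") {
        growth_rates(synth$N)
      } else {
        growth_rates(synth$W)
      }
      fit <- quiet_fit(spec, response, covs)
      truth <- unlist(sc$true_params[spec$params])
      expect_true(fit$converged)
      expect_lt(max(abs(unlist(fit$params) - truth) / abs(truth)), 1e-6)
      expect_lt(fit$rss, 1e-12)
    }
  }
})

test_that("the NLS solution matches the closed-form linearization", {
  # every variant's rate is linear in transformed coefficients, so an
  # ordinary least-squares fit in that basis is an independent oracle
  synth <- generate_coupled(scenario_northern_like(seed = 21,
                                                   obs_noise_sd = 0.05))
  r <- growth_rates(synth$N)
  fit <- quiet_fit("pop_climate", r, list(N = synth$N, C = synth$C))
  df <- data.frame(rate = r$values,
                   N = utils::head(synth$N$values, -1),
                   C = utils::head(synth$C$values, -1))
  ols <- stats::lm(rate ~ N + C, data = df)
  b <- stats::coef(ols)
  expect_equal(fit$params$rN, unname(b[1]), tolerance = 1e-6)
  expect_equal(fit$params$k, unname(-b[1] / b[2]), tolerance = 1e-6)
  expect_equal(fit$params$alpha, unname(b[3] / b[1]), tolerance = 1e-6)
  expect_equal(fit$rss, sum(stats::residuals(ols)^2), tolerance = 1e-8)
  expect_equal(fit$r_squared, summary(ols)$r.squared, tolerance = 1e-8)

  # warfare response: w = lambda * N - mu is a straight line in N
  rw <- growth_rates(synth$W)
  fitw <- quiet_fit("war_basic", rw,
                    list(N = synth$N, W = synth$W, C = synth$C))
  dfw <- data.frame(rate = rw$values, N = utils::head(synth$N$values, -1))
  bw <- stats::coef(stats::lm(rate ~ N, data = dfw))
  expect_equal(fitw$params$lambda, unname(bw[2]), tolerance = 1e-6)
  expect_equal(fitw$params$mu, unname(-bw[1]), tolerance = 1e-6)
})

test_that("moderate noise still recovers rN and k well", {
  errs <- vapply(1:20, function(i) {
    synth <- generate_coupled(scenario_northern_like(seed = 500 + i,
                                                     obs_noise_sd = 0.01))
    fit <- quiet_fit("pop_climate", growth_rates(synth$N),
                     list(N = synth$N, C = synth$C))
    c(abs(fit$params$rN - 0.3) / 0.3, abs(fit$params$k - 0.35) / 0.35)
  }, numeric(2))
  expect_lt(stats::median(errs[1, ]), 0.1)
  expect_lt(stats::median(errs[2, ]), 0.1)
})

test_that("a nested model never explains more variance than its superset", {
  synth <- generate_coupled(scenario_boom_bust(seed = 8,
                                               obs_noise_sd = 0.02))
  covs <- list(N = synth$N, W = synth$W, C = synth$C)
  r <- growth_rates(synth$N)
  r2_nested <- quiet_fit("pop_climate", r, covs)$r_squared
  r2_full <- quiet_fit("pop_climate_warfare", r, covs)$r_squared
  expect_gte(r2_full, r2_nested - 1e-8)
})

test_that("fitting validates degrees of freedom and flags degeneracy", {
  synth <- generate_coupled(scenario_northern_like(seed = 2))
  short <- rate_series(synth$N$times[2:4], growth_rates(synth$N)$values[1:3],
                       step = 25)
  expect_error(quiet_fit("pop_climate_warfare", short,
                         list(N = synth$N, W = synth$W, C = synth$C)),
               "more observations")
  # a constant covariate is reported in the fit's warnings
  const_C <- proxy_series(synth$C$times, rep(35, 36))
  fit <- quiet_fit("pop_climate", growth_rates(synth$N),
                   list(N = synth$N, C = const_C))
  expect_true(any(grepl("constant", fit$warnings)))
})

test_that("trajectory validation scores the generating model at 1", {
  sc <- scenario_southern_like(seed = 13, obs_noise_sd = 0)
  synth <- generate_coupled(sc)
  fit <- quiet_fit("pop_warfare", growth_rates(synth$N),
                   list(N = synth$N, W = synth$W))
  fit <- validate_trajectory(fit, synth$N, list(W = synth$W))
  expect_equal(fit$sigma2, 1, tolerance = 1e-10)
  # compositional identity with an explicit simulation
  expect_equal(fit$sigma2,
               coefficient_of_prediction(synth$N$values,
                                         fit$trajectory$values))
  # a deliberately damaged carrying capacity predicts worse than truth
  bad <- fit
  bad$params$k <- bad$params$k / 2
  bad <- validate_trajectory(bad, synth$N, list(W = synth$W))
  expect_lt(bad$sigma2, 1)
})

test_that("diverging validation yields -Inf with a flag, honestly", {
  sc <- scenario_southern_like(seed = 13, obs_noise_sd = 0)
  synth <- generate_coupled(sc)
  fit <- quiet_fit("pop_warfare", growth_rates(synth$N),
                   list(N = synth$N, W = synth$W))
  boom <- fit
  boom$params <- list(rN = 49, k = 1e9, beta = 1e-9)
  expect_warning(
    boom <- validate_trajectory(boom, synth$N, list(W = synth$W)),
    "diverged")
  expect_identical(boom$sigma2, -Inf)
  expect_true(boom$diverged)
  nc <- fit
  nc$converged <- FALSE
  expect_error(validate_trajectory(nc, synth$N, list(W = synth$W)),
               "did not converge")
})

test_that("model comparison sorts by BIC with documented tie-breaks", {
  n <- 36
  f_small <- stub_fit("war_basic", n, 2, rss = 0.5, sigma2 = 0.4)
  # rss chosen so both models land on exactly the same BIC
  rss_big <- n * exp((bic_rss(0.5, n, 2) - 3 * log(n)) / n)
  f_big <- stub_fit("war_additive_climate", n, 3, rss = rss_big,
                    sigma2 = 0.9)
  tab <- compare_models(list(f_big, f_small))
  expect_equal(tab$bic[1], tab$bic[2])
  expect_identical(tab$model[1], "war_basic")  # fewer parameters wins ties
  expect_equal(tab$delta_bic, c(0, 0))
  expect_true(tab$best[1] && !tab$best[2])

  single <- compare_models(list(f_small))
  expect_equal(nrow(single), 1)
  expect_equal(single$delta_bic, 0)
  expect_true(single$best)

  mixed_n <- stub_fit("war_basic", 20, 2, rss = 0.5)
  expect_error(compare_models(list(f_small, mixed_n)), "refused")
  mixed_target <- stub_fit("pop_climate", n, 3, rss = 0.5)
  expect_error(compare_models(list(f_small, mixed_target)), "refused")
})

test_that("BIC selection of the generating variant improves with n", {
  frac_for_n <- function(n_steps, seeds) {
    hits <- vapply(seeds, function(s) {
      sc <- synthetic_scenario(
        "pop_climate", "war_additive_climate",
        true_params = scenario_northern_like()$true_params,
        n_steps = n_steps, step = 25, start_year = 50,
        N0 = 0.05, W0 = 2,
        climate = list(kind = "ar1", level = 35, sd = 4, rho = 0.8),
        obs_noise_sd = 0.02, seed = s)
      synth <- generate_coupled(sc)
      covs <- list(N = synth$N, W = synth$W, C = synth$C)
      r <- growth_rates(synth$N)
      quiet_fit("pop_climate", r, covs)$bic <
        quiet_fit("pop_warfare", r, covs)$bic
    }, logical(1))
    mean(hits)
  }
  seeds <- 700 + 1:25
  expect_gte(frac_for_n(150, seeds), frac_for_n(36, seeds) - 0.04)
})
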