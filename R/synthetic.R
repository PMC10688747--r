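#' Generate a synthetic hydroclimate proxy series
#'
#' Emulates the statistical character of a smoothed lithic-concentration
#' proxy (positive, slowly varying, autocorrelated) without reproducing
#' any real record.  Four kinds are available:
#'
#' * `constant` — every value equals `level`;
#' * `trend` — linear drift `level + slope * (0:(n-1))`;
#' * `ar1` — stationary AR(1) around `level` with marginal standard
#'   deviation `sd` and lag-1 autocorrelation `rho`;
#' * `regime_shift` — AR(1) fluctuations whose mean switches from `level`
#'   to `level2` at step `shift_step` (emulating a multicentennial change
#'   of mean state such as a sustained La Nina-like phase).
#'
#' @param kind One of `"constant"`, `"trend"`, `"ar1"`, `"regime_shift"`.
#' @param n_steps Number of grid points (>= 2).
#' @param level Mean level (percent-like scale; default 35).
#' @param sd Marginal standard deviation of the AR(1) kinds.
#' @param rho Lag-1 autocorrelation of the AR(1) kinds.
#' @param slope Per-step drift of the `trend` kind.
#' @param level2 Post-shift mean of the `regime_shift` kind.
#' @param shift_step Step index at which the mean switches.
#' @param start_year,step Calendar grid of the output series.
#' @param seed Optional integer seed; the global RNG state is preserved.
#' @return A positive [proxy_series()]; parameter choices that produce a
#'   non-positive value are rejected with an error.
#' @examples
#' generate_climate("ar1", 36, seed = 1)
#' @export
generate_climate <- function(kind = c("ar1", "constant", "trend",
                                      "regime_shift"),
                             n_steps, level = 35, sd = 5, rho = 0.8,
                             slope = -0.2, level2 = 25,
                             shift_step = max(2, floor(2 * n_steps / 3)),
                             start_year = 50, step = 25, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_steps >= 2)
  gen <- function() {
    means <- switch(kind,
      constant = rep(level, n_steps),
      trend = level + slope * (seq_len(n_steps) - 1),
      ar1 = rep(level, n_steps),
      regime_shift = c(rep(level, shift_step - 1),
                       rep(level2, n_steps - shift_step + 1)))
    if (kind %in% c("ar1", "regime_shift")) {
      sd_innov <- sd * sqrt(1 - rho^2)
      x <- numeric(n_steps)
      x[1] <- means[1] + stats::rnorm(1, 0, sd)
      for (i in 2:n_steps) {
        x[i] <- means[i] + rho * (x[i - 1] - means[i - 1]) +
          stats::rnorm(1, 0, sd_innov)
      }
      x
    } else {
      means
    }
  }
  vals <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  if (any(vals <= 0)) {
    stop("climate parameters produced non-positive values; ",
         "increase `level` or reduce `sd`", call. = FALSE)
  }
  proxy_series(seq(start_year, by = step, length.out = n_steps), vals,
               label = paste0("synthetic climate (", kind, ")"),
               step = step)
}

#' Define a synthetic ground-truth scenario
#'
#' Bundles everything needed to generate coupled population-warfare-
#' climate series with known parameters: the generating variant pair,
#' true parameter values, initial conditions, the climate generator
#' settings, the observation-noise level and the seed.  Observation noise
#' is multiplicative lognormal on both endogenous series, so log rates
#' carry additive Gaussian noise — the same error structure the
#' least-squares fitting layer assumes.
#'
#' @param pop_variant,war_variant Generating variants (one population,
#'   one warfare model).
#' @param true_params Named list covering the parameters of both
#'   variants.
#' @param n_steps Number of grid points (default 36, the length of a
#'   typical 875-year window at 25-year steps).
#' @param step Grid spacing in years (default 25).
#' @param start_year First calendar year AD of the grid.
#' @param N0,W0 Initial population and warfare values (positive).
#' @param climate List of arguments for [generate_climate()] (without
#'   `n_steps`, grid or seed, which the scenario supplies).
#' @param obs_noise_sd Standard deviation of the lognormal observation
#'   error (0 for noise-free output).
#' @param seed Integer seed; the same scenario and seed always produce
#'   bit-identical output.
#' @param label Scenario label.
#' @return An object of class `andean_scenario`.
#' @seealso [scenario_northern_like()], [scenario_southern_like()],
#'   [scenario_boom_bust()], [generate_coupled()]
#' @export
synthetic_scenario <- function(pop_variant, war_variant, true_params,
                               n_steps = 36, step = 25, start_year = 50,
                               N0 = 0.05, W0 = 0.5,
                               climate = list(kind = "ar1", level = 35,
                                              sd = 5, rho = 0.8),
                               obs_noise_sd = 0.01, seed = 1,
                               label = "synthetic scenario") {
  pspec <- model_spec(pop_variant)
  wspec <- model_spec(war_variant)
  stopifnot(pspec$target == "population", wspec$target == "warfare",
            N0 > 0, W0 > 0, obs_noise_sd >= 0, n_steps >= 3)
  need <- union(pspec$params, wspec$params)
  missing <- setdiff(need, names(true_params))
  if (length(missing)) {
    stop("true_params is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(pop_variant = pspec$variant, war_variant = wspec$variant,
                 true_params = as.list(true_params)[need],
                 n_steps = n_steps, step = step, start_year = start_year,
                 N0 = N0, W0 = W0, climate = climate,
                 obs_noise_sd = obs_noise_sd, seed = as.integer(seed),
                 label = label),
            class = "andean_scenario")
}

#' @export
print.andean_scenario <- function(x, ...) {
  cat(sprintf("<andean_scenario> %s\n", x$label))
  cat(sprintf("  %s + %s, %d steps of %d yr from AD %d, noise sd %g, seed %d\n",
              x$pop_variant, x$war_variant, x$n_steps, x$step,
              x$start_year, x$obs_noise_sd, x$seed))
  cat("  truth:",
      paste(sprintf("%s = %g", names(x$true_params),
                    unlist(x$true_params)), collapse = ", "), "\n")
  invisible(x)
}

#' Northern-like preset: climate-driven population dynamics
#'
#' A 36-step (875-year) scenario on the AD 50-925 grid in which the
#' population follows the climate-lateral-perturbation model and warfare
#' follows the additive population + climate model — the qualitative
#' regime inferred for the northern coastal societies.
#'
#' @param seed Scenario seed.
#' @param obs_noise_sd Lognormal observation-noise standard deviation.
#' @return An `andean_scenario`.
#' @export
scenario_northern_like <- function(seed = 1, obs_noise_sd = 0.01) {
  synthetic_scenario(
    pop_variant = "pop_climate", war_variant = "war_additive_climate",
    true_params = list(rN = 0.3, k = 0.35, alpha = 0.05,
                       lambda = 0.2, psi = 0.004, mu = 0.28),
    n_steps = 36, step = 25, start_year = 50, N0 = 0.05, W0 = 2,
    climate = list(kind = "regime_shift", level = 38, sd = 4, rho = 0.8,
                   level2 = 26, shift_step = 25),
    obs_noise_sd = obs_noise_sd, seed = seed,
    label = "northern-like (climate-driven)")
}

#' Southern-like preset: warfare-driven boom and bust
#'
#' A 40-step (975-year) scenario on the AD 250-1225 grid in which warfare
#' mortality drives the population model and warfare itself is driven by
#' population pressure (the population/climate ratio), with a
#' regime-shift climate whose mean state drops mid-series — the
#' qualitative regime inferred for the southern highland societies.
#'
#' @inheritParams scenario_northern_like
#' @return An `andean_scenario`.
#' @export
scenario_southern_like <- function(seed = 1, obs_noise_sd = 0.01) {
  synthetic_scenario(
    pop_variant = "pop_warfare", war_variant = "war_pressure",
    true_params = list(rN = 0.35, k = 1, beta = 0.05,
                       lambda = 6, mu = 0.05),
    n_steps = 40, step = 25, start_year = 250, N0 = 0.05, W0 = 0.5,
    climate = list(kind = "regime_shift", level = 38, sd = 4, rho = 0.8,
                   level2 = 28, shift_step = 27),
    obs_noise_sd = obs_noise_sd, seed = seed,
    label = "southern-like (warfare-driven)")
}

#' Boom-bust preset: full productivity coupling
#'
#' Population follows the climate + warfare land-productivity model and
#' warfare the basic population-driven model, producing a multi-century
#' rise of population followed by a sustained decline while warfare keeps
#' rising through the collapse phase.
#'
#' @inheritParams scenario_northern_like
#' @return An `andean_scenario`.
#' @export
scenario_boom_bust <- function(seed = 1, obs_noise_sd = 0.01) {
  synthetic_scenario(
    pop_variant = "pop_climate_warfare", war_variant = "war_basic",
    true_params = list(rN = 0.3, k = 1, alpha = 0.01, gamma = -0.15,
                       lambda = 0.3, mu = 0.1),
    n_steps = 36, step = 25, start_year = 50, N0 = 0.05, W0 = 0.5,
    climate = list(kind = "ar1", level = 35, sd = 5, rho = 0.8),
    obs_noise_sd = obs_noise_sd, seed = seed,
    label = "boom-bust (productivity coupling)")
}

#' Generate coupled series from a scenario
#'
#' Draws the climate series, iterates the coupled deterministic maps for
#' the latent population and warfare trajectories, and applies
#' multiplicative lognormal observation noise.  The latent trajectories
#' are deterministic given the climate draw, so changing the noise level
#' never changes the latent truth.
#'
#' @param scenario An [synthetic_scenario()] object.
#' @return A list of class `andean_synth` with observed series `N`, `W`,
#'   `C` (all [proxy_series()]), the noise-free `latent` list, the
#'   `truth` parameter list and the `scenario` itself.
#' @examples
#' synth <- generate_coupled(scenario_northern_like(seed = 7))
#' plot(synth$N$times, synth$N$values, type = "l")
#' @export
generate_coupled <- function(scenario) {
  stopifnot(inherits(scenario, "andean_scenario"))
  out <- withr::with_seed(scenario$seed, {
    cl_args <- c(scenario$climate,
                 list(n_steps = scenario$n_steps,
                      start_year = scenario$start_year,
                      step = scenario$step))
    C <- do.call(generate_climate, cl_args)
    latent <- tryCatch(
      simulate_coupled(scenario$pop_variant, scenario$war_variant,
                       scenario$true_params, scenario$N0, scenario$W0, C),
      error = function(e) {
        stop("scenario rejected: ", conditionMessage(e),
             "\n  truth: ",
             paste(sprintf("%s = %g", names(scenario$true_params),
                           unlist(scenario$true_params)), collapse = ", "),
             call. = FALSE)
      })
    n <- scenario$n_steps
    noise_N <- exp(stats::rnorm(n, 0, scenario$obs_noise_sd))
    noise_W <- exp(stats::rnorm(n, 0, scenario$obs_noise_sd))
    list(C = C, latent = latent, noise_N = noise_N, noise_W = noise_W)
  })
  obs_N <- proxy_series(out$latent$N$times,
                        out$latent$N$values * out$noise_N,
                        label = "population (observed)",
                        step = scenario$step)
  obs_W <- proxy_series(out$latent$W$times,
                        out$latent$W$values * out$noise_W,
                        label = "warfare (observed)",
                        step = scenario$step)
  structure(list(N = obs_N, W = obs_W, C = out$C,
                 latent = out$latent,
                 truth = scenario$true_params,
                 scenario = scenario),
            class = "andean_synth")
}

default_fixture_scenario <- function(variant, seed) {
  presets <- list(
    pop_climate = scenario_northern_like(seed),
    pop_warfare = scenario_southern_like(seed),
    pop_climate_warfare = scenario_boom_bust(seed),
    war_basic = scenario_boom_bust(seed),
    war_additive_climate = scenario_northern_like(seed),
    war_pressure = scenario_southern_like(seed))
  presets[[variant]]
}

#' Write a set of CSV test fixtures
#'
#' Writes, into `dir`: one `fixture_<variant>.csv` per model variant with
#' columns `year`, `N`, `W`, `C` (observed series from a scenario whose
#' generating process features that variant), and
#' `fixture_sdata_synthetic.csv`, a 36-row table with the nine exchange
#' columns `calBP`, `yearAD`, `SPDn`, `SPDnn`, `Rn`, `Rnn`, `LithPct`,
#' `War`, `Rwar` (875-year span at 25-year steps).  The unnormalized SPD
#' column is emulated as a rescaled second noise realization of the same
#' latent population.  A `fixtures.yml` sidecar records the seed and
#' scenario of every file; regeneration with the same seed is
#' byte-identical.  All series are synthetic.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer seed.
#' @return Invisibly, the paths of the written files.
#' @export
make_fixture_set <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- list(seed = seed, files = list())
  for (v in names(.variant_info)) {
    sc <- default_fixture_scenario(v, seed)
    synth <- generate_coupled(sc)
    df <- data.frame(year = synth$N$times, N = synth$N$values,
                     W = synth$W$values, C = synth$C$values)
    path <- file.path(dir, paste0("fixture_", v, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    paths <- c(paths, path)
    meta$files[[basename(path)]] <- list(scenario = sc$label, seed = seed,
                                         variant = v)
  }
  sc <- scenario_northern_like(seed)
  synth <- generate_coupled(sc)
  spd_nn <- withr::with_seed(seed + 1, {
    proxy_series(synth$N$times,
                 1.15 * synth$latent$N$values *
                   exp(stats::rnorm(sc$n_steps, 0, sc$obs_noise_sd)),
                 label = "population (observed, unnormalized-like)",
                 step = sc$step)
  })
  tab <- sdata_table(synth$N, spd_nn, synth$C, synth$W)
  path <- file.path(dir, "fixture_sdata_synthetic.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  paths <- c(paths, path)
  meta$files[[basename(path)]] <- list(scenario = sc$label, seed = seed,
                                       note = "synthetic, nine-column exchange layout")
  yaml_path <- file.path(dir, "fixtures.yml")
  yaml::write_yaml(meta, yaml_path)
  invisible(c(paths, yaml_path))
}
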