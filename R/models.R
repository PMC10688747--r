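#' The six dynamic model variants
#'
#' The analysis couples two endogenous variables — population size `N`
#' (proxied by SPD mass) and warfare intensity `W` — with an exogenous
#' hydroclimate proxy `C`.  Each variant is a discrete-time Ricker-type
#' map `X[t] = X[t-1] * exp(rate)` whose log rate depends on the state and
#' forcings at the previous step:
#'
#' * `pop_climate`: `rN * (1 - N/k + alpha * C)` — logistic growth with
#'   climate as a lateral perturbation of the carrying capacity.
#' * `pop_warfare`: `rN * (1 - N/k) - beta * W` — logistic growth with
#'   direct warfare mortality.
#' * `pop_climate_warfare`: `rN * (1 - N/k + alpha * C + gamma * W)` —
#'   both climate and warfare acting on land productivity.
#' * `war_basic`: `lambda * N - mu` — conflict onset proportional to
#'   population density with exponential decay `mu`.
#' * `war_additive_climate`: `lambda * N + psi * C - mu` — an additive
#'   climate effect on conflict.
#' * `war_pressure`: `lambda * N / C - mu` — conflict driven by population
#'   pressure, the ratio of population to resource availability.
#'
#' Parameters `rN`, `k`, `lambda` and `mu` are positive; the coefficients
#' `alpha`, `beta`, `gamma` and `psi` are unrestricted in sign (the model
#' layer is agnostic about the direction of the climate proxy — high
#' lithic concentrations mean a wetter coast but drier highlands, and the
#' coefficients absorb the direction).
#'
#' @return A data frame listing, for each variant, its target variable and
#'   free parameters.
#' @export
model_variants <- function() {
  data.frame(
    variant = c("pop_climate", "pop_warfare", "pop_climate_warfare",
                "war_basic", "war_additive_climate", "war_pressure"),
    target = c("population", "population", "population",
               "warfare", "warfare", "warfare"),
    parameters = c("rN, k, alpha", "rN, k, beta", "rN, k, alpha, gamma",
                   "lambda, mu", "lambda, psi, mu", "lambda, mu"),
    covariates = c("N, C", "N, W", "N, C, W", "W, N", "W, N, C", "W, N, C")
  )
}

.variant_info <- list(
  pop_climate = list(target = "population",
                     params = c("rN", "k", "alpha"), needs = c("N", "C")),
  pop_warfare = list(target = "population",
                     params = c("rN", "k", "beta"), needs = c("N", "W")),
  pop_climate_warfare = list(target = "population",
                             params = c("rN", "k", "alpha", "gamma"),
                             needs = c("N", "C", "W")),
  war_basic = list(target = "warfare",
                   params = c("lambda", "mu"), needs = c("W", "N")),
  war_additive_climate = list(target = "warfare",
                              params = c("lambda", "psi", "mu"),
                              needs = c("W", "N", "C")),
  war_pressure = list(target = "warfare",
                      params = c("lambda", "mu"), needs = c("W", "N", "C"))
)

# positive-constrained parameters (fitted through a log transform)
.positive_params <- c("rN", "k", "lambda", "mu")

# division guard for the population-pressure ratio N/C
.c_guard <- 1e-8

#' Model specification
#'
#' Identifies one of the six dynamic models and validates a parameter set
#' against it.
#'
#' @param variant One of the identifiers listed by [model_variants()].
#' @return A list of class `model_spec` with elements `variant`, `target`,
#'   `params` (free parameter names) and `needs` (required state/forcing
#'   variables at the previous step).
#' @export
model_spec <- function(variant) {
  variant <- match.arg(variant, names(.variant_info))
  info <- .variant_info[[variant]]
  structure(list(variant = variant, target = info$target,
                 params = info$params, needs = info$needs),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%s response); parameters: %s\n",
              x$variant, x$target, paste(x$params, collapse = ", ")))
  invisible(x)
}

check_params <- function(spec, params) {
  params <- as.list(params)
  extra <- setdiff(names(params), spec$params)
  if (length(extra)) {
    stop("parameter(s) foreign to variant ", spec$variant, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(spec$params, names(params))
  if (length(missing)) {
    stop("missing parameter(s) for variant ", spec$variant, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- intersect(.positive_params, spec$params)
  bad <- bad[vapply(params[bad], function(v) v <= 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  params
}

# Unified log-rate evaluation; vectorized over N, W, C.
model_rate <- function(spec, params, N = NULL, W = NULL, C = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  p <- check_params(spec, params)
  need_var <- function(nm, x) {
    if (is.null(x)) {
      stop("variant ", spec$variant, " requires `", nm,
           "` at the previous step", call. = FALSE)
    }
    x
  }
  switch(spec$variant,
    pop_climate = {
      N <- need_var("N", N); C <- need_var("C", C)
      p$rN * (1 - N / p$k + p$alpha * C)
    },
    pop_warfare = {
      N <- need_var("N", N); W <- need_var("W", W)
      p$rN * (1 - N / p$k) - p$beta * W
    },
    pop_climate_warfare = {
      N <- need_var("N", N); C <- need_var("C", C); W <- need_var("W", W)
      p$rN * (1 - N / p$k + p$alpha * C + p$gamma * W)
    },
    war_basic = {
      N <- need_var("N", N)
      p$lambda * N - p$mu
    },
    war_additive_climate = {
      N <- need_var("N", N); C <- need_var("C", C)
      p$lambda * N + p$psi * C - p$mu
    },
    war_pressure = {
      N <- need_var("N", N); C <- need_var("C", C)
      if (any(C <= .c_guard)) {
        stop("population-pressure ratio undefined: climate value <= ",
             .c_guard, call. = FALSE)
      }
      p$lambda * N / C - p$mu
    })
}

#' Log growth rate predicted by a population model
#'
#' Evaluates the log rate of population change for one of the population
#' variants given the state and forcings at the previous step.
#'
#' @param variant `"pop_climate"`, `"pop_warfare"` or
#'   `"pop_climate_warfare"` (or a [model_spec()]).
#' @param params Named list/vector with the variant's parameters.
#' @param N_prev Population size at the previous step (positive).
#' @param C_prev,W_prev Climate and warfare values at the previous step,
#'   required when the variant uses them.
#' @return The log growth rate (vectorized over the inputs).
#' @examples
#' pop_rate("pop_climate", list(rN = 0.1, k = 1, alpha = 0.2),
#'          N_prev = 0.5, C_prev = 0.3)  # 0.056
#' @export
pop_rate <- function(variant, params, N_prev, C_prev = NULL,
                     W_prev = NULL) {
  spec <- if (inherits(variant, "model_spec")) variant else
    model_spec(variant)
  if (spec$target != "population") {
    stop(spec$variant, " is not a population variant", call. = FALSE)
  }
  if (any(N_prev <= 0)) stop("`N_prev` must be positive", call. = FALSE)
  model_rate(spec, params, N = N_prev, W = W_prev, C = C_prev)
}

#' Log growth rate predicted by a warfare model
#'
#' @param variant `"war_basic"`, `"war_additive_climate"` or
#'   `"war_pressure"` (or a [model_spec()]).
#' @param params Named list/vector with the variant's parameters.
#' @param W_prev Warfare intensity at the previous step (positive).
#' @param N_prev Population size at the previous step.
#' @param C_prev Climate value at the previous step (positive for
#'   `war_pressure`, which divides by it).
#' @return The log growth rate of warfare intensity (vectorized).
#' @examples
#' war_rate("war_additive_climate",
#'          list(lambda = 0.02, psi = 0.5, mu = 0.3),
#'          W_prev = 1, N_prev = 10, C_prev = 0.4)  # 0.1
#' @export
war_rate <- function(variant, params, W_prev, N_prev = NULL,
                     C_prev = NULL) {
  spec <- if (inherits(variant, "model_spec")) variant else
    model_spec(variant)
  if (spec$target != "warfare") {
    stop(spec$variant, " is not a warfare variant", call. = FALSE)
  }
  if (any(W_prev <= 0)) stop("`W_prev` must be positive", call. = FALSE)
  model_rate(spec, params, N = N_prev, W = W_prev, C = C_prev)
}

# exponent clip: |rate| beyond this triggers a divergence warning and is
# clipped, so exp() cannot overflow under extreme trial parameters
.rate_clip <- 50

clip_rate <- function(rate, warn = TRUE) {
  if (any(abs(rate) > .rate_clip)) {
    if (warn) {
      warning("rate exponent clipped at +/-", .rate_clip,
              " (divergent trial parameters?)", call. = FALSE)
    }
    rate <- pmin(pmax(rate, -.rate_clip), .rate_clip)
  }
  rate
}

#' Advance the state by one time step
#'
#' Applies the exponential (Ricker-form) update
#' `X[t] = X[t-1] * exp(rate)`, which keeps the state strictly positive
#' for any finite rate.  For `pop_warfare` an alternative reading of the
#' map — warfare mortality subtracted from the updated population rather
#' than entering the exponent — is available via `warfare_term =
#' "subtract"`; the default exponent form is the one whose log transform
#' is linear in the fitted rate and is used throughout the fitting layer.
#'
#' @param variant Model variant identifier or [model_spec()].
#' @param params Named parameters of the variant.
#' @param state_prev Previous value of the target variable (`N` for
#'   population variants, `W` for warfare variants); positive.
#' @param forcing_prev Named list with the previous-step values of the
#'   other variables the variant needs (among `N`, `W`, `C`).
#' @param warfare_term `"exponent"` (default) or `"subtract"`; only
#'   meaningful for `pop_warfare`.
#' @return The next value of the target variable.
#' @examples
#' step_state("pop_climate", list(rN = 0.1, k = 1, alpha = 0.2),
#'            state_prev = 0.5, forcing_prev = list(C = 0.3))
#' @export
step_state <- function(variant, params, state_prev,
                       forcing_prev = list(),
                       warfare_term = c("exponent", "subtract")) {
  spec <- if (inherits(variant, "model_spec")) variant else
    model_spec(variant)
  warfare_term <- match.arg(warfare_term)
  if (state_prev <= 0) stop("state must be positive", call. = FALSE)
  f <- as.list(forcing_prev)
  if (spec$target == "population") {
    if (spec$variant == "pop_warfare" && warfare_term == "subtract") {
      p <- check_params(spec, params)
      if (is.null(f$W)) stop("pop_warfare requires `W`", call. = FALSE)
      r <- clip_rate(p$rN * (1 - state_prev / p$k))
      out <- state_prev * exp(r) - p$beta * f$W
      if (out <= 0) {
        stop("subtractive warfare term drove the population non-positive",
             call. = FALSE)
      }
      return(out)
    }
    r <- model_rate(spec, params, N = state_prev, W = f$W, C = f$C)
  } else {
    r <- model_rate(spec, params, N = f$N, W = state_prev, C = f$C)
  }
  state_prev * exp(clip_rate(r))
}

#' Simulate a total trajectory under one model
#'
#' Iterates the one-step map from an initial value across the whole
#' analysis grid, using *observed* exogenous forcings and the *simulated*
#' endogenous value — the trajectory is never re-anchored to the
#' observations after the first point.  This is the trajectory used for
#' model validation: it is started at the first observed value and scored
#' against the observed series with the coefficient of prediction.
#'
#' @param variant Model variant identifier or [model_spec()].
#' @param params Named parameters of the variant.
#' @param initial Initial value of the target variable (positive).
#' @param forcings Named list of [proxy_series()] for the variables the
#'   variant needs besides its target (among `N`, `W`, `C`), all on the
#'   same uniform time grid; the trajectory is returned on that grid.
#' @param cap Divergence cap: the simulation aborts with an error naming
#'   the step if the state exceeds `cap`.
#' @param warfare_term Passed to [step_state()].
#' @return A [proxy_series()] on the forcing grid; its first element is
#'   `initial`.
#' @export
simulate_trajectory <- function(variant, params, initial, forcings,
                                cap = 1e10,
                                warfare_term = c("exponent", "subtract")) {
  spec <- if (inherits(variant, "model_spec")) variant else
    model_spec(variant)
  warfare_term <- match.arg(warfare_term)
  if (initial <= 0) stop("`initial` must be positive", call. = FALSE)
  forcings <- forcings[!vapply(forcings, is.null, logical(1))]
  need <- setdiff(spec$needs, if (spec$target == "population") "N" else "W")
  missing <- setdiff(need, names(forcings))
  if (length(missing)) {
    stop("missing forcing series: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grid <- forcings[[1]]$times
  for (f in forcings) {
    if (!identical(f$times, grid)) {
      stop("all forcing series must share the same time grid",
           call. = FALSE)
    }
  }
  n <- length(grid)
  x <- numeric(n)
  x[1] <- initial
  for (i in 2:n) {
    fp <- lapply(forcings, function(f) f$values[i - 1])
    x[i] <- step_state(spec, params, x[i - 1], fp,
                       warfare_term = warfare_term)
    if (!is.finite(x[i]) || x[i] > cap) {
      stop(sprintf("trajectory diverged at step %d (year AD %s)",
                   i, format(grid[i])), call. = FALSE)
    }
  }
  proxy_series(grid, x,
               label = paste0("simulated ", spec$target,
                              " (", spec$variant, ")"),
               step = forcings[[1]]$step)
}

#' Simulate coupled population-warfare dynamics
#'
#' Runs a population variant and a warfare variant together, each feeding
#' the other its simulated previous-step value, under an observed (or
#' generated) exogenous climate series.  This is the generating process of
#' the synthetic-data module; the validation layer instead simulates each
#' fitted model separately against observed covariates, which is the
#' default elsewhere.
#'
#' @param pop_variant,war_variant Variant identifiers (one population, one
#'   warfare).
#' @param params Named parameters covering both variants (the two
#'   parameter sets are disjoint).
#' @param N0,W0 Initial population and warfare values (positive).
#' @param climate A [proxy_series()] giving the exogenous climate forcing;
#'   the trajectories are returned on its grid.
#' @param cap Divergence cap as in [simulate_trajectory()].
#' @return A list with elements `N` and `W`, both [proxy_series()] on the
#'   climate grid.
#' @export
simulate_coupled <- function(pop_variant, war_variant, params, N0, W0,
                             climate, cap = 1e10) {
  pspec <- model_spec(pop_variant)
  wspec <- model_spec(war_variant)
  stopifnot(pspec$target == "population", wspec$target == "warfare")
  if (N0 <= 0 || W0 <= 0) stop("initial values must be positive",
                               call. = FALSE)
  ppar <- as.list(params)[pspec$params]
  wpar <- as.list(params)[wspec$params]
  grid <- climate$times
  n <- length(grid)
  N <- numeric(n); W <- numeric(n)
  N[1] <- N0; W[1] <- W0
  for (i in 2:n) {
    Cp <- climate$values[i - 1]
    N[i] <- step_state(pspec, ppar, N[i - 1],
                       list(W = W[i - 1], C = Cp))
    W[i] <- step_state(wspec, wpar, W[i - 1],
                       list(N = N[i - 1], C = Cp))
    if (!all(is.finite(c(N[i], W[i]))) || max(N[i], W[i]) > cap) {
      stop(sprintf("coupled simulation diverged at step %d (year AD %s)",
                   i, format(grid[i])), call. = FALSE)
    }
  }
  list(N = proxy_series(grid, N, label = "population (latent)",
                        step = climate$step),
       W = proxy_series(grid, W, label = "warfare (latent)",
                        step = climate$step))
}
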