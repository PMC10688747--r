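#' Gaussian BIC from a residual sum of squares
#'
#' Bayesian information criterion under a Gaussian error model,
#' `n * ln(rss / n) + p * ln(n)`.  The additive Gaussian constant
#' `n * ln(2*pi) + n` is dropped: only BIC differences between models
#' fitted to the same response matter for selection, and the constant
#' cancels in every difference.
#'
#' @param rss Residual sum of squares (positive).
#' @param n Number of fitted observations.
#' @param p Number of free parameters.
#' @return The BIC value; `-Inf` with a warning when `rss <= 0` (a
#'   numerically perfect fit).
#' @examples
#' bic_rss(1, 10, 2)  # 10 * log(0.1) + 2 * log(10)
#' @export
bic_rss <- function(rss, n, p) {
  stopifnot(n > 0, p >= 0)
  if (rss <= 0) {
    warning("rss <= 0 (perfect fit); returning -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n) + p * log(n)
}

#' Coefficient of prediction
#'
#' Scores a vector of predictions against observations as
#' `1 - sum((pred - obs)^2) / sum((mean(obs) - obs)^2)`.
#' It equals 1 when the predictions reproduce the observations exactly, 0
#' when they do no better than the observation mean, and is negative when
#' they do worse than the mean.  Unlike an in-sample R-squared it is
#' computed on *simulated total trajectories*, so it can be arbitrarily
#' negative.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2);
#'   `observed` must not be constant.
#' @return A real number `<= 1`.
#' @examples
#' coefficient_of_prediction(c(1, 2, 3), c(3, 2, 1))  # -3
#' @export
coefficient_of_prediction <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("need at least 2 observations", call. = FALSE)
  }
  denom <- sum((mean(observed) - observed)^2)
  if (denom == 0) {
    stop("coefficient of prediction undefined for a constant observed ",
         "sequence", call. = FALSE)
  }
  1 - sum((predicted - observed)^2) / denom
}

# --- internal: parameter transforms -------------------------------------
# rN, k, lambda, mu are positive by definition and are optimized on the
# log scale (a soft positivity constraint); the sign-free coefficients
# alpha, beta, gamma, psi are optimized as-is.

theta_from_params <- function(spec, params) {
  th <- vapply(spec$params, function(nm) {
    v <- params[[nm]]
    if (nm %in% .positive_params) log(v) else v
  }, numeric(1))
  names(th) <- spec$params
  th
}

params_from_theta <- function(spec, theta) {
  p <- as.list(theta)
  names(p) <- spec$params
  for (nm in intersect(spec$params, .positive_params)) p[[nm]] <- exp(p[[nm]])
  p
}

# --- internal: align response and lagged covariates ---------------------

make_fit_data <- function(spec, response, covariates) {
  stopifnot(inherits(response, "rate_ts"))
  step <- response$step
  df <- data.frame(time = response$times, rate = response$values)
  for (nm in spec$needs) {
    cov <- covariates[[nm]]
    if (is.null(cov)) {
      stop("variant ", spec$variant, " needs covariate series `", nm, "`",
           call. = FALSE)
    }
    idx <- match(df$time - step, cov$times)
    if (anyNA(idx)) {
      stop("covariate `", nm, "` does not cover the lagged time stamps ",
           "of the response", call. = FALSE)
    }
    df[[nm]] <- cov$values[idx]
  }
  df
}

# --- internal: multistart grid ------------------------------------------
# Default grid: rN in 0.05-1; k at {0.5, 1, 2} x max(N); sign-free
# coefficients at +/-{0.01, 0.1, 1}; conflict-onset lambda scaled so that
# lambda x mean(driver) is {0.05, 0.5, 5}; decay mu at {0.01, 0.1, 1}.
# Starts are ranked by their initial RSS and Levenberg-Marquardt is run
# from the best few, the final fit being the best-of-starts by RSS.

start_grid <- function(spec, df) {
  coef_vals <- c(-1, -0.1, -0.01, 0.01, 0.1, 1)
  axes <- lapply(spec$params, function(nm) {
    switch(nm,
      rN = c(0.05, 0.2, 0.5, 1),
      k = c(0.5, 1, 2) * max(df$N),
      lambda = {
        driver <- if (spec$variant == "war_pressure") df$N / df$C else df$N
        c(0.05, 0.5, 5) / mean(abs(driver))
      },
      mu = c(0.01, 0.1, 1),
      coef_vals)
  })
  names(axes) <- spec$params
  expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
}

check_degenerate <- function(spec, df) {
  warnings <- character(0)
  cols <- intersect(c("N", "W", "C"), names(df))
  for (nm in cols) {
    if (stats::sd(df[[nm]]) < 1e-12) {
      warnings <- c(warnings,
                    paste0("covariate `", nm, "` is constant"))
    }
  }
  if (length(cols) >= 2) {
    cc <- stats::cor(df[cols])
    up <- cc[upper.tri(cc)]
    if (any(is.finite(up) & abs(up) > 0.999)) {
      warnings <- c(warnings, "covariates are nearly collinear")
    }
  }
  warnings
}

#' Fit a dynamic model to log rates by nonlinear least squares
#'
#' Estimates the parameters of one model variant by minimizing the sum of
#' squared differences between observed log rates of change and the
#' variant's predicted rate, using Levenberg-Marquardt least squares.
#' The response is the one-step log rate stamped at time `t`; every
#' covariate enters at `t - step`, matching the structure of the
#' difference equations.
#'
#' When no starting values are supplied, a multistart policy is applied:
#' a grid of starting points spanning plausible orders of magnitude is
#' ranked by initial residual sum of squares, Levenberg-Marquardt is run
#' from the best `n_starts`, and the fit with the lowest final RSS wins.
#' Positive parameters (`rN`, `k`, `lambda`, `mu`) are optimized on the
#' log scale.
#'
#' @param spec A [model_spec()] or variant identifier.
#' @param response A [rate_series()] of observed log rates (population or
#'   warfare, matching the variant's target).
#' @param covariates Named list of [proxy_series()] (among `N`, `W`, `C`)
#'   on the source grid; each must cover `response$times - step`.
#' @param init Optional named list of starting values on the natural
#'   scale; when supplied, only this start is used.
#' @param n_starts Number of grid starts from which the optimizer is run
#'   (after ranking by initial RSS).
#' @param control A [minpack.lm::nls.lm.control()] list; defaults to
#'   relative tolerances of 1e-10 and at most 10000 function evaluations.
#' @return An object of class `andean_fit` with elements `spec`, `params`
#'   (natural scale), `rss`, `n`, `p`, `r_squared`, `bic`, `sigma2`
#'   (`NA` until [validate_trajectory()] is run), `converged`,
#'   `start_points`, `warnings`, `data` (the aligned fitting frame) and
#'   `fitted` (predicted rates).
#' @examples
#' C <- proxy_series(seq(0, 250, 25), rep(0.3, 11))
#' N <- simulate_trajectory("pop_climate",
#'                          list(rN = 0.3, k = 1, alpha = 0.2),
#'                          initial = 0.1, forcings = list(C = C))
#' fit <- fit_model("pop_climate", growth_rates(N), list(N = N, C = C))
#' unlist(fit$params)
#' @export
fit_model <- function(spec, response, covariates, init = NULL,
                      n_starts = 10, control = NULL) {
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  df <- make_fit_data(spec, response, covariates)
  n <- nrow(df)
  p <- length(spec$params)
  if (n <= p) {
    stop(sprintf("need more observations (%d) than parameters (%d)", n, p),
         call. = FALSE)
  }
  if (is.null(control)) {
    control <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                          maxfev = 10000, maxiter = 150)
  }
  fit_warnings <- check_degenerate(spec, df)

  resid_fn <- function(theta) {
    df$rate - model_rate(spec, params_from_theta(spec, theta),
                         N = df$N, W = df$W, C = df$C)
  }

  if (!is.null(init)) {
    starts <- as.data.frame(as.list(unlist(init)[spec$params]))
    names(starts) <- spec$params
  } else {
    starts <- start_grid(spec, df)
    rss0 <- vapply(seq_len(nrow(starts)), function(i) {
      th <- theta_from_params(spec, as.list(starts[i, , drop = FALSE]))
      sum(resid_fn(th)^2)
    }, numeric(1))
    starts <- starts[order(rss0), , drop = FALSE]
    starts <- utils::head(starts, n_starts)
  }

  lm_quiet <- function(par) {
    withCallingHandlers(
      minpack.lm::nls.lm(par = par, fn = resid_fn, control = control),
      warning = function(w) {
        if (grepl("lmdif|lmder|maxfev|maxiter", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  best <- NULL
  best_ok <- FALSE
  tried <- 0L
  for (i in seq_len(nrow(starts))) {
    th0 <- theta_from_params(spec, as.list(starts[i, , drop = FALSE]))
    res <- tryCatch(lm_quiet(th0), error = function(e) NULL)
    if (is.null(res)) next
    tried <- tried + 1L
    ok <- res$info %in% 1:4
    if (!ok) {
      # iteration budget hit: restart once from the final point; if the
      # deviance is stationary the optimum has been reached along a flat
      # direction (common for misspecified variants where a parameter
      # escapes on the log scale) and the fit is accepted as converged
      res2 <- tryCatch(lm_quiet(res$par), error = function(e) NULL)
      if (!is.null(res2) && res2$deviance <= res$deviance) {
        improvement <- (res$deviance - res2$deviance) /
          max(res$deviance, .Machine$double.eps)
        ok <- res2$info %in% 1:4 || improvement < 1e-8
        res <- res2
      }
    }
    if (is.null(best) || res$deviance < best$deviance) {
      best <- res
      best_ok <- ok
    }
  }
  if (is.null(best)) {
    stop("optimization failed from every starting point for variant ",
         spec$variant, call. = FALSE)
  }

  params <- params_from_theta(spec, best$par)
  rss <- best$deviance
  tss <- sum((df$rate - mean(df$rate))^2)
  converged <- best_ok
  if (!converged) {
    fit_warnings <- c(fit_warnings,
                      paste0("optimizer did not converge (info = ",
                             best$info, ")"))
  }
  structure(list(
    spec = spec,
    params = params,
    rss = rss,
    n = n,
    p = p,
    r_squared = 1 - rss / tss,
    bic = suppressWarnings(bic_rss(rss, n, p)),
    sigma2 = NA_real_,
    converged = converged,
    start_points = list(policy = if (is.null(init)) "grid" else "user",
                        n_tried = tried,
                        starts = starts),
    warnings = fit_warnings,
    data = df,
    fitted = df$rate - resid_fn(best$par),
    theta = best$par,
    hessian = best$hessian
  ), class = "andean_fit")
}

#' @export
print.andean_fit <- function(x, ...) {
  cat(sprintf("<andean_fit> %s (%s response), n = %d\n",
              x$spec$variant, x$spec$target, x$n))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  cat(sprintf("  RSS = %.4g  R2 = %.4f  BIC = %.2f  sigma2 = %s%s\n",
              x$rss, x$r_squared, x$bic,
              if (is.na(x$sigma2)) "(not validated)" else
                sprintf("%.4f", x$sigma2),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Validate a fitted model by total-trajectory simulation
#'
#' Simulates the fitted model's full trajectory, initiated with the first
#' observed value and driven by the observed exogenous covariates (the
#' endogenous variable is never re-anchored to the data after the start),
#' then scores the simulation against the observed series with the
#' coefficient of prediction.
#'
#' @param fit An `andean_fit` from [fit_model()] (must have converged).
#' @param observed The observed [proxy_series()] of the target variable on
#'   the analysis grid.
#' @param forcings Named list of observed covariate series on the same
#'   grid (the non-target variables the variant needs).
#' @param warfare_term Passed to [simulate_trajectory()].
#' @return The fit with `sigma2` (the coefficient of prediction),
#'   `trajectory` (the simulated [proxy_series()]) and `diverged` filled
#'   in; a diverging simulation yields `sigma2 = -Inf` and
#'   `diverged = TRUE`.
#' @export
validate_trajectory <- function(fit, observed, forcings,
                                warfare_term = c("exponent", "subtract")) {
  stopifnot(inherits(fit, "andean_fit"))
  if (!fit$converged) {
    stop("refusing to validate a fit that did not converge", call. = FALSE)
  }
  warfare_term <- match.arg(warfare_term)
  sim <- tryCatch(
    simulate_trajectory(fit$spec, fit$params,
                        initial = observed$values[1],
                        forcings = forcings, warfare_term = warfare_term),
    error = function(e) e)
  if (inherits(sim, "error")) {
    fit$sigma2 <- -Inf
    fit$diverged <- TRUE
    fit$trajectory <- NULL
    warning("trajectory diverged during validation: ",
            conditionMessage(sim), call. = FALSE)
  } else {
    fit$sigma2 <- coefficient_of_prediction(observed$values, sim$values)
    fit$diverged <- FALSE
    fit$trajectory <- sim
  }
  fit
}

#' Rank competing fitted models
#'
#' Builds the model-comparison table: one row per fit, sorted by BIC
#' (ascending).  Ties on BIC are broken by fewer parameters, then by
#' higher coefficient of prediction.  All fits must target the same
#' response series (same variable and same number of observations);
#' otherwise the comparison is refused.
#'
#' @param fits A list of `andean_fit` objects.
#' @return A data frame with columns `model`, `target`, the union of
#'   parameter estimates, `p`, `rss`, `r_squared`, `bic`, `delta_bic`
#'   (difference from the best model), `sigma2` and `best` (logical flag
#'   on the top row).
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "andean_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "andean_fit")))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  targets <- vapply(fits, function(f) f$spec$target, character(1))
  if (length(unique(ns)) != 1 || length(unique(targets)) != 1) {
    stop("comparison refused: fits must share the same response series ",
         "(same target variable and same n)", call. = FALSE)
  }
  par_names <- unique(unlist(lapply(fits, function(f) names(f$params))))
  rows <- lapply(fits, function(f) {
    pr <- stats::setNames(rep(NA_real_, length(par_names)), par_names)
    pr[names(f$params)] <- unlist(f$params)
    cbind(data.frame(model = f$spec$variant, target = f$spec$target),
          as.data.frame(as.list(pr)),
          data.frame(p = f$p, rss = f$rss, r_squared = f$r_squared,
                     bic = f$bic, sigma2 = f$sigma2,
                     converged = f$converged))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$bic, tab$p, -ifelse(is.na(tab$sigma2), -Inf, tab$sigma2))
  tab <- tab[ord, , drop = FALSE]
  tab$delta_bic <- tab$bic - tab$bic[1]
  tab$best <- seq_len(nrow(tab)) == 1
  rownames(tab) <- NULL
  tab
}

#' Parametric-bootstrap confidence band for a model trajectory
#'
#' Draws parameter vectors from the asymptotic normal approximation to
#' the least-squares estimate (on the transformed scale used by the
#' optimizer), re-simulates the total trajectory for each draw, and
#' returns pointwise quantile bands.  This is this package's own choice
#' of interval construction for trajectory plots; draws whose simulation
#' diverges are dropped.
#'
#' @param fit A converged `andean_fit`.
#' @param observed Observed target series (supplies the initial value and
#'   the grid).
#' @param forcings Observed covariate series as in [validate_trajectory()].
#' @param B Number of bootstrap draws.
#' @param level Band coverage (default 0.95).
#' @param seed Optional seed for reproducible draws.
#' @return A data frame with columns `year`, `lower`, `upper`, `median`.
#' @export
trajectory_ci <- function(fit, observed, forcings, B = 200, level = 0.95,
                          seed = NULL) {
  stopifnot(inherits(fit, "andean_fit"), fit$converged)
  sigma2_hat <- fit$rss / (fit$n - fit$p)
  vc <- tryCatch(sigma2_hat * solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc)) {
    stop("parameter covariance is singular; no band available",
         call. = FALSE)
  }
  ch <- chol((vc + t(vc)) / 2)
  run <- function() {
    sims <- matrix(NA_real_, nrow = B, ncol = length(observed$times))
    for (b in seq_len(B)) {
      th <- fit$theta + drop(t(ch) %*% stats::rnorm(length(fit$theta)))
      tr <- tryCatch(suppressWarnings(
        simulate_trajectory(fit$spec, params_from_theta(fit$spec, th),
                            initial = observed$values[1],
                            forcings = forcings)),
        error = function(e) NULL)
      if (!is.null(tr)) sims[b, ] <- tr$values
    }
    sims
  }
  sims <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  sims <- sims[stats::complete.cases(sims), , drop = FALSE]
  if (nrow(sims) == 0) {
    stop("all bootstrap trajectories diverged", call. = FALSE)
  }
  a <- (1 - level) / 2
  data.frame(year = observed$times,
             lower = apply(sims, 2, stats::quantile, probs = a),
             upper = apply(sims, 2, stats::quantile, probs = 1 - a),
             median = apply(sims, 2, stats::median))
}
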