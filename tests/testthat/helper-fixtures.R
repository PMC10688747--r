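# Shared helpers: all fixtures are generated in code at test time.

# fit without the convergence/collinearity warning chatter
quiet_fit <- function(...) suppressWarnings(fit_model(...))

# deterministic positive series for rate checks
random_positive_series <- function(n = 20, seed = 42) {
  vals <- withr::with_seed(seed, exp(stats::rnorm(n, 0, 0.3)))
  proxy_series(seq(50, by = 25, length.out = n), vals, label = "random")
}

# pure logistic trajectory via the climate variant with alpha = 0
logistic_series <- function(n, rN, k, N0, step = 25) {
  C <- proxy_series(seq(50, by = step, length.out = n), rep(1, n))
  simulate_trajectory("pop_climate", list(rN = rN, k = k, alpha = 0),
                      initial = N0, forcings = list(C = C))
}

# minimal fit-shaped object for ranking-logic tests
stub_fit <- function(variant, n, p, rss, sigma2 = NA_real_) {
  spec <- model_spec(variant)
  structure(list(spec = spec,
                 params = stats::setNames(as.list(rep(1, p)),
                                          spec$params[seq_len(p)]),
                 rss = rss, n = n, p = p,
                 r_squared = NA_real_,
                 bic = bic_rss(rss, n, p),
                 sigma2 = sigma2, converged = TRUE),
            class = "andean_fit")
}
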