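#' Analysis configuration
#'
#' Collects every setting of the full analysis in one object.  The
#' defaults reproduce the reference preprocessing settings: a 25-year
#' analysis grid, a smoothing parameter of 0.90 for the warfare index and
#' 0.65 for the climate proxy, and the full menu of three population and
#' three warfare model variants fitted to both SPD variants in parallel.
#'
#' Input can be either a [synthetic_scenario()] (self-contained, no
#' files) or a list of file paths:
#' `inputs = list(spd_n =, spd_nn =, warfare =, climate =)`, where the
#' SPD and climate files are two-column proxy CSVs (`year`, `value`) and
#' the warfare file is either an annual proxy CSV or a period table
#' (`name`, `start`, `end`, `code`; CSV or YAML).
#'
#' @param area Free-text label for the analysis area.
#' @param scenario Optional [synthetic_scenario()].
#' @param inputs Optional list of input file paths (see above); exactly
#'   one of `scenario`/`inputs` must be given.
#' @param window Length-2 vector `c(start, end)` in calendar years AD;
#'   defaults to the scenario grid or to the widest window covered by all
#'   inputs and divisible by `step`.
#' @param step Analysis grid spacing in years.
#' @param spar_warfare,spar_climate Smoothing parameters for the warfare
#'   and climate series (annual file input only; scenario series are
#'   already on the model grid).
#' @param warfare_floor Positive floor applied to the warfare index
#'   before log rates are taken.
#' @param models_pop,models_war Model menus for the two responses; may be
#'   empty.
#' @param fit_spdnn Fit the unnormalized SPD variant in parallel
#'   (default `TRUE`).
#' @param seed Integer seed governing every random element of the run.
#' @return An object of class `andean_config`.
#' @export
analysis_config <- function(area = "synthetic", scenario = NULL,
                            inputs = NULL, window = NULL, step = 25,
                            spar_warfare = 0.90, spar_climate = 0.65,
                            warfare_floor = 0.1,
                            models_pop = c("pop_climate", "pop_warfare",
                                           "pop_climate_warfare"),
                            models_war = c("war_basic",
                                           "war_additive_climate",
                                           "war_pressure"),
                            fit_spdnn = TRUE, seed = 1) {
  if (is.null(scenario) == is.null(inputs)) {
    stop("supply exactly one of `scenario` or `inputs`", call. = FALSE)
  }
  if (!is.null(scenario)) stopifnot(inherits(scenario, "andean_scenario"))
  if (length(models_pop)) {
    models_pop <- vapply(models_pop,
                         function(v) model_spec(v)$variant, character(1))
  }
  if (length(models_war)) {
    models_war <- vapply(models_war,
                         function(v) model_spec(v)$variant, character(1))
  }
  structure(list(area = area, scenario = scenario, inputs = inputs,
                 window = window, step = step,
                 spar_warfare = spar_warfare,
                 spar_climate = spar_climate,
                 warfare_floor = warfare_floor,
                 models_pop = unname(models_pop),
                 models_war = unname(models_war),
                 fit_spdnn = isTRUE(fit_spdnn), seed = as.integer(seed)),
            class = "andean_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

prepare_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    synth <- generate_coupled(sc)
    spd_nn <- withr::with_seed(sc$seed + 1L, {
      proxy_series(synth$N$times,
                   1.15 * synth$latent$N$values *
                     exp(stats::rnorm(sc$n_steps, 0, sc$obs_noise_sd)),
                   label = "population (observed, unnormalized-like)",
                   step = sc$step)
    })
    prepared <- list(spd_n = synth$N, spd_nn = spd_nn,
                     warfare = synth$W, climate = synth$C)
    window <- config$window
    if (!is.null(window)) {
      prepared <- lapply(prepared, resample, step = config$step,
                         start = window[1], end = window[2])
    }
    return(c(prepared, list(synth = synth)))
  }
  inp <- config$inputs
  spd_n <- read_proxy_csv(inp$spd_n, label = "SPDn")
  spd_nn <- if (!is.null(inp$spd_nn)) {
    read_proxy_csv(inp$spd_nn, label = "SPDnn")
  } else {
    spd_n
  }
  climate <- read_proxy_csv(inp$climate, label = "climate proxy")
  war_head <- names(utils::read.csv(inp$warfare, nrows = 1))
  warfare <- if (all(c("name", "start", "end", "code") %in% war_head) ||
                 grepl("\\.ya?ml$", inp$warfare)) {
    coding <- read_warfare_coding(inp$warfare)
    encode_warfare(coding, c(min(coding$start), max(coding$end) - 1))
  } else {
    read_proxy_csv(inp$warfare, label = "warfare index")
  }
  warfare <- smooth_spline(warfare, spar = config$spar_warfare,
                           clip = c(0, 6))
  climate <- smooth_spline(climate, spar = config$spar_climate)
  window <- config$window
  if (is.null(window)) {
    lo <- max(vapply(list(spd_n, spd_nn, warfare, climate),
                     function(s) s$times[1], numeric(1)))
    hi <- min(vapply(list(spd_n, spd_nn, warfare, climate),
                     function(s) s$times[length(s$times)], numeric(1)))
    window <- c(ceiling(lo / config$step) * config$step,
                floor(hi / config$step) * config$step)
  }
  list(spd_n = resample(spd_n, config$step, window[1], window[2]),
       spd_nn = resample(spd_nn, config$step, window[1], window[2]),
       warfare = resample(warfare, config$step, window[1], window[2]),
       climate = resample(climate, config$step, window[1], window[2]))
}

fit_and_validate <- function(variant, response, covariates, observed,
                             forcings) {
  fit <- fit_model(variant, response, covariates)
  if (fit$converged) {
    fit <- suppressWarnings(validate_trajectory(fit, observed, forcings))
  }
  fit
}

#' Run the full analysis
#'
#' Executes every stage of the pipeline from one [analysis_config()]:
#' input acquisition (files or synthetic scenario), preprocessing
#' (smoothing, resampling to the 25-year grid, log rates), nonlinear
#' least-squares fitting of the configured model menus for the population
#' response (normalized and, in parallel, unnormalized SPD) and the
#' warfare response, total-trajectory validation of every fit, and
#' BIC-ranked model comparison.  Any stage failure aborts with an error
#' naming the stage.  Reruns with the same configuration and seed are
#' deterministic.
#'
#' @param config An [analysis_config()].
#' @return An object of class `andean_report`: a list with the aligned
#'   `series` table (nine exchange columns), the `prepared` series, all
#'   validated `fits` (named `<response>.<spd variant>.<model>`),
#'   `comparisons` (one BIC table per response/SPD-variant pair) and a
#'   machine-readable `manifest`.
#' @examples
#' \donttest{
#' rep <- run_analysis(analysis_config(
#'   scenario = scenario_northern_like(seed = 2)))
#' rep$comparisons$population_SPDn
#' }
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "andean_config"))
  prepared <- with_stage("prep", prepare_inputs(config))
  series <- with_stage("prep",
    sdata_table(prepared$spd_n, prepared$spd_nn, prepared$climate,
                prepared$warfare, warfare_floor = config$warfare_floor))

  rates <- with_stage("rates", list(
    Rn = growth_rates(prepared$spd_n),
    Rnn = growth_rates(prepared$spd_nn),
    Rwar = suppressMessages(growth_rates(prepared$warfare,
                                         floor = config$warfare_floor))))

  spd_variants <- c("SPDn", if (config$fit_spdnn) "SPDnn")
  fits <- list()
  comparisons <- list()
  for (sv in spd_variants) {
    spd <- if (sv == "SPDn") prepared$spd_n else prepared$spd_nn
    rate <- if (sv == "SPDn") rates$Rn else rates$Rnn
    covs <- list(N = spd, W = prepared$warfare, C = prepared$climate)
    pop_fits <- with_stage("fit", lapply(config$models_pop, function(v) {
      fit_and_validate(v, rate, covs, observed = spd,
                       forcings = list(W = prepared$warfare,
                                       C = prepared$climate))
    }))
    names(pop_fits) <- config$models_pop
    war_fits <- with_stage("fit", lapply(config$models_war, function(v) {
      fit_and_validate(v, rates$Rwar, covs, observed = prepared$warfare,
                       forcings = list(N = spd, C = prepared$climate))
    }))
    names(war_fits) <- config$models_war
    for (nm in names(pop_fits)) {
      fits[[paste("population", sv, nm, sep = ".")]] <- pop_fits[[nm]]
    }
    for (nm in names(war_fits)) {
      fits[[paste("warfare", sv, nm, sep = ".")]] <- war_fits[[nm]]
    }
    if (length(pop_fits)) {
      comparisons[[paste0("population_", sv)]] <-
        with_stage("compare", compare_models(pop_fits))
    }
    if (length(war_fits)) {
      comparisons[[paste0("warfare_", sv)]] <-
        with_stage("compare", compare_models(war_fits))
    }
  }

  manifest <- list(
    package = "andeandyn",
    version = as.character(utils::packageVersion("andeandyn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    area = config$area,
    seed = config$seed,
    step = config$step,
    window = range(prepared$spd_n$times),
    spar_warfare = config$spar_warfare,
    spar_climate = config$spar_climate,
    warfare_floor = config$warfare_floor,
    models_pop = config$models_pop,
    models_war = config$models_war,
    optimizer = list(method = "Levenberg-Marquardt multistart",
                     ftol = 1e-10, ptol = 1e-10, maxfev = 10000),
    scenario = if (!is.null(config$scenario)) {
      unclass(config$scenario)
    }
  )

  structure(list(config = config, prepared = prepared[c(
    "spd_n", "spd_nn", "warfare", "climate")],
    series = series, rates = rates, fits = fits,
    comparisons = comparisons, manifest = manifest),
    class = "andean_report")
}

#' @export
print.andean_report <- function(x, ...) {
  cat(sprintf("<andean_report> area '%s': %d aligned points, %d fits\n",
              x$config$area, nrow(x$series), length(x$fits)))
  for (nm in names(x$comparisons)) {
    best <- x$comparisons[[nm]][1, ]
    cat(sprintf("  %-18s best: %-20s BIC %8.2f  R2 %6.3f  sigma2 %s\n",
                nm, best$model, best$bic, best$r_squared,
                ifelse(is.na(best$sigma2), "NA",
                       sprintf("%6.3f", best$sigma2))))
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes the aligned series table, one comparison CSV per response, one
#' observed-vs-predicted trajectory CSV per validated fit, and the run
#' manifest as JSON.  Output is deterministic for a fixed configuration
#' and seed.
#'
#' @param report An `andean_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "andean_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "aligned_series.csv")
  utils::write.csv(report$series, p, row.names = FALSE)
  paths <- c(paths, p)
  for (nm in names(report$comparisons)) {
    p <- file.path(dir, paste0("comparison_", nm, ".csv"))
    utils::write.csv(report$comparisons[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(report$fits)) {
    fit <- report$fits[[nm]]
    if (is.null(fit$trajectory)) next
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    obs <- if (parts[1] == "population") {
      if (parts[2] == "SPDn") report$prepared$spd_n else
        report$prepared$spd_nn
    } else {
      report$prepared$warfare
    }
    p <- file.path(dir, paste0("trajectory_", gsub("\\.", "_", nm), ".csv"))
    utils::write.csv(data.frame(year = obs$times, observed = obs$values,
                                predicted = fit$trajectory$values),
                     p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Plot a report
#'
#' Produces the figure set for a report: one multi-panel preprocessing
#' figure (population proxies, growth rates, warfare index, climate
#' proxy) and one observed-vs-predicted trajectory figure per validated
#' fit, optionally with a parametric-bootstrap confidence band.
#'
#' @param report An `andean_report`.
#' @param ci Add a [trajectory_ci()] band to each trajectory figure.
#' @param ci_B,ci_level Bootstrap settings for the band.
#' @return A named list of ggplot objects: `series` plus one entry per
#'   fit.
#' @export
plot_report <- function(report, ci = FALSE, ci_B = 200, ci_level = 0.95) {
  stopifnot(inherits(report, "andean_report"))
  s <- report$series
  long <- rbind(
    data.frame(year = s$yearAD, value = s$SPDn, panel = "population proxy",
               series = "SPDn"),
    data.frame(year = s$yearAD, value = s$SPDnn, panel = "population proxy",
               series = "SPDnn"),
    data.frame(year = s$yearAD, value = s$Rn, panel = "growth rate",
               series = "Rn"),
    data.frame(year = s$yearAD, value = s$Rnn, panel = "growth rate",
               series = "Rnn"),
    data.frame(year = s$yearAD, value = s$War, panel = "warfare index",
               series = "War"),
    data.frame(year = s$yearAD, value = s$LithPct, panel = "climate proxy",
               series = "LithPct"))
  plots <- list(series = ggplot2::ggplot(
    long[!is.na(long$value), ],
    ggplot2::aes(x = .data$year, y = .data$value,
                 colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "calendar year AD", y = NULL,
                  title = paste("Aligned series:", report$config$area)) +
    ggplot2::theme_minimal())

  for (nm in names(report$fits)) {
    fit <- report$fits[[nm]]
    if (is.null(fit$trajectory)) next
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    obs <- if (parts[1] == "population") {
      if (parts[2] == "SPDn") report$prepared$spd_n else
        report$prepared$spd_nn
    } else {
      report$prepared$warfare
    }
    df <- data.frame(year = obs$times, observed = obs$values,
                     predicted = fit$trajectory$values)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$year)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                          colour = "steelblue") +
      ggplot2::geom_line(ggplot2::aes(y = .data$observed),
                         colour = "steelblue", linetype = 2) +
      ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                         colour = "firebrick") +
      ggplot2::labs(x = "calendar year AD", y = parts[1],
                    title = sprintf("%s (%s): sigma2 = %.3f", parts[3],
                                    parts[2], fit$sigma2)) +
      ggplot2::theme_minimal()
    if (ci) {
      band <- tryCatch(
        trajectory_ci(fit, obs,
                      forcings = if (parts[1] == "population") {
                        list(W = report$prepared$warfare,
                             C = report$prepared$climate)
                      } else {
                        list(N = if (parts[2] == "SPDn")
                          report$prepared$spd_n else
                            report$prepared$spd_nn,
                          C = report$prepared$climate)
                      },
                      B = ci_B, level = ci_level,
                      seed = report$config$seed),
        error = function(e) NULL)
      if (is.null(band)) {
        message("no confidence band for ", nm, " (bootstrap failed)")
      } else {
        p <- p + ggplot2::geom_ribbon(
          data = band,
          ggplot2::aes(x = .data$year, ymin = .data$lower,
                       ymax = .data$upper),
          inherit.aes = FALSE, alpha = 0.2, fill = "firebrick")
      }
    }
    plots[[nm]] <- p
  }
  plots
}

#' Read an analysis configuration from YAML
#'
#' Maps a YAML mapping onto [analysis_config()].  Keys mirror the
#' function's arguments.  `scenario` may be either the name of a preset
#' (`"northern_like"`, `"southern_like"`, `"boom_bust"`), optionally with
#' `seed`/`obs_noise_sd` overrides, or a full mapping with the arguments
#' of [synthetic_scenario()].
#'
#' @param path Path to a YAML file.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    if (is.character(sc) || !is.null(sc$preset)) {
      preset <- if (is.character(sc)) sc else sc$preset
      maker <- switch(preset,
                      northern_like = scenario_northern_like,
                      southern_like = scenario_southern_like,
                      boom_bust = scenario_boom_bust,
                      stop("unknown scenario preset: ", preset,
                           call. = FALSE))
      args <- list()
      if (!is.character(sc)) {
        args <- sc[intersect(names(sc), c("seed", "obs_noise_sd"))]
      }
      if (!is.null(raw$seed) && is.null(args$seed)) args$seed <- raw$seed
      raw$scenario <- do.call(maker, args)
    } else {
      raw$scenario <- do.call(synthetic_scenario, sc)
    }
  }
  keep <- intersect(names(raw), names(formals(analysis_config)))
  do.call(analysis_config, raw[keep])
}
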