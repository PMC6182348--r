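#' Run configuration for the end-to-end pipeline
#'
#' Either `input_file` (a life-table CSV in the [read_abridged_tables()]
#' schema) or `preset` (one or more synthetic presets of
#' [make_ground_truth()]) must be given.
#'
#' @param input_file Path to a life-table CSV, or `NULL`.
#' @param preset Synthetic preset name(s), or `NULL`.
#' @param models Model names to fit (non-empty subset of
#'   [model_names()]).
#' @param fraction Hold-out training share in (0, 1).
#' @param horizon Forecast horizon in years (0 disables forecasting).
#' @param level Prediction-interval coverage in (0, 1).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed for all randomness.
#' @param verbose Print one progress line per stage.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_file = NULL, preset = NULL,
                       models = c("LC", "LC2"), fraction = 0.75,
                       horizon = 20L, level = 0.95,
                       out_dir = "mortabridge-run", seed = 20180101L,
                       verbose = TRUE) {
  cfg <- list(
    input_file = input_file, preset = preset, models = models,
    fraction = fraction, horizon = horizon, level = level,
    out_dir = out_dir, seed = seed, verbose = verbose
  )
  problems <- validate_config(cfg)
  if (length(problems) > 0L) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(cfg$input_file) && is.null(cfg$preset)) {
    add("one of 'input_file' or 'preset' must be given")
  }
  if (!is.null(cfg$preset) &&
      !all(cfg$preset %in% c("female_like", "male_like", "flat"))) {
    add(sprintf("unknown preset(s): %s",
                paste(setdiff(cfg$preset,
                              c("female_like", "male_like", "flat")),
                      collapse = ", ")))
  }
  if (length(cfg$models) == 0L) add("'models' must be non-empty")
  unknown <- setdiff(toupper(cfg$models), model_names())
  if (length(unknown) > 0L) {
    add(sprintf("unknown model(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.numeric(cfg$fraction) || length(cfg$fraction) != 1L ||
      cfg$fraction <= 0 || cfg$fraction >= 1) {
    add("'fraction' must lie strictly between 0 and 1")
  }
  if (!is.numeric(cfg$horizon) || length(cfg$horizon) != 1L ||
      cfg$horizon < 0) {
    add("'horizon' must be a non-negative number of years")
  }
  if (!is.numeric(cfg$level) || length(cfg$level) != 1L ||
      cfg$level <= 0 || cfg$level >= 1) {
    add("'level' must lie strictly between 0 and 1")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    add("'seed' must be a single integer")
  }
  problems
}

CONFIG_KEYS <- c("input_file", "preset", "models", "fraction", "horizon",
                 "level", "out_dir", "seed", "verbose")

#' Load (or save) a pipeline configuration from YAML or JSON
#'
#' Unknown keys and invalid values are reported together in one error.
#' Defaults: `models = c("LC", "LC2")`, `fraction = 0.75`,
#' `horizon = 20`, `level = 0.95`, `seed = 20180101`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  problems <- character(0)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  raw <- raw[intersect(names(raw), CONFIG_KEYS)]
  cfg <- do.call(function(...) {
    defaults <- formals(run_config)
    supplied <- list(...)
    merged <- modifyList(
      lapply(defaults, function(d) if (is.call(d)) eval(d) else d),
      supplied
    )
    merged
  }, raw)
  problems <- c(problems, validate_config(cfg))
  if (length(problems) > 0L) {
    stop("invalid configuration in '", path, "':\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(cfg[CONFIG_KEYS], class = "run_config")
}

#' @rdname load_config
#' @param config A [run_config()].
#' @export
save_config <- function(config, path) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  lst <- unclass(config)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Run the end-to-end mortality-forecasting pipeline
#'
#' Reads (or generates) abridged life tables, runs the hold-out model
#' comparison per sex, refits the converged models on the full period,
#' forecasts their period indices and death probabilities over the
#' horizon, computes indicator series for observed and forecast years,
#' and writes a report bundle of CSV files plus a run log to
#' `config$out_dir`. Identical configuration and seed produce
#' byte-identical CSV outputs. Non-converged models appear in the
#' comparison table with absent measures and are excluded from
#' forecasting.
#'
#' Bundle contents per sex `<s>`: `comparison.csv` (all sexes),
#' `params_<model>_<s>.csv`, `residuals_<model>_<s>.csv`,
#' `index_forecast_<model>_<s>.csv`, `q_forecast_<model>_<s>.csv`,
#' `indicators_<s>.csv`, and `run_log.txt`.
#'
#' @param config A [run_config()] (or path to a config file).
#' @return Invisibly, a list with the comparison table, fitted models,
#'   forecasts and indicator series.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "run_config")) {
    stop("'config' must be a run_config or a path to one")
  }
  t_start <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character(0)
  stage <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    if (isTRUE(config$verbose)) message(line)
    log_lines <<- c(log_lines, line)
  }
  stage(sprintf("run started; seed %d; models %s", config$seed,
                paste(config$models, collapse = ",")))

  # 1. input
  if (!is.null(config$input_file)) {
    tables <- read_abridged_tables(config$input_file)
    stage(sprintf("read %d life tables from %s", length(tables),
                  config$input_file))
  } else {
    tables <- list()
    for (i in seq_along(config$preset)) {
      gt <- make_ground_truth(config$preset[i],
                              seed = config$seed + (i - 1L) * 1000L)
      tables <- c(tables, simulate_life_tables(gt))
    }
    stage(sprintf("generated %d synthetic life tables (preset %s)",
                  length(tables), paste(config$preset, collapse = ",")))
  }

  # 2. hold-out comparison
  years_all <- sort(unique(vapply(tables, attr, numeric(1), "year")))
  plan <- holdout_split(years_all, config$fraction)
  comparison <- compare_models(tables, config$models, plan)
  utils::write.csv(as.data.frame(comparison),
                   file.path(config$out_dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  stage(sprintf("hold-out comparison done (train %d / validation %d years)",
                length(plan$train_years), length(plan$validation_years)))

  sexes <- unique(vapply(tables, function(lt) as.character(attr(lt, "sex")),
                         character(1)))
  full_fits <- list()
  forecasts <- list()
  indicators <- list()
  for (sx in sexes) {
    tabs <- Filter(function(lt) identical(as.character(attr(lt, "sex")), sx),
                   tables)
    ind_obs <- indicator_series(tabs)
    ind_obs$source <- "observed"
    ind_rows <- list(ind_obs)

    for (mn in toupper(config$models)) {
      fit <- fit_mortality_model(tabs, mn)
      full_fits[[paste0(mn, "/", sx)]] <- fit
      stage(sprintf("refit %s (%s) on full period: deviance %.2f, converged %s",
                    mn, sx, fit$deviance, fit$converged))
      write_model_params(fit, file.path(
        config$out_dir, sprintf("params_%s_%s.csv", mn, sx)
      ))
      if (!fit$converged) next
      q_hat <- predict_q(fit)
      res <- deviance_residuals(fit$d_obs, fit$E * q_hat, fit$E,
                                ages = fit$ages, years = fit$years)
      utils::write.csv(as.data.frame(res), file.path(
        config$out_dir, sprintf("residuals_%s_%s.csv", mn, sx)
      ), row.names = FALSE, quote = FALSE)

      if (config$horizon > 0) {
        fyears <- max(fit$years) + seq_len(config$horizon)
        idx_fc <- list(k1 = forecast_index(
          fit_index_model(fit$k1, "rw_drift"), h = config$horizon,
          level = config$level, horizon_years = fyears
        ))
        if (!is.null(fit$k2)) {
          k2_model <- if (fit$spec$cbd_structure) {
            fit_index_model(fit$k2, "rw_drift")
          } else {
            fit_second_index_model(fit$k2, "ar1_mean")
          }
          stage(sprintf("k2 index of %s (%s) modelled as %s", mn, sx,
                        k2_model$kind))
          idx_fc$k2 <- forecast_index(
            k2_model, h = config$horizon,
            level = config$level, horizon_years = fyears
          )
        }
        write_index_forecasts(idx_fc, file.path(
          config$out_dir, sprintf("index_forecast_%s_%s.csv", mn, sx)
        ))
        qf <- suppressWarnings(
          forecast_probabilities(fit, idx_fc, years = fyears)
        )
        write_q_forecast(qf, file.path(
          config$out_dir, sprintf("q_forecast_%s_%s.csv", mn, sx)
        ), age_lower = fit$grid$lower)
        forecasts[[paste0(mn, "/", sx)]] <- qf

        ind_fc <- indicator_series(lapply(seq_along(fyears), function(j) {
          build_life_table(qf$central[, j], fit$grid, year = fyears[j],
                           sex = sx)
        }))
        ind_fc$source <- mn
        ind_rows[[length(ind_rows) + 1L]] <- ind_fc
        stage(sprintf("forecast %s (%s) to %d", mn, sx, max(fyears)))
      }
    }
    ind_all <- do.call(rbind, ind_rows)
    utils::write.csv(ind_all,
                     file.path(config$out_dir,
                               sprintf("indicators_%s.csv", sx)),
                     row.names = FALSE, quote = FALSE)
    indicators[[sx]] <- ind_all
  }

  stage(sprintf("run finished in %.1f s",
                as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  log_lines <- c(log_lines, sprintf("seed: %d", config$seed),
                 sprintf("R version: %s", R.version.string),
                 sprintf("convergence: %s", paste(
                   vapply(names(full_fits), function(nm) {
                     sprintf("%s=%s", nm, full_fits[[nm]]$converged)
                   }, character(1)), collapse = "; ")))
  writeLines(log_lines, log_path)
  invisible(list(comparison = comparison, fits = full_fits,
                 forecasts = forecasts, indicators = indicators,
                 plan = plan, out_dir = config$out_dir))
}

write_model_params <- function(fit, path) {
  pad <- function(v, n) c(v, rep(NA_real_, n - length(v)))
  n <- max(length(fit$ages), length(fit$years), length(fit$cohort_levels))
  out <- data.frame(row = seq_len(n))
  out$age <- pad(fit$ages, n)
  if (!is.null(fit$a)) out$a <- pad(fit$a, n)
  if (!is.null(fit$b1)) out$b1 <- pad(fit$b1, n)
  if (!is.null(fit$b2)) out$b2 <- pad(fit$b2, n)
  out$year <- pad(fit$years, n)
  if (!is.null(fit$k1)) out$k1 <- pad(fit$k1, n)
  if (!is.null(fit$k2)) out$k2 <- pad(fit$k2, n)
  if (!is.null(fit$gamma)) {
    out$cohort <- pad(fit$cohort_levels, n)
    out$gamma <- pad(as.numeric(fit$gamma), n)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_index_forecasts <- function(idx_fc, path) {
  rows <- lapply(names(idx_fc), function(nm) {
    fc <- idx_fc[[nm]]
    data.frame(index = nm, year = fc$horizon_years, central = fc$central,
               lower = fc$lower, upper = fc$upper, level = fc$level)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
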