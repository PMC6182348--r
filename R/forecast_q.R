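#' Forecast death probabilities from forecast period indices
#'
#' Propagates index forecasts through the fitted predictor:
#' `q_hat = expit(eta)` with the central index paths, and interval
#' bounds obtained by monotone interval arithmetic -- for each index the
#' bound that decreases (increases) the predictor is chosen per cell
#' according to the sign of its age loading, so bounds are exact images
#' of the index bounds when a single index varies and conservative when
#' several do (correlation between indices is ignored). Models with a
#' cohort term hold the cohort effect at its last estimated value for
#' unseen cohorts, with a warning.
#'
#' @param model A converged `fitted_mortality_model`.
#' @param index_forecasts Named list of [forecast_index()] results, one
#'   per free index of the model (`k1`, and `k2` where the model has
#'   one).
#' @param years Calendar years of the forecast horizon (defaults to the
#'   years following the fitting period, matching the forecast length).
#' @param ages Age-group midpoints (default: fitted ages).
#' @return A list of class `q_forecast` with matrices `central`, `lower`
#'   and `upper` (ages x years, probabilities), plus `years`, `ages`,
#'   `level` and `model_name`.
#' @export
forecast_probabilities <- function(model, index_forecasts, years = NULL,
                                   ages = NULL) {
  if (!inherits(model, "fitted_mortality_model")) {
    stop("'model' must be a fitted_mortality_model")
  }
  if (!isTRUE(model$converged)) {
    stop(sprintf("model %s did not converge; refusing to forecast",
                 model$spec$name))
  }
  spec <- model$spec
  required <- "k1"
  if (spec$bilinear_terms >= 2L || spec$cbd_structure) {
    required <- c(required, "k2")
  }
  missing_idx <- setdiff(required, names(index_forecasts))
  if (length(missing_idx) > 0L) {
    stop(sprintf("missing index forecast(s): %s (required: %s)",
                 paste(missing_idx, collapse = ", "),
                 paste(required, collapse = ", ")))
  }
  h <- length(index_forecasts$k1$central)
  if (is.null(years)) years <- max(model$years) + seq_len(h)
  if (length(years) != h) {
    stop("'years' must match the forecast horizon of the index forecasts")
  }
  if ("k2" %in% required &&
      length(index_forecasts$k2$central) != h) {
    stop("all index forecasts must share one horizon")
  }
  if (is.null(ages)) ages <- model$ages

  loading_of <- function(idx) {
    if (spec$cbd_structure) {
      if (idx == "k1") rep(1, length(ages)) else ages - model$x_bar
    } else if (idx == "k1") {
      if (spec$bilinear_terms >= 1L) model$b1[match(ages, model$ages)]
      else rep(1, length(ages))  # APC
    } else {
      model$b2[match(ages, model$ages)]
    }
  }

  pick_bound <- function(side) {
    # side "lower": minimise eta; "upper": maximise
    k <- list()
    for (idx in required) {
      fc <- index_forecasts[[idx]]
      lo <- matrix(fc$lower, length(ages), h, byrow = TRUE)
      hi <- matrix(fc$upper, length(ages), h, byrow = TRUE)
      L <- loading_of(idx)
      use_lo <- if (side == "lower") L >= 0 else L < 0
      k[[idx]] <- ifelse(matrix(use_lo, length(ages), h), lo, hi)
    }
    k
  }

  # predictor with all indices at 0; a single cohort-freeze warning can
  # surface here. The predictor is linear in the indices, so bounds and
  # central paths are base + sum of loading * index value.
  eta_base <- model_eta_at(
    model, ages, years,
    k1 = stats::setNames(rep(0, h), years),
    k2 = if ("k2" %in% required) stats::setNames(rep(0, h), years),
    freeze_gamma = TRUE
  )
  eta_matrix <- function(kmats) {
    eta <- eta_base
    for (idx in required) {
      eta <- eta + loading_of(idx) * kmats[[idx]]
    }
    eta
  }
  central_k <- lapply(index_forecasts[required], function(fc) {
    matrix(fc$central, length(ages), h, byrow = TRUE)
  })
  q_central <- expit(eta_matrix(central_k))
  q_lower <- expit(eta_matrix(pick_bound("lower")))
  q_upper <- expit(eta_matrix(pick_bound("upper")))

  structure(
    list(central = q_central, lower = q_lower, upper = q_upper,
         years = years, ages = ages,
         level = index_forecasts$k1$level,
         model_name = spec$name, sex = model$sex),
    class = "q_forecast"
  )
}

#' Write a probability forecast as CSV
#'
#' One row per (year, age group): `year`, `age_lower`, `q_central`,
#' `q_lower`, `q_upper`, `model`, `sex`, `level`.
#'
#' @param fc A [forecast_probabilities()] result.
#' @param path Output file path.
#' @param age_lower Lower bounds matching `fc$ages` (defaults to
#'   midpoint minus half the implied width is not attempted; pass the
#'   grid's lower bounds for labelled output).
#' @export
write_q_forecast <- function(fc, path, age_lower = NULL) {
  if (!inherits(fc, "q_forecast")) stop("'fc' must be a q_forecast")
  if (is.null(age_lower)) age_lower <- fc$ages
  out <- data.frame(
    year = rep(fc$years, each = length(fc$ages)),
    age_lower = rep(age_lower, length(fc$years)),
    q_central = as.vector(fc$central),
    q_lower = as.vector(fc$lower),
    q_upper = as.vector(fc$upper),
    model = fc$model_name,
    sex = fc$sex,
    level = fc$level
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
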