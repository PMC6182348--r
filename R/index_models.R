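#' Fit a time-series model to a fitted period index
#'
#' Two closed-form models cover the index dynamics used for the logit
#' Lee-Carter family: a random walk with drift, ARIMA(0,1,0) with
#' constant, for the main period index (drift = mean of the first
#' differences, sigma = their standard deviation), and a stationary
#' AR(1) about a mean, ARIMA(1,0,0), for the second LC2 index
#' (conditional least-squares estimates). `kind = "auto"` chooses among
#' a small candidate set -- (0,1,0)+drift, (1,0,0)+mean, (1,1,0),
#' (0,1,1) -- by corrected AIC, mimicking automatic ARIMA selection;
#' `kind = "custom_arima"` fits a user-specified order via
#' [stats::arima()].
#'
#' @param series Numeric index values in year order (at least 3
#'   observations; at least 4 for `ar1_mean`).
#' @param kind One of `"rw_drift"`, `"ar1_mean"`, `"auto"`,
#'   `"custom_arima"`.
#' @param order Length-3 `c(p, d, q)` for `kind = "custom_arima"`.
#' @return An object of class `index_model` with fields `kind`, `drift`,
#'   `phi`, `mu`, `sigma`, `last_value` and (for custom orders) the
#'   underlying `arima` fit.
#' @examples
#' fit_index_model(c(0, -1, -2, -3), "rw_drift")  # drift -1, sigma 0
#' @export
fit_index_model <- function(series, kind = c("rw_drift", "ar1_mean",
                                             "auto", "custom_arima"),
                            order = NULL) {
  kind <- match.arg(kind)
  series <- as.numeric(series)
  n <- length(series)
  if (kind == "auto") return(auto_index_model(series))
  if (kind == "rw_drift") {
    if (n < 3L) stop("rw_drift needs at least 3 observations, got ", n)
    dd <- diff(series)
    model <- list(kind = "rw_drift", drift = mean(dd),
                  phi = NA_real_, mu = NA_real_,
                  sigma = stats::sd(dd), last_value = series[n])
  } else if (kind == "ar1_mean") {
    if (n < 4L) stop("ar1_mean needs at least 4 observations, got ", n)
    y <- series[-1L]
    x <- series[-n]
    vx <- sum((x - mean(x))^2)
    phi <- if (vx < 1e-300) 0 else
      sum((x - mean(x)) * (y - mean(y))) / vx
    if (abs(phi) >= 1) {
      warning(sprintf(
        "estimated AR coefficient %.4f is outside (-1, 1); the process is non-stationary",
        phi
      ))
    }
    mu <- if (abs(1 - phi) < 1e-12) mean(series) else
      (mean(y) - phi * mean(x)) / (1 - phi)
    resid <- y - mu - phi * (x - mu)
    sigma <- sqrt(sum(resid^2) / max(1L, n - 3L))
    model <- list(kind = "ar1_mean", drift = NA_real_, phi = phi, mu = mu,
                  sigma = sigma, last_value = series[n])
  } else {
    if (is.null(order) || length(order) != 3L) {
      stop("custom_arima needs 'order = c(p, d, q)'")
    }
    if (n < sum(order) + 2L) stop("series too short for the requested order")
    fit <- stats::arima(series, order = order,
                        include.mean = order[2L] == 0L, method = "ML")
    model <- list(kind = "custom_arima", order = order, fit = fit,
                  drift = NA_real_, phi = NA_real_, mu = NA_real_,
                  sigma = sqrt(fit$sigma2), last_value = series[n])
  }
  structure(model, class = "index_model")
}

# Default index model for a second (nominally mean-reverting) index:
# AR(1) about a mean, falling back to a random walk with drift when the
# AR estimate is non-stationary (|phi| >= 1), i.e. when the realised
# index trends instead of reverting.
fit_second_index_model <- function(series, kind = "ar1_mean") {
  if (kind != "ar1_mean") return(fit_index_model(series, kind))
  m <- withCallingHandlers(
    fit_index_model(series, "ar1_mean"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.finite(m$phi) && abs(m$phi) >= 1) {
    return(fit_index_model(series, "rw_drift"))
  }
  m
}

# Corrected-AIC choice among the small candidate set.
auto_index_model <- function(series) {
  n <- length(series)
  cands <- list(
    rw_drift = function() {
      dd <- diff(series)
      k <- 2  # drift + sigma
      ll <- sum(stats::dnorm(dd, mean(dd),
                             max(stats::sd(dd) * sqrt((n - 2) / (n - 1)), 1e-8),
                             log = TRUE))
      list(aicc = -2 * ll + 2 * k * (n - 1) / max(n - 2 - k, 1),
           model = fit_index_model(series, "rw_drift"))
    },
    ar1_mean = function() {
      m <- fit_index_model(series, "ar1_mean")
      r <- series[-1L] - m$mu - m$phi * (series[-n] - m$mu)
      k <- 3
      ll <- sum(stats::dnorm(r, 0, max(m$sigma, 1e-8), log = TRUE))
      list(aicc = -2 * ll + 2 * k * (n - 1) / max(n - 1 - k - 1, 1), model = m)
    },
    arima110 = function() {
      f <- stats::arima(series, order = c(1, 1, 0), method = "ML")
      k <- 2
      list(aicc = f$aic + 2 * k * (k + 1) / max(n - k - 1, 1),
           model = structure(list(kind = "custom_arima", order = c(1, 1, 0),
                                  fit = f, sigma = sqrt(f$sigma2),
                                  last_value = series[n]),
                             class = "index_model"))
    },
    arima011 = function() {
      f <- stats::arima(series, order = c(0, 1, 1), method = "ML")
      k <- 2
      list(aicc = f$aic + 2 * k * (k + 1) / max(n - k - 1, 1),
           model = structure(list(kind = "custom_arima", order = c(0, 1, 1),
                                  fit = f, sigma = sqrt(f$sigma2),
                                  last_value = series[n]),
                             class = "index_model"))
    }
  )
  # candidate evaluation must not leak warnings for models not chosen
  results <- lapply(cands, function(f) {
    tryCatch(suppressWarnings(f()), error = function(e) NULL)
  })
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L) stop("no candidate index model could be fitted")
  best <- results[[which.min(vapply(results, `[[`, numeric(1), "aicc"))]]
  best$model
}

#' @export
print.index_model <- function(x, ...) {
  desc <- switch(x$kind,
    rw_drift = sprintf("random walk with drift %.4g (sigma %.4g)",
                       x$drift, x$sigma),
    ar1_mean = sprintf("AR(1) about mean %.4g, phi %.4g (sigma %.4g)",
                       x$mu, x$phi, x$sigma),
    custom_arima = sprintf("ARIMA(%s) (sigma %.4g)",
                           paste(x$order, collapse = ","), x$sigma)
  )
  cat("Index model:", desc, "\n")
  invisible(x)
}

#' Forecast a period index with prediction intervals
#'
#' Central forecasts and normal prediction intervals from the index
#' process alone (no parameter uncertainty), following the original
#' Lee-Carter proposal of deriving intervals from the prediction errors
#' of the index. For the random walk with drift the central path at step
#' `s` is `last + s * drift` with interval half-width
#' `z * sigma * sqrt(s)`; for the AR(1) it is
#' `mu + phi^s * (last - mu)` with the standard AR(1) forecast error
#' variance `sigma^2 * (1 - phi^(2s)) / (1 - phi^2)`.
#'
#' @param model An [fit_index_model()] result.
#' @param h Forecast horizon in years (at least 1).
#' @param level Interval coverage in (0, 1), default 0.95.
#' @param last_value Origin of the forecast; defaults to the last
#'   observed value stored in the model.
#' @param horizon_years Optional calendar-year labels for the horizon.
#' @return An object of class `index_forecast` with fields
#'   `horizon_years`, `central`, `lower`, `upper`, `level`.
#' @export
forecast_index <- function(model, h, level = 0.95,
                           last_value = model$last_value,
                           horizon_years = NULL) {
  if (!inherits(model, "index_model")) stop("'model' must be an index_model")
  if (!is.numeric(h) || length(h) != 1L || h < 1) {
    stop("'h' must be a positive horizon")
  }
  h <- as.integer(h)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must lie strictly between 0 and 1")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  s <- seq_len(h)
  if (model$kind == "rw_drift") {
    central <- last_value + s * model$drift
    half <- z * model$sigma * sqrt(s)
  } else if (model$kind == "ar1_mean") {
    central <- model$mu + model$phi^s * (last_value - model$mu)
    varh <- if (abs(model$phi) >= 1) {
      model$sigma^2 * s
    } else {
      model$sigma^2 * (1 - model$phi^(2 * s)) / (1 - model$phi^2)
    }
    half <- z * sqrt(varh)
  } else {
    pr <- stats::predict(model$fit, n.ahead = h)
    central <- as.numeric(pr$pred)
    half <- z * as.numeric(pr$se)
  }
  if (is.null(horizon_years)) horizon_years <- s
  structure(
    list(horizon_years = horizon_years, central = central,
         lower = central - half, upper = central + half, level = level),
    class = "index_forecast"
  )
}

#' @export
print.index_forecast <- function(x, ...) {
  cat(sprintf("Index forecast, %d steps, %g%% intervals\n",
              length(x$central), 100 * x$level))
  print(data.frame(year = x$horizon_years, central = x$central,
                   lower = x$lower, upper = x$upper), row.names = FALSE)
  invisible(x)
}

#' @export
plot.index_forecast <- function(x, ...) {
  yl <- range(x$lower, x$upper)
  plot(x$horizon_years, x$central, type = "l", ylim = yl,
       xlab = "year", ylab = "index", ...)
  graphics::lines(x$horizon_years, x$lower, lty = 3)
  graphics::lines(x$horizon_years, x$upper, lty = 3)
  invisible(x)
}
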