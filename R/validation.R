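#' Hold-out split of calendar years
#'
#' Splits a contiguous block of years into a training block (the first
#' `ceiling(fraction * T)` years) and a validation block (the rest).
#' With 33 years and the default fraction 0.75 this yields a 25-year
#' training period and an 8-year validation period. The split is
#' label-based: reordering the input years does not change it.
#'
#' @param years Calendar years (at least 4).
#' @param fraction Training share in (0, 1), default 0.75.
#' @return An object of class `holdout_plan` with fields `train_years`,
#'   `validation_years` and `fraction`.
#' @examples
#' holdout_split(1973:2005)  # train 1973-1997, validation 1998-2005
#' @export
holdout_split <- function(years, fraction = 0.75) {
  years <- sort(unique(as.numeric(years)))
  if (length(years) < 4L) stop("need at least 4 years to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("'fraction' must lie strictly between 0 and 1")
  }
  n_train <- ceiling(fraction * length(years))
  if (n_train >= length(years)) {
    stop(sprintf(
      "fraction %g leaves an empty validation set for %d years",
      fraction, length(years)
    ))
  }
  structure(
    list(train_years = years[seq_len(n_train)],
         validation_years = years[-seq_len(n_train)],
         fraction = fraction),
    class = "holdout_plan"
  )
}

#' @export
print.holdout_plan <- function(x, ...) {
  cat(sprintf(
    "Hold-out plan: train %g-%g (%d years), validation %g-%g (%d years), fraction %g\n",
    min(x$train_years), max(x$train_years), length(x$train_years),
    min(x$validation_years), max(x$validation_years),
    length(x$validation_years), x$fraction
  ))
  invisible(x)
}

check_same_shape <- function(q_obs, q_hat) {
  q_obs <- as.matrix(q_obs)
  q_hat <- as.matrix(q_hat)
  if (!identical(dim(q_obs), dim(q_hat))) {
    stop(sprintf("shape mismatch: observed %dx%d vs predicted %dx%d",
                 nrow(q_obs), ncol(q_obs), nrow(q_hat), ncol(q_hat)))
  }
  if (anyNA(q_obs) || anyNA(q_hat)) stop("missing cells are not allowed")
  list(q_obs = q_obs, q_hat = q_hat)
}

#' Root mean square error over an age x year block
#'
#' `sqrt(sum((q - q_hat)^2) / (n_x * T))` over all cells.
#'
#' @param q_obs,q_hat Matrices (or vectors) of equal shape.
#' @return Non-negative scalar.
#' @export
rmse <- function(q_obs, q_hat) {
  m <- check_same_shape(q_obs, q_hat)
  sqrt(sum((m$q_obs - m$q_hat)^2) / length(m$q_obs))
}

#' Mean absolute percentage error over an age x year block
#'
#' `100 * sum(|q - q_hat| / q) / (n_x * T)`. Every observed cell must be
#' positive; by default a zero observed probability is an error rather
#' than a silently dropped cell (`drop_zero_cells = TRUE` opts into
#' exclusion).
#'
#' @param q_obs,q_hat Matrices (or vectors) of equal shape.
#' @param drop_zero_cells Exclude cells with `q_obs = 0` instead of
#'   erroring (default `FALSE`).
#' @return Percentage (scalar).
#' @export
mape <- function(q_obs, q_hat, drop_zero_cells = FALSE) {
  m <- check_same_shape(q_obs, q_hat)
  zero <- m$q_obs == 0
  if (any(zero)) {
    if (!drop_zero_cells) {
      stop(sprintf(
        "%d cell(s) have observed q = 0; relative error is undefined (set drop_zero_cells = TRUE to exclude them)",
        sum(zero)
      ))
    }
    m$q_obs <- m$q_obs[!zero]
    m$q_hat <- m$q_hat[!zero]
  }
  100 * sum(abs(m$q_obs - m$q_hat) / m$q_obs) / length(m$q_obs)
}

#' Standardized deviance residuals for binomial death counts
#'
#' `r = sign(d - d_hat) * sqrt(2 * (d log(d / d_hat) +
#' (E - d) log((E - d) / (E - d_hat))))` with `0 log 0 = 0`. Under a
#' well-specified model these are approximately standard normal;
#' the reference interval (-2, 2) captures about 95.5% of a standard
#' normal and (-2.5, 2.5) about 99%, so cells outside them are flagged
#' as outliers.
#'
#' @param d_obs Observed deaths (matrix or vector), `0 <= d_obs <= E`.
#' @param d_hat Fitted deaths, strictly inside `(0, E)`.
#' @param E Initial exposures.
#' @param ages,years Optional labels; when `d_obs` is a matrix with
#'   ages in rows and years in columns these label the cells and enable
#'   cohort grouping in [residual_series()].
#' @return An object of class `residual_set`: a data.frame with columns
#'   `age`, `year`, `cohort`, `r`, `outlier_2` and `outlier_2.5`, with
#'   attribute `deviance_total` (`sum(r^2)`).
#' @export
deviance_residuals <- function(d_obs, d_hat, E, ages = NULL, years = NULL) {
  d_obs <- as.matrix(d_obs)
  d_hat <- as.matrix(d_hat)
  E <- as.matrix(E)
  if (!identical(dim(d_obs), dim(d_hat)) || !identical(dim(d_obs), dim(E))) {
    stop("'d_obs', 'd_hat' and 'E' must have identical shapes")
  }
  if (any(d_obs < 0 | d_obs > E)) stop("'d_obs' must lie in [0, E]")
  if (any(d_hat <= 0 | d_hat >= E)) {
    stop("'d_hat' must lie strictly inside (0, E)")
  }
  dev_cell <- 2 * (xlogy(d_obs, d_obs / d_hat) +
                   xlogy(E - d_obs, (E - d_obs) / (E - d_hat)))
  dev_cell <- pmax(dev_cell, 0)  # guard tiny negative rounding
  r <- sign(d_obs - d_hat) * sqrt(dev_cell)
  if (is.null(ages)) ages <- seq_len(nrow(d_obs))
  if (is.null(years)) years <- seq_len(ncol(d_obs))
  out <- data.frame(
    age = rep(ages, times = ncol(d_obs)),
    year = rep(years, each = nrow(d_obs)),
    r = as.vector(r)
  )
  out$cohort <- out$year - out$age
  out$outlier_2 <- abs(out$r) >= 2
  out$outlier_2.5 <- abs(out$r) >= 2.5
  structure(out, deviance_total = sum(dev_cell),
            class = c("residual_set", "data.frame"))
}

#' Standard-normal capture percentage of a residual reference interval
#'
#' The mass of a standard normal inside `(-halfwidth, halfwidth)`, in
#' percent: the expected share of standardized deviance residuals inside
#' the reference band under a well-specified model (about 95.5% for
#' halfwidth 2, about 99% for 2.5).
#'
#' @param halfwidth Positive half-width of the reference interval.
#' @return Percentage in (0, 100).
#' @export
residual_capture_percent <- function(halfwidth = 2) {
  if (halfwidth <= 0) stop("'halfwidth' must be positive")
  100 * (2 * stats::pnorm(halfwidth) - 1)
}

#' Residual scatter series by age, period or cohort
#'
#' @param res A [deviance_residuals()] result.
#' @param axis One of `"age"`, `"period"`, `"cohort"`.
#' @return A data.frame with columns `value` (axis coordinate) and `r`,
#'   plus attribute `reference = c(-2, 2)`.
#' @export
residual_series <- function(res, axis = c("age", "period", "cohort")) {
  if (!inherits(res, "residual_set")) stop("'res' must be a residual_set")
  axis <- match.arg(axis)
  value <- switch(axis, age = res$age, period = res$year,
                  cohort = res$cohort)
  structure(data.frame(value = value, r = res$r),
            axis = axis, reference = c(-2, 2))
}
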