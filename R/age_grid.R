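#' Abridged age grid
#'
#' An age grid describes contiguous, half-open age groups
#' `[lower, lower + width)`. Each group is represented in model fitting by
#' its midpoint age, the convention used throughout the package for the
#' age argument `x` of the mortality models and for cohort labels
#' `c = t - x`.
#'
#' @param lower_bounds Numeric vector of group lower bounds in years,
#'   strictly increasing, first element 0.
#' @param widths Numeric vector of group widths in years, all positive.
#'   Groups must tile: `lower_bounds[i + 1] == lower_bounds[i] + widths[i]`.
#'
#' @return An object of class `age_grid`: a list with elements
#'   `lower`, `width` and `midpoint` (all numeric vectors of equal length).
#' @seealso [paper_age_grid()] for the standard 18-group abridged grid.
#' @examples
#' g <- age_grid(c(0, 1, 5), c(1, 4, 5))
#' g$midpoint  # 0.5 3.0 7.5
#' @export
age_grid <- function(lower_bounds, widths) {
  lower_bounds <- as.numeric(lower_bounds)
  widths <- as.numeric(widths)
  if (length(lower_bounds) == 0L) {
    stop("age grid must contain at least one group")
  }
  if (length(widths) != length(lower_bounds)) {
    stop("'lower_bounds' and 'widths' must have the same length")
  }
  if (lower_bounds[1L] != 0) {
    stop("first age-group lower bound must be 0, got ", lower_bounds[1L])
  }
  if (any(widths <= 0)) {
    stop("all age-group widths must be positive")
  }
  if (length(lower_bounds) > 1L) {
    if (any(diff(lower_bounds) <= 0)) {
      stop("age-group lower bounds must be strictly increasing")
    }
    gap <- lower_bounds[-1L] - (lower_bounds[-length(lower_bounds)] +
                                  widths[-length(widths)])
    if (any(abs(gap) > 1e-9)) {
      i <- which(abs(gap) > 1e-9)[1L]
      stop(sprintf(
        "age groups must be contiguous: group starting at %g ends at %g but next group starts at %g",
        lower_bounds[i], lower_bounds[i] + widths[i], lower_bounds[i + 1L]
      ))
    }
  }
  structure(
    list(
      lower = lower_bounds,
      width = widths,
      midpoint = lower_bounds + widths / 2
    ),
    class = "age_grid"
  )
}

#' Standard 18-group abridged age grid
#'
#' The abridged grouping used by the Latin American Human Mortality
#' Database tables: `[0,1)`, `[1,5)`, `[5,10)`, then 5-year groups up to
#' the closing age 85.
#'
#' @return An [age_grid()] with 18 groups ending at age 85.
#' @export
paper_age_grid <- function() {
  age_grid(
    lower_bounds = c(0, 1, seq(5, 80, by = 5)),
    widths = c(1, 4, rep(5, 16))
  )
}

#' @export
print.age_grid <- function(x, ...) {
  n <- length(x$lower)
  cat(sprintf(
    "Abridged age grid: %d groups, ages [0, %g)\n",
    n, x$lower[n] + x$width[n]
  ))
  cat("  groups:", paste0(
    "[", x$lower, ",", x$lower + x$width, ")",
    collapse = " "
  ), "\n")
  invisible(x)
}

#' @export
length.age_grid <- function(x) length(x$lower)

#' @rdname age_grid
#' @param x Object to test or print.
#' @export
is_age_grid <- function(x) inherits(x, "age_grid")

#' Logit and inverse-logit transforms for death probabilities
#'
#' The models in this package act on the logit scale,
#' `logit(q) = log(q / (1 - q))`, so that fitted death probabilities
#' always lie in (0, 1).
#'
#' @param q Death probabilities, strictly inside (0, 1).
#' @param eta Real-valued predictor.
#' @return `logit()` returns real values; `expit()` returns probabilities
#'   in (0, 1).
#' @examples
#' logit(0.5)        # 0
#' expit(logit(0.1)) # 0.1
#' @export
logit <- function(q) {
  bad <- which(!is.na(q) & (q <= 0 | q >= 1))
  if (length(bad) > 0L) {
    stop(sprintf(
      "logit requires probabilities strictly in (0, 1); offending element %d has value %g",
      bad[1L], q[bad[1L]]
    ))
  }
  log(q / (1 - q))
}

#' @rdname logit
#' @export
expit <- function(eta) {
  1 / (1 + exp(-eta))
}

#' Continuity-corrected empirical death probability
#'
#' `(d + 0.5) / (E + 1)`, used only to initialise model fits when an
#' empirical probability of 0 or 1 would break the logit transform.
#' Stored data are never silently modified.
#'
#' @param d Observed deaths per cell.
#' @param E Initially exposed to risk per cell.
#' @return Probabilities strictly inside (0, 1).
#' @keywords internal
continuity_corrected_q <- function(d, E) {
  (d + 0.5) / (E + 1)
}
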