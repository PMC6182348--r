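#' Life expectancy at a group-start age
#'
#' `e_x = T_x / l_x`: the mean further years lived from age `x` under
#' the table's mortality.
#'
#' @param table An `abridged_life_table`.
#' @param x Age at which to evaluate; must be a group boundary (lower
#'   bound of some group).
#' @return Years (scalar).
#' @examples
#' g <- age_grid(c(0, 1, 5), c(1, 4, 5))
#' life_expectancy(build_life_table(c(0, 0, 1), g), 0)  # 7.5
#' @export
life_expectancy <- function(table, x = 0) {
  if (!inherits(table, "abridged_life_table")) {
    stop("'table' must be an abridged_life_table")
  }
  i <- which(abs(table$age_lower - x) < 1e-9)
  if (length(i) != 1L) {
    nearest <- table$age_lower[which.min(abs(table$age_lower - x))]
    stop(sprintf(
      "age %g is not a group boundary of this table; nearest boundary is %g",
      x, nearest
    ))
  }
  if (table$l[i] <= 0) {
    stop(sprintf("no survivors at age %g (l = 0); life expectancy undefined", x))
  }
  table$T[i] / table$l[i]
}

#' Modal age-at-death interval
#'
#' The age group with the maximum number of life-table deaths `d` among
#' groups whose lower bound is at least `min_age`; ties are broken
#' toward the youngest interval. The default `min_age = 10` targets the
#' adult mode, which is the longevity indicator of interest even when
#' infant deaths are numerous; set `min_age = 0` for the global mode.
#'
#' @param table An `abridged_life_table`.
#' @param min_age Minimum group lower bound considered (years).
#' @return Numeric `c(lower, upper)` of the modal interval.
#' @export
modal_age_interval <- function(table, min_age = 10) {
  if (!inherits(table, "abridged_life_table")) {
    stop("'table' must be an abridged_life_table")
  }
  keep <- table$age_lower >= min_age
  if (!any(keep)) {
    stop(sprintf("no age group at or above min_age = %g", min_age))
  }
  d <- table$d[keep]
  if (all(d == 0)) stop("all life-table deaths are zero; no modal interval")
  i <- which.max(d)  # first maximum = youngest on ties
  lower <- table$age_lower[keep][i]
  c(lower = lower, upper = lower + table$age_width[keep][i])
}

#' Lorenz curve of mortality
#'
#' Plots, from a start age `x0`, the cumulative proportion of deaths
#' `N_i` against the cumulative proportion of years lived by those
#' decedents `Y_i`, where the years lived by deaths in a group are
#' `d * xbar` with `xbar = lower + a_frac * width` (the mean age at
#' death within the group under the table's person-years convention).
#' The curve starts at (0, 0) and ends at (1, 1); for age-ordered groups
#' it lies on or below the diagonal.
#'
#' @param table An `abridged_life_table`.
#' @param x0 Start age (a group boundary), default 0.
#' @return An object of class `lorenz_curve`: a data.frame with columns
#'   `N` and `Y` (first row (0, 0)), with attribute `start_age`.
#' @export
lorenz_points <- function(table, x0 = 0) {
  if (!inherits(table, "abridged_life_table")) {
    stop("'table' must be an abridged_life_table")
  }
  keep <- table$age_lower >= x0 - 1e-9
  if (!any(keep)) stop(sprintf("no age groups at or above x0 = %g", x0))
  d <- table$d[keep]
  if (sum(d) <= 0) {
    stop(sprintf("no life-table deaths from age %g onward", x0))
  }
  xbar <- table$age_lower[keep] + table$a_frac[keep] * table$age_width[keep]
  N <- cumsum(d) / sum(d)
  Y <- cumsum(d * xbar) / sum(d * xbar)
  out <- data.frame(N = c(0, N), Y = c(0, Y))
  structure(out, start_age = x0, class = c("lorenz_curve", "data.frame"))
}

#' @export
plot.lorenz_curve <- function(x, ...) {
  plot(x$N, x$Y, type = "l", xlab = "cumulative proportion of deaths",
       ylab = "cumulative proportion of years lived", xlim = c(0, 1),
       ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Gini index of mortality for abridged tables
#'
#' The trapezoidal Gini over the Lorenz points,
#' `G = |1 - sum_i (N_i - N_(i-1)) * (Y_(i-1) + Y_i)|`, with
#' `N_(x0-1) = Y_(x0-1) = 0`. Zero means all individuals die at
#' (approximately) the same age; values near one indicate strong
#' inequality in age at death.
#'
#' @param table An `abridged_life_table`.
#' @param x0 Start age (group boundary), default 0.
#' @return Dimensionless index in `[0, 1]`.
#' @export
gini_abridged <- function(table, x0 = 0) {
  lp <- lorenz_points(table, x0)
  n <- nrow(lp)
  dN <- lp$N[-1L] - lp$N[-n]
  sY <- lp$Y[-n] + lp$Y[-1L]
  abs(1 - sum(dN * sY))
}

#' Gini index at birth from complete-table columns
#'
#' The alternative expression using survivors and remaining person-years
#' at every table age `x < omega`:
#' `G_0 = sum(f_x - g_x) / sum(f_x)` with
#' `f_x = (l_0 - l_x) / l_0` and `g_x = (T_0 - T_x - x l_x) / T_0`.
#' The table must be extinct at its closing age (the default
#' [build_life_table()] closure guarantees this). On fine (1-year)
#' grids this agrees closely with [gini_abridged()].
#'
#' @param table An `abridged_life_table`, extinct at `omega`.
#' @return Dimensionless index.
#' @export
gini_complete <- function(table) {
  if (!inherits(table, "abridged_life_table")) {
    stop("'table' must be an abridged_life_table")
  }
  l0 <- table$l[1L]
  if (l0 <= 0) stop("empty table: l at age 0 is 0")
  last_q <- table$q[nrow(table)]
  if (abs(last_q - 1) > 1e-9) {
    stop("gini_complete needs a table closed at omega (q = 1 in the last group); rebuild with close_last = TRUE")
  }
  x <- table$age_lower
  l <- table$l
  T0 <- table$T[1L]
  f <- (l0 - l) / l0
  g <- (T0 - table$T - x * l) / T0
  sum_f <- sum(f)
  if (sum_f <= 0) stop("degenerate table: no deaths before omega")
  sum(f - g) / sum_f
}

#' Death and survival curve series
#'
#' Plottable series of the life-table death distribution `d` and the
#' survival curve `l` against the group start ages. Rectangularization
#' shows as death mass shifting right while `l` stays high longer.
#'
#' @param table An `abridged_life_table`.
#' @return A list with data.frames `deaths` (`age`, `d`) and `survival`
#'   (`age`, `l`).
#' @export
death_survival_curves <- function(table) {
  if (!inherits(table, "abridged_life_table")) {
    stop("'table' must be an abridged_life_table")
  }
  list(
    deaths = data.frame(age = table$age_lower, d = table$d),
    survival = data.frame(age = table$age_lower, l = table$l)
  )
}

#' Indicator series for a set of life tables
#'
#' Per-year summary of the indicators studied alongside the mortality
#' models: life expectancy at birth and at 65, Gini indices at birth and
#' at 65, and the modal age-at-death interval.
#'
#' @param tables A list of `abridged_life_table` objects (or one table).
#' @param modal_min_age Passed to [modal_age_interval()].
#' @return A data.frame with columns `year`, `sex`, `e0`, `e65`, `G0`,
#'   `G65`, `modal_lower`, `modal_upper`.
#' @export
indicator_series <- function(tables, modal_min_age = 10) {
  if (inherits(tables, "abridged_life_table")) tables <- list(tables)
  rows <- lapply(tables, function(lt) {
    m <- modal_age_interval(lt, min_age = modal_min_age)
    data.frame(
      year = attr(lt, "year"),
      sex = attr(lt, "sex"),
      e0 = life_expectancy(lt, 0),
      e65 = life_expectancy(lt, 65),
      G0 = gini_abridged(lt, 0),
      G65 = gini_abridged(lt, 65),
      modal_lower = m[["lower"]],
      modal_upper = m[["upper"]]
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$sex, out$year), , drop = FALSE]
}
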