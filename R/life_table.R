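#' Build an abridged life table from death probabilities
#'
#' Computes the classical life-table columns on an abridged age grid from
#' per-group probabilities of death: survivors `l`, life-table deaths `d`,
#' person-years `L`, remaining person-years `T` and life expectancy `e`.
#' Person-years in a group of width `n` are
#' `L = n * (l - d) + a_frac * n * d`, i.e. those dying in the group are
#' assumed to live a fraction `a_frac` of it (default 0.5, mid-interval
#' deaths).
#'
#' The grid has no open-ended final interval; indicator work (Lorenz
#' curve, Gini index) needs the cohort to be extinct by the closing age,
#' so with `close_last = TRUE` (the default) the last group's probability
#' is forced to 1 and the table records the closing age as `omega`.
#'
#' @param q Numeric vector of death probabilities per group, in `[0, 1]`.
#' @param grid An [age_grid()].
#' @param radix Survivors at age 0 (default 100000).
#' @param a_frac Average fraction of the interval lived by those dying in
#'   it; scalar or per-group vector in `[0, 1]`. Default 0.5.
#' @param year Calendar year label (optional).
#' @param sex Sex label (optional).
#' @param E Initially exposed to risk per group (optional, persons).
#' @param d_obs Observed death counts per group (optional, persons).
#' @param close_last Force `q = 1` in the last group so the table closes.
#'
#' @return An object of class `abridged_life_table`: a `data.frame` with
#'   columns `age_lower`, `age_width`, `age_mid`, `q`, `a_frac`, `l`, `d`,
#'   `L`, `T`, `e` (and `E`, `d_obs` when supplied), with attributes
#'   `grid`, `radix`, `year`, `sex` and `omega`.
#' @examples
#' g <- age_grid(c(0, 1, 5), c(1, 4, 5))
#' lt <- build_life_table(c(0, 0, 1), g, radix = 1)
#' lt$e[1]  # 7.5: survive 1 + 4 years, then die mid-way through 5
#' @export
build_life_table <- function(q, grid, radix = 1e5, a_frac = 0.5,
                             year = NA, sex = NA_character_,
                             E = NULL, d_obs = NULL, close_last = TRUE) {
  if (!is_age_grid(grid)) stop("'grid' must be an age_grid")
  n <- length(grid)
  q <- as.numeric(q)
  if (length(q) != n) {
    stop(sprintf("'q' has length %d but the grid has %d groups", length(q), n))
  }
  if (anyNA(q)) stop("'q' must not contain missing values")
  if (any(q < 0 | q > 1)) {
    bad <- which(q < 0 | q > 1)[1L]
    stop(sprintf("probabilities of death must lie in [0, 1]; q[%d] = %g",
                 bad, q[bad]))
  }
  if (!is.numeric(radix) || length(radix) != 1L || radix <= 0) {
    stop("'radix' must be a single positive number")
  }
  a_frac <- rep_len(as.numeric(a_frac), n)
  if (any(a_frac < 0 | a_frac > 1)) {
    stop("'a_frac' must lie in [0, 1]")
  }
  if (close_last) q[n] <- 1

  l <- numeric(n)
  l[1L] <- radix
  for (i in seq_len(n - 1L)) l[i + 1L] <- l[i] * (1 - q[i])
  d <- l * q
  w <- grid$width
  L <- w * (l - d) + a_frac * w * d
  T_ <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T_ / l, 0)

  out <- data.frame(
    age_lower = grid$lower,
    age_width = grid$width,
    age_mid = grid$midpoint,
    q = q,
    a_frac = a_frac,
    l = l,
    d = d,
    L = L,
    T = T_,
    e = e
  )
  if (!is.null(E)) {
    E <- as.numeric(E)
    if (length(E) != n) stop("'E' must have one value per age group")
    if (any(E < 0)) stop("'E' must be non-negative")
    out$E <- E
  }
  if (!is.null(d_obs)) {
    d_obs <- as.numeric(d_obs)
    if (length(d_obs) != n) stop("'d_obs' must have one value per age group")
    if (any(d_obs < 0)) stop("'d_obs' must be non-negative")
    if (!is.null(E) && any(d_obs > E + 1e-9)) {
      bad <- which(d_obs > E + 1e-9)[1L]
      stop(sprintf(
        "observed deaths exceed exposure in age group [%g,%g): d = %g, E = %g",
        grid$lower[bad], grid$lower[bad] + grid$width[bad], d_obs[bad], E[bad]
      ))
    }
    out$d_obs <- d_obs
  }
  structure(
    out,
    grid = grid,
    radix = radix,
    year = year,
    sex = sex,
    omega = grid$lower[n] + grid$width[n],
    class = c("abridged_life_table", "data.frame")
  )
}

#' @export
print.abridged_life_table <- function(x, ...) {
  cat(sprintf(
    "Abridged life table (%s, year %s): %d age groups, radix %g, e0 = %.2f\n",
    ifelse(is.na(attr(x, "sex")), "sex n/a", attr(x, "sex")),
    ifelse(is.na(attr(x, "year")), "n/a", attr(x, "year")),
    nrow(x), attr(x, "radix"), x$e[1L]
  ))
  print.data.frame(x, digits = 4, row.names = FALSE, ...)
  invisible(x)
}

#' Interpolated population counts between censuses
#'
#' Holds per-age-group population counts at census years and interpolates
#' linearly, per age group, for intercensal years. No extrapolation is
#' performed outside the census range.
#'
#' @param grid An [age_grid()].
#' @param census_years Strictly increasing integer census years.
#' @param census_counts Matrix of persons, one row per age group, one
#'   column per census year.
#' @return An object of class `population_series`.
#' @export
population_series <- function(grid, census_years, census_counts) {
  if (!is_age_grid(grid)) stop("'grid' must be an age_grid")
  census_years <- as.numeric(census_years)
  if (length(census_years) < 2L) stop("need at least two census years")
  if (any(diff(census_years) <= 0)) {
    stop("'census_years' must be strictly increasing")
  }
  census_counts <- as.matrix(census_counts)
  if (nrow(census_counts) != length(grid) ||
      ncol(census_counts) != length(census_years)) {
    stop("'census_counts' must be n_groups x n_census_years")
  }
  if (any(census_counts < 0)) stop("census counts must be non-negative")
  structure(
    list(grid = grid, census_years = census_years, counts = census_counts),
    class = "population_series"
  )
}

#' @describeIn population_series Linear interpolation of the population at
#'   `year`, which must lie within the census range; returns the census
#'   column exactly at a census year.
#' @param series A `population_series`.
#' @param year Calendar year at which to interpolate.
#' @export
interpolate_populations <- function(series, year) {
  if (!inherits(series, "population_series")) {
    stop("'series' must be a population_series")
  }
  yrs <- series$census_years
  if (year < yrs[1L] || year > yrs[length(yrs)]) {
    stop(sprintf(
      "year %g outside census range [%g, %g]: no extrapolation",
      year, yrs[1L], yrs[length(yrs)]
    ))
  }
  hit <- which(yrs == year)
  if (length(hit) == 1L) return(series$counts[, hit])
  j <- findInterval(year, yrs)
  f <- (year - yrs[j]) / (yrs[j + 1L] - yrs[j])
  (1 - f) * series$counts[, j] + f * series$counts[, j + 1L]
}
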