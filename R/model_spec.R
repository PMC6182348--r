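#' Mortality model specifications
#'
#' Declarative description of the seven logit mortality models supported
#' by the package. All act on `logit(q_xt)` with `x` the age-group
#' midpoint and `t` the calendar year; `c = t - x` is the birth cohort.
#'
#' \describe{
#'   \item{LC}{`a_x + b_x k_t`; constraints `sum(b) = 1`, `k[t0] = 0`.}
#'   \item{LC2}{`a_x + b1_x k1_t + b2_x k2_t`; per term `sum(b) = 1`,
#'     `k[t0] = 0`.}
#'   \item{LCC}{`a_x + b1_x k_t + b2_x gamma_c`; `sum(b1) = sum(b2) = 1`,
#'     `k[t0] = 0`, `gamma[c0] = 0`.}
#'   \item{APC}{`a_x + k_t + gamma_c`; `k[t0] = 0`, `gamma[c0] = 0`.}
#'   \item{RH}{`a_x + b1_x k1_t + gamma_c`; `sum(b1) = 1`,
#'     `sum_t k_t = 0`, `sum_c gamma_c = 0`.}
#'   \item{CBD}{`k1_t + (x - xbar) k2_t`, `xbar` the mean age in the
#'     data; no constraints.}
#'   \item{M8}{`k1_t + (x - xbar) k2_t + (xc - x) gamma_c` with `xc` an
#'     estimated constant; `sum_c gamma_c = 0`.}
#' }
#'
#' @param name One of `"LC"`, `"LC2"`, `"LCC"`, `"APC"`, `"RH"`,
#'   `"CBD"`, `"M8"`.
#' @return An object of class `mortality_model_spec` with fields `name`,
#'   `has_static_age`, `bilinear_terms` (count of age-period b*k
#'   products), `cohort_term` (one of `"none"`, `"free_slope"`,
#'   `"unit_slope"`, `"cbd_slope"`), `cbd_structure` and `constraints`.
#' @examples
#' model_spec("LC")
#' @export
model_spec <- function(name) {
  name <- match.arg(toupper(name), model_names())
  fields <- switch(name,
    LC = list(has_static_age = TRUE, bilinear_terms = 1L,
              cohort_term = "none", cbd_structure = FALSE,
              constraints = c("sum_b1 = 1", "k1[t0] = 0")),
    LC2 = list(has_static_age = TRUE, bilinear_terms = 2L,
               cohort_term = "none", cbd_structure = FALSE,
               constraints = c("sum_b1 = 1", "k1[t0] = 0",
                               "sum_b2 = 1", "k2[t0] = 0")),
    LCC = list(has_static_age = TRUE, bilinear_terms = 1L,
               cohort_term = "free_slope", cbd_structure = FALSE,
               constraints = c("sum_b1 = 1", "k1[t0] = 0",
                               "sum_b2 = 1", "gamma[c0] = 0")),
    APC = list(has_static_age = TRUE, bilinear_terms = 0L,
               cohort_term = "unit_slope", cbd_structure = FALSE,
               constraints = c("k1[t0] = 0", "gamma[c0] = 0")),
    RH = list(has_static_age = TRUE, bilinear_terms = 1L,
              cohort_term = "unit_slope", cbd_structure = FALSE,
              constraints = c("sum_b1 = 1", "sum_t k1 = 0",
                              "sum_c gamma = 0")),
    CBD = list(has_static_age = FALSE, bilinear_terms = 0L,
               cohort_term = "none", cbd_structure = TRUE,
               constraints = character(0)),
    M8 = list(has_static_age = FALSE, bilinear_terms = 0L,
              cohort_term = "cbd_slope", cbd_structure = TRUE,
              constraints = "sum_c gamma = 0")
  )
  structure(c(list(name = name), fields), class = "mortality_model_spec")
}

#' @rdname model_spec
#' @export
model_names <- function() c("LC", "LC2", "LCC", "APC", "RH", "CBD", "M8")

#' @export
print.mortality_model_spec <- function(x, ...) {
  cat(sprintf("Mortality model spec: %s\n", x$name))
  cat(sprintf(
    "  static age: %s | bilinear age-period terms: %d | cohort term: %s%s\n",
    x$has_static_age, x$bilinear_terms, x$cohort_term,
    if (x$cbd_structure) " | CBD age structure" else ""
  ))
  if (length(x$constraints) > 0L) {
    cat("  constraints:", paste(x$constraints, collapse = ", "), "\n")
  } else {
    cat("  constraints: none\n")
  }
  invisible(x)
}

as_model_spec <- function(spec) {
  if (inherits(spec, "mortality_model_spec")) spec else model_spec(spec)
}

#' Cohort labels for an age grid and year range
#'
#' The cohort of a cell is the year of birth `c = t - x`, with `x` the
#' age-group midpoint. On the abridged grid this produces half-integer
#' labels for most groups.
#'
#' @param grid An [age_grid()].
#' @param years Vector of calendar years.
#' @return A list with `matrix` (cohort label per age x year cell) and
#'   `labels` (sorted distinct labels).
#' @examples
#' cl <- cohort_labels(paper_age_grid(), 1973:1975)
#' cl$matrix[1, 1]  # 1972.5
#' @export
cohort_labels <- function(grid, years) {
  if (!is_age_grid(grid)) stop("'grid' must be an age_grid")
  years <- as.numeric(years)
  m <- outer(-grid$midpoint, years, `+`)
  dimnames(m) <- list(
    paste0("[", grid$lower, ",", grid$lower + grid$width, ")"),
    as.character(years)
  )
  list(matrix = m, labels = sort(unique(as.vector(m))))
}

#' Residual degrees of freedom of a mortality model
#'
#' Number of data cells minus the number of identifiable parameters. The
#' count per component: a static age profile contributes `n_ages`; each
#' age-period bilinear term `b_x k_t` contributes `n_ages + n_years - 2`
#' (one scale and one location normalisation each), and a second bilinear
#' period term loses 2 more to the rotational freedom between the two
#' terms; an age-cohort bilinear term contributes
#' `n_ages + n_cohorts - 2`; a unit-slope cohort term contributes
#' `n_cohorts - 1`, and the APC model loses 1 more to the exact
#' age + cohort - period collinearity; the CBD structure contributes
#' `2 * n_years`; the M8 cohort term contributes `n_cohorts - 1` plus 1
#' for the estimated constant `xc`. The count equals the numerical rank
#' of the linearised predictor whenever the parameter count does not
#' exceed the cell count.
#'
#' @param spec A [model_spec()] or model name.
#' @param n_ages,n_years,n_cohorts Grid dimensions (cohort count after
#'   any pooling).
#' @return Integer degrees of freedom (may be negative if the model is
#'   over-parameterised for the grid).
#' @examples
#' residual_degrees_of_freedom("LC", 18, 25)  # 391
#' @export
residual_degrees_of_freedom <- function(spec, n_ages, n_years,
                                        n_cohorts = NULL) {
  spec <- as_model_spec(spec)
  if (n_ages < 1 || n_years < 1) stop("dimensions must be at least 1")
  needs_cohorts <- spec$cohort_term != "none"
  if (needs_cohorts && is.null(n_cohorts)) {
    stop(sprintf("model %s needs 'n_cohorts'", spec$name))
  }
  p <- 0L
  if (spec$has_static_age) p <- p + n_ages
  if (spec$bilinear_terms > 0L) {
    p <- p + spec$bilinear_terms * (n_ages + n_years - 2L)
    if (spec$bilinear_terms > 1L) p <- p - 2L  # inter-term rotation
  }
  if (spec$cbd_structure) p <- p + 2L * n_years
  if (spec$name == "APC") p <- p + n_years - 1L  # unit-slope period index
  p <- p + switch(spec$cohort_term,
    none = 0L,
    free_slope = n_ages + n_cohorts - 2L,
    unit_slope = (n_cohorts - 1L) - if (spec$name == "APC") 1L else 0L,
    cbd_slope = (n_cohorts - 1L) + 1L
  )
  as.integer(n_ages * n_years - p)
}
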