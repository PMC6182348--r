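# Synthetic abridged life tables with known Lee-Carter structure.
#
# The age profiles are smooth parametric shapes chosen to look like a
# middle-mortality country in demographic transition: a logistic-like
# infant decline, a Gompertz-type (log-linear) adult rise, and -- for the
# male preset -- a Gaussian young-adult hump centred near age 27 whose
# loading is negative (mortality at those ages worsens as the overall
# index falls). No claim is made of matching any country's estimates.

synthetic_a_profile <- function(m, preset) {
  switch(preset,
    male_like = -6.0 + 0.068 * m + 2.9 * exp(-m / 3) +
      0.6 * exp(-((m - 27) / 10)^2),
    female_like = -6.3 + 0.066 * m + 2.9 * exp(-m / 3),
    flat = rep(-4, length(m))
  )
}

synthetic_b1_profile <- function(m, preset) {
  raw <- switch(preset,
    male_like = 0.4 + 2 * exp(-m / 10) - 1.6 * exp(-((m - 27) / 13)^2),
    female_like = 0.5 + 2 * exp(-m / 12),
    flat = rep(1, length(m))
  )
  raw / sum(raw)
}

synthetic_b2_profile <- function(m) {
  raw <- 0.3 + 1.5 * exp(-m / 6)
  raw / sum(raw)
}

#' Ground truth for synthetic abridged life tables
#'
#' Builds the true parameters of a logit Lee-Carter world: a static age
#' profile `a`, normalised age loadings `b1` (and `b2`), a
#' random-walk-with-drift period index `k1` started at 0, and a
#' stationary AR(1) second index `k2` (entering the probabilities only
#' when `two_terms = TRUE`). The `male_like` preset has a young-adult
#' mortality hump in `a` and negative `b1` exactly on the groups with
#' midpoints in [15, 39]; `female_like` has `b1 > 0` everywhere.
#'
#' @param preset One of `"male_like"`, `"female_like"`, `"flat"`.
#' @param grid An [age_grid()] (default [paper_age_grid()]).
#' @param years Calendar years (default 1973:2005, 33 years).
#' @param seed Integer seed driving all randomness of this truth.
#' @param E_level Exposure per cell (persons, default 1e5); must be
#'   positive.
#' @param drift,sigma Random-walk drift and innovation standard
#'   deviation of `k1`, in logit units per year.
#' @param phi2,sigma2 AR(1) coefficient and innovation standard
#'   deviation of `k2`.
#' @param two_terms Include `b2 * k2` in the true predictor.
#' @param exposure_profile Optional per-age multipliers for an
#'   age-shaped exposure pattern.
#' @return An object of class `mortality_ground_truth`.
#' @export
make_ground_truth <- function(preset = c("female_like", "male_like", "flat"),
                              grid = paper_age_grid(), years = 1973:2005,
                              seed = 20180101, E_level = 1e5,
                              drift = -0.3, sigma = 0.4,
                              phi2 = 0.6, sigma2 = 0.15,
                              two_terms = FALSE,
                              exposure_profile = NULL) {
  preset <- match.arg(preset)
  if (!is_age_grid(grid)) stop("'grid' must be an age_grid")
  years <- as.numeric(years)
  if (length(years) < 2L || any(diff(years) != 1)) {
    stop("'years' must be at least two contiguous calendar years")
  }
  if (!is.numeric(E_level) || E_level <= 0) {
    stop("'E_level' must be positive")
  }
  m <- grid$midpoint
  gt <- structure(
    list(
      preset = preset, grid = grid, years = years,
      sex = switch(preset, male_like = "male", female_like = "female",
                   flat = "flat"),
      a_true = synthetic_a_profile(m, preset),
      b1_true = synthetic_b1_profile(m, preset),
      b2_true = synthetic_b2_profile(m),
      drift = drift, sigma = sigma, phi2 = phi2, sigma2 = sigma2,
      two_terms = two_terms, E_level = E_level,
      exposure_profile = exposure_profile,
      seed = as.integer(seed)
    ),
    class = "mortality_ground_truth"
  )
  paths <- simulate_indices(gt)
  gt$k1_path <- paths$k1_path
  gt$k2_path <- paths$k2_path
  gt
}

#' @export
print.mortality_ground_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic ground truth '%s': %d ages x %d years, E = %g/cell, seed %d\n",
    x$preset, length(x$grid), length(x$years), x$E_level, x$seed
  ))
  cat(sprintf("  k1: random walk, drift %g, sigma %g; k2 (%s): AR(1) phi %g, sigma %g\n",
              x$drift, x$sigma,
              if (x$two_terms) "active" else "inactive",
              x$phi2, x$sigma2))
  invisible(x)
}

#' Simulate the period-index paths of a ground truth
#'
#' `k1` is a random walk with drift started at 0; `k2` is a stationary
#' AR(1) around 0. The paths are a deterministic function of the ground
#' truth's seed: the same truth always yields identical paths.
#'
#' @param gt A [make_ground_truth()] result.
#' @param h Number of steps (default: the truth's year count).
#' @return A list with `k1_path` and `k2_path` of length `h`.
#' @export
simulate_indices <- function(gt, h = length(gt$years)) {
  if (!inherits(gt, "mortality_ground_truth")) {
    stop("'gt' must be a mortality_ground_truth")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(gt$seed)
  k1 <- c(0, cumsum(gt$drift + gt$sigma * stats::rnorm(h - 1L)))
  k2 <- numeric(h)
  sd0 <- if (abs(gt$phi2) < 1) gt$sigma2 / sqrt(1 - gt$phi2^2) else gt$sigma2
  k2[1L] <- sd0 * stats::rnorm(1L)
  for (t in seq_len(h - 1L)) {
    k2[t + 1L] <- gt$phi2 * k2[t] + gt$sigma2 * stats::rnorm(1L)
  }
  list(k1_path = k1, k2_path = k2)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' True death probabilities implied by a ground truth
#'
#' @param gt A [make_ground_truth()] result.
#' @return Matrix of probabilities, ages x years.
#' @export
true_probabilities <- function(gt) {
  eta <- gt$a_true + outer(gt$b1_true, gt$k1_path)
  if (gt$two_terms) eta <- eta + outer(gt$b2_true, gt$k2_path)
  q <- expit(eta)
  bad <- which(!is.finite(q) | q <= 0 | q >= 1, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "implied q outside (0, 1) at age group %d, year %g",
      bad[1L, 1L], gt$years[bad[1L, 2L]]
    ))
  }
  dimnames(q) <- list(as.character(gt$grid$midpoint),
                      as.character(gt$years))
  q
}

#' Simulate abridged life tables from a ground truth
#'
#' Draws `d_obs ~ Binomial(E, q_true)` per cell (seeded by the truth's
#' seed) and assembles one `abridged_life_table` per year with empirical
#' probabilities `q = d_obs / E`.
#'
#' @param gt A [make_ground_truth()] result.
#' @param radix,a_frac Passed to [build_life_table()].
#' @return A list of `abridged_life_table` objects, one per year,
#'   with the ground truth attached as attribute `ground_truth`.
#' @export
simulate_life_tables <- function(gt, radix = 1e5, a_frac = 0.5) {
  if (!inherits(gt, "mortality_ground_truth")) {
    stop("'gt' must be a mortality_ground_truth")
  }
  q_true <- true_probabilities(gt)
  nx <- length(gt$grid)
  nt <- length(gt$years)
  E <- matrix(gt$E_level, nx, nt)
  if (!is.null(gt$exposure_profile)) {
    E <- E * rep_len(gt$exposure_profile, nx)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(gt$seed + 1L)
  d_obs <- matrix(
    stats::rbinom(nx * nt, size = round(as.vector(E)), prob = as.vector(q_true)),
    nx, nt
  )
  tables <- vector("list", nt)
  names(tables) <- as.character(gt$years)
  for (j in seq_len(nt)) {
    tables[[j]] <- build_life_table(
      q = d_obs[, j] / E[, j], grid = gt$grid, radix = radix,
      a_frac = a_frac, year = gt$years[j], sex = gt$sex,
      E = E[, j], d_obs = d_obs[, j]
    )
  }
  attr(tables, "ground_truth") <- gt
  tables
}
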