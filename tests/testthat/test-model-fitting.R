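test_that("model specs encode the predictor structure of each model", {
  expect_error(model_spec("XYZ"), "arg")
  lc <- model_spec("LC")
  expect_true(lc$has_static_age)
  expect_identical(lc$bilinear_terms, 1L)
  expect_identical(lc$cohort_term, "none")
  expect_identical(model_spec("LC2")$bilinear_terms, 2L)
  expect_identical(model_spec("LCC")$cohort_term, "free_slope")
  expect_identical(model_spec("APC")$bilinear_terms, 0L)
  expect_identical(model_spec("RH")$cohort_term, "unit_slope")
  cbd <- model_spec("CBD")
  expect_false(cbd$has_static_age)
  expect_true(cbd$cbd_structure)
  expect_length(cbd$constraints, 0L)
  expect_identical(model_spec("M8")$cohort_term, "cbd_slope")
})

test_that("cohort labels are year minus midpoint age", {
  g <- paper_age_grid()
  cl <- cohort_labels(g, 1973:1997)
  expect_equal(cl$matrix["[0,1)", "1973"], 1972.5)
  expect_equal(cl$matrix["[1,5)", "1990"], 1987)
  # distinct-label count agrees with brute-force enumeration over cells
  brute <- sort(unique(as.vector(
    vapply(1973:1997, function(t) t - g$midpoint, numeric(18))
  )))
  expect_equal(cl$labels, brute)
})

# Independent linearised-design oracle: the Jacobian of the predictor
# with respect to all raw parameters, evaluated at a generic random
# point; its column rank counts the identifiable parameters.
predictor_jacobian_dof <- function(model, nx, nt) {
  g <- age_grid(0:(nx - 1), rep(1, nx))
  x <- g$midpoint
  yrs <- 2000 + 0:(nt - 1)
  cl <- cohort_labels(g, yrs)
  labs <- cl$labels
  nc <- length(labs)
  Ci <- matrix(match(cl$matrix, labs), nx, nt)
  set.seed(99)
  b1 <- rnorm(nx); b2 <- rnorm(nx); k1 <- rnorm(nt); k2 <- rnorm(nt)
  gam <- rnorm(nc); xc <- 7.3
  cols <- list()
  add <- function(m) cols[[length(cols) + 1L]] <<- as.vector(m)
  one <- matrix(1, nx, nt)
  if (model %in% c("LC", "LC2", "LCC", "APC", "RH")) {
    for (i in 1:nx) { m <- matrix(0, nx, nt); m[i, ] <- 1; add(m) }
  }
  if (model %in% c("LC", "LC2", "LCC", "RH")) {
    for (i in 1:nx) { m <- matrix(0, nx, nt); m[i, ] <- k1; add(m) }
    for (t in 1:nt) { m <- matrix(0, nx, nt); m[, t] <- b1; add(m) }
  }
  if (model == "LC2") {
    for (i in 1:nx) { m <- matrix(0, nx, nt); m[i, ] <- k2; add(m) }
    for (t in 1:nt) { m <- matrix(0, nx, nt); m[, t] <- b2; add(m) }
  }
  if (model == "APC") {
    for (t in 1:nt) { m <- matrix(0, nx, nt); m[, t] <- 1; add(m) }
  }
  if (model %in% c("CBD", "M8")) {
    for (t in 1:nt) { m <- matrix(0, nx, nt); m[, t] <- 1; add(m) }
    for (t in 1:nt) { m <- matrix(0, nx, nt); m[, t] <- x - mean(x); add(m) }
  }
  if (model %in% c("LCC", "APC", "RH", "M8")) {
    L <- switch(model, LCC = matrix(b2, nx, nt), APC = one, RH = one,
                M8 = matrix(xc - x, nx, nt))
    for (cc in 1:nc) {
      m <- matrix(0, nx, nt); m[Ci == cc] <- L[Ci == cc]; add(m)
    }
    if (model == "LCC") {
      for (i in 1:nx) { m <- matrix(0, nx, nt); m[i, ] <- gam[Ci[i, ]]; add(m) }
    }
    if (model == "M8") add(matrix(gam[Ci], nx, nt))
  }
  J <- do.call(cbind, cols)
  list(dof = nx * nt - qr(J)$rank, n_cohorts = nc)
}

test_that("degrees of freedom match printed LC value and saturation limit", {
  expect_identical(residual_degrees_of_freedom("LC", 18, 25), 391L)
  expect_identical(residual_degrees_of_freedom("LC", 2, 2), 0L)
})

test_that("degrees of freedom equal the rank of the linearised design", {
  # all small grids for the models whose parameter count stays at or
  # below the cell count there; the largest grids for the cohort models
  # (on tinier grids those models are over-parameterised by arithmetic)
  cases <- list()
  for (nx in 2:5) for (nt in 2:5) {
    cases[[length(cases) + 1L]] <- list("LC", nx, nt)
    cases[[length(cases) + 1L]] <- list("LC2", nx, nt)
    cases[[length(cases) + 1L]] <- list("CBD", nx, nt)
    cases[[length(cases) + 1L]] <- list("APC", nx, nt)
  }
  cases <- c(cases, list(list("LCC", 5, 5), list("RH", 5, 5),
                         list("RH", 5, 4), list("M8", 4, 4),
                         list("M8", 5, 5)))
  n_checked <- 0L
  for (cs in cases) {
    oracle <- predictor_jacobian_dof(cs[[1]], cs[[2]], cs[[3]])
    cf <- residual_degrees_of_freedom(cs[[1]], cs[[2]], cs[[3]],
                                      n_cohorts = oracle$n_cohorts)
    if (cf < 0) next  # over-parameterised grid: rank is capped at n_cells
    n_checked <- n_checked + 1L
    expect_identical(cf, as.integer(oracle$dof),
                     label = sprintf("%s %dx%d", cs[[1]], cs[[2]], cs[[3]]))
  }
  expect_gte(n_checked, 60L)
})

test_that("constraint normalisation follows the closed-form LC transform", {
  p <- apply_identifiability_constraints(
    list(a = c(0, 0), b1 = c(2, 2), k1 = c(1, 3)), spec = "LC"
  )
  expect_equal(p$b1, c(0.5, 0.5))
  expect_equal(p$k1, c(0, 8))
  expect_equal(p$a, c(2, 2))
  # idempotence
  p2 <- apply_identifiability_constraints(p, spec = "LC")
  expect_equal(p2, p)
  expect_error(
    apply_identifiability_constraints(
      list(a = c(0, 0), b1 = c(1, -1), k1 = c(1, 3)), spec = "LC"
    ),
    "degenerate scale"
  )
})

test_that("normalisation never changes the predictor", {
  # random raw parameter sets for every model; eta recomputed by a
  # cellwise brute-force loop before and after
  g <- age_grid(c(0, 1, 5, 10), c(1, 4, 5, 5))
  yrs <- 2001:2005
  cl <- cohort_labels(g, yrs)
  labs <- cl$labels
  eta_brute <- function(par, name) {
    sapply(seq_along(yrs), function(j) {
      sapply(seq_along(g$midpoint), function(i) {
        x <- g$midpoint[i]
        gidx <- match(yrs[j] - x, labs)
        switch(name,
          LC = par$a[i] + par$b1[i] * par$k1[j],
          LC2 = par$a[i] + par$b1[i] * par$k1[j] + par$b2[i] * par$k2[j],
          LCC = par$a[i] + par$b1[i] * par$k1[j] +
            par$b2[i] * par$gamma[gidx],
          APC = par$a[i] + par$k1[j] + par$gamma[gidx],
          RH = par$a[i] + par$b1[i] * par$k1[j] + par$gamma[gidx],
          CBD = par$k1[j] + (x - par$x_bar) * par$k2[j],
          M8 = par$k1[j] + (x - par$x_bar) * par$k2[j] +
            (par$x_c - x) * par$gamma[gidx]
        )
      })
    })
  }
  set.seed(5)
  for (name in model_names()) {
    for (rep in 1:5) {
      par <- list(
        a = rnorm(4), b1 = rnorm(4, 1), b2 = rnorm(4, 1),
        k1 = rnorm(5), k2 = rnorm(5), gamma = rnorm(length(labs)),
        x_bar = mean(g$midpoint), x_c = 20 + runif(1)
      )
      spec <- model_spec(name)
      norm <- apply_identifiability_constraints(par, spec = spec)
      expect_lt(max(abs(eta_brute(par, name) - eta_brute(norm, name))),
                1e-10)
      # declared constraints hold exactly
      if (name %in% c("LC", "LC2", "LCC", "RH")) {
        expect_equal(sum(norm$b1), 1, tolerance = 1e-12)
      }
      if (name %in% c("LC2", "LCC")) {
        expect_equal(sum(norm$b2), 1, tolerance = 1e-12)
      }
      if (name %in% c("LC", "LC2", "LCC", "APC")) {
        expect_equal(norm$k1[1], 0, tolerance = 1e-12)
      }
      if (name == "LC2") expect_equal(norm$k2[1], 0, tolerance = 1e-12)
      if (name %in% c("LCC", "APC")) {
        expect_equal(norm$gamma[1], 0, tolerance = 1e-12)
      }
      if (name == "RH") {
        expect_equal(mean(norm$k1), 0, tolerance = 1e-12)
        expect_equal(mean(norm$gamma), 0, tolerance = 1e-12)
      }
      if (name == "M8") expect_equal(mean(norm$gamma), 0, tolerance = 1e-12)
    }
  }
})

test_that("noiseless LC data is fitted exactly", {
  gt <- make_ground_truth("female_like", seed = 2, years = 1990:2009)
  q <- true_probabilities(gt)
  tabs <- exact_tables(q, gt$grid, gt$years)
  fit <- fit_mortality_model(tabs, "LC")
  expect_true(fit$converged)
  expect_lt(fit$deviance, 1e-6)
  expect_lt(max(abs(predict_q(fit) - q)), 1e-8)
})

test_that("deviance is non-increasing across fitting iterations", {
  for (mn in c("LC", "LC2", "APC", "CBD")) {
    fit <- cached_fit(mn)
    expect_true(all(diff(fit$deviance_trace) <= 1e-8), label = mn)
    expect_gte(fit$deviance, 0)
  }
})

test_that("LC2 attains at most the LC deviance on identical data", {
  f1 <- cached_fit("LC")
  f2 <- cached_fit("LC2")
  expect_lte(f2$deviance, f1$deviance + 1e-6)
})

test_that("LC recovers the generating parameters from binomial data", {
  gt <- attr(cached_tables("female_like", seed = 1), "ground_truth")
  fit <- cached_fit("LC", "female_like", 1)
  expect_true(fit$converged)
  expect_gt(cor(fit$k1, gt$k1_path), 0.999)
  expect_lt(max(abs(fit$a - gt$a_true)), 0.05)
  # loadings recovered up to simulation noise
  expect_gt(cor(fit$b1, gt$b1_true), 0.99)
})

test_that("CBD recovers linear-in-age logit truths", {
  # manufacture a CBD world: logit q linear in age with drifting level
  g <- age_grid(seq(0, 85, by = 5), rep(5, 18))
  yrs <- 1981:2010
  x <- g$midpoint
  k1_true <- -3 - 0.03 * seq_along(yrs)
  k2_true <- 0.07 + 0.0005 * seq_along(yrs)
  eta <- matrix(k1_true, 18, 30, byrow = TRUE) +
    outer(x - mean(x), k2_true)
  q <- expit(eta)
  E <- 1e5
  set.seed(31)
  d <- matrix(rbinom(18 * 30, E, as.vector(q)), 18, 30)
  tabs <- lapply(seq_along(yrs), function(j) {
    build_life_table(d[, j] / E, g, year = yrs[j], sex = "m",
                     E = rep(E, 18), d_obs = d[, j], close_last = FALSE)
  })
  fit <- fit_mortality_model(tabs, "CBD")
  expect_true(fit$converged)
  expect_gt(cor(fit$k1, k1_true), 0.999)
  expect_gt(cor(fit$k2, k2_true), 0.99)
  expect_lt(max(abs(fit$k1 - k1_true)), 0.02)
})

test_that("in-sample predictions equal the cellwise predictor oracle", {
  fit <- cached_fit("LC")
  q <- predict_q(fit)
  for (i in c(1, 7, 18)) {
    for (j in c(1, 15, 33)) {
      expect_equal(q[i, j],
                   expit(unname(fit$a[i] + fit$b1[i] * fit$k1[j])),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(q > 0 & q < 1))
  # monotone in a supplied index when the loading is positive
  i <- which.max(fit$b1)
  yr <- max(fit$years) + 1
  qs <- vapply(c(-1, 0, 1), function(k) {
    predict_q(fit, ages = fit$ages[i], years = yr,
              k1 = stats::setNames(k, yr))[1, 1]
  }, numeric(1))
  expect_true(all(diff(qs) > 0))
})

test_that("out-of-sample years require supplied indices", {
  fit <- cached_fit("LC")
  expect_error(predict_q(fit, years = max(fit$years) + 1),
               "forecast the index")
})

test_that("non-converged fits are flagged and refused downstream", {
  tabs <- cached_tables("female_like", seed = 1)
  fit <- fit_mortality_model(tabs, "LC", max_iter = 1L)
  expect_false(fit$converged)
  expect_error(predict_q(fit), "did not converge")
  expect_error(forecast_probabilities(fit, list()), "did not converge")
})

test_that("fitting validates its inputs", {
  tabs <- cached_tables("female_like", seed = 1)
  expect_error(fit_mortality_model(list(), "LC"), "no life tables")
  expect_error(fit_mortality_model(tabs[c(1, 3)], "LC"), "contiguous")
})
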