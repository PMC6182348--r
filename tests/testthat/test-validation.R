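test_that("hold-out split reproduces the 25/8 partition of 1973-2005", {
  plan <- holdout_split(1973:2005, fraction = 0.75)
  expect_equal(plan$train_years, 1973:1997)
  expect_equal(plan$validation_years, 1998:2005)
  expect_length(plan$train_years, 25L)
  expect_length(plan$validation_years, 8L)
})

test_that("hold-out split is label-based, contiguous and exhaustive", {
  expect_equal(holdout_split(c(2003, 2001, 2004, 2002))$train_years,
               2001:2003)
  for (n in c(4, 7, 13)) {
    yrs <- 1990 + seq_len(n) - 1
    plan <- holdout_split(yrs, 0.6)
    expect_length(intersect(plan$train_years, plan$validation_years), 0L)
    expect_equal(sort(c(plan$train_years, plan$validation_years)), yrs)
    expect_true(max(plan$train_years) < min(plan$validation_years))
  }
  expect_error(holdout_split(2001:2003), "at least 4")
  expect_error(holdout_split(2001:2010, 0.999), "empty validation")
  expect_error(holdout_split(2001:2010, 1.2), "between 0 and 1")
})

test_that("rmse and mape reproduce hand computations", {
  expect_equal(rmse(c(0.1, 0.3), c(0.1, 0.3)), 0)
  expect_equal(rmse(c(0.1, 0.3), c(0.2, 0.2)), 0.1)
  expect_equal(mape(c(0.1, 0.3), c(0.1, 0.3)), 0)
  expect_equal(mape(c(0.1, 0.3), c(0.2, 0.2)), (1 + 1 / 3) / 2 * 100,
               tolerance = 1e-12)
  expect_error(rmse(matrix(0.1, 2, 2), matrix(0.1, 2, 3)), "shape mismatch")
  expect_error(mape(c(0, 0.1), c(0.1, 0.1)), "q = 0")
  expect_equal(mape(c(0, 0.1), c(0.1, 0.2), drop_zero_cells = TRUE), 100)
})

test_that("rmse and mape agree with brute-force loops; mape is scale-free", {
  set.seed(33)
  for (rep in 1:20) {
    nx <- sample(2:10, 1)
    nt <- sample(2:10, 1)
    q <- matrix(runif(nx * nt, 0.01, 0.9), nx, nt)
    qh <- matrix(runif(nx * nt, 0.01, 0.9), nx, nt)
    acc_r <- 0; acc_m <- 0
    for (i in 1:nx) for (j in 1:nt) {
      acc_r <- acc_r + (q[i, j] - qh[i, j])^2
      acc_m <- acc_m + abs(q[i, j] - qh[i, j]) / q[i, j]
    }
    expect_equal(rmse(q, qh), sqrt(acc_r / (nx * nt)), tolerance = 1e-12)
    expect_equal(mape(q, qh), acc_m / (nx * nt) * 100, tolerance = 1e-12)
    cc <- runif(1, 0.1, 1.1)
    expect_equal(mape(cc * q, cc * qh), mape(q, qh), tolerance = 1e-9)
  }
})

test_that("deviance residuals match the binomial formula", {
  # d = d_hat gives r = 0
  expect_equal(deviance_residuals(5, 5 + 1e-12, 10)$r, 0, tolerance = 1e-5)
  # direct evaluation at E = 10, d = 5, d_hat = 2.5
  r <- deviance_residuals(5, 2.5, 10)$r
  expect_equal(r, sqrt(2 * (5 * log(2) + 5 * log(5 / 7.5))),
               tolerance = 1e-12)
  expect_equal(r, 1.6961, tolerance = 1e-4)
  # sign follows d - d_hat
  expect_lt(deviance_residuals(2, 5, 10)$r, 0)
  expect_error(deviance_residuals(11, 5, 10), "\\[0, E\\]")
  expect_error(deviance_residuals(5, 10, 10), "strictly inside")
})

test_that("squared residuals sum to the total binomial deviance", {
  set.seed(37)
  for (rep in 1:10) {
    E <- matrix(sample(50:500, 12), 3, 4)
    q <- matrix(runif(12, 0.05, 0.6), 3, 4)
    d <- matrix(rbinom(12, as.vector(E), as.vector(q)), 3, 4)
    qh <- pmin(pmax(q + rnorm(12, 0, 0.02), 0.01), 0.9)
    dh <- E * qh
    res <- deviance_residuals(d, dh, E)
    # independent oracle: accumulate the deviance cell by cell
    oracle <- 0
    for (i in 1:3) for (j in 1:4) {
      t1 <- if (d[i, j] > 0) d[i, j] * log(d[i, j] / dh[i, j]) else 0
      t2 <- if (E[i, j] - d[i, j] > 0) {
        (E[i, j] - d[i, j]) * log((E[i, j] - d[i, j]) / (E[i, j] - dh[i, j]))
      } else 0
      oracle <- oracle + 2 * (t1 + t2)
    }
    expect_equal(sum(res$r^2), oracle, tolerance = 1e-8)
    expect_equal(attr(res, "deviance_total"), oracle, tolerance = 1e-8)
    expect_equal(sign(res$r), as.vector(sign(d - dh)))
  }
})

test_that("residuals of a well-specified fit are close to standard normal", {
  tabs <- cached_tables("female_like", seed = 1)
  fit <- cached_fit("LC")
  q_hat <- predict_q(fit)
  res <- deviance_residuals(fit$d_obs, fit$E * q_hat, fit$E,
                            ages = fit$ages, years = fit$years)
  frac2 <- mean(abs(res$r) < 2)
  expect_lt(abs(frac2 - 0.954), 0.03)
  frac25 <- mean(abs(res$r) < 2.5)
  expect_gt(frac25, 0.97)
  expect_lt(abs(mean(res$r)), 0.15)
})

test_that("residual reference intervals capture the normal mass", {
  expect_equal(round(residual_capture_percent(2), 1), 95.4)
  expect_equal(round(residual_capture_percent(2.5)), 99)
})

test_that("residual series partition the cells by age, period and cohort", {
  fit <- cached_fit("LC")
  q_hat <- predict_q(fit)
  res <- deviance_residuals(fit$d_obs, fit$E * q_hat, fit$E,
                            ages = fit$ages, years = fit$years)
  n <- nrow(res)
  for (axis in c("age", "period", "cohort")) {
    s <- residual_series(res, axis)
    expect_equal(nrow(s), n)
    expect_equal(sum(table(s$value)), n)
    expect_equal(attr(s, "reference"), c(-2, 2))
  }
  expect_equal(sort(unique(residual_series(res, "cohort")$value)),
               sort(unique(res$year - res$age)))
  expect_error(residual_series(res, "time"), "arg")
})

test_that("model comparison favours the generating model on noiseless data", {
  gt <- make_ground_truth("female_like", seed = 8, years = 1981:2000)
  q <- true_probabilities(gt)
  tabs <- exact_tables(q, gt$grid, gt$years)
  cm <- compare_models(tabs, c("LC", "CBD"))
  lc <- cm[cm$model == "LC", ]
  expect_equal(lc$rmse_train, 0, tolerance = 1e-6)
  other <- cm[cm$model != "LC" & cm$converged, ]
  expect_true(all(lc$rmse_valid <= other$rmse_valid + 1e-9))
})

test_that("comparison reports non-converged models as absent cells", {
  tabs <- cached_tables("female_like", seed = 1)
  cm <- compare_models(tabs, c("LC", "LC2"), max_iter = c(500L)[1])
  expect_true(all(cm$converged))
  # starve the optimiser to force non-convergence of every model
  expect_error(compare_models(tabs, "LC", max_iter = 1L),
               "no candidate model converged")
  cm2 <- suppressMessages(compare_models(tabs, c("LC", "LC2"),
                                         max_iter = 40L))
  if (any(!cm2$converged)) {
    bad <- cm2[!cm2$converged, ]
    expect_true(all(is.na(bad$rmse_train)))
    expect_true(all(is.na(bad$rmse_valid)))
    good <- cm2[cm2$converged, ]
    expect_true(all(is.finite(good$rmse_valid)))
  }
})

test_that("comparison ranks LC at or above LC2 on LC-generated data", {
  tabs <- cached_tables("female_like", seed = 1)
  cm <- compare_models(tabs, c("LC", "LC2"))
  rv <- setNames(cm$rmse_valid, cm$model)
  expect_lte(rv[["LC"]], rv[["LC2"]] + 1e-3)
})
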