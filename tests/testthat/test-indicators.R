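test_that("life expectancy equals T/l at group boundaries", {
  g <- tiny_grid()
  lt <- build_life_table(c(0, 0, 1), g, radix = 1)
  expect_equal(life_expectancy(lt, 0), 7.5)
  lt2 <- build_life_table(c(1, 0, 1), g, radix = 1)
  expect_equal(life_expectancy(lt2, 0), 0.5)
  expect_error(life_expectancy(lt, 2), "nearest boundary is 1")
  expect_error(life_expectancy(lt2, 1), "no survivors")
})

test_that("life expectancy matches the person-years oracle on random tables", {
  g <- paper_age_grid()
  set.seed(51)
  for (rep in 1:10) {
    lt <- build_life_table(runif(18, 0, 0.4), g)
    for (x in c(0, 15, 65)) {
      i <- which(lt$age_lower == x)
      keep <- lt$age_lower >= x
      expect_equal(life_expectancy(lt, x), sum(lt$L[keep]) / lt$l[i],
                   tolerance = 1e-12)
    }
  }
})

test_that("life expectancy falls when any death probability rises", {
  g <- paper_age_grid()
  set.seed(52)
  q <- runif(18, 0.01, 0.3)
  e_base <- life_expectancy(build_life_table(q, g), 0)
  for (i in c(1, 5, 12, 17)) {
    q2 <- q
    q2[i] <- min(q2[i] + 0.1, 1)
    expect_lt(life_expectancy(build_life_table(q2, g), 0), e_base)
  }
})

test_that("modal interval is the argmax of life-table deaths", {
  g <- age_grid(c(0, 5, 10, 15), rep(5, 4))
  mk <- function(d) {
    lt <- build_life_table(rep(0.1, 4), g)
    lt$d <- d
    lt
  }
  expect_equal(modal_age_interval(mk(c(10, 2, 50, 7)), min_age = 0),
               c(lower = 10, upper = 15))
  # ties break toward the youngest interval
  expect_equal(modal_age_interval(mk(c(1, 5, 5, 2)), min_age = 0),
               c(lower = 5, upper = 10))
  # min_age excludes younger groups
  expect_equal(modal_age_interval(mk(c(100, 2, 3, 7)), min_age = 5),
               c(lower = 15, upper = 20))
  expect_error(modal_age_interval(mk(c(1, 1, 1, 1)), min_age = 30),
               "no age group")
})

test_that("an old-age death mass puts the modal interval at [80,85)", {
  g <- paper_age_grid()
  # low mortality until old age, then extinction concentrated at the end
  q <- c(0.02, rep(0.004, 14), 0.05, 0.1, 1)
  lt <- build_life_table(q, g)
  expect_equal(unname(modal_age_interval(lt)), c(80, 85))
})

test_that("Lorenz points match hand computations and normalisation", {
  g <- age_grid(c(0, 50), c(50, 50))
  lt <- build_life_table(c(0.5, 1), g, radix = 2, a_frac = 0.5)
  # deaths (1, 1), mean ages at death (25, 75)
  lp <- lorenz_points(lt, 0)
  expect_equal(lp$N, c(0, 0.5, 1))
  expect_equal(lp$Y, c(0, 0.25, 1))
  expect_equal(lp$N[1], 0)
  expect_equal(lp$Y[nrow(lp)], 1)
  # all deaths in one interval: a single step
  g3 <- tiny_grid()
  lt3 <- build_life_table(c(0, 0, 1), g3, radix = 1)
  lp3 <- lorenz_points(lt3, 0)
  expect_equal(lp3$N[nrow(lp3)], 1)
  expect_equal(lp3$Y[nrow(lp3)], 1)
  expect_true(all(diff(lp3$N) >= 0) && all(diff(lp3$Y) >= 0))
})

test_that("Lorenz curves are non-decreasing and end at (1,1)", {
  g <- paper_age_grid()
  set.seed(53)
  for (rep in 1:10) {
    lt <- build_life_table(runif(18, 0.01, 0.3), g)
    lp <- lorenz_points(lt, 0)
    expect_equal(c(lp$N[1], lp$Y[1]), c(0, 0))
    expect_equal(c(lp$N[nrow(lp)], lp$Y[nrow(lp)]), c(1, 1))
    expect_true(all(diff(lp$N) >= -1e-12))
    expect_true(all(diff(lp$Y) >= -1e-12))
    # mean-age-ordered groups: curve on or below the diagonal
    expect_true(all(lp$Y <= lp$N + 1e-12))
  }
})

test_that("abridged Gini reproduces the two-point closed form", {
  g <- age_grid(c(0, 50), c(50, 50))
  lt <- build_life_table(c(0.5, 1), g, radix = 2, a_frac = 0.5)
  # |1 - (0.5*0.25 + 0.5*1.25)| = 0.25 = classical mean|Xi-Xj|/(2 mean)
  expect_equal(gini_abridged(lt, 0), 0.25, tolerance = 1e-12)
  xs <- c(25, 75)
  classical <- mean(abs(outer(xs, xs, "-"))) / (2 * mean(xs))
  expect_equal(gini_abridged(lt, 0), classical, tolerance = 1e-12)
  # all deaths at one interval: no inequality
  lt1 <- build_life_table(c(0, 0, 1), tiny_grid(), radix = 1)
  expect_equal(gini_abridged(lt1, 0), 0, tolerance = 1e-12)
})

test_that("abridged Gini equals the trapezoid-area oracle", {
  g <- paper_age_grid()
  set.seed(54)
  for (rep in 1:10) {
    lt <- build_life_table(runif(18, 0.01, 0.3), g)
    for (x0 in c(0, 65)) {
      lp <- lorenz_points(lt, x0)
      n <- nrow(lp)
      area <- sum((lp$N[-1] - lp$N[-n]) * (lp$Y[-1] + lp$Y[-n]) / 2)
      expect_equal(gini_abridged(lt, x0), abs(1 - 2 * area),
                   tolerance = 1e-12)
      expect_gte(gini_abridged(lt, x0), 0)
      expect_lte(gini_abridged(lt, x0), 1)
    }
  }
})

test_that("Gini is invariant to scaling deaths and falls with concentration", {
  g <- paper_age_grid()
  q <- c(0.03, rep(0.01, 10), 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 1)
  lt <- build_life_table(q, g)
  for (radix in c(1, 1000, 1e5)) {
    expect_equal(gini_abridged(build_life_table(q, g, radix = radix), 0),
                 gini_abridged(lt, 0), tolerance = 1e-12)
  }
  # nested sequence concentrating a uniform death mass into ever fewer
  # of the oldest groups
  ginis <- vapply(c(16, 8, 4, 2), function(k) {
    lt2 <- build_life_table(rep(0.1, 18), g)
    lt2$d <- c(rep(0, 18 - k), rep(1 / k, k))
    gini_abridged(lt2, 0)
  }, numeric(1))
  expect_true(all(diff(ginis) < 0))
})

test_that("complete-table Gini agrees with the abridged formula on fine grids", {
  # smooth synthetic mortality on a 1-year grid to age 100
  g <- age_grid(0:99, rep(1, 100))
  x <- g$midpoint
  q <- expit(-9 + 0.085 * x + 2.5 * exp(-x / 2))
  lt <- build_life_table(q, g)
  g0_complete <- gini_complete(lt)
  g0_abridged <- gini_abridged(lt, 0)
  expect_lt(abs(g0_complete - g0_abridged), 0.02)
  expect_gt(g0_complete, 0)
  expect_lt(g0_complete, 1)
  # everyone dying within one interior one-year interval: zero inequality
  q_deg <- rep(0, 100)
  q_deg[51] <- 1  # the group [50,51)
  expect_equal(gini_complete(build_life_table(q_deg, g)), 0,
               tolerance = 1e-12)
  # death mass confined to the closing interval leaves the formula 0/0
  expect_error(gini_complete(build_life_table(c(rep(0, 99), 1), g)),
               "no deaths before omega")
  # bound check on random tables
  set.seed(55)
  for (rep in 1:5) {
    ltr <- build_life_table(runif(100, 0.005, 0.2), g)
    expect_gte(gini_complete(ltr), 0)
    expect_lte(gini_complete(ltr), 1)
  }
})

test_that("complete-table Gini requires a closed table", {
  lt <- build_life_table(c(0.1, 0.1, 0.2), tiny_grid(), close_last = FALSE)
  expect_error(gini_complete(lt), "closed at omega")
})

test_that("death and survival curves conserve the radix", {
  g <- paper_age_grid()
  lt <- build_life_table(runif(18, 0.02, 0.3), g, radix = 1e5)
  cv <- death_survival_curves(lt)
  expect_equal(cv$survival$l[1], 1e5)
  expect_true(all(diff(cv$survival$l) <= 0))
  expect_equal(sum(cv$deaths$d), 1e5, tolerance = 1e-6)  # closed table
  # uniformly lower mortality dominates pointwise in survival
  q_hi <- rep(0.25, 18)
  q_lo <- rep(0.10, 18)
  l_hi <- death_survival_curves(build_life_table(q_hi, g))$survival$l
  l_lo <- death_survival_curves(build_life_table(q_lo, g))$survival$l
  expect_true(all(l_lo >= l_hi))
})

test_that("indicator series summarises a table set per year", {
  tabs <- cached_tables("female_like", seed = 1)
  ind <- indicator_series(tabs[c(1, 17, 33)])
  expect_equal(ind$year, c(1973, 1989, 2005))
  expect_true(all(ind$e0 > 0 & ind$e0 < 85))
  expect_true(all(ind$G0 >= 0 & ind$G0 <= 1))
  expect_true(all(ind$e65 < ind$e0))
  expect_true(all(ind$G65 < ind$G0))
  # mortality declines with the drifting index: e0 rises, G0 falls
  expect_gt(ind$e0[3], ind$e0[1])
  expect_lt(ind$G0[3], ind$G0[1])
})
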