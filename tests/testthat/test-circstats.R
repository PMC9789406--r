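oracle_hr <- function(deg) {
  th <- deg * pi / 180
  n <- length(th)
  total <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      d <- th[i] - th[j]
      total <- total + abs(abs(d) - pi) - pi / 2 - 2.895 * (abs(sin(d)) - 2 / pi)
    }
  }
  total / n
}

test_that("the Hermans-Rasson statistic matches a double-loop oracle", {
  set.seed(10)
  for (n in c(5, 17, 40)) {
    x <- runif(n, 0, 360)
    expect_equal(hr_statistic(x), oracle_hr(x), tolerance = 1e-9)
    # rotation invariance is exact
    expect_equal(hr_statistic(x), hr_statistic((x + 123.4) %% 360),
                 tolerance = 1e-9)
  }
})

test_that("the Hermans-Rasson test rejects clustering and antipodal bimodality", {
  expect_lte(hermans_rasson_test(rep(37, 20), n_mc = 999, seed = 1)$p, 0.05)
  expect_lte(hermans_rasson_test(c(rep(0, 20), rep(180, 20)),
                                 n_mc = 999, seed = 1)$p, 0.05)
  # evenly spread grid: near-minimal statistic, clearly not rejected
  expect_gt(hermans_rasson_test(seq(0, 342, by = 18), n_mc = 999, seed = 1)$p,
            0.05)
  expect_error(hermans_rasson_test(c(1, 2, 3)), "n >= 4")
  # deterministic given a seed
  x <- with_seed_test(99, function() runif(20, 0, 360))
  expect_identical(hermans_rasson_test(x, n_mc = 999, seed = 9)$p,
                   hermans_rasson_test(x, n_mc = 999, seed = 9)$p)
})

test_that("Rayleigh's statistic matches the complex-sum oracle", {
  set.seed(11)
  for (i in 1:5) {
    x <- runif(30, 0, 360)
    r <- rayleigh_test(x)
    z <- mean(exp(1i * x * pi / 180))
    expect_equal(r$r_bar, Mod(z), tolerance = 1e-12)
  }
  expect_equal(rayleigh_test(rep(45, 10))$r_bar, 1)
  expect_lt(rayleigh_test(rep(45, 10))$p, 1e-3)
  anti <- rayleigh_test(c(rep(0, 10), rep(180, 10)))
  expect_lt(anti$r_bar, 1e-12)
  expect_equal(anti$p, 1)
  expect_error(rayleigh_test(c(1, 2)), "n >= 3")
})

test_that("circular mean and angular variance follow the vector sum", {
  m <- circular_mean_variance(c(90, 90, 90))
  expect_equal(m$mean_deg, 90)
  expect_equal(m$ang_var, 0)
  m2 <- circular_mean_variance(c(350, 10))
  expect_lt(min(m2$mean_deg, 360 - m2$mean_deg), 1e-6)
  expect_equal(m2$ang_var, 1 - cos(10 * pi / 180), tolerance = 1e-12)
  expect_error(circular_mean_variance(c(0, 180)), "undefined")
})

test_that("the von Mises check accepts von Mises data and rejects bimodality", {
  accept <- vapply(1:40, function(i) {
    x <- with_seed_test(1000 + i, function() rvonmises(100, 90, 3))
    vonmises_check(x, n_boot = 99, seed = 2000 + i)$ok
  }, logical(1))
  expect_gte(mean(accept), 0.9)
  reject <- vapply(1:40, function(i) {
    x <- with_seed_test(3000 + i, function() c(rvonmises(50, 0, 10),
                                               rvonmises(50, 180, 10)))
    !vonmises_check(x, n_boot = 99, seed = 4000 + i)$ok
  }, logical(1))
  expect_gte(mean(reject), 0.9)
  expect_error(vonmises_check(c(1, 2, 3, 4)), "n >= 5")
})

test_that("the classification procedure separates the three regimes", {
  x_uni <- with_seed_test(50, function() runif(100, 0, 360))
  cl <- classify_distribution(x_uni, n_mc = 1999, seed = 51)
  expect_equal(cl$classification, "uniform")
  expect_true(is.na(cl$mean_deg) && is.na(cl$ang_var))

  x_tight <- with_seed_test(52, function() rvonmises(30, 180, 8))
  cl2 <- classify_distribution(x_tight, n_mc = 1999, seed = 53)
  expect_equal(cl2$classification, "nonuniform_unimodal")
  expect_lt(abs(cl2$mean_deg - 180), 15)
  expect_false(is.na(cl2$ang_var))

  x_bi <- with_seed_test(54, function() c(rvonmises(30, 0, 10),
                                          rvonmises(30, 180, 10)))
  cl3 <- classify_distribution(x_bi, n_mc = 1999, seed = 55)
  expect_equal(cl3$classification, "nonuniform_multimodal")
  expect_true(is.na(cl3$mean_deg) && is.na(cl3$ang_var))

  # within-trial screening skips the HR step
  cl4 <- classify_distribution(x_tight, seed = 56, skip_hr = TRUE)
  expect_true(is.na(cl4$hr_p))
  expect_equal(cl4$classification, "nonuniform_unimodal")
})

test_that("uniform samples are classified uniform at roughly the 95% rate", {
  null20 <- with_seed_test(60, function() {
    vapply(1:1999, function(i) hr_statistic(runif(100, 0, 360)), numeric(1))
  })
  res <- vapply(1:60, function(i) {
    x <- with_seed_test(6000 + i, function() runif(100, 0, 360))
    classify_distribution(x, seed = 7000 + i, hr_null = null20)$classification
  }, character(1))
  expect_gte(mean(res == "uniform"), 0.88)
})

test_that("Watson-Williams has correct size, power, and degenerate behavior", {
  # type-I: same von Mises population
  pvals <- vapply(1:200, function(i) {
    g <- with_seed_test(8000 + i, function() {
      list(rvonmises(30, 45, 4), rvonmises(30, 45, 4))
    })
    watson_williams(g)$p
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.12)
  # power: means 0 vs 90 deg at kappa = 4
  power <- vapply(1:100, function(i) {
    g <- with_seed_test(9000 + i, function() {
      list(rvonmises(30, 0, 4), rvonmises(30, 90, 4))
    })
    watson_williams(g)$p < 0.05
  }, logical(1))
  expect_gt(mean(power), 0.95)
  g0 <- with_seed_test(70, function() rvonmises(30, 10, 5))
  w <- watson_williams(list(g0, g0))
  expect_equal(w$F, 0, tolerance = 1e-9)
  expect_error(watson_williams(list(g0)), "2 groups")
  pentagon <- c(0, 72, 144, 216, 288)  # zero resultant: undefined mean
  expect_error(suppressWarnings(watson_williams(list(g0, pentagon))), "undefined")
})

test_that("dispersion comparison detects concentration differences", {
  disp_power <- vapply(1:40, function(i) {
    g <- with_seed_test(10000 + i, function() {
      list(a = rvonmises(40, 0, 1), b = rvonmises(40, 0, 20))
    })
    dispersion_compare(g)$p < 0.05
  }, logical(1))
  expect_gte(mean(disp_power), 0.95)
  # dispersion values are the absolute circular distances to the group mean
  g <- list(a = c(10, 20, 350), b = c(100, 140, 120))
  dc <- dispersion_compare(g)
  ma <- circular_mean_variance(g$a)$mean_deg
  oracle <- abs(((g$a - ma + 180) %% 360) - 180)
  expect_equal(dc$dispersion$disp_deg[dc$dispersion$group == "a"], oracle,
               tolerance = 1e-9)
  expect_equal(nrow(dc$pairwise), 1)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 3), 1.0)
  expect_equal(bonferroni_adjust(c(0.2, 0.04), 1), c(0.2, 0.04))
  expect_error(bonferroni_adjust(1.2, 2), "pvalues")
  expect_error(bonferroni_adjust(0.1, 0), "family_size")
})

test_that("classification is invariant to a common rotation", {
  x <- with_seed_test(80, function() rvonmises(40, 77, 6))
  a <- classify_distribution(x, n_mc = 1999, seed = 81)
  b <- classify_distribution((x + 90) %% 360, n_mc = 1999, seed = 81)
  expect_equal(b$classification, a$classification)
  expect_equal((b$mean_deg - a$mean_deg) %% 360, 90, tolerance = 1e-6)
  expect_equal(b$ang_var, a$ang_var, tolerance = 1e-12)
})
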