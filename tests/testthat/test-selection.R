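# Truncated-normal selection mathematics: thresholds, the variance
# reduction factor, the mean-shift maps, and the selection covariance rule.

test_that("variance reduction factor matches direct quadrature", {
  # independent oracle: Var(X | X > t) by numerical integration
  for (alpha in c(0.02, 0.055, 0.2, 0.5, 0.9)) {
    t <- qnorm(1 - alpha)
    m1 <- integrate(function(x) x * dnorm(x), t, Inf,
                    rel.tol = 1e-12)$value / alpha
    m2 <- integrate(function(x) x^2 * dnorm(x), t, Inf,
                    rel.tol = 1e-12)$value / alpha
    expect_equal(selection_constants(alpha)$xi, 1 - (m2 - m1^2),
                 tolerance = 1e-9)
    expect_equal(selection_constants(alpha)$lambda, m1, tolerance = 1e-9)
  }
  # closed half-normal case and the frozen biobank-rate value
  expect_equal(selection_constants(0.5)$xi, 2 / pi, tolerance = 1e-12)
  expect_equal(selection_constants(0.055)$xi, 0.8583513, tolerance = 1e-6)
})

test_that("no-selection limit and monotonicity of xi", {
  sc1 <- selection_constants(1)
  expect_identical(sc1$xi, 0)
  expect_identical(sc1$t_alpha, -Inf)
  expect_lt(selection_constants(1 - 1e-6)$xi, 1e-4)
  grid <- c(0.001, 0.01, 0.055, 0.2, 0.5, 0.8, 0.99, 1)
  xis <- vapply(grid, function(a) selection_constants(a)$xi, numeric(1))
  expect_true(all(diff(xis) < 0))
  expect_true(all(xis >= 0 & xis < 1))
})

test_that("invalid participation rates are rejected", {
  expect_error(selection_constants(0), "0, 1")
  expect_error(selection_constants(-0.1), "0, 1")
  expect_error(selection_constants(1.5), "0, 1")
})

test_that("mean shift map: trivial and closed-form values", {
  expect_identical(mean_shift_from_rho(0, selection_constants(0.3)), 0)
  # rho = 1, alpha = 0.5: half-normal mean over half-normal SD
  expect_equal(mean_shift_from_rho(1, selection_constants(0.5)),
               sqrt(2 / pi) / sqrt(1 - 2 / pi), tolerance = 1e-12)
  expect_error(mean_shift_from_rho(1.2, selection_constants(0.5)),
               "within")
})

test_that("mean shift matches the Monte Carlo oracle", {
  # bivariate (X, Y), corr 0.5, alpha = 0.055: E[Y|sel]/SD(Y|sel)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  mc <- mc_truncated_mvn(c(0, 0), S, 0.055, n_draws = 1e6, seed = 91)
  d_mc <- mc$mean[2] / sqrt(mc$cov[2, 2])
  se <- mc$mc_se_mean[2] / sqrt(mc$cov[2, 2])   # dominant error term
  d_cf <- mean_shift_from_rho(0.5, selection_constants(0.055))
  expect_equal(d_cf, 1.141107, tolerance = 1e-5)
  expect_lt(abs(d_mc - d_cf), 4 * se)
})

test_that("delta <-> rho inversion is exact on a grid", {
  for (alpha in c(0.01, 0.055, 0.2, 0.5, 0.9)) {
    sc <- selection_constants(alpha)
    rho <- seq(-0.9, 0.9, by = 0.1)
    back <- rho_from_mean_shift(mean_shift_from_rho(rho, sc), sc)
    expect_equal(back, rho, tolerance = 1e-10)
  }
  # degenerate no-selection case
  expect_identical(rho_from_mean_shift(0, selection_constants(1)), 0)
  expect_error(rho_from_mean_shift(0.5, selection_constants(1)),
               "no selection")
})

test_that("selection covariance rule: trivial cases and MC agreement", {
  sc <- selection_constants(0.055)
  expect_equal(selected_cov(0.3, 0, 0.7, sc), 0.3)
  expect_equal(selected_cov(1, 1, 1, sc), 1 - sc$xi)
  # trivariate configuration checked against the MC oracle
  S <- matrix(c(1, 0.125, 0.458,
                0.125, 0.2, 0.132,
                0.458, 0.132, 1), 3)
  got <- selected_cov(0.132, 0.125, 0.458, sc)
  expect_equal(got, 0.132 - sc$xi * 0.125 * 0.458, tolerance = 1e-12)
  mc <- mc_truncated_mvn(rep(0, 3), S, 0.055, n_draws = 1e6, seed = 7)
  expect_lt(abs(mc$cov[2, 3] - got), 4 * mc$mc_se_cov[2, 3])
  # Var(Y | sel) = 1 - xi rho^2
  expect_lt(abs(mc$cov[3, 3] - selected_cov(1, 0.458, 0.458, sc)),
            4 * mc$mc_se_cov[3, 3])
})

test_that("MC oracle agrees with plain rejection sampling", {
  # independent cross-check of the conditional sampler against base R
  set.seed(11)
  x <- rnorm(4e5)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(4e5)
  keep <- x > qnorm(0.5)
  mc <- mc_truncated_mvn(c(0, 0), matrix(c(1, .6, .6, 1), 2), 0.5,
                         n_draws = 4e5, seed = 5)
  se <- sqrt(mc$mc_se_mean[2]^2 * 2)
  expect_lt(abs(mc$mean[2] - mean(y[keep])), 5 * se)
  expect_lt(abs(mc$cov[1, 1] - var(x[keep])),
            5 * sqrt(2) * mc$mc_se_cov[1, 1])
})

test_that("MC oracle is deterministic given the seed", {
  S <- diag(2); S[1, 2] <- S[2, 1] <- 0.4
  a <- mc_truncated_mvn(c(0, 0), S, 0.1, n_draws = 1e4, seed = 42)
  b <- mc_truncated_mvn(c(0, 0), S, 0.1, n_draws = 1e4, seed = 42)
  expect_identical(a$mean, b$mean)
  expect_identical(a$cov, b$cov)
  expect_error(mc_truncated_mvn(c(0, 0), S, 0.1, n_draws = 1e4),
               "mandatory")
})

test_that("alpha = 1 reproduces unconditional moments", {
  S <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  mc <- mc_truncated_mvn(c(0, 0), S, 1, n_draws = 5e5, seed = 3)
  expect_lt(max(abs(mc$mean)), 4 * max(mc$mc_se_mean))
  expect_lt(max(abs(mc$cov - S)), 5 * max(mc$mc_se_cov))
})
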