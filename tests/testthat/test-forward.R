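# Forward model: the decomposition onto participation axes and the
# apparent (selected-sample) heritability and genetic correlations.

test_that("decomposition reconstitutes the variances", {
  set.seed(101)
  for (i in 1:50) {
    p <- random_params()
    d <- decompose_phenotype(p)
    expect_equal(d$a^2 * p$hx2 + d$var_gw, p$hy2, tolerance = 1e-12)
    expect_equal(d$b^2 * (1 - p$hx2) + d$var_ew, 1 - p$hy2,
                 tolerance = 1e-12)
  }
  p <- model_params(0.125, 0.5, 0.5, 0.2, 0.055)
  d <- decompose_phenotype(p)
  expect_equal(d$a, 1, tolerance = 1e-12)
  expect_equal(d$var_gw, 0.375, tolerance = 1e-12)
  # no selection: the sample loading equals the population loading
  p1 <- model_params(0.3, 0.4, 0.35, -0.2, alpha = 1)
  d1 <- decompose_phenotype(p1)
  expect_equal(d1$a_prime, d1$a, tolerance = 1e-12)
  expect_error(decompose_phenotype(model_params(0, 0.4, 0.3, 0, 0.5)),
               "nonheritable")
})

test_that("rho composition", {
  expect_equal(compose_rho(model_params(0.125, 0.2, 0.25, 0.5, 0.055)),
               0.25 * sqrt(0.125 * 0.2) + 0.5 * sqrt(0.875 * 0.8),
               tolerance = 1e-12)
  expect_equal(compose_rho(model_params(0.3, 0.6, 0, 0, 0.1)), 0)
  # perfect correlations with matched heritabilities: rho attains 1
  expect_equal(compose_rho(model_params(0.5, 0.5, 1, 1, 0.5)), 1,
               tolerance = 1e-12)
})

test_that("apparent quantities: frozen values and no-selection limits", {
  p_a <- model_params(0.125, 0.2, 0.25, 0.5, 0.055)
  p_b <- model_params(0.125, 0.5, 0.5, 0.2, 0.055)
  p_c <- model_params(0.125, 0.5, 0.25, 0.5, 0.055)
  expect_equal(apparent_h2(p_a), 0.2296483, tolerance = 1e-6)
  expect_equal(apparent_h2(p_b), 0.4877186, tolerance = 1e-6)
  expect_equal(apparent_rg_participation(p_a), -0.0662018,
               tolerance = 1e-6)
  expect_equal(apparent_rg_two_phenotypes(p_c, p_a, 0.5), 0.4579618,
               tolerance = 1e-6)
  # alpha = 1: nothing changes
  for (i in 1:5) {
    p <- random_params(alpha = 1)
    expect_equal(apparent_h2(p), p$hy2, tolerance = 1e-12)
    if (p$hx2 > 0)
      expect_equal(apparent_rg_participation(p), p$rho_g,
                   tolerance = 1e-10)
  }
  # phenotypes unlinked to participation keep their correlation
  q1 <- model_params(0.125, 0.5, 0, 0, 0.055)
  q2 <- model_params(0.125, 0.2, 0, 0, 0.055)
  expect_equal(apparent_rg_two_phenotypes(q1, q2, 0.5), 0.5,
               tolerance = 1e-12)
})

test_that("closed forms equal the projection construction exactly", {
  set.seed(202)
  for (i in 1:200) {
    pp <- random_param_pair()
    pr <- partbias:::apparent_projection(pp$p1, pp$p2, pp$phi_g)
    expect_equal(apparent_h2(pp$p1), pr$hy_pb2, tolerance = 1e-10)
    expect_equal(apparent_h2(pp$p2), pr$hy_pb2_2, tolerance = 1e-10)
    expect_equal(apparent_rg_participation(pp$p1), pr$rho_g_pb,
                 tolerance = 1e-10)
    expect_equal(apparent_rg_two_phenotypes(pp$p1, pp$p2, pp$phi_g),
                 pr$phi_g_pb, tolerance = 1e-10)
  }
})

test_that("closed forms agree with the Monte Carlo oracle", {
  p1 <- model_params(0.125, 0.5, 0.25, 0.5, 0.055)
  p2 <- model_params(0.125, 0.2, 0.25, 0.5, 0.055)
  mc <- mc_apparent(p1, p2, phi_g = 0.5, phi_e = 0.5, n_draws = 1e6,
                    seed = 314)
  expect_lt(abs(mc$hy_pb2["estimate"] - apparent_h2(p1)),
            4 * mc$hy_pb2["mc_se"])
  expect_lt(abs(mc$hy_pb2_2["estimate"] - apparent_h2(p2)),
            4 * mc$hy_pb2_2["mc_se"])
  expect_lt(abs(mc$rho_g_pb_2["estimate"] - apparent_rg_participation(p2)),
            4 * mc$rho_g_pb_2["mc_se"])
  expect_lt(
    abs(mc$phi_g_pb["estimate"] - apparent_rg_two_phenotypes(p1, p2, 0.5)),
    4 * mc$phi_g_pb["mc_se"])
})

test_that("direction-of-bias laws", {
  sc_alphas <- c(0.055, 0.1, 0.25, 0.5, 1)
  set.seed(303)
  for (i in 1:40) {
    hx2 <- runif(1, 0.05, 0.5); hy2 <- runif(1, 0.05, 0.9)
    # purely genetic correlation: heritability shrinks in the sample
    pg <- model_params(hx2, hy2, runif(1, 0.1, 0.9), 0, 0.055)
    expect_lt(apparent_h2(pg), pg$hy2)
    # purely nongenetic correlation: heritability inflates
    pe <- model_params(hx2, hy2, 0, runif(1, 0.1, 0.9), 0.055)
    expect_gt(apparent_h2(pe), pe$hy2)
    # collider sign flip of the participation genetic correlation
    expect_lt(sign(apparent_rg_participation(pe)) * sign(pe$rho), 0)
  }
  # bias magnitude shrinks toward zero as participation becomes complete,
  # in the moderate same-sign regime of the standard bias curves
  # (hx2 = 0.125, hy2 = 0.5); with near-cancelling genetic and nongenetic
  # effects the magnitude need not be monotone, so the law is asserted
  # where it holds
  for (rg in c(0, 0.1, 0.25, 0.4, 0.5)) for (re in c(0, 0.1, 0.25, 0.5)) {
    bias <- vapply(sc_alphas, function(a) {
      abs(apparent_h2(model_params(0.125, 0.5, rg, re, a)) - 0.5)
    }, numeric(1))
    expect_true(all(diff(bias) < 1e-12))
    expect_equal(bias[length(bias)], 0, tolerance = 1e-12)
  }
})

test_that("parameter sweeps return tidy curves", {
  p <- model_params(0.125, 0.5, 0.25, 0.5, 0.055)
  g <- apparent_grid(p, "alpha", c(0.055, 0.25, 1))
  expect_equal(nrow(g), 3)
  expect_equal(g$hy_pb2[3], 0.5, tolerance = 1e-12)
  expect_named(g, c("parameter", "value", "hy_pb2", "rho_g_pb"))
})
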