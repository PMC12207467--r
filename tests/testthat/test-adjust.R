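# The inverse problem: recovering population-scale parameters from
# participant-sample estimates, and jackknife error propagation.

test_that("covariance conversion and adjustment: frozen chain values", {
  sc <- selection_constants(0.055)
  # forward fixture: hx2 = 0.125, hy2 = 0.2, rho_g = 0.25, rho_e = 0.5
  p <- model_params(0.125, 0.2, 0.25, 0.5, 0.055)
  rg_pb <- apparent_rg_participation(p)      # -0.066202
  h2_pb <- apparent_h2(p)                    # 0.229648
  rG_hat <- raw_genetic_covariance(rg_pb, 0.125, h2_pb, sc)
  # independent algebra: the estimator targets Cov(Gx, Gy' | sel) divided
  # by the selected-sample phenotype SD
  expect_equal(rG_hat,
               (p$rho_G - sc$xi * p$rho * 0.125) / sqrt(1 - sc$xi * p$rho^2),
               tolerance = 1e-10)
  expect_equal(rG_hat, -0.010598, tolerance = 1e-4)
  rG_tilde <- adjusted_genetic_covariance(rG_hat, p$rho, 0.125, sc)
  expect_equal(rG_tilde, p$rho_G, tolerance = 1e-10)   # = 0.0395285
  h2_tilde <- adjusted_h2(h2_pb, p$rho, rG_tilde, 0.125, sc)
  expect_equal(as.numeric(h2_tilde), 0.2, tolerance = 1e-10)
  expect_equal(as.numeric(adjusted_rg_participation(rG_tilde, 0.125,
                                                    h2_tilde)),
               0.25, tolerance = 1e-10)
  expect_equal(as.numeric(adjusted_rho_e(p$rho, 0.25, 0.125, 0.2)), 0.5,
               tolerance = 1e-10)
  # trivial cases
  expect_equal(raw_genetic_covariance(0, 0.3, 0.4, sc), 0)
  expect_equal(raw_genetic_covariance(0.3, 0.2, 0.5, 1),
               0.3 * sqrt(0.2 * 0.5), tolerance = 1e-12)
  expect_equal(adjusted_genetic_covariance(0.12, 0.3, 0.2, 1), 0.12)
  expect_error(raw_genetic_covariance(0.1, 0, 0.5, sc), "hx2")
  expect_error(raw_genetic_covariance(0.1, 0.5, -0.2, sc), "positive")
})

test_that("adjustment chain inverts the forward model exactly", {
  set.seed(404)
  for (i in 1:500) {
    pp <- random_param_pair()
    raw <- forward_raw(pp$p1, pp$p2, pp$phi_g)
    adj <- adjust_estimates(raw, pp$p1$alpha)
    expect_equal(adj$hy2_tilde, pp$p1$hy2, tolerance = 1e-10)
    expect_equal(adj$hy2_tilde_2, pp$p2$hy2, tolerance = 1e-10)
    expect_equal(adj$rho_g_tilde, pp$p1$rho_g, tolerance = 1e-9)
    expect_equal(adj$rho_g_tilde_2, pp$p2$rho_g, tolerance = 1e-9)
    expect_equal(adj$rho_e_tilde, pp$p1$rho_e, tolerance = 1e-9)
    expect_equal(adj$phi_g_tilde, pp$phi_g, tolerance = 1e-9)
  }
})

test_that("no-selection limit: adjustment is the identity", {
  pp <- random_param_pair(alpha = 1)
  raw <- forward_raw(pp$p1, pp$p2, pp$phi_g)
  adj <- adjust_estimates(raw, 1)
  expect_equal(adj$hy2_tilde, raw$hy2_hat, tolerance = 1e-12)
  expect_equal(adj$phi_g_tilde, raw$phi_g_hat, tolerance = 1e-10)
})

test_that("sign preservation and underestimation direction", {
  # moderate-correlation regime: same-signed genetic and nongenetic
  # correlations, participation-like alpha
  set.seed(505)
  kept <- 0
  for (i in 1:200) {
    p <- model_params(0.125, runif(1, 0.05, 0.6), runif(1, 0.05, 0.5),
                      runif(1, 0.05, 0.5), 0.055)
    raw <- forward_raw(p)
    adj <- adjust_estimates(raw, 0.055)
    d <- raw$delta_hat
    if (sign(raw$rho_g_hat) == sign(d) && abs(raw$rho_g_hat) > 1e-3) {
      kept <- kept + 1
      expect_identical(sign(adj$rho_g_tilde), sign(raw$rho_g_hat))
      expect_gte(abs(adj$rho_g_tilde) + 1e-12, abs(raw$rho_g_hat))
    }
  }
  expect_gt(kept, 20)  # the regime is actually exercised
})

test_that("jackknife machinery: linear statistic and hand-computed case", {
  # pseudovalue jackknife of a mean equals the textbook SE of the mean
  set.seed(606)
  x <- rnorm(40)
  loo <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  jk <- jackknife_pseudovalues(mean(x), loo)
  expect_equal(jk$estimate, mean(x), tolerance = 1e-12)
  expect_equal(jk$se, sd(x) / sqrt(length(x)), tolerance = 1e-12)
  # hand-computed 4-block jackknife
  v <- c(1, 3, 2, 6)
  jk4 <- jackknife_pseudovalues(3, c(11 / 3, 3, 10 / 3, 2))
  # pseudovalues: 4*3 - 3*loo = (1, 3, 2, 6)
  expect_equal(jk4$pseudovalues, v, tolerance = 1e-12)
  expect_equal(jk4$estimate, 3, tolerance = 1e-12)
  expect_equal(jk4$se, sqrt(var(v) / 4), tolerance = 1e-12)
})

test_that("jackknife through the adjustment chain", {
  p <- model_params(0.125, 0.3, 0.3, 0.4, 0.055)
  raw0 <- forward_raw(p)
  B <- 10
  # identical blocks: zero SE, estimate equals the full chain
  rawc <- raw_estimates(raw0$hy2_hat, raw0$rho_g_hat, raw0$hx2_hat,
                        raw0$delta_hat,
                        blocks = list(hy2_hat = rep(raw0$hy2_hat, B),
                                      rho_g_hat = rep(raw0$rho_g_hat, B)))
  adj <- adjust_estimates(rawc, 0.055)
  expect_equal(adj$se$hy2_tilde, 0, tolerance = 1e-12)
  expect_equal(adj$jackknife_estimate$hy2_tilde, adj$hy2_tilde,
               tolerance = 1e-12)
  # varying blocks: jackknife of the (nonlinear) chain matches a direct
  # computation from pseudovalues
  set.seed(707)
  hyb <- raw0$hy2_hat + rnorm(B, 0, 0.01)
  rawv <- raw_estimates(raw0$hy2_hat, raw0$rho_g_hat, raw0$hx2_hat,
                        raw0$delta_hat, blocks = list(hy2_hat = hyb))
  jk <- jackknife_adjust(rawv, 0.055)
  sc <- selection_constants(0.055)
  direct <- vapply(hyb, function(h) {
    as.numeric(partbias:::adjust_chain_one(h, raw0$rho_g_hat,
                                           raw0$hx2_hat, raw0$delta_hat,
                                           sc)$hy2_tilde)
  }, numeric(1))
  pj <- jackknife_pseudovalues(adj$hy2_tilde, direct)
  expect_equal(jk$se$hy2_tilde, pj$se, tolerance = 1e-12)
  expect_error(jackknife_adjust(raw0, 0.055), "no jackknife")
})

test_that("out-of-domain raw estimates are flagged, not clamped", {
  sc <- selection_constants(0.055)
  ch <- partbias:::adjust_chain_one(-0.05, 0.1, 0.125, 0.3, sc)
  expect_true(is.nan(as.numeric(ch$hy2_tilde)))
  expect_identical(attr(ch$hy2_tilde, "flag"), "raw_h2_out_of_domain")
  # an adjusted value outside [0, 1] is returned raw with a flag
  out <- adjusted_h2(1.4, 0.1, 0.02, 0.125, sc)
  expect_gt(as.numeric(out), 1)
  expect_identical(attr(out, "flag"), "h2_out_of_range")
})

test_that("hx2 sensitivity multiplier shifts the adjustment", {
  p <- model_params(0.125, 0.3, 0.3, 0.4, 0.055)
  raw <- forward_raw(p)
  a1 <- adjust_estimates(raw, 0.055)
  a2 <- adjust_estimates(raw, 0.055, hx2_scale = 0.75)
  expect_equal(a1$hy2_tilde, p$hy2, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(a1$hy2_tilde, a2$hy2_tilde)))
  # the multiplier is exactly equivalent to supplying a scaled hx2
  raw75 <- raw
  raw75$hx2_hat <- raw$hx2_hat * 0.75
  a3 <- adjust_estimates(raw75, 0.055)
  expect_equal(a2$hy2_tilde, a3$hy2_tilde, tolerance = 1e-12)
  expect_equal(a2$rho_g_tilde, a3$rho_g_tilde, tolerance = 1e-12)
})
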