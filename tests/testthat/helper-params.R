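# shared helpers: random valid parameter draws and a forward -> raw
# constructor used by the inversion tests

random_params <- function(alpha = NULL) {
  repeat {
    hx2 <- runif(1, 0.02, 0.6)
    hy2 <- runif(1, 0.02, 0.95)
    rho_g <- runif(1, -0.9, 0.9)
    rho_e <- runif(1, -0.9, 0.9)
    a <- if (is.null(alpha)) runif(1, 0.02, 0.9) else alpha
    p <- tryCatch(model_params(hx2, hy2, rho_g, rho_e, a),
                  error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

# a pair of phenotypes sharing alpha/hx2 plus a feasible phi_g
random_param_pair <- function(alpha = NULL) {
  repeat {
    p1 <- random_params(alpha)
    p2 <- tryCatch(
      model_params(p1$hx2, runif(1, 0.02, 0.95), runif(1, -0.9, 0.9),
                   runif(1, -0.9, 0.9), p1$alpha),
      error = function(e) NULL)
    if (is.null(p2)) next
    # effect-size correlation matrix must be PSD for phi_g to be feasible
    lo <- p1$rho_g * p2$rho_g -
      sqrt((1 - p1$rho_g^2) * (1 - p2$rho_g^2))
    hi <- p1$rho_g * p2$rho_g +
      sqrt((1 - p1$rho_g^2) * (1 - p2$rho_g^2))
    phi_g <- runif(1, lo + 0.02 * (hi - lo), hi - 0.02 * (hi - lo))
    return(list(p1 = p1, p2 = p2, phi_g = phi_g))
  }
}

# exact forward quantities packed as raw estimates (the noiseless fixture
# for inversion tests)
forward_raw <- function(p1, p2 = NULL, phi_g = NULL, hx2 = p1$hx2) {
  sc <- selection_constants(p1$alpha)
  if (is.null(p2)) {
    raw_estimates(
      hy2_hat = apparent_h2(p1),
      rho_g_hat = apparent_rg_participation(p1),
      hx2_hat = hx2,
      delta_hat = mean_shift_from_rho(p1$rho, sc))
  } else {
    raw_estimates(
      hy2_hat = apparent_h2(p1),
      rho_g_hat = apparent_rg_participation(p1),
      hx2_hat = hx2,
      delta_hat = mean_shift_from_rho(p1$rho, sc),
      hy2_hat_2 = apparent_h2(p2),
      rho_g_hat_2 = apparent_rg_participation(p2),
      delta_hat_2 = mean_shift_from_rho(p2$rho, sc),
      phi_g_hat = apparent_rg_two_phenotypes(p1, p2, phi_g))
  }
}
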