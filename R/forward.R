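#' Population-scale parameters of one phenotype-participation system
#'
#' Bundles the parameters of the liability model
#' `X = Gx + ex`, `Y = Gy + ey` (both standardized in the population):
#' heritabilities `hx2 = Var(Gx)`, `hy2 = Var(Gy)`, genetic correlation
#' `rho_g = Corr(Gx, Gy)`, nongenetic correlation `rho_e = Corr(ex, ey)`,
#' and the participation rate `alpha`. The implied phenotypic correlation
#' `rho = rho_g * sqrt(hx2 * hy2) + rho_e * sqrt((1 - hx2) * (1 - hy2))`
#' must itself be a valid correlation.
#'
#' @param hx2 Heritability of the participation liability, in `[0, 1]`.
#' @param hy2 Heritability of the phenotype, in `[0, 1]`.
#' @param rho_g,rho_e Genetic and nongenetic correlations, in `[-1, 1]`.
#' @param alpha Participation rate, in `(0, 1]`.
#'
#' @return Object of class `"model_params"`, a list with the inputs plus
#'   the covariances `rho_G`, `rho_E` and phenotypic correlation `rho`.
#' @export
model_params <- function(hx2, hy2, rho_g, rho_e, alpha = 0.055) {
  for (nm in c("hx2", "hy2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1)
      stop("`", nm, "` must be a single value in [0, 1].")
  }
  for (nm in c("rho_g", "rho_e")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || abs(v) > 1)
      stop("`", nm, "` must be a single value in [-1, 1].")
  }
  rho_G <- rho_g * sqrt(hx2 * hy2)
  rho_E <- rho_e * sqrt((1 - hx2) * (1 - hy2))
  rho <- rho_G + rho_E
  if (abs(rho) > 1)
    stop("implied phenotypic correlation rho = ", signif(rho, 4),
         " lies outside [-1, 1]: invalid parameter combination.")
  structure(list(hx2 = hx2, hy2 = hy2, rho_g = rho_g, rho_e = rho_e,
                 alpha = alpha, rho_G = rho_G, rho_E = rho_E, rho = rho),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: hx2 = %g, hy2 = %g, rho_g = %g, rho_e = %g, alpha = %g\n",
    x$hx2, x$hy2, x$rho_g, x$rho_e, x$alpha))
  cat(sprintf("  implied rho = %g (rho_G = %g, rho_E = %g)\n",
              x$rho, x$rho_G, x$rho_E))
  invisible(x)
}

#' Phenotypic correlation implied by model parameters
#'
#' `rho = rho_g * sqrt(hx2 * hy2) + rho_e * sqrt((1 - hx2) * (1 - hy2))`,
#' the sum of the genetic covariance `rho_G` and nongenetic covariance
#' `rho_E` of `X` and `Y`.
#'
#' @param params A [model_params()] object.
#' @return The phenotypic correlation `rho`.
#' @export
compose_rho <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$rho
}

#' Decomposition of a phenotype onto the participation axes
#'
#' Writes `Gy = a * Gx + Gw` and `ey = b * ex + ew` with `Gw, ew`
#' orthogonal to `Gx, ex`, so that selection (which only acts through
#' `X = Gx + ex`) leaves `Gw` and `ew` untouched:
#' `a = rho_g * sqrt(hy2 / hx2)`, `Var(Gw) = (1 - rho_g^2) * hy2`,
#' `b = rho_e * sqrt((1 - hy2) / (1 - hx2))`,
#' `Var(ew) = (1 - rho_e^2) * (1 - hy2)`.
#'
#' After selection the regression loading of `Gx` in the sample genetic
#' component shrinks to
#' `a' = (rho_G - xi * rho * hx2) / (hx2 * (1 - xi * hx2))`,
#' the collider-bias attenuation verified against the Monte Carlo oracle.
#'
#' @param params A [model_params()] object.
#' @return List with `a`, `b`, `var_gw`, `var_ew`, `a_prime`.
#' @export
decompose_phenotype <- function(params) {
  stopifnot(inherits(params, "model_params"))
  p <- params
  if (p$hx2 == 0 && p$rho_g != 0)
    stop("genetic correlation with a nonheritable liability (hx2 = 0, ",
         "rho_g != 0) is undefined.")
  if (p$hx2 == 1 && p$rho_e != 0)
    stop("nongenetic correlation with a fully heritable liability (hx2 = 1, ",
         "rho_e != 0) is undefined.")
  a <- if (p$hx2 > 0) p$rho_g * sqrt(p$hy2 / p$hx2) else 0
  b <- if (p$hx2 < 1) p$rho_e * sqrt((1 - p$hy2) / (1 - p$hx2)) else 0
  xi <- selection_constants(p$alpha)$xi
  a_prime <- if (p$hx2 > 0)
    (p$rho_G - xi * p$rho * p$hx2) / (p$hx2 * (1 - xi * p$hx2)) else 0
  list(a = a, b = b,
       var_gw = (1 - p$rho_g^2) * p$hy2,
       var_ew = (1 - p$rho_e^2) * (1 - p$hy2),
       a_prime = a_prime)
}

#' Apparent (participant-sample) heritability
#'
#' The heritability an unadjusted estimator targets in the selected sample,
#' i.e. the squared correlation between `Y` and its genetic component among
#' participants:
#' \deqn{h^2_{y,PB} = \frac{h^2_y - \xi\rho_G(\rho_G + 2\rho_E)
#'   + \xi^2 h^2_x \rho_E^2 / (1 - \xi h^2_x)}{1 - \xi\rho^2}.}
#' The denominator is the phenotype variance after selection; the numerator
#' is the variance accounted for by the genetic axes `(Gx, Gw)` after
#' selection. The expression is exactly reproduced by the projection
#' construction built on [selected_cov()] (see tests), which resolves any
#' reading ambiguity in the grouping of terms.
#'
#' @param params A [model_params()] object.
#' @return The apparent heritability (a squared correlation, in `[0, 1]`).
#' @export
apparent_h2 <- function(params) {
  stopifnot(inherits(params, "model_params"))
  p <- params
  xi <- selection_constants(p$alpha)$xi
  num <- p$hy2 - xi * p$rho_G * (p$rho_G + 2 * p$rho_E) +
    xi^2 * p$hx2 * p$rho_E^2 / (1 - xi * p$hx2)
  num / (1 - xi * p$rho^2)
}

#' Apparent genetic correlation between participation and a phenotype
#'
#' What a genetic-correlation estimator computed from a population-scale
#' participation GWAS and a participant-sample phenotype GWAS targets:
#' \deqn{\rho_{g,PB} = \frac{\rho_G - \xi h^2_x \rho}
#'   {\sqrt{(1-\xi\rho^2)(1-\xi h^2_x)}\sqrt{h^2_x h^2_{y,PB}}}.}
#' When `rho_g = 0` but `rho != 0`, collider bias makes this quantity take
#' the sign opposite to `rho`.
#'
#' @param params A [model_params()] object.
#' @return The apparent genetic correlation with participation.
#' @export
apparent_rg_participation <- function(params) {
  stopifnot(inherits(params, "model_params"))
  p <- params
  if (p$hx2 <= 0) stop("`hx2` must be positive.")
  xi <- selection_constants(p$alpha)$xi
  h2pb <- apparent_h2(p)
  if (h2pb <= 0)
    stop("apparent heritability is zero: degenerate phenotype after selection.")
  (p$rho_G - xi * p$hx2 * p$rho) /
    (sqrt((1 - xi * p$rho^2) * (1 - xi * p$hx2)) * sqrt(p$hx2 * h2pb))
}

#' Apparent genetic correlation between two phenotypes
#'
#' Both phenotypes follow the liability model with a common participation
#' liability (same `hx2`, same `alpha`); `phi_g` is their population genetic
#' correlation, with genetic covariance `phi_G = phi_g * sqrt(hy1^2 hy2^2)`.
#' In the selected sample the estimator targets
#' \deqn{\varphi_{g,PB} = \frac{\varphi_G
#'   - \xi(\rho_{E1}\rho_{G2} + \rho_{E2}\rho_{G1} + \rho_{G1}\rho_{G2})
#'   + \xi^2 h^2_x \rho_{E1}\rho_{E2} / (1 - \xi h^2_x)}
#'   {\sqrt{(1-\xi\rho_1^2)(1-\xi\rho_2^2)}\sqrt{h^2_{y1,PB} h^2_{y2,PB}}}.}
#' The nongenetic correlation between the two phenotypes does not enter.
#'
#' @param params_y1,params_y2 [model_params()] objects for the two
#'   phenotypes; must share `alpha` and `hx2`.
#' @param phi_g Population genetic correlation between the two phenotypes.
#' @return The apparent cross-phenotype genetic correlation.
#' @export
apparent_rg_two_phenotypes <- function(params_y1, params_y2, phi_g) {
  stopifnot(inherits(params_y1, "model_params"),
            inherits(params_y2, "model_params"))
  p1 <- params_y1; p2 <- params_y2
  if (p1$alpha != p2$alpha || p1$hx2 != p2$hx2)
    stop("the two phenotypes must share `alpha` and `hx2`.")
  if (abs(phi_g) > 1) stop("`phi_g` must be in [-1, 1].")
  xi <- selection_constants(p1$alpha)$xi
  phi_G <- phi_g * sqrt(p1$hy2 * p2$hy2)
  h1pb <- apparent_h2(p1); h2pb <- apparent_h2(p2)
  if (h1pb <= 0 || h2pb <= 0)
    stop("apparent heritability is zero: degenerate phenotype after selection.")
  num <- phi_G - xi * (p1$rho_E * p2$rho_G + p2$rho_E * p1$rho_G +
                         p1$rho_G * p2$rho_G) +
    xi^2 * p1$hx2 * p1$rho_E * p2$rho_E / (1 - xi * p1$hx2)
  num / (sqrt((1 - xi * p1$rho^2) * (1 - xi * p2$rho^2)) * sqrt(h1pb * h2pb))
}

# ---------------------------------------------------------------------------
# Independent construction of the apparent quantities from the selection
# operator alone (no use of the closed forms above). Regresses Y on the
# genetic axes (Gx, Gw) under the selected distribution, all of whose
# second moments follow from selected_cov(). Used as the dual route in
# tests; any grouping mistake in the closed forms would break the match.
apparent_projection <- function(params_y1, params_y2 = NULL, phi_g = NULL) {
  sc <- selection_constants(params_y1$alpha)
  one <- function(p) {
    vGx <- selected_cov(p$hx2, p$hx2, p$hx2, sc)
    vGw <- (1 - p$rho_g^2) * p$hy2            # Cov(Gw, X) = 0: unchanged
    cYGx <- selected_cov(p$rho_G, p$rho, p$hx2, sc)
    cYGw <- vGw                               # loading of Gw in Y is 1
    vY <- selected_cov(1, p$rho, p$rho, sc)
    bGx <- if (vGx > 0) cYGx / vGx else 0
    bGw <- if (vGw > 0) cYGw / vGw else 0
    var_gen <- bGx^2 * vGx + bGw^2 * vGw      # Gx, Gw stay orthogonal
    list(h2_pb = var_gen / vY,
         cov_gx = bGx * vGx,                  # Cov(Gx, Gy' | sel)
         b = c(bGx, bGw), vGx = vGx, vGw = vGw, var_gen = var_gen)
  }
  r1 <- one(params_y1)
  out <- list(
    hy_pb2 = r1$h2_pb,
    rho_g_pb = r1$cov_gx / sqrt(r1$vGx * r1$var_gen))
  if (!is.null(params_y2)) {
    p1 <- params_y1; p2 <- params_y2
    r2 <- one(p2)
    a1 <- decompose_phenotype(p1)$a; a2 <- decompose_phenotype(p2)$a
    phi_G <- phi_g * sqrt(p1$hy2 * p2$hy2)
    cGw12 <- phi_G - a1 * a2 * p1$hx2         # Cov(Gw1, Gw2), unselected
    cov12 <- r1$b[1] * r2$b[1] * r1$vGx +
      r1$b[1] * r2$b[2] * 0 + r1$b[2] * r2$b[1] * 0 +
      r1$b[2] * r2$b[2] * cGw12
    out$hy_pb2_2 <- r2$h2_pb
    out$rho_g_pb_2 <- r2$cov_gx / sqrt(r2$vGx * r2$var_gen)
    out$phi_g_pb <- cov12 / sqrt(r1$var_gen * r2$var_gen)
  }
  out
}

#' Monte Carlo estimate of the apparent quantities
#'
#' Draws the latent variables `(X, Gx, Gw1, Y1[, Gw2, Y2])` conditional on
#' participation with [mc_truncated_mvn()] and computes the apparent
#' heritabilities, participation genetic correlations, and (for a pair) the
#' cross-phenotype genetic correlation *empirically*, by regressing each
#' phenotype on the genetic axes in the selected draws. Entirely
#' independent of the closed-form expressions, hence usable as their
#' oracle; each statistic carries a batch-based Monte Carlo SE.
#'
#' @inheritParams apparent_rg_two_phenotypes
#' @param phi_e Nongenetic correlation between the two phenotypes (needed
#'   only to complete the joint distribution; it does not affect the
#'   genetic quantities).
#' @param n_draws,seed,n_batches Passed to [mc_truncated_mvn()].
#' @return List with elements `hy_pb2`, `rho_g_pb` (and for pairs
#'   `hy_pb2_2`, `rho_g_pb_2`, `phi_g_pb`), each a vector
#'   `c(estimate, mc_se)`.
#' @export
mc_apparent <- function(params_y1, params_y2 = NULL, phi_g = NULL,
                        phi_e = 0, n_draws = 1e6, seed, n_batches = 100) {
  p1 <- params_y1
  two <- !is.null(params_y2)
  # covariance of (X, Gx, Gw1, Y1[, Gw2, Y2]) in the population
  build <- function(p) {
    vGw <- (1 - p$rho_g^2) * p$hy2
    list(vGw = vGw, a = decompose_phenotype(p)$a)
  }
  b1 <- build(p1)
  if (!two) {
    v <- c("X", "Gx", "Gw1", "Y1")
    S <- diag(c(1, p1$hx2, b1$vGw, 1))
    S["X", "Gx"] <- S["Gx", "X"] <- p1$hx2
    dimnames(S) <- list(v, v)
    S["X", "Y1"] <- S["Y1", "X"] <- p1$rho
    S["Gx", "Y1"] <- S["Y1", "Gx"] <- p1$rho_G
    S["Gw1", "Y1"] <- S["Y1", "Gw1"] <- b1$vGw
  } else {
    p2 <- params_y2
    b2 <- build(p2)
    phi_G <- phi_g * sqrt(p1$hy2 * p2$hy2)
    phi_E <- phi_e * sqrt((1 - p1$hy2) * (1 - p2$hy2))
    cGw12 <- phi_G - b1$a * b2$a * p1$hx2
    v <- c("X", "Gx", "Gw1", "Y1", "Gw2", "Y2")
    S <- diag(c(1, p1$hx2, b1$vGw, 1, b2$vGw, 1))
    dimnames(S) <- list(v, v)
    S["X", "Gx"] <- S["Gx", "X"] <- p1$hx2
    S["X", "Y1"] <- S["Y1", "X"] <- p1$rho
    S["X", "Y2"] <- S["Y2", "X"] <- p2$rho
    S["Gx", "Y1"] <- S["Y1", "Gx"] <- p1$rho_G
    S["Gx", "Y2"] <- S["Y2", "Gx"] <- p2$rho_G
    S["Gw1", "Y1"] <- S["Y1", "Gw1"] <- b1$vGw
    S["Gw2", "Y2"] <- S["Y2", "Gw2"] <- b2$vGw
    S["Gw1", "Gw2"] <- S["Gw2", "Gw1"] <- cGw12
    S["Gw1", "Y2"] <- S["Y2", "Gw1"] <- cGw12
    S["Gw2", "Y1"] <- S["Y1", "Gw2"] <- cGw12
    S["Y1", "Y2"] <- S["Y2", "Y1"] <- phi_G + phi_E
  }
  mc <- mc_truncated_mvn(rep(0, nrow(S)), S, p1$alpha, n_draws = n_draws,
                         seed = seed, n_batches = n_batches)
  stats_from_cov <- function(V) {
    gen <- function(iy, ig) {
      Vg <- V[ig, ig, drop = FALSE]
      cg <- V[ig, iy]
      b <- solve(Vg, cg)
      varg <- drop(crossprod(b, Vg %*% b))
      list(h2 = varg / V[iy, iy],
           covgx = drop(Vg[1, ] %*% b), varg = varg, b = b, Vg = Vg)
    }
    if (!two) {
      g1 <- gen(4, 2:3)
      c(hy_pb2 = g1$h2,
        rho_g_pb = g1$covgx / sqrt(V[2, 2] * g1$varg))
    } else {
      g1 <- gen(4, c(2, 3))
      g2 <- gen(6, c(2, 5))
      # Cov(Gy1', Gy2' | sel) from the two projections
      V12 <- V[c(2, 3), c(2, 5), drop = FALSE]
      cov12 <- drop(crossprod(g1$b, V12 %*% g2$b))
      c(hy_pb2 = g1$h2,
        rho_g_pb = g1$covgx / sqrt(V[2, 2] * g1$varg),
        hy_pb2_2 = g2$h2,
        rho_g_pb_2 = g2$covgx / sqrt(V[2, 2] * g2$varg),
        phi_g_pb = cov12 / sqrt(g1$varg * g2$varg))
    }
  }
  point <- stats_from_cov(mc$cov)
  B <- mc$n_batches
  bstats <- t(vapply(seq_len(B),
                     function(b) stats_from_cov(mc$batch$cov[b, , ]),
                     numeric(length(point))))
  se <- apply(bstats, 2, sd) / sqrt(B)
  out <- lapply(seq_along(point),
                function(i) c(estimate = unname(point[i]), mc_se = unname(se[i])))
  names(out) <- names(point)
  out
}

#' Sweep a parameter and tabulate the apparent quantities
#'
#' Produces tidy curves of apparent heritability and genetic correlations
#' across a grid of one parameter (typically `alpha`), holding the others
#' fixed — the standard way to visualise how the bias grows as the
#' participation rate falls.
#'
#' @inheritParams apparent_rg_two_phenotypes
#' @param vary Name of the parameter to sweep: one of `"alpha"`, `"hx2"`,
#'   `"hy2"`, `"rho_g"`, `"rho_e"`.
#' @param values Grid of values for the swept parameter.
#' @return A data.frame with columns `parameter`, `value`, `hy_pb2`,
#'   `rho_g_pb` and (when a second phenotype is supplied) `phi_g_pb`.
#' @export
apparent_grid <- function(params_y1, vary = "alpha", values,
                          params_y2 = NULL, phi_g = NULL) {
  stopifnot(vary %in% c("alpha", "hx2", "hy2", "rho_g", "rho_e"))
  rows <- lapply(values, function(v) {
    a1 <- modifyList(params_y1[c("hx2", "hy2", "rho_g", "rho_e", "alpha")],
                     stats::setNames(list(v), vary))
    q1 <- do.call(model_params, a1)
    row <- data.frame(parameter = vary, value = v,
                      hy_pb2 = apparent_h2(q1),
                      rho_g_pb = apparent_rg_participation(q1))
    if (!is.null(params_y2)) {
      a2 <- modifyList(params_y2[c("hx2", "hy2", "rho_g", "rho_e", "alpha")],
                       stats::setNames(list(v), if (vary == "hy2") "hy2" else vary))
      q2 <- do.call(model_params, a2)
      row$phi_g_pb <- apparent_rg_two_phenotypes(q1, q2, phi_g)
    }
    row
  })
  do.call(rbind, rows)
}
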