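#' Selection constants for a liability-threshold participation model
#'
#' Participation is modelled as a latent standard-normal liability `X`; an
#' invited individual participates iff `X > t_alpha`, with
#' `t_alpha = qnorm(1 - alpha)` and `alpha` the participation rate. All
#' distortions induced by this selection are governed by the variance
#' reduction factor `xi = 1 - Var(X | X > t_alpha)`, computed here through
#' the inverse Mills ratio `lambda = dnorm(t_alpha) / alpha` as
#' `xi = lambda * (lambda - t_alpha)`.
#'
#' `alpha = 1` (everyone participates) is handled as an explicit
#' no-selection case with `t_alpha = -Inf` and `xi = 0`, so every downstream
#' formula degrades gracefully to its unselected limit.
#'
#' @param alpha Participation rate, in `(0, 1]`.
#'
#' @return An object of class `"selection_constants"`: a list with elements
#'   `alpha`, `t_alpha`, `xi` and `lambda` (the upper-tail inverse Mills
#'   ratio, i.e. `E[X | X > t_alpha]`).
#'
#' @examples
#' sc <- selection_constants(0.055)
#' sc$xi            # ~0.858: participation at UK Biobank's invited rate
#' selection_constants(0.5)$xi  # 2/pi, the half-normal case
#' @export
selection_constants <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha))
    stop("`alpha` must be a single finite number.")
  if (alpha <= 0 || alpha > 1)
    stop("`alpha` must be in (0, 1], got ", alpha, ".")
  if (alpha == 1) {
    out <- list(alpha = 1, t_alpha = -Inf, xi = 0, lambda = 0)
  } else {
    t_alpha <- qnorm(alpha, lower.tail = FALSE)
    # log-scale ratio avoids cancellation for very small alpha
    lambda <- exp(dnorm(t_alpha, log = TRUE) - log(alpha))
    out <- list(alpha = alpha, t_alpha = t_alpha,
                xi = lambda * (lambda - t_alpha), lambda = lambda)
  }
  structure(out, class = "selection_constants")
}

#' @export
print.selection_constants <- function(x, ...) {
  cat("Liability-threshold selection constants\n")
  cat(sprintf("  participation rate alpha = %g\n", x$alpha))
  cat(sprintf("  threshold t_alpha        = %g\n", x$t_alpha))
  cat(sprintf("  variance reduction xi    = %g\n", x$xi))
  invisible(x)
}

as_selection_constants <- function(x) {
  if (inherits(x, "selection_constants")) x else selection_constants(x)
}

#' Mean shift of a phenotype induced by selection on participation
#'
#' For a phenotype `Y` with phenotypic correlation `rho` with the
#' participation liability, selection `X > t_alpha` shifts the mean of `Y`.
#' The shift reported here is standardized by the *selected-sample* standard
#' deviation (the convention under which observed sample-vs-population mean
#' differences are computed in practice):
#' `delta = rho * lambda / sqrt(1 - xi * rho^2)`.
#'
#' @param rho Phenotypic correlation(s) between the phenotype and the
#'   participation liability; must lie in `[-1, 1]`.
#' @param constants A [selection_constants()] object, or a participation
#'   rate `alpha` to be converted.
#'
#' @return Mean shift(s) `delta`, same length as `rho`.
#' @seealso [rho_from_mean_shift()] for the exact inverse.
#' @export
mean_shift_from_rho <- function(rho, constants) {
  sc <- as_selection_constants(constants)
  if (any(!is.finite(rho)) || any(abs(rho) > 1))
    stop("`rho` must be finite and within [-1, 1].")
  rho * sc$lambda / sqrt(1 - sc$xi * rho^2)
}

#' Phenotypic correlation recovered from an observed mean shift
#'
#' Exact inverse of [mean_shift_from_rho()]:
#' `rho = alpha * delta / sqrt(xi * alpha^2 * delta^2 + dnorm(t_alpha)^2)`.
#' Finite shifts always map into `(-1, 1)`; `|rho| = 1` is reached only in
#' the infinite-shift limit.
#'
#' @param delta Observed standardized mean shift(s) (selected sample minus
#'   population, in selected-sample SD units).
#' @inheritParams mean_shift_from_rho
#'
#' @return Phenotypic correlation(s) `rho`.
#' @export
rho_from_mean_shift <- function(delta, constants) {
  sc <- as_selection_constants(constants)
  if (any(!is.finite(delta))) stop("`delta` must be finite.")
  if (sc$alpha == 1) {
    if (any(delta != 0))
      stop("with alpha = 1 there is no selection: a nonzero mean shift ",
           "is inconsistent with the model.")
    return(rep(0, length(delta)))
  }
  phi_t <- dnorm(sc$t_alpha)
  sc$alpha * delta / sqrt(sc$xi * sc$alpha^2 * delta^2 + phi_t^2)
}

#' Covariance after selection on an upper tail of a Gaussian variable
#'
#' For jointly Gaussian `(U, V, X)` with `Var(X) = 1`, conditioning on
#' `X > t_alpha` changes covariances by the Pearson-Lawley selection rule
#' `Cov(U, V | X > t_alpha) = Cov(U, V) - xi * Cov(U, X) * Cov(V, X)`.
#' This single operator reconstructs every "apparent" quantity in the
#' package from first principles and is used as an independent route to
#' cross-check the closed forms.
#'
#' @param cov_uv,cov_ux,cov_vx Unselected covariances (vectorized).
#' @inheritParams mean_shift_from_rho
#'
#' @return Selected-sample covariance(s).
#' @export
selected_cov <- function(cov_uv, cov_ux, cov_vx, constants) {
  sc <- as_selection_constants(constants)
  cov_uv - sc$xi * cov_ux * cov_vx
}

#' Monte Carlo moments of a truncated multivariate normal
#'
#' Samples a multivariate normal conditional on its first coordinate `X`
#' (required to have zero mean and unit variance) exceeding the
#' `(1 - alpha)` quantile. `X` is drawn exactly from its truncated marginal
#' by inverse CDF and the remaining coordinates from their Gaussian
#' conditional, so acceptance never degenerates at small `alpha` (no
#' rejection sampling is involved). Every moment carries a Monte Carlo
#' standard error computed from batch means.
#'
#' This is the package's verification oracle: closed-form selected-sample
#' quantities are tested against it rather than derived from it.
#'
#' @param mean Mean vector; `mean[1]` must be 0 (standard-normal liability).
#' @param cov Covariance matrix; `cov[1, 1]` must be 1.
#' @param alpha Participation rate in `(0, 1]`.
#' @param n_draws Number of Monte Carlo draws (default `1e6`).
#' @param seed Integer seed (mandatory: results are reproducible given the
#'   seed and independent of R's global RNG state).
#' @param n_batches Number of batches for Monte Carlo standard errors.
#'
#' @return An object of class `"mc_oracle"`: list with `mean`, `cov`
#'   (selected-sample moment estimates), `mc_se_mean`, `mc_se_cov`
#'   (batch-based standard errors), `n_draws`, `n_batches`, `seed`, `alpha`,
#'   and `batch` (per-batch means and covariances, for derived statistics).
#' @export
mc_truncated_mvn <- function(mean, cov, alpha, n_draws = 1e6, seed,
                             n_batches = 100) {
  if (missing(seed)) stop("`seed` is mandatory for the Monte Carlo oracle.")
  d <- length(mean)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == d)) stop("`mean` and `cov` dimensions disagree.")
  if (abs(cov[1, 1] - 1) > 1e-12 || abs(mean[1]) > 1e-12)
    stop("the first coordinate must be the standard-normal liability ",
         "(mean 0, variance 1).")
  if (alpha <= 0 || alpha > 1) stop("`alpha` must be in (0, 1].")
  if (n_batches < 2 || n_draws < n_batches)
    stop("need n_draws >= n_batches >= 2.")

  if (d == 1) {
    coef <- numeric(0)
    L <- matrix(0, 0, 0)
  } else {
    coef <- cov[-1, 1]
    cc <- cov[-1, -1, drop = FALSE] - tcrossprod(coef)
    L <- psd_factor(cc)
  }
  t_alpha <- if (alpha == 1) -Inf else qnorm(alpha, lower.tail = FALSE)
  res <- cpp_mc_truncated(alpha, coef, L, as.integer(n_draws),
                          as.integer(n_batches), as.double(seed))
  per <- res$per_batch
  bmean <- res$batch_sum / per
  # shift conditional coordinates by their unconditional means
  if (d > 1) bmean[, -1] <- sweep(bmean[, -1, drop = FALSE], 2, mean[-1], "+")
  bcov <- array(0, c(n_batches, d, d))
  for (a in seq_len(d)) for (b in a:d) {
    cr <- res$batch_cross[, (a - 1) * d + b] / per
    # cross sums were accumulated on centred coordinates for a,b > 1
    mu_a <- if (a == 1) 0 else mean[a]
    mu_b <- if (b == 1) 0 else mean[b]
    raw_a <- bmean[, a] - mu_a
    raw_b <- bmean[, b] - mu_b
    cv <- cr - raw_a * raw_b
    bcov[, a, b] <- cv
    bcov[, b, a] <- cv
  }
  est_mean <- colMeans(bmean)
  est_cov <- apply(bcov, c(2, 3), mean)
  structure(list(
    mean = est_mean,
    cov = est_cov,
    mc_se_mean = apply(bmean, 2, sd) / sqrt(n_batches),
    mc_se_cov = apply(bcov, c(2, 3), sd) / sqrt(n_batches),
    n_draws = per * n_batches, n_batches = n_batches,
    seed = seed, alpha = alpha,
    batch = list(mean = bmean, cov = bcov)
  ), class = "mc_oracle")
}

# factor S = L %*% t(L) for a symmetric PSD matrix, tolerating zero
# eigenvalues (perfect correlations are legitimate corners of the model)
psd_factor <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("matrix is not positive semi-definite.")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values))
}
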