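#' Contiguous block jackknife of a mean
#'
#' Splits per-SNP values into `n_blocks` contiguous blocks in the supplied
#' order (blocking is meaningful when the order is genomic, so that
#' deleted blocks are approximately independent), and jackknifes the mean.
#' Any remainder after equal division is spread over the first blocks.
#'
#' @param values Numeric vector of per-SNP values.
#' @param n_blocks Number of blocks, between 2 and `length(values)`.
#' @return List with `estimate` (the mean), `se` (jackknife SE),
#'   `block_series` (leave-one-out estimates, length `n_blocks`), and
#'   `block_id` (the assignment used).
#' @export
block_jackknife <- function(values, n_blocks = 200) {
  m <- length(values)
  if (n_blocks < 2 || n_blocks > m)
    stop("`n_blocks` must be between 2 and the number of values.")
  id <- block_ids(m, n_blocks)
  tot <- sum(values)
  bsum <- rowsum(values, id)[, 1]
  bn <- tabulate(id, n_blocks)
  loo <- (tot - bsum) / (m - bn)
  jk <- jackknife_pseudovalues(tot / m, loo)
  list(estimate = tot / m, se = jk$se, block_series = loo, block_id = id)
}

# contiguous blocks, remainder spread over the first blocks
block_ids <- function(m, n_blocks) {
  base <- m %/% n_blocks
  extra <- m %% n_blocks
  rep(seq_len(n_blocks), times = base + (seq_len(n_blocks) <= extra))
}

# weighted least squares with a leave-one-block-out series, via per-block
# sufficient statistics (k is 1 or 2, so everything stays closed form)
wls_blocks <- function(X, y, w, block_id, n_blocks) {
  Xw <- X * w
  A_full <- crossprod(Xw, X)
  c_full <- crossprod(Xw, y)
  k <- ncol(X)
  A_blk <- array(0, c(n_blocks, k, k))
  c_blk <- matrix(0, n_blocks, k)
  for (a in seq_len(k)) {
    c_blk[, a] <- rowsum(Xw[, a] * y, block_id)[, 1]
    for (b in a:k) {
      s <- rowsum(Xw[, a] * X[, b], block_id)[, 1]
      A_blk[, a, b] <- s
      A_blk[, b, a] <- s
    }
  }
  coef <- tryCatch(unname(drop(solve(A_full, c_full))),
                   error = function(e)
                     stop("singular regression design (constant LD scores ",
                          "with a free intercept?)", call. = FALSE))
  loo <- matrix(NA_real_, n_blocks, k)
  for (bb in seq_len(n_blocks)) {
    loo[bb, ] <- solve(A_full - A_blk[bb, , ], c_full - c_blk[bb, ])
  }
  list(coef = coef, loo = loo)
}

# one weighted fit of E[y] = intercept + slope * x (intercept optionally
# fixed); returns coefficients, leave-one-block-out series, fitted means
wls_fit <- function(x, y, w, fix_intercept, block_id, n_blocks) {
  if (is.null(fix_intercept)) {
    fit <- wls_blocks(cbind(1, x), y, w, block_id, n_blocks)
    out <- list(slope = fit$coef[2], intercept = fit$coef[1],
                slope_loo = fit$loo[, 2], intercept_loo = fit$loo[, 1])
  } else {
    fit <- wls_blocks(cbind(x), y - fix_intercept, w, block_id, n_blocks)
    out <- list(slope = fit$coef[1], intercept = fix_intercept,
                slope_loo = fit$loo[, 1],
                intercept_loo = rep(fix_intercept, n_blocks))
  }
  out$fitted <- out$intercept + out$slope * x
  out
}

# LDSC weighting, two passes. Pass 1 uses the heteroscedasticity /
# over-counting factor 1 / max(l, 1) alone; pass 2 divides further by the
# squared fitted mean (for a chi-square, Var = 2 * mean^2) or, for a
# cross-trait product, by (fitted1 * fitted2 + fitted_cross^2). Keeping the
# same functional form in both places makes the genetic correlation of a
# trait with itself exactly 1. Two passes, never more: deterministic.
ldsc_weights_uni <- function(l2, fitted = NULL) {
  base <- 1 / pmax(l2, 1)
  if (is.null(fitted)) base
  else base / pmax(fitted, 0.1)^2
}
ldsc_weights_cross <- function(l2, f1 = NULL, f2 = NULL, fc = NULL) {
  base <- 1 / pmax(l2, 1)
  if (is.null(f1)) base
  else base / (pmax(f1, 0.1) * pmax(f2, 0.1) + fc^2)
}

check_sumstats <- function(ss, name = "sumstats") {
  need <- c("snp", "a1", "a2", "n", "z")
  names(ss) <- tolower(names(ss))
  if (!all(need %in% names(ss)))
    stop("`", name, "` must have columns SNP, A1, A2, N, Z.")
  if (anyDuplicated(ss$snp)) {
    dup <- ss$snp[duplicated(ss$snp)][1]
    stop("duplicate SNP id in `", name, "`: ", dup)
  }
  if (any(!is.finite(ss$z))) stop("`", name, "` has non-finite Z values.")
  if (any(ss$n <= 0)) stop("`", name, "` has nonpositive N.")
  ss
}

# inner join on "snp" preserving the order of `ss`
merge_keep_order <- function(ss, ldscores) {
  idx <- match(ss$snp, ldscores$snp)
  keep <- !is.na(idx)
  out <- ss[keep, , drop = FALSE]
  out$l2 <- ldscores$l2[idx[keep]]
  out
}

#' SNP heritability by LD score regression
#'
#' Fits `E[chi2_j] = intercept + (N_j * h2 / M) * l_j` by weighted least
#' squares over SNPs, where `chi2_j = z_j^2` and `l_j` is the LD score.
#' Weights combine a `1 / max(l_j, 1)` heteroscedasticity and
#' over-counting factor with, in a second pass, the inverse squared fitted
#' mean (the chi-square variance factor); the two-pass scheme is fixed for
#' determinism. With `intercept_free = FALSE` the intercept is fixed at 1
#' (no confounding); the free intercept absorbs confounding and
#' relatedness inflation. Standard errors come from a contiguous block
#' jackknife in the supplied SNP order.
#'
#' @param sumstats Data frame with columns `SNP, A1, A2, N, Z`
#'   (case-insensitive), e.g. from [read_sumstats()].
#' @param ldscores Data frame with columns `SNP, L2`, e.g. from
#'   [read_ldscores()].
#' @param m_total Number of SNPs `M` the heritability refers to; defaults
#'   to the number of merged SNPs.
#' @param intercept_free Estimate the intercept (default) or fix it at 1.
#' @param n_blocks Number of jackknife blocks (default 200).
#' @return Object of class `"ldsc_fit"`: list with `h2`, `intercept`,
#'   `se` (jackknife), `blocks` (leave-one-out h2 series), `n_snp`,
#'   `m_total`, and `flags` (e.g. a nonpositive slope).
#' @export
ldsc_h2 <- function(sumstats, ldscores, m_total = NULL,
                    intercept_free = TRUE, n_blocks = 200) {
  ss <- check_sumstats(sumstats)
  names(ldscores) <- tolower(names(ldscores))
  if (!all(c("snp", "l2") %in% names(ldscores)))
    stop("`ldscores` must have columns SNP and L2.")
  mg <- merge_keep_order(ss, ldscores)
  m <- nrow(mg)
  if (m < 3) stop("fewer than 3 SNPs after merging with LD scores.")
  if (is.null(m_total)) m_total <- m
  chi2 <- mg$z^2
  x <- mg$n * mg$l2 / m_total
  block_id <- block_ids(m, n_blocks)
  fix <- if (intercept_free) NULL else 1
  p1 <- wls_fit(x, chi2, ldsc_weights_uni(mg$l2), fix, block_id, n_blocks)
  p2 <- wls_fit(x, chi2, ldsc_weights_uni(mg$l2, p1$fitted), fix,
                block_id, n_blocks)
  flags <- character(0)
  if (p2$slope <= 0) flags <- "nonpositive_h2"
  jk <- jackknife_pseudovalues(p2$slope, p2$slope_loo)
  structure(list(h2 = p2$slope, intercept = p2$intercept, se = jk$se,
                 blocks = p2$slope_loo, intercept_blocks = p2$intercept_loo,
                 n_snp = m, m_total = m_total,
                 intercept_free = intercept_free, n_blocks = n_blocks,
                 flags = flags),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("LDSC h2: %.4f (SE %.4f), intercept %s%.4f, %d SNPs\n",
              x$h2, x$se, if (x$intercept_free) "" else "[fixed] ",
              x$intercept, x$n_snp))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Genetic covariance and correlation by bivariate LD score regression
#'
#' Fits `E[z1_j z2_j] = intercept + (sqrt(N1_j N2_j) * gcov / M) * l_j`.
#' With `intercept_zero = TRUE` the intercept is fixed at 0 — the
#' convention for the participation-phenotype correlation, where overlap
#' between the GWAS samples has been removed and fixing the intercept
#' reduces the standard error. The genetic correlation is
#' `rg = gcov / sqrt(h2_1 * h2_2)`, with the two heritabilities fitted on
#' the same merged SNP set, the same blocks and the same weighting scheme,
#' so the jackknife series of `rg` is internally consistent and the
#' genetic correlation of a trait with itself is exactly 1.
#'
#' Alleles are aligned before the fit: SNPs whose `(A1, A2)` pair is
#' swapped between the two tables have `z2` negated; SNPs whose alleles
#' cannot be reconciled are dropped (an error is raised if more than 10%
#' drop out).
#'
#' @param sumstats_1,sumstats_2 Summary-statistics tables (see
#'   [ldsc_h2()]).
#' @param ldscores,m_total,n_blocks As in [ldsc_h2()].
#' @param intercept_zero Fix the cross-trait intercept at 0?
#' @param h2_intercept_free Intercept convention for the two univariate
#'   fits (default free).
#' @return Object of class `"ldsc_rg_fit"`: list with `rg`, `gcov`,
#'   `h2_1`, `h2_2`, `intercept`, `se` (jackknife SE of `rg`), `se_gcov`,
#'   `blocks` (list of leave-one-out series for `rg`, `gcov`, `h2_1`,
#'   `h2_2`), and `n_dropped`.
#' @export
ldsc_rg <- function(sumstats_1, sumstats_2, ldscores, m_total = NULL,
                    intercept_zero = FALSE, h2_intercept_free = TRUE,
                    n_blocks = 200) {
  s1 <- check_sumstats(sumstats_1, "sumstats_1")
  s2 <- check_sumstats(sumstats_2, "sumstats_2")
  names(ldscores) <- tolower(names(ldscores))
  if (!all(c("snp", "l2") %in% names(ldscores)))
    stop("`ldscores` must have columns SNP and L2.")

  idx2 <- match(s1$snp, s2$snp)
  keep <- !is.na(idx2)
  s1 <- s1[keep, , drop = FALSE]; s2 <- s2[idx2[keep], , drop = FALSE]
  a1_1 <- toupper(s1$a1); a2_1 <- toupper(s1$a2)
  a1_2 <- toupper(s2$a1); a2_2 <- toupper(s2$a2)
  same <- a1_1 == a1_2 & a2_1 == a2_2
  flip <- a1_1 == a2_2 & a2_1 == a1_2
  drop <- !(same | flip)
  n_dropped <- sum(drop) + sum(!keep)
  if (n_dropped > 0.10 * length(keep))
    stop("more than 10% of SNPs dropped during allele alignment (",
         n_dropped, " of ", length(keep), ").")
  s1 <- s1[!drop, , drop = FALSE]; s2 <- s2[!drop, , drop = FALSE]
  z2_al <- ifelse(flip[!drop], -s2$z, s2$z)

  mg <- merge_keep_order(s1, ldscores)
  sel <- match(mg$snp, s1$snp)
  z2_al <- z2_al[sel]
  n2 <- s2$n[sel]
  m <- nrow(mg)
  if (m < 3) stop("fewer than 3 SNPs after merging with LD scores.")
  if (is.null(m_total)) m_total <- m

  block_id <- block_ids(m, n_blocks)
  fixu <- if (h2_intercept_free) NULL else 1
  fixc <- if (intercept_zero) 0 else NULL
  x1 <- mg$n * mg$l2 / m_total
  x2 <- n2 * mg$l2 / m_total
  xc <- sqrt(mg$n * n2) * mg$l2 / m_total
  w0 <- ldsc_weights_uni(mg$l2)
  u1 <- wls_fit(x1, mg$z^2, w0, fixu, block_id, n_blocks)
  u2 <- wls_fit(x2, z2_al^2, w0, fixu, block_id, n_blocks)
  c0 <- wls_fit(xc, mg$z * z2_al, ldsc_weights_cross(mg$l2), fixc,
                block_id, n_blocks)
  f1 <- wls_fit(x1, mg$z^2, ldsc_weights_uni(mg$l2, u1$fitted), fixu,
                block_id, n_blocks)
  f2 <- wls_fit(x2, z2_al^2, ldsc_weights_uni(mg$l2, u2$fitted), fixu,
                block_id, n_blocks)
  fc <- wls_fit(xc, mg$z * z2_al,
                ldsc_weights_cross(mg$l2, u1$fitted, u2$fitted, c0$fitted),
                fixc, block_id, n_blocks)

  gcov <- fc$slope
  denom <- function(h1, h2) sqrt(pmax(h1, 1e-12) * pmax(h2, 1e-12))
  rg <- gcov / denom(f1$slope, f2$slope)
  rg_loo <- fc$slope_loo / denom(f1$slope_loo, f2$slope_loo)
  jk_rg <- jackknife_pseudovalues(rg, rg_loo)
  jk_g <- jackknife_pseudovalues(gcov, fc$slope_loo)
  structure(list(rg = rg, gcov = gcov, h2_1 = f1$slope, h2_2 = f2$slope,
                 intercept = fc$intercept, se = jk_rg$se,
                 se_gcov = jk_g$se,
                 blocks = list(rg = rg_loo, gcov = fc$slope_loo,
                               h2_1 = f1$slope_loo, h2_2 = f2$slope_loo),
                 n_snp = m, m_total = m_total, n_dropped = n_dropped,
                 n_blocks = n_blocks),
            class = "ldsc_rg_fit")
}

#' @export
print.ldsc_rg_fit <- function(x, ...) {
  cat(sprintf("LDSC rg: %.4f (SE %.4f), gcov %.5g, h2 = %.4f / %.4f\n",
              x$rg, x$se, x$gcov, x$h2_1, x$h2_2))
  if (x$n_dropped) cat("  SNPs dropped in allele alignment:", x$n_dropped, "\n")
  invisible(x)
}
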