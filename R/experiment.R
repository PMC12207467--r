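#' Run the full simulate-estimate-adjust validation loop
#'
#' For each replicate: draw LD blocks and effect sizes; stream a cohort of
#' `n_individuals` through the genotype kernel (no genotype matrix is ever
#' materialized), selecting participants by liability threshold; compute
#' per-SNP GWAS z-statistics for each phenotype among participants and the
#' oracle participation GWAS on the full cohort; estimate heritabilities
#' and genetic correlations by LD score regression with exact
#' (population) LD scores; compute each phenotype's mean shift between
#' participants and the full cohort; and run the adjustment chain with
#' block-jackknife standard errors.
#'
#' LDSC conventions follow the participation-bias analysis design: free
#' intercepts for heritabilities and for the phenotype-phenotype genetic
#' correlation; intercept fixed at zero for participation-phenotype
#' genetic correlations.
#'
#' @param config A [sim_config()] object (unrelated-individuals form).
#' @param n_replicates Number of replicates (default 20).
#' @param seed Master seed; every source of randomness in the loop
#'   descends from it.
#' @param n_blocks Jackknife blocks for LDSC (default 200).
#' @param keep_fits Keep the per-replicate LDSC fit objects? (memory)
#' @param verbose Print one line per replicate.
#' @return A data.frame with one row per replicate: participant counts,
#'   raw LDSC estimates (`hy2_hat*`, `rho_g_hat*`, `phi_g_hat`,
#'   `hx2_hat`), mean shifts (`delta_*`), adjusted estimates
#'   (`hy2_tilde*`, `rho_g_tilde*`, `rho_e_tilde*`, `phi_g_tilde`) and
#'   their jackknife SEs (`se_*`). The closed-form apparent values implied
#'   by the configuration are attached as attribute `"expected"`, and the
#'   configuration as `"config"`.
#' @export
run_experiment <- function(config, n_replicates = 20, seed = 1,
                           n_blocks = 200, keep_fits = FALSE,
                           verbose = interactive()) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$n_individuals))
    stop("run_experiment uses the unrelated-individuals configuration; ",
         "sib-pair cohorts are materialized via sample_cohort().")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  rows <- vector("list", n_replicates)
  fits <- if (keep_fits) vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- one_replicate(config, rep_seeds[r], n_blocks)
    rows[[r]] <- res$row
    if (keep_fits) fits[[r]] <- res$fits
    if (verbose)
      message(sprintf("replicate %d/%d: %d participants, hy2_hat = %.4f",
                      r, n_replicates, res$row$n_part, res$row$hy2_hat))
  }
  out <- do.call(rbind, rows)
  out$replicate <- seq_len(n_replicates)
  attr(out, "expected") <- expected_apparent(config)
  attr(out, "config") <- config
  if (keep_fits) attr(out, "fits") <- fits
  out
}

# closed-form apparent values implied by the configuration
expected_apparent <- function(config) {
  ps <- config$params
  out <- list(hy_pb2 = vapply(ps, apparent_h2, numeric(1)),
              rho_g_pb = vapply(ps, apparent_rg_participation, numeric(1)))
  if (config$n_phenotypes == 2)
    out$phi_g_pb <- apparent_rg_two_phenotypes(ps[[1]], ps[[2]],
                                               config$phi_g)
  out
}

one_replicate <- function(config, rep_seed, n_blocks) {
  set.seed(rep_seed)
  m <- config$m_snps
  kp <- config$n_phenotypes
  K <- 1 + kp
  blocks <- make_ld_blocks(m, config$block_size)
  effects <- sample_effects(m, config$causal_fraction, config$hx2,
                            config$hy2, config$rho_g, config$phi_g)
  bt <- block_transitions(blocks)
  ld2 <- ld_scores_from_r(blocks, bt$r_used)
  t_alpha <- qnorm(config$alpha, lower.tail = FALSE)

  n <- config$n_individuals
  eps <- matrix(rnorm(n * K), n, K) %*% t(residual_factor(config))
  sd_g <- sqrt(2 * blocks$freq * (1 - blocks$freq))
  bstd <- t(effects$beta[effects$causal, , drop = FALSE] /
              sd_g[effects$causal])              # K x nc
  offs <- as.numeric(bstd %*% (2 * blocks$freq[effects$causal]))
  st <- cpp_cohort_stats(bt$trans, as.integer(effects$causal - 1L), bstd,
                         offs, eps, t_alpha, new_subseed())

  n0 <- st$n; np <- st$n_part
  # oracle participation GWAS on the full cohort, from sufficient stats
  sg_full <- st$cnt1 + 2 * st$cnt2
  sg2_full <- st$cnt1 + 4 * st$cnt2
  z_x <- z_from_sums(st$sum_gx, sg_full, sg2_full, st$full_sum[1],
                     st$full_sum2[1], n0)
  ss_x <- data.frame(snp = blocks$snp, a1 = "A", a2 = "B", n = n0, z = z_x,
                     stringsAsFactors = FALSE)
  ss_y <- lapply(seq_len(kp), function(k) {
    zk <- z_from_sums(st$part_gy[, k + 1], st$part_g, st$part_g2,
                      st$part_sum[k + 1], st$part_sum2[k + 1], np)
    data.frame(snp = blocks$snp, a1 = "A", a2 = "B", n = np, z = zk,
               stringsAsFactors = FALSE)
  })

  # mean shift: participants vs full cohort, participant-SD standardized
  delta <- vapply(seq_len(kp), function(k) {
    mp <- st$part_sum[k + 1] / np
    vf <- st$full_sum[k + 1] / n0
    sdp <- sqrt((st$part_sum2[k + 1] - np * mp^2) / (np - 1))
    (mp - vf) / sdp
  }, numeric(1))

  fit_hx2 <- ldsc_h2(ss_x, ld2, m_total = m, intercept_free = TRUE,
                     n_blocks = n_blocks)
  fit_hy <- lapply(ss_y, ldsc_h2, ldscores = ld2, m_total = m,
                   intercept_free = TRUE, n_blocks = n_blocks)
  fit_rgx <- lapply(ss_y, function(s)
    ldsc_rg(ss_x, s, ld2, m_total = m, intercept_zero = TRUE,
            n_blocks = n_blocks))
  fit_phi <- if (kp == 2)
    ldsc_rg(ss_y[[1]], ss_y[[2]], ld2, m_total = m, intercept_zero = FALSE,
            n_blocks = n_blocks)

  blocks_list <- list(hy2_hat = fit_hy[[1]]$blocks,
                      rho_g_hat = fit_rgx[[1]]$blocks$rg,
                      hx2_hat = fit_hx2$blocks)
  if (kp == 2) {
    blocks_list$hy2_hat_2 <- fit_hy[[2]]$blocks
    blocks_list$rho_g_hat_2 <- fit_rgx[[2]]$blocks$rg
    blocks_list$phi_g_hat <- fit_phi$blocks$rg
  }
  raw <- raw_estimates(
    hy2_hat = fit_hy[[1]]$h2, rho_g_hat = fit_rgx[[1]]$rg,
    hx2_hat = fit_hx2$h2, delta_hat = delta[1],
    hy2_hat_2 = if (kp == 2) fit_hy[[2]]$h2,
    rho_g_hat_2 = if (kp == 2) fit_rgx[[2]]$rg,
    delta_hat_2 = if (kp == 2) delta[2],
    phi_g_hat = if (kp == 2) fit_phi$rg,
    blocks = blocks_list)
  adj <- adjust_estimates(raw, config$alpha)

  row <- data.frame(
    n = n0, n_part = np,
    hx2_hat = fit_hx2$h2, se_hx2_hat = fit_hx2$se,
    hy2_hat = fit_hy[[1]]$h2, se_hy2_hat = fit_hy[[1]]$se,
    rho_g_hat = fit_rgx[[1]]$rg, se_rho_g_hat = fit_rgx[[1]]$se,
    delta = delta[1],
    hy2_tilde = adj$hy2_tilde, se_hy2_tilde = adj$se$hy2_tilde,
    rho_g_tilde = adj$rho_g_tilde, se_rho_g_tilde = adj$se$rho_g_tilde,
    rho_e_tilde = adj$rho_e_tilde, se_rho_e_tilde = adj$se$rho_e_tilde,
    flags = paste(adj$flags, collapse = ";"),
    stringsAsFactors = FALSE)
  if (kp == 2) {
    row$hy2_hat_2 <- fit_hy[[2]]$h2; row$se_hy2_hat_2 <- fit_hy[[2]]$se
    row$rho_g_hat_2 <- fit_rgx[[2]]$rg
    row$se_rho_g_hat_2 <- fit_rgx[[2]]$se
    row$delta_2 <- delta[2]
    row$phi_g_hat <- fit_phi$rg; row$se_phi_g_hat <- fit_phi$se
    row$hy2_tilde_2 <- adj$hy2_tilde_2
    row$se_hy2_tilde_2 <- adj$se$hy2_tilde_2
    row$rho_g_tilde_2 <- adj$rho_g_tilde_2
    row$se_rho_g_tilde_2 <- adj$se$rho_g_tilde_2
    row$rho_e_tilde_2 <- adj$rho_e_tilde_2
    row$se_rho_e_tilde_2 <- adj$se$rho_e_tilde_2
    row$phi_g_tilde <- adj$phi_g_tilde
    row$se_phi_g_tilde <- adj$se$phi_g_tilde
  }
  list(row = row,
       fits = list(hx2 = fit_hx2, hy = fit_hy, rgx = fit_rgx,
                   phi = fit_phi, adjusted = adj))
}

z_from_sums <- function(sgy, sg, sg2, sy, sy2, n) {
  vg <- sg2 - sg^2 / n
  vy <- sy2 - sy^2 / n
  cg <- sgy - sg * sy / n
  mono <- vg <= 0 | vy <= 0
  r <- ifelse(mono, 0, cg / sqrt(pmax(vg, 1e-300) * vy))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  r * sqrt((n - 2) / (1 - r^2))
}

# LD scores from already-computed realized lag-1 correlations
ld_scores_from_r <- function(blocks, r_used) {
  m <- nrow(blocks)
  l2 <- numeric(m)
  for (b in unique(blocks$block)) {
    idx <- which(blocks$block == b)
    pl <- length(idx)
    rl <- r_used[idx]
    R <- diag(pl)
    if (pl > 1) {
      for (i in seq_len(pl - 1)) {
        acc <- 1
        for (j in (i + 1):pl) {
          acc <- acc * rl[j]
          R[i, j] <- R[j, i] <- acc
        }
      }
    }
    l2[idx] <- colSums(R^2)
  }
  data.frame(snp = blocks$snp, l2 = l2, stringsAsFactors = FALSE)
}
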