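# Genotype simulator: LD block structure, effect sizes, sibling
# calibration, cohort construction and the per-SNP association scan.

test_that("block layout, determinism and the rho distribution", {
  expect_message(make_ld_blocks(101, 50, seed = 1), "truncated")
  b <- make_ld_blocks(100, 50, seed = 1)
  expect_equal(max(b$block), 2)
  expect_equal(nrow(b), 100)
  b2 <- make_ld_blocks(100, 50, seed = 1)
  expect_identical(b, b2)
  # distribution of the block autocorrelations
  big <- make_ld_blocks(50 * 10000, 50, seed = 2)
  rho_l <- big$rho[!duplicated(big$block)]
  expect_gt(stats::ks.test(rho_l, "punif", 0.1, 0.9)$p.value, 0.01)
  # float collisions among 5e5 draws trigger a spurious ties warning
  expect_gt(suppressWarnings(
    stats::ks.test(big$freq, "punif", 0.1, 0.9)$p.value), 0.01)
  expect_error(make_ld_blocks(100, 0), "block_size")
})

test_that("genotypes: margins, AR(1) decay, determinism", {
  # equal within-block frequencies so the AR(1) target is feasible
  b <- make_ld_blocks(10, 10, seed = 3)
  b$freq <- 0.35; b$rho <- 0.6
  g <- sample_genotypes(b, 1e5, seed = 11)
  expect_equal(attr(g, "n_clipped"), 0)
  # binomial margins
  expect_lt(abs(mean(g[, 4]) / 2 - 0.35), 3 * sqrt(0.35 * 0.65 / 2 / 1e5))
  # adjacent and lag-3 correlation (geometric decay oracle)
  se_r <- 1 / sqrt(1e5)
  expect_lt(abs(cor(g[, 4], g[, 5]) - 0.6), 4 * se_r)
  expect_lt(abs(cor(g[, 2], g[, 5]) - 0.6^3), 4 * se_r)
  # rho = 0: independent binomial sites
  b0 <- b; b0$rho <- 0
  g0 <- sample_genotypes(b0, 5e4, seed = 12)
  expect_lt(abs(cor(g0[, 1], g0[, 2])), 4 / sqrt(5e4))
  # determinism
  expect_identical(sample_genotypes(b, 100, seed = 5),
                   sample_genotypes(b, 100, seed = 5))
})

test_that("infeasible AR(1) targets are clipped or raised", {
  b <- make_ld_blocks(2, 2, seed = 4)
  b$freq <- c(0.1, 0.9); b$rho <- 0.9
  expect_error(sample_genotypes(b, 10, seed = 1, on_infeasible = "error"),
               "block 1")
  g <- sample_genotypes(b, 2e4, seed = 1)
  expect_equal(attr(g, "n_clipped"), 1)
  r_used <- attr(g, "r_used")[2]
  expect_lt(r_used, 0.9)
  expect_lt(abs(cor(g[, 1], g[, 2]) - r_used), 4 / sqrt(2e4))
})

test_that("effect sizes hit their variance and correlation targets", {
  set.seed(21)
  e <- sample_effects(1000, 0.1, hx2 = 0.125, hy2 = 0.2, rho_g = 1)
  expect_equal(length(e$causal), 100)
  # perfect genetic correlation: effects proportional on causal SNPs
  ratio <- e$beta[e$causal, 2] / e$beta[e$causal, 1]
  expect_equal(ratio, rep(sqrt(0.2 / 0.125), 100), tolerance = 1e-10)
  # variance target: E[sum beta^2] = h2 on the standardized scale
  sums <- replicate(200, {
    ee <- sample_effects(1000, 0.1, 0.125, 0.2, 0.25)
    c(sum(ee$beta[, 1]^2), sum(ee$beta[, 2]^2),
      cor(ee$beta[ee$causal, 1], ee$beta[ee$causal, 2]))
  })
  expect_lt(abs(mean(sums[1, ]) - 0.125), 3 * sd(sums[1, ]) / sqrt(200))
  expect_lt(abs(mean(sums[2, ]) - 0.2), 3 * sd(sums[2, ]) / sqrt(200))
  expect_lt(abs(mean(sums[3, ]) - 0.25), 3 * sd(sums[3, ]) / sqrt(200))
  # uncorrelated effects
  e0 <- sample_effects(2000, 0.1, 0.125, 0.2, 0, seed = 9)
  expect_lt(abs(cor(e0$beta[e0$causal, 1], e0$beta[e0$causal, 2])),
            3 / sqrt(200))
  expect_error(sample_effects(100, 0.1, 0.125, c(0.2, 0.5), c(1, -1),
                              phi_g = 1), "positive semi-definite")
})

test_that("sibling environment calibration solves the orthant equation", {
  expect_error(calibrate_sib_env(0.055, 1, 0.125), "infeasible")
  expect_error(calibrate_sib_env(0.055, 20, 0.125), "exceed")
  # perfect concordance limit: lambda -> 1/alpha
  t <- qnorm(1 - 0.055)
  # limit approached at rate sqrt(1 - r^2)
  expect_equal(partbias:::bvn_upper_orthant(t, 0.9999999), 0.055,
               tolerance = 1e-3)
  cal <- calibrate_sib_env(0.055, 2, 0.125)
  expect_gt(cal$c2_shared, 0)
  expect_equal(cal$r_sib, cal$c2_shared + 0.5 * 0.125, tolerance = 1e-12)
  # Monte Carlo verification of the recurrence risk at the solved r
  set.seed(22)
  n <- 2e6
  x1 <- rnorm(n)
  x2 <- cal$r_sib * x1 + sqrt(1 - cal$r_sib^2) * rnorm(n)
  p_both <- mean(x1 > t & x2 > t)
  target <- 2 * 0.055^2
  expect_lt(abs(p_both - target), 3 * sqrt(target / n))
})

test_that("cohorts: participation rate, liability scale, determinism", {
  cfg <- sim_config(n_individuals = 20000, m_snps = 2000, block_size = 50,
                    hx2 = 0.125, hy2 = 0.2, rho_g = 0.25, rho_e = 0.5)
  ch <- sample_cohort(cfg, seed = 31)
  # participation close to alpha; tolerance combines binomial noise and
  # the replicate-level wobble of the realized genetic variance
  expect_lt(abs(mean(ch$participated) - 0.055), 0.008)
  expect_lt(abs(var(ch$x_liability) - 1), 0.05)
  expect_lt(abs(var(ch$y[, 1]) - 1), 0.05)
  expect_lt(abs(cor(ch$x_liability, ch$y[, 1]) - cfg$params[[1]]$rho),
            0.05)
  ch2 <- sample_cohort(cfg, seed = 31)
  expect_identical(ch$genotypes, ch2$genotypes)
  expect_equal(ch$x_liability, ch2$x_liability)
  # alpha = 1: everyone participates
  cfg1 <- sim_config(n_individuals = 500, m_snps = 100, alpha = 1)
  expect_true(all(sample_cohort(cfg1, seed = 1)$participated))
})

test_that("sibling cohorts share environment and genetics", {
  cfg <- sim_config(n_sib_pairs = 4000, m_snps = 500, block_size = 50,
                    hx2 = 0.125, hy2 = 0.2, rho_g = 0.25, rho_e = 0.5,
                    lambda_s = 2)
  ch <- sample_cohort(cfg, seed = 41)
  expect_equal(nrow(ch$genotypes), 8000)
  x <- matrix(ch$x_liability, nrow = 2)
  cal <- calibrate_sib_env(0.055, 2, 0.125)
  # sibling liability correlation near the calibrated value
  expect_lt(abs(cor(x[1, ], x[2, ]) - cal$r_sib), 4 / sqrt(4000))
  # sibling genotype correlation ~ 0.5 at a SNP
  expect_lt(abs(cor(ch$genotypes[seq(1, 8000, 2), 3],
                    ch$genotypes[seq(2, 8000, 2), 3]) - 0.5),
            5 / sqrt(4000))
  # one participant per pair in the default GWAS subset
  sub <- participant_subset(ch)
  expect_false(any(duplicated(ch$sib_index[sub])))
})

test_that("association scan: planted signal, null calibration, flags", {
  cfg <- sim_config(n_individuals = 8000, m_snps = 300, block_size = 50,
                    alpha = 1)
  ch <- sample_cohort(cfg, seed = 51)
  # phenotype equal to a SNP's standardized dosage: that z dominates
  k <- 123
  pheno <- as.numeric(scale(ch$genotypes[, k]))
  ss <- gwas(ch, pheno, subset = seq_len(8000))
  expect_equal(which.max(abs(ss$z)), k)
  expect_gt(abs(ss$z[k]), 10 * max(abs(ss$z[-k][1:50])))
  # permuted phenotype: mean chi-square near 1
  set.seed(52)
  ssp <- gwas(ch, sample(ch$y[, 1]), subset = seq_len(8000))
  expect_lt(abs(mean(ssp$z^2) - 1), 0.15)
  # monomorphic SNP -> z = 0 with a count
  ch$genotypes[, 7] <- 1L
  ssm <- gwas(ch, pheno, subset = seq_len(8000))
  expect_identical(ssm$z[7], 0)
  expect_gte(attr(ssm, "n_monomorphic"), 1)
})

test_that("oracle participation GWAS recovers the liability heritability", {
  cfg <- sim_config(n_individuals = 40000, m_snps = 2000, block_size = 50,
                    hx2 = 0.125, hy2 = 0.2, rho_g = 0.25, rho_e = 0.5)
  ch <- sample_cohort(cfg, seed = 61)
  ss <- participation_oracle_gwas(ch)
  expect_true(attr(ss, "oracle"))
  ld <- ld_scores(ch$blocks)
  fit <- ldsc_h2(ss, ld, m_total = 2000, n_blocks = 40)
  expect_lt(abs(fit$h2 - 0.125), 3 * fit$se)
  # and the participation-phenotype genetic correlation in participants
  # reproduces the apparent (collider-biased) value
  ssy <- gwas(ch, "y1")
  rg <- ldsc_rg(ss, ssy, ld, m_total = 2000, intercept_zero = TRUE,
                n_blocks = 40)
  expect_lt(abs(rg$rg - apparent_rg_participation(cfg$params[[1]])),
            3 * rg$se)
  ch$x_liability <- NULL
  expect_error(participation_oracle_gwas(ch), "liability")
})
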