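# Genotype-level simulator: LD-blocked genotypes with AR(1) correlation
# decay, correlated effect sizes, liability construction, threshold
# selection, GWAS, sibling pairs with calibrated recurrence risk, and an
# oracle participation GWAS standing in for IBD-based participation
# statistics.

#' Draw LD block specifications
#'
#' Splits `m_snps` SNPs into contiguous blocks of `block_size` (the last
#' block is truncated, with a message, when the division is not exact).
#' Each block gets a base autocorrelation `rho ~ Unif(0.1, 0.9)` — the
#' target correlation between *adjacent* SNPs, decaying as `rho^|i-j|`
#' within the block and zero across blocks — and each SNP an allele
#' frequency `~ Unif(0.1, 0.9)`.
#'
#' @param m_snps Total number of SNPs.
#' @param block_size SNPs per block (default 50).
#' @param seed Optional integer seed.
#' @return Object of class `"ld_blocks"`: a data.frame with columns
#'   `snp`, `block`, `freq`, `rho` (block-level autocorrelation).
#' @export
make_ld_blocks <- function(m_snps, block_size = 50, seed = NULL) {
  if (block_size < 1) stop("`block_size` must be at least 1.")
  if (m_snps < 1) stop("`m_snps` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(m_snps / block_size)
  if (m_snps %% block_size != 0)
    message("last block truncated to ", m_snps %% block_size, " SNPs.")
  block <- rep(seq_len(n_blocks), each = block_size)[seq_len(m_snps)]
  rho_b <- runif(n_blocks, 0.1, 0.9)
  out <- data.frame(
    snp = sprintf("snp%06d", seq_len(m_snps)),
    block = block,
    freq = runif(m_snps, 0.1, 0.9),
    rho = rho_b[block],
    stringsAsFactors = FALSE)
  class(out) <- c("ld_blocks", "data.frame")
  out
}

# Haplotype-chain transition probabilities for each SNP. With
# heterogeneous allele frequencies, the AR(1) target correlation between
# adjacent binary haplotype states is not always attainable; infeasible
# targets are clipped to the Frechet-type bound (the largest correlation
# compatible with the two marginal frequencies), or raised as an error.
# The *realized* lag-1 correlations (`r_used`) are what all LD
# calculations use, so LD scores remain exact.
block_transitions <- function(blocks, on_infeasible = c("clip", "error")) {
  on_infeasible <- match.arg(on_infeasible)
  m <- nrow(blocks)
  p <- blocks$freq
  start <- c(TRUE, diff(blocks$block) != 0)
  p_prev <- c(p[1], p[-m])
  r <- ifelse(start, 0, blocks$rho)
  q <- 1 - p; q_prev <- 1 - p_prev
  r_max <- pmin(sqrt(p_prev * q / (q_prev * p)),
                sqrt(q_prev * p / (p_prev * q)))
  clipped <- r > r_max
  if (any(clipped) && on_infeasible == "error") {
    bad <- blocks$block[which(clipped)[1]]
    stop("AR(1) correlation infeasible for the marginal frequencies in ",
         "block ", bad, " (and possibly others); use on_infeasible = ",
         "\"clip\" to cap at the attainable bound.")
  }
  r_used <- pmin(r, r_max)
  t1 <- p + r_used * sqrt(p * q * q_prev / p_prev)
  t0 <- p - r_used * sqrt(p * q * p_prev / q_prev)
  t0[start] <- p[start]; t1[start] <- p[start]
  trans <- rbind((1 - t0)^2, (1 - t1) * (1 - t0), (1 - t1)^2,
                 1 - t0^2, 1 - t1 * t0, 1 - t1^2)
  list(trans = trans, t0 = t0, t1 = t1, r_target = r, r_used = r_used,
       start = start, n_clipped = sum(clipped))
}

#' Exact LD scores for simulated LD blocks
#'
#' Computes `l_j = sum_k r_jk^2` from the realized lag-1 correlations of
#' the genotype chains (pairwise correlations within a block are products
#' of consecutive lag-1 correlations; across blocks they are zero). These
#' are the population ("true LD matrix") scores used when regressing
#' simulated GWAS statistics.
#'
#' @param blocks An [make_ld_blocks()] object.
#' @inheritParams sample_genotypes
#' @return Data frame with columns `snp`, `l2`.
#' @export
ld_scores <- function(blocks, on_infeasible = "clip") {
  bt <- block_transitions(blocks, on_infeasible)
  ld_scores_from_r(blocks, bt$r_used)
}

#' Sample genotypes with block-wise AR(1) linkage disequilibrium
#'
#' Each haplotype is a stationary two-state Markov chain along the SNPs of
#' a block, with stationary probabilities equal to the allele frequencies
#' and lag-1 correlation equal to the block autocorrelation; lag-k
#' correlations therefore decay exactly geometrically. A genotype is the
#' sum of two independent haplotypes (equivalently, a three-state Markov
#' chain), giving dosages 0/1/2 with binomial margins.
#'
#' @param blocks An [make_ld_blocks()] object.
#' @param n Number of individuals.
#' @param seed Integer seed (mandatory; generation is deterministic given
#'   the seed, independent of R's RNG state).
#' @param on_infeasible `"clip"` (default) caps adjacent-SNP correlations
#'   at the bound attainable for the two marginal frequencies, recording
#'   the realized values; `"error"` raises instead, naming the block.
#' @return Integer matrix `n x m` of dosages, with SNP ids as column
#'   names and attributes `r_used` (realized lag-1 correlations) and
#'   `n_clipped`.
#' @export
sample_genotypes <- function(blocks, n, seed, on_infeasible = "clip") {
  if (missing(seed)) stop("`seed` is mandatory.")
  bt <- block_transitions(blocks, on_infeasible)
  g <- cpp_sample_genotypes(bt$trans, as.integer(n), as.double(seed))
  colnames(g) <- blocks$snp
  attr(g, "r_used") <- bt$r_used
  attr(g, "n_clipped") <- bt$n_clipped
  g
}

#' Draw correlated per-SNP effect sizes
#'
#' A fraction `causal_fraction` of SNPs (chosen uniformly at random)
#' receives effects drawn from a multivariate normal across traits: the
#' participation liability plus one or two phenotypes. Per-trait effect
#' variances are `variance / n_causal` on the standardized-genotype scale,
#' so the genetic variance of each trait targets its heritability at any
#' SNP count.
#'
#' @param m Number of SNPs.
#' @param causal_fraction Fraction of causal SNPs (default 0.1).
#' @param hx2 Heritability of the participation liability.
#' @param hy2 Phenotype heritability (length 1 or 2).
#' @param rho_g Genetic correlation(s) of the phenotype(s) with
#'   participation (same length as `hy2`).
#' @param phi_g Genetic correlation between the two phenotypes (required
#'   when `length(hy2) == 2`).
#' @param seed Optional integer seed.
#' @return Object of class `"effect_sizes"`: list with `beta` (an
#'   `m x K` matrix on the standardized-genotype scale, zero rows for
#'   non-causal SNPs; column 1 is participation), `causal` (indices),
#'   `vars`, `cor`.
#' @export
sample_effects <- function(m, causal_fraction = 0.1, hx2, hy2, rho_g,
                           phi_g = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kp <- length(hy2)
  if (length(rho_g) != kp)
    stop("`rho_g` must have one entry per phenotype.")
  if (kp == 2 && is.null(phi_g))
    stop("`phi_g` is required for two phenotypes.")
  if (kp > 2) stop("at most two phenotypes are supported.")
  K <- 1 + kp
  C <- diag(K)
  C[1, 1 + seq_len(kp)] <- C[1 + seq_len(kp), 1] <- rho_g
  if (kp == 2) C[2, 3] <- C[3, 2] <- phi_g
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("effect-size correlation matrix is not positive semi-definite.")
  n_causal <- max(1L, round(m * causal_fraction))
  causal <- sort(sample.int(m, n_causal))
  vars <- c(hx2, hy2)
  L <- psd_factor(C)
  draws <- matrix(rnorm(n_causal * K), n_causal, K) %*% t(L)
  draws <- sweep(draws, 2, sqrt(vars / n_causal), "*")
  beta <- matrix(0, m, K)
  beta[causal, ] <- draws
  structure(list(beta = beta, causal = causal, m = m,
                 causal_fraction = causal_fraction, vars = vars, cor = C),
            class = "effect_sizes")
}

#' Calibrate the shared sibling environment to a recurrence risk
#'
#' Siblings share half their genetic liability variance in expectation;
#' an additional shared-environment variance `c2` in the nongenetic part
#' raises the sibling liability correlation to `r = 0.5 * hx2 + c2`.
#' This function solves for the `r` (hence `c2`) at which the sibling
#' recurrence risk equals `lambda_s`, i.e.
#' `P(X_sib > t_alpha | X > t_alpha) = lambda_s * alpha`, using the
#' bivariate-normal upper-orthant probability.
#'
#' @param alpha Participation rate.
#' @param lambda_s Target sibling recurrence risk (`lambda_s * alpha <= 1`).
#' @param hx2 Heritability of the participation liability.
#' @return List with `c2_shared`, `r_sib` (the sibling liability
#'   correlation), and the inputs.
#' @export
calibrate_sib_env <- function(alpha, lambda_s, hx2) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1).")
  if (lambda_s * alpha > 1)
    stop("`lambda_s * alpha` cannot exceed 1 (perfect concordance gives ",
         "lambda = 1/alpha).")
  t <- qnorm(alpha, lower.tail = FALSE)
  target <- lambda_s * alpha^2        # P(both sibs participate)
  f <- function(r) bvn_upper_orthant(t, r) - target
  root <- uniroot(f, c(-0.999999, 0.999999), tol = 1e-12)
  r_sib <- root$root
  c2 <- r_sib - 0.5 * hx2
  if (c2 < 0)
    stop("infeasible: recurrence risk lambda_s = ", lambda_s,
         " requires sibling correlation ", signif(r_sib, 4),
         " below the genetic floor 0.5 * hx2 = ", 0.5 * hx2,
         " (a negative shared-environment variance).")
  if (c2 > 1 - hx2)
    stop("infeasible: required shared-environment variance ", signif(c2, 4),
         " exceeds the nongenetic variance ", 1 - hx2, ".")
  list(c2_shared = c2, r_sib = r_sib, alpha = alpha, lambda_s = lambda_s,
       hx2 = hx2)
}

#' Bivariate normal upper orthant probability
#'
#' `P(Z1 > t, Z2 > t)` for standard bivariate normal with correlation `r`,
#' by one-dimensional quadrature of the conditional tail.
#'
#' @param t Threshold (common to both coordinates).
#' @param r Correlation in `(-1, 1)`.
#' @return The orthant probability.
#' @keywords internal
bvn_upper_orthant <- function(t, r) {
  if (abs(r) >= 1) {
    if (r >= 1) return(pnorm(t, lower.tail = FALSE))
    return(max(0, 1 - 2 * pnorm(t)))
  }
  s <- sqrt(1 - r^2)
  integrate(function(x) dnorm(x) * pnorm((t - r * x) / s, lower.tail = FALSE),
            t, Inf, rel.tol = 1e-10, abs.tol = 1e-13)$value
}

#' Simulation configuration
#'
#' Bundles and validates all parameters of one simulated
#' phenotype-participation system. Defaults reproduce the validation
#' design: 50-SNP LD blocks, 10% causal SNPs, participation-liability
#' heritability 0.125, participation rate 0.055 and sibling recurrence
#' risk 2.
#'
#' @param n_individuals Number of unrelated individuals (exclusive with
#'   `n_sib_pairs`).
#' @param n_sib_pairs Number of sibling pairs (each contributing two
#'   individuals; the shared environment is calibrated to `lambda_s`).
#' @param m_snps,block_size,causal_fraction Genotype architecture.
#' @param hx2,hy2,rho_g,rho_e,phi_g,phi_e,alpha Model parameters
#'   ([model_params()] semantics; `hy2`, `rho_g`, `rho_e` may have length
#'   2 for a phenotype pair, in which case `phi_g` and `phi_e` are
#'   required).
#' @param lambda_s Sibling recurrence risk (used only with sib pairs).
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = NULL, n_sib_pairs = NULL,
                       m_snps = 10000, block_size = 50,
                       causal_fraction = 0.1, hx2 = 0.125, hy2 = 0.2,
                       rho_g = 0.25, rho_e = 0.5, phi_g = NULL,
                       phi_e = NULL, alpha = 0.055, lambda_s = 2) {
  if (is.null(n_individuals) == is.null(n_sib_pairs))
    stop("specify exactly one of `n_individuals` or `n_sib_pairs`.")
  kp <- length(hy2)
  if (length(rho_g) != kp || length(rho_e) != kp)
    stop("`hy2`, `rho_g`, `rho_e` must have equal lengths (1 or 2).")
  if (kp == 2 && (is.null(phi_g) || is.null(phi_e)))
    stop("two phenotypes require `phi_g` and `phi_e`.")
  if (kp > 2) stop("at most two phenotypes are supported.")
  # per-phenotype parameter validity (also checks the implied rho)
  params <- lapply(seq_len(kp), function(i)
    model_params(hx2, hy2[i], rho_g[i], rho_e[i], alpha))
  Ce <- diag(1 + kp)
  Ce[1, 1 + seq_len(kp)] <- Ce[1 + seq_len(kp), 1] <- rho_e
  if (kp == 2) Ce[2, 3] <- Ce[3, 2] <- phi_e
  if (min(eigen(Ce, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("residual correlation matrix is not positive semi-definite.")
  structure(list(n_individuals = n_individuals, n_sib_pairs = n_sib_pairs,
                 m_snps = m_snps, block_size = block_size,
                 causal_fraction = causal_fraction, hx2 = hx2, hy2 = hy2,
                 rho_g = rho_g, rho_e = rho_e, phi_g = phi_g, phi_e = phi_e,
                 alpha = alpha, lambda_s = lambda_s, params = params,
                 residual_cor = Ce, n_phenotypes = kp),
            class = "sim_config")
}

# residual covariance factor: D %*% chol-type factor of the residual
# correlation, D = diag(sqrt(1 - h2)) over (X, Y1[, Y2])
residual_factor <- function(config) {
  D <- diag(sqrt(1 - c(config$hx2, config$hy2)),
            nrow = 1 + config$n_phenotypes)
  D %*% psd_factor(config$residual_cor)
}

#' Simulate a cohort under the participation model
#'
#' Materializes genotypes, liabilities and participation for a cohort of
#' unrelated individuals or sibling pairs. Genotypes are standardized with
#' the *population* allele frequencies (known in simulation) when building
#' liabilities, matching the model's population-scale definitions. For
#' sibling pairs, genotypes are built by per-block Mendelian transmission
#' from simulated parental haplotypes, and the nongenetic liability
#' component includes a shared-environment term calibrated via
#' [calibrate_sib_env()]; phenotype residuals inherit sibling correlation
#' only through their loading on the participation residual.
#'
#' Intended for moderate cohort sizes (the matrix is held in memory); the
#' large-scale replication loop uses the streaming path in
#' [run_experiment()] instead.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed.
#' @return Object of class `"sim_cohort"`: list with `genotypes` (n x m
#'   integer), `x_liability`, `y` (n x n_phenotypes matrix), `participated`
#'   (logical), `sib_index` (or `NULL`), `blocks`, `effects`, `config`.
#' @export
sample_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("`seed` is mandatory.")
  set.seed(seed)
  m <- config$m_snps
  blocks <- make_ld_blocks(m, config$block_size)
  effects <- sample_effects(m, config$causal_fraction, config$hx2,
                            config$hy2, config$rho_g, config$phi_g)
  K <- 1 + config$n_phenotypes
  t_alpha <- qnorm(config$alpha, lower.tail = FALSE)

  sib <- !is.null(config$n_sib_pairs)
  if (!sib) {
    n <- config$n_individuals
    g <- sample_genotypes(blocks, n, seed = new_subseed())
    sib_index <- NULL
    eps <- matrix(rnorm(n * K), n, K) %*% t(residual_factor(config))
  } else {
    np <- config$n_sib_pairs
    n <- 2L * np
    bt <- block_transitions(blocks)
    hap <- function() cpp_sample_haplotypes(bt$t0, bt$t1, np, new_subseed())
    F1 <- hap(); F2 <- hap(); M1 <- hap(); M2 <- hap()
    nb <- max(blocks$block)
    transmit <- function() {
      # per-block choice of parental haplotype (recombination at block
      # boundaries), independently for each parent and each sib
      pickf <- matrix(runif(np * nb) < 0.5, np, nb)[, blocks$block]
      pickm <- matrix(runif(np * nb) < 0.5, np, nb)[, blocks$block]
      ifelse(pickf, F1, F2) + ifelse(pickm, M1, M2)
    }
    g <- matrix(0L, n, m)
    g[seq(1, n, by = 2), ] <- transmit()
    g[seq(2, n, by = 2), ] <- transmit()
    colnames(g) <- blocks$snp
    sib_index <- rep(seq_len(np), each = 2)
    cal <- calibrate_sib_env(config$alpha, config$lambda_s, config$hx2)
    # participation residual: shared + unique; phenotype residuals load on
    # it with coefficient b and keep their own independent remainder
    shared <- rep(rnorm(np, 0, sqrt(cal$c2_shared)), each = 2)
    ex <- shared + rnorm(n, 0, sqrt(1 - config$hx2 - cal$c2_shared))
    eps <- matrix(0, n, K)
    eps[, 1] <- ex
    b <- config$rho_e * sqrt((1 - config$hy2) / (1 - config$hx2))
    if (config$n_phenotypes == 1) {
      w <- rnorm(n, 0, sqrt((1 - config$rho_e^2) * (1 - config$hy2)))
      eps[, 2] <- b * ex + w
    } else {
      # joint remainder keeps the target cross-phenotype residual corr
      phi_E <- config$phi_e * sqrt(prod(1 - config$hy2))
      cw <- phi_E - b[1] * b[2] * (1 - config$hx2)
      Sw <- matrix(c((1 - config$rho_e[1]^2) * (1 - config$hy2[1]), cw,
                     cw, (1 - config$rho_e[2]^2) * (1 - config$hy2[2])), 2)
      W <- matrix(rnorm(2 * n), n, 2) %*% t(psd_factor(Sw))
      eps[, 2] <- b[1] * ex + W[, 1]
      eps[, 3] <- b[2] * ex + W[, 2]
    }
  }

  sd_g <- sqrt(2 * blocks$freq * (1 - blocks$freq))
  bstd <- effects$beta[effects$causal, , drop = FALSE] / sd_g[effects$causal]
  gen <- g[, effects$causal, drop = FALSE] %*% bstd
  gen <- sweep(gen, 2, colSums(bstd * 2 * blocks$freq[effects$causal]), "-")
  lia <- gen + eps
  structure(list(genotypes = g, x_liability = lia[, 1],
                 y = lia[, -1, drop = FALSE],
                 participated = lia[, 1] > t_alpha,
                 sib_index = sib_index, blocks = blocks, effects = effects,
                 config = config, seed = seed),
            class = "sim_cohort")
}

# fresh kernel seed drawn from R's RNG stream (so everything remains a
# deterministic function of the caller's set.seed)
new_subseed <- function() sample.int(.Machine$integer.max, 1)

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d individuals x %d SNPs, %d participants (%.3f)\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(x$participated),
              mean(x$participated)))
  if (!is.null(x$sib_index)) cat("  sibling pairs:", max(x$sib_index), "\n")
  invisible(x)
}

#' Default GWAS subset: participants, one per sibling pair
#'
#' @param cohort A [sample_cohort()] object.
#' @return Integer indices of the rows to use in a participant GWAS.
#' @export
participant_subset <- function(cohort) {
  idx <- which(cohort$participated)
  if (is.null(cohort$sib_index)) return(idx)
  # keep the first participating sib of each pair
  idx[!duplicated(cohort$sib_index[idx])]
}

#' Per-SNP association scan
#'
#' Simple linear regression of a phenotype on each SNP dosage over the
#' chosen subset; `z = beta_hat / se(beta_hat)`, equal to
#' `r * sqrt((n - 2) / (1 - r^2))` with `r` the sample correlation.
#' Monomorphic SNPs in the subset get `z = 0` and are counted in the
#' `"n_monomorphic"` attribute.
#'
#' @param cohort A [sample_cohort()] object.
#' @param phenotype Phenotype column (`"y1"` or `"y2"`), or a numeric
#'   vector of length `nrow(genotypes)`.
#' @param subset Row indices (default: [participant_subset()]).
#' @return Summary-statistics data frame (`snp, a1, a2, n, z`).
#' @export
gwas <- function(cohort, phenotype = "y1", subset = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(subset)) subset <- participant_subset(cohort)
  if (length(subset) < 3) stop("GWAS subset must have at least 3 rows.")
  y <- if (is.character(phenotype)) {
    k <- match(phenotype, c("y1", "y2"))
    if (is.na(k) || k > ncol(cohort$y)) stop("unknown phenotype: ", phenotype)
    cohort$y[subset, k]
  } else phenotype[subset]
  zstats_from_matrix(cohort$genotypes[subset, , drop = FALSE], y,
                     cohort$blocks$snp)
}

zstats_from_matrix <- function(G, y, snp_ids) {
  ns <- nrow(G)
  gm <- colMeans(G)
  sg2 <- colSums(G^2) - ns * gm^2
  yc <- y - mean(y)
  sgy <- as.numeric(crossprod(G, yc))
  sy2 <- sum(yc^2)
  mono <- sg2 <= 0 | sy2 <= 0
  r <- ifelse(mono, 0, sgy / sqrt(pmax(sg2, 1e-300) * sy2))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- r * sqrt((ns - 2) / (1 - r^2))
  out <- data.frame(snp = snp_ids, a1 = "A", a2 = "B", n = ns, z = z,
                    stringsAsFactors = FALSE)
  attr(out, "n_monomorphic") <- sum(mono)
  out
}

#' Oracle participation GWAS
#'
#' Regresses the *latent* participation liability on each SNP over the
#' full invited cohort — an idealized stand-in for a population-scale
#' participation GWAS obtained without nonparticipant genotypes (in real
#' data, from IBD-based sibling comparisons). Clearly labelled as an
#' oracle in the result's attributes.
#'
#' @param cohort A [sample_cohort()] object (must retain `x_liability`).
#' @return Summary-statistics data frame with attribute `oracle = TRUE`.
#' @export
participation_oracle_gwas <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(cohort$x_liability))
    stop("the cohort does not retain the participation liability.")
  out <- zstats_from_matrix(cohort$genotypes, cohort$x_liability,
                            cohort$blocks$snp)
  attr(out, "oracle") <- TRUE
  out
}
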