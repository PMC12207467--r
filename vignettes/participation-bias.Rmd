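---
title: "Selection on participation: the model behind partbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection on participation: the model behind partbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partbias)
```

## The model

Study participation is treated as a liability-threshold trait. A latent
participation liability $X$ is standard normal in the invited population,
and an individual participates iff $X > t_\alpha = \Phi^{-1}(1-\alpha)$,
where $\alpha$ is the participation rate. A phenotype $Y$ (standardized in
the population) shares genetic and nongenetic sources with $X$:

$$X = G_x + \epsilon_x, \qquad Y = G_y + \epsilon_y,$$

with $\mathrm{Var}(G_x) = h^2_x$, $\mathrm{Var}(G_y) = h^2_y$,
$\rho_g = \mathrm{Corr}(G_x, G_y)$ and
$\rho_e = \mathrm{Corr}(\epsilon_x, \epsilon_y)$. The phenotypic
correlation decomposes as $\rho = \rho_G + \rho_E$ with
$\rho_G = \rho_g\sqrt{h^2_x h^2_y}$ and
$\rho_E = \rho_e\sqrt{(1-h^2_x)(1-h^2_y)}$.

Everything selection does to second moments is governed by one scalar,
the variance-reduction factor

$$\xi(\alpha) = 1 - \mathrm{Var}(X \mid X > t_\alpha)
  = \lambda(\lambda - t_\alpha), \qquad
  \lambda = \phi(t_\alpha)/\alpha,$$

through the Pearson–Lawley rule for jointly Gaussian $(U, V, X)$:

$$\mathrm{Cov}(U, V \mid X > t_\alpha)
  = \mathrm{Cov}(U, V) - \xi\,\mathrm{Cov}(U, X)\,\mathrm{Cov}(V, X).$$

Writing $G_y = a G_x + G_w$ and $\epsilon_y = b \epsilon_x + \epsilon_w$
with $G_w, \epsilon_w$ orthogonal to the participation axes isolates what
selection can touch: $G_w$ and $\epsilon_w$ pass through unchanged, while
$G_x$ and $\epsilon_x$ shrink and become negatively correlated (collider
bias). The "apparent" quantities that estimators target in the selected
sample — `apparent_h2()`, `apparent_rg_participation()`,
`apparent_rg_two_phenotypes()` — follow in closed form. Two readings of
the typeset expressions differ in which terms the factor
$(1-\xi h^2_x)$ divides; the package resolves this by requiring exact
agreement (to $10^{-10}$, enforced in the test suite) with an independent
construction that regresses $Y$ on $(G_x, G_w)$ under the selected
distribution using only the selection rule above, and statistical
agreement with a truncated-MVN Monte Carlo oracle (`mc_apparent()`).

```{r apparent}
p <- model_params(hx2 = 0.125, hy2 = 0.2, rho_g = 0.25, rho_e = 0.5,
                  alpha = 0.055)
c(apparent_h2 = apparent_h2(p),
  apparent_rg = apparent_rg_participation(p))
```

Note the sign flip: with $\rho_g = 0.25$ the apparent genetic correlation
with participation is *negative* — conditioning on a collider can reverse
signs, not just attenuate.

## The adjustment

The inverse problem takes four participant-side inputs: the LDSC
heritability $\hat h^2_y$ in participants, the LDSC genetic correlation
$\hat\rho_g$ between a population-scale participation GWAS and the
phenotype GWAS, the participation-liability SNP heritability $\hat h^2_x$
(from IBD-based sibling comparisons in real data; consumed as given), and
the standardized mean shift $\hat\delta$ of the phenotype between
participants and a population reference. The chain is

1. $\hat\rho$ from $\hat\delta$ (`rho_from_mean_shift()` — the exact
   inverse of the mean-shift map);
2. $\hat\rho_G$ from $\hat\rho_g$ (`raw_genetic_covariance()`);
3. $\tilde\rho_G = \sqrt{1-\xi\hat\rho^2}\,\hat\rho_G +
   \xi\hat\rho\hat h^2_x$ (`adjusted_genetic_covariance()`);
4. $\tilde h^2_y$ (`adjusted_h2()`), then $\tilde\rho_g$ and, via the
   composition identity, $\tilde\rho_e$.

For a pair of phenotypes, the cross-trait genetic covariance is recovered
by exactly inverting the selected-sample expression, with the *adjusted*
participation covariances $\tilde\rho_{Gi}$ appearing in the interaction
terms:

$$\tilde\varphi_G = \sqrt{(1-\xi\hat\rho_1^2)(1-\xi\hat\rho_2^2)}\,
  \hat\varphi_G + \xi(\hat\rho_1\tilde\rho_{G2} +
  \hat\rho_2\tilde\rho_{G1}) - \xi^2\hat\rho_1\hat\rho_2\hat h^2_x
  - \frac{\xi}{1-\xi\hat h^2_x}
    (\tilde\rho_{G1}-\xi\hat\rho_1\hat h^2_x)
    (\tilde\rho_{G2}-\xi\hat\rho_2\hat h^2_x).$$

A variant that keeps the unadjusted $\hat\rho_{Gi}$ in those terms is
only a first-order approximation; it is *not* an exact inverse (on the
standard validation parameters it would return 0.39 where the true value
is 0.5), so the package uses the exact form. The whole chain is pinned
down by a property test: `adjust(forward(params)) = params` to
$10^{-10}$ over hundreds of random parameter draws — this single
round-trip requirement eliminates every grouping ambiguity at once.

Out-of-range adjusted values (heritabilities outside $[0,1]$,
correlations outside $[-1,1]$) are returned raw with machine-readable
flags, never clamped: clamping would silently break the linearity that
block-jackknife pseudovalues rely on. Standard errors are obtained by
rerunning the full chain on each leave-one-block-out replicate of the
LDSC inputs and jackknifing the pseudovalues (`jackknife_adjust()`); the
mean shift, which has no SNP-block structure, is held fixed across
replicates.

## Mean shifts

`compute_mean_shift()` implements the observational side:
$\hat\delta = (\bar y_{\text{sample}} - \bar y_{\text{ref}}) /
\mathrm{SD}_{\text{sample}}$, standardized by the *sample* SD because
that is the scale on which the participant-side analyses live. Two
processing choices needed fixing where practice varies:

* the rank-based inverse-normal transform is computed on the **pooled**
  cohorts (optionally within strata such as sex). Transforming each
  cohort separately would force both means to zero and destroy the
  signal; pooled ranking keeps the shift and makes it invariant to any
  strictly monotone rescaling of the raw measurements.
* covariate slopes are estimated on the pooled data **with a cohort
  fixed effect**, and only the covariate part is subtracted. Omitting
  the cohort term would let a covariate whose distribution differs
  between cohorts absorb part of the shift itself.

## LD score regression

`ldsc_h2()` and `ldsc_rg()` are deliberately minimal:
$E[\chi^2_j] = c + (N_j h^2/M)\,\ell_j$ and
$E[z_{1j} z_{2j}] = c + (\sqrt{N_{1j}N_{2j}}\,\varphi_G/M)\,\ell_j$ by
weighted least squares. Weighting is the standard heuristic, fixed at
two passes for determinism: pass one uses the $1/\max(\ell_j, 1)$
heteroscedasticity/over-counting factor alone; pass two divides further
by the squared fitted mean (chi-square variance) or by
$(\hat f_{1j}\hat f_{2j} + \hat f_{cj}^2)$ for cross products. Using the
same functional form in both places has a convenient consequence: the
genetic correlation of a trait with itself is exactly 1. Fitted means
are floored at 0.1 when inverted, so near-zero fits cannot blow up the
weights. The intercept conventions are an argument, not a policy:
heritabilities and phenotype–phenotype correlations default to a free
intercept (absorbing confounding and sample overlap), while
participation–phenotype correlations are fitted with the intercept fixed
at zero, the convention appropriate when sample overlap has been
removed. Standard errors use a contiguous block jackknife (default 200
blocks) in the supplied SNP order, which the caller should keep genomic;
all three regressions inside `ldsc_rg()` share one merged SNP set and
one block assignment, so the leave-one-out series of the correlation is
internally consistent.

The selected sample violates one LDSC assumption: selection induces
long-range (cross-block) LD among SNPs affecting participation. No
correction is applied; at the scales exercised here the resulting bias
in the apparent-scale estimates is small relative to sampling noise, and
the adjustment consumes those estimates as they are.

## The simulator

`sim_config()` / `run_experiment()` emulate the validation design:

* **LD blocks** of 50 SNPs; per block an AR(1) base correlation
  $\rho_l \sim U(0.1, 0.9)$, per SNP an allele frequency
  $\sim U(0.1, 0.9)$. Haplotypes are stationary two-state Markov chains
  with those margins and lag-1 correlation $\rho_l$; lag-$k$
  correlations decay exactly as products of lag-1 values, and a genotype
  is the sum of two independent chains. For unequal adjacent
  frequencies, the AR(1) target can exceed the largest correlation a
  binary pair can support; the generator then clips to the attainable
  bound (about 40% of adjacent pairs at these defaults) and records the
  realized correlations, from which the exact population LD scores are
  computed. `on_infeasible = "error"` is available when clipping is not
  acceptable.
* **Effects**: 10% of SNPs causal, multivariate-normal effects across
  traits with per-trait variance $h^2 / m_{\text{causal}}$ on the
  standardized-genotype scale, so heritability targets hold at any SNP
  count.
* **Cohort**: liabilities built with population-frequency
  standardization; participants are those with $X > t_\alpha$. Residual
  cross-trait correlations are exact by construction. Realized genetic
  variance fluctuates around its target between replicates (the effects
  are drawn, not normalized), as it would in any finite genome.
* **Participation GWAS oracle**: the latent $X$ regressed on dosages in
  the full invited cohort. This stands in for a population-scale
  participation GWAS that real analyses obtain from IBD-based sibling
  comparisons without nonparticipant genotypes; it is labelled an
  oracle in the output. Sibling-pair machinery (Mendelian transmission
  from simulated parental haplotypes, shared environment calibrated so
  that the sibling recurrence risk $\lambda$ hits its target via the
  bivariate-normal orthant equation, `calibrate_sib_env()`) exists in
  `sample_cohort()` for cohort-level studies, but the replication loop
  uses unrelated individuals: with the oracle GWAS in place, sib pairs
  would only halve the effective sample.
* **Scale**: the default experiment uses 545,000 individuals per
  replicate so that roughly 30,000 participate at $\alpha = 0.055$,
  with 10,000 SNPs and 20 replicates — a desk-scale design chosen so a
  full run completes in minutes on one core while participant-side
  LDSC still has realistic signal. The full-size design (tens of
  millions of individuals, 50 replicates) is reachable through the same
  interface but is not run by default.

The cohort loop is streaming: one individual's genotype row is generated,
scored, and reduced to sufficient statistics in cache; no genotype matrix
is ever materialized at experiment scale.

What the simulator does **not** emulate: real human LD maps (block-wise
AR(1) is a caricature with the right decay, not the right topology),
rare variants (frequencies are bounded away from 0), genotyping error and
missingness, indirect genetic effects, assortative mating, invitation-
stage bias (the invited list is the population; a sensitivity multiplier
`hx2_scale` on the participation heritability stands in for the two
invitation-bias extremes), and the IBD estimation noise of a real
participation GWAS (the oracle is noisier than the truth only through
GWAS sampling error). Passing tests therefore demonstrate that the
estimators and the adjustment chain are correct under the stated model,
not that the model captures every feature of biobank data.

## Numerical choices

* $\xi$ is computed as $\lambda(\lambda - t_\alpha)$ with
  $\lambda = \exp(\log\phi(t_\alpha) - \log\alpha)$, stable to very
  small $\alpha$; $\alpha = 1$ is an explicit no-selection case
  ($t_\alpha = -\infty$, $\xi = 0$) so all limits are exact.
* The truncated-MVN oracle samples $X$ by inverse CDF on the upper tail
  and the rest from the Gaussian conditional — no rejection, so tiny
  $\alpha$ costs nothing. Monte Carlo standard errors come from 100
  batch means. Covariance factors use an eigendecomposition, so exact
  correlations (singular covariances) are legal corners.
* Degenerate corners raise informative errors where a limit does not
  exist (e.g. $\rho_g \ne 0$ with $h^2_x = 0$) and return exact limits
  where it does.
* All simulator randomness descends from one caller seed; the C++
  kernels use a counter-seeded xoshiro256++ stream whose seeds are drawn
  from R's RNG, so results are reproducible end to end and independent
  of platform RNG quirks.

## Known limitations

* Binary phenotypes are handled only on a liability-proxy scale: no
  conversion from prevalence differences to liability-scale mean shifts
  is provided.
* The participation-liability heritability is consumed as given; its
  estimation (IBD-based) is outside scope, and errors in it propagate
  undamped through the chain (the `hx2_scale` multiplier exposes this
  sensitivity).
* The magnitude-of-bias curve is monotone in $\alpha$ in the moderate
  same-sign regime, but when genetic and nongenetic distortions nearly
  cancel the net bias is tiny and need not be monotone — the qualitative
  laws are asserted where they actually hold.
* Selection-induced long-range LD is left uncorrected in the LDSC step,
  as discussed above.
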