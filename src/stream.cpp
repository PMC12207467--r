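// Streaming genotype simulation kernels.
//
// Genotypes are sums of two independent two-state Markov haplotype chains,
// which makes the genotype itself a three-state Markov chain along each LD
// block; pairwise haplotype correlations therefore decay exactly
// geometrically within a block (the AR(1) target). All transition
// probabilities are precomputed in R and passed in as cumulative thresholds
// (a 6 x m matrix, so each SNP's thresholds are contiguous), and the cohort
// kernel is a single streaming pass: one individual's genotype row lives in
// cache, liabilities are formed as soon as the row is complete, and only
// per-SNP sufficient statistics are accumulated. No genotype matrix is ever
// materialized for the large cohorts.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: fast, deterministic across
// platforms, independent of R's RNG state (kernel seeds are drawn from R's
// stream so reproducibility still flows from one top-level seed).
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // uniform in (0,1)
    return (next() >> 11) * 0x1.0p-53 + 0x1.0p-54;
  }
  // Box-Muller, second value cached
  double spare = 0.0; bool has_spare = false;
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a); has_spare = true;
    return r * std::cos(a);
  }
};

// Walk one genotype chain into row (length m). trans is 6 x m, column j =
// (c0 | prev = 0, 1, 2, c1 | prev = 0, 1, 2): cumulative P(next <= 0) and
// P(next <= 1). Block-start SNPs carry their stationary law in all rows.
inline void walk_chain(const double* trans, int m, Xoshiro& rng,
                       int8_t* row) {
  int prev = 0;
  const double* col = trans;
  for (int j = 0; j < m; ++j, col += 6) {
    double u = rng.unif();
    int g = (u >= col[prev]) + (u >= col[3 + prev]);  // branchless
    row[j] = (int8_t)g;
    prev = g;
  }
}

}  // namespace

// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_sample_genotypes(NumericMatrix trans, int n, double seed) {
  const int m = trans.ncol();
  IntegerMatrix out(n, m);
  int* o = INTEGER(out);
  Xoshiro rng((uint64_t)seed);
  std::vector<int8_t> row(m);
  for (int i = 0; i < n; ++i) {
    walk_chain(&trans(0, 0), m, rng, row.data());
    for (int j = 0; j < m; ++j) o[(size_t)j * n + i] = row[j];
  }
  return out;
}

// Haplotype-level generator (0/1), used for sib-pair Mendelian
// transmission; t0/t1 are P(h_j = 1 | h_{j-1} = 0 or 1), block starts
// encode t0 = t1 = p.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_sample_haplotypes(NumericVector t0, NumericVector t1,
                                    int n, double seed) {
  const int m = t0.size();
  IntegerMatrix out(n, m);
  int* o = INTEGER(out);
  Xoshiro rng((uint64_t)seed);
  for (int i = 0; i < n; ++i) {
    int prev = 0;
    for (int j = 0; j < m; ++j) {
      double p = prev ? t1[j] : t0[j];
      int h = rng.unif() < p ? 1 : 0;
      o[(size_t)j * n + i] = h;
      prev = h;
    }
  }
  return out;
}

// Streaming cohort simulation. Generates n individuals' genotypes, builds
// K liabilities (column 0 = participation liability X, the rest are
// phenotypes) from compacted standardized effects and pre-drawn residuals,
// selects participants (X > t_alpha), and accumulates per-SNP sufficient
// statistics:
//   full cohort:  sum(g * x), genotype counts c1, c2
//   participants: sum(g), sum(g^2), sum(g * y_k)
// eff_idx: 0-based indices of causal SNPs (length nc);
// eff_val: K x nc standardized effects (beta_j / sd(g_j));
// offs: length K, sum_j eff[j,k] * 2 p_j; eps: n x K residuals.
// [[Rcpp::export(rng = false)]]
List cpp_cohort_stats(NumericMatrix trans, IntegerVector eff_idx,
                      NumericMatrix eff_val, NumericVector offs,
                      NumericMatrix eps, double t_alpha, double seed) {
  const int m = trans.ncol();
  const R_xlen_t n = eps.nrow();
  const int K = eps.ncol();
  const int nc = eff_idx.size();
  Xoshiro rng((uint64_t)seed);

  NumericVector sum_gx(m);
  NumericVector part_g(m), part_g2(m);
  NumericMatrix part_gy(m, K);
  NumericVector full_sum(K), full_sum2(K), part_sum(K), part_sum2(K);
  std::vector<int64_t> c1(m, 0), c2(m, 0);
  R_xlen_t n_part = 0;

  std::vector<int8_t> row(m);
  std::vector<double> pheno(K);
  double* sgx = REAL(sum_gx);
  double* pg = REAL(part_g); double* pg2 = REAL(part_g2);
  const double* ev = REAL(eff_val);
  const double* ep = REAL(eps);
  const int* ix = INTEGER(eff_idx);

  for (R_xlen_t i = 0; i < n; ++i) {
    walk_chain(&trans(0, 0), m, rng, row.data());
    for (int k = 0; k < K; ++k) pheno[k] = ep[i + (R_xlen_t)k * n] - offs[k];
    for (int jj = 0; jj < nc; ++jj) {
      double g = (double)row[ix[jj]];
      if (g != 0.0) {
        const double* e = ev + (size_t)K * jj;
        for (int k = 0; k < K; ++k) pheno[k] += e[k] * g;
      }
    }
    const double x = pheno[0];
    for (int j = 0; j < m; ++j) {
      int g = row[j];
      sgx[j] += g * x;
      c1[j] += (g == 1);
      c2[j] += (g == 2);
    }
    for (int k = 0; k < K; ++k) {
      full_sum[k] += pheno[k];
      full_sum2[k] += pheno[k] * pheno[k];
    }
    if (x > t_alpha) {
      ++n_part;
      double y1 = K > 1 ? pheno[1] : 0.0;
      double y2 = K > 2 ? pheno[2] : 0.0;
      double* gy1 = K > 1 ? &part_gy(0, 1) : pg;
      double* gy2 = K > 2 ? &part_gy(0, 2) : pg;
      for (int j = 0; j < m; ++j) {
        double g = row[j];
        pg[j] += g; pg2[j] += g * g;
        gy1[j] += g * y1; gy2[j] += g * y2;
      }
      for (int k = 3; k < K; ++k) {  // rarely used: >2 phenotypes
        double yk = pheno[k];
        double* col = &part_gy(0, k);
        for (int j = 0; j < m; ++j) col[j] += row[j] * yk;
      }
      for (int k = 0; k < K; ++k) {
        part_sum[k] += pheno[k];
        part_sum2[k] += pheno[k] * pheno[k];
      }
    }
  }

  NumericVector cnt1(m), cnt2(m);
  for (int j = 0; j < m; ++j) { cnt1[j] = (double)c1[j]; cnt2[j] = (double)c2[j]; }

  return List::create(
    _["n"] = (double)n, _["n_part"] = (double)n_part,
    _["sum_gx"] = sum_gx, _["cnt1"] = cnt1, _["cnt2"] = cnt2,
    _["part_g"] = part_g, _["part_g2"] = part_g2, _["part_gy"] = part_gy,
    _["full_sum"] = full_sum, _["full_sum2"] = full_sum2,
    _["part_sum"] = part_sum, _["part_sum2"] = part_sum2);
}

// Batched moments of (X, Z_1..Z_d) given X > t_alpha: X is drawn from its
// truncated upper-tail marginal by inverse CDF, the remaining coordinates
// from their Gaussian conditional Z | X = x ~ N(coef * x, L L') with L a
// (dense) factor of the conditional covariance. Returns per-batch
// sums and upper-triangle cross-product sums of the d+1 variables, so any
// derived moment carries a batch-level Monte Carlo standard error.
// [[Rcpp::export(rng = false)]]
List cpp_mc_truncated(double alpha, NumericVector coef, NumericMatrix L,
                      int n_draws, int n_batches, double seed) {
  const int d = coef.size();
  const int v = d + 1;
  Xoshiro rng((uint64_t)seed);
  const int per = n_draws / n_batches;
  NumericMatrix bsum(n_batches, v);
  NumericMatrix bcross(n_batches, v * v);
  std::vector<double> z(d), w(v);
  for (int b = 0; b < n_batches; ++b) {
    double* sm = &bsum(b, 0);
    double* cr = &bcross(b, 0);
    for (int it = 0; it < per; ++it) {
      double u = rng.unif();
      double x = R::qnorm(alpha * u, 0.0, 1.0, 0, 0);  // upper tail
      for (int k = 0; k < d; ++k) z[k] = rng.norm();
      w[0] = x;
      for (int k = 0; k < d; ++k) {
        double acc = coef[k] * x;
        for (int l = 0; l < d; ++l) acc += L(k, l) * z[l];
        w[1 + k] = acc;
      }
      for (int a = 0; a < v; ++a) {
        sm[(size_t)a * n_batches] += w[a];
        for (int c = a; c < v; ++c)
          cr[((size_t)a * v + c) * n_batches] += w[a] * w[c];
      }
    }
  }
  return List::create(_["batch_sum"] = bsum, _["batch_cross"] = bcross,
                      _["per_batch"] = per);
}
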