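// Haplotype-copying hidden Markov model (Li-Stephens style).
//
// Hidden state at marker m = which reference haplotype the target haplotype
// is copying. Between adjacent markers the chain switches template with
// probability 1 - exp(-rate_per_bp * delta_bp * K), the new template drawn
// uniformly from the K reference haplotypes (including the current one).
// Emission: observed allele matches the template allele with probability
// 1 - copy_error; missing observations are uninformative.
//
// All randomness uses R's RNG so results are reproducible via set.seed().
// Inner loops use raw column pointers and a caller-owned workspace: phasing
// runs the forward recursion once per haplotype per iteration, which is the
// hot path of the whole package.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct HmmWork {
  std::vector<double> alpha; // K x M, column-major
  std::vector<double> sw;    // M - 1
  std::vector<double> beta, nbeta;
  void ensure(int K, int M) {
    if ((int)alpha.size() < K * M) alpha.assign((size_t)K * M, 0.0);
    if ((int)sw.size() < M - 1 && M > 1) sw.assign(M - 1, 0.0);
    if ((int)beta.size() < K) { beta.assign(K, 0.0); nbeta.assign(K, 0.0); }
  }
};

// forward pass with per-column normalisation; rows skip1/skip2 (excluded
// haplotypes, e.g. the animal's own during phasing) are clamped to 0.
static void forward_pass(const int *H, int K, int M, int skip1, int skip2,
                         const int *obs, const double *rate_dbp, double e,
                         HmmWork &w) {
  int keff = K - (skip1 >= 0) - (skip2 >= 0 && skip2 != skip1);
  if (keff <= 0) stop("no reference haplotypes left after exclusions");
  for (int m = 0; m + 1 < M; ++m)
    w.sw[m] = 1.0 - std::exp(-rate_dbp[m] * keff);
  const double em0 = e, em1 = 1.0 - e;
  double *a = w.alpha.data();
  {
    const int *hc = H;
    const double init = 1.0 / keff;
    int o = obs[0];
    for (int k = 0; k < K; ++k) {
      double em = (o < 0) ? 1.0 : (hc[k] == o ? em1 : em0);
      a[k] = init * em;
    }
    if (skip1 >= 0) a[skip1] = 0.0;
    if (skip2 >= 0) a[skip2] = 0.0;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += a[k];
    double inv = 1.0 / tot;
    for (int k = 0; k < K; ++k) a[k] *= inv;
  }
  for (int m = 1; m < M; ++m) {
    const int *hc = H + (size_t)m * K;
    const double *prev = a + (size_t)(m - 1) * K;
    double *cur = a + (size_t)m * K;
    const double s = w.sw[m - 1];
    const double stay = 1.0 - s, move = s / keff;
    const int o = obs[m];
    if (o < 0) {
      for (int k = 0; k < K; ++k) cur[k] = stay * prev[k] + move;
    } else {
      for (int k = 0; k < K; ++k) {
        double v = stay * prev[k] + move;
        cur[k] = (hc[k] == o) ? v * em1 : v * em0;
      }
    }
    if (skip1 >= 0) cur[skip1] = 0.0;
    if (skip2 >= 0) cur[skip2] = 0.0;
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += cur[k];
    double inv = 1.0 / tot;
    for (int k = 0; k < K; ++k) cur[k] *= inv;
  }
}

// P(target allele = 1 | data) per marker, via forward-backward
static void posterior_allele1(const int *H, int K, int M, int skip1, int skip2,
                              const int *obs, const double *rate_dbp, double e,
                              HmmWork &w, double *p1) {
  forward_pass(H, K, M, skip1, skip2, obs, rate_dbp, e, w);
  int keff = K - (skip1 >= 0) - (skip2 >= 0 && skip2 != skip1);
  const double em0 = e, em1 = 1.0 - e;
  double *beta = w.beta.data(), *nbeta = w.nbeta.data();
  for (int k = 0; k < K; ++k) beta[k] = 1.0;
  if (skip1 >= 0) beta[skip1] = 0.0;
  if (skip2 >= 0) beta[skip2] = 0.0;
  for (int m = M - 1; m >= 0; --m) {
    const int *hc = H + (size_t)m * K;
    const double *am = w.alpha.data() + (size_t)m * K;
    double tot = 0.0, psum = 0.0;
    for (int k = 0; k < K; ++k) {
      double g = am[k] * beta[k];
      tot += g;
      psum += (hc[k] == 1) ? g * em1 : g * em0;
    }
    p1[m] = psum / tot;
    if (m == 0) break;
    // beta_k(m-1) = sum_j T(k->j) em_j(m) beta_j(m)
    const double s = w.sw[m - 1];
    const double stay = 1.0 - s, move = s / keff;
    const int o = obs[m];
    double pool = 0.0;
    for (int k = 0; k < K; ++k) {
      double em = (o < 0) ? 1.0 : (hc[k] == o ? em1 : em0);
      nbeta[k] = em * beta[k];
      pool += nbeta[k];
    }
    double scale = 0.0;
    for (int k = 0; k < K; ++k) {
      beta[k] = stay * nbeta[k] + move * pool;
      scale += beta[k];
    }
    if (skip1 >= 0) beta[skip1] = 0.0;
    if (skip2 >= 0) beta[skip2] = 0.0;
    double inv = keff / scale; // keep magnitudes near 1
    for (int k = 0; k < K; ++k) beta[k] *= inv;
  }
}

// sample a template path from its posterior; out[m] = template allele
static void sample_path_alleles(const int *H, int K, int M, int skip1,
                                int skip2, const int *obs,
                                const double *rate_dbp, double e, HmmWork &w,
                                int *out) {
  forward_pass(H, K, M, skip1, skip2, obs, rate_dbp, e, w);
  int keff = K - (skip1 >= 0) - (skip2 >= 0 && skip2 != skip1);
  const double *a = w.alpha.data();
  // columns are normalised to sum 1
  const double *alast = a + (size_t)(M - 1) * K;
  double u = unif_rand(), acc = 0.0;
  int z = -1;
  for (int k = 0; k < K; ++k) {
    acc += alast[k];
    if (u <= acc) { z = k; break; }
  }
  if (z < 0) { for (z = K - 1; z == skip1 || z == skip2; --z) {} }
  out[M - 1] = H[(size_t)(M - 1) * K + z];
  for (int m = M - 2; m >= 0; --m) {
    const double *am = a + (size_t)m * K;
    const double s = w.sw[m];
    const double stay = 1.0 - s, move = s / keff;
    double p_stay = stay * am[z] / (stay * am[z] + move);
    if (unif_rand() > p_stay) {
      u = unif_rand();
      acc = 0.0;
      int nz = -1;
      for (int k = 0; k < K; ++k) {
        acc += am[k];
        if (u <= acc) { nz = k; break; }
      }
      if (nz < 0) { for (nz = K - 1; nz == skip1 || nz == skip2; --nz) {} }
      z = nz;
    }
    out[m] = H[(size_t)m * K + z];
  }
}

// [[Rcpp::export(name = ".ls_posterior_cpp")]]
NumericVector ls_posterior_cpp(IntegerMatrix H, IntegerVector obs,
                               NumericVector rate_dbp, double copy_error,
                               int skip1 = -1, int skip2 = -1) {
  if (H.nrow() < 1) stop("zero reference haplotypes");
  const int M = H.ncol();
  if (obs.size() != M) stop("obs length must match marker count");
  HmmWork w;
  w.ensure(H.nrow(), M);
  NumericVector p1(M);
  posterior_allele1(INTEGER(H), H.nrow(), M, skip1, skip2, INTEGER(obs),
                    REAL(rate_dbp), copy_error, w, REAL(p1));
  return p1;
}

// [[Rcpp::export(name = ".ls_sample_path_cpp")]]
IntegerVector ls_sample_path_cpp(IntegerMatrix H, IntegerVector obs,
                                 NumericVector rate_dbp, double copy_error,
                                 int skip1 = -1, int skip2 = -1) {
  const int M = H.ncol();
  HmmWork w;
  w.ensure(H.nrow(), M);
  IntegerVector out(M);
  sample_path_alleles(INTEGER(H), H.nrow(), M, skip1, skip2, INTEGER(obs),
                      REAL(rate_dbp), copy_error, w, INTEGER(out));
  return out;
}

// iterative conditional phasing of one chromosome.
// geno: N x M with codes 0/1/2 and -1 for missing.
// Returns 2N x M haplotypes (rows 2i-1, 2i of animal i), stored transposed
// internally (markers fastest) for cache-friendly column access.
// [[Rcpp::export(name = ".phase_chromosome_cpp")]]
IntegerMatrix phase_chromosome_cpp(IntegerMatrix geno, NumericVector rate_dbp,
                                   double copy_error, int n_iter) {
  const int N = geno.nrow(), M = geno.ncol();
  const int K = 2 * N;
  // H kept K x M column-major (haplotypes fastest within a marker column)
  std::vector<int> H((size_t)K * M);
  std::vector<double> freq(M, 0.5);
  for (int m = 0; m < M; ++m) {
    double s = 0.0;
    int n = 0;
    for (int i = 0; i < N; ++i) {
      int g = geno(i, m);
      if (g >= 0) { s += g; ++n; }
    }
    if (n > 0) freq[m] = s / (2.0 * n);
  }
  for (int m = 0; m < M; ++m) {
    int *col = H.data() + (size_t)m * K;
    for (int i = 0; i < N; ++i) {
      int g = geno(i, m);
      int a1, a2;
      if (g == 0) { a1 = 0; a2 = 0; }
      else if (g == 2) { a1 = 1; a2 = 1; }
      else if (g == 1) { a1 = unif_rand() < 0.5 ? 1 : 0; a2 = 1 - a1; }
      else {
        a1 = unif_rand() < freq[m] ? 1 : 0;
        a2 = unif_rand() < freq[m] ? 1 : 0;
      }
      col[2 * i] = a1;
      col[2 * i + 1] = a2;
    }
  }
  if (N >= 2) {
    HmmWork w;
    w.ensure(K, M);
    std::vector<int> obs(M), path(M);
    std::vector<int> order(N);
    for (int i = 0; i < N; ++i) order[i] = i;
    for (int it = 0; it < n_iter; ++it) {
      for (int i = N - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
      for (int oi = 0; oi < N; ++oi) {
        int i = order[oi];
        int r1 = 2 * i, r2 = 2 * i + 1;
        // chain for the leading haplotype: genotype-constrained emissions
        for (int m = 0; m < M; ++m) {
          int g = geno(i, m);
          obs[m] = (g == 0) ? 0 : (g == 2) ? 1 : -1;
        }
        sample_path_alleles(H.data(), K, M, r1, r2, obs.data(), REAL(rate_dbp),
                            copy_error, w, path.data());
        bool any_missing = false;
        for (int m = 0; m < M; ++m) {
          int g = geno(i, m);
          int *col = H.data() + (size_t)m * K;
          int a1 = (g == 0) ? 0 : (g == 2) ? 1 : path[m];
          col[r1] = a1;
          if (g >= 0) {
            col[r2] = g - a1;
            obs[m] = col[r2];
          } else {
            obs[m] = -1;
            any_missing = true;
          }
        }
        // complement chain fills the missing calls of the second haplotype
        if (any_missing) {
          sample_path_alleles(H.data(), K, M, r1, r2, obs.data(),
                              REAL(rate_dbp), copy_error, w, path.data());
          for (int m = 0; m < M; ++m)
            if (geno(i, m) < 0) H[(size_t)m * K + r2] = path[m];
        }
        // swap so that neither haplotype systematically leads
        if (unif_rand() < 0.5) {
          for (int m = 0; m < M; ++m) {
            int *col = H.data() + (size_t)m * K;
            std::swap(col[r1], col[r2]);
          }
        }
      }
    }
  }
  IntegerMatrix out(K, M);
  for (int m = 0; m < M; ++m) {
    const int *col = H.data() + (size_t)m * K;
    for (int k = 0; k < K; ++k) out(k, m) = col[k];
  }
  return out;
}

// phase target animals at their observed markers against a fixed reference
// panel; unobserved sites are returned as -1.
// [[Rcpp::export(name = ".phase_target_cpp")]]
IntegerMatrix phase_target_cpp(IntegerMatrix ref, IntegerMatrix geno,
                               NumericVector rate_dbp, double copy_error,
                               int n_pass) {
  const int N = geno.nrow(), M = geno.ncol();
  const int K = ref.nrow();
  if (ref.ncol() != M) stop("reference and target marker counts differ");
  IntegerMatrix H(2 * N, M);
  HmmWork w;
  w.ensure(K, M);
  std::vector<int> obs(M), path(M);
  for (int i = 0; i < N; ++i) {
    int r1 = 2 * i, r2 = 2 * i + 1;
    for (int pass = 0; pass < n_pass; ++pass) {
      if (pass == 0) {
        for (int m = 0; m < M; ++m) {
          int g = geno(i, m);
          obs[m] = (g == 0) ? 0 : (g == 2) ? 1 : -1;
        }
      } else {
        // refine: condition on the previous estimate of haplotype 1
        for (int m = 0; m < M; ++m)
          obs[m] = (geno(i, m) >= 0) ? H(r1, m) : -1;
      }
      sample_path_alleles(INTEGER(ref), K, M, -1, -1, obs.data(),
                          REAL(rate_dbp), copy_error, w, path.data());
      for (int m = 0; m < M; ++m) {
        int g = geno(i, m);
        if (g == 0) H(r1, m) = 0;
        else if (g == 2) H(r1, m) = 1;
        else if (g == 1) H(r1, m) = path[m];
        else H(r1, m) = -1;
        H(r2, m) = (g >= 0) ? g - H(r1, m) : -1;
      }
    }
  }
  return H;
}

// allele-1 posteriors for a batch of target haplotypes (rows of `haps`,
// -1 = unobserved) against a fixed reference panel.
// [[Rcpp::export(name = ".impute_posteriors_cpp")]]
NumericMatrix impute_posteriors_cpp(IntegerMatrix ref, IntegerMatrix haps,
                                    NumericVector rate_dbp, double copy_error) {
  const int n = haps.nrow(), M = haps.ncol();
  const int K = ref.nrow();
  NumericMatrix out(n, M);
  HmmWork w;
  w.ensure(K, M);
  std::vector<int> obs(M);
  std::vector<double> p1(M);
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < M; ++m) obs[m] = haps(i, m);
    posterior_allele1(INTEGER(ref), K, M, -1, -1, obs.data(), REAL(rate_dbp),
                      copy_error, w, p1.data());
    for (int m = 0; m < M; ++m) out(i, m) = p1[m];
  }
  return out;
}
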