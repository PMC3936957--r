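#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Haplotype copying (PAC) composite likelihood.
//
// Haplotype at ordering position t (0-based, t >= 1) is modelled as an
// imperfect mosaic copy of the t haplotypes before it. Writing k = t + 1,
// the copying template switches across interval j with probability
//   s_j = 1 - exp(-rho_j * d_j / k)        (d_j in kb, rho_j per kb)
// landing uniformly on one of the t templates (self included), and each
// copied site mismatches with probability mu = theta / (2 (k + theta)).
// The first haplotype contributes L * log(1/2) (uniform over alleles),
// a constant in rho.

static inline double emit(int a, int b, double mu) {
  return (a == b) ? (1.0 - mu) : mu;
}

// Forward pass for the haplotype at ordering position t. Returns its log
// conditional likelihood; if F is non-null it must have size K*L and
// receives the normalized forward vectors (column-major by site).
static double pac_forward(const IntegerMatrix& A, const IntegerVector& ord,
                          int t, const std::vector<double>& s, double mu,
                          std::vector<double>* F) {
  const int L = A.ncol();
  const int K = t;
  const int row = ord[t];
  std::vector<double> f(K);
  double loglik = 0.0, tot = 0.0;
  for (int i = 0; i < K; ++i) {
    f[i] = emit(A(ord[i], 0), A(row, 0), mu) / K;
    tot += f[i];
  }
  loglik += std::log(tot);
  for (int i = 0; i < K; ++i) f[i] /= tot;
  if (F) for (int i = 0; i < K; ++i) (*F)[i] = f[i];
  for (int j = 0; j + 1 < L; ++j) {
    const double stay = 1.0 - s[j];
    const double jump = s[j] / K; // sum(f) == 1 after normalization
    tot = 0.0;
    for (int i = 0; i < K; ++i) {
      double g = stay * f[i] + jump;
      f[i] = g * emit(A(ord[i], j + 1), A(row, j + 1), mu);
      tot += f[i];
    }
    loglik += std::log(tot);
    for (int i = 0; i < K; ++i) f[i] /= tot;
    if (F) for (int i = 0; i < K; ++i) (*F)[(size_t)(j + 1) * K + i] = f[i];
  }
  return loglik;
}

static void switch_probs(const NumericVector& d_kb, const NumericVector& rho,
                         int k, std::vector<double>* s) {
  const int M = d_kb.size();
  s->resize(M);
  for (int j = 0; j < M; ++j)
    (*s)[j] = 1.0 - std::exp(-rho[j] * d_kb[j] / k);
}

// [[Rcpp::export]]
double pac_loglik_cpp(IntegerMatrix A, NumericVector d_kb, NumericVector rho,
                      IntegerVector ord, double theta) {
  const int n = A.nrow(), L = A.ncol();
  if (ord.size() != n) stop("ordering length must equal the number of haplotypes");
  if (d_kb.size() != L - 1 || rho.size() != L - 1)
    stop("interval vectors must have length L - 1");
  double loglik = L * std::log(0.5);
  std::vector<double> s;
  for (int t = 1; t < n; ++t) {
    const int k = t + 1;
    const double mu = theta / (2.0 * (k + theta));
    switch_probs(d_kb, rho, k, &s);
    loglik += pac_forward(A, ord, t, s, mu, nullptr);
  }
  return loglik;
}

// Forward-backward decomposition used by the per-interval grid updates.
// For ordering position t and interval j the log-likelihood of haplotype t
// as a function of that interval's switch probability s is
//   const + log((1 - s) * U_tj + (s / K) * V_tj)
// with U_tj = sum_i f_j(i) q_j(i), V_tj = sum_i q_j(i),
// q_j(i) = e_{j+1}(i) * beta_{j+1}(i) (normalized backward vector).
static void pac_uv(const IntegerMatrix& A, const IntegerVector& ord, int t,
                   const std::vector<double>& s, double mu,
                   double* U, double* V, int stride) {
  const int L = A.ncol();
  const int K = t;
  const int row = ord[t];
  std::vector<double> F((size_t)K * L);
  pac_forward(A, ord, t, s, mu, &F);
  std::vector<double> b(K, 1.0 / K), q(K);
  for (int j = L - 2; j >= 0; --j) {
    double u = 0.0, v = 0.0;
    for (int i = 0; i < K; ++i) {
      q[i] = emit(A(ord[i], j + 1), A(row, j + 1), mu) * b[i];
      v += q[i];
      u += F[(size_t)j * K + i] * q[i];
    }
    U[(size_t)j * stride] = u;
    V[(size_t)j * stride] = v;
    const double stay = 1.0 - s[j];
    const double jump = s[j] / K;
    double tot = 0.0;
    for (int i = 0; i < K; ++i) {
      b[i] = stay * q[i] + jump * v;
      tot += b[i];
    }
    for (int i = 0; i < K; ++i) b[i] /= tot;
  }
}

// Exposed for testing the decomposition against pac_loglik_cpp.
// Returns U and V as (L-1) x (n-1) matrices for a single ordering.
// [[Rcpp::export]]
List pac_uv_cpp(IntegerMatrix A, NumericVector d_kb, NumericVector rho,
                IntegerVector ord, double theta) {
  const int n = A.nrow(), L = A.ncol();
  NumericMatrix U(L - 1, n - 1), V(L - 1, n - 1);
  std::vector<double> s;
  for (int t = 1; t < n; ++t) {
    const int k = t + 1;
    const double mu = theta / (2.0 * (k + theta));
    switch_probs(d_kb, rho, k, &s);
    pac_uv(A, ord, t, s, mu, &U(0, t - 1), &V(0, t - 1), 1);
  }
  return List::create(_["U"] = U, _["V"] = V);
}

// Penalized grid coordinate ascent for the per-interval recombination rates.
// Objective: mean over orderings of the PAC log-likelihood minus
// lambda * sum_j (log rho_{j+1} - log rho_j)^2. Each sweep refreshes the
// forward-backward decomposition at the current rates, then updates every
// interval on the grid (penalty uses the freshest neighbour values).
// Deterministic given the orderings.
// [[Rcpp::export]]
List estimate_profile_cpp(IntegerMatrix A, NumericVector d_kb,
                          NumericVector grid, double lambda,
                          IntegerMatrix orderings, double theta,
                          int max_sweeps, double tol) {
  const int n = A.nrow(), L = A.ncol(), M = L - 1;
  const int n_ord = orderings.nrow();
  const int G = grid.size();
  if (orderings.ncol() != n) stop("orderings must have one column per haplotype");
  std::vector<double> log_grid(G);
  for (int g = 0; g < G; ++g) log_grid[g] = std::log(grid[g]);

  NumericVector rho(M);
  // initialize at the best constant-rate fit (penalty-free for any
  // constant profile), searched on a thinned grid — the per-interval
  // sweeps refine it; ties resolve to the smallest rate
  int best_g0 = 0;
  double best_ll0 = -INFINITY;
  const int step = (G > 9) ? (G - 1) / 8 : 1;
  for (int g = 0; g < G; g += step) {
    for (int j = 0; j < M; ++j) rho[j] = grid[g];
    double ll = 0.0;
    for (int o = 0; o < n_ord; ++o) {
      IntegerVector ord = orderings(o, _);
      ll += pac_loglik_cpp(A, d_kb, rho, ord, theta);
    }
    if (ll > best_ll0 + 1e-9) { best_ll0 = ll; best_g0 = g; }
  }
  std::vector<double> lr(M, log_grid[best_g0]);
  for (int j = 0; j < M; ++j) rho[j] = std::exp(lr[j]);

  const int nk = n - 1; // modelled haplotypes per ordering
  std::vector<double> U((size_t)M * n_ord * nk), V((size_t)M * n_ord * nk);
  std::vector<double> s;
  std::vector<double> mean_ll_terms;

  auto objective = [&](const NumericVector& r) {
    double ll = 0.0;
    for (int o = 0; o < n_ord; ++o) {
      IntegerVector ord = orderings(o, _);
      ll += pac_loglik_cpp(A, d_kb, r, ord, theta);
    }
    ll /= n_ord;
    double pen = 0.0;
    for (int j = 0; j + 1 < M; ++j) {
      double dl = std::log(r[j + 1]) - std::log(r[j]);
      pen += dl * dl;
    }
    return ll - lambda * pen;
  };

  double obj = objective(rho);
  int sweeps = 0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    ++sweeps;
    // refresh decomposition at current rates
    for (int o = 0; o < n_ord; ++o) {
      IntegerVector ord = orderings(o, _);
      for (int t = 1; t < n; ++t) {
        const int k = t + 1;
        const double mu = theta / (2.0 * (k + theta));
        switch_probs(d_kb, rho, k, &s);
        size_t idx = (size_t)(o * nk + (t - 1));
        // layout: U[j * (n_ord*nk) + idx]
        pac_uv(A, ord, t, s, mu, &U[idx], &V[idx], n_ord * nk);
      }
    }
    bool changed = false;
    for (int j = 0; j < M; ++j) {
      double best = -INFINITY;
      int best_g = -1;
      for (int g = 0; g < G; ++g) {
        double ll = 0.0;
        for (int o = 0; o < n_ord; ++o) {
          for (int t = 1; t < n; ++t) {
            const int k = t + 1;
            const int K = t;
            const double sg = 1.0 - std::exp(-grid[g] * d_kb[j] / k);
            size_t idx = (size_t)j * n_ord * nk + (size_t)(o * nk + (t - 1));
            ll += std::log((1.0 - sg) * U[idx] + (sg / K) * V[idx]);
          }
        }
        ll /= n_ord;
        double pen = 0.0;
        if (j > 0) { double dl = log_grid[g] - lr[j - 1]; pen += dl * dl; }
        if (j + 1 < M) { double dl = lr[j + 1] - log_grid[g]; pen += dl * dl; }
        double o2 = ll - lambda * pen;
        if (best_g < 0 || o2 > best + 1e-12) { best = o2; best_g = g; }
      }
      if (std::abs(log_grid[best_g] - lr[j]) > 1e-15) changed = true;
      lr[j] = log_grid[best_g];
      rho[j] = grid[best_g];
    }
    double new_obj = objective(rho);
    bool small = std::abs(new_obj - obj) < tol;
    obj = new_obj;
    if (!changed || small) break;
  }
  return List::create(_["rho"] = rho, _["objective"] = obj,
                      _["sweeps"] = sweeps);
}
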