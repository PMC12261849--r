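#include <Rcpp.h>
#include <random>
#include <map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Dense representation of a triangular QUBO: h holds the diagonal, J the
// symmetrised couplings (each off-diagonal coefficient stored once on each
// side so that local fields are a single row scan).
static void build_dense(int n, const IntegerVector &ti, const IntegerVector &tj,
                        const NumericVector &tv, std::vector<double> &h,
                        std::vector<double> &J) {
  h.assign(n, 0.0);
  J.assign((size_t)n * n, 0.0);
  for (R_xlen_t k = 0; k < ti.size(); ++k) {
    int i = ti[k] - 1, j = tj[k] - 1;
    if (i == j) {
      h[i] += tv[k];
    } else {
      J[(size_t)i * n + j] += tv[k];
      J[(size_t)j * n + i] += tv[k];
    }
  }
}

static double full_energy(int n, const std::vector<double> &h,
                          const std::vector<double> &J, double offset,
                          const std::vector<uint8_t> &x) {
  double e = offset;
  for (int i = 0; i < n; ++i) {
    if (!x[i]) continue;
    e += h[i];
    const double *row = &J[(size_t)i * n];
    for (int j = i + 1; j < n; ++j)
      if (x[j]) e += row[j];
  }
  return e;
}

// TRUE if a is lexicographically smaller than b (component order x1, x2, ...).
static bool lex_less(const std::vector<uint8_t> &a, const std::vector<uint8_t> &b) {
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) return a[i] < b[i];
  return false;
}

// Exhaustive minimisation by Gray-code enumeration; ties broken by the
// lexicographically smallest bit vector. n is capped by the caller.
// [[Rcpp::export]]
List bf_minimize_cpp(int n, IntegerVector ti, IntegerVector tj,
                     NumericVector tv, double offset) {
  std::vector<double> h, J;
  build_dense(n, ti, tj, tv, h, J);
  std::vector<uint8_t> x(n, 0), best(n, 0);
  double E = offset, bestE = offset;
  const double tol = 1e-9;
  uint64_t total = 1ULL << n;
  for (uint64_t s = 1; s < total; ++s) {
#if defined(__GNUC__) || defined(__clang__)
    int b = __builtin_ctzll(s);
#else
    int b = 0; while (!((s >> b) & 1ULL)) ++b;
#endif
    double f = h[b];
    const double *row = &J[(size_t)b * n];
    for (int j = 0; j < n; ++j)
      if (x[j]) f += row[j];
    double delta = (1 - 2 * (int)x[b]) * f;
    x[b] ^= 1;
    E += delta;
    if (E < bestE - tol) {
      bestE = E;
      best = x;
    } else if (std::fabs(E - bestE) <= tol && lex_less(x, best)) {
      bestE = E;
      best = x;
    }
  }
  // recompute exactly to remove accumulated drift
  bestE = full_energy(n, h, J, offset, best);
  return List::create(_["bits"] = IntegerVector(best.begin(), best.end()),
                      _["energy"] = bestE);
}

// Energies of all 2^n states, indexed by the state integer
// s = sum_i x_i * 2^(i-1) (variable 1 is the least-significant bit).
// [[Rcpp::export]]
NumericVector bf_energies_cpp(int n, IntegerVector ti, IntegerVector tj,
                              NumericVector tv, double offset) {
  std::vector<double> h, J;
  build_dense(n, ti, tj, tv, h, J);
  uint64_t total = 1ULL << n;
  NumericVector out((R_xlen_t)total);
  std::vector<uint8_t> x(n, 0);
  double E = offset;
  uint64_t idx = 0;
  out[0] = offset;
  for (uint64_t s = 1; s < total; ++s) {
#if defined(__GNUC__) || defined(__clang__)
    int b = __builtin_ctzll(s);
#else
    int b = 0; while (!((s >> b) & 1ULL)) ++b;
#endif
    double f = h[b];
    const double *row = &J[(size_t)b * n];
    for (int j = 0; j < n; ++j)
      if (x[j]) f += row[j];
    E += (1 - 2 * (int)x[b]) * f;
    x[b] ^= 1;
    idx ^= (1ULL << b);
    out[(R_xlen_t)idx] = E;
  }
  return out;
}

struct PoolEntry {
  std::vector<uint8_t> bits;
  double energy;
};

// Single-bit-flip Metropolis annealer with a geometric inverse-temperature
// schedule. Keeps a capped pool of distinct low-energy states; energies in
// the pool are recomputed exactly so reported energies never drift.
// [[Rcpp::export]]
List anneal_cpp(int n, IntegerVector ti, IntegerVector tj, NumericVector tv,
                double offset, int sweeps, int restarts, double seed,
                int top_m, double beta_min, double beta_max,
                int restart_offset) {
  std::vector<double> h, J;
  build_dense(n, ti, tj, tv, h, J);
  size_t cap = (size_t)std::max(top_m * 4, 16);
  std::map<std::vector<uint8_t>, double> pool;
  double pool_worst = R_PosInf;

  auto pool_insert = [&](const std::vector<uint8_t> &x) {
    if (pool.size() >= cap && pool.count(x) == 0) {
      // quick reject against the current worst before the exact energy
      double e = full_energy(n, h, J, offset, x);
      if (e >= pool_worst) return;
      pool[x] = e;
      // evict the worst entry
      auto worst = pool.begin();
      for (auto it = pool.begin(); it != pool.end(); ++it)
        if (it->second > worst->second) worst = it;
      pool.erase(worst);
      pool_worst = -R_PosInf;
      for (auto &kv : pool) pool_worst = std::max(pool_worst, kv.second);
    } else if (pool.count(x) == 0) {
      double e = full_energy(n, h, J, offset, x);
      pool[x] = e;
      if (pool.size() == cap) {
        pool_worst = -R_PosInf;
        for (auto &kv : pool) pool_worst = std::max(pool_worst, kv.second);
      }
    }
  };

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double ratio = (sweeps > 1) ? std::pow(beta_max / beta_min,
                                         1.0 / (double)(sweeps - 1))
                              : 1.0;
  for (int r = 0; r < restarts; ++r) {
    uint64_t sd = (uint64_t)seed * 0x9E3779B97F4A7C15ULL +
                  (uint64_t)(r + restart_offset);
    std::mt19937_64 rng(sd);
    std::vector<uint8_t> x(n);
    for (int i = 0; i < n; ++i) x[i] = (uint8_t)(rng() & 1ULL);
    double E = full_energy(n, h, J, offset, x);
    pool_insert(x);
    double beta = beta_min;
    for (int s = 0; s < sweeps; ++s) {
      for (int b = 0; b < n; ++b) {
        double f = h[b];
        const double *row = &J[(size_t)b * n];
        for (int j = 0; j < n; ++j)
          if (x[j]) f += row[j];
        if (x[b]) f -= 0.0; // diag already in h; row[b] is 0
        double delta = (1 - 2 * (int)x[b]) * f;
        if (delta <= 0.0 || unif(rng) < std::exp(-beta * delta)) {
          x[b] ^= 1;
          E += delta;
          if (delta < 0.0 && (pool.size() < cap || E < pool_worst))
            pool_insert(x);
        }
      }
      beta *= ratio;
    }
    pool_insert(x);
  }

  std::vector<PoolEntry> entries;
  entries.reserve(pool.size());
  for (auto &kv : pool) entries.push_back(PoolEntry{kv.first, kv.second});
  std::sort(entries.begin(), entries.end(),
            [](const PoolEntry &a, const PoolEntry &b) {
              if (a.energy != b.energy) return a.energy < b.energy;
              return lex_less(a.bits, b.bits);
            });
  int m = std::min((int)entries.size(), top_m);
  List out(m);
  for (int k = 0; k < m; ++k) {
    out[k] = List::create(
        _["bits"] = IntegerVector(entries[k].bits.begin(), entries[k].bits.end()),
        _["energy"] = entries[k].energy);
  }
  return out;
}
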