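#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

// Self-contained deterministic PRNG (splitmix64 seeding xoshiro256**),
// so sampler output is bitwise reproducible per seed across platforms
// and independent of R's global RNG state.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double uniform() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

// Single-spin-flip Metropolis simulated annealing on a QUBO
// E(x) = sum_i linear_i x_i + sum_{i<j} v_ij x_i x_j  (offset added in R).
// Each read is an independent restart over a geometric inverse-temperature
// ladder from beta0 to beta1, followed by zero-temperature (greedy) sweeps
// until no single flip improves the energy.
// [[Rcpp::export(name = ".sa_sample_cpp")]]
Rcpp::List sa_sample_cpp(Rcpp::NumericVector linear,
                         Rcpp::IntegerVector coupler_i,
                         Rcpp::IntegerVector coupler_j,
                         Rcpp::NumericVector coupler_v,
                         int reads, int sweeps,
                         double beta0, double beta1,
                         double seed_in, int max_greedy_passes = 100) {
  const int n = linear.size();
  const int nnz = coupler_i.size();

  // symmetric adjacency in CSR form
  std::vector<int> deg(n, 0);
  for (int k = 0; k < nnz; ++k) {
    ++deg[coupler_i[k] - 1];
    ++deg[coupler_j[k] - 1];
  }
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> adj_idx(start[n]);
  std::vector<double> adj_val(start[n]);
  {
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int k = 0; k < nnz; ++k) {
      const int a = coupler_i[k] - 1, b = coupler_j[k] - 1;
      const double v = coupler_v[k];
      adj_idx[fill[a]] = b; adj_val[fill[a]++] = v;
      adj_idx[fill[b]] = a; adj_val[fill[b]++] = v;
    }
  }

  std::vector<double> betas(sweeps);
  if (sweeps == 1) {
    betas[0] = beta1;
  } else {
    const double ratio = std::pow(beta1 / beta0, 1.0 / (sweeps - 1));
    double b = beta0;
    for (int s = 0; s < sweeps; ++s) { betas[s] = b; b *= ratio; }
  }

  Rcpp::IntegerMatrix states(reads, n);
  Rcpp::NumericVector energies(reads);
  const uint64_t base_seed = static_cast<uint64_t>(seed_in);

  std::vector<int> x(n);
  std::vector<double> field(n);  // field_i = linear_i + sum_j v_ij x_j

  for (int r = 0; r < reads; ++r) {
    uint64_t rs = base_seed;
    uint64_t mix = splitmix64(rs) ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(r + 1));
    Xoshiro256 rng(mix);

    for (int i = 0; i < n; ++i) x[i] = (rng.next() & 1ULL) ? 1 : 0;
    for (int i = 0; i < n; ++i) {
      double f = linear[i];
      for (int k = start[i]; k < start[i + 1]; ++k)
        f += adj_val[k] * x[adj_idx[k]];
      field[i] = f;
    }

    auto try_flip = [&](int i, double beta, bool greedy) -> bool {
      const double dE = (1 - 2 * x[i]) * field[i];
      bool accept;
      if (greedy) {
        accept = dE < -1e-12;
      } else {
        accept = (dE <= 0.0) || (rng.uniform() < std::exp(-beta * dE));
      }
      if (accept) {
        const int delta = 1 - 2 * x[i];
        x[i] = 1 - x[i];
        for (int k = start[i]; k < start[i + 1]; ++k)
          field[adj_idx[k]] += delta * adj_val[k];
      }
      return accept;
    };

    for (int s = 0; s < sweeps; ++s) {
      const double beta = betas[s];
      for (int i = 0; i < n; ++i) try_flip(i, beta, false);
    }
    for (int pass = 0; pass < max_greedy_passes; ++pass) {
      bool improved = false;
      for (int i = 0; i < n; ++i)
        if (try_flip(i, 0.0, true)) improved = true;
      if (!improved) break;
    }

    double e = 0.0;
    for (int i = 0; i < n; ++i) if (x[i]) e += linear[i];
    for (int k = 0; k < nnz; ++k)
      if (x[coupler_i[k] - 1] && x[coupler_j[k] - 1]) e += coupler_v[k];
    energies[r] = e;
    for (int i = 0; i < n; ++i) states(r, i) = x[i];
  }

  return Rcpp::List::create(Rcpp::Named("states") = states,
                            Rcpp::Named("energies") = energies);
}
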