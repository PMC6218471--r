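#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Integer power by squaring; Hill coefficients are small integers, so this
// avoids the cost of pow() in the inner loop.
static inline double ipow(double base, int e) {
  double r = 1.0;
  while (e > 0) {
    if (e & 1) r *= base;
    base *= base;
    e >>= 1;
  }
  return r;
}

// Euler-Maruyama integration of an ensemble of shifted-Hill circuit models.
//
// state0: n_inst x n_genes matrix of initial conditions (one row per
//   simulated instance). Parameter matrices (Gm, Km: n_models x n_genes;
//   X0m, Nm, Lm: n_models x n_edges) are indexed through midx (1-based map
//   from instance to parameter row), so several instances can share one
//   model without copying parameters.
// src, tgt: 1-based gene indices of each edge. D: per-instance noise
//   amplitude; the per-step noise term is D*sqrt(dt)*eta (additive) or
//   D*sqrt(dt)*x*eta (multiplicative, noise_mult != 0). States are clamped
//   at zero after every step.
// rec_steps: strictly increasing 1-based step indices at which the state of
//   every instance is recorded. Returns a list of n_inst x n_genes matrices,
//   one per recorded step.
//
// Uses R's RNG (norm_rand), so runs are reproducible under set.seed(). With
// D = 0 no random numbers are drawn and the scheme is exactly forward Euler.
// [[Rcpp::export]]
List sim_ensemble_cpp(NumericMatrix state0,
                      NumericMatrix Gm, NumericMatrix Km,
                      NumericMatrix X0m, IntegerMatrix Nm, NumericMatrix Lm,
                      IntegerVector src, IntegerVector tgt,
                      IntegerVector midx,
                      double dt, int nsteps, NumericVector D,
                      IntegerVector rec_steps, int noise_mult) {
  const int ninst = state0.nrow();
  const int ng = state0.ncol();
  const int ne = src.size();
  const int nrec = rec_steps.size();

  std::vector<double> x(state0.begin(), state0.end());  // column-major
  std::vector<double> amp(ninst);
  std::vector<bool> noisy(ninst);
  for (int i = 0; i < ninst; ++i) {
    amp[i] = D[i] * std::sqrt(dt);
    noisy[i] = D[i] > 0.0;
  }

  List out(nrec);
  std::vector<double> prod(ng);
  int next_rec = 0;

  for (int s = 1; s <= nsteps; ++s) {
    for (int i = 0; i < ninst; ++i) {
      const int m = midx[i] - 1;
      for (int g = 0; g < ng; ++g) prod[g] = 1.0;
      for (int e = 0; e < ne; ++e) {
        const double xv = x[i + (size_t)ninst * (src[e] - 1)];
        const double lam = Lm(m, e);
        const double h =
            lam + (1.0 - lam) / (1.0 + ipow(xv / X0m(m, e), Nm(m, e)));
        prod[tgt[e] - 1] *= h;
      }
      for (int g = 0; g < ng; ++g) {
        const size_t idx = i + (size_t)ninst * g;
        const double xg = x[idx];
        double xn = xg + (Gm(m, g) * prod[g] - Km(m, g) * xg) * dt;
        if (noisy[i]) {
          const double eta = norm_rand();
          xn += noise_mult ? amp[i] * xg * eta : amp[i] * eta;
        }
        if (xn < 0.0) xn = 0.0;
        x[idx] = xn;
      }
    }
    if (next_rec < nrec && s == rec_steps[next_rec]) {
      NumericMatrix snap(ninst, ng);
      std::copy(x.begin(), x.end(), snap.begin());
      out[next_rec] = snap;
      ++next_rec;
    }
  }
  return out;
}

// Greedy clustering of putative fixed points into distinct steady states.
//
// pts: rows are terminal states, grouped contiguously by model;
// group: 1-based model id per row (rows with the same id must be adjacent).
// Two points belong to the same state when every coordinate agrees within
// relative tolerance tol (denominator floored at `floorv` so that
// biologically indistinguishable near-zero levels merge).
// Returns, per row, the 1-based state index within its model's group.
// [[Rcpp::export]]
IntegerVector cluster_fixed_points_cpp(NumericMatrix pts, IntegerVector group,
                                       double tol, double floorv) {
  const int n = pts.nrow(), d = pts.ncol();
  IntegerVector assign(n);
  std::vector<int> reps;  // row indices of cluster representatives
  reps.reserve(16);

  int i = 0;
  while (i < n) {
    const int g = group[i];
    reps.clear();
    for (; i < n && group[i] == g; ++i) {
      int found = 0;
      for (size_t r = 0; r < reps.size() && !found; ++r) {
        bool same = true;
        for (int c = 0; c < d; ++c) {
          const double a = pts(i, c), b = pts(reps[r], c);
          double den = std::max(std::abs(a), std::abs(b));
          if (den < floorv) den = floorv;
          if (std::abs(a - b) / den > tol) { same = false; break; }
        }
        if (same) { assign[i] = (int)r + 1; found = 1; }
      }
      if (!found) {
        reps.push_back(i);
        assign[i] = (int)reps.size();
      }
    }
  }
  return assign;
}
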