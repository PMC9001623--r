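// 1D Metropolis Monte Carlo of hard-core particles with a cut-and-shifted
// generalized Lennard-Jones pair potential, plus pair-distance binning.
// Positions are kept sorted so energy evaluations touch only the O(1)
// neighbors inside the interaction cutoff (1D cell-list equivalent).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct GLJ {
  bool active;          // false => hard core only (or free particles)
  double eps, sigma, del, nu, rcut, vshift;

  double energy(double r) const {
    if (!active || r >= rcut) return 0.0;
    const double s = sigma / r;
    return 4.0 * eps * (std::pow(s, del) - std::pow(s, nu)) - vshift;
  }
};

GLJ make_glj(bool active, double eps, double sigma, double del, double nu,
             double rcut) {
  GLJ p;
  p.active = active;
  p.eps = eps;
  p.sigma = sigma;
  p.del = del;
  p.nu = nu;
  p.rcut = rcut;
  p.vshift = 0.0;
  if (active && std::isfinite(rcut)) {
    const double s = sigma / rcut;
    p.vshift = 4.0 * eps * (std::pow(s, del) - std::pow(s, nu));
  }
  return p;
}

inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0;  // guard against floating rounding at the boundary
  return x;
}

// Sum of pair energies between a virtual particle at xi and all particles in
// the sorted vector x, skipping index `skip`. Periodic scans use raw forward /
// backward gaps, valid because rcut <= L/2 is enforced by the caller.
double local_energy(const std::vector<double>& x, int skip, double xi,
                    const GLJ& pot, double L, bool periodic) {
  const int n = static_cast<int>(x.size());
  if (!pot.active || n == 0) return 0.0;
  double e = 0.0;
  // insertion point of xi
  int i0 = static_cast<int>(
      std::upper_bound(x.begin(), x.end(), xi) - x.begin());
  if (periodic) {
    // rightwards
    int cnt = 0;
    for (int j = i0; cnt < n; ++j, ++cnt) {
      int jj = j % n;
      if (jj == skip) continue;
      double d = x[jj] - xi;
      if (d < 0) d += L;
      if (d > pot.rcut) break;
      e += pot.energy(d);
    }
    // leftwards
    cnt = 0;
    for (int j = i0 - 1; cnt < n; --j, ++cnt) {
      int jj = ((j % n) + n) % n;
      if (jj == skip) continue;
      double d = xi - x[jj];
      if (d < 0) d += L;
      if (d >= pot.rcut) break;  // strict on one side avoids double count at L/2
      e += pot.energy(d);
    }
  } else {
    for (int j = i0; j < n; ++j) {
      if (j == skip) continue;
      double d = x[j] - xi;
      if (d > pot.rcut) break;
      e += pot.energy(d);
    }
    for (int j = i0 - 1; j >= 0; --j) {
      if (j == skip) continue;
      double d = xi - x[j];
      if (d > pot.rcut) break;
      e += pot.energy(d);
    }
  }
  return e;
}

double total_energy(const std::vector<double>& x, const GLJ& pot, double L,
                    bool periodic) {
  const int n = static_cast<int>(x.size());
  double e = 0.0;
  if (!pot.active) return 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = x[j] - x[i];
      if (periodic && d > L / 2.0) d = L - d;
      if (d < pot.rcut) e += pot.energy(d);
    }
  }
  return e;
}

// Hard-core clearance of a virtual particle at xi against all others.
bool core_ok(const std::vector<double>& x, int skip, double xi, double core,
             double L, bool periodic) {
  if (core <= 0) return true;
  const int n = static_cast<int>(x.size());
  int i0 = static_cast<int>(
      std::upper_bound(x.begin(), x.end(), xi) - x.begin());
  // nearest neighbor to the right and to the left (with wrap if periodic)
  double dr = R_PosInf, dl = R_PosInf;
  for (int j = i0; j < i0 + n; ++j) {
    int jj = j % n;
    if (jj == skip) continue;
    double d = x[jj] - xi;
    if (d < 0) {
      if (!periodic) break;
      d += L;
    }
    dr = d;
    break;
  }
  for (int j = i0 - 1; j > i0 - 1 - n; --j) {
    int jj = ((j % n) + n) % n;
    if (jj == skip) continue;
    double d = xi - x[jj];
    if (d < 0) {
      if (!periodic) break;
      d += L;
    }
    dl = d;
    break;
  }
  return dr >= core && dl >= core;
}

}  // namespace

// Core Metropolis run. One sweep = one proposed move per particle, particles
// visited in index order. Returns sampled conformations (sorted positions),
// acceptance fraction, and both incremental and recomputed final energies
// for bookkeeping checks.
// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(NumericVector init, double L, double core, bool has_potential,
                double eps, double sigma, double del, double nu, double rcut,
                double lambda, int n_sweeps, int burn_in, int sample_every,
                bool periodic, double seed) {
  std::vector<double> x(init.begin(), init.end());
  std::sort(x.begin(), x.end());
  const int n = static_cast<int>(x.size());
  if (periodic && rcut > L / 2.0) rcut = L / 2.0;
  const GLJ pot = make_glj(has_potential, eps, sigma, del, nu, rcut);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif01(0.0, 1.0);

  double energy = total_energy(x, pot, L, periodic);
  long long n_acc = 0, n_att = 0;

  std::vector<std::vector<double>> samples;
  std::vector<int> sample_sweeps;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      ++n_att;
      const double u = (2.0 * unif01(rng) - 1.0) * lambda;
      double xn = x[i] + u;
      if (periodic) {
        xn = wrap(xn, L);
      } else if (xn < 0.0 || xn >= L) {
        continue;  // reject: outside walls
      }
      if (!core_ok(x, i, xn, core, L, periodic)) continue;
      const double e_old = local_energy(x, i, x[i], pot, L, periodic);
      const double e_new = local_energy(x, i, xn, pot, L, periodic);
      const double dE = e_new - e_old;
      if (dE <= 0.0 || unif01(rng) < std::exp(-dE)) {
        ++n_acc;
        energy += dE;
        // reinsert xn keeping x sorted
        x.erase(x.begin() + i);
        auto it = std::upper_bound(x.begin(), x.end(), xn);
        x.insert(it, xn);
      }
    }
    if (sweep > burn_in && sample_every > 0 &&
        (sweep - burn_in) % sample_every == 0) {
      samples.push_back(x);
      sample_sweeps.push_back(sweep);
    }
  }

  NumericMatrix smat(static_cast<int>(samples.size()), n);
  for (size_t r = 0; r < samples.size(); ++r)
    for (int c = 0; c < n; ++c) smat(static_cast<int>(r), c) = samples[r][c];

  return List::create(
      _["samples"] = smat, _["sample_sweeps"] = wrap(sample_sweeps),
      _["acceptance"] = n_att > 0 ? double(n_acc) / double(n_att) : NA_REAL,
      _["energy_incremental"] = energy,
      _["energy_recomputed"] = total_energy(x, pot, L, periodic),
      _["final_positions"] = wrap(x));
}

// Pair-distance histogram over one or many conformations (rows). Counts are
// ordered pairs (each unordered pair contributes 2), summed over rows.
// Bin k covers [k*bin_width, (k+1)*bin_width); distances > r_max dropped.
// [[Rcpp::export(name = ".pair_counts_cpp")]]
NumericVector pair_counts_cpp(NumericMatrix positions, double L,
                              double bin_width, double r_max, bool periodic) {
  const int nbin = static_cast<int>(std::ceil(r_max / bin_width));
  NumericVector counts(nbin);
  const int nr = positions.nrow(), n = positions.ncol();
  std::vector<double> x(n);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < n; ++c) x[c] = positions(r, c);
    std::sort(x.begin(), x.end());
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double d = x[j] - x[i];
        if (periodic && d > L / 2.0) d = L - d;
        if (d > r_max) {
          if (!periodic) break;  // sorted: later j only larger
          continue;
        }
        int k = static_cast<int>(d / bin_width);
        if (k >= nbin) k = nbin - 1;  // d == r_max boundary
        counts[k] += 2.0;
      }
    }
  }
  return counts;
}
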