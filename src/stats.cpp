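// Pairwise statistics for point patterns and velocity fields: ring-binned
// density pair correlation, binned directional correlations, local velocity
// fluctuations, susceptibility, and nearest-neighbor distances.  These are
// plain O(N^2) double loops in C++; test oracles re-implement them in R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double pair_dist(const NumericMatrix& p, int i, int j, double L,
                               bool periodic) {
  double dx = p(i, 0) - p(j, 0);
  double dy = p(i, 1) - p(j, 1);
  if (periodic) {
    if (dx > 0.5 * L) dx -= L; else if (dx < -0.5 * L) dx += L;
    if (dy > 0.5 * L) dy -= L; else if (dy < -0.5 * L) dy += L;
  }
  return std::sqrt(dx * dx + dy * dy);
}

// ordered-pair counts in rings [k*a - a/2, k*a + a/2), k = 1..nbin
// [[Rcpp::export]]
NumericVector cpp_ring_counts(NumericMatrix pos, double a, int nbin, double L,
                              bool periodic) {
  int n = pos.nrow();
  NumericVector counts(nbin);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = pair_dist(pos, i, j, L, periodic);
      int k = (int)std::floor(d / a + 0.5);  // ring index: nearest multiple of a
      if (k >= 1 && k <= nbin) counts[k - 1] += 2.0;  // ordered pairs
    }
  }
  return counts;
}

// binned sums of u_i . u_j over ordered pairs, bins [k*a, (k+1)*a), k=0..nbin-1
// [[Rcpp::export]]
List cpp_binned_dot(NumericMatrix pos, NumericMatrix u, double a, int nbin,
                    double L, bool periodic) {
  int n = pos.nrow();
  NumericVector sums(nbin), counts(nbin);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = pair_dist(pos, i, j, L, periodic);
      int k = (int)std::floor(d / a);
      if (k >= 0 && k < nbin) {
        double dot = u(i, 0) * u(j, 0) + u(i, 1) * u(j, 1);
        sums[k] += 2.0 * dot;
        counts[k] += 2.0;
      }
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}

// Local velocity fluctuations: for each focal cell, the neighborhood is all
// cells within r_c (focal included); delta_v = v - neighborhood mean;
// delta_u = delta_v / rms of the neighborhood's own fluctuations.
// Cells with no neighbor within r_c are unusable.
// [[Rcpp::export]]
List cpp_fluctuations(NumericMatrix pos, NumericMatrix vel, double r_c,
                      double L, bool periodic) {
  int n = pos.nrow();
  NumericMatrix du(n, 2);
  LogicalVector usable(n);
  IntegerVector nneigh(n);
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) {
    idx.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (pair_dist(pos, i, j, L, periodic) <= r_c) idx.push_back(j);
    }
    nneigh[i] = (int)idx.size();
    if ((int)idx.size() < 1) {
      usable[i] = false;
      du(i, 0) = 0.0; du(i, 1) = 0.0;
      continue;
    }
    double mx = vel(i, 0), my = vel(i, 1);
    for (int j : idx) { mx += vel(j, 0); my += vel(j, 1); }
    int m = (int)idx.size() + 1;
    mx /= m; my /= m;
    double ss = (vel(i, 0) - mx) * (vel(i, 0) - mx) +
                (vel(i, 1) - my) * (vel(i, 1) - my);
    for (int j : idx) {
      ss += (vel(j, 0) - mx) * (vel(j, 0) - mx) +
            (vel(j, 1) - my) * (vel(j, 1) - my);
    }
    double rms = std::sqrt(ss / m);
    usable[i] = true;
    if (rms > 0) {
      du(i, 0) = (vel(i, 0) - mx) / rms;
      du(i, 1) = (vel(i, 1) - my) / rms;
    } else {
      du(i, 0) = 0.0; du(i, 1) = 0.0;  // all-equal neighborhood: zero fluctuation
    }
  }
  return List::create(_["delta_u"] = du, _["usable"] = usable,
                      _["n_neighbors"] = nneigh);
}

// Connected correlation: Eq-1 form on delta_u, ordered pairs restricted to
// each focal cell's neighborhood (r_ij <= r_c), both members usable.
// [[Rcpp::export]]
List cpp_connected_binned(NumericMatrix pos, NumericMatrix du,
                          LogicalVector usable, double r_c, double a, int nbin,
                          double L, bool periodic) {
  int n = pos.nrow();
  NumericVector sums(nbin), counts(nbin);
  for (int i = 0; i < n; ++i) {
    if (!usable[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (!usable[j]) continue;
      double d = pair_dist(pos, i, j, L, periodic);
      if (d > r_c) continue;
      int k = (int)std::floor(d / a);
      if (k >= 0 && k < nbin) {
        double dot = du(i, 0) * du(j, 0) + du(i, 1) * du(j, 1);
        sums[k] += 2.0 * dot;
        counts[k] += 2.0;
      }
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}

// chi = (1/N) sum_{i != j} du_i . du_j theta(xi0 - r_ij) over usable cells
// [[Rcpp::export]]
double cpp_susceptibility(NumericMatrix pos, NumericMatrix du,
                          LogicalVector usable, double xi0, double L,
                          bool periodic) {
  int n = pos.nrow();
  double total = 0.0;
  int nu = 0;
  for (int i = 0; i < n; ++i) if (usable[i]) ++nu;
  for (int i = 0; i < n; ++i) {
    if (!usable[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (!usable[j]) continue;
      double d = pair_dist(pos, i, j, L, periodic);
      if (d < xi0)
        total += 2.0 * (du(i, 0) * du(j, 0) + du(i, 1) * du(j, 1));
    }
  }
  return total / nu;
}

// mean over cells of the distance to the nearest other cell
// [[Rcpp::export]]
double cpp_nn_distance(NumericMatrix pos, double L, bool periodic) {
  int n = pos.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = pair_dist(pos, i, j, L, periodic);
      if (d < best) best = d;
    }
    total += best;
  }
  return total / n;
}
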