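#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area on a deterministic
// generalized-spiral (Fibonacci) point lattice. No randomness: areas are
// bit-stable across runs for a given n_points.
// coords: N x 3 (Angstrom), radii: length N van der Waals radii.
// Returns per-atom accessible area in Angstrom^2.
// [[Rcpp::export]]
NumericVector sasa_cpp(const NumericMatrix& coords, const NumericVector& radii,
                       const double probe, const int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // unit-sphere lattice
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));  // golden angle
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    px[k] = std::cos(ga * k) * r;
    py[k] = std::sin(ga * k) * r;
    pz[k] = z;
  }

  std::vector<double> er(n);  // expanded radii
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = er[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double cut = ri + er[j];
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                   dz = coords(j, 2) - zi;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      const double tx = xi + ri * px[k], ty = yi + ri * py[k],
                   tz = zi + ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double dx = tx - coords(j, 0), dy = ty - coords(j, 1),
                     dz = tz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * exposed / n_points;
  }
  return area;
}

// Count of heavy-atom pairs closer than `cutoff` whose residues are at
// least `min_sep` apart in sequence. res_idx is the 1-based ordinal
// residue index of each atom.
// [[Rcpp::export]]
int clash_count_cpp(const NumericMatrix& coords, const IntegerVector& res_idx,
                    const double cutoff, const int min_sep) {
  const int n = coords.nrow();
  const double c2 = cutoff * cutoff;
  int count = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (std::abs(res_idx[j] - res_idx[i]) < min_sep) continue;
      const double dx = coords(j, 0) - coords(i, 0);
      const double dy = coords(j, 1) - coords(i, 1);
      const double dz = coords(j, 2) - coords(i, 2);
      if (dx * dx + dy * dy + dz * dz < c2) ++count;
    }
  }
  return count;
}
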