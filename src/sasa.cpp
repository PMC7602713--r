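#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley point-exclusion kernel.
//
// xyz: n x 3 atom centres; radii: per-atom vdW radii; probe: probe radius;
// sphere: m x 3 unit vectors (deterministic spiral, generated in R).
// Returns per-atom accessible area: exposed-point fraction times the area of
// the expanded sphere 4*pi*(r_i + probe)^2.
//
// Neighbour candidates are collected per atom with a plain distance screen;
// a cell grid would be faster still, but n^2 screening in compiled code is
// comfortably fast at the sizes this package handles (<~2e4 atoms).
// [[Rcpp::export]]
NumericVector sasa_kernel(NumericMatrix xyz, NumericVector radii,
                          double probe, NumericMatrix sphere) {
  const int n = xyz.nrow();
  const int m = sphere.nrow();
  NumericVector area(n);
  std::vector<double> ext(n);
  for (int i = 0; i < n; ++i) ext[i] = radii[i] + probe;

  std::vector<int> nbr;
  nbr.reserve(256);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const double ri = ext[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double cut = ri + ext[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nbr.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xi + ri * sphere(k, 0);
      const double py = yi + ri * sphere(k, 1);
      const double pz = zi + ri * sphere(k, 2);
      bool free_point = true;
      for (size_t q = 0; q < nbr.size(); ++q) {
        const int j = nbr[q];
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1),
                     dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < ext[j] * ext[j]) {
          free_point = false;
          break;
        }
      }
      if (free_point) ++exposed;
    }
    area[i] = (double)exposed / m * 4.0 * M_PI * ri * ri;
  }
  return area;
}

// Minimum-distance pair search between two atom sets within a cutoff.
// Returns a 3-column matrix (i, j, dist) of all cross pairs with
// dist <= cutoff; indices are 1-based into the input matrices.
// [[Rcpp::export]]
NumericMatrix close_pairs(NumericMatrix a, NumericMatrix b, double cutoff) {
  std::vector<double> out;
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      const double dx = a(i, 0) - b(j, 0);
      const double dy = a(i, 1) - b(j, 1);
      const double dz = a(i, 2) - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 <= c2) {
        out.push_back(i + 1);
        out.push_back(j + 1);
        out.push_back(std::sqrt(d2));
      }
    }
  }
  NumericMatrix res(out.size() / 3, 3);
  for (size_t r = 0; r < out.size() / 3; ++r) {
    res(r, 0) = out[3 * r];
    res(r, 1) = out[3 * r + 1];
    res(r, 2) = out[3 * r + 2];
  }
  return res;
}
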