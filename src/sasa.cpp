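#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley accessible surface areas with a deterministic golden-spiral
// (Fibonacci) point set, so results are bit-reproducible for a fixed n_points.
// Coordinates and radii in nm; returned areas in nm^2.
// [[Rcpp::export]]
NumericVector sasa_shrake_rupley_cpp(NumericMatrix xyz, NumericVector radius,
                                     double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }

  std::vector<double> R(n);
  double Rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    R[i] = radius[i] + probe;
    if (R[i] > Rmax) Rmax = R[i];
  }

  // cell list for neighbour search
  const double cell = 2.0 * Rmax;
  double xmin = xyz(0, 0), ymin = xyz(0, 1), zmin = xyz(0, 2);
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, xyz(i, 0));
    ymin = std::min(ymin, xyz(i, 1));
    zmin = std::min(zmin, xyz(i, 2));
  }
  auto cix = [&](double v, double vmin) { return (int)std::floor((v - vmin) / cell); };
  std::map<long long, std::vector<int>> grid;
  auto key = [](int a, int b, int c) {
    return ((long long)(a + 1000000) << 40) ^ ((long long)(b + 1000000) << 20) ^
           (long long)(c + 1000000);
  };
  for (int i = 0; i < n; ++i)
    grid[key(cix(xyz(i, 0), xmin), cix(xyz(i, 1), ymin), cix(xyz(i, 2), zmin))].push_back(i);

  std::vector<int> nb;
  std::vector<double> nbd2;
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2), Ri = R[i];
    nb.clear();
    nbd2.clear();
    int cx = cix(xi, xmin), cy = cix(yi, ymin), cz = cix(zi, zmin);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(key(cx + dx, cy + dy, cz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double ddx = xyz(j, 0) - xi, ddy = xyz(j, 1) - yi, ddz = xyz(j, 2) - zi;
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            double rc = Ri + R[j];
            if (d2 < rc * rc) {
              nb.push_back(j);
              nbd2.push_back(d2);
            }
          }
        }
    // closest occluders first: earlier loop exits
    std::vector<int> ord(nb.size());
    for (size_t t = 0; t < ord.size(); ++t) ord[t] = (int)t;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return nbd2[a] < nbd2[b]; });

    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xi + Ri * px[k], qy = yi + Ri * py[k], qz = zi + Ri * pz[k];
      bool free_pt = true;
      for (int t : ord) {
        int j = nb[t];
        double ddx = qx - xyz(j, 0), ddy = qy - xyz(j, 1), ddz = qz - xyz(j, 2);
        // tolerant <=: coincident duplicate atoms occlude each other (zero area)
        if (ddx * ddx + ddy * ddy + ddz * ddz <= R[j] * R[j] * (1.0 + 1e-12)) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)acc / (double)n_points;
  }
  return area;
}
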