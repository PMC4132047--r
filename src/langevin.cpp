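#include <Rcpp.h>
using namespace Rcpp;

// Monotone lookup of sliding speed from total friction force.
// vgrid/fgrid: per-residue bond force table (N) on an increasing speed grid (m/s),
// odd-extended at call time. Total friction G(v) = Nc * fbond(v) + cw * v.
static double solve_speed(double Ftot, double Nc, double cw,
                          const std::vector<double>& vg, const std::vector<double>& fg) {
  double sgn = Ftot < 0 ? -1.0 : 1.0;
  double F = std::fabs(Ftot);
  const int n = (int)vg.size();
  auto G = [&](int i) { return Nc * fg[i] + cw * vg[i]; };
  if (F <= G(0)) {
    double g0 = G(0);
    return sgn * (g0 > 0 ? vg[0] * F / g0 : 0.0);
  }
  if (F >= G(n - 1)) { // beyond table: bond force ~ flat, water linear
    return sgn * (vg[n - 1] + (F - G(n - 1)) / std::max(cw, 1e-30));
  }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (G(mid) < F) lo = mid; else hi = mid;
  }
  double g1 = G(lo), g2 = G(hi);
  double w = (F - g1) / std::max(g2 - g1, 1e-300);
  return sgn * (vg[lo] + w * (vg[hi] - vg[lo]));
}

static double dGdv(double v, double Nc, double cw,
                   const std::vector<double>& vg, const std::vector<double>& fg) {
  double va = std::fabs(v);
  const int n = (int)vg.size();
  if (va <= vg[0]) {
    double g0 = Nc * fg[0] + cw * vg[0];
    return std::max(g0 / std::max(vg[0], 1e-30), cw);
  }
  if (va >= vg[n - 1]) return cw;
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (vg[mid] < va) lo = mid; else hi = mid;
  }
  double g1 = Nc * fg[lo] + cw * vg[lo], g2 = Nc * fg[hi] + cw * vg[hi];
  return std::max((g2 - g1) / std::max(vg[hi] - vg[lo], 1e-300), cw);
}

// Overdamped constant-velocity spring pulling of one effective bundle coordinate.
// SI units throughout. Returns recorded (time, spring_pos, x, force) rows.
// noise: standard normal draws, one per step (from R for reproducibility).
// [[Rcpp::export]]
List pull_langevin_cpp(double V, double k, double dt, double kT,
                       double N0, double cw, double hold, double detach,
                       NumericVector bond_vgrid, NumericVector bond_fgrid,
                       NumericVector noise, bool start_steady, int record_every,
                       int n_max) {
  std::vector<double> vg(bond_vgrid.begin(), bond_vgrid.end());
  std::vector<double> fg(bond_fgrid.begin(), bond_fgrid.end());
  double x = 0.0;
  // steady start: spring pre-tensioned to the deterministic steady force
  double Fsteady = 0.0;
  {
    // steady per-residue bond force at speed V by table interpolation
    double fb = 0.0;
    const int n = (int)vg.size();
    if (V <= vg[0]) fb = fg[0] * (vg[0] > 0 ? V / vg[0] : 0.0);
    else if (V >= vg[n - 1]) fb = fg[n - 1];
    else {
      int lo = 0, hi = n - 1;
      while (hi - lo > 1) { int mid = (lo + hi) / 2; if (vg[mid] < V) lo = mid; else hi = mid; }
      double w = (V - vg[lo]) / (vg[hi] - vg[lo]);
      fb = fg[lo] + w * (fg[hi] - fg[lo]);
    }
    Fsteady = N0 * fb + cw * V;
  }
  double s = start_steady ? Fsteady / k : 0.0; // spring anchor position
  double Ld = hold + detach;
  int nrec = 0;
  std::vector<double> rt, rs, rx, rf;
  rt.reserve(n_max / record_every + 2);
  rs.reserve(n_max / record_every + 2);
  rx.reserve(n_max / record_every + 2);
  rf.reserve(n_max / record_every + 2);
  int steps_done = 0;
  for (int i = 0; i < n_max; ++i) {
    double Nc = N0;
    if (x > hold) Nc = detach > 0 ? N0 * std::max(0.0, 1.0 - (x - hold) / detach) : 0.0;
    double Fs = k * (s - x);
    double vdrift = solve_speed(Fs, Nc, cw, vg, fg);
    double xieff = dGdv(vdrift, Nc, cw, vg, fg);
    double D = kT / xieff;
    if (i % record_every == 0) {
      rt.push_back(i * dt);
      rs.push_back(s);
      rx.push_back(x);
      rf.push_back(Fs);
      ++nrec;
    }
    double eta = (i < noise.size()) ? noise[i] : 0.0;
    x += vdrift * dt + std::sqrt(2.0 * D * dt) * eta;
    s += V * dt;
    steps_done = i + 1;
    if (x >= Ld) break;
  }
  // record final state
  rt.push_back(steps_done * dt);
  rs.push_back(s);
  rx.push_back(x);
  rf.push_back(k * (s - x));
  return List::create(_["time"] = wrap(rt), _["spring_pos"] = wrap(rs),
                      _["x"] = wrap(rx), _["force"] = wrap(rf),
                      _["steps"] = steps_done, _["detached"] = (x >= Ld));
}

// Brownian dynamics of an overdamped particle in a tilted cosine washboard
// potential: U(x) = u*kT*cos(2 pi x / a) - F*x, friction xi. Returns the mean
// velocity over n_steps after n_burn. Independent oracle for the mobility law.
// [[Rcpp::export]]
double washboard_bd_cpp(double Fext, double a, double ukT, double xi, double kT,
                        double dt, int n_burn, int n_steps, NumericVector noise) {
  const double twopi = 2.0 * M_PI;
  const double amp = ukT * twopi / a; // |dU/dx| scale
  double x = 0.0;
  double sq = std::sqrt(2.0 * kT / xi * dt);
  for (int i = 0; i < n_burn; ++i) {
    double Fp = amp * std::sin(twopi * x / a) + Fext;
    x += Fp / xi * dt + sq * noise[i];
  }
  double x0 = x;
  for (int i = n_burn; i < n_burn + n_steps; ++i) {
    double Fp = amp * std::sin(twopi * x / a) + Fext;
    x += Fp / xi * dt + sq * noise[i];
  }
  return (x - x0) / (n_steps * dt);
}
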