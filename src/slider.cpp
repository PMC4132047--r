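#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voigt convention: [xx, yy, zz, xy]; strain carries engineering shear gamma_xy.
// Plane strain; SI units (m, Pa, kg, s); per-unit-depth forces.

static inline double vm_stress(const double* s) {
  double p = (s[0] + s[1] + s[2]) / 3.0;
  double dx = s[0] - p, dy = s[1] - p, dz = s[2] - p, dxy = s[3];
  return std::sqrt(1.5 * (dx * dx + dy * dy + dz * dz + 2.0 * dxy * dxy));
}

// J2 radial-return with bilinear isotropic/kinematic hardening.
// state: sig[4], alpha[4], ep; deps: strain increment (eng. shear).
// Returns plastic dissipation increment per unit volume.
static double plastic_point(double* sig, double* alpha, double* ep,
                            const double* deps, double E, double nu,
                            double sigy0, double Et, double mix) {
  double lam = E * nu / ((1 + nu) * (1 - 2 * nu));
  double mu = E / (2 * (1 + nu));
  double H = (E > Et) ? E * Et / (E - Et) : 0.0;
  double Hiso = (1.0 - mix) * H, Hkin = mix * H;
  double tr = deps[0] + deps[1] + deps[2];
  double st[4];
  st[0] = sig[0] + lam * tr + 2 * mu * deps[0];
  st[1] = sig[1] + lam * tr + 2 * mu * deps[1];
  st[2] = sig[2] + lam * tr + 2 * mu * deps[2];
  st[3] = sig[3] + mu * deps[3];
  double p = (st[0] + st[1] + st[2]) / 3.0;
  double xi[4] = {st[0] - p - alpha[0], st[1] - p - alpha[1], st[2] - p - alpha[2],
                  st[3] - alpha[3]};
  double nrm = std::sqrt(xi[0] * xi[0] + xi[1] * xi[1] + xi[2] * xi[2] +
                         2.0 * xi[3] * xi[3]);
  double f = nrm - std::sqrt(2.0 / 3.0) * (sigy0 + Hiso * (*ep));
  if (f <= 0.0 || nrm <= 0.0) {
    for (int c = 0; c < 4; ++c) sig[c] = st[c];
    return 0.0;
  }
  double dgam = f / (2.0 * mu + (2.0 / 3.0) * (Hiso + Hkin));
  double n[4] = {xi[0] / nrm, xi[1] / nrm, xi[2] / nrm, xi[3] / nrm};
  sig[0] = st[0] - 2 * mu * dgam * n[0];
  sig[1] = st[1] - 2 * mu * dgam * n[1];
  sig[2] = st[2] - 2 * mu * dgam * n[2];
  sig[3] = st[3] - 2 * mu * dgam * n[3];
  for (int c = 0; c < 4; ++c) alpha[c] += (2.0 / 3.0) * Hkin * dgam * n[c];
  *ep += std::sqrt(2.0 / 3.0) * dgam;
  // plastic work (incl. hardening storage), sigma_new : deps_p
  double depsp[4] = {dgam * n[0], dgam * n[1], dgam * n[2], dgam * n[3]};
  return sig[0] * depsp[0] + sig[1] * depsp[1] + sig[2] * depsp[2] +
         2.0 * sig[3] * depsp[3];
}

// [[Rcpp::export]]
List plastic_update_cpp(NumericVector deps, NumericVector sig, NumericVector alpha,
                        double ep, double E, double nu, double sigy0, double Et,
                        double mix) {
  double s[4] = {sig[0], sig[1], sig[2], sig[3]};
  double a[4] = {alpha[0], alpha[1], alpha[2], alpha[3]};
  double d[4] = {deps[0], deps[1], deps[2], deps[3]};
  double e = ep;
  double w = plastic_point(s, a, &e, d, E, nu, sigy0, Et, mix);
  return List::create(_["stress"] = NumericVector::create(s[0], s[1], s[2], s[3]),
                      _["backstress"] = NumericVector::create(a[0], a[1], a[2], a[3]),
                      _["ep"] = e, _["wp"] = w);
}

// Viscoelastic: deviatoric G(t) = Ginf + (G0-Ginf) e^{-beta t}, elastic bulk K.
// state: q[4] (branch dev stress), e[4] (dev strain), evol; returns dissipation inc.
static double visco_point(double* sig, double* q, double* e, double* evol,
                          const double* deps, double Kb, double G0, double Ginf,
                          double beta, double dt) {
  double Gm = G0 - Ginf;
  double tr = deps[0] + deps[1] + deps[2];
  double de[4] = {deps[0] - tr / 3.0, deps[1] - tr / 3.0, deps[2] - tr / 3.0,
                  deps[3] / 2.0}; // tensor shear
  double qold[4] = {q[0], q[1], q[2], q[3]};
  double ef = std::exp(-beta * dt), eh = std::exp(-beta * dt / 2.0);
  for (int c = 0; c < 4; ++c) q[c] = q[c] * ef + 2.0 * Gm * eh * de[c];
  for (int c = 0; c < 4; ++c) e[c] += de[c];
  *evol += tr;
  double p = Kb * (*evol);
  sig[0] = p + 2 * Ginf * e[0] + q[0];
  sig[1] = p + 2 * Ginf * e[1] + q[1];
  sig[2] = p + 2 * Ginf * e[2] + q[2];
  sig[3] = 2 * Ginf * e[3] + q[3];
  if (Gm <= 0) return 0.0;
  double psi_old = (qold[0] * qold[0] + qold[1] * qold[1] + qold[2] * qold[2] +
                    2 * qold[3] * qold[3]) / (4.0 * Gm);
  double psi_new = (q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + 2 * q[3] * q[3]) /
                   (4.0 * Gm);
  double win = 0.0;
  for (int c = 0; c < 4; ++c) {
    double qm = 0.5 * (qold[c] + q[c]);
    win += qm * de[c] * (c == 3 ? 2.0 : 1.0);
  }
  return win - (psi_new - psi_old);
}

// [[Rcpp::export]]
List visco_update_cpp(NumericVector deps, NumericVector q, NumericVector e,
                      double evol, double Kb, double G0, double Ginf, double beta,
                      double dt) {
  double s[4], qq[4] = {q[0], q[1], q[2], q[3]}, ee[4] = {e[0], e[1], e[2], e[3]};
  double ev = evol;
  double d[4] = {deps[0], deps[1], deps[2], deps[3]};
  double dis = visco_point(s, qq, ee, &ev, d, Kb, G0, Ginf, beta, dt);
  return List::create(_["stress"] = NumericVector::create(s[0], s[1], s[2], s[3]),
                      _["q"] = NumericVector::create(qq[0], qq[1], qq[2], qq[3]),
                      _["e"] = NumericVector::create(ee[0], ee[1], ee[2], ee[3]),
                      _["evol"] = ev, _["dissipation"] = dis);
}

// Explicit central-difference FE: crystalline block (elastoplastic) sliding on an
// amorphous plate (viscoelastic) through a Newtonian film (tangential viscous
// traction + squeeze damping + normal penalty).
// [[Rcpp::export]]
List slider_run_cpp(NumericMatrix nodes, IntegerMatrix elems, IntegerVector matid,
                    List mat_plastic, List mat_visco, NumericVector rho,
                    IntegerVector driven, NumericVector vdrive,
                    IntegerVector fixed,
                    IntegerMatrix film_pairs, NumericVector film_area,
                    double film_eta, double film_h, double kpen, double standoff,
                    double pen_tol, double dt, int n_steps, int record_every) {
  const int nn = nodes.nrow(), ne = elems.nrow();
  const double Ep = as<double>(mat_plastic["youngs"]), nup = as<double>(mat_plastic["poisson"]);
  const double sy = as<double>(mat_plastic["yield"]), Etp = as<double>(mat_plastic["tangent"]);
  const double mixp = as<double>(mat_plastic["mix"]);
  const double Kb = as<double>(mat_visco["bulk"]), G0 = as<double>(mat_visco["G0"]);
  const double Gi = as<double>(mat_visco["Ginf"]), bet = as<double>(mat_visco["beta"]);

  // Gauss points
  const double g = 1.0 / std::sqrt(3.0);
  const double gp[4][2] = {{-g, -g}, {g, -g}, {g, g}, {-g, g}};

  // precompute dN/dx, dN/dy, w*detJ per element/gp
  std::vector<double> dNx(ne * 4 * 4), dNy(ne * 4 * 4), wdet(ne * 4);
  std::vector<double> mass(nn, 0.0);
  for (int e = 0; e < ne; ++e) {
    double xs[4], ys[4];
    for (int a = 0; a < 4; ++a) {
      xs[a] = nodes(elems(e, a), 0);
      ys[a] = nodes(elems(e, a), 1);
    }
    double earea = 0.0;
    for (int q = 0; q < 4; ++q) {
      double xi = gp[q][0], eta = gp[q][1];
      double dNxi[4] = {-(1 - eta) / 4, (1 - eta) / 4, (1 + eta) / 4, -(1 + eta) / 4};
      double dNet[4] = {-(1 - xi) / 4, -(1 + xi) / 4, (1 + xi) / 4, (1 - xi) / 4};
      double J11 = 0, J12 = 0, J21 = 0, J22 = 0;
      for (int a = 0; a < 4; ++a) {
        J11 += dNxi[a] * xs[a];
        J12 += dNxi[a] * ys[a];
        J21 += dNet[a] * xs[a];
        J22 += dNet[a] * ys[a];
      }
      double det = J11 * J22 - J12 * J21;
      double i11 = J22 / det, i12 = -J12 / det, i21 = -J21 / det, i22 = J11 / det;
      for (int a = 0; a < 4; ++a) {
        dNx[(e * 4 + q) * 4 + a] = i11 * dNxi[a] + i12 * dNet[a];
        dNy[(e * 4 + q) * 4 + a] = i21 * dNxi[a] + i22 * dNet[a];
      }
      wdet[e * 4 + q] = det; // weight 1 per gp
      earea += det;
    }
    for (int a = 0; a < 4; ++a) mass[elems(e, a)] += rho[matid[e]] * earea / 4.0;
  }

  // state
  std::vector<double> sig(ne * 4 * 4, 0.0), alpha(ne * 4 * 4, 0.0), ep(ne * 4, 0.0);
  std::vector<double> qb(ne * 4 * 4, 0.0), edev(ne * 4 * 4, 0.0), evol(ne * 4, 0.0);
  std::vector<double> epsT(ne * 4 * 4, 0.0); // total strain (energy bookkeeping)

  std::vector<double> vx(nn, 0.0), vy(nn, 0.0), fx(nn), fy(nn);
  std::vector<double> ux(nn, 0.0), uy(nn, 0.0);
  std::vector<char> is_driven(nn, 0), is_fixed(nn, 0);
  for (int i = 0; i < driven.size(); ++i) is_driven[driven[i]] = 1;
  for (int i = 0; i < fixed.size(); ++i) is_fixed[fixed[i]] = 1;
  // block nodes start at the driving velocity (no startup shock): any node of a
  // plastic-material element is "block"
  std::vector<char> is_block(nn, 0);
  for (int e = 0; e < ne; ++e)
    if (matid[e] == 0)
      for (int a = 0; a < 4; ++a) is_block[elems(e, a)] = 1;
  for (int i = 0; i < nn; ++i)
    if (is_block[i] && !is_fixed[i]) {
      vx[i] = vdrive[0];
      vy[i] = vdrive[1];
    }

  double W_ext = 0.0, D_pl = 0.0, D_ve = 0.0, D_film = 0.0;
  const int npair = film_pairs.nrow();

  int nrec_max = n_steps / record_every + 2;
  NumericVector r_t(nrec_max), r_vmc(nrec_max), r_vmc_max(nrec_max), r_vma(nrec_max),
      r_vma_max(nrec_max), r_tau(nrec_max), r_wext(nrec_max), r_ke(nrec_max),
      r_est(nrec_max), r_dpl(nrec_max), r_dve(nrec_max), r_dfilm(nrec_max),
      r_epen(nrec_max), r_gap(nrec_max);
  int nrec = 0;
  bool penetration_fail = false;
  int step_fail = -1;

  for (int step = 0; step < n_steps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);

    // strain increments from current velocities, stress update, internal forces
    for (int e = 0; e < ne; ++e) {
      int na[4];
      for (int a = 0; a < 4; ++a) na[a] = elems(e, a);
      for (int q = 0; q < 4; ++q) {
        const double* Dx = &dNx[(e * 4 + q) * 4];
        const double* Dy = &dNy[(e * 4 + q) * 4];
        double dexx = 0, deyy = 0, dgxy = 0;
        for (int a = 0; a < 4; ++a) {
          dexx += Dx[a] * vx[na[a]];
          deyy += Dy[a] * vy[na[a]];
          dgxy += Dy[a] * vx[na[a]] + Dx[a] * vy[na[a]];
        }
        double deps[4] = {dexx * dt, deyy * dt, 0.0, dgxy * dt};
        double* S = &sig[(e * 4 + q) * 4];
        double vol = wdet[e * 4 + q];
        for (int c = 0; c < 4; ++c) epsT[(e * 4 + q) * 4 + c] += deps[c];
        if (matid[e] == 0) {
          D_pl += vol * plastic_point(S, &alpha[(e * 4 + q) * 4], &ep[e * 4 + q],
                                      deps, Ep, nup, sy, Etp, mixp);
        } else {
          D_ve += vol * visco_point(S, &qb[(e * 4 + q) * 4], &edev[(e * 4 + q) * 4],
                                    &evol[e * 4 + q], deps, Kb, G0, Gi, bet, dt);
        }
        for (int a = 0; a < 4; ++a) {
          fx[na[a]] -= (Dx[a] * S[0] + Dy[a] * S[3]) * vol;
          fy[na[a]] -= (Dy[a] * S[1] + Dx[a] * S[3]) * vol;
        }
      }
    }

    // film normal penalty (position based)
    double E_pen = 0.0, min_gap = 1e300;
    for (int p = 0; p < npair; ++p) {
      int i = film_pairs(p, 0), j = film_pairs(p, 1);
      double gap = ((nodes(i, 1) + uy[i]) - (nodes(j, 1) + uy[j])) - standoff;
      if (gap < min_gap) min_gap = gap;
      if (gap < 0.0) {
        double F = -kpen * film_area[p] * gap; // push apart
        fy[i] += F;
        fy[j] -= F;
        E_pen += 0.5 * kpen * film_area[p] * gap * gap;
      }
    }
    if (min_gap < -pen_tol) {
      penetration_fail = true;
      step_fail = step;
      break;
    }

    // velocity update (free nodes); driven/fixed nodes: constraint work
    for (int i = 0; i < nn; ++i) {
      if (is_fixed[i]) {
        vx[i] = 0.0;
        vy[i] = 0.0;
      } else if (is_driven[i]) {
        vx[i] = vdrive[0];
        vy[i] = vdrive[1];
        // constraint supplies -f dt to keep the velocity constant
        W_ext += -(fx[i] * vx[i] + fy[i] * vy[i]) * dt;
      } else {
        vx[i] += dt * fx[i] / mass[i];
        vy[i] += dt * fy[i] / mass[i];
      }
    }

    // implicit pairwise film viscous coupling (tangential + squeeze)
    double tau_sum = 0.0, area_sum = 0.0;
    for (int p = 0; p < npair; ++p) {
      int i = film_pairs(p, 0), j = film_pairs(p, 1);
      double c = film_eta * film_area[p] / film_h;
      double wi = (is_driven[i] || is_fixed[i]) ? 0.0 : 1.0 / mass[i];
      double wj = (is_driven[j] || is_fixed[j]) ? 0.0 : 1.0 / mass[j];
      double denom = 1.0 + dt * c * (wi + wj);
      // tangential (x)
      double dvx = (vx[i] - vx[j]) / denom;
      double Jx = dt * c * dvx;
      vx[i] -= Jx * wi;
      vx[j] += Jx * wj;
      D_film += c * dvx * dvx * dt;
      if (wi == 0.0) W_ext += Jx * vx[i];   // constraint holds node i against film drag
      if (wj == 0.0) W_ext += -Jx * vx[j];
      // squeeze (y)
      double dvy = (vy[i] - vy[j]) / denom;
      double Jy = dt * c * dvy;
      vy[i] -= Jy * wi;
      vy[j] += Jy * wj;
      D_film += c * dvy * dvy * dt;
      if (wi == 0.0) W_ext += Jy * vy[i];
      if (wj == 0.0) W_ext += -Jy * vy[j];
      tau_sum += c * dvx; // traction * area, signed
      area_sum += film_area[p];
    }

    // position update
    for (int i = 0; i < nn; ++i) {
      ux[i] += vx[i] * dt;
      uy[i] += vy[i] * dt;
    }

    if (step % record_every == 0 || step == n_steps - 1) {
      double vmc = 0, vmcM = 0, vma = 0, vmaM = 0;
      int nc = 0, namo = 0;
      double KE = 0, Est = 0;
      for (int i = 0; i < nn; ++i)
        KE += 0.5 * mass[i] * (vx[i] * vx[i] + vy[i] * vy[i]);
      for (int e = 0; e < ne; ++e) {
        double vme = 0.0;
        for (int q = 0; q < 4; ++q) {
          const double* S = &sig[(e * 4 + q) * 4];
          vme += vm_stress(S) / 4.0;
          double vol = wdet[e * 4 + q];
          if (matid[e] == 0) {
            double trs = S[0] + S[1] + S[2];
            double ss = S[0] * S[0] + S[1] * S[1] + S[2] * S[2] + 2 * S[3] * S[3];
            Est += vol * 0.5 * ((1 + nup) / Ep * ss - nup / Ep * trs * trs);
          } else {
            const double* ee = &edev[(e * 4 + q) * 4];
            const double* qq = &qb[(e * 4 + q) * 4];
            double e2 = ee[0] * ee[0] + ee[1] * ee[1] + ee[2] * ee[2] + 2 * ee[3] * ee[3];
            double q2 = qq[0] * qq[0] + qq[1] * qq[1] + qq[2] * qq[2] + 2 * qq[3] * qq[3];
            double Gm = G0 - Gi;
            Est += vol * (Gi * e2 + (Gm > 0 ? q2 / (4 * Gm) : 0.0) +
                          0.5 * Kb * evol[e * 4 + q] * evol[e * 4 + q]);
          }
        }
        if (matid[e] == 0) {
          vmc += vme;
          vmcM = std::max(vmcM, vme);
          ++nc;
        } else {
          vma += vme;
          vmaM = std::max(vmaM, vme);
          ++namo;
        }
      }
      r_t[nrec] = (step + 1) * dt;
      r_vmc[nrec] = nc ? vmc / nc : 0.0;
      r_vmc_max[nrec] = vmcM;
      r_vma[nrec] = namo ? vma / namo : 0.0;
      r_vma_max[nrec] = vmaM;
      r_tau[nrec] = area_sum > 0 ? tau_sum / area_sum : 0.0;
      r_wext[nrec] = W_ext;
      r_ke[nrec] = KE;
      r_est[nrec] = Est;
      r_dpl[nrec] = D_pl;
      r_dve[nrec] = D_ve;
      r_dfilm[nrec] = D_film;
      r_epen[nrec] = E_pen;
      r_gap[nrec] = min_gap;
      ++nrec;
    }
  }

  auto head = [&](NumericVector v) { return NumericVector(v.begin(), v.begin() + nrec); };
  return List::create(
      _["time"] = head(r_t), _["vm_crystal"] = head(r_vmc),
      _["vm_crystal_max"] = head(r_vmc_max), _["vm_amorphous"] = head(r_vma),
      _["vm_amorphous_max"] = head(r_vma_max), _["tau_interface"] = head(r_tau),
      _["W_ext"] = head(r_wext), _["KE"] = head(r_ke), _["E_stored"] = head(r_est),
      _["D_plastic"] = head(r_dpl), _["D_visco"] = head(r_dve),
      _["D_film"] = head(r_dfilm), _["E_penalty"] = head(r_epen),
      _["min_gap"] = head(r_gap), _["penetration_fail"] = penetration_fail,
      _["step_fail"] = step_fail);
}
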