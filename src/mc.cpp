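// Metropolis Monte Carlo samplers for the analytically solvable toy systems.
// All randomness goes through R's RNG so that set.seed() at the R level makes
// every trajectory bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB_KCAL = 0.0019872041; // kcal mol^-1 K^-1

static inline double sq(double x) { return x * x; }

// ---------------------------------------------------------------------------
// Harmonic alchemical path
// ---------------------------------------------------------------------------

// U_A = 0.5 kA |x - cA|^2, U_B = 0.5 kB |x - cB|^2, U_lambda = (1-l)U_A + l U_B.
// One chain per window; each window starts from the previous window's final
// configuration.  Recorded per retained frame: dU = U_{l+dl} - U_l.
// [[Rcpp::export]]
List mc_harmonic_path(int dim, double kA, double kB,
                      NumericVector cA, NumericVector cB,
                      double temperature, NumericVector lambdas,
                      int n_steps, double equil_fraction,
                      double step_size, bool keep_positions) {
  if (temperature <= 0) stop("temperature must be positive");
  const double kT = KB_KCAL * temperature;
  const int n_win = lambdas.size() - 1;
  std::vector<double> x(dim), xp(dim);
  for (int d = 0; d < dim; ++d) x[d] = cA[d];
  const int n_equil = (int)std::floor(equil_fraction * n_steps);
  const int n_rec = n_steps - n_equil;

  List windows(n_win);
  RNGScope scope;

  for (int w = 0; w < n_win; ++w) {
    const double l = lambdas[w], ln = lambdas[w + 1];
    NumericVector dU(n_rec);
    NumericMatrix pos;
    if (keep_positions) pos = NumericMatrix(n_rec, dim);
    double uA = 0, uB = 0;
    for (int d = 0; d < dim; ++d) {
      uA += 0.5 * kA * sq(x[d] - cA[d]);
      uB += 0.5 * kB * sq(x[d] - cB[d]);
    }
    double ul = (1 - l) * uA + l * uB;
    long n_acc = 0;
    double sum_x2 = 0;
    for (int s = 0; s < n_steps; ++s) {
      double uAp = 0, uBp = 0;
      for (int d = 0; d < dim; ++d) {
        xp[d] = x[d] + step_size * norm_rand();
        uAp += 0.5 * kA * sq(xp[d] - cA[d]);
        uBp += 0.5 * kB * sq(xp[d] - cB[d]);
      }
      double ulp = (1 - l) * uAp + l * uBp;
      if (ulp <= ul || unif_rand() < std::exp(-(ulp - ul) / kT)) {
        x = xp; uA = uAp; uB = uBp; ul = ulp; ++n_acc;
      }
      if (s >= n_equil) {
        int r = s - n_equil;
        dU[r] = (ln - l) * (uB - uA);
        double x2 = 0;
        for (int d = 0; d < dim; ++d) {
          x2 += sq(x[d]);
          if (keep_positions) pos(r, d) = x[d];
        }
        sum_x2 += x2;
      }
    }
    List wi = List::create(
      _["delta_u"] = dU,
      _["acceptance"] = (double)n_acc / n_steps,
      _["mean_x2"] = sum_x2 / n_rec);
    if (keep_positions) wi["positions"] = pos;
    windows[w] = wi;
  }
  return windows;
}

// ---------------------------------------------------------------------------
// Host-guest system with orientable single-site pseudo-waters
// ---------------------------------------------------------------------------
//
// Interactions:
//   LJ between every non-bonded pair: 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ],
//     eps_ij = sqrt(eps_i eps_j), sig_ij = (sig_i + sig_j)/2.
//   water-water dipole:  -mu_i mu_j (u_i . u_j) / r^3
//   solute-water dipole: -mu_s mu_w (u_w . rhat_sw) / r^3  (rhat from solute
//     to water, so a positive solute mu orients waters pointing away from it)
//   guest bonds: 0.5 k (r - r0)^2 (bonded guest pairs are LJ-excluded)
//   positional restraint on guests: 0.5 k_restr |r - r_ref|^2
//
// Guest nonbonded/bond parameters exist in two sets (A and B end states);
// the sampled Hamiltonian interpolates linearly between the guest terms:
//   U_l = U_env + (1-l) U_guest(A) + l U_guest(B) + U_restr.

struct HGSystem {
  int nh, ng, nw;
  std::vector<double> hpos, heps, hsig, hmu;  // host (fixed)
  std::vector<double> gpos, gref;             // guest coords + restraint ref
  std::vector<double> geA, gsA, gmA, geB, gsB, gmB;
  std::vector<int> bi, bj;                    // bonds (guest indices)
  std::vector<double> bkA, br0A, bkB, br0B;
  std::vector<std::vector<bool>> bonded;      // guest pair exclusion
  std::vector<double> wpos, wu;               // waters: position + unit dipole
  double weps, wsig, wmu;
  double R, krestr, kT, lambda;

  double lj(double eps, double sig, double r2) const {
    double s2 = sig * sig / r2, s6 = s2 * s2 * s2;
    return 4.0 * eps * (s6 * s6 - s6);
  }
  // solute particle (pos p, eps, sig, mu) vs water w
  double sw_pair(const double* p, double eps, double sig, double mu, int w) const {
    double dx = wpos[3 * w] - p[0], dy = wpos[3 * w + 1] - p[1], dz = wpos[3 * w + 2] - p[2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double e = lj(std::sqrt(eps * weps), 0.5 * (sig + wsig), r2);
    if (mu != 0 && wmu != 0) {
      double r = std::sqrt(r2);
      double udotr = (wu[3 * w] * dx + wu[3 * w + 1] * dy + wu[3 * w + 2] * dz) / r;
      e += -mu * wmu * udotr / (r2 * r);
    }
    return e;
  }
  double ww_pair(int i, int j) const {
    double dx = wpos[3 * i] - wpos[3 * j], dy = wpos[3 * i + 1] - wpos[3 * j + 1],
           dz = wpos[3 * i + 2] - wpos[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    double e = lj(weps, wsig, r2);
    if (wmu != 0) {
      double r = std::sqrt(r2);
      double udotu = wu[3 * i] * wu[3 * j] + wu[3 * i + 1] * wu[3 * j + 1] +
                     wu[3 * i + 2] * wu[3 * j + 2];
      e += -wmu * wmu * udotu / (r2 * r);
    }
    return e;
  }
  double gg_pair(int i, int j, bool stateB) const {
    if (bonded[i][j]) return 0.0;
    double dx = gpos[3 * i] - gpos[3 * j], dy = gpos[3 * i + 1] - gpos[3 * j + 1],
           dz = gpos[3 * i + 2] - gpos[3 * j + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (stateB) return lj(std::sqrt(geB[i] * geB[j]), 0.5 * (gsB[i] + gsB[j]), r2);
    return lj(std::sqrt(geA[i] * geA[j]), 0.5 * (gsA[i] + gsA[j]), r2);
  }
  double bond_energy(bool stateB) const {
    double e = 0;
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = bi[b], j = bj[b];
      double dx = gpos[3 * i] - gpos[3 * j], dy = gpos[3 * i + 1] - gpos[3 * j + 1],
             dz = gpos[3 * i + 2] - gpos[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      e += stateB ? 0.5 * bkB[b] * sq(r - br0B[b]) : 0.5 * bkA[b] * sq(r - br0A[b]);
    }
    return e;
  }
  double gh_pair(int g, int h, bool stateB) const {
    double dx = hpos[3 * h] - gpos[3 * g], dy = hpos[3 * h + 1] - gpos[3 * g + 1],
           dz = hpos[3 * h + 2] - gpos[3 * g + 2];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (stateB) return lj(std::sqrt(geB[g] * heps[h]), 0.5 * (gsB[g] + hsig[h]), r2);
    return lj(std::sqrt(geA[g] * heps[h]), 0.5 * (gsA[g] + hsig[h]), r2);
  }
  double restraint() const {
    if (krestr == 0) return 0.0;
    double e = 0;
    for (int g = 0; g < 3 * ng; ++g) e += sq(gpos[g] - gref[g]);
    return 0.5 * krestr * e;
  }

  // full component recomputation (used at every recorded frame)
  void components(double* c) const {
    // order: hh, hw, ww, ghA, ghB, gwA, gwB, ggA, ggB, restr
    for (int k = 0; k < 10; ++k) c[k] = 0;
    for (int i = 0; i < nh; ++i)
      for (int j = i + 1; j < nh; ++j) {
        double dx = hpos[3 * i] - hpos[3 * j], dy = hpos[3 * i + 1] - hpos[3 * j + 1],
               dz = hpos[3 * i + 2] - hpos[3 * j + 2];
        c[0] += lj(std::sqrt(heps[i] * heps[j]), 0.5 * (hsig[i] + hsig[j]),
                   dx * dx + dy * dy + dz * dz);
      }
    for (int h = 0; h < nh; ++h)
      for (int w = 0; w < nw; ++w)
        c[1] += sw_pair(&hpos[3 * h], heps[h], hsig[h], hmu[h], w);
    for (int i = 0; i < nw; ++i)
      for (int j = i + 1; j < nw; ++j) c[2] += ww_pair(i, j);
    for (int g = 0; g < ng; ++g)
      for (int h = 0; h < nh; ++h) {
        c[3] += gh_pair(g, h, false);
        c[4] += gh_pair(g, h, true);
      }
    for (int g = 0; g < ng; ++g)
      for (int w = 0; w < nw; ++w) {
        c[5] += sw_pair(&gpos[3 * g], geA[g], gsA[g], gmA[g], w);
        c[6] += sw_pair(&gpos[3 * g], geB[g], gsB[g], gmB[g], w);
      }
    for (int i = 0; i < ng; ++i)
      for (int j = i + 1; j < ng; ++j) {
        c[7] += gg_pair(i, j, false);
        c[8] += gg_pair(i, j, true);
      }
    c[7] += bond_energy(false);
    c[8] += bond_energy(true);
    c[9] = restraint();
  }

  // lambda-weighted local energy of one water (interactions only)
  double water_local(int w) const {
    double env = 0, gA = 0, gB = 0;
    for (int h = 0; h < nh; ++h) env += sw_pair(&hpos[3 * h], heps[h], hsig[h], hmu[h], w);
    for (int j = 0; j < nw; ++j) if (j != w) env += ww_pair(w, j);
    for (int g = 0; g < ng; ++g) {
      gA += sw_pair(&gpos[3 * g], geA[g], gsA[g], gmA[g], w);
      gB += sw_pair(&gpos[3 * g], geB[g], gsB[g], gmB[g], w);
    }
    return env + (1 - lambda) * gA + lambda * gB;
  }
  // lambda-weighted local energy of one guest particle
  double guest_local(int g) const {
    double gA = 0, gB = 0;
    for (int h = 0; h < nh; ++h) { gA += gh_pair(g, h, false); gB += gh_pair(g, h, true); }
    for (int w = 0; w < nw; ++w) {
      gA += sw_pair(&gpos[3 * g], geA[g], gsA[g], gmA[g], w);
      gB += sw_pair(&gpos[3 * g], geB[g], gsB[g], gmB[g], w);
    }
    for (int j = 0; j < ng; ++j) if (j != g) { gA += gg_pair(g, j, false); gB += gg_pair(g, j, true); }
    // bonds involving g
    for (size_t b = 0; b < bi.size(); ++b) {
      if (bi[b] != g && bj[b] != g) continue;
      int i = bi[b], j = bj[b];
      double dx = gpos[3 * i] - gpos[3 * j], dy = gpos[3 * i + 1] - gpos[3 * j + 1],
             dz = gpos[3 * i + 2] - gpos[3 * j + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      gA += 0.5 * bkA[b] * sq(r - br0A[b]);
      gB += 0.5 * bkB[b] * sq(r - br0B[b]);
    }
    double e = (1 - lambda) * gA + lambda * gB;
    if (krestr > 0)
      e += 0.5 * krestr * (sq(gpos[3 * g] - gref[3 * g]) + sq(gpos[3 * g + 1] - gref[3 * g + 1]) +
                           sq(gpos[3 * g + 2] - gref[3 * g + 2]));
    return e;
  }
};

// reflect a proposed position back inside the sphere; returns false if the
// move must be rejected outright (pathologically far outside)
static inline bool reflect(double* p, double R) {
  double r = std::sqrt(p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
  if (r <= R) return true;
  if (r >= 2 * R) return false;
  double f = (2 * R - r) / r;
  p[0] *= f; p[1] *= f; p[2] *= f;
  return true;
}

// [[Rcpp::export]]
List mc_hostguest(NumericMatrix host_pos, NumericVector host_eps, NumericVector host_sig,
                  NumericVector host_mu,
                  NumericMatrix guest_pos, NumericMatrix guest_ref,
                  NumericVector geps_A, NumericVector gsig_A, NumericVector gmu_A,
                  NumericVector geps_B, NumericVector gsig_B, NumericVector gmu_B,
                  IntegerMatrix bonds, NumericVector bond_kA, NumericVector bond_r0A,
                  NumericVector bond_kB, NumericVector bond_r0B,
                  NumericMatrix water_pos, NumericMatrix water_u,
                  double water_eps, double water_sig, double water_mu,
                  double sphere_radius, double k_restraint,
                  double temperature, double lambda,
                  int n_steps, int n_equil, int stride, int traj_stride,
                  double trans_step, double rot_step) {
  if (temperature <= 0) stop("temperature must be positive");
  HGSystem S;
  S.nh = host_pos.nrow(); S.ng = guest_pos.nrow(); S.nw = water_pos.nrow();
  S.hpos.assign(host_pos.begin(), host_pos.end()); // caller passes row-major flattened
  // NumericMatrix is column-major; flatten explicitly
  auto flatten = [](NumericMatrix m) {
    std::vector<double> v(3 * m.nrow());
    for (int i = 0; i < m.nrow(); ++i)
      for (int d = 0; d < 3; ++d) v[3 * i + d] = m(i, d);
    return v;
  };
  S.hpos = flatten(host_pos);
  S.gpos = flatten(guest_pos);
  S.gref = flatten(guest_ref);
  S.wpos = flatten(water_pos);
  S.wu = flatten(water_u);
  S.heps.assign(host_eps.begin(), host_eps.end());
  S.hsig.assign(host_sig.begin(), host_sig.end());
  S.hmu.assign(host_mu.begin(), host_mu.end());
  S.geA.assign(geps_A.begin(), geps_A.end());
  S.gsA.assign(gsig_A.begin(), gsig_A.end());
  S.gmA.assign(gmu_A.begin(), gmu_A.end());
  S.geB.assign(geps_B.begin(), geps_B.end());
  S.gsB.assign(gsig_B.begin(), gsig_B.end());
  S.gmB.assign(gmu_B.begin(), gmu_B.end());
  S.bonded.assign(S.ng, std::vector<bool>(S.ng, false));
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.bi.push_back(bonds(b, 0)); S.bj.push_back(bonds(b, 1));
    S.bonded[bonds(b, 0)][bonds(b, 1)] = true;
    S.bonded[bonds(b, 1)][bonds(b, 0)] = true;
    S.bkA.push_back(bond_kA[b]); S.br0A.push_back(bond_r0A[b]);
    S.bkB.push_back(bond_kB[b]); S.br0B.push_back(bond_r0B[b]);
  }
  S.weps = water_eps; S.wsig = water_sig; S.wmu = water_mu;
  S.R = sphere_radius; S.krestr = k_restraint;
  S.kT = KB_KCAL * temperature; S.lambda = lambda;

  const int n_mobile = S.ng + S.nw;
  const int n_rec = (n_steps - n_equil) / stride;
  NumericMatrix comps(n_rec, 10);
  colnames(comps) = CharacterVector::create("hh", "hw", "ww", "gh_A", "gh_B",
                                            "gw_A", "gw_B", "gg_A", "gg_B", "restr");
  const int n_traj = traj_stride > 0 ? (n_steps - n_equil) / traj_stride : 0;
  List traj_w(n_traj), traj_u(n_traj), traj_g(n_traj);

  long n_acc = 0, n_try = 0;
  int rec = 0, trec = 0;
  RNGScope scope;

  for (int s = 0; s < n_steps; ++s) {
    // one sweep = n_mobile attempted single-particle moves
    for (int m = 0; m < n_mobile; ++m) {
      int pick = (int)std::floor(unif_rand() * n_mobile);
      if (pick >= n_mobile) pick = n_mobile - 1;
      ++n_try;
      if (pick < S.ng) {
        int g = pick;
        double old[3] = {S.gpos[3 * g], S.gpos[3 * g + 1], S.gpos[3 * g + 2]};
        double e0 = S.guest_local(g);
        double prop[3] = {old[0] + trans_step * norm_rand(),
                          old[1] + trans_step * norm_rand(),
                          old[2] + trans_step * norm_rand()};
        if (!reflect(prop, S.R)) continue;
        S.gpos[3 * g] = prop[0]; S.gpos[3 * g + 1] = prop[1]; S.gpos[3 * g + 2] = prop[2];
        double e1 = S.guest_local(g);
        if (e1 <= e0 || unif_rand() < std::exp(-(e1 - e0) / S.kT)) { ++n_acc; }
        else { S.gpos[3 * g] = old[0]; S.gpos[3 * g + 1] = old[1]; S.gpos[3 * g + 2] = old[2]; }
      } else {
        int w = pick - S.ng;
        double oldp[3] = {S.wpos[3 * w], S.wpos[3 * w + 1], S.wpos[3 * w + 2]};
        double oldu[3] = {S.wu[3 * w], S.wu[3 * w + 1], S.wu[3 * w + 2]};
        double e0 = S.water_local(w);
        double prop[3] = {oldp[0] + trans_step * norm_rand(),
                          oldp[1] + trans_step * norm_rand(),
                          oldp[2] + trans_step * norm_rand()};
        if (!reflect(prop, S.R)) continue;
        double nu[3] = {oldu[0] + rot_step * norm_rand(),
                        oldu[1] + rot_step * norm_rand(),
                        oldu[2] + rot_step * norm_rand()};
        double nn = std::sqrt(nu[0] * nu[0] + nu[1] * nu[1] + nu[2] * nu[2]);
        if (nn < 1e-12) continue;
        for (int d = 0; d < 3; ++d) { S.wpos[3 * w + d] = prop[d]; S.wu[3 * w + d] = nu[d] / nn; }
        double e1 = S.water_local(w);
        if (e1 <= e0 || unif_rand() < std::exp(-(e1 - e0) / S.kT)) { ++n_acc; }
        else {
          for (int d = 0; d < 3; ++d) { S.wpos[3 * w + d] = oldp[d]; S.wu[3 * w + d] = oldu[d]; }
        }
      }
    }
    if (s >= n_equil) {
      int k = s - n_equil;
      if (k % stride == 0 && rec < n_rec) {
        double c[10];
        S.components(c);
        for (int q = 0; q < 10; ++q) comps(rec, q) = c[q];
        ++rec;
      }
      if (traj_stride > 0 && k % traj_stride == 0 && trec < n_traj) {
        NumericMatrix wp(S.nw, 3), wu(S.nw, 3), gp(S.ng, 3);
        for (int i = 0; i < S.nw; ++i)
          for (int d = 0; d < 3; ++d) { wp(i, d) = S.wpos[3 * i + d]; wu(i, d) = S.wu[3 * i + d]; }
        for (int i = 0; i < S.ng; ++i)
          for (int d = 0; d < 3; ++d) gp(i, d) = S.gpos[3 * i + d];
        traj_w[trec] = wp; traj_u[trec] = wu; traj_g[trec] = gp;
        ++trec;
      }
    }
  }

  NumericMatrix gfin(S.ng, 3), wfin(S.nw, 3), ufin(S.nw, 3);
  for (int i = 0; i < S.ng; ++i)
    for (int d = 0; d < 3; ++d) gfin(i, d) = S.gpos[3 * i + d];
  for (int i = 0; i < S.nw; ++i)
    for (int d = 0; d < 3; ++d) { wfin(i, d) = S.wpos[3 * i + d]; ufin(i, d) = S.wu[3 * i + d]; }

  return List::create(
    _["components"] = comps,
    _["acceptance"] = n_try > 0 ? (double)n_acc / n_try : NA_REAL,
    _["guest_final"] = gfin, _["water_final"] = wfin, _["orient_final"] = ufin,
    _["traj_water"] = traj_w, _["traj_orient"] = traj_u, _["traj_guest"] = traj_g);
}
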