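// Compiled kernels: potential energy + analytic forces for the two-bead
// peptide model, the stochastic leapfrog (Langevin) integrator, and the
// inter-chain contact scan used by the cluster analysis.
//
// Units throughout: length nm, time ps, energy kJ/mol, mass amu
// (=> velocity nm/ps, force kJ mol^-1 nm^-1). kB in these units:
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.008314462618; // kJ mol^-1 K^-1

inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// flat system description shared by the energy and dynamics entry points
struct System {
  int n;
  double L;
  std::vector<int> bond_i, bond_j;
  std::vector<double> bond_k, bond_r0;
  std::vector<int> ang_i, ang_j, ang_k;
  std::vector<double> angk, angc0;
  std::vector<int> kind;
  double sig[16], eps[16];
  int rep[16];
  double vshift[16]; // potential value at the cutoff (0 if not shifting)
  double cutoff2;
  bool bonded_only;
  std::unordered_set<long long> excl;
};

static System build_system(NumericMatrix pos, double L, IntegerMatrix bonds,
                           NumericVector bond_k, NumericVector bond_r0,
                           IntegerMatrix angles, NumericVector ang_k,
                           NumericVector ang_cos0, IntegerVector kind,
                           NumericMatrix sig44, NumericMatrix eps44,
                           IntegerMatrix rep44, double cutoff, bool shift,
                           bool bonded_only) {
  System s;
  s.n = pos.nrow();
  s.L = L;
  int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    s.bond_i.push_back(bonds(b, 0));
    s.bond_j.push_back(bonds(b, 1));
    s.bond_k.push_back(bond_k[b]);
    s.bond_r0.push_back(bond_r0[b]);
    long long i = bonds(b, 0), j = bonds(b, 1);
    s.excl.insert(i < j ? i * s.n + j : j * s.n + i);
  }
  for (int t = 0; t < angles.nrow(); ++t) {
    s.ang_i.push_back(angles(t, 0));
    s.ang_j.push_back(angles(t, 1));
    s.ang_k.push_back(angles(t, 2));
    s.angk.push_back(ang_k[t]);
    s.angc0.push_back(ang_cos0[t]);
  }
  s.kind.assign(kind.begin(), kind.end());
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b) {
      double sg = sig44(a, b), e = eps44(a, b);
      s.sig[4 * a + b] = sg;
      s.eps[4 * a + b] = e;
      s.rep[4 * a + b] = rep44(a, b);
      double vc = 0.0;
      if (shift && e > 0.0) {
        double sc6 = std::pow(sg / cutoff, 6.0);
        vc = rep44(a, b) ? 4.0 * e * sc6 * sc6 : 4.0 * e * (sc6 * sc6 - sc6);
      }
      s.vshift[4 * a + b] = vc;
    }
  s.cutoff2 = cutoff * cutoff;
  s.bonded_only = bonded_only;
  return s;
}

// energy terms: [bond, angle, lj, replj]; F must be zeroed by the caller.
// Returns the squared distance of the closest nonbonded pair.
static double compute_forces(const double *x, const System &s, double *F,
                             double eterm[4]) {
  const int n = s.n;
  const double L = s.L;
  eterm[0] = eterm[1] = eterm[2] = eterm[3] = 0.0;
  double min_nb2 = R_PosInf;

  for (size_t b = 0; b < s.bond_i.size(); ++b) {
    int i = s.bond_i[b], j = s.bond_j[b];
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      d[c] = min_image(x[i + c * n] - x[j + c * n], L);
      r2 += d[c] * d[c];
    }
    double r = std::sqrt(r2);
    double dr = r - s.bond_r0[b];
    eterm[0] += 0.5 * s.bond_k[b] * dr * dr;
    if (r > 0) {
      double f = -s.bond_k[b] * dr / r;
      for (int c = 0; c < 3; ++c) {
        F[i + c * n] += f * d[c];
        F[j + c * n] -= f * d[c];
      }
    }
  }

  for (size_t t = 0; t < s.ang_i.size(); ++t) {
    int i = s.ang_i[t], j = s.ang_j[t], k = s.ang_k[t]; // j = vertex
    double a[3], bb[3], la2 = 0.0, lb2 = 0.0, ab = 0.0;
    for (int c = 0; c < 3; ++c) {
      a[c] = min_image(x[i + c * n] - x[j + c * n], L);
      bb[c] = min_image(x[k + c * n] - x[j + c * n], L);
      la2 += a[c] * a[c];
      lb2 += bb[c] * bb[c];
      ab += a[c] * bb[c];
    }
    double la = std::sqrt(la2), lb = std::sqrt(lb2);
    double ca = ab / (la * lb);
    if (ca > 1.0) ca = 1.0;
    if (ca < -1.0) ca = -1.0;
    double dca = ca - s.angc0[t];
    eterm[1] += 0.5 * s.angk[t] * dca * dca;
    double dVdca = s.angk[t] * dca;
    for (int c = 0; c < 3; ++c) {
      double gi = bb[c] / (la * lb) - ca * a[c] / la2;
      double gk = a[c] / (la * lb) - ca * bb[c] / lb2;
      F[i + c * n] -= dVdca * gi;
      F[k + c * n] -= dVdca * gk;
      F[j + c * n] += dVdca * (gi + gk);
    }
  }

  if (!s.bonded_only) {
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (s.excl.count((long long)i * n + j)) continue;
        double d[3], r2 = 0.0;
        for (int c = 0; c < 3; ++c) {
          d[c] = min_image(x[i + c * n] - x[j + c * n], L);
          r2 += d[c] * d[c];
        }
        if (r2 < min_nb2) min_nb2 = r2;
        if (r2 > s.cutoff2) continue;
        int p = 4 * s.kind[i] + s.kind[j];
        double e = s.eps[p];
        if (e == 0.0) continue;
        double sg = s.sig[p];
        double sr2 = sg * sg / r2;
        double sr6 = sr2 * sr2 * sr2;
        double sr12 = sr6 * sr6;
        double V, ffac;
        if (s.rep[p]) {
          V = 4.0 * e * sr12 - s.vshift[p];
          ffac = 48.0 * e * sr12 / r2;
          eterm[3] += V;
        } else {
          V = 4.0 * e * (sr12 - sr6) - s.vshift[p];
          ffac = 24.0 * e * (2.0 * sr12 - sr6) / r2;
          eterm[2] += V;
        }
        for (int c = 0; c < 3; ++c) {
          F[i + c * n] += ffac * d[c];
          F[j + c * n] -= ffac * d[c];
        }
      }
    }
  }
  return min_nb2;
}

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, double L, IntegerMatrix bonds,
                       NumericVector bond_k, NumericVector bond_r0,
                       IntegerMatrix angles, NumericVector ang_k,
                       NumericVector ang_cos0, IntegerVector kind,
                       NumericMatrix sig44, NumericMatrix eps44,
                       IntegerMatrix rep44, double cutoff, bool shift,
                       bool bonded_only) {
  System s = build_system(pos, L, bonds, bond_k, bond_r0, angles, ang_k,
                          ang_cos0, kind, sig44, eps44, rep44, cutoff, shift,
                          bonded_only);
  NumericMatrix F(s.n, 3);
  double eterm[4];
  double min_nb2 = compute_forces(REAL(pos), s, REAL(F), eterm);
  return List::create(
      _["bond"] = eterm[0], _["angle"] = eterm[1], _["lj"] = eterm[2],
      _["replj"] = eterm[3],
      _["total"] = eterm[0] + eterm[1] + eterm[2] + eterm[3],
      _["forces"] = F,
      _["min_nonbonded_dist"] = bonded_only ? NA_REAL : std::sqrt(min_nb2));
}

// Langevin leapfrog: full-step deterministic kick, Ornstein-Uhlenbeck
// velocity mixing (exact for the friction+noise part over dt), then drift.
// alpha = exp(-dt/tau); noise variance (1 - alpha^2) kB T / m per component.
// tau = Inf -> plain (symplectic) leapfrog, no friction, no noise.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_run_dynamics(NumericMatrix pos0, NumericMatrix vel0,
                      NumericVector mass, double L, IntegerMatrix bonds,
                      NumericVector bond_k, NumericVector bond_r0,
                      IntegerMatrix angles, NumericVector ang_k,
                      NumericVector ang_cos0, IntegerVector kind,
                      NumericMatrix sig44, NumericMatrix eps44,
                      IntegerMatrix rep44, double cutoff, bool shift,
                      bool bonded_only, bool no_interactions, double dt,
                      double tau, double temperature, int n_steps,
                      int sample_every, double t0) {
  System s = build_system(pos0, L, bonds, bond_k, bond_r0, angles, ang_k,
                          ang_cos0, kind, sig44, eps44, rep44, cutoff, shift,
                          bonded_only);
  const int n = s.n;
  std::vector<double> x(REAL(pos0), REAL(pos0) + 3 * n);
  std::vector<double> v(REAL(vel0), REAL(vel0) + 3 * n);
  std::vector<double> F(3 * n), dtm(n), sd(n);
  double eterm[4];
  double alpha = std::isfinite(tau) ? std::exp(-dt / tau) : 1.0;
  double noise2 = (1.0 - alpha * alpha) * KB * temperature;
  for (int i = 0; i < n; ++i) {
    dtm[i] = dt / mass[i];
    sd[i] = std::sqrt(noise2 / mass[i]);
  }

  int n_frames = n_steps / sample_every;
  NumericVector traj(Dimension(n, 3, n_frames));
  NumericVector vels(Dimension(n, 3, n_frames));
  NumericVector times(n_frames);

  int frame = 0;
  for (int step = 1; step <= n_steps; ++step) {
    if (!no_interactions) {
      std::fill(F.begin(), F.end(), 0.0);
      compute_forces(x.data(), s, F.data(), eterm);
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c) v[i + c * n] += F[i + c * n] * dtm[i];
    }
    if (alpha < 1.0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          v[i + c * n] = alpha * v[i + c * n] + sd[i] * norm_rand();
    }
    for (int i = 0; i < 3 * n; ++i) x[i] += v[i] * dt;

    if (step % sample_every == 0) {
      for (int i = 0; i < 3 * n; ++i) {
        if (!std::isfinite(x[i]))
          stop("non-finite coordinate at step %d (bead %d)", step,
               i % n + 1);
        traj[frame * 3 * n + i] = x[i];
        vels[frame * 3 * n + i] = v[i];
      }
      times[frame] = t0 + step * dt;
      ++frame;
    }
  }
  NumericMatrix xf(n, 3), vf(n, 3);
  std::copy(x.begin(), x.end(), REAL(xf));
  std::copy(v.begin(), v.end(), REAL(vf));
  return List::create(_["trajectory"] = traj, _["velocities"] = vels,
                      _["times"] = times, _["final_pos"] = xf,
                      _["final_vel"] = vf);
}

// All inter-chain bead pairs at minimum-image distance <= cutoff, reported
// as unique 0-based chain index pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_contact_pairs(NumericMatrix pos, double L,
                                IntegerVector chain, double cutoff) {
  const int n = pos.nrow();
  const double c2 = cutoff * cutoff;
  int n_chain = 0;
  for (int i = 0; i < n; ++i)
    if (chain[i] + 1 > n_chain) n_chain = chain[i] + 1;
  std::unordered_set<long long> seen;
  std::vector<int> ci, cj;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (chain[i] == chain[j]) continue;
      long long a = chain[i], b = chain[j];
      long long key = a < b ? a * n_chain + b : b * n_chain + a;
      if (seen.count(key)) continue;
      double r2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        double d = min_image(pos(i, c) - pos(j, c), L);
        r2 += d * d;
      }
      if (r2 <= c2) {
        seen.insert(key);
        ci.push_back(a < b ? a : b);
        cj.push_back(a < b ? b : a);
      }
    }
  }
  IntegerMatrix out(ci.size(), 2);
  for (size_t k = 0; k < ci.size(); ++k) {
    out(k, 0) = ci[k];
    out(k, 1) = cj[k];
  }
  return out;
}
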