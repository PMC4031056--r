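// Overdamped (Brownian) dynamics of sticky bead-molecules in a periodic
// cubic box. Two interaction modes:
//  - sticky: harmonic core repulsion + flat-bottom attractive well between
//    designated sticky beads of different molecules, with either stochastic
//    (Markov, rate k_off) or thermally activated (well-escape) unbinding;
//  - ljc: Lennard-Jones + (reaction-field) Coulomb for all non-excluded
//    pairs, used to cross-validate the R energy-decomposition code.
// Uses R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double min_image(double d, double box) {
  return d - box * std::round(d / box);
}

struct StickyParams {
  double eps, r_core, k_rep, r_on, w;
};

// energy and radial force magnitude (F = -dU/dr) of the sticky potential;
// `attractive` toggles the well, repulsion always acts below r_core
static inline void sticky_eval(double r, bool attractive,
                               const StickyParams &sp, double &u,
                               double &f) {
  u = 0.0; f = 0.0;
  if (r < sp.r_core) {
    double d = sp.r_core - r;
    u = 0.5 * sp.k_rep * d * d;
    f = sp.k_rep * d;  // repulsive, pushes apart (positive = outward)
  }
  if (attractive) {
    if (r < sp.r_on) {
      u -= sp.eps;
    } else if (r < sp.r_on + sp.w) {
      double s = (r - sp.r_on) / sp.w;
      u -= sp.eps * 0.5 * (1.0 + std::cos(M_PI * s));
      f -= sp.eps * 0.5 * M_PI / sp.w * std::sin(M_PI * s);
    }
  }
}

struct LjcParams {
  double cutoff, krf, crf;
  bool use_rf;
};

static inline void ljc_eval(double r, double qq, double sig, double eps,
                            const LjcParams &lp, double &u, double &f) {
  u = 0.0; f = 0.0;
  if (r > lp.cutoff) return;
  const double F_COUL = 138.935458;
  double sr2 = sig * sig / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  u = 4.0 * eps * (sr6 * sr6 - sr6);
  f = 4.0 * eps * (12.0 * sr6 * sr6 - 6.0 * sr6) / r;
  if (lp.use_rf) {
    u += F_COUL * qq * (1.0 / r + lp.krf * r * r - lp.crf);
    f += F_COUL * qq * (1.0 / (r * r) - 2.0 * lp.krf * r);
  } else {
    u += F_COUL * qq / r;
    f += F_COUL * qq / (r * r);
  }
}

// [[Rcpp::export]]
List bd_simulate_cpp(NumericMatrix x0, IntegerVector molecule,
                     LogicalVector sticky, IntegerVector is_protein,
                     NumericVector box, NumericVector D_bead, double dt,
                     int n_steps, int save_every, double kT,
                     double eps_well, double r_core, double k_rep,
                     double r_on, double w_switch, IntegerMatrix bonds,
                     double k_bond, double b0, IntegerMatrix exclusions,
                     double k_off_per_ps, double r_release, bool lj_mode,
                     NumericVector charge, NumericVector sigma,
                     NumericVector epsilon, double cutoff, double krf,
                     double crf, bool use_rf, double t0) {
  const int n = x0.nrow();
  const int n_mol = max(molecule);
  StickyParams sp{eps_well, r_core, k_rep, r_on, w_switch};
  LjcParams lp{cutoff, krf, crf, use_rf};

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = x0(i, k);

  std::vector<char> excl(static_cast<size_t>(n) * n, 0);
  for (int e = 0; e < exclusions.nrow(); ++e) {
    int i = exclusions(e, 0) - 1, j = exclusions(e, 1) - 1;
    excl[static_cast<size_t>(i) * n + j] = 1;
    excl[static_cast<size_t>(j) * n + i] = 1;
  }

  // molecule-pair state (upper triangle, index i*n_mol+j with i<j)
  std::vector<char> attr_on(static_cast<size_t>(n_mol) * n_mol, 1);
  std::vector<char> bound(static_cast<size_t>(n_mol) * n_mol, 0);
  std::vector<double> bind_time(static_cast<size_t>(n_mol) * n_mol, -1.0);
  std::vector<double> mindist(static_cast<size_t>(n_mol) * n_mol);
  const bool markov = k_off_per_ps >= 0.0;

  std::vector<int> ev_i, ev_j;
  std::vector<double> ev_bind, ev_unbind;

  const int n_frames = n_steps / save_every + 1;
  NumericMatrix frames(n_frames, 3 * n);
  NumericVector frame_time(n_frames);
  NumericMatrix frame_energy(n_frames, 3);  // pp, ps, ss

  std::vector<double> force(3 * n);
  std::vector<double> sqrt2Ddt(n);
  std::vector<double> DkT(n);
  for (int i = 0; i < n; ++i) {
    sqrt2Ddt[i] = std::sqrt(2.0 * D_bead[i] * dt);
    DkT[i] = D_bead[i] / kT * dt;
  }

  auto pair_geometry = [&](int i, int j, double d[3]) {
    double r2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      d[k] = min_image(x[3 * i + k] - x[3 * j + k], box[k]);
      r2 += d[k] * d[k];
    }
    return std::sqrt(r2);
  };

  auto save_frame = [&](int slot, double time) {
    frame_time[slot] = time;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double v = x[3 * i + k];
        frames(slot, 3 * i + k) = v - box[k] * std::floor(v / box[k]);
      }
    double epp = 0.0, eps_ = 0.0, ess = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (excl[static_cast<size_t>(i) * n + j]) continue;
        bool same = molecule[i] == molecule[j];
        if (!lj_mode && same) continue;
        double d[3];
        double r = pair_geometry(i, j, d);
        double u = 0.0, f = 0.0;
        if (lj_mode) {
          ljc_eval(r, charge[i] * charge[j],
                   std::sqrt(sigma[i] * sigma[j]),
                   std::sqrt(epsilon[i] * epsilon[j]), lp, u, f);
        } else {
          if (!(is_protein[i] && is_protein[j])) continue;
          int mi = std::min(molecule[i], molecule[j]) - 1;
          int mj = std::max(molecule[i], molecule[j]) - 1;
          bool attractive = sticky[i] && sticky[j] &&
                            attr_on[static_cast<size_t>(mi) * n_mol + mj];
          sticky_eval(r, attractive, sp, u, f);
        }
        if (is_protein[i] && is_protein[j]) epp += u;
        else if (!is_protein[i] && !is_protein[j]) ess += u;
        else eps_ += u;
      }
    }
    frame_energy(slot, 0) = epp;
    frame_energy(slot, 1) = eps_;
    frame_energy(slot, 2) = ess;
  };

  save_frame(0, t0);
  int slot = 1;

  for (int step = 1; step <= n_steps; ++step) {
    std::fill(force.begin(), force.end(), 0.0);
    std::fill(mindist.begin(), mindist.end(), 1e30);

    for (int e = 0; e < bonds.nrow(); ++e) {
      int i = bonds(e, 0) - 1, j = bonds(e, 1) - 1;
      double d[3];
      double r = pair_geometry(i, j, d);
      double fmag = -k_bond * (r - b0);  // negative when stretched
      for (int k = 0; k < 3; ++k) {
        double fk = fmag * d[k] / r;
        force[3 * i + k] += fk;
        force[3 * j + k] -= fk;
      }
    }

    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (excl[static_cast<size_t>(i) * n + j]) continue;
        bool same = molecule[i] == molecule[j];
        if (!lj_mode && same) continue;
        double d[3];
        double r = pair_geometry(i, j, d);
        double u = 0.0, fmag = 0.0;
        if (lj_mode) {
          if (r > lp.cutoff) continue;
          ljc_eval(r, charge[i] * charge[j],
                   std::sqrt(sigma[i] * sigma[j]),
                   std::sqrt(epsilon[i] * epsilon[j]), lp, u, fmag);
        } else {
          if (!(is_protein[i] && is_protein[j])) continue;
          int mi = std::min(molecule[i], molecule[j]) - 1;
          int mj = std::max(molecule[i], molecule[j]) - 1;
          size_t p = static_cast<size_t>(mi) * n_mol + mj;
          if (sticky[i] && sticky[j]) {
            if (r < mindist[p]) mindist[p] = r;
            sticky_eval(r, attr_on[p] != 0, sp, u, fmag);
          } else {
            sticky_eval(r, false, sp, u, fmag);
          }
        }
        if (fmag != 0.0 && r > 0.0) {
          for (int k = 0; k < 3; ++k) {
            double fk = fmag * d[k] / r;
            force[3 * i + k] += fk;
            force[3 * j + k] -= fk;
          }
        }
      }
    }

    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        x[3 * i + k] += DkT[i] * force[3 * i + k] +
                        sqrt2Ddt[i] * norm_rand();

    if (!lj_mode) {
      double t_now = t0 + step * dt;
      for (int mi = 0; mi < n_mol; ++mi) {
        for (int mj = mi + 1; mj < n_mol; ++mj) {
          size_t p = static_cast<size_t>(mi) * n_mol + mj;
          if (bound[p]) {
            bool unbind = false;
            if (markov) {
              if (k_off_per_ps > 0.0 && unif_rand() < k_off_per_ps * dt)
                unbind = true;
            } else if (mindist[p] > sp.r_on + sp.w) {
              unbind = true;  // thermal escape past the well edge
            }
            if (unbind) {
              bound[p] = 0;
              if (markov) attr_on[p] = 0;
              ev_i.push_back(mi + 1);
              ev_j.push_back(mj + 1);
              ev_bind.push_back(bind_time[p]);
              ev_unbind.push_back(t_now);
            }
          } else {
            if (!attr_on[p] && mindist[p] > r_release) attr_on[p] = 1;
            if (attr_on[p] && mindist[p] < sp.r_on) {
              bound[p] = 1;
              bind_time[p] = t_now;
            }
          }
        }
      }
    }

    if (step % save_every == 0) {
      save_frame(slot, t0 + step * dt);
      ++slot;
    }
  }

  // still-bound pairs at the end: censored events
  for (int mi = 0; mi < n_mol; ++mi)
    for (int mj = mi + 1; mj < n_mol; ++mj) {
      size_t p = static_cast<size_t>(mi) * n_mol + mj;
      if (bound[p]) {
        ev_i.push_back(mi + 1);
        ev_j.push_back(mj + 1);
        ev_bind.push_back(bind_time[p]);
        ev_unbind.push_back(NA_REAL);
      }
    }

  return List::create(
      _["frames"] = frames, _["times"] = frame_time,
      _["energy"] = frame_energy, _["ev_i"] = wrap(ev_i),
      _["ev_j"] = wrap(ev_j), _["ev_bind"] = wrap(ev_bind),
      _["ev_unbind"] = wrap(ev_unbind));
}
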