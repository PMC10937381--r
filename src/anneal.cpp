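#include <Rcpp.h>
using namespace Rcpp;

// Metropolis single-bead annealing of the coarse-grained bead model.
//
// Energy (reduced units, kT = 1 at T = 1):
//   bonds:      k_bond * (|d| - d0)^2
//   angles:     k_angle * theta^2          (theta = deviation from straight)
//   repulsion:  k_rep * (r_i + r_j - |d|)^2 for overlapping bead pairs
//   restraints: w_ij * k_restr * (|d| - d_contact)^2 when |d| > d_contact
//
// Moves are per-bead Gaussian displacements; cooling is geometric. Uses R's
// RNG, so results are reproducible per set.seed().

static inline double dist3(const NumericMatrix &x, int i, int j) {
  double dx = x(i, 0) - x(j, 0);
  double dy = x(i, 1) - x(j, 1);
  double dz = x(i, 2) - x(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

static double angle_energy(const NumericMatrix &x, int a, int b, int c,
                           double k_angle) {
  double v1[3], v2[3], n1 = 0.0, n2 = 0.0, dot = 0.0;
  for (int d = 0; d < 3; ++d) {
    v1[d] = x(b, d) - x(a, d);
    v2[d] = x(c, d) - x(b, d);
    n1 += v1[d] * v1[d];
    n2 += v2[d] * v2[d];
    dot += v1[d] * v2[d];
  }
  double denom = std::sqrt(n1 * n2);
  if (denom <= 0.0) return 0.0;
  double ct = dot / denom;
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  double th = std::acos(ct);
  return k_angle * th * th;
}

// [[Rcpp::export]]
List anneal_cpp(NumericMatrix coords,
                IntegerMatrix bonds, NumericVector bond_d0, double k_bond,
                IntegerMatrix angles, double k_angle,
                NumericVector radii, double k_rep,
                IntegerMatrix restr, NumericVector restr_w,
                double k_restr, double d_contact,
                int n_sweeps, double t_start, double t_end, double move_sd) {
  int n = coords.nrow();
  int nb = bonds.nrow();
  int na = angles.nrow();
  int nr = restr.nrow();
  NumericMatrix x = clone(coords);

  // adjacency: bonds / angles / restraints touching each bead
  std::vector<std::vector<int> > bead_bonds(n), bead_angles(n), bead_restr(n);
  for (int k = 0; k < nb; ++k) {
    bead_bonds[bonds(k, 0)].push_back(k);
    bead_bonds[bonds(k, 1)].push_back(k);
  }
  for (int k = 0; k < na; ++k)
    for (int c = 0; c < 3; ++c) bead_angles[angles(k, c)].push_back(k);
  for (int k = 0; k < nr; ++k) {
    bead_restr[restr(k, 0)].push_back(k);
    bead_restr[restr(k, 1)].push_back(k);
  }

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);

  // local energy of bead i against current coordinates
  auto local_energy = [&](int i) {
    double e = 0.0;
    for (size_t q = 0; q < bead_bonds[i].size(); ++q) {
      int k = bead_bonds[i][q];
      double d = dist3(x, bonds(k, 0), bonds(k, 1)) - bond_d0[k];
      e += k_bond * d * d;
    }
    for (size_t q = 0; q < bead_angles[i].size(); ++q) {
      int k = bead_angles[i][q];
      e += angle_energy(x, angles(k, 0), angles(k, 1), angles(k, 2), k_angle);
    }
    for (size_t q = 0; q < bead_restr[i].size(); ++q) {
      int k = bead_restr[i][q];
      double d = dist3(x, restr(k, 0), restr(k, 1));
      if (d > d_contact) {
        double ex = d - d_contact;
        e += restr_w[k] * k_restr * ex * ex;
      }
    }
    double cut_i = radii[i] + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = dist3(x, i, j);
      if (d < cut_i) {
        double ov = radii[i] + radii[j] - d;
        if (ov > 0.0) e += k_rep * ov * ov;
      }
    }
    return e;
  };

  auto total_energy = [&]() {
    double e = 0.0;
    for (int k = 0; k < nb; ++k) {
      double d = dist3(x, bonds(k, 0), bonds(k, 1)) - bond_d0[k];
      e += k_bond * d * d;
    }
    for (int k = 0; k < na; ++k)
      e += angle_energy(x, angles(k, 0), angles(k, 1), angles(k, 2), k_angle);
    for (int k = 0; k < nr; ++k) {
      double d = dist3(x, restr(k, 0), restr(k, 1));
      if (d > d_contact) {
        double ex = d - d_contact;
        e += restr_w[k] * k_restr * ex * ex;
      }
    }
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double ov = radii[i] + radii[j] - dist3(x, i, j);
        if (ov > 0.0) e += k_rep * ov * ov;
      }
    }
    return e;
  };

  NumericVector trace(n_sweeps);
  double cool = (n_sweeps > 1)
    ? std::pow(t_end / t_start, 1.0 / (n_sweeps - 1)) : 1.0;
  double T = t_start;
  long accepted = 0, proposed = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      double old[3] = { x(i, 0), x(i, 1), x(i, 2) };
      double e0 = local_energy(i);
      for (int d = 0; d < 3; ++d) x(i, d) = old[d] + norm_rand() * move_sd;
      double e1 = local_energy(i);
      double dE = e1 - e0;
      ++proposed;
      // cap the exponent: beyond 50 kT the acceptance probability (<2e-22)
      // is indistinguishable from zero, and extreme exp() arguments can hit
      // slow libm paths
      double r = dE / T;
      bool accept;
      if (dE <= 0.0) {
        accept = true;
      } else if (r > 50.0) {
        accept = false;
      } else {
        accept = unif_rand() < std::exp(-r);
      }
      if (accept) {
        ++accepted;
      } else {
        for (int d = 0; d < 3; ++d) x(i, d) = old[d];
      }
    }
    trace[sweep] = total_energy();
    if (!std::isfinite(trace[sweep]))
      stop("annealing diverged: non-finite energy at sweep %d", sweep + 1);
    T *= cool;
  }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      if (!std::isfinite(x(i, d))) stop("non-finite coordinates after annealing");

  return List::create(_["coords"] = x, _["energy_trace"] = trace,
                      _["acceptance"] = proposed ? (double)accepted / proposed : 0.0);
}

// Total energy of a configuration (exposed for tests and the energy report).
// [[Rcpp::export]]
double bead_energy_cpp(NumericMatrix coords,
                       IntegerMatrix bonds, NumericVector bond_d0, double k_bond,
                       IntegerMatrix angles, double k_angle,
                       NumericVector radii, double k_rep,
                       IntegerMatrix restr, NumericVector restr_w,
                       double k_restr, double d_contact) {
  NumericMatrix x = coords;
  int n = x.nrow();
  double e = 0.0;
  for (int k = 0; k < bonds.nrow(); ++k) {
    double d = dist3(x, bonds(k, 0), bonds(k, 1)) - bond_d0[k];
    e += k_bond * d * d;
  }
  for (int k = 0; k < angles.nrow(); ++k)
    e += angle_energy(x, angles(k, 0), angles(k, 1), angles(k, 2), k_angle);
  for (int k = 0; k < restr.nrow(); ++k) {
    double d = dist3(x, restr(k, 0), restr(k, 1));
    if (d > d_contact) {
      double ex = d - d_contact;
      e += restr_w[k] * k_restr * ex * ex;
    }
  }
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double ov = radii[i] + radii[j] - dist3(x, i, j);
      if (ov > 0.0) e += k_rep * ov * ov;
    }
  return e;
}
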