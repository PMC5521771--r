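// Metropolis Monte Carlo engine for the coarse-grained chitosan chain.
//
// State: one rigid pose (rotation + translation) per monomer, one (phi, psi)
// pair per glycosidic link, one 0/1 charge per monomer. Moves:
//   - pivot: re-draw one link's (phi, psi) uniformly over the allowed
//     (below-cutoff) region of its map and rigidly rotate the downstream
//     chain; accepted with min(1, exp(-(dE_map + dE_LJ + dE_DH)));
//   - titration: flip the protonation state of one titratable site; accepted
//     with min(1, exp(-(d(mu z) + d(pair DH incl. nearest neighbours)))), and
//     on acceptance the maps of the (up to) two adjacent links are swapped to
//     match the new monomer states.
// All energies in k_BT, lengths in nm. Uses R's RNG so runs are reproducible
// from set.seed(). RNG stream order per sweep: pivot (link, bin, phi jitter,
// psi jitter, acceptance), then each titration attempt (site, acceptance);
// acceptance uniforms are always drawn.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 v3(double x, double y, double z) { return {x, y, z}; }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
static inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
static inline Vec3 unit(Vec3 a) { return (1.0 / norm(a)) * a; }

// 3x3 rotation, column-major
struct Mat3 {
  double m[9];
  Vec3 mul(Vec3 v) const {
    return {m[0] * v.x + m[3] * v.y + m[6] * v.z,
            m[1] * v.x + m[4] * v.y + m[7] * v.z,
            m[2] * v.x + m[5] * v.y + m[8] * v.z};
  }
};
static inline Mat3 matmul(const Mat3 &a, const Mat3 &b) {
  Mat3 r;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i)
      r.m[i + 3 * j] = a.m[i] * b.m[3 * j] + a.m[i + 3] * b.m[1 + 3 * j] +
                       a.m[i + 6] * b.m[2 + 3 * j];
  return r;
}
static inline Mat3 transpose(const Mat3 &a) {
  Mat3 r;
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) r.m[i + 3 * j] = a.m[j + 3 * i];
  return r;
}
static inline Mat3 from_cols(Vec3 a, Vec3 b, Vec3 c) {
  Mat3 r;
  r.m[0] = a.x; r.m[1] = a.y; r.m[2] = a.z;
  r.m[3] = b.x; r.m[4] = b.y; r.m[5] = b.z;
  r.m[6] = c.x; r.m[7] = c.y; r.m[8] = c.z;
  return r;
}
// project a near-rotation onto an exact rotation (Gram-Schmidt); without
// this the scale error of the incremental pivot transform compounds
// multiplicatively over accepted moves
static inline Mat3 orthonormalize(const Mat3 &R) {
  Vec3 a = unit(v3(R.m[0], R.m[1], R.m[2]));
  Vec3 b0 = v3(R.m[3], R.m[4], R.m[5]);
  Vec3 b = unit(b0 - dot(b0, a) * a);
  return from_cols(a, b, cross(a, b));
}

struct Pose {
  Mat3 R;
  Vec3 t;
};

struct Geometry {
  Vec3 o5, c1, o1, c4, site;  // local atom coords
  Vec3 a_loc, b_loc;
  double bond_o1_c4, ang_c1_o1_c4, bond_c4_c5, ang_o1_c4_c5;
};

// matches the R-side nerf_place (negated out-of-plane component)
static Vec3 nerf(Vec3 a, Vec3 b, Vec3 c, double bond, double angle, double dih) {
  Vec3 bc = unit(c - b);
  Vec3 n = unit(cross(b - a, bc));
  Vec3 m = cross(n, bc);
  double d1 = -bond * std::cos(angle);
  double d2 = bond * std::sin(angle) * std::cos(dih);
  double d3 = -bond * std::sin(angle) * std::sin(dih);
  return c + d1 * bc + d2 * m + d3 * n;
}

static Pose pose_from_link(const Pose &p, double phi, double psi, const Geometry &g) {
  Vec3 o5 = p.R.mul(g.o5) + p.t;
  Vec3 c1 = p.R.mul(g.c1) + p.t;
  Vec3 o1 = p.R.mul(g.o1) + p.t;
  Vec3 c4p = nerf(o5, c1, o1, g.bond_o1_c4, g.ang_c1_o1_c4, phi);
  Vec3 c5p = nerf(c1, o1, c4p, g.bond_c4_c5, g.ang_o1_c4_c5, psi);
  Vec3 a_w = unit(o1 - c4p);
  Vec3 v = c5p - c4p;
  Vec3 b_w = unit(v - dot(v, a_w) * a_w);
  Mat3 Mw = from_cols(a_w, b_w, cross(a_w, b_w));
  Mat3 Ml = from_cols(g.a_loc, g.b_loc, cross(g.a_loc, g.b_loc));
  Pose out;
  out.R = matmul(Mw, transpose(Ml));
  out.t = c4p - out.R.mul(g.c4);
  return out;
}

struct MapGrid {
  const double *g;
  int np, nq;
  const int *allowed;  // 0-based linear indices (col-major: i + np * j)
  int n_allowed;
  double interp(double phi, double psi) const {
    double u = phi / TWOPI * np;
    double v = psi / TWOPI * nq;
    u -= np * std::floor(u / np);
    v -= nq * std::floor(v / nq);
    int i0 = (int)std::floor(u), j0 = (int)std::floor(v);
    double f = u - i0, h = v - j0;
    i0 %= np; j0 %= nq;
    int i1 = (i0 + 1) % np, j1 = (j0 + 1) % nq;
    return (1 - f) * (1 - h) * g[i0 + np * j0] + f * (1 - h) * g[i1 + np * j0] +
           (1 - f) * h * g[i0 + np * j1] + f * h * g[i1 + np * j1];
  }
};

static inline double wrap2pi(double x) { return x - TWOPI * std::floor(x / TWOPI); }

// [[Rcpp::export]]
List cg_run_engine(List geom_in, IntegerVector kinds, IntegerVector charges0,
                   List map_grids, List map_allowed, IntegerVector link_map_idx0,
                   IntegerMatrix state_map_idx, NumericMatrix dihedrals0,
                   double lambda_b, double kappa, double mu, double sigma,
                   double eps_kbt, double rc, bool elec_on, bool titration_on,
                   bool swap_on, bool include_bonded, bool double_count,
                   int n_sweeps, int titr_per_sweep, int log_stride,
                   bool collect_frames, bool collect_dihedrals) {
  const int dp = kinds.size();
  const int nlink = dp - 1;

  Geometry g;
  {
    NumericVector o5 = geom_in["o5"], c1 = geom_in["c1"], o1 = geom_in["o1"],
                  c4 = geom_in["c4"], st = geom_in["site"], al = geom_in["a_loc"],
                  bl = geom_in["b_loc"];
    g.o5 = v3(o5[0], o5[1], o5[2]); g.c1 = v3(c1[0], c1[1], c1[2]);
    g.o1 = v3(o1[0], o1[1], o1[2]); g.c4 = v3(c4[0], c4[1], c4[2]);
    g.site = v3(st[0], st[1], st[2]);
    g.a_loc = v3(al[0], al[1], al[2]); g.b_loc = v3(bl[0], bl[1], bl[2]);
    g.bond_o1_c4 = geom_in["bond_o1_c4"];
    g.ang_c1_o1_c4 = geom_in["angle_c1_o1_c4"];
    g.bond_c4_c5 = geom_in["bond_c4_c5"];
    g.ang_o1_c4_c5 = geom_in["angle_o1_c4_c5"];
  }

  const int nmaps = map_grids.size();
  std::vector<MapGrid> maps(nmaps);
  std::vector<NumericMatrix> grids_keep(nmaps);
  std::vector<IntegerVector> allowed_keep(nmaps);
  for (int m = 0; m < nmaps; ++m) {
    grids_keep[m] = as<NumericMatrix>(map_grids[m]);
    allowed_keep[m] = as<IntegerVector>(map_allowed[m]);
    maps[m].g = grids_keep[m].begin();
    maps[m].np = grids_keep[m].nrow();
    maps[m].nq = grids_keep[m].ncol();
    maps[m].allowed = allowed_keep[m].begin();
    maps[m].n_allowed = allowed_keep[m].size();
  }

  std::vector<int> z(charges0.begin(), charges0.end());
  std::vector<int> link_map(nlink);
  for (int k = 0; k < nlink; ++k) link_map[k] = link_map_idx0[k] - 1;
  std::vector<double> phi(nlink), psi(nlink);
  for (int k = 0; k < nlink; ++k) { phi[k] = dihedrals0(k, 0); psi[k] = dihedrals0(k, 1); }

  std::vector<int> titr;
  for (int i = 0; i < dp; ++i)
    if (kinds[i] == 1) titr.push_back(i);
  const int n_t = (int)titr.size();

  // initial geometry
  std::vector<Pose> pose(dp);
  pose[0].R = from_cols(v3(1, 0, 0), v3(0, 1, 0), v3(0, 0, 1));
  pose[0].t = v3(0, 0, 0);
  for (int k = 0; k < nlink; ++k)
    pose[k + 1] = pose_from_link(pose[k], phi[k], psi[k], g);
  std::vector<Vec3> site(dp);
  for (int i = 0; i < dp; ++i) site[i] = pose[i].R.mul(g.site) + pose[i].t;

  auto mstate = [&](int i) -> int { return kinds[i] == 0 ? 0 : (z[i] ? 2 : 1); };
  auto map_for = [&](int k) -> int {
    return state_map_idx(mstate(k), mstate(k + 1)) - 1;
  };

  auto lj = [&](double r) -> double {
    if (r > rc) return 0.0;
    double s6 = std::pow(sigma / r, 6);
    return 4.0 * eps_kbt * (s6 * s6 - s6 + 0.25);
  };
  auto dh = [&](double r) -> double { return lambda_b * std::exp(-kappa * r) / r; };

  // initial energies
  std::vector<double> e_link(nlink);
  double E_map = 0;
  for (int k = 0; k < nlink; ++k) {
    e_link[k] = maps[link_map[k]].interp(phi[k], psi[k]);
    E_map += e_link[k];
  }
  double E_lj = 0, E_dh = 0, F_pair = 0;
  for (int i = 0; i < dp; ++i)
    for (int j = i + 2; j < dp; ++j) {
      double r = norm(site[i] - site[j]);
      E_lj += lj(r);
      if (elec_on && z[i] && z[j]) E_dh += dh(r);
    }
  if (elec_on)
    for (int i = 0; i < dp; ++i)
      for (int j = i + 1; j < dp; ++j)
        if (z[i] && z[j]) F_pair += dh(norm(site[i] - site[j]));
  if (double_count) F_pair *= 2.0;
  int zsum = 0;
  for (int i = 0; i < dp; ++i) zsum += z[i];
  double F_mu = mu * zsum;
  const double pair_mult = double_count ? 2.0 : 1.0;

  long piv_att = 0, piv_acc = 0, tit_att = 0, tit_acc = 0;

  // logging
  const int n_log = n_sweeps / log_stride + 1;
  NumericMatrix log_mat(n_log, 13);
  colnames(log_mat) = CharacterVector::create(
      "step", "rg", "ree", "alpha", "e_map", "e_lj", "e_dh", "f_mu", "f_pair",
      "pivot_attempted", "pivot_accepted", "titration_attempted", "titration_accepted");
  NumericVector frames(collect_frames ? (R_xlen_t)n_log * dp * 3 : 0);
  NumericVector dtrace(collect_dihedrals ? (R_xlen_t)n_log * nlink * 2 : 0);
  int log_row = 0;

  auto log_state = [&](int sweep) {
    Vec3 cm = v3(0, 0, 0);
    for (int i = 0; i < dp; ++i) cm = cm + site[i];
    cm = (1.0 / dp) * cm;
    double rg2 = 0;
    for (int i = 0; i < dp; ++i) {
      Vec3 d = site[i] - cm;
      rg2 += dot(d, d);
    }
    double rg = std::sqrt(rg2 / dp);
    double ree = norm(site[dp - 1] - site[0]);
    double alpha = 1.0;
    if (n_t > 0) {
      int s = 0;
      for (int i : titr) s += z[i];
      alpha = 1.0 - (double)s / n_t;
    }
    double total = E_map + E_lj + E_dh + F_mu + F_pair;
    if (!std::isfinite(total))
      stop("non-finite energy at sweep %d (e_map=%g e_lj=%g e_dh=%g f=%g)",
           sweep, E_map, E_lj, E_dh, F_mu + F_pair);
    log_mat(log_row, 0) = sweep;
    log_mat(log_row, 1) = rg;
    log_mat(log_row, 2) = ree;
    log_mat(log_row, 3) = alpha;
    log_mat(log_row, 4) = E_map;
    log_mat(log_row, 5) = E_lj;
    log_mat(log_row, 6) = E_dh;
    log_mat(log_row, 7) = F_mu;
    log_mat(log_row, 8) = F_pair;
    log_mat(log_row, 9) = (double)piv_att;
    log_mat(log_row, 10) = (double)piv_acc;
    log_mat(log_row, 11) = (double)tit_att;
    log_mat(log_row, 12) = (double)tit_acc;
    if (collect_frames)
      for (int i = 0; i < dp; ++i) {
        frames[log_row + (R_xlen_t)n_log * (0 * dp + i)] = site[i].x;
        frames[log_row + (R_xlen_t)n_log * (1 * dp + i)] = site[i].y;
        frames[log_row + (R_xlen_t)n_log * (2 * dp + i)] = site[i].z;
      }
    if (collect_dihedrals)
      for (int k = 0; k < nlink; ++k) {
        dtrace[log_row + (R_xlen_t)n_log * (0 * nlink + k)] = phi[k];
        dtrace[log_row + (R_xlen_t)n_log * (1 * nlink + k)] = psi[k];
      }
    ++log_row;
  };
  log_state(0);

  std::vector<Pose> new_pose(dp);
  std::vector<Vec3> new_site(dp);

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    // ---- pivot move
    {
      ++piv_att;
      int k = (int)(unif_rand() * nlink);
      if (k >= nlink) k = nlink - 1;
      const MapGrid &mp = maps[link_map[k]];
      int pick = (int)(unif_rand() * mp.n_allowed);
      if (pick >= mp.n_allowed) pick = mp.n_allowed - 1;
      int cell = mp.allowed[pick];
      double dphi_bin = TWOPI / mp.np, dpsi_bin = TWOPI / mp.nq;
      double nphi = wrap2pi((cell % mp.np) * dphi_bin + (unif_rand() - 0.5) * dphi_bin);
      double npsi = wrap2pi((cell / mp.np) * dpsi_bin + (unif_rand() - 0.5) * dpsi_bin);
      double e_new = mp.interp(nphi, npsi);
      double d_map = e_new - e_link[k];

      new_pose[k + 1] = pose_from_link(pose[k], nphi, npsi, g);
      Mat3 A = orthonormalize(matmul(new_pose[k + 1].R, transpose(pose[k + 1].R)));
      Vec3 b = new_pose[k + 1].t - A.mul(pose[k + 1].t);
      for (int j = k + 2; j < dp; ++j) {
        new_pose[j].R = matmul(A, pose[j].R);
        new_pose[j].t = A.mul(pose[j].t) + b;
      }
      for (int j = k + 1; j < dp; ++j) new_site[j] = A.mul(site[j]) + b;

      double d_lj = 0, d_dh = 0, d_fpair = 0;
      for (int i = 0; i <= k; ++i)
        for (int j = k + 1; j < dp; ++j) {
          double r_old = norm(site[i] - site[j]);
          double r_new = norm(site[i] - new_site[j]);
          if (j - i >= 2) {
            d_lj += lj(r_new) - lj(r_old);
            if (elec_on && z[i] && z[j]) d_dh += dh(r_new) - dh(r_old);
          }
          if (elec_on && z[i] && z[j]) d_fpair += dh(r_new) - dh(r_old);
        }
      d_fpair *= pair_mult;

      double dE = d_map + d_lj + d_dh;
      double u = unif_rand();
      if (dE <= 0 || u < std::exp(-dE)) {
        ++piv_acc;
        for (int j = k + 1; j < dp; ++j) {
          pose[j] = new_pose[j];
          site[j] = new_site[j];
        }
        phi[k] = nphi; psi[k] = npsi;
        E_map += d_map; e_link[k] = e_new;
        E_lj += d_lj; E_dh += d_dh; F_pair += d_fpair;
      }
    }

    // ---- titration moves
    if (titration_on && n_t > 0) {
      for (int tmove = 0; tmove < titr_per_sweep; ++tmove) {
        ++tit_att;
        int pick = (int)(unif_rand() * n_t);
        if (pick >= n_t) pick = n_t - 1;
        int s = titr[pick];
        int znew = 1 - z[s];
        double sgn = znew ? 1.0 : -1.0;
        double d_mu = sgn * mu;
        double d_pair = 0, d_dh_conf = 0;
        if (elec_on) {
          for (int j = 0; j < dp; ++j) {
            if (j == s || !z[j]) continue;
            double u = dh(norm(site[s] - site[j]));
            d_pair += u;
            if (std::abs(j - s) >= 2) d_dh_conf += u;
          }
          d_pair *= sgn * pair_mult;
          d_dh_conf *= sgn;
        }
        double d_map = 0;
        int nm_left = -1, nm_right = -1;
        double el_new = 0, er_new = 0;
        if (swap_on || include_bonded) {
          int zsave = z[s];
          z[s] = znew;
          if (s > 0) {
            nm_left = map_for(s - 1);
            el_new = maps[nm_left].interp(phi[s - 1], psi[s - 1]);
            d_map += el_new - e_link[s - 1];
          }
          if (s < dp - 1) {
            nm_right = map_for(s);
            er_new = maps[nm_right].interp(phi[s], psi[s]);
            d_map += er_new - e_link[s];
          }
          z[s] = zsave;
        }
        double dF = d_mu + d_pair + (include_bonded ? d_map : 0.0);
        double u = unif_rand();
        if (dF <= 0 || u < std::exp(-dF)) {
          ++tit_acc;
          z[s] = znew;
          F_mu += d_mu; F_pair += d_pair; E_dh += d_dh_conf;
          if (swap_on) {
            if (s > 0) {
              link_map[s - 1] = nm_left;
              E_map += el_new - e_link[s - 1];
              e_link[s - 1] = el_new;
            }
            if (s < dp - 1) {
              link_map[s] = nm_right;
              E_map += er_new - e_link[s];
              e_link[s] = er_new;
            }
          }
        }
      }
    }

    // periodic refresh: rebuild geometry and energy caches from scratch so
    // residual floating-point drift of the incremental updates stays bounded
    if (sweep % 2000 == 0) {
      for (int k = 0; k < nlink; ++k)
        pose[k + 1] = pose_from_link(pose[k], phi[k], psi[k], g);
      for (int i = 0; i < dp; ++i) site[i] = pose[i].R.mul(g.site) + pose[i].t;
      E_map = 0;
      for (int k = 0; k < nlink; ++k) {
        e_link[k] = maps[link_map[k]].interp(phi[k], psi[k]);
        E_map += e_link[k];
      }
      E_lj = 0; E_dh = 0; F_pair = 0;
      for (int i = 0; i < dp; ++i)
        for (int j = i + 2; j < dp; ++j) {
          double r = norm(site[i] - site[j]);
          E_lj += lj(r);
          if (elec_on && z[i] && z[j]) E_dh += dh(r);
        }
      if (elec_on)
        for (int i = 0; i < dp; ++i)
          for (int j = i + 1; j < dp; ++j)
            if (z[i] && z[j]) F_pair += dh(norm(site[i] - site[j]));
      F_pair *= pair_mult;
      zsum = 0;
      for (int i = 0; i < dp; ++i) zsum += z[i];
      F_mu = mu * zsum;
    }

    if (sweep % log_stride == 0) log_state(sweep);
  }

  NumericMatrix dih_out(nlink, 2);
  for (int k = 0; k < nlink; ++k) { dih_out(k, 0) = phi[k]; dih_out(k, 1) = psi[k]; }
  IntegerVector z_out(dp), lm_out(nlink);
  for (int i = 0; i < dp; ++i) z_out[i] = z[i];
  for (int k = 0; k < nlink; ++k) lm_out[k] = link_map[k] + 1;
  NumericMatrix sites_out(dp, 3);
  for (int i = 0; i < dp; ++i) {
    sites_out(i, 0) = site[i].x; sites_out(i, 1) = site[i].y; sites_out(i, 2) = site[i].z;
  }
  if (collect_frames) frames.attr("dim") = IntegerVector::create(n_log, dp, 3);
  if (collect_dihedrals) dtrace.attr("dim") = IntegerVector::create(n_log, nlink, 2);

  return List::create(
      _["log"] = log_mat, _["dihedrals"] = dih_out, _["charges"] = z_out,
      _["link_map_idx"] = lm_out, _["sites"] = sites_out,
      _["frames"] = frames, _["dihedral_trace"] = dtrace,
      _["energies"] = NumericVector::create(
          _["e_map"] = E_map, _["e_lj"] = E_lj, _["e_dh"] = E_dh,
          _["f_mu"] = F_mu, _["f_pair"] = F_pair),
      _["counters"] = NumericVector::create(
          _["pivot_attempted"] = (double)piv_att, _["pivot_accepted"] = (double)piv_acc,
          _["titration_attempted"] = (double)tit_att,
          _["titration_accepted"] = (double)tit_acc));
}
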