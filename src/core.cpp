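#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Segment-segment minimum distance (closest-point parametrisation with
// clamping; robust for parallel and degenerate segments). Segments are given
// by centre, unit direction and half-length.
// ---------------------------------------------------------------------------

static inline double clamp01s(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static double seg_seg_dist(const double* p1, const double* u1, double l1,
                           const double* p2, const double* u2, double l2) {
  // minimise |(p1 + s u1) - (p2 + t u2)|, s in [-l1,l1], t in [-l2,l2]
  double r[3] = {p1[0] - p2[0], p1[1] - p2[1], p1[2] - p2[2]};
  double a = l1 * l1;                    // |d1|^2 with d1 = u1*l1 ... use raw
  double b = 0.0, c = l2 * l2, d = 0.0, e = 0.0;
  // work with unnormalised direction vectors d1 = u1, d2 = u2 over s,t in
  // [-l1,l1] x [-l2,l2]; since |u|=1, a = 1, c = 1.
  a = 1.0; c = 1.0;
  for (int k = 0; k < 3; ++k) {
    b += u1[k] * u2[k];
    d += u1[k] * r[k];
    e += u2[k] * r[k];
  }
  double denom = a * c - b * b;          // = 1 - cos^2 >= 0
  double s, t;
  if (denom > 1e-14) {
    s = clamp01s((b * e - c * d) / denom, -l1, l1);
  } else {
    s = 0.0;                             // parallel: pick centre, fix below
  }
  t = b * s + e;                         // minimiser of t given s (c = 1)
  if (t < -l2) t = -l2; else if (t > l2) t = l2;
  // re-minimise s given clamped t
  s = b * t - d;
  if (s < -l1) s = -l1; else if (s > l1) s = l1;
  // one more t pass for correctness after s clamp
  t = b * s + e;
  if (t < -l2) t = -l2; else if (t > l2) t = l2;
  double dd = 0.0;
  for (int k = 0; k < 3; ++k) {
    double diff = r[k] + s * u1[k] - t * u2[k];
    dd += diff * diff;
  }
  return std::sqrt(dd);
}

// [[Rcpp::export]]
double seg_dist_cpp(NumericVector p1, NumericVector u1, double l1,
                    NumericVector p2, NumericVector u2, double l2) {
  return seg_seg_dist(p1.begin(), u1.begin(), l1, p2.begin(), u2.begin(), l2);
}

// ---------------------------------------------------------------------------
// Wall feasibility: endpoints between the plates and inside the outer wall
// (sufficient by convexity), axis segment clear of the inner post.
// ---------------------------------------------------------------------------

// distance from the origin to the 2D segment (x,y) +- s*(ux,uy), s in [-l,l]
static double seg_point_dist2d(double x, double y, double ux, double uy,
                               double l) {
  double uu = ux * ux + uy * uy;
  double s;
  if (uu < 1e-24) s = 0.0;
  else {
    s = -(x * ux + y * uy) / uu;
    if (s < -l) s = -l; else if (s > l) s = l;
  }
  double px = x + s * ux, py = y + s * uy;
  return std::sqrt(px * px + py * py);
}

static bool wall_ok(const double* c, const double* u, double L, double D,
                    double Router, double Rinner, double H) {
  double hl = 0.5 * L;
  for (int sgn = -1; sgn <= 1; sgn += 2) {
    double ex = c[0] + sgn * hl * u[0];
    double ey = c[1] + sgn * hl * u[1];
    double ez = c[2] + sgn * hl * u[2];
    if (ez < 0.5 * D - 1e-12 || ez > H - 0.5 * D + 1e-12) return false;
    double rr = std::sqrt(ex * ex + ey * ey);
    if (rr > Router - 0.5 * D + 1e-12) return false;
  }
  if (Rinner > 0.0) {
    double dmin = seg_point_dist2d(c[0], c[1], u[0], u[1], hl);
    if (dmin < Rinner + 0.5 * D - 1e-12) return false;
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector wall_ok_cpp(NumericMatrix centers, NumericMatrix us, double L,
                          double D, double Router, double Rinner, double H) {
  int n = centers.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    double c[3] = {centers(i, 0), centers(i, 1), centers(i, 2)};
    double u[3] = {us(i, 0), us(i, 1), us(i, 2)};
    out[i] = wall_ok(c, u, L, D, Router, Rinner, H);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Cell list over the chamber footprint. Edge >= L + D guarantees any
// axis-overlapping pair sits in adjacent cells.
// ---------------------------------------------------------------------------

struct CellList {
  int ncell;            // cells per side
  double edge, origin;  // origin = -Router
  std::vector<std::vector<int> > cells;
  std::vector<int> cell_of;

  void build(const std::vector<double>& cx, const std::vector<double>& cy,
             double Router, double range) {
    ncell = (int)std::floor(2.0 * Router / range);
    if (ncell < 1) ncell = 1;
    if (ncell > 64) ncell = 64;
    edge = 2.0 * Router / ncell;
    origin = -Router;
    cells.assign(ncell * ncell, std::vector<int>());
    int n = (int)cx.size();
    cell_of.assign(n, 0);
    for (int i = 0; i < n; ++i) {
      int k = index_of(cx[i], cy[i]);
      cell_of[i] = k;
      cells[k].push_back(i);
    }
  }
  int index_of(double x, double y) const {
    int ix = (int)std::floor((x - origin) / edge);
    int iy = (int)std::floor((y - origin) / edge);
    if (ix < 0) ix = 0; if (ix >= ncell) ix = ncell - 1;
    if (iy < 0) iy = 0; if (iy >= ncell) iy = ncell - 1;
    return ix + ncell * iy;
  }
  void move(int i, double x, double y) {
    int k = index_of(x, y);
    if (k == cell_of[i]) return;
    std::vector<int>& v = cells[cell_of[i]];
    for (size_t j = 0; j < v.size(); ++j)
      if (v[j] == i) { v[j] = v.back(); v.pop_back(); break; }
    cells[k].push_back(i);
    cell_of[i] = k;
  }
  template <typename F>
  void for_neighbours(double x, double y, F f) const {
    int ix = (int)std::floor((x - origin) / edge);
    int iy = (int)std::floor((y - origin) / edge);
    for (int dx = -1; dx <= 1; ++dx) {
      int jx = ix + dx;
      if (jx < 0 || jx >= ncell) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int jy = iy + dy;
        if (jy < 0 || jy >= ncell) continue;
        const std::vector<int>& v = cells[jx + ncell * jy];
        for (size_t j = 0; j < v.size(); ++j) f(v[j]);
      }
    }
  }
};

// Simulation state shared by init and run.
struct SimState {
  std::vector<double> cx, cy, cz, ux, uy, uz;
  double L, D, Router, Rinner, H;
  bool planar;
  CellList cl;

  int n() const { return (int)cx.size(); }

  void rebuild_cells() { cl.build(cx, cy, Router, L + D + 1e-9); }

  // min axis distance from rod i (with trial coords) to all others
  double min_dist_trial(int i, const double* c, const double* u,
                        double cutoff) const {
    double hl = 0.5 * L, best = 1e30;
    double pref = L + cutoff;  // centre-distance prefilter
    double pref2 = pref * pref;
    const SimState* self = this;
    cl.for_neighbours(c[0], c[1], [&](int j) {
      if (j == i) return;
      double dx = c[0] - self->cx[j], dy = c[1] - self->cy[j],
             dz = c[2] - self->cz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 >= pref2) return;
      double p2[3] = {self->cx[j], self->cy[j], self->cz[j]};
      double u2[3] = {self->ux[j], self->uy[j], self->uz[j]};
      double d = seg_seg_dist(c, u, hl, p2, u2, hl);
      if (d < best) best = d;
    });
    return best;
  }

  // total pair-overlap depth of rod i at trial coordinates w.r.t. diam
  double overlap_sum_trial(int i, const double* c, const double* u,
                           double diam) const {
    double hl = 0.5 * L;
    double pref = L + diam;
    double pref2 = pref * pref;
    double sum = 0.0;
    const SimState* self = this;
    cl.for_neighbours(c[0], c[1], [&](int j) {
      if (j == i) return;
      double dx = c[0] - self->cx[j], dy = c[1] - self->cy[j],
             dz = c[2] - self->cz[j];
      if (dx * dx + dy * dy + dz * dz >= pref2) return;
      double p2[3] = {self->cx[j], self->cy[j], self->cz[j]};
      double u2[3] = {self->ux[j], self->uy[j], self->uz[j]};
      double d = seg_seg_dist(c, u, hl, p2, u2, hl);
      if (d < diam) sum += diam - d;
    });
    return sum;
  }

  bool overlap_free_trial(int i, const double* c, const double* u,
                          double diam) const {
    double hl = 0.5 * L;
    double pref = L + diam;
    double pref2 = pref * pref;
    bool ok = true;
    const SimState* self = this;
    cl.for_neighbours(c[0], c[1], [&](int j) {
      if (!ok || j == i) return;
      double dx = c[0] - self->cx[j], dy = c[1] - self->cy[j],
             dz = c[2] - self->cz[j];
      if (dx * dx + dy * dy + dz * dz >= pref2) return;
      double p2[3] = {self->cx[j], self->cy[j], self->cz[j]};
      double u2[3] = {self->ux[j], self->uy[j], self->uz[j]};
      if (seg_seg_dist(c, u, hl, p2, u2, hl) < diam) ok = false;
    });
    return ok;
  }
};

static void random_unit_vector(bool planar, double* u) {
  if (planar) {
    double phi = 2.0 * M_PI * unif_rand();
    u[0] = std::cos(phi); u[1] = std::sin(phi); u[2] = 0.0;
  } else {
    double z = 2.0 * unif_rand() - 1.0;
    double phi = 2.0 * M_PI * unif_rand();
    double s = std::sqrt(std::max(0.0, 1.0 - z * z));
    u[0] = s * std::cos(phi); u[1] = s * std::sin(phi); u[2] = z;
  }
}

// rotate u by angle about a random axis (3D) or in-plane (planar)
static void propose_rotation(const double* u, double dr, bool planar,
                             double* out) {
  if (planar) {
    double th = std::atan2(u[1], u[0]) + dr * (2.0 * unif_rand() - 1.0);
    out[0] = std::cos(th); out[1] = std::sin(th); out[2] = 0.0;
    return;
  }
  double ax[3];
  random_unit_vector(false, ax);
  double ang = dr * unif_rand();
  double ca = std::cos(ang), sa = std::sin(ang);
  double dot = ax[0] * u[0] + ax[1] * u[1] + ax[2] * u[2];
  double cr[3] = {ax[1] * u[2] - ax[2] * u[1],
                  ax[2] * u[0] - ax[0] * u[2],
                  ax[0] * u[1] - ax[1] * u[0]};
  double nn = 0.0;
  for (int k = 0; k < 3; ++k) {
    out[k] = u[k] * ca + cr[k] * sa + ax[k] * dot * (1.0 - ca);
    nn += out[k] * out[k];
  }
  nn = std::sqrt(nn);
  for (int k = 0; k < 3; ++k) out[k] /= nn;
}

// largest eigenvalue of the symmetric 3x3 nematic order tensor
static double lambda_max_sym3(double a11, double a22, double a33, double a12,
                              double a13, double a23) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-30) return std::max(a11, std::max(a22, a33));
  double q = (a11 + a22 + a33) / 3.0;
  double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
              (a33 - q) * (a33 - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
  double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
  double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                b13 * (b12 * b23 - b22 * b13);
  double r = detB / 2.0;
  if (r < -1.0) r = -1.0; if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  return q + 2.0 * p * std::cos(phi);
}

static double global_lambda_max(const SimState& st) {
  int n = st.n();
  double a11 = 0, a22 = 0, a33 = 0, a12 = 0, a13 = 0, a23 = 0;
  for (int i = 0; i < n; ++i) {
    a11 += st.ux[i] * st.ux[i]; a22 += st.uy[i] * st.uy[i];
    a33 += st.uz[i] * st.uz[i]; a12 += st.ux[i] * st.uy[i];
    a13 += st.ux[i] * st.uz[i]; a23 += st.uy[i] * st.uz[i];
  }
  a11 /= n; a22 /= n; a33 /= n; a12 /= n; a13 /= n; a23 /= n;
  return lambda_max_sym3(1.5 * a11 - 0.5, 1.5 * a22 - 0.5, 1.5 * a33 - 0.5,
                         1.5 * a12, 1.5 * a13, 1.5 * a23);
}

static void state_from_R(SimState& st, NumericMatrix centers, NumericMatrix us,
                         double L, double D, double Router, double Rinner,
                         double H, bool planar) {
  int n = centers.nrow();
  st.cx.resize(n); st.cy.resize(n); st.cz.resize(n);
  st.ux.resize(n); st.uy.resize(n); st.uz.resize(n);
  for (int i = 0; i < n; ++i) {
    st.cx[i] = centers(i, 0); st.cy[i] = centers(i, 1); st.cz[i] = centers(i, 2);
    st.ux[i] = us(i, 0); st.uy[i] = us(i, 1); st.uz[i] = us(i, 2);
  }
  st.L = L; st.D = D; st.Router = Router; st.Rinner = Rinner; st.H = H;
  st.planar = planar;
  st.rebuild_cells();
}

static List state_to_R(const SimState& st) {
  int n = st.n();
  NumericMatrix centers(n, 3), us(n, 3);
  for (int i = 0; i < n; ++i) {
    centers(i, 0) = st.cx[i]; centers(i, 1) = st.cy[i]; centers(i, 2) = st.cz[i];
    us(i, 0) = st.ux[i]; us(i, 1) = st.uy[i]; us(i, 2) = st.uz[i];
  }
  return List::create(_["centers"] = centers, _["us"] = us);
}

// propose a joint translation+rotation for rod i; returns accepted flag,
// committing the move when accepted. diam is the overlap diameter in force.
static bool do_move(SimState& st, int i, double dt, double dr, double diam,
                    bool grow_rule, double dnext, double grow_temp = 0.02) {
  double c[3] = {st.cx[i] + dt * (2.0 * unif_rand() - 1.0),
                 st.cy[i] + dt * (2.0 * unif_rand() - 1.0),
                 st.cz[i] + (st.planar ? 0.0 : dt * (2.0 * unif_rand() - 1.0))};
  double u0[3] = {st.ux[i], st.uy[i], st.uz[i]};
  double u[3];
  propose_rotation(u0, dr, st.planar, u);
  if (!wall_ok(c, u, st.L, st.D, st.Router, st.Rinner, st.H)) return false;
  bool ok;
  if (!grow_rule) {
    ok = st.overlap_free_trial(i, c, u, diam);
  } else {
    // inflation: descent on the rod's total overlap depth at the trial
    // diameter, so rods can slide past each other while residual overlaps
    // shrink; clear moves skip the second scan
    double e1 = st.overlap_sum_trial(i, c, u, dnext);
    if (e1 == 0.0) {
      ok = true;
    } else {
      double c0[3] = {st.cx[i], st.cy[i], st.cz[i]};
      double e0 = st.overlap_sum_trial(i, c0, u0, dnext);
      // Metropolis on overlap depth, gated to rods that already overlap:
      // stuck rods can wiggle uphill out of strict-descent deadlocks, but
      // clean rods can never re-create overlaps, so stage clearance is
      // reached and then stays
      ok = (e1 <= e0 + 1e-12) ||
           (e0 > 0.0 && unif_rand() < std::exp(-(e1 - e0) / grow_temp));
    }
  }
  if (ok) {
    st.cx[i] = c[0]; st.cy[i] = c[1]; st.cz[i] = c[2];
    st.ux[i] = u[0]; st.uy[i] = u[1]; st.uz[i] = u[2];
    st.cl.move(i, c[0], c[1]);
  }
  return ok;
}

// all-pairs validity via cell list: smallest axis separation
static double global_min_pair_dist(const SimState& st) {
  double best = 1e30;
  int n = st.n();
  double hl = 0.5 * st.L;
  for (int i = 0; i < n; ++i) {
    double c[3] = {st.cx[i], st.cy[i], st.cz[i]};
    double u[3] = {st.ux[i], st.uy[i], st.uz[i]};
    const SimState& s = st;
    st.cl.for_neighbours(c[0], c[1], [&](int j) {
      if (j <= i) return;
      double dx = c[0] - s.cx[j], dy = c[1] - s.cy[j], dz = c[2] - s.cz[j];
      double pref = s.L + s.D;
      if (dx * dx + dy * dy + dz * dz >= pref * pref) return;
      double p2[3] = {s.cx[j], s.cy[j], s.cz[j]};
      double u2[3] = {s.ux[j], s.uy[j], s.uz[j]};
      double d = seg_seg_dist(c, u, hl, p2, u2, hl);
      if (d < best) best = d;
    });
  }
  return best;
}

// [[Rcpp::export]]
double min_pair_dist_cpp(NumericMatrix centers, NumericMatrix us, double L,
                         double D, double Router, double Rinner, double H,
                         bool planar) {
  if (centers.nrow() < 2) return R_PosInf;
  SimState st;
  state_from_R(st, centers, us, L, D, Router, Rinner, H, planar);
  return global_min_pair_dist(st);
}

// ---------------------------------------------------------------------------
// Initialisation: sequential insertion at a reduced diameter, then staged
// inflation with relaxation sweeps, then step-size auto-tuning.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mc_init_cpp(int N, double L, double D, double Router, double Rinner,
                 double H, bool planar, double d0, double dstep,
                 int relax_sweeps, int max_stage_sweeps, int insert_tries,
                 double dt0, double dr0, int tune_sweeps) {
  RNGScope scope;
  SimState st;
  st.L = L; st.D = D; st.Router = Router; st.Rinner = Rinner; st.H = H;
  st.planar = planar;
  st.cx.clear(); st.cy.clear(); st.cz.clear();
  st.ux.clear(); st.uy.clear(); st.uz.clear();
  st.rebuild_cells();

  double dcur = std::min(D, d0);
  double hl = 0.5 * L;
  // sequential insertion at diameter dcur (walls at full D throughout)
  for (int i = 0; i < N; ++i) {
    bool placed = false;
    for (int t = 0; t < insert_tries; ++t) {
      double rmax = Router - 0.5 * D;
      double rmin2 = 0.0;
      // sample centres uniformly over the annular footprint
      double rr = std::sqrt(rmin2 + unif_rand() * (rmax * rmax - rmin2));
      double phi = 2.0 * M_PI * unif_rand();
      double c[3];
      c[0] = rr * std::cos(phi);
      c[1] = rr * std::sin(phi);
      c[2] = planar ? 0.5 * H : 0.5 * D + unif_rand() * (H - D);
      double u[3];
      random_unit_vector(planar, u);
      if (!wall_ok(c, u, L, D, Router, Rinner, H)) continue;
      if (!st.overlap_free_trial(-1, c, u, dcur)) continue;
      st.cx.push_back(c[0]); st.cy.push_back(c[1]); st.cz.push_back(c[2]);
      st.ux.push_back(u[0]); st.uy.push_back(u[1]); st.uz.push_back(u[2]);
      st.rebuild_cells();
      placed = true;
      break;
    }
    if (!placed) {
      return List::create(_["ok"] = false, _["stage"] = "insert",
                          _["n_placed"] = (int)st.cx.size(),
                          _["diameter"] = dcur);
    }
  }

  // staged inflation to full diameter; the committed diameter advances to
  // the current global clearance, so partial progress within a stage counts
  double dt = dt0, dr = dr0;
  int stalled = 0;
  while (dcur < D - 1e-12) {
    double dnext = std::min(D, dcur + dstep);
    for (int s = 0; s < relax_sweeps; ++s) {
      int n = st.n();
      for (int m = 0; m < n; ++m) {
        int i = (int)std::floor(unif_rand() * n);
        if (i >= n) i = n - 1;
        do_move(st, i, dt, dr, dcur, true, dnext);
      }
    }
    double gm = st.n() < 2 ? D : global_min_pair_dist(st);
    if (gm > dcur + 1e-9) {
      dcur = std::min(dnext, gm);
      stalled = 0;
    } else {
      stalled += relax_sweeps;
      if (stalled >= max_stage_sweeps) {
        return List::create(_["ok"] = false, _["stage"] = "inflate",
                            _["n_placed"] = st.n(),
                            _["diameter"] = std::min(dcur, gm));
      }
    }
  }

  // auto-tune step sizes toward 30-40% acceptance at full diameter
  for (int s = 0; s < tune_sweeps; ++s) {
    int n = st.n();
    if (n == 0) break;
    int acc = 0;
    for (int m = 0; m < n; ++m) {
      int i = (int)std::floor(unif_rand() * n);
      if (i >= n) i = n - 1;
      if (do_move(st, i, dt, dr, D, false, D)) ++acc;
    }
    double rate = (double)acc / n;
    double f = rate > 0.40 ? 1.15 : (rate < 0.30 ? 0.85 : 1.0);
    dt = std::min(std::max(dt * f, 1e-4), hl);
    dr = std::min(std::max(dr * f, 1e-4), M_PI);
  }

  List out = state_to_R(st);
  out["ok"] = true;
  out["diameter"] = dcur;
  out["delta_t"] = dt;
  out["delta_r"] = dr;
  return out;
}

// ---------------------------------------------------------------------------
// Production run: n_sweeps sweeps of N single-particle moves; order-parameter
// series each sweep; snapshots every sample_every sweeps.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mc_run_cpp(NumericMatrix centers, NumericMatrix us, double L, double D,
                double Router, double Rinner, double H, bool planar,
                int n_sweeps, double delta_t, double delta_r,
                int sample_every, int audit_every) {
  RNGScope scope;
  SimState st;
  state_from_R(st, centers, us, L, D, Router, Rinner, H, planar);
  int n = st.n();
  NumericVector lambda(n_sweeps);
  std::vector<int> snap_sweeps;
  List snaps;
  long long accepted = 0, attempted = 0;
  for (int sw = 1; sw <= n_sweeps; ++sw) {
    for (int m = 0; m < n; ++m) {
      int i = (int)std::floor(unif_rand() * n);
      if (i >= n) i = n - 1;
      if (do_move(st, i, delta_t, delta_r, D, false, D)) ++accepted;
      ++attempted;
    }
    lambda[sw - 1] = n > 0 ? global_lambda_max(st) : NA_REAL;
    if (audit_every > 0 && sw % audit_every == 0 && n > 1) {
      if (global_min_pair_dist(st) < D)
        stop("validity audit failed at sweep %d", sw);
    }
    if (sample_every > 0 && sw % sample_every == 0) {
      snaps.push_back(state_to_R(st));
      snap_sweeps.push_back(sw);
    }
  }
  List fin = state_to_R(st);
  return List::create(_["centers"] = fin["centers"], _["us"] = fin["us"],
                      _["lambda"] = lambda, _["snapshots"] = snaps,
                      _["snap_sweeps"] = wrap(snap_sweeps),
                      _["acceptance"] = attempted > 0 ?
                        (double)accepted / (double)attempted : NA_REAL);
}

// single-move interface (commits on acceptance); i is 0-based
// [[Rcpp::export]]
List attempt_move_cpp(NumericMatrix centers, NumericMatrix us, double L,
                      double D, double Router, double Rinner, double H,
                      bool planar, int i, double delta_t, double delta_r) {
  RNGScope scope;
  SimState st;
  state_from_R(st, centers, us, L, D, Router, Rinner, H, planar);
  if (i < 0 || i >= st.n()) stop("rod index out of range");
  bool acc = do_move(st, i, delta_t, delta_r, D, false, D);
  List out = state_to_R(st);
  out["accepted"] = acc;
  return out;
}

// proposal-only acceptance probe from a frozen configuration
// [[Rcpp::export]]
double acceptance_probe_cpp(NumericMatrix centers, NumericMatrix us, double L,
                            double D, double Router, double Rinner, double H,
                            bool planar, int n_trials, double delta_t,
                            double delta_r) {
  RNGScope scope;
  SimState st;
  state_from_R(st, centers, us, L, D, Router, Rinner, H, planar);
  int n = st.n();
  if (n == 0) return NA_REAL;
  int acc = 0;
  for (int t = 0; t < n_trials; ++t) {
    int i = (int)std::floor(unif_rand() * n);
    if (i >= n) i = n - 1;
    double c[3] = {st.cx[i] + delta_t * (2.0 * unif_rand() - 1.0),
                   st.cy[i] + delta_t * (2.0 * unif_rand() - 1.0),
                   st.cz[i] + (planar ? 0.0
                                      : delta_t * (2.0 * unif_rand() - 1.0))};
    double u0[3] = {st.ux[i], st.uy[i], st.uz[i]};
    double u[3];
    propose_rotation(u0, delta_r, planar, u);
    if (wall_ok(c, u, L, D, Router, Rinner, H) &&
        st.overlap_free_trial(i, c, u, D))
      ++acc;
  }
  return (double)acc / n_trials;
}

// [[Rcpp::export]]
double lambda_max_cpp(NumericMatrix us) {
  int n = us.nrow();
  if (n == 0) stop("empty configuration");
  double a11 = 0, a22 = 0, a33 = 0, a12 = 0, a13 = 0, a23 = 0;
  for (int i = 0; i < n; ++i) {
    a11 += us(i, 0) * us(i, 0); a22 += us(i, 1) * us(i, 1);
    a33 += us(i, 2) * us(i, 2); a12 += us(i, 0) * us(i, 1);
    a13 += us(i, 0) * us(i, 2); a23 += us(i, 1) * us(i, 2);
  }
  a11 /= n; a22 /= n; a33 /= n; a12 /= n; a13 /= n; a23 /= n;
  return lambda_max_sym3(1.5 * a11 - 0.5, 1.5 * a22 - 0.5, 1.5 * a33 - 0.5,
                         1.5 * a12, 1.5 * a13, 1.5 * a23);
}

// ---------------------------------------------------------------------------
// Minimal single-constant 2D Q-tensor relaxation with Dirichlet anchoring.
// q1, q2 are the two independent components of the symmetric traceless Q.
// interior cells evolve; defined-but-not-interior cells are held fixed.
// ---------------------------------------------------------------------------

static double q2d_energy(const std::vector<double>& q1,
                         const std::vector<double>& q2,
                         const std::vector<int>& def, int nx, int ny, double h,
                         double a2, double a4, double K) {
  double E = 0.0, h2 = h * h;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int k = i + nx * j;
      if (!def[k]) continue;
      double P = q1[k] * q1[k] + q2[k] * q2[k];
      E += (a2 * P + a4 * P * P) * h2;   // (a2/2) trQ^2 + (a4/4)(trQ^2)^2
      if (i + 1 < nx && def[k + 1]) {
        double d1 = q1[k + 1] - q1[k], d2 = q2[k + 1] - q2[k];
        E += K * (d1 * d1 + d2 * d2);    // (K/2)|dQ|^2 = K(|dq1|^2+|dq2|^2)
      }
      if (j + 1 < ny && def[k + nx]) {
        double d1 = q1[k + nx] - q1[k], d2 = q2[k + nx] - q2[k];
        E += K * (d1 * d1 + d2 * d2);
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List relax_q2d_cpp(NumericVector q1_in, NumericVector q2_in,
                   IntegerVector defined, IntegerVector interior, int nx,
                   int ny, double h, double a2, double a4, double K,
                   double step, double tol, int max_iter, int check_every) {
  std::vector<double> q1(q1_in.begin(), q1_in.end());
  std::vector<double> q2(q2_in.begin(), q2_in.end());
  std::vector<int> def(defined.begin(), defined.end());
  std::vector<int> inter(interior.begin(), interior.end());
  int ncell = nx * ny;
  std::vector<double> g1(ncell), g2(ncell);
  std::vector<double> trace;
  double E_prev = q2d_energy(q1, q2, def, nx, ny, h, a2, a4, K);
  trace.push_back(E_prev);
  bool converged = false;
  int it = 0;
  double h2 = h * h;
  for (it = 1; it <= max_iter; ++it) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int k = i + nx * j;
        if (!inter[k]) continue;
        // 5-point Laplacian; undefined neighbours mirror the centre (zero
        // normal flux) -- interior cells normally have all neighbours defined
        double c1 = q1[k], c2 = q2[k];
        double l1 = 0.0, l2 = 0.0;
        int kk;
        kk = k - 1;  if (i > 0 && def[kk]) { l1 += q1[kk] - c1; l2 += q2[kk] - c2; }
        kk = k + 1;  if (i + 1 < nx && def[kk]) { l1 += q1[kk] - c1; l2 += q2[kk] - c2; }
        kk = k - nx; if (j > 0 && def[kk]) { l1 += q1[kk] - c1; l2 += q2[kk] - c2; }
        kk = k + nx; if (j + 1 < ny && def[kk]) { l1 += q1[kk] - c1; l2 += q2[kk] - c2; }
        double P = c1 * c1 + c2 * c2;
        double bulk = 2.0 * (a2 + 2.0 * a4 * P);
        g1[k] = bulk * c1 - 2.0 * K * l1 / h2;
        g2[k] = bulk * c2 - 2.0 * K * l2 / h2;
      }
    }
    for (int k = 0; k < ncell; ++k) {
      if (!inter[k]) continue;
      q1[k] -= step * g1[k];
      q2[k] -= step * g2[k];
    }
    if (it % check_every == 0) {
      double E = q2d_energy(q1, q2, def, nx, ny, h, a2, a4, K);
      trace.push_back(E);
      double per_step = (E_prev - E) / check_every;
      if (per_step < tol && per_step > -tol) { converged = true; break; }
      E_prev = E;
    }
  }
  return List::create(_["q1"] = wrap(q1), _["q2"] = wrap(q2),
                      _["energy"] = wrap(trace), _["iterations"] = it,
                      _["converged"] = converged);
}
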