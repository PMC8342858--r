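// Core numerics for the sphere-packed neuropil simulator.
//
// Units: micrometres (um) for length, milliseconds (ms) for time,
// um^2/ms for diffusion coefficients, throughout.
//
// All randomness comes from R's RNG (unif_rand), so every exported
// routine is reproducible from set.seed() on the R side. Draw order is
// fixed and documented next to each loop.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

namespace {

// Uniform-grid cell list over the arena cube [-half, half]^3. Each sphere
// is registered in every cell its bounding box -- inflated by `pad` --
// touches, so any query about "spheres whose (pad-expanded) surface could
// reach point p" only needs the single cell containing p.
struct Grid {
  double half = 0.0;
  double cell = 0.05;
  int n = 1;                     // cells per axis
  std::vector<double> sx, sy, sz, sr;
  std::vector<double> rin2, rout2;  // (r -/+ pad)^2, for shell tests
  std::vector<int> start;        // CSR offsets, length n^3 + 1
  std::vector<int> items;        // sphere indices

  int nsph() const { return static_cast<int>(sx.size()); }

  int clampi(int i) const { return i < 0 ? 0 : (i >= n ? n - 1 : i); }
  int cellOf(double v) const {
    return clampi(static_cast<int>(std::floor((v + half) / cell)));
  }
  int idx(int ix, int iy, int iz) const { return (ix * n + iy) * n + iz; }
};

Grid build_grid(const NumericMatrix& spheres, double half, double pad,
                double cell) {
  Grid g;
  g.half = half;
  g.cell = cell;
  g.n = std::max(1, static_cast<int>(std::ceil(2.0 * half / cell)));
  const int m = spheres.nrow();
  g.sx.resize(m); g.sy.resize(m); g.sz.resize(m); g.sr.resize(m);
  g.rin2.resize(m); g.rout2.resize(m);
  for (int j = 0; j < m; ++j) {
    g.sx[j] = spheres(j, 0);
    g.sy[j] = spheres(j, 1);
    g.sz[j] = spheres(j, 2);
    g.sr[j] = spheres(j, 3);
    const double rin = std::max(g.sr[j] - pad, 0.0);
    const double rout = g.sr[j] + pad;
    g.rin2[j] = rin * rin;
    g.rout2[j] = rout * rout;
  }
  const int ncell = g.n * g.n * g.n;
  std::vector<int> count(ncell, 0);
  auto cellRange = [&](int j, int lo[3], int hi[3]) {
    const double reach = g.sr[j] + pad;
    lo[0] = g.cellOf(g.sx[j] - reach); hi[0] = g.cellOf(g.sx[j] + reach);
    lo[1] = g.cellOf(g.sy[j] - reach); hi[1] = g.cellOf(g.sy[j] + reach);
    lo[2] = g.cellOf(g.sz[j] - reach); hi[2] = g.cellOf(g.sz[j] + reach);
  };
  int lo[3], hi[3];
  for (int j = 0; j < m; ++j) {
    cellRange(j, lo, hi);
    for (int ix = lo[0]; ix <= hi[0]; ++ix)
      for (int iy = lo[1]; iy <= hi[1]; ++iy)
        for (int iz = lo[2]; iz <= hi[2]; ++iz)
          ++count[g.idx(ix, iy, iz)];
  }
  g.start.assign(ncell + 1, 0);
  for (int c = 0; c < ncell; ++c) g.start[c + 1] = g.start[c] + count[c];
  g.items.resize(g.start[ncell]);
  std::vector<int> cursor(g.start.begin(), g.start.end() - 1);
  for (int j = 0; j < m; ++j) {
    cellRange(j, lo, hi);
    for (int ix = lo[0]; ix <= hi[0]; ++ix)
      for (int iy = lo[1]; iy <= hi[1]; ++iy)
        for (int iz = lo[2]; iz <= hi[2]; ++iz)
          g.items[cursor[g.idx(ix, iy, iz)]++] = j;
  }
  return g;
}

// Fast endpoint classification against the spheres in the endpoint's cell
// (grid must be built with pad = catchment): returns -1 on penetration
// deeper than the catchment shell, j >= 0 for the nearest catchment-shell
// sphere (its signed surface distance written to *sd), -2 when clear of
// all spheres.
inline int classify_point(const Grid& g, double x, double y, double z,
                          double* sd) {
  const int c = g.idx(g.cellOf(x), g.cellOf(y), g.cellOf(z));
  int best = -2;
  double bestgap = std::numeric_limits<double>::infinity();
  for (int k = g.start[c]; k < g.start[c + 1]; ++k) {
    const int j = g.items[k];
    const double dx = x - g.sx[j], dy = y - g.sy[j], dz = z - g.sz[j];
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < g.rin2[j]) return -1;
    if (d2 <= g.rout2[j]) {
      const double d = std::sqrt(d2) - g.sr[j];
      if (std::fabs(d) < bestgap) { bestgap = std::fabs(d); best = j; *sd = d; }
    }
  }
  return best;
}

inline bool inside_any(const Grid& g, double x, double y, double z) {
  const int c = g.idx(g.cellOf(x), g.cellOf(y), g.cellOf(z));
  for (int k = g.start[c]; k < g.start[c + 1]; ++k) {
    const int j = g.items[k];
    const double dx = x - g.sx[j], dy = y - g.sy[j], dz = z - g.sz[j];
    if (dx * dx + dy * dy + dz * dz < g.sr[j] * g.sr[j]) return true;
  }
  return false;
}

// Synaptic cleft: two reflecting discs of radius R at z = +-H (H = height/2),
// centred on the origin, axis +z. Particles never bind to the discs.
struct Cleft {
  bool present = false;
  double R = 0.0;   // disc radius, um
  double H = 0.0;   // half-height, um
};

Cleft as_cleft(const NumericVector& v) {
  Cleft c;
  if (v.size() == 2) { c.present = true; c.R = v[0]; c.H = v[1]; }
  return c;
}

// Does the segment old -> cand cross either disc within its radius?
inline bool crosses_disc(const Cleft& c, const double* o, const double* p) {
  if (!c.present) return false;
  for (int s = 0; s < 2; ++s) {
    const double plane = s == 0 ? c.H : -c.H;
    const double a = o[2] - plane, b = p[2] - plane;
    if ((a > 0.0 && b > 0.0) || (a < 0.0 && b < 0.0)) continue;
    const double denom = p[2] - o[2];
    if (denom == 0.0) continue;  // moving within the plane: no crossing
    const double f = (plane - o[2]) / denom;
    const double xc = o[0] + f * (p[0] - o[0]);
    const double yc = o[1] + f * (p[1] - o[1]);
    if (xc * xc + yc * yc <= c.R * c.R) return true;
  }
  return false;
}

// Distance from a point to a (zero-thickness) disc.
inline double disc_dist(const Cleft& c, int which, double x, double y,
                        double z) {
  const double plane = which == 0 ? c.H : -c.H;
  const double rho = std::sqrt(x * x + y * y);
  const double dr = rho > c.R ? rho - c.R : 0.0;
  const double dz = z - plane;
  return std::sqrt(dr * dr + dz * dz);
}

inline bool sphere_hits_cleft(const Cleft& c, double x, double y, double z,
                              double r) {
  if (!c.present) return false;
  const double rho = std::sqrt(x * x + y * y);
  const double dr = rho > c.R ? rho - c.R : 0.0;
  const double az = std::fabs(z);
  const double dz = az > c.H ? az - c.H : 0.0;
  return dr * dr + dz * dz < r * r;
}

enum MoveCode { MOVE_FREE = 0, MOVE_BIND = 1, MOVE_REJECT = 2,
                MOVE_ESCAPE = 3 };

// Resolve one candidate endpoint. `cand` is modified in place (boundary
// fold, or projection onto the capture surface). Consumes one extra
// uniform draw if (and only if) the endpoint lies in a catchment shell.
inline int classify_move(const Grid& g, const Cleft& cleft, double half,
                         const double* oldp, double* cand, double p_bind,
                         double catchment, int boundary_mode) {
  for (int a = 0; a < 3; ++a) {
    if (cand[a] > half) {
      if (boundary_mode == 1) return MOVE_ESCAPE;
      cand[a] = 2.0 * half - cand[a];
    } else if (cand[a] < -half) {
      if (boundary_mode == 1) return MOVE_ESCAPE;
      cand[a] = -2.0 * half - cand[a];
    }
  }
  if (crosses_disc(cleft, oldp, cand)) return MOVE_REJECT;
  double sd = 0.0;
  const int jmin = classify_point(g, cand[0], cand[1], cand[2], &sd);
  if (jmin == -1) return MOVE_REJECT;
  if (jmin >= 0) {
    // surface encounter inside the +-catchment shell: a Bernoulli draw
    // decides capture; otherwise the collision is elastic, i.e. the move
    // is rejected if (and only if) the endpoint penetrates the surface
    if (unif_rand() < p_bind) {
      const double cx = g.sx[jmin], cy = g.sy[jmin], cz = g.sz[jmin];
      double vx = cand[0] - cx, vy = cand[1] - cy, vz = cand[2] - cz;
      double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
      if (nv == 0.0) { vx = 1.0; vy = 0.0; vz = 0.0; nv = 1.0; }
      const double r = g.sr[jmin];
      cand[0] = cx + r * vx / nv;
      cand[1] = cy + r * vy / nv;
      cand[2] = cz + r * vz / nv;
      return MOVE_BIND;
    }
    return sd < 0.0 ? MOVE_REJECT : MOVE_FREE;
  }
  return MOVE_FREE;
}

}  // namespace

// Sample n sphere centres uniformly in the arena cube with radii uniform in
// [rmin, rmax], rejecting spheres that contain the origin (if avoid_origin)
// or intersect the cleft cylinder (if cleft = c(radius, half_height)).
// Draw order per attempt: cx, cy, cz, r.
// [[Rcpp::export]]
NumericMatrix cpp_sample_spheres(int n, double half, double rmin, double rmax,
                                 bool avoid_origin, NumericVector cleft) {
  RNGScope scope;
  const Cleft cl = as_cleft(cleft);
  NumericMatrix out(n, 4);
  long long attempts = 0;
  const long long max_attempts = 1000LL * std::max(n, 1) + 1000LL;
  for (int i = 0; i < n; ++i) {
    for (;;) {
      if (++attempts > max_attempts)
        stop("sphere rejection sampling failed to place %d spheres", n);
      const double x = (2.0 * unif_rand() - 1.0) * half;
      const double y = (2.0 * unif_rand() - 1.0) * half;
      const double z = (2.0 * unif_rand() - 1.0) * half;
      const double r = rmin + unif_rand() * (rmax - rmin);
      if (avoid_origin && x * x + y * y + z * z <= r * r) continue;
      if (sphere_hits_cleft(cl, x, y, z, r)) continue;
      out(i, 0) = x; out(i, 1) = y; out(i, 2) = z; out(i, 3) = r;
      break;
    }
  }
  return out;
}

// Monte Carlo estimate of the occupied volume fraction beta: the fraction
// of uniformly scattered test points falling inside at least one sphere.
// Draw order per point: x, y, z.
// [[Rcpp::export]]
double cpp_estimate_beta(NumericMatrix spheres, double half, int n_points,
                         double cell = 0.05) {
  RNGScope scope;
  const Grid g = build_grid(spheres, half, 0.0, cell);
  long long inside = 0;
  for (int i = 0; i < n_points; ++i) {
    const double x = (2.0 * unif_rand() - 1.0) * half;
    const double y = (2.0 * unif_rand() - 1.0) * half;
    const double z = (2.0 * unif_rand() - 1.0) * half;
    if (inside_any(g, x, y, z)) ++inside;
  }
  return static_cast<double>(inside) / static_cast<double>(n_points);
}

// Signed distance to the nearest obstacle surface (sphere or cleft disc)
// for each query point. Sphere distances are |p - c| - r (negative inside);
// disc distances are always >= 0. ids: 1-based sphere index, -1 for the
// +z disc, -2 for the -z disc, 0 when there is no obstacle at all.
// Expanding-shell search over the grid; exact (terminates only once no
// closer cell can exist).
// [[Rcpp::export]]
List cpp_nearest_surface(NumericMatrix spheres, double half,
                         NumericVector cleft, NumericMatrix points,
                         double cell = 0.05) {
  const Grid g = build_grid(spheres, half, 0.0, cell);
  const Cleft cl = as_cleft(cleft);
  const int np = points.nrow();
  NumericVector dist(np);
  IntegerVector id(np);
  for (int i = 0; i < np; ++i) {
    const double x = points(i, 0), y = points(i, 1), z = points(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bestid = 0;
    const int cx = g.cellOf(x), cy = g.cellOf(y), cz = g.cellOf(z);
    for (int s = 0; s < g.n; ++s) {
      if (s > 0 && (s - 1) * g.cell > std::fabs(best)) break;
      bool any_cell = false;
      const int xlo = cx - s, xhi = cx + s;
      const int ylo = cy - s, yhi = cy + s;
      const int zlo = cz - s, zhi = cz + s;
      for (int ix = xlo; ix <= xhi; ++ix) {
        if (ix < 0 || ix >= g.n) continue;
        for (int iy = ylo; iy <= yhi; ++iy) {
          if (iy < 0 || iy >= g.n) continue;
          for (int iz = zlo; iz <= zhi; ++iz) {
            if (iz < 0 || iz >= g.n) continue;
            // only the surface of the Chebyshev shell
            if (s > 0 && ix != xlo && ix != xhi && iy != ylo && iy != yhi &&
                iz != zlo && iz != zhi)
              continue;
            any_cell = true;
            const int c = g.idx(ix, iy, iz);
            for (int k = g.start[c]; k < g.start[c + 1]; ++k) {
              const int j = g.items[k];
              const double dx = x - g.sx[j], dy = y - g.sy[j],
                           dz = z - g.sz[j];
              const double d =
                  std::sqrt(dx * dx + dy * dy + dz * dz) - g.sr[j];
              if (std::fabs(d) < std::fabs(best)) { best = d; bestid = j + 1; }
            }
          }
        }
      }
      if (!any_cell && s > 0 && (s - 1) * g.cell > 2.0 * half) break;
    }
    if (cl.present) {
      for (int w = 0; w < 2; ++w) {
        const double d = disc_dist(cl, w, x, y, z);
        if (d < std::fabs(best)) { best = d; bestid = -(w + 1); }
      }
    }
    dist[i] = best;
    id[i] = bestid;
  }
  return List::create(_["distance"] = dist, _["id"] = id);
}

// Resolve a single proposed move with reject-and-redraw semantics: the
// first attempt uses the supplied candidate; each retry (up to max_retries)
// redraws the displacement as scale * U(-1,1) * delta1d per axis.
// [[Rcpp::export]]
List cpp_resolve_move(NumericMatrix spheres, double half, NumericVector cleft,
                      NumericVector old_position,
                      NumericVector candidate_position, double p_bind,
                      double catchment, double delta1d, double scale,
                      int boundary_mode, int max_retries,
                      double cell = 0.05) {
  RNGScope scope;
  const Grid g = build_grid(spheres, half, catchment, cell);
  const Cleft cl = as_cleft(cleft);
  double oldp[3] = {old_position[0], old_position[1], old_position[2]};
  double cand[3] = {candidate_position[0], candidate_position[1],
                    candidate_position[2]};
  int code = classify_move(g, cl, half, oldp, cand, p_bind, catchment,
                           boundary_mode);
  int attempt = 1;
  while (code == MOVE_REJECT && attempt <= max_retries) {
    for (int a = 0; a < 3; ++a)
      cand[a] = oldp[a] + scale * (2.0 * unif_rand() - 1.0) * delta1d;
    code = classify_move(g, cl, half, oldp, cand, p_bind, catchment,
                         boundary_mode);
    ++attempt;
  }
  NumericVector newp(3);
  if (code == MOVE_REJECT) {          // retries exhausted: rest this step
    newp[0] = oldp[0]; newp[1] = oldp[1]; newp[2] = oldp[2];
  } else {
    newp[0] = cand[0]; newp[1] = cand[1]; newp[2] = cand[2];
  }
  return List::create(_["new_position"] = newp,
                      _["became_bound"] = code == MOVE_BIND,
                      _["escaped"] = code == MOVE_ESCAPE,
                      _["rested"] = code == MOVE_REJECT);
}

// Propagate the ensemble for n_steps time steps.
//
// status codes: 0 free, 1 bound, 2 escaped (absorb-count mode only).
// Per free particle per attempt the draw order is dx, dy, dz; one extra
// uniform is consumed on a catchment encounter. sphere_bindable: for
// per-sphere binding mode, a 0/1 flag per sphere (length 0 = all bindable
// with per-encounter probability p_bind; otherwise flagged spheres capture
// with probability 1 and unflagged never do).
//
// Returns checkpointed snapshots, a sampled time course (time, bound and
// escaped fractions, and the mean squared displacement of free particles
// from the origin, used to verify the effective diffusion coefficient),
// and the final ensemble state.
// [[Rcpp::export]]
List cpp_run_sim(NumericMatrix spheres, double half, NumericVector cleft,
                 NumericMatrix init_pos, IntegerVector init_status,
                 NumericVector init_bind_time, double t0, double D, double dt,
                 int n_steps, double p_bind, double catchment,
                 double step_scale, int boundary_mode,
                 IntegerVector checkpoint_steps, int sample_every,
                 int max_retries, IntegerVector sphere_bindable,
                 double cell = 0.05) {
  RNGScope scope;
  const Grid g = build_grid(spheres, half, catchment, cell);
  const Cleft cl = as_cleft(cleft);
  const int n = init_pos.nrow();
  const double delta1d = std::sqrt(2.0 * D * dt);
  const bool per_sphere = sphere_bindable.size() > 0;

  std::vector<double> px(n), py(n), pz(n), btime(n);
  std::vector<int> status(n);
  for (int i = 0; i < n; ++i) {
    px[i] = init_pos(i, 0); py[i] = init_pos(i, 1); pz[i] = init_pos(i, 2);
    status[i] = init_status[i];
    btime[i] = init_bind_time[i];
  }

  const int n_cp = checkpoint_steps.size();
  List cps(n_cp);
  int next_cp = 0;

  std::vector<double> tc_t, tc_bound, tc_esc, tc_msd;
  std::vector<int> tc_nfree;
  auto sample_tc = [&](double t) {
    int nb = 0, ne = 0, nf = 0;
    double msd = 0.0;
    for (int i = 0; i < n; ++i) {
      if (status[i] == 1) ++nb;
      else if (status[i] == 2) ++ne;
      else {
        ++nf;
        msd += px[i] * px[i] + py[i] * py[i] + pz[i] * pz[i];
      }
    }
    tc_t.push_back(t);
    tc_bound.push_back(static_cast<double>(nb) / n);
    tc_esc.push_back(static_cast<double>(ne) / n);
    tc_msd.push_back(nf > 0 ? msd / nf : NA_REAL);
    tc_nfree.push_back(nf);
  };
  auto snapshot = [&](double t) {
    NumericMatrix pos(n, 3);
    IntegerVector st(n);
    NumericVector bt(n);
    for (int i = 0; i < n; ++i) {
      pos(i, 0) = px[i]; pos(i, 1) = py[i]; pos(i, 2) = pz[i];
      st[i] = status[i];
      bt[i] = btime[i];
    }
    return List::create(_["time"] = t, _["positions"] = pos,
                        _["status"] = st, _["bind_time"] = bt);
  };

  sample_tc(t0);
  while (next_cp < n_cp && checkpoint_steps[next_cp] == 0) {
    cps[next_cp] = snapshot(t0);
    ++next_cp;
  }

  double oldp[3], cand[3];
  for (int s = 1; s <= n_steps; ++s) {
    const double t = t0 + s * dt;
    for (int i = 0; i < n; ++i) {
      if (status[i] != 0) continue;
      oldp[0] = px[i]; oldp[1] = py[i]; oldp[2] = pz[i];
      int code = MOVE_REJECT;
      for (int attempt = 0; attempt <= max_retries; ++attempt) {
        cand[0] = oldp[0] + step_scale * (2.0 * unif_rand() - 1.0) * delta1d;
        cand[1] = oldp[1] + step_scale * (2.0 * unif_rand() - 1.0) * delta1d;
        cand[2] = oldp[2] + step_scale * (2.0 * unif_rand() - 1.0) * delta1d;
        if (per_sphere) {
          // capture decided by the identity of the encountered sphere
          for (int a = 0; a < 3; ++a) {
            if (cand[a] > half) {
              if (boundary_mode == 1) { code = MOVE_ESCAPE; break; }
              cand[a] = 2.0 * half - cand[a];
            } else if (cand[a] < -half) {
              if (boundary_mode == 1) { code = MOVE_ESCAPE; break; }
              cand[a] = -2.0 * half - cand[a];
            }
          }
          if (code == MOVE_ESCAPE) break;
          if (crosses_disc(cl, oldp, cand)) { code = MOVE_REJECT; continue; }
          double sd = 0.0;
          const int jmin = classify_point(g, cand[0], cand[1], cand[2], &sd);
          if (jmin == -1) { code = MOVE_REJECT; continue; }
          if (jmin >= 0) {
            if (sphere_bindable[jmin] == 1) {
              const double cx = g.sx[jmin], cy = g.sy[jmin], cz = g.sz[jmin];
              double vx = cand[0] - cx, vy = cand[1] - cy, vz = cand[2] - cz;
              double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
              if (nv == 0.0) { vx = 1.0; nv = 1.0; }
              cand[0] = cx + g.sr[jmin] * vx / nv;
              cand[1] = cy + g.sr[jmin] * vy / nv;
              cand[2] = cz + g.sr[jmin] * vz / nv;
              code = MOVE_BIND;
              break;
            }
            // non-astroglial surface: elastic, reject only on penetration
            if (sd < 0.0) { code = MOVE_REJECT; continue; }
            code = MOVE_FREE;
            break;
          }
          code = MOVE_FREE;
          break;
        }
        code = classify_move(g, cl, half, oldp, cand, p_bind, catchment,
                             boundary_mode);
        if (code != MOVE_REJECT) break;
      }
      if (code == MOVE_REJECT) continue;  // deadlocked: rest this step
      if (code == MOVE_ESCAPE) { status[i] = 2; continue; }
      px[i] = cand[0]; py[i] = cand[1]; pz[i] = cand[2];
      if (code == MOVE_BIND) {
        status[i] = 1;
        btime[i] = t;
      }
    }
    if (sample_every > 0 && s % sample_every == 0) sample_tc(t);
    while (next_cp < n_cp && checkpoint_steps[next_cp] == s) {
      cps[next_cp] = snapshot(t);
      ++next_cp;
    }
  }
  if (sample_every > 0 && n_steps % sample_every != 0) sample_tc(t0 + n_steps * dt);

  NumericMatrix fpos(n, 3);
  IntegerVector fst(n);
  NumericVector fbt(n);
  for (int i = 0; i < n; ++i) {
    fpos(i, 0) = px[i]; fpos(i, 1) = py[i]; fpos(i, 2) = pz[i];
    fst[i] = status[i];
    fbt[i] = btime[i];
  }
  DataFrame tc = DataFrame::create(
      _["time"] = tc_t, _["bound_fraction"] = tc_bound,
      _["escaped_fraction"] = tc_esc, _["msd_free"] = tc_msd,
      _["n_free"] = tc_nfree);
  return List::create(_["checkpoints"] = cps, _["timecourse"] = tc,
                      _["positions"] = fpos, _["status"] = fst,
                      _["bind_time"] = fbt,
                      _["time"] = t0 + n_steps * dt);
}
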