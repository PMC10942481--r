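#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#ifndef DTFAC
#define DTFAC 0.35
#endif
#ifndef DMAXFAC
#define DMAXFAC 1.0
#endif
#ifndef SKINFAC
#define SKINFAC 1.0
#endif
#ifndef REBUILD_GAP
#define REBUILD_GAP 6
#endif
using namespace Rcpp;

// Linked-cell neighbor structure shared by the overlap counter, the
// relaxation loop, coordination numbers and distance histograms.

// Counting-sort cell layout: beads are reordered cell by cell into
// contiguous arrays, so the pair sweep touches memory sequentially.
struct SortedCells {
  double cell, x0, y0, z0;
  int nx, ny, nz, n;
  std::vector<int> start;        // per-cell range into the sorted arrays
  std::vector<int> order;        // sorted slot -> original bead index
  std::vector<double> sx, sy, sz;
  std::vector<int> nonempty;     // ids of occupied cells, ascending

  inline int clampi(int v, int hi) const {
    return v < 0 ? 0 : (v >= hi ? hi - 1 : v);
  }
  void build(const double *x, const double *y, const double *z, int n_,
             double cell_size) {
    n = n_;
    cell = cell_size;
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    x0 = xmin; y0 = ymin; z0 = zmin;
    nx = std::max(1, (int)((xmax - xmin) / cell) + 1);
    ny = std::max(1, (int)((ymax - ymin) / cell) + 1);
    nz = std::max(1, (int)((zmax - zmin) / cell) + 1);
    size_t ncell = (size_t)nx * ny * nz;
    std::vector<int> cid(n);
    start.assign(ncell + 1, 0);
    for (int i = 0; i < n; ++i) {
      int ix = clampi((int)((x[i] - x0) / cell), nx);
      int iy = clampi((int)((y[i] - y0) / cell), ny);
      int iz = clampi((int)((z[i] - z0) / cell), nz);
      cid[i] = (ix * ny + iy) * nz + iz;
      ++start[cid[i] + 1];
    }
    nonempty.clear();
    for (size_t c = 0; c < ncell; ++c) {
      if (start[c + 1] > 0) nonempty.push_back((int)c);
      start[c + 1] += start[c];
    }
    order.assign(n, 0);
    sx.assign(n, 0.0); sy.assign(n, 0.0); sz.assign(n, 0.0);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) {
      int slot = fill[cid[i]]++;
      order[slot] = i;
      sx[slot] = x[i]; sy[slot] = y[i]; sz[slot] = z[i];
    }
  }
};

// Apply f(i, j, r2) to every unordered pair with distance^2 < cut2.
// kdiv subdivides the cell edge (cut/kdiv): 1 for short contact cutoffs
// (near one bead per cell), 2-3 for long histogram cutoffs where coarse
// cells would visit too many distant pairs.
template <typename F>
static void for_each_pair(const double *x, const double *y, const double *z,
                          int n, double cut, F f, int kdiv = 1) {
  SortedCells cl;
  double cs = cut / kdiv;
  cl.build(x, y, z, n, cs);
  double cut2 = cut * cut;
  // half-space offsets pruned by minimum cell-to-cell distance
  std::vector<int> offs;
  for (int dx = -kdiv; dx <= kdiv; ++dx)
    for (int dy = -kdiv; dy <= kdiv; ++dy)
      for (int dz = -kdiv; dz <= kdiv; ++dz) {
        bool half = dx > 0 || (dx == 0 && (dy > 0 || (dy == 0 && dz > 0)));
        if (!half) continue;
        double mx = std::max(0, std::abs(dx) - 1) * cs;
        double my = std::max(0, std::abs(dy) - 1) * cs;
        double mz = std::max(0, std::abs(dz) - 1) * cs;
        if (mx*mx + my*my + mz*mz > cut2) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  int noff = (int)offs.size() / 3;
  for (int c : cl.nonempty) {
    int s = cl.start[c], e = cl.start[c + 1];
    int iz = c % cl.nz, iy = (c / cl.nz) % cl.ny, ix = c / (cl.nz * cl.ny);
    // same-cell pairs
    for (int a = s; a < e; ++a)
      for (int b = a + 1; b < e; ++b) {
        double dx = cl.sx[a]-cl.sx[b], dy = cl.sy[a]-cl.sy[b],
               dz = cl.sz[a]-cl.sz[b];
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < cut2) f(cl.order[a], cl.order[b], r2);
      }
    // cross-cell pairs over the half-space offsets
    for (int k = 0; k < noff; ++k) {
      int jx = ix + offs[3*k], jy = iy + offs[3*k+1], jz = iz + offs[3*k+2];
      if (jx < 0 || jx >= cl.nx || jy < 0 || jy >= cl.ny ||
          jz < 0 || jz >= cl.nz) continue;
      int c2 = (jx * cl.ny + jy) * cl.nz + jz;
      int s2 = cl.start[c2], e2 = cl.start[c2 + 1];
      for (int a = s; a < e; ++a)
        for (int b = s2; b < e2; ++b) {
          double dx = cl.sx[a]-cl.sx[b], dy = cl.sy[a]-cl.sy[b],
                 dz = cl.sz[a]-cl.sz[b];
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 < cut2) f(cl.order[a], cl.order[b], r2);
        }
    }
  }
}

// [[Rcpp::export]]
int count_overlaps_cpp(NumericMatrix pos, double ro) {
  int n = pos.nrow();
  if (n < 2) return 0;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
  long count = 0;
  for_each_pair(x.data(), y.data(), z.data(), n, 2.0 * ro,
                [&](int, int, double) { ++count; });
  return (int)count;
}

// [[Rcpp::export]]
IntegerVector coordination_cpp(NumericMatrix pos, double radius) {
  int n = pos.nrow();
  IntegerVector cn(n);
  if (n < 2) return cn;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
  for_each_pair(x.data(), y.data(), z.data(), n, radius,
                [&](int i, int j, double) { cn[i]++; cn[j]++; });
  return cn;
}

// [[Rcpp::export]]
double min_pair_distance_cpp(NumericMatrix pos, double cutoff) {
  // smallest pair distance below cutoff; +Inf if none
  int n = pos.nrow();
  if (n < 2) return R_PosInf;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
  double best = R_PosInf;
  for_each_pair(x.data(), y.data(), z.data(), n, cutoff,
                [&](int, int, double r2) { best = std::min(best, r2); });
  return std::isfinite(best) ? std::sqrt(best) : R_PosInf;
}

// Distance histogram from reference beads (0-based indices) to all beads.
// breaks are uniform: dr spacing from 0 to r_max.  Self-pairs excluded;
// each ordered pair (ref, other) counts once.
// [[Rcpp::export]]
NumericVector dist_hist_cpp(NumericMatrix pos, IntegerVector refs,
                            double dr, double r_max) {
  int n = pos.nrow();
  int nb = (int)std::ceil(r_max / dr);
  NumericVector hist(nb);
  std::vector<char> is_ref(n, 0);
  for (int k = 0; k < refs.size(); ++k) is_ref[refs[k]] = 1;
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
  for_each_pair(x.data(), y.data(), z.data(), n, r_max,
                [&](int i, int j, double r2) {
                  if (!is_ref[i] && !is_ref[j]) return;
                  int b = (int)(std::sqrt(r2) / dr);
                  if (b >= nb) b = nb - 1;
                  double w = (is_ref[i] ? 1.0 : 0.0) + (is_ref[j] ? 1.0 : 0.0);
                  hist[b] += w;
                }, 3);
  return hist;
}

// Overdamped zero/low-temperature relaxation of the bead chain.
//
// Soft-core pair repulsion E = k_rep (range - r)^2 for r < range, where
// range = 2 ro (1 + margin): the small margin keeps a restoring force
// alive at the contact distance itself, so bond tension cannot pin pairs
// at an infinitesimal overlap.  Harmonic bonds E = k_bond (r - r0)^2
// along the chain path, reflecting spherical confinement at rc about the
// origin.  Positions move down the gradient (step gamma, per-step
// displacement capped at 0.5 ro); the loop stops the moment no pair is
// closer than 2 ro.
// method 0: damped inertial MD with FIRE adaptive time-stepping (fast,
//           the production path); method 1: plain overdamped descent
//           (strictly energy-decreasing at temperature 0).
// [[Rcpp::export]]
List relax_cpp(NumericMatrix pos_in, NumericVector rest_len, double ro,
               double rc, double k_rep, double k_bond, double gamma,
               int max_iter, double temperature, double margin, int method) {
  int n = pos_in.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i]=pos_in(i,0); y[i]=pos_in(i,1); z[i]=pos_in(i,2); }
  std::vector<double> fx(n), fy(n), fz(n);
  double two_ro = 2.0 * ro;
  double range = two_ro * (1.0 + margin);
  double two_ro2 = two_ro * two_ro;
  double dmax = (method == 0 ? DMAXFAC : 0.5) * ro;  // stability cap per iteration
  double noise = std::sqrt(2.0 * gamma * temperature);
  std::vector<double> energy_trace;
  energy_trace.reserve(256);
  int iter = 0;
  long overlaps = -1;

  // FIRE state (Bitzek et al. scheme)
  std::vector<double> vx, vy, vz;
  double dt = 0.0, fire_a = 0.1;
  int n_pos = 0;
  const double f_inc = 1.1, f_dec = 0.5, a_start = 0.1, f_a = 0.99;
  double dt_max = 0.0;
  if (method == 0) {
    vx.assign(n, 0.0); vy.assign(n, 0.0); vz.assign(n, 0.0);
    dt = gamma;            // gamma doubles as the initial timestep
    // keep dt * omega well below the harmonic stability bound
    dt_max = DTFAC / std::sqrt(2.0 * std::max(k_rep, k_bond));
    if (dt > dt_max) dt = dt_max;
  }

  // Verlet pair list with a skin radius: rebuilt only when the two
  // largest accumulated displacements could let an unlisted pair enter
  // the force range.  Termination is always verified on a fresh list.
  double skin = SKINFAC * ro;
  double list_cut = range + skin;
  std::vector<int> pi, pj;
  std::vector<double> acc_disp(n, 0.0);
  bool need_rebuild = true, fresh = false, force_rebuild = true;
  int since_rebuild = 0;
  const int rebuild_gap = REBUILD_GAP;  // tolerate briefly stale lists

  for (iter = 0; iter < max_iter; ++iter) {
    // descent mode keeps the list exact so the energy trace is a true
    // descent; FIRE tolerates briefly stale lists between rebuilds
    if (need_rebuild &&
        (force_rebuild || method == 1 || since_rebuild >= rebuild_gap)) {
      pi.clear(); pj.clear();
      for_each_pair(x.data(), y.data(), z.data(), n, list_cut,
                    [&](int i, int j, double) { pi.push_back(i); pj.push_back(j); });
      std::fill(acc_disp.begin(), acc_disp.end(), 0.0);
      need_rebuild = false;
      force_rebuild = false;
      since_rebuild = 0;
      fresh = true;
    } else {
      fresh = false;
      ++since_rebuild;
    }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double energy = 0.0;
    long ov = 0;
    double range2 = range * range;
    for (size_t k = 0; k < pi.size(); ++k) {
      int i = pi[k], j = pj[k];
      double ddx = x[i]-x[j], ddy = y[i]-y[j], ddz = z[i]-z[j];
      double r2 = ddx*ddx + ddy*ddy + ddz*ddz;
      if (r2 >= range2) continue;
      if (r2 < two_ro2) ++ov;
      double r = std::sqrt(r2);
      double overlap = range - r;
      energy += k_rep * overlap * overlap;
      double dx, dy, dz;
      if (r > 1e-9) {
        dx = ddx/r; dy = ddy/r; dz = ddz/r;
      } else {
        // coincident beads: deterministic split along index parity
        dx = (i % 2 ? 1.0 : -1.0); dy = 0.0; dz = 0.0;
      }
      double f = 2.0 * k_rep * overlap;
      fx[i] += f*dx; fy[i] += f*dy; fz[i] += f*dz;
      fx[j] -= f*dx; fy[j] -= f*dy; fz[j] -= f*dz;
    }
    for (int b = 0; b < n - 1; ++b) {
      double dx = x[b+1]-x[b], dy = y[b+1]-y[b], dz = z[b+1]-z[b];
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double stretch = r - rest_len[b];
      energy += k_bond * stretch * stretch;
      if (r > 1e-9) {
        double f = 2.0 * k_bond * stretch / r;
        fx[b]   += f*dx; fy[b]   += f*dy; fz[b]   += f*dz;
        fx[b+1] -= f*dx; fy[b+1] -= f*dy; fz[b+1] -= f*dz;
      }
    }
    energy_trace.push_back(energy);
    overlaps = ov;
    if (ov == 0) {
      if (fresh) break;                  // terminate as soon as resolved
      need_rebuild = force_rebuild = true;  // re-verify on a fresh list
      continue;
    }

    if (method == 0) {
      // FIRE: adapt timestep/mixing from the power F.v, then integrate
      double P = 0.0;
      for (int i = 0; i < n; ++i)
        P += fx[i]*vx[i] + fy[i]*vy[i] + fz[i]*vz[i];
      if (P > 0.0) {
        if (++n_pos > 5) {
          dt = std::min(dt * f_inc, dt_max);
          fire_a *= f_a;
        }
      } else {
        n_pos = 0;
        dt *= f_dec;
        fire_a = a_start;
        std::fill(vx.begin(), vx.end(), 0.0);
        std::fill(vy.begin(), vy.end(), 0.0);
        std::fill(vz.begin(), vz.end(), 0.0);
      }
      double v2 = 0.0, f2 = 0.0;
      for (int i = 0; i < n; ++i) {
        vx[i] += dt * fx[i]; vy[i] += dt * fy[i]; vz[i] += dt * fz[i];
        v2 += vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i];
        f2 += fx[i]*fx[i] + fy[i]*fy[i] + fz[i]*fz[i];
      }
      if (f2 > 0.0) {
        double mix = fire_a * std::sqrt(v2 / f2);
        for (int i = 0; i < n; ++i) {
          vx[i] = (1.0 - fire_a) * vx[i] + mix * fx[i];
          vy[i] = (1.0 - fire_a) * vy[i] + mix * fy[i];
          vz[i] = (1.0 - fire_a) * vz[i] + mix * fz[i];
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      double ox = x[i], oy = y[i], oz = z[i];
      double mx, my, mz;
      if (method == 0) {
        mx = dt * vx[i]; my = dt * vy[i]; mz = dt * vz[i];
      } else {
        mx = gamma * fx[i]; my = gamma * fy[i]; mz = gamma * fz[i];
      }
      double m2 = mx*mx + my*my + mz*mz;
      if (m2 > dmax * dmax) {
        double s = dmax / std::sqrt(m2);
        mx *= s; my *= s; mz *= s;
      }
      if (temperature > 0.0) {
        mx += noise * norm_rand();
        my += noise * norm_rand();
        mz += noise * norm_rand();
      }
      x[i] += mx; y[i] += my; z[i] += mz;
      double r2 = x[i]*x[i] + y[i]*y[i] + z[i]*z[i];
      if (r2 > rc * rc) {
        double r = std::sqrt(r2);
        double rr = 2.0 * rc - r;        // reflect at the sphere
        if (rr < 0.0) rr = rc;
        double s = rr / r;
        x[i] *= s; y[i] *= s; z[i] *= s;
      }
      double ddx = x[i]-ox, ddy = y[i]-oy, ddz = z[i]-oz;
      acc_disp[i] += std::sqrt(ddx*ddx + ddy*ddy + ddz*ddz);
    }
    // top two distinct accumulated displacements
    double top1 = 0.0, top2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (acc_disp[i] > top1) { top2 = top1; top1 = acc_disp[i]; }
      else if (acc_disp[i] > top2) top2 = acc_disp[i];
    }
    if (top1 + top2 > skin) need_rebuild = true;
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0)=x[i]; out(i,1)=y[i]; out(i,2)=z[i]; }
  return List::create(_["positions"] = out,
                      _["iterations"] = iter,
                      _["overlaps"] = (double)overlaps,
                      _["energy_trace"] = NumericVector(energy_trace.begin(),
                                                        energy_trace.end()),
                      _["converged"] = (overlaps == 0));
}

// [[Rcpp::export]]
double chain_energy_cpp(NumericMatrix pos, NumericVector rest_len, double ro,
                        double k_rep, double k_bond) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
  double energy = 0.0, two_ro = 2.0 * ro;
  for_each_pair(x.data(), y.data(), z.data(), n, two_ro,
                [&](int, int, double r2) {
                  double ovl = two_ro - std::sqrt(r2);
                  energy += k_rep * ovl * ovl;
                });
  for (int b = 0; b < n - 1; ++b) {
    double dx = x[b+1]-x[b], dy = y[b+1]-y[b], dz = z[b+1]-z[b];
    double s = std::sqrt(dx*dx + dy*dy + dz*dz) - rest_len[b];
    energy += k_bond * s * s;
  }
  return energy;
}

// Stratified pair subsampling for distance-vs-genomic-separation curves.
// s must be non-decreasing (cumulative genomic coordinate, bp).  For each
// log-spaced bin [edges[b], edges[b+1]) draw up to pairs_per_bin pairs:
// a random bead i, a random side, then a uniform choice among the beads j
// whose genomic separation from i falls in the bin.  Accumulates the sum
// of squared 3D distances, the contact count (< cutoff) and the number of
// sampled pairs per bin.  Uses R's RNG.
// [[Rcpp::export]]
List curve_pairs_cpp(NumericMatrix pos, NumericVector s, NumericVector edges,
                     int pairs_per_bin, double cutoff) {
  int n = pos.nrow();
  int nb = edges.size() - 1;
  NumericVector sum_r2(nb), n_pairs(nb), n_contact(nb);
  double cut2 = cutoff * cutoff;
  const double *sp = REAL(s);
  for (int b = 0; b < nb; ++b) {
    double lo = edges[b], hi = edges[b + 1];
    for (int k = 0; k < pairs_per_bin; ++k) {
      int i = (int)(unif_rand() * n);
      if (i >= n) i = n - 1;
      bool up = unif_rand() < 0.5;
      double tlo = up ? sp[i] + lo : sp[i] - hi;
      double thi = up ? sp[i] + hi : sp[i] - lo;
      // index range with s in [tlo, thi)
      int jlo = (int)(std::lower_bound(sp, sp + n, tlo) - sp);
      int jhi = (int)(std::lower_bound(sp, sp + n, thi) - sp);
      if (jhi <= jlo) continue;
      int j = jlo + (int)(unif_rand() * (jhi - jlo));
      if (j >= jhi) j = jhi - 1;
      if (j == i) continue;
      double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1),
             dz = pos(i,2)-pos(j,2);
      double r2 = dx*dx + dy*dy + dz*dz;
      sum_r2[b] += r2;
      n_pairs[b] += 1.0;
      if (r2 < cut2) n_contact[b] += 1.0;
    }
  }
  return List::create(_["sum_r2"] = sum_r2, _["n"] = n_pairs,
                      _["n_contact"] = n_contact);
}
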