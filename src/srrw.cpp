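#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Self-returning random walk generator.
//
// At each step the walk either returns over the most recent un-returned
// forward step (probability U0^(-alpha)/alpha, U0 = length of that step)
// or performs a forward jump of length U ~ (alpha+1) U^-(alpha+2), U > 1,
// truncated at u_max by rejection, in a uniformly random direction.
// Forward jumps whose endpoint lies farther than rc (unit lengths) from
// the running center of mass of the already-generated nodes are rejected
// and fully resampled.  Un-returned forward steps live on a stack; a
// return pops the stack and moves the walker back to the site it jumped
// from, so revisited sites are matched by stack identity.
//
// Uses R's RNG (RNGScope via Rcpp attributes): deterministic under set.seed().

static inline void rand_unit_vector(double &dx, double &dy, double &dz) {
  // Marsaglia (1972) rejection method on the unit disk
  double a, b, s;
  do {
    a = 2.0 * unif_rand() - 1.0;
    b = 2.0 * unif_rand() - 1.0;
    s = a * a + b * b;
  } while (s >= 1.0 || s == 0.0);
  double root = 2.0 * std::sqrt(1.0 - s);
  dx = a * root;
  dy = b * root;
  dz = 1.0 - 2.0 * s;
}

static inline double sample_jump(double alpha, double u_max) {
  // inverse CDF of the untruncated law, rejection against the local cutoff
  for (;;) {
    double u = unif_rand();
    double U = std::pow(1.0 - u, -1.0 / (alpha + 1.0));
    if (U <= u_max) return U;
  }
}

// [[Rcpp::export]]
List srrw_generate_cpp(int n_steps, double alpha, double rc, double u_max,
                       bool returns_enabled, bool confine, int max_retries) {
  NumericMatrix pos(n_steps + 1, 3);
  LogicalVector is_return(n_steps);
  NumericVector step_len(n_steps);
  IntegerVector site_id(n_steps + 1);

  std::vector<double> stk_dx, stk_dy, stk_dz, stk_u;
  std::vector<int> stk_site; // site at the base of each un-returned step
  stk_dx.reserve(1024); stk_dy.reserve(1024); stk_dz.reserve(1024);
  stk_u.reserve(1024); stk_site.reserve(1024);

  double px = 0.0, py = 0.0, pz = 0.0;      // walker position
  double sx = 0.0, sy = 0.0, sz = 0.0;      // sum over generated nodes
  int n_nodes = 1;
  int cur_site = 0, next_site = 1;
  site_id[0] = 0;
  double rc2 = rc * rc;

  for (int t = 0; t < n_steps; ++t) {
    bool do_return = false;
    if (returns_enabled && !stk_u.empty()) {
      double u0 = stk_u.back();
      double pr = std::pow(u0, -alpha) / alpha;
      if (unif_rand() < pr) do_return = true;
    }
    if (do_return) {
      px -= stk_dx.back();
      py -= stk_dy.back();
      pz -= stk_dz.back();
      step_len[t] = stk_u.back();
      cur_site = stk_site.back();
      is_return[t] = true;
      stk_dx.pop_back(); stk_dy.pop_back(); stk_dz.pop_back();
      stk_u.pop_back(); stk_site.pop_back();
    } else {
      double cx = sx / n_nodes, cy = sy / n_nodes, cz = sz / n_nodes;
      double nx = 0, ny = 0, nz = 0, U = 0;
      bool accepted = false;
      for (int tries = 0; tries < max_retries; ++tries) {
        U = sample_jump(alpha, u_max);
        double dx, dy, dz;
        rand_unit_vector(dx, dy, dz);
        nx = px + U * dx; ny = py + U * dy; nz = pz + U * dz;
        if (!confine) { accepted = true; break; }
        double ddx = nx - cx, ddy = ny - cy, ddz = nz - cz;
        if (ddx * ddx + ddy * ddy + ddz * ddz <= rc2) { accepted = true; break; }
      }
      if (!accepted)
        stop("forward-jump rejection budget exhausted at step %d", t + 1);
      stk_dx.push_back(nx - px); stk_dy.push_back(ny - py); stk_dz.push_back(nz - pz);
      stk_u.push_back(U); stk_site.push_back(cur_site);
      px = nx; py = ny; pz = nz;
      step_len[t] = U;
      cur_site = next_site++;
      is_return[t] = false;
    }
    pos(t + 1, 0) = px; pos(t + 1, 1) = py; pos(t + 1, 2) = pz;
    site_id[t + 1] = cur_site;
    sx += px; sy += py; sz += pz;
    ++n_nodes;
  }

  return List::create(_["positions"] = pos,
                      _["is_return"] = is_return,
                      _["step_lengths"] = step_len,
                      _["site_id"] = site_id,
                      _["n_sites"] = next_site);
}
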