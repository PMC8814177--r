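// Tick engine for the agent-based pathway simulator.
//
// The world is passed in from R as a flat list of vectors (see init_world()),
// advanced n_ticks, and handed back together with the snapshots recorded at
// the requested interval.  All randomness is drawn from R's RNG so that a
// single set.seed() upstream makes whole runs reproducible.
//
// Conventions:
//   kind: 0 = metabolite, 1 = free enzyme, 2 = complex
//   wait: -1 for anything that is not a saturated complex; a saturated
//         complex is created with wait = wait_ticks + 1 and decremented once
//         per tick, so products appear exactly wait_ticks ticks after the
//         saturating bind.
//   direction: 0 forward, 1 reverse.
//   Overlap is strict (centre distance < r_i + r_j); touching spheres are
//   legal.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline double runi() { return unif_rand(); }

static inline int rint_below(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

static void shuffle_ids(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rint_below(i + 1);
    std::swap(v[i], v[j]);
  }
}

static inline void rand_dir(double *u) {
  double c = 2.0 * runi() - 1.0;
  double ph = 2.0 * M_PI * runi();
  double s = std::sqrt(std::max(0.0, 1.0 - c * c));
  u[0] = s * std::cos(ph);
  u[1] = s * std::sin(ph);
  u[2] = c;
}

// fold a coordinate into [0, side) by specular reflection (boundary 0)
// or wrap-around (boundary 1)
static inline double fold_coord(double x, double side, int boundary) {
  if (boundary == 1) {
    double p = x - side * std::floor(x / side);
    if (p >= side) p = 0.0;
    return p;
  }
  double two = 2.0 * side;
  double p = x - two * std::floor(x / two);
  if (p < 0) p += two;
  double r = (p < side) ? p : two - p;
  if (r >= side) r = std::nextafter(side, 0.0);
  return r;
}

static inline double dist2(double ax, double ay, double az,
                           double bx, double by, double bz,
                           double side, int boundary) {
  double dx = ax - bx, dy = ay - by, dz = az - bz;
  if (boundary == 1) { // minimum image
    dx -= side * std::round(dx / side);
    dy -= side * std::round(dy / side);
    dz -= side * std::round(dz / side);
  }
  return dx * dx + dy * dy + dz * dz;
}

// ---------------------------------------------------------------------------
// uniform-grid spatial index
// ---------------------------------------------------------------------------
struct Grid {
  double side, cs;
  int m;
  std::vector<std::vector<int> > cells;

  void init(double side_, double cell_hint) {
    side = side_;
    m = std::max(1, (int)std::floor(side / std::max(cell_hint, 1e-9)));
    if (m > 64) m = 64;
    cs = side / m;
    cells.assign((size_t)m * m * m, std::vector<int>());
  }
  inline int idx1(double x) const {
    int i = (int)std::floor(x / cs);
    if (i < 0) i = 0;
    if (i >= m) i = m - 1;
    return i;
  }
  inline int cell_of(double x, double y, double z) const {
    return (idx1(x) * m + idx1(y)) * m + idx1(z);
  }
  void insert(int id, double x, double y, double z, std::vector<int> &acell) {
    int c = cell_of(x, y, z);
    cells[c].push_back(id);
    acell[id] = c;
  }
  void remove(int id, std::vector<int> &acell) {
    int c = acell[id];
    if (c < 0) return;
    std::vector<int> &v = cells[c];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == id) { v[k] = v.back(); v.pop_back(); break; }
    acell[id] = -1;
  }
  // gather ids in cells overlapping a sphere of radius rq around p
  void gather(double x, double y, double z, double rq, int boundary,
              std::vector<int> &out) const {
    out.clear();
    int span = (int)std::ceil(rq / cs);
    int ix = idx1(x), iy = idx1(y), iz = idx1(z);
    for (int a = ix - span; a <= ix + span; ++a) {
      int aa = a;
      if (boundary == 1) { aa = ((a % m) + m) % m; }
      else { if (a < 0 || a >= m) continue; }
      for (int b = iy - span; b <= iy + span; ++b) {
        int bb = b;
        if (boundary == 1) { bb = ((b % m) + m) % m; }
        else { if (b < 0 || b >= m) continue; }
        for (int c = iz - span; c <= iz + span; ++c) {
          int cc = c;
          if (boundary == 1) { cc = ((c % m) + m) % m; }
          else { if (c < 0 || c >= m) continue; }
          const std::vector<int> &v = cells[(aa * m + bb) * m + cc];
          out.insert(out.end(), v.begin(), v.end());
        }
      }
    }
    if (boundary == 1 && span * 2 + 1 >= m) { // cells may repeat after wrap
      std::sort(out.begin(), out.end());
      out.erase(std::unique(out.begin(), out.end()), out.end());
    }
  }
};

// ---------------------------------------------------------------------------
// binding probability law
//   law 0: uniform       p = 1 anywhere inside the perception distance
//   law 1: inv_cube      p = 1 for s <= s0, (s0/s)^3 beyond (resonant 1/r^3)
//   law 2: inv_six       p = 1 for s <= s0, (s0/s)^6 beyond
// ---------------------------------------------------------------------------
static inline double bind_prob(double s, int law, double s0, double d) {
  if (s > d) return 0.0;
  if (law == 0) return 1.0;
  if (s <= s0) return 1.0;
  double q = s0 / s;
  double p = (law == 1) ? q * q * q : q * q * q * q * q * q;
  return (p > 1.0) ? 1.0 : p;
}

// exported so the selection logic can be unit-tested against its sampling
// distribution without building a whole world
// [[Rcpp::export(name = ".select_candidate_cpp")]]
int select_candidate_cpp(NumericVector surface_dist, int law, double s0,
                         double d, int mode, NumericVector priority) {
  int n = surface_dist.size();
  if (n == 0) return 0;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  shuffle_ids(ord); // random tie-break even in specificity mode
  if (mode == 1) {
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return priority[a] > priority[b]; });
  }
  for (int k = 0; k < n; ++k) {
    int i = ord[k];
    double p = bind_prob(surface_dist[i], law, s0, d);
    if (p >= 1.0 || runi() < p) return i + 1;
  }
  return 0;
}

// ---------------------------------------------------------------------------
// collision-free placement of spheres, largest first
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".place_spheres_cpp")]]
NumericMatrix place_spheres_cpp(NumericVector radii, double side,
                                int max_tries, int boundary) {
  int n = radii.size();
  NumericMatrix pos(n, 3);
  if (n == 0) return pos;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return radii[a] > radii[b]; });
  double maxr = radii[ord[0]];
  double vol = 0.0;
  for (int i = 0; i < n; ++i)
    vol += 4.0 / 3.0 * M_PI * radii[i] * radii[i] * radii[i];
  double packing = vol / (side * side * side);

  Grid g;
  g.init(side, std::max(2.0 * maxr + 1.0, side / 24.0));
  std::vector<int> acell(n, -1);
  std::vector<int> cand;
  for (int k = 0; k < n; ++k) {
    int id = ord[k];
    double r = radii[id];
    double lo = (boundary == 1) ? 0.0 : r;
    double span = (boundary == 1) ? side : side - 2.0 * r;
    if (span < 0)
      stop("sphere of radius %g cannot fit in a box of side %g", r, side);
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      double x = lo + runi() * span;
      double y = lo + runi() * span;
      double z = lo + runi() * span;
      g.gather(x, y, z, r + maxr, boundary, cand);
      bool clash = false;
      for (size_t j = 0; j < cand.size(); ++j) {
        int oj = cand[j];
        double rr = r + radii[oj];
        if (dist2(x, y, z, pos(oj, 0), pos(oj, 1), pos(oj, 2), side,
                  boundary) < rr * rr) { clash = true; break; }
      }
      if (!clash) {
        pos(id, 0) = x; pos(id, 1) = y; pos(id, 2) = z;
        g.insert(id, x, y, z, acell);
        placed = true;
        break;
      }
    }
    if (!placed)
      stop("could not place sphere %d of %d after %d tries "
           "(packing fraction %.3f)", k + 1, n, max_tries, packing);
  }
  return pos;
}

// ---------------------------------------------------------------------------
// grid-backed fixed-radius neighbour query (centre-to-centre distance)
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".neighbors_within_cpp")]]
IntegerVector neighbors_within_cpp(NumericMatrix pts, NumericVector q,
                                   double radius, double side, int boundary) {
  int n = pts.nrow();
  std::vector<int> hits;
  double r2 = radius * radius;
  if (n > 32 && radius < side / 3.0) {
    Grid g;
    g.init(side, std::max(radius, side / 24.0));
    std::vector<int> acell(n, -1);
    for (int i = 0; i < n; ++i)
      g.insert(i, pts(i, 0), pts(i, 1), pts(i, 2), acell);
    std::vector<int> cand;
    g.gather(q[0], q[1], q[2], radius, boundary, cand);
    for (size_t k = 0; k < cand.size(); ++k) {
      int i = cand[k];
      if (dist2(pts(i, 0), pts(i, 1), pts(i, 2), q[0], q[1], q[2], side,
                boundary) <= r2)
        hits.push_back(i + 1);
    }
  } else {
    for (int i = 0; i < n; ++i)
      if (dist2(pts(i, 0), pts(i, 1), pts(i, 2), q[0], q[1], q[2], side,
                boundary) <= r2)
        hits.push_back(i + 1);
  }
  std::sort(hits.begin(), hits.end());
  return wrap(hits);
}

// ---------------------------------------------------------------------------
// the tick loop
// ---------------------------------------------------------------------------
struct World {
  // species tables
  int S;
  std::vector<double> sp_radius, sp_step;
  std::vector<int> sp_is_enzyme;
  // reactions
  int R;
  std::vector<int> renzyme, reversible, wait_f, wait_r;
  IntegerMatrix sub_f, prod_f;       // R x S stoichiometries
  NumericMatrix spec_const;          // R x S kcat/Km (NA allowed)
  std::vector<std::vector<int> > rx_of_species;
  // agents
  std::vector<int> a_species, a_kind, a_reaction, a_dir, a_wait, a_age;
  std::vector<char> a_alive;
  std::vector<double> ax, ay, az, a_radius, a_step;
  std::vector<std::vector<int> > a_bound; // per-agent per-species bound count
  // environment / options
  double side, d, s0, step_coef;
  int boundary, law, mode, k_retries, unbind_timeout, gaussian;
  // bookkeeping
  long tick;
  std::vector<double> completions; // R x 2
  long deferred;
  double max_metab_radius;

  Grid grid;
  std::vector<int> acell;

  int n() const { return (int)a_species.size(); }

  void rebuild_grid() {
    double maxr = 1.0;
    for (int i = 0; i < n(); ++i)
      if (a_alive[i] && a_radius[i] > maxr) maxr = a_radius[i];
    grid.init(side, std::max(2.0 * maxr + 1.0, side / 24.0));
    acell.assign(n(), -1);
    for (int i = 0; i < n(); ++i)
      if (a_alive[i]) grid.insert(i, ax[i], ay[i], az[i], acell);
  }

  bool overlaps(double x, double y, double z, double r, int self,
                const std::vector<int> &extra_idx,
                const std::vector<double> *tx = NULL,
                const std::vector<double> *ty = NULL,
                const std::vector<double> *tz = NULL,
                const std::vector<double> *tr = NULL) {
    static std::vector<int> cand;
    double maxr = grid.cs / 2.0; // grid cell sized to max diameter
    grid.gather(x, y, z, r + maxr, boundary, cand);
    for (size_t k = 0; k < cand.size(); ++k) {
      int j = cand[k];
      if (j == self || !a_alive[j]) continue;
      double rr = r + a_radius[j];
      if (dist2(x, y, z, ax[j], ay[j], az[j], side, boundary) < rr * rr)
        return true;
    }
    if (tx) { // tentative (not yet committed) positions
      for (size_t k = 0; k < tx->size(); ++k) {
        double rr = r + (*tr)[k];
        if (dist2(x, y, z, (*tx)[k], (*ty)[k], (*tz)[k], side, boundary) <
            rr * rr)
          return true;
      }
    }
    (void)extra_idx;
    return false;
  }

  void move_phase() {
    std::vector<int> order;
    for (int i = 0; i < n(); ++i)
      if (a_alive[i] && !(a_kind[i] == 2 && a_wait[i] >= 1)) order.push_back(i);
    shuffle_ids(order);
    std::vector<int> noextra;
    double u[3];
    for (size_t k = 0; k < order.size(); ++k) {
      int i = order[k];
      double L = a_step[i];
      if (L <= 0) continue;
      for (int t = 0; t <= k_retries; ++t) {
        if (gaussian) {
          // isotropic Gaussian displacement with the same MSD as the
          // fixed-modulus step
          double sg = L / std::sqrt(3.0);
          u[0] = sg * norm_rand();
          u[1] = sg * norm_rand();
          u[2] = sg * norm_rand();
          double nxg = fold_coord(ax[i] + u[0], side, boundary);
          double nyg = fold_coord(ay[i] + u[1], side, boundary);
          double nzg = fold_coord(az[i] + u[2], side, boundary);
          if (!overlaps(nxg, nyg, nzg, a_radius[i], i, noextra)) {
            grid.remove(i, acell);
            ax[i] = nxg; ay[i] = nyg; az[i] = nzg;
            grid.insert(i, nxg, nyg, nzg, acell);
            break;
          }
          continue;
        }
        rand_dir(u);
        double nx = fold_coord(ax[i] + L * u[0], side, boundary);
        double ny = fold_coord(ay[i] + L * u[1], side, boundary);
        double nz = fold_coord(az[i] + L * u[2], side, boundary);
        if (!overlaps(nx, ny, nz, a_radius[i], i, noextra)) {
          grid.remove(i, acell);
          ax[i] = nx; ay[i] = ny; az[i] = nz;
          grid.insert(i, nx, ny, nz, acell);
          break;
        }
      }
    }
  }

  // species still required by agent i (free enzyme: any substrate of any
  // open direction of its reactions; partial complex: unmet stoichiometry)
  void needed_species(int i, std::vector<char> &need) {
    std::fill(need.begin(), need.end(), 0);
    if (a_kind[i] == 1) {
      const std::vector<int> &rxs = rx_of_species[a_species[i]];
      for (size_t k = 0; k < rxs.size(); ++k) {
        int r = rxs[k];
        for (int s = 0; s < S; ++s) {
          if (sub_f(r, s) > 0) need[s] = 1;
          if (reversible[r] && prod_f(r, s) > 0) need[s] = 1;
        }
      }
    } else {
      int r = a_reaction[i];
      for (int s = 0; s < S; ++s) {
        int req = (a_dir[i] == 0) ? sub_f(r, s) : prod_f(r, s);
        if (req > a_bound[i][s]) need[s] = 1;
      }
    }
  }

  void update_complex_geometry(int i) {
    double v = std::pow(sp_radius[a_species[i]], 3);
    for (int s = 0; s < S; ++s)
      if (a_bound[i][s] > 0) v += a_bound[i][s] * std::pow(sp_radius[s], 3);
    a_radius[i] = std::cbrt(v);
    a_step[i] = step_coef / std::sqrt(a_radius[i]);
  }

  void bind_phase() {
    std::vector<int> order;
    for (int i = 0; i < n(); ++i)
      if (a_alive[i] &&
          (a_kind[i] == 1 || (a_kind[i] == 2 && a_wait[i] < 0)))
        order.push_back(i);
    shuffle_ids(order);
    std::vector<char> need(S, 0);
    std::vector<int> cand_id, cand;
    std::vector<double> cand_s;
    for (size_t k = 0; k < order.size(); ++k) {
      int i = order[k];
      needed_species(i, need);
      // collect perceivable cognate metabolites
      cand_id.clear(); cand_s.clear();
      double rq = a_radius[i] + d + max_metab_radius;
      bool brute = (rq >= side / 3.0);
      if (brute) {
        for (int j = 0; j < n(); ++j) {
          if (!a_alive[j] || a_kind[j] != 0 || !need[a_species[j]]) continue;
          double s = std::sqrt(dist2(ax[i], ay[i], az[i], ax[j], ay[j], az[j],
                                     side, boundary)) -
                     a_radius[i] - a_radius[j];
          if (s < 0) s = 0;
          if (s <= d) { cand_id.push_back(j); cand_s.push_back(s); }
        }
      } else {
        grid.gather(ax[i], ay[i], az[i], rq, boundary, cand);
        for (size_t c = 0; c < cand.size(); ++c) {
          int j = cand[c];
          if (j == i || !a_alive[j] || a_kind[j] != 0 ||
              !need[a_species[j]]) continue;
          double s = std::sqrt(dist2(ax[i], ay[i], az[i], ax[j], ay[j], az[j],
                                     side, boundary)) -
                     a_radius[i] - a_radius[j];
          if (s < 0) s = 0;
          if (s <= d) { cand_id.push_back(j); cand_s.push_back(s); }
        }
      }
      int nc = (int)cand_id.size();
      if (nc == 0) continue;
      // order candidates: uniformly random; in specificity mode, sort by
      // kcat/Km of the (enzyme, metabolite) pair after the shuffle so ties
      // stay random
      std::vector<int> ord(nc);
      for (int c = 0; c < nc; ++c) ord[c] = c;
      shuffle_ids(ord);
      if (mode == 1) {
        std::vector<double> prio(nc, 0.0);
        for (int c = 0; c < nc; ++c) {
          int sp = a_species[cand_id[c]];
          double best = -1.0;
          if (a_kind[i] == 2) best = spec_const(a_reaction[i], sp);
          else {
            const std::vector<int> &rxs = rx_of_species[a_species[i]];
            for (size_t q = 0; q < rxs.size(); ++q) {
              double v = spec_const(rxs[q], sp);
              if (!NumericVector::is_na(v) && v > best) best = v;
            }
          }
          prio[c] = best;
        }
        std::stable_sort(ord.begin(), ord.end(),
                         [&](int a, int b) { return prio[a] > prio[b]; });
      }
      for (int c = 0; c < nc; ++c) {
        int j = cand_id[ord[c]];
        if (!a_alive[j]) continue; // bound earlier this phase
        double p = bind_prob(cand_s[ord[c]], law, s0, d);
        if (p < 1.0 && runi() >= p) continue;
        do_bind(i, j);
        break; // one bind per agent per tick
      }
    }
  }

  void do_bind(int i, int j) {
    int sp = a_species[j];
    if (a_kind[i] == 1) {
      // choose (reaction, direction) uniformly among open options
      std::vector<std::pair<int, int> > opts;
      const std::vector<int> &rxs = rx_of_species[a_species[i]];
      for (size_t k = 0; k < rxs.size(); ++k) {
        int r = rxs[k];
        if (sub_f(r, sp) > 0) opts.push_back(std::make_pair(r, 0));
        if (reversible[r] && prod_f(r, sp) > 0)
          opts.push_back(std::make_pair(r, 1));
      }
      std::pair<int, int> pick = opts[opts.size() == 1 ? 0
                                      : rint_below((int)opts.size())];
      a_kind[i] = 2;
      a_reaction[i] = pick.first;
      a_dir[i] = pick.second;
      std::fill(a_bound[i].begin(), a_bound[i].end(), 0);
      a_age[i] = 0;
    }
    a_bound[i][sp] += 1;
    // metabolite absorbed into the complex
    a_alive[j] = 0;
    grid.remove(j, acell);
    update_complex_geometry(i);
    // saturated?
    int r = a_reaction[i];
    bool sat = true;
    for (int s = 0; s < S; ++s) {
      int req = (a_dir[i] == 0) ? sub_f(r, s) : prod_f(r, s);
      if (a_bound[i][s] < req) { sat = false; break; }
    }
    if (sat)
      a_wait[i] = ((a_dir[i] == 0) ? wait_f[r] : wait_r[r]) + 1;
  }

  int spawn_agent(int sp, double x, double y, double z) {
    a_species.push_back(sp);
    a_kind.push_back(sp_is_enzyme[sp] ? 1 : 0);
    a_reaction.push_back(-1);
    a_dir.push_back(0);
    a_wait.push_back(-1);
    a_age.push_back(0);
    a_alive.push_back(1);
    ax.push_back(x); ay.push_back(y); az.push_back(z);
    a_radius.push_back(sp_radius[sp]);
    a_step.push_back(sp_step[sp]);
    a_bound.push_back(std::vector<int>(S, 0));
    acell.push_back(-1);
    int id = n() - 1;
    grid.insert(id, x, y, z, acell);
    return id;
  }

  // find collision-free positions for a set of spheres adjacent to agent i,
  // on an expanding shell; returns false (and places nothing) on failure
  bool place_adjacent(int i, double base_r, const std::vector<int> &species,
                      std::vector<double> &px, std::vector<double> &py,
                      std::vector<double> &pz) {
    px.clear(); py.clear(); pz.clear();
    std::vector<double> pr;
    std::vector<int> noextra;
    double u[3];
    for (size_t k = 0; k < species.size(); ++k) {
      double r = sp_radius[species[k]];
      bool ok = false;
      double shell = base_r + r + 0.5;
      for (int t = 0; t < 60; ++t) {
        if (t > 0 && t % 12 == 0) shell *= 1.25;
        rand_dir(u);
        double x = fold_coord(ax[i] + shell * u[0], side, boundary);
        double y = fold_coord(ay[i] + shell * u[1], side, boundary);
        double z = fold_coord(az[i] + shell * u[2], side, boundary);
        if (!overlaps(x, y, z, r, i, noextra, &px, &py, &pz, &pr)) {
          px.push_back(x); py.push_back(y); pz.push_back(z); pr.push_back(r);
          ok = true;
          break;
        }
      }
      if (!ok) return false;
    }
    return true;
  }

  void release_phase() {
    int n0 = n(); // agents spawned this phase do not act this tick
    for (int i = 0; i < n0; ++i) {
      if (!a_alive[i] || a_kind[i] != 2) continue;
      if (a_wait[i] >= 1) {
        a_wait[i] -= 1;
        if (a_wait[i] == 0) {
          int r = a_reaction[i];
          std::vector<int> out;
          for (int s = 0; s < S; ++s) {
            int k = (a_dir[i] == 0) ? prod_f(r, s) : sub_f(r, s);
            for (int c = 0; c < k; ++c) out.push_back(s);
          }
          std::vector<double> px, py, pz;
          double enz_r = sp_radius[a_species[i]];
          if (place_adjacent(i, enz_r, out, px, py, pz)) {
            completions[r * 2 + a_dir[i]] += 1.0;
            // revert to free enzyme first (shrinks its radius)
            a_kind[i] = 1;
            a_reaction[i] = -1;
            a_wait[i] = -1;
            std::fill(a_bound[i].begin(), a_bound[i].end(), 0);
            a_radius[i] = enz_r;
            a_step[i] = sp_step[a_species[i]];
            for (size_t k = 0; k < out.size(); ++k)
              spawn_agent(out[k], px[k], py[k], pz[k]);
          } else {
            a_wait[i] = 1; // no room: retry next tick
            deferred += 1;
          }
        }
      } else if (unbind_timeout > 0) {
        // optional dissociation of long-lived partial complexes
        a_age[i] += 1;
        if (a_age[i] > unbind_timeout) {
          std::vector<int> out;
          for (int s = 0; s < S; ++s)
            for (int c = 0; c < a_bound[i][s]; ++c) out.push_back(s);
          std::vector<double> px, py, pz;
          double enz_r = sp_radius[a_species[i]];
          if (place_adjacent(i, enz_r, out, px, py, pz)) {
            a_kind[i] = 1;
            a_reaction[i] = -1;
            a_wait[i] = -1;
            a_age[i] = 0;
            std::fill(a_bound[i].begin(), a_bound[i].end(), 0);
            a_radius[i] = enz_r;
            a_step[i] = sp_step[a_species[i]];
            for (size_t k = 0; k < out.size(); ++k)
              spawn_agent(out[k], px[k], py[k], pz[k]);
          }
        }
      }
    }
  }
};

// [[Rcpp::export(name = ".abm_advance_cpp")]]
List abm_advance_cpp(List world, int n_ticks, int record_every) {
  RNGScope scope;
  World w;

  // --- unpack ---
  NumericVector spr = world["species_radius"], sps = world["species_step"];
  IntegerVector spe = world["species_is_enzyme"];
  w.S = spr.size();
  w.sp_radius.assign(spr.begin(), spr.end());
  w.sp_step.assign(sps.begin(), sps.end());
  w.sp_is_enzyme.assign(spe.begin(), spe.end());

  IntegerVector re = world["r_enzyme"], rv = world["r_reversible"];
  IntegerVector wf = world["r_wait_f"], wr = world["r_wait_r"];
  w.R = re.size();
  w.renzyme.assign(re.begin(), re.end());
  w.reversible.assign(rv.begin(), rv.end());
  w.wait_f.assign(wf.begin(), wf.end());
  w.wait_r.assign(wr.begin(), wr.end());
  w.sub_f = as<IntegerMatrix>(world["r_sub"]);
  w.prod_f = as<IntegerMatrix>(world["r_prod"]);
  w.spec_const = as<NumericMatrix>(world["r_spec_const"]);
  w.rx_of_species.assign(w.S, std::vector<int>());
  for (int r = 0; r < w.R; ++r) w.rx_of_species[w.renzyme[r]].push_back(r);

  IntegerVector asp = world["a_species"], akd = world["a_kind"],
               arx = world["a_reaction"], adr = world["a_dir"],
               awt = world["a_wait"], aag = world["a_age"];
  LogicalVector alv = world["a_alive"];
  NumericVector vx = world["a_x"], vy = world["a_y"], vz = world["a_z"],
               ar = world["a_radius"], as_ = world["a_step"];
  IntegerMatrix ab = world["a_bound"];
  int N = asp.size();
  w.a_species.assign(asp.begin(), asp.end());
  w.a_kind.assign(akd.begin(), akd.end());
  w.a_reaction.assign(arx.begin(), arx.end());
  w.a_dir.assign(adr.begin(), adr.end());
  w.a_wait.assign(awt.begin(), awt.end());
  w.a_age.assign(aag.begin(), aag.end());
  w.a_alive.assign(N, 1);
  for (int i = 0; i < N; ++i) w.a_alive[i] = alv[i] ? 1 : 0;
  w.ax.assign(vx.begin(), vx.end());
  w.ay.assign(vy.begin(), vy.end());
  w.az.assign(vz.begin(), vz.end());
  w.a_radius.assign(ar.begin(), ar.end());
  w.a_step.assign(as_.begin(), as_.end());
  w.a_bound.assign(N, std::vector<int>(w.S, 0));
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < w.S; ++s) w.a_bound[i][s] = ab(i, s);

  w.side = as<double>(world["side"]);
  w.boundary = as<int>(world["boundary"]);
  w.d = as<double>(world["perception_distance"]);
  w.law = as<int>(world["law"]);
  w.s0 = as<double>(world["law_s0"]);
  w.mode = as<int>(world["mode"]);
  w.k_retries = as<int>(world["k_retries"]);
  w.unbind_timeout = as<int>(world["unbind_timeout"]);
  w.gaussian = as<int>(world["gaussian"]);
  w.step_coef = as<double>(world["step_coef"]);
  w.tick = (long)as<double>(world["tick"]);
  NumericVector comp = world["completions"];
  w.completions.assign(comp.begin(), comp.end());
  w.deferred = (long)as<double>(world["deferred"]);
  w.max_metab_radius = 1.0;
  for (int s = 0; s < w.S; ++s)
    if (!w.sp_is_enzyme[s] && w.sp_radius[s] > w.max_metab_radius)
      w.max_metab_radius = w.sp_radius[s];

  w.rebuild_grid();

  // --- records ---
  int nrec_max = (record_every > 0) ? (n_ticks / record_every + 1) : 0;
  IntegerMatrix rec_free(w.S, std::max(nrec_max, 1));
  IntegerMatrix rec_bound(w.S, std::max(nrec_max, 1));
  IntegerMatrix rec_partial(w.R, std::max(nrec_max, 1));
  IntegerMatrix rec_saturated(w.R, std::max(nrec_max, 1));
  NumericMatrix rec_comp(2 * w.R, std::max(nrec_max, 1));
  std::vector<double> rec_ticks;

  for (int t = 0; t < n_ticks; ++t) {
    w.move_phase();
    w.bind_phase();
    w.release_phase();
    w.tick += 1;
    if (record_every > 0 && (w.tick % record_every) == 0) {
      int col = (int)rec_ticks.size();
      if (col < nrec_max) {
        for (int i = 0; i < w.n(); ++i) {
          if (!w.a_alive[i]) continue;
          if (w.a_kind[i] == 0 || w.a_kind[i] == 1)
            rec_free(w.a_species[i], col) += 1;
          else {
            rec_bound(w.a_species[i], col) += 1; // the enzyme itself
            for (int s = 0; s < w.S; ++s)
              rec_bound(s, col) += w.a_bound[i][s];
            if (w.a_wait[i] >= 1) rec_saturated(w.a_reaction[i], col) += 1;
            else rec_partial(w.a_reaction[i], col) += 1;
          }
        }
        for (int r = 0; r < 2 * w.R; ++r) rec_comp(r, col) = w.completions[r];
        rec_ticks.push_back((double)w.tick);
      }
    }
    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // --- repack (compact dead agents) ---
  std::vector<int> keep;
  for (int i = 0; i < w.n(); ++i) if (w.a_alive[i]) keep.push_back(i);
  int M = (int)keep.size();
  IntegerVector osp(M), okd(M), orx(M), odr(M), owt(M), oag(M);
  LogicalVector oal(M);
  NumericVector ox(M), oy(M), oz(M), orad(M), ostep(M);
  IntegerMatrix obound(M, w.S);
  for (int k = 0; k < M; ++k) {
    int i = keep[k];
    osp[k] = w.a_species[i]; okd[k] = w.a_kind[i]; orx[k] = w.a_reaction[i];
    odr[k] = w.a_dir[i]; owt[k] = w.a_wait[i]; oag[k] = w.a_age[i];
    oal[k] = true;
    ox[k] = w.ax[i]; oy[k] = w.ay[i]; oz[k] = w.az[i];
    orad[k] = w.a_radius[i]; ostep[k] = w.a_step[i];
    for (int s = 0; s < w.S; ++s) obound(k, s) = w.a_bound[i][s];
  }

  List outw = clone(world);
  outw["a_species"] = osp; outw["a_kind"] = okd; outw["a_reaction"] = orx;
  outw["a_dir"] = odr; outw["a_wait"] = owt; outw["a_age"] = oag;
  outw["a_alive"] = oal;
  outw["a_x"] = ox; outw["a_y"] = oy; outw["a_z"] = oz;
  outw["a_radius"] = orad; outw["a_step"] = ostep;
  outw["a_bound"] = obound;
  outw["tick"] = (double)w.tick;
  outw["completions"] = wrap(w.completions);
  outw["deferred"] = (double)w.deferred;

  int nrec = (int)rec_ticks.size();
  IntegerMatrix f2(w.S, nrec), b2(w.S, nrec), p2(w.R, nrec), s2(w.R, nrec);
  NumericMatrix c2(2 * w.R, nrec);
  for (int c = 0; c < nrec; ++c) {
    for (int s = 0; s < w.S; ++s) { f2(s, c) = rec_free(s, c);
                                    b2(s, c) = rec_bound(s, c); }
    for (int r = 0; r < w.R; ++r) { p2(r, c) = rec_partial(r, c);
                                    s2(r, c) = rec_saturated(r, c); }
    for (int r = 0; r < 2 * w.R; ++r) c2(r, c) = rec_comp(r, c);
  }

  return List::create(_["world"] = outw,
                      _["rec_ticks"] = wrap(rec_ticks),
                      _["rec_free"] = f2,
                      _["rec_bound"] = b2,
                      _["rec_partial"] = p2,
                      _["rec_saturated"] = s2,
                      _["rec_completions"] = c2);
}
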