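// Territorial random walk: lattice simulator core.
//
// Walkers hop on a periodic lattice in discrete sweeps (each walker attempts
// one hop per step, in freshly shuffled order), deposit scent marks that
// stay active for TA steps, and respond to active foreign marks either by
// full retreat (exclusion) or by a centroid-directed biased step whose
// strength depends on the age of the encountered mark (alpha family).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NEVER = -2000000000;

// p(tau): retreat bias of the alpha family; 1/2 beyond TA.
// alpha <= 0 is the scent-ignoring sentinel (p = 1/2 always).
static double bias_p(double tau, double TA, double alpha) {
  if (alpha <= 0) return 0.5;
  if (tau > TA) return 0.5;
  double r = tau / TA;
  double inner;
  if (!R_finite(alpha)) inner = (r < 1.0) ? 0.0 : 1.0;  // alpha -> infinity
  else inner = std::pow(r, alpha);
  double s = 1.0 - inner;
  if (s < 0) s = 0;
  return 0.5 * (1.0 + std::sqrt(s));
}

// minimal-image offset on a ring of size n, in (-n/2, n/2]
static inline int mimage(int d, int n) {
  d %= n;
  if (d <= -n / 2) d += n;
  if (d > n / 2) d -= n;
  return d;
}

struct TrwState {
  int nx, ny, N, TA;
  double alpha;
  bool exclusion;       // full_exclusion mode
  bool check_before;    // inspect target site before hopping
  std::vector<int> px, py;            // wrapped positions
  std::vector<int> ux, uy;            // unwrapped positions
  std::vector<std::vector<int>> dep;  // dep[i][site]: last deposit time
  std::vector<int> pending_age;       // age of encountered mark, -1 if none
  // per-owner list of (site) deposits for centroid scans
  std::vector<std::vector<int>> marked_sites;
  std::vector<std::vector<int>> marked_times;

  int site(int x, int y) const { return y * nx + x; }

  bool active(int i, int s, int now) const {
    return dep[i][s] != NEVER && now - dep[i][s] <= TA;
  }
  // youngest active foreign mark at site s; returns age or -1
  int foreign_age(int i, int s, int now) const {
    int best = -1;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      if (active(j, s, now)) {
        int age = now - dep[j][s];
        if (best < 0 || age < best) best = age;
      }
    }
    return best;
  }
  bool has_foreign(int i, int s, int now) const {
    for (int j = 0; j < N; ++j)
      if (j != i && active(j, s, now)) return true;
    return false;
  }

  void deposit(int i, int now) {
    int s = site(px[i], py[i]);
    if (dep[i][s] == NEVER || now - dep[i][s] > 0) {
      marked_sites[i].push_back(s);
      marked_times[i].push_back(now);
    }
    dep[i][s] = now;
    if (exclusion)
      for (int j = 0; j < N; ++j)
        if (j != i) dep[j][s] = NEVER;  // ownership is exclusive
    // compact the scan list occasionally
    if ((int)marked_sites[i].size() > 4 * TA + 64) compact(i, now);
  }

  void compact(int i, int now) {
    std::vector<int> s2, t2;
    s2.reserve(2 * TA);
    t2.reserve(2 * TA);
    for (size_t k = 0; k < marked_sites[i].size(); ++k) {
      int s = marked_sites[i][k], t = marked_times[i][k];
      if (dep[i][s] == t && now - t <= TA) {
        s2.push_back(s);
        t2.push_back(t);
      }
    }
    marked_sites[i].swap(s2);
    marked_times[i].swap(t2);
  }

  // centroid of owner i's active marks, in minimal-image coordinates
  // relative to the walker's current position; true if any active mark
  bool centroid(int i, int now, double &cx, double &cy) {
    double sx = 0, sy = 0;
    int cnt = 0;
    std::vector<bool> seen;  // dedupe stale list entries via dep check
    for (size_t k = 0; k < marked_sites[i].size(); ++k) {
      int s = marked_sites[i][k], t = marked_times[i][k];
      if (dep[i][s] != t || now - t > TA) continue;
      int mx = s % nx, my = s / nx;
      sx += mimage(mx - px[i], nx);
      sy += mimage(my - py[i], ny);
      ++cnt;
    }
    if (cnt == 0) return false;
    cx = px[i] + sx / cnt;
    cy = py[i] + sy / cnt;
    return true;
  }
};

// direction probabilities of the biased step (Eq. of the alpha family):
// order left(-x), right(+x), up(+y), down(-y)
static void step_probs(double dx, double dy, double p, double pr[4]) {
  double dist = std::sqrt(dx * dx + dy * dy);
  double kl = (dist > 0) ? dx / dist : 0.0;
  double ku = (dist > 0) ? dy / dist : 0.0;
  double b = 2.0 * p - 1.0;
  pr[0] = 0.25 * (1.0 + b * kl);
  pr[1] = 0.25 * (1.0 - b * kl);
  pr[2] = 0.25 * (1.0 - b * ku);
  pr[3] = 0.25 * (1.0 + b * ku);
}

// [[Rcpp::export(name = ".trw_simulate_cpp")]]
List trw_simulate_cpp(int nx, int ny, int N, int TA, double alpha,
                      int steps, bool exclusion, bool check_before,
                      int record_every, int util_window,
                      IntegerMatrix init) {
  TrwState S;
  S.nx = nx; S.ny = ny; S.N = N; S.TA = TA; S.alpha = alpha;
  S.exclusion = exclusion; S.check_before = check_before;
  S.px.resize(N); S.py.resize(N); S.ux.resize(N); S.uy.resize(N);
  S.dep.assign(N, std::vector<int>(nx * ny, NEVER));
  S.pending_age.assign(N, -1);
  S.marked_sites.resize(N);
  S.marked_times.resize(N);
  for (int i = 0; i < N; ++i) {
    S.px[i] = init(i, 0); S.py[i] = init(i, 1);
    S.ux[i] = S.px[i]; S.uy[i] = S.py[i];
    S.deposit(i, 0);
  }

  int n_rec = steps / record_every + 1;
  IntegerMatrix rec_x(n_rec, N), rec_y(n_rec, N);
  IntegerVector rec_t(n_rec);
  NumericMatrix util(N, nx * ny);
  int overlap_checks = 0, overlap_violations = 0;
  int util_start = steps - util_window;
  if (util_start < 0) util_start = 0;

  int irec = 0;
  for (int i = 0; i < N; ++i) { rec_x(irec, i) = S.ux[i]; rec_y(irec, i) = S.uy[i]; }
  rec_t(irec++) = 0;

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  const int DX[4] = {-1, 1, 0, 0}, DY[4] = {0, 0, 1, -1};

  for (int t = 1; t <= steps; ++t) {
    // fresh random sweep order
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < N; ++k) {
      int i = order[k];
      int dir = -1;
      if (S.pending_age[i] >= 0 && S.exclusion) {
        // full retreat: uniform among neighbours free of foreign marks
        int free_dirs[4], nf = 0;
        for (int d = 0; d < 4; ++d) {
          int x2 = (S.px[i] + DX[d] + nx) % nx;
          int y2 = (S.py[i] + DY[d] + ny) % ny;
          if (!S.has_foreign(i, S.site(x2, y2), t)) free_dirs[nf++] = d;
        }
        if (nf > 0) {
          int pick = (int)std::floor(unif_rand() * nf);
          if (pick >= nf) pick = nf - 1;
          dir = free_dirs[pick];
        }  // else stay put
      } else if (S.pending_age[i] >= 0) {
        // alpha family: centroid-directed biased step
        double cx, cy;
        double pr[4];
        if (S.centroid(i, t, cx, cy)) {
          double p = bias_p((double)S.pending_age[i], (double)TA, alpha);
          step_probs((double)S.px[i] - cx, (double)S.py[i] - cy, p, pr);
          double r = unif_rand(), acc = 0;
          dir = 3;
          for (int d = 0; d < 4; ++d) { acc += pr[d]; if (r < acc) { dir = d; break; } }
        } else {
          dir = (int)std::floor(unif_rand() * 4);
          if (dir > 3) dir = 3;
        }
      } else {
        dir = (int)std::floor(unif_rand() * 4);
        if (dir > 3) dir = 3;
      }
      S.pending_age[i] = -1;

      if (dir >= 0) {
        int x2 = (S.px[i] + DX[dir] + nx) % nx;
        int y2 = (S.py[i] + DY[dir] + ny) % ny;
        if (S.check_before) {
          int age = S.foreign_age(i, S.site(x2, y2), t);
          if (age >= 0) {
            // respond without entering: flag and stay this sweep
            S.pending_age[i] = age;
            S.deposit(i, t);
            continue;
          }
        }
        S.px[i] = x2; S.py[i] = y2;
        S.ux[i] += DX[dir]; S.uy[i] += DY[dir];
      }
      // land-then-respond: note foreign mark age before own deposit
      if (!S.check_before) {
        int age = S.foreign_age(i, S.site(S.px[i], S.py[i]), t);
        if (age >= 0) S.pending_age[i] = age;
      }
      S.deposit(i, t);
    }

    if (t >= util_start)
      for (int i = 0; i < N; ++i)
        util(i, S.site(S.px[i], S.py[i])) += 1.0;

    if (t % record_every == 0) {
      for (int i = 0; i < N; ++i) { rec_x(irec, i) = S.ux[i]; rec_y(irec, i) = S.uy[i]; }
      rec_t(irec++) = t;
      if (exclusion) {
        ++overlap_checks;
        for (int s = 0; s < nx * ny; ++s) {
          int na = 0;
          for (int i = 0; i < N; ++i) if (S.active(i, s, t)) ++na;
          if (na > 1) ++overlap_violations;
        }
      }
    }
  }

  // normalise utilization rows
  for (int i = 0; i < N; ++i) {
    double tot = 0;
    for (int s = 0; s < nx * ny; ++s) tot += util(i, s);
    if (tot > 0) for (int s = 0; s < nx * ny; ++s) util(i, s) /= tot;
  }

  // final active-mark field: owner ages (-1 inactive)
  IntegerMatrix mark_age(N, nx * ny);
  for (int i = 0; i < N; ++i)
    for (int s = 0; s < nx * ny; ++s)
      mark_age(i, s) = S.active(i, s, steps) ? steps - S.dep[i][s] : -1;

  return List::create(
    _["t"] = rec_t, _["x"] = rec_x, _["y"] = rec_y,
    _["utilization"] = util, _["mark_age"] = mark_age,
    _["overlap_checks"] = overlap_checks,
    _["overlap_violations"] = overlap_violations);
}

// [[Rcpp::export(name = ".trw1d_simulate_cpp")]]
List trw1d_simulate_cpp(int nx, int N, int TA, int steps,
                        int record_every, IntegerVector init) {
  // 1d full-exclusion TRW on a ring; tracks territory edges.
  // Ownership is exclusive in 1d full exclusion, so a single
  // (owner, deposit-time) field per site suffices: O(1) foreign checks.
  std::vector<int> px(N), uxp(N);
  std::vector<int> owner(nx, -1), dep_t(nx, NEVER);
  std::vector<int> pending(N, 0);
  for (int i = 0; i < N; ++i) {
    px[i] = init[i]; uxp[i] = init[i];
    owner[px[i]] = i; dep_t[px[i]] = 0;
  }

  auto has_foreign = [&](int i, int s, int now) {
    return owner[s] != -1 && owner[s] != i && now - dep_t[s] <= TA;
  };

  int n_rec = steps / record_every + 1;
  NumericMatrix edges(n_rec, N);       // edge k: between owner k and k+1
  IntegerMatrix collapsed(n_rec, N);   // owner lost all active marks
  IntegerVector rec_t(n_rec);
  std::vector<double> prev_edge(N, NA_REAL);

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  auto record = [&](int irec, int t) {
    rec_t[irec] = t;
    // per-owner active arc relative to walker position (minimal image)
    std::vector<int> lo(N, nx), hi(N, -nx);
    std::vector<bool> any(N, false);
    for (int s = 0; s < nx; ++s) {
      int i = owner[s];
      if (i < 0 || t - dep_t[s] > TA) continue;
      int off = mimage(s - px[i], nx);
      if (off < lo[i]) lo[i] = off;
      if (off > hi[i]) hi[i] = off;
      any[i] = true;
    }
    for (int i = 0; i < N; ++i) {
      int j = (i + 1) % N;
      if (!any[i] || !any[j]) {
        collapsed(irec, i) = 1;
        edges(irec, i) = prev_edge[i];
        continue;
      }
      double right_i = uxp[i] + hi[i];
      // right neighbour's leftmost mark, lifted next to owner i's walker
      // minimal-image gap to the neighbour's leftmost mark; transiently
      // slightly negative when expiring marks leave holes at the border
      double gap = mimage((px[j] + lo[j]) - (px[i] + hi[i]), nx);
      double e = right_i + gap / 2.0;
      edges(irec, i) = e;
      prev_edge[i] = e;
    }
  };
  record(0, 0);
  int irec = 1;

  for (int t = 1; t <= steps; ++t) {
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < N; ++k) {
      int i = order[k];
      int dir = 0;  // -1 or +1; 0 = stay
      if (pending[i]) {
        int freeo[2], nf = 0;
        for (int d = -1; d <= 1; d += 2) {
          int x2 = (px[i] + d + nx) % nx;
          if (!has_foreign(i, x2, t)) freeo[nf++] = d;
        }
        if (nf > 0) {
          int pick = (int)std::floor(unif_rand() * nf);
          if (pick >= nf) pick = nf - 1;
          dir = freeo[pick];
        }
      } else {
        dir = (unif_rand() < 0.5) ? -1 : 1;
      }
      pending[i] = 0;
      if (dir != 0) {
        // full exclusion, target inspected before hopping: never enter a
        // site carrying an active foreign mark
        int x2 = (px[i] + dir + nx) % nx;
        if (has_foreign(i, x2, t)) {
          pending[i] = 1;
        } else {
          px[i] = x2;
          uxp[i] += dir;
        }
      }
      owner[px[i]] = i;
      dep_t[px[i]] = t;
    }
    if (t % record_every == 0) record(irec++, t);
  }

  return List::create(_["t"] = rec_t, _["edges"] = edges,
                      _["collapsed"] = collapsed);
}

// [[Rcpp::export(name = ".lattice_return_times_cpp")]]
List lattice_return_times_cpp(int nx, int ny, int steps) {
  // single unbiased walker on a periodic lattice; return times to the
  // starting site (Kac recurrence: mean should equal nx*ny)
  int x = 0, y = 0;
  long last = 0, nret = 0;
  double sum = 0;
  const int DX[4] = {-1, 1, 0, 0}, DY[4] = {0, 0, 1, -1};
  for (long t = 1; t <= steps; ++t) {
    int d = (int)std::floor(unif_rand() * 4);
    if (d > 3) d = 3;
    x = (x + DX[d] + nx) % nx;
    y = (y + DY[d] + ny) % ny;
    if (x == 0 && y == 0) {
      sum += (double)(t - last);
      last = t;
      ++nret;
    }
  }
  return List::create(_["mean_return"] = (nret > 0) ? sum / nret : NA_REAL,
                      _["n_returns"] = (double)nret);
}
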