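// Core particle-simulation kernels: minimum-image geometry, k-nearest-
// neighbour search, attraction-repulsion social forces, resource peaks,
// semi-implicit integration, and order-parameter computations.
//
// All randomness uses R's RNG stream so set.seed() in R controls every draw.
// Draw order within a time step is fixed (agent noise by index, then peaks)
// so trajectories are bit-reproducible for a given seed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <functional>

using namespace Rcpp;

static const double EPS_SPEED = 1e-8;       // below this |v| the heading is undefined
static const double EPS_COINCIDENT = 1e-12; // pair force dropped below this distance

// minimum-image displacement component on a torus of edge L, result in [-L/2, L/2]
static inline double mimg(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

static inline double wrap_coord(double x, double L) {
  x -= L * std::floor(x / L);
  if (x < 0) x += L;
  if (x >= L) x = 0;  // guard rounding at the boundary
  return x;
}

// squared minimum-image distance
static inline double dist2(double xi, double yi, double xj, double yj, double L) {
  double dx = mimg(xi - xj, L);
  double dy = mimg(yi - yj, L);
  return dx * dx + dy * dy;
}

// ---------------------------------------------------------------------------
// neighbour search: for agent i, the (up to) k nearest others within lmax_i,
// ordered by distance then index.  Brute force O(N^2); N stays in the
// hundreds for all protocols, and brute force doubles as the test oracle
// contract (any future index must match it exactly).
// ---------------------------------------------------------------------------

struct Cand { double d2; int j; };

static inline bool cand_lt(const Cand &a, const Cand &b) {
  return a.d2 < b.d2 || (a.d2 == b.d2 && a.j < b.j);
}

// fills nbr (indices, 0-based) and nd2 (squared distances) for agent i;
// returns the count (<= k)
static int knn_within(const std::vector<double> &px, const std::vector<double> &py,
                      int i, double lmax, int k, double L,
                      std::vector<Cand> &buf) {
  const int n = (int)px.size();
  if (k <= 0 || lmax <= 0) return 0;
  const double l2 = lmax * lmax;
  int cnt = 0; // number currently kept (<= k), buf[0..cnt-1] sorted
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double d2 = dist2(px[i], py[i], px[j], py[j], L);
    if (d2 > l2) continue;
    Cand c{d2, j};
    if (cnt < k) {
      int p = cnt++;
      while (p > 0 && cand_lt(c, buf[p - 1])) { buf[p] = buf[p - 1]; --p; }
      buf[p] = c;
    } else if (cand_lt(c, buf[k - 1])) {
      int p = k - 1;
      while (p > 0 && cand_lt(c, buf[p - 1])) { buf[p] = buf[p - 1]; --p; }
      buf[p] = c;
    }
  }
  return cnt;
}

// [[Rcpp::export]]
List cpp_neighbor_sets(NumericMatrix pos, NumericVector lmax, int k, double L) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); }
  std::vector<Cand> buf(std::max(k, 1));
  List out(n);
  for (int i = 0; i < n; ++i) {
    int cnt = knn_within(px, py, i, lmax[i], k, L, buf);
    IntegerVector v(cnt);
    for (int q = 0; q < cnt; ++q) v[q] = buf[q].j + 1;
    out[i] = v;
  }
  return out;
}

// social force on each agent given its neighbour set; coefficient
// (Cr/lr) e^(-d/lr) - (Ca/la) e^(-d/la) applied along the unit vector from
// neighbour towards the focal agent (positive = repulsion)
static void social_forces(const std::vector<double> &px, const std::vector<double> &py,
                          const NumericVector &lmax, int k, double L,
                          double Cr, double Ca, double lr, double la,
                          std::vector<double> &fx, std::vector<double> &fy,
                          std::vector<Cand> &buf) {
  const int n = (int)px.size();
  const double ar = Cr / lr, aa = Ca / la;
  for (int i = 0; i < n; ++i) {
    double sx = 0.0, sy = 0.0;
    int cnt = knn_within(px, py, i, lmax[i], k, L, buf);
    for (int q = 0; q < cnt; ++q) {
      int j = buf[q].j;
      double d = std::sqrt(buf[q].d2);
      if (d < EPS_COINCIDENT) continue;
      double coef = ar * std::exp(-d / lr) - aa * std::exp(-d / la);
      double ux = mimg(px[i] - px[j], L) / d;
      double uy = mimg(py[i] - py[j], L) / d;
      sx += coef * ux;
      sy += coef * uy;
    }
    fx[i] = sx;
    fy[i] = sy;
  }
}

// variant used by the stepping loop: distances read from a precomputed
// symmetric matrix D (row-major n x n, self-distance set to +inf); results
// are identical to social_forces — minimum-image squared distances are
// symmetric — at half the distance evaluations
static void social_forces_sym(const std::vector<double> &px, const std::vector<double> &py,
                              const std::vector<double> &D, int n,
                              const NumericVector &lmax, int k, double L,
                              double Cr, double Ca, double lr, double la,
                              std::vector<double> &fx, std::vector<double> &fy,
                              std::vector<Cand> &buf) {
  const double ar = Cr / lr, aa = Ca / la;
  for (int i = 0; i < n; ++i) {
    const double *row = &D[(size_t)i * n];
    double l2 = lmax[i] * lmax[i];
    int cnt = 0;
    if (k > 0 && lmax[i] > 0) {
      for (int j = 0; j < n; ++j) {
        double d2 = row[j];
        if (d2 > l2) continue;
        Cand c{d2, j};
        if (cnt < k) {
          int p = cnt++;
          while (p > 0 && cand_lt(c, buf[p - 1])) { buf[p] = buf[p - 1]; --p; }
          buf[p] = c;
        } else if (cand_lt(c, buf[k - 1])) {
          int p = k - 1;
          while (p > 0 && cand_lt(c, buf[p - 1])) { buf[p] = buf[p - 1]; --p; }
          buf[p] = c;
        }
      }
    }
    double sx = 0.0, sy = 0.0;
    for (int q = 0; q < cnt; ++q) {
      int j = buf[q].j;
      double d = std::sqrt(buf[q].d2);
      if (d < EPS_COINCIDENT) continue;
      double coef = ar * std::exp(-d / lr) - aa * std::exp(-d / la);
      sx += coef * mimg(px[i] - px[j], L) / d;
      sy += coef * mimg(py[i] - py[j], L) / d;
    }
    fx[i] = sx;
    fy[i] = sy;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_social_forces(NumericMatrix pos, NumericVector lmax, int k, double L,
                                double Cr, double Ca, double lr, double la) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); }
  std::vector<Cand> buf(std::max(k, 1));
  social_forces(px, py, lmax, k, L, Cr, Ca, lr, la, fx, fy, buf);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// resource value of each peak summed at (x, y); peaks: columns x, y, amp, lambda1
static inline double field_at(const NumericMatrix &peaks, double x, double y, double L) {
  double s = 0.0;
  for (int p = 0; p < peaks.nrow(); ++p) {
    double d2 = dist2(x, y, peaks(p, 0), peaks(p, 1), L);
    double l1 = peaks(p, 3);
    s += peaks(p, 2) * std::exp(-d2 / (l1 * l1));
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_field_values(NumericMatrix peaks, NumericMatrix x, double L) {
  const int n = x.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = field_at(peaks, x(i, 0), x(i, 1), L);
  return out;
}

// ---------------------------------------------------------------------------
// main stepping loop
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, NumericMatrix vel0,
                  NumericVector psi0, NumericVector psi1, NumericVector lmax,
                  double Cr, double Ca, double lr, double la, int k,
                  double m, double eta, double gamma, double tau, int n_sub,
                  NumericMatrix peaks0, NumericVector amp_init,
                  double L, NumericVector alpha, double beta, double tau_p,
                  double u, bool move_peaks,
                  int n_steps, int record_every,
                  double count_radius, int count_peak) {
  const int n = pos0.nrow();
  const int npk = peaks0.nrow();
  std::vector<double> px(n), py(n), vx(n), vy(n), fx(n), fy(n), Sv(n), Psi(n),
      fit(n, 0.0);
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1);
  }
  NumericMatrix peaks = clone(peaks0);
  std::vector<Cand> buf(std::max(k, 1));

  const bool do_count = count_radius > 0 && npk > 0;
  IntegerVector counts(do_count ? n_steps : 0);

  const int n_rec = record_every > 0 ? n_steps / record_every : 0;
  NumericMatrix rx(n_rec, n), ry(n_rec, n), rvx(n_rec, n), rvy(n_rec, n),
      rS(n_rec, n);
  IntegerVector rt(n_rec);
  NumericMatrix rpk(n_rec * npk, 4); // t, x, y, amp
  int irec = 0;

  const double h = tau / n_sub;
  const double relocate_p = (tau_p > 0 && std::isfinite(tau_p)) ? 1.0 / tau_p : 0.0;

  std::vector<double> drain(npk), parts(npk);
  std::vector<double> D((size_t)n * n);

  for (int t = 0; t < n_steps; ++t) {
    // information frozen over the step: S and social force at step start;
    // depletion consumes u*S(xi) at the same frozen positions, attributed to
    // peaks in proportion to their contribution to S(xi)
    std::fill(drain.begin(), drain.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double stot = 0.0;
      for (int p = 0; p < npk; ++p) {
        double l1 = peaks(p, 3);
        double d2p = dist2(px[i], py[i], peaks(p, 0), peaks(p, 1), L);
        double v = peaks(p, 2) * std::exp(-d2p / (l1 * l1));
        parts[p] = v;
        stot += v;
      }
      Sv[i] = stot;
      Psi[i] = psi0[i] - psi1[i] * stot;
      fit[i] += stot;  // fitness uses pre-depletion S
      if (u > 0 && stot > 0) {
        double cons = u * stot;
        for (int p = 0; p < npk; ++p) drain[p] += cons * parts[p] / stot;
      }
    }
    if (u > 0)
      for (int p = 0; p < npk; ++p)
        peaks(p, 2) = std::max(0.0, peaks(p, 2) - drain[p]);
    for (int i = 0; i < n; ++i) {
      D[(size_t)i * n + i] = R_PosInf;
      for (int j = i + 1; j < n; ++j) {
        double d2 = dist2(px[i], py[i], px[j], py[j], L);
        D[(size_t)i * n + j] = d2;
        D[(size_t)j * n + i] = d2;
      }
    }
    social_forces_sym(px, py, D, n, lmax, k, L, Cr, Ca, lr, la, fx, fy, buf);

    // semi-implicit Euler sub-steps, operator-split: social kick, then the
    // autonomous force as a scalar speed update along the current heading
    // (it acts along v/|v|, so it can decelerate the agent at most to rest,
    // never reverse it within a sub-step), then the position update
    for (int s = 0; s < n_sub; ++s) {
      for (int i = 0; i < n; ++i) {
        vx[i] += h * fx[i] / m;
        vy[i] += h * fy[i] / m;
        double sp = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
        if (sp >= EPS_SPEED) {
          double s2 = sp + h * (Psi[i] - eta * sp * sp) / m;
          if (s2 < 0) s2 = 0;
          double f = s2 / sp;
          vx[i] *= f;
          vy[i] *= f;
        }
        px[i] += h * vx[i];
        py[i] += h * vy[i];
      }
    }

    // navigational noise: exact magnitude gamma, uniform heading
    for (int i = 0; i < n; ++i) {
      if (gamma > 0) {
        double th = unif_rand() * 2.0 * M_PI;
        vx[i] += gamma * std::cos(th);
        vy[i] += gamma * std::sin(th);
      }
      px[i] = wrap_coord(px[i], L);
      py[i] = wrap_coord(py[i], L);
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) ||
          !std::isfinite(vx[i]) || !std::isfinite(vy[i]))
        stop("non-finite state for agent %d at step %d", i + 1, t + 1);
    }

    // peak dynamics: drift + diffusion, then relocation at rate 1/tau_p
    if (move_peaks && npk > 0) {
      for (int p = 0; p < npk; ++p) {
        peaks(p, 0) = wrap_coord(peaks(p, 0) + alpha[0] * tau + beta * norm_rand(), L);
        peaks(p, 1) = wrap_coord(peaks(p, 1) + alpha[1] * tau + beta * norm_rand(), L);
        if (relocate_p > 0 && unif_rand() < relocate_p) {
          peaks(p, 0) = unif_rand() * L;
          peaks(p, 1) = unif_rand() * L;
          peaks(p, 2) = amp_init[p];
        }
      }
    }

    if (do_count) {
      int c = 0;
      const double r2 = count_radius * count_radius;
      for (int i = 0; i < n; ++i)
        if (dist2(px[i], py[i], peaks(count_peak, 0), peaks(count_peak, 1), L) <= r2)
          ++c;
      counts[t] = c;
    }

    if (record_every > 0 && ((t + 1) % record_every == 0) && irec < n_rec) {
      rt[irec] = t + 1;
      for (int i = 0; i < n; ++i) {
        rx(irec, i) = px[i]; ry(irec, i) = py[i];
        rvx(irec, i) = vx[i]; rvy(irec, i) = vy[i];
        rS(irec, i) = Sv[i];
      }
      for (int p = 0; p < npk; ++p) {
        int row = irec * npk + p;
        rpk(row, 0) = t + 1;
        rpk(row, 1) = peaks(p, 0);
        rpk(row, 2) = peaks(p, 1);
        rpk(row, 3) = peaks(p, 2);
      }
      ++irec;
    }
  }

  NumericMatrix pos(n, 2), vel(n, 2);
  NumericVector fitness(n), Sout(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = px[i]; pos(i, 1) = py[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i];
    fitness[i] = fit[i] / n_steps;
    Sout[i] = Sv[i];
  }
  return List::create(_["positions"] = pos, _["velocities"] = vel,
                      _["peaks"] = peaks, _["fitness"] = fitness,
                      _["S_last"] = Sout, _["counts"] = counts,
                      _["rec_t"] = rt, _["rec_x"] = rx, _["rec_y"] = ry,
                      _["rec_vx"] = rvx, _["rec_vy"] = rvy, _["rec_S"] = rS,
                      _["rec_peaks"] = rpk);
}

// ---------------------------------------------------------------------------
// order parameters
// ---------------------------------------------------------------------------

// mean over agents of the mean distance to their nn nearest others (no lmax cutoff)
// [[Rcpp::export]]
double cpp_mean_dist_knn(NumericMatrix pos, double L, int nn) {
  const int n = pos.nrow();
  if (n <= nn) stop("need more agents than n_neighbors");
  std::vector<double> d2(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int j = 0; j < n; ++j)
      if (j != i) d2[cnt++] = dist2(pos(i, 0), pos(i, 1), pos(j, 0), pos(j, 1), L);
    std::nth_element(d2.begin(), d2.begin() + nn - 1, d2.begin() + cnt);
    double s = 0.0;
    for (int q = 0; q < nn; ++q) s += std::sqrt(d2[q]);
    acc += s / nn;
  }
  return acc / n;
}

// mean over agents of the pair potential summed over each agent's neighbour set
// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix pos, NumericVector lmax, int k, double L,
                            double Cr, double Ca, double lr, double la) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); }
  std::vector<Cand> buf(std::max(k, 1));
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int cnt = knn_within(px, py, i, lmax[i], k, L, buf);
    for (int q = 0; q < cnt; ++q) {
      double d = std::sqrt(buf[q].d2);
      acc += Cr * std::exp(-d / lr) - Ca * std::exp(-d / la);
    }
  }
  return acc / n;
}

// connected components of the social interaction graph (edge if i in N_j or
// j in N_i); returns 1-based component labels
// [[Rcpp::export]]
IntegerVector cpp_components(NumericMatrix pos, NumericVector lmax, int k, double L) {
  const int n = pos.nrow();
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); }
  std::vector<Cand> buf(std::max(k, 1));
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  for (int i = 0; i < n; ++i) {
    int cnt = knn_within(px, py, i, lmax[i], k, L, buf);
    for (int q = 0; q < cnt; ++q) {
      int ra = find(i), rb = find(buf[q].j);
      if (ra != rb) parent[ra] = rb;
    }
  }
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}
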