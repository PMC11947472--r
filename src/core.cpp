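// Hot loops of the two interface simulators.
//
// Conventions shared with the R layer:
//  - a row of N cells is a vector of N+1 vertex positions; cell i (0-based)
//    spans [x[i], x[i+1]]; the first and last vertices are pinned.
//  - cell types are integer codes 0 (S) / 1 (T); `eps` and `Tadh` are
//    symmetric 2x2 matrices indexed by the two facing types.
//  - adhesion is favorable: E_adh = -sum(eps * contact length), so a larger
//    same-type eps rewards same-type contact.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 0-based index of the cell of row `x` covering point p. At a breakpoint,
// side > 0 returns the cell just right of p, side < 0 the cell just left.
static inline int cover_cell(const NumericVector& x, double p, int side) {
  int N = x.size() - 1;
  int j;
  if (side > 0) {
    j = int(std::upper_bound(x.begin(), x.end(), p) - x.begin()) - 1;
  } else {
    j = int(std::lower_bound(x.begin(), x.end(), p) - x.begin()) - 1;
  }
  if (j < 0) j = 0;
  if (j > N - 1) j = N - 1;
  return j;
}

static double elastic_full(const NumericVector& x, const NumericVector& L0,
                           double K) {
  double E = 0.0;
  const int N = L0.size();
  for (int i = 0; i < N; ++i) {
    const double d = (x[i + 1] - x[i]) - L0[i];
    E += K * d * d;
  }
  return E;
}

// Interface segmentation: merge the two rows' vertices, type each positive
// length segment by the pair of covering cells (midpoint rule).
static double adhesion_full(const NumericVector& x1, const NumericVector& x2,
                            const IntegerVector& t1, const IntegerVector& t2,
                            const NumericMatrix& eps) {
  std::vector<double> bp(x1.begin(), x1.end());
  bp.insert(bp.end(), x2.begin(), x2.end());
  std::sort(bp.begin(), bp.end());
  double E = 0.0;
  for (size_t j = 0; j + 1 < bp.size(); ++j) {
    const double len = bp[j + 1] - bp[j];
    if (len <= 0) continue;
    const double m = 0.5 * (bp[j] + bp[j + 1]);
    E -= eps(t1[cover_cell(x1, m, +1)], t2[cover_cell(x2, m, +1)]) * len;
  }
  return E;
}

// [[Rcpp::export]]
double cpp_total_energy(NumericVector x1, NumericVector x2, IntegerVector t1,
                        IntegerVector t2, NumericVector L01, NumericVector L02,
                        NumericMatrix eps, double K) {
  return elastic_full(x1, L01, K) + elastic_full(x2, L02, K) +
         adhesion_full(x1, x2, t1, t2, eps);
}

// Adhesion energy restricted to the window [wl, wr]. The moved row
// contributes its two cells with types (tl | tr) split at `pos`; the other
// row is read from its full vertex/type vectors.
static double adhesion_window(const NumericVector& xo, const IntegerVector& to,
                              int tl, int tr, double pos, double wl, double wr,
                              const NumericMatrix& eps) {
  std::vector<double> bp;
  bp.reserve(8);
  bp.push_back(wl);
  bp.push_back(pos);
  bp.push_back(wr);
  const double* lo = std::upper_bound(xo.begin(), xo.end(), wl);
  const double* hi = std::lower_bound(xo.begin(), xo.end(), wr);
  for (const double* it = lo; it != hi; ++it) bp.push_back(*it);
  std::sort(bp.begin(), bp.end());
  double E = 0.0;
  for (size_t j = 0; j + 1 < bp.size(); ++j) {
    const double len = bp[j + 1] - bp[j];
    if (len <= 0) continue;
    const double m = 0.5 * (bp[j] + bp[j + 1]);
    const int a = (m < pos) ? tl : tr;
    E -= eps(a, to[cover_cell(xo, m, +1)]) * len;
  }
  return E;
}

// Energy change for moving interior vertex i (0-based) of the row (xr, tr_)
// by dx. Valid for allowed moves (new position stays inside [x[i-1], x[i+1]]),
// for which only the two flanking cells and the interface segments inside
// that window change.
static double delta_energy_core(const NumericVector& xr,
                                const NumericVector& xo,
                                const IntegerVector& tr_,
                                const IntegerVector& to,
                                const NumericVector& L0r, double K,
                                const NumericMatrix& eps, int i, double dx) {
  const double wl = xr[i - 1], wr = xr[i + 1];
  const double p0 = xr[i], p1 = p0 + dx;
  const int tl = tr_[i - 1], tr = tr_[i];
  const double a = L0r[i - 1], b = L0r[i];
  const double Ll0 = p0 - wl, Lr0 = wr - p0, Ll1 = p1 - wl, Lr1 = wr - p1;
  double dE = K * ((Ll1 - a) * (Ll1 - a) - (Ll0 - a) * (Ll0 - a) +
                   (Lr1 - b) * (Lr1 - b) - (Lr0 - b) * (Lr0 - b));
  dE += adhesion_window(xo, to, tl, tr, p1, wl, wr, eps) -
        adhesion_window(xo, to, tl, tr, p0, wl, wr, eps);
  return dE;
}

// [[Rcpp::export]]
double cpp_delta_energy(NumericVector x1, NumericVector x2, IntegerVector t1,
                        IntegerVector t2, NumericVector L01, NumericVector L02,
                        NumericMatrix eps, double K, int row, int vertex,
                        double dx) {
  const int N = L01.size();
  const int i = vertex - 1;  // 1-based vertex -> 0-based
  if (row < 1 || row > 2) stop("row must be 1 or 2");
  if (i < 1 || i > N - 1) stop("vertex must be interior (2..N)");
  const NumericVector& xr = (row == 1) ? x1 : x2;
  const double Ll = xr[i] - xr[i - 1], Lr = xr[i + 1] - xr[i];
  if ((dx > 0 && dx > Lr) || (dx < 0 && -dx > Ll))
    stop("move is not allowed (would flip or overlap cells)");
  if (row == 1) return delta_energy_core(x1, x2, t1, t2, L01, K, eps, i, dx);
  return delta_energy_core(x2, x1, t2, t1, L02, K, eps, i, dx);
}

// Mean over sister pairs of the pair mismatch ratio;
// transient zero-length cells take the limit value 1 (their overlap is 0).
static double tissue_mismatch_core(const NumericVector& x1,
                                   const NumericVector& x2) {
  const int N = x1.size() - 1;
  double s = 0.0;
  for (int i = 0; i < N; ++i) {
    const double L1 = x1[i + 1] - x1[i], L2 = x2[i + 1] - x2[i];
    double ov = std::min(x1[i + 1], x2[i + 1]) - std::max(x1[i], x2[i]);
    if (ov < 0) ov = 0;
    const double m1 = (L1 > 0) ? (L1 - ov) / L1 : 1.0;
    const double m2 = (L2 > 0) ? (L2 - ov) / L2 : 1.0;
    s += 0.5 * (m1 + m2);
  }
  return s / N;
}

// [[Rcpp::export]]
double cpp_tissue_mismatch(NumericVector x1, NumericVector x2) {
  return tissue_mismatch_core(x1, x2);
}

// Metropolis chain. Uses R's RNG (reproducible under set.seed); one step is
// one proposal. Records step index, tissue mismatch and (fully recomputed)
// total energy every `record_every` proposals, including step 0.
// [[Rcpp::export]]
List cpp_mcmc_run(NumericVector x1, NumericVector x2, IntegerVector t1,
                  IntegerVector t2, NumericVector L01, NumericVector L02,
                  NumericMatrix eps, double K, double E0, double deltaX,
                  double n_steps, int record_every,
                  bool record_positions = false) {
  NumericVector y1 = clone(x1), y2 = clone(x2);
  const int N = L01.size();
  if (N < 2) stop("need at least 2 cells per row (no movable vertex)");
  const long steps = (long)n_steps;
  const long n_rec = steps / record_every + 1;
  NumericVector rec_step(n_rec), rec_mis(n_rec), rec_E(n_rec);
  NumericMatrix P1, P2;
  if (record_positions) {
    P1 = NumericMatrix(n_rec, N + 1);
    P2 = NumericMatrix(n_rec, N + 1);
  }
  long r = 0, acc = 0;
  auto record = [&](long s) {
    rec_step[r] = (double)s;
    rec_mis[r] = tissue_mismatch_core(y1, y2);
    rec_E[r] = elastic_full(y1, L01, K) + elastic_full(y2, L02, K) +
               adhesion_full(y1, y2, t1, t2, eps);
    if (record_positions) {
      for (int k = 0; k <= N; ++k) {
        P1(r, k) = y1[k];
        P2(r, k) = y2[k];
      }
    }
    ++r;
  };
  record(0);
  for (long s = 1; s <= steps; ++s) {
    const int row = (unif_rand() < 0.5) ? 0 : 1;
    int i = 1 + (int)(unif_rand() * (N - 1));
    if (i > N - 1) i = N - 1;
    const double dx = norm_rand() * deltaX;
    NumericVector& xr = row == 0 ? y1 : y2;
    const double Ll = xr[i] - xr[i - 1], Lr = xr[i + 1] - xr[i];
    const bool allowed = !((dx > 0 && dx > Lr) || (dx < 0 && -dx > Ll));
    if (allowed) {
      const double dE =
          (row == 0)
              ? delta_energy_core(y1, y2, t1, t2, L01, K, eps, i, dx)
              : delta_energy_core(y2, y1, t2, t1, L02, K, eps, i, dx);
      const double p = (dE <= 0) ? 1.0 : std::exp(-dE / E0);
      if (unif_rand() < p) {
        xr[i] += dx;
        ++acc;
      }
    }
    if (s % record_every == 0) record(s);
  }
  List out = List::create(
      _["step"] = rec_step, _["mismatch"] = rec_mis, _["energy"] = rec_E,
      _["accepted"] = (double)acc, _["n_steps"] = (double)steps,
      _["x1"] = y1, _["x2"] = y2);
  if (record_positions) {
    out["pos1"] = P1;
    out["pos2"] = P2;
  }
  return out;
}

// Force on interior vertex i of row (x, t): difference of the interfacial
// tensions of the two segments flanking the vertex along the shared midline
// plus the logarithmic elastic terms of the two cells sharing the vertex.
static double vertex_force_core(const NumericVector& x,
                                const NumericVector& xo,
                                const IntegerVector& t,
                                const IntegerVector& to,
                                const NumericVector& L0,
                                const NumericVector& Kc,
                                const NumericMatrix& Tadh, int i) {
  const double p = x[i];
  const double Ll = x[i] - x[i - 1], Lr = x[i + 1] - x[i];
  if (Ll <= 0 || Lr <= 0) stop("degenerate geometry: non-positive cell length");
  const double Tl = Tadh(t[i - 1], to[cover_cell(xo, p, -1)]);
  const double Tr = Tadh(t[i], to[cover_cell(xo, p, +1)]);
  return (Tr - Tl) + Kc[i] * std::log(Lr / L0[i]) -
         Kc[i - 1] * std::log(Ll / L0[i - 1]);
}

// [[Rcpp::export]]
double cpp_vertex_force(NumericVector x1, NumericVector x2, IntegerVector t1,
                        IntegerVector t2, NumericVector L01, NumericVector L02,
                        NumericMatrix Tadh, NumericVector K1, NumericVector K2,
                        int row, int vertex) {
  const int N = L01.size();
  const int i = vertex - 1;
  if (i < 1 || i > N - 1) stop("vertex must be interior (2..N)");
  if (row == 1) return vertex_force_core(x1, x2, t1, t2, L01, K1, Tadh, i);
  return vertex_force_core(x2, x1, t2, t1, L02, K2, Tadh, i);
}

// Overdamped explicit-Euler integration, synchronous update, deterministic.
// A displacement larger than both adjacent cell lengths aborts (timestep too
// large); displacements that would push a cell below `len_floor` are clamped
// to half the available slack (both cell ends may move in one step).
// [[Rcpp::export]]
List cpp_dynamics_run(NumericVector x1, NumericVector x2, IntegerVector t1,
                      IntegerVector t2, NumericVector L01, NumericVector L02,
                      NumericMatrix Tadh, NumericVector K1, NumericVector K2,
                      double xi, double dt, double n_steps, int record_every,
                      double len_floor = 1e-6) {
  NumericVector y1 = clone(x1), y2 = clone(x2);
  const int N = L01.size();
  const long steps = (long)n_steps;
  const long n_rec = steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_mis(n_rec);
  long r = 0, clamped = 0;
  rec_t[0] = 0.0;
  rec_mis[0] = tissue_mismatch_core(y1, y2);
  ++r;
  std::vector<double> d1(N + 1, 0.0), d2(N + 1, 0.0);
  for (long s = 1; s <= steps; ++s) {
    for (int rowi = 0; rowi < 2; ++rowi) {
      NumericVector& x = rowi == 0 ? y1 : y2;
      const NumericVector& xo = rowi == 0 ? y2 : y1;
      const IntegerVector& t = rowi == 0 ? t1 : t2;
      const IntegerVector& to = rowi == 0 ? t2 : t1;
      const NumericVector& L0 = rowi == 0 ? L01 : L02;
      const NumericVector& Kc = rowi == 0 ? K1 : K2;
      std::vector<double>& d = rowi == 0 ? d1 : d2;
      for (int i = 1; i <= N - 1; ++i) {
        double dx =
            (dt / xi) * vertex_force_core(x, xo, t, to, L0, Kc, Tadh, i);
        const double Ll = x[i] - x[i - 1], Lr = x[i + 1] - x[i];
        if (std::abs(dx) > std::max(Ll, Lr))
          stop("unstable step: |dx| exceeds adjacent cell length; reduce dt");
        const double lo = -std::max(0.0, Ll - len_floor) / 2.0;
        const double hi = std::max(0.0, Lr - len_floor) / 2.0;
        if (dx < lo) {
          dx = lo;
          ++clamped;
        } else if (dx > hi) {
          dx = hi;
          ++clamped;
        }
        d[i] = dx;
      }
    }
    for (int i = 1; i <= N - 1; ++i) {
      y1[i] += d1[i];
      y2[i] += d2[i];
    }
    if (s % record_every == 0) {
      rec_t[r] = s * dt;
      rec_mis[r] = tissue_mismatch_core(y1, y2);
      ++r;
    }
  }
  return List::create(_["time"] = rec_t, _["mismatch"] = rec_mis,
                      _["x1"] = y1, _["x2"] = y2,
                      _["n_clamped"] = (double)clamped);
}
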