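// Agent-based swarm engine: velocity alignment plus an inferred local-density
// preference, with per-agent Bayesian / inverse-Bayesian state.
//
// All randomness is drawn from R's RNG (unif_rand) in a fixed documented
// order so that runs are reproducible from set.seed() and so that the pure-R
// reference engine in R/swarm.R can consume the identical stream:
//   per step:  N-1 shuffle draws (asynchronous order only)
//   per agent: h_max tie draw (only when tied), d_max tie draw (only when
//              tied), candidate tie draw (only when tied), and in BIB mode
//              an h_s tie draw (only when tied) followed by one replacement
//              coin.
//
// std::fmod is deliberately avoided (its C23 symbol version is not loadable
// on every glibc this package targets); wrapping uses floor arithmetic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int NSYM = 4;
const int NCAND = 72;
// belief lower bound: replaced likelihood rows can contain exact zeros, and
// a hypothesis whose probability underflows to zero is absorbing under
// multiplicative updating; the floor keeps every hypothesis revivable
const double BELIEF_FLOOR = 1e-12;

inline double wrap_coord(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}

// one bounce is enough: per-step moves are far smaller than the arena
inline double reflect_coord(double x, double L) {
  if (x < 0) x = -x;
  if (x > L) x = 2 * L - x;
  if (x < 0) x = 0;
  if (x > L) x = L;
  return x;
}

inline double coord_diff(double a, double b, double L, bool periodic) {
  double d = a - b;
  if (periodic) {
    if (d > L / 2) d -= L;
    else if (d < -L / 2) d += L;
  }
  return d;
}

inline int density_code(int nr, int n2r) {
  if (n2r == 0) return 0;
  int d = (int)(4.0 * nr / n2r);
  return d > 3 ? 3 : d;
}

// uniform pick from ties; consumes one variate only when |ties| > 1
inline int pick_tie(const std::vector<int> &ties) {
  if (ties.size() == 1) return ties[0];
  int k = (int)std::floor(unif_rand() * ties.size());
  if (k >= (int)ties.size()) k = (int)ties.size() - 1;
  return ties[k];
}

} // namespace

// [[Rcpp::export(name = ".swarm_engine_cpp")]]
List swarm_engine_cpp(int N, double r, double R_align, double p, double u,
                      int M, double L, int T, bool bib, bool async,
                      bool periodic, bool record) {
  const int n = NSYM;
  std::vector<double> px(N), py(N), vx(N), vy(N);
  std::vector<double> opx, opy, ovx, ovy; // synchronous-mode snapshot
  std::vector<double> belief(N * n, 1.0 / n);
  std::vector<double> lik(N * n * n);
  for (int i = 0; i < N; i++)
    for (int k = 0; k < n; k++)
      for (int j = 0; j < n; j++)
        lik[(i * n + k) * n + j] = (j == k) ? p : (1 - p) / (n - 1);
  std::vector<int> win(N * M, -1), winlen(N, 0), winpos(N, 0);
  std::vector<int> counts(N * n, 0);

  // initial conditions: uniform positions, uniform headings at speed u
  for (int i = 0; i < N; i++) {
    px[i] = unif_rand() * L;
    py[i] = unif_rand() * L;
    double th = unif_rand() * 2 * M_PI;
    vx[i] = u * std::cos(th);
    vy[i] = u * std::sin(th);
  }

  NumericVector psi(T), d_mean(T);
  NumericMatrix X, Y;
  IntegerMatrix D;
  if (record) {
    X = NumericMatrix(T + 1, N);
    Y = NumericMatrix(T + 1, N);
    D = IntegerMatrix(T, N);
    for (int i = 0; i < N; i++) { X(0, i) = px[i]; Y(0, i) = py[i]; }
  }

  std::vector<double> cth(NCAND), sth(NCAND);
  for (int k = 0; k < NCAND; k++) {
    cth[k] = std::cos(k * M_PI / 36.0);
    sth[k] = std::sin(k * M_PI / 36.0);
  }
  std::vector<int> order(N);
  std::vector<double> sdx, sdy;
  std::vector<int> ties;
  sdx.reserve(N); sdy.reserve(N); ties.reserve(NCAND);

  for (int t = 0; t < T; t++) {
    for (int i = 0; i < N; i++) order[i] = i;
    if (async) {
      for (int i = N - 1; i > 0; i--) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
    } else {
      opx = px; opy = py; ovx = vx; ovy = vy;
    }
    const std::vector<double> &qx = async ? px : opx;
    const std::vector<double> &qy = async ? py : opy;
    const std::vector<double> &qvx = async ? vx : ovx;
    const std::vector<double> &qvy = async ? vy : ovy;
    double dsum = 0;

    for (int oi = 0; oi < N; oi++) {
      int i = order[oi];
      double xi = async ? px[i] : opx[i];
      double yi = async ? py[i] : opy[i];

      // (1) observe the density datum at the current position
      int nr = 0, n2r = 0, nal = 0;
      double svx = 0, svy = 0;
      for (int j = 0; j < N; j++) {
        double dx = coord_diff(qx[j], xi, L, periodic);
        double dy = coord_diff(qy[j], yi, L, periodic);
        double d2 = dx * dx + dy * dy;
        if (j != i) {
          if (d2 <= r * r) nr++;
          if (d2 <= 4 * r * r) n2r++;
        }
        if (d2 <= R_align * R_align) { svx += qvx[j]; svy += qvy[j]; nal++; }
      }
      int dobs = density_code(nr, n2r);
      dsum += dobs;
      if (record) D(t, i) = dobs;

      // (2) window append (oldest evicted) and Bayesian update
      if (winlen[i] == M) {
        counts[i * n + win[i * M + winpos[i]]]--;
      } else winlen[i]++;
      win[i * M + winpos[i]] = dobs;
      counts[i * n + dobs]++;
      winpos[i] = (winpos[i] + 1) % M;

      double *bel = &belief[i * n];
      double *Lk = &lik[i * n * n];
      double den = 0;
      for (int k = 0; k < n; k++) den += Lk[k * n + dobs] * bel[k];
      if (den > 0)
        for (int k = 0; k < n; k++) bel[k] = Lk[k * n + dobs] * bel[k] / den;
      bool low = false;
      for (int k = 0; k < n; k++) if (bel[k] < BELIEF_FLOOR) low = true;
      if (low) {
        double bs = 0;
        for (int k = 0; k < n; k++) {
          if (bel[k] < BELIEF_FLOOR) bel[k] = BELIEF_FLOOR;
          bs += bel[k];
        }
        for (int k = 0; k < n; k++) bel[k] /= bs;
      }

      // (3) h_max, then the preferred density d_max from its likelihood row
      double bmax = bel[0];
      for (int k = 1; k < n; k++) if (bel[k] > bmax) bmax = bel[k];
      ties.clear();
      for (int k = 0; k < n; k++) if (bel[k] == bmax) ties.push_back(k);
      int hmax = pick_tie(ties);
      double pmax = Lk[hmax * n];
      for (int j = 1; j < n; j++)
        if (Lk[hmax * n + j] > pmax) pmax = Lk[hmax * n + j];
      ties.clear();
      for (int j = 0; j < n; j++)
        if (Lk[hmax * n + j] == pmax) ties.push_back(j);
      int dmax = pick_tie(ties);

      // (4) anticipated position from the alignment rule (focal included)
      double ax = svx / nal, ay = svy / nal;
      double hx = xi + ax, hy = yi + ay;
      if (periodic) { hx = wrap_coord(hx, L); hy = wrap_coord(hy, L); }
      else { hx = reflect_coord(hx, L); hy = reflect_coord(hy, L); }

      // (5) choose among the 72 candidates on the u-circle around x-hat the
      // one whose density datum is closest to d_max.  Only neighbours within
      // u of the r / 2r circles can change counts between candidates, so the
      // rest contribute fixed base counts.
      int base_r = 0, base_2r = 0;
      sdx.clear(); sdy.clear();
      double rin = r - u > 0 ? r - u : 0, rout = r + u;
      double r2in = 2 * r - u > 0 ? 2 * r - u : 0, r2out = 2 * r + u;
      for (int j = 0; j < N; j++) {
        if (j == i) continue;
        double dx = coord_diff(qx[j], hx, L, periodic);
        double dy = coord_diff(qy[j], hy, L, periodic);
        double dd = std::sqrt(dx * dx + dy * dy);
        if (dd < rin) { base_r++; base_2r++; continue; }
        if (dd > r2out) continue;
        if (dd > rout && dd < r2in) { base_2r++; continue; }
        sdx.push_back(dx); sdy.push_back(dy);
      }
      int best = NSYM + 1;
      ties.clear();
      for (int k = 0; k < NCAND; k++) {
        double cx = u * cth[k], cy = u * sth[k];
        int cnr = base_r, cn2r = base_2r;
        for (size_t s = 0; s < sdx.size(); s++) {
          double dx = sdx[s] - cx, dy = sdy[s] - cy;
          double d2 = dx * dx + dy * dy;
          if (d2 <= r * r) cnr++;
          if (d2 <= 4 * r * r) cn2r++;
        }
        int sc = density_code(cnr, cn2r) - dmax;
        if (sc < 0) sc = -sc;
        if (sc < best) { best = sc; ties.clear(); ties.push_back(k); }
        else if (sc == best) ties.push_back(k);
      }
      int kc = pick_tie(ties);

      // (6) move; the velocity is the realized displacement
      double nxp = hx + u * cth[kc], nyp = hy + u * sth[kc];
      if (periodic) { nxp = wrap_coord(nxp, L); nyp = wrap_coord(nyp, L); }
      else { nxp = reflect_coord(nxp, L); nyp = reflect_coord(nyp, L); }
      vx[i] = coord_diff(nxp, xi, L, periodic);
      vy[i] = coord_diff(nyp, yi, L, periodic);
      px[i] = nxp; py[i] = nyp;

      // (7) inverse-Bayesian replacement from the agent's own window
      if (bib && winlen[i] > 0) {
        double bmin = bel[0];
        for (int k = 1; k < n; k++) if (bel[k] < bmin) bmin = bel[k];
        ties.clear();
        for (int k = 0; k < n; k++) if (bel[k] == bmin) ties.push_back(k);
        int hs = pick_tie(ties);
        if (unif_rand() < 1 - bel[hs]) {
          for (int j = 0; j < n; j++)
            Lk[hs * n + j] = (double)counts[i * n + j] / winlen[i];
        }
      }
    }

    // polarization of the realized velocities
    double sx = 0, sy = 0;
    int inc = 0;
    for (int i = 0; i < N; i++) {
      double nv = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
      if (nv > 0) { sx += vx[i] / nv; sy += vy[i] / nv; inc++; }
    }
    psi[t] = inc > 0 ? std::sqrt(sx * sx + sy * sy) / inc : NA_REAL;
    d_mean[t] = dsum / N;
    if (record) {
      for (int i = 0; i < N; i++) { X(t + 1, i) = px[i]; Y(t + 1, i) = py[i]; }
    }
  }

  NumericMatrix bel_out(N, n);
  NumericVector lik_out(Dimension(n, n, N));
  for (int i = 0; i < N; i++) {
    for (int k = 0; k < n; k++) {
      bel_out(i, k) = belief[i * n + k];
      for (int j = 0; j < n; j++)
        lik_out[i * n * n + j * n + k] = lik[(i * n + k) * n + j];
    }
  }

  List out = List::create(
    _["psi"] = psi, _["d_mean"] = d_mean,
    _["belief"] = bel_out, _["likelihood"] = lik_out);
  if (record) {
    out["x"] = X;
    out["y"] = Y;
    out["d"] = D;
  }
  return out;
}
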