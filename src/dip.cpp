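// Hartigan dip statistic for unimodality.
//
// The dip of an empirical CDF F_n is the smallest d such that some unimodal
// (convex-then-concave) distribution function stays within a sup-norm band
// of half-width d around F_n.  Tied observations are treated as
// infinitesimally separated order statistics, the convention of the
// classical index-based algorithm; it implies dip >= 1/(2n) for every
// sample, with equality for perfectly unimodal configurations, and
// dip = 1/2 for a single observation.
//
// Computation: collapse the sample to distinct values v_1 < ... < v_K with
// cumulative proportions p_0 = 0 <= ... <= p_K = 1.  Placing the mode at
// v_k, a band-feasible unimodal CDF exists at level d iff
//   * a nondecreasing convex chain L_1..L_{k-1}, a with
//       L_t in [p_t - d, p_{t-1} + d],  a in [p_{k-1} - d, p_{k-1} + d]
//   * a nondecreasing concave chain b, R_{k+1}..R_K with
//       R_t in [p_t - d, p_{t-1} + d],  b in [p_k - d, p_k + d]
//   * a <= b  (the mode's atom is climbed between a and b)
// all exist (values clamped to [0, 1]).  Mode-in-gap placements are special
// cases of the adjacent mode-at-value placements.  Feasibility of a convex
// chain through interval constraints is decided exactly by propagating the
// reachable set in the (value, slope) plane, which stays a convex polygon
// under the three per-step operations (slope relaxation upward, shear by
// the spacing, clipping to the band).  The dip is then located by bisection
// over d; the bound 1/(2n) is returned exactly when it is feasible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct P2 {
  double l;  // CDF value
  double s;  // incoming rise (slope * gap)
};

typedef std::vector<P2> Poly;

// scratch buffers reused across calls to avoid allocation churn
struct Workspace {
  Poly poly, q, e, pts, h;
  std::vector<double> v, p, aLo, aHi, bLo, bHi;
  std::vector<char> aOk, bOk;
};

double cross(const P2& o, const P2& a, const P2& b) {
  return (a.l - o.l) * (b.s - o.s) - (a.s - o.s) * (b.l - o.l);
}

// Convex hull (monotone chain) of pts into h; tolerant of degenerate input.
void hull(Poly& pts, Poly& h) {
  const size_t n = pts.size();
  h.clear();
  if (n <= 2) { h = pts; return; }
  std::sort(pts.begin(), pts.end(), [](const P2& a, const P2& b) {
    return a.l < b.l || (a.l == b.l && a.s < b.s);
  });
  h.resize(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {  // lower
    while (k >= 2 && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  for (size_t i = n - 1, t = k + 1; i-- > 0;) {  // upper
    while (k >= t && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k > 1 ? k - 1 : k);
}

// Clip convex polygon to halfplane keep: a*l + b*s <= c; result in out.
void clip_hp(const Poly& poly, double a, double b, double c, double eps,
             Poly& out) {
  out.clear();
  const size_t n = poly.size();
  if (n == 0) return;
  for (size_t i = 0; i < n; ++i) {
    const P2& cur = poly[i];
    const P2& nxt = poly[(i + 1) % n];
    const double dc = a * cur.l + b * cur.s - c;
    const double dn = a * nxt.l + b * nxt.s - c;
    if (dc <= eps) out.push_back(cur);
    if ((dc < -eps && dn > eps) || (dc > eps && dn < -eps)) {
      const double t = dc / (dc - dn);
      P2 ip;
      ip.l = cur.l + t * (nxt.l - cur.l);
      ip.s = cur.s + t * (nxt.s - cur.s);
      out.push_back(ip);
    }
    if (n == 1) break;
  }
}

// Allow the incoming rise to grow anywhere up to cap (convexity step).
void relax_up(Poly& poly, double cap, Poly& pts, Poly& out) {
  if (poly.empty()) { out.clear(); return; }
  double lmin = poly[0].l, lmax = poly[0].l;
  for (const P2& p : poly) {
    lmin = std::min(lmin, p.l);
    lmax = std::max(lmax, p.l);
  }
  pts = poly;
  P2 a; a.l = lmin; a.s = cap; pts.push_back(a);
  P2 b; b.l = lmax; b.s = cap; pts.push_back(b);
  hull(pts, out);
}

void shear(Poly& poly) {
  for (P2& p : poly) p.l += p.s;
}

void l_range(const Poly& poly, double& lo, double& hi) {
  lo = R_PosInf; hi = R_NegInf;
  for (const P2& p : poly) {
    lo = std::min(lo, p.l);
    hi = std::max(hi, p.l);
  }
}

// One-directional chain sweep.  For direction = +1 this walks t = 1..K and
// records, for every candidate mode position k, the achievable interval of
// the convex chain endpoint a at v_k (endpoint band centred on p_{k-1}).
// For direction = -1 it walks t = K..1 for the concave side (endpoint band
// centred on p_k): reflecting the axis alone preserves concavity, so the
// values are negated as well (H = -R on u = -v), which makes the concave
// chain convex and reuses the same propagation; the recorded endpoint
// intervals are mapped back to the original scale.
//
// The slope state is stored as the rise over the gap just traversed
// (r = slope * gap), keeping every coordinate O(1): convexity becomes
// r_next >= r_prev * (gap_next / gap_prev), and rises that overshoot the
// reachable bands are clipped away before they can degrade the polygon
// arithmetic.
void sweep(Workspace& ws, double d, int direction,
           std::vector<double>& eLo, std::vector<double>& eHi,
           std::vector<char>& eOk) {
  const std::vector<double>& v = ws.v;
  const std::vector<double>& p = ws.p;
  const int K = static_cast<int>(v.size());
  const double eps = 1e-12;
  eLo.assign(K, 0.0); eHi.assign(K, 0.0); eOk.assign(K, 0);

  // interior band at value index t (0-based): [p[t+1] - d, p[t] + d] clamped
  // left endpoint band at k: [p[k] - d, p[k] + d]   (p before the stack)
  // right endpoint band at k: [p[k+1] - d, p[k+1] + d]  (p after the stack)
  Poly& poly = ws.poly;
  Poly& q = ws.q;
  bool alive = false;
  double prev_dx = -1.0;
  const double flip = (direction > 0) ? 1.0 : -1.0;

  for (int step = 0; step < K; ++step) {
    const int t = (direction > 0) ? step : (K - 1 - step);
    const double pe = (direction > 0) ? p[t] : p[t + 1];  // endpoint band centre
    double elo = std::max(0.0, pe - d);
    double ehi = std::min(1.0, pe + d);
    double ilo = std::max(0.0, p[t + 1] - d);
    double ihi = std::min(1.0, p[t] + d);
    const bool eEmpty = elo > ehi + eps;
    const bool iEmpty = ilo > ihi + eps;
    if (flip < 0) {  // work on negated values
      std::swap(elo, ehi); elo = -elo; ehi = -ehi;
      std::swap(ilo, ihi); ilo = -ilo; ihi = -ihi;
    }

    if (step == 0) {
      if (!eEmpty) {
        eOk[t] = 1;
        eLo[t] = flip > 0 ? elo : -ehi;
        eHi[t] = flip > 0 ? ehi : -elo;
      }
      if (!iEmpty) {
        P2 a; a.l = ilo; a.s = 0.0;
        P2 b; b.l = ihi; b.s = 0.0;
        poly.clear(); poly.push_back(a);
        if (ihi > ilo) poly.push_back(b);
        alive = true;
        prev_dx = -1.0;  // no gap traversed yet; state rises are all zero
      }
      continue;
    }
    if (!alive) continue;
    const int tprev = (direction > 0) ? (t - 1) : (t + 1);
    const double dx = std::fabs(v[t] - v[tprev]);
    q = poly;
    if (prev_dx > 0.0 && prev_dx != dx) {
      const double ratio = dx / prev_dx;
      for (P2& pt : q) pt.s *= ratio;  // convexity in rise units
    }
    prev_dx = dx;
    // rises beyond the reachable bands can never survive the value clip
    double lmin, lmax;
    l_range(q, lmin, lmax);
    const double cap = std::max(ihi, eEmpty ? ihi : ehi) - lmin + 1e-9;
    if (cap < 0) { alive = false; poly.clear(); continue; }
    clip_hp(q, 0.0, 1.0, cap, eps, ws.e);        // r <= cap
    if (ws.e.empty()) { alive = false; poly.clear(); continue; }
    relax_up(ws.e, cap, ws.pts, ws.h);
    q = ws.h;
    shear(q);                                    // l += r (rise units)
    // endpoint extraction
    if (!eEmpty) {
      clip_hp(q, 1.0, 0.0, ehi, eps, ws.e);      // l <= ehi
      clip_hp(ws.e, -1.0, 0.0, -elo, eps, ws.pts);
      if (!ws.pts.empty()) {
        double lo, hi; l_range(ws.pts, lo, hi);
        eOk[t] = 1;
        eLo[t] = flip > 0 ? lo : -hi;
        eHi[t] = flip > 0 ? hi : -lo;
      }
    }
    // interior continuation
    if (iEmpty) { alive = false; poly.clear(); continue; }
    clip_hp(q, 1.0, 0.0, ihi, eps, ws.e);
    clip_hp(ws.e, -1.0, 0.0, -ilo, eps, poly);
    if (poly.empty()) alive = false;
  }
}

bool feasible(Workspace& ws, double d) {
  const int K = static_cast<int>(ws.v.size());
  sweep(ws, d, +1, ws.aLo, ws.aHi, ws.aOk);
  bool any = false;
  for (int k = 0; k < K; ++k) if (ws.aOk[k]) { any = true; break; }
  if (!any) return false;
  sweep(ws, d, -1, ws.bLo, ws.bHi, ws.bOk);
  for (int k = 0; k < K; ++k) {
    if (ws.aOk[k] && ws.bOk[k] && ws.aLo[k] <= ws.bHi[k] + 1e-12) return true;
  }
  return false;
}

double dip_sorted(Workspace& ws, const std::vector<double>& x) {
  const int n = static_cast<int>(x.size());
  if (n < 1) Rcpp::stop("empty sample");
  const double floor_d = 0.5 / n;
  // collapse ties
  ws.v.clear();
  ws.p.assign(1, 0.0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[j] == x[i]) ++j;
    ws.v.push_back(x[i]);
    ws.p.push_back(static_cast<double>(j) / n);
    i = j;
  }
  if (ws.v.size() == 1) return floor_d;

  if (feasible(ws, floor_d + 1e-13)) return floor_d;
  double lo = floor_d, hi = 0.2500001;
  if (!feasible(ws, hi)) hi = 0.5000001;  // defensive; dip <= 1/4
  for (int it = 0; it < 40; ++it) {
    const double mid = 0.5 * (lo + hi);
    if (feasible(ws, mid)) hi = mid; else lo = mid;
  }
  return 0.5 * (lo + hi);
}

}  // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  for (double xi : xs)
    if (!R_FINITE(xi)) Rcpp::stop("non-finite values in sample");
  std::sort(xs.begin(), xs.end());
  Workspace ws;
  return dip_sorted(ws, xs);
}

// [[Rcpp::export(name = ".dip_stat_batch_cpp")]]
NumericVector dip_stat_batch_cpp(NumericMatrix m) {
  const int reps = m.ncol();
  NumericVector out(reps);
  std::vector<double> xs(m.nrow());
  Workspace ws;
  for (int j = 0; j < reps; ++j) {
    for (int i = 0; i < m.nrow(); ++i) xs[i] = m(i, j);
    std::sort(xs.begin(), xs.end());
    out[j] = dip_sorted(ws, xs);
  }
  return out;
}

// Subsampled crowdsourcing runs: for each run and each picture draw k
// ratings without replacement from that picture's pool and record the run
// mean and SD.  Uses R's RNG so results are reproducible under set.seed().
// pool: pictures x max_pool matrix padded with NA; sizes: ratings per picture.
// [[Rcpp::export(name = ".sim_run_stats_cpp")]]
List sim_run_stats_cpp(NumericMatrix pool, IntegerVector sizes, int k, int nruns) {
  const int np = pool.nrow();
  NumericMatrix means(np, nruns), sds(np, nruns);
  std::vector<double> buf;
  std::vector<int> idx;
  GetRNGstate();
  for (int r = 0; r < nruns; ++r) {
    for (int i = 0; i < np; ++i) {
      const int m = sizes[i];
      idx.resize(m);
      for (int j = 0; j < m; ++j) idx[j] = j;
      // partial Fisher-Yates for k draws
      double sum = 0.0, sumsq = 0.0;
      for (int j = 0; j < k; ++j) {
        const int pick = j + static_cast<int>(unif_rand() * (m - j));
        std::swap(idx[j], idx[pick]);
        const double val = pool(i, idx[j]);
        sum += val;
        sumsq += val * val;
      }
      const double mean = sum / k;
      means(i, r) = mean;
      sds(i, r) = (k > 1) ? std::sqrt(std::max(0.0, (sumsq - k * mean * mean) / (k - 1)))
                          : NA_REAL;
    }
  }
  PutRNGstate();
  return List::create(_["means"] = means, _["sds"] = sds);
}
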