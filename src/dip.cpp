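#include <Rcpp.h>
using namespace Rcpp;

// Hartigan & Hartigan dip statistic for a sorted sample.
//
//   dip(F_n) = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|
//
// Write the empirical CDF in count units: c_k = cumulative count at the k-th
// unique value t_k (c_0 = 0).  G lies within sup-distance d = h/n of F_n iff
// its values thread the tubes [c_k - h, c_{k-1} + h]: a convex increasing
// chain left of the mode, a concave increasing chain right of it, joined
// monotonically (G may jump upward at the mode).  For each mode placement
// (inside a gap between unique values, or at a unique value, where the tube
// constraint at that value is dropped) the minimal 2h decomposes into three
// terms, each computable from convex hulls of the count points:
//
//   left term  A = max_k [ c_k - gcm(t_k) ],  gcm = lower hull of (t_i, c_{i-1})
//   right term B = max_k [ lcm(t_k) - c_{k-1} ], lcm = upper hull of (t_i, c_i)
//   link term: the chains must join monotonically across the mode, i.e.
//     amin <= bmax, where amin is the smallest feasible value of the convex
//     chain at its right end and bmax the largest feasible value of the
//     concave chain at its left end.  Both are extreme values of threading
//     chains and reduce to maxima over two-point anchor bounds
//       amin = max(L_j, max_{k1<k2} [ L_k2 + (L_k2 - U_k1) (t_j - t_k2)/(t_k2 - t_k1) ])
//     (mirrored for bmax), with L = c - h, U = c_prev + h.
//
// The dip is min over mode placements of max(A, B, link)/2n.  A is
// nondecreasing and B nonincreasing along the ordered placements, so the
// linked minimum is found by scanning placements in increasing max(A, B)
// with binary search on h for the link term.  The whole construction is
// cross-checked against an exact linear-programming minimization over
// unimodal CDFs on small fixtures (see the test suite).

namespace {

struct DipCtx {
  const double *t;  // 1-based unique values
  const double *c;  // 1-based cumulative counts, c[0] = 0
  int K;
  double n;
  std::vector<int> stack;

  double L(int k, double h) const { return c[k] - h; }
  double U(int k, double h) const { return c[k - 1] + h; }

  // A(j, pt) = max_{k <= j - pt} [ c_k - hull(t_k) ],
  // hull = lower convex hull of (t_i, c_{i-1}), i = 1..j
  double left_term(int j, int pt) {
    int kmax = j - pt;
    if (j < 1 || kmax < 1) return 0.0;
    stack.clear();
    for (int i = 1; i <= j; ++i) {
      while (stack.size() >= 2) {
        int b = stack[stack.size() - 1], a = stack[stack.size() - 2];
        if ((c[b - 1] - c[a - 1]) * (t[i] - t[b]) <
            (c[i - 1] - c[b - 1]) * (t[b] - t[a])) break;
        stack.pop_back();
      }
      stack.push_back(i);
    }
    double best = 0.0;
    size_t seg = 0;
    for (int k = 1; k <= kmax; ++k) {
      while (seg + 1 < stack.size() && t[stack[seg + 1]] < t[k]) ++seg;
      int a = stack[seg];
      double hv;
      if (seg + 1 >= stack.size() || t[k] <= t[a]) {
        hv = c[a - 1];
      } else {
        int b = stack[seg + 1];
        hv = c[a - 1] + (t[k] - t[a]) * (c[b - 1] - c[a - 1]) / (t[b] - t[a]);
      }
      double dev = c[k] - hv;
      if (dev > best) best = dev;
    }
    return best;
  }

  // B(s, pt) = max_{k >= s + pt} [ hull(t_k) - c_{k-1} ],
  // hull = upper concave hull of (t_i, c_i), i = s..K
  double right_term(int s, int pt) {
    int kmin = s + pt;
    if (s > K || kmin > K) return 0.0;
    stack.clear();
    for (int i = K; i >= s; --i) {
      while (stack.size() >= 2) {
        int b = stack[stack.size() - 1], a = stack[stack.size() - 2];
        if ((c[b] - c[i]) * (t[a] - t[b]) >
            (c[a] - c[b]) * (t[b] - t[i])) break;
        stack.pop_back();
      }
      stack.push_back(i);
    }
    double best = 0.0;
    size_t seg = 0;
    for (int k = K; k >= kmin; --k) {
      while (seg + 1 < stack.size() && t[stack[seg + 1]] > t[k]) ++seg;
      int a = stack[seg];
      double hv;
      if (seg + 1 >= stack.size() || t[k] >= t[a]) {
        hv = c[a];
      } else {
        int b = stack[seg + 1];
        hv = c[a] + (t[k] - t[a]) * (c[b] - c[a]) / (t[b] - t[a]);
      }
      double dev = hv - c[k - 1];
      if (dev > best) best = dev;
    }
    return best;
  }

  // smallest feasible right-end value of the convex chain for placement
  // (gap j: region 1..j, end t_j; point M: region 1..M without the lower
  // tube constraint at t_M itself)
  double amin(int j, int pt, double h) {
    if (j < 1 || (pt && j < 2)) return 0.0;
    int k2max = j - pt;
    double te = t[j];
    double best = pt ? L(j - 1, h) : L(j, h);
    // lower hull of upper-tube points (t_i, U_i); tangent query per k2
    std::vector<int> hull;
    for (int k2 = 1; k2 <= k2max; ++k2) {
      if (hull.size() >= 1 && k2 >= 2) {
        // max slope from (t_k2, L_k2) back to hull points: unimodal in index
        int lo = 0, hi = (int)hull.size() - 1;
        while (hi - lo > 2) {
          int m1 = lo + (hi - lo) / 3, m2 = hi - (hi - lo) / 3;
          double s1 = (L(k2, h) - U(hull[m1], h)) / (t[k2] - t[hull[m1]]);
          double s2 = (L(k2, h) - U(hull[m2], h)) / (t[k2] - t[hull[m2]]);
          if (s1 < s2) lo = m1 + 1; else hi = m2 - 1;
        }
        double s = -R_PosInf;
        for (int i = lo; i <= hi; ++i) {
          double si = (L(k2, h) - U(hull[i], h)) / (t[k2] - t[hull[i]]);
          if (si > s) s = si;
        }
        double cand = L(k2, h) + s * (te - t[k2]);
        if (cand > best) best = cand;
      }
      // push (t_k2, U_k2) onto the lower hull
      while (hull.size() >= 2) {
        int b = hull[hull.size() - 1], a = hull[hull.size() - 2];
        if ((U(b, h) - U(a, h)) * (t[k2] - t[b]) <
            (U(k2, h) - U(b, h)) * (t[b] - t[a])) break;
        hull.pop_back();
      }
      hull.push_back(k2);
    }
    return best > 0.0 ? best : 0.0;
  }

  // largest feasible left-end value of the concave chain for placement
  // (gap j: region s = j+1..K, start t_s; point M: region M..K without the
  // upper tube constraint at t_M itself)
  double bmax(int s, int pt, double h) {
    if (s > K || (pt && s > K - 1)) return n;
    int k3min = s + pt;
    double ts = t[s];
    double best = pt ? U(s + 1, h) : U(s, h);
    // upper hull of lower-tube points (t_i, L_i), scanned right-to-left;
    // hull holds indices in decreasing t order (all right of the query point)
    std::vector<int> hull;
    for (int k3 = K; k3 >= k3min; --k3) {
      if (hull.size() >= 1 && k3 <= K - 1) {
        // steepest forward slope from (t_k3, U_k3) to a hull point:
        // unimodal along the hull, so ternary search for the maximum
        int lo = 0, hi = (int)hull.size() - 1;
        while (hi - lo > 2) {
          int m1 = lo + (hi - lo) / 3, m2 = hi - (hi - lo) / 3;
          double s1 = (L(hull[m1], h) - U(k3, h)) / (t[hull[m1]] - t[k3]);
          double s2 = (L(hull[m2], h) - U(k3, h)) / (t[hull[m2]] - t[k3]);
          if (s1 < s2) lo = m1 + 1; else hi = m2 - 1;
        }
        double sl = -R_PosInf;
        for (int i = lo; i <= hi; ++i) {
          double si = (L(hull[i], h) - U(k3, h)) / (t[hull[i]] - t[k3]);
          if (si > sl) sl = si;
        }
        double cand = U(k3, h) + sl * (ts - t[k3]);  // ts < t[k3]
        if (cand < best) best = cand;
      }
      // keep b while slope(k3 -> b) > slope(b -> a), i.e. b above chord
      while (hull.size() >= 2) {
        int b = hull[hull.size() - 1], a = hull[hull.size() - 2];
        if ((L(b, h) - L(k3, h)) * (t[a] - t[b]) >
            (L(a, h) - L(b, h)) * (t[b] - t[k3])) break;
        hull.pop_back();
      }
      hull.push_back(k3);
    }
    return best < n ? best : n;
  }

  // variant v: even -> mode in gap j = v/2; odd -> mode at point M = (v+1)/2
  double lterm(int v) {
    return (v % 2 == 0) ? left_term(v / 2, 0) : left_term((v + 1) / 2, 1);
  }
  double rterm(int v) {
    return (v % 2 == 0) ? right_term(v / 2 + 1, 0) : right_term((v + 1) / 2, 1);
  }
  bool link_ok(int v, double h) {
    int j, s, pt;
    if (v % 2 == 0) { j = v / 2; s = j + 1; pt = 0; }
    else { j = (v + 1) / 2; s = j; pt = 1; }
    if (j < 1 || s > K) return true;  // one side empty: no join needed
    return amin(j, pt, h) <= bmax(s, pt, h) + 1e-9;
  }

  // exact per-variant value of 2h, given its side bound m = max(A, B)
  double exact_variant(int v, double m, double cap) {
    if (link_ok(v, m / 2.0)) return m;
    // bracket the link threshold: corrections are usually < 1 count unit
    double lo = m / 2.0, hi = lo + 0.25, capH = cap / 2.0;
    while (hi < capH && !link_ok(v, hi)) {
      lo = hi;
      hi = lo + 2.0 * (hi - m / 2.0);
    }
    if (hi >= capH) {
      if (!link_ok(v, capH)) return R_PosInf;  // worse than current best
      hi = capH;
    }
    for (int it = 0; it < 50 && hi - lo > 1e-7; ++it) {
      double mid = (lo + hi) / 2.0;
      if (link_ok(v, mid)) hi = mid; else lo = mid;
    }
    return 2.0 * hi;
  }
};

}  // namespace

// [[Rcpp::export(name = ".dip_sorted")]]
double dip_sorted(NumericVector x) {
  const int n = x.size();
  if (n < 2) return 0.0;
  if (x[n - 1] == x[0]) return 0.0;  // point mass: exactly unimodal

  std::vector<double> t(n + 1), c(n + 1);
  c[0] = 0.0;
  int K = 0;
  for (int i = 0; i < n; ++i) {
    if (K == 0 || x[i] > t[K]) {
      ++K;
      t[K] = x[i];
      c[K] = c[K - 1];
    }
    c[K] += 1.0;
  }

  DipCtx w;
  w.t = t.data();
  w.c = c.data();
  w.K = K;
  w.n = (double)n;

  // fast path: the side terms are monotone along the ordered placements, so
  // the side-only optimum sits at their crossing
  int lo = 0, hi = 2 * K;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (w.lterm(mid) >= w.rterm(mid)) hi = mid; else lo = mid + 1;
  }
  double h0 = R_PosInf;
  int v0 = lo;
  for (int v = std::max(0, lo - 2); v <= std::min(2 * K, lo + 2); ++v) {
    double m = std::max(w.lterm(v), w.rterm(v));
    if (m < h0) { h0 = m; v0 = v; }
  }
  if (w.link_ok(v0, h0 / 2.0)) return h0 / (2.0 * n);

  // slow path: the side bound m(v) is V-shaped around the crossing, so walk
  // outward with two pointers, visiting placements in increasing m(v) and
  // adding the link term where it binds
  double best = R_PosInf;
  int vl = v0 - 1, vr = v0;
  double ml = (vl >= 0) ? std::max(w.lterm(vl), w.rterm(vl)) : R_PosInf;
  double mr = (vr <= 2 * K) ? std::max(w.lterm(vr), w.rterm(vr)) : R_PosInf;
  for (;;) {
    int v;
    double m;
    if (ml <= mr) {
      if (!R_FINITE(ml)) break;
      v = vl; m = ml;
      --vl;
      ml = (vl >= 0) ? std::max(w.lterm(vl), w.rterm(vl)) : R_PosInf;
    } else {
      if (!R_FINITE(mr)) break;
      v = vr; m = mr;
      ++vr;
      mr = (vr <= 2 * K) ? std::max(w.lterm(vr), w.rterm(vr)) : R_PosInf;
    }
    if (m >= best) break;
    double e = w.exact_variant(v, m, std::min(best, 2.0 * w.n));
    if (e < best) best = e;
    if (e == m) break;  // placements with larger side bounds cannot beat this
  }
  return best / (2.0 * n);
}

// Dip statistics for the rows of a matrix (each row sorted internally).
// [[Rcpp::export(name = ".dip_rows")]]
NumericVector dip_rows(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector out(nr);
  NumericVector buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = m(i, j);
    std::sort(buf.begin(), buf.end());
    out[i] = dip_sorted(buf);
  }
  return out;
}
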