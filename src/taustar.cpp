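#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quartet sign kernel a(z1,z2,z3,z4) = sign(|z1-z2|+|z3-z4|-|z1-z3|-|z2-z4|).
// Evaluated exactly through the equivalent characterization: +1 iff the pairs
// {z1,z3} and {z2,z4} are strictly separated on the line, -1 iff {z1,z2} and
// {z3,z4} are, else 0. (At most one of the three pair splits of four points
// can be strictly separated, and the unseparated pairings have mathematically
// equal absolute-difference sums, so naive floating-point evaluation of the
// formula suffers exact-zero cancellation; comparisons avoid that.)
static inline int quartet_sign(double z1, double z2, double z3, double z4) {
  bool bsep = (std::max(z1, z3) < std::min(z2, z4)) ||
              (std::max(z2, z4) < std::min(z1, z3));
  bool asep = (std::max(z1, z2) < std::min(z3, z4)) ||
              (std::max(z3, z4) < std::min(z1, z2));
  return (int)bsep - (int)asep;
}

// [[Rcpp::export]]
IntegerVector cpp_sign_kernel(NumericVector z1, NumericVector z2,
                              NumericVector z3, NumericVector z4) {
  R_xlen_t n = z1.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = quartet_sign(z1[i], z2[i], z3[i], z4[i]);
  return out;
}

// Brute-force U-statistic: direct average of a(x-quartet)*a(y-quartet) over all
// ordered quadruples of distinct indices, straight from the defining formula.
// O(n^4); the ground-truth oracle for the other tiers.
// [[Rcpp::export]]
double cpp_tau_brute(NumericVector x, NumericVector y) {
  int n = x.size();
  long double total = 0.0L;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      for (int k = 0; k < n; ++k) {
        if (k == i || k == j) continue;
        for (int l = 0; l < n; ++l) {
          if (l == i || l == j || l == k) continue;
          int ax = quartet_sign(x[i], x[j], x[k], x[l]);
          if (ax == 0) continue;
          int ay = quartet_sign(y[i], y[j], y[k], y[l]);
          total += (long double)(ax * ay);
        }
      }
    }
  long double nn = (long double)n;
  long double n4 = nn * (nn - 1) * (nn - 2) * (nn - 3);
  return (double)(total / n4);
}

static inline double choose2(double m) { return m > 1.5 ? m * (m - 1.0) / 2.0 : 0.0; }

// ---------------------------------------------------------------------------
// Fast path. Cells sorted by strictly increasing pseudotime; y given as level
// codes 1..M (levels sorted ascending). For positions i<j<k<l the x-separated
// split is always {i,j}|{k,l}, so
//   tau* = (16*Nc - 8*Nd) / (n(n-1)(n-2)(n-3)),
// Nc = # quadruples whose left pair is strictly below or above the right pair
// in y, Nd = (# quadruples y-separated under some split) - Nc.
// Nc is counted with ~4M O(n) threshold sweeps (the O(Mn) core step); the
// y-separated total depends only on level multiplicities, costing O(M).
// ---------------------------------------------------------------------------

// #{i<j<k<l : left pair codes <= a, right pair codes > b}, a <= b.
static double sweep_low_high(const int* yc, int n, int a, int b) {
  double cntLow = 0.0, S = 0.0, total = 0.0;
  for (int p = 0; p < n; ++p) {
    int c = yc[p];
    if (c > b) { total += S; S += choose2(cntLow); }
    else if (c <= a) cntLow += 1.0;
  }
  return total;
}

// #{i<j<k<l : left pair codes >= a, right pair codes < b}, b <= a.
static double sweep_high_low(const int* yc, int n, int a, int b) {
  double cntHigh = 0.0, S = 0.0, total = 0.0;
  for (int p = 0; p < n; ++p) {
    int c = yc[p];
    if (c < b) { total += S; S += choose2(cntHigh); }
    else if (c >= a) cntHigh += 1.0;
  }
  return total;
}

// [[Rcpp::export]]
double cpp_tau_fast_sorted(IntegerVector ycode, int M) {
  int n = ycode.size();
  const int* yc = INTEGER(ycode);
  double n4 = (double)n * (n - 1.0) * (n - 2.0) * (n - 3.0);
  if (M <= 1) return 0.0;

  // concordant count
  double Nc = 0.0;
  for (int l = 1; l <= M - 1; ++l)   // max(left) at level l, right pair above
    Nc += sweep_low_high(yc, n, l, l) - sweep_low_high(yc, n, l - 1, l);
  for (int l = 2; l <= M; ++l)       // min(left) at level l, right pair below
    Nc += sweep_high_low(yc, n, l, l) - sweep_high_low(yc, n, l + 1, l);

  // total y-separated quadruples: 4-subsets with strictly distinct middle
  // order statistics; position-free, from level multiplicities.
  std::vector<double> m(M + 1, 0.0);
  for (int p = 0; p < n; ++p) m[yc[p]] += 1.0;
  double below = 0.0, nosep = 0.0, nd = (double)n;
  for (int l = 1; l <= M; ++l) {
    double ml = m[l], above = nd - below - ml;
    nosep += ml * (ml - 1) * (ml - 2) * (ml - 3) / 24.0       // all four tied
           + ml * (ml - 1) * (ml - 2) / 6.0 * (below + above) // middle three tied
           + choose2(ml) * below * above;                     // middle two tied
    below += ml;
  }
  double Nsep = nd * (nd - 1) * (nd - 2) * (nd - 3) / 24.0 - nosep;
  double Nd = Nsep - Nc;
  return (16.0 * Nc - 8.0 * Nd) / n4;
}

// ---------------------------------------------------------------------------
// Pairwise reference tier, exact with ties in either margin, O(n^2 log n).
// A quadruple is concordant iff the same split of its four points is strictly
// separated in both margins, discordant iff two different splits are separated
// (one in x, one in y); tau* = (16*Nc - 8*Nd)/n^(4). Each such quadruple is
// counted twice, once per pair of its x-separated split: for a pair (a,b) with
// x-range (mx,Mx) and y-range (alpha,beta), the partner pair {c,d} must lie
// strictly on one x-side (sets H = {x > Mx}, L = {x < mx});
//   concordant: both partners beyond beta or below alpha in y;
//   discordant: alpha < beta and, with (u,v) = sorted partner y-values,
//               u < beta and v > alpha  (equivalently max(alpha,u) < min(beta,v)).
// Counting uses a Fenwick tree over y-ranks.
// ---------------------------------------------------------------------------

// Dynamic multiset of y-ranks supporting (i) prefix point counts and
// (ii) prefix sums of within-level pair counts sum_{w<=r} C(m_w, 2), the
// latter needed to discard candidate partner pairs with tied y-values
// (a pair with u = v can never complete a mixed separated split).
struct SideSet {
  std::vector<int> t;                  // Fenwick: point counts
  std::vector<long long> tp;           // Fenwick: within-level pair counts
  std::vector<int> m;                  // per-rank multiplicities
  int n, total;
  void init(int n_) {
    n = n_; total = 0;
    t.assign(n + 1, 0); tp.assign(n + 1, 0); m.assign(n + 1, 0);
  }
  void add(int r) {
    long long d = m[r]++;              // C(m+1,2)-C(m,2) = m
    for (int i = r; i <= n; i += i & -i) { ++t[i]; tp[i] += d; }
    ++total;
  }
  void remove(int r) {
    long long d = --m[r];
    for (int i = r; i <= n; i += i & -i) { --t[i]; tp[i] -= d; }
    --total;
  }
  int prefix(int i) const {            // #points with rank <= i
    if (i <= 0) return 0;
    if (i > n) i = n;
    int s = 0;
    for (; i > 0; i -= i & -i) s += t[i];
    return s;
  }
  long long prefix_pairs(int i) const { // sum_{w<=i} C(m_w,2)
    if (i <= 0) return 0;
    if (i > n) i = n;
    long long s = 0;
    for (; i > 0; i -= i & -i) s += tp[i];
    return s;
  }
};

// accumulate concordant/discordant pair counts for pair with y-ranks ra, rb
// against the point set held on one x-side
static inline void pair_side_counts(const SideSet& fw, int ra, int rb,
                                    double& Csum, double& Dsum) {
  int lo = std::min(ra, rb), hi = std::max(ra, rb);
  int h = fw.total;
  int nHigh = h - fw.prefix(hi);       // y strictly above beta
  int nLow  = fw.prefix(lo - 1);       // y strictly below alpha
  Csum += choose2((double)nHigh) + choose2((double)nLow);
  if (lo != hi) {
    int nGeqB = h - fw.prefix(hi - 1); // y >= beta
    int nLeqA = fw.prefix(lo);         // y <= alpha
    // tied partner pairs with level strictly inside (alpha, beta)
    long long tied = fw.prefix_pairs(hi - 1) - fw.prefix_pairs(lo);
    Dsum += choose2((double)h) - choose2((double)nGeqB)
          - choose2((double)nLeqA) - (double)tied;
  }
}

// [[Rcpp::export]]
double cpp_tau_pairwise(NumericVector x, NumericVector y) {
  int n = x.size();
  double n4 = (double)n * (n - 1.0) * (n - 2.0) * (n - 3.0);

  // y ranks 1..K (ties share a rank)
  std::vector<int> ord(n), yr(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return y[a] < y[b]; });
  int K = 0;
  for (int s = 0; s < n; ++s) {
    if (s == 0 || y[ord[s]] > y[ord[s - 1]]) ++K;
    yr[ord[s]] = K;
  }

  // x order, grouped by tied x values
  std::vector<int> xo(n);
  for (int i = 0; i < n; ++i) xo[i] = i;
  std::sort(xo.begin(), xo.end(), [&](int a, int b) { return x[a] < x[b]; });
  std::vector<int> gstart;             // start index (in xo) of each x-group
  for (int s = 0; s < n; ++s)
    if (s == 0 || x[xo[s]] > x[xo[s - 1]]) gstart.push_back(s);
  gstart.push_back(n);
  int G = (int)gstart.size() - 1;

  double Csum = 0.0, Dsum = 0.0;
  SideSet fwL, fwH;

  // Pass 1: pairs with distinct x. Anchor a = smaller-x point; L = {x < x_a}
  // held in fwL (grown group by group); partners scanned in decreasing x while
  // fwH accumulates {x > x_b}.
  fwL.init(K);
  for (int g = 0; g < G; ++g) {
    for (int s = gstart[g]; s < gstart[g + 1]; ++s) {
      int a = xo[s], ra = yr[a];
      if (g + 1 >= G) continue;
      fwH.init(K);
      int ins = n - 1;                 // insertion cursor from the largest x down
      for (int gb = G - 1; gb > g; --gb) {
        // ensure fwH holds exactly {x > x of group gb}
        while (ins >= gstart[gb + 1]) { fwH.add(yr[xo[ins]]); --ins; }
        for (int t = gstart[gb]; t < gstart[gb + 1]; ++t) {
          int b = xo[t];
          int lo = std::min(ra, yr[b]), hi = std::max(ra, yr[b]);
          pair_side_counts(fwH, lo, hi, Csum, Dsum);
          pair_side_counts(fwL, lo, hi, Csum, Dsum);
        }
      }
    }
    for (int s = gstart[g]; s < gstart[g + 1]; ++s) fwL.add(yr[xo[s]]);
  }

  // Pass 2: pairs with tied x. L = {x < x_group}, H = {x > x_group}.
  fwL.init(K);
  fwH.init(K);
  for (int i = 0; i < n; ++i) fwH.add(yr[i]);
  for (int g = 0; g < G; ++g) {
    int s0 = gstart[g], s1 = gstart[g + 1];
    for (int s = s0; s < s1; ++s) fwH.remove(yr[xo[s]]);
    if (s1 - s0 >= 2) {
      for (int s = s0; s < s1; ++s)
        for (int t = s + 1; t < s1; ++t) {
          int a = xo[s], b = xo[t];
          int lo = std::min(yr[a], yr[b]), hi = std::max(yr[a], yr[b]);
          pair_side_counts(fwH, lo, hi, Csum, Dsum);
          pair_side_counts(fwL, lo, hi, Csum, Dsum);
        }
    }
    for (int s = s0; s < s1; ++s) fwL.add(yr[xo[s]]);
  }

  double Nc = Csum / 2.0, Nd = Dsum / 2.0;
  return (16.0 * Nc - 8.0 * Nd) / n4;
}

// Permutation null draws: x held fixed (strictly increasing, already sorted),
// y level codes reshuffled B times with R's RNG; each draw re-counted with the
// fast path. Returns B values of tau*.
// [[Rcpp::export]]
NumericVector cpp_perm_null_fast(IntegerVector ycode, int M, int B) {
  int n = ycode.size();
  std::vector<int> yc(ycode.begin(), ycode.end());
  IntegerVector buf(n);
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    // Fisher-Yates with R's RNG for reproducibility under set.seed()
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(yc[i], yc[j]);
    }
    std::copy(yc.begin(), yc.end(), buf.begin());
    out[b] = cpp_tau_fast_sorted(buf, M);
  }
  return out;
}
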