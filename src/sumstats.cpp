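// Haplotype-structure kernels: per-window haplotype spectra and
// EHH-integral scores (iHS in bp distance, nSL in site-count distance).
// Haplotype sets are tracked as 128-bit masks (samples up to 128
// chromosomes), so partition refinement is a handful of AND/popcount
// operations per SNP.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

struct Mask {
  uint64_t a, b;
  Mask() : a(0), b(0) {}
  inline void set(int i) { if (i < 64) a |= (uint64_t) 1 << i; else b |= (uint64_t) 1 << (i - 64); }
  inline Mask and_(const Mask& o) const { Mask r; r.a = a & o.a; r.b = b & o.b; return r; }
  inline Mask andnot(const Mask& o) const { Mask r; r.a = a & ~o.a; r.b = b & ~o.b; return r; }
  inline int count() const {
    return __builtin_popcountll(a) + __builtin_popcountll(b);
  }
  inline bool empty() const { return a == 0 && b == 0; }
};

// Haplotype frequency spectrum within one column range [from, to) of a
// 0/1 matrix: returns n_H, H1, H12, H2. Rows are identified by a pair of
// 64-bit FNV-style hashes over the window's alleles.
static void spectrum_stats(std::vector<std::pair<uint64_t, uint64_t>>& h,
                           double* out) {
  int n = (int) h.size();
  std::sort(h.begin(), h.end());
  std::vector<double> p;
  int run = 1;
  for (int i = 1; i <= n; ++i) {
    if (i < n && h[i] == h[i - 1]) { ++run; continue; }
    p.push_back((double) run / n);
    run = 1;
  }
  std::sort(p.begin(), p.end(), std::greater<double>());
  double H1 = 0.0;
  for (double x : p) H1 += x * x;
  double H12 = H1;
  if (p.size() >= 2) H12 += 2.0 * p[0] * p[1];
  out[0] = (double) p.size();
  out[1] = H1;
  out[2] = H12;
  out[3] = H1 - p[0] * p[0];
}

static inline void hash_step(uint64_t& h1, uint64_t& h2, int allele) {
  h1 = (h1 ^ (uint64_t) (allele + 1)) * 1099511628211ULL;
  h2 = (h2 + (uint64_t) (allele + 131)) * 6364136223846793005ULL + 1442695040888963407ULL;
}

// [[Rcpp::export(name = ".hap_spectrum")]]
NumericVector hap_spectrum(IntegerMatrix M, int from, int to) {
  int n = M.nrow();
  std::vector<std::pair<uint64_t, uint64_t>> h(n);
  for (int i = 0; i < n; ++i) {
    uint64_t h1 = 1469598103934665603ULL, h2 = 88172645463325252ULL;
    for (int j = from; j < to; ++j) hash_step(h1, h2, M(i, j));
    h[i] = {h1, h2};
  }
  double out[4];
  spectrum_stats(h, out);
  return NumericVector::create(_["n_H"] = out[0], _["H1"] = out[1],
                               _["H12"] = out[2], _["H2"] = out[3]);
}

// Spectra for many (possibly overlapping) column windows in one pass.
// starts/ends are 0-based half-open column ranges. Returns nw x 4.
// [[Rcpp::export(name = ".hap_spectrum_windows")]]
NumericMatrix hap_spectrum_windows(IntegerMatrix M, IntegerVector starts,
                                   IntegerVector ends) {
  int n = M.nrow(), nw = starts.size();
  NumericMatrix out(nw, 4);
  std::vector<std::pair<uint64_t, uint64_t>> h(n);
  for (int w = 0; w < nw; ++w) {
    for (int i = 0; i < n; ++i) {
      uint64_t h1 = 1469598103934665603ULL, h2 = 88172645463325252ULL;
      for (int j = starts[w]; j < ends[w]; ++j) hash_step(h1, h2, M(i, j));
      h[i] = {h1, h2};
    }
    double v[4];
    spectrum_stats(h, v);
    for (int k = 0; k < 4; ++k) out(w, k) = v[k];
  }
  colnames(out) = CharacterVector::create("n_H", "H1", "H12", "H2");
  return out;
}

// EHH area on one side of the pivot for the haplotype set `subset`.
// Walks outward refining the mask partition at each SNP; integrates EHH
// by the trapezoid rule until EHH < cutoff (the crossing trapezoid is
// included) or the edge of the data.
static double ehh_area(const std::vector<Mask>& colmask, const Mask& subset,
                       const std::vector<double>& dist, int pivot, int dir,
                       double cutoff, int S) {
  int n = subset.count();
  if (n < 2) return NA_REAL;
  double denom = (double) n * (n - 1) / 2.0;
  std::vector<Mask> groups;
  groups.push_back(subset);
  std::vector<Mask> next;
  double ehh_prev = 1.0, x_prev = dist[pivot], area = 0.0;
  for (int j = pivot + dir; j >= 0 && j < S; j += dir) {
    next.clear();
    double hom = 0.0;
    for (const Mask& g : groups) {
      Mask g1 = g.and_(colmask[j]);
      Mask g0 = g.andnot(colmask[j]);
      int c1 = g1.count(), c0 = g0.count();
      if (c1 > 1) { next.push_back(g1); hom += (double) c1 * (c1 - 1) / 2.0; }
      if (c0 > 1) { next.push_back(g0); hom += (double) c0 * (c0 - 1) / 2.0; }
    }
    groups.swap(next);
    double ehh = hom / denom;
    area += 0.5 * (ehh_prev + ehh) * std::abs(dist[j] - x_prev);
    ehh_prev = ehh;
    x_prev = dist[j];
    if (ehh < cutoff) break;
  }
  return area;
}

// Unstandardised EHH-integral scores log(iHH_ancestral / iHH_derived) for
// every pivot SNP whose derived frequency lies within [min_f, max_f].
// `use_bp` selects bp distances (iHS) or site-rank distances (nSL).
// [[Rcpp::export(name = ".ehh_scores")]]
NumericMatrix ehh_scores(IntegerMatrix M, NumericVector positions,
                         bool use_bp, double min_f, double max_f,
                         double cutoff) {
  int n = M.nrow(), S = M.ncol();
  if (n > 128) stop("EHH kernels support at most 128 haplotypes");
  std::vector<double> dist(S);
  for (int j = 0; j < S; ++j) dist[j] = use_bp ? positions[j] : (double) j;
  std::vector<Mask> colmask(S);
  std::vector<int> dcount(S, 0);
  for (int j = 0; j < S; ++j) {
    for (int i = 0; i < n; ++i) {
      if (M(i, j) == 1) { colmask[j].set(i); ++dcount[j]; }
    }
  }
  Mask all;
  for (int i = 0; i < n; ++i) all.set(i);
  std::vector<int> pivots;
  for (int j = 0; j < S; ++j) {
    double f = (double) dcount[j] / n;
    if (f >= min_f && f <= max_f) pivots.push_back(j);
  }
  NumericMatrix out((int) pivots.size(), 3);
  for (size_t k = 0; k < pivots.size(); ++k) {
    int j = pivots[k];
    Mask der = colmask[j];
    Mask anc = all.andnot(colmask[j]);
    double dr = ehh_area(colmask, der, dist, j, +1, cutoff, S);
    double dl = ehh_area(colmask, der, dist, j, -1, cutoff, S);
    double ar = ehh_area(colmask, anc, dist, j, +1, cutoff, S);
    double al = ehh_area(colmask, anc, dist, j, -1, cutoff, S);
    double score = NA_REAL;
    if (!ISNA(dr) && !ISNA(dl) && !ISNA(ar) && !ISNA(al)) {
      double D = dr + dl, A = ar + al;
      if (D > 0 && A > 0) score = std::log(A / D);
    }
    out(k, 0) = j + 1;
    out(k, 1) = dcount[j];
    out(k, 2) = score;
  }
  colnames(out) = CharacterVector::create("col", "derived_count", "score");
  return out;
}
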