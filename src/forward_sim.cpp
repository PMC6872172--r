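// Forward infinite-sites Wright-Fisher engine for a recombining region in a
// panmictic or two-deme diploid population.
//
// A chromosome is a vector of site indices (0-based into `positions`),
// sorted by position. Each generation: chromosomes are paired at random
// into transient diploids within each deme; offspring chromosomes pick a
// parent individual proportional to co-dominant diploid fitness at the
// selected site (1 : 1+s : (1+s)^2); transmission recombines the parent's
// pair with probability cc at one uniform breakpoint; Poisson(mu) new
// mutations land at uniform positions; whole individuals migrate between
// demes with a balanced swap. Fixed and lost sites are pruned every
// generation (the selected site is exempt).
//
// Uses R's RNG throughout so set.seed() in R makes runs reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

typedef std::vector<int> Chrom;

struct Pop {
  std::vector<Chrom> chroms;      // all chromosomes, deme-contiguous
  std::vector<int> deme_start;    // start index per deme (+ end sentinel)
  std::vector<double> positions;  // site id -> bp
  int sel_site;                   // site id of selected site, -1 if none
};

static inline int deme_size(const Pop& p, int d) {
  return p.deme_start[d + 1] - p.deme_start[d];
}

static inline bool carries(const Chrom& c, const std::vector<double>& pos,
                           int site) {
  double x = pos[site];
  // chromosomes are position-sorted; find by position then match id
  size_t lo = 0, hi = c.size();
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (pos[c[mid]] < x) lo = mid + 1; else hi = mid;
  }
  for (size_t i = lo; i < c.size() && pos[c[i]] <= x; ++i)
    if (c[i] == site) return true;
  return false;
}

static int count_selected(const Pop& p, int d) {
  if (p.sel_site < 0) return 0;
  int n = 0;
  for (int i = p.deme_start[d]; i < p.deme_start[d + 1]; ++i)
    if (carries(p.chroms[i], p.positions, p.sel_site)) ++n;
  return n;
}

// merge left part (< bp) of a and right part (>= bp) of b
static Chrom recombine(const Chrom& a, const Chrom& b,
                       const std::vector<double>& pos, double bp) {
  Chrom out;
  out.reserve(a.size() + b.size());
  for (int s : a) { if (pos[s] < bp) out.push_back(s); else break; }
  for (int s : b) if (pos[s] >= bp) out.push_back(s);
  return out;
}

static void add_mutations(Chrom& c, Pop& p,
                          std::unordered_set<double>& taken,
                          double mu, double L) {
  int nmut = (int) R::rpois(mu);
  for (int k = 0; k < nmut; ++k) {
    double u;
    do { u = R::runif(0.0, L); } while (taken.count(u));
    taken.insert(u);
    p.positions.push_back(u);
    int id = (int) p.positions.size() - 1;
    Chrom::iterator it = std::lower_bound(
        c.begin(), c.end(), id,
        [&](int s, int v) { return p.positions[s] < p.positions[v]; });
    c.insert(it, id);
  }
}

// drop fixed/lost sites (selected exempt), remap ids, keep position order
static void prune(Pop& p, std::unordered_set<double>& taken) {
  int S = (int) p.positions.size();
  int n_tot = (int) p.chroms.size();
  std::vector<int> cnt(S, 0);
  for (const Chrom& c : p.chroms)
    for (int s : c) ++cnt[s];
  std::vector<int> remap(S, -1);
  std::vector<double> newpos;
  newpos.reserve(S);
  for (int s = 0; s < S; ++s) {
    bool keep = (cnt[s] > 0 && cnt[s] < n_tot) || s == p.sel_site;
    if (keep) {
      remap[s] = (int) newpos.size();
      newpos.push_back(p.positions[s]);
    } else if (cnt[s] > 0 || taken.count(p.positions[s])) {
      taken.erase(p.positions[s]);
    }
  }
  if ((int) newpos.size() == S) return;
  for (Chrom& c : p.chroms) {
    Chrom nc;
    nc.reserve(c.size());
    for (int s : c) if (remap[s] >= 0) nc.push_back(remap[s]);
    c.swap(nc);
  }
  if (p.sel_site >= 0) p.sel_site = remap[p.sel_site];
  p.positions.swap(newpos);
}

// Fisher-Yates over a span of an index vector using R's RNG
static void shuffle_span(std::vector<int>& v, int from, int to) {
  for (int i = to - from - 1; i > 0; --i) {
    int j = (int) (R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[from + i], v[from + j]);
  }
}

static void step_generation_cpp(Pop& p, std::unordered_set<double>& taken,
                                const std::vector<double>& s, double m,
                                double mu, double cc, double L) {
  int D = (int) p.deme_start.size() - 1;
  std::vector<Chrom> next(p.chroms.size());
  int out_idx = 0;
  for (int d = 0; d < D; ++d) {
    int N = deme_size(p, d);
    int K = N / 2;
    // random pairing into diploids
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = p.deme_start[d] + i;
    shuffle_span(idx, 0, N);
    // cumulative fitness over diploids
    std::vector<double> cum(K);
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      int g = 0;
      if (p.sel_site >= 0) {
        g = (carries(p.chroms[idx[2 * k]], p.positions, p.sel_site) ? 1 : 0) +
            (carries(p.chroms[idx[2 * k + 1]], p.positions, p.sel_site) ? 1 : 0);
      }
      double w = (g == 0) ? 1.0 : ((g == 1) ? 1.0 + s[d] :
                                   (1.0 + s[d]) * (1.0 + s[d]));
      tot += w;
      cum[k] = tot;
    }
    for (int i = 0; i < N; ++i) {
      double u = R::unif_rand() * tot;
      int k = (int) (std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (k >= K) k = K - 1;
      const Chrom& a = p.chroms[idx[2 * k]];
      const Chrom& b = p.chroms[idx[2 * k + 1]];
      Chrom child;
      if (R::unif_rand() < cc) {
        double bp = R::runif(0.0, L);
        if (R::unif_rand() < 0.5) child = recombine(a, b, p.positions, bp);
        else child = recombine(b, a, p.positions, bp);
      } else {
        child = (R::unif_rand() < 0.5) ? a : b;
      }
      add_mutations(child, p, taken, mu, L);
      next[out_idx++] = std::move(child);
    }
  }
  p.chroms.swap(next);
  // balanced migration: k ~ Binomial(K, m) whole individuals swapped both
  // ways; with random re-pairing each generation, swapping 2k random
  // chromosomes per direction is equivalent in distribution
  if (D == 2 && m > 0) {
    int K = deme_size(p, 0) / 2;
    int k = (int) R::rbinom(K, m);
    if (k > 0) {
      int n0 = deme_size(p, 0), n1 = deme_size(p, 1);
      std::vector<int> i0(n0), i1(n1);
      for (int i = 0; i < n0; ++i) i0[i] = p.deme_start[0] + i;
      for (int i = 0; i < n1; ++i) i1[i] = p.deme_start[1] + i;
      shuffle_span(i0, 0, n0);
      shuffle_span(i1, 0, n1);
      for (int j = 0; j < 2 * k; ++j)
        std::swap(p.chroms[i0[j]], p.chroms[i1[j]]);
    }
  }
  // pruning of fixed/lost sites is done lazily by the caller: lost sites
  // have no carriers and fixed ones are monomorphic, so postponing the
  // id remap changes nothing statistically and saves a full rebuild per
  // generation
}

static Pop pop_from_r(List chroms, NumericVector positions,
                      IntegerVector deme_sizes, int sel_site) {
  Pop p;
  p.positions = std::vector<double>(positions.begin(), positions.end());
  p.chroms.resize(chroms.size());
  for (int i = 0; i < chroms.size(); ++i) {
    IntegerVector v = chroms[i];
    Chrom c(v.begin(), v.end());
    std::sort(c.begin(), c.end(), [&](int a, int b) {
      return p.positions[a] < p.positions[b];
    });
    p.chroms[i] = c;
  }
  p.deme_start.push_back(0);
  for (int d = 0; d < deme_sizes.size(); ++d)
    p.deme_start.push_back(p.deme_start.back() + deme_sizes[d]);
  if ((int) p.chroms.size() != p.deme_start.back())
    stop("deme sizes do not sum to the number of chromosomes");
  p.sel_site = sel_site;
  return p;
}

static List pop_to_r(const Pop& p, int generation, std::string stage,
                     int trigger_deme) {
  int D = (int) p.deme_start.size() - 1;
  List chroms(p.chroms.size());
  for (size_t i = 0; i < p.chroms.size(); ++i)
    chroms[i] = IntegerVector(p.chroms[i].begin(), p.chroms[i].end());
  IntegerVector deme_of(p.chroms.size());
  NumericVector freq(D);
  for (int d = 0; d < D; ++d) {
    for (int i = p.deme_start[d]; i < p.deme_start[d + 1]; ++i)
      deme_of[i] = d + 1;
    freq[d] = p.sel_site >= 0 ?
      (double) count_selected(p, d) / deme_size(p, d) : 0.0;
  }
  return List::create(
    _["generation"] = generation, _["stage"] = stage,
    _["trigger_deme"] = trigger_deme, _["sel_freq"] = freq,
    _["chroms"] = chroms,
    _["positions"] = NumericVector(p.positions.begin(), p.positions.end()),
    _["deme"] = deme_of, _["sel_site"] = p.sel_site + 1);
}

// [[Rcpp::export(name = ".fw_simulate")]]
List fw_simulate(List chroms, NumericVector positions, IntegerVector deme_sizes,
                 NumericVector s, double m, double mu, double cc, double L,
                 int sel_site, double sel_pos, std::string schedule_mode,
                 NumericVector freq_triggers, NumericVector post_offsets,
                 int snapshot_interval, int n_interval_snapshots, int max_gen) {
  Pop p = pop_from_r(chroms, positions, deme_sizes, sel_site - 1);
  std::unordered_set<double> taken(p.positions.begin(), p.positions.end());
  int D = (int) p.deme_start.size() - 1;

  // hard sweep: brand-new mutation at sel_pos on one random chromosome of d1
  if (p.sel_site < 0 && schedule_mode != "none") {
    double pos = sel_pos;
    while (taken.count(pos)) pos += 1e-9;
    taken.insert(pos);
    p.positions.push_back(pos);
    p.sel_site = (int) p.positions.size() - 1;
    int i0 = p.deme_start[0] +
      (int) (R::unif_rand() * deme_size(p, 0));
    Chrom& c = p.chroms[i0];
    Chrom::iterator it = std::lower_bound(
        c.begin(), c.end(), p.sel_site,
        [&](int a, int b) { return p.positions[a] < p.positions[b]; });
    c.insert(it, p.sel_site);
  }

  Pop init = p;  // reset target on loss

  int nF = freq_triggers.size(), nP = post_offsets.size();
  std::vector<std::vector<bool>> freq_fired(D, std::vector<bool>(nF, false));
  std::vector<int> t995(D, -1);
  std::vector<std::vector<bool>> post_fired(D, std::vector<bool>(nP, false));
  bool fix_fired = false;
  int n_resets = 0;
  int gen = 0;
  int intervals_done = 0;
  std::vector<List> snaps;

  const int prune_every = 25;

  if (schedule_mode == "none") {
    for (gen = 0; gen < max_gen; ++gen) {
      step_generation_cpp(p, taken, as<std::vector<double>>(s), m, mu, cc, L);
      if ((gen + 1) % prune_every == 0) prune(p, taken);
    }
    prune(p, taken);
    snaps.push_back(pop_to_r(p, gen, "final", 0));
    List out = List::create(_["snapshots"] = wrap(snaps),
                            _["n_resets"] = 0, _["truncated"] = false,
                            _["generations"] = gen);
    return out;
  }

  bool truncated = false;
  while (true) {
    if (gen >= max_gen) {
      truncated = schedule_mode != "interval" ||
        intervals_done < n_interval_snapshots;
      break;
    }
    step_generation_cpp(p, taken, as<std::vector<double>>(s), m, mu, cc, L);
    ++gen;
    if (gen % prune_every == 0) prune(p, taken);
    // global loss: reset to initial state
    int tot_sel = 0;
    std::vector<int> cnt(D);
    for (int d = 0; d < D; ++d) { cnt[d] = count_selected(p, d); tot_sel += cnt[d]; }
    if (tot_sel == 0) {
      p = init;
      taken = std::unordered_set<double>(p.positions.begin(), p.positions.end());
      for (int d = 0; d < D; ++d) {
        std::fill(freq_fired[d].begin(), freq_fired[d].end(), false);
        std::fill(post_fired[d].begin(), post_fired[d].end(), false);
        t995[d] = -1;
      }
      fix_fired = false;
      ++n_resets;
      gen = 0;
      intervals_done = 0;
      snaps.clear();
      continue;
    }
    if (schedule_mode == "interval") {
      if (intervals_done < n_interval_snapshots &&
          gen == (intervals_done + 1) * snapshot_interval) {
        ++intervals_done;
        prune(p, taken);
        snaps.push_back(pop_to_r(p, gen,
                                 "t" + std::to_string(gen), 0));
      }
      if (intervals_done >= n_interval_snapshots) break;
      continue;
    }
    // frequency-trigger schedule
    int N_tot = p.deme_start[D];
    for (int d = 0; d < D; ++d) {
      double f = (double) cnt[d] / deme_size(p, d);
      for (int k = 0; k < nF; ++k) {
        if (!freq_fired[d][k] && f >= freq_triggers[k]) {
          freq_fired[d][k] = true;
          if (freq_triggers[k] >= 0.995 && t995[d] < 0) t995[d] = gen;
          char buf[32];
          double pct = freq_triggers[k] * 100;
          if (pct == (int) pct) snprintf(buf, 32, "f%ds", (int) pct);
          else snprintf(buf, 32, "f%.1fs", pct);
          prune(p, taken);
          snaps.push_back(pop_to_r(p, gen, buf, d + 1));
        }
      }
      if (t995[d] >= 0) {
        for (int k = 0; k < nP; ++k) {
          if (!post_fired[d][k] && gen == t995[d] + (int) post_offsets[k]) {
            post_fired[d][k] = true;
            prune(p, taken);
            snaps.push_back(pop_to_r(p, gen,
                                     "t" + std::to_string(k + 1) + "Kr", d + 1));
          }
        }
      }
    }
    if (!fix_fired && tot_sel == N_tot) {
      fix_fired = true;
      prune(p, taken);
      snaps.push_back(pop_to_r(p, gen, "f100s", 0));
    }
    bool all_done = fix_fired;
    for (int d = 0; d < D && all_done; ++d) {
      for (int k = 0; k < nF; ++k) if (!freq_fired[d][k]) all_done = false;
      for (int k = 0; k < nP; ++k) if (!post_fired[d][k]) all_done = false;
    }
    if (all_done) break;
  }
  return List::create(_["snapshots"] = wrap(snaps), _["n_resets"] = n_resets,
                      _["truncated"] = truncated, _["generations"] = gen);
}

// One bare generation step exposed for unit tests on the engine's moments.
// [[Rcpp::export(name = ".fw_step_once")]]
List fw_step_once(List chroms, NumericVector positions,
                  IntegerVector deme_sizes, NumericVector s, double m,
                  double mu, double cc, double L, int sel_site) {
  Pop p = pop_from_r(chroms, positions, deme_sizes, sel_site - 1);
  std::unordered_set<double> taken(p.positions.begin(), p.positions.end());
  step_generation_cpp(p, taken, as<std::vector<double>>(s), m, mu, cc, L);
  return pop_to_r(p, 1, "step", 0);
}

// Binary sample matrix for chosen chromosomes: columns are sites
// polymorphic within the sample (the selected site always kept when
// present in the population), in position order.
// [[Rcpp::export(name = ".fw_sample_matrix")]]
List fw_sample_matrix(List chroms, NumericVector positions,
                      IntegerVector take, int sel_site) {
  int n = take.size();
  int S = positions.size();
  std::vector<int> cnt(S, 0);
  std::vector<std::vector<int>> rows(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = chroms[take[i] - 1];
    rows[i] = std::vector<int>(v.begin(), v.end());
    for (int s : rows[i]) ++cnt[s];
  }
  int sel0 = sel_site - 1;
  std::vector<int> keep;
  for (int s = 0; s < S; ++s)
    if ((cnt[s] > 0 && cnt[s] < n) || s == sel0) keep.push_back(s);
  std::sort(keep.begin(), keep.end(), [&](int a, int b) {
    return positions[a] < positions[b];
  });
  std::vector<int> col_of(S, -1);
  for (size_t j = 0; j < keep.size(); ++j) col_of[keep[j]] = (int) j;
  IntegerMatrix M(n, (int) keep.size());
  for (int i = 0; i < n; ++i)
    for (int s : rows[i])
      if (col_of[s] >= 0) M(i, col_of[s]) = 1;
  NumericVector kp((int) keep.size());
  for (size_t j = 0; j < keep.size(); ++j) kp[j] = positions[keep[j]];
  int sel_col = (sel0 >= 0 && col_of[sel0] >= 0) ? col_of[sel0] + 1 : NA_INTEGER;
  return List::create(_["matrix"] = M, _["positions"] = kp,
                      _["sel_col"] = sel_col);
}
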