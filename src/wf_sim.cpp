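// Forward-time Wright-Fisher simulator of a neutral chromosomal inversion.
//
// Chromosomes are sparse: a sorted vector of derived-mutation positions on
// the continuous interval [0, L) (infinite-sites: positions are doubles, so
// two mutations never collide), plus one arrangement flag (0 = standard,
// 1 = inverted). Recombination in arrangement-heterozygous parents is
// suppressed inside the inversion interval: crossover breakpoints falling
// there are resampled outside it, so the whole inverted segment is always
// inherited from a single parental chromosome and mutations inside the
// interval can never cross between arrangement classes.
//
// All randomness comes from R's RNG (unif_rand / R::rpois), so results are
// fully controlled by set.seed() on the R side.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

typedef std::vector<double> Chrom;

struct Population {
  std::vector<Chrom> hap;           // 2 * Ne chromosomes
  std::vector<unsigned char> inv;   // arrangement flag per chromosome
};

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static void make_gamete(const Population& p, int parent, double L,
                        double muL, double rL,
                        double inv_s, double inv_e,
                        Chrom& out, unsigned char& flag) {
  const Chrom& A = p.hap[2 * parent];
  const Chrom& B = p.hap[2 * parent + 1];
  unsigned char fa = p.inv[2 * parent], fb = p.inv[2 * parent + 1];
  int start = (unif_rand() < 0.5) ? 1 : 0;
  int k = (rL > 0.0) ? (int) R::rpois(rL) : 0;
  out.clear();
  if (k == 0) {
    out = start ? B : A;
    flag = start ? fb : fa;
  } else {
    std::vector<double> cuts((size_t)k);
    bool het = (fa != fb);
    for (int i = 0; i < k; ++i) {
      double c = unif_rand() * L;
      if (het) while (c > inv_s && c < inv_e) c = unif_rand() * L;
      cuts[(size_t)i] = c;
    }
    std::sort(cuts.begin(), cuts.end());
    int cur = start;
    double lo = 0.0;
    for (int s = 0; s <= k; ++s) {
      double hi = (s < k) ? cuts[(size_t)s] : L + 1.0;
      const Chrom& src = cur ? B : A;
      Chrom::const_iterator it0 = std::lower_bound(src.begin(), src.end(), lo);
      Chrom::const_iterator it1 = std::lower_bound(src.begin(), src.end(), hi);
      out.insert(out.end(), it0, it1);
      cur ^= 1;
      lo = hi;
    }
    // the chromosome contributing the inversion interval sets the flag
    // (for heterokaryotypes no cut lies inside the interval, so the whole
    // interval descends from one source; homokaryotypes have equal flags)
    int ncuts_before = 0;
    for (int i = 0; i < k; ++i) if (cuts[(size_t)i] <= inv_s) ++ncuts_before;
    int src_inv = (start + ncuts_before) % 2;
    flag = src_inv ? fb : fa;
  }
  if (muL > 0.0) {
    int m = (int) R::rpois(muL);
    for (int i = 0; i < m; ++i) {
      double pos = unif_rand() * L;
      Chrom::iterator it = std::lower_bound(out.begin(), out.end(), pos);
      if (it == out.end() || *it != pos) out.insert(it, pos);
    }
  }
}

static void next_generation(const Population& p, Population& q, int Ne,
                            double L, double muL, double rL,
                            double inv_s, double inv_e) {
  int M = 2 * Ne;
  q.hap.resize((size_t)M);
  q.inv.resize((size_t)M);
  for (int j = 0; j < M; ++j) {
    int parent = runif_int(Ne);
    make_gamete(p, parent, L, muL, rL, inv_s, inv_e,
                q.hap[(size_t)j], q.inv[(size_t)j]);
  }
}

// remove mutations fixed in the whole population (monomorphic, so never
// segregating in any sample); keeps chromosome vectors from bloating
static void drop_fixed(Population& p) {
  if (p.hap.empty()) return;
  Chrom common = p.hap[0];
  for (size_t i = 1; i < p.hap.size() && !common.empty(); ++i) {
    Chrom tmp;
    std::set_intersection(common.begin(), common.end(),
                          p.hap[i].begin(), p.hap[i].end(),
                          std::back_inserter(tmp));
    common.swap(tmp);
  }
  if (common.empty()) return;
  for (size_t i = 0; i < p.hap.size(); ++i) {
    Chrom tmp;
    std::set_difference(p.hap[i].begin(), p.hap[i].end(),
                        common.begin(), common.end(),
                        std::back_inserter(tmp));
    p.hap[i].swap(tmp);
  }
}

static IntegerVector sample_without_replacement(const std::vector<int>& idx,
                                                int n) {
  std::vector<int> pool(idx);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int j = runif_int((int)pool.size());
    out[i] = pool[(size_t)j];
    pool[(size_t)j] = pool.back();
    pool.pop_back();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_run_replicate(int Ne, double L, double mu, double r,
                       double inv_start, double inv_end,
                       double target_freq, int burnin_gens,
                       double max_generations,
                       int n_inverted, int n_standard) {
  double muL = mu * L, rL = r * L;
  int M = 2 * Ne;
  Population pop, buf;
  pop.hap.assign((size_t)M, Chrom());
  pop.inv.assign((size_t)M, 0);
  for (int g = 0; g < burnin_gens; ++g) {
    next_generation(pop, buf, Ne, L, muL, rL, inv_start, inv_end);
    std::swap(pop, buf);
    if ((g + 1) % 50 == 0) drop_fixed(pop);
  }
  drop_fixed(pop);
  Population base = pop;   // standing variation at inversion introduction

  long restarts = -1;
  double gens_total = 0;
  bool success = false, exhausted = false;
  double freq = 0.0;
  while (!success && !exhausted) {
    ++restarts;
    pop = base;
    int origin = runif_int(M);
    pop.inv[(size_t)origin] = 1;
    while (true) {
      if (gens_total >= max_generations) { exhausted = true; break; }
      next_generation(pop, buf, Ne, L, muL, rL, inv_start, inv_end);
      std::swap(pop, buf);
      gens_total += 1;
      int cnt = 0;
      for (int j = 0; j < M; ++j) cnt += pop.inv[(size_t)j];
      if (cnt == 0) break;                               // lost: restart
      if ((double)cnt / M >= target_freq) {
        success = true;
        freq = (double)cnt / M;
        break;
      }
      if (((long)gens_total) % 100 == 0) drop_fixed(pop);
    }
  }
  if (!success) {
    return List::create(_["success"] = false,
                        _["restarts"] = (double)restarts,
                        _["generations"] = gens_total);
  }
  drop_fixed(pop);
  std::vector<int> inv_idx, std_idx;
  for (int j = 0; j < M; ++j) {
    if (pop.inv[(size_t)j]) inv_idx.push_back(j); else std_idx.push_back(j);
  }
  if ((int)inv_idx.size() < n_inverted || (int)std_idx.size() < n_standard)
    stop("sample sizes exceed available chromosomes at the sampling generation");
  IntegerVector pick_inv = sample_without_replacement(inv_idx, n_inverted);
  IntegerVector pick_std = sample_without_replacement(std_idx, n_standard);
  int n_tot = n_inverted + n_standard;
  List haps(n_tot);
  IntegerVector flags(n_tot);
  for (int i = 0; i < n_inverted; ++i) {
    haps[i] = NumericVector(pop.hap[(size_t)pick_inv[i]].begin(),
                            pop.hap[(size_t)pick_inv[i]].end());
    flags[i] = 1;
  }
  for (int i = 0; i < n_standard; ++i) {
    haps[n_inverted + i] = NumericVector(pop.hap[(size_t)pick_std[i]].begin(),
                                         pop.hap[(size_t)pick_std[i]].end());
    flags[n_inverted + i] = 0;
  }
  return List::create(_["success"] = true,
                      _["haplotypes"] = haps,
                      _["inverted"] = flags,
                      _["generations"] = gens_total,
                      _["restarts"] = (double)restarts,
                      _["frequency"] = freq);
}

// Unconditioned neutral run (no inversion): used for controls and scaling
// checks against coalescent expectations.
// [[Rcpp::export]]
List cpp_neutral_sample(int Ne, double L, double mu, double r,
                        int generations, int n_sample) {
  double muL = mu * L, rL = r * L;
  int M = 2 * Ne;
  if (n_sample > M) stop("n_sample exceeds population size");
  Population pop, buf;
  pop.hap.assign((size_t)M, Chrom());
  pop.inv.assign((size_t)M, 0);
  for (int g = 0; g < generations; ++g) {
    next_generation(pop, buf, Ne, L, muL, rL, -1.0, -1.0);
    std::swap(pop, buf);
    if ((g + 1) % 50 == 0) drop_fixed(pop);
  }
  drop_fixed(pop);
  std::vector<int> idx((size_t)M);
  for (int j = 0; j < M; ++j) idx[(size_t)j] = j;
  IntegerVector pick = sample_without_replacement(idx, n_sample);
  List haps(n_sample);
  for (int i = 0; i < n_sample; ++i)
    haps[i] = NumericVector(pop.hap[(size_t)pick[i]].begin(),
                            pop.hap[(size_t)pick[i]].end());
  return List::create(_["haplotypes"] = haps);
}
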