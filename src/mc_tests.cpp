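// Monte-Carlo engines for the permutation tests. All randomness comes from
// R's RNG (callers set.seed() first), so results are reproducible from R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Conditional log-probability ordering statistic of a genotype array given
// the allele counts (Levene / Guo-Thompson): up to a constant,
// h*log(2) - sum_{i<=j} lgamma(n_ij + 1), h = heterozygote count.
static double hwe_stat(const std::vector<int>& cell, int k, int het) {
  double s = het * M_LN2;
  for (int i = 0; i < k * k; i++)
    if (cell[i] > 0) s -= std::lgamma((double)cell[i] + 1.0);
  return s;
}

// Monte-Carlo exact HWE test: shuffle the 2N gene copies into N random
// pairs; count shuffles whose conditional probability is <= the observed.
// a1, a2: 0-based allele codes per individual.
// [[Rcpp::export]]
List hwe_mc_cpp(IntegerVector a1, IntegerVector a2, int k, int nperm) {
  int n = a1.size();
  std::vector<int> pool(2 * n);
  std::vector<int> cell(k * k, 0);
  int het = 0;
  for (int i = 0; i < n; i++) {
    int x = a1[i], y = a2[i];
    pool[2 * i] = x;
    pool[2 * i + 1] = y;
    if (x != y) het++;
    int lo = x < y ? x : y, hi = x < y ? y : x;
    cell[lo * k + hi]++;
  }
  double obs = hwe_stat(cell, k, het);
  // canonical pool order: results depend only on the allele multiset,
  // not on the order individuals were supplied in
  std::sort(pool.begin(), pool.end());
  int n_le = 0;
  for (int p = 0; p < nperm; p++) {
    for (int i = 2 * n - 1; i > 0; i--) {
      int j = rand_below(i + 1);
      std::swap(pool[i], pool[j]);
    }
    std::fill(cell.begin(), cell.end(), 0);
    het = 0;
    for (int i = 0; i < n; i++) {
      int x = pool[2 * i], y = pool[2 * i + 1];
      if (x != y) het++;
      int lo = x < y ? x : y, hi = x < y ? y : x;
      cell[lo * k + hi]++;
    }
    if (hwe_stat(cell, k, het) <= obs + 1e-9) n_le++;
  }
  return List::create(_["stat"] = obs, _["n_le"] = n_le);
}

static double g2_table(const std::vector<int>& cnt, int ka, int kb, int n) {
  std::vector<int> rt(ka, 0), ct(kb, 0);
  for (int i = 0; i < ka; i++)
    for (int j = 0; j < kb; j++) {
      rt[i] += cnt[i * kb + j];
      ct[j] += cnt[i * kb + j];
    }
  double g2 = 0.0;
  for (int i = 0; i < ka; i++)
    for (int j = 0; j < kb; j++) {
      int o = cnt[i * kb + j];
      if (o > 0)
        g2 += o * std::log((double)o * n / ((double)rt[i] * ct[j]));
    }
  return 2.0 * g2;
}

// G2 permutation test of a two-way contingency table built from class
// codes; the null reshuffles gb across individuals.
// [[Rcpp::export]]
List g2_perm_cpp(IntegerVector ga, IntegerVector gb, int ka, int kb,
                 int nperm) {
  int n = ga.size();
  std::vector<int> b(gb.begin(), gb.end());
  std::vector<int> cnt(ka * kb, 0);
  for (int i = 0; i < n; i++) cnt[ga[i] * kb + b[i]]++;
  double obs = g2_table(cnt, ka, kb, n);
  int n_ge = 0;
  for (int p = 0; p < nperm; p++) {
    for (int i = n - 1; i > 0; i--) {
      int j = rand_below(i + 1);
      std::swap(b[i], b[j]);
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; i++) cnt[ga[i] * kb + b[i]]++;
    if (g2_table(cnt, ka, kb, n) >= obs - 1e-9) n_ge++;
  }
  return List::create(_["g2"] = obs, _["n_ge"] = n_ge);
}

// Allele-permutation homogeneity test of a 2 x k count table: pooled gene
// copies are randomly reassigned to the two populations preserving totals.
// [[Rcpp::export]]
List difftest_perm_cpp(IntegerVector cx, IntegerVector cy, int nperm) {
  int k = cx.size();
  int n1 = 0, n2 = 0;
  for (int i = 0; i < k; i++) { n1 += cx[i]; n2 += cy[i]; }
  int n = n1 + n2;
  std::vector<int> pool;
  pool.reserve(n);
  for (int i = 0; i < k; i++) {
    for (int c = 0; c < cx[i]; c++) pool.push_back(i);
    for (int c = 0; c < cy[i]; c++) pool.push_back(i);
  }
  std::vector<int> cnt(2 * k, 0);
  for (int i = 0; i < k; i++) { cnt[i] = cx[i]; cnt[k + i] = cy[i]; }
  double obs = g2_table(cnt, 2, k, n);
  int n_ge = 0;
  for (int p = 0; p < nperm; p++) {
    for (int i = n - 1; i > 0; i--) {
      int j = rand_below(i + 1);
      std::swap(pool[i], pool[j]);
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n1; i++) cnt[pool[i]]++;
    for (int i = n1; i < n; i++) cnt[k + pool[i]]++;
    if (g2_table(cnt, 2, k, n) >= obs - 1e-9) n_ge++;
  }
  return List::create(_["g2"] = obs, _["n_ge"] = n_ge);
}
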