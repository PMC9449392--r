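#include <Rcpp.h>
using namespace Rcpp;

// Incremental prefix-grouping EHH engine. ht: haplotypes x sites (0/1).
// Group ids refine at each SNP stepping away from the core; haplotypes
// whose group becomes a singleton are dropped (they can never again
// contribute to the pair-homozygosity numerator).
static void ehh_one_side(const IntegerMatrix& ht, const IntegerVector& pos,
                         int core, int step_dir, double cutoff,
                         double max_gap, const std::vector<int>& g0,
                         double e0, std::vector<double>& dist,
                         std::vector<double>& vals) {
  const int n = ht.nrow(), n_sites = ht.ncol();
  dist.push_back(0.0);
  vals.push_back(e0);
  if (e0 < cutoff || e0 <= 0.0) return;

  std::vector<int> g(g0);
  std::vector<int> active;
  {  // keep only members of groups of size >= 2
    std::vector<int> cnt;
    for (int i = 0; i < n; ++i) {
      if ((int)cnt.size() <= g[i]) cnt.resize(g[i] + 1, 0);
      cnt[g[i]]++;
    }
    for (int i = 0; i < n; ++i)
      if (cnt[g[i]] > 1) active.push_back(i);
  }
  const double denom = (double)n * (n - 1);
  double prev_pos = pos[core];
  double e_prev = e0;
  std::vector<int> cnt, remap, ga;
  for (int j = core + step_dir; j >= 0 && j < n_sites && active.size() >= 2;
       j += step_dir) {
    if (std::abs((double)pos[j] - prev_pos) > max_gap) break;
    prev_pos = pos[j];
    const int m = active.size();
    // a site monomorphic among the active haplotypes splits no group:
    // EHH is unchanged and no renumbering is needed
    {
      const int first = ht(active[0], j);
      bool mixed = false;
      for (int k = 1; k < m; ++k) {
        if (ht(active[k], j) != first) { mixed = true; break; }
      }
      if (!mixed) {
        dist.push_back(std::abs((double)pos[j] - (double)pos[core]));
        vals.push_back(e_prev);
        continue;
      }
    }
    ga.resize(m);
    int maxid = 0;
    for (int k = 0; k < m; ++k) {
      ga[k] = g[active[k]] * 2 + ht(active[k], j);
      if (ga[k] > maxid) maxid = ga[k];
    }
    cnt.assign(maxid + 1, 0);
    for (int k = 0; k < m; ++k) cnt[ga[k]]++;
    double num = 0.0;
    for (int id = 0; id <= maxid; ++id)
      num += (double)cnt[id] * (cnt[id] - 1);
    const double e = num / denom;
    if (e < cutoff) break;
    dist.push_back(std::abs((double)pos[j] - (double)pos[core]));
    vals.push_back(e);
    e_prev = e;
    if (e == 0.0) break;
    remap.assign(maxid + 1, 0);
    int next_id = 1;
    for (int id = 0; id <= maxid; ++id)
      if (cnt[id] > 0) remap[id] = next_id++;
    int w = 0;
    for (int k = 0; k < m; ++k) {
      if (cnt[ga[k]] > 1) {
        g[active[k]] = remap[ga[k]];
        active[w++] = active[k];
      }
    }
    active.resize(w);
  }
}

static double core_groups(const IntegerMatrix& ht, int core,
                          bool per_allele, int core_allele,
                          std::vector<int>& g, int& n_used) {
  const int n = ht.nrow();
  g.assign(n, 0);
  if (per_allele) {
    // caller subsets to carriers; here all haplotypes form one group
    for (int i = 0; i < n; ++i) g[i] = 1;
    n_used = n;
    return 1.0;
  }
  int c0 = 0, c1 = 0;
  for (int i = 0; i < n; ++i) {
    g[i] = ht(i, core) + 1;
    if (ht(i, core) == 1) c1++; else c0++;
  }
  n_used = n;
  return ((double)c0 * (c0 - 1) + (double)c1 * (c1 - 1)) /
         ((double)n * (n - 1));
}

// [[Rcpp::export(name = ".ehh_curve_cpp")]]
List ehh_curve_cpp(IntegerMatrix ht, IntegerVector pos, int core,
                   int step_dir, double cutoff, double max_gap,
                   bool per_allele) {
  std::vector<int> g;
  int n_used;
  double e0 = core_groups(ht, core - 1, per_allele, 1, g, n_used);
  std::vector<double> dist, vals;
  ehh_one_side(ht, pos, core - 1, step_dir, cutoff, max_gap, g, e0, dist,
               vals);
  return List::create(_["distance"] = dist, _["ehh"] = vals);
}

static double trapz(const std::vector<double>& d,
                    const std::vector<double>& e) {
  double a = 0.0;
  for (size_t k = 1; k < d.size(); ++k)
    a += (d[k] - d[k - 1]) * (e[k] + e[k - 1]) / 2.0;
  return a;
}

// iHH (both sides) at every core SNP of one population.
// [[Rcpp::export(name = ".ihh_all_cpp")]]
NumericVector ihh_all_cpp(IntegerMatrix ht, IntegerVector pos,
                          double cutoff, double max_gap) {
  const int n_sites = ht.ncol();
  NumericVector out(n_sites);
  std::vector<int> g;
  std::vector<double> dist, vals;
  for (int core = 0; core < n_sites; ++core) {
    int n_used;
    double e0 = core_groups(ht, core, false, 1, g, n_used);
    double ih = 0.0;
    for (int sd = -1; sd <= 1; sd += 2) {
      dist.clear(); vals.clear();
      ehh_one_side(ht, pos, core, sd, cutoff, max_gap, g, e0, dist, vals);
      ih += trapz(dist, vals);
    }
    out[core] = ih;
  }
  return out;
}
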