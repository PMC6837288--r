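// Structured-coalescent core: multi-deme models with population splits,
// piecewise-constant deme sizes and backward per-lineage migration hops.
// Time is continuous, measured in generations; deme sizes are diploids, so a
// pair of haploid lineages in deme d coalesces at rate 1/(2*N[d]) per
// generation. One segregating site is placed per independent genealogy, on a
// branch chosen proportionally to its length (ms "-s 1" semantics).
//
// All randomness comes from R's RNG (unif_rand/exp_rand) so that set.seed()
// in R makes every exported routine bit-reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

const int MAXD = 4;  // supported number of demes

struct Lin {
  double birth;    // time the lineage came into existence (0 for leaves)
  int cnt[MAXD];   // leaves subtended, per sampling deme
};

struct Edge {
  double len;
  int cnt[MAXD];
};

struct Model {
  int nd;
  std::vector<double> sizes;          // present-day diploid sizes
  std::vector<double> split_times;    // ascending, generations
  std::vector<int> split_from, split_to;
  std::vector<double> split_parent_sizes;  // NA -> keep parent size
  NumericMatrix mig;                  // backward per-lineage hop rate /gen
};

inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Simulate one genealogy; fills `edges` and returns the TMRCA.
double simulate_one(const Model& M, const std::vector<int>& samp_hap,
                    std::vector<Edge>& edges) {
  const int nd = M.nd;
  std::vector<double> N(M.sizes);
  std::vector<bool> alive(nd, true);
  std::vector<std::vector<Lin> > byDeme(nd);

  int n_act = 0;
  for (int d = 0; d < nd; ++d) {
    for (int i = 0; i < samp_hap[d]; ++i) {
      Lin l;
      l.birth = 0.0;
      for (int q = 0; q < MAXD; ++q) l.cnt[q] = 0;
      l.cnt[d] = 1;
      byDeme[d].push_back(l);
      ++n_act;
    }
  }

  edges.clear();
  edges.reserve(2 * n_act);
  double t = 0.0;
  size_t next_split = 0;

  while (n_act > 1) {
    // event rates in the current epoch
    double tot = 0.0;
    std::vector<double> coal_rate(nd, 0.0), mig_out(nd, 0.0);
    for (int d = 0; d < nd; ++d) {
      if (!alive[d]) continue;
      double k = (double)byDeme[d].size();
      coal_rate[d] = k * (k - 1.0) / 2.0 / (2.0 * N[d]);
      double mo = 0.0;
      for (int j = 0; j < nd; ++j)
        if (j != d && alive[j]) mo += M.mig(d, j);
      mig_out[d] = k * mo;
      tot += coal_rate[d] + mig_out[d];
    }

    double t_event = (tot > 0.0) ? t + exp_rand() / tot : R_PosInf;

    if (next_split < M.split_times.size() &&
        t_event >= M.split_times[next_split]) {
      // apply the split: move derived deme's lineages into the parent
      t = M.split_times[next_split];
      int from = M.split_from[next_split], to = M.split_to[next_split];
      for (size_t i = 0; i < byDeme[from].size(); ++i)
        byDeme[to].push_back(byDeme[from][i]);
      byDeme[from].clear();
      alive[from] = false;
      double ps = M.split_parent_sizes[next_split];
      if (R_finite(ps) && ps > 0) N[to] = ps;
      ++next_split;
      continue;
    }

    if (!R_finite(t_event))
      stop("non-coalescing model: no events possible with >1 lineage left");
    t = t_event;

    double u = unif_rand() * tot;
    for (int d = 0; d < nd; ++d) {
      if (!alive[d]) continue;
      if (u < coal_rate[d]) {
        // coalescence of a uniform random pair in deme d
        int k = (int)byDeme[d].size();
        int i = runif_int(k);
        int j = runif_int(k - 1);
        if (j >= i) ++j;
        Lin& a = byDeme[d][i];
        Lin& b = byDeme[d][j];
        Edge ea; ea.len = t - a.birth;
        for (int q = 0; q < MAXD; ++q) ea.cnt[q] = a.cnt[q];
        edges.push_back(ea);
        Edge eb; eb.len = t - b.birth;
        for (int q = 0; q < MAXD; ++q) eb.cnt[q] = b.cnt[q];
        edges.push_back(eb);
        Lin par;
        par.birth = t;
        for (int q = 0; q < MAXD; ++q) par.cnt[q] = a.cnt[q] + b.cnt[q];
        // swap-remove the two children (larger index first)
        int hi = (i > j) ? i : j, lo = (i > j) ? j : i;
        byDeme[d][hi] = byDeme[d].back(); byDeme[d].pop_back();
        byDeme[d][lo] = byDeme[d].back(); byDeme[d].pop_back();
        byDeme[d].push_back(par);
        --n_act;
        break;
      }
      u -= coal_rate[d];
      if (u < mig_out[d]) {
        // one lineage hops d -> j, j chosen by relative rate
        double v = unif_rand() * (mig_out[d] / (double)byDeme[d].size());
        int dest = -1;
        for (int j = 0; j < nd; ++j) {
          if (j == d || !alive[j]) continue;
          if (v < M.mig(d, j)) { dest = j; break; }
          v -= M.mig(d, j);
        }
        if (dest < 0) stop("internal error: migration destination");
        int i = runif_int((int)byDeme[d].size());
        byDeme[dest].push_back(byDeme[d][i]);
        byDeme[d][i] = byDeme[d].back();
        byDeme[d].pop_back();
        break;
      }
      u -= mig_out[d];
    }
  }
  return t;
}

Model build_model(NumericVector deme_sizes, NumericMatrix mig,
                  NumericVector split_times, IntegerVector split_from,
                  IntegerVector split_to, NumericVector split_parent_sizes) {
  Model M;
  M.nd = deme_sizes.size();
  if (M.nd > MAXD) stop("at most %d demes supported", MAXD);
  M.sizes.assign(deme_sizes.begin(), deme_sizes.end());
  M.split_times.assign(split_times.begin(), split_times.end());
  for (int i = 0; i < split_from.size(); ++i) {
    M.split_from.push_back(split_from[i] - 1);  // R is 1-based
    M.split_to.push_back(split_to[i] - 1);
  }
  M.split_parent_sizes.assign(split_parent_sizes.begin(),
                              split_parent_sizes.end());
  M.mig = mig;
  return M;
}

}  // namespace

// choose an edge with probability proportional to its length
size_t pick_edge(const std::vector<Edge>& edges, double L) {
  double u = unif_rand() * L;
  for (size_t e = 0; e < edges.size(); ++e) {
    if (u < edges[e].len) return e;
    u -= edges[e].len;
  }
  return edges.size() - 1;
}

// Expected total branch length from a short pilot run, used to calibrate the
// per-tree Poisson mutation count to ~1 under infinite-sites placement.
double pilot_mean_length(const Model& M, const std::vector<int>& samp) {
  std::vector<Edge> edges;
  double tot = 0.0;
  const int n_pilot = 200;
  for (int s = 0; s < n_pilot; ++s) {
    simulate_one(M, samp, edges);
    for (size_t e = 0; e < edges.size(); ++e) tot += edges[e].len;
  }
  return tot / n_pilot;
}

// Simulate neutral SNPs and return per-deme derived allele counts (and, for
// diploid output, heterozygote counts from random pairing of haploids within
// each deme).  Under infinite-sites placement (`one_per_tree = false`) each
// genealogy carries Poisson(L/Lbar) mutations, so genealogies contribute
// SNPs in proportion to their total length L and the marginal SFS matches
// the neutral expectation; `one_per_tree = true` gives ms "-s 1" semantics
// (exactly one site per genealogy, which mildly over-weights short trees).
// [[Rcpp::export(name = ".sim_snps_cpp")]]
List sim_snps_cpp(NumericVector deme_sizes, NumericMatrix mig,
                  NumericVector split_times, IntegerVector split_from,
                  IntegerVector split_to, NumericVector split_parent_sizes,
                  IntegerVector sample_haploids, int n_snps, bool genotypes,
                  bool one_per_tree) {
  Model M = build_model(deme_sizes, mig, split_times, split_from, split_to,
                        split_parent_sizes);
  std::vector<int> samp(sample_haploids.begin(), sample_haploids.end());
  const int nd = M.nd;

  IntegerMatrix derived(n_snps, nd), het(genotypes ? n_snps : 0, nd);
  NumericVector tmrca(n_snps);
  std::vector<Edge> edges;
  std::vector<int> alleles;
  double lambda = one_per_tree ? 0.0 : 1.0 / pilot_mean_length(M, samp);

  int s = 0;
  while (s < n_snps) {
    double tm = simulate_one(M, samp, edges);
    double L = 0.0;
    for (size_t e = 0; e < edges.size(); ++e) L += edges[e].len;
    int k = one_per_tree ? 1 : (int)R::rpois(lambda * L);
    for (int midx = 0; midx < k && s < n_snps; ++midx) {
      size_t hit = pick_edge(edges, L);
      tmrca[s] = tm;
      for (int d = 0; d < nd; ++d) derived(s, d) = edges[hit].cnt[d];
      if (genotypes) {
        // leaves within a deme are exchangeable given the per-deme derived
        // count: random diploid pairing = shuffle alleles, pair consecutive
        for (int d = 0; d < nd; ++d) {
          int n = samp[d];
          alleles.assign(n, 0);
          for (int i = 0; i < derived(s, d); ++i) alleles[i] = 1;
          for (int i = n - 1; i > 0; --i) {
            int j = runif_int(i + 1);
            std::swap(alleles[i], alleles[j]);
          }
          int h = 0;
          for (int i = 0; i + 1 < n; i += 2)
            if (alleles[i] != alleles[i + 1]) ++h;
          het(s, d) = h;
        }
      }
      ++s;
    }
  }

  List out = List::create(_["derived"] = derived, _["tmrca"] = tmrca);
  if (genotypes) out["het"] = het;
  return out;
}

// Monte-Carlo expected joint branch-length SFS: mean total branch length
// subtending (i leaves in deme 1, j leaves in deme 2) over n_sims
// independent genealogies, plus the Monte-Carlo variance of each cell mean
// (used downstream for a second-order bias correction of the composite
// log-likelihood).  For a single deme the second dimension is degenerate.
// [[Rcpp::export(name = ".branch_sfs_cpp")]]
List branch_sfs_cpp(NumericVector deme_sizes, NumericMatrix mig,
                    NumericVector split_times,
                    IntegerVector split_from, IntegerVector split_to,
                    NumericVector split_parent_sizes,
                    IntegerVector sample_haploids, int n_sims, bool fold) {
  Model M = build_model(deme_sizes, mig, split_times, split_from, split_to,
                        split_parent_sizes);
  if (M.nd > 2) stop("branch SFS supported for 1 or 2 demes");
  std::vector<int> samp(sample_haploids.begin(), sample_haploids.end());
  int n1 = samp[0], n2 = (M.nd == 2) ? samp[1] : 0;

  NumericMatrix out(n1 + 1, n2 + 1), sumsq(n1 + 1, n2 + 1);
  NumericMatrix tree(n1 + 1, n2 + 1);
  std::vector<Edge> edges;
  int tot = n1 + n2;
  for (int s = 0; s < n_sims; ++s) {
    simulate_one(M, samp, edges);
    std::fill(tree.begin(), tree.end(), 0.0);
    for (size_t e = 0; e < edges.size(); ++e) {
      int i = edges[e].cnt[0];
      int j = (M.nd == 2) ? edges[e].cnt[1] : 0;
      tree(i, j) += edges[e].len;
    }
    if (fold) {
      // minor-allele folding per genealogy (same keep rule as fold_sfs in
      // R) so that cell variances refer to the folded spectrum
      for (int i = 0; i <= n1; ++i)
        for (int j = 0; j <= n2; ++j) {
          int d = i + j, ii = n1 - i, jj = n2 - j;
          bool keep = (2 * d < tot) ||
            (2 * d == tot && (i < ii || (i == ii && j <= jj)));
          if (!keep) {
            tree(ii, jj) += tree(i, j);
            tree(i, j) = 0.0;
          }
        }
    }
    for (int i = 0; i <= n1; ++i)
      for (int j = 0; j <= n2; ++j) {
        out(i, j) += tree(i, j);
        sumsq(i, j) += tree(i, j) * tree(i, j);
      }
  }
  NumericMatrix var_mean(n1 + 1, n2 + 1);
  for (int i = 0; i <= n1; ++i)
    for (int j = 0; j <= n2; ++j) {
      double mu = out(i, j) / n_sims;
      double v = sumsq(i, j) / n_sims - mu * mu;
      out(i, j) = mu;
      var_mean(i, j) = (v > 0) ? v / n_sims : 0.0;
    }
  return List::create(_["mean"] = out, _["var_mean"] = var_mean);
}

// Haplotype matrix variant of the SNP simulator: returns 0/1 alleles for
// every sampled haploid (columns grouped by deme), for building genotype
// matrices.  Exchangeability within a deme justifies uniform assignment of
// the derived alleles given the per-deme derived count.
// [[Rcpp::export(name = ".sim_haplotypes_cpp")]]
IntegerMatrix sim_haplotypes_cpp(NumericVector deme_sizes, NumericMatrix mig,
                                 NumericVector split_times,
                                 IntegerVector split_from,
                                 IntegerVector split_to,
                                 NumericVector split_parent_sizes,
                                 IntegerVector sample_haploids, int n_snps,
                                 bool one_per_tree) {
  Model M = build_model(deme_sizes, mig, split_times, split_from, split_to,
                        split_parent_sizes);
  std::vector<int> samp(sample_haploids.begin(), sample_haploids.end());
  const int nd = M.nd;
  int n_tot = 0;
  for (int d = 0; d < nd; ++d) n_tot += samp[d];

  IntegerMatrix hap(n_snps, n_tot);
  std::vector<Edge> edges;
  std::vector<int> alleles;
  double lambda = one_per_tree ? 0.0 : 1.0 / pilot_mean_length(M, samp);
  int s = 0;
  while (s < n_snps) {
    simulate_one(M, samp, edges);
    double L = 0.0;
    for (size_t e = 0; e < edges.size(); ++e) L += edges[e].len;
    int k = one_per_tree ? 1 : (int)R::rpois(lambda * L);
    for (int midx = 0; midx < k && s < n_snps; ++midx) {
      size_t hit = pick_edge(edges, L);
      int col0 = 0;
      for (int d = 0; d < nd; ++d) {
        int n = samp[d];
        alleles.assign(n, 0);
        for (int i = 0; i < edges[hit].cnt[d]; ++i) alleles[i] = 1;
        for (int i = n - 1; i > 0; --i) {
          int j = runif_int(i + 1);
          std::swap(alleles[i], alleles[j]);
        }
        for (int i = 0; i < n; ++i) hap(s, col0 + i) = alleles[i];
        col0 += n;
      }
      ++s;
    }
  }
  return hap;
}
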