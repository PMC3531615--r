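// Single-population equilibrium coalescent simulator for microsatellite
// loci under stepwise (SMM) and two-phase (TPM) mutation. This is the
// inner loop of the heterozygosity-excess bottleneck test: for each locus
// many replicate samples of n gene copies are simulated at a given theta
// (= 4 N beta) and summarised by the allele count k and the unbiased
// expected heterozygosity. Uses R's RNG so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

static inline int step_size(int model, double p_ss, double q_geom) {
  // model 0 = SMM (always one repeat unit); model 1 = TPM: with prob
  // 1 - p_ss the jump magnitude is geometric on {1, 2, ...} with success
  // probability q_geom (variance (1-q)/q^2)
  if (model == 1 && unif_rand() > p_ss) {
    return 1 + (int) R::rgeom(q_geom);
  }
  return 1;
}

// [[Rcpp::export]]
List sim_msat_replicates(int n, double theta, int n_rep, int model,
                         double p_ss, double q_geom) {
  if (n < 2) stop("need at least 2 gene copies");
  if (theta <= 0) stop("theta must be positive");
  IntegerVector k_out(n_rep);
  NumericVector he_out(n_rep);
  int n_nodes = 2 * n - 1;
  std::vector<int> parent(n_nodes);
  std::vector<double> time(n_nodes);
  std::vector<int> active(n);
  std::vector<long> value(n_nodes);

  for (int rep = 0; rep < n_rep; ++rep) {
    for (int i = 0; i < n; ++i) { time[i] = 0.0; active[i] = i; }
    int k_act = n, next = n;
    double t = 0.0;
    while (k_act > 1) {
      double rate = k_act * (k_act - 1) / 2.0;
      t += R::exp_rand() / rate;
      int i = (int)(unif_rand() * k_act); if (i == k_act) i = k_act - 1;
      int j = (int)(unif_rand() * (k_act - 1)); if (j == k_act - 1) j = k_act - 2;
      if (j >= i) j += 1;
      int ci = active[i], cj = active[j];
      parent[ci] = next; parent[cj] = next;
      time[next] = t;
      // replace the two children by the parent in the active list
      int lo = i < j ? i : j, hi = i < j ? j : i;
      active[lo] = next;
      active[hi] = active[k_act - 1];
      k_act -= 1; next += 1;
    }
    int root = n_nodes - 1;
    value[root] = 0;
    for (int v = n_nodes - 2; v >= 0; --v) {
      double branch = time[parent[v]] - time[v];
      int nmut = (int) R::rpois(0.5 * theta * branch);
      long disp = 0;
      for (int m = 0; m < nmut; ++m) {
        int s = step_size(model, p_ss, q_geom);
        disp += (unif_rand() < 0.5) ? s : -s;
      }
      value[v] = value[parent[v]] + disp;
    }
    std::map<long, int> counts;
    for (int i = 0; i < n; ++i) counts[value[i]] += 1;
    double sump2 = 0.0;
    for (std::map<long, int>::iterator it = counts.begin();
         it != counts.end(); ++it) {
      double p = (double) it->second / n;
      sump2 += p * p;
    }
    k_out[rep] = (int) counts.size();
    he_out[rep] = n * (1.0 - sump2) / (n - 1.0);
  }
  return List::create(_["k"] = k_out, _["he"] = he_out);
}
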