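#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// Multiplicative karyotype fitness: product of per-chromosome copy-state
// factors times any matching pairwise interaction terms.
static double karyotype_fitness_cpp(const std::vector<int> &kar,
                                    const NumericMatrix &fitness,
                                    const IntegerVector &ia,
                                    const IntegerVector &ib,
                                    const IntegerVector &ica,
                                    const IntegerVector &icb,
                                    const NumericVector &ifac) {
  double w = 1.0;
  const int C = kar.size();
  for (int j = 0; j < C; ++j) {
    w *= fitness(j, kar[j]);
    if (w == 0.0) return 0.0;
  }
  for (int r = 0; r < ia.size(); ++r) {
    if (kar[ia[r]] == ica[r] && kar[ib[r]] == icb[r]) w *= ifac[r];
  }
  return w;
}

// One Wright-Fisher serial-passaging replicate. Population state is a table
// of (karyotype, cell count) clones. Each generation: multinomial offspring
// sampling proportional to count * fitness, then missegregation events
// (total per clone ~ Binomial(count * C, m), each event assigned to a
// uniform chromosome slot and a +/-1 direction with probability 1/2 each --
// equivalent in distribution to independent Binomial(count, m/2) gains and
// losses per chromosome). Gains at max_copy and losses at 0 are no-ops.
// Each round ends with a colony-picking bottleneck: one clone sampled
// proportional to its frequency. Returns the bottleneck karyotype per round
// (last row = final karyotype), or a 0-row matrix on extinction.
// [[Rcpp::export]]
IntegerMatrix wf_replicate(NumericMatrix fitness, IntegerVector ia,
                           IntegerVector ib, IntegerVector ica,
                           IntegerVector icb, NumericVector ifac, double m,
                           int N, int rounds, int gens, int max_copy,
                           int ploidy) {
  const int C = fitness.nrow();
  std::vector<std::vector<int> > kar(1, std::vector<int>(C, ploidy));
  std::vector<double> w(1);
  std::vector<int> cnt(1, N);
  w[0] = karyotype_fitness_cpp(kar[0], fitness, ia, ib, ica, icb, ifac);
  IntegerMatrix lineage(rounds, C);

  std::vector<double> prob;
  std::vector<int> draws;

  for (int round = 0; round < rounds; ++round) {
    for (int gen = 0; gen < gens; ++gen) {
      const int nc = kar.size();
      double total = 0.0;
      prob.assign(nc, 0.0);
      for (int i = 0; i < nc; ++i) {
        prob[i] = cnt[i] * w[i];
        total += prob[i];
      }
      if (total <= 0.0) return IntegerMatrix(0, C);  // extinct
      for (int i = 0; i < nc; ++i) prob[i] /= total;
      draws.assign(nc, 0);
      rmultinom(N, prob.data(), nc, draws.data());

      // map merges identical karyotypes (parents and new missegregants)
      std::map<std::vector<int>, int> pool;
      for (int i = 0; i < nc; ++i) {
        int n_i = draws[i];
        if (n_i == 0) continue;
        if (m > 0.0) {
          int events = (int) R::rbinom((double) n_i * C, m);
          for (int e = 0; e < events && n_i > 0; ++e) {
            int j = (int) (unif_rand() * C);
            if (j >= C) j = C - 1;
            int step = (unif_rand() < 0.5) ? 1 : -1;
            int newc = kar[i][j] + step;
            if (newc < 0 || newc > max_copy) continue;  // no-op at bounds
            std::vector<int> daughter(kar[i]);
            daughter[j] = newc;
            pool[daughter] += 1;
            n_i -= 1;
          }
        }
        if (n_i > 0) pool[kar[i]] += n_i;
      }

      std::vector<std::vector<int> > kar2;
      std::vector<double> w2;
      std::vector<int> cnt2;
      kar2.reserve(pool.size());
      w2.reserve(pool.size());
      cnt2.reserve(pool.size());
      for (std::map<std::vector<int>, int>::iterator it = pool.begin();
           it != pool.end(); ++it) {
        kar2.push_back(it->first);
        cnt2.push_back(it->second);
        w2.push_back(karyotype_fitness_cpp(it->first, fitness, ia, ib, ica,
                                           icb, ifac));
      }
      kar.swap(kar2);
      w.swap(w2);
      cnt.swap(cnt2);
    }

    // bottleneck: pick one clone proportional to frequency
    double u = unif_rand() * N;
    int pick = 0;
    double acc = 0.0;
    for (size_t i = 0; i < kar.size(); ++i) {
      acc += cnt[i];
      if (u <= acc) { pick = i; break; }
    }
    std::vector<int> chosen = kar[pick];
    for (int j = 0; j < C; ++j) lineage(round, j) = chosen[j];
    kar.assign(1, chosen);
    cnt.assign(1, N);
    w.assign(1, karyotype_fitness_cpp(chosen, fitness, ia, ib, ica, icb,
                                      ifac));
  }
  return lineage;
}
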