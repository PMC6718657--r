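#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo Hardy-Weinberg p-value by random allele pairing.
// Each draw shuffles the 2n observed alleles (nA copies of A, na of a) into n
// genotypes and records the heterozygote count; the p-value is the fraction of
// draws whose heterozygote count has conditional probability at most that of
// the observed configuration. Used as a simulation oracle for the exact test.
// [[Rcpp::export]]
List hwe_mc_pvalue(int n_AA, int n_Aa, int n_aa, int n_draws) {
  int n = n_AA + n_Aa + n_aa;
  int nA = 2 * n_AA + n_Aa;
  int total = 2 * n;

  // exact conditional log-probabilities only to order configurations by
  // probability; the p-value itself is purely Monte Carlo
  int nmin = std::min(nA, total - nA);
  std::vector<double> logp(nmin + 1, R_NegInf);
  for (int h = nmin % 2; h <= nmin; h += 2) {
    logp[h] = R::lgammafn(n + 1) - R::lgammafn((nA - h) / 2.0 + 1) -
              R::lgammafn(h + 1.0) - R::lgammafn((total - nA - h) / 2.0 + 1) +
              h * std::log(2.0) + R::lgammafn(nA + 1) +
              R::lgammafn(total - nA + 1) - R::lgammafn(total + 1.0);
  }
  double obs_logp = logp[n_Aa];

  // a random pairing is summarized by the positions of the minority alleles:
  // draw that subset with a partial Fisher-Yates shuffle and count genotype
  // slots receiving exactly one minority allele
  int s = nmin;
  std::vector<int> idx(total);
  std::vector<int> mark(n, -1);
  for (int i = 0; i < total; ++i) idx[i] = i;

  long hits = 0;
  const double tol = 1e-9; // ties in probability count as "as extreme"
  for (int d = 0; d < n_draws; ++d) {
    int doubles = 0;
    for (int i = 0; i < s; ++i) {
      int j = i + (int)(unif_rand() * (total - i));
      std::swap(idx[i], idx[j]);
      int g = idx[i] >> 1;
      if (mark[g] == d) ++doubles; else mark[g] = d;
    }
    int het = s - 2 * doubles;
    if (logp[het] <= obs_logp + tol) ++hits;
  }
  double p = (double)hits / n_draws;
  double se = std::sqrt(std::max(p * (1 - p), 1.0 / n_draws) / n_draws);
  return List::create(_["p"] = p, _["se"] = se);
}
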