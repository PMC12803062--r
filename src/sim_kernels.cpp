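#include <Rcpp.h>
using namespace Rcpp;

// Single-factor Gaussian copula haplotype model. Each haplotype h carries one
// latent factor W_h ~ N(0,1); the latent value at SNP j is
//   Z_hj = sqrt(rho) * W_h + sqrt(1 - rho) * e_hj,   e_hj ~ N(0,1) iid,
// and the haplotype carries allele A at SNP j iff Z_hj < qnorm(p_j).
// Marginal allele-A frequency is p_j and the correlation of allele
// indicators across SNPs on a haplotype is exchangeable (driven by rho).
// All randomness comes from R's RNG so set.seed() governs everything.

static inline int hap_allele(double w, double srho, double s1m, double th) {
  return (srho * w + s1m * norm_rand() < th) ? 1 : 0;
}

// Draw a full haplotype given its factor value.
static inline void draw_hap(double w, double srho, double s1m,
                            const NumericVector& th, int S, int* hap) {
  for (int j = 0; j < S; ++j) hap[j] = hap_allele(w, srho, s1m, th[j]);
}

// Simulate per-SNP genotype counts for n diploid individuals of one sex.
//
// mode: 0 = neutral, 1 = genotype-weighted sampling at the target SNP
//       (viability or participation selection; w = weights for AA/AB/BB
//       counting A alleles, i.e. index = number of A alleles reversed:
//       g = a1 + a2 in {0,1,2}, weight w[g] where w[2] is the AA weight),
//       2 = gametic transmission bias (tau = probability that a
//       heterozygous father transmits the A-carrying haplotype).
// f_coef: inbreeding-like distortion in [0,1): with probability f_coef an
//       individual's second haplotype is an identical copy of the first
//       (IBD), yielding genotype frequencies p^2+Fpq, 2pq(1-F), q^2+Fpq at
//       every SNP. Only used for modes 0 and 1.
// target: 0-based index of the SNP selection acts on.
// Returns a list: counts = 3 x S integer matrix (rows n_AA, n_AB, n_BB,
// counting the A allele), and optionally dosages = n x S integer matrix of
// A-allele dosages when want_dosages is true.
// [[Rcpp::export]]
List sim_gene_counts_cpp(int n, NumericVector thresh, double rho,
                         int mode, double f_coef, NumericVector w,
                         double tau, int target, bool want_dosages) {
  const int S = thresh.size();
  if (n < 1) stop("n must be >= 1");
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)");
  if (f_coef < 0 || f_coef >= 1) stop("F must be in [0, 1) for simulation");
  if (target < 0 || target >= S) stop("target SNP index out of range");
  const double srho = std::sqrt(rho), s1m = std::sqrt(1.0 - rho);

  IntegerMatrix counts(3, S);
  IntegerMatrix dos = want_dosages ? IntegerMatrix(n, S) : IntegerMatrix(0, 0);
  std::vector<int> h1(S), h2(S);

  double wmax = 1.0;
  if (mode == 1) {
    wmax = std::max(w[0], std::max(w[1], w[2]));
    if (wmax <= 0) stop("degenerate selection weights (all zero)");
  }

  for (int i = 0; i < n; ++i) {
    if (mode == 2) {
      // Offspring: one maternal haplotype (neutral transmission) and one
      // paternal haplotype chosen from the father's pair with bias tau at
      // the target SNP when the father is heterozygous there.
      double wm = norm_rand();
      draw_hap(wm, srho, s1m, thresh, S, h1.data());
      double wf1 = norm_rand(), wf2 = norm_rand();
      int a1 = hap_allele(wf1, srho, s1m, thresh[target]);
      int a2 = hap_allele(wf2, srho, s1m, thresh[target]);
      double wchosen;
      int at;
      if (a1 != a2) {
        // transmit the A-carrier with probability tau
        bool takeA = unif_rand() < tau;
        if ((a1 == 1) == takeA) { wchosen = wf1; at = a1; }
        else                    { wchosen = wf2; at = a2; }
      } else {
        wchosen = (unif_rand() < 0.5) ? wf1 : wf2;
        at = a1;
      }
      for (int j = 0; j < S; ++j)
        h2[j] = (j == target) ? at : hap_allele(wchosen, srho, s1m, thresh[j]);
    } else {
      // Neutral or genotype-weighted individual; rejection-sample under the
      // target-SNP genotype weights so sampled frequencies equal the
      // post-selection closed form.
      for (;;) {
        bool ibd = (f_coef > 0.0) && (unif_rand() < f_coef);
        double w1 = norm_rand();
        double w2 = ibd ? w1 : norm_rand();
        int a1 = hap_allele(w1, srho, s1m, thresh[target]);
        int a2;
        if (ibd) a2 = a1; else a2 = hap_allele(w2, srho, s1m, thresh[target]);
        int g = a1 + a2;
        if (mode == 1 && unif_rand() >= w[g] / wmax) continue;
        for (int j = 0; j < S; ++j) {
          if (j == target) { h1[j] = a1; h2[j] = a2; continue; }
          h1[j] = hap_allele(w1, srho, s1m, thresh[j]);
          h2[j] = ibd ? h1[j] : hap_allele(w2, srho, s1m, thresh[j]);
        }
        break;
      }
    }
    for (int j = 0; j < S; ++j) {
      int g = h1[j] + h2[j]; // A-allele dosage
      counts(2 - g, j) += 1; // row 0 = n_AA, 1 = n_AB, 2 = n_BB
      if (want_dosages) dos(i, j) = g;
    }
  }

  if (want_dosages) return List::create(_["counts"] = counts, _["dosages"] = dos);
  return List::create(_["counts"] = counts);
}
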