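#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Local forward algorithm over the simplified profile model in log2
// space.  States per position j (0-based): Match M_j, Insert I_j
// (j <= M-2), Delete D_j (j >= 1).  Entry at any match state with mass
// 1/M; exit from any match state with weight 1.  Emission odds are
// ratios against the background; wildcard residues (index -1) emit with
// background probability, so their odds ratio is 1.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log2(1.0 + std::exp2(b - a));
}

// [[Rcpp::export(name = ".forward_bits")]]
double forward_bits(IntegerVector seq, NumericMatrix match_emis,
                    NumericVector insert_emis, NumericVector background,
                    NumericVector tMM, NumericVector tMI, NumericVector tMD,
                    NumericVector tII, NumericVector tIM,
                    NumericVector tDD, NumericVector tDM) {
  const int M = match_emis.nrow();
  const int L = seq.size();
  if (L == 0) stop("empty sequence");

  std::vector<double> lMM(std::max(M - 1, 0)), lMI(std::max(M - 1, 0)),
      lMD(std::max(M - 1, 0)), lII(std::max(M - 1, 0)), lIM(std::max(M - 1, 0)),
      lDD(std::max(M - 1, 0)), lDM(std::max(M - 1, 0));
  for (int k = 0; k < M - 1; ++k) {
    lMM[k] = std::log2(tMM[k]); lMI[k] = std::log2(tMI[k]);
    lMD[k] = std::log2(tMD[k]); lII[k] = std::log2(tII[k]);
    lIM[k] = std::log2(tIM[k]); lDD[k] = std::log2(tDD[k]);
    lDM[k] = std::log2(tDM[k]);
  }
  const double log_entry = -std::log2((double)M);

  // log2 emission odds per (state j, residue position i)
  std::vector<double> ler((size_t)M * L), lir(L);
  for (int i = 0; i < L; ++i) {
    int a = seq[i];
    lir[i] = (a < 0) ? 0.0 : std::log2(insert_emis[a] / background[a]);
    for (int j = 0; j < M; ++j) {
      ler[(size_t)j * L + i] =
          (a < 0) ? 0.0 : std::log2(match_emis(j, a) / background[a]);
    }
  }

  std::vector<double> VM(M, NEG_INF), VI(M, NEG_INF), VD(M, NEG_INF);
  std::vector<double> nVM(M), nVI(M), nVD(M);
  double total = NEG_INF;

  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < M; ++j) {
      double acc = log_entry;
      if (j > 0) {
        acc = lse2(acc, VM[j - 1] + lMM[j - 1]);
        acc = lse2(acc, VI[j - 1] + lIM[j - 1]);
        acc = lse2(acc, VD[j - 1] + lDM[j - 1]);
      }
      nVM[j] = ler[(size_t)j * L + i] + acc;
    }
    for (int j = 0; j < M; ++j) {
      nVI[j] = (j < M - 1)
                   ? lir[i] + lse2(VM[j] + lMI[j], VI[j] + lII[j])
                   : NEG_INF;
    }
    nVD[0] = NEG_INF;
    for (int j = 1; j < M; ++j) {
      nVD[j] = lse2(nVM[j - 1] + lMD[j - 1], nVD[j - 1] + lDD[j - 1]);
    }
    for (int j = 0; j < M; ++j) total = lse2(total, nVM[j]);
    VM.swap(nVM); VI.swap(nVI); VD.swap(nVD);
  }
  return total;
}
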