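#include <Rcpp.h>
using namespace Rcpp;

// One attempted checkerboard swap on a binary matrix: pick a random 2x2
// submatrix; if it is [[1,0],[0,1]] or [[0,1],[1,0]], flip it. Picking the
// submatrix uniformly and flipping conditionally gives a symmetric chain,
// hence a uniform stationary distribution over the margin-preserving state
// space. Uses R's RNG so set.seed() governs reproducibility.
static inline int attempt_swap(IntegerMatrix& m, int R, int C) {
  int r1 = (int)(unif_rand() * R);
  int r2 = (int)(unif_rand() * (R - 1));
  if (r2 >= r1) r2++;
  int c1 = (int)(unif_rand() * C);
  int c2 = (int)(unif_rand() * (C - 1));
  if (c2 >= c1) c2++;
  int a = m(r1, c1), b = m(r1, c2), c = m(r2, c1), d = m(r2, c2);
  if (a == d && b == c && a != b) {
    m(r1, c1) = 1 - a; m(r1, c2) = 1 - b;
    m(r2, c1) = 1 - c; m(r2, c2) = 1 - d;
    return 1;
  }
  return 0;
}

// [[Rcpp::export]]
IntegerMatrix cpp_swap(IntegerMatrix mat, int nswaps) {
  IntegerMatrix m = clone(mat);
  int R = m.nrow(), C = m.ncol();
  if (R < 2 || C < 2) return m;
  for (int i = 0; i < nswaps; i++) attempt_swap(m, R, C);
  return m;
}

// Run the swap chain, sampling N matrices after burnin attempts with
// `spacing` attempts between samples. Returns per-matrix C-score and
// checkerboard statistics, per-pair checkerboard-unit samples, the sampled
// matrices and the overall swap acceptance rate.
// [[Rcpp::export]]
List cpp_null_ensemble(IntegerMatrix mat, int N, double burnin,
                       double spacing) {
  IntegerMatrix m = clone(mat);
  int R = m.nrow(), C = m.ncol();
  int P = R * (R - 1) / 2;
  NumericMatrix pairCU(P, N);
  NumericVector cs(N), ckPairs(N), ckUnits(N);
  IntegerVector mats(R * C * N);
  std::vector<int> rs(R, 0);
  for (int i = 0; i < R; i++)
    for (int j = 0; j < C; j++) rs[i] += m(i, j);
  long long attempts = 0, accepted = 0;
  if (R >= 2 && C >= 2) {
    for (long long t = 0; t < (long long)burnin; t++) {
      accepted += attempt_swap(m, R, C);
      attempts++;
    }
  }
  for (int s = 0; s < N; s++) {
    if (R >= 2 && C >= 2) {
      for (long long t = 0; t < (long long)spacing; t++) {
        accepted += attempt_swap(m, R, C);
        attempts++;
      }
    }
    for (int i = 0; i < R; i++)
      for (int j = 0; j < C; j++)
        mats[(long long)s * R * C + j * R + i] = m(i, j);
    int p = 0;
    double totCU = 0.0;
    int nzPairs = 0;
    for (int i = 0; i < R; i++) {
      for (int j = i + 1; j < R; j++) {
        int S = 0;
        for (int k = 0; k < C; k++) S += m(i, k) & m(j, k);
        double cu = (double)(rs[i] - S) * (double)(rs[j] - S);
        pairCU(p, s) = cu;
        totCU += cu;
        if (S == 0) nzPairs++;
        p++;
      }
    }
    cs[s] = P > 0 ? totCU / P : NA_REAL;
    ckUnits[s] = totCU;
    ckPairs[s] = nzPairs;
  }
  double acc = attempts > 0 ? (double)accepted / (double)attempts : NA_REAL;
  return List::create(_["pairCU"] = pairCU, _["cscores"] = cs,
                      _["checkerPairs"] = ckPairs,
                      _["checkerUnits"] = ckUnits, _["matrices"] = mats,
                      _["acceptanceRate"] = acc);
}
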