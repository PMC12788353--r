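#include <Rcpp.h>
using namespace Rcpp;

// Symmetric reflection with edge duplication into [0, n).
// Valid for any offset because it folds repeatedly; in practice r < n.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    else i = 2 * n - i - 1;
  }
  return i;
}

// Per-pixel spectral similarity weights on a mirror-padded feature raster.
// padded: (M+2r) x (N+2r) x d array (column-major). Returns M x N x (2r+1)^2
// with offset index off = (dv+r)*(2r+1) + (du+r), du = row offset, dv = col
// offset, i.e. the column-major flattening of the (2r+1)x(2r+1) offset grid.
// [[Rcpp::export]]
NumericVector spectral_weights_cpp(NumericVector padded, int M, int N, int r,
                                   double sigma_w) {
  const int w = 2 * r + 1, nOff = w * w;
  const int Mp = M + 2 * r, Np = N + 2 * r;
  const int d = padded.size() / (Mp * Np);
  const double inv2s2 = 1.0 / (2.0 * sigma_w * sigma_w);
  NumericVector W(static_cast<R_xlen_t>(M) * N * nOff);
  W.attr("dim") = IntegerVector::create(M, N, nOff);
  const double* f = padded.begin();
  double* out = W.begin();
  for (int dv = -r; dv <= r; ++dv) {
    for (int du = -r; du <= r; ++du) {
      const int off = (dv + r) * w + (du + r);
      for (int j = 0; j < N; ++j) {
        for (int i = 0; i < M; ++i) {
          // pixel (i, j) sits at padded (i+r, j+r)
          double d2 = 0.0;
          const int pi = i + r, pj = j + r;
          const int qi = pi + du, qj = pj + dv;
          for (int b = 0; b < d; ++b) {
            const double diff = f[pi + static_cast<R_xlen_t>(Mp) * (pj + static_cast<R_xlen_t>(Np) * b)] -
                                f[qi + static_cast<R_xlen_t>(Mp) * (qj + static_cast<R_xlen_t>(Np) * b)];
            d2 += diff * diff;
          }
          out[i + static_cast<R_xlen_t>(M) * (j + static_cast<R_xlen_t>(N) * off)] =
              std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return W;
}

// Class energy of pixel (i0, j0) for class k (1-based), given current labels
// and probability raster. Neighbor indices are mirror-reflected into the
// scene; neighbors labeled 0 (background) contribute nothing.
static double pixel_energy(const int* lab, const double* P, const double* W,
                           const double* S, int M, int N, int K, int r,
                           double beta, int form, int i0, int j0, int k) {
  const int w = 2 * r + 1;
  const R_xlen_t MN = static_cast<R_xlen_t>(M) * N;
  double acc = 0.0;
  for (int dv = -r; dv <= r; ++dv) {
    for (int du = -r; du <= r; ++du) {
      if (du == 0 && dv == 0) continue;
      const int ni = reflect_idx(i0 + du, M);
      const int nj = reflect_idx(j0 + dv, N);
      const int lj = lab[ni + static_cast<R_xlen_t>(M) * nj];
      if (lj == 0) continue;
      const int off = (dv + r) * w + (du + r);
      const double wij = W[i0 + static_cast<R_xlen_t>(M) * j0 + MN * off];
      const double sij = S[off];
      const double pj = P[ni + static_cast<R_xlen_t>(M) * nj + MN * (k - 1)];
      const double ind = (lj == k) ? 1.0 : -1.0;
      if (form == 0) {
        // grouped form: spectral term (1-b)*W*P, spatial term b*(S*P + I)
        acc += (1.0 - beta) * wij * pj + beta * (sij * pj + ind);
      } else {
        // ungrouped form: (1-b)*(W+S)*P + b*I
        acc += (1.0 - beta) * (wij + sij) * pj + beta * ind;
      }
    }
  }
  return -acc;
}

// Full M x N x K energy array. Background pixels get 0 energies (unused).
// [[Rcpp::export]]
NumericVector energies_cpp(IntegerMatrix labels, NumericVector P,
                           NumericVector W, NumericVector S, int r,
                           double beta, int form) {
  const int M = labels.nrow(), N = labels.ncol();
  const int K = IntegerVector(P.attr("dim"))[2];
  NumericVector E(static_cast<R_xlen_t>(M) * N * K);
  E.attr("dim") = IntegerVector::create(M, N, K);
  const int* lab = labels.begin();
  const double *p = P.begin(), *w = W.begin(), *s = S.begin();
  double* e = E.begin();
  const R_xlen_t MN = static_cast<R_xlen_t>(M) * N;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < M; ++i) {
      if (lab[i + static_cast<R_xlen_t>(M) * j] == 0) continue;
      for (int k = 1; k <= K; ++k)
        e[i + static_cast<R_xlen_t>(M) * j + MN * (k - 1)] =
            pixel_energy(lab, p, w, s, M, N, K, r, beta, form, i, j, k);
    }
  return E;
}

// One ICM sweep in raster (row-major) order with in-place label updates.
// clamp marks pixels whose label must not change (training pixels).
// Ties broken toward the smallest class id.
// [[Rcpp::export]]
IntegerMatrix icm_sweep_cpp(IntegerMatrix labels, NumericVector P,
                            NumericVector W, NumericVector S, int r,
                            double beta, int form, LogicalMatrix clamp) {
  const int M = labels.nrow(), N = labels.ncol();
  const int K = IntegerVector(P.attr("dim"))[2];
  IntegerMatrix out = clone(labels);
  int* lab = out.begin();
  const double *p = P.begin(), *w = W.begin(), *s = S.begin();
  for (int i = 0; i < M; ++i) {      // raster order: row by row,
    for (int j = 0; j < N; ++j) {    // columns within a row
      if (lab[i + static_cast<R_xlen_t>(M) * j] == 0) continue;
      if (clamp(i, j)) continue;
      int best = 1;
      double ebest = pixel_energy(lab, p, w, s, M, N, K, r, beta, form, i, j, 1);
      for (int k = 2; k <= K; ++k) {
        const double ek = pixel_energy(lab, p, w, s, M, N, K, r, beta, form, i, j, k);
        if (ek < ebest) { ebest = ek; best = k; }
      }
      lab[i + static_cast<R_xlen_t>(M) * j] = best;
    }
  }
  return out;
}
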