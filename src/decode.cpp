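// Pairwise cross-validated linear-discriminant decoding across time.
//
// For every unordered stimulus pair, every cross-validation fold and every
// time sample, fits a two-class linear discriminant with a shared covariance
// estimated from the training folds (Ledoit-Wolf analytic shrinkage toward
// the scaled identity, or a fixed shrinkage intensity) and scores the
// held-out fold. Accuracy is the proportion of correct predictions pooled
// over folds. Ties at the decision boundary go to the first class
// (the lower stimulus id), deterministically.
//
// The inner loop runs millions of small (~6-channel) fits per call, so it
// is written allocation-free with a hand-rolled Cholesky solve.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cholesky factorization of a symmetric positive-definite matrix stored as
// a dense C x C row-major buffer; returns false if not SPD.
static bool chol_solve(const int C, std::vector<double>& A,
                       const double* b, double* x) {
  // in-place lower Cholesky
  for (int j = 0; j < C; ++j) {
    double d = A[j * C + j];
    for (int k = 0; k < j; ++k) d -= A[j * C + k] * A[j * C + k];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[j * C + j] = d;
    for (int i = j + 1; i < C; ++i) {
      double s = A[i * C + j];
      for (int k = 0; k < j; ++k) s -= A[i * C + k] * A[j * C + k];
      A[i * C + j] = s / d;
    }
  }
  // forward then backward substitution
  for (int i = 0; i < C; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= A[i * C + k] * x[k];
    x[i] = s / A[i * C + i];
  }
  for (int i = C - 1; i >= 0; --i) {
    double s = x[i];
    for (int k = i + 1; k < C; ++k) s -= A[k * C + i] * x[k];
    x[i] = s / A[i * C + i];
  }
  return true;
}

// [[Rcpp::export]]
arma::cube cpp_pairwise_decode(const arma::cube& X,      // trials x channels x time
                               const arma::ivec& labels, // 1..n_stim codes per trial
                               const arma::ivec& folds,  // 0..(F-1) per trial
                               const int n_stim,
                               const double shrinkage) { // < 0 => Ledoit-Wolf
  const uword n_trials = X.n_rows, C = X.n_cols, T = X.n_slices;
  if (labels.n_elem != n_trials || folds.n_elem != n_trials)
    Rcpp::stop("labels/folds length must match trial count");
  const int F = folds.max() + 1;

  std::vector<std::vector<uword>> by_stim(n_stim);
  for (uword i = 0; i < n_trials; ++i) {
    int s = labels(i) - 1;
    if (s < 0 || s >= n_stim) Rcpp::stop("label out of range");
    by_stim[s].push_back(i);
  }

  cube acc(n_stim, n_stim, T);
  acc.fill(datum::nan);

  std::vector<double> xb;             // pair trials, row-major (np x C)
  std::vector<int> yv, fv;
  std::vector<double> m0(C), m1(C), diff(C), msum(C), w(C), z(C);
  std::vector<double> S(C * C), Sig(C * C);

  for (int a = 0; a < n_stim - 1; ++a) {
    if (by_stim[a].empty()) continue;
    for (int b = a + 1; b < n_stim; ++b) {
      if (by_stim[b].empty()) continue;
      const uword n0 = by_stim[a].size(), n1 = by_stim[b].size();
      const uword np = n0 + n1;
      std::vector<uword> idx(np);
      yv.assign(np, 0); fv.assign(np, 0);
      for (uword i = 0; i < n0; ++i) {
        idx[i] = by_stim[a][i]; yv[i] = 0; fv[i] = folds(by_stim[a][i]);
      }
      for (uword i = 0; i < n1; ++i) {
        idx[n0 + i] = by_stim[b][i]; yv[n0 + i] = 1; fv[n0 + i] = folds(by_stim[b][i]);
      }
      xb.assign(np * C, 0.0);

      for (uword t = 0; t < T; ++t) {
        const double* slice = X.slice_memptr(t);  // column-major trials x C
        for (uword i = 0; i < np; ++i)
          for (uword c = 0; c < C; ++c)
            xb[i * C + c] = slice[idx[i] + c * n_trials];

        int correct = 0, total = 0;
        for (int fold = 0; fold < F; ++fold) {
          std::fill(m0.begin(), m0.end(), 0.0);
          std::fill(m1.begin(), m1.end(), 0.0);
          uword c0 = 0, c1 = 0;
          bool any_test = false;
          for (uword i = 0; i < np; ++i) {
            if (fv[i] == fold) { any_test = true; continue; }
            const double* xi = &xb[i * C];
            if (yv[i] == 0) { for (uword c = 0; c < C; ++c) m0[c] += xi[c]; ++c0; }
            else            { for (uword c = 0; c < C; ++c) m1[c] += xi[c]; ++c1; }
          }
          if (!any_test || c0 == 0 || c1 == 0) continue;
          for (uword c = 0; c < C; ++c) { m0[c] /= c0; m1[c] /= c1; }

          std::fill(S.begin(), S.end(), 0.0);
          double quart = 0.0;
          const uword n_train = c0 + c1;
          for (uword i = 0; i < np; ++i) {
            if (fv[i] == fold) continue;
            const double* xi = &xb[i * C];
            const double* m = (yv[i] == 0) ? m0.data() : m1.data();
            double q = 0.0;
            for (uword c = 0; c < C; ++c) { z[c] = xi[c] - m[c]; q += z[c] * z[c]; }
            quart += q * q;
            for (uword c = 0; c < C; ++c)
              for (uword d = c; d < C; ++d) S[c * C + d] += z[c] * z[d];
          }
          const double inv_n = 1.0 / n_train;
          double tr = 0.0, s2 = 0.0;
          for (uword c = 0; c < C; ++c)
            for (uword d = c; d < C; ++d) {
              const double v = S[c * C + d] * inv_n;
              S[c * C + d] = v; S[d * C + c] = v;
              s2 += (c == d) ? v * v : 2.0 * v * v;
              if (c == d) tr += v;
            }
          const double mu = tr / C;
          double lam;
          if (shrinkage >= 0.0) {
            lam = shrinkage;
          } else {
            const double d2 = s2 - C * mu * mu;
            double bbar = quart * inv_n * inv_n - s2 * inv_n;
            if (bbar < 0) bbar = 0;
            lam = (d2 > 0) ? std::min(1.0, bbar / d2) : 1.0;
          }
          const double ridge = lam * mu + 1e-12 * (mu > 0 ? mu : 1.0);
          for (uword c = 0; c < C; ++c) {
            for (uword d = 0; d < C; ++d) Sig[c * C + d] = (1.0 - lam) * S[c * C + d];
            Sig[c * C + c] += ridge;
          }
          for (uword c = 0; c < C; ++c) {
            diff[c] = m0[c] - m1[c];
            msum[c] = 0.5 * (m0[c] + m1[c]);
          }
          if (!chol_solve((int)C, Sig, diff.data(), w.data()))
            std::fill(w.begin(), w.end(), 0.0);
          double thr = 0.0;
          for (uword c = 0; c < C; ++c) thr += w[c] * msum[c];

          for (uword i = 0; i < np; ++i) {
            if (fv[i] != fold) continue;
            const double* xi = &xb[i * C];
            double score = -thr;
            for (uword c = 0; c < C; ++c) score += w[c] * xi[c];
            const int pred = (score >= 0.0) ? 0 : 1;  // tie -> first class
            if (pred == yv[i]) ++correct;
            ++total;
          }
        }
        if (total > 0) {
          const double a_t = (double)correct / total;
          acc(a, b, t) = a_t;
          acc(b, a, t) = a_t;
        }
      }
    }
  }
  return acc;
}
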