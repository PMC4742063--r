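// Compiled kernels for the CCP descriptor: batch extraction of
// rotation-invariant patches (bilinear inverse mapping) with their 2-D DCT,
// and the exhaustive search over coefficient comparisons (i, j, delta).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Bilinear sample of img at (row y, col x), 1-based continuous coordinates.
// Caller guarantees the 2x2 neighborhood is inside the image.
static inline double bilinear(const arma::mat& img, double y, double x) {
  int r0 = (int)std::floor(y), c0 = (int)std::floor(x);
  double fy = y - r0, fx = x - c0;
  if (r0 >= (int)img.n_rows) { r0 = img.n_rows - 1; fy = 1.0; }
  if (c0 >= (int)img.n_cols) { c0 = img.n_cols - 1; fx = 1.0; }
  const double* col0 = img.colptr(c0 - 1);
  const double* col1 = (fx > 0.0) ? img.colptr(c0) : col0;
  double v00 = col0[r0 - 1];
  double v10 = (fy > 0.0) ? col0[r0] : v00;
  double v01 = col1[r0 - 1];
  double v11 = (fy > 0.0) ? col1[r0] : v01;
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) +
         fy       * ((1 - fx) * v10 + fx * v11);
}

// For k centers (row, col) with per-center orientation theta (radians),
// sample the n x n patch whose x-axis is aligned with theta and return a
// k x n^2 matrix: row-major DCT coefficients D = C P C' (or the raw patch
// samples if raw = true and Dmat is the identity).
// [[Rcpp::export(name = "ccp_patch_coeffs")]]
arma::mat ccp_patch_coeffs(const arma::mat& img, const arma::mat& centers,
                           const arma::vec& theta, int n,
                           const arma::mat& Dmat, bool raw) {
  const int k = centers.n_rows;
  const double h = (n - 1) / 2.0;
  arma::mat out(k, n * n);
  arma::mat P(n, n), D(n, n);
  const double rad = h * std::sqrt(2.0) + 1.0;
  for (int t = 0; t < k; ++t) {
    const double r = centers(t, 0), c = centers(t, 1);
    if (r - rad < 1.0 || c - rad < 1.0 ||
        r + rad > (double)img.n_rows || c + rad > (double)img.n_cols)
      stop("patch footprint exits the image at center (%f, %f)", r, c);
    const double ct = std::cos(theta[t]), st = std::sin(theta[t]);
    for (int a = 0; a < n; ++a) {          // patch row: v (perpendicular)
      const double v = a - h;
      for (int b = 0; b < n; ++b) {        // patch col: u (along the ridge)
        const double u = b - h;
        const double x = c + u * ct - v * st;   // col offset
        const double y = r + u * st + v * ct;   // row offset (y down)
        P(a, b) = bilinear(img, y, x);
      }
    }
    if (raw) {
      for (int a = 0; a < n; ++a)
        for (int b = 0; b < n; ++b) out(t, a * n + b) = P(a, b);
    } else {
      D = Dmat * P * Dmat.t();
      for (int a = 0; a < n; ++a)
        for (int b = 0; b < n; ++b) out(t, a * n + b) = D(a, b);
    }
  }
  return out;
}

// Best delta on the grid from per-bin counts: cnt*[m] holds the number of
// patches whose event (c_i + delta) > c_j first becomes true at grid index
// m.  Ties over delta are broken toward |delta| closest to 0, then the
// smaller delta.
static inline void best_delta(const std::vector<double>& cnt1,
                              const std::vector<double>& cnt2,
                              double N1, double N2,
                              double lo, double step, int M,
                              double& bdelta, double& bscore) {
  double f1 = 0.0, f2 = 0.0, best = -1.0, bd = lo, babs = 1e300;
  for (int m = 0; m < M; ++m) {
    f1 += cnt1[m]; f2 += cnt2[m];
    const double score = std::fabs(f1 / N1 - f2 / N2);
    const double delta = lo + m * step;
    const double ad = std::fabs(delta);
    if (score > best + 1e-12 ||
        (score > best - 1e-12 &&
         (ad < babs - 1e-12 || (ad < babs + 1e-12 && delta < bd)))) {
      if (score > best) best = score;
      bd = delta; babs = ad;
    }
  }
  bdelta = bd; bscore = best;
}

// Exhaustive search over ordered coefficient pairs (i, j), i != j, both in
// `valid` (1-based indices), for the delta on the grid
// {lo, lo+step, ..., lo+(M-1)*step} maximizing
// | P_1[(c_i + delta) > c_j] - P_2[(c_i + delta) > c_j] |.
// C1, C2: normalized-coefficient matrices (patches x m) of the two classes.
// Both orders of each pair are scored in one pass (their difference vectors
// are exact negations).  Returns a (#pairs x 4) matrix: i, j, best delta,
// best score.
// [[Rcpp::export(name = "ccp_pair_search")]]
arma::mat ccp_pair_search(const arma::mat& C1, const arma::mat& C2,
                          const arma::ivec& valid,
                          double lo, double step, int M) {
  const int nv = valid.n_elem;
  const long npairs = (long)nv * (nv - 1);
  arma::mat out(npairs, 4);
  // cnt[0]/cnt[1]: order (i,j), classes 1/2; cnt[2]/cnt[3]: order (j,i)
  std::vector<double> cnt[4];
  for (int q = 0; q < 4; ++q) cnt[q].assign(M + 1, 0.0);
  const double N1 = C1.n_rows, N2 = C2.n_rows;
  const double inv = 1.0 / step;
  long row = 0;
  for (int ii = 0; ii < nv; ++ii) {
    const int i = valid[ii];
    const double* a1 = C1.colptr(i - 1);
    const double* a2 = C2.colptr(i - 1);
    for (int jj = ii + 1; jj < nv; ++jj) {
      const int j = valid[jj];
      const double* b1 = C1.colptr(j - 1);
      const double* b2 = C2.colptr(j - 1);
      for (int q = 0; q < 4; ++q)
        std::fill(cnt[q].begin(), cnt[q].end(), 0.0);
      // event (c_i + delta) > c_j  <=>  delta > w with w = c_j - c_i;
      // the first grid index where it holds is floor((w - lo)/step) + 1
      for (arma::uword t = 0; t < C1.n_rows; ++t) {
        const double w = b1[t] - a1[t];
        long m0 = (long)std::floor((w - lo) * inv) + 1;
        if (m0 < 0) m0 = 0; else if (m0 > M) m0 = M;
        cnt[0][m0] += 1.0;
        long m1 = (long)std::floor((-w - lo) * inv) + 1;
        if (m1 < 0) m1 = 0; else if (m1 > M) m1 = M;
        cnt[2][m1] += 1.0;
      }
      for (arma::uword t = 0; t < C2.n_rows; ++t) {
        const double w = b2[t] - a2[t];
        long m0 = (long)std::floor((w - lo) * inv) + 1;
        if (m0 < 0) m0 = 0; else if (m0 > M) m0 = M;
        cnt[1][m0] += 1.0;
        long m1 = (long)std::floor((-w - lo) * inv) + 1;
        if (m1 < 0) m1 = 0; else if (m1 > M) m1 = M;
        cnt[3][m1] += 1.0;
      }
      double bd, bs;
      best_delta(cnt[0], cnt[1], N1, N2, lo, step, M, bd, bs);
      out(row, 0) = i; out(row, 1) = j; out(row, 2) = bd; out(row, 3) = bs;
      ++row;
      best_delta(cnt[2], cnt[3], N1, N2, lo, step, M, bd, bs);
      out(row, 0) = j; out(row, 1) = i; out(row, 2) = bd; out(row, 3) = bs;
      ++row;
    }
  }
  return out.rows(0, row - 1);
}
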