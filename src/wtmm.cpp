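// Numerical kernels for the WTMM anisotropy pipeline.
//
// The continuous wavelet transform at one scale is a pair of
// cross-correlations of the image with sampled derivative-of-Gaussian
// kernels.  Both components are obtained from a single complex FFT
// product: the caller supplies conj(fft(k1)) + i*conj(fft(k2)) so that
// Re / Im of the inverse transform are the x / y gradient responses.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// [[Rcpp::export]]
arma::cx_mat fft_corr_pair(const arma::mat& f, const arma::cx_mat& kspec) {
  cx_mat F = fft2(conv_to<cx_mat>::from(f));
  return ifft2(F % kspec);
}

// [[Rcpp::export]]
arma::mat fft_amplitude(const arma::mat& f) {
  return abs(fft2(conv_to<cx_mat>::from(f)));
}

// Spatial convolution with edge-replication, for small degradation
// kernels (pillbox blur, motion blur).  Kernel dims must be odd.
// [[Rcpp::export]]
arma::mat conv2_replicate(const arma::mat& f, const arma::mat& k) {
  const int nr = f.n_rows, nc = f.n_cols;
  const int kr = k.n_rows, kc = k.n_cols;
  const int hr = kr / 2, hc = kc / 2;
  mat out(nr, nc, fill::zeros);
  for (int dj = -hc; dj <= hc; ++dj) {
    for (int di = -hr; di <= hr; ++di) {
      const double w = k(di + hr, dj + hc);
      if (w == 0.0) continue;
      for (int j = 0; j < nc; ++j) {
        int sj = j + dj;
        sj = sj < 0 ? 0 : (sj >= nc ? nc - 1 : sj);
        const double* col = f.colptr(sj);
        double* ocol = out.colptr(j);
        for (int i = 0; i < nr; ++i) {
          int si = i + di;
          si = si < 0 ? 0 : (si >= nr ? nr - 1 : si);
          ocol[i] += w * col[si];
        }
      }
    }
  }
  return out;
}

static inline double bilinear(const arma::mat& m, double r, double c) {
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double fr = r - r0, fc = c - c0;
  return (1 - fr) * (1 - fc) * m(r0, c0) + (1 - fr) * fc * m(r0, c0 + 1) +
         fr * (1 - fc) * m(r0 + 1, c0) + fr * fc * m(r0 + 1, c0 + 1);
}

// Directional local-maximum test: a pixel is a WTMM point when its
// modulus strictly exceeds the bilinearly interpolated modulus one
// pixel forward along the argument direction and is >= the value one
// pixel backward (strict/non-strict pair breaks plateau ties
// deterministically).  Returns 1-based linear indices (column-major).
// [[Rcpp::export]]
Rcpp::IntegerVector wtmm_points(const arma::mat& modulus,
                                const arma::mat& argument,
                                int border, double floor_value) {
  const int nr = modulus.n_rows, nc = modulus.n_cols;
  if (border < 2) border = 2;
  std::vector<int> keep;
  for (int c = border; c < nc - border; ++c) {
    for (int r = border; r < nr - border; ++r) {
      const double m = modulus(r, c);
      if (m <= floor_value) continue;
      const double a = argument(r, c);
      const double ux = std::cos(a), uy = std::sin(a);
      const double mf = bilinear(modulus, r + uy, c + ux);
      if (m <= mf) continue;
      const double mb = bilinear(modulus, r - uy, c - ux);
      if (m < mb) continue;
      keep.push_back(c * nr + r + 1);
    }
  }
  return Rcpp::IntegerVector(keep.begin(), keep.end());
}

// Max-composite anti-aliased rotated rectangles (simulated fibers)
// onto a zero canvas.  (cx, cy) are 1-based pixel-center coordinates
// (x = column, y = row); theta in radians measured from the +x axis;
// len/wid in pixels; value is the foreground intensity.  Edge pixels
// get fractional coverage so oblique fibers are free of staircase
// artifacts; overlapping fibers composite by maximum.
// [[Rcpp::export]]
arma::mat render_fibers(int nr, int nc, const arma::vec& cx,
                        const arma::vec& cy, const arma::vec& theta,
                        const arma::vec& len, const arma::vec& wid,
                        double value) {
  mat canvas(nr, nc, fill::zeros);
  for (uword k = 0; k < cx.n_elem; ++k) {
    const double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    const double hl = len[k] / 2.0, hw = wid[k] / 2.0;
    const double reach = std::fabs(hl * ct) + std::fabs(hw * st) + 2.0;
    const double reach_y = std::fabs(hl * st) + std::fabs(hw * ct) + 2.0;
    int c0 = std::max(0, (int)std::floor(cx[k] - reach) - 1);
    int c1 = std::min(nc - 1, (int)std::ceil(cx[k] + reach) - 1);
    int r0 = std::max(0, (int)std::floor(cy[k] - reach_y) - 1);
    int r1 = std::min(nr - 1, (int)std::ceil(cy[k] + reach_y) - 1);
    for (int c = c0; c <= c1; ++c) {
      const double dx = (c + 1) - cx[k];
      for (int r = r0; r <= r1; ++r) {
        const double dy = (r + 1) - cy[k];
        const double u = dx * ct + dy * st;   // along the fiber axis
        const double v = -dx * st + dy * ct;  // across the fiber
        double cu = 0.5 + hl - std::fabs(u);
        double cv = 0.5 + hw - std::fabs(v);
        cu = cu < 0 ? 0 : (cu > 1 ? 1 : cu);
        cv = cv < 0 ? 0 : (cv > 1 ? 1 : cv);
        const double val = value * cu * cv;
        if (val > canvas(r, c)) canvas(r, c) = val;
      }
    }
  }
  return canvas;
}
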