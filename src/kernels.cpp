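// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

// Whole-field block statistics on the detection-band spectrum.
//
// frames: T*H*W vector in (time, row, column) column-major order.
// Per complete block (row-fastest order): mean in-band power across the
// block's pixels, its peak (index into `bins`, 1-based; first maximum on
// ties = lowest frequency), and the median over the strictly-in-band bins
// flagged by `strict` (noise floor).
// [[Rcpp::export(name = ".cpp_block_band_stats")]]
List cpp_block_band_stats(const NumericVector& frames, int H, int W,
                          int block_size, const arma::vec& w, bool detrend,
                          const arma::uvec& bins, const arma::vec& coef,
                          const LogicalVector& strict) {
  const int T = static_cast<int>(w.n_elem);
  const arma::uword npix = static_cast<arma::uword>(H) * W;
  const arma::mat x(const_cast<double*>(frames.begin()),
                    static_cast<arma::uword>(T), npix, false, true);
  arma::mat xt = x;
  if (detrend) {
    arma::rowvec mu = arma::mean(xt, 0);
    xt.each_row() -= mu;
  }
  xt.each_col() %= w;
  // per-pixel tapered energy = total one-sided spectral power (Parseval)
  arma::rowvec en = arma::sum(arma::square(xt), 0);

  const arma::uword nb = bins.n_elem;
  arma::mat C(nb, T), S(nb, T);
  const double two_pi = 2.0 * M_PI;
  for (arma::uword i = 0; i < nb; ++i) {
    const double k = static_cast<double>(bins[i]);
    for (int t = 0; t < T; ++t) {
      const double a = two_pi * k * static_cast<double>(t) / static_cast<double>(T);
      C(i, t) = std::cos(a);
      S(i, t) = std::sin(a);
    }
  }
  arma::mat re = C * xt;
  arma::mat im = S * xt;
  arma::mat P = arma::square(re) + arma::square(im);   // nb x npix
  P.each_col() %= coef;

  const int n_rows = H / block_size;
  const int n_cols = W / block_size;
  const int n_blocks = n_rows * n_cols;
  const double inv_bp = 1.0 / (block_size * block_size);

  IntegerVector peak_idx(n_blocks);
  NumericVector peak_power(n_blocks), floor_power(n_blocks), energy(n_blocks);
  std::vector<arma::uword> sidx;
  for (arma::uword i = 0; i < nb; ++i) if (strict[i]) sidx.push_back(i);
  std::vector<double> bp(nb), sv(sidx.size() > 0 ? sidx.size() : nb);

  for (int bc = 0; bc < n_cols; ++bc) {
    for (int br = 0; br < n_rows; ++br) {
      std::fill(bp.begin(), bp.end(), 0.0);
      double be = 0.0;
      for (int cc = bc * block_size; cc < (bc + 1) * block_size; ++cc) {
        for (int rr = br * block_size; rr < (br + 1) * block_size; ++rr) {
          const arma::uword pix = static_cast<arma::uword>(rr) +
            static_cast<arma::uword>(H) * cc;
          const double* col = P.colptr(pix);
          for (arma::uword i = 0; i < nb; ++i) bp[i] += col[i];
          be += en[pix];
        }
      }
      for (arma::uword i = 0; i < nb; ++i) bp[i] *= inv_bp;
      const int b = br + n_rows * bc;
      energy[b] = be * inv_bp;
      arma::uword imax = 0;
      for (arma::uword i = 1; i < nb; ++i) if (bp[i] > bp[imax]) imax = i;
      peak_idx[b] = static_cast<int>(imax) + 1;
      peak_power[b] = bp[imax];
      if (!sidx.empty()) {
        sv.resize(sidx.size());
        for (size_t i = 0; i < sidx.size(); ++i) sv[i] = bp[sidx[i]];
      } else {
        sv.assign(bp.begin(), bp.end());
      }
      const size_t n = sv.size();
      std::nth_element(sv.begin(), sv.begin() + n / 2, sv.end());
      double med = sv[n / 2];
      if (n % 2 == 0) {
        const double lo = *std::max_element(sv.begin(), sv.begin() + n / 2);
        med = (med + lo) / 2.0;
      }
      floor_power[b] = med;
    }
  }
  return List::create(_["peak_idx"] = peak_idx, _["peak_power"] = peak_power,
                      _["noise_floor"] = floor_power, _["energy"] = energy);
}

// Render a synthetic beating-epithelium stack.
//
// Frames are returned as a flat vector in (time, row, column) column-major
// order, i.e. element index t + T*(r + H*c): each pixel's time series is
// contiguous. moving_idx holds 0-based pixel indices p = r + H*c; freq (Hz)
// and phase (rad) are per moving pixel. Gaussian camera noise
// ~ N(0, noise_sd^2) is drawn per pixel in index order then per frame from
// a mt19937 stream seeded with `seed` (single-precision draws: intensities
// are quantised to whole grey levels downstream), so output is fully
// reproducible. The deterministic beating term is evaluated in double
// precision. Intensities are clipped to [clip_lo, clip_hi] and optionally
// rounded to whole grey levels (camera quantisation).
// [[Rcpp::export(name = ".cpp_render_frames")]]
NumericVector cpp_render_frames(int H, int W, int Tn, double fps,
                                double baseline, double amplitude,
                                IntegerVector moving_idx,
                                NumericVector freq, NumericVector phase,
                                double noise_sd, double harmonic_weight,
                                double clip_lo, double clip_hi,
                                bool quantize, double seed) {
  const R_xlen_t npix = static_cast<R_xlen_t>(H) * W;
  NumericVector out(static_cast<R_xlen_t>(Tn) * npix);
  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::normal_distribution<float> nd(0.0f, 1.0f);

  std::vector<R_xlen_t> slot(npix, -1);
  for (R_xlen_t j = 0; j < moving_idx.size(); ++j) slot[moving_idx[j]] = j;

  const double two_pi = 2.0 * M_PI;
  const float fsd = static_cast<float>(noise_sd);
  for (R_xlen_t p = 0; p < npix; ++p) {
    double* col = &out[p * Tn];
    const R_xlen_t j = slot[p];
    if (j >= 0) {
      const double om = two_pi * freq[j] / fps;
      const double ph = phase[j];
      for (int t = 0; t < Tn; ++t) {
        const double a = om * t + ph;
        double v = baseline + amplitude * std::sin(a);
        if (harmonic_weight > 0.0) v += amplitude * harmonic_weight * std::sin(2.0 * a);
        if (fsd > 0.0f) v += fsd * nd(rng);
        if (v < clip_lo) v = clip_lo;
        if (v > clip_hi) v = clip_hi;
        col[t] = quantize ? std::floor(v + 0.5) : v;
      }
    } else if (fsd > 0.0f) {
      for (int t = 0; t < Tn; ++t) {
        double v = baseline + fsd * nd(rng);
        if (v < clip_lo) v = clip_lo;
        if (v > clip_hi) v = clip_hi;
        col[t] = quantize ? std::floor(v + 0.5) : v;
      }
    } else {
      const double v0 = std::min(std::max(baseline, clip_lo), clip_hi);
      const double v = quantize ? std::floor(v0 + 0.5) : v0;
      for (int t = 0; t < Tn; ++t) col[t] = v;
    }
  }
  out.attr("dim") = IntegerVector::create(Tn, H, W);
  return out;
}
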