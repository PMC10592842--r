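// Centre-anchored affine resampling (rotation + isotropic scale +
// translation + flips) used by the geometric augmentation. Inverse
// mapping; bilinear for images, nearest-neighbour for masks; zero fill.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::NumericVector warp_affine_cpp(Rcpp::NumericVector img, double dr,
                                    double dc, double theta, double scale,
                                    bool flip_h, bool flip_v,
                                    bool bilinear = true) {
  Rcpp::IntegerVector dim = img.attr("dim");
  const int H = dim[0], W = dim[1], C = dim.size() > 2 ? dim[2] : 1;
  Rcpp::NumericVector out((size_t)H * W * C);
  out.attr("dim") = dim;
  const double cr = (H + 1) / 2.0, cc = (W + 1) / 2.0;
  const double ct = std::cos(-theta), st = std::sin(-theta);
  const double* src = img.begin();
  double* dst = out.begin();
  const size_t plane = (size_t)H * W;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double rr = (i + 1) - cr, ccd = (j + 1) - cc;
      if (flip_h) ccd = -ccd;
      if (flip_v) rr = -rr;
      double r1 = rr - dr, c1 = ccd - dc;
      double r2 = (r1 * ct - c1 * st) / scale + cr;
      double c2 = (r1 * st + c1 * ct) / scale + cc;
      if (bilinear) {
        int r0 = (int)std::floor(r2), c0 = (int)std::floor(c2);
        double fr = r2 - r0, fc = c2 - c0;
        for (int ch = 0; ch < C; ++ch) {
          const double* p = src + ch * plane;
          auto gv = [&](int ri, int ci) -> double {
            if (ri < 1 || ri > H || ci < 1 || ci > W) return 0.0;
            return p[(size_t)(ci - 1) * H + (ri - 1)];
          };
          double v = (1 - fr) * (1 - fc) * gv(r0, c0) +
                     (1 - fr) * fc * gv(r0, c0 + 1) +
                     fr * (1 - fc) * gv(r0 + 1, c0) +
                     fr * fc * gv(r0 + 1, c0 + 1);
          dst[ch * plane + (size_t)j * H + i] = v;
        }
      } else {
        int ri = (int)std::lround(r2), ci = (int)std::lround(c2);
        bool ok = ri >= 1 && ri <= H && ci >= 1 && ci <= W;
        for (int ch = 0; ch < C; ++ch) {
          dst[ch * plane + (size_t)j * H + i] =
            ok ? src[ch * plane + (size_t)(ci - 1) * H + (ri - 1)] : 0.0;
        }
      }
    }
  }
  return out;
}
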