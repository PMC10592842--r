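// Compact CPU CNN engine for the multi-task fiber-bundle model:
// a U-Net segmentation backbone plus a classification/embedding arm read
// off the encoder bottleneck. Convolutions are im2col + BLAS gemm; manual
// backpropagation; Adam updates. Single-threaded, single precision
// (the R boundary converts to and from double).
//
// Layout conventions: a feature map is an arma::cube (H x W x C); a batch
// is std::vector<cube>. R passes batches as [H, W, C, N] arrays
// (column-major, matching arma).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// The engine computes in single precision: the conv gemms are memory-
// bandwidth-bound at these layer shapes, so float roughly doubles
// throughput on one CPU core. The R boundary stays double.
using real_t = float;
using mat = arma::Mat<real_t>;
using cube = arma::Cube<real_t>;
using vec = arma::Col<real_t>;
using rowvec = arma::Row<real_t>;
using arma::uword;
using arma::ivec;
using arma::ucube;
using arma::conv_to;
namespace fill = arma::fill;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

// ---------------------------------------------------------------------------
// Parameter with Adam state
// ---------------------------------------------------------------------------
struct Param {
  mat w, g, m, v;
  Param() {}
  explicit Param(int r, int c) : w(r, c, fill::zeros), g(r, c, fill::zeros),
                                 m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void zero_grad() { g.zeros(); }
  void adam(double lr, double b1, double b2, double eps, long t) {
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * square(g);
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
};

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3 same-padding convolution. The batched variants
// write into / read from one tall matrix holding all samples of the batch
// (rows n*HW .. (n+1)*HW - 1 belong to sample n), so each layer performs
// a single BLAS gemm per batch.
// ---------------------------------------------------------------------------
static void im2col3_into(const cube& x, mat& X, size_t row0) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    int k = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy, ++k) {
        real_t* dst = X.colptr(c * 9 + k) + row0;
        int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        if (r0 > 0 || c0 > 0 || r1 < H || c1 < W) {
          std::fill(dst, dst + (size_t)H * W, (real_t)0);
        }
        for (int cc = c0; cc < c1; ++cc) {
          const real_t* src = s.colptr(cc + dx) + (r0 + dy);
          std::copy(src, src + (r1 - r0), dst + (size_t)cc * H + r0);
        }
      }
    }
  }
}

static void col2im3_from(const mat& Xg, size_t row0, int H, int W, int C,
                         cube& dx) {
  dx.set_size(H, W, C);
  dx.zeros();
  for (int c = 0; c < C; ++c) {
    mat& s = dx.slice(c);
    int k = 0;
    for (int dx_ = -1; dx_ <= 1; ++dx_) {
      for (int dy = -1; dy <= 1; ++dy, ++k) {
        const real_t* src0 = Xg.colptr(c * 9 + k) + row0;
        int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        int c0 = std::max(0, -dx_), c1 = std::min(W, W - dx_);
        for (int cc = c0; cc < c1; ++cc) {
          real_t* dst = s.colptr(cc + dx_) + (r0 + dy);
          const real_t* src = src0 + (size_t)cc * H + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
    }
  }
}

// split a tall (N*HW x C) matrix back into per-sample H x W x C cubes
static void tall_to_batch(const mat& Y, int H, int W, int C, int N,
                          std::vector<cube>& y) {
  y.resize(N);
  const size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    y[n].set_size(H, W, C);
    for (int c = 0; c < C; ++c) {
      std::copy(Y.colptr(c) + n * hw, Y.colptr(c) + (n + 1) * hw,
                y[n].slice_memptr(c));
    }
  }
}

static void batch_to_tall(const std::vector<cube>& y, mat& Y) {
  const int N = y.size(), H = y[0].n_rows, W = y[0].n_cols,
            C = y[0].n_slices;
  const size_t hw = (size_t)H * W;
  Y.set_size(hw * N, C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      std::copy(y[n].slice_memptr(c), y[n].slice_memptr(c) + hw,
                Y.colptr(c) + n * hw);
    }
  }
}

// ---------------------------------------------------------------------------
// Layers
// ---------------------------------------------------------------------------
struct Conv3 {           // 3x3, stride 1, same padding
  int cin, cout;
  Param W;               // (9*cin) x cout
  Param b;               // 1 x cout
  std::vector<mat> Xc;   // cached per-sample im2col (HW x 9*cin)
  void init(int ci, int co, std::mt19937_64& rng) {
    cin = ci; cout = co;
    W = Param(9 * ci, co); b = Param(1, co);
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / (9.0 * ci)));
    for (uword i = 0; i < W.w.n_elem; ++i) W.w(i) = nd(rng);
  }
  void forward(const std::vector<cube>& x, std::vector<cube>& y, bool cache) {
    const int N = x.size(), H = x[0].n_rows, Wd = x[0].n_cols;
    const size_t hw = (size_t)H * Wd;
    y.resize(N);
    if (cache) Xc.resize(N);
    mat Xtmp;
    for (int n = 0; n < N; ++n) {
      mat& X = cache ? Xc[n] : Xtmp;
      X.set_size(hw, 9 * cin);
      im2col3_into(x[n], X, 0);
      mat Y = X * W.w;
      Y.each_row() += b.w;
      y[n] = cube(Y.memptr(), H, Wd, cout);
    }
  }
  void backward(const std::vector<cube>& dy, std::vector<cube>& dx,
                int H, int Wd) {
    const int N = dy.size();
    const size_t hw = (size_t)H * Wd;
    dx.resize(N);
    for (int n = 0; n < N; ++n) {
      mat dYf(const_cast<real_t*>(dy[n].memptr()), hw, cout, false, true);
      W.g += Xc[n].t() * dYf;
      b.g += sum(dYf, 0);
      mat dXc = dYf * W.w.t();
      col2im3_from(dXc, 0, H, Wd, cin, dx[n]);
    }
  }
};

struct Conv1 {           // 1x1 convolution (pixelwise linear)
  int cin, cout;
  Param W, b;            // cin x cout, 1 x cout
  std::vector<mat> Xc;
  void init(int ci, int co, std::mt19937_64& rng) {
    cin = ci; cout = co;
    W = Param(ci, co); b = Param(1, co);
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / ci));
    for (uword i = 0; i < W.w.n_elem; ++i) W.w(i) = nd(rng);
  }
  void forward(const std::vector<cube>& x, std::vector<cube>& y, bool cache) {
    const int N = x.size(), H = x[0].n_rows, Wd = x[0].n_cols;
    const size_t hw = (size_t)H * Wd;
    y.resize(N);
    if (cache) Xc.resize(N);
    for (int n = 0; n < N; ++n) {
      mat X(const_cast<real_t*>(x[n].memptr()), hw, cin, false, true);
      if (cache) Xc[n] = X;
      mat Y = X * W.w;
      Y.each_row() += b.w;
      y[n] = cube(Y.memptr(), H, Wd, cout);
    }
  }
  void backward(const std::vector<cube>& dy, std::vector<cube>& dx,
                int H, int Wd) {
    const int N = dy.size();
    const size_t hw = (size_t)H * Wd;
    dx.resize(N);
    for (int n = 0; n < N; ++n) {
      mat dYf(const_cast<real_t*>(dy[n].memptr()), hw, cout, false, true);
      W.g += Xc[n].t() * dYf;
      b.g += sum(dYf, 0);
      mat dX = dYf * W.w.t();
      dx[n] = cube(dX.memptr(), H, Wd, cin);
    }
  }
};

struct BatchNorm {       // per-channel over batch + spatial
  int C;
  Param gamma, beta;
  rowvec run_mean, run_var;
  std::vector<cube> xhat;
  rowvec invstd;
  void init(int c) {
    C = c;
    gamma = Param(1, c); gamma.w.ones();
    beta = Param(1, c);
    run_mean = rowvec(c, fill::zeros);
    run_var = rowvec(c, fill::ones);
  }
  void forward(std::vector<cube>& x, bool train) {
    size_t N = x.size();
    if (train) {
      rowvec mu(C, fill::zeros), var(C, fill::zeros);
      double cnt = 0;
      for (size_t n = 0; n < N; ++n) {
        cnt += x[n].n_rows * x[n].n_cols;
        for (int c = 0; c < C; ++c) mu(c) += accu(x[n].slice(c));
      }
      mu /= cnt;
      for (size_t n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c)
          var(c) += accu(square(x[n].slice(c) - mu(c)));
      var /= cnt;
      invstd = 1.0 / sqrt(var + BN_EPS);
      xhat.resize(N);
      for (size_t n = 0; n < N; ++n) {
        xhat[n].set_size(size(x[n]));
        for (int c = 0; c < C; ++c) {
          xhat[n].slice(c) = (x[n].slice(c) - mu(c)) * invstd(c);
          x[n].slice(c) = gamma.w(c) * xhat[n].slice(c) + beta.w(c);
        }
      }
      run_mean = (1.0 - BN_MOMENTUM) * run_mean + BN_MOMENTUM * mu;
      run_var  = (1.0 - BN_MOMENTUM) * run_var  + BN_MOMENTUM * var;
    } else {
      rowvec is = 1.0 / sqrt(run_var + BN_EPS);
      for (size_t n = 0; n < N; ++n)
        for (int c = 0; c < C; ++c)
          x[n].slice(c) =
            gamma.w(c) * (x[n].slice(c) - run_mean(c)) * is(c) + beta.w(c);
    }
  }
  void backward(std::vector<cube>& dy) {   // in-place: dy -> dx
    size_t N = dy.size();
    double cnt = 0;
    rowvec sum_dy(C, fill::zeros), sum_dy_xhat(C, fill::zeros);
    for (size_t n = 0; n < N; ++n) {
      cnt += dy[n].n_rows * dy[n].n_cols;
      for (int c = 0; c < C; ++c) {
        sum_dy(c) += accu(dy[n].slice(c));
        sum_dy_xhat(c) += accu(dy[n].slice(c) % xhat[n].slice(c));
      }
    }
    gamma.g += sum_dy_xhat;
    beta.g += sum_dy;
    for (size_t n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c)
        dy[n].slice(c) = gamma.w(c) * invstd(c) *
          (dy[n].slice(c) - sum_dy(c) / cnt -
           xhat[n].slice(c) * (sum_dy_xhat(c) / cnt));
  }
};

struct ReLU {
  std::vector<cube> mask;
  void forward(std::vector<cube>& x, bool cache) {
    size_t N = x.size();
    if (cache) mask.resize(N);
    for (size_t n = 0; n < N; ++n) {
      if (cache) mask[n].set_size(size(x[n]));
      real_t* p = x[n].memptr();
      real_t* m = cache ? mask[n].memptr() : nullptr;
      const uword ne = x[n].n_elem;
      for (uword i = 0; i < ne; ++i) {
        bool pos = p[i] > 0;
        if (m) m[i] = pos ? (real_t)1 : (real_t)0;
        if (!pos) p[i] = (real_t)0;
      }
    }
  }
  void backward(std::vector<cube>& dy) {
    for (size_t n = 0; n < dy.size(); ++n) dy[n] %= mask[n];
  }
};

struct MaxPool2 {
  std::vector<ucube> idx;    // 0..3 winner within 2x2 block
  void forward(const std::vector<cube>& x, std::vector<cube>& y, bool cache) {
    size_t N = x.size();
    y.resize(N);
    if (cache) idx.resize(N);
    for (size_t n = 0; n < N; ++n) {
      const int H = x[n].n_rows, W = x[n].n_cols, C = x[n].n_slices;
      y[n].set_size(H / 2, W / 2, C);
      if (cache) idx[n].set_size(H / 2, W / 2, C);
      for (int c = 0; c < C; ++c) {
        const real_t* s = x[n].slice_memptr(c);
        real_t* yo = y[n].slice_memptr(c);
        uword* ix = cache ? idx[n].slice_memptr(c) : nullptr;
        const int h2 = H / 2, w2 = W / 2;
        for (int j = 0; j < w2; ++j) {
          const real_t* c0 = s + (2 * j) * H;
          const real_t* c1 = s + (2 * j + 1) * H;
          for (int i = 0; i < h2; ++i) {
            real_t v00 = c0[2 * i], v10 = c0[2 * i + 1];
            real_t v01 = c1[2 * i], v11 = c1[2 * i + 1];
            real_t best = v00; unsigned k = 0;
            if (v10 > best) { best = v10; k = 1; }
            if (v01 > best) { best = v01; k = 2; }
            if (v11 > best) { best = v11; k = 3; }
            yo[j * h2 + i] = best;
            if (ix) ix[j * h2 + i] = k;
          }
        }
      }
    }
  }
  void backward(const std::vector<cube>& dy, std::vector<cube>& dx) {
    size_t N = dy.size();
    dx.resize(N);
    for (size_t n = 0; n < N; ++n) {
      const int h = dy[n].n_rows, w = dy[n].n_cols, C = dy[n].n_slices;
      dx[n].zeros(2 * h, 2 * w, C);
      for (int c = 0; c < C; ++c)
        for (int j = 0; j < w; ++j)
          for (int i = 0; i < h; ++i) {
            unsigned k = idx[n](i, j, c);
            dx[n](2 * i + (k & 1u), 2 * j + (k >> 1), c) = dy[n](i, j, c);
          }
    }
  }
};

static void upsample2(const std::vector<cube>& x, std::vector<cube>& y) {
  size_t N = x.size();
  y.resize(N);
  for (size_t n = 0; n < N; ++n) {
    const int H = x[n].n_rows, W = x[n].n_cols, C = x[n].n_slices;
    y[n].set_size(2 * H, 2 * W, C);
    for (int c = 0; c < C; ++c) {
      const real_t* s = x[n].slice_memptr(c);
      real_t* d = y[n].slice_memptr(c);
      const int H2 = 2 * H;
      for (int j = 0; j < W; ++j) {
        real_t* d0 = d + (2 * j) * H2;
        real_t* d1 = d + (2 * j + 1) * H2;
        for (int i = 0; i < H; ++i) {
          real_t v = s[j * H + i];
          d0[2 * i] = v; d0[2 * i + 1] = v;
          d1[2 * i] = v; d1[2 * i + 1] = v;
        }
      }
    }
  }
}

static void upsample2_backward(const std::vector<cube>& dy,
                               std::vector<cube>& dx) {
  size_t N = dy.size();
  dx.resize(N);
  for (size_t n = 0; n < N; ++n) {
    const int H = dy[n].n_rows / 2, W = dy[n].n_cols / 2, C = dy[n].n_slices;
    dx[n].set_size(H, W, C);
    for (int c = 0; c < C; ++c) {
      const real_t* s = dy[n].slice_memptr(c);
      real_t* d = dx[n].slice_memptr(c);
      const int H2 = 2 * H;
      for (int j = 0; j < W; ++j) {
        const real_t* s0 = s + (2 * j) * H2;
        const real_t* s1 = s + (2 * j + 1) * H2;
        for (int i = 0; i < H; ++i)
          d[j * H + i] = s0[2 * i] + s0[2 * i + 1] +
                         s1[2 * i] + s1[2 * i + 1];
      }
    }
  }
}

struct Dense {
  int din, dout;
  Param W, b;            // din x dout, 1 x dout
  mat Xc;                // N x din cache
  void init(int di, int dn, std::mt19937_64& rng) {
    din = di; dout = dn;
    W = Param(di, dn); b = Param(1, dn);
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / di));
    for (uword i = 0; i < W.w.n_elem; ++i) W.w(i) = nd(rng);
  }
  mat forward(const mat& x, bool cache) {   // x: N x din
    if (cache) Xc = x;
    mat y = x * W.w;
    y.each_row() += b.w;
    return y;
  }
  mat backward(const mat& dy) {
    W.g += Xc.t() * dy;
    b.g += sum(dy, 0);
    return dy * W.w.t();
  }
};

// ---------------------------------------------------------------------------
// Conv block: conv-bn-relu x2
// ---------------------------------------------------------------------------
struct ConvBlock {
  Conv3 c1, c2;
  BatchNorm b1, b2;
  ReLU r1, r2;
  int H_in = 0, W_in = 0;
  void init(int cin, int cout, std::mt19937_64& rng) {
    c1.init(cin, cout, rng); c2.init(cout, cout, rng);
    b1.init(cout); b2.init(cout);
  }
  void forward(const std::vector<cube>& x, std::vector<cube>& y,
               bool train, bool cache) {
    H_in = x[0].n_rows; W_in = x[0].n_cols;
    c1.forward(x, y, cache);
    b1.forward(y, train);
    r1.forward(y, cache);
    std::vector<cube> t;
    c2.forward(y, t, cache);
    b2.forward(t, train);
    r2.forward(t, cache);
    y = std::move(t);
  }
  void backward(std::vector<cube>& dy, std::vector<cube>& dx) {
    r2.backward(dy);
    b2.backward(dy);
    std::vector<cube> d1;
    c2.backward(dy, d1, H_in, W_in);
    r1.backward(d1);
    b1.backward(d1);
    c1.backward(d1, dx, H_in, W_in);
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&c1.W); ps.push_back(&c1.b);
    ps.push_back(&b1.gamma); ps.push_back(&b1.beta);
    ps.push_back(&c2.W); ps.push_back(&c2.b);
    ps.push_back(&b2.gamma); ps.push_back(&b2.beta);
  }
};

// ---------------------------------------------------------------------------
// The multi-task network
// ---------------------------------------------------------------------------
struct Net {
  // config
  int depth, base, in_ch, seg_classes, patch, fc1_sz, fc2_sz, class_out;
  long adam_t = 0;
  int epoch = 0;

  std::vector<ConvBlock> enc;      // depth blocks (last = bottleneck)
  std::vector<MaxPool2> pool;      // depth-1
  std::vector<ConvBlock> dec;      // depth-1 blocks
  Conv1 head;                      // 1x1 -> seg_classes

  // classification arm off the bottleneck: (pool + convblock) x2, fc x3
  MaxPool2 cpool1, cpool2;
  ConvBlock cblk1, cblk2;
  Dense fc1, fc2, fc3;
  ReLU fcr;                        // relu after fc1 (on flattened, use mat)
  mat fcr_mask;

  // caches for backward
  std::vector<std::vector<cube>> enc_out;   // encoder outputs per level
  std::vector<std::vector<cube>> dec_in;    // concat inputs per dec level
  std::vector<cube> bottleneck;             // shared cache for class arm
  int seg_H = 0, seg_W = 0;

  std::vector<Param*> params;

  int ch(int level) const { return base << (level - 1); }   // level 1..depth

  void build(int depth_, int base_, int in_ch_, int seg_classes_,
             int patch_, int fc1_, int fc2_, int class_out_,
             unsigned long seed) {
    depth = depth_; base = base_; in_ch = in_ch_; seg_classes = seg_classes_;
    patch = patch_; fc1_sz = fc1_; fc2_sz = fc2_; class_out = class_out_;
    std::mt19937_64 rng(seed);
    enc.resize(depth); pool.resize(depth - 1); dec.resize(depth - 1);
    for (int l = 1; l <= depth; ++l)
      enc[l - 1].init(l == 1 ? in_ch : ch(l - 1), ch(l), rng);
    for (int l = depth - 1; l >= 1; --l)
      dec[l - 1].init(ch(l) + ch(l + 1), ch(l), rng);
    head.init(ch(1), seg_classes, rng);
    int cb = ch(depth);
    cblk1.init(cb, cb, rng);
    cblk2.init(cb, cb, rng);
    int bspat = patch >> (depth - 1);          // bottleneck spatial size
    if (bspat % 4 != 0)
      Rcpp::stop("patch size not divisible by 2^(depth+1)");
    int flat = (bspat / 4) * (bspat / 4) * cb;
    fc1.init(flat, fc1_sz, rng);
    fc2.init(fc1_sz, fc2_sz, rng);
    fc3.init(fc2_sz, class_out, rng);
    params.clear();
    for (auto& b : enc) b.collect(params);
    for (auto& b : dec) b.collect(params);
    params.push_back(&head.W); params.push_back(&head.b);
    cblk1.collect(params); cblk2.collect(params);
    for (Dense* d : {&fc1, &fc2, &fc3}) {
      params.push_back(&d->W); params.push_back(&d->b);
    }
  }

  // ---- encoder shared by both arms --------------------------------------
  void encode(const std::vector<cube>& x, bool train, bool cache) {
    enc_out.assign(depth, {});
    std::vector<cube> cur = x;
    for (int l = 1; l <= depth; ++l) {
      enc[l - 1].forward(cur, enc_out[l - 1], train, cache);
      if (l < depth) pool[l - 1].forward(enc_out[l - 1], cur, cache);
    }
    bottleneck = enc_out[depth - 1];
  }

  // ---- segmentation forward: returns softmax probabilities ---------------
  void forward_seg(const std::vector<cube>& x, std::vector<cube>& probs,
                   bool train, bool cache) {
    seg_H = x[0].n_rows; seg_W = x[0].n_cols;
    encode(x, train, cache);
    dec_in.assign(depth - 1, {});
    std::vector<cube> cur = bottleneck;
    for (int l = depth - 1; l >= 1; --l) {
      std::vector<cube> up;
      upsample2(cur, up);
      size_t N = up.size();
      std::vector<cube>& cat = dec_in[l - 1];
      cat.resize(N);
      for (size_t n = 0; n < N; ++n)
        cat[n] = join_slices(up[n], enc_out[l - 1][n]);
      dec[l - 1].forward(cat, cur, train, cache);
    }
    std::vector<cube> logits;
    head.forward(cur, logits, cache);
    size_t N = logits.size();
    probs.resize(N);
    for (size_t n = 0; n < N; ++n) {
      // stable 2-class (or k-class) softmax over slices
      cube& z = logits[n];
      cube mx = max(z, 2);
      probs[n].set_size(size(z));
      for (int c = 0; c < (int)z.n_slices; ++c)
        probs[n].slice(c) = exp(z.slice(c) - mx.slice(0));
      cube denom = sum(probs[n], 2);
      for (int c = 0; c < (int)z.n_slices; ++c)
        probs[n].slice(c) /= denom.slice(0);
    }
  }

  // dlogits: gradient of loss wrt pre-softmax seg logits.
  // Runs decoder + encoder backward, accumulating parameter gradients.
  // extra_dbottleneck (may be empty) is added at the bottleneck (class arm).
  void backward_seg(std::vector<cube>& dlogits,
                    std::vector<cube>* extra_dbottleneck) {
    size_t N = dlogits.size();
    std::vector<cube> d;
    head.backward(dlogits, d, seg_H, seg_W);
    // decoder levels 1..depth-1 were applied in order l = depth-1 .. 1;
    // reverse: l = 1 .. depth-1
    std::vector<std::vector<cube>> dskip(depth, std::vector<cube>());
    for (int l = 1; l <= depth - 1; ++l) {
      std::vector<cube> dcat;
      dec[l - 1].backward(d, dcat);
      int cup = ch(l + 1), cskip = ch(l);
      std::vector<cube> dup(N);
      dskip[l - 1].resize(N);
      for (size_t n = 0; n < N; ++n) {
        dup[n] = dcat[n].slices(0, cup - 1);
        dskip[l - 1][n] = dcat[n].slices(cup, cup + cskip - 1);
      }
      upsample2_backward(dup, d);
    }
    // d now holds gradient wrt bottleneck output
    if (extra_dbottleneck && !extra_dbottleneck->empty()) {
      if (d.empty()) d = *extra_dbottleneck;
      else for (size_t n = 0; n < N; ++n) d[n] += (*extra_dbottleneck)[n];
    }
    // encoder backward: levels depth .. 1
    for (int l = depth; l >= 1; --l) {
      if (l < depth) {
        std::vector<cube> dpre;
        pool[l - 1].backward(d, dpre);
        d = std::move(dpre);
        for (size_t n = 0; n < N; ++n) d[n] += dskip[l - 1][n];
      }
      std::vector<cube> dx;
      enc[l - 1].backward(d, dx);
      d = std::move(dx);
    }
  }

  // class-arm only backward (no seg path): gradient enters at bottleneck
  void backward_class_only(std::vector<cube>& dbottleneck) {
    size_t N = dbottleneck.size();
    std::vector<cube> d = dbottleneck;
    for (int l = depth; l >= 1; --l) {
      if (l < depth) {
        std::vector<cube> dpre;
        pool[l - 1].backward(d, dpre);
        d = std::move(dpre);
      }
      std::vector<cube> dx;
      enc[l - 1].backward(d, dx);
      d = std::move(dx);
    }
  }

  // ---- classification arm -------------------------------------------------
  // returns (logits N x class_out, embedding N x fc2_sz)
  void forward_class(const std::vector<cube>& x, mat& logits, mat& emb,
                     bool train, bool cache) {
    encode(x, train, cache);
    std::vector<cube> t, t2;
    cpool1.forward(bottleneck, t, cache);
    cblk1.forward(t, t2, train, cache);
    cpool2.forward(t2, t, cache);
    std::vector<cube> feat;
    cblk2.forward(t, feat, train, cache);
    size_t N = feat.size();
    mat flat(N, feat[0].n_elem);
    for (size_t n = 0; n < N; ++n)
      flat.row(n) = vectorise(feat[n]).t();
    mat h1 = fc1.forward(flat, cache);
    fcr_mask = conv_to<mat>::from(h1 > 0);
    h1 %= fcr_mask;
    emb = fc2.forward(h1, cache);
    logits = fc3.forward(emb, cache);
  }

  // demb: N x fc2_sz, dlogits: N x class_out (either may be zero-filled).
  // Produces gradient at bottleneck and runs encoder backward.
  void backward_class(const mat& demb, const mat& dlogits) {
    mat d2 = fc3.backward(dlogits) + demb;      // grad at embedding
    mat d1 = fc2.backward(d2);
    d1 %= fcr_mask;
    mat dflat = fc1.backward(d1);
    size_t N = dflat.n_rows;
    int cb = ch(depth);
    int s = (patch >> (depth - 1)) / 4;
    std::vector<cube> dfeat(N);
    for (size_t n = 0; n < N; ++n) {
      vec v = dflat.row(n).t();
      dfeat[n] = cube(v.memptr(), s, s, cb);
    }
    std::vector<cube> d, d0;
    cblk2.backward(dfeat, d);
    cpool2.backward(d, d0);
    cblk1.backward(d0, d);
    std::vector<cube> dbn;
    cpool1.backward(d, dbn);
    backward_class_only(dbn);
  }

  void zero_grad() { for (Param* p : params) p->zero_grad(); }
  void step(double lr) {
    ++adam_t;
    for (Param* p : params) p->adam(lr, 0.9, 0.999, 1e-8, adam_t);
  }
  long n_params() const {
    long n = 0;
    for (const Param* p : params) n += p->w.n_elem;
    return n;
  }
};

// ---------------------------------------------------------------------------
// Losses (training-side, with gradients)
// ---------------------------------------------------------------------------
static const real_t P_EPS = (real_t)1e-7f;

// focal loss + gradient wrt seg logits; probs = softmax output (cached),
// targets in {0,1}. Mean over all pixels of all samples.
static double focal_loss_grad(const std::vector<cube>& probs,
                              const std::vector<mat>& targets,
                              double alpha, double gamma, bool alpha_weight,
                              std::vector<cube>* dlogits) {
  size_t N = probs.size();
  double total = 0, cnt = 0;
  if (dlogits) dlogits->resize(N);
  for (size_t n = 0; n < N; ++n) cnt += probs[n].n_rows * probs[n].n_cols;
  for (size_t n = 0; n < N; ++n) {
    const mat& p1 = probs[n].slice(1);           // fiber-class probability
    const mat& y = targets[n];
    mat pt = y % p1 + ((real_t)1 - y) % ((real_t)1 - p1);
    pt = clamp(pt, P_EPS, (real_t)1 - P_EPS);
    mat at(size(y), fill::ones);
    if (alpha_weight) at = (real_t)alpha * y + (real_t)(1.0 - alpha) * ((real_t)1 - y);
    mat lp = log(pt);
    mat w = pow((real_t)1 - pt, (real_t)gamma);
    total += (double)accu(-at % w % lp);
    if (dlogits) {
      // dL/dpt
      mat dpt;
      if (gamma == 0.0) dpt = -at / pt;
      else dpt = at % ((real_t)gamma * pow((real_t)1 - pt, (real_t)(gamma - 1.0)) % lp - w / pt);
      mat sgn = (real_t)2 * y - (real_t)1;       // dpt/dp1
      mat dp1 = dpt % sgn;
      mat dz1 = dp1 % p1 % ((real_t)1 - p1) / (real_t)cnt;  // softmax chain
      (*dlogits)[n].set_size(p1.n_rows, p1.n_cols, 2);
      (*dlogits)[n].slice(1) = dz1;
      (*dlogits)[n].slice(0) = -dz1;
    }
  }
  return total / cnt;
}

// NT-Xent: embeddings F (2N x d), positive pairs (2i, 2i+1).
// loss = mean over 2N ordered pairs of -log softmax; gradient wrt F.
// Templated so the training path runs in float while the standalone
// oracle exposed to R evaluates in double.
template <typename T>
static double ntxent_grad_t(const arma::Mat<T>& F, double tau,
                            arma::Mat<T>* dF) {
  const int M = F.n_rows;                        // 2N
  if (M < 4 || M % 2 != 0) Rcpp::stop("contrastive batch needs 2N >= 4");
  arma::Col<T> nrm(M);
  for (int i = 0; i < M; ++i) {
    nrm(i) = norm(F.row(i), 2);
    if (nrm(i) < 1e-12) Rcpp::stop("zero-norm embedding in contrastive batch");
  }
  arma::Mat<T> U = F;
  U.each_col() /= nrm;
  arma::Mat<T> S = U * U.t();                    // cosine similarities
  double loss = 0;
  arma::Mat<T> dS(M, M, fill::zeros);
  for (int i = 0; i < M; ++i) {
    int j = (i % 2 == 0) ? i + 1 : i - 1;        // positive partner
    // softmax over k != i of S(i,k)/tau
    arma::Row<T> s = S.row(i) / (T)tau;
    s(i) = -std::numeric_limits<T>::infinity();
    T mx = s.max();
    arma::Row<T> e = exp(s - mx);
    e(i) = 0;
    T Z = accu(e);
    loss += -(double)(s(j) - mx - std::log(Z));
    if (dF) {
      arma::Row<T> p = e / Z;
      p(j) -= (T)1;
      dS.row(i) += p / (T)tau / (T)M;
    }
  }
  loss /= M;
  if (dF) {
    // dL/dU: S = U U^T, with dS rows only (asymmetric use)
    arma::Mat<T> dU = (dS + dS.t()) * U;
    // back through normalization u = f/||f||
    dF->set_size(M, F.n_cols);
    for (int i = 0; i < M; ++i) {
      arma::Row<T> u = U.row(i);
      arma::Row<T> g = dU.row(i);
      dF->row(i) = (g - dot(g, u) * u) / nrm(i);
    }
  }
  return loss;
}

static double ntxent_grad(const mat& F, double tau, mat* dF) {
  return ntxent_grad_t<real_t>(F, tau, dF);
}

// softmax cross-entropy on class logits (N x K), labels 0-based ints
static double ce_class_grad(const mat& logits, const ivec& labels, mat* dZ) {
  int N = logits.n_rows, K = logits.n_cols;
  double loss = 0;
  if (dZ) dZ->set_size(N, K);
  for (int n = 0; n < N; ++n) {
    rowvec z = logits.row(n);
    real_t mx = z.max();
    rowvec e = exp(z - mx);
    real_t Z = accu(e);
    rowvec p = e / Z;
    loss += -(double)(z(labels(n)) - mx - std::log(Z));
    if (dZ) {
      rowvec g = p;
      g(labels(n)) -= (real_t)1;
      dZ->row(n) = g / (real_t)N;
    }
  }
  return loss / N;
}

// ---------------------------------------------------------------------------
// R interface helpers
// ---------------------------------------------------------------------------
static std::vector<cube> batch_from_r(const Rcpp::NumericVector& arr) {
  Rcpp::IntegerVector dim = arr.attr("dim");
  if (dim.size() != 4) Rcpp::stop("batch must be a 4-d array [H,W,C,N]");
  int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  std::vector<cube> out(N);
  const double* p = arr.begin();
  size_t stride = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    out[n].set_size(H, W, C);
    real_t* q = out[n].memptr();
    const double* src = p + n * stride;
    for (size_t i = 0; i < stride; ++i) q[i] = (real_t)src[i];
  }
  return out;
}

static Rcpp::NumericVector batch_to_r(const std::vector<cube>& b) {
  int N = b.size();
  int H = b[0].n_rows, W = b[0].n_cols, C = b[0].n_slices;
  Rcpp::NumericVector out((size_t)H * W * C * N);
  size_t stride = (size_t)H * W * C;
  for (int n = 0; n < N; ++n) {
    const real_t* q = b[n].memptr();
    double* dst = out.begin() + n * stride;
    for (size_t i = 0; i < stride; ++i) dst[i] = (double)q[i];
  }
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C, N);
  return out;
}

static std::vector<mat> targets_from_r(const Rcpp::NumericVector& arr) {
  Rcpp::IntegerVector dim = arr.attr("dim");
  if (dim.size() != 3) Rcpp::stop("targets must be [H,W,N]");
  int H = dim[0], W = dim[1], N = dim[2];
  std::vector<mat> out(N);
  const double* p = arr.begin();
  size_t hw = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    out[n].set_size(H, W);
    real_t* q = out[n].memptr();
    const double* src = p + n * hw;
    for (size_t i = 0; i < hw; ++i) q[i] = (real_t)src[i];
  }
  return out;
}

// [[Rcpp::export]]
SEXP net_create(int depth, int base_channels, int in_channels,
                int seg_classes, int patch_size, int fc1, int fc2,
                int class_out, int seed) {
  Net* net = new Net();
  net->build(depth, base_channels, in_channels, seg_classes, patch_size,
             fc1, fc2, class_out, (unsigned long)seed);
  Rcpp::XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
long net_n_params(SEXP net_) {
  Rcpp::XPtr<Net> net(net_);
  return net->n_params();
}

// [[Rcpp::export]]
Rcpp::NumericVector net_get_params(SEXP net_) {
  Rcpp::XPtr<Net> net(net_);
  long n = net->n_params();
  Rcpp::NumericVector out(n);
  long k = 0;
  for (Param* p : net->params) {
    for (uword i = 0; i < p->w.n_elem; ++i) out[k + i] = (double)p->w(i);
    k += p->w.n_elem;
  }
  return out;
}

// [[Rcpp::export]]
void net_set_params(SEXP net_, Rcpp::NumericVector v) {
  Rcpp::XPtr<Net> net(net_);
  if ((long)v.size() != net->n_params()) Rcpp::stop("parameter length mismatch");
  long k = 0;
  for (Param* p : net->params) {
    for (uword i = 0; i < p->w.n_elem; ++i) p->w(i) = (real_t)v[k + i];
    k += p->w.n_elem;
  }
}

// running batch-norm statistics (needed for faithful checkpointing)
// [[Rcpp::export]]
Rcpp::NumericVector net_get_bn_stats(SEXP net_) {
  Rcpp::XPtr<Net> net(net_);
  std::vector<double> out;
  auto push = [&](BatchNorm& b) {
    for (int c = 0; c < b.C; ++c) out.push_back(b.run_mean(c));
    for (int c = 0; c < b.C; ++c) out.push_back(b.run_var(c));
  };
  for (auto& blk : net->enc) { push(blk.b1); push(blk.b2); }
  for (auto& blk : net->dec) { push(blk.b1); push(blk.b2); }
  push(net->cblk1.b1); push(net->cblk1.b2);
  push(net->cblk2.b1); push(net->cblk2.b2);
  return Rcpp::wrap(out);
}

// [[Rcpp::export]]
void net_set_bn_stats(SEXP net_, Rcpp::NumericVector v) {
  Rcpp::XPtr<Net> net(net_);
  long k = 0;
  auto pull = [&](BatchNorm& b) {
    for (int c = 0; c < b.C; ++c) b.run_mean(c) = v[k++];
    for (int c = 0; c < b.C; ++c) b.run_var(c) = v[k++];
  };
  for (auto& blk : net->enc) { pull(blk.b1); pull(blk.b2); }
  for (auto& blk : net->dec) { pull(blk.b1); pull(blk.b2); }
  pull(net->cblk1.b1); pull(net->cblk1.b2);
  pull(net->cblk2.b1); pull(net->cblk2.b2);
  if (k != (long)v.size()) Rcpp::stop("bn stats length mismatch");
}

// [[Rcpp::export]]
Rcpp::NumericVector net_forward_seg(SEXP net_, Rcpp::NumericVector x,
                                    bool train = false) {
  Rcpp::XPtr<Net> net(net_);
  std::vector<cube> batch = batch_from_r(x);
  std::vector<cube> probs;
  net->forward_seg(batch, probs, train, false);
  return batch_to_r(probs);
}

// [[Rcpp::export]]
Rcpp::List net_forward_class(SEXP net_, Rcpp::NumericVector x,
                             bool train = false) {
  Rcpp::XPtr<Net> net(net_);
  std::vector<cube> batch = batch_from_r(x);
  mat logits, emb;
  net->forward_class(batch, logits, emb, train, false);
  return Rcpp::List::create(
    Rcpp::Named("logits") = conv_to<arma::Mat<double>>::from(logits),
    Rcpp::Named("embedding") = conv_to<arma::Mat<double>>::from(emb));
}

// Combined training step:
//   seg batch (x, targets) -> focal loss; contrastive batch xc (2N views,
//   consecutive pairs positive) -> NT-Xent * lambda_con; optional class
//   labels for the 2-node head (CE). Any component may be omitted (NULL).
// Performs one Adam update; returns the component losses.
// [[Rcpp::export]]
Rcpp::List net_train_step(SEXP net_, SEXP x_, SEXP targets_,
                          double alpha, double gamma, bool alpha_weight,
                          SEXP xc_, double tau, double lambda_con,
                          SEXP class_x_, SEXP class_labels_,
                          double lambda_class, double lr,
                          bool update = true) {
  Rcpp::XPtr<Net> net(net_);
  net->zero_grad();
  double lseg = NA_REAL, lcon = NA_REAL, lcls = NA_REAL;
  if (x_ != R_NilValue) {
    std::vector<cube> batch = batch_from_r(x_);
    std::vector<mat> targets = targets_from_r(targets_);
    std::vector<cube> probs;
    net->forward_seg(batch, probs, true, true);
    std::vector<cube> dlogits;
    lseg = focal_loss_grad(probs, targets, alpha, gamma, alpha_weight,
                           &dlogits);
    net->backward_seg(dlogits, nullptr);
  }
  if (xc_ != R_NilValue) {
    std::vector<cube> cbatch = batch_from_r(xc_);
    mat logits, emb;
    net->forward_class(cbatch, logits, emb, true, true);
    mat dF;
    lcon = ntxent_grad(emb, tau, &dF);
    dF *= lambda_con;
    mat dZ(logits.n_rows, logits.n_cols, fill::zeros);
    if (class_labels_ != R_NilValue) {
      ivec labels = Rcpp::as<ivec>(class_labels_);
      mat dZc;
      lcls = ce_class_grad(logits, labels, &dZc);
      dZ = lambda_class * dZc;
    }
    net->backward_class(dF, dZ);
  } else if (class_x_ != R_NilValue && class_labels_ != R_NilValue) {
    std::vector<cube> cbatch = batch_from_r(class_x_);
    mat logits, emb;
    net->forward_class(cbatch, logits, emb, true, true);
    ivec labels = Rcpp::as<ivec>(class_labels_);
    mat dZ;
    lcls = ce_class_grad(logits, labels, &dZ);
    dZ *= lambda_class;
    mat demb(emb.n_rows, emb.n_cols, fill::zeros);
    net->backward_class(demb, dZ);
  }
  if (update) net->step(lr);
  return Rcpp::List::create(Rcpp::Named("loss_seg") = lseg,
                            Rcpp::Named("loss_con") = lcon,
                            Rcpp::Named("loss_class") = lcls);
}

// evaluation-mode focal loss (no gradients, running BN stats)
// [[Rcpp::export]]
double net_eval_focal(SEXP net_, Rcpp::NumericVector x,
                      Rcpp::NumericVector targets,
                      double alpha, double gamma, bool alpha_weight) {
  Rcpp::XPtr<Net> net(net_);
  std::vector<cube> batch = batch_from_r(x);
  std::vector<mat> tg = targets_from_r(targets);
  std::vector<cube> probs;
  net->forward_seg(batch, probs, false, false);
  return focal_loss_grad(probs, tg, alpha, gamma, alpha_weight, nullptr);
}

// loss + full parameter gradient (no update) — used for gradient checking
// [[Rcpp::export]]
Rcpp::List net_loss_and_grad(SEXP net_, SEXP x_, SEXP targets_,
                             double alpha, double gamma, bool alpha_weight,
                             SEXP xc_, double tau, double lambda_con) {
  Rcpp::XPtr<Net> net(net_);
  net->zero_grad();
  double loss = 0;
  if (x_ != R_NilValue) {
    std::vector<cube> batch = batch_from_r(x_);
    std::vector<mat> targets = targets_from_r(targets_);
    std::vector<cube> probs;
    net->forward_seg(batch, probs, true, true);
    std::vector<cube> dlogits;
    loss += focal_loss_grad(probs, targets, alpha, gamma, alpha_weight,
                            &dlogits);
    net->backward_seg(dlogits, nullptr);
  }
  if (xc_ != R_NilValue) {
    std::vector<cube> cbatch = batch_from_r(xc_);
    mat logits, emb;
    net->forward_class(cbatch, logits, emb, true, true);
    mat dF;
    double lc = ntxent_grad(emb, tau, &dF);
    loss += lambda_con * lc;
    dF *= lambda_con;
    mat dZ(logits.n_rows, logits.n_cols, fill::zeros);
    net->backward_class(dF, dZ);
  }
  long n = net->n_params();
  Rcpp::NumericVector g(n);
  long k = 0;
  for (Param* p : net->params) {
    for (uword i = 0; i < p->g.n_elem; ++i) g[k + i] = (double)p->g(i);
    k += p->g.n_elem;
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = g);
}

// same loss as training (batch-norm in training mode) without touching grads
// [[Rcpp::export]]
double net_loss_only(SEXP net_, SEXP x_, SEXP targets_,
                     double alpha, double gamma, bool alpha_weight,
                     SEXP xc_, double tau, double lambda_con) {
  Rcpp::XPtr<Net> net(net_);
  double loss = 0;
  if (x_ != R_NilValue) {
    std::vector<cube> batch = batch_from_r(x_);
    std::vector<mat> targets = targets_from_r(targets_);
    std::vector<cube> probs;
    net->forward_seg(batch, probs, true, false);
    loss += focal_loss_grad(probs, targets, alpha, gamma, alpha_weight,
                            nullptr);
  }
  if (xc_ != R_NilValue) {
    std::vector<cube> cbatch = batch_from_r(xc_);
    mat logits, emb;
    net->forward_class(cbatch, logits, emb, true, false);
    loss += lambda_con * ntxent_grad(emb, tau, nullptr);
  }
  return loss;
}

// standalone NT-Xent evaluation on an embedding matrix (for tests / R API)
// [[Rcpp::export]]
double ntxent_loss_cpp(Rcpp::NumericMatrix F, double tau) {
  arma::Mat<double> Fm = Rcpp::as<arma::Mat<double>>(F);
  return ntxent_grad_t<double>(Fm, tau, nullptr);
}

// [[Rcpp::export]]
Rcpp::List net_config_echo(SEXP net_) {
  Rcpp::XPtr<Net> net(net_);
  return Rcpp::List::create(
    Rcpp::Named("depth") = net->depth,
    Rcpp::Named("base_channels") = net->base,
    Rcpp::Named("in_channels") = net->in_ch,
    Rcpp::Named("seg_classes") = net->seg_classes,
    Rcpp::Named("patch_size") = net->patch,
    Rcpp::Named("fc_sizes") = Rcpp::IntegerVector::create(net->fc1_sz,
                                                          net->fc2_sz),
    Rcpp::Named("class_out") = net->class_out,
    Rcpp::Named("epoch") = net->epoch);
}

// [[Rcpp::export]]
void net_set_epoch(SEXP net_, int e) {
  Rcpp::XPtr<Net> net(net_);
  net->epoch = e;
}
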