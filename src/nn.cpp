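// Bilateral variational domain-adversarial network: layers, model, training.
//
// Feature maps are stored one sample per column as (H*W*C) x N matrices with
// row index r = h + H*(w + W*c).  All randomness flows through a private
// mt19937_64 so a (seed, config, data) triple reproduces training bitwise on
// one machine.  Transposed convolutions are implemented as the exact adjoint
// of the matching forward convolution, which keeps encoder and decoder
// geometry mirror-symmetric by construction.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>
#include <map>
#ifdef __GLIBC__
#include <malloc.h>
// keep multi-megabyte tensor buffers on the reusable heap instead of
// per-allocation mmap/munmap cycles, which page-fault on every first touch
static const bool g_mallopt_done = []() {
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  return true;
}();
#endif
// [[Rcpp::depends(RcppArmadillo)]]

typedef float real;       // training arithmetic is single precision
typedef arma::fmat mat;
typedef arma::fvec vec;
typedef arma::mat dmat;   // histories and R-facing summaries stay double
using arma::uvec;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;
static const double PROB_FLOOR = 1e-12;

// fast exp: range-reduced degree-7 polynomial, ~1e-9 relative accuracy.
// std::exp dominates the decoder forward pass otherwise.
static inline double fast_exp(double x) {
  if (x > 700.0) x = 700.0;
  if (x < -700.0) return 0.0;
  double t = x * 1.4426950408889634;
  double n = std::floor(t + 0.5);
  double r = x - n * 0.6931471805599453;
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6.0 + r * (1.0 / 24.0 +
             r * (1.0 / 120.0 + r * (1.0 / 720.0 + r / 5040.0))))));
  union { double d; uint64_t u; } v;
  v.u = (uint64_t)((int64_t)n + 1023) << 52;
  return p * v.d;
}

// ---------------------------------------------------------------------------
// RNG

struct Rng {
  std::mt19937_64 gen;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;
  explicit Rng(uint64_t seed) : gen(seed), norm(0.0, 1.0), unif(0.0, 1.0) {}
  double normal() { return norm(gen); }
  double uniform() { return unif(gen); }
  void fill_normal(mat& M) { for (arma::uword i = 0; i < M.n_elem; ++i) M(i) = normal(); }
  // Fisher-Yates shuffle of 0..n-1
  std::vector<int> permutation(int n) {
    std::vector<int> p(n);
    for (int i = 0; i < n; ++i) p[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(gen() % (uint64_t)(i + 1));
      std::swap(p[i], p[j]);
    }
    return p;
  }
};

// ---------------------------------------------------------------------------
// Parameter with gradient and Adam state

struct Param {
  mat W;       // value
  mat G;       // gradient
  mat m, v;    // Adam moments
  double t = 0.0;
  bool trainable = true;
  std::string name;

  void init_state() {
    G.zeros(W.n_rows, W.n_cols);
    m.zeros(W.n_rows, W.n_cols);
    v.zeros(W.n_rows, W.n_cols);
    t = 0.0;
  }
  void adam(double lr) {
    if (!trainable) return;
    t += 1.0;
    m = 0.9 * m + 0.1 * G;
    v = 0.999 * v + 0.001 * (G % G);
    double bc1 = 1.0 - std::pow(0.9, t);
    double bc2 = 1.0 - std::pow(0.999, t);
    W -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
  }
};

// ---------------------------------------------------------------------------
// Convolution geometry ('same' padding, TF convention: extra pad on the
// bottom/right when the total is odd)

struct ConvGeom {
  int H, W, C, kh, kw, sh, sw, Cout;
  int oH, oW, P, K;
  std::vector<int> src;  // (k, p) -> source row in input, -1 for padding

  void setup(int H_, int W_, int C_, int kh_, int kw_, int sh_, int sw_, int Cout_) {
    H = H_; W = W_; C = C_; kh = kh_; kw = kw_; sh = sh_; sw = sw_; Cout = Cout_;
    oH = (H + sh - 1) / sh;
    oW = (W + sw - 1) / sw;
    P = oH * oW;
    K = kh * kw * C;
    int padH = std::max(0, (oH - 1) * sh + kh - H);
    int padW = std::max(0, (oW - 1) * sw + kw - W);
    int pt = padH / 2, pl = padW / 2;
    src.assign((size_t)K * P, -1);
    for (int ow = 0; ow < oW; ++ow) {
      for (int oh = 0; oh < oH; ++oh) {
        int p = oh + oH * ow;
        for (int c = 0; c < C; ++c) {
          for (int iw = 0; iw < kw; ++iw) {
            for (int ih = 0; ih < kh; ++ih) {
              int k = ih + kh * (iw + kw * c);
              int h = oh * sh - pt + ih;
              int w = ow * sw - pl + iw;
              if (h >= 0 && h < H && w >= 0 && w < W)
                src[(size_t)k + (size_t)K * p] = h + H * (w + W * c);
            }
          }
        }
      }
    }
  }

  // gather input (H*W*C) x N into columns (K) x (P*N)
  void im2col(const mat& X, mat& col) const {
    int N = X.n_cols;
    col.set_size(K, (size_t)P * N);
    for (int n = 0; n < N; ++n) {
      const real* xp = X.colptr(n);
      for (int p = 0; p < P; ++p) {
        real* cp = col.colptr((size_t)p + (size_t)P * n);
        const int* sp = &src[(size_t)K * p];
        for (int k = 0; k < K; ++k) cp[k] = (sp[k] >= 0) ? xp[sp[k]] : 0.0f;
      }
    }
  }

  // scatter-add columns back into (H*W*C) x N
  void col2im(const mat& col, mat& X, int N) const {
    X.zeros((size_t)H * W * C, N);
    for (int n = 0; n < N; ++n) {
      real* xp = X.colptr(n);
      for (int p = 0; p < P; ++p) {
        const real* cp = col.colptr((size_t)p + (size_t)P * n);
        const int* sp = &src[(size_t)K * p];
        for (int k = 0; k < K; ++k) if (sp[k] >= 0) xp[sp[k]] += cp[k];
      }
    }
  }

  // (Cout x P*N) grouped layout -> (P*Cout) x N map layout
  void group_to_map(const mat& G, mat& Y, int N) const {
    Y.set_size((size_t)P * Cout, N);
    for (int n = 0; n < N; ++n) {
      real* yp = Y.colptr(n);
      for (int p = 0; p < P; ++p) {
        const real* gp = G.colptr((size_t)p + (size_t)P * n);
        for (int c = 0; c < Cout; ++c) yp[p + P * c] = gp[c];
      }
    }
  }

  void map_to_group(const mat& Y, mat& G, int N) const {
    G.set_size(Cout, (size_t)P * N);
    for (int n = 0; n < N; ++n) {
      const real* yp = Y.colptr(n);
      for (int p = 0; p < P; ++p) {
        real* gp = G.colptr((size_t)p + (size_t)P * n);
        for (int c = 0; c < Cout; ++c) gp[c] = yp[p + P * c];
      }
    }
  }
};

// ---------------------------------------------------------------------------
// Layers

struct Conv {
  ConvGeom g;
  Param W, b;  // W: Cout x K, b: Cout x 1
  mat col;     // cached im2col of the last forward input

  void setup(const std::string& nm, int H, int Wd, int C, int k, int sh, int sw,
             int Cout, Rng& rng) {
    g.setup(H, Wd, C, k, k, sh, sw, Cout);
    double lim = std::sqrt(6.0 / (g.K + Cout));
    W.W.set_size(Cout, g.K);
    for (arma::uword i = 0; i < W.W.n_elem; ++i) W.W(i) = (2.0 * rng.uniform() - 1.0) * lim;
    b.W.zeros(Cout, 1);
    W.name = nm + ".W"; b.name = nm + ".b";
    W.init_state(); b.init_state();
  }

  mat forward(const mat& X, bool cache) {
    int N = X.n_cols;
    mat c; g.im2col(X, c);
    mat Yg = W.W * c;
    Yg.each_col() += b.W.col(0);
    if (cache) col = std::move(c);
    mat Y; g.group_to_map(Yg, Y, N);
    return Y;
  }

  // accumulate parameter grads, return grad wrt input
  mat backward(const mat& dY) {
    int N = dY.n_cols;
    mat dYg; g.map_to_group(dY, dYg, N);
    W.G += dYg * col.t();
    b.G += arma::sum(dYg, 1);
    mat dcol = W.W.t() * dYg;
    mat dX; g.col2im(dcol, dX, N);
    return dX;
  }
};

// Transposed convolution: adjoint of the conv with geometry g (which maps the
// convT *output* shape to its *input* shape).
struct ConvT {
  ConvGeom g;   // conv geometry: big (H,W,Cin_of_conv) -> small (oH,oW,Cout_of_conv)
  Param W, b;   // W as in the adjoint conv: (g.Cout) x (g.K); bias over big-side channels (g.C)
  mat Xin;      // cached convT input (small side), map layout

  void setup(const std::string& nm, int bigH, int bigW, int bigC, int k, int sh,
             int sw, int smallC, Rng& rng) {
    g.setup(bigH, bigW, bigC, k, k, sh, sw, smallC);
    double lim = std::sqrt(6.0 / (g.K + g.Cout));
    W.W.set_size(g.Cout, g.K);
    for (arma::uword i = 0; i < W.W.n_elem; ++i) W.W(i) = (2.0 * rng.uniform() - 1.0) * lim;
    b.W.zeros(bigC, 1);
    W.name = nm + ".W"; b.name = nm + ".b";
    W.init_state(); b.init_state();
  }

  // X: (g.P * g.Cout) x N (small) -> (g.H * g.W * g.C) x N (big)
  mat forward(const mat& X, bool cache) {
    int N = X.n_cols;
    if (cache) Xin = X;
    mat Xg; g.map_to_group(X, Xg, N);
    mat dcol = W.W.t() * Xg;
    mat Y; g.col2im(dcol, Y, N);
    // per-channel bias on the big side (channel blocks are contiguous rows)
    int HW = g.H * g.W;
    for (int c = 0; c < g.C; ++c) Y.rows((size_t)c * HW, (size_t)(c + 1) * HW - 1) += b.W(c, 0);
    return Y;
  }

  mat backward(const mat& dY) {
    int N = dY.n_cols;
    int HW = g.H * g.W;
    for (int c = 0; c < g.C; ++c)
      b.G(c, 0) += arma::accu(dY.rows((size_t)c * HW, (size_t)(c + 1) * HW - 1));
    mat colY; g.im2col(dY, colY);          // dY lives on the big side
    mat Xg; g.map_to_group(Xin, Xg, N);
    W.G += Xg * colY.t();
    mat dXg = W.W * colY;                  // conv forward on dY
    mat dX; g.group_to_map(dXg, dX, N);
    return dX;
  }
};

struct Dense {
  Param W, b;
  mat Xin;

  void setup(const std::string& nm, int in, int out, Rng& rng) {
    double lim = std::sqrt(6.0 / (in + out));
    W.W.set_size(out, in);
    for (arma::uword i = 0; i < W.W.n_elem; ++i) W.W(i) = (2.0 * rng.uniform() - 1.0) * lim;
    b.W.zeros(out, 1);
    W.name = nm + ".W"; b.name = nm + ".b";
    W.init_state(); b.init_state();
  }
  mat forward(const mat& X, bool cache) {
    if (cache) Xin = X;
    mat Y = W.W * X;
    Y.each_col() += b.W.col(0);
    return Y;
  }
  mat backward(const mat& dY) {
    W.G += dY * Xin.t();
    b.G += arma::sum(dY, 1);
    return W.W.t() * dY;
  }
};

// Batch normalization over columns.  For spatial maps `groups` = number of
// channels and each channel occupies a contiguous block of rows; for dense
// inputs `groups` = number of rows (one statistic per feature).
struct BatchNorm {
  int rows = 0, groups = 0, block = 1;
  Param gamma, beta;
  mat rmean, rvar;           // running buffers (groups x 1)
  mat xhat;                  // cache
  vec invstd;                // per group
  bool last_train = false;

  void setup(const std::string& nm, int rows_, int groups_, Rng&) {
    rows = rows_; groups = groups_; block = rows_ / groups_;
    gamma.W.ones(groups, 1); beta.W.zeros(groups, 1);
    gamma.name = nm + ".gamma"; beta.name = nm + ".beta";
    gamma.init_state(); beta.init_state();
    rmean.zeros(groups, 1); rvar.ones(groups, 1);
  }

  mat forward(const mat& X, bool train, bool update_buffers, bool cache) {
    int N = X.n_cols;
    mat Y(X.n_rows, N);
    if (cache) { xhat.set_size(X.n_rows, N); invstd.set_size(groups); }
    last_train = train;
    if (block == 1) {  // dense: one statistic per row, fully vectorized
      vec mu_v, var_v;
      if (train) {
        mu_v = arma::mean(X, 1);
        mat cen = X.each_col() - mu_v;
        var_v = arma::sum(cen % cen, 1) / (double)N;
        if (update_buffers) {
          rmean.col(0) = BN_MOMENTUM * rmean.col(0) + (1.0 - BN_MOMENTUM) * mu_v;
          rvar.col(0)  = BN_MOMENTUM * rvar.col(0)  + (1.0 - BN_MOMENTUM) * var_v;
        }
      } else {
        mu_v = rmean.col(0); var_v = rvar.col(0);
      }
      vec is_v = 1.0 / arma::sqrt(var_v + BN_EPS);
      mat xh = (X.each_col() - mu_v).each_col() % is_v;
      Y = (xh.each_col() % gamma.W.col(0)).each_col() + beta.W.col(0);
      if (cache) { xhat = xh; invstd = is_v; }
      return Y;
    }
    for (int gi = 0; gi < groups; ++gi) {
      arma::span rs((size_t)gi * block, (size_t)(gi + 1) * block - 1);
      double mu, var;
      if (train) {
        mu = arma::accu(X.rows(rs)) / ((double)block * N);
        mat cen = X.rows(rs) - mu;
        var = arma::accu(cen % cen) / ((double)block * N);
        if (update_buffers) {
          rmean(gi, 0) = BN_MOMENTUM * rmean(gi, 0) + (1.0 - BN_MOMENTUM) * mu;
          rvar(gi, 0)  = BN_MOMENTUM * rvar(gi, 0)  + (1.0 - BN_MOMENTUM) * var;
        }
      } else {
        mu = rmean(gi, 0); var = rvar(gi, 0);
      }
      double is = 1.0 / std::sqrt(var + BN_EPS);
      mat xh = (X.rows(rs) - mu) * is;
      Y.rows(rs) = gamma.W(gi, 0) * xh + beta.W(gi, 0);
      if (cache) { xhat.rows(rs) = xh; invstd(gi) = is; }
    }
    return Y;
  }

  mat backward(const mat& dY) {
    int N = dY.n_cols;
    double M = (double)block * N;
    mat dX(dY.n_rows, N);
    if (block == 1) {
      vec s1 = arma::sum(dY, 1);
      vec s2 = arma::sum(dY % xhat, 1);
      gamma.G.col(0) += s2;
      beta.G.col(0) += s1;
      if (last_train) {
        mat t = M * dY;
        t.each_col() -= s1;
        t -= xhat.each_col() % s2;
        dX = t.each_col() % (gamma.W.col(0) % invstd / M);
      } else {
        dX = dY.each_col() % (gamma.W.col(0) % invstd);
      }
      return dX;
    }
    for (int gi = 0; gi < groups; ++gi) {
      arma::span rs((size_t)gi * block, (size_t)(gi + 1) * block - 1);
      const mat dYg = dY.rows(rs);
      const mat xh = xhat.rows(rs);
      double s1 = arma::accu(dYg);
      double s2 = arma::accu(dYg % xh);
      gamma.G(gi, 0) += s2;
      beta.G(gi, 0) += s1;
      if (last_train) {
        dX.rows(rs) = (gamma.W(gi, 0) * invstd(gi) / M) * (M * dYg - s1 - xh * s2);
      } else {
        dX.rows(rs) = gamma.W(gi, 0) * invstd(gi) * dYg;
      }
    }
    return dX;
  }
};

// average pooling / nearest upsampling over pool x pool blocks, layout
// r = h + H*(w + W*c); used as a fixed (parameter-free) stem so scaled-down
// configurations can run their convolution pyramid on reduced maps
static mat avg_pool(const mat& X, int H, int W, int C, int pool) {
  int h = H / pool, w = W / pool;
  int N = X.n_cols;
  mat Y((size_t)h * w * C, N);
  real inv = (real)(1.0 / (pool * pool));
  for (int n = 0; n < N; ++n) {
    const real* xp = X.colptr(n);
    real* yp = Y.colptr(n);
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < w; ++ow)
        for (int oh = 0; oh < h; ++oh) {
          const real* base = xp + (size_t)oh * pool + H * ((size_t)ow * pool + (size_t)W * c);
          real s = 0.0f;
          for (int j = 0; j < pool; ++j)
            for (int i = 0; i < pool; ++i) s += base[i + H * j];
          yp[oh + h * (ow + w * c)] = s * inv;
        }
  }
  return Y;
}

static mat upsample(const mat& X, int h, int w, int C, int pool) {
  int H = h * pool, W = w * pool;
  int N = X.n_cols;
  mat Y((size_t)H * W * C, N);
  for (int n = 0; n < N; ++n) {
    const real* xp = X.colptr(n);
    real* yp = Y.colptr(n);
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < w; ++ow)
        for (int oh = 0; oh < h; ++oh) {
          real v = xp[oh + h * (ow + w * c)];
          real* base = yp + (size_t)oh * pool + H * ((size_t)ow * pool + (size_t)W * c);
          for (int j = 0; j < pool; ++j)
            for (int i = 0; i < pool; ++i) base[i + H * j] = v;
        }
  }
  return Y;
}

static mat upsample_back(const mat& dY, int h, int w, int C, int pool) {
  int H = h * pool, W = w * pool;
  int N = dY.n_cols;
  mat dX((size_t)h * w * C, N);
  for (int n = 0; n < N; ++n) {
    const real* gp = dY.colptr(n);
    real* dp = dX.colptr(n);
    for (int c = 0; c < C; ++c)
      for (int ow = 0; ow < w; ++ow)
        for (int oh = 0; oh < h; ++oh) {
          const real* base = gp + (size_t)oh * pool + H * ((size_t)ow * pool + (size_t)W * c);
          real s = 0.0f;
          for (int j = 0; j < pool; ++j)
            for (int i = 0; i < pool; ++i) s += base[i + H * j];
          dp[oh + h * (ow + w * c)] = s;
        }
  }
  return dX;
}

struct Relu {
  arma::umat mask;
  mat forward(const mat& X, bool cache) {
    mat Y = arma::clamp(X, 0.0, arma::datum::inf);
    if (cache) mask = (X > 0.0);
    return Y;
  }
  mat backward(const mat& dY) { return dY % arma::conv_to<mat>::from(mask); }
};

// Bounded output squash mapping R -> (0, 1): 0.5 * (1 + u / (1 + |u|)) with
// u = x / 2.  Smooth, sigmoid-shaped (slope 1/4 at 0, like the logistic) and
// branch-free, so it vectorizes on the baseline SIMD target.
static mat squash(const mat& X) {
  mat Y(X.n_rows, X.n_cols);
  const real* xp = X.memptr();
  real* yp = Y.memptr();
  for (arma::uword i = 0; i < X.n_elem; ++i) {
    real u = 0.5f * xp[i];
    yp[i] = 0.5f + 0.5f * u / (1.0f + std::abs(u));
  }
  return Y;
}

// derivative of squash expressed through its output: 0.25 * (1 - |2y - 1|)^2
static mat squash_deriv(const mat& Y) {
  mat D(Y.n_rows, Y.n_cols);
  const real* yp = Y.memptr();
  real* dp = D.memptr();
  for (arma::uword i = 0; i < Y.n_elem; ++i) {
    real t = 1.0f - std::abs(2.0f * yp[i] - 1.0f);
    dp[i] = 0.25f * t * t;
  }
  return D;
}

static mat sigmoid(const mat& X) {
  mat Y(X.n_rows, X.n_cols);
  const real* xp = X.memptr();
  real* yp = Y.memptr();
  for (arma::uword i = 0; i < X.n_elem; ++i) yp[i] = (real)(1.0 / (1.0 + fast_exp(-(double)xp[i])));
  return Y;
}

static mat softmax_cols(const mat& Z) {
  mat S = Z;
  S.each_row() -= arma::max(Z, 0);
  S = arma::exp(S);
  S.each_row() /= arma::sum(S, 0);
  return S;
}

// ---------------------------------------------------------------------------
// Architecture description

struct Arch {
  int C = 3, H = 64, W = 32;          // hemisphere image: bands x rows x cols
  int pool = 1;                        // fixed average-pooling stem factor
  int latent = 64;
  std::vector<int> enc_ch {32, 64, 128};
  std::vector<int> enc_st {2, 2, 2};
  int enc_dense = 512;
  std::vector<int> ext_ch {32, 64};
  int ext_dense = 128;                 // width of the two dense stages = embedding
  std::vector<int> head_dense {256, 256, 64};
  int n_classes = 2, n_subjects = 2;
  int hemi = 0;                        // 0 both, 1 left only, 2 right only

  static Arch from_list(const List& a) {
    Arch r;
    IntegerVector inp = a["input"];
    r.C = inp[0]; r.H = inp[1]; r.W = inp[2];
    if (a.containsElementNamed("pool")) r.pool = Rcpp::as<int>(a["pool"]);
    if (r.pool < 1 || r.H % r.pool != 0 || r.W % r.pool != 0)
      Rcpp::stop("pool must divide the input height and width");
    r.latent = Rcpp::as<int>(a["latent"]);
    r.enc_ch = Rcpp::as<std::vector<int>>(a["enc_channels"]);
    r.enc_st = Rcpp::as<std::vector<int>>(a["enc_strides"]);
    r.enc_dense = Rcpp::as<int>(a["enc_dense"]);
    r.ext_ch = Rcpp::as<std::vector<int>>(a["ext_channels"]);
    r.ext_dense = Rcpp::as<int>(a["ext_dense"]);
    r.head_dense = Rcpp::as<std::vector<int>>(a["head_dense"]);
    r.n_classes = Rcpp::as<int>(a["n_classes"]);
    r.n_subjects = Rcpp::as<int>(a["n_subjects"]);
    std::string h = Rcpp::as<std::string>(a["hemi"]);
    r.hemi = (h == "left") ? 1 : (h == "right") ? 2 : 0;
    return r;
  }
};

// ---------------------------------------------------------------------------
// Networks

struct Encoder {
  Conv c1, c2, c3;
  BatchNorm b1, b2, b3, bd;
  Relu r1, r2, r3, rd;
  Dense d0, dmu, dlv;
  int flat = 0;
  int pool = 1, inH = 0, inW = 0, inC = 0;

  void setup(const std::string& nm, const Arch& a, Rng& rng) {
    pool = a.pool; inH = a.H; inW = a.W; inC = a.C;
    int H = a.H / a.pool, W = a.W / a.pool;
    c1.setup(nm + ".c1", H, W, a.C, 3, a.enc_st[0], a.enc_st[0], a.enc_ch[0], rng);
    H = c1.g.oH; W = c1.g.oW;
    b1.setup(nm + ".bn1", H * W * a.enc_ch[0], a.enc_ch[0], rng);
    c2.setup(nm + ".c2", H, W, a.enc_ch[0], 3, a.enc_st[1], a.enc_st[1], a.enc_ch[1], rng);
    H = c2.g.oH; W = c2.g.oW;
    b2.setup(nm + ".bn2", H * W * a.enc_ch[1], a.enc_ch[1], rng);
    c3.setup(nm + ".c3", H, W, a.enc_ch[1], 3, a.enc_st[2], a.enc_st[2], a.enc_ch[2], rng);
    H = c3.g.oH; W = c3.g.oW;
    b3.setup(nm + ".bn3", H * W * a.enc_ch[2], a.enc_ch[2], rng);
    flat = H * W * a.enc_ch[2];
    d0.setup(nm + ".d0", flat, a.enc_dense, rng);
    bd.setup(nm + ".bnd", a.enc_dense, a.enc_dense, rng);
    dmu.setup(nm + ".dmu", a.enc_dense, a.latent, rng);
    dlv.setup(nm + ".dlv", a.enc_dense, a.latent, rng);
    // start with a small posterior sd (sigma ~ e^-1.5) so early latent
    // samples are informative; the KL term pulls sigma up as beta ramps
    dlv.b.W.fill(-3.0);
  }

  void forward(const mat& X, bool train, bool upd, bool cache, mat& mu, mat& lv) {
    mat pooled;
    const mat* Xp = &X;
    if (pool > 1) { pooled = avg_pool(X, inH, inW, inC, pool); Xp = &pooled; }
    mat h = r1.forward(b1.forward(c1.forward(*Xp, cache), train, upd, cache), cache);
    h = r2.forward(b2.forward(c2.forward(h, cache), train, upd, cache), cache);
    h = r3.forward(b3.forward(c3.forward(h, cache), train, upd, cache), cache);
    h = rd.forward(bd.forward(d0.forward(h, cache), train, upd, cache), cache);
    mu = dmu.forward(h, cache);
    lv = dlv.forward(h, cache);
  }

  mat backward(const mat& dmu_, const mat& dlv_) {
    mat dh = dmu.backward(dmu_) + dlv.backward(dlv_);
    dh = d0.backward(bd.backward(rd.backward(dh)));
    dh = c3.backward(b3.backward(r3.backward(dh)));
    dh = c2.backward(b2.backward(r2.backward(dh)));
    return c1.backward(b1.backward(r1.backward(dh)));
  }

  void params(std::vector<Param*>& out) {
    out.push_back(&c1.W); out.push_back(&c1.b);
    out.push_back(&b1.gamma); out.push_back(&b1.beta);
    out.push_back(&c2.W); out.push_back(&c2.b);
    out.push_back(&b2.gamma); out.push_back(&b2.beta);
    out.push_back(&c3.W); out.push_back(&c3.b);
    out.push_back(&b3.gamma); out.push_back(&b3.beta);
    out.push_back(&d0.W); out.push_back(&d0.b);
    out.push_back(&bd.gamma); out.push_back(&bd.beta);
    out.push_back(&dmu.W); out.push_back(&dmu.b);
    out.push_back(&dlv.W); out.push_back(&dlv.b);
  }
  void buffers(std::vector<std::pair<std::string, mat*>>& out, const std::string& nm) {
    out.push_back({nm + ".bn1.rmean", &b1.rmean}); out.push_back({nm + ".bn1.rvar", &b1.rvar});
    out.push_back({nm + ".bn2.rmean", &b2.rmean}); out.push_back({nm + ".bn2.rvar", &b2.rvar});
    out.push_back({nm + ".bn3.rmean", &b3.rmean}); out.push_back({nm + ".bn3.rvar", &b3.rvar});
    out.push_back({nm + ".bnd.rmean", &bd.rmean}); out.push_back({nm + ".bnd.rvar", &bd.rvar});
  }
};

struct Decoder {
  Dense d0, d1;
  BatchNorm b0, b1, bt3, bt2;
  Relu r0, r1, rt3, rt2;
  ConvT t3, t2, t1;
  mat out_cache;  // squash output at pooled resolution
  int pool = 1, outh = 0, outw = 0, outC = 0;

  void setup(const std::string& nm, const Arch& a, const Encoder& enc, Rng& rng) {
    pool = a.pool; outh = a.H / a.pool; outw = a.W / a.pool; outC = a.C;
    d0.setup(nm + ".d0", a.latent, a.enc_dense, rng);
    b0.setup(nm + ".bn0", a.enc_dense, a.enc_dense, rng);
    d1.setup(nm + ".d1", a.enc_dense, enc.flat, rng);
    b1.setup(nm + ".bn1", enc.flat, enc.flat, rng);
    // adjoints of the encoder convs, deepest first
    t3.setup(nm + ".t3", enc.c3.g.H, enc.c3.g.W, enc.c3.g.C, 3, a.enc_st[2], a.enc_st[2], a.enc_ch[2], rng);
    bt3.setup(nm + ".bnt3", enc.c3.g.H * enc.c3.g.W * enc.c3.g.C, enc.c3.g.C, rng);
    t2.setup(nm + ".t2", enc.c2.g.H, enc.c2.g.W, enc.c2.g.C, 3, a.enc_st[1], a.enc_st[1], a.enc_ch[1], rng);
    bt2.setup(nm + ".bnt2", enc.c2.g.H * enc.c2.g.W * enc.c2.g.C, enc.c2.g.C, rng);
    t1.setup(nm + ".t1", enc.c1.g.H, enc.c1.g.W, enc.c1.g.C, 3, a.enc_st[0], a.enc_st[0], a.enc_ch[0], rng);
  }

  mat forward(const mat& Z, bool train, bool upd, bool cache) {
    mat h = r0.forward(b0.forward(d0.forward(Z, cache), train, upd, cache), cache);
    h = r1.forward(b1.forward(d1.forward(h, cache), train, upd, cache), cache);
    h = rt3.forward(bt3.forward(t3.forward(h, cache), train, upd, cache), cache);
    h = rt2.forward(bt2.forward(t2.forward(h, cache), train, upd, cache), cache);
    mat y = squash(t1.forward(h, cache));
    if (cache) out_cache = y;
    if (pool > 1) y = upsample(y, outh, outw, outC, pool);
    return y;
  }

  mat backward(const mat& dY) {
    mat dpool;
    const mat* dp = &dY;
    if (pool > 1) { dpool = upsample_back(dY, outh, outw, outC, pool); dp = &dpool; }
    mat dh = t1.backward((*dp) % squash_deriv(out_cache));
    dh = t2.backward(bt2.backward(rt2.backward(dh)));
    dh = t3.backward(bt3.backward(rt3.backward(dh)));
    dh = d1.backward(b1.backward(r1.backward(dh)));
    return d0.backward(b0.backward(r0.backward(dh)));
  }

  void params(std::vector<Param*>& out) {
    out.push_back(&d0.W); out.push_back(&d0.b);
    out.push_back(&b0.gamma); out.push_back(&b0.beta);
    out.push_back(&d1.W); out.push_back(&d1.b);
    out.push_back(&b1.gamma); out.push_back(&b1.beta);
    out.push_back(&t3.W); out.push_back(&t3.b);
    out.push_back(&bt3.gamma); out.push_back(&bt3.beta);
    out.push_back(&t2.W); out.push_back(&t2.b);
    out.push_back(&bt2.gamma); out.push_back(&bt2.beta);
    out.push_back(&t1.W); out.push_back(&t1.b);
  }
  void buffers(std::vector<std::pair<std::string, mat*>>& out, const std::string& nm) {
    out.push_back({nm + ".bn0.rmean", &b0.rmean}); out.push_back({nm + ".bn0.rvar", &b0.rvar});
    out.push_back({nm + ".bn1.rmean", &b1.rmean}); out.push_back({nm + ".bn1.rvar", &b1.rvar});
    out.push_back({nm + ".bnt3.rmean", &bt3.rmean}); out.push_back({nm + ".bnt3.rvar", &bt3.rvar});
    out.push_back({nm + ".bnt2.rmean", &bt2.rmean}); out.push_back({nm + ".bnt2.rvar", &bt2.rvar});
  }
};

// Bilateral feature extractor: the two latent vectors are stacked as a
// 2 x J one-channel map (rows = hemispheres) so that 2x2 convolutions mix
// left and right; unilateral variants use a 1 x J map.
struct Extractor {
  Conv c1, c2;
  BatchNorm b1, b2, bd1, bd2;
  Relu r1, r2, rd1, rd2;
  Dense d1, d2;
  int rows_in = 2, J = 0;

  void setup(const std::string& nm, const Arch& a, Rng& rng) {
    J = a.latent;
    rows_in = (a.hemi == 0) ? 2 : 1;
    c1.setup(nm + ".c1", rows_in, J, 1, 2, rows_in, 2, a.ext_ch[0], rng);
    b1.setup(nm + ".bn1", c1.g.P * a.ext_ch[0], a.ext_ch[0], rng);
    c2.setup(nm + ".c2", c1.g.oH, c1.g.oW, a.ext_ch[0], 2, 1, 2, a.ext_ch[1], rng);
    b2.setup(nm + ".bn2", c2.g.P * a.ext_ch[1], a.ext_ch[1], rng);
    int flat = c2.g.P * a.ext_ch[1];
    d1.setup(nm + ".d1", flat, a.ext_dense, rng);
    bd1.setup(nm + ".bnd1", a.ext_dense, a.ext_dense, rng);
    d2.setup(nm + ".d2", a.ext_dense, a.ext_dense, rng);
    bd2.setup(nm + ".bnd2", a.ext_dense, a.ext_dense, rng);
  }

  // interleave z_l, z_r as rows of the 2 x J map (row-major within column)
  mat stack(const mat& zl, const mat& zr) const {
    if (rows_in == 1) return zl;  // unilateral: the active hemisphere only
    int N = zl.n_cols;
    mat X(2 * J, N);
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < J; ++j) { X(2 * j, n) = zl(j, n); X(2 * j + 1, n) = zr(j, n); }
    return X;
  }
  void unstack(const mat& dX, mat& dzl, mat& dzr) const {
    int N = dX.n_cols;
    if (rows_in == 1) { dzl = dX; dzr.zeros(J, N); return; }
    dzl.set_size(J, N); dzr.set_size(J, N);
    for (int n = 0; n < N; ++n)
      for (int j = 0; j < J; ++j) { dzl(j, n) = dX(2 * j, n); dzr(j, n) = dX(2 * j + 1, n); }
  }

  mat forward(const mat& X, bool train, bool upd, bool cache) {
    mat h = r1.forward(b1.forward(c1.forward(X, cache), train, upd, cache), cache);
    h = r2.forward(b2.forward(c2.forward(h, cache), train, upd, cache), cache);
    h = rd1.forward(bd1.forward(d1.forward(h, cache), train, upd, cache), cache);
    return rd2.forward(bd2.forward(d2.forward(h, cache), train, upd, cache), cache);
  }
  mat backward(const mat& dY) {
    mat dh = d2.backward(bd2.backward(rd2.backward(dY)));
    dh = d1.backward(bd1.backward(rd1.backward(dh)));
    dh = c2.backward(b2.backward(r2.backward(dh)));
    return c1.backward(b1.backward(r1.backward(dh)));
  }

  void params(std::vector<Param*>& out) {
    out.push_back(&c1.W); out.push_back(&c1.b);
    out.push_back(&b1.gamma); out.push_back(&b1.beta);
    out.push_back(&c2.W); out.push_back(&c2.b);
    out.push_back(&b2.gamma); out.push_back(&b2.beta);
    out.push_back(&d1.W); out.push_back(&d1.b);
    out.push_back(&bd1.gamma); out.push_back(&bd1.beta);
    out.push_back(&d2.W); out.push_back(&d2.b);
    out.push_back(&bd2.gamma); out.push_back(&bd2.beta);
  }
  void buffers(std::vector<std::pair<std::string, mat*>>& out, const std::string& nm) {
    out.push_back({nm + ".bn1.rmean", &b1.rmean}); out.push_back({nm + ".bn1.rvar", &b1.rvar});
    out.push_back({nm + ".bn2.rmean", &b2.rmean}); out.push_back({nm + ".bn2.rvar", &b2.rvar});
    out.push_back({nm + ".bnd1.rmean", &bd1.rmean}); out.push_back({nm + ".bnd1.rvar", &bd1.rvar});
    out.push_back({nm + ".bnd2.rmean", &bd2.rmean}); out.push_back({nm + ".bnd2.rvar", &bd2.rvar});
  }
};

// Emotion classifier / subject discriminator head: three batch-normalized
// dense stages + softmax output.
struct Head {
  Dense d1, d2, d3, dout;
  BatchNorm b1, b2, b3;
  Relu r1, r2, r3;
  mat probs;

  void setup(const std::string& nm, int in, const std::vector<int>& hidden, int nout, Rng& rng) {
    d1.setup(nm + ".d1", in, hidden[0], rng);
    b1.setup(nm + ".bn1", hidden[0], hidden[0], rng);
    d2.setup(nm + ".d2", hidden[0], hidden[1], rng);
    b2.setup(nm + ".bn2", hidden[1], hidden[1], rng);
    d3.setup(nm + ".d3", hidden[1], hidden[2], rng);
    b3.setup(nm + ".bn3", hidden[2], hidden[2], rng);
    dout.setup(nm + ".dout", hidden[2], nout, rng);
  }
  mat forward(const mat& X, bool train, bool upd, bool cache) {
    mat h = r1.forward(b1.forward(d1.forward(X, cache), train, upd, cache), cache);
    h = r2.forward(b2.forward(d2.forward(h, cache), train, upd, cache), cache);
    h = r3.forward(b3.forward(d3.forward(h, cache), train, upd, cache), cache);
    mat p = softmax_cols(dout.forward(h, cache));
    if (cache) probs = p;
    return p;
  }
  // dlogits must be the gradient wrt the softmax logits
  mat backward(const mat& dlogits) {
    mat dh = dout.backward(dlogits);
    dh = d3.backward(b3.backward(r3.backward(dh)));
    dh = d2.backward(b2.backward(r2.backward(dh)));
    return d1.backward(b1.backward(r1.backward(dh)));
  }
  void params(std::vector<Param*>& out) {
    out.push_back(&d1.W); out.push_back(&d1.b);
    out.push_back(&b1.gamma); out.push_back(&b1.beta);
    out.push_back(&d2.W); out.push_back(&d2.b);
    out.push_back(&b2.gamma); out.push_back(&b2.beta);
    out.push_back(&d3.W); out.push_back(&d3.b);
    out.push_back(&b3.gamma); out.push_back(&b3.beta);
    out.push_back(&dout.W); out.push_back(&dout.b);
  }
  void buffers(std::vector<std::pair<std::string, mat*>>& out, const std::string& nm) {
    out.push_back({nm + ".bn1.rmean", &b1.rmean}); out.push_back({nm + ".bn1.rvar", &b1.rvar});
    out.push_back({nm + ".bn2.rmean", &b2.rmean}); out.push_back({nm + ".bn2.rvar", &b2.rvar});
    out.push_back({nm + ".bn3.rmean", &b3.rmean}); out.push_back({nm + ".bn3.rvar", &b3.rvar});
  }
};

// ---------------------------------------------------------------------------
// Full model

struct Model {
  Arch a;
  Encoder enc_l, enc_r;
  Decoder dec_l, dec_r;
  Extractor ext;
  Head cls, dsc;

  // switch to consuming data that was average-pooled up front: the encoders
  // skip their pooling stem and the decoders emit (and are penalized at)
  // the pooled resolution.  Used by the training loops; arithmetically
  // equivalent gradients, far less per-batch traffic.
  void use_prepooled_data() {
    enc_l.pool = enc_r.pool = 1;
    dec_l.pool = dec_r.pool = 1;
  }

  void setup(const Arch& arch, Rng& rng) {
    a = arch;
    enc_l.setup("enc_l", a, rng);
    enc_r.setup("enc_r", a, rng);
    dec_l.setup("dec_l", a, enc_l, rng);
    dec_r.setup("dec_r", a, enc_r, rng);
    ext.setup("ext", a, rng);
    cls.setup("cls", a.ext_dense, a.head_dense, a.n_classes, rng);
    dsc.setup("dsc", a.ext_dense, a.head_dense, a.n_subjects, rng);
  }

  std::vector<Param*> group(const std::string& which) {
    std::vector<Param*> out;
    if (which == "enc") {
      if (a.hemi != 2) enc_l.params(out);
      if (a.hemi != 1) enc_r.params(out);
    } else if (which == "dec") {
      if (a.hemi != 2) dec_l.params(out);
      if (a.hemi != 1) dec_r.params(out);
    } else if (which == "ext") ext.params(out);
    else if (which == "cls") cls.params(out);
    else if (which == "dsc") dsc.params(out);
    return out;
  }

  std::vector<Param*> all_params() {
    std::vector<Param*> out;
    enc_l.params(out); enc_r.params(out);
    dec_l.params(out); dec_r.params(out);
    ext.params(out); cls.params(out); dsc.params(out);
    return out;
  }
  std::vector<std::pair<std::string, mat*>> all_buffers() {
    std::vector<std::pair<std::string, mat*>> out;
    enc_l.buffers(out, "enc_l"); enc_r.buffers(out, "enc_r");
    dec_l.buffers(out, "dec_l"); dec_r.buffers(out, "dec_r");
    ext.buffers(out, "ext"); cls.buffers(out, "cls"); dsc.buffers(out, "dsc");
    return out;
  }

  List to_list() {
    List out;
    for (Param* p : all_params()) out[p->name] = Rcpp::wrap(p->W);
    for (auto& b : all_buffers()) out[b.first] = Rcpp::wrap(*b.second);
    return out;
  }
  void from_list(const List& l) {
    for (Param* p : all_params()) {
      if (l.containsElementNamed(p->name.c_str())) p->W = Rcpp::as<mat>(l[p->name]);
      p->init_state();
    }
    for (auto& b : all_buffers())
      if (l.containsElementNamed(b.first.c_str())) *b.second = Rcpp::as<mat>(l[b.first]);
  }

  void zero_grads(std::vector<Param*>& ps) { for (Param* p : ps) p->G.zeros(); }
  void step(std::vector<Param*>& ps, double lr) { for (Param* p : ps) p->adam(lr); }

  struct Snapshot { std::vector<mat> w, buf; };
  Snapshot snapshot() {
    Snapshot s;
    for (Param* p : all_params()) s.w.push_back(p->W);
    for (auto& b : all_buffers()) s.buf.push_back(*b.second);
    return s;
  }
  void restore(const Snapshot& s) {
    size_t i = 0; for (Param* p : all_params()) p->W = s.w[i++];
    i = 0; for (auto& b : all_buffers()) *b.second = s.buf[i++];
  }
};

// ---------------------------------------------------------------------------
// Losses (batch means)

static double mse_loss(const mat& x, const mat& xhat) {
  mat d = xhat - x;
  return (double)arma::accu(d % d) / (double)d.n_elem;
}

static double kl_loss(const mat& mu, const mat& lv) {
  // mean over batch of 0.5 * sum_j (mu^2 + sigma^2 - 1 - log sigma^2)
  return 0.5 * (double)arma::accu(mu % mu + arma::exp(lv) - 1.0f - lv) / (double)mu.n_cols;
}

static double ce_loss(const mat& probs, const IntegerVector& lab, const uvec& idx) {
  double s = 0.0;
  for (arma::uword i = 0; i < idx.n_elem; ++i)
    s -= std::log(std::max((double)probs(lab[idx(i)], i), PROB_FLOOR));
  return s / (double)idx.n_elem;
}

// gradient of mean CE wrt softmax logits
static mat ce_dlogits(const mat& probs, const IntegerVector& lab, const uvec& idx) {
  mat d = probs;
  for (arma::uword i = 0; i < idx.n_elem; ++i) d(lab[idx(i)], i) -= 1.0;
  return d / (double)idx.n_elem;
}

static double acc(const mat& probs, const IntegerVector& lab, const uvec& idx) {
  int ok = 0;
  for (arma::uword i = 0; i < idx.n_elem; ++i) {
    arma::uword am = arma::index_max(probs.col(i));
    if ((int)am == lab[idx(i)]) ++ok;
  }
  return (double)ok / (double)idx.n_elem;
}

// ---------------------------------------------------------------------------
// Step helpers

struct StepOpts {
  double lr = 1e-4;
  double disc_lr_mult = 1.0;   // two-time-scale update: the discriminator may
                               // train faster than the shared path
  int disc_steps = 1;          // discriminator inner iterations per batch
  double beta = 0.0, lambda = 0.0;
  bool use_recon = true, use_kl = true, use_disc = true;
  bool sample_z = true;
  int hemi = 0;
};

// One encoder+decoder reconstruction step for a single hemisphere.
// Returns (recon, kl); updates enc/dec params via Adam when lr > 0.
static void vae_pass(Encoder& enc, Decoder& dec, const mat& X, const StepOpts& o,
                     Rng& rng, Model& M, const std::string& enc_grp,
                     bool update, double& recon_out, double& kl_out) {
  mat mu, lv;
  enc.forward(X, true, update, true, mu, lv);
  mat eps;
  mat z;
  if (o.use_kl && o.sample_z) {
    eps.set_size(mu.n_rows, mu.n_cols);
    rng.fill_normal(eps);
    z = mu + arma::exp(0.5 * lv) % eps;
  } else {
    z = mu;
  }
  mat xhat = dec.forward(z, true, update, true);
  recon_out = mse_loss(X, xhat);
  kl_out = o.use_kl ? kl_loss(mu, lv) : 0.0;
  if (!update) return;
  double N = (double)X.n_cols;
  mat dxhat = 2.0 * (xhat - X) / (double)X.n_elem;
  mat dz = dec.backward(dxhat);
  mat dmu = dz;
  mat dlv;
  if (o.use_kl && o.sample_z) dlv = dz % eps % (0.5 * arma::exp(0.5 * lv));
  else dlv = arma::zeros<mat>(lv.n_rows, lv.n_cols);
  if (o.use_kl && o.beta > 0.0) {
    dmu += o.beta * mu / N;
    dlv += o.beta * 0.5 * (arma::exp(lv) - 1.0) / N;
  }
  enc.backward(dmu, dlv);
  (void)M; (void)enc_grp;
}

// forward the shared path (encoders + extractor), optionally caching for
// backward; z handling controlled by opts
struct SharedCache { mat mu_l, lv_l, mu_r, lv_r, eps_l, eps_r, z_l, z_r, emb, Xstack; };

static void shared_forward(Model& M, const mat& Xl, const mat& Xr, const StepOpts& o,
                           bool train, bool upd, bool cache, Rng* rng, SharedCache& sc) {
  int N = (o.hemi == 2) ? Xr.n_cols : Xl.n_cols;
  bool sample = train && o.use_kl && o.sample_z && rng != nullptr;
  if (o.hemi != 2) {
    M.enc_l.forward(Xl, train, upd, cache, sc.mu_l, sc.lv_l);
    if (sample) { sc.eps_l.set_size(sc.mu_l.n_rows, N); rng->fill_normal(sc.eps_l);
      sc.z_l = sc.mu_l + arma::exp(0.5 * sc.lv_l) % sc.eps_l; }
    else sc.z_l = sc.mu_l;
  }
  if (o.hemi != 1) {
    M.enc_r.forward(Xr, train, upd, cache, sc.mu_r, sc.lv_r);
    if (sample) { sc.eps_r.set_size(sc.mu_r.n_rows, N); rng->fill_normal(sc.eps_r);
      sc.z_r = sc.mu_r + arma::exp(0.5 * sc.lv_r) % sc.eps_r; }
    else sc.z_r = sc.mu_r;
  }
  const mat& zl = (o.hemi == 2) ? sc.z_r : sc.z_l;  // unilateral uses the active side
  const mat& zr = (o.hemi == 1) ? sc.z_l : sc.z_r;
  sc.Xstack = M.ext.stack((o.hemi == 0) ? sc.z_l : zl, zr);
  sc.emb = M.ext.forward(sc.Xstack, train, upd, cache);
}

static void shared_backward(Model& M, const StepOpts& o, SharedCache& sc, const mat& demb) {
  mat dX = M.ext.backward(demb);
  mat dzl, dzr;
  M.ext.unstack(dX, dzl, dzr);
  if (o.hemi == 0) {
    mat dlv_l = (o.use_kl && o.sample_z) ? mat(dzl % sc.eps_l % (0.5 * arma::exp(0.5 * sc.lv_l)))
                                         : arma::zeros<mat>(sc.lv_l.n_rows, sc.lv_l.n_cols);
    mat dlv_r = (o.use_kl && o.sample_z) ? mat(dzr % sc.eps_r % (0.5 * arma::exp(0.5 * sc.lv_r)))
                                         : arma::zeros<mat>(sc.lv_r.n_rows, sc.lv_r.n_cols);
    M.enc_l.backward(dzl, dlv_l);
    M.enc_r.backward(dzr, dlv_r);
  } else if (o.hemi == 1) {
    mat dlv = (o.use_kl && o.sample_z) ? mat(dzl % sc.eps_l % (0.5 * arma::exp(0.5 * sc.lv_l)))
                                       : arma::zeros<mat>(sc.lv_l.n_rows, sc.lv_l.n_cols);
    M.enc_l.backward(dzl, dlv);
  } else {
    mat dlv = (o.use_kl && o.sample_z) ? mat(dzl % sc.eps_r % (0.5 * arma::exp(0.5 * sc.lv_r)))
                                       : arma::zeros<mat>(sc.lv_r.n_rows, sc.lv_r.n_cols);
    M.enc_r.backward(dzl, dlv);
  }
}

// ---------------------------------------------------------------------------
// Exported: parameter initialization

// [[Rcpp::export(name = ".nn_init")]]
List nn_init(List arch, int seed) {
  Rng rng((uint64_t)seed);
  Model M;
  M.setup(Arch::from_list(arch), rng);
  return M.to_list();
}

// [[Rcpp::export(name = ".nn_shapes")]]
List nn_shapes(List arch) {
  Rng rng(1);
  Model M;
  M.setup(Arch::from_list(arch), rng);
  // encoder pyramid for documentation / construction-time assertions
  return List::create(
    Rcpp::Named("enc_flat") = M.enc_l.flat,
    Rcpp::Named("enc_stages") = IntegerVector::create(
      M.enc_l.c1.g.oH, M.enc_l.c1.g.oW, M.enc_l.c2.g.oH, M.enc_l.c2.g.oW,
      M.enc_l.c3.g.oH, M.enc_l.c3.g.oW),
    Rcpp::Named("ext_flat") = M.ext.c2.g.P * M.a.ext_ch[1],
    Rcpp::Named("emb_dim") = M.a.ext_dense);
}

// ---------------------------------------------------------------------------
// Exported: inference-mode module operations (z := mu, running statistics)

// [[Rcpp::export(name = ".nn_encode")]]
List nn_encode(List params, List arch, const arma::fmat& X, std::string side) {
  Rng rng(1);
  Model M; M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  mat mu, lv;
  if (side == "left") M.enc_l.forward(X, false, false, false, mu, lv);
  else M.enc_r.forward(X, false, false, false, mu, lv);
  return List::create(Rcpp::Named("mu") = mu, Rcpp::Named("log_var") = lv);
}

// [[Rcpp::export(name = ".nn_decode")]]
arma::fmat nn_decode(List params, List arch, const arma::fmat& Z, std::string side) {
  Rng rng(1);
  Model M; M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  return (side == "left") ? M.dec_l.forward(Z, false, false, false)
                          : M.dec_r.forward(Z, false, false, false);
}

// [[Rcpp::export(name = ".nn_bilateral")]]
arma::fmat nn_bilateral(List params, List arch, const arma::fmat& Zl, const arma::fmat& Zr) {
  Rng rng(1);
  Model M; M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  mat X = M.ext.stack(Zl, Zr);
  return M.ext.forward(X, false, false, false);
}

// [[Rcpp::export(name = ".nn_head")]]
arma::fmat nn_head(List params, List arch, const arma::fmat& emb, std::string which) {
  Rng rng(1);
  Model M; M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  return (which == "classifier") ? M.cls.forward(emb, false, false, false)
                                 : M.dsc.forward(emb, false, false, false);
}

// Full inference pass: probabilities, embeddings, hemispheric means.
// [[Rcpp::export(name = ".nn_predict")]]
List nn_predict(List params, List arch, const arma::fmat& Xl, const arma::fmat& Xr) {
  Rng rng(1);
  Model M; M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  StepOpts o; o.hemi = M.a.hemi; o.sample_z = false; o.use_kl = false;
  SharedCache sc;
  shared_forward(M, Xl, Xr, o, false, false, false, nullptr, sc);
  mat probs = M.cls.forward(sc.emb, false, false, false);
  mat sprob = M.dsc.forward(sc.emb, false, false, false);
  List out = List::create(
    Rcpp::Named("probs") = probs,
    Rcpp::Named("emb") = sc.emb,
    Rcpp::Named("subject_probs") = sprob);
  if (M.a.hemi != 2) out["mu_l"] = sc.mu_l;
  if (M.a.hemi != 1) out["mu_r"] = sc.mu_r;
  return out;
}

// ---------------------------------------------------------------------------
// Exported: loss+gradient probes (finite-difference oracles in the tests)

static StepOpts opts_from_list(const List& o) {
  StepOpts s;
  if (o.containsElementNamed("lr")) s.lr = Rcpp::as<double>(o["lr"]);
  if (o.containsElementNamed("disc_lr_mult")) s.disc_lr_mult = Rcpp::as<double>(o["disc_lr_mult"]);
  if (o.containsElementNamed("disc_steps")) s.disc_steps = Rcpp::as<int>(o["disc_steps"]);
  if (o.containsElementNamed("beta")) s.beta = Rcpp::as<double>(o["beta"]);
  if (o.containsElementNamed("lambda")) s.lambda = Rcpp::as<double>(o["lambda"]);
  if (o.containsElementNamed("use_recon")) s.use_recon = Rcpp::as<bool>(o["use_recon"]);
  if (o.containsElementNamed("use_kl")) s.use_kl = Rcpp::as<bool>(o["use_kl"]);
  if (o.containsElementNamed("use_disc")) s.use_disc = Rcpp::as<bool>(o["use_disc"]);
  if (o.containsElementNamed("sample_z")) s.sample_z = Rcpp::as<bool>(o["sample_z"]);
  if (o.containsElementNamed("hemi")) s.hemi = Rcpp::as<int>(o["hemi"]);
  return s;
}

// Deterministic (eps supplied or z = mu) VAE loss and parameter gradients for
// the left hemisphere; used by finite-difference tests of the backward pass.
// [[Rcpp::export(name = ".nn_vae_grad")]]
List nn_vae_grad(List params, List arch, const arma::fmat& X, double beta, bool sample,
                 Rcpp::Nullable<Rcpp::NumericMatrix> eps_ = R_NilValue) {
  Rng rng(1);
  Model M; M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  std::vector<Param*> ps = M.group("enc");
  std::vector<Param*> pd = M.group("dec");
  ps.insert(ps.end(), pd.begin(), pd.end());
  M.zero_grads(ps);

  mat mu, lv;
  M.enc_l.forward(X, true, false, true, mu, lv);
  mat eps;
  if (sample && eps_.isNotNull()) eps = Rcpp::as<mat>(eps_);
  mat z = sample ? mat(mu + arma::exp(0.5 * lv) % eps) : mu;
  mat xhat = M.dec_l.forward(z, true, false, true);
  double recon = mse_loss(X, xhat);
  double kl = kl_loss(mu, lv);
  double loss = recon + beta * kl;

  double N = (double)X.n_cols;
  mat dxhat = 2.0 * (xhat - X) / (double)X.n_elem;
  mat dz = M.dec_l.backward(dxhat);
  mat dmu = dz;
  mat dlv = sample ? mat(dz % eps % (0.5 * arma::exp(0.5 * lv)))
                   : arma::zeros<mat>(lv.n_rows, lv.n_cols);
  dmu += beta * mu / N;
  dlv += beta * 0.5 * (arma::exp(lv) - 1.0) / N;
  M.enc_l.backward(dmu, dlv);

  List grads;
  for (Param* p : M.group("enc")) grads[p->name] = Rcpp::wrap(p->G);
  for (Param* p : M.group("dec")) grads[p->name] = Rcpp::wrap(p->G);
  return List::create(Rcpp::Named("loss") = loss, Rcpp::Named("recon") = recon,
                      Rcpp::Named("kl") = kl, Rcpp::Named("grads") = grads);
}

// Supervised loss (emotion CE - lambda * subject CE through gradient
// reversal) and gradients; deterministic (z = mu, batch statistics).
// [[Rcpp::export(name = ".nn_adv_grad")]]
List nn_adv_grad(List params, List arch, const arma::fmat& Xl, const arma::fmat& Xr,
                 IntegerVector y, IntegerVector s, double lambda) {
  Rng rng(1);
  Model M; M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  std::vector<Param*> ps = M.all_params();
  M.zero_grads(ps);

  StepOpts o; o.hemi = M.a.hemi; o.sample_z = false; o.use_kl = false;
  SharedCache sc;
  shared_forward(M, Xl, Xr, o, true, false, true, nullptr, sc);
  int N = sc.emb.n_cols;
  uvec idx = arma::regspace<uvec>(0, N - 1);
  mat py = M.cls.forward(sc.emb, true, false, true);
  mat pd = M.dsc.forward(sc.emb, true, false, true);
  double ly = ce_loss(py, y, idx);
  double ld = ce_loss(pd, s, idx);

  mat demb = M.cls.backward(ce_dlogits(py, y, idx));
  // gradient reversal: the subject loss back-propagates through the
  // discriminator stack, then flips sign and scales by lambda upstream
  mat demb_d = M.dsc.backward(ce_dlogits(pd, s, idx));
  demb += (-lambda) * demb_d;
  shared_backward(M, o, sc, demb);

  List grads;
  for (Param* p : ps) grads[p->name] = Rcpp::wrap(p->G);
  return List::create(Rcpp::Named("loss_y") = ly, Rcpp::Named("loss_d") = ld,
                      Rcpp::Named("loss") = ly - lambda * ld,
                      Rcpp::Named("grads") = grads);
}

// ---------------------------------------------------------------------------
// Interleaved training step (exported individually for isolation tests)

static void do_vae_step(Model& M, const mat& Xl, const mat& Xr, const StepOpts& o,
                        Rng& rng, double& recon_l, double& recon_r,
                        double& kl_l, double& kl_r) {
  recon_l = recon_r = kl_l = kl_r = arma::datum::nan;
  std::vector<Param*> ps = M.group("enc");
  std::vector<Param*> pd = M.group("dec");
  ps.insert(ps.end(), pd.begin(), pd.end());
  M.zero_grads(ps);
  if (o.hemi != 2) vae_pass(M.enc_l, M.dec_l, Xl, o, rng, M, "enc_l", true, recon_l, kl_l);
  if (o.hemi != 1) vae_pass(M.enc_r, M.dec_r, Xr, o, rng, M, "enc_r", true, recon_r, kl_r);
  M.step(ps, o.lr);
}

static void do_disc_step(Model& M, const mat& Xl, const mat& Xr, const IntegerVector& s,
                         const uvec& idx, const StepOpts& o, Rng& rng,
                         double& loss_d, double& acc_d) {
  std::vector<Param*> ps = M.group("dsc");
  M.zero_grads(ps);
  StepOpts od = o;
  SharedCache sc;
  // frozen shared path: batch statistics, no buffer updates, no grads kept
  shared_forward(M, Xl, Xr, od, true, false, false, &rng, sc);
  mat pd = M.dsc.forward(sc.emb, true, true, true);
  loss_d = ce_loss(pd, s, idx);
  acc_d = acc(pd, s, idx);
  M.dsc.backward(ce_dlogits(pd, s, idx));
  M.step(ps, o.lr * o.disc_lr_mult);
}

static void do_adv_step(Model& M, const mat& Xl, const mat& Xr, const IntegerVector& y,
                        const IntegerVector& s, const uvec& idx, const StepOpts& o,
                        Rng& rng, double& loss_y, double& acc_y, double& loss_d_out) {
  std::vector<Param*> ps = M.group("enc");
  std::vector<Param*> pe = M.group("ext");
  std::vector<Param*> pc = M.group("cls");
  ps.insert(ps.end(), pe.begin(), pe.end());
  ps.insert(ps.end(), pc.begin(), pc.end());
  std::vector<Param*> pd = M.group("dsc");
  M.zero_grads(ps);
  M.zero_grads(pd);  // discriminator grads accumulate but are not stepped

  StepOpts od = o;
  SharedCache sc;
  shared_forward(M, Xl, Xr, od, true, true, true, &rng, sc);
  mat py = M.cls.forward(sc.emb, true, true, true);
  loss_y = ce_loss(py, y, idx);
  acc_y = acc(py, y, idx);
  mat demb = M.cls.backward(ce_dlogits(py, y, idx));
  loss_d_out = arma::datum::nan;
  if (o.use_disc && o.lambda != 0.0) {
    mat pdp = M.dsc.forward(sc.emb, true, false, true);
    loss_d_out = ce_loss(pdp, s, idx);
    mat demb_d = M.dsc.backward(ce_dlogits(pdp, s, idx));
    demb += (-o.lambda) * demb_d;
  }
  shared_backward(M, od, sc, demb);
  M.step(ps, o.lr);
}

// Fused supervised update used by the training loop: one shared forward
// serves both the discriminator step and the adversarial classification
// step.  The discriminator step only updates theta_d (the shared path and
// its statistics are frozen for it), so this is arithmetically the same as
// running the two steps with separate forward passes, at two-thirds of the
// cost.  The reversal pass re-runs the (cheap) discriminator head forward
// after its update so the adversarial gradient sees the improved
// discriminator, exactly as in the sequential formulation.
static void do_sup_fused(Model& M, const mat& Xl, const mat& Xr,
                         const IntegerVector& y, const IntegerVector& s,
                         const uvec& idx, const StepOpts& o, Rng& rng,
                         double& loss_d, double& acc_d,
                         double& loss_y, double& acc_y) {
  loss_d = acc_d = arma::datum::nan;
  StepOpts od = o;
  SharedCache sc;
  shared_forward(M, Xl, Xr, od, true, true, true, &rng, sc);
  std::vector<Param*> pd = M.group("dsc");
  if (o.use_disc) {
    for (int it = 0; it < std::max(1, o.disc_steps); ++it) {
      M.zero_grads(pd);
      mat pdp = M.dsc.forward(sc.emb, true, it == 0, true);
      loss_d = ce_loss(pdp, s, idx);
      acc_d = acc(pdp, s, idx);
      M.dsc.backward(ce_dlogits(pdp, s, idx));
      M.step(pd, o.lr * o.disc_lr_mult);
    }
  }
  std::vector<Param*> ps = M.group("enc");
  std::vector<Param*> pe = M.group("ext");
  std::vector<Param*> pc = M.group("cls");
  ps.insert(ps.end(), pe.begin(), pe.end());
  ps.insert(ps.end(), pc.begin(), pc.end());
  M.zero_grads(ps);
  mat py = M.cls.forward(sc.emb, true, true, true);
  loss_y = ce_loss(py, y, idx);
  acc_y = acc(py, y, idx);
  mat demb = M.cls.backward(ce_dlogits(py, y, idx));
  if (o.use_disc && o.lambda != 0.0) {
    M.zero_grads(pd);
    mat pdp = M.dsc.forward(sc.emb, true, false, true);
    mat demb_d = M.dsc.backward(ce_dlogits(pdp, s, idx));
    demb += (-o.lambda) * demb_d;
  }
  shared_backward(M, od, sc, demb);
  M.step(ps, o.lr);
}

// [[Rcpp::export(name = ".nn_step")]]
List nn_step(List params, List arch, const arma::fmat& Xl, const arma::fmat& Xr,
             IntegerVector y, IntegerVector s, List opts, std::string which, int seed) {
  Rng rng((uint64_t)seed);
  Model M; M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  StepOpts o = opts_from_list(opts);
  o.hemi = M.a.hemi;
  int N = (o.hemi == 2) ? Xr.n_cols : Xl.n_cols;
  uvec idx = arma::regspace<uvec>(0, N - 1);
  double a1, a2, a3, a4;
  if (which == "vae") do_vae_step(M, Xl, Xr, o, rng, a1, a2, a3, a4);
  else if (which == "disc") do_disc_step(M, Xl, Xr, s, idx, o, rng, a1, a2);
  else if (which == "adv") do_adv_step(M, Xl, Xr, y, s, idx, o, rng, a1, a2, a3);
  else Rcpp::stop("unknown step");
  return M.to_list();
}

// ---------------------------------------------------------------------------
// Training loops

static double ramp_value(int epoch, double maxv, int ramp_epochs) {
  if (ramp_epochs <= 0) return maxv;
  double f = (double)epoch / (double)ramp_epochs;
  return std::min(f, 1.0) * maxv;
}

// [[Rcpp::export(name = ".nn_pretrain")]]
List nn_pretrain(List params, List arch, const arma::fmat& Xl, const arma::fmat& Xr,
                 List opts) {
  Model M;
  StepOpts base = opts_from_list(opts);
  int epochs = Rcpp::as<int>(opts["epochs"]);
  int batch = Rcpp::as<int>(opts["batch"]);
  double beta_max = Rcpp::as<double>(opts["beta_max"]);
  int beta_ramp = Rcpp::as<int>(opts["beta_ramp"]);
  int seed = Rcpp::as<int>(opts["seed"]);
  Rng rng((uint64_t)seed);
  M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  base.hemi = M.a.hemi;

  mat Xlp, Xrp;
  const mat* pXl = &Xl; const mat* pXr = &Xr;
  if (M.a.pool > 1) {
    if (base.hemi != 2) { Xlp = avg_pool(Xl, M.a.H, M.a.W, M.a.C, M.a.pool); pXl = &Xlp; }
    if (base.hemi != 1) { Xrp = avg_pool(Xr, M.a.H, M.a.W, M.a.C, M.a.pool); pXr = &Xrp; }
    M.use_prepooled_data();
  }

  int N = (base.hemi == 2) ? pXr->n_cols : pXl->n_cols;
  dmat hist(epochs, 6);
  for (int ep = 0; ep < epochs; ++ep) {
    StepOpts o = base;
    o.beta = ramp_value(ep, beta_max, beta_ramp);
    std::vector<int> perm = rng.permutation(N);
    double srl = 0, srr = 0, skl = 0, skr = 0; int nb = 0;
    for (int start = 0; start < N; start += batch) {
      int end = std::min(start + batch, N);
      if (end - start < 2) break;
      uvec bidx(end - start);
      for (int i = start; i < end; ++i) bidx(i - start) = perm[i];
      mat bXl = (base.hemi != 2) ? mat(pXl->cols(bidx)) : mat();
      mat bXr = (base.hemi != 1) ? mat(pXr->cols(bidx)) : mat();
      double rl, rr, kl, kr;
      do_vae_step(M, bXl, bXr, o, rng, rl, rr, kl, kr);
      if (base.hemi != 2) { srl += rl; skl += kl; }
      if (base.hemi != 1) { srr += rr; skr += kr; }
      ++nb;
    }
    hist(ep, 0) = ep + 1; hist(ep, 1) = o.beta;
    hist(ep, 2) = srl / std::max(nb, 1); hist(ep, 3) = srr / std::max(nb, 1);
    hist(ep, 4) = skl / std::max(nb, 1); hist(ep, 5) = skr / std::max(nb, 1);
  }
  return List::create(Rcpp::Named("params") = M.to_list(),
                      Rcpp::Named("history") = hist);
}

// [[Rcpp::export(name = ".nn_train")]]
List nn_train(List params, List arch, const arma::fmat& Xl, const arma::fmat& Xr,
              IntegerVector y, IntegerVector s, IntegerVector train_idx,
              IntegerVector val_idx, List opts) {
  Model M;
  StepOpts base = opts_from_list(opts);
  int epochs = Rcpp::as<int>(opts["epochs"]);
  int batch = Rcpp::as<int>(opts["batch"]);
  double beta_max = Rcpp::as<double>(opts["beta_max"]);
  int beta_ramp = Rcpp::as<int>(opts["beta_ramp"]);
  double lambda_max = Rcpp::as<double>(opts["lambda_max"]);
  int lambda_ramp = Rcpp::as<int>(opts["lambda_ramp"]);
  int patience = Rcpp::as<int>(opts["patience"]);
  int seed = Rcpp::as<int>(opts["seed"]);
  Rng rng((uint64_t)seed);
  M.setup(Arch::from_list(arch), rng);
  M.from_list(params);
  base.hemi = M.a.hemi;

  mat Xlp, Xrp;
  const mat* pXl = &Xl; const mat* pXr = &Xr;
  if (M.a.pool > 1) {
    if (base.hemi != 2) { Xlp = avg_pool(Xl, M.a.H, M.a.W, M.a.C, M.a.pool); pXl = &Xlp; }
    if (base.hemi != 1) { Xrp = avg_pool(Xr, M.a.H, M.a.W, M.a.C, M.a.pool); pXr = &Xrp; }
    M.use_prepooled_data();
  }

  int Ntr = train_idx.size(), Nval = val_idx.size();
  uvec vidx(Nval);
  for (int i = 0; i < Nval; ++i) vidx(i) = (arma::uword)val_idx[i];
  mat vXl, vXr;
  if (base.hemi != 2) vXl = pXl->cols(vidx);
  if (base.hemi != 1) vXr = pXr->cols(vidx);

  const int NC = 14;
  dmat hist(epochs, NC, arma::fill::value(arma::datum::nan));
  double best_val = -1.0;
  int best_epoch = 0, wait = 0, last_epoch = 0;
  Model::Snapshot best = M.snapshot();

  for (int ep = 0; ep < epochs; ++ep) {
    StepOpts o = base;
    o.beta = ramp_value(ep, beta_max, beta_ramp);
    o.lambda = base.use_disc ? ramp_value(ep, lambda_max, lambda_ramp) : 0.0;

    std::vector<int> perm = rng.permutation(Ntr);
    double srl = 0, srr = 0, skl = 0, skr = 0, sly = 0, sld = 0;
    double say = 0, sad = 0;
    int nb = 0, nb_vae = 0, nb_disc = 0;
    for (int start = 0; start < Ntr; start += batch) {
      int end = std::min(start + batch, Ntr);
      if (end - start < 2) break;
      int B = end - start;
      uvec bidx(B);
      IntegerVector by(B), bs(B);
      for (int i = 0; i < B; ++i) {
        bidx(i) = (arma::uword)train_idx[perm[start + i]];
        by[i] = y[bidx(i)]; bs[i] = s[bidx(i)];
      }
      mat bXl = (base.hemi != 2) ? mat(pXl->cols(bidx)) : mat();
      mat bXr = (base.hemi != 1) ? mat(pXr->cols(bidx)) : mat();
      uvec local = arma::regspace<uvec>(0, B - 1);
      IntegerVector byl(B), bsl(B);
      for (int i = 0; i < B; ++i) { byl[i] = by[i]; bsl[i] = bs[i]; }

      // (1) reconstruction step
      if (base.use_recon) {
        double rl, rr, kl, kr;
        do_vae_step(M, bXl, bXr, o, rng, rl, rr, kl, kr);
        if (base.hemi != 2) { srl += rl; skl += kl; }
        if (base.hemi != 1) { srr += rr; skr += kr; }
        ++nb_vae;
      }
      // (2) discriminator step + (3) adversarial classification step,
      // fused over one shared forward pass
      {
        double ld, ad, ly, ay;
        do_sup_fused(M, bXl, bXr, byl, bsl, local, o, rng, ld, ad, ly, ay);
        if (base.use_disc) { sld += ld; sad += ad; ++nb_disc; }
        sly += ly; say += ay;
      }
      ++nb;
    }

    // validation metrics in inference mode
    double vacc = arma::datum::nan, vdacc = arma::datum::nan;
    if (Nval > 0) {
      StepOpts oe = base; oe.sample_z = false;
      SharedCache sc;
      shared_forward(M, vXl, vXr, oe, false, false, false, nullptr, sc);
      mat py = M.cls.forward(sc.emb, false, false, false);
      uvec lidx = arma::regspace<uvec>(0, Nval - 1);
      IntegerVector vy(Nval), vs(Nval);
      for (int i = 0; i < Nval; ++i) { vy[i] = y[vidx(i)]; vs[i] = s[vidx(i)]; }
      vacc = acc(py, vy, lidx);
      if (base.use_disc) {
        mat pdp = M.dsc.forward(sc.emb, false, false, false);
        vdacc = acc(pdp, vs, lidx);
      }
    }

    double m_rl = base.use_recon && base.hemi != 2 ? srl / std::max(nb_vae, 1) : arma::datum::nan;
    double m_rr = base.use_recon && base.hemi != 1 ? srr / std::max(nb_vae, 1) : arma::datum::nan;
    double m_kl = base.use_recon && base.use_kl && base.hemi != 2 ? skl / std::max(nb_vae, 1) : arma::datum::nan;
    double m_kr = base.use_recon && base.use_kl && base.hemi != 1 ? skr / std::max(nb_vae, 1) : arma::datum::nan;
    double m_ly = sly / std::max(nb, 1);
    double m_ld = base.use_disc ? sld / std::max(nb_disc, 1) : arma::datum::nan;
    double tot = (std::isnan(m_rl) ? 0 : m_rl) + (std::isnan(m_rr) ? 0 : m_rr)
               + o.beta * ((std::isnan(m_kl) ? 0 : m_kl) + (std::isnan(m_kr) ? 0 : m_kr))
               + m_ly - o.lambda * (std::isnan(m_ld) ? 0 : m_ld);

    hist(ep, 0) = ep + 1; hist(ep, 1) = o.beta; hist(ep, 2) = o.lambda;
    hist(ep, 3) = m_rl; hist(ep, 4) = m_rr; hist(ep, 5) = m_kl; hist(ep, 6) = m_kr;
    hist(ep, 7) = m_ly; hist(ep, 8) = m_ld; hist(ep, 9) = tot;
    hist(ep, 10) = say / std::max(nb, 1); hist(ep, 11) = vacc;
    hist(ep, 12) = base.use_disc ? sad / std::max(nb_disc, 1) : arma::datum::nan;
    hist(ep, 13) = vdacc;
    last_epoch = ep + 1;

    // early stopping on emotion validation accuracy; ties keep the latest
    // equally good checkpoint (training continues to shape the embedding
    // after the accuracy plateaus) while patience counts strict gains only
    if (Nval > 0) {
      if (vacc >= best_val - 1e-12) {
        if (vacc > best_val + 1e-12) wait = 0; else ++wait;
        best_val = std::max(best_val, vacc); best_epoch = ep + 1;
        best = M.snapshot();
      } else ++wait;
      if (wait > patience) break;
    } else {
      best_epoch = ep + 1;
      best = M.snapshot();
    }
    Rcpp::checkUserInterrupt();
  }
  if (Nval > 0) M.restore(best);
  return List::create(Rcpp::Named("params") = M.to_list(),
                      Rcpp::Named("history") = dmat(hist.rows(0, last_epoch - 1)),
                      Rcpp::Named("best_epoch") = best_epoch);
}
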