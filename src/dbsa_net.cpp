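// Numerical core of the dual-branch selective-attention capsule network.
//
// Everything runs in single precision on top of BLAS sgemm. Data layouts:
//   * spectral-path tensors: (C*D, N) matrices, row index c + C*d,
//     one column per pixel; N folds batch and space (pixel-major, h fastest);
//   * spatial maps: (C, Npix*n) with per-sample column blocks;
//   * depth-only convolutions then reduce to submatrix-view GEMMs, and the
//     full-depth spectral collapse is a single GEMM.
// Backward passes are hand-derived, including the fully unrolled gradient
// of the dynamic-routing iterations.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>

using arma::fmat;
using arma::fvec;
using arma::frowvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOM = 0.1f;

// direct single-precision GEMM on strided submatrices (column-major);
// avoids the temporaries Armadillo materializes for subview operands
extern "C" void cblas_sgemm(int order, int transA, int transB, int M, int N,
                            int K, float alpha, const float* A, int lda,
                            const float* B, int ldb, float beta, float* C,
                            int ldc);
static inline void sgemm_strided(bool ta, bool tb, int M, int N, int K,
                                 float alpha, const float* A, int lda,
                                 const float* B, int ldb, float beta,
                                 float* C, int ldc) {
  cblas_sgemm(102 /*ColMajor*/, ta ? 112 : 111, tb ? 112 : 111, M, N, K,
              alpha, A, lda, B, ldb, beta, C, ldc);
}

static inline void relu_mask_inplace(fmat& dY, const fmat& Y) {
  float* d = dY.memptr();
  const float* y = Y.memptr();
  const arma::uword n = dY.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (y[i] <= 0.0f) d[i] = 0.0f;
}

// ---------------------------------------------------------------------------
// parameters + Adam state
// ---------------------------------------------------------------------------
struct Param {
  std::string name;
  fmat w, g, m, v;
  void init(const std::string& nm, int r, int c) {
    name = nm;
    w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

static void fill_normal(fmat& M, std::mt19937& rng, float sd) {
  std::normal_distribution<float> d(0.0f, sd);
  for (arma::uword i = 0; i < M.n_elem; ++i) M(i) = d(rng);
}

// ---------------------------------------------------------------------------
// layers
// ---------------------------------------------------------------------------

// depth-only convolution (d x 1 x 1 kernel, valid padding): per-pixel 1-D
// convolution along the band axis; covers the spectral stack and, with
// k == D, the spatial branch's full-depth collapse.
struct DepthConv {
  int Cin = 0, Cout = 0, k = 0, s = 0, Din = 0, Dout = 0;
  bool relu = true;
  Param W, b;  // W: (Cout, Cin*k)
  fmat X, Y;   // caches

  void build(const std::string& nm, int cin, int cout, int kk, int ss, int din,
             std::mt19937& rng) {
    Cin = cin; Cout = cout; k = kk; s = ss; Din = din;
    if (din < kk)
      Rcpp::stop("%s: band depth %d smaller than kernel %d", nm.c_str(), din, kk);
    Dout = (din - kk) / ss + 1;
    W.init(nm + ".weight", cout, cin * kk);
    b.init(nm + ".bias", cout, 1);
    fill_normal(W.w, rng, std::sqrt(2.0f / (cin * kk)));
  }
  const fmat& forward(const fmat& Xin, bool keep) {
    if ((int)Xin.n_rows != Cin * Din)
      Rcpp::stop("%s: expected %d input rows, got %d", W.name.c_str(),
                 Cin * Din, (int)Xin.n_rows);
    const int N = Xin.n_cols;
    const int ldx = Cin * Din, ldy = Cout * Dout;
    Y.set_size(ldy, N);
    for (int t = 0; t < Dout; ++t)
      sgemm_strided(false, false, Cout, N, Cin * k, 1.0f, W.w.memptr(), Cout,
                    Xin.memptr() + (size_t)t * s * Cin, ldx, 0.0f,
                    Y.memptr() + (size_t)t * Cout, ldy);
    // fused bias + rectifier pass
    float* yp = Y.memptr();
    const float* bp = b.w.memptr();
    for (size_t j = 0; j < (size_t)N; ++j) {
      float* col = yp + j * ldy;
      for (int t = 0; t < Dout; ++t) {
        float* blk = col + (size_t)t * Cout;
        for (int c = 0; c < Cout; ++c) {
          float v = blk[c] + bp[c];
          blk[c] = (relu && v < 0.0f) ? 0.0f : v;
        }
      }
    }
    if (keep) X = Xin;
    return Y;
  }
  fmat backward(fmat dY) {
    if (relu) relu_mask_inplace(dY, Y);
    const int N = X.n_cols;
    const int ldx = Cin * Din, ldy = Cout * Dout;
    fmat dX(ldx, N, arma::fill::zeros);
    for (int t = 0; t < Dout; ++t) {
      // W.g += dY_t X_win^T ; dX_win += W^T dY_t  (in place, beta = 1)
      sgemm_strided(false, true, Cout, Cin * k, N, 1.0f,
                    dY.memptr() + (size_t)t * Cout, ldy,
                    X.memptr() + (size_t)t * s * Cin, ldx, 1.0f,
                    W.g.memptr(), Cout);
      sgemm_strided(true, false, Cin * k, N, Cout, 1.0f, W.w.memptr(), Cout,
                    dY.memptr() + (size_t)t * Cout, ldy, 1.0f,
                    dX.memptr() + (size_t)t * s * Cin, ldx);
    }
    // bias gradient: per output channel, summed over depth and columns
    float* bg = b.g.memptr();
    const float* dp = dY.memptr();
    for (size_t j = 0; j < (size_t)N; ++j) {
      const float* col = dp + j * ldy;
      for (int t = 0; t < Dout; ++t) {
        const float* blk = col + (size_t)t * Cout;
        for (int c = 0; c < Cout; ++c) bg[c] += blk[c];
      }
    }
    X.reset(); Y.reset();
    return dX;
  }
};

// geometry helpers shared by Conv2d / ConvT2d ------------------------------
static void im2col(const float* x, int C, int H, int W, int k, int s, int p,
                   int Ho, int Wo, fmat& col) {
  col.zeros((arma::uword)C * k * k, (arma::uword)Ho * Wo);
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      arma::uword j = ho + (arma::uword)Ho * wo;
      float* cj = col.colptr(j);
      for (int kw = 0; kw < k; ++kw) {
        int w = wo * s - p + kw;
        if (w < 0 || w >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          int h = ho * s - p + kh;
          if (h < 0 || h >= H) continue;
          const float* xp = x + (arma::uword)C * (h + (arma::uword)H * w);
          float* cp = cj + (arma::uword)C * (kh + k * kw);
          std::copy(xp, xp + C, cp);
        }
      }
    }
}

static void col2im_add(const fmat& col, int C, int H, int W, int k, int s,
                       int p, int Ho, int Wo, float* x) {
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho) {
      arma::uword j = ho + (arma::uword)Ho * wo;
      const float* cj = col.colptr(j);
      for (int kw = 0; kw < k; ++kw) {
        int w = wo * s - p + kw;
        if (w < 0 || w >= W) continue;
        for (int kh = 0; kh < k; ++kh) {
          int h = ho * s - p + kh;
          if (h < 0 || h >= H) continue;
          float* xp = x + (arma::uword)C * (h + (arma::uword)H * w);
          const float* cp = cj + (arma::uword)C * (kh + k * kw);
          for (int c = 0; c < C; ++c) xp[c] += cp[c];
        }
      }
    }
}

// 2-D convolution over (C, H*W*n) maps; im2col + GEMM per sample, and the
// im2col buffer is recomputed in the backward pass instead of cached.
struct Conv2d {
  int Cin = 0, Cout = 0, k = 0, s = 0, p = 0, H = 0, Wd = 0, Ho = 0, Wo = 0;
  int act = 1;  // 0 none, 1 relu, 2 sigmoid
  Param W, b;   // W: (Cout, Cin*k*k)
  fmat X, Y;

  void build(const std::string& nm, int cin, int cout, int kk, int ss, int pp,
             int h, int w, std::mt19937& rng) {
    Cin = cin; Cout = cout; k = kk; s = ss; p = pp; H = h; Wd = w;
    if (h + 2 * pp < kk)
      Rcpp::stop("%s: spatial size %d smaller than kernel %d", nm.c_str(), h, kk);
    Ho = (h + 2 * pp - kk) / ss + 1;
    Wo = (w + 2 * pp - kk) / ss + 1;
    W.init(nm + ".weight", cout, cin * kk * kk);
    b.init(nm + ".bias", cout, 1);
    fill_normal(W.w, rng, std::sqrt(2.0f / (cin * kk * kk)));
  }
  const fmat& forward(const fmat& Xin, bool keep) {
    int n = Xin.n_cols / ((arma::uword)H * Wd);
    Y.set_size(Cout, (arma::uword)Ho * Wo * n);
    fmat col;
    fvec bv = b.w.col(0);
    for (int i = 0; i < n; ++i) {
      im2col(Xin.colptr((arma::uword)i * H * Wd), Cin, H, Wd, k, s, p, Ho, Wo, col);
      Y.cols((arma::uword)i * Ho * Wo, (arma::uword)(i + 1) * Ho * Wo - 1) = W.w * col;
      Y.cols((arma::uword)i * Ho * Wo, (arma::uword)(i + 1) * Ho * Wo - 1)
          .each_col() += bv;
    }
    if (act == 1) Y.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    if (act == 2) Y.transform([](float x) { return 1.0f / (1.0f + std::exp(-x)); });
    if (keep) X = Xin;
    return Y;
  }
  fmat backward(fmat dY) {
    if (act == 1) relu_mask_inplace(dY, Y);
    if (act == 2) dY %= Y % (1.0f - Y);
    int n = X.n_cols / ((arma::uword)H * Wd);
    fmat dX(X.n_rows, X.n_cols, arma::fill::zeros);
    fmat col;
    for (int i = 0; i < n; ++i) {
      im2col(X.colptr((arma::uword)i * H * Wd), Cin, H, Wd, k, s, p, Ho, Wo, col);
      fmat dYi = dY.cols((arma::uword)i * Ho * Wo, (arma::uword)(i + 1) * Ho * Wo - 1);
      W.g += dYi * col.t();
      b.g += arma::sum(dYi, 1);
      fmat dcol = W.w.t() * dYi;
      col2im_add(dcol, Cin, H, Wd, k, s, p, Ho, Wo,
                 dX.colptr((arma::uword)i * H * Wd));
    }
    X.reset(); Y.reset();
    return dX;
  }
};

// transposed 2-D convolution (used by the upsampling reconstruction decoder)
struct ConvT2d {
  int Cin = 0, Cout = 0, k = 0, s = 0, p = 0, Hi = 0, Wi = 0, Ho = 0, Wo = 0;
  bool relu = true;
  Param W, b;  // W: (Cout*k*k, Cin)
  fmat X, Y;

  void build(const std::string& nm, int cin, int cout, int kk, int ss, int pp,
             int hi, int wi, std::mt19937& rng) {
    Cin = cin; Cout = cout; k = kk; s = ss; p = pp; Hi = hi; Wi = wi;
    Ho = (hi - 1) * ss - 2 * pp + kk;
    Wo = (wi - 1) * ss - 2 * pp + kk;
    W.init(nm + ".weight", cout * kk * kk, cin);
    b.init(nm + ".bias", cout, 1);
    fill_normal(W.w, rng, std::sqrt(2.0f / (cin * kk * kk)));
  }
  const fmat& forward(const fmat& Xin, bool keep) {
    int n = Xin.n_cols / ((arma::uword)Hi * Wi);
    Y.zeros(Cout, (arma::uword)Ho * Wo * n);
    fvec bv = b.w.col(0);
    for (int i = 0; i < n; ++i) {
      fmat dcol = W.w * Xin.cols((arma::uword)i * Hi * Wi,
                                 (arma::uword)(i + 1) * Hi * Wi - 1);
      col2im_add(dcol, Cout, Ho, Wo, k, s, p, Hi, Wi,
                 Y.colptr((arma::uword)i * Ho * Wo));
      Y.cols((arma::uword)i * Ho * Wo, (arma::uword)(i + 1) * Ho * Wo - 1)
          .each_col() += bv;
    }
    if (relu) Y.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    if (keep) X = Xin;
    return Y;
  }
  fmat backward(fmat dY) {
    if (relu) relu_mask_inplace(dY, Y);
    int n = X.n_cols / ((arma::uword)Hi * Wi);
    fmat dX(X.n_rows, X.n_cols);
    fmat col;
    for (int i = 0; i < n; ++i) {
      fmat dYi = dY.cols((arma::uword)i * Ho * Wo, (arma::uword)(i + 1) * Ho * Wo - 1);
      b.g += arma::sum(dYi, 1);
      im2col(dYi.colptr(0), Cout, Ho, Wo, k, s, p, Hi, Wi, col);
      fmat Xi = X.cols((arma::uword)i * Hi * Wi, (arma::uword)(i + 1) * Hi * Wi - 1);
      W.g += col * Xi.t();
      dX.cols((arma::uword)i * Hi * Wi, (arma::uword)(i + 1) * Hi * Wi - 1) =
          W.w.t() * col;
    }
    X.reset(); Y.reset();
    return dX;
  }
};

struct Dense {
  int in = 0, out = 0, act = 0;  // 0 none, 1 relu, 2 sigmoid
  Param W, b;
  fmat X, Y;
  void build(const std::string& nm, int i, int o, int a, std::mt19937& rng) {
    in = i; out = o; act = a;
    W.init(nm + ".weight", o, i);
    b.init(nm + ".bias", o, 1);
    fill_normal(W.w, rng, act == 2 ? std::sqrt(1.0f / i) : std::sqrt(2.0f / i));
  }
  const fmat& forward(const fmat& Xin, bool keep) {
    Y = W.w * Xin;
    Y.each_col() += fvec(b.w.col(0));
    if (act == 1) Y.transform([](float x) { return x > 0.0f ? x : 0.0f; });
    if (act == 2) Y.transform([](float x) { return 1.0f / (1.0f + std::exp(-x)); });
    if (keep) X = Xin;
    return Y;
  }
  fmat backward(fmat dY) {
    if (act == 1) relu_mask_inplace(dY, Y);
    if (act == 2) dY %= Y % (1.0f - Y);
    W.g += dY * X.t();
    b.g += arma::sum(dY, 1);
    fmat dX = W.w.t() * dY;
    X.reset(); Y.reset();
    return dX;
  }
};

// batch normalization over channels (rows); columns are positions x samples
struct BatchNorm {
  int C = 0;
  Param gamma, beta;
  fvec rmean, rvar;  // running statistics (buffers)
  fmat xhat;
  fvec invstd;
  void build(const std::string& nm, int c) {
    C = c;
    gamma.init(nm + ".gamma", c, 1); gamma.w.ones();
    beta.init(nm + ".beta", c, 1);
    rmean.zeros(c); rvar.ones(c);
  }
  const fmat& forward(const fmat& X, bool train, fmat& out) {
    if (train) {
      fvec mu = arma::mean(X, 1);
      fmat cent = X.each_col() - mu;
      fvec var = arma::mean(arma::square(cent), 1);
      invstd = 1.0f / arma::sqrt(var + BN_EPS);
      xhat = cent.each_col() % invstd;
      rmean = (1.0f - BN_MOM) * rmean + BN_MOM * mu;
      rvar = (1.0f - BN_MOM) * rvar + BN_MOM * var;
      out = xhat.each_col() % fvec(gamma.w.col(0));
      out.each_col() += fvec(beta.w.col(0));
    } else {
      fvec is = 1.0f / arma::sqrt(rvar + BN_EPS);
      out = (X.each_col() - rmean).each_col() % (is % fvec(gamma.w.col(0)));
      out.each_col() += fvec(beta.w.col(0));
    }
    return out;
  }
  fmat backward(const fmat& dY) {
    float M = (float)dY.n_cols;
    gamma.g += arma::sum(dY % xhat, 1);
    beta.g += arma::sum(dY, 1);
    fmat dxhat = dY.each_col() % fvec(gamma.w.col(0));
    fvec s1 = arma::sum(dxhat, 1);
    fvec s2 = arma::sum(dxhat % xhat, 1);
    fmat dX = dxhat * M;
    dX.each_col() -= s1;
    dX -= xhat.each_col() % s2;
    dX.each_col() %= (invstd / M);
    xhat.reset();
    return dX;
  }
};

// squeeze-and-excitation channel descriptor: global average pool ->
// bottleneck affine -> rectifier -> affine -> sigmoid
struct SEBlock {
  int C = 0, red = 0;
  Dense fc1, fc2;
  int Npix = 0;
  void build(const std::string& nm, int c, int reduction, std::mt19937& rng) {
    C = c; red = reduction;
    fc1.build(nm + ".fc1", c, c / reduction, 1, rng);
    fc2.build(nm + ".fc2", c / reduction, c, 2, rng);
  }
  // U: (C, Npix*n) -> z: (C, n)
  fmat forward(const fmat& U, int npix, bool keep) {
    Npix = npix;
    int n = U.n_cols / npix;
    fmat pooled(C, n);
    for (int i = 0; i < n; ++i)
      pooled.col(i) = arma::mean(U.cols((arma::uword)i * npix,
                                        (arma::uword)(i + 1) * npix - 1), 1);
    return fc2.forward(fc1.forward(pooled, keep), keep);
  }
  // returns the pooled-path gradient dU (C, Npix*n)
  fmat backward(const fmat& dz) {
    fmat dpool = fc1.backward(fc2.backward(dz));
    int n = dpool.n_cols;
    fmat dU(C, (arma::uword)Npix * n);
    for (int i = 0; i < n; ++i)
      dU.cols((arma::uword)i * Npix, (arma::uword)(i + 1) * Npix - 1) =
          arma::repmat(dpool.col(i) / (float)Npix, 1, Npix);
    return dU;
  }
};

// ---------------------------------------------------------------------------
// squash and routing helpers
// ---------------------------------------------------------------------------
static void squash_cols(const fmat& S, fmat& V) {
  V.set_size(S.n_rows, S.n_cols);
  for (arma::uword j = 0; j < S.n_cols; ++j) {
    float n2 = arma::dot(S.col(j), S.col(j));
    float n = std::sqrt(n2 + 1e-12f);
    V.col(j) = S.col(j) * (n / (1.0f + n2));
  }
}

static void squash_backward_cols(const fmat& dV, const fmat& S, fmat& dS) {
  dS.set_size(S.n_rows, S.n_cols);
  for (arma::uword j = 0; j < S.n_cols; ++j) {
    float n2 = arma::dot(S.col(j), S.col(j));
    float n = std::sqrt(n2 + 1e-12f);
    float a = 1.0f / (1.0f + n2);
    float sd = arma::dot(S.col(j), dV.col(j));
    dS.col(j) = n * a * dV.col(j) + S.col(j) * (a * (1.0f / n - 2.0f * n * a) * sd);
  }
}

static void softmax_rows_percol(const fmat& B, fmat& C) {
  // softmax over rows (output capsules), independently per column
  frowvec mx = arma::max(B, 0);
  C = arma::exp(B.each_row() - mx);
  frowvec s = arma::sum(C, 0);
  C.each_row() /= s;
}

// routing by agreement; caches per iteration for the unrolled backward
struct RoutingCache {
  std::vector<fmat> c, s, v;  // per iteration: c (K, ncaps), s/v (16, K)
};

static fmat route_forward(const fmat& uh, int K, int dout, int iters,
                          RoutingCache* cache) {
  int ncaps = uh.n_cols;
  fmat b(K, ncaps, arma::fill::zeros), c, s(dout, K), v;
  for (int it = 0; it < iters; ++it) {
    softmax_rows_percol(b, c);
    for (int j = 0; j < K; ++j)
      s.col(j) = uh.rows(j * dout, (j + 1) * dout - 1) * c.row(j).t();
    squash_cols(s, v);
    if (it < iters - 1)
      for (int j = 0; j < K; ++j)
        b.row(j) += v.col(j).t() * uh.rows(j * dout, (j + 1) * dout - 1);
    if (cache) { cache->c.push_back(c); cache->s.push_back(s); cache->v.push_back(v); }
  }
  return v;
}

static fmat route_backward(const fmat& uh, const RoutingCache& cache,
                           const fmat& dv_out, int K, int dout) {
  int iters = cache.c.size();
  int ncaps = uh.n_cols;
  fmat duh(uh.n_rows, ncaps, arma::fill::zeros);
  fmat db(K, ncaps, arma::fill::zeros);  // dL/db_{it+1} carry
  for (int it = iters - 1; it >= 0; --it) {
    fmat dv(dout, K, arma::fill::zeros);
    if (it == iters - 1) dv = dv_out;
    if (it < iters - 1) {
      // b_{it+1} = b_it + <uh, v_it>;  db holds dL/db_{it+1}
      for (int j = 0; j < K; ++j) {
        duh.rows(j * dout, (j + 1) * dout - 1) += cache.v[it].col(j) * db.row(j);
        dv.col(j) += uh.rows(j * dout, (j + 1) * dout - 1) * db.row(j).t();
      }
    }
    fmat ds;
    squash_backward_cols(dv, cache.s[it], ds);
    fmat dc(K, ncaps);
    for (int j = 0; j < K; ++j) {
      dc.row(j) = ds.col(j).t() * uh.rows(j * dout, (j + 1) * dout - 1);
      duh.rows(j * dout, (j + 1) * dout - 1) += ds.col(j) * cache.c[it].row(j);
    }
    frowvec dots = arma::sum(cache.c[it] % dc, 0);
    db += cache.c[it] % (dc.each_row() - dots);  // softmax backward per column
  }
  return duh;
}

// ---------------------------------------------------------------------------
// the network
// ---------------------------------------------------------------------------
struct Net {
  std::string variant;
  int bands = 150, H = 64, Wsp = 64, nclass = 3, iters = 3;
  bool use_spe = true, use_spa = true, use_att = true, hybrid = false;
  bool caps_head = true;
  int rec = 0;
  int Cf = 256;           // fused channel count entering the head
  int ctypes = 64, cdim = 8, ddim = 16, grid = 9, ncaps = 5184;
  float m_plus = 0.9f, m_minus = 0.1f, lambda_down = 0.5f;
  float rec_scale = 0.0005f;

  // layers
  DepthConv sp1, sp2, sp3;          // spectral stack
  DepthConv collapse;               // spatial branch spectral collapse
  Conv2d sa1, sa2;                  // spatial 3x3 stack
  Conv2d hyb;                       // hybrid variant's 2-D layer
  SEBlock se_spe, se_spa;
  Conv2d prim; BatchNorm bn;        // primary capsule projection
  std::vector<Param> Wd;            // digit transforms: cdim mats (K*ddim, ncaps)
  Conv2d headconv; Dense fc;        // convolutional + affine head (DBNet/DBSA)
  Dense r1a, r1b, r1c;              // reconstruction decoders
  Dense r2fc; Conv2d r2conv;
  Dense r3fc; ConvT2d r3up; Conv2d r3conv;

  std::vector<Param*> params;
  std::vector<BatchNorm*> bns;
  long long adam_t = 0;

  // per-microbatch caches
  int Npix = 0, grid2 = 0;
  fmat Uspe, Uspa, att1, att2, Vmap;
  fmat bn_out;
  std::vector<fmat> u_pre_c, u_c, uh_c;
  std::vector<RoutingCache> rc_c;
  fmat digit_v;  // (ddim, K*n)
  fmat input_c;  // kept when a reconstruction decoder is attached

  void reg(Param& p) { params.push_back(&p); }

  void build(const std::string& var, int nb, int h, int w, int ncls, int it,
             unsigned int seed) {
    variant = var; bands = nb; H = h; Wsp = w; nclass = ncls; iters = it;
    std::mt19937 rng(seed);
    if (var == "DBSACaps") { }
    else if (var == "DBCaps") { use_att = false; }
    else if (var == "DBSA") { caps_head = false; }
    else if (var == "DBNet") { use_att = false; caps_head = false; }
    else if (var == "SpectralCaps") { use_spa = false; use_att = false; }
    else if (var == "SpatialCaps") { use_spe = false; use_att = false; }
    else if (var == "HybridCaps") { use_spa = false; use_att = false; hybrid = true; }
    else if (var == "DBSACapsWithRec1") { rec = 1; }
    else if (var == "DBSACapsWithRec2") { rec = 2; }
    else if (var == "DBSACapsWithRec3") { rec = 3; }
    else Rcpp::stop("unknown variant '%s'; valid: DBSACaps, DBCaps, DBSA, DBNet, "
                    "HybridCaps, SpectralCaps, SpatialCaps, DBSACapsWithRec1, "
                    "DBSACapsWithRec2, DBSACapsWithRec3", var.c_str());
    if (h < 6 || w < 6) Rcpp::stop("spatial size must be at least 6x6");
    Npix = h * w;

    if (use_spe) {
      sp1.build("spectral.conv1", 1, 64, 7, 2, bands, rng);
      sp2.build("spectral.conv2", 64, 64, 7, 2, sp1.Dout, rng);
      if (sp2.Dout != 33)
        Rcpp::stop("spectral.conv3 (3DConv_3) requires band depth 33 after the "
                   "second layer; %d bands give %d", bands, sp2.Dout);
      sp3.build("spectral.conv3", 64, 128, 33, 1, sp2.Dout, rng);
      if (hybrid) hyb.build("hybrid.conv2d", 128, 128, 3, 1, 1, h, w, rng);
    }
    if (use_spa) {
      if (bands != 150)
        Rcpp::stop("spatial.collapse (3DConv_4) is configured for 150 bands, got %d",
                   bands);
      collapse.build("spatial.collapse", 1, 64, bands, 1, bands, rng);
      sa1.build("spatial.conv1", 64, 64, 3, 1, 1, h, w, rng);
      sa2.build("spatial.conv2", 64, 128, 3, 1, 1, h, w, rng);
    }
    Cf = (use_spe && use_spa) ? 256 : 128;
    if (use_att) {
      se_spe.build("se.spectral", 128, 16, rng);
      se_spa.build("se.spatial", 128, 16, rng);
    }
    if (caps_head) {
      prim.build("caps.primary_conv", Cf, ctypes * cdim, 6, 7, 0, h, w, rng);
      prim.act = 0;
      grid = prim.Ho; grid2 = grid * prim.Wo; ncaps = ctypes * grid2;
      bn.build("caps.primary_bn", ctypes * cdim);
      reg(bn.gamma); reg(bn.beta); bns.push_back(&bn);
      Wd.resize(cdim);
      for (int d = 0; d < cdim; ++d) {
        // scaled so initial digit lengths sit mid-range, clear of squash
        // saturation at both ends
        Wd[d].init("caps.digit_w" + std::to_string(d), nclass * ddim, ncaps);
        fill_normal(Wd[d].w, rng, 0.02f);
        reg(Wd[d]);
      }
    } else {
      headconv.build("head.conv", Cf, 64, 6, 7, 0, h, w, rng);
      grid = headconv.Ho; grid2 = grid * headconv.Wo;
      fc.build("head.fc", 64 * grid2, nclass, 0, rng);
    }
    if (rec == 1) {
      r1a.build("rec1.fc1", nclass * ddim, 512, 1, rng);
      r1b.build("rec1.fc2", 512, 1024, 1, rng);
      r1c.build("rec1.fc3", 1024, bands * Npix, 2, rng);
    } else if (rec == 2) {
      r2fc.build("rec2.fc", nclass * ddim, Npix, 1, rng);
      r2conv.build("rec2.conv", 1, bands, 3, 1, 1, H, Wsp, rng);
      r2conv.act = 2;
    } else if (rec == 3) {
      if (H % 2 != 0 || Wsp % 2 != 0)
        Rcpp::stop("rec3.upconv: the upsampling decoder requires even spatial size");
      r3fc.build("rec3.fc", nclass * ddim, (H / 2) * (Wsp / 2), 1, rng);
      r3up.build("rec3.upconv", 1, 16, 4, 2, 1, H / 2, Wsp / 2, rng);
      r3conv.build("rec3.conv", 16, bands, 3, 1, 1, H, Wsp, rng);
      r3conv.act = 2;
    }

    // registration order fixes the flat-parameter layout
    if (use_spe) {
      reg(sp1.W); reg(sp1.b); reg(sp2.W); reg(sp2.b); reg(sp3.W); reg(sp3.b);
      if (hybrid) { reg(hyb.W); reg(hyb.b); }
    }
    if (use_spa) {
      reg(collapse.W); reg(collapse.b); reg(sa1.W); reg(sa1.b);
      reg(sa2.W); reg(sa2.b);
    }
    if (use_att) {
      reg(se_spe.fc1.W); reg(se_spe.fc1.b); reg(se_spe.fc2.W); reg(se_spe.fc2.b);
      reg(se_spa.fc1.W); reg(se_spa.fc1.b); reg(se_spa.fc2.W); reg(se_spa.fc2.b);
    }
    if (caps_head) { reg(prim.W); reg(prim.b); }
    else { reg(headconv.W); reg(headconv.b); reg(fc.W); reg(fc.b); }
    if (rec == 1) { reg(r1a.W); reg(r1a.b); reg(r1b.W); reg(r1b.b); reg(r1c.W); reg(r1c.b); }
    if (rec == 2) { reg(r2fc.W); reg(r2fc.b); reg(r2conv.W); reg(r2conv.b); }
    if (rec == 3) { reg(r3fc.W); reg(r3fc.b); reg(r3up.W); reg(r3up.b);
                    reg(r3conv.W); reg(r3conv.b); }
  }

  long long n_params() const {
    long long n = 0;
    for (const Param* p : params) n += (long long)p->w.n_elem;
    return n;
  }

  // ---- forward -----------------------------------------------------------
  // X: (bands, Npix*n).  Returns class scores (nclass, n): capsule lengths
  // for capsule heads, softmax probabilities for affine heads.
  fmat forward(const fmat& X, bool train, bool keep) {
    int n = X.n_cols / Npix;
    if ((int)X.n_rows != bands)
      Rcpp::stop("input stage: expected %d bands, got %d", bands, (int)X.n_rows);
    if (rec > 0 && keep) input_c = X;

    if (use_spe) {
      Uspe = sp3.forward(sp2.forward(sp1.forward(X, keep), keep), keep);
      if (hybrid) Uspe = hyb.forward(Uspe, keep);
    }
    if (use_spa)
      Uspa = sa2.forward(sa1.forward(collapse.forward(X, keep), keep), keep);

    const fmat& U1 = use_spe ? Uspe : Uspa;
    if (use_att) {
      fmat z1 = se_spe.forward(Uspe, Npix, keep);
      fmat z2 = se_spa.forward(Uspa, Npix, keep);
      att1 = 1.0f / (1.0f + arma::exp(z2 - z1));  // softmax over the two branches
      att2 = 1.0f - att1;
      Vmap.set_size(256, X.n_cols);
      for (int i = 0; i < n; ++i) {
        arma::uword c0 = (arma::uword)i * Npix, c1 = c0 + Npix - 1;
        Vmap.submat(0, c0, 127, c1) = Uspe.cols(c0, c1).each_col() % fvec(att1.col(i));
        Vmap.submat(128, c0, 255, c1) = Uspa.cols(c0, c1).each_col() % fvec(att2.col(i));
      }
    } else if (use_spe && use_spa) {
      Vmap = arma::join_cols(Uspe, Uspa);
    } else {
      Vmap = U1;
    }

    if (!caps_head) {
      const fmat& hc = headconv.forward(Vmap, keep);
      fmat flat(const_cast<float*>(hc.memptr()), (arma::uword)64 * grid2, n, false, true);
      fmat logits = fc.forward(flat, keep);
      fmat probs;
      softmax_rows_percol(logits, probs);
      return probs;
    }

    const fmat& P = prim.forward(Vmap, keep);
    bn.forward(P, train, bn_out);
    u_pre_c.assign(n, fmat()); u_c.assign(n, fmat()); uh_c.assign(n, fmat());
    rc_c.assign(n, RoutingCache());
    digit_v.set_size(ddim, (arma::uword)nclass * n);
    fmat lengths(nclass, n);
    for (int i = 0; i < n; ++i) {
      fmat up(cdim, ncaps);
      for (int t = 0; t < ctypes; ++t)
        for (int p2 = 0; p2 < grid2; ++p2)
          up.col((arma::uword)t * grid2 + p2) =
              bn_out.submat(t * cdim, (arma::uword)i * grid2 + p2,
                            (t + 1) * cdim - 1, (arma::uword)i * grid2 + p2);
      fmat u;
      squash_cols(up, u);
      fmat uh(nclass * ddim, ncaps, arma::fill::zeros);
      for (int d = 0; d < cdim; ++d) uh += Wd[d].w.each_row() % u.row(d);
      fmat v = route_forward(uh, nclass, ddim, iters, keep ? &rc_c[i] : nullptr);
      digit_v.cols((arma::uword)i * nclass, (arma::uword)(i + 1) * nclass - 1) = v;
      for (int j = 0; j < nclass; ++j) lengths(j, i) = arma::norm(v.col(j));
      if (keep) { u_pre_c[i] = up; u_c[i] = u; uh_c[i] = uh; }
    }
    return lengths;
  }

  // ---- loss + backward ---------------------------------------------------
  // y: 0-based labels, length n. Accumulates gradients (unscaled sum over
  // samples); caller divides by the full batch size before the Adam step.
  double backward_from_loss(const fmat& scores, const std::vector<int>& y) {
    int n = scores.n_cols;
    double loss = 0.0;

    if (!caps_head) {  // cross-entropy on softmax probabilities
      fmat dlogits = scores;
      for (int i = 0; i < n; ++i) {
        loss -= std::log(std::max(scores(y[i], i), 1e-12f));
        dlogits(y[i], i) -= 1.0f;
      }
      fmat dflat = fc.backward(dlogits);
      fmat dhc(dflat.memptr(), 64, (arma::uword)grid2 * n, false, true);
      fmat dV = headconv.backward(dhc);
      backward_fusion(dV, n);
      return loss;
    }

    // margin loss on capsule lengths
    fmat dBnOut(bn_out.n_rows, bn_out.n_cols, arma::fill::zeros);
    fmat xhat_rec, drec_v;
    if (rec > 0) {
      xhat_rec = reconstruct_masked(y, n, true);
      fmat err = xhat_rec - input_c_as_mat(n);
      loss += rec_scale * (double)arma::accu(arma::square(err));
      drec_v = recon_backward(2.0f * rec_scale * err, y, n);  // (ddim, K*n) masked
    }
    for (int i = 0; i < n; ++i) {
      fmat v = digit_v.cols((arma::uword)i * nclass, (arma::uword)(i + 1) * nclass - 1);
      fmat dv(ddim, nclass, arma::fill::zeros);
      for (int j = 0; j < nclass; ++j) {
        float l = arma::norm(v.col(j));
        float dl;
        if (j == y[i]) {
          float hp = std::max(0.0f, m_plus - l);
          loss += hp * hp;
          dl = -2.0f * hp;
        } else {
          float hm = std::max(0.0f, l - m_minus);
          loss += lambda_down * hm * hm;
          dl = 2.0f * lambda_down * hm;
        }
        if (l > 1e-9f) dv.col(j) = (dl / l) * v.col(j);
      }
      if (rec > 0)
        dv += drec_v.cols((arma::uword)i * nclass, (arma::uword)(i + 1) * nclass - 1);
      fmat duh = route_backward(uh_c[i], rc_c[i], dv, nclass, ddim);
      fmat du(cdim, ncaps);
      for (int d = 0; d < cdim; ++d) {
        du.row(d) = arma::sum(Wd[d].w % duh, 0);
        Wd[d].g += duh.each_row() % u_c[i].row(d);
      }
      fmat dup;
      squash_backward_cols(du, u_pre_c[i], dup);
      for (int t = 0; t < ctypes; ++t)
        for (int p2 = 0; p2 < grid2; ++p2)
          dBnOut.submat(t * cdim, (arma::uword)i * grid2 + p2,
                        (t + 1) * cdim - 1, (arma::uword)i * grid2 + p2) =
              dup.col((arma::uword)t * grid2 + p2);
    }
    fmat dP = bn.backward(dBnOut);
    fmat dV = prim.backward(dP);
    backward_fusion(dV, n);
    u_pre_c.clear(); u_c.clear(); uh_c.clear(); rc_c.clear();
    bn_out.reset(); input_c.reset();
    return loss;
  }

  void backward_fusion(fmat& dV, int n) {
    fmat dUspe, dUspa;
    if (use_att) {
      dUspe.set_size(128, dV.n_cols); dUspa.set_size(128, dV.n_cols);
      fmat da1(128, n), da2(128, n);
      for (int i = 0; i < n; ++i) {
        arma::uword c0 = (arma::uword)i * Npix, c1 = c0 + Npix - 1;
        fmat dV1 = dV.submat(0, c0, 127, c1), dV2 = dV.submat(128, c0, 255, c1);
        dUspe.cols(c0, c1) = dV1.each_col() % fvec(att1.col(i));
        dUspa.cols(c0, c1) = dV2.each_col() % fvec(att2.col(i));
        da1.col(i) = arma::sum(dV1 % Uspe.cols(c0, c1), 1);
        da2.col(i) = arma::sum(dV2 % Uspa.cols(c0, c1), 1);
      }
      fmat dz1 = att1 % att2 % (da1 - da2);
      dUspe += se_spe.backward(dz1);
      dUspa += se_spa.backward(-dz1);
    } else if (use_spe && use_spa) {
      dUspe = dV.rows(0, 127);
      dUspa = dV.rows(128, 255);
    } else if (use_spe) {
      dUspe = dV;
    } else {
      dUspa = dV;
    }
    if (use_spe) {
      if (hybrid) dUspe = hyb.backward(dUspe);
      sp1.backward(sp2.backward(sp3.backward(dUspe)));
    }
    if (use_spa) collapse.backward(sa1.backward(sa2.backward(dUspa)));
    Uspe.reset(); Uspa.reset(); Vmap.reset(); att1.reset(); att2.reset();
  }

  // ---- reconstruction decoders -------------------------------------------
  fmat input_c_as_mat(int n) {
    if (rec == 1) return fmat(input_c.memptr(), (arma::uword)bands * Npix, n, false, true);
    return input_c;  // (bands, Npix*n) for the convolutional decoders
  }
  fmat masked_digits(const std::vector<int>& y, int n) {
    fmat md(nclass * ddim, n, arma::fill::zeros);
    for (int i = 0; i < n; ++i)
      md.submat(y[i] * ddim, i, (y[i] + 1) * ddim - 1, i) =
          digit_v.col((arma::uword)i * nclass + y[i]);
    return md;
  }
  fmat reconstruct_masked(const std::vector<int>& y, int n, bool keep) {
    fmat md = masked_digits(y, n);
    if (rec == 1)
      return r1c.forward(r1b.forward(r1a.forward(md, keep), keep), keep);
    if (rec == 2) {
      fmat h = r2fc.forward(md, keep);
      fmat himg(h.memptr(), 1, (arma::uword)Npix * n, false, true);
      return r2conv.forward(himg, keep);
    }
    fmat h = r3fc.forward(md, keep);
    fmat himg(h.memptr(), 1, (arma::uword)(H / 2) * (Wsp / 2) * n, false, true);
    return r3conv.forward(r3up.forward(himg, keep), keep);
  }
  // derr: gradient wrt decoder output; returns gradient on digit capsules
  // (ddim, K*n), nonzero only in the masked class column
  fmat recon_backward(const fmat& derr, const std::vector<int>& y, int n) {
    fmat dmd;
    if (rec == 1) {
      fmat de = derr;
      dmd = r1a.backward(r1b.backward(r1c.backward(de)));
    } else if (rec == 2) {
      fmat dh = r2conv.backward(derr);
      fmat dhm(dh.memptr(), Npix, n, false, true);
      dmd = r2fc.backward(dhm);
    } else {
      fmat dh = r3up.backward(r3conv.backward(derr));
      fmat dhm(dh.memptr(), (arma::uword)(H / 2) * (Wsp / 2), n, false, true);
      dmd = r3fc.backward(dhm);
    }
    fmat dv(ddim, (arma::uword)nclass * n, arma::fill::zeros);
    for (int i = 0; i < n; ++i)
      dv.col((arma::uword)i * nclass + y[i]) =
          dmd.submat(y[i] * ddim, i, (y[i] + 1) * ddim - 1, i);
    return dv;
  }

  // ---- optimizer ----------------------------------------------------------
  void zero_grads() { for (Param* p : params) p->g.zeros(); }
  void scale_grads(float s) { for (Param* p : params) p->g *= s; }
  void adam_step(float lr, float wd) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    ++adam_t;
    float c1 = 1.0f - std::pow(b1, (float)adam_t);
    float c2 = 1.0f - std::pow(b2, (float)adam_t);
    for (Param* p : params) {
      if (wd != 0.0f) p->g += wd * p->w;
      p->m = b1 * p->m + (1.0f - b1) * p->g;
      p->v = b2 * p->v + (1.0f - b2) * arma::square(p->g);
      p->w -= lr * (p->m / c1) / (arma::sqrt(p->v / c2) + eps);
    }
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------
typedef Rcpp::XPtr<Net> NetPtr;

static fmat as_fmat(const Rcpp::NumericMatrix& X) {
  fmat M(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) M(i, j) = (float)X(i, j);
  return M;
}

static Rcpp::NumericMatrix as_rmat(const fmat& M) {
  Rcpp::NumericMatrix X(M.n_rows, M.n_cols);
  for (arma::uword j = 0; j < M.n_cols; ++j)
    for (arma::uword i = 0; i < M.n_rows; ++i) X(i, j) = M(i, j);
  return X;
}

// batch array (bands, H, W, n) -> (bands, Npix*n)
static fmat batch_to_fmat(const Rcpp::NumericVector& x, int bands, int npix) {
  R_xlen_t total = x.size();
  if (total % ((R_xlen_t)bands * npix) != 0)
    Rcpp::stop("input stage: batch length not divisible by bands*H*W");
  R_xlen_t ncol = total / bands;
  fmat M(bands, ncol);
  const double* xp = x.begin();
  float* mp = M.memptr();
  for (R_xlen_t i = 0; i < total; ++i) mp[i] = (float)xp[i];
  return M;
}

// [[Rcpp::export]]
SEXP net_create(std::string variant, int bands, int height, int width,
                int nclass, int routing_iters, int seed) {
  Net* net = new Net();
  try {
    net->build(variant, bands, height, width, nclass, routing_iters,
               (unsigned int)seed);
  } catch (...) {
    delete net;
    throw;
  }
  return NetPtr(net, true);
}

// [[Rcpp::export]]
double net_nparams(SEXP ptr) { return (double)NetPtr(ptr)->n_params(); }

// [[Rcpp::export]]
Rcpp::DataFrame net_param_table(SEXP ptr) {
  NetPtr net(ptr);
  int k = net->params.size();
  Rcpp::CharacterVector nm(k);
  Rcpp::IntegerVector rr(k), cc(k);
  Rcpp::NumericVector nn(k);
  for (int i = 0; i < k; ++i) {
    nm[i] = net->params[i]->name;
    rr[i] = net->params[i]->w.n_rows;
    cc[i] = net->params[i]->w.n_cols;
    nn[i] = (double)net->params[i]->w.n_elem;
  }
  return Rcpp::DataFrame::create(Rcpp::Named("name") = nm, Rcpp::Named("rows") = rr,
                                 Rcpp::Named("cols") = cc, Rcpp::Named("n") = nn);
}

// [[Rcpp::export]]
Rcpp::List net_info(SEXP ptr) {
  NetPtr net(ptr);
  return Rcpp::List::create(
      Rcpp::Named("variant") = net->variant, Rcpp::Named("bands") = net->bands,
      Rcpp::Named("height") = net->H, Rcpp::Named("width") = net->Wsp,
      Rcpp::Named("nclass") = net->nclass, Rcpp::Named("routing_iters") = net->iters,
      Rcpp::Named("caps_head") = net->caps_head, Rcpp::Named("grid") = net->grid,
      Rcpp::Named("ncaps") = net->caps_head ? net->ncaps : NA_INTEGER,
      Rcpp::Named("n_params") = (double)net->n_params());
}

// [[Rcpp::export]]
Rcpp::NumericMatrix net_predict(SEXP ptr, Rcpp::NumericVector x, int microbatch) {
  NetPtr net(ptr);
  fmat X = batch_to_fmat(x, net->bands, net->Npix);
  int n = X.n_cols / net->Npix;
  fmat scores(net->nclass, n);
  for (int i0 = 0; i0 < n; i0 += microbatch) {
    int i1 = std::min(n, i0 + microbatch);
    fmat Xi = X.cols((arma::uword)i0 * net->Npix, (arma::uword)i1 * net->Npix - 1);
    scores.cols(i0, i1 - 1) = net->forward(Xi, false, false);
  }
  return as_rmat(scores.t());
}

// [[Rcpp::export]]
double net_train_batch(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector y,
                       double lr, double weight_decay, int microbatch) {
  NetPtr net(ptr);
  fmat X = batch_to_fmat(x, net->bands, net->Npix);
  int n = X.n_cols / net->Npix;
  if ((int)y.size() != n) Rcpp::stop("labels: expected %d, got %d", n, (int)y.size());
  net->zero_grads();
  double loss = 0.0;
  for (int i0 = 0; i0 < n; i0 += microbatch) {
    int i1 = std::min(n, i0 + microbatch);
    fmat Xi = X.cols((arma::uword)i0 * net->Npix, (arma::uword)i1 * net->Npix - 1);
    std::vector<int> yi(y.begin() + i0, y.begin() + i1);
    fmat scores = net->forward(Xi, true, true);
    double l = net->backward_from_loss(scores, yi);
    if (!std::isfinite(l))
      Rcpp::stop("non-finite loss in training batch (samples %d-%d)", i0 + 1, i1);
    loss += l;
  }
  net->scale_grads(1.0f / n);
  net->adam_step((float)lr, (float)weight_decay);
  return loss / n;
}

// loss and flat gradient without an optimizer step (used by the
// finite-difference checks of the hand-derived backward passes)
// [[Rcpp::export]]
Rcpp::List net_loss_grad(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector y,
                         int microbatch, bool train_mode) {
  NetPtr net(ptr);
  fmat X = batch_to_fmat(x, net->bands, net->Npix);
  int n = X.n_cols / net->Npix;
  net->zero_grads();
  double loss = 0.0;
  for (int i0 = 0; i0 < n; i0 += microbatch) {
    int i1 = std::min(n, i0 + microbatch);
    fmat Xi = X.cols((arma::uword)i0 * net->Npix, (arma::uword)i1 * net->Npix - 1);
    std::vector<int> yi(y.begin() + i0, y.begin() + i1);
    fmat scores = net->forward(Xi, train_mode, true);
    loss += net->backward_from_loss(scores, yi);
  }
  net->scale_grads(1.0f / n);
  Rcpp::NumericVector g(net->n_params());
  R_xlen_t k = 0;
  for (Param* p : net->params)
    for (arma::uword i = 0; i < p->g.n_elem; ++i) g[k++] = p->g(i);
  return Rcpp::List::create(Rcpp::Named("loss") = loss / n,
                            Rcpp::Named("grad") = g);
}

// loss only (for finite differencing); must match net_loss_grad's forward
// [[Rcpp::export]]
double net_loss_only(SEXP ptr, Rcpp::NumericVector x, Rcpp::IntegerVector y,
                     int microbatch, bool train_mode) {
  NetPtr net(ptr);
  fmat X = batch_to_fmat(x, net->bands, net->Npix);
  int n = X.n_cols / net->Npix;
  double loss = 0.0;
  for (int i0 = 0; i0 < n; i0 += microbatch) {
    int i1 = std::min(n, i0 + microbatch);
    fmat Xi = X.cols((arma::uword)i0 * net->Npix, (arma::uword)i1 * net->Npix - 1);
    std::vector<int> yi(y.begin() + i0, y.begin() + i1);
    fmat scores = net->forward(Xi, train_mode, true);
    // evaluate the same objective without touching gradients
    double l = 0.0;
    if (!net->caps_head) {
      for (int i = 0; i < (int)yi.size(); ++i)
        l -= std::log(std::max(scores(yi[i], i), 1e-12f));
    } else {
      if (net->rec > 0) {
        fmat xh = net->reconstruct_masked(yi, yi.size(), false);
        fmat err = xh - net->input_c_as_mat(yi.size());
        l += net->rec_scale * (double)arma::accu(arma::square(err));
      }
      for (int i = 0; i < (int)yi.size(); ++i)
        for (int j = 0; j < net->nclass; ++j) {
          float ln = scores(j, i);
          if (j == yi[i]) {
            float hp = std::max(0.0f, net->m_plus - ln);
            l += hp * hp;
          } else {
            float hm = std::max(0.0f, ln - net->m_minus);
            l += net->lambda_down * hm * hm;
          }
        }
    }
    loss += l;
  }
  return loss / n;
}

// [[Rcpp::export]]
Rcpp::List net_forward_detail(SEXP ptr, Rcpp::NumericVector x) {
  NetPtr net(ptr);
  fmat X = batch_to_fmat(x, net->bands, net->Npix);
  int n = X.n_cols / net->Npix;
  fmat scores = net->forward(X, false, true);
  Rcpp::List out;
  out["scores"] = as_rmat(scores.t());
  if (net->use_spe) out["U_spe"] = as_rmat(net->Uspe);
  if (net->use_spa) out["U_spa"] = as_rmat(net->Uspa);
  if (net->use_att) {
    out["att_spe"] = as_rmat(net->att1);
    out["att_spa"] = as_rmat(net->att2);
  }
  if (net->Vmap.n_elem) out["V"] = as_rmat(net->Vmap);
  if (net->caps_head) {
    Rcpp::List us(n), vs(n), cs(n);
    for (int i = 0; i < n; ++i) {
      us[i] = as_rmat(net->u_c[i]);
      vs[i] = as_rmat(net->digit_v.cols((arma::uword)i * net->nclass,
                                        (arma::uword)(i + 1) * net->nclass - 1));
      cs[i] = as_rmat(net->rc_c[i].c.back());
    }
    out["primary"] = us;
    out["digit"] = vs;
    out["coupling"] = cs;
  }
  out["n"] = n;
  return out;
}

// [[Rcpp::export]]
Rcpp::List net_branch_trace(SEXP ptr) {
  NetPtr net(ptr);
  Rcpp::List out;
  if (net->use_spe)
    out["spectral_depths"] = Rcpp::IntegerVector::create(
        net->sp1.Din, net->sp1.Dout, net->sp2.Dout, net->sp3.Dout);
  if (net->use_spa)
    out["spatial_collapse_depth"] = net->collapse.Dout;
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector net_get_params(SEXP ptr) {
  NetPtr net(ptr);
  Rcpp::NumericVector out(net->n_params());
  R_xlen_t k = 0;
  for (Param* p : net->params)
    for (arma::uword i = 0; i < p->w.n_elem; ++i) out[k++] = p->w(i);
  return out;
}

// [[Rcpp::export]]
void net_set_params(SEXP ptr, Rcpp::NumericVector w) {
  NetPtr net(ptr);
  if ((R_xlen_t)net->n_params() != w.size())
    Rcpp::stop("parameter vector length %lld does not match model (%lld)",
               (long long)w.size(), net->n_params());
  R_xlen_t k = 0;
  for (Param* p : net->params)
    for (arma::uword i = 0; i < p->w.n_elem; ++i) p->w(i) = (float)w[k++];
}

// [[Rcpp::export]]
Rcpp::NumericVector net_get_buffers(SEXP ptr) {
  NetPtr net(ptr);
  std::vector<double> out;
  for (BatchNorm* b : net->bns) {
    for (arma::uword i = 0; i < b->rmean.n_elem; ++i) out.push_back(b->rmean(i));
    for (arma::uword i = 0; i < b->rvar.n_elem; ++i) out.push_back(b->rvar(i));
  }
  return Rcpp::wrap(out);
}

// [[Rcpp::export]]
void net_set_buffers(SEXP ptr, Rcpp::NumericVector b) {
  NetPtr net(ptr);
  R_xlen_t k = 0;
  for (BatchNorm* bnp : net->bns) {
    for (arma::uword i = 0; i < bnp->rmean.n_elem; ++i) bnp->rmean(i) = (float)b[k++];
    for (arma::uword i = 0; i < bnp->rvar.n_elem; ++i) bnp->rvar(i) = (float)b[k++];
  }
  if (k != b.size()) Rcpp::stop("buffer vector length mismatch");
}

// standalone routing, exposed for the routing-oracle cross-checks:
// uhat (nclass*dout, ncaps) -> list(v, coupling)
// [[Rcpp::export]]
Rcpp::List cpp_dynamic_routing(Rcpp::NumericMatrix uhat, int nclass, int dout,
                               int iters) {
  if (iters < 1) Rcpp::stop("routing needs at least one iteration");
  fmat uh = as_fmat(uhat);
  if (!uh.is_finite()) Rcpp::stop("non-finite prediction vectors");
  if ((int)uh.n_rows != nclass * dout)
    Rcpp::stop("uhat must have nclass*dout rows");
  RoutingCache cache;
  fmat v = route_forward(uh, nclass, dout, iters, &cache);
  Rcpp::List citers(iters);
  for (int t = 0; t < iters; ++t) citers[t] = as_rmat(cache.c[t]);
  return Rcpp::List::create(Rcpp::Named("v") = as_rmat(v),
                            Rcpp::Named("coupling") = as_rmat(cache.c.back()),
                            Rcpp::Named("coupling_iters") = citers);
}
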