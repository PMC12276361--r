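// Diffusion-colored trajectory rasterizer and the HTC convolutional
// network (5 conv blocks, each conv -> 2x2 max pool -> batch norm ->
// ReLU, then adaptive 3x3 max pool, flatten, dense, softmax), trained
// with Adam on cross-entropy. Single precision; convolutions are
// computed as im2col + GEMM so the heavy lifting runs on BLAS.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

// ---------------------------------------------------------------- render

// Draw one standardized trajectory onto a size x size x 3 canvas.
// xy: n x 2 coordinates (um), channel: per-segment channel 1..3,
// window_um: physical width mapped onto the canvas. Segments are drawn
// at sub-pixel precision by marching points along the segment and
// splatting bilinear weights; intensities are clamped to [0, 1].
// [[Rcpp::export]]
Rcpp::NumericVector render_traj_cpp(const Rcpp::NumericMatrix& xy,
                                    const Rcpp::IntegerVector& channel,
                                    int size, double window_um,
                                    double step_px = 0.4,
                                    bool auto_expand = true) {
  const int n = xy.nrow();
  Rcpp::NumericVector out(static_cast<R_xlen_t>(size) * size * 3);
  out.attr("dim") = Rcpp::IntegerVector::create(size, size, 3);
  if (n < 2) { out.attr("n_clipped") = 0; return out; }
  const double c0 = size / 2.0;         // canvas centre
  // centre the canvas on the track's bounding box; with auto_expand the
  // window grows (never shrinks) to keep the whole track in view
  double xmin = xy(0, 0), xmax = xy(0, 0), ymin = xy(0, 1), ymax = xy(0, 1);
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, xy(i, 0)); xmax = std::max(xmax, xy(i, 0));
    ymin = std::min(ymin, xy(i, 1)); ymax = std::max(ymax, xy(i, 1));
  }
  const double cx = (xmin + xmax) / 2.0, cy = (ymin + ymax) / 2.0;
  double eff_window = window_um;
  if (auto_expand) {
    const double span = 1.1 * std::max(xmax - xmin, ymax - ymin);
    eff_window = std::max(window_um, span);
  }
  const double sc = size / eff_window;  // px per um
  int clipped = 0;
  double* px = REAL(out);
  const R_xlen_t plane = static_cast<R_xlen_t>(size) * size;
  for (int s = 0; s < n - 1; ++s) {
    const int ch = channel[s] - 1;
    if (ch < 0 || ch > 2) continue;
    double x0 = (xy(s, 0) - cx) * sc + c0, y0 = (xy(s, 1) - cy) * sc + c0;
    double x1 = (xy(s + 1, 0) - cx) * sc + c0, y1 = (xy(s + 1, 1) - cy) * sc + c0;
    const double len = std::hypot(x1 - x0, y1 - y0);
    const int m = std::max(1, (int)std::ceil(len / step_px));
    for (int t = 0; t <= m; ++t) {
      const double f = (double)t / m;
      const double xx = x0 + f * (x1 - x0), yy = y0 + f * (y1 - y0);
      const int ix = (int)std::floor(xx), iy = (int)std::floor(yy);
      const double fx = xx - ix, fy = yy - iy;
      bool any = false;
      for (int dx = 0; dx <= 1; ++dx)
        for (int dy = 0; dy <= 1; ++dy) {
          const int jx = ix + dx, jy = iy + dy;
          if (jx < 0 || jx >= size || jy < 0 || jy >= size) continue;
          any = true;
          const double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy);
          double* cell = px + ch * plane + jx * size + jy; // row=y, col=x
          *cell = std::min(1.0, *cell + w);
        }
      if (!any) ++clipped;
    }
  }
  out.attr("n_clipped") = clipped;
  return out;
}

// --------------------------------------------------------------- network

struct Adam { fmat m, v; };

struct ConvLayer {
  int k, cin, cout, pad_l;
  fmat W;      // (k*k*cin) x cout
  frowvec b;
  Adam aW, ab;
};

struct BNLayer {
  fvec gamma, beta, rmean, rvar;
  Adam ag, abt;
  // batch cache
  fvec save_invstd, save_mean;
};

struct HTCNet {
  int S;                      // input image size
  std::vector<ConvLayer> conv;
  BNLayer bn[5];
  fmat Wd; frowvec bd;        // dense head 4608 -> 3
  Adam aWd, abd;
  long step = 0;
  std::vector<int> sp;        // spatial size entering each conv block
};

static void adam_init(Adam& a, int r, int c) {
  a.m.zeros(r, c); a.v.zeros(r, c);
}

static void adam_update(fmat& w, Adam& a, const fmat& g, double lr, long t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  a.m = b1 * a.m + (1 - b1) * g;
  a.v = b2 * a.v + (1 - b2) * (g % g);
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  w -= (float)lr * (a.m / c1) / (sqrt(a.v / c2) + eps);
}

static HTCNet* make_net(int S, int seed) {
  if (S < 96) Rcpp::stop("image_size must be >= 96 for the 5-stage pooling stack");
  HTCNet* net = new HTCNet();
  net->S = S;
  const int ks[5] = {8, 5, 2, 2, 2};
  const int nf[5] = {32, 64, 128, 256, 512};
  std::mt19937 rng(seed);
  int cin = 3, s = S;
  for (int l = 0; l < 5; ++l) {
    ConvLayer c;
    c.k = ks[l]; c.cin = cin; c.cout = nf[l];
    c.pad_l = (ks[l] - 1) / 2;
    const int fan_in = ks[l] * ks[l] * cin;
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / fan_in));
    c.W.set_size(fan_in, nf[l]);
    for (uword j = 0; j < c.W.n_elem; ++j) c.W(j) = nd(rng);
    c.b.zeros(nf[l]);
    adam_init(c.aW, fan_in, nf[l]); adam_init(c.ab, 1, nf[l]);
    net->conv.push_back(std::move(c));
    net->bn[l].gamma.ones(nf[l]); net->bn[l].beta.zeros(nf[l]);
    net->bn[l].rmean.zeros(nf[l]); net->bn[l].rvar.ones(nf[l]);
    adam_init(net->bn[l].ag, nf[l], 1); adam_init(net->bn[l].abt, nf[l], 1);
    net->sp.push_back(s);
    s = s / 2;          // 2x2 max pool, stride 2
    cin = nf[l];
  }
  const int flat = 3 * 3 * 512;
  std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / flat));
  net->Wd.set_size(flat, 3);
  for (uword j = 0; j < net->Wd.n_elem; ++j) net->Wd(j) = nd(rng);
  net->bd.zeros(3);
  adam_init(net->aWd, flat, 3); adam_init(net->abd, 1, 3);
  return net;
}

// im2col for 'same' stride-1 convolution: out (s*s) x (k*k*cin);
// patch column index = (c*k + ky)*k + kx. Output pixel row index =
// x*s + y (column-major image with row=y).
static void im2col(const fcube& X, int k, int pad_l, fmat& M) {
  const int s = X.n_rows, cin = X.n_slices;
  M.zeros(s * s, k * k * cin);
  for (int c = 0; c < cin; ++c) {
    const fmat& plane = X.slice(c);
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const int col = (c * k + ky) * k + kx;
        const int oy = ky - pad_l, ox = kx - pad_l;
        const int y0 = std::max(0, -oy), y1 = std::min(s, s - oy);
        const int x0 = std::max(0, -ox), x1 = std::min(s, s - ox);
        float* mcol = M.colptr(col);
        for (int x = x0; x < x1; ++x) {
          const float* src = plane.colptr(x + ox) + (y0 + oy);
          float* dst = mcol + x * s + y0;
          std::copy(src, src + (y1 - y0), dst);
        }
      }
  }
}

// adjoint of im2col: scatter-add dM back to dX
static void col2im(const fmat& dM, int k, int pad_l, int s, int cin, fcube& dX) {
  dX.zeros(s, s, cin);
  for (int c = 0; c < cin; ++c) {
    fmat& plane = dX.slice(c);
    for (int ky = 0; ky < k; ++ky)
      for (int kx = 0; kx < k; ++kx) {
        const int col = (c * k + ky) * k + kx;
        const int oy = ky - pad_l, ox = kx - pad_l;
        const int y0 = std::max(0, -oy), y1 = std::min(s, s - oy);
        const int x0 = std::max(0, -ox), x1 = std::min(s, s - ox);
        const float* mcol = dM.colptr(col);
        for (int x = x0; x < x1; ++x) {
          float* dst = plane.colptr(x + ox) + (y0 + oy);
          const float* src = mcol + x * s + y0;
          for (int y = 0; y < y1 - y0; ++y) dst[y] += src[y];
        }
      }
  }
}

// 2x2 stride-2 max pool; records flat argmax indices into the input cube
static void maxpool2(const fcube& X, fcube& Y, Mat<uword>& arg) {
  const int s = X.n_rows, c = X.n_slices, h = s / 2;
  Y.set_size(h, h, c);
  arg.set_size(h * h, c);
  for (int z = 0; z < c; ++z) {
    const fmat& p = X.slice(z);
    for (int j = 0; j < h; ++j)
      for (int i = 0; i < h; ++i) {
        uword best = 0; float bv = -1e30f;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int y = 2 * i + di, x = 2 * j + dj;
            const float v = p(y, x);
            if (v > bv) { bv = v; best = (uword)x * s + y; }
          }
        Y(i, j, z) = bv;
        arg(j * h + i, z) = best;
      }
  }
}

// adaptive max pool to out x out
static void adamaxpool(const fcube& X, int out, fcube& Y, Mat<uword>& arg) {
  const int s = X.n_rows, c = X.n_slices;
  Y.set_size(out, out, c);
  arg.set_size(out * out, c);
  for (int z = 0; z < c; ++z) {
    const fmat& p = X.slice(z);
    for (int j = 0; j < out; ++j) {
      const int x0 = (j * s) / out, x1 = ((j + 1) * s + out - 1) / out;
      for (int i = 0; i < out; ++i) {
        const int y0 = (i * s) / out, y1 = ((i + 1) * s + out - 1) / out;
        uword best = 0; float bv = -1e30f;
        for (int x = x0; x < x1; ++x)
          for (int y = y0; y < y1; ++y) {
            const float v = p(y, x);
            if (v > bv) { bv = v; best = (uword)x * s + y; }
          }
        Y(i, j, z) = bv;
        arg(j * out + i, z) = best;
      }
    }
  }
}

struct BatchCache {
  std::vector<std::vector<fcube>> conv_in;   // per layer, per image
  std::vector<std::vector<fcube>> pooled;    // post-pool pre-BN
  std::vector<std::vector<Mat<uword>>> parg; // pool argmax
  std::vector<std::vector<fcube>> bn_out;    // post-BN post-ReLU
  std::vector<Mat<uword>> aarg;              // adaptive pool argmax per image
  fmat flat;                                 // B x 4608
};

// forward pass over a batch; training=true uses batch statistics and
// fills the cache, training=false uses running statistics.
static fmat forward(HTCNet& net, const std::vector<fcube>& X, bool training,
                    BatchCache* cache) {
  const int B = X.size();
  std::vector<fcube> cur = X;
  if (cache) {
    cache->conv_in.resize(5); cache->pooled.resize(5);
    cache->parg.resize(5); cache->bn_out.resize(5);
    cache->aarg.resize(B);
  }
  for (int l = 0; l < 5; ++l) {
    ConvLayer& C = net.conv[l];
    BNLayer& bn = net.bn[l];
    const int s = cur[0].n_rows, h = s / 2, co = C.cout;
    std::vector<fcube> pooled(B);
    std::vector<Mat<uword>> parg(B);
    fmat Mbuf;
    for (int i = 0; i < B; ++i) {
      im2col(cur[i], C.k, C.pad_l, Mbuf);
      fmat Y = Mbuf * C.W;
      Y.each_row() += C.b;
      fcube Yc(Y.memptr(), s, s, co);   // column x*s+y layout matches cube
      maxpool2(Yc, pooled[i], parg[i]);
    }
    // batch norm across batch and spatial dims, per channel
    fvec mean(co), var(co);
    if (training) {
      const double nper = (double)B * h * h;
      for (int z = 0; z < co; ++z) {
        double su = 0, sq = 0;
        for (int i = 0; i < B; ++i) {
          const fmat& p = pooled[i].slice(z);
          su += accu(p); sq += accu(p % p);
        }
        mean(z) = su / nper;
        var(z) = std::max(0.0, sq / nper - mean(z) * mean(z));
      }
      bn.rmean = 0.9f * bn.rmean + 0.1f * mean;
      bn.rvar = 0.9f * bn.rvar + 0.1f * var;
    } else { mean = bn.rmean; var = bn.rvar; }
    fvec invstd = 1.0f / sqrt(var + 1e-5f);
    if (cache) {
      bn.save_invstd = invstd; bn.save_mean = mean;
      cache->conv_in[l] = cur;
      cache->pooled[l] = pooled;
      cache->parg[l] = parg;
    }
    std::vector<fcube> act(B);
    for (int i = 0; i < B; ++i) {
      act[i].set_size(h, h, co);
      for (int z = 0; z < co; ++z) {
        const float a = bn.gamma(z) * invstd(z);
        const float c0 = bn.beta(z) - a * mean(z);
        act[i].slice(z) = a * pooled[i].slice(z) + c0;
        act[i].slice(z).transform([](float v) { return v > 0 ? v : 0.0f; });
      }
    }
    if (cache) cache->bn_out[l] = act;
    cur = std::move(act);
  }
  // adaptive 3x3 max pool + flatten + dense
  fmat flat(B, 3 * 3 * 512);
  for (int i = 0; i < B; ++i) {
    fcube Y; Mat<uword> arg;
    adamaxpool(cur[i], 3, Y, arg);
    if (cache) cache->aarg[i] = arg;
    for (uword j = 0; j < Y.n_elem; ++j) flat(i, j) = Y(j);
  }
  if (cache) cache->flat = flat;
  fmat logits = flat * net.Wd;
  logits.each_row() += net.bd;
  return logits;
}

static fmat softmax_rows(const fmat& z) {
  fmat p = z.each_col() - max(z, 1);
  p = exp(p);
  p.each_col() /= sum(p, 1);
  return p;
}

// backward + Adam update; returns mean cross-entropy loss
static double train_step(HTCNet& net, const std::vector<fcube>& X,
                         const std::vector<int>& y, double lr) {
  const int B = X.size();
  BatchCache cache;
  fmat logits = forward(net, X, true, &cache);
  fmat p = softmax_rows(logits);
  double loss = 0;
  fmat dlogit = p;
  for (int i = 0; i < B; ++i) {
    loss -= std::log(std::max(1e-12f, p(i, y[i])));
    dlogit(i, y[i]) -= 1.0f;
  }
  loss /= B;
  if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");
  dlogit /= (float)B;
  net.step += 1;
  // dense head
  fmat dWd = cache.flat.t() * dlogit;
  fmat dbd = sum(dlogit, 0);
  fmat dflat = dlogit * net.Wd.t();
  // back through adaptive pool into 5th activation gradient
  const int s5 = net.sp[4] / 2, c5 = 512;
  std::vector<fcube> dcur(B);
  for (int i = 0; i < B; ++i) {
    dcur[i].zeros(s5, s5, c5);
    for (int z = 0; z < c5; ++z)
      for (int j = 0; j < 9; ++j) {
        const uword flatidx = (uword)z * 9 + j;
        dcur[i].slice(z)(cache.aarg[i](j, z)) += dflat(i, flatidx);
      }
  }
  for (int l = 4; l >= 0; --l) {
    ConvLayer& C = net.conv[l];
    BNLayer& bn = net.bn[l];
    const int s = net.sp[l], h = s / 2, co = C.cout;
    const double nper = (double)B * h * h;
    // ReLU mask then BN backward (batch statistics)
    fvec dgamma(co, fill::zeros), dbeta(co, fill::zeros);
    fvec sum_dy(co, fill::zeros), sum_dy_xhat(co, fill::zeros);
    std::vector<fcube> xhat(B), dy(B);
    for (int i = 0; i < B; ++i) {
      xhat[i].set_size(h, h, co);
      dy[i].set_size(h, h, co);
      for (int z = 0; z < co; ++z) {
        xhat[i].slice(z) =
          (cache.pooled[l][i].slice(z) - bn.save_mean(z)) * bn.save_invstd(z);
        // ReLU gradient: activation > 0
        fmat mask = conv_to<fmat>::from(cache.bn_out[l][i].slice(z) > 0);
        dy[i].slice(z) = dcur[i].slice(z) % mask;
        dgamma(z) += accu(dy[i].slice(z) % xhat[i].slice(z));
        dbeta(z) += accu(dy[i].slice(z));
      }
    }
    sum_dy = dbeta; sum_dy_xhat = dgamma;
    // dpooled = gamma*invstd/n * (n*dy - sum_dy - xhat*sum_dy_xhat)
    std::vector<fcube> dpooled(B);
    for (int i = 0; i < B; ++i) {
      dpooled[i].set_size(h, h, co);
      for (int z = 0; z < co; ++z) {
        const float a = bn.gamma(z) * bn.save_invstd(z) / (float)nper;
        dpooled[i].slice(z) =
          a * ((float)nper * dy[i].slice(z) - sum_dy(z)
               - xhat[i].slice(z) * sum_dy_xhat(z));
      }
    }
    // pool backward into conv output grad, then conv backward
    fmat dW(C.W.n_rows, C.W.n_cols, fill::zeros);
    fmat db(1, co, fill::zeros);
    std::vector<fcube> dprev;
    if (l > 0) dprev.resize(B);
    fmat Mbuf;
    for (int i = 0; i < B; ++i) {
      fmat dY(s * s, co, fill::zeros);
      for (int z = 0; z < co; ++z) {
        const Mat<uword>& arg = cache.parg[l][i];
        float* dYcol = dY.colptr(z);
        const fmat& dp = dpooled[i].slice(z);
        for (int j = 0; j < h * h; ++j)
          dYcol[arg(j, z)] += dp(j);
      }
      im2col(cache.conv_in[l][i], C.k, C.pad_l, Mbuf);
      dW += Mbuf.t() * dY;
      db += sum(dY, 0);
      if (l > 0) {
        fmat dM = dY * C.W.t();
        col2im(dM, C.k, C.pad_l, s, C.cin, dprev[i]);
      }
    }
    adam_update(C.W, C.aW, dW, lr, net.step);
    { fmat bb(C.b); adam_update(bb, C.ab, db, lr, net.step); C.b = bb.row(0); }
    { fmat g(bn.gamma), dg(dgamma);
      adam_update(g, bn.ag, dg, lr, net.step); bn.gamma = g.col(0); }
    { fmat bt(bn.beta), dbt(dbeta);
      adam_update(bt, bn.abt, dbt, lr, net.step); bn.beta = bt.col(0); }
    if (l > 0) dcur = std::move(dprev);
  }
  adam_update(net.Wd, net.aWd, dWd, lr, net.step);
  { fmat bb(net.bd); adam_update(bb, net.abd, dbd, lr, net.step);
    net.bd = bb.row(0); }
  return loss;
}

// ------------------------------------------------------------- interface

static std::vector<fcube> as_batch(const Rcpp::NumericVector& x, int S) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 4 || dim[0] != S || dim[1] != S || dim[2] != 3)
    Rcpp::stop("batch must be a size x size x 3 x B array");
  const int B = dim[3];
  std::vector<fcube> out(B);
  const double* p = REAL(x);
  const R_xlen_t per = (R_xlen_t)S * S * 3;
  for (int i = 0; i < B; ++i) {
    out[i].set_size(S, S, 3);
    const double* src = p + i * per;
    for (R_xlen_t j = 0; j < per; ++j) out[i](j) = (float)src[j];
  }
  return out;
}

// [[Rcpp::export]]
SEXP htc_create(int image_size, int seed) {
  Rcpp::XPtr<HTCNet> ptr(make_net(image_size, seed), true);
  return ptr;
}

// [[Rcpp::export]]
double htc_nparams(SEXP net_) {
  Rcpp::XPtr<HTCNet> net(net_);
  double n = 0;
  for (auto& c : net->conv) n += c.W.n_elem + c.b.n_elem;
  for (int l = 0; l < 5; ++l)
    n += net->bn[l].gamma.n_elem + net->bn[l].beta.n_elem;
  n += net->Wd.n_elem + net->bd.n_elem;
  return n;
}

// [[Rcpp::export]]
int htc_image_size(SEXP net_) {
  Rcpp::XPtr<HTCNet> net(net_);
  return net->S;
}

// [[Rcpp::export]]
double htc_train_batch(SEXP net_, const Rcpp::NumericVector& x,
                       const Rcpp::IntegerVector& y, double lr) {
  Rcpp::XPtr<HTCNet> net(net_);
  std::vector<fcube> X = as_batch(x, net->S);
  if ((int)X.size() != y.size()) Rcpp::stop("batch/label size mismatch");
  std::vector<int> yy(y.begin(), y.end());
  for (int v : yy) if (v < 0 || v > 2) Rcpp::stop("labels must be 0..2");
  return train_step(*net, X, yy, lr);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix htc_predict(SEXP net_, const Rcpp::NumericVector& x) {
  Rcpp::XPtr<HTCNet> net(net_);
  std::vector<fcube> X = as_batch(x, net->S);
  fmat logits = forward(*net, X, false, nullptr);
  fmat p = softmax_rows(logits);
  Rcpp::NumericMatrix out(p.n_rows, 3);
  for (uword i = 0; i < p.n_rows; ++i)
    for (uword j = 0; j < 3; ++j) out(i, j) = p(i, j);
  return out;
}

static Rcpp::NumericMatrix wrap_f(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_elem; ++j) out[j] = m(j);
  return out;
}
static fmat unwrap_f(const Rcpp::NumericMatrix& m) {
  fmat out(m.nrow(), m.ncol());
  for (uword j = 0; j < out.n_elem; ++j) out(j) = (float)m[j];
  return out;
}

// [[Rcpp::export]]
Rcpp::List htc_get_state(SEXP net_) {
  Rcpp::XPtr<HTCNet> net(net_);
  Rcpp::List conv(5), bn(5);
  for (int l = 0; l < 5; ++l) {
    conv[l] = Rcpp::List::create(
      Rcpp::Named("W") = wrap_f(net->conv[l].W),
      Rcpp::Named("b") = wrap_f(fmat(net->conv[l].b)));
    bn[l] = Rcpp::List::create(
      Rcpp::Named("gamma") = wrap_f(fmat(net->bn[l].gamma)),
      Rcpp::Named("beta") = wrap_f(fmat(net->bn[l].beta)),
      Rcpp::Named("rmean") = wrap_f(fmat(net->bn[l].rmean)),
      Rcpp::Named("rvar") = wrap_f(fmat(net->bn[l].rvar)));
  }
  return Rcpp::List::create(
    Rcpp::Named("image_size") = net->S,
    Rcpp::Named("conv") = conv, Rcpp::Named("bn") = bn,
    Rcpp::Named("Wd") = wrap_f(net->Wd),
    Rcpp::Named("bd") = wrap_f(fmat(net->bd)),
    Rcpp::Named("step") = (double)net->step);
}

// [[Rcpp::export]]
SEXP htc_from_state(const Rcpp::List& state) {
  const int S = Rcpp::as<int>(state["image_size"]);
  HTCNet* net = make_net(S, 0);
  Rcpp::List conv = state["conv"], bn = state["bn"];
  for (int l = 0; l < 5; ++l) {
    Rcpp::List cl = conv[l], bl = bn[l];
    net->conv[l].W = unwrap_f(cl["W"]);
    net->conv[l].b = unwrap_f(Rcpp::as<Rcpp::NumericMatrix>(cl["b"])).row(0);
    net->bn[l].gamma = unwrap_f(Rcpp::as<Rcpp::NumericMatrix>(bl["gamma"])).col(0);
    net->bn[l].beta = unwrap_f(Rcpp::as<Rcpp::NumericMatrix>(bl["beta"])).col(0);
    net->bn[l].rmean = unwrap_f(Rcpp::as<Rcpp::NumericMatrix>(bl["rmean"])).col(0);
    net->bn[l].rvar = unwrap_f(Rcpp::as<Rcpp::NumericMatrix>(bl["rvar"])).col(0);
  }
  net->Wd = unwrap_f(state["Wd"]);
  net->bd = unwrap_f(Rcpp::as<Rcpp::NumericMatrix>(state["bd"])).row(0);
  net->step = (long)Rcpp::as<double>(state["step"]);
  Rcpp::XPtr<HTCNet> ptr(net, true);
  return ptr;
}
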