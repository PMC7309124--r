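// Native training engine for the multi-resolution ASPP network.
//
// Feature maps are stored as arma::cube A(C, H*W, N): channel x spatial x
// sample, spatial linear index s = x*H + y (column-major in the image
// matrix). Convolutions are evaluated by im2col + BLAS gemm; max-pooling
// caches argmax indices; batch normalization keeps running statistics for
// evaluation mode. SGD with momentum updates every trainable tensor.

#include <RcppArmadillo.h>
#include <cstring>
#include <map>
#include <random>
#include <string>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
// single-precision engine: the training workload is memory-bound and the
// extra double precision buys nothing for SGD
using cube = arma::fcube;
using mat = arma::fmat;
using vec = arma::fvec;

static mat get_mat(const List& params, const std::string& nm) {
  return arma::conv_to<mat>::from(as<arma::mat>(params[nm]));
}
static vec get_vec(const List& params, const std::string& nm) {
  return arma::conv_to<vec>::from(as<arma::vec>(params[nm]));
}
static SEXP put_mat(const mat& m) {
  return wrap(arma::conv_to<arma::mat>::from(m));
}
static SEXP put_vec(const vec& v) {
  return wrap(arma::conv_to<arma::vec>::from(v));
}
static cube to_fcube(const arma::cube& X) {
  return arma::conv_to<cube>::from(X);
}

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1; // running = (1-m)*running + m*batch

struct ConvP {
  mat W;  // NF x (Cin*k*k)
  vec b;  // NF
  mat dW; vec db;
  mat vW; vec vb;
  int k, dil;
};

struct BNP {
  vec g, be, rm, rv;
  vec dg, dbe;
  vec vg, vbe;
};

struct StageCache {
  cube A;      // post-ReLU (input of BN) when relu_first, else post-conv
  vec mu, invstd;
  mat cols;    // im2col matrix of the conv input, kept for the backward pass
};

struct NetConfig {
  int nf1, nf2, nf3, H, W;
  double dropout;
  bool relu_first; // conv -> ReLU -> BN (the published order)
  int r2, r3, r4;
};

struct Net {
  NetConfig cfg;
  std::map<std::string, ConvP> conv;
  BNP bn[12];
  std::map<std::string, int> bn_index;
  mat fcW; vec fcb;
  mat fc_dW; vec fc_db;
  mat fc_vW; vec fc_vb;
};

static const char* CONV_NAMES[12] = {
  "b1k3", "b1k5", "b1k7", "b2k3", "b2k5", "b2k7",
  "a1", "a2", "a3", "a4", "a5", "fus"};

static Net load_net(const List& params, const List& cfg) {
  Net net;
  net.cfg.nf1 = as<int>(cfg["nf1"]);
  net.cfg.nf2 = as<int>(cfg["nf2"]);
  net.cfg.nf3 = as<int>(cfg["nf3"]);
  net.cfg.H = as<int>(cfg["input_size"]);
  net.cfg.W = net.cfg.H;
  net.cfg.dropout = as<double>(cfg["dropout"]);
  net.cfg.relu_first = as<bool>(cfg["relu_before_bn"]);
  IntegerVector rates = cfg["atrous_rates"];
  net.cfg.r2 = rates[0]; net.cfg.r3 = rates[1]; net.cfg.r4 = rates[2];
  int ks[12]  = {3, 5, 7, 3, 5, 7, 1, 3, 3, 3, 1, 1};
  int dls[12] = {1, 1, 1, 1, 1, 1, 1, net.cfg.r2, net.cfg.r3, net.cfg.r4, 1, 1};
  for (int i = 0; i < 12; ++i) {
    std::string nm(CONV_NAMES[i]);
    ConvP cp;
    cp.W = get_mat(params, nm + ".W");
    cp.b = get_vec(params, nm + ".b");
    cp.dW.zeros(cp.W.n_rows, cp.W.n_cols);
    cp.db.zeros(cp.b.n_elem);
    cp.vW.zeros(cp.W.n_rows, cp.W.n_cols);
    cp.vb.zeros(cp.b.n_elem);
    cp.k = ks[i]; cp.dil = dls[i];
    net.conv[nm] = cp;
    BNP bp;
    bp.g = get_vec(params, nm + ".gamma");
    bp.be = get_vec(params, nm + ".beta");
    bp.rm = get_vec(params, nm + ".rmean");
    bp.rv = get_vec(params, nm + ".rvar");
    int C = bp.g.n_elem;
    bp.dg.zeros(C); bp.dbe.zeros(C); bp.vg.zeros(C); bp.vbe.zeros(C);
    net.bn[i] = bp;
    net.bn_index[nm] = i;
  }
  net.fcW = get_mat(params, "fc.W");
  net.fcb = get_vec(params, "fc.b");
  net.fc_dW.zeros(net.fcW.n_rows, net.fcW.n_cols);
  net.fc_db.zeros(net.fcb.n_elem);
  net.fc_vW.zeros(net.fcW.n_rows, net.fcW.n_cols);
  net.fc_vb.zeros(net.fcb.n_elem);
  return net;
}

static List dump_params(const Net& net) {
  List out;
  for (int i = 0; i < 12; ++i) {
    std::string nm(CONV_NAMES[i]);
    const ConvP& cp = net.conv.at(nm);
    const BNP& bp = net.bn[i];
    out[nm + ".W"] = put_mat(cp.W);
    out[nm + ".b"] = put_vec(cp.b);
    out[nm + ".gamma"] = put_vec(bp.g);
    out[nm + ".beta"] = put_vec(bp.be);
    out[nm + ".rmean"] = put_vec(bp.rm);
    out[nm + ".rvar"] = put_vec(bp.rv);
  }
  out["fc.W"] = put_mat(net.fcW);
  out["fc.b"] = put_vec(net.fcb);
  return out;
}

// ---------------------------------------------------------------------------
// primitive layers

// Fill the column matrix for one sample, writing at column offset col0
// of a (possibly multi-sample) destination buffer. Padding positions are
// zeroed explicitly.
static void im2col(const mat& Xs, int Cin, int H, int W, int k, int dil,
                   mat& cols, arma::uword col0 = 0) {
  int r = (k - 1) / 2;
  arma::uword S = static_cast<arma::uword>(H) * W;
  cols.cols(col0, col0 + S - 1).zeros();
  for (int kx = 0; kx < k; ++kx) {
    int ox = (kx - r) * dil;
    for (int ky = 0; ky < k; ++ky) {
      int oy = (ky - r) * dil;
      int rowbase = (kx * k + ky) * Cin;
      for (int x = 0; x < W; ++x) {
        int xi = x + ox;
        if (xi < 0 || xi >= W) continue;
        for (int y = 0; y < H; ++y) {
          int yi = y + oy;
          if (yi < 0 || yi >= H) continue;
          std::memcpy(cols.colptr(col0 + x * H + y) + rowbase,
                      Xs.colptr(xi * H + yi), Cin * sizeof(float));
        }
      }
    }
  }
}

static void col2im_add(const mat& dcols, int Cin, int H, int W, int k, int dil,
                       mat& dXs) {
  int r = (k - 1) / 2;
  for (int kx = 0; kx < k; ++kx) {
    int ox = (kx - r) * dil;
    for (int ky = 0; ky < k; ++ky) {
      int oy = (ky - r) * dil;
      int rowbase = (kx * k + ky) * Cin;
      for (int x = 0; x < W; ++x) {
        int xi = x + ox;
        if (xi < 0 || xi >= W) continue;
        for (int y = 0; y < H; ++y) {
          int yi = y + oy;
          if (yi < 0 || yi >= H) continue;
          float* dst = dXs.colptr(xi * H + yi);
          const float* src = dcols.colptr(x * H + y) + rowbase;
          for (int c = 0; c < Cin; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

// Samples per im2col/gemm chunk, bounding the column buffer to ~160 MB.
static int conv_chunk(arma::uword rows, arma::uword S, int N) {
  double per_sample = static_cast<double>(rows) * S * 4.0;
  int chunk = static_cast<int>(160.0e6 / std::max(per_sample, 1.0));
  return std::max(1, std::min(N, chunk));
}

// When `keep_cols` is given and the full-batch column matrix fits the
// cache budget, it is built once and retained for the backward pass.
static cube conv_forward(const cube& X, const ConvP& cp, int H, int W,
                         mat* keep_cols = nullptr) {
  int Cin = X.n_rows, N = X.n_slices;
  int NF = cp.W.n_rows;
  arma::uword S = static_cast<arma::uword>(H) * W;
  cube Y(NF, S, N);
  if (cp.k == 1) {
    for (int n = 0; n < N; ++n) {
      Y.slice(n) = cp.W * X.slice(n);
      Y.slice(n).each_col() += cp.b;
    }
    return Y;
  }
  arma::uword rows = static_cast<arma::uword>(Cin) * cp.k * cp.k;
  bool cache_all = keep_cols != nullptr &&
    static_cast<double>(rows) * S * N * 4.0 <= 6.0e8;
  if (cache_all) {
    mat& cols = *keep_cols;
    cols.set_size(rows, S * static_cast<arma::uword>(N));
    for (int n = 0; n < N; ++n) {
      im2col(X.slice(n), Cin, H, W, cp.k, cp.dil, cols,
             static_cast<arma::uword>(n) * S);
    }
    mat Yc = cp.W * cols;
    for (int n = 0; n < N; ++n) {
      Y.slice(n) = Yc.cols(static_cast<arma::uword>(n) * S,
                           static_cast<arma::uword>(n + 1) * S - 1);
      Y.slice(n).each_col() += cp.b;
    }
    return Y;
  }
  if (keep_cols) keep_cols->reset();
  int chunk = conv_chunk(rows, S, N);
  mat cols(rows, S * chunk);
  for (int at = 0; at < N; at += chunk) {
    int hi = std::min(N, at + chunk);
    int nc = hi - at;
    for (int n = at; n < hi; ++n) {
      im2col(X.slice(n), Cin, H, W, cp.k, cp.dil, cols,
             static_cast<arma::uword>(n - at) * S);
    }
    mat Yc = cp.W * cols.cols(0, static_cast<arma::uword>(nc) * S - 1);
    for (int n = at; n < hi; ++n) {
      Y.slice(n) = Yc.cols(static_cast<arma::uword>(n - at) * S,
                           static_cast<arma::uword>(n - at + 1) * S - 1);
      Y.slice(n).each_col() += cp.b;
    }
  }
  return Y;
}

// dY -> param grads (accumulated) and optional dX
static cube conv_backward(const cube& X, ConvP& cp, const cube& dY,
                          int H, int W, bool need_dx,
                          const mat* cols_cached = nullptr) {
  int Cin = X.n_rows, N = X.n_slices;
  arma::uword S = static_cast<arma::uword>(H) * W;
  cube dX;
  if (need_dx) dX.zeros(Cin, S, N);
  for (int n = 0; n < N; ++n) cp.db += arma::sum(dY.slice(n), 1);
  if (cp.k == 1) {
    for (int n = 0; n < N; ++n) {
      cp.dW += dY.slice(n) * X.slice(n).t();
      if (need_dx) dX.slice(n) = cp.W.t() * dY.slice(n);
    }
    return dX;
  }
  arma::uword rows = static_cast<arma::uword>(Cin) * cp.k * cp.k;
  if (cols_cached != nullptr && cols_cached->n_elem ==
        rows * S * static_cast<arma::uword>(N)) {
    mat dYc(cp.W.n_rows, S * static_cast<arma::uword>(N));
    for (int n = 0; n < N; ++n) {
      std::memcpy(dYc.colptr(static_cast<arma::uword>(n) * S),
                  dY.slice(n).memptr(), dY.n_rows * S * sizeof(float));
    }
    cp.dW += dYc * cols_cached->t();
  } else {
  int chunk = conv_chunk(rows, S, N);
  mat cols(rows, S * chunk);
  mat dYc(cp.W.n_rows, S * chunk);
  for (int at = 0; at < N; at += chunk) {
    int hi = std::min(N, at + chunk);
    int nc = hi - at;
    for (int n = at; n < hi; ++n) {
      im2col(X.slice(n), Cin, H, W, cp.k, cp.dil, cols,
             static_cast<arma::uword>(n - at) * S);
      std::memcpy(dYc.colptr(static_cast<arma::uword>(n - at) * S),
                  dY.slice(n).memptr(), dY.n_rows * S * sizeof(float));
    }
    const mat colsc = cols.cols(0, static_cast<arma::uword>(nc) * S - 1);
    const mat dYcc = dYc.cols(0, static_cast<arma::uword>(nc) * S - 1);
    cp.dW += dYcc * colsc.t();
  }
  }
  if (need_dx) {
    // dX is the correlation of dY with the spatially flipped kernel
    // (a stride-1 transposed convolution), evaluated with the same
    // batched im2col machinery instead of a scatter.
    int NF = cp.W.n_rows;
    ConvP tp;
    tp.k = cp.k; tp.dil = cp.dil;
    tp.b.zeros(Cin);
    tp.W.set_size(Cin, static_cast<arma::uword>(NF) * cp.k * cp.k);
    for (int kx = 0; kx < cp.k; ++kx) {
      for (int ky = 0; ky < cp.k; ++ky) {
        int fx = cp.k - 1 - kx, fy = cp.k - 1 - ky;
        for (int f = 0; f < NF; ++f) {
          for (int c = 0; c < Cin; ++c) {
            tp.W(c, static_cast<arma::uword>(kx * cp.k + ky) * NF + f) =
              cp.W(f, static_cast<arma::uword>(fx * cp.k + fy) * Cin + c);
          }
        }
      }
    }
    dX = conv_forward(dY, tp, H, W);
  }
  return dX;
}

static void relu_inplace(cube& X) {
  X.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

static cube bn_forward(const cube& X, BNP& bp, bool training,
                       StageCache* cache) {
  int C = X.n_rows, S = X.n_cols, N = X.n_slices;
  double M = static_cast<double>(S) * N;
  vec mu(C), varv(C);
  if (training) {
    mu.zeros(); varv.zeros();
    for (int n = 0; n < N; ++n) mu += arma::sum(X.slice(n), 1);
    mu /= M;
    for (int n = 0; n < N; ++n) {
      mat d = X.slice(n);
      d.each_col() -= mu;
      varv += arma::sum(arma::square(d), 1);
    }
    varv /= M;
    bp.rm = (1.0 - BN_MOMENTUM) * bp.rm + BN_MOMENTUM * mu;
    bp.rv = (1.0 - BN_MOMENTUM) * bp.rv + BN_MOMENTUM * varv;
  } else {
    mu = bp.rm; varv = bp.rv;
  }
  vec invstd = 1.0 / arma::sqrt(varv + BN_EPS);
  cube Y(C, S, N);
  for (int n = 0; n < N; ++n) {
    mat xh = X.slice(n);
    xh.each_col() -= mu;
    xh.each_col() %= invstd;
    Y.slice(n) = xh;
    Y.slice(n).each_col() %= bp.g;
    Y.slice(n).each_col() += bp.be;
  }
  if (cache) { cache->mu = mu; cache->invstd = invstd; }
  return Y;
}

// Batch-statistics BN backward. A = BN input (cached), dY = grad at output.
static cube bn_backward(const cube& A, const StageCache& cache, BNP& bp,
                        const cube& dY) {
  int C = A.n_rows, S = A.n_cols, N = A.n_slices;
  double M = static_cast<double>(S) * N;
  vec sum_dy(C, arma::fill::zeros), sum_dy_xhat(C, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    mat xh = A.slice(n);
    xh.each_col() -= cache.mu;
    xh.each_col() %= cache.invstd;
    sum_dy += arma::sum(dY.slice(n), 1);
    sum_dy_xhat += arma::sum(dY.slice(n) % xh, 1);
  }
  bp.dbe += sum_dy;
  bp.dg += sum_dy_xhat;
  vec mean_dy = sum_dy / M;
  vec mean_dy_xhat = sum_dy_xhat / M;
  cube dX(C, S, N);
  for (int n = 0; n < N; ++n) {
    mat xh = A.slice(n);
    xh.each_col() -= cache.mu;
    xh.each_col() %= cache.invstd;
    mat t = dY.slice(n);
    t.each_col() -= mean_dy;
    t -= xh.each_col() % mean_dy_xhat;
    t.each_col() %= bp.g % cache.invstd;
    dX.slice(n) = t;
  }
  return dX;
}

static cube maxpool_forward(const cube& X, int H, int W, arma::ucube& idx) {
  int C = X.n_rows, N = X.n_slices;
  int Ho = H / 2, Wo = W / 2;
  cube Y(C, static_cast<arma::uword>(Ho) * Wo, N);
  idx.set_size(C, static_cast<arma::uword>(Ho) * Wo, N);
  for (int n = 0; n < N; ++n) {
    const mat& Xs = X.slice(n);
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        int so = xo * Ho + yo;
        int s00 = (2 * xo) * H + 2 * yo;
        int s01 = (2 * xo + 1) * H + 2 * yo;
        int cand[4] = {s00, s00 + 1, s01, s01 + 1};
        for (int c = 0; c < C; ++c) {
          double best = Xs(c, cand[0]);
          int bi = cand[0];
          for (int q = 1; q < 4; ++q) {
            double v = Xs(c, cand[q]);
            if (v > best) { best = v; bi = cand[q]; }
          }
          Y(c, so, n) = best;
          idx(c, so, n) = bi;
        }
      }
    }
  }
  return Y;
}

static cube maxpool_backward(const cube& dY, const arma::ucube& idx,
                             int C, int H, int W) {
  int N = dY.n_slices;
  cube dX(C, static_cast<arma::uword>(H) * W, N, arma::fill::zeros);
  int So = dY.n_cols;
  for (int n = 0; n < N; ++n) {
    for (int so = 0; so < So; ++so) {
      for (int c = 0; c < C; ++c) {
        dX(c, idx(c, so, n), n) += dY(c, so, n);
      }
    }
  }
  return dX;
}

static cube concat_channels(const std::vector<const cube*>& parts) {
  int S = parts[0]->n_cols, N = parts[0]->n_slices;
  int C = 0;
  for (auto p : parts) C += p->n_rows;
  cube Y(C, S, N);
  for (int n = 0; n < N; ++n) {
    int at = 0;
    for (auto p : parts) {
      Y.slice(n).rows(at, at + p->n_rows - 1) = p->slice(n);
      at += p->n_rows;
    }
  }
  return Y;
}

// conv -> ReLU -> BN stage (or conv -> BN -> ReLU with relu_first = false)
static cube stage_forward(const cube& X, ConvP& cp, BNP& bp, int H, int W,
                          bool training, bool relu_first, StageCache* cache) {
  cube Z = conv_forward(X, cp, H, W, cache ? &cache->cols : nullptr);
  if (relu_first) {
    relu_inplace(Z);
    if (cache) cache->A = Z;
    return bn_forward(Z, bp, training, cache);
  }
  if (cache) cache->A = Z;
  cube Y = bn_forward(Z, bp, training, cache);
  relu_inplace(Y);
  return Y;
}

static cube stage_backward(const cube& Xin, ConvP& cp, BNP& bp,
                           const StageCache& cache, cube dY, int H, int W,
                           bool relu_first, bool need_dx) {
  if (relu_first) {
    cube dA = bn_backward(cache.A, cache, bp, dY);
    // ReLU mask from the cached post-ReLU activations
    for (arma::uword i = 0; i < dA.n_elem; ++i) {
      if (cache.A(i) <= 0.0) dA(i) = 0.0;
    }
    return conv_backward(Xin, cp, dA, H, W, need_dx, &cache.cols);
  }
  // conv -> BN -> ReLU: dY passes the ReLU mask of BN output; the mask is
  // recomputed from the BN output sign via xhat*g+be > 0.
  cube dZmask = dY;
  for (int n = 0; n < (int)dY.n_slices; ++n) {
    mat xh = cache.A.slice(n);
    xh.each_col() -= cache.mu;
    xh.each_col() %= cache.invstd;
    xh.each_col() %= bp.g;
    xh.each_col() += bp.be;
    dZmask.slice(n) %= arma::conv_to<mat>::from(xh > 0.0);
  }
  cube dZ = bn_backward(cache.A, cache, bp, dZmask);
  return conv_backward(Xin, cp, dZ, H, W, need_dx, &cache.cols);
}

// ---------------------------------------------------------------------------
// whole-network forward (+ caches) and backward

struct ForwardState {
  cube x0, p1, p2, ac, f;        // stage inputs needed by backward
  cube gap_mean;                 // C x 1 x N means for the pooling branch
  StageCache st[12];
  arma::ucube idx1, idx2;
  cube drop_mask;
  mat probs;                     // N x 2
  std::vector<arma::uword> c1_dims, c2_dims;
};

static mat softmax_rows(const mat& logits) {
  mat P = logits;
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    float m = P.row(i).max();
    arma::frowvec e = arma::exp(P.row(i) - m);
    P.row(i) = e / arma::accu(e);
  }
  return P;
}

static void net_forward(Net& net, const cube& X, bool training,
                        std::mt19937* rng, ForwardState& fs) {
  const NetConfig& c = net.cfg;
  int H = c.H, W = c.W, N = X.n_slices;
  StageCache* sc = training ? fs.st : nullptr;
  fs.x0 = X;
  // block 1 @ H
  cube y13 = stage_forward(X, net.conv["b1k3"], net.bn[0], H, W, training,
                           c.relu_first, sc ? &fs.st[0] : nullptr);
  cube y15 = stage_forward(X, net.conv["b1k5"], net.bn[1], H, W, training,
                           c.relu_first, sc ? &fs.st[1] : nullptr);
  cube y17 = stage_forward(X, net.conv["b1k7"], net.bn[2], H, W, training,
                           c.relu_first, sc ? &fs.st[2] : nullptr);
  cube c1 = concat_channels({&y13, &y15, &y17, &X});
  y13.reset(); y15.reset(); y17.reset();
  fs.c1_dims = {c1.n_rows, c1.n_cols};
  fs.p1 = maxpool_forward(c1, H, W, fs.idx1);
  c1.reset();
  int H2 = H / 2, W2 = W / 2;
  // block 2 @ H/2
  cube y23 = stage_forward(fs.p1, net.conv["b2k3"], net.bn[3], H2, W2,
                           training, c.relu_first, sc ? &fs.st[3] : nullptr);
  cube y25 = stage_forward(fs.p1, net.conv["b2k5"], net.bn[4], H2, W2,
                           training, c.relu_first, sc ? &fs.st[4] : nullptr);
  cube y27 = stage_forward(fs.p1, net.conv["b2k7"], net.bn[5], H2, W2,
                           training, c.relu_first, sc ? &fs.st[5] : nullptr);
  cube c2 = concat_channels({&y23, &y25, &y27, &fs.p1});
  y23.reset(); y25.reset(); y27.reset();
  fs.c2_dims = {c2.n_rows, c2.n_cols};
  fs.p2 = maxpool_forward(c2, H2, W2, fs.idx2);
  c2.reset();
  int H4 = H2 / 2, W4 = W2 / 2;
  int S4 = H4 * W4;
  // ASPP branches @ H/4
  cube a1 = stage_forward(fs.p2, net.conv["a1"], net.bn[6], H4, W4, training,
                          c.relu_first, sc ? &fs.st[6] : nullptr);
  cube a2 = stage_forward(fs.p2, net.conv["a2"], net.bn[7], H4, W4, training,
                          c.relu_first, sc ? &fs.st[7] : nullptr);
  cube a3 = stage_forward(fs.p2, net.conv["a3"], net.bn[8], H4, W4, training,
                          c.relu_first, sc ? &fs.st[8] : nullptr);
  cube a4 = stage_forward(fs.p2, net.conv["a4"], net.bn[9], H4, W4, training,
                          c.relu_first, sc ? &fs.st[9] : nullptr);
  // branch 5: global average pooling -> 1x1 conv -> broadcast upsample
  int Cp2 = fs.p2.n_rows;
  fs.gap_mean.set_size(Cp2, 1, N);
  cube gap_lin(net.cfg.nf3, S4, N);
  {
    ConvP& g = net.conv["a5"];
    for (int n = 0; n < N; ++n) {
      vec m = arma::mean(fs.p2.slice(n), 1);
      fs.gap_mean.slice(n).col(0) = m;
      vec o = g.W * m + g.b;
      gap_lin.slice(n).each_col() = o;
    }
  }
  cube a5;
  { // ReLU + BN on the broadcast map, mirroring the other branches
    if (c.relu_first) {
      relu_inplace(gap_lin);
      if (sc) fs.st[10].A = gap_lin;
      a5 = bn_forward(gap_lin, net.bn[10], training, sc ? &fs.st[10] : nullptr);
    } else {
      if (sc) fs.st[10].A = gap_lin;
      a5 = bn_forward(gap_lin, net.bn[10], training, sc ? &fs.st[10] : nullptr);
      relu_inplace(a5);
    }
  }
  gap_lin.reset();
  fs.ac = concat_channels({&a1, &a2, &a3, &a4, &a5});
  a1.reset(); a2.reset(); a3.reset(); a4.reset(); a5.reset();
  // fusion 1x1 conv -> ReLU -> BN -> dropout
  cube f = stage_forward(fs.ac, net.conv["fus"], net.bn[11], H4, W4, training,
                         c.relu_first, sc ? &fs.st[11] : nullptr);
  if (training && c.dropout > 0.0 && rng) {
    double keep = 1.0 - c.dropout;
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    fs.drop_mask.set_size(f.n_rows, f.n_cols, f.n_slices);
    for (arma::uword i = 0; i < f.n_elem; ++i) {
      fs.drop_mask(i) = (unif(*rng) < keep) ? (float)(1.0 / keep) : 0.0f;
    }
    f %= fs.drop_mask;
  } else {
    fs.drop_mask.reset();
  }
  fs.f = f;
  // fully connected head
  mat logits(N, 2);
  for (int n = 0; n < N; ++n) {
    vec v = arma::vectorise(f.slice(n));
    logits.row(n) = (net.fcW * v + net.fcb).t();
  }
  fs.probs = softmax_rows(logits);
}

// Cross-entropy loss and full backward pass; gradients are accumulated in
// the Net's d* fields (caller zeroes them first).
static double net_backward(Net& net, const arma::ivec& y, ForwardState& fs) {

  const NetConfig& c = net.cfg;
  int H = c.H, W = c.W, H2 = H / 2, W2 = W / 2, H4 = H2 / 2, W4 = W2 / 2;
  int N = fs.probs.n_rows;
  double loss = 0.0;
  mat dlogits = fs.probs;
  for (int n = 0; n < N; ++n) {
    loss += -std::log(std::max((double)fs.probs(n, y(n)), 1e-12));
    dlogits(n, y(n)) -= 1.0;
  }
  loss /= N;
  dlogits /= N;
  // FC
  cube df(fs.f.n_rows, fs.f.n_cols, N);
  for (int n = 0; n < N; ++n) {
    vec v = arma::vectorise(fs.f.slice(n));
    vec dl = dlogits.row(n).t();
    net.fc_dW += dl * v.t();
    net.fc_db += dl;
    vec dv = net.fcW.t() * dl;
    df.slice(n) = arma::reshape(dv, fs.f.n_rows, fs.f.n_cols);
  }
  if (fs.drop_mask.n_elem > 0) df %= fs.drop_mask;
  // fusion stage
  cube dac = stage_backward(fs.ac, net.conv["fus"], net.bn[11], fs.st[11],
                            df, H4, W4, c.relu_first, true);
  df.reset();
  // split to the five ASPP branches
  int nf3 = c.nf3;
  cube dp2(fs.p2.n_rows, fs.p2.n_cols, N, arma::fill::zeros);
  const char* branch[4] = {"a1", "a2", "a3", "a4"};
  for (int bidx = 0; bidx < 4; ++bidx) {
    cube dbr(nf3, dac.n_cols, N);
    for (int n = 0; n < N; ++n) {
      dbr.slice(n) = dac.slice(n).rows(bidx * nf3, (bidx + 1) * nf3 - 1);
    }
    dp2 += stage_backward(fs.p2, net.conv[branch[bidx]], net.bn[6 + bidx],
                          fs.st[6 + bidx], dbr, H4, W4, c.relu_first, true);
  }
  { // pooling branch: BN/ReLU backward, then the broadcast and mean
    cube dbr(nf3, dac.n_cols, N);
    for (int n = 0; n < N; ++n) {
      dbr.slice(n) = dac.slice(n).rows(4 * nf3, 5 * nf3 - 1);
    }
    cube dlin;
    if (c.relu_first) {
      dlin = bn_backward(fs.st[10].A, fs.st[10], net.bn[10], dbr);
      for (arma::uword i = 0; i < dlin.n_elem; ++i) {
        if (fs.st[10].A(i) <= 0.0) dlin(i) = 0.0;
      }
    } else {
      cube masked = dbr;
      for (int n = 0; n < N; ++n) {
        mat xh = fs.st[10].A.slice(n);
        xh.each_col() -= fs.st[10].mu;
        xh.each_col() %= fs.st[10].invstd;
        xh.each_col() %= net.bn[10].g;
        xh.each_col() += net.bn[10].be;
        masked.slice(n) %= arma::conv_to<mat>::from(xh > 0.0);
      }
      dlin = bn_backward(fs.st[10].A, fs.st[10], net.bn[10], masked);
    }
    ConvP& g = net.conv["a5"];
    int S4 = dlin.n_cols;
    for (int n = 0; n < N; ++n) {
      vec dsum = arma::sum(dlin.slice(n), 1); // broadcast backward
      vec m = fs.gap_mean.slice(n).col(0);
      g.dW += dsum * m.t();
      g.db += dsum;
      vec dm = g.W.t() * dsum;
      dp2.slice(n).each_col() += dm / static_cast<double>(S4);
    }
  }
  dac.reset();
  // unpool 2 and split concat [block2 | p1]
  cube dc2 = maxpool_backward(dp2, fs.idx2, fs.c2_dims[0], H2, W2);
  dp2.reset();
  int nf2 = c.nf2, nf1 = c.nf1;
  cube dp1(fs.p1.n_rows, fs.p1.n_cols, N, arma::fill::zeros);
  const char* b2names[3] = {"b2k3", "b2k5", "b2k7"};
  for (int bidx = 0; bidx < 3; ++bidx) {
    cube dbr(nf2, dc2.n_cols, N);
    for (int n = 0; n < N; ++n) {
      dbr.slice(n) = dc2.slice(n).rows(bidx * nf2, (bidx + 1) * nf2 - 1);
    }
    dp1 += stage_backward(fs.p1, net.conv[b2names[bidx]], net.bn[3 + bidx],
                          fs.st[3 + bidx], dbr, H2, W2, c.relu_first, true);
  }
  for (int n = 0; n < N; ++n) { // the shortcut part of the concat
    dp1.slice(n) += dc2.slice(n).rows(3 * nf2, 3 * nf2 + fs.p1.n_rows - 1);
  }
  dc2.reset();
  // unpool 1 and split concat [block1 | input]; input grad is discarded
  cube dc1 = maxpool_backward(dp1, fs.idx1, fs.c1_dims[0], H, W);
  dp1.reset();
  const char* b1names[3] = {"b1k3", "b1k5", "b1k7"};
  for (int bidx = 0; bidx < 3; ++bidx) {
    cube dbr(nf1, dc1.n_cols, N);
    for (int n = 0; n < N; ++n) {
      dbr.slice(n) = dc1.slice(n).rows(bidx * nf1, (bidx + 1) * nf1 - 1);
    }
    stage_backward(fs.x0, net.conv[b1names[bidx]], net.bn[bidx],
                   fs.st[bidx], dbr, H, W, c.relu_first, false);
  }
  return loss;
}

static void zero_grads(Net& net) {
  for (auto& kv : net.conv) { kv.second.dW.zeros(); kv.second.db.zeros(); }
  for (int i = 0; i < 12; ++i) { net.bn[i].dg.zeros(); net.bn[i].dbe.zeros(); }
  net.fc_dW.zeros(); net.fc_db.zeros();
}

static void sgd_step(Net& net, double lr, double momentum) {
  for (auto& kv : net.conv) {
    ConvP& cp = kv.second;
    cp.vW = momentum * cp.vW - lr * cp.dW; cp.W += cp.vW;
    cp.vb = momentum * cp.vb - lr * cp.db; cp.b += cp.vb;
  }
  for (int i = 0; i < 12; ++i) {
    BNP& bp = net.bn[i];
    bp.vg = momentum * bp.vg - lr * bp.dg; bp.g += bp.vg;
    bp.vbe = momentum * bp.vbe - lr * bp.dbe; bp.be += bp.vbe;
  }
  net.fc_vW = momentum * net.fc_vW - lr * net.fc_dW; net.fcW += net.fc_vW;
  net.fc_vb = momentum * net.fc_vb - lr * net.fc_db; net.fcb += net.fc_vb;
}

static List update_norms(const Net& net) {
  List out;
  for (const auto& kv : net.conv) {
    out[kv.first + ".W"] = arma::norm(kv.second.vW, "fro");
    out[kv.first + ".b"] = arma::norm(kv.second.vb, 2);
  }
  for (int i = 0; i < 12; ++i) {
    std::string nm(CONV_NAMES[i]);
    out[nm + ".gamma"] = arma::norm(net.bn[i].vg, 2);
    out[nm + ".beta"] = arma::norm(net.bn[i].vbe, 2);
  }
  out["fc.W"] = arma::norm(net.fc_vW, "fro");
  out["fc.b"] = arma::norm(net.fc_vb, 2);
  return out;
}

static cube slices_subset(const cube& X, const std::vector<int>& ids) {
  cube Y(X.n_rows, X.n_cols, ids.size());
  for (size_t i = 0; i < ids.size(); ++i) Y.slice(i) = X.slice(ids[i]);
  return Y;
}

// ---------------------------------------------------------------------------
// exported entry points

// Evaluation-mode class probabilities (running BN statistics, no dropout).
// [[Rcpp::export]]
arma::mat cpp_cnn_predict(List params, List cfg, arma::cube Xd, int batch = 64) {
  Net net = load_net(params, cfg);
  cube X = to_fcube(Xd);
  int N = X.n_slices;
  arma::mat probs(N, 2);
  ForwardState fs;
  for (int at = 0; at < N; at += batch) {
    int hi = std::min(N, at + batch);
    std::vector<int> ids;
    for (int i = at; i < hi; ++i) ids.push_back(i);
    cube Xb = slices_subset(X, ids);
    net_forward(net, Xb, false, nullptr, fs);
    probs.rows(at, hi - 1) = arma::conv_to<arma::mat>::from(fs.probs);
  }
  return probs;
}

// Volume shapes probed from an actual forward pass on one sample.
// [[Rcpp::export]]
List cpp_cnn_shapes(List params, List cfg, arma::cube Xd) {
  Net net = load_net(params, cfg);
  cube X = to_fcube(Xd);
  const NetConfig& c = net.cfg;
  int H = c.H;
  // re-run the pieces to capture each stage's dims
  cube y13 = stage_forward(X, net.conv["b1k3"], net.bn[0], H, H, false,
                           c.relu_first, nullptr);
  cube y15 = stage_forward(X, net.conv["b1k5"], net.bn[1], H, H, false,
                           c.relu_first, nullptr);
  cube y17 = stage_forward(X, net.conv["b1k7"], net.bn[2], H, H, false,
                           c.relu_first, nullptr);
  cube b1 = concat_channels({&y13, &y15, &y17});
  cube c1 = concat_channels({&b1, &X});
  arma::ucube idx;
  cube p1 = maxpool_forward(c1, H, H, idx);
  int H2 = H / 2;
  cube y23 = stage_forward(p1, net.conv["b2k3"], net.bn[3], H2, H2, false,
                           c.relu_first, nullptr);
  cube y25 = stage_forward(p1, net.conv["b2k5"], net.bn[4], H2, H2, false,
                           c.relu_first, nullptr);
  cube y27 = stage_forward(p1, net.conv["b2k7"], net.bn[5], H2, H2, false,
                           c.relu_first, nullptr);
  cube b2 = concat_channels({&y23, &y25, &y27});
  cube c2 = concat_channels({&b2, &p1});
  arma::ucube idx2;
  cube p2 = maxpool_forward(c2, H2, H2, idx2);
  int H4 = H2 / 2;
  cube a1 = stage_forward(p2, net.conv["a1"], net.bn[6], H4, H4, false,
                          c.relu_first, nullptr);
  cube a2 = stage_forward(p2, net.conv["a2"], net.bn[7], H4, H4, false,
                          c.relu_first, nullptr);
  cube a3 = stage_forward(p2, net.conv["a3"], net.bn[8], H4, H4, false,
                          c.relu_first, nullptr);
  cube a4 = stage_forward(p2, net.conv["a4"], net.bn[9], H4, H4, false,
                          c.relu_first, nullptr);
  cube gap_lin(c.nf3, H4 * H4, (int)X.n_slices);
  {
    ConvP& g = net.conv["a5"];
    for (int n = 0; n < (int)X.n_slices; ++n) {
      vec m = arma::mean(p2.slice(n), 1);
      gap_lin.slice(n).each_col() = g.W * m + g.b;
    }
  }
  cube ac = concat_channels({&a1, &a2, &a3, &a4, &gap_lin});
  cube f = stage_forward(ac, net.conv["fus"], net.bn[11], H4, H4, false,
                         c.relu_first, nullptr);
  auto shp = [](const cube& v, int side) {
    return IntegerVector::create(_["channels"] = (int)v.n_rows,
                                 _["height"] = side, _["width"] = side);
  };
  return List::create(
    _["input"] = shp(X, H),
    _["block1 output"] = shp(b1, H),
    _["block1 concat"] = shp(c1, H),
    _["after first max-pooling"] = shp(p1, H2),
    _["block2 output"] = shp(b2, H2),
    _["block2 concat"] = shp(c2, H2),
    _["after second max-pooling"] = shp(p2, H4),
    _["aspp pre-fusion concat"] = shp(ac, H4),
    _["aspp output"] = shp(f, H4),
    _["aspp branches"] = 5);
}

// Loss and gradients of one batch (dropout disabled, train-mode BN) for
// finite-difference verification.
// [[Rcpp::export]]
List cpp_cnn_loss_grads(List params, List cfg, arma::cube Xd, arma::ivec y) {
  List cfg2 = clone(cfg);
  cfg2["dropout"] = 0.0;
  Net net = load_net(params, cfg2);
  cube X = to_fcube(Xd);
  ForwardState fs;
  net_forward(net, X, true, nullptr, fs);
  zero_grads(net);
  double loss = net_backward(net, y, fs);
  List grads;
  for (const auto& kv : net.conv) {
    grads[kv.first + ".W"] = put_mat(kv.second.dW);
    grads[kv.first + ".b"] = put_vec(kv.second.db);
  }
  for (int i = 0; i < 12; ++i) {
    std::string nm(CONV_NAMES[i]);
    grads[nm + ".gamma"] = put_vec(net.bn[i].dg);
    grads[nm + ".beta"] = put_vec(net.bn[i].dbe);
  }
  grads["fc.W"] = put_mat(net.fc_dW);
  grads["fc.b"] = put_vec(net.fc_db);
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// Loss only (same modes as cpp_cnn_loss_grads), for finite differences.
// [[Rcpp::export]]
double cpp_cnn_loss(List params, List cfg, arma::cube Xd, arma::ivec y) {
  List cfg2 = clone(cfg);
  cfg2["dropout"] = 0.0;
  Net net = load_net(params, cfg2);
  cube X = to_fcube(Xd);
  ForwardState fs;
  net_forward(net, X, true, nullptr, fs);
  int N = fs.probs.n_rows;
  double loss = 0.0;
  for (int n = 0; n < N; ++n) {
    loss += -std::log(std::max((double)fs.probs(n, y(n)), 1e-12));
  }
  return loss / N;
}

// SGD training loop with per-epoch validation; returns the final and the
// best-validation-accuracy parameters plus the training history.
// [[Rcpp::export]]
List cpp_cnn_train(List params, List cfg, arma::cube Xd, arma::ivec y,
                   arma::cube Xvald, arma::ivec yval, int epochs, int batch,
                   double lr, double momentum, int seed) {
  Net net = load_net(params, cfg);
  cube X = to_fcube(Xd);
  cube Xval = to_fcube(Xvald);
  int N = X.n_slices;
  if (N == 0) stop("empty training data");
  std::mt19937 rng(static_cast<unsigned>(seed));
  NumericVector train_loss(epochs), val_acc(epochs);
  List first_norms;
  List best_params = dump_params(net);
  double best_acc = -1.0;
  int best_epoch = 0;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  ForwardState fs;
  bool first_step = true;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int at = 0; at < N; at += batch) {
      int hi = std::min(N, at + batch);
      std::vector<int> ids(order.begin() + at, order.begin() + hi);
      cube Xb = slices_subset(X, ids);
      arma::ivec yb(ids.size());
      for (size_t i = 0; i < ids.size(); ++i) yb(i) = y(ids[i]);
      net_forward(net, Xb, true, &rng, fs);
      zero_grads(net);
      ep_loss += net_backward(net, yb, fs);
      sgd_step(net, lr, momentum);
      if (first_step) { first_norms = update_norms(net); first_step = false; }
      ++n_batches;
      Rcpp::checkUserInterrupt();
    }
    train_loss[ep] = ep_loss / std::max(1, n_batches);
    // validation accuracy in evaluation mode
    double acc = NA_REAL;
    if (Xval.n_slices > 0) {
      int correct = 0;
      ForwardState fv;
      for (int at = 0; at < (int)Xval.n_slices; at += batch) {
        int hi = std::min((int)Xval.n_slices, at + batch);
        std::vector<int> ids;
        for (int i = at; i < hi; ++i) ids.push_back(i);
        cube Xb = slices_subset(Xval, ids);
        net_forward(net, Xb, false, nullptr, fv);
        for (int i = at; i < hi; ++i) {
          int pred = fv.probs(i - at, 1) > 0.5 ? 1 : 0;
          if (pred == yval(i)) ++correct;
        }
      }
      acc = static_cast<double>(correct) / Xval.n_slices;
      if (acc > best_acc) {
        best_acc = acc;
        best_epoch = ep + 1;
        best_params = dump_params(net);
      }
    }
    val_acc[ep] = acc;
  }
  List final_params = dump_params(net);
  if (Xval.n_slices == 0) { best_params = final_params; best_epoch = epochs; }
  return List::create(_["best_params"] = best_params,
                      _["final_params"] = final_params,
                      _["train_loss"] = train_loss,
                      _["val_acc"] = val_acc,
                      _["best_epoch"] = best_epoch,
                      _["first_step_update_norms"] = first_norms);
}
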