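// U-net forward/backward primitives.
//
// Feature maps are (H*W) x C matrices in R's column-major pixel order
// (pixel p = r + H*c), so an R array H x W x C reshapes to one without
// copying semantics. 3x3 convolutions are im2col + GEMM; weights are
// (Cout x 9*Cin) with column j = cin*9 + o, o = (dc+1)*3 + (dr+1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;

static void im2col3(const mat& X, int H, int W, mat& col) {
  const int C = X.n_cols;
  col.zeros(H * W, 9 * C);
  for (int k = 0; k < C; ++k) {
    const double* src = X.colptr(k);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int o = (dc + 1) * 3 + (dr + 1);
        double* dst = col.colptr(k * 9 + o);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int c = c0; c < c1; ++c) {
          const double* s = src + (c + dc) * H + (r0 + dr);
          std::copy(s, s + (r1 - r0), dst + c * H + r0);
        }
      }
    }
  }
}

static void col2im3(const mat& dcol, int H, int W, mat& dX) {
  const int C = dX.n_cols;
  dX.zeros();
  for (int k = 0; k < C; ++k) {
    double* dst = dX.colptr(k);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int o = (dc + 1) * 3 + (dr + 1);
        const double* src = dcol.colptr(k * 9 + o);
        const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int c = c0; c < c1; ++c) {
          const double* s = src + c * H + r0;
          double* d = dst + (c + dc) * H + (r0 + dr);
          for (int r = 0; r < r1 - r0; ++r) d[r] += s[r];
        }
      }
    }
  }
}

static mat conv3_fwd(const mat& X, int H, int W, const mat& Wt, const rowvec& b) {
  mat col;
  im2col3(X, H, W, col);
  mat Y = col * Wt.t();
  Y.each_row() += b;
  return Y;
}

// gradients of a 3x3 conv given its input and the output gradient
static void conv3_bwd(const mat& X, int H, int W, const mat& Wt,
                      const mat& dY, mat& dX, mat& dW, rowvec& db) {
  mat col;
  im2col3(X, H, W, col);
  dW = dY.t() * col;
  db = arma::sum(dY, 0);
  mat dcol = dY * Wt;
  dX.set_size(X.n_rows, X.n_cols);
  col2im3(dcol, H, W, dX);
}

static mat avgpool2(const mat& X, int H, int W) {
  const int H2 = H / 2, W2 = W / 2, C = X.n_cols;
  mat Y(H2 * W2, C);
  for (int k = 0; k < C; ++k) {
    const double* s = X.colptr(k);
    double* d = Y.colptr(k);
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r) {
        const double* b = s + (2 * c) * H + 2 * r;
        d[c * H2 + r] = 0.25 * (b[0] + b[1] + b[H] + b[H + 1]);
      }
  }
  return Y;
}

static mat avgpool2_bwd(const mat& dY, int H, int W) {
  const int H2 = H / 2, W2 = W / 2, C = dY.n_cols;
  mat dX(H * W, C, arma::fill::zeros);
  for (int k = 0; k < C; ++k) {
    const double* s = dY.colptr(k);
    double* d = dX.colptr(k);
    for (int c = 0; c < W2; ++c)
      for (int r = 0; r < H2; ++r) {
        const double g = 0.25 * s[c * H2 + r];
        double* b = d + (2 * c) * H + 2 * r;
        b[0] += g; b[1] += g; b[H] += g; b[H + 1] += g;
      }
  }
  return dX;
}

struct UpIdx {
  std::vector<int> i0, i1;
  std::vector<double> w;
};

// 2x bilinear sampling grid: output i samples input at (i + 0.5)/2 - 0.5
static UpIdx upidx(int H) {
  UpIdx u;
  u.i0.resize(2 * H); u.i1.resize(2 * H); u.w.resize(2 * H);
  for (int i = 0; i < 2 * H; ++i) {
    double src = (i + 0.5) / 2.0 - 0.5;
    int a = (int)std::floor(src);
    double w = src - a;
    if (a < 0) { a = 0; w = 0.0; }
    int b = a + 1;
    if (b > H - 1) { b = H - 1; w = 0.0; }
    u.i0[i] = a; u.i1[i] = b; u.w[i] = w;
  }
  return u;
}

static mat up2(const mat& X, int H, int W) {
  UpIdx ur = upidx(H), uc = upidx(W);
  const int C = X.n_cols;
  mat Y(4 * H * W, C);
  std::vector<double> tmp(2 * H * W);
  for (int k = 0; k < C; ++k) {
    const double* s = X.colptr(k);
    double* d = Y.colptr(k);
    for (int c = 0; c < W; ++c) {
      const double* sc = s + c * H;
      double* tc = tmp.data() + c * 2 * H;
      for (int i = 0; i < 2 * H; ++i)
        tc[i] = (1 - ur.w[i]) * sc[ur.i0[i]] + ur.w[i] * sc[ur.i1[i]];
    }
    for (int j = 0; j < 2 * W; ++j) {
      double* dc = d + j * 2 * H;
      const double* c0 = tmp.data() + uc.i0[j] * 2 * H;
      const double* c1 = tmp.data() + uc.i1[j] * 2 * H;
      const double w = uc.w[j];
      for (int i = 0; i < 2 * H; ++i) dc[i] = (1 - w) * c0[i] + w * c1[i];
    }
  }
  return Y;
}

static mat up2_bwd(const mat& dY, int H, int W) {
  UpIdx ur = upidx(H), uc = upidx(W);
  const int C = dY.n_cols;
  mat dX(H * W, C, arma::fill::zeros);
  std::vector<double> tmp(2 * H * W);
  for (int k = 0; k < C; ++k) {
    const double* s = dY.colptr(k);
    double* d = dX.colptr(k);
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int j = 0; j < 2 * W; ++j) {
      const double* sc = s + j * 2 * H;
      const double w = uc.w[j];
      double* t0 = tmp.data() + uc.i0[j] * 2 * H;
      double* t1 = tmp.data() + uc.i1[j] * 2 * H;
      for (int i = 0; i < 2 * H; ++i) { t0[i] += (1 - w) * sc[i]; t1[i] += w * sc[i]; }
    }
    for (int c = 0; c < W; ++c) {
      const double* tc = tmp.data() + c * 2 * H;
      double* dcn = d + c * H;
      for (int i = 0; i < 2 * H; ++i) {
        dcn[ur.i0[i]] += (1 - ur.w[i]) * tc[i];
        dcn[ur.i1[i]] += ur.w[i] * tc[i];
      }
    }
  }
  return dX;
}

// zero the entries of G where the (post-ReLU) activation A is zero
static void mask_relu(mat& G, const mat& A) {
  const double* a = A.memptr();
  double* g = G.memptr();
  const arma::uword n = G.n_elem;
  for (arma::uword i = 0; i < n; ++i)
    if (a[i] <= 0) g[i] = 0.0;
}

static mat getmat(const List& p, const std::string& nm) {
  return as<mat>(p[nm]);
}

struct Net {
  int L;
  std::vector<mat> eaW, ebW, pW, daW, dbW;
  std::vector<rowvec> eab, ebb, pb, dab, dbb;
  mat finW;
  rowvec finb;
};

static Net load_net(const List& p, int L) {
  Net n;
  n.L = L;
  for (int l = 1; l <= L; ++l) {
    std::string s = std::to_string(l);
    n.eaW.push_back(getmat(p, "enc" + s + "_aW"));
    n.eab.push_back(as<rowvec>(p["enc" + s + "_ab"]));
    n.ebW.push_back(getmat(p, "enc" + s + "_bW"));
    n.ebb.push_back(as<rowvec>(p["enc" + s + "_bb"]));
    n.pW.push_back(getmat(p, "dec" + s + "_pW"));
    n.pb.push_back(as<rowvec>(p["dec" + s + "_pb"]));
    n.daW.push_back(getmat(p, "dec" + s + "_aW"));
    n.dab.push_back(as<rowvec>(p["dec" + s + "_ab"]));
    n.dbW.push_back(getmat(p, "dec" + s + "_bW"));
    n.dbb.push_back(as<rowvec>(p["dec" + s + "_bb"]));
  }
  n.finW = getmat(p, "finW");
  n.finb = as<rowvec>(p["finb"]);
  return n;
}

struct Acts {
  // caches needed for the backward pass
  std::vector<mat> enc_in, enc_mid, skip;       // per level
  std::vector<mat> dec_up_in, dec_up, dec_cat, dec_mid, dec_out;
  mat bottom_in; // skip[L-1] (input to last pool)
  mat pred_in;   // input to final 1x1
};

static mat forward(const Net& n, const mat& x0, int H, int W, Acts* a) {
  mat X = x0;
  int h = H, w = W;
  std::vector<mat> skip(n.L);
  for (int l = 0; l < n.L; ++l) {
    if (a) a->enc_in.push_back(X);
    mat A = conv3_fwd(X, h, w, n.eaW[l], n.eab[l]);
    A.transform([](double v) { return v > 0 ? v : 0.0; });
    if (a) a->enc_mid.push_back(A);
    mat B = conv3_fwd(A, h, w, n.ebW[l], n.ebb[l]);
    B.transform([](double v) { return v > 0 ? v : 0.0; });
    skip[l] = B;
    X = avgpool2(B, h, w);
    h /= 2; w /= 2;
  }
  if (a) a->skip = skip;
  for (int l = n.L - 1; l >= 0; --l) {
    if (a) a->dec_up_in.push_back(X);
    mat U = up2(X, h, w);
    h *= 2; w *= 2;
    if (a) a->dec_up.push_back(U);
    mat P = U * n.pW[l].t();
    P.each_row() += n.pb[l];
    mat K = arma::join_rows(P, skip[l]);
    if (a) a->dec_cat.push_back(K);
    mat A = conv3_fwd(K, h, w, n.daW[l], n.dab[l]);
    A.transform([](double v) { return v > 0 ? v : 0.0; });
    if (a) a->dec_mid.push_back(A);
    mat B = conv3_fwd(A, h, w, n.dbW[l], n.dbb[l]);
    B.transform([](double v) { return v > 0 ? v : 0.0; });
    if (a) a->dec_out.push_back(B);
    X = B;
  }
  if (a) a->pred_in = X;
  mat pred = X * n.finW.t();
  pred.each_row() += n.finb;
  return pred;
}

// [[Rcpp::export]]
NumericMatrix unet_forward_cpp(List params, NumericVector x, int H, int W,
                               int L, int in_channels) {
  mat X(x.begin(), H * W, in_channels);
  Net n = load_net(params, L);
  mat pred = forward(n, X, H, W, nullptr);
  NumericMatrix out(H, W);
  std::copy(pred.colptr(0), pred.colptr(0) + H * W, out.begin());
  return out;
}

// [[Rcpp::export]]
List unet_grad_cpp(List params, NumericVector x, NumericVector y,
                   int H, int W, int L, int in_channels) {
  mat X(x.begin(), H * W, in_channels);
  mat Y(y.begin(), H * W, 1);
  Net n = load_net(params, L);
  Acts a;
  mat pred = forward(n, X, H, W, &a);

  const double m = (double)(H * W);
  mat diff = pred - Y;
  double loss = arma::accu(arma::abs(diff)) / m;
  mat dpred = arma::sign(diff) / m;

  List g;
  // final 1x1
  g["finW"] = wrap(mat(dpred.t() * a.pred_in));
  g["finb"] = wrap(rowvec(arma::sum(dpred, 0)));
  mat dX = dpred * n.finW;

  int h = H, w = W;
  std::vector<mat> dskip(n.L);
  // decoder backward, l = 0 (top level, executed last) .. L-1 (bottom)
  for (int l = 0; l < n.L; ++l) {
    const int di = n.L - 1 - l; // index into dec_* vectors (pushed bottom-first)
    std::string s = std::to_string(l + 1);
    mat dB = dX; mask_relu(dB, a.dec_out[di]);
    mat dA, dWb; rowvec dbb_;
    conv3_bwd(a.dec_mid[di], h, w, n.dbW[l], dB, dA, dWb, dbb_);
    g["dec" + s + "_bW"] = wrap(dWb);
    g["dec" + s + "_bb"] = wrap(dbb_);
    mask_relu(dA, a.dec_mid[di]);
    mat dK, dWa; rowvec dab_;
    conv3_bwd(a.dec_cat[di], h, w, n.daW[l], dA, dK, dWa, dab_);
    g["dec" + s + "_aW"] = wrap(dWa);
    g["dec" + s + "_ab"] = wrap(dab_);
    const int Sc = n.pW[l].n_rows; // projected channel count
    mat dP = dK.cols(0, Sc - 1);
    dskip[l] = dK.cols(Sc, dK.n_cols - 1);
    g["dec" + s + "_pW"] = wrap(mat(dP.t() * a.dec_up[di]));
    g["dec" + s + "_pb"] = wrap(rowvec(arma::sum(dP, 0)));
    mat dU = dP * n.pW[l];
    h /= 2; w /= 2;
    dX = up2_bwd(dU, h, w);
  }
  // dX now holds the gradient at the bottom (output of the last pool);
  // encoder backward from bottom to top
  for (int l = n.L - 1; l >= 0; --l) {
    std::string s = std::to_string(l + 1);
    int eh = H >> l, ew = W >> l; // spatial size of this encoder level
    mat dB = avgpool2_bwd(dX, eh, ew);
    dB += dskip[l]; // gradient flowing in through the skip connection
    mask_relu(dB, a.skip[l]); // relu mask of encoder conv_b output
    mat dA, dWb; rowvec dbb_;
    conv3_bwd(a.enc_mid[l], eh, ew, n.ebW[l], dB, dA, dWb, dbb_);
    g["enc" + s + "_bW"] = wrap(dWb);
    g["enc" + s + "_bb"] = wrap(dbb_);
    mask_relu(dA, a.enc_mid[l]);
    mat dIn, dWa; rowvec dab_;
    conv3_bwd(a.enc_in[l], eh, ew, n.eaW[l], dA, dIn, dWa, dab_);
    g["enc" + s + "_aW"] = wrap(dWa);
    g["enc" + s + "_ab"] = wrap(dab_);
    dX = dIn; // unused at l == 0
  }

  NumericMatrix predm(H, W);
  std::copy(pred.colptr(0), pred.colptr(0) + H * W, predm.begin());
  return List::create(_["loss"] = loss, _["grads"] = g, _["pred"] = predm);
}
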