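// Core numerics for the layered classifier: 3x3 same-padding convolutions via
// im2col + GEMM, 2x2 max pooling, dense layers, inverted dropout, softmax
// cross-entropy, and Adam. Activations use the flattened layout
// idx = y + h*x + h*w*channel (column-major spatial, channel slowest), which
// matches as.vector() on an R array of dim c(h, w, c).
//
// All arithmetic is single precision; weights handed in from R are doubles
// that are exactly float-representable (they are always written back from
// floats), so the double<->float round trip is lossless.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

static const double ADAM_B1 = 0.9;
static const double ADAM_B2 = 0.999;
static const double ADAM_EPS = 1e-7;

struct Layer {
  std::string type;   // "conv", "pool", "dense", "dropout"
  fmat W;
  fvec b;
  int h = 0, w = 0, c = 0;  // input spatial dims (conv/pool)
  int cout = 0;             // conv output channels
  std::string act;          // dense: "relu" or "softmax"
  double rate = 0.0;        // dropout
  // caches for backward
  fmat in;       // input activations (d_in x n)
  fmat col;      // conv: im2col matrix
  fmat z;        // conv: pre-ReLU output in (cout x hw*n) layout; dense: pre-act
  arma::umat amax;  // pool: argmax input indices (d_out x n)
  fmat mask;     // dropout mask
};

static std::vector<Layer> parse_layers(const List& layers) {
  std::vector<Layer> net;
  net.reserve(layers.size());
  for (int i = 0; i < layers.size(); ++i) {
    List sp(layers[i]);
    Layer L;
    L.type = as<std::string>(sp["type"]);
    if (L.type == "conv") {
      L.W = arma::conv_to<fmat>::from(as<arma::mat>(sp["W"]));
      L.b = arma::conv_to<fvec>::from(as<arma::vec>(sp["b"]));
      L.h = as<int>(sp["h"]); L.w = as<int>(sp["w"]); L.c = as<int>(sp["c"]);
      L.cout = (int)L.W.n_rows;
    } else if (L.type == "pool") {
      L.h = as<int>(sp["h"]); L.w = as<int>(sp["w"]); L.c = as<int>(sp["c"]);
      if (L.h % 2 || L.w % 2) stop("pool layer requires even spatial dims");
    } else if (L.type == "dense") {
      L.W = arma::conv_to<fmat>::from(as<arma::mat>(sp["W"]));
      L.b = arma::conv_to<fvec>::from(as<arma::vec>(sp["b"]));
      L.act = as<std::string>(sp["act"]);
    } else if (L.type == "dropout") {
      L.rate = as<double>(sp["rate"]);
    } else {
      stop("unknown layer type '%s'", L.type.c_str());
    }
    net.push_back(std::move(L));
  }
  return net;
}

// im2col for 3x3 kernels, zero 'same' padding.
// Output: (c*9) x (h*w*n); row index = (ky + 3*kx) + 9*ch, ky/kx in {0,1,2}
// standing for offsets {-1,0,+1}; column index = (y + h*x) + h*w*s.
// Each output column is written contiguously (interior pixels via a
// branch-free fast path) so the construction is cache-friendly.
static fmat im2col3(const fmat& A, int h, int w, int c) {
  const int n = (int)A.n_cols, hw = h * w, K = c * 9;
  fmat col(K, (uword)hw * n);
  for (int s = 0; s < n; ++s) {
    const float* a = A.colptr(s);
    for (int x = 0; x < w; ++x) {
      const bool xin = (x > 0 && x < w - 1);
      for (int y = 0; y < h; ++y) {
        float* dst = col.colptr((uword)hw * s + (uword)h * x + y);
        if (xin && y > 0 && y < h - 1) {
          const float* base = a + (y - 1) + (size_t)h * (x - 1);
          for (int ch = 0; ch < c; ++ch) {
            const float* src = base + (size_t)hw * ch;
            float* d = dst + 9 * ch;
            std::memcpy(d, src, 3 * sizeof(float));
            std::memcpy(d + 3, src + h, 3 * sizeof(float));
            std::memcpy(d + 6, src + 2 * (size_t)h, 3 * sizeof(float));
          }
        } else {
          for (int ch = 0; ch < c; ++ch) {
            const float* ach = a + (size_t)hw * ch;
            float* d = dst + 9 * ch;
            for (int kx = 0; kx < 3; ++kx) {
              int sx = x + kx - 1;
              for (int ky = 0; ky < 3; ++ky) {
                int sy = y + ky - 1;
                d[ky + 3 * kx] = (sx >= 0 && sx < w && sy >= 0 && sy < h)
                                   ? ach[sy + (size_t)h * sx] : 0.0f;
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// adjoint of im2col3: scatter-add columns back into image layout
static fmat col2im3(const fmat& dcol, int h, int w, int c, int n) {
  const int hw = h * w;
  fmat dA((uword)hw * c, n, arma::fill::zeros);
  for (int s = 0; s < n; ++s) {
    float* a = dA.colptr(s);
    for (int x = 0; x < w; ++x) {
      const bool xin = (x > 0 && x < w - 1);
      for (int y = 0; y < h; ++y) {
        const float* src = dcol.colptr((uword)hw * s + (uword)h * x + y);
        if (xin && y > 0 && y < h - 1) {
          float* base = a + (y - 1) + (size_t)h * (x - 1);
          for (int ch = 0; ch < c; ++ch) {
            float* d = base + (size_t)hw * ch;
            const float* sc = src + 9 * ch;
            for (int ky = 0; ky < 3; ++ky) {
              d[ky] += sc[ky];
              d[ky + (size_t)h] += sc[ky + 3];
              d[ky + 2 * (size_t)h] += sc[ky + 6];
            }
          }
        } else {
          for (int ch = 0; ch < c; ++ch) {
            float* ach = a + (size_t)hw * ch;
            const float* sc = src + 9 * ch;
            for (int kx = 0; kx < 3; ++kx) {
              int sx = x + kx - 1;
              if (sx < 0 || sx >= w) continue;
              for (int ky = 0; ky < 3; ++ky) {
                int sy = y + ky - 1;
                if (sy >= 0 && sy < h) ach[sy + (size_t)h * sx] += sc[ky + 3 * kx];
              }
            }
          }
        }
      }
    }
  }
  return dA;
}

// permute (cout x hw*n) -> (hw*cout x n)
static fmat chw_to_cols(const fmat& Z, int hw, int cout, int n) {
  fmat out((uword)hw * cout, n);
  for (int s = 0; s < n; ++s) {
    fmat blk = Z.cols((uword)hw * s, (uword)hw * (s + 1) - 1);  // cout x hw
    out.col(s) = arma::vectorise(blk.t());
  }
  return out;
}

// inverse permutation: (hw*cout x n) -> (cout x hw*n)
static fmat cols_to_chw(const fmat& A, int hw, int cout, int n) {
  fmat out(cout, (uword)hw * n);
  for (int s = 0; s < n; ++s) {
    const fmat blk(const_cast<float*>(A.colptr(s)), hw, cout, false, true);
    out.cols((uword)hw * s, (uword)hw * (s + 1) - 1) = fmat(blk.t());
  }
  return out;
}

static void softmax_cols(fmat& Z) {
  for (uword j = 0; j < Z.n_cols; ++j) {
    fvec col = Z.col(j);
    col -= col.max();
    col = arma::exp(col);
    Z.col(j) = col / arma::accu(col);
  }
}

// forward through all layers; caches intermediates when train = true
static fmat forward_pass(std::vector<Layer>& net, const fmat& X, bool train) {
  fmat A = X;
  const int n = (int)X.n_cols;
  for (auto& L : net) {
    if (L.type == "conv") {
      if (train) L.in = A;
      fmat col = im2col3(A, L.h, L.w, L.c);
      fmat Z = L.W * col;               // cout x hw*n
      Z.each_col() += L.b;
      if (train) { L.col = std::move(col); L.z = Z; }
      Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      A = chw_to_cols(Z, L.h * L.w, L.cout, n);
    } else if (L.type == "pool") {
      const int h = L.h, w = L.w, c = L.c, h2 = h / 2, w2 = w / 2;
      fmat out((uword)h2 * w2 * c, n);
      arma::umat amax((uword)h2 * w2 * c, n);
      for (int s = 0; s < n; ++s) {
        const float* a = A.colptr(s);
        float* o = out.colptr(s);
        uword* m = amax.colptr(s);
        for (int ch = 0; ch < c; ++ch)
          for (int x2 = 0; x2 < w2; ++x2)
            for (int y2 = 0; y2 < h2; ++y2) {
              uword base = (uword)h * w * ch;
              uword i00 = base + (uword)h * (2 * x2) + 2 * y2;
              uword idx[4] = {i00, i00 + 1, i00 + (uword)h, i00 + (uword)h + 1};
              uword best = idx[0];
              float bv = a[idx[0]];
              for (int k = 1; k < 4; ++k)
                if (a[idx[k]] > bv) { bv = a[idx[k]]; best = idx[k]; }
              uword oi = (uword)h2 * w2 * ch + (uword)h2 * x2 + y2;
              o[oi] = bv; m[oi] = best;
            }
      }
      if (train) L.amax = std::move(amax);
      A = std::move(out);
    } else if (L.type == "dense") {
      if (train) L.in = A;
      fmat Z = L.W * A;
      Z.each_col() += L.b;
      if (L.act == "relu") {
        if (train) L.z = Z;
        Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      } else if (L.act == "softmax") {
        softmax_cols(Z);
      }
      A = std::move(Z);
    } else if (L.type == "dropout") {
      if (train) {
        fmat mask(A.n_rows, A.n_cols);
        const float scale = (float)(1.0 / (1.0 - L.rate));
        for (uword j = 0; j < mask.n_cols; ++j)
          for (uword i = 0; i < mask.n_rows; ++i)
            mask(i, j) = (R::unif_rand() >= L.rate) ? scale : 0.0f;
        A %= mask;
        L.mask = std::move(mask);
      }
      // eval mode: identity (inverted dropout)
    }
  }
  return A;
}

// [[Rcpp::export(rng = false)]]
arma::mat net_forward_cpp(List layers, const arma::mat& X) {
  std::vector<Layer> net = parse_layers(layers);
  fmat Xf = arma::conv_to<fmat>::from(X);
  fmat P = forward_pass(net, Xf, false);
  return arma::conv_to<arma::mat>::from(P);
}

// [[Rcpp::export(rng = false)]]
arma::mat net_activations_cpp(List layers, const arma::mat& X, int upto) {
  if (upto < 1 || upto > layers.size()) stop("layer index out of range");
  std::vector<Layer> net = parse_layers(layers);
  net.resize(upto);
  fmat Xf = arma::conv_to<fmat>::from(X);
  fmat A = forward_pass(net, Xf, false);
  return arma::conv_to<arma::mat>::from(A);
}

// One full epoch of minibatch training with softmax cross-entropy and Adam.
// y is 0-based class ids; order is a 0-based permutation of columns of X.
// adam is list(t = int, layers = list per layer of list(mW, vW, mb, vb)) or
// empty (initialised here). Returns updated layers, adam state, mean loss.
// [[Rcpp::export]]
List net_train_epoch_cpp(List layers, const arma::mat& X, IntegerVector y,
                         List adam, double lr, int batch_size,
                         IntegerVector order, int n_classes) {
  std::vector<Layer> net = parse_layers(layers);
  const int n = (int)X.n_cols;
  if (batch_size < 1) stop("batch_size must be >= 1");
  if ((int)order.size() != n) stop("order must permute all samples");

  // Adam state in float
  int t = 0;
  std::vector<fmat> mW(net.size()), vW(net.size());
  std::vector<fvec> mb(net.size()), vb(net.size());
  bool fresh = adam.size() == 0;
  List ast;
  if (!fresh) { t = as<int>(adam["t"]); ast = as<List>(adam["layers"]); }
  for (size_t i = 0; i < net.size(); ++i) {
    if (net[i].type != "conv" && net[i].type != "dense") continue;
    if (fresh) {
      mW[i].zeros(net[i].W.n_rows, net[i].W.n_cols);
      vW[i].zeros(net[i].W.n_rows, net[i].W.n_cols);
      mb[i].zeros(net[i].b.n_elem);
      vb[i].zeros(net[i].b.n_elem);
    } else {
      List li(ast[i]);
      mW[i] = arma::conv_to<fmat>::from(as<arma::mat>(li["mW"]));
      vW[i] = arma::conv_to<fmat>::from(as<arma::mat>(li["vW"]));
      mb[i] = arma::conv_to<fvec>::from(as<arma::vec>(li["mb"]));
      vb[i] = arma::conv_to<fvec>::from(as<arma::vec>(li["vb"]));
    }
  }

  double total_loss = 0.0;
  for (int start = 0; start < n; start += batch_size) {
    int bn = std::min(batch_size, n - start);
    fmat Xb(X.n_rows, bn);
    arma::ivec yb(bn);
    for (int j = 0; j < bn; ++j) {
      int idx = order[start + j];
      Xb.col(j) = arma::conv_to<fvec>::from(X.col(idx));
      yb[j] = y[idx];
    }
    fmat P = forward_pass(net, Xb, true);
    // loss + output gradient
    double loss = 0.0;
    fmat dA = P;
    for (int j = 0; j < bn; ++j) {
      float p = std::max(P((uword)yb[j], j), 1e-12f);
      loss += -std::log((double)p);
      dA((uword)yb[j], j) -= 1.0f;
    }
    loss /= bn;
    total_loss += loss * bn;
    dA /= (float)bn;

    // backward
    ++t;
    const float bc1 = (float)(1.0 - std::pow(ADAM_B1, t));
    const float bc2 = (float)(1.0 - std::pow(ADAM_B2, t));
    for (int li = (int)net.size() - 1; li >= 0; --li) {
      Layer& L = net[li];
      if (L.type == "dense") {
        if (L.act == "relu")
          dA %= arma::conv_to<fmat>::from(L.z > 0.0f);
        fmat dW = dA * L.in.t();
        fvec db = arma::sum(dA, 1);
        fmat dIn = L.W.t() * dA;
        // Adam
        mW[li] = (float)ADAM_B1 * mW[li] + (float)(1 - ADAM_B1) * dW;
        vW[li] = (float)ADAM_B2 * vW[li] + (float)(1 - ADAM_B2) * arma::square(dW);
        L.W -= (float)lr * (mW[li] / bc1) / (arma::sqrt(vW[li] / bc2) + (float)ADAM_EPS);
        mb[li] = (float)ADAM_B1 * mb[li] + (float)(1 - ADAM_B1) * db;
        vb[li] = (float)ADAM_B2 * vb[li] + (float)(1 - ADAM_B2) * arma::square(db);
        L.b -= (float)lr * (mb[li] / bc1) / (arma::sqrt(vb[li] / bc2) + (float)ADAM_EPS);
        dA = std::move(dIn);
      } else if (L.type == "conv") {
        const int hw = L.h * L.w;
        fmat dZ = cols_to_chw(dA, hw, L.cout, bn);
        dZ %= arma::conv_to<fmat>::from(L.z > 0.0f);
        fmat dW = dZ * L.col.t();
        fvec db = arma::sum(dZ, 1);
        fmat dcol = L.W.t() * dZ;
        fmat dIn = col2im3(dcol, L.h, L.w, L.c, bn);
        mW[li] = (float)ADAM_B1 * mW[li] + (float)(1 - ADAM_B1) * dW;
        vW[li] = (float)ADAM_B2 * vW[li] + (float)(1 - ADAM_B2) * arma::square(dW);
        L.W -= (float)lr * (mW[li] / bc1) / (arma::sqrt(vW[li] / bc2) + (float)ADAM_EPS);
        mb[li] = (float)ADAM_B1 * mb[li] + (float)(1 - ADAM_B1) * db;
        vb[li] = (float)ADAM_B2 * vb[li] + (float)(1 - ADAM_B2) * arma::square(db);
        L.b -= (float)lr * (mb[li] / bc1) / (arma::sqrt(vb[li] / bc2) + (float)ADAM_EPS);
        dA = std::move(dIn);
        L.col.reset(); L.z.reset(); L.in.reset();
      } else if (L.type == "pool") {
        const int h = L.h, w = L.w, c = L.c;
        fmat dIn((uword)h * w * c, bn, arma::fill::zeros);
        for (int s = 0; s < bn; ++s) {
          const uword* m = L.amax.colptr(s);
          const float* g = dA.colptr(s);
          float* o = dIn.colptr(s);
          uword dout = (uword)(h / 2) * (w / 2) * c;
          for (uword i = 0; i < dout; ++i) o[m[i]] += g[i];
        }
        dA = std::move(dIn);
      } else if (L.type == "dropout") {
        dA %= L.mask;
        L.mask.reset();
      }
    }
  }

  // pack results back to R (doubles)
  List out_layers = clone(layers);
  List out_adam_layers(net.size());
  for (size_t i = 0; i < net.size(); ++i) {
    if (net[i].type == "conv" || net[i].type == "dense") {
      List sp(out_layers[i]);
      sp["W"] = wrap(arma::conv_to<arma::mat>::from(net[i].W));
      arma::vec bd = arma::conv_to<arma::vec>::from(net[i].b);
      sp["b"] = NumericVector(bd.begin(), bd.end());
      out_layers[i] = sp;
      out_adam_layers[i] = List::create(
        _["mW"] = wrap(arma::conv_to<arma::mat>::from(mW[i])),
        _["vW"] = wrap(arma::conv_to<arma::mat>::from(vW[i])),
        _["mb"] = wrap(arma::conv_to<arma::vec>::from(mb[i])),
        _["vb"] = wrap(arma::conv_to<arma::vec>::from(vb[i])));
    } else {
      out_adam_layers[i] = R_NilValue;
    }
  }
  return List::create(
    _["layers"] = out_layers,
    _["adam"] = List::create(_["t"] = t, _["layers"] = out_adam_layers),
    _["loss"] = total_loss / n);
}

// [[Rcpp::export(rng = false)]]
NumericVector float_round_cpp(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = (double)(float)x[i];
  return y;
}

// ---- augmentation -------------------------------------------------------

// symmetric reflection of index i into [0, n)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int p = 2 * n;
  i %= p;
  if (i < 0) i += p;
  return (i < n) ? i : p - 1 - i;
}

// Affine augmentation by inverse mapping with bilinear interpolation and
// symmetric-reflection fill. params: 5 x n matrix with rows
// (angle_rad, shift_x_px, shift_y_px, zoom, flip(0/1)).
// [[Rcpp::export(rng = false)]]
arma::mat augment_batch_cpp(const arma::mat& X, int h, int w,
                            const arma::mat& params) {
  const int n = (int)X.n_cols;
  const int c = (int)(X.n_rows / ((size_t)h * w));
  if ((size_t)h * w * c != X.n_rows) stop("image size does not divide input");
  if ((int)params.n_cols != n || params.n_rows != 5)
    stop("params must be 5 x n");
  arma::mat out(X.n_rows, n);
  const double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  for (int s = 0; s < n; ++s) {
    const double th = params(0, s), tx = params(1, s), ty = params(2, s);
    const double z = params(3, s);
    const bool flip = params(4, s) != 0.0;
    const double ct = std::cos(th), st = std::sin(th);
    const double* in = X.colptr(s);
    double* o = out.colptr(s);
    for (int x = 0; x < w; ++x) {
      for (int y = 0; y < h; ++y) {
        double u = x - cx - tx, v = y - cy - ty;
        double su = (ct * u + st * v) / z;
        double sv = (-st * u + ct * v) / z;
        double sx = cx + su, sy = cy + sv;
        if (flip) sx = (w - 1) - sx;
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        double fx = sx - x0, fy = sy - y0;
        int x0r = reflect_idx(x0, w), x1r = reflect_idx(x0 + 1, w);
        int y0r = reflect_idx(y0, h), y1r = reflect_idx(y0 + 1, h);
        for (int ch = 0; ch < c; ++ch) {
          const double* a = in + (size_t)h * w * ch;
          double v00 = a[y0r + (size_t)h * x0r], v01 = a[y0r + (size_t)h * x1r];
          double v10 = a[y1r + (size_t)h * x0r], v11 = a[y1r + (size_t)h * x1r];
          double val = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                       fy * ((1 - fx) * v10 + fx * v11);
          o[y + (size_t)h * x + (size_t)h * w * ch] = val;
        }
      }
    }
  }
  return out;
}
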