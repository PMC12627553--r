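// Compact sequential CNN for spectrogram-tile classification.
//
// The network is a stack of valid (unpadded) square convolutions with
// stride 1, each followed by ReLU, non-overlapping 2x2 max pooling and
// (in training mode) inverted dropout; a global average pool reduces the
// final feature map to one value per channel, followed by fully connected
// ReLU layers and a single logistic output unit.
//
// The core computes in single precision (the standard for CNN training):
// narrow layers run as direct pointer convolutions, wide layers as
// im2col + GEMM through BLAS, so a scaled-down training study fits on one
// CPU without any deep-learning framework. Parameters and gradients cross
// the R boundary as doubles.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

typedef arma::fmat Mat;
typedef arma::fvec Vec;
typedef arma::fcube Cube;
typedef float real;

struct ConvLayer {
  Cube W;  // k x k x (cin*cout); slice index ci + cin*co
  Vec b;
  int k, cin, cout;
};

struct DenseLayer {
  Mat W;  // in x out
  Vec b;
};

std::vector<ConvLayer> unpackConv(const List& conv) {
  std::vector<ConvLayer> out;
  for (int i = 0; i < conv.size(); ++i) {
    List l = conv[i];
    NumericVector Wv = l["W"];
    IntegerVector d = Wv.attr("dim");  // k, k, cin, cout
    ConvLayer cl;
    cl.k = d[0];
    cl.cin = d[2];
    cl.cout = d[3];
    cl.W.set_size(d[0], d[1], (arma::uword)d[2] * d[3]);
    std::copy(Wv.begin(), Wv.end(), cl.W.begin());
    NumericVector bv = l["b"];
    cl.b.set_size(bv.size());
    std::copy(bv.begin(), bv.end(), cl.b.begin());
    out.push_back(cl);
  }
  return out;
}

std::vector<DenseLayer> unpackDense(const List& dense) {
  std::vector<DenseLayer> out;
  for (int i = 0; i < dense.size(); ++i) {
    List l = dense[i];
    NumericMatrix Wm = l["W"];
    DenseLayer dl;
    dl.W.set_size(Wm.nrow(), Wm.ncol());
    std::copy(Wm.begin(), Wm.end(), dl.W.begin());
    NumericVector bv = l["b"];
    dl.b.set_size(bv.size());
    std::copy(bv.begin(), bv.end(), dl.b.begin());
    out.push_back(dl);
  }
  return out;
}

// the k x k x cin weight block of each output channel, flattened
// column-major, is exactly one column of a (k*k*cin) x cout matrix
Mat weightMatrix(const ConvLayer& L) {
  return Mat(const_cast<real*>(L.W.memptr()),
             (arma::uword)L.k * L.k * L.cin, L.cout, false);
}

// layers with very few output channels (the first conv of this
// architecture) are faster via direct pointer loops; wider layers via
// im2col + GEMM
inline bool useGemm(const ConvLayer& L) { return L.cout >= 8; }

// direct valid convolution (shift-and-add, axpy inner loops); bias included
Cube convDirect(const Cube& x, const ConvLayer& L) {
  const int Ho = (int)x.n_rows - L.k + 1;
  const int Wo = (int)x.n_cols - L.k + 1;
  const int xr = (int)x.n_rows;
  Cube out(Ho, Wo, L.cout);
  for (int co = 0; co < L.cout; ++co) {
    Mat& acc = out.slice(co);
    acc.fill(L.b[co]);
    for (int ci = 0; ci < L.cin; ++ci) {
      const real* xmem = x.slice_memptr(ci);
      const Mat& Ws = L.W.slice(ci + (arma::uword)L.cin * co);
      for (int kj = 0; kj < L.k; ++kj)
        for (int ki = 0; ki < L.k; ++ki) {
          const real w = Ws(ki, kj);
          for (int j = 0; j < Wo; ++j) {
            const real* src = xmem + (size_t)(j + kj) * xr + ki;
            real* dst = acc.colptr(j);
            for (int i = 0; i < Ho; ++i) dst[i] += w * src[i];
          }
        }
    }
  }
  return out;
}

// patches matrix P: one row per output position (n = i + Ho*j), one column
// per kernel tap (r = ki + k*kj + k*k*ci)
Mat im2col(const Cube& x, int k) {
  const int xr = (int)x.n_rows;
  const int Ho = xr - k + 1;
  const int Wo = (int)x.n_cols - k + 1;
  const size_t N = (size_t)Ho * Wo;
  Mat P(N, (arma::uword)k * k * x.n_slices);
  for (arma::uword ci = 0; ci < x.n_slices; ++ci) {
    const real* base = x.slice_memptr(ci);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        real* dst = P.colptr(ki + (size_t)k * kj + (size_t)k * k * ci);
        for (int j = 0; j < Wo; ++j)
          std::memcpy(dst + (size_t)j * Ho,
                      base + (size_t)(j + kj) * xr + ki,
                      Ho * sizeof(real));
      }
  }
  return P;
}

// scatter-add of the patches-layout gradient back onto the input grid
void col2im(const Mat& dP, int k, Cube& dX) {
  const int xr = (int)dX.n_rows;
  const int Ho = xr - k + 1;
  const int Wo = (int)dX.n_cols - k + 1;
  for (arma::uword ci = 0; ci < dX.n_slices; ++ci) {
    real* base = dX.slice_memptr(ci);
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const real* src =
            dP.colptr(ki + (size_t)k * kj + (size_t)k * k * ci);
        for (int j = 0; j < Wo; ++j) {
          real* dst = base + (size_t)(j + kj) * xr + ki;
          const real* s = src + (size_t)j * Ho;
          for (int i = 0; i < Ho; ++i) dst[i] += s[i];
        }
      }
  }
}

// pooled extent: floor(d/2); a partial window is kept only when d < pool
// size (d == 1 -> 1), so that the deepest valid stage survives.
inline int poolExtent(int d) { return d >= 2 ? d / 2 : 1; }

Cube maxPool2(const Cube& x, arma::ucube& argmax) {
  const int Ho = poolExtent((int)x.n_rows);
  const int Wo = poolExtent((int)x.n_cols);
  Cube out(Ho, Wo, x.n_slices);
  argmax.set_size(Ho, Wo, x.n_slices);
  for (arma::uword c = 0; c < x.n_slices; ++c) {
    const Mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j) {
      const int j0 = 2 * j;
      const int j1 = std::min(j0 + 1, (int)x.n_cols - 1);
      for (int i = 0; i < Ho; ++i) {
        const int i0 = 2 * i;
        const int i1 = std::min(i0 + 1, (int)x.n_rows - 1);
        real best = xs(i0, j0);
        arma::uword bidx = i0 + x.n_rows * j0;
        for (int jj = j0; jj <= j1; ++jj)
          for (int ii = i0; ii <= i1; ++ii)
            if (xs(ii, jj) > best) {
              best = xs(ii, jj);
              bidx = ii + x.n_rows * jj;
            }
        out(i, j, c) = best;
        argmax(i, j, c) = bidx;
      }
    }
  }
  return out;
}

inline double sigmoidStable(double z) {
  if (z >= 0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

struct ForwardCache {
  std::vector<Mat> patches;          // im2col matrix (GEMM layers)
  std::vector<Cube> conv_in;         // layer input (direct layers)
  std::vector<arma::uvec> in_dims;   // input dims per conv layer
  std::vector<Cube> relu_out;        // post-ReLU, pre-pool
  std::vector<arma::ucube> pool_arg; // argmax per pooled cell
  std::vector<Cube> drop_mask;       // pooled dims (training only)
  Vec gap;                           // global-average-pooled features
  std::vector<Vec> dense_in;         // input to each dense layer
  std::vector<Vec> dense_relu;       // post-ReLU hidden activations
  std::vector<Vec> dense_drop;       // dropout masks on hidden activations
  double logit = 0.0;
};

double forwardOne(const Mat& tile,
                  const std::vector<ConvLayer>& conv,
                  const std::vector<DenseLayer>& dense,
                  double dropout, bool training, std::mt19937& rng,
                  ForwardCache* cache) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const real keep = (real)(1.0 - dropout);
  Cube x(tile.n_rows, tile.n_cols, 1);
  x.slice(0) = tile;

  for (size_t l = 0; l < conv.size(); ++l) {
    const ConvLayer& L = conv[l];
    const int Ho = (int)x.n_rows - L.k + 1;
    const int Wo = (int)x.n_cols - L.k + 1;
    Cube y;
    if (useGemm(L)) {
      Mat P = im2col(x, L.k);
      Mat Ymat = P * weightMatrix(L);  // N x cout, via BLAS
      Ymat.each_row() += L.b.t();
      y.set_size(Ho, Wo, L.cout);
      std::memcpy(y.memptr(), Ymat.memptr(), Ymat.n_elem * sizeof(real));
      if (cache) {
        cache->patches.push_back(std::move(P));
        cache->conv_in.push_back(Cube());
      }
    } else {
      y = convDirect(x, L);
      if (cache) {
        cache->patches.push_back(Mat());
        cache->conv_in.push_back(x);
      }
    }
    if (cache)
      cache->in_dims.push_back(
          arma::uvec({x.n_rows, x.n_cols, x.n_slices}));
    y.transform([](real v) { return v > 0 ? v : (real)0; });
    if (cache) cache->relu_out.push_back(y);
    arma::ucube arg;
    Cube p = maxPool2(y, arg);
    if (cache) cache->pool_arg.push_back(arg);
    if (training && dropout > 0.0) {
      Cube m(p.n_rows, p.n_cols, p.n_slices);
      for (arma::uword i = 0; i < m.n_elem; ++i)
        m(i) = unif(rng) < keep ? (real)1.0 / keep : (real)0;
      p %= m;
      if (cache) cache->drop_mask.push_back(m);
    } else if (cache) {
      cache->drop_mask.push_back(Cube());
    }
    x = p;
  }

  Vec g(x.n_slices);
  for (arma::uword c = 0; c < x.n_slices; ++c)
    g(c) = arma::accu(x.slice(c)) / (real)(x.n_rows * x.n_cols);
  if (cache) cache->gap = g;

  Vec h = g;
  // hidden dense layers: all but the last entry of `dense`
  for (size_t l = 0; l + 1 < dense.size(); ++l) {
    if (cache) cache->dense_in.push_back(h);
    Vec z = dense[l].W.t() * h + dense[l].b;
    z.transform([](real v) { return v > 0 ? v : (real)0; });
    if (cache) cache->dense_relu.push_back(z);
    if (training && dropout > 0.0) {
      Vec m(z.n_elem);
      for (arma::uword i = 0; i < m.n_elem; ++i)
        m(i) = unif(rng) < keep ? (real)1.0 / keep : (real)0;
      z %= m;
      if (cache) cache->dense_drop.push_back(m);
    } else if (cache) {
      cache->dense_drop.push_back(Vec());
    }
    h = z;
  }
  if (cache) cache->dense_in.push_back(h);
  const DenseLayer& outl = dense.back();
  double logit = (double)arma::as_scalar(outl.W.t() * h) + outl.b(0);
  if (cache) cache->logit = logit;
  return sigmoidStable(logit);
}

// one tile of the R double array converted to a float matrix
Mat sliceAsFloat(const double* base, int F, int T, int slice) {
  Mat tile(F, T);
  const double* src = base + (size_t)slice * F * T;
  for (size_t i = 0; i < (size_t)F * T; ++i) tile(i) = (real)src[i];
  return tile;
}

}  // namespace

// Forward pass in evaluation mode (dropout off). `tiles` is an F x T x n
// array; `idx` selects tiles (1-based).
// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericVector cnn_predict_cpp(NumericVector tiles, IntegerVector dims,
                              IntegerVector idx, List params) {
  std::vector<ConvLayer> conv = unpackConv(params["conv"]);
  std::vector<DenseLayer> dense = unpackDense(params["dense"]);
  std::mt19937 rng(1);
  NumericVector out(idx.size());
  for (int i = 0; i < idx.size(); ++i) {
    Mat tile = sliceAsFloat(tiles.begin(), dims[0], dims[1], idx[i] - 1);
    out[i] = forwardOne(tile, conv, dense, 0.0, false, rng, nullptr);
  }
  return out;
}

// One training batch: class-weighted binary cross-entropy loss, mean over
// the batch, and its gradient w.r.t. every parameter. Dropout is active;
// `seed` makes the masks reproducible.
// [[Rcpp::export(name = ".cnn_grad_cpp")]]
List cnn_grad_cpp(NumericVector tiles, IntegerVector dims, IntegerVector idx,
                  NumericVector y, NumericVector sw, List params,
                  double dropout, int seed) {
  std::vector<ConvLayer> conv = unpackConv(params["conv"]);
  std::vector<DenseLayer> dense = unpackDense(params["dense"]);
  const int B = idx.size();
  std::mt19937 rng((unsigned)seed);

  // zero-initialized gradient accumulators
  std::vector<Cube> gW;
  std::vector<Vec> gb;
  for (auto& L : conv) {
    gW.push_back(Cube(L.k, L.k, (arma::uword)L.cin * L.cout,
                      arma::fill::zeros));
    gb.push_back(Vec(L.cout, arma::fill::zeros));
  }
  std::vector<Mat> gDW;
  std::vector<Vec> gDb;
  for (auto& L : dense) {
    gDW.push_back(Mat(L.W.n_rows, L.W.n_cols, arma::fill::zeros));
    gDb.push_back(Vec(L.b.n_elem, arma::fill::zeros));
  }

  double loss = 0.0;
  NumericVector probs(B);
  const double eps = 1e-9;

  for (int s = 0; s < B; ++s) {
    ForwardCache cache;
    Mat tile = sliceAsFloat(tiles.begin(), dims[0], dims[1], idx[s] - 1);
    double p = forwardOne(tile, conv, dense, dropout, true, rng, &cache);
    probs[s] = p;
    double pc = std::min(std::max(p, eps), 1.0 - eps);
    loss += -sw[s] * (y[s] * std::log(pc) + (1.0 - y[s]) * std::log(1.0 - pc));

    // ---- backward ----
    real dz = (real)(sw[s] * (p - y[s]) / (double)B);

    // output layer
    size_t nd = dense.size();
    Vec h = cache.dense_in[nd - 1];
    gDW[nd - 1] += h * dz;
    gDb[nd - 1](0) += dz;
    Vec dh = dense[nd - 1].W.col(0) * dz;

    // hidden dense layers, in reverse
    for (int l = (int)nd - 2; l >= 0; --l) {
      if (cache.dense_drop[l].n_elem > 0) dh %= cache.dense_drop[l];
      const Vec& act = cache.dense_relu[l];
      for (arma::uword i = 0; i < dh.n_elem; ++i)
        if (act(i) <= 0) dh(i) = 0;
      const Vec& in = cache.dense_in[l];
      gDW[l] += in * dh.t();
      gDb[l] += dh;
      dh = dense[l].W * dh;
    }

    // GAP backward: dh has one entry per channel of the last pooled map,
    // whose dims are those of the final pool argmax cube
    const arma::ucube& lastArg = cache.pool_arg.back();
    Cube dPooled(lastArg.n_rows, lastArg.n_cols, lastArg.n_slices);
    const real inv = (real)1.0 / (real)(lastArg.n_rows * lastArg.n_cols);
    for (arma::uword c = 0; c < dPooled.n_slices; ++c)
      dPooled.slice(c).fill(dh(c) * inv);

    // conv stack backward
    for (int l = (int)conv.size() - 1; l >= 0; --l) {
      if (cache.drop_mask[l].n_elem > 0) dPooled %= cache.drop_mask[l];
      const Cube& relu = cache.relu_out[l];
      const arma::ucube& arg = cache.pool_arg[l];
      Cube dY(relu.n_rows, relu.n_cols, relu.n_slices, arma::fill::zeros);
      for (arma::uword c = 0; c < arg.n_slices; ++c) {
        real* dYc = dY.slice_memptr(c);
        for (arma::uword j = 0; j < arg.n_cols; ++j)
          for (arma::uword i = 0; i < arg.n_rows; ++i)
            dYc[arg(i, j, c)] += dPooled(i, j, c);
      }
      // ReLU grad (relu holds post-ReLU values)
      for (arma::uword i = 0; i < dY.n_elem; ++i)
        if (relu(i) <= 0) dY(i) = 0;

      const ConvLayer& L = conv[l];
      const arma::uword N = dY.n_rows * dY.n_cols;
      if (useGemm(L)) {
        // dY as an N x cout matrix (shared memory, same layout)
        Mat dYt(dY.memptr(), N, L.cout, false);
        gb[l] += arma::sum(dYt, 0).t();
        const Mat& P = cache.patches[l];
        // conv weight gradients share the cube's memory layout
        Mat gWmat(gW[l].memptr(), (arma::uword)L.k * L.k * L.cin,
                  L.cout, false);
        gWmat += P.t() * dYt;
        if (l > 0) {
          Mat dP = dYt * weightMatrix(L).t();  // N x (k*k*cin)
          const arma::uvec& d = cache.in_dims[l];
          Cube dX(d[0], d[1], d[2], arma::fill::zeros);
          col2im(dP, L.k, dX);
          dPooled = dX;
        }
      } else {
        const Cube& xin = cache.conv_in[l];
        const int Ho = (int)dY.n_rows, Wo = (int)dY.n_cols;
        const int xr = (int)xin.n_rows;
        Cube dX;
        if (l > 0) dX.zeros(xin.n_rows, xin.n_cols, xin.n_slices);
        for (int co = 0; co < L.cout; ++co) {
          const Mat& dYs = dY.slice(co);
          gb[l](co) += arma::accu(dYs);
          for (int ci = 0; ci < L.cin; ++ci) {
            const real* xmem = xin.slice_memptr(ci);
            const Mat& Ws = L.W.slice(ci + (arma::uword)L.cin * co);
            Mat& gWs = gW[l].slice(ci + (arma::uword)L.cin * co);
            for (int kj = 0; kj < L.k; ++kj)
              for (int ki = 0; ki < L.k; ++ki) {
                real gacc = 0;
                for (int j = 0; j < Wo; ++j) {
                  const size_t off = (size_t)(j + kj) * xr + ki;
                  const real* xcol = xmem + off;
                  const real* dcol = dYs.colptr(j);
                  if (l > 0) {
                    real* dxcol = dX.slice_memptr(ci) + off;
                    const real w = Ws(ki, kj);
                    for (int i = 0; i < Ho; ++i) {
                      gacc += xcol[i] * dcol[i];
                      dxcol[i] += w * dcol[i];
                    }
                  } else {
                    for (int i = 0; i < Ho; ++i) gacc += xcol[i] * dcol[i];
                  }
                }
                gWs(ki, kj) += gacc;
              }
          }
        }
        if (l > 0) dPooled = dX;
      }
    }
  }
  loss /= (double)B;

  // pack gradients mirroring the params structure, back to doubles
  List convIn = params["conv"];
  List convOut(conv.size());
  for (size_t l = 0; l < conv.size(); ++l) {
    List pl = convIn[l];
    NumericVector Wv = pl["W"];
    NumericVector gWv(gW[l].n_elem);
    std::copy(gW[l].begin(), gW[l].end(), gWv.begin());
    gWv.attr("dim") = Wv.attr("dim");
    NumericVector gbv(gb[l].n_elem);
    std::copy(gb[l].begin(), gb[l].end(), gbv.begin());
    convOut[l] = List::create(_["W"] = gWv, _["b"] = gbv);
  }
  List denseOut(dense.size());
  for (size_t l = 0; l < dense.size(); ++l) {
    NumericMatrix gWm(gDW[l].n_rows, gDW[l].n_cols);
    std::copy(gDW[l].begin(), gDW[l].end(), gWm.begin());
    NumericVector gbv(gDb[l].n_elem);
    std::copy(gDb[l].begin(), gDb[l].end(), gbv.begin());
    denseOut[l] = List::create(_["W"] = gWm, _["b"] = gbv);
  }
  return List::create(_["loss"] = loss, _["probs"] = probs,
                      _["grads"] = List::create(_["conv"] = convOut,
                                                _["dense"] = denseOut));
}
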