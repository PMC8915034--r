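// 1-D CNN engine: valid convolutions, pool-2/stride-2 max pooling with
// floor division, inverted dropout, dense layers, sigmoid/BCE output,
// Adam optimizer. Single precision; all heavy work is GEMM on im2col
// buffers reused across samples. Deterministic given the seed
// (single-threaded sample loop).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

constexpr int CONV = 1, POOL = 2, DROPOUT = 3, FLATTEN = 4, DENSE = 5;

struct Layer {
  int type = 0;
  int K = 0, L = 0;      // conv kernel length / filter count
  float rate = 0.0f;     // dropout
  int units = 0, sigmoid_act = 0;  // dense
  int in_len = 0, in_ch = 0, out_len = 0, out_ch = 0;
  int fan_in = 0;        // dense input width
  int widx = -1;         // index into the weight vectors, -1 if untrainable
};

std::vector<Layer> parse_layers(const Rcpp::IntegerMatrix& enc,
                                int input_len, int input_ch, int* n_weights) {
  std::vector<Layer> layers;
  int len = input_len, ch = input_ch, flat = -1, w = 0;
  for (int i = 0; i < enc.nrow(); ++i) {
    Layer l;
    l.type = enc(i, 0);
    l.in_len = len; l.in_ch = ch;
    switch (l.type) {
      case CONV:
        l.K = enc(i, 1); l.L = enc(i, 2);
        l.out_len = len - l.K + 1;
        if (l.out_len < 1) Rcpp::stop("conv layer %d leaves non-positive length", i + 1);
        l.out_ch = l.L;
        l.widx = w++;
        len = l.out_len; ch = l.out_ch;
        break;
      case POOL:
        l.out_len = len / 2;
        if (l.out_len < 1) Rcpp::stop("pool layer %d leaves non-positive length", i + 1);
        l.out_ch = ch;
        len = l.out_len;
        break;
      case DROPOUT:
        l.rate = static_cast<float>(enc(i, 1)) / 1000.0f;
        l.out_len = len; l.out_ch = ch;
        break;
      case FLATTEN:
        flat = len * ch;
        l.out_len = flat; l.out_ch = 1;
        break;
      case DENSE:
        if (flat < 0) Rcpp::stop("dense layer %d before flatten", i + 1);
        l.units = enc(i, 1); l.sigmoid_act = enc(i, 2);
        l.fan_in = flat;
        l.widx = w++;
        flat = l.units;
        l.out_len = flat; l.out_ch = 1;
        break;
      default:
        Rcpp::stop("unknown layer type %d", l.type);
    }
    layers.push_back(l);
  }
  *n_weights = w;
  return layers;
}

struct Params {
  std::vector<fmat> W;
  std::vector<fvec> b;
  long long n_params() const {
    long long t = 0;
    for (size_t i = 0; i < W.size(); ++i) t += W[i].n_elem + b[i].n_elem;
    return t;
  }
};

inline void relu_inplace(fmat& Y) {
  float* p = Y.memptr();
  const uword n = Y.n_elem;
  for (uword j = 0; j < n; ++j) p[j] = p[j] > 0.0f ? p[j] : 0.0f;
}

struct Engine {
  std::vector<Layer> layers;
  int n_weights = 0;

  // per-layer buffers, allocated once and reused for every sample
  std::vector<fmat> col;     // im2col per conv layer
  std::vector<fmat> act;     // output activation per layer (flat as 1 column)
  std::vector<fmat> dact;    // gradient w.r.t. act[i]
  std::vector<umat> poolix;  // chosen offset (0/1) per pool layer
  std::vector<fmat> mask;    // dropout mask
  fmat x_mat;                // input as (channels x len)

  explicit Engine(const std::vector<Layer>& ls) : layers(ls) {
    const size_t m = layers.size();
    col.resize(m); act.resize(m); dact.resize(m);
    poolix.resize(m); mask.resize(m);
    for (size_t i = 0; i < m; ++i) {
      const Layer& l = layers[i];
      switch (l.type) {
        case CONV:
          col[i].set_size(l.K * l.in_ch, l.out_len);
          act[i].set_size(l.out_ch, l.out_len);
          break;
        case POOL:
          act[i].set_size(l.out_ch, l.out_len);
          poolix[i].set_size(l.out_ch, l.out_len);
          break;
        case DROPOUT:
          act[i].set_size(l.out_ch, l.out_len);
          mask[i].set_size(l.out_ch, l.out_len);
          break;
        case FLATTEN:
          act[i].set_size(l.out_len, 1);
          break;
        case DENSE:
          act[i].set_size(l.units, 1);
          break;
      }
      dact[i].set_size(act[i].n_rows, act[i].n_cols);
    }
  }

  const fmat& input_of(size_t i) const {
    return i == 0 ? x_mat : act[i - 1];
  }

  // Forward one sample (x0 already laid out as channels x len in x_mat);
  // returns the sigmoid output probability.
  float forward(const Params& p, bool training, std::mt19937* g) {
    float out = 0.0f;
    for (size_t i = 0; i < layers.size(); ++i) {
      const Layer& l = layers[i];
      const fmat& A = input_of(i);
      switch (l.type) {
        case CONV: {
          fmat& C = col[i];
          const int D = l.in_ch;
          for (int k = 0; k < l.K; ++k) {
            C.rows(k * D, k * D + D - 1) = A.cols(k, k + l.out_len - 1);
          }
          act[i] = p.W[l.widx] * C;
          act[i].each_col() += p.b[l.widx];
          relu_inplace(act[i]);
          break;
        }
        case POOL: {
          fmat& Y = act[i];
          umat& ix = poolix[i];
          const uword D = A.n_rows;
          for (int t = 0; t < l.out_len; ++t) {
            const float* c0 = A.colptr(2 * t);
            const float* c1 = A.colptr(2 * t + 1);
            float* yo = Y.colptr(t);
            uword* io = ix.colptr(t);
            for (uword d = 0; d < D; ++d) {
              if (c0[d] >= c1[d]) { yo[d] = c0[d]; io[d] = 0; }
              else { yo[d] = c1[d]; io[d] = 1; }
            }
          }
          break;
        }
        case DROPOUT: {
          if (training) {
            const float keep = 1.0f - l.rate;
            const float inv_keep = 1.0f / keep;
            const uint32_t thresh = static_cast<uint32_t>(
                keep * 4294967296.0);
            fmat& M = mask[i];
            float* mp = M.memptr();
            for (uword j = 0; j < M.n_elem; ++j) {
              mp[j] = ((*g)() < thresh) ? inv_keep : 0.0f;
            }
            act[i] = A % M;
          } else {
            act[i] = A;
          }
          break;
        }
        case FLATTEN: {
          act[i] = reshape(A, l.out_len, 1);
          break;
        }
        case DENSE: {
          act[i] = p.W[l.widx] * A + p.b[l.widx];
          if (l.sigmoid_act) {
            out = 1.0f / (1.0f + std::exp(-act[i](0, 0)));
          } else {
            relu_inplace(act[i]);
          }
          break;
        }
      }
    }
    return out;
  }

  // Backward one sample (dLoss/dz_out = p - y for sigmoid + BCE), adding
  // gradients into gW/gb. Requires the caches of the matching forward.
  void backward(const Params& p, float dz_out,
                std::vector<fmat>& gW, std::vector<fvec>& gb, bool training) {
    for (int i = static_cast<int>(layers.size()) - 1; i >= 0; --i) {
      const Layer& l = layers[i];
      const fmat& A = input_of(i);
      fmat& dY = dact[i];
      switch (l.type) {
        case DENSE: {
          if (l.sigmoid_act) {
            dY(0, 0) = dz_out;
          } else {
            // relu gate on this layer's own output
            const float* a = act[i].memptr();
            float* d = dY.memptr();
            for (uword j = 0; j < dY.n_elem; ++j) if (a[j] <= 0.0f) d[j] = 0.0f;
          }
          gW[l.widx] += dY * A.t();
          gb[l.widx] += dY.col(0);
          if (i > 0) dact[i - 1] = p.W[l.widx].t() * dY;
          break;
        }
        case FLATTEN: {
          if (i > 0) dact[i - 1] = reshape(dY, l.in_ch, l.in_len);
          break;
        }
        case DROPOUT: {
          if (i > 0) {
            if (training) dact[i - 1] = dY % mask[i];
            else dact[i - 1] = dY;
          }
          break;
        }
        case POOL: {
          if (i == 0) break;
          fmat& dprev = dact[i - 1];
          dprev.zeros();
          const umat& ix = poolix[i];
          const uword D = dprev.n_rows;
          for (int t = 0; t < l.out_len; ++t) {
            const float* dp = dY.colptr(t);
            const uword* io = ix.colptr(t);
            for (uword d = 0; d < D; ++d) {
              dprev(d, 2 * t + io[d]) += dp[d];
            }
          }
          break;
        }
        case CONV: {
          // relu gate
          {
            const float* a = act[i].memptr();
            float* d = dY.memptr();
            for (uword j = 0; j < dY.n_elem; ++j) if (a[j] <= 0.0f) d[j] = 0.0f;
          }
          gW[l.widx] += dY * col[i].t();
          gb[l.widx] += sum(dY, 1);
          if (i > 0) {
            const fmat dC = p.W[l.widx].t() * dY;   // (K*D) x out_len
            fmat& dprev = dact[i - 1];
            dprev.zeros();
            const int D = l.in_ch;
            for (int k = 0; k < l.K; ++k) {
              dprev.cols(k, k + l.out_len - 1) += dC.rows(k * D, k * D + D - 1);
            }
          }
          break;
        }
      }
    }
  }
};

Params init_params(const std::vector<Layer>& layers, int n_weights, std::mt19937& g) {
  Params p;
  p.W.resize(n_weights); p.b.resize(n_weights);
  for (const Layer& l : layers) {
    if (l.widx < 0) continue;
    int rows, cols, fan_in, fan_out;
    if (l.type == CONV) {
      rows = l.L; cols = l.K * l.in_ch;
      fan_in = l.K * l.in_ch; fan_out = l.K * l.L;
    } else {
      rows = l.units; cols = l.fan_in;
      fan_in = l.fan_in; fan_out = l.units;
    }
    const float limit = std::sqrt(6.0f / static_cast<float>(fan_in + fan_out));
    std::uniform_real_distribution<float> u(-limit, limit);
    fmat W(rows, cols);
    for (uword j = 0; j < W.n_elem; ++j) W(j) = u(g);  // column-major fill
    p.W[l.widx] = std::move(W);
    p.b[l.widx] = fvec(rows, fill::zeros);
  }
  return p;
}

Params params_from_r(int n_weights, const Rcpp::List& weights) {
  Params p;
  p.W.resize(n_weights); p.b.resize(n_weights);
  for (int j = 0; j < n_weights; ++j) {
    Rcpp::NumericMatrix W = weights[2 * j];
    Rcpp::NumericVector b = weights[2 * j + 1];
    p.W[j] = conv_to<fmat>::from(mat(W.begin(), W.nrow(), W.ncol(), false));
    p.b[j] = conv_to<fvec>::from(vec(b.begin(), b.size(), false));
  }
  return p;
}

Rcpp::List params_to_r(const Params& p) {
  Rcpp::List out(2 * p.W.size());
  for (size_t i = 0; i < p.W.size(); ++i) {
    out[2 * i] = Rcpp::wrap(conv_to<mat>::from(p.W[i]));
    out[2 * i + 1] = Rcpp::wrap(conv_to<vec>::from(p.b[i]));
  }
  return out;
}

void load_input(Engine& eng, const fmat& Xf, int idx, int input_ch) {
  const int len = Xf.n_rows / input_ch;
  eng.x_mat = reshape(Xf.col(idx), input_ch, len);
}

}  // namespace

// [[Rcpp::export]]
double cpp_cnn_param_count(Rcpp::IntegerMatrix enc, int input_len, int input_ch) {
  int n_weights = 0;
  std::vector<Layer> layers = parse_layers(enc, input_len, input_ch, &n_weights);
  std::mt19937 g(0);
  Params p = init_params(layers, n_weights, g);
  return static_cast<double>(p.n_params());
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::IntegerMatrix enc, Rcpp::NumericMatrix X,
                         Rcpp::IntegerVector y, int input_ch,
                         int epochs, int batch_size, double lr,
                         double beta1, double beta2, double eps, int seed) {
  const int n = X.ncol();
  int n_weights = 0;
  std::vector<Layer> layers = parse_layers(enc, X.nrow() / input_ch, input_ch, &n_weights);
  std::mt19937 g(static_cast<unsigned>(seed));
  Params p = init_params(layers, n_weights, g);
  Engine eng(layers);

  std::vector<fmat> mW(n_weights), vW(n_weights), gW(n_weights);
  std::vector<fvec> mb(n_weights), vb(n_weights), gb(n_weights);
  for (int i = 0; i < n_weights; ++i) {
    mW[i] = fmat(size(p.W[i]), fill::zeros); vW[i] = mW[i]; gW[i] = mW[i];
    mb[i] = fvec(size(p.b[i]), fill::zeros); vb[i] = mb[i]; gb[i] = mb[i];
  }

  fmat Xf = conv_to<fmat>::from(mat(X.begin(), X.nrow(), X.ncol(), false));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Rcpp::NumericVector h_loss(epochs), h_acc(epochs);
  const float flr = static_cast<float>(lr), fb1 = static_cast<float>(beta1),
              fb2 = static_cast<float>(beta2), feps = static_cast<float>(eps);
  long long step = 0;

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), g);
    double ep_loss = 0.0;
    long long ep_correct = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int bsz = std::min(batch_size, n - start);
      for (int i = 0; i < n_weights; ++i) { gW[i].zeros(); gb[i].zeros(); }
      for (int bi = 0; bi < bsz; ++bi) {
        const int idx = order[start + bi];
        load_input(eng, Xf, idx, input_ch);
        const float prob = eng.forward(p, true, &g);
        const float yy = static_cast<float>(y[idx]);
        const float pc = std::min(std::max(prob, 1e-7f), 1.0f - 1e-7f);
        ep_loss += -(yy * std::log(pc) + (1.0f - yy) * std::log(1.0f - pc));
        ep_correct += ((prob >= 0.5f) == (y[idx] == 1)) ? 1 : 0;
        eng.backward(p, prob - yy, gW, gb, true);
      }
      const float inv_b = 1.0f / static_cast<float>(bsz);
      ++step;
      const float bc1 = 1.0f - std::pow(fb1, static_cast<float>(step));
      const float bc2 = 1.0f - std::pow(fb2, static_cast<float>(step));
      for (int i = 0; i < n_weights; ++i) {
        gW[i] *= inv_b; gb[i] *= inv_b;
        mW[i] = fb1 * mW[i] + (1.0f - fb1) * gW[i];
        vW[i] = fb2 * vW[i] + (1.0f - fb2) * square(gW[i]);
        p.W[i] -= flr * (mW[i] / bc1) / (sqrt(vW[i] / bc2) + feps);
        mb[i] = fb1 * mb[i] + (1.0f - fb1) * gb[i];
        vb[i] = fb2 * vb[i] + (1.0f - fb2) * square(gb[i]);
        p.b[i] -= flr * (mb[i] / bc1) / (sqrt(vb[i] / bc2) + feps);
      }
      Rcpp::checkUserInterrupt();
    }
    h_loss[e] = ep_loss / n;
    h_acc[e] = static_cast<double>(ep_correct) / n;
  }

  return Rcpp::List::create(
    Rcpp::Named("weights") = params_to_r(p),
    Rcpp::Named("loss") = h_loss,
    Rcpp::Named("accuracy") = h_acc,
    Rcpp::Named("n_params") = static_cast<double>(p.n_params())
  );
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn_predict(Rcpp::IntegerMatrix enc, Rcpp::List weights,
                                    Rcpp::NumericMatrix X, int input_ch) {
  int n_weights = 0;
  std::vector<Layer> layers = parse_layers(enc, X.nrow() / input_ch, input_ch, &n_weights);
  Params p = params_from_r(n_weights, weights);
  Engine eng(layers);
  fmat Xf = conv_to<fmat>::from(mat(X.begin(), X.nrow(), X.ncol(), false));
  Rcpp::NumericVector out(X.ncol());
  for (int i = 0; i < X.ncol(); ++i) {
    load_input(eng, Xf, i, input_ch);
    out[i] = eng.forward(p, false, nullptr);
  }
  return out;
}
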