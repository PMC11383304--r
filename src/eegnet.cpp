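// Compact convolutional network for PRP classification, in the EEGNet-8,2
// style: temporal convolution (F1 kernels, same padding), depthwise
// spatial convolution over all electrodes (D filters per temporal filter),
// ELU, average pooling, dropout, separable temporal convolution (depthwise
// + pointwise), ELU, average pooling, dropout, dense softmax readout.
// Computation is single precision (as is standard for network training);
// the temporal stage runs as batched GEMM against a banded kernel matrix.
// Manual backpropagation is verified against finite differences in the
// test suite. Training uses Adam with a step-decay learning-rate schedule
// and early stopping on validation cross-entropy; DeepLIFT attribution
// with the Rescale rule propagates multipliers to the pre-softmax class
// score.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct Net {
  int n_e, n_t, n_classes, F1, D, k1, k2, p1, p2;
  int C2, T1, T2;
  fmat W1;   // F1 x k1
  fvec b1;   // F1
  fmat W2;   // C2 x n_e
  fvec b2;   // C2
  fmat W3d;  // C2 x k2
  fmat W3p;  // C2 x C2
  fvec b3;   // C2
  fmat W4;   // n_classes x C2*T2
  fvec b4;   // n_classes

  void derive() {
    C2 = F1 * D;
    if (n_t % p1 != 0 || (n_t / p1) % p2 != 0 || n_t / p1 / p2 < 1)
      Rcpp::stop("input grid incompatible with the pooling pipeline");
    T1 = n_t / p1;
    T2 = T1 / p2;
  }
  // banded T x T matrix for same-padding convolution with W1 row f:
  // (X * C_f)(e, t) = sum_j W1(f, j) * x(e, t + j - pad)
  fmat band(int f) const {
    const int pad = (k1 - 1) / 2;
    fmat C(n_t, n_t, fill::zeros);
    for (int t = 0; t < n_t; ++t)
      for (int j = 0; j < k1; ++j) {
        const int s = t + j - pad;
        if (s >= 0 && s < n_t) C(s, t) += W1(f, j);
      }
    return C;
  }
};

static Net net_from_list(const List& par) {
  Net n;
  List meta = par["meta"];
  n.n_e = meta["n_e"]; n.n_t = meta["n_t"]; n.n_classes = meta["n_classes"];
  n.F1 = meta["F1"]; n.D = meta["D"]; n.k1 = meta["k1"]; n.k2 = meta["k2"];
  n.p1 = meta["p1"]; n.p2 = meta["p2"];
  n.derive();
  n.W1 = conv_to<fmat>::from(Rcpp::as<mat>(par["W1"]));
  n.b1 = conv_to<fvec>::from(Rcpp::as<vec>(par["b1"]));
  n.W2 = conv_to<fmat>::from(Rcpp::as<mat>(par["W2"]));
  n.b2 = conv_to<fvec>::from(Rcpp::as<vec>(par["b2"]));
  n.W3d = conv_to<fmat>::from(Rcpp::as<mat>(par["W3d"]));
  n.W3p = conv_to<fmat>::from(Rcpp::as<mat>(par["W3p"]));
  n.b3 = conv_to<fvec>::from(Rcpp::as<vec>(par["b3"]));
  n.W4 = conv_to<fmat>::from(Rcpp::as<mat>(par["W4"]));
  n.b4 = conv_to<fvec>::from(Rcpp::as<vec>(par["b4"]));
  return n;
}

static List net_to_list(const Net& n) {
  List meta = List::create(Named("n_e") = n.n_e, Named("n_t") = n.n_t,
                           Named("n_classes") = n.n_classes,
                           Named("F1") = n.F1, Named("D") = n.D,
                           Named("k1") = n.k1, Named("k2") = n.k2,
                           Named("p1") = n.p1, Named("p2") = n.p2);
  return List::create(Named("meta") = meta,
                      Named("W1") = conv_to<mat>::from(n.W1),
                      Named("b1") = conv_to<vec>::from(n.b1),
                      Named("W2") = conv_to<mat>::from(n.W2),
                      Named("b2") = conv_to<vec>::from(n.b2),
                      Named("W3d") = conv_to<mat>::from(n.W3d),
                      Named("W3p") = conv_to<mat>::from(n.W3p),
                      Named("b3") = conv_to<vec>::from(n.b3),
                      Named("W4") = conv_to<mat>::from(n.W4),
                      Named("b4") = conv_to<vec>::from(n.b4));
}

static inline float elu(float a) { return a > 0 ? a : std::expm1(a); }
static inline float elu_grad(float a) { return a > 0 ? 1.0f : std::exp(a); }

// per-sample caches for the stages after the (batched) temporal stage
struct Cache {
  fmat a2, h2;    // C2 x n_t
  fmat pool1;     // C2 x T1
  fmat drop1;     // mask (scaled)
  fmat pin;       // pooled + dropout
  fmat a3d;       // depthwise out
  fmat a3, h3;    // pointwise out
  fmat pool2;     // C2 x T2
  fmat drop2;
  fvec flat, logits, probs;
};

struct BatchState {
  fmat Xstack;                 // (E*B) x T
  std::vector<fmat> H;         // per temporal filter: (E*B) x T
  std::vector<Cache> cache;    // per sample
};

// batched forward; masks may be empty (=> all ones / evaluation mode)
static void forward_batch(const Net& n, const fcube& X,
                          const std::vector<fmat>& m1,
                          const std::vector<fmat>& m2, BatchState& bs) {
  const int B = X.n_slices, E = n.n_e, T = n.n_t;
  bs.Xstack.set_size(E * B, T);
  for (int b = 0; b < B; ++b)
    bs.Xstack.rows(b * E, b * E + E - 1) = X.slice(b);
  bs.H.resize(n.F1);
  for (int f = 0; f < n.F1; ++f) {
    bs.H[f] = bs.Xstack * n.band(f);
    bs.H[f] += n.b1(f);
  }
  bs.cache.resize(B);
  const int pad2 = (n.k2 - 1) / 2;
  for (int b = 0; b < B; ++b) {
    Cache& c = bs.cache[b];
    c.a2.set_size(n.C2, T);
    for (int ch = 0; ch < n.C2; ++ch) {
      const int f = ch / n.D;
      c.a2.row(ch) = n.W2.row(ch) *
        bs.H[f].rows(b * E, b * E + E - 1) + n.b2(ch);
    }
    c.h2 = c.a2;
    c.h2.transform([](float a) { return elu(a); });
    c.pool1.set_size(n.C2, n.T1);
    for (int t = 0; t < n.T1; ++t)
      c.pool1.col(t) = mean(c.h2.cols(t * n.p1, (t + 1) * n.p1 - 1), 1);
    if (!m1.empty()) { c.drop1 = m1[b]; c.pin = c.pool1 % m1[b]; }
    else { c.drop1.ones(n.C2, n.T1); c.pin = c.pool1; }
    c.a3d.zeros(n.C2, n.T1);
    for (int ch = 0; ch < n.C2; ++ch)
      for (int j = 0; j < n.k2; ++j) {
        const float w = n.W3d(ch, j);
        const int off = j - pad2;
        const int t0 = std::max(0, -off), t1 = std::min(n.T1, n.T1 - off);
        for (int t = t0; t < t1; ++t) c.a3d(ch, t) += w * c.pin(ch, t + off);
      }
    c.a3 = n.W3p * c.a3d;
    c.a3.each_col() += n.b3;
    c.h3 = c.a3;
    c.h3.transform([](float a) { return elu(a); });
    c.pool2.set_size(n.C2, n.T2);
    for (int t = 0; t < n.T2; ++t)
      c.pool2.col(t) = mean(c.h3.cols(t * n.p2, (t + 1) * n.p2 - 1), 1);
    if (!m2.empty()) { c.drop2 = m2[b]; c.flat = vectorise(c.pool2 % m2[b]); }
    else { c.drop2.ones(n.C2, n.T2); c.flat = vectorise(c.pool2); }
    c.logits = n.W4 * c.flat + n.b4;
    const float mx = c.logits.max();
    c.probs = exp(c.logits - mx);
    c.probs /= accu(c.probs);
  }
}

struct Grads {
  fmat W1, W2, W3d, W3p, W4;
  fvec b1, b2, b3, b4;
  void init(const Net& n) {
    W1.zeros(n.F1, n.k1); b1.zeros(n.F1);
    W2.zeros(n.C2, n.n_e); b2.zeros(n.C2);
    W3d.zeros(n.C2, n.k2); W3p.zeros(n.C2, n.C2); b3.zeros(n.C2);
    W4.zeros(n.n_classes, n.C2 * n.T2); b4.zeros(n.n_classes);
  }
};

// batched backward for cross-entropy; dlogits[b] = (probs - onehot)/B
static void backward_batch(const Net& n, const BatchState& bs,
                           const std::vector<fvec>& dlogits, Grads& g) {
  const int B = bs.cache.size(), E = n.n_e, T = n.n_t;
  const int pad1 = (n.k1 - 1) / 2, pad2 = (n.k2 - 1) / 2;
  std::vector<fmat> dH(n.F1);
  for (int f = 0; f < n.F1; ++f) dH[f].zeros(E * B, T);

  for (int b = 0; b < B; ++b) {
    const Cache& c = bs.cache[b];
    g.W4 += dlogits[b] * c.flat.t();
    g.b4 += dlogits[b];
    fvec dflat = n.W4.t() * dlogits[b];
    fmat dpool2 = reshape(dflat, n.C2, n.T2) % c.drop2;
    fmat dh3(n.C2, n.T1);
    for (int t = 0; t < n.T1; ++t) dh3.col(t) = dpool2.col(t / n.p2) / n.p2;
    fmat da3 = dh3;
    for (uword i = 0; i < da3.n_elem; ++i) da3[i] *= elu_grad(c.a3[i]);
    g.W3p += da3 * c.a3d.t();
    g.b3 += sum(da3, 1);
    fmat da3d = n.W3p.t() * da3;
    fmat dpin(n.C2, n.T1, fill::zeros);
    for (int ch = 0; ch < n.C2; ++ch)
      for (int j = 0; j < n.k2; ++j) {
        const int off = j - pad2;
        const int t0 = std::max(0, -off), t1 = std::min(n.T1, n.T1 - off);
        float gw = 0.0f;
        for (int t = t0; t < t1; ++t) {
          gw += da3d(ch, t) * c.pin(ch, t + off);
          dpin(ch, t + off) += da3d(ch, t) * n.W3d(ch, j);
        }
        g.W3d(ch, j) += gw;
      }
    fmat dpool1 = dpin % c.drop1;
    fmat dh2(n.C2, T);
    for (int t = 0; t < T; ++t) dh2.col(t) = dpool1.col(t / n.p1) / n.p1;
    fmat da2 = dh2;
    for (uword i = 0; i < da2.n_elem; ++i) da2[i] *= elu_grad(c.a2[i]);
    for (int ch = 0; ch < n.C2; ++ch) {
      const int f = ch / n.D;
      g.W2.row(ch) += da2.row(ch) *
        bs.H[f].rows(b * E, b * E + E - 1).t();
      g.b2(ch) += accu(da2.row(ch));
      dH[f].rows(b * E, b * E + E - 1) += n.W2.row(ch).t() * da2.row(ch);
    }
  }
  // temporal stage gradients via one GEMM per filter: with
  // M = Xstack' * dH_f (T x T), dW1(f, j) sums the diagonal at offset
  // j - pad and b1 sums everything
  for (int f = 0; f < n.F1; ++f) {
    g.b1(f) += accu(dH[f]);
    fmat M = bs.Xstack.t() * dH[f];
    for (int j = 0; j < n.k1; ++j) {
      const int off = j - pad1;
      float s = 0.0f;
      const int t0 = std::max(0, -off), t1 = std::min(T, T - off);
      for (int t = t0; t < t1; ++t) s += M(t + off, t);
      g.W1(f, j) += s;
    }
  }
}

// [[Rcpp::export]]
List eegnet_init_cpp(int n_e, int n_t, int n_classes, int F1, int D,
                     int k1, int k2, int p1, int p2, int seed) {
  Net n;
  n.n_e = n_e; n.n_t = n_t; n.n_classes = n_classes;
  n.F1 = F1; n.D = D; n.k1 = k1; n.k2 = k2; n.p1 = p1; n.p2 = p2;
  n.derive();
  std::mt19937 rng(seed);
  auto glorot = [&](fmat& W, double fan_in, double fan_out) {
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> u(-lim, lim);
    W.imbue([&]() { return (float)u(rng); });
  };
  n.W1.set_size(n.F1, n.k1); glorot(n.W1, n.k1, n.k1);
  n.b1.zeros(n.F1);
  n.W2.set_size(n.C2, n.n_e); glorot(n.W2, n.n_e, n.n_e);
  n.b2.zeros(n.C2);
  n.W3d.set_size(n.C2, n.k2); glorot(n.W3d, n.k2, n.k2);
  n.W3p.set_size(n.C2, n.C2); glorot(n.W3p, n.C2, n.C2);
  n.b3.zeros(n.C2);
  n.W4.set_size(n.n_classes, n.C2 * n.T2);
  glorot(n.W4, n.C2 * n.T2, n.n_classes);
  n.b4.zeros(n.n_classes);
  return net_to_list(n);
}

static fcube as_fcube(const arma::cube& X) {
  return conv_to<fcube>::from(X);
}

// [[Rcpp::export]]
arma::mat eegnet_predict_cpp(const List& par, const arma::cube& X,
                             bool logits = false) {
  Net n = net_from_list(par);
  fcube Xf = as_fcube(X);
  BatchState bs;
  std::vector<fmat> none;
  forward_batch(n, Xf, none, none, bs);
  mat out(X.n_slices, n.n_classes);
  for (uword s = 0; s < X.n_slices; ++s)
    out.row(s) = conv_to<rowvec>::from(
      logits ? bs.cache[s].logits : bs.cache[s].probs);
  return out;
}

// [[Rcpp::export]]
double eegnet_loss_cpp(const List& par, const arma::cube& X,
                       const arma::ivec& y) {
  Net n = net_from_list(par);
  fcube Xf = as_fcube(X);
  BatchState bs;
  std::vector<fmat> none;
  forward_batch(n, Xf, none, none, bs);
  double loss = 0.0;
  for (uword s = 0; s < X.n_slices; ++s)
    loss += -std::log(std::max((double)bs.cache[s].probs[y[s]], 1e-30));
  return loss / X.n_slices;
}

// mean cross-entropy gradients over a batch (no dropout); for testing
// [[Rcpp::export]]
List eegnet_grad_cpp(const List& par, const arma::cube& X,
                     const arma::ivec& y) {
  Net n = net_from_list(par);
  fcube Xf = as_fcube(X);
  BatchState bs;
  std::vector<fmat> none;
  forward_batch(n, Xf, none, none, bs);
  Grads g; g.init(n);
  std::vector<fvec> dlog(X.n_slices);
  for (uword s = 0; s < X.n_slices; ++s) {
    dlog[s] = bs.cache[s].probs;
    dlog[s][y[s]] -= 1.0f;
    dlog[s] /= (float)X.n_slices;
  }
  backward_batch(n, bs, dlog, g);
  return List::create(Named("W1") = conv_to<mat>::from(g.W1),
                      Named("b1") = conv_to<vec>::from(g.b1),
                      Named("W2") = conv_to<mat>::from(g.W2),
                      Named("b2") = conv_to<vec>::from(g.b2),
                      Named("W3d") = conv_to<mat>::from(g.W3d),
                      Named("W3p") = conv_to<mat>::from(g.W3p),
                      Named("b3") = conv_to<vec>::from(g.b3),
                      Named("W4") = conv_to<mat>::from(g.W4),
                      Named("b4") = conv_to<vec>::from(g.b4));
}

struct Adam {
  std::vector<fmat*> params;
  std::vector<fmat> m, v;
  float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long t = 0;
  void init(std::vector<fmat*> p) {
    params = p;
    for (auto* w : p) { m.emplace_back(size(*w), fill::zeros);
                        v.emplace_back(size(*w), fill::zeros); }
  }
  void step(const std::vector<const fmat*>& grads, float lr) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1 - b2) * square(*grads[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

// [[Rcpp::export]]
List eegnet_train_cpp(List par, const arma::cube& X, const arma::ivec& y,
                      const arma::cube& Xval, const arma::ivec& yval,
                      double lr0, double lr_decay, int decay_every,
                      int batch, int max_epochs, double dropout,
                      int patience, int seed) {
  Net n = net_from_list(par);
  const int ns = X.n_slices;
  fcube Xf = as_fcube(X), Xvf = as_fcube(Xval);
  std::mt19937 rng(seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const float keep = 1.0f - (float)dropout;

  fmat b1m(n.b1), b2m(n.b2), b3m(n.b3), b4m(n.b4);
  Adam opt;
  opt.init({&n.W1, &b1m, &n.W2, &b2m, &n.W3d, &n.W3p, &b3m, &n.W4, &b4m});

  Net best = n;
  double best_val = datum::inf;
  int best_epoch = -1, wait = 0;
  std::vector<double> val_trace;
  std::vector<int> order(ns);
  for (int i = 0; i < ns; ++i) order[i] = i;
  BatchState bs, vbs;
  std::vector<fmat> none;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    const float lr = lr0 * std::pow(lr_decay, epoch / decay_every);
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < ns; start += batch) {
      const int bsz = std::min(batch, ns - start);
      fcube Xb(n.n_e, n.n_t, bsz);
      ivec yb(bsz);
      std::vector<fmat> m1(bsz), m2(bsz);
      for (int k = 0; k < bsz; ++k) {
        const int s = order[start + k];
        Xb.slice(k) = Xf.slice(s);
        yb[k] = y[s];
        m1[k].set_size(n.C2, n.T1);
        m2[k].set_size(n.C2, n.T2);
        if (dropout > 0) {
          m1[k].imbue([&]() { return unif(rng) < keep ? 1.0f / keep : 0.0f; });
          m2[k].imbue([&]() { return unif(rng) < keep ? 1.0f / keep : 0.0f; });
        } else { m1[k].ones(); m2[k].ones(); }
      }
      forward_batch(n, Xb, m1, m2, bs);
      Grads g; g.init(n);
      std::vector<fvec> dlog(bsz);
      for (int k = 0; k < bsz; ++k) {
        dlog[k] = bs.cache[k].probs;
        dlog[k][yb[k]] -= 1.0f;
        dlog[k] /= (float)bsz;
      }
      backward_batch(n, bs, dlog, g);
      n.b1 = b1m.col(0); n.b2 = b2m.col(0); n.b3 = b3m.col(0); n.b4 = b4m.col(0);
      fmat gb1(g.b1), gb2(g.b2), gb3(g.b3), gb4(g.b4);
      opt.step({&g.W1, &gb1, &g.W2, &gb2, &g.W3d, &g.W3p, &gb3, &g.W4, &gb4},
               lr);
      n.b1 = b1m.col(0); n.b2 = b2m.col(0); n.b3 = b3m.col(0); n.b4 = b4m.col(0);
    }
    // validation cross-entropy; the model at the minimum is kept
    forward_batch(n, Xvf, none, none, vbs);
    double vl = 0.0;
    for (uword s = 0; s < Xvf.n_slices; ++s)
      vl += -std::log(std::max((double)vbs.cache[s].probs[yval[s]], 1e-30));
    vl /= Xvf.n_slices;
    val_trace.push_back(vl);
    if (vl < best_val - 1e-6) {
      best_val = vl;
      best = n;
      best_epoch = epoch;
      wait = 0;
    } else if (++wait >= patience) break;
  }
  return List::create(Named("params") = net_to_list(best),
                      Named("val_loss") = val_trace,
                      Named("best_epoch") = best_epoch + 1,
                      Named("best_val_loss") = best_val);
}

// double-precision forward caches for attribution (evaluation mode)
struct DCache {
  mat a2, pin, a3d, a3;
  vec logits;
};

static void forward_double(const List& par, const mat& x, DCache& c) {
  List meta = par["meta"];
  const int n_e = meta["n_e"], n_t = meta["n_t"];
  const int F1 = meta["F1"], D = meta["D"];
  const int k1 = meta["k1"], k2 = meta["k2"];
  const int p1 = meta["p1"], p2 = meta["p2"];
  const int C2 = F1 * D, T1 = n_t / p1, T2 = T1 / p2;
  const mat W1 = Rcpp::as<mat>(par["W1"]);
  const vec b1 = Rcpp::as<vec>(par["b1"]);
  const mat W2 = Rcpp::as<mat>(par["W2"]);
  const vec b2 = Rcpp::as<vec>(par["b2"]);
  const mat W3d = Rcpp::as<mat>(par["W3d"]);
  const mat W3p = Rcpp::as<mat>(par["W3p"]);
  const vec b3 = Rcpp::as<vec>(par["b3"]);
  const mat W4 = Rcpp::as<mat>(par["W4"]);
  const vec b4 = Rcpp::as<vec>(par["b4"]);
  const int pad1 = (k1 - 1) / 2, pad2 = (k2 - 1) / 2;
  (void)n_e;

  std::vector<mat> H(F1);
  for (int f = 0; f < F1; ++f) {
    H[f].zeros(x.n_rows, n_t);
    for (int j = 0; j < k1; ++j) {
      const double w = W1(f, j);
      const int off = j - pad1;
      const int t0 = std::max(0, -off), t1 = std::min(n_t, n_t - off);
      if (t0 < t1)
        H[f].cols(t0, t1 - 1) += w * x.cols(t0 + off, t1 - 1 + off);
    }
    H[f] += b1(f);
  }
  c.a2.set_size(C2, n_t);
  for (int ch = 0; ch < C2; ++ch)
    c.a2.row(ch) = W2.row(ch) * H[ch / D] + b2(ch);
  mat h2 = c.a2;
  h2.transform([](double a) { return a > 0 ? a : std::expm1(a); });
  mat pool1(C2, T1);
  for (int t = 0; t < T1; ++t)
    pool1.col(t) = mean(h2.cols(t * p1, (t + 1) * p1 - 1), 1);
  c.pin = pool1;
  c.a3d.zeros(C2, T1);
  for (int ch = 0; ch < C2; ++ch)
    for (int j = 0; j < k2; ++j) {
      const double w = W3d(ch, j);
      const int off = j - pad2;
      const int t0 = std::max(0, -off), t1 = std::min(T1, T1 - off);
      for (int t = t0; t < t1; ++t) c.a3d(ch, t) += w * c.pin(ch, t + off);
    }
  c.a3 = W3p * c.a3d;
  c.a3.each_col() += b3;
  mat h3 = c.a3;
  h3.transform([](double a) { return a > 0 ? a : std::expm1(a); });
  mat pool2(C2, T2);
  for (int t = 0; t < T2; ++t)
    pool2.col(t) = mean(h3.cols(t * p2, (t + 1) * p2 - 1), 1);
  c.logits = W4 * vectorise(pool2) + b4;
}

// DeepLIFT with the Rescale rule, attributing the pre-softmax score of
// `target` (0-based) to the input grid relative to `baseline`. Runs in
// double precision so that completeness holds to numerical accuracy.
// [[Rcpp::export]]
arma::mat eegnet_deeplift_cpp(const List& par, const arma::mat& x,
                              const arma::mat& baseline, int target) {
  List meta = par["meta"];
  const int n_t = meta["n_t"];
  const int F1 = meta["F1"], D = meta["D"];
  const int k1 = meta["k1"], k2 = meta["k2"];
  const int p1 = meta["p1"], p2 = meta["p2"];
  const int C2 = F1 * D, T1 = n_t / p1, T2 = T1 / p2;
  const mat W1 = Rcpp::as<mat>(par["W1"]);
  const mat W2 = Rcpp::as<mat>(par["W2"]);
  const mat W3d = Rcpp::as<mat>(par["W3d"]);
  const mat W3p = Rcpp::as<mat>(par["W3p"]);
  const mat W4 = Rcpp::as<mat>(par["W4"]);
  const int pad1 = (k1 - 1) / 2, pad2 = (k2 - 1) / 2;

  DCache cx, c0;
  forward_double(par, x, cx);
  forward_double(par, baseline, c0);
  if (!cx.logits.is_finite()) Rcpp::stop("non-finite activations");

  auto rescale = [](const mat& m_out, const mat& a, const mat& a0) {
    mat m_in = m_out;
    for (uword i = 0; i < a.n_elem; ++i) {
      const double da = a[i] - a0[i];
      const double fa = a[i] > 0 ? a[i] : std::expm1(a[i]);
      const double f0 = a0[i] > 0 ? a0[i] : std::expm1(a0[i]);
      const double mult = std::fabs(da) > 1e-9
        ? (fa - f0) / da
        : (a[i] > 0 ? 1.0 : std::exp(a[i]));
      m_in[i] *= mult;
    }
    return m_in;
  };

  vec mflat = W4.row(target).t();
  mat mpool2 = reshape(mflat, C2, T2);
  mat mh3(C2, T1);
  for (int t = 0; t < T1; ++t) mh3.col(t) = mpool2.col(t / p2) / p2;
  mat ma3 = rescale(mh3, cx.a3, c0.a3);
  mat ma3d = W3p.t() * ma3;
  mat mpin(C2, T1, fill::zeros);
  for (int ch = 0; ch < C2; ++ch)
    for (int j = 0; j < k2; ++j) {
      const int off = j - pad2;
      const int t0 = std::max(0, -off), t1 = std::min(T1, T1 - off);
      for (int t = t0; t < t1; ++t)
        mpin(ch, t + off) += ma3d(ch, t) * W3d(ch, j);
    }
  mat mh2(C2, n_t);
  for (int t = 0; t < n_t; ++t) mh2.col(t) = mpin.col(t / p1) / p1;
  mat ma2 = rescale(mh2, cx.a2, c0.a2);
  std::vector<mat> mh1(F1);
  for (int f = 0; f < F1; ++f) mh1[f].zeros(x.n_rows, n_t);
  for (int ch = 0; ch < C2; ++ch)
    mh1[ch / D] += W2.row(ch).t() * ma2.row(ch);
  mat mx(x.n_rows, n_t, fill::zeros);
  for (int f = 0; f < F1; ++f) {
    const mat& M = mh1[f];
    for (int j = 0; j < k1; ++j) {
      const double w = W1(f, j);
      if (w == 0.0) continue;
      const int off = j - pad1;
      const int t0 = std::max(0, -off), t1 = std::min(n_t, n_t - off);
      if (t0 < t1)
        mx.cols(t0 + off, t1 - 1 + off) += w * M.cols(t0, t1 - 1);
    }
  }
  return mx % (x - baseline);
}
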