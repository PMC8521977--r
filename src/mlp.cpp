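// Funnel MLP regressor: fully connected -> batch normalization -> ReLU per
// hidden layer, linear output head, trained with Adam on minibatches.
// Training is deterministic given the parameter initialisation and the
// integer seed: minibatch shuffles come from a self-contained xorshift64*
// generator rather than any platform RNG. The forward/backward passes are
// written allocation-light (in-place column sweeps around the BLAS GEMMs)
// because desk-scale experiments retrain this network dozens of times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Layer {
  arma::mat W;            // d_in x d_out
  arma::rowvec b, gamma, beta, rm, rv;
};

struct Net {
  std::vector<Layer> hidden;
  arma::vec w_out;        // last width x 1
  double b_out;
};

Net net_from_list(const List& params) {
  Net net;
  List hidden = params["hidden"];
  for (int i = 0; i < hidden.size(); ++i) {
    List l = hidden[i];
    Layer lay;
    lay.W = as<arma::mat>(l["W"]);
    lay.b = as<arma::rowvec>(l["b"]);
    lay.gamma = as<arma::rowvec>(l["gamma"]);
    lay.beta = as<arma::rowvec>(l["beta"]);
    lay.rm = as<arma::rowvec>(l["rm"]);
    lay.rv = as<arma::rowvec>(l["rv"]);
    net.hidden.push_back(lay);
  }
  List out = params["out"];
  net.w_out = as<arma::vec>(out["W"]);
  net.b_out = as<double>(out["b"]);
  return net;
}

List net_to_list(const Net& net) {
  List hidden(net.hidden.size());
  for (size_t i = 0; i < net.hidden.size(); ++i) {
    const Layer& l = net.hidden[i];
    hidden[i] = List::create(_["W"] = l.W, _["b"] = l.b,
                             _["gamma"] = l.gamma, _["beta"] = l.beta,
                             _["rm"] = l.rm, _["rv"] = l.rv);
  }
  return List::create(_["hidden"] = hidden,
                      _["out"] = List::create(_["W"] = net.w_out,
                                              _["b"] = net.b_out));
}

const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.9;

// Eval-mode forward pass using the running batch-norm statistics.
arma::vec forward_eval(const Net& net, const arma::mat& X) {
  arma::mat A = X;
  for (const Layer& l : net.hidden) {
    arma::mat Z = A * l.W;
    const arma::uword m = Z.n_rows, d = Z.n_cols;
    for (arma::uword j = 0; j < d; ++j) {
      const double scale = l.gamma[j] / std::sqrt(l.rv[j] + BN_EPS);
      const double shift = l.beta[j] + scale * (l.b[j] - l.rm[j]);
      double* z = Z.colptr(j);
      for (arma::uword i = 0; i < m; ++i) {
        double v = z[i] * scale + shift;
        z[i] = v > 0.0 ? v : 0.0;
      }
    }
    A = std::move(Z);
  }
  return A * net.w_out + net.b_out;
}

struct Cache {
  std::vector<arma::mat> input;   // activation entering each hidden layer
  std::vector<arma::mat> xhat;    // normalized pre-activation
  std::vector<arma::mat> mask;    // ReLU derivative (0/1)
  std::vector<arma::rowvec> istd;
  arma::mat last;                 // activation entering the output head
};

// Train-mode forward pass (batch statistics). Optionally updates the
// running statistics in-place.
arma::vec forward_train(Net& net, const arma::mat& X, Cache& cache,
                        bool update_running) {
  arma::mat A = X;
  const double m = (double)X.n_rows;
  for (Layer& l : net.hidden) {
    cache.input.push_back(A);
    arma::mat Z = cache.input.back() * l.W;
    const arma::uword nr = Z.n_rows, nc = Z.n_cols;
    arma::rowvec istd(nc);
    arma::mat mask(nr, nc);
    arma::mat Anext(nr, nc);
    for (arma::uword j = 0; j < nc; ++j) {
      double* z = Z.colptr(j);
      double mu = 0.0;
      for (arma::uword i = 0; i < nr; ++i) mu += z[i];
      mu = mu / m + l.b[j];  // mean of the biased pre-activation
      // center: (raw + b) - mu, then batch variance
      const double shift = mu - l.b[j];
      double var = 0.0;
      for (arma::uword i = 0; i < nr; ++i) {
        z[i] -= shift;
        var += z[i] * z[i];
      }
      var /= m;
      const double is = 1.0 / std::sqrt(var + BN_EPS);
      istd[j] = is;
      const double g = l.gamma[j], be = l.beta[j];
      double* mk = mask.colptr(j);
      double* an = Anext.colptr(j);
      for (arma::uword i = 0; i < nr; ++i) {
        z[i] *= is;                       // xhat
        const double h = z[i] * g + be;   // BN affine
        const bool pos = h > 0.0;
        mk[i] = pos ? 1.0 : 0.0;
        an[i] = pos ? h : 0.0;            // ReLU
      }
      if (update_running) {
        const double unbias = (m > 1.5) ? m / (m - 1.0) : 1.0;
        l.rm[j] = BN_MOMENTUM * l.rm[j] + (1.0 - BN_MOMENTUM) * mu;
        l.rv[j] = BN_MOMENTUM * l.rv[j] + (1.0 - BN_MOMENTUM) * var * unbias;
      }
    }
    cache.xhat.push_back(std::move(Z));
    cache.mask.push_back(std::move(mask));
    cache.istd.push_back(std::move(istd));
    A = std::move(Anext);
  }
  cache.last = A;
  return cache.last * net.w_out + net.b_out;
}

struct Grads {
  std::vector<Layer> hidden;  // reuse Layer fields W,b,gamma,beta as grads
  arma::vec w_out;
  double b_out;
};

// Backward pass for mean-squared-error loss on one batch (the RMSE
// objective has the same minimiser; traces are reported in RMSE units).
Grads backward(const Net& net, const Cache& cache, const arma::vec& pred,
               const arma::vec& y) {
  const double m = (double)pred.n_elem;
  Grads g;
  g.hidden.resize(net.hidden.size());
  arma::vec dout = (2.0 / m) * (pred - y);
  g.w_out = cache.last.t() * dout;
  g.b_out = arma::accu(dout);
  arma::mat dA = dout * net.w_out.t();
  for (int i = (int)net.hidden.size() - 1; i >= 0; --i) {
    const Layer& l = net.hidden[i];
    const arma::mat& xhat = cache.xhat[i];
    const arma::mat& mask = cache.mask[i];
    const arma::uword nr = dA.n_rows, nc = dA.n_cols;
    arma::rowvec dgamma(nc), dbeta(nc);
    // dA is consumed in place: dH -> dXhat -> dZ, column by column
    for (arma::uword j = 0; j < nc; ++j) {
      double* da = dA.colptr(j);
      const double* mk = mask.colptr(j);
      const double* xh = xhat.colptr(j);
      double sg = 0.0, sb = 0.0;
      for (arma::uword i = 0; i < nr; ++i) {
        da[i] *= mk[i];                   // through ReLU
        sg += da[i] * xh[i];
        sb += da[i];
      }
      dgamma[j] = sg;
      dbeta[j] = sb;
      // through batch norm: dZ = istd/m * (m*dXhat - sum(dXhat)
      //                                    - xhat * sum(dXhat % xhat))
      const double gval = l.gamma[j];
      const double s1 = sb * gval, s2 = sg * gval;
      const double c = cache.istd[i][j] / nr;
      for (arma::uword ii = 0; ii < nr; ++ii) {
        da[ii] = c * (nr * da[ii] * gval - s1 - xh[ii] * s2);
      }
    }
    g.hidden[i].gamma = dgamma;
    g.hidden[i].beta = dbeta;
    g.hidden[i].W = cache.input[i].t() * dA;
    g.hidden[i].b = arma::sum(dA, 0);
    if (i > 0) dA = dA * l.W.t();
  }
  return g;
}

// Fused Adam update over a raw parameter array.
inline void adam_step(double* p, double* m, double* v, const double* g,
                      size_t n, double lr, double b1, double b2,
                      double bc1, double bc2) {
  for (size_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1.0 - b1) * g[i];
    v[i] = b2 * v[i] + (1.0 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + 1e-8);
  }
}

struct AdamState {
  std::vector<Layer> m_h, v_h;
  arma::vec m_out, v_out;
  double m_b, v_b;
  long t;
};

// xorshift64* PRNG: platform-independent minibatch shuffles.
struct XorShift {
  uint64_t state;
  explicit XorShift(uint64_t seed) : state(seed * 2685821657736338717ULL + 1) {}
  uint64_t next() {
    state ^= state >> 12;
    state ^= state << 25;
    state ^= state >> 27;
    return state * 2685821657736338717ULL;
  }
};

void shuffle_idx(std::vector<arma::uword>& idx, XorShift& rng) {
  for (size_t i = idx.size() - 1; i > 0; --i) {
    size_t j = (size_t)(rng.next() % (uint64_t)(i + 1));
    std::swap(idx[i], idx[j]);
  }
}

double rmse(const arma::vec& a, const arma::vec& b) {
  return std::sqrt(arma::mean(arma::square(a - b)));
}

}  // namespace

// [[Rcpp::export(name = ".mlp_predict_cpp")]]
arma::vec mlp_predict_cpp(List params, arma::mat X) {
  Net net = net_from_list(params);
  return forward_eval(net, X);
}

// One train-mode forward/backward on a single batch; exposed so the
// analytic gradients can be checked against numerical differentiation.
// [[Rcpp::export(name = ".mlp_grad_cpp")]]
List mlp_grad_cpp(List params, arma::mat X, arma::vec y) {
  Net net = net_from_list(params);
  Cache cache;
  arma::vec pred = forward_train(net, X, cache, false);
  double loss = arma::mean(arma::square(pred - y));
  Grads g = backward(net, cache, pred, y);
  List hidden(g.hidden.size());
  for (size_t i = 0; i < g.hidden.size(); ++i) {
    hidden[i] = List::create(_["W"] = g.hidden[i].W, _["b"] = g.hidden[i].b,
                             _["gamma"] = g.hidden[i].gamma,
                             _["beta"] = g.hidden[i].beta);
  }
  return List::create(_["loss"] = loss, _["hidden"] = hidden,
                      _["out"] = List::create(_["W"] = g.w_out,
                                              _["b"] = g.b_out));
}

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(List params, arma::mat X, arma::vec y,
                   arma::mat X_val, arma::vec y_val,
                   int batch_size, int max_epochs, double lr,
                   int patience, double beta1, double beta2, int seed) {
  Net net = net_from_list(params);
  const size_t L = net.hidden.size();
  AdamState st;
  st.m_h.resize(L);
  st.v_h.resize(L);
  for (size_t i = 0; i < L; ++i) {
    const Layer& l = net.hidden[i];
    for (auto* s : {&st.m_h[i], &st.v_h[i]}) {
      s->W = arma::zeros<arma::mat>(l.W.n_rows, l.W.n_cols);
      s->b = arma::zeros<arma::rowvec>(l.b.n_elem);
      s->gamma = arma::zeros<arma::rowvec>(l.gamma.n_elem);
      s->beta = arma::zeros<arma::rowvec>(l.beta.n_elem);
    }
  }
  st.m_out = arma::zeros<arma::vec>(net.w_out.n_elem);
  st.v_out = arma::zeros<arma::vec>(net.w_out.n_elem);
  st.m_b = 0.0;
  st.v_b = 0.0;
  st.t = 0;

  XorShift rng((uint64_t)(seed < 0 ? -seed : seed) + 0x9E3779B97F4A7C15ULL);
  std::vector<arma::uword> idx(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) idx[i] = i;

  const bool have_val = X_val.n_rows > 0;
  std::vector<double> train_trace, val_trace;
  Net best = net;
  double best_val = arma::datum::inf;
  int best_epoch = 0, bad_epochs = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    shuffle_idx(idx, rng);
    double sse = 0.0;
    arma::uword n_seen = 0;
    for (arma::uword start = 0; start < X.n_rows;
         start += (arma::uword)batch_size) {
      arma::uword stop = std::min(start + (arma::uword)batch_size,
                                  (arma::uword)X.n_rows);
      if (stop - start < 2 && X.n_rows > 1) break;  // batch-norm degenerate
      arma::uvec take(stop - start);
      for (arma::uword i = start; i < stop; ++i) take[i - start] = idx[i];
      arma::mat Xb = X.rows(take);
      arma::vec yb = y.elem(take);
      Cache cache;
      arma::vec pred = forward_train(net, Xb, cache, true);
      if (!pred.is_finite())
        throw Rcpp::exception("non-finite predictions during training");
      sse += arma::accu(arma::square(pred - yb));
      n_seen += yb.n_elem;
      Grads g = backward(net, cache, pred, yb);
      st.t += 1;
      const double bc1 = 1.0 - std::pow(beta1, (double)st.t);
      const double bc2 = 1.0 - std::pow(beta2, (double)st.t);
      for (size_t i = 0; i < L; ++i) {
        Layer& l = net.hidden[i];
        adam_step(l.W.memptr(), st.m_h[i].W.memptr(), st.v_h[i].W.memptr(),
                  g.hidden[i].W.memptr(), l.W.n_elem, lr, beta1, beta2,
                  bc1, bc2);
        adam_step(l.b.memptr(), st.m_h[i].b.memptr(), st.v_h[i].b.memptr(),
                  g.hidden[i].b.memptr(), l.b.n_elem, lr, beta1, beta2,
                  bc1, bc2);
        adam_step(l.gamma.memptr(), st.m_h[i].gamma.memptr(),
                  st.v_h[i].gamma.memptr(), g.hidden[i].gamma.memptr(),
                  l.gamma.n_elem, lr, beta1, beta2, bc1, bc2);
        adam_step(l.beta.memptr(), st.m_h[i].beta.memptr(),
                  st.v_h[i].beta.memptr(), g.hidden[i].beta.memptr(),
                  l.beta.n_elem, lr, beta1, beta2, bc1, bc2);
      }
      adam_step(net.w_out.memptr(), st.m_out.memptr(), st.v_out.memptr(),
                g.w_out.memptr(), net.w_out.n_elem, lr, beta1, beta2,
                bc1, bc2);
      adam_step(&net.b_out, &st.m_b, &st.v_b, &g.b_out, 1, lr, beta1, beta2,
                bc1, bc2);
    }
    double train_rmse = std::sqrt(sse / std::max<arma::uword>(n_seen, 1));
    train_trace.push_back(train_rmse);
    if (have_val) {
      double vr = rmse(forward_eval(net, X_val), y_val);
      val_trace.push_back(vr);
      if (vr < best_val - 1e-6) {
        best_val = vr;
        best = net;
        best_epoch = epoch;
        bad_epochs = 0;
      } else if (++bad_epochs >= patience) {
        break;
      }
    } else {
      best = net;
      best_epoch = epoch;
    }
    if (!std::isfinite(train_rmse))
      throw Rcpp::exception("non-finite training loss");
  }

  return List::create(
      _["params"] = net_to_list(best),
      _["train_rmse"] = NumericVector(train_trace.begin(), train_trace.end()),
      _["val_rmse"] = NumericVector(val_trace.begin(), val_trace.end()),
      _["best_epoch"] = best_epoch);
}
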