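// 5-5-2 sigmoid multilayer perceptron trained by full-batch backpropagation:
// per-pattern weight deltas are accumulated over an epoch and applied as one
// summed update scaled by the learning rate. Written in C++ because the
// training protocol runs to 80,000 epochs and ensembles retrain many times.
#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

struct Net {
  int n_in, n_hid, n_out;
  std::vector<double> W_hi, b_h, W_oh, b_o; // W_hi: n_hid x n_in (row-major)
  bool input_sigmoid, use_bias;
};

static Net make_net(NumericMatrix W_hi, NumericVector b_h, NumericMatrix W_oh,
                    NumericVector b_o, bool input_sigmoid, bool use_bias) {
  Net net;
  net.n_hid = W_hi.nrow();
  net.n_in = W_hi.ncol();
  net.n_out = W_oh.nrow();
  if (W_oh.ncol() != net.n_hid) stop("W_oh columns must match hidden units");
  if (b_h.size() != net.n_hid || b_o.size() != net.n_out)
    stop("bias lengths inconsistent with weight shapes");
  net.W_hi.assign(net.n_hid * net.n_in, 0.0);
  net.W_oh.assign(net.n_out * net.n_hid, 0.0);
  for (int j = 0; j < net.n_hid; ++j)
    for (int i = 0; i < net.n_in; ++i) net.W_hi[j * net.n_in + i] = W_hi(j, i);
  for (int k = 0; k < net.n_out; ++k)
    for (int j = 0; j < net.n_hid; ++j) net.W_oh[k * net.n_hid + j] = W_oh(k, j);
  net.b_h.assign(b_h.begin(), b_h.end());
  net.b_o.assign(b_o.begin(), b_o.end());
  net.input_sigmoid = input_sigmoid;
  net.use_bias = use_bias;
  return net;
}

// forward pass for one pattern; fills h and o
static void forward_one(const Net &net, const double *x, double *xs,
                        double *h, double *o) {
  for (int i = 0; i < net.n_in; ++i)
    xs[i] = net.input_sigmoid ? sigmoid(x[i]) : x[i];
  for (int j = 0; j < net.n_hid; ++j) {
    double s = net.use_bias ? net.b_h[j] : 0.0;
    const double *w = &net.W_hi[j * net.n_in];
    for (int i = 0; i < net.n_in; ++i) s += w[i] * xs[i];
    h[j] = sigmoid(s);
  }
  for (int k = 0; k < net.n_out; ++k) {
    double s = net.use_bias ? net.b_o[k] : 0.0;
    const double *w = &net.W_oh[k * net.n_hid];
    for (int j = 0; j < net.n_hid; ++j) s += w[j] * h[j];
    o[k] = sigmoid(s);
  }
}

// accumulate gradients of E = 0.5 * sum_k (o_k - t_k)^2 for one pattern;
// returns the pattern's summed squared error
static double backprop_one(const Net &net, const double *x, const double *t,
                           std::vector<double> &gW_hi, std::vector<double> &gb_h,
                           std::vector<double> &gW_oh, std::vector<double> &gb_o,
                           std::vector<double> &buf) {
  double *xs = buf.data();
  double *h = xs + net.n_in;
  double *o = h + net.n_hid;
  double *dout = o + net.n_out;
  double *dhid = dout + net.n_out;
  forward_one(net, x, xs, h, o);
  double sse = 0.0;
  for (int k = 0; k < net.n_out; ++k) {
    double e = o[k] - t[k];
    sse += e * e;
    dout[k] = e * o[k] * (1.0 - o[k]);
  }
  for (int j = 0; j < net.n_hid; ++j) {
    double s = 0.0;
    for (int k = 0; k < net.n_out; ++k) s += net.W_oh[k * net.n_hid + j] * dout[k];
    dhid[j] = s * h[j] * (1.0 - h[j]);
  }
  for (int k = 0; k < net.n_out; ++k) {
    for (int j = 0; j < net.n_hid; ++j) gW_oh[k * net.n_hid + j] += dout[k] * h[j];
    gb_o[k] += dout[k];
  }
  for (int j = 0; j < net.n_hid; ++j) {
    for (int i = 0; i < net.n_in; ++i) gW_hi[j * net.n_in + i] += dhid[j] * xs[i];
    gb_h[j] += dhid[j];
  }
  return sse;
}

static List net_to_list(const Net &net) {
  NumericMatrix W_hi(net.n_hid, net.n_in), W_oh(net.n_out, net.n_hid);
  for (int j = 0; j < net.n_hid; ++j)
    for (int i = 0; i < net.n_in; ++i) W_hi(j, i) = net.W_hi[j * net.n_in + i];
  for (int k = 0; k < net.n_out; ++k)
    for (int j = 0; j < net.n_hid; ++j) W_oh(k, j) = net.W_oh[k * net.n_hid + j];
  return List::create(
      _["W_hi"] = W_hi, _["b_h"] = NumericVector(net.b_h.begin(), net.b_h.end()),
      _["W_oh"] = W_oh, _["b_o"] = NumericVector(net.b_o.begin(), net.b_o.end()));
}

// [[Rcpp::export(name = ".mlp_forward_cpp")]]
NumericMatrix mlp_forward_cpp(NumericMatrix X, NumericMatrix W_hi,
                              NumericVector b_h, NumericMatrix W_oh,
                              NumericVector b_o, bool input_sigmoid,
                              bool use_bias) {
  Net net = make_net(W_hi, b_h, W_oh, b_o, input_sigmoid, use_bias);
  if (X.ncol() != net.n_in) stop("X columns must match input units");
  int n = X.nrow();
  NumericMatrix out(n, net.n_out);
  std::vector<double> x(net.n_in), xs(net.n_in), h(net.n_hid), o(net.n_out);
  for (int p = 0; p < n; ++p) {
    for (int i = 0; i < net.n_in; ++i) x[i] = X(p, i);
    forward_one(net, x.data(), xs.data(), h.data(), o.data());
    for (int k = 0; k < net.n_out; ++k) out(p, k) = o[k];
  }
  return out;
}

// [[Rcpp::export(name = ".mlp_gradient_cpp")]]
List mlp_gradient_cpp(NumericMatrix X, NumericMatrix Y, NumericMatrix W_hi,
                      NumericVector b_h, NumericMatrix W_oh, NumericVector b_o,
                      bool input_sigmoid, bool use_bias) {
  Net net = make_net(W_hi, b_h, W_oh, b_o, input_sigmoid, use_bias);
  int n = X.nrow();
  if (Y.nrow() != n || Y.ncol() != net.n_out) stop("Y shape mismatch");
  std::vector<double> gW_hi(net.n_hid * net.n_in, 0.0), gb_h(net.n_hid, 0.0);
  std::vector<double> gW_oh(net.n_out * net.n_hid, 0.0), gb_o(net.n_out, 0.0);
  std::vector<double> buf(net.n_in + net.n_hid + 2 * net.n_out + net.n_hid);
  std::vector<double> x(net.n_in), t(net.n_out);
  double sse = 0.0;
  for (int p = 0; p < n; ++p) {
    for (int i = 0; i < net.n_in; ++i) x[i] = X(p, i);
    for (int k = 0; k < net.n_out; ++k) t[k] = Y(p, k);
    sse += backprop_one(net, x.data(), t.data(), gW_hi, gb_h, gW_oh, gb_o, buf);
  }
  NumericMatrix GW_hi(net.n_hid, net.n_in), GW_oh(net.n_out, net.n_hid);
  for (int j = 0; j < net.n_hid; ++j)
    for (int i = 0; i < net.n_in; ++i) GW_hi(j, i) = gW_hi[j * net.n_in + i];
  for (int k = 0; k < net.n_out; ++k)
    for (int j = 0; j < net.n_hid; ++j) GW_oh(k, j) = gW_oh[k * net.n_hid + j];
  return List::create(
      _["W_hi"] = GW_hi, _["b_h"] = NumericVector(gb_h.begin(), gb_h.end()),
      _["W_oh"] = GW_oh, _["b_o"] = NumericVector(gb_o.begin(), gb_o.end()),
      _["mse"] = sse / (n * net.n_out));
}

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(NumericMatrix X, NumericMatrix Y, NumericMatrix W_hi,
                   NumericVector b_h, NumericMatrix W_oh, NumericVector b_o,
                   double lr, int max_epochs, bool input_sigmoid, bool use_bias,
                   int trace_every) {
  Net net = make_net(W_hi, b_h, W_oh, b_o, input_sigmoid, use_bias);
  int n = X.nrow();
  if (Y.nrow() != n || Y.ncol() != net.n_out) stop("Y shape mismatch");
  int nw_hi = net.n_hid * net.n_in, nw_oh = net.n_out * net.n_hid;
  std::vector<double> gW_hi(nw_hi), gb_h(net.n_hid), gW_oh(nw_oh), gb_o(net.n_out);
  std::vector<double> buf(net.n_in + net.n_hid + 2 * net.n_out + net.n_hid);
  std::vector<double> x(net.n_in), t(net.n_out);
  std::vector<int> order(n);
  for (int p = 0; p < n; ++p) order[p] = p;

  std::vector<int> trace_epoch;
  std::vector<double> trace_mse;
  RNGScope rng; // presentation order drawn from R's RNG stream

  for (int e = 0; e < max_epochs; ++e) {
    std::fill(gW_hi.begin(), gW_hi.end(), 0.0);
    std::fill(gb_h.begin(), gb_h.end(), 0.0);
    std::fill(gW_oh.begin(), gW_oh.end(), 0.0);
    std::fill(gb_o.begin(), gb_o.end(), 0.0);
    // randomized presentation order (a no-op under summed full-batch updates,
    // retained to mirror the training protocol)
    for (int p = n - 1; p > 0; --p) {
      int q = (int)(unif_rand() * (p + 1));
      if (q > p) q = p;
      std::swap(order[p], order[q]);
    }
    double sse = 0.0;
    for (int pp = 0; pp < n; ++pp) {
      int p = order[pp];
      for (int i = 0; i < net.n_in; ++i) x[i] = X(p, i);
      for (int k = 0; k < net.n_out; ++k) t[k] = Y(p, k);
      sse += backprop_one(net, x.data(), t.data(), gW_hi, gb_h, gW_oh, gb_o, buf);
    }
    double mse = sse / (n * net.n_out); // MSE before this epoch's update
    if (!std::isfinite(mse)) stop("training diverged (non-finite MSE) at epoch %d", e);
    if (e % trace_every == 0) {
      trace_epoch.push_back(e);
      trace_mse.push_back(mse);
    }
    for (int i = 0; i < nw_hi; ++i) net.W_hi[i] -= lr * gW_hi[i];
    for (int i = 0; i < nw_oh; ++i) net.W_oh[i] -= lr * gW_oh[i];
    if (use_bias) {
      for (int j = 0; j < net.n_hid; ++j) net.b_h[j] -= lr * gb_h[j];
      for (int k = 0; k < net.n_out; ++k) net.b_o[k] -= lr * gb_o[k];
    }
  }

  // final MSE after the last update
  double sse = 0.0;
  std::vector<double> xs(net.n_in), h(net.n_hid), o(net.n_out);
  for (int p = 0; p < n; ++p) {
    for (int i = 0; i < net.n_in; ++i) x[i] = X(p, i);
    forward_one(net, x.data(), xs.data(), h.data(), o.data());
    for (int k = 0; k < net.n_out; ++k) {
      double err = o[k] - Y(p, k);
      sse += err * err;
    }
  }
  double final_mse = sse / (n * net.n_out);
  trace_epoch.push_back(max_epochs);
  trace_mse.push_back(final_mse);

  List weights = net_to_list(net);
  return List::create(
      _["weights"] = weights,
      _["trace_epoch"] = IntegerVector(trace_epoch.begin(), trace_epoch.end()),
      _["trace_mse"] = NumericVector(trace_mse.begin(), trace_mse.end()),
      _["final_mse"] = final_mse);
}
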