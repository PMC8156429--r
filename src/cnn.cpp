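// One-dimensional convolutional network for spectral regression.
//
// Fixed topology: input (B x 1) -> conv1 (stride 1, 'same' padding) + ReLU
// -> batch norm -> max pool 2 -> conv2 + ReLU -> batch norm -> max pool 5
// -> dropout -> flatten -> dense + ReLU -> dropout -> dense(1, linear).
// MSE loss, Adadelta updates, early stopping on validation MSE with
// best-weight restoration. All randomness (shuffling, dropout masks) comes
// from R's RNG so training is reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

static const double BN_EPS = 1e-3;
static const double BN_MOMENTUM = 0.99;
static const int POOL1 = 2;
static const int POOL2 = 5;

struct Params {
  cube W1; vec b1; vec g1, be1, rm1, rv1;
  cube W2; vec b2; vec g2, be2, rm2, rv2;
  mat W3; vec b3; mat W4; vec b4;
};

static Params params_from_list(const List& p) {
  Params q;
  q.W1 = as<cube>(p["W1"]); q.b1 = as<vec>(p["b1"]);
  q.g1 = as<vec>(p["g1"]); q.be1 = as<vec>(p["be1"]);
  q.rm1 = as<vec>(p["rm1"]); q.rv1 = as<vec>(p["rv1"]);
  q.W2 = as<cube>(p["W2"]); q.b2 = as<vec>(p["b2"]);
  q.g2 = as<vec>(p["g2"]); q.be2 = as<vec>(p["be2"]);
  q.rm2 = as<vec>(p["rm2"]); q.rv2 = as<vec>(p["rv2"]);
  q.W3 = as<mat>(p["W3"]); q.b3 = as<vec>(p["b3"]);
  q.W4 = as<mat>(p["W4"]); q.b4 = as<vec>(p["b4"]);
  return q;
}

static List params_to_list(const Params& q) {
  return List::create(
    _["W1"] = q.W1, _["b1"] = q.b1, _["g1"] = q.g1, _["be1"] = q.be1,
    _["rm1"] = q.rm1, _["rv1"] = q.rv1,
    _["W2"] = q.W2, _["b2"] = q.b2, _["g2"] = q.g2, _["be2"] = q.be2,
    _["rm2"] = q.rm2, _["rv2"] = q.rv2,
    _["W3"] = q.W3, _["b3"] = q.b3, _["W4"] = q.W4, _["b4"] = q.b4);
}

// 'same' padding, stride 1: out[t] = b + sum_j W_j * in[t + j - padL],
// padL = (k - 1) / 2 (integer division; matches the left-heavy convention
// for even kernels).
static void conv_forward(const cube& W, const vec& b, const cube& in,
                         cube& out) {
  const int k = W.n_slices;
  const int L = in.n_cols;
  const int nb = in.n_slices;
  const int padL = (k - 1) / 2;
  out.zeros();
  for (int s = 0; s < nb; ++s) {
    for (int j = 0; j < k; ++j) {
      int t1 = std::max(0, padL - j);
      int t2 = std::min(L - 1, L - 1 + padL - j);
      if (t1 > t2) continue;
      out.slice(s).cols(t1, t2) +=
        W.slice(j) * in.slice(s).cols(t1 + j - padL, t2 + j - padL);
    }
    out.slice(s).each_col() += b;
  }
}

static void conv_backward(const cube& W, const cube& in, const cube& dOut,
                          cube& dW, vec& db, cube* dIn) {
  const int k = W.n_slices;
  const int L = in.n_cols;
  const int nb = in.n_slices;
  const int padL = (k - 1) / 2;
  dW.zeros(); db.zeros();
  if (dIn) dIn->zeros();
  for (int s = 0; s < nb; ++s) {
    for (int j = 0; j < k; ++j) {
      int t1 = std::max(0, padL - j);
      int t2 = std::min(L - 1, L - 1 + padL - j);
      if (t1 > t2) continue;
      int c1 = t1 + j - padL, c2 = t2 + j - padL;
      dW.slice(j) += dOut.slice(s).cols(t1, t2) *
                     in.slice(s).cols(c1, c2).t();
      if (dIn)
        dIn->slice(s).cols(c1, c2) += W.slice(j).t() *
                                      dOut.slice(s).cols(t1, t2);
    }
    db += arma::sum(dOut.slice(s), 1);
  }
}

// Batch norm over (positions x batch) per channel.
struct BNCache { cube xhat; vec invstd; };

static void bn_forward_train(const cube& in, const vec& g, const vec& be,
                             vec& rm, vec& rv, cube& out, BNCache& cache) {
  const int C = in.n_rows, nb = in.n_slices;
  const double N = double(in.n_cols) * nb;
  vec mu(C, arma::fill::zeros), var(C, arma::fill::zeros);
  for (int s = 0; s < nb; ++s) mu += arma::sum(in.slice(s), 1);
  mu /= N;
  for (int s = 0; s < nb; ++s) {
    mat c = in.slice(s);
    c.each_col() -= mu;
    var += arma::sum(arma::square(c), 1);
  }
  var /= N;
  cache.invstd = 1.0 / arma::sqrt(var + BN_EPS);
  cache.xhat.set_size(arma::size(in));
  out.set_size(arma::size(in));
  for (int s = 0; s < nb; ++s) {
    mat c = in.slice(s);
    c.each_col() -= mu;
    c.each_col() %= cache.invstd;
    cache.xhat.slice(s) = c;
    c.each_col() %= g;
    c.each_col() += be;
    out.slice(s) = c;
  }
  rm = BN_MOMENTUM * rm + (1.0 - BN_MOMENTUM) * mu;
  rv = BN_MOMENTUM * rv + (1.0 - BN_MOMENTUM) * var;
}

static void bn_forward_infer(const cube& in, const vec& g, const vec& be,
                             const vec& rm, const vec& rv, cube& out) {
  const int nb = in.n_slices;
  vec invstd = 1.0 / arma::sqrt(rv + BN_EPS);
  out.set_size(arma::size(in));
  for (int s = 0; s < nb; ++s) {
    mat c = in.slice(s);
    c.each_col() -= rm;
    c.each_col() %= invstd % g;
    c.each_col() += be;
    out.slice(s) = c;
  }
}

static void bn_backward(const cube& dOut, const BNCache& cache, const vec& g,
                        cube& dIn, vec& dg, vec& dbe) {
  const int C = dOut.n_rows, nb = dOut.n_slices;
  const double N = double(dOut.n_cols) * nb;
  dg.zeros(C); dbe.zeros(C);
  vec m_d(C, arma::fill::zeros), m_dx(C, arma::fill::zeros);
  for (int s = 0; s < nb; ++s) {
    dbe += arma::sum(dOut.slice(s), 1);
    dg += arma::sum(dOut.slice(s) % cache.xhat.slice(s), 1);
  }
  m_d = dbe / N;          // mean of upstream grad per channel
  m_dx = dg / N;          // mean of grad * xhat per channel
  dIn.set_size(arma::size(dOut));
  for (int s = 0; s < nb; ++s) {
    mat c = dOut.slice(s);
    c.each_col() -= m_d;
    c -= cache.xhat.slice(s).each_col() % m_dx;
    c.each_col() %= g % cache.invstd;
    dIn.slice(s) = c;
  }
}

// Non-overlapping max pool with floor truncation of the tail.
static void pool_forward(const cube& in, int p, cube& out, arma::ucube& idx) {
  const int C = in.n_rows, nb = in.n_slices;
  const int Lo = in.n_cols / p;
  out.set_size(C, Lo, nb);
  idx.set_size(C, Lo, nb);
  for (int s = 0; s < nb; ++s) {
    for (int t = 0; t < Lo; ++t) {
      for (int c = 0; c < C; ++c) {
        double best = in(c, t * p, s); uword bj = t * p;
        for (int j = 1; j < p; ++j) {
          double v = in(c, t * p + j, s);
          if (v > best) { best = v; bj = t * p + j; }
        }
        out(c, t, s) = best;
        idx(c, t, s) = bj;
      }
    }
  }
}

static void pool_backward(const cube& dOut, const arma::ucube& idx, int Lin,
                          cube& dIn) {
  const int C = dOut.n_rows, Lo = dOut.n_cols, nb = dOut.n_slices;
  dIn.zeros(C, Lin, nb);
  for (int s = 0; s < nb; ++s)
    for (int t = 0; t < Lo; ++t)
      for (int c = 0; c < C; ++c)
        dIn(c, idx(c, t, s), s) += dOut(c, t, s);
}

// Inverted dropout mask from R's RNG (reproducible under set.seed).
static void dropout_mask_cube(cube& m, double rate) {
  const double keep = 1.0 - rate;
  for (uword i = 0; i < m.n_elem; ++i)
    m(i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
}
static void dropout_mask_mat(mat& m, double rate) {
  const double keep = 1.0 - rate;
  for (uword i = 0; i < m.n_elem; ++i)
    m(i) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
}

// Inference-mode forward over a sample chunk; X rows are spectra.
static vec forward_infer(const Params& q, const mat& X) {
  const int nb = X.n_rows, B = X.n_cols;
  cube in1(1, B, nb);
  for (int s = 0; s < nb; ++s) in1.slice(s) = X.row(s);
  cube z1(q.W1.n_rows, B, nb);
  conv_forward(q.W1, q.b1, in1, z1);
  z1.transform([](double v) { return v > 0 ? v : 0.0; });
  cube y1;
  bn_forward_infer(z1, q.g1, q.be1, q.rm1, q.rv1, y1);
  cube p1; arma::ucube i1;
  pool_forward(y1, POOL1, p1, i1);
  cube z2(q.W2.n_rows, p1.n_cols, nb);
  conv_forward(q.W2, q.b2, p1, z2);
  z2.transform([](double v) { return v > 0 ? v : 0.0; });
  cube y2;
  bn_forward_infer(z2, q.g2, q.be2, q.rm2, q.rv2, y2);
  cube p2; arma::ucube i2;
  pool_forward(y2, POOL2, p2, i2);
  mat F(p2.n_rows * p2.n_cols, nb);
  for (int s = 0; s < nb; ++s) F.col(s) = arma::vectorise(p2.slice(s));
  mat H = q.W3 * F;
  H.each_col() += q.b3;
  H.transform([](double v) { return v > 0 ? v : 0.0; });
  mat out = q.W4 * H;
  out += q.b4(0);
  return out.t();
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(List params, arma::mat X) {
  Params q = params_from_list(params);
  const int n = X.n_rows;
  vec out(n);
  const int chunk = 128;
  for (int start = 0; start < n; start += chunk) {
    int end = std::min(n, start + chunk) - 1;
    out.subvec(start, end) = forward_infer(q, X.rows(start, end));
  }
  return out;
}

struct Adadelta {
  cube EgW1, EdW1, EgW2, EdW2;
  vec Egb1, Edb1, Egg1, Edg1, Egbe1, Edbe1;
  vec Egb2, Edb2, Egg2, Edg2, Egbe2, Edbe2;
  mat EgW3, EdW3, EgW4, EdW4;
  vec Egb3, Edb3, Egb4, Edb4;
  double lr, rho, eps;

  void init(const Params& q, double lr_, double rho_, double eps_) {
    lr = lr_; rho = rho_; eps = eps_;
    EgW1.zeros(arma::size(q.W1)); EdW1.zeros(arma::size(q.W1));
    EgW2.zeros(arma::size(q.W2)); EdW2.zeros(arma::size(q.W2));
    EgW3.zeros(arma::size(q.W3)); EdW3.zeros(arma::size(q.W3));
    EgW4.zeros(arma::size(q.W4)); EdW4.zeros(arma::size(q.W4));
    Egb1.zeros(q.b1.n_elem); Edb1.zeros(q.b1.n_elem);
    Egg1.zeros(q.g1.n_elem); Edg1.zeros(q.g1.n_elem);
    Egbe1.zeros(q.be1.n_elem); Edbe1.zeros(q.be1.n_elem);
    Egb2.zeros(q.b2.n_elem); Edb2.zeros(q.b2.n_elem);
    Egg2.zeros(q.g2.n_elem); Edg2.zeros(q.g2.n_elem);
    Egbe2.zeros(q.be2.n_elem); Edbe2.zeros(q.be2.n_elem);
    Egb3.zeros(q.b3.n_elem); Edb3.zeros(q.b3.n_elem);
    Egb4.zeros(q.b4.n_elem); Edb4.zeros(q.b4.n_elem);
  }

  template <typename T>
  void step(T& param, const T& grad, T& Eg, T& Ed) {
    Eg = rho * Eg + (1.0 - rho) * (grad % grad);
    T upd = grad % arma::sqrt((Ed + eps) / (Eg + eps));
    Ed = rho * Ed + (1.0 - rho) * (upd % upd);
    param -= lr * upd;
  }
};

// [[Rcpp::export]]
List cnn_train_cpp(List params, arma::mat X, arma::vec y,
                   arma::mat Xval, arma::vec yval,
                   double lr, double rho, double eps,
                   int batch_size, int max_epochs, int patience,
                   double dropout1, double dropout2) {
  Params q = params_from_list(params);
  Adadelta opt;
  opt.init(q, lr, rho, eps);

  const int n = X.n_rows, B = X.n_cols;
  const int f1 = q.W1.n_rows, f2 = q.W2.n_rows;
  batch_size = std::min(batch_size, n);

  std::vector<double> hist_train, hist_val;
  Params best = q;
  double best_val = arma::datum::inf;
  int best_epoch = -1, wait = 0, stopped_epoch = max_epochs;
  bool diverged = false; int diverged_epoch = -1;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = int(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double sse = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int nb = std::min(batch_size, n - start);
      cube in1(1, B, nb);
      vec yb(nb);
      for (int s = 0; s < nb; ++s) {
        in1.slice(s) = X.row(order[start + s]);
        yb(s) = y(order[start + s]);
      }
      // ---- forward (training mode) ----
      cube z1(f1, B, nb);
      conv_forward(q.W1, q.b1, in1, z1);
      cube a1 = z1;
      a1.transform([](double v) { return v > 0 ? v : 0.0; });
      cube y1; BNCache c1;
      bn_forward_train(a1, q.g1, q.be1, q.rm1, q.rv1, y1, c1);
      cube p1; arma::ucube i1;
      pool_forward(y1, POOL1, p1, i1);
      const int L1 = p1.n_cols;
      cube z2(f2, L1, nb);
      conv_forward(q.W2, q.b2, p1, z2);
      cube a2 = z2;
      a2.transform([](double v) { return v > 0 ? v : 0.0; });
      cube y2; BNCache c2;
      bn_forward_train(a2, q.g2, q.be2, q.rm2, q.rv2, y2, c2);
      cube p2; arma::ucube i2;
      pool_forward(y2, POOL2, p2, i2);
      cube dm1(arma::size(p2));
      if (dropout1 > 0) dropout_mask_cube(dm1, dropout1); else dm1.ones();
      cube d1 = p2 % dm1;
      const int flat = d1.n_rows * d1.n_cols;
      mat F(flat, nb);
      for (int s = 0; s < nb; ++s) F.col(s) = arma::vectorise(d1.slice(s));
      mat Hpre = q.W3 * F;
      Hpre.each_col() += q.b3;
      mat H = Hpre;
      H.transform([](double v) { return v > 0 ? v : 0.0; });
      mat dm2(arma::size(H));
      if (dropout2 > 0) dropout_mask_mat(dm2, dropout2); else dm2.ones();
      mat D2 = H % dm2;
      arma::rowvec yhat = q.W4 * D2 + q.b4(0);
      arma::rowvec err = yhat - yb.t();
      sse += arma::accu(arma::square(err));
      if (!err.is_finite()) { diverged = true; diverged_epoch = epoch + 1; break; }
      // ---- backward ----
      arma::rowvec dyhat = 2.0 * err / double(nb);
      mat dW4 = dyhat * D2.t();
      vec db4(1); db4(0) = arma::accu(dyhat);
      mat dD2 = q.W4.t() * dyhat;
      mat dH = dD2 % dm2;
      mat dHpre = dH;
      for (uword ii = 0; ii < dHpre.n_elem; ++ii)
        if (Hpre(ii) <= 0) dHpre(ii) = 0.0;
      mat dW3 = dHpre * F.t();
      vec db3 = arma::sum(dHpre, 1);
      mat dF = q.W3.t() * dHpre;
      cube dD1(arma::size(d1));
      for (int s = 0; s < nb; ++s)
        dD1.slice(s) = arma::reshape(dF.col(s), d1.n_rows, d1.n_cols);
      cube dP2 = dD1 % dm1;
      cube dY2;
      pool_backward(dP2, i2, y2.n_cols, dY2);
      cube dA2; vec dg2, dbe2;
      bn_backward(dY2, c2, q.g2, dA2, dg2, dbe2);
      cube dZ2 = dA2;
      for (uword ii = 0; ii < dZ2.n_elem; ++ii)
        if (z2(ii) <= 0) dZ2(ii) = 0.0;
      cube dW2(arma::size(q.W2)); vec db2; cube dP1(arma::size(p1));
      db2.set_size(f2);
      conv_backward(q.W2, p1, dZ2, dW2, db2, &dP1);
      cube dY1;
      pool_backward(dP1, i1, y1.n_cols, dY1);
      cube dA1; vec dg1, dbe1;
      bn_backward(dY1, c1, q.g1, dA1, dg1, dbe1);
      cube dZ1 = dA1;
      for (uword ii = 0; ii < dZ1.n_elem; ++ii)
        if (z1(ii) <= 0) dZ1(ii) = 0.0;
      cube dW1(arma::size(q.W1)); vec db1;
      db1.set_size(f1);
      conv_backward(q.W1, in1, dZ1, dW1, db1, nullptr);
      // ---- Adadelta updates ----
      opt.step(q.W1, dW1, opt.EgW1, opt.EdW1);
      opt.step(q.b1, db1, opt.Egb1, opt.Edb1);
      opt.step(q.g1, dg1, opt.Egg1, opt.Edg1);
      opt.step(q.be1, dbe1, opt.Egbe1, opt.Edbe1);
      opt.step(q.W2, dW2, opt.EgW2, opt.EdW2);
      opt.step(q.b2, db2, opt.Egb2, opt.Edb2);
      opt.step(q.g2, dg2, opt.Egg2, opt.Edg2);
      opt.step(q.be2, dbe2, opt.Egbe2, opt.Edbe2);
      opt.step(q.W3, dW3, opt.EgW3, opt.EdW3);
      opt.step(q.b3, db3, opt.Egb3, opt.Edb3);
      opt.step(q.W4, dW4, opt.EgW4, opt.EdW4);
      opt.step(q.b4, db4, opt.Egb4, opt.Edb4);
    }
    if (diverged) break;
    double train_mse = sse / n;
    vec pv = forward_infer(q, Xval);
    double val_mse = arma::accu(arma::square(pv - yval)) / yval.n_elem;
    hist_train.push_back(train_mse);
    hist_val.push_back(val_mse);
    if (!std::isfinite(val_mse)) { diverged = true; diverged_epoch = epoch + 1; break; }
    if (val_mse < best_val) {
      best_val = val_mse;
      best = q;
      best_epoch = epoch + 1;
      wait = 0;
    } else if (++wait >= patience) {
      stopped_epoch = epoch + 1;
      break;
    }
    if (epoch + 1 == max_epochs) stopped_epoch = max_epochs;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["params"] = params_to_list(best_epoch > 0 ? best : q),
    _["train_history"] = hist_train,
    _["val_history"] = hist_val,
    _["best_epoch"] = best_epoch,
    _["stopped_epoch"] = stopped_epoch,
    _["diverged"] = diverged,
    _["diverged_epoch"] = diverged_epoch);
}
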