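// Incremental (per-sample) backpropagation trainer for the one-hidden-layer
// nonlinear MVAR network. Uses R's RNG so set.seed() in R fully determines
// initialization and sample ordering. Weight matrices are kept transposed
// (inputs x hidden, hidden x outputs) so the per-sample loops walk
// column-major memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// W1t: D x H, W2t: H x M. X: D x N, Y: M x N.
static double mse_of(const mat& W1t, const vec& b1, const mat& W2t,
                     const vec& b2, const mat& X, const mat& Y,
                     const uvec& idx) {
  mat Z = W1t.t() * X.cols(idx);
  Z.each_col() += b1;
  mat H = tanh(Z);
  mat E = W2t.t() * H - Y.cols(idx);
  E.each_col() += b2;
  return accu(E % E) / E.n_elem;
}

// [[Rcpp::export(name = ".train_mlp_cpp")]]
Rcpp::List train_mlp_cpp(const arma::mat& Xr, const arma::mat& Yr,
                         int hidden,
                         arma::uvec idx_train, arma::uvec idx_val,
                         double eta, double momentum,
                         double lr_up, double lr_down, double err_ratio,
                         double lr_decay, double eta_min,
                         int max_epochs, int patience, double init_range,
                         int avg_tail) {
  mat X = Xr.t();                  // D x N
  mat Y = Yr.t();                  // M x N
  const int D = X.n_rows, M = Y.n_rows, H = hidden;
  idx_train -= 1; idx_val -= 1;

  Rcpp::RNGScope scope;
  auto runif_mat = [&](int r, int c) {
    mat A(r, c);
    for (uword j = 0; j < A.n_elem; ++j)
      A(j) = R::runif(-init_range, init_range);
    return A;
  };
  // Initialization order matches the conceptual H x D / M x H layout.
  mat W1t = runif_mat(H, D).t();
  vec b1 = runif_mat(H, 1);
  mat W2t = runif_mat(M, H).t();
  vec b2 = runif_mat(M, 1);

  mat vW1t(D, H, fill::zeros), vW2t(H, M, fill::zeros);
  vec vb1(H, fill::zeros), vb2(M, fill::zeros);
  vec h(H), dz(H), e(M);

  // ring buffer of epoch-end weights for tail averaging
  std::vector<mat> rW1, rW2; std::vector<vec> rb1, rb2;
  int ring_n = std::max(avg_tail, 0), ring_pos = 0, ring_fill = 0;
  if (ring_n) {
    rW1.assign(ring_n, W1t); rW2.assign(ring_n, W2t);
    rb1.assign(ring_n, b1); rb2.assign(ring_n, b2);
  }

  const int n_train = idx_train.n_elem;
  double prev_train = mse_of(W1t, b1, W2t, b2, X, Y, idx_train);
  double best_val = datum::inf;
  mat bW1t = W1t, bW2t = W2t; vec bb1 = b1, bb2 = b2;
  int best_epoch = 0, stall = 0, epoch = 0;
  double train_mse = prev_train, val_mse = datum::inf;
  std::vector<uword> ord(idx_train.begin(), idx_train.end());

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    mat sW1t = W1t, sW2t = W2t; vec sb1 = b1, sb2 = b2;
    mat svW1t = vW1t, svW2t = vW2t; vec svb1 = vb1, svb2 = vb2;

    for (int i = n_train - 1; i > 0; --i) {       // Fisher-Yates via R RNG
      int j = (int)(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }

    for (int s = 0; s < n_train; ++s) {
      const double* x = X.colptr(ord[s]);
      const double* y = Y.colptr(ord[s]);
      // forward
      for (int k = 0; k < H; ++k) {
        const double* w = W1t.colptr(k);
        double z = b1[k];
        for (int d = 0; d < D; ++d) z += w[d] * x[d];
        h[k] = std::tanh(z);
      }
      for (int m = 0; m < M; ++m) {
        const double* w = W2t.colptr(m);
        double z = b2[m];
        for (int k = 0; k < H; ++k) z += w[k] * h[k];
        e[m] = z - y[m];
      }
      // backward
      dz.zeros();
      for (int m = 0; m < M; ++m) {
        const double* w = W2t.colptr(m);
        const double em = e[m];
        for (int k = 0; k < H; ++k) dz[k] += w[k] * em;
      }
      for (int k = 0; k < H; ++k) dz[k] *= (1.0 - h[k] * h[k]);
      // momentum updates
      for (int m = 0; m < M; ++m) {
        double* v = vW2t.colptr(m);
        double* w = W2t.colptr(m);
        const double g = eta * e[m];
        for (int k = 0; k < H; ++k) {
          v[k] = momentum * v[k] - g * h[k];
          w[k] += v[k];
        }
        vb2[m] = momentum * vb2[m] - g;
        b2[m] += vb2[m];
      }
      for (int k = 0; k < H; ++k) {
        double* v = vW1t.colptr(k);
        double* w = W1t.colptr(k);
        const double g = eta * dz[k];
        for (int d = 0; d < D; ++d) {
          v[d] = momentum * v[d] - g * x[d];
          w[d] += v[d];
        }
        vb1[k] = momentum * vb1[k] - g;
        b1[k] += vb1[k];
      }
    }

    train_mse = mse_of(W1t, b1, W2t, b2, X, Y, idx_train);
    if (!std::isfinite(train_mse))
      Rcpp::stop("training diverged (non-finite MSE) at epoch %d", epoch);

    if (train_mse > prev_train * err_ratio) {
      // discard this epoch's update, cool the learning rate
      W1t = sW1t; W2t = sW2t; b1 = sb1; b2 = sb2;
      vW1t = svW1t; vW2t = svW2t; vb1 = svb1; vb2 = svb2;
      eta *= lr_down;
      train_mse = prev_train;
    } else {
      if (train_mse < prev_train) eta *= lr_up;
      prev_train = train_mse;
    }
    eta = std::max(eta * lr_decay, eta_min);

    if (ring_n) {
      rW1[ring_pos] = W1t; rW2[ring_pos] = W2t;
      rb1[ring_pos] = b1; rb2[ring_pos] = b2;
      ring_pos = (ring_pos + 1) % ring_n;
      if (ring_fill < ring_n) ++ring_fill;
    }

    val_mse = mse_of(W1t, b1, W2t, b2, X, Y, idx_val);
    if (val_mse < best_val - 1e-12) {
      best_val = val_mse;
      bW1t = W1t; bW2t = W2t; bb1 = b1; bb2 = b2;
      best_epoch = epoch;
      stall = 0;
    } else if (++stall >= patience) break;
  }

  if (ring_n && ring_fill) {
    // replace the best-validation snapshot by the tail average: the mean
    // of the last ring_fill epoch-end weights, which bracket the
    // early-stopping optimum and average out the SGD weight noise
    bW1t.zeros(); bW2t.zeros(); bb1.zeros(); bb2.zeros();
    for (int r = 0; r < ring_fill; ++r) {
      bW1t += rW1[r]; bW2t += rW2[r]; bb1 += rb1[r]; bb2 += rb2[r];
    }
    bW1t /= ring_fill; bW2t /= ring_fill; bb1 /= ring_fill; bb2 /= ring_fill;
    best_val = mse_of(bW1t, bb1, bW2t, bb2, X, Y, idx_val);
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = bW1t.t(), Rcpp::Named("b1") = bb1,
    Rcpp::Named("W2") = bW2t.t(), Rcpp::Named("b2") = bb2,
    Rcpp::Named("train_mse") = mse_of(bW1t, bb1, bW2t, bb2, X, Y, idx_train),
    Rcpp::Named("val_mse") = best_val,
    Rcpp::Named("epochs") = std::min(epoch, max_epochs),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("eta_final") = eta);
}
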