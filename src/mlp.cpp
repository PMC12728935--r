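// Feed-forward regression network used for interaction-energy prediction.
// Hand-rolled because no deep-learning backend is available in the target
// environment; the training loop implements Adam, per-sample loss weights,
// elastic-net weight penalties, learning-rate halving on validation
// stagnation and early stopping with best-weight restoration.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static mat leaky(const mat& z, double slope) {
  // for slope < 1: z > 0 -> z, z < 0 -> slope*z
  return arma::max(z, slope * z);
}

static mat leaky_grad(const mat& z, double slope) {
  mat g(arma::size(z));
  g.fill(slope);
  g.elem(find(z > 0)).ones();
  return g;
}

static vec forward_all(const mat& X, const std::vector<mat>& W,
                       const std::vector<vec>& b, double slope) {
  mat A = X;
  const size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    mat Z = A * W[l];
    Z.each_row() += b[l].t();
    A = (l + 1 == L) ? Z : leaky(Z, slope);
  }
  return A.col(0);
}

// [[Rcpp::export]]
arma::vec mlp_forward(const arma::mat& X, const Rcpp::List& W_,
                      const Rcpp::List& b_, double slope) {
  std::vector<mat> W;
  std::vector<vec> b;
  for (int l = 0; l < W_.size(); ++l) {
    W.push_back(Rcpp::as<mat>(W_[l]));
    b.push_back(Rcpp::as<vec>(b_[l]));
  }
  return forward_all(X, W, b, slope);
}

// [[Rcpp::export]]
Rcpp::List mlp_train(const arma::mat& X, const arma::vec& y,
                     const arma::vec& w,
                     const arma::mat& Xval, const arma::vec& yval,
                     const arma::ivec& hidden, double slope,
                     double lr0, double lr_floor, int lr_patience,
                     int batch, int max_epochs,
                     int es_patience, double min_delta,
                     double l1, double l2, int seed) {
  const uword n = X.n_rows;
  const uword d = X.n_cols;
  std::vector<uword> sizes;
  sizes.push_back(d);
  for (uword i = 0; i < hidden.n_elem; ++i) sizes.push_back((uword)hidden[i]);
  sizes.push_back(1);
  const size_t L = sizes.size() - 1;

  std::mt19937 gen((unsigned)seed);
  std::vector<mat> W(L), mW(L), vW(L), bestW(L);
  std::vector<vec> b(L), mb(L), vb(L), bestb(L);
  for (size_t l = 0; l < L; ++l) {
    // He-uniform initialization
    double lim = std::sqrt(6.0 / (double)sizes[l]);
    std::uniform_real_distribution<double> U(-lim, lim);
    W[l].set_size(sizes[l], sizes[l + 1]);
    for (uword j = 0; j < W[l].n_elem; ++j) W[l](j) = U(gen);
    b[l].zeros(sizes[l + 1]);
    mW[l].zeros(arma::size(W[l])); vW[l].zeros(arma::size(W[l]));
    mb[l].zeros(sizes[l + 1]);    vb[l].zeros(sizes[l + 1]);
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  double lr = lr0;
  long long t_adam = 0;
  double best_val = datum::inf;
  int best_epoch = 0, lr_wait = 0, es_wait = 0;
  bestW = W; bestb = b;

  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> h_epoch, h_lr, h_train, h_val;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), gen);
    for (uword start = 0; start < n; start += (uword)batch) {
      uword stop = std::min(n, start + (uword)batch);
      uvec bi(stop - start);
      for (uword k = start; k < stop; ++k) bi[k - start] = idx[k];
      mat A0 = X.rows(bi);
      vec yb = y.elem(bi);
      vec wb = w.elem(bi);
      double nb = (double)bi.n_elem;

      // forward, caching pre-activations
      std::vector<mat> Z(L), A(L + 1);
      A[0] = A0;
      for (size_t l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l].t();
        A[l + 1] = (l + 1 == L) ? Z[l] : leaky(Z[l], slope);
      }
      vec err = A[L].col(0) - yb;
      if (!err.is_finite()) Rcpp::stop("non-finite loss at epoch %d", epoch);

      // backward: weighted MSE gradient
      mat delta = (2.0 / nb) * (err % wb);
      for (size_t l = L; l-- > 0;) {
        mat gW = A[l].t() * delta;
        vec gb = sum(delta, 0).t();
        gW += 2.0 * l2 * W[l] + l1 * sign(W[l]);
        if (l > 0) delta = (delta * W[l].t()) % leaky_grad(Z[l - 1], slope);
        ++t_adam;
        double c1 = 1.0 - std::pow(beta1, (double)t_adam);
        double c2 = 1.0 - std::pow(beta2, (double)t_adam);
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * square(gW);
        W[l] -= lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * square(gb);
        b[l] -= lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + eps);
      }
    }

    double train_rmse = std::sqrt(mean(square(forward_all(X, W, b, slope) - y)));
    double val_rmse = std::sqrt(mean(square(forward_all(Xval, W, b, slope) - yval)));
    h_epoch.push_back(epoch); h_lr.push_back(lr);
    h_train.push_back(train_rmse); h_val.push_back(val_rmse);

    if (val_rmse < best_val - min_delta) {
      best_val = val_rmse; best_epoch = epoch;
      bestW = W; bestb = b;
      lr_wait = 0; es_wait = 0;
    } else {
      ++lr_wait; ++es_wait;
      if (lr_wait >= lr_patience) {
        lr = std::max(lr / 2.0, lr_floor);
        lr_wait = 0;
      }
      if (es_wait >= es_patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) { Wout[l] = bestW[l]; bout[l] = bestb[l]; }
  mat hist(h_epoch.size(), 4);
  for (size_t i = 0; i < h_epoch.size(); ++i) {
    hist(i, 0) = h_epoch[i]; hist(i, 1) = h_lr[i];
    hist(i, 2) = h_train[i]; hist(i, 3) = h_val[i];
  }
  return List::create(Named("W") = Wout, Named("b") = bout,
                      Named("history") = hist,
                      Named("best_epoch") = best_epoch,
                      Named("best_val_rmse") = best_val);
}
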