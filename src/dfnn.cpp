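// Minibatch trainer for the feedforward pair-similarity network.
// The R side owns the validation split, Glorot initialization, and the seed;
// all randomness here (epoch shuffling) goes through R's RNG so a single
// set.seed() reproduces training exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double bce(const arma::vec& p, const arma::vec& y) {
  arma::vec q = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  return -arma::mean(y % arma::log(q) + (1.0 - y) % arma::log(1.0 - q));
}

// forward through ReLU hidden layers + sigmoid output; fills activations
static arma::vec forward(const arma::mat& X,
                         const std::vector<arma::mat>& W,
                         const std::vector<arma::vec>& b,
                         std::vector<arma::mat>& acts) {
  const size_t L = W.size();          // layers including output
  arma::mat H = X;
  for (size_t l = 0; l + 1 < L; ++l) {
    H = H * W[l];
    H.each_row() += b[l].t();
    H.transform([](double v) { return v > 0.0 ? v : 0.0; });
    acts[l] = H;
  }
  arma::vec logits = H * W[L - 1] + b[L - 1](0);
  logits = arma::clamp(logits, -30.0, 30.0);
  return 1.0 / (1.0 + arma::exp(-logits));
}

static arma::vec forward_nograd(const arma::mat& X,
                                const std::vector<arma::mat>& W,
                                const std::vector<arma::vec>& b) {
  std::vector<arma::mat> acts(W.size() > 0 ? W.size() - 1 : 0);
  return forward(X, W, b, acts);
}

// [[Rcpp::export(name = ".dfnn_fit")]]
List dfnn_fit(const arma::mat& Ztr, const arma::vec& ytr,
              const arma::mat& Zval, const arma::vec& yval,
              List init_weights, List init_biases,
              double lr, int batch_size, int max_epochs, int patience) {
  const size_t L = init_weights.size();
  std::vector<arma::mat> W(L);
  std::vector<arma::vec> b(L);
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::vec> mB(L), vB(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(init_weights[l]);
    b[l] = as<arma::vec>(init_biases[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mB[l].zeros(b[l].n_elem);
    vB[l].zeros(b[l].n_elem);
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-7;
  const int n = Ztr.n_rows;
  std::vector<double> log_train, log_val;
  double best_val = arma::datum::inf;
  int stalled = 0, stopped = max_epochs;
  long t_step = 0;
  std::vector<arma::mat> acts(L - 1);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // shuffle through R's RNG for reproducibility under set.seed()
    IntegerVector ord_r = sample(n, n, false);
    arma::uvec ord(n);
    for (int i = 0; i < n; ++i) ord[i] = ord_r[i] - 1;
    double epoch_loss = 0.0;

    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n) - 1;
      arma::uvec idx = ord.subvec(start, end);
      arma::mat Xb = Ztr.rows(idx);
      arma::vec yb = ytr.elem(idx);
      const double nb = static_cast<double>(idx.n_elem);

      arma::vec p = forward(Xb, W, b, acts);
      epoch_loss += bce(p, yb) * nb;     // running (pre-update) training loss
      arma::mat delta = (p - yb) / nb;   // dL/dlogit for sigmoid + BCE

      ++t_step;
      const double c1 = 1.0 - std::pow(beta1, (double)t_step);
      const double c2 = 1.0 - std::pow(beta2, (double)t_step);

      for (int l = (int)L - 1; l >= 0; --l) {
        const arma::mat& A_prev = (l == 0) ? Xb : acts[l - 1];
        arma::mat gW = A_prev.t() * delta;
        arma::vec gB = arma::sum(delta, 0).t();
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<arma::mat>::from(acts[l - 1] > 0.0);
        }
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * (gW % gW);
        W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        mB[l] = beta1 * mB[l] + (1.0 - beta1) * gB;
        vB[l] = beta2 * vB[l] + (1.0 - beta2) * (gB % gB);
        b[l] -= lr * (mB[l] / c1) / (arma::sqrt(vB[l] / c2) + eps);
      }
    }

    log_train.push_back(epoch_loss / n);
    double vloss = bce(forward_nograd(Zval, W, b), yval);
    log_val.push_back(vloss);
    stopped = epoch;
    if (vloss < best_val) {
      best_val = vloss;
      stalled = 0;
    } else if (++stalled >= patience) {
      break;
    }
  }

  List out_w(L), out_b(L);
  for (size_t l = 0; l < L; ++l) {
    out_w[l] = W[l];
    out_b[l] = NumericVector(b[l].begin(), b[l].end());
  }
  return List::create(_["weights"] = out_w, _["biases"] = out_b,
                      _["train_loss"] = log_train, _["val_loss"] = log_val,
                      _["stopped_epoch"] = stopped);
}
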