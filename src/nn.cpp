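#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

// Compact fully connected classifier: input -> (width ReLU) x depth ->
// n_class softmax, trained with Adam on the cross-entropy of integer
// class labels. Single-threaded and deterministic given `seed`.

namespace {

struct Net {
  std::vector<arma::mat> W; // W[l]: in x out
  std::vector<arma::rowvec> b;
};

Net init_net(int n_in, int depth, int width, int n_class, std::mt19937& rng) {
  Net net;
  std::vector<int> sizes;
  sizes.push_back(n_in);
  for (int l = 0; l < depth; ++l) sizes.push_back(width);
  sizes.push_back(n_class);
  std::normal_distribution<double> gauss(0.0, 1.0);
  for (size_t l = 0; l + 1 < sizes.size(); ++l) {
    arma::mat W(sizes[l], sizes[l + 1]);
    const double sd = std::sqrt(2.0 / sizes[l]); // He scaling for ReLU
    for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = sd * gauss(rng);
    net.W.push_back(W);
    net.b.push_back(arma::rowvec(sizes[l + 1], arma::fill::zeros));
  }
  return net;
}

// Forward pass; fills per-layer activations (A[0] = X) and returns
// row-normalized softmax probabilities.
arma::mat forward(const Net& net, const arma::mat& X,
                  std::vector<arma::mat>* acts) {
  const size_t L = net.W.size();
  arma::mat A = X;
  if (acts) acts->push_back(A);
  for (size_t l = 0; l < L; ++l) {
    arma::mat Z = A * net.W[l];
    Z.each_row() += net.b[l];
    if (l + 1 < L) {
      A = arma::clamp(Z, 0.0, arma::datum::inf); // ReLU
      if (acts) acts->push_back(A);
    } else {
      Z.each_col() -= arma::max(Z, 1);
      arma::mat P = arma::exp(Z);
      P.each_col() /= arma::sum(P, 1);
      return P;
    }
  }
  return A; // unreachable
}

} // namespace

// [[Rcpp::export]]
List nn_train_cpp(const arma::mat& X, const arma::ivec& y, int depth,
                  int width, int n_class, int epochs, double lr,
                  int batch_size, int seed) {
  const int n = X.n_rows;
  std::mt19937 rng(static_cast<unsigned>(seed));
  Net net = init_net(X.n_cols, depth, width, n_class, rng);
  const size_t L = net.W.size();

  // Adam state
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    vW[l] = mW[l];
    mb[l].zeros(net.b[l].n_elem);
    vb[l] = mb[l];
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-7;
  long step = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  arma::vec epoch_loss(epochs, arma::fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    long loss_n = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int bend = std::min(start + batch_size, n);
      const int bs = bend - start;
      arma::uvec idx(bs);
      for (int i = 0; i < bs; ++i) idx[i] = order[start + i];
      arma::mat Xb = X.rows(idx);

      std::vector<arma::mat> acts;
      acts.reserve(L);
      arma::mat P = forward(net, Xb, &acts);

      // cross-entropy and output delta
      arma::mat delta = P;
      for (int i = 0; i < bs; ++i) {
        const int cls = y[idx[i]];
        loss_sum += -std::log(std::max(P(i, cls), 1e-300));
        delta(i, cls) -= 1.0;
      }
      loss_n += bs;
      delta /= bs;

      ++step;
      const double corr =
          lr * std::sqrt(1.0 - std::pow(beta2, step)) / (1.0 - std::pow(beta1, step));
      // backprop, updating layer by layer from the top
      for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
        arma::mat gW = acts[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * net.W[l].t();
          delta %= arma::conv_to<arma::mat>::from(acts[l] > 0.0);
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW);
        net.W[l] -= corr * mW[l] / (arma::sqrt(vW[l]) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb);
        net.b[l] -= corr * mb[l] / (arma::sqrt(vb[l]) + eps);
      }
    }
    epoch_loss[ep] = loss_sum / std::max<long>(loss_n, 1);
    Rcpp::checkUserInterrupt();
  }

  List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = net.W[l];
    bl[l] = arma::vec(net.b[l].t());
  }
  return List::create(_["weights"] = Wl, _["biases"] = bl,
                      _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
arma::mat nn_predict_cpp(const List& weights, const List& biases,
                         const arma::mat& X) {
  Net net;
  const int L = weights.size();
  for (int l = 0; l < L; ++l) {
    net.W.push_back(as<arma::mat>(weights[l]));
    arma::vec b = as<arma::vec>(biases[l]);
    net.b.push_back(b.t());
  }
  return forward(net, X, nullptr);
}
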