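// Minimal fully connected network trainer: ReLU hidden layers, Adam,
// softmax cross-entropy (classifier) or linear output + MSE (autoencoder).
// All randomness (weight init, epoch shuffling) comes from a std::mt19937
// seeded explicitly, so a (data, architecture, config, seed) tuple maps to
// one deterministic set of trained parameters on a single CPU thread.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct AdamState {
  arma::mat mW, vW;
  arma::rowvec mb, vb;
};

inline arma::mat relu(const arma::mat& z) { return arma::clamp(z, 0.0, arma::datum::inf); }

// Row-wise softmax with max-subtraction for stability.
inline arma::mat softmax_rows(const arma::mat& z) {
  arma::mat s = z;
  s.each_col() -= arma::max(z, 1);
  s = arma::exp(s);
  arma::vec rs = arma::sum(s, 1);
  s.each_col() /= rs;
  return s;
}

} // namespace

// Train a feed-forward net and return predictions on a held-out matrix.
// layer_sizes gives every width including input and output, e.g.
// c(784, 64, 32, 16, 10) or the mirrored autoencoder stack.
// [[Rcpp::export]]
Rcpp::List cpp_train_mlp(const arma::mat& x_train,
                         const arma::mat& t_train,
                         const arma::mat& x_test,
                         const arma::ivec& layer_sizes,
                         const bool softmax_out,
                         const int epochs,
                         const int batch_size,
                         const double lr,
                         const int seed,
                         const arma::mat& x_val,
                         const arma::mat& t_val,
                         const int patience) {
  const arma::uword n = x_train.n_rows;
  const arma::uword n_layers = layer_sizes.n_elem - 1;
  if (n_layers < 1) stop("need at least one layer");
  if (x_train.n_cols != static_cast<arma::uword>(layer_sizes[0]))
    stop("x_train has %d columns but the input layer expects %d",
         (int)x_train.n_cols, (int)layer_sizes[0]);
  if (t_train.n_cols != static_cast<arma::uword>(layer_sizes[n_layers]))
    stop("t_train width does not match the output layer");

  std::mt19937 rng(static_cast<unsigned int>(seed));

  // Standard linear-layer initialisation of the major deep-learning
  // frameworks: W, b ~ U(-1/sqrt(fan_in), 1/sqrt(fan_in)). The small scale
  // matters scientifically: an untrained network outputs near zero, so on
  // standardised data its reconstruction loss starts at the variance
  // baseline, and under a fixed epoch budget the loss curve stays at that
  // baseline until the sample size supplies enough gradient signal.
  std::vector<arma::mat> W(n_layers);
  std::vector<arma::rowvec> b(n_layers);
  std::vector<AdamState> opt(n_layers);
  for (arma::uword l = 0; l < n_layers; ++l) {
    const arma::uword din = layer_sizes[l], dout = layer_sizes[l + 1];
    const double k = 1.0 / std::sqrt(static_cast<double>(din));
    std::uniform_real_distribution<double> unif(-k, k);
    W[l].set_size(din, dout);
    // column-major fill in a fixed order keeps init reproducible
    for (arma::uword j = 0; j < dout; ++j)
      for (arma::uword i = 0; i < din; ++i) W[l](i, j) = unif(rng);
    b[l].set_size(dout);
    for (arma::uword j = 0; j < dout; ++j) b[l](j) = unif(rng);
    opt[l].mW.zeros(din, dout); opt[l].vW.zeros(din, dout);
    opt[l].mb.zeros(dout);      opt[l].vb.zeros(dout);
  }

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  const arma::uword bs = std::min<arma::uword>(std::max(batch_size, 1), n);
  std::vector<arma::mat> act(n_layers + 1), zs(n_layers);

  // forward pass through the current weights (shared by val and test eval)
  auto forward = [&](const arma::mat& x) {
    arma::mat h = x;
    for (arma::uword l = 0; l < n_layers; ++l) {
      h = h * W[l];
      h.each_row() += b[l];
      if (l + 1 < n_layers) h = relu(h);
    }
    return h;
  };
  auto eval_loss = [&](const arma::mat& x, const arma::mat& tt) {
    arma::mat out = forward(x);
    if (softmax_out) {
      out = softmax_rows(out);
      return -arma::accu(tt % arma::log(out + 1e-12)) /
             static_cast<double>(x.n_rows);
    }
    return arma::accu(arma::square(out - tt)) /
           static_cast<double>(out.n_elem);
  };

  const bool early_stop = patience > 0 && x_val.n_rows > 0;
  double best_val = arma::datum::inf;
  int stall = 0;
  std::vector<arma::mat> bestW = W;
  std::vector<arma::rowvec> bestb = b;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (arma::uword start = 0; start < n; start += bs) {
      const arma::uword stop_ = std::min(start + bs, n);
      arma::uvec idx(stop_ - start);
      for (arma::uword i = start; i < stop_; ++i) idx[i - start] = order[i];
      const double B = static_cast<double>(idx.n_elem);

      act[0] = x_train.rows(idx);
      for (arma::uword l = 0; l < n_layers; ++l) {
        zs[l] = act[l] * W[l];
        zs[l].each_row() += b[l];
        act[l + 1] = (l + 1 < n_layers) ? relu(zs[l]) : zs[l];
      }

      arma::mat target = t_train.rows(idx);
      arma::mat delta; // dLoss/dZ at the output layer
      if (softmax_out) {
        delta = (softmax_rows(act[n_layers]) - target) / B;
      } else {
        delta = 2.0 * (act[n_layers] - target) /
                (B * static_cast<double>(act[n_layers].n_cols));
      }

      ++t;
      const double bc1 = 1.0 - std::pow(beta1, t);
      const double bc2 = 1.0 - std::pow(beta2, t);
      for (arma::uword l = n_layers; l-- > 0;) {
        arma::mat gW = act[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<arma::mat>::from(zs[l - 1] > 0.0);
        }
        AdamState& s = opt[l];
        s.mW = beta1 * s.mW + (1.0 - beta1) * gW;
        s.vW = beta2 * s.vW + (1.0 - beta2) * arma::square(gW);
        s.mb = beta1 * s.mb + (1.0 - beta1) * gb;
        s.vb = beta2 * s.vb + (1.0 - beta2) * arma::square(gb);
        W[l] -= lr * (s.mW / bc1) / (arma::sqrt(s.vW / bc2) + eps);
        b[l] -= lr * (s.mb / bc1) / (arma::sqrt(s.vb / bc2) + eps);
      }
    }

    if (early_stop) {
      const double vl = eval_loss(x_val, t_val);
      if (vl < best_val) {
        best_val = vl; stall = 0; bestW = W; bestb = b;
      } else if (++stall >= patience) {
        break;
      }
    }
  }
  if (early_stop && arma::is_finite(best_val)) { W = bestW; b = bestb; }

  arma::mat out = forward(x_test);
  if (softmax_out) out = softmax_rows(out);

  long n_par = 0;
  for (arma::uword l = 0; l < n_layers; ++l)
    n_par += static_cast<long>(layer_sizes[l]) * layer_sizes[l + 1] + layer_sizes[l + 1];

  return List::create(_["predictions"] = out, _["n_parameters"] = n_par);
}
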