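// Minibatch training loop for the feedforward encoder/fusion networks:
// ReLU hidden layers, softmax output, categorical cross-entropy, Adam.
// All randomness (initial weights, batch permutations) is drawn on the R
// side, so the loop is fully deterministic in its inputs. The loop runs in
// single precision: gradient noise from minibatching dwarfs float rounding,
// and the halved memory traffic roughly doubles throughput.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::fmat softmax_rows(const arma::fmat& z) {
  arma::fmat s = z.each_col() - arma::max(z, 1);
  s = arma::exp(s);
  arma::fvec rs = arma::sum(s, 1);
  s.each_col() /= rs;
  return s;
}

// [[Rcpp::export(name = ".cpp_mlp_train")]]
List cpp_mlp_train(List W0, List b0, const arma::mat& X, const arma::mat& Y,
                   const arma::imat& perms, int batch_size,
                   double lr, double beta1, double beta2) {
  const int L = W0.size();
  const int n = X.n_rows;
  const int epochs = perms.n_rows;
  const float eps = 1e-8f;
  const float b1 = (float)beta1, b2 = (float)beta2, alpha = (float)lr;

  arma::fmat Xf = arma::conv_to<arma::fmat>::from(X);
  arma::fmat Yf = arma::conv_to<arma::fmat>::from(Y);

  std::vector<arma::fmat> W(L), mW(L), vW(L);
  std::vector<arma::frowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = arma::conv_to<arma::fmat>::from(as<arma::mat>(W0[l]));
    b[l] = arma::conv_to<arma::frowvec>::from(as<arma::vec>(b0[l]));
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }

  arma::vec losses(epochs, arma::fill::zeros);
  long t = 0;
  std::vector<arma::fmat> acts(L + 1);

  for (int ep = 0; ep < epochs; ++ep) {
    float ep_loss = 0.0f;
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(s + batch_size, n) - 1;
      arma::uvec idx(e - s + 1);
      for (int k = s; k <= e; ++k) idx[k - s] = (arma::uword)(perms(ep, k) - 1);
      const int nb = idx.n_elem;

      acts[0] = Xf.rows(idx);
      for (int l = 0; l < L - 1; ++l) {
        arma::fmat z = acts[l] * W[l];
        z.each_row() += b[l];
        acts[l + 1] = arma::clamp(z, 0.0f, arma::datum::inf);
      }
      arma::fmat zout = acts[L - 1] * W[L - 1];
      zout.each_row() += b[L - 1];
      arma::fmat P = softmax_rows(zout);

      arma::fmat Yb = Yf.rows(idx);
      ep_loss += -arma::accu(Yb % arma::log(arma::clamp(P, 1e-12f, 1.0f)));

      arma::fmat delta = (P - Yb) / (float)nb;
      ++t;
      // bias-corrected step size folded into alpha_t (standard reformulation)
      const float bc1 = 1.0f - std::pow(b1, (float)t);
      const float bc2 = 1.0f - std::pow(b2, (float)t);
      const float alpha_t = alpha * std::sqrt(bc2) / bc1;
      const float eps_t = eps * std::sqrt(bc2);
      for (int l = L - 1; l >= 0; --l) {
        arma::fmat gW = acts[l].t() * delta;
        arma::frowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta.elem(arma::find(acts[l] <= 0.0f)).zeros();
        }
        mW[l] = b1 * mW[l] + (1.0f - b1) * gW;
        vW[l] = b2 * vW[l] + (1.0f - b2) * arma::square(gW);
        W[l] -= alpha_t * mW[l] / (arma::sqrt(vW[l]) + eps_t);
        mb[l] = b1 * mb[l] + (1.0f - b1) * gb;
        vb[l] = b2 * vb[l] + (1.0f - b2) * arma::square(gb);
        b[l] -= alpha_t * mb[l] / (arma::sqrt(vb[l]) + eps_t);
      }
    }
    losses[ep] = ep_loss / n;
  }

  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = arma::conv_to<arma::mat>::from(W[l]);
    bout[l] = arma::conv_to<arma::vec>::from(b[l].t());
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["loss_history"] = losses);
}
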