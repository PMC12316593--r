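// Small hybrid 1-D convolutional network for 4-s window noise classification.
//
// Fixed architecture (valid convolutions, ceil-mode max pooling so the second
// pool stays non-degenerate on 1000-sample inputs):
//   input 1000 -> conv(16 filters, length 500) -> ReLU -> maxpool 2  -> 251x16
//             -> conv(32 filters, length 250) -> ReLU -> maxpool 2  ->   1x32
//   concat(32 conv features, n_hand hand-engineered quality features)
//             -> dense 32 ReLU -> dense 1 sigmoid
// Trained with minibatch Adam on binary cross-entropy. Randomness (weight
// init, shuffling) comes from R's RNG.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Net {
  arma::mat W1, W2, W3, W4;
  arma::rowvec b1, b2, b3;
  double b4;
  int l1, l2;  // filter lengths
};

Net net_from_list(const List &w) {
  Net nt;
  nt.W1 = as<arma::mat>(w["W1"]); nt.W2 = as<arma::mat>(w["W2"]);
  nt.W3 = as<arma::mat>(w["W3"]); nt.W4 = as<arma::mat>(w["W4"]);
  nt.b1 = as<arma::rowvec>(w["b1"]); nt.b2 = as<arma::rowvec>(w["b2"]);
  nt.b3 = as<arma::rowvec>(w["b3"]); nt.b4 = as<double>(w["b4"]);
  nt.l1 = as<int>(w["l1"]); nt.l2 = as<int>(w["l2"]);
  return nt;
}

inline int ceil_half(int n) { return (n + 1) / 2; }

arma::mat im2col(const arma::vec &x, int len) {
  const int n = (int)x.n_elem - len + 1;
  arma::mat A(n, len);
  for (int i = 0; i < n; ++i)
    A.row(i) = x.subvec(i, i + len - 1).t();
  return A;
}

// stack sliding windows of rows of P (m x k) -> (m-len+1) x (len*k)
arma::mat im2col_rows(const arma::mat &P, int len) {
  const int n = (int)P.n_rows - len + 1;
  arma::mat B(n, len * P.n_cols);
  for (int i = 0; i < n; ++i) {
    arma::mat blk = P.rows(i, i + len - 1);
    B.row(i) = arma::vectorise(blk).t();  // column-major: channel blocks
  }
  return B;
}

void maxpool(const arma::mat &Z, arma::mat &P, arma::umat &idx) {
  const int m = ceil_half((int)Z.n_rows);
  P.set_size(m, Z.n_cols);
  idx.set_size(m, Z.n_cols);
  for (int j = 0; j < (int)Z.n_cols; ++j) {
    for (int i = 0; i < m; ++i) {
      const int a = 2 * i;
      const int b = std::min(a + 1, (int)Z.n_rows - 1);
      if (Z(a, j) >= Z(b, j)) { P(i, j) = Z(a, j); idx(i, j) = a; }
      else                    { P(i, j) = Z(b, j); idx(i, j) = b; }
    }
  }
}

struct Fwd {
  arma::mat A, Z1, P1, B, Z2, P2;
  arma::umat i1, i2;
  arma::rowvec f, Z3, R3;
  double z4, p;
};

void forward(const Net &nt, const arma::vec &x, const arma::rowvec &h, Fwd &F) {
  F.A = im2col(x, nt.l1);
  F.Z1 = F.A * nt.W1;
  F.Z1.each_row() += nt.b1;
  arma::mat R1 = arma::clamp(F.Z1, 0.0, arma::datum::inf);
  maxpool(R1, F.P1, F.i1);
  F.B = im2col_rows(F.P1, nt.l2);
  F.Z2 = F.B * nt.W2;
  F.Z2.each_row() += nt.b2;
  arma::mat R2 = arma::clamp(F.Z2, 0.0, arma::datum::inf);
  maxpool(R2, F.P2, F.i2);
  F.f = arma::join_rows(arma::vectorise(F.P2).t(), h);
  F.Z3 = F.f * nt.W3 + nt.b3;
  F.R3 = arma::clamp(F.Z3, 0.0, arma::datum::inf);
  F.z4 = arma::as_scalar(F.R3 * nt.W4) + nt.b4;
  F.p = 1.0 / (1.0 + std::exp(-F.z4));
}

struct Grad {
  arma::mat W1, W2, W3, W4;
  arma::rowvec b1, b2, b3;
  double b4;
  void zero(const Net &nt) {
    W1.zeros(arma::size(nt.W1)); W2.zeros(arma::size(nt.W2));
    W3.zeros(arma::size(nt.W3)); W4.zeros(arma::size(nt.W4));
    b1.zeros(nt.b1.n_elem); b2.zeros(nt.b2.n_elem); b3.zeros(nt.b3.n_elem);
    b4 = 0.0;
  }
};

void backward(const Net &nt, const Fwd &F, double y, Grad &G) {
  const double dz4 = F.p - y;
  G.W4 += F.R3.t() * dz4;
  G.b4 += dz4;
  arma::rowvec dR3 = dz4 * nt.W4.t();
  arma::rowvec dZ3 = dR3 % arma::conv_to<arma::rowvec>::from(F.Z3 > 0);
  G.W3 += F.f.t() * dZ3;
  G.b3 += dZ3;
  arma::rowvec df = dZ3 * nt.W3.t();
  const int k2 = (int)F.P2.n_cols;
  // conv-feature part of df (P2 has a single pooled row)
  arma::mat dP2(arma::size(F.P2), arma::fill::zeros);
  for (int j = 0; j < k2; ++j) dP2(0, j) = df[j];
  arma::mat dR2(arma::size(F.Z2), arma::fill::zeros);
  for (int j = 0; j < k2; ++j)
    for (int i = 0; i < (int)F.P2.n_rows; ++i)
      dR2(F.i2(i, j), j) += dP2(i, j);
  arma::mat dZ2 = dR2 % arma::conv_to<arma::mat>::from(F.Z2 > 0);
  G.W2 += F.B.t() * dZ2;
  G.b2 += arma::sum(dZ2, 0);
  arma::mat dB = dZ2 * nt.W2.t();  // n2 x (l2*k1)
  arma::mat dP1(arma::size(F.P1), arma::fill::zeros);
  const int k1 = (int)F.P1.n_cols;
  for (int w = 0; w < (int)dB.n_rows; ++w)
    for (int j = 0; j < k1; ++j)
      for (int r = 0; r < nt.l2; ++r)
        dP1(w + r, j) += dB(w, j * nt.l2 + r);
  arma::mat dR1(arma::size(F.Z1), arma::fill::zeros);
  for (int j = 0; j < k1; ++j)
    for (int i = 0; i < (int)F.P1.n_rows; ++i)
      dR1(F.i1(i, j), j) += dP1(i, j);
  arma::mat dZ1 = dR1 % arma::conv_to<arma::mat>::from(F.Z1 > 0);
  G.W1 += F.A.t() * dZ1;
  G.b1 += arma::sum(dZ1, 0);
}

struct Adam {
  arma::mat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4;
  arma::rowvec mb1, vb1, mb2, vb2, mb3, vb3;
  double mb4 = 0.0, vb4 = 0.0;
  long t = 0;
  void init(const Net &nt) {
    mW1.zeros(arma::size(nt.W1)); vW1.zeros(arma::size(nt.W1));
    mW2.zeros(arma::size(nt.W2)); vW2.zeros(arma::size(nt.W2));
    mW3.zeros(arma::size(nt.W3)); vW3.zeros(arma::size(nt.W3));
    mW4.zeros(arma::size(nt.W4)); vW4.zeros(arma::size(nt.W4));
    mb1.zeros(nt.b1.n_elem); vb1.zeros(nt.b1.n_elem);
    mb2.zeros(nt.b2.n_elem); vb2.zeros(nt.b2.n_elem);
    mb3.zeros(nt.b3.n_elem); vb3.zeros(nt.b3.n_elem);
  }
};

template <class M>
void adam_step(M &w, M &m, M &v, const M &g, double lr, double bc1,
               double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + 1e-8);
}

void adam_scalar(double &w, double &m, double &v, double g, double lr,
                 double bc1, double bc2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * g * g;
  w -= lr * (m / bc1) / (std::sqrt(v / bc2) + 1e-8);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_convnet_init")]]
List cpp_convnet_init(int input_len, int n_hand, int k1, int l1, int k2,
                      int l2, int fc) {
  RNGScope scope;
  const int n1 = input_len - l1 + 1;
  if (n1 < 1) stop("input shorter than first conv filter");
  const int m1 = ceil_half(n1);
  const int n2 = m1 - l2 + 1;
  if (n2 < 1) stop("pooled map shorter than second conv filter");
  const int m2 = ceil_half(n2);
  const int n_feat = m2 * k2 + n_hand;
  auto he = [](int rows, int cols, int fan_in) {
    arma::mat W(rows, cols);
    const double s = std::sqrt(2.0 / fan_in);
    for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = norm_rand() * s;
    return W;
  };
  if (m2 != 1)
    stop("architecture expects a single pooled row after the second conv");
  return List::create(
      _["W1"] = he(l1, k1, l1), _["b1"] = arma::rowvec(k1, arma::fill::zeros),
      _["W2"] = he(l2 * k1, k2, l2 * k1),
      _["b2"] = arma::rowvec(k2, arma::fill::zeros),
      _["W3"] = he(n_feat, fc, n_feat),
      _["b3"] = arma::rowvec(fc, arma::fill::zeros),
      _["W4"] = he(fc, 1, fc), _["b4"] = 0.0, _["l1"] = l1, _["l2"] = l2);
}

// [[Rcpp::export(name = ".cpp_convnet_train")]]
List cpp_convnet_train(List weights, const arma::mat &X, const arma::mat &H,
                       const arma::vec &y, int epochs, int batch, double lr) {
  RNGScope scope;
  Net nt = net_from_list(weights);
  Adam ad;
  ad.init(nt);
  const int n = (int)X.n_rows;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  Fwd F;
  Grad G;
  arma::vec loss_hist(epochs);
  for (int e = 0; e < epochs; ++e) {
    for (int i = n - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(ord[i], ord[k]);
    }
    double ep_loss = 0.0;
    for (int b0 = 0; b0 < n; b0 += batch) {
      const int b1 = std::min(b0 + batch, n);
      G.zero(nt);
      for (int i = b0; i < b1; ++i) {
        const int r = ord[i];
        forward(nt, X.row(r).t(), H.row(r), F);
        const double p = std::min(std::max(F.p, 1e-12), 1.0 - 1e-12);
        ep_loss += -(y[r] * std::log(p) + (1.0 - y[r]) * std::log(1.0 - p));
        backward(nt, F, y[r], G);
      }
      const double bs = b1 - b0;
      ad.t += 1;
      const double bc1 = 1.0 - std::pow(0.9, (double)ad.t);
      const double bc2 = 1.0 - std::pow(0.999, (double)ad.t);
      adam_step(nt.W1, ad.mW1, ad.vW1, arma::mat(G.W1 / bs), lr, bc1, bc2);
      adam_step(nt.W2, ad.mW2, ad.vW2, arma::mat(G.W2 / bs), lr, bc1, bc2);
      adam_step(nt.W3, ad.mW3, ad.vW3, arma::mat(G.W3 / bs), lr, bc1, bc2);
      adam_step(nt.W4, ad.mW4, ad.vW4, arma::mat(G.W4 / bs), lr, bc1, bc2);
      adam_step(nt.b1, ad.mb1, ad.vb1, arma::rowvec(G.b1 / bs), lr, bc1, bc2);
      adam_step(nt.b2, ad.mb2, ad.vb2, arma::rowvec(G.b2 / bs), lr, bc1, bc2);
      adam_step(nt.b3, ad.mb3, ad.vb3, arma::rowvec(G.b3 / bs), lr, bc1, bc2);
      adam_scalar(nt.b4, ad.mb4, ad.vb4, G.b4 / bs, lr, bc1, bc2);
    }
    loss_hist[e] = ep_loss / n;
  }
  return List::create(_["W1"] = nt.W1, _["b1"] = nt.b1, _["W2"] = nt.W2,
                      _["b2"] = nt.b2, _["W3"] = nt.W3, _["b3"] = nt.b3,
                      _["W4"] = nt.W4, _["b4"] = nt.b4, _["l1"] = nt.l1,
                      _["l2"] = nt.l2, _["loss"] = loss_hist);
}

// [[Rcpp::export(name = ".cpp_convnet_predict")]]
arma::vec cpp_convnet_predict(List weights, const arma::mat &X,
                              const arma::mat &H) {
  Net nt = net_from_list(weights);
  const int n = (int)X.n_rows;
  arma::vec out(n);
  Fwd F;
  for (int i = 0; i < n; ++i) {
    forward(nt, X.row(i).t(), H.row(i), F);
    out[i] = F.p;
  }
  return out;
}
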