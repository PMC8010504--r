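// LSTM layer recurrence and backpropagation-through-time.
// Gate order in the stacked weight matrices is (i, g, f, o):
//   i_t = sigmoid(Wxi x_t + Whi h_{t-1} + b_i)
//   g_t = tanh   (Wxg x_t + Whg h_{t-1} + b_g)
//   f_t = sigmoid(Wxf x_t + Whf h_{t-1} + b_f)
//   o_t = sigmoid(Wxo x_t + Who h_{t-1} + b_o)
//   c_t = f_t % c_{t-1} + i_t % g_t,  h_t = o_t % tanh(c_t)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigmoid_v(const arma::vec& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// [[Rcpp::export]]
List lstm_fwd_cpp(const arma::mat& X, const arma::mat& Wx,
                  const arma::mat& Wh, const arma::vec& b) {
  const int T = X.n_rows, H = b.n_elem / 4;
  arma::mat AX = X * Wx.t();              // T x 4H
  arma::mat Hm(T, H), Cm(T, H), Im(T, H), Gm(T, H), Fm(T, H), Om(T, H);
  arma::vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::vec a = AX.row(t).t() + Wh * h + b;
    arma::vec i = sigmoid_v(a.subvec(0, H - 1));
    arma::vec g = arma::tanh(a.subvec(H, 2 * H - 1));
    arma::vec f = sigmoid_v(a.subvec(2 * H, 3 * H - 1));
    arma::vec o = sigmoid_v(a.subvec(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    Im.row(t) = i.t(); Gm.row(t) = g.t(); Fm.row(t) = f.t();
    Om.row(t) = o.t(); Cm.row(t) = c.t(); Hm.row(t) = h.t();
  }
  return List::create(Named("H") = Hm, Named("C") = Cm, Named("I") = Im,
                      Named("G") = Gm, Named("Fg") = Fm, Named("O") = Om);
}

// [[Rcpp::export]]
List lstm_bwd_cpp(const arma::mat& X, const arma::mat& Wx,
                  const arma::mat& Wh, const arma::vec& b,
                  const arma::mat& Hm, const arma::mat& Cm,
                  const arma::mat& Im, const arma::mat& Gm,
                  const arma::mat& Fm, const arma::mat& Om,
                  const arma::mat& dH) {
  const int T = X.n_rows, H = Hm.n_cols;
  arma::mat dWx(arma::size(Wx), arma::fill::zeros);
  arma::mat dWh(arma::size(Wh), arma::fill::zeros);
  arma::vec db(4 * H, arma::fill::zeros);
  arma::mat dX(arma::size(X), arma::fill::zeros);
  arma::vec dh_rec(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::vec i = Im.row(t).t(), g = Gm.row(t).t();
    arma::vec f = Fm.row(t).t(), o = Om.row(t).t();
    arma::vec c = Cm.row(t).t();
    arma::vec c_prev = (t > 0) ? Cm.row(t - 1).t()
                               : arma::vec(H, arma::fill::zeros);
    arma::vec h_prev = (t > 0) ? Hm.row(t - 1).t()
                               : arma::vec(H, arma::fill::zeros);
    arma::vec tc = arma::tanh(c);
    arma::vec dh = dH.row(t).t() + dh_rec;
    arma::vec dc = dh % o % (1.0 - tc % tc) + dc_next;
    arma::vec da(4 * H);
    da.subvec(0, H - 1) = dc % g % i % (1.0 - i);
    da.subvec(H, 2 * H - 1) = dc % i % (1.0 - g % g);
    da.subvec(2 * H, 3 * H - 1) = dc % c_prev % f % (1.0 - f);
    da.subvec(3 * H, 4 * H - 1) = dh % tc % o % (1.0 - o);
    dc_next = dc % f;
    dWx += da * X.row(t);
    dWh += da * h_prev.t();
    db += da;
    dX.row(t) = (Wx.t() * da).t();
    dh_rec = Wh.t() * da;
  }
  return List::create(Named("dX") = dX, Named("dWx") = dWx,
                      Named("dWh") = dWh, Named("db") = db);
}
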