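// Single-layer LSTM forward/backward over scalar sequences.
// Gate order in the stacked weight matrices: input, forget, output,
// candidate. Read-out is the hidden-state mean over time or the final
// hidden state; see the R wrappers in nn-layers.R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat sigm(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// [[Rcpp::export]]
List lstm_fwd_cpp(const arma::mat& Wx, const arma::mat& Wh,
                  const arma::vec& b, const arma::mat& x, bool mean_readout) {
  const int hd = Wh.n_cols, N = x.n_rows, T = x.n_cols;
  arma::cube I(hd, N, T), F(hd, N, T), O(hd, N, T), G(hd, N, T),
             Cs(hd, N, T), Tc(hd, N, T), Hs(hd, N, T);
  arma::mat h(hd, N, arma::fill::zeros), c(hd, N, arma::fill::zeros);
  arma::mat hsum(hd, N, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat g = Wx * x.col(t).t() + Wh * h;
    g.each_col() += b;
    arma::mat i_ = sigm(g.rows(0, hd - 1));
    arma::mat f_ = sigm(g.rows(hd, 2 * hd - 1));
    arma::mat o_ = sigm(g.rows(2 * hd, 3 * hd - 1));
    arma::mat g_ = arma::tanh(g.rows(3 * hd, 4 * hd - 1));
    c = f_ % c + i_ % g_;
    arma::mat tc = arma::tanh(c);
    h = o_ % tc;
    I.slice(t) = i_; F.slice(t) = f_; O.slice(t) = o_; G.slice(t) = g_;
    Cs.slice(t) = c; Tc.slice(t) = tc; Hs.slice(t) = h;
    if (mean_readout) hsum += h;
  }
  arma::mat y = mean_readout ? arma::mat(hsum.t() / T) : arma::mat(h.t());
  return List::create(_["y"] = y, _["I"] = I, _["F"] = F, _["O"] = O,
                      _["G"] = G, _["Cs"] = Cs, _["Tc"] = Tc, _["Hs"] = Hs);
}

// [[Rcpp::export]]
List lstm_bwd_cpp(const arma::mat& Wx, const arma::mat& Wh,
                  const arma::mat& x, const arma::mat& dy,
                  const arma::cube& I, const arma::cube& F,
                  const arma::cube& O, const arma::cube& G,
                  const arma::cube& Cs, const arma::cube& Tc,
                  const arma::cube& Hs, bool mean_readout) {
  const int hd = Wh.n_cols, N = x.n_rows, T = x.n_cols;
  const int din = Wx.n_cols;
  arma::mat dyt = dy.t();
  arma::mat dh(hd, N, arma::fill::zeros), dc(hd, N, arma::fill::zeros);
  arma::mat gWx(4 * hd, din, arma::fill::zeros);
  arma::mat gWh(4 * hd, hd, arma::fill::zeros);
  arma::vec gb(4 * hd, arma::fill::zeros);
  arma::mat dx(N, T, arma::fill::zeros);
  arma::mat G4(4 * hd, N);
  for (int t = T - 1; t >= 0; --t) {
    if (mean_readout) dh += dyt / T;
    else if (t == T - 1) dh += dyt;
    const arma::mat& i_ = I.slice(t);
    const arma::mat& f_ = F.slice(t);
    const arma::mat& o_ = O.slice(t);
    const arma::mat& g_ = G.slice(t);
    const arma::mat& tc = Tc.slice(t);
    arma::mat c_prev = (t > 0) ? Cs.slice(t - 1)
                               : arma::mat(hd, N, arma::fill::zeros);
    arma::mat h_prev = (t > 0) ? Hs.slice(t - 1)
                               : arma::mat(hd, N, arma::fill::zeros);
    arma::mat do_ = dh % tc;
    dc += dh % o_ % (1.0 - tc % tc);
    arma::mat di = dc % g_;
    arma::mat dg = dc % i_;
    arma::mat df = dc % c_prev;
    dc %= f_;
    G4.rows(0, hd - 1) = di % i_ % (1.0 - i_);
    G4.rows(hd, 2 * hd - 1) = df % f_ % (1.0 - f_);
    G4.rows(2 * hd, 3 * hd - 1) = do_ % o_ % (1.0 - o_);
    G4.rows(3 * hd, 4 * hd - 1) = dg % (1.0 - g_ % g_);
    gWx += G4 * x.col(t);
    gWh += G4 * h_prev.t();
    gb += arma::sum(G4, 1);
    dx.col(t) = (Wx.t() * G4).t();
    dh = Wh.t() * G4;
  }
  return List::create(_["gWx"] = gWx, _["gWh"] = gWh, _["gb"] = gb,
                      _["dx"] = dx);
}
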