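// Fused post-norm transformer layer (multi-head self-attention + ReLU
// feed-forward, each followed by layer normalization) with an explicit
// backward pass. Only the encoder's hot loop lives here; everything else
// stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;

static void ln_fwd(const arma::mat& X, const arma::vec& g, const arma::vec& b,
                   arma::mat& Y, arma::mat& Xhat, arma::vec& inv) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat Xc = X.each_col() - mu;
  arma::vec v = arma::mean(arma::square(Xc), 1);
  inv = 1.0 / arma::sqrt(v + LN_EPS);
  Xhat = Xc.each_col() % inv;
  Y = Xhat.each_row() % g.t();
  Y.each_row() += b.t();
}

static void ln_bwd(const arma::mat& dY, const arma::mat& Xhat,
                   const arma::vec& inv, const arma::vec& g,
                   arma::mat& dX, arma::vec& dg, arma::vec& db) {
  const double D = (double) Xhat.n_cols;
  arma::mat dXhat = dY.each_row() % g.t();
  arma::vec r1 = arma::sum(dXhat, 1) / D;
  arma::vec r2 = arma::sum(dXhat % Xhat, 1) / D;
  dX = dXhat;
  dX.each_col() -= r1;
  dX -= Xhat.each_col() % r2;
  dX.each_col() %= inv;
  dg = arma::sum(dY % Xhat, 0).t();
  db = arma::sum(dY, 0).t();
}

// softmax over rows, in place
static void softmax_rows(arma::mat& S) {
  arma::vec m = arma::max(S, 1);
  S.each_col() -= m;
  S = arma::exp(S);
  arma::vec s = arma::sum(S, 1);
  S.each_col() /= s;
}

// [[Rcpp::export(name = ".cpp_enc_layer_fwd")]]
List cpp_enc_layer_fwd(const arma::mat& X,
                       const arma::mat& Wq, const arma::mat& Wk,
                       const arma::mat& Wv, const arma::mat& Wo,
                       const arma::vec& g1, const arma::vec& b1,
                       const arma::mat& W1, const arma::vec& bf1,
                       const arma::mat& W2, const arma::vec& bf2,
                       const arma::vec& g2, const arma::vec& b2,
                       int n_heads) {
  const int D = X.n_cols;
  const int dh = D / n_heads;
  const double sc = 1.0 / std::sqrt((double) dh);
  arma::mat Q = X * Wq, K = X * Wk, V = X * Wv;
  arma::mat O(X.n_rows, D);
  List Ps(n_heads);
  for (int h = 0; h < n_heads; ++h) {
    arma::span ix(h * dh, (h + 1) * dh - 1);
    arma::mat S = Q.cols(ix) * K.cols(ix).t() * sc;
    softmax_rows(S);
    O.cols(ix) = S * V.cols(ix);
    Ps[h] = S;
  }
  arma::mat A = O * Wo;
  arma::mat Y1, Xhat1; arma::vec inv1;
  ln_fwd(X + A, g1, b1, Y1, Xhat1, inv1);
  arma::mat H1 = Y1 * W1;
  H1.each_row() += bf1.t();
  H1.transform([](double x) { return x > 0 ? x : 0.0; });
  arma::mat FF = H1 * W2;
  FF.each_row() += bf2.t();
  arma::mat Y2, Xhat2; arma::vec inv2;
  ln_fwd(Y1 + FF, g2, b2, Y2, Xhat2, inv2);
  return List::create(_["Y"] = Y2, _["Q"] = Q, _["K"] = K, _["V"] = V,
                      _["O"] = O, _["P"] = Ps,
                      _["Xhat1"] = Xhat1, _["inv1"] = inv1, _["Y1"] = Y1,
                      _["H1"] = H1, _["Xhat2"] = Xhat2, _["inv2"] = inv2);
}

// [[Rcpp::export(name = ".cpp_enc_layer_bwd")]]
List cpp_enc_layer_bwd(const arma::mat& dY, const List& cache,
                       const arma::mat& X,
                       const arma::mat& Wq, const arma::mat& Wk,
                       const arma::mat& Wv, const arma::mat& Wo,
                       const arma::vec& g1,
                       const arma::mat& W1, const arma::mat& W2,
                       const arma::vec& g2,
                       int n_heads) {
  const int D = X.n_cols;
  const int dh = D / n_heads;
  const double sc = 1.0 / std::sqrt((double) dh);
  arma::mat Q = cache["Q"], K = cache["K"], V = cache["V"], O = cache["O"];
  arma::mat Xhat1 = cache["Xhat1"], Y1 = cache["Y1"], H1 = cache["H1"],
            Xhat2 = cache["Xhat2"];
  arma::vec inv1 = cache["inv1"], inv2 = cache["inv2"];
  List Ps = cache["P"];

  arma::mat dS2; arma::vec dg2, db2;
  ln_bwd(dY, Xhat2, inv2, g2, dS2, dg2, db2);   // grad wrt (Y1 + FF)
  arma::mat dFF = dS2;
  arma::vec dbf2 = arma::sum(dFF, 0).t();
  arma::mat dW2 = H1.t() * dFF;
  arma::mat dH1 = dFF * W2.t();
  dH1.elem(arma::find(H1 <= 0)).zeros();
  arma::vec dbf1 = arma::sum(dH1, 0).t();
  arma::mat dW1 = Y1.t() * dH1;
  arma::mat dY1 = dS2 + dH1 * W1.t();
  arma::mat dS1; arma::vec dg1, db1;
  ln_bwd(dY1, Xhat1, inv1, g1, dS1, dg1, db1);  // grad wrt (X + A)
  // attention backward
  arma::mat dO = dS1 * Wo.t();
  arma::mat dWo = O.t() * dS1;
  arma::mat dQ(X.n_rows, D, arma::fill::zeros), dK = dQ, dV = dQ;
  for (int h = 0; h < n_heads; ++h) {
    arma::span ix(h * dh, (h + 1) * dh - 1);
    arma::mat P = Ps[h];
    arma::mat dOh = dO.cols(ix);
    arma::mat dP = dOh * V.cols(ix).t();
    dV.cols(ix) = P.t() * dOh;
    arma::vec rs = arma::sum(dP % P, 1);
    arma::mat dS = P % (dP.each_col() - rs);
    dS *= sc;
    dQ.cols(ix) = dS * K.cols(ix);
    dK.cols(ix) = dS.t() * Q.cols(ix);
  }
  arma::mat dX = dS1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  return List::create(_["dX"] = dX,
                      _["dWq"] = X.t() * dQ, _["dWk"] = X.t() * dK,
                      _["dWv"] = X.t() * dV, _["dWo"] = dWo,
                      _["dg1"] = dg1, _["db1"] = db1,
                      _["dW1"] = dW1, _["dbf1"] = dbf1,
                      _["dW2"] = dW2, _["dbf2"] = dbf2,
                      _["dg2"] = dg2, _["db2"] = db2);
}
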