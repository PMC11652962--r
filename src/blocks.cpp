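// Compiled kernels for the pathway transformer.
//
// Token activations are (N*p) x d matrices in sample-major row order (row
// s*p + k is token k of sample s, 0-based).  Parameters are looked up by
// name in the flat parameter list shared with the R side, so the compiled
// and interpreted paths stay interchangeable; block_fwd_cpp/block_bwd_cpp
// serve the staged R path (public stage ops, relevance propagation), and
// nn_fwdbwd_cpp fuses one full training step (forward, loss, gradient)
// with all intermediate caches kept local.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LN_EPS = 1e-5;

static arma::mat ln_forward(const arma::mat& X, const arma::rowvec& g,
                            const arma::rowvec& b, arma::mat& xhat,
                            arma::vec& sd) {
  arma::vec mu = arma::mean(X, 1);
  arma::mat Xc = X.each_col() - mu;
  sd = arma::sqrt(arma::mean(Xc % Xc, 1) + LN_EPS);
  xhat = Xc.each_col() / sd;
  arma::mat Y = xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static arma::mat ln_backward(const arma::mat& dY, const arma::rowvec& g,
                             const arma::mat& xhat, const arma::vec& sd,
                             arma::rowvec& dg, arma::rowvec& db) {
  arma::mat dxhat = dY.each_row() % g;
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % xhat, 1);
  arma::mat dX = dxhat.each_col() - m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() /= sd;
  dg = arma::sum(dY % xhat, 0);
  db = arma::sum(dY, 0);
  return dX;
}

static arma::mat getm(const List& par, const std::string& nm) {
  return as<arma::mat>(par[nm]);
}
static arma::rowvec getv(const List& par, const std::string& nm) {
  return as<arma::rowvec>(par[nm]);
}

// everything block_backward needs from the forward pass
struct BlockCache {
  arma::mat Tm, X1, Q, K, V, O, attn_out, X2, X3, pre1, Phi, Hh, M, out;
  arma::mat xhat1, xhat2;
  arma::vec sd1, sd2;
  arma::cube Attn;
};

static void block_forward(const arma::mat& Tm, const List& par,
                          const std::string& pre, int N, int p, int n_heads,
                          BlockCache& c) {
  const int d = Tm.n_cols;
  const int dh = d / n_heads;
  const double scal = 1.0 / std::sqrt((double)dh);
  c.Tm = Tm;
  c.X1 = ln_forward(Tm, getv(par, pre + "ln1.g"), getv(par, pre + "ln1.b"),
                    c.xhat1, c.sd1);
  c.Q = c.X1 * getm(par, pre + "Wq"); c.Q.each_row() += getv(par, pre + "bq");
  c.K = c.X1 * getm(par, pre + "Wk"); c.K.each_row() += getv(par, pre + "bk");
  c.V = c.X1 * getm(par, pre + "Wv"); c.V.each_row() += getv(par, pre + "bv");
  c.O.set_size(N * p, d);
  c.Attn.set_size(p, p, (size_t)N * n_heads);
  for (int s = 0; s < N; ++s) {
    arma::span rs(s * p, s * p + p - 1);
    for (int h = 0; h < n_heads; ++h) {
      arma::span ch(h * dh, h * dh + dh - 1);
      arma::mat S = c.Q(rs, ch) * c.K(rs, ch).t() * scal;
      S.each_col() -= arma::max(S, 1);
      arma::mat E = arma::exp(S);
      E.each_col() /= arma::sum(E, 1);
      c.O(rs, ch) = E * c.V(rs, ch);
      c.Attn.slice((size_t)s * n_heads + h) = E;
    }
  }
  c.attn_out = c.O * getm(par, pre + "Wo");
  c.attn_out.each_row() += getv(par, pre + "bo");
  c.X2 = Tm + c.attn_out;
  c.X3 = ln_forward(c.X2, getv(par, pre + "ln2.g"), getv(par, pre + "ln2.b"),
                    c.xhat2, c.sd2);
  c.pre1 = c.X3 * getm(par, pre + "W1");
  c.pre1.each_row() += getv(par, pre + "b1");
  c.Phi = arma::normcdf(c.pre1);
  c.Hh = c.pre1 % c.Phi;          // exact GELU: x * pnorm(x)
  c.M = c.Hh * getm(par, pre + "W2");
  c.M.each_row() += getv(par, pre + "b2");
  c.out = c.X2 + c.M;
}

static arma::mat block_backward(const arma::mat& dout, const List& par,
                                const std::string& pre, const BlockCache& c,
                                int N, int p, int n_heads, List& gr) {
  const int d = dout.n_cols;
  const int dh = d / n_heads;
  const double scal = 1.0 / std::sqrt((double)dh);
  arma::mat dM = dout;
  gr[pre + "W2"] = arma::mat(c.Hh.t() * dM);
  gr[pre + "b2"] = arma::rowvec(arma::sum(dM, 0));
  arma::mat dHh = dM * getm(par, pre + "W2").t();
  arma::mat dpre1 = dHh % (c.Phi + c.pre1 % arma::normpdf(c.pre1));
  gr[pre + "W1"] = arma::mat(c.X3.t() * dpre1);
  gr[pre + "b1"] = arma::rowvec(arma::sum(dpre1, 0));
  arma::mat dX3 = dpre1 * getm(par, pre + "W1").t();
  arma::rowvec dg2, db2;
  arma::mat dX2 = ln_backward(dX3, getv(par, pre + "ln2.g"), c.xhat2, c.sd2,
                              dg2, db2);
  gr[pre + "ln2.g"] = dg2;
  gr[pre + "ln2.b"] = db2;
  dX2 += dout;
  gr[pre + "Wo"] = arma::mat(c.O.t() * dX2);
  gr[pre + "bo"] = arma::rowvec(arma::sum(dX2, 0));
  arma::mat dO = dX2 * getm(par, pre + "Wo").t();
  arma::mat dQ(N * p, d), dK(N * p, d), dV(N * p, d);
  for (int s = 0; s < N; ++s) {
    arma::span rs(s * p, s * p + p - 1);
    for (int h = 0; h < n_heads; ++h) {
      arma::span ch(h * dh, h * dh + dh - 1);
      const arma::mat& A = c.Attn.slice((size_t)s * n_heads + h);
      arma::mat dOsh = dO(rs, ch);
      arma::mat dA = dOsh * c.V(rs, ch).t();
      dV(rs, ch) = A.t() * dOsh;
      arma::vec rsum = arma::sum(dA % A, 1);
      arma::mat dS = A % (dA.each_col() - rsum);
      dQ(rs, ch) = dS * c.K(rs, ch) * scal;
      dK(rs, ch) = dS.t() * c.Q(rs, ch) * scal;
    }
  }
  gr[pre + "Wq"] = arma::mat(c.X1.t() * dQ);
  gr[pre + "bq"] = arma::rowvec(arma::sum(dQ, 0));
  gr[pre + "Wk"] = arma::mat(c.X1.t() * dK);
  gr[pre + "bk"] = arma::rowvec(arma::sum(dK, 0));
  gr[pre + "Wv"] = arma::mat(c.X1.t() * dV);
  gr[pre + "bv"] = arma::rowvec(arma::sum(dV, 0));
  arma::mat dX1 = dQ * getm(par, pre + "Wq").t() +
                  dK * getm(par, pre + "Wk").t() +
                  dV * getm(par, pre + "Wv").t();
  arma::rowvec dg1, db1;
  arma::mat dTm = ln_backward(dX1, getv(par, pre + "ln1.g"), c.xhat1, c.sd1,
                              dg1, db1);
  gr[pre + "ln1.g"] = dg1;
  gr[pre + "ln1.b"] = db1;
  return dTm + dX2;
}

// [[Rcpp::export]]
List block_fwd_cpp(const arma::mat& Tm, const List& par,
                   const std::string& pre, int N, int p, int n_heads,
                   bool keep_cache) {
  BlockCache c;
  block_forward(Tm, par, pre, N, p, n_heads, c);
  if (!keep_cache) return List::create(_["out"] = c.out);
  return List::create(
    _["out"] = c.out, _["Tm"] = c.Tm, _["X1"] = c.X1, _["Q"] = c.Q,
    _["K"] = c.K, _["V"] = c.V, _["O"] = c.O, _["attn"] = c.Attn,
    _["attn_out"] = c.attn_out, _["X2"] = c.X2, _["X3"] = c.X3,
    _["pre1"] = c.pre1, _["Phi"] = c.Phi, _["Hh"] = c.Hh, _["M"] = c.M,
    _["xhat1"] = c.xhat1, _["sd1"] = c.sd1, _["xhat2"] = c.xhat2,
    _["sd2"] = c.sd2);
}

// [[Rcpp::export]]
List block_bwd_cpp(const arma::mat& dout, const List& par,
                   const std::string& pre, const List& cache,
                   int N, int p, int n_heads) {
  BlockCache c;
  c.Tm = as<arma::mat>(cache["Tm"]);   c.X1 = as<arma::mat>(cache["X1"]);
  c.Q = as<arma::mat>(cache["Q"]);     c.K = as<arma::mat>(cache["K"]);
  c.V = as<arma::mat>(cache["V"]);     c.O = as<arma::mat>(cache["O"]);
  c.X3 = as<arma::mat>(cache["X3"]);   c.pre1 = as<arma::mat>(cache["pre1"]);
  c.Phi = as<arma::mat>(cache["Phi"]); c.Hh = as<arma::mat>(cache["Hh"]);
  c.Attn = as<arma::cube>(cache["attn"]);
  c.xhat1 = as<arma::mat>(cache["xhat1"]);
  c.xhat2 = as<arma::mat>(cache["xhat2"]);
  c.sd1 = as<arma::vec>(cache["sd1"]);
  c.sd2 = as<arma::vec>(cache["sd2"]);
  List gr;
  arma::mat dTm = block_backward(dout, par, pre, c, N, p, n_heads, gr);
  return List::create(_["dTm"] = dTm, _["gr"] = gr);
}

// One fused training step: forward pass, task loss, full gradient.
// task: 0 = masked MSE regression (Y, Mobs), 1 = cross-entropy (labels,
// 1-based).  keep_fac: per-pathway dropout scale factors (length p;
// all-ones when dropout is off).  Returns loss and the named gradient
// list; gradients of encoder columns fed by all-zero features are exact
// zeros.
// [[Rcpp::export]]
List nn_fwdbwd_cpp(const List& par, const List& A_list, const arma::mat& Y,
                   const arma::mat& Mobs, const IntegerVector& labels,
                   int task, const arma::vec& keep_fac, int d, int n_layers,
                   int n_heads, int n_head_layers, int pooling_flatten) {
  const int p = A_list.size();
  std::vector<arma::mat> A(p);
  for (int k = 0; k < p; ++k) A[k] = as<arma::mat>(A_list[k]);
  const int N = A[0].n_rows;

  // encoder
  arma::mat H0(N * p, d);
  arma::uvec tok(N);
  for (int k = 0; k < p; ++k) {
    for (int s = 0; s < N; ++s) tok(s) = (size_t)s * p + k;
    char nm[32];
    std::snprintf(nm, sizeof(nm), "enc%d.W", k + 1);
    arma::mat Hk = A[k] * getm(par, nm).t();
    std::snprintf(nm, sizeof(nm), "enc%d.b", k + 1);
    Hk.each_row() += getv(par, nm);
    H0.rows(tok) = Hk;
  }
  // pathway dropout (inverted scaling; factors shared across the batch)
  arma::vec rowfac(N * p);
  bool any_drop = false;
  for (int r = 0; r < N * p; ++r) {
    rowfac(r) = keep_fac(r % p);
    if (rowfac(r) != 1.0) any_drop = true;
  }
  arma::mat Tm = any_drop ? arma::mat(H0.each_col() % rowfac) : H0;

  std::vector<BlockCache> blocks(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    char pre[16];
    std::snprintf(pre, sizeof(pre), "blk%d.", l + 1);
    block_forward(Tm, par, pre, N, p, n_heads, blocks[l]);
    Tm = blocks[l].out;
  }
  // pooling
  arma::mat pooled;
  if (pooling_flatten) {
    pooled.set_size(N, (size_t)d * p);
    for (int s = 0; s < N; ++s)
      for (int k = 0; k < p; ++k)
        pooled(arma::span(s, s), arma::span((size_t)k * d, (size_t)k * d + d - 1)) =
          Tm.row((size_t)s * p + k);
  } else {
    pooled.zeros(N, d);
    for (int s = 0; s < N; ++s)
      pooled.row(s) = arma::mean(Tm.rows((size_t)s * p, (size_t)s * p + p - 1), 0);
  }
  // head MLP
  std::vector<arma::mat> hin(n_head_layers), hpre(n_head_layers);
  arma::mat X = pooled;
  for (int i = 0; i < n_head_layers; ++i) {
    hin[i] = X;
    char nm[32];
    std::snprintf(nm, sizeof(nm), "head%d.W", i + 1);
    arma::mat Z = X * getm(par, nm);
    std::snprintf(nm, sizeof(nm), "head%d.b", i + 1);
    Z.each_row() += getv(par, nm);
    hpre[i] = Z;
    X = (i < n_head_layers - 1) ? arma::mat(arma::clamp(Z, 0.0, arma::datum::inf)) : Z;
  }
  arma::mat out = X;

  // loss and its gradient
  double loss;
  arma::mat dout;
  if (task == 0) {
    double nobs = arma::accu(Mobs);
    arma::mat diff = (out - Y) % Mobs;
    loss = arma::accu(diff % diff) / nobs;
    dout = 2.0 * diff / nobs;
  } else {
    arma::vec mx = arma::max(out, 1);
    arma::mat E = arma::exp(out.each_col() - mx);
    arma::vec se = arma::sum(E, 1);
    arma::mat P = E.each_col() / se;
    loss = 0.0;
    for (int s = 0; s < N; ++s)
      loss += std::log(se(s)) + mx(s) - out(s, labels[s] - 1);
    loss /= N;
    dout = P;
    for (int s = 0; s < N; ++s) dout(s, labels[s] - 1) -= 1.0;
    dout /= N;
  }

  // backward
  List gr;
  arma::mat dX = dout;
  for (int i = n_head_layers - 1; i >= 0; --i) {
    if (i < n_head_layers - 1)
      dX = dX % arma::conv_to<arma::mat>::from(hpre[i] > 0);
    char nm[32];
    std::snprintf(nm, sizeof(nm), "head%d.W", i + 1);
    gr[nm] = arma::mat(hin[i].t() * dX);
    std::string wn = nm;
    std::snprintf(nm, sizeof(nm), "head%d.b", i + 1);
    gr[nm] = arma::rowvec(arma::sum(dX, 0));
    dX = dX * getm(par, wn).t();
  }
  arma::mat dTm(N * p, d);
  if (pooling_flatten) {
    for (int s = 0; s < N; ++s)
      for (int k = 0; k < p; ++k)
        dTm.row((size_t)s * p + k) =
          dX(arma::span(s, s), arma::span((size_t)k * d, (size_t)k * d + d - 1));
  } else {
    for (int s = 0; s < N; ++s)
      for (int k = 0; k < p; ++k)
        dTm.row((size_t)s * p + k) = dX.row(s) / p;
  }
  for (int l = n_layers - 1; l >= 0; --l) {
    char pre[16];
    std::snprintf(pre, sizeof(pre), "blk%d.", l + 1);
    dTm = block_backward(dTm, par, pre, blocks[l], N, p, n_heads, gr);
  }
  if (any_drop) dTm.each_col() %= rowfac;
  for (int k = 0; k < p; ++k) {
    for (int s = 0; s < N; ++s) tok(s) = (size_t)s * p + k;
    arma::mat dHk = dTm.rows(tok);
    char nm[32];
    std::snprintf(nm, sizeof(nm), "enc%d.W", k + 1);
    gr[nm] = arma::mat(dHk.t() * A[k]);
    std::snprintf(nm, sizeof(nm), "enc%d.b", k + 1);
    gr[nm] = arma::rowvec(arma::sum(dHk, 0));
  }
  return List::create(_["loss"] = loss, _["gr"] = gr);
}
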