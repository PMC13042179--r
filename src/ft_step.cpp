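// Batched forward/backward pass of the feature-tokenizer transformer
// autoencoder. Mirrors the reference R implementation in R/ft-transformer.R
// one-to-one (the test suite cross-checks both paths and finite
// differences); exists because cohort-scale training is matrix-bound.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static mat get_m(const List &p, const std::string &nm) {
  return as<mat>(p[nm]);
}
static rowvec get_rv(const List &p, const std::string &nm) {
  return as<rowvec>(as<NumericVector>(p[nm]));
}

struct LnCache { mat xhat; vec inv; };

static mat ln_fwd(const mat &X, const rowvec &g, const rowvec &b, LnCache &c) {
  vec mu = arma::mean(X, 1);
  mat xc = X.each_col() - mu;
  vec v = arma::mean(arma::square(xc), 1);
  c.inv = 1.0 / arma::sqrt(v + 1e-5);
  c.xhat = xc.each_col() % c.inv;
  mat out = c.xhat.each_row() % g;
  out.each_row() += b;
  return out;
}

static mat ln_bwd(const mat &dout, const LnCache &c, const rowvec &g,
                  rowvec &dg, rowvec &db) {
  dg = arma::sum(dout % c.xhat, 0);
  db = arma::sum(dout, 0);
  mat dxhat = dout.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % c.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= c.xhat.each_col() % m2;
  dx.each_col() %= c.inv;
  return dx;
}

static void softmax_rows_ip(mat &S) {
  vec m = arma::max(S, 1);
  S.each_col() -= m;
  S = arma::exp(S);
  vec rs = arma::sum(S, 1);
  S.each_col() /= rs;
}

// One training step on a batch: loss, latent, reconstruction, gradients.
// masks_attn / masks_ffn: per-block dropout masks (possibly empty lists).
// [[Rcpp::export]]
List cpp_ft_step(const List &p, const arma::mat &X, int n_blocks, int n_heads,
                 int d_head, const List &masks_attn, const List &masks_ffn,
                 bool want_grad) {
  const int B = X.n_rows, Fn = X.n_cols;
  const int d = n_heads * d_head;
  const int T = Fn + 1;
  const int R = B * T;
  const bool use_drop = masks_attn.size() > 0;

  mat W_tok = get_m(p, "W_tok"), B_tok = get_m(p, "B_tok");
  rowvec cls = get_rv(p, "cls");
  mat pos = get_m(p, "pos");

  mat H(R, d);
  for (int b = 0; b < B; ++b) {
    H.row(b * T) = cls;
    for (int f = 0; f < Fn; ++f) {
      H.row(b * T + 1 + f) = X(b, f) * W_tok.row(f) + B_tok.row(f);
    }
  }
  for (int b = 0; b < B; ++b) H.rows(b * T, b * T + T - 1) += pos;

  std::vector<mat> Hin(n_blocks), Qs(n_blocks), Ks(n_blocks), Vs(n_blocks),
      Os(n_blocks), H1s(n_blocks), Z1s(n_blocks), Ar(n_blocks);
  std::vector<LnCache> ln1(n_blocks), ln2(n_blocks);
  std::vector< std::vector<mat> > As(n_blocks);

  const double scale = 1.0 / std::sqrt((double)d_head);
  char buf[32];

  for (int l = 1; l <= n_blocks; ++l) {
    int li = l - 1;
    Hin[li] = H;
    snprintf(buf, 32, "Wq%d", l); mat Wq = get_m(p, buf);
    snprintf(buf, 32, "Wk%d", l); mat Wk = get_m(p, buf);
    snprintf(buf, 32, "Wv%d", l); mat Wv = get_m(p, buf);
    snprintf(buf, 32, "Wo%d", l); mat Wo = get_m(p, buf);
    snprintf(buf, 32, "bq%d", l); rowvec bq = get_rv(p, buf);
    snprintf(buf, 32, "bk%d", l); rowvec bk = get_rv(p, buf);
    snprintf(buf, 32, "bv%d", l); rowvec bv = get_rv(p, buf);
    snprintf(buf, 32, "bo%d", l); rowvec bo = get_rv(p, buf);
    mat Q = H * Wq; Q.each_row() += bq;
    mat K = H * Wk; K.each_row() += bk;
    mat V = H * Wv; V.each_row() += bv;
    mat O(R, d);
    As[li].resize(B * n_heads);
    for (int b = 0; b < B; ++b) {
      int r0 = b * T, r1 = b * T + T - 1;
      for (int h = 0; h < n_heads; ++h) {
        int c0 = h * d_head, c1 = (h + 1) * d_head - 1;
        mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scale;
        softmax_rows_ip(S);
        O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
        if (want_grad) As[li][b * n_heads + h] = std::move(S);
      }
    }
    mat AO = O * Wo; AO.each_row() += bo;
    if (use_drop) AO %= as<mat>(masks_attn[li]);
    mat R1 = H + AO;
    mat H1;
    {
      snprintf(buf, 32, "g1_%d", l); rowvec g1 = get_rv(p, buf);
      snprintf(buf, 32, "b1_%d", l); rowvec b1 = get_rv(p, buf);
      H1 = ln_fwd(R1, g1, b1, ln1[li]);
    }
    snprintf(buf, 32, "W1_%d", l); mat W1 = get_m(p, buf);
    snprintf(buf, 32, "bf1_%d", l); rowvec bf1 = get_rv(p, buf);
    mat Z1 = H1 * W1; Z1.each_row() += bf1;
    mat Arelu = arma::clamp(Z1, 0.0, arma::datum::inf);
    snprintf(buf, 32, "W2_%d", l); mat W2 = get_m(p, buf);
    snprintf(buf, 32, "bf2_%d", l); rowvec bf2 = get_rv(p, buf);
    mat FF = Arelu * W2; FF.each_row() += bf2;
    if (use_drop) FF %= as<mat>(masks_ffn[li]);
    mat R2 = H1 + FF;
    {
      snprintf(buf, 32, "g2_%d", l); rowvec g2 = get_rv(p, buf);
      snprintf(buf, 32, "b2_%d", l); rowvec b2 = get_rv(p, buf);
      H = ln_fwd(R2, g2, b2, ln2[li]);
    }
    Qs[li] = std::move(Q); Ks[li] = std::move(K); Vs[li] = std::move(V);
    Os[li] = std::move(O); H1s[li] = std::move(H1); Z1s[li] = std::move(Z1);
    Ar[li] = std::move(Arelu);
  }

  // head: CLS rows -> latent -> decoder
  mat Wl = get_m(p, "Wl"); rowvec bl = get_rv(p, "bl");
  mat Wd1 = get_m(p, "Wd1"); rowvec bd1 = get_rv(p, "bd1");
  mat Wd2 = get_m(p, "Wd2"); rowvec bd2 = get_rv(p, "bd2");
  arma::uvec cls_rows(B);
  for (int b = 0; b < B; ++b) cls_rows[b] = b * T;
  mat Hc = H.rows(cls_rows);
  mat Z = Hc * Wl; Z.each_row() += bl;
  mat D1 = Z * Wd1; D1.each_row() += bd1;
  mat D1r = arma::clamp(D1, 0.0, arma::datum::inf);
  mat Xhat = D1r * Wd2; Xhat.each_row() += bd2;
  double loss = arma::accu(arma::square(Xhat - X)) / (double)(B * Fn);

  List out = List::create(Named("loss") = loss, Named("Z") = Z,
                          Named("Xhat") = Xhat);
  if (!want_grad) return out;

  List g;
  mat dXhat = 2.0 * (Xhat - X) / (double)(B * Fn);
  g["Wd2"] = D1r.t() * dXhat;
  g["bd2"] = arma::sum(dXhat, 0);
  mat dD1 = (dXhat * Wd2.t()) % (D1r > 0);
  g["Wd1"] = Z.t() * dD1;
  g["bd1"] = arma::sum(dD1, 0);
  mat dZ = dD1 * Wd1.t();
  g["Wl"] = Hc.t() * dZ;
  g["bl"] = arma::sum(dZ, 0);
  mat dHc = dZ * Wl.t();

  mat dH(R, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) dH.row(b * T) = dHc.row(b);

  for (int l = n_blocks; l >= 1; --l) {
    int li = l - 1;
    snprintf(buf, 32, "g2_%d", l); rowvec g2 = get_rv(p, buf);
    rowvec dg2, db2;
    mat dR2 = ln_bwd(dH, ln2[li], g2, dg2, db2);
    snprintf(buf, 32, "g2_%d", l); g[std::string(buf)] = dg2;
    snprintf(buf, 32, "b2_%d", l); g[std::string(buf)] = db2;
    mat dFF = dR2;
    if (use_drop) dFF %= as<mat>(masks_ffn[li]);
    snprintf(buf, 32, "W2_%d", l); mat W2 = get_m(p, buf);
    snprintf(buf, 32, "W2_%d", l); g[std::string(buf)] = Ar[li].t() * dFF;
    snprintf(buf, 32, "bf2_%d", l); g[std::string(buf)] = arma::sum(dFF, 0);
    mat dZ1 = (dFF * W2.t()) % (Z1s[li] > 0);
    snprintf(buf, 32, "W1_%d", l); mat W1 = get_m(p, buf);
    snprintf(buf, 32, "W1_%d", l); g[std::string(buf)] = H1s[li].t() * dZ1;
    snprintf(buf, 32, "bf1_%d", l); g[std::string(buf)] = arma::sum(dZ1, 0);
    mat dH1 = dR2 + dZ1 * W1.t();
    snprintf(buf, 32, "g1_%d", l); rowvec g1 = get_rv(p, buf);
    rowvec dg1, db1;
    mat dR1 = ln_bwd(dH1, ln1[li], g1, dg1, db1);
    snprintf(buf, 32, "g1_%d", l); g[std::string(buf)] = dg1;
    snprintf(buf, 32, "b1_%d", l); g[std::string(buf)] = db1;
    mat dAO = dR1;
    if (use_drop) dAO %= as<mat>(masks_attn[li]);
    snprintf(buf, 32, "Wo%d", l); mat Wo = get_m(p, buf);
    snprintf(buf, 32, "Wo%d", l); g[std::string(buf)] = Os[li].t() * dAO;
    snprintf(buf, 32, "bo%d", l); g[std::string(buf)] = arma::sum(dAO, 0);
    mat dO = dAO * Wo.t();
    mat dQ(R, d, arma::fill::zeros), dK(R, d, arma::fill::zeros),
        dV(R, d, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      int r0 = b * T, r1 = b * T + T - 1;
      for (int h = 0; h < n_heads; ++h) {
        int c0 = h * d_head, c1 = (h + 1) * d_head - 1;
        const mat &A = As[li][b * n_heads + h];
        mat dOb = dO.submat(r0, c0, r1, c1);
        mat dA = dOb * Vs[li].submat(r0, c0, r1, c1).t();
        dV.submat(r0, c0, r1, c1) = A.t() * dOb;
        vec rs = arma::sum(dA % A, 1);
        mat dS = A % (dA.each_col() - rs);
        dS *= scale;
        dQ.submat(r0, c0, r1, c1) = dS * Ks[li].submat(r0, c0, r1, c1);
        dK.submat(r0, c0, r1, c1) = dS.t() * Qs[li].submat(r0, c0, r1, c1);
      }
    }
    snprintf(buf, 32, "Wq%d", l); mat Wq = get_m(p, buf);
    snprintf(buf, 32, "Wk%d", l); mat Wk = get_m(p, buf);
    snprintf(buf, 32, "Wv%d", l); mat Wv = get_m(p, buf);
    snprintf(buf, 32, "Wq%d", l); g[std::string(buf)] = Hin[li].t() * dQ;
    snprintf(buf, 32, "bq%d", l); g[std::string(buf)] = arma::sum(dQ, 0);
    snprintf(buf, 32, "Wk%d", l); g[std::string(buf)] = Hin[li].t() * dK;
    snprintf(buf, 32, "bk%d", l); g[std::string(buf)] = arma::sum(dK, 0);
    snprintf(buf, 32, "Wv%d", l); g[std::string(buf)] = Hin[li].t() * dV;
    snprintf(buf, 32, "bv%d", l); g[std::string(buf)] = arma::sum(dV, 0);
    dH = dR1 + dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  }

  // token embeddings
  mat dpos(T, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) dpos += dH.rows(b * T, b * T + T - 1);
  g["pos"] = dpos;
  rowvec dcls(d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) dcls += dH.row(b * T);
  g["cls"] = dcls;
  mat dW_tok(Fn, d, arma::fill::zeros), dB_tok(Fn, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < Fn; ++f) {
      dW_tok.row(f) += dH.row(b * T + 1 + f) * X(b, f);
      dB_tok.row(f) += dH.row(b * T + 1 + f);
    }
  }
  g["W_tok"] = dW_tok;
  g["B_tok"] = dB_tok;

  out["grads"] = g;
  return out;
}
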