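// Dense-algebra kernels for the CNN/LSTM engine.
//
// Batch layout: a minibatch is an arma::cube with slice = sample.
//   conv stage : slice is (T, C * n_maps); column index = map * C + channel.
//   lstm stage : slice is (T_seq, F); row = time step.
// Weight layouts match the R side exactly:
//   conv W : (kh * kw * n_in) x n_out, row p = m*kh*kw + dc*kh + dt.
//   lstm Wx: F x 4H, Wh: H x 4H, gate order (i, f, g, o).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// im2col over a zero-padded single sample, written into rows
// [row0, row0 + To*Co) of P so whole-batch patch matrices feed one GEMM.
// Patch-row index within the block is r = to + co*To.
static void im2col_into(mat& P, const int row0, const mat& Xs,
                        const int C, const int n_in,
                        const int kh, const int kw,
                        const int pt0, const int pt1,
                        const int pc0, const int pc1) {
  const int T  = Xs.n_rows;
  const int Tp = T + pt0 + pt1;
  const int Cp = C + pc0 + pc1;
  const int To = Tp - kh + 1;
  const int Co = Cp - kw + 1;

  mat Xp(Tp, Cp * n_in, fill::zeros);
  for (int m = 0; m < n_in; ++m)
    Xp.submat(pt0, m * Cp + pc0, pt0 + T - 1, m * Cp + pc0 + C - 1) =
      Xs.cols(m * C, m * C + C - 1);

  for (int m = 0; m < n_in; ++m)
    for (int dc = 0; dc < kw; ++dc)
      for (int dt = 0; dt < kh; ++dt) {
        const int p = m * kh * kw + dc * kh + dt;
        P.submat(row0, p, row0 + To * Co - 1, p) = vectorise(
          Xp.submat(dt, m * Cp + dc, dt + To - 1, m * Cp + dc + Co - 1));
      }
}

// When the kernel spans the full channel width with no channel padding
// (kw == C, output width 1) the convolution is a 1-D correlation along
// time. It is computed with one fat GEMM per sample against Wcat, W's
// entries rearranged to (CM x n_out*kh) with column index mo*kh + dt and
// row index m*kw + c (the input's column layout), followed by a cheap
// lag-diagonal gather. This covers both conv layers of every variant here
// and avoids materialising patch matrices.
static mat cat_weights(const mat& W, const int n_in, const int kh,
                       const int kw) {
  const int CM = kw * n_in;
  const int n_out = W.n_cols;
  mat Wcat(CM, n_out * kh);
  for (int mo = 0; mo < n_out; ++mo)
    for (int dt = 0; dt < kh; ++dt)
      for (int m = 0; m < n_in; ++m)
        for (int c = 0; c < kw; ++c)
          Wcat(m * kw + c, mo * kh + dt) = W(m * kh * kw + c * kh + dt, mo);
  return Wcat;
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube& X, const arma::mat& W,
                          const arma::vec& b, const int C, const int n_in,
                          const int kh, const int kw,
                          const int pt0, const int pt1,
                          const int pc0, const int pc1) {
  const int B  = X.n_slices;
  const int T  = X.n_rows;
  const int To = T + pt0 + pt1 - kh + 1;
  const int Co = C + pc0 + pc1 - kw + 1;
  const int n_out = W.n_cols;

  cube Y(To, Co * n_out, B);
  if (pc0 == 0 && pc1 == 0 && kw == C) {
    mat Wcat = cat_weights(W, n_in, kh, kw);
    const int Tp = T + pt0 + pt1;
    mat Xp(Tp, C * n_in, fill::zeros);
    for (int s = 0; s < B; ++s) {
      Xp.rows(pt0, pt0 + T - 1) = X.slice(s);
      mat F = Xp * Wcat;                       // Tp x (n_out*kh)
      mat Z(To, n_out);
      for (int mo = 0; mo < n_out; ++mo) {
        vec acc = F.col(mo * kh).rows(0, To - 1);
        for (int dt = 1; dt < kh; ++dt)
          acc += F.col(mo * kh + dt).rows(dt, dt + To - 1);
        Z.col(mo) = acc + b[mo];
      }
      Y.slice(s) = Z;
    }
    return Y;
  }
  mat P(To * Co, W.n_rows);
  for (int s = 0; s < B; ++s) {
    im2col_into(P, 0, X.slice(s), C, n_in, kh, kw, pt0, pt1, pc0, pc1);
    mat Z = P * W;
    Z.each_row() += b.t();
    for (int mo = 0; mo < n_out; ++mo)
      Y.slice(s).cols(mo * Co, mo * Co + Co - 1) = reshape(Z.col(mo), To, Co);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(const arma::cube& X, const arma::mat& W,
                          const arma::cube& dY, const int C, const int n_in,
                          const int kh, const int kw,
                          const int pt0, const int pt1,
                          const int pc0, const int pc1,
                          const bool need_dx) {
  const int B  = X.n_slices;
  const int T  = X.n_rows;
  const int Tp = T + pt0 + pt1;
  const int Cp = C + pc0 + pc1;
  const int To = Tp - kh + 1;
  const int Co = Cp - kw + 1;
  const int n_out = W.n_cols;

  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(n_out, fill::zeros);
  cube dX;
  if (need_dx) dX.zeros(T, C * n_in, B);

  if (pc0 == 0 && pc1 == 0 && kw == C) {
    const int Tp = T + pt0 + pt1;
    const int CM = C * n_in;
    mat Wcat = cat_weights(W, n_in, kh, kw);
    mat dWcat(CM, n_out * kh, fill::zeros);
    mat Xp(Tp, CM, fill::zeros);
    mat dZsh(Tp, n_out * kh);
    for (int s = 0; s < B; ++s) {
      Xp.rows(pt0, pt0 + T - 1) = X.slice(s);
      const mat& dZ = dY.slice(s);            // To x n_out (Co == 1)
      db += sum(dZ, 0).t();
      dZsh.zeros();
      for (int mo = 0; mo < n_out; ++mo)
        for (int dt = 0; dt < kh; ++dt)
          dZsh.col(mo * kh + dt).rows(dt, dt + To - 1) = dZ.col(mo);
      dWcat += Xp.t() * dZsh;
      if (need_dx) {
        mat dXp = dZsh * Wcat.t();            // Tp x CM
        dX.slice(s) = dXp.rows(pt0, pt0 + T - 1);
      }
    }
    for (int mo = 0; mo < n_out; ++mo)
      for (int dt = 0; dt < kh; ++dt)
        for (int m = 0; m < n_in; ++m)
          for (int c = 0; c < kw; ++c)
            dW(m * kh * kw + c * kh + dt, mo) = dWcat(m * kw + c, mo * kh + dt);
    return Rcpp::List::create(Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db,
                              Rcpp::Named("dX") = dX);
  }

  mat P(To * Co, W.n_rows);
  mat dZ(To * Co, n_out);
  for (int s = 0; s < B; ++s) {
    im2col_into(P, 0, X.slice(s), C, n_in, kh, kw, pt0, pt1, pc0, pc1);
    for (int mo = 0; mo < n_out; ++mo)
      dZ.col(mo) = vectorise(dY.slice(s).cols(mo * Co, mo * Co + Co - 1));
    dW += P.t() * dZ;
    db += sum(dZ, 0).t();

    if (need_dx) {
      mat dP = dZ * W.t();                       // (To*Co) x (kh*kw*n_in)
      mat dXp(Tp, Cp * n_in, fill::zeros);
      for (int m = 0; m < n_in; ++m)
        for (int dc = 0; dc < kw; ++dc)
          for (int dt = 0; dt < kh; ++dt) {
            const int p = m * kh * kw + dc * kh + dt;
            dXp.submat(dt, m * Cp + dc, dt + To - 1, m * Cp + dc + Co - 1) +=
              reshape(dP.col(p), To, Co);
          }
      for (int m = 0; m < n_in; ++m)
        dX.slice(s).cols(m * C, m * C + C - 1) =
          dXp.submat(pt0, m * Cp + pc0, pt0 + T - 1, m * Cp + pc0 + C - 1);
    }
  }

  return Rcpp::List::create(Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

static inline mat sigm(const mat& Z) { return 1.0 / (1.0 + exp(-Z)); }

// Returns hidden/cell caches with slice t+1 = state after step t (slice 0 is
// the zero initial state) and the activated gates per step.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_fwd(const arma::cube& X, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::vec& b) {
  const int Tn = X.n_rows;
  const int F  = X.n_cols;
  const int B  = X.n_slices;
  const int H  = Wh.n_rows;

  cube Hs(H, B, Tn + 1, fill::zeros);
  cube Cs(H, B, Tn + 1, fill::zeros);
  cube Gs(4 * H, B, Tn);

  const mat WxT = Wx.t();
  const mat WhT = Wh.t();
  mat Xt(F, B);

  for (int t = 0; t < Tn; ++t) {
    for (int s = 0; s < B; ++s) Xt.col(s) = X.slice(s).row(t).t();
    mat Z = WxT * Xt + WhT * Hs.slice(t);
    Z.each_col() += b;

    mat I  = sigm(Z.rows(0, H - 1));
    mat Fg = sigm(Z.rows(H, 2 * H - 1));
    mat G  = tanh(Z.rows(2 * H, 3 * H - 1));
    mat O  = sigm(Z.rows(3 * H, 4 * H - 1));

    Cs.slice(t + 1) = Fg % Cs.slice(t) + I % G;
    Hs.slice(t + 1) = O % tanh(Cs.slice(t + 1));
    Gs.slice(t) = join_cols(join_cols(I, Fg), join_cols(G, O));
  }

  return Rcpp::List::create(Rcpp::Named("Hs") = Hs,
                            Rcpp::Named("Cs") = Cs,
                            Rcpp::Named("Gs") = Gs);
}

// dH: (H, B, Tn) gradient w.r.t. the hidden output at every step (zero where
// the loss does not touch the step).
// [[Rcpp::export]]
Rcpp::List cpp_lstm_bwd(const arma::cube& X, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::cube& Hs,
                        const arma::cube& Cs, const arma::cube& Gs,
                        const arma::cube& dH) {
  const int Tn = X.n_rows;
  const int F  = X.n_cols;
  const int B  = X.n_slices;
  const int H  = Wh.n_rows;

  mat dWx(F, 4 * H, fill::zeros);
  mat dWh(H, 4 * H, fill::zeros);
  vec db(4 * H, fill::zeros);
  cube dX(Tn, F, B, fill::zeros);

  mat dh_next(H, B, fill::zeros);
  mat dc_next(H, B, fill::zeros);
  mat Xt(F, B);

  for (int t = Tn - 1; t >= 0; --t) {
    const mat I  = Gs.slice(t).rows(0, H - 1);
    const mat Fg = Gs.slice(t).rows(H, 2 * H - 1);
    const mat G  = Gs.slice(t).rows(2 * H, 3 * H - 1);
    const mat O  = Gs.slice(t).rows(3 * H, 4 * H - 1);

    mat dh = dH.slice(t) + dh_next;
    mat tc = tanh(Cs.slice(t + 1));
    mat do_ = dh % tc;
    mat dc  = dc_next + dh % O % (1.0 - tc % tc);

    mat di = dc % G;
    mat df = dc % Cs.slice(t);
    mat dg = dc % I;

    mat dZ = join_cols(join_cols(di % I % (1.0 - I), df % Fg % (1.0 - Fg)),
                       join_cols(dg % (1.0 - G % G), do_ % O % (1.0 - O)));

    for (int s = 0; s < B; ++s) Xt.col(s) = X.slice(s).row(t).t();
    dWx += Xt * dZ.t();
    dWh += Hs.slice(t) * dZ.t();
    db  += sum(dZ, 1);

    mat dXt = Wx * dZ;                            // F x B
    for (int s = 0; s < B; ++s) dX.slice(s).row(t) = dXt.col(s).t();

    dh_next = Wh * dZ;
    dc_next = dc % Fg;
  }

  return Rcpp::List::create(Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
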