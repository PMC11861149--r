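// Batched forward/backward kernels for the recurrent layers.
//
// Sequence tensors are arma::cube with dimensions (batch, channels, time);
// per-step slices are then plain (batch x channels) matrices. Gate blocks
// are packed [i, f, z, o] (LSTM/sLSTM) or [i, f] (mLSTM) along columns.
//
// The mLSTM memory is a square H x H matrix per sample, stored row-major-
// by-column-blocks in a (batch x H*H) matrix: element (r, c) lives in
// column c*H + r, so a row-wise gate broadcast is repmat(gate, 1, H).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------- LSTM ----

// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const arma::cube& X, const arma::mat& W,
                            const arma::mat& U, const arma::rowvec& b) {
  const uword B = X.n_rows, T = X.n_slices, H = U.n_rows;
  cube Hs(B, H, T), Cs(B, H, T), G(B, 4 * H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = X.slice(t) * W + h * U;
    A.each_row() += b;
    mat i = sigmoid(A.cols(0, H - 1));
    mat f = sigmoid(A.cols(H, 2 * H - 1));
    mat z = tanh(A.cols(2 * H, 3 * H - 1));
    mat o = sigmoid(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % z;
    h = o % tanh(c);
    G.slice(t) = join_rows(join_rows(i, f), join_rows(z, o));
    Cs.slice(t) = c;
    Hs.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("h") = Hs, Rcpp::Named("c") = Cs,
                            Rcpp::Named("g") = G);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_backward(const arma::cube& X, const arma::mat& W,
                             const arma::mat& U, const arma::cube& Hs,
                             const arma::cube& Cs, const arma::cube& G,
                             const arma::cube& dH) {
  const uword B = X.n_rows, Cin = X.n_cols, T = X.n_slices, H = U.n_rows;
  cube dX(B, Cin, T);
  mat dW(Cin, 4 * H, fill::zeros), dU(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh_carry(B, H, fill::zeros), dc_carry(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const mat& g = G.slice(tt);
    mat i = g.cols(0, H - 1), f = g.cols(H, 2 * H - 1);
    mat z = g.cols(2 * H, 3 * H - 1), o = g.cols(3 * H, 4 * H - 1);
    mat c = Cs.slice(tt);
    mat c_prev = (tt == 0) ? mat(B, H, fill::zeros) : Cs.slice(tt - 1);
    mat h_prev = (tt == 0) ? mat(B, H, fill::zeros) : Hs.slice(tt - 1);
    mat tc = tanh(c);
    mat dh = dH.slice(tt) + dh_carry;
    mat do_ = dh % tc;
    mat dc = dh % o % (1.0 - tc % tc) + dc_carry;
    mat di = dc % z, df = dc % c_prev, dz = dc % i;
    dc_carry = dc % f;
    mat dA = join_rows(join_rows(di % i % (1.0 - i), df % f % (1.0 - f)),
                       join_rows(dz % (1.0 - z % z), do_ % o % (1.0 - o)));
    dW += X.slice(tt).t() * dA;
    dU += h_prev.t() * dA;
    db += sum(dA, 0);
    dh_carry = dA * U.t();
    dX.slice(tt) = dA * W.t();
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}

// --------------------------------------------------------------- sLSTM ----
// Exponential input/forget gates with a log-domain stabilizer m_t
// (max-shift). The readout c/n is exactly invariant to the shift, so m is
// treated as a constant in the backward pass.

// [[Rcpp::export]]
Rcpp::List cpp_slstm_forward(const arma::cube& X, const arma::mat& W,
                             const arma::mat& U, const arma::rowvec& b) {
  const uword B = X.n_rows, T = X.n_slices, H = U.n_rows;
  cube Hs(B, H, T), Cs(B, H, T), Ns(B, H, T), G(B, 4 * H, T), Ms(B, H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros), n(B, H, fill::zeros),
      m(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = X.slice(t) * W + h * U;
    A.each_row() += b;
    mat it_ = A.cols(0, H - 1);
    mat ft_ = A.cols(H, 2 * H - 1);
    mat z = tanh(A.cols(2 * H, 3 * H - 1));
    mat o = sigmoid(A.cols(3 * H, 4 * H - 1));
    mat m_new = arma::max(ft_ + m, it_);
    mat i = exp(it_ - m_new);
    mat f = exp(ft_ + m - m_new);
    m = m_new;
    c = f % c + i % z;
    n = f % n + i;
    h = o % (c / n);
    G.slice(t) = join_rows(join_rows(i, f), join_rows(z, o));
    Cs.slice(t) = c;
    Ns.slice(t) = n;
    Ms.slice(t) = m;
    Hs.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("h") = Hs, Rcpp::Named("c") = Cs,
                            Rcpp::Named("n") = Ns, Rcpp::Named("m") = Ms,
                            Rcpp::Named("g") = G);
}

// [[Rcpp::export]]
Rcpp::List cpp_slstm_backward(const arma::cube& X, const arma::mat& W,
                              const arma::mat& U, const arma::cube& Hs,
                              const arma::cube& Cs, const arma::cube& Ns,
                              const arma::cube& G, const arma::cube& dH) {
  const uword B = X.n_rows, Cin = X.n_cols, T = X.n_slices, H = U.n_rows;
  cube dX(B, Cin, T);
  mat dW(Cin, 4 * H, fill::zeros), dU(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh_carry(B, H, fill::zeros), dc_carry(B, H, fill::zeros),
      dn_carry(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const mat& g = G.slice(tt);
    mat i = g.cols(0, H - 1), f = g.cols(H, 2 * H - 1);
    mat z = g.cols(2 * H, 3 * H - 1), o = g.cols(3 * H, 4 * H - 1);
    mat c = Cs.slice(tt), n = Ns.slice(tt);
    mat c_prev = (tt == 0) ? mat(B, H, fill::zeros) : Cs.slice(tt - 1);
    mat n_prev = (tt == 0) ? mat(B, H, fill::zeros) : Ns.slice(tt - 1);
    mat h_prev = (tt == 0) ? mat(B, H, fill::zeros) : Hs.slice(tt - 1);
    mat hb = c / n;
    mat dh = dH.slice(tt) + dh_carry;
    mat do_ = dh % hb;
    mat dhb = dh % o;
    mat dc = dhb / n + dc_carry;
    mat dn = -dhb % c / (n % n) + dn_carry;
    mat di = dc % z + dn;
    mat df = dc % c_prev + dn % n_prev;
    mat dz = dc % i;
    dc_carry = dc % f;
    dn_carry = dn % f;
    // d(exp(a - m))/da = exp(a - m) with m held constant
    mat dA = join_rows(join_rows(di % i, df % f),
                       join_rows(dz % (1.0 - z % z), do_ % o % (1.0 - o)));
    dW += X.slice(tt).t() * dA;
    dU += h_prev.t() * dA;
    db += sum(dA, 0);
    dh_carry = dA * U.t();
    dX.slice(tt) = dA * W.t();
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}

// --------------------------------------------------------------- mLSTM ----
// Square H x H matrix memory per sample, sigmoid gates broadcast row-wise,
// tanh candidate matrix from [h_{t-1}, x_t], query q_t = W_q x_t + b_q,
// normalizer n_t = f .* n_{t-1} + i, readout C q / max(n' q, 1).

// [[Rcpp::export]]
Rcpp::List cpp_mlstm_forward(const arma::cube& X, const arma::mat& Wg,
                             const arma::rowvec& bg, const arma::mat& Wc,
                             const arma::rowvec& bc, const arma::mat& Wq,
                             const arma::rowvec& bq, const bool want_cache) {
  const uword B = X.n_rows, T = X.n_slices, H = Wq.n_cols;
  const uword H2 = H * H;
  cube Hs(B, H, T);
  cube G, Q, N, Cseq, Mseq;
  mat S;
  if (want_cache) {
    G.set_size(B, 2 * H, T);
    Q.set_size(B, H, T);
    N.set_size(B, H, T);
    Cseq.set_size(B, H2, T);
    Mseq.set_size(B, H2, T);
    S.set_size(B, T);
  }
  mat h(B, H, fill::zeros), C(B, H2, fill::zeros), n(B, H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat u = join_rows(h, X.slice(t));
    mat Ga = u * Wg;
    Ga.each_row() += bg;
    Ga = sigmoid(Ga);
    mat i = Ga.cols(0, H - 1), f = Ga.cols(H, 2 * H - 1);
    mat M = u * Wc;
    M.each_row() += bc;
    M = tanh(M);
    C = C % repmat(f, 1, H) + M % repmat(i, 1, H);
    mat q = X.slice(t) * Wq;
    q.each_row() += bq;
    n = n % f + i;
    vec s = sum(n % q, 1);
    vec den = s;
    den.transform([](double v) { return v < 1.0 ? 1.0 : v; });
    mat Cq(B, H, fill::zeros);
    for (uword cc = 0; cc < H; ++cc) {
      Cq += C.cols(cc * H, cc * H + H - 1) % repmat(q.col(cc), 1, H);
    }
    h = Cq;
    h.each_col() /= den;
    Hs.slice(t) = h;
    if (want_cache) {
      G.slice(t) = Ga;
      Q.slice(t) = q;
      N.slice(t) = n;
      Cseq.slice(t) = C;
      Mseq.slice(t) = M;
      S.col(t) = s;
    }
  }
  if (!want_cache) return Rcpp::List::create(Rcpp::Named("h") = Hs);
  return Rcpp::List::create(
      Rcpp::Named("h") = Hs, Rcpp::Named("g") = G, Rcpp::Named("q") = Q,
      Rcpp::Named("n") = N, Rcpp::Named("C") = Cseq, Rcpp::Named("M") = Mseq,
      Rcpp::Named("s") = S);
}

// [[Rcpp::export]]
Rcpp::List cpp_mlstm_backward(const arma::cube& X, const arma::mat& Wg,
                              const arma::mat& Wc, const arma::mat& Wq,
                              const arma::cube& Hs, const arma::cube& G,
                              const arma::cube& Q, const arma::cube& N,
                              const arma::cube& Cseq, const arma::cube& Mseq,
                              const arma::mat& S, const arma::cube& dH) {
  const uword B = X.n_rows, Cin = X.n_cols, T = X.n_slices, H = Wq.n_cols;
  const uword H2 = H * H;
  cube dX(B, Cin, T);
  mat dWg(Wg.n_rows, Wg.n_cols, fill::zeros);
  mat dWc(Wc.n_rows, Wc.n_cols, fill::zeros);
  mat dWq(Wq.n_rows, Wq.n_cols, fill::zeros);
  rowvec dbg(2 * H, fill::zeros), dbc(H2, fill::zeros), dbq(H, fill::zeros);
  mat dh_carry(B, H, fill::zeros), dC_carry(B, H2, fill::zeros),
      dn_carry(B, H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const mat& Ga = G.slice(tt);
    mat i = Ga.cols(0, H - 1), f = Ga.cols(H, 2 * H - 1);
    const mat& q = Q.slice(tt);
    const mat& n = N.slice(tt);
    const mat& C = Cseq.slice(tt);
    const mat& M = Mseq.slice(tt);
    mat C_prev = (tt == 0) ? mat(B, H2, fill::zeros) : Cseq.slice(tt - 1);
    mat n_prev = (tt == 0) ? mat(B, H, fill::zeros) : N.slice(tt - 1);
    mat h_prev = (tt == 0) ? mat(B, H, fill::zeros) : Hs.slice(tt - 1);
    vec s = S.col(tt);
    vec den = s;
    den.transform([](double v) { return v < 1.0 ? 1.0 : v; });

    mat dh = dH.slice(tt) + dh_carry;
    mat Cq = Hs.slice(tt);
    Cq.each_col() %= den;  // h * den
    mat dCq = dh;
    dCq.each_col() /= den;
    vec dden = -sum(dh % Hs.slice(tt), 1) / den;  // -sum(dh % Cq)/den^2
    vec ds = dden % conv_to<vec>::from(s > 1.0);
    mat dsrep = repmat(ds, 1, H);
    mat dn = dsrep % q + dn_carry;
    mat dq = dsrep % n;
    mat dC = dC_carry;
    for (uword cc = 0; cc < H; ++cc) {
      const uword a = cc * H, bcol = cc * H + H - 1;
      dC.cols(a, bcol) += dCq % repmat(q.col(cc), 1, H);
      dq.col(cc) += sum(dCq % C.cols(a, bcol), 1);
    }
    mat di = dn, df = dn % n_prev;
    for (uword cc = 0; cc < H; ++cc) {
      const uword a = cc * H, bcol = cc * H + H - 1;
      di += dC.cols(a, bcol) % M.cols(a, bcol);
      df += dC.cols(a, bcol) % C_prev.cols(a, bcol);
    }
    mat dM = dC % repmat(i, 1, H);
    mat dMt = dM % (1.0 - M % M);
    dC_carry = dC % repmat(f, 1, H);
    dn_carry = dn % f;
    mat dG = join_rows(di % i % (1.0 - i), df % f % (1.0 - f));
    mat u = join_rows(h_prev, X.slice(tt));
    mat du = dG * Wg.t() + dMt * Wc.t();
    dWg += u.t() * dG;
    dbg += sum(dG, 0);
    dWc += u.t() * dMt;
    dbc += sum(dMt, 0);
    dWq += X.slice(tt).t() * dq;
    dbq += sum(dq, 0);
    dX.slice(tt) = du.cols(H, H + Cin - 1) + dq * Wq.t();
    dh_carry = du.cols(0, H - 1);
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dWg") = dWg,
      Rcpp::Named("dbg") = dbg, Rcpp::Named("dWc") = dWc,
      Rcpp::Named("dbc") = dbc, Rcpp::Named("dWq") = dWq,
      Rcpp::Named("dbq") = dbq);
}
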