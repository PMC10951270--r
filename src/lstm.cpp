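// Sequence-LSTM forward/backward kernels.
// Gate packing in W (D x 4H), U (H x 4H), b (4H): [i | f | g | o].
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline rowvec sigmoid(const rowvec& x) {
  return 1.0 / (1.0 + exp(-x));
}

// [[Rcpp::export(name = ".lstm_fwd_cpp")]]
Rcpp::List lstm_fwd_cpp(const arma::mat& X, const arma::mat& W,
                        const arma::mat& U, const arma::rowvec& b) {
  const uword T = X.n_rows, H = U.n_rows;
  mat XP = X * W;
  XP.each_row() += b;
  mat I(T, H), F(T, H), G(T, H), O(T, H), C(T, H), Hs(T, H), TC(T, H);
  rowvec h(H, fill::zeros), c(H, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    rowvec a = XP.row(t) + h * U;
    rowvec i = sigmoid(a.cols(0, H - 1));
    rowvec f = sigmoid(a.cols(H, 2 * H - 1));
    rowvec g = tanh(a.cols(2 * H, 3 * H - 1));
    rowvec o = sigmoid(a.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    rowvec tc = tanh(c);
    h = o % tc;
    I.row(t) = i; F.row(t) = f; G.row(t) = g; O.row(t) = o;
    C.row(t) = c; TC.row(t) = tc; Hs.row(t) = h;
  }
  return Rcpp::List::create(
    Rcpp::Named("H") = Hs, Rcpp::Named("C") = C, Rcpp::Named("I") = I,
    Rcpp::Named("F") = F, Rcpp::Named("G") = G, Rcpp::Named("O") = O,
    Rcpp::Named("TC") = TC);
}

// [[Rcpp::export(name = ".lstm_bwd_cpp")]]
Rcpp::List lstm_bwd_cpp(const arma::mat& X, const arma::mat& W,
                        const arma::mat& U, const Rcpp::List& cache,
                        const arma::mat& dH) {
  const uword T = X.n_rows, H = U.n_rows;
  const mat Hs = cache["H"], C = cache["C"], I = cache["I"],
            F = cache["F"], G = cache["G"], O = cache["O"],
            TC = cache["TC"];
  mat dX(T, X.n_cols, fill::zeros), dW(size(W), fill::zeros),
      dU(size(U), fill::zeros);
  rowvec db(4 * H, fill::zeros);
  rowvec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    rowvec dh = dH.row(tt) + dh_next;
    rowvec i = I.row(tt), f = F.row(tt), g = G.row(tt), o = O.row(tt);
    rowvec tc = TC.row(tt);
    rowvec c_prev = (tt == 0) ? rowvec(H, fill::zeros) : C.row(tt - 1);
    rowvec h_prev = (tt == 0) ? rowvec(H, fill::zeros) : Hs.row(tt - 1);
    rowvec dc = dc_next + dh % o % (1.0 - tc % tc);
    rowvec da(4 * H);
    da.cols(0, H - 1)          = dc % g % i % (1.0 - i);
    da.cols(H, 2 * H - 1)      = dc % c_prev % f % (1.0 - f);
    da.cols(2 * H, 3 * H - 1)  = dc % i % (1.0 - g % g);
    da.cols(3 * H, 4 * H - 1)  = dh % tc % o % (1.0 - o);
    dX.row(tt) = da * W.t();
    dW += X.row(tt).t() * da;
    dU += h_prev.t() * da;
    db += da;
    dh_next = da * U.t();
    dc_next = dc % f;
  }
  return Rcpp::List::create(
    Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
    Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}

// Batched fragment aggregation: for each fragment, an LSTM over its
// cleavage-feature rows, attention pooling over the LSTM outputs, and a
// dense head. One call per spectrum instead of one per fragment.
// idx: 0-based rows of CF, concatenated; off: fragment start offsets
// (length nfrag + 1).
// [[Rcpp::export(name = ".frags_fwd_cpp")]]
Rcpp::List frags_fwd_cpp(const arma::mat& CF, const arma::uvec& idx,
                         const arma::uvec& off, const arma::mat& W,
                         const arma::mat& U, const arma::rowvec& b,
                         const arma::vec& attw, const double attb,
                         const arma::mat& headW,
                         const arma::rowvec& headb) {
  const uword nfrag = off.n_elem - 1, H = U.n_rows,
              nout = headW.n_cols, total = idx.n_elem;
  mat I(total, H), F(total, H), G(total, H), O(total, H), C(total, H),
      TC(total, H), Hs(total, H);
  vec alpha(total);
  mat V(nfrag, H);
  mat out(nfrag, nout);
  for (uword f = 0; f < nfrag; ++f) {
    const uword s = off(f), e = off(f + 1);
    rowvec h(H, fill::zeros), c(H, fill::zeros);
    for (uword t = s; t < e; ++t) {
      rowvec a = CF.row(idx(t)) * W + b + h * U;
      rowvec i = sigmoid(a.cols(0, H - 1));
      rowvec fg = sigmoid(a.cols(H, 2 * H - 1));
      rowvec g = tanh(a.cols(2 * H, 3 * H - 1));
      rowvec o = sigmoid(a.cols(3 * H, 4 * H - 1));
      c = fg % c + i % g;
      rowvec tc = tanh(c);
      h = o % tc;
      I.row(t) = i; F.row(t) = fg; G.row(t) = g; O.row(t) = o;
      C.row(t) = c; TC.row(t) = tc; Hs.row(t) = h;
    }
    vec sc = Hs.rows(s, e - 1) * attw + attb;
    sc -= sc.max();
    vec al = exp(sc);
    al /= accu(al);
    alpha.subvec(s, e - 1) = al;
    rowvec v = al.t() * Hs.rows(s, e - 1);
    V.row(f) = v;
    out.row(f) = v * headW + headb;
  }
  return Rcpp::List::create(
    Rcpp::Named("out") = out, Rcpp::Named("V") = V,
    Rcpp::Named("alpha") = alpha, Rcpp::Named("Hs") = Hs,
    Rcpp::Named("I") = I, Rcpp::Named("F") = F, Rcpp::Named("G") = G,
    Rcpp::Named("O") = O, Rcpp::Named("C") = C, Rcpp::Named("TC") = TC);
}

// [[Rcpp::export(name = ".frags_bwd_cpp")]]
Rcpp::List frags_bwd_cpp(const arma::mat& CF, const arma::uvec& idx,
                         const arma::uvec& off, const arma::mat& W,
                         const arma::mat& U, const arma::vec& attw,
                         const arma::mat& headW, const Rcpp::List& cache,
                         const arma::mat& dOut) {
  const uword nfrag = off.n_elem - 1, H = U.n_rows, total = idx.n_elem;
  const mat Hs = cache["Hs"], I = cache["I"], F = cache["F"],
            G = cache["G"], O = cache["O"], C = cache["C"],
            TC = cache["TC"], V = cache["V"];
  const vec alpha = cache["alpha"];
  mat dCF(CF.n_rows, CF.n_cols, fill::zeros);
  mat dW(size(W), fill::zeros), dU(size(U), fill::zeros);
  rowvec db(4 * H, fill::zeros);
  vec dattw(H, fill::zeros);
  double dattb = 0.0;
  mat dheadW(size(headW), fill::zeros);
  rowvec dheadb(headW.n_cols, fill::zeros);
  for (uword f = 0; f < nfrag; ++f) {
    const uword s = off(f), e = off(f + 1);
    rowvec dy = dOut.row(f);
    if (!any(dy != 0.0)) continue;
    // head
    dheadW += V.row(f).t() * dy;
    dheadb += dy;
    rowvec dv = dy * headW.t();
    // attention
    const mat Hblk = Hs.rows(s, e - 1);
    const vec al = alpha.subvec(s, e - 1);
    vec dal = Hblk * dv.t();
    vec ds = al % (dal - accu(al % dal));
    mat dH = al * dv + ds * attw.t();
    dattw += Hblk.t() * ds;
    dattb += accu(ds);
    // LSTM
    rowvec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
    for (uword t = e; t-- > s;) {
      rowvec dh = dH.row(t - s) + dh_next;
      rowvec i = I.row(t), fg = F.row(t), gg = G.row(t), o = O.row(t);
      rowvec tc = TC.row(t);
      rowvec c_prev = (t == s) ? rowvec(H, fill::zeros) : C.row(t - 1);
      rowvec h_prev = (t == s) ? rowvec(H, fill::zeros) : Hs.row(t - 1);
      rowvec dc = dc_next + dh % o % (1.0 - tc % tc);
      rowvec da(4 * H);
      da.cols(0, H - 1)         = dc % gg % i % (1.0 - i);
      da.cols(H, 2 * H - 1)     = dc % c_prev % fg % (1.0 - fg);
      da.cols(2 * H, 3 * H - 1) = dc % i % (1.0 - gg % gg);
      da.cols(3 * H, 4 * H - 1) = dh % tc % o % (1.0 - o);
      dCF.row(idx(t)) += da * W.t();
      dW += CF.row(idx(t)).t() * da;
      dU += h_prev.t() * da;
      db += da;
      dh_next = da * U.t();
      dc_next = dc % fg;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("dCF") = dCF, Rcpp::Named("dW") = dW,
    Rcpp::Named("dU") = dU, Rcpp::Named("db") = db,
    Rcpp::Named("dattw") = dattw, Rcpp::Named("dattb") = dattb,
    Rcpp::Named("dheadW") = dheadW, Rcpp::Named("dheadb") = dheadb);
}

// Child-sum tree LSTM over a generic predecessor structure.
// order: 0-based processing order (all predecessors before the node);
// pidx/poff: concatenated 0-based predecessor ids with offsets per node
// (poff indexed by node id, length n + 1 in processing-independent node
// order).
// [[Rcpp::export(name = ".treelstm_fwd_cpp")]]
Rcpp::List treelstm_fwd_cpp(const arma::mat& X, const arma::mat& W,
                            const arma::mat& U, const arma::rowvec& b,
                            const arma::uvec& order,
                            const arma::uvec& pidx,
                            const arma::uvec& poff) {
  const uword n = X.n_rows, H = U.n_rows;
  const mat Ui = U.cols(0, H - 1), Uf = U.cols(H, 2 * H - 1),
            Ug = U.cols(2 * H, 3 * H - 1), Uo = U.cols(3 * H, 4 * H - 1);
  mat XP = X * W;
  XP.each_row() += b;
  mat h(n, H, fill::zeros), c(n, H, fill::zeros), tc(n, H, fill::zeros);
  mat I(n, H), G(n, H), O(n, H), HS(n, H, fill::zeros);
  mat Fg(pidx.n_elem, H); // per-predecessor forget gates
  for (uword oi = 0; oi < n; ++oi) {
    const uword v = order(oi);
    rowvec h_sum(H, fill::zeros);
    for (uword t = poff(v); t < poff(v + 1); ++t) {
      h_sum += h.row(pidx(t));
    }
    rowvec i = sigmoid(XP(v, span(0, H - 1)) + h_sum * Ui);
    rowvec g = tanh(XP(v, span(2 * H, 3 * H - 1)) + h_sum * Ug);
    rowvec o = sigmoid(XP(v, span(3 * H, 4 * H - 1)) + h_sum * Uo);
    rowvec cv = i % g;
    for (uword t = poff(v); t < poff(v + 1); ++t) {
      rowvec fk = sigmoid(XP(v, span(H, 2 * H - 1)) +
                          h.row(pidx(t)) * Uf);
      Fg.row(t) = fk;
      cv += fk % c.row(pidx(t));
    }
    I.row(v) = i; G.row(v) = g; O.row(v) = o; HS.row(v) = h_sum;
    c.row(v) = cv;
    tc.row(v) = tanh(cv);
    h.row(v) = o % tc.row(v);
  }
  return Rcpp::List::create(
    Rcpp::Named("out") = h, Rcpp::Named("C") = c,
    Rcpp::Named("TC") = tc, Rcpp::Named("I") = I,
    Rcpp::Named("G") = G, Rcpp::Named("O") = O,
    Rcpp::Named("HS") = HS, Rcpp::Named("Fg") = Fg);
}

// [[Rcpp::export(name = ".treelstm_bwd_cpp")]]
Rcpp::List treelstm_bwd_cpp(const arma::mat& X, const arma::mat& W,
                            const arma::mat& U, const arma::uvec& order,
                            const arma::uvec& pidx,
                            const arma::uvec& poff,
                            const Rcpp::List& cache,
                            const arma::mat& dH_ext) {
  const uword n = X.n_rows, H = U.n_rows;
  const mat Ui = U.cols(0, H - 1), Uf = U.cols(H, 2 * H - 1),
            Ug = U.cols(2 * H, 3 * H - 1), Uo = U.cols(3 * H, 4 * H - 1);
  const mat h = cache["out"], c = cache["C"], tc = cache["TC"],
            I = cache["I"], G = cache["G"], O = cache["O"],
            HS = cache["HS"], Fg = cache["Fg"];
  mat dX(n, X.n_cols, fill::zeros), dW(size(W), fill::zeros),
      dU(size(U), fill::zeros);
  rowvec db(4 * H, fill::zeros);
  mat dh = dH_ext, dc(n, H, fill::zeros);
  for (uword oi = n; oi-- > 0;) {
    const uword v = order(oi);
    rowvec i = I.row(v), g = G.row(v), o = O.row(v), tcv = tc.row(v);
    rowvec dhv = dh.row(v);
    rowvec dcv = dc.row(v) + dhv % o % (1.0 - tcv % tcv);
    rowvec da_i = dcv % g % i % (1.0 - i);
    rowvec da_g = dcv % i % (1.0 - g % g);
    rowvec da_o = dhv % tcv % o % (1.0 - o);
    rowvec da_f_sum(H, fill::zeros);
    rowvec dh_sum = da_i * Ui.t() + da_g * Ug.t() + da_o * Uo.t();
    for (uword t = poff(v); t < poff(v + 1); ++t) {
      const uword k = pidx(t);
      rowvec fk = Fg.row(t);
      rowvec da_f = dcv % c.row(k) % fk % (1.0 - fk);
      da_f_sum += da_f;
      dc.row(k) += dcv % fk;
      dh.row(k) += da_f * Uf.t() + dh_sum;
      dU.cols(H, 2 * H - 1) += h.row(k).t() * da_f;
    }
    rowvec da(4 * H);
    da.cols(0, H - 1) = da_i;
    da.cols(H, 2 * H - 1) = da_f_sum;
    da.cols(2 * H, 3 * H - 1) = da_g;
    da.cols(3 * H, 4 * H - 1) = da_o;
    dX.row(v) = da * W.t();
    dW += X.row(v).t() * da;
    rowvec hs = HS.row(v);
    dU.cols(0, H - 1) += hs.t() * da_i;
    dU.cols(2 * H, 3 * H - 1) += hs.t() * da_g;
    dU.cols(3 * H, 4 * H - 1) += hs.t() * da_o;
    db += da;
  }
  return Rcpp::List::create(
    Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
    Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}
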