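// Bidirectional LSTM sequence labeller: forward pass, analytic
// backpropagation through time, and softmax readout. Two stacked BiLSTM
// layers (encoder, decoder) map a per-sample scalar input to one class
// distribution per sample. Parameters live in an R list of matrices; all
// randomness (init, dropout masks, batch order) is drawn on the R side so
// the compiled code is deterministic.
//
// Parameter layout per LSTM cell: W (4H x D), U (4H x H), b (4H), with the
// gate rows ordered [input; forget; candidate; output].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

struct LstmCache {
  cube i, f, g, o, c, h;  // each H x B x T
};

// One direction of one layer. X_in: D x B x T. Returns H x B x T.
// The input projection W * x_t is hoisted out of the time loop as a single
// GEMM over all timesteps; only the recurrent product stays per-step.
static cube lstm_forward(const mat& W, const mat& U, const vec& b,
                         const cube& X_in, bool reverse, LstmCache* cache) {
  const uword H = U.n_cols, B = X_in.n_cols, T = X_in.n_slices;
  const uword D = X_in.n_rows;
  cube Hs(H, B, T);
  if (cache) {
    cache->i.set_size(H, B, T); cache->f.set_size(H, B, T);
    cache->g.set_size(H, B, T); cache->o.set_size(H, B, T);
    cache->c.set_size(H, B, T); cache->h.set_size(H, B, T);
  }
  const mat Xf(const_cast<double*>(X_in.memptr()), D, B * T, false, true);
  mat WX = W * Xf;  // 4H x (B*T)
  mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    uword t = reverse ? (T - 1 - step) : step;
    mat pre = WX.cols(t * B, (t + 1) * B - 1) + U * h_prev;
    pre.each_col() += b;
    mat gi = sigmoid(pre.rows(0, H - 1));
    mat gf = sigmoid(pre.rows(H, 2 * H - 1));
    mat gg = tanh(pre.rows(2 * H, 3 * H - 1));
    mat go = sigmoid(pre.rows(3 * H, 4 * H - 1));
    mat c_t = gf % c_prev + gi % gg;
    mat h_t = go % tanh(c_t);
    if (cache) {
      cache->i.slice(t) = gi; cache->f.slice(t) = gf;
      cache->g.slice(t) = gg; cache->o.slice(t) = go;
      cache->c.slice(t) = c_t; cache->h.slice(t) = h_t;
    }
    Hs.slice(t) = h_t;
    h_prev = h_t; c_prev = c_t;
  }
  return Hs;
}

// Backward through one direction. dH: H x B x T gradient w.r.t. outputs.
// Returns gradient w.r.t. X_in (D x B x T); accumulates dW, dU, db.
static cube lstm_backward(const mat& W, const mat& U, const cube& X_in,
                          bool reverse, const LstmCache& cc, const cube& dH,
                          mat& dW, mat& dU, vec& db) {
  const uword H = U.n_cols, B = X_in.n_cols, T = X_in.n_slices, D = X_in.n_rows;
  dU.zeros(U.n_rows, U.n_cols);
  cube dPre(4 * H, B, T);
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    // walk in reverse of the forward direction
    uword t = reverse ? step : (T - 1 - step);
    mat dh = dH.slice(t) + dh_next;
    const mat& gi = cc.i.slice(t); const mat& gf = cc.f.slice(t);
    const mat& gg = cc.g.slice(t); const mat& go = cc.o.slice(t);
    const mat& c_t = cc.c.slice(t);
    mat tc = tanh(c_t);
    mat dc = dh % go % (1.0 - tc % tc) + dc_next;
    bool first = reverse ? (t == T - 1) : (t == 0);
    mat c_prev = first ? mat(H, B, fill::zeros)
                       : cc.c.slice(reverse ? t + 1 : t - 1);
    mat h_prev = first ? mat(H, B, fill::zeros)
                       : cc.h.slice(reverse ? t + 1 : t - 1);
    mat& dpre = dPre.slice(t);
    dpre.rows(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
    dpre.rows(H, 2 * H - 1) = (dc % c_prev) % gf % (1.0 - gf);
    dpre.rows(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    dpre.rows(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    dU += dpre * h_prev.t();
    dh_next = U.t() * dpre;
    dc_next = dc % gf;
  }
  // input-side products as single GEMMs over all timesteps
  const mat Xf(const_cast<double*>(X_in.memptr()), D, B * T, false, true);
  const mat dPf(const_cast<double*>(dPre.memptr()), 4 * H, B * T, false, true);
  dW = dPf * Xf.t();
  db = sum(dPf, 1);
  mat dXf = W.t() * dPf;  // D x (B*T)
  cube dX(dXf.memptr(), D, B, T);
  return dX;
}

static cube as_input_cube(const mat& X) {
  // X: T x B scalar series -> 1 x B x T
  cube out(1, X.n_cols, X.n_rows);
  for (uword t = 0; t < X.n_rows; ++t)
    out.slice(t) = X.row(t);
  return out;
}

struct Params {
  mat l1f_W, l1f_U, l1b_W, l1b_U, l2f_W, l2f_U, l2b_W, l2b_U, out_W;
  vec l1f_b, l1b_b, l2f_b, l2b_b, out_b;
};

static Params unpack(const Rcpp::List& p) {
  Params q;
  q.l1f_W = Rcpp::as<mat>(p["l1f_W"]); q.l1f_U = Rcpp::as<mat>(p["l1f_U"]);
  q.l1b_W = Rcpp::as<mat>(p["l1b_W"]); q.l1b_U = Rcpp::as<mat>(p["l1b_U"]);
  q.l2f_W = Rcpp::as<mat>(p["l2f_W"]); q.l2f_U = Rcpp::as<mat>(p["l2f_U"]);
  q.l2b_W = Rcpp::as<mat>(p["l2b_W"]); q.l2b_U = Rcpp::as<mat>(p["l2b_U"]);
  q.out_W = Rcpp::as<mat>(p["out_W"]);
  q.l1f_b = Rcpp::as<vec>(p["l1f_b"]); q.l1b_b = Rcpp::as<vec>(p["l1b_b"]);
  q.l2f_b = Rcpp::as<vec>(p["l2f_b"]); q.l2b_b = Rcpp::as<vec>(p["l2b_b"]);
  q.out_b = Rcpp::as<vec>(p["out_b"]);
  return q;
}

// Shared forward machinery. drop_mask: 2H x B (already scaled), or empty.
struct ForwardState {
  cube x_in, h1cat, h1drop, h2cat;  // inputs/outputs per stage
  LstmCache c1f, c1b, c2f, c2b;
  cube probs;  // C x B x T
};

static void full_forward(const Params& q, const mat& X, const mat& drop_mask,
                         bool keep_cache, ForwardState& st) {
  const uword T = X.n_rows, B = X.n_cols;
  const uword H = q.l1f_U.n_cols, C = q.out_W.n_rows;
  st.x_in = as_input_cube(X);
  cube h1f = lstm_forward(q.l1f_W, q.l1f_U, q.l1f_b, st.x_in, false,
                          keep_cache ? &st.c1f : nullptr);
  cube h1b = lstm_forward(q.l1b_W, q.l1b_U, q.l1b_b, st.x_in, true,
                          keep_cache ? &st.c1b : nullptr);
  st.h1cat.set_size(2 * H, B, T);
  for (uword t = 0; t < T; ++t)
    st.h1cat.slice(t) = join_cols(h1f.slice(t), h1b.slice(t));
  st.h1drop = st.h1cat;
  if (drop_mask.n_elem > 0)
    for (uword t = 0; t < T; ++t)
      st.h1drop.slice(t) %= drop_mask;
  cube h2f = lstm_forward(q.l2f_W, q.l2f_U, q.l2f_b, st.h1drop, false,
                          keep_cache ? &st.c2f : nullptr);
  cube h2b = lstm_forward(q.l2b_W, q.l2b_U, q.l2b_b, st.h1drop, true,
                          keep_cache ? &st.c2b : nullptr);
  st.h2cat.set_size(2 * H, B, T);
  for (uword t = 0; t < T; ++t)
    st.h2cat.slice(t) = join_cols(h2f.slice(t), h2b.slice(t));
  st.probs.set_size(C, B, T);
  for (uword t = 0; t < T; ++t) {
    mat logits = q.out_W * st.h2cat.slice(t);
    logits.each_col() += q.out_b;
    logits.each_row() -= max(logits, 0);
    mat e = exp(logits);
    st.probs.slice(t) = e.each_row() / sum(e, 0);
  }
}

// [[Rcpp::export]]
arma::cube cpp_bilstm_probs(const Rcpp::List& params, const arma::mat& X) {
  Params q = unpack(params);
  ForwardState st;
  full_forward(q, X, mat(), false, st);
  return st.probs;  // C x B x T
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_loss_grad(const Rcpp::List& params, const arma::mat& X,
                                const arma::imat& Y, const arma::mat& drop_mask,
                                bool want_grad) {
  Params q = unpack(params);
  const uword T = X.n_rows, B = X.n_cols;
  const uword H = q.l1f_U.n_cols, C = q.out_W.n_rows;
  if (Y.n_rows != T || Y.n_cols != B)
    Rcpp::stop("label matrix shape mismatch");
  ForwardState st;
  full_forward(q, X, drop_mask, want_grad, st);

  double loss = 0.0; uword correct = 0;
  const double scale = 1.0 / double(T * B);
  cube dH2(2 * H, B, T, fill::none);
  mat dOutW(C, 2 * H, fill::zeros); vec dOutB(C, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat p = st.probs.slice(t);
    mat dlog = p;
    for (uword b = 0; b < B; ++b) {
      int y = Y(t, b);
      if (y < 0 || y >= int(C)) Rcpp::stop("label out of range");
      loss -= std::log(std::max(p(y, b), 1e-12));
      dlog(y, b) -= 1.0;
      uword amax = index_max(p.col(b));
      if (int(amax) == y) ++correct;
    }
    if (want_grad) {
      dlog *= scale;
      dOutW += dlog * st.h2cat.slice(t).t();
      dOutB += sum(dlog, 1);
      dH2.slice(t) = q.out_W.t() * dlog;
    }
  }
  loss *= scale;

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("accuracy") = double(correct) / double(T * B));
  if (!want_grad) return out;

  cube dH2f = dH2.rows(0, H - 1), dH2b = dH2.rows(H, 2 * H - 1);
  mat d_l2f_W, d_l2f_U, d_l2b_W, d_l2b_U; vec d_l2f_b, d_l2b_b;
  cube dH1drop = lstm_backward(q.l2f_W, q.l2f_U, st.h1drop, false, st.c2f,
                               dH2f, d_l2f_W, d_l2f_U, d_l2f_b);
  dH1drop += lstm_backward(q.l2b_W, q.l2b_U, st.h1drop, true, st.c2b,
                           dH2b, d_l2b_W, d_l2b_U, d_l2b_b);
  if (drop_mask.n_elem > 0)
    for (uword t = 0; t < T; ++t)
      dH1drop.slice(t) %= drop_mask;
  cube dH1f = dH1drop.rows(0, H - 1), dH1b = dH1drop.rows(H, 2 * H - 1);
  mat d_l1f_W, d_l1f_U, d_l1b_W, d_l1b_U; vec d_l1f_b, d_l1b_b;
  lstm_backward(q.l1f_W, q.l1f_U, st.x_in, false, st.c1f, dH1f,
                d_l1f_W, d_l1f_U, d_l1f_b);
  lstm_backward(q.l1b_W, q.l1b_U, st.x_in, true, st.c1b, dH1b,
                d_l1b_W, d_l1b_U, d_l1b_b);

  out["grads"] = Rcpp::List::create(
    Rcpp::Named("l1f_W") = d_l1f_W, Rcpp::Named("l1f_U") = d_l1f_U,
    Rcpp::Named("l1f_b") = d_l1f_b,
    Rcpp::Named("l1b_W") = d_l1b_W, Rcpp::Named("l1b_U") = d_l1b_U,
    Rcpp::Named("l1b_b") = d_l1b_b,
    Rcpp::Named("l2f_W") = d_l2f_W, Rcpp::Named("l2f_U") = d_l2f_U,
    Rcpp::Named("l2f_b") = d_l2f_b,
    Rcpp::Named("l2b_W") = d_l2b_W, Rcpp::Named("l2b_U") = d_l2b_U,
    Rcpp::Named("l2b_b") = d_l2b_b,
    Rcpp::Named("out_W") = dOutW, Rcpp::Named("out_b") = dOutB);
  return out;
}
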