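// Bidirectional two-layer LSTM classifier ("ConcNet") engine.
//
// Layer 1: bidirectional LSTM, H units per direction, sequence output
//          (2H x T), dropout.
// Layer 2: bidirectional LSTM, H units per direction, final hidden
//          states concatenated (2H), dropout.
// Head:    dense F units + ReLU, dropout, dense 2, softmax,
//          cross-entropy loss.
//
// The whole minibatch is propagated together: tensors are stored as
// time-major column blocks (columns [t*B, (t+1)*B) hold time step t
// for all B sequences), so each recurrent step is one GEMM rather
// than B small mat-vec products. All randomness (dropout masks) is
// drawn from R's RNG so the R-side set.seed() governs training
// exactly. Gradients are exact BPTT and are validated in the test
// suite against central finite differences.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Params {
  arma::mat W1f, U1f, W1b, U1b, W2f, U2f, W2b, U2b, Wd1, Wd2;
  arma::vec b1f, b1b, b2f, b2b, bd1, bd2;
};

static Params unpack(const List& p) {
  Params q;
  q.W1f = as<arma::mat>(p["W1f"]); q.U1f = as<arma::mat>(p["U1f"]);
  q.b1f = as<arma::vec>(p["b1f"]);
  q.W1b = as<arma::mat>(p["W1b"]); q.U1b = as<arma::mat>(p["U1b"]);
  q.b1b = as<arma::vec>(p["b1b"]);
  q.W2f = as<arma::mat>(p["W2f"]); q.U2f = as<arma::mat>(p["U2f"]);
  q.b2f = as<arma::vec>(p["b2f"]);
  q.W2b = as<arma::mat>(p["W2b"]); q.U2b = as<arma::mat>(p["U2b"]);
  q.b2b = as<arma::vec>(p["b2b"]);
  q.Wd1 = as<arma::mat>(p["Wd1"]); q.bd1 = as<arma::vec>(p["bd1"]);
  q.Wd2 = as<arma::mat>(p["Wd2"]); q.bd2 = as<arma::vec>(p["bd2"]);
  return q;
}

// reverse the time order of a time-major block matrix (T blocks of B)
static arma::mat flip_blocks(const arma::mat& M, int T, int B) {
  arma::mat out(M.n_rows, M.n_cols);
  for (int t = 0; t < T; ++t)
    out.cols((arma::uword)t * B, (arma::uword)(t + 1) * B - 1) =
        M.cols((arma::uword)(T - 1 - t) * B, (arma::uword)(T - t) * B - 1);
  return out;
}

struct LstmCache {
  arma::mat G;   // gates (4H x T*B), [i; f; g; o] post-activation
  arma::mat C;   // cell states (H x T*B)
  arma::mat Hs;  // hidden states (H x T*B)
};

// Batched forward pass of one LSTM direction. X: (Din x T*B).
static LstmCache lstm_forward(const arma::mat& W, const arma::mat& U,
                              const arma::vec& b, const arma::mat& X,
                              int T, int B) {
  const int H = U.n_rows / 4;
  LstmCache cc;
  cc.G.set_size(4 * H, (arma::uword)T * B);
  cc.C.set_size(H, (arma::uword)T * B);
  cc.Hs.set_size(H, (arma::uword)T * B);
  arma::mat pre = W * X;
  pre.each_col() += b;
  arma::mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    const arma::uword c0 = (arma::uword)t * B, c1 = c0 + B - 1;
    arma::mat z = pre.cols(c0, c1) + U * h;
    arma::mat gi = 1.0 / (1.0 + arma::exp(-z.rows(0, H - 1)));
    arma::mat gf = 1.0 / (1.0 + arma::exp(-z.rows(H, 2 * H - 1)));
    arma::mat gg = arma::tanh(z.rows(2 * H, 3 * H - 1));
    arma::mat go = 1.0 / (1.0 + arma::exp(-z.rows(3 * H, 4 * H - 1)));
    c = gf % c + gi % gg;
    h = go % arma::tanh(c);
    cc.G.submat(0, c0, H - 1, c1) = gi;
    cc.G.submat(H, c0, 2 * H - 1, c1) = gf;
    cc.G.submat(2 * H, c0, 3 * H - 1, c1) = gg;
    cc.G.submat(3 * H, c0, 4 * H - 1, c1) = go;
    cc.C.cols(c0, c1) = c;
    cc.Hs.cols(c0, c1) = h;
  }
  return cc;
}

// Batched BPTT for one direction. dH: gradient wrt hidden outputs
// (H x T*B). Accumulates dW, dU, db; returns gradient wrt inputs X.
static arma::mat lstm_backward(const arma::mat& W, const arma::mat& U,
                               const arma::mat& X, const LstmCache& cc,
                               const arma::mat& dH, int T, int B,
                               arma::mat& dW, arma::mat& dU, arma::vec& db) {
  const int H = U.n_rows / 4;
  arma::mat dZ(4 * H, (arma::uword)T * B);
  arma::mat dh_next(H, B, arma::fill::zeros), dc_next(H, B, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const arma::uword c0 = (arma::uword)t * B, c1 = c0 + B - 1;
    arma::mat gi = cc.G.submat(0, c0, H - 1, c1);
    arma::mat gf = cc.G.submat(H, c0, 2 * H - 1, c1);
    arma::mat gg = cc.G.submat(2 * H, c0, 3 * H - 1, c1);
    arma::mat go = cc.G.submat(3 * H, c0, 4 * H - 1, c1);
    arma::mat tc = arma::tanh(cc.C.cols(c0, c1));
    arma::mat dh = dH.cols(c0, c1) + dh_next;
    arma::mat dgo = dh % tc;
    arma::mat dc = dc_next + dh % go % (1.0 - tc % tc);
    arma::mat c_prev = (t > 0) ? arma::mat(cc.C.cols(c0 - B, c0 - 1))
                               : arma::mat(H, B, arma::fill::zeros);
    arma::mat dz(4 * H, B);
    dz.rows(0, H - 1)         = (dc % gg) % gi % (1.0 - gi);
    dz.rows(H, 2 * H - 1)     = (dc % c_prev) % gf % (1.0 - gf);
    dz.rows(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    dz.rows(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);
    dZ.cols(c0, c1) = dz;
    dh_next = U.t() * dz;
    dc_next = dc % gf;
  }
  dW += dZ * X.t();
  db += arma::sum(dZ, 1);
  arma::mat Hprev(U.n_cols, (arma::uword)T * B, arma::fill::zeros);
  if (T > 1)
    Hprev.cols(B, (arma::uword)T * B - 1) =
        cc.Hs.cols(0, (arma::uword)(T - 1) * B - 1);
  dU += dZ * Hprev.t();
  return W.t() * dZ;
}

static arma::mat dropout_mask(arma::uword r, arma::uword c, double p) {
  arma::mat m(r, c);
  const double keep = 1.0 - p;
  for (arma::uword k = 0; k < m.n_elem; ++k)
    m(k) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

// Shared forward to logits (no dropout when p = 0 / masks all-ones).
// Xmat is time-major blocked (D x T*B).

// Forward pass to class probabilities for one sequence; no dropout.
// [[Rcpp::export]]
arma::vec cn_predict_cpp(const List& params, const arma::mat& X) {
  Params q = unpack(params);
  const int T = X.n_cols, B = 1;
  LstmCache f1 = lstm_forward(q.W1f, q.U1f, q.b1f, X, T, B);
  arma::mat Xr = arma::fliplr(X);
  LstmCache b1 = lstm_forward(q.W1b, q.U1b, q.b1b, Xr, T, B);
  arma::mat O1 = arma::join_vert(f1.Hs, arma::fliplr(b1.Hs));
  LstmCache f2 = lstm_forward(q.W2f, q.U2f, q.b2f, O1, T, B);
  arma::mat O1r = arma::fliplr(O1);
  LstmCache b2 = lstm_forward(q.W2b, q.U2b, q.b2b, O1r, T, B);
  arma::vec feat = arma::join_vert(arma::vec(f2.Hs.col(T - 1)),
                                   arma::vec(b2.Hs.col(T - 1)));
  arma::vec a = arma::clamp(q.Wd1 * feat + q.bd1, 0.0, arma::datum::inf);
  arma::vec logits = q.Wd2 * a + q.bd2;
  logits -= logits.max();
  arma::vec p = arma::exp(logits);
  return p / arma::accu(p);
}

// Summed loss and summed gradients over a minibatch of equal-length
// sequences. Xs: list of (D x T) matrices; ys: 0/1 labels (1 =
// positive class, output unit 0). Returns list(loss, n, grads).
// [[Rcpp::export]]
List cn_grad_batch_cpp(const List& params, const List& Xs,
                       const IntegerVector& ys, double dropout) {
  Params q = unpack(params);
  const int H = q.U1f.n_rows / 4;
  const int B = Xs.size();
  arma::mat X0 = as<arma::mat>(Xs[0]);
  const int D = X0.n_rows, T = X0.n_cols;

  // time-major blocked batch matrix
  arma::mat X(D, (arma::uword)T * B);
  for (int s = 0; s < B; ++s) {
    arma::mat Xi = as<arma::mat>(Xs[s]);
    if ((int)Xi.n_cols != T || (int)Xi.n_rows != D)
      stop("all sequences in a batch must share dimensions");
    for (int t = 0; t < T; ++t) X.col((arma::uword)t * B + s) = Xi.col(t);
  }

  LstmCache f1 = lstm_forward(q.W1f, q.U1f, q.b1f, X, T, B);
  arma::mat Xr = flip_blocks(X, T, B);
  LstmCache b1 = lstm_forward(q.W1b, q.U1b, q.b1b, Xr, T, B);
  arma::mat O1 = arma::join_vert(f1.Hs, flip_blocks(b1.Hs, T, B));

  arma::mat M1 = dropout > 0 ? dropout_mask(O1.n_rows, O1.n_cols, dropout)
                             : arma::mat(O1.n_rows, O1.n_cols, arma::fill::ones);
  arma::mat O1d = O1 % M1;

  LstmCache f2 = lstm_forward(q.W2f, q.U2f, q.b2f, O1d, T, B);
  arma::mat O1dr = flip_blocks(O1d, T, B);
  LstmCache b2 = lstm_forward(q.W2b, q.U2b, q.b2b, O1dr, T, B);
  const arma::uword last0 = (arma::uword)(T - 1) * B;
  arma::mat feat = arma::join_vert(
      arma::mat(f2.Hs.cols(last0, last0 + B - 1)),
      arma::mat(b2.Hs.cols(last0, last0 + B - 1)));   // 2H x B

  arma::mat M2 = dropout > 0 ? dropout_mask(feat.n_rows, B, dropout)
                             : arma::mat(feat.n_rows, B, arma::fill::ones);
  arma::mat featd = feat % M2;

  arma::mat apre = q.Wd1 * featd;
  apre.each_col() += q.bd1;
  arma::mat a = arma::clamp(apre, 0.0, arma::datum::inf);
  arma::mat M3 = dropout > 0 ? dropout_mask(a.n_rows, B, dropout)
                             : arma::mat(a.n_rows, B, arma::fill::ones);
  arma::mat ad = a % M3;

  arma::mat logits = q.Wd2 * ad;
  logits.each_col() += q.bd2;
  arma::rowvec mx = arma::max(logits, 0);
  logits.each_row() -= mx;
  arma::mat ex = arma::exp(logits);
  arma::rowvec norm = arma::sum(ex, 0);
  arma::mat prob = ex;
  prob.each_row() /= norm;

  double total_loss = 0.0;
  arma::mat dlogit = prob;
  for (int s = 0; s < B; ++s) {
    const int target = (ys[s] == 1) ? 0 : 1;
    total_loss += -std::log(std::max(prob(target, s), 1e-300));
    dlogit(target, s) -= 1.0;
  }

  // ---- backward ----
  arma::mat dWd2 = dlogit * ad.t();
  arma::vec dbd2 = arma::sum(dlogit, 1);
  arma::mat dad = q.Wd2.t() * dlogit;
  arma::mat dapre = (dad % M3) % arma::conv_to<arma::mat>::from(apre > 0);
  arma::mat dWd1 = dapre * featd.t();
  arma::vec dbd1 = arma::sum(dapre, 1);
  arma::mat dfeat = (q.Wd1.t() * dapre) % M2;  // 2H x B

  arma::mat dH2f(H, (arma::uword)T * B, arma::fill::zeros);
  arma::mat dH2b(H, (arma::uword)T * B, arma::fill::zeros);
  dH2f.cols(last0, last0 + B - 1) = dfeat.rows(0, H - 1);
  dH2b.cols(last0, last0 + B - 1) = dfeat.rows(H, 2 * H - 1);

  arma::mat dW2f(arma::size(q.W2f), arma::fill::zeros), dU2f(arma::size(q.U2f), arma::fill::zeros);
  arma::mat dW2b(arma::size(q.W2b), arma::fill::zeros), dU2b(arma::size(q.U2b), arma::fill::zeros);
  arma::mat dW1f(arma::size(q.W1f), arma::fill::zeros), dU1f(arma::size(q.U1f), arma::fill::zeros);
  arma::mat dW1b(arma::size(q.W1b), arma::fill::zeros), dU1b(arma::size(q.U1b), arma::fill::zeros);
  arma::vec db2f(q.b2f.n_elem, arma::fill::zeros), db2b(q.b2b.n_elem, arma::fill::zeros);
  arma::vec db1f(q.b1f.n_elem, arma::fill::zeros), db1b(q.b1b.n_elem, arma::fill::zeros);

  arma::mat dO1d = lstm_backward(q.W2f, q.U2f, O1d, f2, dH2f, T, B,
                                 dW2f, dU2f, db2f);
  arma::mat dO1d_r = lstm_backward(q.W2b, q.U2b, O1dr, b2, dH2b, T, B,
                                   dW2b, dU2b, db2b);
  dO1d += flip_blocks(dO1d_r, T, B);
  arma::mat dO1 = dO1d % M1;

  arma::mat dH1f = dO1.rows(0, H - 1);
  arma::mat dH1b = flip_blocks(dO1.rows(H, 2 * H - 1), T, B);
  lstm_backward(q.W1f, q.U1f, X, f1, dH1f, T, B, dW1f, dU1f, db1f);
  lstm_backward(q.W1b, q.U1b, Xr, b1, dH1b, T, B, dW1b, dU1b, db1b);

  List grads = List::create(
    _["W1f"] = dW1f, _["U1f"] = dU1f, _["b1f"] = db1f,
    _["W1b"] = dW1b, _["U1b"] = dU1b, _["b1b"] = db1b,
    _["W2f"] = dW2f, _["U2f"] = dU2f, _["b2f"] = db2f,
    _["W2b"] = dW2b, _["U2b"] = dU2b, _["b2b"] = db2b,
    _["Wd1"] = dWd1, _["bd1"] = dbd1,
    _["Wd2"] = dWd2, _["bd2"] = dbd2);
  return List::create(_["loss"] = total_loss, _["n"] = B,
                      _["grads"] = grads);
}
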