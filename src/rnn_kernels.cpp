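// Native BiLSTM sequence-regression kernels.
//
// Architecture (fixed topology, sizes from the R-side spec):
//   input (C channels per node) -> BiLSTM(H1) -> dropout -> BiLSTM(H2)
//   -> dropout -> FC(F1, tanh) -> FC(F2, tanh) -> FC(2, linear)
// applied per node of the 101-node sequence.  Gate order in the stacked
// weight matrices is (input, forget, candidate, output).
//
// Layout: sequences are passed as cubes (rows = channels, cols = batch,
// slices = time) and flattened internally to (channels x batch*time)
// matrices so that input projections, the fully connected stack and the
// weight-gradient accumulations run as single GEMMs; only the recurrent
// h-to-h path iterates over time.  The kernels are templated on the
// element type: single precision is the training default, the double
// instantiation backs the finite-difference gradient checks.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

template <typename eT>
static inline Mat<eT> sigm(const Mat<eT>& x) {
  return eT(1) / (eT(1) + exp(-x));
}

template <typename eT>
struct LSTMCache {
  Mat<eT> gates;  // 4H x B*T (post-activation)
  Mat<eT> c;      // H x B*T
  Mat<eT> h;      // H x B*T
};

// One direction over the full sequence; X is C x B*T (time-major blocks).
template <typename eT>
static void lstm_forward(const Mat<eT>& W, const Mat<eT>& U,
                         const Col<eT>& b, const Mat<eT>& X, uword B,
                         uword T, bool reverse, LSTMCache<eT>& cc) {
  const uword H = U.n_cols;
  Mat<eT> Zin = W * X;           // bulk input projection
  Zin.each_col() += b;
  cc.gates.set_size(4 * H, B * T);
  cc.c.set_size(H, B * T);
  cc.h.set_size(H, B * T);
  Mat<eT> h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    const uword t = reverse ? (T - 1 - step) : step;
    const uword a = t * B, e = (t + 1) * B - 1;
    Mat<eT> z = Zin.cols(a, e) + U * h_prev;
    Mat<eT> i = sigm<eT>(z.rows(0, H - 1));
    Mat<eT> f = sigm<eT>(z.rows(H, 2 * H - 1));
    Mat<eT> g = tanh(z.rows(2 * H, 3 * H - 1));
    Mat<eT> o = sigm<eT>(z.rows(3 * H, 4 * H - 1));
    c_prev = f % c_prev + i % g;
    h_prev = o % tanh(c_prev);
    cc.gates.submat(0, a, H - 1, e) = i;
    cc.gates.submat(H, a, 2 * H - 1, e) = f;
    cc.gates.submat(2 * H, a, 3 * H - 1, e) = g;
    cc.gates.submat(3 * H, a, 4 * H - 1, e) = o;
    cc.c.cols(a, e) = c_prev;
    cc.h.cols(a, e) = h_prev;
  }
}

// Backward pass of one direction; dH holds gradients w.r.t. the hidden
// states (H x B*T).  Fills dW, dU, db and returns dX unless skip_dx.
template <typename eT>
static Mat<eT> lstm_backward(const Mat<eT>& W, const Mat<eT>& U,
                             const Mat<eT>& X, const LSTMCache<eT>& cc,
                             const Mat<eT>& dH, uword B, uword T,
                             bool reverse, Mat<eT>& dW, Mat<eT>& dU,
                             Col<eT>& db, bool skip_dx) {
  const uword H = U.n_cols;
  Mat<eT> DZ(4 * H, B * T);
  Mat<eT> Hprev(H, B * T, fill::zeros);  // h_{t-1} aligned with t
  Mat<eT> dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    const uword t = reverse ? step : (T - 1 - step);  // reverse of forward
    const uword a = t * B, e = (t + 1) * B - 1;
    Mat<eT> i = cc.gates.submat(0, a, H - 1, e);
    Mat<eT> f = cc.gates.submat(H, a, 2 * H - 1, e);
    Mat<eT> g = cc.gates.submat(2 * H, a, 3 * H - 1, e);
    Mat<eT> o = cc.gates.submat(3 * H, a, 4 * H - 1, e);
    Mat<eT> tc = tanh(cc.c.cols(a, e));
    Mat<eT> dh = dH.cols(a, e) + dh_next;
    Mat<eT> dc = dc_next + dh % o % (eT(1) - tc % tc);
    const bool has_prev = step < T - 1;
    Mat<eT> c_prev(H, B, fill::zeros);
    if (has_prev) {
      const uword tp = reverse ? t + 1 : t - 1;
      c_prev = cc.c.cols(tp * B, (tp + 1) * B - 1);
      Hprev.cols(a, e) = cc.h.cols(tp * B, (tp + 1) * B - 1);
    }
    Mat<eT> dz(4 * H, B);
    dz.rows(0, H - 1) = (dc % g) % i % (eT(1) - i);
    dz.rows(H, 2 * H - 1) = (dc % c_prev) % f % (eT(1) - f);
    dz.rows(2 * H, 3 * H - 1) = (dc % i) % (eT(1) - g % g);
    dz.rows(3 * H, 4 * H - 1) = (dh % tc) % o % (eT(1) - o);
    DZ.cols(a, e) = dz;
    dh_next = U.t() * dz;
    dc_next = dc % f;
  }
  dW = DZ * X.t();
  dU = DZ * Hprev.t();
  db = sum(DZ, 1);
  if (skip_dx) return Mat<eT>();
  return W.t() * DZ;
}

template <typename eT>
struct Net {
  Mat<eT> Wf1, Uf1, Wb1, Ub1, Wf2, Uf2, Wb2, Ub2, Wfc1, Wfc2, Wfc3;
  Col<eT> bf1, bb1, bf2, bb2, bfc1, bfc2, bfc3;
};

template <typename eT>
static Mat<eT> getm(const Rcpp::List& p, const char* nm) {
  return conv_to<Mat<eT>>::from(Rcpp::as<mat>(p[nm]));
}
template <typename eT>
static Col<eT> getv(const Rcpp::List& p, const char* nm) {
  return conv_to<Col<eT>>::from(Rcpp::as<vec>(p[nm]));
}

template <typename eT>
static Net<eT> unpack(const Rcpp::List& p) {
  Net<eT> n;
  n.Wf1 = getm<eT>(p, "Wf1"); n.Uf1 = getm<eT>(p, "Uf1");
  n.bf1 = getv<eT>(p, "bf1");
  n.Wb1 = getm<eT>(p, "Wb1"); n.Ub1 = getm<eT>(p, "Ub1");
  n.bb1 = getv<eT>(p, "bb1");
  n.Wf2 = getm<eT>(p, "Wf2"); n.Uf2 = getm<eT>(p, "Uf2");
  n.bf2 = getv<eT>(p, "bf2");
  n.Wb2 = getm<eT>(p, "Wb2"); n.Ub2 = getm<eT>(p, "Ub2");
  n.bb2 = getv<eT>(p, "bb2");
  n.Wfc1 = getm<eT>(p, "Wfc1"); n.bfc1 = getv<eT>(p, "bfc1");
  n.Wfc2 = getm<eT>(p, "Wfc2"); n.bfc2 = getv<eT>(p, "bfc2");
  n.Wfc3 = getm<eT>(p, "Wfc3"); n.bfc3 = getv<eT>(p, "bfc3");
  return n;
}

template <typename eT>
static cube forward_impl(const Rcpp::List& params, const cube& X) {
  Net<eT> n = unpack<eT>(params);
  const uword B = X.n_cols, T = X.n_slices;
  Mat<eT> Xf = conv_to<Mat<eT>>::from(
    mat(const_cast<double*>(X.memptr()), X.n_rows, B * T, false));
  LSTMCache<eT> cf1, cb1, cf2, cb2;
  lstm_forward<eT>(n.Wf1, n.Uf1, n.bf1, Xf, B, T, false, cf1);
  lstm_forward<eT>(n.Wb1, n.Ub1, n.bb1, Xf, B, T, true, cb1);
  Mat<eT> O1 = join_cols(cf1.h, cb1.h);
  lstm_forward<eT>(n.Wf2, n.Uf2, n.bf2, O1, B, T, false, cf2);
  lstm_forward<eT>(n.Wb2, n.Ub2, n.bb2, O1, B, T, true, cb2);
  Mat<eT> O2 = join_cols(cf2.h, cb2.h);
  Mat<eT> A1 = n.Wfc1 * O2;  A1.each_col() += n.bfc1;  A1 = tanh(A1);
  Mat<eT> A2 = n.Wfc2 * A1;  A2.each_col() += n.bfc2;  A2 = tanh(A2);
  Mat<eT> Ym = n.Wfc3 * A2;  Ym.each_col() += n.bfc3;
  mat Yd = conv_to<mat>::from(Ym);
  return cube(Yd.memptr(), n.Wfc3.n_rows, B, T);
}

// Forward pass at inference (no dropout).
// [[Rcpp::export(name = ".rnn_forward")]]
arma::cube rnn_forward_cpp(Rcpp::List params, arma::cube X,
                           bool single = true) {
  return single ? forward_impl<float>(params, X)
                : forward_impl<double>(params, X);
}

template <typename eT>
static Rcpp::List loss_grad_impl(const Rcpp::List& params, const cube& X,
                                 const cube& Ytrue, const cube& mask1,
                                 const cube& mask2) {
  Net<eT> n = unpack<eT>(params);
  const uword B = X.n_cols, T = X.n_slices;
  const uword H1 = n.Uf1.n_cols, H2 = n.Uf2.n_cols;
  const bool use_m1 = mask1.n_elem > 1, use_m2 = mask2.n_elem > 1;
  Mat<eT> Xf = conv_to<Mat<eT>>::from(
    mat(const_cast<double*>(X.memptr()), X.n_rows, B * T, false));
  Mat<eT> Yt = conv_to<Mat<eT>>::from(
    mat(const_cast<double*>(Ytrue.memptr()), Ytrue.n_rows, B * T, false));

  LSTMCache<eT> cf1, cb1, cf2, cb2;
  lstm_forward<eT>(n.Wf1, n.Uf1, n.bf1, Xf, B, T, false, cf1);
  lstm_forward<eT>(n.Wb1, n.Ub1, n.bb1, Xf, B, T, true, cb1);
  Mat<eT> O1 = join_cols(cf1.h, cb1.h);
  Mat<eT> M1, M2;
  if (use_m1) {
    M1 = conv_to<Mat<eT>>::from(
      mat(const_cast<double*>(mask1.memptr()), 2 * H1, B * T, false));
    O1 %= M1;
  }
  lstm_forward<eT>(n.Wf2, n.Uf2, n.bf2, O1, B, T, false, cf2);
  lstm_forward<eT>(n.Wb2, n.Ub2, n.bb2, O1, B, T, true, cb2);
  Mat<eT> O2 = join_cols(cf2.h, cb2.h);
  if (use_m2) {
    M2 = conv_to<Mat<eT>>::from(
      mat(const_cast<double*>(mask2.memptr()), 2 * H2, B * T, false));
    O2 %= M2;
  }
  Mat<eT> A1 = n.Wfc1 * O2;  A1.each_col() += n.bfc1;  A1 = tanh(A1);
  Mat<eT> A2 = n.Wfc2 * A1;  A2.each_col() += n.bfc2;  A2 = tanh(A2);
  Mat<eT> Y = n.Wfc3 * A2;   Y.each_col() += n.bfc3;

  Mat<eT> E = Y - Yt;
  const double denom = (double)E.n_elem;
  const double loss = accu(conv_to<mat>::from(E % E)) / denom;

  // FC stack backward (bulk)
  Mat<eT> dY = (eT)(2.0 / denom) * E;
  Mat<eT> dWfc3 = dY * A2.t();
  Col<eT> dbfc3 = sum(dY, 1);
  Mat<eT> dA2 = (n.Wfc3.t() * dY) % (eT(1) - A2 % A2);
  Mat<eT> dWfc2 = dA2 * A1.t();
  Col<eT> dbfc2 = sum(dA2, 1);
  Mat<eT> dA1 = (n.Wfc2.t() * dA2) % (eT(1) - A1 % A1);
  Mat<eT> dWfc1 = dA1 * O2.t();
  Col<eT> dbfc1 = sum(dA1, 1);
  Mat<eT> dO2 = n.Wfc1.t() * dA1;
  if (use_m2) dO2 %= M2;

  Mat<eT> dWf2, dUf2, dWb2, dUb2;
  Col<eT> dbf2, dbb2;
  Mat<eT> dO1 = lstm_backward<eT>(n.Wf2, n.Uf2, O1, cf2,
                                  dO2.rows(0, H2 - 1), B, T, false, dWf2,
                                  dUf2, dbf2, false);
  dO1 += lstm_backward<eT>(n.Wb2, n.Ub2, O1, cb2, dO2.rows(H2, 2 * H2 - 1),
                           B, T, true, dWb2, dUb2, dbb2, false);
  if (use_m1) dO1 %= M1;

  Mat<eT> dWf1, dUf1, dWb1, dUb1;
  Col<eT> dbf1, dbb1;
  lstm_backward<eT>(n.Wf1, n.Uf1, Xf, cf1, dO1.rows(0, H1 - 1), B, T, false,
                    dWf1, dUf1, dbf1, true);
  lstm_backward<eT>(n.Wb1, n.Ub1, Xf, cb1, dO1.rows(H1, 2 * H1 - 1), B, T,
                    true, dWb1, dUb1, dbb1, true);

  auto wm = [](const Mat<eT>& m) { return Rcpp::wrap(conv_to<mat>::from(m)); };
  auto wv = [](const Col<eT>& v) { return Rcpp::wrap(conv_to<vec>::from(v)); };
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("Wf1") = wm(dWf1), Rcpp::Named("Uf1") = wm(dUf1),
      Rcpp::Named("bf1") = wv(dbf1), Rcpp::Named("Wb1") = wm(dWb1),
      Rcpp::Named("Ub1") = wm(dUb1), Rcpp::Named("bb1") = wv(dbb1),
      Rcpp::Named("Wf2") = wm(dWf2), Rcpp::Named("Uf2") = wm(dUf2),
      Rcpp::Named("bf2") = wv(dbf2), Rcpp::Named("Wb2") = wm(dWb2),
      Rcpp::Named("Ub2") = wm(dUb2), Rcpp::Named("bb2") = wv(dbb2),
      Rcpp::Named("Wfc1") = wm(dWfc1), Rcpp::Named("bfc1") = wv(dbfc1),
      Rcpp::Named("Wfc2") = wm(dWfc2), Rcpp::Named("bfc2") = wv(dbfc2),
      Rcpp::Named("Wfc3") = wm(dWfc3), Rcpp::Named("bfc3") = wv(dbfc3)));
}

// Training step: forward with dropout masks, MSE loss, full backward pass.
// mask1/mask2 are inverted-dropout masks (entries 0 or 1/(1-p)) with the
// same layout as the respective BiLSTM outputs; pass 1x1x1 cubes to
// disable.
// [[Rcpp::export(name = ".rnn_loss_grad")]]
Rcpp::List rnn_loss_grad_cpp(Rcpp::List params, arma::cube X,
                             arma::cube Ytrue, arma::cube mask1,
                             arma::cube mask2, bool single = true) {
  return single ? loss_grad_impl<float>(params, X, Ytrue, mask1, mask2)
                : loss_grad_impl<double>(params, X, Ytrue, mask1, mask2);
}
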