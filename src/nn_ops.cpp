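// Compiled kernels for the two classifiers: masked batched LSTM layer
// (forward + backward-through-time), length-preserving kernel-3 1-D
// convolution, and stride-k max pooling. Orchestration, Adam and the model
// definitions live in R; these routines only carry the hot loops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// A: (B x D x T) cube of step inputs; lens: true step count per sequence.
// Gate order in the 4H pre-activation: input, forget, cell, output.
// Sequences past their length keep a frozen state, so h equals each
// sequence's hidden state at its own last step.
// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& A, const arma::ivec& lens,
                            const arma::mat& W, const arma::mat& U,
                            const arma::vec& b, bool keep_cache) {
  const uword B = A.n_rows, T = A.n_slices;
  const uword H = U.n_rows;
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  cube I, F, G, O, TC, CP, HP;
  mat M(B, T, fill::zeros);
  if (keep_cache) {
    I.set_size(B, H, T); F.set_size(B, H, T); G.set_size(B, H, T);
    O.set_size(B, H, T); TC.set_size(B, H, T);
    CP.set_size(B, H, T); HP.set_size(B, H, T);
  }
  for (uword t = 0; t < T; ++t) {
    mat Z = A.slice(t) * W + h * U;
    Z.each_row() += b.t();
    mat i = 1.0 / (1.0 + exp(-Z.cols(0, H - 1)));
    mat f = 1.0 / (1.0 + exp(-Z.cols(H, 2 * H - 1)));
    mat g = tanh(Z.cols(2 * H, 3 * H - 1));
    mat o = 1.0 / (1.0 + exp(-Z.cols(3 * H, 4 * H - 1)));
    mat c_new = f % c + i % g;
    mat tc = tanh(c_new);
    mat h_new = o % tc;
    vec m(B);
    for (uword r = 0; r < B; ++r) m(r) = (lens(r) >= (sword)(t + 1)) ? 1.0 : 0.0;
    if (keep_cache) {
      I.slice(t) = i; F.slice(t) = f; G.slice(t) = g; O.slice(t) = o;
      TC.slice(t) = tc; CP.slice(t) = c; HP.slice(t) = h;
      M.col(t) = m;
    }
    c = c_new.each_col() % m + c.each_col() % (1.0 - m);
    h = h_new.each_col() % m + h.each_col() % (1.0 - m);
  }
  if (keep_cache) {
    return Rcpp::List::create(
        Rcpp::Named("h") = h, Rcpp::Named("I") = I, Rcpp::Named("F") = F,
        Rcpp::Named("G") = G, Rcpp::Named("O") = O, Rcpp::Named("TC") = TC,
        Rcpp::Named("CP") = CP, Rcpp::Named("HP") = HP, Rcpp::Named("M") = M);
  }
  return Rcpp::List::create(Rcpp::Named("h") = h);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& A, const Rcpp::List& cache,
                             const arma::mat& dH_last, const arma::mat& W,
                             const arma::mat& U, bool need_dx) {
  const uword B = A.n_rows, D = A.n_cols, T = A.n_slices;
  const uword H = U.n_rows;
  const cube I = cache["I"], F = cache["F"], G = cache["G"], O = cache["O"],
             TC = cache["TC"], CP = cache["CP"], HP = cache["HP"];
  const mat M = cache["M"];
  mat dW(D, 4 * H, fill::zeros), dU(H, 4 * H, fill::zeros);
  rowvec db(4 * H, fill::zeros);
  cube dX;
  if (need_dx) dX.zeros(B, D, T);
  mat dh = dH_last, dc(B, H, fill::zeros);
  for (uword ti = T; ti-- > 0;) {
    vec m = M.col(ti);
    mat dh_new = dh.each_col() % m;
    mat dh_pass = dh.each_col() % (1.0 - m);
    mat dc_new = dc.each_col() % m;
    mat dc_pass = dc.each_col() % (1.0 - m);
    const mat& i = I.slice(ti); const mat& f = F.slice(ti);
    const mat& g = G.slice(ti); const mat& o = O.slice(ti);
    const mat& tc = TC.slice(ti); const mat& cp = CP.slice(ti);
    mat do_ = dh_new % tc;
    dc_new += dh_new % o % (1.0 - tc % tc);
    mat df = dc_new % cp;
    mat di = dc_new % g;
    mat dg = dc_new % i;
    mat dc_prev = dc_new % f;
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = di % i % (1.0 - i);
    dz.cols(H, 2 * H - 1) = df % f % (1.0 - f);
    dz.cols(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    dz.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dW += A.slice(ti).t() * dz;
    dU += HP.slice(ti).t() * dz;
    db += sum(dz, 0);
    if (need_dx) dX.slice(ti) = dz * W.t();
    dh = dz * U.t() + dh_pass;
    dc = dc_prev + dc_pass;
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("dW") = dW, Rcpp::Named("dU") = dU,
      Rcpp::Named("db") = db.t());
  if (need_dx) out["dX"] = dX;
  return out;
}

// Length-preserving kernel-3 conv over rows of X (time x channels):
// Y[t] = X[t-1] W1 + X[t] W2 + X[t+1] W3 + b (zero-padded edges).
// [[Rcpp::export]]
arma::mat conv1d_forward_cpp(const arma::mat& X, const arma::mat& W1,
                             const arma::mat& W2, const arma::mat& W3,
                             const arma::vec& b, bool apply_relu) {
  const uword T = X.n_rows;
  mat Y = X * W2;
  if (T > 1) {
    Y.rows(1, T - 1) += X.rows(0, T - 2) * W1;
    Y.rows(0, T - 2) += X.rows(1, T - 1) * W3;
  }
  Y.each_row() += b.t();
  if (apply_relu) Y.elem(find(Y < 0)).zeros();
  return Y;
}

// Backward through (ReLU o conv). Yact is the post-ReLU output from the
// forward pass; dY is modified by the ReLU mask internally.
// [[Rcpp::export]]
Rcpp::List conv1d_backward_cpp(const arma::mat& X, arma::mat dY,
                               const arma::mat& Yact, const arma::mat& W1,
                               const arma::mat& W2, const arma::mat& W3) {
  const uword T = X.n_rows;
  dY.elem(find(Yact <= 0)).zeros();
  mat dW1(size(W1), fill::zeros), dW3(size(W3), fill::zeros);
  mat dW2 = X.t() * dY;
  if (T > 1) {
    dW1 = X.rows(0, T - 2).t() * dY.rows(1, T - 1);
    dW3 = X.rows(1, T - 1).t() * dY.rows(0, T - 2);
  }
  vec db = sum(dY, 0).t();
  mat dX = dY * W2.t();
  if (T > 1) {
    dX.rows(0, T - 2) += dY.rows(1, T - 1) * W1.t();
    dX.rows(1, T - 1) += dY.rows(0, T - 2) * W3.t();
  }
  return Rcpp::List::create(Rcpp::Named("dW1") = dW1, Rcpp::Named("dW2") = dW2,
                            Rcpp::Named("dW3") = dW3, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}

// Max pool rows by factor k (stride k); remainder rows dropped. Returns the
// pooled matrix and 1-based winning source row per (position, channel).
// [[Rcpp::export]]
Rcpp::List maxpool_forward_cpp(const arma::mat& X, int k) {
  const uword Tn = X.n_rows / k, C = X.n_cols;
  mat Y(Tn, C);
  umat src(Tn, C);
  for (uword c = 0; c < C; ++c) {
    for (uword t = 0; t < Tn; ++t) {
      uword best = t * k;
      double bv = X(best, c);
      for (uword j = 1; j < (uword)k; ++j) {
        double v = X(t * k + j, c);
        if (v > bv) { bv = v; best = t * k + j; }
      }
      Y(t, c) = bv;
      src(t, c) = best + 1;
    }
  }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("src_row") = src);
}

// [[Rcpp::export]]
arma::mat maxpool_backward_cpp(const arma::umat& src, const arma::mat& dY,
                               int n_rows_in) {
  mat dX(n_rows_in, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c)
    for (uword t = 0; t < dY.n_rows; ++t)
      dX(src(t, c) - 1, c) += dY(t, c);
  return dX;
}
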