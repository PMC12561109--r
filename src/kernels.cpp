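// Compiled kernels for the hot paths of the autograd engine: scaled
// dot-product multi-head attention and strided 1-D convolution (im2col).
// Activations use the package's sample-major 2-D layout: row r = (b-1)*T + t.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// Scores are held transposed (Tk x Tq, one column per query) so the softmax
// reductions run down columns (contiguous in memory) and both products are
// plain GEMMs.
// [[Rcpp::export]]
List attn_forward_cpp(const arma::mat& Q, const arma::mat& K, const arma::mat& V,
                      int B, int Tq, int Tk, int H) {
  const int E = Q.n_cols;
  const int dh = E / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat out(B * Tq, E, fill::zeros);
  cube A(Tk, Tq, B * H);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      mat Qb = Q.submat(b * Tq, h * dh, (b + 1) * Tq - 1, (h + 1) * dh - 1);
      mat Kb = K.submat(b * Tk, h * dh, (b + 1) * Tk - 1, (h + 1) * dh - 1);
      mat Vb = V.submat(b * Tk, h * dh, (b + 1) * Tk - 1, (h + 1) * dh - 1);
      mat S = Kb * Qb.t() * scale;          // Tk x Tq
      S.each_row() -= max(S, 0);
      S = exp(S);
      S.each_row() /= sum(S, 0);
      A.slice(b * H + h) = S;
      out.submat(b * Tq, h * dh, (b + 1) * Tq - 1, (h + 1) * dh - 1) = S.t() * Vb;
    }
  }
  return List::create(_["out"] = out, _["A"] = A);
}

// [[Rcpp::export]]
List attn_backward_cpp(const arma::mat& G, const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::cube& A,
                       int B, int Tq, int Tk, int H) {
  const int E = Q.n_cols;
  const int dh = E / H;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat gq(size(Q), fill::zeros), gk(size(K), fill::zeros), gv(size(V), fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      const mat& S = A.slice(b * H + h);    // Tk x Tq
      mat Gc = G.submat(b * Tq, h * dh, (b + 1) * Tq - 1, (h + 1) * dh - 1);
      mat Qb = Q.submat(b * Tq, h * dh, (b + 1) * Tq - 1, (h + 1) * dh - 1);
      mat Kb = K.submat(b * Tk, h * dh, (b + 1) * Tk - 1, (h + 1) * dh - 1);
      mat Vb = V.submat(b * Tk, h * dh, (b + 1) * Tk - 1, (h + 1) * dh - 1);
      gv.submat(b * Tk, h * dh, (b + 1) * Tk - 1, (h + 1) * dh - 1) = S * Gc;
      mat dA = Vb * Gc.t();                 // Tk x Tq
      rowvec cs = sum(dA % S, 0);
      mat dS = (dA.each_row() - cs) % S * scale;
      gq.submat(b * Tq, h * dh, (b + 1) * Tq - 1, (h + 1) * dh - 1) = dS.t() * Kb;
      gk.submat(b * Tk, h * dh, (b + 1) * Tk - 1, (h + 1) * dh - 1) = dS * Qb;
    }
  }
  return List::create(_["gq"] = gq, _["gk"] = gk, _["gv"] = gv);
}

// x: [B, Cin, T] cube; W: [Kk, Cin, Cout] cube; returns the output cube
// [B, Cout, Tout] and the im2col matrix cached for the backward pass.
// Column layout of Xcol: (k-1)*Cin + cin; row layout: (b-1)*Tout + t.
// [[Rcpp::export]]
List conv1d_forward_cpp(const arma::cube& x, const arma::cube& W,
                        const arma::vec& bias, int stride, int padl) {
  const int B = x.n_rows, Cin = x.n_cols, T = x.n_slices;
  const int Kk = W.n_rows, Cout = W.n_slices;
  const int Tout = (T + stride - 1) / stride;
  mat Xcol(B * Tout, Cin * Kk, fill::zeros);
  for (int k = 0; k < Kk; ++k) {
    for (int t = 0; t < Tout; ++t) {
      int ti = t * stride + k - padl;
      if (ti < 0 || ti >= T) continue;
      // x.slice(ti) is B x Cin
      const mat& sl = x.slice(ti);
      for (int c = 0; c < Cin; ++c)
        for (int b = 0; b < B; ++b)
          Xcol(b * Tout + t, k * Cin + c) = sl(b, c);
    }
  }
  mat Wm(Cin * Kk, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < Kk; ++k)
      for (int c = 0; c < Cin; ++c)
        Wm(k * Cin + c, o) = W(k, c, o);
  mat Ym = Xcol * Wm;
  Ym.each_row() += bias.t();
  cube out(B, Cout, Tout);
  for (int t = 0; t < Tout; ++t)
    for (int o = 0; o < Cout; ++o)
      for (int b = 0; b < B; ++b)
        out(b, o, t) = Ym(b * Tout + t, o);
  return List::create(_["out"] = out, _["Xcol"] = Xcol);
}

// [[Rcpp::export]]
List conv1d_backward_cpp(const arma::cube& g, const arma::mat& Xcol,
                         const arma::cube& W, int B, int Cin, int T,
                         int stride, int padl) {
  const int Cout = g.n_cols, Tout = g.n_slices;
  const int Kk = W.n_rows;
  mat Gm(B * Tout, Cout);
  for (int t = 0; t < Tout; ++t)
    for (int o = 0; o < Cout; ++o)
      for (int b = 0; b < B; ++b)
        Gm(b * Tout + t, o) = g(b, o, t);
  mat gWm = Xcol.t() * Gm;                       // (Cin*Kk) x Cout
  cube gW(Kk, Cin, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < Kk; ++k)
      for (int c = 0; c < Cin; ++c)
        gW(k, c, o) = gWm(k * Cin + c, o);
  vec gb = sum(Gm, 0).t();
  mat Wm(Cin * Kk, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int k = 0; k < Kk; ++k)
      for (int c = 0; c < Cin; ++c)
        Wm(k * Cin + c, o) = W(k, c, o);
  mat gXcol = Gm * Wm.t();                       // (B*Tout) x (Cin*Kk)
  cube gx(B, Cin, T, fill::zeros);
  for (int k = 0; k < Kk; ++k) {
    for (int t = 0; t < Tout; ++t) {
      int ti = t * stride + k - padl;
      if (ti < 0 || ti >= T) continue;
      for (int c = 0; c < Cin; ++c)
        for (int b = 0; b < B; ++b)
          gx(b, c, ti) += gXcol(b * Tout + t, k * Cin + c);
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
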