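// Compute kernels for the network engine: im2col convolution, overlapping
// max pooling, and a single-precision gemm helper for the fully connected
// layers. Activations are D x N matrices (one column per sample) flattened
// in (H, W, channel) order; gather indices are precomputed in R (1-based
// into the padded buffer). Matrix products run in single precision - the
// usual arithmetic for CNN training - which roughly doubles throughput on
// one core; parameters and activations remain double at the R interface.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::fmat gather_cols(const arma::mat& Mp, const IntegerMatrix& idx) {
  const int K = idx.nrow(), P = idx.ncol();
  const arma::uword N = Mp.n_cols;
  arma::fmat Xcol(K, (arma::uword)P * N);
  for (arma::uword n = 0; n < N; ++n) {
    const double* col = Mp.colptr(n);
    for (int p = 0; p < P; ++p) {
      float* dst = Xcol.colptr((arma::uword)p + (arma::uword)P * n);
      const int* ip = &idx(0, p);
      for (int k = 0; k < K; ++k) dst[k] = (float)col[ip[k] - 1];
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
List nn_conv_fwd(const arma::mat& Mp, const IntegerMatrix& idx,
                 const arma::mat& W, const arma::vec& b,
                 const bool keep_cols) {
  const int P = idx.ncol();
  const arma::uword N = Mp.n_cols, Cout = W.n_cols;
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fvec bf = arma::conv_to<arma::fvec>::from(b);
  arma::fmat* Xcol = new arma::fmat(gather_cols(Mp, idx));
  arma::fmat Z = Wf.t() * (*Xcol);      // Cout x (P*N)
  Z.each_col() += bf;
  arma::mat out((arma::uword)P * Cout, N);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword co = 0; co < Cout; ++co) {
      const arma::uword zc = (arma::uword)P * n;
      double* dst = out.colptr(n) + (arma::uword)P * co;
      for (int p = 0; p < P; ++p) dst[p] = (double)Z(co, zc + p);
    }
  }
  if (!keep_cols) {
    delete Xcol;
    return List::create(_["out"] = out);
  }
  // hand the im2col buffer back as an external pointer so the backward
  // pass can reuse it without regathering
  Rcpp::XPtr<arma::fmat> xp(Xcol, true);
  return List::create(_["out"] = out, _["xcol"] = xp);
}

// [[Rcpp::export]]
List nn_conv_bwd(SEXP xcol_ptr, const IntegerMatrix& idx,
                 const arma::mat& W, const arma::mat& dout,
                 const int dpad) {
  Rcpp::XPtr<arma::fmat> Xcol(xcol_ptr);
  const int K = idx.nrow(), P = idx.ncol();
  const arma::uword N = dout.n_cols, Cout = W.n_cols;
  arma::fmat Wf = arma::conv_to<arma::fmat>::from(W);
  arma::fmat dZ(Cout, (arma::uword)P * N);
  for (arma::uword n = 0; n < N; ++n) {
    for (arma::uword co = 0; co < Cout; ++co) {
      const double* src = dout.colptr(n) + (arma::uword)P * co;
      for (int p = 0; p < P; ++p)
        dZ(co, (arma::uword)P * n + p) = (float)src[p];
    }
  }
  arma::fmat dWf = (*Xcol) * dZ.t();
  arma::fvec dbf = arma::sum(dZ, 1);
  arma::fmat dXcol = Wf * dZ;           // K x (P*N)
  arma::mat dMp(dpad, N, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n) {
    double* acc = dMp.colptr(n);
    for (int p = 0; p < P; ++p) {
      const float* src = dXcol.colptr((arma::uword)p + (arma::uword)P * n);
      const int* ip = &idx(0, p);
      for (int k = 0; k < K; ++k) acc[ip[k] - 1] += (double)src[k];
    }
  }
  return List::create(_["dW"] = arma::conv_to<arma::mat>::from(dWf),
                      _["db"] = arma::conv_to<arma::vec>::from(dbf),
                      _["dX"] = dMp);
}

// [[Rcpp::export]]
List nn_pool_fwd(const arma::mat& Mp, const IntegerMatrix& idx) {
  const int z2 = idx.nrow(), Q = idx.ncol();
  const arma::uword N = Mp.n_cols;
  arma::mat out(Q, N);
  IntegerMatrix amax(Q, N);
  for (arma::uword n = 0; n < N; ++n) {
    const double* col = Mp.colptr(n);
    double* o = out.colptr(n);
    for (int q = 0; q < Q; ++q) {
      const int* ip = &idx(0, q);
      double best = col[ip[0] - 1];
      int bk = 0;
      for (int k = 1; k < z2; ++k) {
        const double v = col[ip[k] - 1];
        if (v > best) { best = v; bk = k; }
      }
      o[q] = best;
      amax(q, n) = bk + 1;              // 1-based for the R side
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
arma::mat nn_pool_bwd(const arma::mat& dout, const IntegerMatrix& idx,
                      const IntegerMatrix& amax, const int dpad) {
  const int Q = idx.ncol();
  const arma::uword N = dout.n_cols;
  arma::mat dMp(dpad, N, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n) {
    const double* g = dout.colptr(n);
    double* acc = dMp.colptr(n);
    for (int q = 0; q < Q; ++q) {
      acc[idx(amax(q, n) - 1, q) - 1] += g[q];
    }
  }
  return dMp;
}

// Single-precision matrix product op(A) * op(B), returned as double.
// [[Rcpp::export]]
arma::mat nn_sgemm(const arma::mat& A, const arma::mat& B,
                   const bool ta, const bool tb) {
  arma::fmat Af = arma::conv_to<arma::fmat>::from(A);
  arma::fmat Bf = arma::conv_to<arma::fmat>::from(B);
  arma::fmat C;
  if (!ta && !tb)      C = Af * Bf;
  else if (ta && !tb)  C = Af.t() * Bf;
  else if (!ta && tb)  C = Af * Bf.t();
  else                 C = Af.t() * Bf.t();
  return arma::conv_to<arma::mat>::from(C);
}

// Sliding cross-channel window sum for local response normalization.
// A is (S*C) x N with channel-major stride S; window is [c-half, c+half].
// [[Rcpp::export]]
arma::mat nn_lrn_wsum(const arma::mat& A, const int S, const int C,
                      const int half) {
  const arma::uword N = A.n_cols;
  arma::mat out(A.n_rows, N, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n) {
    const double* a = A.colptr(n);
    double* o = out.colptr(n);
    for (int c = 0; c < C; ++c) {
      const int lo = std::max(0, c - half), hi = std::min(C - 1, c + half);
      double* oc = o + (arma::uword)S * c;
      for (int d = lo; d <= hi; ++d) {
        const double* ad = a + (arma::uword)S * d;
        for (int s = 0; s < S; ++s) oc[s] += ad[s];
      }
    }
  }
  return out;
}

// In-place momentum-SGD step: V = mom*V - lr*(G + wd*W); W += V.
// Mutates W and V directly (they are owned exclusively by the training
// loop), avoiding large temporaries for the fc-layer weight matrices.
// [[Rcpp::export]]
void nn_sgd_step(NumericVector W, NumericVector V, const NumericVector& G,
                 const double lr, const double mom, const double wd) {
  const R_xlen_t n = W.size();
  double* w = REAL(W);
  double* v = REAL(V);
  const double* g = REAL(G);
  for (R_xlen_t i = 0; i < n; ++i) {
    v[i] = mom * v[i] - lr * (g[i] + wd * w[i]);
    w[i] += v[i];
  }
}
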