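// Numerical kernels for the fusion network: exact GELU, row-wise layer
// normalisation, row broadcasts, and batched multi-head scaled-dot-product
// attention over fixed-length sequences.
//
// Sequence batches are stored as (b * n) x D matrices with sample-major
// row blocks: rows (s*n + 1) .. (s*n + n) hold sample s (0-based s).
// Attention weight matrices are stacked as ((s*h + t)*nq + i, j) so tests
// can check row-normalisation per sample and head. Keys and values arrive
// as one (b * nk) x 2D matrix (columns [K | V]) so the upstream projection
// is a single wide GEMM.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double INV_SQRT2 = 0.70710678118654752440;
static const double INV_SQRT_2PI = 0.39894228040143267794;

// Exact GELU: x * Phi(x) with the Gaussian CDF.
// [[Rcpp::export]]
NumericMatrix cpp_gelu(NumericMatrix x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const double* xi = x.begin();
  double* yi = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    yi[i] = 0.5 * xi[i] * (1.0 + std::erf(xi[i] * INV_SQRT2));
  }
  return y;
}

// dy * d/dx GELU, with d/dx GELU = Phi(x) + x * phi(x)
// [[Rcpp::export]]
NumericMatrix cpp_gelu_bwd(NumericMatrix dy, NumericMatrix x) {
  NumericMatrix out(x.nrow(), x.ncol());
  const double* xi = x.begin();
  const double* di = dy.begin();
  double* oi = out.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double Phi = 0.5 * (1.0 + std::erf(xi[i] * INV_SQRT2));
    double phi = INV_SQRT_2PI * std::exp(-0.5 * xi[i] * xi[i]);
    oi[i] = di[i] * (Phi + xi[i] * phi);
  }
  return out;
}

// y = x + row-broadcast(v)
// [[Rcpp::export]]
NumericMatrix cpp_addrow(NumericMatrix x, NumericVector v) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix y(n, m);
  for (int j = 0; j < m; ++j) {
    const double* c = &x(0, j);
    double* o = &y(0, j);
    const double vj = v[j];
    for (int i = 0; i < n; ++i) o[i] = c[i] + vj;
  }
  return y;
}

// y = x * row-broadcast(v)
// [[Rcpp::export]]
NumericMatrix cpp_mulrow(NumericMatrix x, NumericVector v) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix y(n, m);
  for (int j = 0; j < m; ++j) {
    const double* c = &x(0, j);
    double* o = &y(0, j);
    const double vj = v[j];
    for (int i = 0; i < n; ++i) o[i] = c[i] * vj;
  }
  return y;
}

// Row-wise layer normalisation with affine (g, b). Returns the output plus
// the normalised activations and inverse SD needed by the backward pass.
// [[Rcpp::export]]
List cpp_ln_forward(NumericMatrix x, NumericVector g, NumericVector b,
                    double eps) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix xh(n, m), out(n, m);
  NumericVector inv(n);
  std::vector<double> mu(n, 0.0), var(n, 0.0);
  for (int j = 0; j < m; ++j) {
    const double* c = &x(0, j);
    for (int i = 0; i < n; ++i) mu[i] += c[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= m;
  for (int j = 0; j < m; ++j) {
    const double* c = &x(0, j);
    for (int i = 0; i < n; ++i) {
      double d = c[i] - mu[i];
      var[i] += d * d;
    }
  }
  for (int i = 0; i < n; ++i) inv[i] = 1.0 / std::sqrt(var[i] / m + eps);
  for (int j = 0; j < m; ++j) {
    const double* c = &x(0, j);
    double* xj = &xh(0, j);
    double* oj = &out(0, j);
    const double gj = g[j], bj = b[j];
    for (int i = 0; i < n; ++i) {
      double v = (c[i] - mu[i]) * inv[i];
      xj[i] = v;
      oj[i] = v * gj + bj;
    }
  }
  return List::create(Named("out") = out, Named("xh") = xh,
                      Named("inv") = inv);
}

// [[Rcpp::export]]
List cpp_ln_backward(NumericMatrix dy, NumericVector g, NumericMatrix xh,
                     NumericVector inv) {
  const int n = dy.nrow(), m = dy.ncol();
  NumericMatrix dx(n, m);
  NumericVector dg(m), db(m);
  std::vector<double> t1(n, 0.0), t2(n, 0.0);
  for (int j = 0; j < m; ++j) {
    const double* dj = &dy(0, j);
    const double* xj = &xh(0, j);
    const double gj = g[j];
    double sg = 0.0, sb = 0.0;
    for (int i = 0; i < n; ++i) {
      double dxh = dj[i] * gj;
      t1[i] += dxh;
      t2[i] += dxh * xj[i];
      sg += dj[i] * xj[i];
      sb += dj[i];
    }
    dg[j] = sg;
    db[j] = sb;
  }
  for (int j = 0; j < m; ++j) {
    const double* dj = &dy(0, j);
    const double* xj = &xh(0, j);
    double* oj = &dx(0, j);
    const double gj = g[j];
    for (int i = 0; i < n; ++i) {
      oj[i] = (dj[i] * gj - (t1[i] + xj[i] * t2[i]) / m) * inv[i];
    }
  }
  return List::create(Named("dx") = dx, Named("dg") = dg, Named("db") = db);
}

// Multi-head attention forward. Q: (b*nq) x D, KV: (b*nk) x 2D with K in
// the first D columns and V in the last D. dropmask, when given, has the
// same layout as the returned weight matrix A and holds 0 or 1/(1-p)
// entries (inverted dropout on attention weights). Returns
// O = (masked) softmax(Q K^T * scale) V and the pre-mask weights A.
// [[Rcpp::export]]
List cpp_attn_forward(const arma::mat& Q, const arma::mat& KV,
                      int nq, int nk, int b, int h, double scale,
                      Nullable<NumericMatrix> dropmask) {
  const int D = Q.n_cols;
  const int dh = D / h;
  arma::mat O(b * nq, D);
  arma::mat A(b * h * nq, nk);
  const bool has_mask = dropmask.isNotNull();
  arma::mat M;
  if (has_mask) M = as<arma::mat>(dropmask.get());

  for (int s = 0; s < b; ++s) {
    const int q0 = s * nq, k0 = s * nk;
    for (int t = 0; t < h; ++t) {
      const int c0 = t * dh;
      arma::mat S = Q.submat(q0, c0, q0 + nq - 1, c0 + dh - 1) *
                    KV.submat(k0, c0, k0 + nk - 1, c0 + dh - 1).t() * scale;
      arma::colvec mx = arma::max(S, 1);
      S.each_col() -= mx;
      S = arma::exp(S);
      arma::colvec sm = arma::sum(S, 1);
      S.each_col() /= sm;
      const int a0 = (s * h + t) * nq;
      A.rows(a0, a0 + nq - 1) = S;
      if (has_mask) S %= M.rows(a0, a0 + nq - 1);
      O.submat(q0, c0, q0 + nq - 1, c0 + dh - 1) =
          S * KV.submat(k0, D + c0, k0 + nk - 1, D + c0 + dh - 1);
    }
  }
  return List::create(Named("O") = O, Named("A") = A);
}

// Backward pass matching cpp_attn_forward. A is the pre-mask softmax output
// saved by the forward pass; returns dQ and the combined dKV.
// [[Rcpp::export]]
List cpp_attn_backward(const arma::mat& dO, const arma::mat& Q,
                       const arma::mat& KV, const arma::mat& A,
                       int nq, int nk, int b, int h, double scale,
                       Nullable<NumericMatrix> dropmask) {
  const int D = Q.n_cols;
  const int dh = D / h;
  arma::mat dQ(arma::size(Q), arma::fill::zeros);
  arma::mat dKV(arma::size(KV), arma::fill::zeros);
  const bool has_mask = dropmask.isNotNull();
  arma::mat M;
  if (has_mask) M = as<arma::mat>(dropmask.get());

  for (int s = 0; s < b; ++s) {
    const int q0 = s * nq, k0 = s * nk;
    for (int t = 0; t < h; ++t) {
      const int c0 = t * dh, a0 = (s * h + t) * nq;
      arma::mat As = A.rows(a0, a0 + nq - 1);
      arma::mat Ad = As;
      arma::mat Ms;
      if (has_mask) {
        Ms = M.rows(a0, a0 + nq - 1);
        Ad %= Ms;
      }
      arma::mat dOh = dO.submat(q0, c0, q0 + nq - 1, c0 + dh - 1);
      dKV.submat(k0, D + c0, k0 + nk - 1, D + c0 + dh - 1) += Ad.t() * dOh;
      arma::mat dA = dOh *
          KV.submat(k0, D + c0, k0 + nk - 1, D + c0 + dh - 1).t();
      if (has_mask) dA %= Ms;
      arma::colvec rs = arma::sum(dA % As, 1);
      arma::mat dS = As % (dA.each_col() - rs);
      dS *= scale;
      dQ.submat(q0, c0, q0 + nq - 1, c0 + dh - 1) =
          dS * KV.submat(k0, c0, k0 + nk - 1, c0 + dh - 1);
      dKV.submat(k0, c0, k0 + nk - 1, c0 + dh - 1) +=
          dS.t() * Q.submat(q0, c0, q0 + nq - 1, c0 + dh - 1);
    }
  }
  return List::create(Named("dQ") = dQ, Named("dKV") = dKV);
}
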