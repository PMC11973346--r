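// Hot-path kernels for the network engine: temporal convolution,
// fused activation + batch-norm, and temporal max-pooling.  Shapes follow
// the R side: band tensor X [B, C, T, n] (column-major), feature-map
// matrices [F, N] with N = C*T*n or T*n.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Z[f, c + C*t + C*T*i] = bias[f] + sum_{b,k} W[f,b,k] X[b,c,t+k-padL,i]
// (zero padding outside [0, T))
// [[Rcpp::export]]
NumericMatrix cpp_conv_time_fwd(NumericVector X, NumericVector W,
                                NumericVector bias, int padL) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dw = W.attr("dim");
  const int B = dx[0], C = dx[1], T = dx[2], n = dx[3];
  const int F0 = dw[0], K0 = dw[2];
  arma::mat Xm(X.begin(), (size_t)B, (size_t)C * T * n, false);
  arma::mat Z((size_t)F0, (size_t)C * T * n);
  Z.each_col() = arma::vec(bias.begin(), F0);
  for (int k = 0; k < K0; ++k) {
    // W[,,k] as F0 x B
    arma::mat Wk((size_t)F0, (size_t)B);
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F0; ++f)
        Wk(f, b) = W[f + F0 * (b + B * k)];
    const int dlt = k - padL;  // source t = t + dlt
    for (int i = 0; i < n; ++i) {
      const int t0 = std::max(0, -dlt), t1 = std::min(T, T - dlt);
      if (t0 >= t1) continue;
      const size_t zc0 = (size_t)C * (t0 + (size_t)T * i);
      const size_t xc0 = (size_t)C * (t0 + dlt + (size_t)T * i);
      const size_t len = (size_t)C * (t1 - t0);
      Z.cols(zc0, zc0 + len - 1) += Wk * Xm.cols(xc0, xc0 + len - 1);
    }
  }
  NumericMatrix out(F0, C * T * n);
  std::copy(Z.begin(), Z.end(), out.begin());
  return out;
}

// dW[f,b,k] = sum_{c,t,i} dZ[f, c+C*t+C*T*i] X[b,c,t+k-padL,i]
// [[Rcpp::export]]
NumericVector cpp_conv_time_wgrad(NumericVector X, NumericMatrix dZ,
                                  int F0, int K0, int padL) {
  IntegerVector dx = X.attr("dim");
  const int B = dx[0], C = dx[1], T = dx[2], n = dx[3];
  arma::mat Xm(X.begin(), (size_t)B, (size_t)C * T * n, false);
  arma::mat dZm(dZ.begin(), (size_t)F0, (size_t)C * T * n, false);
  NumericVector dW(F0 * B * K0);
  dW.attr("dim") = IntegerVector::create(F0, B, K0);
  for (int k = 0; k < K0; ++k) {
    arma::mat acc((size_t)F0, (size_t)B, arma::fill::zeros);
    const int dlt = k - padL;
    for (int i = 0; i < n; ++i) {
      const int t0 = std::max(0, -dlt), t1 = std::min(T, T - dlt);
      if (t0 >= t1) continue;
      const size_t zc0 = (size_t)C * (t0 + (size_t)T * i);
      const size_t xc0 = (size_t)C * (t0 + dlt + (size_t)T * i);
      const size_t len = (size_t)C * (t1 - t0);
      acc += dZm.cols(zc0, zc0 + len - 1) *
             Xm.cols(xc0, xc0 + len - 1).t();
    }
    for (int b = 0; b < B; ++b)
      for (int f = 0; f < F0; ++f)
        dW[f + F0 * (b + B * k)] = acc(f, b);
  }
  return dW;
}

// Fused (optional ReLU) -> batch-norm -> (optional ELU) forward over a
// [F, N] matrix.  train: batch statistics (biased), returns xhat/istd;
// eval: uses run_mean/run_var.
// [[Rcpp::export]]
List cpp_actnorm_fwd(NumericMatrix Z, NumericVector g, NumericVector beta,
                     NumericVector run_mean, NumericVector run_var,
                     double eps, bool relu_in, bool elu_out, bool train) {
  const int F = Z.nrow(); const R_xlen_t N = Z.ncol();
  NumericMatrix out(F, N);
  NumericVector mu(F), var(F);
  if (train) {
    std::vector<double> sq(F, 0.0);
    for (R_xlen_t j = 0; j < N; ++j) {
      const double* z = &Z(0, j);
      for (int f = 0; f < F; ++f) {
        double v = z[f];
        if (relu_in && v < 0) v = 0;
        mu[f] += v;
        sq[f] += v * v;
      }
    }
    for (int f = 0; f < F; ++f) {
      mu[f] /= (double)N;
      var[f] = sq[f] / (double)N - mu[f] * mu[f];
      if (var[f] < 0) var[f] = 0;
    }
  } else {
    mu = clone(run_mean);
    var = clone(run_var);
  }
  NumericVector istd(F);
  for (int f = 0; f < F; ++f) istd[f] = 1.0 / std::sqrt(var[f] + eps);
  NumericMatrix xhat;
  if (train) xhat = NumericMatrix(F, N);
  for (R_xlen_t j = 0; j < N; ++j) {
    const double* z = &Z(0, j);
    double* o = &out(0, j);
    double* xh = train ? &xhat(0, j) : (double*)nullptr;
    for (int f = 0; f < F; ++f) {
      double v = z[f];
      if (relu_in && v < 0) v = 0;
      const double h = (v - mu[f]) * istd[f];
      if (train) xh[f] = h;
      double y = h * g[f] + beta[f];
      if (elu_out && y < 0) y = std::expm1(y);
      o[f] = y;
    }
  }
  if (train)
    return List::create(_["out"] = out, _["xhat"] = xhat, _["istd"] = istd,
                        _["mu"] = mu, _["var"] = var);
  return List::create(_["out"] = out);
}

// Backward of the fused block: given d(out), the stored xhat/istd, the
// affine parameters and the pre-activation Z (for the ReLU mask).
// Returns dZ, dgamma, dbeta.
// [[Rcpp::export]]
List cpp_actnorm_bwd(NumericMatrix dout, NumericMatrix xhat,
                     NumericVector istd, NumericVector g,
                     NumericVector beta, NumericMatrix Z,
                     bool relu_in, bool elu_out) {
  const int F = dout.nrow(); const R_xlen_t N = dout.ncol();
  NumericVector dg(F), db(F);
  // pass 1: dyhat-space row sums (dy = dout * elu'(y))
  for (R_xlen_t j = 0; j < N; ++j) {
    const double* do_ = &dout(0, j);
    const double* xh = &xhat(0, j);
    for (int f = 0; f < F; ++f) {
      double dy = do_[f];
      if (elu_out) {
        const double y = xh[f] * g[f] + beta[f];
        if (y < 0) dy *= std::exp(y);
      }
      dg[f] += dy * xh[f];
      db[f] += dy;
    }
  }
  NumericMatrix dZ(F, N);
  for (R_xlen_t j = 0; j < N; ++j) {
    const double* do_ = &dout(0, j);
    const double* xh = &xhat(0, j);
    const double* z = &Z(0, j);
    double* dz = &dZ(0, j);
    for (int f = 0; f < F; ++f) {
      double dy = do_[f];
      if (elu_out) {
        const double y = xh[f] * g[f] + beta[f];
        if (y < 0) dy *= std::exp(y);
      }
      double dx = g[f] * istd[f] *
        (dy - db[f] / (double)N - xh[f] * dg[f] / (double)N);
      if (relu_in && z[f] <= 0) dx = 0;
      dz[f] = dx;
    }
  }
  return List::create(_["dZ"] = dZ, _["dg"] = dg, _["db"] = db);
}

// Max-pool with stride = width = pool along the time axis of [F,C,T,n].
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector E, int pool) {
  IntegerVector de = E.attr("dim");
  const int F = de[0], C = de[1], T = de[2], n = de[3];
  const int P = T / pool;
  NumericVector Y((R_xlen_t)F * C * P * n);
  IntegerVector arg((R_xlen_t)F * C * P * n);
  Y.attr("dim") = IntegerVector::create(F, C, P, n);
  arg.attr("dim") = IntegerVector::create(F, C, P, n);
  const R_xlen_t FC = (R_xlen_t)F * C;
  for (int i = 0; i < n; ++i)
    for (int pp = 0; pp < P; ++pp) {
      const R_xlen_t yoff = FC * (pp + (R_xlen_t)P * i);
      const R_xlen_t eoff = FC * ((R_xlen_t)pp * pool + (R_xlen_t)T * i);
      for (R_xlen_t u = 0; u < FC; ++u) {
        double best = E[eoff + u];
        int bw = 0;
        for (int w = 1; w < pool; ++w) {
          const double v = E[eoff + FC * w + u];
          if (v > best) { best = v; bw = w; }
        }
        Y[yoff + u] = best;
        arg[yoff + u] = bw;
      }
    }
  return List::create(_["y"] = Y, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dY, IntegerVector arg,
                              int pool, int T) {
  IntegerVector dy = dY.attr("dim");
  const int F = dy[0], C = dy[1], P = dy[2], n = dy[3];
  NumericVector dE((R_xlen_t)F * C * T * n);
  dE.attr("dim") = IntegerVector::create(F, C, T, n);
  const R_xlen_t FC = (R_xlen_t)F * C;
  for (int i = 0; i < n; ++i)
    for (int pp = 0; pp < P; ++pp) {
      const R_xlen_t yoff = FC * (pp + (R_xlen_t)P * i);
      const R_xlen_t eoff = FC * ((R_xlen_t)pp * pool + (R_xlen_t)T * i);
      for (R_xlen_t u = 0; u < FC; ++u)
        dE[eoff + FC * arg[yoff + u] + u] = dY[yoff + u];
    }
  return dE;
}
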