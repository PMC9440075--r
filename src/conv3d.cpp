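#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays in column-major order with dims
//   X: (batch, cin, d1, d2, d3)
//   W: (k, k, k, cin, cout)
// Convolution is cross-correlation (no kernel flip) with zero 'same'
// padding p = (k - 1) / 2; kernels here are odd so padding is symmetric.

static inline R_xlen_t xidx(int b, int c, int i, int j, int k,
                            int B, int C, int D1, int D2) {
  return b + (R_xlen_t)B * (c + (R_xlen_t)C * (i + (R_xlen_t)D1 * (j + (R_xlen_t)D2 * k)));
}

static inline R_xlen_t widx(int a, int bb, int cc, int ci, int co, int K, int Cin) {
  return a + (R_xlen_t)K * (bb + (R_xlen_t)K * (cc + (R_xlen_t)K * (ci + (R_xlen_t)Cin * co)));
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector X, NumericVector W,
                                 NumericVector bias, int stride) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dw = W.attr("dim");
  int B = dx[0], Cin = dx[1], D1 = dx[2], D2 = dx[3], D3 = dx[4];
  int K = dw[0], Cout = dw[4];
  if (dw[3] != Cin) stop("conv3d: kernel channel depth %d != input channels %d", dw[3], Cin);
  int pad = (K - 1) / 2;
  int O1 = (D1 + 2 * pad - K) / stride + 1;
  int O2 = (D2 + 2 * pad - K) / stride + 1;
  int O3 = (D3 + 2 * pad - K) / stride + 1;
  NumericVector Y((R_xlen_t)B * Cout * O1 * O2 * O3);
  Y.attr("dim") = IntegerVector::create(B, Cout, O1, O2, O3);
  const double *xp = X.begin(), *wp = W.begin(), *bp = bias.begin();
  double *yp = Y.begin();
  for (int ok = 0; ok < O3; ++ok)
    for (int oj = 0; oj < O2; ++oj)
      for (int oi = 0; oi < O1; ++oi)
        for (int co = 0; co < Cout; ++co)
          for (int b = 0; b < B; ++b) {
            double acc = bp[co];
            for (int kk = 0; kk < K; ++kk) {
              int zk = ok * stride + kk - pad;
              if (zk < 0 || zk >= D3) continue;
              for (int kj = 0; kj < K; ++kj) {
                int zj = oj * stride + kj - pad;
                if (zj < 0 || zj >= D2) continue;
                for (int ki = 0; ki < K; ++ki) {
                  int zi = oi * stride + ki - pad;
                  if (zi < 0 || zi >= D1) continue;
                  for (int ci = 0; ci < Cin; ++ci)
                    acc += xp[xidx(b, ci, zi, zj, zk, B, Cin, D1, D2)] *
                           wp[widx(ki, kj, kk, ci, co, K, Cin)];
                }
              }
            }
            yp[xidx(b, co, oi, oj, ok, B, Cout, O1, O2)] = acc;
          }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector X, NumericVector W,
                         NumericVector dY, int stride) {
  IntegerVector dx = X.attr("dim");
  IntegerVector dw = W.attr("dim");
  IntegerVector dy = dY.attr("dim");
  int B = dx[0], Cin = dx[1], D1 = dx[2], D2 = dx[3], D3 = dx[4];
  int K = dw[0], Cout = dw[4];
  int O1 = dy[2], O2 = dy[3], O3 = dy[4];
  int pad = (K - 1) / 2;
  NumericVector dX((R_xlen_t)B * Cin * D1 * D2 * D3);
  dX.attr("dim") = IntegerVector::create(B, Cin, D1, D2, D3);
  NumericVector dW((R_xlen_t)K * K * K * Cin * Cout);
  dW.attr("dim") = IntegerVector::create(K, K, K, Cin, Cout);
  NumericVector db(Cout);
  const double *xp = X.begin(), *wp = W.begin(), *gp = dY.begin();
  double *dxp = dX.begin(), *dwp = dW.begin(), *dbp = db.begin();
  for (int ok = 0; ok < O3; ++ok)
    for (int oj = 0; oj < O2; ++oj)
      for (int oi = 0; oi < O1; ++oi)
        for (int co = 0; co < Cout; ++co)
          for (int b = 0; b < B; ++b) {
            double g = gp[xidx(b, co, oi, oj, ok, B, Cout, O1, O2)];
            if (g == 0.0) continue;
            dbp[co] += g;
            for (int kk = 0; kk < K; ++kk) {
              int zk = ok * stride + kk - pad;
              if (zk < 0 || zk >= D3) continue;
              for (int kj = 0; kj < K; ++kj) {
                int zj = oj * stride + kj - pad;
                if (zj < 0 || zj >= D2) continue;
                for (int ki = 0; ki < K; ++ki) {
                  int zi = oi * stride + ki - pad;
                  if (zi < 0 || zi >= D1) continue;
                  for (int ci = 0; ci < Cin; ++ci) {
                    R_xlen_t xi = xidx(b, ci, zi, zj, zk, B, Cin, D1, D2);
                    R_xlen_t wi = widx(ki, kj, kk, ci, co, K, Cin);
                    dwp[wi] += xp[xi] * g;
                    dxp[xi] += wp[wi] * g;
                  }
                }
              }
            }
          }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool3d_forward(NumericVector X, int k, int stride) {
  IntegerVector dx = X.attr("dim");
  int B = dx[0], C = dx[1], D1 = dx[2], D2 = dx[3], D3 = dx[4];
  if (k > D1 || k > D2 || k > D3)
    stop("maxpool3d: kernel %d exceeds spatial extent (%d, %d, %d)", k, D1, D2, D3);
  int O1 = (D1 - k) / stride + 1;
  int O2 = (D2 - k) / stride + 1;
  int O3 = (D3 - k) / stride + 1;
  NumericVector Y((R_xlen_t)B * C * O1 * O2 * O3);
  Y.attr("dim") = IntegerVector::create(B, C, O1, O2, O3);
  IntegerVector A(Y.size());  // 1-based flat index into X of each winner
  const double *xp = X.begin();
  double *yp = Y.begin();
  int *ap = A.begin();
  for (int ok = 0; ok < O3; ++ok)
    for (int oj = 0; oj < O2; ++oj)
      for (int oi = 0; oi < O1; ++oi)
        for (int c = 0; c < C; ++c)
          for (int b = 0; b < B; ++b) {
            double best = R_NegInf;
            R_xlen_t besti = -1;
            for (int kk = 0; kk < k; ++kk)
              for (int kj = 0; kj < k; ++kj)
                for (int ki = 0; ki < k; ++ki) {
                  R_xlen_t xi = xidx(b, c, oi * stride + ki, oj * stride + kj,
                                     ok * stride + kk, B, C, D1, D2);
                  if (xp[xi] > best) { best = xp[xi]; besti = xi; }
                }
            R_xlen_t yi = xidx(b, c, oi, oj, ok, B, C, O1, O2);
            yp[yi] = best;
            ap[yi] = (int)(besti + 1);
          }
  return List::create(_["Y"] = Y, _["argmax"] = A);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_backward(NumericVector dY, IntegerVector argmax,
                                     IntegerVector dimX) {
  R_xlen_t n = 1;
  for (int i = 0; i < dimX.size(); ++i) n *= dimX[i];
  NumericVector dX(n);
  dX.attr("dim") = dimX;
  const double *gp = dY.begin();
  double *dxp = dX.begin();
  for (R_xlen_t i = 0; i < dY.size(); ++i) dxp[argmax[i] - 1] += gp[i];
  return dX;
}
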