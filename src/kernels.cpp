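#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

static void dgemm_nn(const double* A, const double* B, double* C,
                     int m, int n, int k) {
  const char nt = 'N';
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)(&nt, &nt, &m, &n, &k, &one, A, &m, B, &k, &zero, C, &m FCONE FCONE);
}
static void dgemm_tn(const double* A, const double* B, double* C,
                     int m, int n, int k) {
  // C (m x n) = A^T (m x k') B with A stored (k x m): here m = cols(A)
  const char tr = 'T', nt = 'N';
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)(&tr, &nt, &m, &n, &k, &one, A, &k, B, &k, &zero, C, &m FCONE FCONE);
}
static void dgemm_nt(const double* A, const double* B, double* C,
                     int m, int n, int k) {
  // C (m x n) = A (m x k) B^T with B stored (n x k)
  const char nt = 'N', tr = 'T';
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)(&nt, &tr, &m, &n, &k, &one, A, &m, B, &n, &zero, C, &m FCONE FCONE);
}

// Hot elementwise and gather/scatter kernels behind the neural-network
// layers. Index vectors are 1-based (as produced by the R-side plans).
// No RNG lives here: all stochastic state stays in R.

// out[i, j] = X[i, j] * a[j] + b[j]
// [[Rcpp::export]]
NumericMatrix cpp_scale_shift(const NumericMatrix& X,
                              const NumericVector& a,
                              const NumericVector& b) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix out(n, C);
  for (int j = 0; j < C; ++j) {
    const double aj = a[j], bj = b[j];
    const double* xj = &X(0, j);
    double* oj = &out(0, j);
    for (int i = 0; i < n; ++i) oj[i] = xj[i] * aj + bj;
  }
  return out;
}

// fused batch-normalization backward pass
// [[Rcpp::export]]
List cpp_bn_bwd(const NumericMatrix& dY, const NumericMatrix& X,
                const NumericVector& mu, const NumericVector& invstd,
                const NumericVector& gamma) {
  const int n = dY.nrow(), C = dY.ncol();
  NumericMatrix dX(n, C);
  NumericVector dgamma(C), dbeta(C);
  for (int j = 0; j < C; ++j) {
    const double muj = mu[j], sj = invstd[j], gj = gamma[j];
    const double* xj = &X(0, j);
    const double* dyj = &dY(0, j);
    double s_dy = 0.0, s_dyx = 0.0;
    for (int i = 0; i < n; ++i) {
      const double xh = (xj[i] - muj) * sj;
      s_dy += dyj[i];
      s_dyx += dyj[i] * xh;
    }
    dbeta[j] = s_dy;
    dgamma[j] = s_dyx;
    const double m1 = gj * s_dy / n, m2 = gj * s_dyx / n;
    double* dxj = &dX(0, j);
    for (int i = 0; i < n; ++i) {
      const double xh = (xj[i] - muj) * sj;
      dxj[i] = (gj * dyj[i] - m1 - xh * m2) * sj;
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// patch gather: Pcat[i, (k-1)*C + j] = P[selcat[(k-1)*NHW + i], j]
// [[Rcpp::export]]
NumericMatrix cpp_gather(const NumericMatrix& P, const IntegerVector& selcat,
                         const int NHW) {
  const int C = P.ncol();
  const int K = selcat.size() / NHW;
  NumericMatrix out(NHW, K * C);
  for (int k = 0; k < K; ++k) {
    const int* sk = &selcat[k * NHW];
    for (int j = 0; j < C; ++j) {
      const double* pj = &P(0, j);
      double* oj = &out(0, (long)k * C + j);
      for (int i = 0; i < NHW; ++i) oj[i] = pj[sk[i] - 1];
    }
  }
  return out;
}

// scatter-add of the patch gradient back onto the padded plane:
// dP[selcat[(k-1)*NHW + i], j] += dPg[(k-1)*NHW + i, (k? no) j-th chan]
// dPg laid out as (K*NHW, C) with offset blocks stacked row-wise
// [[Rcpp::export]]
NumericMatrix cpp_scatter_add(const NumericMatrix& dPg,
                              const IntegerVector& selcat,
                              const int NHW, const int pad_rows) {
  const int C = dPg.ncol();
  const int K = selcat.size() / NHW;
  NumericMatrix dP(pad_rows, C);
  for (int j = 0; j < C; ++j) {
    double* dpj = &dP(0, j);
    const double* gj = &dPg(0, j);
    for (int k = 0; k < K; ++k) {
      const int* sk = &selcat[k * NHW];
      const double* gkj = gj + (long)k * NHW;
      for (int i = 0; i < NHW; ++i) dpj[sk[i] - 1] += gkj[i];
    }
  }
  return dP;
}

// mean over the four 2x2 block positions
// [[Rcpp::export]]
NumericMatrix cpp_pool4_mean(const NumericMatrix& P, const IntegerVector& s1,
                             const IntegerVector& s2, const IntegerVector& s3,
                             const IntegerVector& s4) {
  const int n = s1.size(), C = P.ncol();
  NumericMatrix out(n, C);
  for (int j = 0; j < C; ++j) {
    const double* pj = &P(0, j);
    double* oj = &out(0, j);
    for (int i = 0; i < n; ++i) {
      oj[i] = (pj[s1[i] - 1] + pj[s2[i] - 1] + pj[s3[i] - 1] + pj[s4[i] - 1]) / 4.0;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_pool4_bwd(const NumericMatrix& dO, const IntegerVector& s1,
                            const IntegerVector& s2, const IntegerVector& s3,
                            const IntegerVector& s4, const int pad_rows) {
  const int n = s1.size(), C = dO.ncol();
  NumericMatrix dP(pad_rows, C);
  for (int j = 0; j < C; ++j) {
    double* dpj = &dP(0, j);
    const double* gj = &dO(0, j);
    for (int i = 0; i < n; ++i) {
      const double g = gj[i] / 4.0;
      dpj[s1[i] - 1] += g;
      dpj[s2[i] - 1] += g;
      dpj[s3[i] - 1] += g;
      dpj[s4[i] - 1] += g;
    }
  }
  return dP;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu(const NumericMatrix& X) {
  const long n = (long)X.nrow() * X.ncol();
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = X.begin();
  double* o = out.begin();
  for (long i = 0; i < n; ++i) o[i] = x[i] > 0 ? x[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_relu_bwd(const NumericMatrix& dY, const NumericMatrix& X) {
  const long n = (long)X.nrow() * X.ncol();
  NumericMatrix out(X.nrow(), X.ncol());
  const double* x = X.begin();
  const double* dy = dY.begin();
  double* o = out.begin();
  for (long i = 0; i < n; ++i) o[i] = x[i] > 0 ? dy[i] : 0.0;
  return out;
}

// ---- fused convolutional stem ------------------------------------------
// conv(same) -> batchnorm -> relu -> 2x2 mean pool, applied twice.
// Plans are Lists with integer fields produced by the R-side planners.

static void pad_into(const NumericMatrix& A, const Rcpp::Nullable<IntegerVector>& interior,
                     int pad_rows, NumericMatrix& P) {
  const int C = A.ncol();
  if (interior.isNull()) {
    std::copy(A.begin(), A.end(), P.begin());
    return;
  }
  IntegerVector intr(interior);
  std::fill(P.begin(), P.end(), 0.0);
  const int n = intr.size();
  for (int j = 0; j < C; ++j) {
    double* pj = &P(0, j);
    const double* aj = &A(0, j);
    for (int i = 0; i < n; ++i) pj[intr[i] - 1] = aj[i];
  }
}

static NumericMatrix conv_gather_mm(const NumericMatrix& P, const IntegerVector& selcat,
                                    int NHW, const NumericMatrix& Km,
                                    const NumericVector& b, NumericMatrix& Pcat) {
  const int C = P.ncol();
  const int F = Km.ncol();
  // Pcat (NHW, 9*C), channel fastest within offset block
  for (int k = 0; k < 9; ++k) {
    const int* sk = &selcat[k * NHW];
    for (int j = 0; j < C; ++j) {
      const double* pj = &P(0, j);
      double* oj = &Pcat(0, k * C + j);
      for (int i = 0; i < NHW; ++i) oj[i] = pj[sk[i] - 1];
    }
  }
  NumericMatrix X = Rcpp::no_init(NHW, F);
  const int KC = 9 * C;
  dgemm_nn(Pcat.begin(), Km.begin(), X.begin(), NHW, F, KC);
  for (int f = 0; f < F; ++f) {
    double* xf = &X(0, f);
    const double bf = b[f];
    for (int i = 0; i < NHW; ++i) xf[i] += bf;
  }
  return X;
}

// batchnorm + relu forward; fills mu/invstd and returns activated output
static NumericMatrix bn_relu(const NumericMatrix& X, const NumericVector& gamma,
                             const NumericVector& beta, bool training,
                             NumericVector& rmean, NumericVector& rvar,
                             double momentum, double eps,
                             NumericVector& mu, NumericVector& invstd) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix out = Rcpp::no_init(n, C);
  for (int j = 0; j < C; ++j) {
    const double* xj = &X(0, j);
    double m, v;
    if (training) {
      double s = 0, s2 = 0;
      for (int i = 0; i < n; ++i) { s += xj[i]; s2 += xj[i] * xj[i]; }
      m = s / n;
      v = s2 / n - m * m;
      if (v < 0) v = 0;
      rmean[j] = momentum * rmean[j] + (1 - momentum) * m;
      rvar[j] = momentum * rvar[j] + (1 - momentum) * v;
    } else {
      m = rmean[j];
      v = rvar[j];
    }
    const double is = 1.0 / std::sqrt(v + eps);
    mu[j] = m; invstd[j] = is;
    const double a = gamma[j] * is, b = beta[j] - m * a;
    double* oj = &out(0, j);
    for (int i = 0; i < n; ++i) {
      const double y = xj[i] * a + b;
      oj[i] = y > 0 ? y : 0.0;
    }
  }
  return out;
}

static NumericMatrix pool_mean(const NumericMatrix& A, const List& plan) {
  IntegerVector s1 = plan["sel1"], s2 = plan["sel2"], s3 = plan["sel3"], s4 = plan["sel4"];
  const int pad_rows = as<int>(plan["pad_rows"]);
  const int C = A.ncol();
  NumericMatrix P = Rcpp::no_init(pad_rows, C);
  Rcpp::Nullable<IntegerVector> intr = plan["interior"];
  pad_into(A, intr, pad_rows, P);
  const int n = s1.size();
  NumericMatrix out = Rcpp::no_init(n, C);
  for (int j = 0; j < C; ++j) {
    const double* pj = &P(0, j);
    double* oj = &out(0, j);
    for (int i = 0; i < n; ++i)
      oj[i] = (pj[s1[i] - 1] + pj[s2[i] - 1] + pj[s3[i] - 1] + pj[s4[i] - 1]) / 4.0;
  }
  return out;
}

static NumericMatrix pool_mean_bwd(const NumericMatrix& dO, const List& plan, int in_rows) {
  IntegerVector s1 = plan["sel1"], s2 = plan["sel2"], s3 = plan["sel3"], s4 = plan["sel4"];
  const int pad_rows = as<int>(plan["pad_rows"]);
  const int C = dO.ncol();
  NumericMatrix dP(pad_rows, C);
  const int n = s1.size();
  for (int j = 0; j < C; ++j) {
    double* dpj = &dP(0, j);
    const double* gj = &dO(0, j);
    for (int i = 0; i < n; ++i) {
      const double g = gj[i] / 4.0;
      dpj[s1[i] - 1] += g; dpj[s2[i] - 1] += g;
      dpj[s3[i] - 1] += g; dpj[s4[i] - 1] += g;
    }
  }
  Rcpp::Nullable<IntegerVector> intr = plan["interior"];
  if (intr.isNull()) return dP;
  IntegerVector iv(intr);
  NumericMatrix dA = Rcpp::no_init(in_rows, C);
  for (int j = 0; j < C; ++j) {
    const double* dpj = &dP(0, j);
    double* daj = &dA(0, j);
    for (int i = 0; i < in_rows; ++i) daj[i] = dpj[iv[i] - 1];
  }
  return dA;
}

// [[Rcpp::export]]
List cpp_stem_fwd(const NumericMatrix& A1, const List& conv1, const List& pool1,
                  const List& conv2, const List& pool2,
                  const NumericMatrix& K1m, const NumericVector& c1b,
                  const NumericVector& g1, const NumericVector& be1,
                  const NumericMatrix& K2m, const NumericVector& c2b,
                  const NumericVector& g2, const NumericVector& be2,
                  const bool training,
                  const NumericVector& rmean1, const NumericVector& rvar1,
                  const NumericVector& rmean2, const NumericVector& rvar2,
                  const double momentum, const double eps) {
  NumericVector rm1 = clone(rmean1), rv1 = clone(rvar1);
  NumericVector rm2 = clone(rmean2), rv2 = clone(rvar2);
  // conv1 (input has one channel)
  IntegerVector sel1 = conv1["selcat"];
  const int NHW1 = as<int>(conv1["pos"]);
  NumericMatrix P1 = Rcpp::no_init(as<int>(conv1["pad_rows"]), 1);
  Rcpp::Nullable<IntegerVector> int1 = conv1["interior"];
  pad_into(A1, int1, as<int>(conv1["pad_rows"]), P1);
  NumericMatrix Pcat1 = Rcpp::no_init(NHW1, 9);
  NumericMatrix X1 = conv_gather_mm(P1, sel1, NHW1, K1m, c1b, Pcat1);
  NumericVector mu1(X1.ncol()), iv1(X1.ncol());
  NumericMatrix r1 = bn_relu(X1, g1, be1, training, rm1, rv1, momentum, eps, mu1, iv1);
  NumericMatrix p1 = pool_mean(r1, pool1);
  // conv2
  IntegerVector sel2 = conv2["selcat"];
  const int NHW2 = as<int>(conv2["pos"]);
  const int F1 = p1.ncol();
  NumericMatrix P2 = Rcpp::no_init(as<int>(conv2["pad_rows"]), F1);
  Rcpp::Nullable<IntegerVector> int2 = conv2["interior"];
  pad_into(p1, int2, as<int>(conv2["pad_rows"]), P2);
  NumericMatrix Pcat2 = Rcpp::no_init(NHW2, 9 * F1);
  NumericMatrix X2 = conv_gather_mm(P2, sel2, NHW2, K2m, c2b, Pcat2);
  NumericVector mu2(X2.ncol()), iv2(X2.ncol());
  NumericMatrix r2 = bn_relu(X2, g2, be2, training, rm2, rv2, momentum, eps, mu2, iv2);
  NumericMatrix p2 = pool_mean(r2, pool2);
  return List::create(_["out"] = p2,
                      _["Pcat1"] = Pcat1, _["X1"] = X1, _["mu1"] = mu1,
                      _["iv1"] = iv1, _["r1"] = r1,
                      _["Pcat2"] = Pcat2, _["X2"] = X2, _["mu2"] = mu2,
                      _["iv2"] = iv2, _["r2"] = r2,
                      _["rmean1"] = rm1, _["rvar1"] = rv1,
                      _["rmean2"] = rm2, _["rvar2"] = rv2);
}

// backward of bn+relu given post-activation r (mask), conv pre-bn X
static NumericMatrix bn_relu_bwd(const NumericMatrix& dR, const NumericMatrix& r,
                                 const NumericMatrix& X, const NumericVector& mu,
                                 const NumericVector& invstd, const NumericVector& gamma,
                                 NumericVector& dgamma, NumericVector& dbeta) {
  const int n = X.nrow(), C = X.ncol();
  NumericMatrix dX = Rcpp::no_init(n, C);
  for (int j = 0; j < C; ++j) {
    const double* xj = &X(0, j);
    const double* rj = &r(0, j);
    const double* drj = &dR(0, j);
    const double m = mu[j], is = invstd[j], gj = gamma[j];
    double s_dy = 0, s_dyx = 0;
    for (int i = 0; i < n; ++i) {
      if (rj[i] > 0) {
        const double xh = (xj[i] - m) * is;
        s_dy += drj[i];
        s_dyx += drj[i] * xh;
      }
    }
    dgamma[j] = s_dyx; dbeta[j] = s_dy;
    const double m1 = gj * s_dy / n, m2 = gj * s_dyx / n;
    double* dxj = &dX(0, j);
    for (int i = 0; i < n; ++i) {
      const double xh = (xj[i] - m) * is;
      const double dy = rj[i] > 0 ? drj[i] : 0.0;
      dxj[i] = (gj * dy - m1 - xh * m2) * is;
    }
  }
  return dX;
}

// conv backward: fills dKm/db and returns dA (unpadded input gradient);
// skipped entirely when want_dA is false (first layer)
static NumericMatrix conv_bwd_inner(const NumericMatrix& dX, const NumericMatrix& Pcat,
                                    const NumericMatrix& Km, const List& plan,
                                    int in_rows, NumericMatrix& dKm, NumericVector& db,
                                    bool want_dA) {
  const int NHW = dX.nrow(), F = dX.ncol();
  const int KC = Km.nrow();
  const int C = KC / 9;
  for (int f = 0; f < F; ++f) {
    const double* dxf = &dX(0, f);
    double s = 0;
    for (int i = 0; i < NHW; ++i) s += dxf[i];
    db[f] = s;
  }
  dgemm_tn(Pcat.begin(), dX.begin(), dKm.begin(), KC, F, NHW);
  if (!want_dA) return NumericMatrix(0, 0);
  IntegerVector selcat = plan["selcat"];
  const int pad_rows = as<int>(plan["pad_rows"]);
  NumericMatrix dPg = Rcpp::no_init(NHW, KC);
  dgemm_nt(dX.begin(), Km.begin(), dPg.begin(), NHW, KC, F);
  NumericMatrix dP(pad_rows, C);
  for (int k = 0; k < 9; ++k) {
    const int* sk = &selcat[k * NHW];
    for (int j = 0; j < C; ++j) {
      double* dpj = &dP(0, j);
      const double* gj = &dPg(0, k * C + j);
      for (int i = 0; i < NHW; ++i) dpj[sk[i] - 1] += gj[i];
    }
  }
  Rcpp::Nullable<IntegerVector> intr = plan["interior"];
  if (intr.isNull()) return dP;
  IntegerVector iv(intr);
  NumericMatrix dA = Rcpp::no_init(in_rows, C);
  for (int j = 0; j < C; ++j) {
    const double* dpj = &dP(0, j);
    double* daj = &dA(0, j);
    for (int i = 0; i < in_rows; ++i) daj[i] = dpj[iv[i] - 1];
  }
  return dA;
}

// [[Rcpp::export]]
List cpp_stem_bwd(const NumericMatrix& dOut, const List& fwd,
                  const List& conv1, const List& pool1,
                  const List& conv2, const List& pool2,
                  const NumericMatrix& K1m, const NumericVector& g1,
                  const NumericMatrix& K2m, const NumericVector& g2) {
  NumericMatrix r2 = fwd["r2"], X2 = fwd["X2"], Pcat2 = fwd["Pcat2"];
  NumericMatrix r1 = fwd["r1"], X1 = fwd["X1"], Pcat1 = fwd["Pcat1"];
  NumericVector mu2 = fwd["mu2"], iv2 = fwd["iv2"];
  NumericVector mu1 = fwd["mu1"], iv1 = fwd["iv1"];
  NumericMatrix dR2 = pool_mean_bwd(dOut, pool2, r2.nrow());
  NumericVector dg2(X2.ncol()), dbe2(X2.ncol());
  NumericMatrix dX2 = bn_relu_bwd(dR2, r2, X2, mu2, iv2, g2, dg2, dbe2);
  NumericMatrix dK2m = Rcpp::no_init(K2m.nrow(), K2m.ncol());
  NumericVector dc2b = Rcpp::no_init(X2.ncol());
  // pool1 output rows = conv2 input rows
  NumericMatrix dP1 = conv_bwd_inner(dX2, Pcat2, K2m, conv2,
                                     as<int>(conv2["in_rows"]), dK2m, dc2b, true);
  NumericMatrix dR1 = pool_mean_bwd(dP1, pool1, r1.nrow());
  NumericVector dg1(X1.ncol()), dbe1(X1.ncol());
  NumericMatrix dX1 = bn_relu_bwd(dR1, r1, X1, mu1, iv1, g1, dg1, dbe1);
  NumericMatrix dK1m = Rcpp::no_init(K1m.nrow(), K1m.ncol());
  NumericVector dc1b = Rcpp::no_init(X1.ncol());
  conv_bwd_inner(dX1, Pcat1, K1m, conv1, 0, dK1m, dc1b, false);
  return List::create(_["dK1m"] = dK1m, _["dc1b"] = dc1b,
                      _["dg1"] = dg1, _["dbe1"] = dbe1,
                      _["dK2m"] = dK2m, _["dc2b"] = dc2b,
                      _["dg2"] = dg2, _["dbe2"] = dbe2);
}
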