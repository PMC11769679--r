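// Compiled kernels for the annotation-weight block of the coordinate
// ascent. These implement exactly the closed forms documented in
// R/engine.R; the R functions .updateQW / .updateXiRho are thin wrappers.
// Linear algebra goes straight to the BLAS/LAPACK shipped with R.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#include <cmath>

#ifndef FCONE
#define FCONE
#endif

using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

// lambda(xi) = tanh(xi/2)/(4 xi), with the series 1/8 - xi^2/96 near zero.
static inline double lambdaScalar(double x) {
  return (x < 1e-4) ? 0.125 - x * x / 96.0 : std::tanh(x / 2.0) / (4.0 * x);
}

// One q(w_l) update. A is p x m, tA its transpose (m x p, precomputed).
// Returns the posterior mean, trace and log-determinant of the posterior
// covariance, abar = A mu, quad_j = A_j' Sigma A_j, and optionally Sigma.
// [[Rcpp::export]]
Rcpp::List cppUpdateQW(const NumericMatrix& A, const NumericMatrix& tA,
                       const NumericVector& alpha, const NumericVector& xi,
                       double rho, double sigmaw2, bool wantSigma) {
  const int p = A.nrow(), m = A.ncol();
  const double one = 1.0, zero = 0.0;
  const int ione = 1;

  // B = rows of A scaled by sqrt(2 lambda(xi_j))
  std::vector<double> s(p), B((size_t)p * m), P((size_t)m * m);
  for (int j = 0; j < p; ++j) s[j] = std::sqrt(2.0 * lambdaScalar(xi[j]));
  for (int k = 0; k < m; ++k) {
    const double* a = &A[(size_t)k * p];
    double* b = &B[(size_t)k * p];
    for (int j = 0; j < p; ++j) b[j] = a[j] * s[j];
  }
  // P = B'B + I/sigmaw2 (upper triangle)
  F77_CALL(dsyrk)("U", "T", &m, &p, &one, B.data(), &p, &zero, P.data(), &m
                  FCONE FCONE);
  for (int k = 0; k < m; ++k) P[(size_t)k * m + k] += 1.0 / sigmaw2;

  int info = 0;
  F77_CALL(dpotrf)("U", &m, P.data(), &m, &info FCONE);
  if (info != 0)
    Rcpp::stop("q(w) precision matrix not positive definite");
  // P now holds the upper Cholesky factor U
  double logdetS = 0.0;
  for (int k = 0; k < m; ++k) logdetS -= 2.0 * std::log(P[(size_t)k * m + k]);

  // rhs = A' (alpha - 1/2 + 2 lambda rho); mu = U^-1 U^-T rhs
  std::vector<double> c(p), mu(m);
  for (int j = 0; j < p; ++j)
    c[j] = alpha[j] - 0.5 + 2.0 * lambdaScalar(xi[j]) * rho;
  F77_CALL(dgemv)("T", &p, &m, &one, &A[0], &p, c.data(), &ione, &zero,
                  mu.data(), &ione FCONE);
  F77_CALL(dtrsv)("U", "T", "N", &m, P.data(), &m, mu.data(), &ione
                  FCONE FCONE FCONE);
  F77_CALL(dtrsv)("U", "N", "N", &m, P.data(), &m, mu.data(), &ione
                  FCONE FCONE FCONE);

  // V = U^-T A'   (m x p triangular solve), quad_j = ||V_j||^2
  std::vector<double> V(tA.begin(), tA.end());
  F77_CALL(dtrsm)("L", "U", "T", "N", &m, &p, &one, P.data(), &m, V.data(),
                  &m FCONE FCONE FCONE FCONE);
  NumericVector quad(p);
  for (int j = 0; j < p; ++j) {
    const double* v = &V[(size_t)j * m];
    double acc = 0.0;
    for (int k = 0; k < m; ++k) acc += v[k] * v[k];
    quad[j] = acc;
  }

  // Uinv (in place); tr(Sigma) = ||Uinv||_F^2
  F77_CALL(dtrtri)("U", "N", &m, P.data(), &m, &info FCONE FCONE);
  if (info != 0) Rcpp::stop("triangular inversion failed");
  double trS = 0.0;
  for (int k = 0; k < m; ++k)
    for (int j = 0; j <= k; ++j) {
      double u = P[(size_t)k * m + j];
      trS += u * u;
    }

  NumericVector abar(p), muOut(m);
  std::copy(mu.begin(), mu.end(), muOut.begin());
  F77_CALL(dgemv)("N", &p, &m, &one, &A[0], &p, mu.data(), &ione, &zero,
                  &abar[0], &ione FCONE);

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("mu") = muOut,
    Rcpp::Named("trS") = trS,
    Rcpp::Named("logdetS") = logdetS,
    Rcpp::Named("abar") = abar,
    Rcpp::Named("quad") = quad);
  if (wantSigma) {
    // Sigma = Uinv Uinv' via dlauum on the triangular inverse
    F77_CALL(dlauum)("U", &m, P.data(), &m, &info FCONE);
    if (info != 0) Rcpp::stop("covariance reconstruction failed");
    NumericMatrix Sigma(m, m);
    for (int k = 0; k < m; ++k)
      for (int j = 0; j <= k; ++j) {
        double v = P[(size_t)k * m + j];
        Sigma(j, k) = v;
        Sigma(k, j) = v;
      }
    out["Sigma"] = Sigma;
  }
  return out;
}

// Alternate the tightness condition xi_j = sqrt((abar_j - rho)^2 + quad_j)
// with the stationary point of the expected bound in rho. Each sub-step is
// a monotone coordinate update; a short burst approaches the joint fixed
// point. Returns the final (xi, rho).
// [[Rcpp::export]]
Rcpp::List cppUpdateXiRho(const NumericVector& abar, const NumericVector& quad,
                          double rho, int maxInner) {
  const int p = abar.size();
  const double halfp = p / 2.0 - 1.0;
  for (int it = 0; it < maxInner; ++it) {
    double sl = 0.0, sla = 0.0;
    for (int j = 0; j < p; ++j) {
      double dv = abar[j] - rho;
      double xi2 = dv * dv + quad[j];
      double lam2 = 2.0 * lambdaScalar(std::sqrt(xi2));
      sl += lam2;
      sla += lam2 * abar[j];
    }
    double rhoNew = (sla + halfp) / sl;
    bool done = std::abs(rhoNew - rho) < 1e-8 * (1.0 + std::abs(rho));
    rho = rhoNew;
    if (done) break;
  }
  NumericVector xi(p);
  for (int j = 0; j < p; ++j) {
    double dv = abar[j] - rho;
    xi[j] = std::sqrt(dv * dv + quad[j]);
  }
  return Rcpp::List::create(Rcpp::Named("xi") = xi, Rcpp::Named("rho") = rho);
}

// y = S x for a symmetric matrix stored fully (uses the upper triangle).
// [[Rcpp::export]]
NumericVector cppSymv(const NumericMatrix& S, const NumericVector& x) {
  const int n = S.nrow();
  const double one = 1.0, zero = 0.0;
  const int ione = 1;
  NumericVector y(n);
  F77_CALL(dsymv)("U", &n, &one, &S[0], &n, &x[0], &ione, &zero, &y[0],
                  &ione FCONE);
  return y;
}
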