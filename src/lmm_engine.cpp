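#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Profiled ML for the Gaussian linear mixed model
//   y = X beta + Z_i b_i + e,  b_i ~ N(0, sigma2 * Lambda),  e ~ N(0, sigma2 I)
// with one grouping factor (subject) and a q-dimensional random term
// (q = 2: intercept + age slope; q = 1: slope only).  Lambda = L L' is the
// relative random-effect covariance, parameterised by the lower triangle of
// L (theta), the standard profiled-deviance formulation: beta and sigma2
// are profiled out in closed form, leaving a q(q+1)/2-dimensional search
// solved by Nelder-Mead entirely in C++.  Subject-level cross-products are
// precomputed once per design, so a deviance evaluation is O(n_subjects)
// small-matrix work; this is what makes the forward search and its
// permutation null affordable.

namespace {

struct Precomp {
  cube S, U;     // per-subject Z'Z (q,q,ng) and Z'X (q,p,ng)
  mat v;         // per-subject Z'y (q,ng)
  mat XtX;
  vec Xty;
  double yty;
  uword n, p, q, ng;
};

void build_precomp(const mat& X, const mat& Z, const vec& y,
                   const ivec& starts, const ivec& ends, Precomp& pc) {
  pc.ng = starts.n_elem;
  pc.p = X.n_cols;
  pc.q = Z.n_cols;
  pc.n = X.n_rows;
  pc.S.set_size(pc.q, pc.q, pc.ng);
  pc.U.set_size(pc.q, pc.p, pc.ng);
  pc.v.set_size(pc.q, pc.ng);
  for (uword i = 0; i < pc.ng; ++i) {
    const uword a = starts[i], b = ends[i] - 1;
    const mat Zi = Z.rows(a, b);
    pc.S.slice(i) = Zi.t() * Zi;
    pc.U.slice(i) = Zi.t() * X.rows(a, b);
    pc.v.col(i) = Zi.t() * y.subvec(a, b);
  }
  pc.XtX = X.t() * X;
  pc.Xty = X.t() * y;
  pc.yty = dot(y, y);
}

mat theta_to_lambda(const vec& theta, const uword q) {
  mat L(q, q, fill::zeros);
  if (q == 1) {
    L(0, 0) = theta[0];
  } else {
    L(0, 0) = theta[0];
    L(1, 0) = theta[1];
    L(1, 1) = theta[2];
  }
  return L * L.t();
}

// Profiled -2 lnL; optionally returns beta, vcov, sigma2 at the solution.
// The per-subject 2x2 (or 1x1) algebra is written out in scalars: this is
// the innermost loop of every fit and avoids small-matrix temporaries.
double profiled_deviance(const vec& theta, const Precomp& pc,
                         vec* beta_out = nullptr, mat* vcov_out = nullptr,
                         double* sigma2_out = nullptr) {
  const uword p = pc.p;
  mat A = pc.XtX;
  vec b = pc.Xty;
  double c = pc.yty, logdet = 0.0;
  double* Ap = A.memptr();
  double* bp = b.memptr();
  std::vector<double> w1(p), w2(p);

  if (pc.q == 2) {
    const double t1 = theta[0], t2 = theta[1], t3 = theta[2];
    const double l11 = t1 * t1, l12 = t1 * t2, l22 = t2 * t2 + t3 * t3;
    for (uword i = 0; i < pc.ng; ++i) {
      const double* S = pc.S.slice_memptr(i);   // col-major 2x2
      const double s11 = S[0], s12 = S[1], s22 = S[3];
      const double b11 = 1.0 + s11 * l11 + s12 * l12;
      const double b12 = s11 * l12 + s12 * l22;
      const double b21 = s12 * l11 + s22 * l12;
      const double b22 = 1.0 + s12 * l12 + s22 * l22;
      const double det = b11 * b22 - b12 * b21;
      if (det <= 0.0) return datum::inf;
      logdet += std::log(det);
      const double m11 = (l11 * b22 - l12 * b21) / det;
      const double m12 = (-l11 * b12 + l12 * b11) / det;
      const double m21 = (l12 * b22 - l22 * b21) / det;
      const double m22 = (-l12 * b12 + l22 * b11) / det;
      const double ms = 0.5 * (m12 + m21);      // symmetrise numerically
      const double* U = pc.U.slice_memptr(i);   // 2 x p col-major
      for (uword j = 0; j < p; ++j) {
        const double u1 = U[2 * j], u2 = U[2 * j + 1];
        w1[j] = m11 * u1 + ms * u2;
        w2[j] = ms * u1 + m22 * u2;
      }
      for (uword k = 0; k < p; ++k) {
        const double u1k = U[2 * k], u2k = U[2 * k + 1];
        double* Acol = Ap + k * p;
        const double w1k = w1[k], w2k = w2[k];
        (void) u1k; (void) u2k;
        for (uword j = 0; j < p; ++j) {
          Acol[j] -= U[2 * j] * w1k + U[2 * j + 1] * w2k;
        }
      }
      const double v1 = pc.v(0, i), v2 = pc.v(1, i);
      for (uword j = 0; j < p; ++j) bp[j] -= w1[j] * v1 + w2[j] * v2;
      c -= m11 * v1 * v1 + 2.0 * ms * v1 * v2 + m22 * v2 * v2;
    }
  } else {
    const double lam = theta[0] * theta[0];
    for (uword i = 0; i < pc.ng; ++i) {
      const double s = pc.S.slice_memptr(i)[0];
      const double B = 1.0 + s * lam;
      logdet += std::log(B);
      const double m = lam / B;
      const double* U = pc.U.slice_memptr(i);   // 1 x p
      const double v1 = pc.v(0, i);
      for (uword k = 0; k < p; ++k) {
        const double wk = m * U[k];
        double* Acol = Ap + k * p;
        for (uword j = 0; j < p; ++j) Acol[j] -= U[j] * wk;
        bp[k] -= wk * v1;
      }
      c -= m * v1 * v1;
    }
  }

  vec beta;
  if (!solve(beta, A, b, solve_opts::no_approx)) return datum::inf;
  double rss = c - dot(b, beta);
  // noiseless-data guard, scaled so it dominates cancellation noise in the
  // accumulated cross-products (keeps the surface smooth when rss -> 0)
  const double rss_floor = 1e-12 * std::max(1.0, pc.yty);
  if (rss < rss_floor) rss = rss_floor;
  const double sigma2 = rss / pc.n;
  const double dev = pc.n * std::log(2.0 * M_PI * sigma2) + logdet + pc.n;

  if (beta_out) {
    *beta_out = beta;
    mat As = 0.5 * (A + A.t());
    mat Ainv;
    if (!inv_sympd(Ainv, As)) Ainv = pinv(As);
    *vcov_out = sigma2 * Ainv;
    *sigma2_out = sigma2;
  }
  return dev;
}

// Standard Nelder-Mead on the profiled deviance.
vec nelder_mead(vec x0, const Precomp& pc, const double reltol,
                const int maxit, double& fmin, bool& converged) {
  const uword d = x0.n_elem;
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  std::vector<vec> xs(d + 1);
  vec fs(d + 1);
  xs[0] = x0;
  fs[0] = profiled_deviance(x0, pc);
  for (uword i = 0; i < d; ++i) {
    vec xi = x0;
    xi[i] += (xi[i] != 0.0) ? 0.1 * std::abs(xi[i]) : 0.1;
    xs[i + 1] = xi;
    fs[i + 1] = profiled_deviance(xi, pc);
  }
  int it = 0;
  converged = false;
  while (it++ < maxit) {
    uvec ord = sort_index(fs);
    std::vector<vec> xs2(d + 1);
    vec fs2(d + 1);
    for (uword i = 0; i <= d; ++i) { xs2[i] = xs[ord[i]]; fs2[i] = fs[ord[i]]; }
    xs = xs2; fs = fs2;
    if (std::abs(fs[d] - fs[0]) <=
        reltol * (std::abs(fs[0]) + std::abs(fs[d]) + 1e-10)) {
      converged = true;
      break;
    }
    vec cen(d, fill::zeros);
    for (uword i = 0; i < d; ++i) cen += xs[i];
    cen /= d;
    vec xr = cen + alpha * (cen - xs[d]);
    double fr = profiled_deviance(xr, pc);
    if (fr < fs[0]) {
      vec xe = cen + gamma * (xr - cen);
      double fe = profiled_deviance(xe, pc);
      if (fe < fr) { xs[d] = xe; fs[d] = fe; }
      else { xs[d] = xr; fs[d] = fr; }
    } else if (fr < fs[d - 1]) {
      xs[d] = xr; fs[d] = fr;
    } else {
      vec xc = cen + rho * (xs[d] - cen);
      double fc = profiled_deviance(xc, pc);
      if (fc < fs[d]) { xs[d] = xc; fs[d] = fc; }
      else {
        for (uword i = 1; i <= d; ++i) {
          xs[i] = xs[0] + sigma * (xs[i] - xs[0]);
          fs[i] = profiled_deviance(xs[i], pc);
        }
      }
    }
  }
  uword best = fs.index_min();
  fmin = fs[best];
  return xs[best];
}

}  // namespace

// Full ML fit: precompute, optimise theta, return estimates.
// rows of X, Z, y must be grouped by subject; starts/ends are 0-based
// [start, end) row ranges per subject.  restart > 0 reruns Nelder-Mead from
// the first solution that many times (guards against simplex collapse).
// [[Rcpp::export]]
Rcpp::List lmm_fit_cpp(const arma::mat& X, const arma::mat& Z,
                       const arma::vec& y, const arma::ivec& starts,
                       const arma::ivec& ends, const arma::vec& start_theta,
                       const double reltol, const int maxit,
                       const int restart) {
  Precomp pc;
  build_precomp(X, Z, y, starts, ends, pc);

  double fmin;
  bool conv;
  vec th = nelder_mead(start_theta, pc, reltol, maxit, fmin, conv);
  for (int r = 0; r < restart; ++r) {
    double f2;
    bool c2;
    vec th2 = nelder_mead(th, pc, reltol, maxit, f2, c2);
    if (f2 < fmin - 1e-12) { th = th2; fmin = f2; conv = c2; }
    else { conv = conv || c2; break; }
  }

  vec beta;
  mat vcov;
  double sigma2;
  const double dev = profiled_deviance(th, pc, &beta, &vcov, &sigma2);
  return Rcpp::List::create(
    Rcpp::Named("theta") = th, Rcpp::Named("deviance") = dev,
    Rcpp::Named("beta") = beta, Rcpp::Named("vcov") = vcov,
    Rcpp::Named("sigma2") = sigma2,
    Rcpp::Named("G") = mat(sigma2 * theta_to_lambda(th, pc.q)),
    Rcpp::Named("converged") = conv);
}

// Profiled -2 lnL at a fixed theta (exposed for oracle tests).
// [[Rcpp::export]]
double lmm_deviance_cpp(const arma::vec& theta, const arma::mat& X,
                        const arma::mat& Z, const arma::vec& y,
                        const arma::ivec& starts, const arma::ivec& ends) {
  Precomp pc;
  build_precomp(X, Z, y, starts, ends, pc);
  return profiled_deviance(theta, pc);
}
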