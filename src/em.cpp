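#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// The EM engine is specialized for 1- and 2-dimensional data (the only cases
// the dependency measure needs): per-component densities and covariance
// updates are written out in scalar form, which keeps a model-selection sweep
// over component counts fast enough to score thousands of gene pairs.
//
// Restart strategy: every k-means++ initialization is run to a coarse
// tolerance first, and only the best-log-likelihood chain is then polished to
// the configured tolerance. Polishing is plain EM continued from the best
// chain's responsibilities, so the log-likelihood stays monotone and the
// returned fit dominates every restart.

struct Comp {
  double w;
  double mu1, mu2;
  double s11, s12, s22;  // s12, s22 unused when d == 1
};

// clamp the eigenvalues of a symmetric 2x2 covariance to >= fl
static void floor_cov2(double& s11, double& s12, double& s22, double fl) {
  if (s12 == 0.0) {
    if (s11 < fl) s11 = fl;
    if (s22 < fl) s22 = fl;
    return;
  }
  double tr = s11 + s22;
  double gap = std::sqrt(0.25 * (s11 - s22) * (s11 - s22) + s12 * s12);
  double l1 = 0.5 * tr + gap;  // l1 >= l2
  double l2 = 0.5 * tr - gap;
  if (l2 >= fl) return;
  // eigenvector for l1; pick the better-conditioned expression
  double v1, v2;
  if (std::fabs(l1 - s11) > std::fabs(l1 - s22)) {
    v1 = s12; v2 = l1 - s11;
  } else {
    v1 = l1 - s22; v2 = s12;
  }
  double nv = std::sqrt(v1 * v1 + v2 * v2);
  v1 /= nv; v2 /= nv;
  l2 = fl;
  if (l1 < fl) l1 = fl;
  s11 = l1 * v1 * v1 + l2 * v2 * v2;
  s22 = l1 * v2 * v2 + l2 * v1 * v1;
  s12 = (l1 - l2) * v1 * v2;
}

static const double LOG2PI = std::log(2.0 * M_PI);

struct EmState {
  std::vector<Comp> comp;
  std::vector<double> R;  // responsibilities, column-major R[g*n + i]
  double loglik;
  int iter;
  bool converged;
  double max_decrease;
  bool ok;
  EmState() : loglik(-datum::inf), iter(0), converged(false),
              max_decrease(0.0), ok(false) {}
};

// alternate M/E steps starting from the responsibilities in st.R;
// st.loglik (if finite) is the log-likelihood those responsibilities came
// from, used for the monotonicity ledger when a chain is resumed
static void em_chain(const mat& X, EmState& st, double tol, int max_iter,
                     double fl) {
  const uword n = X.n_rows, d = X.n_cols;
  const uword G = st.comp.size();
  const double* x1 = X.colptr(0);
  const double* x2 = (d == 2) ? X.colptr(1) : nullptr;
  std::vector<double>& R = st.R;
  std::vector<Comp>& comp = st.comp;
  std::vector<double> L(n * G);
  double ll_prev = st.loglik, ll = st.loglik;
  bool have_prev = std::isfinite(ll_prev);
  int it;

  for (it = 0; it < max_iter; ++it) {
    // ---- M-step ----
    for (uword g = 0; g < G; ++g) {
      const double* r = &R[g * n];
      double ng = 0.0;
      for (uword i = 0; i < n; ++i) ng += r[i];
      Comp& c = comp[g];
      if (ng < 1e-10) {
        // component captured no responsibility: freeze it at negligible weight
        c.w = 1e-12;
        continue;
      }
      c.w = ng / (double)n;
      double m1 = 0.0, m2 = 0.0;
      for (uword i = 0; i < n; ++i) m1 += r[i] * x1[i];
      m1 /= ng;
      if (d == 2) {
        for (uword i = 0; i < n; ++i) m2 += r[i] * x2[i];
        m2 /= ng;
      }
      double a11 = 0.0, a12 = 0.0, a22 = 0.0;
      if (d == 1) {
        for (uword i = 0; i < n; ++i) {
          double dx = x1[i] - m1;
          a11 += r[i] * dx * dx;
        }
        a11 /= ng;
        if (a11 < fl) a11 = fl;
      } else {
        for (uword i = 0; i < n; ++i) {
          double dx = x1[i] - m1, dy = x2[i] - m2;
          a11 += r[i] * dx * dx;
          a12 += r[i] * dx * dy;
          a22 += r[i] * dy * dy;
        }
        a11 /= ng; a12 /= ng; a22 /= ng;
        floor_cov2(a11, a12, a22, fl);
      }
      c.mu1 = m1; c.mu2 = m2;
      c.s11 = a11; c.s12 = a12; c.s22 = a22;
    }
    double wsum = 0.0;
    for (uword g = 0; g < G; ++g) wsum += comp[g].w;
    for (uword g = 0; g < G; ++g) comp[g].w /= wsum;

    // ---- E-step ----
    for (uword g = 0; g < G; ++g) {
      const Comp& c = comp[g];
      double* lg = &L[g * n];
      if (d == 1) {
        double logc = std::log(c.w) - 0.5 * (LOG2PI + std::log(c.s11));
        double inv = 0.5 / c.s11;
        for (uword i = 0; i < n; ++i) {
          double dx = x1[i] - c.mu1;
          lg[i] = logc - inv * dx * dx;
        }
      } else {
        double det = c.s11 * c.s22 - c.s12 * c.s12;
        double logc = std::log(c.w) - LOG2PI - 0.5 * std::log(det);
        double i11 = c.s22 / det, i22 = c.s11 / det, i12 = -c.s12 / det;
        for (uword i = 0; i < n; ++i) {
          double dx = x1[i] - c.mu1, dy = x2[i] - c.mu2;
          lg[i] = logc - 0.5 * (i11 * dx * dx + 2.0 * i12 * dx * dy + i22 * dy * dy);
        }
      }
    }
    ll = 0.0;
    for (uword i = 0; i < n; ++i) {
      double m = -datum::inf;
      for (uword g = 0; g < G; ++g) {
        double v = L[g * n + i];
        if (v > m) m = v;
      }
      double s = 0.0;
      for (uword g = 0; g < G; ++g) {
        double t = L[g * n + i] - m;
        double e = (t < -45.0) ? 0.0 : std::exp(t);  // below double precision
        R[g * n + i] = e;
        s += e;
      }
      ll += m + std::log(s);
      double sinv = 1.0 / s;
      for (uword g = 0; g < G; ++g) R[g * n + i] *= sinv;
    }

    if (have_prev) {
      double dec = ll_prev - ll;
      if (dec > st.max_decrease) st.max_decrease = dec;
      double rel = std::fabs(ll - ll_prev) / (std::fabs(ll_prev) + 1.0);
      if (rel < tol) { st.converged = true; ++it; break; }
    }
    ll_prev = ll;
    have_prev = true;
  }

  st.loglik = ll;
  st.iter += it;
  st.ok = std::isfinite(ll);
}

static EmState em_from_centers(const mat& X, const mat& centers, double tol,
                               int max_iter, double fl) {
  const uword n = X.n_rows, d = X.n_cols, G = centers.n_rows;
  EmState st;
  st.comp.resize(G);
  for (uword g = 0; g < G; ++g) {
    st.comp[g].w = 1.0 / (double)G;
    st.comp[g].mu1 = centers(g, 0);
    st.comp[g].mu2 = (d == 2) ? centers(g, 1) : 0.0;
    st.comp[g].s11 = st.comp[g].s22 = std::max(fl, 1e-12);
    st.comp[g].s12 = 0.0;
  }
  st.R.assign(n * G, 0.0);
  const double* x1 = X.colptr(0);
  const double* x2 = (d == 2) ? X.colptr(1) : nullptr;
  for (uword i = 0; i < n; ++i) {
    uword best = 0;
    double bd = datum::inf;
    for (uword g = 0; g < G; ++g) {
      double dx = x1[i] - centers(g, 0);
      double dd = dx * dx;
      if (d == 2) {
        double dy = x2[i] - centers(g, 1);
        dd += dy * dy;
      }
      if (dd < bd) { bd = dd; best = g; }
    }
    st.R[best * n + i] = 1.0;
  }
  em_chain(X, st, tol, max_iter, fl);
  return st;
}

//' @noRd
// [[Rcpp::export]]
Rcpp::List em_fit_engine(const arma::mat& X, const Rcpp::List& inits,
                         double tol, int max_iter, double cov_floor) {
  if (X.n_cols < 1 || X.n_cols > 2)
    Rcpp::stop("only 1- or 2-dimensional data are supported");
  const int nrest = inits.size();
  const double coarse_tol = std::max(tol, 1e-3);
  const int coarse_iter = std::min(max_iter, 100);

  EmState best;
  for (int r = 0; r < nrest; ++r) {
    mat centers = Rcpp::as<mat>(inits[r]);
    EmState st = (nrest == 1)
        ? em_from_centers(X, centers, tol, max_iter, cov_floor)
        : em_from_centers(X, centers, coarse_tol, coarse_iter, cov_floor);
    if (st.ok && (!best.ok || st.loglik > best.loglik)) best = st;
  }
  if (!best.ok)
    Rcpp::stop("EM failed for every restart (non-finite log-likelihood)");
  if (nrest > 1 && !(best.converged && coarse_tol <= tol)) {
    best.converged = false;
    em_chain(X, best, tol, max_iter, cov_floor);
  }

  const uword d = X.n_cols, G = best.comp.size();
  vec w(G);
  mat mu(G, d);
  cube S(d, d, G);
  for (uword g = 0; g < G; ++g) {
    const Comp& c = best.comp[g];
    w[g] = c.w;
    mu(g, 0) = c.mu1;
    S(0, 0, g) = c.s11;
    if (d == 2) {
      mu(g, 1) = c.mu2;
      S(0, 1, g) = c.s12;
      S(1, 0, g) = c.s12;
      S(1, 1, g) = c.s22;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = w,
      Rcpp::Named("means") = mu,
      Rcpp::Named("covariances") = S,
      Rcpp::Named("loglik") = best.loglik,
      Rcpp::Named("n_iter") = best.iter,
      Rcpp::Named("converged") = best.converged,
      Rcpp::Named("max_ll_decrease") = best.max_decrease);
}
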