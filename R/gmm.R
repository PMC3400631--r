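#' Mixture-fitting configuration
#'
#' Bundles the knobs shared by every mixture fit in the package: the component
#' search range, EM convergence control, restart count, covariance
#' regularization and the RNG seed. One `fit_config` is reused for the joint
#' and both marginal fits of a DBoMM score so the three models are selected
#' under identical conditions.
#'
#' @param g_min,g_max Component-count search range (inclusive).
#' @param tol Relative log-likelihood convergence tolerance for EM.
#' @param max_iter EM iteration cap per run.
#' @param n_restarts Independent k-means++ initializations per component
#'   count; the best log-likelihood run is kept.
#' @param cov_floor Covariance eigenvalue floor. `NULL` (default) resolves at
#'   fit time to `1e-6 * max(mean per-dimension variance, 1)`, which keeps the
#'   floor scale-aware yet nonzero for constant data.
#' @param seed Integer seed; all randomness in a fit flows through it.
#'
#' @return An object of class `fit_config`.
#' @export
#' @examples
#' fit_config(g_max = 3, seed = 42)
fit_config <- function(g_min = 1L, g_max = 9L, tol = 1e-6, max_iter = 500L,
                       n_restarts = 5L, cov_floor = NULL, seed = 1L) {
  g_min <- as.integer(g_min)
  g_max <- as.integer(g_max)
  if (g_min < 1L || g_min > g_max) stop("need 1 <= g_min <= g_max")
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  structure(list(g_min = g_min, g_max = g_max, tol = tol,
                 max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 cov_floor = cov_floor, seed = as.integer(seed)),
            class = "fit_config")
}

#' Bayesian Information Criterion (maximize convention)
#'
#' `BIC = 2*loglik - k*ln(n)`: larger values indicate better models, the
#' convention under which the DBoMM score of a dependent pair is positive.
#'
#' @param loglik Maximized log-likelihood (natural log).
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return The BIC value.
#' @export
#' @examples
#' bic_score(-200, 5, 100)
bic_score <- function(loglik, k, n) {
  if (!is.finite(loglik)) stop("loglik must be finite")
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be a positive integer")
  if (k < 0) stop("k must be nonnegative")
  2 * loglik - k * log(n)
}

# free parameters of a G-component unconstrained Gaussian mixture:
# (G-1) weights + G*d means + G*d*(d+1)/2 covariance entries
gmm_n_params <- function(G, d) {
  as.integer((G - 1L) + G * d + G * d * (d + 1L) / 2L)
}

# coerce 1-D vector or n x d matrix (d <= 2) to a point matrix
as_point_matrix <- function(data) {
  if (is.null(dim(data))) data <- matrix(as.numeric(data), ncol = 1L)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) > 2L) stop("only 1- or 2-dimensional data are supported")
  if (nrow(data) < 1L) stop("data must be nonempty")
  if (!all(is.finite(data))) stop("data must be finite")
  dimnames(data) <- NULL
  data
}

resolve_cov_floor <- function(X, config) {
  if (!is.null(config$cov_floor)) return(config$cov_floor)
  n <- nrow(X)
  vscale <- mean(apply(X, 2L, function(v) sum((v - mean(v))^2) / n))
  1e-6 * max(vscale, 1)
}

# k-means++ seeding: centers are data points, chosen with squared-distance
# weighting; uses the current R RNG stream
kmeanspp_centers <- function(X, G) {
  n <- nrow(X)
  idx <- integer(G)
  idx[1L] <- sample.int(n, 1L)
  if (G > 1L) {
    d2 <- rowSums((X - X[rep.int(idx[1L], n), , drop = FALSE])^2)
    for (g in 2:G) {
      w <- if (all(d2 == 0)) rep.int(1, n) else d2
      idx[g] <- sample.int(n, 1L, prob = w)
      d2g <- rowSums((X - X[rep.int(idx[g], n), , drop = FALSE])^2)
      d2 <- pmin(d2, d2g)
    }
  }
  X[idx, , drop = FALSE]
}

new_gmm <- function(engine, G, X, config, cov_floor) {
  d <- ncol(X)
  n <- nrow(X)
  covs <- lapply(seq_len(G), function(g) {
    S <- engine$covariances[, , g, drop = TRUE]
    if (d == 1L) matrix(S, 1L, 1L) else matrix(S, d, d)
  })
  k <- gmm_n_params(G, d)
  structure(list(
    dimension = d,
    G = as.integer(G),
    weights = as.numeric(engine$weights),
    means = matrix(engine$means, G, d),
    covariances = covs,
    loglik = engine$loglik,
    n_params = k,
    n_obs = n,
    bic = bic_score(engine$loglik, k, n),
    converged = isTRUE(engine$converged),
    n_iter = engine$n_iter,
    max_ll_decrease = engine$max_ll_decrease,
    cov_floor = cov_floor,
    data = X,
    config = config
  ), class = "gmm")
}

#' Fit a Gaussian mixture with a fixed number of components
#'
#' EM fit of a `G`-component Gaussian mixture with fully unconstrained
#' per-component covariances (the "VVV" parameterization), for 1- or
#' 2-dimensional data. Runs `config$n_restarts` seeded k-means++
#' initializations and keeps the best log-likelihood solution. Non-convergence
#' within `max_iter` returns the best iterate with `converged = FALSE` rather
#' than failing.
#'
#' @param data Numeric vector (univariate) or an n x 2 matrix (paired
#'   profiles).
#' @param G Number of mixture components.
#' @param config A [fit_config()].
#' @return An object of class `gmm`: weights, means, covariances, `loglik`,
#'   `n_params`, `n_obs`, `bic`, convergence information and the fitted data.
#' @export
#' @examples
#' x <- c(rnorm(100), rnorm(100, 8))
#' em_fit(x, G = 2, fit_config(seed = 1))
em_fit <- function(data, G, config = fit_config()) {
  X <- as_point_matrix(data)
  G <- as.integer(G)
  if (G < 1L) stop("G must be >= 1")
  n_distinct <- nrow(unique(X))
  if (n_distinct < G) {
    stop("degenerate data: ", n_distinct, " distinct point(s) but G = ", G)
  }
  fl <- resolve_cov_floor(X, config)
  n_init <- if (G == 1L) 1L else config$n_restarts
  inits <- withr::with_seed(config$seed, {
    lapply(seq_len(n_init), function(i) kmeanspp_centers(X, G))
  })
  engine <- em_fit_engine(X, inits, config$tol, config$max_iter, fl)
  new_gmm(engine, G, X, config, fl)
}

#' Select the best mixture by BIC
#'
#' Fits mixtures for every component count in `config$g_min:config$g_max`
#' (counts exceeding the number of distinct data points are skipped) and
#' returns the fit with maximal BIC; ties break toward fewer components.
#'
#' @inheritParams em_fit
#' @return The selected `gmm` object.
#' @export
#' @examples
#' fit_best_mixture(rnorm(200), fit_config(g_max = 4, seed = 7))
fit_best_mixture <- function(data, config = fit_config()) {
  X <- as_point_matrix(data)
  n_distinct <- nrow(unique(X))
  g_hi <- min(config$g_max, n_distinct)
  if (config$g_min > g_hi) {
    stop("fewer distinct points (", n_distinct, ") than g_min (", config$g_min, ")")
  }
  best <- NULL
  for (G in config$g_min:g_hi) {
    fit <- em_fit(X, G, config)
    if (is.null(best) || fit$bic > best$bic) best <- fit
  }
  best
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%dD, unconstrained covariance): G = %d, n = %d\n",
              x$dimension, x$G, x$n_obs))
  cat(sprintf("  loglik = %.4f, k = %d, BIC = %.4f, converged = %s\n",
              x$loglik, x$n_params, x$bic, x$converged))
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}
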