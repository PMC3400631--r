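#' Euclidean distance between two expression profiles
#'
#' @param x,y Numeric profiles of equal length.
#' @return Nonnegative distance; 0 iff `x == y`. Smaller values indicate
#'   stronger dependence when used as a dependency measure.
#' @export
#' @examples
#' euclidean(c(0, 0), c(3, 4))
euclidean <- function(x, y) {
  check_profiles(x, y, min_n = 1L)
  sqrt(sum((x - y)^2))
}

#' Pearson correlation between two expression profiles
#'
#' Standard product-moment correlation about the mean expression levels.
#' Constant profiles are rejected (the coefficient is undefined) rather than
#' silently scored 0.
#'
#' @inheritParams euclidean
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  check_profiles(x, y, min_n = 2L)
  if (var(x) == 0 || var(y) == 0) {
    stop("Pearson correlation undefined for a constant profile")
  }
  cor(x, y)
}

#' Kendall's tau rank correlation (tau-b)
#'
#' Tie-corrected concordant-minus-discordant pair statistic; equals tau-a when
#' no ties are present.
#'
#' @inheritParams euclidean
#' @return Rank correlation in `[-1, 1]`.
#' @export
kendall_tau <- function(x, y) {
  check_profiles(x, y, min_n = 2L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("Kendall's tau undefined for an all-tied profile")
  }
  cor(x, y, method = "kendall")
}

#' Binned mutual information between two expression profiles
#'
#' Each profile is independently discretized into `bins` equal-width intervals
#' over its own observed range (the expression values are treated as discrete
#' after binning), and mutual information is computed from the joint count
#' table in nats, with the convention `0 * log 0 = 0`. A constant profile
#' occupies a single bin and yields MI 0. `binning = "frequency"` switches to
#' equal-frequency (quantile) bins.
#'
#' @inheritParams euclidean
#' @param bins Number of bins per profile (default 10).
#' @param binning `"width"` (default) for equal-width bins, `"frequency"` for
#'   quantile bins.
#' @return Mutual information in nats, `>= 0`.
#' @export
#' @examples
#' x <- rep(c(0, 1), 10)
#' mutual_information(x, x, bins = 2)  # ln 2
mutual_information <- function(x, y, bins = 10L, binning = c("width", "frequency")) {
  check_profiles(x, y, min_n = 1L)
  binning <- match.arg(binning)
  if (bins < 1L) stop("bins must be >= 1")
  bx <- discretize_profile(x, bins, binning)
  by <- discretize_profile(y, bins, binning)
  mi_from_table(table(bx, by))
}

discretize_profile <- function(x, bins, binning = "width") {
  r <- range(x)
  if (r[1] == r[2]) return(rep.int(1L, length(x)))
  if (binning == "width") {
    idx <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
    pmin.int(as.integer(idx), as.integer(bins))
  } else {
    qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
    as.integer(cut(x, breaks = qs, include.lowest = TRUE))
  }
}

mi_from_table <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / e[keep]))
}

check_profiles <- function(x, y, min_n = 1L) {
  if (length(x) != length(y)) {
    stop("profiles have different lengths (", length(x), " vs ", length(y), ")")
  }
  if (length(x) < min_n) stop("profiles must have length >= ", min_n)
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("profiles must be finite")
  invisible(TRUE)
}

# lexicographic order used to canonicalize a pair before the joint fit,
# making dbomm(x, y) and dbomm(y, x) bit-identical
lex_greater <- function(x, y) {
  d <- x != y
  if (!any(d)) return(FALSE)
  i <- which.max(d)
  x[i] > y[i]
}

swap_joint_model <- function(model) {
  model$means <- model$means[, c(2L, 1L), drop = FALSE]
  model$covariances <- lapply(model$covariances,
                              function(S) S[c(2L, 1L), c(2L, 1L)])
  model$data <- model$data[, c(2L, 1L), drop = FALSE]
  model
}

#' Fit the joint and marginal mixtures of a gene pair
#'
#' Workhorse behind [dbomm()] and [loglik_ratio()]: selects (by BIC) a
#' bivariate mixture for the paired profiles and a univariate mixture for each
#' marginal, all under the same `config`, and returns the three models
#' together with the DBoMM and log-likelihood-ratio statistics. Component
#' counts are selected independently for the three fits.
#'
#' @inheritParams euclidean
#' @param config A [fit_config()] shared by the three fits.
#' @return A list with elements `joint`, `marginal_x`, `marginal_y` (`gmm`
#'   objects), `dbomm` and `llr`.
#' @export
dbomm_fit <- function(x, y, config = fit_config()) {
  check_profiles(x, y, min_n = 2L)
  if (length(x) < 10L) {
    warning("fewer than 10 conditions; mixture fits will be unstable")
  }
  swap <- lex_greater(x, y)
  P <- if (swap) cbind(y, x) else cbind(x, y)
  joint <- fit_best_mixture(P, config)
  # marginals subtracted in canonical order so the score is bit-symmetric
  m1 <- fit_best_mixture(P[, 1L], config)
  m2 <- fit_best_mixture(P[, 2L], config)
  score <- joint$bic - m1$bic - m2$bic
  llr <- joint$loglik - m1$loglik - m2$loglik
  if (swap) joint <- swap_joint_model(joint)
  list(joint = joint,
       marginal_x = if (swap) m2 else m1,
       marginal_y = if (swap) m1 else m2,
       dbomm = score, llr = llr)
}

#' DBoMM dependency score
#'
#' The difference in BIC between the selected joint bivariate mixture and the
#' product of the selected marginal univariate mixtures:
#' `BIC(M_joint) - BIC(M_x) - BIC(M_y)` under the maximize convention
#' `BIC = 2 ln L - k ln n`. Larger values indicate stronger dependence; zero
#' is the natural decision threshold (the joint model wins on posterior model
#' probability). With the component search fixed at `G = 1` the score reduces
#' to `-n ln(1 - r^2) - ln n`, a pure function of the sample correlation.
#'
#' @inheritParams dbomm_fit
#' @return The DBoMM score (symmetric in `x` and `y`).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(100); y <- 0.8 * x + rnorm(100, sd = 0.6)
#' dbomm(x, y, fit_config(g_max = 3, seed = 1))
dbomm <- function(x, y, config = fit_config()) {
  dbomm_fit(x, y, config)$dbomm
}

#' Log-likelihood-ratio dependency score
#'
#' `loglik(M_joint) - loglik(M_x) - loglik(M_y)` for the BIC-selected models;
#' the unpenalized variant of [dbomm()]. The two satisfy
#' `dbomm = 2*llr - (k_joint - k_x - k_y) * ln n`.
#'
#' @inheritParams dbomm_fit
#' @return The log-likelihood ratio (nats).
#' @export
loglik_ratio <- function(x, y, config = fit_config()) {
  dbomm_fit(x, y, config)$llr
}

measure_orientation <- function(method) {
  # higher-is-dependent for the model/information scores and Pearson,
  # lower-is-dependent for the distance-like Euclidean and for tau as tested
  # against curated edges
  switch(method,
         dbomm = , llr = , mi = , cor = "higher",
         euc = , tau = "lower",
         stop("unknown method: ", method))
}

#' Score a panel of gene pairs with one dependency measure
#'
#' @param expr Expression matrix (genes x conditions) with unique gene row
#'   names, e.g. from [read_expression_matrix()] or [simulate_expression()].
#' @param pairs Two-column data frame or matrix of gene identifiers; pairs
#'   must be unique as unordered pairs.
#' @param method One of `"dbomm"`, `"llr"`, `"euc"`, `"cor"`, `"tau"`, `"mi"`.
#' @param config [fit_config()] used by the model-based methods; its seed is
#'   applied per pair, so results do not depend on evaluation order.
#' @param bins Bin count for `method = "mi"`.
#' @return A `dependency_scores` object: a data frame with columns `gene_a`,
#'   `gene_b`, `score` and (for model-based methods) the selected component
#'   counts, plus `method` and `orientation` attributes.
#' @export
score_all_pairs <- function(expr, pairs, method = c("dbomm", "llr", "euc", "cor", "tau", "mi"),
                            config = fit_config(), bins = 10L) {
  method <- match.arg(method)
  expr <- validate_expression_matrix(expr)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("pairs must have two columns")
  pairs <- data.frame(gene_a = as.character(pairs[[1L]]),
                      gene_b = as.character(pairs[[2L]]),
                      stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(expr))
  if (length(unknown) > 0L) {
    stop("gene id(s) not in expression matrix: ", paste(unknown, collapse = ", "))
  }
  key <- paste(pmin(pairs$gene_a, pairs$gene_b), pmax(pairs$gene_a, pairs$gene_b))
  if (anyDuplicated(key)) {
    stop("duplicate (unordered) pair(s): ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (any(pairs$gene_a == pairs$gene_b)) {
    stop("self-pair(s) are not scoreable")
  }

  n_pairs <- nrow(pairs)
  scores <- numeric(n_pairs)
  g_joint <- g_x <- g_y <- rep(NA_integer_, n_pairs)

  if (method %in% c("dbomm", "llr")) {
    # marginal fits depend only on the gene, so cache them per gene
    marg_cache <- new.env(parent = emptyenv())
    get_marginal <- function(g) {
      if (is.null(marg_cache[[g]])) {
        marg_cache[[g]] <- fit_best_mixture(expr[g, ], config)
      }
      marg_cache[[g]]
    }
    for (i in seq_len(n_pairs)) {
      x <- expr[pairs$gene_a[i], ]
      y <- expr[pairs$gene_b[i], ]
      swap <- lex_greater(x, y)
      P <- if (swap) cbind(y, x) else cbind(x, y)
      joint <- fit_best_mixture(P, config)
      mx <- get_marginal(pairs$gene_a[i])
      my <- get_marginal(pairs$gene_b[i])
      m1 <- if (swap) my else mx  # canonical subtraction order (symmetry)
      m2 <- if (swap) mx else my
      scores[i] <- if (method == "dbomm") {
        joint$bic - m1$bic - m2$bic
      } else {
        joint$loglik - m1$loglik - m2$loglik
      }
      g_joint[i] <- joint$G
      g_x[i] <- mx$G
      g_y[i] <- my$G
    }
  } else {
    fun <- switch(method,
                  euc = euclidean,
                  cor = pearson,
                  tau = kendall_tau,
                  mi = function(x, y) mutual_information(x, y, bins = bins))
    for (i in seq_len(n_pairs)) {
      scores[i] <- fun(expr[pairs$gene_a[i], ], expr[pairs$gene_b[i], ])
    }
  }
  if (any(!is.finite(scores))) stop("non-finite score produced")

  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    score = scores,
                    n_components_joint = g_joint,
                    n_components_x = g_x,
                    n_components_y = g_y,
                    stringsAsFactors = FALSE)
  structure(out, method = method,
            orientation = measure_orientation(method),
            mi_bins = if (method == "mi") as.integer(bins) else NULL,
            class = c("dependency_scores", "data.frame"))
}

#' @export
print.dependency_scores <- function(x, ...) {
  cat(sprintf("Dependency scores: method = %s (%s-is-dependent), %d pair(s)\n",
              attr(x, "method"), attr(x, "orientation"), nrow(x)))
  NextMethod()
}
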