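#' Assign experimental conditions to mixture components
#'
#' Given the BIC-selected joint mixture of a gene pair, computes each
#' condition's posterior membership (responsibility) for every component and
#' hard-assigns it to the maximum-posterior component (ties break toward the
#' lower component index). Conditions falling in the same component are
#' experiments under which the pair shows the same joint expression regime,
#' which is how a condition-dependent regulatory interaction is read off the
#' fitted model.
#'
#' @param model A 2-dimensional `gmm` fitted on exactly `cbind(x, y)` (checked
#'   against the data stored in the model).
#' @param x,y The paired expression profiles the model was fitted on.
#' @param condition_ids Optional condition labels (defaults to `C1..Cn`).
#' @return A `condition_clustering` object: `labels`, `posteriors` (n x G),
#'   `cluster_means` (model means), `cluster_sizes`, `condition_ids` and the
#'   fitted model.
#' @export
#' @examples
#' p <- make_pair("dependent", n = 120, n_components = 2, seed = 3)
#' fit <- fit_best_mixture(cbind(p$x, p$y), fit_config(g_max = 4, seed = 3))
#' cl <- assign_conditions(fit, p$x, p$y)
#' table(cl$labels)
assign_conditions <- function(model, x, y, condition_ids = NULL) {
  stopifnot(inherits(model, "gmm"))
  if (model$dimension != 2L) stop("model must be bivariate")
  check_profiles(x, y, min_n = 1L)
  P <- cbind(as.numeric(x), as.numeric(y))
  dimnames(P) <- NULL
  if (model$n_obs != nrow(P) || !identical(model$data, P)) {
    stop("model was not fitted on these profiles")
  }
  if (is.null(condition_ids)) {
    condition_ids <- paste0("C", seq_len(nrow(P)))
  }
  if (length(condition_ids) != nrow(P)) {
    stop("condition_ids length must match the number of conditions")
  }

  G <- model$G
  logdens <- sapply(seq_len(G), function(g) {
    log(model$weights[g]) +
      dmvnorm2_log(P, model$means[g, ], model$covariances[[g]])
  })
  logdens <- matrix(logdens, nrow = nrow(P), ncol = G)
  m <- apply(logdens, 1L, max)
  post <- exp(logdens - m)
  post <- post / rowSums(post)
  labels <- apply(post, 1L, which.max)  # ties -> lower index
  structure(list(
    labels = as.integer(labels),
    posteriors = post,
    cluster_means = model$means,
    cluster_sizes = tabulate(labels, nbins = G),
    condition_ids = as.character(condition_ids),
    model = model
  ), class = "condition_clustering")
}

# log density of a bivariate (or univariate) normal at the rows of P
dmvnorm2_log <- function(P, mu, S) {
  d <- ncol(P)
  ch <- chol(S)
  Z <- forwardsolve(t(ch), t(P) - mu)
  quad <- colSums(Z^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
}

#' Per-cluster condition summary
#'
#' One row per mixture component: size, empirical mean expression of both
#' genes over the hard-assigned member conditions, the model (component)
#' means, and the member condition identifiers. Components that capture no
#' condition are still reported, with size 0 and `NA` empirical means.
#'
#' @param clustering A [assign_conditions()] result.
#' @return Data frame with columns `cluster`, `size`, `mean_x`, `mean_y`,
#'   `model_mean_x`, `model_mean_y`, `conditions`.
#' @export
cluster_report <- function(clustering) {
  stopifnot(inherits(clustering, "condition_clustering"))
  model <- clustering$model
  G <- model$G
  P <- model$data
  out <- lapply(seq_len(G), function(g) {
    members <- clustering$labels == g
    data.frame(
      cluster = g,
      size = sum(members),
      mean_x = if (any(members)) mean(P[members, 1L]) else NA_real_,
      mean_y = if (any(members)) mean(P[members, 2L]) else NA_real_,
      model_mean_x = model$means[g, 1L],
      model_mean_y = model$means[g, 2L],
      conditions = paste(clustering$condition_ids[members], collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.condition_clustering <- function(x, ...) {
  cat(sprintf("Condition clustering: %d condition(s) in %d component(s)\n",
              length(x$labels), x$model$G))
  print(table(cluster = x$labels))
  invisible(x)
}
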