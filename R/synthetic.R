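#' Sample a gold-standard regulatory network topology
#'
#' Draws a directed TF -> gene network with preferential attachment on TF
#' out-degree, giving the hub-heavy degree distribution typical of curated
#' regulatory networks. TFs are the first `n_tfs` genes; edges never
#' self-loop and are unique.
#'
#' @param n_genes Total number of genes.
#' @param n_tfs Number of transcription factors (must be `< n_genes`).
#' @param n_edges Number of edges; at most `n_tfs * (n_genes - 1)`.
#' @param seed RNG seed.
#' @return List with `edges` (data frame `tf`, `target`), `tfs` and `genes`.
#' @export
#' @examples
#' net <- simulate_network(20, 4, 30, seed = 1)
#' head(net$edges)
simulate_network <- function(n_genes = 100L, n_tfs = 10L, n_edges = 150L,
                             seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_tfs <- as.integer(n_tfs)
  n_edges <- as.integer(n_edges)
  if (n_tfs < 1L || n_tfs >= n_genes) stop("need 1 <= n_tfs < n_genes")
  max_edges <- n_tfs * (n_genes - 1L)
  if (n_edges < 1L || n_edges > max_edges) {
    stop("n_edges must be in 1..", max_edges, " for this gene/TF count")
  }
  width <- max(3L, nchar(n_genes))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(n_genes))
  tfs <- genes[seq_len(n_tfs)]

  edges <- withr::with_seed(seed, {
    taken <- new.env(parent = emptyenv())
    outdeg <- rep.int(0L, n_tfs)
    tf_idx <- integer(n_edges)
    tgt_idx <- integer(n_edges)
    made <- 0L
    tries <- 0L
    max_tries <- 50L * n_edges
    while (made < n_edges && tries < max_tries) {
      tries <- tries + 1L
      i <- sample.int(n_tfs, 1L, prob = outdeg + 1)
      j <- sample.int(n_genes, 1L)
      if (j == i) next
      key <- paste0(i, "_", j)
      if (!is.null(taken[[key]])) next
      taken[[key]] <- TRUE
      made <- made + 1L
      tf_idx[made] <- i
      tgt_idx[made] <- j
      outdeg[i] <- outdeg[i] + 1L
    }
    if (made < n_edges) {
      # dense request: fill the remainder uniformly from the untaken pairs
      all_pairs <- expand.grid(i = seq_len(n_tfs), j = seq_len(n_genes))
      all_pairs <- all_pairs[all_pairs$i != all_pairs$j, , drop = FALSE]
      free <- !(paste0(all_pairs$i, "_", all_pairs$j) %in% ls(taken))
      pool <- all_pairs[free, , drop = FALSE]
      pick <- pool[sample.int(nrow(pool), n_edges - made), , drop = FALSE]
      idx <- made + seq_len(nrow(pick))
      tf_idx[idx] <- pick$i
      tgt_idx[idx] <- pick$j
    }
    data.frame(tf = genes[tf_idx], target = genes[tgt_idx],
               stringsAsFactors = FALSE)
  })
  list(edges = edges, tfs = tfs, genes = genes)
}

# saturating Hill-type transfer of a TF activity in [0, 1]
hill <- function(a, coef, k) a^coef / (k^coef + a^coef)

#' Simulate an expression compendium over a known network
#'
#' Steady-state style generator emulating SynTReN-like benchmark data: per
#' condition, each TF gets an independent latent activity in `[0, 1]`; a
#' regulated gene's noise-free expression is the average over its regulators
#' of a saturating Hill-type term (activating edges contribute `h(a)`,
#' repressing edges `1 - h(a)`; signs are drawn once per edge at generation
#' time); a TF's own expression tracks its latent activity, and unregulated
#' non-TF genes vary with their own independent latent activity. Expression
#' is on a centred log-ratio-like scale (baseline 0).
#'
#' Noise enters in two forms, both scaled by `noise_level`: biological noise
#' multiplies each noise-free value by `exp(N(0, noise_level^2))`
#' (lognormal perturbation of the regulated mean), and experimental noise
#' adds `N(0, (noise_level * sd_signal)^2)` measurement error, where
#' `sd_signal` is the within-gene standard deviation of the noise-free
#' matrix. At `noise_level = 0` the map from latent activities to the matrix
#' is deterministic.
#'
#' @param edges Data frame of directed edges (`tf`, `target`), e.g. from
#'   [simulate_network()].
#' @param tfs Transcription-factor identifiers (edge sources must be TFs).
#' @param n_conditions Number of experimental conditions (columns).
#' @param noise_level Noise intensity in `[0, 1]`; the benchmark sweep uses
#'   0, 0.2, 0.4, 0.6, 0.8.
#' @param seed RNG seed; regeneration with identical arguments is
#'   bit-identical.
#' @param genes Gene universe; defaults to TFs plus all edge endpoints.
#' @param reg_gain,tf_gain Output amplitude of regulation and of a TF's own
#'   activity.
#' @param hill_coef,hill_k Hill coefficient and half-saturation constant.
#' @param p_repress Probability that an edge is repressing.
#' @return A `synthetic_dataset`: `expr` (genes x conditions matrix),
#'   `gold_edges`, `tfs`, `noise_level`, `seed` and a `params` echo sufficient
#'   to regenerate the dataset.
#' @export
#' @examples
#' net <- simulate_network(20, 4, 30, seed = 1)
#' ds <- simulate_expression(net$edges, net$tfs, n_conditions = 50,
#'                           noise_level = 0.2, seed = 1)
#' dim(ds$expr)
simulate_expression <- function(edges, tfs, n_conditions = 100L,
                                noise_level = 0, seed = 1L, genes = NULL,
                                reg_gain = 2, tf_gain = 2,
                                hill_coef = 2, hill_k = 0.5,
                                p_repress = 0.3) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges)[1:2] <- c("tf", "target")
  tfs <- as.character(tfs)
  if (!all(edges$tf %in% tfs)) stop("every edge source must be a TF")
  if (any(edges$tf == edges$target)) stop("self-loops are not allowed")
  if (!is.numeric(noise_level) || length(noise_level) != 1L ||
      noise_level < 0 || noise_level > 1) {
    stop("noise_level must be a single value in [0, 1]")
  }
  if (is.null(genes)) genes <- unique(c(tfs, edges$tf, edges$target))
  genes <- as.character(genes)
  n_genes <- length(genes)
  n_conditions <- as.integer(n_conditions)

  withr::with_seed(seed, {
    signs <- ifelse(rbinom(nrow(edges), 1L, p_repress) == 1L, -1L, 1L)
    # latent activity per gene per condition; only a gene's own row (for TFs
    # and unregulated genes) and regulator rows (via the network) are used
    activity <- matrix(runif(n_genes * n_conditions), n_genes, n_conditions,
                       dimnames = list(genes, NULL))
    regulated <- genes %in% edges$target
    is_tf <- genes %in% tfs

    signal <- matrix(0, n_genes, n_conditions,
                     dimnames = list(genes, paste0("cond", seq_len(n_conditions))))
    for (i in seq_len(n_genes)) {
      g <- genes[i]
      row <- numeric(n_conditions)
      if (is_tf[i] || !regulated[i]) {
        # own latent activity, centred to the log-ratio-like scale
        row <- row + tf_gain * (activity[g, ] - 0.5)
      }
      if (regulated[i]) {
        e <- which(edges$target == g)
        contrib <- matrix(0, length(e), n_conditions)
        for (k in seq_along(e)) {
          a <- activity[edges$tf[e[k]], ]
          h <- hill(a, hill_coef, hill_k)
          contrib[k, ] <- if (signs[e[k]] > 0) h else 1 - h
        }
        row <- row + reg_gain * (colMeans(contrib) - 0.5)
      }
      signal[i, ] <- row
    }

    expr <- signal
    if (noise_level > 0) {
      # biological: lognormal multiplicative perturbation of the mean
      expr <- expr * matrix(rlnorm(length(expr), meanlog = 0, sdlog = noise_level),
                            n_genes, n_conditions)
      # experimental: additive Gaussian measurement error, scaled to the
      # typical within-gene signal variation
      sd_signal <- sqrt(mean(apply(signal, 1L, var)))
      expr <- expr + matrix(rnorm(length(expr), sd = noise_level * sd_signal),
                            n_genes, n_conditions)
    }

    structure(list(
      expr = expr,
      gold_edges = edges[, c("tf", "target")],
      tfs = tfs,
      noise_level = noise_level,
      seed = as.integer(seed),
      params = list(n_conditions = n_conditions, genes = genes,
                    edge_signs = signs, reg_gain = reg_gain,
                    tf_gain = tf_gain, hill_coef = hill_coef,
                    hill_k = hill_k, p_repress = p_repress,
                    noise_model = list(
                      biological = "multiplicative lognormal, sdlog = noise_level",
                      experimental = "additive Gaussian, sd = noise_level * within-gene signal sd"))
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d gene(s) x %d condition(s), %d gold edge(s), noise %.2f, seed %d\n",
              nrow(x$expr), ncol(x$expr), nrow(x$gold_edges),
              x$noise_level, x$seed))
  invisible(x)
}

#' Generate a dependent or independent expression-profile pair
#'
#' Test-scale generator for the two regimes a dependency measure must
#' separate. `kind = "dependent"` draws `(x, y)` jointly from an
#' `n_components` bivariate Gaussian mixture with unit within-component
#' variances and within-component correlation `within_r`; the distinct
#' component means sit on a circle of radius `mean_spacing`, so the
#' between-component covariance of `x` and `y` is (near) zero and the
#' dependence is conditional — a shared component plus within-component
#' correlation — rather than a single global linear trend. That is the
#' regime a condition-dependent regulatory interaction produces, where
#' profile-distance measures are weak but a joint mixture model is not.
#' `kind = "independent"` keeps the same marginal mixtures but decouples the
#' component draw and the noise of `x` from those of `y`, so the generative
#' mutual information between the two is 0.
#'
#' @param kind `"dependent"` or `"independent"`.
#' @param n Number of conditions (>= 10).
#' @param n_components Number of mixture components.
#' @param within_r Within-component correlation, in `(-1, 1)`.
#' @param seed RNG seed.
#' @param mean_spacing Radius of the circle the component means sit on.
#' @return List with `x`, `y` and (planted) `components` — for dependent
#'   pairs the shared component label, for independent pairs the label of
#'   `x`'s draw.
#' @export
#' @examples
#' p <- make_pair("dependent", n = 100, seed = 1)
#' cor(p$x, p$y)
make_pair <- function(kind = c("dependent", "independent"), n = 100L,
                      n_components = 3L, within_r = 0.8, seed = 1L,
                      mean_spacing = 4) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 10L) stop("n must be >= 10")
  if (!is.numeric(within_r) || within_r <= -1 || within_r >= 1) {
    stop("within_r must be in (-1, 1)")
  }
  n_components <- as.integer(n_components)
  if (n_components < 1L) stop("n_components must be >= 1")
  theta <- pi / 2 + 2 * pi * (seq_len(n_components) - 1L) / n_components
  mu_x <- mean_spacing * cos(theta)
  mu_y <- mean_spacing * sin(theta)
  if (n_components == 1L) mu_x <- mu_y <- 0

  withr::with_seed(seed, {
    if (kind == "dependent") {
      z <- sample.int(n_components, n, replace = TRUE)
      e1 <- rnorm(n)
      e2 <- rnorm(n)
      x <- mu_x[z] + e1
      y <- mu_y[z] + within_r * e1 + sqrt(1 - within_r^2) * e2
      list(x = x, y = y, components = z)
    } else {
      zx <- sample.int(n_components, n, replace = TRUE)
      zy <- sample.int(n_components, n, replace = TRUE)
      x <- mu_x[zx] + rnorm(n)
      y <- mu_y[zy] + rnorm(n)
      list(x = x, y = y, components = zx)
    }
  })
}

#' Scorable TF-gene pair panel of a synthetic dataset
#'
#' All (TF, gene) pairs of the dataset's universe, as an unordered unique
#' panel ready for [score_all_pairs()] (TF-TF pairs appear once).
#'
#' @param ds A `synthetic_dataset`.
#' @return Data frame with columns `gene_a`, `gene_b`.
#' @export
tf_gene_pairs <- function(ds) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  genes <- rownames(ds$expr)
  all_pairs <- expand.grid(gene_a = ds$tfs, gene_b = genes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$gene_a != all_pairs$gene_b, , drop = FALSE]
  key <- paste(pmin(all_pairs$gene_a, all_pairs$gene_b),
               pmax(all_pairs$gene_a, all_pairs$gene_b))
  out <- all_pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
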