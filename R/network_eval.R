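#' Construct a reference regulatory network
#'
#' A curated set of directed TF -> target edges plus the TF list and the gene
#' universe; defines the "real" and "background" edge populations used for
#' evaluation. Self-loops are dropped (with a message) and duplicate edges
#' collapsed, mirroring the standard filtering applied to curated exports.
#'
#' @param edges Two-column data frame or matrix: regulator (TF), target.
#' @param tfs Regulator identifiers; defaults to the unique edge sources.
#' @param genes Gene universe; defaults to all edge endpoints plus `tfs`.
#' @return An object of class `reference_network` with elements `edges`
#'   (data frame `tf`, `target`), `tfs` and `genes`.
#' @export
reference_network <- function(edges, tfs = NULL, genes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have two columns (tf, target)")
  edges <- data.frame(tf = as.character(edges[[1L]]),
                      target = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  n_self <- sum(edges$tf == edges$target)
  if (n_self > 0L) {
    message("dropping ", n_self, " self-regulation edge(s)")
    edges <- edges[edges$tf != edges$target, , drop = FALSE]
  }
  edges <- unique(edges)
  if (is.null(tfs)) tfs <- unique(edges$tf)
  tfs <- unique(as.character(tfs))
  if (is.null(genes)) genes <- unique(c(tfs, edges$tf, edges$target))
  genes <- unique(as.character(genes))
  if (!all(edges$tf %in% tfs)) stop("every edge source must be a TF")
  if (!all(c(edges$tf, edges$target) %in% genes)) {
    stop("every edge endpoint must be in the gene universe")
  }
  if (!all(tfs %in% genes)) stop("every TF must be in the gene universe")
  rownames(edges) <- NULL
  structure(list(edges = edges, tfs = tfs, genes = genes),
            class = "reference_network")
}

#' @export
print.reference_network <- function(x, ...) {
  cat(sprintf("Reference network: %d TF(s), %d gene(s), %d edge(s)\n",
              length(x$tfs), length(x$genes), nrow(x$edges)))
  invisible(x)
}

edge_keys <- function(tf, target) paste(tf, target, sep = "\r")

#' Background TF-gene pairs of a reference network
#'
#' All directed (TF, gene) pairs over the network's universe, excluding
#' self-pairs and the curated ("real") edges.
#'
#' @param ref A [reference_network()].
#' @return Data frame with columns `tf`, `target`.
#' @export
background_pairs <- function(ref) {
  stopifnot(inherits(ref, "reference_network"))
  if (length(ref$tfs) == 0L) stop("reference network has no TFs")
  all_pairs <- expand.grid(tf = ref$tfs, target = ref$genes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$tf != all_pairs$target, , drop = FALSE]
  real <- edge_keys(ref$edges$tf, ref$edges$target)
  keep <- !(edge_keys(all_pairs$tf, all_pairs$target) %in% real)
  out <- all_pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Real-versus-background score test
#'
#' One-sided Welch two-sample t-test of whether dependency scores on curated
#' (real) interactions have a larger mean (for higher-is-dependent measures)
#' or a smaller mean (for distance-like measures) than scores on background
#' TF-gene pairs.
#'
#' @param real_scores,bg_scores Numeric score vectors.
#' @param orientation `"higher"` if larger scores indicate dependence,
#'   `"lower"` otherwise.
#' @return List with `t_stat`, `p_value`, the group means and the alternative
#'   tested.
#' @export
real_vs_background_test <- function(real_scores, bg_scores,
                                    orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  if (length(real_scores) < 2L || length(bg_scores) < 2L) {
    stop("both samples must have size >= 2")
  }
  if (var(real_scores) == 0 && var(bg_scores) == 0) {
    stop("degenerate samples: both have zero variance")
  }
  alt <- if (orientation == "higher") "greater" else "less"
  ht <- t.test(real_scores, bg_scores, alternative = alt, var.equal = FALSE)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       mean_real = mean(real_scores), mean_bg = mean(bg_scores),
       alternative = alt, test = "Welch two-sample t")
}

# mark each scored (unordered) pair real if it matches a reference edge in
# either direction
pair_is_real <- function(scores, ref) {
  real <- edge_keys(ref$edges$tf, ref$edges$target)
  edge_keys(scores$gene_a, scores$gene_b) %in% real |
    edge_keys(scores$gene_b, scores$gene_a) %in% real
}

rank_value <- function(scores, ranking = c("auto", "raw")) {
  ranking <- match.arg(ranking)
  method <- attr(scores, "method")
  v <- scores$score
  if (ranking == "auto" && method %in% c("cor", "tau")) {
    # correlation coefficients rank by magnitude: strong negative correlation
    # is still strong dependence
    return(abs(v))
  }
  if (attr(scores, "orientation") == "lower") -v else v
}

#' Precision-recall curve against a reference network
#'
#' Scored pairs are restricted to genes present in the reference universe,
#' sorted by decreasing dependency (per the measure's orientation; for
#' correlation coefficients by decreasing magnitude under
#' `ranking = "auto"`), and one precision/recall point is emitted per distinct
#' score value, treating that value as the pruning threshold. Precision is
#' TP/(TP+FP) and recall TP/(TP+FN), with false negatives counted against the
#' real pairs present in the constrained, scored set.
#'
#' @param scores A `dependency_scores` object from [score_all_pairs()].
#' @param ref A [reference_network()].
#' @param ranking `"auto"` (default: magnitude ranking for `cor`/`tau`) or
#'   `"raw"` (orientation-signed raw scores).
#' @return A `pr_curve` object: data frame with columns `threshold`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`.
#' @export
pr_curve <- function(scores, ref, ranking = c("auto", "raw")) {
  stopifnot(inherits(ref, "reference_network"))
  ranking <- match.arg(ranking)
  keep <- scores$gene_a %in% ref$genes & scores$gene_b %in% ref$genes
  if (!any(keep)) stop("no scored pair overlaps the reference gene set")
  sc <- scores[keep, , drop = FALSE]
  rv <- rank_value(scores, ranking)[keep]
  real <- pair_is_real(sc, ref)
  n_real <- sum(real)
  if (n_real == 0L) stop("no scored pair matches a reference edge")

  ord <- order(rv, decreasing = TRUE)
  rv <- rv[ord]
  real <- real[ord]
  thr <- sc$score[ord]
  cum_tp <- cumsum(real)
  cum_fp <- cumsum(!real)
  # one point per distinct ranking value: the last (most permissive) prefix
  last <- !duplicated(rv, fromLast = TRUE)
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  fn <- n_real - tp
  precision <- ifelse(tp + fp == 0L, 1.0, tp / (tp + fp))
  out <- data.frame(threshold = thr[last], tp = tp, fp = fp, fn = fn,
                    precision = precision, recall = tp / n_real)
  rownames(out) <- NULL
  structure(out, n_real = n_real, n_scored = nrow(sc),
            method = attr(scores, "method"),
            class = c("pr_curve", "data.frame"))
}

#' Area under a precision-recall curve
#'
#' Trapezoidal integration over recall, anchored at recall 0 with the first
#' point's precision.
#'
#' @param curve A [pr_curve()] result.
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(curve) {
  stopifnot(inherits(curve, "pr_curve"), nrow(curve) >= 1L)
  r <- curve$recall
  p <- curve$precision
  area <- r[1L] * p[1L]
  if (nrow(curve) > 1L) {
    dr <- diff(r)
    area <- area + sum(dr * (p[-1L] + p[-length(p)]) / 2)
  }
  area
}

#' Threshold scores into a directed regulatory network
#'
#' Keeps pairs whose score is beyond `threshold` in the dependent direction
#' (strictly above for higher-is-dependent measures, strictly below for
#' distance-like measures) and orients each kept pair from the transcription
#' factor to the non-TF gene. TF-TF pairs are emitted in both directions
#' (dependency measures are symmetric) and flagged; pairs with no TF member
#' are dropped with a logged count. Zero is the natural threshold for DBoMM:
#' a positive score means the joint model has the larger posterior model
#' probability.
#'
#' @param scores A `dependency_scores` object.
#' @param threshold Score cutoff (default 0, the DBoMM convention).
#' @param ref_tfs Character vector of transcription-factor identifiers.
#' @return Data frame with columns `tf`, `target`, `score`, `tf_tf`.
#' @export
infer_network <- function(scores, threshold = 0, ref_tfs) {
  if (missing(ref_tfs) || length(ref_tfs) == 0L) stop("ref_tfs must be nonempty")
  ref_tfs <- as.character(ref_tfs)
  keep <- if (attr(scores, "orientation") == "higher") {
    scores$score > threshold
  } else {
    scores$score < threshold
  }
  sc <- scores[keep, , drop = FALSE]
  a_tf <- sc$gene_a %in% ref_tfs
  b_tf <- sc$gene_b %in% ref_tfs
  n_no_tf <- sum(!a_tf & !b_tf)
  if (n_no_tf > 0L) {
    message("dropping ", n_no_tf, " pair(s) with no TF member")
  }
  rows <- list()
  both <- a_tf & b_tf
  if (any(both)) {
    rows$ab <- data.frame(tf = sc$gene_a[both], target = sc$gene_b[both],
                          score = sc$score[both], tf_tf = TRUE,
                          stringsAsFactors = FALSE)
    rows$ba <- data.frame(tf = sc$gene_b[both], target = sc$gene_a[both],
                          score = sc$score[both], tf_tf = TRUE,
                          stringsAsFactors = FALSE)
  }
  only_a <- a_tf & !b_tf
  if (any(only_a)) {
    rows$a <- data.frame(tf = sc$gene_a[only_a], target = sc$gene_b[only_a],
                         score = sc$score[only_a], tf_tf = FALSE,
                         stringsAsFactors = FALSE)
  }
  only_b <- b_tf & !a_tf
  if (any(only_b)) {
    rows$b <- data.frame(tf = sc$gene_b[only_b], target = sc$gene_a[only_b],
                         score = sc$score[only_b], tf_tf = FALSE,
                         stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L) {
    data.frame(tf = character(), target = character(), score = numeric(),
               tf_tf = logical(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, unname(rows))
  }
  rownames(out) <- NULL
  out
}
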