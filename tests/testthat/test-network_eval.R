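toy_scores <- function(scores, genes_a, genes_b, method = "dbomm") {
  structure(data.frame(gene_a = genes_a, gene_b = genes_b, score = scores,
                       n_components_joint = NA_integer_,
                       n_components_x = NA_integer_,
                       n_components_y = NA_integer_,
                       stringsAsFactors = FALSE),
            method = method, orientation = dbomm:::measure_orientation(method),
            class = c("dependency_scores", "data.frame"))
}

test_that("background pairs are the TF x gene complement of the real edges", {
  ref <- reference_network(data.frame(tf = c("t1", "t2"), target = c("g3", "t1")),
                           tfs = c("t1", "t2"), genes = c("t1", "t2", "g3"))
  bg <- background_pairs(ref)
  # 2 TFs x 3 genes - 2 self-pairs - 2 real = 2
  expect_equal(nrow(bg), 2)
  expect_setequal(paste(bg$tf, bg$target), c("t1 t2", "t2 g3"))

  ref0 <- reference_network(data.frame(tf = character(), target = character()),
                            tfs = c("t1", "t2"), genes = c("t1", "t2", "g3"))
  expect_equal(nrow(background_pairs(ref0)), 4)

  full <- expand.grid(tf = c("t1", "t2"), target = c("t1", "t2", "g3"),
                      stringsAsFactors = FALSE)
  full <- full[full$tf != full$target, ]
  ref_full <- reference_network(full, tfs = c("t1", "t2"),
                                genes = c("t1", "t2", "g3"))
  expect_equal(nrow(background_pairs(ref_full)), 0)
})

test_that("real-vs-background test is a directional Welch t-test", {
  s <- c(1, 2, 3, 4)
  same <- real_vs_background_test(s, s, "higher")
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 0.5)

  real <- c(10, 11, 12, 13); bg <- c(0, 1, 2, 3)
  up <- real_vs_background_test(real, bg, "higher")
  oracle <- welch_oracle(real, bg, "greater")
  expect_equal(up$t_stat, oracle$t)
  expect_equal(up$p_value, oracle$p)
  expect_lt(up$p_value, 0.01)
  down <- real_vs_background_test(real, bg, "lower")
  expect_gt(down$p_value, 0.99)
  expect_error(real_vs_background_test(rep(1, 3), rep(2, 3), "higher"),
               "degenerate")
})

test_that("the 4-pair toy PR curve matches hand enumeration", {
  # descending dependency: real, background, real, background
  ref <- reference_network(data.frame(tf = c("t1", "t1"), target = c("a", "c")),
                           tfs = "t1", genes = c("t1", "a", "b", "c", "d"))
  sc <- toy_scores(c(4, 3, 2, 1), rep("t1", 4), c("a", "b", "c", "d"))
  curve <- pr_curve(sc, ref)
  expect_equal(curve$precision, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(curve$recall, c(0.5, 0.5, 1, 1))
  expect_equal(curve$tp, c(1, 1, 2, 2))
  expect_equal(curve$fp, c(0, 1, 1, 2))
  expect_equal(curve$fn, c(1, 1, 0, 0))
  expect_equal(aupr(curve), 19 / 24, tolerance = 1e-12)
})

test_that("PR arithmetic holds row-wise against independent counters", {
  set.seed(21)
  genes <- paste0("g", 1:30)
  ref_edges <- data.frame(tf = "t1", target = sample(genes, 8))
  ref <- reference_network(ref_edges, tfs = "t1", genes = c("t1", genes))
  sc <- toy_scores(rnorm(30), rep("t1", 30), genes)
  curve <- pr_curve(sc, ref)
  real_set <- paste("t1", ref_edges$target)
  ord <- order(sc$score, decreasing = TRUE)
  is_real <- paste(sc$gene_a, sc$gene_b)[ord] %in% real_set
  for (k in seq_len(nrow(curve))) {
    # counters recomputed independently from the sorted prefix
    prefix <- sum(curve$tp[k] + curve$fp[k])
    tp <- sum(is_real[seq_len(prefix)])
    expect_equal(curve$tp[k], tp)
    expect_equal(curve$precision[k], tp / prefix)
    expect_equal(curve$recall[k], tp / 8)
    expect_equal(curve$fn[k], 8 - tp)
  }
})

test_that("perfect separation gives precision 1 everywhere and AUPR 1", {
  ref <- reference_network(data.frame(tf = "t1", target = c("a", "b")),
                           tfs = "t1", genes = c("t1", "a", "b", "c"))
  sc <- toy_scores(c(5, 4, 1), rep("t1", 3), c("a", "b", "c"))
  curve <- pr_curve(sc, ref)
  expect_true(all(curve$precision[curve$recall <= 1] >= 0.5))
  expect_equal(curve$precision[curve$recall == 1][1], 1)
  expect_equal(aupr(curve), 1)
})

test_that("a single-point curve integrates to its precision", {
  ref <- reference_network(data.frame(tf = "t1", target = "a"),
                           tfs = "t1", genes = c("t1", "a", "b"))
  sc <- toy_scores(c(2, 2), c("t1", "t1"), c("a", "b"))
  curve <- pr_curve(sc, ref)
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$recall, 1)
  expect_equal(aupr(curve), curve$precision)
})

test_that("lower-is-dependent scores are ranked ascending", {
  ref <- reference_network(data.frame(tf = "t1", target = c("a", "b")),
                           tfs = "t1", genes = c("t1", "a", "b", "c", "d"))
  # euclidean distances: the two real pairs are the two smallest
  sc <- toy_scores(c(1, 2, 9, 8), rep("t1", 4), c("a", "b", "c", "d"),
                   method = "euc")
  curve <- pr_curve(sc, ref, ranking = "raw")
  expect_equal(aupr(curve), 1)
})

test_that("infer_network thresholds, orients and handles TF-TF pairs", {
  sc <- toy_scores(c(5, -1, 3), c("t1", "t1", "g9"), c("g2", "g3", "t1"))
  net <- infer_network(sc, threshold = 0, ref_tfs = "t1")
  expect_equal(nrow(net), 2)
  expect_setequal(paste(net$tf, net$target), c("t1 g2", "t1 g9"))

  none <- infer_network(toy_scores(c(-5, -2), c("t1", "t1"), c("a", "b")),
                        threshold = 0, ref_tfs = "t1")
  expect_equal(nrow(none), 0)

  both <- infer_network(toy_scores(4, "t1", "t2"), threshold = 0,
                        ref_tfs = c("t1", "t2"))
  expect_setequal(paste(both$tf, both$target), c("t1 t2", "t2 t1"))
  expect_true(all(both$tf_tf))

  expect_message(
    dropped <- infer_network(toy_scores(c(4, 4), c("t1", "g5"), c("g2", "g6")),
                             threshold = 0, ref_tfs = "t1"),
    "no TF")
  expect_equal(nrow(dropped), 1)
  expect_error(infer_network(sc, 0, character()), "nonempty")
})
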