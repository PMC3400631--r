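test_that("euclidean distance matches hand-computed values", {
  expect_equal(euclidean(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean(c(1, 2, 3), c(2, 4, 1)), 3)  # sqrt(1 + 4 + 4)
  expect_error(euclidean(1:3, 1:4), "length")
})

test_that("pearson matches the product-moment formula and rejects constants", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson(x, rep(2, 4)), "constant")
})

test_that("kendall_tau is the tie-corrected tau-b", {
  expect_equal(kendall_tau(1:3, 1:3), 1)
  expect_equal(kendall_tau(1:3, 3:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2)), 1 / 3)
  # tie case against a hand tau-b: x ties reduce the denominator
  x <- c(1, 1, 2, 3)
  y <- c(1, 2, 3, 4)
  n0 <- 6; n1 <- 1  # one tied x pair
  concordant <- 5; discordant <- 0
  expect_equal(kendall_tau(x, y), (concordant - discordant) / sqrt((n0 - n1) * n0))
  expect_error(kendall_tau(c(1, 1, 1), 1:3), "tied")
})

test_that("binned mutual information matches the contingency definition", {
  x <- rep(c(0, 1), 10)
  expect_equal(mutual_information(x, x, bins = 2), log(2))
  # exact product table -> independence -> 0
  xi <- rep(c(0, 1), each = 10)
  yi <- rep(c(0, 1), 10)
  expect_equal(mutual_information(xi, yi, bins = 2), 0)
  # 2x2 table [[4,1],[1,4]]
  xa <- c(rep(0, 5), rep(1, 5))
  ya <- c(rep(0, 4), 1, 0, rep(1, 4))
  # exact cell sum: 2*0.4*ln(0.4/0.25) + 2*0.1*ln(0.1/0.25) ~= 0.192745
  expect_equal(mutual_information(xa, ya, bins = 2),
               0.8 * log(1.6) + 0.2 * log(0.4), tolerance = 1e-12)
  expect_equal(mutual_information(xa, ya, bins = 2),
               mi_bruteforce(table(xa, ya)))
  # constant profile collapses to one bin
  expect_equal(mutual_information(rep(1, 10), rnorm(10)), 0)
})

test_that("mutual information agrees with the brute-force oracle on random data", {
  for (seed in 1:10) {
    xy <- withr::with_seed(seed, list(x = rnorm(60), y = rnorm(60)))
    got <- mutual_information(xy$x, xy$y, bins = 7)
    bx <- dbomm:::discretize_profile(xy$x, 7)
    by <- dbomm:::discretize_profile(xy$y, 7)
    expect_lt(abs(got - mi_bruteforce(table(bx, by))), 1e-12)
  }
})

test_that("dbomm with G fixed at 1 reduces to the correlation closed form", {
  cfg <- fit_config(g_min = 1, g_max = 1, seed = 1)
  for (seed in 1:6) {
    n <- c(30, 100, 250)[seed %% 3 + 1]
    pr <- exact_cor_pair(n, r_target = 0.6, seed = seed)
    got <- dbomm(pr$x, pr$y, cfg)
    want <- -n * log(1 - 0.6^2) - log(n)
    expect_equal(got, want, tolerance = 1e-6)
    # the unpenalized variant: llr = -(n/2) ln(1 - r^2)
    expect_equal(loglik_ratio(pr$x, pr$y, cfg), -n / 2 * log(1 - 0.36),
                 tolerance = 1e-6)
  }
})

test_that("dbomm is exactly symmetric and satisfies the BIC/llr identity", {
  for (seed in 1:4) {
    p <- make_pair("dependent", n = 60, n_components = 2, seed = seed)
    cfg <- fit_config(g_max = 4, seed = 7)
    expect_identical(dbomm(p$x, p$y, cfg), dbomm(p$y, p$x, cfg))
    fit <- dbomm_fit(p$x, p$y, cfg)
    dk <- fit$joint$n_params - fit$marginal_x$n_params - fit$marginal_y$n_params
    expect_equal(fit$dbomm, 2 * fit$llr - dk * log(60), tolerance = 1e-9)
  }
})

test_that("short profiles score with a warning rather than an error", {
  p <- rnorm_pair(8, 0.5, seed = 1)
  expect_warning(dbomm(p$x, p$y, fit_config(g_max = 2, seed = 1)), "10")
})

test_that("score_all_pairs delegates, validates and is order-independent", {
  expr <- withr::with_seed(3, matrix(rnorm(5 * 40), 5, 40,
                                     dimnames = list(paste0("g", 1:5), NULL)))
  one <- score_all_pairs(expr, data.frame(a = "g1", b = "g2"), method = "euc")
  expect_equal(one$score, euclidean(expr["g1", ], expr["g2", ]))
  expect_error(score_all_pairs(expr, data.frame(a = c("g1", "g2"), b = c("g2", "g1")),
                               method = "euc"), "duplicate")
  expect_error(score_all_pairs(expr, data.frame(a = "g1", b = "gX"),
                               method = "euc"), "gX")

  pairs <- t(combn(paste0("g", 1:5), 2))
  cfg <- fit_config(g_max = 3, seed = 5)
  s1 <- score_all_pairs(expr, pairs, method = "dbomm", config = cfg)
  s2 <- score_all_pairs(expr, pairs[nrow(pairs):1, ], method = "dbomm", config = cfg)
  expect_equal(s1$score, rev(s2$score))
  s3 <- score_all_pairs(expr, pairs, method = "dbomm", config = cfg)
  expect_identical(s1$score, s3$score)
  expect_identical(attr(s1, "orientation"), "higher")
})

test_that("dbomm ranking is robust to removing a few conditions", {
  # distribution-based scores should be insensitive to dropping 5% of data
  n <- 100
  panel <- lapply(1:20, function(i) {
    kind <- if (i %% 2 == 0) "dependent" else "independent"
    make_pair(kind, n = n, n_components = 1 + i %% 3, seed = 400 + i)
  })
  cfg <- fit_config(g_max = 4, seed = 2)
  keep <- withr::with_seed(9, sort(sample.int(n, round(0.95 * n))))
  full <- vapply(panel, function(p) dbomm(p$x, p$y, cfg), numeric(1))
  sub <- vapply(panel, function(p) dbomm(p$x[keep], p$y[keep], cfg), numeric(1))
  expect_gte(cor(full, sub, method = "spearman"), 0.8)
})
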