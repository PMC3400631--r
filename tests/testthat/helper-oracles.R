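# Independent oracles used across the suite. Everything here is deliberately
# brute-force / closed-form and shares no code with the package internals.

# closed-form MLE log-likelihood of a single d-dimensional Gaussian
# (covariance with 1/n normalization)
gauss_mle_loglik <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  S <- crossprod(Xc) / n
  -0.5 * n * (d * log(2 * pi) + log(det(S)) + d)
}

# brute-force mutual information from a contingency table: explicit double
# loop over cells, 0 * log 0 := 0
mi_bruteforce <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      p <- tab[i, j] / n
      if (p > 0) {
        px <- sum(tab[i, ]) / n
        py <- sum(tab[, j]) / n
        total <- total + p * log(p / (px * py))
      }
    }
  }
  total
}

# Welch two-sample t statistic and one-sided p, written out from the formula
welch_oracle <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- if (alternative == "greater") pt(t, df, lower.tail = FALSE) else pt(t, df)
  list(t = t, p = p)
}

# adjusted Rand index between two label vectors (closed form on the
# contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# standardize a profile to zero mean / unit sd
zstd <- function(v) (v - mean(v)) / sd(v)

# draw a correlated Gaussian pair with roughly the requested correlation
rnorm_pair <- function(n, r, seed) {
  withr::with_seed(seed, {
    e1 <- rnorm(n)
    e2 <- rnorm(n)
    list(x = e1, y = r * e1 + sqrt(1 - r^2) * e2)
  })
}

# rescale y so the sample correlation with x is exactly r_target
exact_cor_pair <- function(n, r_target, seed) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    z <- rnorm(n)
  })
  # orthogonalize z against x, then mix to hit r_target exactly
  xs <- zstd(x)
  zr <- resid(lm(z ~ x))
  zr <- zr / sqrt(sum(zr^2) / (n - 1))
  y <- r_target * xs + sqrt(1 - r_target^2) * zr
  stopifnot(abs(cor(x, y) - r_target) < 1e-12)
  list(x = x, y = y)
}
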