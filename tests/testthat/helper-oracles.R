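# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# Median-of-ratios size factors computed literally: per-gene geometric mean
# via prod()^(1/n) over genes nonzero in every sample, then the per-sample
# median of count/geomean ratios.
oracle_size_factors <- function(m) {
  ok <- apply(m, 1, function(r) all(r > 0))
  ref <- m[ok, , drop = FALSE]
  geo <- apply(ref, 1, function(r) prod(r)^(1 / length(r)))
  apply(ref, 2, function(cnt) median(cnt / geo))
}

# Step-up Benjamini-Hochberg by direct enumeration: adj_i = min over j with
# p_(j) >= p_(i) of p_(j) * n / j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[ord] <- pmin(1, adj)
  out
}

# Welch two-sided t-test from the textbook formulas.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, p = 2 * pt(-abs(t), df))
}

# Simple-linear-regression slope/intercept/R2 from the normal equations.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  fit <- a + b * x
  r2 <- 1 - sum((y - fit)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r2 = r2)
}

random_count_matrix <- function(ngene = 50, nsmp = 10, lambda = 30) {
  m <- matrix(rpois(ngene * nsmp, lambda) + 1L, ngene, nsmp)
  dimnames(m) <- list(paste0("g", seq_len(ngene)), paste0("s", seq_len(nsmp)))
  m
}
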