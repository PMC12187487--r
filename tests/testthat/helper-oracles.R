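# Independent oracles used to freeze or cross-check expected values.
# These deliberately use a different computational route than the package.

# Spearman via the classical rank-difference formula (valid without ties)
oracle_spearman <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# two-sided exact signed-rank p by full 2^n enumeration of sign assignments
oracle_signrank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w)
  p_ge <- mean(w_all >= w)
  min(1, 2 * min(p_le, p_ge))
}

# OLS R^2 by explicit normal equations
oracle_r2 <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# ICC(A,1) from a two-way aov fit (package route uses direct mean squares)
oracle_icc_a1 <- function(r1, r2) {
  n <- length(r1)
  d <- data.frame(
    y = c(r1, r2),
    subject = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
}

# brute-force three-branch Goldberg classifier
oracle_goldberg <- function(ratio, lower = 1.05, upper = 2.28) {
  vapply(ratio, function(r) {
    if (r < lower) "UR" else if (r > upper) "OR" else "AR"
  }, character(1))
}
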