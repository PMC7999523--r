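# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: quantiles by numerical integration of the density,
# Pearson by the raw sum formula, hypergeometric moments by enumeration.

# chi-squared q-quantile by integrating the density and root-finding
oracle_chisq_quantile <- function(p, df) {
  cdf <- function(x) stats::integrate(function(t) stats::dchisq(t, df),
                                      0, x, rel.tol = 1e-10)$value
  stats::uniroot(function(x) cdf(x) - p, c(1e-8, df + 40 * sqrt(2 * df)),
                 tol = 1e-10)$root
}

oracle_chi2_correction <- function(r) {
  0.5 * (sqrt(r / oracle_chisq_quantile(0.975, r)) +
           sqrt(r / oracle_chisq_quantile(0.025, r)))
}

# Pearson correlation from the raw definition, no cor()
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# full brute-force correlation matrix by a double loop
oracle_cor_matrix <- function(mat) {
  n <- nrow(mat)
  out <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- oracle_pearson(mat[i, ], mat[j, ])
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

# exact hypergeometric pmf/moments by direct enumeration over choose()
oracle_hyper_pmf <- function(N, R, n) {
  k <- 0:min(n, R)
  p <- choose(R, k) * choose(N - R, n - k) / choose(N, n)
  names(p) <- k
  p
}

oracle_hyper_moments <- function(N, R, n) {
  pmf <- oracle_hyper_pmf(N, R, n)
  k <- as.numeric(names(pmf))
  m <- sum(k * pmf)
  list(mean = m, var = sum((k - m)^2 * pmf))
}

oracle_hyper_tail <- function(r, N, R, n) {
  pmf <- oracle_hyper_pmf(N, R, n)
  sum(pmf[as.numeric(names(pmf)) >= r])
}

# Welch t-test p-value from the closed-form statistic and df
oracle_welch_p <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# one-sided critical correlation by grid inversion of the t CDF
oracle_critical_rho <- function(n, alpha) {
  grid <- seq(0, 0.999999, by = 1e-6)
  tval <- grid * sqrt(n - 2) / sqrt(1 - grid^2)
  pval <- 1 - stats::pt(tval, df = n - 2)
  grid[which(pval < alpha)[1]]
}
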