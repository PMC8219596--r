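# Shared closed-form oracles and small utilities for the test suite.

# inverse Gaussian (Wald) moments for threshold alpha, drift xi
wald_mean <- function(alpha, xi) alpha / xi
wald_var <- function(alpha, xi) alpha / xi^3
# variance of the sample variance: (mu4 - sigma^4) / n, with
# mu4 = (3 + excess kurtosis) sigma^4 and excess kurtosis 15 m / lambda
wald_se_var <- function(alpha, xi, n) {
  m <- alpha / xi; lambda <- alpha^2
  s2 <- wald_var(alpha, xi)
  mu4 <- (3 + 15 * m / lambda) * s2^2
  sqrt((mu4 - s2^2) / n)
}

# moments of the normal truncated to [0, Inf)
tn0_mean <- function(mu, sigma) {
  lam <- dnorm(mu / sigma) / pnorm(mu / sigma)
  mu + sigma * lam
}
tn0_var <- function(mu, sigma) {
  a0 <- -mu / sigma
  lam <- dnorm(mu / sigma) / pnorm(mu / sigma)
  sigma^2 * (1 + a0 * lam - lam^2)
}

# model CDF on a dense grid by trapezoid integration of a density function,
# returned as a vectorized function clamped to [0, 1]
cdf_from_density <- function(dfun, lower, upper, n = 8001) {
  x <- seq(lower, upper, length.out = n)
  y <- dfun(x)
  Fx <- c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
  f <- approxfun(x, pmin(Fx, 1), yleft = 0, yright = 1)
  function(q) pmin(pmax(f(q), 0), 1)
}

# two-sided Kolmogorov-Smirnov distance between a sample and a CDF
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# 1% critical value of the one-sample KS statistic (asymptotic)
ks_crit_1pct <- function(n) 1.6276 / sqrt(n)
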