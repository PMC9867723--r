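# Independent oracles, kept deliberately naive.

# Benjamini-Hochberg by literal step-up rule application
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m / seq_len(m) * p[o]
  # step-up: enforce monotonicity from the largest rank downwards
  if (m > 1) for (i in seq(m - 1, 1)) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Upper-tail hypergeometric p by exhaustive enumeration of all draws
ora_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # universe 1..N, set = 1..K
  mean(hits >= k)
}

# E[S | X = x] + offset under Normal(mu, sigma^2) + Exp(mean alpha), by quadrature
normexp_quadrature <- function(x, mu, sigma, alpha, offset = 0) {
  f <- function(s) stats::dnorm(x - s, mu, sigma) * stats::dexp(s, 1 / alpha)
  # the integrand is concentrated near s = x - mu (width sigma); a finite
  # window keeps adaptive quadrature from missing the peak at large x
  hi <- max(0, x - mu) + 25 * sigma
  num <- stats::integrate(function(s) s * f(s), 0, hi, rel.tol = 1e-13,
                          abs.tol = 0)$value
  den <- stats::integrate(f, 0, hi, rel.tol = 1e-13, abs.tol = 0)$value
  num / den + offset
}

# ordinary unequal-variance two-sample t statistic, direct formula
welch_t_oracle <- function(x_pd, x_hc) {
  v1 <- apply(x_pd, 1, var)
  v2 <- apply(x_hc, 1, var)
  (rowMeans(x_pd) - rowMeans(x_hc)) /
    sqrt(v1 / ncol(x_pd) + v2 / ncol(x_hc))
}
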