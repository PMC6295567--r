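# Closed-form binomial-cascade spectrum, used as the independent oracle
# for the multifractal estimators: tau(q) = -log2(p1^q + p2^q),
# alpha = dtau/dq (analytic), f = q*alpha - tau.
cascade_tau <- function(q, p1) -log2(p1^q + (1 - p1)^q)

cascade_alpha <- function(q, p1) {
  p2 <- 1 - p1
  -(p1^q * log(p1) + p2^q * log(p2)) / ((p1^q + p2^q) * log(2))
}

cascade_f <- function(q, p1) q * cascade_alpha(q, p1) - cascade_tau(q, p1)

# Sample autocovariance at lag k assuming a known zero mean.
sample_acov <- function(x, k) {
  n <- length(x)
  sum(x[1:(n - k)] * x[(k + 1):n]) / n
}

# Plain reference log-sum-exp for normalizing test measures.
logsumexp_ref <- function(w) log(sum(exp(w - max(w)))) + max(w)

# Theoretical fGn autocovariance.
fgn_gamma <- function(k, hurst, sigma = 1) {
  (sigma^2 / 2) * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                     abs(k - 1)^(2 * hurst))
}
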