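# Independent oracles used across tests.

# Clopper-Pearson by direct bisection on the binomial tail probabilities
# (independent of the beta-quantile route used by the package).
cp_tail_inversion <- function(k, n, level = 0.95, tol = 1e-12) {
  a <- (1 - level) / 2
  low <- if (k == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  high <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - a,
                   c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  c(low, high)
}

# Excess-free sample kurtosis.
sample_kurtosis <- function(x) {
  z <- x - mean(x)
  mean(z^4) / mean(z^2)^2
}

# Measured-ratio model with a channel-efficiency bias: methylated template
# amplifies b-fold relative to unmethylated, distorting the apparent mix.
biased_mix <- function(m, b) b * m / (b * m + (1 - m))
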