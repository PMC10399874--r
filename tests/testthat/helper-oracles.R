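# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and direct definitions only.

# Direct-sum ACF estimator: G(k) = mean(x_i * x_{i+k}) / mean(x)^2 - 1,
# looped lag by lag.
direct_acf <- function(x, lags_bins) {
  n <- length(x)
  mu <- mean(x)
  sapply(lags_bins, function(k) {
    s <- 0
    for (i in 1:(n - k)) s <- s + x[i] * x[i + k]
    s / (n - k) / mu^2 - 1
  })
}

# Brute-force per-pixel N&B moments and estimators.
brute_force_nandb <- function(counts, dwell) {
  d <- dim(counts)
  eps <- num <- mu <- v <- matrix(NA_real_, d[2], d[3])
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      tr <- counts[, i, j]
      mu[i, j] <- mean(tr)
      v[i, j] <- var(tr)
      ex <- v[i, j] - mu[i, j]
      if (ex > 0 && mu[i, j] > 0) {
        eps[i, j] <- ex / mu[i, j] / dwell
        num[i, j] <- mu[i, j]^2 / ex
      } else {
        eps[i, j] <- 0
      }
    }
  }
  list(mean = mu, variance = v, epsilon_cps = eps, number = num)
}

# Apparent (q^2-weighted) brightness for oligomers with q ~ Binomial(s, p),
# by exhaustive enumeration of q: epsilon_app = lambda * sum(f_q q^2) /
# sum(f_q q).
enumerated_apparent_brightness <- function(lambda, subunits, p) {
  q <- 0:subunits
  f <- dbinom(q, subunits, p)
  lambda * sum(f * q^2) / sum(f * q)
}

# Endpoint-averaged bleached fraction of an exponential decay
# exp(-k * t) sampled at frame times t_i = (i - 1) * dt, with head/tail
# windows of n_edge frames.
exponential_bleached_fraction <- function(k, n_frames, dt, n_edge) {
  y <- exp(-k * ((seq_len(n_frames)) - 1) * dt)
  1 - mean(y[(n_frames - n_edge + 1):n_frames]) / mean(y[1:n_edge])
}
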