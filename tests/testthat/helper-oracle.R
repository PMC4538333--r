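# Independent, naively-coded oracles used to cross-check the compiled
# estimators on tiny inputs.

oracle_entropy_fixed_m <- function(x, m) {
  x <- sort(x)
  n <- length(x)
  s <- 0
  for (k in 1:(n - m)) s <- s + log((n / m) * (x[k + m] - x[k]))
  s / (n - m) - digamma(m) + log(m)
}

oracle_entropy_avg <- function(x) {
  n <- length(x)
  mean(vapply(1:(n - 1), function(m) oracle_entropy_fixed_m(x, m), 0.0))
}

# conditional entropy by direct per-class application of the oracle
oracle_cond_entropy <- function(y, labels) {
  n <- length(y)
  h <- 0
  for (g in unique(labels)) {
    yg <- y[labels == g]
    if (length(yg) >= 2) h <- h + length(yg) / n * oracle_entropy_avg(yg)
  }
  h
}

euler_gamma <- -digamma(1)
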