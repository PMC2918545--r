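# Small fixture builders used across test files.

unit_square_dataset <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  reg <- region_square(0.5, c(0.5, 0.5))
  y <- rbinom(n, 1, p)
  while (all(y == 0) || all(y == 1)) y <- rbinom(n, 1, p)
  point_dataset(cbind(runif(n), runif(n)), y, reg)
}

# Independent R implementation of the Bernoulli zone log-likelihood ratio,
# written directly from the binomial log-likelihood (used as a brute-force
# oracle; deliberately separate from the package code path).
llr_oracle <- function(c_z, n_z, C, N) {
  ll <- function(c, n) {
    out <- 0
    if (c > 0) out <- out + c * log(c / n)
    if (n - c > 0) out <- out + (n - c) * log(1 - c / n)
    out
  }
  ll(c_z, n_z) + ll(C - c_z, N - n_z) - ll(C, N)
}

# Exhaustive scan over every circular zone (centre = subject, radius = any
# subject distance), both directions, honouring the half-population cap and
# tied distances entering together.
scan_oracle <- function(coords, y) {
  N <- length(y); C <- sum(y); K <- N %/% 2
  D <- as.matrix(dist(coords))
  best <- 0
  for (i in seq_len(N)) {
    o <- order(D[i, ], seq_len(N))
    dd <- D[i, o]
    cum <- cumsum(y[o])
    for (k in seq_len(K)) {
      if (k < N && dd[k] == dd[k + 1]) next  # tied subjects enter together
      c_z <- cum[k]
      if (c_z * N == C * k) next
      v <- llr_oracle(c_z, k, C, N)
      if (v > best) best <- v
    }
  }
  best
}
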