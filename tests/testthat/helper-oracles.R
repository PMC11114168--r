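# Independent brute-force oracles used to validate the production code.

# Direct O(Q^2) evaluation of the windowed periodogram of one channel:
# p(f) = |(1/Q) sum_k w(k) x(k) exp(-i 2 pi f k T)|^2
periodogram_oracle <- function(x, w, rate, freqs) {
  Q <- length(x)
  Tt <- 1 / rate
  k <- 0:(Q - 1)
  vapply(freqs, function(f)
    Mod(sum(w * x * exp(-2i * pi * f * k * Tt)) / Q)^2, numeric(1))
}

# Exact two-sided Mann-Whitney p by enumerating group assignments and
# counting pairwise wins directly (no ranks), independent of the package's
# rank-based path.
mwu_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, u_of)
  mu <- n1 * n2 / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(U = u_obs, p = p)
}

# ECDF-corner enumeration of the KS statistic against a given CDF.
ks_d_oracle <- function(sample, cdf) {
  s <- sort(sample)
  n <- length(s)
  Fx <- cdf(s)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}
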