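# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force or closed form, never by calling the code paths
# they check.

# Mean and SD of a normal left-truncated at `floor` (closed form).
oracle_truncnorm <- function(mean, sd, floor) {
  a <- (floor - mean) / sd
  lambda <- dnorm(a) / (1 - pnorm(a))
  delta <- lambda * (lambda - a)
  c(mean = mean + sd * lambda, sd = sd * sqrt(1 - delta))
}

# Exhaustive best-matching-unit scan.
oracle_bmu <- function(W, x) {
  d2 <- apply(W, 1, function(w) sum((w - x)^2))
  which(d2 == min(d2))[1]
}

# Per-point local least-squares polynomial derivative (normal equations),
# interior points only.
oracle_sg <- function(x, window, polyorder, deriv) {
  half <- (window - 1) / 2
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    t <- -half:half
    B <- outer(t, 0:polyorder, `^`)
    co <- solve(crossprod(B), crossprod(B, x[(i - half):(i + half)]))
    out[i] <- co[deriv + 1] * factorial(deriv)
  }
  out
}

# Two-sided exact Mann-Whitney p by enumeration of all rank splits.
oracle_u_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(U_obs - mu) - 1e-9)
}

# Sort-based quartiles with linear interpolation (type 7), written directly.
oracle_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# Noiseless class-mean spectrum for a fraction/state.
mean_spectrum <- function(fraction, state, axis = ev_axis()) {
  ev_simulate_spectrum(ev_peak_table(fraction, state), ev_noise_none(),
                       axis, seed = 1)$intensity
}

# Small separable toy dataset: two Gaussian blobs in D dims.
toy_blobs <- function(n_per = 10, d = 5, sep = 6, seed = 1, k = 2) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d) * 0 +
    outer(seq_len(k) * sep, rep(1, d))
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_per * d, 0, 0.3), n_per, d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)
  }))
  ev_dataset(X, seq_len(d), tibble::tibble(
    sample_id = sprintf("t%03d", seq_len(k * n_per)),
    class = rep(LETTERS[seq_len(k)], each = n_per)))
}
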