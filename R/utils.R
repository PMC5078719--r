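# Internal numerical helpers shared across modules.

# Row-wise log density of a multivariate normal; x is a matrix with one
# observation per row (a vector is treated as a single row).
dmvnorm_log <- function(x, mu, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- length(mu)
  ch <- chol(sigma)
  centered <- sweep(x, 2, mu)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# log(sum(exp(x))) by row for a matrix, guarded against underflow.
logsumexp_rows <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# Numerically symmetrize and check positive semi-definiteness.
check_psd <- function(s, label = "matrix", tol = 1e-8) {
  s <- (s + t(s)) / 2
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    stop(label, " is not positive semi-definite", call. = FALSE)
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
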