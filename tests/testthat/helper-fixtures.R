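# Shared fixture builders; everything is generated in code at test time.

# Small panel with known values and a controllable missing mask.
toy_panel <- function(y, covs = NULL) {
  panel_dataset(y, covariates = covs)
}

# Direct multivariate-normal log density used as an independent oracle
# (plain determinant/solve arithmetic, no shared code path with the
# package internals).
oracle_mvn_logdens <- function(x, mu, sigma) {
  p <- length(mu)
  d <- x - mu
  -0.5 * (p * log(2 * pi) + log(det(sigma)) +
            drop(t(d) %*% solve(sigma) %*% d))
}

# Brute-force mixture log-likelihood over complete-data rows.
oracle_mixture_loglik <- function(y, pi, means, covs) {
  sum(apply(y, 1, function(row) {
    dens <- mapply(function(p, m, s) p * exp(oracle_mvn_logdens(row, m, s)),
                   pi, means, covs)
    log(sum(dens))
  }))
}

# Tiny well-separated two-class growth panel for quick fitting tests.
small_two_class_panel <- function(n = 300, seed = 42, delta = 3) {
  cfg <- generator_config(
    n = n, seed = seed, structural_mode = "null", pi_high = 0.6,
    growth = list(
      stage1 = list(
        high = list(mu = c(delta, 1), psi = diag(c(0.05, 0.01))),
        low = list(mu = c(0, 1), psi = diag(c(0.05, 0.01)))
      ),
      stage2 = list(
        high = list(mu = c(delta + 1, 0.5), psi = diag(c(0.05, 0.01))),
        low = list(mu = c(0.5, 0.5), psi = diag(c(0.05, 0.01)))
      )
    ),
    residual_sds = list(stage1 = rep(0.2, 3), stage2 = rep(0.2, 4)),
    missing_rates = c(y1 = 0),
    knot_mode = "duplicate"
  )
  generate_panel(cfg)
}

stage1_spec <- function(K = 2) {
  stage_spec(1, c("y1", "y2", "y3a"), c(0, 0.5, 1.5), K = K)
}
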