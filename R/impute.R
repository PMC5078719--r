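#' Maximum-likelihood fit of a joint normal to incomplete data
#'
#' EM for the mean vector and covariance matrix of a multivariate normal
#' when cells are missing at random: each E-step replaces the missing
#' sub-vector of a row by its conditional expectation given the observed
#' entries and adds the conditional covariance to the cross-product
#' accumulator.
#'
#' @param x numeric matrix with `NA` for missing cells.
#' @param max_iter,tol EM stopping rule on the observed-data
#'   log-likelihood change.
#' @param ridge small diagonal inflation keeping the covariance
#'   invertible.
#' @return list with `mu`, `sigma`, `loglik`, `n_iter`, `converged`.
#' @keywords internal
mvn_em <- function(x, max_iter = 200, tol = 1e-6, ridge = 1e-8) {
  x <- as.matrix(x)
  p <- ncol(x)
  n <- nrow(x)
  obs <- !is.na(x)
  if (any(colSums(obs) == 0)) {
    stop("variable(s) with no observed values cannot be imputed: ",
         paste(colnames(x)[colSums(obs) == 0], collapse = ", "),
         call. = FALSE)
  }
  mu <- colMeans(x, na.rm = TRUE)
  sigma <- diag(apply(x, 2, stats::var, na.rm = TRUE) + ridge, p)
  pattern <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pattern)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    sum_x <- numeric(p)
    sum_xx <- matrix(0, p, p)
    ll <- 0
    for (idx in groups) {
      o <- obs[idx[1], ]
      xi <- x[idx, , drop = FALSE]
      if (all(o)) {
        sum_x <- sum_x + colSums(xi)
        sum_xx <- sum_xx + crossprod(xi)
        ll <- ll + sum(dmvnorm_log(xi, mu, sigma))
        next
      }
      so <- sigma[o, o, drop = FALSE]
      som <- sigma[o, !o, drop = FALSE]
      smm <- sigma[!o, !o, drop = FALSE]
      so_inv <- chol2inv(chol(so))
      b <- so_inv %*% som                      # obs -> mis regression
      cond_cov <- smm - t(som) %*% b
      xo <- xi[, o, drop = FALSE]
      centered <- sweep(xo, 2, mu[o])
      xm_hat <- sweep(centered %*% b, 2, mu[!o], "+")
      xi[, !o] <- xm_hat
      sum_x <- sum_x + colSums(xi)
      cp <- crossprod(xi)
      cp[!o, !o] <- cp[!o, !o, drop = FALSE] + length(idx) * cond_cov
      sum_xx <- sum_xx + cp
      ll <- ll + sum(dmvnorm_log(xo, mu[o], so))
    }
    mu <- sum_x / n
    sigma <- sum_xx / n - tcrossprod(mu)
    sigma <- (sigma + t(sigma)) / 2 + diag(ridge, p)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  names(mu) <- colnames(x)
  dimnames(sigma) <- list(colnames(x), colnames(x))
  list(mu = mu, sigma = sigma, loglik = ll_old, n_iter = iter,
       converged = converged)
}

#' Multiple imputation of a panel under a joint-normal model
#'
#' Fits one joint normal over all analysis columns (indicators and
#' covariates together) by EM on the observed data, then fills the
#' missing cells of each of `m` copies with independent draws from the
#' conditional normal of the missing sub-vector given the observed one.
#' Observed cells are never altered.
#'
#' @param data a [panel_dataset].
#' @param m number of imputations (default 10).
#' @param seed integer seed.
#' @return list of `m` completed [panel_dataset] objects.
#' @export
impute_multiply <- function(data, m = 10, seed = 1) {
  stopifnot(m >= 2)
  x <- panel_columns(data)
  obs <- !is.na(x)
  T_ind <- ncol(data$y)
  if (all(obs)) {
    return(replicate(m, data, simplify = FALSE))
  }
  fit <- mvn_em(x)
  set.seed(seed)
  lapply(seq_len(m), function(j) {
    xi <- x
    for (i in which(rowSums(!obs) > 0)) {
      o <- obs[i, ]
      so_inv <- chol2inv(chol(fit$sigma[o, o, drop = FALSE]))
      som <- fit$sigma[o, !o, drop = FALSE]
      cond_mean <- fit$mu[!o] +
        drop(t(som) %*% so_inv %*% (x[i, o] - fit$mu[o]))
      cond_cov <- fit$sigma[!o, !o, drop = FALSE] -
        t(som) %*% so_inv %*% som
      cond_cov <- (cond_cov + t(cond_cov)) / 2
      xi[i, !o] <- MASS::mvrnorm(1, cond_mean, cond_cov)
    }
    cov_df <- data$covariates
    if (ncol(cov_df)) cov_df[] <- as.data.frame(xi[, -seq_len(T_ind), drop = FALSE])
    panel_dataset(xi[, seq_len(T_ind), drop = FALSE], covariates = cov_df,
                  unit_id = data$unit_id, truth = data$truth)
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates numeric vector of per-imputation point estimates.
#' @param ses numeric vector of per-imputation standard errors.
#' @return list with `estimate`, `within_var`, `between_var`,
#'   `total_var`, `se`, `m`. The total variance is
#'   `within + (1 + 1/m) * between`.
#' @export
pool_rubin <- function(estimates, ses) {
  if (length(estimates) != length(ses)) {
    stop("estimates and ses must have equal length", call. = FALSE)
  }
  m <- length(estimates)
  stopifnot(m >= 2)
  est <- mean(estimates)
  within <- mean(ses^2)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  list(estimate = est, within_var = within, between_var = between,
       total_var = total, se = sqrt(total), m = m)
}
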