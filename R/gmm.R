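#' Specification of one growth stage
#'
#' A stage is a set of repeated indicators measured at known times from
#' the stage origin, modelled by a K-class mixture of linear latent
#' growth curves. The first time score must be 0 so the intercept factor
#' is the status at the stage origin.
#'
#' @param stage_id integer stage label (1 or 2 in the two-stage design).
#' @param indicators ordered character vector of indicator column names.
#' @param time_scores numeric vector of times (same length), strictly
#'   increasing, starting at 0.
#' @param K number of latent classes.
#' @return object of class `stage_spec`.
#' @export
stage_spec <- function(stage_id, indicators, time_scores, K = 2) {
  stopifnot(length(indicators) == length(time_scores),
            length(indicators) >= 2, K >= 1)
  if (time_scores[1] != 0) stop("first time score must be 0", call. = FALSE)
  if (any(diff(time_scores) <= 0)) {
    stop("time scores must be strictly increasing", call. = FALSE)
  }
  structure(list(stage_id = stage_id, indicators = indicators,
                 time_scores = time_scores, K = K),
            class = "stage_spec")
}

#' Growth-mixture parameter set
#'
#' @param pi class weights (length K, positive, summing to 1).
#' @param mu K x 2 matrix of growth-factor means (intercept, slope).
#' @param psi list of K symmetric PSD 2 x 2 factor covariance matrices
#'   (a single matrix is recycled).
#' @param theta K x T matrix of residual variances (a length-T vector is
#'   recycled across classes).
#' @param cov_equal_across_classes,residuals_equal_across_classes
#'   constraint flags recorded with the parameters.
#' @return object of class `gmm_params`.
#' @export
gmm_params <- function(pi, mu, psi, theta,
                       cov_equal_across_classes = TRUE,
                       residuals_equal_across_classes = TRUE) {
  K <- length(pi)
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("class weights must be positive and sum to 1", call. = FALSE)
  }
  mu <- matrix(mu, nrow = K, ncol = 2)
  if (is.matrix(psi)) psi <- replicate(K, psi, simplify = FALSE)
  psi <- lapply(psi, check_psd, label = "factor covariance")
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = K, ncol = length(theta),
                                         byrow = TRUE)
  if (any(theta < 0)) stop("residual variances must be >= 0", call. = FALSE)
  structure(list(pi = pi, mu = mu, psi = psi, theta = theta, K = K,
                 cov_equal_across_classes = cov_equal_across_classes,
                 residuals_equal_across_classes = residuals_equal_across_classes),
            class = "gmm_params")
}

growth_loadings <- function(spec) {
  cbind(1, spec$time_scores)
}

#' Model-implied indicator moments for one class
#'
#' Under the linear growth measurement model the class-c indicator mean
#' is `intercept + time * slope` and the covariance is
#' `Lambda Psi_c Lambda' + diag(theta_c)` with `Lambda = [1, time]`.
#'
#' @param params a [gmm_params].
#' @param spec a [stage_spec].
#' @param class_index class whose moments to compute.
#' @return list with `mean` (length T) and `cov` (T x T).
#' @export
implied_moments <- function(params, spec, class_index) {
  stopifnot(class_index >= 1, class_index <= params$K)
  lambda <- growth_loadings(spec)
  mu <- drop(lambda %*% params$mu[class_index, ])
  sigma <- lambda %*% params$psi[[class_index]] %*% t(lambda) +
    diag(params$theta[class_index, ], nrow = nrow(lambda))
  names(mu) <- spec$indicators
  list(mean = mu, cov = sigma)
}

#' Number of free parameters of a growth mixture
#'
#' K-1 class weights, 2 means per class, factor (co)variances subject to
#' the shared-covariance flag, and residual variances subject to the
#' shared-residual flag.
#'
#' @param spec a [stage_spec].
#' @param cov_equal_across_classes,residuals_equal_across_classes
#'   constraint flags (defaults match [fit_gmm]).
#' @return integer count.
#' @export
count_params <- function(spec, cov_equal_across_classes = TRUE,
                         residuals_equal_across_classes = TRUE) {
  K <- spec$K
  T_ind <- length(spec$indicators)
  n_psi <- if (cov_equal_across_classes && K > 1) 2 * K + 1 else 3 * K
  n_theta <- if (residuals_equal_across_classes) T_ind else K * T_ind
  (K - 1) + 2 * K + n_psi + n_theta
}

# Group units of the stage sub-matrix by observed-indicator pattern.
pattern_prep <- function(data, spec, na_action = c("drop", "fail")) {
  na_action <- match.arg(na_action)
  missing_cols <- setdiff(spec$indicators, colnames(data$y))
  if (length(missing_cols)) {
    stop("indicator(s) not in panel: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- data$y[, spec$indicators, drop = FALSE]
  obs <- !is.na(y)
  empty <- rowSums(obs) == 0
  keep <- !empty
  if (any(empty)) {
    if (na_action == "fail") {
      stop(sum(empty), " unit(s) have no observed indicators for stage ",
           spec$stage_id, call. = FALSE)
    }
    warning(sum(empty), " unit(s) with no observed stage indicators dropped")
    y <- y[keep, , drop = FALSE]
    obs <- obs[keep, , drop = FALSE]
  }
  key <- apply(obs, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- lapply(split(seq_len(nrow(y)), key), function(idx) {
    list(idx = idx, obs = obs[idx[1], ])
  })
  # per-unit OLS growth-factor scores (used by the start heuristics)
  lam <- cbind(1, spec$time_scores)
  fs <- matrix(NA_real_, nrow(y), 2)
  for (g in groups) {
    o <- g$obs
    if (sum(o) >= 2) {
      h <- solve(crossprod(lam[o, , drop = FALSE]),
                 t(lam[o, , drop = FALSE]))
      fs[g$idx, ] <- y[g$idx, o, drop = FALSE] %*% t(h)
    } else {
      fs[g$idx, 1] <- y[g$idx, o]
      fs[g$idx, 2] <- 0
    }
  }
  list(y = y, groups = groups, n = nrow(y), keep = keep, fs = fs)
}

# Core E-step on a prepared pattern object; returns responsibilities,
# per-class posterior factor means, per-pattern posterior factor
# covariances, and the observed-data log-likelihood.
e_step_core <- function(params, spec, prep) {
  K <- params$K
  n <- prep$n
  lambda <- growth_loadings(spec)
  logdens <- matrix(NA_real_, n, K)
  eta_mean <- lapply(seq_len(K), function(c) matrix(NA_real_, n, 2))
  eta_cov <- vector("list", length(prep$groups))
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    o <- g$obs
    lam_o <- lambda[o, , drop = FALSE]
    yo <- prep$y[g$idx, o, drop = FALSE]
    covs_c <- vector("list", K)
    for (c in seq_len(K)) {
      psi <- params$psi[[c]]
      sig <- lam_o %*% psi %*% t(lam_o) +
        diag(params$theta[c, o], nrow = sum(o))
      ch <- chol(sig)
      sig_inv <- chol2inv(ch)
      centered <- sweep(yo, 2, drop(lam_o %*% params$mu[c, ]))
      qf <- rowSums((centered %*% sig_inv) * centered)
      logdens[g$idx, c] <- -0.5 * sum(o) * log(2 * pi) -
        sum(log(diag(ch))) - 0.5 * qf
      b <- psi %*% t(lam_o) %*% sig_inv        # 2 x T_obs gain
      eta_mean[[c]][g$idx, ] <- sweep(centered %*% t(b), 2,
                                      params$mu[c, ], "+")
      covs_c[[c]] <- psi - b %*% lam_o %*% psi
    }
    eta_cov[[gi]] <- covs_c
  }
  logpost <- sweep(logdens, 2, log(params$pi), "+")
  lse <- logsumexp_rows(logpost)
  resp <- exp(logpost - lse)
  list(resp = resp, eta_mean = eta_mean, eta_cov = eta_cov,
       loglik = sum(lse), logdens = logdens)
}

#' Mixture E-step
#'
#' Computes posterior class probabilities (responsibilities) and the
#' posterior mean and covariance of the growth factors per unit per
#' class, conditioning each unit's Gaussian on its observed indicators
#' only (full information). Work is done in log space; responsibility
#' rows always sum to 1.
#'
#' @inheritParams implied_moments
#' @param data a [panel_dataset].
#' @param na_action what to do with units observing none of the stage's
#'   indicators: `"drop"` (default, with warning) or `"fail"`.
#' @return list with `resp` (n x K), `eta_mean` (list of K n x 2
#'   matrices), `eta_cov` (per missingness pattern), `loglik`.
#' @export
e_step <- function(params, spec, data, na_action = "drop") {
  prep <- pattern_prep(data, spec, na_action)
  out <- e_step_core(params, spec, prep)
  out$prep <- prep
  out
}

#' Mixture marginal log-likelihood
#'
#' Sum over units of the log mixture density of each unit's observed
#' indicator sub-vector under the implied class moments.
#'
#' @inheritParams e_step
#' @return scalar log-likelihood.
#' @export
marginal_loglik <- function(params, spec, data, na_action = "drop") {
  e_step(params, spec, data, na_action)$loglik
}

# Constrained Psi update: maximizes the complete-data criterion
#   sum_c w_c * (-log|Psi_c| - tr(Psi_c^{-1} S_c))
# over 2x2 matrices sharing one off-diagonal across classes. Started
# from the current value so the generalized EM step never decreases the
# objective.
update_psi_constrained <- function(s_list, w, psi_current) {
  K <- length(s_list)
  obj <- function(par) {
    a <- exp(par[seq_len(K)])
    b <- exp(par[K + seq_len(K)])
    d <- par[2 * K + 1]
    val <- 0
    for (c in seq_len(K)) {
      det_c <- a[c] * b[c] - d^2
      if (det_c <= 1e-12) return(1e10)
      inv <- matrix(c(b[c], -d, -d, a[c]), 2, 2) / det_c
      val <- val + w[c] * (log(det_c) + sum(inv * s_list[[c]]))
    }
    val
  }
  pack <- function(psis, d) c(log(pmax(sapply(psis, `[`, 1, 1), 1e-10)),
                              log(pmax(sapply(psis, `[`, 2, 2), 1e-10)), d)
  starts <- list(
    pack(psi_current, psi_current[[1]][1, 2]),
    pack(s_list, sum(w * sapply(s_list, `[`, 1, 2)) / sum(w))
  )
  best <- NULL
  for (st in starts) {
    if (!all(is.finite(st)) || obj(st) >= 1e10) next
    fit <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 40, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {          # fall back to the unconstrained moments
    return(s_list)
  }
  par <- best$par
  lapply(seq_len(K), function(c) {
    matrix(c(exp(par[c]), par[2 * K + 1], par[2 * K + 1],
             exp(par[K + c])), 2, 2)
  })
}

#' Mixture M-step
#'
#' Closed-form responsibility-weighted updates of class weights, growth
#' means, factor covariances and residual variances from the E-step
#' posterior moments. Equality constraints pool weighted sufficient
#' statistics across classes (the shared intercept-slope covariance uses
#' an inner maximization of the complete-data criterion started at the
#' current value, so the EM objective never decreases).
#'
#' @param estep output of [e_step] (with its `prep` element).
#' @param spec a [stage_spec].
#' @param params current [gmm_params] (supplies constraint flags and the
#'   starting point of constrained updates).
#' @return updated [gmm_params]; attribute `degenerate` flags classes
#'   with vanishing total responsibility.
#' @export
m_step <- function(estep, spec, params) {
  K <- params$K
  prep <- estep$prep
  resp <- estep$resp
  n <- nrow(resp)
  lambda <- growth_loadings(spec)
  T_ind <- length(spec$indicators)
  w <- colSums(resp)
  degenerate <- w < 1e-8
  w_safe <- pmax(w, 1e-12)
  pi_new <- pmax(w, 1e-12) / sum(pmax(w, 1e-12))

  mu_new <- matrix(0, K, 2)
  s_list <- vector("list", K)
  for (c in seq_len(K)) {
    em <- estep$eta_mean[[c]]
    mu_new[c, ] <- colSums(resp[, c] * em) / w_safe[c]
    centered <- sweep(em, 2, mu_new[c, ])
    s <- crossprod(centered * resp[, c], centered)
    for (gi in seq_along(prep$groups)) {
      wg <- sum(resp[prep$groups[[gi]]$idx, c])
      s <- s + wg * estep$eta_cov[[gi]][[c]]
    }
    s_list[[c]] <- s / w_safe[c] + diag(1e-10, 2)
  }
  psi_new <- if (params$cov_equal_across_classes && K > 1) {
    update_psi_constrained(s_list, w_safe, params$psi)
  } else {
    s_list
  }

  # residual variances: E[(y_t - lambda_t eta)^2 | class] accumulated
  # over observed cells only
  num <- matrix(0, K, T_ind)
  den <- matrix(0, K, T_ind)
  for (gi in seq_along(prep$groups)) {
    g <- prep$groups[[gi]]
    o <- which(g$obs)
    yo <- prep$y[g$idx, o, drop = FALSE]
    for (c in seq_len(K)) {
      em <- estep$eta_mean[[c]][g$idx, , drop = FALSE]
      fitted <- em %*% t(lambda[o, , drop = FALSE])
      sq <- (yo - fitted)^2
      cv <- estep$eta_cov[[gi]][[c]]
      quad <- rowSums((lambda[o, , drop = FALSE] %*% cv) *
                        lambda[o, , drop = FALSE])
      rc <- resp[g$idx, c]
      num[c, o] <- num[c, o] + colSums(rc * sq) + sum(rc) * quad
      den[c, o] <- den[c, o] + sum(rc)
    }
  }
  if (params$residuals_equal_across_classes) {
    theta_shared <- colSums(num) / pmax(colSums(den), 1e-12)
    theta_new <- matrix(pmax(theta_shared, 1e-6), K, T_ind, byrow = TRUE)
  } else {
    theta_new <- pmax(num / pmax(den, 1e-12), 1e-6)
  }

  out <- gmm_params(pi_new, mu_new, psi_new, theta_new,
                    cov_equal_across_classes = params$cov_equal_across_classes,
                    residuals_equal_across_classes =
                      params$residuals_equal_across_classes)
  attr(out, "degenerate") <- degenerate
  out
}

# Canonical label order: descending class weight, ties broken by
# ascending intercept mean.
canonical_order <- function(params) {
  order(-params$pi, params$mu[, 1])
}

relabel_params <- function(params, ord) {
  gmm_params(params$pi[ord], params$mu[ord, , drop = FALSE],
             params$psi[ord], params$theta[ord, , drop = FALSE],
             cov_equal_across_classes = params$cov_equal_across_classes,
             residuals_equal_across_classes =
               params$residuals_equal_across_classes)
}

# Starting responsibilities. For K = 2 the first seven starts are
# deterministic: quantile cuts of the unit-level mean score at several
# split proportions, then quantile cuts of the per-unit OLS intercept
# score (mixing proportions of latent ability groups are often very
# unequal, and a flat-ridge likelihood needs starts probing both the
# mean-level and the growth-factor structure of the small-class basin);
# the rest are random partitions softened by Dirichlet noise.
n_deterministic_starts <- function(K) if (K == 2) 7L else 1L

start_resp <- function(prep, K, start, seed) {
  n <- prep$n
  det <- list()
  if (K == 2) {
    score <- rowMeans(prep$y, na.rm = TRUE)
    for (p_hi in c(0.5, 0.75, 0.9, 0.95)) {
      det[[length(det) + 1]] <- list(score = score, p_hi = p_hi, hard = 0.7)
    }
    for (p_hi in c(0.75, 0.9, 0.95)) {
      det[[length(det) + 1]] <- list(score = prep$fs[, 1], p_hi = p_hi,
                                     hard = 0.9)
    }
  } else {
    det[[1]] <- list(score = rowMeans(prep$y, na.rm = TRUE),
                     p_hi = NA, hard = 0.7)
  }
  hard_w <- 0.7
  if (K == 1) {
    cls <- rep(1L, n)
  } else if (start <= length(det)) {
    d <- det[[start]]
    hard_w <- d$hard
    if (K == 2) {
      cls <- ifelse(rank(d$score, ties.method = "first") / n > 1 - d$p_hi,
                    1L, 2L)
    } else {
      cls <- (K + 1L) - as.integer(cut(rank(d$score, ties.method = "first"),
                                       breaks = K, labels = FALSE))
    }
  } else {
    set.seed(seed + start)
    cls <- sample.int(K, n, replace = TRUE)
  }
  set.seed(seed + start)
  noise <- matrix(stats::rgamma(n * K, 1), n, K)
  noise <- noise / rowSums(noise)
  hard <- matrix(0, n, K)
  hard[cbind(seq_len(n), cls)] <- 1
  hard_w * hard + (1 - hard_w) * noise
}

# Pack mixture parameters into an unconstrained real vector (log
# weights, means, log factor variances, covariance, log residuals) so
# EM iterates can be extrapolated; unpacking projects back to the
# feasible set (weights renormalized, covariance clipped inside the PSD
# boundary).
pack_gmm <- function(params) {
  K <- params$K
  a <- sapply(params$psi, `[`, 1, 1)
  b <- sapply(params$psi, `[`, 2, 2)
  d <- sapply(params$psi, `[`, 1, 2)
  if (params$cov_equal_across_classes) d <- d[1]
  th <- if (params$residuals_equal_across_classes) params$theta[1, ]
    else as.vector(params$theta)
  c(log(params$pi), params$mu, log(pmax(a, 1e-10)), log(pmax(b, 1e-10)),
    d, log(pmax(th, 1e-8)))
}

unpack_gmm <- function(vec, K, T_ind, cov_equal, res_equal) {
  i <- 0
  take <- function(k) { out <- vec[i + seq_len(k)]; i <<- i + k; out }
  lp <- take(K)
  pi <- exp(lp - max(lp)); pi <- pmax(pi / sum(pi), 1e-12); pi <- pi / sum(pi)
  mu <- matrix(take(2 * K), K, 2)
  a <- exp(take(K)); b <- exp(take(K))
  d <- take(if (cov_equal) 1 else K)
  if (cov_equal) d <- rep(d, K)
  psi <- lapply(seq_len(K), function(c) {
    lim <- 0.995 * sqrt(a[c] * b[c])
    dc <- sign(d[c]) * min(abs(d[c]), lim)
    matrix(c(a[c], dc, dc, b[c]), 2, 2)
  })
  if (cov_equal) {
    dd <- sapply(psi, `[`, 1, 2)
    dmin <- dd[which.min(abs(dd))]
    psi <- lapply(psi, function(m) { m[1, 2] <- m[2, 1] <- dmin; m })
  }
  th <- exp(take(if (res_equal) T_ind else K * T_ind))
  theta <- if (res_equal) matrix(th, K, T_ind, byrow = TRUE)
    else matrix(th, K, T_ind)
  gmm_params(pi, mu, psi, pmax(theta, 1e-8),
             cov_equal_across_classes = cov_equal,
             residuals_equal_across_classes = res_equal)
}

# One EM run from given parameters, with squared-extrapolation
# acceleration (SQUAREM-type): every cycle takes two EM steps, proposes
# an extrapolated jump along the observed parameter trajectory, and
# accepts it only when it does not lower the log-likelihood, so the
# recorded trace stays monotone. Stops when the Aitken-projected
# remaining log-likelihood gain falls below tol.
run_em <- function(params, spec, prep, tol, max_iter, trace = numeric(0),
                   accelerate = TRUE) {
  K <- params$K
  T_ind <- length(spec$indicators)
  cov_eq <- params$cov_equal_across_classes
  res_eq <- params$residuals_equal_across_classes
  converged <- FALSE
  degenerate <- rep(FALSE, K)
  em_map <- function(p) {
    est <- e_step_core(p, spec, prep)
    np <- m_step(c(est, list(prep = prep)), spec, p)
    degenerate <<- degenerate | attr(np, "degenerate")
    list(loglik = est$loglik, params = np, estep = est)
  }
  check_stop <- function(tr) {
    t_len <- length(tr)
    if (t_len < 2) return(FALSE)
    d2 <- tr[t_len] - tr[t_len - 1]
    if (d2 < tol) return(TRUE)
    if (t_len >= 3) {
      d1 <- tr[t_len - 1] - tr[t_len - 2]
      r <- if (d1 > 0) d2 / d1 else 0
      if (r > 0 && r < 1 && d2 / (1 - r) - d2 < tol) return(TRUE)
    }
    FALSE
  }
  it <- 0
  estep <- NULL
  cycle_start_ll <- -Inf
  while (it < max_iter) {
    s1 <- em_map(params)
    it <- it + 1
    trace <- c(trace, s1$loglik)
    estep <- s1$estep
    if (!accelerate) {
      if (check_stop(trace)) { converged <- TRUE; params <- s1$params; break }
      params <- s1$params
      next
    }
    # accelerated cycle: the stop decision uses the improvement of the
    # whole previous cycle (two EM steps plus any accepted jump) and the
    # pure single-EM-step gain, both of which are meaningful under
    # extrapolation (the raw trace mixes jump and EM gains)
    cycle_impr <- s1$loglik - cycle_start_ll
    cycle_start_ll <- s1$loglik
    if (it + 1 > max_iter) { params <- s1$params; next }
    s2 <- em_map(s1$params)
    it <- it + 1
    trace <- c(trace, s2$loglik)
    estep <- s2$estep
    em_gain <- s2$loglik - s1$loglik
    if (cycle_impr < tol && em_gain < tol) {
      converged <- TRUE
      params <- s2$params
      break
    }
    v0 <- pack_gmm(params)
    v1 <- pack_gmm(s1$params)
    v2 <- pack_gmm(s2$params)
    r <- v1 - v0
    v <- (v2 - v1) - r
    vn <- sqrt(sum(v^2))
    params <- s2$params
    if (vn > 1e-12) {
      alpha <- max(-sqrt(sum(r^2)) / vn, -50)
      if (alpha < -1) {
        cand <- try(unpack_gmm(v0 - 2 * alpha * r + alpha^2 * v,
                               K, T_ind, cov_eq, res_eq), silent = TRUE)
        if (!inherits(cand, "try-error")) {
          est_c <- try(e_step_core(cand, spec, prep), silent = TRUE)
          if (!inherits(est_c, "try-error") && is.finite(est_c$loglik) &&
              est_c$loglik >= trace[length(trace)]) {
            params <- cand
          }
        }
      }
    }
  }
  # final E-step so responsibilities, trace and parameters agree
  estep <- e_step_core(params, spec, prep)
  trace <- c(trace, estep$loglik)
  list(params = params, trace = trace, converged = converged,
       estep = estep, degenerate = degenerate, n_iter = it + 1,
       loglik = estep$loglik)
}

#' Fit a growth mixture model by multi-start EM
#'
#' Estimates a K-class mixture of linear latent growth curves on the
#' stage's indicators by EM with full-information handling of missing
#' cells. The search follows the usual two-phase strategy of mixture
#' software: every initialization is run for a short burn-in, then the
#' most promising few are iterated to convergence; the best final
#' log-likelihood wins. Classes are relabelled canonically (descending
#' weight, ties by ascending intercept mean).
#'
#' @inheritParams e_step
#' @param n_starts number of initializations (first one deterministic,
#'   rest random).
#' @param seed integer seed for the random starts.
#' @param tol EM stops when the Aitken-projected remaining
#'   log-likelihood gain falls below this.
#' @param max_iter iteration cap per retained start.
#' @param burn_iter burn-in iterations given to every start.
#' @param n_final number of starts iterated to convergence.
#' @param cov_equal_across_classes share the intercept-slope covariance
#'   across classes (default TRUE).
#' @param residuals_equal_across_classes share residual variances across
#'   classes (default TRUE).
#' @param verbose print per-start progress.
#' @return object of class `gmm_fit`: `params`, `loglik`, `loglik_trace`,
#'   `resp` (responsibilities, canonical order), `n_params`, `converged`,
#'   `n_iter`, `best_start_seed`, `degenerate`, `spec`, `n`.
#' @export
fit_gmm <- function(data, spec, n_starts = 20, seed = 1, tol = 1e-6,
                    max_iter = 2000, burn_iter = 50, n_final = 4,
                    cov_equal_across_classes = TRUE,
                    residuals_equal_across_classes = TRUE,
                    na_action = "drop", verbose = FALSE) {
  stopifnot(spec$K >= 1, n_starts >= 1)
  prep <- pattern_prep(data, spec, na_action)
  K <- spec$K
  T_ind <- length(spec$indicators)
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    resp0 <- start_resp(prep, K, s, seed)
    # seed params from the start's partition via one M-step on flat
    # factor posteriors
    mu0 <- matrix(0, K, 2)
    score_i <- rowMeans(prep$y, na.rm = TRUE)
    lambda <- growth_loadings(spec)
    for (c in seq_len(K)) {
      wc <- resp0[, c] / sum(resp0[, c])
      ybar <- colSums(wc * prep$y, na.rm = TRUE) /
        colSums(wc * !is.na(prep$y))
      fit0 <- stats::lm.fit(lambda, ybar)
      mu0[c, ] <- fit0$coefficients
    }
    v0 <- stats::var(score_i, na.rm = TRUE)
    pi0 <- pmax(colMeans(resp0), 0.02)
    params <- gmm_params(pi0 / sum(pi0), mu0,
                         replicate(K, diag(c(max(v0, 0.05), 0.05)),
                                   simplify = FALSE),
                         matrix(max(v0, 0.05) / 2, K, T_ind),
                         cov_equal_across_classes,
                         residuals_equal_across_classes)
    runs[[s]] <- run_em(params, spec, prep, tol,
                        min(burn_iter, max_iter))
    runs[[s]]$start <- s
    if (verbose) {
      message(sprintf("start %d: burn-in loglik %.4f", s,
                      runs[[s]]$loglik))
    }
  }
  # always carry the deterministic quantile-cut starts (they probe the
  # unequal-weight basins a flat likelihood hides) plus the best others
  n_det <- min(n_deterministic_starts(K), n_starts)
  keep_runs <- union(seq_len(n_det),
                     order(sapply(runs, `[[`, "loglik"),
                           decreasing = TRUE)[seq_len(min(n_final,
                                                          n_starts))])
  best <- NULL
  for (s in keep_runs) {
    r <- runs[[s]]
    if (!r$converged) {
      r2 <- run_em(r$params, spec, prep, tol,
                   max(1, max_iter - r$n_iter), trace = r$trace)
      r2$start <- r$start
      r2$degenerate <- r$degenerate | r2$degenerate
      r <- r2
    }
    if (verbose) {
      message(sprintf("start %d: final loglik %.4f after %d iterations",
                      r$start, r$loglik, length(r$trace)))
    }
    if (is.null(best) || r$loglik > best$loglik) best <- r
  }
  best$resp <- best$estep$resp
  best$n_iter <- length(best$trace)
  ord <- canonical_order(best$params)
  params <- relabel_params(best$params, ord)
  resp <- best$resp[, ord, drop = FALSE]
  structure(
    list(params = params, loglik = best$loglik, loglik_trace = best$trace,
         resp = resp, n_params = count_params(spec, cov_equal_across_classes,
                                              residuals_equal_across_classes),
         converged = best$converged, n_iter = best$n_iter,
         best_start_seed = seed + best$start,
         degenerate = any(best$degenerate) ||
           any(params$pi < 1e-4),
         spec = spec, n = prep$n, keep = prep$keep),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: stage %d, K = %d, n = %d\n",
              x$spec$stage_id, x$spec$K, x$n))
  cat(sprintf("  loglik %.3f (%d iterations, converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  cat("  class weights:", sprintf("%.3f", x$params$pi), "\n")
  for (c in seq_len(x$params$K)) {
    cat(sprintf("  class %d: intercept %.3f, slope %.3f\n",
                c, x$params$mu[c, 1], x$params$mu[c, 2]))
  }
  invisible(x)
}
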