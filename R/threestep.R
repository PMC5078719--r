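# Steps 2-3 of the 3-step latent transition analysis: modal class
# assignment, classification-error matrices, and maximum-likelihood
# estimation of the transition model treating the modal classes as
# error-prone indicators of the true classes.

LOGIT_CLAMP <- 15

#' Modal class assignment
#'
#' Assigns each unit to its highest-posterior class; ties break toward
#' the lower class index so the rule is deterministic.
#'
#' @param resp n x K responsibility matrix.
#' @return list with `classes` (integer vector) and `proportions`.
#' @export
modal_assign <- function(resp) {
  resp <- as.matrix(resp)
  cls <- max.col(resp, ties.method = "first")
  K <- ncol(resp)
  list(classes = cls,
       proportions = tabulate(cls, nbins = K) / nrow(resp))
}

#' Classification-error matrix
#'
#' `q[k, s] = P(modal class = s | true class = k)`, estimated as the
#' responsibility-weighted cross-tabulation of modal assignments:
#' `q[k, s] = sum_i p_ik 1(W_i = s) / sum_i p_ik`. The matrix is fixed
#' in step 3 as the measurement part linking the true class to its
#' error-prone modal indicator; `logits` are `log(q[k, s] / q[k, K])`
#' with probabilities clamped away from 0 and 1.
#'
#' @param resp n x K responsibility matrix.
#' @param modal output of [modal_assign] (recomputed when omitted).
#' @return object of class `error_matrix`: `q`, `logits`, `clamped`.
#' @export
classification_error <- function(resp, modal = NULL) {
  resp <- as.matrix(resp)
  if (is.null(modal)) modal <- modal_assign(resp)
  K <- ncol(resp)
  col_tot <- colSums(resp)
  if (any(col_tot <= 0)) {
    stop("degenerate class: zero total posterior mass in class ",
         which(col_tot <= 0)[1], call. = FALSE)
  }
  ind <- matrix(0, nrow(resp), K)
  ind[cbind(seq_len(nrow(resp)), modal$classes)] <- 1
  q <- t(resp) %*% ind / col_tot
  pmin_q <- exp(-LOGIT_CLAMP)
  q_cl <- pmin(pmax(q, pmin_q), 1 - pmin_q)
  logits <- log(q_cl / q_cl[, K])
  structure(list(q = q, logits = logits,
                 clamped = (q < pmin_q) | (q > 1 - pmin_q)),
            class = "error_matrix")
}

identity_error_matrix <- function(K = 2) {
  structure(list(q = diag(K),
                 logits = matrix(c(LOGIT_CLAMP, 0, 0, 0)[seq_len(K * K)],
                                 K, K),
                 clamped = diag(K) == 0 | diag(K) == 1),
            class = "error_matrix")
}

#' Structural parameters of the transition model
#'
#' Two latent classes per stage, class 1 = high (canonical majority),
#' class 2 = low (reference). Stage-1 membership:
#' `P(G1 = high | x) = logistic(alpha1 + beta1' x)`. Stage-2 membership
#' given the origin class:
#' `P(G2 = high | G1 = g, x) = logistic(alpha2_g + (beta2 + gamma 1[g = low])' x)`,
#' so `beta2` is the Stage-2 membership effect and `gamma` the extra
#' transition effect that applies to children starting in the low class.
#'
#' @param alpha1,beta1 Stage-1 intercept and covariate coefficients.
#' @param alpha2_high,alpha2_low Stage-2 intercepts per origin class.
#' @param beta2,gamma Stage-2 membership and transition covariate
#'   coefficients.
#' @param covariate_names character vector naming the covariates (may be
#'   empty for the null model).
#' @export
structural_params <- function(alpha1, beta1 = numeric(),
                              alpha2_high, alpha2_low,
                              beta2 = numeric(), gamma = numeric(),
                              covariate_names = names(beta1) %||% character()) {
  p <- length(beta1)
  stopifnot(length(beta2) == p, length(gamma) == p)
  structure(list(alpha1 = alpha1, beta1 = beta1,
                 alpha2_high = alpha2_high, alpha2_low = alpha2_low,
                 beta2 = beta2, gamma = gamma,
                 covariate_names = covariate_names),
            class = "structural_params")
}

pack_structural <- function(sp) {
  c(sp$alpha1, sp$beta1, sp$alpha2_high, sp$alpha2_low, sp$beta2, sp$gamma)
}

unpack_structural <- function(par, p, covariate_names = character()) {
  structural_params(
    alpha1 = par[1], beta1 = par[1 + seq_len(p)],
    alpha2_high = par[p + 2], alpha2_low = par[p + 3],
    beta2 = par[p + 3 + seq_len(p)], gamma = par[2 * p + 3 + seq_len(p)],
    covariate_names = covariate_names
  )
}

# Linear predictors and cell log-probabilities of the latent (G1, G2)
# table for every unit; returns n x 4 matrix, cells ordered
# (high,high), (high,low), (low,high), (low,low).
structural_cell_logprob <- function(sp, X) {
  n <- if (is.null(X)) 1L else nrow(X)
  xb <- function(b) if (length(b)) drop(X %*% b) else 0
  eta1 <- sp$alpha1 + xb(sp$beta1)
  eta2_h <- sp$alpha2_high + xb(sp$beta2)
  eta2_l <- sp$alpha2_low + xb(sp$beta2 + sp$gamma)
  lp1_h <- stats::plogis(eta1, log.p = TRUE)
  lp1_l <- stats::plogis(-eta1, log.p = TRUE)
  lp2_hh <- stats::plogis(eta2_h, log.p = TRUE)
  lp2_hl <- stats::plogis(-eta2_h, log.p = TRUE)
  lp2_lh <- stats::plogis(eta2_l, log.p = TRUE)
  lp2_ll <- stats::plogis(-eta2_l, log.p = TRUE)
  cells <- cbind(lp1_h + lp2_hh, lp1_h + lp2_hl,
                 lp1_l + lp2_lh, lp1_l + lp2_ll)
  if (n > 1 && nrow(cells) == 1) cells <- cells[rep(1, n), , drop = FALSE]
  cells
}

#' Step-3 marginal log-likelihood
#'
#' Sums over the latent (G1, G2) cells, weighting each cell's structural
#' probability by the fixed classification-error probabilities of the
#' observed modal classes:
#' `sum_i log sum_{g1,g2} P(g1|x) P(g2|g1,x) q1[g1,W1_i] q2[g2,W2_i]`.
#'
#' @param sp a [structural_params].
#' @param W1,W2 integer modal class vectors (1 = high, 2 = low).
#' @param X numeric covariate matrix or `NULL` for the null model.
#' @param q1,q2 [classification_error] matrices of the two stages.
#' @export
step3_loglik <- function(sp, W1, W2, X = NULL, q1 = identity_error_matrix(),
                         q2 = identity_error_matrix()) {
  stopifnot(length(W1) == length(W2))
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (any(!is.finite(X))) stop("covariates must be finite", call. = FALSE)
    stopifnot(nrow(X) == length(W1))
  }
  lq <- function(q, W, g) log(pmax(q$q[g, W], 1e-300))
  cells <- structural_cell_logprob(sp, X)
  if (nrow(cells) == 1 && length(W1) > 1) {
    cells <- cells[rep(1, length(W1)), , drop = FALSE]
  }
  g1_of <- c(1, 1, 2, 2)
  g2_of <- c(1, 2, 1, 2)
  for (j in 1:4) {
    cells[, j] <- cells[, j] + lq(q1, W1, g1_of[j]) + lq(q2, W2, g2_of[j])
  }
  sum(logsumexp_rows(cells))
}

# Negative loglik and analytic gradient in the packed parameterization,
# used by the quasi-Newton optimizer; X may be NULL.
step3_objective <- function(par, p, W1, W2, X, q1, q2) {
  sp <- unpack_structural(par, p)
  n <- length(W1)
  xb <- function(b) if (p) drop(X %*% b) else 0
  eta1 <- sp$alpha1 + xb(sp$beta1)
  eta2_h <- sp$alpha2_high + xb(sp$beta2)
  eta2_l <- sp$alpha2_low + xb(sp$beta2 + sp$gamma)
  cells <- cbind(
    stats::plogis(eta1, log.p = TRUE) + stats::plogis(eta2_h, log.p = TRUE),
    stats::plogis(eta1, log.p = TRUE) + stats::plogis(-eta2_h, log.p = TRUE),
    stats::plogis(-eta1, log.p = TRUE) + stats::plogis(eta2_l, log.p = TRUE),
    stats::plogis(-eta1, log.p = TRUE) + stats::plogis(-eta2_l, log.p = TRUE)
  )
  if (n > 1 && nrow(cells) == 1) cells <- cells[rep(1, n), , drop = FALSE]
  lq <- function(q, W, g) log(pmax(q$q[g, W], 1e-300))
  cells[, 1] <- cells[, 1] + lq(q1, W1, 1) + lq(q2, W2, 1)
  cells[, 2] <- cells[, 2] + lq(q1, W1, 1) + lq(q2, W2, 2)
  cells[, 3] <- cells[, 3] + lq(q1, W1, 2) + lq(q2, W2, 1)
  cells[, 4] <- cells[, 4] + lq(q1, W1, 2) + lq(q2, W2, 2)
  lse <- logsumexp_rows(cells)
  w <- exp(cells - lse)
  p1 <- stats::plogis(eta1)
  p2h <- stats::plogis(eta2_h)
  p2l <- stats::plogis(eta2_l)
  d_eta1 <- (w[, 1] + w[, 2]) - p1
  d_eta2h <- w[, 1] - (w[, 1] + w[, 2]) * p2h
  d_eta2l <- w[, 3] - (w[, 3] + w[, 4]) * p2l
  grad <- numeric(length(par))
  grad[1] <- sum(d_eta1)
  grad[p + 2] <- sum(d_eta2h)
  grad[p + 3] <- sum(d_eta2l)
  if (p) {
    grad[1 + seq_len(p)] <- drop(crossprod(X, d_eta1))
    grad[p + 3 + seq_len(p)] <- drop(crossprod(X, d_eta2h + d_eta2l))
    grad[2 * p + 3 + seq_len(p)] <- drop(crossprod(X, d_eta2l))
  }
  list(value = -sum(lse), gradient = -grad, w = w)
}

#' Fit the 3-step transition model
#'
#' Maximizes [step3_loglik] over the structural parameters with the
#' classification-error matrices held fixed, by bounded quasi-Newton
#' (L-BFGS-B) with analytic gradients from several starting points.
#' Coefficients are bounded at +/-15 on the logit scale; a parameter at
#' the bound indicates separation (e.g. an empty transition cell) and is
#' flagged rather than treated as a finite estimate. Covariates are
#' standardized internally; coefficients and standard errors are
#' reported on the original scale. Standard errors come from the
#' observed information (numerically differentiated analytic gradient).
#'
#' @inheritParams step3_loglik
#' @param n_starts number of optimizer starts (first one moment-based).
#' @param seed seed for the jittered extra starts.
#' @return object of class `lta_fit`: `structural`, `se`, `t`, `p_value`,
#'   `loglik`, `bic`, `abic`, `entropy`, `combination_table`,
#'   `transition_matrix`, `stage1_proportions`, `clamped`, `n`,
#'   `n_params`, `vcov`.
#' @export
fit_step3 <- function(W1, W2, X = NULL, q1 = identity_error_matrix(),
                      q2 = identity_error_matrix(), n_starts = 3, seed = 1) {
  n <- length(W1)
  stopifnot(length(W2) == n)
  if (length(unique(W1)) < 2 || length(unique(W2)) < 2) {
    stop("need at least 2 observed modal classes at each stage",
         call. = FALSE)
  }
  has_x <- !is.null(X) && ncol(as.matrix(X)) > 0
  if (has_x) {
    X <- as.matrix(X)
    x_mean <- colMeans(X)
    x_sd <- apply(X, 2, stats::sd)
    x_sd[x_sd == 0] <- 1
    Z <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
    p <- ncol(X)
    cov_names <- colnames(X) %||% paste0("x", seq_len(p))
  } else {
    Z <- NULL
    p <- 0L
    cov_names <- character()
  }
  npar <- 3 + 3 * p
  clamp <- function(v) pmin(pmax(v, -LOGIT_CLAMP + 0.5), LOGIT_CLAMP - 0.5)
  pr <- function(x) min(max(x, 1e-4), 1 - 1e-4)
  p1_hat <- pr(mean(W1 == 1))
  p2h_hat <- pr(mean(W2[W1 == 1] == 1))
  p2l_hat <- pr(mean(W2[W1 == 2] == 1))
  base_start <- c(clamp(stats::qlogis(p1_hat)), rep(0, p),
                  clamp(stats::qlogis(p2h_hat)), clamp(stats::qlogis(p2l_hat)),
                  rep(0, 2 * p))
  set.seed(seed)
  starts <- c(list(base_start),
              replicate(max(0, n_starts - 1),
                        base_start + stats::rnorm(npar, sd = 0.5),
                        simplify = FALSE))
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(
      st,
      fn = function(par) step3_objective(par, p, W1, W2, Z, q1, q2)$value,
      gr = function(par) step3_objective(par, p, W1, W2, Z, q1, q2)$gradient,
      method = "L-BFGS-B", lower = -LOGIT_CLAMP, upper = LOGIT_CLAMP,
      control = list(maxit = 500, factr = 1e4)
    )
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par_std <- best$par
  clamped_std <- abs(par_std) >= LOGIT_CLAMP - 1e-6
  if (any(clamped_std)) {
    warning("coefficient(s) at the logit bound (separation); ",
            "estimates clamped at +/-", LOGIT_CLAMP)
  }
  hess <- try(stats::optimHess(
    par_std,
    fn = function(par) step3_objective(par, p, W1, W2, Z, q1, q2)$value,
    gr = function(par) step3_objective(par, p, W1, W2, Z, q1, q2)$gradient
  ), silent = TRUE)
  vcov_std <- matrix(NA_real_, npar, npar)
  free <- !clamped_std
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess[free, free, drop = FALSE]), silent = TRUE)
    if (!inherits(vc, "try-error")) vcov_std[free, free] <- vc
  }
  # map standardized-scale parameters back to the original scale
  if (has_x) {
    M <- diag(npar)
    ms <- x_mean / x_sd
    i_b1 <- 1 + seq_len(p); i_b2 <- p + 3 + seq_len(p)
    i_g <- 2 * p + 3 + seq_len(p)
    M[1, i_b1] <- -ms
    M[p + 2, i_b2] <- -ms
    M[p + 3, i_b2] <- -ms
    M[p + 3, i_g] <- -ms
    M[cbind(i_b1, i_b1)] <- 1 / x_sd
    M[cbind(i_b2, i_b2)] <- 1 / x_sd
    M[cbind(i_g, i_g)] <- 1 / x_sd
    par_orig <- drop(M %*% par_std)
    vcov_orig <- M %*% vcov_std %*% t(M)
  } else {
    par_orig <- par_std
    vcov_orig <- vcov_std
  }
  ses <- sqrt(pmax(diag(vcov_orig), 0))
  ses[clamped_std] <- NA_real_
  sp <- unpack_structural(par_orig, p, cov_names)
  names(sp$beta1) <- names(sp$beta2) <- names(sp$gamma) <- cov_names

  obj <- step3_objective(par_std, p, W1, W2, Z, q1, q2)
  loglik <- -obj$value
  w <- obj$w
  combo_labels <- c("High-High", "High-Low", "Low-High", "Low-Low")
  modal_combo <- max.col(w, ties.method = "first")
  counts <- tabulate(modal_combo, nbins = 4)
  # model-implied transition matrix, averaged over units (equals the
  # plain logistic transforms in the null model)
  cells <- exp(structural_cell_logprob(sp, if (has_x) X else NULL))
  if (nrow(cells) == 1) cells <- cells[rep(1, n), , drop = FALSE]
  p_g1_high <- rowSums(cells[, 1:2, drop = FALSE])
  tau <- rbind(
    high = colMeans(cells[, 1:2, drop = FALSE] / pmax(p_g1_high, 1e-12)),
    low = colMeans(cells[, 3:4, drop = FALSE] / pmax(1 - p_g1_high, 1e-12))
  )
  colnames(tau) <- c("high", "low")
  combination_table <- data.frame(
    combination = combo_labels,
    stage1 = c("High", "High", "Low", "Low"),
    stage2 = c("High", "Low", "High", "Low"),
    count = counts,
    proportion = counts / n,
    transition_probability = c(tau[1, 1], tau[1, 2], tau[2, 1], tau[2, 2])
  )
  tvals <- par_orig / ses
  structure(
    list(structural = sp, se = ses, t = tvals,
         p_value = 2 * stats::pnorm(-abs(tvals)),
         loglik = loglik,
         bic = bic(-2 * loglik, sum(free), n),
         abic = abic(-2 * loglik, sum(free), n),
         entropy = entropy(w),
         combination_table = combination_table,
         transition_matrix = tau,
         stage1_proportions = c(high = mean(p_g1_high),
                                low = mean(1 - p_g1_high)),
         posterior = w, clamped = clamped_std,
         n = n, n_params = sum(free), vcov = vcov_orig,
         covariate_names = cov_names),
    class = "lta_fit"
  )
}

#' @export
print.lta_fit <- function(x, ...) {
  cat(sprintf("lta_fit: n = %d, loglik %.3f, entropy %.3f\n",
              x$n, x$loglik, x$entropy))
  cat("  stage-1 proportions:",
      sprintf("%s %.3f", names(x$stage1_proportions), x$stage1_proportions),
      "\n")
  cat("  transition matrix (rows = stage-1 class):\n")
  print(round(x$transition_matrix, 3))
  invisible(x)
}

#' Odds ratios of the structural coefficients
#'
#' @param sp a [structural_params] (or an `lta_fit`, whose structural
#'   block is used).
#' @return data frame with block, covariate, coefficient and odds ratio;
#'   clamped coefficients are flagged.
#' @export
odds_ratios <- function(sp) {
  clamped <- rep(FALSE, length(pack_structural(if (inherits(sp, "lta_fit"))
    sp$structural else sp)))
  if (inherits(sp, "lta_fit")) {
    clamped <- sp$clamped
    sp <- sp$structural
  }
  nm <- sp$covariate_names
  p <- length(sp$beta1)
  rows <- data.frame(
    block = c("stage1_intercept", rep("stage1", p),
              "stage2_intercept_high", "stage2_intercept_low",
              rep("stage2", p), rep("transition", p)),
    term = c("(alpha1)", nm, "(alpha2_high)", "(alpha2_low)", nm, nm),
    beta = pack_structural(sp)
  )
  rows$odds_ratio <- exp(rows$beta)
  rows$clamped <- clamped
  rows
}

#' Fit step 3 on multiply imputed covariates and pool
#'
#' Runs [fit_step3] once per imputed covariate set and pools each
#' coefficient across imputations by Rubin's rules.
#'
#' @param W1,W2,q1,q2 as in [fit_step3] (shared across imputations).
#' @param X_list list of covariate matrices, one per imputation.
#' @param ... passed to [fit_step3].
#' @return list with `pooled` (data frame: term, estimate, se, t,
#'   p_value), `fits` (per-imputation `lta_fit`s).
#' @export
fit_step3_pooled <- function(W1, W2, X_list, q1, q2, ...) {
  fits <- lapply(X_list, function(X) fit_step3(W1, W2, X, q1, q2, ...))
  est <- sapply(fits, function(f) pack_structural(f$structural))
  ses <- sapply(fits, function(f) f$se)
  pooled <- lapply(seq_len(nrow(est)), function(j) {
    pool_rubin(est[j, ], ses[j, ])
  })
  terms <- odds_ratios(fits[[1]])$term
  blocks <- odds_ratios(fits[[1]])$block
  tab <- data.frame(
    block = blocks, term = terms,
    estimate = sapply(pooled, `[[`, "estimate"),
    se = sapply(pooled, `[[`, "se")
  )
  tab$t <- tab$estimate / tab$se
  tab$p_value <- 2 * stats::pnorm(-abs(tab$t))
  tab$odds_ratio <- exp(tab$estimate)
  list(pooled = tab, fits = fits)
}
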