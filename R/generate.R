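# Synthetic longitudinal panel generator. The defaults emulate a large
# early-reading cohort followed from kindergarten to Grade 8: four
# baseline covariates with realistic means/SDs/correlations, a two-class
# piecewise growth structure (fast-growing majority, slower minority),
# an upward-only transition between stages, and sparse missingness.

eclsk_covariate_names <- c("parent_rating", "teacher_rating", "ses", "poverty")

eclsk_covariate_corr <- function() {
  r <- diag(4)
  dimnames(r) <- list(eclsk_covariate_names, eclsk_covariate_names)
  r["parent_rating", "teacher_rating"] <- r["teacher_rating", "parent_rating"] <- 0.23
  r["parent_rating", "ses"] <- r["ses", "parent_rating"] <- 0.18
  r["parent_rating", "poverty"] <- r["poverty", "parent_rating"] <- 0.12
  r["teacher_rating", "ses"] <- r["ses", "teacher_rating"] <- 0.19
  r["teacher_rating", "poverty"] <- r["poverty", "teacher_rating"] <- 0.15
  r["ses", "poverty"] <- r["poverty", "ses"] <- 0.49
  r
}

# Per-variable missingness rates; the first reading score is hardest to
# collect (7%), everything else stays in the 0.5-4.8% band, overall 2.6%.
eclsk_missing_rates <- function() {
  c(parent_rating = 0.030, teacher_rating = 0.048, ses = 0.018,
    poverty = 0.012, y1 = 0.070, y2 = 0.008, y3 = 0.010,
    y4 = 0.020, y5 = 0.024, y6 = 0.020)
}

default_growth <- function() {
  list(
    stage1 = list(
      high = list(mu = c(-1.10, 0.93),
                  psi = matrix(c(0.18, -0.05, -0.05, 0.04), 2, 2)),
      low = list(mu = c(-1.58, 0.89),
                 psi = matrix(c(0.16, -0.05, -0.05, 0.09), 2, 2))
    ),
    stage2 = list(
      high = list(mu = c(0.41, 0.12),
                  psi = matrix(c(0.01, 0.005, 0.005, 0.004), 2, 2)),
      low = list(mu = c(-0.48, 0.19),
                 psi = matrix(c(0.01, 0.005, 0.005, 0.004), 2, 2))
    )
  )
}

#' Generator configuration
#'
#' Complete recipe for a synthetic panel. All defaults emulate the
#' reference cohort; every piece is overridable.
#'
#' @param n number of units (default 7803).
#' @param seed integer seed.
#' @param covariate_means,covariate_sds length-4 vectors for parent
#'   rating, teacher rating, SES, poverty.
#' @param covariate_corr 4 x 4 correlation matrix (symmetric PSD, unit
#'   diagonal).
#' @param structural_mode `"null"` (class and transition probabilities)
#'   or `"covariate"` (logistic membership/transition with calibrated
#'   intercepts).
#' @param pi_high Stage-1 high-class probability (null mode and the
#'   calibration target of covariate mode).
#' @param tau 2 x 2 transition matrix, rows = Stage-1 class (high, low).
#' @param beta1,beta2,gamma covariate-mode coefficient vectors (Stage-1
#'   membership, Stage-2 membership, transition increment for the
#'   low-origin class).
#' @param force_high_stay keep high-origin units in the high class with
#'   probability 1 (default TRUE, matching `tau["high", ]`).
#' @param growth nested list `stageX$class$mu/psi` of growth-factor
#'   means and covariances.
#' @param residual_sds list with `stage1` (length 3) and `stage2`
#'   (length 4) residual SDs.
#' @param time_scores list with `stage1` and `stage2` time scores
#'   (years from each stage origin).
#' @param knot_mode how the shared Spring-Grade-1 wave is emitted:
#'   `"duplicate"` (separate `y3a`/`y3b` columns), `"average"`,
#'   `"stage1"` or `"stage2"`.
#' @param missing_rates named per-variable missingness rates.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (masking probability
#'   logistic in SES, rescaled to each variable's marginal rate).
#' @param mar_coef logistic coefficient on standardized SES under MAR.
#' @param truncate_ratings clip rating scales to [1, 4] (off by default).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n = 7803, seed = 1,
                             covariate_means = c(3.13, 3.06, 0.11, 1.84),
                             covariate_sds = c(0.22, 0.42, 0.63, 0.14),
                             covariate_corr = eclsk_covariate_corr(),
                             structural_mode = c("null", "covariate"),
                             pi_high = 0.909,
                             tau = rbind(high = c(1, 0),
                                         low = c(0.474, 0.526)),
                             beta1 = NULL, beta2 = NULL, gamma = NULL,
                             force_high_stay = TRUE,
                             growth = default_growth(),
                             residual_sds = list(stage1 = rep(0.3, 3),
                                                 stage2 = rep(0.15, 4)),
                             time_scores = list(stage1 = c(0, 0.5, 1.5),
                                                stage2 = c(0, 2, 4, 7)),
                             knot_mode = c("duplicate", "average",
                                           "stage1", "stage2"),
                             missing_rates = eclsk_missing_rates(),
                             missing_mechanism = c("MCAR", "MAR"),
                             mar_coef = 1,
                             truncate_ratings = FALSE) {
  structural_mode <- match.arg(structural_mode)
  knot_mode <- match.arg(knot_mode)
  missing_mechanism <- match.arg(missing_mechanism)
  ev <- eigen(covariate_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("covariate correlation matrix is not PSD; nearest-PSD repair ",
         "(e.g. clipping negative eigenvalues) is required", call. = FALSE)
  }
  if (any(abs(diag(covariate_corr) - 1) > 1e-8)) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  if (any(abs(rowSums(tau) - 1) > 1e-8) || any(tau < 0)) {
    stop("transition matrix rows must be probabilities summing to 1",
         call. = FALSE)
  }
  if (any(missing_rates < 0 | missing_rates >= 1)) {
    stop("missing rates must lie in [0, 1)", call. = FALSE)
  }
  if (structural_mode == "covariate") {
    if (is.null(beta1)) stop("covariate mode needs beta1", call. = FALSE)
    beta2 <- beta2 %||% rep(0, length(beta1))
    gamma <- gamma %||% rep(0, length(beta1))
  }
  for (st in names(growth)) {
    for (cl in names(growth[[st]])) {
      growth[[st]][[cl]]$psi <- check_psd(growth[[st]][[cl]]$psi,
                                          "growth factor covariance")
    }
  }
  structure(list(
    n = n, seed = seed, covariate_means = covariate_means,
    covariate_sds = covariate_sds, covariate_corr = covariate_corr,
    structural_mode = structural_mode, pi_high = pi_high, tau = tau,
    beta1 = beta1, beta2 = beta2, gamma = gamma,
    force_high_stay = force_high_stay, growth = growth,
    residual_sds = residual_sds, time_scores = time_scores,
    knot_mode = knot_mode, missing_rates = missing_rates,
    missing_mechanism = missing_mechanism, mar_coef = mar_coef,
    truncate_ratings = truncate_ratings
  ), class = "generator_config")
}

#' Packaged fixture: final two-class model, no covariates
#'
#' Class, transition and growth parameters at the reference final-model
#' values; membership is driven by marginal probabilities only.
#' @param n,seed,... passed to [generator_config].
#' @export
final_model_null <- function(n = 7803, seed = 20161025, ...) {
  generator_config(n = n, seed = seed, structural_mode = "null", ...)
}

#' Packaged fixture: final model with covariate effects
#'
#' Stage-1 membership, Stage-2 membership and transition increments at
#' the reference logistic coefficients, with intercepts calibrated at
#' generation time so the class marginals match the null fixture.
#' @param n,seed,... passed to [generator_config].
#' @export
final_model_covariates <- function(n = 7803, seed = 20161025, ...) {
  generator_config(
    n = n, seed = seed, structural_mode = "covariate",
    beta1 = c(parent_rating = 0.65, teacher_rating = 1.95,
              ses = 1.65, poverty = 0.59),
    beta2 = c(parent_rating = 2.58, teacher_rating = -6.02,
              ses = 3.66, poverty = -8.57),
    gamma = c(parent_rating = -2.77, teacher_rating = 5.66,
              ses = -4.14, poverty = 8.48),
    ...
  )
}

#' Sample baseline covariates
#'
#' Joint normal with the configured means, SDs and correlations.
#'
#' @param config a [generator_config].
#' @param n,seed overrides of the config's values.
#' @return data frame with the four covariate columns.
#' @export
sample_covariates <- function(config, n = config$n, seed = config$seed) {
  set.seed(seed)
  d <- diag(config$covariate_sds)
  sigma <- d %*% config$covariate_corr %*% d
  x <- MASS::mvrnorm(n, mu = config$covariate_means, Sigma = sigma)
  colnames(x) <- eclsk_covariate_names
  x <- as.data.frame(x)
  if (config$truncate_ratings) {
    x$parent_rating <- pmin(pmax(x$parent_rating, 1), 4)
    x$teacher_rating <- pmin(pmax(x$teacher_rating, 1), 4)
  }
  x
}

#' Calibrate a logistic intercept to a target marginal
#'
#' Finds `alpha` such that `mean(plogis(alpha + X beta)) = target` by
#' monotone root search.
#'
#' @param beta coefficient vector.
#' @param X covariate matrix (rows = units).
#' @param target_marginal target mean probability in (0, 1).
#' @param tol root-search tolerance on the achieved marginal.
#' @export
calibrate_intercept <- function(beta, X, target_marginal, tol = 1e-4) {
  stopifnot(target_marginal > 0, target_marginal < 1)
  X <- as.matrix(X)
  xb <- if (length(beta)) drop(X %*% beta) else rep(0, nrow(X))
  f <- function(a) mean(stats::plogis(a + xb)) - target_marginal
  lo <- -60; hi <- 60
  if (f(lo) > 0 || f(hi) < 0) {
    stop("target marginal ", target_marginal, " unattainable for these ",
         "covariates", call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  if (abs(f(root)) > tol) {
    stop("intercept calibration did not reach the target", call. = FALSE)
  }
  root
}

#' Sample latent class memberships
#'
#' Stage-1 class from the marginal (null mode) or a calibrated logistic
#' in the covariates; Stage-2 class from the transition row of the
#' Stage-1 class, with the low-origin row logistic in the covariates in
#' covariate mode. Class coding: 1 = high, 2 = low.
#'
#' @param X covariate data frame (ignored in null mode).
#' @param config a [generator_config].
#' @param seed integer seed.
#' @return list with `g1`, `g2` (integer vectors) and the calibrated
#'   intercepts `alpha1`, `alpha2_low` (covariate mode).
#' @export
sample_classes <- function(X, config, seed = config$seed) {
  n <- if (config$structural_mode == "covariate") nrow(X) else config$n
  set.seed(seed)
  alpha1 <- alpha2_low <- NA_real_
  if (config$structural_mode == "null") {
    p1 <- rep(config$pi_high, n)
  } else {
    Xm <- as.matrix(X[, names(config$beta1) %||% eclsk_covariate_names])
    alpha1 <- calibrate_intercept(config$beta1, Xm, config$pi_high)
    p1 <- stats::plogis(alpha1 + drop(Xm %*% config$beta1))
  }
  g1 <- ifelse(stats::runif(n) < p1, 1L, 2L)
  g2 <- integer(n)
  hi <- g1 == 1L
  if (config$force_high_stay) {
    g2[hi] <- 1L
  } else {
    g2[hi] <- ifelse(stats::runif(sum(hi)) < config$tau["high", 1], 1L, 2L)
  }
  lo <- !hi
  if (any(lo)) {
    if (config$structural_mode == "null") {
      p2 <- rep(config$tau["low", 1], sum(lo))
    } else {
      Xm <- as.matrix(X[, names(config$beta1) %||% eclsk_covariate_names])
      blg <- config$beta2 + config$gamma
      alpha2_low <- calibrate_intercept(blg, Xm[lo, , drop = FALSE],
                                        config$tau["low", 1])
      p2 <- stats::plogis(alpha2_low + drop(Xm[lo, , drop = FALSE] %*% blg))
    }
    g2[lo] <- ifelse(stats::runif(sum(lo)) < p2, 1L, 2L)
  }
  list(g1 = g1, g2 = g2, alpha1 = alpha1, alpha2_low = alpha2_low)
}

#' Sample growth trajectories given classes
#'
#' Per unit, Stage-1 and Stage-2 growth factors are drawn independently
#' from their class-specific normals; indicators are
#' `intercept + time * slope + noise`. The shared Spring-Grade-1 wave is
#' emitted per `knot_mode`: `"duplicate"` keeps the Stage-1 endpoint
#' (`y3a`) and Stage-2 origin (`y3b`) as separate columns, `"average"`
#' emits their mean as a single `y3`, `"stage1"`/`"stage2"` keep one.
#'
#' @param g1,g2 class vectors (1 = high, 2 = low).
#' @param config a [generator_config].
#' @param seed integer seed.
#' @return list with `y` (indicator matrix) and `truth` factors.
#' @export
sample_trajectories <- function(g1, g2, config, seed = config$seed) {
  n <- length(g1)
  set.seed(seed)
  draw_factors <- function(stage, cls) {
    out <- matrix(NA_real_, n, 2)
    for (k in 1:2) {
      lbl <- if (k == 1) "high" else "low"
      idx <- which(cls == k)
      if (!length(idx)) next
      gp <- config$growth[[stage]][[lbl]]
      out[idx, ] <- MASS::mvrnorm(length(idx), gp$mu, gp$psi)
    }
    out
  }
  f1 <- draw_factors("stage1", g1)
  f2 <- draw_factors("stage2", g2)
  traj <- function(f, times, sds) {
    mean_y <- f[, 1] %o% rep(1, length(times)) + f[, 2] %o% times
    mean_y + matrix(stats::rnorm(n * length(times), sd = rep(sds, each = n)),
                    n, length(times))
  }
  y1s <- traj(f1, config$time_scores$stage1, config$residual_sds$stage1)
  y2s <- traj(f2, config$time_scores$stage2, config$residual_sds$stage2)
  y <- switch(config$knot_mode,
    duplicate = {
      m <- cbind(y1s, y2s)
      colnames(m) <- c("y1", "y2", "y3a", "y3b", "y4", "y5", "y6")
      m
    },
    average = {
      m <- cbind(y1s[, 1:2], (y1s[, 3] + y2s[, 1]) / 2, y2s[, 2:4])
      colnames(m) <- paste0("y", 1:6)
      m
    },
    stage1 = {
      m <- cbind(y1s, y2s[, 2:4])
      colnames(m) <- paste0("y", 1:6)
      m
    },
    stage2 = {
      m <- cbind(y1s[, 1:2], y2s)
      colnames(m) <- paste0("y", 1:6)
      m
    }
  )
  truth <- data.frame(int1 = f1[, 1], slp1 = f1[, 2],
                      int2 = f2[, 1], slp2 = f2[, 2])
  list(y = y, truth = truth)
}

#' Mask cells to emulate survey missingness
#'
#' MCAR masks each cell independently at its variable's rate. MAR makes
#' the masking probability logistic in (standardized, pre-masking) SES
#' and rescales the intercept so each variable still hits its marginal
#' rate. A rate named `y3` applies one shared mask to the `y3a`/`y3b`
#' pair when the panel carries the duplicated knot columns.
#'
#' @param data a [panel_dataset].
#' @param rates named per-variable rates.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param seed integer seed.
#' @param mar_coef logistic coefficient on standardized SES under MAR.
#' @return the panel with cells set missing.
#' @export
apply_missingness <- function(data, rates = eclsk_missing_rates(),
                              mechanism = c("MCAR", "MAR"), seed = 1,
                              mar_coef = 1) {
  mechanism <- match.arg(mechanism)
  set.seed(seed)
  n <- data$n
  cols_y <- colnames(data$y)
  cols_c <- colnames(data$covariates)
  ses <- data$covariates$ses
  z_ses <- if (!is.null(ses)) as.numeric(scale(ses)) else rep(0, n)
  mask_prob <- function(rate) {
    if (rate == 0) return(rep(0, n))
    if (mechanism == "MCAR") return(rep(rate, n))
    f <- function(a) mean(stats::plogis(a + mar_coef * z_ses)) - rate
    a <- stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
    stats::plogis(a + mar_coef * z_ses)
  }
  for (nm in names(rates)) {
    rate <- rates[[nm]]
    targets <- if (nm %in% c(cols_y, cols_c)) nm
      else intersect(paste0(nm, c("a", "b")), cols_y)
    if (!length(targets)) next
    hit <- stats::runif(n) < mask_prob(rate)
    for (tg in targets) {
      if (tg %in% cols_y) data$y[hit, tg] <- NA_real_
      else data$covariates[hit, tg] <- NA_real_
    }
  }
  data
}

#' Generate a complete synthetic panel
#'
#' Composes covariate sampling, class sampling, trajectory sampling and
#' missingness into one reproducible panel with a truth block (classes,
#' growth factors, pre-masking values, calibrated intercepts).
#'
#' @param config a [generator_config].
#' @return a [panel_dataset] with `truth`.
#' @export
generate_panel <- function(config) {
  covs <- sample_covariates(config, seed = config$seed)
  cls <- sample_classes(covs, config, seed = config$seed + 1)
  tr <- sample_trajectories(cls$g1, cls$g2, config, seed = config$seed + 2)
  truth <- list(g1 = cls$g1, g2 = cls$g2, factors = tr$truth,
                y_complete = tr$y, covariates_complete = covs,
                alpha1 = cls$alpha1, alpha2_low = cls$alpha2_low,
                config = config)
  panel <- panel_dataset(tr$y, covariates = covs, truth = truth)
  apply_missingness(panel, rates = config$missing_rates,
                    mechanism = config$missing_mechanism,
                    seed = config$seed + 3, mar_coef = config$mar_coef)
}

#' Stage specifications matching a generator config
#'
#' Convenience constructor of the Stage-1/Stage-2 [stage_spec]s implied
#' by the config's knot mode and time scores.
#'
#' @param config a [generator_config].
#' @param K classes per stage (default 2).
#' @return list with `stage1` and `stage2`.
#' @export
stage_specs_for <- function(config, K = 2) {
  s1_ind <- if (config$knot_mode == "duplicate") c("y1", "y2", "y3a")
    else c("y1", "y2", "y3")
  s2_ind <- if (config$knot_mode == "duplicate") c("y3b", "y4", "y5", "y6")
    else c("y3", "y4", "y5", "y6")
  list(stage1 = stage_spec(1, s1_ind, config$time_scores$stage1, K = K),
       stage2 = stage_spec(2, s2_ind, config$time_scores$stage2, K = K))
}
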