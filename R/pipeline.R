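#' Full 3-step latent transition analysis
#'
#' Step 1 fits the per-stage growth mixtures on each stage's own
#' indicators; step 2 assigns modal classes and computes the
#' classification-error matrices; step 3 estimates the transition model
#' with those matrices fixed, optionally with covariate effects on
#' Stage-1 membership, Stage-2 membership and the low-origin transition.
#' Covariates with missing values are multiply imputed (joint-normal
#' model over all analysis columns) and the step-3 coefficients pooled
#' by Rubin's rules; indicator missingness is handled inside the
#' mixture likelihood (full information), so it needs no imputation.
#'
#' @param data a [panel_dataset].
#' @param specs list with `stage1` and `stage2` [stage_spec]s; derived
#'   from the panel's columns when `NULL`.
#' @param covariates character vector of covariate names for the
#'   structural model, or `NULL` for the null model.
#' @param n_starts,seed,... passed to [fit_gmm].
#' @param m_imputations imputations used when covariates have missing
#'   cells.
#' @return list of class `lta3_result`: `stage1`, `stage2` ([fit_gmm]),
#'   `q1`, `q2`, `step3` (an `lta_fit`, or a pooled list when imputing),
#'   `W1`, `W2`, `units` (row indices used in step 3).
#' @export
lta_3step <- function(data, specs = NULL, covariates = NULL,
                      n_starts = 20, seed = 1, m_imputations = 10, ...) {
  if (is.null(specs)) {
    knot <- if ("y3a" %in% colnames(data$y)) "duplicate" else "average"
    cfg <- generator_config(n = data$n, knot_mode = knot)
    specs <- stage_specs_for(cfg)
  }
  fit1 <- fit_gmm(data, specs$stage1, n_starts = n_starts, seed = seed, ...)
  fit2 <- fit_gmm(data, specs$stage2, n_starts = n_starts,
                  seed = seed + 100, ...)
  W1_full <- rep(NA_integer_, data$n)
  W2_full <- rep(NA_integer_, data$n)
  W1_full[fit1$keep] <- modal_assign(fit1$resp)$classes
  W2_full[fit2$keep] <- modal_assign(fit2$resp)$classes
  q1 <- classification_error(fit1$resp)
  q2 <- classification_error(fit2$resp)
  units <- which(!is.na(W1_full) & !is.na(W2_full))
  W1 <- W1_full[units]
  W2 <- W2_full[units]
  if (is.null(covariates)) {
    step3 <- fit_step3(W1, W2, NULL, q1, q2, seed = seed)
  } else {
    X <- as.matrix(data$covariates[units, covariates, drop = FALSE])
    if (anyNA(X)) {
      imps <- impute_multiply(data, m = m_imputations, seed = seed + 200)
      X_list <- lapply(imps, function(d)
        as.matrix(d$covariates[units, covariates, drop = FALSE]))
      step3 <- fit_step3_pooled(W1, W2, X_list, q1, q2, seed = seed)
    } else {
      step3 <- fit_step3(W1, W2, X, q1, q2, seed = seed)
    }
  }
  structure(list(stage1 = fit1, stage2 = fit2, q1 = q1, q2 = q2,
                 step3 = step3, W1 = W1, W2 = W2, units = units,
                 covariates = covariates),
            class = "lta3_result")
}

#' @export
print.lta3_result <- function(x, ...) {
  cat("3-step LTA with growth-mixture measurement\n")
  cat(sprintf("  stage 1: K = %d, weights %s\n", x$stage1$spec$K,
              paste(sprintf("%.3f", x$stage1$params$pi), collapse = "/")))
  cat(sprintf("  stage 2: K = %d, weights %s\n", x$stage2$spec$K,
              paste(sprintf("%.3f", x$stage2$params$pi), collapse = "/")))
  if (inherits(x$step3, "lta_fit")) print(x$step3)
  else cat("  step 3 pooled over", length(x$step3$fits), "imputations\n")
  invisible(x)
}
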