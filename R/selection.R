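#' Bayesian information criterion
#'
#' `-2LL + p * ln(n)`; `n` is the number of units, following the usual
#' mixture-model convention.
#'
#' @param minus2LL minus twice the maximized log-likelihood.
#' @param p number of free parameters.
#' @param n number of units.
#' @export
bic <- function(minus2LL, p, n) {
  stopifnot(n >= 1, p >= 0)
  minus2LL + p * log(n)
}

#' Sample-size-adjusted BIC
#'
#' Replaces `n` in the BIC penalty by `(n + 2) / 24`, the adjustment
#' favoured in mixture class-enumeration simulations.
#'
#' @inheritParams bic
#' @export
abic <- function(minus2LL, p, n) {
  stopifnot(n >= 1)
  minus2LL + p * log((n + 2) / 24)
}

#' Relative entropy of a mixture classification
#'
#' `1 - sum(-p * ln p) / (n * ln K)`: 1 means every unit is assigned
#' with certainty, 0 means posterior class probabilities are uniform.
#' Undefined for K = 1 (returns `NA` with a `"sentinel"` attribute).
#'
#' @param resp n x K responsibility matrix with rows summing to 1.
#' @export
entropy <- function(resp) {
  resp <- as.matrix(resp)
  K <- ncol(resp)
  if (K < 2) {
    out <- NA_real_
    attr(out, "sentinel") <- "entropy undefined for K = 1"
    return(out)
  }
  p <- resp
  terms <- ifelse(p > 0, -p * log(p), 0)
  1 - sum(terms) / (nrow(resp) * log(K))
}

#' Class-enumeration table and selection
#'
#' Fits the stage mixture for each candidate number of classes, tabulates
#' -2LL, BIC, aBIC, entropy and class proportions, and selects the
#' smallest-aBIC model among candidates that are non-degenerate and whose
#' smallest class proportion is at least `min_class_prop` (default 5%):
#' a class that tiny is treated as empirically negligible even when the
#' information criteria prefer the larger model. The full table is always
#' returned so the screen is transparent.
#'
#' @param data a [panel_dataset].
#' @param spec_template a [stage_spec]; its `K` is replaced by each
#'   candidate.
#' @param k_range integer vector of candidate class counts.
#' @param min_class_prop smallest admissible class proportion.
#' @param entropy_warn entropy level below which a classification-quality
#'   warning is recorded (advisory, not a gate).
#' @param ... passed to [fit_gmm] (`n_starts`, `seed`, ...).
#' @return list with `table` (data frame, one row per K), `selected_k`,
#'   `fits` (named list of [fit_gmm] results), `fallback` (TRUE when no
#'   candidate passed the screen).
#' @export
enumerate_classes <- function(data, spec_template, k_range,
                              min_class_prop = 0.05, entropy_warn = 0.6,
                              ...) {
  stopifnot(length(k_range) >= 1)
  rows <- list()
  fits <- list()
  for (K in k_range) {
    spec_k <- stage_spec(spec_template$stage_id, spec_template$indicators,
                         spec_template$time_scores, K = K)
    fit <- fit_gmm(data, spec_k, ...)
    ent <- entropy(fit$resp)
    m2 <- -2 * fit$loglik
    rows[[as.character(K)]] <- data.frame(
      model_label = sprintf("GMM_%dc", K),
      K = K,
      minus2LL = m2,
      bic = bic(m2, fit$n_params, fit$n),
      abic = abic(m2, fit$n_params, fit$n),
      entropy = as.numeric(ent),
      n_params = fit$n_params,
      min_class_prop = min(fit$params$pi),
      degenerate = fit$degenerate,
      low_entropy = is.finite(ent) && ent < entropy_warn
    )
    fits[[as.character(K)]] <- fit
  }
  tab <- do.call(rbind, rows)
  tab$class_proportions <- I(lapply(fits, function(f) f$params$pi))
  eligible <- !tab$degenerate & tab$min_class_prop >= min_class_prop
  fallback <- !any(eligible)
  selected_k <- if (fallback) {
    warning("no candidate passed the class-size screen; ",
            "falling back to the smallest K")
    min(k_range)
  } else {
    tab$K[eligible][which.min(tab$abic[eligible])]
  }
  list(table = tab, selected_k = selected_k, fits = fits,
       fallback = fallback)
}
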