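# Report rendering and thin run drivers. Every rendered number is a
# pure function of a stored result object; drivers write JSON results
# plus a manifest so each artifact is traceable to one run.

#' Class trajectory means
#'
#' Model-implied indicator means per class at the stage's time scores —
#' the numbers behind a trajectory plot.
#'
#' @param fit a [fit_gmm] result.
#' @return data frame with class, indicator, time and implied mean.
#' @export
trajectory_means <- function(fit) {
  spec <- fit$spec
  rows <- lapply(seq_len(fit$params$K), function(c) {
    mom <- implied_moments(fit$params, spec, c)
    data.frame(class = c, indicator = spec$indicators,
               time = spec$time_scores, mean = unname(mom$mean))
  })
  do.call(rbind, rows)
}

#' Growth-factor estimate table (per-class means, variances, covariance)
#' @param fit a [fit_gmm] result.
#' @return data frame, one row per class.
#' @export
growth_table <- function(fit) {
  K <- fit$params$K
  data.frame(
    class = seq_len(K),
    weight = fit$params$pi,
    int_mean = fit$params$mu[, 1],
    slp_mean = fit$params$mu[, 2],
    int_var = sapply(fit$params$psi, `[`, 1, 1),
    slp_var = sapply(fit$params$psi, `[`, 2, 2),
    int_slp_cov = sapply(fit$params$psi, `[`, 1, 2)
  )
}

#' Render the class-enumeration comparison as text
#' @param enum result of [enumerate_classes].
#' @export
render_selection_table <- function(enum) {
  tab <- enum$table
  lines <- c(sprintf("%-10s %10s %10s %10s %8s %8s",
                     "model", "-2LL", "BIC", "aBIC", "entropy", "minProp"))
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf("%-10s %10.1f %10.1f %10.1f %8.3f %8.3f%s",
                              tab$model_label[i], tab$minus2LL[i], tab$bic[i],
                              tab$abic[i], tab$entropy[i],
                              tab$min_class_prop[i],
                              if (tab$degenerate[i]) " [degenerate]" else ""))
  }
  lines <- c(lines, sprintf("selected K = %d%s", enum$selected_k,
                            if (enum$fallback) " (fallback)" else ""))
  paste(lines, collapse = "\n")
}

#' Render the combination/transition table as text
#' @param fit an `lta_fit`.
#' @export
render_transition_table <- function(fit) {
  tab <- fit$combination_table
  lines <- c(sprintf("%-12s %-6s %-6s %8s %10s %10s", "combination",
                     "G1", "G2", "count", "prop", "P(G2|G1)"))
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf("%-12s %-6s %-6s %8d %10.3f %10.3f",
                              tab$combination[i], tab$stage1[i], tab$stage2[i],
                              tab$count[i], tab$proportion[i],
                              tab$transition_probability[i]))
  }
  paste(lines, collapse = "\n")
}

#' Render the structural coefficient blocks as text
#' @param fit an `lta_fit` or the pooled result of [fit_step3_pooled].
#' @export
render_covariate_table <- function(fit) {
  if (inherits(fit, "lta_fit")) {
    or_tab <- odds_ratios(fit)
    or_tab$se <- fit$se
    or_tab$t <- fit$t
    or_tab$p_value <- fit$p_value
    tab <- or_tab
  } else {
    tab <- fit$pooled
    tab$beta <- tab$estimate
  }
  lines <- sprintf("%-22s %-16s %8s %8s %8s %10s %10s",
                   "block", "term", "beta", "SE", "t", "p", "OR")
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf(
      "%-22s %-16s %8.2f %8.2f %8.2f %10.3g %10.2f",
      tab$block[i], tab$term[i], tab$beta[i], tab$se[i],
      tab$beta[i] / tab$se[i], 2 * stats::pnorm(-abs(tab$beta[i] / tab$se[i])),
      tab$odds_ratio[i]))
  }
  paste(lines, collapse = "\n")
}

run_manifest <- function(command, config = NULL, seed = NULL, outputs = character()) {
  list(command = command,
       package_version = as.character(utils::packageVersion("ltagmm")),
       seed = seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs,
       config = config)
}

#' Simulate a panel to disk
#'
#' Writes the panel CSV, a truth CSV and a JSON manifest recording the
#' full configuration and seed, so the files are reproducible from the
#' manifest alone.
#'
#' @param config a [generator_config].
#' @param out_dir output directory (created if needed).
#' @param seed optional seed override; when omitted the config's seed is
#'   used and recorded.
#' @return paths of the written files (invisibly).
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- generate_panel(config)
  data_path <- file.path(out_dir, "panel.csv")
  truth_path <- file.path(out_dir, "truth.csv")
  write_panel(panel, data_path, truth_path)
  cfg <- config
  cfg$covariate_corr <- as.data.frame(cfg$covariate_corr)
  cfg$tau <- as.data.frame(cfg$tau)
  man <- run_manifest("simulate", config = unclass(cfg), seed = config$seed,
                      outputs = c(data_path, truth_path))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(data = data_path, truth = truth_path, manifest = man_path))
}

#' Fit models on a panel and write results
#'
#' @param data a [panel_dataset] (or a CSV path readable by
#'   [read_panel] with default column names).
#' @param mode `"gmm"` (one stage), `"enumerate"` (class enumeration) or
#'   `"lta3step"` (full pipeline).
#' @param out_dir output directory.
#' @param stage stage number for `"gmm"`/`"enumerate"`.
#' @param k_range candidate class counts for `"enumerate"`.
#' @param covariates covariate names for `"lta3step"` (NULL = null model).
#' @param seed,n_starts,m_imputations estimation controls.
#' @param ... passed to the fitting functions.
#' @return the fitted object (invisibly); JSON and text tables on disk.
#' @export
run_fit <- function(data, mode = c("gmm", "enumerate", "lta3step"),
                    out_dir, stage = 1, k_range = 2:4, covariates = NULL,
                    seed = 1, n_starts = 20, m_imputations = 10, ...) {
  mode <- match.arg(mode)
  if (is.character(data)) {
    header <- names(utils::read.csv(data, nrows = 1, check.names = FALSE))
    inds <- grep("^y", header, value = TRUE)
    covs <- intersect(eclsk_covariate_names, header)
    data <- read_panel(data, indicators = inds, covariates = covs,
                       id_col = if ("unit_id" %in% header) "unit_id")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  knot <- if ("y3a" %in% colnames(data$y)) "duplicate" else "average"
  specs <- stage_specs_for(generator_config(n = data$n, knot_mode = knot))
  spec <- if (stage == 1) specs$stage1 else specs$stage2
  result <- switch(mode,
    gmm = fit_gmm(data, spec, n_starts = n_starts, seed = seed, ...),
    enumerate = enumerate_classes(data, spec, k_range, n_starts = n_starts,
                                  seed = seed, ...),
    lta3step = lta_3step(data, specs, covariates = covariates,
                         n_starts = n_starts, seed = seed,
                         m_imputations = m_imputations, ...)
  )
  json_path <- file.path(out_dir, paste0(mode, "_result.json"))
  txt_path <- file.path(out_dir, paste0(mode, "_tables.txt"))
  txt <- switch(mode,
    gmm = paste0("Growth-factor estimates (stage ", stage, ")\n",
                 paste(utils::capture.output(print(growth_table(result))),
                       collapse = "\n")),
    enumerate = render_selection_table(result),
    lta3step = {
      s3 <- if (inherits(result$step3, "lta_fit")) result$step3
        else result$step3$fits[[1]]
      paste(render_transition_table(s3),
            if (!is.null(covariates)) render_covariate_table(
              if (inherits(result$step3, "lta_fit")) result$step3
              else result$step3),
            sep = "\n\n")
    })
  writeLines(txt, txt_path)
  jsonlite::write_json(serialize_result(result, mode), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  man <- run_manifest(paste0("fit:", mode), seed = seed,
                      outputs = c(json_path, txt_path))
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

serialize_result <- function(result, mode) {
  switch(mode,
    gmm = list(
      loglik = result$loglik, n_params = result$n_params,
      converged = result$converged, n_iter = result$n_iter,
      degenerate = result$degenerate,
      class_weights = result$params$pi, growth = growth_table(result),
      theta = result$params$theta, loglik_trace = result$loglik_trace
    ),
    enumerate = list(
      table = result$table[, setdiff(names(result$table),
                                     "class_proportions")],
      selected_k = result$selected_k, fallback = result$fallback
    ),
    lta3step = {
      s3 <- if (inherits(result$step3, "lta_fit")) result$step3
        else result$step3$fits[[1]]
      list(
        stage1 = serialize_result(result$stage1, "gmm"),
        stage2 = serialize_result(result$stage2, "gmm"),
        q1 = result$q1$q, q2 = result$q2$q,
        combination_table = s3$combination_table,
        transition_matrix = s3$transition_matrix,
        stage1_proportions = s3$stage1_proportions,
        loglik = s3$loglik, bic = s3$bic, abic = s3$abic,
        entropy = s3$entropy,
        coefficients = if (inherits(result$step3, "lta_fit"))
          odds_ratios(result$step3) else result$step3$pooled
      )
    })
}

#' Consolidated text report over stored results
#'
#' Reads one or more JSON result files written by [run_fit] and renders
#' a consolidated report, including the per-class trajectory means at
#' the fitted time scores.
#'
#' @param results_paths character vector of JSON result paths.
#' @return report text (also returned invisibly when printed).
#' @export
run_report <- function(results_paths) {
  if (!length(results_paths)) stop("no result files given", call. = FALSE)
  blocks <- lapply(results_paths, function(p) {
    res <- jsonlite::read_json(p, simplifyVector = TRUE)
    header <- paste0("== ", basename(p), " ==")
    body <- if (!is.null(res$stage1)) {
      paste(c(render_growth_block(res$stage1, "Stage 1"),
              render_growth_block(res$stage2, "Stage 2"),
              render_json_transition(res)), collapse = "\n")
    } else if (!is.null(res$growth)) {
      render_growth_block(res, "Stage")
    } else if (!is.null(res$table)) {
      paste(utils::capture.output(print(res$table)), collapse = "\n")
    } else {
      paste(utils::capture.output(utils::str(res)), collapse = "\n")
    }
    paste(header, body, sep = "\n")
  })
  paste(unlist(blocks), collapse = "\n\n")
}

render_growth_block <- function(res, label) {
  g <- as.data.frame(res$growth)
  lines <- sprintf("%s: class weights %s", label,
                   paste(sprintf("%.3f", res$class_weights), collapse = "/"))
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf(
      "  class %d: INT %.3f SLP %.3f (var %.3f/%.3f, cov %.3f)",
      g$class[i], g$int_mean[i], g$slp_mean[i], g$int_var[i], g$slp_var[i],
      g$int_slp_cov[i]))
  }
  paste(lines, collapse = "\n")
}

render_json_transition <- function(res) {
  tab <- as.data.frame(res$combination_table)
  lines <- "Combinations (count / proportion / P(G2|G1)):"
  for (i in seq_len(nrow(tab))) {
    lines <- c(lines, sprintf("  %-10s %6d  %.3f  %.3f", tab$combination[i],
                              tab$count[i], tab$proportion[i],
                              tab$transition_probability[i]))
  }
  paste(lines, collapse = "\n")
}
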