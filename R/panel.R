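#' Wide-format longitudinal panel
#'
#' Container for the analysis panel: one row per child, repeated ability
#' scores on a common (IRT-linked) scale, and baseline covariates.
#' Missing cells are stored as `NA`, so a cell is either observed with a
#' value or missing, never both.
#'
#' @param y numeric matrix (or data frame) of repeated ability scores,
#'   one column per wave; `NA` marks a missing cell.
#' @param covariates data frame of baseline covariates (may have zero
#'   columns); `NA` marks a missing cell.
#' @param unit_id optional identifier vector, defaults to `1:n`.
#' @param truth optional list with generating-truth components (class
#'   labels `g1`, `g2`, latent growth factors, pre-masking values);
#'   present only for synthetic panels.
#' @return an object of class `panel_dataset` with elements `y`,
#'   `covariates`, `unit_id`, `truth`, `n`.
#' @export
panel_dataset <- function(y, covariates = NULL, unit_id = NULL, truth = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(y)
  if (is.null(covariates)) {
    covariates <- as.data.frame(matrix(numeric(0), nrow = n, ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != n) {
    stop("covariates must have one row per unit (", n, "), got ",
         nrow(covariates), call. = FALSE)
  }
  if (is.null(unit_id)) unit_id <- seq_len(n)
  if (length(unit_id) != n) stop("unit_id length must equal n", call. = FALSE)
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  structure(
    list(y = y, covariates = covariates, unit_id = unit_id,
         truth = truth, n = n),
    class = "panel_dataset"
  )
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("panel_dataset:", x$n, "units,", ncol(x$y), "indicators,",
      ncol(x$covariates), "covariates\n")
  ms <- summarize_missingness(x)
  cat(sprintf("  missing cells: %.2f%% overall (%d units with any missing)\n",
              100 * ms$overall_rate, ms$n_units_any_missing))
  if (!is.null(x$truth)) cat("  truth labels present (synthetic panel)\n")
  invisible(x)
}

panel_columns <- function(data) {
  cbind(data$y, as.matrix(data$covariates))
}

#' Read a wide-format panel from delimited text
#'
#' Reads a CSV (header row required) and maps file columns onto the
#' panel's indicator and covariate slots. Empty cells and the literal
#' token `NA` are read as missing.
#'
#' @param path file path to a delimited text file.
#' @param indicators character vector of indicator column names, in wave
#'   order, as they appear in the file (or as the targets of `column_map`).
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param column_map optional named character vector mapping canonical
#'   names to file header names, e.g. `c(y1 = "C1SCORE")`.
#' @param id_col optional name of an identifier column.
#' @param sep field separator, default comma.
#' @return a [panel_dataset].
#' @export
read_panel <- function(path, indicators, covariates = character(),
                       column_map = NULL, id_col = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           na.strings = c("", "NA"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  resolve <- function(nm) if (!is.null(column_map) && nm %in% names(column_map))
    column_map[[nm]] else nm
  take <- function(nm) {
    file_nm <- resolve(nm)
    if (!file_nm %in% names(raw)) {
      stop("column '", file_nm, "' (for '", nm, "') not found in ", path,
           call. = FALSE)
    }
    col <- raw[[file_nm]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      stop("non-numeric value '", col[bad[1]], "' in column '", file_nm,
           "' at data row ", bad[1], call. = FALSE)
    }
    num
  }
  y <- sapply(indicators, take)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1, dimnames = list(NULL, indicators))
  covs <- as.data.frame(lapply(stats::setNames(covariates, covariates), take),
                        optional = TRUE)
  if (!length(covariates)) covs <- NULL
  ids <- if (!is.null(id_col)) raw[[resolve(id_col)]] else NULL
  panel_dataset(y, covariates = covs, unit_id = ids)
}

#' Write a panel to CSV
#'
#' Missing cells are written as empty fields; [read_panel] on the output
#' reproduces values and missingness exactly.
#'
#' @param data a [panel_dataset].
#' @param path output file path.
#' @param truth_path optional path for the truth block (synthetic panels).
#' @export
write_panel <- function(data, path, truth_path = NULL) {
  # %.17g keeps the round trip bit-exact for doubles
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) ifelse(is.na(col), NA, sprintf("%.17g", col))
      else col
    })
    df
  }
  out <- fmt(data.frame(unit_id = data$unit_id, data$y, data$covariates,
                        check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(truth_path) && !is.null(data$truth)) {
    tr <- fmt(data.frame(unit_id = data$unit_id,
                         g1 = data$truth$g1, g2 = data$truth$g2,
                         data$truth$factors, check.names = FALSE))
    utils::write.csv(tr, truth_path, row.names = FALSE, na = "",
                     quote = FALSE)
  }
  invisible(path)
}

#' Summarize missingness of a panel
#'
#' @param data a [panel_dataset].
#' @param variables optional character subset of columns (indicators
#'   and/or covariates); default all.
#' @return list with `per_variable_rate`, `overall_rate`,
#'   `n_units_any_missing`.
#' @export
summarize_missingness <- function(data, variables = NULL) {
  all_cols <- panel_columns(data)
  if (!is.null(variables)) {
    unknown <- setdiff(variables, colnames(all_cols))
    if (length(unknown)) {
      stop("unknown variable(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    all_cols <- all_cols[, variables, drop = FALSE]
  }
  miss <- is.na(all_cols)
  list(
    per_variable_rate = colMeans(miss),
    overall_rate = mean(miss),
    n_units_any_missing = sum(rowSums(miss) > 0)
  )
}
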