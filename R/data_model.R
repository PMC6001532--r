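#' Attach missingness indicators to a rectangular dataset
#'
#' Converts a data frame (or numeric matrix) with missing entries into an
#' `incomplete_data` object: the numeric data table, a logical missingness
#' mask, per-variable complete/incomplete flags, and one 0/1 missingness
#' indicator column `M_<var>` for every incomplete variable (1 = missing).
#' Fully observed variables are flagged complete and get no indicator.
#'
#' Only continuous and binary 0/1 variables are supported; columns that are
#' not numeric (or logical) are rejected.  A column with no observed value
#' is an error, as is a zero-row table.
#'
#' @param data data frame or numeric matrix, one row per subject. Missing
#'   entries are `NA`.
#' @return An object of class `incomplete_data`: a list with elements
#'   `values` (numeric matrix, `NA` where missing), `miss` (logical matrix),
#'   `var_names`, `incomplete` (names of variables with any missing entry),
#'   `complete` (fully observed variables), `indicators` (n x k 0/1 matrix,
#'   columns `M_<var>`), and `n`.
#' @examples
#' d <- data.frame(y1 = c(1, NA, 3), y2 = c(2, 5, NA), x = c(0, 1, 1))
#' inc <- incomplete_data(d)
#' inc$indicators
#' @export
incomplete_data <- function(data) {
  if (is.matrix(data)) data <- as.data.frame(data)
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("dataset has zero rows")
  if (is.null(names(data)) || any(!nzchar(names(data))))
    stop("all columns must be named")
  vals <- vapply(seq_along(data), function(j) {
    col <- data[[j]]
    if (is.logical(col)) col <- as.numeric(col)
    if (!is.numeric(col))
      stop("variable '", names(data)[j],
           "' is not numeric; only continuous and binary 0/1 variables are supported")
    as.numeric(col)
  }, numeric(nrow(data)))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(data))
  colnames(vals) <- names(data)
  miss <- is.na(vals)
  all_missing <- colnames(vals)[colSums(miss) == nrow(vals)]
  if (length(all_missing))
    stop("variable entirely missing: ", paste(all_missing, collapse = ", "))
  incomplete <- colnames(vals)[colSums(miss) > 0L]
  complete <- setdiff(colnames(vals), incomplete)
  ind <- matrix(0, nrow(vals), length(incomplete),
                dimnames = list(NULL, sprintf("M_%s", incomplete)))
  for (v in incomplete) ind[, paste0("M_", v)] <- as.numeric(miss[, v])
  structure(list(values = vals, miss = miss, var_names = colnames(vals),
                 incomplete = incomplete, complete = complete,
                 indicators = ind, n = nrow(vals)),
            class = "incomplete_data")
}

#' @export
print.incomplete_data <- function(x, ...) {
  cat("Incomplete dataset:", x$n, "subjects x", length(x$var_names),
      "variables\n")
  cat("  incomplete:",
      if (length(x$incomplete)) paste(x$incomplete, collapse = ", ") else "(none)",
      "\n")
  pm <- colMeans(x$miss[, x$incomplete, drop = FALSE])
  if (length(pm))
    cat("  missing fraction:",
        paste(sprintf("%s=%.3f", x$incomplete, pm), collapse = ", "), "\n")
  invisible(x)
}

#' Build the predictor set for one incomplete variable's imputation model
#'
#' The NARFCS imputation model for an incomplete variable regresses it on
#' all other variables, plus the missingness indicators of the other
#' incomplete variables, plus its own indicator (whose coefficient is the
#' inestimable conditional sensitivity parameter, the CSP).  A
#' cross-indicator can only enter the fit if its coefficient is estimable
#' on the rows where the target is observed: under monotone dropout an
#' indicator may be constant there, or indicators may be collinear.  Such
#' indicators are dropped (recorded, never fatal); the target's own
#' indicator is always retained and tagged as the CSP term.
#'
#' @param data an [incomplete_data()] object.
#' @param target name of an incomplete variable.
#' @param cond_tol condition-number threshold beyond which an indicator is
#'   considered non-estimable in the indicator design (default `1e8`).
#' @return List with `target`, `vars` (all other variables), `indicators`
#'   (retained cross-indicator column names), `csp_term` (`M_<target>`),
#'   and `dropped` (removed cross-indicators).
#' @examples
#' d <- data.frame(y1 = c(1, NA, 3, 4), y2 = c(2, 5, NA, 1), x = 1:4 / 4)
#' build_predictor_set(incomplete_data(d), "y1")
#' @export
build_predictor_set <- function(data, target, cond_tol = 1e8) {
  stopifnot(inherits(data, "incomplete_data"))
  if (!target %in% data$incomplete)
    stop("target '", target, "' is not an incomplete variable")
  obs <- !data$miss[, target]
  others <- setdiff(data$incomplete, target)
  kept <- character(0)
  dropped <- character(0)
  # greedy estimability screen on the observed-rows indicator design
  design <- matrix(1, sum(obs), 1)
  for (v in others) {
    col_name <- paste0("M_", v)
    col <- data$indicators[obs, col_name]
    cand <- cbind(design, col)
    if (length(unique(col)) < 2L || kappa(cand, exact = TRUE) > cond_tol) {
      dropped <- c(dropped, col_name)
    } else {
      kept <- c(kept, col_name)
      design <- cand
    }
  }
  list(target = target,
       vars = setdiff(data$var_names, target),
       indicators = kept,
       csp_term = paste0("M_", target),
       dropped = dropped)
}

#' Read a delimited dataset and attach missingness indicators
#'
#' CSV with a header row; empty fields and the literal `NA` both parse as
#' missing.
#'
#' @param path file path.
#' @return An [incomplete_data()] object.
#' @export
read_incomplete_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("NA", ""))
  incomplete_data(df)
}

#' Write completed (imputed) datasets to CSV
#'
#' One file per imputation, named `imp_<i>.csv`, each with a leading
#' `.imp` column holding the imputation index.
#'
#' @param imp a `narfcs_imp` object from [narfcs_impute()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_completed_csv <- function(imp, dir) {
  stopifnot(inherits(imp, "narfcs_imp"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(imp$m)
  for (i in seq_len(imp$m)) {
    df <- cbind(.imp = i, imp$completed[[i]])
    files[i] <- file.path(dir, sprintf("imp_%d.csv", i))
    utils::write.csv(df, files[i], row.names = FALSE)
  }
  invisible(files)
}
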