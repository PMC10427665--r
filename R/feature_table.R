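# The subjects x features container consumed by the age model.
#
# Feature columns are named "RV:<region name>" and "SVR:<region name>"; rows
# align with per-session PMA targets in weeks.

#' Construct a feature table
#'
#' @param subject_id,session_id character keys, one per row.
#' @param pma_weeks numeric PMA at scan per row (the regression target).
#' @param values numeric matrix, rows = sessions, columns = features.
#' @param feature_names unique character feature names; default
#'   `colnames(values)`.
#' @return object of class `feature_table`: list with `subjects`
#'   (data.frame), `ages`, `feature_names`, `values`.
#' @export
feature_table <- function(subject_id, session_id, pma_weeks, values,
                          feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(feature_names)) stopf("feature names are required")
  if (anyDuplicated(feature_names)) stopf("duplicate feature names")
  if (length(feature_names) != ncol(values)) {
    stopf("feature_names length (%d) != number of columns (%d)",
          length(feature_names), ncol(values))
  }
  n <- nrow(values)
  if (length(subject_id) != n || length(session_id) != n ||
      length(pma_weeks) != n) {
    stopf("subject_id, session_id, pma_weeks must match the row count (%d)", n)
  }
  if (anyNA(values)) stopf("feature values must not contain NA")
  colnames(values) <- feature_names
  structure(
    list(subjects = data.frame(subject_id = as.character(subject_id),
                               session_id = as.character(session_id),
                               stringsAsFactors = FALSE),
         ages = as.numeric(pma_weeks),
         feature_names = as.character(feature_names),
         values = values),
    class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d sessions x %d features, PMA %.1f-%.1f weeks\n",
              nrow(x$values), ncol(x$values),
              min(x$ages), max(x$ages)))
  invisible(x)
}

#' Number of rows / subset of a feature table
#'
#' @param x a `feature_table`.
#' @param rows integer or logical row index.
#' @return `ft_rows` returns the subsetted `feature_table`.
#' @export
ft_rows <- function(x, rows) {
  feature_table(x$subjects$subject_id[rows], x$subjects$session_id[rows],
                x$ages[rows], x$values[rows, , drop = FALSE],
                x$feature_names)
}

#' Write / read a feature table as CSV
#'
#' Layout: columns `subject_id`, `session_id`, `pma_weeks`, then one column
#' per feature. Values are written with 10 significant digits, so
#' read(write(x)) reproduces `x` to ~1e-9 relative error.
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  d <- data.frame(subject_id = table$subjects$subject_id,
                  session_id = table$subjects$session_id,
                  pma_weeks = signif(table$ages, 10),
                  signif(table$values, 10),
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @return `read_feature_table` returns a `feature_table`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character",
                                      session_id = "character"))
  if (anyDuplicated(names(d))) stopf("duplicate feature names in %s", path)
  need <- c("subject_id", "session_id", "pma_weeks")
  if (!all(need %in% names(d))) {
    stopf("feature table must start with columns: %s",
          paste(need, collapse = ", "))
  }
  fn <- setdiff(names(d), need)
  vals <- as.matrix(d[, fn, drop = FALSE])
  if (nrow(d) > 0 && !is.numeric(vals)) stopf("malformed CSV: non-numeric features")
  if (nrow(d) == 0) vals <- matrix(numeric(0), 0, length(fn),
                                   dimnames = list(NULL, fn))
  feature_table(d$subject_id, d$session_id, d$pma_weeks, vals, fn)
}

# Assemble a feature_table from per-session morphometry data.frames
# (extract_features output), in manifest order.
features_to_table <- function(manifest, morpho_list) {
  stopifnot(nrow(manifest) == length(morpho_list))
  first <- morpho_list[[1]]
  fn <- c(paste0("RV:", first$region_name), paste0("SVR:", first$region_name))
  rows <- t(vapply(morpho_list, function(m) c(m$rv, m$svr),
                   numeric(2L * nrow(first))))
  feature_table(manifest$subject_id, manifest$session_id, manifest$pma_weeks,
                rows, fn)
}
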