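# Permutation feature importance (PFI) and its per-family (RV / SVR)
# region-level reporting.
#
# PFI measures the drop in a trained model's score when one feature column is
# randomly shuffled (severing the feature-target link) while the others stay
# intact. The per-family variant trains one model per feature family so that
# correlated RV/SVR pairs of the same region cannot mask each other across
# families.

#' Permutation feature importance
#'
#' For each feature used by the model: importance = baseline score minus the
#' mean score over `repeats` shuffles of that column. The score is the
#' coefficient of determination (1 - SSE/SST) on the supplied rows;
#' `scorer = "neg_mae"` uses negative MAE instead. The baseline is computed
#' once; shuffles come from the seeded generator, features in model order,
#' repeats innermost, so results are bit-reproducible.
#'
#' @param model a [fit_age_model()] result.
#' @param table a `feature_table` of evaluation rows (>= 5).
#' @param repeats shuffles per feature (default 30).
#' @param seed integer seed.
#' @param scorer `"r2_cod"` (default) or `"neg_mae"`.
#' @return data.frame: `feature`, `raw_importance`, `importance_sd`.
#' @export
permutation_importance <- function(model, table, repeats = 30L, seed = 0L,
                                   scorer = c("r2_cod", "neg_mae")) {
  stopifnot(inherits(model, "fitted_age_model"),
            inherits(table, "feature_table"))
  scorer <- match.arg(scorer)
  if (nrow(table$values) < 5L) stopf("need >= 5 rows for PFI")
  if (repeats < 1L) stopf("repeats must be >= 1")
  missing <- setdiff(model$selected_features, table$feature_names)
  if (length(missing)) {
    stopf("feature missing from table: %s", missing[1])
  }

  score_fun <- switch(scorer,
    r2_cod = function(y, p) 1 - sum((y - p)^2) / sum((y - mean(y))^2),
    neg_mae = function(y, p) -mean(abs(y - p)))

  vals <- table$values
  y <- table$ages
  baseline <- score_fun(y, predict_age(model, vals))
  feats <- model$selected_features

  with_seed(seed, {
    out <- lapply(feats, function(f) {
      scores <- vapply(seq_len(repeats), function(r) {
        shuffled <- vals
        shuffled[, f] <- shuffled[sample.int(nrow(vals)), f]
        score_fun(y, predict_age(model, shuffled))
      }, numeric(1))
      c(raw = baseline - mean(scores),
        sd = if (repeats > 1L) stats::sd(scores) else 0)
    })
  })
  m <- do.call(rbind, out)
  data.frame(feature = feats,
             raw_importance = unname(m[, "raw"]),
             importance_sd = unname(m[, "sd"]),
             stringsAsFactors = FALSE)
}

#' Rescale importances to [0, 1]
#'
#' Divides by the maximum raw importance after clipping negatives at zero,
#' so true zeros stay zero and the strongest feature maps to 1. All
#' non-positive input yields all zeros. Ranking among non-negative values is
#' preserved and the operation is idempotent.
#'
#' @param raw numeric raw importances.
#' @return numeric vector in \[0, 1\].
#' @export
rescale_importance <- function(raw) {
  if (length(raw) == 0L) stopf("empty importance list")
  clipped <- pmax(raw, 0)
  mx <- max(raw)
  if (mx <= 0) return(rep(0, length(raw)))
  clipped / mx
}

#' Per-family region importance report
#'
#' Restricts the table to one feature family (`RV:` or `SVR:` columns),
#' fits a Bayesian ridge model on the training rows (all family features, no
#' top-k selection unless `k_select` is given), and runs
#' [permutation_importance()] on the held-out rows, attaching region names
#' and \[0, 1\]-rescaled importances.
#'
#' @param table a `feature_table` containing both families.
#' @param family `"RV"` or `"SVR"`.
#' @param train_rows logical or integer index of training rows; default a
#'   seeded 75/25 split.
#' @param repeats,seed,scorer forwarded to [permutation_importance()].
#' @param k_select optional within-family top-k selection before fitting.
#' @return object of class `importance_report`: data.frame `entries`
#'   (family, region_name, feature, raw_importance, importance_sd,
#'   scaled_importance) plus fields `repeats`, `scorer`, `seed`.
#' @export
family_importance <- function(table, family = c("RV", "SVR"),
                              train_rows = NULL, repeats = 30L, seed = 0L,
                              scorer = "r2_cod", k_select = NULL) {
  stopifnot(inherits(table, "feature_table"))
  family <- match.arg(family)
  fam_cols <- grep(paste0("^", family, ":"), table$feature_names, value = TRUE)
  if (length(fam_cols) < 2L) stopf("family %s absent (or < 2 features)", family)

  n <- nrow(table$values)
  if (is.null(train_rows)) {
    idx <- with_seed(derive_seed(seed, 1L), sample.int(n))
    train_rows <- idx[seq_len(floor(0.75 * n))]
  }
  is_train <- rep(FALSE, n); is_train[train_rows] <- TRUE

  fam_table <- feature_table(table$subjects$subject_id,
                             table$subjects$session_id,
                             table$ages,
                             table$values[, fam_cols, drop = FALSE],
                             fam_cols)
  train_tab <- ft_rows(fam_table, is_train)
  test_tab <- ft_rows(fam_table, !is_train)

  selected <- if (is.null(k_select)) fam_cols
              else select_features(train_tab, k_select)
  model <- fit_age_model(train_tab, selected, "bayesian_ridge", seed = seed)
  imp <- permutation_importance(model, test_tab, repeats = repeats,
                                seed = derive_seed(seed, 2L), scorer = scorer)

  entries <- data.frame(
    family = family,
    region_name = sub(paste0("^", family, ":"), "", imp$feature),
    feature = imp$feature,
    raw_importance = imp$raw_importance,
    importance_sd = imp$importance_sd,
    scaled_importance = rescale_importance(imp$raw_importance),
    stringsAsFactors = FALSE)
  structure(list(entries = entries, repeats = as.integer(repeats),
                 scorer = scorer, seed = as.integer(seed)),
            class = "importance_report")
}

#' @exportS3Method base::print
print.importance_report <- function(x, ...) {
  top <- x$entries[order(-x$entries$scaled_importance), ][1:min(5, nrow(x$entries)), ]
  cat(sprintf("<importance_report> %s family, %d features, %d repeats (%s)\n",
              x$entries$family[1], nrow(x$entries), x$repeats, x$scorer))
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-45s %.3f\n", top$region_name[i], top$scaled_importance[i]))
  }
  invisible(x)
}

#' Save / load an importance report
#'
#' JSON for the full report; [write_importance_csv()] exports the tidy
#' per-region table for plotting.
#'
#' @param report an `importance_report`.
#' @param path output path.
#' @export
save_importance_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_importance_report
#' @export
load_importance_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$entries <- as.data.frame(p$entries, stringsAsFactors = FALSE)
  structure(p, class = "importance_report")
}

#' @rdname save_importance_report
#' @export
write_importance_csv <- function(report, path) {
  utils::write.csv(report$entries, path, row.names = FALSE)
  invisible(path)
}
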