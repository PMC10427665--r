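# Postmenstrual-age regression: correlation-based feature selection,
# z-score standardization, a pluggable regressor (Bayesian ridge by
# default), and the evaluation metrics.

#' Select the most age-correlated features
#'
#' Ranks features by the absolute Pearson correlation between the feature
#' column and PMA over the supplied (training) rows and returns the top
#' `min(k, n_features)` names. Constant features get correlation 0. Ties are
#' broken by the original column order, making the selection deterministic
#' and invariant to row permutations.
#'
#' @param table a [feature_table()] restricted to training rows.
#' @param k number of features to keep (default 100).
#' @return ordered character vector of selected feature names.
#' @export
select_features <- function(table, k = 100L) {
  stopifnot(inherits(table, "feature_table"))
  if (k < 1L) stopf("k must be >= 1")
  if (nrow(table$values) < 2L) stopf("need at least 2 rows for correlation")
  sds <- apply(table$values, 2L, stats::sd)
  r <- rep(0, ncol(table$values))
  ok <- sds > 0 & stats::sd(table$ages) > 0
  if (any(ok)) {
    r[ok] <- abs(suppressWarnings(
      stats::cor(table$values[, ok, drop = FALSE], table$ages)))
  }
  r[!is.finite(r)] <- 0
  ord <- order(-r, seq_along(r))
  table$feature_names[ord[seq_len(min(k, length(r)))]]
}

#' Fit an age-regression model
#'
#' Standardizes the selected feature columns with training means and
#' standard deviations (constant columns get divisor 1) and fits the chosen
#' regressor on the standardized matrix against PMA.
#'
#' @param table training [feature_table()].
#' @param selected feature names to use; default [select_features()] with
#'   `k = 100`.
#' @param regressor_kind one of `"bayesian_ridge"` (default),
#'   `"kernel_ridge"`, `"elastic_net"`, `"gradient_boosting"`.
#' @param seed integer seed recorded in the model and forwarded to backends.
#' @return object of class `fitted_age_model`.
#' @export
fit_age_model <- function(table, selected = NULL,
                          regressor_kind = "bayesian_ridge", seed = 0L) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(selected)) selected <- select_features(table, 100L)
  if (length(selected) == 0L) stopf("empty feature selection")
  missing <- setdiff(selected, table$feature_names)
  if (length(missing)) {
    stopf("selected features absent from table: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  }
  if (nrow(table$values) < 3L) stopf("need at least 3 training rows")
  if (stats::sd(table$ages) == 0) stopf("degenerate (constant) ages")

  x <- table$values[, selected, drop = FALSE]
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2L, mu), 2L, sdv, "/")
  reg <- fit_regressor(regressor_kind, xs, table$ages, seed = seed)

  structure(
    list(selected_features = selected,
         standardization = list(mean = mu, sd = sdv),
         regressor_kind = regressor_kind,
         regressor = reg,
         training_meta = list(seed = as.integer(seed),
                              n_train = nrow(x),
                              k_select = length(selected))),
    class = "fitted_age_model")
}

#' @exportS3Method base::print
print.fitted_age_model <- function(x, ...) {
  cat(sprintf("<fitted_age_model> %s, %d features, n_train = %d\n",
              x$regressor_kind, length(x$selected_features),
              x$training_meta$n_train))
  invisible(x)
}

#' Predict PMA for new sessions
#'
#' Input columns are aligned by feature name, so column order is irrelevant.
#' Predictions are not clipped.
#'
#' @param model a `fitted_age_model`.
#' @param features a `feature_table`, or a numeric matrix/data.frame with
#'   named columns covering the model's selected features.
#' @return numeric predicted PMA in weeks, one per row.
#' @export
predict_age <- function(model, features) {
  stopifnot(inherits(model, "fitted_age_model"))
  vals <- if (inherits(features, "feature_table")) features$values
          else as.matrix(features)
  missing <- setdiff(model$selected_features, colnames(vals))
  if (length(missing)) {
    stopf("missing feature column(s): %s",
          paste(utils::head(missing, 3), collapse = ", "))
  }
  x <- vals[, model$selected_features, drop = FALSE]
  xs <- sweep(sweep(x, 2L, model$standardization$mean),
              2L, model$standardization$sd, "/")
  predict_regressor(model$regressor, xs)
}

#' Evaluate age predictions
#'
#' Reports MAE, RMSE, the squared Pearson correlation between truths and
#' predictions (`r2`, the printed determination score, which is invariant to
#' a constant shift of the predictions), the error-based coefficient of
#' determination (`r2_cod = 1 - SSE/SST`) to avoid ambiguity between the two
#' conventions, and per-interval MAE.
#'
#' @param truths,preds numeric vectors of equal length >= 2, weeks.
#' @param intervals optional increasing numeric break points for the
#'   per-interval MAE; default 2-week bins spanning the truth range.
#' @return list of class `eval_report`: `mae`, `rmse`, `r2`, `r2_cod`,
#'   `per_interval_mae`.
#' @export
evaluate <- function(truths, preds, intervals = NULL) {
  if (length(truths) != length(preds)) stopf("length mismatch")
  n <- length(truths)
  if (n < 2L) stopf("need at least 2 samples")
  err <- truths - preds
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  r2 <- if (stats::sd(preds) == 0 || stats::sd(truths) == 0) 0
        else suppressWarnings(stats::cor(truths, preds))^2
  r2_cod <- 1 - sum(err^2) / sum((truths - mean(truths))^2)

  if (is.null(intervals)) {
    lo <- floor(min(truths)); hi <- ceiling(max(truths))
    intervals <- seq(lo, max(hi, lo + 2), by = 2)
    if (intervals[length(intervals)] < hi) {
      intervals <- c(intervals, intervals[length(intervals)] + 2)
    }
  }
  bins <- cut(truths, intervals, include.lowest = TRUE)
  per_int <- tapply(abs(err), bins, mean)

  structure(list(mae = mae, rmse = rmse, r2 = unname(r2), r2_cod = r2_cod,
                 per_interval_mae = per_int),
            class = "eval_report")
}

#' @exportS3Method base::print
print.eval_report <- function(x, ...) {
  cat(sprintf("MAE %.3f weeks | RMSE %.3f weeks | R2 (sq. Pearson) %.3f | R2 (CoD) %.3f\n",
              x$mae, x$rmse, x$r2, x$r2_cod))
  invisible(x)
}

#' Save / load a fitted age model as JSON
#'
#' Linear backends (Bayesian ridge, kernel ridge, elastic net) and the stump
#' ensemble serialize completely, so reloaded models predict identically
#' without retraining.
#'
#' @param model a `fitted_age_model`.
#' @param path JSON file path.
#' @export
save_age_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_age_model"))
  payload <- list(
    selected_features = model$selected_features,
    standardization = list(mean = unname(model$standardization$mean),
                           sd = unname(model$standardization$sd)),
    regressor_kind = model$regressor_kind,
    state = serialize_state(model$regressor),
    training_meta = model$training_meta)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_age_model
#' @export
load_age_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- deserialize_state(p$regressor_kind, p$state)
  structure(
    list(selected_features = p$selected_features,
         standardization = list(
           mean = setNames(p$standardization$mean, p$selected_features),
           sd = setNames(p$standardization$sd, p$selected_features)),
         regressor_kind = p$regressor_kind,
         regressor = reg,
         training_meta = p$training_meta),
    class = "fitted_age_model")
}

serialize_state <- function(reg) {
  s <- reg$state
  if (reg$kind == "gradient_boosting") {
    list(init = s$init, learning_rate = s$learning_rate, stumps = s$stumps)
  } else {
    list(coef = unname(as.numeric(s$coef)), intercept = s$intercept,
         alpha = s$alpha %||% NULL, lambda = s$lambda %||% NULL)
  }
}

deserialize_state <- function(kind, s) {
  state <- if (kind == "gradient_boosting") {
    list(init = s$init, learning_rate = s$learning_rate,
         stumps = as.data.frame(s$stumps))
  } else if (kind == "bayesian_ridge") {
    structure(list(coef = s$coef, intercept = s$intercept,
                   alpha = s$alpha, lambda = s$lambda),
              class = "bayes_ridge")
  } else {
    list(coef = s$coef, intercept = s$intercept)
  }
  structure(list(kind = kind, state = state), class = "nba_regressor")
}
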