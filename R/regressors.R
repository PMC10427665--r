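# Pluggable regression backends behind one fit/predict interface.
#
# bayesian_ridge is the reference model (see bayes_ridge.R). kernel_ridge,
# elastic_net and gradient_boosting are alternatives with conventional
# defaults; all are deterministic, so a `seed` is accepted for interface
# uniformity but only consumed by backends that need randomness (none today).
# SVM and MLP backends are not provided: no suitable library is available in
# the supported environment and re-implementing them would add nothing to the
# scientific core.

REGRESSOR_KINDS <- c("bayesian_ridge", "kernel_ridge", "elastic_net",
                     "gradient_boosting")

fit_regressor <- function(kind, x, y, seed = 0L) {
  kind <- match.arg(kind, REGRESSOR_KINDS)
  state <- switch(kind,
    bayesian_ridge = bayes_ridge(x, y),
    kernel_ridge = fit_kernel_ridge(x, y),
    elastic_net = fit_elastic_net(x, y),
    gradient_boosting = fit_gb_stumps(x, y))
  structure(list(kind = kind, state = state), class = "nba_regressor")
}

predict_regressor <- function(reg, x) {
  switch(reg$kind,
    bayesian_ridge = predict(reg$state, x),
    kernel_ridge = predict_linear_state(reg$state, x),
    elastic_net = predict_linear_state(reg$state, x),
    gradient_boosting = predict_gb_stumps(reg$state, x))
}

predict_linear_state <- function(state, x) {
  drop(as.matrix(x) %*% state$coef) + state$intercept
}

# Linear-kernel ridge with unit penalty, solved in the dual and stored as the
# equivalent primal weights so the state stays small and serializable. The
# response is centered (and its mean restored at prediction) since the kernel
# machine itself has no intercept.
fit_kernel_ridge <- function(x, y, penalty = 1) {
  x <- as.matrix(x)
  yc <- y - mean(y)
  k <- tcrossprod(x)
  dual <- solve(k + diag(penalty, nrow(x)), yc)
  list(coef = drop(crossprod(x, dual)), intercept = mean(y))
}

# Elastic net at fixed penalty (lambda = 1, mixing 0.5), matching the
# common default configuration; backed by glmnet.
fit_elastic_net <- function(x, y, lambda = 1, mix = 0.5) {
  fit <- glmnet::glmnet(x, y, alpha = mix, lambda = lambda,
                        standardize = FALSE)
  cf <- as.numeric(stats::coef(fit))
  list(coef = cf[-1], intercept = cf[1])
}

# Least-squares gradient boosting with depth-1 trees (stumps). Deterministic:
# no row/column subsampling; ties in split gain resolved by the first
# (feature, threshold) in scan order.
fit_gb_stumps <- function(x, y, n_trees = 100L, learning_rate = 0.1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  ord <- lapply(seq_len(p), function(j) order(x[, j]))
  init <- mean(y)
  pred <- rep(init, n)
  stumps <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    r <- y - pred
    best <- list(gain = -Inf)
    for (j in seq_len(p)) {
      o <- ord[[j]]
      xs <- x[o, j]
      rs <- r[o]
      cs <- cumsum(rs)
      tot <- cs[n]
      k <- seq_len(n - 1L)
      valid <- xs[k] < xs[k + 1L]
      if (!any(valid)) next
      gain <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k) - tot^2 / n
      gain[!valid] <- -Inf
      kb <- which.max(gain)
      if (gain[kb] > best$gain) {
        best <- list(gain = gain[kb], feature = j,
                     threshold = (xs[kb] + xs[kb + 1L]) / 2,
                     left = cs[kb] / kb,
                     right = (tot - cs[kb]) / (n - kb))
      }
    }
    if (!is.finite(best$gain)) { stumps <- stumps[seq_len(t - 1L)]; break }
    stumps[[t]] <- c(feature = best$feature, threshold = best$threshold,
                     left = best$left, right = best$right)
    step <- ifelse(x[, best$feature] <= best$threshold, best$left, best$right)
    pred <- pred + learning_rate * step
  }
  stumps <- do.call(rbind, stumps)
  list(init = init, learning_rate = learning_rate,
       stumps = as.data.frame(stumps))
}

predict_gb_stumps <- function(state, x) {
  x <- as.matrix(x)
  pred <- rep(state$init, nrow(x))
  st <- state$stumps
  if (is.null(st) || nrow(st) == 0L) return(pred)
  for (i in seq_len(nrow(st))) {
    step <- ifelse(x[, st$feature[i]] <= st$threshold[i],
                   st$left[i], st$right[i])
    pred <- pred + state$learning_rate * step
  }
  pred
}
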