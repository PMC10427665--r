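# Feature selection, Bayesian ridge, regressor backends, metrics.

test_that("select_features ranks by |Pearson| with deterministic ties", {
  set.seed(21)
  ages <- runif(40, 29, 45)
  vals <- cbind(`SVR:perfect` = ages,
                `SVR:anti` = -ages + rnorm(40, sd = 0.1),
                `RV:noise1` = rnorm(40),
                `RV:const` = rep(0.5, 40))
  tab <- feature_table(sprintf("s%d", 1:40), rep("x", 40), ages, vals)
  sel <- select_features(tab, 2)
  expect_identical(sel[1], "SVR:perfect")
  expect_identical(sel[2], "SVR:anti")   # negative correlation qualifies
  # k >= n_features returns everything; constant feature ranks last
  expect_identical(select_features(tab, 10),
                   c("SVR:perfect", "SVR:anti", "RV:noise1", "RV:const"))
  # permutation invariance to row order
  perm <- sample.int(40)
  tab_p <- ft_rows(tab, perm)
  expect_identical(select_features(tab_p, 4), select_features(tab, 4))
  expect_error(select_features(tab, 0), "k must be")
})

test_that("bayes_ridge reproduces the reference implementation", {
  # Expected values frozen from scikit-learn's BayesianRidge (default
  # hyperpriors) run on this exact fixture.
  set.seed(42)
  n <- 60; p <- 5
  x <- matrix(rnorm(n * p), n, p)
  y <- 2 * x[, 1] - 1.5 * x[, 3] + 0.5 + rnorm(n, sd = 0.3)
  fit <- bayes_ridge(x, y)
  expect_equal(fit$coef,
               c(2.03061292, -0.01169227, -1.55260380, -0.00556682,
                 0.04796036),
               tolerance = 1e-6)
  expect_equal(fit$intercept, 0.47228163138783197, tolerance = 1e-6)
  expect_equal(fit$alpha, 17.580628202694335, tolerance = 1e-4)
  expect_equal(fit$lambda, 0.7642889436613602, tolerance = 1e-4)
  xnew <- matrix(seq(-1, 1, length.out = 10), 2, 5)
  expect_equal(predict(fit, xnew), c(-1.34387715, -1.23083040),
               tolerance = 1e-6)
})

test_that("noiseless identity feature is recovered to < 0.05 weeks", {
  ages <- seq(29, 45, length.out = 30)
  vals <- cbind(`SVR:identity` = ages,
                `RV:noise` = sin(seq_len(30)))
  tab <- feature_table(sprintf("s%d", 1:30), rep("x", 30), ages, vals)
  train <- ft_rows(tab, 1:20); held <- ft_rows(tab, 21:30)
  m <- fit_age_model(train, select_features(train, 1))
  expect_lt(max(abs(predict_age(m, held) - held$ages)), 0.05)
  expect_lt(max(abs(predict_age(m, train) - train$ages)), 0.05)
})

test_that("prediction aligns columns by name and tolerates zero rows", {
  tab <- toy_feature_table()
  m <- fit_age_model(tab, tab$feature_names)
  swapped <- tab$values[, rev(colnames(tab$values))]
  expect_equal(predict_age(m, swapped), predict_age(m, tab))
  zero_row <- matrix(0, 1, 2,
                     dimnames = list(NULL, colnames(tab$values)))
  expect_true(is.finite(predict_age(m, zero_row)))
  expect_error(predict_age(m, tab$values[, 1, drop = FALSE]), "missing feature")
})

test_that("every regressor kind fits and predicts through one interface", {
  sim <- simulate_feature_table(80, 10, informative = 1:3, seed = 5)
  train <- ft_rows(sim$table, 1:60); test <- ft_rows(sim$table, 61:80)
  sel <- select_features(train, 10)
  for (kind in c("bayesian_ridge", "kernel_ridge", "elastic_net",
                 "gradient_boosting")) {
    m <- fit_age_model(train, sel, kind, seed = 1)
    p <- predict_age(m, test)
    expect_length(p, 20)
    expect_true(all(is.finite(p)))
    # all backends must beat the cohort-mean predictor on planted signal
    expect_lt(mean(abs(p - test$ages)),
              mean(abs(mean(train$ages) - test$ages)))
    # refit determinism
    m2 <- fit_age_model(train, sel, kind, seed = 1)
    expect_identical(predict_age(m2, test), p)
  }
})

test_that("models serialize to JSON and reload prediction-stable", {
  sim <- simulate_feature_table(50, 8, informative = 1:2, seed = 9)
  train <- ft_rows(sim$table, 1:40); test <- ft_rows(sim$table, 41:50)
  for (kind in c("bayesian_ridge", "gradient_boosting")) {
    m <- fit_age_model(train, select_features(train, 5), kind, seed = 2)
    path <- withr::local_tempfile(fileext = ".json")
    save_age_model(m, path)
    m2 <- load_age_model(path)
    expect_equal(predict_age(m2, test), predict_age(m, test),
                 tolerance = 1e-12)
  }
})

test_that("evaluate implements the printed metric semantics", {
  truths <- c(30, 35, 40, 44)
  perfect <- evaluate(truths, truths)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$r2_cod, 1)

  # constant shift: squared-Pearson R2 stays 1 while MAE equals the shift,
  # which is exactly why the error-based CoD is reported alongside
  shifted <- evaluate(truths, truths + 1)
  expect_equal(shifted$mae, 1)
  expect_equal(shifted$rmse, 1)
  expect_equal(shifted$r2, 1)
  expect_lt(shifted$r2_cod, 1)

  hand <- evaluate(c(30, 40), c(31, 39))
  expect_equal(hand$mae, 1.0)
  expect_equal(hand$rmse, 1.0)

  expect_error(evaluate(1:3, 1:4), "mismatch")
  expect_error(evaluate(1, 1), "at least 2")
})

test_that("MAE <= RMSE for arbitrary prediction vectors", {
  set.seed(31)
  for (i in 1:20) {
    t <- runif(15, 29, 45)
    p <- t + rnorm(15, sd = runif(1, 0.1, 5))
    ev <- evaluate(t, p)
    expect_lte(ev$mae, ev$rmse + 1e-12)
    expect_true(ev$r2 >= 0 && ev$r2 <= 1)
  }
})

test_that("test MAE approaches the analytic noise floor as n grows", {
  floor_mae <- 0.5 * sqrt(2 / pi)
  maes <- sapply(c(50, 300), function(n) {
    sim <- simulate_feature_table(n, 20, informative = 1:5, noise_sd = 0.5,
                                  seed = 77)
    n_tr <- floor(0.75 * n)
    train <- ft_rows(sim$table, 1:n_tr)
    test <- ft_rows(sim$table, (n_tr + 1):n)
    m <- fit_age_model(train, select_features(train, 20))
    mean(abs(predict_age(m, test) - test$ages))
  })
  # with 5 informative features the multi-feature fit can beat the
  # univariate floor; it must at least come close at n = 50 and improve
  expect_lt(maes[2], maes[1])
  expect_lt(maes[2], floor_mae)
})
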