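# Permutation feature importance and rescaling.

make_pfi_fixture <- function(n = 120, seed = 3) {
  sim <- simulate_feature_table(n, 12, informative = 1:3, noise_sd = 0.5,
                                seed = seed)
  n_tr <- floor(0.75 * n)
  list(train = ft_rows(sim$table, 1:n_tr),
       test = ft_rows(sim$table, (n_tr + 1):n),
       table = sim$table)
}

test_that("an ignored feature has importance 0 and informative ones dominate", {
  fx <- make_pfi_fixture()
  sel <- select_features(fx$train, 6)
  m <- fit_age_model(fx$train, sel)
  imp <- permutation_importance(m, fx$test, repeats = 30, seed = 1)

  # the strongest importance must be an informative SVR feature
  top <- imp$feature[which.max(imp$raw_importance)]
  expect_true(top %in% paste0("SVR:", region_names(1:3)))

  # force a known-zero coefficient: a feature the model never saw
  m0 <- fit_age_model(fx$train, sel[1])
  imp0 <- permutation_importance(m0, fx$test, repeats = 30, seed = 1)
  expect_equal(nrow(imp0), 1L)

  # a pure-noise feature's importance is within 3 MC sds of 0
  noise_feats <- grep("SVR", imp$feature, value = TRUE, invert = FALSE)
  noise_feats <- setdiff(imp$feature, paste0("SVR:", region_names(1:3)))
  if (length(noise_feats)) {
    i <- match(noise_feats[1], imp$feature)
    expect_lt(abs(imp$raw_importance[i]),
              3 * max(imp$importance_sd[i], 1e-6))
  }
})

test_that("PFI is deterministic and sd shrinks with repeats", {
  fx <- make_pfi_fixture()
  m <- fit_age_model(fx$train, select_features(fx$train, 6))
  a <- permutation_importance(m, fx$test, repeats = 10, seed = 7)
  b <- permutation_importance(m, fx$test, repeats = 10, seed = 7)
  expect_identical(a, b)
  one <- permutation_importance(m, fx$test, repeats = 1, seed = 7)
  many <- permutation_importance(m, fx$test, repeats = 30, seed = 7)
  i_top <- which.max(many$raw_importance)
  expect_identical(sign(one$raw_importance[i_top]),
                   sign(many$raw_importance[i_top]))
  expect_identical(one$importance_sd, rep(0, nrow(one)))
})

test_that("rescale_importance divides by max, clips negatives, idempotent", {
  expect_equal(rescale_importance(c(0.2, 0.1, 0.05)), c(1.0, 0.5, 0.25))
  expect_equal(rescale_importance(c(-0.3, -0.1, 0)), c(0, 0, 0))
  expect_equal(rescale_importance(c(-0.1, 0.2)), c(0, 1))
  set.seed(13)
  for (i in 1:10) {
    raw <- rnorm(8)
    sc <- rescale_importance(raw)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_true(max(sc) %in% c(0, 1))
    # idempotent and ranking-preserving among non-negatives
    expect_equal(rescale_importance(sc), sc)
    pos <- raw >= 0
    expect_identical(order(sc[pos]), order(raw[pos]))
  }
})

test_that("family_importance recovers planted regions and is reproducible", {
  sim <- simulate_feature_table(150, 15, informative = 1:4, seed = 11)
  rep1 <- family_importance(sim$table, "RV", repeats = 15, seed = 2)
  rep2 <- family_importance(sim$table, "RV", repeats = 15, seed = 2)
  expect_identical(rep1, rep2)
  expect_equal(max(rep1$entries$scaled_importance), 1)
  expect_true(all(rep1$entries$family == "RV"))
  expect_equal(nrow(rep1$entries), 15L)

  top6 <- order(-rep1$entries$scaled_importance)[1:6]
  expect_gte(sum(top6 %in% 1:4), 3)

  svr_rep <- family_importance(sim$table, "SVR", repeats = 15, seed = 2)
  top_svr <- order(-svr_rep$entries$scaled_importance)[1:4]
  expect_gte(sum(top_svr %in% 1:4), 3)

  # family absent
  rv_only <- feature_table(sim$table$subjects$subject_id,
                           sim$table$subjects$session_id,
                           sim$table$ages,
                           sim$table$values[, 1:15],
                           sim$table$feature_names[1:15])
  expect_error(family_importance(rv_only, "SVR"), "absent")
})

test_that("duplicating an informative column dilutes its importance", {
  fx <- make_pfi_fixture(n = 150, seed = 19)
  best <- select_features(fx$train, 1)
  single <- fit_age_model(fx$train, c(best, "RV:Hippocampus left"))
  imp_single <- permutation_importance(single, fx$test, repeats = 20, seed = 4)

  dup_vals <- cbind(fx$table$values, `SVR:dup` = fx$table$values[, best])
  dup_tab <- feature_table(fx$table$subjects$subject_id,
                           fx$table$subjects$session_id,
                           fx$table$ages, dup_vals)
  n_tr <- nrow(fx$train$values)
  dup_train <- ft_rows(dup_tab, 1:n_tr)
  dup_test <- ft_rows(dup_tab, (n_tr + 1):nrow(dup_tab$values))
  dup_m <- fit_age_model(dup_train, c(best, "SVR:dup", "RV:Hippocampus left"))
  imp_dup <- permutation_importance(dup_m, dup_test, repeats = 20, seed = 4)

  expect_lt(imp_dup$raw_importance[imp_dup$feature == best],
            imp_single$raw_importance[imp_single$feature == best])
})

test_that("importance reports round-trip through JSON and CSV", {
  sim <- simulate_feature_table(60, 8, informative = 1:2, seed = 23)
  rep <- family_importance(sim$table, "SVR", repeats = 5, seed = 3)
  jp <- withr::local_tempfile(fileext = ".json")
  save_importance_report(rep, jp)
  back <- load_importance_report(jp)
  expect_equal(back$entries$raw_importance, rep$entries$raw_importance,
               tolerance = 1e-12)
  expect_equal(back$repeats, rep$repeats)
  cp <- withr::local_tempfile(fileext = ".csv")
  write_importance_csv(rep, cp)
  expect_equal(nrow(read.csv(cp)), nrow(rep$entries))
})
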