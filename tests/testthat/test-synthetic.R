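# Phantom and tabular generators: determinism, invariants, planted trends.

small_spec <- function(age, n_regions = 12L, grid = c(28, 28, 28), ...) {
  phantom_spec(grid_shape = grid, n_regions = n_regions, age_weeks = age, ...)
}

test_that("phantoms satisfy label-volume invariants and are deterministic", {
  sp <- small_spec(40)
  v1 <- generate_phantom(sp)
  v2 <- generate_phantom(sp)
  expect_identical(v1$voxels, v2$voxels)
  expect_identical(v1$region_ids, 1:12)
  expect_true(all(v1$voxels >= 0L))
  # every region non-empty
  expect_true(all(tabulate(v1$voxels[v1$voxels > 0], 12) > 0))
  # a hopeless grid errors
  expect_error(generate_phantom(phantom_spec(c(8, 8, 8), 87)), "too small")
})

test_that("RV shares follow the softmax growth trend across ages", {
  ages <- c(29, 37, 45)
  rv <- sapply(ages, function(a) {
    extract_features(generate_phantom(small_spec(a)), 1:12)$rv
  })
  g <- default_growth <- small_spec(29)$growth_coefs
  # region 1 grows (+0.05/week), region 2 shrinks (-0.05/week)
  expect_true(all(diff(rv[1, ]) > 0))
  expect_true(all(diff(rv[2, ]) < 0))
  # shares approximately match the softmax target at each age
  for (i in seq_along(ages)) {
    z <- g * (ages[i] - 37)
    target <- exp(z) / sum(exp(z))
    expect_lt(max(abs(rv[, i] - target)), 0.02)
  }
})

test_that("fold coefficients raise SVR with age while shares stay planted", {
  f29 <- extract_features(generate_phantom(small_spec(29, 16)), 1:16)
  f45 <- extract_features(generate_phantom(small_spec(45, 16)), 1:16)
  fold <- small_spec(29, 16)$fold_coefs
  for (r in which(fold > 0)) {
    expect_gt(f45$svr[r], f29$svr[r])
  }
  # with all folds off and flat growth, SVR is age-stable (< 2% relative)
  flat29 <- small_spec(29, 12, growth_coefs = rep(0, 12),
                       fold_coefs = rep(0, 12))
  flat45 <- small_spec(45, 12, growth_coefs = rep(0, 12),
                       fold_coefs = rep(0, 12))
  s29 <- extract_features(generate_phantom(flat29), 1:12)$svr
  s45 <- extract_features(generate_phantom(flat45), 1:12)$svr
  expect_lt(max(abs(s45 / s29 - 1)), 0.02)
})

test_that("boundary noise flips only boundary voxels and respects the seed", {
  sp <- small_spec(38, noise_sd = 0.2, seed = 5)
  clean <- generate_phantom(small_spec(38))
  noisy <- generate_phantom(sp)
  changed <- which(noisy$voxels != clean$voxels)
  expect_gt(length(changed), 0)
  # flipped voxels were on a structure boundary in the clean volume
  sm <- neobrainage:::surface_mask(clean$voxels, 6)
  expect_true(all(sm[changed]))
  expect_identical(generate_phantom(sp)$voxels, noisy$voxels)
})

test_that("generate_cohort writes volumes + manifest and plants RV trends", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(8, template = small_spec(40), seed = 31, dir = dir)
  expect_equal(nrow(coh$manifest), 8L)
  expect_true(all(file.exists(coh$manifest$volume_path)))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(all(coh$manifest$pma_weeks >= 29 & coh$manifest$pma_weeks <= 45))
  expect_identical(coh$truth$ages, coh$manifest$pma_weeks)
  expect_true(length(coh$truth$informative_regions) > 0)

  # same seed reproduces the manifest exactly
  coh2 <- generate_cohort(8, template = small_spec(40), seed = 31,
                          dir = withr::local_tempdir())
  expect_equal(coh2$manifest$pma_weeks, coh$manifest$pma_weeks)

  # planted RV-age correlation signs for the strongest growth regions
  feats <- lapply(coh$manifest$volume_path, function(p) {
    extract_features(read_label_volume(p), 1:12)
  })
  tab <- neobrainage:::features_to_table(coh$manifest, feats)
  g <- small_spec(40)$growth_coefs
  top5 <- order(-abs(g))[1:5]
  for (r in top5) {
    rho <- cor(tab$values[, paste0("RV:", region_names(r))], tab$ages)
    expect_identical(sign(rho), sign(g[r]))
  }
})

test_that("simulate_feature_table satisfies its stated contracts", {
  sim <- simulate_feature_table(40, 10, informative = 1:3, noise_sd = 0.5,
                                seed = 17)
  rv <- sim$table$values[, 1:10]
  expect_equal(unname(rowSums(rv)), rep(1, 40), tolerance = 1e-12)
  expect_equal(sim$truth$noise_floor_mae, 0.5 * sqrt(2 / pi))
  expect_equal(ncol(sim$table$values), 20L)
  # determinism
  sim2 <- simulate_feature_table(40, 10, informative = 1:3, noise_sd = 0.5,
                                 seed = 17)
  expect_identical(sim2$table$values, sim$table$values)
  expect_error(simulate_feature_table(10, 5, informative = 1:9), "1..n_regions")
})

test_that("noiseless single-feature cohort is recovered to < 0.05 weeks", {
  sim <- simulate_feature_table(60, 8, informative = 1L, noise_sd = 0,
                                seed = 29)
  train <- ft_rows(sim$table, 1:45); test <- ft_rows(sim$table, 46:60)
  sel <- select_features(train, 1)
  expect_identical(sel, paste0("SVR:", region_names(1)))
  m <- fit_age_model(train, sel)
  expect_lt(mean(abs(predict_age(m, test) - test$ages)), 0.05)
})
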