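test_that("Ki converts to free energy via RT ln(Ki)", {
  expect_equal(ki_to_dg(1), 0)
  expect_equal(ki_to_dg(1e-9), -12.279, tolerance = 1e-3)
  expect_equal(ki_to_dg(1e-6), ki_to_dg(1e-9) * 2 / 3, tolerance = 1e-12)
  expect_equal(ki_to_dg(1e-3, temperature = 310),
               0.0019872 * 310 * log(1e-3), tolerance = 1e-12)
  expect_error(ki_to_dg(0), "positive")
  expect_error(ki_to_dg(-1), "positive")
})

test_that("training tables validate their contract", {
  tt <- make_training_table(20, seed = 1)$table
  expect_s3_class(tt, "training_table")
  expect_equal(length(feature_names(tt)), 11L)
  dup <- as.data.frame(tt)
  dup$complex_id[2] <- dup$complex_id[1]
  expect_error(training_table(dup), "unique")
  bad <- as.data.frame(tt)
  bad$dg[1] <- NA
  expect_error(training_table(bad), "finite")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_training_table(tt, f)
  expect_equal(as.data.frame(read_training_table(f)), as.data.frame(tt),
               tolerance = 1e-12)
})

test_that("noise-free tables are fitted exactly", {
  gen <- make_training_table(60, noise_sd = 0, seed = 2)
  fit <- suppressWarnings(  # stats flags the deliberately perfect fit
    fit_affinity(gen$table, features = gen$true_model$feature_order))
  expect_equal(unname(fit$coefficients[gen$true_model$feature_order]),
               unname(gen$true_model$coefficients), tolerance = 1e-8)
  expect_equal(fit$intercept, gen$true_model$intercept, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-10)
})

test_that("two points determine an exact single-feature line", {
  df <- data.frame(complex_id = c("a", "b"), f = c(1, 3), dg = c(2, 8))
  fit <- suppressWarnings(fit_affinity(training_table(df), features = "f"))
  expect_equal(unname(fit$coefficients), 3)
  expect_equal(fit$intercept, -1)
})

test_that("collinear designs are rejected with the feature named", {
  gen <- make_training_table(50, seed = 3)
  df <- as.data.frame(gen$table)
  df$ac_dup <- df$ac_cc
  expect_error(fit_affinity(training_table(df)), "ac_dup")
})

test_that("the recorded AIC follows the n ln(RSS/n) + 2(p+1) convention", {
  gen <- make_training_table(80, seed = 4)
  fit <- fit_affinity(gen$table, features = c("e_elec", "ac_cc"))
  n <- nrow(gen$table)
  expect_equal(fit$aic, n * log(fit$rss / n) + 2 * 3, tolerance = 1e-10)
  # and matches R's stepwise extractAIC scale
  expect_equal(fit$aic, unname(stats::extractAIC(fit$fit)[2]), tolerance = 1e-8)
})

test_that("stepwise selection keeps the true features and lowers AIC monotonically", {
  gen <- make_training_table(200, noise_sd = 1.5, seed = 11)
  sel <- aic_stepwise(gen$table)
  expect_true(all(gen$true_model$feature_order %in% sel$feature_order))
  aics <- sel$anova$AIC
  expect_true(all(diff(aics) <= 1e-8))
  # deterministic given the table
  sel2 <- aic_stepwise(gen$table)
  expect_identical(sel$feature_order, sel2$feature_order)
})

test_that("a single perfectly predictive feature is selected alone", {
  set.seed(5)
  df <- data.frame(complex_id = sprintf("c%02d", 1:40),
                   good = rnorm(40), junk1 = rnorm(40), junk2 = rnorm(40))
  df$dg <- 2 * df$good + 1
  sel <- suppressWarnings(  # noiseless target makes the selection exact
    aic_stepwise(training_table(df)))
  expect_identical(sel$feature_order, "good")
  expect_equal(unname(sel$coefficients), 2, tolerance = 1e-8)
})

test_that("pure-noise targets yield small selected models with no signal", {
  # AIC admits each irrelevant feature with modest probability, so the
  # selected set should be far smaller than the candidate set and explain
  # almost nothing
  gen <- make_training_table(200, noise_sd = 1.5, seed = 17)
  df <- as.data.frame(gen$table)
  df$dg <- with_seed_rnorm(17, nrow(df), sd = 1.5)
  tt <- training_table(df)
  sel <- aic_stepwise(tt)
  expect_lt(length(sel$feature_order), length(feature_names(tt)))
  r2 <- 1 - sel$rss / sum((tt$dg - mean(tt$dg))^2)
  expect_lt(r2, 0.15)
})

test_that("cross-validation is deterministic, partitions rows, and scores a perfect model perfectly", {
  gen <- make_training_table(60, noise_sd = 0, seed = 6)
  cv <- suppressWarnings(
    cross_validate(gen$table, k = 4, repeats = 2, seed = 9, method = "ols"))
  cv2 <- suppressWarnings(
    cross_validate(gen$table, k = 4, repeats = 2, seed = 9, method = "ols"))
  expect_identical(cv$per_repeat, cv2$per_repeat)
  expect_equal(cv$means[["pearson_r"]], 1, tolerance = 1e-6)
  expect_lt(cv$means[["rmse"]], 1e-6)
  for (folds in cv$folds) {
    expect_equal(length(folds), 60L)
    expect_true(all(folds %in% 1:4))
    expect_true(all(table(folds) >= 1))
  }
  expect_error(cross_validate(gen$table, k = 61), "exceeds")
})

test_that("permuted targets show no held-out correlation", {
  gen <- make_training_table(200, noise_sd = 1.5, seed = 7)
  df <- as.data.frame(gen$table)
  df$dg <- df$dg[with_seed_perm(123, nrow(df))]
  cv <- cross_validate(training_table(df), k = 4, repeats = 10, seed = 3,
                       method = "ols")
  expect_lt(abs(cv$means[["pearson_r"]]), 0.2)
})

test_that("fitted coefficients cover the truth within three standard errors", {
  hits <- 0L
  for (seed in 1:20) {
    gen <- make_training_table(200, noise_sd = 1.5, seed = seed)
    fit <- fit_affinity(gen$table, features = gen$true_model$feature_order)
    truth <- c(gen$true_model$intercept, gen$true_model$coefficients)
    est <- c(fit$intercept, fit$coefficients)
    se <- fit$se[c("(Intercept)", gen$true_model$feature_order)]
    if (all(abs(est - truth) <= 3 * se)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
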