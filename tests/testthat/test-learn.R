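# Learning harness: splitting, MAE, selection, tuning, evaluation,
# double CV, learning curves, permutation importance.

small_table <- function(n = 120, seed = 7, sigma = 0.3, nf = 6L,
                        active = 1L, coefs = 2) {
  ft <- generate_feature_table(n, n_features = nf, active = active,
                               coefs = coefs, sigma = sigma, seed = seed)
  ft <- split_table(ft, 0.2, seed = seed)
  standardize(prune(ft), "train")
}

test_that("split is reproducible, exhaustive, and literature-safe", {
  ft <- generate_feature_table(1000, seed = 1)
  ft$split[1:40] <- "literature"
  s1 <- split_table(ft, 0.2, seed = 9)
  s2 <- split_table(ft, 0.2, seed = 9)
  expect_identical(s1$split, s2$split)
  expect_equal(sum(s1$split == "train"), 768)   # 80% of 960
  expect_equal(sum(s1$split == "test"), 192)
  expect_true(all(s1$split[1:40] == "literature"))
  # the canonical 1000-reaction, 80/20 case
  ft2 <- generate_feature_table(1000, seed = 2)
  s3 <- split_table(ft2, 0.2, seed = 3)
  expect_equal(sum(s3$split == "train"), 800)
  expect_equal(sum(s3$split == "test"), 200)
  expect_error(split_table(ft2, 1.2, 1), "test_fraction")
  expect_error(split_table(generate_feature_table(5, seed = 1), 0.5, 1),
               "fewer than 5")
})

test_that("mae_se matches hand values and the half-normal identity", {
  expect_equal(mae_se(c(1, 2), c(1, 2)), list(mae = 0, se = 0, n = 2L))
  m <- mae_se(c(1, 3), c(0, 0))
  expect_equal(m$mae, 2)
  expect_equal(m$se, 1)    # sd({1,3})/sqrt(2) = sqrt(2)/sqrt(2)
  expect_error(mae_se(1:3, 1:2), "length mismatch")
  # E|N(0, s)| = s sqrt(2/pi)
  set.seed(4)
  s <- 0.7
  err <- stats::rnorm(1e4, 0, s)
  m2 <- mae_se(err, rep(0, 1e4))
  expect_lt(abs(m2$mae - s * sqrt(2 / pi)), 3 * m2$se)
})

test_that("forward selection finds the planted signal first", {
  hits <- 0L
  for (seed in 1:50) {
    ft <- generate_feature_table(80, n_features = 10, active = 3L,
                                 coefs = 2, sigma = 0.4, seed = seed)
    ft <- split_table(ft, 0.2, seed = seed)
    ft <- standardize(prune(ft), "train")
    spec <- model_spec("ridge", grid = data.frame(alpha = 1e-2),
                       mode = "delta", seed = seed)
    rows <- which(ft$split == "train")
    x <- ft$x[rows, , drop = FALSE]
    y <- ft$y[rows] - ft$baseline[rows]
    # first SFS pick = single best feature by CV; recompute directly
    first <- names(which.min(vapply(colnames(x), function(f) {
      deltabarrier:::.cv_mae(x[, f, drop = FALSE], y, spec,
                             list(alpha = 1e-2), 4L, seed)
    }, 0)))
    if (first == "f03") hits <- hits + 1L
  }
  expect_gte(hits, 40L)   # 50-seed majority, planted f03

  # full SFS returns a subset containing the causal feature
  ft <- small_table(seed = 3, nf = 8L, active = 2L)
  sel <- select_features(ft, model_spec("ridge",
                                        grid = data.frame(alpha = 1e-2),
                                        mode = "delta", seed = 3),
                         k_folds = 4)
  expect_true("f02" %in% sel)

  # tol = Inf stops after the first feature
  sel1 <- select_features(ft, model_spec("ridge",
                                         grid = data.frame(alpha = 1e-2),
                                         mode = "delta", seed = 3),
                          k_folds = 4, tol = Inf, patience = 1)
  expect_length(sel1, 1L)
})

test_that("selection and tuning never touch held-out rows", {
  ft <- small_table(seed = 5)
  locked <- ft_lock(ft, allow = "train")
  spec <- model_spec("ridge", grid = data.frame(alpha = 1e-2),
                     mode = "delta", seed = 5)
  expect_silent(select_features(locked, spec, k_folds = 3, tol = Inf,
                                patience = 1))
  expect_silent(fit <- tune_and_fit(locked, spec = spec, k_folds = 3))
  # but touching test rows through the guard raises
  expect_error(deltabarrier:::.ft_rows(locked,
                                       which(ft$split == "test")),
               "access guard")
  # and evaluation works because it unlocks explicitly
  expect_silent(evaluate_model(fit, locked, sets = "test"))
})

test_that("delta mode with a perfect baseline is exact; units agree", {
  ft <- generate_feature_table(100, n_features = 4, active = 1L,
                               coefs = 0, sigma = 0, seed = 8)
  # target == baseline exactly (coefs and sigma zero)
  ft <- split_table(ft, 0.2, seed = 8)
  ft <- standardize(prune(ft), "train")
  spec <- model_spec("ridge", grid = data.frame(alpha = 1e-8),
                     mode = "delta", seed = 8)
  fit <- tune_and_fit(ft, spec = spec)
  ev <- evaluate_model(fit, ft, sets = "test")
  expect_lt(ev$test$mae, 1e-6)

  # direct and delta predictions are both on the original scale:
  # noiseless linear world, both recover the target to high accuracy
  ft2 <- generate_feature_table(200, n_features = 4, active = 2L,
                                coefs = 1.5, sigma = 0, seed = 9)
  ft2 <- split_table(ft2, 0.2, seed = 9)
  ft2 <- standardize(prune(ft2), "train")
  for (mode in c("direct", "delta")) {
    sp <- model_spec("ridge", grid = data.frame(alpha = 1e-8), mode = mode,
                     seed = 9)
    f <- tune_and_fit(ft2, spec = sp)
    expect_lt(evaluate_model(f, ft2, sets = "test")$test$mae, 1e-6)
  }
})

test_that("every model family trains and evaluates", {
  ft <- small_table(n = 90, seed = 12, nf = 5L)
  grids <- list(
    ridge = data.frame(alpha = c(1e-3, 1)),
    nnr = data.frame(k = c(3, 7)),
    rfr = data.frame(n_trees = 40, max_depth = Inf),
    gbr = data.frame(n_trees = 60, max_depth = 3, learning_rate = 0.1),
    svr = data.frame(C = 10, epsilon = 0.1, gamma = NA),
    krr = data.frame(alpha = c(1e-3, 1e-1), gamma = NA),
    gpr = data.frame(nu = 2.5))
  for (fam in names(grids)) {
    spec <- model_spec(fam, grid = grids[[fam]], mode = "delta", seed = 12)
    fit <- tune_and_fit(ft, spec = spec, k_folds = 3)
    ev <- evaluate_model(fit, ft, sets = "test")
    expect_true(is.finite(ev$test$mae), info = fam)
    expect_lt(ev$test$mae, 3, label = paste(fam, "test MAE"))
  }
  # kernel families require a kernel; polynomial KRR also runs
  expect_error(model_spec("gpr", kernel = "rbf"), "Matern")
  spec_poly <- model_spec("krr", kernel = "poly",
                          grid = data.frame(alpha = 1e-2, degree = 2),
                          mode = "delta", seed = 12)
  expect_true(is.finite(
    evaluate_model(tune_and_fit(ft, spec = spec_poly, k_folds = 3),
                   ft, sets = "test")$test$mae))
})

test_that("evaluation reports errors, outliers, and skips empty sets", {
  ft <- small_table(seed = 20)
  spec <- model_spec("ridge", grid = data.frame(alpha = 1e-2),
                     mode = "delta", seed = 20)
  fit <- tune_and_fit(ft, spec = spec)
  expect_warning(ev <- evaluate_model(fit, ft,
                                      sets = c("test", "literature")),
                 "empty")
  expect_null(ev$literature)
  expect_named(ev$test$errors)
  expect_equal(ev$test$n, sum(ft$split == "test"))
  # outlier rule: plant one absurd target
  ft2 <- ft
  bad_row <- which(ft2$split == "test")[1]
  ft2$y[bad_row] <- ft2$y[bad_row] + 50
  ev2 <- evaluate_model(fit, ft2, sets = "test")
  expect_equal(ev2$test$outliers, rownames(ft2$x)[bad_row])
  # constant predictor: MAE equals the mean absolute deviation
  y <- ft$y[ft$split == "test"]
  expect_equal(mae_se(rep(mean(y), length(y)), y)$mae,
               mean(abs(y - mean(y))), tolerance = 1e-12)
})

test_that("double CV aggregates across splits and stabilizes with n", {
  ft <- generate_feature_table(240, n_features = 5, active = 1L,
                               coefs = 1.5, sigma = 0.4, seed = 2)
  ft <- standardize(prune(split_table(ft, 0.2, 2), stats_from = "train"),
                    "train")
  spec <- model_spec("ridge", grid = data.frame(alpha = 1e-2),
                     mode = "delta", seed = 2)
  dc <- suppressWarnings(double_cv(ft, spec, n_extra_splits = 5))
  expect_length(dc$reports, 6L)
  expect_equal(dc$aggregate$test_mae,
               mean(vapply(dc$reports, function(r) r$test$mae, 0)),
               tolerance = 1e-12)
  # split-to-split scatter shrinks with more data
  sd_small <- sd(vapply(dc$reports, function(r) r$test$mae, 0))
  ft_big <- generate_feature_table(900, n_features = 5, active = 1L,
                                   coefs = 1.5, sigma = 0.4, seed = 2)
  ft_big <- standardize(prune(split_table(ft_big, 0.2, 2)),
                        "train")
  dc_big <- suppressWarnings(double_cv(ft_big, spec, n_extra_splits = 5))
  sd_big <- sd(vapply(dc_big$reports, function(r) r$test$mae, 0))
  expect_lt(sd_big, sd_small)
})

test_that("learning curves behave and agree with tuning at full size", {
  ft <- generate_feature_table(400, n_features = 6, active = 2L,
                               coefs = 1.5, sigma = 0.4, seed = 6)
  ft <- standardize(prune(split_table(ft, 0.2, 6)), "train")
  spec <- model_spec("ridge", grid = data.frame(alpha = 1e-2),
                     mode = "delta", seed = 6)
  n_train <- sum(ft$split == "train")
  lc <- learning_curve(ft, spec, train_sizes = c(40, 120, n_train),
                       k_folds = 5)
  expect_equal(nrow(lc), 3L)
  # more data helps, and the train score is optimistic vs CV
  expect_gt(lc$cv_mae[1], lc$cv_mae[3])
  expect_true(all(lc$train_mae <= lc$cv_mae + 1e-9))
  # at full size the CV point matches tune_and_fit's CV MAE
  fit <- tune_and_fit(ft, spec = spec, k_folds = 5)
  expect_equal(lc$cv_mae[3], fit$cv_mae, tolerance = 1e-10)
  expect_error(learning_curve(ft, spec, train_sizes = n_train + 1),
               "exceed")
})

test_that("permutation importance: zero-coefficient feature, recovery,
           reproducibility", {
  ft <- small_table(n = 150, seed = 14, nf = 6L, active = 2L)
  spec <- model_spec("ridge", grid = data.frame(alpha = 1e-2),
                     mode = "delta", seed = 14)
  fit <- tune_and_fit(ft, spec = spec)
  # force a zero coefficient: shuffling that feature changes nothing
  fit0 <- fit
  fit0$model$fit$beta["f05"] <- 0
  imp0 <- permutation_importance(fit0, ft, set = "test", seed = 1)
  expect_equal(unname(imp0["f05"]), 0)
  # the causal feature tops the ranking
  imp <- permutation_importance(fit, ft, set = "test", seed = 1)
  expect_equal(names(imp)[1], "f02")
  # reproducible under a fixed seed
  expect_identical(imp, permutation_importance(fit, ft, set = "test",
                                               seed = 1))
})

test_that("delta beats direct when the baseline is informative", {
  wins <- 0L
  for (seed in 1:10) {
    ft <- generate_feature_table(220, n_features = 8, active = 2L,
                                 coefs = 1.5, sigma = 0.5, seed = seed)
    ft <- standardize(prune(split_table(ft, 0.2, seed)), "train")
    maes <- vapply(c("delta", "direct"), function(mode) {
      spec <- model_spec("krr", grid = data.frame(alpha = 1e-2, gamma = NA),
                         mode = mode, seed = seed)
      evaluate_model(tune_and_fit(ft, spec = spec, k_folds = 3), ft,
                     sets = "test")$test$mae
    }, 0)
    if (maes["delta"] <= maes["direct"]) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("pipeline reports are reproducible from (table, spec, seed)", {
  ft <- small_table(seed = 22)
  spec <- model_spec("ridge", grid = data.frame(alpha = 1e-2),
                     mode = "delta", seed = 22)
  r1 <- suppressWarnings(run_pipeline(ft, spec, seed = 22,
                                      importance = TRUE))
  r2 <- suppressWarnings(run_pipeline(ft, spec, seed = 22,
                                      importance = TRUE))
  expect_identical(report_json(r1), report_json(r2))
  expect_s3_class(r1, "eval_report")
})
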