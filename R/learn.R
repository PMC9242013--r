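# Training and evaluation harness. The workflow mirrors the standard
# barrier-ML protocol: random 80/20 train/test split (literature rows
# held out entirely), greedy sequential forward feature selection and
# grid-search hyperparameter tuning by k-fold CV inside the train split,
# external evaluation on test and literature sets with MAE +/- SE,
# double CV over extra splits, learning curves, and permutation feature
# importances. Delta mode fits target - baseline (the SQM barrier) and
# adds the baseline back at prediction time.

#' Mean absolute error with standard error
#'
#' SE is the sample standard deviation of the absolute errors divided
#' by sqrt(n), making scores comparable across sample sizes.
#'
#' @param pred,truth equal-length numeric vectors
#' @return list with `mae`, `se`, `n`
#' @export
mae_se <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (!length(pred)) stop("empty vectors")
  ae <- abs(pred - truth)
  list(mae = mean(ae),
       se = if (length(ae) > 1) stats::sd(ae) / sqrt(length(ae)) else 0,
       n = length(ae))
}

#' Random train/test split of a feature table
#'
#' Splits the non-literature rows into disjoint, exhaustive train and
#' test sets, reproducibly under `seed`. Rows tagged `"literature"`
#' keep their tag and never enter either split.
#'
#' @param table a [feature_table()]
#' @param test_fraction fraction of splittable rows assigned to test
#' @param seed integer seed
#' @return the table with its `split` tags updated
#' @export
split_table <- function(table, test_fraction = 0.2, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  pool <- which(table$split != "literature")
  n_test <- round(length(pool) * test_fraction)
  set.seed(seed)
  test_rows <- sample(pool, n_test)
  table$split[pool] <- "train"
  table$split[test_rows] <- "test"
  if (sum(table$split == "train") < 5L) stop("fewer than 5 train rows")
  table
}

# deterministic k-fold assignment
.cv_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

# training target under the spec's mode
.train_target <- function(table, rows, mode) {
  y <- table$y[rows]
  if (anyNA(y)) stop("target missing for some training rows")
  if (mode == "delta") {
    if (is.null(table$baseline)) {
      stop("delta mode needs a baseline (assemble with subset 'All')")
    }
    y <- y - table$baseline[rows]
  }
  y
}

# fold-CV MAE of one hyperparameter setting on (x, y)
.cv_mae <- function(x, y, spec, params, k_folds, seed) {
  folds <- .cv_folds(length(y), k_folds, seed)
  errs <- numeric(0)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    if (sum(tr) < 2 || sum(!tr) < 1) next
    m <- fit_model(x[tr, , drop = FALSE], y[tr], spec, params)
    errs <- c(errs, abs(predict(m, x[!tr, , drop = FALSE]) - y[!tr]))
  }
  mean(errs)
}

#' Greedy sequential forward feature selection
#'
#' Starting from the empty set, repeatedly adds the feature whose
#' addition gives the lowest k-fold CV MAE inside the train rows;
#' stops when the best addition has failed to improve the running best
#' CV MAE by at least `tol` for `patience` consecutive steps, and
#' returns the best prefix. Selection fits use the first row of the
#' spec's grid (tuning happens afterwards on the selected set).
#'
#' @param table a [feature_table()] (locked or not; only train rows are
#'   read)
#' @param spec a [model_spec()]
#' @param k_folds CV folds (default 5)
#' @param tol minimum CV-MAE improvement, kcal/mol (default 0.01)
#' @param patience non-improving steps tolerated (default 3)
#' @param max_features optional cap on the subset size
#' @return character vector of selected feature names
#' @export
select_features <- function(table, spec, k_folds = 5L, tol = 0.01,
                            patience = 3L, max_features = Inf) {
  rows <- .ft_rows(table, .split_rows(table, "train"))
  x <- table$x[rows, , drop = FALSE]
  y <- .train_target(table, rows, spec$mode)
  params <- as.list(spec$grid[1, , drop = FALSE])
  all_feats <- colnames(x)
  selected <- character(0)
  best_score <- Inf; best_prefix <- character(0)
  stall <- 0L
  while (length(selected) < min(length(all_feats), max_features)) {
    remaining <- setdiff(all_feats, selected)
    scores <- vapply(remaining, function(f) {
      .cv_mae(x[, c(selected, f), drop = FALSE], y, spec, params,
              k_folds, spec$seed)
    }, 0)
    f_best <- remaining[which.min(scores)]
    s_best <- min(scores)
    selected <- c(selected, f_best)
    improved <- !is.finite(best_score) || s_best < best_score - tol
    if (improved) {
      best_score <- s_best
      best_prefix <- selected
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  if (!length(best_prefix)) best_prefix <- selected[1]
  best_prefix
}

#' Grid-search tuning and final fit on the train split
#'
#' Every grid row is scored by k-fold CV MAE inside the train rows and
#' the best setting refit on the full train split. For GPR, length
#' scale and noise are optimized by marginal likelihood on the full
#' train set per Matern nu (the grid), nu is chosen by marginal
#' likelihood, and the reported CV MAE refits the GP per fold at the
#' chosen kernel.
#'
#' In delta mode the fit target is `y - baseline`; [predict_barriers()]
#' adds the baseline back so predictions are always on the original
#' kcal/mol scale.
#'
#' @param table a [feature_table()]
#' @param features feature names to use (default: all columns)
#' @param spec a [model_spec()]
#' @param k_folds CV folds (default 5)
#' @return object of class `db_fit`: list with `model`, `features`,
#'   `params`, `cv_mae`, `spec`
#' @export
tune_and_fit <- function(table, features = NULL, spec, k_folds = 5L) {
  rows <- .ft_rows(table, .split_rows(table, "train"))
  if (is.null(features)) features <- colnames(table$x)
  if (!length(features)) stop("features must be non-empty")
  x <- table$x[rows, features, drop = FALSE]
  y <- .train_target(table, rows, spec$mode)
  if (spec$family == "gpr") {
    fits <- lapply(seq_len(nrow(spec$grid)), function(i) {
      fit_model(x, y, spec, as.list(spec$grid[i, , drop = FALSE]))
    })
    nlls <- vapply(fits, function(m) m$fit$nll, 0)
    best_i <- which.min(nlls)
    model <- fits[[best_i]]
    params <- as.list(spec$grid[best_i, , drop = FALSE])
    # fold-CV at the chosen kernel hyperparameters
    kp <- model$fit$kp; sf <- model$fit$sf
    folds <- .cv_folds(length(y), k_folds, spec$seed)
    errs <- numeric(0)
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      Xt <- x[tr, , drop = FALSE]
      yc <- y[tr] - mean(y[tr])
      K <- sf^2 * .kernel_matrix(Xt, Xt, "matern", kp) +
        (model$fit$sn^2 + 1e-10) * diag(nrow(Xt))
      alpha <- solve(K, yc)
      Ks <- sf^2 * .kernel_matrix(x[!tr, , drop = FALSE], Xt, "matern", kp)
      pr <- drop(Ks %*% alpha) + mean(y[tr])
      errs <- c(errs, abs(pr - y[!tr]))
    }
    cv <- mean(errs)
  } else {
    scores <- vapply(seq_len(nrow(spec$grid)), function(i) {
      .cv_mae(x, y, spec, as.list(spec$grid[i, , drop = FALSE]),
              k_folds, spec$seed)
    }, 0)
    if (all(is.na(scores))) stop("grid exhausted with all-NaN CV scores")
    best_i <- which.min(scores)
    params <- as.list(spec$grid[best_i, , drop = FALSE])
    model <- fit_model(x, y, spec, params)
    cv <- scores[best_i]
  }
  structure(list(model = model, features = features, params = params,
                 cv_mae = cv, spec = spec),
            class = "db_fit")
}

#' Predict barriers (original units) for selected rows
#'
#' @param fit a `db_fit` from [tune_and_fit()]
#' @param table the feature table the fit belongs to
#' @param rows integer row indices
#' @return numeric predictions, kcal/mol
#' @export
predict_barriers <- function(fit, table, rows) {
  p <- predict(fit$model, table$x[rows, fit$features, drop = FALSE])
  if (fit$spec$mode == "delta") p <- p + table$baseline[rows]
  p
}

#' Evaluate a fitted model on the held-out sets
#'
#' MAE +/- SE per evaluation set, per-reaction absolute errors, and an
#' outlier flag for reactions with `|error| > mean + 3 sd` within their
#' set. Empty sets are skipped with a warning.
#'
#' @param fit a `db_fit`
#' @param table the (possibly locked) feature table; evaluation unlocks
#' @param sets split tags to evaluate (default test + literature)
#' @return named list per set: `mae`, `se`, `n`, `errors` (named),
#'   `outliers`
#' @export
evaluate_model <- function(fit, table, sets = c("test", "literature")) {
  table <- ft_unlock(table)
  out <- list()
  for (s in sets) {
    rows <- .split_rows(table, s)
    rows <- rows[!is.na(table$y[rows])]
    if (!length(rows)) {
      warning("evaluation set '", s, "' is empty; skipped", call. = FALSE)
      next
    }
    pred <- predict_barriers(fit, table, rows)
    m <- mae_se(pred, table$y[rows])
    ae <- abs(pred - table$y[rows])
    names(ae) <- rownames(table$x)[rows]
    thr <- mean(ae) + 3 * stats::sd(ae)
    out[[s]] <- list(mae = m$mae, se = m$se, n = m$n, errors = ae,
                     outliers = names(ae)[is.finite(thr) & ae > thr])
  }
  out
}

#' Permutation feature importance
#'
#' Importance of a feature on an evaluation set = mean increase of that
#' set's MAE over `n_repeats` random shuffles of the feature's column
#' (predictions in original units; delta mode keeps its baseline).
#'
#' @param fit a `db_fit`
#' @param table the feature table
#' @param set split tag of the evaluation set (default `"test"`)
#' @param n_repeats shuffles per feature (default 5)
#' @param seed RNG seed
#' @return named numeric vector, sorted decreasing
#' @export
permutation_importance <- function(fit, table, set = "test",
                                   n_repeats = 5L, seed = 1L) {
  table <- ft_unlock(table)
  rows <- .split_rows(table, set)
  rows <- rows[!is.na(table$y[rows])]
  if (!length(rows)) stop("evaluation set '", set, "' is empty")
  truth <- table$y[rows]
  base_mae <- mae_se(predict_barriers(fit, table, rows), truth)$mae
  set.seed(seed)
  imp <- stats::setNames(numeric(length(fit$features)), fit$features)
  for (f in fit$features) {
    deg <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      tbl <- table
      tbl$x[rows, f] <- sample(tbl$x[rows, f])
      deg[r] <- mae_se(predict_barriers(fit, tbl, rows), truth)$mae - base_mae
    }
    imp[f] <- mean(deg)
  }
  sort(imp, decreasing = TRUE)
}

#' Run the full pipeline on one split and build an evaluation report
#'
#' split -> (optional) forward selection -> tuning -> evaluation,
#' optionally with permutation importances per set. Everything inside
#' is seeded from `seed`, so reports are bit-reproducible.
#'
#' @param table an assembled, pruned, standardized [feature_table()]
#'   (standardize after splitting if you need train-only statistics; if
#'   the table is not yet split, `run_pipeline` splits it)
#' @param spec a [model_spec()]
#' @param test_fraction test fraction (default 0.2)
#' @param seed split seed (model seed comes from `spec$seed`)
#' @param select run forward selection (default FALSE: use all features)
#' @param k_folds CV folds
#' @param importance compute permutation importances (default FALSE)
#' @param importance_sets sets for importances
#' @return object of class `eval_report`
#' @export
run_pipeline <- function(table, spec, test_fraction = 0.2, seed = 1L,
                         select = FALSE, k_folds = 5L,
                         importance = FALSE,
                         importance_sets = c("train", "test")) {
  if (!any(table$split %in% c("train", "test"))) {
    table <- split_table(table, test_fraction, seed)
  }
  table <- ft_lock(table, allow = "train")
  feats <- if (select) {
    select_features(table, spec, k_folds = k_folds)
  } else colnames(table$x)
  fit <- tune_and_fit(table, features = feats, spec = spec,
                      k_folds = k_folds)
  ev <- evaluate_model(fit, table)
  report <- list(
    family = spec$family, kernel = spec$kernel, mode = spec$mode,
    split_seed = seed, model_seed = spec$seed,
    selected_features = fit$features,
    hyperparameters = fit$params,
    train_cv_mae = fit$cv_mae,
    test = ev$test, literature = ev$literature)
  if (importance) {
    report$importances <- lapply(
      stats::setNames(importance_sets, importance_sets),
      function(s) {
        rows <- .split_rows(table, s)
        if (!length(rows) || all(is.na(table$y[rows]))) return(NULL)
        permutation_importance(fit, table, set = s, seed = spec$seed)
      })
  }
  attr(report, "fit") <- fit
  attr(report, "table") <- ft_unlock(table)
  class(report) <- "eval_report"
  report
}

#' Serialize an evaluation report to canonical JSON
#'
#' Deterministic serialization (fixed precision, stable ordering) so
#' identical runs give byte-identical reports.
#'
#' @param report an `eval_report`
#' @return JSON string
#' @export
report_json <- function(report) {
  r <- unclass(report)
  attributes(r) <- list(names = names(r))
  as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = 10,
                                null = "null"))
}

#' Double cross validation over additional random splits
#'
#' Repeats the full pipeline (split, optional selection, tuning,
#' evaluation) at the original seed plus `n_extra_splits` further
#' seeds, and aggregates mean MAEs across splits.
#'
#' @param table a [feature_table()] (unsplit tags are re-drawn per seed)
#' @param spec a [model_spec()]
#' @param n_extra_splits extra splits beyond the first (default 5)
#' @param seeds optional explicit seeds (length `n_extra_splits + 1`)
#' @param ... passed to [run_pipeline()]
#' @return list with `reports` (one per split) and `aggregate`
#'   (mean train-CV/test/literature MAEs)
#' @export
double_cv <- function(table, spec, n_extra_splits = 5L, seeds = NULL, ...) {
  if (n_extra_splits < 1L) stop("n_extra_splits must be >= 1")
  if (is.null(seeds)) seeds <- spec$seed + 0:n_extra_splits
  if (length(seeds) != n_extra_splits + 1L) {
    stop("need n_extra_splits + 1 seeds")
  }
  fresh <- table
  fresh$split[fresh$split %in% c("train", "test")] <- "unassigned"
  reports <- lapply(seeds, function(s) {
    run_pipeline(fresh, spec, seed = s, ...)
  })
  agg <- list(
    train_cv_mae = mean(vapply(reports, `[[`, 0, "train_cv_mae")),
    test_mae = mean(vapply(reports, function(r) r$test$mae, 0)),
    literature_mae = {
      v <- vapply(reports, function(r) r$literature$mae %||% NA_real_, 0)
      if (all(is.na(v))) NULL else mean(v, na.rm = TRUE)
    })
  list(reports = reports, aggregate = agg)
}

#' Learning curve
#'
#' For each train size, draws a seeded subsample of the train rows and
#' computes k-fold CV MAEs (fold-train score and fold-validation score)
#' at the spec's first grid row.
#'
#' @param table a split [feature_table()]
#' @param spec a [model_spec()]
#' @param train_sizes integer vector of train-set sizes
#' @param k_folds CV folds
#' @return data frame with `size`, `train_mae`, `train_sd`, `cv_mae`,
#'   `cv_sd`
#' @export
learning_curve <- function(table, spec, train_sizes, k_folds = 5L) {
  rows_all <- .ft_rows(table, .split_rows(table, "train"))
  if (any(train_sizes > length(rows_all))) {
    stop("train_sizes exceed the train-set size")
  }
  params <- as.list(spec$grid[1, , drop = FALSE])
  out <- lapply(train_sizes, function(sz) {
    set.seed(spec$seed + sz)
    rows <- sort(sample(rows_all, sz))
    x <- table$x[rows, , drop = FALSE]
    y <- .train_target(table, rows, spec$mode)
    folds <- .cv_folds(sz, k_folds, spec$seed)
    tr_mae <- cv_mae <- numeric(0)
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      if (sum(tr) < 2 || sum(!tr) < 1) next
      m <- fit_model(x[tr, , drop = FALSE], y[tr], spec, params)
      tr_mae <- c(tr_mae, mae_se(predict(m, x[tr, , drop = FALSE]),
                                 y[tr])$mae)
      cv_mae <- c(cv_mae, mae_se(predict(m, x[!tr, , drop = FALSE]),
                                 y[!tr])$mae)
    }
    data.frame(size = sz, train_mae = mean(tr_mae),
               train_sd = stats::sd(tr_mae),
               cv_mae = mean(cv_mae), cv_sd = stats::sd(cv_mae))
  })
  do.call(rbind, out)
}
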