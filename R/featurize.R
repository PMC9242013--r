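# Feature-table assembly and preprocessing. A `feature_table` carries
# the reactions x descriptors matrix, the DFT target barriers, the raw
# SQM baseline barrier (for delta learning), per-row split tags, and the
# preprocessing state (standardization parameters, pruning report).
#
# Leakage control: a table can be locked to its train rows; every
# train-side routine (standardization statistics, pruning, feature
# selection, tuning) reads rows through the guard, so touching test or
# literature rows before evaluation raises an error.

#' Construct a feature table
#'
#' @param x numeric matrix, reactions x features, with row and column
#'   names
#' @param y optional target vector (DFT barrier, kcal/mol); NA allowed
#' @param baseline optional raw SQM barrier per row (kcal/mol), the
#'   delta-learning baseline
#' @param level level-of-theory tag
#' @param subset one of `"MA"`, `"TS"`, `"All"`
#' @param split character vector per row: `"train"`, `"test"`,
#'   `"literature"`, `"unassigned"`
#' @return object of class `feature_table`
#' @export
feature_table <- function(x, y = NULL, baseline = NULL, level = "NA",
                          subset = "All",
                          split = rep("unassigned", nrow(x))) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("feature names must be present and unique")
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("rxn", seq_len(nrow(x)))
  if (!is.null(y) && length(y) != nrow(x)) stop("y length mismatch")
  if (!is.null(baseline) && length(baseline) != nrow(x)) {
    stop("baseline length mismatch")
  }
  stopifnot(length(split) == nrow(x))
  structure(list(x = x, y = y, baseline = baseline, level = level,
                 subset = subset, split = as.character(split),
                 scaler = NULL, removals = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d x %d [%s/%s] splits: %s%s\n",
    nrow(x$x), ncol(x$x), x$level, x$subset,
    paste(names(table(x$split)), table(x$split), sep = "=", collapse = " "),
    if (!is.null(x$scaler)) " (standardized)" else ""))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Lock a feature table to a subset of split tags
#'
#' After locking, any internal row access outside `allow` raises an
#' error; [evaluate_model()] unlocks explicitly. Used to enforce the
#' no-leakage contract during selection/tuning.
#'
#' @param table a [feature_table()]
#' @param allow character vector of permitted split tags
#' @return the locked table
#' @export
ft_lock <- function(table, allow = "train") {
  attr(table, "guard_allow") <- allow
  table
}

#' Remove a feature-table access lock
#' @param table a [feature_table()]
#' @return the unlocked table
#' @export
ft_unlock <- function(table) {
  attr(table, "guard_allow") <- NULL
  table
}

# guarded row access; `rows` are integer indices
.ft_rows <- function(table, rows) {
  allow <- attr(table, "guard_allow")
  if (!is.null(allow) && !all(table$split[rows] %in% allow)) {
    stop("access guard: attempt to read rows outside splits [",
         paste(allow, collapse = ", "), "] before evaluation", call. = FALSE)
  }
  rows
}

.split_rows <- function(table, tag) which(table$split %in% tag)

#' Assemble a feature table from reaction records
#'
#' One row per reaction; columns are descriptor features of the MA
#' and/or TS species at `level` according to `subset` (`"MA"`, `"TS"`,
#' or `"All"` = MA + TS + the SQM reaction barrier). The target column
#' is the DFT quasiharmonic barrier when `target_level` records exist.
#' Reactions with any missing descriptor are excluded with a logged
#' reason (`attr(x, "exclusions")`); nothing is imputed.
#'
#' @param reactions list of [reaction_record()]s
#' @param level SQM level for features
#' @param subset `"MA"`, `"TS"` or `"All"`
#' @param target_level level providing target barriers (default "DFT");
#'   NULL for no target
#' @param T,conc thermochemistry settings for barrier features/targets
#' @return a [feature_table()] with attribute `"exclusions"`
#' @export
assemble <- function(reactions, level, subset = c("All", "MA", "TS"),
                     target_level = "DFT", T = 298.15, conc = 1.0) {
  subset <- match.arg(subset)
  roles <- switch(subset, MA = "MA", TS = "TS", All = c("MA", "TS"))
  rows <- list(); ids <- character(0)
  y <- numeric(0); base <- numeric(0); split <- character(0)
  exclusions <- data.frame(reaction_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  for (rx in reactions) {
    res <- tryCatch({
      feats <- numeric(0)
      for (role in roles) {
        rec <- get_record(rx, level, role)
        fv <- .species_features(rec, rx$key_atoms)
        names(fv) <- paste(role, names(fv), sep = "_")
        feats <- c(feats, fv)
      }
      bl <- NA_real_
      if (subset == "All") {
        bl <- activation_barrier(rx, level, T = T, conc = conc)$dG_act
        feats <- c(feats, stats::setNames(bl, paste0("barrier_", level)))
      }
      tg <- NA_real_
      if (!is.null(target_level) && !is.null(rx$records[[target_level]])) {
        tg <- activation_barrier(rx, target_level, T = T, conc = conc)$dG_act
      }
      if (anyNA(feats)) {
        stop("missing descriptor(s): ",
             paste(names(feats)[is.na(feats)], collapse = ", "),
             call. = FALSE)
      }
      list(feats = feats, y = tg, baseline = bl, split = rx$split_tag)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      exclusions <- rbind(exclusions,
                          data.frame(reaction_id = rx$reaction_id,
                                     reason = conditionMessage(res),
                                     stringsAsFactors = FALSE))
    } else {
      rows[[rx$reaction_id]] <- res$feats
      ids <- c(ids, rx$reaction_id)
      y <- c(y, res$y); base <- c(base, res$baseline)
      split <- c(split, res$split)
    }
  }
  if (!length(rows)) stop("no reactions survived feature assembly")
  x <- do.call(rbind, rows)
  rownames(x) <- ids
  ft <- feature_table(x, y = y,
                      baseline = if (subset == "All") base else NULL,
                      level = level, subset = subset, split = split)
  attr(ft, "exclusions") <- exclusions
  ft
}

# named feature vector for one species record
.species_features <- function(rec, key_atoms) {
  s <- rec$structure
  bonds <- perceive_bonds(s)
  ds <- descriptor_set(rec, key_atoms, bonds = bonds)
  at <- c(carbonyl_o = key_atoms$carbonyl_o, beta_c = key_atoms$beta_c)
  if (s$role == "TS") at <- c(at, nu_c = key_atoms$nu_c)
  out <- numeric(0)
  if (!is.null(ds$mulliken)) {
    out <- c(out, stats::setNames(ds$mulliken[at],
                                  paste0("mulliken_", names(at))))
  }
  out <- c(out, stats::setNames(ds$peoe[at], paste0("peoe_", names(at))))
  est <- ds$estate[c(key_atoms$carbonyl_o, key_atoms$beta_c)]
  out <- c(out, stats::setNames(est, paste0("estate_",
                                            c("carbonyl_o", "beta_c"))))
  for (k in seq_along(ds$sterimol)) {
    out <- c(out, stats::setNames(ds$sterimol[[k]],
                                  paste0("sterimol_", c("L", "B1", "B5"),
                                         "_R", k)))
  }
  out <- c(out, stats::setNames(ds$pbv, paste0("pbv_", names(ds$pbv))))
  out <- c(out,
           stats::setNames(ds$sasa_atom[at], paste0("sasa_", names(at))),
           sasa_total = ds$sasa_total)
  out
}

#' Standardize features to zero mean and unit variance
#'
#' Means and standard deviations are computed ONLY on the designated
#' rows (the train split by default) and stored on the table for reuse
#' on new rows; test/literature rows are transformed with the train
#' statistics. A zero-variance feature reaching this stage is an error
#' (it should have been pruned).
#'
#' @param table a [feature_table()]
#' @param stats_from split tag(s) whose rows define the statistics
#' @return the standardized table (scaler stored in `$scaler`)
#' @export
standardize <- function(table, stats_from = "train") {
  rows <- .ft_rows(table, .split_rows(table, stats_from))
  if (!length(rows)) stop("stats_from selects no rows")
  mu <- colMeans(table$x[rows, , drop = FALSE])
  sd <- apply(table$x[rows, , drop = FALSE], 2, stats::sd)
  if (any(sd <= 0)) {
    stop("zero-variance feature(s) reached standardize: ",
         paste(colnames(table$x)[sd <= 0], collapse = ", "), call. = FALSE)
  }
  table$x <- sweep(sweep(table$x, 2, mu), 2, sd, "/")
  table$scaler <- list(mean = mu, sd = sd, stats_from = stats_from)
  table
}

#' Apply or invert a stored standardization
#' @param table a standardized [feature_table()] (provides the scaler)
#' @param x new feature matrix with matching columns
#' @param invert undo instead of apply
#' @return transformed matrix
#' @export
apply_scaler <- function(table, x, invert = FALSE) {
  sc <- table$scaler
  if (is.null(sc)) stop("table has no stored scaler")
  x <- as.matrix(x)
  if (invert) {
    sweep(sweep(x, 2, sc$sd[colnames(x)], "*"), 2, -sc$mean[colnames(x)])
  } else {
    sweep(sweep(x, 2, sc$mean[colnames(x)]), 2, sc$sd[colnames(x)], "/")
  }
}

#' Prune zero-variance and collinear features
#'
#' Drops features whose variance (over the statistics rows, train by
#' default) is `<= var_tol`, then greedily removes one member of each
#' remaining pair with `|Pearson r| > corr_threshold`, keeping the
#' lexicographically earlier feature name (deterministic tie-break).
#'
#' @param table a [feature_table()]
#' @param var_tol variance threshold (default 0)
#' @param corr_threshold absolute correlation threshold (default 0.95)
#' @param stats_from split tag(s) defining the statistics rows
#' @return pruned table; removal report in `$removals` (data frame of
#'   `feature`, `reason`, `partner`)
#' @export
prune <- function(table, var_tol = 0, corr_threshold = 0.95,
                  stats_from = "train") {
  rows <- .ft_rows(table, .split_rows(table, stats_from))
  if (!length(rows)) rows <- .ft_rows(table, seq_len(nrow(table$x)))
  x <- table$x[rows, , drop = FALSE]
  removals <- data.frame(feature = character(0), reason = character(0),
                         partner = character(0), stringsAsFactors = FALSE)
  v <- apply(x, 2, stats::var)
  zv <- colnames(x)[v <= var_tol]
  if (length(zv)) {
    removals <- rbind(removals,
                      data.frame(feature = zv, reason = "zero_variance",
                                 partner = NA_character_,
                                 stringsAsFactors = FALSE))
    x <- x[, setdiff(colnames(x), zv), drop = FALSE]
  }
  # greedy collinearity pass in lexicographic column order
  ord <- order(colnames(x))
  x <- x[, ord, drop = FALSE]
  keep <- colnames(x)
  if (ncol(x) >= 2L) {
    cm <- abs(stats::cor(x))
    dropped <- character(0)
    cols <- colnames(x)
    for (a in seq_along(cols)) {
      if (cols[a] %in% dropped) next
      for (b in seq_along(cols)) {
        if (b <= a || cols[b] %in% dropped) next
        if (cm[a, b] > corr_threshold) {
          dropped <- c(dropped, cols[b])
          removals <- rbind(removals,
                            data.frame(feature = cols[b],
                                       reason = "collinear",
                                       partner = cols[a],
                                       stringsAsFactors = FALSE))
        }
      }
    }
    keep <- setdiff(cols, dropped)
  }
  # restore original column order on the retained features
  keep <- colnames(table$x)[colnames(table$x) %in% keep]
  table$x <- table$x[, keep, drop = FALSE]
  table$removals <- removals
  table
}

#' Write a feature table as CSV plus JSON sidecar
#'
#' The CSV holds reaction id, split, baseline, target and features; the
#' sidecar records level, subset, standardization parameters and the
#' removal report. Content round-trips through [read_feature_table()].
#'
#' @param table a [feature_table()]
#' @param path CSV path (sidecar gets `.json` appended)
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(reaction_id = rownames(table$x), split = table$split,
                   stringsAsFactors = FALSE)
  if (!is.null(table$baseline)) df$baseline <- table$baseline
  if (!is.null(table$y)) df$target <- table$y
  df <- cbind(df, as.data.frame(table$x))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(level = table$level, subset = table$subset,
               scaler = table$scaler, removals = table$removals)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path
#' @return a [feature_table()]
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  feat_cols <- setdiff(names(df),
                       c("reaction_id", "split", "baseline", "target"))
  x <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(x) <- df$reaction_id
  ft <- feature_table(x, y = df$target, baseline = df$baseline,
                      level = meta$level, subset = meta$subset,
                      split = df$split)
  if (!is.null(meta$scaler) && length(meta$scaler)) {
    ft$scaler <- list(mean = unlist(meta$scaler$mean),
                      sd = unlist(meta$scaler$sd),
                      stats_from = meta$scaler$stats_from)
  }
  ft
}
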