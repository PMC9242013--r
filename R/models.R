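# Regressor backends. Seven families: ridge (closed form), k-nearest
# neighbours, random forest and gradient boosting (on a shared CART
# regression tree), support vector regression (kernelized, smoothed
# epsilon-insensitive primal), kernel ridge (closed form) and Gaussian
# process regression (Matern kernel, hyperparameters by marginal
# likelihood). All operate on a numeric feature matrix and numeric
# target; categorical handling, weights etc. are out of scope.

#' Model specification
#'
#' @param family one of `"ridge"`, `"nnr"`, `"rfr"`, `"gbr"`, `"svr"`,
#'   `"krr"`, `"gpr"`
#' @param kernel kernel name for the kernel families: `"rbf"`,
#'   `"poly"` (svr/krr) or `"matern"` (gpr)
#' @param grid data frame of hyperparameter combinations to search
#'   (defaults via [default_grid()])
#' @param mode `"direct"` (predict the DFT barrier) or `"delta"` (fit
#'   the DFT - SQM difference; predictions add the baseline back)
#' @param seed integer seed controlling all stochastic components
#' @return object of class `model_spec`
#' @export
model_spec <- function(family = c("ridge", "nnr", "rfr", "gbr", "svr",
                                  "krr", "gpr"),
                       kernel = NULL, grid = NULL,
                       mode = c("direct", "delta"), seed = 1L) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  if (family %in% c("svr", "krr", "gpr") && is.null(kernel)) {
    kernel <- if (family == "gpr") "matern" else "rbf"
  }
  if (family == "gpr" && !identical(kernel, "matern")) {
    stop("gpr uses the Matern kernel")
  }
  if (is.null(grid)) grid <- default_grid(family, kernel)
  if (!nrow(grid)) stop("hyperparameter grid is empty")
  structure(list(family = family, kernel = kernel, grid = grid,
                 mode = mode, seed = as.integer(seed)),
            class = "model_spec")
}

#' Default hyperparameter grids
#'
#' Documented defaults standing in for settings the source data do not
#' pin down: ridge alpha 10^-3..10^3; NNR k 1..15; forest/boosting
#' trees {100,300,500} x depth {3,5,Inf}; SVR C 10^-2..10^3,
#' epsilon {0.01,0.1,0.5}, RBF gamma {scale,10^-3..1}; KRR alpha
#' 10^-4..10 with RBF or degree-2/3 polynomial kernels; GPR Matern
#' nu {1.5, 2.5} with length scale and noise optimized by marginal
#' likelihood.
#'
#' @param family model family string
#' @param kernel kernel name where applicable
#' @return data frame, one row per hyperparameter combination
#' @export
default_grid <- function(family, kernel = NULL) {
  switch(family,
    ridge = data.frame(alpha = 10^seq(-3, 3)),
    nnr = data.frame(k = 1:15),
    rfr = expand.grid(n_trees = c(100, 300, 500), max_depth = c(3, 5, Inf)),
    gbr = expand.grid(n_trees = c(100, 300, 500), max_depth = c(3, 5, Inf),
                      learning_rate = 0.1),
    svr = {
      g <- expand.grid(C = 10^seq(-2, 3), epsilon = c(0.01, 0.1, 0.5),
                       gamma = c(NA, 10^seq(-3, 0)))
      g   # gamma NA = "scale" (1 / (p * mean feature variance))
    },
    krr = if (identical(kernel, "poly")) {
      expand.grid(alpha = 10^seq(-4, 1), degree = c(2, 3))
    } else {
      expand.grid(alpha = 10^seq(-4, 1), gamma = c(NA, 10^seq(-3, 0)))
    },
    gpr = data.frame(nu = c(1.5, 2.5)),
    stop("unknown family: ", family))
}

# ---- kernels ----------------------------------------------------------------

.sq_dists <- function(X1, X2) {
  d <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  pmax(d, 0)
}

.kernel_matrix <- function(X1, X2, kernel, pars) {
  switch(kernel,
    rbf = exp(-pars$gamma * .sq_dists(X1, X2)),
    poly = (pars$gamma * tcrossprod(X1, X2) + 1)^pars$degree,
    matern = {
      d <- sqrt(.sq_dists(X1, X2)) / pars$lengthscale
      if (pars$nu == 1.5) {
        (1 + sqrt(3) * d) * exp(-sqrt(3) * d)
      } else if (pars$nu == 2.5) {
        (1 + sqrt(5) * d + 5 * d^2 / 3) * exp(-sqrt(5) * d)
      } else stop("matern nu must be 1.5 or 2.5")
    },
    stop("unknown kernel: ", kernel))
}

.scale_gamma <- function(x) 1 / (ncol(x) * max(mean(apply(x, 2, stats::var)),
                                               1e-12))

# ---- ridge ------------------------------------------------------------------

.fit_ridge <- function(x, y, params, seed) {
  X <- cbind(intercept = 1, x)
  P <- diag(c(0, rep(params$alpha, ncol(x))))
  beta <- solve(crossprod(X) + P, crossprod(X, y))
  list(beta = drop(beta))
}

.predict_ridge <- function(fit, x) drop(cbind(1, x) %*% fit$beta)

# ---- k-nearest neighbours ---------------------------------------------------

.fit_nnr <- function(x, y, params, seed) list(x = x, y = y, k = params$k)

.predict_nnr <- function(fit, x) {
  d <- .sq_dists(as.matrix(x), fit$x)
  apply(d, 1, function(row) {
    mean(fit$y[order(row)[seq_len(min(fit$k, length(row)))]])
  })
}

# ---- CART regression tree (shared by rfr/gbr) -------------------------------

.fit_tree <- function(x, y, idx, depth, max_depth, min_node, mtry) {
  n <- length(idx)
  node_val <- mean(y[idx])
  if (depth >= max_depth || n < 2 * min_node ||
      stats::var(y[idx]) < 1e-12) {
    return(list(leaf = TRUE, value = node_val))
  }
  p <- ncol(x)
  feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
  best <- list(gain = 0)
  sum_all <- sum(y[idx])
  for (j in feats) {
    xs <- x[idx, j]
    ord <- order(xs)
    xs_o <- xs[ord]; ys_o <- y[idx][ord]
    cs <- cumsum(ys_o)
    k <- seq_len(n - 1L)
    valid <- xs_o[k] < xs_o[k + 1L]
    valid <- valid & k >= min_node & (n - k) >= min_node
    if (!any(valid)) next
    nl <- k; nr <- n - k
    gain <- cs[k]^2 / nl + (sum_all - cs[k])^2 / nr
    gain[!valid] <- -Inf
    kb <- which.max(gain)
    g <- gain[kb] - sum_all^2 / n
    if (is.finite(g) && g > best$gain + 1e-12) {
      best <- list(gain = g, var = j,
                   split = (xs_o[kb] + xs_o[kb + 1L]) / 2)
    }
  }
  if (best$gain <= 0) return(list(leaf = TRUE, value = node_val))
  left <- idx[x[idx, best$var] <= best$split]
  right <- idx[x[idx, best$var] > best$split]
  list(leaf = FALSE, var = best$var, split = best$split,
       left = .fit_tree(x, y, left, depth + 1L, max_depth, min_node, mtry),
       right = .fit_tree(x, y, right, depth + 1L, max_depth, min_node, mtry))
}

.predict_tree <- function(tree, x) {
  out <- numeric(nrow(x))
  recurse <- function(node, rows) {
    if (!length(rows)) return()
    if (node$leaf) { out[rows] <<- node$value; return() }
    go_left <- x[rows, node$var] <= node$split
    recurse(node$left, rows[go_left])
    recurse(node$right, rows[!go_left])
  }
  recurse(tree, seq_len(nrow(x)))
  out
}

# ---- random forest ----------------------------------------------------------

.fit_rfr <- function(x, y, params, seed) {
  set.seed(seed)
  n <- nrow(x)
  mtry <- max(1L, floor(ncol(x) / 3))
  md <- if (is.finite(params$max_depth)) params$max_depth else 1000L
  trees <- lapply(seq_len(params$n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    .fit_tree(x, y, idx, 0L, md, min_node = 3L, mtry = mtry)
  })
  list(trees = trees)
}

.predict_rfr <- function(fit, x) {
  preds <- vapply(fit$trees, .predict_tree, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) mean(preds) else rowMeans(preds)
}

# ---- gradient boosting ------------------------------------------------------

.fit_gbr <- function(x, y, params, seed) {
  set.seed(seed)
  md <- if (is.finite(params$max_depth)) params$max_depth else 1000L
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", params$n_trees)
  for (b in seq_len(params$n_trees)) {
    tr <- .fit_tree(x, resid, seq_len(nrow(x)), 0L, md,
                    min_node = 3L, mtry = ncol(x))
    trees[[b]] <- tr
    resid <- resid - params$learning_rate * .predict_tree(tr, x)
  }
  list(f0 = f0, trees = trees, lr = params$learning_rate)
}

.predict_gbr <- function(fit, x) {
  out <- rep(fit$f0, nrow(x))
  for (tr in fit$trees) out <- out + fit$lr * .predict_tree(tr, x)
  out
}

# ---- support vector regression ---------------------------------------------

# kernelized primal with squared epsilon-insensitive loss (smooth, so
# L-BFGS applies): min 0.5 a'Ka + C sum max(0, |y - Ka - b| - eps)^2
.fit_svr <- function(x, y, params, seed, kernel = "rbf") {
  gamma <- if (is.na(params$gamma)) .scale_gamma(x) else params$gamma
  kp <- list(gamma = gamma, degree = params$degree %||% 3)
  K <- .kernel_matrix(x, x, kernel, kp)
  n <- nrow(x)
  eps <- params$epsilon; C <- params$C
  obj <- function(theta) {
    a <- theta[1:n]; b <- theta[n + 1]
    Ka <- drop(K %*% a)
    r <- y - Ka - b
    s <- sign(r) * pmax(0, abs(r) - eps)
    0.5 * sum(a * Ka) + C * sum(s^2)
  }
  grad <- function(theta) {
    a <- theta[1:n]; b <- theta[n + 1]
    Ka <- drop(K %*% a)
    r <- y - Ka - b
    s <- sign(r) * pmax(0, abs(r) - eps)
    c(Ka - 2 * C * drop(K %*% s), -2 * C * sum(s))
  }
  res <- stats::optim(c(rep(0, n), mean(y)), obj, grad,
                      method = "L-BFGS-B",
                      control = list(maxit = 200))
  list(x = x, alpha = res$par[1:n], b = res$par[n + 1],
       kernel = kernel, kp = kp)
}

.predict_svr <- function(fit, x) {
  drop(.kernel_matrix(as.matrix(x), fit$x, fit$kernel, fit$kp) %*%
         fit$alpha) + fit$b
}

# ---- kernel ridge -----------------------------------------------------------

.fit_krr <- function(x, y, params, seed, kernel = "rbf") {
  gamma <- if (kernel == "rbf" && is.na(params$gamma)) {
    .scale_gamma(x)
  } else params$gamma %||% (1 / ncol(x))
  kp <- list(gamma = gamma, degree = params$degree %||% 3)
  K <- .kernel_matrix(x, x, kernel, kp)
  ybar <- mean(y)
  dual <- solve(K + params$alpha * diag(nrow(x)), y - ybar)
  list(x = x, dual = dual, ybar = ybar, kernel = kernel, kp = kp)
}

.predict_krr <- function(fit, x) {
  drop(.kernel_matrix(as.matrix(x), fit$x, fit$kernel, fit$kp) %*%
         fit$dual) + fit$ybar
}

# ---- Gaussian process regression -------------------------------------------

# constant-mean GP with Matern covariance; (lengthscale, signal sd,
# noise sd) optimized on the log scale by Nelder-Mead on the negative
# log marginal likelihood
.gpr_nll <- function(logp, D2, yc, nu) {
  ell <- exp(logp[1]); sf <- exp(logp[2]); sn <- exp(logp[3])
  d <- sqrt(D2) / ell
  K <- if (nu == 1.5) (1 + sqrt(3) * d) * exp(-sqrt(3) * d) else
    (1 + sqrt(5) * d + 5 * d^2 / 3) * exp(-sqrt(5) * d)
  K <- sf^2 * K + (sn^2 + 1e-10) * diag(nrow(K))
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  0.5 * sum(yc * alpha) + sum(log(diag(ch))) + 0.5 * length(yc) * log(2 * pi)
}

.fit_gpr <- function(x, y, params, seed, maxit = 80) {
  D2 <- .sq_dists(x, x)
  ybar <- mean(y)
  yc <- y - ybar
  sdy <- max(stats::sd(y), 1e-6)
  med <- stats::median(sqrt(D2[upper.tri(D2)]))
  init <- log(c(max(med, 1e-3), sdy, 0.1 * sdy))
  opt <- stats::optim(init, .gpr_nll, D2 = D2, yc = yc, nu = params$nu,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit))
  ell <- exp(opt$par[1]); sf <- exp(opt$par[2]); sn <- exp(opt$par[3])
  kp <- list(lengthscale = ell, nu = params$nu)
  K <- sf^2 * .kernel_matrix(x, x, "matern", kp) +
    (sn^2 + 1e-10) * diag(nrow(x))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(x = x, alpha = alpha, ybar = ybar, sf = sf, sn = sn, kp = kp,
       nll = opt$value)
}

.predict_gpr <- function(fit, x) {
  Ks <- fit$sf^2 * .kernel_matrix(as.matrix(x), fit$x, "matern", fit$kp)
  drop(Ks %*% fit$alpha) + fit$ybar
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- unified front end ------------------------------------------------------

#' Fit one model at fixed hyperparameters
#'
#' Low-level fitting entry used by [tune_and_fit()]; `params` is one
#' row of the family's grid as a list.
#'
#' @param x numeric feature matrix
#' @param y numeric target
#' @param spec a [model_spec()]
#' @param params named list of hyperparameters
#' @return object of class `db_model`
#' @export
fit_model <- function(x, y, spec, params) {
  x <- as.matrix(x)
  fit <- switch(spec$family,
    ridge = .fit_ridge(x, y, params, spec$seed),
    nnr = .fit_nnr(x, y, params, spec$seed),
    rfr = .fit_rfr(x, y, params, spec$seed),
    gbr = .fit_gbr(x, y, params, spec$seed),
    svr = .fit_svr(x, y, params, spec$seed, kernel = spec$kernel %||% "rbf"),
    krr = .fit_krr(x, y, params, spec$seed, kernel = spec$kernel %||% "rbf"),
    gpr = .fit_gpr(x, y, params, spec$seed))
  structure(list(family = spec$family, fit = fit, params = params,
                 features = colnames(x)),
            class = "db_model")
}

#' Predict from a fitted model
#' @param object a `db_model` from [fit_model()]
#' @param newdata feature matrix (columns must cover the model features)
#' @param ... unused
#' @return numeric predictions
#' @export
predict.db_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  switch(object$family,
    ridge = .predict_ridge(object$fit, x),
    nnr = .predict_nnr(object$fit, x),
    rfr = .predict_rfr(object$fit, x),
    gbr = .predict_gbr(object$fit, x),
    svr = .predict_svr(object$fit, x),
    krr = .predict_krr(object$fit, x),
    gpr = .predict_gpr(object$fit, x))
}
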