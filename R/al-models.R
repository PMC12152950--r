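## Surrogate models for the active-learning loop.
##
## gp_tanimoto     Gaussian process regression with the Tanimoto kernel on
##                 binary fingerprints, plus a constant kernel term that
##                 absorbs the label mean (so the zero-mean GP is well
##                 specified without ad hoc centering).
## linear_regression  kernel ridge regression with a (scaled) linear kernel
##                 plus the same constant term; the small default ridge makes
##                 it the minimum-norm least-squares fit when p > n.
## random_forest   randomForest, seeded.

.tanimoto_kernel <- function(A, B = NULL) {
  if (is.null(B)) B <- A
  A <- matrix(as.numeric(A), nrow = nrow(A))
  B <- matrix(as.numeric(B), nrow = nrow(B))
  inter <- A %*% t(B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  k <- inter / un
  k[un == 0] <- 1  # two empty fingerprints are identical objects
  k
}

.linear_kernel <- function(A, B = NULL) {
  if (is.null(B)) B <- A
  (matrix(as.numeric(A), nrow = nrow(A)) %*%
     t(matrix(as.numeric(B), nrow = nrow(B)))) / ncol(A)
}

## Hyperparameter grids for the inner cross-validation search.
.hyper_grid <- function(algorithm) {
  switch(algorithm,
    linear_regression = list(list(lambda = 1e-8), list(lambda = 1)),
    gp_tanimoto = list(list(noise = 1e-4), list(noise = 1e-2), list(noise = 1e-1)),
    random_forest = list(list(ntree = 100, nodesize = 1),
                         list(ntree = 100, nodesize = 5),
                         list(ntree = 500, nodesize = 1),
                         list(ntree = 500, nodesize = 5)),
    .stopf("unknown algorithm '%s'", algorithm)
  )
}

.kernel_for <- function(algorithm, A, B = NULL, const = 10) {
  base <- if (algorithm == "gp_tanimoto") .tanimoto_kernel(A, B)
          else .linear_kernel(A, B)
  base + const
}

#' Fit a surrogate model
#'
#' @param algorithm `"linear_regression"`, `"random_forest"` or
#'   `"gp_tanimoto"`.
#' @param X binary fingerprint matrix (rows = molecules).
#' @param y numeric labels (kcal/mol).
#' @param hyperparameters named list (see the model zoo grids).
#' @param seed RNG seed (random forest only).
#' @return an object of class `alfe_model`.
#' @export
fit_model <- function(algorithm, X, y,
                      hyperparameters = .hyper_grid(algorithm)[[1]],
                      seed = 1L) {
  algorithm <- match.arg(algorithm,
                         c("linear_regression", "random_forest", "gp_tanimoto"))
  stopifnot(nrow(X) == length(y))
  model <- if (algorithm == "random_forest") {
    .with_seed(seed, randomForest::randomForest(
      x = X, y = y,
      ntree = hyperparameters$ntree %||% 100,
      nodesize = hyperparameters$nodesize %||% 1))
  } else {
    sy <- stats::var(y); if (!is.finite(sy) || sy == 0) sy <- 1
    reg <- if (algorithm == "gp_tanimoto") hyperparameters$noise %||% 1e-2
           else hyperparameters$lambda %||% 1e-8
    K <- sy * .kernel_for(algorithm, X) + diag(reg * sy, nrow(X))
    list(alpha = solve(K, y), X_train = X, sy = sy, reg = reg)
  }
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 model = model, seed = seed),
            class = "alfe_model")
}

#' @rdname fit_model
#' @param object a fitted `alfe_model`.
#' @param newdata fingerprint matrix to predict.
#' @param ... unused.
#' @export
predict.alfe_model <- function(object, newdata, ...) {
  if (object$algorithm == "random_forest")
    return(unname(stats::predict(object$model, newdata)))
  m <- object$model
  Ks <- m$sy * .kernel_for(object$algorithm, newdata, m$X_train)
  as.numeric(Ks %*% m$alpha)
}

#' Leave-one-out cross-validated R-squared
#'
#' For each training entry, fit on the remainder and predict it; returns
#' `R^2 = 1 - SSE/SST` over the held-out predictions. Kernel models use the
#' exact closed form (identical to refitting n times); random forests refit
#' explicitly. Zero label variance returns `-Inf` with a warning (undefined
#' R-squared sentinel, so a degenerate cell can never win model selection).
#'
#' @param spec list with `algorithm` and `hyperparameters`.
#' @param X fingerprint matrix.
#' @param y labels.
#' @param seed RNG seed for stochastic learners.
#' @return LOOCV R-squared (<= 1), or `-Inf` if undefined.
#' @export
loocv_r2 <- function(spec, X, y, seed = 1L) {
  n <- length(y)
  if (n < 3) .stopf("need at least 3 training entries for LOOCV")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    .warnf("zero label variance: LOOCV R^2 undefined")
    return(-Inf)
  }
  pred <- .loocv_predictions(spec, X, y, seed = seed)
  1 - sum((y - pred)^2) / sst
}

.loocv_predictions <- function(spec, X, y, seed = 1L) {
  n <- length(y)
  if (spec$algorithm == "random_forest") {
    vapply(seq_len(n), function(i) {
      fit <- fit_model("random_forest", X[-i, , drop = FALSE], y[-i],
                       spec$hyperparameters, seed = seed + i)
      stats::predict(fit$model, X[i, , drop = FALSE])
    }, numeric(1))
  } else {
    sy <- stats::var(y); if (!is.finite(sy) || sy == 0) sy <- 1
    reg <- if (spec$algorithm == "gp_tanimoto") spec$hyperparameters$noise %||% 1e-2
           else spec$hyperparameters$lambda %||% 1e-8
    K <- sy * .kernel_for(spec$algorithm, X) + diag(reg * sy, n)
    Ki <- solve(K)
    alpha <- Ki %*% y
    ## exact LOO for kernel ridge / GP mean: y_i - alpha_i / Kinv_ii
    as.numeric(y - alpha / diag(Ki))
  }
}

## Inner k-fold cross-validation MSE for hyperparameter tuning.
.cv_mse <- function(spec, X, y, folds = 5L, seed = 1L) {
  n <- length(y)
  folds <- min(folds, n)
  assign_fold <- .with_seed(seed, sample(rep_len(seq_len(folds), n)))
  err <- 0
  for (f in seq_len(folds)) {
    te <- which(assign_fold == f)
    if (length(te) == 0 || length(te) == n) next
    fit <- fit_model(spec$algorithm, X[-te, , drop = FALSE], y[-te],
                     spec$hyperparameters, seed = seed + f)
    p <- stats::predict(fit, X[te, , drop = FALSE])
    err <- err + sum((y[te] - p)^2)
  }
  err / n
}

#' AutoML model selection
#'
#' For every (representation, algorithm) cell: tune hyperparameters by an
#' inner 5-fold cross-validation grid search, then score the tuned cell by
#' LOOCV R-squared; the argmax cell (ties: first in declared grid order) is
#' refit on all data. Deterministic for fixed seed and inputs.
#'
#' @param features named list of fingerprint matrices (one per
#'   representation), rows aligned with `labels` names.
#' @param labels named numeric vector of absolute binding free energies
#'   (kcal/mol), names = molecule ids present in every feature matrix.
#' @param algorithms algorithms to consider (declared order breaks ties).
#' @param seed RNG seed.
#' @param inner_folds folds of the inner tuning loop (default 5).
#' @return a `model_spec`: list with `representation`, `algorithm`,
#'   `hyperparameters`, `cv_r2` and the refit `model`.
#' @export
automl_select <- function(features, labels,
                          algorithms = c("linear_regression", "random_forest",
                                         "gp_tanimoto"),
                          seed = 1L, inner_folds = 5L) {
  stopifnot(is.list(features), length(features) > 0, !is.null(names(labels)))
  ids <- names(labels)
  best <- NULL
  for (rep_name in names(features)) {
    Xall <- features[[rep_name]]
    if (!all(ids %in% rownames(Xall))) .stopf(
      "representation '%s' lacks features for some labeled molecules", rep_name)
    X <- Xall[ids, , drop = FALSE]
    for (alg in algorithms) {
      grid <- .hyper_grid(alg)
      cvs <- vapply(grid, function(hp)
        .cv_mse(list(algorithm = alg, hyperparameters = hp), X, labels,
                folds = inner_folds, seed = seed), numeric(1))
      hp <- grid[[which.min(cvs)]]
      r2 <- suppressWarnings(
        loocv_r2(list(algorithm = alg, hyperparameters = hp), X, labels,
                 seed = seed))
      if (is.null(best) || r2 > best$cv_r2) {
        best <- list(representation = rep_name, algorithm = alg,
                     hyperparameters = hp, cv_r2 = r2)
      }
    }
  }
  if (is.null(best) || !is.finite(best$cv_r2) && best$cv_r2 == -Inf) {
    if (is.null(best)) .stopf("all model cells failed")
  }
  X <- features[[best$representation]][ids, , drop = FALSE]
  best$model <- fit_model(best$algorithm, X, labels, best$hyperparameters,
                          seed = seed)
  class(best) <- "model_spec"
  best
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s on %s (LOOCV R^2 = %.3f)\n",
              x$algorithm, x$representation, x$cv_r2))
  invisible(x)
}
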