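#' @title Baseline regression models
#' @description The five descriptor-based regressors of the benchmark - k-
#' nearest neighbours, support vector machine (RBF kernel), gradient
#' boosting, random forest, and a feed-forward neural network - with the
#' benchmark's hyperparameter search protocol: at most 50 configurations
#' evaluated by fivefold cross-validated RMSE, best configuration refit on
#' the full training set. All grids fit within the budget, so the search is
#' exhaustive.
#' @name models
NULL

ALGORITHMS <- c("KNN", "SVM", "GBM", "RF", "MLP")

#' Default hyperparameter grid of an algorithm
#'
#' KNN: k in 3/5/11/21. SVM: gamma over six decades 1e-6..1e-1 crossed with
#' C in 1/10/100/1000/10000. GBM: boosting stages 100/200/400 crossed with
#' depth 5/6/7. RF: 100/250/500/1000 trees. MLP: learning rate
#' 5e-4/5e-5/5e-6, hidden width 256/512/1024, depth 1..5.
#'
#' @param algorithm one of `r paste(ALGORITHMS, collapse=", ")`.
#' @return data.frame, one row per configuration.
#' @export
default_grid <- function(algorithm = ALGORITHMS) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    KNN = data.frame(k = c(3L, 5L, 11L, 21L)),
    SVM = expand.grid(gamma = 10^(-6:-1), cost = c(1, 10, 100, 1000, 10000)),
    GBM = expand.grid(nrounds = c(100L, 200L, 400L), max_depth = 5:7),
    RF = data.frame(ntree = c(100L, 250L, 500L, 1000L)),
    MLP = expand.grid(lr = c(5e-4, 5e-5, 5e-6),
                      n_hidden = c(256L, 512L, 1024L), n_layers = 1:5)
  )
}

# Stratified k-fold assignment (stratum = cliff label when given).
.cv_folds <- function(n, k, strata = NULL, seed = 1L) {
  if (is.null(strata)) strata <- rep(1L, n)
  fold <- integer(n)
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

.fit_one <- function(algorithm, x, y, par, seed) {
  switch(algorithm,
    KNN = list(kind = "KNN", x = x, y = y, k = par$k),
    SVM = with_seed(seed,
      e1071::svm(x = x, y = y, kernel = "radial", gamma = par$gamma,
                 cost = par$cost, scale = FALSE)),
    GBM = xgboost::xgboost(x = x, y = y, nrounds = par$nrounds,
                           max_depth = par$max_depth, learning_rate = 0.1,
                           nthreads = 1L, verbosity = 0L,
                           seed = as.integer(seed)),
    RF = with_seed(seed,
      randomForest::randomForest(x = x, y = y, ntree = par$ntree)),
    MLP = mlp_fit(x, y, lr = par$lr, n_hidden = par$n_hidden,
                  n_layers = par$n_layers, seed = seed)
  )
}

.predict_one <- function(algorithm, fit, x) {
  switch(algorithm,
    KNN = knn_predict(fit, x),
    SVM = as.numeric(stats::predict(fit, x)),
    GBM = as.numeric(stats::predict(fit, x)),
    RF = as.numeric(stats::predict(fit, x)),
    MLP = mlp_predict(fit, x)
  )
}

# k-nearest-neighbour regression: mean response of the k nearest training
# rows by Euclidean distance; ties broken by training order.
knn_predict <- function(fit, x) {
  d <- .pairwise_dist(as.matrix(x), fit$x, binary = FALSE)
  k <- min(fit$k, ncol(d))
  apply(d, 1, function(row) mean(fit$y[order(row)[seq_len(k)]]))
}

#' Tune and fit one model
#'
#' Evaluates up to 50 grid configurations by seeded stratified fivefold
#' cross-validation (mean RMSE), then refits the best configuration on the
#' full training set. Ties go to the earlier grid row.
#'
#' @param x numeric training descriptor matrix.
#' @param y numeric p-unit activities.
#' @param algorithm one of `r paste(ALGORITHMS, collapse=", ")`.
#' @param grid hyperparameter grid (data.frame); defaults to the
#'   algorithm's published grid.
#' @param cliff_labels optional logical vector; folds are stratified on it.
#' @param seed integer seed controlling folds and stochastic learners.
#' @param n_folds number of cross-validation folds.
#' @param max_evals configuration budget.
#' @return object of class `cliff_model` with elements `algorithm`, `par`
#'   (selected row), `cv_rmse`, `cv_table`, `fit`, `seed`.
#' @export
tune_and_fit <- function(x, y, algorithm = ALGORITHMS, grid = NULL,
                         cliff_labels = NULL, seed = 1L, n_folds = 5L,
                         max_evals = 50L) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= n_folds)
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!nrow(grid)) stop("GRID_EMPTY: no configurations to evaluate",
                        call. = FALSE)
  if (nrow(grid) > max_evals) grid <- grid[seq_len(max_evals), , drop = FALSE]
  fold <- .cv_folds(nrow(x), n_folds, strata = cliff_labels, seed = seed)
  cv <- vapply(seq_len(nrow(grid)), function(g) {
    par <- grid[g, , drop = FALSE]
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      if (!any(tr) || all(tr)) return(NA_real_)
      fit <- .fit_one(algorithm, x[tr, , drop = FALSE], y[tr], par,
                      seed = derive_seed(seed, "cv", g, f))
      pred <- .predict_one(algorithm, fit, x[!tr, , drop = FALSE])
      sqrt(mean((pred - y[!tr])^2))
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  best <- which.min(cv)
  par <- grid[best, , drop = FALSE]
  fit <- .fit_one(algorithm, x, y, par, seed = derive_seed(seed, "final"))
  structure(list(algorithm = algorithm, par = par, cv_rmse = cv[best],
                 cv_table = cbind(grid, cv_rmse = cv), fit = fit,
                 n_features = ncol(x), seed = as.integer(seed)),
            class = "cliff_model")
}

#' @export
predict.cliff_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!nrow(newdata)) return(numeric(0))
  if (ncol(newdata) != object$n_features) {
    stop("KIND_MISMATCH: model was trained on ", object$n_features,
         " features, got ", ncol(newdata), call. = FALSE)
  }
  .predict_one(object$algorithm, object$fit, newdata)
}

#' @export
print.cliff_model <- function(x, ...) {
  cat(sprintf("cliffbench %s model (CV RMSE %.4f)\n", x$algorithm, x$cv_rmse))
  cat("  selected:",
      paste(names(x$par), unlist(x$par), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
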