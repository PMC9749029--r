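#' @title Performance evaluation
#' @description Root-mean-square error over the whole test set and over its
#' activity-cliff compounds only, the method-by-dataset benchmark table, a
#' PCA-based global ranking anchored at per-dataset best/worst rows, and
#' correlation analyses of the two error measures.
#' @name evaluation
NULL

#' Prediction set
#'
#' Aligned experimental and predicted p-unit activities for one test set,
#' with per-molecule cliff labels.
#'
#' @param y experimental p-activities.
#' @param y_hat predicted p-activities.
#' @param cliff_label logical cliff-compound labels.
#' @return list of class `prediction_set`.
#' @export
prediction_set <- function(y, y_hat, cliff_label) {
  stopifnot(length(y) == length(y_hat), length(y) == length(cliff_label))
  structure(list(y = as.numeric(y), y_hat = as.numeric(y_hat),
                 cliff_label = as.logical(cliff_label),
                 n = length(y), n_c = sum(cliff_label)),
            class = "prediction_set")
}

#' Root-mean-square error
#'
#' @param pred a [prediction_set()].
#' @return sqrt of the mean squared residual over all n molecules.
#' @export
rmse <- function(pred) {
  if (pred$n < 1L) stop("EMPTY: no predictions", call. = FALSE)
  sqrt(mean((pred$y_hat - pred$y)^2))
}

#' Cliff-restricted root-mean-square error
#'
#' RMSE computed only over molecules that belong to at least one
#' activity-cliff pair. Undefined (NA) when the test set has no cliff
#' compounds.
#'
#' @param pred a [prediction_set()].
#' @return numeric, or `NA` with a warning when `n_c = 0`.
#' @export
rmse_cliff <- function(pred) {
  if (pred$n_c < 1L) {
    warning("NO_CLIFFS: no cliff compounds in the prediction set")
    return(NA_real_)
  }
  keep <- pred$cliff_label
  sqrt(mean((pred$y_hat[keep] - pred$y[keep])^2))
}

#' Assemble a benchmark table
#'
#' @param results data.frame with columns `method`, `dataset`, `rmse`,
#'   `rmse_cliff`.
#' @return the same data.frame, classed `benchmark_table`.
#' @export
benchmark_table <- function(results) {
  stopifnot(all(c("method", "dataset", "rmse", "rmse_cliff") %in%
                  names(results)))
  class(results) <- c("benchmark_table", "data.frame")
  results
}

.bench_matrix <- function(table, metric) {
  methods <- unique(table$method)
  datasets <- unique(table$dataset)
  m <- matrix(NA_real_, length(methods), length(datasets),
              dimnames = list(methods, datasets))
  m[cbind(match(table$method, methods), match(table$dataset, datasets))] <-
    table[[metric]]
  m
}

#' PCA-based global ranking of methods
#'
#' Builds the method-by-dataset matrix of the chosen metric, appends two
#' synthetic anchor rows holding the per-dataset best (column minima) and
#' worst (column maxima) values, mean-centres the columns and projects all
#' rows onto the first two principal components. Orientation is fixed so
#' the "Best" anchor has the smaller first coordinate; coordinates min-max
#' scaled along the Best-Worst axis are also returned.
#'
#' @param table a [benchmark_table()].
#' @param metric `"rmse_cliff"` (default) or `"rmse"`.
#' @return list of class `pca_ranking`: `coords` (data.frame with method,
#'   PC1, PC2, scaled), `explained` (variance fractions), `anchors`.
#' @export
pca_ranking <- function(table, metric = c("rmse_cliff", "rmse")) {
  metric <- match.arg(metric)
  m <- .bench_matrix(table, metric)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 methods and 2 datasets", call. = FALSE)
  }
  if (any(is.na(m))) stop("benchmark table has missing cells", call. = FALSE)
  anchors <- rbind(Best = apply(m, 2, min), Worst = apply(m, 2, max))
  full <- rbind(m, anchors)
  if (all(apply(full, 2, stats::sd) == 0)) {
    stop("DEGENERATE: constant benchmark matrix", call. = FALSE)
  }
  pc <- stats::prcomp(full, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) coords <- cbind(coords, PC2 = 0)
  ib <- nrow(m) + 1L
  iw <- nrow(m) + 2L
  if (coords[ib, 1] > coords[iw, 1]) coords[, 1] <- -coords[, 1]
  axis <- coords[iw, ] - coords[ib, ]
  denom <- sum(axis^2)
  scaled <- if (denom > 0) {
    as.numeric((sweep(coords, 2, coords[ib, ]) %*% axis) / denom)
  } else {
    rep(NA_real_, nrow(coords))
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    coords = data.frame(method = rownames(full), PC1 = coords[, 1],
                        PC2 = coords[, 2], scaled = scaled,
                        row.names = NULL, stringsAsFactors = FALSE),
    explained = ev[seq_len(k)],
    anchors = anchors,
    metric = metric
  ), class = "pca_ranking")
}

#' @export
print.pca_ranking <- function(x, ...) {
  cat(sprintf("PCA ranking on %s (PC1 %.1f%%, PC2 %.1f%% variance)\n",
              x$metric, 100 * x$explained[1],
              100 * ifelse(length(x$explained) > 1, x$explained[2], 0)))
  ord <- order(x$coords$scaled)
  print(x$coords[ord, ], digits = 3)
  invisible(x)
}

#' Failure-mode correlation analyses
#'
#' Per dataset: the Pearson correlation across methods between overall RMSE
#' and cliff RMSE, and the mean excess error on cliffs
#' (RMSE_cliff - RMSE). Both summaries are then correlated against the
#' training-set sizes.
#'
#' @param table a [benchmark_table()].
#' @param train_sizes named numeric vector of training-set sizes per
#'   dataset (optional).
#' @return list of class `failure_modes`: `per_dataset` (data.frame) and
#'   `vs_train_size` (correlations, NA when sizes are absent).
#' @export
failure_mode_analysis <- function(table, train_sizes = NULL) {
  mr <- .bench_matrix(table, "rmse")
  mc <- .bench_matrix(table, "rmse_cliff")
  ds <- colnames(mr)
  per <- data.frame(
    dataset = ds,
    r = vapply(ds, function(d) {
      if (stats::sd(mr[, d]) == 0 || stats::sd(mc[, d]) == 0) return(NA_real_)
      stats::cor(mr[, d], mc[, d])
    }, numeric(1)),
    mean_excess = vapply(ds, function(d) mean(mc[, d] - mr[, d]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vs <- list(r_vs_size = NA_real_, excess_vs_size = NA_real_)
  if (!is.null(train_sizes) && length(ds) >= 3L) {
    sz <- train_sizes[ds]
    if (!anyNA(sz)) {
      if (stats::sd(per$r, na.rm = TRUE) > 0 && stats::sd(sz) > 0) {
        vs$r_vs_size <- stats::cor(per$r, sz, use = "complete.obs")
      }
      if (stats::sd(per$mean_excess) > 0 && stats::sd(sz) > 0) {
        vs$excess_vs_size <- stats::cor(per$mean_excess, sz)
      }
    }
  }
  structure(list(per_dataset = per, vs_train_size = vs),
            class = "failure_modes")
}
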