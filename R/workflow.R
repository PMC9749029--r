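#' @title End-to-end benchmark runs
#' @description Orchestrates curation, cliff detection, splitting,
#' featurization, model tuning and evaluation over several datasets and
#' methods, with per-stage seeds derived deterministically from one master
#' seed.
#' @name workflow
NULL

#' Benchmark run configuration
#'
#' @param datasets named list of raw data.frames (columns `smiles`,
#'   `activity_nM`, optional `validity_flag`).
#' @param methods data.frame with columns `algorithm` and `descriptor`.
#' @param curation a [curation_config()].
#' @param cliffs a [cliff_config()].
#' @param split a [split_config()] (its `seed` is overridden by a derived
#'   seed per dataset).
#' @param grids optional named list of hyperparameter grids per algorithm.
#' @param master_seed master seed; every random stage uses a seed derived
#'   from it with [derive_seed()].
#' @param out_dir optional directory; when given, curated data, cliff
#'   tables, split files, predictions and the benchmark table are written
#'   there as CSV.
#' @return list of class `run_config`.
#' @export
run_config <- function(datasets, methods,
                       curation = curation_config(),
                       cliffs = cliff_config(),
                       split = split_config(),
                       grids = NULL,
                       master_seed = 1L,
                       out_dir = NULL) {
  stopifnot(is.list(datasets), length(names(datasets)) == length(datasets),
            is.data.frame(methods),
            all(c("algorithm", "descriptor") %in% names(methods)))
  stopifnot(all(methods$algorithm %in% ALGORITHMS),
            all(methods$descriptor %in% DESCRIPTOR_KINDS))
  structure(list(datasets = datasets, methods = methods, curation = curation,
                 cliffs = cliffs, split = split, grids = grids,
                 master_seed = as.integer(master_seed), out_dir = out_dir),
            class = "run_config")
}

.method_label <- function(algorithm, descriptor) {
  paste(algorithm, descriptor, sep = "_")
}

#' Run the full benchmark
#'
#' For every dataset: curate, detect cliffs, cluster and split; for every
#' method: featurize (real-valued kinds standardized with training
#' statistics), tune by cross-validation, refit, predict the test set and
#' score RMSE and cliff RMSE. Returns the benchmark table plus all
#' intermediate artifacts and a manifest of derived seeds.
#'
#' @param config a [run_config()].
#' @return list of class `benchmark_run`: `table` ([benchmark_table()]),
#'   `datasets` (per-dataset artifacts), `ranking` (a [pca_ranking()], when
#'   at least 2 methods and 2 datasets), `failure_modes`, `manifest`.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ms <- config$master_seed
  manifest <- list(master_seed = ms, config_hash = derive_seed(
    ms, paste(names(config$datasets), collapse = ","),
    paste(config$methods$algorithm, config$methods$descriptor,
          collapse = ",")))
  results <- list()
  artifacts <- list()
  for (ds in names(config$datasets)) {
    raw <- config$datasets[[ds]]
    cur <- curate_dataset(raw, config$curation)
    if (!nrow(cur$data)) {
      stop("dataset '", ds, "': curation produced an empty dataset",
           call. = FALSE)
    }
    pairs <- find_cliff_pairs(cur$data, config$cliffs)
    ann <- annotate_cliffs(cur$data, pairs)
    split_cfg <- config$split
    split_cfg$seed <- derive_seed(ms, "split", ds)
    assignment <- split_dataset(cur$data, ann$is_cliff, split_cfg)
    tr <- assignment$split == "train"
    te <- assignment$split == "test"

    desc_cache <- list()
    for (mi in seq_len(nrow(config$methods))) {
      algo <- config$methods$algorithm[mi]
      kind <- config$methods$descriptor[mi]
      if (is.null(desc_cache[[kind]])) {
        desc_cache[[kind]] <- descriptor_matrix(
          cur$data$smiles, kind, seed = derive_seed(ms, "conf", ds))
      }
      m <- desc_cache[[kind]]
      ok <- !apply(m, 1, anyNA)
      xtr <- m[tr & ok, , drop = FALSE]
      xte <- m[te & ok, , drop = FALSE]
      if (!descriptor_is_binary(kind)) {
        st <- standardize_descriptors(xtr, xte, kind = kind)
        xtr <- st$train
        xte <- st$test
      }
      ytr <- cur$data$y[tr & ok]
      yte <- cur$data$y[te & ok]
      grid <- config$grids[[algo]]
      model <- tune_and_fit(xtr, ytr, algorithm = algo, grid = grid,
                            cliff_labels = ann$is_cliff[tr & ok],
                            seed = derive_seed(ms, "fit", ds, algo, kind))
      pred <- prediction_set(yte, predict(model, xte),
                             ann$is_cliff[te & ok])
      results[[length(results) + 1L]] <- data.frame(
        method = .method_label(algo, kind), dataset = ds,
        rmse = rmse(pred),
        rmse_cliff = if (pred$n_c > 0) rmse_cliff(pred) else NA_real_,
        stringsAsFactors = FALSE)
      artifacts[[ds]]$predictions[[.method_label(algo, kind)]] <- pred
      artifacts[[ds]]$models[[.method_label(algo, kind)]] <- model
    }
    artifacts[[ds]]$curated <- cur
    artifacts[[ds]]$pairs <- pairs
    artifacts[[ds]]$annotation <- ann
    artifacts[[ds]]$assignment <- assignment
    artifacts[[ds]]$n_train <- sum(tr)
    manifest$seeds[[ds]] <- c(split = derive_seed(ms, "split", ds),
                              conf = derive_seed(ms, "conf", ds))
  }
  table <- benchmark_table(do.call(rbind, results))
  ranking <- NULL
  failure <- NULL
  n_methods <- length(unique(table$method))
  n_ds <- length(unique(table$dataset))
  if (n_methods >= 2L && n_ds >= 2L && !anyNA(table$rmse_cliff)) {
    ranking <- pca_ranking(table)
    sizes <- vapply(artifacts, `[[`, numeric(1), "n_train")
    failure <- failure_mode_analysis(table, train_sizes = sizes)
  }
  run <- structure(list(table = table, datasets = artifacts,
                        ranking = ranking, failure_modes = failure,
                        manifest = manifest),
                   class = "benchmark_run")
  if (!is.null(config$out_dir)) write_benchmark_run(run, config$out_dir)
  run
}

#' @export
print.benchmark_run <- function(x, ...) {
  cat("cliffbench benchmark run\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Write the artifacts of a benchmark run to a directory
#'
#' @param run a `benchmark_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$table, file.path(dir, "benchmark_table.csv"),
                   row.names = FALSE)
  for (ds in names(run$datasets)) {
    art <- run$datasets[[ds]]
    write_curated_csv(art$curated, file.path(dir, paste0(ds, "_curated.csv")))
    utils::write.csv(art$pairs, file.path(dir, paste0(ds, "_cliff_pairs.csv")),
                     row.names = FALSE)
    ann_df <- data.frame(smiles = art$curated$data$smiles,
                         cliff_mol = as.integer(art$annotation$is_cliff),
                         n_partners = art$annotation$n_partners,
                         cluster = art$assignment$cluster,
                         split = art$assignment$split)
    utils::write.csv(ann_df, file.path(dir, paste0(ds, "_molecules.csv")),
                     row.names = FALSE)
  }
  if (!is.null(run$ranking)) {
    utils::write.csv(run$ranking$coords, file.path(dir, "pca_ranking.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
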