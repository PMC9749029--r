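#' @title Cliff-stratified train/test splitting
#' @description Molecules are clustered by structure (spectral clustering on
#' an ECFP Tanimoto affinity matrix, five clusters by default); inside every
#' cluster an 80/20 train/test split is drawn, stratified on the cliff label
#' so that cliff and non-cliff proportions carry over to both sides. An
#' audit compares train and test descriptor-space neighbourhood distances
#' with a Mann-Whitney U test per descriptor kind (Benjamini-Hochberg
#' corrected).
#' @name splitting
NULL

#' Split configuration
#'
#' @param n_clusters number of spectral clusters.
#' @param test_fraction fraction of each cluster-stratum assigned to test.
#' @param seed random seed for clustering initialization and sampling.
#' @param gaussian_affinity if `TRUE`, apply a Gaussian transform
#'   `exp(-d^2 / (2 sigma^2))` of the Tanimoto distance instead of using the
#'   Tanimoto similarity itself as the affinity.
#' @param sigma bandwidth of the optional Gaussian transform.
#' @return list of class `split_config`.
#' @export
split_config <- function(n_clusters = 5L, test_fraction = 0.2, seed = 1L,
                         gaussian_affinity = FALSE, sigma = 1.0) {
  stopifnot(n_clusters >= 1, test_fraction > 0, test_fraction < 1)
  structure(list(n_clusters = as.integer(n_clusters),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 gaussian_affinity = gaussian_affinity, sigma = sigma),
            class = "split_config")
}

#' Tanimoto affinity matrix
#'
#' @param fp binary fingerprint matrix (molecules x bits).
#' @param cfg a [split_config()]; controls the optional Gaussian transform.
#' @return symmetric affinity matrix with unit diagonal.
#' @export
tanimoto_affinity <- function(fp, cfg = split_config()) {
  if (nrow(fp) < cfg$n_clusters) {
    stop("TOO_FEW: need at least ", cfg$n_clusters, " molecules", call. = FALSE)
  }
  sim <- tanimoto_matrix(fp)
  if (cfg$gaussian_affinity) {
    d <- 1 - sim
    sim <- exp(-d^2 / (2 * cfg$sigma^2))
  }
  sim
}

#' Spectral clustering of an affinity matrix
#'
#' Normalized spectral clustering (Ng-Jordan-Weiss): the top eigenvectors of
#' the symmetrically normalized affinity are row-normalized and clustered
#' with k-means. Deterministic for a given seed.
#'
#' @param affinity symmetric non-negative matrix.
#' @param cfg a [split_config()].
#' @return integer vector of cluster ids in `1..n_clusters`.
#' @export
spectral_cluster <- function(affinity, cfg = split_config()) {
  n <- nrow(affinity)
  k <- cfg$n_clusters
  if (n < k) stop("TOO_FEW: fewer molecules than clusters", call. = FALSE)
  if (k == 1L) return(rep(1L, n))
  d <- rowSums(affinity)
  d[d <= 0] <- 1e-12
  dis <- 1 / sqrt(d)
  lsym <- affinity * tcrossprod(dis)
  eg <- eigen(lsym, symmetric = TRUE)
  u <- eg$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  norms[norms == 0] <- 1
  u <- u / norms
  with_seed(cfg$seed, {
    km <- stats::kmeans(u, centers = k, nstart = 20L, iter.max = 100L)
  })
  as.integer(km$cluster)
}

# Largest-remainder allocation of test counts across strata of one cluster.
# Guarantees at least one test molecule per cluster of size >= 2.
.allocate_test <- function(stratum_sizes, frac) {
  quota <- stratum_sizes * frac
  base <- floor(quota)
  seats <- round(sum(quota)) - sum(base)
  if (seats > 0) {
    rem <- quota - base
    ord <- order(-rem, seq_along(rem))
    take <- ord[seq_len(seats)]
    base[take] <- base[take] + 1
  }
  if (sum(base) == 0 && sum(stratum_sizes) >= 2) {
    big <- which.max(stratum_sizes)
    base[big] <- 1
  }
  pmin(base, stratum_sizes)
}

#' Cliff-stratified train/test split
#'
#' For each cluster and each cliff stratum (yes/no) a seeded random
#' `test_fraction` sample is assigned to the test set, with
#' largest-remainder rounding across the strata of the cluster.
#'
#' @param cluster_ids integer cluster assignment per molecule.
#' @param cliff_labels logical cliff-compound label per molecule.
#' @param cfg a [split_config()].
#' @return object of class `split_assignment`: data.frame with columns
#'   `cluster` and `split` ("train"/"test"), plus attribute `seed`.
#' @export
stratified_split <- function(cluster_ids, cliff_labels, cfg = split_config()) {
  n <- length(cluster_ids)
  stopifnot(length(cliff_labels) == n)
  membership <- rep("train", n)
  with_seed(cfg$seed, {
    for (cl in sort(unique(cluster_ids))) {
      members <- which(cluster_ids == cl)
      if (length(members) < 2L) next
      strata <- base::split(members, cliff_labels[members])
      sizes <- lengths(strata)
      alloc <- .allocate_test(sizes, cfg$test_fraction)
      for (s in seq_along(strata)) {
        if (alloc[s] > 0) {
          grp <- strata[[s]]
          take <- grp[sample.int(length(grp), alloc[s])]
          membership[take] <- "test"
        }
      }
    }
  })
  out <- data.frame(cluster = as.integer(cluster_ids), split = membership,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- cfg$seed
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Cluster a dataset and draw the stratified split
#'
#' Convenience wrapper: ECFP fingerprints, Tanimoto affinity, spectral
#' clustering, stratified split.
#'
#' @param data curated data.frame with a `smiles` column.
#' @param cliff_labels logical vector from [annotate_cliffs()].
#' @param cfg a [split_config()].
#' @return a `split_assignment` (see [stratified_split()]).
#' @export
split_dataset <- function(data, cliff_labels, cfg = split_config()) {
  fp <- compute_ecfp(data$smiles)
  aff <- tanimoto_affinity(fp, cfg)
  cl <- spectral_cluster(aff, cfg)
  stratified_split(cl, cliff_labels, cfg)
}

# Mean distance of each row of `q` to its k nearest rows of `ref`,
# excluding self-matches when `exclude_self`.
.mean_knn_dist <- function(dmat, k, exclude_self = FALSE) {
  apply(dmat, 1, function(row) {
    if (exclude_self) row <- row[-which.min(row)]
    mean(sort(row)[seq_len(min(k, length(row)))])
  })
}

.pairwise_dist <- function(a, b, binary) {
  if (binary) {
    inter <- tcrossprod(a, b)
    pa <- rowSums(a)
    pb <- rowSums(b)
    uni <- outer(pa, pb, "+") - inter
    1 - ifelse(uni == 0, 1, inter / pmax(uni, 1))
  } else {
    n2a <- rowSums(a^2)
    n2b <- rowSums(b^2)
    d2 <- outer(n2a, n2b, "+") - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  }
}

#' Audit descriptor-space similarity of a train/test split
#'
#' For each descriptor kind, compares (A) the mean distance of every
#' training molecule to its five nearest training neighbours (self
#' excluded) with (B) the mean distance of every test molecule to its five
#' nearest training neighbours, using a two-sided Mann-Whitney U test.
#' P-values are Benjamini-Hochberg adjusted across kinds; kinds with
#' adjusted p < 0.05 are flagged as distribution-shifted.
#'
#' Binary kinds use the Jaccard (1 - Tanimoto) distance; real-valued kinds
#' are standardized with training statistics and use Euclidean distance.
#'
#' @param descriptors named list of descriptor matrices (all molecules),
#'   names in `DESCRIPTOR_KINDS`.
#' @param assignment a `split_assignment`.
#' @param k number of nearest neighbours.
#' @param fdr false-discovery-rate level.
#' @return data.frame of class `split_audit` with one row per kind: U
#'   statistic, raw and adjusted p-value, flagged.
#' @export
audit_split <- function(descriptors, assignment, k = 5L, fdr = 0.05) {
  tr <- assignment$split == "train"
  te <- assignment$split == "test"
  if (sum(tr) < k + 1L) stop("TOO_FEW: need more than ", k,
                             " training molecules", call. = FALSE)
  rows <- lapply(names(descriptors), function(kind) {
    m <- descriptors[[kind]]
    binary <- descriptor_is_binary(kind)
    mtr <- m[tr, , drop = FALSE]
    mte <- m[te, , drop = FALSE]
    ok_tr <- !apply(mtr, 1, anyNA)
    ok_te <- !apply(mte, 1, anyNA)
    mtr <- mtr[ok_tr, , drop = FALSE]
    mte <- mte[ok_te, , drop = FALSE]
    if (!binary) {
      st <- standardize_descriptors(mtr, mte, kind = kind)
      mtr <- st$train
      mte <- st$test
    }
    a <- .mean_knn_dist(.pairwise_dist(mtr, mtr, binary), k,
                        exclude_self = TRUE)
    b <- .mean_knn_dist(.pairwise_dist(mte, mtr, binary), k)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(kind = kind, U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$flagged <- out$p_adj < fdr
  class(out) <- c("split_audit", "data.frame")
  out
}
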