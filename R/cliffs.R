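#' @title Activity-cliff detection
#' @description An activity cliff is a pair of structurally highly similar
#' molecules with a large potency difference. Structural similarity is a
#' soft consensus over three measures - substructure (Tanimoto on ECFP),
#' scaffold (Tanimoto on ECFP of the Bemis-Murcko frameworks) and SMILES
#' string (scaled Levenshtein converted to 1 - distance) - any one of which
#' at or above the threshold qualifies the pair; the potency criterion is a
#' fold change of at least 10 in nM units (equivalently at least 1 p-unit).
#' @name cliffs
NULL

#' Cliff-detection configuration
#'
#' @param similarity_threshold minimum similarity (any of the three
#'   measures) for a pair to count as structurally similar.
#' @param fold_threshold minimum activity fold change (max/min, nM) for a
#'   similar pair to count as a cliff. Both thresholds are inclusive.
#' @return list of class `cliff_config`.
#' @export
cliff_config <- function(similarity_threshold = 0.9, fold_threshold = 10.0) {
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1,
            fold_threshold > 1)
  structure(list(similarity_threshold = similarity_threshold,
                 fold_threshold = fold_threshold),
            class = "cliff_config")
}

#' Tanimoto coefficient of two binary vectors
#'
#' @param a,b equal-length 0/1 vectors.
#' @return |a AND b| / |a OR b|; 1.0 when both vectors are all-zero.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    stop("LENGTH_MISMATCH: fingerprint lengths differ", call. = FALSE)
  }
  u <- sum(a | b)
  if (u == 0) return(1.0)
  sum(a & b) / u
}

# All-pairs Tanimoto similarity of the rows of a binary matrix, via the
# bit-count identity |A&B| = a.b for 0/1 vectors.
tanimoto_matrix <- function(fp) {
  fp <- as.matrix(fp)
  inter <- tcrossprod(fp)
  pop <- diag(inter)
  uni <- outer(pop, pop, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  diag(sim) <- 1
  sim
}

#' Scaffold similarity of two molecules
#'
#' Tanimoto coefficient on the ECFPs of the Bemis-Murcko frameworks. By
#' convention two acyclic molecules (empty frameworks) have similarity 1.0
#' and an empty framework has similarity 0.0 against any non-empty one.
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @return similarity in `[0, 1]`.
#' @export
scaffold_similarity <- function(smiles_a, smiles_b) {
  fp <- scaffold_fingerprints(c(smiles_a, smiles_b))
  scaffold_tanimoto_pair(fp, 1L, 2L)
}

# Batch scaffold fingerprints: returns list(fp = matrix or NULL rows marker,
# empty = logical) where empty marks acyclic molecules.
scaffold_fingerprints <- function(smiles, nbits = 1024L) {
  blocks <- ob_molblock(smiles)
  n <- length(smiles)
  empty <- logical(n)
  scaf_mols <- vector("list", n)
  for (k in seq_len(n)) {
    if (is.na(blocks[k])) {
      stop("PARSE_ERROR: could not parse SMILES '", smiles[k], "'",
           call. = FALSE)
    }
    mol <- parse_molblock(blocks[k])
    fw <- murcko_framework(mol)
    if (is.null(fw)) empty[k] <- TRUE else scaf_mols[[k]] <- fw
  }
  fp <- matrix(0L, n, nbits)
  todo <- which(!empty)
  if (length(todo)) {
    sdf <- vapply(seq_along(todo), function(q) {
      paste0(write_molblock(scaf_mols[[todo[q]]], title = as.character(q)),
             "\n$$$$")
    }, character(1))
    got <- ob_fingerprint(sdf = sdf, type = "ECFP4", nbits = nbits)
    fp[todo, ] <- got
  }
  list(fp = fp, empty = empty)
}

scaffold_tanimoto_pair <- function(sf, i, j) {
  if (sf$empty[i] && sf$empty[j]) return(1.0)
  if (sf$empty[i] || sf$empty[j]) return(0.0)
  tanimoto(sf$fp[i, ], sf$fp[j, ])
}

#' SMILES string similarity
#'
#' One minus the Levenshtein edit distance scaled by the longer string
#' length. Two empty strings have similarity 1.0 by convention.
#'
#' @param smiles_a,smiles_b character strings (canonical SMILES).
#' @return similarity in `[0, 1]`.
#' @export
smiles_similarity <- function(smiles_a, smiles_b) {
  la <- nchar(smiles_a)
  lb <- nchar(smiles_b)
  if (la == 0 && lb == 0) return(1.0)
  d <- utils::adist(smiles_a, smiles_b)[1, 1]
  1 - d / max(la, lb)
}

#' Activity fold change
#'
#' @param activity_a_nM,activity_b_nM positive activities in nM.
#' @return max/min ratio, always >= 1.
#' @export
fold_change <- function(activity_a_nM, activity_b_nM) {
  if (any(c(activity_a_nM, activity_b_nM) <= 0)) {
    stop("NONPOSITIVE: activities must be > 0", call. = FALSE)
  }
  pmax(activity_a_nM, activity_b_nM) / pmin(activity_a_nM, activity_b_nM)
}

#' Find activity-cliff pairs in a curated dataset
#'
#' Evaluates all unordered molecule pairs: a pair is a cliff when at least
#' one of the three similarity measures reaches the similarity threshold and
#' the activity fold change reaches the fold threshold. All three similarity
#' values are recorded for every returned pair.
#'
#' @param data data.frame with columns `smiles` (unique canonical SMILES)
#'   and `exp_mean_nM`.
#' @param cfg a [cliff_config()].
#' @return data.frame of class `cliff_pairs` with columns `i`, `j` (i < j),
#'   `sim_substructure`, `sim_scaffold`, `sim_smiles`, `fold_change`, and
#'   logical columns `by_substructure`, `by_scaffold`, `by_smiles`.
#' @export
find_cliff_pairs <- function(data, cfg = cliff_config()) {
  n <- nrow(data)
  empty <- data.frame(i = integer(0), j = integer(0),
                      sim_substructure = numeric(0), sim_scaffold = numeric(0),
                      sim_smiles = numeric(0), fold_change = numeric(0),
                      by_substructure = logical(0), by_scaffold = logical(0),
                      by_smiles = logical(0))
  class(empty) <- c("cliff_pairs", "data.frame")
  if (n < 2L) return(empty)
  stopifnot(!anyDuplicated(data$smiles))

  fp <- compute_ecfp(data$smiles)
  sim_sub <- tanimoto_matrix(fp)
  sf <- scaffold_fingerprints(data$smiles)
  sim_scaf <- tanimoto_matrix(sf$fp)
  # empty-framework conventions
  if (any(sf$empty)) {
    sim_scaf[sf$empty, ] <- 0
    sim_scaf[, sf$empty] <- 0
    sim_scaf[sf$empty, sf$empty] <- 1
  }
  dl <- utils::adist(data$smiles)
  len <- nchar(data$smiles)
  maxlen <- outer(len, len, pmax)
  sim_smi <- 1 - dl / pmax(maxlen, 1)
  diag(sim_smi) <- 1

  act <- data$exp_mean_nM
  fold <- outer(act, act, pmax) / outer(act, act, pmin)

  thr <- cfg$similarity_threshold
  pass_sim <- sim_sub >= thr | sim_scaf >= thr | sim_smi >= thr
  hit <- pass_sim & fold >= cfg$fold_threshold
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  out <- data.frame(
    i = idx[, 1], j = idx[, 2],
    sim_substructure = sim_sub[idx],
    sim_scaffold = sim_scaf[idx],
    sim_smiles = sim_smi[idx],
    fold_change = fold[idx],
    by_substructure = sim_sub[idx] >= thr,
    by_scaffold = sim_scaf[idx] >= thr,
    by_smiles = sim_smi[idx] >= thr
  )
  class(out) <- c("cliff_pairs", "data.frame")
  out
}

#' Label cliff compounds
#'
#' Molecules participating in at least one activity-cliff pair are labelled
#' activity-cliff compounds.
#'
#' @param data curated data.frame (defines the molecule count and order).
#' @param pairs result of [find_cliff_pairs()] on the same data.
#' @return list of class `cliff_annotation`: `is_cliff` (logical vector),
#'   `n_partners` (integer vector), `pct_cliff`, `mean_partners` and
#'   `sd_partners` (over labelled molecules).
#' @export
annotate_cliffs <- function(data, pairs) {
  n <- nrow(data)
  n_partners <- tabulate(c(pairs$i, pairs$j), nbins = n)
  is_cliff <- n_partners >= 1L
  labelled <- n_partners[is_cliff]
  structure(list(
    is_cliff = is_cliff,
    n_partners = n_partners,
    pct_cliff = if (n > 0) 100 * sum(is_cliff) / n else 0,
    mean_partners = if (length(labelled)) mean(labelled) else NA_real_,
    sd_partners = if (length(labelled) > 1) stats::sd(labelled) else NA_real_
  ), class = "cliff_annotation")
}

#' @export
print.cliff_annotation <- function(x, ...) {
  cat(sprintf("Cliff annotation: %d/%d molecules (%.1f%%) in >=1 cliff pair\n",
              sum(x$is_cliff), length(x$is_cliff), x$pct_cliff))
  if (!is.na(x$mean_partners)) {
    cat(sprintf("  partners per cliff compound: %.2f +/- %.2f\n",
                x$mean_partners,
                ifelse(is.na(x$sd_partners), 0, x$sd_partners)))
  }
  invisible(x)
}
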