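#' @title Bioactivity curation pipeline
#' @description Transforms raw per-target bioactivity tables (SMILES +
#' activity in nM, replicate rows allowed) into curated datasets: validity
#' filtering, sanitization/neutralization, replicate aggregation with Dixon's
#' Q outlier screening and a 1-log standard-deviation cutoff, p-unit
#' conversion, and removal of stereo-duplicate structures.
#' @name curation
NULL

#' Curation configuration
#'
#' @param dixon_alpha significance level of Dixon's Q outlier test applied to
#'   replicate activity annotations. Only 0.05 is tabulated.
#' @param sd_cutoff_log maximum allowed standard deviation (log10 nM units)
#'   of the replicate annotations of one molecule.
#' @param ecfp_radius,ecfp_nbits fingerprint settings used for
#'   stereo-duplicate detection.
#' @return list of class `curation_config`.
#' @export
curation_config <- function(dixon_alpha = 0.05, sd_cutoff_log = 1.0,
                            ecfp_radius = 2L, ecfp_nbits = 1024L) {
  stopifnot(dixon_alpha > 0, dixon_alpha < 1, sd_cutoff_log >= 0)
  structure(list(dixon_alpha = dixon_alpha, sd_cutoff_log = sd_cutoff_log,
                 ecfp_radius = as.integer(ecfp_radius),
                 ecfp_nbits = as.integer(ecfp_nbits)),
            class = "curation_config")
}

#' Convert activities between nM and p-units
#'
#' p-unit activity is the negative decadic logarithm of the molar
#' concentration: p = -log10(nM * 1e-9).
#'
#' @param nM activity in nanomolar.
#' @param p activity in p-units (pKi / pEC50).
#' @return numeric vector.
#' @export
p_from_nM <- function(nM) -log10(nM * 1e-9)

#' @rdname p_from_nM
#' @export
nM_from_p <- function(p) 10^(9 - p)

# Two-sided critical values of Dixon's Q (r10) at alpha = 0.05, n = 3..30
# (Rorabacher, Anal. Chem. 1991).
.dixon_q05 <- c(
  0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466, 0.444, 0.426,
  0.410, 0.396, 0.384, 0.374, 0.365, 0.356, 0.349, 0.342, 0.337, 0.331,
  0.326, 0.321, 0.317, 0.312, 0.308, 0.305, 0.301, 0.298
)

#' Dixon's Q test for a single outlier
#'
#' Tests the more extreme of the smallest/largest value of a replicate set.
#' The classical validity range is 3 <= n <= 30; outside it the test is not
#' applicable and the caller should skip it.
#'
#' @param values numeric vector of replicate measurements.
#' @param alpha significance level; only 0.05 is tabulated.
#' @return integer index of the flagged outlier, or `NULL` when no value is
#'   flagged (including the degenerate zero-range case).
#' @export
dixon_q_outlier <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L || n > 30L) {
    stop("Dixon's Q test applies to 3 <= n <= 30 values (got ", n, ")",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(alpha, 0.05))) {
    stop("only alpha = 0.05 critical values are tabulated", call. = FALSE)
  }
  rng <- range(values)
  span <- rng[2] - rng[1]
  if (span <= 0) return(NULL)
  s <- sort(values)
  gap_low <- s[2] - s[1]
  gap_high <- s[n] - s[n - 1]
  if (gap_high >= gap_low) {
    q <- gap_high / span
    idx <- which.max(values)
  } else {
    q <- gap_low / span
    idx <- which.min(values)
  }
  if (q > .dixon_q05[n - 2L]) idx else NULL
}

#' Sanitize and neutralize one SMILES string
#'
#' Parses, neutralizes (+1/-1 centres) and canonicalizes a SMILES string.
#' Multi-fragment records (salts, mixtures) and unparseable strings are
#' rejected.
#'
#' @param smiles a single SMILES string.
#' @return canonical SMILES string, or an object of class
#'   `curation_rejection` with a `reason` of "REJECT_PARSE" or
#'   "REJECT_MULTIFRAGMENT".
#' @export
sanitize_and_neutralize <- function(smiles) {
  res <- sanitize_batch(smiles)
  if (is.na(res$canonical[1])) {
    structure(list(reason = res$reason[1], smiles = smiles),
              class = "curation_rejection")
  } else {
    res$canonical[1]
  }
}

# Vectorized sanitization; returns data.frame(canonical, reason).
sanitize_batch <- function(smiles) {
  n <- length(smiles)
  reason <- rep(NA_character_, n)
  multi <- !is.na(smiles) & grepl(".", smiles, fixed = TRUE)
  reason[multi] <- "REJECT_MULTIFRAGMENT"
  todo <- !multi
  canonical <- rep(NA_character_, n)
  if (any(todo)) {
    canonical[todo] <- ob_canonical(smiles[todo], neutralize = TRUE)
  }
  reason[todo & is.na(canonical)] <- "REJECT_PARSE"
  data.frame(canonical = canonical, reason = reason, stringsAsFactors = FALSE)
}

#' Aggregate replicate annotations of one molecule
#'
#' Applies Dixon's Q outlier removal (on the nM scale, when 3-30 replicates
#' are present), then computes the arithmetic mean in nM and converts it to
#' p-units. The molecule is rejected when the standard deviation of the
#' log10(nM) annotations used for the mean exceeds the cutoff.
#'
#' @param activities_nM numeric vector of replicate activities (nM).
#' @param cfg a [curation_config()].
#' @return list with `mean_nM`, `p`, `n_replicates`, `sd_log`,
#'   `outlier_removed` (index or NULL), or a `curation_rejection` with
#'   reason "REJECT_SD".
#' @export
aggregate_replicates <- function(activities_nM, cfg = curation_config()) {
  stopifnot(length(activities_nM) >= 1, all(activities_nM > 0))
  vals <- activities_nM
  outlier <- NULL
  if (length(vals) >= 3L && length(vals) <= 30L && diff(range(vals)) > 0) {
    outlier <- dixon_q_outlier(vals, cfg$dixon_alpha)
    if (!is.null(outlier)) vals <- vals[-outlier]
  }
  sd_log <- if (length(vals) > 1L) stats::sd(log10(vals)) else 0
  if (sd_log > cfg$sd_cutoff_log) {
    return(structure(list(reason = "REJECT_SD", sd_log = sd_log),
                     class = "curation_rejection"))
  }
  mean_nM <- mean(vals)
  list(mean_nM = mean_nM, p = p_from_nM(mean_nM),
       n_replicates = length(vals), sd_log = sd_log,
       outlier_removed = outlier)
}

#' Remove stereo-duplicate records
#'
#' Groups of two or more records with distinct canonical SMILES but
#' bit-identical ECFPs (radius 2, 1024 bits) indicate inconsistent
#' stereochemistry annotation; all members of such groups are removed.
#'
#' @param data data.frame with a `smiles` column of canonical SMILES.
#' @param cfg a [curation_config()].
#' @return data.frame restricted to retained rows (order preserved), with
#'   attribute `removed` holding the removed SMILES.
#' @export
remove_stereo_duplicates <- function(data, cfg = curation_config()) {
  if (!nrow(data)) {
    attr(data, "removed") <- character(0)
    return(data)
  }
  fp <- ob_fingerprint(data$smiles, "ECFP4", nbits = cfg$ecfp_nbits)
  key <- apply(fp, 1, function(b) paste(which(b == 1L), collapse = ","))
  key[apply(fp, 1, anyNA)] <- NA
  dup_groups <- split(seq_len(nrow(data)), key)
  drop <- unlist(lapply(dup_groups, function(ix) {
    if (length(unique(data$smiles[ix])) >= 2L) ix else integer(0)
  }), use.names = FALSE)
  keep <- setdiff(seq_len(nrow(data)), drop)
  out <- data[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data$smiles[sort(drop)]
  out
}

#' Curate a raw bioactivity table
#'
#' Runs the full preparation pipeline, in order: validity-flag filter,
#' sanitization/neutralization (rejecting salts and unparseable strings),
#' grouping by canonical SMILES, replicate aggregation (Dixon's Q + mean +
#' p-unit conversion + SD cutoff), and stereo-duplicate removal.
#'
#' @param raw data.frame with columns `smiles`, `activity_nM` and optionally
#'   `validity_flag` (non-empty value = doubtful record, removed).
#' @param cfg a [curation_config()].
#' @return object of class `curated_dataset`: a list with `data` (data.frame:
#'   smiles, exp_mean_nM, y, n_replicates, sd_log) and `report` (named counts
#'   and percentages removed per stage).
#' @export
curate_dataset <- function(raw, cfg = curation_config()) {
  stopifnot(is.data.frame(raw), all(c("smiles", "activity_nM") %in% names(raw)))
  n0 <- nrow(raw)
  report <- list(n_input = n0)

  # stage 1: validity flags
  if ("validity_flag" %in% names(raw)) {
    flagged <- !is.na(raw$validity_flag) & nzchar(trimws(raw$validity_flag))
  } else {
    flagged <- rep(FALSE, n0)
  }
  report$n_invalid_flag <- sum(flagged)
  raw <- raw[!flagged, , drop = FALSE]

  # stage 2: sanitize / neutralize / canonicalize
  san <- sanitize_batch(raw$smiles)
  report$n_reject_parse <- sum(san$reason == "REJECT_PARSE", na.rm = TRUE)
  report$n_reject_multifragment <-
    sum(san$reason == "REJECT_MULTIFRAGMENT", na.rm = TRUE)
  keep <- !is.na(san$canonical)
  raw <- raw[keep, , drop = FALSE]
  raw$canonical <- san$canonical[keep]

  # stage 3: group by canonical SMILES, aggregate replicates
  groups <- split(raw$activity_nM, raw$canonical)
  agg <- lapply(groups, aggregate_replicates, cfg = cfg)
  rejected_sd <- vapply(agg, inherits, logical(1), "curation_rejection")
  report$n_reject_sd <- sum(rejected_sd)
  report$n_dixon_outliers <- sum(vapply(agg, function(a) {
    !inherits(a, "curation_rejection") && !is.null(a$outlier_removed)
  }, logical(1)))
  # keep first-appearance order of canonical SMILES
  order_first <- unique(raw$canonical)
  kept <- order_first[!rejected_sd[order_first]]
  data <- data.frame(
    smiles = kept,
    exp_mean_nM = vapply(agg[kept], `[[`, numeric(1), "mean_nM"),
    y = vapply(agg[kept], `[[`, numeric(1), "p"),
    n_replicates = vapply(agg[kept], `[[`, numeric(1), "n_replicates"),
    sd_log = vapply(agg[kept], `[[`, numeric(1), "sd_log"),
    row.names = NULL, stringsAsFactors = FALSE
  )

  # stage 4: stereo duplicates
  data <- remove_stereo_duplicates(data, cfg)
  report$n_stereo_duplicates <- length(attr(data, "removed"))
  report$stereo_duplicates_removed <- attr(data, "removed")
  attr(data, "removed") <- NULL
  report$n_output <- nrow(data)
  report$pct_removed <- if (n0 > 0) 100 * (1 - nrow(data) / n0) else 0

  if (!nrow(data)) {
    warning("curation removed every record (EMPTY_RESULT)")
  }
  structure(list(data = data, report = report, config = cfg),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  r <- x$report
  cat("Curated bioactivity dataset\n")
  cat(sprintf("  input records:      %d\n", r$n_input))
  cat(sprintf("  invalid-flag rows:  %d\n", r$n_invalid_flag))
  cat(sprintf("  parse rejections:   %d (+%d multi-fragment)\n",
              r$n_reject_parse, r$n_reject_multifragment))
  cat(sprintf("  Dixon outliers:     %d replicate values removed\n",
              r$n_dixon_outliers))
  cat(sprintf("  SD > cutoff:        %d molecules removed\n", r$n_reject_sd))
  cat(sprintf("  stereo duplicates:  %d molecules removed\n",
              r$n_stereo_duplicates))
  cat(sprintf("  curated molecules:  %d\n", r$n_output))
  invisible(x)
}

#' Read / write the curated-dataset CSV dialect
#'
#' The on-disk format uses the column vocabulary `smiles`,
#' `exp_mean [nM]`, `y`; raw input tables additionally understand
#' `data_validity_comment`.
#'
#' @param path CSV path.
#' @return for `read_raw_csv`, a data.frame with columns `smiles`,
#'   `activity_nM`, `validity_flag`.
#' @export
read_raw_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("smiles" %in% names(df))
  act_col <- intersect(c("exp_mean [nM]", "activity_nM"), names(df))[1]
  stopifnot(!is.na(act_col))
  out <- data.frame(smiles = df$smiles,
                    activity_nM = as.numeric(df[[act_col]]),
                    stringsAsFactors = FALSE)
  if ("data_validity_comment" %in% names(df)) {
    out$validity_flag <- df$data_validity_comment
  }
  out
}

#' @rdname read_raw_csv
#' @param curated a `curated_dataset` (or its `$data`).
#' @export
write_curated_csv <- function(curated, path) {
  data <- if (inherits(curated, "curated_dataset")) curated$data else curated
  out <- data.frame(smiles = data$smiles,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[["exp_mean [nM]"]] <- data$exp_mean_nM
  out[["y"]] <- data$y
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
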