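# Independent oracles, deliberately written as plain double loops /
# textbook dynamic programming so they share no code with the package
# internals they check.

oracle_tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- 0L
  uni <- 0L
  for (k in seq_along(a)) {
    if (a[k] == 1L && b[k] == 1L) inter <- inter + 1L
    if (a[k] == 1L || b[k] == 1L) uni <- uni + 1L
  }
  if (uni == 0L) 1 else inter / uni
}

oracle_levenshtein <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  na <- length(sa)
  nb <- length(sb)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1L] <- 0:na
  d[1L, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[na + 1L, nb + 1L]
}

# Brute-force cliff-pair detector: per-pair calls of the three scalar
# similarity functions plus the fold criterion, in a double loop.
oracle_cliff_pairs <- function(data, sim_threshold = 0.9, fold_threshold = 10) {
  n <- nrow(data)
  fp <- compute_ecfp(data$smiles)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s1 <- tanimoto(fp[i, ], fp[j, ])
      s2 <- scaffold_similarity(data$smiles[i], data$smiles[j])
      s3 <- smiles_similarity(data$smiles[i], data$smiles[j])
      fc <- fold_change(data$exp_mean_nM[i], data$exp_mean_nM[j])
      if (max(s1, s2, s3) >= sim_threshold && fc >= fold_threshold) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else matrix(integer(0), 0, 2)
}
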