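test_that("the affinity matrix is the pairwise Tanimoto similarity", {
  fp <- compute_ecfp(c("CCO", "CCO", "CCCO", "c1ccccc1", "CCN"))
  aff <- tanimoto_affinity(fp, split_config(n_clusters = 2))
  expect_equal(diag(aff), rep(1, 5))
  expect_equal(aff, t(aff))
  expect_equal(aff[1, 2], 1.0)  # duplicate fingerprints
  for (i in 1:5) for (j in 1:5) {
    expect_equal(aff[i, j], oracle_tanimoto(fp[i, ], fp[j, ]))
  }
  expect_error(tanimoto_affinity(fp[1:3, ], split_config(n_clusters = 5)),
               "TOO_FEW")
})

test_that("spectral clustering recovers planted scaffold families exactly", {
  fx <- clean_fixture()
  data <- fx$curated$data
  fam <- fx$truth$molecules$family[
    match(data$smiles, ob_canonical(fx$truth$molecules$smiles))]
  cfg <- split_config(n_clusters = length(unique(fam)), seed = 11)
  cl <- spectral_cluster(tanimoto_affinity(compute_ecfp(data$smiles), cfg),
                         cfg)
  # every cluster maps to exactly one family and vice versa
  tab <- table(fam, cl)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  cl2 <- spectral_cluster(tanimoto_affinity(compute_ecfp(data$smiles), cfg),
                          cfg)
  expect_identical(cl, cl2)
})

test_that("block-diagonal affinities cluster into their blocks", {
  blocks <- rep(1:5, each = 6)
  aff <- outer(blocks, blocks, function(a, b) ifelse(a == b, 1, 0.01))
  diag(aff) <- 1
  cl <- spectral_cluster(aff, split_config(n_clusters = 5, seed = 3))
  tab <- table(blocks, cl)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("stratified splitting preserves strata and cluster fractions", {
  # one cluster of 10 with 5 cliffs: 2 test molecules, one per stratum
  asg <- stratified_split(rep(1L, 10), rep(c(TRUE, FALSE), each = 5),
                          split_config(n_clusters = 1, seed = 4))
  expect_identical(sum(asg$split == "test"), 2L)
  expect_identical(sum(asg$split == "test" & rep(c(TRUE, FALSE), each = 5)),
                   1L)
  # plain 80/20 without cliffs
  asg2 <- stratified_split(rep(1L, 100), rep(FALSE, 100),
                           split_config(n_clusters = 1, seed = 4))
  expect_identical(sum(asg2$split == "test"), 20L)
  # reproducibility and partition
  asg3 <- stratified_split(rep(1L, 100), rep(FALSE, 100),
                           split_config(n_clusters = 1, seed = 4))
  expect_identical(asg2$split, asg3$split)
  expect_true(all(asg2$split %in% c("train", "test")))
})

test_that("cliff proportions carry over within the rounding bound", {
  fx <- cliff_model_fixture()
  tr <- fx$asg$split == "train"
  pct_tr <- 100 * mean(fx$ann$is_cliff[tr])
  pct_te <- 100 * mean(fx$ann$is_cliff[!tr])
  n_clusters <- length(unique(fx$asg$cluster))
  n_te <- sum(!tr)
  bound <- 100 * n_clusters / n_te  # one molecule per cluster-stratum
  expect_lt(abs(pct_tr - pct_te), bound + 1e-9)
  # every cluster of size >= 2 contributes at least one test molecule
  for (cl in unique(fx$asg$cluster)) {
    if (sum(fx$asg$cluster == cl) >= 2) {
      expect_gte(sum(fx$asg$cluster == cl & !tr), 1)
    }
  }
})

test_that("the split audit accepts exchangeable splits and flags shifted ones", {
  fx <- clean_fixture()
  data <- fx$curated$data
  pairs <- find_cliff_pairs(data)
  ann <- annotate_cliffs(data, pairs)
  desc <- list(ECFP = compute_ecfp(data$smiles),
               PHYSCHEM = compute_physchem(data$smiles))
  flags <- 0L; total <- 0L
  for (s in 1:20) {
    asg <- split_dataset(data, ann$is_cliff,
                         split_config(n_clusters = 4, seed = s))
    aud <- audit_split(desc, asg)
    flags <- flags + sum(aud$flagged)
    total <- total + nrow(aud)
  }
  expect_lte(flags / total, 0.10)
  # a test set from a disjoint scaffold family is flagged
  fam <- fx$truth$molecules$family[
    match(data$smiles, ob_canonical(fx$truth$molecules$smiles))]
  shifted <- data.frame(cluster = 1L,
                        split = ifelse(fam == fam[1], "test", "train"))
  aud <- audit_split(desc, shifted)
  expect_true(all(aud$flagged))
})
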