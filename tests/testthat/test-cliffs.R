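test_that("tanimoto handles the textbook cases and degenerate input", {
  a <- integer(10); a[c(1, 2, 3)] <- 1L
  b <- integer(10); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)  # |intersection| 2 / |union| 4
  expect_equal(tanimoto(a, a), 1.0)
  d <- integer(10); d[8:10] <- 1L
  expect_equal(tanimoto(a, d), 0.0)
  expect_equal(tanimoto(integer(5), integer(5)), 1.0)
  expect_error(tanimoto(a, b[1:5]), "LENGTH_MISMATCH")
})

test_that("similarity measures are symmetric, unit on self, and in [0,1]", {
  set.seed(8)
  smi <- clean_fixture()$curated$data$smiles[1:8]
  fp <- compute_ecfp(smi)
  for (r in 1:12) {
    i <- sample(8, 1); j <- sample(8, 1)
    s1 <- tanimoto(fp[i, ], fp[j, ])
    s2 <- scaffold_similarity(smi[i], smi[j])
    s3 <- smiles_similarity(smi[i], smi[j])
    expect_true(all(c(s1, s2, s3) >= 0 & c(s1, s2, s3) <= 1))
    expect_equal(s1, tanimoto(fp[j, ], fp[i, ]))
    expect_equal(s2, scaffold_similarity(smi[j], smi[i]))
    expect_equal(s3, smiles_similarity(smi[j], smi[i]))
    if (i == j) expect_equal(c(s1, s2, s3), c(1, 1, 1))
  }
})

test_that("scaffold similarity follows the framework conventions", {
  expect_equal(scaffold_similarity("Cc1ccccc1", "CCc1ccccc1"), 1.0)
  expect_equal(scaffold_similarity("CCOc1ccccc1", "CCOc1ccccc1"), 1.0)
  expect_lt(scaffold_similarity("Cc1ccccc1", "Cc1ccncc1"), 1.0)
  expect_equal(scaffold_similarity("CCO", "CCN"), 1.0)       # both acyclic
  expect_equal(scaffold_similarity("CCO", "c1ccccc1"), 0.0)  # empty vs ring
})

test_that("SMILES similarity equals 1 - scaled edit distance (DP oracle)", {
  expect_equal(smiles_similarity("CCO", "CCN"), 1 - 1 / 3)
  expect_equal(smiles_similarity("CCO", "CCO"), 1.0)
  expect_equal(smiles_similarity("", "C"), 0.0)
  expect_equal(smiles_similarity("", ""), 1.0)
  set.seed(5)
  alphabet <- c("C", "c", "O", "N", "(", ")", "1", "=", "F")
  for (r in 1:20) {
    a <- paste(sample(alphabet, sample(1:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(1:12, 1), replace = TRUE), collapse = "")
    expect_equal(smiles_similarity(a, b),
                 1 - oracle_levenshtein(a, b) / max(nchar(a), nchar(b)))
  }
})

test_that("fold change is the max/min activity ratio", {
  expect_equal(fold_change(5, 500), 100)
  expect_equal(fold_change(500, 5), 100)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(5, 40), 8)
  expect_error(fold_change(-1, 5), "NONPOSITIVE")
})

test_that("a ten-fold change corresponds exactly to a one-log p gap", {
  set.seed(13)
  for (r in 1:50) {
    a <- 10^runif(1, -2, 7)
    b <- 10^runif(1, -2, 7)
    dp <- abs(p_from_nM(a) - p_from_nM(b))
    expect_equal(fold_change(a, b) >= 10 - 1e-9, dp >= 1 - 1e-9)
    expect_equal(log10(fold_change(a, b)), dp, tolerance = 1e-9)
  }
})

test_that("pair detection matches the brute-force oracle and recovers ground truth", {
  fx <- clean_fixture()
  data <- fx$curated$data
  pairs <- find_cliff_pairs(data)
  # brute-force double-loop oracle on a 30-molecule subset
  sub <- data[1:30, ]
  sub_pairs <- find_cliff_pairs(sub)
  oracle <- oracle_cliff_pairs(sub)
  expect_identical(cbind(sub_pairs$i, sub_pairs$j), unname(oracle))
  # exact recovery of the noise-free expected set on the full fixture
  want <- canonical_key(ob_canonical(fx$truth$expected_cliff_smiles[, 1]),
                        ob_canonical(fx$truth$expected_cliff_smiles[, 2]))
  got <- canonical_key(data$smiles[pairs$i], data$smiles[pairs$j])
  expect_setequal(got, want)
  # recorded similarity values agree with scalar recomputation
  fp <- compute_ecfp(data$smiles)
  for (r in seq_len(min(5, nrow(pairs)))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    expect_equal(pairs$sim_substructure[r], oracle_tanimoto(fp[i, ], fp[j, ]))
    expect_equal(pairs$sim_smiles[r],
                 smiles_similarity(data$smiles[i], data$smiles[j]))
    expect_equal(pairs$sim_scaffold[r],
                 scaffold_similarity(data$smiles[i], data$smiles[j]))
  }
})

test_that("pair detection is order-invariant and threshold-monotone", {
  data <- clean_fixture()$curated$data
  pairs <- find_cliff_pairs(data)
  set.seed(2)
  perm <- sample(nrow(data))
  shuffled <- data[perm, ]
  rownames(shuffled) <- NULL
  pairs_p <- find_cliff_pairs(shuffled)
  back <- canonical_key(shuffled$smiles[pairs_p$i], shuffled$smiles[pairs_p$j])
  orig <- canonical_key(data$smiles[pairs$i], data$smiles[pairs$j])
  expect_setequal(back, orig)
  # raising either threshold never adds pairs
  for (cfg in list(cliff_config(similarity_threshold = 0.95),
                   cliff_config(fold_threshold = 50))) {
    stricter <- find_cliff_pairs(data, cfg)
    expect_true(all(canonical_key(data$smiles[stricter$i],
                                  data$smiles[stricter$j]) %in% orig))
  }
  expect_identical(nrow(find_cliff_pairs(data[1, , drop = FALSE])), 0L)
})

test_that("a similar pair below the potency threshold is not a cliff", {
  df <- data.frame(smiles = ob_canonical(c("CCc1ccccc1", "CCCc1ccccc1")),
                   exp_mean_nM = c(100, 200), stringsAsFactors = FALSE)
  expect_gte(scaffold_similarity(df$smiles[1], df$smiles[2]), 0.9)
  expect_identical(nrow(find_cliff_pairs(df)), 0L)
  df$exp_mean_nM <- c(100, 1000)  # exactly ten-fold: inclusive boundary
  expect_identical(nrow(find_cliff_pairs(df)), 1L)
})

test_that("cliff annotation labels molecules and computes dataset stats", {
  data <- data.frame(smiles = sprintf("m%d", 1:10),
                     exp_mean_nM = rep(1, 10))
  none <- annotate_cliffs(data, find_cliff_pairs(data[0, ], cliff_config()))
  expect_true(all(!none$is_cliff))
  expect_equal(none$pct_cliff, 0)
  one <- data.frame(i = 2L, j = 7L)
  ann <- annotate_cliffs(data, one)
  expect_equal(ann$pct_cliff, 20)
  expect_identical(which(ann$is_cliff), c(2L, 7L))
  chain <- data.frame(i = c(1L, 2L), j = c(2L, 3L))
  ann2 <- annotate_cliffs(data, chain)
  expect_identical(ann2$n_partners[1:3], c(1L, 2L, 1L))
  expect_equal(ann2$mean_partners, 4 / 3)
})
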