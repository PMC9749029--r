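test_that("sanitization neutralizes, canonicalizes and rejects salts", {
  expect_identical(sanitize_and_neutralize("CCO"), "CCO")
  expect_identical(sanitize_and_neutralize("OCC"), "CCO")
  expect_identical(sanitize_and_neutralize("CC(=O)[O-]"), "CC(=O)O")
  # permanently charged centres are retained as-is
  expect_identical(sanitize_and_neutralize("C[N+](C)(C)C"), "C[N+](C)(C)C")
  salt <- sanitize_and_neutralize("CCO.Cl")
  expect_s3_class(salt, "curation_rejection")
  expect_identical(salt$reason, "REJECT_MULTIFRAGMENT")
  bad <- sanitize_and_neutralize("not_a_smiles")
  expect_s3_class(bad, "curation_rejection")
  expect_identical(bad$reason, "REJECT_PARSE")
})

test_that("Dixon's Q flags the tabulated example and not near-uniform data", {
  expect_null(dixon_q_outlier(c(5.0, 5.1, 5.05)))
  # Q = (0.95 - 0.15) / (0.95 - 0.10) = 0.941 > 0.829 (n = 4)
  expect_identical(dixon_q_outlier(c(0.10, 0.12, 0.15, 0.95)), 4L)
  expect_null(dixon_q_outlier(c(1.0, 1.0, 1.0)))
  expect_error(dixon_q_outlier(c(1, 2)), "3 <= n <= 30")
  expect_error(dixon_q_outlier(rep(1:31)), "3 <= n <= 30")
})

test_that("Dixon flagging is invariant under affine rescaling", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    a <- runif(1, 0.1, 50)
    b <- runif(1, -100, 100)
    expect_identical(dixon_q_outlier(x), dixon_q_outlier(a * x + b))
  }
})

test_that("replicate aggregation means in nM, converts to p, enforces SD cutoff", {
  one <- aggregate_replicates(10)
  expect_equal(one$p, 8.0, tolerance = 1e-12)
  trip <- aggregate_replicates(c(100, 100, 100))
  expect_equal(trip$mean_nM, 100)
  expect_equal(trip$p, 7.0, tolerance = 1e-12)
  expect_equal(trip$sd_log, 0)
  wide <- aggregate_replicates(c(1, 10000))  # sd(log10) = 2.83 > 1
  expect_s3_class(wide, "curation_rejection")
  expect_identical(wide$reason, "REJECT_SD")
  # a Dixon-detectable wild replicate is removed before the mean
  out <- aggregate_replicates(c(5, 5, 5000))
  expect_equal(out$mean_nM, 5)
  expect_identical(out$outlier_removed, 3L)
})

test_that("p-unit conversion round-trips across the activity range", {
  nM <- 10^seq(-3, 9, length.out = 50)
  expect_equal(nM_from_p(p_from_nM(nM)), nM, tolerance = 1e-9)
  expect_equal(p_from_nM(nM_from_p(seq(0, 12, by = 0.25))),
               seq(0, 12, by = 0.25), tolerance = 1e-9)
})

test_that("stereo-duplicate removal drops whole groups, keeps distinct structures", {
  df <- data.frame(
    smiles = ob_canonical(c("C[C@H](N)O", "C[C@@H](N)O", "CCO", "CCN")),
    stringsAsFactors = FALSE)
  expect_identical(length(unique(df$smiles)), 4L)  # canonical forms differ
  out <- remove_stereo_duplicates(df)
  expect_identical(out$smiles, df$smiles[3:4])
  expect_identical(sort(attr(out, "removed")), sort(df$smiles[1:2]))
  empty <- remove_stereo_duplicates(df[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
})

test_that("the curation pipeline removes exactly the planted artifacts", {
  fx <- dirty_fixture()
  cur <- fx$curated
  truth <- fx$truth
  expect_identical(cur$report$n_invalid_flag, length(truth$invalid_smiles))
  expect_identical(cur$report$n_reject_sd, length(truth$sd_reject_smiles))
  expect_identical(cur$report$n_dixon_outliers, length(truth$outlier_smiles))
  expect_identical(cur$report$n_stereo_duplicates,
                   length(truth$stereo_dup_smiles))
  # survivors are exactly the clean molecules, with exact activities
  expect_setequal(cur$data$smiles, fx$clean_canonical)
  m <- match(cur$data$smiles, fx$clean_canonical)
  expect_equal(cur$data$y, truth$molecules$p_true[m], tolerance = 1e-9)
})

test_that("curation is idempotent and outputs unique structures", {
  fx <- dirty_fixture()
  cur <- fx$curated
  expect_false(anyDuplicated(cur$data$smiles) > 0)
  again <- curate_dataset(
    data.frame(smiles = cur$data$smiles, activity_nM = cur$data$exp_mean_nM,
               stringsAsFactors = FALSE))
  expect_identical(again$data$smiles, cur$data$smiles)
  expect_equal(again$data$exp_mean_nM, cur$data$exp_mean_nM,
               tolerance = 1e-12)
  expect_identical(again$report$n_output, cur$report$n_output)
  # no two survivors share an ECFP either
  fp <- compute_ecfp(cur$data$smiles)
  keys <- apply(fp, 1, paste, collapse = "")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("curated CSV round-trips through the published column vocabulary", {
  fx <- dirty_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_curated_csv(fx$curated, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "smiles,exp_mean [nM],y")
  back <- read_raw_csv(path)
  expect_identical(back$smiles, fx$curated$data$smiles)
  expect_equal(back$activity_nM, fx$curated$data$exp_mean_nM,
               tolerance = 1e-6)
})
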