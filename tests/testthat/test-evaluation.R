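test_that("rmse follows its definition", {
  expect_equal(rmse(prediction_set(c(1, 2), c(1, 2), c(FALSE, FALSE))), 0)
  expect_equal(rmse(prediction_set(c(0, 0), c(1, 1), c(TRUE, TRUE))), 1)
  expect_equal(rmse(prediction_set(c(8.0, 6.0, 7.5), c(7.5, 6.5, 7.5),
                                   rep(TRUE, 3))),
               sqrt(0.5 / 3), tolerance = 1e-12)
  expect_error(rmse(prediction_set(numeric(0), numeric(0), logical(0))),
               "EMPTY")
})

test_that("cliff rmse restricts to cliff compounds exactly", {
  p <- prediction_set(c(8, 6), c(7, 6), c(TRUE, FALSE))
  expect_equal(rmse_cliff(p), 1.0)
  all_cliff <- prediction_set(c(8, 6, 5), c(7.2, 6.1, 5.5), rep(TRUE, 3))
  expect_equal(rmse_cliff(all_cliff), rmse(all_cliff))
  mixed <- prediction_set(c(8, 6, 5), c(8, 9, 5), c(TRUE, FALSE, TRUE))
  expect_equal(rmse_cliff(mixed), 0)
  expect_warning(out <- rmse_cliff(prediction_set(7, 7, FALSE)), "NO_CLIFFS")
  expect_true(is.na(out))
  # identity with rmse on the subset, on random prediction sets
  set.seed(19)
  for (r in 1:20) {
    n <- sample(3:40, 1)
    y <- rnorm(n, 7); yh <- y + rnorm(n, 0, 0.5)
    lab <- runif(n) < 0.4
    if (!any(lab)) lab[1] <- TRUE
    full <- prediction_set(y, yh, lab)
    sub <- prediction_set(y[lab], yh[lab], rep(TRUE, sum(lab)))
    expect_identical(rmse_cliff(full), rmse(sub))
  }
})

test_that("rmse is permutation-invariant and scales with the residuals", {
  set.seed(23)
  y <- rnorm(15, 7); yh <- y + rnorm(15, 0, 0.3); lab <- runif(15) < 0.5
  perm <- sample(15)
  p1 <- prediction_set(y, yh, lab)
  p2 <- prediction_set(y[perm], yh[perm], lab[perm])
  expect_equal(rmse(p1), rmse(p2), tolerance = 1e-12)
  s <- 3.7
  p3 <- prediction_set(y, y + s * (yh - y), lab)
  expect_equal(rmse(p3), abs(s) * rmse(p1), tolerance = 1e-12)
  if (any(lab)) expect_equal(rmse_cliff(p3), abs(s) * rmse_cliff(p1),
                             tolerance = 1e-12)
})

test_that("the PCA ranking anchors, orients and scales as specified", {
  tab <- benchmark_table(data.frame(
    method = rep(c("good", "bad", "mid"), each = 3),
    dataset = rep(c("a", "b", "c"), 3),
    rmse = c(0.5, 0.6, 0.4, 1.5, 1.4, 1.6, 1.0, 1.0, 1.0),
    rmse_cliff = c(0.5, 0.6, 0.4, 1.5, 1.4, 1.6, 1.0, 1.0, 1.0)))
  rk <- pca_ranking(tab)
  co <- rk$coords
  # "good" holds every column minimum, so it coincides with the Best anchor
  expect_equal(co$PC1[co$method == "good"], co$PC1[co$method == "Best"],
               tolerance = 1e-9)
  expect_equal(co$scaled[co$method == "good"], 0, tolerance = 1e-9)
  expect_equal(co$scaled[co$method == "bad"], 1, tolerance = 1e-9)
  expect_lt(co$PC1[co$method == "Best"], co$PC1[co$method == "Worst"])
  expect_true(all(diff(rk$explained) <= 1e-12))
  expect_lte(sum(rk$explained), 1 + 1e-12)
  # identical methods project identically
  tab2 <- benchmark_table(data.frame(
    method = rep(c("m1", "m2", "m3"), each = 2),
    dataset = rep(c("a", "b"), 3),
    rmse = c(1, 2, 1, 2, 3, 1), rmse_cliff = c(1, 2, 1, 2, 3, 1)))
  rk2 <- pca_ranking(tab2)
  expect_equal(rk2$coords$PC1[1], rk2$coords$PC1[2], tolerance = 1e-9)
  expect_equal(rk2$coords$PC2[1], rk2$coords$PC2[2], tolerance = 1e-9)
})

test_that("failure-mode analysis reports the right correlations", {
  tab <- benchmark_table(data.frame(
    method = rep(c("m1", "m2", "m3", "m4"), each = 2),
    dataset = rep(c("a", "b"), 4),
    rmse = c(1, 1, 2, 2, 3, 3, 4, 4),
    rmse_cliff = c(1, 4, 2, 3, 3, 2, 4, 1)))
  fm <- failure_mode_analysis(tab)
  expect_equal(fm$per_dataset$r[fm$per_dataset$dataset == "a"], 1)
  expect_equal(fm$per_dataset$r[fm$per_dataset$dataset == "b"], -1)
  expect_equal(fm$per_dataset$mean_excess,
               c(0, 0), tolerance = 1e-12)
  # hand-computed Pearson on a 3-point column
  tab2 <- benchmark_table(data.frame(
    method = c("m1", "m2", "m3"), dataset = "a",
    rmse = c(1, 2, 4), rmse_cliff = c(2, 2.5, 6)))
  fm2 <- failure_mode_analysis(tab2)
  expect_equal(fm2$per_dataset$r, cor(c(1, 2, 4), c(2, 2.5, 6)),
               tolerance = 1e-12)
})
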