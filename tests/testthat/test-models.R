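test_that("the published grids match the search protocol", {
  expect_identical(default_grid("KNN")$k, c(3L, 5L, 11L, 21L))
  svm <- default_grid("SVM")
  expect_identical(nrow(svm), 30L)
  expect_setequal(unique(svm$gamma), 10^(-6:-1))
  expect_setequal(unique(svm$cost), c(1, 10, 100, 1000, 10000))
  expect_identical(nrow(default_grid("GBM")), 9L)
  expect_identical(default_grid("RF")$ntree, c(100L, 250L, 500L, 1000L))
  mlp <- default_grid("MLP")
  expect_identical(nrow(mlp), 45L)  # under the 50-evaluation budget
  expect_true(all(vapply(c("KNN", "SVM", "GBM", "RF", "MLP"),
                         function(a) nrow(default_grid(a)) <= 50,
                         logical(1))))
})

test_that("grid search is exhaustive, fivefold, and tie-stable", {
  set.seed(6)
  x <- matrix(rnorm(60 * 4), 60, 4)
  y <- x[, 1] + rnorm(60, 0, 0.1)
  m <- tune_and_fit(x, y, "KNN", seed = 3)
  expect_identical(nrow(m$cv_table), 4L)   # all KNN configs evaluated
  expect_true(all(is.finite(m$cv_table$cv_rmse)))
  expect_true(m$par$k %in% default_grid("KNN")$k)
  expect_error(tune_and_fit(x, y, "KNN", grid = data.frame()), "GRID_EMPTY")
  # constant response: every fold predicts the constant
  mc <- tune_and_fit(x, rep(2.5, 60), "KNN", seed = 3)
  expect_equal(mc$cv_rmse, 0, tolerance = 1e-12)
})

test_that("KNN predicts the mean of its nearest neighbours, order-free", {
  xtr <- matrix(c(0, 0, 1, 1, 2, 2, 10, 10), ncol = 2, byrow = TRUE)
  m <- tune_and_fit(xtr, c(7, 8, 9, 100), "KNN", grid = data.frame(k = 3),
                    seed = 1, n_folds = 2)
  expect_equal(predict(m, matrix(c(0.1, 0.1), 1)), 8)  # mean(7, 8, 9)
  expect_identical(predict(m, xtr[0, , drop = FALSE]), numeric(0))
  expect_error(predict(m, matrix(0, 1, 3)), "KIND_MISMATCH")
  set.seed(9)
  xtr2 <- matrix(rnorm(40), 20, 2)
  y2 <- rnorm(20)
  perm <- sample(20)
  m1 <- tune_and_fit(xtr2, y2, "KNN", grid = data.frame(k = 5), seed = 2,
                     n_folds = 2)
  m2 <- tune_and_fit(xtr2[perm, ], y2[perm], "KNN",
                     grid = data.frame(k = 5), seed = 2, n_folds = 2)
  xq <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(m1, xq), predict(m2, xq), tolerance = 1e-12)
})

test_that("models learn a linear response better than the no-information baseline", {
  set.seed(21)
  x <- matrix(rnorm(150 * 8), 150, 8)
  rs <- generate_response_surface(x, noise_sd = 0.1,
                                  interaction_strength = 0, seed = 31)
  y <- rs$y_train
  for (algo in c("SVM", "KNN")) {
    m <- tune_and_fit(x, y, algo, seed = 4)
    expect_lt(m$cv_rmse, sd(y))
  }
})

test_that("tuning and prediction are reproducible given the seed", {
  set.seed(17)
  x <- matrix(rnorm(80 * 5), 80, 5)
  y <- x[, 2] - 0.5 * x[, 4] + rnorm(80, 0, 0.2)
  for (algo in c("RF", "GBM")) {
    grid <- utils::head(default_grid(algo), 2)
    m1 <- tune_and_fit(x, y, algo, grid = grid, seed = 5)
    m2 <- tune_and_fit(x, y, algo, grid = grid, seed = 5)
    expect_identical(m1$par, m2$par)
    expect_equal(predict(m1, x[1:10, ]), predict(m2, x[1:10, ]),
                 tolerance = 1e-12)
  }
})

test_that("a deep forest memorizes its training points", {
  set.seed(12)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- rnorm(40, 7, 1)
  m <- tune_and_fit(x, y, "RF", grid = data.frame(ntree = 500), seed = 8,
                    n_folds = 2)
  expect_lt(sqrt(mean((predict(m, x) - y)^2)), 0.6 * sd(y))
})

test_that("the MLP trains deterministically and fits a smooth response", {
  set.seed(33)
  x <- matrix(rnorm(200 * 6), 200, 6)
  y <- as.numeric(x %*% c(1, -1, 0.5, 0, 0, 0)) + rnorm(200, 0, 0.2)
  f1 <- mlp_fit(x, y, lr = 5e-4, n_hidden = 64, n_layers = 2, seed = 4,
                max_epochs = 150)
  f2 <- mlp_fit(x, y, lr = 5e-4, n_hidden = 64, n_layers = 2, seed = 4,
                max_epochs = 150)
  expect_identical(f1$layers, f2$layers)
  pred <- mlp_predict(f1, x)
  expect_lt(sqrt(mean((pred - y)^2)), 0.6 * sd(y))
  m <- tune_and_fit(x, y, "MLP",
                    grid = data.frame(lr = 5e-4, n_hidden = 32, n_layers = 1),
                    seed = 2)
  expect_lt(m$cv_rmse, sd(y))
})
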