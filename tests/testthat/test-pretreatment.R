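test_that("truncate_positive zeroes strictly positive entries and is idempotent", {
  X <- matrix(c(-1.2, 0.0, 0.3, -0.7), 2, 2, byrow = TRUE)
  expect_equal(truncate_positive(X),
               matrix(c(-1.2, 0.0, 0.0, -0.7), 2, 2, byrow = TRUE))
  neg <- matrix(c(-1, -2, -3, -4), 2)
  expect_equal(truncate_positive(neg), neg)
  set.seed(1)
  R <- matrix(rnorm(60), 10)
  expect_identical(truncate_positive(truncate_positive(R)), truncate_positive(R))
})

test_that("filter_low_variance uses the n-1 sample standard deviation", {
  X <- cbind(const = rep(2, 4), a = c(0, 1, 0, 1), b = rnorm(4))
  out <- filter_low_variance(X, 0.01)
  expect_equal(out$retained_columns, c(2L, 3L))
  # threshold 0 retains everything
  expect_equal(filter_low_variance(X, 0)$retained_columns, 1:3)
  # {0,1} column: sample sd = sqrt(1/3 * ... ) with n-1 denominator = 0.5774
  Y <- cbind(c(0, 1, 0, 1), rnorm(4))
  expect_equal(sd(Y[, 1]), sqrt(1 / 3), tolerance = 1e-12)
  # at n = 2, {0,1} has sample sd 0.7071: retained at 0.5, removed at 0.8
  Z <- rbind(c(0, 5), c(1, 6))
  expect_equal(filter_low_variance(Z, 0.5)$retained_columns, 1:2)
  expect_error(filter_low_variance(Z, 0.8), "lower")
  expect_error(filter_low_variance(X[1, , drop = FALSE], 0.1), ">= 2 rows")
})

test_that("PCA on collinear data puts all variance on component 1", {
  t_ <- seq(-2, 2, length.out = 9)
  X <- cbind(3 * t_, -4 * t_)  # exactly on a line
  fp <- pretreat_fit(X, pretreat_config(truncate_positive = FALSE, n_components = 1))
  expect_equal(sum(fp$explained_variance) / fp$total_variance, 1, tolerance = 1e-12)
})

test_that("the training column-mean row maps to the zero score vector", {
  set.seed(8)
  X <- matrix(rnorm(48, sd = 2), 8, 6)
  fp <- pretreat_fit(X, pretreat_config(truncate_positive = FALSE, n_components = 3))
  mean_row <- matrix(colMeans(X), 1)
  expect_lt(max(abs(pretreat_transform(fp, mean_row))), 1e-10)
})

test_that("full-rank PCA reconstructs the centered matrix", {
  set.seed(5)
  X <- matrix(rnorm(60, sd = 3), 10, 6)
  cfg <- pretreat_config(truncate_positive = FALSE, n_components = 6)
  fp <- pretreat_fit(X, cfg)
  S <- pretreat_transform(fp, X)
  Z <- sweep(X, 2L, fp$column_means, "-")
  recon <- sweep(S %*% fp$pca_loadings, 2L, fp$pca_mean, "+")
  expect_lt(max(abs(recon - Z)), 1e-8)
})

test_that("fitted pretreatment invariants hold", {
  set.seed(13)
  X <- matrix(rnorm(70) - 0.3, 10, 7)   # mixed signs so truncation acts
  fp <- pretreat_fit(X, pretreat_config(n_components = 4))
  # orthonormal loadings
  G <- fp$pca_loadings %*% t(fp$pca_loadings)
  expect_lt(max(abs(G - diag(4))), 1e-8)
  # non-increasing explained variance
  expect_true(all(diff(fp$explained_variance) <= 1e-12))
  # training-score variances equal explained variance; scores uncorrelated
  S <- pretreat_transform(fp, X)
  expect_equal(unname(apply(S, 2, var)), fp$explained_variance, tolerance = 1e-8)
  CS <- cov(S)
  expect_lt(max(abs(CS[upper.tri(CS)])), 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(nrow(fp$pca_loadings))) {
    expect_gt(fp$pca_loadings[j, which.max(abs(fp$pca_loadings[j, ]))], 0)
  }
})

test_that("transform is frozen: no statistic depends on new data", {
  set.seed(21)
  X <- matrix(rnorm(50), 10, 5)
  fp <- pretreat_fit(X, pretreat_config(n_components = 2))
  snapshot <- unclass(fp)
  invisible(pretreat_transform(fp, matrix(rnorm(25, sd = 50), 5, 5)))
  expect_identical(unclass(fp), snapshot)
  # same input rows always give the same scores
  expect_identical(pretreat_transform(fp, X), pretreat_transform(fp, X))
})

test_that("pretreatment errors are informative", {
  set.seed(2)
  X <- matrix(rnorm(30), 6, 5)
  expect_error(pretreat_fit(X, pretreat_config(n_components = 6)), "n_components")
  fp <- pretreat_fit(X, pretreat_config(n_components = 2))
  expect_error(pretreat_transform(fp, X[, 1:3]), "columns")
})

test_that("standardization scales every retained column to unit variance", {
  set.seed(4)
  X <- cbind(rnorm(12, sd = 10), rnorm(12, sd = 0.1), rnorm(12))
  fp <- pretreat_fit(X, pretreat_config(truncate_positive = FALSE,
                                        standardize = TRUE, n_components = 2))
  expect_equal(unname(fp$column_scales), unname(apply(X, 2, sd)), tolerance = 1e-12)
  # after scaling, total variance equals the column count
  expect_equal(fp$total_variance, 3, tolerance = 1e-8)
})

test_that("select_n_components picks the Q2-maximizing count", {
  b <- quick_benchmark(n = 25, n_res = 3, noise_sd = 0.1, seed = 17)
  sel <- select_n_components(b$X, b$dataset$pkoff, regressor_spec("PLSR"),
                             candidates = c(1, 3, 5))
  expect_true(sel$n_components %in% c(1, 3, 5))
  expect_equal(unname(sel$q2[as.character(sel$n_components)]), max(sel$q2))
})
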