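test_that("ranked_split reproduces the published dataset divisions", {
  set.seed(1)
  d66 <- kinetic_dataset(sprintf("c%02d", 1:66), rnorm(66))
  s66 <- ranked_split(d66)
  expect_length(s66$train_indices, 53L)
  expect_length(s66$test_indices, 13L)

  d35 <- kinetic_dataset(sprintf("c%02d", 1:35), rnorm(35))
  s35 <- ranked_split(d35)
  expect_length(s35$train_indices, 28L)
  expect_length(s35$test_indices, 7L)

  # N = 5: single period, the largest-pkoff sample is held out
  d5 <- kinetic_dataset(letters[1:5], c(3, 1, 5, 2, 4))
  s5 <- ranked_split(d5)
  expect_equal(s5$test_indices, 3L)   # pkoff = 5 sits at sorted position 5
  expect_length(s5$train_indices, 4L)
  expect_error(ranked_split(kinetic_dataset("a", 1)), "at least 5")
})

test_that("ranked_split partitions every N in 5..200 with |test| = floor(N/5)", {
  set.seed(42)
  for (n in 5:200) {
    d <- kinetic_dataset(paste0("c", seq_len(n)), rnorm(n))
    s <- ranked_split(d)
    expect_length(s$test_indices, n %/% 5L)
    expect_setequal(c(s$train_indices, s$test_indices), seq_len(n))
    expect_length(intersect(s$train_indices, s$test_indices), 0L)
  }
})

test_that("ranked_split breaks pkoff ties by stable input order", {
  d <- kinetic_dataset(paste0("c", 1:10), c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2))
  s <- ranked_split(d)
  # sorted order is input order here, so positions 5 and 10 are held out
  expect_equal(s$test_indices, c(5L, 10L))
})

test_that("compute_metrics matches hand-computed worked examples", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3), "train")
  expect_equal(m$r2, 1); expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0); expect_equal(m$r, 1)
  expect_equal(m$m, 3L)

  # predicting the mean gives exactly R2 = 0
  m0 <- compute_metrics(c(1, 2, 3), c(2, 2, 2 + 1e-9), "test")
  expect_equal(m0$r2, 0, tolerance = 1e-6)

  # hand-computed: SSres = 0.5, SStot = 5 -> R2 = 0.9; |e| = (.5,0,0,.5)
  m1 <- compute_metrics(c(0, 1, 2, 3), c(0.5, 1, 2, 2.5), "test")
  expect_equal(m1$mae, 0.25, tolerance = 1e-4)
  expect_equal(m1$rmse, 0.35355, tolerance = 1e-4)
  expect_equal(m1$r2, 0.9, tolerance = 1e-4)
  expect_equal(m1$r, 0.98995, tolerance = 1e-4)

  expect_error(compute_metrics(c(1, 1, 1), c(1, 2, 3)), "zero variance in y_exp")
  expect_error(compute_metrics(c(1, 2, 3), c(2, 2, 2)), "zero variance in y_pred")
  expect_error(compute_metrics(1, 1), "at least 2")
})

test_that("mae never exceeds rmse", {
  set.seed(7)
  for (i in 1:25) {
    y <- rnorm(20); p <- y + rnorm(20, 0, runif(1, 0.01, 2))
    m <- compute_metrics(y, p, "test")
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("loo_cv reproduces the hand-worked mean-only example", {
  # y = (1,2,3), mean-only predictor: held-out predictions (2.5, 2, 1.5),
  # PRESS = 4.5, SStot = 2 -> Q2 = -1.25
  X <- matrix(rnorm(6), 3, 2)
  cv <- loo_cv(regressor_spec("Mean"), NULL, X, c(1, 2, 3))
  expect_equal(cv$predictions, c(2.5, 2, 1.5), tolerance = 1e-12)
  expect_equal(cv$q2, -1.25, tolerance = 1e-4)
  expect_length(cv$predictions, 3L)   # one prediction per fold
})

test_that("loo_cv is deterministic and matches the naive double-loop oracle", {
  b <- quick_benchmark(n = 12, n_res = 3, noise_sd = 0.3, seed = 23)
  y <- b$dataset$pkoff
  pc <- pretreat_config(n_components = 3)
  for (kind in c("PLSR", "RF")) {
    spec <- regressor_spec(kind, seed = 2L)
    cv1 <- loo_cv(spec, pc, b$X, y)
    cv2 <- loo_cv(spec, pc, b$X, y)
    expect_identical(cv1$q2, cv2$q2, info = kind)
    expect_equal(cv1$q2, naive_loo_q2(spec, pc, b$X, y), tolerance = 1e-12,
                 info = kind)
  }
  # and without pretreatment
  spec <- regressor_spec("BR")
  expect_equal(loo_cv(spec, NULL, b$X, y)$q2,
               naive_loo_q2(spec, NULL, b$X, y), tolerance = 1e-12)
})

test_that("loo_cv identifies the failing fold", {
  X <- matrix(rnorm(12), 6, 2)
  y <- rnorm(6)
  # n_components = 4 exceeds what a 5-row fold can support
  expect_error(loo_cv(regressor_spec("PLSR"), pretreat_config(n_components = 5), X, y),
               "fold 1")
})

test_that("compare_models reports 12 indicators per model with a ranking", {
  b <- quick_benchmark(n = 30, n_res = 4, noise_sd = 0.2, seed = 19)
  specs <- list(regressor_spec("PLSR"), regressor_spec("BR"), regressor_spec("PLSR"))
  tab <- compare_models(specs, b$dataset, b$X, pretreat_config(n_components = 4))
  expect_equal(nrow(tab), 3L)
  expect_named(tab, c("model",
                      "r2_train", "mae_train", "r_train", "rmse_train",
                      "q2_cv", "mae_cv", "r_cv", "rmse_cv",
                      "r2_test", "mae_test", "r_test", "rmse_test"))
  # identical specs give identical rows
  expect_equal(tab[1, -1], tab[3, -1], tolerance = 1e-12,
               ignore_attr = TRUE)
  # two linear-family models agree closely on a linear plant
  expect_lt(abs(tab$r2_test[1] - tab$r2_test[2]), 0.05)
  expect_setequal(attr(tab, "ranking"), tab$model)
})
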