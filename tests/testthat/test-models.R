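# Shared-contract suite over every regressor kind, plus kind-specific
# oracles. BNN-specific behavior (ELBO, intervals, calibration) is below.

all_kinds <- c("BNN", "PLSR", "BR", "GPR", "PCR", "RF", "SVM", "XGBoost", "Mean")

test_that("every regressor kind honors the fit/predict contract", {
  set.seed(10)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- drop(x %*% c(1, -0.5, 0.25)) + rnorm(40, 0, 0.1)
  x_new <- matrix(rnorm(6 * 3), 6, 3)
  for (kind in all_kinds) {
    hp <- if (kind == "BNN") list(epochs = 200L) else list()
    spec <- regressor_spec(kind, hp, seed = 4L)
    reg <- make_regressor(spec)
    m1 <- reg$fit(x, y)
    p_tr <- reg$predict(m1, x)
    p_new <- reg$predict(m1, x_new)
    expect_length(p_tr, 40L)
    expect_length(p_new, 6L)
    expect_true(all(is.finite(c(p_tr, p_new))), info = kind)
    # determinism under a fixed seed
    m2 <- reg$fit(x, y)
    expect_identical(reg$predict(m2, x_new), p_new, info = kind)
    # wrong column count rejected
    expect_error(reg$predict(m1, x_new[, 1:2]), "column|feature", info = kind)
  }
  expect_error(regressor_spec("deep-kernel-machine"), "unknown regressor kind")
})

test_that("PLSR with full components reproduces ordinary least squares", {
  set.seed(4)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- drop(X %*% c(1, -2, 0.5, 0.3)) + rnorm(30, 0, 0.1)
  ols_pred <- drop(cbind(1, X) %*% stats::lm.fit(cbind(1, X), y)$coefficients)
  mp <- fit_regressor(regressor_spec("PLSR"), X, y)
  expect_equal(mp$n_components, 4L)
  expect_lt(max(abs(predict(mp, X) - ols_pred)), 1e-6)
  # PCR at full rank agrees too
  mq <- fit_regressor(regressor_spec("PCR"), X, y)
  expect_lt(max(abs(predict(mq, X) - ols_pred)), 1e-6)
})

test_that("kernel and ensemble baselines fit y = x with default settings", {
  x <- matrix(seq(-2, 2, length.out = 100))
  y <- x[, 1]
  for (kind in c("SVM", "GPR", "BR", "XGBoost")) {
    m <- fit_regressor(regressor_spec(kind, seed = 1L), x, y)
    rmse <- sqrt(mean((y - predict(m, x))^2))
    expect_lt(rmse, 0.2, label = sprintf("%s train RMSE (%.3f)", kind, rmse))
  }
})

test_that("BNN recovers a noise-free linear function at default settings", {
  x <- matrix(seq(-2, 2, length.out = 50))
  y <- 2 * x[, 1]
  fit <- bnn_fit(x, y, bnn_config(seed = 5L))
  pp <- bnn_predict(fit, x)
  expect_lt(sqrt(mean((y - pp$mean)^2)), 0.1)
  # the trained ELBO must not be worse than the initialization's
  expect_gt(fit$elbo_final, fit$elbo_init)
})

test_that("BNN on a constant target predicts that constant", {
  set.seed(3)
  x <- matrix(rnorm(30))
  fit <- bnn_fit(x, rep(1.7, 30), bnn_config(seed = 2L))
  pp <- bnn_predict(fit, matrix(seq(min(x), max(x), length.out = 20)))
  expect_lt(max(abs(pp$mean - 1.7)), 0.05)
})

test_that("BNN predictions are seed-deterministic and seed-sensitive", {
  set.seed(6)
  x <- matrix(rnorm(25 * 2), 25, 2)
  y <- x[, 1] - x[, 2] + rnorm(25, 0, 0.2)
  cfg <- bnn_config(epochs = 300L, seed = 11L)
  f1 <- bnn_fit(x, y, cfg); f2 <- bnn_fit(x, y, cfg)
  expect_identical(bnn_predict(f1, x)$mean, bnn_predict(f2, x)$mean)
  f3 <- bnn_fit(x, y, bnn_config(epochs = 300L, seed = 12L))
  expect_false(identical(bnn_predict(f1, x)$mean, bnn_predict(f3, x)$mean))
})

test_that("posterior intervals behave at the boundaries", {
  set.seed(9)
  x <- matrix(rnorm(20)); y <- x[, 1] + rnorm(20, 0, 0.3)
  fit <- bnn_fit(x, y, bnn_config(epochs = 300L, seed = 3L))
  # a single draw gives a degenerate interval equal to the mean
  p1 <- bnn_predict(fit, x, posterior_samples = 1L)
  expect_identical(p1$mean, p1$lower95)
  expect_identical(p1$mean, p1$upper95)
  # with many draws the interval brackets the mean and has positive width
  pm <- bnn_predict(fit, x, posterior_samples = 500L)
  expect_true(all(pm$lower95 <= pm$mean & pm$mean <= pm$upper95))
  expect_true(all(pm$upper95 - pm$lower95 > 0))
  expect_error(bnn_predict(fit, matrix(rnorm(10), 5, 2)), "columns")
})

test_that("posterior interval width grows with generator noise", {
  widths <- vapply(c(0.1, 0.4, 0.9), function(noise) {
    set.seed(31)
    x <- matrix(rnorm(60))
    y <- x[, 1] + rnorm(60, 0, noise)
    fit <- bnn_fit(x, y, bnn_config(epochs = 500L, seed = 7L))
    pp <- bnn_predict(fit, x, posterior_samples = 400L)
    median(pp$upper95 - pp$lower95)
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("BNN test error shrinks as training size grows", {
  gen <- function(n, seed) {
    with_seed <- getFromNamespace("with_seed", "koffkit")
    with_seed(seed, {
      x <- matrix(runif(n, -2, 2))
      list(x = x, y = sin(x[, 1]) + 0.5 * x[, 1])
    })
  }
  te <- gen(100, 99)
  rmse <- vapply(c(20, 200), function(n) {
    tr <- gen(n, 17)
    fit <- bnn_fit(tr$x, tr$y, bnn_config(epochs = 800L, seed = 5L))
    sqrt(mean((te$y - bnn_predict(fit, te$x)$mean)^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("a diverging fit reports a usable error", {
  set.seed(2)
  x <- matrix(rnorm(10) * 1e4)
  y <- rnorm(10) * 1e6
  expect_error(
    bnn_fit(x, y, bnn_config(learning_rate = 1e6, epochs = 50L, seed = 1L)),
    "learning_rate|diverged")
})
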