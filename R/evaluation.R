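# Ranked 4:1 splitting, leave-one-out cross-validation, and the twelve
# regression statistics (R2/Q2, r, MAE, RMSE on train/cv/test).

#' Ranked train/test split
#'
#' Samples are stably sorted ascending by pkoff (ties keep input order) and
#' every \code{period}-th sample of the sorted list goes to the test set, a
#' 4:1 split at the default period of 5. For N = 66 this yields 53 train /
#' 13 test; for N = 35, 28 train / 7 test.
#'
#' @param dataset a \code{\link{kinetic_dataset}}.
#' @param period every \code{period}-th ranked sample is held out (default 5).
#' @return list of class \code{split_result} with \code{train_indices} and
#'   \code{test_indices} (1-based indices into the dataset row order).
#' @export
ranked_split <- function(dataset, period = 5L) {
  if (!is_count(period) || period < 2) stopf("period must be an integer >= 2")
  n <- nrow(dataset)
  if (n < period) stopf("need at least %d samples for a ranked 1-in-%d split, got %d",
                        period, period, n)
  ord <- order(dataset$pkoff)          # radix sort: stable for ties
  test_pos <- seq.int(period, n, by = period)
  test_idx <- sort(ord[test_pos])
  train_idx <- sort(ord[-test_pos])
  structure(list(train_indices = train_idx, test_indices = test_idx),
            class = "split_result")
}

#' Regression statistics for one prediction context
#'
#' Computes the determination coefficient
#' \eqn{R^2 = 1 - \sum(y_{exp} - y_{pred})^2 / \sum(y_{exp} - \bar y_{exp})^2},
#' the mean absolute error, the root mean square error, and the Pearson
#' correlation \eqn{r}. (\eqn{R^2} over held-out LOO predictions is the
#' \eqn{Q^2_{cv}} statistic; see \code{\link{loo_cv}}.)
#'
#' @param y_exp experimental values.
#' @param y_pred predicted values (same length, >= 2).
#' @param context one of \code{"train"}, \code{"cv"}, \code{"test"}.
#' @return list of class \code{regression_metrics} with \code{r2},
#'   \code{mae}, \code{rmse}, \code{r}, \code{context}, \code{m}.
#' @export
compute_metrics <- function(y_exp, y_pred, context = c("train", "cv", "test")) {
  context <- match.arg(context)
  y_exp <- as.numeric(y_exp); y_pred <- as.numeric(y_pred)
  m <- length(y_exp)
  if (length(y_pred) != m) stopf("y_exp and y_pred lengths differ")
  if (m < 2L) stopf("need at least 2 samples")
  if (!all(is.finite(y_exp)) || !all(is.finite(y_pred))) stopf("non-finite values")
  sstot <- sum((y_exp - mean(y_exp))^2)
  if (sstot == 0) stopf("zero variance in y_exp: R2 and r are undefined")
  if (var(y_pred) == 0) stopf("zero variance in y_pred: r is undefined")
  ssres <- sum((y_exp - y_pred)^2)
  structure(list(
    r2 = 1 - ssres / sstot,
    mae = mean(abs(y_exp - y_pred)),
    rmse = sqrt(mean((y_exp - y_pred)^2)),
    r = cor(y_exp, y_pred),
    context = context,
    m = m
  ), class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("<%s metrics (m = %d): R2 = %.3f, r = %.3f, MAE = %.3f, RMSE = %.3f>\n",
              x$context, x$m, x$r2, x$r, x$mae, x$rmse))
  invisible(x)
}

#' Leave-one-out cross-validation of a pretreatment + regressor pipeline
#'
#' Runs exactly \code{n} folds: fold i refits the pretreatment (when
#' \code{pre_cfg} is non-NULL) and the model on all rows except i and
#' predicts row i, so the full descriptor-to-label pipeline is validated
#' without leakage. \eqn{Q^2_{cv}} is computed over the assembled held-out
#' predictions with the centering mean \eqn{\bar y_{exp}} taken over the
#' full training set.
#'
#' @param spec a \code{\link{regressor_spec}}.
#' @param pre_cfg a \code{\link{pretreat_config}} refit inside every fold, or
#'   \code{NULL} to feed the raw matrix to the model.
#' @param X_train descriptor matrix (training rows).
#' @param y_train pkoff labels.
#' @return list with \code{q2}, \code{mae_cv}, \code{r_cv}, \code{rmse_cv}
#'   and \code{predictions} (held-out predictions in row order).
#' @export
loo_cv <- function(spec, pre_cfg, X_train, y_train) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n != length(y_train)) stopf("X_train and y_train disagree on sample count")
  if (n < 3L) stopf("LOO-CV needs at least 3 training rows")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      Xi <- X_train[-i, , drop = FALSE]
      yi <- y_train[-i]
      if (is.null(pre_cfg)) {
        si <- Xi
        s_new <- X_train[i, , drop = FALSE]
      } else {
        fp <- pretreat_fit(Xi, pre_cfg)
        si <- pretreat_transform(fp, Xi)
        s_new <- pretreat_transform(fp, X_train[i, , drop = FALSE])
      }
      model <- fit_regressor(spec, si, yi)
      predict(model, s_new)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stopf("LOO fold %d (%s) failed: %s", i, spec$kind, conditionMessage(res))
    }
    preds[i] <- res
  }
  press <- sum((y_train - preds)^2)
  sstot <- sum((y_train - mean(y_train))^2)
  if (sstot == 0) stopf("zero variance in y_train: Q2 undefined")
  list(q2 = 1 - press / sstot,
       mae_cv = mean(abs(y_train - preds)),
       r_cv = if (var(preds) > 0) cor(y_train, preds) else NA_real_,
       rmse_cv = sqrt(press / n),
       predictions = preds)
}

#' Compare regressors under a shared split and pretreatment
#'
#' Applies \code{\link{ranked_split}} to the dataset, fits the pretreatment
#' on the training rows, then for every spec reports the twelve statistics:
#' \eqn{R^2}/MAE/\eqn{r}/RMSE on the training set, \eqn{Q^2_{cv}}/MAE/\eqn{r}/
#' RMSE from leave-one-out cross-validation (pipeline refit per fold), and
#' \eqn{R^2}/MAE/\eqn{r}/RMSE on the held-out test set.
#'
#' @param specs list of \code{\link{regressor_spec}} objects.
#' @param dataset a \code{\link{kinetic_dataset}} aligned with the rows of
#'   \code{X}.
#' @param X descriptor matrix (one row per dataset entry, same order).
#' @param pre_cfg shared \code{\link{pretreat_config}}.
#' @param period ranked-split period (default 5).
#' @return data frame of class \code{model_comparison}, one row per model,
#'   with a \code{ranking} attribute ordering models by \code{r2_test}.
#' @export
compare_models <- function(specs, dataset, X, pre_cfg = pretreat_config(),
                           period = 5L) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(dataset)) stopf("X rows and dataset entries disagree")
  sp <- ranked_split(dataset, period)
  tr <- sp$train_indices; te <- sp$test_indices
  y <- dataset$pkoff
  fp <- pretreat_fit(X[tr, , drop = FALSE], pre_cfg)
  s_tr <- pretreat_transform(fp, X[tr, , drop = FALSE])
  s_te <- pretreat_transform(fp, X[te, , drop = FALSE])

  rows <- lapply(specs, function(spec) {
    model <- fit_regressor(spec, s_tr, y[tr])
    mt <- compute_metrics(y[tr], predict(model, s_tr), "train")
    cv <- loo_cv(spec, pre_cfg, X[tr, , drop = FALSE], y[tr])
    ms <- compute_metrics(y[te], predict(model, s_te), "test")
    data.frame(model = spec$kind,
               r2_train = mt$r2, mae_train = mt$mae, r_train = mt$r,
               rmse_train = mt$rmse,
               q2_cv = cv$q2, mae_cv = cv$mae_cv, r_cv = cv$r_cv,
               rmse_cv = cv$rmse_cv,
               r2_test = ms$r2, mae_test = ms$mae, r_test = ms$r,
               rmse_test = ms$rmse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ranking") <- out$model[order(out$r2_test, decreasing = TRUE)]
  attr(out, "split") <- sp
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  cat("ranking by r2_test:", paste(attr(x, "ranking"), collapse = " > "), "\n")
  invisible(x)
}
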