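# Four-step descriptor pretreatment: positive-energy truncation,
# standard-deviation feature filter, optional standardization, PCA.
# Fitted statistics are frozen on the training rows so transforms of new
# data never leak information.

#' Pretreatment configuration
#'
#' @param truncate_positive replace strictly positive interaction energies by
#'   zero before anything else (default \code{TRUE}); positive energies in a
#'   minimized structure usually flag force-field artifacts.
#' @param std_threshold columns whose sample standard deviation (n-1
#'   denominator) is below this value (kcal/mol) are dropped; 0 keeps all.
#' @param standardize scale retained columns to zero mean / unit variance
#'   before PCA (default \code{FALSE}).
#' @param n_components number of principal components; \code{NULL} defaults at
#'   fit time to \code{min(n_rows - 1, n_retained_columns)}.
#' @return list of class \code{pretreat_config}.
#' @export
pretreat_config <- function(truncate_positive = TRUE, std_threshold = 0,
                            standardize = FALSE, n_components = NULL) {
  if (!is.numeric(std_threshold) || std_threshold < 0) {
    stopf("std_threshold must be >= 0")
  }
  if (!is.null(n_components) && !is_count(n_components)) {
    stopf("n_components must be a positive integer")
  }
  structure(list(truncate_positive = isTRUE(truncate_positive),
                 std_threshold = std_threshold,
                 standardize = isTRUE(standardize),
                 n_components = if (is.null(n_components)) NULL else as.integer(n_components)),
            class = "pretreat_config")
}

#' Truncate positive interaction energies to zero
#'
#' @param X numeric descriptor matrix.
#' @return matrix with every strictly positive entry replaced by 0.
#' @export
truncate_positive <- function(X) {
  X <- as.matrix(X)
  X[X > 0] <- 0
  X
}

#' Drop low-variance descriptor columns
#'
#' @param X numeric matrix with at least 2 rows.
#' @param std_threshold columns with sample standard deviation strictly below
#'   this are removed.
#' @return list with \code{X} (reduced matrix, column order preserved) and
#'   \code{retained_columns} (integer indices into the input).
#' @export
filter_low_variance <- function(X, std_threshold) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stopf("need >= 2 rows to estimate column standard deviations")
  sds <- apply(X, 2L, sd)
  keep <- unname(which(sds >= std_threshold))
  if (!length(keep)) {
    stopf("std_threshold = %g removes every column; lower the threshold", std_threshold)
  }
  list(X = X[, keep, drop = FALSE], retained_columns = keep)
}

#' Fit the pretreatment pipeline on training descriptors
#'
#' Applies, in order: positive truncation, the standard-deviation filter,
#' optional standardization, and PCA (by SVD of the centered matrix, with
#' each component's sign fixed so its largest-magnitude loading is positive).
#' All statistics are estimated from \code{X} only and frozen in the returned
#' object.
#'
#' @param X training descriptor matrix (rows = complexes).
#' @param cfg a \code{\link{pretreat_config}}.
#' @return object of class \code{fitted_pretreatment} with elements
#'   \code{retained_columns}, \code{column_means}, \code{column_scales},
#'   \code{pca_mean}, \code{pca_loadings} (components in rows) and
#'   \code{explained_variance}.
#' @export
pretreat_fit <- function(X, cfg = pretreat_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stopf("pretreatment needs >= 2 training rows")
  X1 <- if (cfg$truncate_positive) truncate_positive(X) else X
  fl <- filter_low_variance(X1, cfg$std_threshold)
  Xr <- fl$X
  means <- colMeans(Xr)
  scales <- if (cfg$standardize) apply(Xr, 2L, sd) else rep(1, ncol(Xr))
  if (any(scales == 0)) stopf("cannot standardize a zero-variance column")
  Z <- sweep(sweep(Xr, 2L, means, "-"), 2L, scales, "/")
  k_max <- min(n - 1L, ncol(Z))
  k <- if (is.null(cfg$n_components)) k_max else cfg$n_components
  if (k > k_max) {
    stopf("n_components = %d exceeds min(n_rows - 1, retained columns) = %d", k, k_max)
  }
  p <- pca_fit(Z, k)
  structure(list(
    config = cfg,
    n_input_columns = ncol(X),
    input_column_names = colnames(X),
    retained_columns = fl$retained_columns,
    column_means = means,
    column_scales = scales,
    pca_mean = p$mean,
    pca_loadings = p$loadings,
    explained_variance = p$ev,
    total_variance = p$total_var,
    n_components = k
  ), class = "fitted_pretreatment")
}

#' @export
print.fitted_pretreatment <- function(x, ...) {
  cat(sprintf("<fitted_pretreatment: %d/%d columns retained, %d components (%.1f%% variance)>\n",
              length(x$retained_columns), x$n_input_columns, x$n_components,
              100 * sum(x$explained_variance) / max(x$total_variance, .Machine$double.eps)))
  invisible(x)
}

#' Apply a fitted pretreatment to new descriptors
#'
#' Applies the frozen truncate / filter / scale / project sequence; no
#' statistic is re-estimated from \code{X_new}.
#'
#' @param fitted a \code{\link{pretreat_fit}} result.
#' @param X_new matrix with the same columns as the training matrix.
#' @return component-score matrix (rows x \code{n_components}).
#' @export
pretreat_transform <- function(fitted, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != fitted$n_input_columns) {
    stopf("X_new has %d columns; pretreatment was fitted on %d",
          ncol(X_new), fitted$n_input_columns)
  }
  X1 <- if (fitted$config$truncate_positive) truncate_positive(X_new) else X_new
  Xr <- X1[, fitted$retained_columns, drop = FALSE]
  Z <- sweep(sweep(Xr, 2L, fitted$column_means, "-"), 2L, fitted$column_scales, "/")
  S <- pca_scores(list(mean = fitted$pca_mean, loadings = fitted$pca_loadings), Z)
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  rownames(S) <- rownames(X_new)
  S
}

#' Choose the number of principal components by LOO-CV Q-squared
#'
#' Runs \code{\link{loo_cv}} over candidate component counts and returns the
#' count maximizing \eqn{Q^2_{cv}}. Used when a configuration leaves
#' \code{n_components} unset and labels are available.
#'
#' @param X training descriptor matrix.
#' @param y training pkoff labels.
#' @param spec a \code{\link{regressor_spec}} evaluated at each candidate.
#' @param cfg base \code{\link{pretreat_config}} (its \code{n_components} is
#'   overridden).
#' @param candidates integer vector of component counts to try; defaults to
#'   1 .. min(n-2, retained columns, 10).
#' @return list with \code{n_components} and \code{q2} per candidate.
#' @export
select_n_components <- function(X, y, spec, cfg = pretreat_config(),
                                candidates = NULL) {
  X <- as.matrix(X)
  if (is.null(candidates)) {
    upper <- min(nrow(X) - 2L, ncol(X), 10L)
    candidates <- seq_len(max(upper, 1L))
  }
  q2 <- vapply(candidates, function(k) {
    cfg_k <- cfg
    cfg_k$n_components <- as.integer(k)
    loo_cv(spec, cfg_k, X, y)$q2
  }, numeric(1))
  list(n_components = candidates[which.max(q2)],
       q2 = setNames(q2, candidates))
}
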