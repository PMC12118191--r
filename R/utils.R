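# Internal helpers shared across modules.

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the prior
# RNG state afterwards so library calls never clobber a user's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  expr
}

# Deterministic per-stage seed derived from one global seed; kept < 2^31.
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) + 7919 * h) %% 2147483587L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# PCA by SVD of a centered (already scaled, if requested) matrix.
# Returns loadings with components in ROWS, sign-fixed so the
# largest-magnitude loading of each component is positive.
# `ev` is the sample variance (n-1 denominator) along each component.
pca_fit <- function(M, n_components) {
  M <- as.matrix(M)
  n <- nrow(M)
  ctr <- colMeans(M)
  Z <- sweep(M, 2L, ctr, "-")
  sv <- svd(Z, nu = 0L, nv = min(n_components, min(dim(Z))))
  if (ncol(sv$v) < n_components) {
    stopf("requested %d principal components but rank is at most %d",
          n_components, ncol(sv$v))
  }
  L <- t(sv$v[, seq_len(n_components), drop = FALSE])
  for (j in seq_len(nrow(L))) {
    k <- which.max(abs(L[j, ]))
    if (L[j, k] < 0) L[j, ] <- -L[j, ]
  }
  list(
    mean = ctr,
    loadings = L,
    ev = (sv$d[seq_len(n_components)]^2) / (n - 1),
    total_var = sum(Z^2) / (n - 1)
  )
}

pca_scores <- function(fit, M) {
  sweep(as.matrix(M), 2L, fit$mean, "-") %*% t(fit$loadings)
}
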