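# Exact-greedy regression tree used by the random-forest and boosted-tree
# regressors. Leaf values and split gains use the regularized sum form
#   value(S) = sum(r_S) / (|S| + lambda)
#   gain     = G_L^2/(n_L+lambda) + G_R^2/(n_R+lambda) - G^2/(n+lambda)
# which reduces to variance-reduction splitting with mean leaves at
# lambda = 0 (random forest) and to second-order (unit-Hessian) boosting
# gains otherwise.

grow_tree <- function(X, r, lambda = 0, min_child = 5L, max_depth = 12L,
                      mtry = ncol(X)) {
  nodes <- list()
  add_node <- function(idx, depth) {
    id <- length(nodes) + 1L
    n <- length(idx)
    G <- sum(r[idx])
    node <- list(leaf = TRUE, value = G / (n + lambda),
                 var = NA_integer_, split = NA_real_, left = NA_integer_,
                 right = NA_integer_)
    nodes[[id]] <<- node
    if (depth >= max_depth || n < 2L * min_child) return(id)

    feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
    best <- list(gain = 1e-12)
    parent_score <- G^2 / (n + lambda)
    for (j in feats) {
      xj <- X[idx, j]
      o <- order(xj)
      xs <- xj[o]
      cs <- cumsum(r[idx][o])
      nl <- seq_len(n - 1L)
      valid <- (xs[nl] < xs[nl + 1L]) & (nl >= min_child) & ((n - nl) >= min_child)
      if (!any(valid)) next
      gl <- cs[nl]
      score <- gl^2 / (nl + lambda) + (G - gl)^2 / (n - nl + lambda) - parent_score
      score[!valid] <- -Inf
      k <- which.max(score)
      if (score[k] > best$gain) {
        best <- list(gain = score[k], var = j,
                     split = (xs[k] + xs[k + 1L]) / 2,
                     left_idx = idx[o[seq_len(k)]],
                     right_idx = idx[o[(k + 1L):n]])
      }
    }
    if (is.null(best$var)) return(id)
    left_id <- add_node(best$left_idx, depth + 1L)
    right_id <- add_node(best$right_idx, depth + 1L)
    nodes[[id]]$leaf <<- FALSE
    nodes[[id]]$var <<- best$var
    nodes[[id]]$split <<- best$split
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    id
  }
  add_node(seq_len(nrow(X)), 0L)
  nodes
}

predict_tree <- function(nodes, X) {
  out <- numeric(nrow(X))
  walk <- function(id, idx) {
    node <- nodes[[id]]
    if (node$leaf) {
      out[idx] <<- node$value
      return(invisible(NULL))
    }
    go_left <- X[idx, node$var] <= node$split
    if (any(go_left)) walk(node$left, idx[go_left])
    if (any(!go_left)) walk(node$right, idx[!go_left])
  }
  if (nrow(X)) walk(1L, seq_len(nrow(X)))
  out
}
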