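# The uniform fit/predict regressor contract: the Bayesian neural network
# plus seven classical baselines (PLSR, BR, GPR, PCR, RF, SVM, XGBoost) and
# a "Mean" null model. The pre-installed stack offers no PLS/SVM/forest/
# boosting packages, so the baselines are compact in-repo implementations of
# the standard algorithms (NIPALS PLS1, evidence-maximization Bayesian ridge,
# marginal-likelihood RBF GP, SVD PCR, bagged/boosted exact-greedy trees,
# dual-QP epsilon-SVR via quadprog).

REGRESSOR_KINDS <- c("BNN", "PLSR", "BR", "GPR", "PCR", "RF", "SVM",
                     "XGBoost", "Mean")

#' Specify a regressor
#'
#' @param kind one of \code{"BNN"}, \code{"PLSR"}, \code{"BR"}, \code{"GPR"},
#'   \code{"PCR"}, \code{"RF"}, \code{"SVM"}, \code{"XGBoost"} or the null
#'   baseline \code{"Mean"} (case-insensitive).
#' @param hyperparameters named list of kind-specific settings (see Details).
#' @param seed RNG seed honored by every stochastic kind.
#'
#' @details Recognized hyperparameters by kind:
#' \describe{
#'   \item{BNN}{any \code{\link{bnn_config}} argument.}
#'   \item{PLSR / PCR}{\code{n_components} (default: full rank).}
#'   \item{BR}{\code{max_iter}, \code{tol}.}
#'   \item{GPR}{\code{init_length_scale}, \code{init_noise_frac}.}
#'   \item{RF}{\code{ntree} (200), \code{mtry} (p/3), \code{min_node} (5),
#'     \code{max_depth} (12).}
#'   \item{SVM}{\code{cost} (1), \code{epsilon} (0.1), \code{gamma}
#'     (1/(p * var(x)), the "scale" heuristic).}
#'   \item{XGBoost}{\code{nrounds} (100), \code{eta} (0.3), \code{max_depth}
#'     (3), \code{lambda} (1), \code{min_child} (1).}
#' }
#' @return list of class \code{regressor_spec}.
#' @export
regressor_spec <- function(kind, hyperparameters = list(), seed = 1L) {
  i <- match(tolower(kind), tolower(REGRESSOR_KINDS))
  if (is.na(i)) {
    stopf("unknown regressor kind '%s'; expected one of %s", kind,
          paste(REGRESSOR_KINDS, collapse = ", "))
  }
  structure(list(kind = REGRESSOR_KINDS[i],
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "regressor_spec")
}

#' Build a regressor object with a uniform fit/predict contract
#'
#' @param spec a \code{\link{regressor_spec}}.
#' @return list with elements \code{spec}, \code{fit(x, y)} returning a
#'   fitted model, and \code{predict(fitted, x)} returning numeric
#'   predictions.
#' @export
make_regressor <- function(spec) {
  stopifnot(inherits(spec, "regressor_spec"))
  list(spec = spec,
       fit = function(x, y) fit_regressor(spec, x, y),
       predict = function(fitted, x) predict(fitted, x))
}

#' Fit a regressor specified by a \code{regressor_spec}
#'
#' @inheritParams make_regressor
#' @param x numeric predictor matrix (pretreatment component scores).
#' @param y numeric response vector.
#' @return fitted model of class \code{koff_<kind>} (and
#'   \code{koff_regressor}) supporting \code{predict(fitted, x)}.
#' @export
fit_regressor <- function(spec, x, y) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("x and y disagree on sample count")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite training values")
  hp <- spec$hyperparameters
  fitted <- switch(spec$kind,
    BNN = fit_bnn_kind(x, y, hp, spec$seed),
    PLSR = fit_plsr(x, y, hp),
    BR = fit_bayes_ridge(x, y, hp),
    GPR = fit_gpr(x, y, hp),
    PCR = fit_pcr(x, y, hp),
    RF = with_seed(spec$seed, fit_rf(x, y, hp)),
    SVM = fit_svr(x, y, hp),
    XGBoost = fit_xgb(x, y, hp),
    Mean = list(mean = mean(y))
  )
  fitted$kind <- spec$kind
  fitted$n_features <- ncol(x)
  class(fitted) <- c(paste0("koff_", tolower(spec$kind)), "koff_regressor")
  fitted
}

check_predict_input <- function(object, x) {
  x <- as.matrix(x)
  if (ncol(x) != object$n_features) {
    stopf("%s model expects %d feature columns, got %d", object$kind,
          object$n_features, ncol(x))
  }
  x
}

#' @export
print.koff_regressor <- function(x, ...) {
  cat(sprintf("<fitted %s regressor on %d features>\n", x$kind, x$n_features))
  invisible(x)
}

# --- BNN adapter ------------------------------------------------------------

fit_bnn_kind <- function(x, y, hp, seed) {
  args <- hp
  if (is.null(args$seed)) args$seed <- seed
  cfg <- do.call(bnn_config, args)
  list(model = bnn_fit(x, y, cfg))
}

#' @export
predict.koff_bnn <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  bnn_predict(object$model, x)$mean
}

# --- PLSR: univariate-response NIPALS --------------------------------------
# With n_components equal to the predictor rank this reproduces OLS.

fit_plsr <- function(x, y, hp) {
  n <- nrow(x); p <- ncol(x)
  ncomp <- hp$n_components %||% min(p, n - 1L)
  if (!is_count(ncomp) || ncomp > min(p, n - 1L)) {
    stopf("PLSR n_components must be in 1..min(p, n-1) = %d", min(p, n - 1L))
  }
  mx <- colMeans(x); my <- mean(y)
  E <- sweep(x, 2L, mx, "-"); f <- y - my
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    P[, a] <- crossprod(E, t_) / tt
    q[a] <- sum(f * t_) / tt
    W[, a] <- w
    E <- E - t_ %*% t(P[, a])
    f <- f - t_ * q[a]
  }
  if (ncomp < 1L) stopf("PLSR found no usable component (zero-variance response?)")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  B <- W %*% solve(t(P) %*% W, q)
  list(coef = B, x_mean = mx, y_mean = my, n_components = ncomp)
}

#' @export
predict.koff_plsr <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  drop(sweep(x, 2L, object$x_mean, "-") %*% object$coef) + object$y_mean
}

# --- Bayesian ridge: evidence maximization (MacKay updates) -----------------

fit_bayes_ridge <- function(x, y, hp) {
  max_iter <- hp$max_iter %||% 300L
  tol <- hp$tol %||% 1e-8
  n <- nrow(x); p <- ncol(x)
  mx <- colMeans(x); my <- mean(y)
  Xc <- sweep(x, 2L, mx, "-"); yc <- y - my
  XtX <- crossprod(Xc); Xty <- crossprod(Xc, yc)
  alpha <- 1 / max(var(yc), 1e-8)   # noise precision
  lambda <- 1e-4                    # weight precision
  m <- numeric(p)
  for (it in seq_len(max_iter)) {
    A <- alpha * XtX + diag(lambda, p)
    m_new <- drop(alpha * solve(A, Xty))
    gamma <- p - lambda * sum(diag(solve(A)))
    rss <- sum((yc - Xc %*% m_new)^2)
    lambda_new <- gamma / max(sum(m_new^2), 1e-12)
    alpha_new <- max(n - gamma, 1e-8) / max(rss, 1e-12)
    done <- max(abs(m_new - m)) < tol
    m <- m_new; lambda <- lambda_new; alpha <- alpha_new
    if (done) break
  }
  list(coef = m, x_mean = mx, y_mean = my, alpha = alpha, lambda = lambda)
}

#' @export
predict.koff_br <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  drop(sweep(x, 2L, object$x_mean, "-") %*% object$coef) + object$y_mean
}

# --- GPR: RBF kernel, type-II maximum likelihood ----------------------------

rbf_kernel <- function(D2, log_ell, log_sf) {
  exp(2 * log_sf) * exp(-D2 / (2 * exp(2 * log_ell)))
}

sq_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  pmax(outer(an, bn, "+") - 2 * A %*% t(B), 0)
}

fit_gpr <- function(x, y, hp) {
  n <- nrow(x)
  my <- mean(y); yc <- y - my
  D2 <- sq_dist(x, x)
  med <- stats::median(sqrt(D2[upper.tri(D2)]))
  theta0 <- c(log_ell = log(hp$init_length_scale %||% max(med, 1e-3)),
              log_sf = log(max(sd(yc), 1e-3)),
              log_sn = log(max((hp$init_noise_frac %||% 0.1) * sd(yc), 1e-4)))
  nll <- function(theta) {
    K <- rbf_kernel(D2, theta[1], theta[2]) + diag(exp(2 * theta[3]) + 1e-8, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    a <- backsolve(ch, forwardsolve(t(ch), yc))
    0.5 * sum(yc * a) + sum(log(diag(ch))) + n / 2 * log(2 * pi)
  }
  opt <- optim(theta0, nll, method = "L-BFGS-B",
               lower = c(log(1e-3), log(1e-4), log(1e-5)),
               upper = c(log(1e4), log(1e4), log(1e4)))
  th <- opt$par
  K <- rbf_kernel(D2, th[1], th[2]) + diag(exp(2 * th[3]), n)
  jitter <- 1e-8
  ch <- NULL
  while (is.null(ch) && jitter < 1e-2) {
    ch <- tryCatch(chol(K + diag(jitter, n)), error = function(e) NULL)
    if (is.null(ch)) jitter <- jitter * 10
  }
  if (is.null(ch)) stopf("GPR kernel matrix is numerically singular")
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(x_train = x, alpha = alpha, theta = th, y_mean = my)
}

#' @export
predict.koff_gpr <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  Ks <- rbf_kernel(sq_dist(x, object$x_train), object$theta[1], object$theta[2])
  drop(Ks %*% object$alpha) + object$y_mean
}

# --- PCR: PCA then ordinary least squares on scores ------------------------

fit_pcr <- function(x, y, hp) {
  n <- nrow(x); p <- ncol(x)
  ncomp <- hp$n_components %||% min(p, n - 1L)
  if (!is_count(ncomp) || ncomp > min(p, n - 1L)) {
    stopf("PCR n_components must be in 1..min(p, n-1) = %d", min(p, n - 1L))
  }
  pca <- pca_fit(x, ncomp)
  S <- pca_scores(pca, x)
  my <- mean(y)
  beta <- drop(solve(crossprod(S) + diag(1e-10, ncomp), crossprod(S, y - my)))
  list(pca = pca, coef = beta, y_mean = my, n_components = ncomp)
}

#' @export
predict.koff_pcr <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  drop(pca_scores(object$pca, x) %*% object$coef) + object$y_mean
}

# --- Random forest: bagged variance-reduction trees ------------------------

fit_rf <- function(x, y, hp) {
  ntree <- hp$ntree %||% 200L
  mtry <- hp$mtry %||% max(1L, floor(ncol(x) / 3))
  min_node <- hp$min_node %||% 5L
  max_depth <- hp$max_depth %||% 12L
  n <- nrow(x)
  trees <- lapply(seq_len(ntree), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], y[idx], lambda = 0,
              min_child = min_node, max_depth = max_depth, mtry = mtry)
  })
  list(trees = trees)
}

#' @export
predict.koff_rf <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  preds <- vapply(object$trees, function(tr) predict_tree(tr, x), numeric(nrow(x)))
  if (nrow(x) == 1L) mean(preds) else rowMeans(preds)
}

# --- epsilon-SVR: dual quadratic program (RBF kernel) ----------------------
# Standard 2n-variable dual with box constraints solved by quadprog; a small
# ridge keeps the (PSD, singular) dual Hessian numerically positive definite.

fit_svr <- function(x, y, hp) {
  n <- nrow(x)
  cost <- hp$cost %||% 1
  epsilon <- hp$epsilon %||% 0.1
  gamma <- hp$gamma %||% (1 / (ncol(x) * max(mean(apply(x, 2L, var)), 1e-8)))
  K <- exp(-gamma * sq_dist(x, x))
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-8, 2 * n)
  dvec <- c(y - epsilon, -y - epsilon)
  # constraints: sum(a) - sum(a*) = 0 (eq), a >= 0, a <= C
  Amat <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), rep(-cost, 2 * n))
  sol <- quadprog::solve.QP(D, dvec, Amat, bvec, meq = 1L)
  beta <- sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
  f0 <- drop(K %*% beta)
  # intercept from unbounded support vectors; fall back to median residual
  a <- sol$solution[1:n]; as_ <- sol$solution[(n + 1):(2 * n)]
  tolC <- 1e-6 * cost
  up <- a > tolC & a < cost - tolC
  lo <- as_ > tolC & as_ < cost - tolC
  b_cands <- c(y[up] - epsilon - f0[up], y[lo] + epsilon - f0[lo])
  b <- if (length(b_cands)) mean(b_cands) else stats::median(y - f0)
  list(x_train = x, beta = beta, b = b, gamma = gamma)
}

#' @export
predict.koff_svm <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  K <- exp(-object$gamma * sq_dist(x, object$x_train))
  drop(K %*% object$beta) + object$b
}

# --- XGBoost-style Newton boosting (squared loss => unit Hessian) ----------

fit_xgb <- function(x, y, hp) {
  nrounds <- hp$nrounds %||% 100L
  eta <- hp$eta %||% 0.3
  max_depth <- hp$max_depth %||% 3L
  lambda <- hp$lambda %||% 1
  min_child <- hp$min_child %||% 1L
  base <- mean(y)
  pred <- rep(base, length(y))
  trees <- vector("list", nrounds)
  for (m in seq_len(nrounds)) {
    tr <- grow_tree(x, y - pred, lambda = lambda, min_child = min_child,
                    max_depth = max_depth, mtry = ncol(x))
    trees[[m]] <- tr
    pred <- pred + eta * predict_tree(tr, x)
  }
  list(trees = trees, base = base, eta = eta)
}

#' @export
predict.koff_xgboost <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  out <- rep(object$base, nrow(x))
  for (tr in object$trees) out <- out + object$eta * predict_tree(tr, x)
  out
}

# --- Mean: null baseline ----------------------------------------------------

#' @export
predict.koff_mean <- function(object, newdata, ...) {
  x <- check_predict_input(object, newdata)
  rep(object$mean, nrow(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
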