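# Variational Bayesian neural network regressor.
#
# A fully connected network whose weights and biases carry a fully factorized
# Gaussian variational posterior q(w) = prod N(mu, sigma^2). Training
# minimizes the negative evidence lower bound
#     -ELBO = -E_q[log p(y | f_w(x), sigma_n)] + KL(q || N(0, prior_std^2))
# by stochastic gradient (reparameterized weight samples, Adam). The
# Gaussian observation noise scale sigma_n is a single learnable
# (log-parameterized) point parameter. Predictions are Monte Carlo draws
# from the posterior predictive: weight draw + likelihood noise.

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)
inv_softplus <- function(y) log(expm1(y))

#' Bayesian neural network configuration
#'
#' @param hidden_layer_sizes integer vector of hidden-layer widths (default
#'   one layer of 16 units).
#' @param activation \code{"sigmoid"} (default), \code{"tanh"} or
#'   \code{"relu"}.
#' @param prior_std standard deviation of the zero-mean Gaussian weight prior.
#' @param learning_rate Adam step size (default 1e-2).
#' @param epochs full-batch gradient steps (default 2000).
#' @param elbo_mc_samples Monte Carlo weight draws per gradient step.
#' @param posterior_samples predictive draws used by
#'   \code{\link{bnn_predict}} (default 1000).
#' @param seed RNG seed; fits are bitwise deterministic given the seed.
#' @return list of class \code{bnn_config}.
#' @export
bnn_config <- function(hidden_layer_sizes = 16L, activation = "sigmoid",
                       prior_std = 1.0, learning_rate = 1e-2, epochs = 2000L,
                       elbo_mc_samples = 1L, posterior_samples = 1000L,
                       seed = 1L) {
  if (!all(vapply(hidden_layer_sizes, is_count, logical(1)))) {
    stopf("hidden_layer_sizes must be positive integers")
  }
  activation <- match.arg(activation, c("sigmoid", "tanh", "relu"))
  if (!is.numeric(prior_std) || prior_std <= 0) stopf("prior_std must be > 0")
  for (nm in c("epochs", "elbo_mc_samples", "posterior_samples")) {
    if (!is_count(get(nm))) stopf("%s must be a positive integer", nm)
  }
  structure(list(hidden_layer_sizes = as.integer(hidden_layer_sizes),
                 activation = activation, prior_std = prior_std,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 elbo_mc_samples = as.integer(elbo_mc_samples),
                 posterior_samples = as.integer(posterior_samples),
                 seed = as.integer(seed)),
            class = "bnn_config")
}

bnn_act <- function(z, kind) {
  switch(kind,
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         relu = pmax(z, 0))
}

bnn_act_grad <- function(a, z, kind) {
  switch(kind,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         relu = (z > 0) + 0)
}

# allocate parameter arrays for layer sizes c(d, hidden..., 1)
bnn_init_params <- function(sizes, init_sigma = 0.05) {
  L <- length(sizes) - 1L
  mk <- function(nr, nc, sd0) matrix(rnorm(nr * nc, 0, sd0), nr, nc)
  list(
    mu_W = lapply(seq_len(L), function(l) mk(sizes[l], sizes[l + 1L], 1 / sqrt(sizes[l]))),
    rho_W = lapply(seq_len(L), function(l) matrix(inv_softplus(init_sigma), sizes[l], sizes[l + 1L])),
    # hidden biases start spread out so the sigmoid features are not
    # collinear at initialization; the output bias starts at zero
    mu_b = lapply(seq_len(L), function(l) {
      if (l < L) rnorm(sizes[l + 1L], 0, 1) else numeric(sizes[l + 1L])
    }),
    rho_b = lapply(seq_len(L), function(l) rep(inv_softplus(init_sigma), sizes[l + 1L]))
  )
}

# KL(q || prior) summed over all weights/biases, plus its gradients
bnn_kl <- function(p, prior_std) {
  kl <- 0
  for (l in seq_along(p$mu_W)) {
    for (part in c("W", "b")) {
      mu <- p[[paste0("mu_", part)]][[l]]
      sg <- softplus(p[[paste0("rho_", part)]][[l]])
      kl <- kl + sum(log(prior_std / sg) + (sg^2 + mu^2) / (2 * prior_std^2) - 0.5)
    }
  }
  kl
}

# forward pass with explicit weights; returns prediction and caches
bnn_forward <- function(X, W, b, activation) {
  L <- length(W)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% W[[l]] + matrix(b[[l]], nrow(X), length(b[[l]]), byrow = TRUE)
    A[[l + 1L]] <- if (l < L) bnn_act(Z[[l]], activation) else Z[[l]]
  }
  list(f = A[[L + 1L]][, 1L], A = A, Z = Z)
}

# backprop of dLoss/df through the network; returns grads wrt W and b
bnn_backward <- function(fw, W, dL_df, activation) {
  L <- length(W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix(dL_df, ncol = 1L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(W[[l]])) *
        bnn_act_grad(fw$A[[l]], fw$Z[[l - 1L]], activation)
    }
  }
  list(W = gW, b = gb)
}

# Monte Carlo ELBO estimate at the current variational parameters
bnn_elbo_estimate <- function(p, log_sigma, X, yc, cfg, n_draws = 100L) {
  n <- length(yc)
  sn <- exp(log_sigma)
  ll <- vapply(seq_len(n_draws), function(s) {
    W <- vector("list", length(p$mu_W)); b <- W
    for (l in seq_along(W)) {
      W[[l]] <- p$mu_W[[l]] + softplus(p$rho_W[[l]]) * matrix(rnorm(length(p$mu_W[[l]])), nrow(p$mu_W[[l]]))
      b[[l]] <- p$mu_b[[l]] + softplus(p$rho_b[[l]]) * rnorm(length(p$mu_b[[l]]))
    }
    f <- bnn_forward(X, W, b, cfg$activation)$f
    -n / 2 * log(2 * pi) - n * log_sigma - sum((yc - f)^2) / (2 * sn^2)
  }, numeric(1))
  mean(ll) - bnn_kl(p, cfg$prior_std)
}

#' Fit the Bayesian neural network
#'
#' Trains a mean-field Gaussian variational posterior over all network
#' weights and biases by full-batch Adam on the negative ELBO, using
#' reparameterized weight samples. Targets are centered internally (the mean
#' is restored at prediction time). The fit records Monte Carlo ELBO
#' estimates (100 draws) at initialization and after training.
#'
#' @param x numeric matrix of predictors (pretreatment component scores).
#' @param y numeric vector of pkoff labels (>= 3 values).
#' @param cfg a \code{\link{bnn_config}}.
#' @return object of class \code{bnn_fit}.
#' @export
bnn_fit <- function(x, y, cfg = bnn_config()) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stopf("x and y disagree on sample count")
  if (length(y) < 3L) stopf("BNN needs >= 3 training rows")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite training values")

  with_seed(cfg$seed, {
    n <- length(y)
    y_mean <- mean(y)
    yc <- y - y_mean
    sizes <- c(ncol(x), cfg$hidden_layer_sizes, 1L)
    p <- bnn_init_params(sizes)
    # warm-start the output-layer means by ridge least squares on the
    # initial hidden activations: purely an optimization aid (the ELBO is
    # unchanged), it saves Adam hundreds of epochs of linear-readout fitting
    nl <- length(p$mu_W)
    Ah <- x
    for (l in seq_len(nl - 1L)) {
      Ah <- bnn_act(Ah %*% p$mu_W[[l]] +
                      matrix(p$mu_b[[l]], n, length(p$mu_b[[l]]), byrow = TRUE),
                    cfg$activation)
    }
    Ahc <- cbind(Ah, 1)
    beta0 <- drop(solve(crossprod(Ahc) + diag(1e-2, ncol(Ahc)), crossprod(Ahc, yc)))
    p$mu_W[[nl]][, 1L] <- beta0[seq_len(ncol(Ah))]
    p$mu_b[[nl]][1L] <- beta0[ncol(Ahc)]
    # start the likelihood confident (a fraction of the label spread): a
    # noise scale initialized at sd(y) mutes early likelihood gradients and
    # lets the noise term absorb signal, a common VI local optimum
    log_sigma <- log(max(0.25 * sd(yc), 1e-3))
    elbo_init <- bnn_elbo_estimate(p, log_sigma, x, yc, cfg, 100L)

    # flat Adam state over the parameter lists + log_sigma
    slots <- c("mu_W", "rho_W", "mu_b", "rho_b")
    adam_m <- lapply(p, function(g) lapply(g, function(a) a * 0))
    adam_v <- adam_m
    m_ls <- 0; v_ls <- 0
    b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
    lr <- cfg$learning_rate
    S <- cfg$elbo_mc_samples

    for (t in seq_len(cfg$epochs)) {
      grad <- lapply(p, function(g) lapply(g, function(a) a * 0))
      g_ls <- 0
      sn2 <- exp(2 * log_sigma)
      L <- length(p$mu_W)
      for (s in seq_len(S)) {
        # local reparameterization: hidden pre-activations are sampled as
        # Z ~ N(A mu_W + mu_b, A^2 sig_W^2 + sig_b^2) per unit; the final
        # (linear-Gaussian) layer is marginalized in closed form,
        # E[(y - Z_L)^2] = (y - M_L)^2 + V_L. Both choices leave the ELBO
        # estimate unbiased while cutting gradient variance.
        A <- vector("list", L + 1L); A[[1L]] <- x
        Sdv <- vector("list", L); E <- Sdv; Z <- Sdv
        M_out <- NULL; V_out <- NULL
        sw <- lapply(p$rho_W, softplus); sb <- lapply(p$rho_b, softplus)
        for (l in seq_len(L)) {
          q_out <- length(p$mu_b[[l]])
          M <- A[[l]] %*% p$mu_W[[l]] +
            matrix(p$mu_b[[l]], n, q_out, byrow = TRUE)
          V <- (A[[l]]^2) %*% (sw[[l]]^2) +
            matrix(sb[[l]]^2, n, q_out, byrow = TRUE)
          if (l < L) {
            Sdv[[l]] <- sqrt(V + 1e-12)
            E[[l]] <- matrix(rnorm(n * q_out), n, q_out)
            Z[[l]] <- M + Sdv[[l]] * E[[l]]
            A[[l + 1L]] <- bnn_act(Z[[l]], cfg$activation)
          } else {
            M_out <- M; V_out <- V
          }
        }
        resid <- yc - M_out[, 1L]
        # d(-E[loglik])/dM_L = -(y - M)/sigma_n^2 ; d/dV_L = 1/(2 sigma_n^2)
        delta <- matrix(-resid / sn2, ncol = 1L)
        for (l in rev(seq_len(L))) {
          Cm <- if (l == L) matrix(1 / (2 * sn2), n, 1L) else
            delta * E[[l]] / (2 * Sdv[[l]])
          sig_rW <- 1 / (1 + exp(-p$rho_W[[l]]))   # d softplus/d rho
          sig_rb <- 1 / (1 + exp(-p$rho_b[[l]]))
          grad$mu_W[[l]] <- grad$mu_W[[l]] + crossprod(A[[l]], delta) / S
          grad$mu_b[[l]] <- grad$mu_b[[l]] + colSums(delta) / S
          grad$rho_W[[l]] <- grad$rho_W[[l]] +
            (crossprod(A[[l]]^2, Cm) * 2 * sw[[l]] * sig_rW) / S
          grad$rho_b[[l]] <- grad$rho_b[[l]] +
            (colSums(Cm) * 2 * sb[[l]] * sig_rb) / S
          if (l > 1L) {
            dA <- delta %*% t(p$mu_W[[l]]) +
              (Cm %*% t(sw[[l]]^2)) * (2 * A[[l]])
            delta <- dA * bnn_act_grad(A[[l]], Z[[l - 1L]], cfg$activation)
          }
        }
        # d(-E[loglik])/d log_sigma = n - (SSE + sum V)/sigma_n^2
        g_ls <- g_ls + (n - (sum(resid^2) + sum(V_out)) / sn2) / S
      }
      # KL gradients (deterministic)
      ps2 <- cfg$prior_std^2
      for (l in seq_along(p$mu_W)) {
        for (part in c("W", "b")) {
          mu_nm <- paste0("mu_", part); rho_nm <- paste0("rho_", part)
          sg <- softplus(p[[rho_nm]][[l]])
          dsg <- 1 / (1 + exp(-p[[rho_nm]][[l]]))
          grad[[mu_nm]][[l]] <- grad[[mu_nm]][[l]] + p[[mu_nm]][[l]] / ps2
          grad[[rho_nm]][[l]] <- grad[[rho_nm]][[l]] + (sg / ps2 - 1 / sg) * dsg
        }
      }
      if (!all(vapply(grad, function(g) all(vapply(g, function(a) all(is.finite(a)), logical(1))), logical(1))) ||
          !is.finite(g_ls)) {
        stopf("BNN training diverged (non-finite gradient at step %d); try a smaller learning_rate", t)
      }
      # Adam updates
      bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
      for (slot in slots) {
        for (l in seq_along(p[[slot]])) {
          g <- grad[[slot]][[l]]
          adam_m[[slot]][[l]] <- b1 * adam_m[[slot]][[l]] + (1 - b1) * g
          adam_v[[slot]][[l]] <- b2 * adam_v[[slot]][[l]] + (1 - b2) * g^2
          p[[slot]][[l]] <- p[[slot]][[l]] -
            lr * (adam_m[[slot]][[l]] / bc1) / (sqrt(adam_v[[slot]][[l]] / bc2) + eps_adam)
        }
      }
      # the noise scale is frozen for the first quarter of training so the
      # network mean fits before the likelihood width adapts (avoids the
      # noise term absorbing unexplained signal early)
      if (t > cfg$epochs %/% 4L) {
        m_ls <- b1 * m_ls + (1 - b1) * g_ls
        v_ls <- b2 * v_ls + (1 - b2) * g_ls^2
        log_sigma <- log_sigma - lr * (m_ls / bc1) / (sqrt(v_ls / bc2) + eps_adam)
      }
    }

    elbo_final <- bnn_elbo_estimate(p, log_sigma, x, yc, cfg, 100L)
    structure(list(params = p, log_sigma = log_sigma, y_mean = y_mean,
                   n_features = ncol(x), config = cfg,
                   elbo_init = elbo_init, elbo_final = elbo_final),
              class = "bnn_fit")
  })
}

#' @export
print.bnn_fit <- function(x, ...) {
  cat(sprintf("<bnn_fit: %d features, hidden [%s], noise sd %.3f, ELBO %.1f -> %.1f>\n",
              x$n_features, paste(x$config$hidden_layer_sizes, collapse = ","),
              exp(x$log_sigma), x$elbo_init, x$elbo_final))
  invisible(x)
}

#' Posterior-predictive draws from a fitted BNN
#'
#' Each draw samples one set of weights from the variational posterior,
#' evaluates the network, and adds Gaussian likelihood noise. The point
#' prediction is the draw mean; \code{lower95}/\code{upper95} are the 2.5 and
#' 97.5 percent empirical quantiles of the draws.
#'
#' @param fitted a \code{\link{bnn_fit}}.
#' @param x_new matrix with the training column count.
#' @param posterior_samples number of draws; defaults to the fit
#'   configuration's value.
#' @param keep_draws also return the draw matrix (draws x rows).
#' @return list of class \code{posterior_prediction} with \code{mean},
#'   \code{lower95}, \code{upper95} and optionally \code{draws}.
#' @export
bnn_predict <- function(fitted, x_new, posterior_samples = NULL,
                        keep_draws = FALSE) {
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != fitted$n_features) {
    stopf("x_new has %d columns; model was trained on %d",
          ncol(x_new), fitted$n_features)
  }
  S <- if (is.null(posterior_samples)) fitted$config$posterior_samples else as.integer(posterior_samples)
  if (!is_count(S)) stopf("posterior_samples must be a positive integer")
  p <- fitted$params
  cfg <- fitted$config
  sn <- exp(fitted$log_sigma)
  with_seed(cfg$seed + 1L, {
    draws <- matrix(0, S, nrow(x_new))
    for (s in seq_len(S)) {
      W <- vector("list", length(p$mu_W)); b <- W
      for (l in seq_along(W)) {
        W[[l]] <- p$mu_W[[l]] + softplus(p$rho_W[[l]]) * matrix(rnorm(length(p$mu_W[[l]])), nrow(p$mu_W[[l]]))
        b[[l]] <- p$mu_b[[l]] + softplus(p$rho_b[[l]]) * rnorm(length(p$mu_b[[l]]))
      }
      f <- bnn_forward(x_new, W, b, cfg$activation)$f
      draws[s, ] <- f + fitted$y_mean + rnorm(nrow(x_new), 0, sn)
    }
    out <- list(mean = colMeans(draws),
                lower95 = apply(draws, 2L, quantile, probs = 0.025, names = FALSE),
                upper95 = apply(draws, 2L, quantile, probs = 0.975, names = FALSE))
    if (keep_draws) out$draws <- draws
    structure(out, class = "posterior_prediction")
  })
}
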