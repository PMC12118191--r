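# Dataset quality checks and the Bronsted-Evans-Polanyi validity fit.
#
# The BEP relation ties a kinetic quantity (activation energy, here proxied
# by pkoff = -log10 koff) linearly to a thermodynamic one (reaction energy,
# proxied by pKd). A reasonable linear pkoff ~ pKd fit supports using
# equilibrium-geometry descriptors to predict kinetics at all.

#' Fit the Bronsted-Evans-Polanyi proxy relation pkoff = alpha' pKd + beta'
#'
#' Ordinary least squares of pkoff on pKd over entries that carry both
#' values; entries with missing pKd are dropped with a warning.
#'
#' @param dataset a \code{\link{kinetic_dataset}} with a \code{pkd} column.
#' @return list of class \code{bep_fit} with \code{alpha_prime} (slope),
#'   \code{beta_prime} (intercept), \code{r2} and \code{n}.
#' @export
bep_fit <- function(dataset) {
  if (!("pkd" %in% names(dataset))) stopf("dataset has no pkd column")
  ok <- is.finite(dataset$pkoff) & is.finite(dataset$pkd)
  if (any(!ok)) {
    warnf("dropping %d entr%s without pKd", sum(!ok), if (sum(!ok) == 1) "y" else "ies")
  }
  x <- dataset$pkd[ok]; y <- dataset$pkoff[ok]
  if (length(x) < 3L) stopf("BEP fit needs >= 3 entries with both pkoff and pKd")
  if (var(x) == 0) stopf("pKd has zero variance: slope undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- fit$coefficients
  pred <- drop(cbind(1, x) %*% beta)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 0) 1 - sum((y - pred)^2) / sstot else NA_real_
  structure(list(alpha_prime = unname(beta[2]), beta_prime = unname(beta[1]),
                 r2 = r2, n = length(x)),
            class = "bep_fit")
}

#' @export
print.bep_fit <- function(x, ...) {
  cat(sprintf("<bep_fit (n = %d): pkoff = %.3f * pKd + %.3f, R2 = %.3f>\n",
              x$n, x$alpha_prime, x$beta_prime, x$r2))
  invisible(x)
}

#' Two-component chemical-space projection of molecular fingerprints
#'
#' PCA (centered, unscaled, same conventions as the pretreatment module) of a
#' binary or count fingerprint matrix; returns the first two component scores
#' and their explained-variance fractions. Any fingerprint type works; in the
#' intended use the rows are extended-connectivity fingerprints (radius 2,
#' 2048 bits) computed by an external cheminformatics tool.
#'
#' @param fingerprints numeric matrix, one molecule per row, >= 3 rows and
#'   >= 2 columns.
#' @return list of class \code{chemical_space} with \code{coords} (N x 2) and
#'   \code{explained} (length-2 variance fractions).
#' @export
chemical_space <- function(fingerprints) {
  M <- as.matrix(fingerprints)
  if (nrow(M) < 3L || ncol(M) < 2L) stopf("need >= 3 molecules and >= 2 fingerprint bits")
  if (all(apply(M, 2L, function(v) length(unique(v)) == 1L))) {
    stopf("all fingerprints identical: chemical space is degenerate")
  }
  p <- pca_fit(M, 2L)
  coords <- pca_scores(p, M)
  colnames(coords) <- c("PC1", "PC2")
  rownames(coords) <- rownames(M)
  structure(list(coords = coords, explained = p$ev / p$total_var),
            class = "chemical_space")
}

#' Summarize the pkoff label distribution
#'
#' Histogram over the full label range plus the adjusted Fisher--Pearson
#' skewness coefficient, quantifying how biased the label distribution is.
#'
#' @param dataset a \code{\link{kinetic_dataset}}.
#' @param bins number of equal-width histogram bins (default 10).
#' @return list with \code{breaks}, \code{counts}, \code{range},
#'   \code{skewness} and \code{n}.
#' @export
label_summary <- function(dataset, bins = 10L) {
  y <- dataset$pkoff
  n <- length(y)
  if (n < 3L) stopf("need >= 3 labels")
  rng <- range(y)
  breaks <- if (diff(rng) > 0) seq(rng[1], rng[2], length.out = bins + 1L) else
    seq(rng[1] - 0.5, rng[2] + 0.5, length.out = bins + 1L)
  counts <- as.integer(table(cut(y, breaks, include.lowest = TRUE)))
  m2 <- mean((y - mean(y))^2)
  m3 <- mean((y - mean(y))^3)
  g1 <- if (m2 > 0) m3 / m2^1.5 else 0
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  list(breaks = breaks, counts = counts, range = rng, skewness = skew, n = n)
}
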