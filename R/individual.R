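#' Observational (ordinary least squares) estimate
#'
#' Slope from the unadjusted linear regression of the outcome on the
#' exposure.  In the presence of confounding this is a biased estimate of
#' the causal effect; it is reported in simulation studies to show the
#' direction of confounding that weak-instrument bias acts towards.
#'
#' @param x exposure vector.
#' @param y outcome vector (same length, n >= 3).
#' @return A [causal_estimate()] with method `"ols"`.
#' @export
fit_ols <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("exposure has zero variance")
  b <- sum(xc * yc) / sxx
  rss <- sum(yc^2) - b * sum(xc * yc)
  se <- sqrt(max(rss, 0) / (n - 2) / sxx)
  if (se == 0) se <- .Machine$double.eps  # exact linear relationship
  causal_estimate(b, se, "ols", k_used = 0L)
}

#' Two-stage least squares with multiple instruments
#'
#' Regresses the exposure on all K genotype columns (first stage), then the
#' outcome on the fitted exposure (second stage).  Standard errors use the
#' conventional homoskedastic 2SLS variance, with second-stage residuals
#' recomputed at the observed exposure `y - a - b*x`, not at the fitted
#' values.
#'
#' @param g n x K genotype (dosage) matrix with entries in \{0, 1, 2\}.
#' @param x exposure vector.
#' @param y outcome vector.
#' @return A [causal_estimate()] with method `"2sls"`.
#' @export
fit_2sls <- function(g, x, y) {
  g <- as.matrix(g)
  n <- nrow(g); K <- ncol(g)
  stopifnot(length(x) == n, length(y) == n, n > K + 1)
  Z <- cbind(1, g)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- setdiff(seq_len(ncol(Z)), qz$pivot[seq_len(qz$rank)]) - 1L
    stop("first-stage design is rank deficient; offending genotype column(s): ",
         paste(bad, collapse = ", "))
  }
  xhat <- qr.fitted(qz, x)
  iv_fit(xhat, x, y, method = "2sls", k_used = K)
}

# Shared second stage: regress y on [1, xhat], residuals at observed x.
iv_fit <- function(xhat, x, y, method, k_used) {
  n <- length(y)
  hc <- xhat - mean(xhat)
  shh <- sum(hc^2)
  shx <- sum(hc * (x - mean(x)))
  if (shh < .Machine$double.eps * n || abs(shx) < .Machine$double.eps * n)
    stop("instrument explains no variance in the exposure (zero covariance)")
  b <- sum(hc * (y - mean(y))) / shx  # equals cov(y, xhat)/cov(x, xhat)
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 * shh / shx^2)
  causal_estimate(b, se, method, k_used = as.integer(k_used))
}

#' Build a weighted allele score
#'
#' Per-individual weighted sum of risk-allele counts, `z_i = sum_k w_k g_ik`.
#' With unit weights the score is integer-valued in \[0, 2K\].
#'
#' @param g n x K genotype matrix.
#' @param weights per-variant weights (length K).
#' @return Numeric score vector of length n.
#' @export
build_allele_score <- function(g, weights) {
  g <- as.matrix(g)
  stopifnot(length(weights) == ncol(g))
  as.vector(g %*% weights)
}

#' Allele score used as a single instrument
#'
#' Collapses the K variants into one weighted score and applies the ratio
#' (equivalently single-instrument 2SLS) method.  With weights estimated
#' from the analysis sample itself ("crude" weights) this reproduces the
#' multivariable 2SLS estimate asymptotically, inheriting its weak
#' instrument bias; with equal or externally derived weights the estimator
#' is median-unbiased even when instruments are weak.
#'
#' @param g n x K genotype matrix.
#' @param x exposure vector.
#' @param y outcome vector.
#' @param weights per-variant score weights.
#' @return A [causal_estimate()] with method `"allele_score_2sls"`.
#' @export
allele_score_2sls <- function(g, x, y, weights) {
  z <- build_allele_score(g, weights)
  n <- length(z)
  stopifnot(length(x) == n, length(y) == n)
  if (stats::var(z) == 0) stop("allele score is constant (zero variance)")
  zc <- z - mean(z)
  b1 <- sum(zc * (x - mean(x))) / sum(zc^2)
  xhat <- mean(x) + b1 * zc
  iv_fit(xhat, x, y, method = "allele_score_2sls", k_used = ncol(as.matrix(g)))
}

#' First-stage instrument strength
#'
#' R-squared and F statistic from the multivariable regression of the
#' exposure on all K instruments: `F = ((n - K - 1) / K) * R2 / (1 - R2)`.
#'
#' @param g n x K genotype matrix.
#' @param x exposure vector.
#' @return A list of class `instrument_strength` with `r_squared`, `f_stat`,
#'   `k` and `n`.
#' @export
instrument_strength <- function(g, x) {
  g <- as.matrix(g)
  n <- nrow(g); K <- ncol(g)
  stopifnot(length(x) == n, n > K + 1)
  fit <- stats::lm.fit(cbind(1, g), x)
  tss <- sum((x - mean(x))^2)
  if (tss == 0) stop("exposure has zero variance")
  r2 <- 1 - sum(fit$residuals^2) / tss
  if (r2 >= 1) stop("exposure is an exact linear function of the instruments (R^2 = 1)")
  structure(list(r_squared = r2,
                 f_stat = (n - K - 1) / K * r2 / (1 - r2),
                 k = K, n = n),
            class = "instrument_strength")
}

#' @export
print.instrument_strength <- function(x, ...) {
  cat(sprintf("first stage: R^2 = %.4f, F = %.2f (K = %d, n = %d)\n",
              x$r_squared, x$f_stat, x$k, x$n))
  invisible(x)
}

#' Per-variant univariate associations from individual-level data
#'
#' Fits, for each variant in turn, the univariate linear regressions of the
#' exposure and of the outcome on that variant's dosage, returning the
#' summarized association estimates and standard errors as a
#' [summary_set()].  For a binary outcome, per-variant logistic regressions
#' are used for the outcome associations (log-odds scale).
#'
#' @param g n x K genotype matrix.
#' @param x exposure vector.
#' @param y outcome vector; treated as binary when `binary_y = TRUE`.
#' @param binary_y fit logistic regressions for the outcome associations.
#' @param ld_from_genotypes also attach the Pearson correlation matrix of
#'   the dosages as the LD matrix.
#' @return A [summary_set()] with `k = ncol(g)` variants.
#' @export
summarize_associations <- function(g, x, y, binary_y = FALSE,
                                   ld_from_genotypes = FALSE) {
  g <- as.matrix(g)
  ax <- univariate_assoc(g, x)
  if (binary_y) {
    K <- ncol(g)
    by <- numeric(K); sy <- numeric(K)
    for (k in seq_len(K)) {
      fit <- stats::glm.fit(cbind(1, g[, k]), y,
                            family = stats::binomial())
      cf <- fit$coefficients[2]
      # dispersion-1 covariance from the weighted cross-product
      W <- fit$weights
      Xd <- cbind(1, g[, k])
      V <- solve(crossprod(Xd * sqrt(W)))
      by[k] <- cf
      sy[k] <- sqrt(V[2, 2])
    }
    ay <- list(beta = by, se = sy)
  } else {
    ay <- univariate_assoc(g, y)
  }
  summary_set(beta_x = ax$beta, se_x = ax$se,
              beta_y = ay$beta, se_y = ay$se,
              ld = if (ld_from_genotypes) stats::cor(g) else NULL,
              n_x = nrow(g), n_y = nrow(g))
}

# Vectorized one-variant-at-a-time linear regressions of v on each column
# of g (slope and standard error).  Equivalent to K calls to lm().
univariate_assoc <- function(g, v) {
  n <- nrow(g)
  gc <- sweep(g, 2, colMeans(g))
  vc <- v - mean(v)
  sxx <- colSums(gc^2)
  if (any(sxx == 0)) stop("monomorphic genotype column(s): ",
                          paste(which(sxx == 0), collapse = ", "))
  sxy <- as.vector(crossprod(gc, vc))
  b <- sxy / sxx
  rss <- sum(vc^2) - b * sxy
  list(beta = b, se = sqrt(pmax(rss, 0) / (n - 2) / sxx))
}

#' Estimate pairwise variant correlations from genotype dosages
#'
#' Pearson correlation of the dosage columns, the correlation implicitly
#' used by individual-level multi-instrument methods.
#'
#' @param g n x K genotype matrix.
#' @return K x K correlation matrix.
#' @export
ld_from_genotypes <- function(g) stats::cor(as.matrix(g))
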