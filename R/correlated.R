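#' Weighting matrix for correlated variants
#'
#' Builds the K x K matrix \eqn{\Omega_{k_1 k_2} = \sigma_{Yk_1}
#' \sigma_{Yk_2} \rho_{k_1 k_2}} used by the generalized least squares
#' estimator.  If the matrix is numerically singular (smallest eigenvalue
#' below `1e-8` times the largest), positive definiteness is restored by
#' adding the smallest ridge from \{1e-8, 1e-6, 1e-4, 1e-2\} to the
#' diagonal of the correlation matrix, with a warning; published off-
#' diagonal correlations are preserved.  Failure at the largest ridge
#' (e.g. duplicated variants with correlation 1) is an error advising
#' pruning.
#'
#' @param s a [summary_set()] carrying an LD matrix.
#' @return A list of class `omega_matrix` with fields `omega`, `condition`
#'   (condition-number estimate), `repaired` and `ridge`.
#' @export
build_omega <- function(s) {
  s <- validate_summary_set(s)
  if (is.null(s$ld)) stop("summary_set carries no LD matrix")
  rho <- s$ld
  off <- abs(rho[upper.tri(rho)])
  if (any(off >= 1 - 1e-12))
    stop("LD matrix contains a correlation of magnitude 1 (duplicated ",
         "variants); prune before estimation (see ld_prune)")
  repaired <- FALSE; ridge <- 0
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev)) {
    for (eps in c(1e-8, 1e-6, 1e-4, 1e-2)) {
      ev2 <- ev + eps
      if (min(ev2) >= 1e-8 * max(ev2)) { ridge <- eps; break }
    }
    if (ridge == 0)
      stop("LD matrix could not be repaired at ridge 1e-2; ",
           "prune near-duplicate variants (see ld_prune)")
    diag(rho) <- diag(rho) + ridge
    repaired <- TRUE
    warning(sprintf("LD matrix numerically singular; ridge %.0e added to diagonal",
                    ridge))
    ev <- ev + ridge
  }
  omega <- tcrossprod(s$se_y) * rho
  structure(list(omega = omega,
                 condition = max(ev) / min(ev),
                 repaired = repaired, ridge = ridge),
            class = "omega_matrix")
}

#' Allele score standard error with correlated variants
#'
#' Standard error of the summarized allele score estimate when the variants
#' are correlated:
#' \deqn{se = \frac{\sqrt{\sum_{k_1}\sum_{k_2} \rho_{k_1k_2} w_{k_1} w_{k_2}
#'   \sigma_{Yk_1}^{-1}\sigma_{Yk_2}^{-1}}}
#'   {\big|\sum_k w_k \hat\beta_{Xk}\sigma_{Yk}^{-2}\big|}.}
#' Only the first (leading) term of the delta-method expansion is used.
#' With an identity LD matrix this reduces exactly to the first term of the
#' uncorrelated expression in [allele_score_se()].
#'
#' @param s a [summary_set()] carrying an LD matrix.
#' @param weights per-variant weights (default: the set's weights, else
#'   equal weights).
#' @return The standard error (scalar).
#' @export
allele_score_se_correlated <- function(s, weights = NULL) {
  s <- validate_summary_set(s)
  if (is.null(s$ld)) stop("summary_set carries no LD matrix")
  w <- resolve_weights(s, weights)
  a <- w / s$se_y
  den <- sum(w * s$beta_x * s$se_y^-2)
  if (den == 0) stop("denominator sum is zero: causal effect unidentified")
  num2 <- as.numeric(t(a) %*% s$ld %*% a)
  if (num2 <= 0) stop("quadratic form in LD matrix is non-positive")
  sqrt(num2) / abs(den)
}

#' IVW expression as a test of the causal null with correlated variants
#'
#' With correlated variants the IVW expression no longer estimates the
#' causal effect, but it can still be used to test the null hypothesis of
#' no effect when paired with the correlation-aware standard error
#' \deqn{se = \frac{\sqrt{\sum_{k_1}\sum_{k_2}\rho_{k_1k_2}
#'   \hat\beta_{Xk_1}\hat\beta_{Xk_2}\sigma_{Yk_1}^{-1}\sigma_{Yk_2}^{-1}}}
#'   {\sum_k \hat\beta_{Xk}^2 \sigma_{Yk}^{-2}}.}
#' With weights equal to the exposure associations the resulting z
#' statistic is identical to the allele-score z statistic using
#' [allele_score_se_correlated()], so the two methods reject together.
#'
#' @param s a [summary_set()] carrying an LD matrix.
#' @param level confidence level for the (test-only) interval.
#' @return A list of class `ivw_test` with the [causal_estimate()]
#'   (flagged as a test statistic, not an effect estimate), `z` and
#'   `p_value`.
#' @export
ivw_test_correlated <- function(s, level = 0.95) {
  s <- validate_summary_set(s)
  if (is.null(s$ld)) stop("summary_set carries no LD matrix")
  wy2 <- s$se_y^-2
  den <- sum(s$beta_x^2 * wy2)
  if (den == 0) stop("all beta_x are zero: causal effect unidentified")
  est <- sum(s$beta_x * s$beta_y * wy2) / den
  a <- s$beta_x / s$se_y
  se <- sqrt(as.numeric(t(a) %*% s$ld %*% a)) / den
  z <- est / se
  ce <- causal_estimate(est, se, "ivw_test_correlated", k_used = s$k,
                        level = level,
                        notes = "test statistic only, not an effect estimate")
  structure(list(estimate = ce, z = z,
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "ivw_test")
}

#' @export
print.ivw_test <- function(x, ...) {
  cat(sprintf("IVW causal-null test with correlated variants: z = %.3f, p = %.3g\n",
              x$z, x$p_value))
  cat("(the underlying expression is not an estimate of the causal effect)\n")
  invisible(x)
}

#' Weighted generalized least squares causal estimate
#'
#' Causal estimate for correlated variants from the generalized weighted
#' regression of the outcome associations on the exposure associations
#' with weighting matrix \eqn{\Omega} from [build_omega()]:
#' \deqn{\hat\beta = (\hat\beta_X^T \Omega^{-1} \hat\beta_X)^{-1}
#'   \hat\beta_X^T \Omega^{-1} \hat\beta_Y, \qquad
#'   se = (\hat\beta_X^T \Omega^{-1} \hat\beta_X)^{-1/2}.}
#' Solved via a Cholesky factorization of \eqn{\Omega}; the matrix is never
#' inverted explicitly.  With an identity LD matrix this reduces exactly to
#' [ivw_estimate()].
#'
#' @param s a [summary_set()] carrying an LD matrix.
#' @param level confidence level.
#' @return A [causal_estimate()] with method `"gls"`.
#' @export
gls_estimate <- function(s, level = 0.95) {
  s <- validate_summary_set(s)
  om <- build_omega(s)
  R <- chol(om$omega)
  bx_t <- backsolve(R, s$beta_x, transpose = TRUE)
  by_t <- backsolve(R, s$beta_y, transpose = TRUE)
  den <- sum(bx_t^2)   # beta_x' Omega^-1 beta_x, > 0 for PD Omega
  stopifnot(den > 0)
  causal_estimate(sum(bx_t * by_t) / den, 1 / sqrt(den), "gls",
                  k_used = s$k, level = level,
                  notes = if (om$repaired)
                    sprintf("LD matrix repaired with ridge %.0e", om$ridge))
}

#' Prune variants in high linkage disequilibrium
#'
#' Greedy pruning in variant order: a variant is dropped when its squared
#' correlation with any earlier retained variant exceeds the threshold.
#'
#' @param s a [summary_set()] carrying an LD matrix.
#' @param r2_threshold squared-correlation threshold above which the later
#'   variant is dropped (default 0.8).
#' @return The pruned [summary_set()], with attribute `"dropped"` naming
#'   removed variants.
#' @export
ld_prune <- function(s, r2_threshold = 0.8) {
  s <- validate_summary_set(s)
  if (is.null(s$ld)) stop("summary_set carries no LD matrix")
  keep <- logical(s$k)
  for (k in seq_len(s$k)) {
    keep[k] <- !any(keep & s$ld[k, ]^2 > r2_threshold & seq_len(s$k) != k)
  }
  dropped <- s$variant[!keep]
  out <- subset_variants(s, keep)
  attr(out, "dropped") <- dropped
  out
}
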