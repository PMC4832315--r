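#' Summarized-data allele score estimate
#'
#' Point estimate of the causal effect from the allele score method using
#' only summarized data:
#' \deqn{\hat\beta = \frac{\sum_k w_k \hat\beta_{Yk} \sigma_{Yk}^{-2}}
#'                        {\sum_k w_k \hat\beta_{Xk} \sigma_{Yk}^{-2}}}
#' where the weights \eqn{w_k} are pre-specified (equal, external, or
#' crude).  The derivation relies on the approximation that the variance of
#' each variant's dosage is proportional to \eqn{\sigma_{Yk}^{-2}}, which
#' holds when each variant explains a small proportion of outcome variance.
#' The formula itself does not use the correlation between variants, so the
#' point estimate is valid for correlated variants too; only its standard
#' error changes (see [allele_score_se_correlated()]).
#'
#' @param s a [summary_set()].
#' @param weights per-variant weights; defaults to `s$weights`, or equal
#'   weights if the set carries none.
#' @return The point estimate (scalar).  See [mr_allele_score()] for the
#'   full estimate with standard error and confidence interval.
#' @export
allele_score_estimate <- function(s, weights = NULL) {
  s <- validate_summary_set(s)
  w <- resolve_weights(s, weights)
  wy2 <- s$se_y^-2
  den <- sum(w * s$beta_x * wy2)
  if (den == 0)
    stop("sum of w * beta_x * se_y^-2 is zero: causal effect unidentified")
  sum(w * s$beta_y * wy2) / den
}

resolve_weights <- function(s, weights) {
  w <- if (is.null(weights)) s$weights else weights
  if (is.null(w)) w <- rep(1, s$k)
  if (length(w) != s$k) stop("weights must have one entry per variant")
  w
}

#' Delta-method standard error of the summarized allele score estimate
#'
#' Standard error of [allele_score_estimate()] for uncorrelated variants,
#' from the delta-method expansion of the ratio of the two weighted sums.
#' Writing \eqn{A = \sum w_k \hat\beta_{Yk}\sigma_{Yk}^{-2}},
#' \eqn{B = \sum w_k \hat\beta_{Xk}\sigma_{Yk}^{-2}} and
#' \eqn{C = \sum w_k^2 \sigma_{Yk}^{-2}}, the variance is
#' \deqn{C/B^2 + A^2 C / B^4 - 2\,\theta_S\, A C / B^3,}
#' where \eqn{\theta_S} is the correlation between the numerator and
#' denominator sums, arising when both are estimated in the same
#' individuals.  In a two-sample analysis \eqn{\theta_S = 0}; in a
#' one-sample analysis it can be estimated by bootstrapping or specified
#' as the observed exposure--outcome correlation, and a sensitivity sweep
#' is available via [theta_s_sweep()].  With `terms = "first"` only the
#' leading term
#' \eqn{\sqrt{C}/|B|} is returned; with weights equal to the exposure
#' associations that leading term coincides with the IVW standard error of
#' [ivw_estimate()].
#'
#' @param s a [summary_set()].
#' @param weights per-variant weights (default as in
#'   [allele_score_estimate()]).
#' @param theta_s correlation between the numerator and denominator sums,
#'   in \[-1, 1\]; default 0 (two-sample setting).
#' @param terms `"all"` (default) for the full three-term expression, or
#'   `"first"` for the leading term only.
#' @return The standard error (scalar).
#' @export
allele_score_se <- function(s, weights = NULL, theta_s = 0,
                            terms = c("all", "first")) {
  terms <- match.arg(terms)
  s <- validate_summary_set(s)
  stopifnot(abs(theta_s) <= 1)
  w <- resolve_weights(s, weights)
  wy2 <- s$se_y^-2
  A <- sum(w * s$beta_y * wy2)
  B <- sum(w * s$beta_x * wy2)
  C <- sum(w^2 * wy2)
  if (B == 0) stop("denominator sum is zero: causal effect unidentified")
  if (terms == "first") return(sqrt(C) / abs(B))
  v <- C / B^2 + A^2 * C / B^4 - 2 * theta_s * A * C / B^3
  if (v <= 0)
    stop(sprintf("delta-method variance is non-positive (%.3g) at theta_s = %.3g",
                 v, theta_s))
  sqrt(v)
}

#' Summarized-data allele score method
#'
#' Combines [allele_score_estimate()] with the appropriate standard error:
#' the delta-method expression for uncorrelated variants, or the
#' correlation-aware expression ([allele_score_se_correlated()]) when the
#' set carries an LD matrix.
#'
#' @inheritParams allele_score_se
#' @param level confidence level (default 0.95).
#' @return A [causal_estimate()] with method `"allele_score"`.
#' @export
mr_allele_score <- function(s, weights = NULL, theta_s = 0, level = 0.95) {
  s <- validate_summary_set(s)
  est <- allele_score_estimate(s, weights)
  se <- if (is.null(s$ld)) allele_score_se(s, weights, theta_s = theta_s)
        else allele_score_se_correlated(s, weights)
  causal_estimate(est, se, "allele_score", k_used = s$k, level = level,
                  notes = if (!is.null(s$ld)) "SE accounts for LD (first delta term only)")
}

#' Inverse-variance weighted (summary statistic) estimate
#'
#' Fixed-effect inverse-variance weighted meta-analysis of the per-variant
#' ratio estimates \eqn{\hat\beta_{Yk}/\hat\beta_{Xk}} using first-order
#' ratio standard errors \eqn{\sigma_{Yk}/\hat\beta_{Xk}}:
#' \deqn{\hat\beta_{IVW} =
#'   \frac{\sum_k \hat\beta_{Xk}\hat\beta_{Yk}\sigma_{Yk}^{-2}}
#'        {\sum_k \hat\beta_{Xk}^2 \sigma_{Yk}^{-2}}, \qquad
#'   se = \Big(\sum_k \hat\beta_{Xk}^2\sigma_{Yk}^{-2}\Big)^{-1/2}.}
#' Assumes the variants are uncorrelated (in linkage equilibrium).  The
#' estimate equals the summarized allele score estimate with weights
#' \eqn{w_k = \hat\beta_{Xk}}.
#'
#' @param s a [summary_set()].
#' @param level confidence level (default 0.95).
#' @return A [causal_estimate()] with method `"ivw"`.
#' @export
ivw_estimate <- function(s, level = 0.95) {
  s <- validate_summary_set(s)
  wy2 <- s$se_y^-2
  den <- sum(s$beta_x^2 * wy2)
  if (den == 0) stop("all beta_x are zero: causal effect unidentified")
  causal_estimate(sum(s$beta_x * s$beta_y * wy2) / den,
                  1 / sqrt(den), "ivw", k_used = s$k, level = level)
}

#' IVW estimate via weighted regression through the origin
#'
#' The IVW estimate can equivalently be obtained as the slope of the
#' weighted linear regression of the outcome associations on the exposure
#' associations without an intercept, with weights \eqn{\sigma_{Yk}^{-2}}.
#' The standard error reported by standard regression software is
#' incorrect for this purpose and is repaired by forcing the residual
#' standard error to one (dividing the reported slope standard error by the
#' residual standard error).  The result matches [ivw_estimate()] to
#' machine precision; both forms are kept because the regression
#' formulation generalizes to the pleiotropy (intercept) test.
#'
#' @inheritParams ivw_estimate
#' @return A [causal_estimate()] with method `"ivw_regression"`.
#' @export
ivw_via_regression <- function(s, level = 0.95) {
  s <- validate_summary_set(s)
  if (sum(s$beta_x^2) == 0) stop("all beta_x are zero: causal effect unidentified")
  fit <- stats::lm(s$beta_y ~ s$beta_x - 1, weights = s$se_y^-2)
  sm <- summary(fit)
  se <- sm$coefficients[1, 2] / sm$sigma
  causal_estimate(unname(stats::coef(fit)[1]), se, "ivw_regression",
                  k_used = s$k, level = level)
}

#' Sensitivity sweep over the numerator-denominator correlation
#'
#' Recomputes the allele-score standard error (and confidence interval)
#' across a grid of \eqn{\theta_S} values, for one-sample analyses where
#' the correlation between the numerator and denominator of the
#' summarized allele score estimate is unknown.
#'
#' @param s a [summary_set()].
#' @param weights per-variant weights.
#' @param theta_grid numeric grid of \eqn{\theta_S} values.
#' @param level confidence level.
#' @return A data frame with columns `theta_s`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`.
#' @export
theta_s_sweep <- function(s, weights = NULL,
                          theta_grid = seq(-0.5, 0.5, by = 0.1),
                          level = 0.95) {
  est <- allele_score_estimate(s, weights)
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- vapply(theta_grid, function(th)
    allele_score_se(s, weights, theta_s = th), numeric(1))
  data.frame(theta_s = theta_grid, estimate = est, se = se,
             ci_lower = est - z * se, ci_upper = est + z * se)
}
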