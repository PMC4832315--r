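#' Per-variant ratio estimates
#'
#' The ratio estimate of the causal effect from variant k alone is
#' \eqn{\hat\beta_{Yk}/\hat\beta_{Xk}}, with first-order standard error
#' \eqn{\sigma_{Yk}/|\hat\beta_{Xk}|}.  Variants with a zero exposure
#' association have no defined ratio and are excluded with a warning.  The
#' second-order standard error
#' \eqn{\sqrt{\sigma_{Yk}^2/\hat\beta_{Xk}^2 +
#'   \hat\beta_{Yk}^2\sigma_{Xk}^2/\hat\beta_{Xk}^4}}
#' is available as an option but is off by default, matching the
#' first-order weighting used by the IVW estimator.
#'
#' @param s a [summary_set()].
#' @param second_order include the exposure-uncertainty term in the
#'   standard errors (requires `se_x`).
#' @return A data frame with columns `variant`, `estimate`, `se`.
#' @export
per_variant_ratios <- function(s, second_order = FALSE) {
  s <- validate_summary_set(s)
  keep <- s$beta_x != 0
  if (!any(keep)) stop("all variants have beta_x = 0; no ratio estimates defined")
  if (!all(keep))
    warning("excluding variant(s) with beta_x = 0: ",
            paste(s$variant[!keep], collapse = ", "))
  bx <- s$beta_x[keep]; by <- s$beta_y[keep]; sy <- s$se_y[keep]
  se <- sy / abs(bx)
  if (second_order) {
    if (is.null(s$se_x)) stop("second-order ratio SE requires se_x")
    sx <- s$se_x[keep]
    se <- sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  }
  data.frame(variant = s$variant[keep], estimate = by / bx, se = se,
             stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity test over ratio estimates
#'
#' Overidentification test from summarized data: under the hypothesis that
#' all variants identify the same causal effect, the weighted sum of
#' squared deviations of the per-variant ratio estimates from the IVW
#' pooled estimate, \eqn{Q = \sum_k se_k^{-2} (\hat\theta_k -
#' \hat\theta_{IVW})^2}, follows a chi-square distribution with K - 1
#' degrees of freedom.  Excess heterogeneity suggests that some variants
#' are invalid instruments (e.g. have pleiotropic effects).
#'
#' @param ratios a data frame from [per_variant_ratios()], or a
#'   [summary_set()] (ratios are computed first).
#' @return A list of class `cochran_q` with `q`, `df`, `p_value` and the
#'   pooled estimate.
#' @export
cochran_q <- function(ratios) {
  if (inherits(ratios, "summary_set")) ratios <- per_variant_ratios(ratios)
  k <- nrow(ratios)
  if (k < 2) stop("Cochran's Q requires at least 2 variants")
  w <- ratios$se^-2
  pooled <- sum(w * ratios$estimate) / sum(w)
  q <- sum(w * (ratios$estimate - pooled)^2)
  structure(list(q = q, df = k - 1L,
                 p_value = stats::pchisq(q, k - 1L, lower.tail = FALSE),
                 pooled = pooled),
            class = "cochran_q")
}

#' @export
print.cochran_q <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g (pooled estimate %.4f)\n",
              x$q, x$df, x$p_value, x$pooled))
  invisible(x)
}

#' Directional pleiotropy (intercept) test
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with an intercept term, weights \eqn{\sigma_{Yk}^{-2}},
#' and standard errors repaired by forcing the residual standard error to
#' one (as in [ivw_via_regression()]).  The intercept represents the
#' average association of a variant with the outcome in the absence of any
#' association with the exposure; under the instrumental-variable
#' assumptions it is zero, and a non-zero intercept indicates directional
#' pleiotropy.  The slope is returned as a secondary causal estimate that
#' is robust to directional pleiotropy.  Variants must be oriented to
#' their risk-increasing alleles first ([orient_to_risk_increasing()]):
#' the intercept, unlike the slope-only estimators, is not invariant to
#' allele recoding.  P-values use a t distribution with K - 2 degrees of
#' freedom, appropriate for the small numbers of variants typical in
#' practice.
#'
#' @param s a [summary_set()] with at least 3 variants, oriented to
#'   risk-increasing alleles.
#' @return A list of class `pleiotropy_test` with `intercept`,
#'   `intercept_se`, `p_value`, and `slope` (a [causal_estimate()]).
#' @export
intercept_pleiotropy_test <- function(s) {
  s <- validate_summary_set(s)
  if (s$k < 3) stop("intercept test requires at least 3 variants")
  fit <- stats::lm(s$beta_y ~ s$beta_x, weights = s$se_y^-2)
  sm <- summary(fit)
  est <- sm$coefficients[, 1]
  se <- sm$coefficients[, 2] / sm$sigma  # force residual SE to one
  tval <- est[1] / se[1]
  structure(
    list(intercept = unname(est[1]), intercept_se = unname(se[1]),
         p_value = 2 * stats::pt(-abs(tval), df = s$k - 2),
         slope = causal_estimate(unname(est[2]), unname(se[2]),
                                 "pleiotropy_adjusted_slope", k_used = s$k)),
    class = "pleiotropy_test")
}

#' @export
print.pleiotropy_test <- function(x, ...) {
  cat(sprintf("pleiotropy intercept %.4f (se %.4f), p = %.3g\n",
              x$intercept, x$intercept_se, x$p_value))
  print(x$slope)
  invisible(x)
}

#' Instrument strength from summarized data
#'
#' When exposure associations are reported in standard-deviation units,
#' the variance in the exposure explained by the variants is approximately
#' \eqn{R^2 = \sum_k 2\hat\beta_{Xk}^2\,MAF_k(1 - MAF_k)} and the F
#' statistic follows as \eqn{F = ((N - K - 1)/K)\, R^2/(1 - R^2)}.
#'
#' @param beta_x_sd_units per-variant exposure associations in SD units.
#' @param maf minor-allele frequencies in (0, 0.5].
#' @param n sample size behind the exposure associations.
#' @param k number of variants (defaults to `length(beta_x_sd_units)`).
#' @return A list of class `instrument_strength` (as from
#'   [instrument_strength()]).
#' @export
summarized_strength <- function(beta_x_sd_units, maf, n,
                                k = length(beta_x_sd_units)) {
  stopifnot(length(maf) == length(beta_x_sd_units),
            all(maf > 0), all(maf <= 0.5), n > k + 1)
  r2 <- sum(2 * beta_x_sd_units^2 * maf * (1 - maf))
  if (r2 >= 1) stop("summarized R^2 is >= 1; check that beta_x is in SD units")
  structure(list(r_squared = r2,
                 f_stat = (n - k - 1) / k * r2 / (1 - r2),
                 k = as.integer(k), n = as.integer(n)),
            class = "instrument_strength")
}
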