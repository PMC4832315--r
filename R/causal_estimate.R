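#' Construct a causal estimate
#'
#' Container for a causal effect estimate: the point estimate (in outcome
#' units, or log odds, per unit of exposure), its standard error, a
#' normal-approximation confidence interval at the stated level, the method
#' label, and the number of variants used.
#'
#' @param estimate point estimate of the causal effect.
#' @param se standard error (strictly positive).
#' @param method character label for the method.
#' @param k_used number of variants contributing to the estimate.
#' @param level confidence level, default 0.95 (normal quantiles).
#' @param notes optional character vector of flags, e.g. marking a quantity
#'   that is a test statistic rather than an effect estimate.
#' @return An object of class `causal_estimate`.
#' @export
causal_estimate <- function(estimate, se, method, k_used,
                            level = 0.95, notes = NULL) {
  stopifnot(is.finite(estimate), is.finite(se), se > 0,
            level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(estimate = estimate, se = se,
         ci_lower = estimate - z * se, ci_upper = estimate + z * se,
         level = level, method = method, k_used = k_used,
         notes = notes),
    class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s (K = %d variants)\n", x$method, x$k_used))
  cat(sprintf("  estimate %s  se %s  %g%% CI [%s, %s]\n",
              format(x$estimate, digits = digits),
              format(x$se, digits = digits),
              100 * x$level,
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Report a causal estimate on the exponentiated (odds ratio) scale
#'
#' When the outcome associations are log odds ratios from logistic
#' regression, the causal estimate is a log odds ratio per unit exposure and
#' is conventionally reported as an odds ratio.  Exponentiation is applied
#' to the point estimate and the confidence limits only; it is a
#' presentation transform, never used in intermediate computation.
#'
#' @param x a [causal_estimate()].
#' @return A list with `or`, `ci_lower`, `ci_upper`, `level` and `method`.
#' @export
exponentiate <- function(x) {
  stopifnot(inherits(x, "causal_estimate"))
  list(or = exp(x$estimate),
       ci_lower = exp(x$ci_lower), ci_upper = exp(x$ci_upper),
       level = x$level, method = x$method)
}

#' @export
as.data.frame.causal_estimate <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_lower = x$ci_lower, ci_upper = x$ci_upper,
             level = x$level, k_used = x$k_used,
             notes = if (is.null(x$notes)) "" else paste(x$notes, collapse = "; "),
             stringsAsFactors = FALSE)
}
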