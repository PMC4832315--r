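#' Per-variant summarized association data
#'
#' A `summary_set` holds, for each of K genetic variants, the estimated
#' association with the exposure (risk factor) and with the outcome, together
#' with their standard errors, and optionally effect-allele frequencies,
#' pre-specified allele-score weights, sample sizes, and a K x K matrix of
#' signed correlations (linkage disequilibrium) between the variants.
#'
#' Exposure associations `beta_x` are in exposure units per additional
#' effect allele; outcome associations `beta_y` are in outcome units (or
#' log odds, for a binary outcome) per additional effect allele.  Standard
#' errors are treated as known throughout, the usual assumption when working
#' with published summary statistics.
#'
#' @param beta_x numeric vector of per-variant exposure association estimates.
#' @param se_x their standard errors (strictly positive).  May be `NULL` when
#'   only methods that do not use exposure standard errors (allele score,
#'   IVW, GLS) will be applied.
#' @param beta_y numeric vector of per-variant outcome association estimates.
#' @param se_y their standard errors (strictly positive).
#' @param variant optional character vector of variant identifiers; defaults
#'   to `"v1" ... "vK"`.
#' @param eaf optional effect-allele frequencies in (0, 1).
#' @param weights optional pre-specified per-variant allele-score weights.
#' @param ld optional K x K signed correlation matrix between variants;
#'   symmetric with unit diagonal and entries in \[-1, 1\].  Row/column order
#'   must match the variant order.
#' @param n_x,n_y optional sample sizes behind the exposure and outcome
#'   associations.
#'
#' @return An object of class `summary_set`: a validated list with the above
#'   fields and `k`, the number of variants.
#' @seealso [validate_summary_set()], [orient_to_risk_increasing()],
#'   [read_summary_table()]
#' @export
#' @examples
#' s <- summary_set(beta_x = c(0.5, 0.25), se_x = c(0.05, 0.05),
#'                  beta_y = c(0.1, 0.05), se_y = c(0.1, 0.2))
#' ivw_estimate(s)
summary_set <- function(beta_x, se_x = NULL, beta_y, se_y,
                        variant = NULL, eaf = NULL, weights = NULL,
                        ld = NULL, n_x = NULL, n_y = NULL) {
  k <- length(beta_x)
  if (is.null(variant)) variant <- paste0("v", seq_len(k))
  s <- structure(
    list(variant = as.character(variant),
         beta_x = as.numeric(beta_x),
         se_x = if (is.null(se_x)) NULL else as.numeric(se_x),
         beta_y = as.numeric(beta_y),
         se_y = as.numeric(se_y),
         eaf = if (is.null(eaf)) NULL else as.numeric(eaf),
         weights = if (is.null(weights)) NULL else as.numeric(weights),
         ld = ld,
         n_x = n_x, n_y = n_y,
         k = k),
    class = "summary_set")
  validate_summary_set(s)
}

#' Validate a summary_set
#'
#' Checks the structural invariants of a [summary_set()]: all per-variant
#' vectors have a common length K >= 1, standard errors are strictly
#' positive, allele frequencies (if given) lie in (0, 1), and the LD matrix
#' (if given) is K x K, symmetric to within `1e-8` after symmetrization,
#' with unit diagonal and entries in \[-1, 1\].  Small published-rounding
#' asymmetries in the LD matrix are repaired by replacing it with
#' `(A + t(A)) / 2`.  The function is idempotent: a valid set is returned
#' unchanged.
#'
#' @param s a `summary_set` (or a bare list with the same fields).
#' @return The validated `summary_set`.
#' @export
validate_summary_set <- function(s) {
  k <- length(s$beta_x)
  if (k < 1L) stop("summary_set must contain at least one variant")
  vec_fields <- c("variant", "beta_y", "se_y",
                  if (!is.null(s$se_x)) "se_x",
                  if (!is.null(s$eaf)) "eaf",
                  if (!is.null(s$weights)) "weights")
  for (f in vec_fields) {
    if (length(s[[f]]) != k)
      stop(sprintf("length of '%s' (%d) does not match number of variants (%d)",
                   f, length(s[[f]]), k))
  }
  num_fields <- c("beta_x", "beta_y", "se_y",
                  if (!is.null(s$se_x)) "se_x",
                  if (!is.null(s$weights)) "weights")
  for (f in num_fields) {
    if (anyNA(s[[f]]) || any(!is.finite(s[[f]])))
      stop(sprintf("'%s' contains missing or non-finite values", f))
  }
  if (any(s$se_y <= 0)) stop("se_y must be strictly positive")
  if (!is.null(s$se_x) && any(s$se_x <= 0)) stop("se_x must be strictly positive")
  if (!is.null(s$eaf) && any(s$eaf <= 0 | s$eaf >= 1))
    stop("eaf must lie strictly between 0 and 1")
  if (!is.null(s$ld)) {
    ld <- as.matrix(s$ld)
    if (nrow(ld) != k || ncol(ld) != k)
      stop(sprintf("ld matrix is %dx%d but there are %d variants",
                   nrow(ld), ncol(ld), k))
    if (max(abs(ld - t(ld))) > 1e-8)
      stop("ld matrix is not symmetric (tolerance 1e-8)")
    ld <- (ld + t(ld)) / 2
    if (max(abs(diag(ld) - 1)) > 1e-8)
      stop("ld matrix must have unit diagonal")
    diag(ld) <- 1
    if (any(abs(ld) > 1 + 1e-8)) stop("ld entries must lie in [-1, 1]")
    ld[ld > 1] <- 1
    ld[ld < -1] <- -1
    dimnames(ld) <- list(s$variant, s$variant)
    s$ld <- ld
  }
  s$k <- k
  class(s) <- "summary_set"
  s
}

#' Orient all variants to the risk-increasing allele
#'
#' Allele codings in published summary statistics are arbitrary: the same
#' variant may be reported with respect to either allele.  Methods that use
#' pre-specified weights (notably equal weights) require every variant to be
#' coded so that its association with the exposure is non-negative.  This
#' function flips the coding of each variant with `beta_x < 0`: `beta_x` and
#' `beta_y` (and any `weights`) are negated, `eaf` becomes `1 - eaf`, and
#' rows/columns of the LD matrix are rescaled by the flip signs
#' (`rho'[j,k] = s_j * s_k * rho[j,k]`), so that every causal estimator in
#' the package is invariant to the original coding.
#'
#' Variants with `beta_x` exactly zero have no defined direction; they are
#' retained unflipped and flagged with a warning (they receive zero weight
#' in inverse-variance formulas, so dropping them silently would change the
#' number of variants K without changing estimates).
#'
#' @param s a [summary_set()].
#' @return The oriented `summary_set`, with an attribute `"flipped"` giving
#'   the logical flip indicator per variant.
#' @export
orient_to_risk_increasing <- function(s) {
  s <- validate_summary_set(s)
  if (any(s$beta_x == 0))
    warning("beta_x is exactly 0 for variant(s) ",
            paste(s$variant[s$beta_x == 0], collapse = ", "),
            ": orientation undefined, left unchanged")
  sgn <- ifelse(s$beta_x < 0, -1, 1)
  s$beta_x <- sgn * s$beta_x
  s$beta_y <- sgn * s$beta_y
  if (!is.null(s$weights)) s$weights <- sgn * s$weights
  if (!is.null(s$eaf)) s$eaf <- ifelse(sgn < 0, 1 - s$eaf, s$eaf)
  if (!is.null(s$ld)) s$ld <- s$ld * tcrossprod(sgn)
  attr(s, "flipped") <- sgn < 0
  validate_summary_set(s)
}

#' @export
print.summary_set <- function(x, ...) {
  cat(sprintf("summary_set: %d variant(s)%s%s\n", x$k,
              if (!is.null(x$ld)) ", with LD matrix" else "",
              if (!is.null(x$weights)) ", with weights" else ""))
  df <- data.frame(variant = x$variant, beta_x = x$beta_x,
                   beta_y = x$beta_y, se_y = x$se_y)
  if (!is.null(x$se_x)) df$se_x <- x$se_x
  if (!is.null(x$eaf)) df$eaf <- x$eaf
  print(utils::head(df, 10), row.names = FALSE)
  if (x$k > 10) cat(sprintf("... and %d more\n", x$k - 10))
  invisible(x)
}

#' Subset a summary_set by variant
#'
#' @param s a [summary_set()].
#' @param i integer or logical index of variants to keep.
#' @return The subsetted `summary_set`.
#' @export
subset_variants <- function(s, i) {
  idx <- seq_len(s$k)[i]
  for (f in c("variant", "beta_x", "se_x", "beta_y", "se_y", "eaf", "weights"))
    if (!is.null(s[[f]])) s[[f]] <- s[[f]][idx]
  if (!is.null(s$ld)) s$ld <- s$ld[idx, idx, drop = FALSE]
  validate_summary_set(s)
}
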