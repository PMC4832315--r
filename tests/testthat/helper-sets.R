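# Shared fixtures, built in code.

# Worked two-variant example: both ratio estimates equal 0.2.
worked_set <- function(ld = NULL, se_x = c(0.05, 0.05)) {
  summary_set(beta_x = c(0.5, 0.25), se_x = se_x,
              beta_y = c(0.1, 0.05), se_y = c(0.1, 0.2), ld = ld)
}

# Random valid summary set, optionally with a random PD correlation matrix.
random_set <- function(k = 5, seed = 1, with_ld = FALSE, with_weights = FALSE) {
  set.seed(seed)
  bx <- rnorm(k, 0.1, 0.04)
  sx <- runif(k, 0.01, 0.03)
  by <- 0.3 * bx + rnorm(k, 0, 0.02)
  sy <- runif(k, 0.03, 0.08)
  ld <- NULL
  if (with_ld) {
    a <- matrix(rnorm((k + 4) * k), k + 4, k)
    ld <- stats::cov2cor(crossprod(a) + 0.5 * k * diag(k))
  }
  summary_set(beta_x = bx, se_x = sx, beta_y = by, se_y = sy, ld = ld,
              weights = if (with_weights) runif(k, 0.5, 1.5))
}

# Arbitrarily recode allele directions of a summary set (flip random signs).
recode_alleles <- function(s, flip) {
  sgn <- ifelse(flip, -1, 1)
  s$beta_x <- sgn * s$beta_x
  s$beta_y <- sgn * s$beta_y
  if (!is.null(s$weights)) s$weights <- sgn * s$weights
  if (!is.null(s$eaf)) s$eaf <- ifelse(flip, 1 - s$eaf, s$eaf)
  if (!is.null(s$ld)) s$ld <- s$ld * tcrossprod(sgn)
  validate_summary_set(s)
}

fixture_path <- function(f) system.file("extdata", f, package = "mrcombine")
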