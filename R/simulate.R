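#' Simulation configuration
#'
#' Parameters of the two data-generating processes used throughout the
#' package's simulation studies.  In both, subject i has risk factor
#' `x_i = sum_k alpha_k g_ik + u_i + eps_Xi` and outcome
#' `y_i = beta_x x_i + beta_u u_i + eps_Yi` with standard normal
#' confounder and noise terms; per-variant effects are redrawn each
#' replicate as `alpha_k ~ U(0.5 alpha, 1.5 alpha)`.  Uncorrelated
#' variants are binomial, `g_ik ~ Binomial(2, pi_k)` with
#' `pi_k ~ U(0.01, 0.5)`.  Correlated variants arise from a latent
#' Gaussian haplotype model: a Wishart draw `Lambda ~ Wishart(K, Lambda0)`
#' (with `Lambda0` unit-diagonal and constant off-diagonal `ld_offdiag`)
#' is reduced to a correlation matrix `Phi = cor(Lambda)`; two haplotype
#' vectors per subject are drawn from `N_K(0, Phi)` and a risk allele is
#' recorded whenever a haplotype component exceeds the variant's threshold
#' `pi'_k ~ U(0, 2)` (so threshold 0 gives allele frequency 0.5 and
#' threshold 1.96 gives 0.025).
#'
#' @param n sample size per dataset (default 5000).
#' @param k number of instruments (default 15).
#' @param alpha mean per-variant effect on the risk factor (default 0.05).
#' @param beta_x causal effect of the risk factor on the outcome
#'   (default 0.2; 0 for null scenarios).
#' @param beta_u confounder effect on the outcome (+1 or -1).
#' @param ld `"none"` for independent binomial variants or `"wishart"`
#'   for the correlated haplotype model.
#' @param ld_offdiag off-diagonal element of the Wishart scale matrix
#'   (default 0.5).
#' @param outcome `"continuous"` or `"binary"`.
#' @param prevalence target outcome prevalence for binary outcomes
#'   (default 0.3).
#' @param n_external sample size behind external weights (default 5000;
#'   `Inf` for oracle weights).
#' @param reps number of simulation replicates.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 5000, k = 15, alpha = 0.05, beta_x = 0.2,
                       beta_u = 1, ld = c("none", "wishart"),
                       ld_offdiag = 0.5,
                       outcome = c("continuous", "binary"),
                       prevalence = 0.3, n_external = 5000, reps = 1000) {
  ld <- match.arg(ld)
  outcome <- match.arg(outcome)
  stopifnot(n > 0, k > 0, alpha >= 0, reps >= 1,
            abs(ld_offdiag) < 1, prevalence > 0, prevalence < 1)
  structure(list(n = n, k = as.integer(k), alpha = alpha, beta_x = beta_x,
                 beta_u = beta_u, ld = ld, ld_offdiag = ld_offdiag,
                 outcome = outcome, prevalence = prevalence,
                 n_external = n_external, reps = as.integer(reps)),
            class = "sim_config")
}

#' Generate a dataset with uncorrelated (binomial) variants
#'
#' @param cfg a [sim_config()] with `ld = "none"`.
#' @param seed optional integer seed; when supplied the dataset is
#'   bit-reproducible.
#' @return A list of class `individual_dataset` with fields `g` (n x K
#'   dosage matrix), `x`, `y`, and `truth` (the realized `alpha_k` and
#'   `pi_k`).
#' @export
gen_uncorrelated <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n; K <- cfg$k
  pi_k <- stats::runif(K, 0.01, 0.5)
  alpha_k <- stats::runif(K, 0.5 * cfg$alpha, 1.5 * cfg$alpha)
  g <- matrix(stats::rbinom(n * K, 2, rep(pi_k, each = n)), n, K)
  finish_dataset(cfg, g, truth = list(alpha_k = alpha_k, pi_k = pi_k))
}

#' Generate a dataset with correlated variants (latent haplotype model)
#'
#' See [sim_config()] for the model.  The Wishart-derived correlation
#' matrix `Phi = cor(Lambda)` is rank-deficient by construction, so the
#' latent haplotype normals are drawn through an eigenvalue factorization;
#' a numerically invalid draw (non-finite correlation entries) is redrawn,
#' up to 10 attempts.
#'
#' @param cfg a [sim_config()] with `ld = "wishart"`.
#' @param seed optional integer seed.
#' @param truth optionally reuse the variant-level parameters (`alpha_k`,
#'   `pi_prime`, `Phi`) from an earlier dataset, drawing only new
#'   individuals; used to generate the independent external-weight sample.
#' @return A list of class `individual_dataset`; `truth` carries
#'   `alpha_k`, `pi_prime` and `Phi`.
#' @export
gen_correlated <- function(cfg, seed = NULL, truth = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n; K <- cfg$k
  if (is.null(truth)) {
    L0 <- matrix(cfg$ld_offdiag, K, K); diag(L0) <- 1
    Phi <- NULL
    for (attempt in seq_len(10)) {
      Lambda <- stats::rWishart(1, df = K, Sigma = L0)[, , 1]
      Phi <- stats::cor(Lambda)
      if (all(is.finite(Phi))) break
      Phi <- NULL
    }
    if (is.null(Phi)) stop("failed to draw a valid Wishart correlation matrix")
    truth <- list(alpha_k = stats::runif(K, 0.5 * cfg$alpha, 1.5 * cfg$alpha),
                  pi_prime = stats::runif(K, 0, 2),
                  Phi = Phi)
  }
  ev <- eigen(truth$Phi, symmetric = TRUE)
  fac <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), K)
  thr <- rep(truth$pi_prime, each = n)
  psi1 <- matrix(stats::rnorm(n * K), n, K) %*% t(fac)
  psi2 <- matrix(stats::rnorm(n * K), n, K) %*% t(fac)
  g <- (psi1 > thr) + (psi2 > thr)
  storage.mode(g) <- "double"
  finish_dataset(cfg, g, truth = truth)
}

# Draw confounder/noise and form x and y (continuous or binary outcome).
finish_dataset <- function(cfg, g, truth) {
  n <- cfg$n
  u <- stats::rnorm(n); ex <- stats::rnorm(n)
  x <- as.vector(g %*% truth$alpha_k) + u + ex
  if (cfg$outcome == "binary") {
    eta <- cfg$beta_x * x + cfg$beta_u * u
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - cfg$prevalence,
                         interval = c(-20, 20))$root
    y <- stats::rbinom(n, 1, stats::plogis(b0 + eta))
    truth$intercept <- b0
  } else {
    y <- cfg$beta_x * x + cfg$beta_u * u + stats::rnorm(n)
  }
  structure(list(g = g, x = x, y = y, truth = truth, config = cfg),
            class = "individual_dataset")
}

#' Generate a dataset with a binary outcome
#'
#' Correlated-variant data as in [gen_correlated()] but with outcome
#' `y ~ Bernoulli(expit(b0 + beta_x x + beta_u u))`, the intercept `b0`
#' solved numerically so that the realized prevalence matches
#' `cfg$prevalence`.  Per-variant outcome associations for such data are
#' obtained on the log-odds scale by univariate logistic regression
#' ([summarize_associations()] with `binary_y = TRUE`).
#'
#' @param cfg a [sim_config()] with `outcome = "binary"`.
#' @param seed optional integer seed.
#' @return A list of class `individual_dataset`.
#' @export
gen_binary_outcome <- function(cfg, seed = NULL) {
  stopifnot(cfg$outcome == "binary")
  if (cfg$ld == "wishart") gen_correlated(cfg, seed = seed)
  else gen_uncorrelated(cfg, seed = seed)
}

#' Generate external weights for a simulated dataset
#'
#' External weights emulate exposure associations estimated in an
#' independent sample of size `n_external` from the same population.  For
#' uncorrelated variants they are drawn directly from the sampling
#' distribution of a univariate regression slope, `Normal(alpha_k,
#' 1 / (N pi_k (1 - pi_k)))`.  For correlated variants an independent
#' dataset is simulated from the same variant-level parameters and
#' univariate per-variant regressions are fitted.  With `n_external = Inf`
#' ("oracle" weights) the true effects `alpha_k` are returned and the
#' standard errors are undefined (`NA`).
#'
#' @param truth the `truth` record of an [gen_uncorrelated()] /
#'   [gen_correlated()] dataset.
#' @param n_external external sample size, or `Inf` for oracle weights.
#' @param cfg the [sim_config()] (required for correlated truth records).
#' @param seed optional integer seed.
#' @return A list with `weights` and `se` (length-K vectors).
#' @export
gen_external_weights <- function(truth, n_external, cfg = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.infinite(n_external))
    return(list(weights = truth$alpha_k,
                se = rep(NA_real_, length(truth$alpha_k))))
  stopifnot(n_external > 0)
  if (!is.null(truth$Phi)) {
    stopifnot(!is.null(cfg))
    ext_cfg <- cfg
    ext_cfg$n <- n_external
    d <- gen_correlated(ext_cfg, truth = truth)
    a <- univariate_assoc(d$g, d$x)
    list(weights = a$beta, se = a$se)
  } else {
    se <- sqrt(1 / (n_external * truth$pi_k * (1 - truth$pi_k)))
    list(weights = stats::rnorm(length(truth$alpha_k), truth$alpha_k, se),
         se = se)
  }
}

#' Run a simulation study
#'
#' Repeatedly generates datasets from the configured model, applies the
#' requested estimators under the requested weighting schemes, and
#' aggregates bias, precision, coverage and power summaries with their
#' Monte-Carlo standard errors.
#'
#' Each analysis is a string `"method"` or `"method:scheme"`.  Methods:
#' `ols` (observational slope), `tsls` (multivariable 2SLS), `score`
#' (individual-level allele score as single IV), `score_summ`
#' (summarized-data allele score; two-sample delta-method SE, or the
#' correlation-aware SE when the model generates correlated variants),
#' `ivw` (summary
#' statistic method), `ivw_test` (IVW expression with correlation-aware
#' SE, a test only), `gls` (weighted generalized least squares), `ml`
#' (likelihood-based method).  Schemes: `crude` (in-sample univariate
#' slopes), `equal` (unit weights), `external` (independent-sample
#' weights, see [gen_external_weights()]), `oracle` (true effects).  For
#' `ivw`, `gls` and `ml`, the scheme's weights are used in place of the
#' exposure association estimates; `ml` additionally uses the external
#' weights' standard errors as `se_x`.
#'
#' Replicates in which an estimator fails are excluded from that
#' estimator's summaries and counted in `n_fail`, and failures of the
#' likelihood method to produce a usable standard error are treated the
#' same way.
#'
#' @param cfg a [sim_config()].
#' @param analyses character vector of `"method:scheme"` specs.
#' @param seed integer seed; the full study is deterministic given
#'   `cfg` and `seed`.
#' @param level nominal confidence level for coverage/power (default
#'   0.95, symmetric normal intervals).
#' @return An object of class `mr_study`: a list with `results` (one row
#'   per analysis: median/mean/SD of estimates, median/mean SE, coverage
#'   and power in percent, Monte-Carlo SEs, failure count), `strength`
#'   (mean first-stage R-squared and F), `config` and `seed`.
#' @export
run_study <- function(cfg, analyses = c("ols", "score:crude", "score:equal",
                                        "score:external"),
                      seed = 1, level = 0.95) {
  set.seed(seed)
  specs <- lapply(strsplit(analyses, ":", fixed = TRUE), function(p)
    list(method = p[1], scheme = if (length(p) > 1) p[2] else "crude"))
  known <- c("ols", "tsls", "score", "score_summ", "ivw", "ivw_test", "gls", "ml")
  for (sp in specs)
    if (!sp$method %in% known)
      stop("unknown method '", sp$method, "'; available: ",
           paste(known, collapse = ", "))
  z <- stats::qnorm(1 - (1 - level) / 2)
  n_an <- length(specs)
  est <- se <- matrix(NA_real_, cfg$reps, n_an)
  r2v <- fv <- numeric(cfg$reps)
  correlated <- cfg$ld == "wishart"

  for (r in seq_len(cfg$reps)) {
    d <- if (correlated) gen_correlated(cfg) else gen_uncorrelated(cfg)
    ax <- univariate_assoc(d$g, d$x)
    ay <- if (cfg$outcome == "binary") {
      su <- summarize_associations(d$g, d$x, d$y, binary_y = TRUE)
      list(beta = su$beta_y, se = su$se_y)
    } else univariate_assoc(d$g, d$y)
    rho <- if (correlated) stats::cor(d$g) else NULL
    # External-weight analyses are framed as two-sample, so the delta-method
    # cross term is dropped (theta_s = 0); the confounding-direction
    # asymmetry in summarized SEs arises from the outcome-residual variance
    # inside se_y, not from this term.
    theta_s <- 0
    st <- instrument_strength(d$g, d$x)
    r2v[r] <- st$r_squared; fv[r] <- st$f_stat
    ext <- NULL
    if (any(vapply(specs, function(sp) sp$scheme == "external", logical(1))))
      ext <- gen_external_weights(d$truth, cfg$n_external, cfg)
    for (j in seq_len(n_an)) {
      sp <- specs[[j]]
      w <- switch(sp$scheme,
                  crude = ax$beta,
                  equal = rep(1, cfg$k),
                  external = ext$weights,
                  oracle = d$truth$alpha_k,
                  stop("unknown weight scheme '", sp$scheme, "'"))
      res <- tryCatch(
        study_analysis(sp, d, ax, ay, rho, theta_s, w,
                       w_se = if (sp$scheme == "external") ext$se else NULL),
        error = function(e) NULL)
      if (!is.null(res) && is.finite(res[1]) && is.finite(res[2]) && res[2] > 0) {
        est[r, j] <- res[1]; se[r, j] <- res[2]
      }
    }
  }

  rows <- lapply(seq_len(n_an), function(j) {
    e <- est[, j]; s <- se[, j]
    ok <- is.finite(e) & is.finite(s)
    e <- e[ok]; s <- s[ok]
    R <- length(e)
    cover <- 100 * mean(abs(e - cfg$beta_x) <= z * s)
    power <- 100 * mean(abs(e) > z * s)
    sde <- if (R > 1) stats::sd(e) else NA_real_
    data.frame(method = specs[[j]]$method, scheme = specs[[j]]$scheme,
               median_est = stats::median(e), mean_est = mean(e),
               sd_est = sde,
               median_se = stats::median(s), mean_se = mean(s),
               coverage = cover, power = power,
               n_used = R, n_fail = cfg$reps - R,
               mc_se_median = if (R > 1) 1.2533 * sde / sqrt(R) else NA_real_,
               mc_se_coverage = sqrt(cover * (100 - cover) / R),
               mc_se_power = sqrt(power * (100 - power) / R),
               stringsAsFactors = FALSE)
  })
  structure(list(results = do.call(rbind, rows),
                 strength = list(mean_r_squared = mean(r2v),
                                 mean_f = mean(fv),
                                 mc_se_r_squared = stats::sd(r2v) / sqrt(cfg$reps),
                                 mc_se_f = stats::sd(fv) / sqrt(cfg$reps)),
                 config = cfg, seed = seed, level = level),
            class = "mr_study")
}

# One estimator applied to one replicate; returns c(estimate, se).
study_analysis <- function(sp, d, ax, ay, rho, theta_s, w, w_se = NULL) {
  K <- length(ax$beta)
  switch(sp$method,
    ols = { f <- fit_ols(d$x, d$y); c(f$estimate, f$se) },
    tsls = { f <- fit_2sls(d$g, d$x, d$y); c(f$estimate, f$se) },
    score = { f <- allele_score_2sls(d$g, d$x, d$y, w); c(f$estimate, f$se) },
    score_summ = {
      s <- summary_set(beta_x = ax$beta, se_x = ax$se,
                       beta_y = ay$beta, se_y = ay$se, ld = rho)
      c(allele_score_estimate(s, w),
        if (is.null(rho)) allele_score_se(s, w, theta_s = theta_s)
        else allele_score_se_correlated(s, w))
    },
    ivw = {
      s <- summary_set(beta_x = w, beta_y = ay$beta, se_y = ay$se)
      f <- ivw_estimate(s)
      c(f$estimate, f$se)
    },
    ivw_test = {
      s <- summary_set(beta_x = w, beta_y = ay$beta, se_y = ay$se,
                       ld = if (is.null(rho)) diag(K) else rho)
      f <- ivw_test_correlated(s)
      c(f$estimate$estimate, f$estimate$se)
    },
    gls = {
      s <- summary_set(beta_x = w, beta_y = ay$beta, se_y = ay$se,
                       ld = if (is.null(rho)) diag(K) else rho)
      f <- gls_estimate(s)
      c(f$estimate, f$se)
    },
    ml = {
      se_x <- if (!is.null(w_se)) w_se else ax$se
      s <- summary_set(beta_x = w, se_x = se_x,
                       beta_y = ay$beta, se_y = ay$se, ld = rho)
      f <- fit_ml(s, theta_l = 0)
      if (!f$hessian_ok) stop("no usable standard error")
      c(f$estimate$estimate, f$estimate$se)
    })
}

#' @export
print.mr_study <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf("simulation study: %d reps, n = %d, K = %d, alpha = %g, beta_x = %g, beta_u = %+g, %s variants, %s outcome\n",
              cfg$reps, cfg$n, cfg$k, cfg$alpha, cfg$beta_x, cfg$beta_u,
              if (cfg$ld == "wishart") "correlated" else "uncorrelated",
              cfg$outcome))
  cat(sprintf("mean first-stage R^2 = %.3f, mean F = %.1f\n",
              x$strength$mean_r_squared, x$strength$mean_f))
  print(x$results, digits = digits, row.names = FALSE)
  invisible(x)
}
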