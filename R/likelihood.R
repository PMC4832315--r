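#' Log-likelihood of the bivariate-normal summarized-data model
#'
#' The summarized associations for each variant are modelled jointly as
#' \deqn{(\hat\beta_{Xk}, \hat\beta_{Yk}) \sim
#'   N_2\big((\xi_k,\ \beta_L \xi_k),\ \Sigma_k\big), \qquad
#'   \Sigma_k = \begin{pmatrix} \sigma_{Xk}^2 &
#'   \theta_L \sigma_{Xk}\sigma_{Yk} \\ \theta_L\sigma_{Xk}\sigma_{Yk} &
#'   \sigma_{Yk}^2\end{pmatrix}}
#' where \eqn{\beta_L} is the causal parameter, \eqn{\xi_k} the true
#' per-variant exposure association, and \eqn{\theta_L} the within-variant
#' correlation between the exposure and outcome association estimates
#' (zero in a two-sample analysis).  When the set carries an LD matrix the
#' model is a single 2K-variate normal whose cross-variant blocks are
#' scaled by the variant correlations:
#' \eqn{cov(\hat\beta_{Xk_1}, \hat\beta_{Xk_2}) =
#'   \rho_{k_1k_2}\sigma_{Xk_1}\sigma_{Xk_2}},
#' \eqn{cov(\hat\beta_{Yk_1}, \hat\beta_{Yk_2}) =
#'   \rho_{k_1k_2}\sigma_{Yk_1}\sigma_{Yk_2}},
#' \eqn{cov(\hat\beta_{Xk_1}, \hat\beta_{Yk_2}) =
#'   \theta_L\,\rho_{k_1k_2}\sigma_{Xk_1}\sigma_{Yk_2}}
#' (a Kronecker-structured covariance, which reduces to the independent
#' bivariate terms for an identity LD matrix).
#'
#' @param s a [summary_set()] with `se_x` present.
#' @param beta_l causal parameter value.
#' @param xi length-K vector of true exposure associations.
#' @param theta_l within-variant correlation, `|theta_l| < 1`.
#' @param use_ld use the set's LD matrix if present (default `TRUE`).
#' @return The log-likelihood (scalar).
#' @export
mr_loglik <- function(s, beta_l, xi, theta_l = 0, use_ld = TRUE) {
  ctx <- ml_context(s, theta_l, use_ld)
  ml_ll(ctx, c(beta_l, xi))
}

# Precomputed quantities shared by all likelihood evaluations: the 2K
# observation vector z = (beta_x, beta_y), the Cholesky factor of the
# covariance, and its log-determinant contribution.
ml_context <- function(s, theta_l, use_ld = TRUE) {
  s <- validate_summary_set(s)
  if (is.null(s$se_x)) stop("likelihood model requires se_x")
  if (abs(theta_l) >= 1) stop("theta_l must lie strictly inside (-1, 1)")
  K <- s$k
  rho <- if (use_ld && !is.null(s$ld)) s$ld else diag(K)
  # PD repair of the correlation matrix as in build_omega
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * max(ev)) {
    eps <- c(1e-8, 1e-6, 1e-4, 1e-2)
    ok <- eps[(min(ev) + eps) >= 1e-8 * (max(ev) + eps)]
    if (!length(ok)) stop("LD matrix could not be repaired; prune variants")
    diag(rho) <- diag(rho) + ok[1]
    warning(sprintf("LD matrix numerically singular; ridge %.0e added", ok[1]))
  }
  Theta <- matrix(c(1, theta_l, theta_l, 1), 2, 2)
  S <- kronecker(Theta, rho) * tcrossprod(c(s$se_x, s$se_y))
  R <- chol(S)
  list(K = K, z = c(s$beta_x, s$beta_y), R = R,
       const = -K * log(2 * pi) - sum(log(diag(R))),
       s = s, theta_l = theta_l)
}

ml_mean <- function(ctx, par) {
  xi <- par[-1]
  c(xi, par[1] * xi)
}

ml_ll <- function(ctx, par) {
  r <- ctx$z - ml_mean(ctx, par)
  u <- backsolve(ctx$R, r, transpose = TRUE)
  ctx$const - 0.5 * sum(u^2)
}

ml_grad <- function(ctx, par) {
  K <- ctx$K
  r <- ctx$z - ml_mean(ctx, par)
  u <- backsolve(ctx$R, r, transpose = TRUE)
  v <- backsolve(ctx$R, u)           # S^{-1} (z - m)
  vx <- v[seq_len(K)]; vy <- v[K + seq_len(K)]
  xi <- par[-1]
  c(sum(xi * vy), vx + par[1] * vy)  # d loglik / d (beta_l, xi)
}

#' Maximum-likelihood fit of the summarized-data model
#'
#' Maximizes the log-likelihood of [mr_loglik()] over
#' \eqn{(\beta_L, \xi_1, \dots, \xi_K)} by quasi-Newton (BFGS) optimization
#' with an analytic gradient.  Initialization takes \eqn{\xi_k} at the
#' observed exposure associations and \eqn{\beta_L} at the IVW estimate
#' (the GLS estimate when an LD matrix is present); a single deterministic
#' restart from \eqn{\xi_k + 0.1\,\sigma_{Xk}} guards against spurious
#' convergence, and `converged` is set to `FALSE` if the restart improves
#' the log-likelihood by more than `1e-4` or the optimizer reports failure.
#' The standard error is taken from the inverse Hessian at the optimum;
#' when the Hessian is singular or yields a non-positive variance the fit
#' falls back to a profile-likelihood curvature standard error and flags
#' `hessian_ok = FALSE`.
#'
#' @param s a [summary_set()] with `se_x` present.
#' @param theta_l within-variant correlation (default 0, two-sample).
#' @param use_ld use the set's LD matrix if present.
#' @param level confidence level.
#' @return An object of class `mr_ml_fit` with fields `estimate` (a
#'   [causal_estimate()]), `xi_hat`, `loglik`, `converged` and
#'   `hessian_ok`.
#' @export
fit_ml <- function(s, theta_l = 0, use_ld = TRUE, level = 0.95) {
  ctx <- ml_context(s, theta_l, use_ld)
  s <- ctx$s
  beta0 <- tryCatch(
    if (use_ld && !is.null(s$ld)) gls_estimate(s)$estimate
    else ivw_estimate(s)$estimate,
    error = function(e) 0)
  negll <- function(p) -ml_ll(ctx, p)
  neggr <- function(p) -ml_grad(ctx, p)
  run <- function(start) stats::optim(start, negll, neggr, method = "BFGS",
                                      control = list(maxit = 500, reltol = 1e-12))
  fit1 <- run(c(beta0, s$beta_x))
  fit2 <- run(c(beta0, s$beta_x + 0.1 * s$se_x))
  best <- if (fit2$value < fit1$value) fit2 else fit1
  converged <- best$convergence == 0 &&
    abs(fit1$value - fit2$value) <= 1e-4
  ll <- -best$value
  # standard error from the inverse Hessian of the negative log-likelihood
  H <- stats::optimHess(best$par, negll, neggr)
  se <- tryCatch({
    v <- solve(H)[1, 1]
    if (!is.finite(v) || v <= 0) stop("non-positive variance")
    sqrt(v)
  }, error = function(e) NA_real_)
  hessian_ok <- is.finite(se)
  if (!hessian_ok) se <- ml_profile_se(ctx, best$par[1])
  notes <- c(if (!converged) "optimizer did not converge cleanly",
             if (!hessian_ok) "SE from profile-likelihood curvature (Hessian singular)")
  structure(
    list(estimate = causal_estimate(best$par[1], se, "likelihood",
                                    k_used = s$k, level = level,
                                    notes = notes),
         xi_hat = best$par[-1], loglik = ll,
         converged = converged, hessian_ok = hessian_ok),
    class = "mr_ml_fit")
}

#' @export
print.mr_ml_fit <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  loglik %.4f, converged: %s, hessian ok: %s\n",
              x$loglik, x$converged, x$hessian_ok))
  invisible(x)
}

# Profile log-likelihood at a single beta: the inner maximization over xi
# is a generalized least squares problem with design [I; beta I], solved
# in closed form.
ml_profile_at <- function(ctx, beta) {
  K <- ctx$K
  W <- chol2inv(ctx$R)
  Wxx <- W[seq_len(K), seq_len(K)]
  Wxy <- W[seq_len(K), K + seq_len(K)]
  Wyy <- W[K + seq_len(K), K + seq_len(K)]
  A <- Wxx + beta * (Wxy + t(Wxy)) + beta^2 * Wyy
  b <- (Wxx + beta * t(Wxy)) %*% ctx$z[seq_len(K)] +
       (Wxy + beta * Wyy) %*% ctx$z[K + seq_len(K)]
  xi <- solve(A, b)
  list(loglik = ml_ll(ctx, c(beta, xi)), xi = as.vector(xi))
}

ml_profile_se <- function(ctx, beta_hat, h = 1e-3) {
  p0 <- ml_profile_at(ctx, beta_hat)$loglik
  pp <- ml_profile_at(ctx, beta_hat + h)$loglik
  pm <- ml_profile_at(ctx, beta_hat - h)$loglik
  d2 <- (pp - 2 * p0 + pm) / h^2
  if (d2 >= 0) return(NA_real_)
  1 / sqrt(-d2)
}

#' Profile log-likelihood over a causal-parameter grid
#'
#' For each value of \eqn{\beta} on the grid, maximizes the log-likelihood
#' over the nuisance parameters \eqn{\xi} (closed form: for fixed
#' \eqn{\beta} the inner problem is generalized least squares; in the
#' uncorrelated two-sample case this is
#' \eqn{\hat\xi_k = (\hat\beta_{Xk}\sigma_{Xk}^{-2} +
#' \beta\hat\beta_{Yk}\sigma_{Yk}^{-2}) / (\sigma_{Xk}^{-2} +
#' \beta^2\sigma_{Yk}^{-2})}).  Serves as an independent check on
#' [fit_ml()] and as a fallback confidence procedure.
#'
#' @param s a [summary_set()] with `se_x` present.
#' @param beta_grid numeric grid of causal-parameter values.
#' @param theta_l within-variant correlation.
#' @param use_ld use the set's LD matrix if present.
#' @return A data frame with columns `beta` and `loglik`.
#' @export
profile_loglik <- function(s, beta_grid, theta_l = 0, use_ld = TRUE) {
  ctx <- ml_context(s, theta_l, use_ld)
  data.frame(beta = beta_grid,
             loglik = vapply(beta_grid,
                             function(b) ml_profile_at(ctx, b)$loglik,
                             numeric(1)))
}

#' Sensitivity sweep over the within-variant correlation
#'
#' Refits the likelihood model across a grid of \eqn{\theta_L} values, for
#' one-sample analyses where the correlation between the exposure and
#' outcome association estimates is unknown.
#'
#' @param s a [summary_set()] with `se_x` present.
#' @param theta_grid grid of \eqn{\theta_L} values (each strictly inside
#'   (-1, 1)).
#' @param use_ld use the set's LD matrix if present.
#' @return A data frame with columns `theta_l`, `estimate`, `se`,
#'   `converged`.
#' @export
theta_l_sweep <- function(s, theta_grid = seq(-0.5, 0.5, by = 0.25),
                          use_ld = TRUE) {
  rows <- lapply(theta_grid, function(th) {
    f <- fit_ml(s, theta_l = th, use_ld = use_ld)
    data.frame(theta_l = th, estimate = f$estimate$estimate,
               se = f$estimate$se, converged = f$converged)
  })
  do.call(rbind, rows)
}
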