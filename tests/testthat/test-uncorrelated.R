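test_that("summarized allele score estimate matches hand arithmetic", {
  s <- worked_set()
  # equal weights: (0.1*100 + 0.05*25) / (0.5*100 + 0.25*25) = 11.25 / 56.25
  expect_equal(allele_score_estimate(s, c(1, 1)), 11.25 / 56.25,
               tolerance = 1e-12)
  expect_equal(allele_score_estimate(s, c(1, 1)), 0.2, tolerance = 1e-12)
  # single variant: ratio estimate for any nonzero weight
  s1 <- summary_set(beta_x = 0.4, beta_y = 0.1, se_y = 0.05)
  expect_equal(allele_score_estimate(s1, 3.7), 0.25, tolerance = 1e-12)
  expect_error(allele_score_estimate(
    summary_set(beta_x = c(1, -1), beta_y = c(0, 0), se_y = c(1, 1)),
    c(1, 1)), "unidentified")
})

test_that("IVW estimate and SE match hand arithmetic", {
  s <- worked_set()
  f <- ivw_estimate(s)
  expect_equal(f$estimate, 0.2, tolerance = 1e-12)
  expect_equal(f$se, 1 / sqrt(26.5625), tolerance = 1e-12)
  expect_equal(f$se, 0.1940, tolerance = 5e-4)
  s1 <- summary_set(beta_x = 0.4, beta_y = 0.1, se_y = 0.05)
  f1 <- ivw_estimate(s1)
  expect_equal(f1$estimate, 0.25, tolerance = 1e-12)
  expect_equal(f1$se, 0.05 / 0.4, tolerance = 1e-12)
})

test_that("IVW via weighted regression through the origin equals the formula", {
  for (seed in 1:6) {
    s <- random_set(k = 4 + seed, seed = seed)
    a <- ivw_estimate(s)
    b <- ivw_via_regression(s)
    expect_equal(b$estimate, a$estimate, tolerance = 1e-10)
    expect_equal(b$se, a$se, tolerance = 1e-10)
  }
})

test_that("the residual-SE correction matters when residual SE is not one", {
  s <- random_set(k = 8, seed = 2)
  fit <- lm(s$beta_y ~ s$beta_x - 1, weights = s$se_y^-2)
  raw_se <- summary(fit)$coefficients[1, 2]
  corrected <- ivw_via_regression(s)$se
  expect_false(isTRUE(all.equal(raw_se, corrected, tolerance = 1e-4)))
  expect_equal(corrected, ivw_estimate(s)$se, tolerance = 1e-10)
})

test_that("exposure-association weights make the score estimate the IVW estimate", {
  for (seed in 1:5) {
    s <- random_set(k = 7, seed = seed)
    expect_equal(allele_score_estimate(s, weights = s$beta_x),
                 ivw_estimate(s)$estimate, tolerance = 1e-12)
    expect_equal(allele_score_se(s, weights = s$beta_x, terms = "first"),
                 ivw_estimate(s)$se, tolerance = 1e-12)
  }
})

test_that("delta-method SE reduces correctly and matches a numerical oracle", {
  s1 <- summary_set(beta_x = 0.4, beta_y = 0, se_y = 0.05)
  expect_equal(allele_score_se(s1, weights = 1, theta_s = 0), 0.05 / 0.4,
               tolerance = 1e-12)

  s <- random_set(k = 3, seed = 11)
  w <- c(1, 1, 1)
  wy2 <- s$se_y^-2
  A <- sum(w * s$beta_y * wy2); B <- sum(w * s$beta_x * wy2)
  C <- sum(w^2 * wy2)
  # numerical delta oracle: differentiate the ratio A/B and apply the
  # 2x2 covariance of (A, B) with Var(A) = Var(B) = C, Cov = theta * C
  for (theta in c(0, 0.3, -0.4)) {
    h <- 1e-6
    gA <- ((A + h) / B - (A - h) / B) / (2 * h)
    gB <- (A / (B + h) - A / (B - h)) / (2 * h)
    Sig <- C * matrix(c(1, theta, theta, 1), 2, 2)
    oracle <- sqrt(c(gA, gB) %*% Sig %*% c(gA, gB))[1]
    expect_equal(allele_score_se(s, w, theta_s = theta), oracle,
                 tolerance = 1e-6)
  }
  # with a positive estimate, positive theta shrinks the cross term
  expect_lt(allele_score_se(s, w, theta_s = 0.5),
            allele_score_se(s, w, theta_s = 0))
})

test_that("estimates and SEs scale with the outcome units", {
  s <- random_set(k = 6, seed = 12)
  c_ <- 3.7
  s2 <- s; s2$beta_y <- c_ * s$beta_y; s2$se_y <- c_ * s$se_y
  expect_equal(ivw_estimate(s2)$estimate, c_ * ivw_estimate(s)$estimate,
               tolerance = 1e-12)
  expect_equal(ivw_estimate(s2)$se, c_ * ivw_estimate(s)$se, tolerance = 1e-12)
  expect_equal(allele_score_estimate(s2, rep(1, 6)),
               c_ * allele_score_estimate(s, rep(1, 6)), tolerance = 1e-12)
  # the full delta SE is not scale-free (its second term squares the
  # dimensioned causal estimate); only the leading term scales with c
  expect_equal(allele_score_se(s2, rep(1, 6), terms = "first"),
               c_ * allele_score_se(s, rep(1, 6), terms = "first"),
               tolerance = 1e-12)
})

test_that("adding an informative variant strictly increases IVW precision", {
  s <- random_set(k = 5, seed = 13)
  s_plus <- summary_set(beta_x = c(s$beta_x, 0.05), se_x = c(s$se_x, 0.01),
                        beta_y = c(s$beta_y, 0.01), se_y = c(s$se_y, 0.05))
  expect_lt(ivw_estimate(s_plus)$se, ivw_estimate(s)$se)
})

test_that("summarized allele score estimates track individual-level ones", {
  cfg <- sim_config(n = 5000, k = 15, alpha = 0.1, beta_x = 0.2, beta_u = 1)
  set.seed(14)
  agree <- matrix(NA, 100, 3)
  for (r in 1:100) {
    d <- gen_uncorrelated(cfg)
    ax <- mrcombine:::univariate_assoc(d$g, d$x)
    ay <- mrcombine:::univariate_assoc(d$g, d$y)
    s <- summary_set(beta_x = ax$beta, beta_y = ay$beta, se_y = ay$se)
    ext <- gen_external_weights(d$truth, 5000)
    schemes <- list(crude = ax$beta, equal = rep(1, 15), external = ext$weights)
    for (j in seq_along(schemes)) {
      ind <- allele_score_2sls(d$g, d$x, d$y, schemes[[j]])$estimate
      summ <- allele_score_estimate(s, schemes[[j]])
      agree[r, j] <- abs(ind - summ) < 5e-4
    }
  }
  expect_gte(mean(agree), 0.99)
})

test_that("theta_s sweep reports a monotone interval width over the grid", {
  s <- random_set(k = 5, seed = 15)
  sw <- theta_s_sweep(s, weights = rep(1, 5), theta_grid = seq(-0.5, 0.5, 0.25))
  expect_equal(nrow(sw), 5L)
  expect_true(all(diff(sw$se) < 0))  # positive estimate: se falls with theta
  expect_equal(unique(sw$estimate), allele_score_estimate(s, rep(1, 5)))
})
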