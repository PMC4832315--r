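test_that("the weighting matrix is built from outcome SEs and correlations", {
  s <- worked_set(ld = diag(2))
  om <- build_omega(s)
  expect_equal(om$omega, diag(c(0.01, 0.04)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_false(om$repaired)

  s2 <- worked_set(ld = matrix(c(1, 0.5, 0.5, 1), 2, 2))
  expect_equal(build_omega(s2)$omega[1, 2], 0.1 * 0.2 * 0.5, tolerance = 1e-12)

  dup <- worked_set(ld = matrix(c(1, 1, 1, 1), 2, 2))
  expect_error(build_omega(dup), "prune")
})

test_that("near-singular LD is repaired by the smallest workable ridge", {
  ld <- matrix(0.999999999, 3, 3); diag(ld) <- 1
  s <- summary_set(beta_x = c(0.5, 0.4, 0.3), beta_y = c(0.1, 0.08, 0.06),
                   se_y = c(0.1, 0.1, 0.1), ld = ld)
  expect_warning(om <- build_omega(s), "ridge")
  expect_true(om$repaired)
  expect_gt(om$ridge, 0)
  expect_equal(om$omega[1, 2], 0.01 * ld[1, 2], tolerance = 1e-12)
})

test_that("correlated allele-score SE reduces to the first delta term at identity LD", {
  for (seed in 1:4) {
    s <- random_set(k = 6, seed = seed)
    s$ld <- diag(6); s <- validate_summary_set(s)
    w <- runif(6, 0.5, 1.5)
    expect_equal(allele_score_se_correlated(s, w),
                 allele_score_se(s, w, terms = "first"), tolerance = 1e-10)
  }
})

test_that("perfect exchangeable correlation scales the SE numerator by sqrt(K)", {
  K <- 3
  base <- summary_set(beta_x = rep(0.4, K), beta_y = rep(0.08, K),
                      se_y = rep(0.05, K), ld = diag(K))
  full <- base; full$ld <- matrix(1, K, K); full <- validate_summary_set(full)
  w <- rep(1, K)
  expect_equal(allele_score_se_correlated(full, w) /
                 allele_score_se_correlated(base, w),
               sqrt(K), tolerance = 1e-10)
})

test_that("IVW test with identity LD reproduces the uncorrelated z statistic", {
  s <- random_set(k = 5, seed = 21)
  s$ld <- diag(5); s <- validate_summary_set(s)
  tst <- ivw_test_correlated(s)
  ref <- ivw_estimate(s)
  expect_equal(tst$z, ref$estimate / ref$se, tolerance = 1e-10)
  expect_match(tst$estimate$notes, "test statistic only")
})

test_that("with exposure-association weights the IVW and allele-score z agree", {
  s <- random_set(k = 6, seed = 22, with_ld = TRUE)
  tst <- ivw_test_correlated(s)
  z_score <- allele_score_estimate(s, s$beta_x) /
    allele_score_se_correlated(s, s$beta_x)
  expect_equal(tst$z, z_score, tolerance = 1e-10)
})

test_that("GLS reduces to IVW at identity LD and matches a brute-force solve", {
  s <- random_set(k = 5, seed = 23)
  s$ld <- diag(5); s <- validate_summary_set(s)
  g <- gls_estimate(s); ivw <- ivw_estimate(s)
  expect_equal(g$estimate, ivw$estimate, tolerance = 1e-10)
  expect_equal(g$se, ivw$se, tolerance = 1e-10)

  for (seed in 24:26) {
    s2 <- random_set(k = 6, seed = seed, with_ld = TRUE)
    g2 <- gls_estimate(s2)
    Oi <- solve(tcrossprod(s2$se_y) * s2$ld)  # explicit inverse, small K only
    brute <- as.numeric((t(s2$beta_x) %*% Oi %*% s2$beta_y) /
                          (t(s2$beta_x) %*% Oi %*% s2$beta_x))
    brute_se <- as.numeric(1 / sqrt(t(s2$beta_x) %*% Oi %*% s2$beta_x))
    expect_equal(g2$estimate, brute, tolerance = 1e-8)
    expect_equal(g2$se, brute_se, tolerance = 1e-8)
  }
})

test_that("GLS of proportional associations returns the common ratio", {
  for (r in c(-0.3, 0, 0.4, 0.7)) {
    ld <- matrix(c(1, r, r, 1), 2, 2)
    s <- summary_set(beta_x = c(0.5, 0.25), beta_y = c(0.1, 0.05),
                     se_y = c(0.1, 0.2), ld = ld)
    expect_equal(gls_estimate(s)$estimate, 0.2, tolerance = 1e-10)
  }
})

test_that("LD pruning drops the later variant of a high-correlation pair", {
  ld <- diag(3)
  ld[1, 2] <- ld[2, 1] <- 0.95
  ld[1, 3] <- ld[3, 1] <- 0.2
  ld[2, 3] <- ld[3, 2] <- 0.25
  s <- summary_set(beta_x = c(0.5, 0.4, 0.3), beta_y = c(0.1, 0.09, 0.05),
                   se_y = c(0.1, 0.1, 0.1), ld = ld,
                   variant = c("a", "b", "c"))
  p <- ld_prune(s, r2_threshold = 0.8)
  expect_equal(p$variant, c("a", "c"))
  expect_equal(attr(p, "dropped"), "b")
})
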