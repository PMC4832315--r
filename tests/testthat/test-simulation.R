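test_that("datasets are bit-reproducible given a seed", {
  cfg <- sim_config(n = 200, k = 4, alpha = 0.1)
  d1 <- gen_uncorrelated(cfg, seed = 81)
  d2 <- gen_uncorrelated(cfg, seed = 81)
  expect_identical(d1, d2)
  cfgc <- sim_config(n = 200, k = 4, alpha = 0.1, ld = "wishart")
  expect_identical(gen_correlated(cfgc, seed = 82),
                   gen_correlated(cfgc, seed = 82))
})

test_that("a null first stage leaves genotypes uncorrelated with the exposure", {
  cfg <- sim_config(n = 4000, k = 6, alpha = 0)
  d <- gen_uncorrelated(cfg, seed = 83)
  expect_true(all(abs(cor(d$g, d$x)) < 0.05))
  expect_equal(d$truth$alpha_k, rep(0, 6))
})

test_that("haplotype thresholds map to allele frequencies as expected", {
  cfg <- sim_config(n = 20000, k = 4, alpha = 0.1, ld = "wishart")
  truth <- list(alpha_k = rep(0.1, 4), pi_prime = rep(1.96, 4), Phi = diag(4))
  set.seed(84)
  d <- gen_correlated(cfg, truth = truth)
  freq <- colMeans(d$g) / 2
  expect_true(all(abs(freq - 0.025) < 0.006))
})

test_that("the Wishart LD model induces mostly positive genotype correlations", {
  cfg <- sim_config(n = 5000, k = 15, alpha = 0.1, ld = "wishart")
  set.seed(85)
  offs <- unlist(lapply(1:8, function(i) {
    d <- gen_correlated(cfg)
    r <- cor(d$g)
    r[upper.tri(r)]
  }))
  expect_gt(mean(offs > 0), 0.65)
  expect_lt(mean(offs > 0), 0.9)
})

test_that("external weights behave like independent-sample estimates", {
  truth <- list(alpha_k = c(0.05, 0.1), pi_k = c(0.2, 0.4))
  oracle <- gen_external_weights(truth, Inf)
  expect_identical(oracle$weights, truth$alpha_k)
  expect_true(all(is.na(oracle$se)))

  w5k <- gen_external_weights(truth, 5000, seed = 86)
  w50k <- gen_external_weights(truth, 50000, seed = 86)
  expect_equal(w5k$se / w50k$se, rep(sqrt(10), 2), tolerance = 1e-12)
  expect_equal(w5k$se, sqrt(1 / (5000 * truth$pi_k * (1 - truth$pi_k))),
               tolerance = 1e-12)

  # empirical spread of repeated draws matches the nominal standard error
  set.seed(87)
  draws <- replicate(3000, gen_external_weights(truth, 5000)$weights[1])
  expect_lt(abs(sd(draws) - w5k$se[1]), 0.05 * w5k$se[1])
  expect_lt(abs(mean(draws) - 0.05), 3 * w5k$se[1] / sqrt(3000))
})

test_that("studies are deterministic given config and seed", {
  cfg <- sim_config(n = 400, k = 5, alpha = 0.2, reps = 5)
  a <- run_study(cfg, c("ols", "score:equal", "ivw:external"), seed = 88)
  b <- run_study(cfg, c("ols", "score:equal", "ivw:external"), seed = 88)
  expect_identical(a$results, b$results)
  expect_error(run_study(cfg, "magic:equal", seed = 1), "unknown method")
})

test_that("a single-replicate study degrades gracefully", {
  cfg <- sim_config(n = 300, k = 4, alpha = 0.2, reps = 1)
  st <- run_study(cfg, c("ols", "score:equal"), seed = 89)
  expect_true(all(is.na(st$results$sd_est)))
  expect_equal(st$results$n_used, c(1L, 1L))
})

test_that("crude-weight bias follows the direction of confounding", {
  reps <- 120
  for (bu in c(1, -1)) {
    cfg <- sim_config(n = 5000, k = 15, alpha = 0.05, beta_x = 0.2,
                      beta_u = bu, reps = reps)
    st <- run_study(cfg, c("score:crude", "score:equal"), seed = 90 + bu)
    crude <- st$results$median_est[st$results$scheme == "crude"]
    equal <- st$results$median_est[st$results$scheme == "equal"]
    if (bu > 0) expect_gt(crude, 0.25) else expect_lt(crude, 0.15)
    # equal weights stay median-unbiased in the same conditions
    mc <- st$results$mc_se_median[st$results$scheme == "equal"]
    expect_lt(abs(equal - 0.2), 3 * mc)
  }
})

test_that("imprecise external weights attenuate the IVW estimate toward the null", {
  cfg <- sim_config(n = 5000, k = 15, alpha = 0.05, beta_x = 0.2, beta_u = 1,
                    reps = 120)
  st <- run_study(cfg, "ivw:external", seed = 92)
  med <- st$results$median_est
  expect_gt(med, 0.05)
  expect_lt(med, 0.19)
})

test_that("binary outcomes hit the target prevalence and yield log-odds associations", {
  cfg <- sim_config(n = 5000, k = 5, alpha = 0.2, beta_x = 0.2,
                    ld = "wishart", outcome = "binary", prevalence = 0.3)
  d <- gen_binary_outcome(cfg, seed = 93)
  expect_true(all(d$y %in% c(0, 1)))
  expect_equal(mean(d$y), 0.3, tolerance = 0.03)
  su <- summarize_associations(d$g, d$x, d$y, binary_y = TRUE)
  fit <- glm(d$y ~ d$g[, 1], family = binomial())
  expect_equal(su$beta_y[1], unname(coef(fit)[2]), tolerance = 1e-6)
  expect_equal(su$se_y[1], unname(summary(fit)$coefficients[2, 2]),
               tolerance = 1e-6)
})
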