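test_that("cronbach's alpha follows its defining formula", {
  x1 <- c(0, 1, 2)
  expect_equal(cronbach_alpha(cbind(x1, x1)), 1)
  # variances 1 and 1, covariance 0.5: alpha = 2 * (1 - 2/3)
  x2 <- c(1, 0, 2)
  expect_equal(cronbach_alpha(cbind(x1, x2)), 2 * (1 - 2 / 3))
  # exactly orthogonal columns with equal variance: alpha = 0
  h <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  expect_equal(cronbach_alpha(h), 0)
  expect_error(cronbach_alpha(cbind(x1)), "2 items")
})

test_that("the Feldt interval behaves and matches an independent inversion", {
  expect_equal(unname(alpha_ci(1, 100, 10)), c(1, 1))
  ci_small <- alpha_ci(0.8, 50, 10)
  ci_big <- alpha_ci(0.8, 5000, 10)
  expect_true(ci_small["low"] < 0.8 && 0.8 < ci_small["high"])
  expect_true(diff(ci_big) < diff(ci_small))

  # oracle: invert the F cdf by root-finding instead of qf
  f_quantile <- function(p, d1, d2)
    stats::uniroot(function(q) stats::pf(q, d1, d2) - p, c(1e-8, 1e8),
                   tol = 1e-12)$root
  got <- alpha_ci(0.8, 101, 10)
  want_low <- 1 - (1 - 0.8) * f_quantile(0.975, 100, 900)
  want_high <- 1 - (1 - 0.8) * f_quantile(0.025, 100, 900)
  expect_equal(unname(got), c(want_low, want_high), tolerance = 1e-7)
})

test_that("item-total correlations match a naive per-item recomputation", {
  set.seed(5)
  x <- matrix(rnorm(300 * 10), 300, 10,
              dimnames = list(NULL, paste0("i", 1:10)))
  got <- item_total_correlations(x)
  want <- vapply(1:10, function(j)
    stats::cor(x[, j], rowSums(x[, -j])), numeric(1))
  expect_equal(unname(got), want)

  # an item independent of the rest correlates near zero
  d <- one_factor_design(6)
  cfg <- sim_config(d, n_respondents = 5000, prevalence = 0, seed = 61,
                    loadings = stats::setNames(c(rep(0.7, 5), 1e-4),
                                               scored_items(d)))
  m <- assemble_study(cfg)$responses
  expect_lt(abs(item_total_correlations(m$values)[["Q06"]]), 0.05)
})

test_that("omega coefficients respect their structural identities", {
  # near-unit factor correlations: the general factor absorbs everything
  d <- toy_design(k = 4)
  fmap <- d$factor_map
  phi <- matrix(0.95, 3, 3); diag(phi) <- 1
  dimnames(phi) <- list(unique(fmap), unique(fmap))
  x <- continuous_factor_data(2000, stats::setNames(rep(0.7, 12), names(fmap)),
                              fmap, phi, seed = 9)
  om <- omega_coefficients(x, d)
  expect_true(om$omega_h <= om$omega_t)
  expect_true(om$omega_t <= 1)
  expect_lt(om$omega_t - om$omega_h, 0.06)

  # distinct group factors: omega_h clearly below omega_t, and the
  # hierarchical share agrees with a one-factor EFA oracle
  phi2 <- matrix(0.55, 3, 3); diag(phi2) <- 1
  dimnames(phi2) <- dimnames(phi)
  x2 <- continuous_factor_data(3000, stats::setNames(rep(0.7, 12), names(fmap)),
                               fmap, phi2, seed = 10)
  om2 <- omega_coefficients(x2, d)
  expect_gt(om2$omega_t - om2$omega_h, 0.05)
  # oracle: omega_h from the true generating parameters (second-order
  # loading sqrt(0.55), first-order loadings 0.7 -> g = 0.7 * sqrt(0.55),
  # s = 0.7 * sqrt(0.45), psi = 0.51)
  g_true <- rep(0.7 * sqrt(0.55), 12)
  s_true <- rep(0.7 * sqrt(0.45), 12)
  v_true <- sum(g_true)^2 + 3 * sum(s_true[1:4])^2 + 12 * (1 - 0.7^2)
  expect_equal(om2$omega_h, sum(g_true)^2 / v_true, tolerance = 0.05)
  expect_equal(om2$omega_t,
               (sum(g_true)^2 + 3 * sum(s_true[1:4])^2) / v_true,
               tolerance = 0.05)

  # tau-equivalent data: omega_t approaches alpha
  d1 <- one_factor_design(8)
  cfg <- sim_config(d1, n_respondents = 5000, prevalence = 0, seed = 71,
                    loadings = stats::setNames(rep(0.6, 8), scored_items(d1)))
  m <- assemble_study(cfg)$responses
  om1 <- omega_coefficients(m$values, NULL)
  expect_lt(abs(om1$omega_t - cronbach_alpha(m$values)), 0.01)
  expect_equal(om1$omega_h, om1$omega_t)
})

test_that("the ML engine recovers parameters and reports exact CR/AVE arithmetic", {
  # continuous data from the model: lambda 0.7, k = 4 -> CR 0.794, AVE 0.49
  fmap <- stats::setNames(rep("g", 4), paste0("i", 1:4))
  x <- continuous_factor_data(20000, stats::setNames(rep(0.7, 4), names(fmap)),
                              fmap, matrix(1, 1, 1, dimnames = list("g", "g")),
                              seed = 3)
  fit <- carescreen:::fit_cfa_matrix(x, fmap)
  expect_equal(unname(fit$lambda_std), rep(0.7, 4), tolerance = 0.02)
  expect_equal(unname(fit$cr), 0.794, tolerance = 0.01)
  expect_equal(unname(fit$ave), 0.49, tolerance = 0.015)
  expect_true(fit$convergence$converged)
  expect_equal(fit$df, 2)

  # categorical simulation: loadings recovered up to discretization
  cfg <- default_sdas_config(n_respondents = 2000, prevalence = 0, seed = 83)
  m <- recode_reverse(assemble_study(cfg)$responses, cfg$design)
  f2 <- fit_cfa(m, cfg$design)
  err <- abs(f2$lambda_std - cfg$loadings[names(f2$lambda_std)])
  expect_lt(max(err), 0.07)
  expect_lt(f2$chi2 / f2$df, 1.25)
  expect_equal(f2$df, 591)

  # two-indicator one-factor model is underidentified
  expect_error(
    carescreen:::fit_cfa_matrix(x[, 1:2],
                                stats::setNames(rep("g", 2),
                                                colnames(x)[1:2])),
    "underidentified")
})

test_that("the fitted model reproduces itself from its own implied moments", {
  skip_if_not_installed("MASS")
  d <- toy_design(k = 3)
  fmap <- d$factor_map
  phi <- matrix(0.5, 3, 3); diag(phi) <- 1
  dimnames(phi) <- list(unique(fmap), unique(fmap))
  x <- continuous_factor_data(600, stats::setNames(seq(0.5, 0.72,
                                                       length.out = 9),
                                                   names(fmap)),
                              fmap, phi, seed = 11)
  fit1 <- carescreen:::fit_cfa_matrix(x, fmap)
  # data whose sample covariance equals the fitted implied covariance
  lam <- fit1$lambda_std
  sigma <- diag(9)
  for (a in 1:9) for (b in 1:9)
    sigma[a, b] <- if (a == b) 1 else
      lam[a] * lam[b] * fit1$phi_cor[fmap[a], fmap[b]]
  y <- MASS::mvrnorm(1000, rep(0, 9), sigma, empirical = TRUE)
  colnames(y) <- names(fmap)
  fit2 <- carescreen:::fit_cfa_matrix(y, fmap)
  expect_equal(fit2$lambda_std, lam, tolerance = 1e-3)
  expect_lt(fit2$chi2, 1e-4)
  expect_equal(fit2$cfi, 1)
})

test_that("CR and AVE are invariant to item-order permutation", {
  d <- toy_design(k = 4)
  fmap <- d$factor_map
  phi <- matrix(0.4, 3, 3); diag(phi) <- 1
  dimnames(phi) <- list(unique(fmap), unique(fmap))
  set.seed(12)
  lam <- stats::setNames(stats::runif(12, 0.4, 0.8), names(fmap))
  x <- continuous_factor_data(800, lam, fmap, phi, seed = 13)
  fit_a <- carescreen:::fit_cfa_matrix(x, fmap)
  set.seed(14)
  perm <- sample(12)
  fit_b <- carescreen:::fit_cfa_matrix(x[, perm], fmap[perm])
  expect_equal(fit_a$cr[sort(names(fit_a$cr))],
               fit_b$cr[sort(names(fit_b$cr))], tolerance = 1e-3)
  expect_equal(fit_a$ave[sort(names(fit_a$ave))],
               fit_b$ave[sort(names(fit_b$ave))], tolerance = 1e-3)
})

test_that("fit indices follow their closed forms", {
  perfect <- fit_indices(591, 591, 10000, 630, 1112)
  expect_equal(perfect$cfi, 1)
  expect_equal(perfect$rmsea, 0)
  same_as_baseline <- fit_indices(10000, 591, 10000, 630, 1112)
  expect_equal(same_as_baseline$cfi, 0)
  # chi2 1635.37 on 591 df at n = 1112: plain-ML RMSEA 0.0399
  idx <- fit_indices(1635.37, 591, 20000, 630, 1112)
  expect_equal(idx$rmsea, sqrt((1635.37 - 591) / (591 * 1111)))
  expect_equal(round(idx$rmsea, 4), 0.0399)
  expect_true(idx$rmsea_ci[1] <= idx$rmsea && idx$rmsea <= idx$rmsea_ci[2])
  expect_error(fit_indices(100, 0, 200, 10, 50), "df_m")
  expect_error(fit_indices(100, 50, 200, 40, 50), "baseline")
})

test_that("the invariance ladder has the right df arithmetic and null behavior", {
  d <- toy_design(k = 3)   # 9 items, 3 factors
  cfgA <- sim_config(d, n_respondents = 300, prevalence = 0, seed = 101,
                     loadings = stats::setNames(seq(0.45, 0.75,
                                                    length.out = 9),
                                                scored_items(d)))
  cfgB <- sim_config(d, n_respondents = 300, prevalence = 0, seed = 102,
                     loadings = cfgA$loadings)
  g1 <- assemble_study(cfgA)$responses
  g2 <- assemble_study(cfgB)$responses
  iv <- invariance_sequence(g1, g2, d, min_n = 100)
  # df: configural = 2 * 54 - 2 * (6 + 6 + 9 + 9); metric adds
  # (#items - #factors); scalar adds (#items - #factors) again
  expect_equal(iv$df, c(48, 54, 60))
  expect_equal(diff(iv$df), rep(9 - 3, 2))
  expect_true(all(diff(iv$df) > 0))
  # two samples from the same process: both constrained steps supported
  expect_true(all(iv$supported[2:3]))
  expect_error(invariance_sequence(g1, g2, d, min_n = 400), "at least")
})

test_that("the invariance decision rule matches the published cutoffs", {
  expect_true(invariance_decision(-0.001, -0.001))
  expect_false(invariance_decision(-0.020, 0.004))
  expect_true(invariance_decision(-0.010, 0.015))   # boundary inclusive
  expect_false(invariance_decision(-0.011, 0))
  expect_false(invariance_decision(0, 0.016))
})
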