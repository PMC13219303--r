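test_that("the nested permutation test is exact under enumeration", {
  flat <- permutation_nested_mean_test(rep(4, 10), c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_equal(flat$observed_delta, 0)
  expect_equal(flat$p_two_sided, 1)
  expect_true(flat$exhaustive)

  # scores (1,2,3,10), the 10 flagged: delta = 4 - 2 = 2, p = 1/4
  r <- permutation_nested_mean_test(c(1, 2, 3, 10),
                                    c(FALSE, FALSE, FALSE, TRUE))
  expect_true(r$exhaustive)
  expect_equal(r$observed_delta, 2)
  expect_equal(r$p_two_sided, 1 / 4)

  expect_error(permutation_nested_mean_test(1:4, rep(TRUE, 4)), "subset")
})

test_that("sampled permutation p agrees with exhaustive enumeration", {
  set.seed(19)
  scores <- round(rnorm(12, 50, 8), 1)
  flags <- c(rep(TRUE, 3), rep(FALSE, 9))
  exact <- permutation_nested_mean_test(scores, flags)
  expect_true(exact$exhaustive)
  sampled <- permutation_nested_mean_test(scores, flags, B = 4000,
                                          seed = 99, exhaustive_cap = 10)
  expect_false(sampled$exhaustive)
  p <- exact$p_two_sided
  expect_lt(abs(sampled$p_two_sided - p), 2 * sqrt(p * (1 - p) / 4000) + 1e-9)
  # seeded determinism
  again <- permutation_nested_mean_test(scores, flags, B = 4000,
                                        seed = 99, exhaustive_cap = 10)
  expect_identical(sampled$p_two_sided, again$p_two_sided)
})

test_that("fisher z / cohen's q comparisons follow the transform", {
  same <- fisher_q_compare(0.4, 200, 0.4, 300)
  expect_equal(same$fisher_z, 0)
  expect_equal(same$p, 1)
  expect_equal(same$cohens_q, 0)
  expect_equal(same$q_label, "negligible")

  # published comparison: r .288 (n 1112) vs .321 (n 986) -> q = 0.036
  pub <- fisher_q_compare(0.288, 1112, 0.321, 986)
  expect_equal(round(pub$cohens_q, 3), 0.036)
  expect_equal(pub$q_label, "negligible")

  # oracle grid: q via the hyperbolic-arctangent definition
  set.seed(23)
  for (i in 1:20) {
    r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
    n1 <- sample(10:500, 1); n2 <- sample(10:500, 1)
    got <- fisher_q_compare(r1, n1, r2, n2)
    expect_equal(got$cohens_q,
                 abs(0.5 * log((1 + r1) / (1 - r1)) -
                     0.5 * log((1 + r2) / (1 - r2))))
    expect_equal(got$fisher_z,
                 (atanh(r1) - atanh(r2)) /
                   sqrt(1 / (n1 - 3) + 1 / (n2 - 3)))
  }
  expect_error(fisher_q_compare(1, 100, 0.5, 100), "\\|r\\|")
  # boundary values land in the lower bin
  expect_equal(fisher_q_compare(tanh(0.10), 100, 0, 100)$q_label, "negligible")
  expect_equal(fisher_q_compare(tanh(0.30), 100, 0, 100)$q_label, "small")
})

test_that("cohen's d has correct point estimates, labels and consistency", {
  same <- cohens_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$cohens_d, 0)
  expect_true(same$ci[1] < 0 && 0 < same$ci[2])

  # exact d = 0.5 by construction; boundary goes to the lower bin ("small")
  half <- cohens_d(c(1, 2, 3), c(0.5, 1.5, 2.5))
  expect_equal(half$cohens_d, 0.5)
  expect_equal(half$d_label, "small")

  set.seed(27)
  big <- cohens_d(rnorm(1e4, 0.5), rnorm(1e4, 0))
  expect_equal(big$cohens_d, 0.5, tolerance = 0.03)
  expect_true(big$ci[1] < big$cohens_d & big$cohens_d < big$ci[2])
  expect_equal(cohens_d(rnorm(50, 0.15, 1e-6), rnorm(50, 0, 1e-6))$d_label,
               "large")  # tiny sd inflates d; label tracks the estimate
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled variance")
})

test_that("minimum detectable d solves the noncentral-t power equation", {
  expect_equal(round(min_detectable_d(986, 126, 0.05, 0.80), 2), 0.27)
  expect_equal(min_detectable_d(64, 64, 0.05, 0.80), 0.50, tolerance = 0.005)
  # the solution actually attains the requested power
  d <- min_detectable_d(80, 40, 0.05, 0.9)
  df <- 118; ncp <- d * sqrt(80 * 40 / 120); tc <- qt(0.975, df)
  expect_equal(pt(tc, df, ncp, lower.tail = FALSE) + pt(-tc, df, ncp), 0.9,
               tolerance = 1e-6)
  # monotone in n
  ds <- sapply(c(50, 200, 1000, 5000), function(n)
    min_detectable_d(n, n, 0.05, 0.80))
  expect_true(all(diff(ds) < 0))
})

test_that("the CSI is the unweighted component sum with positional tie-breaks", {
  rows <- published_csi_rows()
  a <- fake_item_stats(rows$item, rows$dM, rows$dr, rows$dlam,
                       types = rows$type)
  b <- fake_item_stats(rows$item, rep(0, 10), rep(0, 10), rep(0, 10),
                       types = rows$type)
  tab <- csi_compute(a, b)
  expect_equal(tab$csi, rows$csi, tolerance = 1e-12)
  # symmetric in the sample labels
  tab_rev <- csi_compute(b, a)
  expect_equal(tab_rev$csi, tab$csi)
  # zero components give zero CSI
  z <- csi_compute(b, b)
  expect_true(all(z$csi == 0))
  expect_equal(z$rank, seq_len(10))   # pure positional tie-break
  expect_error(csi_compute(a, fake_item_stats("x", 1, 1, 1)), "item sets")

  top <- top_k_report(tab, 3)
  expect_equal(top$top$item, c("SDAS_27", "SDAS_03", "SDAS_04"))
  expect_equal(top_k_report(tab, 10)$n_reverse_top, 6)
  expect_error(top_k_report(tab, 11), "exceeds")
})

test_that("the z-scored CSI is the component z-sum and preserves equal-sd rankings", {
  # pre-standardized components: z-scoring is the identity
  tab <- data.frame(item = paste0("i", 1:4), factor = "f", type = "standard",
                    position = 1:4,
                    dM = scale(c(1, 2, 3, 4))[, 1],
                    dr = scale(c(4, 1, 3, 2))[, 1],
                    dlam = scale(c(2, 4, 1, 3))[, 1])
  tab$csi <- tab$dM + tab$dr + tab$dlam
  tab$rank <- carescreen:::rank_desc(tab$csi, tab$position)
  out <- csi_z(tab)
  expect_equal(out$csi_z, tab$dM + tab$dr + tab$dlam)

  # constant component is an error path
  bad <- tab; bad$dr <- 1
  expect_error(csi_z(bad), "zero-variance")

  # equal component sds: CSI and CSI-z order identically
  set.seed(31)
  eq <- data.frame(item = paste0("i", 1:12), factor = "f",
                   type = "standard", position = 1:12,
                   dM = runif(12), dr = runif(12), dlam = runif(12))
  for (cl in c("dM", "dr", "dlam")) eq[[cl]] <- eq[[cl]] / sd(eq[[cl]])
  eq$csi <- eq$dM + eq$dr + eq$dlam
  eq$rank <- carescreen:::rank_desc(eq$csi, eq$position)
  out2 <- csi_z(eq)
  expect_equal(out2$rank_z, out2$rank)
})

test_that("rank agreement matches hand-counted concordance", {
  ident <- rank_agreement(1:10, 1:10)
  expect_equal(ident$spearman_rho, 1)
  expect_equal(ident$kendall_tau_b, 1)
  rev <- rank_agreement(1:10, 10:1)
  expect_equal(rev$spearman_rho, -1)
  expect_equal(rev$kendall_tau_b, -1)
  # (1,2,3,4) vs (1,2,4,3): 5 concordant, 1 discordant -> tau = 2/3,
  # rho = 1 - 6*2/60 = 0.8
  swap <- rank_agreement(c(1, 2, 3, 4), c(1, 2, 4, 3))
  expect_equal(swap$kendall_tau_b, 2 / 3)
  expect_equal(swap$spearman_rho, 0.8)
  expect_error(rank_agreement(rep(1, 5), 1:5), "constant")
})
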