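test_that("the instructed-item rule flags exactly the non-required responses", {
  d <- toy_design(k = 2, instructed = TRUE)
  v <- matrix(3L, 3, 7, dimnames = list(NULL, d$item_ids))
  v[2, "T_CHK"] <- 4L
  m <- response_matrix(v, paste0("r", 1:3), d)
  expect_equal(unname(flag_instructed(m, d)), c(FALSE, TRUE, FALSE))
  expect_error(flag_instructed(m, toy_design(k = 2)), "instructed")
})

test_that("archetype-contaminated samples reproduce the study's prevalence flow", {
  # 986 attentive + 126 acquiescent (who never emit the required category)
  cfg <- default_sdas_config(seed = 8)
  att <- simulate_attentive(cfg, 986)
  car <- simulate_careless(cfg, "acquiescent", 126, first_counter = 987)
  d <- cfg$design
  v <- rbind(att$values, car$values)
  m <- response_matrix(v, sprintf("R%04d", 1:1112), d,
                       truth_labels = c(att$truth_labels, car$truth_labels))
  fl <- flag_instructed(m, d)
  expect_equal(sum(fl), 126)
  expect_equal(careless_prevalence(sum(fl), length(fl)), 11.33)
  sam <- split_samples(m, fl)
  expect_equal(unname(sam$counts), c(1112L, 986L, 126L))
})

test_that("longstring matches the brute-force oracle", {
  d <- one_factor_design(5)
  m <- response_matrix(matrix(c(1L, 1L, 1L, 2L, 2L), 1,
                              dimnames = list(NULL, d$item_ids)), "a", d)
  expect_equal(unname(longstring_index(m)), 3L)

  d37 <- sdas_design()
  const <- response_matrix(matrix(3L, 1, 37,
                                  dimnames = list(NULL, d37$item_ids)),
                           "a", d37)
  expect_equal(unname(longstring_index(const)), 37L)

  set.seed(12)
  v <- matrix(sample(1:5, 1000 * 37, TRUE, prob = c(1, 1, 4, 4, 2)), 1000,
              dimnames = list(NULL, d37$item_ids))
  m <- response_matrix(v, sprintf("r%04d", 1:1000), d37)
  expect_identical(unname(longstring_index(m)),
                   vapply(seq_len(1000), function(i)
                     longstring_oracle(v[i, ]), integer(1)))
})

test_that("even-odd inconsistency follows its defining transform", {
  d <- toy_design(k = 2)   # 3 factors x 2 items: odd = first, even = second
  # perfectly consistent: odd and even half-means identical, with spread
  v <- matrix(c(1L, 1L, 3L, 3L, 5L, 5L), 1, dimnames = list(NULL, d$item_ids))
  m <- response_matrix(v, "a", d)
  expect_equal(unname(evenodd_index(m, d)), 0)

  # half-mean pairs (5,1), (1,5), (3,3): r = -1, clipped, index 2
  v <- matrix(c(5L, 1L, 1L, 5L, 3L, 3L), 1, dimnames = list(NULL, d$item_ids))
  m <- response_matrix(v, "a", d)
  expect_equal(unname(evenodd_index(m, d)), 2)

  # pure straightliner: zero-variance half-means get the maximal score
  v <- matrix(4L, 1, 6, dimnames = list(NULL, d$item_ids))
  m <- response_matrix(v, "a", d)
  expect_equal(unname(evenodd_index(m, d)), 2)

  # affine increasing map between half-means gives r = 1, index 0
  v <- matrix(c(1L, 2L, 3L, 4L, 5L, 5L), 1, dimnames = list(NULL, d$item_ids))
  # odd means (1,3,5); even means (2,4,5): not affine -- construct affine:
  v <- matrix(c(1L, 2L, 3L, 3L, 5L, 4L), 1, dimnames = list(NULL, d$item_ids))
  # odd (1,3,5), even (2,3,4) = 1.5 + 0.5*odd
  m <- response_matrix(v, "a", d)
  expect_equal(unname(evenodd_index(m, d)), 0)

  expect_error(evenodd_index(m, minimal_design()), "3 factors")

  # 500 simulated rows equal the straight-line oracle
  dd <- sdas_design()
  cfg <- default_sdas_config(n_respondents = 500, seed = 13)
  rec <- recode_reverse(assemble_study(cfg)$responses, dd)
  got <- evenodd_index(rec, dd)
  want <- vapply(seq_len(500), function(i)
    evenodd_oracle_row(rec$values[i, ], dd), numeric(1))
  expect_equal(unname(got), want)
})

test_that("the outlier pre-screen flags extreme standardized totals", {
  scores <- c(rep(100, 1112), rep(500, 7))   # 7 planted extremes
  scores[1:1112] <- scores[1:1112] + rep_len(c(-2, -1, 0, 1, 2), 1112)
  fl <- outlier_flag(scores, 4)
  expect_equal(sum(fl), 7)
  expect_equal(sum(!fl), 1112)
  expect_false(any(outlier_flag(scores, Inf)))
  expect_error(outlier_flag(rep(3, 10)), "zero variance")
})

test_that("extended flags are the union of the three indicators with 2-sd cuts", {
  cfg <- default_sdas_config(n_respondents = 600, seed = 23)
  study <- assemble_study(cfg)
  d <- cfg$design
  sr <- screen_sample(study$responses, d)
  expect_true(all(sr$flag_extended[sr$flag_primary]))  # primary implies extended
  expect_equal(attr(sr, "longstring_cut"),
               mean(sr$longstring) + 2 * stats::sd(sr$longstring))
  expect_equal(attr(sr, "evenodd_cut"),
               mean(sr$evenodd) + 2 * stats::sd(sr$evenodd))
  manual <- sr$instructed_fail | sr$longstring >= attr(sr, "longstring_cut") |
    sr$evenodd >= attr(sr, "evenodd_cut")
  expect_identical(sr$flag_extended, manual)

  # a midpoint straightliner passes the check but exceeds the longstring
  # cut: extended-flagged without being primary-flagged
  cfg2 <- default_sdas_config(n_respondents = 600, seed = 23,
                              archetype_mix = c(acquiescent = 0.8,
                                                midpoint_straightliner = 0.2))
  st2 <- assemble_study(cfg2)
  sr2 <- screen_sample(st2$responses, d)
  mids <- st2$responses$truth_labels == "midpoint_straightliner"
  expect_true(any(mids))
  expect_true(all(!sr2$flag_primary[mids]))
  expect_true(all(sr2$flag_extended[mids]))   # longstring 37 is over any cut
})

test_that("a pure uniform-random careless mix exposes the single-check blind spot", {
  cfg <- default_sdas_config(n_respondents = 2000, prevalence = 0.2,
                             archetype_mix = c(random_uniform = 1), seed = 29)
  m <- assemble_study(cfg)$responses
  fl <- flag_instructed(m, cfg$design)
  # flagged fraction approximates prevalence * (1 - 1/5) = 0.16
  expect_lt(abs(mean(fl) - 0.16), 0.025)
})

test_that("degenerate partitions are refused downstream", {
  cfg <- default_sdas_config(n_respondents = 50, prevalence = 0, seed = 4)
  m <- assemble_study(cfg)$responses
  sam <- split_samples(m, rep(TRUE, 50))
  expect_equal(nrow(sam$screened$values), 0)
  expect_error(fit_cfa(recode_reverse(sam$screened, cfg$design), cfg$design))
  expect_error(split_samples(m, TRUE), "aligned")
})
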