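cfg4 <- score_config(4)

test_that("contingency counts match direct tallies", {
  ds <- genotype_dataset(matrix(c(1L, 1L, 0L, 2L), ncol = 1),
                         phenotype = c(1L, 0L, 1L, 0L))
  cc <- count_contingency(ds, 1L)
  expect_equal(cc$q, 3L)
  expect_equal(unname(cc$n), matrix(c(1L, 1L, 0L, 0L, 1L, 1L), ncol = 2))

  ds2 <- genotype_dataset(matrix(0L, 5, 2), phenotype = c(1L, 1L, 1L, 0L, 0L))
  cc0 <- count_contingency(ds2, integer(0))
  expect_equal(cc0$q, 1L)
  expect_equal(unname(cc0$n), matrix(c(3L, 2L), nrow = 1))

  for (seed in 1:5) {
    ds3 <- make_toy_fixture(37, 4, seed = seed)
    cc3 <- count_contingency(ds3, c(2L, 4L))
    expect_equal(sum(cc3$n), 37L)
    expect_equal(cc3$q, 9L)
  }
  expect_error(count_contingency(ds3, c(1L, 1L)), "duplicate")
  expect_error(count_contingency(ds3, 9L), "range")
})

test_that("degenerate scores have their closed-form values", {
  ds <- genotype_dataset(matrix(integer(0), 0, 1), phenotype = integer(0))
  cc <- count_contingency(ds, integer(0))
  expect_equal(bdeu_local_log_score(cc, cfg4), 0)
  expect_equal(bdeu_expansion_log_bound(cc, 1, cfg4), 0)

  # one case, empty pattern, alpha = 2: marginal likelihood is
  # a_jk / a_j = 1/2
  ds1 <- genotype_dataset(matrix(0L, 1, 1), phenotype = 1L)
  cc1 <- count_contingency(ds1, integer(0))
  expect_equal(bdeu_local_log_score(cc1, score_config(2)), log(1 / 2))
})

test_that("log-space score matches the direct gamma-ratio product oracle", {
  ds <- make_toy_fixture(20, 4, seed = 7)
  for (pattern in list(integer(0), 1L, 3L, c(1L, 2L), c(2L, 4L), c(1L, 3L, 4L))) {
    cc <- count_contingency(ds, pattern)
    expect_equal(bdeu_local_log_score(cc, cfg4),
                 oracle_bdeu_log_score(cc$n, cc$q, 4), tolerance = 1e-10)
  }
  # and for a non-default alpha
  cc <- count_contingency(ds, c(1L, 4L))
  expect_equal(bdeu_local_log_score(cc, score_config(1.5)),
               oracle_bdeu_log_score(cc$n, cc$q, 1.5), tolerance = 1e-10)
})

test_that("score and bound are invariant to the order of SNPs in a pattern", {
  ds <- make_toy_fixture(40, 5, seed = 2)
  for (perm in list(c(1L, 3L, 5L), c(5L, 1L, 3L), c(3L, 5L, 1L))) {
    cc <- count_contingency(ds, perm)
    expect_equal(bdeu_local_log_score(cc, cfg4),
                 bdeu_local_log_score(count_contingency(ds, c(1L, 3L, 5L)), cfg4))
    expect_equal(bdeu_expansion_log_bound(cc, 1, cfg4),
                 bdeu_expansion_log_bound(count_contingency(ds, c(1L, 3L, 5L)),
                                          1, cfg4))
  }
})

test_that("the expansion bound dominates every actual expansion (toy exhaustive)", {
  ds <- make_toy_fixture(30, 5, seed = 3)
  expect_gte(oracle_dominance_margin(ds, base_size = 1, m = 1, cfg4), 0)
  expect_gte(oracle_dominance_margin(ds, base_size = 0, m = 1, cfg4), 0)
  expect_gte(oracle_dominance_margin(ds, base_size = 2, m = 1, cfg4), 0)
})

test_that("the bound depends on m only through the refined hyperparameters", {
  ds <- make_toy_fixture(30, 3, seed = 5)
  cc <- count_contingency(ds, 1L)
  b1 <- bdeu_expansion_log_bound(cc, 1, cfg4)
  b2 <- bdeu_expansion_log_bound(cc, 2, cfg4)
  expect_false(isTRUE(all.equal(b1, b2)))
  # the bound is a function of q' = q * 3^m and the counts alone, so adding
  # two SNPs to a 1-SNP pattern equals adding one SNP at a 3x-refined base q
  cc3 <- cc
  cc3$q <- cc$q * 3L
  expect_equal(bdeu_expansion_log_bound(cc3, 1, cfg4), b2, tolerance = 1e-12)
  expect_error(bdeu_expansion_log_bound(cc, 0, cfg4), "m must be")
})

test_that("evaluate_pattern bundles score and bounds deterministically", {
  ds <- make_toy_fixture(30, 5, seed = 3)
  ev <- evaluate_pattern(ds, c(2L, 4L), m_list = c(1, 2), cfg4)
  ev2 <- evaluate_pattern(ds, c(2L, 4L), m_list = c(1, 2), cfg4)
  expect_identical(ev, ev2)
  expect_true(is.finite(ev$log_score))
  expect_named(ev$log_bound, c("1", "2"))
  # empty pattern with m = 1 bounds all 1-SNP scores
  b0 <- evaluate_pattern(ds, integer(0), m_list = 1, cfg4)$log_bound[["1"]]
  for (j in 1:5)
    expect_gte(b0, evaluate_pattern(ds, j, cfg = cfg4)$log_score)
})

test_that("alpha must be positive and configurable", {
  expect_error(score_config(0), "alpha")
  expect_error(score_config(-1), "alpha")
  ds <- make_toy_fixture(20, 2, seed = 1)
  cc <- count_contingency(ds, 1L)
  expect_false(isTRUE(all.equal(bdeu_local_log_score(cc, score_config(1)),
                                bdeu_local_log_score(cc, score_config(8)))))
})
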