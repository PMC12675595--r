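test_that("generator is deterministic and validates its configuration", {
  cfg <- synthetic_config(n_drugs = 20L, n_targets = 10L, n_pairs = 60L,
                          seed = 7L)
  d1 <- generate_synthetic(cfg)
  d2 <- generate_synthetic(cfg)
  expect_identical(d1$records, d2$records)
  expect_equal(n_records(d1), 60L)
  # no duplicate pairs
  expect_false(anyDuplicated(paste(d1$records$drug_id, d1$records$target_id)) > 0)

  expect_error(synthetic_config(n_drugs = 5L, n_targets = 5L, n_pairs = 100L),
               "exceeds")
  expect_error(synthetic_config(n_pairs = 10L, n_drugs = 50L, n_targets = 5L),
               "n_pairs")
  expect_error(synthetic_config(target_bias = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(extreme_eps = 0.6), "extreme_eps")
})

test_that("extreme target bias drives the target tendency to its analytic value", {
  # with target propensities at eps / 1 - eps and mid-range drug propensities
  # (mean 0.5), the label mixture gives E[z_t] = (0.5 + theta_t) / 2, hence
  # Z = 0.5 + (0.5 - eps) / 2; checked against that closed form
  eps <- 0.01
  cfg <- synthetic_config(n_drugs = 60L, n_targets = 25L, n_pairs = 1200L,
                          target_bias = 1, drug_bias = 0,
                          mechanism_weight = 0, extreme_eps = eps, seed = 3L)
  d <- generate_synthetic(cfg)
  z_target <- overall_tendency(sequence_tendency(d, "target"))
  expect_lt(abs(z_target - (0.5 + (0.5 - eps) / 2)), 0.03)
  expect_lte(z_target, 1)
})

test_that("target-biased generation puts more prior tendency on targets than drugs", {
  for (seed in 1:20) {
    d <- generate_synthetic(synthetic_config(
      n_drugs = 40L, n_targets = 15L, n_pairs = 300L, target_bias = 1,
      drug_bias = 0, mechanism_weight = 0, seed = seed))
    z_t <- overall_tendency(sequence_tendency(d, "target"))
    z_d <- overall_tendency(sequence_tendency(d, "drug"))
    expect_gt(z_t, z_d)
  }
})
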