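test_that("per-sequence tendency is the exact positive fraction", {
  d <- hand_dataset()
  tt <- sequence_tendency(d, "target")
  expect_equal(tt$M, 2L)
  e <- tt$entries[order(tt$entries$id), ]
  # MKT: labels 1,1,0 -> 2/3; ACD: labels 1,0,0 -> 1/3 (ids in first-seen order)
  expect_equal(sort(e$z), c(1 / 3, 2 / 3))
  expect_equal(e$n, c(3L, 3L))

  td <- sequence_tendency(d, "drug")
  expect_equal(sort(td$entries$z), c(0, 0.5, 1))

  one <- dti_dataset("CCO", "MKT", 1)
  t1 <- sequence_tendency(one, "target")
  expect_equal(t1$entries$z, 1)
  expect_equal(t1$entries$n, 1L)
})

test_that("overall tendency Z is the normalized mean deviation with range [0.5, 1]", {
  mk_table <- function(z, n = rep(2L, length(z))) {
    structure(list(axis = "target",
                   entries = data.frame(id = as.character(seq_along(z)),
                                        n = n, z = z),
                   M = length(z)),
              class = "tendency_table")
  }
  expect_equal(overall_tendency(mk_table(c(0.5, 0.5, 0.5))), 0.5)
  expect_equal(overall_tendency(mk_table(c(0, 1, 1, 0))), 1.0)
  expect_equal(overall_tendency(mk_table(c(0.75, 0.25))), 0.75)
  # occurrence-weighted variant
  expect_equal(overall_tendency(mk_table(c(1, 0.5), n = c(3L, 1L)),
                                weighted = TRUE), 0.5 + 3 / 4 * 0.5)
  # invariance to relabeling positive <-> negative
  z <- c(0.1, 0.4, 0.9, 0.65)
  expect_equal(overall_tendency(mk_table(z)), overall_tendency(mk_table(1 - z)))
})

test_that("global proportion and deviation statistic match hand values", {
  d <- hand_dataset()
  expect_equal(global_proportion(d), 0.5)

  mk_table <- function(z, n) {
    structure(list(axis = "drug",
                   entries = data.frame(id = as.character(seq_along(z)),
                                        n = n, z = z), M = length(z)),
              class = "tendency_table")
  }
  # two sequences, n = 2 each, z = 1 and 0, g = 0.5 -> T = 1
  expect_equal(deviation_statistic(mk_table(c(1, 0), c(2L, 2L)), 0.5), 1.0)
  # single sequence n = 4, z = 0.75, g = 0.5 -> T = 0.25
  expect_equal(deviation_statistic(mk_table(0.75, 4L), 0.5), 0.25)
  # null identity: all z_i = g gives exactly zero
  expect_equal(deviation_statistic(mk_table(c(0.3, 0.3), c(5L, 7L)), 0.3), 0)
})

test_that("permutation test obeys its p-value contract", {
  # a target axis so extreme that no permutation matches the observed T
  d <- generate_synthetic(synthetic_config(
    n_drugs = 40L, n_targets = 10L, n_pairs = 400L, target_bias = 1,
    drug_bias = 0, mechanism_weight = 0, extreme_eps = 0.01, seed = 2L))
  pt <- permutation_test(d, "target", B = 200L, seed = 5L)
  expect_equal(pt$p_value, 1 / 201)
  expect_length(pt$permuted_T, 200L)
  expect_gte(pt$p_value, 1 / (1 + pt$B))

  # degenerate: all labels equal -> every permutation reproduces T_obs
  ones <- dti_dataset(sprintf("C%sO", strrep("C", 1:6)),
                      rep(c("MKT", "ACD", "WYH"), 2L), rep(1, 6))
  p1 <- permutation_test(ones, "target", B = 50L, seed = 1L)
  expect_equal(p1$p_value, 1)
  expect_true(all(p1$permuted_T == p1$T_obs))

  # determinism and monotonicity in T_obs for fixed draws
  p2 <- permutation_test(d, "target", B = 200L, seed = 5L)
  expect_identical(pt$permuted_T, p2$permuted_T)
  expect_error(permutation_test(d, "target", B = 0L), "positive")
})

test_that("bias report aggregates both axes with conserved histograms", {
  d <- tiny_dataset(60L, seed = 4L)
  br <- bias_report(d, B = 50L, seed = 1L)
  for (axis in c("drug", "target")) {
    a <- br[[axis]]
    expect_equal(sum(unlist(a$histogram)), a$M)
    expect_gte(a$Z, 0.5)
    expect_lte(a$Z, 1)
    expect_gte(a$p_value, 1 / 51)
  }
  json <- write_bias_report(br)
  parsed <- jsonlite::fromJSON(json)
  expect_equal(parsed$target$M, br$target$M)
})
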