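test_that("drug-biased construction yields a 50% split with extreme drug priors", {
  d <- generate_synthetic(synthetic_config(
    n_drugs = 40L, n_targets = 15L, n_pairs = 250L, seed = 8L))
  out <- build_drug_biased_split(d, seed = 3L)
  expect_equal(mean(out$records$label), 0.5)
  # every target perfectly balanced, every drug all-positive or all-negative
  zt <- sequence_tendency(out, "target")$entries$z
  zd <- sequence_tendency(out, "drug")$entries$z
  expect_true(all(zt == 0.5))
  expect_true(all(zd %in% c(0, 1)))
  expect_equal(overall_tendency(sequence_tendency(out, "target")), 0.5)
  expect_equal(overall_tendency(sequence_tendency(out, "drug")), 1.0)
  # no emitted negative duplicates a positive pair of the input
  pos_in <- with(d$records[d$records$label == 1L, ],
                 paste(drug_id, target_id))
  neg_out <- with(out$records[out$records$label == 0L, ],
                  paste(drug_id, target_id))
  expect_length(intersect(pos_in, neg_out), 0L)
})

test_that("drug-biased construction handles the minimal and degenerate inputs", {
  # one positive pair plus one spare drug -> exactly 2 records
  d <- dti_dataset(c("CCO", "CCN"), c("MKT", "ACD"), c(1, 0))
  out <- build_drug_biased_split(d, seed = 1L)
  expect_equal(n_records(out), 2L)
  expect_equal(sort(out$records$label), c(0L, 1L))

  # no positives at all
  neg <- dti_dataset(c("CCO", "CCN"), c("MKT", "ACD"), c(0, 0))
  expect_error(build_drug_biased_split(neg, seed = 1L), "no positive")
})

test_that("balanced construction balances every single drug and target", {
  d <- generate_synthetic(synthetic_config(
    n_drugs = 40L, n_targets = 15L, n_pairs = 250L, seed = 9L))
  out <- build_balanced_split(d, seed = 2L)
  expect_equal(mean(out$records$label), 0.5)
  expect_true(all(sequence_tendency(out, "drug")$entries$z == 0.5))
  expect_true(all(sequence_tendency(out, "target")$entries$z == 0.5))
  expect_equal(overall_tendency(sequence_tendency(out, "drug")), 0.5)
  expect_equal(overall_tendency(sequence_tendency(out, "target")), 0.5)
  # output size is twice the unique-entity positive set
  expect_equal(n_records(out) %% 2L, 0L)
  # derangement: no negative recreates a positive pair of the input
  pos_in <- with(d$records[d$records$label == 1L, ], paste(drug_id, target_id))
  neg_out <- with(out$records[out$records$label == 0L, ],
                  paste(drug_id, target_id))
  expect_length(intersect(pos_in, neg_out), 0L)

  single <- dti_dataset(c("CCO", "CCN"), c("MKT", "ACD"), c(1, 0))
  expect_error(build_balanced_split(single, seed = 1L), "derangement")
})
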