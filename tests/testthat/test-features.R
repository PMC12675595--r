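test_that("toy embedder is deterministic with local context only", {
  prov <- toy_target_embedder(d_e = 8L, context = 1L)
  m1 <- provide_target_features(prov, "MKTAYIAKQR")
  m2 <- provide_target_features(prov, "MKTAYIAKQR")
  expect_identical(m1$features, m2$features)
  expect_true(m1$special_mask[1L])
  expect_equal(nrow(m1$features), 11L)  # [cls] + residues

  # a provider built later gives the same table (session-independent)
  m3 <- provide_target_features(toy_target_embedder(d_e = 8L), "MKTAYIAKQR")
  expect_identical(m1$features, m3$features)

  # a single substitution changes only a window of 2*context + 1 rows
  alt <- provide_target_features(prov, "MKTAWIAKQR")
  differs <- which(rowSums(m1$features != alt$features) > 0)
  expect_true(all(differs %in% 5:7))  # residues 4..6, offset +1 for [cls]
  expect_lte(length(differs), 3L)

  expect_error(provide_target_features(prov, "MKB"), "unknown residue")
})

test_that("feature store round trips matrices exactly and names misses", {
  dir <- withr::local_tempdir()
  store <- feature_store(dir)
  prov <- toy_target_embedder(d_e = 6L)
  seq <- "MKTAYIAKQRTWYF"
  m <- provide_target_features(prov, seq)
  store_save(store, seq, m)
  got <- provide_target_features(store, seq)
  expect_equal(unname(got$features), unname(m$features), tolerance = 0)
  expect_identical(got$special_mask, m$special_mask)
  expect_identical(got$residue_types, m$residue_types)

  expect_error(provide_target_features(store, "ACDEFACDEF"),
               "store miss for sequence hash")
})
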