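test_that("amino-acid dictionary entries are per-letter feature means", {
  v <- rnorm(4)
  mA <- residue_feature_matrix(rbind(v, v), rep(FALSE, 2), c("A", "A"))
  u <- rnorm(4)
  w <- rnorm(4)
  mC <- residue_feature_matrix(rbind(u, w), rep(FALSE, 2), c("C", "C"))
  others <- lapply(setdiff(AA_LETTERS, c("A", "C")), function(l) {
    residue_feature_matrix(matrix(rnorm(4), 1L), FALSE, l)
  })
  dict <- build_amino_acid_dictionary(c(list(mA, mC), others))
  expect_equal(unname(dict["A", ]), v)
  expect_equal(unname(dict["C", ]), (u + w) / 2)

  # a missing letter is an error listing the absent letters
  expect_error(build_amino_acid_dictionary(c(list(mA), others)), "C")
})

test_that("residue deletion keeps the rounded survivor count in order", {
  set.seed(1)
  m <- rand_rfm(11L)  # [cls] + 10 residues
  out <- random_residue_deletion(m, 0.7)
  expect_equal(nrow(out$features), 4L)  # cls + round(0.3 * 10)
  expect_true(out$special_mask[1L])
  # original order preserved: surviving rows appear in the input in order
  surv <- out$features[-1L, , drop = FALSE]
  pos <- apply(surv, 1L, function(r) {
    which(apply(m$features, 1L, function(x) all(x == r)))
  })
  expect_true(all(diff(pos) > 0))

  # ratio 0 is the identity on the residue set
  expect_equal(random_residue_deletion(m, 0)$features, m$features)
  only_cls <- residue_feature_matrix(matrix(0, 1L, 4L), TRUE)
  expect_error(random_residue_deletion(only_cls, 0.5), "non-special")
})

test_that("deletion removes the configured fraction on average", {
  set.seed(7)
  deleted <- replicate(200L, {
    m <- rand_rfm(201L, d = 4L)
    out <- random_residue_deletion(m, 0.7)
    1 - (nrow(out$features) - 1L) / 200L
  })
  expect_lt(abs(mean(deleted) - 0.7), 0.01)
})

test_that("feature mutation replaces positions at the configured rate", {
  dict <- full_aa_dictionary(d = 4L)
  set.seed(11)
  m <- rand_rfm(41L, d = 4L)
  expect_equal(residue_feature_mutation(m, 0, dict)$features, m$features)

  vdict <- structure(matrix(rnorm(4), 1L, 4L, dimnames = list("A", NULL)),
                     class = "aa_dictionary")
  all_mut <- residue_feature_mutation(m, 1, vdict)
  expect_true(all(apply(all_mut$features[-1L, ], 1L,
                        function(r) all(r == vdict[1L, ]))))
  expect_equal(all_mut$features[1L, ], m$features[1L, ])  # [cls] untouched

  changed <- 0L
  total <- 0L
  for (i in 1:50) {
    mi <- rand_rfm(401L, d = 4L)
    out <- residue_feature_mutation(mi, 0.2, dict)
    changed <- changed + sum(rowSums(out$features != mi$features) > 0)
    total <- total + 400L
  }
  expect_lt(abs(changed / total - 0.2), 0.005)

  expect_error(residue_feature_mutation(m, 0.2, NULL), "dictionary")
})

test_that("mlm corruption follows the 15/80/10/10 trichotomy", {
  v <- tiny_vocab()
  set.seed(3)
  ids <- c(v$cls_id, sample(which(!v$special), 119L, replace = TRUE))
  out0 <- mlm_corrupt(ids, v, select_rate = 0)
  expect_identical(out0$ids, ids)
  expect_false(any(out0$mask))

  sel_n <- 0L
  masked_n <- 0L
  kept_n <- 0L
  changed_off_mask <- 0L
  for (i in 1:400) {
    out <- mlm_corrupt(ids, v)
    expect_false(out$mask[1L])  # [cls] never selected
    sel_n <- sel_n + sum(out$mask)
    masked_n <- masked_n + sum(out$ids[out$mask] == v$mask_id)
    kept_n <- kept_n + sum(out$ids[out$mask] == ids[out$mask])
    changed_off_mask <- changed_off_mask + sum(out$ids[!out$mask] != ids[!out$mask])
  }
  expect_equal(changed_off_mask, 0L)  # unselected positions untouched
  expect_lt(abs(sel_n / (400 * 119) - 0.15), 0.005)
  expect_lt(abs(masked_n / sel_n - 0.8), 0.01)
  expect_lt(abs(kept_n / sel_n - 0.1), 0.015)
  expect_error(mlm_corrupt(ids, v, mask_frac = 0.5, keep_frac = 0.1,
                           random_frac = 0.1), "sum to 1")
})

test_that("tokenizer splits multi-character tokens and flags unknowns", {
  expect_equal(smiles_tokenize("CC(=O)Cl"),
               c("C", "C", "(", "=", "O", ")", "Cl"))
  expect_equal(smiles_tokenize("[nH]c1Br"), c("[nH]", "c", "1", "Br"))
  v <- tiny_vocab()
  ids <- smiles_encode("CCO", v)
  expect_equal(ids[1L], v$cls_id)
  expect_length(ids, 4L)
  expect_error(smiles_encode("CCI", v), "out-of-vocabulary")
})
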