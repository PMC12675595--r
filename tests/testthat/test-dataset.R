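test_that("dataset construction validates records", {
  d <- dti_dataset(c("CCO", "CCN", "CCO"), c("MKT", "MKT", "ACD"), c(1, 0, 1))
  expect_s3_class(d, "dti_dataset")
  expect_equal(n_records(d), 3L)
  expect_equal(sum(d$records$label), 2L)
  # first-seen id assignment
  expect_equal(d$records$drug_id[1L], d$records$drug_id[3L])
  expect_length(d$drug_index, 2L)

  expect_error(dti_dataset("CCO", "MK2T", 1), "amino-acid alphabet")
  expect_error(dti_dataset("CCO", "MKT", 2), "non-binary")
  expect_error(dti_dataset(character(0), character(0), numeric(0)),
               "at least one record")
  expect_error(dti_dataset(c("C", "C"), c("MK", "MK"), c(1, 0)), "duplicate")
  expect_silent(dti_dataset(c("C", "C"), c("MK", "MK"), c(1, 0),
                            allow_duplicates = TRUE))
})

test_that("read/write round trip preserves records", {
  d <- tiny_dataset(10L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interactions(d, path)
  d2 <- read_interactions(path)
  expect_equal(d2$records, d$records)

  # default DrugBAN-style header
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES,Protein,Y", "CCO,MKT,1", "CCN,MKT,0", "CCS,ACD,1"),
             path2)
  d3 <- read_interactions(path2)
  expect_equal(n_records(d3), 3L)
  expect_equal(sum(d3$records$label), 2L)

  # non-binary label names the row
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES,Protein,Y", "CCO,MKT,1", "CCN,MKT,2"), path3)
  expect_error(read_interactions(path3), "row 2")

  # missing column is a format error naming the column
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES,Sequence,Y", "CCO,MKT,1"), path4)
  expect_error(read_interactions(path4), "Protein")

  expect_error(write_interactions(d, file.path(tempdir(), "no/such/dir/x.csv")),
               "cannot write")
})

test_that("random_split gives floored shares with remainder to train", {
  d <- tiny_dataset(100L, seed = 3L)
  sp <- random_split(d, c(7, 1, 2), seed = 9L)
  expect_equal(n_records(sp$train), 70L)
  expect_equal(n_records(sp$valid), 10L)
  expect_equal(n_records(sp$test), 20L)
  # partition: union of outputs equals input
  key <- function(x) sort(paste(x$records$drug_id, x$records$target_id))
  expect_equal(sort(c(key(sp$train), key(sp$valid), key(sp$test))), key(d))
  # determinism
  sp2 <- random_split(d, c(7, 1, 2), seed = 9L)
  expect_identical(sp$train$records, sp2$train$records)
  # zero ratios need the explicit flag
  expect_error(random_split(d, c(1, 0, 0), seed = 1L), "allow_empty")
  sp3 <- random_split(d, c(1, 0, 0), seed = 1L, allow_empty = TRUE)
  expect_equal(n_records(sp3$train), 100L)
  expect_null(sp3$valid)
  small <- dti_dataset(c("CCO", "CCN"), c("MKT", "ACD"), c(1, 0))
  expect_error(random_split(small, c(7, 1, 2), seed = 1L), "too small")
})

test_that("cross_domain_split yields entity-disjoint domains", {
  d <- tiny_dataset(200L, seed = 5L)
  cd <- cross_domain_split(d, 0.6, seed = 2L)
  expect_length(intersect(names(cd$source_train$drug_index),
                          names(cd$target_test$drug_index)), 0L)
  expect_length(intersect(names(cd$source_train$target_index),
                          names(cd$target_test$target_index)), 0L)
  expect_lte(n_records(cd$source_train) + n_records(cd$target_test), 200L)
  expect_error(cross_domain_split(d, 1, seed = 1L), "empty")
})
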