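#' Construct a drug-target interaction dataset
#'
#' A `dti_dataset` holds one record per (drug, target) pair: the drug's SMILES
#' string, the target's amino-acid sequence, and a binary interaction label,
#' together with per-drug and per-target indices into the record table.
#'
#' @param smiles character vector of SMILES strings (non-empty).
#' @param sequence character vector of amino-acid sequences over the 20-letter
#'   alphabet (X allowed for unknown residues).
#' @param label integer/numeric vector of binary labels in `{0, 1}`.
#' @param drug_id,target_id optional identifier vectors; when absent, ids are
#'   assigned in first-seen order of the distinct SMILES / sequences.
#' @param allow_duplicates keep duplicate `(drug, target, label)` triples and
#'   conflicting labels for the same pair instead of rejecting them.
#' @return an object of class `dti_dataset`.
#' @export
dti_dataset <- function(smiles, sequence, label,
                        drug_id = NULL, target_id = NULL,
                        allow_duplicates = FALSE) {
  n <- length(smiles)
  if (length(sequence) != n || length(label) != n) {
    stop_format("smiles, sequence and label must have equal length")
  }
  if (n == 0L) stop_format("a dti_dataset must contain at least one record")
  smiles <- as.character(smiles)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(smiles))) stop_format("empty SMILES string in records")
  if (any(!nzchar(sequence))) stop_format("empty target sequence in records")
  bad_seq <- grepl(sprintf("[^%s]", paste(AA21, collapse = "")), sequence)
  if (any(bad_seq)) {
    stop_format("sequence contains letters outside the amino-acid alphabet at record %d",
                which(bad_seq)[1L])
  }
  lab <- suppressWarnings(as.numeric(label))
  bad <- is.na(lab) | !(lab %in% c(0, 1))
  if (any(bad)) {
    stop_format("non-binary label %s at record %d",
                deparse(as.character(label[which(bad)[1L]])), which(bad)[1L])
  }
  if (is.null(drug_id)) {
    drug_id <- sprintf("D%04d", match(smiles, unique(smiles)))
  }
  if (is.null(target_id)) {
    target_id <- sprintf("T%04d", match(sequence, unique(sequence)))
  }
  records <- data.frame(
    drug_id = as.character(drug_id),
    smiles = smiles,
    target_id = as.character(target_id),
    sequence = sequence,
    label = as.integer(lab),
    stringsAsFactors = FALSE
  )
  if (!allow_duplicates) {
    pair <- paste(records$drug_id, records$target_id, sep = "\r")
    if (anyDuplicated(pair)) {
      first <- which(duplicated(pair))[1L]
      stop_format("duplicate (drug, target) pair at record %d; set allow_duplicates = TRUE to keep",
                  first)
    }
  }
  structure(
    list(
      records = records,
      drug_index = split(seq_len(n), records$drug_id),
      target_index = split(seq_len(n), records$target_id)
    ),
    class = "dti_dataset"
  )
}

#' @export
print.dti_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("dti_dataset: %d pairs, %d drugs, %d targets, %.1f%% positive\n",
              nrow(r), length(x$drug_index), length(x$target_index),
              100 * mean(r$label)))
  invisible(x)
}

#' @export
summary.dti_dataset <- function(object, ...) {
  r <- object$records
  out <- list(
    n_pairs = nrow(r),
    n_drugs = length(object$drug_index),
    n_targets = length(object$target_index),
    positive_fraction = mean(r$label)
  )
  class(out) <- "summary.dti_dataset"
  out
}

#' @export
print.summary.dti_dataset <- function(x, ...) {
  cat(sprintf("pairs: %d\ndrugs: %d\ntargets: %d\npositive fraction: %.4f\n",
              x$n_pairs, x$n_drugs, x$n_targets, x$positive_fraction))
  invisible(x)
}

#' Number of records in a dataset
#' @param dataset a `dti_dataset`.
#' @return integer record count.
#' @export
n_records <- function(dataset) {
  stopifnot(inherits(dataset, "dti_dataset"))
  nrow(dataset$records)
}

# subset a dataset by record positions, keeping ids
dataset_subset <- function(dataset, idx, allow_duplicates = TRUE) {
  r <- dataset$records[idx, , drop = FALSE]
  if (nrow(r) == 0L) stop_format("subset would produce an empty dataset")
  dti_dataset(r$smiles, r$sequence, r$label,
              drug_id = r$drug_id, target_id = r$target_id,
              allow_duplicates = allow_duplicates)
}

#' Read a DTI interaction table from delimited text
#'
#' Expects a CSV with columns for SMILES, target sequence and binary label.
#' The default dialect is the `SMILES,Protein,Y` layout used by the public
#' DTI benchmark releases; arbitrary headers are supported through `col_map`.
#' Optional `DrugID`/`TargetID` columns are honoured when present.
#'
#' @param path path to a CSV file with a header row.
#' @param col_map named list mapping the roles `smiles`, `sequence`, `label`
#'   (optionally `drug_id`, `target_id`) to column names in the file.
#' @param allow_duplicates passed to [dti_dataset()].
#' @return a [dti_dataset()].
#' @export
read_interactions <- function(path, col_map = NULL, allow_duplicates = FALSE) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(col_map)) {
    col_map <- list(smiles = "SMILES", sequence = "Protein", label = "Y")
    if ("DrugID" %in% names(df)) col_map$drug_id <- "DrugID"
    if ("TargetID" %in% names(df)) col_map$target_id <- "TargetID"
  }
  for (role in c("smiles", "sequence", "label")) {
    col <- col_map[[role]]
    if (is.null(col) || !(col %in% names(df))) {
      stop_format("missing column for %s (expected '%s') in %s",
                  role, if (is.null(col)) "?" else col, path)
    }
  }
  lab_raw <- df[[col_map$label]]
  lab <- suppressWarnings(as.numeric(lab_raw))
  bad <- is.na(lab) | !(lab %in% c(0, 1))
  if (any(bad)) {
    stop_format("non-binary label '%s' at row %d of %s",
                as.character(lab_raw[which(bad)[1L]]), which(bad)[1L], path)
  }
  dti_dataset(
    smiles = df[[col_map$smiles]],
    sequence = df[[col_map$sequence]],
    label = lab,
    drug_id = if (!is.null(col_map$drug_id)) df[[col_map$drug_id]] else NULL,
    target_id = if (!is.null(col_map$target_id)) df[[col_map$target_id]] else NULL,
    allow_duplicates = allow_duplicates
  )
}

#' Write a DTI dataset to delimited text
#'
#' Emits the `SMILES,Protein,Y` layout plus `DrugID`/`TargetID` columns so a
#' round trip through [read_interactions()] reproduces the records exactly.
#'
#' @param dataset a `dti_dataset`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_interactions <- function(dataset, path) {
  stopifnot(inherits(dataset, "dti_dataset"))
  if (nrow(dataset$records) == 0L) stop_format("refusing to write an empty dataset")
  r <- dataset$records
  out <- data.frame(SMILES = r$smiles, Protein = r$sequence, Y = r$label,
                    DrugID = r$drug_id, TargetID = r$target_id,
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_format("cannot write to %s", path)
  invisible(path)
}

#' Random train/validation/test split
#'
#' Partitions the records into three sets by a seeded shuffle. Validation and
#' test sizes are the floored ratio shares; the remainder goes to training,
#' so 100 records at ratios 7:1:2 give sizes 70/10/20.
#'
#' @param dataset a `dti_dataset`.
#' @param ratios positive reals for train/valid/test; normalized internally.
#' @param seed integer seed making the partition deterministic.
#' @param allow_empty allow zero ratios (producing empty splits).
#' @return list with elements `train`, `valid`, `test`.
#' @export
random_split <- function(dataset, ratios = c(7, 1, 2), seed = 1L,
                         allow_empty = FALSE) {
  stopifnot(inherits(dataset, "dti_dataset"), length(ratios) == 3L)
  if (any(ratios < 0)) stop_format("ratios must be nonnegative")
  if (any(ratios == 0) && !allow_empty) {
    stop_format("zero ratios produce empty splits; set allow_empty = TRUE if intended")
  }
  n <- nrow(dataset$records)
  if (n < 3L) stop_format("dataset too small to split (need >= 3 records)")
  ratios <- ratios / sum(ratios)
  n_valid <- floor(ratios[2L] * n)
  n_test <- floor(ratios[3L] * n)
  perm <- with_seed(seed, sample.int(n))
  idx_train <- perm[seq_len(n - n_valid - n_test)]
  idx_valid <- perm[n - n_valid - n_test + seq_len(n_valid)]
  idx_test <- perm[n - n_test + seq_len(n_test)]
  mk <- function(idx) if (length(idx)) dataset_subset(dataset, idx) else NULL
  list(train = mk(idx_train), valid = mk(idx_valid), test = mk(idx_test))
}

#' Entity-disjoint source/target split
#'
#' Partitions drugs and targets into disjoint source and target pools, keeps
#' source-train pairs whose drug and target are both in the source pools and
#' target-test pairs with both entities in the target pools; straddling pairs
#' are dropped. Mirrors cross-domain evaluation where source and target
#' domains share no drugs or targets.
#'
#' @param dataset a `dti_dataset` with at least 2 drugs and 2 targets.
#' @param fraction_source fraction of drugs and of targets assigned to the
#'   source pool, in (0, 1).
#' @param seed integer seed.
#' @return list with elements `source_train` and `target_test`.
#' @export
cross_domain_split <- function(dataset, fraction_source = 0.6, seed = 1L) {
  stopifnot(inherits(dataset, "dti_dataset"))
  drugs <- names(dataset$drug_index)
  targets <- names(dataset$target_index)
  if (length(drugs) < 2L || length(targets) < 2L) {
    stop_format("cross-domain split needs >= 2 drugs and >= 2 targets")
  }
  n_sd <- round(fraction_source * length(drugs))
  n_st <- round(fraction_source * length(targets))
  if (n_sd < 1L || n_sd >= length(drugs) || n_st < 1L || n_st >= length(targets)) {
    stop_format("fraction_source = %.2f leaves an empty source or target pool; choose a different fraction or seed",
                fraction_source)
  }
  pools <- with_seed(seed, {
    list(sd = sample(drugs, n_sd), st = sample(targets, n_st))
  })
  r <- dataset$records
  in_src <- r$drug_id %in% pools$sd & r$target_id %in% pools$st
  in_tgt <- !(r$drug_id %in% pools$sd) & !(r$target_id %in% pools$st)
  if (!any(in_src) || !any(in_tgt)) {
    stop_format("a pool is empty after partition; choose a different fraction or seed")
  }
  list(source_train = dataset_subset(dataset, which(in_src)),
       target_test = dataset_subset(dataset, which(in_tgt)))
}
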