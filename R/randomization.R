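#' Amino-acid feature dictionary
#'
#' One feature vector per residue letter, each the elementwise mean of that
#' letter's per-position features over a training collection (special
#' positions excluded). Used as the replacement pool for residue feature
#' mutation.
#'
#' @param training_features list of [residue_feature_matrix()] objects with
#'   `residue_types` set.
#' @return an `aa_dictionary`: a `20 x D_e` matrix with residue-letter
#'   rownames.
#' @export
build_amino_acid_dictionary <- function(training_features) {
  stopifnot(length(training_features) > 0L)
  sums <- NULL
  counts <- stats::setNames(numeric(length(AA20)), AA20)
  for (m in training_features) {
    stopifnot(inherits(m, "residue_feature_matrix"))
    if (is.null(m$residue_types)) {
      stop_format("training features must carry residue_types")
    }
    if (is.null(sums)) {
      sums <- matrix(0, length(AA20), ncol(m$features),
                     dimnames = list(AA20, NULL))
    }
    keep <- !m$special_mask & m$residue_types %in% AA20
    if (!any(keep)) next
    grp <- m$residue_types[keep]
    agg <- rowsum(m$features[keep, , drop = FALSE], grp)
    sums[rownames(agg), ] <- sums[rownames(agg), , drop = FALSE] + agg
    cnt <- table(grp)
    counts[names(cnt)] <- counts[names(cnt)] + as.numeric(cnt)
  }
  absent <- AA20[counts == 0]
  if (length(absent)) {
    stop_format("residue letters absent from the training features: %s",
                paste(absent, collapse = ", "))
  }
  structure(sums / counts, class = "aa_dictionary")
}

#' Random residue deletion
#'
#' Deletes a fixed proportion of the non-special residue positions,
#' keeping `round((1 - deletion_ratio) * L_res)` residues (at least one) in
#' their original order; `[cls]` and other special positions are always
#' kept. The default ratio of 0.7 removes 70 percent of the residues. The
#' `"bernoulli"` mode instead keeps each residue independently with
#' probability `1 - deletion_ratio`.
#'
#' @param matrix a [residue_feature_matrix()].
#' @param deletion_ratio fraction of residues to delete, in `[0, 1)`.
#' @param mode `"fixed"` (deterministic count, default) or `"bernoulli"`.
#' @return a [residue_feature_matrix()] with the surviving rows.
#' @export
random_residue_deletion <- function(matrix, deletion_ratio = 0.7,
                                    mode = c("fixed", "bernoulli")) {
  stopifnot(inherits(matrix, "residue_feature_matrix"))
  mode <- match.arg(mode)
  if (deletion_ratio < 0 || deletion_ratio >= 1) {
    stop_format("deletion_ratio must lie in [0, 1)")
  }
  res <- which(!matrix$special_mask)
  if (length(res) == 0L) stop_format("matrix has no non-special positions")
  if (mode == "fixed") {
    n_keep <- max(1L, round((1 - deletion_ratio) * length(res)))
    kept <- if (n_keep >= length(res)) res else sort(sample(res, n_keep))
  } else {
    kept <- res[runif(length(res)) >= deletion_ratio]
    if (length(kept) == 0L) kept <- res[sample.int(length(res), 1L)]
    kept <- sort(kept)
  }
  idx <- sort(c(which(matrix$special_mask), kept))
  residue_feature_matrix(
    features = matrix$features[idx, , drop = FALSE],
    special_mask = matrix$special_mask[idx],
    residue_types = if (is.null(matrix$residue_types)) NULL else matrix$residue_types[idx]
  )
}

#' Residue feature mutation
#'
#' Each non-special position is independently replaced, with probability
#' `mutation_rate`, by a residue feature drawn uniformly from the amino-acid
#' dictionary; otherwise it is left unchanged. The recorded residue type of
#' a mutated position is updated to the sampled letter.
#'
#' @param matrix a [residue_feature_matrix()].
#' @param mutation_rate replacement probability in `[0, 1]` (default 0.2).
#' @param dict an [build_amino_acid_dictionary()] dictionary.
#' @return a mutated [residue_feature_matrix()].
#' @export
residue_feature_mutation <- function(matrix, mutation_rate = 0.2, dict) {
  stopifnot(inherits(matrix, "residue_feature_matrix"),
            mutation_rate >= 0, mutation_rate <= 1)
  if (missing(dict) || is.null(dict) || nrow(dict) == 0L) {
    stop_format("a non-empty amino-acid dictionary is required")
  }
  if (ncol(dict) != ncol(matrix$features)) {
    stop_format("dictionary width %d does not match feature width %d",
                ncol(dict), ncol(matrix$features))
  }
  res <- which(!matrix$special_mask)
  feats <- matrix$features
  types <- matrix$residue_types
  if (length(res)) {
    hit <- res[runif(length(res)) < mutation_rate]
    if (length(hit)) {
      pick <- sample.int(nrow(dict), length(hit), replace = TRUE)
      feats[hit, ] <- dict[pick, , drop = FALSE]
      if (!is.null(types)) types[hit] <- rownames(dict)[pick]
    }
  }
  residue_feature_matrix(feats, matrix$special_mask, types)
}

#' Amino-acid randomization (deletion then mutation)
#'
#' Convenience composition of [random_residue_deletion()] and
#' [residue_feature_mutation()], the augmentation applied fresh to every
#' target feature matrix each training epoch.
#'
#' @param matrix a [residue_feature_matrix()].
#' @param deletion_ratio,mutation_rate the two randomization rates.
#' @param dict amino-acid dictionary for mutation.
#' @return a randomized [residue_feature_matrix()].
#' @export
randomize_target_features <- function(matrix, deletion_ratio = 0.7,
                                      mutation_rate = 0.2, dict) {
  out <- random_residue_deletion(matrix, deletion_ratio)
  residue_feature_mutation(out, mutation_rate, dict)
}
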