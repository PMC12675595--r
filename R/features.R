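#' Per-residue target feature matrix
#'
#' Wraps an `L x D_e` real matrix of residue-level target features with a
#' special-position mask (the `[cls]` row and any padding) and, optionally,
#' the residue letter at each position. Special positions are never deleted
#' or mutated by the randomization operations.
#'
#' @param features numeric matrix, one row per position.
#' @param special_mask logical vector marking `[cls]`/padding rows; defaults
#'   to all `FALSE`.
#' @param residue_types optional character vector of residue letters
#'   (`NA` on special positions).
#' @return an object of class `residue_feature_matrix`.
#' @export
residue_feature_matrix <- function(features, special_mask = NULL,
                                   residue_types = NULL) {
  features <- as.matrix(features)
  L <- nrow(features)
  if (is.null(special_mask)) special_mask <- rep(FALSE, L)
  stopifnot(length(special_mask) == L)
  if (!is.null(residue_types)) stopifnot(length(residue_types) == L)
  structure(list(features = features, special_mask = as.logical(special_mask),
                 residue_types = residue_types),
            class = "residue_feature_matrix")
}

#' @export
print.residue_feature_matrix <- function(x, ...) {
  cat(sprintf("residue_feature_matrix: %d positions (%d special) x %d features\n",
              nrow(x$features), sum(x$special_mask), ncol(x$features)))
  invisible(x)
}

#' Deterministic toy target embedder
#'
#' A stand-in feature provider for desk-scale work: each residue letter has a
#' fixed random base embedding (drawn once from an internal seed, so the
#' table is identical across sessions), and each position's feature is a
#' local-context average of the base embeddings in a window of
#' `context` residues on either side. A `[cls]` row is prepended. Two
#' sequences differing at one residue therefore differ only within a window
#' of `2 * context + 1` rows.
#'
#' @param d_e feature dimension.
#' @param context half-width of the local averaging window.
#' @param table_seed internal seed of the embedding table; fixed by default
#'   so that equal configurations give identical features everywhere.
#' @return a provider of class `c("toy_embedder", "target_feature_provider")`.
#' @export
toy_target_embedder <- function(d_e = 16L, context = 1L, table_seed = 760301L) {
  d_e <- as.integer(d_e)
  tab <- with_seed(table_seed, {
    m <- matrix(stats::rnorm(length(AA21) * d_e), length(AA21), d_e)
    rownames(m) <- AA21
    list(base = m, cls = stats::rnorm(d_e))
  })
  structure(list(d_e = d_e, context = as.integer(context),
                 base = tab$base, cls = tab$cls),
            class = c("toy_embedder", "target_feature_provider"))
}

#' Obtain per-residue features for a target sequence
#'
#' Generic provider contract: implementations must return a
#' [residue_feature_matrix()] whose first row is the `[cls]` position.
#'
#' @param provider a `target_feature_provider`.
#' @param sequence amino-acid sequence string.
#' @return a [residue_feature_matrix()].
#' @export
provide_target_features <- function(provider, sequence) {
  UseMethod("provide_target_features")
}

#' @export
provide_target_features.toy_embedder <- function(provider, sequence) {
  letters_seq <- strsplit(toupper(sequence), "")[[1L]]
  if (length(letters_seq) == 0L) stop_format("empty target sequence")
  unknown <- !(letters_seq %in% AA21)
  if (any(unknown)) {
    stop_format("unknown residue letter '%s'", letters_seq[which(unknown)[1L]])
  }
  base <- provider$base[letters_seq, , drop = FALSE]
  L <- nrow(base)
  ctx <- provider$context
  out <- base
  if (ctx > 0L) {
    for (o in seq_len(ctx)) {
      w <- 0.5 / o
      lead <- rbind(base[-seq_len(o), , drop = FALSE],
                    matrix(0, o, provider$d_e))
      lag <- rbind(matrix(0, o, provider$d_e),
                   base[seq_len(L - o), , drop = FALSE])
      out <- out + w * (lead + lag)
    }
  }
  residue_feature_matrix(
    features = rbind(provider$cls, out),
    special_mask = c(TRUE, rep(FALSE, L)),
    residue_types = c(NA_character_, letters_seq)
  )
}

#' On-disk target feature store
#'
#' A plain-text tensor store: one TSV file per sequence, keyed by a hash of
#' the sequence string, holding the special mask, residue letters and the
#' feature matrix. Suited to precomputed protein-language-model features
#' that are extracted once and reused across runs.
#'
#' @param dir store directory (created if missing).
#' @return a provider of class `c("feature_store", "target_feature_provider")`.
#' @export
feature_store <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(list(dir = dir),
            class = c("feature_store", "target_feature_provider"))
}

store_path <- function(store, sequence) {
  file.path(store$dir, paste0(fnv1a_hash(sequence), "_", nchar(sequence), ".tsv"))
}

#' Save a feature matrix into a store
#'
#' @param store a [feature_store()].
#' @param sequence the sequence the matrix belongs to.
#' @param matrix a [residue_feature_matrix()].
#' @return invisibly, the file path written.
#' @export
store_save <- function(store, sequence, matrix) {
  stopifnot(inherits(store, "feature_store"),
            inherits(matrix, "residue_feature_matrix"))
  # %.17g round-trips IEEE doubles exactly through text
  num_chr <- apply(matrix$features, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(num_chr))) num_chr <- matrix(num_chr, nrow = 1L)
  df <- data.frame(
    special = as.integer(matrix$special_mask),
    residue = if (is.null(matrix$residue_types)) NA_character_ else matrix$residue_types,
    num_chr,
    stringsAsFactors = FALSE
  )
  path <- store_path(store, sequence)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
provide_target_features.feature_store <- function(provider, sequence) {
  path <- store_path(provider, sequence)
  if (!file.exists(path)) {
    stop_format("feature store miss for sequence hash %s", fnv1a_hash(sequence))
  }
  # fix column classes: residue letters like "T" must not become logicals
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character",
                                         rep("numeric", length(hdr) - 2L)),
                          stringsAsFactors = FALSE)
  residue_types <- as.character(df$residue)
  if (all(is.na(residue_types))) residue_types <- NULL
  residue_feature_matrix(
    features = as.matrix(df[, -(1:2), drop = FALSE]),
    special_mask = df$special == 1L,
    residue_types = residue_types
  )
}
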