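#' Per-sequence prior tendency
#'
#' For every unique drug or target, the prior tendency `z_i` is the fraction
#' of its pairs labelled positive, `z_i = sum_j y_ij / n_i`. Values are kept
#' as exact ratios; rounding to one decimal is a display convention only.
#'
#' @param dataset a [dti_dataset()].
#' @param axis `"drug"` or `"target"`: which side's sequences to profile.
#' @return a `tendency_table`: list with `axis`, `entries` (data.frame with
#'   `id`, `n`, `z`), and `M`, the number of unique sequences.
#' @export
sequence_tendency <- function(dataset, axis = c("target", "drug")) {
  stopifnot(inherits(dataset, "dti_dataset"))
  axis <- match.arg(axis)
  if (nrow(dataset$records) == 0L) stop_format("empty dataset")
  idx <- if (axis == "drug") dataset$drug_index else dataset$target_index
  lab <- dataset$records$label
  n_i <- vapply(idx, length, integer(1))
  pos <- vapply(idx, function(j) sum(lab[j]), numeric(1))
  entries <- data.frame(id = names(idx), n = as.integer(n_i), z = pos / n_i,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(axis = axis, entries = entries, M = nrow(entries)),
            class = "tendency_table")
}

#' @export
print.tendency_table <- function(x, ...) {
  cat(sprintf("tendency_table (%s axis): M = %d unique sequences, Z = %.4f\n",
              x$axis, x$M, overall_tendency(x)))
  invisible(x)
}

#' Overall prior tendency Z
#'
#' Aggregates per-sequence tendencies into the dataset-level statistic
#' `Z = mean_i |z_i - 0.5| + 0.5`, which ranges from 0.5 (every sequence
#' perfectly balanced) to 1.0 (every sequence all-positive or all-negative).
#' The unweighted mean over unique sequences is the default; `weighted = TRUE`
#' weights each sequence by its occurrence share `n_i / sum(n_i)`.
#'
#' @param table a `tendency_table` from [sequence_tendency()].
#' @param weighted use occurrence-weighted averaging.
#' @return the scalar Z in `[0.5, 1]`.
#' @export
overall_tendency <- function(table, weighted = FALSE) {
  stopifnot(inherits(table, "tendency_table"))
  if (nrow(table$entries) == 0L) stop_format("empty tendency table")
  dev <- abs(table$entries$z - 0.5)
  if (weighted) {
    w <- table$entries$n / sum(table$entries$n)
    sum(w * dev) + 0.5
  } else {
    mean(dev) + 0.5
  }
}

#' Global positive interaction proportion
#'
#' @param dataset a [dti_dataset()].
#' @return `g = sum(Y) / N`, the fraction of positive pairs.
#' @export
global_proportion <- function(dataset) {
  stopifnot(inherits(dataset, "dti_dataset"))
  if (nrow(dataset$records) == 0L) stop_format("empty dataset")
  mean(dataset$records$label)
}

#' Weighted sum-of-squared-deviations test statistic
#'
#' `T = sum_i n_i (z_i - g)^2`, computed on unrounded tendencies. T is zero
#' exactly when every sequence's tendency equals the global proportion; the
#' `n_i` weighting makes contributions proportional to sample size while
#' keeping sparse sequences visible.
#'
#' @param table a `tendency_table`.
#' @param g global positive proportion in `[0, 1]`.
#' @return the scalar statistic T >= 0.
#' @export
deviation_statistic <- function(table, g) {
  stopifnot(inherits(table, "tendency_table"), g >= 0, g <= 1)
  with(table$entries, sum(n * (z - g)^2))
}

#' Label permutation test for prior tendency
#'
#' Tests the null that labels are assigned independently of the chosen axis's
#' sequences. Pair structure is held fixed while labels are reshuffled across
#' all pairs (a permutation, preserving the label multiset) for `B`
#' iterations; the one-sided p-value is
#' `(1 + #\{T_b >= T_obs\}) / (1 + B)`.
#'
#' @param dataset a [dti_dataset()].
#' @param axis `"drug"` or `"target"`.
#' @param B number of permutations (>= 1), 1000 by default.
#' @param seed integer seed.
#' @return a `permutation_result` with `T_obs`, `g`, `N`, `B`, `permuted_T`,
#'   `p_value`, `axis`, `seed`.
#' @export
permutation_test <- function(dataset, axis = c("target", "drug"),
                             B = 1000L, seed = 1L) {
  axis <- match.arg(axis)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop_format("B must be a positive integer")
  tab <- sequence_tendency(dataset, axis)
  g <- global_proportion(dataset)
  t_obs <- deviation_statistic(tab, g)
  r <- dataset$records
  key <- if (axis == "drug") r$drug_id else r$target_id
  grp <- match(key, tab$entries$id)
  n_i <- tab$entries$n
  lab <- r$label
  n <- length(lab)
  # rowsum orders rows by the sorted group levels 1..M, matching n_i
  permuted <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      zp <- rowsum(lab[sample.int(n)], grp)[, 1L] / n_i
      sum(n_i * (zp - g)^2)
    }, numeric(1))
  })
  p <- (1 + sum(permuted >= t_obs)) / (1 + B)
  structure(list(axis = axis, T_obs = t_obs, g = g, N = n, B = B,
                 permuted_T = permuted, p_value = p, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s axis): T_obs = %.4f, g = %.4f, B = %d, p = %.4g\n",
              x$axis, x$T_obs, x$g, x$B, x$p_value))
  invisible(x)
}

#' Dataset bias report
#'
#' Audits prior tendency on both axes: per-sequence tendency histogram
#' (rounded to one decimal for display), overall tendency Z, the deviation
#' statistic and its permutation p-value.
#'
#' @param dataset a [dti_dataset()].
#' @param B permutation iterations per axis.
#' @param seed integer seed.
#' @param weighted use the occurrence-weighted Z variant.
#' @return a `bias_report`: per-axis list of `histogram`, `Z`, `M`, `T_obs`,
#'   `B`, `p_value`.
#' @export
bias_report <- function(dataset, B = 1000L, seed = 1L, weighted = FALSE) {
  stopifnot(inherits(dataset, "dti_dataset"))
  one_axis <- function(axis, seed_axis) {
    tab <- sequence_tendency(dataset, axis)
    pt <- permutation_test(dataset, axis, B = B, seed = seed_axis)
    bins <- table(factor(sprintf("%.1f", round(tab$entries$z, 1)),
                         levels = sprintf("%.1f", seq(0, 1, 0.1))))
    list(axis = axis, histogram = as.list(as.integer(bins)) |>
           stats::setNames(names(bins)),
         Z = overall_tendency(tab, weighted = weighted), M = tab$M,
         T_obs = pt$T_obs, B = pt$B, p_value = pt$p_value)
  }
  structure(list(drug = one_axis("drug", seed),
                 target = one_axis("target", seed + 1L)),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  for (axis in c("drug", "target")) {
    a <- x[[axis]]
    cat(sprintf("%s axis: M = %d, Z = %.4f, T_obs = %.4f, p = %.4g (B = %d)\n",
                axis, a$M, a$Z, a$T_obs, a$p_value, a$B))
  }
  invisible(x)
}

#' Plot a bias report
#'
#' Side-by-side tendency histograms for the drug and target axes.
#'
#' @param x a `bias_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.bias_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (axis in c("drug", "target")) {
    a <- x[[axis]]
    graphics::barplot(unlist(a$histogram),
                      main = sprintf("%s tendency (p = %.3g)", axis, a$p_value),
                      xlab = "z", ylab = "frequency", ...)
  }
  invisible(x)
}

#' Serialize a bias report to JSON
#'
#' @param report a `bias_report`.
#' @param path output path; when `NULL`, the JSON string is returned.
#' @return invisibly `path`, or the JSON string when `path` is `NULL`.
#' @export
write_bias_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "bias_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
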