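# Greedy maximal set of positive pairs in which every drug and every target
# appears exactly once: shuffle positives under the seed, then first-fit.
select_unique_positives <- function(dataset) {
  r <- dataset$records
  pos <- which(r$label == 1L)
  if (length(pos) == 0L) stop_format("dataset contains no positive pairs")
  pos <- pos[sample.int(length(pos))]
  seen_d <- new.env(hash = TRUE)
  seen_t <- new.env(hash = TRUE)
  keep <- integer(0)
  for (i in pos) {
    d <- r$drug_id[i]
    t <- r$target_id[i]
    if (is.null(seen_d[[d]]) && is.null(seen_t[[t]])) {
      seen_d[[d]] <- TRUE
      seen_t[[t]] <- TRUE
      keep <- c(keep, i)
    }
  }
  keep
}

pair_key <- function(drug_id, target_id) paste(drug_id, target_id, sep = "\r")

#' Drug-biased counter-prior training set
#'
#' Builds a training set in which every drug carries an extreme prior
#' tendency while every target is perfectly balanced. A positive set `S_p`
#' is selected so each drug and each target appears once; each `S_p` target
#' then receives exactly one negative pair whose drug is drawn from the
#' drugs outside `S_p` (cycling over that pool when it is smaller than
#' `S_p`), never duplicating a pair present in the input. The union has a
#' 50/50 label split, target-axis Z of 0.5 and drug-axis Z of 1.0.
#'
#' @param dataset a [dti_dataset()] with at least one positive pair and at
#'   least one drug outside the selected positive set.
#' @param seed integer seed.
#' @return a [dti_dataset()] with the re-split records in shuffled order.
#' @export
build_drug_biased_split <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "dti_dataset"))
  with_seed(seed, {
    r <- dataset$records
    sp <- select_unique_positives(dataset)
    sp_drugs <- r$drug_id[sp]
    leftover <- setdiff(names(dataset$drug_index), sp_drugs)
    if (length(leftover) == 0L) {
      stop_format("no drugs left outside the positive set to form negatives")
    }
    leftover <- leftover[sample.int(length(leftover))]
    existing <- new.env(hash = TRUE)
    for (k in pair_key(r$drug_id, r$target_id)) existing[[k]] <- TRUE
    drug_row <- match(leftover, r$drug_id)
    neg_drug <- character(length(sp))
    cursor <- 0L
    for (j in seq_along(sp)) {
      tgt <- r$target_id[sp[j]]
      placed <- FALSE
      for (tries in seq_along(leftover)) {
        cursor <- cursor %% length(leftover) + 1L
        cand <- leftover[cursor]
        key <- pair_key(cand, tgt)
        if (is.null(existing[[key]])) {
          existing[[key]] <- TRUE
          neg_drug[j] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop_format("could not place a novel negative pair for target %s", tgt)
      }
    }
    neg_row <- match(neg_drug, r$drug_id)
    out <- data.frame(
      drug_id = c(r$drug_id[sp], neg_drug),
      smiles = c(r$smiles[sp], r$smiles[neg_row]),
      target_id = c(r$target_id[sp], r$target_id[sp]),
      sequence = c(r$sequence[sp], r$sequence[sp]),
      label = c(rep(1L, length(sp)), rep(0L, length(sp))),
      stringsAsFactors = FALSE
    )
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    dti_dataset(out$smiles, out$sequence, out$label,
                drug_id = out$drug_id, target_id = out$target_id)
  })
}

#' Balanced counter-prior training set
#'
#' Builds a training set in which every single drug and target has one
#' positive and one negative pair, so the prior tendency is exactly 0.5 on
#' both axes. Negatives are formed by a seeded derangement of the drug
#' column of the unique-entity positive set `S_p` (no drug keeps its own
#' positive target, and no recreated pair may coincide with a positive pair
#' of the input; the permutation is redrawn until both hold).
#'
#' @param dataset a [dti_dataset()] whose unique-entity positive set has at
#'   least 2 pairs.
#' @param seed integer seed.
#' @param max_retries derangement redraw bound before giving up.
#' @return a [dti_dataset()] of size `2 * |S_p|`.
#' @export
build_balanced_split <- function(dataset, seed = 1L, max_retries = 1000L) {
  stopifnot(inherits(dataset, "dti_dataset"))
  with_seed(seed, {
    r <- dataset$records
    sp <- select_unique_positives(dataset)
    m <- length(sp)
    if (m < 2L) stop_format("need at least 2 unique-entity positive pairs for a derangement")
    pos_keys <- new.env(hash = TRUE)
    for (k in pair_key(r$drug_id[r$label == 1L], r$target_id[r$label == 1L])) {
      pos_keys[[k]] <- TRUE
    }
    admissible <- function(cand) {
      if (any(cand == seq_len(m))) return(FALSE)
      keys <- pair_key(r$drug_id[sp][cand], r$target_id[sp])
      !any(vapply(keys, function(k) !is.null(pos_keys[[k]]), logical(1)))
    }
    perm <- NULL
    for (tries in seq_len(max_retries)) {
      cand <- sample.int(m)
      if (admissible(cand)) {
        perm <- cand
        break
      }
    }
    if (is.null(perm)) {
      # dense datasets make rejection sampling hopeless: fall back to a
      # randomized greedy assignment under the same constraints
      forbidden <- function(j, i) {
        i == j || !is.null(pos_keys[[pair_key(r$drug_id[sp][i],
                                              r$target_id[sp][j])]])
      }
      for (attempt in seq_len(200L)) {
        cand <- integer(m)
        left <- seq_len(m)
        ok <- TRUE
        for (j in sample.int(m)) {
          allowed <- left[!vapply(left, function(i) forbidden(j, i), logical(1))]
          if (length(allowed) == 0L) {
            ok <- FALSE
            break
          }
          pick <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
          cand[j] <- pick
          left <- left[left != pick]
        }
        if (ok && admissible(cand)) {
          perm <- cand
          break
        }
      }
    }
    if (is.null(perm)) {
      stop_format("no admissible derangement found in %d retries", max_retries)
    }
    out <- data.frame(
      drug_id = c(r$drug_id[sp], r$drug_id[sp][perm]),
      smiles = c(r$smiles[sp], r$smiles[sp][perm]),
      target_id = c(r$target_id[sp], r$target_id[sp]),
      sequence = c(r$sequence[sp], r$sequence[sp]),
      label = c(rep(1L, m), rep(0L, m)),
      stringsAsFactors = FALSE
    )
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    dti_dataset(out$smiles, out$sequence, out$label,
                drug_id = out$drug_id, target_id = out$target_id)
  })
}
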