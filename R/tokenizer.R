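# Atom-wise SMILES tokenization: bracket atoms, two-character element
# symbols, stereo marks and two-digit ring closures are kept whole, anything
# else is a single character.
SMILES_TOKEN_REGEX <- paste0(
  "\\[[^\\]]+\\]|Br|Cl|Si|Se|@@|%[0-9]{2}|",
  "[A-Za-z0-9=#\\-\\+\\(\\)/\\\\\\.:~\\*@]"
)

#' Tokenize a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @export
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  m <- gregexpr(SMILES_TOKEN_REGEX, smiles, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character(0))
  toks <- regmatches(smiles, list(m))[[1L]]
  if (sum(nchar(toks)) != nchar(smiles)) {
    stop_format("untokenizable characters in SMILES: %s", smiles)
  }
  toks
}

#' Build a SMILES token vocabulary from data
#'
#' Special tokens `[pad]`, `[cls]`, `[mask]` occupy the first slots; the
#' remaining slots hold the sorted distinct tokens observed in the corpus.
#'
#' @param smiles character vector of SMILES strings.
#' @return a `smiles_vocab`: list with `tokens`, `special` (logical mask),
#'   and the ids `pad_id`, `cls_id`, `mask_id`.
#' @export
build_vocab <- function(smiles) {
  toks <- sort(unique(unlist(lapply(smiles, smiles_tokenize))))
  specials <- c("[pad]", "[cls]", "[mask]")
  tokens <- c(specials, setdiff(toks, specials))
  structure(
    list(tokens = tokens,
         special = seq_along(tokens) <= length(specials),
         pad_id = 1L, cls_id = 2L, mask_id = 3L),
    class = "smiles_vocab"
  )
}

#' @export
print.smiles_vocab <- function(x, ...) {
  cat(sprintf("smiles_vocab: %d tokens (%d special)\n",
              length(x$tokens), sum(x$special)))
  invisible(x)
}

#' Encode a SMILES string to token ids
#'
#' Prepends the `[cls]` token. Unknown tokens are an error: the vocabulary
#' is built from the training corpus and prediction inputs must be encodable.
#'
#' @param smiles a single SMILES string.
#' @param vocab a [build_vocab()] vocabulary.
#' @param max_len optional length cap (including `[cls]`); longer sequences
#'   are truncated.
#' @return integer vector of token ids.
#' @export
smiles_encode <- function(smiles, vocab, max_len = NULL) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  ids <- match(smiles_tokenize(smiles), vocab$tokens)
  if (anyNA(ids)) {
    stop_format("out-of-vocabulary token '%s' in SMILES %s",
                smiles_tokenize(smiles)[which(is.na(ids))[1L]], smiles)
  }
  out <- c(vocab$cls_id, ids)
  if (!is.null(max_len) && length(out) > max_len) out <- out[seq_len(max_len)]
  out
}

#' Masked-language-model corruption of token ids
#'
#' Selects `round(select_rate * L)` of the non-special tokens; each selected
#' token is replaced by `[mask]` with probability `mask_frac`, left unchanged
#' with probability `keep_frac`, or replaced by a random non-special
#' vocabulary token with probability `random_frac`.
#'
#' @param token_ids integer vector of token ids.
#' @param vocab a [build_vocab()] vocabulary.
#' @param select_rate fraction of eligible tokens to select (default 0.15).
#' @param mask_frac,keep_frac,random_frac trichotomy probabilities among the
#'   selected tokens; must sum to 1 (defaults 0.8 / 0.1 / 0.1).
#' @return list with `ids` (corrupted ids) and `mask` (logical selection
#'   mask over positions, the `m_ij` of the MLM loss).
#' @export
mlm_corrupt <- function(token_ids, vocab, select_rate = 0.15,
                        mask_frac = 0.8, keep_frac = 0.1, random_frac = 0.1) {
  stopifnot(inherits(vocab, "smiles_vocab"))
  if (abs(mask_frac + keep_frac + random_frac - 1) > 1e-12) {
    stop_format("mask_frac + keep_frac + random_frac must sum to 1")
  }
  special_ids <- which(vocab$special)
  eligible <- which(!(token_ids %in% special_ids))
  sel_mask <- rep(FALSE, length(token_ids))
  out <- token_ids
  n_sel <- round(select_rate * length(eligible))
  if (n_sel > 0L) {
    sel <- if (length(eligible) == 1L) eligible else sample(eligible, n_sel)
    sel_mask[sel] <- TRUE
    u <- runif(n_sel)
    to_mask <- sel[u < mask_frac]
    to_random <- sel[u >= mask_frac + keep_frac]
    out[to_mask] <- vocab$mask_id
    if (length(to_random)) {
      pool <- which(!vocab$special)
      out[to_random] <- sample(pool, length(to_random), replace = TRUE)
    }
  }
  list(ids = out, mask = sel_mask)
}
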