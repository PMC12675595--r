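#' @keywords internal
#' @useDynLib tapb, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Amino-acid alphabet used throughout; X marks unknown/non-standard residues.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so seeded package internals never perturb the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  expr
}

# FNV-1a 32-bit string hash, done in double arithmetic to stay inside R's
# exact-integer range; used to key sequences in the on-disk feature store.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  # h exceeds R's integer range, so format the two 16-bit halves separately
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of a 32-bit value held in a double with a value below 2^31: only the
# low 31 bits can change, so split off the high bit first
bitwXor_dbl <- function(h, b) {
  lo <- h %% 2147483648
  hi <- h - lo
  hi + as.double(bitwXor(as.integer(lo), as.integer(b)))
}

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
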