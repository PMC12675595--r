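# small in-code fixtures shared across the suite

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

tiny_dataset <- function(n = 12L, seed = 1L) {
  generate_synthetic(synthetic_config(
    n_drugs = max(4L, n %/% 2L), n_targets = max(3L, n %/% 3L),
    n_pairs = n, target_bias = 0.5, mechanism_weight = 0, seed = seed))
}

hand_dataset <- function() {
  # 6 pairs, 3 drugs x 2 targets, labels chosen for easy hand arithmetic
  dti_dataset(
    smiles = c("CCO", "CCO", "CCN", "CCN", "CCC", "CCC"),
    sequence = c("MKT", "ACD", "MKT", "ACD", "MKT", "ACD"),
    label = c(1, 1, 1, 0, 0, 0))
}

tiny_vocab <- function() build_vocab(c("CCO", "c1ccccc1N", "CC(=O)ClBr"))

tiny_model <- function(variant = "full", seed = 1L, ...) {
  cfg <- tapb_variant(variant, d_m = 8L, d_e = 8L, n_heads = 2L,
                      n_enc_layers = 2L, n_agg_layers = 2L, d_ff = 12L, ...)
  tapb_model(cfg, tiny_vocab(), seed = seed)
}

rand_rfm <- function(L = 10L, d = 8L, cls = TRUE) {
  Lr <- if (cls) L - 1L else L
  residue_feature_matrix(
    features = matrix(stats::rnorm(L * d), L, d),
    special_mask = c(if (cls) TRUE, rep(FALSE, Lr)),
    residue_types = c(if (cls) NA_character_,
                      sample(AA_LETTERS, Lr, replace = TRUE)))
}

full_aa_dictionary <- function(d = 8L, seed = 42L) {
  tapb:::with_seed(seed, {
    mats <- lapply(1:8, function(i) {
      letters_seq <- sample(rep(AA_LETTERS, 2L))
      residue_feature_matrix(matrix(stats::rnorm(40 * d), 40, d),
                             rep(FALSE, 40), letters_seq)
    })
    build_amino_acid_dictionary(mats)
  })
}
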