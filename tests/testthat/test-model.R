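test_that("configuration invariants are enforced", {
  expect_error(tapb_config(n_heads = 4L, dict_size = 8L), "must equal")
  expect_error(tapb_config(d_m = 30L, n_heads = 4L), "divisible")
  expect_error(tapb_config(d_e = 10L, n_heads = 4L), "divisible")
  expect_error(tapb_config(n_enc_layers = 0L), "depths")
  cfg <- tapb_variant("base")
  expect_false(cfg$use_cam || cfg$use_backdoor || cfg$use_mlm ||
                 cfg$use_randomization)
  expect_true(all(unlist(tapb_variant("full")[c(
    "use_cam", "use_backdoor", "use_mlm", "use_randomization")])))
})

test_that("drug encoder is deterministic, position-sensitive and shape-correct", {
  m <- tiny_model()
  ids <- smiles_encode("c1ccccc1N", m$vocab)
  D1 <- encode_drug(m, ids)
  expect_equal(dim(D1), c(length(ids), m$config$d_m))
  expect_identical(D1, encode_drug(m, ids))
  # swapping two non-special tokens changes the output (rotary positions)
  swap <- which(ids != ids[2L])[2L]
  ids2 <- ids
  ids2[c(2L, swap)] <- ids2[c(swap, 2L)]
  expect_gt(max(abs(encode_drug(m, ids2) - D1)), 0)
  expect_error(encode_drug(m, c(1L, 999L)), "out of vocabulary")
})

test_that("confounder alignment broadcasts singleton-key values per head", {
  m <- tiny_model()
  E <- matrix(rnorm(5 * 8), 5, 8)
  Tm <- confounder_align(m, E)
  expect_equal(dim(Tm), c(5L, 8L))
  # singleton softmax weight is 1, so the pre-residual message is the same
  # value row at every position: T differs across rows only through E
  p <- m$params$cam
  M <- Tm - (E %*% p$Wg + rep(p$bg, each = 5L))
  V <- m$dict$centers %*% p$Wv
  manual <- cbind(matrix(V[1L, 1:4], 5, 4, byrow = TRUE),
                  matrix(V[2L, 5:8], 5, 4, byrow = TRUE)) %*% p$Wg
  expect_equal(M, manual, tolerance = 1e-12)

  # no-CAM ablation uses an independent projection with no dictionary path
  m2 <- tiny_model("rm-ba")
  Tm2 <- confounder_align(m2, E)
  expect_equal(Tm2, E %*% m2$params$nocam$Wg +
                 rep(m2$params$nocam$bg, each = 5L))
  expect_error(confounder_align(m, matrix(0, 3, 5)), "width")
})

test_that("aggregator exposes normalized per-head attention maps", {
  m <- tiny_model()
  ids <- smiles_encode("CC(=O)ClBr", m$vocab)
  D <- encode_drug(m, ids)
  Tm <- confounder_align(m, matrix(rnorm(6 * 8), 6, 8))
  agg <- aggregate_features(m, D, Tm)
  expect_equal(dim(agg$F), dim(D))
  expect_length(agg$target_attention, m$config$n_heads)
  for (A in agg$target_attention) {
    expect_equal(dim(A), c(nrow(D), nrow(Tm)))
    expect_equal(rowSums(A), rep(1, nrow(D)), tolerance = 1e-8)
  }
  for (A in agg$drug_attention) {
    expect_equal(rowSums(A), rep(1, nrow(D)), tolerance = 1e-8)
  }
  expect_error(aggregate_features(m, D[0, , drop = FALSE], Tm), "empty")
})

test_that("partition is an exact channel inverse", {
  F <- matrix(rnorm(7 * 32), 7, 32)
  segs <- partition_by_confounder(F, 4L)
  expect_length(segs, 4L)
  expect_identical(do.call(cbind, segs), F)
  expect_identical(partition_by_confounder(F, 1L)[[1L]], F)
  expect_error(partition_by_confounder(F, 5L), "divisible")
})

test_that("conditional probabilities are masked pooled softmax rows", {
  m <- tiny_model()
  segs <- partition_by_confounder(matrix(rnorm(6 * 8), 6, 8), 2L)
  P <- conditional_probabilities(m, segs)
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-6)
  # identical segments map to identical rows through the shared head
  P2 <- conditional_probabilities(m, list(segs[[1L]], segs[[1L]]))
  expect_equal(P2[1L, ], P2[2L, ])
  # zero-weight head gives the symmetric prediction
  m0 <- m
  m0$params$head$Wy[] <- 0
  m0$params$head$by[] <- 0
  expect_equal(conditional_probabilities(m0, segs),
               matrix(0.5, 2L, 2L), tolerance = 1e-12)
  expect_error(conditional_probabilities(m, segs, mask = rep(FALSE, 6L)),
               "mask")
})

test_that("backdoor prediction equals the explicit per-cluster sum", {
  set.seed(4)
  for (i in 1:10) {
    I <- sample(2:6, 1L)
    cond <- matrix(runif(I * 2), I)
    cond <- cond / rowSums(cond)
    w <- runif(I)
    w <- w / sum(w)
    oracle <- c(0, 0)
    for (k in seq_len(I)) oracle <- oracle + w[k] * cond[k, ]
    expect_equal(backdoor_predict(cond, w), oracle, tolerance = 1e-12)
    expect_equal(sum(backdoor_predict(cond, w)), 1, tolerance = 1e-6)
  }
  # I = 1 reduces to plain conditioning
  row <- c(0.3, 0.7)
  expect_equal(backdoor_predict(matrix(row, 1L), 1), row)
  expect_error(backdoor_predict(matrix(row, 1L), c(0.5, 0.5)), "weights")
  expect_error(backdoor_predict(rbind(row, row), c(0.9, 0.3)), "sum to 1")
})

test_that("losses match their definitions and loop oracles", {
  expect_equal(classification_loss(c(1, 0), 0), 0, tolerance = 1e-9)
  expect_equal(classification_loss(c(0.5, 0.5), 1), log(2))
  expect_lte(classification_loss(c(0, 1), 0), -log(1e-12) + 1e-9)

  m <- tiny_model()
  set.seed(2)
  H <- matrix(rnorm(6 * 8), 6, 8)
  mask <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  true_ids <- sample(4:10, 6L, replace = TRUE)
  loss <- mlm_loss(m, H, mask, true_ids)
  # independent per-position loop oracle
  oracle <- 0
  for (j in which(mask)) {
    logit <- H[j, ] %*% m$params$mlm$W + m$params$mlm$b
    p <- exp(logit - max(logit))
    p <- p / sum(p)
    oracle <- oracle - log(p[true_ids[j]])
  }
  expect_equal(loss, as.numeric(oracle), tolerance = 1e-10)
  expect_equal(mlm_loss(m, H, rep(FALSE, 6L), true_ids), 0)

  expect_equal(total_loss(0.4, 0.3, tapb_variant("full")), 0.7)
  expect_equal(total_loss(0.4, 0.3, tapb_variant("r")), 0.4)
})

test_that("confounder dictionary clusters pooled features with proportion weights", {
  set.seed(6)
  # two well-separated blobs of sizes 60/40
  blob <- function(center, n) {
    lapply(seq_len(n), function(i) {
      residue_feature_matrix(
        rbind(rnorm(4), matrix(rnorm(20, mean = center, sd = 0.1), 5L)),
        c(TRUE, rep(FALSE, 5L)))
    })
  }
  feats <- c(blob(5, 60L), blob(-5, 40L))
  dict <- build_confounder_dictionary(feats, 2L, seed = 1L)
  expect_equal(sort(dict$weights), c(0.4, 0.6))
  expect_equal(sum(dict$weights), 1)
  expect_equal(sort(rowMeans(dict$centers)), c(-5, 5), tolerance = 0.05)

  d1 <- build_confounder_dictionary(feats[1:10], 1L, seed = 1L)
  pooled <- t(vapply(feats[1:10], function(m) colMeans(m$features[-1L, ]),
                     numeric(4L)))
  expect_equal(as.numeric(d1$centers), colMeans(pooled), tolerance = 1e-10)
  expect_equal(d1$weights, 1)
  expect_error(build_confounder_dictionary(feats[1:3], 5L), "fewer targets")
})

test_that("analytic gradients match finite differences end to end", {
  ns <- asNamespace("tapb")
  set.seed(42)
  cfg <- tapb_variant("full", d_m = 8L, d_e = 8L, n_heads = 2L,
                      n_enc_layers = 2L, n_agg_layers = 2L, d_ff = 12L)
  vocab <- tiny_vocab()
  params <- ns$init_params(cfg, length(vocab$tokens))
  dict <- structure(list(centers = matrix(rnorm(16), 2L, 8L),
                         weights = c(0.6, 0.4), fit_metadata = list()),
                    class = "confounder_dictionary")
  rope <- ns$rope_cache(cfg$max_len_drug, cfg$d_m %/% cfg$n_heads)
  ids_true <- smiles_encode("c1ccccc1N", vocab)
  mask <- rep(FALSE, length(ids_true))
  mask[c(3L, 5L)] <- TRUE
  ids_in <- ids_true
  ids_in[3L] <- vocab$mask_id
  E <- matrix(rnorm(48), 6L, 8L)
  loss_fn <- function(p) {
    fwd <- ns$model_forward_sample(p, cfg, ids_in, E, dict, rope, mask, ids_true)
    lc <- -log(max(fwd$backdoor[2L], 1e-12))
    lm <- -sum(log(pmax(
      fwd$mlm$probs[cbind(seq_along(fwd$mlm$sel), fwd$mlm$true)], 1e-12)))
    0.7 * lc + 0.3 * lm
  }
  fwd <- ns$model_forward_sample(params, cfg, ids_in, E, dict, rope, mask,
                                 ids_true, keep_caches = TRUE)
  g <- ns$model_backward_sample(fwd, params, cfg, dict, 1L,
                                cls_weight = 0.7, mlm_weight = 0.3)
  idx1 <- function(p) if (grepl("^[0-9]+$", p)) as.integer(p) else p
  get_leaf <- function(tree, path) {
    for (p in path) tree <- tree[[idx1(p)]]
    tree
  }
  set_leaf <- function(tree, path, val) {
    if (length(path) == 1L) {
      tree[[idx1(path)]] <- val
      return(tree)
    }
    tree[[idx1(path[1L])]] <- set_leaf(tree[[idx1(path[1L])]], path[-1L], val)
    tree
  }
  paths <- list(c("emb"), c("enc", "1", "sa", "Wq"), c("enc", "2", "ff", "W1"),
                c("enc", "2", "ln2", "g"), c("agg", "1", "ca", "Wk"),
                c("agg", "2", "sa", "Wo"), c("agg", "2", "ff", "W2"),
                c("cam", "Wv"), c("cam", "Wg"), c("head", "Wy"),
                c("mlm", "W"))
  eps <- 1e-5
  for (path in paths) {
    leaf <- get_leaf(params, path)
    gleaf <- get_leaf(g, path)
    for (j in sample(seq_along(leaf), 3L)) {
      lp <- leaf
      lp[j] <- lp[j] + eps
      lm_ <- leaf
      lm_[j] <- lm_[j] - eps
      num <- (loss_fn(set_leaf(params, path, lp)) -
                loss_fn(set_leaf(params, path, lm_))) / (2 * eps)
      expect_equal(gleaf[j], num, tolerance = 1e-4,
                   label = paste(path, collapse = "."))
    }
  }
})

test_that("compiled and reference engines agree to machine precision", {
  ns <- asNamespace("tapb")
  set.seed(5)
  for (variant in c("full", "base", "rm-cam")) {
    cfg <- tapb_variant(variant, d_m = 8L, d_e = 8L, n_heads = 2L,
                        n_enc_layers = 2L, n_agg_layers = 2L, d_ff = 12L)
    vocab <- tiny_vocab()
    params <- ns$init_params(cfg, length(vocab$tokens))
    dict <- structure(list(centers = matrix(rnorm(16), 2L, 8L),
                           weights = c(0.6, 0.4), fit_metadata = list()),
                      class = "confounder_dictionary")
    rope <- ns$rope_cache(cfg$max_len_drug, cfg$d_m %/% cfg$n_heads)
    mk <- function(sm, y) {
      ids0 <- smiles_encode(sm, vocab)
      sel <- if (cfg$use_mlm) sort(sample(2:length(ids0), 2L)) else integer(0)
      ids <- ids0
      if (length(sel)) ids[sel[1L]] <- vocab$mask_id
      list(ids = ids, sel = sel, true_ids = ids0,
           E = matrix(rnorm(40), 5L, 8L), y = y)
    }
    batch <- list(mk("CCO", 1L), mk("c1ccccc1N", 0L))
    res <- ns$tapb_batch_cpp(params, unclass(cfg), dict$centers, dict$weights,
                             rope$cos, rope$sin, batch, 0.5, 0.25)
    gacc <- NULL
    lc <- 0
    for (bi in batch) {
      mask <- rep(FALSE, length(bi$true_ids))
      mask[bi$sel] <- TRUE
      fwd <- ns$model_forward_sample(params, cfg, bi$ids, bi$E, dict, rope,
                                     if (cfg$use_mlm) mask, bi$true_ids,
                                     keep_caches = TRUE)
      pred <- if (cfg$use_backdoor) fwd$backdoor else fwd$plain
      lc <- lc - log(max(pred[bi$y + 1L], 1e-12))
      g <- ns$model_backward_sample(fwd, params, cfg, dict, bi$y,
                                    cls_weight = 0.5, mlm_weight = 0.25)
      gacc <- if (is.null(gacc)) g else ns$tree_add(gacc, g)
    }
    expect_equal(res$loss_cls, lc, tolerance = 1e-12)
    expect_lt(max(abs(unlist(ns$tree_map(`-`, gacc, res$grads)))), 1e-12)
  }
})
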