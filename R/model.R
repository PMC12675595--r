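#' TAPB model configuration
#'
#' Architecture and ablation switches for the TAPB model. The aggregator's
#' head count `n_heads` must equal the confounder dictionary size
#' `dict_size`, because each cross-attention head is paired with one
#' confounder cluster; `d_m` must be divisible by `n_heads` (with an even
#' per-head width for the rotary encoding), and `d_e` by `dict_size` for the
#' per-head confounder alignment.
#'
#' @param d_m model width of the drug encoder and aggregator.
#' @param d_e width of the target residue features.
#' @param n_heads attention heads H of the aggregator's cross-attention.
#' @param dict_size confounder dictionary size I; must equal `n_heads`.
#' @param n_enc_layers drug encoder depth (3 by default).
#' @param n_agg_layers aggregator depth (3 by default).
#' @param d_ff feed-forward hidden width.
#' @param max_len_drug,max_len_target maximum sequence lengths.
#' @param deletion_ratio,mutation_rate amino-acid randomization rates.
#' @param mlm_select_rate,mlm_mask_frac,mlm_keep_frac,mlm_random_frac MLM
#'   corruption rates for the drug branch.
#' @param use_randomization,use_mlm,use_cam,use_backdoor ablation flags; all
#'   on is the full model, all off the plain dual-tower baseline.
#' @param init_sd standard deviation of the random weight initialization.
#' @param cam_keys `"single"` (each head attends to its own cluster center, a
#'   singleton key whose softmax weight is identically 1) or `"all"` (every
#'   head attends over all I centers).
#' @param partition_point `"post_ffn"` partitions the final aggregator
#'   output; `"pre_ffn"` partitions before the last feed-forward block, which
#'   otherwise mixes channels across head segments.
#' @return a `tapb_config` list.
#' @export
tapb_config <- function(d_m = 32L, d_e = 16L, n_heads = 4L,
                        dict_size = n_heads, n_enc_layers = 3L,
                        n_agg_layers = 3L, d_ff = 2L * d_m,
                        max_len_drug = 64L, max_len_target = 128L,
                        deletion_ratio = 0.7, mutation_rate = 0.2,
                        mlm_select_rate = 0.15, mlm_mask_frac = 0.8,
                        mlm_keep_frac = 0.1, mlm_random_frac = 0.1,
                        use_randomization = TRUE, use_mlm = TRUE,
                        use_cam = TRUE, use_backdoor = TRUE,
                        init_sd = 0.1,
                        cam_keys = c("single", "all"),
                        partition_point = c("post_ffn", "pre_ffn")) {
  cfg <- list(d_m = as.integer(d_m), d_e = as.integer(d_e),
              n_heads = as.integer(n_heads), dict_size = as.integer(dict_size),
              n_enc_layers = as.integer(n_enc_layers),
              n_agg_layers = as.integer(n_agg_layers), d_ff = as.integer(d_ff),
              max_len_drug = as.integer(max_len_drug),
              max_len_target = as.integer(max_len_target),
              deletion_ratio = deletion_ratio, mutation_rate = mutation_rate,
              mlm_select_rate = mlm_select_rate, mlm_mask_frac = mlm_mask_frac,
              mlm_keep_frac = mlm_keep_frac, mlm_random_frac = mlm_random_frac,
              use_randomization = isTRUE(use_randomization),
              use_mlm = isTRUE(use_mlm), use_cam = isTRUE(use_cam),
              use_backdoor = isTRUE(use_backdoor),
              init_sd = init_sd,
              cam_keys = match.arg(cam_keys),
              partition_point = match.arg(partition_point))
  if (cfg$n_heads != cfg$dict_size) {
    stop_format("n_heads (H = %d) must equal the confounder dictionary size (I = %d)",
                cfg$n_heads, cfg$dict_size)
  }
  if (cfg$d_m %% cfg$n_heads != 0L) {
    stop_format("d_m must be divisible by n_heads")
  }
  if ((cfg$d_m %/% cfg$n_heads) %% 2L != 0L) {
    stop_format("per-head width d_m / n_heads must be even for rotary encoding")
  }
  if (cfg$d_e %% cfg$dict_size != 0L) {
    stop_format("d_e must be divisible by dict_size for per-head confounder alignment")
  }
  if (cfg$n_enc_layers < 1L || cfg$n_agg_layers < 1L) {
    stop_format("encoder and aggregator depths must be >= 1")
  }
  structure(cfg, class = "tapb_config")
}

#' TAPB ablation variants
#'
#' Maps a named variant to its ablation flags: `base` (plain dual tower),
#' `r` (+ amino-acid randomization), `rm` (+ MLM loss), `rm-ba` (+ backdoor
#' adjustment without CAM), `rm-cam` (+ CAM without backdoor adjustment),
#' `full` (all components).
#'
#' @param variant one of `"base"`, `"r"`, `"rm"`, `"rm-ba"`, `"rm-cam"`,
#'   `"full"`.
#' @param ... further arguments passed to [tapb_config()].
#' @return a [tapb_config()].
#' @export
tapb_variant <- function(variant = c("full", "base", "r", "rm", "rm-ba", "rm-cam"),
                         ...) {
  variant <- match.arg(variant)
  flags <- switch(variant,
    "base"   = list(FALSE, FALSE, FALSE, FALSE),
    "r"      = list(TRUE, FALSE, FALSE, FALSE),
    "rm"     = list(TRUE, TRUE, FALSE, FALSE),
    "rm-ba"  = list(TRUE, TRUE, FALSE, TRUE),
    "rm-cam" = list(TRUE, TRUE, TRUE, FALSE),
    "full"   = list(TRUE, TRUE, TRUE, TRUE)
  )
  tapb_config(use_randomization = flags[[1L]], use_mlm = flags[[2L]],
              use_cam = flags[[3L]], use_backdoor = flags[[4L]], ...)
}

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_attn <- function(d_in, d_out, sd) {
  list(Wq = init_mat(d_in, d_out, sd), bq = numeric(d_out),
       Wk = init_mat(d_in, d_out, sd), bk = numeric(d_out),
       Wv = init_mat(d_in, d_out, sd), bv = numeric(d_out),
       Wo = init_mat(d_out, d_out, sd), bo = numeric(d_out))
}

init_block <- function(d_m, d_ff, sd) {
  list(sa = init_attn(d_m, d_m, sd),
       ln1 = list(g = rep(1, d_m), b = numeric(d_m)),
       ff = list(W1 = init_mat(d_m, d_ff, sd), b1 = numeric(d_ff),
                 W2 = init_mat(d_ff, d_m, sd), b2 = numeric(d_m)),
       ln2 = list(g = rep(1, d_m), b = numeric(d_m)))
}

init_agg_block <- function(d_m, d_ff, sd) {
  list(sa = init_attn(d_m, d_m, sd),
       ln1 = list(g = rep(1, d_m), b = numeric(d_m)),
       ca = init_attn(d_m, d_m, sd),
       ln2 = list(g = rep(1, d_m), b = numeric(d_m)),
       ff = list(W1 = init_mat(d_m, d_ff, sd), b1 = numeric(d_ff),
                 W2 = init_mat(d_ff, d_m, sd), b2 = numeric(d_m)),
       ln3 = list(g = rep(1, d_m), b = numeric(d_m)))
}

init_params <- function(cfg, vocab_size) {
  dk_seg <- cfg$d_m %/% cfg$dict_size
  sd <- if (is.null(cfg$init_sd)) 0.02 else cfg$init_sd
  p <- list(
    emb = init_mat(vocab_size, cfg$d_m, sd),
    enc = lapply(seq_len(cfg$n_enc_layers),
                 function(l) init_block(cfg$d_m, cfg$d_ff, sd)),
    agg = lapply(seq_len(cfg$n_agg_layers),
                 function(l) init_agg_block(cfg$d_m, cfg$d_ff, sd)),
    head = list(Wy = init_mat(dk_seg, 2L, sd), by = numeric(2L)),
    headp = list(Wy = init_mat(cfg$d_m, 2L, sd), by = numeric(2L)),
    mlm = list(W = init_mat(cfg$d_m, vocab_size, sd), b = numeric(vocab_size))
  )
  if (cfg$use_cam) {
    p$cam <- list(Wv = init_mat(cfg$d_e, cfg$d_e, sd),
                  Wg = init_mat(cfg$d_e, cfg$d_m, sd), bg = numeric(cfg$d_m))
    if (cfg$cam_keys == "all") {
      p$cam$Wq <- init_mat(cfg$d_e, cfg$d_e, sd)
      p$cam$Wk <- init_mat(cfg$d_e, cfg$d_e, sd)
    }
  } else {
    p$nocam <- list(Wg = init_mat(cfg$d_e, cfg$d_m, sd), bg = numeric(cfg$d_m))
  }
  p
}

# recursive tree helpers over nested parameter lists
tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- tree_map(f, a[[i]], if (is.null(b)) NULL else b[[i]])
    }
    out
  } else if (is.null(b)) {
    f(a)
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) tree_map(function(x) x * 0, a)
tree_add <- function(a, b) tree_map(`+`, a, b)
tree_scale <- function(a, s) tree_map(function(x) x * s, a)

#' Build the confounder dictionary by K-Means over target features
#'
#' Each training target is reduced to one vector by mean pooling its
#' non-special residue features; the pooled vectors are clustered with
#' K-Means (k-means++ initialization, Lloyd iterations). The cluster centers
#' form the dictionary and the cluster membership proportions are the
#' backdoor adjustment weights `P(c_i)`.
#'
#' @param training_features list of [residue_feature_matrix()] objects (one
#'   per unique training target), or an already pooled numeric matrix with
#'   one row per target.
#' @param I dictionary size (number of clusters).
#' @param seed integer seed for the initialization.
#' @return a `confounder_dictionary`: list with `centers` (`I x D_e`),
#'   `weights` (length `I`, summing to 1) and `fit_metadata`.
#' @export
build_confounder_dictionary <- function(training_features, I, seed = 1L) {
  I <- as.integer(I)
  if (is.matrix(training_features)) {
    pooled <- training_features
  } else {
    pooled <- t(vapply(training_features, function(m) {
      stopifnot(inherits(m, "residue_feature_matrix"))
      colMeans(m$features[!m$special_mask, , drop = FALSE])
    }, numeric(ncol(training_features[[1L]]$features))))
  }
  n <- nrow(pooled)
  if (n < I) stop_format("fewer targets (%d) than dictionary size I = %d", n, I)
  if (I == 1L) {
    centers <- matrix(colMeans(pooled), 1L)
    assign_w <- 1
  } else {
    res <- with_seed(seed, {
      init <- kmeanspp_init(pooled, I)
      stats::kmeans(pooled, centers = init, iter.max = 100L,
                    algorithm = "Lloyd")
    })
    centers <- res$centers
    assign_w <- as.numeric(table(factor(res$cluster, levels = seq_len(I)))) / n
  }
  structure(list(centers = unname(centers), weights = as.numeric(assign_w),
                 fit_metadata = list(seed = as.integer(seed), n_targets = n)),
            class = "confounder_dictionary")
}

# k-means++ seeding: iteratively sample new centers proportional to the
# squared distance from the nearest chosen center
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

#' @export
print.confounder_dictionary <- function(x, ...) {
  cat(sprintf("confounder_dictionary: I = %d centers of width %d; weights: %s\n",
              nrow(x$centers), ncol(x$centers),
              paste(sprintf("%.3f", x$weights), collapse = ", ")))
  invisible(x)
}

# ---- forward passes -------------------------------------------------------

encoder_forward <- function(params, cfg, ids, rope) {
  X <- params$emb[ids, , drop = FALSE]
  emb <- X
  caches <- vector("list", cfg$n_enc_layers)
  for (l in seq_len(cfg$n_enc_layers)) {
    p <- params$enc[[l]]
    sa <- nn_mha_fwd(X, X, p$sa, cfg$n_heads, rope)
    ln1 <- nn_layernorm_fwd(X + sa$out, p$ln1$g, p$ln1$b)
    ff <- nn_ffn_fwd(ln1$out, p$ff)
    ln2 <- nn_layernorm_fwd(ln1$out + ff$out, p$ln2$g, p$ln2$b)
    caches[[l]] <- list(sa = sa, ln1 = ln1, ff = ff, ln2 = ln2)
    X <- ln2$out
  }
  list(out = X, emb = emb, ids = ids, layers = caches)
}

encoder_backward <- function(dX, cache, params, cfg) {
  grads <- vector("list", cfg$n_enc_layers)
  for (l in rev(seq_len(cfg$n_enc_layers))) {
    p <- params$enc[[l]]
    cc <- cache$layers[[l]]
    g2 <- nn_layernorm_bwd(dX, cc$ln2)
    fb <- nn_ffn_bwd(g2$dx, cc$ff, p$ff)
    d1 <- g2$dx + fb$dx
    g1 <- nn_layernorm_bwd(d1, cc$ln1)
    sb <- nn_mha_bwd(g1$dx, cc$sa, p$sa)
    dX <- g1$dx + sb$dxq + sb$dxkv
    grads[[l]] <- list(sa = sb$grads,
                       ln1 = list(g = g1$dg, b = g1$db),
                       ff = fb$grads,
                       ln2 = list(g = g2$dg, b = g2$db))
  }
  demb <- rowsum(dX, cache$ids)
  demb_full <- matrix(0, nrow(params$emb), ncol(params$emb))
  demb_full[as.integer(rownames(demb)), ] <- demb
  list(grads = list(emb = demb_full, enc = grads))
}

cam_forward <- function(params, cfg, E, dict) {
  I <- cfg$dict_size
  d_seg <- cfg$d_e %/% I
  C <- dict$centers
  L <- nrow(E)
  if (ncol(E) != cfg$d_e) {
    stop_format("target feature width %d does not match d_e = %d", ncol(E), cfg$d_e)
  }
  if (nrow(C) != I) {
    stop_format("dictionary size %d does not match config dict_size %d", nrow(C), I)
  }
  p <- params$cam
  M <- matrix(0, L, cfg$d_e)
  cache <- list(E = E, C = C, mode = cfg$cam_keys)
  if (cfg$cam_keys == "single") {
    # one center per head: the softmax over a singleton key is identically 1,
    # so each head's output is its value vector broadcast to every position
    V <- C %*% p$Wv
    for (i in seq_len(I)) {
      blk <- (i - 1L) * d_seg + seq_len(d_seg)
      M[, blk] <- rep(V[i, blk], each = L)
    }
    cache$V <- V
  } else {
    Q <- E %*% p$Wq
    K <- C %*% p$Wk
    V <- C %*% p$Wv
    heads <- vector("list", I)
    for (i in seq_len(I)) {
      blk <- (i - 1L) * d_seg + seq_len(d_seg)
      A <- softmax_rows(tcrossprod(Q[, blk, drop = FALSE],
                                   K[, blk, drop = FALSE]) / sqrt(d_seg))
      M[, blk] <- A %*% V[, blk, drop = FALSE]
      heads[[i]] <- A
    }
    cache$Q <- Q
    cache$K <- K
    cache$V <- V
    cache$heads <- heads
  }
  lin <- nn_linear_fwd(M + E, p$Wg, p$bg)
  cache$M <- M
  cache$lin <- lin
  list(out = lin$out, cache = cache)
}

cam_backward <- function(dout, cache, params, cfg) {
  p <- params$cam
  I <- cfg$dict_size
  d_seg <- cfg$d_e %/% I
  lb <- nn_linear_bwd(dout, cache$lin, p$Wg)
  dME <- lb$dx
  grads <- list(Wv = matrix(0, cfg$d_e, cfg$d_e), Wg = lb$dW, bg = lb$db)
  if (cache$mode == "single") {
    for (i in seq_len(I)) {
      blk <- (i - 1L) * d_seg + seq_len(d_seg)
      dVi <- colSums(dME[, blk, drop = FALSE])
      grads$Wv[, blk] <- tcrossprod(cache$C[i, ], dVi)
    }
    dE <- dME  # residual path only; attention weight is constant
  } else {
    dQ <- matrix(0, nrow(cache$E), cfg$d_e)
    dK <- matrix(0, I, cfg$d_e)
    dV <- matrix(0, I, cfg$d_e)
    for (i in seq_len(I)) {
      blk <- (i - 1L) * d_seg + seq_len(d_seg)
      A <- cache$heads[[i]]
      dMblk <- dME[, blk, drop = FALSE]
      dA <- tcrossprod(dMblk, cache$V[, blk, drop = FALSE])
      dV[, blk] <- crossprod(A, dMblk)
      dS <- A * (dA - rowSums(dA * A))
      dQ[, blk] <- dS %*% cache$K[, blk, drop = FALSE] / sqrt(d_seg)
      dK[, blk] <- crossprod(dS, cache$Q[, blk, drop = FALSE]) / sqrt(d_seg)
    }
    grads$Wq <- crossprod(cache$E, dQ)
    grads$Wk <- crossprod(cache$C, dK)
    grads$Wv <- crossprod(cache$C, dV)
    dE <- dME + dQ %*% t(p$Wq)
  }
  list(dE = dE, grads = grads)
}

aggregator_forward <- function(params, cfg, D, Tm, rope) {
  Fm <- D
  caches <- vector("list", cfg$n_agg_layers)
  for (l in seq_len(cfg$n_agg_layers)) {
    p <- params$agg[[l]]
    last <- l == cfg$n_agg_layers
    sa <- nn_mha_fwd(Fm, Fm, p$sa, cfg$n_heads, rope)
    ln1 <- nn_layernorm_fwd(Fm + sa$out, p$ln1$g, p$ln1$b)
    ca <- nn_mha_fwd(ln1$out, Tm, p$ca, cfg$n_heads, NULL)
    ln2 <- nn_layernorm_fwd(ln1$out + ca$out, p$ln2$g, p$ln2$b)
    if (last && cfg$partition_point == "pre_ffn") {
      caches[[l]] <- list(sa = sa, ln1 = ln1, ca = ca, ln2 = ln2, ffn_used = FALSE)
      Fm <- ln2$out
    } else {
      ff <- nn_ffn_fwd(ln2$out, p$ff)
      ln3 <- nn_layernorm_fwd(ln2$out + ff$out, p$ln3$g, p$ln3$b)
      caches[[l]] <- list(sa = sa, ln1 = ln1, ca = ca, ln2 = ln2, ff = ff,
                          ln3 = ln3, ffn_used = TRUE)
      Fm <- ln3$out
    }
  }
  final <- caches[[cfg$n_agg_layers]]
  list(out = Fm, layers = caches,
       self_attention = lapply(final$sa$heads, function(h) h$A),
       cross_attention = lapply(final$ca$heads, function(h) h$A))
}

aggregator_backward <- function(dF, cache, params, cfg) {
  grads <- vector("list", cfg$n_agg_layers)
  dT <- NULL
  for (l in rev(seq_len(cfg$n_agg_layers))) {
    p <- params$agg[[l]]
    cc <- cache$layers[[l]]
    if (cc$ffn_used) {
      g3 <- nn_layernorm_bwd(dF, cc$ln3)
      fb <- nn_ffn_bwd(g3$dx, cc$ff, p$ff)
      d2 <- g3$dx + fb$dx
      ff_g <- fb$grads
      ln3_g <- list(g = g3$dg, b = g3$db)
    } else {
      d2 <- dF
      ff_g <- tree_zero(p$ff)
      ln3_g <- tree_zero(p$ln3)
    }
    g2 <- nn_layernorm_bwd(d2, cc$ln2)
    cb <- nn_mha_bwd(g2$dx, cc$ca, p$ca)
    dT <- if (is.null(dT)) cb$dxkv else dT + cb$dxkv
    d1 <- g2$dx + cb$dxq
    g1 <- nn_layernorm_bwd(d1, cc$ln1)
    sb <- nn_mha_bwd(g1$dx, cc$sa, p$sa)
    dF <- g1$dx + sb$dxq + sb$dxkv
    grads[[l]] <- list(sa = sb$grads, ln1 = list(g = g1$dg, b = g1$db),
                       ca = cb$grads, ln2 = list(g = g2$dg, b = g2$db),
                       ff = ff_g, ln3 = ln3_g)
  }
  list(dD = dF, dT = dT, grads = grads)
}

#' Partition fused features into per-confounder segments
#'
#' Splits the fused feature matrix along its channel dimension into `I`
#' contiguous blocks, one per confounder cluster, in head order. The
#' concatenation of the segments reconstructs the input exactly.
#'
#' @param F numeric matrix `L x D_m` of fused features.
#' @param I number of segments; must divide `ncol(F)`.
#' @return list of `I` matrices of width `D_m / I`.
#' @export
partition_by_confounder <- function(F, I) {
  I <- as.integer(I)
  if (ncol(F) %% I != 0L) {
    stop_format("feature width %d is not divisible by I = %d", ncol(F), I)
  }
  dk <- ncol(F) %/% I
  lapply(seq_len(I), function(i) {
    F[, (i - 1L) * dk + seq_len(dk), drop = FALSE]
  })
}

#' Per-cluster conditional interaction probabilities
#'
#' Masked average pooling over positions of each segment, followed by a
#' shared two-class linear head and a row softmax, giving one
#' `P(Y | D, T, c_i)` row per confounder cluster.
#'
#' @param model a [tapb_model()] (or fitted `tapb`) supplying the shared head.
#' @param segments list of `L x D_k` matrices from [partition_by_confounder()].
#' @param mask optional logical vector over positions; `TRUE` rows enter the
#'   pooling (all rows by default).
#' @return numeric matrix `I x 2`; each row sums to 1.
#' @export
conditional_probabilities <- function(model, segments, mask = NULL) {
  stopifnot(inherits(model, "tapb"))
  L <- nrow(segments[[1L]])
  if (is.null(mask)) mask <- rep(TRUE, L)
  if (!any(mask)) stop_format("pooling mask excludes every position")
  pooled <- t(vapply(segments, function(s) {
    colMeans(s[mask, , drop = FALSE])
  }, numeric(ncol(segments[[1L]]))))
  logits <- addb(pooled %*% model$params$head$Wy, model$params$head$by)
  softmax_rows(logits)
}

#' Backdoor-adjusted interaction probability
#'
#' The interventional prediction
#' `P(Y | D, do(T)) = sum_i P(c_i) P(Y | D, T, c_i)`: an exact weighted sum
#' over the confounder clusters (no geometric-mean approximation).
#'
#' @param conditional numeric matrix `I x 2` of per-cluster probabilities.
#' @param weights adjustment weights `P(c_i)`, summing to 1.
#' @return length-2 probability vector.
#' @export
backdoor_predict <- function(conditional, weights) {
  conditional <- as.matrix(conditional)
  if (nrow(conditional) != length(weights)) {
    stop_format("got %d conditional rows but %d weights",
                nrow(conditional), length(weights))
  }
  if (abs(sum(weights) - 1) > 1e-6) {
    stop_format("adjustment weights must sum to 1")
  }
  as.numeric(crossprod(conditional, weights))
}

#' Binary cross-entropy on a probability row
#'
#' `-sum_i y_i log(p_i)` with a one-hot label and a floor of 1e-12 inside
#' the logarithm.
#'
#' @param prob length-2 probability vector (positions: class 0, class 1).
#' @param label binary label in `{0, 1}`.
#' @return the scalar loss.
#' @export
classification_loss <- function(prob, label) {
  stopifnot(length(prob) == 2L, label %in% c(0, 1))
  -log(pmax(prob[label + 1L], 1e-12))
}

#' Masked-language-model loss on drug tokens
#'
#' `-sum_j m_j log P(w_j | H_j)` over the selected positions, using the
#' token-prediction head over the drug encoder's output states.
#'
#' @param model a [tapb_model()] supplying the token head.
#' @param hidden `L x D_m` matrix of encoder output states.
#' @param mask logical selection mask over positions.
#' @param true_ids integer vector of the original token ids.
#' @param reduce `"sum"` (the raw double sum) or `"mean"` (per selected
#'   token, the scaling used during training).
#' @return the scalar loss; 0 when the mask is empty.
#' @export
mlm_loss <- function(model, hidden, mask, true_ids,
                     reduce = c("sum", "mean")) {
  stopifnot(inherits(model, "tapb"))
  reduce <- match.arg(reduce)
  sel <- which(mask)
  if (length(sel) == 0L) return(0)
  logits <- addb(hidden[sel, , drop = FALSE] %*% model$params$mlm$W,
                 model$params$mlm$b)
  probs <- softmax_rows(logits)
  ll <- -log(pmax(probs[cbind(seq_along(sel), true_ids[sel])], 1e-12))
  if (reduce == "sum") sum(ll) else mean(ll)
}

#' Total training loss
#'
#' `L = L_b + L_mlm` with unit weights; the MLM term is dropped when the
#' `use_mlm` ablation flag is off.
#'
#' @param l_b classification loss.
#' @param l_mlm MLM loss.
#' @param config a [tapb_config()].
#' @return the scalar total loss.
#' @export
total_loss <- function(l_b, l_mlm, config) {
  stopifnot(is.finite(l_b), is.finite(l_mlm))
  if (isTRUE(config$use_mlm)) l_b + l_mlm else l_b
}

# ---- whole-model forward / backward (single sample) -----------------------

target_to_model_space <- function(params, cfg, E, dict) {
  if (cfg$use_cam) {
    cam_forward(params, cfg, E, dict)
  } else {
    lin <- nn_linear_fwd(E, params$nocam$Wg, params$nocam$bg)
    list(out = lin$out, cache = list(lin = lin, mode = "none"))
  }
}

model_forward_sample <- function(params, cfg, ids, E, dict, rope,
                                 mlm_mask = NULL, true_ids = NULL,
                                 keep_caches = FALSE) {
  enc <- encoder_forward(params, cfg, ids, rope)
  tgt <- target_to_model_space(params, cfg, E, dict)
  agg <- aggregator_forward(params, cfg, enc$out, tgt$out, rope)
  I <- cfg$dict_size
  dk <- cfg$d_m %/% I
  Fm <- agg$out
  L <- nrow(Fm)
  pooled_seg <- matrix(0, I, dk)
  for (i in seq_len(I)) {
    pooled_seg[i, ] <- colMeans(Fm[, (i - 1L) * dk + seq_len(dk), drop = FALSE])
  }
  cond_logits <- addb(pooled_seg %*% params$head$Wy, params$head$by)
  cond <- softmax_rows(cond_logits)
  backdoor <- as.numeric(crossprod(cond, dict$weights))
  pooled_full <- colMeans(Fm)
  plain_logits <- pooled_full %*% params$headp$Wy + params$headp$by
  plain <- as.numeric(softmax_rows(plain_logits))
  mlm <- NULL
  if (!is.null(mlm_mask) && any(mlm_mask)) {
    sel <- which(mlm_mask)
    logits <- addb(enc$out[sel, , drop = FALSE] %*% params$mlm$W, params$mlm$b)
    probs <- softmax_rows(logits)
    mlm <- list(sel = sel, probs = probs, true = true_ids[sel])
  }
  out <- list(conditional = cond, backdoor = backdoor, plain = plain,
              mlm = mlm, pooled_seg = pooled_seg, pooled_full = pooled_full,
              self_attention = agg$self_attention,
              cross_attention = agg$cross_attention,
              D = enc$out, T = tgt$out, F = Fm)
  if (keep_caches) {
    out$caches <- list(enc = enc, tgt = tgt, agg = agg, L = L)
  }
  out
}

# gradient of the per-sample loss w.r.t. every parameter; the target feature
# provider and dictionary centers are fixed buffers, so backprop stops at E
model_backward_sample <- function(fwd, params, cfg, dict, label,
                                  cls_weight = 1, mlm_weight = 1) {
  caches <- fwd$caches
  L <- caches$L
  I <- cfg$dict_size
  dk <- cfg$d_m %/% I
  grads <- list()
  y1 <- label + 1L
  dF <- matrix(0, L, cfg$d_m)
  if (cfg$use_backdoor) {
    dpred <- numeric(2L)
    dpred[y1] <- -cls_weight / max(fwd$backdoor[y1], 1e-12)
    dcond <- tcrossprod(dict$weights, dpred)        # I x 2
    s <- fwd$conditional
    dlog <- s * (dcond - rowSums(dcond * s))        # softmax rows backward
    grads$head <- list(Wy = crossprod(fwd$pooled_seg, dlog),
                       by = colSums(dlog))
    grads$headp <- tree_zero(params$headp)
    dpooled <- dlog %*% t(params$head$Wy)           # I x dk
    for (i in seq_len(I)) {
      dF[, (i - 1L) * dk + seq_len(dk)] <-
        rep(dpooled[i, ] / L, each = L)
    }
  } else {
    dpred <- numeric(2L)
    dpred[y1] <- -cls_weight / max(fwd$plain[y1], 1e-12)
    s <- fwd$plain
    dlog <- s * (dpred - sum(dpred * s))
    grads$headp <- list(Wy = tcrossprod(fwd$pooled_full, dlog),
                        by = dlog)
    grads$head <- tree_zero(params$head)
    dpooled <- as.numeric(params$headp$Wy %*% dlog)
    dF <- dF + rep(dpooled / L, each = L)
  }
  ab <- aggregator_backward(dF, caches$agg, params, cfg)
  grads$agg <- ab$grads
  # MLM branch: gradient of -sum log p at selected positions w.r.t. logits
  dD_extra <- NULL
  if (cfg$use_mlm && !is.null(fwd$mlm)) {
    m <- fwd$mlm
    dlogits <- m$probs
    dlogits[cbind(seq_along(m$sel), m$true)] <-
      dlogits[cbind(seq_along(m$sel), m$true)] - 1
    dlogits <- dlogits * mlm_weight
    H_sel <- caches$enc$out[m$sel, , drop = FALSE]
    grads$mlm <- list(W = crossprod(H_sel, dlogits), b = colSums(dlogits))
    dD_extra <- matrix(0, L, cfg$d_m)
    dD_extra[m$sel, ] <- dlogits %*% t(params$mlm$W)
  } else {
    grads$mlm <- tree_zero(params$mlm)
  }
  dD <- ab$dD + if (is.null(dD_extra)) 0 else dD_extra
  if (cfg$use_cam) {
    cb <- cam_backward(ab$dT, caches$tgt$cache, params, cfg)
    grads$cam <- cb$grads
  } else {
    lb <- nn_linear_bwd(ab$dT, caches$tgt$cache$lin, params$nocam$Wg)
    grads$nocam <- list(Wg = lb$dW, bg = lb$db)
  }
  eb <- encoder_backward(dD, caches$enc, params, cfg)
  grads$emb <- eb$grads$emb
  grads$enc <- eb$grads$enc
  # order fields like params for tree arithmetic
  grads[names(params)]
}
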