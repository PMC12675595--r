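# ---- sample preparation ---------------------------------------------------

truncate_rfm <- function(m, max_len) {
  if (nrow(m$features) <= max_len) return(m)
  idx <- seq_len(max_len)
  residue_feature_matrix(m$features[idx, , drop = FALSE],
                         m$special_mask[idx],
                         if (is.null(m$residue_types)) NULL else m$residue_types[idx])
}

prep_samples <- function(dataset, vocab, provider, cfg) {
  r <- dataset$records
  useq <- unique(r$sequence)
  feats <- lapply(useq, function(s) {
    truncate_rfm(provide_target_features(provider, s), cfg$max_len_target)
  })
  names(feats) <- useq
  usmi <- unique(r$smiles)
  ids <- lapply(usmi, smiles_encode, vocab = vocab, max_len = cfg$max_len_drug)
  names(ids) <- usmi
  list(ids = ids, feats = feats, drug_key = r$smiles, target_key = r$sequence,
       labels = r$label)
}

# letter-mean dictionary tolerant of letters absent from small training sets
build_aa_dict_lenient <- function(training_features) {
  out <- tryCatch(build_amino_acid_dictionary(training_features),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  sums <- NULL
  counts <- NULL
  for (m in training_features) {
    keep <- !m$special_mask & m$residue_types %in% AA20
    if (!any(keep)) next
    agg <- rowsum(m$features[keep, , drop = FALSE], m$residue_types[keep])
    cnt <- table(m$residue_types[keep])
    if (is.null(sums)) {
      sums <- matrix(0, length(AA20), ncol(m$features), dimnames = list(AA20, NULL))
      counts <- stats::setNames(numeric(length(AA20)), AA20)
    }
    sums[rownames(agg), ] <- sums[rownames(agg), , drop = FALSE] + agg
    counts[names(cnt)] <- counts[names(cnt)] + as.numeric(cnt)
  }
  present <- counts > 0
  structure((sums / pmax(counts, 1))[present, , drop = FALSE],
            class = "aa_dictionary")
}

adam_step <- function(p, g, m, v, lr, b1, b2, eps, bc1, bc2) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      r <- adam_step(p[[i]], g[[i]], m[[i]], v[[i]], lr, b1, b2, eps, bc1, bc2)
      p[[i]] <- r$p
      m[[i]] <- r$m
      v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
  }
}

# forward-only scores (clean inputs, no augmentation): P(interaction)
scores_internal <- function(params, cfg, dict, samples, rope, engine = "cpp") {
  n <- length(samples$labels)
  if (engine == "cpp") {
    slist <- lapply(seq_len(n), function(k) {
      list(ids = samples$ids[[samples$drug_key[k]]],
           E = samples$feats[[samples$target_key[k]]]$features)
    })
    return(tapb_scores_cpp(params, unclass(cfg), dict$centers, dict$weights,
                           rope$cos, rope$sin, slist, 0L, FALSE)$scores)
  }
  out <- numeric(n)
  for (k in seq_len(n)) {
    fwd <- model_forward_sample(
      params, cfg, samples$ids[[samples$drug_key[k]]],
      samples$feats[[samples$target_key[k]]]$features, dict, rope)
    out[k] <- if (cfg$use_backdoor) fwd$backdoor[2L] else fwd$plain[2L]
  }
  out
}

#' Construct an untrained TAPB model
#'
#' Initializes model parameters for a given configuration; useful for
#' exercising the architectural components before or without training.
#'
#' @param config a [tapb_config()].
#' @param vocab a [build_vocab()] SMILES vocabulary.
#' @param dict a [build_confounder_dictionary()]; when `NULL`, a single-use
#'   dictionary of standard-normal centers with uniform weights is created.
#' @param provider a target feature provider; the toy embedder by default.
#' @param seed integer seed for parameter initialization.
#' @return an object of class `tapb` (untrained).
#' @export
tapb_model <- function(config = tapb_config(), vocab, dict = NULL,
                       provider = NULL, seed = 1L) {
  stopifnot(inherits(config, "tapb_config"), inherits(vocab, "smiles_vocab"))
  if (is.null(provider)) provider <- toy_target_embedder(config$d_e)
  if (is.null(dict)) {
    dict <- with_seed(seed, structure(list(
      centers = matrix(stats::rnorm(config$dict_size * config$d_e),
                       config$dict_size, config$d_e),
      weights = rep(1 / config$dict_size, config$dict_size),
      fit_metadata = list(seed = as.integer(seed), n_targets = 0L)),
      class = "confounder_dictionary"))
  }
  params <- with_seed(seed + 1L, init_params(config, length(vocab$tokens)))
  structure(list(params = params, config = config, vocab = vocab,
                 dict = dict, provider = provider, aa_dict = NULL,
                 seed = as.integer(seed), trained = FALSE, history = NULL),
            class = "tapb")
}

#' Fit a TAPB model
#'
#' Trains the interventional DTI model on a training set with Adam,
#' minimizing the backdoor-adjusted (or plain, under ablation) binary
#' cross-entropy plus, when enabled, the drug masked-language-model loss.
#' Amino-acid randomization and MLM corruption are redrawn fresh every
#' epoch. When a validation set is supplied, the checkpoint with the highest
#' validation AUROC is kept.
#'
#' @param train,valid training and optional validation [dti_dataset()]s.
#' @param config a [tapb_config()].
#' @param provider target feature provider; the deterministic toy embedder
#'   at width `config$d_e` by default.
#' @param epochs,batch_size,lr optimization settings.
#' @param clip_norm global gradient-norm clipping threshold (`Inf` disables).
#' @param warmup_frac fraction of total updates over which the learning rate
#'   ramps linearly from 0 to `lr`.
#' @param seed integer seed governing all randomness of the fit
#'   (initialization, shuffling, augmentation, dictionary clustering).
#' @param verbose print a line per epoch.
#' @return a fitted object of class `tapb` with a training `history`.
#' @export
tapb_fit <- function(train, valid = NULL, config = tapb_config(),
                     provider = NULL, epochs = 8L, batch_size = 16L,
                     lr = 1e-3, clip_norm = 1, warmup_frac = 0.05,
                     seed = 1L, verbose = FALSE,
                     engine = c("cpp", "r")) {
  stopifnot(inherits(train, "dti_dataset"), inherits(config, "tapb_config"))
  engine <- match.arg(engine)
  if (is.null(provider)) provider <- toy_target_embedder(config$d_e)
  with_seed(seed, {
    vocab <- build_vocab(unique(train$records$smiles))
    samples <- prep_samples(train, vocab, provider, config)
    vsamples <- if (!is.null(valid)) prep_samples(valid, vocab, provider, config)
    aa_dict <- build_aa_dict_lenient(samples$feats)
    dict <- build_confounder_dictionary(samples$feats, config$dict_size,
                                        seed = seed)
    params <- init_params(config, length(vocab$tokens))
    rope <- rope_cache(config$max_len_drug, config$d_m %/% config$n_heads)
    mstate <- tree_zero(params)
    vstate <- tree_zero(params)
    step <- 0L
    n <- length(samples$labels)
    n_updates <- epochs * ceiling(n / batch_size)
    warmup_steps <- max(1L, floor(warmup_frac * n_updates))
    hist <- data.frame(epoch = integer(0), loss_cls = numeric(0),
                       loss_mlm = numeric(0), val_auroc = numeric(0))
    best <- list(params = params, auroc = -Inf, epoch = 0L)
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_cls <- 0
      ep_mlm <- 0
      ep_masked <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        batch <- perm[start:min(start + batch_size - 1L, n)]
        nb <- length(batch)
        binputs <- vector("list", nb)
        total_masked <- 0L
        for (j in seq_len(nb)) {
          k <- batch[j]
          ids0 <- samples$ids[[samples$drug_key[k]]]
          E0 <- samples$feats[[samples$target_key[k]]]
          if (config$use_randomization) {
            E0 <- randomize_target_features(E0, config$deletion_ratio,
                                            config$mutation_rate, aa_dict)
          }
          if (config$use_mlm) {
            mc <- mlm_corrupt(ids0, vocab, config$mlm_select_rate,
                              config$mlm_mask_frac, config$mlm_keep_frac,
                              config$mlm_random_frac)
            binputs[[j]] <- list(ids = mc$ids, sel = which(mc$mask),
                                 true_ids = ids0, E = E0$features,
                                 y = samples$labels[k])
            total_masked <- total_masked + sum(mc$mask)
          } else {
            binputs[[j]] <- list(ids = ids0, sel = integer(0),
                                 true_ids = ids0, E = E0$features,
                                 y = samples$labels[k])
          }
        }
        mlm_w <- if (total_masked > 0L) 1 / total_masked else 0
        if (engine == "cpp") {
          res <- tapb_batch_cpp(params, unclass(config), dict$centers,
                                dict$weights, rope$cos, rope$sin, binputs,
                                1 / nb, mlm_w)
          if (!is.finite(res$loss_cls)) {
            stop_format("training diverged (non-finite loss) at epoch %d", epoch)
          }
          gacc <- res$grads
          ep_cls <- ep_cls + res$loss_cls
          ep_mlm <- ep_mlm + res$loss_mlm
          ep_masked <- ep_masked + res$n_masked
        } else {
        gacc <- NULL
        for (j in seq_len(nb)) {
          bi <- binputs[[j]]
          mask <- rep(FALSE, length(bi$true_ids))
          mask[bi$sel] <- TRUE
          fwd <- model_forward_sample(params, config, bi$ids, bi$E, dict,
                                      rope, if (config$use_mlm) mask,
                                      bi$true_ids, keep_caches = TRUE)
          pred <- if (config$use_backdoor) fwd$backdoor else fwd$plain
          l_cls <- -log(max(pred[bi$y + 1L], 1e-12))
          if (!is.finite(l_cls)) {
            stop_format("training diverged (non-finite loss) at epoch %d", epoch)
          }
          ep_cls <- ep_cls + l_cls
          if (!is.null(fwd$mlm)) {
            lm <- -sum(log(pmax(
              fwd$mlm$probs[cbind(seq_along(fwd$mlm$sel), fwd$mlm$true)],
              1e-12)))
            ep_mlm <- ep_mlm + lm
            ep_masked <- ep_masked + length(fwd$mlm$sel)
          }
          g <- model_backward_sample(
            fwd, params, config, dict, bi$y,
            cls_weight = 1 / nb, mlm_weight = mlm_w)
          gacc <- if (is.null(gacc)) g else tree_add(gacc, g)
        }
        }
        step <- step + 1L
        if (is.finite(clip_norm)) {
          gnorm <- sqrt(sum(unlist(gacc, use.names = FALSE)^2))
          if (gnorm > clip_norm) gacc <- tree_scale(gacc, clip_norm / gnorm)
        }
        lr_t <- if (step < warmup_steps) lr * step / warmup_steps else lr
        r <- adam_step(params, gacc, mstate, vstate, lr_t, 0.9, 0.999, 1e-8,
                       1 - 0.9^step, 1 - 0.999^step)
        params <- r$p
        mstate <- r$m
        vstate <- r$v
      }
      val_auroc <- NA_real_
      if (!is.null(valid) && length(unique(vsamples$labels)) > 1L) {
        vs <- scores_internal(params, config, dict, vsamples, rope, engine)
        val_auroc <- auroc(vs, vsamples$labels)
        if (val_auroc > best$auroc) {
          best <- list(params = params, auroc = val_auroc, epoch = epoch)
        }
      }
      hist <- rbind(hist, data.frame(
        epoch = epoch, loss_cls = ep_cls / n,
        loss_mlm = if (ep_masked > 0L) ep_mlm / ep_masked else 0,
        val_auroc = val_auroc))
      if (verbose) {
        message(sprintf("epoch %d: loss_cls %.4f loss_mlm %.4f val_auroc %s",
                        epoch, ep_cls / n,
                        if (ep_masked > 0L) ep_mlm / ep_masked else 0,
                        ifelse(is.na(val_auroc), "-", sprintf("%.4f", val_auroc))))
      }
    }
    final_params <- if (is.finite(best$auroc)) best$params else params
    structure(list(params = final_params, config = config, vocab = vocab,
                   dict = dict, provider = provider, aa_dict = aa_dict,
                   seed = as.integer(seed), trained = TRUE, history = hist,
                   best_epoch = if (is.finite(best$auroc)) best$epoch else epochs,
                   epochs = epochs, lr = lr, batch_size = batch_size,
                   engine = engine),
              class = "tapb")
  })
}

#' @export
print.tapb <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "TAPB model (%s): d_m = %d, H = I = %d, enc %d / agg %d layers\n",
    if (isTRUE(x$trained)) "trained" else "untrained",
    cfg$d_m, cfg$n_heads, cfg$n_enc_layers, cfg$n_agg_layers))
  cat(sprintf("flags: randomization %s, mlm %s, cam %s, backdoor %s\n",
              cfg$use_randomization, cfg$use_mlm, cfg$use_cam, cfg$use_backdoor))
  if (!is.null(x$history) && nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("epochs: %d (best %s), final loss %.4f\n",
                nrow(x$history),
                if (!is.null(x$best_epoch)) x$best_epoch else "-",
                last$loss_cls))
  }
  invisible(x)
}

#' @export
summary.tapb <- function(object, ...) {
  out <- list(config = object$config, history = object$history,
              dict_weights = object$dict$weights,
              n_params = sum(unlist(tree_map(length, object$params))))
  class(out) <- "summary.tapb"
  out
}

#' @export
print.summary.tapb <- function(x, ...) {
  cat(sprintf("TAPB model, %d parameters\n", x$n_params))
  cat(sprintf("confounder weights: %s\n",
              paste(sprintf("%.3f", x$dict_weights), collapse = ", ")))
  if (!is.null(x$history) && nrow(x$history)) {
    print(x$history)
  }
  invisible(x)
}

#' @export
coef.tapb <- function(object, ...) {
  object$params
}

#' Plot training history
#'
#' Classification loss per epoch, with validation AUROC on a second panel
#' when recorded.
#'
#' @param x a fitted `tapb`.
#' @param ... ignored.
#' @export
plot.tapb <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop_format("no training history to plot")
  has_val <- any(is.finite(h$val_auroc))
  op <- graphics::par(mfrow = c(1L, 1L + has_val))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss_cls, type = "b", xlab = "epoch",
                 ylab = "classification loss", main = "training loss")
  if (has_val) {
    graphics::plot(h$epoch, h$val_auroc, type = "b", xlab = "epoch",
                   ylab = "validation AUROC", main = "validation")
  }
  invisible(x)
}

#' Predict interaction probabilities
#'
#' Scores new drug-target pairs with a fitted (or initialized) model.
#' `type = "score"` returns the positive-class probability from the active
#' prediction path (backdoor-adjusted when enabled), `"class"` thresholds
#' it, and `"bundle"` returns the full per-pair prediction bundle with
#' per-cluster conditionals and attention maps.
#'
#' @param object a `tapb` model.
#' @param newdata a [dti_dataset()].
#' @param type `"score"`, `"class"` or `"bundle"`.
#' @param threshold decision threshold for `type = "class"`.
#' @param ... ignored.
#' @return numeric vector, integer vector, or list of `prediction_bundle`s.
#' @export
predict.tapb <- function(object, newdata, type = c("score", "class", "bundle"),
                         threshold = 0.5, ...) {
  stopifnot(inherits(newdata, "dti_dataset"))
  type <- match.arg(type)
  cfg <- object$config
  samples <- prep_samples(newdata, object$vocab, object$provider, cfg)
  rope <- rope_cache(cfg$max_len_drug, cfg$d_m %/% cfg$n_heads)
  if (type != "bundle") {
    engine <- if (is.null(object$engine)) "cpp" else object$engine
    sc <- scores_internal(object$params, cfg, object$dict, samples, rope,
                          engine)
    if (type == "score") return(sc)
    return(as.integer(sc >= threshold))
  }
  lapply(seq_len(length(samples$labels)), function(k) {
    fwd <- model_forward_sample(
      object$params, cfg, samples$ids[[samples$drug_key[k]]],
      samples$feats[[samples$target_key[k]]]$features, object$dict, rope)
    structure(list(conditional_probs = fwd$conditional,
                   backdoor_prob = fwd$backdoor,
                   plain_prob = fwd$plain,
                   drug_attention = fwd$self_attention,
                   target_attention = fwd$cross_attention),
              class = "prediction_bundle")
  })
}

#' @export
print.prediction_bundle <- function(x, ...) {
  cat(sprintf("prediction_bundle: P(Y|D,do(T)) = (%.4f, %.4f) over %d clusters\n",
              x$backdoor_prob[1L], x$backdoor_prob[2L],
              nrow(x$conditional_probs)))
  invisible(x)
}

#' Export attention maps as JSON
#'
#' Writes a bundle's final-layer attention maps keyed by head index, for
#' downstream interpretability visualization.
#'
#' @param bundle a `prediction_bundle` from [predict.tapb()].
#' @param path output path; when `NULL` the JSON string is returned.
#' @return invisibly `path`, or the JSON string.
#' @export
attention_to_json <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "prediction_bundle"))
  payload <- list(
    drug_attention = stats::setNames(bundle$drug_attention,
                                     paste0("head_", seq_along(bundle$drug_attention))),
    target_attention = stats::setNames(bundle$target_attention,
                                       paste0("head_", seq_along(bundle$target_attention)))
  )
  json <- jsonlite::toJSON(payload, digits = NA)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

#' Evaluate a model on a test set
#'
#' AUROC/AUPRC from raw scores; accuracy, sensitivity and specificity at
#' the Youden threshold calibrated on a separate split (the validation set
#' by convention; the test set itself when no calibration set is given).
#'
#' @param model a fitted `tapb`.
#' @param test_set test [dti_dataset()] (both classes required).
#' @param calibration_set optional [dti_dataset()] for threshold fitting.
#' @return a `tapb_metrics` object.
#' @export
evaluate_dti <- function(model, test_set, calibration_set = NULL) {
  stopifnot(inherits(model, "tapb"))
  lab <- test_set$records$label
  if (length(unique(lab)) < 2L) {
    stop_format("AUROC undefined: test labels contain a single class")
  }
  sc <- predict(model, test_set)
  if (is.null(calibration_set)) {
    classification_metrics(sc, lab)
  } else {
    csc <- predict(model, calibration_set)
    classification_metrics(sc, lab, csc, calibration_set$records$label)
  }
}

#' Random-feature bias probe
#'
#' Replaces one branch's features with standard-normal noise of matching
#' shape and measures how predictive the remaining branch still is: in
#' `"target_random"` mode the target feature tensor entering the aggregator
#' is replaced (probing drug-side reliance is gone; what remains is the
#' target-independent signal), and vice versa for `"drug_random"`. Reported
#' are the AUROC of probe scores against the true labels and the normalized
#' distance between class centroids in the pooled classification-feature
#' space; a model free of the probed bias stays near chance (0.5 AUROC,
#' near-zero separation).
#'
#' @param model a fitted `tapb`.
#' @param dataset a [dti_dataset()].
#' @param mode `"target_random"` (probes target bias via (T, R)... drug kept)
#'   or `"drug_random"`.
#' @param replicates independent noise draws per pair; scores and features
#'   are averaged over replicates.
#' @param seed integer seed for the noise.
#' @param return_embedding also return a 2D principal-component embedding of
#'   the pooled features for visualization.
#' @return a `probe_result` with `score_label_auroc`, `feature_separation`,
#'   `scores`, `labels`, and optionally `embedding_2d`.
#' @export
bias_probe <- function(model, dataset, mode = c("target_random", "drug_random"),
                       replicates = 1L, seed = 1L, return_embedding = FALSE) {
  stopifnot(inherits(model, "tapb"), inherits(dataset, "dti_dataset"))
  mode <- match.arg(mode)
  cfg <- model$config
  params <- model$params
  dict <- model$dict
  samples <- prep_samples(dataset, model$vocab, model$provider, cfg)
  rope <- rope_cache(cfg$max_len_drug, cfg$d_m %/% cfg$n_heads)
  n <- length(samples$labels)
  with_seed(seed, {
    scores <- numeric(n)
    feats <- matrix(0, n, cfg$d_m)
    for (k in seq_len(n)) {
      ids <- samples$ids[[samples$drug_key[k]]]
      E <- samples$feats[[samples$target_key[k]]]$features
      D <- encoder_forward(params, cfg, ids, rope)$out
      Tm <- target_to_model_space(params, cfg, E, dict)$out
      for (rep_i in seq_len(replicates)) {
        if (mode == "target_random") {
          Tm_use <- matrix(stats::rnorm(length(Tm)), nrow(Tm), ncol(Tm))
          D_use <- D
        } else {
          D_use <- matrix(stats::rnorm(length(D)), nrow(D), ncol(D))
          Tm_use <- Tm
        }
        agg <- aggregator_forward(params, cfg, D_use, Tm_use, rope)
        Fm <- agg$out
        I <- cfg$dict_size
        dk <- cfg$d_m %/% I
        pooled_seg <- matrix(0, I, dk)
        for (i in seq_len(I)) {
          pooled_seg[i, ] <- colMeans(Fm[, (i - 1L) * dk + seq_len(dk),
                                         drop = FALSE])
        }
        cond <- softmax_rows(addb(pooled_seg %*% params$head$Wy,
                                  params$head$by))
        pred <- if (cfg$use_backdoor) {
          as.numeric(crossprod(cond, dict$weights))
        } else {
          as.numeric(softmax_rows(colMeans(Fm) %*% params$headp$Wy +
                                    params$headp$by))
        }
        scores[k] <- scores[k] + pred[2L] / replicates
        feats[k, ] <- feats[k, ] + colMeans(Fm) / replicates
      }
    }
    lab <- samples$labels
    sep <- if (length(unique(lab)) > 1L) {
      c1 <- colMeans(feats[lab == 1L, , drop = FALSE])
      c0 <- colMeans(feats[lab == 0L, , drop = FALSE])
      pooled_sd <- sqrt(mean(c(apply(feats[lab == 1L, , drop = FALSE], 2L, stats::var),
                               apply(feats[lab == 0L, , drop = FALSE], 2L, stats::var))))
      sqrt(sum((c1 - c0)^2)) / max(pooled_sd, 1e-12)
    } else {
      NA_real_
    }
    out <- list(mode = mode,
                score_label_auroc = if (length(unique(lab)) > 1L) auroc(scores, lab) else NA_real_,
                feature_separation = sep,
                scores = scores, labels = lab,
                replicates = as.integer(replicates), seed = as.integer(seed))
    if (return_embedding) {
      pc <- stats::prcomp(feats, rank. = 2L)
      out$embedding_2d <- data.frame(pc1 = pc$x[, 1L], pc2 = pc$x[, 2L],
                                     label = lab)
    }
    structure(out, class = "probe_result")
  })
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("bias probe (%s, %d replicate%s): score-label AUROC = %.4f, feature separation = %.4f\n",
              x$mode, x$replicates, if (x$replicates > 1L) "s" else "",
              x$score_label_auroc, x$feature_separation))
  invisible(x)
}

# ---- standalone architectural operations ----------------------------------

#' Encode a drug token sequence
#'
#' Runs the BERT-style drug encoder (token embedding plus rotary-position
#' self-attention blocks) in evaluation mode.
#'
#' @param model a `tapb` model.
#' @param token_ids integer token ids (from [smiles_encode()]).
#' @return numeric matrix `L_d x D_m`.
#' @export
encode_drug <- function(model, token_ids) {
  stopifnot(inherits(model, "tapb"))
  cfg <- model$config
  if (any(token_ids < 1L | token_ids > nrow(model$params$emb))) {
    stop_format("token id out of vocabulary range")
  }
  if (length(token_ids) > cfg$max_len_drug) {
    stop_format("drug sequence longer than max_len_drug = %d", cfg$max_len_drug)
  }
  rope <- rope_cache(cfg$max_len_drug, cfg$d_m %/% cfg$n_heads)
  encoder_forward(model$params, cfg, token_ids, rope)$out
}

#' Align target features with the confounder dictionary
#'
#' Applies the confounder alignment module: every cluster center acts as
#' key/value for its attention head against the target residue features,
#' followed by a residual connection and the linear map into model space.
#' Under the `use_cam = FALSE` ablation an independent linear projection is
#' used instead (no dictionary path).
#'
#' @param model a `tapb` model.
#' @param E a [residue_feature_matrix()] or plain `L_t x D_e` matrix.
#' @return numeric matrix `L_t x D_m`.
#' @export
confounder_align <- function(model, E) {
  stopifnot(inherits(model, "tapb"))
  if (inherits(E, "residue_feature_matrix")) E <- E$features
  target_to_model_space(model$params, model$config, E, model$dict)$out
}

#' Aggregate drug and target features
#'
#' Runs the stacked aggregator blocks (rotary self-attention on the fused
#' state, multi-head cross-attention with the target features as keys and
#' values, then a feed-forward block, each with residual connection and
#' layer normalization) and returns the fused features with the final
#' layer's attention maps.
#'
#' @param model a `tapb` model.
#' @param D drug features `L_d x D_m` from [encode_drug()].
#' @param Tm target features `L_t x D_m` from [confounder_align()].
#' @return list with `F` (`L_d x D_m`), `drug_attention` and
#'   `target_attention` (per-head maps of the final layer).
#' @export
aggregate_features <- function(model, D, Tm) {
  stopifnot(inherits(model, "tapb"))
  if (nrow(D) == 0L || nrow(Tm) == 0L) stop_format("empty input to aggregator")
  cfg <- model$config
  rope <- rope_cache(max(cfg$max_len_drug, nrow(D)), cfg$d_m %/% cfg$n_heads)
  agg <- aggregator_forward(model$params, cfg, D, Tm, rope)
  list(F = agg$out, drug_attention = agg$self_attention,
       target_attention = agg$cross_attention)
}
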