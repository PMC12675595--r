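test_that("training reduces the classification loss on a small biased set", {
  d <- generate_synthetic(synthetic_config(
    n_drugs = 30L, n_targets = 10L, n_pairs = 200L, target_bias = 1,
    mechanism_weight = 0, extreme_eps = 0.02, seed = 21L))
  cfg <- tapb_variant("base", d_m = 16L, d_e = 16L, n_heads = 2L,
                      n_enc_layers = 1L, n_agg_layers = 1L)
  fit <- tapb_fit(d, config = cfg, epochs = 5L, lr = 3e-3, batch_size = 8L,
                  seed = 2L)
  expect_lt(fit$history$loss_cls[5L], fit$history$loss_cls[1L])
  expect_s3_class(fit, "tapb")
  expect_true(fit$trained)
})

test_that("fits are deterministic given the seed", {
  d <- tiny_dataset(60L, seed = 3L)
  cfg <- tapb_variant("full", d_m = 8L, d_e = 8L, n_heads = 2L,
                      n_enc_layers = 1L, n_agg_layers = 1L)
  f1 <- tapb_fit(d, config = cfg, epochs = 2L, seed = 7L)
  f2 <- tapb_fit(d, config = cfg, epochs = 2L, seed = 7L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(predict(f1, d), predict(f2, d))
})

test_that("ablation with all flags off predicts through the plain path", {
  d <- tiny_dataset(40L, seed = 9L)
  cfg <- tapb_variant("base", d_m = 8L, d_e = 8L, n_heads = 2L,
                      n_enc_layers = 1L, n_agg_layers = 1L)
  fit <- tapb_fit(d, config = cfg, epochs = 1L, seed = 1L)
  sc <- predict(fit, d)
  bundles <- predict(fit, d, type = "bundle")
  expect_equal(sc, vapply(bundles, function(b) b$plain_prob[2L], numeric(1)),
               tolerance = 1e-10)
  # the full model predicts through the backdoor-adjusted path instead
  cfgF <- tapb_variant("full", d_m = 8L, d_e = 8L, n_heads = 2L,
                       n_enc_layers = 1L, n_agg_layers = 1L)
  fitF <- tapb_fit(d, config = cfgF, epochs = 1L, seed = 1L)
  scF <- predict(fitF, d)
  bundlesF <- predict(fitF, d, type = "bundle")
  expect_equal(scF, vapply(bundlesF, function(b) b$backdoor_prob[2L],
                           numeric(1)), tolerance = 1e-10)
  for (b in bundlesF) {
    expect_equal(rowSums(b$conditional_probs),
                 rep(1, nrow(b$conditional_probs)), tolerance = 1e-6)
    expect_equal(sum(b$backdoor_prob), 1, tolerance = 1e-6)
  }
})

test_that("youden threshold matches exhaustive search", {
  set.seed(8)
  for (i in 1:10) {
    scores <- round(runif(30L), 2L)
    labels <- rbinom(30L, 1L, 0.5)
    if (length(unique(labels)) < 2L) next
    thr <- youden_threshold(scores, labels)
    j_at <- function(t) {
      mean(scores[labels == 1L] >= t) + mean(scores[labels == 0L] < t) - 1
    }
    best <- max(vapply(sort(unique(scores)), j_at, numeric(1)))
    expect_equal(j_at(thr), best, tolerance = 1e-12)
    # ties break toward the lower threshold
    cands <- sort(unique(scores))
    expect_equal(thr, cands[which(vapply(cands, j_at, numeric(1)) >=
                                    best - 1e-12)][1L])
  }
  expect_equal(youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.8)
  expect_error(youden_threshold(1:4, rep(1, 4)), "one class")
})

test_that("classification metrics match independent computations", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.5, 0.4, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 0, 1, 0, 1, 0, 0, 1, 0)
  m <- classification_metrics(scores, labels)
  # rank-based AUROC against the pROC reference implementation
  ref <- suppressMessages(pROC::auc(labels, scores))
  expect_equal(m$auroc, as.numeric(ref), tolerance = 1e-10)
  # AUPRC against a direct precision/recall step sum
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  prec <- cumsum(lab) / seq_along(lab)
  rec <- cumsum(lab) / sum(lab)
  ap <- sum(diff(c(0, rec)) * prec)
  expect_equal(m$auprc, ap, tolerance = 1e-10)
  expect_equal(m$accuracy, mean((scores >= m$threshold) == labels))

  expect_equal(auroc(labels, labels), 1)
  expect_error(auroc(scores, rep(1, 10L)), "one class")

  agg <- aggregate_metrics(list(m, m))
  expect_equal(nrow(attr(agg, "per_seed")), 2L)
  expect_equal(agg$sd, rep(0, 5L))
})

test_that("random scores sit at chance level", {
  set.seed(13)
  aucs <- replicate(50L, auroc(runif(40L), rep(c(0, 1), 20L)))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the bias probe perturbs exactly one branch and is reproducible", {
  d <- tiny_dataset(30L, seed = 12L)
  cfg <- tapb_variant("base", d_m = 8L, d_e = 8L, n_heads = 2L,
                      n_enc_layers = 1L, n_agg_layers = 1L)
  fit <- tapb_fit(d, config = cfg, epochs = 1L, seed = 1L)
  p1 <- bias_probe(fit, d, "target_random", seed = 4L)
  p2 <- bias_probe(fit, d, "target_random", seed = 4L)
  expect_identical(p1$scores, p2$scores)
  expect_s3_class(p1, "probe_result")
  expect_true(is.finite(p1$score_label_auroc))
  pd <- bias_probe(fit, d, "drug_random", seed = 4L, return_embedding = TRUE)
  expect_equal(ncol(pd$embedding_2d), 3L)
  expect_error(bias_probe(fit, d, "both_random"), "arg")
})

test_that("evaluation requires both classes and uses the calibration split", {
  d <- tiny_dataset(60L, seed = 2L)
  sp <- random_split(d, c(6, 2, 2), seed = 1L)
  cfg <- tapb_variant("base", d_m = 8L, d_e = 8L, n_heads = 2L,
                      n_enc_layers = 1L, n_agg_layers = 1L)
  fit <- tapb_fit(sp$train, config = cfg, epochs = 1L, seed = 1L)
  if (length(unique(sp$test$records$label)) > 1L) {
    m <- evaluate_dti(fit, sp$test, sp$valid)
    expect_s3_class(m, "tapb_metrics")
    expect_true(all(unlist(m[c("auroc", "auprc", "accuracy")]) >= 0))
  }
  onecls <- dti_dataset(c("CCO", "CCN"), c("MKT", "ACD"), c(1, 1))
  expect_error(evaluate_dti(fit, onecls), "single class")
})
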