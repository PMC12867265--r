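# Independent AUC oracle: exact probability that a random positive outranks a
# random negative, ties counting one half.
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  acc <- 0
  for (p in pos) for (q in neg) acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

test_that("confusion counting thresholds with ties to positive", {
  cc <- confusion(c(1, 0), c(0.9, 0.1), 0.5)
  expect_identical(cc[c("TP", "TN", "FP", "FN")],
                   list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  cc <- confusion(c(1, 1, 0, 0), c(0.6, 0.4, 0.6, 0.4), 0.5)
  expect_identical(unlist(cc[c("TP", "FN", "FP", "TN")]),
                   c(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  cc <- confusion(c(1, 0), c(0.5, 0.5), 0.5)   # exactly at threshold
  expect_identical(cc$TP, 1L)
  expect_identical(cc$FP, 1L)
  expect_error(confusion(c(1, 0), c(0.5)), "equal length")
})

test_that("the nine-metric report reproduces worked examples", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  for (m in c("SN", "SP", "ACC", "BACC", "PREC", "F1", "AUC", "AUPR")) {
    expect_equal(unname(perfect[m]), 1, info = m)
  }
  expect_equal(unname(perfect["MCC"]), 1)

  # confusion implied by SN 0.97 / SP 1.00 on a 67 + 67 test set
  rep <- metrics_from_counts(TP = 65, FP = 0, TN = 67, FN = 2)
  expect_equal(round(unname(rep["F1"]), 3), 0.985)
  expect_equal(round(unname(rep["BACC"]), 3), 0.985)
  expect_equal(unname(rep["SP"]), 1)
  expect_equal(round(unname(rep["SN"]), 2), 0.97)

  allneg <- compute_metrics(c(1, 1, 0, 0), rep(0.1, 4))
  expect_equal(unname(allneg["SN"]), 0)
  expect_equal(unname(allneg["SP"]), 1)
  expect_equal(unname(allneg["BACC"]), 0.5)
  expect_true("PREC" %in% attr(allneg, "undefined"))
})

test_that("metric identities hold on random confusion counts", {
  set.seed(31)
  for (i in 1:20) {
    cnt <- as.list(rmultinom(1, 40, c(0.3, 0.2, 0.3, 0.2))[, 1] + 1L)
    names(cnt) <- c("TP", "FP", "TN", "FN")
    rep <- do.call(metrics_from_counts, cnt)
    expect_equal(unname(rep["BACC"]), unname((rep["SN"] + rep["SP"]) / 2))
    expect_equal(unname(rep["F1"]),
                 unname(2 * rep["PREC"] * rep["SN"] /
                          (rep["PREC"] + rep["SN"])))
    # MCC is symmetric under flipping labels and predictions together
    flipped <- metrics_from_counts(TP = cnt$TN, FP = cnt$FN,
                                   TN = cnt$TP, FN = cnt$FP)
    expect_equal(unname(rep["MCC"]), unname(flipped["MCC"]))
  }
})

test_that("AUC equals the positive-outranks-negative probability", {
  set.seed(17)
  for (i in 1:8) {
    n <- sample(20:120, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)  # rounding forces ties
    rep <- compute_metrics(y, s)
    expect_equal(unname(rep["AUC"]), oracle_auc(y, s), tolerance = 1e-12)
  }
  single <- compute_metrics(c(1, 1), c(0.2, 0.8))
  expect_true(all(c("AUC", "AUPR") %in% attr(single, "undefined")))
})

test_that("stratified k-fold partitions evenly by class", {
  d <- generate_dataset(generator_config(595, 595, seed = 1))
  folds <- stratified_kfold(d, k = 10, seed = 2)
  test_sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_true(all(test_sizes == 119L))
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, seq_len(1190L))
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    cls <- table(d$label[f$test])
    expect_true(all(abs(cls - 595 / 10) <= 1))
  }
  expect_error(stratified_kfold(d, k = 1), "k must be")
  expect_error(stratified_kfold(toy_set(), k = 5), "at least k")
})

test_that("training follows the recipe and is seed-reproducible", {
  cfg <- small_cfg(epochs = 4L, batch_size = 16L)
  b <- planted_bundle(n = 12L, seed = 6L)
  prov <- small_provider()
  tr1 <- train_model(b$train, prov, cfg, seed = 9)
  expect_length(tr1$history, 4L)
  tr2 <- train_model(b$train, prov, cfg, seed = 9)
  expect_identical(tr1$history, tr2$history)
  expect_identical(predict(tr1, b$test, prov), predict(tr2, b$test, prov))
  tr3 <- train_model(b$train, prov, cfg, seed = 10)
  expect_false(identical(tr1$history, tr3$history))

  p <- predict(tr1, b$test, prov)
  expect_true(all(p > 0 & p < 1))
  perm <- sample(nrow(b$test))
  pp <- predict(tr1, rna5hmc:::subset_samples(b$test, perm), prov)
  expect_equal(unname(pp), unname(p[perm]), tolerance = 1e-12)

  expect_identical(classify_probs(c(0.4, 0.5, 0.6)), c(0L, 1L, 1L))
})

test_that("a provider missing samples fails before training starts", {
  b <- planted_bundle(n = 6L, seed = 2L)
  prov <- small_provider(dim = 8L)
  path <- withr::local_tempfile(fileext = ".rds")
  cache_store(rna5hmc:::subset_samples(b$train, 1:3), prov, path)
  partial <- external_lm_adapter(provider_spec("ext", cache_path = path))
  expect_error(
    train_model(b$train, partial, small_cfg(epochs = 1L)),
    "embedding unavailable")
})

test_that("training reduces loss and fits a separable planted motif", {
  cfg <- model_config(embed_dim = 16L, transformer_heads = 2L,
                      transformer_ffn_dim = 32L, transformer_layers = 2L,
                      batch_size = 50L)
  d <- generate_dataset(generator_config(75, 75, seed = 3,
                                         motif = motif_spec(0.5, 0.25)))
  prov <- small_provider(dim = 16L, seed = 3L)
  tr <- train_model(d, prov, cfg, seed = 1)
  expect_lt(tr$history[cfg$epochs], tr$history[1])
  rep <- compute_metrics(d$label, predict(tr, d, prov))
  expect_gt(unname(rep["BACC"]), 0.9)
})
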