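test_that("an inception module has four length-preserving paths", {
  set.seed(1)
  mod <- rna5hmc:::with_seed(1, build_inception_module(32L))
  expect_setequal(setdiff(names(mod$sub), "bn"), c("p1", "p2", "p3", "p4"))
  x <- matrix(rnorm(2 * 41 * 32), 2 * 41, 32)
  ctx <- list(training = FALSE, B = 2L, L = 41L)
  r <- rna5hmc:::mod_forward(mod, x, ctx)
  expect_identical(dim(r$y), c(2L * 41L, 64L))   # (batch, 64, 41) layout
  for (p in c("p1", "p2", "p3", "p4")) {
    rp <- rna5hmc:::mod_forward(mod$sub[[p]], x, ctx)
    expect_identical(nrow(rp$y), 2L * 41L)        # length preserved
  }
  expect_error(build_inception_module(0L), "in_channels")
  expect_error(inception_config(c(1, 2, 3)), "four")
})

test_that("the dual model forwards to per-sample probabilities", {
  cfg <- small_cfg()
  m <- build_model(cfg, seed = 3)
  d <- generate_dataset(generator_config(3, 2, seed = 4))
  prov <- small_provider()
  batch <- list(int = rna5hmc:::encode_set_int(d),
                emb = rna5hmc:::embed_stack(prov, d))
  fwd <- rna5hmc:::model_forward(m, batch)
  expect_length(fwd$probs, 5L)
  expect_true(all(fwd$probs > 0 & fwd$probs < 1))

  # identical sample twice in one batch gives identical outputs
  idx <- c(1L, 1L, 2L)
  b2 <- rna5hmc:::slice_batch(batch, idx)
  f2 <- rna5hmc:::model_forward(m, b2)
  expect_identical(f2$probs[1], f2$probs[2])

  # permuting the batch permutes the outputs identically
  perm <- c(4L, 2L, 5L, 1L, 3L)
  fp <- rna5hmc:::model_forward(m, rna5hmc:::slice_batch(batch, perm))
  expect_equal(fp$probs, fwd$probs[perm], tolerance = 1e-12)
})

test_that("single-branch and recurrent variants build and forward", {
  d <- generate_dataset(generator_config(2, 2, seed = 8))
  prov <- small_provider()
  batch <- list(int = rna5hmc:::encode_set_int(d),
                emb = rna5hmc:::embed_stack(prov, d))
  for (mode in c("inception_only", "transformer_only")) {
    m <- build_model(small_cfg(branch_mode = mode), seed = 1)
    expect_length(m$branches, 1L)
    p <- rna5hmc:::model_forward(m, batch)$probs
    expect_true(all(p > 0 & p < 1))
  }
  for (types in list(c("lstm", "transformer"), c("rnn", "transformer"),
                     c("inception", "lstm"), c("inception", "rnn"))) {
    m <- build_model(small_cfg(branch1_type = types[1],
                               branch2_type = types[2]), seed = 1)
    p <- rna5hmc:::model_forward(m, batch)$probs
    expect_length(p, 4L)
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(build_model(small_cfg(branch1_type = "transformer"), seed = 1),
               "branch 2 position")
  expect_error(model_config(branch1_type = "bogus"), "branch types")
})

test_that("parameter counting is exact and seed-stable", {
  lin <- rna5hmc:::with_seed(1, rna5hmc:::nn_linear(2L, 3L))
  expect_identical(sum(lengths(rna5hmc:::flatten_params(lin))), 9L)

  dual <- build_model(small_cfg(), seed = 2)
  single <- build_model(small_cfg(branch_mode = "transformer_only"), seed = 2)
  expect_gt(count_parameters(dual), count_parameters(single))

  dual2 <- build_model(small_cfg(), seed = 2)
  expect_identical(rna5hmc:::model_flat_params(dual),
                   rna5hmc:::model_flat_params(dual2))
  dual3 <- build_model(small_cfg(), seed = 3)
  expect_false(identical(rna5hmc:::model_flat_params(dual),
                         rna5hmc:::model_flat_params(dual3)))
})

test_that("backpropagation matches finite differences on every layer type", {
  cfg <- model_config(embed_dim = 12L, transformer_heads = 2L,
                      transformer_ffn_dim = 24L, transformer_layers = 1L,
                      rnn_hidden = 8L, dropout_inception = 0,
                      dropout_other = 0)
  m <- build_model(cfg, seed = 2)
  flat <- rna5hmc:::model_flat_params(m)
  set.seed(99)  # non-degenerate output layer so gradients flow everywhere
  for (nm in grep("head\\.m05", names(flat), value = TRUE)) {
    flat[[nm]][] <- rnorm(length(flat[[nm]]), sd = 0.5)
  }
  m <- rna5hmc:::model_set_params(m, flat)
  d <- generate_dataset(generator_config(2, 2, seed = 5))
  prov <- small_provider(dim = 12L, seed = 9L)
  batch <- list(int = rna5hmc:::encode_set_int(d),
                emb = rna5hmc:::embed_stack(prov, d))
  y <- d$label
  loss_at <- function(fl) {
    mm <- rna5hmc:::model_set_params(m, fl)
    rna5hmc:::bce_loss(rna5hmc:::model_forward(mm, batch,
                                               training = TRUE)$probs, y)
  }
  fwd <- rna5hmc:::model_forward(m, batch, training = TRUE)
  g <- rna5hmc:::model_backward(m, fwd$cache, (fwd$probs - y) / length(y))
  grads <- rna5hmc:::model_flat_grads(m, g)
  expect_setequal(names(grads), names(flat))

  set.seed(7)
  picked <- unique(c(
    sample(names(flat), 10),
    grep("mha\\.Wk|ffn\\.m01|bn\\.gamma|m01\\.W$", names(flat),
         value = TRUE)[1:4]
  ))
  for (nm in picked[!is.na(picked)]) {
    p <- flat[[nm]]
    i <- sample(length(p), 1L)
    f2 <- flat
    p2 <- p; p2[i] <- p2[i] + 1e-5; f2[[nm]] <- p2
    up <- loss_at(f2)
    p2[i] <- p[i] - 1e-5; f2[[nm]] <- p2
    num <- (up - loss_at(f2)) / 2e-5
    expect_lt(abs(as.numeric(grads[[nm]])[i] - num), 1e-6 + 2e-3 * abs(num))
  }
})

test_that("checkpoints reload bit-exactly", {
  cfg <- small_cfg(epochs = 2L, batch_size = 8L)
  b <- planted_bundle(n = 8L, seed = 3L)
  prov <- small_provider()
  tr <- train_model(b$train, prov, cfg, seed = 4)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(tr, path)
  tr2 <- load_checkpoint(path)
  expect_identical(rna5hmc:::model_flat_params(tr2$model),
                   rna5hmc:::model_flat_params(tr$model))
  expect_identical(predict(tr2, b$test, prov), predict(tr, b$test, prov))
  expect_identical(tr2$history, tr$history)
})

test_that("feature-axis pooling reduces 1280 dims to 639 per position", {
  expect_identical(pooled_feature_dim(1280L), 639L)
  pool <- rna5hmc:::nn_maxpool_feat(3L, 2L)
  x <- matrix(rnorm(41 * 1280), 41, 1280)
  r <- rna5hmc:::mod_forward(pool, x, list(training = FALSE, B = 1L, L = 41L))
  expect_identical(ncol(r$y), 639L)
  # pooled values are window maxima
  expect_equal(r$y[5, 1], max(x[5, 1:3]))
  expect_equal(r$y[3, 639], max(x[3, 1277:1279]))
})
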