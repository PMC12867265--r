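# Independent Wilcoxon oracle: exact enumeration of all sign assignments.
oracle_signed_rank <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vdist <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(vdist <= v), mean(vdist >= v)))
}

test_that("wilcoxon comparison matches exact enumeration and R", {
  w <- wilcoxon_compare(1:10 + 0.5, 1:10 * 0)
  expect_equal(w$p_value, 2 / 1024)
  expect_identical(w$direction, "a>b")
  w2 <- wilcoxon_compare(1:10 * 0, 1:10 + 0.5)
  expect_equal(w2$p_value, w$p_value)
  expect_identical(w2$direction, "a<b")

  same <- wilcoxon_compare(1:6, 1:6)
  expect_identical(same$p_value, 1)
  expect_true(same$degenerate)

  set.seed(5)
  for (i in 1:6) {
    n <- sample(6:12, 1)
    a <- round(rnorm(n), 1)
    b <- round(a + rnorm(n, sd = 0.8), 1)
    got <- wilcoxon_compare(a, b)
    expect_equal(got$p_value, oracle_signed_rank(a, b), info = i)
  }
  # against stats::wilcox.test when no zeros/ties interfere
  set.seed(6)
  a <- rnorm(12); b <- a + rnorm(12)
  expect_equal(wilcoxon_compare(a, b)$p_value,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  expect_error(wilcoxon_compare(1:3, 2:4), "at least 5")
})

test_that("friedman test flags dominant conditions and nothing else", {
  m <- matrix(rnorm(30), 10, 3)
  same <- cbind(m[, 1], m[, 1], m[, 1])
  expect_identical(friedman_across_folds(same)$p_value, 1)

  dom <- m; dom[, 1] <- dom[, 1] + 10
  ft <- friedman_across_folds(dom)
  expect_lt(ft$p_value, 0.05)
  # rank-based: invariant under a monotone transform of the metric
  ft2 <- friedman_across_folds(exp(dom))
  expect_equal(ft$statistic, ft2$statistic)
  expect_error(friedman_across_folds(m[1, , drop = FALSE]), "at least 2")
})

test_that("descriptor benchmarking tabulates mean and sd per metric", {
  d <- generate_dataset(generator_config(40, 40, seed = 8,
                                         motif = motif_spec(0.5, 0.2)))
  tab <- descriptor_benchmark(d, c("NAC", "Kmer", "EIIP"), k = 4, seed = 1)
  expect_identical(nrow(tab), 3L)
  mn <- grep("_mean$", names(tab), value = TRUE)
  sd_ <- grep("_sd$", names(tab), value = TRUE)
  expect_length(mn, 9L)
  expect_length(sd_, 9L)
  rng <- unlist(tab[, setdiff(mn, "MCC_mean")])
  expect_true(all(rng >= 0 & rng <= 1))
  expect_true(all(tab$MCC_mean >= -1 & tab$MCC_mean <= 1))
  expect_true(all(unlist(tab[, sd_]) >= 0))
  expect_identical(tab$n, rep(4L, 3L))
  expect_error(descriptor_benchmark(d, "nope", k = 4), "unknown descriptor")
})

test_that("a position-aware descriptor beats plain composition on a motif", {
  baccs <- sapply(1:5, function(s) {
    d <- generate_dataset(generator_config(60, 60, seed = 100 + s,
                                           motif = motif_spec(0.5, 0.25)))
    tab <- descriptor_benchmark(d, c("ENAC", "NAC"), k = 4, seed = s)
    tab$BACC_mean[match(c("ENAC", "NAC"), tab$name)]
  })
  expect_gt(mean(baccs[1, ]), mean(baccs[2, ]))
})

test_that("classical baselines run on mean-pooled embeddings", {
  d <- generate_dataset(generator_config(40, 40, seed = 4,
                                         motif = motif_spec(0.5, 0.25)))
  prov <- small_provider(dim = 12L, seed = 4L)
  tab <- ml_baseline_experiment(d, prov, repeats = 2L, split_seed = 1L)
  expect_setequal(tab$name, c("svm", "xgb", "lr", "knn"))
  expect_identical(tab$n, rep(2L, 4L))
  expect_true(all(tab$BACC_mean > 0.5))
  man <- attr(tab, "manifest")
  expect_identical(man$seeds, 1:2)
  expect_true(!is.null(man$hyperparameters$svm))
})

test_that("branch-combination tables are reproducible from their manifest", {
  d <- generate_dataset(generator_config(24, 24, seed = 5,
                                         motif = motif_spec(0.4, 0.2)))
  prov <- small_provider(dim = 8L, seed = 5L)
  cfg <- model_config(embed_dim = 8L, transformer_heads = 2L,
                      transformer_ffn_dim = 16L, transformer_layers = 1L,
                      rnn_hidden = 8L, epochs = 2L, batch_size = 40L)
  combos <- list(c("inception", "transformer"), c("lstm", "rnn"))
  tab <- branch_combination_experiment(d, combos, prov, cfg, repeats = 2L,
                                       split_seed = 3L)
  expect_identical(tab$name, c("inception+transformer", "lstm+rnn"))
  expect_identical(tab$n, rep(2L, 2L))
  expect_true(all(unlist(tab[, grep("_sd$", names(tab))]) >= 0))

  tab2 <- branch_combination_experiment(d, combos, prov, cfg, repeats = 2L,
                                        split_seed = 3L)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  expect_identical(attr(tab, "manifest")$seeds, 1:2)
})

test_that("ablation compares the three modes under one seed list", {
  b <- planted_bundle(n = 16L, seed = 7L)
  prov <- small_provider(dim = 8L, seed = 7L)
  cfg <- model_config(embed_dim = 8L, transformer_heads = 2L,
                      transformer_ffn_dim = 16L, transformer_layers = 1L,
                      epochs = 2L, batch_size = 32L)
  tab <- ablation_experiment(b$train, b$test, prov, cfg, seeds = 1:2)
  expect_identical(tab$name, c("inception_only", "transformer_only", "dual"))
  expect_identical(attr(tab, "manifest")$seeds, 1:2)
  expect_error(ablation_experiment(b$train, b$train, prov, cfg), "overlap")
})

test_that("grid search selects by rank-sum and returns a grid member", {
  b <- planted_bundle(n = 20L, seed = 9L)
  prov <- small_provider(dim = 8L, seed = 9L)
  cfg <- model_config(embed_dim = 8L, transformer_heads = 2L,
                      transformer_ffn_dim = 16L, transformer_layers = 1L,
                      batch_size = 32L, branch_mode = "inception_only")
  g1 <- grid_spec(epochs = 2L, dropout_inception = 0.4, dropout_other = 0.3)
  r1 <- grid_search(b$train, g1, prov, cfg, seed = 1)
  expect_identical(nrow(r1$table), 1L)
  expect_identical(r1$best_config$epochs, 2L)
  expect_identical(r1$best_config$dropout_inception, 0.4)

  g2 <- grid_spec(epochs = c(2L, 3L), dropout_inception = 0.5,
                  dropout_other = c(0.3, 0.4))
  r2 <- grid_search(b$train, g2, prov, cfg, seed = 1)
  expect_identical(nrow(r2$table), 4L)
  expect_true(r2$best_config$epochs %in% g2$epochs)
  expect_true(r2$best_config$dropout_other %in% g2$dropout_other)
  # selection is a pure function of the stored score table
  expect_identical(rna5hmc:::rank_select_best(r2$table),
                   rna5hmc:::rank_select_best(r2$table))
  expect_identical(
    r2$best$F1,
    r2$table$F1[rna5hmc:::rank_select_best(r2$table)])
  expect_error(grid_spec(epochs = integer()), "non-empty")
})

test_that("the default grid enumerates 27 combinations", {
  g <- grid_spec()
  combos <- expand.grid(g$epochs, g$dropout_inception, g$dropout_other)
  expect_identical(nrow(combos), 27L)
  expect_identical(g$epochs, c(15L, 18L, 20L))
})
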