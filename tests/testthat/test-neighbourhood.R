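test_that("positional profiles are per-position frequencies", {
  d <- toy_set()
  pp <- positional_profile(d, 1)   # s1 (all A) and s3 (all U)
  expect_identical(dim(pp), c(41L, 4L))
  expect_equal(unname(rowSums(pp)), rep(1, 41))
  expect_equal(unname(pp["0", ]), c(0.5, 0, 0, 0.5))     # A and U flank
  expect_equal(unname(pp["20", "C"]), 1)                 # central C always
  expect_identical(attr(pp, "n"), 2L)

  # hand tally on a 5-sequence set
  d5 <- sample_set(
    id = paste0("h", 1:5),
    sequence = c(flank_seq("A"), flank_seq("A"), flank_seq("G"),
                 flank_seq("U"), flank_seq("C")),
    label = rep(1L, 5))
  p5 <- positional_profile(d5, 1)
  expect_equal(unname(p5["3", ]), c(2, 1, 1, 1) / 5)
  expect_error(positional_profile(d5, 0), "no samples")
})

test_that("region aggregation is additive and spans the documented ranges", {
  rs <- region_spec()
  expect_length(rs$upstream, 20L)
  expect_identical(rs$motif, 21:26)
  expect_error(region_spec(upstream = -1:5), "within 0..40")

  d <- generate_dataset(generator_config(30, 30, seed = 12))
  pp <- positional_profile(d, 1)
  rc <- region_counts(pp, rs)
  expect_identical(rownames(rc), names(rs))
  expect_equal(colSums(rc[c("upstream", "center", "downstream"), ]),
               colSums(pp))
  # toy arithmetic: all-A flanks give upstream A count 20
  pa <- positional_profile(rna5hmc:::subset_samples(toy_set(), 1), 1)
  expect_equal(unname(region_counts(pa, rs)["upstream", "A"]), 20)
  expect_equal(unname(region_counts(pa, rs)["center", "C"]), 1)
})

test_that("enrichment contrasts match the null and planted cases", {
  d <- generate_dataset(generator_config(60, 60, seed = 3))
  pp <- positional_profile(d, 1)
  en0 <- two_sample_enrichment(pp, pp)
  expect_true(all(abs(en0$diff) < 1e-12))
  expect_true(all(en0$p > 0.999))

  # per position the four nucleotide differences sum to zero
  dp <- generate_dataset(generator_config(500, 500, seed = 5,
                                          motif = motif_spec(0.3, 0)))
  en <- two_sample_enrichment(positional_profile(dp, 1),
                              positional_profile(dp, 0))
  sums <- tapply(en$diff, en$position, sum)
  expect_true(all(abs(sums) < 1e-12))

  hits <- en[en$nucleotide == "A" & en$position %in% 21:26, ]
  expect_true(all(hits$diff > 0))
  expect_true(all(hits$p < 0.05))

  adj <- two_sample_enrichment(positional_profile(dp, 1),
                               positional_profile(dp, 0), adjust = TRUE)
  expect_true(all(adj$p_adj >= adj$p))
})

test_that("enrichment estimates converge to the planted delta", {
  d <- generate_dataset(generator_config(5000, 5000, seed = 77,
                                         motif = motif_spec(0.3, 0)))
  en <- two_sample_enrichment(positional_profile(d, 1),
                              positional_profile(d, 0))
  a <- en[en$nucleotide == "A" & en$position %in% 21:26, ]
  expect_true(all(abs(a$diff - 0.3) < 0.03))
})

test_that("the A/G-count classifier recovers motif signal from 2 features", {
  b <- planted_bundle(n = 500L, a_delta = 0.3, g_delta = 0, seed = 9L)
  rep <- ag_region_classifier(b$train, b$test)
  expect_identical(attr(rep, "features"), c("A_count", "G_count"))
  expect_gt(unname(rep["BACC"]), 0.6)
  # counting bound: A + G counts within the 6-wide region never exceed 6
  chars <- do.call(rbind, strsplit(b$train$sequence, ""))
  ag <- rowSums(chars[, 22:27] == "A") + rowSums(chars[, 22:27] == "G")
  expect_true(all(ag <= 6))
  expect_error(ag_region_classifier(b$train, b$train), "overlap")
  expect_error(ag_region_classifier(b$train, b$test, region = 39:42),
               "0..40")
})

test_that("attribution of an untrained zero-head model is flat at zero", {
  cfg <- small_cfg()
  m <- build_model(cfg, seed = 1)
  untrained <- structure(list(model = m, config = cfg, history = numeric(),
                              seed = 1L), class = "trained_model")
  d <- generate_dataset(generator_config(4, 4, seed = 2))
  prov <- small_provider()
  ra <- range_attribution(untrained, d, provider = prov, n_perm = 4L,
                          seed = 1)
  expect_identical(nrow(ra), 6L)
  expect_true(all(abs(ra$value) < 1e-12))
  expect_identical(attr(ra, "method"), "shapley")
  expect_error(range_attribution(m, d, provider = prov), "trained model")
})

test_that("attribution output covers the requested ranges for both methods", {
  cfg <- small_cfg(epochs = 2L, batch_size = 16L)
  b <- planted_bundle(n = 10L, seed = 4L)
  prov <- small_provider()
  tr <- train_model(b$train, prov, cfg, seed = 2)
  rgs <- list(left = 0:20, motif = 21:26, right = 27:40)
  ra <- range_attribution(tr, b$test, ranges = rgs, provider = prov,
                          n_perm = 4L, seed = 5)
  expect_identical(ra$range, c("left", "motif", "right"))
  expect_length(attr(ra, "per_position"), 41L)
  gi <- range_attribution(tr, b$test, ranges = rgs,
                          method = "gradient_input", provider = prov)
  expect_identical(nrow(gi), 3L)
  expect_true(all(gi$value >= 0))
  expect_identical(attr(gi, "method"), "gradient_input")
})
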