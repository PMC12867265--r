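# Brute-force oracles, written independently of the package implementations.

oracle_dac <- function(seq, max_lag, props) {
  chars <- strsplit(seq, "")[[1]]
  dn <- sapply(seq_len(length(chars) - 1L),
               function(i) paste0(chars[i], chars[i + 1L]))
  out <- c()
  for (p in colnames(props)) {
    vals <- props[dn, p]
    pbar <- mean(vals)
    for (g in seq_len(max_lag)) {
      acc <- 0
      for (i in seq_len(length(dn) - g)) {
        acc <- acc + (vals[i] - pbar) * (vals[i + g] - pbar)
      }
      out <- c(out, acc / (length(dn) - g))
    }
  }
  unname(out)
}

oracle_psednc <- function(seq, lam, w, variant, props) {
  chars <- strsplit(seq, "")[[1]]
  dn <- sapply(seq_len(length(chars) - 1L),
               function(i) paste0(chars[i], chars[i + 1L]))
  all_dn <- as.vector(sapply(c("A", "C", "G", "U"),
                             function(a) paste0(a, c("A", "C", "G", "U"))))
  all_dn <- sort(all_dn)
  f <- sapply(all_dn, function(k) sum(dn == k)) / length(dn)
  theta <- numeric(lam)
  for (j in seq_len(lam)) {
    acc <- 0
    for (i in seq_len(length(dn) - j)) {
      a <- props[dn[i], ]; b <- props[dn[i + j], ]
      acc <- acc + if (variant == "series") mean((a - b)^2) else mean(a * b)
    }
    theta[j] <- acc / (length(dn) - j)
  }
  denom <- sum(f) + w * sum(theta)
  c(f / denom, w * theta / denom)
}

test_that("the registry holds the fourteen descriptors at their sizes", {
  reg <- descriptor_registry()
  expect_length(reg, 14L)
  expected <- c(ANF = 41L, binary = 164L, DAC = 12L, DNC = 16L, EIIP = 41L,
                ENAC = 148L, Kmer = 16L, NAC = 4L, NCP = 123L, PCPseDNC = 18L,
                PseDNC = 18L, PseEIIP = 64L, RCKmer = 10L, TNC = 64L)
  expect_setequal(names(reg), names(expected))
  for (nm in names(expected)) {
    expect_identical(reg[[nm]]$expected_length, expected[[nm]], info = nm)
  }
  for (seed in 1:3) {
    s <- random_valid_seq(seed)
    for (nm in names(reg)) {
      v <- reg[[nm]]$fn(s)
      expect_length(v, reg[[nm]]$expected_length)
      expect_true(all(is.finite(v)), info = nm)
    }
  }
})

test_that("composition descriptors are normalized frequencies", {
  for (seed in 1:5) {
    s <- random_valid_seq(seed + 10)
    expect_equal(sum(kmer_composition(s, 1)), 1, tolerance = 1e-9)
    expect_equal(sum(kmer_composition(s, 2)), 1, tolerance = 1e-9)
    expect_equal(sum(kmer_composition(s, 3)), 1, tolerance = 1e-9)
    expect_equal(sum(rc_kmer(s)), 1, tolerance = 1e-9)
    expect_equal(sum(pse_dnc(s)), 1, tolerance = 1e-9)
    expect_equal(sum(pse_dnc(s, variant = "parallel")), 1, tolerance = 1e-9)
    e <- enac(s)
    blocks <- matrix(e, nrow = 4L)
    expect_equal(colSums(blocks), rep(1, 37), tolerance = 1e-9)
    b <- one_hot_binary(s)
    expect_equal(colSums(matrix(b, nrow = 4L)), rep(1, 41))
  }
})

test_that("k-mer composition matches hand-computed toys", {
  expect_equal(unname(kmer_composition("ACGU", 1)), rep(0.25, 4))
  k2 <- kmer_composition("AAAA", 2)
  expect_equal(unname(k2["AA"]), 1)
  expect_equal(sum(k2), 1)
  expect_error(kmer_composition("ACGU", 0), "k must be")
})

test_that("reverse-complement k-mer collapse has 10 classes and is symmetric", {
  v <- rc_kmer(random_valid_seq(3))
  expect_length(v, 10L)
  x <- rc_kmer("AAUU")
  expect_equal(unname(x["AA"]), 2 / 3)
  expect_equal(unname(x["AU"]), 1 / 3)
  expect_equal(sum(x), 1)
  for (seed in 1:5) {
    s <- random_valid_seq(seed + 20)
    expect_equal(rc_kmer(s), rc_kmer(reverse_complement(s)))
  }
})

test_that("positional encodings follow their defining conventions", {
  s <- flank_seq("A")
  b <- one_hot_binary(s)
  expect_identical(unname(b[1:4]), c(1, 0, 0, 0))       # A block
  expect_identical(unname(b[81:84]), c(0, 1, 0, 0))     # central C block

  a <- anf(paste0("AACA", substr(random_valid_seq(1), 5, 41)))
  expect_equal(unname(a[1:4]), c(1, 1, 1 / 3, 3 / 4))
  expect_equal(unname(anf("AAAA")[1:4]), rep(1, 4))
  for (seed in 1:3) expect_equal(unname(anf(random_valid_seq(seed))[1]), 1)

  n <- ncp(s)
  expect_identical(unname(n[1:3]), c(1, 1, 1))          # A code
  codes <- unique(split(ncp("ACGU"), rep(1:4, each = 3)))
  expect_length(codes, 4L)                              # pairwise distinct
})

test_that("EIIP profiles and PseEIIP use the shipped constants", {
  expect_equal(unname(eiip_profile("ACGU")),
               c(0.1260, 0.1340, 0.0806, 0.1335))
  expect_length(eiip_profile(random_valid_seq(2)), 41L)
  expect_true(all(eiip_profile(random_valid_seq(2)) > 0))

  p <- pse_eiip(strrep("A", 10))
  expect_equal(unname(p["AAA"]), 3 * 0.1260, tolerance = 1e-12)
  expect_equal(sum(p != 0), 1L)
  expect_length(pse_eiip(random_valid_seq(4)), 64L)
})

test_that("ENAC windows are per-window frequencies", {
  e <- enac(flank_seq("A"))
  expect_length(e, 148L)
  expect_identical(unname(e[1:4]), c(1, 0, 0, 0))
  expect_error(enac(random_valid_seq(1), window = 0), "window")
})

test_that("the dinucleotide property table is standardized", {
  pr <- dinuc_property_table()
  expect_identical(dim(pr), c(16L, 6L))
  expect_equal(unname(colMeans(pr)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(pr, 2, function(x) mean(x^2))), rep(1, 6),
               tolerance = 1e-12)
})

test_that("DAC matches a brute-force double-loop oracle", {
  pr <- dinuc_property_table()
  for (s in c("ACACGU", "AAGGCCUU", substr(random_valid_seq(5), 1, 10))) {
    expect_equal(unname(dac(s, max_lag = 2)), oracle_dac(s, 2, pr),
                 tolerance = 1e-9, info = s)
  }
  expect_length(dac(random_valid_seq(1)), 12L)
  # a sequence with one repeated dinucleotide has zero covariance
  expect_equal(unname(dac("AAAAAA", max_lag = 2)), rep(0, 12))
  expect_error(dac("ACG", max_lag = 5), "lag")
})

test_that("PseDNC and PCPseDNC match brute-force oracles", {
  pr <- dinuc_property_table()
  for (s in c("ACGUACGU", "AAGGCCUU")) {
    for (variant in c("series", "parallel")) {
      expect_equal(unname(pse_dnc(s, lam = 1, variant = variant)),
                   unname(oracle_psednc(s, 1, 0.05, variant, pr)),
                   tolerance = 1e-9, info = paste(s, variant))
    }
  }
  s41 <- random_valid_seq(6)
  expect_length(pse_dnc(s41), 18L)
  w0 <- pse_dnc(s41, weight = 0)
  expect_equal(unname(w0[1:16]), unname(kmer_composition(s41, 2)),
               tolerance = 1e-12)
  expect_equal(unname(w0[17:18]), c(0, 0))
  expect_true(all(pse_dnc(s41) >= 0))
  expect_error(pse_dnc("ACG", lam = 10), "lam")
})

test_that("descriptor matrices cover sample sets with named columns", {
  d <- toy_set()
  m <- descriptor_matrix(d, "Kmer")
  expect_identical(dim(m), c(4L, 16L))
  expect_identical(rownames(m), d$id)
  expect_true("AA" %in% colnames(m))
  expect_error(descriptor_matrix(d, "nope"), "unknown descriptor")
})
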