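# Synthetic dataset generator. Emulates the statistical shape of the
# hMeRIP-seq-derived benchmark: balanced classes of 41-nt sequences with a
# central C, and (in positives) an A-enriched / G-depleted motif at 0-based
# positions 21-26 of tunable strength.

#' Specify the planted positional motif
#'
#' In positive samples, positions in `range` are drawn from a distribution
#' shifted towards A and away from G. `a_delta` is added to the A probability
#' and funded equally from C and U; `g_delta` is moved from G to A. The
#' adjusted probabilities must remain a valid distribution.
#'
#' @param a_delta Increase of the A probability (funded by C and U).
#' @param g_delta Decrease of the G probability (moved to A).
#' @param range Integer vector of 0-based positions carrying the motif.
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(a_delta = 0, g_delta = 0, range = 21:26) {
  stopifnot(a_delta >= 0, g_delta >= 0)
  if (any(range < 0L) || any(range > 40L)) {
    stop("motif range must lie within 0..40", call. = FALSE)
  }
  if (CENTER_POS %in% range) {
    stop("motif range may not include the central position 20", call. = FALSE)
  }
  structure(list(a_delta = a_delta, g_delta = g_delta,
                 range = as.integer(range)), class = "motif_spec")
}

#' Configure the synthetic dataset generator
#'
#' @param n_pos,n_neg Numbers of positive / negative samples.
#' @param seed Integer seed; the generator is a pure function of this config.
#' @param background Named per-nucleotide probabilities (A, C, G, U),
#'   summing to 1. Default uniform.
#' @param motif A [motif_spec()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_pos, n_neg, seed = 1L,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, U = 0.25),
                             motif = motif_spec()) {
  stopifnot(n_pos >= 0, n_neg >= 0, inherits(motif, "motif_spec"))
  background <- background[RNA_BASES]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-9 ||
      any(background < 0)) {
    stop("background must be named probabilities for A, C, G, U summing to 1",
         call. = FALSE)
  }
  cfg <- structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                        seed = as.integer(seed), background = background,
                        motif = motif), class = "generator_config")
  motif_distribution(cfg)  # validate before any sampling happens
  cfg
}

# Motif-adjusted nucleotide distribution for positive samples:
# A += a_delta + g_delta, C -= a_delta/2, U -= a_delta/2, G -= g_delta.
motif_distribution <- function(cfg) {
  b <- cfg$background
  m <- cfg$motif
  p <- c(A = b[["A"]] + m$a_delta + m$g_delta,
         C = b[["C"]] - m$a_delta / 2,
         G = b[["G"]] - m$g_delta,
         U = b[["U"]] - m$a_delta / 2)
  if (any(p < -1e-12) || p[["A"]] > 1 + 1e-12) {
    stop("motif deltas (a_delta=", m$a_delta, ", g_delta=", m$g_delta,
         ") do not yield a valid probability distribution over the background",
         call. = FALSE)
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Generate a labelled synthetic dataset
#'
#' Every sequence has length 41 with C at 0-based position 20. Non-central
#' positions are drawn i.i.d. from the background distribution, except that
#' motif-range positions of positive samples use the motif-adjusted
#' distribution. Output is fully determined by the config (seed included).
#'
#' @param cfg A [generator_config()].
#' @param tag Dataset tag of the returned set.
#' @return A [sample_set()] with ids `pos_1..n_pos`, `neg_1..n_neg`.
#' @export
generate_dataset <- function(cfg, tag = "unsplit") {
  stopifnot(inherits(cfg, "generator_config"))
  p_motif <- motif_distribution(cfg)
  rng_seed <- derive_seed(cfg$seed, "generate_dataset")
  with_seed(rng_seed, {
    draw <- function(n, motif) {
      if (n == 0L) return(character())
      mat <- matrix(sample(RNA_BASES, n * SEQ_LEN, replace = TRUE,
                           prob = cfg$background),
                    nrow = n, ncol = SEQ_LEN)
      if (motif && length(cfg$motif$range) > 0L &&
          (cfg$motif$a_delta > 0 || cfg$motif$g_delta > 0)) {
        cols <- cfg$motif$range + 1L
        mat[, cols] <- sample(RNA_BASES, n * length(cols), replace = TRUE,
                              prob = p_motif)
      }
      mat[, CENTER_POS + 1L] <- "C"
      apply(mat, 1L, paste, collapse = "")
    }
    pos <- draw(cfg$n_pos, motif = TRUE)
    neg <- draw(cfg$n_neg, motif = FALSE)
    sample_set(
      id = c(sprintf("pos_%d", seq_len(cfg$n_pos)),
             sprintf("neg_%d", seq_len(cfg$n_neg))),
      sequence = c(pos, neg),
      label = c(rep(1L, cfg$n_pos), rep(0L, cfg$n_neg)),
      tag = tag
    )
  })
}

#' Generate a dataset and split it in one step
#'
#' Generates from `cfg`, then applies a seeded stratified split (mirrors the
#' 90/10 train/independent protocol of the benchmark dataset).
#'
#' @param cfg A [generator_config()].
#' @param fraction Fraction of each class in the first partition.
#' @param seed Seed of the split shuffle (independent of the generator seed).
#' @return List with `train`, `test` ([sample_set()]s) and `manifest`.
#' @export
generate_split_bundle <- function(cfg, fraction, seed = cfg$seed) {
  data <- generate_dataset(cfg)
  sp <- split_dataset(data, split_spec(fraction, seed = seed),
                      tags = c("train", "independent"))
  manifest <- c(list(generator = list(n_pos = cfg$n_pos, n_neg = cfg$n_neg,
                                      seed = cfg$seed,
                                      background = as.list(cfg$background),
                                      a_delta = cfg$motif$a_delta,
                                      g_delta = cfg$motif$g_delta,
                                      motif_range = cfg$motif$range)),
                sp$manifest)
  list(train = sp$first, test = sp$second, manifest = manifest)
}
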