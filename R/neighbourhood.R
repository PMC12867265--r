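# Positional neighbourhood analysis: per-position nucleotide profiles, region
# aggregation, two-sample enrichment between classes (two-proportion z-test
# per position/nucleotide cell, as in two-sample-logo-style displays),
# Shapley-value attribution aggregated over position ranges, and the A/G-count
# auxiliary classifier for the 21-26 motif region.

#' Named position regions on the 41-nt window
#'
#' 0-based half-open conventions from the site-centred coordinate system:
#' upstream 0-19, the central candidate C at 20, downstream 21-40, and the
#' A-rich/G-poor motif block 21-26.
#'
#' @param upstream,center,downstream,motif Integer vectors of 0-based
#'   positions.
#' @return A `region_spec` named list of position vectors.
#' @export
region_spec <- function(upstream = 0:19, center = 20L, downstream = 21:40,
                        motif = 21:26) {
  out <- list(upstream = as.integer(upstream), center = as.integer(center),
              downstream = as.integer(downstream), motif = as.integer(motif))
  for (nm in names(out)) {
    if (any(out[[nm]] < 0L) || any(out[[nm]] > 40L)) {
      stop("region '", nm, "' must lie within 0..40", call. = FALSE)
    }
  }
  structure(out, class = "region_spec")
}

#' Per-position nucleotide frequency profile of one class
#'
#' @param data A [sample_set()].
#' @param label Class to profile (1 or 0).
#' @return A `positional_profile`: 41 x 4 matrix of frequencies (rows =
#'   0-based positions, columns A, C, G, U; each row sums to 1), with
#'   attributes `n` (class size) and `label`.
#' @export
positional_profile <- function(data, label) {
  idx <- which(data$label == as.integer(label))
  if (length(idx) == 0L) {
    stop("no samples with label ", label, call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(data$sequence[idx], ""))
  freq <- sapply(RNA_BASES, function(b) colMeans(chars == b))
  rownames(freq) <- as.character(0:(SEQ_LEN - 1L))
  structure(freq, n = length(idx), label = as.integer(label),
            class = c("positional_profile", "matrix"))
}

#' Aggregate a positional profile over regions
#'
#' Sums the per-position mean counts (= frequencies) of each nucleotide
#' within each region, giving the expected nucleotide counts per sequence in
#' that region. Upstream + center + downstream totals equal the full-window
#' totals.
#'
#' @param profile A [positional_profile()].
#' @param regions A [region_spec()].
#' @return Numeric matrix, regions x nucleotides.
#' @export
region_counts <- function(profile, regions = region_spec()) {
  stopifnot(inherits(profile, "positional_profile"),
            inherits(regions, "region_spec"))
  out <- t(vapply(regions, function(pos) {
    colSums(profile[pos + 1L, , drop = FALSE])
  }, numeric(4L)))
  colnames(out) <- RNA_BASES
  out
}

#' Positional enrichment between positive and negative profiles
#'
#' For each position and nucleotide, the frequency difference
#' (positive - negative) and a two-proportion z-test p-value computed from
#' the class sample sizes (no continuity correction, matching the
#' two-sample-logo convention). Benjamini-Hochberg adjustment is available
#' behind `adjust` but off by default.
#'
#' @param pos,neg [positional_profile()]s on identical coordinates.
#' @param n_pos,n_neg Class sample sizes (defaults: the profiles' `n`).
#' @param adjust Apply Benjamini-Hochberg correction (adds column `p_adj`).
#' @return An `enrichment_result` data.frame with columns position (0-based),
#'   nucleotide, diff, p (and p_adj if requested).
#' @export
two_sample_enrichment <- function(pos, neg, n_pos = attr(pos, "n"),
                                  n_neg = attr(neg, "n"), adjust = FALSE) {
  stopifnot(inherits(pos, "positional_profile"),
            inherits(neg, "positional_profile"),
            nrow(pos) == nrow(neg))
  if (is.null(n_pos) || is.null(n_neg) || n_pos < 1L || n_neg < 1L) {
    stop("class sample sizes must be positive", call. = FALSE)
  }
  grid <- expand.grid(position = 0:(nrow(pos) - 1L), nucleotide = RNA_BASES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p1 <- pos[cbind(grid$position + 1L, match(grid$nucleotide, RNA_BASES))]
  p2 <- neg[cbind(grid$position + 1L, match(grid$nucleotide, RNA_BASES))]
  x1 <- round(p1 * n_pos); x2 <- round(p2 * n_neg)
  pooled <- (x1 + x2) / (n_pos + n_neg)
  se <- sqrt(pooled * (1 - pooled) * (1 / n_pos + 1 / n_neg))
  z <- ifelse(se > 0, (p1 - p2) / se, 0)
  grid$diff <- p1 - p2
  grid$p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
  if (adjust) grid$p_adj <- stats::p.adjust(grid$p, method = "BH")
  structure(grid, class = c("enrichment_result", "data.frame"))
}

## ---- attribution -----------------------------------------------------------

# Forward of the model with the inception-branch input replaced while every
# embedding-branch contribution stays fixed at the sample's own value.
inception_branch_fn <- function(trained, sample_row, provider) {
  model <- trained$model
  b1 <- NULL
  fixed <- list()
  for (i in seq_along(model$branches)) {
    br <- model$branches[[i]]
    if (br$input == "int" && is.null(b1)) {
      b1 <- i
    } else {
      x <- if (br$input == "int") {
        matrix(encode_integers(sample_row$sequence[1L]), nrow = 1L)
      } else {
        embed_sample(provider, sample_row)
      }
      ctx <- list(training = FALSE, B = 1L,
                  L = if (br$input == "emb") SEQ_LEN else NULL)
      fixed[[i]] <- mod_forward(br$mod, x, ctx)$y
    }
  }
  if (is.null(b1)) {
    stop("model has no integer-input (inception-style) branch to attribute",
         call. = FALSE)
  }
  function(int_mat) {
    B <- nrow(int_mat)
    ctx <- list(training = FALSE, B = B, L = NULL)
    outs <- vector("list", length(model$branches))
    for (i in seq_along(model$branches)) {
      outs[[i]] <- if (i == b1) {
        mod_forward(model$branches[[i]]$mod, int_mat, ctx)$y
      } else {
        matrix(rep(fixed[[i]], each = B), nrow = B)
      }
    }
    fused <- do.call(cbind, outs)
    r <- mod_forward(model$head, fused, list(training = FALSE, B = B,
                                             L = NULL))
    sigmoid(as.numeric(r$y))
  }
}

default_attribution_ranges <- function() {
  list("0-6" = 0:6, "7-13" = 7:13, "14-20" = 14:20, "21-26" = 21:26,
       "27-33" = 27:33, "34-40" = 34:40)
}

#' Range-aggregated attribution of the inception branch
#'
#' Attributes the model output to the 41 inception-branch input positions by
#' a sampling-based Shapley-value approximation (seeded permutations over
#' positions, background drawn by per-position shuffling of the dataset's
#' sequences), or by the fast gradient-x-input fallback. Absolute
#' attributions are averaged over samples, then over the positions of each
#' requested range. Embedding-branch contributions are held fixed at each
#' sample's own value, so the attribution isolates the sequence branch.
#'
#' @param trained A `trained_model` whose branch 1 consumes integer input.
#' @param data A [sample_set()] of samples to explain.
#' @param ranges Named list of 0-based position vectors (default: six equal
#'   blocks with 21-26 as its own block).
#' @param method `"shapley"` or `"gradient_input"`.
#' @param provider Provider for the fixed embedding branch (dual models).
#' @param n_perm Permutations per sample for the Shapley approximation.
#' @param seed Seed of permutations and backgrounds.
#' @return A `range_attribution` data.frame (range, value) with attributes
#'   `per_position` (length-41 mean absolute attribution) and `method`.
#' @export
range_attribution <- function(trained, data, ranges = NULL,
                              method = c("shapley", "gradient_input"),
                              provider = NULL, n_perm = 128L, seed = 1L) {
  method <- match.arg(method)
  if (!inherits(trained, "trained_model")) {
    stop("range_attribution requires a trained model", call. = FALSE)
  }
  if (is.null(ranges)) ranges <- default_attribution_ranges()
  int_all <- encode_set_int(data)
  n <- nrow(data)
  phi <- matrix(0, n, SEQ_LEN)
  if (method == "shapley") {
    with_seed(derive_seed(seed, "shapley"), {
      for (si in seq_len(n)) {
        f <- inception_branch_fn(trained, subset_samples(data, si), provider)
        x <- int_all[si, ]
        for (p in seq_len(n_perm)) {
          # one background draw: per-position shuffle across the dataset
          bg <- int_all[cbind(sample.int(n, SEQ_LEN, replace = TRUE),
                              seq_len(SEQ_LEN))]
          ord <- sample.int(SEQ_LEN)
          states <- matrix(bg, nrow = SEQ_LEN + 1L, ncol = SEQ_LEN,
                           byrow = TRUE)
          for (k in seq_len(SEQ_LEN)) {
            states[(k + 1L):(SEQ_LEN + 1L), ord[k]] <- x[ord[k]]
          }
          vals <- f(states)
          phi[si, ord] <- phi[si, ord] + diff(vals)
        }
        phi[si, ] <- phi[si, ] / n_perm
      }
    })
  } else {
    for (si in seq_len(n)) {
      phi[si, ] <- gradient_input_attribution(trained,
                                              subset_samples(data, si),
                                              provider)
    }
  }
  per_pos <- colMeans(abs(phi))
  vals <- vapply(ranges, function(r) mean(per_pos[r + 1L]), numeric(1))
  structure(data.frame(range = names(ranges), value = unname(vals),
                       stringsAsFactors = FALSE),
            per_position = per_pos, method = method,
            class = c("range_attribution", "data.frame"))
}

# Gradient of the output logit wrt the word-embedding activations, contracted
# with the activations (gradient x input), summed over channels per position.
gradient_input_attribution <- function(trained, sample_row, provider) {
  model <- trained$model
  b1 <- which(vapply(model$branches, `[[`, character(1), "input") == "int")[1L]
  if (is.na(b1)) {
    stop("model has no integer-input branch to attribute", call. = FALSE)
  }
  br <- model$branches[[b1]]
  stopifnot(br$mod$sub[[1L]]$kind == "embedding")
  int_mat <- matrix(encode_integers(sample_row$sequence[1L]), nrow = 1L)
  batch <- list(int = int_mat,
                emb = if (!is.null(provider) &&
                          model_needs(model)$emb) {
                  embed_sample(provider, sample_row)
                } else NULL)
  fwd <- model_forward(model, batch, training = FALSE)
  g <- model_backward(model, fwd$cache, dlogits = 1)
  # gradient that arrived at the embedding weights, scattered per position
  emb_cache <- fwd$cache$branches[[b1]][[1L]]
  W <- br$mod$sub[[1L]]$params$W
  emb_out <- W[emb_cache$idx, , drop = FALSE]
  # recover d(embedding output) by replaying the branch backward pass
  ctx <- list(training = FALSE, B = 1L, L = SEQ_LEN)
  rest <- br$mod; rest$sub <- rest$sub[-1L]
  r_fwd <- mod_forward(rest, emb_out, ctx)
  d_fused <- attribution_head_grad(model, fwd, b1)
  r_bwd <- mod_backward(rest, r_fwd$cache, d_fused, ctx)
  rowSums(r_bwd$dx * emb_out)
}

attribution_head_grad <- function(model, fwd, b1) {
  ctx_h <- list(training = FALSE, B = fwd$cache$B, L = NULL)
  r_head <- mod_backward(model$head, fwd$cache$head,
                         matrix(1, fwd$cache$B, 1L), ctx_h)
  offs <- cumsum(c(0L, fwd$cache$widths))
  r_head$dx[, (offs[b1] + 1L):offs[b1 + 1L], drop = FALSE]
}

#' A/G-count auxiliary classifier on the motif region
#'
#' Trains a two-feature gradient-boosted-tree classifier on the counts of A
#' and of G within the given 0-based region (default the motif block 21-26)
#' and reports the nine-metric evaluation on `test`. Quantifies how much of
#' the class signal the A-rich/G-poor motif alone carries.
#'
#' @param train,test Disjoint [sample_set()]s.
#' @param region Integer vector of 0-based positions.
#' @param seed Classifier seed.
#' @return A `metric_report` with attribute `features = c("A_count",
#'   "G_count")`.
#' @export
ag_region_classifier <- function(train, test, region = 21:26, seed = 1L) {
  if (any(region < 0L) || any(region > 40L)) {
    stop("region must lie within 0..40", call. = FALSE)
  }
  if (length(intersect(train$id, test$id)) > 0L) {
    stop("train and test sets overlap", call. = FALSE)
  }
  ag_counts <- function(set) {
    chars <- do.call(rbind, strsplit(set$sequence, ""))
    sub <- chars[, region + 1L, drop = FALSE]
    cbind(A_count = rowSums(sub == "A"), G_count = rowSums(sub == "G"))
  }
  probs <- fit_classical("xgb", ag_counts(train), train$label,
                         ag_counts(test), seed = seed)
  rep <- compute_metrics(test$label, probs)
  attr(rep, "features") <- c("A_count", "G_count")
  rep
}
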