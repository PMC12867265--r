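# Per-nucleotide embedding providers. Embeddings enter the package only
# through the provider contract: a provider maps a labelled sample (id +
# sequence) to a (41, dim) real matrix, purely and reproducibly. The external
# language model itself is never loaded here; its embeddings are served from a
# cache populated offline. A deterministic synthetic provider stands on its
# own for simulation studies: it encodes local sequence context, so
# classifiers can in principle recover sequence signal from it.

#' Specify an embedding provider
#'
#' @param name Provider name (recorded in caches and manifests).
#' @param dim Embedding dimension (1280 for the full-scale language model).
#' @param seed Integer seed (synthetic provider only).
#' @param cache_path Optional cache file path (external adapter only).
#' @return A `provider_spec` list.
#' @export
provider_spec <- function(name, dim = 1280L, seed = 1L, cache_path = NULL) {
  if (dim < 1L) stop("dim must be >= 1", call. = FALSE)
  structure(list(name = name, dim = as.integer(dim), seed = as.integer(seed),
                 cache_path = cache_path), class = "provider_spec")
}

new_provider <- function(name, dim, fn) {
  structure(list(name = name, dim = as.integer(dim), fn = fn),
            class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat(sprintf("<embedding_provider> %s (dim %d)\n", x$name, x$dim))
  invisible(x)
}

#' Deterministic synthetic embedding provider
#'
#' Serves (41, dim) matrices built from a seeded random basis: row i is the
#' basis vector of the trinucleotide centred at position i (edges padded with
#' the terminal nucleotide) plus a nucleotide-identity basis vector and a
#' sinusoidal positional component. Identical (sequence, seed) always yields
#' identical matrices; rows for different nucleotides always differ, so the
#' sequence signal is recoverable from the embeddings.
#'
#' @param spec A [provider_spec()]; `spec$dim` and `spec$seed` are used.
#' @return An `embedding_provider`.
#' @export
synthetic_provider <- function(spec = provider_spec("synthetic")) {
  dim <- spec$dim
  basis_seed <- derive_seed(spec$seed, "synthetic_provider_basis")
  bases <- with_seed(basis_seed, {
    list(
      nuc = matrix(stats::rnorm(4L * dim, sd = 1), nrow = 4L,
                   dimnames = list(RNA_BASES, NULL)),
      tri = matrix(stats::rnorm(64L * dim, sd = 0.5), nrow = 64L,
                   dimnames = list(all_kmers(3L), NULL))
    )
  })
  d_idx <- seq_len(dim)
  pos_wave <- outer(seq_len(SEQ_LEN), d_idx, function(p, d) {
    0.3 * sin(p / (10 ^ (2 * (d %% 8) / 8)) + (d %% 2) * pi / 2)
  })
  fn <- function(id, sequence) {
    chars <- desc_chars(sequence)
    padded <- c(chars[1L], chars, chars[length(chars)])
    tri <- vapply(seq_along(chars), function(i) {
      paste(padded[i:(i + 2L)], collapse = "")
    }, character(1))
    m <- bases$nuc[chars, , drop = FALSE] +
      bases$tri[tri, , drop = FALSE] + pos_wave
    dimnames(m) <- NULL
    m
  }
  new_provider(sprintf("synthetic(seed=%d)", spec$seed), dim, fn)
}

#' Embed one sample
#'
#' @param provider An `embedding_provider`.
#' @param sample An [rna_sample()], or a one-row slice of a [sample_set()].
#' @return Numeric (41, dim) matrix.
#' @export
embed_sample <- function(provider, sample) {
  stopifnot(inherits(provider, "embedding_provider"))
  if (inherits(sample, "rna_sample")) {
    m <- provider$fn(sample$id, sample$sequence)
  } else {
    m <- provider$fn(sample$id[1L], sample$sequence[1L])
  }
  stopifnot(nrow(m) == SEQ_LEN, ncol(m) == provider$dim, all(is.finite(m)))
  m
}

#' Embed every sample of a set
#'
#' @param provider An `embedding_provider`.
#' @param data A [sample_set()].
#' @return Named list of (41, dim) matrices, one per sample id.
#' @export
embed_set <- function(provider, data) {
  out <- lapply(seq_len(nrow(data)), function(i) {
    embed_sample(provider, subset_samples(data, i))
  })
  names(out) <- data$id
  out
}

#' Average an embedding matrix along the sequence dimension
#'
#' Column means of the (41, dim) matrix, producing one dim-length vector per
#' sample (the flat representation used by the classical-classifier
#' baselines).
#'
#' @param matrix Numeric (41, dim) embedding matrix.
#' @return Numeric vector of length dim.
#' @export
mean_pool <- function(matrix) {
  colMeans(matrix)
}

#' Store embeddings of a sample set in a cache file
#'
#' Writes one (41, dim) array per sample id into a single R-native serialized
#' container, plus a JSON sidecar manifest (`<path>.json`) recording the
#' dialect, provider name, dim and creation parameters.
#'
#' @param samples A [sample_set()].
#' @param provider An `embedding_provider`.
#' @param path Output cache file path (e.g. `cache.rds`).
#' @return `path`, invisibly.
#' @export
cache_store <- function(samples, provider, path) {
  if (anyDuplicated(samples$id)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "),
         call. = FALSE)
  }
  arrays <- embed_set(provider, samples)
  manifest <- list(dialect = "rds", provider = provider$name,
                   dim = provider$dim, n_samples = length(arrays),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ok <- tryCatch({
    saveRDS(list(manifest = manifest, arrays = arrays), path)
    TRUE
  }, error = function(e) {
    stop("failed to write embedding cache '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Adapter serving externally computed embeddings from a cache
#'
#' Serves per-sample (41, dim) matrices from a cache written by
#' [cache_store()] (or populated offline by an external extraction script
#' around the language model). Requests for ids absent from the cache raise
#' an "embedding unavailable" error; there is no silent fallback.
#'
#' @param spec A [provider_spec()] whose `cache_path` points at the cache.
#' @return An `embedding_provider`.
#' @export
external_lm_adapter <- function(spec) {
  if (is.null(spec$cache_path) || !file.exists(spec$cache_path)) {
    stop("embedding cache not found: ", spec$cache_path %||% "<NULL>",
         call. = FALSE)
  }
  cache <- readRDS(spec$cache_path)
  dim <- cache$manifest$dim
  arrays <- cache$arrays
  fn <- function(id, sequence) {
    m <- arrays[[id]]
    if (is.null(m)) {
      stop("embedding unavailable for sample '", id, "' in cache '",
           spec$cache_path, "'", call. = FALSE)
    }
    m
  }
  new_provider(sprintf("external(%s)", cache$manifest$provider), dim, fn)
}
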