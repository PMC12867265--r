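# Stratified dataset splitting. Per class, a seeded Fisher-Yates shuffle
# assigns the first floor(fraction * n_class) samples to the first partition;
# the remainder goes to the second. 662+662 at fraction 0.9 therefore yields
# 595+595 / 67+67.

#' Specify a dataset split
#'
#' @param fraction_first Fraction (in `[0,1]`) of each class assigned to the
#'   first partition (`floor(fraction * n_class)` samples per class when
#'   stratified).
#' @param seed Integer seed for the per-class shuffle.
#' @param stratified Stratify by label (default `TRUE`).
#' @return A `split_spec` list.
#' @export
split_spec <- function(fraction_first, seed = 1L, stratified = TRUE) {
  if (!is.numeric(fraction_first) || fraction_first < 0 || fraction_first > 1) {
    stop("fraction_first must be in [0, 1]", call. = FALSE)
  }
  structure(list(fraction_first = fraction_first, seed = as.integer(seed),
                 stratified = isTRUE(stratified)), class = "split_spec")
}

#' Split a sample set into two disjoint partitions
#'
#' @param data A non-empty [sample_set()].
#' @param spec A [split_spec()].
#' @param tags Length-2 character vector of tags for the two partitions.
#' @return List with elements `first`, `second` (both `sample_set`s) and
#'   `manifest` (fraction, seed, stratified flag, per-partition label counts).
#' @export
split_dataset <- function(data, spec, tags = c("train", "independent")) {
  stopifnot(inherits(data, "sample_set"), inherits(spec, "split_spec"))
  if (nrow(data) == 0L) stop("cannot split an empty sample set", call. = FALSE)
  idx_first <- with_seed(spec$seed, {
    if (spec$stratified) {
      unlist(lapply(c(1L, 0L), function(lab) {
        cls <- which(data$label == lab)
        n_first <- floor(spec$fraction_first * length(cls))
        sample(cls)[seq_len(n_first)]
      }), use.names = FALSE)
    } else {
      n_first <- floor(spec$fraction_first * nrow(data))
      sample(nrow(data))[seq_len(n_first)]
    }
  })
  idx_first <- sort(idx_first)
  idx_second <- setdiff(seq_len(nrow(data)), idx_first)
  first <- subset_samples(data, idx_first, tag = tags[1L])
  second <- subset_samples(data, idx_second, tag = tags[2L])
  manifest <- list(
    fraction_first = spec$fraction_first, seed = spec$seed,
    stratified = spec$stratified,
    counts = list(first = as.list(label_counts(first)),
                  second = as.list(label_counts(second)))
  )
  list(first = first, second = second, manifest = manifest)
}
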