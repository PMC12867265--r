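# Sample containers: one labelled 41-nt sequence, and an ordered set of them.
# A sample_set is a data.frame (id, sequence, label) with a `tag` attribute so
# the usual data.frame verbs keep working.

#' Construct a labelled 41-nt RNA sample
#'
#' A sample is a 41-nt sequence over `{A,C,G,U}` whose central position
#' (0-based index 20) is the candidate cytosine site, with a binary label
#' (1 = 5hmC site, 0 = non-site).
#'
#' @param id Character identifier.
#' @param sequence 41-character string over `{A,C,G,U}`.
#' @param label 0 or 1.
#' @return An object of class `rna_sample`.
#' @export
rna_sample <- function(id, sequence, label) {
  stopifnot(is.character(id), length(id) == 1L)
  label <- as.integer(label)
  validate_sequence(sequence, id)
  if (!label %in% c(0L, 1L)) {
    stop("sample '", id, "': label must be 0 or 1", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, label = label),
            class = "rna_sample")
}

validate_sequence <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("sample '", id, "': sequence must be a single string", call. = FALSE)
  }
  if (nchar(sequence) != SEQ_LEN) {
    stop("sample '", id, "': sequence must have length 41, got ",
         nchar(sequence), call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), RNA_BASES)
  if (length(bad) > 0L) {
    stop("sample '", id, "': invalid symbol(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (chars[CENTER_POS + 1L] != "C") {
    stop("sample '", id, "': central position (0-based 20) must be 'C', got '",
         chars[CENTER_POS + 1L], "'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a sample set
#'
#' An ordered collection of labelled 41-nt samples with a dataset tag.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of 41-nt sequences.
#' @param label Integer vector of 0/1 labels.
#' @param tag One of `"train"`, `"validation"`, `"independent"`, `"unsplit"`.
#' @return A `sample_set`: a data.frame with columns id, sequence, label.
#' @export
sample_set <- function(id = character(), sequence = character(),
                       label = integer(), tag = "unsplit") {
  tag <- match.arg(tag, c("train", "validation", "independent", "unsplit"))
  stopifnot(length(id) == length(sequence), length(id) == length(label))
  if (anyDuplicated(id)) {
    stop("sample ids must be unique within a set; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  label <- as.integer(label)
  for (i in seq_along(id)) {
    validate_sequence(sequence[i], id[i])
    if (!label[i] %in% c(0L, 1L)) {
      stop("sample '", id[i], "': label must be 0 or 1", call. = FALSE)
    }
  }
  structure(
    data.frame(id = as.character(id), sequence = as.character(sequence),
               label = label, stringsAsFactors = FALSE),
    tag = tag, class = c("sample_set", "data.frame")
  )
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples (tag: %s): %d positive, %d negative\n",
              nrow(x), set_tag(x), sum(x$label == 1L), sum(x$label == 0L)))
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Dataset tag of a sample set
#' @param x A `sample_set`.
#' @return Character scalar.
#' @export
set_tag <- function(x) attr(x, "tag") %||% "unsplit"

#' Per-label counts of a sample set
#' @param x A `sample_set`.
#' @return Named integer vector with elements `positive` and `negative`.
#' @export
label_counts <- function(x) {
  c(positive = sum(x$label == 1L), negative = sum(x$label == 0L))
}

subset_samples <- function(x, idx, tag = set_tag(x)) {
  structure(
    data.frame(id = x$id[idx], sequence = x$sequence[idx],
               label = x$label[idx], stringsAsFactors = FALSE),
    tag = tag, class = c("sample_set", "data.frame")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
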