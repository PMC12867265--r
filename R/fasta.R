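# FASTA input/output. Labels travel in the header as a trailing "|1" / "|0"
# token, or in a companion two-column TSV (id <TAB> label).

#' Read a labelled 41-nt FASTA file
#'
#' Reads a FASTA file of fixed-length 41-nt RNA sequences. Labels are taken
#' from a trailing `|1` / `|0` token in each header, or from a two-column
#' TSV file (`id<TAB>label`, no header) given via `labels`. Sequences are
#' normalized with [normalize_alphabet()] (so DNA-alphabet input with `T` is
#' accepted), then validated: length 41, central C, alphabet `{A,C,G,U}`.
#'
#' @param path Path to a FASTA file.
#' @param labels Optional path to a TSV label file; if `NULL`, labels are
#'   parsed from headers.
#' @param tag Dataset tag for the returned set.
#' @return A [sample_set()]; record order is preserved.
#' @export
read_fasta <- function(path, labels = NULL, tag = "unsplit") {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(recs) == 0L) return(sample_set(tag = tag))
  headers <- names(recs)
  seqs <- vapply(as.character(recs), normalize_alphabet, character(1),
                 USE.NAMES = FALSE)
  if (is.null(labels)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    ids <- vapply(parts, function(p) trimws(p[[1L]]), character(1))
    labs <- vapply(parts, function(p) {
      if (length(p) < 2L) return(NA_integer_)
      tok <- trimws(p[[length(p)]])
      if (tok %in% c("0", "1")) as.integer(tok) else NA_integer_
    }, integer(1))
    if (anyNA(labs)) {
      stop("record(s) without a trailing |1 / |0 label token: ",
           paste(utils::head(ids[is.na(labs)], 5L), collapse = ", "),
           "; supply a label TSV instead", call. = FALSE)
    }
  } else {
    ids <- vapply(strsplit(headers, "[| \t]"), `[[`, character(1), 1L)
    lab_tab <- utils::read.table(labels, sep = "\t", header = FALSE,
                                 col.names = c("id", "label"),
                                 colClasses = c("character", "integer"))
    labs <- lab_tab$label[match(ids, lab_tab$id)]
    if (anyNA(labs)) {
      stop("no label found for record(s): ",
           paste(utils::head(ids[is.na(labs)], 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  sample_set(id = ids, sequence = seqs, label = labs, tag = tag)
}

#' Write a sample set as labelled FASTA
#'
#' Headers carry the label as a trailing `|<label>` token, so
#' `read_fasta(write_fasta(x))` reproduces `x` record-for-record.
#'
#' @param x A [sample_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "sample_set"))
  recs <- Biostrings::BStringSet(x$sequence)
  names(recs) <- paste0(x$id, "|", x$label)
  Biostrings::writeXStringSet(recs, filepath = path, width = 80L)
  invisible(path)
}
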