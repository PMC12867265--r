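#' @keywords internal
#' @useDynLib rna5hmc, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# RNA alphabet conventions used throughout the package.
#
# Two distinct orderings coexist and must not be confused:
#  * the integer encoding fed to the word-embedding layer: A=0, C=1, U=2, G=3;
#  * the lexicographic order A < C < G < U used to index all k-mer-based
#    descriptor vectors (downstream feature indices depend on it).

RNA_BASES <- c("A", "C", "G", "U")          # lexicographic order
INT_CODE  <- c(A = 0L, C = 1L, U = 2L, G = 3L)
RC_BASE   <- c(A = "U", C = "G", G = "C", U = "A")

SEQ_LEN    <- 41L
CENTER_POS <- 20L  # 0-based; R index 21

#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases, strips whitespace, and rewrites `T` to `U` (public datasets mix
#' DNA and RNA alphabets; the descriptor and embedding layers assume RNA).
#'
#' @param raw Character scalar.
#' @return Character scalar over `{A,C,G,U}`.
#' @examples
#' normalize_alphabet("acgt")  # "ACGU"
#' @export
normalize_alphabet <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- toupper(gsub("\\s", "", raw))
  s <- chartr("T", "U", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), RNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s
}

#' Integer-encode a 41-nt sequence
#'
#' Maps each nucleotide to the integer code used by the word-embedding layer:
#' A to 0, C to 1, U to 2, G to 3.
#'
#' @param sample An [rna_sample()] or a valid 41-nt sequence string.
#' @return Integer vector of length 41 with values in 0..3.
#' @export
encode_integers <- function(sample) {
  seq <- if (inherits(sample, "rna_sample")) sample$sequence else sample
  chars <- strsplit(seq, "")[[1]]
  codes <- INT_CODE[chars]
  if (anyNA(codes)) {
    stop("cannot integer-encode symbol(s): ",
         paste(unique(chars[is.na(codes)]), collapse = ", "), call. = FALSE)
  }
  unname(codes)
}

#' Decode an integer-encoded sequence back to nucleotides
#'
#' Inverse of [encode_integers()].
#'
#' @param codes Integer vector with values in 0..3.
#' @return Character scalar.
#' @export
decode_integers <- function(codes) {
  stopifnot(all(codes %in% 0:3))
  paste(names(INT_CODE)[match(codes, INT_CODE)], collapse = "")
}

#' Reverse complement of an RNA sequence
#'
#' @param seq Character scalar over `{A,C,G,U}` (A pairs U, C pairs G).
#' @return Character scalar.
#' @export
reverse_complement <- function(seq) {
  chars <- rev(strsplit(seq, "")[[1]])
  paste(RC_BASE[chars], collapse = "")
}
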