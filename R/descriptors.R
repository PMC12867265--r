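# Sequence-based feature descriptors. All k-mer-indexed vectors use the
# lexicographic base order A < C < G < U; downstream feature indices depend on
# this convention. Descriptor functions accept any sequence over {A,C,G,U}
# long enough for their parameters, so small toy sequences can be used to
# cross-check them; on 41-nt input the output lengths are
#   NAC 4, DNC/Kmer 16, TNC 64, RCKmer 10, binary 164, ANF 41, EIIP 41,
#   PseEIIP 64, ENAC 148, NCP 123, DAC 12, PseDNC 18, PCPseDNC 18.

.desc_cache <- new.env(parent = emptyenv())

desc_chars <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), RNA_BASES)
  if (length(bad) > 0L) {
    stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  chars
}

all_kmers <- function(k) {
  out <- RNA_BASES
  if (k > 1L) for (i in 2L:k) out <- paste0(rep(out, each = 4L), RNA_BASES)
  out
}

seq_kmers <- function(chars, k) {
  n <- length(chars) - k + 1L
  if (n < 1L) stop("sequence shorter than k", call. = FALSE)
  if (k == 1L) return(chars)
  vapply(seq_len(n), function(i) paste(chars[i:(i + k - 1L)], collapse = ""),
         character(1))
}

#' k-mer composition (NAC, DNC/Kmer, TNC)
#'
#' Frequencies of the `4^k` k-mers in lexicographic order (A < C < G < U),
#' normalized by the number of k-mer positions, so the vector sums to 1.
#' `k = 1` is the NAC descriptor (length 4), `k = 2` DNC/Kmer (16),
#' `k = 3` TNC (64).
#'
#' @param sequence Sequence string over `{A,C,G,U}`.
#' @param k k-mer size, 1 to 3.
#' @return Named numeric vector of length `4^k`.
#' @export
kmer_composition <- function(sequence, k = 2L) {
  if (k < 1L || k > 3L) stop("k must be in 1..3", call. = FALSE)
  chars <- desc_chars(sequence)
  km <- all_kmers(k)
  obs <- seq_kmers(chars, k)
  counts <- table(factor(obs, levels = km))
  out <- as.numeric(counts) / length(obs)
  names(out) <- km
  out
}

#' Reverse-complement-collapsed k-mer composition (RCKmer)
#'
#' k-mer frequencies merged over reverse-complement equivalence classes
#' (A pairs U, C pairs G); the canonical class representative is the
#' lexicographically smaller of a k-mer and its reverse complement. For
#' `k = 2` there are 10 classes. The vector sums to 1.
#'
#' @inheritParams kmer_composition
#' @return Named numeric vector (class representatives as names).
#' @export
rc_kmer <- function(sequence, k = 2L) {
  freqs <- kmer_composition(sequence, k)
  km <- names(freqs)
  canon <- vapply(km, function(x) min(x, reverse_complement(x)), character(1))
  classes <- sort(unique(canon))
  out <- vapply(classes, function(cl) sum(freqs[canon == cl]), numeric(1))
  names(out) <- classes
  out
}

#' One-hot binary encoding (binary)
#'
#' Concatenation of one one-hot 4-vector per position, in base order
#' A, C, G, U. Length `4 * nchar(sequence)` (164 for 41-nt input).
#'
#' @inheritParams kmer_composition
#' @return Numeric vector.
#' @export
one_hot_binary <- function(sequence) {
  chars <- desc_chars(sequence)
  m <- outer(chars, RNA_BASES, `==`) * 1
  out <- as.numeric(t(m))
  names(out) <- paste0("pos", rep(seq_along(chars), each = 4L), "_",
                       rep(RNA_BASES, length(chars)))
  out
}

#' Accumulated nucleotide frequency (ANF)
#'
#' Element i is the frequency of the nucleotide at position i within the
#' prefix 1..i, i.e. its running prefix density. Length equals the sequence
#' length (41); element 1 is always 1.
#'
#' @inheritParams kmer_composition
#' @return Numeric vector.
#' @export
anf <- function(sequence) {
  chars <- desc_chars(sequence)
  cum <- sapply(RNA_BASES, function(b) cumsum(chars == b))
  out <- cum[cbind(seq_along(chars), match(chars, RNA_BASES))] /
    seq_along(chars)
  names(out) <- paste0("pos", seq_along(chars))
  out
}

eiip_table <- function() {
  if (is.null(.desc_cache$eiip)) {
    path <- system.file("extdata", "eiip_constants.tsv", package = "rna5hmc",
                        mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#")
    .desc_cache$eiip <- stats::setNames(tab$eiip, tab$nucleotide)
  }
  .desc_cache$eiip
}

#' Electron-ion interaction pseudopotential profile (EIIP)
#'
#' Per-position EIIP constant of the nucleotide at that position. Length
#' equals the sequence length (41).
#'
#' @inheritParams kmer_composition
#' @param table Named EIIP constants (A, C, G, U); default the shipped table.
#' @return Numeric vector.
#' @export
eiip_profile <- function(sequence, table = eiip_table()) {
  chars <- desc_chars(sequence)
  out <- unname(table[chars])
  names(out) <- paste0("pos", seq_along(chars))
  out
}

#' Trinucleotide EIIP composition (PseEIIP)
#'
#' For each of the 64 trinucleotides xyz (lexicographic order), the sum of
#' the three constituent EIIP constants times the normalized trinucleotide
#' frequency. Length 64.
#'
#' @inheritParams eiip_profile
#' @return Named numeric vector of length 64.
#' @export
pse_eiip <- function(sequence, table = eiip_table()) {
  f <- kmer_composition(sequence, 3L)
  tnc <- names(f)
  esum <- vapply(strsplit(tnc, ""), function(ch) sum(table[ch]), numeric(1))
  out <- unname(esum) * as.numeric(f)
  names(out) <- tnc
  out
}

#' Enhanced nucleic acid composition (ENAC)
#'
#' Sliding-window nucleotide frequencies: for each window of `window`
#' consecutive positions, the four base frequencies (A, C, G, U) within the
#' window. With window 5 on 41-nt input there are 37 windows, length 148;
#' every 4-block sums to 1.
#'
#' @inheritParams kmer_composition
#' @param window Window width.
#' @return Named numeric vector of length `4 * (L - window + 1)`.
#' @export
enac <- function(sequence, window = 5L) {
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  chars <- desc_chars(sequence)
  if (window > length(chars)) {
    stop("window exceeds sequence length", call. = FALSE)
  }
  n_win <- length(chars) - window + 1L
  ind <- outer(seq_len(n_win), 0:(window - 1L), `+`)
  out <- numeric(4L * n_win)
  for (w in seq_len(n_win)) {
    sub <- chars[ind[w, ]]
    out[(w - 1L) * 4L + 1:4] <- vapply(RNA_BASES,
                                       function(b) sum(sub == b), numeric(1)) /
      window
  }
  names(out) <- paste0("win", rep(seq_len(n_win), each = 4L), "_",
                       rep(RNA_BASES, n_win))
  out
}

# Chemical-property code: (ring structure, hydrogen bond, functional group).
NCP_CODE <- rbind(A = c(1, 1, 1), C = c(0, 1, 0), G = c(1, 0, 0),
                  U = c(0, 0, 1))

#' Nucleotide chemical property encoding (NCP)
#'
#' Per position, the 3-bit chemical-property code (ring structure, hydrogen
#' bond, functional group): A = (1,1,1), C = (0,1,0), G = (1,0,0),
#' U = (0,0,1). Length `3 * L` (123 for 41-nt input).
#'
#' @inheritParams kmer_composition
#' @return Numeric vector.
#' @export
ncp <- function(sequence) {
  chars <- desc_chars(sequence)
  out <- as.numeric(t(NCP_CODE[chars, , drop = FALSE]))
  names(out) <- paste0("pos", rep(seq_along(chars), each = 3L), "_",
                       rep(c("ring", "hbond", "func"), length(chars)))
  out
}

#' Standardized RNA dinucleotide physicochemical property table
#'
#' The six A-form RNA base-step indices (Shift, Slide, Rise, Tilt, Roll,
#' Twist) shipped with the package, each standardized to mean 0 and
#' population variance 1 over the 16 dinucleotides.
#'
#' @return 16 x 6 numeric matrix, rownames the dinucleotides.
#' @export
dinuc_property_table <- function() {
  if (is.null(.desc_cache$props)) {
    path <- system.file("extdata", "rna_dinucleotide_properties.tsv",
                        package = "rna5hmc", mustWork = TRUE)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#")
    m <- as.matrix(tab[, -1L])
    rownames(m) <- tab$dinucleotide
    m <- apply(m, 2L, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
    .desc_cache$props <- m[all_kmers(2L), ]
  }
  .desc_cache$props
}

#' Dinucleotide-based auto covariance (DAC)
#'
#' For each property p and lag g in `1..max_lag`,
#' `DAC(p, g) = mean over i of (P_p(D_i) - Pbar_p) * (P_p(D_(i+g)) - Pbar_p)`
#' where `D_i` are the overlapping dinucleotides of the sequence and
#' `Pbar_p` the mean of property p over them. Output is ordered
#' property-major (all lags of property 1, then property 2, ...); with the
#' six shipped properties and `max_lag = 2` the length is 12.
#'
#' @inheritParams kmer_composition
#' @param max_lag Maximum lag g.
#' @param props Standardized 16 x n_props dinucleotide property matrix.
#' @return Named numeric vector of length `ncol(props) * max_lag`.
#' @export
dac <- function(sequence, max_lag = 2L, props = dinuc_property_table()) {
  if (max_lag < 1L) stop("max_lag must be >= 1", call. = FALSE)
  chars <- desc_chars(sequence)
  dn <- seq_kmers(chars, 2L)
  n <- length(dn)
  if (n - max_lag < 1L) {
    stop("max_lag too large for sequence length", call. = FALSE)
  }
  vals <- props[dn, , drop = FALSE]
  out <- numeric(0)
  nms <- character(0)
  for (p in colnames(props)) {
    v <- vals[, p]
    dev <- v - mean(v)
    for (g in seq_len(max_lag)) {
      i <- seq_len(n - g)
      out <- c(out, sum(dev[i] * dev[i + g]) / (n - g))
      nms <- c(nms, paste0(p, "_lag", g))
    }
  }
  names(out) <- nms
  out
}

#' Pseudo dinucleotide composition (PseDNC / PCPseDNC)
#'
#' First 16 components are normalized dinucleotide frequencies `f` scaled by
#' `1 / (sum(f) + w * sum(theta))`; the last `lam` components are
#' `w * theta_j / (sum(f) + w * sum(theta))`, where `theta_j` is the mean
#' correlation between dinucleotides j steps apart. The `"series"` variant
#' (PseDNC) uses the averaged squared-difference correlation
#' `mean_p (P_p(a) - P_p(b))^2`; the `"parallel"` variant (PCPseDNC) uses
#' averaged per-property products `mean_p P_p(a) * P_p(b)`. Total length
#' `16 + lam` (18 with the default `lam = 2`); the full vector sums to 1.
#'
#' @inheritParams kmer_composition
#' @param lam Number of correlation tiers (lags).
#' @param weight Weight factor w of the correlation components.
#' @param variant `"series"` or `"parallel"`.
#' @param props Standardized dinucleotide property matrix.
#' @return Named numeric vector of length `16 + lam`.
#' @export
pse_dnc <- function(sequence, lam = 2L, weight = 0.05,
                    variant = c("series", "parallel"),
                    props = dinuc_property_table()) {
  variant <- match.arg(variant)
  if (lam < 1L) stop("lam must be >= 1", call. = FALSE)
  chars <- desc_chars(sequence)
  dn <- seq_kmers(chars, 2L)
  n <- length(dn)
  if (n - lam < 1L) stop("lam too large for sequence length", call. = FALSE)
  f <- kmer_composition(sequence, 2L)
  vals <- props[dn, , drop = FALSE]
  theta <- vapply(seq_len(lam), function(j) {
    i <- seq_len(n - j)
    if (variant == "series") {
      mean(rowMeans((vals[i, , drop = FALSE] - vals[i + j, , drop = FALSE])^2))
    } else {
      mean(rowMeans(vals[i, , drop = FALSE] * vals[i + j, , drop = FALSE]))
    }
  }, numeric(1))
  denom <- sum(f) + weight * sum(theta)
  out <- c(as.numeric(f) / denom, weight * theta / denom)
  names(out) <- c(names(f), paste0("theta", seq_len(lam)))
  out
}

#' Registry of the fourteen sequence descriptors
#'
#' Maps each descriptor name to its computing function and the expected
#' output length on 41-nt input.
#'
#' @return Named list; each entry has elements `fn` (function of a sequence
#'   string) and `expected_length`.
#' @export
descriptor_registry <- function() {
  list(
    ANF      = list(fn = anf, expected_length = 41L),
    binary   = list(fn = one_hot_binary, expected_length = 164L),
    DAC      = list(fn = dac, expected_length = 12L),
    DNC      = list(fn = function(s) kmer_composition(s, 2L),
                    expected_length = 16L),
    EIIP     = list(fn = eiip_profile, expected_length = 41L),
    ENAC     = list(fn = enac, expected_length = 148L),
    Kmer     = list(fn = function(s) kmer_composition(s, 2L),
                    expected_length = 16L),
    NAC      = list(fn = function(s) kmer_composition(s, 1L),
                    expected_length = 4L),
    NCP      = list(fn = ncp, expected_length = 123L),
    PCPseDNC = list(fn = function(s) pse_dnc(s, variant = "parallel"),
                    expected_length = 18L),
    PseDNC   = list(fn = function(s) pse_dnc(s, variant = "series"),
                    expected_length = 18L),
    PseEIIP  = list(fn = pse_eiip, expected_length = 64L),
    RCKmer   = list(fn = rc_kmer, expected_length = 10L),
    TNC      = list(fn = function(s) kmer_composition(s, 3L),
                    expected_length = 64L)
  )
}

#' Compute one descriptor for every sample in a set
#'
#' @param data A [sample_set()].
#' @param name Descriptor name as registered in [descriptor_registry()].
#' @return Numeric matrix, one row per sample (rownames = sample ids),
#'   columns named after the descriptor components.
#' @export
descriptor_matrix <- function(data, name) {
  reg <- descriptor_registry()
  if (!name %in% names(reg)) {
    stop("unknown descriptor '", name, "'; registered: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  fn <- reg[[name]]$fn
  rows <- lapply(data$sequence, fn)
  m <- do.call(rbind, rows)
  rownames(m) <- data$id
  m
}
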