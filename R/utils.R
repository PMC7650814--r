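# Internal sequence helpers.  Genomic sequences are plain upper-case character
# scalars over A/C/G/T/N; Biostrings does the heavy lifting where it applies.

#' @useDynLib capstax, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC code -> set of plain bases it stands for
.iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.iupac_letters <- names(.iupac_sets)

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

is_dna <- function(x, allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  !grepl(sprintf("[^%s]", alphabet), x)
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented symbolically (S -> S, R -> Y, ...).
#'
#' @param x a DNA character scalar
#' @return the reverse-complemented string
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# vectorized character-level match test of an IUPAC pattern against a plain
# window of identical length; returns number of mismatching positions
iupac_mismatches <- function(pattern_chars, window_chars) {
  stopifnot(length(pattern_chars) == length(window_chars))
  n_bad <- 0L
  for (i in seq_along(pattern_chars)) {
    set <- .iupac_sets[[pattern_chars[i]]]
    if (is.null(set) || !(window_chars[i] %in% set)) n_bad <- n_bad + 1L
  }
  n_bad
}

iupac_matches <- function(pattern, window) {
  nchar(pattern) == nchar(window) &&
    iupac_mismatches(chars(pattern), chars(window)) == 0L
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 0-based half-open [start, end) substring
substr0 <- function(x, start, end) substr(x, start + 1L, end)

wrap_text <- function(x, width) {
  if (nchar(x) == 0L) return(character(0))
  starts <- seq(1L, nchar(x), by = width)
  vapply(starts, function(s) substr(x, s, min(s + width - 1L, nchar(x))), "")
}
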