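# Interspersed (nontandem) repeat detection by genome self-comparison, and
# cross-genome repeat comparison.
#
# Seeds are exact shared words of length `min_len` between the sequence and
# itself (direct repeats) or its reverse complement (inverted repeats),
# extended ungapped while identity stays at or above `min_identity`.  The
# trivial self-diagonal is discarded, overlapping hits on one diagonal merge
# into their maximal extension, and a repeat occurring more than twice yields
# one entry per unordered copy pair.

#' Find interspersed repeats in a genome
#'
#' @param sequence DNA character scalar
#' @param min_len minimum repeat length in bases; also the exact-seed length
#'   (default 50, the conventional lower bound for recombinogenic organelle
#'   repeats)
#' @param min_identity minimum percent identity between the two copies
#'   (default 99)
#' @return data frame of class `repeat_set`: `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based half-open, copy A always left of copy B), `orientation`
#'   (`direct`/`inverted`), `length`, `identity`; sorted longest-first
#' @export
find_interspersed_repeats <- function(sequence, min_len = 50L,
                                      min_identity = 99) {
  if (min_len < 20L) stop("min_len must be >= 20 (seed reliability)")
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2L * min_len) stop("sequence shorter than twice min_len")

  direct <- local_align(sequence, sequence, min_identity = min_identity,
                        min_length = min_len, word_size = min_len)
  direct <- direct[direct$a_start != direct$b_start, , drop = FALSE]
  # keep each unordered pair once: copy A strictly left of copy B
  direct <- direct[direct$a_start < direct$b_start, , drop = FALSE]
  if (nrow(direct)) direct$orientation <- "direct"

  rc <- revcomp(sequence)
  inv <- local_align(sequence, rc, min_identity = min_identity,
                     min_length = min_len, word_size = min_len)
  if (nrow(inv)) {
    # map the reverse-complement coordinates back to the forward strand
    inv$b_start2 <- L - inv$b_end
    inv$b_end2 <- L - inv$b_start
    inv$b_start <- inv$b_start2; inv$b_end <- inv$b_end2
    inv$b_start2 <- NULL; inv$b_end2 <- NULL
    # each inverted pair appears twice (mirrored); keep the copy-A-left form,
    # and drop the self-hit of a perfect palindrome
    inv <- inv[inv$a_start < inv$b_start |
                 (inv$a_start == inv$b_start & inv$a_end < inv$b_end), ,
               drop = FALSE]
    if (nrow(inv)) inv$orientation <- "inverted"
  }
  out <- rbind(direct, inv)
  if (!nrow(out)) {
    out <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), length = integer(0),
                      identity = numeric(0))
    class(out) <- c("repeat_set", "data.frame")
    return(out)
  }
  out <- out[, c("a_start", "a_end", "b_start", "b_end", "orientation",
                 "length", "identity")]
  out <- unique(out)
  # collapse hits fully contained in a longer one with the same orientation
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    contained <- out$orientation == out$orientation[i] &
      out$a_start <= out$a_start[i] & out$a_end >= out$a_end[i] &
      out$b_start <= out$b_start[i] & out$b_end >= out$b_end[i] &
      (out$length > out$length[i] |
         (out$length == out$length[i] & seq_len(nrow(out)) < i))
    if (any(contained & keep)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$length, out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_set", "data.frame")
  out
}

#' Extract the sequences of repeat copies
#'
#' @param repeats a `repeat_set` from [find_interspersed_repeats()]
#' @param sequence the genome the repeats were found in
#' @return character vector of copy-A sequences, named `repeat_<i>`
#' @export
repeat_sequences <- function(repeats, sequence) {
  if (!nrow(repeats)) return(character(0))
  stats::setNames(
    vapply(seq_len(nrow(repeats)), function(i)
      substr0(sequence, repeats$a_start[i], repeats$a_end[i]), ""),
    sprintf("repeat_%d", seq_len(nrow(repeats))))
}

#' Compare two repeat sets across genomes
#'
#' Every repeat sequence from set A is locally aligned against every repeat
#' sequence from set B; matches at or above `min_identity` are reported with
#' identity and coverage of the shorter repeat.
#'
#' @param repeats_a,repeats_b `repeat_set` data frames
#' @param genome_a,genome_b the sequences the repeat coordinates refer to
#' @param min_identity minimum percent identity (default 90)
#' @param min_length minimum aligned length (default 30)
#' @return data frame: `repeat_a`, `repeat_b`, `aligned_length`, `identity`,
#'   `coverage` (percent of the shorter repeat covered)
#' @export
compare_repeat_sets <- function(repeats_a, genome_a, repeats_b, genome_b,
                                min_identity = 90, min_length = 30L) {
  seqs_a <- repeat_sequences(repeats_a, genome_a)
  seqs_b <- repeat_sequences(repeats_b, genome_b)
  rows <- list()
  for (na in names(seqs_a)) for (nb in names(seqs_b)) {
    hits <- local_align(seqs_a[[na]], seqs_b[[nb]],
                        min_identity = min_identity,
                        min_length = min(min_length, nchar(seqs_a[[na]]),
                                         nchar(seqs_b[[nb]])),
                        word_size = 12L)
    if (!nrow(hits)) next
    best <- hits[which.max(hits$length), ]
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_a = na, repeat_b = nb, aligned_length = best$length,
      identity = best$identity,
      coverage = round(100 * best$length /
                         min(nchar(seqs_a[[na]]), nchar(seqs_b[[nb]])), 1))
  }
  if (!length(rows))
    return(data.frame(repeat_a = character(0), repeat_b = character(0),
                      aligned_length = integer(0), identity = numeric(0),
                      coverage = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a repeat report as TSV
#' @param repeats a `repeat_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_repeat_report <- function(repeats, path) {
  utils::write.table(as.data.frame(repeats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export repeat copies as BED
#'
#' Both copies of every pair, 0-based half-open as BED requires; inverted
#' second copies are written on the minus strand.
#'
#' @param repeats a `repeat_set`
#' @param chrom chromosome/sequence name for the BED records
#' @param path output file
#' @return `path`, invisibly
#' @export
write_repeat_bed <- function(repeats, chrom, path) {
  if (!nrow(repeats)) { writeLines(character(0), path); return(invisible(path)) }
  n <- nrow(repeats)
  bed <- data.frame(
    chrom = chrom,
    start = c(repeats$a_start, repeats$b_start),
    end = c(repeats$a_end, repeats$b_end),
    name = c(sprintf("repeat_%d_a", seq_len(n)),
             sprintf("repeat_%d_b", seq_len(n))),
    score = 0L,
    strand = c(rep("+", n),
               ifelse(repeats$orientation == "inverted", "-", "+")))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
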