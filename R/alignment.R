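# Per-gene multiple alignments: a built-in deterministic progressive aligner,
# an adapter for externally computed aligned FASTA, column/position maps, and
# a seed-and-extend local aligner shared by the repeat and plastid-region
# modules.
#
# Convention: alignment columns are 0-based; ungapped sequence positions are
# 1-based (the coordinate system in which SNP positions are reported).

#' Per-gene multiple alignment
#'
#' @param gene_name gene symbol
#' @param rows named character vector of gapped sequences (gap = `-`), one per
#'   genome id; all the same length
#' @param lineages named list (or NULL) mapping each row id to its taxonomic
#'   lineage
#' @return object of class `gene_alignment` with fields `gene_name`, `rows`,
#'   `n_columns`, `lineages`
#' @export
gene_alignment <- function(gene_name, rows, lineages = NULL) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("alignment rows differ in length: ", paste(unique(widths), collapse = ", "))
  if (anyDuplicated(names(rows))) stop("duplicate row ids")
  if (!is.null(lineages)) {
    missing <- setdiff(names(rows), names(lineages))
    if (length(missing))
      stop("rows without lineage: ", paste(missing, collapse = ", "))
  }
  structure(list(gene_name = gene_name, rows = rows,
                 n_columns = unname(widths[1L]), lineages = lineages),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d rows x %d columns\n",
              x$gene_name, length(x$rows), x$n_columns))
  invisible(x)
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# ---- built-in progressive aligner -----------------------------------------

kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(vapply(1:(n - k + 1L), function(i) substr(s, i, i + k - 1L), ""))
}

profile_of <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  prof <- matrix(0, nrow = 5, ncol = ncol(m),
                 dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (b in rownames(prof)) prof[b, ] <- colMeans(m == b)
  prof
}

#' Build a multiple alignment of gene sequences
#'
#' Deterministic progressive alignment: pairwise k-mer distances, a UPGMA
#' guide tree, then profile-profile alignment with match/mismatch and affine
#' gap scores.  Ties in the guide tree are broken by lexicographic id order.
#'
#' @param sequences named character vector (or list) of >= 2 DNA strings
#' @param lineages optional named list of lineages, one per sequence id
#' @param gene_name label stored on the alignment
#' @param match,mismatch,gap_open,gap_ext alignment scores (defaults +2, -3,
#'   -6, -1)
#' @param k k-mer size for the guide-tree distances (default 6)
#' @return a [gene_alignment()]
#' @export
build_msa <- function(sequences, lineages = NULL, gene_name = "gene",
                      match = 2, mismatch = -3, gap_open = -6, gap_ext = -1,
                      k = 6L) {
  sequences <- unlist(as.list(sequences))
  if (length(sequences) < 2L) stop("need at least 2 sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by genome id")
  if (any(!nzchar(sequences))) stop("empty input sequence")
  sequences <- sequences[order(names(sequences))]
  ids <- names(sequences)
  n <- length(ids)

  sets <- lapply(sequences, kmer_set, k = k)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    denom <- max(1L, min(length(sets[[i]]), length(sets[[j]])))
    D[i, j] <- D[j, i] <- 1 - shared / denom
  }
  clusters <- lapply(seq_len(n), function(i) sequences[i])
  if (n == 2L) {
    merged <- merge_profiles(clusters[[1L]], clusters[[2L]],
                             match, mismatch, gap_open, gap_ext)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    for (r in seq_len(nrow(hc$merge))) {
      pick <- function(x) if (x < 0) clusters[[-x]] else nodes[[x]]
      nodes[[r]] <- merge_profiles(pick(hc$merge[r, 1]), pick(hc$merge[r, 2]),
                                   match, mismatch, gap_open, gap_ext)
    }
    merged <- nodes[[length(nodes)]]
  }
  merged <- merged[order(names(merged))]
  aln <- gene_alignment(gene_name, merged, lineages)
  # invariant: ungapping reproduces the inputs exactly
  stopifnot(identical(ungap(aln$rows[ids]), sequences))
  attr(aln, "guide_tree") <- if (n > 2L) upgma_newick(D) else NULL
  aln
}

merge_profiles <- function(rows_a, rows_b, match, mismatch, gap_open, gap_ext) {
  ops <- .align_profiles_cpp(profile_of(rows_a), profile_of(rows_b),
                             match, mismatch, gap_open, gap_ext)
  ca <- strsplit(rows_a, "", fixed = TRUE)
  cb <- strsplit(rows_b, "", fixed = TRUE)
  ia <- 0L; ib <- 0L
  out_a <- lapply(ca, function(x) character(length(ops)))
  out_b <- lapply(cb, function(x) character(length(ops)))
  for (t in seq_along(ops)) {
    op <- ops[t]
    if (op == 0L || op == 1L) ia <- ia + 1L
    if (op == 0L || op == 2L) ib <- ib + 1L
    for (r in seq_along(out_a))
      out_a[[r]][t] <- if (op == 2L) "-" else ca[[r]][ia]
    for (r in seq_along(out_b))
      out_b[[r]][t] <- if (op == 1L) "-" else cb[[r]][ib]
  }
  res <- c(vapply(out_a, paste, "", collapse = ""),
           vapply(out_b, paste, "", collapse = ""))
  names(res) <- c(names(rows_a), names(rows_b))
  res
}

# diagnostic newick export of the UPGMA guide tree
upgma_newick <- function(D) {
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  lab <- hc$labels
  rec <- function(node) {
    if (node < 0) return(lab[-node])
    sprintf("(%s,%s)", rec(hc$merge[node, 1]), rec(hc$merge[node, 2]))
  }
  paste0(rec(nrow(hc$merge)), ";")
}

# ---- external alignment import --------------------------------------------

#' Import an externally computed aligned FASTA
#'
#' Adapter for alignments produced by an external tool (e.g. PRANK or MAFFT).
#' All records must have identical length; every id must have a lineage when
#' lineages are supplied.
#'
#' @param path aligned FASTA file
#' @param lineages named list of lineages or NULL
#' @param gene_name label; default: file name without extension
#' @return a [gene_alignment()]
#' @export
import_alignment <- function(path, lineages = NULL, gene_name = NULL) {
  seqs <- read_fasta(path)
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned FASTA records differ in length: ", path)
  gene_name <- gene_name %||% sub("\\.[^.]*$", "", basename(path))
  gene_alignment(gene_name, seqs, lineages)
}

#' Write an alignment as aligned FASTA
#' @param aln a [gene_alignment()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_alignment_fasta <- function(aln, path) {
  write_fasta(as.list(aln$rows), path)
}

# ---- column <-> position maps ---------------------------------------------

#' Map between alignment columns and ungapped sequence positions
#'
#' Columns are 0-based, ungapped positions 1-based.  `col2pos` returns the
#' position of the row's base at the column, or `NA` when the row has a gap
#' there; `pos2col` returns the unique column holding that position.  The two
#' directions are mutually inverse away from gaps.
#'
#' @param aln a [gene_alignment()]
#' @param id row id
#' @param index column (for `col2pos`) or position (for `pos2col`)
#' @param direction `"col2pos"` or `"pos2col"`
#' @return integer position/column, or `NA_integer_` for a gap
#' @export
map_position <- function(aln, id, index, direction = c("col2pos", "pos2col")) {
  direction <- match.arg(direction)
  if (!id %in% names(aln$rows)) stop("no such row: ", id)
  cs <- chars(aln$rows[[id]])
  if (direction == "col2pos") {
    if (index < 0L || index >= aln$n_columns)
      stop("column ", index, " out of range [0, ", aln$n_columns, ")")
    if (cs[index + 1L] == "-") return(NA_integer_)
    sum(cs[seq_len(index + 1L)] != "-")
  } else {
    n_pos <- sum(cs != "-")
    if (index < 1L || index > n_pos)
      stop("position ", index, " out of range [1, ", n_pos, "]")
    which(cumsum(cs != "-") == index & cs != "-")[1L] - 1L
  }
}

# ---- local alignment (seed and extend) ------------------------------------

#' Ungapped local alignments between two sequences
#'
#' Seed-and-extend on shared exact words: every diagonal carrying an exact
#' `word_size`-mer match is scanned and match runs are greedily extended
#' through mismatches while the overall identity stays at or above
#' `min_identity`.  Hits shorter than `min_length` are dropped.  Identity is
#' matches over alignment columns x 100, reported to 0.1%.  Alignments are
#' ungapped; an insertion splits a hit in two.
#'
#' @param a,b DNA character scalars (plus strand each; callers handle reverse
#'   complements)
#' @param min_identity minimum percent identity, in (0, 100]
#' @param min_length minimum aligned length in bases
#' @param word_size exact seed length (default 12)
#' @return data frame: `a_start`, `a_end`, `b_start`, `b_end` (0-based
#'   half-open), `length`, `identity`
#' @export
local_align <- function(a, b, min_identity = 90, min_length = 100,
                        word_size = 12L) {
  if (min_identity <= 0 || min_identity > 100)
    stop("min_identity must be in (0, 100]")
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  a <- toupper(a); b <- toupper(b)
  la <- nchar(a); lb <- nchar(b)
  k <- min(word_size, min_length)
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0), identity = numeric(0))
  if (la < k || lb < k) return(empty)

  words_b <- vapply(1:(lb - k + 1L), function(i) substr(b, i, i + k - 1L), "")
  idx_b <- split(seq_along(words_b) - 1L, words_b)  # 0-based starts
  ca <- chars(a); cb <- chars(b)
  diags <- integer(0)
  for (i in 0:(la - k)) {
    w <- substr(a, i + 1L, i + k)
    hits <- idx_b[[w]]
    if (!is.null(hits)) diags <- c(diags, i - hits)
  }
  diags <- sort(unique(diags))
  rows <- list()
  for (d in diags) {
    a0 <- max(0L, d); a1 <- min(la, lb + d)   # overlap on a: [a0, a1)
    if (a1 - a0 < min_length) next
    mvec <- ca[(a0 + 1L):a1] == cb[(a0 - d + 1L):(a1 - d)]
    for (iv in extend_runs(mvec, k, min_identity / 100, min_length)) {
      s <- a0 + iv[1L] - 1L; e <- a0 + iv[2L]
      len <- e - s
      ident <- round(100 * iv[3L] / len, 1)
      rows[[length(rows) + 1L]] <-
        data.frame(a_start = s, a_end = e, b_start = s - d, b_end = e - d,
                   length = len, identity = ident)
    }
  }
  if (!length(rows)) return(empty)
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# From a logical match vector, extend every >=k-match run outwards by
# X-drop scored extension (match +1, mismatch -2, drop 20): each direction
# stops when the running score falls `xdrop` below its running maximum, and
# the hit ends at the maximum.  Returns list of c(start, end, n_matches),
# 1-based inclusive indices into mvec; hits are trimmed to end on matches by
# construction and overlapping extensions are reported once.
extend_runs <- function(mvec, k, min_frac, min_length,
                        ms = 1, mm = -2, xdrop = 20) {
  r <- rle(mvec)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= k)
  if (!length(runs)) return(list())
  n <- length(mvec)
  out <- list(); last_end <- -1L
  for (ri in runs) {
    s0 <- starts[ri]; e0 <- ends[ri]
    if (s0 <= last_end) next  # inside the previous extension
    # rightwards from e0
    best <- 0; sc <- 0; e <- e0
    j <- e0 + 1L
    while (j <= n) {
      sc <- sc + if (mvec[j]) ms else mm
      if (sc > best) { best <- sc; e <- j }
      if (sc < best - xdrop) break
      j <- j + 1L
    }
    # leftwards from s0
    best <- 0; sc <- 0; s <- s0
    j <- s0 - 1L
    while (j >= 1L) {
      sc <- sc + if (mvec[j]) ms else mm
      if (sc > best) { best <- sc; s <- j }
      if (sc < best - xdrop) break
      j <- j - 1L
    }
    nm <- sum(mvec[s:e])
    if (nm / (e - s + 1L) < min_frac) {
      # extension pulled in too many mismatches; fall back to the pure
      # maximal match run (identity 100%)
      s <- s0; e <- e0; nm <- e0 - s0 + 1L
    }
    if (e - s + 1L >= min_length && nm / (e - s + 1L) >= min_frac) {
      out[[length(out) + 1L]] <- c(s, e, nm)
      last_end <- e
    }
  }
  out
}
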