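# Independent brute-force oracles used to check the package's algorithms,
# plus a cached end-to-end pipeline run on the default simulated clade.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# ---- six-frame ORF enumeration (independent of orf_scan) -------------------

oracle_orf_scan <- function(sequence, min_codons, both_strands = TRUE,
                            exclude_nested = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(sequence)
  one_strand <- function(s) {
    cs <- strsplit(s, "")[[1]]
    hits <- list()
    for (start in seq_len(max(0L, length(cs) - 2L))) {
      if (paste(cs[start:(start + 2L)], collapse = "") != "ATG") next
      j <- start
      while (j + 2L <= length(cs)) {
        codon <- paste(cs[j:(j + 2L)], collapse = "")
        if (j > start && codon %in% stops) {
          ncod <- (j + 2L - start + 1L) / 3L
          if (ncod >= min_codons)
            hits[[length(hits) + 1L]] <- c(start - 1L, j + 2L, ncod)
          break
        }
        j <- j + 3L
      }
    }
    hits
  }
  fwd <- one_strand(sequence)
  rows <- lapply(fwd, function(h) data.frame(start = h[1], end = h[2],
                                             strand = "+",
                                             length_codons = h[3]))
  if (both_strands) {
    rc <- one_strand(capstax::revcomp(sequence))
    rows <- c(rows, lapply(rc, function(h)
      data.frame(start = L - h[2], end = L - h[1], strand = "-",
                 length_codons = h[3])))
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length_codons = integer(0)))
  out <- do.call(rbind, rows)
  if (exclude_nested && nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
      if (i == j || out$strand[i] != out$strand[j]) next
      if (out$start[j] <= out$start[i] && out$end[j] >= out$end[i] &&
          (out$start[j] < out$start[i] || out$end[j] > out$end[i]))
        keep[i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- per-column diagnostic-SNP scan (independent of find_taxon_specific_snps)

oracle_snp_scan <- function(aln, members, non_members) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- names(aln$rows)
  hits <- list()
  for (col in seq_len(ncol(m))) {
    bases <- m[, col]
    if (!all(bases %in% c("A", "C", "G", "T"))) next
    mb <- unique(bases[members])
    if (length(mb) != 1L) next
    if (mb %in% bases[non_members]) next
    hits[[length(hits) + 1L]] <-
      data.frame(column = col - 1L, target_allele = mb,
                 alt_alleles = paste(sort(unique(bases[non_members])),
                                     collapse = ","))
  }
  if (!length(hits))
    return(data.frame(column = integer(0), target_allele = character(0),
                      alt_alleles = character(0)))
  do.call(rbind, hits)
}

# ---- IUPAC sliding-window site scan (independent of find_sites) ------------

iupac_tab <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

oracle_find_sites <- function(sequence, enzyme) {
  cs <- strsplit(sequence, "")[[1]]
  window_match <- function(pat, at) {
    pc <- strsplit(pat, "")[[1]]
    all(vapply(seq_along(pc),
               function(k) cs[at + k - 1L] %in% iupac_tab[[pc[k]]], NA))
  }
  len <- nchar(enzyme$recognition)
  out <- list()
  pats <- list(c(enzyme$recognition, "+"))
  if (!enzyme$palindromic)
    pats <- c(pats, list(c(capstax::revcomp(enzyme$recognition), "-")))
  for (p in pats) {
    for (at in seq_len(max(0L, length(cs) - len + 1L))) {
      if (window_match(p[1], at))
        out[[length(out) + 1L]] <- data.frame(position = at - 1L,
                                              strand = p[2])
    }
  }
  if (!length(out))
    return(data.frame(position = integer(0), strand = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- quadratic longest-common-substring repeat scan ------------------------
# Maximal exact repeated substrings >= min_len, direct and inverted, by
# dynamic programming over all position pairs; mirrors the repeat_set layout.

oracle_repeats <- function(sequence, min_len) {
  cs <- strsplit(sequence, "")[[1]]
  n <- length(cs)
  collect <- function(ct, map_b, skip_equal) {
    hits <- list()
    prev <- integer(length(ct))
    for (i in seq_len(n)) {
      cur <- integer(length(ct))
      match_j <- which(ct == cs[i])
      for (j in match_j) {
        if (skip_equal && j == i) next
        cur[j] <- (if (j > 1L) prev[j - 1L] else 0L) + 1L
      }
      # maximal cells: no extension at (i+1, j+1)
      for (j in which(cur >= min_len)) {
        extends <- i < n && j < length(ct) && cs[i + 1L] == ct[j + 1L] &&
          !(skip_equal && (j + 1L) == (i + 1L))
        if (!extends) {
          L <- cur[j]
          hits[[length(hits) + 1L]] <- c(i - L, i, j - L, j)
        }
      }
      prev <- cur
    }
    hits
  }
  rows <- list()
  for (h in collect(cs, identity, skip_equal = TRUE)) {
    a <- h[1:2]; b <- h[3:4]
    if (a[1] > b[1]) { tmp <- a; a <- b; b <- tmp }
    if (a[1] == b[1]) next  # self pair
    rows[[length(rows) + 1L]] <-
      data.frame(a_start = a[1], a_end = a[2], b_start = b[1], b_end = b[2],
                 orientation = "direct", length = a[2] - a[1], identity = 100)
  }
  ct <- strsplit(capstax::revcomp(sequence), "")[[1]]
  for (h in collect(ct, NULL, skip_equal = FALSE)) {
    a <- c(h[1], h[2])
    b <- c(n - h[4], n - h[3])  # map revcomp coords back
    if (a[1] > b[1] || (a[1] == b[1] && a[2] >= b[2])) next  # mirror/self
    rows[[length(rows) + 1L]] <-
      data.frame(a_start = a[1], a_end = a[2], b_start = b[1], b_end = b[2],
                 orientation = "inverted", length = a[2] - a[1],
                 identity = 100)
  }
  if (!length(rows))
    return(data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      orientation = character(0), length = integer(0),
                      identity = numeric(0)))
  out <- unique(do.call(rbind, rows))
  out <- out[order(-out$length, out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- exhaustive optimal pairwise global alignment score --------------------
# Enumerates every pairwise alignment of two short strings and returns the
# best affine-gap score; independent of the DP kernel.

oracle_best_pairwise <- function(a, b, match = 2, mismatch = -3,
                                 gap_open = -6, gap_ext = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev_op) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1L, j + 1L, score + if (ca[i] == cb[j]) match else mismatch, "M")
    if (i <= length(ca))
      rec(i + 1L, j, score + if (prev_op == "A") gap_ext else gap_open, "A")
    if (j <= length(cb))
      rec(i, j + 1L, score + if (prev_op == "B") gap_ext else gap_open, "B")
  }
  rec(1L, 1L, 0, "")
  best
}

score_alignment_pair <- function(ra, rb, match = 2, mismatch = -3,
                                 gap_open = -6, gap_ext = -1) {
  ca <- strsplit(ra, "")[[1]]; cb <- strsplit(rb, "")[[1]]
  sc <- 0; in_a <- FALSE; in_b <- FALSE
  for (t in seq_along(ca)) {
    x <- ca[t]; y <- cb[t]
    if (x == "-" && y == "-") next
    if (x != "-" && y != "-") {
      sc <- sc + if (x == y) match else mismatch
      in_a <- in_b <- FALSE
    } else if (y == "-") {
      sc <- sc + if (in_a) gap_ext else gap_open
      in_a <- TRUE; in_b <- FALSE
    } else {
      sc <- sc + if (in_b) gap_ext else gap_open
      in_b <- TRUE; in_a <- FALSE
    }
  }
  sc
}

# ---- cached end-to-end run on the default simulated clade ------------------

.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (!is.null(.pipeline_cache$run)) return(.pipeline_cache$run)
  sim <- simulate_clade_dataset(clade_model())
  genomes <- sim$genomes
  lineages <- stats::setNames(
    lapply(genomes, function(g) c(g$lineage, g$organism)),
    vapply(genomes, `[[`, "", "id"))
  gene_seqs <- lapply(genomes, function(gn) {
    x <- extract_gene_sequences(gn)
    names(x) <- capstax:::normalize_gene_name(names(x))
    x
  })
  names(gene_seqs) <- names(lineages)
  shared <- shared_genes(genomes)
  alns <- list()
  for (g in shared) {
    if (!all(vapply(gene_seqs, function(x) g %in% names(x), NA))) next
    alns[[g]] <- build_msa(vapply(gene_seqs, `[[`, "", g),
                           lineages = lineages, gene_name = g)
  }
  snps <- list(); markers <- list()
  for (taxon in c("Fagus", "Fagaceae", "Fagales")) {
    q <- suppressWarnings(taxon_query(taxon, lineages))
    st <- find_taxon_specific_snps(alns, q)
    sc <- st[st$conserved, , drop = FALSE]
    snps[[taxon]] <- st
    markers[[taxon]] <- design_caps_markers(sc, alns, default_enzymes())
  }
  .pipeline_cache$run <- list(sim = sim, lineages = lineages, alns = alns,
                              snps = snps, markers = markers)
  .pipeline_cache$run
}
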