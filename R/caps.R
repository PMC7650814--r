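# CAPS marker design: restriction enzymes with IUPAC recognition sites and
# Type IIS cut geometry, site finding, linear digestion, in-silico PCR, and
# the SNP -> marker design search.
#
# Digestion is modeled by top-strand cut coordinates only: overhangs do not
# change fragment lengths on a gel, which is the assay's readout.  A Type IIS
# cut whose coordinate falls outside the molecule does not cut.

#' Restriction enzyme
#'
#' @param name enzyme name
#' @param recognition recognition sequence over the IUPAC alphabet
#' @param cut_top top-strand cut offset: number of bases from the recognition
#'   start to the cut (may exceed the site length for downstream cutters)
#' @param cut_bottom bottom-strand cut offset, same convention (measured on
#'   the top strand from the recognition start for within-site cutters; for
#'   `(t/b)` cutters it is `length + b`)
#' @return object of class `restriction_enzyme`
#' @export
restriction_enzyme <- function(name, recognition, cut_top, cut_bottom = NULL) {
  recognition <- toupper(recognition)
  bad <- setdiff(chars(recognition), .iupac_letters)
  if (length(bad))
    stop("enzyme ", name, ": invalid IUPAC letter(s) ",
         paste(unique(bad), collapse = ", "))
  len <- nchar(recognition)
  palindromic <- identical(recognition, revcomp(recognition))
  if (is.null(cut_bottom)) cut_bottom <- len - cut_top
  if (cut_top < 0L) stop("enzyme ", name, ": cut_top out of range")
  structure(list(name = name, recognition = recognition,
                 cut_top = as.integer(cut_top),
                 cut_bottom = as.integer(cut_bottom),
                 palindromic = palindromic),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s %s (top cut %d, bottom cut %d%s)\n",
              x$name, x$recognition, x$cut_top, x$cut_bottom,
              if (x$palindromic) ", palindromic" else ""))
  invisible(x)
}

#' Parse a restriction-enzyme table
#'
#' Two-column TSV: name, recognition pattern.  Two REBASE-style notations are
#' accepted: a caret inside the site (`G^AATTC`) for within-site cutters, or
#' a `(t/b)` suffix (`CGTCTC(1/5)`) for enzymes cutting downstream of an
#' asymmetric site, where `t` and `b` are the top- and bottom-strand cut
#' distances past the 3' end of the recognition sequence.
#'
#' @param path TSV file; lines starting with `#` are ignored
#' @return list of [restriction_enzyme()]
#' @export
parse_enzyme_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("enzyme table line lacks a pattern column: '", l, "'")
    parse_enzyme_pattern(f[1L], f[2L])
  })
}

parse_enzyme_pattern <- function(name, pattern) {
  has_caret <- grepl("^", pattern, fixed = TRUE)
  has_tb <- grepl("\\(-?\\d+/-?\\d+\\)$", pattern)
  if (has_caret && has_tb)
    stop("enzyme ", name, ": caret and (t/b) notation are mutually exclusive")
  if (has_caret) {
    cut_top <- regexpr("^", pattern, fixed = TRUE) - 1L
    recognition <- sub("^", "", pattern, fixed = TRUE)
    restriction_enzyme(name, recognition, cut_top)
  } else if (has_tb) {
    m <- regmatches(pattern, regexec("^([A-Za-z]+)\\((-?\\d+)/(-?\\d+)\\)$",
                                     pattern))[[1L]]
    if (length(m) != 4L) stop("enzyme ", name, ": cannot parse '", pattern, "'")
    recognition <- m[2L]
    len <- nchar(recognition)
    restriction_enzyme(name, recognition,
                       cut_top = len + as.integer(m[3L]),
                       cut_bottom = len + as.integer(m[4L]))
  } else {
    stop("enzyme ", name, ": pattern '", pattern,
         "' has neither a caret nor a (t/b) suffix")
  }
}

#' Bundled default enzyme table
#'
#' Includes the four enzymes used by the validated marker set (NciI, BstXI,
#' SfcI, BsmBI) plus common six-cutters.
#'
#' @return list of [restriction_enzyme()]
#' @export
default_enzymes <- function() {
  parse_enzyme_table(system.file("extdata", "enzymes.tsv", package = "capstax",
                                 mustWork = TRUE))
}

#' Find recognition sites of an enzyme in a sequence
#'
#' Matches of the IUPAC recognition on the plus strand, and of its reverse
#' complement reported as minus-strand sites.  For palindromic enzymes only
#' the plus-strand report is emitted (both would be identical).
#'
#' @param sequence DNA character scalar over A/C/G/T
#' @param enzyme a [restriction_enzyme()]
#' @return data frame with `position` (0-based recognition start) and `strand`
#' @export
find_sites <- function(sequence, enzyme) {
  sequence <- toupper(sequence)
  subj <- Biostrings::DNAString(sequence)
  hit_starts <- function(pat) {
    if (nchar(pat) > nchar(sequence)) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = "subject"))
  }
  plus <- hit_starts(enzyme$recognition) - 1L
  out <- data.frame(position = plus,
                    strand = rep("+", length(plus)))
  if (!enzyme$palindromic) {
    minus <- hit_starts(revcomp(enzyme$recognition)) - 1L
    out <- rbind(out, data.frame(position = minus,
                                 strand = rep("-", length(minus))))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest a linear molecule
#'
#' Top-strand cut coordinates are computed for every recognition site with
#' strand-appropriate offsets; cuts outside `[1, L-1]` are discarded (a
#' downstream cutter whose cut coordinate falls off the molecule does not
#' cut).  The unique sorted cuts partition the sequence.
#'
#' @param sequence DNA character scalar
#' @param enzyme a [restriction_enzyme()]
#' @return integer vector of fragment lengths, largest first; `L` itself when
#'   there is no cut
#' @export
digest_linear <- function(sequence, enzyme) {
  L <- nchar(sequence)
  sites <- find_sites(sequence, enzyme)
  len <- nchar(enzyme$recognition)
  cuts <- integer(0)
  if (nrow(sites)) {
    plus <- sites$position[sites$strand == "+"]
    cuts <- c(cuts, plus + enzyme$cut_top)
    if (enzyme$palindromic) {
      # single coordinate per palindromic site (top cut)
    } else {
      minus <- sites$position[sites$strand == "-"]
      cuts <- c(cuts, minus + len - enzyme$cut_bottom)
    }
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts <= L - 1L]))
  sort(diff(c(0L, cuts, L)), decreasing = TRUE)
}

# ---- in-silico PCR ---------------------------------------------------------

primer_binding_sites <- function(template_dna, primer, max_mismatches,
                                 three_prime_first) {
  # returns 0-based start positions of windows where the primer binds
  hits <- Biostrings::matchPattern(primer, template_dna,
                                   max.mismatch = max_mismatches,
                                   fixed = "subject")
  starts <- Biostrings::start(hits)
  if (!length(starts)) return(integer(0))
  tmpl <- as.character(template_dna)
  pc <- chars(primer)
  keep <- vapply(starts, function(s) {
    idx <- if (three_prime_first) s else s + length(pc) - 1L
    p_idx <- if (three_prime_first) 1L else length(pc)
    substr(tmpl, idx, idx) %in% .iupac_sets[[pc[p_idx]]]
  }, NA)
  starts[keep] - 1L
}

#' In-silico PCR on a linear template
#'
#' The forward primer is matched on the plus strand and the reverse primer's
#' reverse complement downstream of it, each with at most `max_mismatches`
#' mismatches and an exactly matching 3'-terminal base.  The amplicon spans
#' the forward-primer start through the end of the reverse-primer binding
#' site, inclusive.
#'
#' @param template DNA character scalar
#' @param fwd,rev primer sequences (>= 12 bases, IUPAC allowed), written
#'   5'->3' as ordered
#' @param max_mismatches mismatch tolerance per primer (3' base always exact)
#' @return the amplicon DNA string
#' @section Errors: signals a condition of class `pcr_no_product` when no
#'   primer pair placement amplifies and `pcr_multiple_products` when more
#'   than one distinct product would form.
#' @export
insilico_pcr <- function(template, fwd, rev, max_mismatches = 0L) {
  if (nchar(fwd) < 12L || nchar(rev) < 12L) stop("primers must be >= 12 bases")
  template <- toupper(template)
  tdna <- Biostrings::DNAString(template)
  f_starts <- primer_binding_sites(tdna, toupper(fwd), max_mismatches,
                                   three_prime_first = FALSE)
  rc <- revcomp(toupper(rev))
  r_starts <- primer_binding_sites(tdna, rc, max_mismatches,
                                   three_prime_first = TRUE)
  products <- character(0)
  for (i in f_starts) for (j in r_starts) {
    if (j >= i + nchar(fwd)) {
      end <- j + nchar(rc)
      products <- c(products, substr0(template, i, end))
    }
  }
  products <- unique(products)
  if (length(products) == 0L)
    stop(errorCondition("no PCR product for this primer pair",
                        class = c("pcr_no_product", "error", "condition")))
  if (length(products) > 1L)
    stop(errorCondition(sprintf("%d distinct PCR products", length(products)),
                        class = c("pcr_multiple_products", "error", "condition")))
  products
}

# ---- design constraints and the design search ------------------------------

#' CAPS design constraints
#'
#' @param max_amplicon maximum amplicon length in bases (default 200; short
#'   amplicons stay amplifiable from degraded DNA such as processed wood)
#' @param primer_len_min,primer_len_max primer window length range (18-25)
#' @param budget_target maximum primer mismatches against target-taxon rows
#'   (default 0)
#' @param budget_non_target maximum primer mismatches against all other rows
#'   (default 2)
#' @param min_fragment smallest reportable digestion fragment in bases
#'   (default 40; smaller bands are unreliable on agarose)
#' @return object of class `design_constraints`
#' @export
design_constraints <- function(max_amplicon = 200L, primer_len_min = 18L,
                               primer_len_max = 25L, budget_target = 0L,
                               budget_non_target = 2L, min_fragment = 40L) {
  stopifnot(max_amplicon > 0, primer_len_min > 0,
            primer_len_max >= primer_len_min,
            budget_target >= 0, budget_non_target >= budget_target,
            min_fragment > 0)
  structure(list(max_amplicon = as.integer(max_amplicon),
                 primer_len_min = as.integer(primer_len_min),
                 primer_len_max = as.integer(primer_len_max),
                 budget_target = as.integer(budget_target),
                 budget_non_target = as.integer(budget_non_target),
                 min_fragment = as.integer(min_fragment)),
            class = "design_constraints")
}

#' Design CAPS markers from taxon-specific SNPs
#'
#' For every SNP x enzyme pair, each placement of the recognition window over
#' the SNP on the member consensus is tested: accepted if the site matches
#' with the target allele (either strand) and fails for every alternative
#' allele.  An amplicon of at most `max_amplicon` bases is then chosen around
#' the SNP whose forward and reverse primer windows are gap-free alignment
#' blocks meeting the mismatch budget (at most `budget_target` mismatches
#' against target-taxon rows, `budget_non_target` elsewhere) — this also
#' operationalizes the requirement that the SNP not lie close to a gene end,
#' since both windows must fit inside the gene.  The accepted design must
#' digest the target-allele amplicon into fragments of at least
#' `min_fragment` bases while every alternative-allele amplicon stays uncut
#' (which also excludes any constitutive second site of the enzyme inside
#' the amplicon).
#'
#' @param snps a `snp_table` from [find_taxon_specific_snps()]
#' @param alignments list of [gene_alignment()] covering the SNPs' genes, each
#'   with lineages (used to classify rows into target and non-target)
#' @param enzymes list of [restriction_enzyme()]
#' @param constraints a [design_constraints()]
#' @return list of `caps_marker` objects (possibly empty); each has fields
#'   `name`, `gene`, `taxon`, `snp` (the SNP row), `enzyme`, `amplicon`,
#'   `amplicon_columns`, `fwd_primer`, `rev_primer`, `fragments_target`,
#'   `fragments_alt` (named list per alternative allele)
#' @export
design_caps_markers <- function(snps, alignments, enzymes,
                                constraints = design_constraints()) {
  stopifnot(length(enzymes) > 0)
  snps_df <- as.data.frame(snps)
  by_gene <- stats::setNames(alignments,
                             vapply(alignments, `[[`, "", "gene_name"))
  markers <- list()
  ctx_cache <- list()
  for (si in seq_len(nrow(snps_df))) {
    snp <- snps_df[si, ]
    aln <- by_gene[[snp$gene]]
    if (is.null(aln)) stop("no alignment for gene '", snp$gene, "'")
    if (is.null(aln$lineages))
      stop("alignment '", snp$gene, "' has no lineages")
    key <- paste(snp$gene, snp$target_taxon)
    if (is.null(ctx_cache[[key]])) {
      q <- suppressWarnings(taxon_query(snp$target_taxon, aln$lineages))
      ctx_cache[[key]] <- design_context(aln, q)
    }
    for (enz in enzymes) {
      mk <- design_one_marker(snp, aln, ctx_cache[[key]], enz, constraints)
      if (!is.null(mk)) markers[[length(markers) + 1L]] <- mk
    }
  }
  markers
}

# per-(alignment, taxon) precomputation shared across the enzyme loop:
# member consensus (majority, ties by base order), gap-free column masks,
# and per-row mismatch-vs-consensus indicators
design_context <- function(aln, query) {
  m <- .aln_matrix(aln)
  ids <- rownames(m)
  mem <- intersect(ids, query$members)
  non <- intersect(ids, query$non_members)
  consensus <- apply(m[mem, , drop = FALSE], 2L, function(cc) {
    tab <- sort(table(cc), decreasing = TRUE)
    sort(names(tab)[tab == max(tab)])[1L]
  })
  list(m = m, mem = mem, non = non, consensus = consensus,
       gapfree_all_col = colSums(m == "-") == 0L,
       gapfree_mem_col = colSums(m[mem, , drop = FALSE] == "-") == 0L,
       mmrow = t(t(m) != consensus))
}

design_one_marker <- function(snp, aln, ctx, enzyme, constraints) {
  mem <- ctx$mem; non <- ctx$non
  col <- snp$column
  alts <- strsplit(snp$alt_alleles, ",", fixed = TRUE)[[1L]]
  len <- nchar(enzyme$recognition)
  nc <- aln$n_columns
  consensus <- ctx$consensus
  mmrow <- ctx$mmrow
  gapfree_mem <- function(jj) all(ctx$gapfree_mem_col[jj + 1L])
  gapfree_all <- function(jj) all(ctx$gapfree_all_col[jj + 1L])

  # 1. discriminative placement of the recognition window over the SNP;
  # record the top-strand cut coordinate implied by the matching strand
  placement <- NULL
  cut_col <- NULL
  for (o in max(0L, col - len + 1L):min(col, nc - len)) {
    jj <- o:(o + len - 1L)
    if (!gapfree_mem(jj)) next
    win <- consensus[jj + 1L]
    win[jj == col] <- snp$target_allele
    ws <- paste(win, collapse = "")
    plus_hit <- iupac_matches(enzyme$recognition, ws)
    minus_hit <- !enzyme$palindromic &&
      iupac_matches(revcomp(enzyme$recognition), ws)
    if (!plus_hit && !minus_hit) next
    alt_safe <- all(vapply(alts, function(a) {
      w <- win; w[jj == col] <- a
      was <- paste(w, collapse = "")
      !iupac_matches(enzyme$recognition, was) &&
        !iupac_matches(revcomp(enzyme$recognition), was)
    }, NA))
    if (alt_safe) {
      placement <- c(o, o + len)
      cut_col <- if (plus_hit) o + enzyme$cut_top
                 else o + len - enzyme$cut_bottom
      break
    }
  }
  if (is.null(placement)) return(NULL)

  # 2. primer windows (gap-free blocks meeting the mismatch budget) and
  # fragment validation, searched jointly: amplicons nearest the site are
  # tried first and grown until the digestion pattern is acceptable
  budget_ok <- function(jj) {
    if (any(jj < 0L) || any(jj >= nc) || !gapfree_all(jj)) return(NULL)
    mm <- rowSums(mmrow[, jj + 1L, drop = FALSE])
    if (any(mm[mem] > constraints$budget_target)) return(NULL)
    if (any(mm[non] > constraints$budget_non_target)) return(NULL)
    paste(consensus[jj + 1L], collapse = "")
  }
  validate_amplicon <- function(amp_cols) {
    if (!gapfree_mem(amp_cols)) return(NULL)
    amp_chars <- consensus[amp_cols + 1L]
    snp_off <- which(amp_cols == col)
    amp_chars[snp_off] <- snp$target_allele
    amplicon <- paste(amp_chars, collapse = "")
    frag_t <- digest_linear(amplicon, enzyme)
    if (length(frag_t) < 2L) return(NULL)
    if (any(frag_t < constraints$min_fragment)) return(NULL)
    frag_a <- lapply(alts, function(a) {
      w <- amp_chars; w[snp_off] <- a
      digest_linear(paste(w, collapse = ""), enzyme)
    })
    names(frag_a) <- alts
    if (!all(vapply(frag_a, function(fr)
      length(fr) == 1L && fr == nchar(amplicon), NA))) return(NULL)
    list(amplicon = amplicon, fragments_target = frag_t, fragments_alt = frag_a)
  }
  # both target fragments must reach min_fragment, which bounds the primer
  # windows relative to the cut coordinate
  best <- NULL
  for (lp in constraints$primer_len_min:constraints$primer_len_max) {
    f_hi <- min(placement[1L] - lp, cut_col - constraints$min_fragment)
    f_lo <- max(0L, placement[2L] + lp - constraints$max_amplicon,
                cut_col + constraints$min_fragment - constraints$max_amplicon)
    if (f_hi < f_lo) next
    for (f in seq(f_hi, f_lo, by = -1L)) {
      fwd <- budget_ok(f:(f + lp - 1L))
      if (is.null(fwd)) next
      r_lo <- max(placement[2L], cut_col + constraints$min_fragment - lp)
      r_hi <- f + constraints$max_amplicon - lp
      if (r_hi < r_lo) next
      for (r0 in seq(r_lo, r_hi)) {
        if (r0 + lp > nc) break
        rev <- budget_ok(r0:(r0 + lp - 1L))
        if (is.null(rev)) next
        val <- validate_amplicon(f:(r0 + lp - 1L))
        if (is.null(val)) next
        best <- c(list(f = f, r0 = r0, lp = lp, fwd = fwd, rev = rev), val)
        break
      }
      if (!is.null(best)) break
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) return(NULL)

  structure(list(
    name = sprintf("%s_%s", snp$target_taxon, snp$gene),
    gene = snp$gene, taxon = snp$target_taxon, snp = snp,
    enzyme = enzyme, amplicon = best$amplicon,
    amplicon_columns = c(best$f, best$r0 + best$lp),
    fwd_primer = best$fwd, rev_primer = revcomp(best$rev),
    fragments_target = best$fragments_target,
    fragments_alt = best$fragments_alt),
    class = "caps_marker")
}

#' @export
print.caps_marker <- function(x, ...) {
  cat(sprintf("<caps_marker> %s: %s %s at column %d, %s, %d bp amplicon\n  fragments %s (target) / %s (others)\n",
              x$name, x$snp$target_allele, paste0("vs ", x$snp$alt_alleles),
              x$snp$column, x$enzyme$name, nchar(x$amplicon),
              paste(x$fragments_target, collapse = "+"),
              paste(unique(vapply(x$fragments_alt, paste, "", collapse = "+")),
                    collapse = ";")))
  invisible(x)
}

#' Write a CAPS marker report as TSV
#'
#' One row per marker, mirroring the layout of published CAPS marker tables:
#' marker name, taxon, gene, reference position, target/alternative alleles,
#' enzyme, fragment sizes (target/others), amplicon length and primers.
#'
#' @param markers list of `caps_marker`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_marker_report <- function(markers, path) {
  rows <- lapply(markers, function(x) data.frame(
    marker = x$name, taxon = x$taxon, gene = x$gene,
    ref_pos = x$snp$ref_pos,
    alleles = sprintf("%s/%s", x$snp$target_allele, x$snp$alt_alleles),
    enzyme = x$enzyme$name,
    fragments = sprintf("%s/%s",
                        paste(x$fragments_target, collapse = ","),
                        paste(unique(unlist(x$fragments_alt)), collapse = ",")),
    amplicon_bp = nchar(x$amplicon),
    fwd_primer = x$fwd_primer, rev_primer = x$rev_primer,
    stringsAsFactors = FALSE))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(0), taxon = character(0), gene = character(0),
               ref_pos = integer(0), alleles = character(0),
               enzyme = character(0), fragments = character(0),
               amplicon_bp = integer(0), fwd_primer = character(0),
               rev_primer = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write marker amplicons as FASTA
#' @param markers list of `caps_marker`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_marker_amplicons <- function(markers, path) {
  seqs <- stats::setNames(lapply(markers, `[[`, "amplicon"),
                          vapply(markers, `[[`, "", "name"))
  write_fasta(seqs, path)
}
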