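# Taxon-diagnostic SNP calling from per-gene multiple alignments.
#
# At every alignment column the taxon is determined for which a base is
# characteristic: all members of the queried taxon share one base and no
# non-member carries it.  Columns with a gap or ambiguity code in any row are
# ineligible — a diagnostic allele must be unambiguous in every taxon.  A SNP
# is flagged "conserved" when both flanks pass the conserved-region filter,
# which is what makes primer design across a broad taxonomic range possible.

#' Define a taxon query over a set of lineages
#'
#' Membership is derived by matching `taxon_name` (case-insensitively) against
#' any rank of each lineage or against the organism name itself.
#'
#' @param taxon_name taxon of interest at any rank (e.g. a genus, family or
#'   order name)
#' @param lineages named list: genome id -> character vector of taxon names
#' @return object of class `taxon_query` with `taxon_name`, `members`,
#'   `non_members`
#' @export
taxon_query <- function(taxon_name, lineages) {
  stopifnot(length(lineages) > 0, !is.null(names(lineages)))
  is_member <- vapply(lineages, function(lin)
    tolower(taxon_name) %in% tolower(lin), NA)
  members <- names(lineages)[is_member]
  non_members <- names(lineages)[!is_member]
  if (!length(members))
    stop("no genome belongs to taxon '", taxon_name, "'")
  if (!length(non_members))
    stop("every genome belongs to taxon '", taxon_name,
         "'; an outgroup is required")
  if (length(members) == 1L)
    warning("taxon '", taxon_name, "' has a single member genome (",
            members, "): taxon-level specificity is extrapolated from one ",
            "sequence", call. = FALSE)
  structure(list(taxon_name = taxon_name, members = members,
                 non_members = non_members), class = "taxon_query")
}

#' @export
print.taxon_query <- function(x, ...) {
  cat(sprintf("<taxon_query> %s: %d member(s) vs %d non-member(s)\n",
              x$taxon_name, length(x$members), length(x$non_members)))
  invisible(x)
}

#' Conserved-flank filter for a candidate SNP column
#'
#' A column passes when each flank of `flank_width` columns (the SNP column
#' excluded) lies fully inside the alignment, is gap-free in every row, and
#' has at least `min_monomorphic` percent monomorphic columns.  A flank
#' truncated by the alignment end is a failure, not a shorter flank.
#'
#' @param aln a [gene_alignment()]
#' @param column 0-based alignment column
#' @param flank_width flank width in columns (default 20)
#' @param min_monomorphic minimum percent of monomorphic columns per flank
#'   (default 90)
#' @return `TRUE` or `FALSE`
#' @export
conserved_flank_filter <- function(aln, column, flank_width = 20L,
                                   min_monomorphic = 90) {
  if (flank_width < 1L) stop("flank_width must be >= 1")
  if (column < 0L || column >= aln$n_columns)
    stop("column ", column, " out of range")
  if (column - flank_width < 0L || column + flank_width >= aln$n_columns)
    return(FALSE)
  m <- .aln_matrix(aln)
  check_flank <- function(cols) {
    sub <- m[, cols + 1L, drop = FALSE]
    if (any(sub == "-")) return(FALSE)
    mono <- vapply(seq_len(ncol(sub)),
                   function(j) length(unique(sub[, j])) == 1L, NA)
    100 * mean(mono) >= min_monomorphic
  }
  check_flank((column - flank_width):(column - 1L)) &&
    check_flank((column + 1L):(column + flank_width))
}

.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  m
}

#' Find taxon-specific SNPs in per-gene alignments
#'
#' For each alignment and each column where (a) no row has a gap or non-ACGT
#' base, (b) every member of the target taxon shares one base, and (c) no
#' non-member carries that base, a candidate SNP is emitted.  The alternative
#' alleles are exactly the bases observed among non-members.  Per-genome
#' 1-based gene positions are attached, and each SNP is flagged by the
#' conserved-flank filter.
#'
#' @param alignments list of [gene_alignment()]; every row id must be
#'   classifiable by `query`
#' @param query a [taxon_query()]
#' @param flank_width,min_monomorphic conservation-filter settings, see
#'   [conserved_flank_filter()]
#' @param reference_id row id in whose gene coordinates the `ref_pos` column
#'   is reported (default: first non-member, mirroring the convention of
#'   reporting against an outgroup reference); falls back to the first row
#' @return object of class `snp_table`: a data frame with columns `gene`,
#'   `column` (0-based), `target_taxon`, `target_allele`, `alt_alleles`
#'   (comma-separated), `ref_id`, `ref_pos`, `conserved`, plus a `positions`
#'   attribute (list of per-genome position maps, one per SNP)
#' @export
find_taxon_specific_snps <- function(alignments, query, flank_width = 20L,
                                     min_monomorphic = 90,
                                     reference_id = NULL) {
  stopifnot(inherits(query, "taxon_query"))
  if (inherits(alignments, "gene_alignment")) alignments <- list(alignments)
  rows_out <- list()
  positions <- list()
  for (aln in alignments) {
    ids <- names(aln$rows)
    unknown <- setdiff(ids, c(query$members, query$non_members))
    if (length(unknown))
      stop("alignment '", aln$gene_name, "' has rows outside the query: ",
           paste(unknown, collapse = ", "))
    mem <- intersect(ids, query$members)
    non <- intersect(ids, query$non_members)
    if (!length(mem) || !length(non)) next
    m <- .aln_matrix(aln)
    for (col in 0:(aln$n_columns - 1L)) {
      bases <- m[, col + 1L]
      if (any(!bases %in% c("A", "C", "G", "T"))) next
      mb <- unique(bases[mem])
      if (length(mb) != 1L) next
      alt <- unique(bases[non])
      if (mb %in% alt) next
      conserved <- conserved_flank_filter(aln, col, flank_width, min_monomorphic)
      pos <- vapply(ids, function(id) map_position(aln, id, col, "col2pos"), 0L)
      ref <- reference_id %||% if (length(non)) non[1L] else ids[1L]
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        gene = aln$gene_name, column = col, target_taxon = query$taxon_name,
        target_allele = mb,
        alt_alleles = paste(sort(alt), collapse = ","),
        ref_id = ref, ref_pos = unname(pos[ref]),
        conserved = conserved, stringsAsFactors = FALSE)
      positions[[length(positions) + 1L]] <- pos
    }
  }
  out <- if (length(rows_out)) do.call(rbind, rows_out) else
    data.frame(gene = character(0), column = integer(0),
               target_taxon = character(0), target_allele = character(0),
               alt_alleles = character(0), ref_id = character(0),
               ref_pos = integer(0), conserved = logical(0))
  o <- order(out$gene, out$column)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "positions") <- positions[o]
  class(out) <- c("snp_table", "data.frame")
  out
}

#' Summarize a SNP table by target taxon
#'
#' @param object a `snp_table` from [find_taxon_specific_snps()]
#' @param conserved_only count only SNPs passing the conservation filter
#'   (default TRUE, matching how headline counts are reported)
#' @param ... unused
#' @return data frame with `target_taxon`, `n_snps`, `n_genes`
#' @method summary snp_table
#' @export
summary.snp_table <- function(object, conserved_only = TRUE, ...) {
  df <- as.data.frame(object)
  if (conserved_only) df <- df[df$conserved, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(target_taxon = character(0), n_snps = integer(0),
                      n_genes = integer(0)))
  agg <- lapply(split(df, df$target_taxon), function(d)
    data.frame(target_taxon = d$target_taxon[1L], n_snps = nrow(d),
               n_genes = length(unique(d$gene))))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Write a SNP report as TSV
#'
#' Columns: gene, column, reference-row position, target taxon, target
#' allele, alternative alleles, conserved flag.
#'
#' @param snps a `snp_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_snp_report <- function(snps, path) {
  df <- as.data.frame(snps)[, c("gene", "column", "ref_id", "ref_pos",
                                "target_taxon", "target_allele",
                                "alt_alleles", "conserved")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
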